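#' Gate configuration for the MIFC pollen cascade
#'
#' Numeric ranges for the stepwise imaging-flow-cytometry gating cascade
#' used to isolate single, in-focus, fertile pollen images: a diameter gate
#' (removes debris and non-pollen objects), brightfield and median pixel
#' intensity gates (remove aborted pollen), symmetry gates (remove stacked
#' pollen) and focus gates on correlation mean and gradient RMS (remove
#' blurred images). All ranges are closed intervals: endpoints pass.
#' Brightfield intensities are background-subtracted and may be negative.
#'
#' @param diameter_range um, default [20, 100].
#' @param brightfield_range a.u., default [-1.2e6, -3e5].
#' @param median_pixel_range a.u., default [-500, -100].
#' @param symmetry3_range,symmetry4_range a.u., default [0, 3].
#' @param correlation_mean_range a.u., default [0.2, 0.6].
#' @param gradient_rms_range a.u., default [8, 19].
#' @param min_particles_per_individual individuals with fewer retained
#'   particles are dropped entirely; default 50.
#' @param trim_quantiles pooled pollen-length quantiles outside which
#'   particles are trimmed; default [0.01, 0.99].
#' @param trim_scope \code{"pooled"} computes the trim quantiles over all
#'   retained particles (default); \code{"per_individual"} computes them
#'   within each individual.
#'
#' @return An object of class \code{gate_config}.
#' @export
gate_config <- function(diameter_range = c(20, 100),
                        brightfield_range = c(-1.2e6, -3e5),
                        median_pixel_range = c(-500, -100),
                        symmetry3_range = c(0, 3),
                        symmetry4_range = c(0, 3),
                        correlation_mean_range = c(0.2, 0.6),
                        gradient_rms_range = c(8, 19),
                        min_particles_per_individual = 50L,
                        trim_quantiles = c(0.01, 0.99),
                        trim_scope = c("pooled", "per_individual")) {
  ranges <- list(diameter_range = diameter_range,
                 brightfield_range = brightfield_range,
                 median_pixel_range = median_pixel_range,
                 symmetry3_range = symmetry3_range,
                 symmetry4_range = symmetry4_range,
                 correlation_mean_range = correlation_mean_range,
                 gradient_rms_range = gradient_rms_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] >= r[2]) stop(nm, " must be [lower, upper]")
  }
  if (any(trim_quantiles < 0) || any(trim_quantiles > 1) ||
      trim_quantiles[1] > trim_quantiles[2]) {
    stop("trim_quantiles must be ordered and lie in [0, 1]")
  }
  structure(c(ranges, list(
    min_particles_per_individual = as.integer(min_particles_per_individual),
    trim_quantiles = trim_quantiles,
    trim_scope = match.arg(trim_scope))), class = "gate_config")
}

# gate steps in cascade order: list of (name, feature columns, range names)
.gate_steps <- list(
  diameter   = list(cols = "diameter", ranges = "diameter_range"),
  brightfield = list(cols = c("brightfield_intensity", "median_pixel"),
                     ranges = c("brightfield_range", "median_pixel_range")),
  symmetry   = list(cols = c("symmetry3", "symmetry4"),
                    ranges = c("symmetry3_range", "symmetry4_range")),
  focus      = list(cols = c("correlation_mean", "gradient_rms"),
                    ranges = c("correlation_mean_range", "gradient_rms_range"))
)

#' Apply the stepwise gating cascade
#'
#' Gates are applied in fixed order: diameter; then brightfield intensity
#' and median pixel intensity; then symmetry 3 and symmetry 4; then
#' correlation mean and gradient RMS. All range tests include the
#' endpoints. The report records the particle count remaining after each
#' step.
#'
#' @param particles data.frame with one row per imaged object and all gate
#'   feature columns.
#' @param config a \code{\link{gate_config}}.
#' @return list with \code{particles} (rows passing every gate) and
#'   \code{report} (a \code{gating_report}: per-step counts; fields for
#'   dropped individuals and trimmed particles are filled by the later
#'   stages).
#' @export
apply_gates <- function(particles, config = gate_config()) {
  needed <- unlist(lapply(.gate_steps, `[[`, "cols"), use.names = FALSE)
  missing_cols <- setdiff(needed, names(particles))
  if (length(missing_cols)) {
    stop("particle table lacks feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  counts <- c(input = nrow(particles))
  kept <- particles
  for (step in names(.gate_steps)) {
    st <- .gate_steps[[step]]
    pass <- rep(TRUE, nrow(kept))
    for (i in seq_along(st$cols)) {
      r <- config[[st$ranges[i]]]
      v <- kept[[st$cols[i]]]
      pass <- pass & !is.na(v) & v >= r[1] & v <= r[2]
    }
    kept <- kept[pass, , drop = FALSE]
    counts[step] <- nrow(kept)
  }
  report <- structure(
    list(counts_after_each_gate = counts,
         individuals_dropped = character(0), particles_trimmed = 0L),
    class = "gating_report")
  list(particles = kept, report = report)
}

#' @export
print.gating_report <- function(x, ...) {
  cat("gating report\n")
  for (nm in names(x$counts_after_each_gate)) {
    cat(sprintf("  %-12s %d\n", nm, x$counts_after_each_gate[[nm]]))
  }
  if (length(x$individuals_dropped)) {
    cat("  individuals dropped (<min particles):",
        paste(x$individuals_dropped, collapse = ", "), "\n")
  }
  cat("  particles trimmed:", x$particles_trimmed, "\n")
  invisible(x)
}

#' Drop individuals with too few retained particles
#'
#' Individuals contributing fewer than
#' \code{min_particles_per_individual} gated particles (default 50) are
#' removed entirely.
#'
#' @param particles gated particle table with an \code{individual_id}
#'   column.
#' @param config a \code{\link{gate_config}}.
#' @param report optional \code{gating_report} to update.
#' @return list with \code{particles} and \code{report}.
#' @export
filter_individuals <- function(particles, config = gate_config(),
                               report = NULL) {
  if (nrow(particles) == 0L) {
    if (!is.null(report)) report$counts_after_each_gate["min_particles"] <- 0L
    return(list(particles = particles, report = report))
  }
  tab <- table(particles$individual_id)
  keep_ids <- names(tab)[tab >= config$min_particles_per_individual]
  dropped <- setdiff(names(tab), keep_ids)
  out <- particles[particles$individual_id %in% keep_ids, , drop = FALSE]
  if (!is.null(report)) {
    report$counts_after_each_gate["min_particles"] <- nrow(out)
    report$individuals_dropped <- dropped
  }
  list(particles = out, report = report)
}

#' Trim pollen-length outliers
#'
#' Computes the lower/upper trim quantiles (default 1\% and 99\%) of
#' \code{pollen_length} -- pooled across all retained particles by default,
#' or within each individual -- with linear-interpolation quantiles, and
#' removes particles strictly outside the closed interval.
#'
#' @param particles particle table after individual filtering.
#' @param config a \code{\link{gate_config}}.
#' @param report optional \code{gating_report} to update.
#' @return list with \code{particles} and \code{report}.
#' @export
trim_length_outliers <- function(particles, config = gate_config(),
                                 report = NULL) {
  if (nrow(particles) < 2L) stop("need at least 2 particles to trim")
  keep <- if (config$trim_scope == "pooled") {
    q <- stats::quantile(particles$pollen_length, config$trim_quantiles,
                         names = FALSE)
    particles$pollen_length >= q[1] & particles$pollen_length <= q[2]
  } else {
    unsplit(lapply(split(particles$pollen_length, particles$individual_id),
                   function(v) {
                     q <- stats::quantile(v, config$trim_quantiles,
                                          names = FALSE)
                     v >= q[1] & v <= q[2]
                   }), particles$individual_id)
  }
  out <- particles[keep, , drop = FALSE]
  if (!is.null(report)) {
    report$particles_trimmed <- sum(!keep)
    report$counts_after_each_gate["length_trim"] <- nrow(out)
  }
  list(particles = out, report = report)
}

#' Per-individual pollen trait medians
#'
#' Summarizes the trimmed particle table to one row per individual: the
#' median of pollen length (PL, um), pollen area (PA, um^2), pollen
#' elongatedness (PE = length/width, a.u.) and the four fluorescence
#' intensities, plus the retained particle count.
#'
#' @param particles trimmed particle table.
#' @return data.frame, one row per individual.
#' @export
summarize_traits <- function(particles) {
  p <- particles
  p$PE <- p$pollen_length / p$pollen_width
  feats <- c(PL = "pollen_length", PA = "pollen_area", PE = "PE",
             PGFI = "fluor_ch2", PYFI = "fluor_ch3", POFI = "fluor_ch4",
             PRFI = "fluor_ch5")
  feats <- feats[unname(feats) %in% names(p)]
  ids <- unique(p$individual_id)
  out <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (nm in names(feats)) {
    med <- tapply(p[[feats[[nm]]]], p$individual_id, stats::median)
    out[[nm]] <- as.numeric(med[ids])
  }
  out$n_particles <- as.integer(table(p$individual_id)[ids])
  out
}

#' Per-individual anther-length medians
#'
#' The study design measures six anthers from one flower per individual;
#' a warning is issued for individuals with a different count.
#'
#' @param anther_lengths data.frame with columns \code{individual_id} and
#'   \code{length_mm}.
#' @param expected_count measurements expected per individual (default 6).
#' @return data.frame with per-individual median anther length (mm).
#' @export
anther_median <- function(anther_lengths, expected_count = 6L) {
  if (is.null(anther_lengths) || nrow(anther_lengths) == 0L) {
    stop("no anther measurements supplied")
  }
  sp <- split(anther_lengths$length_mm, anther_lengths$individual_id)
  odd <- names(sp)[vapply(sp, length, 1L) != expected_count]
  if (length(odd)) {
    warning("individual(s) with a measurement count != ", expected_count,
            ": ", paste(odd, collapse = ", "))
  }
  data.frame(individual_id = names(sp),
             anther_length_mm = vapply(sp, stats::median, numeric(1)),
             n_anthers = vapply(sp, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full gating pipeline
#'
#' Convenience wrapper: gate cascade, minimum-particle filter, length
#' trimming, per-individual trait medians.
#'
#' @param particles raw particle table.
#' @param config a \code{\link{gate_config}}.
#' @return list with \code{traits}, \code{particles} and \code{report}.
#' @export
gate_pipeline <- function(particles, config = gate_config()) {
  g <- apply_gates(particles, config)
  f <- filter_individuals(g$particles, config, g$report)
  t <- trim_length_outliers(f$particles, config, f$report)
  list(traits = summarize_traits(t$particles),
       particles = t$particles, report = t$report)
}
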