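#' Sliding genomic windows
#'
#' Deterministic tiling from position 1 with window \code{size} and
#' \code{overlap} between consecutive windows (step = size - overlap);
#' the last window on each chromosome may be truncated. Defaults: 1 Mb
#' windows overlapping by 250 Kb.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param overlap overlap between consecutive windows in bp (must be
#'   smaller than \code{size}).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (1-based, closed).
#' @export
make_windows <- function(chrom_lengths, size = 1e6, overlap = 250e3) {
  if (overlap >= size) stop("overlap must be smaller than the window size")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  step <- size - overlap
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size - 1, len))
  })
  do.call(rbind, out)
}

# Weir-Cockerham per-site variance components for two populations.
# Returns a data.frame of a (among), b (between individuals within),
# c (within individuals); sites where any group has no called genotype or
# the pooled sample is monomorphic without heterozygotes yield a+b+c = 0
# and are treated as undefined downstream.
.wc_components <- function(geno, group_a, group_b) {
  comp_one <- function(rows) {
    g <- geno$calls[rows, , drop = FALSE]
    n <- colSums(!is.na(g))
    p <- colMeans(g, na.rm = TRUE) / 2
    h <- colMeans(g == 1L, na.rm = TRUE)
    list(n = n, p = p, h = h)
  }
  A <- comp_one(group_a)
  B <- comp_one(group_b)
  if (max(A$n) < 2L || max(B$n) < 2L) {
    stop("each group needs at least 2 called individuals at some site")
  }
  r <- 2
  nbar <- (A$n + B$n) / r
  ok <- A$n >= 1 & B$n >= 1 & nbar > 1
  nc <- r * nbar - (A$n^2 + B$n^2) / (r * nbar)
  nc <- nc / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  data.frame(chrom = geno$chrom, pos = geno$pos, a = a, b = b, c = cc)
}

.group_rows <- function(geno, groups) {
  lv <- sort(unique(groups$group))
  if (length(lv) != 2L) stop("exactly two groups are required")
  lapply(lv, function(g) {
    rows <- match(groups$individual_id[groups$group == g], geno$individuals)
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L) stop("group ", g, " has no genotyped individuals")
    rows
  })
}

#' Weir-Cockerham F_ST between two populations
#'
#' Per-site variance components a (among populations), b (between
#' individuals within populations) and c (within individuals) of the
#' Weir-Cockerham (1984) estimator; window and genome-wide values are
#' ratios of sums, \code{sum(a) / sum(a + b + c)}, over the contributing
#' sites. Negative components are retained (no clipping). Sites where the
#' components are all zero (undefined estimator) are skipped.
#'
#' @param geno a \code{\link{genotype_table}}.
#' @param groups data.frame with columns \code{individual_id},
#'   \code{group} (two groups).
#' @param windows optional window data.frame from
#'   \code{\link{make_windows}}.
#' @return list with \code{per_site} (chrom, pos, a, b, c, fst),
#'   \code{fst_genomewide}, and \code{windowed} (window columns plus
#'   \code{n_snps}, \code{fst}) when windows are supplied.
#' @export
weir_fst <- function(geno, groups, windows = NULL) {
  rows <- .group_rows(geno, groups)
  comp <- .wc_components(geno, rows[[1]], rows[[2]])
  tot <- comp$a + comp$b + comp$c
  comp$fst <- ifelse(tot != 0, comp$a / tot, NA_real_)
  defined <- tot != 0
  res <- list(per_site = comp,
              fst_genomewide = sum(comp$a[defined]) / sum(tot[defined]))
  if (!is.null(windows)) {
    res$windowed <- .window_ratio(comp[defined, , drop = FALSE],
                                  tot[defined], windows)
  }
  res
}

# ratio-of-sums aggregation of W-C components into windows
.window_ratio <- function(comp, tot, windows) {
  n_snps <- integer(nrow(windows))
  fst <- rep(NA_real_, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    sel <- comp$chrom == windows$chrom[i] &
      comp$pos >= windows$start[i] & comp$pos <= windows$end[i]
    n_snps[i] <- sum(sel)
    if (n_snps[i] > 0L) fst[i] <- sum(comp$a[sel]) / sum(tot[sel])
  }
  cbind(windows, n_snps = n_snps, fst = fst)
}

#' Windowed nucleotide diversity
#'
#' Per-site \code{pi = 2 p (1 - p) * n / (n - 1)} with \code{n} the number
#' of called alleles; the window value is the sum of site pi divided by
#' the window length in bp.
#'
#' @param geno a \code{\link{genotype_table}}.
#' @param individuals identifiers (or indices) of the population to use.
#' @param windows window data.frame from \code{\link{make_windows}}.
#' @return numeric vector of per-window diversity (per bp).
#' @export
windowed_pi <- function(geno, individuals, windows) {
  if (is.character(individuals)) {
    individuals <- match(individuals, geno$individuals)
    individuals <- individuals[!is.na(individuals)]
  }
  g <- geno$calls[individuals, , drop = FALSE]
  n_alleles <- 2 * colSums(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  site_pi <- ifelse(n_alleles >= 2,
                    2 * p * (1 - p) * n_alleles / (n_alleles - 1), 0)
  site_pi[is.na(site_pi)] <- 0
  vapply(seq_len(nrow(windows)), function(i) {
    sel <- geno$chrom == windows$chrom[i] &
      geno$pos >= windows$start[i] & geno$pos <= windows$end[i]
    sum(site_pi[sel]) / (windows$end[i] - windows$start[i] + 1)
  }, numeric(1))
}

#' Diversity reduction index
#'
#' \code{DRI = pi_feral / pi_domesticated}; windows where the
#' domesticated-population diversity is zero are undefined (\code{NA}) and
#' must be excluded from percentile ranking.
#'
#' @param pi_feral,pi_domesticated per-window diversities.
#' @return numeric vector of ratios with \code{NA} where undefined.
#' @export
dri <- function(pi_feral, pi_domesticated) {
  ifelse(pi_domesticated > 0, pi_feral / pi_domesticated, NA_real_)
}

#' XP-CLR selection-scan configuration
#'
#' @param sel_coeff_grid selection coefficients to profile over; must
#'   include 0 (the neutral model).
#' @param rec_rate_cM_Mb uniform recombination rate in cM/Mb.
#' @param max_snps_per_window cap on sites used per window (evenly
#'   subsampled above it).
#' @param omega drift variance of the object population relative to the
#'   reference; estimated genome-wide by method of moments when
#'   \code{NULL}.
#' @return An object of class \code{xpclr_config}.
#' @export
xpclr_config <- function(sel_coeff_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
                         rec_rate_cM_Mb = 1, max_snps_per_window = 400L,
                         omega = NULL) {
  if (!0 %in% sel_coeff_grid) stop("sel_coeff_grid must include 0")
  if (rec_rate_cM_Mb <= 0) stop("rec_rate_cM_Mb must be positive")
  structure(list(sel_coeff_grid = sort(sel_coeff_grid),
                 rec_rate_cM_Mb = rec_rate_cM_Mb,
                 max_snps_per_window = as.integer(max_snps_per_window),
                 omega = omega), class = "xpclr_config")
}

# truncated-normal density of the object frequency on [0, 1]
.tnorm_dens <- function(x, mean, sd) {
  z <- stats::pnorm(1, mean, sd) - stats::pnorm(0, mean, sd)
  stats::dnorm(x, mean, sd) / pmax(z, 1e-300)
}

#' Cross-population composite likelihood ratio (XP-CLR) scan
#'
#' Models the object-population allele frequency given the reference
#' frequency as a truncated normal with drift variance
#' \code{omega * p (1 - p)}, where \code{omega} is estimated genome-wide
#' by method of moments from the reference-to-object frequency
#' differentiation. Under a sweep at the window centre, an allele at
#' genetic distance \code{r * d} from the sweep escapes via recombination
#' with probability \code{c = 1 - exp(-r d / s)}; with probability
#' \code{1 - c} it hitchhikes to fixation of one allele. The window score
#' is twice the gain of the composite log likelihood maximized over the
#' selection-coefficient grid relative to the neutral model (s = 0), hence
#' non-negative.
#'
#' @param geno a \code{\link{genotype_table}}.
#' @param groups data.frame with columns \code{individual_id},
#'   \code{group}; the reference population is the first group
#'   alphabetically unless \code{reference} is given.
#' @param windows window data.frame from \code{\link{make_windows}}.
#' @param config an \code{\link{xpclr_config}}.
#' @param reference group label of the reference (non-selected)
#'   population.
#' @return list with \code{scores} (per window), \code{omega} and
#'   \code{best_s} per window.
#' @export
xpclr_scan <- function(geno, groups, windows, config = xpclr_config(),
                       reference = NULL) {
  lv <- sort(unique(groups$group))
  if (length(lv) != 2L) stop("exactly two groups are required")
  if (is.null(reference)) reference <- lv[1]
  obj_lab <- setdiff(lv, reference)
  ref_rows <- match(groups$individual_id[groups$group == reference],
                    geno$individuals)
  obj_rows <- match(groups$individual_id[groups$group == obj_lab],
                    geno$individuals)
  ref_rows <- ref_rows[!is.na(ref_rows)]
  obj_rows <- obj_rows[!is.na(obj_rows)]
  p_ref <- colMeans(geno$calls[ref_rows, , drop = FALSE], na.rm = TRUE) / 2
  p_obj <- colMeans(geno$calls[obj_rows, , drop = FALSE], na.rm = TRUE) / 2

  usable <- is.finite(p_ref) & is.finite(p_obj) & p_ref > 0 & p_ref < 1
  omega <- config$omega
  if (is.null(omega)) {
    omega <- mean((p_obj[usable] - p_ref[usable])^2 /
                    (p_ref[usable] * (1 - p_ref[usable])))
  }
  if (!is.finite(omega) || omega <= 0) {
    stop("drift variance estimate omega is not positive")
  }
  r_per_bp <- config$rec_rate_cM_Mb * 1e-8  # Morgans per bp

  nw <- nrow(windows)
  scores <- rep(NA_real_, nw)
  best_s <- rep(NA_real_, nw)
  for (i in seq_len(nw)) {
    sel <- which(geno$chrom == windows$chrom[i] &
                   geno$pos >= windows$start[i] &
                   geno$pos <= windows$end[i] & usable)
    if (length(sel) == 0L) next
    if (length(sel) > config$max_snps_per_window) {
      sel <- sel[round(seq(1, length(sel),
                           length.out = config$max_snps_per_window))]
    }
    centre <- (windows$start[i] + windows$end[i]) / 2
    d <- abs(geno$pos[sel] - centre)
    p2 <- p_ref[sel]
    p1 <- p_obj[sel]
    sd_drift <- sqrt(omega * p2 * (1 - p2))
    f_neutral <- .tnorm_dens(p1, p2, sd_drift)
    ll <- vapply(config$sel_coeff_grid, function(s) {
      if (s == 0) return(sum(log(pmax(f_neutral, 1e-300))))
      cesc <- 1 - exp(-r_per_bp * d / s)
      f <- cesc * f_neutral +
        (1 - cesc) * (p2 * .tnorm_dens(p1, 1, sd_drift) +
                        (1 - p2) * .tnorm_dens(p1, 0, sd_drift))
      sum(log(pmax(f, 1e-300)))
    }, numeric(1))
    scores[i] <- 2 * (max(ll) - ll[config$sel_coeff_grid == 0])
    best_s[i] <- config$sel_coeff_grid[which.max(ll)]
  }
  list(scores = scores, omega = omega, best_s = best_s)
}

#' Flag windows above the genome-wide 95th percentile
#'
#' Values strictly above the empirical 95th percentile
#' (linear-interpolation quantile) are flagged significant. \code{NA}
#' values (undefined windows) are excluded from the ranking and never
#' flagged.
#'
#' @param values per-window statistic.
#' @param prob percentile (default 0.95).
#' @return logical vector of flags.
#' @export
call_significant <- function(values, prob = 0.95) {
  ok <- !is.na(values)
  if (sum(ok) < 20L) stop("need at least 20 windows for a stable percentile")
  thr <- stats::quantile(values[ok], prob, names = FALSE)
  flags <- values > thr
  flags[!ok] <- FALSE
  flags
}

#' Z-transform of windowed values
#'
#' @param values per-window statistic.
#' @return \code{(x - mean) / sd} over non-missing windows.
#' @export
z_transform <- function(values) {
  (values - mean(values, na.rm = TRUE)) / stats::sd(values, na.rm = TRUE)
}

#' Windowed selection scan between two populations
#'
#' Computes Weir-Cockerham F_ST, nucleotide diversity per population, the
#' diversity reduction index (DRI = pi_feral / pi_domesticated) and XP-CLR
#' on a shared window tiling, Z-transforms F_ST, and flags windows above
#' the genome-wide 95th percentile of each statistic. Windows with no SNP
#' are dropped.
#'
#' @param geno a \code{\link{genotype_table}}.
#' @param groups data.frame with \code{individual_id} and \code{group}
#'   containing the labels \code{"feral"} and \code{"domesticated"}.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size,overlap window tiling parameters (default 1 Mb / 250 Kb).
#' @param xpclr an \code{\link{xpclr_config}}.
#' @return data.frame with one row per SNP-containing window: coordinates,
#'   \code{n_snps}, \code{fst}, \code{z_fst}, \code{pi_feral},
#'   \code{pi_dom}, \code{dri}, \code{xpclr}, and logical flags
#'   \code{fst_sig}, \code{dri_sig}, \code{xpclr_sig}.
#' @export
selection_scan <- function(geno, groups, chrom_lengths,
                           size = 1e6, overlap = 250e3,
                           xpclr = xpclr_config()) {
  stopifnot(all(c("feral", "domesticated") %in% groups$group))
  windows <- make_windows(chrom_lengths, size, overlap)
  fst <- weir_fst(geno, groups, windows)
  w <- fst$windowed
  w$pi_feral <- windowed_pi(
    geno, groups$individual_id[groups$group == "feral"], windows)
  w$pi_dom <- windowed_pi(
    geno, groups$individual_id[groups$group == "domesticated"], windows)
  w$dri <- dri(w$pi_feral, w$pi_dom)
  xp <- xpclr_scan(geno, groups, windows, xpclr, reference = "feral")
  w$xpclr <- xp$scores
  w <- w[w$n_snps > 0L, , drop = FALSE]
  w$z_fst <- z_transform(w$fst)
  w$fst_sig <- call_significant(w$fst)
  w$dri_sig <- call_significant(w$dri)
  w$xpclr_sig <- call_significant(w$xpclr)
  attr(w, "fst_genomewide") <- fst$fst_genomewide
  attr(w, "omega") <- xp$omega
  w
}

#' Screen QTL neighbourhoods for selection signatures
#'
#' For each QTL, checks whether any flagged window of each statistic
#' overlaps the interval \code{[pos - span, pos + span]}.
#'
#' @param qtl data.frame with columns \code{chrom}, \code{pos} (one row
#'   per QTL).
#' @param scan windowed scan table from \code{\link{selection_scan}} (or
#'   any data.frame with \code{chrom}, \code{start}, \code{end} and
#'   logical \code{*_sig} columns).
#' @param span half-width of the screened interval in bp (default 5 Mb).
#' @return list with \code{evidence} (per QTL, per statistic logical plus
#'   \code{any_sig}) and \code{fraction_under_selection}.
#' @export
screen_qtl <- function(qtl, scan, span = 5e6) {
  stats_cols <- grep("_sig$", names(scan), value = TRUE)
  ev <- data.frame(qtl[, c("chrom", "pos")])
  for (sc in stats_cols) {
    ev[[sc]] <- vapply(seq_len(nrow(qtl)), function(i) {
      any(scan$chrom == qtl$chrom[i] & scan[[sc]] &
            scan$start <= qtl$pos[i] + span &
            scan$end >= qtl$pos[i] - span, na.rm = TRUE)
    }, logical(1))
  }
  ev$any_sig <- if (length(stats_cols))
    Reduce(`|`, ev[stats_cols]) else logical(nrow(qtl))
  list(evidence = ev,
       fraction_under_selection = if (nrow(ev)) mean(ev$any_sig) else NA_real_)
}
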