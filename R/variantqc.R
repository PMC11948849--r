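#' Variant filter specification
#'
#' Mirrors the usual VCFtools-style chain: per-genotype depth masking,
#' biallelic-SNP restriction, site callrate and minor-allele-frequency
#' floors. Two named presets encode the study-style chains:
#' \code{"gwas"} = \{minDP 4, max-missing 0.9, maf 0.05, biallelic, no
#' indels\} and \code{"popgen"} = \{minDP 10, maxDP 100, max-missing 0.7,
#' maf 0.01, biallelic, no indels\}.
#'
#' @param min_dp,max_dp per-genotype read-depth bounds; calls outside are
#'   set missing. \code{NULL} disables a bound.
#' @param max_missing minimum called fraction per site in [0, 1] (VCFtools
#'   \code{--max-missing} semantics); 0 disables.
#' @param maf minor-allele-frequency floor in [0, 0.5].
#' @param biallelic_only drop multi-allelic records.
#' @param remove_indels drop records whose REF or ALT is longer than 1 bp.
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(min_dp = NULL, max_dp = NULL, max_missing = 0,
                        maf = 0, biallelic_only = TRUE,
                        remove_indels = TRUE) {
  if (maf < 0 || maf > 0.5) stop("maf must lie in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0, 1]")
  if (!is.null(min_dp) && !is.null(max_dp) && min_dp > max_dp) {
    stop("min_dp must not exceed max_dp")
  }
  structure(list(min_dp = min_dp, max_dp = max_dp,
                 max_missing = max_missing, maf = maf,
                 biallelic_only = biallelic_only,
                 remove_indels = remove_indels),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param preset \code{"gwas"} or \code{"popgen"}.
#' @export
qc_preset <- function(preset = c("gwas", "popgen")) {
  switch(match.arg(preset),
         gwas = filter_spec(min_dp = 4, max_missing = 0.9, maf = 0.05),
         popgen = filter_spec(min_dp = 10, max_dp = 100, max_missing = 0.7,
                              maf = 0.01))
}

#' Filter a genotype table
#'
#' Rules are applied in a fixed order whose consequences matter: (1)
#' per-genotype depth masking (calls with depth outside
#' \code{[min_dp, max_dp]} set missing); (2) drop non-biallelic records and
#' indels; (3) drop sites whose called fraction, after masking, falls below
#' \code{max_missing}; (4) drop sites whose MAF, computed on the remaining
#' calls, falls below \code{maf}.
#'
#' @param geno a \code{\link{genotype_table}}.
#' @param spec a \code{\link{filter_spec}}.
#' @return list with \code{geno} (filtered table) and \code{removed}
#'   (named integer counts: genotypes masked and sites removed per rule).
#' @export
filter_variants <- function(geno, spec = filter_spec()) {
  calls <- geno$calls
  masked <- 0L
  if (!is.null(geno$depths) && (!is.null(spec$min_dp) || !is.null(spec$max_dp))) {
    bad <- matrix(FALSE, nrow(calls), ncol(calls))
    if (!is.null(spec$min_dp)) bad <- bad | geno$depths < spec$min_dp
    if (!is.null(spec$max_dp)) bad <- bad | geno$depths > spec$max_dp
    bad[is.na(bad)] <- FALSE
    masked <- sum(bad & !is.na(calls))
    calls[bad] <- NA_integer_
  }
  m <- ncol(calls)
  keep <- rep(TRUE, m)
  n_multi <- n_indel <- 0L
  if (spec$biallelic_only) {
    multi <- grepl(",", geno$alt, fixed = TRUE)
    n_multi <- sum(keep & multi)
    keep <- keep & !multi
  }
  if (spec$remove_indels) {
    indel <- nchar(geno$ref) > 1L | (nchar(geno$alt) > 1L &
                                       !grepl(",", geno$alt, fixed = TRUE))
    n_indel <- sum(keep & indel)
    keep <- keep & !indel
  }
  callrate <- colMeans(!is.na(calls))
  low_call <- callrate < spec$max_missing
  n_missing <- sum(keep & low_call)
  keep <- keep & !low_call
  p <- colMeans(calls, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  mafs[is.nan(mafs)] <- 0
  low_maf <- mafs < spec$maf
  n_maf <- sum(keep & low_maf)
  keep <- keep & !low_maf

  out <- genotype_table(
    calls = calls[, keep, drop = FALSE],
    chrom = geno$chrom[keep], pos = geno$pos[keep],
    depths = if (!is.null(geno$depths)) geno$depths[, keep, drop = FALSE],
    ref = geno$ref[keep], alt = geno$alt[keep],
    individuals = geno$individuals)
  list(geno = out,
       removed = c(genotypes_masked = masked,
                   multiallelic = n_multi, indel = n_indel,
                   low_callrate = n_missing, low_maf = n_maf))
}

#' Proportion of heterozygous calls for one individual
#'
#' @param geno a \code{\link{genotype_table}}.
#' @param individual identifier or row index.
#' @return fraction of heterozygous calls among non-missing calls.
#' @export
het_proportion <- function(geno, individual) {
  if (is.character(individual)) {
    individual <- match(individual, geno$individuals)
    if (is.na(individual)) stop("unknown individual")
  }
  g <- geno$calls[individual, ]
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("individual has no called genotypes")
  mean(g == 1L)
}

#' Classify ploidy from heterozygosity proportions
#'
#' Comparative classifier: each unknown individual is assigned the ploidy
#' class of the nearest reference-class mean heterozygosity. Ties at the
#' midpoint are broken toward the lower ploidy (conservative call) and
#' reported.
#'
#' @param het_props named numeric vector of per-individual heterozygosity
#'   proportions.
#' @param reference_labels named character vector giving the known ploidy
#'   class (e.g. \code{"diploid"}, \code{"tetraploid"}) of a subset of the
#'   individuals; every class needs at least one reference.
#' @return list with \code{calls} (data.frame individual_id, het, ploidy),
#'   \code{class_means} and \code{midpoints}.
#' @export
classify_ploidy <- function(het_props, reference_labels) {
  if (length(reference_labels) == 0L) stop("no reference individuals given")
  ref_het <- het_props[names(reference_labels)]
  if (anyNA(ref_het)) stop("reference individual missing from het_props")
  means <- tapply(ref_het, reference_labels, mean)
  if (length(means) < 2L) {
    stop("need at least one reference individual per ploidy class")
  }
  ord <- order(means)            # ascending het ~ ascending ploidy
  means <- means[ord]
  mids <- (means[-1] + means[-length(means)]) / 2
  assign_one <- function(h) {
    d <- abs(h - means)
    best <- which(d <= min(d) + 1e-12)
    names(means)[best[1L]]      # ties (midpoint) -> lower-ploidy class
  }
  calls <- vapply(het_props, assign_one, character(1))
  list(calls = data.frame(individual_id = names(het_props),
                          het = unname(het_props),
                          ploidy = unname(calls),
                          stringsAsFactors = FALSE),
       class_means = means, midpoints = mids)
}

#' Linkage-disequilibrium decay by inter-SNP distance
#'
#' Squared Pearson correlation of dosage vectors for all intra-chromosome
#' SNP pairs separated by a distance in \code{[min_dist, max_dist]},
#' binned by distance. Pairs involving missing calls use
#' pairwise-complete observations; pairs where either site is monomorphic
#' over the complete observations are skipped.
#'
#' @param geno a filtered \code{\link{genotype_table}}.
#' @param min_dist,max_dist distance bounds in bp (defaults 1 Mb and 20 Mb).
#' @param bin_width bin width in bp (default 1 Mb).
#' @return data.frame with columns \code{distance_lo}, \code{distance_hi},
#'   \code{mean_r2}, \code{n_pairs}; zero rows when no pair qualifies.
#' @export
ld_r2_by_distance <- function(geno, min_dist = 1e6, max_dist = 20e6,
                              bin_width = 1e6) {
  breaks <- seq(min_dist, max_dist, by = bin_width)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  nb <- length(breaks) - 1L
  sum_r2 <- n_pairs <- numeric(nb)
  x <- geno$calls
  storage.mode(x) <- "double"
  for (ch in unique(geno$chrom)) {
    j <- which(geno$chrom == ch)
    if (length(j) < 2L) next
    pos <- geno$pos[j]
    r <- suppressWarnings(stats::cor(x[, j, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    d <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(d)
    dd <- d[ut]
    rr <- r[ut]^2
    ok <- dd >= min_dist & dd <= max_dist & !is.na(rr)
    if (!any(ok)) next
    bin <- findInterval(dd[ok], breaks, rightmost.closed = TRUE)
    sum_r2 <- sum_r2 + vapply(seq_len(nb), function(b)
      sum(rr[ok][bin == b]), numeric(1))
    n_pairs <- n_pairs + vapply(seq_len(nb), function(b)
      sum(bin == b), numeric(1))
  }
  out <- data.frame(distance_lo = breaks[-length(breaks)],
                    distance_hi = breaks[-1],
                    mean_r2 = ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_),
                    n_pairs = as.integer(n_pairs))
  out[out$n_pairs > 0, , drop = FALSE]
}
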