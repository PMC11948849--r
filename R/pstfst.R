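#' Phenotypic variance components for two populations
#'
#' One-way ANOVA decomposition of a trait measured in two groups:
#' \code{sigma2_w} is the pooled within-group variance (the error mean
#' square) and \code{sigma2_b = (MS_between - MS_within) / n0} with
#' \code{n0 = (N - sum(n_i^2)/N) / (k - 1)}, the standard
#' unbalanced-design coefficient. A negative between-group component is
#' truncated to zero and flagged.
#'
#' @param trait_values numeric trait vector.
#' @param group_labels group factor (exactly two levels, each with at
#'   least 3 observations).
#' @return An object of class \code{pst_components}: \code{sigma2_b},
#'   \code{sigma2_w}, \code{n0}, \code{truncated}.
#' @export
variance_components <- function(trait_values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  n_i <- table(g)
  if (any(n_i < 3L)) stop("each group needs at least 3 observations")
  fit <- stats::lm(trait_values ~ g)
  an <- stats::anova(fit)
  ms_b <- an$`Mean Sq`[1]
  ms_w <- an$`Mean Sq`[2]
  n <- length(trait_values)
  n0 <- (n - sum(n_i^2) / n) / (nlevels(g) - 1L)
  s2b <- (ms_b - ms_w) / n0
  truncated <- s2b < 0
  structure(list(sigma2_b = max(0, s2b), sigma2_w = ms_w, n0 = n0,
                 truncated = truncated), class = "pst_components")
}

#' Phenotypic differentiation index P_ST
#'
#' \code{P_ST = csh * sigma2_b / (csh * sigma2_b + 2 * sigma2_w)}, where
#' \code{csh = c / h^2} scales the between-population phenotypic variance
#' by the proportion that is additive relative to the within-population
#' heritability. In a common-garden design \code{csh = 1} is the usual
#' assumption.
#'
#' @param components a \code{\link{variance_components}} result (or a list
#'   with \code{sigma2_b} and \code{sigma2_w}).
#' @param csh ratio c/h^2, strictly positive (default 1).
#' @return P_ST in [0, 1].
#' @export
pst <- function(components, csh = 1) {
  if (csh <= 0) stop("csh must be positive")
  s2b <- components$sigma2_b
  s2w <- components$sigma2_w
  if (s2b == 0 && s2w == 0) stop("both variance components are zero")
  csh * s2b / (csh * s2b + 2 * s2w)
}

#' P_ST with bootstrap confidence interval
#'
#' Individuals are resampled with replacement within their group; the
#' percentile interval of the bootstrap P_ST distribution is reported at
#' the requested level, with the point estimate taken from the original
#' (unresampled) data. Degenerate resamples in which a group has zero
#' within-variance are redrawn and counted.
#'
#' @param trait_values numeric trait vector.
#' @param group_labels two-level group factor.
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param csh c/h^2 ratio passed to \code{\link{pst}}.
#' @param seed integer seed for the resampling.
#' @return An object of class \code{pst_result}: \code{pst}, \code{ci_low},
#'   \code{ci_high}, \code{boot_values}, \code{n_redrawn},
#'   \code{components}.
#' @export
pst_bootstrap <- function(trait_values, group_labels, n_boot = 1000,
                          level = 0.95, csh = 1, seed = 1L) {
  g <- factor(group_labels)
  point <- pst(variance_components(trait_values, g), csh)
  idx_by_group <- split(seq_along(trait_values), g)
  set.seed(seed)
  boot <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- unlist(lapply(idx_by_group, function(ix)
        sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
      v <- trait_values[idx]
      gl <- g[idx]
      degenerate <- any(vapply(split(v, gl), function(z)
        stats::var(z) == 0, logical(1)))
      if (!degenerate) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_boot) stop("bootstrap resampling degenerate")
    }
    boot[b] <- pst(variance_components(v, gl), csh)
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  structure(list(pst = point, ci_low = ci[1], ci_high = ci[2],
                 level = level, csh = csh, boot_values = boot,
                 n_redrawn = n_redrawn,
                 components = variance_components(trait_values, g)),
            class = "pst_result")
}

#' @export
print.pst_result <- function(x, ...) {
  cat(sprintf("P_ST = %.3f  [%.3f, %.3f] (%d%% percentile bootstrap, csh = %g)\n",
              x$pst, x$ci_low, x$ci_high, round(100 * x$level), x$csh))
  if (!is.null(x$verdict)) {
    cat(sprintf("  genome-wide F_ST = %.4f -> verdict: %s\n",
                x$fst_genomewide, x$verdict))
  }
  invisible(x)
}

#' Compare P_ST against genome-wide F_ST
#'
#' Classifies the trait's between-population divergence: \code{selection}
#' when the lower confidence bound exceeds the genome-wide F_ST (P_ST >
#' F_ST beyond sampling error), \code{drift} when the interval contains
#' F_ST (P_ST = F_ST is compatible), and \code{inconclusive} when even the
#' upper bound falls below F_ST (an unexpected configuration, flagged).
#'
#' @param pst_result a \code{\link{pst_bootstrap}} result.
#' @param fst_genomewide genome-wide Weir-Cockerham F_ST (ratio of sums)
#'   for the same two populations.
#' @return the \code{pst_result} with \code{fst_genomewide} and
#'   \code{verdict} fields added.
#' @export
compare_pst_fst <- function(pst_result, fst_genomewide) {
  verdict <- if (pst_result$ci_low > fst_genomewide) {
    "selection"
  } else if (pst_result$ci_high < fst_genomewide) {
    "inconclusive"
  } else {
    "drift"
  }
  pst_result$fst_genomewide <- fst_genomewide
  pst_result$verdict <- verdict
  pst_result
}
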