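#' Genetic relationship matrix
#'
#' GCTA-style GRM: \code{A[j,k] = (1/m) * sum_i (x_ij - 2 p_i) (x_ik - 2
#' p_i) / (2 p_i (1 - p_i))} over sites i, with missing genotypes
#' mean-imputed to \code{2 p_i}.
#'
#' @param geno a filtered \code{\link{genotype_table}} with no
#'   monomorphic sites.
#' @return list of class \code{grm}: \code{matrix} (individuals x
#'   individuals) and \code{n_snps_used}.
#' @export
compute_grm <- function(geno) {
  p <- allele_freq(geno)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("monomorphic site(s) present; apply a MAF filter first")
  }
  x <- geno$calls
  storage.mode(x) <- "double"
  z <- sweep(x, 2L, 2 * p, "-")
  z[is.na(z)] <- 0          # imputed value 2p centers to zero
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  a <- tcrossprod(z) / length(p)
  dimnames(a) <- list(geno$individuals, geno$individuals)
  structure(list(matrix = a, n_snps_used = length(p)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM:", nrow(x$matrix), "individuals,", x$n_snps_used, "SNPs\n")
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(x$matrix)),
              mean(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

# REML quantities for V = s_g * A + s_e * I in the eigenbasis of A.
# X is the fixed-effect design (rotated), d the eigenvalues of A.
.reml_eval <- function(theta, d, yt, Xt) {
  w <- theta[1] * d + theta[2]
  if (any(w <= 0)) return(NULL)
  p <- ncol(Xt)
  XtViX <- crossprod(Xt, Xt / w)
  XtViy <- crossprod(Xt, yt / w)
  beta <- solve(XtViX, XtViy)
  r <- yt - Xt %*% beta
  Pyt <- drop(r) / w                       # rotated P y
  yPy <- sum(yt * Pyt)
  ll <- -0.5 * (sum(log(w)) + determinant(XtViX)$modulus[1] + yPy)
  list(w = w, Pyt = Pyt, yPy = yPy, ll = as.numeric(ll), XtViX = XtViX)
}

# projection t = P u for a rotated vector u
.reml_project <- function(u, w, Xt, XtViX) {
  XtViu <- crossprod(Xt, u / w)
  (u - Xt %*% solve(XtViX, XtViu)) / w
}

#' GREML SNP heritability
#'
#' Single-genetic-component REML fit of \code{y = Xb + g + e} with
#' \code{g ~ N(0, sigma2_g A)} and \code{e ~ N(0, sigma2_e I)}, where
#' \code{A} is the GRM. Average-information updates with an
#' expectation-maximization fallback when an AI step leaves the parameter
#' space or decreases the restricted likelihood; convergence when the
#' relative log-likelihood change drops below \code{tol}. The standard
#' error of \code{h2 = sigma2_g / (sigma2_g + sigma2_e)} comes from the
#' inverse average-information matrix via the delta method.
#'
#' @param grm a \code{\link{compute_grm}} result (or a bare matrix).
#' @param phenotype numeric trait vector aligned with the GRM rows, or a
#'   data.frame with \code{individual_id}, \code{value}.
#' @param covariates optional numeric covariate matrix (an intercept is
#'   always included).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   likelihood trajectory.
#' @return An object of class \code{reml_h2}: \code{sigma2_g},
#'   \code{sigma2_e}, \code{h2}, \code{se_h2}, \code{loglik},
#'   \code{n_iter}, \code{trajectory}.
#' @export
reml_h2 <- function(grm, phenotype, covariates = NULL,
                    tol = 1e-6, max_iter = 100L) {
  a <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  if (is.data.frame(phenotype)) {
    y <- phenotype$value[match(rownames(a), phenotype$individual_id)]
    if (anyNA(y)) stop("phenotype missing for some GRM individuals")
  } else {
    y <- as.numeric(phenotype)
  }
  n <- length(y)
  if (nrow(a) != n) stop("GRM and phenotype dimensions differ")
  vy <- stats::var(y)
  if (vy == 0) stop("phenotype has zero variance")
  e <- eigen((a + t(a)) / 2, symmetric = TRUE)
  d <- e$values
  if (stats::sd(d) < 1e-8) {
    stop("GRM is (numerically) proportional to the identity; ",
         "genetic and residual variance are not separable")
  }
  X <- cbind(intercept = rep(1, n), covariates)
  yt <- drop(crossprod(e$vectors, y))
  Xt <- crossprod(e$vectors, X)

  theta <- c(g = vy / 2, e = vy / 2)
  floor_v <- 1e-8 * vy
  cur <- .reml_eval(theta, d, yt, Xt)
  traj <- cur$ll
  ai <- NULL
  for (it in seq_len(max_iter)) {
    # gradient and average information
    u_g <- d * cur$Pyt
    u_e <- cur$Pyt
    trPVg <- sum(d / cur$w) -
      sum(diag(solve(cur$XtViX, crossprod(Xt, Xt * (d / cur$w^2)))))
    trPVe <- sum(1 / cur$w) -
      sum(diag(solve(cur$XtViX, crossprod(Xt, Xt * (1 / cur$w^2)))))
    yPVgPy <- sum(cur$Pyt * u_g)
    yPVePy <- sum(cur$Pyt * u_e)
    grad <- -0.5 * c(trPVg - yPVgPy, trPVe - yPVePy)
    t_g <- .reml_project(u_g, cur$w, Xt, cur$XtViX)
    t_e <- .reml_project(u_e, cur$w, Xt, cur$XtViX)
    ai <- 0.5 * matrix(c(sum(u_g * t_g), sum(u_g * t_e),
                         sum(u_e * t_g), sum(u_e * t_e)), 2, 2)
    step_ok <- FALSE
    prop <- tryCatch(theta + drop(solve(ai, grad)), error = function(e) NULL)
    if (!is.null(prop)) {
      prop <- pmax(prop, floor_v)   # clamp to the boundary, GCTA-style
      cand <- .reml_eval(prop, d, yt, Xt)
      if (!is.null(cand) && cand$ll >= cur$ll - 1e-10) {
        theta <- prop; new <- cand; step_ok <- TRUE
      }
    }
    if (!step_ok) {          # EM fallback: guaranteed ascent direction
      prop <- c(theta[1] + theta[1]^2 * (yPVgPy - trPVg) / n,
                theta[2] + theta[2]^2 * (yPVePy - trPVe) / n)
      prop <- pmax(prop, floor_v)
      new <- .reml_eval(prop, d, yt, Xt)
      theta <- prop
    }
    traj <- c(traj, new$ll)
    conv <- abs(new$ll - cur$ll) < tol * max(1, abs(cur$ll))
    cur <- new
    if (conv) break
  }
  if (!conv) {
    stop("REML did not converge in ", max_iter, " iterations; trajectory: ",
         paste(sprintf("%.4f", utils::tail(traj, 5)), collapse = ", "))
  }
  h2 <- theta[1] / sum(theta)
  se_h2 <- tryCatch({
    cv <- solve(ai)
    gr <- c(theta[2], -theta[1]) / sum(theta)^2
    sqrt(drop(t(gr) %*% cv %*% gr))
  }, error = function(e) NA_real_)
  structure(list(sigma2_g = unname(theta[1]), sigma2_e = unname(theta[2]),
                 h2 = unname(h2), se_h2 = se_h2, loglik = cur$ll,
                 n_iter = it, trajectory = traj),
            class = "reml_h2")
}

#' @export
print.reml_h2 <- function(x, ...) {
  cat(sprintf("GREML: h2 = %.3f (SE %.3f); sigma2_g = %.4g, sigma2_e = %.4g\n",
              x$h2, x$se_h2, x$sigma2_g, x$sigma2_e))
  cat(sprintf("  logLik = %.3f after %d iterations\n", x$loglik, x$n_iter))
  invisible(x)
}

# vectorized per-SNP least-squares tests of y ~ W + snp
.marginal_tests <- function(y, W, X, idx = seq_len(ncol(X))) {
  qw <- qr(W)
  Q <- qr.Q(qw)
  ry <- y - Q %*% crossprod(Q, y)
  RX <- X[, idx, drop = FALSE] -
    Q %*% crossprod(Q, X[, idx, drop = FALSE])
  sxx <- colSums(RX^2)
  sxy <- drop(crossprod(RX, ry))
  syy <- sum(ry^2)
  df <- length(y) - qw$rank - 1L
  beta <- ifelse(sxx > 1e-12, sxy / sxx, NA_real_)
  sse <- pmax(syy - ifelse(sxx > 1e-12, sxy^2 / sxx, 0), 0)
  tt <- beta / sqrt(sse / df / sxx)
  pv <- 2 * stats::pt(-abs(tt), df)
  pv[!is.finite(pv)] <- 1
  list(p = pv, beta = beta)
}

# maximized REML log-likelihood of y = Xb + u + e with u ~ N(0, s_g ZZ'/k)
# (low-rank kinship built from k pseudo-QTL dosage columns Z)
.kinship_ll <- function(y, X, Z) {
  k <- ncol(Z)
  n <- length(y)
  Zs <- sweep(Z, 2L, colMeans(Z), "-") / sqrt(k)
  sv <- svd(Zs, nu = min(n, k), nv = 0)
  q <- sum(sv$d > 1e-10)
  if (q == 0L) return(-Inf)
  U <- sv$u[, seq_len(q), drop = FALSE]
  lam <- sv$d[seq_len(q)]^2
  yu <- drop(crossprod(U, y))
  Xu <- crossprod(U, X)
  yy <- sum(y^2); Xy <- drop(crossprod(X, y)); XX <- crossprod(X)
  p <- ncol(X)
  ll_of <- function(loglam) {
    l <- exp(loglam)
    w <- l * lam + 1
    XtViX <- (XX - crossprod(Xu)) + crossprod(Xu, Xu / w)
    XtViy <- (Xy - drop(crossprod(Xu, yu))) + drop(crossprod(Xu, yu / w))
    beta <- solve(XtViX, XtViy)
    yViy <- (yy - sum(yu^2)) + sum(yu^2 / w)
    yPy <- yViy - sum(XtViy * beta)
    s2 <- yPy / (n - p)
    -0.5 * (sum(log(w)) + (n - p) * log(s2) +
              determinant(XtViX)$modulus[1] + (n - p))
  }
  stats::optimize(ll_of, c(-10, 10), maximum = TRUE)$objective
}

#' Iterative fixed/random-effect association scan
#'
#' A FarmCPU-style loop: iteration 0 tests every SNP with a per-marker
#' fixed-effect least-squares model; pseudo-QTL candidates (the most
#' significant SNP per genomic bin among those below the candidacy
#' threshold) are then screened by maximizing the restricted likelihood of
#' a random-effect model whose kinship is built from the candidate SNPs;
#' subsequent iterations re-test every SNP with the selected pseudo-QTLs
#' as fixed covariates, excluding any pseudo-QTL lying in the tested SNP's
#' own bin. The loop stops when the pseudo-QTL set is unchanged or
#' \code{max_iter} is reached. Significance is Bonferroni at
#' \code{alpha / m}; the explained variance (PVE) of each significant SNP
#' is its R-squared increment over the final covariate model.
#'
#' @param geno a filtered \code{\link{genotype_table}}.
#' @param phenotype numeric vector aligned with the genotype individuals,
#'   or a data.frame with \code{individual_id}, \code{value}.
#' @param covariates optional numeric covariate matrix.
#' @param max_iter cap on fixed/random iterations (default 10).
#' @param bin_size genomic bin width for pseudo-QTL selection (default
#'   10 Mb).
#' @param candidate_p candidacy p-value threshold (default 1e-4).
#' @param alpha family-wise level for the Bonferroni threshold.
#' @param max_qtl cap on simultaneously fitted pseudo-QTLs.
#' @return An object of class \code{gwas_scan}: per-SNP \code{results}
#'   (chrom, pos, p, effect, maf, pve), \code{threshold},
#'   \code{significant} (SNP indices), \code{pseudo_qtls}, \code{n_iter}.
#' @export
farmcpu_scan <- function(geno, phenotype, covariates = NULL,
                         max_iter = 10L, bin_size = 1e7,
                         candidate_p = 1e-4, alpha = 0.05,
                         max_qtl = 20L) {
  if (is.data.frame(phenotype)) {
    y <- phenotype$value[match(geno$individuals, phenotype$individual_id)]
  } else {
    y <- as.numeric(phenotype)
  }
  if (anyNA(y)) stop("phenotype must be complete for all tested individuals")
  n <- length(y)
  if (n < 30L) stop("need at least 30 individuals")
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  X <- dosage_matrix(geno)
  m <- ncol(X)
  W0 <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    full <- cbind(W0, covariates)
    qrf <- qr(full)
    if (qrf$rank < ncol(full)) {
      drop_cols <- qrf$pivot[seq(qrf$rank + 1L, ncol(full))]
      warning("dropping singular covariate column(s): ",
              paste(drop_cols - 1L, collapse = ", "))
      full <- full[, qrf$pivot[seq_len(qrf$rank)], drop = FALSE]
    }
    W0 <- full
  }
  bin <- paste(geno$chrom, (geno$pos - 1) %/% bin_size)

  pseudo <- integer(0)
  pv <- rep(1, m); eff <- rep(NA_real_, m)
  for (it in seq_len(max_iter)) {
    W <- if (length(pseudo)) cbind(W0, X[, pseudo, drop = FALSE]) else W0
    mt <- .marginal_tests(y, W, X)
    pv <- mt$p; eff <- mt$beta
    # re-test SNPs sharing a bin with a pseudo-QTL without that covariate
    for (q in pseudo) {
      in_bin <- which(bin == bin[q])
      Wq <- cbind(W0, X[, setdiff(pseudo, q), drop = FALSE])
      mq <- .marginal_tests(y, Wq, X, idx = in_bin)
      pv[in_bin] <- mq$p; eff[in_bin] <- mq$beta
    }
    cand <- which(pv < candidate_p)
    if (length(cand) == 0L) { pseudo_new <- integer(0) }
    else {
      best_per_bin <- vapply(split(cand, bin[cand]), function(ix)
        ix[which.min(pv[ix])], integer(1))
      ord <- best_per_bin[order(pv[best_per_bin])]
      ord <- utils::head(ord, max_qtl)
      # choose how many top bins to keep by the random-model likelihood
      lls <- vapply(seq_along(ord), function(k)
        .kinship_ll(y, W0, X[, ord[seq_len(k)], drop = FALSE]), numeric(1))
      k_best <- which.max(lls)
      pseudo_new <- sort(ord[seq_len(k_best)])
    }
    if (identical(pseudo_new, sort(pseudo))) break
    pseudo <- pseudo_new
  }

  threshold <- alpha / m
  sig <- which(pv < threshold)
  pve <- rep(NA_real_, m)
  if (length(sig)) {
    sst <- sum((y - mean(y))^2)
    for (j in sig) {
      Wj <- cbind(W0, X[, setdiff(pseudo, pseudo[bin[pseudo] == bin[j]]),
                        drop = FALSE])
      q0 <- qr(Wj); r0 <- y - qr.fitted(q0, y)
      q1 <- qr(cbind(Wj, X[, j])); r1 <- y - qr.fitted(q1, y)
      pve[j] <- (sum(r0^2) - sum(r1^2)) / sst
    }
  }
  p_obs <- allele_freq(geno)
  structure(list(
    results = data.frame(chrom = geno$chrom, pos = geno$pos,
                         p = pv, effect = eff,
                         maf = pmin(p_obs, 1 - p_obs), pve = pve),
    threshold = threshold, significant = sig,
    pseudo_qtls = pseudo, n_iter = it), class = "gwas_scan")
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat("association scan:", nrow(x$results), "SNPs;",
      length(x$significant), "significant at Bonferroni",
      format(x$threshold, digits = 3), "\n")
  if (length(x$significant)) {
    print(utils::head(x$results[x$significant, ], 10))
  }
  invisible(x)
}

#' Candidate windows around significant SNPs
#'
#' Closed interval of +/- \code{window} bp around each SNP, clipped to the
#' chromosome bounds.
#'
#' @param snps data.frame with \code{chrom}, \code{pos}.
#' @param window half-width in bp (default 5 Mb).
#' @param chrom_lengths optional named vector for upper clipping.
#' @return data.frame \code{chrom}, \code{pos}, \code{start}, \code{end};
#'   zero rows for empty input.
#' @export
candidate_windows <- function(snps, window = 5e6, chrom_lengths = NULL) {
  if (is.null(snps) || nrow(snps) == 0L) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      start = numeric(0), end = numeric(0)))
  }
  start <- pmax(1, snps$pos - window)
  end <- snps$pos + window
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, unname(chrom_lengths[snps$chrom]))
  }
  data.frame(chrom = snps$chrom, pos = snps$pos, start = start, end = end)
}

#' Detection rate under repeated random subsampling
#'
#' Re-runs the association scan on random subsets of the individuals
#' (default 95\%) and reports, per SNP, the fraction of runs in which it
#' exceeded the Bonferroni threshold.
#'
#' @param geno a \code{\link{genotype_table}}.
#' @param phenotype as in \code{\link{farmcpu_scan}}.
#' @param n_runs subsample replicates (default 1000).
#' @param frac fraction of individuals retained per run, in (0, 1).
#' @param seed integer seed.
#' @param ... passed to \code{\link{farmcpu_scan}}.
#' @return list of class \code{gwas_validation}: \code{detection_rate}
#'   (per SNP), \code{n_runs}.
#' @export
subsample_detection_rate <- function(geno, phenotype, n_runs = 1000,
                                     frac = 0.95, seed = 1L, ...) {
  if (frac <= 0 || frac >= 1) stop("frac must lie in (0, 1)")
  if (is.data.frame(phenotype)) {
    y <- phenotype$value[match(geno$individuals, phenotype$individual_id)]
  } else y <- as.numeric(phenotype)
  n <- n_individuals(geno)
  k <- max(2L, round(frac * n))
  hits <- numeric(n_variants(geno))
  set.seed(seed)
  for (run in seq_len(n_runs)) {
    idx <- sample.int(n, k)
    sub <- subset_genotypes(geno, individuals = idx)
    sc <- farmcpu_scan(sub, y[idx], ...)
    hits[sc$significant] <- hits[sc$significant] + 1
  }
  structure(list(detection_rate = hits / n_runs, n_runs = n_runs),
            class = "gwas_validation")
}

#' Experiment-wise false-positive rate under phenotype permutation
#'
#' Shuffles the phenotype over individuals in each run and records whether
#' any SNP crosses the Bonferroni threshold. Runs in which the permuted
#' phenotype is degenerate (constant) count as having no significant SNP.
#'
#' @param geno a \code{\link{genotype_table}}.
#' @param phenotype as in \code{\link{farmcpu_scan}}.
#' @param n_runs permutation replicates (default 1000).
#' @param seed integer seed.
#' @param ... passed to \code{\link{farmcpu_scan}}.
#' @return list of class \code{gwas_validation}:
#'   \code{permutation_fp_rate}, per-SNP \code{hit_rate}, \code{n_runs}.
#' @export
permutation_null <- function(geno, phenotype, n_runs = 1000, seed = 1L,
                             ...) {
  if (is.data.frame(phenotype)) {
    y <- phenotype$value[match(geno$individuals, phenotype$individual_id)]
  } else y <- as.numeric(phenotype)
  m <- n_variants(geno)
  any_sig <- logical(n_runs)
  hits <- numeric(m)
  set.seed(seed)
  for (run in seq_len(n_runs)) {
    yp <- y[sample.int(length(y))]
    sc <- tryCatch(farmcpu_scan(geno, yp, ...), error = function(e) NULL)
    if (is.null(sc)) next
    any_sig[run] <- length(sc$significant) > 0L
    hits[sc$significant] <- hits[sc$significant] + 1
  }
  structure(list(permutation_fp_rate = mean(any_sig),
                 hit_rate = hits / n_runs, n_runs = n_runs),
            class = "gwas_validation")
}
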