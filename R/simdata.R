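#' Simulation configuration
#'
#' Parameters for the synthetic two-population study: a "feral" population A
#' and a "domesticated" population B diverged under Balding-Nichols drift,
#' optional selective sweeps in population B, polygenic phenotypes with a
#' target narrow-sense heritability, and imaging-flow-cytometry particle
#' tables mixing fertile pollen with gate-violating contaminants.
#'
#' Defaults emulate the statistical structure of a rye domestication panel:
#' mean read depth 19 (reduced-representation sequencing coverage), about
#' 600 imaged pollen per individual, per-individual mean pollen length
#' spanning 39-57 um, and modest genome-wide differentiation
#' (\code{drift_F = 0.05}).
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_pop_a,n_pop_b individuals in populations A (feral) and B
#'   (domesticated).
#' @param n_snps total SNP count across the genome.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (equal for all chromosomes).
#' @param drift_F Balding-Nichols differentiation parameter in [0, 1).
#' @param sweep_loci list of sweeps, each \code{list(chrom=, pos=, strength=)}
#'   with strength in [0, 1]; population-B allele frequencies are pushed
#'   toward fixation with the distortion decaying linearly to zero at
#'   +/- 1 Mb.
#' @param missing_rate per-call missingness fraction.
#' @param depth_mean mean of the Poisson per-call read depth.
#' @param tetraploid_ids identifiers of individuals simulated with doubled
#'   heterozygote probability (capped at 1); genotype coding stays diploid.
#' @param h2 target narrow-sense heritability of the simulated trait.
#' @param n_qtl number of causal SNPs.
#' @param group_shift_sd between-group phenotype shift applied to
#'   population B, in units of the phenotypic SD.
#' @param contaminant_rates named fractions for the aborted, stacked,
#'   debris and blurred particle classes; the remainder is fertile.
#' @param pollen_per_individual particles imaged per individual.
#'
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_pop_a = 50L, n_pop_b = 50L,
                       n_snps = 2000L, n_chrom = 2L, chrom_length = 20e6,
                       drift_F = 0.05,
                       sweep_loci = list(),
                       missing_rate = 0.02, depth_mean = 19,
                       tetraploid_ids = character(0),
                       h2 = 0.5, n_qtl = 100L, group_shift_sd = 0,
                       contaminant_rates = c(aborted = 0.05, stacked = 0.05,
                                             debris = 0.05, blurred = 0.05),
                       pollen_per_individual = 600L) {
  stopifnot(drift_F >= 0, drift_F < 1,
            missing_rate >= 0, missing_rate <= 1,
            depth_mean > 0, n_pop_a >= 1, n_pop_b >= 1,
            n_snps >= 1, n_chrom >= 1, chrom_length >= 1)
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (n_qtl > n_snps) stop("n_qtl must not exceed n_snps")
  if (any(contaminant_rates < 0) || sum(contaminant_rates) > 1) {
    stop("contaminant rates must be non-negative and sum to at most 1")
  }
  for (i in seq_along(sweep_loci)) {
    sw <- sweep_loci[[i]]
    if (sw$chrom > n_chrom || sw$pos < 1 || sw$pos > chrom_length) {
      stop(sprintf("sweep locus %d (chrom %s, pos %s) is off-chromosome",
                   i, sw$chrom, format(sw$pos, scientific = FALSE)))
    }
    if (sw$strength < 0 || sw$strength > 1) {
      stop(sprintf("sweep locus %d has strength outside [0, 1]", i))
    }
  }
  structure(
    list(seed = as.integer(seed), n_pop_a = as.integer(n_pop_a),
         n_pop_b = as.integer(n_pop_b), n_snps = as.integer(n_snps),
         n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
         drift_F = drift_F, sweep_loci = sweep_loci,
         missing_rate = missing_rate, depth_mean = depth_mean,
         tetraploid_ids = tetraploid_ids, h2 = h2,
         n_qtl = as.integer(n_qtl), group_shift_sd = group_shift_sd,
         contaminant_rates = contaminant_rates,
         pollen_per_individual = as.integer(pollen_per_individual)),
    class = "sim_config"
  )
}

# Fixed per-component offsets so each generator draws from its own stream.
.sim_seed <- function(config, offset) {
  set.seed((config$seed + offset) %% 2147483647L)
}

#' Simulate two-population genotypes under Balding-Nichols drift
#'
#' Ancestral allele frequencies are drawn uniform on [0.05, 0.95]; each
#' population's frequencies are Beta-distributed around them with variance
#' \code{drift_F * p * (1 - p)} (Balding-Nichols). At planted sweep loci the
#' population-B frequency is pushed toward fixation, with the push decaying
#' linearly to zero at +/- 1 Mb and scaled by the sweep strength. Genotypes
#' are binomial(2, p), depths Poisson, missingness Bernoulli. Individuals
#' listed in \code{tetraploid_ids} receive doubled heterozygote
#' probability (capped at 1) while staying diploid-coded.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{geno} (a \code{\link{genotype_table}}),
#'   \code{groups} (data.frame individual_id, group in \{feral,
#'   domesticated\}) and \code{truth} (sweep windows, population allele
#'   frequencies, ancestral frequencies, tetraploid ids).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .sim_seed(config, 101L)
  m <- config$n_snps
  per_chrom <- diff(round(seq(0, m, length.out = config$n_chrom + 1L)))
  chrom <- rep(sprintf("chr%d", seq_len(config$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(config$chrom_length, k))), use.names = FALSE)

  p_anc <- stats::runif(m, 0.05, 0.95)
  if (config$drift_F == 0) {
    p_a <- p_anc
    p_b <- p_anc
  } else {
    f <- config$drift_F
    a <- p_anc * (1 - f) / f
    b <- (1 - p_anc) * (1 - f) / f
    p_a <- stats::rbeta(m, a, b)
    p_b <- stats::rbeta(m, a, b)
  }

  sweep_windows <- NULL
  for (sw in config$sweep_loci) {
    ch <- sprintf("chr%d", sw$chrom)
    d <- abs(pos - sw$pos)
    hit <- chrom == ch & d < 1e6
    w <- sw$strength * (1 - d[hit] / 1e6)
    p_b[hit] <- p_b[hit] + (1 - p_b[hit]) * w
    sweep_windows <- rbind(sweep_windows, data.frame(
      chrom = ch, start = max(1, sw$pos - 1e6),
      end = min(config$chrom_length, sw$pos + 1e6),
      strength = sw$strength))
  }

  n_a <- config$n_pop_a
  n_b <- config$n_pop_b
  ids <- c(sprintf("A%03d", seq_len(n_a)), sprintf("B%03d", seq_len(n_b)))
  p_ind <- rbind(matrix(p_a, n_a, m, byrow = TRUE),
                 matrix(p_b, n_b, m, byrow = TRUE))
  calls <- matrix(stats::rbinom(length(p_ind), 2L, p_ind),
                  nrow = n_a + n_b)

  tet <- match(config$tetraploid_ids, ids)
  tet <- tet[!is.na(tet)]
  for (i in tet) {
    p <- p_ind[i, ]
    h <- pmin(1, 2 * 2 * p * (1 - p))
    u <- stats::runif(m)
    homalt <- p^2 / (p^2 + (1 - p)^2)
    calls[i, ] <- ifelse(u < h, 1L,
                         ifelse(stats::runif(m) < homalt, 2L, 0L))
  }

  depths <- matrix(stats::rpois(length(calls), config$depth_mean),
                   nrow = nrow(calls))
  if (config$missing_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < config$missing_rate,
                 nrow = nrow(calls))] <- NA_integer_
  }

  geno <- genotype_table(calls, chrom = chrom, pos = pos, depths = depths,
                         individuals = ids)
  groups <- data.frame(
    individual_id = ids,
    group = rep(c("feral", "domesticated"), c(n_a, n_b)),
    stringsAsFactors = FALSE)
  truth <- list(sweep_windows = sweep_windows,
                p_ancestral = p_anc, p_feral = p_a, p_domesticated = p_b,
                tetraploid_ids = ids[tet])
  list(geno = geno, groups = groups, truth = truth)
}

#' Simulate a polygenic phenotype with target heritability
#'
#' The trait is \code{y = X beta + shift + e}: \code{n_qtl} causal SNPs are
#' drawn at random with standard-normal effects, the environmental variance
#' is scaled so the additive fraction equals \code{h2}, and population B is
#' shifted by \code{group_shift_sd} phenotypic standard deviations.
#'
#' @param sim output of \code{\link{simulate_genotypes}} (or a bare
#'   \code{genotype_table}, in which case all individuals are treated as one
#'   group and no shift is applied).
#' @param config the \code{\link{sim_config}} used for the genotypes.
#' @return list with \code{phenotypes} (data.frame individual_id, value) and
#'   \code{truth} (causal SNP indices/effects, genetic values, realized h2).
#' @export
simulate_phenotypes <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- if (inherits(sim, "genotype_table")) sim else sim$geno
  groups <- if (inherits(sim, "genotype_table")) NULL else sim$groups
  if (config$h2 < 0 || config$h2 > 1) stop("h2 must lie in [0, 1]")
  .sim_seed(config, 202L)
  n <- n_individuals(geno)
  m <- n_variants(geno)

  if (config$h2 == 0) {
    qtl <- integer(0)
    beta <- numeric(0)
    g <- rep(0, n)
    sigma_e <- 1
  } else {
    qtl <- sort(sample.int(m, config$n_qtl))
    beta <- stats::rnorm(config$n_qtl)
    x <- dosage_matrix(geno)[, qtl, drop = FALSE]
    g <- drop(x %*% beta)
    vg <- stats::var(g)
    sigma_e <- if (config$h2 == 1) 0 else sqrt(vg * (1 - config$h2) / config$h2)
  }
  e <- stats::rnorm(n, 0, sigma_e)
  y <- g + e
  if (!is.null(groups) && config$group_shift_sd != 0) {
    shift <- config$group_shift_sd * stats::sd(y)
    y[groups$group == "domesticated"] <- y[groups$group == "domesticated"] + shift
  }
  realized <- if (config$h2 == 0) 0 else stats::var(g) / stats::var(g + e)
  list(
    phenotypes = data.frame(individual_id = geno$individuals, value = y,
                            stringsAsFactors = FALSE),
    truth = list(qtl_index = qtl, qtl_effects = beta, genetic_values = g,
                 target_h2 = config$h2, realized_h2 = realized)
  )
}

# Feature draws strictly inside every gate of the default cascade.
.fertile_features <- function(k, mu_len) {
  len <- pmin(95, pmax(25, stats::rnorm(k, mu_len, 2.5)))
  elong <- stats::runif(k, 1.02, 1.28)
  width <- len / elong
  z <- stats::rnorm(k)
  fl <- function() exp(6.9 + 0.95 * z + 0.31 * stats::rnorm(k))
  data.frame(
    diameter = (len + width) / 2,
    brightfield_intensity = stats::runif(k, -1.1e6, -4e5),
    median_pixel = stats::runif(k, -450, -150),
    symmetry3 = stats::runif(k, 0.5, 2.5),
    symmetry4 = stats::runif(k, 0.5, 2.5),
    correlation_mean = stats::runif(k, 0.25, 0.55),
    gradient_rms = stats::runif(k, 9, 18),
    pollen_length = len, pollen_width = width,
    pollen_area = pi / 4 * len * width,
    fluor_ch2 = fl(), fluor_ch3 = fl(), fluor_ch4 = fl(), fluor_ch5 = fl())
}

#' Simulate an imaging-flow-cytometry particle table
#'
#' Fertile particles carry features strictly inside every gate of the
#' default cascade; each contaminant class violates exactly one designated
#' gate step (aborted: median pixel intensity; stacked: symmetry; debris:
#' diameter; blurred: gradient RMS) and is otherwise in range. Per-individual
#' mean pollen length is uniform on [39, 57] um, emulating the span of
#' per-individual pollen sizes in a diverse rye panel.
#'
#' @param individuals character vector of individual identifiers.
#' @param config a \code{\link{sim_config}}; uses \code{contaminant_rates}
#'   and \code{pollen_per_individual}.
#' @return list with \code{particles} (one row per imaged object) and
#'   \code{truth} (data.frame particle_id, class, individual mean lengths).
#' @export
simulate_mifc_particles <- function(individuals, config) {
  stopifnot(inherits(config, "sim_config"))
  rates <- config$contaminant_rates
  if (sum(rates) > 1) stop("contaminant rates must sum to at most 1")
  .sim_seed(config, 303L)
  classes <- c("fertile", names(rates))
  probs <- c(1 - sum(rates), unname(rates))
  out <- vector("list", length(individuals))
  mu_len <- stats::runif(length(individuals), 39, 57)
  for (i in seq_along(individuals)) {
    k <- config$pollen_per_individual
    cls <- sample(classes, k, replace = TRUE, prob = probs)
    feat <- .fertile_features(k, mu_len[i])
    ab <- cls == "aborted"
    feat$median_pixel[ab] <- stats::runif(sum(ab), -95, -10)
    st <- cls == "stacked"
    feat$symmetry3[st] <- stats::runif(sum(st), 3.2, 6)
    de <- cls == "debris"
    feat$diameter[de] <- stats::runif(sum(de), 5, 19.5)
    bl <- cls == "blurred"
    feat$gradient_rms[bl] <- stats::runif(sum(bl), 2, 7.5)
    out[[i]] <- cbind(data.frame(individual_id = individuals[i],
                                 class = cls, stringsAsFactors = FALSE),
                      feat)
  }
  tab <- do.call(rbind, out)
  tab$particle_id <- seq_len(nrow(tab))
  particles <- tab[, c("particle_id", "individual_id",
                       setdiff(names(tab), c("particle_id", "individual_id",
                                             "class")))]
  truth <- list(
    labels = data.frame(particle_id = tab$particle_id, class = tab$class,
                        stringsAsFactors = FALSE),
    mu_length = stats::setNames(mu_len, individuals))
  list(particles = particles, truth = truth)
}
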