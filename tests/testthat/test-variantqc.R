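# 10-site toy with depths engineered to exercise every rule; the expected
# surviving set is derived by hand below.
make_toy_qc <- function() {
  calls <- matrix(NA_integer_, nrow = 10, ncol = 10)
  set.seed(99)
  for (j in 1:10) calls[, j] <- rbinom(10, 2, 0.5)
  depths <- matrix(10L, 10, 10)
  # site 2: indel; site 3: multiallelic
  ref <- rep("A", 10); alt <- rep("T", 10)
  ref[2] <- "AT"
  alt[3] <- "T,G"
  # site 4: low depth for 3 genotypes -> callrate 0.7 < 0.9
  depths[1:3, 4] <- 2L
  # site 5: rare allele -> MAF < 0.05
  calls[, 5] <- c(1L, rep(0L, 9))       # MAF 0.05... use a rarer one
  calls[, 5] <- c(rep(0L, 10)); calls[1, 5] <- 1L  # MAF 0.05 exactly -> kept
  calls[, 6] <- rep(0L, 10)             # monomorphic -> MAF 0 -> dropped
  # site 7: one masked call keeps callrate 0.9 -> kept
  depths[1, 7] <- 1L
  toy_geno(calls, depths = depths, ref = ref, alt = alt)
}

test_that("filter chain matches the hand-derived surviving set", {
  g <- make_toy_qc()
  spec <- filter_spec(min_dp = 4, max_missing = 0.9, maf = 0.05)
  res <- filter_variants(g, spec)
  # hand application: drop 2 (indel), 3 (multiallelic), 4 (callrate 0.7),
  # 6 (monomorphic); site 5 has MAF exactly 0.05 (floor, kept);
  # site 7 keeps callrate 0.9 after one masked call
  expect_setequal(res$geno$pos, c(1, 5, 7, 8, 9, 10) * 1000)
  expect_identical(unname(res$removed["indel"]), 1L)
  expect_identical(unname(res$removed["multiallelic"]), 1L)
  expect_identical(unname(res$removed["low_callrate"]), 1L)
  expect_identical(unname(res$removed["low_maf"]), 1L)
  # per-rule site counts sum to input - output
  expect_identical(sum(res$removed[-1]),
                   n_variants(g) - n_variants(res$geno))
  # MAF floor holds at every retained site
  p <- allele_freq(res$geno)
  expect_true(all(pmin(p, 1 - p) >= 0.05))
})

test_that("disabled constraints are the identity and filtering is idempotent", {
  g <- make_toy_qc()
  none <- filter_spec(biallelic_only = FALSE, remove_indels = FALSE)
  expect_identical(filter_variants(g, none)$geno$calls, g$calls)
  spec <- qc_preset("gwas")
  once <- filter_variants(g, spec)$geno
  twice <- filter_variants(once, spec)
  expect_identical(twice$geno$calls, once$calls)
  expect_true(all(twice$removed[-1] == 0))
})

test_that("depth masking can push a site below the callrate floor", {
  calls <- matrix(2L, nrow = 20, ncol = 1)
  calls[, 1] <- rbinom(20, 2, 0.5)
  depths <- matrix(10L, 20, 1)
  depths[1:3, 1] <- 2L             # callrate 1.0 -> 0.85 after masking
  g <- toy_geno(calls, depths = depths)
  res <- filter_variants(g, filter_spec(min_dp = 4, max_missing = 0.9))
  expect_identical(n_variants(res$geno), 0L)
})

test_that("presets encode the two study filter chains", {
  gw <- qc_preset("gwas")
  expect_identical(gw$min_dp, 4)
  expect_identical(gw$max_missing, 0.9)
  expect_identical(gw$maf, 0.05)
  pg <- qc_preset("popgen")
  expect_identical(pg$min_dp, 10)
  expect_identical(pg$max_dp, 100)
  expect_identical(pg$max_missing, 0.7)
  expect_identical(pg$maf, 0.01)
  expect_true(gw$biallelic_only && gw$remove_indels)
})

test_that("heterozygosity proportion counts het over non-missing", {
  g <- toy_geno(matrix(c(0L, 1L, 2L, NA), nrow = 1))
  expect_equal(het_proportion(g, 1), 1 / 3)
  g2 <- toy_geno(matrix(rep(1L, 5), nrow = 1))
  expect_identical(het_proportion(g2, 1), 1)
  g3 <- toy_geno(matrix(NA_integer_, nrow = 1, ncol = 3))
  expect_error(het_proportion(g3, 1), "no called")
})

test_that("ploidy classification recovers planted tetraploids", {
  cfg <- sim_config(seed = 47, n_snps = 2000, n_pop_a = 15, n_pop_b = 15,
                    missing_rate = 0, tetraploid_ids = c("A002", "B007"))
  sim <- simulate_genotypes(cfg)
  het <- vapply(seq_len(30), function(i) het_proportion(sim$geno, i),
                numeric(1))
  names(het) <- sim$geno$individuals
  refs <- c(A001 = "diploid", B001 = "diploid", A002 = "tetraploid")
  out <- classify_ploidy(het, refs)
  calls <- setNames(out$calls$ploidy, out$calls$individual_id)
  expect_identical(unname(calls["B007"]), "tetraploid")
  expect_identical(unname(calls["A005"]), "diploid")
  # midpoint ties break toward the lower ploidy
  het2 <- c(r1 = 0.2, r2 = 0.6, unk = 0.4)
  out2 <- classify_ploidy(het2, c(r1 = "diploid", r2 = "tetraploid"))
  expect_identical(out2$calls$ploidy[out2$calls$individual_id == "unk"],
                   "diploid")
  expect_error(classify_ploidy(het2, c(r1 = "diploid")), "per ploidy class")
})

test_that("LD decays as expected for duplicated and independent sites", {
  set.seed(5)
  x <- rbinom(50, 2, 0.5)
  calls <- cbind(x, x, rbinom(50, 2, 0.5))
  g <- toy_geno(matrix(as.integer(calls), nrow = 50),
                pos = c(1L, 1000001L, 30000001L))
  out <- ld_r2_by_distance(g, min_dist = 1e6, max_dist = 20e6,
                           bin_width = 1e6)
  expect_equal(out$mean_r2[out$distance_lo == 1e6][1], 1, tolerance = 1e-12)
  # independent simulated sites: mean r2 near the 1/(n-1) bias floor
  set.seed(6)
  n <- 100
  calls <- matrix(rbinom(n * 200, 2, 0.5), nrow = n)
  g2 <- toy_geno(calls, pos = as.integer(seq(1, 39e6, length.out = 200)))
  out2 <- ld_r2_by_distance(g2)
  mean_r2 <- sum(out2$mean_r2 * out2$n_pairs) / sum(out2$n_pairs)
  expect_lt(abs(mean_r2 - 1 / (n - 1)), 0.005)
  # monomorphic sites yield no usable pair
  g3 <- toy_geno(matrix(c(1L, 1L, 1L, 1L, 0L, 1L, 2L, 1L), nrow = 4),
                 pos = c(1L, 2000001L))
  expect_identical(nrow(ld_r2_by_distance(g3)), 0L)
})
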