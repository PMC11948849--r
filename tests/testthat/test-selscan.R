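test_that("window tiling follows the size/overlap convention", {
  w <- make_windows(c(chr1 = 3e6), size = 1e6, overlap = 250e3)
  expect_identical(w$start, c(1, 750001, 1500001, 2250001))
  expect_identical(w$end, c(1e6, 1750000, 2500000, 3e6))
  # zero overlap: disjoint tiling
  w0 <- make_windows(c(chr1 = 3e6), size = 1e6, overlap = 0)
  expect_identical(w0$start, c(1, 1000001, 2000001))
  expect_true(all(w0$start[-1] == w0$end[-nrow(w0)] + 1))
  # window larger than the chromosome: one truncated window
  w1 <- make_windows(c(chr1 = 5e5), size = 1e6, overlap = 250e3)
  expect_identical(nrow(w1), 1L)
  expect_identical(w1$end, 5e5)
  expect_error(make_windows(c(chr1 = 1e6), size = 1e6, overlap = 1e6),
               "overlap")
})

test_that("per-site components match an independent W-C transcription", {
  set.seed(61)
  tp <- two_pop_geno(runif(50, 0.1, 0.9), runif(50, 0.1, 0.9), n = 10)
  tp$geno$calls[sample(length(tp$geno$calls), 40)] <- NA  # some missing
  res <- weir_fst(tp$geno, tp$groups)
  for (j in seq_len(50)) {
    o <- wc_site_oracle(tp$geno$calls[1:10, j], tp$geno$calls[11:20, j])
    expect_equal(res$per_site$a[j], unname(o["a"]), tolerance = 1e-12)
    expect_equal(res$per_site$b[j], unname(o["b"]), tolerance = 1e-12)
    expect_equal(res$per_site$c[j], unname(o["c"]), tolerance = 1e-12)
  }
})

test_that("fixed differences give F_ST one; identical groups give ~zero", {
  calls <- rbind(matrix(0L, 10, 5), matrix(2L, 10, 5))
  tp <- list(geno = toy_geno(calls,
                             individuals = c(sprintf("A%d", 1:10),
                                             sprintf("B%d", 1:10))),
             groups = data.frame(
               individual_id = c(sprintf("A%d", 1:10), sprintf("B%d", 1:10)),
               group = rep(c("feral", "domesticated"), each = 10)))
  res <- weir_fst(tp$geno, tp$groups)
  expect_equal(res$per_site$fst, rep(1, 5), tolerance = 1e-12)
  p <- runif(200, 0.2, 0.8)
  same <- two_pop_geno(p, p, n = 100, seed = 62)
  expect_lt(abs(weir_fst(same$geno, same$groups)$fst_genomewide), 0.02)
})

test_that("windowed F_ST is a ratio of sums within per-site bounds", {
  set.seed(63)
  tp <- two_pop_geno(runif(100, 0.1, 0.9), runif(100, 0.1, 0.9), n = 15)
  w <- make_windows(c(chr1 = 100e3), size = 50e3, overlap = 0)
  res <- weir_fst(tp$geno, tp$groups, w)
  site_in <- res$per_site$pos <= 50e3
  expect_equal(res$windowed$fst[1],
               sum(res$per_site$a[site_in]) /
                 sum((res$per_site$a + res$per_site$b +
                        res$per_site$c)[site_in]), tolerance = 1e-12)
  rng <- range(res$per_site$fst[site_in], na.rm = TRUE)
  expect_gte(res$windowed$fst[1], rng[1])
  expect_lte(res$windowed$fst[1], rng[2])
})

test_that("windowed diversity matches hand arithmetic and label swap", {
  # one site, p = 0.5, 20 alleles, 1 Mb window
  calls <- matrix(c(rep(0L, 5), rep(2L, 5)), ncol = 1)
  g <- toy_geno(calls, pos = 500000L)
  w <- data.frame(chrom = "chr1", start = 1, end = 1e6)
  got <- windowed_pi(g, 1:10, w)
  expect_equal(got, (2 * 0.25 * 20 / 19) / 1e6, tolerance = 1e-12)
  # allele-label swap leaves pi unchanged
  swapped <- toy_geno(2L - calls, pos = 500000L)
  expect_equal(windowed_pi(swapped, 1:10, w), got, tolerance = 1e-12)
  # monomorphic window is zero
  g0 <- toy_geno(matrix(rep(2L, 10), ncol = 1), pos = 500000L)
  expect_identical(windowed_pi(g0, 1:10, w), 0)
})

test_that("DRI is the diversity ratio with flagged undefined windows", {
  expect_identical(dri(c(1, 0, 2), c(1, 2, 0)), c(1, 0, NA))
  x <- c(0.5, 1.2, 3)
  y <- c(1.1, 0.3, 2)
  expect_equal(dri(x, y) * dri(y, x), rep(1, 3), tolerance = 1e-12)
})

test_that("XP-CLR is zero on a degenerate grid and concentrated under neutrality", {
  cfg <- sim_config(seed = 67, n_snps = 2000, n_chrom = 1,
                    chrom_length = 20e6, drift_F = 0.05,
                    n_pop_a = 30, n_pop_b = 30)
  sim <- simulate_genotypes(cfg)
  w <- make_windows(c(chr1 = 20e6))
  null_only <- xpclr_scan(sim$geno, sim$groups, w,
                          xpclr_config(sel_coeff_grid = 0))
  expect_true(all(null_only$scores[!is.na(null_only$scores)] == 0))
  xp <- xpclr_scan(sim$geno, sim$groups, w)
  sc <- xp$scores[!is.na(xp$scores)]
  expect_true(all(sc >= 0))
  expect_lt(median(sc), quantile(sc, 0.95) / 5 + 1e-9)
})

test_that("sweep strength ranks the sweep-window XP-CLR score", {
  scores <- vapply(c(0.2, 0.5, 0.8), function(s) {
    cfg <- sim_config(seed = 71, n_snps = 2000, n_chrom = 1,
                      chrom_length = 20e6, drift_F = 0.05,
                      n_pop_a = 30, n_pop_b = 30,
                      sweep_loci = list(list(chrom = 1, pos = 10e6,
                                             strength = s)))
    sim <- simulate_genotypes(cfg)
    w <- make_windows(c(chr1 = 20e6))
    xp <- xpclr_scan(sim$geno, sim$groups, w, reference = "feral")
    hit <- w$start <= 10e6 & w$end >= 10e6
    max(xp$scores[hit], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("percentile calling flags exactly the strict top 5%", {
  vals <- sample(1:100)
  flags <- call_significant(vals)
  expect_identical(sum(flags), 5L)
  expect_setequal(vals[flags], 96:100)
  expect_identical(sum(call_significant(rep(1, 30))), 0L)
  expect_error(call_significant(1:10), "20 windows")
  z <- z_transform(vals)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("QTL screening reports overlap with flagged windows", {
  scan <- data.frame(chrom = "chr1",
                     start = c(1, 10e6, 20e6), end = c(1e6, 11e6, 21e6),
                     fst_sig = c(TRUE, FALSE, FALSE),
                     dri_sig = c(FALSE, FALSE, TRUE))
  qtl <- data.frame(chrom = "chr1", pos = c(5e5, 17e6, 40e6))
  out <- screen_qtl(qtl, scan, span = 5e6)
  expect_identical(out$evidence$fst_sig, c(TRUE, FALSE, FALSE))
  expect_identical(out$evidence$dri_sig, c(FALSE, TRUE, FALSE))
  expect_identical(out$evidence$any_sig, c(TRUE, TRUE, FALSE))
  expect_equal(out$fraction_under_selection, 2 / 3)
})
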