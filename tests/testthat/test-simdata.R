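test_that("identical config yields byte-identical outputs", {
  cfg <- sim_config(seed = 7, n_snps = 200, n_pop_a = 10, n_pop_b = 10)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1, s2)
  p1 <- simulate_phenotypes(s1, cfg)
  p2 <- simulate_phenotypes(s2, cfg)
  expect_identical(p1, p2)
  m1 <- simulate_mifc_particles(c("i1", "i2"), cfg)
  m2 <- simulate_mifc_particles(c("i1", "i2"), cfg)
  expect_identical(m1, m2)
})

test_that("no drift means no systematic frequency difference", {
  cfg <- sim_config(seed = 11, drift_F = 0, n_pop_a = 100, n_pop_b = 100,
                    n_snps = 2000, missing_rate = 0)
  sim <- simulate_genotypes(cfg)
  pa <- colMeans(sim$geno$calls[sim$groups$group == "feral", ]) / 2
  pb <- colMeans(sim$geno$calls[sim$groups$group == "domesticated", ]) / 2
  expect_lt(abs(mean(pa - pb)), 0.01)
  # pooled frequency stays within 3 binomial SE of the drawn ancestral one
  pooled <- colMeans(sim$geno$calls) / 2
  se <- sqrt(sim$truth$p_ancestral * (1 - sim$truth$p_ancestral) / 400)
  expect_gt(mean(abs(pooled - sim$truth$p_ancestral) <= 3 * se), 0.99)
})

test_that("sweep loci raise local frequency differentiation", {
  cfg <- sim_config(seed = 13, n_snps = 2000, n_chrom = 1,
                    chrom_length = 20e6, drift_F = 0.02,
                    sweep_loci = list(list(chrom = 1, pos = 10e6,
                                           strength = 0.8)))
  sim <- simulate_genotypes(cfg)
  d <- abs(sim$truth$p_feral - sim$truth$p_domesticated)
  inside <- sim$geno$pos >= 9e6 & sim$geno$pos <= 11e6
  expect_gt(mean(d[inside]), mean(d[!inside]))
})

test_that("off-chromosome sweep positions are rejected by name", {
  expect_error(sim_config(sweep_loci = list(list(chrom = 1, pos = 30e6,
                                                 strength = 0.5))),
               "sweep locus 1")
})

test_that("tetraploid individuals show inflated heterozygosity", {
  cfg <- sim_config(seed = 17, n_snps = 2000, n_pop_a = 20, n_pop_b = 20,
                    missing_rate = 0, tetraploid_ids = c("A001", "B003"))
  sim <- simulate_genotypes(cfg)
  het <- vapply(seq_len(40), function(i) het_proportion(sim$geno, i),
                numeric(1))
  tet <- sim$geno$individuals %in% c("A001", "B003")
  expect_gt(min(het[tet]), mean(het[!tet]))
})

test_that("phenotype heritability matches the generating decomposition", {
  ratios <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_pop_a = 100, n_pop_b = 100, n_snps = 500,
                      h2 = 0.8, n_qtl = 50, missing_rate = 0)
    sim <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(sim, cfg)
    # oracle: direct variance decomposition from known genetic values
    g <- ph$truth$genetic_values
    e <- ph$phenotypes$value - g
    var(g) / (var(g) + var(e))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.8), 0.05)
})

test_that("h2 = 0 phenotypes are independent of the genotypes", {
  cfg <- sim_config(seed = 19, n_pop_a = 50, n_pop_b = 50, n_snps = 500,
                    h2 = 0, missing_rate = 0)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  expect_identical(ph$truth$genetic_values, rep(0, 100))
  expect_error(sim_config(h2 = 1.5), "h2")
})

test_that("group shift moves only the domesticated group mean", {
  base <- sim_config(seed = 23, n_pop_a = 200, n_pop_b = 200, n_snps = 200,
                     h2 = 0, group_shift_sd = 0)
  sim <- simulate_genotypes(base)
  y0 <- simulate_phenotypes(sim, base)$phenotypes$value
  dom <- sim$groups$group == "domesticated"
  expect_lt(abs(mean(y0[dom]) - mean(y0[!dom])), 4 / sqrt(200))
  shifted <- sim_config(seed = 23, n_pop_a = 200, n_pop_b = 200,
                        n_snps = 200, h2 = 0, group_shift_sd = 2)
  y2 <- simulate_phenotypes(sim, shifted)$phenotypes$value
  expect_gt(mean(y2[dom]) - mean(y2[!dom]), 1.5 * sd(y0))
})

test_that("contaminant particles violate exactly their designated gate", {
  cfg <- sim_config(seed = 29, pollen_per_individual = 500,
                    contaminant_rates = c(aborted = 0.1, stacked = 0.1,
                                          debris = 0.1, blurred = 0.1))
  mp <- simulate_mifc_particles(c("i1", "i2"), cfg)
  p <- mp$particles
  cls <- mp$truth$labels$class
  gc <- gate_config()
  in_range <- function(v, r) v >= r[1] & v <= r[2]
  diam_ok <- in_range(p$diameter, gc$diameter_range)
  expect_identical(which(!diam_ok), which(cls == "debris"))
  mp_ok <- in_range(p$median_pixel, gc$median_pixel_range)
  expect_identical(which(!mp_ok), which(cls == "aborted"))
  sym_ok <- in_range(p$symmetry3, gc$symmetry3_range)
  expect_identical(which(!sym_ok), which(cls == "stacked"))
  grms_ok <- in_range(p$gradient_rms, gc$gradient_rms_range)
  expect_identical(which(!grms_ok), which(cls == "blurred"))
  expect_error(sim_config(contaminant_rates = c(aborted = 0.6, debris = 0.6)),
               "contaminant")
})

test_that("particle fluorescence channels are strongly correlated", {
  cfg <- sim_config(seed = 31, pollen_per_individual = 2000,
                    contaminant_rates = c(aborted = 0, stacked = 0,
                                          debris = 0, blurred = 0))
  p <- simulate_mifc_particles("i1", cfg)$particles
  r <- cor(log(p[, c("fluor_ch2", "fluor_ch3", "fluor_ch4", "fluor_ch5")]))
  expect_gt(min(r[upper.tri(r)]), 0.84)
})

test_that("VCF output round-trips through the reader", {
  cfg <- sim_config(seed = 37, n_snps = 100, n_pop_a = 8, n_pop_b = 8,
                    missing_rate = 0.1)
  sim <- simulate_genotypes(cfg)
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$geno, path)
  back <- read_vcf(path)
  expect_identical(unname(back$calls), unname(sim$geno$calls))
  expect_identical(unname(back$depths), unname(sim$geno$depths))
  expect_identical(back$pos, sim$geno$pos)
  expect_identical(back$individuals, sim$geno$individuals)
  # missing calls are serialized as ./.
  lines <- readLines(path)
  na_site <- which(is.na(sim$geno$calls[1, ]))[1]
  row <- grep(sprintf("\tsnp%d\t", na_site), lines, value = TRUE)
  expect_match(strsplit(row, "\t")[[1]][10 + 0], "^\\./\\.")
})

test_that("header-only VCF is written for zero variants", {
  g <- genotype_table(matrix(integer(0), nrow = 3, ncol = 0),
                      chrom = character(0), pos = integer(0),
                      individuals = c("a", "b", "c"))
  path <- tempfile(fileext = ".vcf")
  write_vcf(g, path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "##fileformat=VCFv4.2")))
  expect_true(any(startsWith(lines, "#CHROM")))
  expect_identical(sum(!startsWith(lines, "#")), 0L)
})
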