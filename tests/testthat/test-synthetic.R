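test_that("two-population simulation matches its configuration", {
  cfg <- sim_config(seed = 5, n_snps = 400, n_chromosomes = 4,
                    n_per_pop = 40, generations = 3)
  sim <- simulate_wright_fisher(cfg)
  expect_equal(n_snps(sim$selected), 400)
  expect_equal(n_snps(sim$reference), 400)
  expect_equal(n_samples(sim$selected), 40)
  expect_equal(dim(sim$haplotypes$selected), c(80, 400))
  expect_equal(length(unique(sim$map$chr)), 4)
  # phased haplotypes sum to the genotype calls
  H <- sim$haplotypes$selected
  g <- H[seq(1, 79, 2), ] + H[seq(2, 80, 2), ]
  expect_equal(unname(sim$selected$calls), unname(g))
  # determinism under a fixed seed
  sim2 <- simulate_wright_fisher(cfg)
  expect_identical(sim$selected$calls, sim2$selected$calls)
  expect_identical(sim$haplotypes$reference, sim2$haplotypes$reference)
})

test_that("drift-only simulation moves frequencies only modestly", {
  cfg <- sim_config(seed = 8, n_snps = 500, n_chromosomes = 5,
                    n_per_pop = 1000, generations = 5,
                    n_ancestral_haplotypes = 2000L)
  sim <- simulate_wright_fisher(cfg)
  p1 <- allele_frequencies(sim$selected)$p
  p2 <- allele_frequencies(sim$reference)$p
  # Var(dp) ~ p(1-p) t / (2N) per population: tiny at N = 1000, t = 5
  expect_lt(mean(abs(p1 - p2)), 0.05)
})

test_that("a selected locus rises above the reference across seeds", {
  up <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, n_snps = 300, n_chromosomes = 3,
                      n_per_pop = 60, generations = 40,
                      selected_loci = 150L, s = 0.1)
    sim <- simulate_wright_fisher(cfg)
    sim$truth$p_selected > sim$truth$p_reference
  }, logical(1))
  expect_gte(sum(up), 9)
})

test_that("generated datasets respect the MAF floor and round-trip", {
  cfg <- sim_config(seed = 13, n_snps = 300, n_chromosomes = 3,
                    n_per_pop = 50, generations = 2, maf_floor = 0.05)
  sim <- simulate_wright_fisher(cfg)
  p1 <- allele_frequencies(sim$selected)$p
  p2 <- allele_frequencies(sim$reference)$p
  pooled <- (p1 + p2) / 2
  expect_true(all(pmin(pooled, 1 - pooled) >= 0.05))
  td <- withr::local_tempdir()
  write_plink_text(sim$selected, file.path(td, "s.ped"),
                   file.path(td, "s.map"))
  back <- read_plink_text(file.path(td, "s.ped"), file.path(td, "s.map"))
  expect_identical(unname(back$calls), unname(sim$selected$calls))
})

test_that("half-sib offspring obey Mendelian constraints", {
  set.seed(17)
  m <- 300
  p <- runif(m, 0.1, 0.9)
  sire <- rbinom(m, 2, p)
  fam <- simulate_half_sib_family(sire, p, n_offspring = 15)
  g <- fam$offspring$calls
  expect_equal(dim(g), c(15, m))
  # error = 0: every offspring shares an allele with the sire everywhere
  for (j in seq_len(m)) {
    if (sire[j] == 0) expect_true(all(g[, j] <= 1))
    if (sire[j] == 2) expect_true(all(g[, j] >= 1))
  }
  # sire code 2 with p = 1 fixes all offspring at 2
  fam2 <- simulate_half_sib_family(rep(2L, 10), rep(1, 10), 5)
  expect_true(all(fam2$offspring$calls == 2))
  # missingness applied last at the requested rate
  fam3 <- simulate_half_sib_family(sire, p, 50, missing_rate = 0.2)
  expect_equal(mean(is.na(fam3$offspring$calls)), 0.2, tolerance = 0.02)
})

test_that("heterozygous sire at p = 0.5 yields the (1/4, 1/2, 1/4) mix", {
  set.seed(18)
  fam <- simulate_half_sib_family(1L, 0.5, n_offspring = 10000)
  counts <- tabulate(fam$offspring$calls + 1L, 3)
  gof <- chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.01)
})

test_that("temporal cohorts carry the configured years and pedigree", {
  cfg <- sim_config(seed = 23, n_snps = 400, n_chromosomes = 4,
                    years = 2000:2006, n_founders = 20, n_per_year = 24)
  coh <- simulate_temporal_cohorts(cfg)
  expect_equal(sort(unique(coh$dataset$meta$yob)), 2000:2006)
  expect_equal(n_samples(coh$dataset), 7 * 24)
  # every non-founder's sire is a male of the previous cohort
  ped <- coh$pedigree
  for (y in 2001:2006) {
    rows <- ped[ped$yob == y, ]
    prev <- ped[ped$yob == y - 1, ]
    expect_true(all(rows$sire %in% prev$id[prev$sex == 1]))
    expect_true(all(rows$dam %in% prev$id[prev$sex == 2]))
  }
})

test_that("implanted ROH are homozygous, detectable and monotone", {
  set.seed(29)
  m <- 400
  # one 20 Mb chromosome at 50 SNP/Mb
  map <- data.frame(snp = paste0("r", 1:m), chr = "1",
                    pos = sort(sample.int(2e7, m)))
  g <- matrix(rbinom(5 * m, 2, 0.5), 5, m)
  # heterozygous flanks give the detector sharp boundaries to recover
  g[2, ] <- 1L
  ds <- genotype_dataset(g, map)
  res <- implant_roh(ds, "S2", "1", start_kb = 5000, end_kb = 7000)
  inside <- res$dataset$map$pos >= 5e6 & res$dataset$map$pos <= 7e6
  expect_true(all(res$dataset$calls["S2", inside] != 1, na.rm = TRUE))
  expect_gt(res$interval$n_snps, 0)

  # round trip: detector recovers the implanted boundaries within one
  # inter-SNP spacing
  segs <- detect_roh(res$dataset, min_kb = 1000, min_snps = 30,
                     window_snps = 30)
  mine <- segs[segs$id == "S2", ]
  expect_equal(nrow(mine), 1)
  span <- range(res$dataset$map$pos[inside])
  spacing <- max(diff(res$dataset$map$pos))
  expect_lte(abs(mine$start - span[1]), spacing)
  expect_lte(abs(mine$end - span[2]), spacing)

  # F_ROH grows with implanted length
  res2 <- implant_roh(ds, "S2", "1", start_kb = 5000, end_kb = 12000)
  f1 <- f_roh(detect_roh(res$dataset, min_kb = 1000, min_snps = 30),
              samples = "S2")$f_roh
  f2 <- f_roh(detect_roh(res2$dataset, min_kb = 1000, min_snps = 30),
              samples = "S2")$f_roh
  expect_gt(f2, f1)
  expect_error(implant_roh(ds, "S1", "1", 30000, 31000), "no SNPs")
})

test_that("unlinked-loci simulator produces the expected panel shape", {
  set.seed(31)
  ds <- simulate_wf_unlinked(ne = 60, n_snps = 200, sample_size = 30,
                             generations = 4)
  expect_equal(dim(ds$calls), c(30, 200))
  expect_gt(length(unique(ds$map$chr)), 1)
  expect_error(simulate_wf_unlinked(10, 50, 20), "exceed")
})
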