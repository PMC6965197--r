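test_that("F_IS matches a hand-computed toy and its fixed points", {
  # 5 individuals x 3 SNPs, planted codes; oracle computed independently
  g <- rbind(c(0L, 1L, 2L),
             c(0L, 1L, 1L),
             c(1L, 0L, 2L),
             c(2L, 2L, 0L),
             c(1L, 1L, 2L))
  ds <- genotype_dataset(g, data.frame(snp = c("a", "b", "c"), chr = "1",
                                       pos = 1:3 * 1e5))
  rec <- f_is(ds)
  # independent step-literal computation
  p <- colSums(g) / 10
  ehom <- 1 - 2 * p * (1 - p) * 5 / 4
  for (i in 1:5) {
    O <- sum(g[i, ] != 1)
    E <- sum(ehom)
    expect_equal(rec$f_is[i], (O - E) / (3 - E), tolerance = 1e-12)
  }
  # fully homozygous individual with polymorphic frequencies -> F = 1
  expect_equal(rec$f_is[rec$id == "S4"], 1)
})

test_that("F_IS is zero when observed equals expected homozygosity", {
  # construct a dataset where one individual's O equals E exactly:
  # all p = 0.5, n = 4 -> per-SNP E_hom = 1 - 2*0.25*4/3 = 1/3;
  # an individual with 1 hom in 3 SNPs has O = 1 = E
  g <- rbind(c(0L, 1L, 1L),
             c(2L, 0L, 0L),
             c(0L, 2L, 2L),
             c(2L, 1L, 1L))
  ds <- genotype_dataset(g, data.frame(snp = c("a", "b", "c"), chr = "1",
                                       pos = 1:3 * 1e5))
  rec <- f_is(ds)
  expect_equal(allele_frequencies(ds)$p, rep(0.5, 3))
  expect_equal(rec$f_is[1], 0, tolerance = 1e-12)
})

test_that("ROH detection handles the trivial extremes", {
  m <- 120
  pos <- seq(25000, 3e6, length.out = m)
  map <- data.frame(snp = paste0("s", 1:m), chr = "1", pos = round(pos))
  het <- genotype_dataset(matrix(1L, 1, m), map)
  expect_equal(nrow(detect_roh(het)), 0)
  hom <- genotype_dataset(matrix(2L, 1, m), map)
  segs <- detect_roh(hom)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, map$pos[1])
  expect_equal(segs$end, map$pos[m])
  expect_equal(segs$n_snps, m)
})

test_that("ROH detection equals the exhaustive window/run oracle", {
  set.seed(37)
  for (k in 1:12) {
    n_ind <- sample(1:4, 1)
    m <- sample(80:350, 1)
    ds <- random_dataset(n_ind, m, n_chr = sample(1:2, 1),
                         missing_rate = runif(1, 0, 0.1),
                         pos_step_kb = sample(c(20, 60, 200, 1500), 1))
    # long homozygous stretches so segments actually occur
    for (i in seq_len(n_ind)) {
      a <- sample(m - 40, 1)
      ds$calls[i, a:(a + 39)] <- sample(c(0L, 2L), 40, replace = TRUE)
    }
    got <- detect_roh(ds, min_kb = 500, min_snps = 20, window_snps = 20)
    want <- oracle_roh(ds, min_kb = 500, min_snps = 20, window_snps = 20)
    ord <- function(x) x[order(x$id, x$chr, x$start), ]
    expect_equal(ord(got), ord(want), ignore_attr = TRUE)
  }
})

test_that("F_ROH is total ROH length over the autosomal genome", {
  segs <- data.frame(id = c("A", "A", "B"), chr = c("1", "2", "1"),
                     start = c(1, 1, 1), end = c(2, 2, 2),
                     n_snps = c(40, 40, 40),
                     length_kb = c(30000.2, 14859, 44859.2))
  out <- f_roh(segs, samples = c("A", "B", "C"))
  expect_equal(out$f_roh[out$id == "A"], 44859.2 / 2242960)
  expect_equal(out$f_roh[out$id == "B"], 0.02)
  expect_equal(out$f_roh[out$id == "C"], 0)
  full <- data.frame(id = "X", chr = "1", start = 1, end = 2, n_snps = 1,
                     length_kb = 2242960)
  expect_equal(f_roh(full)$f_roh, 1)
  over <- data.frame(id = "X", chr = "1", start = 1, end = 2, n_snps = 1,
                     length_kb = 3e6)
  expect_error(f_roh(over), "exceeds")
})

test_that("long-ROH F_ROH never exceeds the 1 Mb F_ROH", {
  cfg <- sim_config(seed = 41, n_snps = 2000, n_chromosomes = 4,
                    genome_kb = 200000, years = 2000:2007,
                    n_founders = 16, n_per_year = 20, skew_end = 0.8)
  coh <- simulate_temporal_cohorts(cfg)
  ids <- rownames(coh$dataset$calls)
  s1 <- detect_roh(coh$dataset, min_kb = 1000)
  s5 <- detect_roh(coh$dataset, min_kb = 5000)
  f1 <- f_roh(s1, samples = ids)
  f5 <- f_roh(s5, samples = ids)
  expect_true(all(f5$f_roh <= f1$f_roh + 1e-12))
  expect_true(all(f1$f_roh >= 0 & f1$f_roh <= 1))
})

test_that("ROH prevalence counts covering individuals per SNP", {
  m <- 10
  map <- data.frame(snp = paste0("s", 1:m), chr = "1", pos = 1:m * 1e6)
  ds <- genotype_dataset(matrix(0L, 10, m), map)
  expect_true(all(roh_prevalence(data.frame(id = character(),
                                            chr = character(),
                                            start = numeric(),
                                            end = numeric(),
                                            n_snps = integer(),
                                            length_kb = numeric()),
                                 ds)$per_snp$pct == 0))
  segs <- data.frame(id = paste0("S", 1:3), chr = "1",
                     start = c(2e6, 2e6, 2e6), end = c(4e6, 4e6, 5e6),
                     n_snps = 3, length_kb = 2000)
  prev <- roh_prevalence(segs, ds, top_n = 4)
  expect_equal(prev$per_snp$pct[2:4], c(30, 30, 30))
  expect_equal(prev$per_snp$pct[5], 10)
  expect_equal(prev$per_snp$pct[6], 0)
  expect_equal(prev$top$snp[1:3], c("s2", "s3", "s4"))  # ties by map order
  expect_equal(prev$top$rank, 1:4)
})

test_that("annual trend reproduces exact lines and guards degenerate input", {
  meta <- data.frame(id = paste0("I", 1:60),
                     yob = rep(2000:2009, each = 6))
  # exactly linear annual means
  rec <- data.frame(id = meta$id, f = 0.01 * (meta$yob - 2000) + 0.1)
  tr <- annual_trend(rec, meta, "f")
  expect_equal(tr$slope, 0.01, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1, tolerance = 1e-12)
  expect_lt(tr$p_value, 1e-10)
  expect_true(all(tr$annual$ci_lo <= tr$annual$mean + 1e-12 &
                    tr$annual$mean <= tr$annual$ci_hi + 1e-12))
  # constant measure: zero-variance guard
  rec2 <- data.frame(id = meta$id, f = 0.3)
  tr2 <- annual_trend(rec2, meta, "f")
  expect_equal(tr2$slope, 0)
  expect_equal(tr2$r_squared, 0)
  expect_equal(tr2$p_value, 1)
  expect_error(annual_trend(rec[1:6, ], meta[1:6, ], "f"), "3 distinct")
})

test_that("regional t-tests match textbook pooled arithmetic", {
  meta <- data.frame(id = paste0("I", 1:6),
                     region = rep(c("EUR", "ANZ"), each = 3))
  rec <- data.frame(id = meta$id, f = c(0.10, 0.12, 0.14, 0.09, 0.10, 0.11))
  out <- region_ttest(rec, meta, "f")
  # hand-computed pooled t for (0.10,0.12,0.14) vs (0.09,0.10,0.11)
  m1 <- 0.12; m2 <- 0.10
  sp2 <- (2 * var(c(0.10, 0.12, 0.14)) + 2 * var(c(0.09, 0.10, 0.11))) / 4
  t_hand <- (m2 - m1) / sqrt(sp2 * (1 / 3 + 1 / 3))
  row <- out[out$region1 == "ANZ" & out$region2 == "EUR", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$df, 4)
  # identical samples give t = 0, P = 1
  rec3 <- data.frame(id = meta$id, f = rep(c(1, 2, 3), 2))
  out3 <- region_ttest(rec3, meta, "f")
  expect_equal(out3$t, 0)
  expect_equal(out3$p, 1)
  # swapping groups flips t, keeps P
  meta_sw <- meta
  meta_sw$region <- rev(meta$region)
  out_sw <- region_ttest(rec, meta_sw, "f")
  expect_equal(out_sw$t, -row$t, tolerance = 1e-12)
  expect_equal(out_sw$p, row$p, tolerance = 1e-12)
})

test_that("performance correlation behaves at its fixed points", {
  f <- c(0.1, 0.2, 0.3, 0.4, 0.25)
  expect_equal(performance_correlation(f, 10 + 3 * f)$r, 1,
               tolerance = 1e-12)
  out <- performance_correlation(f, -2 * f + 1)
  expect_equal(out$r, -1, tolerance = 1e-12)
  r1 <- performance_correlation(f, c(5, 3, 8, 1, 9))
  r2 <- performance_correlation(f, -c(5, 3, 8, 1, 9))
  expect_equal(r1$r, -r2$r, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  # missing ratings dropped and counted
  out2 <- performance_correlation(c(f, 0.5), c(5, 3, 8, 1, 9, NA))
  expect_equal(out2$n_used, 5)
  expect_equal(out2$n_dropped, 1)
  expect_error(performance_correlation(f, rep(1, 5)), "zero variance")
})

test_that("the null correlation is small at n = 1000", {
  set.seed(43)
  f <- runif(1000)
  r <- performance_correlation(f, runif(1000))
  expect_lt(abs(r$r), 0.1)
})
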