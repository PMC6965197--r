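make_pair <- function(g1, g2, map = NULL) {
  m <- ncol(g1)
  if (is.null(map)) {
    map <- data.frame(snp = paste0("s", seq_len(m)), chr = "1",
                      pos = seq_len(m) * 1e5)
  }
  list(sel = genotype_dataset(g1, map), ref = genotype_dataset(g2, map))
}

test_that("FST matches its limiting cases and hand arithmetic", {
  # p1 = p2 -> 0; fixed difference -> 1; p1 = 0.8 vs 0.4 -> 1/6
  g1 <- cbind(rep(1L, 5), rep(2L, 5), c(2L, 2L, 2L, 1L, 1L))
  g2 <- cbind(rep(1L, 5), rep(0L, 5), c(1L, 1L, 1L, 1L, 0L))
  pr <- make_pair(g1, g2)
  fst <- fst_per_snp(pr$sel, pr$ref)
  expect_equal(unname(fst), c(0, 1, 1 / 6), tolerance = 1e-12)
  # monomorphic overall -> 0, not NaN
  g3 <- cbind(rep(0L, 5))
  g4 <- cbind(rep(0L, 5))
  pr2 <- make_pair(g3, g4, data.frame(snp = "m", chr = "1", pos = 1e5))
  expect_equal(unname(fst_per_snp(pr2$sel, pr2$ref)), 0)
  expect_error(fst_per_snp(pr$sel, pr2$ref), "identical SNP panel")
})

test_that("delta-SAF tracks the allele favoured in the selected group", {
  # equal -> 0; fixed/absent -> 1; A at 0.3 sel vs 0.6 ref -> track B: 0.3
  g1 <- cbind(rep(1L, 10), rep(2L, 10), rbinom(10, 2, 0))
  g1[, 3] <- c(rep(2L, 7), rep(1L, 0), rep(1L, 3))     # p_B(sel) = 0.85
  g1 <- cbind(rep(1L, 10), rep(2L, 10),
              c(rep(2L, 4), rep(1L, 6)))               # p_B = 0.7
  g2 <- cbind(rep(1L, 10), rep(0L, 10),
              c(rep(1L, 8), rep(0L, 2)))               # p_B = 0.4
  pr <- make_pair(g1, g2)
  d <- delta_saf(pr$sel, pr$ref)
  expect_equal(unname(d), c(0, 1, 0.3), tolerance = 1e-12)
})

test_that("XP-EHH is zero for identical panels and matches the oracle", {
  H <- rbind(c(0L, 1L, 0L, 1L, 0L),
             c(0L, 1L, 0L, 0L, 1L),
             c(1L, 0L, 1L, 0L, 1L),
             c(1L, 1L, 0L, 1L, 0L))
  map <- data.frame(snp = paste0("s", 1:5), chr = "1",
                    pos = c(100, 250, 400, 700, 900) * 1000)
  same <- xp_ehh(H, H, map, ehh_floor = 0.01)
  expect_true(all(abs(same$raw[!is.na(same$raw)]) < 1e-12))

  # integrals equal brute-force pair enumeration of shared prefixes
  H2 <- rbind(c(0L, 0L, 0L, 1L, 1L),
              c(0L, 0L, 0L, 1L, 0L),
              c(0L, 1L, 1L, 0L, 1L),
              c(1L, 1L, 1L, 0L, 0L))
  out <- xp_ehh(H, H2, map, ehh_floor = 0.05)
  for (core in 1:5) {
    expect_equal(out$i_selected[core],
                 oracle_ehh_integral(H, map$pos / 1000, core),
                 tolerance = 1e-12)
    expect_equal(out$i_reference[core],
                 oracle_ehh_integral(H2, map$pos / 1000, core),
                 tolerance = 1e-12)
  }
  # standardized vector has mean 0 and SD 1
  set.seed(61)
  Hs <- matrix(rbinom(20 * 60, 1, 0.5), 20, 60)
  Hr <- matrix(rbinom(20 * 60, 1, 0.5), 20, 60)
  mp <- data.frame(snp = paste0("x", 1:60), chr = "1",
                   pos = sort(sample.int(6e6, 60)))
  st <- xp_ehh(Hs, Hr, mp)
  expect_equal(mean(st$std, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(st$std, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_error(xp_ehh(Hs[1, , drop = FALSE], Hr, mp), "2 haplotypes")
})

test_that("composite score reproduces its closed-form examples", {
  # n = 9, one SNP top-ranked in all m = 3 tests
  set.seed(62)
  base <- replicate(3, runif(9))
  base[9, ] <- 2                      # top in every test
  st <- composite_score(list(a = base[, 1], b = base[, 2], c = base[, 3]))
  r <- 9 / 10
  z <- qnorm(r)
  p <- 1 - pnorm(z * sqrt(3))
  expect_equal(st$css[9], -log10(p), tolerance = 1e-12)
  expect_equal(st$css[9], 1.88, tolerance = 0.005)

  # a SNP at the median rank of every test: P = 0.5, CSS = -log10(0.5)
  x <- c(1, 2, 3, 4, 5)
  st2 <- composite_score(list(a = x, b = x, c = x))
  expect_equal(st2$p[3], 0.5, tolerance = 1e-12)
  expect_equal(st2$css[3], -log10(0.5), tolerance = 1e-12)
})

test_that("composite score equals the step-literal reference to 1e-12", {
  set.seed(63)
  for (k in 1:5) {
    n <- sample(50:500, 1)
    stats_in <- list(fst = rexp(n), dsaf = runif(n), xpehh = rnorm(n))
    got <- composite_score(stats_in)
    want <- oracle_css(stats_in)
    expect_equal(got$css, want, tolerance = 1e-12)
  }
})

test_that("composite score survives permutation and degenerate inputs", {
  set.seed(64)
  n <- 100
  a <- rexp(n)
  b <- runif(n)
  st <- composite_score(list(a = a, b = b))
  perm <- sample(n)
  st_p <- composite_score(list(a = a[perm], b = b[perm]))
  expect_equal(st_p$css, st$css[perm], tolerance = 1e-12)
  # all-identical constituent contributes z = 0 with a warning
  expect_warning(st0 <- composite_score(list(a = a, b = rep(1, n))),
                 "no variance")
  expect_equal(st0$b_z, rep(0, n))
  # NA in one constituent excludes the SNP throughout
  a2 <- a
  a2[5] <- NA
  st_na <- composite_score(list(a = a2, b = b))
  expect_true(is.na(st_na$css[5]))
  expect_equal(sum(!is.na(st_na$css)), n - 1)
})

test_that("smoothing averages within centred 1 Mb windows", {
  map <- data.frame(snp = c("a", "b", "c"), chr = "1",
                    pos = c(0, 400, 2000) * 1000)
  st <- data.frame(chr = map$chr, pos = map$pos, css = c(3, 1, 5))
  sm <- smooth_css(st, window_kb = 1000)
  expect_equal(sm$css_smooth, c(2, 2, 5))
  # constant css stays constant; single-SNP chromosome keeps its value
  st2 <- data.frame(chr = c("1", "1", "2"), pos = c(1e5, 2e5, 1e5),
                    css = c(4, 4, 7))
  expect_equal(smooth_css(st2)$css_smooth, c(4, 4, 7))
  # smoothing never raises the genome-wide maximum
  set.seed(65)
  st3 <- data.frame(chr = "1", pos = sort(sample.int(1e7, 200)),
                    css = rexp(200))
  expect_lte(max(smooth_css(st3)$css_smooth), max(st3$css))
})

test_that("region calling honours tier size, gaps and the 5-SNP rule", {
  n <- 600
  pos <- seq_len(n) * 2e5                   # 200 kb spacing
  st <- data.frame(chr = "1", pos = pos, css = rep(0.1, n),
                   css_smooth = rep(0.1, n))
  # 6 adjacent top SNPs, then one 2 Mb away (still top): one region of 6
  top_idx <- c(100:105, 116)
  st$css_smooth[top_idx] <- 5
  st$css[top_idx] <- 6
  regions <- call_regions(st, top_fraction = 0.01, min_snps = 5,
                          max_gap_kb = 1000)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$n_top_snps, 6)
  expect_equal(regions$start, pos[100])
  expect_equal(regions$end, pos[105])
  expect_equal(regions$top_css, 6)
  # 4 contiguous top SNPs -> nothing (distinct background values so the
  # tie-inclusive cutoff stays sharp)
  st2 <- st
  st2$css_smooth <- seq_len(n) / 1e4
  st2$css_smooth[300:303] <- 5
  expect_equal(nrow(call_regions(st2, 0.01, 5, 1000)), 0)
  # no top-tier clustering at all -> empty frame with the right columns
  st3 <- st
  st3$css_smooth <- runif(n)
  out3 <- call_regions(st3, 0.001, 5, 200)
  expect_s3_class(out3, "data.frame")
})

test_that("the top tier holds floor(f n) SNPs with cutoff ties included", {
  st <- data.frame(css_smooth = c(rep(1, 3), rep(5, 2), 7))
  tier <- css_top_tier(st, 0.5)             # floor(0.5 * 6) = 3, tie at 5
  expect_equal(sum(tier), 3)
  st2 <- data.frame(css_smooth = c(1, 2, 5, 5, 5, 7))
  tier2 <- css_top_tier(st2, 0.5)           # cutoff value 5 is tied
  expect_equal(sum(tier2), 4)
  # a 48,896-SNP panel: the top 0.1% tier holds 48 SNPs
  set.seed(66)
  st3 <- data.frame(css_smooth = rnorm(48896))
  expect_equal(sum(css_top_tier(st3, 0.001)), 48)
})

test_that("gene mapping uses closed intervals with 0.5 Mb flanks", {
  regions <- data.frame(region = 1L, chr = "7", start = 2e6, end = 3e6)
  genes <- data.frame(gene = c("IN", "NEAR", "FAR", "TOUCH", "OTHERCHR"),
                      chr = c("7", "7", "7", "7", "8"),
                      start = c(2.4e6, 3.3e6, 3.61e6, 1.2e6, 2.4e6),
                      end = c(2.6e6, 3.4e6, 3.8e6, 1.5e6, 2.6e6))
  out <- map_genes(regions, genes, flank_kb = 500)
  # TOUCH ends exactly at start - flank: closed-interval touch counts
  expect_setequal(out$gene, c("IN", "NEAR", "TOUCH"))
})

test_that("css_scan wires the full pipeline together", {
  set.seed(67)
  cfg <- sim_config(seed = 71, n_snps = 400, n_chromosomes = 2,
                    genome_kb = 40000, n_per_pop = 40, generations = 8)
  sim <- simulate_wright_fisher(cfg)
  genes <- data.frame(gene = "G1", chr = "1", start = 1, end = 2e7)
  res <- css_scan(sim$selected, sim$reference, sim$haplotypes,
                  gene_table = genes)
  expect_true(all(c("fst", "dsaf", "xpehh", "css", "css_smooth") %in%
                    names(res$stats)))
  expect_equal(nrow(res$stats), 400)
  expect_true(all(res$stats$css >= 0, na.rm = TRUE))
  expect_equal(attr(res$stats, "m"), 3)
})
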