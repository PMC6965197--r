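#' Individual inbreeding coefficients (F_IS)
#'
#' Measures the deficit of observed heterozygosity relative to the
#' Hardy-Weinberg expectation in the sampled population, the classic
#' moment estimator behind PLINK's `--het`. For SNP j with sample B-allele
#' frequency `p_j` over `n_j` non-missing samples, the per-individual
#' expected-homozygosity contribution is
#' `1 - 2 p_j (1 - p_j) n_j / (n_j - 1)`; summing over the individual's
#' non-missing SNPs gives `E_hom`, and
#' `F_IS = (O_hom - E_hom) / (L - E_hom)` with `O_hom` the observed
#' homozygote count and `L` the SNPs used. SNPs with fewer than two calls
#' are skipped (counted in a warning).
#'
#' @param dataset A `GenotypeDataset`, normally LD-pruned.
#' @return Data frame with one row per sample: `id`, `n_used`, `o_hom`,
#'   `e_hom`, `f_is` (clamped to \[-1, 1\]; `NA` with a warning when
#'   `L = E_hom` leaves the ratio undefined).
#' @export
f_is <- function(dataset) {
  calls <- dataset$calls
  fr <- allele_frequencies(dataset)
  usable <- fr$n >= 2
  if (any(!usable)) {
    warning(sum(!usable), " SNP(s) with fewer than 2 calls skipped")
  }
  p <- fr$p
  ehom_snp <- 1 - 2 * p * (1 - p) * fr$n / (fr$n - 1)
  ehom_snp[!usable] <- 0
  M <- (!is.na(calls)) & rep(usable, each = nrow(calls))
  hom <- !is.na(calls) & calls != 1L
  O <- rowSums(hom & M)
  L <- rowSums(M)
  E <- as.vector((M * 1) %*% ehom_snp)
  denom <- L - E
  f <- ifelse(abs(denom) < 1e-12, NA_real_, (O - E) / denom)
  if (anyNA(f)) {
    warning(sum(is.na(f)), " individual(s) with L = E_hom: F_IS undefined")
  }
  data.frame(id = rownames(calls), n_used = L, o_hom = O, e_hom = E,
             f_is = pmin(pmax(f, -1), 1), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Detect runs of homozygosity (PLINK-style sliding window scan)
#'
#' For every individual and chromosome a window of `window_snps` SNPs
#' slides one SNP at a time; a window is called homozygous when it contains
#' at most `window_het` heterozygous and at most `window_missing` missing
#' calls. A SNP is a hit when the fraction of windows containing it that
#' are homozygous is at least `hit_fraction`. Maximal runs of hit SNPs are
#' split wherever two consecutive SNPs are more than `max_gap_kb` apart,
#' and surviving runs are reported when their length exceeds `min_kb`, they
#' contain at least `min_snps` SNPs and their kb-per-SNP density is at most
#' `max_density_kb_per_snp`. Run coordinates are the positions of the first
#' and last SNP in the run. Rerunning with `min_kb = 5000` gives the
#' long-ROH (> 5 Mb) call reflecting recent inbreeding.
#'
#' A chromosome carrying fewer SNPs than `window_snps` is scanned with a
#' single truncated window covering the whole chromosome.
#'
#' @param dataset A `GenotypeDataset` (unpruned, map sorted).
#' @param min_kb Minimum run length in kb, strict (default 1000).
#' @param min_snps Minimum SNPs per run (default 30).
#' @param max_gap_kb Maximum gap between consecutive run SNPs (default
#'   1000).
#' @param max_density_kb_per_snp Maximum kb per SNP in a run (default
#'   1000).
#' @param window_snps,window_het,window_missing Scanning-window size and
#'   tolerance (defaults 30, 1, 2).
#' @param hit_fraction Minimum homozygous-window fraction for a SNP to be
#'   a hit (default 0.05).
#' @return Data frame of segments: `id`, `chr`, `start`, `end` (bp,
#'   inclusive), `n_snps`, `length_kb`.
#' @export
detect_roh <- function(dataset, min_kb = 1000, min_snps = 30,
                       max_gap_kb = 1000, max_density_kb_per_snp = 1000,
                       window_snps = 30, window_het = 1,
                       window_missing = 2, hit_fraction = 0.05) {
  calls <- dataset$calls
  map <- dataset$map
  ids <- rownames(calls)
  res <- vector("list", 64)
  nres <- 0L
  for (ch in unique(map$chr)) {
    jdx <- which(map$chr == ch)
    pos <- map$pos[jdx]
    S <- length(jdx)
    W <- min(window_snps, S)
    nwin <- S - W + 1L
    gap_split <- which(diff(pos) / 1000 > max_gap_kb)
    sub <- calls[, jdx, drop = FALSE]
    for (i in seq_along(ids)) {
      g <- sub[i, ]
      het <- !is.na(g) & g == 1L
      mis <- is.na(g)
      ch_c <- cumsum(het)
      cm_c <- cumsum(mis)
      wh <- ch_c[seq_len(nwin) + W - 1L] -
        c(0, ch_c)[seq_len(nwin)]
      wm <- cm_c[seq_len(nwin) + W - 1L] -
        c(0, cm_c)[seq_len(nwin)]
      win_ok <- wh <= window_het & wm <= window_missing
      cok <- c(0, cumsum(win_ok))
      j <- seq_len(S)
      lo <- pmax(1L, j - W + 1L)
      hi <- pmin(j, nwin)
      frac <- (cok[hi + 1L] - cok[lo]) / (hi - lo + 1L)
      hit <- frac >= hit_fraction
      if (!any(hit)) next
      segs <- hit_runs(hit, gap_split)
      if (!nrow(segs)) next
      len_kb <- (pos[segs$b] - pos[segs$a]) / 1000
      nsnp <- segs$b - segs$a + 1L
      keep <- len_kb > min_kb & nsnp >= min_snps &
        len_kb / nsnp <= max_density_kb_per_snp
      if (!any(keep)) next
      nres <- nres + 1L
      if (nres > length(res)) res <- c(res, vector("list", length(res)))
      res[[nres]] <- data.frame(id = ids[i], chr = ch,
                                start = pos[segs$a[keep]],
                                end = pos[segs$b[keep]],
                                n_snps = nsnp[keep],
                                length_kb = len_kb[keep],
                                stringsAsFactors = FALSE)
    }
  }
  if (nres == 0L) {
    return(data.frame(id = character(), chr = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res[seq_len(nres)])
  rownames(out) <- NULL
  out
}

# maximal runs of TRUE in `hit`, additionally split after any index listed
# in `gap_after` (gap between SNP k and k+1)
hit_runs <- function(hit, gap_after) {
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  a_out <- integer(0)
  b_out <- integer(0)
  for (k in which(r$values)) {
    a <- starts[k]
    b <- ends[k]
    cuts <- gap_after[gap_after >= a & gap_after < b]
    bounds_a <- c(a, cuts + 1L)
    bounds_b <- c(cuts, b)
    a_out <- c(a_out, bounds_a)
    b_out <- c(b_out, bounds_b)
  }
  data.frame(a = a_out, b = b_out)
}

#' Genomic inbreeding from runs of homozygosity (F_ROH)
#'
#' `F_ROH = L_ROH / L_AUTO`: the summed ROH length of an individual divided
#' by the autosomal genome length, by default 2,242,960 kb (the horse
#' autosomes, assembly EquCab2).
#'
#' @param segments Segment table from [detect_roh()].
#' @param l_auto_kb Autosomal genome length in kb.
#' @param samples Optional character vector of sample ids that defines the
#'   output universe; individuals without segments get `F_ROH = 0`.
#'   Defaults to the ids present in `segments`.
#' @return Data frame: `id`, `l_roh_kb`, `f_roh`.
#' @export
f_roh <- function(segments, l_auto_kb = 2242960, samples = NULL) {
  if (is.null(samples)) samples <- unique(segments$id)
  tot <- tapply(segments$length_kb, factor(segments$id, levels = samples),
                sum)
  tot[is.na(tot)] <- 0
  if (any(tot > l_auto_kb)) {
    stop("total ROH length exceeds the autosomal genome for ",
         names(tot)[which(tot > l_auto_kb)[1]],
         "; upstream segments overlap")
  }
  data.frame(id = samples, l_roh_kb = as.numeric(tot),
             f_roh = as.numeric(tot) / l_auto_kb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROH prevalence per SNP
#'
#' For every SNP, the percentage of individuals that have at least one ROH
#' segment covering the SNP's position, plus the table of the `top_n`
#' SNPs ranked by that percentage (descending, ties broken by map order) --
#' a high prevalence flags loci where homozygous haplotypes have risen to
#' high frequency, which can inform on selection.
#'
#' @param segments Segment table from [detect_roh()] (at a stated minimum
#'   length, e.g. > 1 Mb or > 5 Mb).
#' @param dataset The `GenotypeDataset` the segments were called on; its
#'   sample count is the denominator.
#' @param top_n Number of top SNPs to extract (default 1000).
#' @return A list: `per_snp` (data frame `snp`, `chr`, `pos`, `n_covered`,
#'   `pct`) and `top` (the ranked top table with a `rank` column).
#' @export
roh_prevalence <- function(segments, dataset, top_n = 1000) {
  map <- dataset$map
  n_ind <- n_samples(dataset)
  counts <- integer(nrow(map))
  if (nrow(segments)) {
    for (ch in unique(segments$chr)) {
      jdx <- which(map$chr == ch)
      if (!length(jdx)) next
      pos <- map$pos[jdx]
      seg <- segments[segments$chr == ch, , drop = FALSE]
      for (k in seq_len(nrow(seg))) {
        within <- pos >= seg$start[k] & pos <= seg$end[k]
        counts[jdx[within]] <- counts[jdx[within]] + 1L
      }
    }
  }
  per_snp <- data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                        n_covered = counts, pct = 100 * counts / n_ind,
                        stringsAsFactors = FALSE)
  ord <- order(-per_snp$pct, seq_len(nrow(per_snp)))
  top <- per_snp[ord[seq_len(min(top_n, nrow(per_snp)))], , drop = FALSE]
  top$rank <- seq_len(nrow(top))
  rownames(top) <- NULL
  list(per_snp = per_snp, top = top)
}

#' Annual trend of an inbreeding measure
#'
#' Computes the annual mean, SD, SE and normal 95% CI (mean +/- 1.96 SE) of
#' an inbreeding measure by year of birth, then regresses the annual means
#' on year by unweighted ordinary least squares. The slope's two-sided P
#' comes from the t distribution with `n_years - 2` degrees of freedom.
#' A measure with zero variance across years returns slope 0, `R^2 = 0`
#' and `P = 1`.
#'
#' @param records Data frame with an `id` column and the measure column.
#' @param meta Per-sample metadata with `id` and `yob`.
#' @param measure Name of the measure column in `records` (e.g. `"f_is"`,
#'   `"f_roh"`).
#' @param min_year,max_year Year-of-birth window (inclusive); records
#'   outside it, or without a year, are dropped.
#' @return A list of class `TrendResult`: `annual` (data frame `year`, `n`,
#'   `mean`, `sd`, `se`, `ci_lo`, `ci_hi`), `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n_years`.
#' @export
annual_trend <- function(records, meta, measure, min_year = -Inf,
                         max_year = Inf) {
  if (!measure %in% names(records)) {
    stop("records has no column '", measure, "'")
  }
  yob <- meta$yob[match(records$id, meta$id)]
  val <- records[[measure]]
  keep <- !is.na(yob) & !is.na(val) & yob >= min_year & yob <= max_year
  yob <- yob[keep]
  val <- val[keep]
  years <- sort(unique(yob))
  if (length(years) < 3) stop("need at least 3 distinct years with data")
  agg <- lapply(years, function(y) {
    v <- val[yob == y]
    n <- length(v)
    se <- if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(year = y, n = n, mean = mean(v),
               sd = if (n > 1) stats::sd(v) else NA_real_, se = se,
               ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se)
  })
  annual <- do.call(rbind, agg)
  if (stats::sd(annual$mean) < 1e-15) {
    fitres <- list(slope = 0, intercept = annual$mean[1], r_squared = 0,
                   p_value = 1)
  } else {
    fit <- stats::lm(mean ~ year, data = annual)
    sm <- summary(fit)
    fitres <- list(slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r_squared = sm$r.squared,
                   p_value = unname(sm$coefficients[2, 4]))
  }
  structure(c(list(annual = annual), fitres,
              list(n_years = length(years), measure = measure)),
            class = "TrendResult")
}

#' @export
print.TrendResult <- function(x, ...) {
  cat(sprintf(
    "TrendResult (%s): %d years, slope %.3g per year, R^2 = %.3f, P = %.3g\n",
    x$measure, x$n_years, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Pairwise Student's t-tests of an inbreeding measure across regions
#'
#' Two-sided pooled-variance Student's t-test on individual-level values
#' for every pair of regions (Welch's unequal-variance variant behind a
#' flag). Regions with fewer than two records are skipped with a warning.
#'
#' @param records Data frame with `id` and the measure column.
#' @param meta Per-sample metadata with `id` and `region`.
#' @param measure Name of the measure column.
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @return Data frame: `region1`, `region2`, `n1`, `n2`, `t`, `df`, `p`.
#' @export
region_ttest <- function(records, meta, measure, welch = FALSE) {
  region <- meta$region[match(records$id, meta$id)]
  val <- records[[measure]]
  keep <- !is.na(region) & !is.na(val)
  region <- region[keep]
  val <- val[keep]
  tab <- table(region)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("region(s) with < 2 records skipped: ",
            paste(small, collapse = ", "))
  }
  regions <- names(tab)[tab >= 2]
  if (length(regions) < 2) stop("need at least 2 regions with >= 2 records")
  combs <- utils::combn(regions, 2)
  out <- lapply(seq_len(ncol(combs)), function(k) {
    r1 <- combs[1, k]
    r2 <- combs[2, k]
    v1 <- val[region == r1]
    v2 <- val[region == r2]
    tt <- stats::t.test(v1, v2, var.equal = !welch)
    data.frame(region1 = r1, region2 = r2, n1 = length(v1),
               n2 = length(v2), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation between inbreeding and a performance rating
#'
#' Pearson's r with a two-sided P-value from the t transform with `n - 2`
#' degrees of freedom, testing the null hypothesis of no linear
#' correlation. Pairs with a missing value on either side are dropped and
#' counted.
#'
#' @param f_values Numeric vector of inbreeding values.
#' @param ratings Numeric vector of ratings, same length and order.
#' @return A list: `r`, `p_value`, `n_used`, `n_dropped`.
#' @export
performance_correlation <- function(f_values, ratings) {
  if (length(f_values) != length(ratings)) {
    stop("f_values and ratings must be paired")
  }
  keep <- !is.na(f_values) & !is.na(ratings)
  x <- f_values[keep]
  y <- ratings[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_used = length(x),
       n_dropped = sum(!keep))
}
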