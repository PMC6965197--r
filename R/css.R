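#' Per-SNP FST between a selected and a reference population
#'
#' Wright's two-group variance ratio: with sample B-allele frequencies
#' `p1`, `p2` and unweighted mean `pbar`,
#' `FST = Var(p1, p2) / (pbar (1 - pbar))` where the variance uses
#' divisor 2, i.e. `(p1 - p2)^2 / 4` over `pbar qbar`. SNPs monomorphic in
#' the pooled sample get 0; SNPs with no calls in one group get `NA` and
#' are excluded from downstream ranking.
#'
#' @param selected,reference `GenotypeDataset`s on a shared SNP panel.
#' @return Numeric vector of per-SNP FST, named by SNP id.
#' @export
fst_per_snp <- function(selected, reference) {
  check_shared_panel(selected, reference)
  p1 <- allele_frequencies(selected)$p
  p2 <- allele_frequencies(reference)$p
  pbar <- (p1 + p2) / 2
  v <- (p1 - p2)^2 / 4
  fst <- ifelse(pbar <= 0 | pbar >= 1, 0, v / (pbar * (1 - pbar)))
  fst[is.na(p1) | is.na(p2)] <- NA_real_
  names(fst) <- selected$map$snp
  fst
}

check_shared_panel <- function(a, b) {
  if (!identical(a$map$snp, b$map$snp) ||
      !identical(a$map$pos, b$map$pos)) {
    stop("the two datasets must share an identical SNP panel")
  }
}

#' Per-SNP change in selected allele frequency (delta-SAF)
#'
#' The tracked allele at each SNP is the allele with the higher frequency
#' in the selected than in the reference population; delta-SAF is that
#' allele's frequency difference (selected minus reference), which is
#' non-negative by construction and 0 at equal frequencies.
#'
#' @inheritParams fst_per_snp
#' @return Numeric vector of per-SNP delta-SAF, named by SNP id.
#' @export
delta_saf <- function(selected, reference) {
  check_shared_panel(selected, reference)
  p1 <- allele_frequencies(selected)$p
  p2 <- allele_frequencies(reference)$p
  d <- abs(p1 - p2)
  names(d) <- selected$map$snp
  d
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' For each core SNP, `EHH(x)` is the probability that two haplotypes
#' drawn without replacement are identical over the interval from the core
#' to `x`. EHH is extended in both directions from the core until it falls
#' below `ehh_floor` or the chromosome ends; `I` is the trapezoidal
#' integral of EHH over physical distance (kb), summed over the two
#' directions. The raw statistic is `ln(I_selected / I_reference)` and the
#' standardized statistic rescales the raw values genome-wide to mean 0,
#' SD 1. Long haplotype homozygosity in the selected population relative
#' to the reference (a positive score) marks a sweep approaching fixation.
#'
#' Cores where either integral is 0 are flagged `NA` and excluded from
#' ranking.
#'
#' @param hap_selected,hap_reference Phased 0/1 haplotype matrices
#'   (haplotypes in rows, SNPs in columns) on the shared map.
#' @param map SNP map data frame with `chr` and `pos` (bp), one row per
#'   column of the haplotype matrices.
#' @param ehh_floor EHH truncation threshold (default 0.05).
#' @return Data frame: `snp` (when the map carries ids), `i_selected`,
#'   `i_reference`, `raw`, `std`.
#' @export
xp_ehh <- function(hap_selected, hap_reference, map, ehh_floor = 0.05) {
  if (nrow(hap_selected) < 2 || nrow(hap_reference) < 2) {
    stop("each population needs at least 2 haplotypes")
  }
  m <- nrow(map)
  if (ncol(hap_selected) != m || ncol(hap_reference) != m) {
    stop("haplotype matrices and map disagree on SNP count")
  }
  i_sel <- numeric(m)
  i_ref <- numeric(m)
  for (ch in unique(map$chr)) {
    jdx <- which(map$chr == ch)
    pos_kb <- map$pos[jdx] / 1000
    Hs <- hap_selected[, jdx, drop = FALSE]
    Hr <- hap_reference[, jdx, drop = FALSE]
    for (k in seq_along(jdx)) {
      i_sel[jdx[k]] <- ehh_integral(Hs, pos_kb, k, ehh_floor)
      i_ref[jdx[k]] <- ehh_integral(Hr, pos_kb, k, ehh_floor)
    }
  }
  raw <- ifelse(i_sel > 0 & i_ref > 0, log(i_sel / i_ref), NA_real_)
  mu <- mean(raw, na.rm = TRUE)
  sg <- stats::sd(raw, na.rm = TRUE)
  std <- if (is.na(sg) || sg == 0) raw * 0 else (raw - mu) / sg
  out <- data.frame(i_selected = i_sel, i_reference = i_ref, raw = raw,
                    std = std, stringsAsFactors = FALSE)
  if (!is.null(map$snp)) out <- cbind(snp = map$snp, out,
                                      stringsAsFactors = FALSE)
  out
}

# Trapezoidal EHH integral around one core, both directions.
ehh_integral <- function(H, pos_kb, core, floor) {
  N <- nrow(H)
  denom <- N * (N - 1)
  hom <- function(g) {
    tab <- tabulate(g)
    sum(tab * (tab - 1)) / denom
  }
  total <- 0
  for (dir in c(1L, -1L)) {
    g <- match(H[, core], unique(H[, core]))
    ehh <- hom(g)
    prev_pos <- pos_kb[core]
    k <- core + dir
    while (ehh >= floor && k >= 1L && k <= ncol(H)) {
      key <- g * 2L + H[, k]
      g <- match(key, unique(key))
      new_ehh <- hom(g)
      total <- total + (ehh + new_ehh) / 2 * abs(pos_kb[k] - prev_pos)
      prev_pos <- pos_kb[k]
      ehh <- new_ehh
      k <- k + dir
    }
  }
  total
}

#' Composite selection signal from constituent test statistics
#'
#' Combines per-SNP selection statistics into one composite score via
#' fractional ranks: each statistic is ranked genome-wide (ascending,
#' average ranks on ties), converted to a fractional rank
#' `r' = rank / (n + 1)` strictly inside (0, 1), then to
#' `z = qnorm(r')`. The mean z over the `m` tests gets a one-sided
#' upper-tail P from its null distribution N(0, 1/m), and
#' `CSS = -log10(P)`. Evidence of selection corresponds to large values of
#' every constituent statistic as oriented here.
#'
#' SNPs with a missing value in any constituent are excluded from ranking
#' and carry `NA` throughout. A constituent with all-identical values
#' contributes `z = 0` everywhere, with a warning.
#'
#' @param stats Named list (or data frame) of equal-length numeric
#'   constituent statistics, e.g. `list(fst = , dsaf = , xpehh = )`.
#' @param map Optional SNP map (`snp`, `chr`, `pos`) prepended to the
#'   result.
#' @return Data frame with, per constituent `t`: `t` (the statistic),
#'   `t_r` (fractional rank), `t_z`; plus `z_mean`, `p`, `css` and the
#'   attribute `m` (number of constituent tests).
#' @export
composite_score <- function(stats, map = NULL) {
  stats <- as.data.frame(stats)
  m <- ncol(stats)
  if (m < 1) stop("need at least one constituent statistic")
  n_all <- nrow(stats)
  if (n_all < 2) stop("need at least 2 SNPs")
  complete <- stats::complete.cases(stats)
  n <- sum(complete)
  out <- if (is.null(map)) data.frame(row.names = seq_len(n_all)) else
    as.data.frame(map[, intersect(c("snp", "chr", "pos"), names(map)),
                      drop = FALSE])
  zsum <- rep(0, n_all)
  for (nm in names(stats)) {
    x <- stats[[nm]]
    r <- rep(NA_real_, n_all)
    if (stats::sd(x[complete]) == 0) {
      warning("constituent '", nm, "' has no variance; contributes z = 0")
      z <- ifelse(complete, 0, NA_real_)
      r[complete] <- 0.5
    } else {
      r[complete] <- rank(x[complete], ties.method = "average") / (n + 1)
      z <- stats::qnorm(r)
    }
    out[[nm]] <- x
    out[[paste0(nm, "_r")]] <- r
    out[[paste0(nm, "_z")]] <- z
    zsum <- zsum + ifelse(is.na(z), NA_real_, z)
  }
  z_mean <- zsum / m
  p <- 1 - stats::pnorm(z_mean * sqrt(m))
  out$z_mean <- z_mean
  out$p <- p
  out$css <- -log10(p)
  attr(out, "m") <- m
  out
}

#' Smooth the composite score over physical windows
#'
#' Replaces each SNP's CSS by the unweighted mean CSS of all SNPs on the
#' same chromosome within `window_kb / 2` kb on either side of its
#' position (a window centred on the SNP, bounds inclusive). SNPs with a
#' missing CSS neither contribute to nor receive a smoothed value.
#'
#' @param stats Result of [composite_score()] carrying `chr`, `pos` and
#'   `css` columns (pass `map` there, or supply `map` here).
#' @param map Optional map supplying `chr`/`pos` when `stats` lacks them.
#' @param window_kb Full window width in kb (default 1000, i.e. 1 Mb).
#' @return `stats` with a `css_smooth` column appended.
#' @export
smooth_css <- function(stats, map = NULL, window_kb = 1000) {
  chr <- if (!is.null(stats$chr)) stats$chr else map$chr
  pos <- if (!is.null(stats$pos)) stats$pos else map$pos
  if (is.null(chr) || is.null(pos)) stop("chr/pos needed for smoothing")
  css <- stats$css
  half_bp <- window_kb * 1000 / 2
  sm <- rep(NA_real_, length(css))
  for (ch in unique(chr)) {
    jdx <- which(chr == ch & !is.na(css))
    if (!length(jdx)) next
    p <- pos[jdx]
    cs <- c(0, cumsum(css[jdx]))
    lo <- findInterval(p - half_bp - 0.5, p) + 1L
    hi <- findInterval(p + half_bp + 0.5, p)
    sm[jdx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  stats$css_smooth <- sm
  stats
}

#' Top tier of SNPs by smoothed composite score
#'
#' The tier of fraction `f` on a panel of `n` scored SNPs holds
#' `floor(f * n)` SNPs (at least one); ties at the cutoff value are
#' included.
#'
#' @param stats Result of [smooth_css()] (or any frame with the scoring
#'   column).
#' @param fraction Tier fraction (e.g. 0.01 for the top 1%).
#' @param column Scoring column (default `"css_smooth"`).
#' @return Logical vector marking tier membership (`FALSE` for unscored
#'   SNPs).
#' @export
css_top_tier <- function(stats, fraction, column = "css_smooth") {
  x <- stats[[column]]
  ok <- which(!is.na(x))
  k <- max(1L, floor(fraction * length(ok)))
  thr <- sort(x[ok], decreasing = TRUE)[k]
  !is.na(x) & x >= thr
}

#' Call candidate selection regions from the smoothed composite score
#'
#' The top tier is the `top_fraction` of scored SNPs by smoothed CSS
#' (ties at the cutoff included). On each chromosome, maximal chains of
#' tier SNPs with consecutive gaps of at most `max_gap_kb` form clusters;
#' clusters with at least `min_snps` members are reported as regions with
#' boundaries at the member min/max positions.
#'
#' @param stats Result of [smooth_css()] with `chr`, `pos`, `css`,
#'   `css_smooth`.
#' @param top_fraction Tier fraction (default 0.01).
#' @param min_snps Minimum tier SNPs per region (default 5).
#' @param max_gap_kb Maximum gap between consecutive tier SNPs in a
#'   cluster (default 1000).
#' @return Data frame of regions: `region`, `chr`, `start`, `end` (bp),
#'   `n_top_snps`, `top_css` (maximum raw CSS among members),
#'   `top_css_smooth`.
#' @export
call_regions <- function(stats, top_fraction = 0.01, min_snps = 5,
                         max_gap_kb = 1000) {
  tier <- css_top_tier(stats, top_fraction)
  out <- list()
  for (ch in unique(stats$chr)) {
    jdx <- which(tier & stats$chr == ch)
    if (length(jdx) < min_snps) next
    pos <- stats$pos[jdx]
    brk <- which(diff(pos) / 1000 > max_gap_kb)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(jdx))
    for (k in seq_along(starts)) {
      mem <- jdx[starts[k]:ends[k]]
      if (length(mem) < min_snps) next
      out[[length(out) + 1L]] <- data.frame(
        chr = ch, start = stats$pos[mem[1]],
        end = stats$pos[mem[length(mem)]], n_top_snps = length(mem),
        top_css = max(stats$css[mem], na.rm = TRUE),
        top_css_smooth = max(stats$css_smooth[mem]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(region = integer(), chr = character(),
                      start = numeric(), end = numeric(),
                      n_top_snps = integer(), top_css = numeric(),
                      top_css_smooth = numeric(), stringsAsFactors = FALSE))
  }
  regions <- do.call(rbind, out)
  regions <- regions[order(-regions$top_css_smooth), , drop = FALSE]
  regions <- cbind(region = seq_len(nrow(regions)), regions)
  rownames(regions) <- NULL
  regions
}

#' Map genes onto selection regions
#'
#' A gene is reported for a region when the gene interval overlaps the
#' region extended by `flank_kb` on both sides; both intervals are closed,
#' so touching endpoints count as overlap.
#'
#' @param regions Region table from [call_regions()].
#' @param gene_table Gene table from [read_gene_annotation()].
#' @param flank_kb Flank added to each region side (default 500).
#' @return Data frame joining regions to overlapping genes: `region`,
#'   `chr`, `gene`, `gene_start`, `gene_end`.
#' @export
map_genes <- function(regions, gene_table, flank_kb = 500) {
  out <- list()
  flank <- flank_kb * 1000
  for (i in seq_len(nrow(regions))) {
    lo <- regions$start[i] - flank
    hi <- regions$end[i] + flank
    hitg <- gene_table$chr == regions$chr[i] &
      gene_table$start <= hi & gene_table$end >= lo
    if (!any(hitg)) next
    g <- gene_table[hitg, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      region = regions$region[i], chr = regions$chr[i], gene = g$gene,
      gene_start = g$start, gene_end = g$end, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(region = integer(), chr = character(),
                      gene = character(), gene_start = numeric(),
                      gene_end = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' One-call composite selection scan
#'
#' Convenience wrapper running the full scan: FST, delta-SAF and (when
#' phased haplotypes are supplied) XP-EHH, the rank composite, 1 Mb
#' smoothing, region calling and optional gene mapping.
#'
#' @param selected,reference `GenotypeDataset`s on a shared panel.
#' @param haplotypes Optional list with phased matrices `selected` and
#'   `reference` (as returned by [simulate_wright_fisher()]).
#' @param gene_table Optional [read_gene_annotation()] table.
#' @param window_kb,top_fraction,min_snps,max_gap_kb,flank_kb Passed to
#'   the respective steps.
#' @return A list: `stats` (per-SNP table with constituent statistics,
#'   ranks, z-values, composite P, CSS and smoothed CSS), `regions`, and
#'   `genes` (`NULL` without a gene table).
#' @export
css_scan <- function(selected, reference, haplotypes = NULL,
                     gene_table = NULL, window_kb = 1000,
                     top_fraction = 0.01, min_snps = 5, max_gap_kb = 1000,
                     flank_kb = 500) {
  constituents <- list(fst = unname(fst_per_snp(selected, reference)),
                       dsaf = unname(delta_saf(selected, reference)))
  if (!is.null(haplotypes)) {
    xe <- xp_ehh(haplotypes$selected, haplotypes$reference, selected$map)
    constituents$xpehh <- xe$std
  }
  stats <- composite_score(constituents, map = selected$map)
  stats <- smooth_css(stats, window_kb = window_kb)
  regions <- call_regions(stats, top_fraction = top_fraction,
                          min_snps = min_snps, max_gap_kb = max_gap_kb)
  genes <- if (!is.null(gene_table) && nrow(regions)) {
    map_genes(regions, gene_table, flank_kb = flank_kb)
  }
  list(stats = stats, regions = regions, genes = genes)
}
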