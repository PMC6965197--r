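#' Filter samples and SNPs on genotyping call rate
#'
#' SNPs are filtered first (call rate across samples), then samples (call
#' rate across the surviving SNPs). Both comparisons are strict: a unit is
#' kept only when its genotyping rate is greater than the threshold, the
#' usual "genotyping rate > 95%" screen.
#'
#' @param dataset A `GenotypeDataset`.
#' @param sample_min,snp_min Minimum call rates in (0, 1]; default 0.95.
#' @return The filtered `GenotypeDataset`.
#' @export
filter_call_rate <- function(dataset, sample_min = 0.95, snp_min = 0.95) {
  stopifnot(sample_min > 0, sample_min <= 1, snp_min > 0, snp_min <= 1)
  calls <- dataset$calls
  snp_rate <- colMeans(!is.na(calls))
  keep_snp <- snp_rate > snp_min
  if (!any(keep_snp)) {
    stop("call-rate filter removed all ", ncol(calls), " SNPs")
  }
  calls2 <- calls[, keep_snp, drop = FALSE]
  samp_rate <- rowMeans(!is.na(calls2))
  keep_samp <- samp_rate > sample_min
  if (!any(keep_samp)) {
    stop("call-rate filter removed all samples (",
         sum(!keep_snp), " SNPs already removed)")
  }
  subset_dataset(dataset, samples = keep_samp, snps = keep_snp)
}

#' Filter SNPs on minor allele frequency
#'
#' Keeps SNPs whose minor allele frequency is strictly greater than
#' `maf_min`; monomorphic SNPs and SNPs with no calls are removed.
#'
#' @param dataset A `GenotypeDataset`.
#' @param maf_min MAF threshold in \[0, 0.5\]; default 0.05.
#' @return The filtered `GenotypeDataset`.
#' @export
filter_maf <- function(dataset, maf_min = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  fr <- allele_frequencies(dataset)
  maf <- pmin(fr$p, 1 - fr$p)
  keep <- !is.na(maf) & maf > maf_min
  if (!any(keep)) warning("MAF filter removed all SNPs")
  subset_dataset(dataset, snps = keep)
}

#' Sliding-window VIF-based LD pruning
#'
#' Within each window of `window_snps` consecutive kept SNPs per chromosome
#' the SNP with the highest variance inflation factor,
#' `VIF = 1 / (1 - R^2)` with `R^2` the multiple correlation of that SNP's
#' dosage on the other window SNPs, is removed repeatedly until all VIFs
#' are at or below `vif_max`; the window then advances by `step_snps`.
#' Removals are global: a removed SNP never re-enters a later window.
#' Ties on VIF are broken by removing the SNP with the lower MAF, then the
#' earlier SNP in map order. Missing dosages are mean-imputed for the
#' regression only; singular fits fall back to a pseudo-inverse with
#' `R^2` capped at `1 - 1e-12`.
#'
#' @param dataset A `GenotypeDataset`.
#' @param window_snps Window size in SNPs (default 50).
#' @param step_snps Step between window starts (default 5).
#' @param vif_max VIF threshold (default 50).
#' @return A `PruneReport`: list with `kept` (SNP ids), `removed` (data
#'   frame `snp`, `window`, `vif`) and the parameters used. Subset the
#'   dataset with `subset_dataset(dataset, snps = report$kept)`.
#' @export
vif_prune <- function(dataset, window_snps = 50, step_snps = 5,
                      vif_max = 50) {
  stopifnot(window_snps > step_snps, step_snps >= 1)
  calls <- dataset$calls
  map <- dataset$map
  fr <- allele_frequencies(dataset)
  maf <- pmin(fr$p, 1 - fr$p)
  removed_flag <- logical(ncol(calls))
  rem_snp <- character(0)
  rem_win <- integer(0)
  rem_vif <- numeric(0)
  window_counter <- 0L

  for (ch in unique(map$chr)) {
    idx_all <- which(map$chr == ch)
    s <- length(idx_all)
    starts <- seq(1L, s, by = step_snps)
    for (st in starts) {
      window_counter <- window_counter + 1L
      win <- idx_all[st:min(st + window_snps - 1L, s)]
      repeat {
        act <- win[!removed_flag[win]]
        if (length(act) < 2) break
        vifs <- window_vifs(calls[, act, drop = FALSE])
        mx <- max(vifs)
        if (mx <= vif_max) break
        cand <- which(vifs >= mx - 1e-9)
        if (length(cand) > 1) {
          cand <- cand[order(maf[act][cand], act[cand])]
        }
        victim <- act[cand[1]]
        removed_flag[victim] <- TRUE
        rem_snp <- c(rem_snp, map$snp[victim])
        rem_win <- c(rem_win, window_counter)
        rem_vif <- c(rem_vif, mx)
      }
    }
  }
  structure(list(kept = map$snp[!removed_flag],
                 removed = data.frame(snp = rem_snp, window = rem_win,
                                      vif = rem_vif,
                                      stringsAsFactors = FALSE),
                 window_snps = window_snps, step_snps = step_snps,
                 vif_max = vif_max),
            class = "PruneReport")
}

#' @export
print.PruneReport <- function(x, ...) {
  cat("PruneReport:", length(x$kept), "SNPs kept,", nrow(x$removed),
      "removed (window", x$window_snps, "step", x$step_snps, "VIF <=",
      x$vif_max, ")\n")
  invisible(x)
}

# VIF of every SNP in a window from the inverse of the dosage correlation
# matrix; zero-variance columns get VIF 1 and are excluded from the fit.
window_vifs <- function(g) {
  g <- apply(g, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  vifs <- rep(1, ncol(g))
  sds <- apply(g, 2, stats::sd)
  act <- which(sds > 0)
  if (length(act) < 2) return(vifs)
  C <- stats::cor(g[, act, drop = FALSE])
  inv <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(inv)) {
    # singular window (e.g. duplicated SNP): per-SNP least-squares R^2,
    # rank-deficient fits handled by lm.fit, R^2 capped at 1 - 1e-12
    v <- vapply(seq_along(act), function(j) {
      yj <- g[, act[j]]
      Xo <- g[, act[-j], drop = FALSE]
      fit <- stats::lm.fit(cbind(1, Xo), yj)
      r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
      1 / (1 - min(r2, 1 - 1e-12))
    }, numeric(1))
  } else {
    v <- diag(inv)
  }
  v[!is.finite(v)] <- 1e12
  vifs[act] <- pmin(pmax(v, 1), 1e12)   # R^2 capped at 1 - 1e-12
  vifs
}

#' Pairwise pi-hat (genome-wide IBD proportion)
#'
#' Method-of-moments IBD estimation from identity-by-state sharing and
#' sample allele frequencies. For every SNP the probabilities of observing
#' IBS 0, 1 or 2 given an underlying IBD state of 0, 1 or 2 are computed
#' from the sample frequencies using unbiased falling-factorial estimators
#' of the required allele-frequency powers (the small-sample correction).
#' Observed IBS counts for each pair are then decomposed into estimated
#' P(IBD = 0, 1, 2), the solution is bounded to the probability simplex,
#' and `pihat = P(IBD=2) + P(IBD=1) / 2`.
#'
#' @param dataset A `GenotypeDataset` with at least two samples.
#' @return Data frame with one row per sample pair: `id1`, `id2`, `ibs0`,
#'   `ibs1`, `ibs2`, `pihat` (clamped to \[0, 1\]).
#' @export
ibd_pihat <- function(dataset) {
  calls <- dataset$calls
  n <- nrow(calls)
  if (n < 2) stop("pi-hat needs at least two samples")

  cnt <- colSums(!is.na(calls))
  s <- colSums(calls, na.rm = TRUE)
  T_ <- 2 * cnt          # sampled allele count
  XB <- s                # B alleles
  XA <- T_ - s
  usable <- T_ >= 4
  ff <- function(x, k) {
    out <- rep(1, length(x))
    for (i in seq_len(k)) out <- out * pmax(x - (i - 1), 0)
    out
  }
  # P(IBS = i | IBD = z) per SNP, bias-corrected
  P00 <- 2 * ff(XA, 2) * ff(XB, 2) / ff(T_, 4)
  P10 <- (4 * ff(XA, 3) * XB + 4 * XA * ff(XB, 3)) / ff(T_, 4)
  P20 <- (ff(XA, 4) + ff(XB, 4) + 4 * ff(XA, 2) * ff(XB, 2)) / ff(T_, 4)
  P11 <- (2 * ff(XA, 2) * XB + 2 * XA * ff(XB, 2)) / ff(T_, 3)
  P21 <- (ff(XA, 3) + ff(XB, 3) + ff(XA, 2) * XB + XA * ff(XB, 2)) /
    ff(T_, 3)
  P00[!usable] <- NA

  ids <- rownames(calls)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  out <- data.frame(id1 = ids[pairs[1, ]], id2 = ids[pairs[2, ]],
                    ibs0 = integer(np), ibs1 = integer(np),
                    ibs2 = integer(np), pihat = numeric(np),
                    stringsAsFactors = FALSE)
  for (k in seq_len(np)) {
    g1 <- calls[pairs[1, k], ]
    g2 <- calls[pairs[2, k], ]
    mask <- !is.na(g1) & !is.na(g2) & usable
    d <- abs(g1[mask] - g2[mask])
    N0 <- sum(d == 2)
    N1 <- sum(d == 1)
    N2 <- sum(d == 0)
    L <- length(d)
    if (L == 0) {
      out$pihat[k] <- NA_real_
      next
    }
    E00 <- sum(P00[mask])
    E10 <- sum(P10[mask])
    E20 <- sum(P20[mask])
    E11 <- sum(P11[mask])
    E21 <- sum(P21[mask])
    z0 <- if (E00 > 0) N0 / E00 else 0
    z1 <- if (E11 > 0) (N1 - z0 * E10) / E11 else 0
    z2 <- (N2 - z0 * E20 - z1 * E21) / L
    z <- pmax(c(z0, z1, z2), 0)
    z <- pmin(z, 1)
    if (sum(z) == 0) z <- c(1, 0, 0)
    z <- z / sum(z)
    out$ibs0[k] <- N0
    out$ibs1[k] <- N1
    out$ibs2[k] <- N2
    out$pihat[k] <- min(max(z[3] + z[2] / 2, 0), 1)
  }
  out
}

#' Greedy removal of related samples
#'
#' Repeatedly drops the sample participating in the most pairs with
#' `pihat > pihat_max` until no pair exceeds the threshold. Ties are broken
#' by higher genotype missingness, then by sample order.
#'
#' @param dataset A `GenotypeDataset`.
#' @param pairs Pair table from [ibd_pihat()] computed on this dataset.
#' @param pihat_max Relatedness threshold (default 0.25).
#' @return The `GenotypeDataset` with related samples removed.
#' @export
remove_related <- function(dataset, pairs, pihat_max = 0.25) {
  ids <- rownames(dataset$calls)
  if (!all(pairs$id1 %in% ids) || !all(pairs$id2 %in% ids)) {
    stop("pair table refers to samples not in the dataset")
  }
  missingness <- rowMeans(is.na(dataset$calls))
  active <- pairs[!is.na(pairs$pihat) & pairs$pihat > pihat_max,
                  c("id1", "id2")]
  drop <- character(0)
  while (nrow(active) > 0) {
    deg <- table(c(active$id1, active$id2))
    mx <- max(deg)
    cand <- names(deg)[deg == mx]
    if (length(cand) > 1) {
      cand <- cand[order(-missingness[cand], match(cand, ids))]
    }
    victim <- cand[1]
    drop <- c(drop, victim)
    active <- active[active$id1 != victim & active$id2 != victim, ,
                     drop = FALSE]
  }
  subset_dataset(dataset, samples = setdiff(ids, drop))
}
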