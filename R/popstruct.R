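#' Genetic relatedness matrix
#'
#' Standardised-dosage GRM: genotype codes are centred by `2p` and scaled
#' by `sqrt(2 p (1 - p))` per SNP (missing entries contribute 0 after
#' centring), and the sample-by-sample matrix is the cross-product over
#' SNPs divided, per pair, by the number of SNPs non-missing in both
#' samples. SNPs fixed in the sample (`p` of 0 or 1) carry no information
#' and are excluded; their count is attached as attribute
#' `n_excluded_snps`.
#'
#' @param dataset A `GenotypeDataset`.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
grm <- function(dataset) {
  calls <- dataset$calls
  p <- allele_frequencies(dataset)$p
  use <- !is.na(p) & p > 0 & p < 1
  n_excl <- sum(!use)
  calls <- calls[, use, drop = FALSE]
  p <- p[use]
  Z <- sweep(calls, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  M <- !is.na(calls)
  Z[!M] <- 0
  K <- tcrossprod(Z)
  cnt <- tcrossprod(M * 1)
  K <- K / pmax(cnt, 1)
  K[cnt == 0] <- NA
  dimnames(K) <- list(rownames(calls), rownames(calls))
  attr(K, "n_excluded_snps") <- n_excl
  K
}

#' PCA of the relatedness matrix with sigma-based outlier iteration
#'
#' Eigendecomposes the GRM and removes any sample whose coordinate on one
#' of the top `n_evec_checked` components lies more than `sigma` standard
#' deviations from that component's mean, then recomputes on the retained
#' samples; the cycle repeats until no outlier remains or `max_iter`
#' iterations have run. `sigma = Inf` disables removal.
#'
#' @param grm_matrix Symmetric matrix from [grm()].
#' @param sigma Outlier threshold in SDs (default 10).
#' @param n_evec_checked Components screened for outliers (default 10).
#' @param max_iter Maximum removal iterations (default 5).
#' @param K Components reported (default 10).
#' @return A list of class `PcaResult`: `retained` (sample ids),
#'   `eigenvalues` (non-increasing), `coords` (retained x K), `outliers`
#'   (data frame `id`, `iteration`, `component`, `sigma_distance`).
#' @export
pca_outlier <- function(grm_matrix, sigma = 10, n_evec_checked = 10,
                        max_iter = 5, K = 10) {
  if (!isSymmetric(unname(grm_matrix), tol = 1e-8)) {
    stop("grm_matrix must be symmetric")
  }
  ids <- rownames(grm_matrix)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(grm_matrix)))
  keep <- ids
  outliers <- data.frame(id = character(), iteration = integer(),
                         component = integer(), sigma_distance = numeric(),
                         stringsAsFactors = FALSE)
  eg <- NULL
  for (it in seq_len(max_iter + 1L)) {
    sub <- grm_matrix[keep, keep, drop = FALSE]
    eg <- eigen(sub, symmetric = TRUE)
    ncomp <- min(n_evec_checked, length(keep) - 1L)
    flagged <- character(0)
    if (is.finite(sigma) && it <= max_iter && ncomp >= 1) {
      for (c in seq_len(ncomp)) {
        v <- eg$vectors[, c]
        sdv <- stats::sd(v)
        if (!is.finite(sdv) || sdv == 0) next
        dist <- abs(v - mean(v)) / sdv
        bad <- which(dist > sigma)
        for (b in bad) {
          if (keep[b] %in% flagged) next
          flagged <- c(flagged, keep[b])
          outliers <- rbind(outliers,
                           data.frame(id = keep[b], iteration = it,
                                      component = c,
                                      sigma_distance = dist[b],
                                      stringsAsFactors = FALSE))
        }
      }
    }
    if (!length(flagged)) break
    keep <- setdiff(keep, flagged)
    if (length(keep) < 2) stop("outlier removal left fewer than 2 samples")
  }
  k_out <- min(K, length(keep))
  coords <- eg$vectors[, seq_len(k_out), drop = FALSE]
  rownames(coords) <- keep
  structure(list(retained = keep, eigenvalues = eg$values,
                 coords = coords, outliers = outliers),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult:", length(x$retained), "samples retained,",
      nrow(x$outliers), "outlier(s) removed; top eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Effective population size from the LD bias-correction formula
#'
#' The random-mating LD method: subtract the sample-size expectation of
#' the squared allelic correlation from the observed mean, then solve the
#' drift relationship for Ne. For `S >= 30` samples the expectation is
#' `1/S + 3.19/S^2` and `Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')`; for
#' `S < 30` the small-sample constants of the same method are used
#' (`0.0018 + 0.907/S + 4.44/S^2`;
#' `Ne = (0.308 + sqrt(0.308^2 - 2.08 r2'))/(2 r2')`). A drift component
#' `r2' <= 0` means drift is undetectable at this sample size and Ne is
#' reported infinite.
#'
#' @param r2 Mean squared allelic correlation across locus pairs.
#' @param S Sample size (number of individuals).
#' @return A list: `r2_drift` (bias-corrected r2) and `ne` (point
#'   estimate; `Inf` when `r2_drift <= 0`).
#' @export
ne_from_r2 <- function(r2, S) {
  if (S >= 30) {
    r2d <- r2 - 1 / S - 3.19 / S^2
    a <- 1 / 3
    b <- 1 / 9
    cc <- 2.76
  } else {
    r2d <- r2 - 0.0018 - 0.907 / S - 4.44 / S^2
    a <- 0.308
    b <- 0.308^2
    cc <- 2.08
  }
  ne <- if (r2d <= 0) Inf else (a + sqrt(max(0, b - cc * r2d))) / (2 * r2d)
  list(r2_drift = r2d, ne = ne)
}

#' LD-based effective population size
#'
#' Estimates Ne from the excess association between unlinked loci.
#' Pairwise composite linkage disequilibrium (Burrows' Delta) is computed
#' from unphased genotypes for every eligible locus pair, converted to a
#' squared correlation
#' `r^2 = Delta^2 / ((p_j q_j + h_j)(p_k q_k + h_k))` with `h` the
#' homozygote excess, averaged over pairs, bias-corrected for sample size
#' and solved for Ne (see [ne_from_r2()]). By default only
#' inter-chromosomal pairs are used, because physical linkage inflates
#' `r^2` and biases Ne downward; same-chromosome pairs can be included for
#' comparison with tools that use them. Missing genotypes are handled
#' pairwise-complete; `Delta` carries the `n/(n-1)` small-sample factor.
#'
#' The parametric confidence interval treats the pair count as the degrees
#' of freedom of a chi-square distribution for the mean `r^2` and
#' transforms the resulting `r^2` bounds through the same Ne formula.
#'
#' @param dataset A `GenotypeDataset` with at least 10 samples.
#' @param maf_min SNPs with MAF below this are screened out (default
#'   0.05).
#' @param pair_scope `"interchromosomal"` (default) or `"all"`.
#' @return A list of class `NeEstimate`: `S` (harmonic mean sample size
#'   per pair), `n_pairs`, `r2_mean`, `r2_drift`, `ne`, `ne_lo`, `ne_hi`,
#'   `infinite` flag.
#' @export
ld_ne <- function(dataset, maf_min = 0.05,
                  pair_scope = c("interchromosomal", "all")) {
  pair_scope <- match.arg(pair_scope)
  if (n_samples(dataset) < 10) stop("LD Ne needs at least 10 samples")
  fr <- allele_frequencies(dataset)
  maf <- pmin(fr$p, 1 - fr$p)
  keep <- !is.na(maf) & maf >= maf_min
  if (pair_scope == "interchromosomal" &&
      length(unique(dataset$map$chr[keep])) < 2) {
    stop("interchromosomal pairing needs SNPs on at least 2 chromosomes")
  }
  ds <- subset_dataset(dataset, snps = keep)
  X <- ds$calls
  storage.mode(X) <- "double"
  m <- ncol(X)
  M <- (!is.na(X)) * 1
  X0 <- X
  X0[is.na(X0)] <- 0
  B2 <- (X == 2 & !is.na(X)) * 1

  n_pair <- crossprod(M)                 # co-nonmissing counts
  Sx <- crossprod(X0, M)                 # sum of x_j over complete pairs
  Sxy <- crossprod(X0)                   # sum x_j x_k
  Sb2 <- crossprod(B2, M)                # BB count of locus j per pair

  n_ok <- pmax(n_pair, 2)
  pj <- Sx / (2 * n_ok)                  # row locus frequency per pair
  pk <- t(pj)
  cov <- Sxy / n_ok - (Sx / n_ok) * t(Sx / n_ok)
  delta <- cov / 2 * n_ok / (n_ok - 1)
  hj <- Sb2 / n_ok - pj^2
  hk <- t(hj)
  denom <- (pj * (1 - pj) + hj) * (pk * (1 - pk) + hk)
  r2 <- delta^2 / denom

  eligible <- upper.tri(r2) & n_pair >= 10 & is.finite(r2) & denom > 0
  if (pair_scope == "interchromosomal") {
    chrc <- as.integer(factor(ds$map$chr))
    eligible <- eligible & outer(chrc, chrc, "!=")
  }
  if (!any(eligible)) stop("no eligible locus pairs")
  r2v <- r2[eligible]
  nv <- n_pair[eligible]
  J <- length(r2v)
  r2_mean <- mean(r2v)
  S <- J / sum(1 / nv)                   # harmonic mean sample size
  est <- ne_from_r2(r2_mean, S)
  lo_r2 <- r2_mean * J / stats::qchisq(0.975, J)
  hi_r2 <- r2_mean * J / stats::qchisq(0.025, J)
  ne_hi <- ne_from_r2(lo_r2, S)$ne
  ne_lo <- ne_from_r2(hi_r2, S)$ne
  structure(list(S = S, n_pairs = J, r2_mean = r2_mean,
                 r2_drift = est$r2_drift, ne = est$ne, ne_lo = ne_lo,
                 ne_hi = ne_hi, infinite = !is.finite(est$ne)),
            class = "NeEstimate")
}

#' @export
print.NeEstimate <- function(x, ...) {
  cat(sprintf(
    "NeEstimate: Ne = %s (CI %.4g - %s), S = %.1f, %d pairs, r2 = %.6f (drift %.6f)\n",
    if (x$infinite) "Inf" else sprintf("%.1f", x$ne), x$ne_lo,
    if (is.finite(x$ne_hi)) sprintf("%.4g", x$ne_hi) else "Inf",
    x$S, x$n_pairs, x$r2_mean, x$r2_drift))
  invisible(x)
}
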