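#' Expected offspring genotype distribution given a sire genotype
#'
#' Offspring of a known sire and random dams mating under Hardy-Weinberg
#' receive one fair-coin sire allele and one dam allele drawn from the
#' population. With `p` the population frequency of allele A (so
#' `q = 1 - p` the B-allele frequency) the offspring genotype
#' probabilities over (AA, AB, BB) are: sire AA gives `(p, q, 0)`;
#' sire AB gives `(p/2, 1/2, q/2)`; sire BB gives `(0, p, q)`.
#'
#' @param sire_genotype One of `"AA"`, `"AB"`, `"BB"` or the dosage code
#'   0, 1, 2 (count of allele B).
#' @param p Population frequency of allele A in \[0, 1\].
#' @return Named numeric triple `c(AA = , AB = , BB = )`.
#' @export
expected_offspring_distribution <- function(sire_genotype, p) {
  stopifnot(p >= 0, p <= 1)
  g <- normalise_sire_code(sire_genotype)
  q <- 1 - p
  switch(as.character(g),
         "0" = c(AA = p, AB = q, BB = 0),
         "1" = c(AA = p / 2, AB = 0.5, BB = q / 2),
         "2" = c(AA = 0, AB = p, BB = q))
}

normalise_sire_code <- function(x) {
  if (is.character(x)) {
    x <- match(toupper(x), c("AA", "AB", "BB")) - 1L
    if (is.na(x)) stop("sire genotype must be AA, AB, BB or 0/1/2")
  }
  stopifnot(x %in% 0:2)
  as.integer(x)
}

#' Reconstruct a sire's genotype from half-sib progeny
#'
#' Infers the genotype of an ungenotyped sire at every SNP from the
#' genotypes of its half-sib offspring plus population allele frequencies.
#' Per SNP:
#'
#' 1. Hard Mendelian rule: if both homozygote classes occur among the
#'    offspring they cannot share one sire allele, so the sire must be
#'    heterozygous -- candidates are restricted to AB.
#' 2. Any candidate whose expected offspring distribution (see
#'    [expected_offspring_distribution()]) assigns probability 0 to an
#'    observed class is excluded; this is the hard rule as the
#'    expected-count-zero limit.
#' 3. For each remaining candidate G, a goodness-of-fit statistic
#'    `X2_G = sum (O - E)^2 / E` over classes with `E > 0`, with
#'    `E = n * (expected probability)` and `n` the non-missing offspring
#'    count.
#' 4. A likelihood score `L_G` = chi-square density with `df` degrees of
#'    freedom at `X2_G`; relative likelihoods by normalising over
#'    candidates.
#' 5. The argmax candidate is assigned when its relative likelihood
#'    reaches `confidence_min`; ties go to the candidate with the higher
#'    Hardy-Weinberg population genotype frequency, then to the
#'    heterozygote.
#'
#' Loci with fewer than `min_offspring` non-missing offspring calls, and
#' loci where a fixed population frequency contradicts the offspring
#' (flagged inconsistent), are called missing.
#'
#' @param offspring A `GenotypeDataset` of the half-sib family.
#' @param pop_freqs [allele_frequencies()] table (or numeric vector of
#'   B-allele frequencies) from the reference population, covering the
#'   same SNP panel.
#' @param min_offspring Minimum informative offspring per locus
#'   (default 20).
#' @param df Degrees of freedom for the chi-square density (default 2: the
#'   density is finite everywhere, so a perfect fit does not overwhelm the
#'   normalisation the way the unbounded df = 1 density at 0 would).
#' @param confidence_min Minimum relative likelihood to assign a call
#'   (default 0: always assign).
#' @return Data frame with one row per SNP: offspring class counts,
#'   per-candidate `x2_*` statistics and `rl_*` relative likelihoods,
#'   `call` (dosage code 0/1/2 or `NA`), `confidence`, `inconsistent`.
#' @export
reconstruct_sire <- function(offspring, pop_freqs, min_offspring = 20L,
                             df = 2, confidence_min = 0) {
  calls <- offspring$calls
  if (is.data.frame(pop_freqs)) {
    if (!is.null(pop_freqs$snp) &&
        !identical(pop_freqs$snp, offspring$map$snp)) {
      pop_freqs <- pop_freqs[match(offspring$map$snp, pop_freqs$snp), ]
    }
    pB <- pop_freqs$p
  } else {
    pB <- pop_freqs
  }
  if (length(pB) != ncol(calls)) {
    stop("pop_freqs must cover all ", ncol(calls), " SNPs")
  }
  pA <- 1 - pB
  qA <- pB
  nAA <- colSums(calls == 0L, na.rm = TRUE)
  nAB <- colSums(calls == 1L, na.rm = TRUE)
  nBB <- colSums(calls == 2L, na.rm = TRUE)
  n <- nAA + nAB + nBB
  m <- ncol(calls)

  # expected class probabilities per candidate (rows AA/AB/BB of offspring)
  probs <- list(
    `0` = rbind(pA, qA, 0),
    `1` = rbind(pA / 2, 0.5, qA / 2),
    `2` = rbind(0, pA, qA))
  obs <- rbind(nAA, nAB, nBB)
  x2 <- matrix(NA_real_, 3, m, dimnames = list(c("AA", "AB", "BB"), NULL))
  excluded <- matrix(FALSE, 3, m)
  for (k in 1:3) {
    P <- probs[[k]]
    E <- P * rep(n, each = 3)
    impossible <- colSums(obs > 0 & P <= 0) > 0
    excluded[k, ] <- impossible
    contrib <- (obs - E)^2 / E
    contrib[P <= 0] <- 0
    x2[k, ] <- colSums(contrib)
  }
  # hard rule: both homozygote classes observed => sire heterozygous
  both_hom <- nAA > 0 & nBB > 0
  excluded[1, both_hom] <- TRUE
  excluded[3, both_hom] <- TRUE

  L <- stats::dchisq(x2, df = df)
  L[excluded] <- 0
  L[!is.finite(L)] <- 0
  tot <- colSums(L)
  rl <- sweep(L, 2, ifelse(tot > 0, tot, 1), "/")

  # HWE population genotype frequencies used as the tie-break preference
  hwe <- rbind(pA^2, 2 * pA * qA, qA^2)
  call <- integer(m)
  confidence <- numeric(m)
  inconsistent <- tot <= 0 & n > 0
  for (j in seq_len(m)) {
    if (tot[j] <= 0) {
      call[j] <- NA_integer_
      next
    }
    mx <- max(rl[, j])
    cand <- which(rl[, j] >= mx - 1e-12)
    if (length(cand) > 1) {
      cand <- cand[order(-hwe[cand, j], -(cand == 2L))]
    }
    call[j] <- cand[1] - 1L
    confidence[j] <- mx
  }
  low_n <- n < min_offspring
  low_conf <- confidence < confidence_min
  call[low_n | low_conf | inconsistent] <- NA_integer_
  data.frame(snp = offspring$map$snp, n_AA = nAA, n_AB = nAB, n_BB = nBB,
             n_missing = nrow(calls) - n,
             x2_AA = x2[1, ], x2_AB = x2[2, ], x2_BB = x2[3, ],
             rl_AA = rl[1, ], rl_AB = rl[2, ], rl_BB = rl[3, ],
             call = call, confidence = confidence,
             inconsistent = inconsistent, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Concordance between reconstructed and true genotypes
#'
#' @param assigned Integer vector of assigned dosage codes (`NA` = no
#'   call), e.g. the `call` column of [reconstruct_sire()].
#' @param truth Integer vector of true codes on the same SNP panel.
#' @return A list: `concordance_pct` (100 x matches / co-called loci),
#'   `n_co_called`, `call_rate_pct` (percentage of truth-covered loci with
#'   an assignment).
#' @export
reconstruction_concordance <- function(assigned, truth) {
  if (length(assigned) != length(truth)) stop("same SNP panel required")
  both <- !is.na(assigned) & !is.na(truth)
  if (!any(both)) stop("no co-called loci")
  list(concordance_pct = 100 * mean(assigned[both] == truth[both]),
       n_co_called = sum(both),
       call_rate_pct = 100 * mean(!is.na(assigned[!is.na(truth)])))
}
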