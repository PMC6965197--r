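# Independent reference implementations used as oracles. These are written
# as literal enumerations of the definitions and deliberately share no code
# with the package internals.

# Random genotype dataset for fuzzing.
random_dataset <- function(n_samples, n_snps, n_chr = 2,
                           missing_rate = 0.05, pos_step_kb = NULL) {
  g <- matrix(sample(c(0:2, NA), n_samples * n_snps, replace = TRUE,
                     prob = c((1 - missing_rate) / 3,
                              (1 - missing_rate) / 3,
                              (1 - missing_rate) / 3, missing_rate)),
              n_samples, n_snps)
  chr <- sort(rep_len(as.character(seq_len(n_chr)), n_snps))
  pos <- unlist(lapply(table(chr)[unique(chr)], function(k) {
    if (is.null(pos_step_kb)) {
      sort(sample.int(1e8, k))
    } else {
      cumsum(sample.int(pos_step_kb * 1000, k, replace = TRUE))
    }
  }))
  genotype_dataset(g, data.frame(snp = paste0("m", seq_len(n_snps)),
                                 chr = chr, pos = pos,
                                 stringsAsFactors = FALSE))
}

# Exhaustive window/run ROH reference: enumerates every window and run
# literally with loops and sum().
oracle_roh <- function(dataset, min_kb = 1000, min_snps = 30,
                       max_gap_kb = 1000, max_density_kb_per_snp = 1000,
                       window_snps = 30, window_het = 1,
                       window_missing = 2, hit_fraction = 0.05) {
  out <- list()
  for (id in rownames(dataset$calls)) {
    for (ch in unique(dataset$map$chr)) {
      jdx <- which(dataset$map$chr == ch)
      pos <- dataset$map$pos[jdx]
      g <- dataset$calls[id, jdx]
      S <- length(jdx)
      W <- min(window_snps, S)
      wins <- lapply(seq_len(S - W + 1), function(a) a:(a + W - 1))
      ok <- vapply(wins, function(w) {
        sum(g[w] == 1, na.rm = TRUE) <= window_het &&
          sum(is.na(g[w])) <= window_missing
      }, logical(1))
      hit <- vapply(seq_len(S), function(j) {
        # windows containing SNP j are exactly those starting in
        # [j - W + 1, j] clipped to the valid start range
        inw <- max(1, j - W + 1):min(j, length(wins))
        mean(ok[inw]) >= hit_fraction
      }, logical(1))
      # maximal hit runs, split at big gaps
      j <- 1
      while (j <= S) {
        if (!hit[j]) {
          j <- j + 1
          next
        }
        k <- j
        while (k < S && hit[k + 1] &&
               (pos[k + 1] - pos[k]) / 1000 <= max_gap_kb) k <- k + 1
        len_kb <- (pos[k] - pos[j]) / 1000
        n <- k - j + 1
        if (len_kb > min_kb && n >= min_snps &&
            len_kb / n <= max_density_kb_per_snp) {
          out[[length(out) + 1]] <- data.frame(
            id = id, chr = ch, start = pos[j], end = pos[k], n_snps = n,
            length_kb = len_kb, stringsAsFactors = FALSE)
        }
        j <- k + 1
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(), chr = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Step-literal composite-score reference: ranks -> fractional ranks ->
# inverse-normal -> mean -> N(0, 1/m) upper tail -> -log10.
oracle_css <- function(stat_list) {
  n <- length(stat_list[[1]])
  zs <- sapply(stat_list, function(x) {
    r <- rank(x, ties.method = "average")
    qnorm(r / (n + 1))
  })
  m <- length(stat_list)
  zbar <- rowMeans(zs)
  p <- pnorm(zbar, mean = 0, sd = sqrt(1 / m), lower.tail = FALSE)
  -log10(p)
}

# Brute-force EHH integral by enumerating haplotype pairs and shared
# prefixes outward from the core.
oracle_ehh_integral <- function(H, pos_kb, core, floor = 0.05) {
  N <- nrow(H)
  pair_identical <- function(i, j, from, to) {
    all(H[i, from:to] == H[j, from:to])
  }
  ehh_at <- function(from, to) {
    cnt <- 0
    for (i in 1:(N - 1)) for (j in (i + 1):N) {
      if (pair_identical(i, j, from, to)) cnt <- cnt + 1
    }
    cnt / (N * (N - 1) / 2)
  }
  total <- 0
  for (dir in c(1, -1)) {
    prev <- ehh_at(core, core)
    prev_pos <- pos_kb[core]
    k <- core + dir
    while (prev >= floor && k >= 1 && k <= ncol(H)) {
      e <- ehh_at(min(core, k), max(core, k))
      total <- total + (prev + e) / 2 * abs(pos_kb[k] - prev_pos)
      prev_pos <- pos_kb[k]
      prev <- e
      k <- k + dir
    }
  }
  total
}
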