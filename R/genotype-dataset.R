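#' Construct a genotype dataset
#'
#' The central container of the pipeline: a sample-by-SNP matrix of B-allele
#' dosage codes together with the SNP map and per-sample metadata. Genotype
#' codes are 0, 1, 2 (count of the B allele) with `NA` for a missing call.
#'
#' SNPs are stored sorted by (chromosome, position); the constructor sorts
#' its input and requires positions to be strictly increasing within each
#' chromosome afterwards, so a dataset can never carry two SNPs at the same
#' position on one chromosome. Chromosome labels are opaque strings; labels
#' that parse as numbers sort numerically, all others lexicographically
#' after them.
#'
#' @param calls Integer matrix, samples in rows and SNPs in columns, values
#'   in `{0, 1, 2, NA}`. Row names are sample ids, column names SNP ids;
#'   when absent they are generated.
#' @param map Data frame with one row per SNP: columns `snp`, `chr`, `pos`
#'   (1-based bp) and optionally `allele_a`, `allele_b` (the allele counted
#'   by the dosage code is `allele_b`).
#' @param meta Optional data frame of per-sample metadata with columns `id`,
#'   `sire`, `dam`, `sex`, `yob`, `region`; missing columns are filled with
#'   `NA`. Absent metadata is allowed and only rejected by operations that
#'   need it.
#' @return An object of class `GenotypeDataset`: a list with elements
#'   `calls`, `map`, `meta`.
#' @export
genotype_dataset <- function(calls, map, meta = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) colnames(calls) <- map$snp
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("snp", "chr", "pos") %in% names(map))) {
    stop("map must have columns snp, chr, pos")
  }
  map$snp <- as.character(map$snp)
  map$chr <- as.character(map$chr)
  map$pos <- as.numeric(map$pos)
  if (is.null(map$allele_a)) map$allele_a <- NA_character_
  if (is.null(map$allele_b)) map$allele_b <- NA_character_
  if (nrow(map) != ncol(calls)) {
    stop("map rows (", nrow(map), ") != call matrix columns (", ncol(calls), ")")
  }
  if (anyDuplicated(rownames(calls))) {
    stop("duplicated sample id: ",
         rownames(calls)[anyDuplicated(rownames(calls))])
  }
  if (anyDuplicated(map$snp)) {
    stop("duplicated SNP id: ", map$snp[anyDuplicated(map$snp)])
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  ord <- order(chr_sort_key(map$chr), map$pos)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(map) <- NULL
  colnames(calls) <- map$snp
  dup <- unlist(tapply(map$pos, map$chr, function(p) any(diff(p) <= 0)))
  if (any(dup)) {
    stop("positions not strictly increasing on chromosome ",
         names(dup)[which(dup)[1]])
  }
  meta <- normalise_meta(meta, rownames(calls))
  structure(list(calls = calls, map = map, meta = meta),
            class = "GenotypeDataset")
}

# numeric-aware chromosome ordering: "2" before "10", non-numeric labels last
chr_sort_key <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  rank(xtfrm(ifelse(is.na(num),
                    paste0("zzz", chr),
                    sprintf("%015.4f", num))),
       ties.method = "min")
}

normalise_meta <- function(meta, ids) {
  cols <- c("id", "sire", "dam", "sex", "yob", "region")
  if (is.null(meta)) {
    meta <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                       sex = NA_integer_, yob = NA_integer_,
                       region = NA_character_, stringsAsFactors = FALSE)
    return(meta)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"id" %in% names(meta)) stop("meta must have an 'id' column")
  meta$id <- as.character(meta$id)
  if (!setequal(meta$id, ids) || anyDuplicated(meta$id)) {
    stop("meta ids must match sample ids exactly")
  }
  for (cl in setdiff(cols, names(meta))) meta[[cl]] <- NA
  meta <- meta[match(ids, meta$id), cols]
  rownames(meta) <- NULL
  meta
}

#' @export
print.GenotypeDataset <- function(x, ...) {
  cat("GenotypeDataset:", nrow(x$calls), "samples x", ncol(x$calls), "SNPs on",
      length(unique(x$map$chr)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / SNPs in a dataset
#' @param dataset A `GenotypeDataset`.
#' @return Integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$calls)

#' @rdname n_samples
#' @export
n_snps <- function(dataset) ncol(dataset$calls)

#' Subset a genotype dataset
#'
#' @param dataset A `GenotypeDataset`.
#' @param samples Character vector of sample ids, or a logical/integer index
#'   over samples; `NULL` keeps all.
#' @param snps Character vector of SNP ids, or a logical/integer index over
#'   SNPs; `NULL` keeps all.
#' @return A `GenotypeDataset` restricted to the requested samples and SNPs.
#' @export
subset_dataset <- function(dataset, samples = NULL, snps = NULL) {
  calls <- dataset$calls
  meta <- dataset$meta
  map <- dataset$map
  if (!is.null(samples)) {
    idx <- resolve_index(samples, rownames(calls), "sample")
    calls <- calls[idx, , drop = FALSE]
    meta <- meta[idx, , drop = FALSE]
  }
  if (!is.null(snps)) {
    jdx <- resolve_index(snps, map$snp, "SNP")
    calls <- calls[, jdx, drop = FALSE]
    map <- map[jdx, , drop = FALSE]
  }
  rownames(meta) <- NULL
  rownames(map) <- NULL
  structure(list(calls = calls, map = map, meta = meta),
            class = "GenotypeDataset")
}

resolve_index <- function(key, universe, what) {
  if (is.character(key)) {
    idx <- match(key, universe)
    if (anyNA(idx)) stop("unknown ", what, " id: ", key[which(is.na(idx))[1]])
    return(idx)
  }
  seq_along(universe)[key]
}

#' Attach per-sample metadata to a dataset
#'
#' @param dataset A `GenotypeDataset`.
#' @param meta Data frame with an `id` column matching the sample ids and
#'   any of `sire`, `dam`, `sex`, `yob`, `region`.
#' @return The dataset with its `meta` slot replaced.
#' @export
set_sample_meta <- function(dataset, meta) {
  dataset$meta <- normalise_meta(meta, rownames(dataset$calls))
  dataset
}
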