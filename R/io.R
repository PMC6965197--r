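#' Read PLINK text PED/MAP files
#'
#' Parses a whitespace-delimited PED file (six leading columns: family id,
#' individual id, sire, dam, sex, phenotype; then two allele tokens per SNP)
#' together with its MAP file and recodes allele pairs to B-allele dosage.
#'
#' The MAP file may carry four columns (chr, snp, cM, bp) or six, where the
#' fifth column names allele B and the sixth allele A. When the MAP does not
#' dictate alleles, B is the lexicographically later allele observed at that
#' SNP (a stable labelling that affects no downstream statistic, all of
#' which are orientation-symmetric or defined per SNP); a SNP with a single
#' observed allele codes it as A, i.e. dosage 0. "0" denotes a
#' missing allele; the pair "0 0" becomes a missing call. SNPs are sorted by
#' (chromosome, position) on load.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [genotype_dataset()] with `sire`, `dam` and `sex` filled from
#'   the PED columns ("0" read as absent); `yob` and `region` are `NA` and
#'   can be attached with [set_sample_meta()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) < 4) stop("MAP file needs at least 4 columns")
  map <- data.frame(snp = map_raw[[2]], chr = map_raw[[1]],
                    pos = as.numeric(map_raw[[4]]),
                    stringsAsFactors = FALSE)
  map$allele_b <- if (ncol(map_raw) >= 6) map_raw[[5]] else NA_character_
  map$allele_a <- if (ncol(map_raw) >= 6) map_raw[[6]] else NA_character_
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ids <- character(n)
  sire <- dam <- character(n)
  sex <- integer(n)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      stop("PED line ", i, " has ", length(tok), " fields, expected ",
           6 + 2 * m)
    }
    ids[i] <- tok[2]
    sire[i] <- tok[3]
    dam[i] <- tok[4]
    sex[i] <- suppressWarnings(as.integer(tok[5]))
    a1[i, ] <- tok[seq(7, by = 2, length.out = m)]
    a2[i, ] <- tok[seq(8, by = 2, length.out = m)]
  }
  if (anyDuplicated(ids)) {
    stop("duplicated sample id in PED: ", ids[anyDuplicated(ids)])
  }

  calls <- matrix(NA_integer_, n, m, dimnames = list(ids, map$snp))
  for (j in seq_len(m)) {
    obs <- setdiff(unique(c(a1[, j], a2[, j])), "0")
    declared <- c(map$allele_b[j], map$allele_a[j])
    declared <- declared[!is.na(declared) & declared != "0"]
    alleles <- union(declared, obs)
    if (length(alleles) > 2) {
      stop("SNP ", map$snp[j], " has more than two alleles: ",
           paste(sort(alleles), collapse = "/"))
    }
    if (!is.na(map$allele_b[j]) && map$allele_b[j] != "0") {
      b <- map$allele_b[j]
      a <- if (!is.na(map$allele_a[j]) && map$allele_a[j] != "0")
        map$allele_a[j] else setdiff(alleles, b)[1]
    } else if (length(alleles) >= 2) {
      srt <- sort(alleles)                 # B = lexicographically later
      b <- srt[2]
      a <- srt[1]
    } else {
      # monomorphic with no declared alleles: the observed allele is A
      a <- if (length(alleles)) alleles[1] else NA_character_
      b <- NA_character_
    }
    map$allele_b[j] <- if (is.na(b)) NA_character_ else b
    map$allele_a[j] <- if (length(a) && !is.na(a)) a else NA_character_
    ok <- a1[, j] != "0" & a2[, j] != "0"
    calls[ok, j] <- if (is.na(b)) 0L else
      (a1[ok, j] == b) + (a2[ok, j] == b)
  }

  meta <- data.frame(id = ids,
                     sire = ifelse(sire == "0", NA_character_, sire),
                     dam = ifelse(dam == "0", NA_character_, dam),
                     sex = sex, yob = NA_integer_, region = NA_character_,
                     stringsAsFactors = FALSE)
  genotype_dataset(calls, map, meta)
}

#' Write a genotype dataset as PLINK text PED/MAP
#'
#' Produces the six-column MAP dialect read back by [read_plink_text()]
#' (chr, snp, 0 cM, bp, allele B, allele A) and a PED file with missing
#' calls written as "0 0". A dataset with zero samples yields an empty PED
#' and a complete MAP.
#'
#' @param dataset A `GenotypeDataset`.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(dataset, ped_path, map_path) {
  map <- dataset$map
  ab <- fill_allele_labels(map)
  map_lines <- paste(map$chr, map$snp, 0, format_bp(map$pos),
                     ab$b, ab$a)
  ok <- tryCatch({
    writeLines(map_lines, map_path)
    TRUE
  }, error = function(e) stop("cannot write MAP file: ", conditionMessage(e)))

  calls <- dataset$calls
  meta <- dataset$meta
  n <- nrow(calls)
  ped_lines <- character(n)
  tok_a <- ab$a
  tok_b <- ab$b
  for (i in seq_len(n)) {
    g <- calls[i, ]
    h1 <- ifelse(is.na(g), "0", ifelse(g >= 1, tok_b, tok_a))
    h2 <- ifelse(is.na(g), "0", ifelse(g == 2, tok_b, tok_a))
    geno <- as.vector(rbind(h1, h2))
    ped_lines[i] <- paste(c("FAM1", meta$id[i],
                            ifelse(is.na(meta$sire[i]), "0", meta$sire[i]),
                            ifelse(is.na(meta$dam[i]), "0", meta$dam[i]),
                            ifelse(is.na(meta$sex[i]), 0, meta$sex[i]),
                            -9, geno), collapse = " ")
  }
  tryCatch(writeLines(ped_lines, ped_path),
           error = function(e) stop("cannot write PED file: ",
                                    conditionMessage(e)))
  invisible(c(ped = ped_path, map = map_path))
}

# A/B labels for output; synthetic datasets without declared alleles get A/B.
fill_allele_labels <- function(map) {
  a <- map$allele_a
  b <- map$allele_b
  a[is.na(a) | a == "0"] <- "A"
  b[is.na(b) | b == "0"] <- "B"
  list(a = a, b = b)
}

format_bp <- function(pos) format(pos, scientific = FALSE, trim = TRUE)

#' Write a genotype dataset in GENEPOP format
#'
#' Two-digit allele coding: allele A is "01", allele B "02"; a heterozygote
#' is always written "0102" and a missing call "0000". Samples are grouped
#' into populations separated by "Pop" lines.
#'
#' @param dataset A `GenotypeDataset`.
#' @param path Output path.
#' @param pops Factor or character vector of population labels, one per
#'   sample in dataset order (or named by sample id).
#' @param title Title line written at the top of the file.
#' @return Invisibly, `path`.
#' @export
write_genepop <- function(dataset, path, pops,
                          title = "eqpopgen genotype export") {
  calls <- dataset$calls
  n <- nrow(calls)
  if (length(pops) != n) stop("pops must have one label per sample")
  if (!is.null(names(pops))) pops <- pops[rownames(calls)]
  pops <- factor(pops, levels = unique(as.character(pops)))
  code <- c(`0` = "0101", `1` = "0102", `2` = "0202")
  lines <- c(title, dataset$map$snp)
  for (lev in levels(pops)) {
    lines <- c(lines, "Pop")
    for (i in which(pops == lev)) {
      g <- calls[i, ]
      gstr <- ifelse(is.na(g), "0000", code[as.character(g)])
      lines <- c(lines, paste0(rownames(calls)[i], " ,  ",
                               paste(gstr, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation from a BED file
#'
#' BED uses half-open 0-based intervals `[start, end)`; coordinates are
#' converted to 1-based inclusive `[start + 1, end]` to match the SNP map
#' convention used throughout the pipeline. Requires BED3 plus a name
#' column. The returned table is sorted by (chromosome, start).
#'
#' @param bed_path Path to a BED file with at least four columns.
#' @return Data frame with columns `gene`, `chr`, `start`, `end` (1-based
#'   inclusive bp).
#' @export
read_gene_annotation <- function(bed_path) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(gene = character(), chr = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  tok <- strsplit(trimws(lines), "[ \t]+")
  nc <- lengths(tok)
  if (any(nc < 4)) {
    stop("BED line ", which(nc < 4)[1], " has fewer than 4 columns")
  }
  chr <- vapply(tok, `[`, "", 1)
  start0 <- as.numeric(vapply(tok, `[`, "", 2))
  end0 <- as.numeric(vapply(tok, `[`, "", 3))
  gene <- vapply(tok, `[`, "", 4)
  bad <- which(end0 <= start0)
  if (length(bad)) {
    stop("BED line ", bad[1], " (", gene[bad[1]],
         "): end <= start is not a valid half-open interval")
  }
  tab <- data.frame(gene = gene, chr = chr, start = start0 + 1, end = end0,
                    stringsAsFactors = FALSE)
  tab <- tab[order(chr_sort_key(tab$chr), tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-SNP B-allele frequencies
#'
#' @param dataset A `GenotypeDataset`.
#' @param sample_subset Optional character vector of sample ids (or
#'   logical/integer index); defaults to all samples.
#' @return Data frame with one row per SNP: `snp`, `p` (frequency of allele
#'   B, `p = (2 n_BB + n_AB) / (2 n)`), `n` (non-missing sample count) and
#'   `no_calls` (`TRUE` where `n == 0`, with `p` set to `NA`).
#' @export
allele_frequencies <- function(dataset, sample_subset = NULL) {
  calls <- dataset$calls
  if (!is.null(sample_subset)) {
    idx <- resolve_index(sample_subset, rownames(calls), "sample")
    if (!length(idx)) stop("sample_subset is empty")
    calls <- calls[idx, , drop = FALSE]
  }
  n <- colSums(!is.na(calls))
  s <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n > 0, s / (2 * n), NA_real_)
  data.frame(snp = dataset$map$snp, p = unname(p), n = unname(n),
             no_calls = unname(n == 0), stringsAsFactors = FALSE)
}
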