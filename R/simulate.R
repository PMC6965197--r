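#' Simulation configuration
#'
#' Bundles every knob of the synthetic-genotype generators. Defaults mirror
#' the study system the pipeline targets: 31 autosomes totalling
#' 2,242,960 kb (the horse autosomal genome), SNP-array-scale marker
#' panels with MAF above 0.05, half-sib families of 20 offspring per sire,
#' and multi-year cohorts bred with a programmable sire-popularity skew.
#'
#' @param seed Integer seed; a fixed seed gives identical output.
#' @param n_chromosomes Number of autosomes (default 31).
#' @param genome_kb Total autosomal length in kb (default 2,242,960).
#' @param n_snps Marker panel size after MAF thinning (default 5000).
#' @param maf_floor Minimum pooled MAF retained after the post-burn-in
#'   thinning step (default 0.05).
#' @param n_per_pop Diploid census size per population for the
#'   two-population simulator (default 100).
#' @param sample_per_pop Diploid individuals sampled from each population
#'   into the returned datasets (default `n_per_pop`, i.e. the whole
#'   population; a genotyped study cohort is normally a subset of the
#'   breeding population).
#' @param generations Generations of drift/selection after the populations
#'   split (default 40).
#' @param selected_loci Indices (into the thinned panel; loci are
#'   guaranteed retained) of loci under genic selection in the selected
#'   population.
#' @param s Selection coefficient per selected locus (recycled); sampling
#'   weight is `(1 + s)` per copy of the selected allele.
#' @param selected_start_freq Initial frequency of the selected allele
#'   (default 0.1, a realistic standing variant at sweep onset).
#' @param morgans_per_100mb Uniform recombination rate (default 1 Morgan
#'   per 100 Mb, a horse-scale approximation).
#' @param n_ancestral_haplotypes Size of the common ancestral haplotype
#'   pool both populations descend from (default 60, a founder-bottleneck
#'   scale typical of closed domestic breeds); the pool supplies the
#'   background linkage disequilibrium a selective sweep rides on.
#' @param retry_max Whole-simulation redraws allowed when a selected allele
#'   is lost before the final generation (default 20).
#' @param n_offspring,error_rate,missing_rate Half-sib family settings:
#'   offspring per sire, symmetric genotype-flip error rate, missing-call
#'   rate.
#' @param years Cohort years to simulate (default 1996:2007).
#' @param n_founders Founder individuals preceding the first cohort year
#'   (default 40).
#' @param n_per_year Offspring bred per cohort year (default 4000; a
#'   large commercial breed produces thousands of foals per year, which
#'   keeps random drift negligible over a two-decade span).
#' @param sample_per_year Individuals genotyped per cohort year (default
#'   60); only these enter the returned dataset, as in a study that
#'   samples a large breeding population.
#' @param skew_start,skew_end Fraction of matings allocated to the elite
#'   sire pool in the first and last cohort year; intermediate years are
#'   interpolated linearly. `skew_start = skew_end = 0` is uniform random
#'   mating.
#' @param n_elite Number of elite ("popular") sires per year (default 2).
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 31L, genome_kb = 2242960,
                       n_snps = 5000L, maf_floor = 0.05, n_per_pop = 100L,
                       sample_per_pop = NULL,
                       generations = 40L, selected_loci = integer(0),
                       s = 0.1, selected_start_freq = 0.1,
                       morgans_per_100mb = 1,
                       n_ancestral_haplotypes = 60L, retry_max = 20L,
                       n_offspring = 20L, error_rate = 0, missing_rate = 0,
                       years = 1996:2007, n_founders = 400L,
                       n_per_year = 4000L, sample_per_year = 60L,
                       skew_start = 0, skew_end = 0.6,
                       n_elite = 4L) {
  cfg <- as.list(environment())
  if (is.null(cfg$sample_per_pop)) cfg$sample_per_pop <- cfg$n_per_pop
  stopifnot(cfg$n_chromosomes >= 1, cfg$genome_kb > 0, cfg$n_snps >= 2,
            cfg$maf_floor >= 0, cfg$maf_floor < 0.5,
            cfg$sample_per_pop <= cfg$n_per_pop,
            all(cfg$selected_loci >= 1),
            all(cfg$selected_loci <= cfg$n_snps))
  class(cfg) <- "SimulationConfig"
  cfg
}

# Chromosome lengths follow a fixed declining profile (largest ~6x the
# smallest, horse-like) rescaled to sum to genome_kb.
chromosome_lengths_kb <- function(n_chromosomes, genome_kb) {
  w <- seq(3, 0.5, length.out = n_chromosomes)
  round(genome_kb * w / sum(w))
}

# Uniform SNP positions per chromosome (bp), counts proportional to length.
draw_snp_map <- function(n_snps, n_chromosomes, genome_kb,
                         prefix = "snp") {
  len_kb <- chromosome_lengths_kb(n_chromosomes, genome_kb)
  counts <- pmax(1L, round(n_snps * len_kb / sum(len_kb)))
  while (sum(counts) != n_snps) {
    i <- if (sum(counts) > n_snps) which.max(counts) else which.min(counts)
    counts[i] <- counts[i] + sign(n_snps - sum(counts))
  }
  chr <- rep(as.character(seq_len(n_chromosomes)), counts)
  pos <- unlist(lapply(seq_len(n_chromosomes), function(c) {
    p <- sort(sample.int(len_kb[c] * 1000L, counts[c]))
    p
  }))
  map <- data.frame(snp = paste0(prefix, seq_len(n_snps)), chr = chr,
                    pos = pos, allele_a = "A", allele_b = "B",
                    stringsAsFactors = FALSE)
  attr(map, "chr_len_kb") <- len_kb
  map
}

# Precomputed recombination geometry for fast gamete assembly.
gamete_geometry <- function(map, morgans_per_100mb = 1) {
  chr_rle <- rle(map$chr)
  nchr <- length(chr_rle$values)
  chr_len_kb <- attr(map, "chr_len_kb")
  if (is.null(chr_len_kb)) {
    chr_len_kb <- tapply(map$pos, factor(map$chr, levels = chr_rle$values),
                         max) / 1000
  }
  morgans <- as.numeric(chr_len_kb) * 1000 * morgans_per_100mb / 1e8
  offset <- cumsum(c(0, morgans))[seq_len(nchr)]
  cum_m <- map$pos * morgans_per_100mb / 1e8 +
    rep(offset, chr_rle$lengths)
  chr_starts <- cumsum(c(1L, chr_rle$lengths))[seq_len(nchr)]
  list(cum_m = cum_m, chr_lengths = chr_rle$lengths,
       chr_starts = chr_starts, total_morgans = sum(morgans),
       n_chr = nchr)
}

# Advance a loci-major haplotype matrix (S x 2N, columns 2i-1 and 2i =
# individual i) one Wright-Fisher generation. `weights` are per-individual
# sampling weights.
wf_generation <- function(H, geom, weights = NULL) {
  N <- ncol(H) / 2
  mothers <- sample.int(N, N, replace = TRUE, prob = weights)
  fathers <- sample.int(N, N, replace = TRUE, prob = weights)
  gametes_cpp(H, as.integer(rbind(mothers, fathers)), geom$cum_m,
              geom$chr_starts, geom$total_morgans)
}

haplos_to_dataset <- function(H, map, prefix) {
  n <- nrow(H) / 2
  g <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
    H[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(g) <- paste0(prefix, seq_len(n))
  genotype_dataset(g, map)
}

#' Two-population Wright-Fisher simulation with optional sweeps
#'
#' A common ancestral haplotype pool (linkage equilibrium at ancestral
#' frequencies drawn above the MAF floor) splits into a "selected" and a
#' "reference" population which then drift independently for
#' `config$generations` generations with recombination. Loci listed in
#' `config$selected_loci` evolve under genic selection in the selected
#' population only: parents are sampled with weight `(1 + s)` per copy of
#' the selected (B) allele. If a selected allele is lost before the final
#' generation the whole simulation is redrawn, up to `config$retry_max`
#' times.
#'
#' After the burn-in, loci whose pooled MAF falls below `config$maf_floor`
#' are thinned out and the panel is trimmed to `config$n_snps` loci
#' (selected loci are always retained), emulating the MAF screen every
#' array panel has seen.
#'
#' @param config A [sim_config()].
#' @return A list: `selected` and `reference` (`GenotypeDataset`s),
#'   `haplotypes` (list of two 2N-by-SNP 0/1 matrices, phased), `map`, and
#'   `truth` (data frame of selected-locus SNP ids, positions, `s`, and
#'   final allele frequencies in both populations).
#' @export
simulate_wright_fisher <- function(config = sim_config()) {
  stopifnot(config$n_per_pop >= 20, config$generations >= 1)
  set.seed(config$seed)
  for (attempt in seq_len(config$retry_max)) {
    res <- wf_attempt(config)
    if (!is.null(res)) return(res)
  }
  stop("selected allele lost in all ", config$retry_max, " redraws; ",
       "increase selected_start_freq, s or n_per_pop")
}

wf_attempt <- function(config) {
  n_draw <- max(config$n_snps + 20L, ceiling(config$n_snps * 1.3))
  map <- draw_snp_map(n_draw, config$n_chromosomes, config$genome_kb)
  geom <- gamete_geometry(map, config$morgans_per_100mb)
  lo <- min(config$maf_floor + 0.1, 0.45)
  p0 <- stats::runif(n_draw, lo, 1 - lo)

  # selected loci are placed at scaled positions of the eventual panel;
  # explicit draw indices are reserved for them.
  nsel <- length(config$selected_loci)
  sel_draw <- integer(0)
  svec <- numeric(0)
  if (nsel > 0) {
    sel_draw <- round(config$selected_loci * n_draw / config$n_snps)
    sel_draw <- pmin(pmax(sel_draw, 1L), n_draw)
    svec <- rep_len(config$s, nsel)
  }

  # common ancestral haplotype pool: K distinct founder haplotypes that
  # both populations bootstrap from, the source of background LD.
  # Haplotypes are held loci-major (one column per haplotype) so gamete
  # assembly copies contiguous memory.
  K <- config$n_ancestral_haplotypes
  pool <- matrix(stats::rbinom(n_draw * K, 1L, p0), n_draw, K)
  if (nsel > 0) {
    ncar <- max(1L, round(K * config$selected_start_freq))
    for (d in sel_draw) {
      pool[d, ] <- 0L
      pool[d, sample.int(K, ncar)] <- 1L
    }
  }
  n2 <- 2L * config$n_per_pop
  H_sel <- pool[, sample.int(K, n2, replace = TRUE), drop = FALSE]
  H_ref <- pool[, sample.int(K, n2, replace = TRUE), drop = FALSE]
  if (nsel > 0) {
    # both descendant populations must start segregating at selected loci
    if (any(rowSums(H_sel[sel_draw, , drop = FALSE]) == 0) ||
        any(rowSums(H_ref[sel_draw, , drop = FALSE]) == 0)) {
      return(NULL)
    }
  }

  odd <- seq(1L, n2, 2L)
  for (g in seq_len(config$generations)) {
    w <- NULL
    if (nsel > 0) {
      dose <- H_sel[sel_draw, odd, drop = FALSE] +
        H_sel[sel_draw, odd + 1L, drop = FALSE]
      w <- as.vector(exp(crossprod(dose, log(1 + svec))))
    }
    H_sel <- wf_generation(H_sel, geom, w)
    H_ref <- wf_generation(H_ref, geom, NULL)
    if (nsel > 0 && any(rowSums(H_sel[sel_draw, , drop = FALSE]) == 0)) {
      return(NULL)            # selected allele lost: redraw
    }
  }

  pooled_maf <- {
    p <- (rowSums(H_sel) + rowSums(H_ref)) / (2 * n2)
    pmin(p, 1 - p)
  }
  avail <- setdiff(which(pooled_maf >= config$maf_floor), sel_draw)
  n_fill <- config$n_snps - length(sel_draw)
  if (length(avail) < n_fill) {
    # top up with the highest-MAF remainder so dimensions match the config
    backup <- setdiff(order(pooled_maf, decreasing = TRUE),
                      c(avail, sel_draw))
    avail <- c(avail, backup[seq_len(n_fill - length(avail))])
  } else if (length(avail) > n_fill) {
    # thin evenly across the map so the panel spans every chromosome
    avail <- sort(avail)[unique(round(seq(1, length(avail),
                                          length.out = n_fill)))]
    while (length(avail) < n_fill) {
      extra <- setdiff(which(pooled_maf >= config$maf_floor),
                       c(avail, sel_draw))
      avail <- c(avail, extra[seq_len(n_fill - length(avail))])
    }
  }
  keep <- sort(unique(c(sel_draw, avail)))

  map2 <- map[keep, , drop = FALSE]
  map2$snp <- paste0("snp", seq_len(nrow(map2)))
  rownames(map2) <- NULL
  attr(map2, "chr_len_kb") <- attr(map, "chr_len_kb")
  H_sel <- H_sel[keep, , drop = FALSE]
  H_ref <- H_ref[keep, , drop = FALSE]
  ss <- config$sample_per_pop
  if (is.null(ss)) ss <- config$n_per_pop
  if (ss < config$n_per_pop) {
    # genotyped cohort: a random subset of the census population
    take <- function(H) {
      idx <- sort(sample.int(config$n_per_pop, ss))
      H[, as.vector(rbind(2L * idx - 1L, 2L * idx)), drop = FALSE]
    }
    H_sel <- take(H_sel)
    H_ref <- take(H_ref)
  }
  # public layout: haplotypes in rows, SNPs in columns
  H_sel <- t(H_sel)
  H_ref <- t(H_ref)
  colnames(H_sel) <- colnames(H_ref) <- map2$snp

  truth <- NULL
  if (nsel > 0) {
    idx <- match(sel_draw, keep)
    truth <- data.frame(snp = map2$snp[idx], index = idx,
                        chr = map2$chr[idx], pos = map2$pos[idx], s = svec,
                        p_selected = colMeans(H_sel[, idx, drop = FALSE]),
                        p_reference = colMeans(H_ref[, idx, drop = FALSE]),
                        stringsAsFactors = FALSE)
  }
  list(selected = haplos_to_dataset(H_sel, map2, "SEL"),
       reference = haplos_to_dataset(H_ref, map2, "REF"),
       haplotypes = list(selected = H_sel, reference = H_ref),
       map = map2, truth = truth)
}

#' Simulate a Wright-Fisher population at unlinked loci
#'
#' Forward simulation of a diploid random-mating population of constant
#' size `ne` at free-recombining loci: every locus of a gamete picks one
#' of the parent's two alleles by a fair independent coin. After
#' `generations` generations (enough for the drift component of
#' between-locus association to equilibrate at roughly `1/(3 Ne)`),
#' `sample_size` individuals are drawn. This is the ground-truth generator
#' for the LD method of effective population size, where linkage would
#' otherwise inflate the signal; the returned map spreads loci over
#' `n_chromosomes` labels so that inter-chromosomal pairing is available.
#'
#' @param ne True (census = effective) population size in diploids.
#' @param n_snps Number of unlinked loci.
#' @param sample_size Individuals sampled into the returned dataset.
#' @param generations Generations simulated (default 20).
#' @param n_chromosomes Chromosome labels for the map (default 20).
#' @param maf_range Ancestral frequency range (default c(0.15, 0.85)).
#' @return A `GenotypeDataset` of `sample_size` individuals.
#' @export
simulate_wf_unlinked <- function(ne, n_snps, sample_size,
                                 generations = 20L, n_chromosomes = 20L,
                                 maf_range = c(0.15, 0.85)) {
  N <- ne
  if (sample_size > N) stop("sample_size cannot exceed ne")
  L <- n_snps
  p0 <- stats::runif(L, maf_range[1], maf_range[2])
  H <- matrix(stats::rbinom(2L * N * L, 1L, rep(p0, each = 2L * N)),
              2L * N, L)
  odd <- seq(1L, 2L * N, by = 2L)
  for (g in seq_len(generations)) {
    moms <- sample.int(N, N, replace = TRUE)
    dads <- sample.int(N, N, replace = TRUE)
    mk <- matrix(stats::runif(N * L) < 0.5, N, L)
    gm <- H[2L * moms - 1L, , drop = FALSE]
    tmp <- H[2L * moms, , drop = FALSE]
    gm[mk] <- tmp[mk]
    fk <- matrix(stats::runif(N * L) < 0.5, N, L)
    gf <- H[2L * dads - 1L, , drop = FALSE]
    tmp <- H[2L * dads, , drop = FALSE]
    gf[fk] <- tmp[fk]
    H[odd, ] <- gm
    H[odd + 1L, ] <- gf
  }
  idx <- sample.int(N, sample_size)
  G <- H[2L * idx - 1L, , drop = FALSE] + H[2L * idx, , drop = FALSE]
  rownames(G) <- paste0("S", seq_len(sample_size))
  chr <- rep(as.character(seq_len(n_chromosomes)), length.out = L)
  pos <- stats::ave(seq_len(L), chr, FUN = seq_along) * 1000
  genotype_dataset(G, data.frame(snp = paste0("s", seq_len(L)), chr = chr,
                                 pos = pos, stringsAsFactors = FALSE))
}

#' Simulate a half-sib family from a known sire
#'
#' Each offspring receives one sire allele by a fair Mendelian draw and one
#' dam allele drawn Bernoulli(p) per SNP, i.e. dams are random under
#' Hardy-Weinberg at the population frequencies. A genotyping error flips a
#' call to a uniformly chosen different code with probability `error_rate`;
#' missingness is applied last.
#'
#' @param sire_genotype Integer vector of sire dosage codes (0/1/2, `NA`
#'   allowed: offspring inherit a population allele there too, and the
#'   locus carries no sire information).
#' @param freqs Numeric vector of B-allele frequencies per SNP, or an
#'   [allele_frequencies()] table.
#' @param n_offspring Number of offspring (default 20).
#' @param error_rate,missing_rate Per-call error and missing probabilities.
#' @param map Optional SNP map for the returned dataset; a uniform
#'   single-chromosome map is generated when omitted.
#' @return A list: `offspring` (a `GenotypeDataset` whose meta `sire`
#'   column is "SIRE"), `sire` (the true sire vector).
#' @export
simulate_half_sib_family <- function(sire_genotype, freqs,
                                     n_offspring = 20L, error_rate = 0,
                                     missing_rate = 0, map = NULL) {
  if (is.data.frame(freqs)) freqs <- freqs$p
  m <- length(sire_genotype)
  if (length(freqs) != m) stop("freqs must cover all SNPs")
  n <- n_offspring
  sire <- matrix(rep(sire_genotype, each = n), n, m)
  sire_allele <- matrix(0L, n, m)
  het <- !is.na(sire) & sire == 1L
  hom2 <- !is.na(sire) & sire == 2L
  sire_allele[het] <- stats::rbinom(sum(het), 1L, 0.5)
  sire_allele[hom2] <- 1L
  nas <- is.na(sire)
  if (any(nas)) {
    sire_allele[nas] <- stats::rbinom(sum(nas), 1L,
                                      rep(freqs, each = n)[nas])
  }
  dam_allele <- matrix(stats::rbinom(n * m, 1L, rep(freqs, each = n)), n, m)
  g <- sire_allele + dam_allele
  if (error_rate > 0) {
    err <- stats::runif(n * m) < error_rate
    if (any(err)) {
      shift <- sample(1:2, sum(err), replace = TRUE)
      g[err] <- (g[err] + shift) %% 3L
    }
  }
  if (missing_rate > 0) g[stats::runif(n * m) < missing_rate] <- NA_integer_
  if (is.null(map)) {
    map <- data.frame(snp = paste0("snp", seq_len(m)), chr = "1",
                      pos = seq_len(m) * 1000, stringsAsFactors = FALSE)
  }
  rownames(g) <- paste0("OFF", seq_len(n))
  ds <- genotype_dataset(g, map)
  ds$meta$sire <- "SIRE"
  list(offspring = ds, sire = sire_genotype)
}

#' Simulate temporal cohorts with rising sire-popularity skew
#'
#' Starting from an unrelated founder generation, one cohort of offspring
#' is bred per year. For each mating the dam is drawn uniformly from the
#' previous cohort's females; the sire is drawn from the elite pool (the
#' first `n_elite` males of the previous cohort) with probability equal to
#' that year's skew, otherwise uniformly from all males. A rising skew
#' concentrates paternity, shrinks the effective number of sires and drives
#' expected heterozygosity down over years; a zero skew is the
#' random-mating null. Haplotypes recombine as in
#' [simulate_wright_fisher()], so inbreeding manifests as genuine runs of
#' homozygosity.
#'
#' @param config A [sim_config()]; fields used: `seed`, `n_snps`,
#'   `n_chromosomes`, `genome_kb`, `maf_floor`, `morgans_per_100mb`,
#'   `years`, `n_founders`, `n_per_year`, `sample_per_year`,
#'   `skew_start`, `skew_end`, `n_elite`.
#' @return A list: `dataset` (a `GenotypeDataset` of the genotyped cohort
#'   samples with `sire`, `dam`, `sex`, `yob` and `region` metadata) and
#'   `pedigree` (the true pedigree of every bred individual, genotyped or
#'   not, including founders).
#' @export
simulate_temporal_cohorts <- function(config = sim_config()) {
  years <- config$years
  if (length(years) < 2) stop("need at least two cohort years")
  set.seed(config$seed)
  map <- draw_snp_map(config$n_snps, config$n_chromosomes,
                      config$genome_kb)
  geom <- gamete_geometry(map, config$morgans_per_100mb)
  m <- config$n_snps
  lo <- min(config$maf_floor + 0.1, 0.45)
  p0 <- stats::runif(m, lo, 1 - lo)
  skews <- seq(config$skew_start, config$skew_end,
               length.out = length(years))

  nf <- config$n_founders
  # loci-major haplotypes: one column per founder haplotype
  H <- matrix(stats::rbinom(m * 2L * nf, 1L, p0), m, 2L * nf)
  ids <- paste0("F", seq_len(nf))
  sex <- rep(c(1L, 2L), length.out = nf)      # 1 = male, 2 = female
  pedigree <- data.frame(id = ids, sire = NA_character_,
                         dam = NA_character_, sex = sex,
                         yob = min(years) - 1L, stringsAsFactors = FALSE)
  all_calls <- NULL
  all_meta <- NULL

  for (t in seq_along(years)) {
    males <- which(sex == 1L)
    females <- which(sex == 2L)
    if (!length(males) || !length(females)) {
      stop("a cohort ran out of one sex; increase n_per_year")
    }
    elite <- males[seq_len(min(config$n_elite, length(males)))]
    n <- config$n_per_year
    use_elite <- stats::runif(n) < skews[t]
    sires <- ifelse(use_elite,
                    elite[sample.int(length(elite), n, replace = TRUE)],
                    males[sample.int(length(males), n, replace = TRUE)])
    dams <- females[sample.int(length(females), n, replace = TRUE)]
    newH <- gametes_cpp(H, as.integer(rbind(sires, dams)), geom$cum_m,
                        geom$chr_starts, geom$total_morgans)
    new_ids <- paste0("Y", years[t], "_", seq_len(n))
    new_sex <- rep(c(1L, 2L), length.out = n)
    ped_t <- data.frame(id = new_ids, sire = ids[sires], dam = ids[dams],
                        sex = new_sex, yob = years[t],
                        stringsAsFactors = FALSE)
    pedigree <- rbind(pedigree, ped_t)
    # genotype a yearly sample of the cohort
    take <- sort(sample.int(n, min(config$sample_per_year, n)))
    g <- t(newH[, 2L * take - 1L, drop = FALSE] +
             newH[, 2L * take, drop = FALSE])
    rownames(g) <- new_ids[take]
    all_calls <- rbind(all_calls, g)
    meta_t <- cbind(ped_t[take, , drop = FALSE], region = "SIM",
                    stringsAsFactors = FALSE)
    all_meta <- rbind(all_meta, meta_t)
    H <- newH
    ids <- new_ids
    sex <- new_sex
  }
  ds <- genotype_dataset(all_calls, map,
                         all_meta[, c("id", "sire", "dam", "sex", "yob",
                                      "region")])
  list(dataset = ds, pedigree = pedigree)
}

#' Implant an autozygous segment into one individual
#'
#' Forces every call of `individual` inside the interval homozygous by
#' copying one allele of each heterozygous call over the other (a fair coin
#' decides which, emulating which haplotype is duplicated). Homozygous and
#' missing calls are untouched.
#'
#' @param dataset A `GenotypeDataset`.
#' @param individual Sample id.
#' @param chromosome Chromosome label.
#' @param start_kb,end_kb Interval bounds in kb (inclusive).
#' @return A list: `dataset` (modified) and `interval` (a one-row record of
#'   what was implanted, including the SNP count inside).
#' @export
implant_roh <- function(dataset, individual, chromosome, start_kb,
                        end_kb) {
  i <- match(individual, rownames(dataset$calls))
  if (is.na(i)) stop("unknown sample id: ", individual)
  inside <- dataset$map$chr == as.character(chromosome) &
    dataset$map$pos >= start_kb * 1000 & dataset$map$pos <= end_kb * 1000
  if (!any(inside)) {
    stop("interval [", start_kb, ", ", end_kb, "] kb on chromosome ",
         chromosome, " contains no SNPs")
  }
  g <- dataset$calls[i, inside]
  het <- !is.na(g) & g == 1L
  g[het] <- 2L * stats::rbinom(sum(het), 1L, 0.5)
  dataset$calls[i, inside] <- g
  list(dataset = dataset,
       interval = data.frame(id = individual,
                             chr = as.character(chromosome),
                             start_kb = start_kb, end_kb = end_kb,
                             n_snps = sum(inside),
                             stringsAsFactors = FALSE))
}
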