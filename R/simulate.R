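#' Simulation configuration
#'
#' Parameters of the structured-population and amplicon-depth simulator.
#' Defaults describe a panel of inbred crop varieties split into four
#' subpopulations of sizes 78/105/58/20 genotyped at 163 loci, with
#' strong differentiation (`fst_target = 0.4`), residual heterozygosity
#' 0.15, mean amplicon depth 2000x with heavy overdispersion (negative
#' binomial size 1.5, placing about 90% of records in the 100-5000x band),
#' per-read error 0.002 and 2% forced missingness.
#'
#' @param n_subpops Number of subpopulations.
#' @param subpop_sizes Integer vector of varieties per subpopulation.
#' @param n_loci Number of SNP loci.
#' @param fst_target Balding-Nichols divergence parameter in `[0, 1)`; 0
#'   makes every subpopulation frequency equal the ancestral frequency.
#' @param maf_range Range of the ancestral minor-allele frequency; ancestral
#'   frequencies are drawn uniformly on it and assigned to REF or ALT at
#'   random.
#' @param residual_het Residual heterozygosity of the nominally inbred
#'   lines, expressed as the probability of a heterozygous genotype at a
#'   locus with subpopulation frequency 0.5 (must be in `[0, 0.5]`).
#'   Implemented as an autozygosity model -- with probability
#'   `1 - 2 * residual_het` a locus is autozygous (a single allele draw,
#'   doubled), otherwise Hardy-Weinberg -- so allele frequencies are
#'   preserved exactly and the heterozygosity at frequency p is
#'   `4 * residual_het * p * (1 - p)`.
#' @param mean_depth Mean total read depth per variety x locus.
#' @param depth_dispersion Negative-binomial size parameter (smaller =
#'   more overdispersed).
#' @param error_rate Per-read probability of reporting the wrong allele.
#' @param missing_rate Probability that a record's depth is resampled below
#'   `min_major_depth`, forcing a missing call downstream.
#' @param min_major_depth The caller's depth floor that forced-missing
#'   records are pushed under (must match the calling thresholds in use).
#' @param n_chrom Number of chromosomes the loci are spread over.
#' @param seed Integer seed fixing the full output stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subpops = length(subpop_sizes),
                       subpop_sizes = c(78L, 105L, 58L, 20L),
                       n_loci = 163L,
                       fst_target = 0.4,
                       maf_range = c(0.1, 0.5),
                       residual_het = 0.15,
                       mean_depth = 2000,
                       depth_dispersion = 1.5,
                       error_rate = 0.002,
                       missing_rate = 0.02,
                       min_major_depth = 20L,
                       n_chrom = 7L,
                       seed = 1L) {
  cfg <- list(n_subpops = as.integer(n_subpops),
              subpop_sizes = as.integer(subpop_sizes),
              n_loci = as.integer(n_loci),
              fst_target = fst_target,
              maf_range = maf_range,
              residual_het = residual_het,
              mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              error_rate = error_rate,
              missing_rate = missing_rate,
              min_major_depth = as.integer(min_major_depth),
              n_chrom = as.integer(n_chrom),
              seed = as.integer(seed))
  if (cfg$n_subpops < 1L || length(cfg$subpop_sizes) != cfg$n_subpops ||
      any(cfg$subpop_sizes < 1L)) {
    stop("subpop_sizes must give one size >= 1 per subpopulation")
  }
  if (cfg$n_loci < 1L) stop("n_loci must be >= 1")
  if (cfg$fst_target < 0 || cfg$fst_target >= 1) {
    stop("fst_target must be in [0, 1)")
  }
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || diff(cfg$maf_range) < 0) {
    stop("maf_range must be an increasing range within (0, 0.5]")
  }
  for (p in c("error_rate", "missing_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$residual_het < 0 || cfg$residual_het > 0.5) {
    stop("residual_het must be in [0, 0.5]")
  }
  if (cfg$mean_depth <= 0 || cfg$depth_dispersion <= 0) {
    stop("mean_depth and depth_dispersion must be positive")
  }
  if (cfg$min_major_depth < 1L) stop("min_major_depth must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate a structured population of inbred varieties
#'
#' Ancestral allele frequencies are drawn from `maf_range`; subpopulation
#' frequencies diverge around them under the Balding-Nichols model with
#' parameter `fst_target` (frequency variance `F p (1 - p)` across
#' subpopulations). Varieties are inbred lines drawn under an autozygosity
#' model controlled by `residual_het` (see [sim_config()]), which preserves
#' subpopulation allele frequencies exactly. A random reference genome is built
#' around the loci (sites spaced >= 150 bp, >= 100 bp from chromosome ends)
#' so flank-based panel filters can run on simulated data.
#'
#' @param cfg A [sim_config].
#' @return An object of class `truth_set`: list with `genome`
#'   ([reference_genome]), `variants` ([variant_table]), `truth`
#'   ([genotype_matrix] of true genotypes), `subgroups` (named character
#'   vector), `ancestral_freq` (REF-allele frequency per locus) and
#'   `subpop_freq` (loci x subpops matrix of REF-allele frequencies).
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_loci <- cfg$n_loci
  n_var <- sum(cfg$subpop_sizes)
  pops <- paste0("Pop", seq_len(cfg$n_subpops))
  subgroups <- setNames(rep(pops, cfg$subpop_sizes),
                        sprintf("V%03d", seq_len(n_var)))
  varieties <- names(subgroups)

  # genome: loci spread over chromosomes, spaced >= 150 bp, 100 bp margins
  per_chr <- diff(round(seq(0, n_loci, length.out = cfg$n_chrom + 1L)))
  chr_names <- paste0("chr", seq_len(cfg$n_chrom))
  seqs <- character(cfg$n_chrom)
  chrom <- character(0); pos <- integer(0)
  for (k in seq_len(cfg$n_chrom)) {
    nk <- per_chr[k]
    len <- max(2000L, 250L * nk + 400L)
    seqs[k] <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
    if (nk > 0L) {
      # evenly spaced anchors (step >= 250 bp) with +/- 40 bp jitter keep
      # inter-site distance > 150 bp and a 100 bp edge margin
      anchors <- if (nk == 1L) round(len / 2) else
        round(seq(150L, len - 150L, length.out = nk))
      p <- sort(pmin(pmax(anchors + sample(-40:40, nk, replace = TRUE),
                          101L), len - 100L))
      chrom <- c(chrom, rep(chr_names[k], nk))
      pos <- c(pos, p)
    }
  }
  names(seqs) <- chr_names
  genome <- reference_genome(seqs)

  ref <- substr_at(genome, chrom, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")

  # ancestral REF-allele frequency
  m <- runif(n_loci, cfg$maf_range[1L], cfg$maf_range[2L])
  p_anc <- ifelse(runif(n_loci) < 0.5, m, 1 - m)

  # Balding-Nichols subpopulation frequencies
  Fst <- cfg$fst_target
  subpop_freq <- matrix(NA_real_, n_loci, cfg$n_subpops,
                        dimnames = list(NULL, pops))
  for (s in seq_len(cfg$n_subpops)) {
    if (Fst == 0) {
      subpop_freq[, s] <- p_anc
    } else {
      subpop_freq[, s] <- rbeta(n_loci,
                                p_anc * (1 - Fst) / Fst,
                                (1 - p_anc) * (1 - Fst) / Fst)
    }
  }

  # genotypes: allele index 0 = REF, 1 = ALT
  a1 <- matrix(NA_integer_, n_loci, n_var)
  a2 <- a1
  # inbred-line genotypes via an autozygosity model: with probability
  # f_auto = 1 - 2 * residual_het the locus is autozygous (one allele draw,
  # doubled), otherwise two independent draws. Allele frequencies are
  # preserved exactly and P(het) = residual_het at a p = 0.5 locus.
  f_auto <- 1 - 2 * cfg$residual_het
  for (v in seq_len(n_var)) {
    s <- match(subgroups[v], pops)
    p <- subpop_freq[, s]
    auto <- runif(n_loci) < f_auto
    d1 <- ifelse(runif(n_loci) < p, 0L, 1L)
    d2 <- ifelse(runif(n_loci) < p, 0L, 1L)
    a1[, v] <- d1
    a2[, v] <- ifelse(auto, d1, d2)
  }

  ids <- sprintf("L%04d", seq_len(n_loci))
  # order sites by (chrom, pos) — already generated in order
  sites <- data.frame(id = ids, chrom = chrom, pos = pos,
                      ref = unname(ref), alt = unname(alt),
                      stringsAsFactors = FALSE)
  vt <- variant_table(sites, a1, a2, varieties, subgroups = subgroups)

  allele_chars <- rbind(unname(ref), unname(alt))
  g1 <- matrix(allele_chars[cbind(as.vector(a1) + 1L, rep(seq_len(n_loci), n_var))],
               n_loci, n_var)
  g2 <- matrix(allele_chars[cbind(as.vector(a2) + 1L, rep(seq_len(n_loci), n_var))],
               n_loci, n_var)
  calls <- matrix(format_call(as.vector(g1), as.vector(g2)), n_loci, n_var,
                  dimnames = list(ids, varieties))
  truth <- genotype_matrix(t(calls))

  structure(list(genome = genome, variants = vt, truth = truth,
                 subgroups = subgroups,
                 ancestral_freq = setNames(p_anc, ids),
                 subpop_freq = `rownames<-`(subpop_freq, ids),
                 config = cfg),
            class = "truth_set")
}

# vectorized single-base lookup
substr_at <- function(genome, chrom, pos) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- vapply(pos[i], function(p) substr(genome$sequences[[ch]], p, p), "")
  }
  setNames(out, paste0(chrom, ":", pos))
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Synthetic truth set:", nrow(x$truth), "varieties x", ncol(x$truth),
      "loci;", x$config$n_subpops, "subpopulations; fst_target",
      x$config$fst_target, "\n")
  invisible(x)
}

#' Simulate targeted-amplicon allele depths
#'
#' Total depth per variety x locus is negative-binomial (`mean_depth`,
#' `depth_dispersion`); reads then split binomially between the two true
#' alleles: p = 0.5 for a heterozygote, p = 1 - `error_rate` towards the
#' true allele for a homozygote. With probability `missing_rate` the total
#' depth is instead resampled uniformly below `min_major_depth`, forcing the
#' caller to emit a missing genotype.
#'
#' @param truth A `truth_set` from [simulate_population()].
#' @param cfg The same [sim_config] used to generate `truth` (defaults to
#'   the config stored in `truth`).
#' @return A `depth_table` data.frame (columns `variety`, `locus`, `allele`,
#'   `depth`) with two rows (REF and ALT allele) per variety x locus.
#' @export
simulate_depths <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "truth_set"), inherits(cfg, "sim_config"))
  if (ncol(truth$truth) != cfg$n_loci ||
      nrow(truth$truth) != sum(cfg$subpop_sizes)) {
    stop("truth set and sim_config disagree on dimensions")
  }
  set.seed(cfg$seed + 1L)
  varieties <- rownames(truth$truth)
  loci <- colnames(truth$truth)
  sites <- truth$variants$sites
  ref <- sites$ref[match(loci, sites$id)]
  alt <- sites$alt[match(loci, sites$id)]

  n <- length(varieties) * length(loci)
  variety <- rep(varieties, times = length(loci))
  locus <- rep(loci, each = length(varieties))
  g <- as.vector(truth$truth)  # column-major: variety fastest
  al <- split_calls(g)
  is_het <- !is.na(g) & al[, 1L] != al[, 2L]

  total <- rnbinom(n, size = cfg$depth_dispersion, mu = cfg$mean_depth)
  forced <- runif(n) < cfg$missing_rate
  total[forced] <- sample.int(cfg$min_major_depth, sum(forced),
                              replace = TRUE) - 1L

  ref_l <- rep(ref, each = length(varieties))
  alt_l <- rep(alt, each = length(varieties))
  hom_ref <- !is_het & !is.na(g) & al[, 1L] == ref_l
  p_ref <- ifelse(is_het, 0.5,
                  ifelse(hom_ref, 1 - cfg$error_rate, cfg$error_rate))
  d_ref <- rbinom(n, total, p_ref)
  d_alt <- total - d_ref

  depth_table(data.frame(
    variety = c(variety, variety),
    locus = c(locus, locus),
    allele = c(ref_l, alt_l),
    depth = c(d_ref, d_alt),
    stringsAsFactors = FALSE))
}
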