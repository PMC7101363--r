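#' Panel filter thresholds
#'
#' Thresholds of the perfect-SNP criteria: biallelic SNP; flanking 61-mer
#' (30 bp each side) occurring exactly once in the genome over both strands;
#' no other variant or SSR within the flanks; per-site heterozygosity no
#' more than `het_max`; missing rate strictly less than `miss_max`; minor
#' allele frequency strictly above `maf_min` -- or, failing the MAF rule, an
#' allele at frequency `>= subgroup_hi` in exactly one subgroup and
#' `<= subgroup_lo` in every other subgroup (the subgroup-differential
#' rescue).
#'
#' @param flank_bp Flank length in bp on each side of the SNP.
#' @param het_max Maximum per-site heterozygosity (inclusive bound).
#' @param miss_max Missing-rate bound (exclusive: pass requires missing
#'   strictly below it).
#' @param maf_min MAF bound (exclusive: pass requires MAF strictly above it).
#' @param subgroup_hi,subgroup_lo Frequency bounds of the rescue rule
#'   (both inclusive).
#' @param ssr_min_copies Minimum tandem copies per motif length 1..6 that
#'   count as an SSR (defaults follow the MISA convention: mono >= 10,
#'   di >= 6, tri-hexa >= 5).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(flank_bp = 30L, het_max = 0.2, miss_max = 0.2,
                              maf_min = 0.4, subgroup_hi = 0.95,
                              subgroup_lo = 0.05,
                              ssr_min_copies = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  th <- list(flank_bp = as.integer(flank_bp), het_max = het_max,
             miss_max = miss_max, maf_min = maf_min,
             subgroup_hi = subgroup_hi, subgroup_lo = subgroup_lo,
             ssr_min_copies = as.integer(ssr_min_copies))
  if (th$flank_bp < 1L) stop("flank_bp must be >= 1")
  for (p in c("het_max", "miss_max", "maf_min", "subgroup_hi", "subgroup_lo")) {
    if (th[[p]] < 0 || th[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (length(th$ssr_min_copies) != 6L || any(th$ssr_min_copies < 2L)) {
    stop("ssr_min_copies must give a copy threshold >= 2 for motif lengths 1..6")
  }
  structure(th, class = "filter_thresholds")
}

#' Per-site allele frequencies, heterozygosity and missing rate
#'
#' Frequencies are computed over non-missing accessions only (each
#' contributing two allele copies); the heterozygosity is the fraction of
#' heterozygous accessions among non-missing ones; the missing rate is the
#' fraction of missing accessions among all accessions.
#'
#' @param vt A [variant_table].
#' @param site Site id or row index.
#' @param subgroups Optional named character vector (accession -> subgroup);
#'   defaults to the table's own assignment.
#' @return List with `freq` (named per-allele frequencies), `subgroup_freq`
#'   (alleles x subgroups matrix, or NULL), `het`, `missing`, `maf`, and `n`
#'   (non-missing accessions).
#' @export
site_frequencies <- function(vt, site, subgroups = vt$subgroups) {
  stopifnot(inherits(vt, "variant_table"))
  i <- if (is.character(site)) match(site, vt$sites$id) else as.integer(site)
  if (is.na(i) || i < 1L || i > nrow(vt$sites)) stop("unknown site: ", site)
  alleles <- site_alleles(vt, i)
  a1 <- vt$a1[i, ]; a2 <- vt$a2[i, ]
  ok <- !is.na(a1)
  if (!any(ok)) stop("all genotypes missing at site ", vt$sites$id[i])
  counts <- tabulate(c(a1[ok], a2[ok]) + 1L, nbins = length(alleles))
  freq <- setNames(counts / sum(counts), alleles)
  sub_freq <- NULL
  if (!is.null(subgroups)) {
    grp <- subgroups[vt$samples]
    if (anyNA(grp)) stop("subgroup assignment missing for some accessions")
    labs <- unique(grp)
    sub_freq <- vapply(labs, function(g) {
      sel <- ok & grp == g
      if (!any(sel)) return(rep(NA_real_, length(alleles)))
      cc <- tabulate(c(a1[sel], a2[sel]) + 1L, nbins = length(alleles))
      cc / sum(cc)
    }, numeric(length(alleles)))
    sub_freq <- matrix(sub_freq, nrow = length(alleles),
                       dimnames = list(alleles, labs))
  }
  srt <- sort(freq, decreasing = TRUE)
  list(freq = freq, subgroup_freq = sub_freq,
       het = mean(a1[ok] != a2[ok]),
       missing = mean(!ok),
       maf = if (length(srt) > 1L) unname(srt[2L]) else 0,
       n = sum(ok))
}

#' Flanking-sequence uniqueness check
#'
#' Extracts the (2 * `flank_bp` + 1)-mer centred on the SNP and counts its
#' exact occurrences over both strands (forward and reverse complement) of
#' the whole genome; the check passes iff that count is 1. Sites too close
#' to a chromosome end fail with reason `"edge"`; windows containing N fail
#' with reason `"ambiguous base"`.
#'
#' @param genome A [reference_genome].
#' @param chrom,pos Site coordinates (1-based).
#' @param flank_bp Flank length (default 30).
#' @return List with `pass`, `count` (NA when not counted) and `reason`.
#' @export
flanking_unique <- function(genome, chrom, pos, flank_bp = 30L) {
  stopifnot(inherits(genome, "reference_genome"))
  len <- genome$lengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  if (pos - flank_bp < 1L || pos + flank_bp > len) {
    return(list(pass = FALSE, count = NA_integer_, reason = "edge"))
  }
  kmer <- substr(genome$sequences[[chrom]], pos - flank_bp, pos + flank_bp)
  if (grepl("N", kmer, fixed = TRUE)) {
    return(list(pass = FALSE, count = NA_integer_, reason = "ambiguous base"))
  }
  count <- kmer_occurrences(genome, kmer)
  list(pass = count == 1L, count = count,
       reason = if (count == 1L) "" else "multi-hit")
}

# exact occurrence count of a k-mer over both strands of the genome
kmer_occurrences <- function(genome, kmer) {
  subject <- Biostrings::DNAStringSet(genome$sequences)
  pat <- Biostrings::DNAString(kmer)
  fwd <- sum(Biostrings::vcountPattern(pat, subject))
  rev <- sum(Biostrings::vcountPattern(
    Biostrings::reverseComplement(pat), subject))
  as.integer(fwd + rev)
}

#' Scan a sequence for simple sequence repeats (SSRs)
#'
#' Detects perfect tandem repeats of primitive motifs of length 1-6 meeting
#' the per-motif-length copy thresholds. Motifs that are themselves
#' repetitions of a shorter unit are not reported (an (AT)x(2k) run is a
#' di-, not a tetra-nucleotide SSR).
#'
#' @param x Character scalar, uppercase nucleotide sequence.
#' @param min_copies Integer vector of minimum copies for motif lengths 1..6.
#' @return data.frame with columns `start`, `end`, `motif`, `copies`
#'   (0 rows when no SSR is found).
#' @export
find_ssr <- function(x, min_copies = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  stopifnot(is.character(x), length(x) == 1L)
  n <- nchar(x)
  hits <- list()
  for (m in 1:6) {
    if (n < m * min_copies[m]) next
    i <- 1L
    while (i + m - 1L <= n) {
      motif <- substr(x, i, i + m - 1L)
      # extend the run of this motif
      copies <- 1L
      while (i + (copies + 1L) * m - 1L <= n &&
             substr(x, i + copies * m, i + (copies + 1L) * m - 1L) == motif) {
        copies <- copies + 1L
      }
      if (copies >= min_copies[m] && is_primitive(motif)) {
        hits[[length(hits) + 1L]] <-
          data.frame(start = i, end = i + copies * m - 1L,
                     motif = motif, copies = copies,
                     stringsAsFactors = FALSE)
        i <- i + copies * m
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), copies = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$end), , drop = FALSE]
}

# TRUE iff the motif is not a repetition of a shorter unit
is_primitive <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L &&
        motif == paste(rep(substr(motif, 1L, d), m / d), collapse = "")) {
      return(FALSE)
    }
  }
  TRUE
}

#' Flanking-neighbourhood cleanliness check
#'
#' Fails when any other variant (SNP or indel) in the table lies within
#' `flank_bp` of the site, or when the flanking window contains an SSR per
#' the configured motif thresholds.
#'
#' @param vt A [variant_table].
#' @param site Site id or row index.
#' @param genome A [reference_genome] (used for the SSR scan; `NULL` skips
#'   it).
#' @param thresholds A [filter_thresholds].
#' @return List with `pass` and `reasons` (character vector such as
#'   `"SNP@+12"`, `"Indel@-5"`, `"SSR(AT)"`).
#' @export
neighborhood_clean <- function(vt, site, genome = NULL,
                               thresholds = filter_thresholds()) {
  stopifnot(inherits(vt, "variant_table"))
  i <- if (is.character(site)) match(site, vt$sites$id) else as.integer(site)
  if (is.na(i) || i < 1L || i > nrow(vt$sites)) stop("unknown site: ", site)
  fb <- thresholds$flank_bp
  s <- vt$sites
  reasons <- character(0)
  near <- which(s$chrom == s$chrom[i] & abs(s$pos - s$pos[i]) <= fb &
                  seq_len(nrow(s)) != i)
  if (length(near)) {
    is_indel <- nchar(s$ref[near]) != 1L |
      vapply(strsplit(s$alt[near], ",", fixed = TRUE),
             function(a) any(nchar(a) != 1L), TRUE)
    off <- s$pos[near] - s$pos[i]
    reasons <- c(reasons,
                 paste0(ifelse(is_indel, "Indel@", "SNP@"),
                        ifelse(off > 0, "+", ""), off))
  }
  if (!is.null(genome)) {
    len <- genome$lengths[[s$chrom[i]]]
    lo <- max(1L, s$pos[i] - fb)
    hi <- min(len, s$pos[i] + fb)
    win <- genome_subseq(genome, s$chrom[i], lo, hi)
    ssr <- find_ssr(win, thresholds$ssr_min_copies)
    if (nrow(ssr)) {
      reasons <- c(reasons, paste0("SSR(", unique(ssr$motif), ")"))
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Select perfect SNPs from a variant table
#'
#' Applies the full criteria set to every site and returns the passing
#' panel together with one audit row per site and a funnel of per-criterion
#' pass counts. A site passes iff it is a biallelic SNP with unique,
#' variant- and SSR-free flanks, heterozygosity `<= het_max`, missing rate
#' `< miss_max`, and either MAF `> maf_min` or the subgroup-differential
#' rescue (an allele at frequency `>= subgroup_hi` in one subgroup and
#' `<= subgroup_lo` in every other).
#'
#' @param vt A [variant_table].
#' @param genome A [reference_genome].
#' @param thresholds A [filter_thresholds].
#' @param subgroups Optional accession -> subgroup map; defaults to the
#'   table's own. Without one the rescue rule never fires.
#' @return An object of class `snp_panel`: list with `panel` (passing site
#'   ids), `audit` (one data.frame row per site: per-criterion verdicts,
#'   computed het/missing/MAF, failure reasons) and `funnel` (named counts).
#' @export
select_perfect_snps <- function(vt, genome,
                                thresholds = filter_thresholds(),
                                subgroups = vt$subgroups) {
  stopifnot(inherits(vt, "variant_table"), inherits(genome, "reference_genome"))
  n <- nrow(vt$sites)
  if (n == 0L) stop("empty variant table")
  th <- thresholds
  audit <- data.frame(
    id = vt$sites$id, chrom = vt$sites$chrom, pos = vt$sites$pos,
    biallelic = FALSE, flank_unique = NA, flank_count = NA_integer_,
    neighborhood = NA, het = NA_real_, het_ok = NA,
    missing = NA_real_, miss_ok = NA, maf = NA_real_, maf_ok = NA,
    subgroup_diff = FALSE, final = FALSE, reasons = "",
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    reasons <- character(0)
    alleles <- site_alleles(vt, i)
    snp <- all(nchar(alleles) == 1L)
    bial <- length(alleles) == 2L && snp
    audit$biallelic[i] <- bial
    if (!bial) reasons <- c(reasons, if (snp) "multiallelic" else "not a SNP")

    fl <- flanking_unique(genome, vt$sites$chrom[i], vt$sites$pos[i],
                          th$flank_bp)
    audit$flank_unique[i] <- fl$pass
    audit$flank_count[i] <- fl$count
    if (!fl$pass) reasons <- c(reasons, paste0("flank:", fl$reason))

    nb <- neighborhood_clean(vt, i, genome, th)
    audit$neighborhood[i] <- nb$pass
    if (!nb$pass) reasons <- c(reasons, nb$reasons)

    fr <- site_frequencies(vt, i, subgroups)
    audit$het[i] <- fr$het
    audit$het_ok[i] <- fr$het <= th$het_max
    if (!audit$het_ok[i]) reasons <- c(reasons, "het")
    audit$missing[i] <- fr$missing
    audit$miss_ok[i] <- fr$missing < th$miss_max
    if (!audit$miss_ok[i]) reasons <- c(reasons, "missing")
    audit$maf[i] <- fr$maf
    audit$maf_ok[i] <- fr$maf > th$maf_min

    rescue <- FALSE
    if (!is.null(fr$subgroup_freq) && ncol(fr$subgroup_freq) > 1L) {
      sf <- fr$subgroup_freq
      for (a in seq_len(nrow(sf))) {
        f <- sf[a, ]
        if (anyNA(f)) next
        hi <- f >= th$subgroup_hi
        if (sum(hi) == 1L && all(f[!hi] <= th$subgroup_lo)) {
          rescue <- TRUE
          break
        }
      }
    }
    audit$subgroup_diff[i] <- rescue
    if (!audit$maf_ok[i] && !rescue) reasons <- c(reasons, "maf")

    audit$final[i] <- bial && fl$pass && nb$pass && audit$het_ok[i] &&
      audit$miss_ok[i] && (audit$maf_ok[i] || rescue)
    audit$reasons[i] <- paste(reasons, collapse = ";")
  }
  funnel <- c(input = n,
              biallelic = sum(audit$biallelic),
              flank_unique = sum(audit$flank_unique, na.rm = TRUE),
              neighborhood = sum(audit$neighborhood, na.rm = TRUE),
              het = sum(audit$het_ok, na.rm = TRUE),
              missing = sum(audit$miss_ok, na.rm = TRUE),
              maf_or_rescue = sum(audit$maf_ok | audit$subgroup_diff),
              final = sum(audit$final))
  structure(list(panel = audit$id[audit$final], audit = audit,
                 funnel = funnel, thresholds = th),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("Perfect-SNP panel:", length(x$panel), "of", x$funnel[["input"]],
      "sites retained\nFunnel (sites passing each criterion):\n")
  print(x$funnel)
  invisible(x)
}

#' Thin a panel to approximately even genomic spacing
#'
#' Convenience subsampler: keeps `n_keep` sites at near-uniform rank spacing
#' along the genome (per-chromosome order). Provided for panel-size
#' reduction; even spacing alone does not define a unique subset.
#'
#' @param audit The audit data.frame of a `snp_panel` (or any data.frame
#'   with `id`, `chrom`, `pos`), already restricted to passing sites.
#' @param n_keep Number of sites to keep.
#' @return Character vector of retained site ids.
#' @export
thin_panel <- function(audit, n_keep) {
  ord <- order(match(audit$chrom, unique(audit$chrom)), audit$pos)
  ids <- audit$id[ord]
  if (n_keep >= length(ids)) return(ids)
  ids[round(seq(1L, length(ids), length.out = n_keep))]
}
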