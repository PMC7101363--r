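# Fixture builders and independent oracles shared across the test files.

# random genotype matrix of biallelic A/G calls
random_gm <- function(n, m, miss = 0.05, seed = 1) {
  set.seed(seed)
  toks <- c("A/A", "A/G", "G/G")
  calls <- matrix(sample(toks, n * m, replace = TRUE), n, m,
                  dimnames = list(sprintf("v%02d", seq_len(n)),
                                  sprintf("L%03d", seq_len(m))))
  calls[runif(n * m) < miss] <- NA
  genotype_matrix(calls)
}

# variant table from a list of sites; each site is a list with chrom, pos,
# ref, alt and gt: character vector like c("0/0","0/1","./.") per sample
make_vt <- function(site_list, samples, subgroups = NULL) {
  sites <- do.call(rbind, lapply(seq_along(site_list), function(i) {
    s <- site_list[[i]]
    data.frame(id = if (is.null(s$id)) paste0("s", i) else s$id,
               chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
               stringsAsFactors = FALSE)
  }))
  parse1 <- function(g, k) {
    p <- strsplit(g, "/", fixed = TRUE)[[1L]]
    suppressWarnings(as.integer(p[k]))
  }
  a1 <- t(vapply(site_list, function(s)
    vapply(s$gt, parse1, 0L, k = 1L), integer(length(samples))))
  a2 <- t(vapply(site_list, function(s)
    vapply(s$gt, parse1, 0L, k = 2L), integer(length(samples))))
  if (length(site_list) == 1L) { a1 <- matrix(a1, 1L); a2 <- matrix(a2, 1L) }
  variant_table(sites, a1, a2, samples, subgroups = subgroups)
}

# plain-text VCF writer for reader tests
write_test_vcf <- function(path, chrom, pos, id, ref, alt, gt_matrix,
                           samples = colnames(gt_matrix)) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", sep = "\t")
  for (j in seq_len(ncol(gt_matrix))) {
    body <- paste(body, gt_matrix[, j], sep = "\t")
  }
  writeLines(c(hdr, body), path)
  path
}

# reverse complement without Biostrings (oracle helper)
revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]), collapse = "")
}

# brute-force occurrence count of a k-mer over both strands (oracle for
# the flank-uniqueness scan); non-overlapping matches suffice for the
# fixtures used
brute_kmer_count <- function(sequences, kmer) {
  cnt <- 0L
  for (s in sequences) {
    for (pat in c(kmer, revcomp_chr(kmer))) {
      m <- gregexpr(pat, s, fixed = TRUE)[[1L]]
      cnt <- cnt + sum(m > 0L)
    }
  }
  cnt
}

# regex oracle for SSR presence in a window
regex_has_ssr <- function(x, min_copies = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  for (m in 1:6) {
    pat <- paste0("([ACGT]{", m, "})\\1{", min_copies[m] - 1L, ",}")
    if (grepl(pat, x, perl = TRUE)) return(TRUE)
  }
  FALSE
}

# brute-force differential-genotype count matrix (oracle)
brute_diff_matrix <- function(gm) {
  m <- unclass(gm)
  n <- nrow(m)
  out <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u == v) next
      cnt <- 0L
      for (j in seq_len(ncol(m))) {
        if (!is.na(m[u, j]) && !is.na(m[v, j]) && m[u, j] != m[v, j]) {
          cnt <- cnt + 1L
        }
      }
      out[u, v] <- cnt
    }
  }
  out
}

# AMOVA oracle: sums of squares via deviations from centroids of one-hot
# allele-copy vectors (scaled so squared distance = allele mismatch count),
# an independent route to the package's pairwise-distance formulation
amova_oracle <- function(gm, subgroups) {
  m <- unclass(gm)
  n <- nrow(m)
  grp <- subgroups[rownames(m)]
  # build copy-level indicator matrix
  cols <- list()
  for (j in seq_len(ncol(m))) {
    g <- strsplit(m[, j], "/", fixed = TRUE)
    al1 <- vapply(g, `[`, "", 1L)
    al2 <- vapply(g, `[`, "", 2L)
    alleles <- sort(unique(c(al1, al2)))
    for (a in alleles) {
      cols[[length(cols) + 1L]] <-
        c(as.numeric(al1 == a), as.numeric(al2 == a)) / sqrt(2)
    }
  }
  X <- do.call(cbind, cols)               # 2n rows: copy1 block, copy2 block
  copy_grp <- rep(as.character(grp), 2L)
  ind <- rep(seq_len(n), 2L)
  ss_dev <- function(rows) {
    ctr <- colMeans(X[rows, , drop = FALSE])
    sum(sweep(X[rows, , drop = FALSE], 2L, ctr)^2)
  }
  SS_total <- ss_dev(seq_len(2L * n))
  SS_wp <- sum(vapply(unique(copy_grp), function(g)
    ss_dev(which(copy_grp == g)), 0))
  SS_wi <- sum(vapply(seq_len(n), function(i)
    ss_dev(which(ind == i)), 0))
  sizes <- table(grp)
  P <- length(sizes)
  df <- c(P - 1L, n - P, n)
  SS <- c(SS_total - SS_wp, SS_wp - SS_wi, SS_wi)
  MS <- SS / df
  n_c <- (2 * n - sum((2 * sizes)^2) / (2 * n)) / (P - 1L)
  comp <- c((MS[1L] - MS[2L]) / n_c, (MS[2L] - MS[3L]) / 2, MS[3L])
  list(SS = SS, df = df, variance = comp,
       percent = 100 * comp / sum(comp))
}

# rule-table oracle for the depth-based genotype caller
oracle_call <- function(major_d, minor_d, min_depth = 20, het_max = 0.7,
                        hom_min = 0.8) {
  if (major_d + minor_d == 0) return("no_data")
  if (major_d < min_depth) return("low_depth")
  r <- major_d / (major_d + minor_d)
  if (r < het_max) return("het")
  if (r >= hom_min) return("hom")
  "ambiguous_ratio"
}
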