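make_genome <- function(seqs) reference_genome(seqs)

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

test_that("site frequencies, heterozygosity and missing rate are counted right", {
  gt <- c(rep("0/0", 4), rep("1/1", 4), rep("0/1", 2))
  vt <- make_vt(list(list(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                          gt = gt)), samples = paste0("s", 1:10))
  fr <- site_frequencies(vt, 1)
  expect_equal(unname(fr$freq["A"]), 0.5)
  expect_equal(fr$het, 0.2)
  expect_equal(fr$missing, 0)
  expect_equal(fr$maf, 0.5)

  vt2 <- make_vt(list(list(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                           gt = rep("0/0", 10))), paste0("s", 1:10))
  fr2 <- site_frequencies(vt2, 1)
  expect_equal(unname(fr2$freq), c(1, 0))
  expect_equal(fr2$maf, 0)

  vt3 <- make_vt(list(list(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                           gt = c(rep("0/1", 8), "./.", "./."))),
                 paste0("s", 1:10))
  expect_equal(site_frequencies(vt3, 1)$missing, 0.2)

  vt4 <- make_vt(list(list(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                           gt = rep("./.", 4))), paste0("s", 1:4))
  expect_error(site_frequencies(vt4, 1), "missing")
})

test_that("flank uniqueness counts exact occurrences over both strands", {
  set.seed(71)
  base <- rand_seq(5000)
  g1 <- make_genome(c(chr1 = base))
  fl <- flanking_unique(g1, "chr1", 2500)
  expect_true(fl$pass)
  expect_equal(fl$count, 1L)

  # duplicating a 1 kb block makes every site inside it multi-hit
  dup <- paste0(base, substr(base, 1000, 1999), rand_seq(500))
  g2 <- make_genome(c(chr1 = dup))
  for (pos in c(1200, 1500, 1900)) {
    fl <- flanking_unique(g2, "chr1", pos)
    expect_false(fl$pass)
    expect_gte(fl$count, 2L)
    kmer <- substr(dup, pos - 30, pos + 30)
    expect_equal(fl$count, brute_kmer_count(g2$sequences, kmer))
  }
  # a reverse-complement copy also breaks uniqueness
  rc <- paste0(base, revcomp_chr(substr(base, 3000, 3200)))
  g3 <- make_genome(c(chr1 = rc))
  expect_false(flanking_unique(g3, "chr1", 3100)$pass)

  expect_equal(flanking_unique(g1, "chr1", 15)$reason, "edge")
  gN <- make_genome(c(chr1 = paste0(substr(base, 1, 200), "N",
                                    substr(base, 202, 5000))))
  expect_equal(flanking_unique(gN, "chr1", 190)$reason, "ambiguous base")
})

test_that("SSR scanner agrees with a regex oracle", {
  set.seed(72)
  # planted SSRs
  expect_equal(nrow(find_ssr(paste0(rand_seq(20),
                                    strrep("AT", 7), rand_seq(20)))), 1L)
  hit <- find_ssr(paste0("CCGG", strrep("AT", 7), "GGCC"))
  expect_equal(hit$motif, "AT")
  expect_equal(hit$copies, 7L)
  expect_equal(nrow(find_ssr(strrep("A", 9))), 0L)   # below mono threshold
  expect_equal(find_ssr(strrep("A", 10))$motif, "A")
  # (ATAT) runs are di- not tetra-nucleotide repeats
  expect_equal(find_ssr(strrep("AT", 12))$motif, "AT")

  for (i in 1:60) {
    x <- rand_seq(61)
    if (i %% 3 == 0) {
      m <- sample(1:6, 1)
      motif <- rand_seq(m)
      ins <- strrep(motif, c(10, 6, 5, 5, 5, 5)[m])
      at <- sample(1:(61 - nchar(ins)), 1)
      x <- paste0(substr(x, 1, at - 1), ins,
                  substr(x, at + nchar(ins), 61))
    }
    expect_equal(nrow(find_ssr(x)) > 0, regex_has_ssr(x), info = x)
  }
})

test_that("flank neighbourhood rejects nearby variants and SSR flanks", {
  set.seed(73)
  genome <- make_genome(c(chr1 = rand_seq(3000)))
  sites <- list(
    list(chrom = "chr1", pos = 1000, ref = "A", alt = "G",
         gt = c("0/0", "0/1")),
    list(chrom = "chr1", pos = 1012, ref = "C", alt = "T",
         gt = c("0/0", "0/1")),
    list(chrom = "chr1", pos = 1043, ref = "G", alt = "A",
         gt = c("0/0", "0/1")),
    list(chrom = "chr1", pos = 2000, ref = "T", alt = "TA",
         gt = c("0/0", "0/1")),
    list(chrom = "chr1", pos = 2020, ref = "A", alt = "C",
         gt = c("0/0", "0/1")))
  vt <- make_vt(sites, c("s1", "s2"))
  r1 <- neighborhood_clean(vt, 1, genome)
  expect_false(r1$pass)
  expect_true("SNP@+12" %in% r1$reasons)
  # nearest other variant 31 bp away: outside the window
  expect_true(neighborhood_clean(vt, 3, genome)$pass)
  # an indel neighbour is named as such
  r5 <- neighborhood_clean(vt, 5, genome)
  expect_true("Indel@-20" %in% r5$reasons)

  ssr_genome <- make_genome(c(chr1 = paste0(rand_seq(980),
                                            strrep("AT", 7),
                                            rand_seq(2000))))
  vt_ssr <- make_vt(list(list(chrom = "chr1", pos = 1000, ref = "A",
                              alt = "G", gt = c("0/0", "0/1"))),
                    c("s1", "s2"))
  r <- neighborhood_clean(vt_ssr, 1, ssr_genome)
  expect_false(r$pass)
  expect_true(any(grepl("^SSR\\(", r$reasons)))
})

test_that("MAF boundary and subgroup-differential rescue behave as specified", {
  set.seed(74)
  genome <- make_genome(c(chr1 = rand_seq(4000)))
  ref1 <- substr(genome$sequences[["chr1"]], 1000, 1000)
  ref2 <- substr(genome$sequences[["chr1"]], 2000, 2000)
  alt_of <- function(r) setdiff(c("A", "C", "G", "T"), r)[1]
  subgroups <- setNames(rep(paste0("P", 1:4), each = 10),
                        sprintf("s%02d", 1:40))
  # MAF 0.39 (39/100 allele copies impossible at 40 samples; use 0.3875)
  gt_low_maf <- c(rep("0/1", 1), rep("1/1", 15), rep("0/0", 24))
  # rescue pattern: ALT fixed in P1 (freq 0.95+), absent elsewhere
  gt_rescue <- c(rep("1/1", 10), rep("0/0", 30))
  vt <- make_vt(list(
    list(id = "low_maf", chrom = "chr1", pos = 1000, ref = ref1,
         alt = alt_of(ref1), gt = sample(gt_low_maf)),
    list(id = "rescued", chrom = "chr1", pos = 2000, ref = ref2,
         alt = alt_of(ref2), gt = gt_rescue)),
    samples = names(subgroups), subgroups = subgroups)
  res <- select_perfect_snps(vt, genome)
  audit <- res$audit
  low <- audit[audit$id == "low_maf", ]
  expect_false(low$maf_ok)        # MAF 0.3875 is not above 0.4
  expect_false(low$final)
  expect_match(low$reasons, "maf")
  resc <- audit[audit$id == "rescued", ]
  expect_false(resc$maf_ok)       # MAF 0.25 overall
  expect_true(resc$subgroup_diff) # but ALT >= 0.95 in P1, <= 0.05 elsewhere
  expect_true(resc$final)
})

test_that("panel verdicts are order-invariant and monotone in thresholds", {
  set.seed(75)
  genome <- make_genome(c(chr1 = rand_seq(6000)))
  samples <- sprintf("s%02d", 1:20)
  sites <- lapply(1:12, function(i) {
    pos <- 300 * i + 200
    ref <- substr(genome$sequences[["chr1"]], pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    k <- sample(0:20, 1)
    gt <- sample(c(rep("0/0", k), rep("1/1", 20 - k)))
    list(id = paste0("site", i), chrom = "chr1", pos = pos,
         ref = ref, alt = alt, gt = gt)
  })
  vt <- make_vt(sites, samples)
  base <- select_perfect_snps(vt, genome)

  # permute accessions: verdicts unchanged
  perm <- sample(seq_along(samples))
  vt_p <- variant_table(vt$sites, vt$a1[, perm], vt$a2[, perm],
                        vt$samples[perm])
  res_p <- select_perfect_snps(vt_p, genome)
  expect_equal(res_p$audit$final, base$audit$final)
  expect_equal(res_p$panel, base$panel)

  # relaxing maf_min can only grow the panel
  relaxed <- select_perfect_snps(vt, genome,
                                 filter_thresholds(maf_min = 0.1))
  expect_true(all(base$panel %in% relaxed$panel))

  # every rejected site names at least one failed criterion
  rej <- base$audit[!base$audit$final, ]
  expect_true(all(nzchar(rej$reasons)))
})
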