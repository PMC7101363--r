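test_that("FASTA reading uppercases, records lengths, rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr1 some description",
               paste(rep("ACGTAC", 10), collapse = ""),
               ">chr2",
               tolower(paste(rep("ggccat", 10), collapse = ""))), f)
  g <- read_fasta(f)
  expect_s3_class(g, "reference_genome")
  expect_equal(unname(g$lengths), c(60L, 60L))
  expect_named(g$sequences, c("chr1", "chr2"))
  expect_false(grepl("[a-z]", g$sequences[["chr2"]]))

  writeLines(c(">chr1", "ACGT", ">chr1", "GGCC"), f)
  expect_error(read_fasta(f), "duplicated")

  # IUPAC ambiguity codes outside {A,C,G,T,N} are rejected
  writeLines(c(">chrX", "ACRT"), f)
  expect_error(read_fasta(f), "alphabet|outside")
})

test_that("VCF reader parses sites, samples, missing and multi-allelics", {
  f <- withr::local_tempfile(fileext = ".vcf")
  gt <- rbind(c("0/0", "0/1", "1/1", "./."),
              c("0/0", "0/0", "0/1", "0/1"),
              c("1/1", "0/0", "0/0", "0/0"))
  colnames(gt) <- paste0("s", 1:4)
  write_test_vcf(f, chrom = "chr1", pos = c(100, 200, 300),
                 id = c("a", "b", "c"), ref = c("A", "C", "G"),
                 alt = c("G", "T", "A"), gt_matrix = gt)
  vt <- read_vcf(f)
  expect_equal(nrow(vt$sites), 3L)
  expect_equal(vt$samples, paste0("s", 1:4))
  expect_true(is.na(vt$a1["a", "s4"]))
  expect_equal(unname(vt$a1["a", "s2"]), 0L)
  expect_equal(unname(vt$a2["a", "s2"]), 1L)

  # multi-allelic record excluded under require_biallelic, with a count
  write_test_vcf(f, chrom = "chr1", pos = c(100, 200),
                 id = c("a", "b"), ref = c("A", "C"), alt = c("G", "C,T"),
                 gt_matrix = rbind(c("0/0", "0/1"), c("1/2", "0/0")),
                 samples = c("s1", "s2"))
  expect_message(vt2 <- read_vcf(f, require_biallelic = TRUE), "excluded")
  expect_equal(nrow(vt2$sites), 1L)
  expect_equal(attr(vt2, "n_multiallelic_excluded"), 1L)
  vt3 <- read_vcf(f)
  expect_equal(nrow(vt3$sites), 2L)
  expect_equal(unname(vt3$a2["b", "s1"]), 2L)
})

test_that("VCF reader rejects absent GT and sorts non-monotone positions", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t100\t.\tA\tG\t.\tPASS\t.\tDP\t13"), f)
  expect_error(read_vcf(f), "GT")

  gt <- rbind(c("0/0"), c("0/1"))
  colnames(gt) <- "s1"
  write_test_vcf(f, chrom = "chr1", pos = c(300, 100), id = c("x", "y"),
                 ref = c("A", "C"), alt = c("G", "T"), gt_matrix = gt)
  expect_warning(vt <- read_vcf(f), "sort")
  expect_equal(vt$sites$pos, c(100L, 300L))
  expect_equal(vt$sites$id, c("y", "x"))
})

test_that("VCF writer round-trips a variant table", {
  cfg <- sim_config(subpop_sizes = c(4, 4), n_loci = 12, seed = 3)
  truth <- simulate_population(cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(truth$variants, f)
  back <- read_vcf(f)
  expect_equal(back$sites, truth$variants$sites)
  expect_equal(back$a1, truth$variants$a1)
  expect_equal(back$a2, truth$variants$a2)
})

test_that("depth table validates counts and duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variety\tlocus\tallele\tdepth",
               "v1\tL1\tA\t520", "v1\tL1\tG\t480"), f)
  d <- read_depth_table(f)
  expect_s3_class(d, "depth_table")
  expect_equal(nrow(d), 2L)
  expect_equal(sum(d$depth), 1000L)

  writeLines(c("variety\tlocus\tallele\tdepth", "v1\tL1\tA\t-3"), f)
  expect_error(read_depth_table(f), "non-negative")

  writeLines(c("variety\tlocus\tallele\tdepth",
               "v1\tL1\tA\t5", "v1\tL1\tA\t7"), f)
  expect_error(read_depth_table(f), "duplicate")
})

test_that("depth records can be pulled from a VCF AD field", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tv1\tv2",
               "chr1\t100\tL1\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:520,480\t0/0:99,1"),
             f)
  d <- read_depth_table(f)
  expect_equal(d$depth[d$variety == "v1" & d$allele == "A"], 520L)
  expect_equal(d$depth[d$variety == "v2" & d$allele == "G"], 1L)
})

test_that("genotype matrix round-trips with canonical tokens", {
  calls <- rbind(c("A/G", "G/A"), c("./.", "T/T"))
  dimnames(calls) <- list(c("v1", "v2"), c("L1", "L2"))
  gm <- genotype_matrix(calls)
  # het canonicalised regardless of input order
  expect_equal(unclass(gm)["v1", "L2"], "A/G")
  expect_true(is.na(unclass(gm)["v2", "L1"]))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(gm, f)
  back <- read_genotype_matrix(f)
  expect_identical(unclass(back), unclass(gm))
  # and writing what was read is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("genotype matrix reader rejects ragged rows and bad tokens", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variety\tL1\tL2", "v1\tA/A\tA/G", "v2\tG/G"), f)
  expect_error(read_genotype_matrix(f), "ragged")

  writeLines(c("variety\tL1", "v1\tAG"), f)
  expect_error(read_genotype_matrix(f), "malformed")
})

test_that("BED panel export is 0-based half-open and round-trips boundaries", {
  sites <- data.frame(chrom = c("chr1", "chr1"), pos = c(1L, 60L),
                      id = c("first", "last"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_panel_bed(sites, f)
  raw <- read.delim(f, header = FALSE)
  expect_equal(raw$V2, c(0L, 59L))
  expect_equal(raw$V3, c(1L, 60L))
  back <- read_panel_bed(f)
  expect_equal(back$pos, sites$pos)
  expect_equal(back$id, sites$id)
})

test_that("subgroup table round-trips", {
  sg <- c(v1 = "Pop1", v2 = "Pop1", v3 = "Pop2")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_subgroups(sg, f)
  expect_equal(read_subgroups(f), sg)
})
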