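#' Reference genome container
#'
#' Holds chromosome sequences as uppercase character strings restricted to
#' the A/C/G/T/N alphabet, together with their lengths.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @return An object of class `reference_genome` with elements `sequences`
#'   (named uppercase character vector) and `lengths` (named integer vector).
#' @export
reference_genome <- function(sequences) {
  if (!is.character(sequences) || is.null(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stop("'sequences' must be a named character vector")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicated sequence name(s): ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  structure(
    list(sequences = sequences,
         lengths = setNames(nchar(sequences), names(sequences))),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("Reference genome:", length(x$sequences), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a FASTA reference genome
#'
#' Sequences are uppercased on read; duplicate headers are rejected. Only
#' the first whitespace-delimited token of each header is kept as the
#' chromosome name.
#'
#' @param path Path to a FASTA file.
#' @return A [reference_genome].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicated FASTA header(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(ss) <- nm
  reference_genome(setNames(as.character(ss), nm))
}

#' Write a reference genome to FASTA
#'
#' @param genome A [reference_genome].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "reference_genome"))
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# Extract genome[chrom][start..end] (1-based inclusive), error on bounds.
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$sequences)) stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (start < 1L || end > len || start > end) {
    stop("window [", start, ",", end, "] out of bounds for ", chrom,
         " (length ", len, ")")
  }
  substr(genome$sequences[[chrom]], start, end)
}

#' Variant table container
#'
#' Multi-sample variant calls: a site table plus two parallel integer
#' matrices of allele indices (0 = REF, 1 = first ALT, ...) with `NA` for a
#' missing genotype. Genotypes are unordered: the pair is stored sorted so
#' that `a1 <= a2`.
#'
#' @param sites data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt` (comma-separated ALT alleles).
#' @param a1,a2 Integer matrices (sites x samples) of allele indices.
#' @param samples Character vector of sample/accession identifiers.
#' @param subgroups Optional named character vector mapping each sample to a
#'   subgroup label.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, a1, a2, samples, subgroups = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(sites)))
  if (anyDuplicated(sites$id)) stop("duplicated site id(s)")
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  n <- nrow(sites)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (nrow(a1) != n || nrow(a2) != n ||
      ncol(a1) != length(samples) || ncol(a2) != length(samples)) {
    stop("genotype matrices inconsistent with sites/samples")
  }
  # store pairs unordered
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  if (any(xor(is.na(a1), is.na(a2)))) stop("half-missing genotype found")
  n_alleles <- 1L + vapply(strsplit(sites$alt, ",", fixed = TRUE),
                           function(a) length(a[nzchar(a) & a != "."]), 0L)
  mx <- suppressWarnings(apply(a2, 1L, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- 0L
  if (any(mx > n_alleles - 1L)) {
    stop("genotype references an undeclared allele at site(s): ",
         paste(sites$id[mx > n_alleles - 1L], collapse = ", "))
  }
  dimnames(a1) <- dimnames(a2) <- list(sites$id, samples)
  # positions strictly increasing within chromosome
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (is.unsorted(ord)) {
    warning("site positions not sorted within chromosome; sorting")
    sites <- sites[ord, , drop = FALSE]
    a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]
  }
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) stop("duplicate chrom/pos: ",
                     paste(sites$id[dup], collapse = ", "))
  rownames(sites) <- NULL
  structure(list(sites = sites, a1 = a1, a2 = a2,
                 samples = as.character(samples), subgroups = subgroups),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table:", nrow(x$sites), "site(s) x",
      length(x$samples), "sample(s)")
  if (!is.null(x$subgroups)) {
    cat(";", length(unique(x$subgroups)), "subgroup(s)")
  }
  cat("\n")
  invisible(x)
}

# alleles (REF first) declared at site i of a variant_table
site_alleles <- function(vt, i) {
  alt <- strsplit(vt$sites$alt[i], ",", fixed = TRUE)[[1L]]
  alt <- alt[nzchar(alt) & alt != "."]
  c(vt$sites$ref[i], alt)
}

#' Read a multi-sample VCF into a variant table
#'
#' Requires the GT FORMAT field. Multi-allelic records are retained with all
#' ALT alleles unless `require_biallelic` is set, in which case they are
#' dropped and the number excluded is reported as attribute
#' `n_multiallelic_excluded` (and via a message). Missing genotypes (`./.`)
#' become missing states. Non-monotone positions trigger a warning and a
#' stable sort.
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @param require_biallelic Drop records with more than one ALT allele?
#' @param subgroups Optional named character vector (sample -> subgroup).
#' @return A [variant_table].
#' @export
read_vcf <- function(path, require_biallelic = FALSE, subgroups = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fmt <- v@gt[, "FORMAT"]
  has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, TRUE)
  if (!all(has_gt)) stop("VCF record(s) without GT in FORMAT; cannot read genotypes")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  sites <- data.frame(id = id,
                      chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"],
                      alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  n_excl <- 0L
  if (isTRUE(require_biallelic)) {
    multi <- grepl(",", sites$alt, fixed = TRUE)
    n_excl <- sum(multi)
    if (n_excl > 0L) {
      message(n_excl, " multi-allelic record(s) excluded")
      sites <- sites[!multi, , drop = FALSE]
      gt <- gt[!multi, , drop = FALSE]
    }
  }
  if (nrow(sites) == 0L) stop("no variant records retained from ", path)
  # parse GT "0/1" or "0|1"
  parse_gt <- function(g) {
    out <- matrix(NA_integer_, nrow = length(g), ncol = 2L)
    ok <- !is.na(g)
    parts <- strsplit(gsub("|", "/", g[ok], fixed = TRUE), "/", fixed = TRUE)
    al <- suppressWarnings(
      vapply(parts, function(p) as.integer(p[1:2]), integer(2L)))
    out[ok, ] <- t(al)
    out
  }
  a1 <- matrix(NA_integer_, nrow(sites), length(samples))
  a2 <- a1
  for (j in seq_along(samples)) {
    p <- parse_gt(gt[, j])
    a1[, j] <- p[, 1L]; a2[, j] <- p[, 2L]
  }
  a1[is.na(a2)] <- NA_integer_; a2[is.na(a1)] <- NA_integer_
  vt <- variant_table(sites, a1, a2, samples, subgroups = subgroups)
  attr(vt, "n_multiallelic_excluded") <- n_excl
  vt
}

#' Write a variant table as VCF 4.2
#'
#' Minimal plain-text writer emitting the GT field only; genotypes are
#' written with the smaller allele index first (pairs are unordered).
#'
#' @param vt A [variant_table].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=snppanel",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vt$samples), collapse = "\t")), con)
  gt <- matrix(.MISSING_TOKEN, nrow(vt$a1), ncol(vt$a1))
  ok <- !is.na(vt$a1)
  gt[ok] <- paste(vt$a1[ok], vt$a2[ok], sep = "/")
  body <- paste(vt$sites$chrom, vt$sites$pos, vt$sites$id, vt$sites$ref,
                vt$sites$alt, ".", "PASS", ".", "GT", sep = "\t")
  for (j in seq_len(ncol(gt))) body <- paste(body, gt[, j], sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a per-allele read-depth table
#'
#' Accepts either a tab-delimited file with columns `variety`, `locus`,
#' `allele`, `depth` (one row per observed allele; alleles absent from the
#' table have depth 0), or a VCF with an AD FORMAT field (file name ending
#' in `.vcf` or `.vcf.gz`), whose per-sample allele depths are unrolled into
#' the same long layout.
#'
#' @param path Path to the depth TSV or VCF.
#' @return A data.frame of class `depth_table` with columns `variety`,
#'   `locus`, `allele`, `depth`.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) return(depths_from_vcf(path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  depth_table(df)
}

#' Validate a long allele-depth data.frame
#'
#' @param df data.frame with columns `variety`, `locus`, `allele`, `depth`.
#' @return The validated data.frame with class `depth_table` prepended.
#' @export
depth_table <- function(df) {
  need <- c("variety", "locus", "allele", "depth")
  if (!all(need %in% names(df))) {
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (nrow(df) == 0L) stop("empty depth table")
  d <- suppressWarnings(as.numeric(df$depth))
  if (anyNA(d) || any(d < 0) || any(d != floor(d))) {
    stop("depths must be non-negative integers")
  }
  df$depth <- as.integer(d)
  key <- paste(df$variety, df$locus, df$allele, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (variety, locus, allele) row(s), e.g. ",
         gsub("\r", "/", key[duplicated(key)][1L]))
  }
  class(df) <- c("depth_table", "data.frame")
  df
}

# unroll VCF AD fields into the long depth layout
depths_from_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF has no AD FORMAT field")
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1L, dimnames = list(NULL, names(ad)))
  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  alleles <- lapply(seq_len(nrow(fix)), function(i) {
    unname(c(fix[i, "REF"],
             setdiff(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]], ".")))
  })
  id <- unname(id)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    al <- alleles[[i]]
    dd <- strsplit(ad[i, ], ",", fixed = TRUE)
    dm <- vapply(dd, function(x) {
      y <- suppressWarnings(as.integer(x))
      length(y) <- length(al)
      y[is.na(y)] <- 0L
      y
    }, integer(length(al)))
    dimnames(dm) <- NULL
    out[[i]] <- data.frame(
      variety = rep(colnames(ad), each = length(al)),
      locus = id[i],
      allele = rep(al, times = ncol(ad)),
      depth = as.integer(dm),
      stringsAsFactors = FALSE)
  }
  depth_table(do.call(rbind, out))
}

#' Write a long allele-depth table as TSV
#'
#' @param df A `depth_table` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_depth_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype matrix (DNA fingerprint) container
#'
#' A varieties x loci character matrix of canonical genotype tokens
#' (`"A/G"`, alleles sorted lexically) with `NA` for missing. This is the
#' fingerprint object consumed by the diversity, differentiation and core-set
#' stages.
#'
#' @param calls Character matrix with variety row names and locus column
#'   names; entries `"X/Y"`, `"./."`, or `NA`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("calls must have variety row names and locus column names")
  }
  calls[calls == .MISSING_TOKEN] <- NA_character_
  al <- split_calls(as.vector(calls))
  canon <- format_call(al[, 1L], al[, 2L])
  canon[canon == .MISSING_TOKEN] <- NA_character_
  out <- matrix(canon, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  class(out) <- c("genotype_matrix", class(out))
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x), "varieties x", ncol(x), "loci; ",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x))))
  invisible(x)
}

#' Write / read a genotype matrix as TSV
#'
#' Layout: header row of locus ids, first column `variety`; genotype tokens
#' `"A/G"` (alleles sorted lexically), missing `"./."`. `read_genotype_matrix`
#' rejects ragged rows and malformed tokens, and round-trips
#' `write_genotype_matrix` output exactly.
#'
#' @param gm A [genotype_matrix].
#' @param path File path.
#' @return `write_genotype_matrix` returns `path` invisibly;
#'   `read_genotype_matrix` returns a [genotype_matrix].
#' @export
write_genotype_matrix <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- unclass(gm)
  m[is.na(m)] <- .MISSING_TOKEN
  df <- data.frame(variety = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) {
    stop("ragged rows in genotype matrix file ", path)
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (names(df)[1L] != "variety") stop("first column must be 'variety'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$variety
  genotype_matrix(m)
}

#' Export / import a SNP panel as BED
#'
#' BED uses 0-based, half-open coordinates; a 1-based SNP position `pos`
#' becomes the interval `[pos - 1, pos)`. `read_panel_bed` converts back.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `id`.
#' @param path File path.
#' @return `write_panel_bed` returns `path` invisibly; `read_panel_bed`
#'   returns a data.frame with columns `chrom`, `pos`, `id`.
#' @export
write_panel_bed <- function(sites, path) {
  stopifnot(all(c("chrom", "pos", "id") %in% names(sites)))
  bed <- data.frame(chrom = sites$chrom,
                    start = sites$pos - 1L,
                    end = sites$pos,
                    name = sites$id)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_bed
#' @export
read_panel_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("panel BED needs chrom/start/end/name columns")
  data.frame(chrom = bed[[1L]], pos = bed[[2L]] + 1L, id = bed[[4L]],
             stringsAsFactors = FALSE)
}

#' Read a subgroup assignment table
#'
#' Tab-delimited, two columns: variety/accession id and subgroup label.
#'
#' @param path File path.
#' @return Named character vector mapping id to subgroup.
#' @export
read_subgroups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("subgroup table needs two columns (id, subgroup)")
  if (anyDuplicated(df[[1L]])) stop("duplicated id(s) in subgroup table")
  setNames(as.character(df[[2L]]), df[[1L]])
}

#' @rdname read_subgroups
#' @param subgroups Named character vector (id -> subgroup).
#' @param path File path.
#' @export
write_subgroups <- function(subgroups, path) {
  write.table(data.frame(id = names(subgroups), subgroup = subgroups),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
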