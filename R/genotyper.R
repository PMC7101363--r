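#' Genotype-calling thresholds
#'
#' The depth-based calling rule: the allele with the most reads is the
#' major allele; a record with major-allele depth below `min_major_depth`
#' is missing (`low_depth`); otherwise with major-allele ratio
#' r = major / (major + minor), r < `het_ratio_max` is a heterozygote,
#' r >= `hom_ratio_min` a homozygote for the major allele, and the band in
#' between is missing (`ambiguous_ratio`).
#'
#' @param min_major_depth Minimum major-allele read depth for a call.
#' @param het_ratio_max Upper (exclusive) ratio bound for a heterozygous
#'   call.
#' @param hom_ratio_min Lower (inclusive) ratio bound for a homozygous call.
#' @return An object of class `call_thresholds`.
#' @export
call_thresholds <- function(min_major_depth = 20L, het_ratio_max = 0.7,
                            hom_ratio_min = 0.8) {
  th <- list(min_major_depth = as.integer(min_major_depth),
             het_ratio_max = het_ratio_max, hom_ratio_min = hom_ratio_min)
  if (!(0.5 <= th$het_ratio_max && th$het_ratio_max <= th$hom_ratio_min &&
        th$hom_ratio_min <= 1)) {
    stop("need 0.5 <= het_ratio_max <= hom_ratio_min <= 1")
  }
  if (th$min_major_depth < 1L) stop("min_major_depth must be >= 1")
  structure(th, class = "call_thresholds")
}

#' Call one genotype from per-allele read depths
#'
#' The two deepest alleles are the major and minor allele (a depth tie is
#' called heterozygous, with the lexically smaller allele named major);
#' depths of any further alleles are ignored for the ratio but reported as
#' contamination depth.
#'
#' @param depths Named numeric vector of per-allele read counts.
#' @param thresholds A [call_thresholds].
#' @return List with `call` (canonical token or NA), `zygosity`
#'   (`"hom"`/`"het"`/`"missing"`), `major`, `minor`, `major_depth`,
#'   `minor_depth`, `total_depth`, `ratio`, `contamination_depth` and
#'   `reason` (`"low_depth"`, `"ambiguous_ratio"`, `"no_data"` or `"none"`).
#' @export
call_genotype <- function(depths, thresholds = call_thresholds()) {
  if (length(depths) == 0L || sum(depths) == 0) {
    return(list(call = NA_character_, zygosity = "missing",
                major = NA_character_, minor = NA_character_,
                major_depth = 0L, minor_depth = 0L, total_depth = 0L,
                ratio = NA_real_, contamination_depth = 0L,
                reason = "no_data"))
  }
  if (any(depths < 0)) stop("negative depth")
  if (is.null(names(depths)) || any(!nzchar(names(depths)))) {
    stop("depths must be named by allele")
  }
  ord <- order(-depths, names(depths))
  major <- names(depths)[ord[1L]]
  major_d <- unname(depths[ord[1L]])
  if (length(depths) > 1L) {
    minor <- names(depths)[ord[2L]]
    minor_d <- unname(depths[ord[2L]])
  } else {
    minor <- NA_character_; minor_d <- 0
  }
  contam <- sum(depths) - major_d - minor_d
  ratio <- major_d / (major_d + minor_d)
  th <- thresholds
  if (major_d < th$min_major_depth) {
    call <- NA_character_; zyg <- "missing"; reason <- "low_depth"
  } else if (ratio < th$het_ratio_max) {
    call <- format_call(major, minor); zyg <- "het"; reason <- "none"
  } else if (ratio >= th$hom_ratio_min) {
    call <- format_call(major, major); zyg <- "hom"; reason <- "none"
  } else {
    call <- NA_character_; zyg <- "missing"; reason <- "ambiguous_ratio"
  }
  list(call = call, zygosity = zyg, major = major, minor = minor,
       major_depth = major_d, minor_depth = minor_d,
       total_depth = sum(depths), ratio = ratio,
       contamination_depth = contam, reason = reason)
}

#' Call genotypes for every variety x locus record in a depth table
#'
#' Vectorised application of [call_genotype()] to a long allele-depth
#' table.
#'
#' @param depths A `depth_table` data.frame (see [read_depth_table()]).
#' @param thresholds A [call_thresholds].
#' @return data.frame of class `genotype_calls`: one row per variety x
#'   locus with the fields of [call_genotype()].
#' @export
call_genotypes <- function(depths, thresholds = call_thresholds()) {
  stopifnot(is.data.frame(depths),
            all(c("variety", "locus", "allele", "depth") %in% names(depths)))
  key <- paste(depths$variety, depths$locus, sep = "\r")
  ord <- order(key, -depths$depth, depths$allele, method = "radix")
  d <- depths[ord, ]
  k <- key[ord]
  grp_start <- !duplicated(k)
  rank_in_grp <- sequence(rle(k)$lengths)
  idx1 <- which(grp_start)
  n <- length(idx1)

  major <- d$allele[idx1]
  major_d <- d$depth[idx1]
  idx2 <- idx1 + 1L
  has2 <- idx2 <= nrow(d) & rank_in_grp[pmin(idx2, nrow(d))] == 2L
  minor <- ifelse(has2, d$allele[pmin(idx2, nrow(d))], NA_character_)
  minor_d <- ifelse(has2, d$depth[pmin(idx2, nrow(d))], 0L)
  # d is sorted by key, so rowsum's sorted-key order matches group order
  total <- as.vector(rowsum(as.numeric(d$depth), k))
  contam <- total - major_d - minor_d
  ratio <- ifelse(total > 0, major_d / (major_d + minor_d), NA_real_)

  th <- thresholds
  zyg <- rep("missing", n)
  call <- rep(NA_character_, n)
  reason <- rep("no_data", n)
  has_data <- total > 0
  low <- has_data & major_d < th$min_major_depth
  reason[low] <- "low_depth"
  het <- has_data & !low & ratio < th$het_ratio_max
  hom <- has_data & !low & ratio >= th$hom_ratio_min
  amb <- has_data & !low & !het & !hom
  reason[amb] <- "ambiguous_ratio"
  reason[het | hom] <- "none"
  zyg[het] <- "het"; zyg[hom] <- "hom"
  call[het] <- format_call(major[het], minor[het])
  call[hom] <- format_call(major[hom], major[hom])

  out <- data.frame(variety = d$variety[idx1], locus = d$locus[idx1],
                    call = call, zygosity = zyg,
                    major = major, minor = minor,
                    major_depth = major_d, minor_depth = minor_d,
                    total_depth = as.integer(total), ratio = ratio,
                    contamination_depth = as.integer(contam),
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' Assemble a genotype matrix from per-record calls
#'
#' @param calls A `genotype_calls` data.frame from [call_genotypes()].
#' @param panel Locus ids to include as columns (default: loci present in
#'   `calls`). Records for loci outside the panel are dropped with a
#'   warning.
#' @param varieties Variety ids to include as rows (default: varieties
#'   present in `calls`). Cells without a record are missing (`no_data`).
#' @return A [genotype_matrix].
#' @export
build_matrix <- function(calls, panel = NULL, varieties = NULL) {
  stopifnot(is.data.frame(calls),
            all(c("variety", "locus", "call") %in% names(calls)))
  if (is.null(panel)) panel <- unique(calls$locus)
  if (is.null(varieties)) varieties <- unique(calls$variety)
  outside <- !(calls$locus %in% panel)
  if (any(outside)) {
    warning(sum(outside), " record(s) for loci outside the panel dropped")
    calls <- calls[!outside, , drop = FALSE]
  }
  m <- matrix(NA_character_, length(varieties), length(panel),
              dimnames = list(varieties, panel))
  ri <- match(calls$variety, varieties)
  ci <- match(calls$locus, panel)
  keep <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[keep], ci[keep])] <- calls$call[keep]
  genotype_matrix(m)
}

#' QC summaries of a set of genotype calls
#'
#' Summarises the depth and major-allele-ratio distributions, per-locus and
#' per-variety coverage, and flags loci for exclusion when their
#' polymorphism is too low (PIC below `pic_min`) or their missing rate too
#' high (above `miss_max`).
#'
#' @param calls A `genotype_calls` data.frame.
#' @param stats Per-locus diversity table from [locus_stats()] (needs
#'   columns `locus` and `PIC`); `NULL` skips the PIC-based flag.
#' @param pic_min Exclusion threshold: PIC strictly below it flags the
#'   locus.
#' @param miss_max Exclusion threshold: missing rate strictly above it
#'   flags the locus.
#' @param depth_bands Depth band edges for the coverage summary.
#' @param thresholds The [call_thresholds] whose ratio bounds delimit the
#'   ratio bands.
#' @return List with `depth_bands` (fraction of records per band),
#'   `ratio_bands` (fractions with ratio < het bound, in the ambiguous
#'   band, and >= hom bound, plus `confident` = het + hom fractions),
#'   `locus_qc` (per-locus call rate, missing rate, mean depth, PIC, flag),
#'   `variety_depth` (mean depth per variety) and `excluded` (flagged locus
#'   ids).
#' @export
qc_summaries <- function(calls, stats = NULL, pic_min = 0.1, miss_max = 0.1,
                         depth_bands = c(100, 5000),
                         thresholds = call_thresholds()) {
  stopifnot(is.data.frame(calls))
  d <- calls$total_depth
  bands <- c(mean(d < depth_bands[1L]),
             mean(d >= depth_bands[1L] & d <= depth_bands[2L]),
             mean(d > depth_bands[2L]))
  names(bands) <- c(paste0("<", depth_bands[1L]),
                    paste0(depth_bands[1L], "-", depth_bands[2L]),
                    paste0(">", depth_bands[2L]))
  r <- calls$ratio[!is.na(calls$ratio)]
  rb <- c(het = mean(r < thresholds$het_ratio_max),
          ambiguous = mean(r >= thresholds$het_ratio_max &
                             r < thresholds$hom_ratio_min),
          hom = mean(r >= thresholds$hom_ratio_min))
  rb <- c(rb, confident = unname(rb["het"] + rb["hom"]))

  miss <- tapply(calls$zygosity == "missing", calls$locus, mean)
  mdep <- tapply(calls$total_depth, calls$locus, mean)
  locus_qc <- data.frame(locus = names(miss),
                         call_rate = 1 - as.vector(miss),
                         missing = as.vector(miss),
                         mean_depth = as.vector(mdep),
                         PIC = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(stats)) {
    locus_qc$PIC <- stats$PIC[match(locus_qc$locus, stats$locus)]
  }
  locus_qc$excluded <- locus_qc$missing > miss_max |
    (!is.na(locus_qc$PIC) & locus_qc$PIC < pic_min)
  vdep <- tapply(calls$total_depth, calls$variety, mean)
  list(depth_bands = bands, ratio_bands = rb, locus_qc = locus_qc,
       variety_depth = data.frame(variety = names(vdep),
                                  mean_depth = as.vector(vdep)),
       excluded = locus_qc$locus[locus_qc$excluded])
}
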