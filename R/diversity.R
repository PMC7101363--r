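#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` over allele frequencies
#' `p`. For a biallelic locus the maximum is 0.375 at p = 0.5.
#'
#' @param freqs Numeric vector of allele frequencies summing to 1.
#' @return PIC value in `[0, 1)`.
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  s2 <- sum(freqs^2)
  # sum_{i<j} 2 a_i a_j = (sum a)^2 - sum a^2 with a_i = p_i^2
  1 - s2 - (s2^2 - sum(freqs^4))
}

#' Simpson's index of diversity
#'
#' `D = 1 - sum(p_i^2)`; identical to Nei's expected heterozygosity at a
#' single locus.
#'
#' @inheritParams pic
#' @return D value in `[0, 1)`.
#' @export
simpson_d <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

check_freqs <- function(freqs) {
  if (any(freqs < 0)) stop("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  invisible(freqs)
}

#' Inbreeding coefficient
#'
#' `F = 1 - Ho / He`. Undefined (NA) when He is 0.
#'
#' @param ho Observed heterozygosity (fraction of heterozygous
#'   individuals).
#' @param he Expected heterozygosity.
#' @return F value (`<= 1`), or NA where `he` is 0.
#' @export
inbreeding_f <- function(ho, he) {
  ifelse(he > 0, 1 - ho / he, NA_real_)
}

#' Per-locus diversity statistics
#'
#' For each locus, allele frequencies over non-missing calls (two allele
#' copies per variety), MAF (frequency of the second most common allele),
#' observed heterozygosity Ho, expected heterozygosity He = 1 - sum(p^2)
#' (Nei's gene diversity; `corrected = TRUE` applies the small-sample
#' factor 2n/(2n - 1)), PIC, Simpson's D and the inbreeding coefficient
#' F = 1 - Ho/He.
#'
#' @param gm A [genotype_matrix].
#' @param loci Locus ids to include (default all).
#' @param varieties Variety ids to include (default all), e.g. one
#'   subpopulation.
#' @param corrected Apply the 2n/(2n-1) bias correction to He?
#' @return data.frame with one row per locus: `locus`, `n`, `MAF`, `Ho`,
#'   `He`, `PIC`, `D`, `F`.
#' @export
locus_stats <- function(gm, loci = NULL, varieties = NULL,
                        corrected = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(loci)) loci <- colnames(gm)
  if (is.null(varieties)) varieties <- rownames(gm)
  sub <- unclass(gm)[varieties, loci, drop = FALSE]
  out <- lapply(seq_along(loci), function(j) {
    v <- sub[, j]
    al <- split_calls(v)
    ok <- !is.na(al[, 1L])
    if (!any(ok)) stop("all calls missing at locus ", loci[j])
    copies <- c(al[ok, 1L], al[ok, 2L])
    p <- as.vector(table(copies)) / length(copies)
    n <- sum(ok)
    ho <- mean(al[ok, 1L] != al[ok, 2L])
    he <- 1 - sum(p^2)
    if (corrected) he <- he * 2 * n / (2 * n - 1)
    data.frame(locus = loci[j], n = n,
               MAF = if (length(p) > 1L) sort(p, decreasing = TRUE)[2L] else 0,
               Ho = ho, He = he, PIC = pic(p), D = simpson_d(p),
               F = inbreeding_f(ho, he), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-subpopulation diversity summary
#'
#' Means of the per-locus statistics across loci within each
#' subpopulation; with a kinship matrix supplied, also the mean pairwise
#' differential-genotype count within the subpopulation.
#'
#' @param gm A [genotype_matrix].
#' @param subgroups Named character vector (variety -> subgroup).
#' @param kinship Optional [differential_matrix()] result for the same
#'   varieties.
#' @param corrected Passed to [locus_stats()].
#' @return data.frame with one row per subpopulation: `subpop`,
#'   `n_varieties`, mean `PIC`, `MAF`, `Ho`, `He`, `F` and (if `kinship`
#'   given) `mean_diff_markers`.
#' @export
subpop_summary <- function(gm, subgroups, kinship = NULL,
                           corrected = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  grp <- subgroups[rownames(gm)]
  if (anyNA(grp)) stop("subgroup assignment missing for some varieties")
  labs <- unique(grp)
  out <- lapply(labs, function(g) {
    vs <- rownames(gm)[grp == g]
    if (!length(vs)) stop("empty subpopulation: ", g)
    st <- locus_stats(gm, varieties = vs, corrected = corrected)
    row <- data.frame(subpop = g, n_varieties = length(vs),
                      PIC = mean(st$PIC), MAF = mean(st$MAF),
                      Ho = mean(st$Ho), He = mean(st$He),
                      F = mean(st$F, na.rm = TRUE),
                      stringsAsFactors = FALSE)
    if (all(is.na(st$F))) row$F <- NA_real_
    if (!is.null(kinship)) {
      i <- match(vs, kinship$varieties)
      if (anyNA(i)) stop("kinship matrix does not cover subpopulation ", g)
      m <- kinship$diff[i, i, drop = FALSE]
      row$mean_diff_markers <- if (length(vs) > 1L) {
        mean(m[lower.tri(m)])
      } else {
        NA_real_
      }
    }
    row
  })
  do.call(rbind, out)
}
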