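#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical three-level variance decomposition of genotypic distance:
#' among populations, among individuals within populations, and within
#' individuals. Each individual contributes two allele copies; the squared
#' distance between two copies is the number of loci at which their alleles
#' differ (pairwise-complete over loci where both copies are non-missing).
#' Sums of squares are computed from the copy-level distance matrix, and
#' variance components follow from the expected mean squares of the nested
#' design with unequal population sizes. Negative components are reported
#' as computed; percentages are components over their sum times 100.
#'
#' @param gm A [genotype_matrix].
#' @param subgroups Named character vector (variety -> subgroup); every
#'   subpopulation needs at least two varieties.
#' @return An object of class `amova`: list with `table` (rows Among
#'   populations / Among individuals within populations / Within
#'   individuals / Total: `df`, `SS`, `MS`, `variance`, `percent`), `phi`
#'   (named vector with `F_ST`, `F_IS`, `F_IT`) and `n_c` (the
#'   unequal-size coefficient, in allele copies).
#' @export
amova <- function(gm, subgroups) {
  stopifnot(inherits(gm, "genotype_matrix"))
  grp <- subgroups[rownames(gm)]
  if (anyNA(grp)) stop("subgroup assignment missing for some varieties")
  sizes <- table(grp)
  if (length(sizes) < 2L) stop("AMOVA needs at least two subpopulations")
  if (any(sizes < 2L)) {
    stop("subpopulation(s) of size 1 (zero within-population df): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  N <- nrow(gm)
  P <- length(sizes)

  # copy-level allele matrix: 2N rows (copies), loci columns
  al <- split_calls(as.vector(unclass(gm)))
  c1 <- matrix(al[, 1L], N, ncol(gm))
  c2 <- matrix(al[, 2L], N, ncol(gm))
  copies <- rbind(c1, c2)                      # copy k and k+N belong to ind k
  copy_grp <- rep(as.character(grp), 2L)

  # D2[i, j] = number of pairwise-complete loci where copies differ
  n2 <- 2L * N
  D2 <- matrix(0, n2, n2)
  for (j in seq_len(ncol(copies))) {
    v <- copies[, j]
    neq <- outer(v, v, "!=")
    neq[is.na(neq)] <- FALSE
    D2 <- D2 + neq
  }

  ss_group <- function(idx) sum(D2[idx, idx]) / (2 * length(idx))
  SS_total <- ss_group(seq_len(n2))
  SS_wp <- sum(vapply(names(sizes), function(g)
    ss_group(which(copy_grp == g)), 0))
  SS_wi <- sum(D2[cbind(seq_len(N), seq_len(N) + N)]) / 2
  SS_ap <- SS_total - SS_wp
  SS_ai <- SS_wp - SS_wi

  df <- c(P - 1L, N - P, N)
  SS <- c(SS_ap, SS_ai, SS_wi)
  MS <- SS / df
  n_c <- (n2 - sum((2 * sizes)^2) / n2) / (P - 1L)
  sigma_c <- MS[3L]
  sigma_b <- (MS[2L] - MS[3L]) / 2
  sigma_a <- (MS[1L] - MS[2L]) / n_c
  comp <- c(sigma_a, sigma_b, sigma_c)
  pct <- 100 * comp / sum(comp)

  tab <- data.frame(
    source = c("Among populations", "Among individuals within populations",
               "Within individuals", "Total"),
    df = c(df, n2 - 1L),
    SS = c(SS, SS_total),
    MS = c(MS, SS_total / (n2 - 1L)),
    variance = c(comp, sum(comp)),
    percent = c(pct, 100),
    stringsAsFactors = FALSE)
  phi <- c(F_ST = sigma_a / sum(comp),
           F_IS = sigma_b / (sigma_b + sigma_c),
           F_IT = (sigma_a + sigma_b) / sum(comp))
  structure(list(table = tab, phi = phi, n_c = n_c), class = "amova")
}

#' @export
print.amova <- function(x, digits = 3, ...) {
  cat("Analysis of molecular variance\n")
  tab <- x$table
  tab$SS <- round(tab$SS, 1)
  tab$MS <- round(tab$MS, digits)
  tab$variance <- round(tab$variance, digits)
  tab$percent <- sprintf("%.1f%%", tab$percent)
  print(tab, row.names = FALSE)
  cat("Phi statistics: ",
      paste(names(x$phi), round(x$phi, digits), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

# Weir-Cockerham variance components (a, b, c) summed over loci and
# alleles for the populations in `pops`. Returns the component sums.
wc_components <- function(gm, subgroups, pops = NULL) {
  grp <- subgroups[rownames(gm)]
  if (anyNA(grp)) stop("subgroup assignment missing for some varieties")
  if (is.null(pops)) pops <- unique(grp)
  keep <- grp %in% pops
  m <- unclass(gm)[keep, , drop = FALSE]
  grp <- grp[keep]
  r <- length(pops)
  if (r < 2L) stop("need at least two populations")
  sum_a <- sum_bc <- 0
  for (j in seq_len(ncol(m))) {
    al <- split_calls(m[, j])
    ok <- !is.na(al[, 1L])
    if (!any(ok)) next
    n_i <- vapply(pops, function(g) sum(ok & grp == g), 0)
    if (any(n_i < 1)) next
    alleles <- unique(c(al[ok, 1L], al[ok, 2L]))
    if (length(alleles) < 2L) next
    nbar <- mean(n_i)
    n_c <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    if (n_c <= 0 || nbar <= 1) next
    for (a in alleles) {
      p_i <- vapply(pops, function(g) {
        sel <- ok & grp == g
        mean(c(al[sel, 1L] == a, al[sel, 2L] == a))
      }, 0)
      h_i <- vapply(pops, function(g) {
        sel <- ok & grp == g
        mean((al[sel, 1L] == a) != (al[sel, 2L] == a))
      }, 0)
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      va <- (nbar / n_c) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      vb <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r -
           hbar * (2 * nbar - 1) / (4 * nbar))
      vc <- hbar / 2
      sum_a <- sum_a + va
      sum_bc <- sum_bc + vb + vc
    }
  }
  list(a = sum_a, abc = sum_a + sum_bc)
}

#' Multi-locus Weir-Cockerham theta (Fst)
#'
#' The ratio-of-sums estimator `theta = sum(a) / sum(a + b + c)` over loci
#' and alleles, where a, b, c are the among-population, among-individual
#' and within-individual variance components.
#'
#' @param gm A [genotype_matrix].
#' @param subgroups Named character vector (variety -> subgroup).
#' @param pops Subset of subgroup labels to estimate over (default all).
#' @return Theta estimate (NA with a message when every locus is
#'   monomorphic across the chosen populations).
#' @export
wc_theta <- function(gm, subgroups, pops = NULL) {
  comp <- wc_components(gm, subgroups, pops)
  if (comp$abc == 0) {
    message("theta undefined: no polymorphic locus across populations")
    return(NA_real_)
  }
  comp$a / comp$abc
}

#' Pairwise Fst between subpopulations
#'
#' Weir-Cockerham theta for every pair of subpopulations.
#'
#' @param gm A [genotype_matrix].
#' @param subgroups Named character vector (variety -> subgroup).
#' @return List of class `pairwise_fst`: `pairs` (data.frame `pop1`,
#'   `pop2`, `theta`) and `matrix` (symmetric, zero diagonal).
#' @export
pairwise_fst <- function(gm, subgroups) {
  stopifnot(inherits(gm, "genotype_matrix"))
  grp <- subgroups[rownames(gm)]
  if (anyNA(grp)) stop("subgroup assignment missing for some varieties")
  labs <- unique(grp)
  if (length(labs) < 2L) stop("need at least two subpopulations")
  cmb <- combn(labs, 2L)
  theta <- apply(cmb, 2L, function(pr)
    suppressMessages(wc_theta(gm, subgroups, pops = pr)))
  mat <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (k in seq_len(ncol(cmb))) {
    mat[cmb[1L, k], cmb[2L, k]] <- mat[cmb[2L, k], cmb[1L, k]] <- theta[k]
  }
  structure(list(pairs = data.frame(pop1 = cmb[1L, ], pop2 = cmb[2L, ],
                                    theta = theta,
                                    stringsAsFactors = FALSE),
                 matrix = mat),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, digits = 3, ...) {
  cat("Pairwise Fst (Weir-Cockerham theta)\n")
  print(round(x$matrix, digits))
  invisible(x)
}
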