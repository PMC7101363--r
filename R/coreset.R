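#' Pairwise differential-genotype (kinship) matrix
#'
#' For every pair of varieties, the number of loci at which both calls are
#' non-missing and the unordered allele pairs differ; a missing genotype is
#' treated as null and never distinguishes a pair. The number of comparable
#' (both non-missing) loci is recorded alongside.
#'
#' @param gm A [genotype_matrix] with at least two varieties.
#' @return An object of class `kinship_matrix`: list with `varieties`,
#'   `diff` (symmetric count matrix, zero diagonal) and `comparable`
#'   (symmetric matrix of comparable-locus counts).
#' @export
differential_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm)
  if (n < 2L) stop("need at least two varieties")
  m <- unclass(gm)
  diffm <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  comp <- diffm
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    both <- outer(ok, ok, "&")
    ne <- outer(v, v, "!=")
    ne[!both] <- FALSE
    diffm <- diffm + ne
    comp <- comp + both
  }
  diag(diffm) <- 0L
  structure(list(varieties = rownames(m), diff = diffm, comparable = comp),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  n <- length(x$varieties)
  lt <- x$diff[lower.tri(x$diff)]
  cat("Differential-genotype matrix:", n, "varieties,",
      choose(n, 2), "pairs; mean differential count",
      round(mean(lt), 1), "\n")
  invisible(x)
}

# loci x pairs logical matrix: does locus l distinguish pair p?
# pairs are the strictly-lower-triangle entries in column-major order.
resolution_matrix <- function(gm) {
  m <- unclass(gm)
  n <- nrow(m)
  lt <- lower.tri(matrix(0, n, n))
  R <- matrix(FALSE, ncol(m), sum(lt))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    both <- outer(ok, ok, "&")
    ne <- outer(v, v, "!=")
    ne[!both] <- FALSE
    R[j, ] <- ne[lt]
  }
  rownames(R) <- colnames(m)
  R
}

#' Select a core SNP set that distinguishes variety pairs
#'
#' Greedy mode repeatedly adds the locus resolving the most currently
#' unresolved pairs (ties broken by higher PIC, then input locus order)
#' until no locus gains or `max_size` is reached. Exhaustive mode finds a
#' smallest subset reaching the same distinguished-pair count as the full
#' panel by size-increasing search (feasible only for small panels:
#' <= 25 loci and <= 50 varieties). A pair with a missing call at a locus
#' is not distinguished by that locus.
#'
#' @param gm A [genotype_matrix].
#' @param mode `"greedy"` or `"exhaustive"`.
#' @param max_size Stop after this many loci.
#' @param stats Optional [locus_stats()] table supplying PIC for the
#'   greedy tie-break; computed internally when NULL.
#' @return An object of class `core_set`: list with `loci` (selection
#'   order), `curve` (per added locus: cumulative `resolved` pairs,
#'   `fraction` of all pairs, `unique_varieties` fully separated from all
#'   others), `total_pairs`, `distinguishable` (pairs resolvable with the
#'   full panel), `unresolved` (data.frame of variety pairs left
#'   unresolved) and `mode`.
#' @export
select_core_snps <- function(gm, mode = c("greedy", "exhaustive"),
                             max_size = Inf, stats = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mode <- match.arg(mode)
  n <- nrow(gm)
  if (n < 2L) stop("need at least two varieties")
  R <- resolution_matrix(gm)
  total_pairs <- ncol(R)
  target <- sum(colSums(R) > 0L)
  pair_idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)

  if (mode == "exhaustive") {
    if (ncol(gm) > 25L || n > 50L) {
      stop("exhaustive search infeasible beyond 25 loci / 50 varieties; ",
           "use mode = \"greedy\"")
    }
    sel <- NULL
    for (k in seq_len(min(ncol(gm), max_size))) {
      combos <- combn(nrow(R), k)
      for (ci in seq_len(ncol(combos))) {
        idx <- combos[, ci]
        if (sum(colSums(R[idx, , drop = FALSE]) > 0L) == target) {
          sel <- idx
          break
        }
      }
      if (!is.null(sel)) break
    }
    if (is.null(sel)) sel <- seq_len(nrow(R))
    order_sel <- sel
  } else {
    if (is.null(stats)) stats <- locus_stats(gm)
    pic_v <- stats$PIC[match(rownames(R), stats$locus)]
    unresolved <- rep(TRUE, total_pairs)
    order_sel <- integer(0)
    remaining <- seq_len(nrow(R))
    while (length(order_sel) < max_size && length(remaining)) {
      gain <- rowSums(R[remaining, unresolved, drop = FALSE])
      if (max(gain) == 0L) break
      best <- which(gain == max(gain))
      if (length(best) > 1L) {
        best <- best[order(-pic_v[remaining][best], best)][1L]
      }
      pick <- remaining[best]
      order_sel <- c(order_sel, pick)
      unresolved <- unresolved & !R[pick, ]
      remaining <- setdiff(remaining, pick)
    }
  }

  loci <- rownames(R)[order_sel]
  resolved <- rep(FALSE, total_pairs)
  curve <- data.frame(k = seq_along(order_sel), locus = loci,
                      resolved = NA_integer_, fraction = NA_real_,
                      unique_varieties = NA_integer_)
  for (k in seq_along(order_sel)) {
    resolved <- resolved | R[order_sel[k], ]
    curve$resolved[k] <- sum(resolved)
    curve$fraction[k] <- sum(resolved) / total_pairs
    unres_var <- unique(c(pair_idx[!resolved, 1L], pair_idx[!resolved, 2L]))
    curve$unique_varieties[k] <- n - length(unres_var)
  }
  unres <- which(!resolved)
  structure(list(
    loci = loci,
    curve = curve,
    total_pairs = total_pairs,
    distinguishable = target,
    unresolved = data.frame(
      variety1 = rownames(gm)[pair_idx[unres, 2L]],
      variety2 = rownames(gm)[pair_idx[unres, 1L]],
      stringsAsFactors = FALSE),
    mode = mode), class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  k <- length(x$loci)
  res <- if (k) x$curve$resolved[k] else 0L
  cat("Core SNP set (", x$mode, "): ", k, " loci distinguishing ", res,
      "/", x$total_pairs, " variety pairs (",
      sprintf("%.1f%%", 100 * res / x$total_pairs), ")\n", sep = "")
  invisible(x)
}

#' Select core (backbone) varieties by kinship
#'
#' Within each subpopulation, varieties are ranked by their mean
#' differential-genotype count against the other members (ascending: the
#' most central first, ties broken by matrix order) and the top `fraction`
#' (ceiling) are marked as core varieties.
#'
#' @param km A [differential_matrix()] result.
#' @param subgroups Named character vector (variety -> subgroup).
#' @param fraction Fraction selected per subpopulation (default 0.1).
#' @return data.frame of class `core_varieties`: `variety`, `subpop`,
#'   `mean_diff`, `rank` (within subpopulation), `core` (logical).
#' @export
select_core_varieties <- function(km, subgroups, fraction = 0.1) {
  stopifnot(inherits(km, "kinship_matrix"))
  grp <- subgroups[km$varieties]
  if (anyNA(grp)) stop("subgroup assignment missing for some varieties")
  out <- lapply(unique(grp), function(g) {
    idx <- which(grp == g)
    if (!length(idx)) stop("empty subpopulation: ", g)
    sub <- km$diff[idx, idx, drop = FALSE]
    md <- if (length(idx) > 1L) rowSums(sub) / (length(idx) - 1L) else 0
    ord <- order(md, seq_along(idx))  # tie -> matrix order
    rank <- integer(length(idx)); rank[ord] <- seq_along(idx)
    n_core <- ceiling(fraction * length(idx))
    data.frame(variety = km$varieties[idx], subpop = g,
               mean_diff = md, rank = rank, core = rank <= n_core,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("core_varieties", "data.frame")
  out
}

#' Pearson correlation between two pairwise matrices
#'
#' Correlation over the strictly-lower-triangle entries of two symmetric
#' matrices with identical variety ordering; entry pairs with missing
#' values are dropped.
#'
#' @param m1,m2 Numeric symmetric matrices of equal dimension.
#' @return Pearson r (NA with a message when either triangle is constant).
#' @export
matrix_correlation <- function(m1, m2) {
  if (!all(dim(m1) == dim(m2))) stop("matrices must have equal dimensions")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("matrices must share the same variety ordering")
  }
  lt <- lower.tri(m1)
  x <- m1[lt]; y <- m2[lt]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) {
    message("matrix correlation undefined (constant or too few entries)")
    return(NA_real_)
  }
  cor(x, y)
}

#' Allele-sharing genetic distance and similarity
#'
#' Per pair of varieties, the mean over comparable (both non-missing) loci
#' of `(2 - shared) / 2`, where `shared` is the multiset intersection size
#' of the two unordered allele pairs (2 = identical genotype, 1 = one
#' allele in common, 0 = none). `genetic_similarity` is its complement.
#'
#' @param gm A [genotype_matrix].
#' @return Symmetric numeric matrix (NA for pairs with no comparable
#'   locus).
#' @export
genetic_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- unclass(gm)
  n <- nrow(m)
  num <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  den <- num
  for (j in seq_len(ncol(m))) {
    al <- split_calls(m[, j])
    ok <- !is.na(al[, 1L])
    both <- outer(ok, ok, "&")
    # multiset intersection of two sorted pairs = max(positional, crossed)
    pos_m <- outer(al[, 1L], al[, 1L], "==") + outer(al[, 2L], al[, 2L], "==")
    cross <- outer(al[, 1L], al[, 2L], "==") + outer(al[, 2L], al[, 1L], "==")
    shared <- pmax(pos_m, cross)
    d <- (2 - shared) / 2
    d[!both] <- 0
    num <- num + d
    den <- den + both
  }
  out <- num / den
  out[den == 0] <- NA_real_
  diag(out) <- 0
  out
}

#' @rdname genetic_distance
#' @export
genetic_similarity <- function(gm) {
  d <- genetic_distance(gm)
  s <- 1 - d
  diag(s) <- 1
  s
}
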