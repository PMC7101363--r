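test_that("differential counts follow the missing-as-null rule", {
  m <- rbind(v1 = c("A/A", "A/G"), v2 = c("A/A", "G/G"))
  colnames(m) <- c("L1", "L2")
  km <- differential_matrix(genotype_matrix(m))
  expect_equal(km$diff["v1", "v2"], 1L)
  expect_equal(km$comparable["v1", "v2"], 2L)

  m[1, 2] <- NA
  km2 <- differential_matrix(genotype_matrix(m))
  expect_equal(km2$diff["v1", "v2"], 0L)
  expect_equal(km2$comparable["v1", "v2"], 1L)
})

test_that("differential matrix equals a brute-force recount", {
  gm <- random_gm(30, 50, miss = 0.08, seed = 121)
  km <- differential_matrix(gm)
  expect_identical(unname(km$diff), unname(brute_diff_matrix(gm)))
  expect_true(all(km$diff == t(km$diff)))
  expect_true(all(diag(km$diff) == 0))
  expect_true(all(km$diff <= km$comparable))
})

test_that("a fully informative locus resolves all pairs on its own", {
  m <- matrix(c("A/A", "A/G", "G/G"), 3, 1,
              dimnames = list(paste0("v", 1:3), "L1"))
  cs <- select_core_snps(genotype_matrix(m))
  expect_equal(cs$loci, "L1")
  expect_equal(cs$curve$resolved, 3L)
  expect_equal(cs$curve$fraction, 1)
  expect_equal(cs$total_pairs, 3L)
})

test_that("identical varieties stay unresolved", {
  gm <- random_gm(8, 12, miss = 0, seed = 123)
  m <- unclass(gm)
  m["v02", ] <- m["v01", ]
  gm2 <- genotype_matrix(m)
  cs <- select_core_snps(gm2)
  expect_equal(cs$curve$fraction[length(cs$loci)],
               1 - 1 / choose(8, 2))
  expect_equal(nrow(cs$unresolved), 1L)
  expect_setequal(unlist(cs$unresolved[1, ]), c("v01", "v02"))
})

test_that("greedy matches the exhaustive optimum's coverage on small panels", {
  for (seed in 1:4) {
    gm <- random_gm(12, 15, miss = 0.05, seed = 130 + seed)
    greedy <- select_core_snps(gm, mode = "greedy")
    exact <- select_core_snps(gm, mode = "exhaustive")
    expect_gte(length(greedy$loci), length(exact$loci))
    full <- greedy$distinguishable
    expect_equal(greedy$curve$resolved[length(greedy$loci)], full)
    expect_equal(exact$curve$resolved[length(exact$loci)], full)
    # saturation curve is monotone non-decreasing
    expect_true(all(diff(greedy$curve$resolved) >= 0))
  }
  big <- random_gm(60, 30, seed = 140)
  expect_error(select_core_snps(big, mode = "exhaustive"), "greedy")
})

test_that("greedy selection is deterministic and permutation-stable", {
  gm <- random_gm(15, 20, miss = 0.05, seed = 151)
  cs1 <- select_core_snps(gm)
  cs2 <- select_core_snps(gm)
  expect_identical(cs1$loci, cs2$loci)
  perm <- sample(nrow(gm))
  gm_p <- genotype_matrix(unclass(gm)[perm, , drop = FALSE])
  cs3 <- select_core_snps(gm_p)
  expect_equal(cs3$curve$resolved[length(cs3$loci)],
               cs1$curve$resolved[length(cs1$loci)])
})

test_that("core varieties are the most central decile of each subpopulation", {
  # subpop of 20 -> ceil(0.1 * 20) = 2 selected
  gm <- random_gm(30, 40, miss = 0, seed = 161)
  sg <- setNames(rep(c("P1", "P2"), c(20, 10)), rownames(gm))
  km <- differential_matrix(gm)
  cv <- select_core_varieties(km, sg)
  expect_equal(sum(cv$core[cv$subpop == "P1"]), 2L)
  expect_equal(sum(cv$core[cv$subpop == "P2"]), 1L)

  # planted backbone: a variety equal to the subpop consensus is selected
  m <- unclass(gm)
  consensus <- apply(m[1:20, ], 2, function(x)
    names(sort(table(x), decreasing = TRUE))[1])
  m["v05", ] <- consensus
  km2 <- differential_matrix(genotype_matrix(m))
  cv2 <- select_core_varieties(km2, sg)
  expect_true(cv2$core[cv2$variety == "v05"])

  # all-identical subpop: ties broken by matrix order
  m3 <- matrix("A/A", 10, 5, dimnames = list(paste0("u", 1:10),
                                             paste0("L", 1:5)))
  m3[, 1] <- c("A/G", rep("A/A", 9))  # avoid degenerate all-equal matrix
  km3 <- differential_matrix(genotype_matrix(m3))
  cv3 <- select_core_varieties(km3, setNames(rep("P", 10), rownames(m3)))
  expect_equal(cv3$variety[cv3$core], "u2")  # first tie in matrix order
})

test_that("matrix correlation equals the brute-force triangle formula", {
  set.seed(171)
  mk <- function() {
    a <- matrix(rnorm(100), 10, 10)
    a <- a + t(a); diag(a) <- 0
    a
  }
  m1 <- mk(); m2 <- mk()
  lt <- lower.tri(m1)
  expect_equal(matrix_correlation(m1, m2), cor(m1[lt], m2[lt]))
  expect_equal(matrix_correlation(m1, m1), 1)
  expect_equal(matrix_correlation(m1, 5 - m1), -1)
  expect_message(r <- matrix_correlation(matrix(1, 4, 4), mk()[1:4, 1:4]),
                 "undefined")
  expect_true(is.na(r))
  expect_error(matrix_correlation(m1, m2[1:5, 1:5]), "dimensions")
})

test_that("distance, similarity and differential counts are coherent", {
  gm <- random_gm(12, 25, miss = 0.05, seed = 181)
  gd <- genetic_distance(gm)
  gs <- genetic_similarity(gm)
  km <- differential_matrix(gm)
  expect_equal(gs, 1 - gd, tolerance = 1e-12)
  expect_true(all(gd >= 0 & gd <= 1, na.rm = TRUE))
  # a pair differing at more loci is also more distant on average
  r <- matrix_correlation(km$diff, gd)
  expect_gt(r, 0.5)
  r2 <- matrix_correlation(gs, km$diff)
  expect_lt(r2, -0.5)

  # on structured data the three pairwise matrices are strongly coupled
  truth <- simulate_population(sim_config(subpop_sizes = c(15, 15, 15),
                                          n_loci = 80, seed = 182))
  gm_s <- truth$truth
  km_s <- differential_matrix(gm_s)
  expect_gt(matrix_correlation(km_s$diff, genetic_distance(gm_s)), 0.9)
  expect_lt(matrix_correlation(genetic_similarity(gm_s), km_s$diff), -0.9)

  # allele-sharing hand checks
  m <- rbind(v1 = c("A/G", "C/G", "A/A", "A/A"),
             v2 = c("A/G", "A/C", "A/G", "G/G"))
  colnames(m) <- paste0("L", 1:4)
  d <- genetic_distance(genotype_matrix(m))
  # shared: 2, 1, 1, 0 -> distances 0, .5, .5, 1 -> mean 0.5
  expect_equal(d["v1", "v2"], 0.5)
})
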