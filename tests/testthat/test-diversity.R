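mk_div_tab <- function(counts) {
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU_", seq_len(nrow(counts)))
  count_table(counts, data.frame(sample_id = colnames(counts),
                                 experiment = "E1", condition = "bare_soil"))
}

test_that("alpha diversity matches closed forms", {
  tab <- mk_div_tab(cbind(c(10, 0, 0, 0),      # single OTU
                          c(5, 5, 5, 5),       # uniform over 4
                          c(8, 4, 4, 0)))      # proportions (.5,.25,.25)
  a <- alpha_diversity(tab)
  expect_equal(a$observed, c(1, 4, 3))
  expect_equal(a$shannon[1], 0)
  expect_equal(a$simpson[1], 0)
  expect_equal(a$shannon[2], log(4), tolerance = 1e-12)
  expect_equal(a$simpson[2], 0.75, tolerance = 1e-12)
  expect_equal(a$shannon[3], 0.5 * log(2) + 0.5 * log(4), tolerance = 1e-12)
  # all-zero sample is an explicit failure naming the sample
  bad <- mk_div_tab(cbind(c(1, 1), c(0, 0)))
  expect_error(alpha_diversity(bad), "s2")
})

test_that("unweighted UniFrac matches branch-length enumeration", {
  # caterpillar tree (((A,B),C),D), all branch lengths 1
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  tab <- mk_div_tab(rbind(A = c(1, 1), B = c(1, 0), C = c(0, 2), D = c(0, 0)))
  d <- unweighted_unifrac(tab, tree)
  # union {A,B,C} spans branches A,B,C,(AB),(ABC) = 5; unique: B and C = 2
  expect_equal(d["s1", "s2"], 2 / 5, tolerance = 1e-12)
  expect_equal(d["s2", "s1"], d["s1", "s2"])
  # identical presence sets -> 0
  tab2 <- mk_div_tab(rbind(A = c(1, 3), B = c(2, 1), C = c(0, 0), D = c(0, 0)))
  expect_equal(unweighted_unifrac(tab2, tree)["s1", "s2"], 0)
  # disjoint tip sets on a star tree -> 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tab3 <- mk_div_tab(rbind(A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1)))
  expect_equal(unweighted_unifrac(tab3, star)["s1", "s2"], 1)
  # missing tips are listed
  tab4 <- mk_div_tab(rbind(A = c(1, 1), Z = c(1, 1)))
  expect_error(unweighted_unifrac(tab4, tree), "Z")
})

test_that("UniFrac values are distances in [0, 1] with zero diagonal", {
  tree <- ape::read.tree(text = "((A:0.5,B:1.2):0.3,(C:0.8,D:0.4):0.9);")
  set.seed(2)
  counts <- matrix(rpois(4 * 6, 2), 4, 6, dimnames = list(c("A", "B", "C", "D"), NULL))
  counts[, 1] <- c(1, 0, 0, 0)
  tab <- mk_div_tab(counts)
  d <- unweighted_unifrac(tab, tree)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diag(d) == 0))
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
})

test_that("PCoA round-trips Euclidean configurations", {
  set.seed(4)
  pts <- matrix(rnorm(8), 4, 2)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  ord <- pcoa_ordination(d)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))   # sorted non-increasing
  rec <- as.matrix(dist(ord$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  # Euclidean input: no meaningfully negative eigenvalues
  expect_true(all(ord$eigenvalues > -1e-9))
  # all-zero distances -> all-zero coordinates
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(abs(pcoa_ordination(z)$coordinates) < 1e-12))
  # asymmetric input fails
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(pcoa_ordination(bad), "symmetric")
})

test_that("PERMANOVA p-values respect the permutation floor and strata", {
  set.seed(3)
  x <- rbind(matrix(rnorm(60, 0), 10, 6), matrix(rnorm(60, 10), 10, 6))
  d <- as.matrix(dist(x)); rownames(d) <- colnames(d) <- paste0("s", 1:20)
  g <- rep(c("a", "b"), each = 10)
  pr <- permanova(d, g, n_permutations = 999, seed = 1)
  expect_equal(pr$p_value, 0.001)          # minimum attainable with 999
  expect_gte(pr$p_value, 1 / 1000)
  expect_true(pr$pseudo_F > 0)
  # strata identical to groups: no exchangeability, p = 1 (warned)
  expect_warning(pr2 <- permanova(d, g, strata = g, n_permutations = 99,
                                  seed = 1),
                 "single factor level")
  expect_equal(pr2$p_value, 1)
  # group size checks
  expect_error(permanova(d, c("a", rep("b", 19))), "at least 2 samples")
})

test_that("two-way PERMANOVA reports additive terms and flags no interaction", {
  set.seed(5)
  x <- matrix(rnorm(24 * 3), 24, 3)
  d <- as.matrix(dist(x)); rownames(d) <- colnames(d) <- paste0("s", 1:24)
  f1 <- rep(c("w", "p"), each = 12)
  f2 <- rep(c("SC", "IC"), 12)
  pr <- permanova(d, f1, factor2 = f2, n_permutations = 99, seed = 2)
  expect_equal(nrow(pr$terms), 2)
  expect_false(pr$interaction_included)
})

test_that("diversity group tests delegate to the standard rank tests", {
  set.seed(6)
  v <- c(rnorm(10, 0), rnorm(10, 3))
  g <- rep(c("a", "b"), each = 10)
  r <- diversity_group_test(v, g)
  expect_equal(r$test, "wilcoxon-mann-whitney")
  expect_equal(r$p_value,
               suppressWarnings(stats::wilcox.test(v ~ factor(g),
                                                   exact = FALSE)$p.value))
  g3 <- rep(c("a", "b", "c"), length.out = 20)
  r3 <- diversity_group_test(v, g3)
  expect_equal(r3$test, "kruskal-wallis")
  expect_equal(r3$p_value, stats::kruskal.test(v, factor(g3))$p.value)
  expect_true(is.matrix(r3$pairwise))
})
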