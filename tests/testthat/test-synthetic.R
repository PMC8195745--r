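test_that("planted precision matrices have the forced sparsity pattern", {
  th0 <- build_precision(5, NULL, 0.3)
  expect_equal(unclass(th0), diag(5), ignore_attr = TRUE)
  th <- build_precision(3, data.frame(i = 1, j = 2, sign = 1), 0.3)
  expect_true(th[1, 2] != 0)
  expect_equal(th[1, 3], 0)
  expect_equal(th[2, 3], 0)
  expect_true(min(eigen(th, symmetric = TRUE)$values) > 0)
  expect_error(build_precision(4, data.frame(i = 1, j = 1), 0.3), "self-loops")
  expect_error(build_precision(4, data.frame(i = 1, j = 2), 1.2), "strength")
})

test_that("partial correlations of the implied covariance equal the planted strength", {
  edges <- data.frame(i = c(1, 3), j = c(2, 4), sign = c(1, -1))
  th <- build_precision(4, edges, 0.4)
  # independent oracle: invert Theta numerically, then invert Sigma back and
  # normalise to partial correlations
  sigma <- solve(th)
  prec2 <- solve(sigma)
  r <- -prec2 / sqrt(outer(diag(prec2), diag(prec2)))
  expect_equal(r[1, 2], 0.4, tolerance = 1e-10)
  expect_equal(r[3, 4], -0.4, tolerance = 1e-10)
  expect_equal(r[1, 3], 0, tolerance = 1e-10)
  expect_equal(r[2, 4], 0, tolerance = 1e-10)
})

test_that("count simulation is seeded, correctly shaped, non-negative integer", {
  th <- build_precision(6, data.frame(i = 1, j = 2, sign = 1), 0.3)
  t1 <- simulate_pln_counts(th, rep(2, 6), 15, seed = 42)
  t2 <- simulate_pln_counts(th, rep(2, 6), 15, seed = 42)
  expect_identical(t1$counts, t2$counts)
  expect_equal(dim(t1$counts), c(6, 15))
  expect_true(all(t1$counts >= 0 & t1$counts == round(t1$counts)))
  expect_error(simulate_pln_counts(matrix(c(1, 2, 2, 1), 2), rep(0, 2), 5),
               "positive definite")
})

test_that("in the vanishing-latent-variance limit counts are Poisson with the offset mean", {
  # huge diagonal precision => Sigma ~ 0 => Y_ij ~ Poisson(exp(o_i + mu_j))
  p <- 4; n <- 2000
  th <- diag(1e8, p)
  mu <- c(1, 2, 2.5, 3)
  tab <- simulate_pln_counts(th, mu, n, depth_log_mean = 0.2,
                             depth_log_sd = 0.15, seed = 7)
  o <- attr(tab, "offsets")
  lambda <- exp(outer(mu, o, "+"))
  mc_se <- sqrt(rowMeans(lambda) / n)
  expect_true(all(abs(rowMeans(tab$counts) - rowMeans(lambda)) <= 3 * mc_se))
})

test_that("simulated counts are overdispersed relative to Poisson", {
  th <- build_precision(10, NULL, 0.3)   # unit latent variance
  tab <- simulate_pln_counts(th, rep(2.5, 10), 1500, depth_log_sd = 0, seed = 5)
  v <- apply(tab$counts, 1, var)
  m <- rowMeans(tab$counts)
  expect_true(all(v > m))   # PLN: Var = m + m^2 (e^{sigma^2} - 1) > m
})

test_that("study simulation matches its design and is self-consistent", {
  des <- tiny_design(seed = 3)
  sim <- simulate_study(des)
  expect_length(sim$tables, 10)   # 2 experiments x 5 conditions
  expect_equal(unname(vapply(sim$tables, n_samples, numeric(1))),
               rep(12, 10))
  # empty common set => empty common truth fraction
  des0 <- tiny_design(seed = 4, n_common_ic = 0)
  sim0 <- simulate_study(des0)
  expect_equal(n_edges(sim0$truth$fractions$common), 0)
  # no specific sets => all five condition precisions identical
  desb <- tiny_design(seed = 5, n_sc = 0, n_ic_specific = 0, n_common_ic = 0)
  simb <- simulate_study(desb)
  for (cond in desb$conditions)
    expect_equal(simb$truth$precisions[[cond]],
                 simb$truth$precisions$bare_soil)
  # overlapping planted sets are rejected with the colliding pair
  bad <- tiny_design(seed = 6)
  bad$common_ic_edges <- bad$backbone_edges[1, , drop = FALSE]
  expect_error(simulate_study(bad), "overlap on pairs")
})

test_that("netalgebra on the true edge lists returns the planted fractions exactly", {
  des <- tiny_design(seed = 11)
  sim <- simulate_study(des)
  tn <- sim$truth$networks
  interference <- tn[c("bare_soil", "wheat_SC", "pea_SC")]
  cw <- clean_ic_network(tn$wheat_IC, interference)
  cp <- clean_ic_network(tn$pea_IC, interference)
  fr <- split_fractions(cw, cp)
  expect_identical(edge_key_set(fr$common),
                   edge_key_set(sim$truth$fractions$common))
  expect_identical(edge_key_set(fr$unique_wheat),
                   edge_key_set(sim$truth$fractions$unique_wheat))
  expect_identical(edge_key_set(fr$unique_pea),
                   edge_key_set(sim$truth$fractions$unique_pea))
})

test_that("study simulation is reproducible end to end", {
  s1 <- simulate_study(tiny_design(seed = 8))
  s2 <- simulate_study(tiny_design(seed = 8))
  expect_identical(lapply(s1$tables, `[[`, "counts"),
                   lapply(s2$tables, `[[`, "counts"))
})
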