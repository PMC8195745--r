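test_that("graphical lasso solves the penalised likelihood (KKT + limits)", {
  set.seed(1)
  X <- matrix(rnorm(400 * 7), 400, 7)
  S <- stats::cov(X)
  gl <- glasso_fit(S, 0.08)
  W <- solve(gl$Theta)
  # stationarity: unpenalised diagonal exact, off-diagonals within the
  # subgradient bound |W - S| <= lambda
  expect_lt(max(abs(diag(W) - diag(S))), 1e-8)
  expect_true(all(abs((W - S)[upper.tri(S)]) <= 0.08 + 1e-6))
  # active edges sit exactly on the subgradient boundary
  act <- gl$support & upper.tri(S)
  if (any(act))
    expect_true(all(abs(abs((W - S)[act]) - 0.08) < 1e-4))
  # penalty -> 0 recovers the inverse covariance
  expect_equal(glasso_fit(S, 1e-9)$Theta, solve(S), tolerance = 1e-5,
               ignore_attr = TRUE)
  # penalty above the empty-support bound gives a diagonal estimate
  lam_max <- max(abs(S[upper.tri(S)]))
  expect_false(any(glasso_fit(S, lam_max * 1.01)$support))
})

test_that("the ELBO increases monotonically and the fit is deterministic", {
  th <- build_precision(8, data.frame(i = c(1, 3), j = c(2, 4)), 0.35)
  tab <- simulate_pln_counts(th, rep(3, 8), 60, seed = 2)
  f <- fit_pln(tab)
  expect_true(all(diff(f$elbo_trace) > -1e-8 * abs(f$elbo_trace[1])))
  f2 <- fit_pln(tab)
  expect_identical(f$Theta, f2$Theta)
  # Sigma is the inverse of Theta
  expect_lt(max(abs(f$Sigma %*% f$Theta - diag(8))), 1e-6)
})

test_that("a single-OTU table degenerates to a scalar latent variance", {
  th <- matrix(4, 1, 1)
  tab <- simulate_pln_counts(th, 2, 30, seed = 3)
  f <- fit_pln(tab, penalty = 0.5)    # penalty irrelevant at p = 1
  expect_equal(dim(f$Theta), c(1, 1))
  expect_true(f$Theta[1, 1] > 0)
  expect_true(all(diff(f$elbo_trace) > -1e-8 * abs(f$elbo_trace[1])))
})

test_that("in the large-count regime latent means approach log-count minus offset", {
  th <- diag(20, 5)    # small latent variance keeps all counts large
  tab <- simulate_pln_counts(th, rep(8, 5), 40, depth_log_sd = 0.05, seed = 2)
  expect_gt(min(tab$counts), 1000)
  f <- fit_pln(tab, offsets = attr(tab, "offsets"))
  target <- log(t(tab$counts)) - matrix(attr(tab, "offsets"), 40, 5)
  expect_lt(max(abs(f$M - target)), 0.05)
})

test_that("the penalty path moves from empty to dense support with non-decreasing fit", {
  th <- build_precision(10, data.frame(i = c(1, 3, 5), j = c(2, 4, 6)), 0.35)
  tab <- simulate_pln_counts(th, rep(3, 10), 80, seed = 4)
  f0 <- fit_pln(tab)
  pen <- default_penalty_grid(f0, 6)
  fits <- precision_path(tab, penalties = pen)
  sizes <- vapply(fits, function(f) f$criteria$n_edges, numeric(1))
  expect_equal(sizes[1], 0)                       # empty at the sparse end
  expect_gt(sizes[length(sizes)], sizes[1])       # dense end has edges
  r2 <- vapply(fits, function(f) f$criteria$pseudo_r2, numeric(1))
  expect_true(all(diff(r2) > -1e-6))              # nested models improve
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_equal(model_r2(fits), r2[length(r2)])
})

test_that("partial correlations follow the precision matrix exactly", {
  expect_equal(partial_correlation(diag(c(2, 3, 4))),
               diag(3), ignore_attr = TRUE)
  th <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(partial_correlation(th)[1, 2], 0.5)   # closed-form 2x2
  # sign rule: positive precision entry => negative partial correlation
  th2 <- matrix(c(2, 1, 1, 2), 2)
  expect_lt(partial_correlation(th2)[1, 2], 0)
  # sparsity pattern is reproduced exactly
  th3 <- build_precision(6, data.frame(i = 1, j = 4), 0.3)
  r <- partial_correlation(th3)
  expect_equal(r[2, 3], 0)
  expect_equal(r[1, 4], 0.3)
  expect_error(partial_correlation(diag(c(1, -1))), "non-positive")
})

test_that("network thresholding applies |r| and stability cutoffs", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.05
  r[1, 3] <- r[3, 1] <- 0.07
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  n1 <- threshold_network(r, 0.06)
  expect_equal(n_edges(n1), 1)
  expect_equal(n1$edges$otu_a, "a")
  expect_equal(n1$edges$otu_b, "c")
  # min_abs_r = 0 keeps every nonzero entry
  expect_equal(n_edges(threshold_network(r, 0)), 2)
  # everything below threshold -> empty network
  expect_equal(n_edges(threshold_network(r, 0.5)), 0)
  # stability filter removes low-frequency edges
  freq <- matrix(1, 3, 3); freq[1, 3] <- freq[3, 1] <- 0.5
  n2 <- threshold_network(r, 0, stability = freq, min_frequency = 0.9)
  expect_equal(n_edges(n2), 1)
  expect_equal(n2$edges$otu_b, "b")
})

test_that("edge instability is the binomial variance statistic", {
  p <- 6
  half <- matrix(0.5, p, p)
  expect_equal(rhizonet:::edge_instability(half), 0.5)
  sure <- matrix(sample(c(0, 1), p * p, TRUE), p, p)
  expect_equal(rhizonet:::edge_instability(sure), 0)
})

test_that("StARS defaults echo 30 subsamples and selects stable penalties", {
  cfg <- stars_config()
  expect_equal(cfg$n_subsamples, 30)
  expect_equal(cfg$instability_threshold, 0.05)
  th <- build_precision(8, data.frame(i = 1, j = 2), 0.45)
  tab <- simulate_pln_counts(th, rep(3.5, 8), 120, seed = 6)
  st <- stars_select(tab, config = stars_config(seed = 6), n_penalties = 10)
  expect_true(all(st$monotone_instability[seq_len(st$selected_index)] <=
                    0.05 + 1e-12))
  expect_identical(st$monotone_instability, cummax(st$instability))
  f <- st$frequencies[[st$selected_index]]
  expect_true(all(f >= 0 & f <= 1))
  # determinism
  st2 <- stars_select(tab, config = stars_config(seed = 6), n_penalties = 10)
  expect_equal(st$selected_penalty, st2$selected_penalty)
})

test_that("independent OTUs yield an empty selected network in almost all runs", {
  empties <- vapply(1:20, function(s) {
    th <- build_precision(10, NULL, 0.3)
    tab <- simulate_pln_counts(th, rep(3, 10), 100, seed = 1000 + s)
    inf <- infer_network(tab, n_penalties = 10, config = stars_config(seed = s))
    n_edges(inf$network) == 0
  }, logical(1))
  expect_gte(sum(empties), 19)   # >= 95% of 20 runs
})

test_that("a constant depth rescaling shifts offsets but not the selected support", {
  th <- build_precision(12, data.frame(i = c(1, 3), j = c(2, 4)), 0.4)
  tab <- simulate_pln_counts(th, rep(3, 12), 90, seed = 8)
  inf1 <- infer_network(tab, n_penalties = 8, config = stars_config(seed = 1))
  o <- log(colSums(tab$counts))
  inf2 <- infer_network(tab, offsets = o + 2.5, n_penalties = 8,
                        config = stars_config(seed = 1))
  expect_identical(edge_key_set(inf1$network), edge_key_set(inf2$network))
})
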