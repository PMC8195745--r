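#' @useDynLib rhizonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sparse inverse-covariance estimate by the graphical lasso
#'
#' Solves max_Theta log det(Theta) - tr(S Theta) - sum_jk Lambda_jk |Theta_jk|
#' with an unpenalised diagonal, by block coordinate descent. A scalar
#' `penalty` is expanded to a uniform off-diagonal penalty matrix.
#'
#' @param S symmetric positive-definite covariance matrix.
#' @param penalty scalar penalty, or a full penalty matrix.
#' @param warm optional list with `W` and `B` from a previous call (warm
#'   start along a penalty path).
#' @param tol convergence tolerance on the working covariance.
#' @return list with `Theta` (sparse symmetric precision), `support`
#'   (logical matrix of nonzero off-diagonals), `W`, `B`, `converged`.
#' @export
glasso_fit <- function(S, penalty, warm = NULL, tol = 1e-4) {
  p <- nrow(S)
  if (length(penalty) == 1) {
    Lambda <- matrix(penalty, p, p); diag(Lambda) <- 0
  } else Lambda <- penalty
  if (p == 1) {
    theta <- matrix(1 / S[1, 1], 1, 1)
    return(list(Theta = theta, support = matrix(FALSE, 1, 1),
                W = S, B = matrix(0, 1, 1), converged = TRUE))
  }
  if (is.null(warm)) {
    W <- S; B <- matrix(0, p, p)
  } else {
    W <- warm$W; B <- warm$B
  }
  res <- glasso_cpp(S, Lambda, W, B, tol = tol)
  theta <- res$Theta
  dimnames(theta) <- dimnames(S)
  support <- abs(theta) > 1e-10
  diag(support) <- FALSE
  list(Theta = theta, support = support, W = res$W, B = res$B,
       converged = res$converged)
}

# Evidence lower bound of the variational PLN approximation.
# Y, M, S2: n x p; offsets: length n; mu: length p; omega: p x p precision.
# logdet_omega is passed in to avoid recomputing determinants.
pln_elbo <- function(Y, offsets, M, S2, mu, omega, logdet_omega, penalty = 0) {
  n <- nrow(Y); p <- ncol(Y)
  O <- matrix(offsets, n, p)
  A <- exp(O + M + S2 / 2)
  ctr <- sweep(M, 2, mu)
  quad <- sum((ctr %*% omega) * ctr) + sum(colSums(S2) * diag(omega))
  elbo <- sum(Y * (O + M) - A - lgamma(Y + 1)) -
    0.5 * quad + 0.5 * n * logdet_omega + 0.5 * sum(log(S2)) + 0.5 * n * p
  if (penalty > 0)
    elbo <- elbo - 0.5 * n * penalty * (sum(abs(omega)) - sum(abs(diag(omega))))
  elbo
}

#' Fit the Poisson log-normal model with an optional sparsity penalty
#'
#' Counts Y_ij are modelled as Poisson(exp(o_i + Z_ij)) with latent
#' Z_i ~ MVN(mu, Sigma). The posterior of each Z_i is approximated by an
#' independent Gaussian with free mean and diagonal variance (variational
#' mean field); estimation alternates variational updates (with backtracking
#' so the evidence lower bound never decreases) and closed-form M-steps.
#' With `penalty > 0` the M-step for the precision matrix
#' Omega = Sigma^-1 is an L1-penalised inverse-covariance (graphical lasso)
#' step, giving a sparse Omega.
#'
#' @param table a `count_table` (or plain OTUs x samples count matrix).
#' @param offsets per-sample log-offsets; default log of per-sample total
#'   counts.
#' @param penalty L1 penalty on off-diagonal Omega (0 = dense MLE).
#' @param tol relative ELBO change declaring convergence (default 1e-4).
#' @param max_iter maximum alternations (default 200).
#' @param warm optional previous `pln_fit` used to warm-start a penalty
#'   path.
#' @return object of class `pln_fit`: `Theta`, `Sigma`, `support`,
#'   `penalty`, variational parameters `M`, `S2`, `mu`, `offsets`,
#'   `criteria` (loglik = final ELBO, bic, pseudo_r2), `elbo_trace`.
#' @export
fit_pln <- function(table, offsets = NULL, penalty = 0, tol = 1e-4,
                    max_iter = 200, warm = NULL) {
  Y <- if (inherits(table, "count_table")) t(table$counts) else t(as.matrix(table))
  n <- nrow(Y); p <- ncol(Y)
  if (n < 2) stop("at least two samples are required")
  if (is.null(offsets)) offsets <- log(pmax(rowSums(Y), 1))
  stopifnot(length(offsets) == n, all(is.finite(offsets)))
  otu_ids <- colnames(Y)
  if (is.null(otu_ids)) otu_ids <- sprintf("V%d", seq_len(p))

  if (is.null(warm)) {
    M <- log(Y + 0.5) - matrix(offsets, n, p)
    S2 <- matrix(0.1, n, p)
    mu <- colMeans(M)
    gl_state <- NULL
  } else {
    M <- warm$M; S2 <- warm$S2; mu <- warm$mu
    gl_state <- warm$gl_state
  }
  mstep <- function(M, S2, mu, gl_state) {
    ctr <- sweep(M, 2, mu)
    Sbar <- crossprod(ctr) / n + diag(colMeans(S2), p)
    if (penalty > 0) {
      gl <- glasso_fit(Sbar, penalty, warm = gl_state)
      list(omega = gl$Theta, gl_state = list(W = gl$W, B = gl$B),
           support = gl$support)
    } else {
      omega <- chol2inv(chol(Sbar))
      list(omega = omega, gl_state = NULL,
           support = matrix(TRUE, p, p) & !diag(p))
    }
  }
  ms <- mstep(M, S2, mu, gl_state)
  omega <- ms$omega; gl_state <- ms$gl_state
  ld <- as.numeric(determinant(omega, logarithm = TRUE)$modulus)
  elbo <- pln_elbo(Y, offsets, M, S2, mu, omega, ld, penalty)
  trace <- elbo
  O <- matrix(offsets, n, p)
  for (iter in seq_len(max_iter)) {
    # variational step: diagonally preconditioned Newton proposals with
    # geometric backtracking on (M, S2) jointly
    domega <- diag(omega)
    for (sweep_i in 1:2) {
      A <- exp(O + M + S2 / 2)
      S2_new <- 1 / (A + matrix(domega, n, p, byrow = TRUE))
      ctr <- sweep(M, 2, mu)
      G <- Y - A - ctr %*% omega
      H <- A + matrix(domega, n, p, byrow = TRUE)
      M_new <- M + G / H
      step <- 1
      repeat {
        M_try <- M + step * (M_new - M)
        S2_try <- exp(log(S2) + step * (log(S2_new) - log(S2)))
        e_try <- pln_elbo(Y, offsets, M_try, S2_try, mu, omega, ld, penalty)
        if (e_try >= elbo - 1e-10 * abs(elbo)) {
          M <- M_try; S2 <- S2_try; elbo <- e_try
          break
        }
        step <- step / 2
        if (step < 1e-4) break
      }
    }
    # M-step: closed-form mean, then (penalised) inverse covariance
    mu <- colMeans(M)
    ms <- mstep(M, S2, mu, gl_state)
    omega <- ms$omega; gl_state <- ms$gl_state
    ld <- as.numeric(determinant(omega, logarithm = TRUE)$modulus)
    elbo_new <- pln_elbo(Y, offsets, M, S2, mu, omega, ld, penalty)
    trace <- c(trace, elbo_new)
    delta <- abs(elbo_new - elbo) / (abs(elbo) + 1e-8)
    elbo <- elbo_new
    if (delta < tol) break
  }
  if (iter == max_iter && delta >= tol)
    stop(paste0("PLN fit did not converge in ", max_iter,
                " iterations (last relative change ", signif(delta, 3),
                "); ELBO trace tail: ",
                paste(signif(utils::tail(trace, 5), 8), collapse = ", ")))
  theta <- omega
  dimnames(theta) <- list(otu_ids, otu_ids)
  sigma <- chol2inv(chol(theta))
  dimnames(sigma) <- dimnames(theta)
  support <- ms$support
  dimnames(support) <- dimnames(theta)
  n_edges <- sum(support[upper.tri(support)])
  ll_null <- pln_null_loglik(Y, offsets)
  ll_sat <- pln_saturated_loglik(Y)
  r2 <- (elbo - ll_null) / (ll_sat - ll_null)
  clipped <- r2 < 0 || r2 > 1
  r2 <- min(max(r2, 0), 1)
  k_par <- 2 * p + n_edges
  structure(list(
    otu_ids = otu_ids, Theta = theta, Sigma = sigma, support = support,
    penalty = penalty, M = M, S2 = S2, mu = mu, offsets = offsets,
    gl_state = gl_state,
    criteria = list(loglik = elbo, bic = elbo - 0.5 * k_par * log(n),
                    pseudo_r2 = r2, r2_clipped = clipped,
                    loglik_null = ll_null, loglik_saturated = ll_sat,
                    n_edges = n_edges),
    elbo_trace = trace, iterations = iter), class = "pln_fit")
}

#' @export
print.pln_fit <- function(x, ...) {
  cat(sprintf("pln_fit: %d OTUs, penalty %.4g, %d edges, pseudo-R2 %.3f\n",
              length(x$otu_ids), x$penalty, x$criteria$n_edges,
              x$criteria$pseudo_r2))
  invisible(x)
}

# Poisson log-likelihood of the offset + per-OTU-mean model (no latent layer)
pln_null_loglik <- function(Y, offsets) {
  depth <- exp(offsets)
  tj <- colSums(Y) / sum(depth)
  lambda <- outer(depth, tj)
  sum(stats::dpois(Y, pmax(lambda, 1e-12), log = TRUE))
}

# Saturated Poisson log-likelihood: one free rate per observation
pln_saturated_loglik <- function(Y) {
  ll <- stats::dpois(Y, Y, log = TRUE)
  ll[Y == 0] <- 0
  sum(ll)
}

#' Penalty grid spanning the solution path
#'
#' 30 (by default) log-spaced penalties from the smallest value giving an
#' empty support (the largest absolute off-diagonal of the latent
#' covariance) down to 1/100 of it.
#'
#' @param fit an unpenalised `pln_fit` (used for its latent covariance), or
#'   a covariance matrix.
#' @param n_penalties grid size (default 30).
#' @param min_ratio ratio of smallest to largest penalty (default 0.01).
#' @return decreasing numeric vector.
#' @export
default_penalty_grid <- function(fit, n_penalties = 30, min_ratio = 0.01) {
  S <- if (inherits(fit, "pln_fit")) latent_covariance(fit) else fit
  lam_max <- max(abs(S[upper.tri(S)]))
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_penalties))
}

# Empirical covariance of the latent layer implied by the variational fit,
# optionally restricted to a subset of samples.
latent_covariance <- function(fit, rows = NULL) {
  M <- fit$M; S2 <- fit$S2
  if (!is.null(rows)) { M <- M[rows, , drop = FALSE]; S2 <- S2[rows, , drop = FALSE] }
  ctr <- sweep(M, 2, colMeans(M))
  S <- crossprod(ctr) / nrow(M) + diag(colMeans(S2), ncol(M))
  dimnames(S) <- list(fit$otu_ids, fit$otu_ids)
  S
}

#' Fit the sparse PLN model along a decreasing penalty path
#'
#' One penalised fit per penalty, each warm-started from the previous, so
#' the support grows as the penalty decreases.
#'
#' @param table a `count_table`.
#' @param offsets per-sample log-offsets (default log totals).
#' @param penalties strictly decreasing non-negative penalty grid.
#' @param tol,max_iter passed to [fit_pln()].
#' @return list of `pln_fit`, one per penalty.
#' @export
precision_path <- function(table, offsets = NULL, penalties, tol = 1e-4,
                           max_iter = 200) {
  stopifnot(length(penalties) >= 1, all(penalties >= 0),
            all(diff(penalties) < 0) || length(penalties) == 1)
  fits <- vector("list", length(penalties))
  warm <- NULL
  for (k in seq_along(penalties)) {
    fits[[k]] <- tryCatch(
      fit_pln(table, offsets, penalty = penalties[k], tol = tol,
              max_iter = max_iter, warm = warm),
      error = function(e) stop("path fit failed at penalty index ", k,
                               " (penalty ", signif(penalties[k], 4), "): ",
                               conditionMessage(e)))
    warm <- fits[[k]]
    warm$gl_state <- NULL   # penalty changes, lasso coefficients restart
    fits[[k]]$gl_state <- NULL
  }
  fits
}

#' StARS configuration
#'
#' @param n_subsamples number of random subsamples (default 30).
#' @param subsample_size number of samples per subsample; default
#'   `min(floor(10 * sqrt(n)), floor(0.8 * n))`.
#' @param instability_threshold target total instability (default 0.05).
#' @param seed integer seed.
#' @return object of class `stars_config`.
#' @export
stars_config <- function(n_subsamples = 30, subsample_size = NULL,
                         instability_threshold = 0.05, seed = 1) {
  stopifnot(n_subsamples >= 2,
            instability_threshold > 0, instability_threshold < 0.5)
  structure(list(n_subsamples = n_subsamples, subsample_size = subsample_size,
                 instability_threshold = instability_threshold, seed = seed),
            class = "stars_config")
}

# Mean edge instability 2 f (1 - f) over all possible pairs, from a p x p
# selection-frequency matrix.
edge_instability <- function(freq) {
  f <- freq[upper.tri(freq)]
  mean(2 * f * (1 - f))
}

#' Select the penalty by StARS stability selection
#'
#' The model is fitted once on the full data (unpenalised) to obtain the
#' variational latent positions; each of `n_subsamples` random
#' sample-subsets then contributes a latent covariance whose graphical-lasso
#' path yields one edge set per penalty. Per-edge selection frequencies f
#' give edge instabilities 2 f (1 - f); the total instability of a penalty
#' is the mean over all OTU pairs. The selected penalty is the smallest
#' (densest) one whose monotonised instability (running maximum from the
#' sparse end) stays at or below the threshold; if none qualifies the
#' sparsest penalty is returned.
#'
#' @param table a `count_table`.
#' @param offsets per-sample log-offsets (default log totals).
#' @param penalties decreasing penalty grid; default from
#'   [default_penalty_grid()].
#' @param config a [stars_config()].
#' @param fit optional pre-computed unpenalised `pln_fit` on the full data.
#' @param n_penalties grid size when `penalties` is NULL.
#' @return list: `selected_penalty`, `selected_index`, `instability`,
#'   `monotone_instability`, `frequencies` (list of p x p matrices, one per
#'   penalty), `penalties`, `fit` (the full-data unpenalised fit).
#' @export
stars_select <- function(table, offsets = NULL, penalties = NULL,
                         config = stars_config(), fit = NULL,
                         n_penalties = 30) {
  stopifnot(inherits(config, "stars_config"))
  if (is.null(fit)) fit <- fit_pln(table, offsets, penalty = 0)
  n <- nrow(fit$M); p <- ncol(fit$M)
  if (is.null(penalties))
    penalties <- default_penalty_grid(fit, n_penalties = n_penalties)
  b <- config$subsample_size
  if (is.null(b)) b <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  if (b < 3) stop("subsample size ", b, " is too small (need >= 3)")
  if (b >= n) stop("subsample size must be smaller than the number of samples")
  nk <- length(penalties)
  subs <- with_seed(config$seed, {
    lapply(seq_len(config$n_subsamples), function(i) sample.int(n, b))
  })
  Ssub <- lapply(subs, function(rows) latent_covariance(fit, rows))
  warm <- vector("list", config$n_subsamples)
  freq <- vector("list", nk)
  instab <- rep(NA_real_, nk)
  # walk the path from the sparse end; once the running-maximum instability
  # exceeds the threshold no denser penalty can be selected, so stop there
  mono_running <- 0
  last_k <- 0
  for (k in seq_len(nk)) {
    fr <- matrix(0, p, p)
    for (s in seq_len(config$n_subsamples)) {
      gl <- glasso_fit(Ssub[[s]], penalties[k], warm = warm[[s]], tol = 1e-3)
      warm[[s]] <- list(W = gl$W, B = gl$B)
      fr <- fr + gl$support
    }
    fr <- fr / config$n_subsamples
    dimnames(fr) <- list(fit$otu_ids, fit$otu_ids)
    freq[[k]] <- fr
    instab[k] <- edge_instability(fr)
    mono_running <- max(mono_running, instab[k])
    last_k <- k
    if (mono_running > config$instability_threshold && k > 1) break
  }
  instab <- instab[seq_len(last_k)]
  freq <- freq[seq_len(last_k)]
  mono <- cummax(instab)
  ok <- which(mono <= config$instability_threshold)
  idx <- if (length(ok) > 0) max(ok) else 1L
  list(selected_penalty = penalties[idx], selected_index = idx,
       instability = instab, monotone_instability = mono,
       frequencies = freq, penalties = penalties,
       penalties_visited = penalties[seq_len(last_k)], subsample_size = b,
       config = config, fit = fit)
}

#' Partial correlations from a precision matrix
#'
#' r_jk = -Theta_jk / sqrt(Theta_jj Theta_kk); exactly zero wherever
#' Theta_jk is zero, so the sparsity pattern is preserved.
#'
#' @param prec a `pln_fit`, or a positive-definite precision matrix.
#' @return symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_correlation <- function(prec) {
  theta <- if (inherits(prec, "pln_fit")) prec$Theta else prec
  d <- diag(theta)
  if (any(d <= 0)) stop("precision matrix has non-positive diagonal entries")
  r <- -theta / sqrt(outer(d, d))
  diag(r) <- 1
  r
}

#' Threshold a partial-correlation matrix into a signed network
#'
#' An edge (j, k) is called iff |r_jk| > `min_abs_r` and, when stability
#' frequencies are supplied, its selection frequency is at least
#' `min_frequency`. Edge weight is r_jk; nodes are the endpoints of
#' retained edges.
#'
#' @param parcor partial-correlation matrix (OTU ids as dimnames).
#' @param min_abs_r absolute partial-correlation threshold in `[0, 1)`.
#' @param stability optional matrix of per-edge selection frequencies.
#' @param min_frequency stability threshold (default 0.9).
#' @param label provenance label.
#' @return a `signed_network` (edges carry a `stability_frequency` column
#'   when `stability` is given).
#' @export
threshold_network <- function(parcor, min_abs_r = 0.06, stability = NULL,
                              min_frequency = 0.9, label = NA_character_) {
  stopifnot(min_abs_r >= 0, min_abs_r < 1)
  p <- nrow(parcor)
  ids <- rownames(parcor)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(p))
  ut <- which(upper.tri(parcor) & abs(parcor) > min_abs_r, arr.ind = TRUE)
  if (!is.null(stability)) {
    keep <- stability[ut] >= min_frequency
    ut <- ut[keep, , drop = FALSE]
  }
  if (nrow(ut) == 0) return(signed_network(label = label))
  edges <- data.frame(otu_a = ids[ut[, 1]], otu_b = ids[ut[, 2]],
                      weight = parcor[ut], stringsAsFactors = FALSE)
  if (!is.null(stability)) edges$stability_frequency <- stability[ut]
  signed_network(edges, label = label)
}

#' Pseudo-R2 of a fitted model within a criteria path
#'
#' pseudo_R2 = (loglik - loglik_null) / (loglik_saturated - loglik_null),
#' where the null model is the offset + per-OTU-intercept Poisson model and
#' the saturated model fits one rate per observation. Values are clipped to
#' `[0, 1]` (clipping is recorded by the fit).
#'
#' @param fits list of `pln_fit` (a penalty path) or a single fit.
#' @param index which fit to report; default the last (densest).
#' @return pseudo-R2 of the chosen fit.
#' @export
model_r2 <- function(fits, index = NULL) {
  if (inherits(fits, "pln_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  if (is.null(index)) index <- length(fits)
  f <- fits[[index]]
  if (abs(f$criteria$loglik_saturated - f$criteria$loglik_null) < 1e-12)
    stop("degenerate pseudo-R2: saturated and null log-likelihoods coincide")
  f$criteria$pseudo_r2
}

#' Infer a condition-specific signed network from counts
#'
#' The full per-condition recipe: unpenalised PLN fit for the latent
#' covariance, StARS stability selection of the graphical-lasso penalty, a
#' support-constrained refit of the precision matrix at the selected
#' support (removing lasso shrinkage from the partial correlations), and
#' thresholding on |partial correlation| and edge stability.
#'
#' @param table a `count_table` (samples of one condition).
#' @param offsets per-sample log-offsets (default log totals).
#' @param min_abs_r partial-correlation threshold (default 0.06).
#' @param min_frequency StARS edge-frequency threshold (default 0.9).
#' @param config a [stars_config()].
#' @param n_penalties penalty-grid size (default 30).
#' @param label provenance label for the network.
#' @return list: `network` (a `signed_network`), `parcor`, `stars`,
#'   `fit` (support-constrained refit at the selected penalty),
#'   `criteria` of the refit.
#' @export
infer_network <- function(table, offsets = NULL, min_abs_r = 0.06,
                          min_frequency = 0.9, config = stars_config(),
                          n_penalties = 30, label = NA_character_) {
  st <- stars_select(table, offsets, config = config,
                     n_penalties = n_penalties)
  S <- latent_covariance(st$fit)
  gl <- glasso_fit(S, st$selected_penalty)
  # debias: refit Theta restricted to the selected support
  refit <- support_refit(S, gl$support)
  parcor <- partial_correlation(refit)
  net <- threshold_network(parcor, min_abs_r = min_abs_r,
                           stability = st$frequencies[[st$selected_index]],
                           min_frequency = min_frequency, label = label)
  crit <- refit_criteria(st$fit, refit)
  list(network = net, parcor = parcor, stars = st, Theta = refit,
       support = gl$support, criteria = crit)
}

# Support-constrained precision refit: near-zero penalty on the allowed
# support, an effectively infinite penalty elsewhere.
support_refit <- function(S, support) {
  p <- nrow(S)
  if (p == 1 || !any(support)) return(diag(1 / diag(S), p))
  big <- 1e4 * max(abs(S))
  Lambda <- matrix(big, p, p)
  Lambda[support] <- 0
  diag(Lambda) <- 0
  gl <- glasso_fit(S, Lambda, tol = 1e-5)
  theta <- gl$Theta
  theta[!support & !diag(p)] <- 0
  dimnames(theta) <- dimnames(S)
  theta
}

# Criteria of the selected sparse model, evaluating the ELBO of the full
# variational fit under the refitted precision.
refit_criteria <- function(fit, theta) {
  n <- nrow(fit$M); p <- ncol(fit$M)
  ld <- as.numeric(determinant(theta, logarithm = TRUE)$modulus)
  ctr <- sweep(fit$M, 2, fit$mu)
  quad <- sum((ctr %*% theta) * ctr) + sum(colSums(fit$S2) * diag(theta))
  # data terms are unchanged between fits; reuse them from the stored ELBO:
  # loglik = stored ELBO - gaussian part(Omega_full) + gaussian part(theta)
  omega_full <- fit$Theta
  ld_full <- as.numeric(determinant(omega_full, logarithm = TRUE)$modulus)
  quad_full <- sum((ctr %*% omega_full) * ctr) +
    sum(colSums(fit$S2) * diag(omega_full))
  loglik <- fit$criteria$loglik +
    (-0.5 * quad + 0.5 * n * ld) - (-0.5 * quad_full + 0.5 * n * ld_full)
  n_edges <- sum(abs(theta[upper.tri(theta)]) > 1e-10)
  r2 <- (loglik - fit$criteria$loglik_null) /
    (fit$criteria$loglik_saturated - fit$criteria$loglik_null)
  list(loglik = loglik, bic = loglik - 0.5 * (2 * p + n_edges) * log(n),
       pseudo_r2 = min(max(r2, 0), 1), n_edges = n_edges)
}
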