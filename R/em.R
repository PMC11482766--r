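#' Ridge prior specification for MAP estimation
#'
#' Weakly informative matrix-normal priors are placed on the dynamics
#' matrices `A`, `B`, `B0`, `C`, with zero mean and scaled-identity
#' precisions. The covariance parameters `W`, `V`, `W1` carry the
#' (improper) reference measure under which the closed-form covariance
#' updates are exact stationary points of the log-posterior.
#'
#' @param lambda_A,lambda_B,lambda_B0,lambda_C nonnegative ridge precision
#'   scales (default `1e-6`, a scaled identity).
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(lambda_A = 1e-6, lambda_B = 1e-6,
                       lambda_B0 = 1e-6, lambda_C = 1e-6) {
  stopifnot(lambda_A >= 0, lambda_B >= 0, lambda_B0 >= 0, lambda_C >= 0)
  structure(list(lambda_A = lambda_A, lambda_B = lambda_B,
                 lambda_B0 = lambda_B0, lambda_C = lambda_C),
            class = "prior_spec")
}

#' E-step: sufficient statistics of the smoothed latent posterior
#'
#' Runs the RTS smoother and accumulates the nine sufficient statistics of
#' the expected complete-data log-posterior over `N` trials and `T`
#' timesteps: second moments of the smoothed state (`Mtt`, from which any
#' window `M(t1,t2)` can be summed), the lagged cross-moment `Mlag`,
#' input/state cross-moments (`Um`, `Udelta`, `Uu`, `Uu0`, `Udelta0`) and
#' observation moments (`Yy`, `Ydelta`). The smoothed covariances are shared
#' across trials, so each enters every statistic once per trial via the
#' trial count.
#'
#' @param params an `ssm_params` object.
#' @param data an `epoched_dataset`.
#' @param smoother optionally a precomputed [rts_smoother()] result.
#' @return list of class `suff_stats`; includes counts `N`, `T` and the
#'   forward-pass log-likelihood.
#' @export
estep <- function(params, data, smoother = NULL) {
  if (is.null(smoother)) smoother <- rts_smoother(params, data)
  d <- ssm_dims(params)
  n <- n_trials(data); T_ <- n_timesteps(data)
  m <- smoother$m                      # Dx x n x T

  Mtt <- vector("list", T_)            # per-t second moments E[x_t x_t']
  for (t in seq_len(T_)) {
    mt <- matrix(m[, , t], d$Dx, n)
    Mtt[[t]] <- mt %*% t(mt) + n * smoother$P[[t]]
  }
  Mlag <- matrix(0, d$Dx, d$Dx)        # sum_t E[x_{t-1} x_t']
  for (t in seq(2, length.out = T_ - 1)) {
    m0 <- matrix(m[, , t - 1], d$Dx, n); m1 <- matrix(m[, , t], d$Dx, n)
    Mlag <- Mlag + m0 %*% t(m1) + n * smoother$P_lag[[t]]
  }

  Um <- matrix(0, d$Dx, d$Du); Udelta <- matrix(0, d$Dx, d$Du)
  Uu <- matrix(0, d$Du, d$Du)
  for (t in seq_len(T_ - 1)) {
    ut <- matrix(data$U[, , t], nrow = n)             # n x Du
    Um <- Um + matrix(m[, , t], d$Dx, n) %*% ut
    Udelta <- Udelta + matrix(m[, , t + 1], d$Dx, n) %*% ut
    Uu <- Uu + t(ut) %*% ut
  }
  Uu0 <- t(data$U0) %*% data$U0
  Udelta0 <- matrix(m[, , 1], d$Dx, n) %*% data$U0

  Yy <- matrix(0, d$Dy, d$Dy); Ydelta <- matrix(0, d$Dx, d$Dy)
  for (t in seq_len(T_)) {
    yt <- matrix(data$Y[, , t], nrow = n)             # n x Dy
    Yy <- Yy + t(yt) %*% yt
    Ydelta <- Ydelta + matrix(m[, , t], d$Dx, n) %*% yt
  }

  structure(list(Mtt = Mtt, Mlag = Mlag, Um = Um, Udelta = Udelta, Uu = Uu,
                 Uu0 = Uu0, Udelta0 = Udelta0, Yy = Yy, Ydelta = Ydelta,
                 N = n, T = T_, Dx = d$Dx, Dy = d$Dy, Du = d$Du,
                 Du0 = d$Du0, loglik = smoother$total_loglik),
            class = "suff_stats")
}

#' Window sum of smoothed second moments, M(t1, t2)
#' @param stats a `suff_stats` object.
#' @param t1,t2 inclusive 1-based window bounds.
#' @return factors x factors moment matrix.
#' @export
stats_M <- function(stats, t1, t2) {
  Reduce(`+`, stats$Mtt[t1:t2])
}

#' Elementwise sum of two sufficient-statistic sets
#'
#' Statistics are additive over disjoint sets of trials with identical
#' parameters and epoch length.
#' @param a,b `suff_stats` computed with the same params and T.
#' @return combined `suff_stats`.
#' @export
add_stats <- function(a, b) {
  stopifnot(a$T == b$T, a$Dx == b$Dx)
  out <- a
  out$Mtt <- Map(`+`, a$Mtt, b$Mtt)
  for (nm in c("Mlag", "Um", "Udelta", "Uu", "Uu0", "Udelta0", "Yy", "Ydelta"))
    out[[nm]] <- a[[nm]] + b[[nm]]
  out$N <- a$N + b$N
  out$loglik <- a$loglik + b$loglik
  out
}

#' M-step: MAP parameter updates from sufficient statistics
#'
#' Closed-form ridge-regularized updates: `[A, B]` and `C` solve
#' regularized least-squares problems in the expected moments, `B0`
#' regresses the initial smoothed state on the initial-condition inputs, and
#' `W`, `V`, `W1` are expected residual quadratics (including the
#' prior-precision terms) normalized by `N(T-1) - Dx`, `N T - Dy`, and
#' `N - Dx` respectively. Returned covariances are symmetrized, with
#' eigenvalues floored at `1e-12` of their trace to keep the filter
#' runnable on degenerate over-parameterized fits.
#'
#' @param stats a `suff_stats` object from [estep()].
#' @param prior a `prior_spec`.
#' @return an `ssm_params` object.
#' @export
mstep <- function(stats, prior = prior_spec()) {
  Dx <- stats$Dx; Dy <- stats$Dy; Du <- stats$Du; Du0 <- stats$Du0
  N <- stats$N; T_ <- stats$T
  LA <- diag(prior$lambda_A, Dx); LB <- diag(prior$lambda_B, Du)
  LB0 <- diag(prior$lambda_B0, Du0); LC <- diag(prior$lambda_C, Dx)

  M11 <- stats_M(stats, 1, T_ - 1)               # sum_{t=1}^{T-1} E[x x']
  M22 <- stats_M(stats, 2, T_)
  M1T <- stats_M(stats, 1, T_)

  ## [A, B]: regression of x_t on [x_{t-1}; u_{t-1}]
  G <- rbind(cbind(M11 + LA, stats$Um),
             cbind(t(stats$Um), stats$Uu + LB))
  H <- rbind(stats$Mlag, t(stats$Udelta))        # (Dx+Du) x Dx: E[z x_t']
  AB <- tryCatch(t(solve(G, H)), error = function(e)
    stop("singular regularized Gram matrix in [A,B] update; increase the prior precision"))
  A <- AB[, seq_len(Dx), drop = FALSE]
  B <- AB[, Dx + seq_len(Du), drop = FALSE]

  ## C: regression of y_t on x_t
  C <- tryCatch(t(solve(M1T + LC, stats$Ydelta)), error = function(e)
    stop("singular regularized Gram matrix in C update; increase the prior precision"))

  ## B0: regression of x_1 on u_0
  B0 <- tryCatch(t(solve(stats$Uu0 + LB0, t(stats$Udelta0))), error = function(e)
    stop("singular regularized Gram matrix in B0 update; increase the prior precision"))

  ## covariance updates: expected residual quadratics + prior terms
  Qw <- M22 - A %*% stats$Mlag - t(stats$Mlag) %*% t(A) -
    stats$Udelta %*% t(B) - B %*% t(stats$Udelta) +
    A %*% M11 %*% t(A) + B %*% stats$Uu %*% t(B) +
    A %*% stats$Um %*% t(B) + B %*% t(stats$Um) %*% t(A) +
    A %*% LA %*% t(A) + B %*% LB %*% t(B)
  W <- psd_floor(symmetrize(Qw) / (N * (T_ - 1) - Dx))

  Qv <- stats$Yy - C %*% stats$Ydelta - t(stats$Ydelta) %*% t(C) +
    C %*% M1T %*% t(C) + C %*% LC %*% t(C)
  V <- psd_floor(symmetrize(Qv) / (N * T_ - Dy))

  Qw1 <- stats$Mtt[[1]] - B0 %*% t(stats$Udelta0) - stats$Udelta0 %*% t(B0) +
    B0 %*% stats$Uu0 %*% t(B0) + B0 %*% LB0 %*% t(B0)
  W1 <- psd_floor(symmetrize(Qw1) / (N - Dx))

  ssm_params(A = A, B = B, C = C, W = W, V = V, B0 = B0, W1 = W1)
}

## floor eigenvalues at 1e-12 of the trace (degenerate over-parameterized fits)
psd_floor <- function(S, rel = 1e-12) {
  e <- eigen(symmetrize(S), symmetric = TRUE)
  floor_ <- rel * max(sum(pmax(e$values, 0)), 1e-300)
  ev <- pmax(e$values, floor_)
  symmetrize(e$vectors %*% (ev * t(e$vectors)))
}

#' Log-density of the parameter prior
#'
#' Matrix-normal ridge priors on `A`, `B`, `B0`, `C` (row covariances `W`,
#' `W`, `W1`, `V`; column precisions from the `prior_spec`) plus the
#' reference measure on `W`, `V`, `W1` under which the M-step covariance
#' normalizers are exact. Constants independent of the parameters are
#' dropped. The sum `kalman_filter()$total_loglik + log_prior()` is the
#' training objective that EM increases monotonically.
#'
#' @param params an `ssm_params`.
#' @param prior a `prior_spec`.
#' @return scalar log-density (up to an additive constant).
#' @export
log_prior <- function(params, prior = prior_spec()) {
  Dx <- nrow(params$A); Dy <- nrow(params$C)
  Rw <- chol_jitter(params$W, "W"); Rv <- chol_jitter(params$V, "V")
  Rw1 <- chol_jitter(params$W1, "W1")
  quad <- function(R, X, lam) {
    if (ncol(X) == 0 || lam == 0) return(0)
    Z <- backsolve(R, X, transpose = TRUE)
    lam * sum(Z * Z)
  }
  -0.5 * (quad(Rw, params$A, prior$lambda_A) +
          quad(Rw, params$B, prior$lambda_B) +
          quad(Rw1, params$B0, prior$lambda_B0) +
          quad(Rv, params$C, prior$lambda_C)) +
    0.5 * Dx * logdet_chol(Rw) + 0.5 * Dy * logdet_chol(Rv) +
    0.5 * Dx * logdet_chol(Rw1)
}

#' Expected complete-data log-posterior given sufficient statistics
#'
#' Evaluates the EM surrogate objective (expected log joint of latents and
#' data plus the log prior) at a parameter set, using statistics computed
#' under some posterior. Includes the `log 2*pi` constants so traces are
#' comparable across models. One M-step from `stats` maximizes this
#' quantity over the parameters.
#'
#' @param params an `ssm_params`.
#' @param stats a `suff_stats`.
#' @param prior a `prior_spec`.
#' @return scalar.
#' @export
expected_log_posterior <- function(params, stats, prior = prior_spec()) {
  Dx <- stats$Dx; Dy <- stats$Dy; N <- stats$N; T_ <- stats$T
  A <- params$A; B <- params$B; C <- params$C; B0 <- params$B0
  LA <- diag(prior$lambda_A, Dx); LB <- diag(prior$lambda_B, stats$Du)
  LB0 <- diag(prior$lambda_B0, stats$Du0); LC <- diag(prior$lambda_C, Dx)
  M11 <- stats_M(stats, 1, T_ - 1); M22 <- stats_M(stats, 2, T_)
  M1T <- stats_M(stats, 1, T_)

  Qw <- M22 - A %*% stats$Mlag - t(stats$Mlag) %*% t(A) -
    stats$Udelta %*% t(B) - B %*% t(stats$Udelta) +
    A %*% M11 %*% t(A) + B %*% stats$Uu %*% t(B) +
    A %*% stats$Um %*% t(B) + B %*% t(stats$Um) %*% t(A) +
    A %*% LA %*% t(A) + B %*% LB %*% t(B)
  Qv <- stats$Yy - C %*% stats$Ydelta - t(stats$Ydelta) %*% t(C) +
    C %*% M1T %*% t(C) + C %*% LC %*% t(C)
  Qw1 <- stats$Mtt[[1]] - B0 %*% t(stats$Udelta0) - stats$Udelta0 %*% t(B0) +
    B0 %*% stats$Uu0 %*% t(B0) + B0 %*% LB0 %*% t(B0)

  Rw <- chol_jitter(params$W, "W"); Rv <- chol_jitter(params$V, "V")
  Rw1 <- chol_jitter(params$W1, "W1")
  tr_solve <- function(R, Q) {
    sum(diag(chol2inv(R) %*% Q))
  }
  -0.5 * ((N * (T_ - 1) - Dx) * logdet_chol(Rw) + tr_solve(Rw, Qw) +
          (N * T_ - Dy) * logdet_chol(Rv) + tr_solve(Rv, Qv) +
          (N - Dx) * logdet_chol(Rw1) + tr_solve(Rw1, Qw1) +
          N * (T_ - 1) * Dx * log(2 * pi) + N * T_ * Dy * log(2 * pi) +
          N * Dx * log(2 * pi))
}

#' Fit a state-space model by MAP expectation-maximization
#'
#' Alternates [estep()] and [mstep()] from an initialization (typically
#' [cva_identify()] output). The held-out log-likelihood of `data_test` is
#' measured every `check_every` iterations; fitting terminates when the
#' training objective stops improving between checkpoints, when the
#' held-out log-likelihood stops improving between checkpoints, or at
#' `max_iter`. The returned parameters are those of the best held-out
#' checkpoint.
#'
#' @param data_train,data_test disjoint `epoched_dataset`s. `data_test` may
#'   be `NULL`, in which case only the training criterion is used.
#' @param init initial `ssm_params`.
#' @param prior a `prior_spec`.
#' @param max_iter maximum EM iterations.
#' @param check_every checkpoint interval in iterations.
#' @param verbose print checkpoint progress.
#' @return list with `params` (best checkpoint), `trace` (data.frame of
#'   class `fit_trace`: iteration, training objective, held-out
#'   log-likelihood at checkpoints), and `termination` reason.
#' @export
fit_em <- function(data_train, data_test = NULL, init, prior = prior_spec(),
                   max_iter = 500L, check_every = 10L, verbose = FALSE) {
  params <- validate_ssm_params(init)
  obj_fun <- function(p) kalman_filter(p, data_train)$total_loglik + log_prior(p, prior)

  best_test <- -Inf; best_params <- params
  prev_train <- -Inf; prev_test <- -Inf
  rows <- list(); termination <- "max_iter"
  iter <- 0L
  train_obj <- NA_real_
  repeat {
    ## checkpoint
    train_obj_new <- obj_fun(params)
    test_ll <- if (!is.null(data_test))
      kalman_filter(params, data_test)$total_loglik else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      iteration = iter, train_objective = train_obj_new, test_loglik = test_ll)
    if (verbose)
      message(sprintf("iter %5d  train %.4f  test %s", iter, train_obj_new,
                      format(test_ll)))
    if (is.finite(prev_train) &&
        train_obj_new < prev_train - 1e-6 * abs(prev_train) - 1e-8) {
      termination <- "diverged"
      warning(sprintf(
        "training objective decreased at iteration %d (%.6g -> %.6g)",
        iter, prev_train, train_obj_new))
      break
    }
    if (!is.null(data_test) && test_ll > best_test) {
      best_test <- test_ll; best_params <- params
    }
    stop_train <- is.finite(prev_train) &&
      (train_obj_new - prev_train) <= 1e-10 * abs(prev_train)
    stop_test <- !is.null(data_test) && is.finite(prev_test) &&
      (test_ll - prev_test) <= 0
    if (iter > 0 && (stop_train || stop_test)) {
      termination <- if (stop_test && !stop_train) "test_loglik_stopped_improving"
                     else "train_objective_stopped_improving"
      break
    }
    prev_train <- train_obj_new; prev_test <- test_ll
    if (iter >= max_iter) { termination <- "max_iter"; break }

    ## run check_every EM iterations
    n_run <- min(check_every, max_iter - iter)
    for (k in seq_len(n_run)) {
      stats <- estep(params, data_train)
      params <- mstep(stats, prior)
    }
    iter <- iter + n_run
  }
  if (is.null(data_test)) best_params <- params
  trace <- do.call(rbind, rows)
  class(trace) <- c("fit_trace", class(trace))
  attr(trace, "termination") <- termination
  list(params = best_params, trace = trace, termination = termination)
}
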