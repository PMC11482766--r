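#' Kalman filter for an epoched dataset
#'
#' Runs the forward filter on every trial simultaneously. Because the filtered
#' covariances do not depend on the observed values, a single covariance
#' recursion is shared across trials; only the means are per trial. The filter
#' is initialized with prior mean `B0 u_0` and covariance `W1`, and returns
#' the exact log marginal likelihood `sum_t log p(y_t | y_{1:t-1})` per trial.
#'
#' Covariance updates are symmetrized after every step and log-determinants
#' use Cholesky factorizations; a jitter of `1e-10 * mean(diag)` is added only
#' when a Cholesky factorization fails (with a message), since
#' over-parameterized models are near-singular by construction.
#'
#' @param params an `ssm_params` object.
#' @param data an `epoched_dataset` (NaNs are rejected).
#' @return list of class `ssm_filter` with elements:
#'   `m` filtered means (factors x trials x T);
#'   `P` filtered covariances, list over t (shared across trials);
#'   `m_pred`, `P_pred` one-step predictions;
#'   `loglik` per-trial log marginal likelihood;
#'   `total_loglik` their sum.
#' @export
kalman_filter <- function(params, data) {
  validate_ssm_params(params)
  if (anyNA(data$Y)) stop("NaN in data")
  d <- ssm_dims(params)
  n <- n_trials(data); T_ <- n_timesteps(data)
  if (dim(data$Y)[2] != d$Dy) stop("observed dims of data and params differ")
  if (dim(data$U)[2] != d$Du) stop("input dims of data and params differ")
  if (ncol(data$U0) != d$Du0) stop("init-input dims of data and params differ")

  A <- params$A; B <- params$B; C <- params$C
  W <- params$W; V <- params$V

  m <- array(0, dim = c(d$Dx, n, T_))
  m_pred <- array(0, dim = c(d$Dx, n, T_))
  P <- vector("list", T_); P_pred <- vector("list", T_)
  loglik <- numeric(n)
  cst <- d$Dy * log(2 * pi)

  mp <- params$B0 %*% t(data$U0)           # Dx x n prior mean at t = 1
  Pp <- symmetrize(params$W1)
  for (t in seq_len(T_)) {
    if (t > 1) {
      ut <- matrix(data$U[, , t - 1], nrow = n)
      mp <- A %*% m[, , t - 1, drop = TRUE] + B %*% t(ut)
      mp <- matrix(mp, d$Dx, n)
      Pp <- symmetrize(A %*% P[[t - 1]] %*% t(A) + W)
    }
    m_pred[, , t] <- mp; P_pred[[t]] <- Pp

    yt <- t(matrix(data$Y[, , t], nrow = n))          # Dy x n
    e <- yt - C %*% mp                                # innovations
    S <- symmetrize(C %*% Pp %*% t(C) + V)
    R <- tryCatch(chol_jitter(S, sprintf("innovation covariance at t=%d", t)),
                  error = function(err)
                    stop(sprintf("singular innovation covariance at timestep %d", t)))
    ## K = Pp C' S^-1 via the Cholesky factor
    CS <- Pp %*% t(C)
    K <- t(backsolve(R, backsolve(R, t(CS), transpose = TRUE)))
    m[, , t] <- mp + K %*% e
    Pf <- symmetrize(Pp - K %*% C %*% Pp)
    P[[t]] <- Pf
    z <- backsolve(R, e, transpose = TRUE)
    loglik <- loglik - 0.5 * (cst + logdet_chol(R) + colSums(z * z))
  }
  structure(list(m = m, P = P, m_pred = m_pred, P_pred = P_pred,
                 loglik = loglik, total_loglik = sum(loglik)),
            class = "ssm_filter")
}

#' Rauch-Tung-Striebel smoother
#'
#' Backward pass computing smoothed means per trial and smoothed covariances
#' and lag-one covariances per timestep (shared across trials, since for
#' fixed parameters they do not depend on the observed values).
#'
#' @param params an `ssm_params` object.
#' @param data an `epoched_dataset`.
#' @param filter optionally, a precomputed result of [kalman_filter()].
#' @return list of class `ssm_smoother` with elements:
#'   `m` smoothed means (factors x trials x T);
#'   `P` smoothed covariances per t;
#'   `P_lag` lag-one covariances, `P_lag[[t]] = Cov(x_{t-1}, x_t | y_{1:T})`
#'   for t >= 2;
#'   `loglik`, `total_loglik` from the forward pass.
#' @export
rts_smoother <- function(params, data, filter = NULL) {
  if (is.null(filter)) filter <- kalman_filter(params, data)
  A <- params$A
  Dx <- nrow(A); T_ <- n_timesteps(data); n <- n_trials(data)

  ms <- filter$m; Ps <- vector("list", T_); P_lag <- vector("list", T_)
  Ps[[T_]] <- filter$P[[T_]]
  J <- vector("list", T_)
  for (t in rev(seq_len(T_ - 1))) {
    Ppn <- filter$P_pred[[t + 1]]
    R <- chol_jitter(Ppn, sprintf("predicted covariance at t=%d", t + 1))
    ## J_t = P_t A' (P_pred_{t+1})^-1
    Jt <- t(backsolve(R, backsolve(R, A %*% filter$P[[t]], transpose = TRUE)))
    J[[t]] <- Jt
    dm <- ms[, , t + 1, drop = TRUE] - filter$m_pred[, , t + 1, drop = TRUE]
    ms[, , t] <- matrix(filter$m[, , t], Dx, n) + Jt %*% matrix(dm, Dx, n)
    Ps[[t]] <- symmetrize(filter$P[[t]] + Jt %*% (Ps[[t + 1]] - Ppn) %*% t(Jt))
  }
  for (t in seq(2, length.out = max(T_ - 1, 0))) {
    P_lag[[t]] <- J[[t - 1]] %*% Ps[[t]]   # Cov(x_{t-1}, x_t | y_{1:T})
  }
  structure(list(m = ms, P = Ps, P_lag = P_lag,
                 loglik = filter$loglik, total_loglik = filter$total_loglik),
            class = "ssm_smoother")
}
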