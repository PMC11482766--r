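#' Construct an epoched multi-trial dataset
#'
#' Container for trials x dimensions x timesteps arrays plus the per-trial
#' condition labels and the input design. The time convention is 1-based:
#' `U[, , t]` drives the state at `t + 1`, and `U0` drives only the initial
#' condition. Every trial has the same epoch length `T`.
#'
#' @param Y observations, array (trials x observed dims x T).
#' @param U inputs, array (trials x input dims x T-1); may have 0 input dims.
#' @param U0 initial-condition inputs, matrix (trials x init-input dims).
#' @param labels data.frame of per-trial conditions. Task labels are expected
#'   contrast-coded (-1/+1) in columns such as `task` and `prev_task`, with a
#'   logical/0-1 `switch` flag; extra covariates are allowed.
#' @param meta list of metadata (sampling interval, event boundaries in
#'   sample indices such as cue/delay/trial onsets).
#' @return an object of class `epoched_dataset`.
#' @export
epoched_dataset <- function(Y, U = NULL, U0 = NULL, labels = NULL, meta = list()) {
  Y <- as_trial_array(Y, "Y")
  n <- dim(Y)[1]; T_ <- dim(Y)[3]
  if (is.null(U)) U <- array(0, dim = c(n, 0, T_ - 1))
  U <- as_trial_array(U, "U")
  if (is.null(U0)) U0 <- matrix(1, n, 1)
  U0 <- as.matrix(U0)
  if (dim(U)[1] != n || nrow(U0) != n)
    stop("Y, U, U0 must agree on the number of trials")
  if (dim(U)[3] != T_ - 1)
    stop("U must have T-1 timesteps (U[, , t] drives the state at t+1)")
  if (anyNA(Y) || anyNA(U) || anyNA(U0))
    stop("NaN/NA in data are not supported; epochs must be complete")
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(n))
  if (nrow(labels) != n) stop("labels must have one row per trial")
  structure(list(Y = Y, U = U, U0 = U0, labels = labels, meta = meta),
            class = "epoched_dataset")
}

as_trial_array <- function(x, name) {
  if (length(dim(x)) != 3) stop(sprintf("%s must be a 3-d array (trials x dims x time)", name))
  x
}

#' @export
print.epoched_dataset <- function(x, ...) {
  d <- dim(x$Y)
  cat(sprintf("<epoched_dataset> %d trials, %d observed dims, T = %d, %d inputs, %d init inputs\n",
              d[1], d[2], d[3], dim(x$U)[2], ncol(x$U0)))
  invisible(x)
}

#' Number of trials / timesteps helpers
#' @param data an `epoched_dataset`.
#' @return integer count.
#' @export
n_trials <- function(data) dim(data$Y)[1]

#' @rdname n_trials
#' @export
n_timesteps <- function(data) dim(data$Y)[3]

#' Subset an epoched dataset by trial
#' @param data an `epoched_dataset`.
#' @param idx trial indices to keep.
#' @return an `epoched_dataset` with the selected trials.
#' @export
subset_trials <- function(data, idx) {
  epoched_dataset(
    Y = data$Y[idx, , , drop = FALSE],
    U = data$U[idx, , , drop = FALSE],
    U0 = data$U0[idx, , drop = FALSE],
    labels = data$labels[idx, , drop = FALSE],
    meta = data$meta
  )
}

#' Sample trials from a state-space model
#'
#' Draws latent trajectories `x_1 = B0 u_0 + w_1`,
#' `x_t = A x_{t-1} + B u_{t-1} + w_t` and observations `y_t = C x_t + v_t`
#' for the supplied inputs. The generating latent trajectories are retained
#' in the result (element `X`, trials x factors x T) for recovery tests.
#'
#' @param params valid `ssm_params` (covariances are checked PSD; a non-PSD
#'   covariance is rejected with a diagnostic naming the matrix).
#' @param U inputs (trials x input dims x T-1), or an `epoched_dataset`
#'   whose `U`/`U0` should be reused.
#' @param U0 initial-condition inputs (trials x init-input dims).
#' @param T_ epoch length; required when it cannot be inferred from `U`.
#' @param n_trials number of trials; inferred from `U` when omitted.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return an `epoched_dataset` with an extra element `X` holding the latent
#'   trajectories.
#' @export
sample_ssm <- function(params, U = NULL, U0 = NULL, T_ = NULL, n_trials = NULL,
                       seed = 1L) {
  validate_ssm_params(params)
  if (inherits(U, "epoched_dataset")) {
    U0 <- U$U0; U <- U$U
  }
  d <- ssm_dims(params)
  if (is.null(U)) {
    if (is.null(T_) || is.null(n_trials))
      stop("supply U, or T_ and n_trials")
    U <- array(0, dim = c(n_trials, d$Du, T_ - 1))
  }
  n <- dim(U)[1]; T_ <- dim(U)[3] + 1L
  if (is.null(U0)) U0 <- matrix(if (d$Du0 == 1) 1 else 0, n, d$Du0)
  if (ncol(U0) != d$Du0 || dim(U)[2] != d$Du)
    stop("input dimensions do not match params")

  sqW  <- matrix_sqrt_psd(params$W,  "W")
  sqV  <- matrix_sqrt_psd(params$V,  "V")
  sqW1 <- matrix_sqrt_psd(params$W1, "W1")

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  X <- array(0, dim = c(n, d$Dx, T_))
  Y <- array(0, dim = c(n, d$Dy, T_))
  ## x, y as (dims x trials) working matrices
  x <- params$B0 %*% t(U0) + sqW1 %*% matrix(stats::rnorm(d$Dx * n), d$Dx, n)
  for (t in seq_len(T_)) {
    if (t > 1) {
      ut <- matrix(U[, , t - 1], nrow = n)  # n x Du
      x <- params$A %*% x + params$B %*% t(ut) +
        sqW %*% matrix(stats::rnorm(d$Dx * n), d$Dx, n)
    }
    y <- params$C %*% x + sqV %*% matrix(stats::rnorm(d$Dy * n), d$Dy, n)
    X[, , t] <- t(x)
    Y[, , t] <- t(y)
  }
  out <- epoched_dataset(Y = Y, U = U, U0 = U0, meta = list(seed = seed))
  out$X <- X
  out
}
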