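#' Sample a planted ground-truth state-space model with task structure
#'
#' Draws a stable random system wired to a contrast-coded two-task design
#' (time-varying inputs bias/current task/previous task/switch over a
#' spline basis; initial-condition inputs intercept/previous task), then
#' samples an epoched dataset from it. The previous-task column of `B0`
#' controls where trials start relative to the task trajectories:
#' `init_mode = "midpoint"` plants the initial condition at the exact
#' midpoint between the two tasks' states (the column is zero, so the
#' task-subsystem initial state is the origin and the ground-truth midpoint
#' score is 0 by construction); `init_mode = "task"` plants it on the
#' previous task's own trajectory (the column is the cue-period average of
#' the task-subsystem state, so repeat trials begin essentially on top of
#' their task's states and the midpoint score starts near -1).
#'
#' @param n_factors,n_obs latent/observed dimensionality.
#' @param n_trials_sim trials to sample.
#' @param T_ epoch length.
#' @param rho spectral radius of the planted dynamics.
#' @param n_basis spline basis functions per predictor.
#' @param init_mode `"midpoint"` or `"task"`.
#' @param obs_noise,proc_noise noise scales.
#' @param tie_task_columns tie the task-input columns of `B` across spline
#'   bases (constant task drive; required and forced for
#'   `init_mode = "task"`). With `FALSE`, every input column gets an
#'   independent direction and a log-spread magnitude, the regime for
#'   studying how recovery quality depends on column norm.
#' @param seed integer seed (labels, system draw, and sampling).
#' @return list with `params` (the generating `ssm_params`), `data` (an
#'   `epoched_dataset` including latents `X`), `design` (the `ssm_design`),
#'   and `labels`.
#' @export
sample_ground_truth <- function(n_factors = 8, n_obs = 12, n_trials_sim = 400,
                                T_ = 40, rho = 0.9, n_basis = 8,
                                init_mode = c("midpoint", "task"),
                                obs_noise = 0.3, proc_noise = 0.15,
                                tie_task_columns = TRUE, seed = 1L) {
  init_mode <- match.arg(init_mode)
  if (init_mode == "task") tie_task_columns <- TRUE
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)

  ## balanced contrast-coded labels
  n <- n_trials_sim
  labels <- data.frame(
    task = rep(c(-1, 1), length.out = n),
    prev_task = rep(c(-1, -1, 1, 1), length.out = n))
  labels <- labels[sample(n), , drop = FALSE]
  rownames(labels) <- NULL
  labels$switch <- switch_code(labels$task, labels$prev_task)

  spec <- design_spec(predictors = c("bias", "task", "prev_task", "switch"),
                      init_predictors = c("intercept", "prev_task"),
                      n_basis = n_basis)
  design <- spline_inputs(labels, T_, spec)
  Du <- dim(design$U)[2]; Du0 <- ncol(design$U0)

  Dx <- n_factors
  ## slow, smoothly rotating dynamics: a strong identity component plus a
  ## random perturbation, rescaled to the requested spectral radius --
  ## the regime typical of population recordings (states persist across
  ## adjacent timesteps rather than being scrambled)
  R <- matrix(stats::rnorm(Dx * Dx, sd = 0.35 / sqrt(Dx)), Dx, Dx)
  A <- 0.8 * diag(Dx) + R
  A <- A * (rho / spectral_radius(A))
  B <- matrix(stats::rnorm(Dx * Du, sd = 0.5), Dx, Du)
  ## task terms: one encoding direction per predictor, tied across spline
  ## bases (scaled by the design's column scales so the effective task
  ## drive is constant over the epoch -- the basis is a partition of
  ## unity); this gives each task a well-defined target state
  if (tie_task_columns) {
    task_dirs <- list(task = stats::rnorm(Dx, sd = 1),
                      prev_task = stats::rnorm(Dx, sd = 1))
    for (p in names(task_dirs)) {
      cols <- which(design$columns$predictor == p)
      for (cl in cols) B[, cl] <- task_dirs[[p]] * design$scales[cl]
    }
  } else {
    ## independent directions with log-spread magnitudes: weakly and
    ## strongly encoded predictors coexist
    mags <- exp(stats::runif(Du, log(0.2), log(3)))
    B <- sweep(B, 2, mags, `*`)
  }
  C <- matrix(stats::rnorm(n_obs * Dx), n_obs, Dx) / sqrt(Dx)
  rand_cov <- function(d, scale) {
    M <- matrix(stats::rnorm(d * d), d, d)
    scale^2 * symmetrize(M %*% t(M) / d + diag(0.5, d))
  }
  W <- rand_cov(Dx, proc_noise)
  V <- rand_cov(n_obs, obs_noise)
  W1 <- rand_cov(Dx, proc_noise)
  B0 <- cbind(stats::rnorm(Dx, sd = 0.2), rep(0, Dx))
  params <- ssm_params(A = A, B = B, C = C, W = W, V = V, B0 = B0, W1 = W1)

  if (init_mode == "task") {
    ## place the previous-task initial condition on the task's fixed point:
    ## with a constant task drive g, the repeat subsystem started at
    ## x* = (I - A)^{-1} g stays at x* exactly, so the planted midpoint
    ## score is -1 at every timestep
    sub0 <- decompose(params, design, "repeat", task = 1)
    g <- B %*% sub0$u[, 1]
    x_star <- solve(diag(Dx) - A, g)
    B0[, 2] <- x_star * design$init_sds[2]
    params <- ssm_params(A = A, B = B, C = C, W = W, V = V, B0 = B0, W1 = W1)
  }

  data <- sample_ssm(params, U = design$U, U0 = design$U0, seed = seed + 1L)
  data$labels <- labels
  if (!is.null(old)) assign(".Random.seed", envir = globalenv(), value = old)
  list(params = params, data = data, design = design, labels = labels)
}

#' Fit the full pipeline to an epoched dataset
#'
#' Convenience driver used throughout the validation experiments: split
#' trials, initialize with subspace identification, and run MAP-EM.
#'
#' @param data an `epoched_dataset`.
#' @param n_factors latent dimensionality to fit.
#' @param train_frac fraction of trials for training (leading block).
#' @param horizon SSID horizon (defaults to `n_factors`).
#' @param max_iter,check_every EM protocol.
#' @param prior a `prior_spec`.
#' @return list from [fit_em()] plus `train`/`test` index vectors.
#' @export
fit_pipeline <- function(data, n_factors, train_frac = 0.8,
                         horizon = max(n_factors, 10L),
                         max_iter = 200L, check_every = 20L,
                         prior = prior_spec()) {
  n <- n_trials(data)
  n_train <- floor(train_frac * n)
  train <- seq_len(n_train); test <- seq(n_train + 1, n)
  dtr <- subset_trials(data, train); dte <- subset_trials(data, test)
  init <- ssid_initialize(dtr, n_factors = n_factors, horizon = horizon)
  fit <- fit_em(dtr, dte, init = init, max_iter = max_iter,
                check_every = check_every, prior = prior)
  fit$train <- train; fit$test <- test
  fit
}
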