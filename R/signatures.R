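#' Input time courses for a hypothetical trial condition
#'
#' Rebuilds the SSM input matrix `u` (columns over time) and the
#' initial-condition vector `u0` that the design pipeline would produce for
#' a trial with the given label values, passing each predictor through the
#' same centering/scaling used when the design was built. Predictors not
#' named in `values` contribute zero columns.
#'
#' @param design an `ssm_design` from [spline_inputs()].
#' @param values named list/vector of label values (e.g.
#'   `c(task = 1, prev_task = -1)`); use `bias = 1` / `intercept = 1` to
#'   activate the constant terms.
#' @param center apply the design's centering (default FALSE: signature
#'   analyses use the raw contrast value through the design's scale, so
#'   that +1/-1 conditions stay symmetric around the origin).
#' @return list with `u` (input-cols x T-1) and `u0` (init-cols).
#' @export
condition_inputs <- function(design, values, center = FALSE) {
  Tm1 <- nrow(design$basis)
  u <- matrix(0, nrow(design$columns), Tm1)
  for (cl in seq_len(nrow(design$columns))) {
    p <- design$columns$predictor[cl]; b <- design$columns$basis[cl]
    if (!p %in% names(values)) next
    v <- as.numeric(values[[p]])
    if (center) v <- v - design$centers[[p]]
    z <- v / design$sds[[p]]
    u[cl, ] <- z * design$basis[, b] / design$scales[cl]
  }
  u0 <- numeric(nrow(design$init_columns))
  for (j in seq_len(nrow(design$init_columns))) {
    p <- design$init_columns$predictor[j]
    if (!p %in% names(values)) next
    v <- as.numeric(values[[p]])
    if (center) v <- v - design$init_centers[j]
    u0[j] <- v / design$init_sds[j]
  }
  list(u = u, u0 = u0)
}

#' Deterministic propagation of the noise-free linear system
#'
#' @param params an `ssm_params`.
#' @param u input course (input dims x T-1); `u[, t]` drives `x_{t+1}`.
#' @param u0 initial-condition inputs.
#' @return latent trajectory (factors x T).
#' @export
propagate_linear <- function(params, u, u0) {
  T_ <- ncol(u) + 1L
  Dx <- nrow(params$A)
  X <- matrix(0, Dx, T_)
  X[, 1] <- params$B0 %*% u0
  for (t in seq(2, length.out = T_ - 1))
    X[, t] <- params$A %*% X[, t - 1] + params$B %*% u[, t - 1]
  X
}

#' Additive state decomposition into a task subsystem
#'
#' Exploits the superposition property of linear systems to isolate the
#' latent state caused by the task inputs alone:
#' \deqn{x^{task}_t = A x^{task}_{t-1} + B^{task} u^{task}_{t-1}, \quad
#'       x^{task}_1 = B_0^{prevTask} u_0^{prevTask}}
#' With contrast-coded tasks the switch subsystem drives the current- and
#' previous-task predictors with opposite signs (their difference) and the
#' repeat subsystem with the same sign (their sum); the initial condition
#' comes from the previous-task component of `B0` only. The fitted model
#' should be normalized with [normalize_system()] first so latent units are
#' comparable.
#'
#' @param params fitted (normalized) `ssm_params`.
#' @param design the `ssm_design` used to fit the model.
#' @param condition `"switch"` or `"repeat"`.
#' @param task contrast code of the current task (+1 or -1); the other
#'   task's trajectory is its mirror image through the origin.
#' @param task_predictor,prev_predictor,init_prev_predictor label-column
#'   names of the task terms in the design.
#' @return list of class `task_subsystem`: `x` (factors x T), `u`
#'   (input-cols x T-1, only task columns nonzero), `u0`, `condition`,
#'   `task`.
#' @export
decompose <- function(params, design, condition = c("switch", "repeat"),
                      task = 1,
                      task_predictor = "task", prev_predictor = "prev_task",
                      init_prev_predictor = "prev_task") {
  condition <- match.arg(condition)
  for (p in c(task_predictor, prev_predictor))
    if (!p %in% design$columns$predictor)
      stop(sprintf("predictor '%s' absent from design", p))
  if (!init_prev_predictor %in% design$init_columns$predictor)
    stop(sprintf("initial predictor '%s' absent from design", init_prev_predictor))
  prev <- if (condition == "switch") -task else task
  vals <- stats::setNames(list(task, prev), c(task_predictor, prev_predictor))
  ci <- condition_inputs(design, vals)
  ## initial condition: previous-task component only
  vals0 <- stats::setNames(list(prev), init_prev_predictor)
  ci0 <- condition_inputs(design, vals0)
  x <- propagate_linear(params, ci$u, ci0$u0)
  structure(list(x = x, u = ci$u, u0 = ci0$u0,
                 condition = condition, task = task, params = params),
            class = "task_subsystem")
}

#' Cross-lagged cosine similarity between switch and repeat task states
#'
#' Entry (i, j) is the cosine of the angle between the switch-subsystem
#' state at time i and the repeat-subsystem state at time j, analogous to a
#' temporal generalization analysis. States with zero norm give `NA`
#' entries (undefined angle), never 0.
#'
#' @param sub_switch,sub_repeat `task_subsystem` objects (or factors x T
#'   matrices) with equal T.
#' @return T x T matrix of cosines.
#' @export
switch_similarity <- function(sub_switch, sub_repeat) {
  xs <- if (inherits(sub_switch, "task_subsystem")) sub_switch$x else sub_switch
  xr <- if (inherits(sub_repeat, "task_subsystem")) sub_repeat$x else sub_repeat
  if (ncol(xs) != ncol(xr)) stop("subsystems must have equal T")
  ns <- sqrt(colSums(xs^2)); nr <- sqrt(colSums(xr^2))
  S <- crossprod(xs, xr) / outer(ns, nr)
  S[outer(ns == 0, nr == 0, `|`)] <- NA_real_
  S
}

#' Midpoint score: relative distance of the initial state to the two tasks
#'
#' For task trajectories `x^A_t` and `x^B_t` (with `x^B = -x^A` under
#' contrast coding) and the trial's initial state `x^A_1`:
#' \deqn{\delta_t = \frac{\|x^A_1 - x^A_t\| - \|x^A_1 - x^B_t\|}
#'                       {\|x^A_1 - x^A_t\| + \|x^A_1 - x^B_t\|}}
#' so -1 means the initial state sits on task A's state, +1 on task B's,
#' and 0 means it is equidistant (a neutral initial condition). Both
#' distances zero gives `NA`.
#'
#' @param subsystem a `task_subsystem` (task A); or a factors x T matrix.
#' @param xB optional explicit task-B trajectory (defaults to `-x^A`).
#' @param x1 optional explicit initial state (defaults to the subsystem's
#'   own `x[, 1]`).
#' @return numeric series `delta_t` in `[-1, 1]`.
#' @export
midpoint_score <- function(subsystem, xB = NULL, x1 = NULL) {
  xA <- if (inherits(subsystem, "task_subsystem")) subsystem$x else subsystem
  if (is.null(xB)) xB <- -xA
  if (is.null(x1)) x1 <- xA[, 1]
  dA <- sqrt(colSums((x1 - xA)^2))
  dB <- sqrt(colSums((x1 - xB)^2))
  out <- (dA - dB) / (dA + dB)
  out[dA + dB == 0] <- NA_real_
  out
}

#' Convergence of post-task states over the inter-trial interval
#'
#' Computes the log Euclidean distance between the trial-averaged state
#' trajectories following each task over the ITI; the fitted slope of the
#' log-distance over time estimates the exponential convergence rate.
#' Identical trajectories give `NA` (guarding `log 0`), and the distance is
#' invariant under any global rotation of state space.
#'
#' @param post_A,post_B dims x T_iti matrices of trial-averaged states
#'   following task A / task B.
#' @return list with `log_distance` (length T_iti), `slope` (per-timestep
#'   log decay rate; `lambda = exp(slope)`), and `rate` = `exp(slope)`.
#' @export
iti_convergence <- function(post_A, post_B) {
  if (!all(dim(post_A) == dim(post_B))) stop("trajectories must share dimensions")
  if (ncol(post_A) < 2) stop("need at least 2 ITI samples")
  d <- sqrt(colSums((post_A - post_B)^2))
  ld <- ifelse(d > 0, log(d), NA_real_)
  ok <- is.finite(ld)
  slope <- if (sum(ok) >= 2)
    unname(stats::coef(stats::lm(ld[ok] ~ seq_along(ld)[ok]))[2]) else NA_real_
  list(log_distance = ld, slope = slope, rate = exp(slope))
}

#' Time-resolved task energy via the recursive Lyapunov equation
#'
#' Accumulates the task Gramian
#' \deqn{G_t = A G_{t-1} A^\top + (B u^{task}_{t-1})(B u^{task}_{t-1})^\top}
#' from `G_1 = 0` (the initial condition carries no task-input energy), and
#' summarizes it as the average controllability `log tr(G_t)`; timesteps
#' with zero trace (the first sample, or zero inputs) are reported as `NA`
#' rather than epsilon-padded. The switch-vs-repeat contrast is the
#' difference of the two conditions' summaries.
#'
#' @param params (normalized) `ssm_params`.
#' @param sub a `task_subsystem`, or an input course matrix (input dims x
#'   T-1) to drive through `params$B`.
#' @return list with `G` (list of Gramians per t), `trace`, `log_trace`.
#' @export
task_energy <- function(params, sub) {
  u <- if (inherits(sub, "task_subsystem")) sub$u else sub
  T_ <- ncol(u) + 1L
  Dx <- nrow(params$A)
  G <- vector("list", T_)
  G[[1]] <- matrix(0, Dx, Dx)
  for (t in seq(2, length.out = T_ - 1)) {
    b <- params$B %*% u[, t - 1]
    G[[t]] <- symmetrize(params$A %*% G[[t - 1]] %*% t(params$A) + tcrossprod(b))
  }
  tr <- vapply(G, function(g) sum(diag(g)), numeric(1))
  lt <- ifelse(tr > 0, log(tr), NA_real_)
  list(G = G, trace = tr, log_trace = lt)
}

#' Asymptotic controllability Gramian
#'
#' Solves the discrete Lyapunov equation `G = A G A' + B B'` (the state
#' covariance a white-noise input would build up asymptotically) by doubling
#' iteration; requires a stable `A`.
#'
#' @param params an `ssm_params` (or a list with `A` and `B`).
#' @param tol residual tolerance.
#' @return factors x factors Gramian with residual norm below `tol`.
#' @export
asymptotic_gramian <- function(params, tol = 1e-10) {
  A <- params$A; B <- params$B
  if (spectral_radius(A) >= 1) stop("A must be stable (spectral radius < 1)")
  G <- tcrossprod(B)
  Ak <- A
  for (i in 1:200) {
    G_new <- symmetrize(Ak %*% G %*% t(Ak) + G)
    done <- max(abs(G_new - G)) < tol
    G <- G_new
    Ak <- Ak %*% Ak
    if (done) break
  }
  G
}

#' Low-dimensional SVD embedding of stacked trajectories
#'
#' Thin SVD with a deterministic sign convention (the largest-magnitude
#' loading of each right singular vector is made positive) so embeddings
#' are reproducible. Scores are the left singular vectors scaled by their
#' singular values; keeping all components reproduces the input exactly.
#'
#' @param X stacked trajectory matrix (e.g. timesteps x (factors x
#'   participants)).
#' @param k number of components (default all).
#' @return list with `scores` (nrow(X) x k), `d` singular values, `u`, `v`.
#' @export
svd_embed <- function(X, k = min(dim(X))) {
  sv <- svd(X)
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  ks <- seq_len(k)
  list(scores = sv$u[, ks, drop = FALSE] %*% diag(sv$d[ks], k),
       d = sv$d, u = sv$u[, ks, drop = FALSE], v = sv$v[, ks, drop = FALSE])
}
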