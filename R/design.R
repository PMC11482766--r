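#' Design specification for state-space model inputs
#'
#' Declares which per-trial condition labels enter the time-varying input
#' design (each expanded over a temporal spline basis) and which enter the
#' initial-condition design (no temporal expansion). The default is the
#' simulator design: time-varying {bias, current task, previous task,
#' switch-vs-repeat} with initial-condition inputs {intercept, previous
#' task}; recording-oriented designs add cue identity, cue repetition and
#' reaction-time covariates to the same machinery by listing extra label
#' columns.
#'
#' @param predictors character vector of label columns for time-varying
#'   inputs; `"bias"` denotes the time-varying intercept (value 1 on every
#'   trial). Task columns are expected contrast-coded (-1/+1).
#' @param init_predictors label columns for the initial-condition design;
#'   `"intercept"` denotes the constant 1.
#' @param n_basis number of cubic B-spline basis functions per predictor.
#' @param pca_threshold proportion of variance the retained principal
#'   components must explain.
#' @param log_rt_predictors label columns to log-transform before z-scoring
#'   (reaction times).
#' @return list of class `design_spec`.
#' @export
design_spec <- function(predictors = c("bias", "task", "prev_task", "switch"),
                        init_predictors = c("intercept", "prev_task"),
                        n_basis = 10L, pca_threshold = 0.99,
                        log_rt_predictors = character()) {
  stopifnot(pca_threshold > 0, pca_threshold <= 1, n_basis >= 2)
  structure(list(predictors = predictors, init_predictors = init_predictors,
                 n_basis = as.integer(n_basis), pca_threshold = pca_threshold,
                 log_rt_predictors = log_rt_predictors),
            class = "design_spec")
}

#' PCA reduction estimated on training trials only
#'
#' Flattens training observations over trials and timesteps, estimates the
#' principal components, keeps the smallest number of components whose
#' cumulative explained variance reaches `threshold`, and projects both
#' splits onto the training basis.
#'
#' @param Y_train,Y_test observation arrays (trials x channels x T);
#'   `Y_test` may be `NULL`.
#' @param threshold proportion of variance in (0, 1].
#' @param center subtract the training mean before projection (default TRUE).
#' @return list with `scores_train`, `scores_test` (trials x components x T),
#'   `basis` (channels x components), `center`, `explained` (cumulative
#'   variance ratios), `n_components`.
#' @export
pca_reduce <- function(Y_train, Y_test = NULL, threshold = 0.99, center = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  dtr <- dim(Y_train)
  n_samp <- dtr[1] * dtr[3]
  if (n_samp < dtr[2])
    stop("fewer samples (trials x timesteps) than channels")
  flat <- function(Y) {
    d <- dim(Y)
    out <- matrix(0, d[1] * d[3], d[2])
    for (t in seq_len(d[3]))
      out[(t - 1) * d[1] + seq_len(d[1]), ] <- matrix(Y[, , t], nrow = d[1])
    out
  }
  Xtr <- flat(Y_train)
  mu <- if (center) colMeans(Xtr) else rep(0, ncol(Xtr))
  Xc <- sweep(Xtr, 2, mu)
  sv <- svd(Xc)
  var_exp <- sv$d^2 / sum(sv$d^2)
  cum <- cumsum(var_exp)
  k <- which(cum >= threshold - 1e-12)[1]
  basis <- sv$v[, seq_len(k), drop = FALSE]
  project <- function(Y) {
    if (is.null(Y)) return(NULL)
    d <- dim(Y)
    out <- array(0, dim = c(d[1], k, d[3]))
    for (t in seq_len(d[3])) {
      yt <- sweep(matrix(Y[, , t], nrow = d[1]), 2, mu)
      out[, , t] <- yt %*% basis
    }
    out
  }
  list(scores_train = project(Y_train), scores_test = project(Y_test),
       basis = basis, center = mu, explained = cum, n_components = k)
}

#' Cubic B-spline temporal basis over an epoch
#'
#' Clamped cubic B-splines tiling timesteps `1..T` uniformly (interior knots
#' at quantiles of the time axis). With the intercept column included, the
#' basis is a partition of unity: columns are non-negative and sum to 1 at
#' every timestep.
#'
#' @param T_ epoch length in timesteps.
#' @param n_basis number of basis functions.
#' @return T x n_basis matrix.
#' @export
spline_basis <- function(T_, n_basis) {
  splines::bs(seq_len(T_), df = n_basis, degree = 3, intercept = TRUE)[, , drop = FALSE]
}

#' Expand condition labels into spline-basis SSM inputs
#'
#' Each time-varying predictor is z-scored across trials (reaction-time
#' predictors after a log transform) and replicated across its spline
#' columns: column (predictor p, basis b) of `U` carries
#' `value_p(trial) * basis_b(t)`, scaled to unit variance over the
#' trial-by-time design. The time-varying bias is the basis itself, left
#' unscaled (a constant across trials cannot be z-scored). Initial-condition
#' predictors enter `U0` without temporal expansion. A predictor with zero
#' variance across trials (other than the bias/intercept) is dropped with a
#' warning.
#'
#' @param labels per-trial condition data.frame.
#' @param T_ epoch length; `U` gets `T_ - 1` timesteps (inputs drive the
#'   next state).
#' @param spec a `design_spec`.
#' @return list with `U` (trials x columns x T-1), `U0` (trials x init
#'   columns), `columns` (data.frame of predictor/basis per U column),
#'   `init_columns`, `basis` (the spline matrix), `scales` bookkeeping used
#'   by [decompose()].
#' @export
spline_inputs <- function(labels, T_, spec = design_spec()) {
  n <- nrow(labels)
  Bmat <- spline_basis(T_ - 1, spec$n_basis)     # basis over input timesteps
  preds <- spec$predictors
  vals <- list(); keep <- character()
  centers <- c(); sds <- c()
  for (p in preds) {
    if (p == "bias") {
      vals[[p]] <- rep(1, n); keep <- c(keep, p)
      centers[p] <- 0; sds[p] <- 1
      next
    }
    v <- labels[[p]]
    if (is.null(v)) stop(sprintf("predictor '%s' absent from labels", p))
    v <- as.numeric(v)
    if (p %in% spec$log_rt_predictors) v <- log(v)
    if (stats::sd(v) == 0) {
      warning(sprintf("predictor '%s' is constant across trials; dropped", p))
      next
    }
    centers[p] <- mean(v); sds[p] <- stats::sd(v)
    vals[[p]] <- (v - centers[p]) / sds[p]
    keep <- c(keep, p)
  }
  ncol_u <- length(keep) * spec$n_basis
  U <- array(0, dim = c(n, ncol_u, T_ - 1))
  columns <- data.frame(predictor = rep(keep, each = spec$n_basis),
                        basis = rep(seq_len(spec$n_basis), length(keep)))
  scales <- numeric(ncol_u)
  col <- 0L
  for (p in keep) {
    for (b in seq_len(spec$n_basis)) {
      col <- col + 1L
      raw <- outer(vals[[p]], Bmat[, b])         # trials x (T-1)
      s <- if (p == "bias") 1 else stats::sd(as.vector(raw))
      if (s == 0) s <- 1
      U[, col, ] <- raw / s
      scales[col] <- s
    }
  }
  ## initial-condition design: no temporal expansion; intercept left at 1
  ip <- spec$init_predictors
  U0 <- matrix(0, n, length(ip))
  init_centers <- numeric(length(ip)); init_sds <- numeric(length(ip))
  for (j in seq_along(ip)) {
    if (ip[j] == "intercept") { U0[, j] <- 1; init_sds[j] <- 1; next }
    v <- as.numeric(labels[[ip[j]]])
    if (is.null(v)) stop(sprintf("initial predictor '%s' absent from labels", ip[j]))
    if (ip[j] %in% spec$log_rt_predictors) v <- log(v)
    s <- stats::sd(v)
    if (s == 0) { warning(sprintf("initial predictor '%s' constant; dropped scale", ip[j])); s <- 1 }
    init_centers[j] <- mean(v); init_sds[j] <- s
    U0[, j] <- (v - init_centers[j]) / s
  }
  structure(list(U = U, U0 = U0, columns = columns,
                 init_columns = data.frame(predictor = ip),
                 basis = Bmat, scales = scales,
                 centers = centers, sds = sds,
                 init_centers = init_centers, init_sds = init_sds,
                 spec = spec),
            class = "ssm_design")
}

#' Switch/repeat coding from task labels
#'
#' With contrast-coded tasks, a trial repeats when current and previous task
#' agree and switches when they differ.
#' @param task,prev_task contrast-coded (-1/+1) vectors.
#' @return numeric vector: +1 switch, -1 repeat.
#' @export
switch_code <- function(task, prev_task) {
  ifelse(task == prev_task, -1, 1)
}

#' Cut fixed-length epochs out of a continuous recording
#'
#' @param recording channels x total-time matrix.
#' @param onsets 1-based sample index of each trial's epoch start; trials
#'   whose epoch would run past the recording (or with `NA` onset) are
#'   excluded with a message of the count.
#' @param T_ epoch length in samples; epochs are half-open `[onset, onset+T_)`.
#' @param labels optional per-trial labels (subset along with the trials).
#' @param meta metadata passed through.
#' @return an `epoched_dataset` (observations only).
#' @export
epoch_select <- function(recording, onsets, T_, labels = NULL, meta = list()) {
  ok <- !is.na(onsets) & onsets >= 1 & (onsets + T_ - 1) <= ncol(recording)
  if (any(!ok))
    message(sprintf("epoch_select: excluded %d trial(s) with missing/out-of-range markers",
                    sum(!ok)))
  onsets <- onsets[ok]
  n <- length(onsets)
  Y <- array(0, dim = c(n, nrow(recording), T_))
  for (i in seq_len(n))
    Y[i, , ] <- recording[, onsets[i] + 0:(T_ - 1)]
  if (!is.null(labels)) labels <- labels[ok, , drop = FALSE]
  epoched_dataset(Y = Y, labels = labels, meta = c(meta, list(T = T_)))
}

#' Epoch-length arithmetic for the two data sources
#'
#' The simulator's analyzed epoch is the preparation of the second trial:
#' cue period (10 timesteps) + delay period (20) + initial trial period
#' (10) = 40 timesteps. Recording epochs are specified in milliseconds and
#' converted at the sampling rate.
#'
#' @param cue,delay,trial period lengths in timesteps.
#' @return epoch length in timesteps/samples.
#' @export
rnn_epoch_timesteps <- function(cue = 10L, delay = 20L, trial = 10L) {
  as.integer(cue + delay + trial)
}

#' @rdname rnn_epoch_timesteps
#' @param cue_ms,delay_ms,trial_ms period lengths in milliseconds.
#' @param rate_hz sampling rate.
#' @export
eeg_epoch_samples <- function(cue_ms, delay_ms, trial_ms, rate_hz = 125) {
  as.integer(round((cue_ms + delay_ms + trial_ms) / 1000 * rate_hz))
}

#' Split trials into training and test sets by experimental block
#'
#' Whole blocks are assigned to the test set so that train and test trials
#' are temporally separated; the split is reproducible given the seed.
#'
#' @param block_ids block label per trial.
#' @param test_fraction fraction of blocks assigned to test (at least one).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test` (trial indices).
#' @export
split_blocks <- function(block_ids, test_fraction = 0.1, seed = 1L) {
  blocks <- unique(block_ids)
  if (length(blocks) < 2)
    stop("cannot split by block: need at least 2 blocks")
  n_test <- max(1L, round(test_fraction * length(blocks)))
  if (n_test >= length(blocks)) stop("test_fraction leaves no training blocks")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  test_blocks <- sample(blocks, n_test)
  if (!is.null(old)) assign(".Random.seed", envir = globalenv(), value = old)
  test <- which(block_ids %in% test_blocks)
  train <- setdiff(seq_along(block_ids), test)
  list(train = train, test = test)
}
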