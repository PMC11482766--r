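#' Curriculum specification for the task-switching simulator
#'
#' Describes how gated-recurrent-unit networks are trained on the
#' context-dependent decision-making task. Each trial presents a one-hot
#' task cue (10 timesteps), a delay (20 timesteps), and two pairs of
#' stimulus inputs (40 timesteps); the network reports which input of the
#' cued pair has the larger amplitude. Sequences contain one or more trials
#' separated by an input-free inter-trial interval. Switch training
#' ("2-trial") appends a final phase of two-trial sequences (default the
#' final 10% of training) after a single-trial phase; "1-trial" networks
#' never see a second trial during training. Input noise is resampled every
#' epoch at the configured SNRs (dB, signal power over noise power).
#'
#' @param switch_training `"1-trial"` or `"2-trial"`.
#' @param iti_length timesteps between trials (20 short / 60 long).
#' @param n_epochs total training epochs.
#' @param two_trial_fraction fraction of epochs (at the end) trained on
#'   two-trial sequences for the 2-trial curriculum.
#' @param cue_snr_db,trial_snr_db input signal-to-noise ratios in dB.
#' @param reps_per_epoch repetitions of each condition per training epoch
#'   (conditions are fully crossed, so every epoch balances task, target
#'   and distractor transitions).
#' @param batch_size sequences per gradient step within an epoch.
#' @param hidden_size GRU hidden units.
#' @param n_networks networks per curriculum (matched seeds across
#'   curricula).
#' @param learning_rate,weight_decay AdamW settings.
#' @param seed base seed.
#' @return list of class `curriculum_spec`.
#' @export
curriculum_spec <- function(switch_training = c("2-trial", "1-trial"),
                            iti_length = 20L, n_epochs = 100L,
                            two_trial_fraction = 0.5,
                            cue_snr_db = 0, trial_snr_db = -6.5,
                            reps_per_epoch = 8L, batch_size = 64L,
                            hidden_size = 32L, n_networks = 16L,
                            learning_rate = 0.01, weight_decay = 0.01,
                            seed = 1L) {
  switch_training <- match.arg(switch_training)
  structure(list(switch_training = switch_training,
                 iti_length = as.integer(iti_length),
                 n_epochs = as.integer(n_epochs),
                 two_trial_fraction = two_trial_fraction,
                 cue_snr_db = cue_snr_db, trial_snr_db = trial_snr_db,
                 reps_per_epoch = as.integer(reps_per_epoch),
                 batch_size = as.integer(batch_size),
                 hidden_size = as.integer(hidden_size),
                 n_networks = as.integer(n_networks),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "curriculum_spec")
}

## task geometry constants
CUE_LEN <- 10L; DELAY_LEN <- 20L; STIM_LEN <- 40L
TRIAL_LEN <- CUE_LEN + DELAY_LEN + STIM_LEN
N_INPUT <- 6L      # 4 stimulus channels (2 pairs) + 2 one-hot cue channels
N_OUTPUT <- 2L
STIM_HI <- 1.25; STIM_LO <- 0.25   # amplitude grid (declared config default)
LOSS_LAG <- 10L                  # loss starts this many steps into the stimulus

#' Length of a simulator sequence in timesteps
#' @param n_trials_per_seq trials per sequence.
#' @param iti_length timesteps between trials.
#' @return integer sequence length.
#' @export
sequence_length <- function(n_trials_per_seq, iti_length) {
  as.integer(n_trials_per_seq * TRIAL_LEN + (n_trials_per_seq - 1) * iti_length)
}

## the 8 single-trial conditions: task x target pattern x distractor pattern
trial_condition_grid <- function() {
  expand.grid(task = 1:2, target = 1:2, distractor = 1:2)
}

#' Generate batches of task sequences
#'
#' Builds the fully crossed condition grid for the requested number of
#' trials per sequence (8 conditions per trial: task x target pattern x
#' distractor pattern; 64 for two-trial sequences), replicated `reps`
#' times, with optional Gaussian input noise at the spec's SNRs. The
#' correct answer is the larger-amplitude input within the cued pair.
#'
#' @param spec a `curriculum_spec`.
#' @param n_trials_per_seq 1, 2 or 3 trials per sequence.
#' @param reps repetitions of the condition grid.
#' @param noise add input noise (FALSE for test evaluation).
#' @param seed integer seed for the noise and condition shuffling.
#' @return list with `x` inputs (channels x T x sequences), `y` targets
#'   (outputs x T x sequences), `loss_mask` (T), `tasks` (sequences x
#'   trials), `events` (onset indices), `conditions` data.frame.
#' @export
make_sequences <- function(spec, n_trials_per_seq = 1L, reps = 1L,
                           noise = TRUE, seed = spec$seed) {
  iti <- spec$iti_length
  T_ <- sequence_length(n_trials_per_seq, iti)
  g1 <- trial_condition_grid()
  conds <- g1
  if (n_trials_per_seq >= 2) {
    for (k in 2:n_trials_per_seq) {
      conds <- merge(conds, g1, by = NULL, suffixes = c("", paste0(".", k)))
    }
  }
  names(conds)[1:3] <- c("task.1", "target.1", "distractor.1")
  conds <- conds[rep(seq_len(nrow(conds)), reps), , drop = FALSE]
  n <- nrow(conds)

  x <- array(0, dim = c(N_INPUT, T_, n))
  y <- array(0, dim = c(N_OUTPUT, T_, n))
  loss_mask <- rep(0, T_)
  onsets <- integer(n_trials_per_seq)
  for (k in seq_len(n_trials_per_seq)) {
    onsets[k] <- (k - 1) * (TRIAL_LEN + iti) + 1L
    stim_on <- onsets[k] + CUE_LEN + DELAY_LEN
    loss_mask[(stim_on + LOSS_LAG):(stim_on + STIM_LEN - 1)] <- 1
  }
  tasks <- matrix(0L, n, n_trials_per_seq)
  for (i in seq_len(n)) {
    for (k in seq_len(n_trials_per_seq)) {
      task <- conds[[paste0("task.", if (k == 1) "1" else k)]][i]
      target <- conds[[paste0("target.", if (k == 1) "1" else k)]][i]
      distr <- conds[[paste0("distractor.", if (k == 1) "1" else k)]][i]
      tasks[i, k] <- task
      on <- onsets[k]
      ## cue: one-hot over the cue period
      x[4L + task, on:(on + CUE_LEN - 1), i] <- 1
      ## stimulus: relevant pair = channels (2*task-1, 2*task)
      stim_on <- on + CUE_LEN + DELAY_LEN
      span <- stim_on:(stim_on + STIM_LEN - 1)
      rel <- c(2 * task - 1, 2 * task)
      irr <- setdiff(1:4, rel)
      x[rel[target], span, i] <- STIM_HI
      x[rel[3 - target], span, i] <- STIM_LO
      x[irr[distr], span, i] <- STIM_HI
      x[irr[3 - distr], span, i] <- STIM_LO
      ## target output: which input of the cued pair is larger
      y[target, span, i] <- 1
    }
  }
  if (noise) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    sd_cue <- sqrt(1 / 10^(spec$cue_snr_db / 10))
    sd_stim <- sqrt(mean(c(STIM_HI, STIM_LO)^2) / 10^(spec$trial_snr_db / 10))
    x[1:4, , ] <- x[1:4, , ] + rnorm(4 * T_ * n, sd = sd_stim)
    x[5:6, , ] <- x[5:6, , ] + rnorm(2 * T_ * n, sd = sd_cue)
    if (!is.null(old)) assign(".Random.seed", envir = globalenv(), value = old)
  }
  list(x = x, y = y, loss_mask = loss_mask, tasks = tasks,
       events = list(trial_onsets = onsets, cue_len = CUE_LEN,
                     delay_len = DELAY_LEN, stim_len = STIM_LEN, iti = iti),
       conditions = conds)
}

#' Initialize GRU parameters
#'
#' Uniform initialization in `[-1/sqrt(h), 1/sqrt(h)]` per weight, the
#' convention of standard GRU implementations. Ablated variants
#' (`open_reset`: reset gate fixed at 1; `open_update`: hidden state fully
#' overwritten by the new state; `no_gates`: vanilla recurrent network)
#' omit the ablated gate's parameters.
#'
#' @param hidden_size hidden units.
#' @param mode `"full"`, `"open_reset"`, `"open_update"`, `"no_gates"`.
#' @param n_input,n_output input/output channels.
#' @param seed integer seed.
#' @return list of class `gru_params` with weight matrices and `mode`.
#' @export
gru_init <- function(hidden_size, mode = "full", n_input = N_INPUT,
                     n_output = N_OUTPUT, seed = 1L) {
  h <- hidden_size
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  k <- 1 / sqrt(h)
  mk <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  p <- list(mode = mode, hidden_size = h, n_input = n_input, n_output = n_output)
  gates <- switch(mode,
                  full = c("r", "z", "n"),
                  open_reset = c("z", "n"),
                  open_update = c("r", "n"),
                  no_gates = "n",
                  stop("unknown mode"))
  for (g in gates) {
    p[[paste0("Wi", g)]] <- mk(h, n_input)
    p[[paste0("Wh", g)]] <- mk(h, h)
    p[[paste0("bi", g)]] <- stats::runif(h, -k, k)
    p[[paste0("bh", g)]] <- stats::runif(h, -k, k)
  }
  p$Who <- mk(n_output, h)
  p$bho <- stats::runif(n_output, -k, k)
  if (!is.null(old)) assign(".Random.seed", envir = globalenv(), value = old)
  class(p) <- "gru_params"
  p
}

#' Number of trainable parameters of a simulator network
#' @param params a `gru_params`, or a mode/hidden pair via `mode` and
#'   `hidden_size`.
#' @param mode,hidden_size,n_input,n_output used when `params` is missing.
#' @return integer count.
#' @export
gru_n_params <- function(params = NULL, mode = "full", hidden_size = NULL,
                         n_input = N_INPUT, n_output = N_OUTPUT) {
  if (!is.null(params)) {
    mode <- params$mode; hidden_size <- params$hidden_size
    n_input <- params$n_input; n_output <- params$n_output
  }
  n_gates <- switch(mode, full = 3L, open_reset = 2L, open_update = 2L,
                    no_gates = 1L)
  h <- hidden_size
  n_gates * (h * n_input + h * h + 2L * h) + n_output * h + n_output
}

#' Hidden size matching the full model's parameter count
#'
#' Ablated variants get more hidden units so that total trainable
#' parameters match the full architecture as closely as the integer grid
#' allows.
#' @param mode ablation mode.
#' @param full_hidden hidden size of the full model.
#' @param n_input,n_output channel counts.
#' @return integer hidden size.
#' @export
matched_hidden_size <- function(mode, full_hidden, n_input = N_INPUT,
                                n_output = N_OUTPUT) {
  target <- gru_n_params(mode = "full", hidden_size = full_hidden,
                         n_input = n_input, n_output = n_output)
  cand <- seq_len(4 * full_hidden + 16)
  counts <- vapply(cand, function(h)
    gru_n_params(mode = mode, hidden_size = h, n_input = n_input,
                 n_output = n_output), numeric(1))
  cand[which.min(abs(counts - target))]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass of the (possibly ablated) GRU
#'
#' Implements the standard gated-recurrent-unit update,
#' `r = sigma(Wir x + bir + Whr h + bhr)`,
#' `z = sigma(Wiz x + biz + Whz h + bhz)`,
#' `n = tanh(Win x + bin + r * (Whn h + bhn))`,
#' `h' = (1 - z) * n + z * h`, with a sigmoid linear read-out, batched over
#' sequences. Ablations: `open_reset` fixes `r = 1`; `open_update` uses the
#' new state fully (`h' = n`); `no_gates` is a vanilla recurrent network
#' with a ReLU activation.
#'
#' @param params a `gru_params`.
#' @param x inputs (channels x T x sequences), or channels x T for one
#'   sequence.
#' @param keep_cache retain intermediates for backpropagation.
#' @return list with `h` hidden states (hidden x T x sequences), `yhat`
#'   outputs (outputs x T x sequences), and `cache` when requested.
#' @export
gru_forward <- function(params, x, keep_cache = FALSE) {
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  di <- dim(x); T_ <- di[2]; nb <- di[3]
  h <- params$hidden_size
  H <- array(0, dim = c(h, T_, nb))
  Yh <- array(0, dim = c(params$n_output, T_, nb))
  cache <- if (keep_cache) vector("list", T_) else NULL
  hp <- matrix(0, h, nb)
  mode <- params$mode
  for (t in seq_len(T_)) {
    xt <- matrix(x[, t, ], di[1], nb)
    if (mode == "no_gates") {
      a <- params$Win %*% xt + params$bin + params$Whn %*% hp + params$bhn
      ht <- pmax(a, 0)                       # ReLU vanilla network
      if (keep_cache) cache[[t]] <- list(xt = xt, hp = hp, a = a)
    } else {
      r <- if (mode == "open_reset") matrix(1, h, nb) else
        sigmoid(params$Wir %*% xt + params$bir + params$Whr %*% hp + params$bhr)
      hn_pre <- params$Whn %*% hp + params$bhn
      n <- tanh(params$Win %*% xt + params$bin + r * hn_pre)
      if (mode == "open_update") {
        z <- matrix(0, h, nb)
        ht <- n
      } else {
        z <- sigmoid(params$Wiz %*% xt + params$biz + params$Whz %*% hp + params$bhz)
        ht <- (1 - z) * n + z * hp
      }
      if (keep_cache) cache[[t]] <- list(xt = xt, hp = hp, r = r, z = z,
                                         n = n, hn_pre = hn_pre)
    }
    H[, t, ] <- ht
    Yh[, t, ] <- sigmoid(params$Who %*% ht + params$bho)
    hp <- ht
  }
  list(h = H, yhat = Yh, cache = cache)
}

#' Logistic loss of simulator outputs
#'
#' Cross-entropy between targets and outputs over the masked timesteps,
#' averaged over sequences and summed over outputs and masked steps.
#' @param yhat,y outputs/targets (outputs x T x sequences).
#' @param loss_mask length-T 0/1 vector.
#' @return scalar mean loss per sequence.
#' @export
gru_loss <- function(yhat, y, loss_mask) {
  eps <- 1e-12
  nb <- dim(yhat)[3]
  msk <- array(rep(loss_mask, each = dim(yhat)[1]), dim = dim(yhat))
  -sum(msk * (y * log(yhat + eps) + (1 - y) * log(1 - yhat + eps))) / nb
}

## Backpropagation through time. Returns gradients with the same names as
## the parameter matrices, for the mean-per-sequence masked logistic loss.
gru_backward <- function(params, fwd, y, loss_mask) {
  mode <- params$mode
  H <- fwd$h; Yh <- fwd$yhat; cache <- fwd$cache
  h <- params$hidden_size; T_ <- dim(H)[2]; nb <- dim(H)[3]
  gr <- list()
  for (nm in names(params)) {
    if (is.matrix(params[[nm]])) gr[[nm]] <- params[[nm]] * 0
    else if (is.numeric(params[[nm]]) && length(params[[nm]]) > 1)
      gr[[nm]] <- params[[nm]] * 0
  }
  gr$Who <- params$Who * 0; gr$bho <- params$bho * 0
  dh_next <- matrix(0, h, nb)
  for (t in rev(seq_len(T_))) {
    ht <- matrix(H[, t, ], h, nb)
    dh <- dh_next
    if (loss_mask[t] > 0) {
      dlogit <- (matrix(Yh[, t, ], params$n_output, nb) -
                   matrix(y[, t, ], params$n_output, nb)) / nb
      gr$Who <- gr$Who + dlogit %*% t(ht)
      gr$bho <- gr$bho + rowSums(dlogit)
      dh <- dh + t(params$Who) %*% dlogit
    }
    cc <- cache[[t]]
    if (mode == "no_gates") {
      da <- dh * (cc$a > 0)
      gr$Win <- gr$Win + da %*% t(cc$xt)
      gr$Whn <- gr$Whn + da %*% t(cc$hp)
      gr$bin <- gr$bin + rowSums(da); gr$bhn <- gr$bhn + rowSums(da)
      dh_next <- t(params$Whn) %*% da
    } else {
      r <- cc$r; z <- cc$z; n <- cc$n; hp <- cc$hp
      if (mode == "open_update") {
        dn <- dh
        dz <- NULL
        dh_prev <- matrix(0, h, nb)
      } else {
        dn <- dh * (1 - z)
        dz <- dh * (hp - n)
        dh_prev <- dh * z
      }
      dan <- dn * (1 - n^2)
      gr$Win <- gr$Win + dan %*% t(cc$xt)
      gr$bin <- gr$bin + rowSums(dan)
      danr <- dan * r
      gr$Whn <- gr$Whn + danr %*% t(hp)
      gr$bhn <- gr$bhn + rowSums(danr)
      dh_prev <- dh_prev + t(params$Whn) %*% danr
      if (mode != "open_reset") {
        dr <- dan * cc$hn_pre
        dar <- dr * r * (1 - r)
        gr$Wir <- gr$Wir + dar %*% t(cc$xt)
        gr$Whr <- gr$Whr + dar %*% t(hp)
        gr$bir <- gr$bir + rowSums(dar); gr$bhr <- gr$bhr + rowSums(dar)
        dh_prev <- dh_prev + t(params$Whr) %*% dar
      }
      if (!is.null(dz)) {
        daz <- dz * z * (1 - z)
        gr$Wiz <- gr$Wiz + daz %*% t(cc$xt)
        gr$Whz <- gr$Whz + daz %*% t(hp)
        gr$biz <- gr$biz + rowSums(daz); gr$bhz <- gr$bhz + rowSums(daz)
        dh_prev <- dh_prev + t(params$Whz) %*% daz
      }
      dh_next <- dh_prev
    }
  }
  gr
}

## AdamW: decoupled weight decay; state carried across calls
adamw_step <- function(params, grads, state, lr = 0.01, wd = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t; b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) { state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0 }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    params[[nm]] <- params[[nm]] - step - lr * wd * params[[nm]]
  }
  list(params = params, state = state)
}

#' Train one network on a curriculum
#'
#' Gradient training with the masked logistic loss and decoupled
#' weight-decay updates. 2-trial curricula train on single-trial sequences
#' for the first `1 - two_trial_fraction` of epochs and on two-trial
#' sequences afterwards; input noise is resampled every epoch.
#'
#' @param spec a `curriculum_spec`.
#' @param mode architecture mode (see [gru_init()]); ablated modes get a
#'   parameter-matched hidden size automatically.
#' @param net_seed seed for this network (weights + noise stream).
#' @param lr optional learning-rate override (the vanilla network defaults
#'   to 0.001).
#' @return list with `params`, `loss_trace` (per epoch), `spec`, `mode`.
#' @export
train_curriculum <- function(spec, mode = "full", net_seed = spec$seed,
                             lr = NULL) {
  hid <- if (mode == "full") spec$hidden_size else
    matched_hidden_size(mode, spec$hidden_size)
  if (is.null(lr)) lr <- if (mode == "no_gates") 0.001 else spec$learning_rate
  params <- gru_init(hid, mode = mode, seed = net_seed)
  state <- list(t = 0L, m = list(), v = list())
  set.seed((net_seed * 104729L + 7L) %% 2147480L)   # minibatch shuffling stream
  n1 <- if (spec$switch_training == "2-trial")
    round(spec$n_epochs * (1 - spec$two_trial_fraction)) else spec$n_epochs
  loss_trace <- numeric(spec$n_epochs)
  for (ep in seq_len(spec$n_epochs)) {
    ntr <- if (ep <= n1) 1L else 2L
    reps <- if (ntr == 1L) spec$reps_per_epoch * 8L else spec$reps_per_epoch
    sq <- make_sequences(spec, n_trials_per_seq = ntr, reps = reps,
                         noise = TRUE, seed = (net_seed * 7919L + ep) %% 2147480L)
    nb <- dim(sq$x)[3]
    ord <- sample(nb)
    splits <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    ep_loss <- 0
    for (ix in splits) {
      xb <- sq$x[, , ix, drop = FALSE]; yb <- sq$y[, , ix, drop = FALSE]
      fwd <- gru_forward(params, xb, keep_cache = TRUE)
      ep_loss <- ep_loss + gru_loss(fwd$yhat, yb, sq$loss_mask) * length(ix)
      gr <- gru_backward(params, fwd, yb, sq$loss_mask)
      up <- adamw_step(params, gr, state, lr = lr, wd = spec$weight_decay)
      params <- up$params; state <- up$state
    }
    loss_trace[ep] <- ep_loss / nb
    if (!is.finite(loss_trace[ep]))
      stop(sprintf("training diverged (loss %s) at epoch %d",
                   format(loss_trace[ep]), ep))
  }
  list(params = params, loss_trace = loss_trace, spec = spec, mode = mode,
       net_seed = net_seed, phase1_epochs = n1)
}

#' Evaluate a trained network on the noise-free condition grid
#'
#' @param params trained `gru_params`.
#' @param spec the `curriculum_spec` (for the ITI).
#' @param n_trials_per_seq trials per test sequence.
#' @return list with overall `loss`, per-trial losses, `switch_loss` /
#'   `repeat_loss` per trial position (positions >= 2), and `accuracy`
#'   (correct response = larger output at the last masked step of each
#'   trial).
#' @export
evaluate_network <- function(params, spec, n_trials_per_seq = 2L) {
  sq <- make_sequences(spec, n_trials_per_seq = n_trials_per_seq,
                       reps = 1L, noise = FALSE)
  fwd <- gru_forward(params, sq$x)
  nb <- dim(sq$x)[3]
  eps <- 1e-12
  per_seq_trial <- matrix(0, nb, n_trials_per_seq)
  acc <- matrix(0, nb, n_trials_per_seq)
  for (k in seq_len(n_trials_per_seq)) {
    on <- sq$events$trial_onsets[k]
    stim_on <- on + CUE_LEN + DELAY_LEN
    span <- (stim_on + LOSS_LAG):(stim_on + STIM_LEN - 1)
    for (i in seq_len(nb)) {
      yh <- matrix(fwd$yhat[, span, i], N_OUTPUT)
      yy <- matrix(sq$y[, span, i], N_OUTPUT)
      per_seq_trial[i, k] <- -sum(yy * log(yh + eps) + (1 - yy) * log(1 - yh + eps))
      last <- ncol(yh)
      acc[i, k] <- as.numeric(which.max(yh[, last]) == which.max(yy[, last]))
    }
  }
  is_switch <- if (n_trials_per_seq >= 2)
    sq$tasks[, -1, drop = FALSE] != sq$tasks[, -n_trials_per_seq, drop = FALSE] else NULL
  out <- list(loss = mean(per_seq_trial), trial_loss = colMeans(per_seq_trial),
              accuracy = colMeans(acc))
  if (!is.null(is_switch)) {
    out$switch_loss <- vapply(seq_len(ncol(is_switch)), function(k)
      mean(per_seq_trial[is_switch[, k], k + 1]), numeric(1))
    out$repeat_loss <- vapply(seq_len(ncol(is_switch)), function(k)
      mean(per_seq_trial[!is_switch[, k], k + 1]), numeric(1))
  }
  out
}

#' Export the trial-2 preparation epoch of hidden states as a dataset
#'
#' Runs trained networks on two-trial sequences and extracts the hidden
#' states of the second trial's preparation (cue 10 + delay 20 + first 10
#' stimulus timesteps = 40), together with contrast-coded current/previous
#' task labels and the switch flag — the inputs to the state-space fitting
#' pipeline.
#'
#' @param params trained `gru_params`.
#' @param spec the `curriculum_spec`.
#' @param reps repetitions of the 64-condition grid.
#' @param noise simulate with input noise (as in the fitting protocol).
#' @param seed integer seed.
#' @return an `epoched_dataset` of hidden states (trials x hidden x 40)
#'   with labels `task`, `prev_task` (contrast-coded -1/+1) and `switch`.
#' @export
export_hidden_epochs <- function(params, spec, reps = 4L, noise = TRUE,
                                 seed = spec$seed) {
  sq <- make_sequences(spec, n_trials_per_seq = 2L, reps = reps,
                       noise = noise, seed = seed)
  fwd <- gru_forward(params, sq$x)
  on2 <- sq$events$trial_onsets[2]
  T_ep <- rnn_epoch_timesteps()
  span <- on2:(on2 + T_ep - 1)
  nb <- dim(sq$x)[3]
  Y <- array(0, dim = c(nb, params$hidden_size, T_ep))
  for (i in seq_len(nb)) Y[i, , ] <- fwd$h[, span, i]
  code <- function(task) ifelse(task == 1, -1, 1)
  labels <- data.frame(task = code(sq$tasks[, 2]),
                       prev_task = code(sq$tasks[, 1]))
  labels$switch <- switch_code(labels$task, labels$prev_task)
  epoched_dataset(Y = Y, labels = labels,
                  meta = list(cue = CUE_LEN, delay = DELAY_LEN,
                              trial = T_ep - CUE_LEN - DELAY_LEN,
                              iti = spec$iti_length))
}

#' Extract trial-averaged ITI hidden states following each task
#'
#' @param params trained `gru_params`.
#' @param spec the `curriculum_spec`.
#' @param reps repetitions of the condition grid.
#' @param seed integer seed.
#' @return list with `post_A`, `post_B` (hidden x ITI-length trial-averaged
#'   trajectories following task 1 / task 2).
#' @export
iti_states <- function(params, spec, reps = 4L, seed = spec$seed) {
  sq <- make_sequences(spec, n_trials_per_seq = 2L, reps = reps,
                       noise = TRUE, seed = seed)
  fwd <- gru_forward(params, sq$x)
  iti_span <- (TRIAL_LEN + 1):(TRIAL_LEN + spec$iti_length)
  post <- function(task)
    apply(fwd$h[, iti_span, sq$tasks[, 1] == task, drop = FALSE], c(1, 2), mean)
  list(post_A = post(1), post_B = post(2))
}
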