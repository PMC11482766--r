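test_that("sequence lengths follow the cue/delay/stimulus/ITI structure", {
  expect_equal(sequence_length(1, 20), 70)
  expect_equal(sequence_length(2, 20), 160)
  expect_equal(sequence_length(2, 60), 200)
  expect_equal(sequence_length(3, 20), 250)
})

test_that("the condition grid balances task, target and distractor transitions", {
  spec <- curriculum_spec("2-trial", seed = 3)
  sq <- make_sequences(spec, n_trials_per_seq = 2, reps = 1, noise = FALSE)
  expect_equal(dim(sq$x)[3], 64)
  sw <- sq$tasks[, 1] != sq$tasks[, 2]
  expect_equal(sum(sw), 32)                       # half switch, half repeat
  tg <- sq$conditions$target.1 != sq$conditions$target.2
  expect_equal(sum(tg), 32)
  ds <- sq$conditions$distractor.1 != sq$conditions$distractor.2
  expect_equal(sum(ds), 32)
})

test_that("input noise variance matches the configured SNR in dB", {
  spec <- curriculum_spec("1-trial", cue_snr_db = 0, trial_snr_db = -6.5, seed = 9)
  sq0 <- make_sequences(spec, 1, reps = 40, noise = FALSE)
  sq1 <- make_sequences(spec, 1, reps = 40, noise = TRUE, seed = 11)
  noise <- sq1$x - sq0$x
  # cue channels at 0 dB: noise variance equals the unit cue signal power
  expect_equal(var(as.vector(noise[5:6, , ])), 1, tolerance = 0.02)
  # stimulus channels at -6.5 dB: var = mean amplitude^2 * 10^(0.65)
  sig_p <- mean(c(1.25, 0.25)^2)
  expect_equal(var(as.vector(noise[1:4, , ])), sig_p * 10^(0.65), tolerance = 0.05)
  # at 0 dB the two variances would be equal by definition
  spec0 <- curriculum_spec("1-trial", cue_snr_db = 0, trial_snr_db = 0, seed = 9)
  n0 <- make_sequences(spec0, 1, reps = 40, noise = TRUE, seed = 12)$x -
    make_sequences(spec0, 1, reps = 40, noise = FALSE)$x
  expect_equal(var(as.vector(n0[1:4, , ])) / sig_p,
               var(as.vector(n0[5:6, , ])), tolerance = 0.05)
})

test_that("the correct answer is the larger-magnitude input of the cued pair", {
  spec <- curriculum_spec("1-trial", seed = 5)
  sq <- make_sequences(spec, 1, reps = 1, noise = FALSE)
  for (i in seq_len(dim(sq$x)[3])) {
    task <- sq$tasks[i, 1]
    stim_on <- 10 + 20 + 1
    pair <- sq$x[c(2 * task - 1, 2 * task), stim_on, i]
    ans <- which.max(pair)
    expect_equal(unname(which.max(sq$y[, stim_on, i])), unname(ans))
  }
})

test_that("gru_forward matches a hand-unrolled small-network computation", {
  p <- gru_init(2, mode = "full", n_input = 3, n_output = 1, seed = 17)
  x <- matrix(c(0.5, -1, 0.2,
                1.0, 0.3, -0.4,
                -0.2, 0.8, 0.1), 3, 3)
  out <- gru_forward(p, x)
  sig <- function(a) 1 / (1 + exp(-a))
  h <- c(0, 0)
  for (t in 1:3) {
    xt <- x[, t]
    r <- sig(p$Wir %*% xt + p$bir + p$Whr %*% h + p$bhr)
    z <- sig(p$Wiz %*% xt + p$biz + p$Whz %*% h + p$bhz)
    n <- tanh(p$Win %*% xt + p$bin + r * (p$Whn %*% h + p$bhn))
    h <- as.vector((1 - z) * n + z * h)
    expect_equal(out$h[, t, 1], h, tolerance = 1e-12)
    expect_equal(out$yhat[, t, 1], as.vector(sig(p$Who %*% h + p$bho)),
                 tolerance = 1e-12)
  }
})

test_that("gate ablations implement their fixed-gate definitions", {
  set.seed(21)
  x <- array(rnorm(6 * 12 * 2), dim = c(6, 12, 2))
  # update gate forced open: the state is fully overwritten by the new state
  p_u <- gru_init(5, mode = "open_update", seed = 2)
  f_u <- gru_forward(p_u, x, keep_cache = TRUE)
  for (t in c(3, 9))
    expect_equal(f_u$h[, t, 1], f_u$cache[[t]]$n[, 1], tolerance = 1e-12)
  # reset gate forced open: r contributes identically 1
  p_r <- gru_init(5, mode = "open_reset", seed = 2)
  f_r <- gru_forward(p_r, x, keep_cache = TRUE)
  for (t in c(3, 9)) expect_true(all(f_r$cache[[t]]$r == 1))
  # zero weights: hidden stays 0 and outputs 0.5
  p0 <- gru_init(4, mode = "full", seed = 3)
  for (nm in names(p0)) if (is.numeric(p0[[nm]]) && length(p0[[nm]]) > 1) p0[[nm]][] <- 0
  f0 <- gru_forward(p0, x)
  expect_equal(max(abs(f0$h)), 0)
  expect_equal(unique(as.vector(f0$yhat)), 0.5)
  # frozen state when the update gate saturates at 1
  pf <- gru_init(4, mode = "full", seed = 4)
  pf$biz[] <- 50   # z ~= 1 => h_t = h_{t-1}
  ff <- gru_forward(pf, x)
  expect_equal(ff$h[, 12, 1], ff$h[, 1, 1], tolerance = 1e-8)
})

test_that("ablated hidden sizes match the full model's parameter count closely", {
  for (hfull in c(32, 108)) {
    target <- gru_n_params(mode = "full", hidden_size = hfull)
    for (mode in c("open_reset", "open_update", "no_gates")) {
      hm <- matched_hidden_size(mode, hfull)
      got <- gru_n_params(mode = mode, hidden_size = hm)
      # within half the integer-grid granularity of the count function
      gran <- abs(gru_n_params(mode = mode, hidden_size = hm + 1) -
                    gru_n_params(mode = mode, hidden_size = hm - 1)) / 2
      expect_lte(abs(got - target), gran)
      expect_lt(abs(got - target) / target, 0.02)
      expect_gt(hm, hfull)   # fewer gates => more units for the same budget
    }
  }
})

test_that("BPTT gradients match finite differences for every architecture", {
  set.seed(31)
  for (mode in c("full", "open_reset", "open_update", "no_gates")) {
    p <- gru_init(3, mode = mode, seed = 13)
    x <- array(rnorm(6 * 6 * 2), dim = c(6, 6, 2))
    y <- array(rbinom(2 * 6 * 2, 1, 0.5), dim = c(2, 6, 2))
    msk <- c(0, 0, 1, 1, 1, 1)
    fwd <- gru_forward(p, x, keep_cache = TRUE)
    gr <- gru_backward(p, fwd, y, msk)
    for (nm in c("Win", "Whn", "Who")) {
      idx <- sample(length(p[[nm]]), 3)
      for (i in idx) {
        eps <- 1e-5
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
        fd <- (gru_loss(gru_forward(pp, x)$yhat, y, msk) -
               gru_loss(gru_forward(pm, x)$yhat, y, msk)) / (2 * eps)
        expect_equal(gr[[nm]][i], fd, tolerance = 1e-6)
      }
    }
  }
})

test_that("planted ground-truth systems encode the requested initial geometry", {
  gt_mid <- sample_ground_truth(n_factors = 5, n_obs = 6, n_trials_sim = 64,
                                T_ = 24, seed = 7, init_mode = "midpoint")
  sub <- decompose(gt_mid$params, gt_mid$design, "repeat")
  expect_equal(max(abs(sub$x[, 1])), 0)           # initial state at the origin
  d <- midpoint_score(sub)
  expect_true(all(abs(d[-1]) < 1e-10))            # exactly neutral by symmetry
  gt_task <- sample_ground_truth(n_factors = 5, n_obs = 6, n_trials_sim = 64,
                                 T_ = 24, seed = 7, init_mode = "task")
  sub_t <- decompose(gt_task$params, gt_task$design, "repeat")
  d_t <- midpoint_score(sub_t)
  expect_lt(mean(d_t[2:10]), -0.8)                # starts on the task state
  # stationary sampling: no blow-up over the epoch
  expect_lt(max(abs(gt_task$data$Y)), 100)
  # determinism
  gt2 <- sample_ground_truth(n_factors = 5, n_obs = 6, n_trials_sim = 64,
                             T_ = 24, seed = 7, init_mode = "midpoint")
  expect_identical(gt_mid$data$Y, gt2$data$Y)
})

test_that("hidden-state export produces a well-formed epoched dataset", {
  spec <- curriculum_spec("2-trial", seed = 41)
  p <- gru_init(spec$hidden_size, seed = 41)
  d <- export_hidden_epochs(p, spec, reps = 1, noise = FALSE)
  expect_s3_class(d, "epoched_dataset")
  expect_equal(dim(d$Y), c(64, spec$hidden_size, 40))
  expect_true(all(d$labels$task %in% c(-1, 1)))
  expect_true(all(d$labels$switch == switch_code(d$labels$task, d$labels$prev_task)))
  # hidden states bounded by the saturating nonlinearity
  expect_true(all(abs(d$Y) <= 1))
  # epoch alignment: the exported epoch starts at the second trial's cue
  sq <- make_sequences(spec, 2, reps = 1, noise = FALSE)
  fwd <- gru_forward(p, sq$x)
  on2 <- sq$events$trial_onsets[2]
  expect_equal(d$Y[5, , 1], fwd$h[, on2, 5])
})
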