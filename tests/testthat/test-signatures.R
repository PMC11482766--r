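make_design <- function(n = 80, T_ = 21, n_basis = 6, seed = 71) {
  set.seed(seed)
  labels <- data.frame(task = sample(c(-1, 1), n, replace = TRUE),
                       prev_task = sample(c(-1, 1), n, replace = TRUE))
  labels$switch <- switch_code(labels$task, labels$prev_task)
  spec <- design_spec(predictors = c("bias", "task", "prev_task", "switch"),
                      init_predictors = c("intercept", "prev_task"),
                      n_basis = n_basis)
  list(design = spline_inputs(labels, T_, spec), labels = labels, T_ = T_)
}

fitted_like_params <- function(design, Dx = 5, Dy = 4, seed = 72) {
  set.seed(seed)
  Du <- nrow(design$columns); Du0 <- nrow(design$init_columns)
  p <- random_stable_ssm(Dx, Dy, Du = Du, Du0 = Du0, rho = 0.85)
  p
}

test_that("subsystem trajectories superpose to the full deterministic trajectory", {
  dz <- make_design()
  p <- fitted_like_params(dz$design)
  values <- c(bias = 1, task = 1, prev_task = -1, switch = 1,
              intercept = 1)
  ci_full <- condition_inputs(dz$design, values)
  x_full <- propagate_linear(p, ci_full$u, ci_full$u0)
  # split the inputs predictor-by-predictor and re-propagate
  groups <- list(c(bias = 1), c(task = 1), c(prev_task = -1), c(switch = 1),
                 c(intercept = 1))
  x_sum <- 0
  for (g in groups) {
    ci <- condition_inputs(dz$design, g)
    x_sum <- x_sum + propagate_linear(p, ci$u, ci$u0)
  }
  expect_equal(x_sum, x_full, tolerance = 1e-8)
})

test_that("zero task inputs give an identically zero subsystem trajectory", {
  dz <- make_design()
  p <- fitted_like_params(dz$design)
  p$B[, dz$design$columns$predictor %in% c("task", "prev_task")] <- 0
  p$B0[, dz$design$init_columns$predictor == "prev_task"] <- 0
  sub <- decompose(p, dz$design, "switch")
  expect_equal(max(abs(sub$x)), 0)
})

test_that("flipping the task contrast negates the subsystem trajectory exactly", {
  dz <- make_design()
  p <- fitted_like_params(dz$design)
  s_pos <- decompose(p, dz$design, "switch", task = 1)
  s_neg <- decompose(p, dz$design, "switch", task = -1)
  expect_equal(s_pos$x, -s_neg$x, tolerance = 1e-12)
  r_pos <- decompose(p, dz$design, "repeat", task = 1)
  r_neg <- decompose(p, dz$design, "repeat", task = -1)
  expect_equal(r_pos$x, -r_neg$x, tolerance = 1e-12)
})

test_that("decompose errors when the task predictor is missing", {
  dz <- make_design()
  p <- fitted_like_params(dz$design)
  expect_error(decompose(p, dz$design, "switch", task_predictor = "nope"),
               "absent from design")
})

test_that("cross-lag cosine matrix has the expected identities", {
  set.seed(80)
  X <- matrix(rnorm(4 * 7), 4, 7)
  S <- switch_similarity(X, X)
  expect_equal(diag(S), rep(1, 7), tolerance = 1e-12)
  S2 <- switch_similarity(X, -X)
  expect_equal(S2, -S, tolerance = 1e-12)
  # orthogonal constant states: zero everywhere
  Xa <- matrix(rep(c(1, 0), 5), 2, 5)
  Xb <- matrix(rep(c(0, 1), 5), 2, 5)
  expect_equal(max(abs(switch_similarity(Xa, Xb))), 0)
  # zero-norm state yields NA, not zero
  Xz <- X; Xz[, 3] <- 0
  expect_true(all(is.na(switch_similarity(Xz, X)[3, ])))
})

test_that("midpoint score hits its endpoints on constructed geometries", {
  # x1 on task A's state at time t => -1; on task B's state => +1;
  # at the exact midpoint with xB = -xA => 0
  xA <- matrix(c(1, 1, 1, 2, 3, 4), 2, 3)       # 2-dim states over T = 3
  d1 <- midpoint_score(xA, x1 = xA[, 2])
  expect_equal(d1[2], -1)
  d2 <- midpoint_score(xA, x1 = -xA[, 3])
  expect_equal(d2[3], 1)
  d3 <- midpoint_score(xA, x1 = c(0, 0))
  expect_equal(d3, rep(0, 3))
  # undefined when both distances vanish
  x0 <- matrix(0, 2, 2)
  expect_true(all(is.na(midpoint_score(x0, x1 = c(0, 0)))))
  # bounded and antisymmetric under swapping task roles
  set.seed(81)
  xr <- matrix(rnorm(6 * 5), 6, 5); x1 <- rnorm(6)
  dA <- midpoint_score(xr, x1 = x1)
  dB <- midpoint_score(-xr, xB = xr, x1 = x1)
  expect_true(all(abs(dA) <= 1 + 1e-12))
  expect_equal(dA, -dB, tolerance = 1e-12)
})

test_that("ITI log-distance recovers a planted exponential decay rate", {
  Dx <- 3; T_ <- 12; lambda <- 0.8
  v <- c(1, -1, 2); v <- v / sqrt(sum(v^2))
  postA <- sapply(0:(T_ - 1), function(t) 0.5 * lambda^t * v)
  postB <- -postA
  out <- iti_convergence(postA, postB)
  expect_equal(out$slope, log(lambda), tolerance = 1e-10)
  # isometry invariance
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  out2 <- iti_convergence(Q %*% postA, Q %*% postB)
  expect_equal(out2$log_distance, out$log_distance, tolerance = 1e-10)
  # identical trajectories guard the log singularity
  expect_true(all(is.na(iti_convergence(postA, postA)$log_distance)))
  expect_error(iti_convergence(postA[, 1, drop = FALSE], postB[, 1, drop = FALSE]),
               "at least 2")
})

test_that("task-energy recursion matches the unrolled sum and trivial cases", {
  set.seed(90)
  dz <- make_design(T_ = 11, n_basis = 4)
  p <- fitted_like_params(dz$design, Dx = 4, Dy = 3)
  sub <- decompose(p, dz$design, "switch")
  en <- task_energy(p, sub)
  expect_equal(en$G[[1]], matrix(0, 4, 4))
  expect_true(is.na(en$log_trace[1]))
  # unrolled-sum oracle: G_t = sum_{s=2}^{t} A^{t-s} b_{s-1} b_{s-1}' (A^{t-s})'
  for (t in c(3, 7, 11)) {
    Gsum <- matrix(0, 4, 4)
    for (s in 2:t) {
      b <- p$B %*% sub$u[, s - 1]
      Ak <- diag(4)
      for (k in seq_len(t - s)) Ak <- Ak %*% p$A
      Gsum <- Gsum + Ak %*% tcrossprod(b) %*% t(Ak)
    }
    expect_equal(en$G[[t]], Gsum, tolerance = 1e-8)
  }
  # A = 0: each Gramian is just the current input outer product
  p0 <- p; p0$A <- matrix(0, 4, 4)
  en0 <- task_energy(p0, sub)
  for (t in 2:11) {
    b <- p0$B %*% sub$u[, t - 1]
    expect_equal(en0$G[[t]], tcrossprod(b), tolerance = 1e-12)
  }
  # zero inputs: zero trace everywhere
  enz <- task_energy(p, matrix(0, nrow(sub$u), ncol(sub$u)))
  expect_equal(enz$trace, rep(0, 11))
})

test_that("asymptotic Gramian solves the Lyapunov equation", {
  # scalar closed form b^2 / (1 - a^2)
  p <- list(A = matrix(0.7), B = matrix(1.5))
  expect_equal(asymptotic_gramian(p)[1, 1], 1.5^2 / (1 - 0.7^2), tolerance = 1e-8)
  # A = 0 => G = B B'
  set.seed(91)
  B <- matrix(rnorm(6), 3, 2)
  expect_equal(asymptotic_gramian(list(A = matrix(0, 3, 3), B = B)),
               tcrossprod(B), tolerance = 1e-12)
  # residual of the fixed point is tiny for a random stable system
  p2 <- random_stable_ssm(4, 3, Du = 2, rho = 0.9)
  G <- asymptotic_gramian(p2)
  expect_lt(max(abs(G - (p2$A %*% G %*% t(p2$A) + tcrossprod(p2$B)))), 1e-8)
  # unstable system rejected
  expect_error(asymptotic_gramian(list(A = matrix(1.01), B = matrix(1))), "stable")
})

test_that("long-run Gramian recursion with white-noise inputs approaches G_inf", {
  set.seed(92)
  p <- random_stable_ssm(3, 3, Du = 2, rho = 0.8)
  Ginf <- asymptotic_gramian(p)
  T_ <- 6000
  u <- matrix(rnorm(2 * (T_ - 1)), 2, T_ - 1)
  en <- task_energy(p, u)
  # the recursion converges to G_inf in expectation; average over time after
  # burn-in to beat down the fluctuations of a single run
  Gbar <- Reduce(`+`, en$G[200:T_]) / length(200:T_)
  expect_equal(Gbar, Ginf, tolerance = 0.1)
})

test_that("signatures are invariant under orthogonal latent transforms", {
  dz <- make_design(T_ = 13, n_basis = 4)
  p <- fitted_like_params(dz$design, Dx = 4, Dy = 4, seed = 95)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  pQ <- transform_system(p, Q)
  for (cond in c("switch", "repeat")) {
    s1 <- decompose(p, dz$design, cond)
    s2 <- decompose(pQ, dz$design, cond)
    expect_equal(midpoint_score(s1), midpoint_score(s2), tolerance = 1e-8)
    expect_equal(task_energy(p, s1)$trace, task_energy(pQ, s2)$trace,
                 tolerance = 1e-8)
  }
  s1s <- decompose(p, dz$design, "switch"); s1r <- decompose(p, dz$design, "repeat")
  s2s <- decompose(pQ, dz$design, "switch"); s2r <- decompose(pQ, dz$design, "repeat")
  expect_equal(switch_similarity(s1s, s1r), switch_similarity(s2s, s2r),
               tolerance = 1e-8)
})

test_that("svd_embed is exact with all components and deterministic in sign", {
  set.seed(96)
  # rank-1 input: a single nonzero singular value
  X1 <- outer(rnorm(6), rnorm(4))
  sv1 <- svd_embed(X1)
  expect_equal(sum(sv1$d > 1e-10 * sv1$d[1]), 1)
  X <- matrix(rnorm(8 * 5), 8, 5)
  sv <- svd_embed(X)
  expect_equal(sv$scores %*% t(sv$v), X, tolerance = 1e-10)
  expect_equal(t(sv$v) %*% sv$v, diag(5), tolerance = 1e-10)
  expect_equal(t(sv$u) %*% sv$u, diag(5), tolerance = 1e-10)
  # sign convention: the largest-magnitude loading per component is positive
  for (j in 1:5) expect_gt(sv$v[which.max(abs(sv$v[, j])), j], 0)
})
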