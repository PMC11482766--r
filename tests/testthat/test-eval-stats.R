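test_that("generalized R2 equals the standard R2 for an iid-Gaussian linear model", {
  set.seed(101)
  n <- 200
  x <- rnorm(n); y <- 1 + 0.8 * x + rnorm(n, sd = 0.7)
  fit <- lm(y ~ x); null <- lm(y ~ 1)
  g <- generalized_r2(as.numeric(logLik(fit)), as.numeric(logLik(null)), n)
  expect_equal(g, summary(fit)$r.squared, tolerance = 1e-8)
})

test_that("generalized R2 is zero at equality and monotone in the model likelihood", {
  expect_equal(generalized_r2(-50, -50, 100), 0)
  lls <- seq(-60, -40, by = 5)
  vals <- generalized_r2(lls, -55, 100)
  expect_true(all(diff(vals) > 0))
  expect_error(generalized_r2(-1, -2, 0), "positive")
})

sim_dataset <- function(Y) epoched_dataset(Y = Y)

test_that("null models rank as planted: VAR(1) data favor the autoregressive null", {
  set.seed(110)
  n <- 60; Dy <- 3; T_ <- 15
  A <- diag(c(0.9, 0.8, 0.7))
  Y <- array(0, dim = c(n, Dy, T_))
  for (i in 1:n) {
    x <- rnorm(Dy)
    for (t in 1:T_) {
      Y[i, , t] <- x
      x <- A %*% x + rnorm(Dy, sd = 0.3)
    }
  }
  nm <- null_models(sim_dataset(Y[1:45, , , drop = FALSE]),
                    sim_dataset(Y[46:60, , , drop = FALSE]))
  ll <- setNames(nm$loglik, nm$model)
  expect_gt(ll["var1"], ll["intercept"])
  expect_gt(ll["var1"], ll["encoding"])
})

test_that("on white noise the encoding model gains ~zero R2 over the intercept", {
  set.seed(111)
  n <- 80; Dy <- 2; T_ <- 12
  Y <- array(rnorm(n * Dy * T_), dim = c(n, Dy, T_))
  labels <- data.frame(task = sample(c(-1, 1), n, replace = TRUE))
  si <- spline_inputs(labels, T_, design_spec(predictors = c("bias", "task"),
                                              init_predictors = "intercept",
                                              n_basis = 4))
  d <- epoched_dataset(Y = Y, U = si$U, U0 = si$U0, labels = labels)
  tr <- subset_trials(d, 1:60); te <- subset_trials(d, 61:80)
  nm <- null_models(tr, te)
  ll <- setNames(nm$loglik, nm$model)
  r2_gain <- generalized_r2(ll["encoding"], ll["intercept"], nm$n_obs[1] * Dy)
  expect_lt(abs(r2_gain), 0.05)
})

test_that("intercept-only null equals the closed-form Gaussian score", {
  set.seed(112)
  Y <- array(rnorm(30 * 2 * 6, mean = 1.5), dim = c(30, 2, 6))
  tr <- sim_dataset(Y[1:20, , , drop = FALSE]); te <- sim_dataset(Y[21:30, , , drop = FALSE])
  nm <- null_models(tr, te)
  # oracle: per-dim mean/ML-variance from training rows (t = 2..T), scored on test
  stack <- function(Ya) do.call(rbind, lapply(2:6, function(t) matrix(Ya[, , t], nrow = dim(Ya)[1])))
  Str <- stack(Y[1:20, , , drop = FALSE]); Ste <- stack(Y[21:30, , , drop = FALSE])
  ll <- 0
  for (j in 1:2) {
    mu <- mean(Str[, j]); s2 <- mean((Str[, j] - mu)^2)
    ll <- ll + sum(dnorm(Ste[, j], mu, sqrt(s2), log = TRUE))
  }
  expect_equal(nm$loglik[nm$model == "intercept"], ll, tolerance = 1e-6)
})

test_that("protected exceedance is uniform for identical models, ~1 for a dominant one", {
  set.seed(120)
  scores <- matrix(rnorm(12), 6, 2)
  scores[, 2] <- scores[, 1]
  px <- protected_exceedance(scores, n_samples = 2e4, seed = 3)
  expect_equal(sum(px$pxp), 1, tolerance = 1e-10)
  expect_equal(px$pxp, c(0.5, 0.5), tolerance = 0.02)
  # dominance: model 2 better by >= 10 log-units for every subject
  scores2 <- cbind(rnorm(8), rnorm(8) + 12)
  px2 <- protected_exceedance(scores2, n_samples = 2e4, seed = 4)
  expect_gt(px2$pxp[2], 0.95)
  expect_equal(sum(px2$pxp), 1, tolerance = 1e-10)
})

test_that("parameter recovery is exact for identical and similarity-transformed systems", {
  set.seed(130)
  p <- random_stable_ssm(3, 3, Du = 2)
  U <- array(rnorm(50 * 2 * 9), dim = c(50, 2, 9))
  d <- sample_ssm(p, U = U, seed = 131)
  rec <- parameter_recovery(p, p, d$X, d$X)
  expect_true(all(rec$correlations > 1 - 1e-10))
  # a similarity-transformed copy must align back perfectly
  Tm <- matrix(rnorm(9), 3, 3) + 2 * diag(3)
  pT <- transform_system(p, Tm)
  XT <- d$X
  Ti <- solve(Tm)
  for (t in seq_len(dim(d$X)[3])) XT[, , t] <- d$X[, , t] %*% t(Ti)
  recT <- parameter_recovery(p, pT, d$X, XT)
  expect_true(all(recT$correlations > 1 - 1e-6))
})

test_that("TFCE is monotone under amplification and finds a constant effect", {
  set.seed(140)
  s <- abs(rnorm(30))
  e1 <- tfce_enhance(s); e2 <- tfce_enhance(2 * s)
  expect_true(all(e2 >= e1 - 1e-8))
  # constant large-effect maps: every element significant
  maps <- matrix(5, 12, 20) + matrix(rnorm(12 * 20, sd = 0.5), 12, 20)
  out <- tfce_correct(maps, n_perm = 200, seed = 7)
  expect_true(all(out$p < 0.05))
  # sign is preserved for negative effects
  outneg <- tfce_correct(-maps, n_perm = 200, seed = 7)
  expect_true(all(outneg$tfce < 0))
  expect_true(all(outneg$p < 0.05))
})

test_that("TFCE works on 2-D cross-lag maps with 4-connectivity", {
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- TRUE; mask[2, 1] <- TRUE   # connected vertically
  mask[4, 4] <- TRUE                       # separate component
  lab <- taskdyn:::label_components_2d(mask)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 1])
  expect_true(lab[4, 4] != lab[1, 1])
  set.seed(141)
  maps <- array(rnorm(10 * 6 * 6), dim = c(10, 6, 6))
  maps[, 2:3, 2:3] <- maps[, 2:3, 2:3] + 4
  out <- tfce_correct(maps, n_perm = 150, seed = 8)
  expect_true(all(out$p[2:3, 2:3] < 0.05))
  expect_warning(tfce_correct(maps[, 1, ], n_perm = 50, seed = 1), "100 permutations")
})

test_that("cross-modal similarity metrics satisfy their identities", {
  set.seed(150)
  x <- rnorm(20)
  A <- rbind(x, x, x); B <- rbind(x, x)
  cs <- crossmodal_similarity(A, B, metric = "congruence", n_boot = 200, seed = 2)
  expect_equal(cs$estimate, 1, tolerance = 1e-12)
  csn <- crossmodal_similarity(-A, B, metric = "congruence", n_boot = 200, seed = 2)
  expect_equal(csn$estimate, -1, tolerance = 1e-12)
  r2 <- crossmodal_similarity(A, B, metric = "r2", n_boot = 200, seed = 2)
  expect_equal(r2$estimate, 1, tolerance = 1e-12)
})

test_that("bootstrap draws are seed-reproducible and tighten with group size", {
  set.seed(151)
  base <- sin(seq(0, 3, length.out = 25))
  make_group <- function(n, sd) t(replicate(n, base + rnorm(25, sd = sd)))
  A1 <- make_group(8, 0.5); B1 <- make_group(8, 0.5)
  c1 <- crossmodal_similarity(A1, B1, n_boot = 400, seed = 9)
  c1b <- crossmodal_similarity(A1, B1, n_boot = 400, seed = 9)
  expect_identical(c1$draws, c1b$draws)
  A2 <- make_group(64, 0.5); B2 <- make_group(64, 0.5)
  c2 <- crossmodal_similarity(A2, B2, n_boot = 400, seed = 10)
  expect_lt(sd(c2$draws), sd(c1$draws))
  expect_true(c1$ci[1] <= c1$estimate + 0.1 && c1$ci[2] >= c1$estimate - 0.1)
})

test_that("series resampling preserves endpoints and linear trends", {
  x <- seq(2, 10, length.out = 100)
  y <- resample_series(x, 40)
  expect_equal(y[1], 2); expect_equal(y[40], 10)
  expect_equal(y, seq(2, 10, length.out = 40), tolerance = 1e-10)
})
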