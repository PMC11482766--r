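#' Cox-Snell generalized R-squared
#'
#' `1 - (L0 / LM)^(2/n)`, computed in log space from the two models'
#' log-likelihoods on the same data. Equivalent to the standard R-squared
#' for Gaussian linear models with iid residuals, but applicable to any
#' likelihood (e.g. the anisotropic, time-varying predictive covariance of
#' a Kalman filter).
#'
#' @param loglik_model,loglik_null log-likelihoods on the same `n` samples.
#' @param n sample size.
#' @return generalized R-squared (can be negative if the model underfits
#'   the null).
#' @export
generalized_r2 <- function(loglik_model, loglik_null, n) {
  if (n <= 0) stop("n must be positive")
  1 - exp((2 / n) * (loglik_null - loglik_model))
}

## Gaussian log-likelihood of rows of E under a diagonal covariance sigma2
gauss_loglik_diag <- function(E, sigma2) {
  n <- nrow(E)
  -0.5 * (n * sum(log(2 * pi * sigma2)) + sum(sweep(E^2, 2, sigma2, "/")))
}

#' Sensor-level null models for held-out prediction
#'
#' Fits four reference models directly to the observed component scores
#' (no latent embedding): (1) intercept only, (2) spline-basis encoding of
#' the inputs, (3) first-order vector autoregression, (4) autoregression
#' plus encoding. Models are fit on the training split by (ridge-guarded)
#' least squares with diagonal Gaussian residuals, and scored on the test
#' split; model 4 is the usual benchmark.
#'
#' @param train,test `epoched_dataset`s sharing the same design.
#' @param ridge ridge added to the regression Gram matrix when it is
#'   rank-deficient (applied always, at negligible scale, and logged via a
#'   message when it changes the solution).
#' @return data.frame with one row per null model: name, held-out
#'   log-likelihood, number of test samples (`n_obs`, trials x timesteps).
#' @export
null_models <- function(train, test, ridge = 1e-8) {
  stack <- function(data, with_ar, with_enc) {
    n <- n_trials(data); T_ <- n_timesteps(data)
    Dy <- dim(data$Y)[2]; Du <- dim(data$U)[2]
    ## predict y_t for t = 2..T (AR needs a previous observation)
    Yresp <- NULL; X <- NULL
    for (t in 2:T_) {
      yt <- matrix(data$Y[, , t], nrow = n)
      xt <- matrix(1, n, 1)
      if (with_ar) xt <- cbind(xt, matrix(data$Y[, , t - 1], nrow = n))
      if (with_enc && Du > 0) xt <- cbind(xt, matrix(data$U[, , t - 1], nrow = n))
      Yresp <- rbind(Yresp, yt); X <- rbind(X, xt)
    }
    list(Y = Yresp, X = X)
  }
  fit_score <- function(with_ar, with_enc) {
    tr <- stack(train, with_ar, with_enc)
    te <- stack(test, with_ar, with_enc)
    G <- crossprod(tr$X)
    Gr <- G + diag(ridge * max(diag(G), 1), ncol(G))
    if (rcond(G) < 1e-12)
      message("null_models: rank-deficient design; ridge fallback used")
    Bh <- solve(Gr, crossprod(tr$X, tr$Y))
    resid_tr <- tr$Y - tr$X %*% Bh
    sigma2 <- pmax(colMeans(resid_tr^2), 1e-12)
    E <- te$Y - te$X %*% Bh
    gauss_loglik_diag(E, sigma2)
  }
  n_test <- nrow(stack(test, FALSE, FALSE)$Y)
  data.frame(
    model = c("intercept", "encoding", "var1", "var1_encoding"),
    loglik = c(fit_score(FALSE, FALSE), fit_score(FALSE, TRUE),
               fit_score(TRUE, FALSE), fit_score(TRUE, TRUE)),
    n_obs = n_test
  )
}

#' Protected exceedance probabilities for random-effects model selection
#'
#' Variational Bayes over per-subject model frequencies with a uniform
#' Dirichlet prior: estimates the population frequency of each model from
#' per-subject log model evidences, the exceedance probability that each
#' model is the most frequent (by Monte-Carlo sampling of the Dirichlet
#' posterior), and the Bayes omnibus risk (the posterior probability that
#' all models are equally frequent). The protected exceedance probability
#' blends exceedance with chance by the omnibus risk, and sums to 1.
#'
#' @param scores subjects x models matrix of log evidences (e.g. held-out
#'   log-likelihoods).
#' @param n_samples Monte-Carlo draws for the exceedance computation.
#' @param seed integer seed for the draws.
#' @return list with `alpha` (Dirichlet posterior), `expected_freq`, `xp`
#'   (exceedance), `bor`, `pxp`.
#' @export
protected_exceedance <- function(scores, n_samples = 1e5, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores); K <- ncol(scores)
  if (n < 2 || K < 2) stop("need at least 2 subjects and 2 models")
  lme <- scores - apply(scores, 1, max)   # stabilize
  alpha0 <- rep(1, K)
  alpha <- alpha0
  for (it in 1:200) {
    lg <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(lme, 2, lg, `+`)
    u <- exp(lu - apply(lu, 1, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-10) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  ## exceedance probabilities by Dirichlet sampling
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              n_samples, K)
  if (!is.null(old)) assign(".Random.seed", envir = globalenv(), value = old)
  win <- max.col(g, ties.method = "random")
  xp <- tabulate(win, K) / n_samples
  ## Bayes omnibus risk: H0 (equal frequencies) vs H1 (the Dirichlet model)
  F1 <- pxp_free_energy(lme, alpha, alpha0, u)
  F0 <- sum(apply(lme, 1, function(r) log(mean(exp(r - max(r))) ) + max(r)))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- (1 - bor) * xp + bor / K
  list(alpha = alpha, expected_freq = alpha / sum(alpha),
       xp = xp, bor = bor, pxp = pxp)
}

## variational free energy of the random-effects model (up to shared consts)
pxp_free_energy <- function(lme, alpha, alpha0, u) {
  lg <- digamma(alpha) - digamma(sum(alpha))
  Elogjoint <- sum(u * (lme + matrix(lg, nrow(u), ncol(u), byrow = TRUE)))
  lbeta_v <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  kl_dir <- lbeta_v(alpha0) - lbeta_v(alpha) +
    sum((alpha - alpha0) * (digamma(alpha) - digamma(sum(alpha))))
  ent_u <- -sum(u[u > 0] * log(u[u > 0]))
  Elogjoint - kl_dir + ent_u
}

#' Correlate generating and recovered state-space parameters after alignment
#'
#' Latent coordinates are only identified up to an invertible transform, so
#' the estimated system is first aligned to the generating one by
#' regressing the generating latent trajectories on the estimated ones
#' (least-squares alignment map), then each parameter matrix is correlated
#' elementwise; covariance matrices are compared through the lower
#' triangles of their Cholesky factors.
#'
#' @param true,est `ssm_params` objects with equal latent dimension.
#' @param latents_true,latents_est latent trajectories on the same trials
#'   (trials x factors x T arrays, e.g. the generating `X` and the fitted
#'   smoothed means).
#' @return list with `correlations` (named vector over A, B, C, W, V, W1,
#'   B0), the alignment map `Tmat`, and the aligned estimate `est_aligned`.
#' @export
parameter_recovery <- function(true, est, latents_true, latents_est) {
  flatten <- function(L) {
    d <- dim(L)
    out <- matrix(0, d[1] * d[3], d[2])
    for (t in seq_len(d[3])) out[(t - 1) * d[1] + seq_len(d[1]), ] <- matrix(L[, , t], nrow = d[1])
    out
  }
  Xt <- flatten(latents_true); Xe <- flatten(latents_est)
  ## est coordinates -> true coordinates: x_true ~ M x_est
  M <- t(qr.solve(Xe, Xt))                       # Dx_true x Dx_est
  if (nrow(M) != ncol(M) || abs(det(M)) < 1e-12)
    stop("alignment map is not invertible")
  est_al <- transform_system(est, solve(M))     # x' = M x_est
  chol_lower <- function(S) {
    L <- t(chol(symmetrize(S) + diag(1e-12 * max(diag(S), 1e-12), nrow(S))))
    L[lower.tri(L, diag = TRUE)]
  }
  cor_safe <- function(a, b) {
    if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  cors <- c(
    A = cor_safe(as.vector(true$A), as.vector(est_al$A)),
    B = cor_safe(as.vector(true$B), as.vector(est_al$B)),
    C = cor_safe(as.vector(true$C), as.vector(est_al$C)),
    B0 = cor_safe(as.vector(true$B0), as.vector(est_al$B0)),
    W = cor_safe(chol_lower(true$W), chol_lower(est_al$W)),
    V = cor_safe(chol_lower(true$V), chol_lower(est_al$V)),
    W1 = cor_safe(chol_lower(true$W1), chol_lower(est_al$W1))
  )
  list(correlations = cors, Tmat = M, est_aligned = est_al)
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates cluster extent over statistic thresholds:
#' `TFCE(p) = sum_h extent(h)^E * h^H * dh` over thresholds up to the map
#' value at p, with the step `dh = max|stat| / n_steps`. 1-D maps use
#' 2-neighbor adjacency and 2-D maps 4-connectivity. Negative parts are
#' enhanced on the negated map, so the output is signed.
#'
#' @param stat numeric vector (1-D time course) or matrix (2-D
#'   time x time map).
#' @param H height exponent (default 2) and `E` extent exponent (default 1).
#' @param E see above.
#' @param n_steps integration steps.
#' @return TFCE-enhanced map, same shape as `stat`.
#' @export
tfce_enhance <- function(stat, H = 2, E = 1, n_steps = 100) {
  is_mat <- is.matrix(stat)
  enhance_pos <- function(s) {
    out <- array(0, dim = if (is_mat) dim(s) else length(s))
    hmax <- max(s, 0)
    if (hmax == 0) return(out)
    dh <- max(abs(stat)) / n_steps
    hs <- seq(dh, hmax, by = dh)
    for (h in hs) {
      above <- s >= h
      lab <- if (is_mat) label_components_2d(above) else label_components_1d(above)
      if (max(lab) == 0) next
      sizes <- tabulate(lab[lab > 0])
      inc <- sizes^E * h^H * dh
      out[above] <- out[above] + inc[lab[above]]
    }
    out
  }
  pos <- enhance_pos(pmax(stat, 0))
  neg <- enhance_pos(pmax(-stat, 0))
  res <- pos - neg
  if (is_mat) matrix(res, nrow(stat), ncol(stat)) else as.vector(res)
}

label_components_1d <- function(mask) {
  lab <- integer(length(mask)); cur <- 0L; prev <- FALSE
  for (i in seq_along(mask)) {
    if (mask[i]) {
      if (!prev) cur <- cur + 1L
      lab[i] <- cur
    }
    prev <- mask[i]
  }
  lab
}

label_components_2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[s] > 0L) next
      lab[s] <- cur
      r <- (s - 1L) %% nr + 1L; cl <- (s - 1L) %/% nr + 1L
      for (nb in c(if (r > 1) s - 1L, if (r < nr) s + 1L,
                   if (cl > 1) s - nr, if (cl < nc) s + nr)) {
        if (mask[nb] && lab[nb] == 0L) stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Sign-flip permutation test with TFCE correction
#'
#' One-sample group test of a statistic map against zero: the observed map
#' is the group t-statistic over subjects, enhanced with TFCE; the null
#' distribution of the maximum |TFCE| score is built by randomly flipping
#' each subject's sign (exchangeable under a symmetric null) and the
#' corrected two-sided p-value per element compares the observed |TFCE| to
#' that maximum distribution.
#'
#' @param maps subjects x elements matrix, or subjects x d1 x d2 array for
#'   2-D maps.
#' @param n_perm number of sign-flip permutations (a warning is issued
#'   below 100).
#' @param H,E TFCE exponents.
#' @param seed integer seed.
#' @return list with `tfce` (observed enhanced map), `tstat`, `p`
#'   (corrected p-values, same shape), `max_null` (null max distribution).
#' @export
tfce_correct <- function(maps, n_perm = 1000, H = 2, E = 1, seed = 1L) {
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  dm <- dim(maps)
  is_2d <- length(dm) == 3
  n <- dm[1]
  flat <- if (is_2d) matrix(maps, n, dm[2] * dm[3]) else as.matrix(maps)
  shape <- function(v) if (is_2d) matrix(v, dm[2], dm[3]) else v
  tmap_of <- function(M) {
    mu <- colMeans(M); s <- apply(M, 2, stats::sd)
    s[s == 0] <- Inf
    mu / (s / sqrt(n))
  }
  obs_t <- tmap_of(flat)
  obs_tfce <- tfce_enhance(shape(obs_t), H = H, E = E)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  max_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    fl <- sample(c(-1, 1), n, replace = TRUE)
    tb <- tmap_of(flat * fl)
    max_null[b] <- max(abs(tfce_enhance(shape(tb), H = H, E = E)))
  }
  if (!is.null(old)) assign(".Random.seed", envir = globalenv(), value = old)
  pvals <- vapply(abs(as.vector(obs_tfce)), function(v)
    (1 + sum(max_null >= v)) / (n_perm + 1), numeric(1))
  list(tfce = obs_tfce, tstat = shape(obs_t), p = shape(pvals),
       max_null = max_null)
}

#' Bootstrap similarity between signatures from two modalities
#'
#' Resamples both groups with replacement, averages the signature within
#' each group per draw, and computes either the congruence coefficient (the
#' cosine of the vectorized measures) or the R-squared similarity
#' `1 - sum((x - y)^2) / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))`
#' (which can be negative when the between-modality distance exceeds the
#' within-modality variance). The `group2` variant computes the metric
#' difference `metric(eeg, group1) - metric(eeg, group2)` within shared
#' draws of the reference group, which accounts for its sampling
#' variability.
#'
#' @param sig_a list/matrix of signatures for group A (rows = members) --
#'   typically the model group; and `sig_b` the reference group (e.g.
#'   recordings). Signatures must share length (resample first if needed,
#'   e.g. with [resample_series()]).
#' @param sig_a2 optional second model group for the difference variant.
#' @param metric `"congruence"` or `"r2"`.
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param conf percentile interval mass.
#' @return list of class `bootstrap_result`: `estimate` (full-sample
#'   metric), `draws`, `ci`, `metric`, `seed`.
#' @export
crossmodal_similarity <- function(sig_a, sig_b, sig_a2 = NULL,
                                  metric = c("congruence", "r2"),
                                  n_boot = 10000, seed = 1L, conf = 0.95) {
  metric <- match.arg(metric)
  A <- as.matrix(sig_a); B <- as.matrix(sig_b)
  if (ncol(A) != ncol(B)) stop("signature lengths differ; resample first")
  if (!is.null(sig_a2)) {
    A2 <- as.matrix(sig_a2)
    if (ncol(A2) != ncol(A)) stop("signature lengths differ; resample first")
  }
  mfun <- function(x, y) {
    if (metric == "congruence") {
      sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    } else {
      1 - sum((x - y)^2) / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    }
  }
  est <- if (is.null(sig_a2)) mfun(colMeans(A), colMeans(B)) else
    mfun(colMeans(A), colMeans(B)) - mfun(colMeans(A2), colMeans(B))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  draws <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ia <- sample(nrow(A), replace = TRUE)
    ib <- sample(nrow(B), replace = TRUE)
    xb <- colMeans(B[ib, , drop = FALSE])
    if (is.null(sig_a2)) {
      draws[b] <- mfun(colMeans(A[ia, , drop = FALSE]), xb)
    } else {
      ia2 <- sample(nrow(A2), replace = TRUE)
      draws[b] <- mfun(colMeans(A[ia, , drop = FALSE]), xb) -
        mfun(colMeans(A2[ia2, , drop = FALSE]), xb)
    }
  }
  if (!is.null(old)) assign(".Random.seed", envir = globalenv(), value = old)
  qs <- stats::quantile(draws, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(estimate = est, draws = draws, ci = qs, metric = metric,
                 n_boot = n_boot, seed = seed),
            class = "bootstrap_result")
}

#' Linearly resample a series to a target length
#'
#' Used to subsample recording-based signatures to the simulator's epoch
#' length before cross-modality comparison.
#' @param x numeric vector.
#' @param n_out target length.
#' @return length-`n_out` vector interpolated on a common [0, 1] axis.
#' @export
resample_series <- function(x, n_out) {
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n_out))$y
}
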