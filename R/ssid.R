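#' Configuration for subspace identification
#'
#' @param horizon number of lags in the delay embedding; must be at least
#'   `n_factors_max` so the largest model is identifiable from the embedding.
#' @param n_factors_max largest latent dimensionality that will be requested.
#' @param input_timesteps how many initial timesteps of each epoch carry
#'   inputs during identification; later input timesteps are zeroed to
#'   reduce collinearity between lagged inputs.
#' @return list of class `ssid_config`.
#' @export
ssid_config <- function(horizon, n_factors_max = horizon, input_timesteps = 5L) {
  if (horizon < n_factors_max)
    stop("horizon must be >= n_factors_max")
  structure(list(horizon = as.integer(horizon),
                 n_factors_max = as.integer(n_factors_max),
                 input_timesteps = as.integer(input_timesteps)),
            class = "ssid_config")
}

#' Build past/future block-Hankel (delay-embedding) matrices
#'
#' Reshapes the trial-wise data into one long time series (epochs
#' concatenated in trial order), zeroes inputs outside the initial timesteps
#' of each epoch, and assembles lagged past and future copies of
#' observations and inputs with consistent column alignment. Column `j`
#' is anchored at present time `t_j = j + horizon`: the past block stacks
#' `y_{t-1}, ..., y_{t-h}` (and input lags likewise), the future block
#' stacks `y_t, ..., y_{t+h-1}`, and the future-input block stacks
#' `u_{t-1}, ..., u_{t+h-2}` (the inputs driving the future states).
#'
#' @param data an `epoched_dataset`.
#' @param config an `ssid_config`.
#' @return list of class `hankel` with blocks `Yp`, `Up`, `Yf`, `Uf`, the
#'   long series `y_long`/`u_long`, present-time indices `t_present`, the
#'   epoch-start global indices, and dimensions.
#' @export
build_hankel <- function(data, config) {
  h <- config$horizon
  n <- n_trials(data); T_ <- n_timesteps(data)
  Dy <- dim(data$Y)[2]; Du <- dim(data$U)[2]
  Ttot <- n * T_
  if (Ttot < 2 * h)
    stop(sprintf("series length %d is shorter than 2*horizon = %d", Ttot, 2 * h))

  y_long <- matrix(0, Dy, Ttot)
  u_long <- matrix(0, Du, Ttot)       # u_long[, s] drives x_{s+1}
  for (i in seq_len(n)) {
    off <- (i - 1) * T_
    y_long[, off + seq_len(T_)] <- matrix(data$Y[i, , ], nrow = Dy)
  }
  if (Du > 0) {
    keep <- seq_len(min(config$input_timesteps, T_ - 1))
    for (i in seq_len(n)) {
      off <- (i - 1) * T_
      ui <- matrix(data$U[i, , ], nrow = Du)  # Du x (T-1)
      mask <- rep(0, T_ - 1); mask[keep] <- 1
      u_long[, off + seq_len(T_ - 1)] <- ui * rep(mask, each = Du)
    }
  }

  ncol_ <- Ttot - 2 * h + 1
  t_present <- h + seq_len(ncol_)
  stack_lags <- function(M, lags) {
    ## rows: M[, t + lag] for each lag, stacked; columns follow t_present
    out <- matrix(0, nrow(M) * length(lags), ncol_)
    for (k in seq_along(lags)) {
      rows <- (k - 1) * nrow(M) + seq_len(nrow(M))
      out[rows, ] <- M[, t_present + lags[k], drop = FALSE]
    }
    out
  }
  Yp <- stack_lags(y_long, -(1:h))
  Yf <- stack_lags(y_long, 0:(h - 1))
  Up <- if (Du > 0) stack_lags(u_long, -(1:h)) else matrix(0, 0, ncol_)
  Uf <- if (Du > 0) stack_lags(u_long, -1 + 0:(h - 1)) else matrix(0, 0, ncol_)

  structure(list(Yp = Yp, Yf = Yf, Up = Up, Uf = Uf,
                 y_long = y_long, u_long = u_long,
                 t_present = t_present,
                 epoch_starts = (seq_len(n) - 1) * T_ + 1,
                 horizon = h, Dy = Dy, Du = Du, T_epoch = T_, n_trials = n),
            class = "hankel")
}

## symmetric inverse square root with relative rank tolerance
inv_sqrt_sym <- function(S, tol = 1e-10) {
  e <- eigen(symmetrize(S), symmetric = TRUE)
  ev <- e$values
  keep <- ev > tol * max(ev, 0)
  inv <- numeric(length(ev))
  inv[keep] <- 1 / sqrt(ev[keep])
  e$vectors %*% (inv * t(e$vectors))
}

## residualize rows of X on rows of Z (ridge-stabilized projection)
residualize <- function(X, Z) {
  if (nrow(Z) == 0 || all(Z == 0)) return(X)
  G <- Z %*% t(Z)
  G <- G + diag(1e-10 * max(diag(G), 1), nrow(G))
  X - (X %*% t(Z)) %*% solve(G, Z)
}

#' Identify a state-space model by canonical variate analysis
#'
#' Conditions the future and past blocks on the future inputs, whitens both,
#' and takes the SVD of the whitened future-past cross-covariance. Latent
#' states are ordered by their singular values, so truncation to `k`
#' factors equals taking the leading `k`. `A` and `C` come from shift and
#' read-out regressions on the recovered state sequence; `B`, `B0` and the
#' noise covariances come from innovations-style regressions of the state
#' and observation residuals on the (epoch-start) inputs. If `A` is
#' unstable its spectrum is shrunk to radius 0.999 so the filter is
#' runnable.
#'
#' @param hankel result of [build_hankel()].
#' @param config the `ssid_config` used to build it.
#' @param n_factors requested latent dimensionality (<= `n_factors_max`).
#'   Factors beyond the numerical rank (singular values below `1e-10` of
#'   the largest) are dropped with a warning.
#' @return an `ssm_params` initialization; the CVA singular values are
#'   attached as attribute `singular_values`.
#' @export
cva_identify <- function(hankel, config, n_factors) {
  if (n_factors > config$n_factors_max)
    stop("n_factors exceeds n_factors_max")
  F_ <- residualize(hankel$Yf, hankel$Uf)
  P_ <- residualize(rbind(hankel$Yp, hankel$Up), hankel$Uf)
  nc <- ncol(F_)
  Sff <- F_ %*% t(F_) / nc
  Spp <- P_ %*% t(P_) / nc
  Sfp <- F_ %*% t(P_) / nc
  Lf <- inv_sqrt_sym(Sff)
  Lp <- inv_sqrt_sym(Spp)
  sv <- svd(Lf %*% Sfp %*% Lp)
  rank_ok <- sv$d > 1e-10 * sv$d[1]
  k <- n_factors
  if (sum(rank_ok) < k) {
    warning(sprintf("requested %d factors but numerical rank is %d; truncating",
                    k, sum(rank_ok)))
    k <- sum(rank_ok)
  }
  Dy <- hankel$Dy; Du <- hankel$Du
  h <- hankel$horizon
  tp <- hankel$t_present
  y_now <- hankel$y_long[, tp, drop = FALSE]

  ## memory map: x_j = S^(1/2) V' Lp p_j, evaluated on the raw past block;
  ## extended observability O = Sff^(1/2) U S^(1/2) in the same coordinates
  Phi <- (sqrt(sv$d[seq_len(k)]) * t(sv$v[, seq_len(k), drop = FALSE])) %*% Lp
  X <- Phi %*% rbind(hankel$Yp, hankel$Up)          # k x ncol
  ef <- eigen(symmetrize(Sff), symmetric = TRUE)
  Sff_half <- ef$vectors %*% (sqrt(pmax(ef$values, 0)) * t(ef$vectors))
  O <- Sff_half %*% sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(k)]), k)

  ## C from the first block row of O; A from the shift invariance of O
  C <- O[seq_len(Dy), , drop = FALSE]
  O_up <- O[seq_len((h - 1) * Dy), , drop = FALSE]
  O_dn <- O[Dy + seq_len((h - 1) * Dy), , drop = FALSE]
  A <- qr.solve(O_up, O_dn)
  sr <- spectral_radius(A)
  if (sr > 0.999) A <- A * (0.999 / sr)

  ## observation noise from the read-out residual on the state sequence
  V <- symmetrize(tcrossprod(y_now - C %*% X)) / nc
  V <- psd_floor(V + diag(1e-8 * max(diag(V), 1e-8), Dy))

  ## B and process noise from the transition residual with A held fixed
  j0 <- seq_len(nc - 1)
  R_tr <- X[, j0 + 1, drop = FALSE] - A %*% X[, j0, drop = FALSE]
  if (Du > 0) {
    Uj <- hankel$u_long[, tp[j0], drop = FALSE]     # u_t drives x_{t+1}
    Gu <- Uj %*% t(Uj); Gu <- Gu + diag(1e-8 * max(diag(Gu), 1), Du)
    B <- t(solve(Gu, Uj %*% t(R_tr)))
    R_tr <- R_tr - B %*% Uj
  } else {
    B <- matrix(0, k, 0)
  }
  W <- symmetrize(tcrossprod(R_tr)) / (nc - 1)
  W <- psd_floor(W + diag(1e-8 * max(diag(W), 1e-8), k))

  ## initial conditions from epoch-start columns
  starts <- intersect(hankel$epoch_starts, tp)
  B0 <- matrix(0, k, 0); W1 <- NULL
  if (length(starts) >= 2) {
    js <- match(starts, tp)
    X1 <- X[, js, drop = FALSE]
    trial_of <- (starts - 1) %/% hankel$T_epoch + 1
    U0 <- t(attr(hankel, "U0") %||% matrix(1, hankel$n_trials, 1))[, trial_of, drop = FALSE]
    G0 <- U0 %*% t(U0); G0 <- G0 + diag(1e-8 * max(diag(G0), 1), nrow(U0))
    B0 <- t(solve(G0, U0 %*% t(X1)))
    W1 <- symmetrize(tcrossprod(X1 - B0 %*% U0)) / length(js)
  }
  if (is.null(W1) || ncol(B0) == 0) {
    B0 <- matrix(rowMeans(X), k, 1)
    W1 <- symmetrize(tcrossprod(X - as.vector(B0))) / nc
  }
  W1 <- psd_floor(W1 + diag(1e-8 * max(diag(W1), 1e-8), k))

  out <- ssm_params(A = A, B = B, C = C, W = W, V = V, B0 = B0, W1 = W1)
  attr(out, "singular_values") <- sv$d
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize a state-space model from data via SSID
#'
#' Convenience wrapper: builds the delay embedding and runs [cva_identify()].
#' The dataset's `U0` matrix is used for the initial-condition regression.
#'
#' @param data an `epoched_dataset`.
#' @param n_factors requested latent dimensionality.
#' @param horizon embedding horizon; defaults to `n_factors`.
#' @param input_timesteps see [ssid_config()].
#' @return an `ssm_params` initialization.
#' @export
ssid_initialize <- function(data, n_factors, horizon = n_factors,
                            input_timesteps = 5L) {
  config <- ssid_config(horizon = max(horizon, n_factors),
                        n_factors_max = n_factors,
                        input_timesteps = input_timesteps)
  hk <- build_hankel(data, config)
  attr(hk, "U0") <- data$U0
  cva_identify(hk, config, n_factors)
}
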