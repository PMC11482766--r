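#' Construct the parameter set of a linear-Gaussian state-space model
#'
#' The generative model is a partially observed linear dynamical system:
#' \deqn{x_t = A x_{t-1} + B u_{t-1} + w_t, \quad w_t \sim N(0, W)}
#' \deqn{x_1 = B_0 u_0 + w_1, \quad w_1 \sim N(0, W_1)}
#' \deqn{y_t = C x_t + v_t, \quad v_t \sim N(0, V)}
#' Latent factors `x` evolve through recurrent dynamics (`A`), known inputs
#' (`B u`), and Gaussian process noise; observations are a linear read-out
#' (`C`) corrupted by observation noise. The number of latent factors may
#' exceed the number of observed dimensions (the over-parameterized regime),
#' which "lifts" the state so that a linear model can better approximate a
#' nonlinear system.
#'
#' @param A latent dynamics matrix (factors x factors).
#' @param B input matrix (factors x input dims). May have 0 columns.
#' @param C observation matrix (observed dims x factors).
#' @param W process-noise covariance (factors x factors), symmetric PSD.
#' @param V observation-noise covariance (observed x observed), symmetric PSD.
#' @param B0 initial-condition input matrix (factors x init-input dims).
#' @param W1 initial-state covariance (factors x factors), symmetric PSD.
#' @return An object of class `ssm_params`.
#' @export
ssm_params <- function(A, B, C, W, V, B0, W1) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  W <- as.matrix(W); V <- as.matrix(V); B0 <- as.matrix(B0); W1 <- as.matrix(W1)
  p <- structure(list(A = A, B = B, C = C, W = W, V = V, B0 = B0, W1 = W1),
                 class = "ssm_params")
  validate_ssm_params(p)
  p
}

#' @export
print.ssm_params <- function(x, ...) {
  d <- ssm_dims(x)
  cat(sprintf(
    "<ssm_params> %d factors, %d observed dims, %d inputs, %d init inputs\n",
    d$Dx, d$Dy, d$Du, d$Du0))
  cat(sprintf("  spectral radius of A: %.4f\n", spectral_radius(x$A)))
  invisible(x)
}

#' Dimensions of a state-space model
#'
#' @param params an `ssm_params` object.
#' @return list with `Dx` (factors), `Dy` (observed), `Du` (inputs),
#'   `Du0` (initial-condition inputs).
#' @export
ssm_dims <- function(params) {
  list(Dx = nrow(params$A), Dy = nrow(params$C),
       Du = ncol(params$B), Du0 = ncol(params$B0))
}

#' Validate a state-space parameter set
#'
#' Checks mutual dimension consistency and that W, V, W1 are symmetric
#' positive semidefinite to tolerance. Over-parameterized models
#' (factors > observed dims) are legal.
#'
#' @param params an `ssm_params` object.
#' @param tol symmetry / PSD tolerance relative to the matrix scale.
#' @return `params`, invisibly; errors name the offending matrix.
#' @export
validate_ssm_params <- function(params, tol = 1e-8) {
  A <- params$A; Dx <- nrow(A)
  if (ncol(A) != Dx) stop("A must be square")
  if (nrow(params$B) != Dx) stop("B must have as many rows as A")
  if (ncol(params$C) != Dx) stop("C must have `factors` columns")
  if (nrow(params$B0) != Dx) stop("B0 must have as many rows as A")
  for (nm in c("W", "W1")) {
    S <- params[[nm]]
    if (!all(dim(S) == c(Dx, Dx))) stop(sprintf("%s must be factors x factors", nm))
  }
  Dy <- nrow(params$C)
  if (!all(dim(params$V) == c(Dy, Dy))) stop("V must be observed x observed")
  for (nm in c("W", "V", "W1")) {
    S <- params[[nm]]
    sc <- max(abs(S), 1e-300)
    if (max(abs(S - t(S))) > tol * sc)
      stop(sprintf("%s is not symmetric", nm))
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * max(abs(ev), 1e-300))
      stop(sprintf("%s is not positive semidefinite (min eigenvalue %.3e)", nm, min(ev)))
  }
  invisible(params)
}

#' Spectral radius of a matrix
#' @param A square matrix.
#' @return largest eigenvalue magnitude.
#' @export
spectral_radius <- function(A) {
  if (nrow(A) == 0) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Apply an invertible similarity transform to a state-space model
#'
#' Re-expresses the latent coordinates as `x' = T^{-1} x`. The transformed
#' system (`A' = T^{-1} A T`, `B' = T^{-1} B`, `C' = C T`,
#' `W' = T^{-1} W T^{-T}`, likewise `B0`, `W1`; `V` unchanged) has an
#' identical marginal likelihood for any data: the latent basis is a pure
#' modeling degeneracy.
#'
#' @param params an `ssm_params` object.
#' @param Tmat invertible factors x factors matrix.
#' @return transformed `ssm_params`.
#' @export
transform_system <- function(params, Tmat) {
  Ti <- solve(Tmat)
  ssm_params(
    A  = Ti %*% params$A %*% Tmat,
    B  = Ti %*% params$B,
    C  = params$C %*% Tmat,
    W  = symmetrize(Ti %*% params$W %*% t(Ti)),
    V  = params$V,
    B0 = Ti %*% params$B0,
    W1 = symmetrize(Ti %*% params$W1 %*% t(Ti))
  )
}

#' Normalize the latent space to unit per-factor process noise
#'
#' Applies the diagonal similarity transform `T = diag(sqrt(diag(W)))` so the
#' transformed process-noise covariance has unit variance for every factor.
#' Used to put fitted models in comparable latent units before computing
#' dynamic signatures; the marginal likelihood is invariant.
#'
#' @param params an `ssm_params` object with strictly positive `diag(W)`.
#' @return normalized `ssm_params`.
#' @export
normalize_system <- function(params) {
  d <- diag(params$W)
  if (any(d <= 0))
    stop("normalize_system: diagonal of W must be strictly positive")
  transform_system(params, diag(sqrt(d), nrow = length(d)))
}

symmetrize <- function(S) (S + t(S)) / 2

## PSD matrix square root via eigendecomposition; tolerates (clips) tiny
## negative eigenvalues from round-off. Used for sampling from possibly
## singular covariances.
matrix_sqrt_psd <- function(S, name = "covariance") {
  S <- symmetrize(S)
  e <- eigen(S, symmetric = TRUE)
  ev <- e$values
  if (min(ev) < -1e-8 * max(abs(ev), 1e-300))
    stop(sprintf("%s is not positive semidefinite", name))
  ev[ev < 0] <- 0
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

## Cholesky with diagnostic jitter: symmetric PD factorization used in the
## filter. On failure adds 1e-10 * mean(diag) * I once and messages.
chol_jitter <- function(S, what = "matrix") {
  S <- symmetrize(S)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-10 * max(mean(diag(S)), 1e-300)
    R <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (is.null(R))
      stop(sprintf("Cholesky factorization of %s failed even with jitter", what))
    message(sprintf("chol_jitter: added jitter %.3e to %s", jit, what))
  }
  R
}

## log-determinant from an upper-triangular Cholesky factor
logdet_chol <- function(R) 2 * sum(log(diag(R)))
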