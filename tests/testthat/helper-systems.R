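# Shared fixtures: random stable systems and a dense joint-Gaussian oracle
# (built directly from the generative equations, independent of the
# filter/smoother recursions it is used to check).

random_psd <- function(d, scale = 1) {
  M <- matrix(rnorm(d * d), d, d)
  scale * (M %*% t(M) / d + diag(0.1, d))
}

random_stable_ssm <- function(Dx, Dy, Du = 0, Du0 = 1, rho = 0.8,
                              wscale = 1, vscale = 1) {
  A <- matrix(rnorm(Dx * Dx), Dx, Dx)
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  A <- A * (rho / sr)
  ssm_params(
    A = A,
    B = matrix(rnorm(Dx * Du), Dx, Du),
    C = matrix(rnorm(Dy * Dx), Dy, Dx),
    W = random_psd(Dx, wscale),
    V = random_psd(Dy, vscale),
    B0 = matrix(rnorm(Dx * Du0), Dx, Du0),
    W1 = random_psd(Dx)
  )
}

# Joint Gaussian of (x_{1:T}, y_{1:T}) for one trial, from first principles.
# u: Du x (T-1) matrix (columns drive x_{t+1}); u0: Du0 vector.
joint_gaussian_oracle <- function(params, T_, u = NULL, u0 = NULL) {
  Dx <- nrow(params$A); Dy <- nrow(params$C)
  if (is.null(u)) u <- matrix(0, ncol(params$B), T_ - 1)
  if (is.null(u0)) u0 <- rep(1, ncol(params$B0))
  mu_x <- matrix(0, Dx, T_)
  mu_x[, 1] <- params$B0 %*% u0
  for (t in seq(2, length.out = T_ - 1))
    mu_x[, t] <- params$A %*% mu_x[, t - 1] + params$B %*% u[, t - 1]
  # block covariance of x
  Sx <- matrix(0, Dx * T_, Dx * T_)
  blk <- function(s, t) list(r = ((s - 1) * Dx + 1):(s * Dx),
                             c = ((t - 1) * Dx + 1):(t * Dx))
  P <- vector("list", T_)
  P[[1]] <- params$W1
  for (t in seq(2, length.out = T_ - 1))
    P[[t]] <- params$A %*% P[[t - 1]] %*% t(params$A) + params$W
  for (t in seq_len(T_)) {
    b <- blk(t, t); Sx[b$r, b$c] <- P[[t]]
    if (t < T_) {
      cross <- P[[t]]
      for (s in seq(t + 1, T_)) {
        cross <- cross %*% t(params$A)   # Cov(x_t, x_s) grows by A' each step
        b2 <- blk(t, s)
        Sx[b2$r, b2$c] <- cross
        Sx[blk(s, t)$r, blk(s, t)$c] <- t(cross)
      }
    }
  }
  Cbig <- kronecker(diag(T_), params$C)
  Sy <- Cbig %*% Sx %*% t(Cbig) + kronecker(diag(T_), params$V)
  list(mu_x = as.vector(mu_x), mu_y = as.vector(Cbig %*% as.vector(mu_x)),
       Sx = Sx, Sy = Sy, Sxy = Sx %*% t(Cbig), Cbig = Cbig)
}

oracle_loglik <- function(or, yvec) {
  Sy <- (or$Sy + t(or$Sy)) / 2
  R <- chol(Sy)
  e <- yvec - or$mu_y
  z <- backsolve(R, e, transpose = TRUE)
  -0.5 * (length(yvec) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z))
}

oracle_smoothed <- function(or, yvec) {
  Sy <- (or$Sy + t(or$Sy)) / 2
  K <- or$Sxy %*% solve(Sy)
  mean_x <- or$mu_x + K %*% (yvec - or$mu_y)
  cov_x <- or$Sx - K %*% t(or$Sxy)
  list(mean = as.vector(mean_x), cov = cov_x)
}

# flatten one trial of an epoched dataset to the stacked (y_1; ...; y_T) vector
trial_yvec <- function(data, i) as.vector(matrix(data$Y[i, , ], nrow = dim(data$Y)[2]))
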