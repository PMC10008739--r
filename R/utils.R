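# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Swap halves of a vector so that index N/2 + 1 (0-frequency after DFT of a
# signal starting at t = 0) moves to the centre, matching an axis running
# -N/2 .. N/2 - 1.
fftshift_vec <- function(x) {
  n <- length(x)
  half <- ceiling(n / 2)
  c(x[(half + 1L):n], x[1L:half])
}

ifftshift_vec <- function(x) {
  n <- length(x)
  half <- floor(n / 2)
  c(x[(half + 1L):n], x[1L:half])
}

# n-dimensional fftshift for arrays (all dims swapped).
fftshift_arr <- function(a) {
  dims <- dim(a)
  idx <- lapply(dims, function(n) {
    half <- ceiling(n / 2)
    c((half + 1L):n, 1L:half)
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Cholesky factorization Sigma = L %*% Conj(t(L)) for a complex Hermitian
# positive-definite matrix; base chol() only covers the real case.
chol_complex <- function(sigma) {
  n <- nrow(sigma)
  L <- matrix(0 + 0i, n, n)
  for (j in seq_len(n)) {
    s <- sigma[j, j] - sum(Mod(L[j, seq_len(j - 1L)])^2)
    if (Re(s) <= 0) stop("matrix is not positive definite")
    L[j, j] <- sqrt(Re(s))
    if (j < n) {
      for (i in (j + 1L):n) {
        acc <- sum(L[i, seq_len(j - 1L)] * Conj(L[j, seq_len(j - 1L)]))
        L[i, j] <- (sigma[i, j] - acc) / L[j, j]
      }
    }
  }
  L
}

# Mean of a chi distribution with k degrees of freedom for unit-variance
# components: E[chi_k] = sqrt(2) * Gamma((k+1)/2) / Gamma(k/2).
chi_mean <- function(k) {
  sqrt(2) * exp(lgamma((k + 1) / 2) - lgamma(k / 2))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Numeric central-difference Jacobian of fn (vector-valued) at par.
num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (i in seq_along(par)) {
    h <- eps * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    J[, i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

# Linearized parameter covariance sigma_r^2 * (J^T J)^-1 from residuals and a
# Jacobian of the model (not the residuals' sign convention: either works).
vp_covariance <- function(J, residuals, n_par = ncol(J)) {
  n <- length(residuals)
  dof <- max(n - n_par, 1L)
  sigma_r2 <- sum(residuals^2) / dof
  JtJ <- crossprod(J)
  Vp <- tryCatch(sigma_r2 * solve(JtJ), error = function(e) {
    sigma_r2 * MASS::ginv(JtJ)
  })
  Vp <- (Vp + t(Vp)) / 2
  list(Vp = Vp, sigma_r2 = sigma_r2)
}
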