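# Damped (Levenberg-Marquardt-style) least squares with parameter scaling.
# Shared by geometry refinement, profile fitting and peak fitting. Angles
# are handled in the caller's units; scaling keeps the normal matrix
# well-conditioned. Not exported.

num_jacobian <- function(fn, par, scale, r0 = NULL) {
  n <- length(par)
  h <- 1e-6 * pmax(abs(par), scale)
  J <- NULL
  for (j in seq_len(n)) {
    pp <- par; pp[j] <- pp[j] + h[j]
    pm <- par; pm[j] <- pm[j] - h[j]
    col <- (fn(pp) - fn(pm)) / (2 * h[j])
    if (is.null(J)) J <- matrix(0, length(col), n)
    J[, j] <- col
  }
  J
}

# fn: par -> residual vector (already weighted). jac: optional analytic
# jacobian. Returns estimates, covariance scaled by reduced chi-square,
# convergence info and the condition number of the scaled normal matrix.
lm_least_squares <- function(par, fn, jac = NULL, scale = NULL,
                             rel_tol = 1e-10, max_iter = 200L,
                             cond_max = 1e12) {
  par <- as.numeric(par)
  n <- length(par)
  if (is.null(scale)) scale <- pmax(abs(par), 1e-8)
  scale <- pmax(abs(scale), 1e-12)
  r <- fn(par)
  if (any(!is.finite(r))) stop("non-finite residuals at starting point")
  cost <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  J <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- if (is.null(jac)) num_jacobian(fn, par, scale) else jac(par)
    Js <- sweep(J, 2, scale, `*`)          # d r / d (par/scale)
    g <- crossprod(Js, r)
    A <- crossprod(Js)
    if (sqrt(sum(g^2)) <= rel_tol * max(1, sqrt(cost))) { converged <- TRUE; break }
    improved <- FALSE
    for (k in 1:30) {
      Ad <- A + lambda * diag(pmax(diag(A), 1e-30), n)
      step <- tryCatch(solve(Ad, -g), error = function(e) NULL)
      if (!is.null(step)) {
        par_new <- par + as.vector(step) * scale
        r_new <- tryCatch(fn(par_new), error = function(e) NULL)
        if (!is.null(r_new) && all(is.finite(r_new))) {
          cost_new <- sum(r_new^2)
          if (cost_new <= cost) {
            rel_impr <- (cost - cost_new) / max(cost, 1e-300)
            step_rel <- max(abs(step))
            par <- par_new; r <- r_new; cost <- cost_new
            lambda <- max(lambda / 3, 1e-12)
            improved <- TRUE
            if (rel_impr < rel_tol && step_rel < sqrt(rel_tol)) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!improved || converged) { if (improved) converged <- TRUE else converged <- (sqrt(sum(g^2)) <= 1e-6 * max(1, sqrt(cost))); break }
  }
  J <- if (is.null(jac)) num_jacobian(fn, par, scale) else jac(par)
  Js <- sweep(J, 2, scale, `*`)
  A <- crossprod(Js)
  ev <- eigen(A, symmetric = TRUE, only.values = FALSE)
  emax <- max(ev$values)
  # eigenvalues of the Gram matrix can round to tiny negatives; clamp at
  # machine precision relative to the largest before judging conditioning
  evals <- pmax(ev$values, emax * .Machine$double.eps)
  cond <- if (emax <= 0) Inf else emax / min(evals)
  dof <- max(length(r) - n, 1L)
  chi2_red <- cost / dof
  cov <- if (is.finite(cond) && cond < cond_max) {
    V <- ev$vectors
    Ainv <- V %*% diag(1 / evals, n) %*% t(V)
    chi2_red * sweep(sweep(Ainv, 1, scale, `*`), 2, scale, `*`)
  } else NULL
  # parameters loading on the near-null space, for singularity diagnostics
  null_load <- abs(ev$vectors[, n])
  list(par = par, residuals = r, cost = cost, converged = converged,
       iterations = iter, condition = cond, cov = cov,
       chi2_red = chi2_red, null_space = null_load, n_obs = length(r))
}
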