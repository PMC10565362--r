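# Parameter identification: minimize the virtual-power error over
# (mu, alpha, K).
#
# Optimization works in transformed coordinates z = (log mu, alpha,
# log K) to handle positivity and the three-orders-of-magnitude scale
# disparity.  Two routes mirror the reference workflow: a hand-written
# Levenberg-Marquardt on the 3-vector of per-field errors, and
# Nelder-Mead (stats::optim) on the scalar total error with a logistic
# transform enforcing the bounds.  Multi-start uses a Latin-hypercube
# over the bounds (log-uniform in mu and K, uniform in alpha), and the
# same sampler drives the random landscape sweep.

#' @noRd
theta_to_z <- function(params) c(log(params$mu), params$alpha, log(params$K))

#' @noRd
z_to_theta <- function(z, template) {
  p <- template
  p$mu <- exp(z[1]); p$alpha <- z[2]; p$K <- exp(z[3])
  p
}

#' @noRd
bounds_z <- function(bounds) {
  list(lower = c(log(bounds$mu[1]), bounds$alpha[1], log(bounds$K[1])),
       upper = c(log(bounds$mu[2]), bounds$alpha[2], log(bounds$K[2])))
}

#' @noRd
new_identification_result <- function(params, ev, trace, start, converged,
                                      method) {
  structure(list(params = params, errors = ev$errors, total = ev$total,
                 trace = trace, start = start, converged = converged,
                 method = method),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("identification_result (%s): %s\n", x$method,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  mu = %.6g Pa, alpha = %.4g, K = %.6g Pa\n",
              x$params$mu, x$params$alpha, x$params$K))
  cat(sprintf("  per-field errors: %s;  total = %.3g\n",
              paste(sprintf("%.3g", x$errors), collapse = ", "), x$total))
  invisible(x)
}

#' Least-squares identification (Levenberg-Marquardt)
#'
#' Minimizes the 3-vector of per-field equilibrium gaps in the
#' least-squares sense, with a finite-difference Jacobian in the
#' transformed coordinates and steps clamped to the bounds.
#'
#' @param start an [ogden_params()] start point (within bounds).
#' @param bundle a [data_bundle()].
#' @param bounds bounds list (elements `mu`, `alpha`, `K`, each a
#'   2-vector); defaults to the bounds stored on `start`.
#' @param ftol absolute tolerance on the total error change (default
#'   1e-12: landscape minima sit near 1e-8).
#' @param ptol relative parameter-step tolerance (default 1e-6).
#' @param max_iter iteration cap.
#' @return an `identification_result`; non-convergence is a flag, not an
#'   error.
#' @export
identify_leastsq <- function(start, bundle, bounds = start$bounds,
                             ftol = 1e-12, ptol = 1e-6, max_iter = 200L) {
  bz <- bounds_z(bounds)
  z <- pmin(pmax(theta_to_z(start), bz$lower), bz$upper)
  resid <- function(z) evaluate_params(z_to_theta(z, start), bundle)$errors
  r <- resid(z)
  cost <- sum(r^2)
  lambda <- 1e-3
  hstep <- c(1e-6, 1e-4 * max(1, abs(z[2])), 1e-6)  # FD steps per coordinate
  trace <- matrix(c(z, sqrt(cost)), nrow = 1L,
                  dimnames = list(NULL, c("log_mu", "alpha", "log_K", "total")))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Jac <- matrix(0, 3L, 3L)
    for (k in 1:3) {
      zp <- z; zp[k] <- min(z[k] + hstep[k], bz$upper[k])
      zm <- z; zm[k] <- max(z[k] - hstep[k], bz$lower[k])
      Jac[, k] <- (resid(zp) - resid(zm)) / (zp[k] - zm[k])
    }
    g <- crossprod(Jac, r)
    A <- crossprod(Jac)
    improved <- FALSE
    for (try in 1:12) {
      M <- A + lambda * diag(diag(A) + 1e-14, 3L)
      dz <- tryCatch(-solve(M, g), error = function(e) NULL)
      if (is.null(dz)) { lambda <- lambda * 10; next }
      znew <- pmin(pmax(z + as.numeric(dz), bz$lower), bz$upper)
      rnew <- resid(znew)
      cnew <- sum(rnew^2)
      if (cnew < cost) {
        step_rel <- max(abs(znew - z) / pmax(abs(z), 1))
        dcost <- cost - cnew
        z <- znew; r <- rnew; cost <- cnew
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        trace <- rbind(trace, c(z, sqrt(cost)))
        if (sqrt(cost) < ftol || dcost < ftol^2 || step_rel < ptol)
          converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }  # stationary to FD resolution
    if (converged) break
  }
  params <- z_to_theta(z, start)
  new_identification_result(params, evaluate_params(params, bundle),
                            trace, start, converged, "leastsq")
}

#' Simplex identification (Nelder-Mead)
#'
#' Minimizes the scalar total error in (log mu, alpha, log K)
#' coordinates.  Bounds are enforced by evaluating at the projection onto
#' the box plus a quadratic penalty on the excursion (a logistic
#' transform saturates near the bounds and stalls the simplex there).
#'
#' @inheritParams identify_leastsq
#' @param reltol relative convergence tolerance passed to
#'   [stats::optim()] (default 1e-12).
#' @param max_iter iteration cap per restart.
#' @param restarts number of simplex restarts from the incumbent optimum
#'   (Nelder-Mead can converge prematurely when the simplex collapses;
#'   re-inflating it at the incumbent is the standard remedy).
#' @return an `identification_result`.
#' @export
identify_simplex <- function(start, bundle, bounds = start$bounds,
                             reltol = 1e-12, max_iter = 4000L,
                             restarts = 3L) {
  bz <- bounds_z(bounds)
  clampz <- function(z) pmin(pmax(z, bz$lower), bz$upper)
  y0 <- clampz(theta_to_z(start))
  fn <- function(y) {
    z <- clampz(y)
    evaluate_params(z_to_theta(z, start), bundle)$total + sum((y - z)^2)
  }
  opt <- optim(y0, fn, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = max_iter))
  stationary <- opt$convergence == 0L
  for (r in seq_len(restarts)) {
    again <- optim(opt$par, fn, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = max_iter))
    stationary <- again$convergence == 0L ||
      opt$value - again$value <= 1e-12        # below the function tolerance
    opt <- again
    if (stationary) break
  }
  z <- clampz(opt$par)
  params <- z_to_theta(z, start)
  trace <- matrix(c(z, opt$value), nrow = 1L,
                  dimnames = list(NULL, c("log_mu", "alpha", "log_K", "total")))
  new_identification_result(params, evaluate_params(params, bundle),
                            trace, start, stationary, "simplex")
}

#' Latin-hypercube parameter sample in transformed space
#' @noRd
lhs_sample <- function(n, bounds) {
  bz <- bounds_z(bounds)
  Z <- vapply(1:3, function(k) {
    u <- (sample.int(n) - runif(n)) / n
    bz$lower[k] + u * (bz$upper[k] - bz$lower[k])
  }, numeric(n))
  matrix(Z, nrow = n)
}

#' Multi-start identification
#'
#' @param bundle a [data_bundle()].
#' @param n_starts number of start points (>= 1).
#' @param bounds bounds list; default the package defaults of
#'   [ogden_params()].
#' @param seed RNG seed (start points are a Latin hypercube; results are
#'   deterministic given the seed).
#' @param method `"leastsq"`, `"simplex"` or `"both"` (runs each start
#'   through both optimizers).
#' @param ... passed to the single-start optimizers.
#' @return list of `identification_result`s with attribute `starts`.
#' @export
multistart <- function(bundle, n_starts = 8L, bounds = NULL, seed = 1L,
                       method = c("both", "leastsq", "simplex"), ...) {
  method <- match.arg(method)
  if (n_starts < 1L) config_error("`n_starts` must be >= 1")
  template <- ogden_params(1000, -10, 1e5)
  if (is.null(bounds)) bounds <- template$bounds
  Z <- with_seed(seed, lhs_sample(n_starts, bounds))
  runs <- list()
  for (s in seq_len(n_starts)) {
    start <- z_to_theta(Z[s, ], template)
    start$bounds <- bounds
    if (method %in% c("both", "leastsq"))
      runs[[length(runs) + 1L]] <- identify_leastsq(start, bundle, bounds, ...)
    if (method %in% c("both", "simplex"))
      runs[[length(runs) + 1L]] <- identify_simplex(start, bundle, bounds, ...)
  }
  attr(runs, "starts") <- Z
  runs
}

#' Random landscape sweep
#'
#' Evaluates the total error at `n` random parameter sets over the
#' feasible space (log-uniform in mu and K, uniform in alpha) to map the
#' identification uncertainty; the reference workflow uses n = 2800.
#'
#' @param bundle a [data_bundle()].
#' @param n number of samples.
#' @param bounds bounds list (default: [ogden_params()] defaults).
#' @param seed RNG seed; the sweep is reproducible given the seed.
#' @return data.frame of class `landscape_samples`: mu, alpha, K,
#'   per-field errors, err_total.
#' @export
random_sweep <- function(bundle, n, bounds = NULL, seed = 1L) {
  if (n < 1L) config_error("`n` must be >= 1")
  template <- ogden_params(1000, -10, 1e5)
  if (is.null(bounds)) bounds <- template$bounds
  bz <- bounds_z(bounds)
  Z <- with_seed(seed, vapply(1:3, function(k)
    bz$lower[k] + runif(n) * (bz$upper[k] - bz$lower[k]), numeric(n)))
  Z <- matrix(Z, nrow = n)
  out <- data.frame(mu = exp(Z[, 1]), alpha = Z[, 2], K = exp(Z[, 3]),
                    err1 = NA_real_, err2 = NA_real_, err3 = NA_real_,
                    err_total = NA_real_)
  for (s in seq_len(n)) {
    ev <- evaluate_params(z_to_theta(Z[s, ], template), bundle)
    out[s, c("err1", "err2", "err3")] <- ev$errors
    out$err_total[s] <- ev$total
  }
  class(out) <- c("landscape_samples", "data.frame")
  out
}

#' Error thresholds used in the reference landscape figures
#'
#' `optimizer`: 1e-8 / 1e-6 / 1e-4 / 1e-2 (converged-run classification);
#' `sweep`: 1% / 2% / 5% (random-sweep classification).
#' @param set `"optimizer"` or `"sweep"`.
#' @return increasing numeric thresholds.
#' @export
error_thresholds <- function(set = c("optimizer", "sweep")) {
  switch(match.arg(set),
         optimizer = c(1e-8, 1e-6, 1e-4, 1e-2),
         sweep = c(0.01, 0.02, 0.05))
}

#' Classify landscape samples into error bands
#'
#' Half-open bins `[0, t1), [t1, t2), ..., [t_last, Inf)`.
#'
#' @param samples a [random_sweep()] result (or any data.frame with an
#'   `err_total` column).
#' @param thresholds strictly increasing positive thresholds.
#' @return `samples` with an added factor column `error_class`.
#' @export
classify_errors <- function(samples, thresholds = error_thresholds("sweep")) {
  if (length(thresholds) < 1L || any(diff(thresholds) <= 0) || any(thresholds <= 0))
    config_error("`thresholds` must be strictly increasing and positive")
  breaks <- c(0, thresholds, Inf)
  labels <- c(sprintf("<%g", thresholds[1]),
              if (length(thresholds) > 1L)
                sprintf("%g-%g", thresholds[-length(thresholds)], thresholds[-1]),
              sprintf(">=%g", thresholds[length(thresholds)]))
  samples$error_class <- cut(samples$err_total, breaks = breaks,
                             labels = labels, right = FALSE)
  samples
}
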