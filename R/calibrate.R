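#' Expand the free calibration vector into full model parameters
#'
#' The exchange pairs are reduced through the equilibrium constants measured
#' on the pre-bleach frame: `k2 = k1/K` and, in active mode,
#' `k_nc = k_cn/K_M`, so only `alpha, beta, gamma, p, k1` (permeable) or
#' `alpha, beta, gamma, k1, k_cn` (active) are free.
#'
#' @param free named or positional numeric vector: permeable mode
#'   `(alpha, beta, gamma, p, k1)`, active mode
#'   `(alpha, beta, gamma, k1, k_cn)`.
#' @param K aggregate/cytoplasm equilibrium constant (> 0).
#' @param K_M nucleus/cytoplasm equilibrium constant (> 0, active mode).
#' @param membrane_mode `"permeable"` or `"active"`.
#' @return a [flip_parameters()].
#' @export
reduce_parameters <- function(free, K = 1, K_M = 1,
                              membrane_mode = c("permeable", "active")) {
  membrane_mode <- match.arg(membrane_mode)
  if (K <= 0 || K_M <= 0) stop("equilibrium constants must be > 0")
  if (membrane_mode == "permeable") {
    flip_parameters(alpha = free[[1]], beta = free[[2]], gamma = free[[3]],
                    membrane_mode = "permeable", p = free[[4]],
                    k1 = free[[5]], k2 = free[[5]] / K)
  } else {
    flip_parameters(alpha = free[[1]], beta = free[[2]], gamma = free[[3]],
                    membrane_mode = "active",
                    k1 = free[[4]], k2 = free[[4]] / K,
                    k_cn = free[[5]], k_nc = free[[5]] / K_M)
  }
}

#' Nelder-Mead downhill simplex minimizer
#'
#' Standard simplex coefficients (reflection 1, expansion 2, contraction 0.5,
#' shrink 0.5) with the initial simplex built by perturbing each coordinate of
#' the start point by 5% (0.00025 absolute when the coordinate is zero).
#' Termination: the maximum coordinate spread of the simplex around the best
#' vertex and the spread of the function values both (default) or either fall
#' below `tol`. Points with negative coordinates are assigned a large penalty
#' value so the simplex retreats into the feasible region.
#'
#' @param fn objective function of a numeric vector.
#' @param x0 start point (finite objective value required).
#' @param tol stop tolerance on both spreads (default 1e-4).
#' @param maxit maximum number of iterations.
#' @param stop_rule `"both"` (default) or `"either"` spread below `tol`.
#' @param nonneg enforce nonnegative parameters via a penalty value.
#' @param penalty_value objective value assigned to infeasible points.
#' @param trace_fn optional callback `function(iter, fbest, xbest)`.
#' @return list with `par`, `value`, `iterations`, `evaluations`,
#'   `converged`, and `trace` (best misfit per iteration).
#' @export
nelder_mead <- function(fn, x0, tol = 1e-4, maxit = 500L,
                        stop_rule = c("both", "either"), nonneg = TRUE,
                        penalty_value = 1e12, trace_fn = NULL) {
  stop_rule <- match.arg(stop_rule)
  n <- length(x0)
  evals <- 0L
  f <- function(x) {
    if (nonneg && any(x < 0)) return(penalty_value)
    evals <<- evals + 1L
    v <- fn(x)
    if (!is.finite(v)) penalty_value else v
  }
  # initial simplex: scipy-style per-coordinate perturbation
  simplex <- matrix(rep(x0, n + 1L), n + 1L, n, byrow = TRUE)
  for (i in seq_len(n)) {
    if (x0[i] != 0) simplex[i + 1L, i] <- 1.05 * x0[i]
    else simplex[i + 1L, i] <- 0.00025
  }
  fv <- apply(simplex, 1, f)
  if (!is.finite(fv[1]) || fv[1] >= penalty_value)
    stop("objective not finite at the initial guess")
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]
    fv <- fv[ord]
    xspread <- max(abs(sweep(simplex[-1L, , drop = FALSE], 2, simplex[1L, ])))
    fspread <- max(abs(fv[-1L] - fv[1L]))
    small <- c(xspread <= tol, fspread <= tol)
    if (if (stop_rule == "both") all(small) else any(small)) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    xbar <- colMeans(simplex[-(n + 1L), , drop = FALSE])
    xr <- xbar + (xbar - simplex[n + 1L, ])
    fr <- f(xr)
    if (fr < fv[1L]) {
      xe <- xbar + 2 * (xbar - simplex[n + 1L, ])
      fe <- f(xe)
      if (fe < fr) { simplex[n + 1L, ] <- xe; fv[n + 1L] <- fe }
      else { simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr
    } else {
      if (fr < fv[n + 1L]) {           # outside contraction
        xc <- xbar + 0.5 * (xbar - simplex[n + 1L, ])
        fc <- f(xc)
        if (fc <= fr) { simplex[n + 1L, ] <- xc; fv[n + 1L] <- fc }
        else {
          for (i in 2:(n + 1L)) {      # shrink
            simplex[i, ] <- simplex[1L, ] + 0.5 * (simplex[i, ] - simplex[1L, ])
            fv[i] <- f(simplex[i, ])
          }
        }
      } else {                          # inside contraction
        xc <- xbar - 0.5 * (xbar - simplex[n + 1L, ])
        fc <- f(xc)
        if (fc < fv[n + 1L]) { simplex[n + 1L, ] <- xc; fv[n + 1L] <- fc }
        else {
          for (i in 2:(n + 1L)) {
            simplex[i, ] <- simplex[1L, ] + 0.5 * (simplex[i, ] - simplex[1L, ])
            fv[i] <- f(simplex[i, ])
          }
        }
      }
    }
    trace <- c(trace, min(fv))
    if (!is.null(trace_fn)) trace_fn(iter, min(fv), simplex[which.min(fv), ])
  }
  ord <- order(fv)
  list(par = simplex[ord[1L], ], value = fv[ord[1L]], iterations = iter,
       evaluations = evals, converged = converged, trace = trace)
}

#' Build the calibration objective for a FLIP data set
#'
#' Returns `function(free) -> E`: each evaluation expands the free vector via
#' [reduce_parameters()], re-runs the full forward simulation on cached
#' operators (only the parameter-dependent sparse combinations are rebuilt)
#' and evaluates the misfit against the goal series.
#'
#' @param mesh a [flip_mesh()].
#' @param c0 pre-bleach DG field (initial state and hindrance-rate source).
#' @param goal a [frame_series()] of goal fields.
#' @param protocol a [bleach_protocol()].
#' @param membrane_mode `"permeable"` or `"active"`.
#' @param K,K_M equilibrium constants; default: measured from `c0`.
#' @param dt,sigma0 passed to [forward_simulate()].
#' @return objective function with attributes `ops`, `K`, `K_M`.
#' @export
flip_objective <- function(mesh, c0, goal, protocol,
                           membrane_mode = c("permeable", "active"),
                           K = NULL, K_M = NULL, dt = NULL, sigma0 = 10) {
  membrane_mode <- match.arg(membrane_mode)
  ops <- flip_operators(mesh, c0, membrane_mode = membrane_mode,
                        K = K, K_M = K_M, sigma0 = sigma0)
  K <- if (is.null(ops$K)) 1 else ops$K
  K_M <- if (is.null(ops$K_M)) 1 else ops$K_M
  obj <- function(free) {
    params <- reduce_parameters(free, K = K, K_M = K_M,
                                membrane_mode = membrane_mode)
    sim <- forward_simulate(mesh, params, protocol, c0, ops = ops, dt = dt)
    misfit(sim, goal, ops$Mass)
  }
  attr(obj, "ops") <- ops
  attr(obj, "K") <- K
  attr(obj, "K_M") <- K_M
  obj
}

#' Calibrate FLIP model parameters by misfit minimization
#'
#' Runs the Nelder-Mead simplex on a calibration objective from the given
#' initial guesses and reports the recovered parameter set together with the
#' misfit trace.
#'
#' @param objective function from [flip_objective()] (or any `free -> E`).
#' @param init initial free-parameter guesses (positive).
#' @param membrane_mode `"permeable"` or `"active"`.
#' @param K,K_M equilibrium constants used to derive the dependent rates in
#'   the report (defaults: taken from the objective's attributes).
#' @param tol Nelder-Mead stop tolerance (default 1e-4).
#' @param maxit iteration cap.
#' @param stop_rule `"both"` or `"either"` (see [nelder_mead()]).
#' @param log_scale run the simplex on log-parameters (default). The free
#'   parameters are positive rate-type constants spanning four orders of
#'   magnitude; in the original scale the initial simplex is so anisotropic
#'   that it tends to collapse with the smallest rates stuck near zero, while
#'   in log space steps are relative and positivity is automatic. Set to
#'   `FALSE` for the plain-parameter simplex with the nonnegativity penalty.
#' @param restarts maximum number of simplex restarts. A converged simplex
#'   is re-initialized around its best vertex and minimization continues;
#'   restarting stops as soon as a restart improves the misfit by less than
#'   `tol`. Restarting at the claimed minimum is the standard guard against
#'   premature simplex collapse.
#' @param verbose print one line per iteration to stderr.
#' @return object of class `flip_calibration`: recovered [flip_parameters()],
#'   `free`, `E_initial`, `E_final`, `iterations`, `evaluations`,
#'   `converged`, `trace`.
#' @export
calibrate_flip <- function(objective, init,
                           membrane_mode = c("permeable", "active"),
                           K = NULL, K_M = NULL, tol = 1e-4, maxit = 600L,
                           stop_rule = "both", log_scale = TRUE,
                           restarts = 3L, verbose = FALSE) {
  membrane_mode <- match.arg(membrane_mode)
  if (any(init <= 0)) stop("initial guesses must be positive")
  if (is.null(K)) K <- attr(objective, "K") %||% 1
  if (is.null(K_M)) K_M <- attr(objective, "K_M") %||% 1
  E0 <- objective(init)
  tfn <- if (verbose) {
    function(it, fb, xb) message(sprintf("iter %4d  E = %.6g  [%s]", it, fb,
                                         paste(signif(if (log_scale) exp(xb) else xb, 6),
                                               collapse = ", ")))
  } else NULL
  run_once <- function(start) {
    if (log_scale) {
      r <- nelder_mead(function(lx) objective(exp(lx)), log(start), tol = tol,
                       maxit = maxit, stop_rule = stop_rule, nonneg = FALSE,
                       trace_fn = tfn)
      r$par <- exp(r$par)
      r
    } else {
      nelder_mead(objective, start, tol = tol, maxit = maxit,
                  stop_rule = stop_rule, trace_fn = tfn)
    }
  }
  res <- run_once(init)
  for (k in seq_len(restarts)) {
    if (!res$converged) break
    again <- run_once(res$par)
    improved <- res$value - again$value
    if (again$value < res$value) {
      again$iterations <- res$iterations + again$iterations
      again$evaluations <- res$evaluations + again$evaluations
      again$trace <- c(res$trace, again$trace)
      res <- again
    }
    if (improved < tol) break
  }
  if (!res$converged)
    warning("Nelder-Mead stopped at the iteration cap (", res$iterations,
            ") before reaching the tolerance")
  # a full parameter set requires the 5-dimensional free vector; reduced
  # calibrations (some parameters held fixed) report only the free values
  params <- if (length(res$par) == 5L)
    reduce_parameters(res$par, K = K, K_M = K_M, membrane_mode = membrane_mode)
  else NULL
  structure(list(parameters = params, free = res$par,
                 E_initial = E0, E_final = res$value,
                 iterations = res$iterations, evaluations = res$evaluations,
                 converged = res$converged, trace = res$trace,
                 K = K, K_M = K_M),
            class = "flip_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.flip_calibration <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("flip_calibration: E %.4g -> %.4g in %d iterations (%d evaluations)\n",
              x$E_initial, x$E_final, x$iterations, x$evaluations))
  if (is.null(p)) {
    cat("  free parameters:", paste(signif(x$free, 5), collapse = ", "), "\n")
    return(invisible(x))
  }
  if (p$membrane_mode == "permeable") {
    cat(sprintf("  alpha = %.4g um^2/s, beta = %.4g 1/s, gamma = %.4g, p = %.4g um/s\n",
                p$alpha, p$beta, p$gamma, p$p))
  } else {
    cat(sprintf("  alpha = %.4g um^2/s, beta = %.4g 1/s, gamma = %.4g, k_cn = %.4g, k_nc = %.4g 1/s\n",
                p$alpha, p$beta, p$gamma, p$k_cn, p$k_nc))
  }
  cat(sprintf("  k1 = %.4g 1/s, k2 = k1/%.4g = %.4g 1/s\n", p$k1, x$K, p$k2))
  invisible(x)
}
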