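# Finke-Watzky two-step aggregation kinetics.
#
# The model: slow continuous nucleation A -> B (k1) and fast autocatalytic
# growth A + B -> 2B (k2). The monomer obeys dA/dt = -k1*A - k2*A*(A0 - A),
# whose solution is a falling logistic
#
#   [A](t) = K / (1 + exp(r*(t - tmax)))
#
# with K = A0 + k1/k2 (amplitude), r = k1 + k2*A0 (apparent rate), and
# tmax = log(k2*A0/k1)/r the inflection time of the product curve
# [B](t) = A0 - [A](t). The two zeros of the jerk (third time derivative of
# [B]) sit symmetrically about tmax at offset log(2 + sqrt(3))/r and define
# the induction time t1 and the plateau-onset time t2.

# offset multiplier for the jerk zeros of a logistic: log(2 + sqrt(3))
.fw_jerk_const <- log(2 + sqrt(3))

#' Finke-Watzky kinetic parameters
#'
#' Bundles the kinetic triple that defines a Finke-Watzky system: the
#' nucleation rate constant `k1` (per hour), the autocatalytic growth rate
#' constant `k2` (per mM per hour) and the initial monomer concentration `A0`
#' (mM). All three must be positive.
#'
#' The regime is degenerate (no sigmoidal lag phase) when `k1 >= k2*A0`:
#' the analytic inflection time is then non-positive and jerk-based phase
#' times are not meaningful. Such parameter sets are accepted but flagged.
#'
#' @param k1 Nucleation rate constant, h^-1.
#' @param k2 Autocatalytic growth rate constant, mM^-1 h^-1.
#' @param A0 Initial monomer concentration, mM.
#' @return An object of class `fw_params` with derived fields `r = k1 + k2*A0`
#'   (apparent first-order rate, h^-1) and `K = A0 + k1/k2` (logistic
#'   amplitude, mM).
#' @export
#' @examples
#' fw_params(k1 = 0.03, k2 = 0.13, A0 = 2)
fw_params <- function(k1, k2, A0) {
  k1 <- as.numeric(k1); k2 <- as.numeric(k2); A0 <- as.numeric(A0)
  if (!is.finite(k1) || k1 <= 0) stop("k1 must be positive", call. = FALSE)
  if (!is.finite(k2) || k2 <= 0) stop("k2 must be positive", call. = FALSE)
  if (!is.finite(A0) || A0 <= 0) stop("A0 must be positive", call. = FALSE)
  structure(
    list(k1 = k1, k2 = k2, A0 = A0, r = k1 + k2 * A0, K = A0 + k1 / k2,
         degenerate = k1 >= k2 * A0),
    class = "fw_params")
}

#' @export
print.fw_params <- function(x, ...) {
  cat(sprintf("F-W params: k1 = %g h^-1, k2 = %g mM^-1 h^-1, A0 = %g mM\n",
              x$k1, x$k2, x$A0))
  cat(sprintf("  apparent rate r = %g h^-1, amplitude K = %g mM%s\n",
              x$r, x$K, if (x$degenerate) "  [degenerate: k1 >= k2*A0]" else ""))
  invisible(x)
}

.as_fw <- function(params) {
  if (inherits(params, "fw_params")) params
  else do.call(fw_params, as.list(params)[c("k1", "k2", "A0")])
}

#' Closed-form Finke-Watzky monomer concentration
#'
#' Evaluates the remaining soluble monomer \[A\](t) of the two-step model at
#' the requested times. \[A\](0) = A0, \[A\] is strictly decreasing, and
#' \[A\](t) -> 0 as t -> Inf.
#'
#' @param params An [fw_params] object (or a list with k1, k2, A0).
#' @param t Times in hours, >= 0.
#' @return Monomer concentration in mM, same length as `t`.
#' @export
#' @examples
#' p <- fw_params(0.03, 0.13, 2)
#' fw_monomer(p, c(0, 6, 12, 24))
fw_monomer <- function(params, t) {
  p <- .as_fw(params)
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tmax <- log(p$k2 * p$A0 / p$k1) / p$r
  p$K / (1 + exp(p$r * (t - tmax)))
}

#' Finke-Watzky aggregate (product) concentration
#'
#' \[B\](t) = A0 - \[A\](t): mass conservation of the two-step scheme.
#'
#' @inheritParams fw_monomer
#' @return Aggregate concentration in mM.
#' @export
fw_aggregate <- function(params, t) {
  p <- .as_fw(params)
  p$A0 - fw_monomer(p, t)
}

#' Inflection time of the Finke-Watzky sigmoid
#'
#' Returns `tmax = log(k2*A0/k1) / (k1 + k2*A0)`, the time of the maximum
#' growth rate of the product (the inflection point of the curve). In the
#' degenerate regime `k1 >= k2*A0` the value is <= 0 (no lag phase) and a
#' `degenerate` attribute is set to `TRUE` with a warning.
#'
#' @param params An [fw_params].
#' @return Inflection time in hours (attribute `degenerate` flags tmax <= 0).
#' @export
#' @examples
#' fw_tmax(fw_params(0.03, 0.13, 2)) # ~7.45 h
fw_tmax <- function(params) {
  p <- .as_fw(params)
  tm <- log(p$k2 * p$A0 / p$k1) / p$r
  if (tm <= 0) {
    warning("degenerate regime (k1 >= k2*A0): tmax <= 0, no lag phase",
            call. = FALSE)
    attr(tm, "degenerate") <- TRUE
  } else {
    attr(tm, "degenerate") <- FALSE
  }
  tm
}

#' Phase times from the zeros of the jerk (analytic)
#'
#' The induction time `t1` and plateau-onset time `t2` are the two times at
#' which the third time derivative (jerk) of the product concentration
#' vanishes: `t1` is the time of maximum acceleration (lag -> exponential
#' growth transition), `t2` the time of greatest deceleration (growth ->
#' plateau transition). For the logistic solution these sit symmetrically
#' about the inflection at `tmax -/+ log(2 + sqrt(3))/r`, so
#' `tmax == (t1 + t2)/2` exactly.
#'
#' @param params An [fw_params]; the regime must be non-degenerate
#'   (`k1 < k2*A0`) for the phase times to be meaningful.
#' @return An object of class `fw_phase_times`: list with `t1`, `tmax`, `t2`
#'   (hours), the half-width `offset = log(2+sqrt(3))/r`, and a `warning`
#'   field that is non-NA when `t1 < 0` (induction period not resolvable).
#' @export
#' @examples
#' fw_jerk_times(fw_params(0.03, 0.13, 2))
fw_jerk_times <- function(params) {
  p <- .as_fw(params)
  if (p$degenerate) {
    stop("degenerate regime (k1 >= k2*A0): jerk-based phase times undefined",
         call. = FALSE)
  }
  tmax <- log(p$k2 * p$A0 / p$k1) / p$r
  off <- .fw_jerk_const / p$r
  t1 <- tmax - off
  t2 <- tmax + off
  warn <- NA_character_
  if (t1 < 0) {
    warn <- "t1 < 0: induction period not resolvable within t >= 0"
    warning(warn, call. = FALSE)
  }
  structure(list(t1 = t1, tmax = tmax, t2 = t2, offset = off, warning = warn),
            class = "fw_phase_times")
}

#' @export
print.fw_phase_times <- function(x, ...) {
  cat(sprintf("phase times (h): t1 = %.4g, tmax = %.4g, t2 = %.4g\n",
              x$t1, x$tmax, x$t2))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Phase times by numeric root-finding on the jerk (independent oracle)
#'
#' Locates the two sign changes of the numerically evaluated third time
#' derivative of the product concentration \[B\](t), by bracketing on a grid
#' spanning `[0, tmax + 10/r]` followed by bisection (`uniroot`). Serves as an
#' independent cross-check of [fw_jerk_times]; the derivative is evaluated by
#' central finite differences of the closed-form curve, never via the analytic
#' jerk expression.
#'
#' @param params An [fw_params].
#' @param n_grid Number of grid points used for bracketing.
#' @param tol Bisection tolerance in hours.
#' @return An `fw_phase_times` (tmax taken as the numerically located extremum
#'   of the first derivative).
#' @export
fw_jerk_times_numeric <- function(params, n_grid = 2048L, tol = 1e-10) {
  p <- .as_fw(params)
  tmax_a <- log(p$k2 * p$A0 / p$k1) / p$r
  hi <- max(tmax_a, 0) + 10 / p$r
  # step for the finite-difference stencils: large enough that roundoff in the
  # O(h^4) third-derivative stencil stays far below the truncation error
  h <- hi / 400
  b <- function(s) p$A0 - fw_monomer(p, pmax(s, 0))
  # 3rd derivative, O(h^4) central stencil (offsets -3h..3h)
  jerk <- function(t) {
    (b(t - 3 * h) / 8 - b(t - 2 * h) + 13 / 8 * b(t - h) -
       13 / 8 * b(t + h) + b(t + 2 * h) - b(t + 3 * h) / 8) / h^3
  }
  lo <- 3 * h
  grid <- seq(lo, hi, length.out = n_grid)
  jv <- vapply(grid, jerk, numeric(1))
  sgn <- sign(jv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips) < 2L) {
    stop(sprintf(paste0("could not bracket two jerk zeros for k1=%g, k2=%g, ",
                        "A0=%g (degenerate or unresolved regime)"),
                 p$k1, p$k2, p$A0), call. = FALSE)
  }
  roots <- vapply(flips[c(1L, length(flips))], function(i) {
    stats::uniroot(jerk, c(grid[i], grid[i + 1]), tol = tol)$root
  }, numeric(1))
  # inflection: zero of the 2nd derivative (O(h^4) stencil) between the zeros
  accel <- function(t) {
    (-b(t - 2 * h) / 12 + 4 / 3 * b(t - h) - 5 / 2 * b(t) +
       4 / 3 * b(t + h) - b(t + 2 * h) / 12) / h^2
  }
  tmax_n <- stats::uniroot(accel, c(roots[1], roots[2]), tol = tol)$root
  structure(list(t1 = roots[1], tmax = tmax_n, t2 = roots[2],
                 offset = (roots[2] - roots[1]) / 2, warning = NA_character_),
            class = "fw_phase_times")
}

#' Maximum growth rate of the product
#'
#' The rate d\[B\]/dt attains its maximum at the inflection time; for the
#' logistic solution it equals `r*K/4` with `r = k1 + k2*A0` and
#' `K = A0 + k1/k2`.
#'
#' @param params An [fw_params].
#' @return Maximum growth rate in mM/h.
#' @export
#' @examples
#' fw_max_rate(fw_params(0.03, 0.13, 2)) # ~0.162 mM/h
fw_max_rate <- function(params) {
  p <- .as_fw(params)
  p$r * p$K / 4
}

#' Inflection time from the two jerk-zero phase times
#'
#' For the logistic solution of the two-step model the jerk zeros are exactly
#' symmetric about the inflection, so `tmax = (t1 + t2)/2`. This inverts the
#' phase-time extraction: given a reported induction time and plateau-onset
#' time, it returns the implied inflection time.
#'
#' @param t1 Induction time (pre-inflection jerk zero), hours.
#' @param t2 Plateau-onset time (post-inflection jerk zero), hours.
#' @return Inflection time in hours.
#' @export
#' @examples
#' fw_tmax_from_jerk(6.38, 17.34) # 11.86
fw_tmax_from_jerk <- function(t1, t2) {
  t1 <- as.numeric(t1); t2 <- as.numeric(t2)
  if (any(t2 <= t1)) stop("t2 must exceed t1", call. = FALSE)
  (t1 + t2) / 2
}

#' Published ClO4- aggregation kinetics of the triple-arginine peptide
#'
#' The fitted Finke-Watzky parameters and jerk-based phase times reported for
#' the aggregation of the triple-arginine 15-mer (2 mM, pD 5.2 acetate) at
#' three perchlorate concentrations. `kmax` is reproduced verbatim from the
#' published table as an annotation; its defining formula was not stated and
#' this package does not recompute it (see the methods vignette).
#'
#' @return Data frame with columns `salt_mM`, `k1` (h^-1), `t1` (h), `kmax`
#'   (mM^-1 h^-1, annotation only), `tmax` (h), `k2` (mM^-1 h^-1), `t2` (h).
#' @export
clo4_kinetics_table <- function() {
  data.frame(
    salt_mM = c(60, 80, 120),
    k1   = c(0.01, 0.03, 0.03),
    t1   = c(6.38, 3.47, 2.57),
    kmax = c(0.13, 0.14, 0.16),
    tmax = c(11.86, 8.68, 7.13),
    k2   = c(0.11, 0.11, 0.13),
    t2   = c(17.34, 13.90, 11.68))
}

# ---- fitting ---------------------------------------------------------------

# Low-discrepancy start offsets on log(k1), log(k2): van der Corput in bases
# 2 and 3, scaled to +/- 1.5 log units, rotated by the seed. Deterministic.
.fw_start_offsets <- function(n, seed) {
  vdc <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
    r
  }
  idx <- seq_len(n) + (seed %% 1000L)
  u1 <- vapply(idx, vdc, numeric(1), base = 2)
  u2 <- vapply(idx, vdc, numeric(1), base = 3)
  cbind(3 * (u1 - 0.5), 3 * (u2 - 0.5))
}

# Feature-based initial guesses from a monomer-loss trace.
# r0 from the 25-75% crossing interval of the drop (logistic: dt = 2*log(3)/r),
# tmax0 from the 50% crossing (fallback: steepest finite-difference slope),
# then inversion r = k1 + k2*A0, exp(r*tmax) = k2*A0/k1.
.fw_init_guess <- function(times, conc, A0) {
  lo <- min(conc); span <- max(conc) - lo
  if (span <= 0) return(NULL)
  frac <- (conc - lo) / span   # 1 at start, 0 at plateau
  cross <- function(level) {
    below <- which(frac <= level)
    if (!length(below)) return(NA_real_)
    i <- below[1]
    if (i == 1L) return(times[1])
    # linear interpolation
    f1 <- frac[i - 1]; f2 <- frac[i]
    times[i - 1] + (f1 - level) / (f1 - f2) * (times[i] - times[i - 1])
  }
  t75 <- cross(0.75); t50 <- cross(0.50); t25 <- cross(0.25)
  r0 <- if (is.finite(t25) && is.finite(t75) && t25 > t75) {
    2 * log(3) / (t25 - t75)
  } else NA_real_
  tmax0 <- if (is.finite(t50)) t50 else {
    slopes <- diff(conc) / diff(times)
    mean(times[which.min(slopes) + 0:1])
  }
  if (!is.finite(r0) || r0 <= 0) {
    r0 <- 4 / max(diff(range(times)), .Machine$double.eps)
  }
  # invert (r, tmax) -> (k1, k2): k1 = r/(1 + exp(r*tmax)), k2 = (r - k1)/A0
  e <- exp(min(r0 * tmax0, 700))
  k1 <- r0 / (1 + e)
  k2 <- (r0 - k1) / A0
  if (!is.finite(k1) || k1 <= 0) k1 <- 1e-6
  if (!is.finite(k2) || k2 <= 0) k2 <- r0 / (2 * A0)
  c(k1 = k1, k2 = k2)
}

#' Fit the Finke-Watzky model to an aggregation trace
#'
#' Nonlinear least squares of the closed-form monomer curve against a
#' monomer-loss time series. A0 is fixed at the known experimental
#' concentration by default (`fit_amplitude = FALSE`); with
#' `fit_amplitude = TRUE` an amplitude factor is co-fitted to accommodate
#' traces that plateau above zero monomer. Initial guesses are derived from
#' trace features (25-75% crossing interval and the 50% crossing); if the
#' initial fit fails, a deterministic multi-start over log-spaced
#' perturbations (fixed seed) is tried. Results are deterministic for a given
#' trace and configuration.
#'
#' @param trace An [aggregation_trace] (or list with `times` in hours and
#'   `monomer` in mM) of at least 6 points.
#' @param A0 Initial monomer concentration in mM; defaults to the trace
#'   metadata, falling back to 2 mM.
#' @param fit_amplitude Co-fit an amplitude scale (default FALSE).
#' @param r2_threshold Coefficient-of-determination threshold separating
#'   "good" from "poor" fits (default 0.98).
#' @param weights Optional per-point weights for the least squares.
#' @param n_starts Multi-start budget after the feature-based guess.
#' @param seed Seed for the multi-start perturbations (fixed default: fits are
#'   reproducible).
#' @param slack Allowed fractional excess of concentrations over A0.
#' @return An object of class `fw_fit` with elements `params` ([fw_params]),
#'   `phase` ([fw_jerk_times] result or NULL in the degenerate regime),
#'   `max_rate` (mM/h), `r_squared`, `residual_norm` (mM, RMS), `quality`
#'   ("good"/"poor"), `stderr` (named, from the local Jacobian), `converged`,
#'   and `diagnostic` (message for poor/degenerate outcomes).
#' @export
#' @examples
#' p <- fw_params(0.03, 0.13, 2)
#' tr <- gen_fw_trace(p, seq(0, 24, length.out = 49), noise_spec(0))
#' fit <- fit_fw(tr)
#' fit$params$k1
fit_fw <- function(trace, A0 = NULL, fit_amplitude = FALSE,
                   r2_threshold = 0.98, weights = NULL,
                   n_starts = 8L, seed = 20259L, slack = 0.05) {
  times <- as.numeric(trace$times)
  conc <- as.numeric(trace$monomer)
  if (length(times) < 6L) stop("need >= 6 time points", call. = FALSE)
  if (is.null(A0)) A0 <- trace$metadata$A0 %||% 2
  A0 <- as.numeric(A0)
  if (any(conc < 0) || any(conc > A0 * (1 + slack))) {
    stop("concentrations outside [0, A0*(1+slack)]", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, length(times)) else as.numeric(weights)

  model <- function(par, t) {
    k1 <- exp(par[1]); k2 <- exp(par[2])
    amp <- if (fit_amplitude) exp(par[3]) else 1
    r <- k1 + k2 * A0
    tm <- log(k2 * A0 / k1) / r
    amp * (A0 + k1 / k2) / (1 + exp(r * (t - tm)))
  }
  obj <- function(par) {
    res <- model(par, times) - conc
    sum(w * res^2)
  }

  starts <- list()
  g <- .fw_init_guess(times, conc, A0)
  if (!is.null(g)) starts[[1]] <- log(c(g["k1"], g["k2"]))
  base <- if (length(starts)) starts[[1]] else log(c(0.02, 0.1))
  # deterministic multi-start: fixed offsets around the feature-based guess,
  # seeded by a Halton-like low-discrepancy sequence (no global RNG touched)
  offs <- .fw_start_offsets(n_starts, seed)
  for (i in seq_len(n_starts)) {
    starts[[length(starts) + 1L]] <- base + offs[i, ]
  }
  if (fit_amplitude) starts <- lapply(starts, function(s) c(s, 0))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  converged <- !is.null(best) && best$convergence == 0
  diagnostic <- NA_character_

  if (is.null(best)) {
    return(structure(list(params = NULL, phase = NULL, max_rate = NA_real_,
                          r_squared = NA_real_, residual_norm = NA_real_,
                          quality = "poor", stderr = NULL, converged = FALSE,
                          diagnostic = "optimizer failed from all starts"),
                     class = "fw_fit"))
  }
  # polish with Nelder-Mead in case BFGS stalled
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-15))
  best <- stats::optim(best$par, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))

  par <- best$par
  k1 <- exp(par[1]); k2 <- exp(par[2])
  fitted <- model(par, times)
  ss_res <- sum(w * (conc - fitted)^2)
  ss_tot <- sum(w * (conc - stats::weighted.mean(conc, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  quality <- if (is.finite(r2) && r2 >= r2_threshold) "good" else "poor"
  if (quality == "poor") diagnostic <- sprintf("r^2 = %.4f below threshold %.4f",
                                               r2, r2_threshold)

  params <- fw_params(k1, k2, A0)
  phase <- NULL
  if (!params$degenerate) {
    phase <- suppressWarnings(fw_jerk_times(params))
  } else {
    diagnostic <- paste(stats::na.omit(c(diagnostic,
      "degenerate regime (k1 >= k2*A0): phase times undefined")), collapse = "; ")
    quality <- "poor"
  }

  # local stderr via numeric Jacobian of the model in (k1, k2[, amp]) space
  stderr <- tryCatch({
    np <- length(par)
    J <- matrix(0, length(times), np)
    for (j in seq_len(np)) {
      h <- 1e-6 * max(abs(par[j]), 1)
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      J[, j] <- (model(pp, times) - model(pm, times)) / (2 * h)
    }
    dof <- max(length(times) - np, 1)
    s2 <- ss_res / dof
    cv <- s2 * solve(crossprod(J * sqrt(w)))
    se_log <- sqrt(pmax(diag(cv), 0))
    # delta method: parameters fitted on log scale
    se <- se_log[1:2] * c(k1, k2)
    names(se) <- c("k1", "k2")
    se
  }, error = function(e) c(k1 = NA_real_, k2 = NA_real_))

  structure(list(params = params, phase = phase,
                 max_rate = fw_max_rate(params),
                 r_squared = r2,
                 residual_norm = sqrt(ss_res / length(times)),
                 quality = quality, stderr = stderr,
                 converged = converged,
                 diagnostic = diagnostic,
                 fitted = data.frame(time_h = times, fitted_mM = fitted)),
            class = "fw_fit")
}

#' @export
print.fw_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("F-W fit: FAILED -", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat(sprintf("F-W fit (%s): k1 = %.5g h^-1, k2 = %.5g mM^-1 h^-1, A0 = %g mM\n",
              x$quality, x$params$k1, x$params$k2, x$params$A0))
  if (!is.null(x$phase)) {
    cat(sprintf("  t1 = %.3f h, tmax = %.3f h, t2 = %.3f h; max rate %.4g mM/h\n",
                x$phase$t1, x$phase$tmax, x$phase$t2, x$max_rate))
  }
  cat(sprintf("  r^2 = %.5f, RMS residual = %.4g mM\n", x$r_squared, x$residual_norm))
  if (!is.na(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}
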