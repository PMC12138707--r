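# Per-residue anion association constants from fast-exchange NMR titrations,
# and chemical shift perturbation (bubble-map) analysis.
#
# Under fast exchange the observed amide shift is the population-weighted
# average of free and bound shifts. With the salt in large excess over the
# peptide (here >= ~90-fold), free ligand ~ total ligand and the 1:1 isotherm
# reduces to
#
#   delta_obs(c) = delta_free + delta_max * Ka*c / (1 + Ka*c)
#
# delta_max is the signed limiting shift change of the fully bound state
# (upfield shifts are negative).

#' Titration series
#'
#' Observed amide 1H shift versus total salt concentration for one residue.
#' Concentrations must be strictly increasing and start at 0 (free peptide).
#'
#' @param concentrations Total salt concentration, M, ascending from 0.
#' @param shifts Observed shift, ppm, same length.
#' @param residue,peptide,salt Metadata labels.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(concentrations, shifts, residue = NA_character_,
                             peptide = NA_character_, salt = NA_character_) {
  concentrations <- as.numeric(concentrations)
  shifts <- as.numeric(shifts)
  if (length(concentrations) != length(shifts)) {
    stop("concentrations and shifts must have equal length", call. = FALSE)
  }
  if (length(concentrations) < 5L) {
    stop("need >= 5 titration points for fitting", call. = FALSE)
  }
  if (concentrations[1] != 0) {
    stop("first concentration must be 0 (free peptide)", call. = FALSE)
  }
  if (any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  structure(list(concentrations = concentrations, shifts = shifts,
                 residue = residue, peptide = peptide, salt = salt),
            class = "titration_series")
}

#' 1:1 fast-exchange binding isotherm
#'
#' Observed shift under the excess-ligand approximation (free ligand = total
#' ligand): `delta_free + delta_max * Ka*c/(1 + Ka*c)`. Monotone in `conc`,
#' saturating at `delta_free + delta_max`.
#'
#' @param Ka Association constant, M^-1 (>= 0).
#' @param delta_free Free-state shift, ppm.
#' @param delta_max Signed limiting shift change of the bound state, ppm.
#' @param conc Total salt concentration, M (>= 0), vectorized.
#' @return Observed shift in ppm.
#' @export
#' @examples
#' isotherm_shift(6, 8.30, -0.15, 1 / 6) # half-saturation: 8.30 - 0.075
isotherm_shift <- function(Ka, delta_free, delta_max, conc) {
  if (Ka < 0) stop("Ka must be >= 0", call. = FALSE)
  conc <- as.numeric(conc)
  if (any(conc < 0)) stop("conc must be >= 0", call. = FALSE)
  delta_free + delta_max * (Ka * conc) / (1 + Ka * conc)
}

#' Exact 1:1 isotherm (quadratic in the bound fraction)
#'
#' The exact solution without the excess-ligand approximation, for a total
#' peptide-site concentration `P0`. Used behind the `exact = TRUE` flag of
#' [fit_ka] when the ligand excess is modest.
#'
#' @inheritParams isotherm_shift
#' @param P0 Total peptide (binding-site) concentration, M.
#' @return Observed shift in ppm.
#' @export
isotherm_shift_exact <- function(Ka, delta_free, delta_max, conc, P0) {
  if (Ka < 0) stop("Ka must be >= 0", call. = FALSE)
  conc <- as.numeric(conc)
  if (any(conc < 0)) stop("conc must be >= 0", call. = FALSE)
  if (Ka == 0) return(rep(delta_free, length(conc)))
  s <- P0 + conc + 1 / Ka
  bound <- (s - sqrt(s^2 - 4 * P0 * conc)) / (2 * P0)
  delta_free + delta_max * bound
}

#' Fit an association constant to a titration series
#'
#' Nonlinear least squares of [isotherm_shift] (or the exact quadratic form)
#' to one residue's titration. Ka is constrained non-negative by fitting on a
#' log scale with a deterministic multi-start over log-spaced Ka guesses.
#' When saturation is not approached (`max(Ka*conc)` small) Ka and delta_max
#' are nearly collinear; the fit is still returned but carries a
#' weak-binding warning.
#'
#' @param series A [titration_series].
#' @param exact Use the exact 1:1 quadratic isotherm with peptide
#'   concentration `P0` (default FALSE: excess-ligand approximation).
#' @param P0 Peptide (site) concentration in M, used when `exact = TRUE`
#'   (default 0.005, i.e. 5 mM).
#' @param ka_starts Ka multi-start grid, M^-1.
#' @return An object of class `binding_fit`: `Ka` (M^-1), `delta_free`,
#'   `delta_max` (ppm), `r_squared`, `stderr_Ka`, `residue`, `warning`
#'   (NA or a weak-binding/flat-series message), `converged`.
#' @export
#' @examples
#' s <- gen_titration(7, 8.30, -0.15, seq(0, 0.5, length.out = 12), noise_spec(0))
#' fit_ka(s)$Ka
fit_ka <- function(series, exact = FALSE, P0 = 0.005,
                   ka_starts = c(0.1, 0.5, 1, 2, 5, 10, 30, 100)) {
  stopifnot(inherits(series, "titration_series"))
  conc <- series$concentrations
  obs <- series$shifts

  model <- function(par) {
    Ka <- exp(par[1]); df <- par[2]; dm <- par[3]
    if (exact) isotherm_shift_exact(Ka, df, dm, conc, P0)
    else isotherm_shift(Ka, df, dm, conc)
  }
  obj <- function(par) sum((model(par) - obs)^2)

  df0 <- obs[1]
  dm0 <- obs[length(obs)] - obs[1]
  span <- max(abs(dm0), 1e-6)

  best <- NULL
  for (ka0 in ka_starts) {
    start <- c(log(ka0), df0, dm0 * (1 + 1 / max(ka0 * max(conc), 0.1)))
    fit <- tryCatch(
      stats::optim(start, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Ka fit failed to converge from all starts", call. = FALSE)
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-15))
  best <- stats::optim(best$par, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-15))

  Ka <- exp(best$par[1]); delta_free <- best$par[2]; delta_max <- best$par[3]
  fitted <- model(best$par)
  ss_res <- best$value
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0

  warn <- NA_character_
  if (ss_tot == 0 || abs(delta_max) < 10 * .Machine$double.eps * max(abs(obs), 1) ||
      stats::sd(obs) < 1e-12) {
    warn <- "flat series: Ka indistinguishable from 0"
    Ka <- 0
  } else if (Ka * max(conc) < 0.5) {
    warn <- "weak binding: saturation not approached, Ka and delta_max poorly separable"
  }

  # stderr of Ka from the Jacobian at the optimum (delta method off log scale)
  stderr_Ka <- tryCatch({
    par <- best$par
    J <- matrix(0, length(conc), 3)
    for (j in 1:3) {
      h <- 1e-6 * max(abs(par[j]), 1)
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      J[, j] <- (model(pp) - model(pm)) / (2 * h)
    }
    dof <- max(length(conc) - 3, 1)
    cv <- (ss_res / dof) * solve(crossprod(J))
    sqrt(max(cv[1, 1], 0)) * Ka
  }, error = function(e) NA_real_)

  structure(list(Ka = Ka, delta_free = delta_free, delta_max = delta_max,
                 r_squared = r2, stderr_Ka = stderr_Ka,
                 residue = series$residue, peptide = series$peptide,
                 salt = series$salt, warning = warn,
                 converged = best$convergence == 0),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding fit%s: Ka = %.4g M^-1 (se %.2g), delta_free = %.4f ppm, delta_max = %+.4f ppm, r^2 = %.5f\n",
              if (is.na(x$residue)) "" else paste0(" [", x$residue, "]"),
              x$Ka, x$stderr_Ka, x$delta_free, x$delta_max, x$r_squared))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

# ---- chemical shift perturbation -------------------------------------------

#' Per-residue shift table
#'
#' Amide 1H shifts for one peptide under one condition, keyed by residue
#' position. Position 1 (N-terminal amine) typically has no amide entry.
#'
#' @param positions Integer residue positions.
#' @param shifts Amide 1H shifts, ppm.
#' @param peptide Peptide label.
#' @param condition Named list of condition metadata (salt, concentration or
#'   equivalents, pH, temperature), stored verbatim.
#' @return An object of class `shift_table`.
#' @export
shift_table <- function(positions, shifts, peptide = NA_character_,
                        condition = list()) {
  positions <- as.integer(positions)
  shifts <- as.numeric(shifts)
  if (length(positions) != length(shifts)) {
    stop("positions and shifts must have equal length", call. = FALSE)
  }
  if (anyDuplicated(positions)) stop("duplicate positions", call. = FALSE)
  o <- order(positions)
  structure(list(positions = positions[o], shifts = shifts[o],
                 peptide = peptide, condition = condition),
            class = "shift_table")
}

#' Chemical shift perturbation map
#'
#' Per-residue signed shift change upon adding the salt:
#' `delta = shift(bound) - shift(free)`. Upfield (negative) changes are
#' classified as anion "association", downfield (positive) ones as
#' "non-specific" ionic-strength effects; entries with `|delta|` at or below
#' `error_threshold` are flagged insignificant.
#'
#' @param free,bound [shift_table]s of the same peptide with identical residue
#'   coverage.
#' @param error_threshold Magnitude below which a perturbation is treated as
#'   within experimental error, ppm (default 0.005, the bubble-map error
#'   bubble).
#' @param salt Salt label attached to the map (defaults to the bound table's
#'   condition).
#' @return An object of class `csp_map`: data frame `delta` with columns
#'   `position`, `delta_ppm`, `class` ("association"/"non-specific"/"none"),
#'   `significant`; plus `peptide`, `salt`, `error_threshold`.
#' @export
csp <- function(free, bound, error_threshold = 0.005, salt = NULL) {
  stopifnot(inherits(free, "shift_table"), inherits(bound, "shift_table"))
  if (!identical(free$peptide, bound$peptide)) {
    stop("shift tables refer to different peptides", call. = FALSE)
  }
  miss_b <- setdiff(free$positions, bound$positions)
  miss_f <- setdiff(bound$positions, free$positions)
  if (length(miss_b) || length(miss_f)) {
    stop("residue coverage mismatch; missing in bound: {",
         paste(miss_b, collapse = ","), "}, missing in free: {",
         paste(miss_f, collapse = ","), "}", call. = FALSE)
  }
  d <- bound$shifts[match(free$positions, bound$positions)] - free$shifts
  sig <- abs(d) > error_threshold
  cls <- ifelse(!sig, "none", ifelse(d < 0, "association", "non-specific"))
  structure(list(
    delta = data.frame(position = free$positions, delta_ppm = d,
                       class = cls, significant = sig),
    peptide = free$peptide,
    salt = salt %||% (bound$condition$salt %||% NA_character_),
    error_threshold = error_threshold),
    class = "csp_map")
}

#' @export
print.csp_map <- function(x, ...) {
  cat(sprintf("CSP map: peptide %s + %s (error threshold %.3f ppm)\n",
              x$peptide, x$salt, x$error_threshold))
  print(x$delta, row.names = FALSE)
  invisible(x)
}

#' Neighbor asymmetry around charged side chains
#'
#' For each cationic position i, compares the perturbation of the amide on its
#' N-terminal side (N-H of residue i itself) with that on its C-terminal side
#' (N-H of residue i+1) and reports whether `|delta_i| > |delta_{i+1}|` (the
#' rule). Ties under strict inequality count as exceptions. Positions whose
#' i or i+1 amide is not in the map are skipped with a note.
#'
#' @param map A [csp_map].
#' @param charged_positions Integer positions of the cationic side chains.
#' @return List with `comparisons` (data frame: position, delta_i, delta_ip1,
#'   holds) and `summary` (`n_holds`, `n_exceptions`, `skipped`).
#' @export
neighbor_asymmetry <- function(map, charged_positions) {
  stopifnot(inherits(map, "csp_map"))
  d <- map$delta
  rows <- list(); skipped <- integer()
  for (i in sort(as.integer(charged_positions))) {
    di <- d$delta_ppm[d$position == i]
    dip1 <- d$delta_ppm[d$position == i + 1L]
    if (!length(di) || !length(dip1)) { skipped <- c(skipped, i); next }
    rows[[length(rows) + 1L]] <- data.frame(
      position = i, delta_i = di, delta_ip1 = dip1,
      holds = abs(di) > abs(dip1))
  }
  comparisons <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), delta_i = numeric(),
               delta_ip1 = numeric(), holds = logical())
  list(comparisons = comparisons,
       summary = list(n_holds = sum(comparisons$holds),
                      n_exceptions = sum(!comparisons$holds),
                      skipped = skipped))
}

#' Bubble-map plot data
#'
#' Tidy per-residue table for drawing a bubble map: bubble area (not radius)
#' is proportional to `|delta|`, so the radius scales as `sqrt(|delta|)`.
#' Color class follows the sign (upfield/red = association, downfield/blue =
#' non-specific).
#'
#' @param map A [csp_map].
#' @param peptide Optional [peptide_sequence] used to attach residue labels.
#' @param area_scale Area units per ppm (default 1).
#' @return Data frame with columns `position`, `label`, `delta_ppm`, `area`,
#'   `radius`, `color_class` ("up"/"down"/"zero") and `significant`.
#' @export
bubble_map_export <- function(map, peptide = NULL, area_scale = 1) {
  stopifnot(inherits(map, "csp_map"))
  d <- map$delta
  lab <- if (!is.null(peptide)) residue_label(peptide, d$position)
         else as.character(d$position)
  area <- area_scale * abs(d$delta_ppm)
  data.frame(position = d$position, label = lab, delta_ppm = d$delta_ppm,
             area = area, radius = sqrt(area / pi),
             color_class = ifelse(d$delta_ppm < 0, "up",
                                  ifelse(d$delta_ppm > 0, "down", "zero")),
             significant = d$significant)
}

#' Convert salt equivalents to molar concentration
#'
#' The titrations report salt in equivalents of the peptide concentration
#' (5 mM): 93 equivalents = 465 mM.
#'
#' @param equivalents Numeric equivalents.
#' @param peptide_mM Peptide concentration in mM (default 5).
#' @return Concentration in M.
#' @export
equivalents_to_molar <- function(equivalents, peptide_mM = 5) {
  as.numeric(equivalents) * peptide_mM / 1000
}
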