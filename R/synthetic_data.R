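# Synthetic-data generators: forward models for every input the analysis
# consumes, with the statistical structure the analysis assumes. All
# generators draw from a private RNG stream seeded explicitly through a
# noise_spec; the global RNG state is never touched.
#
# Default noise levels mimic the quality of the experimental data the package
# was built around: 0.02-0.05 mM on concentration traces, 0.002 ppm on
# chemical shifts, 0.1 Hz on couplings.

#' Noise specification
#'
#' Gaussian noise of standard deviation `sigma` (in the units of the target
#' quantity) drawn from a stream seeded by `seed`. The same spec always
#' produces the same draws (bit-reproducible).
#'
#' @param sigma Standard deviation, >= 0.
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = 1L) {
  sigma <- as.numeric(sigma)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "noise_spec")
}

# isolate generator draws: save/restore the global seed around the expression
.with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a Finke-Watzky monomer-loss trace
#'
#' Evaluates the closed-form monomer curve at the requested times and adds
#' Gaussian noise, clipping to `[0, A0]` (the number of clipped points is
#' recorded in the trace metadata).
#'
#' @param params An [fw_params].
#' @param times Hours, strictly increasing.
#' @param noise A [noise_spec]; sigma in mM.
#' @param metadata Extra metadata stored on the trace.
#' @return An [aggregation_trace].
#' @export
#' @examples
#' tr <- gen_fw_trace(fw_params(0.03, 0.13, 2),
#'                    seq(0, 24, length.out = 49), noise_spec(0.04, seed = 7))
gen_fw_trace <- function(params, times, noise = noise_spec(0),
                         metadata = list()) {
  p <- .as_fw(params)
  clean <- fw_monomer(p, times)
  eps <- .with_private_seed(noise$seed,
                            if (noise$sigma > 0) stats::rnorm(length(times), sd = noise$sigma)
                            else numeric(length(times)))
  y <- clean + eps
  n_clip <- sum(y < 0 | y > p$A0)
  y <- pmin(pmax(y, 0), p$A0)
  md <- utils::modifyList(list(A0 = p$A0, n_clipped = n_clip), metadata)
  aggregation_trace(times, y, metadata = md)
}

#' Simulate raw methyl-probe integrals from a trace (inverse of normalization)
#'
#' `integral_k(t) = probe_scale_k * monomer(t)/A0 * ref_level (+ noise)`, so
#' that [normalize_trace] recovers the trace (exactly at sigma = 0, within
#' noise otherwise, for any positive probe scales).
#'
#' @param trace An [aggregation_trace].
#' @param probe_scales Named positive constants, default three probes
#'   ("3V", "8L", "15V").
#' @param ref_level Reference integral level, > 0.
#' @param noise A [noise_spec]; sigma in integral units.
#' @return A [raw_integral_series].
#' @export
gen_raw_integrals <- function(trace,
                              probe_scales = c(`3V` = 1, `8L` = 1.5, `15V` = 0.8),
                              ref_level = 100, noise = noise_spec(0)) {
  stopifnot(inherits(trace, "aggregation_trace"))
  if (any(probe_scales <= 0) || ref_level <= 0) {
    stop("probe scales and ref_level must be positive", call. = FALSE)
  }
  A0 <- trace$metadata$A0 %||% 2
  n <- length(trace$times)
  k <- length(probe_scales)
  eps <- .with_private_seed(noise$seed,
                            if (noise$sigma > 0) stats::rnorm(n * k, sd = noise$sigma)
                            else numeric(n * k))
  integrals <- stats::setNames(vector("list", k), names(probe_scales))
  for (i in seq_len(k)) {
    clean <- probe_scales[[i]] * trace$monomer / A0 * ref_level
    v <- clean + eps[((i - 1) * n + 1):(i * n)]
    # keep t = 0 noise-free so self-normalization is well defined
    v[1] <- clean[1]
    integrals[[i]] <- pmax(v, 0)
  }
  raw_integral_series(trace$times, integrals, rep(ref_level, n),
                      metadata = trace$metadata)
}

#' Simulate a fast-exchange titration series
#'
#' [isotherm_shift] at each concentration plus Gaussian noise.
#'
#' @param Ka Association constant, M^-1.
#' @param delta_free,delta_max Isotherm parameters, ppm.
#' @param concs Total salt concentrations, M, ascending from 0.
#' @param noise A [noise_spec]; sigma in ppm.
#' @param residue,peptide,salt Metadata labels.
#' @return A [titration_series].
#' @export
gen_titration <- function(Ka, delta_free, delta_max, concs,
                          noise = noise_spec(0), residue = NA_character_,
                          peptide = NA_character_, salt = NA_character_) {
  clean <- isotherm_shift(Ka, delta_free, delta_max, concs)
  eps <- .with_private_seed(noise$seed,
                            if (noise$sigma > 0) stats::rnorm(length(concs), sd = noise$sigma)
                            else numeric(length(concs)))
  titration_series(concs, clean + eps, residue = residue, peptide = peptide,
                   salt = salt)
}

#' Simulate a variable-temperature shift series
#'
#' Linear series `intercept + slope * T` plus noise. The slope is given in
#' ppb/K with the field's sign convention (positive magnitude = upfield drift
#' with increasing temperature, i.e. the raw ppm slope is negative).
#'
#' @param slope_ppb_per_K Temperature coefficient magnitude, ppb/K.
#' @param intercept_ppm Shift at 0 degrees of the declared unit scale, ppm.
#' @param temps Temperatures, strictly increasing (>= 4 points).
#' @param noise A [noise_spec]; sigma in ppm.
#' @param unit "C" or "K".
#' @param residue Residue label.
#' @return A [vt_series].
#' @export
gen_vt <- function(slope_ppb_per_K, intercept_ppm, temps,
                   noise = noise_spec(0), unit = c("C", "K"),
                   residue = NA_character_) {
  unit <- match.arg(unit)
  temps <- as.numeric(temps)
  if (length(temps) < 4L) stop("need >= 4 temperatures", call. = FALSE)
  clean <- intercept_ppm - slope_ppb_per_K / 1000 * temps
  eps <- .with_private_seed(noise$seed,
                            if (noise$sigma > 0) stats::rnorm(length(temps), sd = noise$sigma)
                            else numeric(length(temps)))
  vt_series(temps, clean + eps, unit = unit, residue = residue)
}

#' Simulate a J-coupling set from backbone dihedrals
#'
#' [karplus_j] per residue plus noise, clipped to the plausible window
#' \[0, 12\] Hz.
#'
#' @param phis Named numeric vector or list: residue position -> phi, degrees.
#' @param params A [karplus_params].
#' @param noise A [noise_spec]; sigma in Hz.
#' @param peptide,condition Metadata.
#' @return A [jcoupling_set].
#' @export
gen_jset <- function(phis, params = karplus_params(), noise = noise_spec(0),
                     peptide = NA_character_, condition = list()) {
  positions <- as.integer(names(phis))
  if (any(is.na(positions))) {
    stop("phis must be named by residue position", call. = FALSE)
  }
  clean <- karplus_j(unlist(phis, use.names = FALSE), params)
  eps <- .with_private_seed(noise$seed,
                            if (noise$sigma > 0) stats::rnorm(length(clean), sd = noise$sigma)
                            else numeric(length(clean)))
  jcoupling_set(positions, pmin(pmax(clean + eps, 0), 12), peptide = peptide,
                condition = condition)
}
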