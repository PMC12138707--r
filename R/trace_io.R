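# Conversion of raw NMR integral time-courses (methyl probe signals vs an
# external reference) into normalized monomer-loss aggregation traces.
#
# Aggregation is monitored by the integrals of the 3V, 8L and 15V methyl
# signals, each referenced to an external standard (sodium ethyl sulfate).
# Ratios are self-normalized to t = 0, so per-probe calibration constants and
# any rescaling of the reference cancel.

#' Raw integral time series
#'
#' @param times Times in hours, strictly increasing, including t = 0.
#' @param integrals Named list (or data frame) of probe-signal integral
#'   vectors, conventionally "3V", "8L", "15V"; each the length of `times`.
#' @param reference External-reference integral per time point, > 0 everywhere.
#' @param metadata Named list: peptide, salt, salt_mM, pH (or pD, recorded
#'   verbatim), A0 in mM.
#' @return An object of class `raw_integral_series`.
#' @export
raw_integral_series <- function(times, integrals, reference, metadata = list()) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  integrals <- lapply(integrals, as.numeric)
  if (is.null(names(integrals)) || any(!nzchar(names(integrals)))) {
    stop("integrals must be a named list of probe signals", call. = FALSE)
  }
  reference <- as.numeric(reference)
  if (length(reference) != length(times)) {
    stop("reference must match times in length", call. = FALSE)
  }
  if (any(reference <= 0)) stop("reference must be > 0 everywhere", call. = FALSE)
  for (nm in names(integrals)) {
    if (length(integrals[[nm]]) != length(times)) {
      stop("integral vector '", nm, "' length mismatch", call. = FALSE)
    }
  }
  structure(list(times = times, integrals = integrals, reference = reference,
                 metadata = metadata),
            class = "raw_integral_series")
}

#' Aggregation trace
#'
#' Soluble-monomer concentration versus time for one peptide/salt/pH
#' condition.
#'
#' @param times Hours, strictly increasing.
#' @param monomer Monomer concentration, mM, within `[0, A0*(1+slack)]`.
#' @param metadata Named list; must carry `A0` (mM) for conversions.
#' @param quality Optional per-time quality metric (probe disagreement).
#' @param slack Tolerated fractional excess over A0 before rejection; values
#'   in (A0, A0*(1+slack)] are clipped to A0 with a count in the metadata.
#' @return An object of class `aggregation_trace`.
#' @export
aggregation_trace <- function(times, monomer, metadata = list(A0 = 2),
                              quality = NULL, slack = 0.05) {
  times <- as.numeric(times)
  monomer <- as.numeric(monomer)
  if (length(times) != length(monomer)) {
    stop("times and monomer must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  A0 <- metadata$A0 %||% 2
  if (any(monomer < 0) || any(monomer > A0 * (1 + slack))) {
    stop("monomer outside [0, A0*(1+slack)]", call. = FALSE)
  }
  n_clip <- sum(monomer > A0)
  if (n_clip > 0) {
    warning(n_clip, " point(s) above A0 clipped (integration noise)", call. = FALSE)
    monomer <- pmin(monomer, A0)
  }
  metadata$n_clipped <- (metadata$n_clipped %||% 0L) + n_clip
  structure(list(times = times, monomer = monomer, metadata = metadata,
                 quality = quality),
            class = "aggregation_trace")
}

#' @export
print.aggregation_trace <- function(x, ...) {
  cat(sprintf("aggregation trace: %d points, %.2g-%.2g h, A0 = %g mM\n",
              length(x$times), min(x$times), max(x$times),
              x$metadata$A0 %||% NA))
  invisible(x)
}

#' Normalize raw integrals to a monomer trace
#'
#' For each probe signal k, forms `ratio_k(t) = integral_k(t)/reference(t)`
#' and self-normalizes to t = 0; the monomer fraction is the mean (or median)
#' over probes of `ratio_k(t)/ratio_k(0)`, and monomer mM = fraction * A0.
#' The maximum pairwise relative spread of the per-probe fractions is attached
#' as a per-time quality metric.
#'
#' @param raw A [raw_integral_series] whose first time point is t = 0.
#' @param A0 Initial monomer concentration in mM (default: metadata, then 2).
#' @param combine "mean" (default) or "median" across probes.
#' @param slack Tolerated fractional excess over A0 (default 0.05): values in
#'   the slack band are clipped to A0, larger ones are rejected.
#' @return An [aggregation_trace].
#' @export
normalize_trace <- function(raw, A0 = NULL, combine = c("mean", "median"),
                            slack = 0.05) {
  stopifnot(inherits(raw, "raw_integral_series"))
  combine <- match.arg(combine)
  if (raw$times[1] != 0) stop("raw series must include t = 0", call. = FALSE)
  A0 <- as.numeric(A0 %||% raw$metadata$A0 %||% 2)
  fr <- vapply(raw$integrals, function(v) {
    ratio <- v / raw$reference
    if (ratio[1] == 0) stop("zero probe ratio at t = 0", call. = FALSE)
    ratio / ratio[1]
  }, numeric(length(raw$times)))
  frac <- apply(fr, 1, if (combine == "mean") mean else stats::median)
  spread <- apply(fr, 1, function(row) {
    m <- mean(row)
    if (m == 0) 0 else (max(row) - min(row)) / abs(m)
  })
  frac <- pmax(frac, 0)
  aggregation_trace(raw$times, frac * A0,
                    metadata = utils::modifyList(raw$metadata, list(A0 = A0)),
                    quality = spread, slack = slack)
}

#' Complement trace: aggregate from monomer (and back)
#'
#' `B(t) = A0 - monomer(t)` on the same time base. Applying the operation
#' twice returns the original trace.
#'
#' @param trace An [aggregation_trace] with `A0` in its metadata.
#' @return An [aggregation_trace] holding the complement.
#' @export
to_aggregate <- function(trace) {
  stopifnot(inherits(trace, "aggregation_trace"))
  A0 <- trace$metadata$A0 %||% stop("trace metadata must carry A0", call. = FALSE)
  aggregation_trace(trace$times, A0 - trace$monomer, metadata = trace$metadata,
                    quality = trace$quality)
}

# ---- CSV I/O ----------------------------------------------------------------

#' Read and write aggregation-trace CSV
#'
#' The dialect is `time_h,concentration_mM` (or `time_h,fraction` plus an `A0`
#' supplied here or in the metadata columns). Optional metadata columns
#' (`peptide`, `salt`, `salt_mM`, `pH`, `A0`) are constant per file.
#'
#' @param path CSV path.
#' @param A0 A0 in mM when the file stores fractions.
#' @return For the reader, an [aggregation_trace].
#' @export
read_trace_csv <- function(path, A0 = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_h" %in% names(df)) stop("missing 'time_h' column", call. = FALSE)
  meta_cols <- intersect(c("peptide", "salt", "salt_mM", "pH", "A0"), names(df))
  metadata <- lapply(df[1, meta_cols, drop = FALSE], identity)
  if (!is.null(A0)) metadata$A0 <- A0
  if ("concentration_mM" %in% names(df)) {
    monomer <- df$concentration_mM
    metadata$A0 <- metadata$A0 %||% 2
  } else if ("fraction" %in% names(df)) {
    A0v <- metadata$A0 %||% stop("fraction trace requires A0", call. = FALSE)
    monomer <- df$fraction * as.numeric(A0v)
    metadata$A0 <- as.numeric(A0v)
  } else {
    stop("need a 'concentration_mM' or 'fraction' column", call. = FALSE)
  }
  aggregation_trace(df$time_h, monomer, metadata = metadata)
}

#' @rdname read_trace_csv
#' @param trace An [aggregation_trace] to write.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "aggregation_trace"))
  df <- data.frame(time_h = trace$times, concentration_mM = trace$monomer)
  for (nm in intersect(c("peptide", "salt", "salt_mM", "pH", "A0"),
                       names(trace$metadata))) {
    df[[nm]] <- trace$metadata[[nm]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a raw-integral CSV
#'
#' Dialect: `time_h,int_3V,int_8L,int_15V,int_ref`, with optional constant
#' metadata columns as in [read_trace_csv].
#'
#' @param path CSV path.
#' @param metadata Extra metadata merged over any metadata columns.
#' @return A [raw_integral_series].
#' @export
read_raw_csv <- function(path, metadata = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_h", "int_ref")
  if (!all(need %in% names(df))) {
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  probe_cols <- grep("^int_(?!ref$)", names(df), perl = TRUE, value = TRUE)
  if (!length(probe_cols)) stop("no probe integral columns (int_*)", call. = FALSE)
  integrals <- stats::setNames(lapply(probe_cols, function(cn) df[[cn]]),
                               sub("^int_", "", probe_cols))
  meta_cols <- intersect(c("peptide", "salt", "salt_mM", "pH", "A0"), names(df))
  md <- utils::modifyList(lapply(df[1, meta_cols, drop = FALSE], identity),
                          metadata)
  raw_integral_series(df$time_h, integrals, df$int_ref, metadata = md)
}

#' @rdname read_raw_csv
#' @param raw A [raw_integral_series] to write.
#' @export
write_raw_csv <- function(raw, path) {
  stopifnot(inherits(raw, "raw_integral_series"))
  df <- data.frame(time_h = raw$times)
  for (nm in names(raw$integrals)) df[[paste0("int_", nm)]] <- raw$integrals[[nm]]
  df$int_ref <- raw$reference
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write titration CSV (`conc_M,shift_ppm` + metadata columns)
#'
#' @param path CSV path.
#' @return For the reader, a [titration_series].
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("conc_M", "shift_ppm") %in% names(df))) {
    stop("need 'conc_M' and 'shift_ppm' columns", call. = FALSE)
  }
  grab <- function(nm) if (nm %in% names(df)) as.character(df[[nm]][1]) else NA_character_
  titration_series(df$conc_M, df$shift_ppm, residue = grab("residue"),
                   peptide = grab("peptide"), salt = grab("salt"))
}

#' @rdname read_titration_csv
#' @param series A [titration_series] to write.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- data.frame(conc_M = series$concentrations, shift_ppm = series$shifts,
                   residue = series$residue, peptide = series$peptide,
                   salt = series$salt)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue shift table CSV (`position,residue,shift_ppm`)
#'
#' @param path CSV path.
#' @param peptide Peptide label.
#' @param condition Condition metadata list.
#' @return A [shift_table].
#' @export
read_shift_csv <- function(path, peptide = NA_character_, condition = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("position", "shift_ppm") %in% names(df))) {
    stop("need 'position' and 'shift_ppm' columns", call. = FALSE)
  }
  shift_table(df$position, df$shift_ppm, peptide = peptide, condition = condition)
}

#' Read a J-coupling CSV (`position,residue,J_Hz`)
#'
#' @inheritParams read_shift_csv
#' @return A [jcoupling_set].
#' @export
read_jset_csv <- function(path, peptide = NA_character_, condition = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("position", "J_Hz") %in% names(df))) {
    stop("need 'position' and 'J_Hz' columns", call. = FALSE)
  }
  jcoupling_set(df$position, df$J_Hz, peptide = peptide, condition = condition)
}

#' Read a VT series CSV (`temperature,shift_ppm`)
#'
#' @param path CSV path.
#' @param unit Temperature unit, "C" or "K".
#' @param residue Residue label.
#' @return A [vt_series].
#' @export
read_vt_csv <- function(path, unit = c("C", "K"), residue = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("temperature", "shift_ppm") %in% names(df))) {
    stop("need 'temperature' and 'shift_ppm' columns", call. = FALSE)
  }
  vt_series(df$temperature, df$shift_ppm, unit = match.arg(unit),
            residue = residue)
}
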