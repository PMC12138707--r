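# Peptide bookkeeping: the three 15-mer N-terminal alpha-synuclein variants
# and residue-label utilities used by every downstream stage.

#' Peptide sequence object
#'
#' Constructs a `peptide_sequence`, the residue-bookkeeping object used by the
#' binding and structure modules. Positions are 1-based.
#'
#' @param id Character label for the peptide (the built-ins use "1", "2", "3").
#' @param residues Character vector of one-letter amino-acid codes, or a single
#'   string which is split into characters.
#' @param variable_positions Integer vector of positions carrying the cationic
#'   X substitution (built-ins: 6, 10, 12).
#' @param charged_positions Integer vector of positions treated as cationic at
#'   the working pH. This is configuration, not computed chemistry: at pH 2.3
#'   the N-terminus and the X positions are protonated for all three variants;
#'   His protonation at pH 5.2 is up to the user. Defaults to
#'   `variable_positions`.
#'
#' @return An object of class `peptide_sequence` with fields `id`, `residues`,
#'   `variable_positions` and `charged_positions`.
#' @export
#' @examples
#' p <- peptide_sequence("wt", "MDVFMKGLSKAKEGV", variable_positions = c(6, 10, 12))
#' residue_label(p, 12)
peptide_sequence <- function(id, residues, variable_positions = integer(),
                             charged_positions = variable_positions) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (!all(residues %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("residues must be one-letter amino-acid codes", call. = FALSE)
  }
  n <- length(residues)
  variable_positions <- sort(unique(as.integer(variable_positions)))
  charged_positions <- sort(unique(as.integer(charged_positions)))
  for (ps in list(variable_positions, charged_positions)) {
    if (length(ps) && (min(ps) < 1L || max(ps) > n)) {
      stop("positions out of range 1..", n, call. = FALSE)
    }
  }
  if (length(variable_positions) > 1L &&
      length(unique(residues[variable_positions])) != 1L) {
    stop("residues at variable positions must be identical", call. = FALSE)
  }
  structure(
    list(id = as.character(id), residues = residues,
         variable_positions = variable_positions,
         charged_positions = charged_positions),
    class = "peptide_sequence"
  )
}

# Wild-type template with X at the three substitution sites.
.pep_template <- c("M", "D", "V", "F", "M", "X", "G", "L", "S", "X",
                   "A", "X", "E", "G", "V")
.pep_x <- c("1" = "K", "2" = "R", "3" = "H")

#' Built-in 15-mer peptides
#'
#' Returns one of the three studied 15-mer peptides: the wild-type N-terminal
#' sequence MDVFMXGLSXAXEGV with X = K (peptide "1"), and the triple mutants
#' with X = R ("2") or X = H ("3") at positions 6, 10 and 12.
#'
#' @param id One of "1", "2" or "3".
#' @return A [peptide_sequence].
#' @export
#' @examples
#' builtin_peptide("1") # lysine wild type, MDVFMKGLSKAKEGV
builtin_peptide <- function(id) {
  id <- as.character(id)
  if (!id %in% names(.pep_x)) {
    stop("unknown peptide id '", id, "'; valid ids: ",
         paste(names(.pep_x), collapse = ", "), call. = FALSE)
  }
  res <- .pep_template
  res[res == "X"] <- .pep_x[[id]]
  peptide_sequence(id, res, variable_positions = c(6L, 10L, 12L))
}

#' Residue label at a position
#'
#' Formats the one-letter code plus position ("K12" style).
#'
#' @param seq A [peptide_sequence].
#' @param position Integer position, 1-based.
#' @return Character label such as "K12".
#' @export
residue_label <- function(seq, position) {
  stopifnot(inherits(seq, "peptide_sequence"))
  position <- as.integer(position)
  if (any(position < 1L | position > length(seq$residues))) {
    stop("position out of range 1..", length(seq$residues), call. = FALSE)
  }
  paste0(seq$residues[position], position)
}

#' Parse a residue label
#'
#' Accepts both the letter-then-number dialect ("S9") and the number-then-letter
#' dialect ("9S"); both appear in the literature this package serves.
#'
#' @param label Character label.
#' @return Named list with `residue` (one-letter code) and `position` (integer).
#' @export
parse_residue_label <- function(label) {
  label <- trimws(as.character(label))
  m1 <- regmatches(label, regexec("^([A-Za-z])([0-9]+)$", label))[[1]]
  m2 <- regmatches(label, regexec("^([0-9]+)([A-Za-z])$", label))[[1]]
  if (length(m1) == 3L) {
    list(residue = toupper(m1[2]), position = as.integer(m1[3]))
  } else if (length(m2) == 3L) {
    list(residue = toupper(m2[3]), position = as.integer(m2[2]))
  } else {
    stop("cannot parse residue label '", label, "'", call. = FALSE)
  }
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat("peptide", x$id, ":", paste(x$residues, collapse = ""), "\n")
  if (length(x$variable_positions)) {
    cat("  variable (X) positions:", paste(x$variable_positions, collapse = ", "), "\n")
  }
  if (length(x$charged_positions)) {
    cat("  charged positions:", paste(x$charged_positions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read or write a plain-text peptide definition (JSON)
#'
#' The on-disk form is `{id, sequence, variable_positions, charged_positions}`.
#'
#' @param path File path.
#' @return For `read_peptide_json`, a [peptide_sequence].
#' @export
read_peptide_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  peptide_sequence(x$id, x$sequence,
                   variable_positions = x$variable_positions %||% integer(),
                   charged_positions = x$charged_positions %||% x$variable_positions %||% integer())
}

#' @rdname read_peptide_json
#' @param seq A [peptide_sequence] to serialize.
#' @export
write_peptide_json <- function(seq, path) {
  stopifnot(inherits(seq, "peptide_sequence"))
  jsonlite::write_json(
    list(id = seq$id, sequence = paste(seq$residues, collapse = ""),
         variable_positions = seq$variable_positions,
         charged_positions = seq$charged_positions),
    path, auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
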