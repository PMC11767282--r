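#' @title Electronic-transition tables
#' @description Data model and plain-text readers/writers for tables of
#'   electronic transitions (absorption and emission lines with wavelengths
#'   and oscillator strengths), the exchange currency between excited-state
#'   calculations and the photophysics formulas in this package.
#' @name transitions
NULL

.transition_kinds <- c("absorption", "emission", "emission_experimental")

.transition_cols <- c("molecule_id", "kind", "state_from", "state_to",
                      "wavelength_nm", "oscillator_strength", "method")

#' Construct a transition table
#'
#' A transition table is a data frame with one row per electronic transition
#' and columns `molecule_id`, `kind` (one of `"absorption"`, `"emission"`,
#' `"emission_experimental"`), `state_from`, `state_to` (electronic-state
#' indices, 0 = ground state), `wavelength_nm`, `oscillator_strength`
#' (`NA` allowed, e.g. for experimental rows), and `method`.
#'
#' @param molecule_id Character vector of molecule labels.
#' @param kind Character vector of transition kinds.
#' @param state_from,state_to Integer electronic-state indices (0 = S0).
#' @param wavelength_nm Positive transition wavelengths in nm.
#' @param oscillator_strength Non-negative oscillator strengths; `NA` for
#'   rows without one (experimental entries).
#' @param method Character vector naming the level of theory or "experiment".
#' @return A `transition_table` (a validated data frame).
#' @examples
#' transition_table(
#'   molecule_id = "BIMC", kind = "emission", state_from = 1, state_to = 0,
#'   wavelength_nm = 458.2, oscillator_strength = 1.2263, method = "STEOM")
#' @export
transition_table <- function(molecule_id = character(), kind = character(),
                             state_from = integer(), state_to = integer(),
                             wavelength_nm = numeric(),
                             oscillator_strength = numeric(),
                             method = character()) {
  tab <- data.frame(
    molecule_id = as.character(molecule_id),
    kind = as.character(kind),
    state_from = as.integer(state_from),
    state_to = as.integer(state_to),
    wavelength_nm = as.numeric(wavelength_nm),
    oscillator_strength = as.numeric(oscillator_strength),
    method = as.character(method),
    stringsAsFactors = FALSE
  )
  validate_transition_table(tab)
}

#' Validate a transition table
#'
#' Checks the container invariants: positive wavelengths, non-negative
#' oscillator strengths where present, emission rows going downward in state
#' index and absorption rows upward, and uniqueness of the
#' (molecule, kind, states, method) key.
#'
#' @param tab A data frame with the transition-table columns.
#' @return The validated table, classed `transition_table`.
#' @export
validate_transition_table <- function(tab) {
  missing_cols <- setdiff(.transition_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("transition table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, .transition_cols, drop = FALSE]
  if (nrow(tab) > 0) {
    bad_kind <- !(tab$kind %in% .transition_kinds)
    if (any(bad_kind)) {
      stop("invalid transition kind at row ", which(bad_kind)[1], ": '",
           tab$kind[bad_kind][1], "'", call. = FALSE)
    }
    if (anyNA(tab$wavelength_nm) || any(tab$wavelength_nm <= 0)) {
      bad <- which(is.na(tab$wavelength_nm) | tab$wavelength_nm <= 0)[1]
      stop("non-positive or unparsable wavelength at row ", bad, call. = FALSE)
    }
    f <- tab$oscillator_strength
    if (any(!is.na(f) & f < 0)) {
      stop("negative oscillator strength at row ", which(!is.na(f) & f < 0)[1],
           call. = FALSE)
    }
    if (anyNA(tab$state_from) || anyNA(tab$state_to) ||
        any(tab$state_from < 0) || any(tab$state_to < 0)) {
      stop("state indices must be non-negative integers", call. = FALSE)
    }
    em <- tab$kind %in% c("emission", "emission_experimental")
    if (any(em & tab$state_from <= tab$state_to)) {
      stop("emission rows require state_from > state_to (row ",
           which(em & tab$state_from <= tab$state_to)[1], ")", call. = FALSE)
    }
    ab <- tab$kind == "absorption"
    if (any(ab & tab$state_from >= tab$state_to)) {
      stop("absorption rows require state_from < state_to (row ",
           which(ab & tab$state_from >= tab$state_to)[1], ")", call. = FALSE)
    }
    key <- paste(tab$molecule_id, tab$kind, tab$state_from, tab$state_to,
                 tab$method, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (molecule_id, kind, state_from, state_to, method) at row ",
           anyDuplicated(key), call. = FALSE)
    }
  }
  class(tab) <- c("transition_table", "data.frame")
  tab
}

#' Read a transition table from CSV
#'
#' Expects the canonical header
#' `molecule_id,kind,state_from,state_to,wavelength_nm,oscillator_strength,method`
#' (UTF-8, comma separated, "." decimal). Empty `oscillator_strength` cells
#' become `NA`, mirroring the "/" of printed experimental rows.
#'
#' @param path Path to a CSV file.
#' @return A `transition_table`.
#' @export
read_transitions_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(.transition_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(transition_table())
  num <- function(x) suppressWarnings(as.numeric(x))
  wl <- num(raw$wavelength_nm)
  if (anyNA(wl) || any(wl <= 0)) {
    bad <- which(is.na(wl) | wl <= 0)[1]
    stop("unparsable or non-positive wavelength at data line ", bad,
         " of ", path, call. = FALSE)
  }
  f_raw <- trimws(raw$oscillator_strength)
  f <- ifelse(f_raw == "" | f_raw == "/", NA_character_, f_raw)
  f_num <- num(f)
  if (any(!is.na(f) & is.na(f_num))) {
    stop("unparsable oscillator strength at data line ",
         which(!is.na(f) & is.na(f_num))[1], " of ", path, call. = FALSE)
  }
  if (any(!is.na(f_num) & f_num < 0)) {
    stop("negative oscillator strength at data line ",
         which(!is.na(f_num) & f_num < 0)[1], " of ", path, call. = FALSE)
  }
  transition_table(
    molecule_id = trimws(raw$molecule_id),
    kind = trimws(raw$kind),
    state_from = num(raw$state_from),
    state_to = num(raw$state_to),
    wavelength_nm = wl,
    oscillator_strength = f_num,
    method = trimws(raw$method)
  )
}

#' Write a transition table to CSV
#'
#' Inverse of [read_transitions_csv()]: a round trip reproduces the table
#' field-for-field. Missing oscillator strengths are written as empty cells.
#'
#' @param tab A `transition_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transitions_csv <- function(tab, path) {
  tab <- validate_transition_table(tab)
  out <- as.data.frame(tab)
  # print full precision; empty cell (not "0", not "NA") for absent f
  out$wavelength_nm <- format(out$wavelength_nm, digits = 15, trim = TRUE)
  f <- out$oscillator_strength
  out$oscillator_strength <- ifelse(is.na(f), "",
                                    format(f, digits = 15, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Parse an excited-state summary block from quantum-chemistry output text
#'
#' Best-effort convenience reader for plain-text excerpts of excited-state
#' output. It scans for lines carrying a state index, a wavelength in nm and
#' an oscillator strength, tolerating unrelated leading/trailing text. Two
#' line dialects are recognized:
#' \itemize{
#'   \item tabular rows of the form
#'     `<state> <energy?> <wavelength_nm> <fosc> ...` where the wavelength
#'     and oscillator strength are the last two numeric fields used;
#'   \item labelled lines such as
#'     `STATE 1: ... 450.0 nm  f= 1.200`.
#' }
#' All parsed states become absorption transitions from the ground state
#' (`state_from = 0`).
#'
#' @param text A character scalar (or vector of lines) of output text.
#' @param molecule_id Label to assign to the parsed transitions.
#' @param method Method label recorded for the parsed rows.
#' @return A `transition_table` of absorption transitions.
#' @export
parse_qm_excited_states <- function(text, molecule_id = "molecule",
                                    method = "qm_output") {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  states <- integer(); wl <- numeric(); f <- numeric()
  # dialect 1: "STATE <i>" ... "<x> nm" ... "f= <y>" on one line
  pat_lab <- "STATE\\s+([0-9]+).*?([0-9]*\\.?[0-9]+)\\s*nm.*?f\\s*=\\s*([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)"
  # dialect 2: bare table row "<i> <wavelength> <fosc>" or with extra columns
  pat_row <- "^[[:space:]]*([0-9]+)[[:space:]]+([-0-9.eE+[:space:]]+)$"
  for (ln in lines) {
    m <- regmatches(ln, regexec(pat_lab, ln))[[1]]
    if (length(m) >= 4) {
      states <- c(states, as.integer(m[2]))
      wl <- c(wl, as.numeric(m[3]))
      f <- c(f, as.numeric(m[4]))
      next
    }
    m <- regmatches(ln, regexec(pat_row, ln))[[1]]
    if (length(m) >= 3) {
      nums <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      nums <- nums[!is.na(nums)]
      if (length(nums) >= 2) {
        states <- c(states, as.integer(m[2]))
        wl <- c(wl, nums[length(nums) - 1])
        f <- c(f, nums[length(nums)])
      }
    }
  }
  if (length(states) == 0) {
    stop("no recognizable excited-state block found", call. = FALSE)
  }
  if (any(wl <= 0)) {
    stop("parsed state with non-positive wavelength", call. = FALSE)
  }
  if (any(f < 0)) {
    stop("parsed state with negative oscillator strength", call. = FALSE)
  }
  transition_table(
    molecule_id = rep(molecule_id, length(states)),
    kind = rep("absorption", length(states)),
    state_from = rep(0L, length(states)),
    state_to = states,
    wavelength_nm = wl,
    oscillator_strength = f,
    method = rep(method, length(states))
  )
}

#' @export
print.transition_table <- function(x, ...) {
  cat("Electronic transition table:", nrow(x), "transition(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}
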