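# File formats and run configuration.

#' Run configuration
#'
#' Collects the tunable knobs of a calculation. `ScreeningR` follows the
#' convention of setting `2*alpha` in Angstrom (default 30.0, a conservative
#' cutoff); the Gaussian damping of the two-electron integrals sets in at
#' `c_cut` bohr (default 10.0). The configuration is validated: the
#' screening must engage beyond the damping onset.
#'
#' @param hamiltonian `"AM1"` or `"MNDO"`.
#' @param screening_r `ScreeningR` keyword: `2*alpha`, Angstrom.
#' @param c_cut damping onset, bohr.
#' @param tol_p SCF convergence threshold on max |dP|.
#' @param tol_e SCF convergence threshold on |dE|, eV.
#' @param max_iter maximum SCF iterations.
#' @param damping density damping factor for the first `damp_iters`
#'   iterations.
#' @param damp_iters number of damped start-up iterations before DIIS.
#' @param diis_size depth of the DIIS history.
#' @param convention damping convention, see [gamma_damped].
#' @param verbose emit per-iteration log lines?
#' @return a named list of class `run_config`.
#' @export
run_config <- function(hamiltonian = "AM1", screening_r = 30.0,
                       c_cut = 10.0, tol_p = 1e-6, tol_e = 1e-6,
                       max_iter = 200L, damping = 0.5, damp_iters = 5L,
                       diis_size = 8L,
                       convention = c("exponent-sum", "product-squared"),
                       verbose = FALSE) {
  convention <- match.arg(convention)
  hamiltonian <- toupper(hamiltonian)
  if (!hamiltonian %in% c("AM1", "MNDO")) {
    stop("hamiltonian must be AM1 or MNDO", call. = FALSE)
  }
  if (screening_r <= 0) stop("ScreeningR must be positive", call. = FALSE)
  if (c_cut <= 0) stop("c_cut must be positive", call. = FALSE)
  if (angstrom_to_bohr(screening_r / 2) <= c_cut) {
    stop("ScreeningR/2 (in bohr) must exceed c_cut: screening must engage ",
         "beyond the damping onset", call. = FALSE)
  }
  structure(list(hamiltonian = hamiltonian, screening_r = screening_r,
                 c_cut = c_cut, tol_p = tol_p, tol_e = tol_e,
                 max_iter = as.integer(max_iter), damping = damping,
                 damp_iters = as.integer(damp_iters),
                 diis_size = as.integer(diis_size),
                 convention = convention, verbose = verbose),
            class = "run_config")
}

.config_keywords <- c("Hamiltonian", "ScreeningR", "CCut", "TolP", "TolE",
                      "MaxIter", "Damping", "DampIters", "DiisSize",
                      "Convention", "Verbose")

#' Parse a keyword configuration file
#'
#' Plain-text `keyword value` lines (case-insensitive keywords, `#`
#' comments). Recognized keywords: `Hamiltonian`, `ScreeningR` (sets
#' `2*alpha` in Angstrom), `CCut` (bohr), `TolP`, `TolE`, `MaxIter`,
#' `Damping`, `DampIters`, `DiisSize`, `Convention`, `Verbose`. Named
#' arguments in `...` override values from the file.
#'
#' @param path path to a config file, or `NULL` for defaults only.
#' @param ... overrides, named as [run_config] arguments.
#' @return a [run_config].
#' @examples
#' cfg <- parse_config(NULL, screening_r = 20)
#' cfg$screening_r / 2    # alpha = 10 Angstrom
#' @export
parse_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "[= \t]+")[[1]]
      if (length(parts) != 2L) {
        stop("malformed config line: '", ln, "'", call. = FALSE)
      }
      key <- .config_keywords[match(tolower(parts[1]),
                                    tolower(.config_keywords))]
      if (is.na(key)) {
        stop("unknown keyword '", parts[1], "'; valid keywords: ",
             paste(.config_keywords, collapse = ", "), call. = FALSE)
      }
      arg <- switch(key, Hamiltonian = "hamiltonian",
                    ScreeningR = "screening_r", CCut = "c_cut",
                    TolP = "tol_p", TolE = "tol_e", MaxIter = "max_iter",
                    Damping = "damping", DampIters = "damp_iters",
                    DiisSize = "diis_size", Convention = "convention",
                    Verbose = "verbose")
      vals[[arg]] <- if (arg %in% c("hamiltonian", "convention")) {
        parts[2]
      } else if (arg == "verbose") {
        toupper(parts[2]) %in% c("TRUE", "T", "1", "YES")
      } else {
        as.numeric(parts[2])
      }
    }
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides   # flags win over the file
  do.call(run_config, vals)
}

#' Read an extended-XYZ structure
#'
#' Standard XYZ with an optional `Lattice="..."` record on the comment line
#' holding 3, 6, or 9 numbers (row-wise lattice vectors for 1-, 2-, or
#' 3-dimensional periodicity) and an optional `Charge=n` record. Element
#' symbols are case-normalized.
#'
#' @param path file path.
#' @return a [cell].
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("malformed atom-count line in ", path, call. = FALSE)
  }
  if (length(lines) < n + 2L) stop("truncated XYZ file", call. = FALSE)
  comment <- lines[2]
  lattice <- NULL
  m <- regmatches(comment,
                  regexpr('Lattice="([^"]*)"', comment, ignore.case = TRUE))
  if (length(m) == 1L) {
    nums <- as.numeric(strsplit(trimws(sub('.*Lattice="([^"]*)".*', "\\1",
                                           m, ignore.case = TRUE)),
                                "[ \t]+")[[1]])
    if (!length(nums) %in% c(3L, 6L, 9L) || any(is.na(nums))) {
      stop("Lattice record must hold 3, 6 or 9 numbers", call. = FALSE)
    }
    lattice <- matrix(nums, ncol = 3L, byrow = TRUE)
  }
  charge <- 0L
  mc <- regmatches(comment,
                   regexpr("Charge=(-?[0-9]+)", comment, ignore.case = TRUE))
  if (length(mc) == 1L) {
    charge <- as.integer(sub(".*Charge=(-?[0-9]+).*", "\\1", mc,
                             ignore.case = TRUE))
  }
  at <- do.call(rbind, lapply(lines[3:(n + 2L)], function(ln) {
    strsplit(trimws(ln), "[ \t]+")[[1]][1:4]
  }))
  syms <- normalize_symbol(at[, 1])
  unknown <- setdiff(unique(syms), supported_elements())
  if (length(unknown) > 0L) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  coords <- matrix(as.numeric(at[, 2:4]), ncol = 3L)
  cell(syms, coords, lattice, charge)
}

#' Write an extended-XYZ structure
#'
#' Deterministic formatting: fixed field order, 10 decimal places, a
#' `Lattice` record if (and only if) the cell is periodic.
#'
#' @param cell a [cell].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(cell, path) {
  hdr <- 'Properties=species:S:1:pos:R:3'
  if (cell$pdim > 0L) {
    lat <- sprintf("%.10f", t(cell$lattice))
    hdr <- sprintf('Lattice="%s" %s', paste(lat, collapse = " "), hdr)
  }
  if (cell$charge != 0L) hdr <- sprintf("%s Charge=%d", hdr, cell$charge)
  xyz <- cell_coords(cell)
  body <- sprintf("%-2s %16.10f %16.10f %16.10f", cell$atoms$element,
                  xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(sprintf("%d", nrow(xyz)), hdr, body), path)
  invisible(path)
}
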