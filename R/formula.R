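#' Parse a molecular formula
#'
#' Parses a Hill-notation sum formula (e.g. `"C6H12O6"`) into a named vector
#' of element counts. Multi-digit counts and two-letter element symbols are
#' supported; unknown symbols are rejected with the offending position.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts (a `FormulaComposition`).
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string", call. = FALSE)
  comp <- integer(0)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    sym <- if (length(m)) m[2] else ""
    if (!nzchar(sym))
      stop(sprintf("formula parse error in '%s' at position %d ('%s')",
                   text, i, substr(text, i, i)), call. = FALSE)
    if (!sym %in% names(.element_masses)) {
      # a two-letter token may be a one-letter element followed by junk
      one <- substr(sym, 1, 1)
      if (nchar(sym) == 2L && one %in% names(.element_masses)) {
        stop(sprintf("formula parse error in '%s' at position %d ('%s')",
                     text, i + 1L, substr(sym, 2, 2)), call. = FALSE)
      }
      stop(sprintf("unknown element '%s' in '%s' at position %d",
                   sym, text, i), call. = FALSE)
    }
    count <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    comp[sym] <- (if (sym %in% names(comp)) comp[[sym]] else 0L) + count
    i <- i + nchar(m[1])
  }
  comp
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times the exact mass of the lightest isotope.
#'
#' @param comp Named integer vector as returned by [parse_formula()], or a
#'   formula string (parsed on the fly).
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")      # 18.010565
#' monoisotopic_mass("C6H12O6")  # 180.063388
#' @export
monoisotopic_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  if (length(comp) == 0L)
    stop("empty composition has no mass", call. = FALSE)
  unknown <- setdiff(names(comp), names(.element_masses))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(comp < 0)) stop("negative element count", call. = FALSE)
  sum(comp * .element_masses[names(comp)])
}

#' Theoretical m/z of an adduct ion
#'
#' Computes `(multimer * neutral_mass + delta_mass) / |charge|` for one adduct
#' definition (a row of [default_adducts()] or any list with fields
#' `multimer`, `delta_mass`, `charge`).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct Adduct definition (list or one-row data frame).
#' @return m/z in Da.
#' @examples
#' adduct_mz(180.063388, list(multimer = 1, delta_mass = 1.00727646, charge = 1))
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), neutral_mass > 0)
  adduct <- as.list(adduct)
  if (adduct$charge == 0) stop("adduct charge must be nonzero", call. = FALSE)
  (adduct$multimer * neutral_mass + adduct$delta_mass) / abs(adduct$charge)
}

#' Signed relative mass error in parts per million
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da, > 0).
#' @return Signed ppm error `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}
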