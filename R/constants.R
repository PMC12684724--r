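# Physical constants used throughout: monoisotopic masses of the lightest
# isotope of each supported element (IUPAC/CODATA), ion mass deltas for the
# default adduct set, and tracer isotope mass differences / natural heavy
# fractions. Electron mass is neglected in adduct arithmetic (< 0.5 mDa,
# below every tolerance used here); the proton mass constant is used directly.

.element_masses <- c(
  H  = 1.0078250319, C  = 12.0000000000, N  = 14.0030740052,
  O  = 15.9949146221, P = 30.97376151,  S  = 31.97207069,
  Na = 22.98976928,  K  = 38.96370649,  Cl = 34.96885271,
  F  = 18.99840322,  Br = 78.9183376,   I  = 126.904473,
  Si = 27.9769265327, Se = 73.9224766,  B  = 11.0093055,
  Fe = 55.9349421,   Mg = 23.9850417,   Ca = 39.96259098,
  Zn = 63.9291422,   Cu = 62.9295975,   Mn = 54.9380451,
  Co = 58.9331950,   Ni = 57.9353429,   Mo = 97.9054082
)

.proton_mass <- 1.00727646

# Heavy-minus-light isotope mass differences (Da per incorporated heavy atom)
# and natural heavy-isotope abundances for the supported tracers.
.tracer_table <- data.frame(
  name             = c("13C", "15N", "2H"),
  element          = c("C", "N", "H"),
  delta_mass       = c(1.0033548, 0.9970349, 1.0062767),
  natural_fraction = c(0.0107, 0.00364, 0.000115),
  stringsAsFactors = FALSE
)

#' Tracer definition
#'
#' Look up a stable-isotope tracer by name. A tracer is described by the
#' element it replaces, the exact mass difference per incorporated heavy atom,
#' and the natural abundance of the heavy isotope (used by the simulator and
#' the optional natural-tail filter allowance).
#'
#' @param name One of `"13C"`, `"15N"`, `"2H"`.
#' @return A list with elements `name`, `element`, `delta_mass` (Da) and
#'   `natural_fraction`.
#' @examples
#' tracer_def("13C")$delta_mass  # 1.0033548
#' @export
tracer_def <- function(name) {
  i <- match(name, .tracer_table$name)
  if (is.na(i)) {
    stop("unknown tracer '", name, "'; supported: ",
         paste(.tracer_table$name, collapse = ", "), call. = FALSE)
  }
  as.list(.tracer_table[i, ])
}

#' Default adduct set
#'
#' The adduct definitions used by [annotate_ms1()] when none are supplied.
#' Each row gives the adduct name, the multimer count n (for `[nM+X]`), the
#' signed mass delta in Da and the charge. The set is deliberately small and
#' user-replaceable: pass any data frame with the same columns.
#'
#' @return A data frame with columns `name`, `multimer`, `delta_mass`,
#'   `charge`.
#' @export
default_adducts <- function() {
  data.frame(
    name       = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M-H]-", "[M+Cl]-",
                   "[2M+H]+", "[M+2H]2+"),
    multimer   = c(1L, 1L, 1L, 1L, 1L, 2L, 1L),
    delta_mass = c(1.00727646, 22.98922070, 18.03382555, -1.00727646,
                   34.96940129, 1.00727646, 2.01455292),
    charge     = c(1L, 1L, 1L, -1L, -1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}
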