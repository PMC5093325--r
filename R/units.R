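#' Round half away from zero
#'
#' Base R's `round()` rounds half to even. Reported concentrations and rates
#' in this package follow the convention of rounding halves up (away from
#' zero), applied only at presentation boundaries, never inside computations.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.345, 2) # 2.35
#' round_half_up(-2.345, 2) # -2.35
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  # nudge by a relative epsilon so values like 2.345 stored as 2.34499...99
  # still round as their printed decimal form
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9 * abs(x) * p) / p
}

#' Define a compound by its molar mass
#'
#' A compound is the unit-conversion anchor between mass (mg/ml) and molar
#' (mM) concentrations. Built-ins are provided for the two dipeptides the
#' package models: `"FF"` (diphenylalanine, 312.4 g/mol, assembles into
#' nanotubes in water) and `"cycloFF"` (cyclo-(Phe-Phe), 294.3 g/mol,
#' needle-like assemblies in DMSO). Any other compound can be defined by
#' supplying `molar_mass_g_mol`.
#'
#' @param name Short label. `"FF"` and `"cycloFF"` (case-insensitive) resolve
#'   to built-in molar masses unless `molar_mass_g_mol` is given.
#' @param molar_mass_g_mol Molar mass in g/mol; strictly positive. Optional
#'   for the built-ins.
#' @return An object of class `"compound"`: a list with `name` and
#'   `molar_mass_g_mol`.
#' @examples
#' compound("FF")
#' compound("glycine", molar_mass_g_mol = 75.07)
#' @export
compound <- function(name, molar_mass_g_mol = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  builtins <- c(ff = 312.4, cycloff = 294.3)
  if (is.null(molar_mass_g_mol)) {
    key <- tolower(name)
    if (!key %in% names(builtins)) {
      stop("no built-in molar mass for '", name,
           "'; supply molar_mass_g_mol", call. = FALSE)
    }
    molar_mass_g_mol <- unname(builtins[[key]])
  }
  stopifnot(is.numeric(molar_mass_g_mol), length(molar_mass_g_mol) == 1)
  if (!is.finite(molar_mass_g_mol) || molar_mass_g_mol <= 0) {
    stop("molar_mass_g_mol must be finite and > 0", call. = FALSE)
  }
  structure(list(name = name, molar_mass_g_mol = molar_mass_g_mol),
            class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s (%.1f g/mol)\n", x$name, x$molar_mass_g_mol))
  invisible(x)
}

as_compound <- function(x) {
  if (inherits(x, "compound")) return(x)
  if (is.character(x) && length(x) == 1) return(compound(x))
  stop("expected a compound object or a compound name", call. = FALSE)
}

#' Convert between mass and molar concentration
#'
#' `to_millimolar()` converts mg/ml to mM; `to_mass_concentration()` is its
#' exact inverse (mM to mg/ml). For FF (312.4 g/mol) the critical
#' concentration 0.76 mg/ml converts to 2.43 mM at the reporting precision of
#' two decimals. Values are returned unrounded; apply [round_half_up()] at
#' the reporting boundary.
#'
#' @param c_mass_mg_ml Mass concentration in mg/ml, non-negative.
#' @param c_mM Molar concentration in mM, non-negative.
#' @param compound A [compound()] object or built-in compound name.
#' @return Numeric vector of converted concentrations (unrounded).
#' @examples
#' round_half_up(to_millimolar(0.76, "FF"), 2) # 2.43
#' round_half_up(to_mass_concentration(3.20, "FF"), 2) # 1.00
#' @export
to_millimolar <- function(c_mass_mg_ml, compound) {
  compound <- as_compound(compound)
  stopifnot(is.numeric(c_mass_mg_ml))
  if (any(!is.finite(c_mass_mg_ml)) || any(c_mass_mg_ml < 0)) {
    stop("mass concentration must be finite and >= 0", call. = FALSE)
  }
  c_mass_mg_ml / compound$molar_mass_g_mol * 1000
}

#' @rdname to_millimolar
#' @export
to_mass_concentration <- function(c_mM, compound) {
  compound <- as_compound(compound)
  stopifnot(is.numeric(c_mM))
  if (any(!is.finite(c_mM)) || any(c_mM < 0)) {
    stop("molar concentration must be finite and >= 0", call. = FALSE)
  }
  c_mM * compound$molar_mass_g_mol / 1000
}
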