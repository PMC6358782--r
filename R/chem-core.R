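# Monoisotopic mass arithmetic: formula parsing, adduct m/z, mass errors.
# All masses in Da; mass errors in mDa unless stated otherwise.

.PROTON_MASS <- 1.007276
.ELECTRON_MASS <- 0.000549

#' Monoisotopic element mass table
#'
#' Monoisotopic (most-abundant-isotope) atomic masses used for all mass
#' arithmetic in the package, fixed to IUPAC/CODATA values so results do not
#' depend on an external atomic-mass table.
#'
#' @return Named numeric vector of monoisotopic masses in Da, plus attributes
#'   `proton` and `electron` (Da).
#' @examples
#' element_masses()[["O"]]
#' @export
element_masses <- function() {
  m <- c(
    H  = 1.007825,
    C  = 12.000000,
    N  = 14.003074,
    O  = 15.994915,
    Na = 22.989770,
    K  = 38.963707
  )
  attr(m, "proton") <- .PROTON_MASS
  attr(m, "electron") <- .ELECTRON_MASS
  m
}

#' Supported positive-mode adducts
#'
#' Cation masses for the singly charged adducts observed in positive-mode
#' ESI of artemisinin-type compounds: `[M+H]+`, `[M+Na]+`, `[M+K]+`.
#' The cation mass already accounts for the electron removed on ionisation
#' (proton mass for H; atomic mass minus one electron mass for Na and K).
#'
#' @param masses element mass table, see [element_masses()].
#' @return Named numeric vector mapping adduct kind (`"M+H"`, `"M+Na"`,
#'   `"M+K"`) to the cation mass added to the neutral monoisotopic mass.
#' @export
default_adducts <- function(masses = element_masses()) {
  c(
    "M+H"  = attr(masses, "proton"),
    "M+Na" = unname(masses[["Na"]] - attr(masses, "electron")),
    "M+K"  = unname(masses[["K"]] - attr(masses, "electron"))
  )
}

#' Parse a molecular formula string
#'
#' Accepts plain Hill-style strings (`"C15H22O5"`) and the underscore dialect
#' used in the source table (`"C_15_H_22_O_5_"`). The result is canonical:
#' element counts are merged, zero counts dropped, and elements ordered in
#' Hill convention (C, H, then alphabetical), so two formulas are equal iff
#' their canonical vectors are identical.
#'
#' @param text formula string; `""` yields the empty formula.
#' @param masses element mass table; parsing fails on symbols it lacks.
#' @return Named integer vector of element counts with class `chem_formula`.
#' @examples
#' parse_formula("C15H22O5")
#' parse_formula("C_15_H_22_O_6_")
#' @export
parse_formula <- function(text, masses = element_masses()) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("_", "", trimws(text))
  counts <- numeric(0)
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    rest <- substr(s, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      stop(sprintf("malformed formula '%s': unexpected character at position %d",
                   text, pos), call. = FALSE)
    }
    sym <- m[2]
    if (!sym %in% names(masses)) {
      stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text),
           call. = FALSE)
    }
    k <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
    pos <- pos + nchar(m[1])
  }
  chem_formula(counts)
}

#' Construct a canonical chemical formula
#'
#' @param counts named numeric vector, element symbol -> non-negative count.
#' @return Canonical `chem_formula` (zero counts dropped, Hill order).
#' @export
chem_formula <- function(counts = numeric(0)) {
  if (length(counts)) {
    stopifnot(!is.null(names(counts)), all(nzchar(names(counts))))
    if (any(counts < 0)) {
      stop("negative element count in formula", call. = FALSE)
    }
    counts <- tapply(counts, names(counts), sum)  # merge duplicates
    counts <- counts[counts > 0]
    counts <- counts[.hill_order(names(counts))]
  }
  out <- as.integer(counts)
  names(out) <- names(counts)
  class(out) <- "chem_formula"
  out
}

.hill_order <- function(syms) {
  rank <- match(syms, c("C", "H"))
  order(ifelse(is.na(rank), 3L, rank), syms)
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", write_formula(x), "\n")
  invisible(x)
}

.as_formula <- function(f, masses = element_masses()) {
  if (inherits(f, "chem_formula")) f else parse_formula(f, masses)
}

#' Write a formula back to Hill-style text
#'
#' Inverse of [parse_formula()]: `parse_formula(write_formula(f))` equals `f`.
#'
#' @param f a `chem_formula` or formula string.
#' @return Single string, e.g. `"C15H22O5"`; empty formula gives `""`.
#' @export
write_formula <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' Neutral monoisotopic mass of a formula
#'
#' @inheritParams write_formula
#' @param masses element mass table, see [element_masses()].
#' @return Mass in Da. Additive: the mass of a merged formula is the sum of
#'   the parts' masses.
#' @examples
#' formula_mass("C15H22O5") # 282.1467
#' @export
formula_mass <- function(f, masses = element_masses()) {
  f <- .as_formula(f, masses)
  if (!length(f)) return(0)
  missing <- setdiff(names(f), names(masses))
  if (length(missing)) {
    stop(sprintf("no monoisotopic mass for element(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sum(unclass(f) * masses[names(f)])
}

#' Theoretical m/z of a singly charged adduct ion
#'
#' m/z of `[M+H]+`, `[M+Na]+` or `[M+K]+` for a neutral formula: neutral
#' monoisotopic mass plus the cation mass (electron mass already subtracted,
#' since the observed species carries +1 charge). Only +1 ions are supported;
#' for a fixed formula `M+H < M+Na < M+K`.
#'
#' @inheritParams formula_mass
#' @param ion adduct kind, one of `names(adducts)`.
#' @param adducts named cation-mass vector, see [default_adducts()].
#' @return Theoretical m/z in Th.
#' @examples
#' ion_mz("C15H22O5", "M+H") # 283.1540
#' @export
ion_mz <- function(f, ion, adducts = default_adducts(),
                   masses = element_masses()) {
  stopifnot(is.character(ion), length(ion) == 1L)
  if (!ion %in% names(adducts)) {
    stop(sprintf("unsupported adduct '%s'; supported: %s", ion,
                 paste(names(adducts), collapse = ", ")), call. = FALSE)
  }
  formula_mass(f, masses) + adducts[[ion]]
}

#' Mass error in mDa
#'
#' Signed accurate-mass error `(observed - theoretical) * 1000`, the
#' identification statistic of accurate-mass metabolite screening
#' (tolerance +/-2 mDa by default throughout the package).
#'
#' @param observed,theoretical m/z values (Th); vectorised.
#' @return Signed error in mDa (unrounded; see [round_mda()] for reporting).
#' @export
mass_error_mda <- function(observed, theoretical) {
  stopifnot(all(observed > 0), all(theoretical > 0))
  (observed - theoretical) * 1000
}

#' Round a mass error for reporting
#'
#' One-decimal rounding with halves away from zero, preserving sign — the
#' convention used when printing mDa errors (e.g. -0.45 -> -0.5), which
#' differs from [round()]'s round-half-even.
#'
#' @param x numeric vector (mDa).
#' @param digits decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_mda <- function(x, digits = 1) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Apply a signed element-count delta to a formula
#'
#' The elementary biotransformation step: e.g. hydroxylation is `c(O = 1)`,
#' deoxygenation `c(O = -1)`, carbonyl reduction `c(H = 2)`. Mass additivity
#' holds exactly: the mass changes by the signed mass of the delta.
#'
#' @inheritParams write_formula
#' @param delta named numeric vector of signed element-count changes.
#' @return New `chem_formula`.
#' @examples
#' apply_formula_delta("C15H22O5", c(O = 1))  # C15H22O6
#' @export
apply_formula_delta <- function(f, delta) {
  f <- .as_formula(f)
  counts <- as.numeric(f)
  names(counts) <- names(f)
  for (sym in names(delta)) {
    counts[sym] <- (if (sym %in% names(counts) && !is.na(counts[sym]))
      counts[[sym]] else 0) + delta[[sym]]
  }
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) {
    bad <- names(counts)[counts < 0]
    stop(sprintf("infeasible transformation: negative count for %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  chem_formula(counts)
}

#' Split a "formula + adduct" string into its parts
#'
#' Parses strings such as `"C_15_H_22_O_6_ + Na^+^"` or `"C15H22O5 + H+"`
#' (the style of the source table's Formula column) into a neutral formula
#' and an adduct kind.
#'
#' @param text formula-plus-adduct string.
#' @return List with elements `formula` (`chem_formula`) and `ion`
#'   (`"M+H"`, `"M+Na"` or `"M+K"`).
#' @export
parse_ion_notation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "+", fixed = TRUE)[[1]]
  parts <- trimws(gsub("\\^", "", parts))
  parts <- parts[nzchar(parts)]
  if (length(parts) != 2L) {
    stop(sprintf("cannot split '%s' into formula and adduct", text),
         call. = FALSE)
  }
  if (!parts[2] %in% c("H", "Na", "K")) {
    stop(sprintf("unrecognised adduct cation '%s' in '%s'", parts[2], text),
         call. = FALSE)
  }
  list(formula = parse_formula(parts[1]), ion = paste0("M+", parts[2]))
}
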