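#' @keywords internal
"_PACKAGE"

# Monoisotopic atomic masses (IUPAC/CODATA), Da.
.element_masses <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928
)

.PROTON_MASS   <- 1.00727646
.ELECTRON_MASS <- 0.00054858

#' Create an elemental composition
#'
#' A composition is a named integer vector of element counts (class
#' `elem_comp`). Only the elements needed for archaeal lipid chemistry are
#' supported: C, H, N, O, P, S, Na.
#'
#' @param ... element counts, e.g. `comp(C = 43, H = 88, O = 3)`.
#' @return an `elem_comp` object.
#' @export
#' @examples
#' comp(H = 2, O = 1)
comp <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- integer(0)
  as_comp(x)
}

#' Coerce a named numeric vector to a composition
#'
#' @param x named vector of non-negative integer counts.
#' @return an `elem_comp` object covering all supported elements.
#' @export
as_comp <- function(x) {
  if (inherits(x, "elem_comp")) return(x)
  if (length(x) > 0) {
    bad <- setdiff(names(x), names(.element_masses))
    if (length(bad) > 0) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    }
    if (any(x < 0)) stop("element counts must be non-negative")
    if (any(x != round(x))) stop("element counts must be integers")
  }
  out <- stats::setNames(integer(length(.element_masses)),
                         names(.element_masses))
  out[names(x)] <- as.integer(x)
  class(out) <- "elem_comp"
  out
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style strings such as `"C43H88O3"` or `"C3H9O6P"`. Two-letter
#' symbols (Na) are recognised before one-letter symbols.
#'
#' @param formula a single formula string; `""` parses to the empty
#'   composition.
#' @return an `elem_comp` object.
#' @export
#' @examples
#' comp_parse("C43H88O3")
comp_parse <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (formula == "" || is.na(formula)) return(as_comp(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    stop("cannot parse formula: ", formula)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (n == "") 1L else as.integer(n)
    if (!sym %in% names(.element_masses)) {
      stop("unknown element symbol: ", sym)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  as_comp(counts)
}

#' Format a composition as a Hill-order formula string
#'
#' @param x an `elem_comp`.
#' @return formula string (C first, then H, then other elements
#'   alphabetically); empty composition formats as `""`.
#' @export
comp_format <- function(x) {
  x <- as_comp(x)
  ord <- c("C", "H", sort(setdiff(names(.element_masses), c("C", "H"))))
  parts <- vapply(ord, function(el) {
    n <- x[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste(parts, collapse = "")
}

#' Element-wise composition arithmetic
#'
#' `comp_add()` adds counts; `comp_sub()` subtracts and errors if any count
#' would go negative (compositions cannot contain negative atoms).
#'
#' @param a,b compositions (or formula strings).
#' @return an `elem_comp`.
#' @export
comp_add <- function(a, b) {
  a <- .as_comp_any(a); b <- .as_comp_any(b)
  out <- unclass(a) + unclass(b)
  class(out) <- "elem_comp"
  out
}

#' @rdname comp_add
#' @export
comp_sub <- function(a, b) {
  a <- .as_comp_any(a); b <- .as_comp_any(b)
  out <- unclass(a) - unclass(b)
  if (any(out < 0)) {
    neg <- names(out)[out < 0]
    stop("subtraction yields negative count for: ",
         paste(neg, collapse = ", "))
  }
  class(out) <- "elem_comp"
  out
}

.as_comp_any <- function(x) {
  if (is.character(x)) comp_parse(x) else as_comp(x)
}

#' Monoisotopic mass of a composition
#'
#' @param x an `elem_comp`, named count vector, or formula string.
#' @return monoisotopic mass in Da (0 for the empty composition).
#' @export
#' @examples
#' monoisotopic_mass("C43H88O3") # archaeol, 652.6733
monoisotopic_mass <- function(x) {
  x <- .as_comp_any(x)
  sum(unclass(x) * .element_masses[names(x)])
}

# neutral adduct part added to M (carrier charge handled separately)
.adduct_neutral <- c("[M+H]+" = 0, "[M+NH4]+" = NA, "[M+Na]+" = NA)

#' Adduct m/z from a neutral mass
#'
#' Computes singly charged positive-mode adduct m/z. Two charge-carrier
#' conventions are supported: `"proton"` uses the true carrier ion masses
#' (proton 1.007276 Da, Na+ = Na - e-), while `"hydrogen_atom"` uses neutral
#' atom masses and neglects the electron, the convention many instrument
#' vendors print (e.g. leucine enkephalin [M+H]+ = 556.2771).
#'
#' @param neutral_mass neutral monoisotopic mass, Da (> 0).
#' @param adduct one of `"[M+H]+"`, `"[M+NH4]+"`, `"[M+Na]+"`.
#' @param convention `"proton"` or `"hydrogen_atom"`.
#' @return m/z of the singly charged ion.
#' @export
#' @examples
#' adduct_mz(monoisotopic_mass("C28H37N5O7"), "[M+H]+", "hydrogen_atom")
adduct_mz <- function(neutral_mass, adduct,
                      convention = c("proton", "hydrogen_atom")) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  convention <- match.arg(convention)
  neutral_mass + adduct_delta(adduct, convention)
}

#' @rdname adduct_mz
#' @export
adduct_delta <- function(adduct, convention = c("proton", "hydrogen_atom")) {
  convention <- match.arg(convention)
  h_atom <- .element_masses[["H"]]
  carrier_h <- if (convention == "proton") .PROTON_MASS else h_atom
  carrier_na <- if (convention == "proton") {
    .element_masses[["Na"]] - .ELECTRON_MASS
  } else {
    .element_masses[["Na"]]
  }
  nh3 <- monoisotopic_mass(comp(N = 1, H = 3))
  switch(adduct,
    "[M+H]+"   = carrier_h,
    "[M+NH4]+" = nh3 + carrier_h,
    "[M+Na]+"  = carrier_na,
    stop("unsupported adduct: ", adduct)
  )
}
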