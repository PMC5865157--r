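# Elemental-formula arithmetic and ion-transform m/z computation shared by
# every diagnostic-ion rule module. All masses are nominal (unit) masses of
# the most abundant isotope: the instruments modelled here are
# unit-resolution quadrupoles and every diagnostic m/z is an integer.

# Integer mass of the most abundant isotope per supported element.
.ELEMENT_MASSES <- c(
  C = 12L, H = 1L, N = 14L, O = 16L, S = 32L,
  P = 31L, F = 19L, Cl = 35L, Si = 28L, Br = 79L, I = 127L
)

#' Parse a Hill-style elemental formula
#'
#' Reads a plain elemental formula such as `"C2H4O2"` into a named integer
#' vector of element counts. Multi-digit counts and two-letter element
#' symbols are supported; parentheses, charges and isotope labels are not
#' (breath VOCs are small neutral molecules).
#'
#' @param formula Single string, e.g. `"C6H5"` or `"C2H7NO2"`.
#' @return Named integer vector of class `"element_counts"`; names are
#'   element symbols, values are counts (all `>= 1`).
#' @examples
#' parse_formula("C2H4O2")
#' nominal_mass(parse_formula("C6H5"))
#' @seealso [nominal_mass()], [format_formula()]
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(trimws(formula))) {
    stop("'formula' must be a single non-empty string", call. = FALSE)
  }
  rest <- trimws(formula)
  counts <- integer(0)
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1L])) {
      stop(sprintf("cannot parse formula '%s': unexpected token at '%s'",
                   formula, rest), call. = FALSE)
    }
    el <- m[2L]
    if (!el %in% names(.ELEMENT_MASSES)) {
      stop(sprintf("unknown element symbol '%s' in formula '%s'", el, formula),
           call. = FALSE)
    }
    n <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
    rest <- substr(rest, nchar(m[1L]) + 1L, nchar(rest))
  }
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) {
    stop(sprintf("formula '%s' contains no atoms", formula), call. = FALSE)
  }
  structure(counts, class = "element_counts")
}

#' Format element counts as a Hill-order formula string
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return Single string: carbon first, hydrogen second, remaining elements
#'   alphabetical.
#' @export
format_formula <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(el) {
    n <- counts[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1L)), collapse = "")
}

#' Nominal molecular mass
#'
#' Sum of element counts times the integer mass of each element's most
#' abundant isotope (C = 12, H = 1, N = 14, O = 16, S = 32). The electron
#' mass is ignored: it is irrelevant at unit resolution.
#'
#' @param x A formula string or an `element_counts` vector.
#' @return Integer mass in Da.
#' @examples
#' nominal_mass("C6H5")   # 77, the phenyl cation
#' nominal_mass("C2H4O2") # 60, acetic acid
#' @export
nominal_mass <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  stopifnot(is.numeric(x), !is.null(names(x)))
  bad <- setdiff(names(x), names(.ELEMENT_MASSES))
  if (length(bad) > 0L) {
    stop(sprintf("unknown element symbol(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(x < 0)) stop("element counts must be non-negative", call. = FALSE)
  as.integer(sum(as.integer(x) * .ELEMENT_MASSES[names(x)]))
}

# Transform registry: label -> (scale on the molecular mass, Da offset).
# "M+H+nH2O" takes its offset from the hydrate count n; "2M+H" is the
# proton-bound dimer (scale 2).
.TRANSFORM_DELTAS <- list(
  "M"        = c(scale = 1, delta = 0),
  "M+H"      = c(scale = 1, delta = 1),
  "M-H"      = c(scale = 1, delta = -1),
  "M-17"     = c(scale = 1, delta = -17),
  "M-18"     = c(scale = 1, delta = -18),
  "M-29"     = c(scale = 1, delta = -29),
  "M-33"     = c(scale = 1, delta = -33),
  "M-73"     = c(scale = 1, delta = -73),
  "M+NO"     = c(scale = 1, delta = 30),
  "2M+H"     = c(scale = 2, delta = 1)
)

#' Construct an ion transform
#'
#' An ion transform maps a nominal molecular mass M to the m/z of a singly
#' charged diagnostic ion, `m/z = scale * M + delta`. Supported labels are
#' `"M"`, `"M+H"`, `"M-H"`, `"M-17"`, `"M-18"`, `"M-29"`, `"M-33"`,
#' `"M-73"`, `"M+NO"` (nitrosonium adduct, +30), `"2M+H"` (proton-bound
#' dimer) and `"M+H+nH2O"` (protonated hydrate, `n` in 1..2).
#'
#' @param label Transform label.
#' @param n Hydrate count for `"M+H+nH2O"`; ignored otherwise.
#' @return List of class `"ion_transform"` with `label`, `scale`, `delta`.
#' @export
ion_transform <- function(label, n = 1L) {
  if (identical(label, "M+H+nH2O")) {
    if (!n %in% c(1L, 2L)) {
      stop("hydrate count n must be 1 or 2 for 'M+H+nH2O'", call. = FALSE)
    }
    out <- list(label = label, n = as.integer(n), scale = 1, delta = 1 + 18 * n)
  } else if (label %in% names(.TRANSFORM_DELTAS)) {
    sd <- .TRANSFORM_DELTAS[[label]]
    out <- list(label = label, n = NA_integer_,
                scale = sd[["scale"]], delta = sd[["delta"]])
  } else {
    stop(sprintf("unknown ion transform '%s' (supported: %s, M+H+nH2O)",
                 label, paste(names(.TRANSFORM_DELTAS), collapse = ", ")),
         call. = FALSE)
  }
  structure(out, class = "ion_transform")
}

#' Apply an ion transform to a nominal molecular mass
#'
#' @param molecular_mass Positive integer nominal mass in Da.
#' @param transform An `ion_transform` or a transform label string.
#' @param n Hydrate count when `transform` is the `"M+H+nH2O"` label.
#' @return Integer m/z (singly charged assumed, so m/z equals the mass).
#'   A transform that would yield a non-positive m/z (e.g. `"M-73"` on a
#'   molecule lighter than 74 Da) signals an error: the rule does not apply.
#' @examples
#' apply_transform(58, "M-29")            # 29, propanal HC=O loss
#' apply_transform(156, "2M+H")           # 313, 4-decanone dimer
#' apply_transform(60, "M+H+nH2O", n = 2) # 97, acetic acid second hydrate
#' @export
apply_transform <- function(molecular_mass, transform, n = 1L) {
  if (!is.numeric(molecular_mass) || length(molecular_mass) != 1L ||
      is.na(molecular_mass) || molecular_mass <= 0) {
    stop("'molecular_mass' must be a single positive number", call. = FALSE)
  }
  if (is.character(transform)) transform <- ion_transform(transform, n = n)
  stopifnot(inherits(transform, "ion_transform"))
  mz <- transform$scale * molecular_mass + transform$delta
  if (mz <= 0) {
    stop(sprintf(
      "transform '%s' does not apply to mass %s Da (non-positive m/z %s)",
      transform$label, molecular_mass, mz), call. = FALSE)
  }
  as.integer(mz)
}
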