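# Compound records: identity, elemental formula, chemical class and
# reference retention index (624-phase column) for one library compound.

#' Supported chemical classes
#'
#' The oxygenated-VOC classes for which diagnostic-ion rules exist:
#' ketones, saturated and unsaturated aldehydes, carboxylic acids, linear
#' primary alcohols, phenols, and other aromatics (benzaldehyde-type).
#' Substituted-benzene behaviour (the phenyl fragment at m/z 77) is carried
#' as a separate flag because it cuts across the phenol/aromatic split.
#'
#' @return Character vector of class names.
#' @export
voc_classes <- function() {
  c("ketone", "aldehyde_saturated", "aldehyde_unsaturated", "acid",
    "alcohol_primary", "phenol", "aromatic")
}

#' Create a compound record
#'
#' @param name Compound name (unique within a library).
#' @param formula Hill-style elemental formula string.
#' @param chem_class One of [voc_classes()].
#' @param carbon_count Optional; defaults to the formula's carbon count and
#'   must agree with it when given.
#' @param reference_ri Reference retention index on the 624-phase column
#'   (unitless; `NA` when unknown).
#' @param proton_affinity Optional proton affinity in kJ/mol.
#' @param aromatic_substituted Logical; `TRUE` for substituted-benzene
#'   compounds (methylphenol, ethylphenol, benzaldehyde) that show the
#'   phenyl fragment at m/z 77 under EI.
#' @return List of class `"compound_record"` with the validated fields plus
#'   `counts` (parsed formula) and `molecular_mass` (nominal Da).
#' @examples
#' propanal <- compound_record("propanal", "C3H6O", "aldehyde_saturated",
#'                             reference_ri = 489)
#' propanal$molecular_mass
#' @export
compound_record <- function(name, formula, chem_class,
                            carbon_count = NULL,
                            reference_ri = NA_real_,
                            proton_affinity = NA_real_,
                            aromatic_substituted = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  chem_class <- match.arg(chem_class, voc_classes())
  counts <- parse_formula(formula)
  n_c <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (is.null(carbon_count) || is.na(carbon_count)) {
    carbon_count <- n_c
  } else if (as.integer(carbon_count) != n_c) {
    stop(sprintf("carbon_count %d inconsistent with formula '%s' (%d carbons)",
                 as.integer(carbon_count), formula, n_c), call. = FALSE)
  }
  if (!is.na(reference_ri) && reference_ri <= 0) {
    stop("reference_ri must be positive when present", call. = FALSE)
  }
  structure(list(
    name = name,
    formula = format_formula(counts),
    counts = counts,
    chem_class = chem_class,
    carbon_count = as.integer(carbon_count),
    molecular_mass = nominal_mass(counts),
    reference_ri = as.numeric(reference_ri),
    proton_affinity = as.numeric(proton_affinity),
    aromatic_substituted = isTRUE(aromatic_substituted)
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s (%s, M = %d Da, class %s%s, RI %s)\n",
              x$name, x$formula, x$molecular_mass, x$chem_class,
              if (x$aromatic_substituted) ", substituted benzene" else "",
              if (is.na(x$reference_ri)) "unknown" else
                format(x$reference_ri)))
  invisible(x)
}

# Coerce a compound library (list of records) element by name or position.
.as_compound_list <- function(compounds) {
  if (inherits(compounds, "compound_record")) return(list(compounds))
  stopifnot(is.list(compounds))
  lapply(compounds, function(x) {
    if (!inherits(x, "compound_record")) {
      stop("expected compound_record objects", call. = FALSE)
    }
    x
  })
}
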