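# Water-reagent positive-chemical-ionisation diagnostic ions.
#
# Water CI (proton affinity 697 kJ/mol) protonates analytes of higher PA
# with little excess energy, so [M+H]+ dominates for most classes; the
# exceptions are long-chain saturated aldehydes ([M-17]+ / [M-73]+ with a
# minor [M+H]+ below 30% relative intensity) and alcohols (hydride
# abstraction, with OH loss taking over above C3).

#' Reagent gas specification for chemical ionisation
#'
#' @param name Reagent name (e.g. `"water"`).
#' @param proton_affinity Proton affinity in kJ/mol (must be positive).
#' @param forms_dimers Logical; whether the reagent is prone to
#'   dimer/trimer adduct formation (methanol is, water is not).
#' @return List of class `"reagent_spec"`.
#' @export
reagent_spec <- function(name, proton_affinity, forms_dimers = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(proton_affinity) || proton_affinity <= 0) {
    stop("proton_affinity must be positive", call. = FALSE)
  }
  structure(list(name = name, proton_affinity = as.numeric(proton_affinity),
                 forms_dimers = isTRUE(forms_dimers)),
            class = "reagent_spec")
}

#' Shipped CI reagent table and the water reagent default
#'
#' The shipped table lists water (PA 697 kJ/mol), methane (PA 552) and
#' methanol (PA 761, dimer-forming).
#'
#' @param path Path to the reagent CSV.
#' @return `known_reagents()`: data.frame; `water_reagent()`: a
#'   [reagent_spec()] for water.
#' @export
known_reagents <- function(path = system.file("extdata", "reagents.csv",
                                              package = "breathvoc")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname known_reagents
#' @export
water_reagent <- function() reagent_spec("water", 697, forms_dimers = FALSE)

#' Is proton transfer from a reagent ion to an analyte favoured?
#'
#' Proton transfer is exothermic (favoured) when the analyte's proton
#' affinity strictly exceeds the reagent's.
#'
#' @param analyte_pa Analyte proton affinity in kJ/mol (`NA` allowed).
#' @param reagent A [reagent_spec()]; default water.
#' @return `TRUE`, `FALSE`, or `NA` when the analyte PA is unknown
#'   (indeterminate, never a silent default).
#' @examples
#' proton_transfer_favoured(761, water_reagent()) # methanol analyte: TRUE
#' proton_transfer_favoured(552, water_reagent()) # methane: FALSE
#' @export
proton_transfer_favoured <- function(analyte_pa, reagent = water_reagent()) {
  stopifnot(inherits(reagent, "reagent_spec"))
  ifelse(is.na(analyte_pa), NA, analyte_pa > reagent$proton_affinity)
}

#' Predict water-PCI diagnostic ions for a compound
#'
#' Only the water reagent is parameterised; any other reagent signals an
#' unsupported-reagent error. When `dimer_audit = TRUE` and the compound is
#' a ketone, an extra `2M+H` row with intensity class `"absent"` is emitted:
#' under water CI no ketone proton-bound dimer is observed, and the audit row
#' lets annotation verify that absence explicitly.
#'
#' @param compound A [compound_record()].
#' @param reagent A [reagent_spec()]; must be water.
#' @param rules Rule table; defaults to the shipped water-PCI table.
#' @param dimer_audit Logical; emit the ketone dimer-absence audit row.
#' @return data.frame in the same layout as [predict_ei_ions()], platform
#'   `"PCI"`.
#' @examples
#' acetic <- compound_record("acetic acid", "C2H4O2", "acid")
#' predict_pci_ions(acetic)  # [M+H]+ at m/z 61, base peak
#' @export
predict_pci_ions <- function(compound, reagent = water_reagent(),
                             rules = pci_rule_table(), dimer_audit = FALSE) {
  stopifnot(inherits(reagent, "reagent_spec"))
  if (!identical(reagent$name, "water")) {
    stop(sprintf("unsupported PCI reagent '%s': only water is parameterised",
                 reagent$name), call. = FALSE)
  }
  preds <- .predict_from_rules(compound, rules, "PCI")
  if (dimer_audit && identical(compound$chem_class, "ketone")) {
    dimer <- .prediction_row(
      "PCI", "2M+H", apply_transform(compound$molecular_mass, "2M+H"),
      "absent", "proton-bound dimer (not formed under water reagent)")
    preds <- rbind(preds, dimer)
  }
  preds
}
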