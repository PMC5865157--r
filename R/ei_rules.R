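# 70 eV electron-ionisation diagnostic ions per chemical class.
#
# Class behaviour encoded in the shipped rule table:
#   ketone                 m/z 43 base (alpha-cleavage), weak molecular ion
#   saturated aldehyde >=C4 m/z 43 + 44 (alpha-cleavage, McLafferty), M+ absent
#   C3 aldehydes           molecular ion kept, HC=O loss to [M-29]+
#   unsaturated aldehyde >C3 m/z 41 base (beta-cleavage ketene-type fragment;
#                          the printed diagnostic value, used literally)
#   acid <=C3              molecular ion + [M-17]+ (OH loss)
#   acid >=C4              McLafferty m/z 60 base + CnH2n-1O2 acylium series
#   primary alcohol        [M-18]+, [M-33]+, m/z 31, [M-H]+
#   phenol / aromatic      distinct M+; substituted benzenes add phenyl m/z 77

#' Predict EI diagnostic ions for a compound
#'
#' Applies the class-characteristic 70 eV EI fragmentation rules and returns
#' one row per predicted diagnostic ion. Intensity classes are three-level
#' (`base` = base peak, `major`, `minor`) plus `absent` for suppressed
#' molecular ions (retained so that annotation can treat an observed M+ for
#' a long-chain saturated aldehyde as non-supporting).
#'
#' @param compound A [compound_record()].
#' @param rules Rule table; defaults to the shipped EI table
#'   ([ei_rule_table()]).
#' @return data.frame with columns `platform` (`"EI"`), `transform`, `n`,
#'   `mz`, `intensity_class`, `channel`.
#' @examples
#' propanal <- compound_record("propanal", "C3H6O", "aldehyde_saturated")
#' predict_ei_ions(propanal)   # M+ 58 and [M-29]+ 29
#' @export
predict_ei_ions <- function(compound, rules = ei_rule_table()) {
  preds <- .predict_from_rules(compound, rules, "EI")
  # EI adds no mass: every ion at or below M+ and never the dimer
  over <- preds$mz > compound$molecular_mass
  if (any(over)) {
    stop(sprintf("EI rule produced m/z above molecular mass for %s",
                 compound$name), call. = FALSE)
  }
  preds
}
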