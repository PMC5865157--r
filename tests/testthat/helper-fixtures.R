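# Shared fixtures built in code.

# Independent formula -> nominal mass lookup: 30 small organics with masses
# written down from the integer isotope masses by hand, independent of the
# parser under test.
formula_mass_oracle <- data.frame(
  formula = c("CH4", "C2H6", "C2H4", "C2H2", "CH4O", "C2H6O", "C3H8O",
              "C4H10O", "C2H4O", "C3H6O", "C4H8O", "C5H10O", "C6H12O",
              "C7H14O", "CH2O2", "C2H4O2", "C3H6O2", "C4H8O2", "C6H12O2",
              "C6H6O", "C7H8O", "C8H10O", "C7H6O", "C6H6", "C3H4O",
              "C5H8O", "C2H7NO2", "CH3NO", "C2H6S", "H2O"),
  mass = c(16L, 30L, 28L, 26L, 32L, 46L, 60L,
           74L, 44L, 58L, 72L, 86L, 100L,
           114L, 46L, 60L, 74L, 88L, 116L,
           94L, 108L, 122L, 106L, 78L, 56L,
           84L, 77L, 45L, 62L, 18L),
  stringsAsFactors = FALSE)

# Small compounds used across rule tests.
fx_propanal <- compound_record("propanal", "C3H6O", "aldehyde_saturated",
                               reference_ri = 489)
fx_acetone <- compound_record("acetone", "C3H6O", "ketone",
                              reference_ri = 498)
fx_acetic <- compound_record("acetic acid", "C2H4O2", "acid",
                             reference_ri = 675)
fx_butanoic <- compound_record("butanoic acid", "C4H8O2", "acid",
                               reference_ri = 863)
fx_hexanoic <- compound_record("hexanoic acid", "C6H12O2", "acid")
fx_heptanal <- compound_record("heptanal", "C7H14O", "aldehyde_saturated")
fx_ethanol <- compound_record("ethanol", "C2H6O", "alcohol_primary",
                              proton_affinity = 776)
fx_butanol <- compound_record("1-butanol", "C4H10O", "alcohol_primary")
fx_phenol <- compound_record("phenol", "C6H6O", "phenol",
                             reference_ri = 1023)
fx_benzaldehyde <- compound_record("benzaldehyde", "C7H6O", "aromatic",
                                   aromatic_substituted = TRUE)
fx_decanone <- compound_record("4-decanone", "C10H20O", "ketone")
fx_ammonium_acetate <- compound_record("ammonium acetate", "C2H7NO2",
                                       "acid")
fx_ethylphenol2 <- compound_record("2-ethylphenol", "C8H10O", "phenol",
                                   reference_ri = 1286,
                                   aromatic_substituted = TRUE)
fx_ethylphenol4 <- compound_record("4-ethylphenol", "C8H10O", "phenol",
                                   reference_ri = 1323,
                                   aromatic_substituted = TRUE)

# Prediction row for a given transform label, error if not present.
pred_mz <- function(preds, transform) {
  hit <- preds$mz[preds$transform == transform]
  stopifnot(length(hit) == 1L)
  hit
}

# Peak group reproducing the acetic-acid worked example.
acetic_peak_group <- function() {
  list(
    EI = peak_table(c(60, 43), c(80, 100), platform = "EI"),
    PCI = peak_table(61, 100, platform = "PCI"),
    SIFT_H3O = peak_table(c(61, 79, 97), c(100, 60, 35),
                          platform = "SIFT_H3O"))
}
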