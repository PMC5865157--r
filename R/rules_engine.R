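# Shared declarative rule engine. EI and water-PCI diagnostic-ion rules are
# plain delimited tables (class -> transform/fixed-m/z, intensity class,
# mechanism), shipped under extdata and reloadable by users, so the rule
# sets can be extended without touching code.

.INTENSITY_CLASSES <- c("base", "major", "minor", "absent")

#' Load a diagnostic-ion rule table
#'
#' Rule tables are CSVs with columns `chem_class`, `c_min`, `c_max`
#' (inclusive carbon-count bounds, blank = unbounded), `kind` (`"transform"`,
#' `"fixed"` or `"acylium"`), `value` (transform label or fixed m/z),
#' `intensity_class` and `mechanism`, plus `requires_flag` (blank or
#' `"substituted"` to gate a row on the substituted-benzene flag).
#'
#' @param path Path to the CSV; defaults select the shipped tables.
#' @return Validated data.frame of class `"ion_rule_table"`.
#' @export
load_rule_table <- function(path) {
  rules <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(c_min = "integer",
                                          c_max = "integer"))
  needed <- c("chem_class", "c_min", "c_max", "kind", "value",
              "intensity_class", "mechanism", "requires_flag")
  missing_cols <- setdiff(needed, names(rules))
  if (length(missing_cols) > 0L) {
    stop(sprintf("rule table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad_class <- setdiff(unique(rules$chem_class), voc_classes())
  if (length(bad_class) > 0L) {
    stop(sprintf("rule table has unsupported chem_class: %s",
                 paste(bad_class, collapse = ", ")), call. = FALSE)
  }
  bad_int <- setdiff(unique(rules$intensity_class), .INTENSITY_CLASSES)
  if (length(bad_int) > 0L) {
    stop(sprintf("rule table has unsupported intensity_class: %s",
                 paste(bad_int, collapse = ", ")), call. = FALSE)
  }
  rules$value <- as.character(rules$value)
  rules$requires_flag <- ifelse(is.na(rules$requires_flag), "",
                                as.character(rules$requires_flag))
  class(rules) <- c("ion_rule_table", class(rules))
  rules
}

#' @rdname load_rule_table
#' @export
ei_rule_table <- function(path = system.file("extdata", "ei_rules.csv",
                                             package = "breathvoc")) {
  load_rule_table(path)
}

#' @rdname load_rule_table
#' @export
pci_rule_table <- function(path = system.file("extdata", "pci_rules.csv",
                                              package = "breathvoc")) {
  load_rule_table(path)
}

#' Write a rule table back to delimited text
#'
#' Serialising and re-loading a rule table reproduces identical predictions
#' (round-trip property used in the test suite).
#'
#' @param rules An `ion_rule_table`.
#' @param path Output path.
#' @export
write_rule_table <- function(rules, path) {
  stopifnot(inherits(rules, "ion_rule_table"))
  utils::write.csv(as.data.frame(unclass(rules))[, c(
    "chem_class", "c_min", "c_max", "kind", "value",
    "intensity_class", "mechanism", "requires_flag")],
    path, row.names = FALSE, na = "")
  invisible(path)
}

# One prediction row in the common IonPrediction layout.
.prediction_row <- function(platform, transform, mz, intensity_class,
                            channel, n = NA_integer_) {
  data.frame(platform = platform, transform = transform, n = n,
             mz = as.integer(mz), intensity_class = intensity_class,
             channel = channel, stringsAsFactors = FALSE)
}

.empty_predictions <- function() {
  data.frame(platform = character(0), transform = character(0),
             n = integer(0), mz = integer(0),
             intensity_class = character(0), channel = character(0),
             stringsAsFactors = FALSE)
}

# Evaluate a rule table for one compound on one platform tag. Transform
# rows that do not apply at the compound's mass (negative m/z) propagate a
# domain error carrying the compound name.
.predict_from_rules <- function(compound, rules, platform) {
  stopifnot(inherits(compound, "compound_record"),
            inherits(rules, "ion_rule_table"))
  if (!compound$chem_class %in% rules$chem_class) {
    stop(sprintf("no %s rules for chemical class '%s' (compound %s)",
                 platform, compound$chem_class, compound$name),
         call. = FALSE)
  }
  sel <- rules$chem_class == compound$chem_class &
    (is.na(rules$c_min) | compound$carbon_count >= rules$c_min) &
    (is.na(rules$c_max) | compound$carbon_count <= rules$c_max) &
    (rules$requires_flag == "" |
       (rules$requires_flag == "substituted" & compound$aromatic_substituted))
  sel_rules <- rules[sel, , drop = FALSE]
  if (nrow(sel_rules) == 0L) return(.empty_predictions())
  out <- lapply(seq_len(nrow(sel_rules)), function(i) {
    r <- sel_rules[i, ]
    mz <- switch(r$kind,
      fixed = as.integer(r$value),
      transform = tryCatch(
        apply_transform(compound$molecular_mass, r$value),
        error = function(e) {
          stop(sprintf("compound %s: %s", compound$name, conditionMessage(e)),
               call. = FALSE)
        }),
      acylium = {
        # CnH2n-1O2 acylium-type series evaluated at the acid's own n
        n <- compound$carbon_count
        nominal_mass(structure(c(C = n, H = 2L * n - 1L, O = 2L),
                               class = "element_counts"))
      },
      stop(sprintf("unknown rule kind '%s'", r$kind), call. = FALSE)
    )
    label <- switch(r$kind,
      fixed = sprintf("mz%s", r$value),
      transform = r$value,
      acylium = "CnH2n-1O2")
    .prediction_row(platform, label, mz, r$intensity_class, r$mechanism)
  })
  preds <- do.call(rbind, out)
  rownames(preds) <- NULL
  preds
}
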