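# SIFT-MS: precursor hydrate series, class-specific reaction channels for
# H3O+ and NO+ precursors, and multi-ion-monitoring quantitation kinetics.

.SIFT_PRECURSORS <- list(
  "H3O+" = c(19L, 37L, 55L, 73L),  # H3O+ . (H2O)n, n = 0..3
  "NO+"  = c(30L, 48L, 66L)        # NO+ . (H2O)n, n = 0..2
)

#' SIFT-MS precursor hydrate series
#'
#' The precursor ions injected into the flow tube carry water-cluster
#' hydrates at +18 Da spacing: H3O+ at m/z 19, 37, 55 and 73; NO+ at
#' m/z 30, 48 and 66. Precursor count rates are summed over the full
#' series.
#'
#' @param name `"H3O+"` or `"NO+"`.
#' @return Integer vector of precursor m/z values, strictly increasing with
#'   spacing 18.
#' @examples
#' precursor_series("H3O+")
#' precursor_series("NO+")
#' @export
precursor_series <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.SIFT_PRECURSORS)) {
    stop(sprintf("unknown SIFT-MS precursor '%s'; supported: %s",
                 as.character(name)[1L],
                 paste(names(.SIFT_PRECURSORS), collapse = ", ")),
         call. = FALSE)
  }
  .SIFT_PRECURSORS[[name]]
}

#' Predict SIFT-MS product ions for a compound and precursor
#'
#' Reaction channels by chemical class:
#' * **H3O+**: protonation for every class; phenols, alcohols and acids
#'   additionally form water adducts `[M+H+nH2O]+` (n up to
#'   `max_hydrates`); alcohols additionally dehydrate to `[M+H-H2O]+`.
#' * **NO+**: phenols (and other aromatics) undergo electron transfer to
#'   M+ with water-adduct side channels; ketones, unsaturated aldehydes and
#'   acids form the nitrosonium adduct `[M+NO]+` (+30 Da); saturated
#'   aldehydes undergo hydride abstraction to `[M-H]+`. Acids additionally
#'   undergo dissociative ionisation; the fragment m/z are instrument
#'   kinetic-library entries, not predicted from structure, so the result
#'   only carries a `dissociative_ionisation` attribute flagging it.
#'
#' Channel predictions depend only on chemical class and precursor, never
#' on intensities.
#'
#' @param compound A [compound_record()].
#' @param precursor `"H3O+"` or `"NO+"`.
#' @param max_hydrates Maximum water-adduct count (default 2).
#' @return data.frame in the common prediction layout, platform
#'   `"SIFT_H3O"` or `"SIFT_NO"`, with attribute
#'   `dissociative_ionisation` (logical).
#' @examples
#' acetic <- compound_record("acetic acid", "C2H4O2", "acid")
#' predict_sift_products(acetic, "H3O+")$mz  # 61, 79, 97
#' @export
predict_sift_products <- function(compound, precursor, max_hydrates = 2L) {
  stopifnot(inherits(compound, "compound_record"))
  series <- precursor_series(precursor)  # validates the name
  max_hydrates <- as.integer(max_hydrates)
  stopifnot(max_hydrates >= 0L, max_hydrates <= 2L)
  M <- compound$molecular_mass
  cls <- compound$chem_class
  platform <- if (identical(precursor, "H3O+")) "SIFT_H3O" else "SIFT_NO"
  dissociative <- FALSE

  hydrate_rows <- function(base_label, base_mz) {
    if (max_hydrates < 1L) return(NULL)
    do.call(rbind, lapply(seq_len(max_hydrates), function(n) {
      .prediction_row(platform, "M+H+nH2O", base_mz + 18L * n, "major",
                      "water adduct", n = n)
    }))
  }

  rows <- if (identical(precursor, "H3O+")) {
    mh <- apply_transform(M, "M+H")
    if (cls %in% c("phenol", "alcohol_primary", "acid")) {
      out <- rbind(.prediction_row(platform, "M+H", mh, "base", "protonation"),
                   hydrate_rows("M+H", mh))
      if (cls == "alcohol_primary") {
        out <- rbind(out, .prediction_row(platform, "M-17",
                                          apply_transform(M, "M-17"),
                                          "major", "dehydration"))
      }
      out
    } else if (cls %in% c("ketone", "aldehyde_saturated",
                          "aldehyde_unsaturated", "aromatic")) {
      .prediction_row(platform, "M+H", mh, "base", "protonation")
    } else {
      stop(sprintf("no H3O+ channel for class '%s'", cls), call. = FALSE)
    }
  } else {
    if (cls %in% c("phenol", "aromatic")) {
      m <- apply_transform(M, "M")
      rbind(.prediction_row(platform, "M", m, "base", "electron transfer"),
            if (max_hydrates >= 1L) do.call(rbind, lapply(
              seq_len(max_hydrates), function(n) {
                .prediction_row(platform, "M+H+nH2O", m + 18L * n, "minor",
                                "water adduct", n = n)
              })))
    } else if (cls %in% c("ketone", "aldehyde_unsaturated", "acid")) {
      out <- .prediction_row(platform, "M+NO", apply_transform(M, "M+NO"),
                             "base", "nitrosonium adduct")
      if (cls == "acid") dissociative <- TRUE
      out
    } else if (cls == "aldehyde_saturated") {
      .prediction_row(platform, "M-H", apply_transform(M, "M-H"),
                      "base", "hydride abstraction")
    } else {
      stop(sprintf("no NO+ channel for class '%s'", cls), call. = FALSE)
    }
  }
  rownames(rows) <- NULL
  attr(rows, "dissociative_ionisation") <- dissociative
  rows
}

#' Kinetic-library entry for SIFT-MS quantitation
#'
#' Rate coefficients and product branching are instrument kinetic-library
#' values supplied by the user, not predicted.
#'
#' @param compound Compound name.
#' @param precursor `"H3O+"` or `"NO+"`.
#' @param k Reaction rate coefficient in cm^3/s (positive).
#' @param product_mz Integer vector of product-ion m/z.
#' @param branching Branching fractions, same length, each in (0, 1],
#'   summing to 1.
#' @return List of class `"kinetic_entry"`.
#' @export
kinetic_entry <- function(compound, precursor, k, product_mz,
                          branching = rep(1 / length(product_mz),
                                          length(product_mz))) {
  precursor_series(precursor)
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("rate coefficient k must be a single positive number", call. = FALSE)
  }
  stopifnot(length(product_mz) == length(branching), length(product_mz) >= 1L)
  if (any(branching <= 0) || any(branching > 1) ||
      abs(sum(branching) - 1) > 1e-9) {
    stop("branching fractions must lie in (0,1] and sum to 1", call. = FALSE)
  }
  structure(list(compound = compound, precursor = precursor, k = k,
                 product_mz = as.integer(product_mz),
                 branching = as.numeric(branching)),
            class = "kinetic_entry")
}

#' Read a SIFT-MS kinetic library from delimited text
#'
#' Columns: `compound`, `precursor`, `k`, `product_mz` (semicolon-separated
#' integers), `branching` (semicolon-separated fractions).
#'
#' @param path CSV path.
#' @return List of [kinetic_entry()] objects.
#' @export
read_kinetic_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    kinetic_entry(df$compound[i], df$precursor[i], df$k[i],
                  as.integer(strsplit(df$product_mz[i], ";")[[1]]),
                  as.numeric(strsplit(df$branching[i], ";")[[1]]))
  })
}

#' SIFT-MS multi-ion-monitoring concentration
#'
#' Standard flow-tube kinetics: the analyte mixing ratio is the product to
#' precursor count-rate ratio divided by (k * reaction time * carrier
#' number density), expressed in parts-per-billion by volume.
#'
#' @param product_counts Product-ion count rate summed over product ions
#'   (counts/s, `>= 0`).
#' @param precursor_counts Precursor count rate summed over the hydrate
#'   series (counts/s, `> 0`).
#' @param k Rate coefficient in cm^3/s, or a [kinetic_entry()].
#' @param reaction_time Flow-tube reaction time in s.
#' @param number_density Carrier-gas number density in cm^-3.
#' @return Concentration in ppbv; linear in `product_counts`.
#' @examples
#' quantify_mim(600, 8e5, k = 3e-9, reaction_time = 0.01,
#'              number_density = 2.5e16)
#' @export
quantify_mim <- function(product_counts, precursor_counts, k,
                         reaction_time, number_density) {
  if (inherits(k, "kinetic_entry")) k <- k$k
  if (!is.numeric(precursor_counts) || any(precursor_counts <= 0)) {
    stop("precursor_counts must be positive: concentration undefined at zero",
         call. = FALSE)
  }
  stopifnot(is.numeric(product_counts), all(product_counts >= 0),
            k > 0, reaction_time > 0, number_density > 0)
  (product_counts / precursor_counts) / (k * reaction_time * number_density) *
    1e9
}
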