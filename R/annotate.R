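# Consensus annotation: combine retention-index, EI, PCI and SIFT-MS
# evidence for a chromatographic feature into a tiered annotation per
# candidate compound.

.PLATFORMS <- c("EI", "PCI", "SIFT_H3O", "SIFT_NO")
.TIERS <- c("confirmed", "probable", "tentative", "rejected")

#' Construct an observed peak table for one sample on one platform
#'
#' @param mz Numeric vector of observed m/z.
#' @param intensity Non-negative intensities (arbitrary units).
#' @param ri Optional retention index (single value for the feature, or one
#'   per peak). SIFT-MS has no chromatography, so SIFT platforms carry no
#'   retention coordinate.
#' @param platform One of `"EI"`, `"PCI"`, `"SIFT_H3O"`, `"SIFT_NO"`.
#' @param sample Sample identifier.
#' @return data.frame of class `"peak_table"` with attributes `platform`
#'   and `sample`.
#' @export
peak_table <- function(mz, intensity, ri = NA_real_, platform, sample = "S1") {
  platform <- match.arg(platform, .PLATFORMS)
  stopifnot(length(mz) == length(intensity))
  ri <- rep_len(as.numeric(ri), length(mz))
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (startsWith(platform, "SIFT") && any(!is.na(ri))) {
    warning("SIFT-MS peaks carry no retention coordinate; 'ri' ignored")
    ri <- NA_real_
  }
  pt <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity),
                   ri = as.numeric(ri))
  attr(pt, "platform") <- platform
  attr(pt, "sample") <- sample
  class(pt) <- c("peak_table", "data.frame")
  pt
}

#' Kovats retention index under temperature programming
#'
#' Linear (van den Dool & Kratz) index against an n-alkane ladder:
#' `RI = 100 * (n + (rt - rt_n) / (rt_(n+1) - rt_n))` for the bracketing
#' alkanes with n and n+1 carbons.
#'
#' @param rt Retention time(s) in minutes; must lie within the ladder span
#'   (no silent extrapolation).
#' @param alkane_ladder data.frame with columns `carbon` (5..20,
#'   increasing) and `rt` (strictly increasing).
#' @return Numeric retention index per input rt.
#' @examples
#' ladder <- data.frame(carbon = 5:8, rt = c(4, 7, 11, 16))
#' compute_ri(4, ladder)   # 500 at the C5 anchor
#' compute_ri(9, ladder)   # midpoint C6-C7: 650
#' @export
compute_ri <- function(rt, alkane_ladder) {
  stopifnot(is.data.frame(alkane_ladder),
            all(c("carbon", "rt") %in% names(alkane_ladder)))
  lad <- alkane_ladder[order(alkane_ladder$carbon), ]
  if (any(diff(lad$rt) <= 0) || any(diff(lad$carbon) <= 0)) {
    stop("alkane ladder must have strictly increasing carbons and rts",
         call. = FALSE)
  }
  if (any(lad$carbon < 5L) || any(lad$carbon > 20L)) {
    stop("alkane ladder carbons must lie in 5..20", call. = FALSE)
  }
  vapply(rt, function(t1) {
    if (is.na(t1) || t1 < lad$rt[1L] || t1 > lad$rt[nrow(lad)]) {
      stop(sprintf(
        "rt %.3f min outside the alkane ladder span [%.3f, %.3f]: refusing to extrapolate",
        t1, lad$rt[1L], lad$rt[nrow(lad)]), call. = FALSE)
    }
    i <- max(which(lad$rt <= t1))
    if (i == nrow(lad)) i <- i - 1L
    n <- lad$carbon[i]
    100 * (n + (lad$carbon[i + 1L] - n) *
             (t1 - lad$rt[i]) / (lad$rt[i + 1L] - lad$rt[i]))
  }, numeric(1L))
}

#' Spectral-library score gate
#'
#' Library match/reverse-match scores below the threshold do not permit
#' standalone annotation; such peaks need cross-platform evidence.
#'
#' @param match_score,reverse_match Integer scores in \[0, 1000\].
#' @param threshold Gate threshold (default 800; "below" is strict).
#' @return `TRUE` when cross-platform evidence is required, i.e. when
#'   `min(match_score, reverse_match) < threshold`.
#' @examples
#' library_gate(750, 820)  # TRUE: needs cross-platform evidence
#' library_gate(800, 800)  # FALSE: at the boundary
#' @export
library_gate <- function(match_score, reverse_match, threshold = 800L) {
  scores <- c(match_score, reverse_match)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1000)) {
    stop("library scores must lie in [0, 1000]", call. = FALSE)
  }
  pmin(match_score, reverse_match) < threshold
}

#' Annotation configuration
#'
#' @param mz_tolerance m/z match tolerance (default 0.3, unit-resolution
#'   quadrupole).
#' @param ri_tolerance Retention-index tolerance (default 15 index units:
#'   wide enough for run-to-run drift, narrow enough to separate the
#'   ethylphenol isomer pair at RI 1286 vs 1323).
#' @param gate_threshold Library-score gate (default 800).
#' @param contradiction_min_peaks Minimum observed peaks (above
#'   `intensity_floor`) on a platform before a total mismatch counts as a
#'   contradiction; absence of evidence on a sparse spectrum must not
#'   reject.
#' @param intensity_floor Intensity below which observed peaks are ignored
#'   by the contradiction rule.
#' @param max_hydrates SIFT water-adduct cap.
#' @return List of class `"annotation_config"`.
#' @export
annotation_config <- function(mz_tolerance = 0.3, ri_tolerance = 15,
                              gate_threshold = 800L,
                              contradiction_min_peaks = 3L,
                              intensity_floor = 0,
                              max_hydrates = 2L) {
  stopifnot(mz_tolerance > 0, ri_tolerance > 0, gate_threshold >= 0,
            contradiction_min_peaks >= 1L, intensity_floor >= 0)
  structure(list(mz_tolerance = mz_tolerance, ri_tolerance = ri_tolerance,
                 gate_threshold = as.integer(gate_threshold),
                 contradiction_min_peaks = as.integer(contradiction_min_peaks),
                 intensity_floor = intensity_floor,
                 max_hydrates = as.integer(max_hydrates)),
            class = "annotation_config")
}

# Short reproducibility fingerprint of a config, embedded in reports.
config_fingerprint <- function(config) {
  stopifnot(inherits(config, "annotation_config"))
  paste(sprintf("%s=%s", names(config),
                vapply(config, format, character(1L))), collapse = ";")
}

#' Predict diagnostic ions for any platform
#'
#' Dispatch wrapper used by annotation and simulation: EI and PCI use the
#' shipped rule tables, SIFT platforms the channel predictor.
#'
#' @param compound A [compound_record()].
#' @param platform One of `"EI"`, `"PCI"`, `"SIFT_H3O"`, `"SIFT_NO"`.
#' @param config An [annotation_config()] (SIFT hydrate cap).
#' @return Prediction data.frame.
#' @export
predict_platform_ions <- function(compound, platform,
                                  config = annotation_config()) {
  platform <- match.arg(platform, .PLATFORMS)
  switch(platform,
         EI = predict_ei_ions(compound),
         PCI = predict_pci_ions(compound),
         SIFT_H3O = predict_sift_products(compound, "H3O+",
                                          config$max_hydrates),
         SIFT_NO = predict_sift_products(compound, "NO+",
                                         config$max_hydrates))
}

#' Match predicted ions against an observed peak table
#'
#' A prediction matches when an observed peak lies within `mz_tolerance` of
#' its m/z. The platform evidence is `matched = TRUE` iff every base-class
#' prediction matches and at least one base or major ion matched.
#' Predictions with intensity class `"absent"` are never counted as
#' support. Whether the base-peak prediction is also the most intense
#' matched ion is recorded (`base_is_top`) but not required.
#'
#' @param predictions Prediction data.frame for one platform.
#' @param peaks A [peak_table()] on the same platform.
#' @param mz_tolerance Match tolerance in m/z units.
#' @return List of class `"evidence_record"`: `platform`, `matched`,
#'   `matched_ions` (data.frame), counts of base/major predictions and
#'   matches, `base_is_top`.
#' @export
match_ions <- function(predictions, peaks, mz_tolerance = 0.3) {
  stopifnot(inherits(peaks, "peak_table"))
  platform <- attr(peaks, "platform")
  if (nrow(predictions) > 0L &&
      !all(predictions$platform == platform)) {
    stop(sprintf("predictions are for platform %s but peaks are %s",
                 paste(unique(predictions$platform), collapse = "/"),
                 platform), call. = FALSE)
  }
  scored <- predictions[predictions$intensity_class != "absent", ,
                        drop = FALSE]
  hits <- lapply(seq_len(nrow(scored)), function(i) {
    d <- abs(peaks$mz - scored$mz[i])
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= mz_tolerance) {
      data.frame(predicted_mz = scored$mz[i], observed_mz = peaks$mz[j],
                 intensity = peaks$intensity[j],
                 intensity_class = scored$intensity_class[i],
                 transform = scored$transform[i])
    } else {
      NULL
    }
  })
  matched_ions <- do.call(rbind, hits)
  if (is.null(matched_ions)) {
    matched_ions <- data.frame(predicted_mz = numeric(0),
                               observed_mz = numeric(0),
                               intensity = numeric(0),
                               intensity_class = character(0),
                               transform = character(0))
  }
  n_base <- sum(scored$intensity_class == "base")
  n_base_matched <- sum(matched_ions$intensity_class == "base")
  n_support <- sum(matched_ions$intensity_class %in% c("base", "major"))
  matched <- nrow(scored) > 0L && n_base_matched == n_base && n_support >= 1L
  base_is_top <- if (n_base_matched > 0L && nrow(matched_ions) > 0L) {
    max(matched_ions$intensity[matched_ions$intensity_class == "base"]) >=
      max(matched_ions$intensity)
  } else {
    NA
  }
  structure(list(platform = platform, matched = matched,
                 matched_ions = matched_ions,
                 n_predictions = nrow(scored), n_base = n_base,
                 n_base_matched = n_base_matched,
                 n_support_matched = n_support,
                 base_is_top = base_is_top),
            class = "evidence_record")
}

# Contradiction: the platform shows a rich spectrum (>= min_peaks above the
# intensity floor) yet none of the candidate's base/major predictions match.
.contradicts <- function(evidence, peaks, config) {
  n_obs <- sum(peaks$intensity > config$intensity_floor)
  n_obs >= config$contradiction_min_peaks &&
    evidence$n_predictions > 0L &&
    evidence$n_support_matched == 0L
}

.assign_tier <- function(n_platforms_matched, ri_match, contradicted) {
  if (contradicted) return("rejected")
  if (isTRUE(ri_match) && n_platforms_matched >= 2L) return("confirmed")
  if (n_platforms_matched >= 2L) return("probable")
  if (n_platforms_matched == 1L && isTRUE(ri_match)) return("probable")
  if (n_platforms_matched == 1L) return("tentative")
  "tentative"
}

#' Screen candidate compounds against a cross-platform peak group
#'
#' For one chromatographic feature (a group of peak tables across
#' platforms, plus an optional observed retention index and library
#' scores), every candidate is scored on each platform with [match_ions()]
#' and against the reference RI, and assigned a consensus tier:
#'
#' * `confirmed` — RI match and >= 2 MS platforms matched;
#' * `probable`  — >= 2 platforms matched without RI, or RI plus exactly one
#'   platform;
#' * `tentative` — at most one platform matched, no contradiction;
#' * `rejected`  — some platform with a rich spectrum contradicts all of
#'   the candidate's base/major predictions.
#'
#' Candidates whose SIFT-MS predictions are identical (isomers such as the
#' ethylphenols) carry each other in `ambiguity_set` unless the observed RI
#' resolves exactly one of them.
#'
#' @param peaks Named list of [peak_table()]s; names are platform tags.
#' @param candidates List of [compound_record()]s (non-empty).
#' @param config An [annotation_config()].
#' @param observed_ri Observed retention index of the feature (`NA` when
#'   unavailable).
#' @param library_scores Optional `c(match, reverse)` NIST-style scores;
#'   recorded through [library_gate()] in the result attribute
#'   `needs_crossplatform`.
#' @return data.frame (class `"annotation_screen"`) with one row per
#'   candidate, sorted by tier, then matched-ion count, then name:
#'   columns `candidate`, `chem_class`, `tier`, `n_platforms_matched`,
#'   `platforms_matched`, `n_ions_matched`, `ri_match`, `ambiguity_set`.
#'   Attribute `evidence` holds the per-candidate evidence records.
#' @export
screen_candidates <- function(peaks, candidates,
                              config = annotation_config(),
                              observed_ri = NA_real_,
                              library_scores = NULL) {
  candidates <- .as_compound_list(candidates)
  if (length(candidates) == 0L) stop("no candidates given", call. = FALSE)
  stopifnot(is.list(peaks), length(peaks) >= 1L,
            !is.null(names(peaks)), all(names(peaks) %in% .PLATFORMS))
  cand_names <- vapply(candidates, `[[`, character(1L), "name")
  names(candidates) <- cand_names

  evidence <- lapply(candidates, function(cand) {
    evs <- lapply(names(peaks), function(pf) {
      preds <- tryCatch(predict_platform_ions(cand, pf, config),
                        error = function(e) .empty_predictions())
      match_ions(preds, peaks[[pf]], config$mz_tolerance)
    })
    names(evs) <- names(peaks)
    evs
  })

  sift_sig <- vapply(candidates, function(cand) {
    mz <- unlist(lapply(c("SIFT_H3O", "SIFT_NO"), function(pf) {
      tryCatch({
        p <- predict_platform_ions(cand, pf, config)
        paste0(pf, ":", p$mz[p$intensity_class != "absent"])
      }, error = function(e) character(0))
    }))
    paste(sort(mz), collapse = ",")
  }, character(1L))

  rows <- lapply(cand_names, function(nm) {
    cand <- candidates[[nm]]
    evs <- evidence[[nm]]
    matched_pf <- names(evs)[vapply(evs, `[[`, logical(1L), "matched")]
    contradicted <- any(vapply(names(evs), function(pf) {
      .contradicts(evs[[pf]], peaks[[pf]], config)
    }, logical(1L)))
    ri_match <- if (is.na(observed_ri) || is.na(cand$reference_ri)) {
      NA
    } else {
      abs(observed_ri - cand$reference_ri) <= config$ri_tolerance
    }
    n_ions <- sum(vapply(evs, function(e) nrow(e$matched_ions), integer(1L)))
    data.frame(candidate = nm, chem_class = cand$chem_class,
               tier = .assign_tier(length(matched_pf), ri_match,
                                   contradicted),
               n_platforms_matched = length(matched_pf),
               platforms_matched = paste(matched_pf, collapse = ";"),
               n_ions_matched = n_ions,
               ri_match = ri_match,
               ambiguity_set = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)

  # isomers indistinguishable by SIFT: mutual ambiguity unless RI resolves
  for (i in seq_len(nrow(res))) {
    nm <- res$candidate[i]
    twins <- cand_names[sift_sig == sift_sig[[nm]] & cand_names != nm &
                          nzchar(sift_sig[[nm]])]
    if (length(twins) > 0L) {
      grp <- c(nm, twins)
      ri_flags <- res$ri_match[match(grp, res$candidate)]
      resolved <- !any(is.na(ri_flags)) && sum(ri_flags) == 1L
      if (!resolved) res$ambiguity_set[i] <- paste(twins, collapse = ";")
    }
  }

  res$tier <- factor(res$tier, levels = .TIERS)
  ord <- order(res$tier, -res$n_ions_matched, res$candidate)
  res <- res[ord, , drop = FALSE]
  res$tier <- as.character(res$tier)
  rownames(res) <- NULL
  attr(res, "evidence") <- evidence
  attr(res, "observed_ri") <- observed_ri
  if (!is.null(library_scores)) {
    attr(res, "needs_crossplatform") <-
      library_gate(library_scores[[1L]], library_scores[[2L]],
                   config$gate_threshold)
  }
  attr(res, "config_fingerprint") <- config_fingerprint(config)
  class(res) <- c("annotation_screen", "data.frame")
  res
}
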