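# Cross-platform quantitative assessment: paired response regression,
# precision (RSD), detection limits from calibration, and class-composition
# profiles across a cohort.

#' Ordinary least-squares fit of paired platform responses
#'
#' Responses of the same loadings measured on two platforms are related by
#' a straight line; the slope is the inter-platform response factor.
#'
#' @param x Responses on platform A (length >= 3, finite, non-constant).
#' @param y Responses on platform B (same length).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @examples
#' fit_paired_response(1:5, 2 * (1:5))  # slope 2, intercept 0, R^2 = 1
#' @export
fit_paired_response <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("responses must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("degenerate fit: zero variance in x", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # noiseless synthetic data fits exactly; the perfect-fit warning from
  # summary.lm is expected there, not a defect
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}

#' Relative standard deviation of replicate responses
#'
#' @param replicates Numeric vector, length >= 2, with non-zero mean.
#' @return RSD in percent: `100 * sd / mean`.
#' @examples
#' relative_sd(c(9, 10, 11))  # 10
#' @export
relative_sd <- function(replicates) {
  stopifnot(is.numeric(replicates))
  if (length(replicates) < 2L) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  m <- mean(replicates)
  if (m == 0) stop("RSD undefined: mean response is zero", call. = FALSE)
  100 * stats::sd(replicates) / m
}

#' Calibration series for one compound on one platform
#'
#' @param compound Compound name.
#' @param platform Platform tag.
#' @param loading Positive loadings (mol, or vapour volume in mL).
#' @param response Detector responses (same length).
#' @param ppbv_per_unit Conversion factor from one loading unit to a ppbv
#'   mixing ratio at the instrument inlet (default 1).
#' @return data.frame of class `"calibration_series"` with attributes.
#' @export
calibration_series <- function(compound, platform, loading, response,
                               ppbv_per_unit = 1) {
  stopifnot(length(loading) == length(response), ppbv_per_unit > 0)
  if (length(loading) < 3L) {
    stop("calibration needs >= 3 points", call. = FALSE)
  }
  if (any(loading <= 0)) stop("loadings must be positive", call. = FALSE)
  out <- data.frame(loading = as.numeric(loading),
                    response = as.numeric(response))
  attr(out, "compound") <- compound
  attr(out, "platform") <- platform
  attr(out, "ppbv_per_unit") <- ppbv_per_unit
  class(out) <- c("calibration_series", "data.frame")
  out
}

#' Limit of detection from a calibration series
#'
#' ICH-style estimate: `LOD = 3.3 * blank_sd / slope` in loading units,
#' converted to ppbv with the series' loading-to-mixing-ratio factor.
#'
#' @param series A [calibration_series()].
#' @param blank_sd Standard deviation of the blank response (`>= 0`).
#' @return LOD in ppbv; zero blank noise gives LOD 0, and LOD is strictly
#'   decreasing in the calibration slope.
#' @export
lod_from_calibration <- function(series, blank_sd) {
  stopifnot(inherits(series, "calibration_series"))
  if (!is.numeric(blank_sd) || blank_sd < 0) {
    stop("blank_sd must be >= 0", call. = FALSE)
  }
  slope <- unname(stats::coef(stats::lm(response ~ loading, data = series))[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("LOD undefined: calibration slope must be positive", call. = FALSE)
  }
  3.3 * blank_sd / slope * attr(series, "ppbv_per_unit")
}

#' Class-composition profile across annotated samples
#'
#' Per sample, the relative abundance of each chemical class is 100 times
#' its summed peak area over the total oxygenated-VOC area (so per-sample
#' abundances sum to 100). The cohort summary reports median and quartiles
#' per class, matching box-plot presentation.
#'
#' @param areas data.frame with columns `sample`, `chem_class`, `area`
#'   (and optionally `tier`, in which case only `confirmed`/`probable`
#'   annotations contribute).
#' @return List of class `"composition_profile"`: `per_sample` (sample,
#'   chem_class, percent) and `cohort` (chem_class, median, q1, q3).
#' @export
class_composition <- function(areas) {
  stopifnot(is.data.frame(areas),
            all(c("sample", "chem_class", "area") %in% names(areas)))
  if ("tier" %in% names(areas)) {
    areas <- areas[areas$tier %in% c("confirmed", "probable"), , drop = FALSE]
  }
  if (nrow(areas) == 0L || all(areas$area == 0)) {
    stop("composition undefined: no positive annotated areas", call. = FALSE)
  }
  if (any(areas$area < 0)) stop("areas must be >= 0", call. = FALSE)
  per_sample <- do.call(rbind, lapply(split(areas, areas$sample), function(d) {
    tot <- sum(d$area)
    if (tot == 0) {
      stop(sprintf("composition undefined for sample %s: all-zero areas",
                   d$sample[1L]), call. = FALSE)
    }
    by_class <- tapply(d$area, d$chem_class, sum)
    data.frame(sample = d$sample[1L], chem_class = names(by_class),
               percent = 100 * as.numeric(by_class) / tot,
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  cohort <- do.call(rbind, lapply(split(per_sample, per_sample$chem_class),
                                  function(d) {
    q <- stats::quantile(d$percent, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(chem_class = d$chem_class[1L], median = q[2L],
               q1 = q[1L], q3 = q[3L], stringsAsFactors = FALSE)
  }))
  rownames(cohort) <- NULL
  structure(list(per_sample = per_sample,
                 cohort = cohort[order(-cohort$median), ]),
            class = "composition_profile")
}
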