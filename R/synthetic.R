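# Synthetic-data generator: multi-platform peak tables, calibration series
# and cohort composition tables with the statistical structure the
# annotation workflow assumes, so the full pipeline is testable without any
# instrument data.

#' Simulation configuration
#'
#' Defaults encode the study conditions the workflow was built around:
#' 9% multiplicative noise (the SIFT-MS replicate RSD regime), three-level
#' intensity bands (base 100, major 30-100, minor below 30% relative
#' intensity), unit-resolution m/z jitter, a few index units of RI drift,
#' decoy background peaks over the 20-250 m/z acquisition range, and
#' cohort composition medians of ketone 77, aldehyde 10, acid 9, phenol 3,
#' alcohol 1 percent (renormalised).
#'
#' @param noise_cv Multiplicative (lognormal) coefficient of variation for
#'   intensities and calibration responses.
#' @param decoy_rate Poisson mean of decoy background peaks per spectrum.
#' @param mz_jitter_sd SD of observed m/z around the nominal value.
#' @param ri_jitter_sd SD of observed RI around the reference, index units.
#' @param decoy_mz_range Acquisition m/z range for decoy peaks.
#' @param composition_medians Named per-class cohort medians (percent;
#'   renormalised to sum to 100).
#' @param composition_concentration Dirichlet concentration for per-sample
#'   composition scatter; `Inf` disables scatter.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(noise_cv = 0.09, decoy_rate = 5,
                       mz_jitter_sd = 0.1, ri_jitter_sd = 5,
                       decoy_mz_range = c(20, 250),
                       composition_medians = c(ketone = 77, aldehyde = 10,
                                               acid = 9, phenol = 3,
                                               alcohol = 1),
                       composition_concentration = 60) {
  stopifnot(noise_cv >= 0, decoy_rate >= 0, mz_jitter_sd >= 0,
            ri_jitter_sd >= 0, length(decoy_mz_range) == 2L,
            decoy_mz_range[1L] < decoy_mz_range[2L],
            all(composition_medians >= 0), sum(composition_medians) > 0,
            composition_concentration > 0)
  composition_medians <- 100 * composition_medians / sum(composition_medians)
  structure(list(noise_cv = noise_cv, decoy_rate = decoy_rate,
                 mz_jitter_sd = mz_jitter_sd, ri_jitter_sd = ri_jitter_sd,
                 decoy_mz_range = decoy_mz_range,
                 composition_medians = composition_medians,
                 composition_concentration = composition_concentration),
            class = "sim_config")
}

.band_intensity <- function(intensity_class) {
  switch(intensity_class,
         base = 100,
         major = stats::runif(1L, 30, 100),
         minor = stats::runif(1L, 1, 30),
         0)
}

#' Simulate an observed peak table for one platform
#'
#' For each compound, its predicted diagnostic ions (rows with intensity
#' class `"absent"` are dropped — the instrument would not show them) are
#' emitted with intensities drawn from the band of their intensity class,
#' perturbed by multiplicative lognormal noise; m/z values carry Gaussian
#' jitter; GC platforms carry the reference RI with Gaussian drift. Poisson
#' decoy background peaks are appended at uniform random m/z over the
#' acquisition range. Output is a pure function of `(compounds, platform,
#' config, seed)`.
#'
#' Compounds whose class has no reaction channel on the requested platform
#' (e.g. alcohols with the NO+ precursor) produce no signal there and are
#' skipped; their names are recorded in the `skipped` attribute.
#'
#' @param compounds List of [compound_record()]s.
#' @param platform Platform tag (`"EI"`, `"PCI"`, `"SIFT_H3O"`,
#'   `"SIFT_NO"`).
#' @param config A [sim_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return data.frame with columns `group` (the spectrum each peak belongs
#'   to, named after the true compound), `feature` (true compound name, or
#'   `"decoy"` for background peaks), `platform`, `ri`, `mz`, `intensity`.
#' @export
simulate_platform_peaks <- function(compounds, platform,
                                    config = sim_config(), seed = NULL) {
  compounds <- .as_compound_list(compounds)
  platform <- match.arg(platform, .PLATFORMS)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  is_gc <- platform %in% c("EI", "PCI")
  skipped <- character(0)
  rows <- lapply(compounds, function(cand) {
    preds <- tryCatch(predict_platform_ions(cand, platform),
                      error = function(e) {
                        skipped <<- c(skipped, cand$name)
                        NULL
                      })
    if (is.null(preds)) return(NULL)
    preds <- preds[preds$intensity_class != "absent", , drop = FALSE]
    ri <- if (is_gc && !is.na(cand$reference_ri)) {
      cand$reference_ri + stats::rnorm(1L, 0, config$ri_jitter_sd)
    } else {
      NA_real_
    }
    sig <- data.frame(
      group = cand$name, feature = cand$name, platform = platform, ri = ri,
      mz = preds$mz + stats::rnorm(nrow(preds), 0, config$mz_jitter_sd),
      intensity = vapply(preds$intensity_class, .band_intensity,
                         numeric(1L)) *
        stats::rlnorm(nrow(preds), 0, config$noise_cv),
      stringsAsFactors = FALSE)
    n_decoy <- stats::rpois(1L, config$decoy_rate)
    if (n_decoy > 0L) {
      dec <- data.frame(
        group = cand$name, feature = "decoy", platform = platform,
        ri = if (is_gc && !is.na(ri))
          ri + stats::rnorm(n_decoy, 0, 2 * config$ri_jitter_sd)
        else NA_real_,
        mz = stats::runif(n_decoy, config$decoy_mz_range[1L],
                          config$decoy_mz_range[2L]),
        intensity = stats::runif(n_decoy, 1, 30),
        stringsAsFactors = FALSE)
      sig <- rbind(sig, dec)
    }
    sig
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# Convert one feature's rows of a simulated table into a peak_table.
.sim_rows_to_peak_table <- function(rows, platform, sample = "sim") {
  peak_table(rows$mz, rows$intensity,
             ri = if (platform %in% c("EI", "PCI")) rows$ri else NA_real_,
             platform = platform, sample = sample)
}

#' Group simulated peak tables into cross-platform feature groups
#'
#' Joins simulated tables from several platforms by their `group` column
#' (one group per true compound spectrum, decoy background included) into
#' the peak-group structure [screen_candidates()] consumes. The observed RI
#' of a group is the mean simulated RI over its GC signal peaks.
#'
#' @param tables Named list of data.frames from
#'   [simulate_platform_peaks()]; names are platform tags.
#' @return Named list (one element per group/true compound) of
#'   `list(peaks = <named list of peak_table>, observed_ri = <numeric>,
#'   truth = <true compound name>)`.
#' @export
group_simulated_peaks <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(names(tables) %in% .PLATFORMS))
  groups <- unique(unlist(lapply(tables, function(t1) unique(t1$group))))
  out <- lapply(groups, function(g) {
    peaks <- list()
    ris <- numeric(0)
    for (pf in names(tables)) {
      rows <- tables[[pf]][tables[[pf]]$group == g, , drop = FALSE]
      if (nrow(rows) == 0L) next
      peaks[[pf]] <- .sim_rows_to_peak_table(rows, pf)
      sig <- rows[rows$feature != "decoy" & !is.na(rows$ri), , drop = FALSE]
      ris <- c(ris, sig$ri)
    }
    list(peaks = peaks,
         observed_ri = if (length(ris) > 0L) mean(ris) else NA_real_,
         truth = g)
  })
  names(out) <- groups
  out
}

#' End-to-end annotation recovery on simulated data
#'
#' Simulates peak tables for every requested platform, groups them per
#' feature, screens the full library against each group, and reports the
#' fraction of features whose top-ranked annotation is the true compound.
#'
#' @param compounds Compound library (list of [compound_record()]s).
#' @param platforms Platform tags to simulate.
#' @param config A [sim_config()].
#' @param annotation_cfg An [annotation_config()].
#' @param seed Integer seed.
#' @return List: `top1_rate` (fraction in \[0, 1\]), `n_features`, and
#'   `results` (per-feature data.frame with truth, top candidate, tier).
#' @export
recovery_benchmark <- function(compounds, platforms = .PLATFORMS,
                               config = sim_config(),
                               annotation_cfg = annotation_config(),
                               seed = NULL) {
  compounds <- .as_compound_list(compounds)
  if (!is.null(seed)) set.seed(seed)
  tables <- lapply(platforms, function(pf) {
    simulate_platform_peaks(compounds, pf, config)
  })
  names(tables) <- platforms
  groups <- group_simulated_peaks(tables)
  res <- do.call(rbind, lapply(groups, function(g) {
    screen <- screen_candidates(g$peaks, compounds, annotation_cfg,
                                observed_ri = g$observed_ri)
    data.frame(truth = g$truth, top = screen$candidate[1L],
               tier = screen$tier[1L],
               hit = screen$candidate[1L] == g$truth,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  list(top1_rate = mean(res$hit), n_features = nrow(res), results = res)
}

#' Simulate a paired calibration experiment
#'
#' Platform A responds unit-proportionally to the loading; platform B
#' responds with `true_slope * loading + true_intercept`. Both carry
#' multiplicative lognormal noise and share the loading schedule, emulating
#' paired sorbent tubes loaded from one permeation source.
#'
#' @param true_slope Inter-platform response slope.
#' @param true_intercept Intercept on platform B.
#' @param loadings Positive loadings, length >= 3.
#' @param config A [sim_config()] (`noise_cv` is used).
#' @param seed Optional integer seed.
#' @param compound,platforms Labels for the generated series.
#' @return List with elements `A` and `B`, each a [calibration_series()].
#' @export
simulate_calibration_series <- function(true_slope, true_intercept = 0,
                                        loadings, config = sim_config(),
                                        seed = NULL,
                                        compound = "synthetic",
                                        platforms = c("A", "B")) {
  stopifnot(inherits(config, "sim_config"), length(loadings) >= 3L,
            all(loadings > 0))
  if (!is.null(seed)) set.seed(seed)
  noise <- function(n) stats::rlnorm(n, 0, config$noise_cv)
  n <- length(loadings)
  resp_a <- loadings * noise(n)
  resp_b <- (true_slope * loadings + true_intercept) * noise(n)
  list(A = calibration_series(compound, platforms[1L], loadings, resp_a),
       B = calibration_series(compound, platforms[2L], loadings, resp_b))
}

#' Simulate per-sample class-composition tables for a cohort
#'
#' Per-sample class proportions are drawn from a Dirichlet distribution
#' centred on the configured medians (gamma construction, concentration
#' `composition_concentration`); infinite concentration reproduces the
#' medians exactly. Areas are scaled to an arbitrary total per sample.
#'
#' @param n_samples Number of samples (>= 1).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param total_area Total oxygenated-VOC area per sample.
#' @return data.frame with columns `sample`, `chem_class`, `area`, ready
#'   for [class_composition()].
#' @export
simulate_cohort <- function(n_samples, config = sim_config(), seed = NULL,
                            total_area = 1e6) {
  stopifnot(inherits(config, "sim_config"), n_samples >= 1L)
  if (!is.null(seed)) set.seed(seed)
  med <- config$composition_medians / 100
  conc <- config$composition_concentration
  rows <- lapply(seq_len(n_samples), function(i) {
    p <- if (is.infinite(conc)) {
      med
    } else {
      g <- stats::rgamma(length(med), shape = conc * med, rate = 1)
      if (sum(g) == 0) med else g / sum(g)
    }
    data.frame(sample = sprintf("S%03d", i), chem_class = names(med),
               area = total_area * as.numeric(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Example compound library
#'
#' Loads the small shipped library of oxygenated breath VOCs spanning every
#' supported chemical class, with reference retention indices on the
#' 624-phase column. Used by examples, tests and the simulator.
#'
#' @param path CSV path; defaults to the shipped file.
#' @return List of [compound_record()]s (a compound library).
#' @export
example_library <- function(path = system.file("extdata",
                                               "example_library.csv",
                                               package = "breathvoc")) {
  read_compound_library(path)
}
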