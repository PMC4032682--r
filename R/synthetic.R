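# Synthetic cohort generator.
#
# Emulates the class-conditional, per-site Doppler velocity statistics of a
# published 30-subject arteriovenous-fistula cohort (three stenosis classes
# x three measurement sites, mean +/- SD for the peak-systolic and
# peak-diastolic velocities), so that feature extraction, recognition-
# coefficient tuning, and classifier evaluation can run without clinical
# data.

#' Reference class-conditional velocity statistics
#'
#' Per stenosis class and measurement site, the mean and standard deviation
#' of the peak-systolic (`V_p`) and peak-diastolic (`V_m`) velocities in
#' cm/s, from a published 30-subject arteriovenous-fistula cohort
#' (12 Class I, 11 Class II, 7 Class III). These are the generator
#' defaults.
#'
#' @return Data frame with columns `dos_class`, `site`, `v_p_mean`,
#'   `v_p_sd`, `v_m_mean`, `v_m_sd` (nine rows).
#' @export
#' @examples
#' reference_velocity_stats()
reference_velocity_stats <- function() {
  data.frame(
    dos_class = factor(rep(CLASS_LEVELS, each = 3), levels = CLASS_LEVELS),
    site = factor(rep(SITE_LEVELS, times = 3), levels = SITE_LEVELS),
    v_p_mean = c(
      103.20, 64.60, 82.56,
      106.70, 54.91, 77.79,
      72.21, 25.61, 66.03
    ),
    v_p_sd = c(
      18.35, 28.05, 25.30,
      28.80, 21.54, 18.54,
      40.58, 9.62, 42.12
    ),
    v_m_mean = c(
      37.00, 28.83, 35.43,
      35.49, 16.61, 29.87,
      17.84, 7.86, 14.92
    ),
    v_m_sd = c(
      10.80, 16.61, 17.37,
      19.96, 8.69, 15.81,
      8.70, 3.84, 14.19
    )
  )
}

#' Synthetic cohort configuration
#'
#' @param class_sizes Named or positional counts for Classes I, II, III
#'   (default `c(12, 11, 7)`, the reference cohort composition).
#' @param velocity_stats Per class x site velocity statistics in the layout
#'   of [reference_velocity_stats()] (the default).
#' @param heart_rate_range Uniform sampling range for the heart rate in Hz
#'   (default `c(1.00, 1.25)`).
#' @param baseline_dh_mean,baseline_dh_sd Mean and SD (mm) of the
#'   per-subject baseline hydraulic diameter, drawn from a normal truncated
#'   below at `baseline_dh_min` (defaults 5, 0.5, truncated at 2 mm).
#' @param baseline_dh_min Lower truncation bound for the baseline diameter
#'   (mm).
#' @param dos_ranges List of per-class uniform sampling ranges for the
#'   degree of stenosis; defaults `I = c(0.05, 0.30)`,
#'   `II = c(0.30, 0.50)`, `III = c(0.50, 0.95)`, each within its class
#'   band (boundaries 0.30 and 0.50).
#' @param vp_vm_correlation Correlation between the `V_p` and `V_m` draws of
#'   one site (default 0.7): independent draws produce implausible
#'   `V_p/V_m` ratios.
#' @param ved_fraction End-diastolic velocity as a fraction of the
#'   peak-diastolic velocity (default 0.6; carried through the schema but
#'   unused by the feature vector).
#' @param stenosis_site Site whose hydraulic diameter is reduced by the
#'   stenosis (default `"L"`, the loop segment); the other sites keep the
#'   baseline diameter.
#' @param fluid A [fluid_properties()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(class_sizes = c(I = 12, II = 11, III = 7),
                          velocity_stats = reference_velocity_stats(),
                          heart_rate_range = c(1.00, 1.25),
                          baseline_dh_mean = 5,
                          baseline_dh_sd = 0.5,
                          baseline_dh_min = 2,
                          dos_ranges = list(
                            I = c(0.05, 0.30),
                            II = c(0.30, 0.50),
                            III = c(0.50, 0.95)
                          ),
                          vp_vm_correlation = 0.7,
                          ved_fraction = 0.6,
                          stenosis_site = "L",
                          fluid = fluid_properties()) {
  if (length(class_sizes) != 3L || any(class_sizes < 1)) {
    stop("`class_sizes` must give a count >= 1 for each of I, II, III",
      call. = FALSE
    )
  }
  class_sizes <- setNames(as.integer(class_sizes), CLASS_LEVELS)
  needed <- c("dos_class", "site", "v_p_mean", "v_p_sd", "v_m_mean", "v_m_sd")
  if (!all(needed %in% names(velocity_stats)) || nrow(velocity_stats) != 9L) {
    stop("`velocity_stats` must have the 9-row class x site layout of ",
      "reference_velocity_stats()",
      call. = FALSE
    )
  }
  if (any(velocity_stats$v_p_sd < 0) || any(velocity_stats$v_m_sd < 0)) {
    stop("velocity SDs must be >= 0", call. = FALSE)
  }
  if (any(velocity_stats$v_p_mean <= 0) ||
    any(velocity_stats$v_m_mean <= 0) ||
    any(velocity_stats$v_m_mean >= velocity_stats$v_p_mean)) {
    stop("velocity means must satisfy 0 < v_m_mean < v_p_mean per row ",
      "(truncated sampling would be infeasible)",
      call. = FALSE
    )
  }
  band_limits <- list(I = c(0, 0.30), II = c(0.30, 0.50), III = c(0.50, 1))
  for (cl in CLASS_LEVELS) {
    rng <- dos_ranges[[cl]]
    if (is.null(rng) || length(rng) != 2L || rng[1] > rng[2] ||
      rng[1] < band_limits[[cl]][1] || rng[2] > band_limits[[cl]][2]) {
      stop("`dos_ranges$", cl, "` must lie within the class band ",
        sprintf(
          "[%.2f, %.2f]", band_limits[[cl]][1],
          band_limits[[cl]][2]
        ),
        call. = FALSE
      )
    }
  }
  if (abs(vp_vm_correlation) >= 1) {
    stop("`vp_vm_correlation` must be in (-1, 1)", call. = FALSE)
  }
  if (!stenosis_site %in% SITE_LEVELS) {
    stop("`stenosis_site` must be one of A, L, V", call. = FALSE)
  }
  if (baseline_dh_mean <= baseline_dh_min) {
    stop("`baseline_dh_mean` must exceed `baseline_dh_min`", call. = FALSE)
  }
  structure(
    list(
      class_sizes = class_sizes,
      velocity_stats = velocity_stats,
      heart_rate_range = heart_rate_range,
      baseline_dh_mean = baseline_dh_mean,
      baseline_dh_sd = baseline_dh_sd,
      baseline_dh_min = baseline_dh_min,
      dos_ranges = dos_ranges,
      vp_vm_correlation = vp_vm_correlation,
      ved_fraction = ved_fraction,
      stenosis_site = stenosis_site,
      fluid = fluid
    ),
    class = "cohort_config"
  )
}

# One correlated (V_p, V_m) draw, resampled until 0 < V_m < V_p.
.draw_vp_vm <- function(stats_row, correlation, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    z1 <- rnorm(1)
    z2 <- correlation * z1 + sqrt(1 - correlation^2) * rnorm(1)
    v_p <- stats_row$v_p_mean + stats_row$v_p_sd * z1
    v_m <- stats_row$v_m_mean + stats_row$v_m_sd * z2
    if (v_p > 0 && v_m > 0 && v_m < v_p) {
      return(c(v_p = v_p, v_m = v_m))
    }
  }
  stop("could not draw velocities with 0 < V_m < V_p after ", max_tries,
    " tries; check the configured velocity statistics",
    call. = FALSE
  )
}

# Normal draw truncated below.
.draw_truncated_normal <- function(mean, sd, lower, max_tries = 1000L) {
  if (sd == 0) {
    if (mean <= lower) stop("infeasible truncation", call. = FALSE)
    return(mean)
  }
  for (try in seq_len(max_tries)) {
    x <- rnorm(1, mean, sd)
    if (x > lower) {
      return(x)
    }
  }
  stop("infeasible truncation: mean ", mean, ", sd ", sd, ", lower ", lower,
    call. = FALSE
  )
}

#' Sample a labelled synthetic cohort
#'
#' Generates one measurement row per subject-site. Per subject: the class
#' label follows the configured class sizes; the degree of stenosis is
#' uniform in the class band; a baseline hydraulic diameter is drawn once
#' and reduced at the stenosis site to
#' `d_H = D_H * sqrt(1 - DOS)`; the heart rate is uniform in its range; per
#' site, `(V_p, V_m)` are drawn from correlated truncated normals with the
#' configured class x site statistics; `V_ed` is a fixed fraction of `V_m`.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; when given, the RNG is seeded first,
#'   making the cohort reproducible.
#' @return Data frame in the measurement schema, one row per subject-site:
#'   `subject_id, site, V_p_cm_s, V_m_cm_s, V_ed_cm_s, heart_rate_hz,
#'   D_H_mm, dos, dos_class`.
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_config(), seed = 1)
#' table(cohort$dos_class) / 3 # subjects per class
sample_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n_subjects <- sum(config$class_sizes)
  classes <- rep(CLASS_LEVELS, times = config$class_sizes)
  ids <- sprintf("S%03d", seq_len(n_subjects))
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cl <- classes[s]
    dos <- runif(1, config$dos_ranges[[cl]][1], config$dos_ranges[[cl]][2])
    dh_base <- .draw_truncated_normal(
      config$baseline_dh_mean,
      config$baseline_dh_sd,
      config$baseline_dh_min
    )
    hr <- runif(1, config$heart_rate_range[1], config$heart_rate_range[2])
    d_h <- setNames(rep(dh_base, 3), SITE_LEVELS)
    d_h[config$stenosis_site] <- dh_base * sqrt(1 - dos)
    site_rows <- lapply(SITE_LEVELS, function(site) {
      stats_row <- config$velocity_stats[
        config$velocity_stats$dos_class == cl &
          config$velocity_stats$site == site, ,
        drop = FALSE
      ]
      v <- .draw_vp_vm(stats_row, config$vp_vm_correlation)
      data.frame(
        subject_id = ids[s],
        site = site,
        V_p_cm_s = v[["v_p"]],
        V_m_cm_s = v[["v_m"]],
        V_ed_cm_s = config$ved_fraction * v[["v_m"]],
        heart_rate_hz = hr,
        D_H_mm = d_h[[site]],
        dos = dos,
        dos_class = cl
      )
    })
    rows[[s]] <- do.call(rbind, site_rows)
  }
  out <- do.call(rbind, rows)
  out$site <- factor(out$site, levels = SITE_LEVELS)
  out$dos_class <- factor(out$dos_class, levels = CLASS_LEVELS)
  rownames(out) <- NULL
  out
}
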