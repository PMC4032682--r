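# Shared fixtures, all built in code.

# Feature-pattern prototypes for three clearly separated stenosis classes,
# shaped like real per-unit ratio / resistive-index patterns: Class I ratios
# near 1 with normal-range resistive indices, Class II ratios below 1 with
# raised indices, Class III ratios well above 1 with high indices.
class_prototypes <- function() {
  rbind(
    I = c(0.95, 1, 0.98, 0.60, 0.55, 0.58),
    II = c(0.78, 1, 0.90, 0.72, 0.66, 0.66),
    III = c(1.35, 1, 1.30, 0.78, 0.70, 0.70)
  )
}

# A small separated training set: each class prototype plus deterministic
# offsets much smaller than the between-class distances.
make_separated_training <- function(per_class = 4) {
  proto <- class_prototypes()
  offsets <- seq(-0.015, 0.015, length.out = per_class)
  patterns <- do.call(rbind, lapply(rownames(proto), function(cl) {
    t(vapply(offsets, function(o) proto[cl, ] + o, numeric(6)))
  }))
  colnames(patterns) <- c(
    "ratio_A", "ratio_L", "ratio_V",
    "res_A", "res_L", "res_V"
  )
  list(
    patterns = patterns,
    classes = factor(rep(c("I", "II", "III"), each = per_class),
      levels = c("I", "II", "III")
    )
  )
}

# Cohort configuration with well-separated classes: the reference velocity
# means with standard deviations scaled down to 20%, so class-conditional
# feature clouds barely overlap. Used for the property-style pipeline
# invariants, which are statements about separable cohorts.
well_separated_config <- function(class_sizes = c(I = 12, II = 11, III = 7)) {
  stats <- reference_velocity_stats()
  stats$v_p_sd <- 0.2 * stats$v_p_sd
  stats$v_m_sd <- 0.2 * stats$v_m_sd
  cohort_config(class_sizes = class_sizes, velocity_stats = stats)
}

# Measurement table for one subject with identical sites.
identical_sites_subject <- function(v_p = 80, v_m = 30, hr = 1.1, dh = 5) {
  data.frame(
    subject_id = "S1",
    site = c("A", "L", "V"),
    V_p_cm_s = v_p, V_m_cm_s = v_m, V_ed_cm_s = 0.6 * v_m,
    heart_rate_hz = hr, D_H_mm = dh
  )
}

# Regular n-gon inscribed in a circle of diameter d: area and side lengths.
ngon_cross_section <- function(n, diameter = 1) {
  r <- diameter / 2
  list(
    area = 0.5 * n * r^2 * sin(2 * pi / n),
    segments = rep(2 * r * sin(pi / n), n)
  )
}
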