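# Assembly of the six-feature pattern used by the classifier:
# Phi = [Ratio_A, Ratio_L, Ratio_V, Res_A, Res_L, Res_V].

FEATURE_NAMES <- c("ratio_A", "ratio_L", "ratio_V", "res_A", "res_L", "res_V")

#' Build the six-feature pattern for one subject
#'
#' Takes the three site measurements (arterial anastomosis `A`, loop `L`,
#' venous anastomosis `V`) of one subject, computes each site's
#' dimensionless profile with [hemodynamic_profile()], and assembles the
#' pattern vector
#' `[Ratio_A, Ratio_L, Ratio_V, Res_A, Res_L, Res_V]`, where the first
#' three entries are the per-unit supracritical-Reynolds ratios (loop entry
#' 1 by construction) and the last three are the site resistive indices.
#'
#' @param measurements Data frame with exactly one row per site, containing
#'   columns `site` (values `A`, `L`, `V`), `V_p_cm_s`, `V_m_cm_s`,
#'   `heart_rate_hz`, `D_H_mm`.
#' @param fluid A [fluid_properties()].
#' @return Named numeric vector of length 6 with names
#'   `ratio_A, ratio_L, ratio_V, res_A, res_L, res_V`.
#' @export
#' @examples
#' m <- data.frame(
#'   site = c("A", "L", "V"),
#'   V_p_cm_s = c(103.2, 64.6, 82.6),
#'   V_m_cm_s = c(37.0, 28.8, 35.4),
#'   heart_rate_hz = 1.1,
#'   D_H_mm = 5
#' )
#' build_feature_vector(m)
build_feature_vector <- function(measurements, fluid = fluid_properties()) {
  required <- c("site", "V_p_cm_s", "V_m_cm_s", "heart_rate_hz", "D_H_mm")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  site <- as.character(measurements$site)
  if (nrow(measurements) != 3L || !setequal(site, SITE_LEVELS) ||
    anyDuplicated(site)) {
    stop("a subject needs exactly one measurement per site A, L, V",
      call. = FALSE
    )
  }
  m <- measurements[match(SITE_LEVELS, site), , drop = FALSE]
  prof <- hemodynamic_profile(
    m$V_p_cm_s, m$V_m_cm_s, m$heart_rate_hz, m$D_H_mm,
    fluid = fluid
  )
  ratios <- supra_ratios(prof$Re_supra[1], prof$Re_supra[2], prof$Re_supra[3])
  setNames(c(ratios, prof$Res), FEATURE_NAMES)
}

#' Featurize a cohort of site measurements
#'
#' Converts a long measurement table (one row per subject-site) into the
#' wide per-subject feature table consumed by the classifier. Label columns
#' (`dos`, `dos_class`), when present, are carried through.
#'
#' @param measurements Data frame in the measurement schema
#'   (`subject_id, site, V_p_cm_s, V_m_cm_s, V_ed_cm_s, heart_rate_hz,
#'   D_H_mm[, dos, dos_class]`), e.g. from [sample_cohort()] or
#'   [read_measurements()].
#' @param fluid A [fluid_properties()].
#' @return Data frame with one row per subject: `subject_id`, the six
#'   feature columns `ratio_A ... res_V`, plus `dos`/`dos_class` when
#'   available.
#' @export
featurize <- function(measurements, fluid = fluid_properties()) {
  if (!"subject_id" %in% names(measurements)) {
    stop("`measurements` must have a `subject_id` column", call. = FALSE)
  }
  ids <- unique(measurements$subject_id)
  phi <- t(vapply(
    ids,
    function(id) {
      rows <- measurements[measurements$subject_id == id, , drop = FALSE]
      tryCatch(
        build_feature_vector(rows, fluid = fluid),
        error = function(e) {
          stop("subject ", id, ": ", conditionMessage(e), call. = FALSE)
        }
      )
    },
    numeric(6)
  ))
  out <- data.frame(subject_id = ids, phi, row.names = NULL)
  for (lab in c("dos", "dos_class")) {
    if (lab %in% names(measurements)) {
      out[[lab]] <- measurements[[lab]][match(ids, measurements$subject_id)]
    }
  }
  if ("dos_class" %in% names(out)) {
    out$dos_class <- factor(as.character(out$dos_class), levels = CLASS_LEVELS)
  }
  out
}

# Extract the K x 6 feature matrix from a featurized data frame (or pass a
# matrix through), checking shape and names.
.feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    missing_cols <- setdiff(FEATURE_NAMES, names(features))
    if (length(missing_cols)) {
      stop("missing feature column(s): ",
        paste(missing_cols, collapse = ", "),
        call. = FALSE
      )
    }
    features <- as.matrix(features[, FEATURE_NAMES, drop = FALSE])
  }
  if (!is.matrix(features) || ncol(features) != 6L) {
    stop("features must be a K x 6 matrix or data frame", call. = FALSE)
  }
  if (any(!is.finite(features)) || any(features < 0)) {
    stop("feature patterns must be finite and >= 0", call. = FALSE)
  }
  colnames(features) <- FEATURE_NAMES
  features
}
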