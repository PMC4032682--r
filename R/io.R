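# CSV and model-file I/O.
#
# Measurement tables are comma-separated UTF-8 with a mandatory header and
# '.' decimals; files written by this package carry provenance comment
# lines ('# ...') which the readers skip.

MEASUREMENT_COLUMNS <- c(
  "subject_id", "site", "V_p_cm_s", "V_m_cm_s", "V_ed_cm_s",
  "heart_rate_hz", "D_H_mm"
)

MODEL_SCHEMA_VERSION <- 1L

.provenance_header <- function(seed = NULL) {
  paste0(
    "# avscreen ", as.character(packageVersion("avscreen")),
    if (!is.null(seed)) paste0(" seed=", seed) else ""
  )
}

#' Read a site-measurement CSV
#'
#' Reads and validates the long measurement table (one row per
#' subject-site). All rows are checked and every violation is reported with
#' its line context before the function stops.
#'
#' @param path Path to a CSV with header
#'   `subject_id,site,V_p_cm_s,V_m_cm_s,V_ed_cm_s,heart_rate_hz,D_H_mm`
#'   and optional `dos`, `dos_class` columns. Comment lines starting with
#'   `#` are ignored.
#' @return Validated data frame with `site` (and `dos_class`, if present)
#'   as factors.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path,
    comment.char = "#", stringsAsFactors = FALSE,
    strip.white = TRUE
  )
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("measurement file lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, paste0(
        "row ", paste(rows, collapse = ","),
        ": ", msg
      ))
    }
  }
  for (col in c("V_p_cm_s", "V_m_cm_s", "V_ed_cm_s", "heart_rate_hz", "D_H_mm")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    note(which(is.na(df[[col]])), paste0("non-numeric ", col))
  }
  note(which(!df$site %in% SITE_LEVELS), "site must be one of A, L, V")
  note(which(df$V_p_cm_s <= 0), "V_p_cm_s must be > 0")
  note(which(df$V_m_cm_s <= 0), "V_m_cm_s must be > 0")
  note(
    which(df$V_m_cm_s > df$V_p_cm_s),
    "V_m_cm_s exceeds V_p_cm_s (peak-systolic/peak-diastolic swapped?)"
  )
  note(which(df$heart_rate_hz <= 0), "heart_rate_hz must be > 0")
  note(which(df$D_H_mm <= 0), "D_H_mm must be > 0")
  dup <- duplicated(df[, c("subject_id", "site")])
  note(which(dup), "duplicate (subject_id, site)")
  site_counts <- table(df$subject_id[df$site %in% SITE_LEVELS])
  incomplete <- names(site_counts)[site_counts != 3L]
  if (length(incomplete)) {
    problems <- c(problems, paste0(
      "subject(s) lacking one of sites A/L/V: ",
      paste(incomplete, collapse = ", ")
    ))
  }
  if (length(problems)) {
    stop("invalid measurement file ", path, ":\n  ",
      paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  df$site <- factor(df$site, levels = SITE_LEVELS)
  if ("dos_class" %in% names(df)) {
    df$dos_class <- factor(as.character(df$dos_class), levels = CLASS_LEVELS)
  }
  df
}

#' Write a site-measurement CSV
#'
#' Writes the measurement table with a provenance comment header
#' (tool version and, when given, the generating seed), in a form
#' [read_measurements()] accepts.
#'
#' @param measurements Measurement data frame.
#' @param path Output path.
#' @param seed Optional integer recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_header(seed), con)
  write.table(measurements, con,
    sep = ",", row.names = FALSE,
    quote = FALSE
  )
  invisible(path)
}

#' Write a feature or classification table
#'
#' CSV writer with the same provenance header as [write_measurements()];
#' numeric columns are printed with four decimals (hue angles and decision
#' values are conventionally reported at that precision).
#'
#' @param x Data frame (features from [featurize()] or predictions from
#'   [predict.cra_model()]).
#' @param path Output path.
#' @param seed Optional integer recorded in the provenance header.
#' @param digits Decimal places for numeric columns (default 4).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, seed = NULL, digits = 4) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(col) sprintf("%.*f", digits, col))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_header(seed), con)
  write.table(y, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a CRA model as JSON
#'
#' Persists the training patterns, class labels, recognition coefficient
#' and decision conventions in a versioned JSON schema. Round-tripping a
#' model through [save_cra_model()]/[load_cra_model()] preserves
#' classification behavior bit for bit.
#'
#' @param model A [cra_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_cra_model <- function(model, path) {
  stopifnot(inherits(model, "cra_model"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    tool = paste0("avscreen ", as.character(packageVersion("avscreen"))),
    xi = model$xi,
    convention = model$convention,
    error_mode = model$error_mode,
    rescale_grades = model$rescale_grades,
    classes = as.character(model$classes),
    feature_names = colnames(model$patterns),
    patterns = unname(apply(model$patterns, 1L, as.numeric, simplify = FALSE))
  )
  # I(17) significant digits: doubles survive the round-trip bit for bit
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = I(17),
    pretty = TRUE
  )
  invisible(path)
}

#' Load a CRA model from JSON
#'
#' @param path Path to a file written by [save_cra_model()].
#' @return A [cra_model()].
#' @export
load_cra_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema_version) ||
    payload$schema_version != MODEL_SCHEMA_VERSION) {
    stop("unsupported model schema version: ",
      if (is.null(payload$schema_version)) {
        "missing"
      } else {
        payload$schema_version
      },
      " (expected ", MODEL_SCHEMA_VERSION, ")",
      call. = FALSE
    )
  }
  if (is.null(payload$xi) || !is.numeric(payload$xi) || payload$xi <= 0) {
    stop("invalid model file: recognition coefficient xi must be > 0",
      call. = FALSE
    )
  }
  patterns <- payload$patterns
  if (is.list(patterns)) patterns <- do.call(rbind, patterns)
  colnames(patterns) <- payload$feature_names
  cra_model(
    patterns,
    classes = payload$classes,
    xi = payload$xi,
    convention = payload$convention,
    error_mode = payload$error_mode,
    rescale_grades = isTRUE(payload$rescale_grades)
  )
}
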