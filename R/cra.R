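# Color relation analysis (CRA) classifier.
#
# A query pattern is compared with every class-labelled training pattern by
# Euclidean distance; the distances are turned into exponential similarity
# ("gray") grades, the grades are averaged per stenosis class, and the three
# class averages are pushed through an HSV-style color transform whose hue
# angle is the scalar decision variable: blue (240 deg) for Class I, green
# (120 deg) for Class II, red (0/360 deg) for Class III.

#' Euclidean distance between two feature patterns
#'
#' @param phi_r,phi_c Numeric vectors of equal length (the six-feature
#'   patterns of the query and one training subject).
#' @return `sqrt(sum((phi_r - phi_c)^2))`.
#' @export
euclidean_distance <- function(phi_r, phi_c) {
  if (length(phi_r) != length(phi_c)) {
    stop("patterns have different lengths", call. = FALSE)
  }
  if (any(!is.finite(phi_r)) || any(!is.finite(phi_c))) {
    stop("patterns must be finite", call. = FALSE)
  }
  sqrt(sum((phi_r - phi_c)^2))
}

# Distances from one query to every row of a training matrix.
.pattern_distances <- function(phi, patterns) {
  sqrt(colSums((t(patterns) - phi)^2))
}

#' Gray grade: exponential similarity of a pattern distance
#'
#' `rho = xi * exp(-xi * ED)`. The recognition coefficient `xi` sets the
#' sharpness of the similarity: the grade equals `xi` at zero distance and
#' decays strictly monotonically with `ED`.
#'
#' @param ed Euclidean distance(s), >= 0.
#' @param xi Recognition coefficient, > 0.
#' @return Grades in `(0, xi]`, same length as `ed`.
#' @export
gray_grade <- function(ed, xi) {
  .check_nonnegative(ed, "ed")
  .check_positive(xi, "xi")
  xi * exp(-xi * ed)
}

#' Class-average gray grades
#'
#' Averages the per-training-pattern grades within each stenosis class and
#' reports the extreme class means.
#'
#' @param rho Numeric vector of gray grades, one per training pattern.
#' @param classes Class labels (`I`, `II`, `III`), same length as `rho`;
#'   every class must be represented.
#' @return List with `rho_ave` (named numeric, one mean per class),
#'   `rho_min` and `rho_max`.
#' @export
class_average_grades <- function(rho, classes) {
  classes <- factor(as.character(classes), levels = CLASS_LEVELS)
  if (length(rho) != length(classes)) {
    stop("`rho` and `classes` lengths differ", call. = FALSE)
  }
  if (anyNA(classes)) {
    stop("class labels must be I, II or III", call. = FALSE)
  }
  if (!all(CLASS_LEVELS %in% classes)) {
    stop("every class (I, II, III) needs at least one training pattern",
      call. = FALSE
    )
  }
  ave <- vapply(
    CLASS_LEVELS, function(cl) mean(rho[classes == cl]),
    numeric(1)
  )
  list(rho_ave = ave, rho_min = min(ave), rho_max = max(ave))
}

# Winning class when several class means tie at the maximum: severity first.
.winning_class <- function(rho_ave) {
  winners <- CLASS_LEVELS[rho_ave == max(rho_ave)]
  for (cl in c("III", "II", "I")) {
    if (cl %in% winners) {
      return(list(class = cl, tie = length(winners) > 1L))
    }
  }
}

#' HSV-style color transform of the class-average grades
#'
#' Maps the three class-average gray grades onto normalized RGB channels
#' `r = (rho_max - rho_ave_III) / delta`, `g = (rho_max - rho_ave_I) /
#' delta`, `b = (rho_max - rho_ave_II) / delta` (with
#' `delta = rho_max - rho_min`), then to a hue angle, saturation
#' `S = (gamma - rho_min) / gamma` and value `gamma = rho_max`. The hue
#' branch is chosen by which class mean attains `rho_max`; the branch
#' offsets depend on `convention`:
#'
#' * `"class_centered"` (default): Class I maps near 240 degrees (blue),
#'   Class II near 120 (green), Class III near 0/360 (red), matching the
#'   critical decisions `H_C = (2/3, 1/3, 1)`.
#' * `"as_printed"`: the alternative layout with the Class I branch at
#'   +120 degrees and Class II at +240.
#'
#' Each branch spans at most 60 degrees either side of its offset. The hue
#' is undefined (and an error raised) when all three class means coincide.
#'
#' @param rho_ave Numeric vector of the three class-average grades, in class
#'   order `I, II, III` (names optional).
#' @param convention Hue branch convention, see above.
#' @return List with `r`, `g`, `b` (each in `[0, 1]`, at least one 0 and
#'   one 1), `H` (degrees in `[0, 360)`), `S`, `gamma`, `winning_class`
#'   and `low_confidence` (TRUE when two class means tie at the maximum).
#' @export
#' @examples
#' hsv_transform(c(I = 0.9, II = 0.3, III = 0.1))
hsv_transform <- function(rho_ave,
                          convention = c("class_centered", "as_printed")) {
  convention <- match.arg(convention)
  if (length(rho_ave) != 3L || any(!is.finite(rho_ave))) {
    stop("`rho_ave` must be three finite class means", call. = FALSE)
  }
  rho_ave <- setNames(as.numeric(rho_ave), CLASS_LEVELS)
  rho_max <- max(rho_ave)
  rho_min <- min(rho_ave)
  if (rho_max == rho_min) {
    stop("degenerate hue: all class-average grades are equal ",
      "(rho_min = rho_max)",
      call. = FALSE
    )
  }
  delta <- rho_max - rho_min
  r <- (rho_max - rho_ave[["III"]]) / delta
  g <- (rho_max - rho_ave[["I"]]) / delta
  b <- (rho_max - rho_ave[["II"]]) / delta
  win <- .winning_class(rho_ave)
  offsets <- switch(convention,
    class_centered = c(I = 240, II = 120, III = 360),
    as_printed = c(I = 120, II = 240, III = 360)
  )
  diff <- switch(win$class,
    I = b - r,
    II = r - g,
    III = g - b
  )
  h <- (60 * diff + offsets[[win$class]]) %% 360
  list(
    r = unname(r), g = unname(g), b = unname(b),
    H = unname(h),
    S = (rho_max - rho_min) / rho_max,
    gamma = rho_max,
    winning_class = win$class,
    low_confidence = win$tie
  )
}

#' Hue angle to the scalar decision variable
#'
#' @param h Hue angle in degrees, `0 <= h <= 360`.
#' @return `h / 360` in `[0, 1]`.
#' @export
hue_to_hc <- function(h) {
  if (any(!is.finite(h)) || any(h < 0) || any(h > 360)) {
    stop("`h` must be in [0, 360] degrees", call. = FALSE)
  }
  h / 360
}

#' Construct a color relation analysis classifier
#'
#' Bundles the class-labelled training patterns with the recognition
#' coefficient and the decision conventions. Use [cra_train()] to pick the
#' recognition coefficient by particle swarm optimization instead of fixing
#' it by hand.
#'
#' @param features Training patterns: a data frame from [featurize()] or a
#'   `K x 6` matrix with columns `ratio_A ... res_V`.
#' @param classes Stenosis class labels (`I`, `II`, `III`), one per training
#'   pattern; all three classes must be represented. May be omitted when
#'   `features` is a data frame with a `dos_class` column.
#' @param xi Recognition coefficient, > 0.
#' @param convention Hue branch convention, see [hsv_transform()].
#' @param error_mode Error definition for [msef()]: `"wrapped"` (circular
#'   hue error, default) or `"plain"`.
#' @param rescale_grades If TRUE, min--max rescale the gray grades to
#'   `[0, 1]` before class averaging (an optional intensity adjustment;
#'   default FALSE keeps the plain class averages).
#' @return Object of class `cra_model`.
#' @export
cra_model <- function(features, classes = NULL, xi = 1,
                      convention = c("class_centered", "as_printed"),
                      error_mode = c("wrapped", "plain"),
                      rescale_grades = FALSE) {
  convention <- match.arg(convention)
  error_mode <- match.arg(error_mode)
  if (is.null(classes)) {
    if (is.data.frame(features) && "dos_class" %in% names(features)) {
      classes <- features$dos_class
    } else {
      stop("`classes` is required unless `features` has a `dos_class` column",
        call. = FALSE
      )
    }
  }
  patterns <- .feature_matrix(features)
  classes <- factor(as.character(classes), levels = CLASS_LEVELS)
  if (nrow(patterns) != length(classes)) {
    stop("number of patterns and class labels differ", call. = FALSE)
  }
  if (anyNA(classes)) {
    stop("class labels must be I, II or III", call. = FALSE)
  }
  if (any(table(classes) == 0L)) {
    stop("every class (I, II, III) needs at least one training pattern",
      call. = FALSE
    )
  }
  .check_positive(xi, "xi")
  structure(
    list(
      patterns = patterns,
      classes = classes,
      xi = xi,
      convention = convention,
      error_mode = error_mode,
      rescale_grades = rescale_grades
    ),
    class = "cra_model"
  )
}

#' @export
print.cra_model <- function(x, ...) {
  cat("Color relation analysis classifier\n")
  cat(sprintf(
    "  training patterns: %d (I: %d, II: %d, III: %d)\n",
    nrow(x$patterns),
    sum(x$classes == "I"), sum(x$classes == "II"), sum(x$classes == "III")
  ))
  cat(sprintf("  recognition coefficient xi: %.4f\n", x$xi))
  cat(sprintf(
    "  hue convention: %s; error mode: %s\n",
    x$convention, x$error_mode
  ))
  if (!is.null(attr(x, "training_msef"))) {
    cat(sprintf(
      "  leave-one-out MSEF at xi: %.4f\n",
      attr(x, "training_msef")
    ))
  }
  invisible(x)
}

# Optional intensity adjustment: min-max rescale of the grades to [0, 1].
.rescale_grades <- function(rho) {
  rng <- range(rho)
  if (rng[1] == rng[2]) {
    return(rho) # flat grades: leave untouched, downstream flags degeneracy
  }
  (rho - rng[1]) / (rng[2] - rng[1])
}

#' Classify one feature pattern
#'
#' Runs the full CRA chain for one query pattern: Euclidean distances to all
#' training patterns, gray grades, class-average grades, HSV transform, hue
#' decision variable, and the predicted class (the class whose critical
#' decision value is closest to `H_C` in circular distance on the unit
#' interval). The decision centers follow the model's hue convention:
#' `(2/3, 1/3, 1)` for `class_centered`, with the Class I/II centers
#' swapped under `as_printed`.
#'
#' @param phi Numeric vector of length 6 (order
#'   `ratio_A, ratio_L, ratio_V, res_A, res_L, res_V`).
#' @param model A [cra_model()].
#' @return Object of class `cra_result`: a list with `grades`, `rho_ave`,
#'   `rho_min`, `rho_max`, `rgb`, `H` (degrees), `S`, `gamma`, `hc`,
#'   `predicted_class` (factor, `NA` if unclassifiable), `low_confidence`
#'   and `unclassifiable`.
#' @export
classify_pattern <- function(phi, model) {
  stopifnot(inherits(model, "cra_model"))
  if (length(phi) != 6L || any(!is.finite(phi))) {
    stop("`phi` must be a finite vector of length 6", call. = FALSE)
  }
  ed <- .pattern_distances(as.numeric(phi), model$patterns)
  rho <- gray_grade(ed, model$xi)
  if (isTRUE(model$rescale_grades)) rho <- .rescale_grades(rho)
  cag <- class_average_grades(rho, model$classes)
  hsv <- tryCatch(
    hsv_transform(cag$rho_ave, model$convention),
    error = function(e) NULL
  )
  if (is.null(hsv)) {
    res <- list(
      grades = rho, rho_ave = cag$rho_ave,
      rho_min = cag$rho_min, rho_max = cag$rho_max,
      rgb = c(r = NA_real_, g = NA_real_, b = NA_real_),
      H = NA_real_, S = NA_real_, gamma = cag$rho_max, hc = NA_real_,
      predicted_class = factor(NA, levels = CLASS_LEVELS),
      low_confidence = TRUE, unclassifiable = TRUE
    )
    return(structure(res, class = "cra_result"))
  }
  hc <- hue_to_hc(hsv$H)
  centers <- .decision_centers(model$convention)
  dist_to_centers <- .circular_distance(hc, centers)
  predicted <- CLASS_LEVELS[which.min(dist_to_centers)]
  structure(
    list(
      grades = rho, rho_ave = cag$rho_ave,
      rho_min = cag$rho_min, rho_max = cag$rho_max,
      rgb = c(r = hsv$r, g = hsv$g, b = hsv$b),
      H = hsv$H, S = hsv$S, gamma = hsv$gamma, hc = hc,
      predicted_class = factor(predicted, levels = CLASS_LEVELS),
      low_confidence = hsv$low_confidence, unclassifiable = FALSE
    ),
    class = "cra_result"
  )
}

#' @export
print.cra_result <- function(x, ...) {
  if (x$unclassifiable) {
    cat("CRA result: unclassifiable (degenerate hue)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "CRA result: Class %s  (H = %.4f deg, H_C = %.4f, S = %.4f)%s\n",
    as.character(x$predicted_class), x$H, x$hc, x$S,
    if (x$low_confidence) "  [low confidence]" else ""
  ))
  invisible(x)
}

#' Classify a table of feature patterns
#'
#' @param object A [cra_model()].
#' @param newdata Feature data frame (from [featurize()]) or `K x 6` matrix.
#' @param ... Unused.
#' @return Data frame with one row per query: `subject_id` (when present in
#'   `newdata`), `H_deg`, `S`, `HC`, `predicted_class`, `low_confidence`.
#' @export
predict.cra_model <- function(object, newdata, ...) {
  ids <- if (is.data.frame(newdata) && "subject_id" %in% names(newdata)) {
    newdata$subject_id
  } else {
    NULL
  }
  mat <- .feature_matrix(newdata)
  results <- apply(mat, 1L, classify_pattern, model = object)
  out <- data.frame(
    H_deg = vapply(results, `[[`, numeric(1), "H"),
    S = vapply(results, `[[`, numeric(1), "S"),
    HC = vapply(results, `[[`, numeric(1), "hc"),
    predicted_class = factor(
      vapply(results, function(r) as.character(r$predicted_class), ""),
      levels = CLASS_LEVELS
    ),
    low_confidence = vapply(results, `[[`, logical(1), "low_confidence")
  )
  if (!is.null(ids)) out <- cbind(subject_id = ids, out)
  out
}

#' Mean squared error of the hue decisions
#'
#' Compares predicted decision values `H_C` with the class targets
#' `T = (2/3, 1/3, 1)` for Classes I--III. In `"wrapped"` mode the error is
#' the circular distance on the unit hue interval,
#' `min(|T - H_C|, 1 - |T - H_C|)`, so a Class III hue just above 0 degrees
#' counts as close to the red target at 360; `"plain"` mode uses the literal
#' difference.
#'
#' @param hc Predicted decision values in `[0, 1]`.
#' @param classes True class labels (`I`, `II`, `III`), same length.
#' @param error_mode `"wrapped"` (default) or `"plain"`.
#' @return Mean of the squared errors.
#' @export
msef <- function(hc, classes, error_mode = c("wrapped", "plain")) {
  error_mode <- match.arg(error_mode)
  classes <- factor(as.character(classes), levels = CLASS_LEVELS)
  if (length(hc) == 0L) stop("empty input", call. = FALSE)
  if (length(hc) != length(classes)) {
    stop("`hc` and `classes` lengths differ", call. = FALSE)
  }
  if (anyNA(classes)) stop("class labels must be I, II or III", call. = FALSE)
  targets <- CRITICAL_HC[as.character(classes)]
  err <- switch(error_mode,
    wrapped = .circular_distance(hc, targets),
    plain = targets - hc
  )
  mean(err^2)
}

#' Accuracy and confusion table of a CRA model on labelled patterns
#'
#' @param model A [cra_model()].
#' @param features Labelled feature data frame or `K x 6` matrix.
#' @param classes True class labels; may be omitted when `features` has a
#'   `dos_class` column. Unclassifiable patterns count as errors.
#' @return List with `accuracy` (fraction correct), `confusion` (3 x 3
#'   table, true class in rows) and `n`.
#' @export
cra_evaluate <- function(model, features, classes = NULL) {
  if (is.null(classes)) {
    if (is.data.frame(features) && "dos_class" %in% names(features)) {
      classes <- features$dos_class
    } else {
      stop("`classes` is required unless `features` has a `dos_class` column",
        call. = FALSE
      )
    }
  }
  classes <- factor(as.character(classes), levels = CLASS_LEVELS)
  if (length(classes) == 0L || anyNA(classes)) {
    stop("true class labels must be I, II or III (nonempty)", call. = FALSE)
  }
  pred <- predict(model, features)$predicted_class
  confusion <- table(true = classes, predicted = pred, useNA = "no")
  correct <- sum(!is.na(pred) & pred == classes)
  list(
    accuracy = correct / length(classes),
    confusion = confusion,
    n = length(classes)
  )
}

# ---- leave-one-out fitness --------------------------------------------------

# Pairwise Euclidean distance matrix between the rows of a pattern matrix.
.pairwise_distances <- function(patterns) {
  as.matrix(stats::dist(patterns, method = "euclidean"))
}

# Leave-one-out hue decisions from a precomputed K x K distance matrix.
# Returns hc values (NA where the hue is degenerate). Used as the PSO
# fitness kernel, so it avoids re-deriving distances per xi.
.loo_hc_from_ed <- function(ed, classes, xi, convention, rescale_grades) {
  k <- nrow(ed)
  rho_all <- xi * exp(-xi * ed)
  hc <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    rho <- rho_all[i, -i]
    cls <- classes[-i]
    if (isTRUE(rescale_grades)) rho <- .rescale_grades(rho)
    ave <- vapply(
      CLASS_LEVELS, function(cl) mean(rho[cls == cl]),
      numeric(1)
    )
    hsv <- tryCatch(hsv_transform(ave, convention), error = function(e) NULL)
    if (!is.null(hsv)) hc[i] <- hsv$H / 360
  }
  hc
}

.loo_msef_from_ed <- function(ed, classes, xi, convention, error_mode,
                              rescale_grades, degenerate_penalty = 0.5) {
  hc <- .loo_hc_from_ed(ed, classes, xi, convention, rescale_grades)
  targets <- .decision_centers(convention)[as.character(classes)]
  err <- switch(error_mode,
    wrapped = .circular_distance(hc, targets),
    plain = targets - hc
  )
  err[is.na(err)] <- degenerate_penalty
  mean(err^2)
}

#' Leave-one-out MSEF of the CRA classifier on a training set
#'
#' Each training pattern is classified against the remaining `K - 1`
#' patterns (leaving it out avoids the self-match at distance zero) and the
#' resulting decision values are scored with [msef()] against the class
#' targets. This is the fitness minimized when tuning the recognition
#' coefficient. A pattern whose leave-one-out hue is degenerate is scored
#' with the maximum wrapped error 0.5.
#'
#' @inheritParams cra_model
#' @param xi Recognition coefficient, > 0.
#' @return The leave-one-out mean squared error.
#' @export
cra_loo_msef <- function(features, classes = NULL, xi,
                         convention = c("class_centered", "as_printed"),
                         error_mode = c("wrapped", "plain"),
                         rescale_grades = FALSE) {
  convention <- match.arg(convention)
  error_mode <- match.arg(error_mode)
  model <- cra_model(features, classes,
    xi = xi, convention = convention,
    error_mode = error_mode, rescale_grades = rescale_grades
  )
  ed <- .pairwise_distances(model$patterns)
  .loo_msef_from_ed(
    ed, model$classes, xi, convention, error_mode,
    rescale_grades
  )
}
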