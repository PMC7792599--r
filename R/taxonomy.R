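# Label taxonomies for the two mobility tests.
#
# Class orderings are fixed constants so that integer label codes are stable
# across runs and across machines.

#' Feature column names used throughout the package
#'
#' The six clinical features recorded per test repetition: completion time in
#' seconds, age in years, height in metres, weight in kilograms, body mass
#' index in kg/m2, and sex coded 0 = female, 1 = male.
#'
#' @return Character vector of the six feature column names.
#' @export
rehab_features <- function() {
  c("completion_time_s", "age_y", "height_m", "weight_kg", "bmi", "sex")
}

# continuous features (sex is a binary code, excluded from outlier screening
# and from SMOTE interpolation)
continuous_features <- function() {
  c("completion_time_s", "age_y", "height_m", "weight_kg", "bmi")
}

.tug_difficulty <- c("walk", "turn", "stand_sit", "normal", "fast")
.ftsts_difficulty <- c("slow", "fast")

.tug_condition <- c(
  "healthy", "geriatric", "parkinsons",
  "parkinsons_nonfallers_medication", "parkinsons_nonfallers_no_medication",
  "parkinsons_fallers", "dementia_mild_moderate", "dementia_severe",
  "arthritis_improvement", "arthritis_knee_arthroplasty", "arthritis",
  "stroke", "brain_injury", "bilateral_vestibular_hypofunction",
  "unilateral_vestibular_hypofunction", "spinal_injury", "paraplegia",
  "tetraplegia"
)

.ftsts_condition <- c(
  "healthy", "geriatric", "geriatric_fallers",
  "parkinsons_stage_1", "parkinsons_stage_2", "parkinsons_stage_2_5",
  "parkinsons_stage_3", "parkinsons_stage_4", "parkinsons",
  "arthritis", "arthritis_knee_arthroplasty", "stroke",
  "vestibular_disorder"
)

#' Build a label taxonomy for a mobility test
#'
#' A taxonomy fixes the ordered set of classes for one label axis of one test,
#' together with the healthy reference class used by the hybrid engine's
#' distance rule. The difficulty axes carry the stage-of-test labels recorded
#' in the instrumented experiment (5 classes for TUG, 2 for FTSTS); the
#' condition axes carry the clinical condition classes of the literature-derived
#' synthetic cohorts (18 for TUG, 13 for FTSTS). The difficulty axes have no
#' clinically "healthy" class, so their non-impaired class stands as the
#' healthy reference: `normal` for TUG, `fast` for FTSTS.
#'
#' @param test_type `"TUG"` or `"FTSTS"`.
#' @param axis `"difficulty"` or `"condition"`.
#' @return An object of class `rehab_taxonomy` with elements `test_type`,
#'   `axis`, `classes` (ordered character vector) and `healthy_reference`.
#' @examples
#' rehab_taxonomy("TUG", "difficulty")$classes
#' @export
rehab_taxonomy <- function(test_type = c("TUG", "FTSTS"),
                           axis = c("difficulty", "condition")) {
  test_type <- match.arg(test_type)
  axis <- match.arg(axis)
  classes <- switch(paste(test_type, axis),
    "TUG difficulty" = .tug_difficulty,
    "TUG condition" = .tug_condition,
    "FTSTS difficulty" = .ftsts_difficulty,
    "FTSTS condition" = .ftsts_condition
  )
  healthy <- switch(paste(test_type, axis),
    "TUG difficulty" = "normal",
    "TUG condition" = "healthy",
    "FTSTS difficulty" = "fast",
    "FTSTS condition" = "healthy"
  )
  structure(
    list(test_type = test_type, axis = axis, classes = classes,
         healthy_reference = healthy),
    class = "rehab_taxonomy"
  )
}

#' @export
print.rehab_taxonomy <- function(x, ...) {
  cat(sprintf("<rehab_taxonomy> %s %s: %d classes (healthy ref: %s)\n",
              x$test_type, x$axis, length(x$classes), x$healthy_reference))
  cat(" ", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Integer codes for class labels
#'
#' Maps class names to 0-based integer codes following the taxonomy's fixed
#' ordering, so codes are reproducible across runs.
#'
#' @param labels Character vector of class names.
#' @param taxonomy A [rehab_taxonomy()].
#' @return Integer vector of 0-based codes.
#' @export
label_code <- function(labels, taxonomy) {
  idx <- match(labels, taxonomy$classes)
  if (anyNA(idx) && !all(is.na(labels))) {
    bad <- unique(labels[is.na(idx) & !is.na(labels)])
    stop(sprintf("unknown %s label(s) for %s: %s", taxonomy$axis,
                 taxonomy$test_type, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  idx - 1L
}

#' @rdname label_code
#' @param codes Integer vector of 0-based codes.
#' @export
label_name <- function(codes, taxonomy) {
  taxonomy$classes[codes + 1L]
}
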