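# Data model and file I/O: labelled subject tables (CSV + JSON sidecar) and
# per-class cohort-statistics parameter files (YAML).

#' Construct a rehabilitation dataset
#'
#' Wraps a data frame of subject records with its label taxonomies, test type,
#' optional normalization state and provenance. Each record holds the six
#' clinical features (see [rehab_features()]) plus optional `difficulty` and
#' `condition` label columns whose values must belong to the attached
#' taxonomies.
#'
#' @param data Data frame with the feature columns and optional label columns.
#' @param test_type `"TUG"` or `"FTSTS"`.
#' @param taxonomies Named list with entries `difficulty` and/or `condition`,
#'   each a [rehab_taxonomy()]. Defaults to the standard taxonomies for the
#'   label columns present in `data`.
#' @param normalization `NULL`, or a `rehab_normalizer` recording that the
#'   feature columns are on the \eqn{[-1, 1]} scale.
#' @param provenance One of `"experimental_fixture"`, `"synthetic"`,
#'   `"user_stream"`.
#' @return An object of class `rehab_dataset`.
#' @export
rehab_dataset <- function(data, test_type = c("TUG", "FTSTS"),
                          taxonomies = NULL, normalization = NULL,
                          provenance = c("experimental_fixture", "synthetic",
                                         "user_stream")) {
  test_type <- match.arg(test_type)
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(rehab_features(), names(data))
  if (length(missing_cols) > 0) {
    stop("dataset is missing feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(taxonomies)) {
    taxonomies <- list()
    for (ax in c("difficulty", "condition")) {
      if (ax %in% names(data)) taxonomies[[ax]] <- rehab_taxonomy(test_type, ax)
    }
  }
  for (ax in names(taxonomies)) {
    if (ax %in% names(data)) {
      lab <- data[[ax]]
      label_code(lab[!is.na(lab)], taxonomies[[ax]]) # validates
    }
  }
  validate_records(data, normalized = !is.null(normalization))
  structure(
    list(data = data, test_type = test_type, taxonomies = taxonomies,
         normalization = normalization, provenance = provenance),
    class = "rehab_dataset"
  )
}

# invariant checks on the feature columns
validate_records <- function(data, normalized = FALSE) {
  feats <- rehab_features()
  for (f in feats) {
    if (!is.numeric(data[[f]])) {
      stop("feature column '", f, "' is not numeric", call. = FALSE)
    }
  }
  if (nrow(data) == 0) return(invisible(TRUE))
  if (!normalized && !all(data$sex %in% c(0, 1))) {
    stop("sex must be coded 0 (female) or 1 (male)", call. = FALSE)
  }
  if (normalized) {
    vals <- as.matrix(data[feats])
    if (any(vals < -1 - 1e-9 | vals > 1 + 1e-9)) {
      stop("normalized dataset has feature values outside [-1, 1]",
           call. = FALSE)
    }
  } else {
    for (f in c("completion_time_s", "height_m", "weight_kg")) {
      if (any(data[[f]] <= 0)) {
        stop("feature '", f, "' must be strictly positive", call. = FALSE)
      }
    }
    # BMI consistency with weight/height (Eq. BMI = W / H^2)
    bmi_ref <- data$weight_kg / data$height_m^2
    rel <- abs(data$bmi - bmi_ref) / pmax(abs(bmi_ref), 1e-12)
    if (any(rel > 1e-6)) {
      stop("bmi column is inconsistent with weight/height at row(s): ",
           paste(utils::head(which(rel > 1e-6), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.rehab_dataset <- function(x, ...) {
  labs <- intersect(c("difficulty", "condition"), names(x$data))
  cat(sprintf("<rehab_dataset> %s, %d records (%s%s)\n", x$test_type,
              nrow(x$data), x$provenance,
              if (!is.null(x$normalization)) ", normalized" else ""))
  for (ax in labs) {
    tab <- table(x$data[[ax]])
    cat(sprintf("  %s: %s\n", ax,
                paste(names(tab), tab, sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.rehab_dataset <- function(object, ...) {
  print(object)
  print(summary(object$data[rehab_features()]))
  invisible(object)
}

#' @export
dim.rehab_dataset <- function(x) dim(x$data)

#' Read a subject-record dataset from CSV
#'
#' Expects one header row naming the feature columns
#' `completion_time_s, age_y, height_m, weight_kg, bmi, sex` plus at least one
#' of `difficulty`, `condition`. String labels are validated against (and
#' coded by) the supplied taxonomies; sex may be written `male`/`female` and
#' is mapped to 1/0. A sidecar `<path>.meta.json`, when present, restores
#' test type, provenance and normalization parameters.
#'
#' @param path CSV file path.
#' @param taxonomies A [rehab_taxonomy()] or named list of them; defaults to
#'   the standard taxonomies of the sidecar's (or `test_type`'s) test.
#' @param test_type Used when no sidecar exists.
#' @return A [rehab_dataset()].
#' @export
read_dataset <- function(path, taxonomies = NULL, test_type = "TUG") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(rehab_features(), names(df))
  if (length(missing_cols) > 0) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!any(c("difficulty", "condition") %in% names(df))) {
    stop("CSV has no label column (difficulty or condition)", call. = FALSE)
  }
  if (is.character(df$sex)) {
    sx <- tolower(df$sex)
    bad <- !sx %in% c("male", "female")
    if (any(bad)) {
      stop("unparseable sex value at row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
    }
    df$sex <- ifelse(sx == "male", 1, 0)
  }
  for (f in continuous_features()) {
    if (!is.numeric(df[[f]])) {
      suppressWarnings(conv <- as.numeric(df[[f]]))
      if (anyNA(conv)) {
        stop(sprintf("non-numeric value in column '%s' at row %d", f,
                     which(is.na(conv))[1]), call. = FALSE)
      }
      df[[f]] <- conv
    }
  }
  meta_path <- paste0(path, ".meta.json")
  normalization <- NULL
  provenance <- "experimental_fixture"
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    test_type <- meta$test_type
    provenance <- meta$provenance
    if (!is.null(meta$normalization)) {
      rng <- cbind(min = meta$normalization$min, max = meta$normalization$max)
      rownames(rng) <- meta$normalization$feature
      normalization <- new_normalizer(rng)
    }
  }
  if (inherits(taxonomies, "rehab_taxonomy")) {
    taxonomies <- stats::setNames(list(taxonomies), taxonomies$axis)
  }
  rehab_dataset(df, test_type = test_type, taxonomies = taxonomies,
                normalization = normalization, provenance = provenance)
}

#' Write a dataset to CSV (with JSON sidecar metadata)
#'
#' The sidecar `<path>.meta.json` records test type, provenance and any fitted
#' normalization parameters so that `read_dataset(write_dataset(d))` is the
#' identity.
#'
#' @param dataset A non-empty [rehab_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "rehab_dataset"))
  if (nrow(dataset$data) == 0) stop("refusing to write an empty dataset",
                                    call. = FALSE)
  utils::write.csv(dataset$data, path, row.names = FALSE)
  meta <- list(test_type = dataset$test_type,
               provenance = dataset$provenance)
  if (!is.null(dataset$normalization)) {
    rng <- dataset$normalization$range
    meta$normalization <- list(feature = rownames(rng),
                               min = unname(rng[, "min"]),
                               max = unname(rng[, "max"]))
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

# printed plausibility ranges for cohort means (soft checks)
cohort_ranges <- function(test_type) {
  if (test_type == "TUG") {
    list(age = c(5, 112), height = c(0.81, 2.20), weight = c(30, 136))
  } else {
    list(age = c(11, 93), height = c(0.94, 2.35), weight = c(22, 120))
  }
}

#' Construct per-class cohort generation statistics
#'
#' One `cohort_stats` object holds the summary statistics driving the
#' synthetic generator for one class: Gaussian (mean, sd) for completion time,
#' age, BMI, weight and height, the fraction of female subjects, and the
#' number of rows to generate.
#'
#' @param class_name Class label the generated rows receive.
#' @param n Number of datapoints to generate (>= 0).
#' @param mu_time,sigma_time Completion time mean/sd, seconds.
#' @param mu_age,sigma_age Age mean/sd, years.
#' @param mu_bmi,sigma_bmi BMI mean/sd, kg/m2.
#' @param mu_weight,sigma_weight Weight mean/sd, kg.
#' @param mu_height,sigma_height Height mean/sd, m.
#' @param pct_female Fraction of female subjects in \eqn{[0, 1]}.
#' @param test_type Test the plausibility ranges are checked against
#'   (warning only), or `NULL` to skip the check.
#' @return An object of class `cohort_stats`.
#' @export
cohort_stats <- function(class_name, n, mu_time, sigma_time, mu_age, sigma_age,
                         mu_bmi, sigma_bmi, mu_weight, sigma_weight,
                         mu_height, sigma_height, pct_female,
                         test_type = NULL) {
  vals <- list(mu_time = mu_time, sigma_time = sigma_time, mu_age = mu_age,
               sigma_age = sigma_age, mu_bmi = mu_bmi, sigma_bmi = sigma_bmi,
               mu_weight = mu_weight, sigma_weight = sigma_weight,
               mu_height = mu_height, sigma_height = sigma_height)
  sigmas <- vals[grepl("^sigma_", names(vals))]
  if (any(unlist(sigmas) < 0)) {
    stop("negative sigma in cohort stats for class '", class_name, "'",
         call. = FALSE)
  }
  mus <- vals[c("mu_time", "mu_bmi", "mu_weight", "mu_height")]
  if (any(unlist(mus) <= 0)) {
    stop("non-positive mean of a physical quantity for class '", class_name,
         "'", call. = FALSE)
  }
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (pct_female < 0 || pct_female > 1) {
    stop("pct_female must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(test_type)) {
    rng <- cohort_ranges(test_type)
    soft <- c(age = mu_age, height = mu_height, weight = mu_weight)
    for (nm in names(soft)) {
      if (soft[[nm]] < rng[[nm]][1] || soft[[nm]] > rng[[nm]][2]) {
        warning(sprintf(
          "class '%s': mean %s %.3g outside the %s plausibility range [%g, %g]",
          class_name, nm, soft[[nm]], test_type, rng[[nm]][1], rng[[nm]][2]),
          call. = FALSE)
      }
    }
  }
  structure(c(list(class_name = class_name, n = as.integer(n)), vals,
              list(pct_female = pct_female)),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf(
    "<cohort_stats> %s: n=%d time %.3g±%.3g s, age %.3g±%.3g y, bmi %.3g±%.3g, %.0f%% female\n",
    x$class_name, x$n, x$mu_time, x$sigma_time, x$mu_age, x$sigma_age,
    x$mu_bmi, x$sigma_bmi, 100 * x$pct_female))
  invisible(x)
}

.stats_fields <- c("n", "mu_time", "sigma_time", "mu_age", "sigma_age",
                   "mu_bmi", "sigma_bmi", "mu_weight", "sigma_weight",
                   "mu_height", "sigma_height", "pct_female")

#' Read a cohort-statistics parameter file
#'
#' The YAML file carries top-level metadata (`test_type`, `non_canonical`,
#' `source_note`) and one mapping per class under `classes`, each with the
#' twelve generation fields. Means are soft-checked against the test's
#' printed plausibility ranges (warnings only); negative sigmas and missing
#' fields are errors.
#'
#' @param path YAML file path.
#' @return A list of [cohort_stats()], with attributes `test_type`,
#'   `non_canonical` and `source_note`.
#' @export
read_cohort_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$classes) || length(y$classes) == 0) {
    stop("cohort-stats file has no 'classes' section", call. = FALSE)
  }
  test_type <- y$test_type
  out <- lapply(names(y$classes), function(cls) {
    blk <- y$classes[[cls]]
    # YAML 1.1 readers coerce a bare `n` key to FALSE; undo that
    names(blk)[names(blk) %in% c("FALSE", "no")] <- "n"
    miss <- setdiff(.stats_fields, names(blk))
    if (length(miss) > 0) {
      stop(sprintf("class '%s' missing field(s): %s", cls,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    do.call(cohort_stats,
            c(list(class_name = cls), blk[.stats_fields],
              list(test_type = test_type)))
  })
  attr(out, "test_type") <- test_type
  attr(out, "non_canonical") <- isTRUE(y$non_canonical)
  attr(out, "source_note") <- y$source_note
  out
}

#' Write a cohort-statistics parameter file
#'
#' @param stats_list List of [cohort_stats()].
#' @param path Output YAML path.
#' @param test_type Test type recorded in the file metadata.
#' @param non_canonical Whether the statistics are a stand-in rather than
#'   harvested from source publications.
#' @param source_note Free-text provenance note.
#' @return `path`, invisibly.
#' @export
write_cohort_stats <- function(stats_list, path, test_type,
                               non_canonical = TRUE, source_note = "") {
  classes <- lapply(stats_list, function(s) s[.stats_fields])
  names(classes) <- vapply(stats_list, function(s) s$class_name, "")
  yaml::write_yaml(list(test_type = test_type,
                        non_canonical = non_canonical,
                        source_note = source_note,
                        classes = classes), path)
  invisible(path)
}

#' Path to a shipped default cohort-statistics file
#'
#' The package ships synthetic default parameter sets for the TUG (18 classes)
#' and FTSTS (13 classes) condition taxonomies. The source publications'
#' per-class statistics are not publicly available, so these defaults are
#' invented values bounded by the published cohort ranges and flagged
#' `non_canonical`; results depending on them are illustrative, not canonical.
#'
#' @param test_type `"TUG"` or `"FTSTS"`.
#' @return File path inside the installed package.
#' @export
default_cohort_stats_path <- function(test_type = c("TUG", "FTSTS")) {
  test_type <- match.arg(test_type)
  fn <- sprintf("%s_condition_stats_synthetic.yaml", tolower(test_type))
  system.file("extdata", fn, package = "rehabstack", mustWork = TRUE)
}
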