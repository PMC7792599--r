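# Synthetic cohort generation: per-class feature tables from summary
# statistics, built by sorted Gaussian sampling with controlled variability
# swaps, height derived from the {BMI, weight} pair with exact moment
# matching, plus correlation validation and the experiment-style fixtures.

#' Variability configuration for the cohort generator
#'
#' The generator induces linear relationships by sorting every feature draw,
#' then injects realism by swapping a controlled number of index pairs.
#' `swap_fraction_age` governs the swaps applied to the age column alone;
#' `swap_fraction_bmi_block` governs both the solo BMI swaps and the joint
#' swaps applied identically to the linked \{BMI, weight, sex\} block.
#' Each swap pairs indices at most `swap_window` apart (default `n/4`),
#' keeping the disturbance local.
#'
#' @param swap_fraction_age Fraction in \eqn{[0,1]}; number of age swaps is
#'   `round(fraction * n)`.
#' @param swap_fraction_bmi_block Fraction in \eqn{[0,1]} for the BMI/block
#'   swaps.
#' @param swap_window Maximum index distance per swap (>= 1), or `NULL` for
#'   `max(1, round(n/4))` at generation time.
#' @param seed Integer seed.
#' @return An object of class `variability_config`.
#' @export
variability_config <- function(swap_fraction_age = 0.15,
                               swap_fraction_bmi_block = 0.15,
                               swap_window = NULL, seed = 1L) {
  stopifnot(swap_fraction_age >= 0, swap_fraction_age <= 1,
            swap_fraction_bmi_block >= 0, swap_fraction_bmi_block <= 1,
            is.null(swap_window) || swap_window >= 1)
  structure(list(swap_fraction_age = swap_fraction_age,
                 swap_fraction_bmi_block = swap_fraction_bmi_block,
                 swap_window = swap_window, seed = as.integer(seed)),
            class = "variability_config")
}

#' Sorted Gaussian sample
#'
#' Draws `n` i.i.d. Normal(mu, sigma^2) values and returns them sorted
#' ascending. An optional lower bound truncates by redraw, excluding the
#' physically impossible tail values (negative times, weights, ...) the
#' Gaussian model would otherwise admit.
#'
#' @param mu Mean.
#' @param sigma Standard deviation (>= 0).
#' @param n Sample size (>= 0).
#' @param seed Integer seed.
#' @param lower Exclusive lower bound for redraw truncation; `-Inf` disables.
#' @return Non-decreasing numeric vector of length `n`.
#' @export
sample_sorted_gaussian <- function(mu, sigma, n, seed, lower = -Inf) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0) return(numeric(0))
  if (is.finite(lower) && sigma == 0 && mu <= lower) {
    stop("degenerate draw at mu <= lower bound", call. = FALSE)
  }
  with_seed(seed, {
    x <- stats::rnorm(n, mu, sigma)
    for (it in 1:1000) {
      bad <- x <= lower
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mu, sigma)
    }
    if (any(x <= lower)) {
      stop("could not draw values above the lower bound", call. = FALSE)
    }
    sort(x)
  })
}

#' Swap index pairs to inject variability into sorted columns
#'
#' Performs `round(swap_fraction * n)` seeded index-pair swaps, each pair at
#' most `swap_window` positions apart, applying the identical swap sequence
#' to every column in the linked set. Swapping permutes values, so every
#' column's multiset — hence its sample mean and SD — is exactly preserved;
#' only cross-column rank correlations are degraded.
#'
#' @param columns A numeric vector, or a list of equal-length vectors that
#'   must move together.
#' @param swap_fraction Fraction in \eqn{[0,1]}.
#' @param swap_window Maximum index distance per swap (>= 1).
#' @param seed Integer seed.
#' @return Object of the same shape as `columns`, with an attribute `swaps`
#'   (two-column matrix of swapped index pairs).
#' @export
insert_variability <- function(columns, swap_fraction, swap_window, seed) {
  single <- !is.list(columns)
  cols <- if (single) list(columns) else columns
  n <- length(cols[[1]])
  if (!all(vapply(cols, length, 0L) == n)) {
    stop("linked columns have mismatched lengths", call. = FALSE)
  }
  stopifnot(swap_fraction >= 0, swap_fraction <= 1, swap_window >= 1)
  n_swaps <- round(swap_fraction * n)
  swaps <- matrix(integer(0), ncol = 2)
  if (n_swaps > 0 && n >= 2) {
    swaps <- with_seed(seed, {
      out <- matrix(0L, nrow = n_swaps, ncol = 2)
      for (s in seq_len(n_swaps)) {
        i <- sample.int(n, 1)
        lo <- max(1L, i - as.integer(swap_window))
        hi <- min(n, i + as.integer(swap_window))
        cand <- setdiff(lo:hi, i)
        j <- cand[sample.int(length(cand), 1)]
        out[s, ] <- c(i, j)
      }
      out
    })
    for (s in seq_len(nrow(swaps))) {
      i <- swaps[s, 1]; j <- swaps[s, 2]
      for (k in seq_along(cols)) {
        tmp <- cols[[k]][i]
        cols[[k]][i] <- cols[[k]][j]
        cols[[k]][j] <- tmp
      }
    }
  }
  out <- if (single) cols[[1]] else cols
  attr(out, "swaps") <- swaps
  out
}

#' Deterministic sex assignment from a female fraction
#'
#' The first `floor(n * pct_female)` entries are coded 0 (female), the rest 1
#' (male). Variability enters later through the joint swaps of the linked
#' \{BMI, weight, sex\} block.
#'
#' @param n Count.
#' @param pct_female Fraction in \eqn{[0,1]}.
#' @return Integer vector of 0/1 codes with exactly `floor(n * pct_female)`
#'   zeros.
#' @export
assign_sex <- function(n, pct_female) {
  stopifnot(pct_female >= 0, pct_female <= 1, n >= 0)
  n_f <- floor(n * pct_female)
  c(rep(0L, n_f), rep(1L, n - n_f))
}

#' Derive height from the (weight, BMI) pair with exact moment matching
#'
#' Heights are computed as `H = sqrt(weight / bmi)` — the inversion of
#' BMI = W/H^2 — then affinely rescaled so the sample mean and SD of the
#' height column equal `(target_mu, target_sigma)` exactly. The BMI column is
#' finally recomputed as `weight / height^2` so the row-wise BMI identity
#' holds; the relative drift this induces in the BMI column's moments is
#' returned and warned about above 10%.
#'
#' `literal = TRUE` switches to the dimensionally inconsistent `H = W/Z`
#' form (a compatibility mode, off by default).
#'
#' @param weight Weight vector, kg (> 0).
#' @param bmi BMI vector, kg/m2 (> 0).
#' @param target_mu,target_sigma Target sample mean/SD of height, metres.
#' @param literal Use the un-rooted ratio instead of its square root.
#' @return List with `height`, recomputed `bmi`, and `bmi_drift`
#'   (named relative drifts of the BMI mean and SD).
#' @export
derive_height <- function(weight, bmi, target_mu, target_sigma,
                          literal = FALSE) {
  stopifnot(length(weight) == length(bmi))
  if (any(weight <= 0) || any(bmi <= 0)) {
    stop("weight and bmi must be strictly positive", call. = FALSE)
  }
  n <- length(weight)
  if (n == 0) {
    return(list(height = numeric(0), bmi = numeric(0),
                bmi_drift = c(mean = 0, sd = 0)))
  }
  h <- if (literal) weight / bmi else sqrt(weight / bmi)
  s <- if (n > 1) stats::sd(h) else 0
  height <- if (s > 0 && target_sigma > 0) {
    target_mu + (h - mean(h)) * (target_sigma / s)
  } else {
    rep(target_mu, n)
  }
  if (any(height <= 0)) {
    stop("infeasible height statistics: rescaling produced non-positive ",
         "heights", call. = FALSE)
  }
  bmi_new <- weight / height^2
  drift <- c(
    mean = abs(mean(bmi_new) - mean(bmi)) / mean(bmi),
    sd = if (n > 1 && stats::sd(bmi) > 0) {
      abs(stats::sd(bmi_new) - stats::sd(bmi)) / stats::sd(bmi)
    } else 0
  )
  if (any(drift >= 0.10)) {
    warning(sprintf(
      "BMI moments drifted %.1f%% (mean) / %.1f%% (sd) after height rescaling",
      100 * drift[["mean"]], 100 * drift[["sd"]]), call. = FALSE)
  }
  list(height = height, bmi = bmi_new, bmi_drift = drift)
}

#' Generate one class table from cohort statistics
#'
#' Executes the generator's line order: completion time sorted; age sorted
#' then varied; BMI sorted then varied; weight sorted; sex assigned
#' deterministically; the linked \{BMI, weight, sex\} block varied jointly;
#' height derived from (weight, BMI) with exact moment matching and BMI
#' recomputed. With all swap fractions zero, every pair of sorted columns has
#' Spearman rank correlation 1. Gaussian draws are truncated at physical
#' bounds (time, BMI, weight > 0; age >= 0) by redraw.
#'
#' @param stats A [cohort_stats()].
#' @param config A [variability_config()].
#' @param literal_height Passed to [derive_height()].
#' @return Data frame with the six feature columns, `stats$n` rows, plus
#'   attribute `class_name`.
#' @export
generate_class <- function(stats, config = variability_config(),
                           literal_height = FALSE) {
  stopifnot(inherits(stats, "cohort_stats"),
            inherits(config, "variability_config"))
  n <- stats$n
  feats <- rehab_features()
  if (n == 0) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), 6), feats))
    attr(df, "class_name") <- stats$class_name
    return(df)
  }
  window <- if (is.null(config$swap_window)) max(1, round(n / 4)) else
    config$swap_window
  sd0 <- config$seed
  time <- sample_sorted_gaussian(stats$mu_time, stats$sigma_time, n,
                                 seed = derive_seed(sd0, 1), lower = 0)
  age <- sample_sorted_gaussian(stats$mu_age, stats$sigma_age, n,
                                seed = derive_seed(sd0, 2), lower = -1e-12)
  age <- insert_variability(age, config$swap_fraction_age, window,
                            seed = derive_seed(sd0, 3))
  bmi <- sample_sorted_gaussian(stats$mu_bmi, stats$sigma_bmi, n,
                                seed = derive_seed(sd0, 4), lower = 0)
  bmi <- insert_variability(bmi, config$swap_fraction_bmi_block, window,
                            seed = derive_seed(sd0, 5))
  weight <- sample_sorted_gaussian(stats$mu_weight, stats$sigma_weight, n,
                                   seed = derive_seed(sd0, 6), lower = 0)
  sex <- assign_sex(n, stats$pct_female)
  block <- insert_variability(list(bmi = bmi, weight = weight, sex = sex),
                              config$swap_fraction_bmi_block, window,
                              seed = derive_seed(sd0, 7))
  hgt <- derive_height(block$weight, block$bmi, stats$mu_height,
                       stats$sigma_height, literal = literal_height)
  df <- data.frame(completion_time_s = time, age_y = as.numeric(age),
                   height_m = hgt$height, weight_kg = block$weight,
                   bmi = hgt$bmi, sex = as.numeric(block$sex))
  attr(df, "class_name") <- stats$class_name
  attr(df, "bmi_drift") <- hgt$bmi_drift
  df
}

#' Generate a labelled synthetic dataset over a taxonomy
#'
#' Concatenates one generated class table per taxonomy class, attaching the
#' class label on the taxonomy's axis. Per-class seeds are derived from the
#' config seed, so identical (stats, config) inputs reproduce the dataset
#' exactly.
#'
#' @param stats_list List of [cohort_stats()], one per taxonomy class (any
#'   order; names must match the taxonomy's classes exactly).
#' @param config A [variability_config()].
#' @param taxonomy A [rehab_taxonomy()].
#' @return A [rehab_dataset()] with provenance `"synthetic"`.
#' @export
generate_dataset <- function(stats_list, config = variability_config(),
                             taxonomy) {
  stopifnot(inherits(taxonomy, "rehab_taxonomy"))
  stat_names <- vapply(stats_list, function(s) s$class_name, "")
  if (!setequal(stat_names, taxonomy$classes) ||
      length(stat_names) != length(taxonomy$classes)) {
    stop("cohort stats classes do not match the taxonomy (",
         taxonomy$test_type, " ", taxonomy$axis, ")", call. = FALSE)
  }
  ord <- match(taxonomy$classes, stat_names)
  tables <- lapply(seq_along(ord), function(i) {
    st <- stats_list[[ord[i]]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 1000 + i)
    tab <- generate_class(st, cfg)
    if (nrow(tab) > 0) tab[[taxonomy$axis]] <- st$class_name
    tab
  })
  tables <- tables[vapply(tables, nrow, 0L) > 0]
  df <- do.call(rbind, tables)
  rownames(df) <- NULL
  rehab_dataset(df, test_type = taxonomy$test_type,
                taxonomies = stats::setNames(list(taxonomy), taxonomy$axis),
                provenance = "synthetic")
}

#' Compare a dataset's feature correlation matrix against a reference
#'
#' Pearson correlations over the six features. Constant features have
#' undefined correlations; they are flagged and excluded from the maximum
#' absolute difference. Used to tune the variability configuration: more
#' swaps weaken the sorted columns' near-perfect correlations toward a
#' realistic reference.
#'
#' @param dataset A [rehab_dataset()].
#' @param reference Symmetric unit-diagonal matrix over the six features.
#' @param tolerance Pass threshold on the maximum absolute difference.
#' @return An object of class `correlation_report` with `correlation`,
#'   `reference`, `diff`, `max_abs_diff`, `excluded` and `pass`.
#' @export
validate_correlations <- function(dataset, reference, tolerance = 0.3) {
  stopifnot(inherits(dataset, "rehab_dataset"))
  feats <- rehab_features()
  reference <- as.matrix(reference)
  if (!isTRUE(all.equal(reference, t(reference))) ||
      !isTRUE(all.equal(unname(diag(reference)), rep(1, nrow(reference))))) {
    stop("reference must be symmetric with unit diagonal", call. = FALSE)
  }
  X <- as.matrix(dataset$data[feats])
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  cm <- suppressWarnings(stats::cor(X))
  d <- abs(cm - reference)
  keep <- !const
  max_abs <- max(d[keep, keep][upper.tri(d[keep, keep])], 0)
  structure(list(correlation = cm, reference = reference, diff = d,
                 max_abs_diff = max_abs, excluded = feats[const],
                 pass = max_abs <= tolerance, tolerance = tolerance),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> max |diff| = %.4f (tolerance %.3f): %s\n",
              x$max_abs_diff, x$tolerance, if (x$pass) "PASS" else "FAIL"))
  if (length(x$excluded) > 0) {
    cat("  constant feature(s) excluded:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

# participant demographic pool for the experiment-style fixtures:
# 8 adults aged 20-45, 7 male / 1 female, mirroring the instrumented study's
# composition (87% male entries, one age group).
fixture_participants <- function(participants, seed) {
  with_seed(seed, {
    sex <- c(0L, rep(1L, participants - 1))
    age <- stats::runif(participants, 20, 45)
    height <- ifelse(sex == 1, stats::rnorm(participants, 1.78, 0.06),
                     stats::rnorm(participants, 1.65, 0.05))
    weight <- ifelse(sex == 1, stats::rnorm(participants, 80, 9),
                     stats::rnorm(participants, 62, 7))
    data.frame(participant = seq_len(participants), age_y = age,
               height_m = height, weight_kg = weight,
               bmi = compute_bmi(weight, height), sex = as.numeric(sex))
  })
}

# default completion-time ranges per difficulty class, seconds.
# Disjoint by construction, with between-class gaps wider than the
# within-class spread so that completion time dominates the class geometry
# (the dominant-feature property of experiment-style data); `overlap`
# (seconds) widens each range symmetrically to create controlled overlap.
fixture_time_ranges <- function(test_type, overlap = 0) {
  base <- if (test_type == "TUG") {
    list(fast = c(4.5, 6), normal = c(8, 9.5), walk = c(11.5, 13),
         turn = c(15, 16.5), stand_sit = c(18.5, 20))
  } else {
    list(fast = c(5, 9), slow = c(17, 21))
  }
  lapply(base, function(r) c(r[1] - overlap, r[2] + overlap))
}

#' Experiment-style fixture dataset
#'
#' Emulates the instrumented 8-participant study: a small, difficulty-labelled
#' dataset with class-separated completion-time distributions (disjoint by
#' default; `overlap` > 0 blurs them) and the study's demographic skew
#' (one female participant, ages 20-45). Rows are assigned to participants
#' cyclically. Each (participant, class) pair has a characteristic time drawn
#' within the class range, and repetitions scatter around it with test-retest
#' noise (`cv`, default 3%), the way repeated clinical measurements behave.
#' The real study's recordings are not public; this fixture is a synthetic
#' stand-in that reproduces its published shape (class counts, demographic
#' imbalance), not its measurements.
#'
#' @param test_type `"TUG"` or `"FTSTS"`.
#' @param participants Number of participants (default 8).
#' @param per_class Named integer vector of per-difficulty-class counts.
#'   Defaults to the published pre-balance counts: TUG
#'   `c(walk=40, turn=40, stand_sit=40, normal=24, fast=39)`; FTSTS
#'   `c(slow=33, fast=40)`.
#' @param seed Integer seed.
#' @param overlap Seconds by which adjacent class time ranges are widened.
#' @param cv Coefficient of variation of a participant's repeated times
#'   around their characteristic class time.
#' @return A difficulty-labelled [rehab_dataset()] (provenance
#'   `"experimental_fixture"`) with an extra `participant` column.
#' @export
fixture_experiment <- function(test_type = c("TUG", "FTSTS"),
                               participants = 8, per_class = NULL, seed,
                               overlap = 0, cv = 0.03) {
  test_type <- match.arg(test_type)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  tax <- rehab_taxonomy(test_type, "difficulty")
  if (is.null(per_class)) {
    per_class <- if (test_type == "TUG") {
      c(walk = 40, turn = 40, stand_sit = 40, normal = 24, fast = 39)
    } else {
      c(slow = 33, fast = 40)
    }
  }
  if (!all(names(per_class) %in% tax$classes)) {
    stop("per_class names must be ", test_type, " difficulty classes",
         call. = FALSE)
  }
  people <- fixture_participants(participants, derive_seed(seed, 1))
  ranges <- fixture_time_ranges(test_type, overlap)
  rows <- with_seed(derive_seed(seed, 2), {
    out <- list()
    for (cls in names(per_class)) {
      n <- per_class[[cls]]
      if (n == 0) next
      pid <- rep_len(seq_len(participants), n)
      r <- ranges[[cls]]
      # characteristic time per participant for this class, kept off the
      # range edges so repetition noise stays inside the class range
      margin <- min(2 * cv * mean(r), 0.25 * (r[2] - r[1]))
      base_pc <- stats::runif(participants, r[1] + margin, r[2] - margin)
      t_s <- base_pc[pid] * (1 + stats::rnorm(n, 0, cv))
      t_s <- pmin(pmax(t_s, r[1]), r[2])
      blk <- people[pid, , drop = FALSE]
      blk$completion_time_s <- t_s
      blk$difficulty <- cls
      out[[cls]] <- blk
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  rows <- rows[c("completion_time_s", "age_y", "height_m", "weight_kg",
                 "bmi", "sex", "difficulty", "participant")]
  rehab_dataset(rows, test_type = test_type,
                taxonomies = list(difficulty = tax),
                provenance = "experimental_fixture")
}

#' Session-stream fixture for one user
#'
#' Generates an ordered sequence of completion times realizing a named trend:
#' `improving` (times drift down), `worsening` (up), `steady` (stationary),
#' `forcing` (implausibly steep improvement), or `abandon` (steady, with the
#' final sessions started but not completed). Noise is Gaussian around the
#' trend line; times are floored at 1 s.
#'
#' @param profile List with `base_time` (s), optional `noise_sd` (s, default
#'   2% of base) and `drift` (total fractional change over the stream,
#'   default 0.3).
#' @param n_sessions Number of sessions.
#' @param trend One of `"improving"`, `"worsening"`, `"steady"`, `"forcing"`,
#'   `"abandon"`.
#' @param seed Integer seed.
#' @return Data frame with columns `session`, `time_s`, `completed`.
#' @export
fixture_session_stream <- function(profile, n_sessions,
                                   trend = c("improving", "worsening",
                                             "steady", "forcing", "abandon"),
                                   seed) {
  trend <- match.arg(trend)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  base <- profile$base_time
  noise_sd <- if (!is.null(profile$noise_sd)) profile$noise_sd else 0.02 * base
  drift <- if (!is.null(profile$drift)) profile$drift else 0.3
  x <- if (n_sessions > 1) (seq_len(n_sessions) - 1) / (n_sessions - 1) else 0
  trendline <- switch(trend,
    improving = base * (1 - drift * x),
    worsening = base * (1 + drift * x),
    steady = rep(base, n_sessions),
    forcing = base * (1 - 2 * drift * x),
    abandon = rep(base, n_sessions)
  )
  times <- with_seed(seed,
                     pmax(1, trendline + stats::rnorm(n_sessions, 0, noise_sd)))
  completed <- rep(TRUE, n_sessions)
  if (trend == "abandon") {
    n_abandon <- max(1, round(0.1 * n_sessions))
    tail_idx <- seq(n_sessions - n_abandon + 1, n_sessions)
    completed[tail_idx] <- FALSE
    times[tail_idx] <- NA_real_
  }
  data.frame(session = seq_len(n_sessions), time_s = times,
             completed = completed)
}
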