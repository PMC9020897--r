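#' Specify a synthetic cardio cohort
#'
#' Builds the specification object consumed by [generate_cohort()]. The
#' generator emulates the cardio record schema used throughout the package:
#' `id`, `age` (days), `gender` (1 = female, 2 = male), `height` (cm),
#' `weight` (kg), `ap_hi`/`ap_lo` (systolic/diastolic blood pressure, mmHg),
#' `cholesterol` and `gluc` (ordinal 1--3), `smoke`, `alco`, `active`
#' (binary habits) and the binary outcome `cardio`.
#'
#' The outcome is drawn from a logistic ground-truth model on derived
#' clinical features: `cardio ~ Bernoulli(sigmoid(intercept + sum(beta_j *
#' z_j)))` where each `z_j` is the named feature standardised against fixed
#' reference constants (so coefficients have a stable scale regardless of
#' `n`). Recognised coefficient names are the raw schema features plus the
#' derived `MAP`, `PP`, `BMI` and `age_years`.
#'
#' @param n Number of clean records to generate.
#' @param seed Integer RNG seed; identical specs regenerate identical tables.
#' @param dup_count Number of exact duplicate rows planted by
#'   [plant_anomalies()].
#' @param outliers Named list/vector of planted rule violations: any of
#'   `negative_bp`, `ap_hi_over_200`, `ap_lo_under_50`, `extreme_hw`.
#' @param risk_coefficients Named numeric vector of logistic weights on
#'   standardised features. Defaults put strong signal on mean arterial
#'   pressure, body-mass index and age.
#' @param intercept Intercept of the logistic label model.
#' @return A `cohort_spec` list.
#' @examples
#' spec <- cohort_spec(n = 200, seed = 1)
#' cohort <- generate_cohort(spec)
#' @export
cohort_spec <- function(n,
                        seed = 1L,
                        dup_count = 0L,
                        outliers = list(),
                        risk_coefficients = c(
                          MAP = 5, BMI = 2.5, age_years = 1.5,
                          cholesterol = 0.7
                        ),
                        intercept = 0) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n)) {
    stop("`n` must be a positive integer count of records", call. = FALSE)
  }
  outliers <- as.list(outliers)
  known_rules <- c("negative_bp", "ap_hi_over_200", "ap_lo_under_50",
                   "extreme_hw")
  bad <- setdiff(names(outliers), known_rules)
  if (length(bad) > 0) {
    stop("unknown outlier rule(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- stats::setNames(rep(0L, length(known_rules)), known_rules)
  for (nm in names(outliers)) counts[[nm]] <- as.integer(outliers[[nm]])
  if (any(counts < 0) || dup_count < 0) {
    stop("planted counts must be non-negative", call. = FALSE)
  }
  bad_coef <- setdiff(names(risk_coefficients), .risk_feature_names())
  if (length(bad_coef) > 0) {
    stop("unknown risk coefficient name(s): ",
         paste(bad_coef, collapse = ", "), call. = FALSE)
  }
  if (n < dup_count + sum(counts)) {
    stop("`n` must be at least dup_count + total planted outliers",
         call. = FALSE)
  }
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed),
      dup_count = as.integer(dup_count), outliers = as.list(counts),
      risk_coefficients = risk_coefficients, intercept = intercept
    ),
    class = "cohort_spec"
  )
}

.risk_feature_names <- function() {
  c("age", "gender", "height", "weight", "ap_hi", "ap_lo", "cholesterol",
    "gluc", "smoke", "alco", "active", "MAP", "PP", "BMI", "age_years")
}

# Fixed reference centres/scales for the logistic linear predictor, so a
# coefficient of 1 means roughly one reference SD of that feature.
.risk_reference <- function() {
  list(
    centre = c(age = 19000, gender = 1.35, height = 166, weight = 74,
               ap_hi = 127, ap_lo = 81, cholesterol = 1.35, gluc = 1.25,
               smoke = 0.09, alco = 0.05, active = 0.8,
               MAP = 96, PP = 45, BMI = 26.5, age_years = 52),
    scale = c(age = 2500, gender = 0.5, height = 8, weight = 14,
              ap_hi = 16, ap_lo = 9, cholesterol = 0.7, gluc = 0.6,
              smoke = 0.3, alco = 0.2, active = 0.4,
              MAP = 10, PP = 12, BMI = 4.5, age_years = 7)
  )
}

# Truncated-normal draw by inverse-CDF on the truncated probability mass.
.rtnorm <- function(n, mean, sd, lower, upper) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

.risk_linear_predictor <- function(tbl, coefficients, intercept) {
  ref <- .risk_reference()
  feats <- tbl
  feats$age_years <- tbl$age / 365.25
  feats$MAP <- (tbl$ap_hi + 2 * tbl$ap_lo) / 3
  feats$PP <- tbl$ap_hi - tbl$ap_lo
  feats$BMI <- tbl$weight / (tbl$height / 100)^2
  eta <- rep(intercept, nrow(tbl))
  for (nm in names(coefficients)) {
    z <- (feats[[nm]] - ref$centre[[nm]]) / ref$scale[[nm]]
    eta <- eta + coefficients[[nm]] * z
  }
  eta
}

#' Generate a synthetic cardio cohort
#'
#' Draws `spec$n` clean records under seeded, reproducible marginals
#' (truncated normals for anthropometrics and blood pressure, categorical
#' draws for cholesterol/glucose and habits) and labels them from the
#' logistic ground-truth model in `spec`. Clean records satisfy
#' `50 <= ap_lo < ap_hi <= 200` and plausible adult height/weight, so every
#' violation seen downstream was planted deliberately by
#' [plant_anomalies()].
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with the 13 cardio schema columns (`id` plus 11 features
#'   plus `cardio`).
#' @seealso [plant_anomalies()], [write_cohort_csv()]
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  tbl <- withr::with_seed(spec$seed, {
    gender <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.65, 0.35))
    height <- round(.rtnorm(n, ifelse(gender == 2L, 175, 161), 7, 145, 200))
    bmi <- .rtnorm(n, 26.5, 4.5, 16, 45)
    weight <- round(bmi * (height / 100)^2, 1)
    ap_lo <- round(.rtnorm(n, 81, 9, 55, 110))
    pp <- round(.rtnorm(n, 45, 12, 20, 80))
    ap_hi <- ap_lo + pp
    out <- tibble::tibble(
      id = seq_len(n) - 1L,
      age = as.integer(round(.rtnorm(n, 19000, 2500, 10600, 23700))),
      gender = gender,
      height = as.integer(height),
      weight = weight,
      ap_hi = as.integer(ap_hi),
      ap_lo = as.integer(ap_lo),
      cholesterol = sample(1:3, n, replace = TRUE,
                           prob = c(0.75, 0.14, 0.11)),
      gluc = sample(1:3, n, replace = TRUE, prob = c(0.85, 0.07, 0.08)),
      smoke = stats::rbinom(n, 1L, 0.09),
      alco = stats::rbinom(n, 1L, 0.05),
      active = stats::rbinom(n, 1L, 0.80)
    )
    eta <- .risk_linear_predictor(out, spec$risk_coefficients,
                                  spec$intercept)
    out$cardio <- stats::rbinom(n, 1L, stats::plogis(eta))
    out
  })
  tbl
}

#' True label probabilities under a cohort's generative model
#'
#' Returns `sigmoid(linear predictor)` for each row of a (generated) cohort
#' table, i.e. the Bernoulli success probability the labels were drawn with.
#' Useful for checking empirical label rates against the model.
#'
#' @param table A cohort tibble.
#' @param spec The [cohort_spec()] that generated it.
#' @return Numeric vector of probabilities.
#' @export
cohort_true_risk <- function(table, spec) {
  stats::plogis(
    .risk_linear_predictor(table, spec$risk_coefficients, spec$intercept)
  )
}

#' Plant duplicates and rule-violating records in a cohort
#'
#' Appends `spec$dup_count` exact copies of uniformly chosen clean rows and,
#' per cleaning rule, the requested number of violating rows:
#' \describe{
#'   \item{negative_bp}{`ap_lo` drawn in \[-90, -10\] (mirrors real-data
#'     entry errors such as a diastolic pressure of -70).}
#'   \item{ap_hi_over_200}{systolic pressure in 205--245 mmHg.}
#'   \item{ap_lo_under_50}{diastolic pressure in 15--45 mmHg (still
#'     positive, systolic kept valid).}
#'   \item{extreme_hw}{implausible height (55--100 or 230--250 cm) or
#'     weight (10--28 or 180--200 kg).}
#' }
#' Planted rows get fresh ids; a provenance attribute records which rule
#' each planted row violates so tests can assert cleaning bookkeeping.
#'
#' @param table A clean cohort tibble from [generate_cohort()].
#' @param spec The same [cohort_spec()].
#' @return The augmented tibble, rows shuffled deterministically, with
#'   attribute `"provenance"`: a tibble of `id`, `rule`.
#' @export
plant_anomalies <- function(table, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- spec$outliers
  total <- spec$dup_count + sum(unlist(counts))
  if (total > nrow(table)) {
    stop("more planted rows requested than rows available", call. = FALSE)
  }
  if (total == 0L) {
    attr(table, "provenance") <- tibble::tibble(id = integer(),
                                                rule = character())
    return(table)
  }
  withr::with_seed(spec$seed + 1L, {
    next_id <- max(table$id) + 1L
    planted <- list()
    prov <- list()
    take <- function(k) table[sample.int(nrow(table), k), , drop = FALSE]

    if (spec$dup_count > 0) {
      dup <- take(spec$dup_count)  # exact copies: id kept identical too
      planted <- c(planted, list(dup))
      prov <- c(prov, list(tibble::tibble(id = dup$id, rule = "duplicate")))
    }
    plant_rule <- function(k, mutate_fn, rule) {
      if (k == 0L) return(invisible(NULL))
      rows <- take(k)
      rows$id <- next_id + seq_len(k) - 1L
      next_id <<- next_id + k
      rows <- mutate_fn(rows)
      planted[[length(planted) + 1L]] <<- rows
      prov[[length(prov) + 1L]] <<- tibble::tibble(id = rows$id,
                                                   rule = rule)
    }
    plant_rule(counts$negative_bp, function(r) {
      r$ap_lo <- -as.integer(sample(10:90, nrow(r), replace = TRUE))
      r
    }, "negative_bp")
    plant_rule(counts$ap_hi_over_200, function(r) {
      r$ap_hi <- as.integer(sample(205:245, nrow(r), replace = TRUE))
      r
    }, "ap_hi_over_200")
    plant_rule(counts$ap_lo_under_50, function(r) {
      r$ap_lo <- as.integer(sample(15:45, nrow(r), replace = TRUE))
      r$ap_hi <- pmin(r$ap_hi, 200L)
      r
    }, "ap_lo_under_50")
    plant_rule(counts$extreme_hw, function(r) {
      low <- stats::runif(nrow(r)) < 0.5
      r$height <- as.integer(ifelse(low, sample(55:100, nrow(r), TRUE),
                                    sample(230:250, nrow(r), TRUE)))
      r$weight <- ifelse(low, stats::runif(nrow(r), 10, 28),
                         stats::runif(nrow(r), 180, 200))
      r
    }, "extreme_hw")

    out <- dplyr::bind_rows(c(list(table), planted))
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    attr(out, "provenance") <- dplyr::bind_rows(prov)
    out
  })
}

#' Convert the cardio `age` column between days and years
#'
#' The cohort schema stores age in days (the dialect of the public cardio
#' CSV); these helpers convert to and from years using 365.25-day years.
#'
#' @param days,years Numeric vectors.
#' @return Numeric vector.
#' @export
age_days_to_years <- function(days) days / 365.25

#' @rdname age_days_to_years
#' @export
age_years_to_days <- function(years) years * 365.25

#' Read or write a cohort CSV
#'
#' The on-disk dialect matches the public cardio file: header
#' `id;age;gender;height;weight;ap_hi;ap_lo;cholesterol;gluc;smoke;alco;`
#' `active;cardio`, semicolon-delimited by default, with a comma option.
#'
#' @param table Cohort tibble.
#' @param path File path.
#' @param delim `";"` (default, the cardio dialect) or `","`.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a cohort tibble.
#' @export
write_cohort_csv <- function(table, path, delim = ";") {
  readr::write_delim(table, path, delim = delim)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, delim = ";") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}
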