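#' Remove exact duplicate records
#'
#' Keeps the first occurrence of each fully identical record. The `id`
#' column (if present) is excluded from the comparison, since duplicated
#' measurements re-entered under a new id are still duplicates.
#'
#' @param table A cohort data frame.
#' @return The deduplicated tibble, with attribute `"removed"` giving the
#'   number of rows dropped (also available via [cleaning_report()] when
#'   called through [clean_cohort()]).
#' @export
drop_duplicates <- function(table) {
  if (nrow(table) == 0L) stop("`table` must be non-empty", call. = FALSE)
  cmp_cols <- setdiff(names(table), "id")
  dup <- duplicated(table[cmp_cols])
  out <- tibble::as_tibble(table[!dup, , drop = FALSE])
  attr(out, "removed") <- sum(dup)
  out
}

#' Filter physiologically impossible and extreme records
#'
#' Applies the cleaning rules for the cardio schema in a fixed order, each
#' rule seeing the survivors of the previous one:
#' \enumerate{
#'   \item `negative_bp`: drop rows with `ap_hi <= 0` or `ap_lo <= 0`
#'     (data-entry sign errors such as a diastolic pressure of -70);
#'   \item `ap_hi_over_200`: drop rows with systolic pressure above
#'     200 mmHg;
#'   \item `ap_lo_under_50`: drop rows with diastolic pressure below
#'     50 mmHg;
#'   \item `height_weight_quantile`: drop rows whose height *or* weight
#'     lies strictly below the `lower_q` quantile or strictly above the
#'     `upper_q` quantile of its own column, quantiles computed on the
#'     table as this rule receives it (linear interpolation between order
#'     statistics).
#' }
#' Each removed row is attributed to the first rule that fires, making the
#' report deterministic.
#'
#' @param table A cohort data frame.
#' @param lower_q,upper_q Trim quantiles for height/weight, defaults
#'   0.05/0.95. `lower_q = 0, upper_q = 1` disables the quantile rule.
#' @return The filtered tibble with attribute `"cleaning_report"`, a list
#'   of `removed_per_rule`, `rows_before`, `rows_after`.
#' @export
filter_outliers <- function(table, lower_q = 0.05, upper_q = 0.95) {
  if (nrow(table) == 0L) stop("`table` must be non-empty", call. = FALSE)
  if (!(lower_q >= 0 && lower_q < upper_q && upper_q <= 1)) {
    stop("need 0 <= lower_q < upper_q <= 1", call. = FALSE)
  }
  rows_before <- nrow(table)
  removed <- c(negative_bp = 0L, ap_hi_over_200 = 0L, ap_lo_under_50 = 0L,
               height_weight_quantile = 0L)

  keep <- !(table$ap_hi <= 0 | table$ap_lo <= 0)
  removed[["negative_bp"]] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  keep <- table$ap_hi <= 200
  removed[["ap_hi_over_200"]] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  keep <- table$ap_lo >= 50
  removed[["ap_lo_under_50"]] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  h_b <- stats::quantile(table$height, c(lower_q, upper_q), names = FALSE)
  w_b <- stats::quantile(table$weight, c(lower_q, upper_q), names = FALSE)
  keep <- !(table$height < h_b[1] | table$height > h_b[2] |
              table$weight < w_b[1] | table$weight > w_b[2])
  removed[["height_weight_quantile"]] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  out <- tibble::as_tibble(table)
  attr(out, "cleaning_report") <- list(
    removed_per_rule = as.list(removed),
    rows_before = rows_before,
    rows_after = nrow(out)
  )
  out
}

#' Deduplicate then filter a cohort, with a combined report
#'
#' Convenience wrapper running [drop_duplicates()] then [filter_outliers()]
#' and merging their bookkeeping into one cleaning report.
#'
#' @inheritParams filter_outliers
#' @return The cleaned tibble with attribute `"cleaning_report"` including
#'   a `duplicate` rule count.
#' @export
clean_cohort <- function(table, lower_q = 0.05, upper_q = 0.95) {
  rows_before <- nrow(table)
  dedup <- drop_duplicates(table)
  ndup <- attr(dedup, "removed")
  out <- filter_outliers(dedup, lower_q = lower_q, upper_q = upper_q)
  rep <- attr(out, "cleaning_report")
  rep$removed_per_rule <- c(list(duplicate = ndup), rep$removed_per_rule)
  rep$rows_before <- rows_before
  attr(out, "cleaning_report") <- rep
  out
}

#' Extract a cleaning report as a tibble
#'
#' @param table A tibble returned by [filter_outliers()] or
#'   [clean_cohort()].
#' @return A tibble with columns `rule`, `removed`, plus attributes
#'   `rows_before`/`rows_after`.
#' @export
cleaning_report <- function(table) {
  rep <- attr(table, "cleaning_report")
  if (is.null(rep)) stop("no cleaning report attached", call. = FALSE)
  out <- tibble::tibble(
    rule = names(rep$removed_per_rule),
    removed = unlist(rep$removed_per_rule, use.names = FALSE)
  )
  attr(out, "rows_before") <- rep$rows_before
  attr(out, "rows_after") <- rep$rows_after
  out
}

#' Add the derived clinical features BMI, MAP and PP
#'
#' Appends three constructed risk features to a cohort table:
#' body-mass index `BMI = weight / height_m^2` (kg/m^2, height converted
#' from cm), mean arterial pressure `MAP = (ap_hi + 2 ap_lo) / 3` (mmHg),
#' and pulse pressure `PP = ap_hi - ap_lo` (mmHg). Original columns are
#' untouched.
#'
#' @param table A cohort data frame with positive heights.
#' @return The tibble with `BMI`, `MAP`, `PP` appended.
#' @export
add_derived_features <- function(table) {
  if (any(table$height <= 0)) {
    stop("height must be positive for BMI", call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(table),
    BMI = .data$weight / (.data$height / 100)^2,
    MAP = (.data$ap_hi + 2 * .data$ap_lo) / 3,
    PP = .data$ap_hi - .data$ap_lo
  )
}

#' Min-max normalise a numeric vector to \[0, 1\]
#'
#' `y_i = (x_i - min x) / (max x - min x)`. A constant column has no scale;
#' it maps to all zeros with a warning rather than erroring, so pipelines
#' on tiny fixtures keep running.
#'
#' @param x Non-empty numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0L) stop("`x` must be non-empty", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant column: min-max normalisation returns zeros",
            call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Min-max normalise the continuous columns of a cohort
#'
#' Applies [minmax_normalize()] to the continuous features so that
#' different physical scales (days of age vs mmHg vs kg) do not dominate
#' one another downstream. Default column set: age, height, weight, ap_hi,
#' ap_lo, MAP, PP; `include_bmi = TRUE` adds BMI.
#'
#' @param table Cohort tibble (after [add_derived_features()] if MAP/PP/BMI
#'   are to be scaled).
#' @param columns Character vector of columns to scale; only those present
#'   are touched.
#' @param include_bmi Also scale BMI (default TRUE).
#' @return The tibble with the named columns rescaled in place.
#' @export
normalize_features <- function(table,
                               columns = c("age", "height", "weight",
                                           "ap_hi", "ap_lo", "MAP", "PP"),
                               include_bmi = TRUE) {
  if (include_bmi) columns <- union(columns, "BMI")
  columns <- intersect(columns, names(table))
  table <- tibble::as_tibble(table)
  for (cl in columns) table[[cl]] <- minmax_normalize(table[[cl]])
  table
}

#' One-hot encode a categorical column
#'
#' Expands a categorical vector into one indicator column per level; each
#' row has exactly one 1 across the produced columns.
#'
#' @param x Vector of category values.
#' @param levels Ordered vector of permitted levels (default: sorted unique
#'   values of `x`).
#' @param prefix Name prefix for the produced columns.
#' @return A tibble of 0/1 indicator columns named `<prefix>_<level>`.
#' @export
one_hot_encode <- function(x, levels = sort(unique(x)), prefix = "x") {
  unseen <- setdiff(unique(x), levels)
  if (length(unseen) > 0) {
    stop("value(s) not in `levels`: ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(levels, function(lv) as.integer(x == lv))
  names(cols) <- paste0(prefix, "_", levels)
  tibble::as_tibble(cols)
}

#' One-hot encode a column inside a cohort table
#'
#' Replaces `column` with its indicator expansion (used for `gender`, whose
#' 1/2 coding would otherwise impose a spurious order).
#'
#' @param table Cohort tibble.
#' @param column Column name to expand.
#' @param levels Permitted levels (default sorted unique values).
#' @return The tibble with `column` replaced by indicator columns.
#' @export
encode_onehot_column <- function(table, column = "gender",
                                 levels = sort(unique(table[[column]]))) {
  enc <- one_hot_encode(table[[column]], levels = levels, prefix = column)
  idx <- match(column, names(table))
  dplyr::bind_cols(
    table[seq_len(idx - 1L)], enc,
    table[setdiff(seq_along(table), seq_len(idx))]
  )
}

#' Pearson correlation matrix of selected columns
#'
#' Entry (a, b) is `Cov(a, b) / (sd_a sd_b)`; the diagonal is 1 and the
#' matrix is symmetric with entries in \[-1, 1\].
#'
#' @param table Cohort data frame.
#' @param columns Columns to correlate (default: all numeric columns).
#' @return A symmetric correlation matrix.
#' @export
pearson_matrix <- function(table,
                           columns = names(table)[vapply(table, is.numeric,
                                                         logical(1))]) {
  m <- as.matrix(table[columns])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(columns[sds == 0], collapse = ", "), call. = FALSE)
  }
  stats::cor(m)
}
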