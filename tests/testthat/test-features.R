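make_small_cohort <- function(n = 60, seed = 2) {
  generate_cohort(cohort_spec(n, seed = seed))
}

test_that("drop_duplicates keeps first occurrences and counts removals", {
  coh <- make_small_cohort()
  pair <- dplyr::bind_rows(coh, coh[4, ])
  out <- drop_duplicates(pair)
  expect_equal(attr(out, "removed"), 1)
  expect_equal(nrow(out), nrow(coh))

  out2 <- drop_duplicates(coh)
  expect_equal(attr(out2, "removed"), 0)
  expect_equal(as.data.frame(out2), as.data.frame(coh),
               ignore_attr = TRUE)

  k <- 7
  many <- dplyr::bind_rows(coh, coh[rep(9, k), ])
  expect_equal(attr(drop_duplicates(many), "removed"), k)

  # duplicates differing only in id are still duplicates
  reid <- coh[4, ]
  reid$id <- 9999L
  expect_equal(attr(drop_duplicates(dplyr::bind_rows(coh, reid)),
                    "removed"), 1)
})

test_that("filter_outliers removes rule violations in order", {
  coh <- make_small_cohort(100)
  bad <- coh[1:5, ]
  bad$id <- 1000:1004
  bad$ap_lo[1] <- -70          # negative blood pressure
  bad$ap_hi[2] <- 230          # systolic over 200
  bad$ap_lo[3] <- 30           # diastolic under 50
  bad$ap_hi[4] <- -150         # negative systolic
  bad$ap_lo[5] <- -1           # boundary: zero is not a valid pressure
  tbl <- dplyr::bind_rows(coh, bad)
  out <- filter_outliers(tbl, lower_q = 0, upper_q = 1)
  rep <- attr(out, "cleaning_report")
  expect_equal(rep$removed_per_rule$negative_bp, 3)
  expect_equal(rep$removed_per_rule$ap_hi_over_200, 1)
  expect_equal(rep$removed_per_rule$ap_lo_under_50, 1)
  expect_equal(rep$removed_per_rule$height_weight_quantile, 0)
  expect_equal(rep$rows_before - rep$rows_after,
               sum(unlist(rep$removed_per_rule)))
  expect_false(any(1000:1004 %in% out$id))
})

test_that("an in-bounds table with trivial quantiles passes unchanged", {
  coh <- make_small_cohort()
  out <- filter_outliers(coh, lower_q = 0, upper_q = 1)
  expect_equal(as.data.frame(out), as.data.frame(coh),
               ignore_attr = TRUE)
})

test_that("quantile trim drops either-column violations", {
  coh <- make_small_cohort(200, seed = 9)
  out <- filter_outliers(coh)
  h_b <- stats::quantile(coh$height, c(0.05, 0.95), names = FALSE)
  w_b <- stats::quantile(coh$weight, c(0.05, 0.95), names = FALSE)
  keep <- !(coh$height < h_b[1] | coh$height > h_b[2] |
              coh$weight < w_b[1] | coh$weight > w_b[2])
  expect_equal(nrow(out), sum(keep))
  expect_setequal(out$id, coh$id[keep])
})

test_that("deduplication and blood-pressure filtering are idempotent", {
  # the anthropometric quantile trim always re-computes its bounds on the
  # table it receives, so it is deliberately excluded here (a second pass
  # trims a further 5% tail of the survivors); see the methods vignette
  spec <- cohort_spec(300, seed = 4, dup_count = 3,
                      outliers = list(negative_bp = 2, ap_hi_over_200 = 2))
  tbl <- plant_anomalies(generate_cohort(spec), spec)
  once <- clean_cohort(tbl, lower_q = 0, upper_q = 1)
  twice <- clean_cohort(once, lower_q = 0, upper_q = 1)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_equal(sum(cleaning_report(twice)$removed), 0)
})

test_that("derived features match their clinical definitions", {
  tbl <- tibble::tibble(height = 170L, weight = 70, ap_hi = 120L,
                        ap_lo = 80L)
  out <- add_derived_features(tbl)
  expect_equal(out$BMI, 70 / 1.7^2, tolerance = 1e-12)   # 24.2214...
  expect_equal(out$MAP, (120 + 2 * 80) / 3, tolerance = 1e-12)
  expect_equal(out$PP, 40)

  eq <- add_derived_features(tibble::tibble(height = 160L, weight = 60,
                                            ap_hi = 95L, ap_lo = 95L))
  expect_equal(eq$MAP, 95)
  expect_equal(eq$PP, 0)

  expect_error(add_derived_features(tibble::tibble(height = 0L,
                                                   weight = 60,
                                                   ap_hi = 1L,
                                                   ap_lo = 1L)),
               "height")
})

test_that("MAP and PP are linear in the underlying pressures", {
  a <- c(ap_hi = 120, ap_lo = 80)
  b <- c(ap_hi = 180, ap_lo = 100)
  lam <- 0.3
  mix <- lam * a + (1 - lam) * b
  map_of <- function(v) (v[["ap_hi"]] + 2 * v[["ap_lo"]]) / 3
  pp_of <- function(v) v[["ap_hi"]] - v[["ap_lo"]]
  expect_equal(map_of(mix), lam * map_of(a) + (1 - lam) * map_of(b))
  expect_equal(pp_of(mix), lam * pp_of(a) + (1 - lam) * pp_of(b))
})

test_that("min-max normalisation maps onto [0,1] with exact endpoints", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(50, sd = 10)
    y <- minmax_normalize(x)
    expect_equal(y[which.min(x)], 0)
    expect_equal(y[which.max(x)], 1)
    expect_true(all(y >= 0 & y <= 1))
    # affine invariance
    a <- runif(1, 0.1, 5)
    b <- rnorm(1)
    expect_equal(minmax_normalize(a * x + b), y, tolerance = 1e-12)
  }
  expect_warning(z <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
})

test_that("normalize_features rescales the continuous block in place", {
  coh <- add_derived_features(make_small_cohort(80, seed = 6))
  out <- normalize_features(coh)
  for (cl in c("age", "height", "weight", "ap_hi", "ap_lo", "MAP", "PP",
               "BMI")) {
    expect_true(all(out[[cl]] >= 0 & out[[cl]] <= 1), info = cl)
  }
  expect_equal(out$cholesterol, coh$cholesterol)  # untouched
})

test_that("one-hot encoding partitions each row", {
  enc <- one_hot_encode(c(1, 2, 1), levels = c(1, 2), prefix = "gender")
  expect_equal(enc$gender_1, c(1L, 0L, 1L))
  expect_equal(enc$gender_2, c(0L, 1L, 0L))
  expect_true(all(rowSums(enc) == 1))

  single <- one_hot_encode(c("a", "a"), prefix = "v")
  expect_equal(single$v_a, c(1L, 1L))

  expect_error(one_hot_encode(c(1, 3), levels = c(1, 2)), "not in")

  coh <- make_small_cohort()
  wide <- encode_onehot_column(coh, "gender")
  expect_false("gender" %in% names(wide))
  expect_true(all(wide$gender_1 + wide$gender_2 == 1))
})

test_that("pearson_matrix agrees with a brute-force moment computation", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 6.5)
  m <- pearson_matrix(tibble::tibble(x = x, y = y))
  # E[XY] - E[X]E[Y] over sd's, with the sample (n-1) convention
  n <- 3
  cov_xy <- (sum(x * y) - n * mean(x) * mean(y)) / (n - 1)
  r_oracle <- cov_xy / (stats::sd(x) * stats::sd(y))
  expect_equal(m["x", "y"], r_oracle, tolerance = 1e-12)
  expect_equal(diag(m), c(x = 1, y = 1))
  expect_equal(m["x", "y"], m["y", "x"])

  m2 <- pearson_matrix(tibble::tibble(a = x, b = -x))
  expect_equal(m2["a", "b"], -1)

  expect_error(pearson_matrix(tibble::tibble(a = x, b = c(1, 1, 1))),
               "zero-variance")
})

test_that("cohort correlation matrices are positive semidefinite", {
  coh <- add_derived_features(make_small_cohort(120, seed = 8))
  m <- pearson_matrix(coh, c("age", "height", "weight", "ap_hi", "ap_lo",
                             "MAP", "PP", "BMI"))
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
  expect_gte(min(eigen(m, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
})
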