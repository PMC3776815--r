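# Ecological layer: link askers to county attributes and relate bullying
# and self-classification accuracy to county obesity prevalence and income.

#' Attach county attributes to asker records via zip code
#'
#' Joins records to counties through a zip-to-county map and a county
#' attribute table. Unmapped zips are allowed: those records get `linked =
#' FALSE` and `NA` attributes, and the unlinked count is reported as a
#' message. Duplicate zips in the map resolve deterministically to the first
#' occurrence, with a warning.
#'
#' @param records Asker records carrying a `zip` column.
#' @param zip_map Tibble with `zip`, `county_id`.
#' @param county_table Tibble with `county_id`, `obesity_pct`,
#'   `median_income`.
#' @return `records` with `county_id`, `obesity_pct`, `median_income` and
#'   `linked` columns; the unlinked count as attribute `n_unlinked`.
#' @export
link_counties <- function(records, zip_map, county_table) {
  if (anyDuplicated(zip_map$zip)) {
    warn("duplicate zip(s) in zip-to-county map; keeping first occurrence")
    zip_map <- zip_map[!duplicated(zip_map$zip), ]
  }
  out <- records |>
    dplyr::left_join(zip_map, by = "zip") |>
    dplyr::left_join(
      dplyr::select(county_table, "county_id", "obesity_pct", "median_income"),
      by = "county_id"
    ) |>
    dplyr::mutate(linked = !is.na(.data$obesity_pct))
  n_unlinked <- sum(!out$linked)
  if (n_unlinked > 0) {
    inform(sprintf("%d record(s) could not be linked to a county", n_unlinked))
  }
  attr(out, "n_unlinked") <- n_unlinked
  out
}

#' Bullying fraction as a function of county obesity prevalence
#'
#' Bins county-linked askers into equal-width bins of county obesity
#' percentage and computes the per-bin fraction with a later bullying post,
#' overall and partitioned by inquiry class (low terms skinny/thin vs high
#' terms fat/obese). Empty bins carry an `NA` fraction.
#'
#' @param records County-linked asker records with a logical `bullied`
#'   column and `obesity_pct`.
#' @param n_bins Number of bins (at least 3).
#' @return A tibble of class `bullying_curve`: `term_class` ("all", "low",
#'   "high"), `bin`, `lo`, `hi`, `mid`, `n_askers`, `n_bullying`,
#'   `fraction`.
#' @export
bullying_fraction_curve <- function(records, n_bins = 10) {
  if (n_bins < 3) abort("n_bins must be at least 3")
  rec <- dplyr::filter(records, .data$linked)
  rng <- range(rec$obesity_pct)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  rec$bin <- cut(rec$obesity_pct, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  rec$term_class <- ifelse(rec$term %in% high_terms(), "high", "low")
  one_curve <- function(df, label) {
    counts <- df |>
      dplyr::count(.data$bin, wt = NULL, name = "n_askers")
    bully <- df |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(n_bullying = sum(.data$bullied), .groups = "drop")
    tibble::tibble(bin = seq_len(n_bins)) |>
      dplyr::left_join(counts, by = "bin") |>
      dplyr::left_join(bully, by = "bin") |>
      dplyr::mutate(
        term_class = label,
        lo = breaks[.data$bin], hi = breaks[.data$bin + 1],
        mid = (.data$lo + .data$hi) / 2,
        n_askers = dplyr::coalesce(.data$n_askers, 0L),
        n_bullying = dplyr::coalesce(as.integer(.data$n_bullying), 0L),
        fraction = ifelse(.data$n_askers > 0, .data$n_bullying / .data$n_askers, NA_real_)
      ) |>
      dplyr::select(
        "term_class", "bin", "lo", "hi", "mid",
        "n_askers", "n_bullying", "fraction"
      )
  }
  out <- dplyr::bind_rows(
    one_curve(rec, "all"),
    one_curve(rec[rec$term_class == "low", ], "low"),
    one_curve(rec[rec$term_class == "high", ], "high")
  )
  structure(out, class = c("bullying_curve", class(out)))
}

#' Quadratic curvature of a bullying curve
#'
#' Fits `fraction ~ mid + mid^2` over occupied bins, weighted by bin size.
#' A positive quadratic coefficient indicates the U-shape (bullying high at
#' both extremes of county obesity).
#'
#' @param curve A `bullying_curve`, see [bullying_fraction_curve()].
#' @param term_class Which partition to fit ("all", "low" or "high").
#' @return A list: `curvature` (quadratic coefficient), `p_value`,
#'   `u_shaped` (positive curvature).
#' @export
curve_curvature <- function(curve, term_class = "all") {
  df <- curve[curve$term_class == term_class & !is.na(curve$fraction), ]
  if (nrow(df) < 3) abort("need at least 3 occupied bins to assess curvature")
  fit <- lm(fraction ~ mid + I(mid^2), data = df, weights = df$n_askers)
  co <- summary(fit)$coefficients
  curvature <- co["I(mid^2)", "Estimate"]
  p <- co["I(mid^2)", "Pr(>|t|)"]
  list(curvature = curvature, p_value = p, u_shaped = curvature > 0)
}

#' Absolute deviation from the mean
#'
#' Transforms county exposure values to `|x - mean(x)|`, the fold used to
#' test whether distance from the average (rather than level) drives an
#' outcome. Shift-invariant: adding a constant to every value changes
#' nothing.
#'
#' @param x Numeric vector (at least one value).
#' @return `abs(x - mean(x))`.
#' @export
#' @examples
#' abs_deviation_transform(c(20, 30, 40)) # 10 0 10
abs_deviation_transform <- function(x) {
  if (length(x) < 1) abort("need at least one value")
  abs(x - mean(x))
}

#' Self-classification accuracy in high- vs low-obesity counties
#'
#' Splits counties at the median (or mean) observed obesity prevalence and
#' compares, per gender x actual weight class (overweight/obese combined),
#' the congruence rate between inquired and actual category across the two
#' county groups with 2x2 chi-squared tests. Also reports the inquiry-
#' composition comparison for normal-weight askers: the fraction asking a
#' high-weight term ("am I fat/obese") in high vs low counties.
#'
#' @param records County-linked records with `congruent`, `gender`,
#'   `actual`, `term`, `obesity_pct`.
#' @param split `"median"` (default) or `"mean"` county split.
#' @return A list of class `county_accuracy`: `congruence` (per group:
#'   rates and p-values), `normal_inquiry` (high-term share among
#'   normal-weight askers), `threshold`.
#' @export
accuracy_by_county <- function(records, split = c("median", "mean")) {
  split <- match.arg(split)
  rec <- dplyr::filter(records, .data$linked)
  counties <- unique(rec[, c("county_id", "obesity_pct")])
  threshold <- if (split == "median") {
    median(counties$obesity_pct)
  } else {
    mean(counties$obesity_pct)
  }
  rec$high_county <- rec$obesity_pct > threshold
  rec$actual3 <- ifelse(rec$actual %in% c("overweight", "obese"),
    "overweight/obese", rec$actual
  )
  congruence <- rec |>
    dplyr::group_by(.data$gender, .data$actual3) |>
    dplyr::group_modify(function(df, key) {
      n_hi <- sum(df$high_county)
      n_lo <- sum(!df$high_county)
      if (n_hi == 0 || n_lo == 0) {
        inform(sprintf(
          "skipping %s/%s: empty county group", key$gender, key$actual3
        ))
        return(tibble::tibble(
          n_high = n_hi, k_high = NA_integer_, n_low = n_lo,
          k_low = NA_integer_, rate_high = NA_real_, rate_low = NA_real_,
          p_value = NA_real_
        ))
      }
      k_hi <- sum(df$congruent[df$high_county])
      k_lo <- sum(df$congruent[!df$high_county])
      tab <- matrix(c(k_hi, n_hi - k_hi, k_lo, n_lo - k_lo), 2, byrow = TRUE)
      tibble::tibble(
        n_high = n_hi, k_high = k_hi, n_low = n_lo, k_low = k_lo,
        rate_high = k_hi / n_hi, rate_low = k_lo / n_lo,
        p_value = test_2x2(tab)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(actual = "actual3")
  normal <- rec[rec$actual == "normal", ]
  normal$high_term <- normal$term %in% high_terms()
  normal_inquiry <- dplyr::bind_rows(
    dplyr::mutate(normal, gender = "all"),
    normal
  ) |>
    dplyr::group_by(.data$gender) |>
    dplyr::group_modify(function(df, key) {
      n_hi <- sum(df$high_county)
      n_lo <- sum(!df$high_county)
      if (n_hi == 0 || n_lo == 0) {
        return(tibble::tibble(
          n_high = n_hi, n_low = n_lo,
          rate_high = NA_real_, rate_low = NA_real_, p_value = NA_real_
        ))
      }
      k_hi <- sum(df$high_term[df$high_county])
      k_lo <- sum(df$high_term[!df$high_county])
      tab <- matrix(c(k_hi, n_hi - k_hi, k_lo, n_lo - k_lo), 2, byrow = TRUE)
      tibble::tibble(
        n_high = n_hi, n_low = n_lo,
        rate_high = k_hi / n_hi, rate_low = k_lo / n_lo,
        p_value = test_2x2(tab)
      )
    }) |>
    dplyr::ungroup()
  structure(
    list(
      congruence = congruence, normal_inquiry = normal_inquiry,
      threshold = threshold, split = split
    ),
    class = "county_accuracy"
  )
}

#' Odds ratio from two binomial groups
#'
#' `(k1 (n0 - k0)) / ((n1 - k1) k0)`: the odds of the outcome in group 1
#' relative to group 0.
#'
#' @param k1,n1 Events and size of group 1.
#' @param k0,n0 Events and size of group 0.
#' @return The odds ratio.
#' @export
#' @examples
#' odds_ratio(100, 1000, 50, 1000) # 2.11
odds_ratio <- function(k1, n1, k0, n0) {
  (k1 * (n0 - k0)) / ((n1 - k1) * k0)
}

#' Association between county median income and bullying
#'
#' Logistic fit of the bullying flag on county median income gives the
#' direction of the association; a Cochran-Armitage-style trend test over
#' income quantile groups supplies the p-value. With a single income level
#' the association is not evaluable.
#'
#' @param records County-linked records with `bullied` and `median_income`.
#' @param n_quantiles Number of income groups for the trend test.
#' @return A list of class `income_assoc`: `direction` (-1, 0, 1),
#'   `slope` (log-odds per income unit), `p_value` (trend test),
#'   `groups` (per-quantile counts), `evaluable`.
#' @export
income_bullying_association <- function(records, n_quantiles = 4) {
  rec <- dplyr::filter(records, .data$linked)
  if (length(unique(rec$median_income)) < 2) {
    return(structure(
      list(
        direction = NA_integer_, slope = NA_real_, p_value = NA_real_,
        groups = NULL, evaluable = FALSE
      ),
      class = "income_assoc"
    ))
  }
  fit <- glm(bullied ~ median_income, data = rec, family = binomial())
  slope <- coef(fit)[["median_income"]]
  qs <- quantile(rec$median_income, probs = seq(0, 1, length.out = n_quantiles + 1))
  grp <- cut(rec$median_income, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  groups <- rec |>
    dplyr::mutate(grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      n = dplyr::n(), k = sum(.data$bullied),
      income_mid = median(.data$median_income), .groups = "drop"
    )
  trend <- prop.trend.test(groups$k, groups$n, score = seq_len(nrow(groups)))
  g1 <- groups[nrow(groups), ]
  g0 <- groups[1, ]
  structure(
    list(
      direction = as.integer(sign(slope)), slope = slope,
      p_value = trend$p.value, groups = groups,
      or_extremes = odds_ratio(g1$k, g1$n, g0$k, g0$n),
      evaluable = TRUE
    ),
    class = "income_assoc"
  )
}

#' @export
print.income_assoc <- function(x, ...) {
  if (!x$evaluable) {
    cat("Income-bullying association: not evaluable (degenerate income)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Income-bullying association: odds %s with income (trend p = %.4g)\n",
    c(`-1` = "decrease", `0` = "flat", `1` = "increase")[as.character(x$direction)],
    x$p_value
  ))
  invisible(x)
}
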