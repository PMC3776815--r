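# Stratified future-posting ratios vs the pooled asker population, BH-FDR
# control, and the bullying association with its gender x term interaction.

#' Posting ratio of a stratum against the pooled population
#'
#' The ratio of the probability that a user in the stratum posts to the
#' category over the same probability in the pooled asker population:
#' `(k_stratum/n_stratum) / (k_all/n_all)`. The p-value comes from a
#' two-sided exact binomial test of `k_stratum` out of `n_stratum` against
#' the pooled rate. When the pooled count is zero the ratio is undefined and
#' the result is flagged not evaluable.
#'
#' @param k_stratum,n_stratum Users in the stratum posting to the category /
#'   total users in the stratum (`n_stratum >= 1`).
#' @param k_all,n_all Same counts for the pooled population
#'   (`n_all >= n_stratum`; the stratum is part of the pool).
#' @param stratum,category Optional labels carried into the result.
#' @return A one-row tibble: counts, `ratio`, `p_value`, `evaluable`.
#' @export
#' @examples
#' posting_ratio(10, 100, 20, 1000) # ratio 5
posting_ratio <- function(k_stratum, n_stratum, k_all, n_all,
                          stratum = NA_character_, category = NA_character_) {
  stopifnot(n_stratum >= 1, n_all >= n_stratum, k_stratum <= n_stratum, k_all <= n_all)
  evaluable <- k_all > 0
  ratio <- if (evaluable) (k_stratum / n_stratum) / (k_all / n_all) else NA_real_
  p <- if (evaluable) {
    binom.test(k_stratum, n_stratum, p = k_all / n_all)$p.value
  } else {
    NA_real_
  }
  tibble::tibble(
    stratum = stratum, category = category,
    n_stratum = n_stratum, k_stratum = k_stratum,
    n_all = n_all, k_all = k_all,
    ratio = ratio, p_value = p, evaluable = evaluable
  )
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up q-values (`stats::p.adjust(method = "BH")`) and a significance
#' flag at the given FDR threshold.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param q_threshold FDR threshold (default 0.05).
#' @return A tibble with `p_value`, `q_value`, `significant`; empty input
#'   gives an empty tibble.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.30))
bh_fdr <- function(p_values, q_threshold = 0.05) {
  if (length(p_values) == 0) {
    return(tibble::tibble(
      p_value = numeric(), q_value = numeric(), significant = logical()
    ))
  }
  assert_prob(p_values, "p_values")
  q <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, q_value = q, significant = q <= q_threshold)
}

#' Default stratification for the over-expression screen
#'
#' Crosses gender with the three-level actual weight class (underweight,
#' normal, overweight/obese combined) and the inquired-term class (low =
#' skinny/thin, high = fat/obese), mirroring how significant posting
#' differences are usually tabulated.
#'
#' @return A tibble with columns `stratum`, `gender`, `actual`, `term`
#'   (`NA` entries are wildcards).
#' @export
default_strata <- function() {
  tidyr::crossing(
    gender = c("male", "female"),
    actual = c("underweight", "normal", "overweight|obese"),
    term = c("skinny|thin", "fat|obese")
  ) |>
    dplyr::mutate(stratum = paste(
      .data$gender,
      sub("\\|.*", "+", .data$actual),
      ifelse(.data$term == "skinny|thin", "low-term", "high-term")
    )) |>
    dplyr::select("stratum", "gender", "actual", "term")
}

#' Stratification over single axes
#'
#' Builds a strata table from any subset of the three axes: gender, actual
#' weight class and inquiry term.
#'
#' @param gender,actual,term Vectors of stratum definitions per axis (each
#'   entry may be `|`-separated or `NA` for "any").
#' @return A strata tibble for [category_overexpression()].
#' @export
#' @examples
#' strata_by(
#'   gender = c("male", "female"),
#'   actual = c("underweight", "normal", "overweight|obese")
#' )
strata_by <- function(gender = NA, actual = NA, term = NA) {
  tidyr::crossing(gender = gender, actual = actual, term = term) |>
    dplyr::mutate(stratum = trimws(paste(
      ifelse(is.na(.data$gender), "", .data$gender),
      ifelse(is.na(.data$actual), "", gsub("|", "/", .data$actual, fixed = TRUE)),
      ifelse(is.na(.data$term), "", paste0("asks:", gsub("|", "/", .data$term, fixed = TRUE)))
    ))) |>
    dplyr::select("stratum", "gender", "actual", "term")
}

# user-level future posts: categories each asker posted to after the inquiry
future_posts_of <- function(records, posts, categories = taxonomy_categories()) {
  rec_t <- parse_time(records$timestamp)
  posts |>
    dplyr::filter(
      .data$user_id %in% records$user_id,
      .data$category %in% categories
    ) |>
    dplyr::mutate(
      after = parse_time(.data$timestamp) >
        rec_t[match(.data$user_id, records$user_id)]
    ) |>
    dplyr::filter(.data$after) |>
    dplyr::distinct(.data$user_id, .data$category)
}

#' Screen categories for over-expression by stratum
#'
#' For every (stratum, category) pair computes the user-level posting ratio
#' against the pooled asker population ([posting_ratio()]) and controls the
#' false discovery rate with Benjamini-Hochberg, by default within each
#' gender's family of tests. A category is over-expressed in a stratum when
#' its ratio exceeds 1 and the q-value passes the threshold.
#'
#' @param records Asker records ([build_asker_records()]); must carry
#'   `user_id`, `timestamp`, `gender`, `actual`, `term`.
#' @param posts Full posts tibble (future posts are selected by user id,
#'   category and a timestamp later than the user's inquiry).
#' @param strata Strata table, see [default_strata()] / [strata_by()].
#' @param categories Category universe to test.
#' @param q_threshold FDR threshold.
#' @param fdr_family `"per_gender"` (default) adjusts within each stratum
#'   gender; `"global"` adjusts across all tests at once.
#' @return A tibble of class `overexpression_result`, one row per stratum x
#'   category: counts, `ratio`, `p_value`, `q_value`, `significant`,
#'   `overexpressed`.
#' @export
category_overexpression <- function(records, posts, strata = default_strata(),
                                    categories = taxonomy_categories(),
                                    q_threshold = 0.05,
                                    fdr_family = c("per_gender", "global")) {
  fdr_family <- match.arg(fdr_family)
  future <- future_posts_of(records, posts, categories)
  n_all <- nrow(records)
  k_all_by_cat <- future |> dplyr::count(.data$category)
  k_all <- setNames(
    k_all_by_cat$n[match(categories, k_all_by_cat$category)], categories
  )
  k_all[is.na(k_all)] <- 0L

  rows <- purrr::pmap_dfr(strata, function(stratum, gender, actual, term) {
    member <- match_stratum(records, gender, actual, term)
    n_s <- sum(member)
    if (n_s == 0) {
      return(tibble::tibble())
    }
    users <- records$user_id[member]
    k_s_by_cat <- future |>
      dplyr::filter(.data$user_id %in% users) |>
      dplyr::count(.data$category)
    purrr::map_dfr(categories, function(cat_path) {
      k_s <- k_s_by_cat$n[match(cat_path, k_s_by_cat$category)]
      k_s <- if (is.na(k_s)) 0L else k_s
      posting_ratio(k_s, n_s, k_all[[cat_path]], n_all,
        stratum = stratum, category = cat_path
      ) |>
        dplyr::mutate(gender = gender, actual = actual, term = term)
    })
  })
  if (nrow(rows) == 0) {
    return(structure(rows, class = c("overexpression_result", class(rows))))
  }
  family <- if (fdr_family == "per_gender") {
    dplyr::coalesce(rows$gender, "all")
  } else {
    rep("all", nrow(rows))
  }
  rows$q_value <- NA_real_
  rows$significant <- NA
  for (fam in unique(family)) {
    idx <- which(family == fam & rows$evaluable)
    if (length(idx) > 0) {
      adj <- bh_fdr(rows$p_value[idx], q_threshold)
      rows$q_value[idx] <- adj$q_value
      rows$significant[idx] <- adj$significant
    }
  }
  rows$overexpressed <- !is.na(rows$significant) & rows$significant & rows$ratio > 1
  rows <- dplyr::relocate(
    rows, "stratum", "gender", "actual", "term", "category"
  )
  structure(rows, class = c("overexpression_result", class(rows)))
}

#' Bullying fractions by stratum and the gender x term interaction
#'
#' Computes, per gender x inquiry-term stratum, the fraction of askers with
#' a later bullying-related post; each stratum is also compared against the
#' rest of its gender with a 2x2 chi-squared test (no continuity
#' correction; exact test fallback with a warning when an expected cell
#' falls below 1). The interaction of term and gender as a predictor of
#' bullying is tested as heterogeneity of term effects across genders: a
#' likelihood-ratio chi-squared between logistic models
#' `bullied ~ gender + term` and `bullied ~ gender * term`.
#'
#' @param records Asker records with `user_id`, `gender`, `term`.
#' @param bullying_flags Either a logical vector along `records`, or a
#'   tibble with `user_id` and logical `bullied` linking flags by user id.
#' @return An object of class `bullying_assoc`: list with `fractions` (a
#'   tibble gender x term: `n`, `k`, `fraction`, `p_vs_rest`) and
#'   `interaction` (`statistic`, `df`, `p_value`, `method`; `NULL` when no
#'   bullying events exist).
#' @export
bullying_association <- function(records, bullying_flags) {
  if (is.data.frame(bullying_flags)) {
    flag <- bullying_flags$bullied[match(records$user_id, bullying_flags$user_id)]
    flag[is.na(flag)] <- FALSE
  } else {
    stopifnot(length(bullying_flags) == nrow(records))
    flag <- bullying_flags
  }
  df <- tibble::tibble(gender = records$gender, term = records$term, bullied = flag)
  fractions <- df |>
    dplyr::group_by(.data$gender, .data$term) |>
    dplyr::summarise(
      n = dplyr::n(), k = sum(.data$bullied),
      fraction = mean(.data$bullied), .groups = "drop"
    )
  # each stratum vs the rest of its gender
  fractions$p_vs_rest <- purrr::pmap_dbl(
    fractions[, c("gender", "term", "n", "k")],
    function(gender, term, n, k) {
      rest <- df[df$gender == gender & df$term != term, ]
      if (nrow(rest) == 0 || sum(df$bullied[df$gender == gender]) == 0) {
        return(NA_real_)
      }
      tab <- matrix(c(k, n - k, sum(rest$bullied), nrow(rest) - sum(rest$bullied)),
        nrow = 2, byrow = TRUE
      )
      test_2x2(tab)
    }
  )
  interaction <- NULL
  if (any(flag)) {
    fit0 <- glm(bullied ~ gender + term, data = df, family = binomial())
    fit1 <- glm(bullied ~ gender * term, data = df, family = binomial())
    lrt <- anova(fit0, fit1, test = "Chisq")
    interaction <- list(
      statistic = lrt$Deviance[2], df = lrt$Df[2],
      p_value = lrt$`Pr(>Chi)`[2],
      method = "likelihood-ratio chi-squared, bullied ~ gender * term vs + term"
    )
  }
  structure(list(fractions = fractions, interaction = interaction),
    class = "bullying_assoc"
  )
}

#' Derive per-user bullying flags from posts
#'
#' Flags an asker as bullied when any of their posts dated after the inquiry
#' matches the bullying term matcher ([match_bullying()]) on title or body.
#'
#' @param records Asker records with `user_id` and `timestamp`.
#' @param posts Posts tibble.
#' @return A tibble with `user_id` and logical `bullied`.
#' @export
bullying_flags_from_posts <- function(records, posts) {
  rec_t <- parse_time(records$timestamp)
  later <- posts |>
    dplyr::filter(.data$user_id %in% records$user_id) |>
    dplyr::mutate(
      after = parse_time(.data$timestamp) >
        rec_t[match(.data$user_id, records$user_id)]
    ) |>
    dplyr::filter(.data$after)
  hits <- later$user_id[match_bullying(stringr::str_c(later$title, " ", later$body))]
  tibble::tibble(
    user_id = records$user_id,
    bullied = records$user_id %in% hits
  )
}

# 2x2 chi-squared without continuity correction; exact fallback when an
# expected count drops below 1
test_2x2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warn("expected cell count < 1; falling back to Fisher's exact test")
    return(fisher.test(tab)$p.value)
  }
  suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
}

#' @export
print.bullying_assoc <- function(x, ...) {
  cat("Bullying by gender and inquiry term\n")
  print(as.data.frame(x$fractions), row.names = FALSE)
  if (!is.null(x$interaction)) {
    cat(sprintf(
      "\nGender x term interaction: chi-squared = %.2f, df = %d, p = %.4g\n",
      x$interaction$statistic, x$interaction$df, x$interaction$p_value
    ))
  } else {
    cat("\nNo bullying events; interaction not tested.\n")
  }
  invisible(x)
}
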