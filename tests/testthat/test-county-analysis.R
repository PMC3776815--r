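# County linkage, bullying curve, deviation transform, accuracy, income.

make_linked_records <- function(n, counties, bully_prob, congruent_prob = 0.6,
                                seed = 1) {
  set.seed(seed)
  idx <- sample.int(nrow(counties), n, replace = TRUE)
  ob <- counties$obesity_pct[idx]
  inc <- counties$median_income[idx]
  p <- if (is.function(bully_prob)) bully_prob(ob, inc) else bully_prob
  pc <- if (is.function(congruent_prob)) congruent_prob(ob) else congruent_prob
  tibble::tibble(
    user_id = sprintf("u%d", seq_len(n)),
    gender = sample(c("male", "female"), n, TRUE),
    actual = sample(weight_classes(), n, TRUE),
    term = sample(inquiry_terms(), n, TRUE),
    county_id = counties$county_id[idx],
    obesity_pct = ob, median_income = inc,
    bullied = runif(n) < p,
    congruent = runif(n) < pc,
    linked = TRUE
  )
}

test_counties <- function() default_county_table()$counties

test_that("county linkage round-trips and reports unlinked records", {
  ct <- default_county_table()
  co <- small_corpus()
  rec <- build_asker_records(extract_posts(co$posts))
  linked <- link_counties(rec, ct$zip_map, ct$counties)
  expect_true(all(linked$linked))
  truth_county <- co$truth$county_id[match(linked$user_id, co$truth$user_id)]
  expect_identical(linked$county_id, truth_county)
  expect_identical(
    linked$obesity_pct,
    ct$counties$obesity_pct[match(truth_county, ct$counties$county_id)]
  )

  # empty map: everything unlinked, count reported
  expect_message(
    none <- link_counties(rec, ct$zip_map[0, ], ct$counties),
    "could not be linked"
  )
  expect_true(all(!none$linked))
  expect_identical(attr(none, "n_unlinked"), nrow(rec))

  # duplicate zips resolve first-wins with a warning
  dup <- dplyr::bind_rows(
    ct$zip_map,
    tibble::tibble(zip = ct$zip_map$zip[1], county_id = ct$counties$county_id[30])
  )
  expect_warning(l2 <- link_counties(rec, dup, ct$counties), "duplicate")
  expect_identical(l2$county_id, linked$county_id)
})

test_that("bullying curve conserves counts and partitions sum to the total", {
  rec <- make_linked_records(5000, test_counties(), bully_prob = 0.05, seed = 2)
  curve <- bullying_fraction_curve(rec, n_bins = 8)
  all_part <- curve[curve$term_class == "all", ]
  expect_identical(sum(all_part$n_askers), nrow(rec))
  lo <- curve[curve$term_class == "low", ]
  hi <- curve[curve$term_class == "high", ]
  expect_identical(lo$n_askers + hi$n_askers, all_part$n_askers)
  expect_identical(lo$n_bullying + hi$n_bullying, all_part$n_bullying)

  # flat generator: curve flat within binomial error everywhere
  ok <- abs(all_part$fraction - 0.05) <
    3 * sqrt(0.05 * 0.95 / pmax(all_part$n_askers, 1))
  expect_true(all(ok))

  # single county occupies a single bin
  one <- rec[rec$county_id == rec$county_id[1], ]
  curve1 <- bullying_fraction_curve(one, n_bins = 5)
  occupied <- curve1[curve1$term_class == "all" & curve1$n_askers > 0, ]
  expect_identical(nrow(occupied), 1L)

  expect_error(bullying_fraction_curve(rec, n_bins = 2), "at least 3")
})

test_that("absolute-deviation transform is correct and shift-invariant", {
  expect_equal(abs_deviation_transform(c(20, 30, 40)), c(10, 0, 10))
  expect_equal(abs_deviation_transform(rep(7, 5)), rep(0, 5))
  x <- c(18, 25, 31, 40)
  expect_equal(abs_deviation_transform(x), abs_deviation_transform(x + 13.7))
  expect_error(abs_deviation_transform(numeric(0)), "at least one")
})

test_that("planted U-shaped county bullying yields positive curvature", {
  u_prob <- function(ob, inc) 0.005 + 0.06 * ((ob - 30) / 15)^2
  hits <- 0
  for (i in 1:20) {
    rec <- make_linked_records(4000, test_counties(), bully_prob = u_prob, seed = 100 + i)
    curve <- bullying_fraction_curve(rec, n_bins = 10)
    if (curve_curvature(curve, "all")$u_shaped) hits <- hits + 1
  }
  expect_gte(hits, 18) # >= 90% of replicates
})

test_that("accuracy comparison: null counties show only nominal significance", {
  false_pos <- 0
  n_tests <- 0
  for (i in 1:100) {
    rec <- make_linked_records(800, test_counties(),
      bully_prob = 0.02,
      congruent_prob = 0.6, seed = 200 + i
    )
    acc <- suppressMessages(accuracy_by_county(rec))
    p <- acc$congruence$p_value
    false_pos <- false_pos + sum(p < 0.05, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(p))
  }
  rate <- false_pos / n_tests
  # nominal 5% plus Monte-Carlo margin
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_tests))
})

test_that("planted county congruence gradients are detected", {
  grad <- function(ob) 0.4 + 0.4 * (ob > 30)
  hits <- 0
  for (i in 1:10) {
    rec <- make_linked_records(20000, test_counties(),
      bully_prob = 0.02,
      congruent_prob = grad, seed = 300 + i
    )
    acc <- suppressMessages(accuracy_by_county(rec))
    row <- acc$congruence[acc$congruence$gender == "female" &
      acc$congruence$actual == "overweight/obese", ]
    if (!is.na(row$p_value) && row$p_value < 0.05 && row$rate_high > row$rate_low) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("income-bullying association recovers a planted negative gradient", {
  neg_prob <- function(ob, inc) pmin(0.2, 0.03 * exp(-(inc - 40000) / 20000))
  hits <- 0
  for (i in 1:20) {
    rec <- make_linked_records(4000, test_counties(), bully_prob = neg_prob, seed = 400 + i)
    ia <- income_bullying_association(rec)
    if (ia$evaluable && ia$direction == -1L && ia$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)

  # no gradient: trend non-significant at about the nominal rate
  set.seed(6)
  sig <- 0
  for (i in 1:50) {
    rec <- make_linked_records(1500, test_counties(), bully_prob = 0.03, seed = 500 + i)
    ia <- income_bullying_association(rec)
    if (ia$evaluable && ia$p_value < 0.05) sig <- sig + 1
  }
  expect_lt(sig / 50, 0.05 + 2 * sqrt(0.05 * 0.95 / 50))

  # degenerate income: not evaluable
  rec1 <- make_linked_records(100, test_counties()[1, ], bully_prob = 0.1)
  ia1 <- income_bullying_association(rec1)
  expect_false(ia1$evaluable)

  # hand odds-ratio check
  expect_equal(round(odds_ratio(100, 1000, 50, 1000), 2), 2.11)
})
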