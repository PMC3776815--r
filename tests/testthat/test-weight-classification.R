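# BMI, adult/teen classification, congruence, and the contingency table.

test_that("BMI follows the imperial formula and scaling law", {
  expect_equal(round(compute_bmi(180, 69), 2), 26.58)
  expect_equal(round(compute_bmi(110, 64), 2), 18.88)
  expect_equal(compute_bmi(150, 130), compute_bmi(150, 65) / 4)
  expect_error(compute_bmi(-1, 60), "positive")
  expect_error(compute_bmi(150, 0), "positive")
})

test_that("adult bands are half-open with edges in the higher band", {
  expect_identical(
    as.character(classify_adult(c(12, 18.4999, 18.5, 24.9, 25, 29.9, 30, 55))),
    c(
      "underweight", "underweight", "normal", "normal",
      "overweight", "overweight", "obese", "obese"
    )
  )
  # partition: every BMI maps to exactly one category
  grid <- seq(10, 60, by = 0.1)
  expect_false(any(is.na(classify_adult(grid))))
})

test_that("teen percentile matches the LMS formula and its inversion", {
  lms <- lms_reference()
  # at a table knot, bmi = M is the 50th percentile by construction
  row <- lms[lms$sex == "male" & lms$agemos == 180, ]
  expect_equal(teen_percentile(row$M, 180, "male"), 50)

  # L = 1 reduces the z-score to (bmi - M) / (M * S)
  toy <- tibble::tibble(
    sex = "male", agemos = c(150, 250), L = 1, M = 20, S = 0.1
  )
  expect_equal(
    teen_percentile(22, 200, "male", lms = toy),
    100 * pnorm((22 - 20) / (20 * 0.1))
  )

  # strictly increasing in bmi at fixed age and sex
  p <- teen_percentile(seq(14, 35, by = 0.25), 200, "female")
  expect_true(all(diff(p) > 0))

  # agrees with numerical quantile inversion to 0.1 percentile points
  for (sex in c("male", "female")) {
    for (agemos in c(156, 171, 200, 239)) {
      for (bmi in c(15, 17, 19.5, 22, 26, 31)) {
        expect_lt(
          abs(
            teen_percentile(bmi, agemos, sex) -
              lms_percentile_oracle(bmi, agemos, sex)
          ),
          0.1
        )
      }
    }
  }

  expect_error(teen_percentile(20, 300, "male"), "outside LMS support")
})

test_that("teen percentile bands partition [0, 100]", {
  expect_identical(
    as.character(classify_teen(c(0, 4.9, 5, 50, 85, 94.9, 95, 97, 100))),
    c("<5", "<5", "5-85", "5-85", "85-95", "85-95", "95+", "95+", "95+")
  )
  expect_false(any(is.na(classify_teen(seq(0, 100, by = 0.5)))))
  expect_error(classify_teen(101), "0, 100")
  expect_identical(
    unname(band_to_class(c("<5", "5-85", "85-95", "95+"))),
    c("underweight", "normal", "overweight", "obese")
  )
})

test_that("congruence follows the high/low term mapping", {
  expect_true(assess_congruence("fat", "obese"))
  expect_false(assess_congruence("obese", "normal"))
  expect_true(assess_congruence("thin", band_to_class("5-85")))
  expect_false(assess_congruence("skinny", "overweight"))
  # configurable mapping: strict per-term matching
  strict <- list(
    high_terms = "obese", high_classes = "obese",
    low_terms = c("skinny", "thin", "fat"),
    low_classes = c("underweight", "normal", "overweight")
  )
  expect_false(assess_congruence("obese", "overweight", strict))
})

test_that("exclusion accounting reproduces retained counts and errors on deficits", {
  acc <- asker_accounting(
    c(skinny = 6189, thin = 17541, fat = 51988, obese = 7353),
    c(skinny = 5965, thin = 16769, fat = 49352, obese = 7059)
  )
  expect_identical(acc$retained, c(224L, 772L, 2636L, 294L))
  expect_identical(attr(acc, "total"), 3926L)
  expect_error(asker_accounting(c(fat = 10), c(fat = 11)), "negative")
})

test_that("the published contingency-table arithmetic reproduces", {
  tab <- asker_table_from_counts()
  expect_identical(round(tab$summary$pct), c(68, 40, 51, 30))
  expect_identical(tab$age$total[tab$age$row == "13-15"], 1708L)
  expect_identical(sum(tab$teen_pct$total), 2937L)
  expect_identical(attr(tab$accounting, "total"), 3926L)
})

test_that("asker records apply the exclusion rules and accounting conserves", {
  co <- small_corpus()
  ex <- extract_posts(co$posts)
  rec <- build_asker_records(ex)
  expect_true(all(!is.na(rec$age) & !is.na(rec$gender) &
    !is.na(rec$weight_lb) & !is.na(rec$height_in)))
  expect_true(all(rec$term %in% inquiry_terms()))
  expect_true(all(rec$age >= 13))
  acc <- attr(rec, "accounting")
  expect_identical(acc$extracted, acc$retained + acc$excluded)
  expect_identical(sum(acc$retained), nrow(rec))
  # teens banded, adults not
  expect_true(all(is.na(rec$teen_band[rec$age_class == "adult"])))
  expect_true(all(rec$teen_band[rec$age_class == "teen"] %in% teen_bands()))

  # records rebuild the same table sections
  tab <- build_asker_table(rec)
  expect_identical(sum(tab$age$total), nrow(rec))
  expect_identical(sum(tab$adult_bmi$total) + sum(tab$teen_pct$total), nrow(rec))
})

test_that("an empty record set yields an all-zero table", {
  co <- small_corpus()
  ex <- extract_posts(co$posts)
  rec <- build_asker_records(ex[0, ])
  tab <- build_asker_table(rec)
  expect_identical(sum(tab$age$total), 0L)
  expect_identical(sum(tab$teen_pct$total), 0L)
})
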