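# Posting ratios, BH-FDR, the over-expression screen, bullying association.

test_that("posting ratio definition and self-comparison identity", {
  r <- posting_ratio(10, 100, 20, 1000)
  expect_equal(r$ratio, 5)
  expect_true(r$evaluable)

  # the pooled population against itself is exactly 1
  self <- posting_ratio(20, 1000, 20, 1000)
  expect_identical(self$ratio, 1)

  # zero pooled count: not evaluable
  z <- posting_ratio(0, 10, 0, 100)
  expect_false(z$evaluable)
  expect_true(is.na(z$ratio))
})

test_that("BH q-values match a brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.30))$q_value, c(0.03, 0.03, 0.30))
  one <- bh_fdr(0.04)
  expect_equal(one$q_value, 0.04)
  expect_true(one$significant)
  expect_false(any(bh_fdr(rep(1, 10))$significant))
  expect_identical(nrow(bh_fdr(numeric(0))), 0L)

  set.seed(4)
  for (rep in 1:200) {
    m <- sample(1:8, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    got <- bh_fdr(p)
    want <- bh_oracle(p)
    expect_equal(got$q_value, want$q, tolerance = 1e-12)
    expect_identical(got$significant, want$significant)
  }
  # q is monotone non-decreasing in sorted-p order and never below p
  set.seed(5)
  p <- runif(50)
  q <- bh_fdr(p)$q_value
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("over-expression screen recovers planted effects and respects families", {
  rec <- planted_records()
  corpus <- planted_corpus()
  ov <- category_overexpression(
    rec, corpus$posts,
    strata = strata_by(
      gender = c("male", "female"),
      actual = c("underweight", "normal", "overweight|obese")
    )
  )
  dia <- ov[ov$gender == "male" & ov$actual == "overweight|obese" &
    ov$category == "Health/Diseases/Diabetes", ]
  expect_true(dia$overexpressed)
  se <- ratio_log_se(dia$k_stratum, dia$n_stratum, dia$k_all, dia$n_all)
  expect_lt(abs(log(dia$ratio) - log(4.6)), 3 * se)

  ttc <- ov[ov$gender == "female" & ov$actual == "overweight|obese" &
    ov$category == "Pregnancy & Parenting/Trying to Conceive", ]
  expect_true(ttc$overexpressed)
  se2 <- ratio_log_se(ttc$k_stratum, ttc$n_stratum, ttc$k_all, ttc$n_all)
  expect_lt(abs(log(ttc$ratio) - log(3.1)), 3 * se2)

  # q-values never fall below their p-values
  expect_true(all(ov$q_value >= ov$p_value, na.rm = TRUE))
})

test_that("a stratum with no future posts yields no over-expressed categories", {
  rec <- tibble::tibble(
    user_id = sprintf("u%d", 1:50),
    timestamp = "2012-01-01T00:00:00Z",
    gender = rep(c("male", "female"), 25),
    actual = "normal", term = "fat"
  )
  posts <- tibble::tibble(
    post_id = "f1", user_id = "none", timestamp = "2012-06-01T00:00:00Z",
    category = taxonomy_categories()[1], title = "x", body = "", zip = "0"
  )
  ov <- category_overexpression(rec, posts)
  expect_false(any(ov$overexpressed, na.rm = TRUE))
  expect_true(all(!ov$evaluable))
})

test_that("bullying fractions, per-stratum tests and the interaction LRT", {
  # all flags false: fractions zero, no interaction test
  rec <- tibble::tibble(
    user_id = sprintf("u%d", 1:80),
    gender = rep(c("male", "female"), each = 40),
    term = rep(inquiry_terms(), 20)
  )
  ba0 <- bullying_association(rec, rep(FALSE, 80))
  expect_true(all(ba0$fractions$fraction == 0))
  expect_null(ba0$interaction)

  # 2x2 chi-squared equals the hand formula (20/1000 vs 6/1000)
  expect_equal(
    weightask:::test_2x2(matrix(c(20, 980, 6, 994), 2, byrow = TRUE)),
    chisq_2x2_oracle(20, 980, 6, 994)
  )

  # planted per-stratum fractions are recovered within binomial error
  set.seed(21)
  n <- 20000
  gender <- sample(c("male", "female"), n, TRUE, prob = c(0.35, 0.65))
  term <- sample(inquiry_terms(), n, TRUE, prob = c(0.07, 0.22, 0.62, 0.09))
  prob <- ifelse(gender == "male" & term == "obese", 0.018,
    ifelse(gender == "male" & term == "fat", 0.006, 0.011)
  )
  recs <- tibble::tibble(user_id = sprintf("u%d", 1:n), gender = gender, term = term)
  ba <- bullying_association(recs, runif(n) < prob)
  mo <- ba$fractions[ba$fractions$gender == "male" & ba$fractions$term == "obese", ]
  expect_lt(abs(mo$fraction - 0.018), 3 * sqrt(0.018 * 0.982 / mo$n))
  mf <- ba$fractions[ba$fractions$gender == "male" & ba$fractions$term == "fat", ]
  expect_lt(abs(mf$fraction - 0.006), 3 * sqrt(0.006 * 0.994 / mf$n))
})

test_that("the interaction LRT is powered against strong heterogeneity and calibrated under the null", {
  set.seed(22)
  detect <- 0
  null_sig <- 0
  for (i in 1:10) {
    n <- 20000
    gender <- sample(c("male", "female"), n, TRUE, prob = c(0.35, 0.65))
    term <- sample(inquiry_terms(), n, TRUE, prob = c(0.07, 0.22, 0.62, 0.09))
    recs <- tibble::tibble(user_id = sprintf("u%d", 1:n), gender = gender, term = term)
    # strong heterogeneity: male term effects span a 10-fold range
    p_alt <- ifelse(gender == "male" & term == "obese", 0.05,
      ifelse(gender == "male" & term == "fat", 0.005, 0.011)
    )
    ba_alt <- bullying_association(recs, runif(n) < p_alt)
    if (ba_alt$interaction$p_value < 0.05) detect <- detect + 1
    # null: same term profile in both genders
    p_null <- ifelse(term %in% c("fat", "obese"), 0.012, 0.008)
    ba_null <- bullying_association(recs, runif(n) < p_null)
    if (ba_null$interaction$p_value < 0.05) null_sig <- null_sig + 1
  }
  expect_gte(detect, 9)
  expect_lte(null_sig, 3)
})

test_that("bullying flags derive from later posts via the term matcher", {
  co <- small_corpus()
  rec <- build_asker_records(extract_posts(co$posts))
  flags <- bullying_flags_from_posts(rec, co$posts)
  truth_flag <- co$truth$bullied[match(rec$user_id, co$truth$user_id)]
  expect_identical(flags$bullied, truth_flag)
})

test_that("tidiers expose fractions and the interaction statistic", {
  rec <- tibble::tibble(
    user_id = sprintf("u%d", 1:400),
    gender = rep(c("male", "female"), each = 200),
    term = rep(inquiry_terms(), 100)
  )
  set.seed(3)
  ba <- bullying_association(rec, runif(400) < 0.1)
  expect_s3_class(tidy(ba), "tbl_df")
  expect_identical(nrow(tidy(ba)), 8L)
  g <- glance(ba)
  expect_identical(nrow(g), 1L)
  expect_true(is.finite(g$p_value))
})
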