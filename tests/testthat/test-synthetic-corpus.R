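# Generator: anthropometrics, rendering, future-post planting, determinism.

test_that("anthropometric draws center on the configured median curves", {
  model <- default_anthropometric_model(sdlog_weight = 0, sdlog_height = 0)
  set.seed(1)
  draw <- sample_anthropometrics(16, "male", model)
  ref <- reference_anthropometrics(16, "male", model)
  expect_equal(draw$height_in, round(ref$height_in))
  expect_equal(draw$weight_lb, round(ref$weight_lb))

  # Monte-Carlo: sample median within 2% of the configured median
  set.seed(2)
  big <- sample_anthropometrics(rep(16, 10000), "female")
  ref_f <- reference_anthropometrics(16, "female")
  expect_lt(abs(median(big$weight_lb) - ref_f$weight_lb) / ref_f$weight_lb, 0.02)

  # same rng state, same output
  set.seed(3)
  a <- sample_anthropometrics(c(15, 17), c("male", "female"))
  set.seed(3)
  b <- sample_anthropometrics(c(15, 17), c("male", "female"))
  expect_identical(a, b)

  expect_error(sample_anthropometrics(9, "male"), "9")
})

test_that("rendered questions carry the inquiry phrase and requested fields", {
  profile <- list(gender = "male", age = 15, weight_lb = 180, height_in = 69)
  set.seed(5)
  q <- render_question(profile, "fat")
  expect_identical(q$title, "Am I fat?")
  text <- paste(q$title, q$body)
  expect_identical(match_inquiry(text), "fat")
  prof <- extract_profile(text)
  expect_identical(prof$gender, "male")
  expect_identical(prof$age, 15L)
  expect_lt(abs(prof$weight_lb - 180), 0.25)
  expect_lt(abs(prof$height_in - 69), 0.25)

  # full omission leaves the phrase and nothing else
  empty <- render_question(profile, "thin", states = c(
    gender = "omitted", age = "omitted", weight = "omitted", height = "omitted"
  ))
  expect_identical(empty$body, "")
  expect_identical(match_inquiry(empty$title), "thin")

  # ambiguous weight renders without a unit and does not trigger the rule
  set.seed(6)
  amb <- render_question(profile, "fat", states = c(
    gender = "omitted", age = "omitted", weight = "ambiguous", height = "omitted"
  ))
  expect_match(amb$body, "^I weigh 180\\.$")
  expect_true(is.na(extract_profile(amb$body)$weight_lb))
})

test_that("ambiguous dialects are never parsed, canonical ones always are", {
  profile <- list(gender = "female", age = 16, weight_lb = 120, height_in = 64)
  for (field in c("gender", "age", "weight", "height")) {
    states <- c(gender = "omitted", age = "omitted", weight = "omitted", height = "omitted")
    states[field] <- "ambiguous"
    set.seed(8)
    q <- render_question(profile, "thin", states = states)
    prof <- extract_profile(paste(q$title, q$body))
    col <- c(gender = "gender", age = "age", weight = "weight_lb", height = "height_in")[field]
    expect_true(is.na(prof[[col]]), label = paste("ambiguous", field, "omitted"))
  }
})

test_that("planted multipliers shape future-post rates as configured", {
  set.seed(11)
  n <- 20000
  truth <- tibble::tibble(
    user_id = sprintf("u%d", 1:n),
    gender = sample(c("male", "female"), n, TRUE),
    actual = sample(weight_classes(), n, TRUE, prob = c(.1, .6, .2, .1)),
    term = sample(inquiry_terms(), n, TRUE)
  )
  base <- c("Health/Diseases/Diabetes" = 0.01)
  eff <- planted_effect("Health/Diseases/Diabetes", 4.6,
    gender = "male", actual = "overweight|obese"
  )
  ev <- assign_future_posts(truth, eff, base)
  member <- truth$gender == "male" & truth$actual %in% c("overweight", "obese")
  rate_s <- mean(truth$user_id[member] %in% ev$user_id)
  se <- sqrt(0.046 * 0.954 / sum(member))
  expect_lt(abs(rate_s - 0.046), 3 * se)

  # empty effect table: all strata share the baseline
  ev0 <- assign_future_posts(truth, planted_effect("x", 1)[0, ], base)
  expect_lt(abs(nrow(ev0) / n - 0.01), 3 * sqrt(0.01 * 0.99 / n))

  # multiplier zero: the stratum never posts
  ev_zero <- assign_future_posts(
    truth, planted_effect("Health/Diseases/Diabetes", 1e-12,
      gender = "male", actual = "overweight|obese"
    ), base
  )
  expect_false(any(ev_zero$user_id %in% truth$user_id[member]))

  # impossible rates are clamped, warning both about the complement deficit
  # and the capped stratum probability
  w <- testthat::capture_warnings(
    assign_future_posts(
      truth, planted_effect("Health/Diseases/Diabetes", 200,
        gender = "male", actual = "overweight|obese"
      ),
      c("Health/Diseases/Diabetes" = 0.9)
    )
  )
  expect_match(w, "clamped", all = FALSE)
  expect_match(w, "complement", all = FALSE)
})

test_that("corpus generation conserves counts and is deterministic", {
  empty <- generate_corpus(corpus_config(seed = 1, n_askers = 0))
  expect_identical(nrow(empty$posts), 0L)
  expect_identical(nrow(empty$truth), 0L)

  co <- generate_corpus(corpus_config(seed = 9, n_askers = 1000))
  expect_identical(nrow(co$truth), 1000L)
  expect_false(anyDuplicated(co$posts$post_id) > 0)
  inquiry_ids <- co$posts$post_id[startsWith(co$posts$post_id, "q")]
  expect_setequal(inquiry_ids, co$truth$inquiry_post_id)
  # future and bullying posts are dated after the inquiry
  t0 <- setNames(co$truth$inquiry_post_id, co$truth$user_id)
  inq_t <- setNames(
    co$posts$timestamp[match(co$truth$inquiry_post_id, co$posts$post_id)],
    co$truth$user_id
  )
  later <- co$posts[!startsWith(co$posts$post_id, "q"), ]
  expect_true(all(later$timestamp > inq_t[later$user_id]))

  co2 <- generate_corpus(corpus_config(seed = 9, n_askers = 1000))
  expect_identical(co$posts, co2$posts)
  expect_identical(co$truth, co2$truth)

  # byte-identical JSONL across runs
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_corpus(co, d1)
  write_corpus(co2, d2)
  expect_identical(
    unname(tools::md5sum(file.path(d1, "posts.jsonl"))),
    unname(tools::md5sum(file.path(d2, "posts.jsonl")))
  )
})

test_that("invalid configurations fail with the offending fields named", {
  expect_error(
    corpus_config(female_fraction = 1.7),
    "female_fraction"
  )
  expect_error(
    corpus_config(omission_rates = c(age = -0.1, gender = 0, weight = 0, height = 0)),
    "omission_rates"
  )
  expect_error(
    corpus_config(age_range = c(10, 20)),
    "age_range"
  )
})

test_that("malformed corpus lines are skipped up to a tolerance", {
  co <- small_corpus()
  dir <- withr::local_tempdir()
  write_corpus(co, dir)
  path <- file.path(dir, "posts.jsonl")
  lines <- readLines(path)
  lines[5] <- "{not json"
  withr::local_file("broken.jsonl")
  writeLines(lines, "broken.jsonl")
  expect_message(posts <- read_posts("broken.jsonl", max_malformed = 0.01), "skipped 1")
  expect_identical(nrow(posts), length(lines) - 1L)
  # too many malformed lines is an error
  lines[1:200] <- "{not json"
  writeLines(lines, "broken.jsonl")
  expect_error(read_posts("broken.jsonl", max_malformed = 0.01), "malformed")
})
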