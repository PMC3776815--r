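# Synthetic corpus generator: ground-truthed Q&A posts with planted effects.

#' Load the rendering-dialect table
#'
#' The versioned YAML fixture listing, per field, the canonical (parseable)
#' and ambiguous (deliberately non-parseable) sentence templates used to
#' render self-reported measurements into post text.
#'
#' @param path Path to a dialect YAML; defaults to the bundled fixture.
#' @return A nested list: `$age$canonical`, `$age$ambiguous`, etc.
#' @export
load_dialects <- function(path = weightask_file("dialects.yaml")) {
  yaml::read_yaml(path)
}

#' Draw true anthropometrics around the reference curves
#'
#' Heights and weights are lognormal around the gender- and age-specific
#' median curves, then rounded to whole inches and pounds (posters report
#' integers). With zero dispersion the draw is exactly the configured median.
#'
#' @inheritParams reference_anthropometrics
#' @return A tibble with columns `height_in` and `weight_lb` (one row per
#'   input age). Uses the current RNG state; wrap in [set.seed()] or
#'   `withr::with_seed()` for reproducibility.
#' @export
#' @examples
#' set.seed(1)
#' sample_anthropometrics(c(16, 16), c("male", "female"))
sample_anthropometrics <- function(age, gender,
                                   model = default_anthropometric_model()) {
  ref <- reference_anthropometrics(age, gender, model)
  n <- nrow(ref)
  h <- rlnorm(n, meanlog = log(ref$height_in), sdlog = model$sdlog_height)
  w <- rlnorm(n, meanlog = log(ref$weight_lb), sdlog = model$sdlog_weight)
  tibble::tibble(height_in = round(h), weight_lb = round(w))
}

# substitute {placeholders} in a vector of templates, pairwise
fill_template <- function(template, values) {
  out <- template
  for (nm in names(values)) {
    out <- stringr::str_replace_all(
      out, stringr::fixed(paste0("{", nm, "}")), as.character(values[[nm]])
    )
  }
  out
}

# pick, per row, a template for one field given its state ("canonical",
# "ambiguous" or "omitted"); returns list(sentence, dialect_index)
render_field <- function(field, state, dialects, values) {
  n <- length(state)
  sentence <- rep("", n)
  dialect <- rep(NA_integer_, n)
  for (st in c("canonical", "ambiguous")) {
    idx <- which(state == st)
    if (length(idx) == 0) next
    templates <- dialects[[field]][[st]]
    pick <- sample.int(length(templates), length(idx), replace = TRUE)
    dialect[idx] <- pick + ifelse(st == "ambiguous", 100L, 0L)
    sentence[idx] <- fill_template(
      templates[pick],
      lapply(values, function(v) v[idx])
    )
  }
  list(sentence = sentence, dialect = dialect)
}

# vectorised renderer over n profiles; states is a list of per-field state
# vectors; returns list(title, body, render_truth tibble fragment)
render_question_batch <- function(profile, term, dialects, states) {
  n <- nrow(profile)
  feet <- profile$height_in %/% 12
  inches <- profile$height_in %% 12
  gender_word <- ifelse(profile$gender == "male",
    sample(c("male", "boy", "man"), n, replace = TRUE),
    sample(c("female", "girl", "woman"), n, replace = TRUE)
  )
  slang <- ifelse(profile$gender == "male", "guy", "gal")
  vals <- list(
    age = profile$age, gender = gender_word, slang = slang,
    weight = profile$weight_lb, kg = round(profile$weight_lb / 2.20462, 1),
    feet = feet, inches = inches, cm = round(profile$height_in * 2.54, 1)
  )
  parts <- list(
    gender = render_field("gender", states$gender, dialects, vals),
    age = render_field("age", states$age, dialects, vals),
    weight = render_field("weight", states$weight, dialects, vals),
    height = render_field("height", states$height, dialects, vals)
  )
  body <- trimws(paste(
    parts$gender$sentence, parts$age$sentence,
    parts$weight$sentence, parts$height$sentence
  ))
  body <- stringr::str_squish(body)
  title <- paste0("Am I ", term, "?")
  render_truth <- purrr::imap_dfr(parts, function(p, nm) {
    st <- states[[nm]]
    tibble::tibble(row = seq_len(n), field = nm, state = st, dialect = p$dialect)
  })
  list(title = title, body = body, render_truth = render_truth)
}

#' Render one weight-inquiry question
#'
#' Turns a profile and an inquiry term into post text, e.g.
#' `"I am a male. I am 15 years old. I weigh 180 pounds. I am 5 foot 9 inches
#' tall."` with title `"Am I fat?"`. Fields can be rendered canonically,
#' ambiguously (unit dropped, so the precision-first extractor will omit
#' them) or left out.
#'
#' @param profile A one-row data frame (or list) with `gender`, `age`,
#'   `weight_lb`, `height_in`.
#' @param term One of `"skinny"`, `"thin"`, `"fat"`, `"obese"`.
#' @param dialects Dialect table, see [load_dialects()].
#' @param states Named character vector giving each field's rendering state
#'   (`"canonical"`, `"ambiguous"` or `"omitted"`); defaults to all
#'   canonical.
#' @return A list with `title`, `body` and a `render_truth` tibble recording
#'   each field's state and dialect.
#' @export
#' @examples
#' set.seed(1)
#' p <- list(gender = "male", age = 15, weight_lb = 180, height_in = 69)
#' render_question(p, "fat")$title
render_question <- function(profile, term, dialects = load_dialects(),
                            states = c(
                              gender = "canonical", age = "canonical",
                              weight = "canonical", height = "canonical"
                            )) {
  term <- match.arg(term, inquiry_terms())
  profile <- tibble::as_tibble(profile[c("gender", "age", "weight_lb", "height_in")])
  out <- render_question_batch(
    profile, term, dialects,
    states = list(
      gender = states[["gender"]], age = states[["age"]],
      weight = states[["weight"]], height = states[["height"]]
    )
  )
  list(
    title = out$title, body = out$body,
    render_truth = dplyr::select(out$render_truth, -"row")
  )
}

# does each row of `df` (gender, actual, term columns) belong to the stratum?
match_stratum <- function(df, gender = NA, actual = NA, term = NA) {
  ok <- rep(TRUE, nrow(df))
  if (!is.na(gender)) ok <- ok & df$gender == gender
  if (!is.na(actual)) ok <- ok & df$actual %in% strsplit(actual, "|", fixed = TRUE)[[1]]
  if (!is.na(term)) ok <- ok & df$term %in% strsplit(term, "|", fixed = TRUE)[[1]]
  ok
}

#' Assign future-category posts with planted rate multipliers
#'
#' For each category, users in a planted stratum post with probability
#' `multiplier` times the configured baseline, where the baseline is the
#' *pooled-population* rate: rates of users outside every planted stratum
#' are deflated so that the population-average rate stays at the baseline.
#' This makes the downstream posting-ratio estimate converge to the planted
#' multiplier. Probabilities above 1 (or negative compensated rates) are
#' clamped with a warning.
#'
#' @param truth Tibble with one row per asker carrying `user_id`, `gender`,
#'   `actual` (true weight class) and `term`.
#' @param effect_table Tibble of planted effects, see [planted_effect()].
#' @param baseline_rates Named per-category baseline probabilities.
#' @return A tibble of posting events with columns `user_id`, `category`.
#'   Uses the current RNG state.
#' @export
assign_future_posts <- function(truth, effect_table, baseline_rates) {
  n <- nrow(truth)
  if (n == 0) {
    return(tibble::tibble(user_id = character(), category = character()))
  }
  events <- vector("list", length(baseline_rates))
  for (ci in seq_along(baseline_rates)) {
    cat_path <- names(baseline_rates)[ci]
    b <- baseline_rates[[ci]]
    mult <- rep(1, n)
    eff <- effect_table[effect_table$category == cat_path, , drop = FALSE]
    if (nrow(eff) > 0) {
      for (j in seq_len(nrow(eff))) {
        m <- match_stratum(truth, eff$gender[j], eff$actual[j], eff$term[j])
        mult[m] <- mult[m] * eff$multiplier[j]
      }
    }
    boosted <- mult != 1
    rate <- rep(b, n)
    if (any(boosted)) {
      rate[boosted] <- b * mult[boosted]
      # deflate the complement so the pooled expectation stays at b
      n0 <- sum(!boosted)
      if (n0 > 0) {
        comp <- (n - sum(mult[boosted])) / n0
        if (comp < 0) {
          warn(sprintf(
            "category '%s': planted effects exceed the pooled baseline; complement rate clamped to 0",
            cat_path
          ))
          comp <- 0
        }
        rate[!boosted] <- b * comp
      }
    }
    if (any(rate > 1)) {
      warn(sprintf(
        "category '%s': baseline x multiplier exceeds 1 for %d asker(s); clamped",
        cat_path, sum(rate > 1)
      ))
      rate <- pmin(rate, 1)
    }
    hit <- runif(n) < rate
    if (any(hit)) {
      events[[ci]] <- tibble::tibble(
        user_id = truth$user_id[hit], category = cat_path
      )
    }
  }
  dplyr::bind_rows(events)
}

bullying_positive_templates <- function() {
  c(
    "I'm being bullied at school because of my weight. What should I do?",
    "How can I make new friends after having been bullied?",
    "Someone keeps calling me names at lunch. Is this bullying?",
    "I feel I'm being bullied by people in my class. Help?"
  )
}

bullying_negative_templates <- function() {
  c(
    "Is my dog bullying the neighbor's dog?",
    "What is the plot of that movie about a school bully?",
    "Why do people say big companies are bullying small shops?"
  )
}

#' Generate a ground-truthed synthetic corpus
#'
#' Simulates a population of askers (age, gender, true anthropometrics,
#' county), renders their "Am I <term>?" inquiry posts with configurable
#' field omission and ambiguity, assigns later topical posts with planted
#' stratum-specific rate multipliers, and assigns later bullying-related
#' posts with planted per-stratum probabilities. Every post is traceable to
#' a ground-truth record.
#'
#' @param config A [corpus_config()].
#' @return A list of class `weightask_corpus` with elements:
#'   * `posts`: tibble of all posts (`post_id`, `user_id`, `timestamp`,
#'     `category`, `title`, `body`, `zip`), inquiry posts first;
#'   * `truth`: one row per asker (true age, gender, height, weight, BMI,
#'     true weight class, term, county, bullying flags, future categories);
#'   * `render_truth`: per inquiry post and field, the rendering state and
#'     dialect used;
#'   * `config`: the generating config.
#' @export
generate_corpus <- function(config) {
  validate_corpus_config(config)
  set.seed(config$seed)
  n <- config$n_askers
  dialects <- load_dialects()
  if (n == 0) {
    empty <- tibble::tibble(
      post_id = character(), user_id = character(), timestamp = character(),
      category = character(), title = character(), body = character(),
      zip = character()
    )
    return(structure(list(
      posts = empty,
      truth = tibble::tibble(user_id = character()),
      render_truth = tibble::tibble(post_id = character()),
      config = config
    ), class = "weightask_corpus"))
  }

  gender <- ifelse(runif(n) < config$female_fraction, "female", "male")
  ages <- seq(config$age_range[1], config$age_range[2])
  agew <- stats::dnbinom(ages - 13L, size = 2.2, mu = 4.2) + 1e-9
  age <- sample(ages, n, replace = TRUE, prob = agew)
  anth <- sample_anthropometrics(age, gender, config$anthropometric_model)
  bmi <- compute_bmi(anth$weight_lb, anth$height_in)
  age_class <- ifelse(age <= 19, "teen", "adult")
  actual <- character(n)
  is_teen <- age_class == "teen"
  if (any(is_teen)) {
    pct <- teen_percentile(bmi[is_teen], 12 * age[is_teen] + 6, gender[is_teen])
    actual[is_teen] <- band_to_class(classify_teen(pct))
  }
  if (any(!is_teen)) {
    actual[!is_teen] <- as.character(classify_adult(bmi[!is_teen]))
  }

  # county assignment and zips
  ct <- config$county_table
  cidx <- sample.int(nrow(ct$counties), n, replace = TRUE, prob = ct$counties$weight)
  county_id <- ct$counties$county_id[cidx]
  obesity <- ct$counties$obesity_pct[cidx]
  income <- ct$counties$median_income[cidx]
  zips_by_county <- split(ct$zip_map$zip, ct$zip_map$county_id)
  zl <- zips_by_county[county_id]
  pick <- sample.int(1000L, n, replace = TRUE)
  zip <- mapply(function(z, k) z[1 + (k - 1) %% length(z)], zl, pick,
    USE.NAMES = FALSE
  )

  # inquiry term given (gender, true class), optionally tilted by county
  im <- config$inquiry_model
  key <- paste(gender, actual)
  imkey <- paste(im$gender, im$true_class)
  w <- as.matrix(im[match(key, imkey), inquiry_terms()])
  if (!is.null(config$congruence_county_effect)) {
    boost <- config$congruence_county_effect(obesity)
    congruent_high <- actual %in% c("overweight", "obese")
    for (tm in inquiry_terms()) {
      cong <- if (tm %in% high_terms()) congruent_high else !congruent_high
      w[, tm] <- w[, tm] * ifelse(cong, boost, 1)
    }
  }
  u <- runif(n) * rowSums(w)
  cw <- t(apply(w, 1, cumsum))
  term <- inquiry_terms()[1 + rowSums(cw < u)]

  user_id <- sprintf("u%06d", seq_len(n))
  inquiry_post_id <- sprintf("q%06d", seq_len(n))
  t0 <- as.POSIXct("2012-01-01", tz = "UTC") + runif(n, 0, 364 * 86400)

  # rendering states per field
  draw_state <- function(field) {
    o <- config$omission_rates[[field]]
    a <- config$ambiguity_rate[[field]]
    u1 <- runif(n)
    ifelse(u1 < o, "omitted", ifelse(runif(n) < a, "ambiguous", "canonical"))
  }
  states <- list(
    gender = draw_state("gender"), age = draw_state("age"),
    weight = draw_state("weight"), height = draw_state("height")
  )
  profile <- tibble::tibble(
    gender = gender, age = age,
    weight_lb = anth$weight_lb, height_in = anth$height_in
  )
  rendered <- render_question_batch(profile, term, dialects, states)
  inquiry_posts <- tibble::tibble(
    post_id = inquiry_post_id, user_id = user_id, timestamp = iso8601(t0),
    category = inquiry_category(), title = rendered$title,
    body = rendered$body, zip = zip
  )
  render_truth <- rendered$render_truth |>
    dplyr::mutate(post_id = inquiry_post_id[.data$row]) |>
    dplyr::select("post_id", "field", "state", "dialect")

  # future topical posts with planted multipliers
  truth_core <- tibble::tibble(
    user_id = user_id, gender = gender, actual = actual, term = term
  )
  future <- assign_future_posts(
    truth_core, config$effect_table, config$baseline_category_rates
  )
  if (nrow(future) > 0) {
    fidx <- match(future$user_id, user_id)
    leaf <- vapply(
      strsplit(future$category, "/", fixed = TRUE),
      function(p) p[[length(p)]], character(1)
    )
    future_posts <- tibble::tibble(
      post_id = sprintf("f%06d", seq_len(nrow(future))),
      user_id = future$user_id,
      timestamp = iso8601(t0[fidx] + runif(nrow(future), 1, 365 * 86400)),
      category = future$category,
      title = paste0("Question about ", leaf, "."),
      body = paste0("I have a question about ", tolower(leaf), ". Any advice?"),
      zip = zip[fidx]
    )
  } else {
    future_posts <- inquiry_posts[0, ]
  }

  # bullying posts: per-stratum probability, optional county modifier
  bm <- config$bullying_model
  bprob <- bm$prob[match(paste(gender, term), paste(bm$gender, bm$term))]
  if (!is.null(config$bullying_county_effect)) {
    bprob <- bprob * config$bullying_county_effect(obesity, income)
  }
  bprob <- pmin(pmax(bprob, 0), 1)
  bullied <- runif(n) < bprob
  bidx <- which(bullied)
  if (length(bidx) > 0) {
    genuine <- runif(length(bidx)) < config$annotation_positive_rate
    pos <- bullying_positive_templates()
    neg <- bullying_negative_templates()
    btext <- ifelse(genuine,
      pos[sample.int(length(pos), length(bidx), replace = TRUE)],
      neg[sample.int(length(neg), length(bidx), replace = TRUE)]
    )
    bully_posts <- tibble::tibble(
      post_id = sprintf("b%06d", seq_along(bidx)),
      user_id = user_id[bidx],
      timestamp = iso8601(t0[bidx] + runif(length(bidx), 1, 365 * 86400)),
      category = "Family & Relationships/Friends",
      title = btext,
      body = "",
      zip = zip[bidx]
    )
  } else {
    genuine <- logical(0)
    bully_posts <- inquiry_posts[0, ]
  }

  future_cats <- split(future$category, factor(future$user_id, levels = user_id))
  truth <- tibble::tibble(
    user_id = user_id, inquiry_post_id = inquiry_post_id,
    age = age, gender = gender,
    height_in = anth$height_in, weight_lb = anth$weight_lb,
    bmi = bmi, age_class = age_class, actual = actual, term = term,
    county_id = county_id, zip = zip,
    n_future_posts = lengths(future_cats),
    future_categories = unname(future_cats),
    bullied = bullied,
    bullying_genuine = replace(rep(NA, n), bidx, genuine)
  )

  structure(list(
    posts = dplyr::bind_rows(inquiry_posts, future_posts, bully_posts),
    truth = truth,
    render_truth = render_truth,
    config = config
  ), class = "weightask_corpus")
}

#' @export
print.weightask_corpus <- function(x, ...) {
  cat(sprintf(
    "<weightask_corpus> %d askers, %d posts (seed %d)\n",
    nrow(x$truth), nrow(x$posts), x$config$seed
  ))
  invisible(x)
}

#' Write a corpus to disk as JSONL
#'
#' Posts, asker ground truth and rendering truth are written as line-
#' delimited JSON; the config (minus any function-valued fields) as YAML.
#' Output is deterministic: identical corpus gives byte-identical files.
#'
#' @param corpus A `weightask_corpus`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_jsonl <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    jsonlite::stream_out(df, con, verbose = FALSE)
  }
  write_jsonl(corpus$posts, file.path(dir, "posts.jsonl"))
  truth <- corpus$truth
  if ("future_categories" %in% names(truth)) {
    truth$future_categories <- vapply(
      truth$future_categories, paste, character(1), collapse = ";"
    )
  }
  write_jsonl(truth, file.path(dir, "truth_askers.jsonl"))
  write_jsonl(corpus$render_truth, file.path(dir, "truth_render.jsonl"))
  cfg <- corpus$config
  cfg <- cfg[!vapply(cfg, is.function, logical(1))]
  cfg <- lapply(cfg, function(x) if (is.data.frame(x)) as.list(x) else x)
  cfg$anthropometric_model$knots <- as.list(cfg$anthropometric_model$knots)
  cfg$county_table <- lapply(cfg$county_table, as.list)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a posts JSONL file
#'
#' Malformed lines are skipped and counted; if more than `max_malformed`
#' (a fraction) of lines are malformed the read fails.
#'
#' @param path Path to a JSONL file (one post object per line).
#' @param max_malformed Maximum tolerated fraction of malformed lines.
#' @return A tibble; the number of skipped lines is attached as attribute
#'   `n_malformed`.
#' @export
read_posts <- function(path, max_malformed = 0.01) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parsed <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
  })
  bad <- vapply(parsed, is.null, logical(1))
  if (length(lines) > 0 && mean(bad) > max_malformed) {
    abort(sprintf(
      "%d of %d lines in '%s' are malformed JSON (> %g%% tolerated)",
      sum(bad), length(lines), path, 100 * max_malformed
    ))
  }
  if (any(bad)) {
    inform(sprintf("skipped %d malformed line(s) in '%s'", sum(bad), path))
  }
  out <- dplyr::bind_rows(lapply(parsed[!bad], tibble::as_tibble))
  attr(out, "n_malformed") <- sum(bad)
  out
}
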