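#' Default median anthropometric curves for the corpus generator
#'
#' Piecewise-linear median height (inches) and weight (pounds) by integer age
#' and gender, shaped like US population medians, together with lognormal
#' dispersion on both axes. The generator draws each asker's true
#' anthropometrics around these curves, so downstream checks that reported
#' weights track a reference curve hold by construction.
#'
#' @param sdlog_weight Lognormal sd (log scale) of weight around its median.
#' @param sdlog_height Lognormal sd (log scale) of height around its median.
#' @return A list with elements `knots` (a tibble of gender, age,
#'   `height_in`, `weight_lb`), `sdlog_weight` and `sdlog_height`.
#' @export
default_anthropometric_model <- function(sdlog_weight = 0.18, sdlog_height = 0.025) {
  ages <- c(13:20, 25, 30, 40, 59)
  knots <- dplyr::bind_rows(
    tibble::tibble(
      gender = "male", age = ages,
      height_in = c(61.5, 64, 66.5, 68, 68.8, 69.2, 69.4, 69.5, 69.5, 69.5, 69.5, 69),
      weight_lb = c(102, 113, 124, 134, 142, 148, 152, 155, 168, 178, 188, 185)
    ),
    tibble::tibble(
      gender = "female", age = ages,
      height_in = c(62, 63.5, 64, 64.2, 64.3, 64.3, 64.3, 64.3, 64.3, 64.3, 64.3, 63.5),
      weight_lb = c(102, 109, 114, 118, 120, 122, 124, 126, 134, 144, 155, 155)
    )
  )
  list(knots = knots, sdlog_weight = sdlog_weight, sdlog_height = sdlog_height)
}

#' Reference median height and weight at given ages
#'
#' Linear interpolation of the model's median curves; the curve the generator
#' centers its draws on, and the curve reported medians are validated against.
#'
#' @param age Vector of ages in years.
#' @param gender Vector (recycled) of `"male"`/`"female"`.
#' @param model An anthropometric model, see [default_anthropometric_model()].
#' @return A tibble with columns `age`, `gender`, `height_in`, `weight_lb`.
#' @export
reference_anthropometrics <- function(age, gender,
                                      model = default_anthropometric_model()) {
  n <- max(length(age), length(gender))
  age <- rep_len(age, n)
  gender <- rep_len(gender, n)
  rng <- range(model$knots$age)
  bad <- age < rng[1] | age > rng[2]
  if (any(bad)) {
    abort(sprintf(
      "age(s) %s outside the anthropometric model support [%s, %s]",
      paste(unique(age[bad]), collapse = ", "), rng[1], rng[2]
    ))
  }
  out <- tibble::tibble(age = age, gender = gender, height_in = NA_real_, weight_lb = NA_real_)
  for (g in unique(gender)) {
    k <- model$knots[model$knots$gender == g, ]
    if (nrow(k) == 0) abort(sprintf("gender '%s' not present in anthropometric model", g))
    idx <- gender == g
    out$height_in[idx] <- approx(k$age, k$height_in, xout = age[idx])$y
    out$weight_lb[idx] <- approx(k$age, k$weight_lb, xout = age[idx])$y
  }
  out
}

#' Default inquiry-term model
#'
#' Probability of each inquiry term ("Am I skinny/thin/fat/obese?") given the
#' asker's gender and true weight class. The defaults encode the asymmetry
#' seen on real Q&A forums: "fat" dominates for both genders, women in the
#' healthy range still predominantly ask about high-weight terms, and people
#' at the extremes skew toward the matching term.
#'
#' @return A tibble with columns `gender`, `true_class`, `skinny`, `thin`,
#'   `fat`, `obese` (rows sum to 1).
#' @export
default_inquiry_model <- function() {
  tibble::tribble(
    ~gender, ~true_class, ~skinny, ~thin, ~fat, ~obese,
    "male", "underweight", 0.30, 0.45, 0.20, 0.05,
    "male", "normal", 0.06, 0.22, 0.62, 0.10,
    "male", "overweight", 0.01, 0.05, 0.78, 0.16,
    "male", "obese", 0.01, 0.03, 0.61, 0.35,
    "female", "underweight", 0.12, 0.38, 0.45, 0.05,
    "female", "normal", 0.05, 0.20, 0.69, 0.06,
    "female", "overweight", 0.01, 0.05, 0.80, 0.14,
    "female", "obese", 0.01, 0.02, 0.70, 0.27
  )
}

#' Default per-stratum bullying model
#'
#' Probability that an asker later posts a bullying-related question, by
#' gender and inquiry term. Defaults plant the elevated rate for men who ask
#' "Am I obese?" (1.8%) against a depressed rate for men asking "Am I fat?"
#' (0.6%) and a flat profile for women.
#'
#' @return A tibble with columns `gender`, `term`, `prob`.
#' @export
default_bullying_model <- function() {
  tidyr::crossing(gender = c("male", "female"), term = inquiry_terms()) |>
    dplyr::mutate(prob = dplyr::case_when(
      .data$gender == "male" & .data$term == "obese" ~ 0.018,
      .data$gender == "male" & .data$term == "fat" ~ 0.006,
      TRUE ~ 0.011
    ))
}

#' Default baseline future-posting rates per category
#'
#' Per-category probability that an asker from the pooled population posts at
#' least one later question to that category.
#'
#' @return A named numeric vector over [taxonomy_categories()].
#' @export
default_baseline_rates <- function() {
  cats <- taxonomy_categories()
  rates <- rep(0.01, length(cats))
  names(rates) <- cats
  rates["Family & Relationships/Singles & Dating"] <- 0.03
  rates["Beauty & Style/Makeup"] <- 0.02
  rates["Beauty & Style/Skin & Body"] <- 0.02
  rates["Health/Mental Health"] <- 0.015
  rates
}

#' Default synthetic county table and zip-code map
#'
#' Sixty synthetic counties with FIPS-style ids whose obesity prevalence
#' spans 15-45% and whose median income declines (with a deterministic
#' wiggle) as obesity rises, mimicking the real negative income-obesity
#' gradient. Each county owns three zip codes.
#'
#' @param n_counties Number of counties.
#' @return A list with `counties` (tibble: `county_id`, `obesity_pct`,
#'   `median_income`, `weight`) and `zip_map` (tibble: `zip`, `county_id`).
#' @export
default_county_table <- function(n_counties = 60) {
  i <- seq_len(n_counties)
  obesity <- round(seq(15, 45, length.out = n_counties), 1)
  income <- round(72000 - 1100 * obesity + 4000 * sin(i * 2.39996), 0)
  counties <- tibble::tibble(
    county_id = sprintf("%05d", 1000 + i * 2),
    obesity_pct = obesity,
    median_income = income,
    weight = 1 / n_counties
  )
  zip_map <- tidyr::crossing(county = i, k = 1:3) |>
    dplyr::mutate(
      zip = sprintf("%05d", 10000 + .data$county * 10 + .data$k),
      county_id = counties$county_id[.data$county]
    ) |>
    dplyr::select("zip", "county_id")
  list(counties = counties, zip_map = zip_map)
}

#' Build a planted-effect table row
#'
#' Convenience constructor for rows of the generator's effect table: a
#' stratum (any combination of gender, actual weight classes and inquiry
#' terms; `NA` means "any") that posts to `category` at `multiplier` times
#' the pooled population rate.
#'
#' @param category Category path, see [taxonomy_categories()].
#' @param multiplier Positive rate multiplier relative to the pooled rate.
#' @param gender `"male"`, `"female"` or `NA` (any).
#' @param actual Actual weight classes, `|`-separated (e.g.
#'   `"overweight|obese"`), or `NA` (any).
#' @param term Inquiry terms, `|`-separated, or `NA` (any).
#' @return A one-row tibble suitable for binding into an effect table.
#' @export
#' @examples
#' planted_effect("Health/Diseases/Diabetes", 4.6,
#'   gender = "male", actual = "overweight|obese"
#' )
planted_effect <- function(category, multiplier, gender = NA, actual = NA, term = NA) {
  stopifnot(is.numeric(multiplier), multiplier > 0)
  tibble::tibble(
    gender = as.character(gender), actual = as.character(actual),
    term = as.character(term), category = category, multiplier = multiplier
  )
}

#' Configuration for the synthetic corpus generator
#'
#' Bundles every knob of the generator: population size and composition, the
#' anthropometric model, how often rendered posts omit fields or use
#' ambiguous dialects, the inquiry-term model, planted future-posting
#' effects, the bullying model, and the synthetic county layer.
#'
#' @param seed Integer seed; identical seed + config gives a byte-identical
#'   corpus.
#' @param n_askers Number of askers to simulate.
#' @param age_range Inclusive integer age range (site minimum is 13).
#' @param female_fraction Proportion of askers who are female.
#' @param anthropometric_model See [default_anthropometric_model()].
#' @param omission_rates Named probabilities (age, gender, weight, height)
#'   that a rendered post omits that field entirely.
#' @param ambiguity_rate Probability that a rendered (non-omitted) field uses
#'   a non-triggering dialect, e.g. "I weigh 128" with no unit. May also be a
#'   named vector per field.
#' @param inquiry_model See [default_inquiry_model()].
#' @param effect_table Tibble of planted effects, see [planted_effect()];
#'   `NULL` for no planted effects.
#' @param baseline_category_rates Named vector of per-category baseline
#'   posting probabilities.
#' @param bullying_model See [default_bullying_model()].
#' @param bullying_county_effect Optional
#'   `function(obesity_pct, median_income)` returning a multiplier applied to
#'   each asker's bullying probability (used to plant county-level shapes).
#' @param congruence_county_effect Optional `function(obesity_pct)` returning
#'   an odds multiplier applied to the congruent inquiry terms' weights
#'   (used to plant county-level accuracy gradients).
#' @param annotation_positive_rate Probability that a bullying-term post is
#'   genuinely about being bullied (the simulated manual-annotation yield).
#' @param county_table See [default_county_table()].
#' @return A validated list of class `corpus_config`.
#' @export
#' @examples
#' cfg <- corpus_config(seed = 1, n_askers = 100)
#' corpus <- generate_corpus(cfg)
#' nrow(corpus$truth)
corpus_config <- function(seed = 1L,
                          n_askers = 5000L,
                          age_range = c(13L, 59L),
                          female_fraction = 0.65,
                          anthropometric_model = default_anthropometric_model(),
                          omission_rates = c(age = 0.20, gender = 0.08, weight = 0.25, height = 0.12),
                          ambiguity_rate = 0.05,
                          inquiry_model = default_inquiry_model(),
                          effect_table = NULL,
                          baseline_category_rates = default_baseline_rates(),
                          bullying_model = default_bullying_model(),
                          bullying_county_effect = NULL,
                          congruence_county_effect = NULL,
                          annotation_positive_rate = 0.68,
                          county_table = default_county_table()) {
  if (length(ambiguity_rate) == 1 && is.null(names(ambiguity_rate))) {
    ambiguity_rate <- c(
      age = ambiguity_rate, gender = ambiguity_rate,
      weight = ambiguity_rate, height = ambiguity_rate
    )
  }
  if (is.null(effect_table)) {
    effect_table <- planted_effect("Health/Diseases/Diabetes", 1)[0, ]
  }
  cfg <- structure(
    list(
      seed = as.integer(seed), n_askers = as.integer(n_askers),
      age_range = as.integer(age_range), female_fraction = female_fraction,
      anthropometric_model = anthropometric_model,
      omission_rates = omission_rates, ambiguity_rate = ambiguity_rate,
      inquiry_model = inquiry_model, effect_table = effect_table,
      baseline_category_rates = baseline_category_rates,
      bullying_model = bullying_model,
      bullying_county_effect = bullying_county_effect,
      congruence_county_effect = congruence_county_effect,
      annotation_positive_rate = annotation_positive_rate,
      county_table = county_table
    ),
    class = "corpus_config"
  )
  validate_corpus_config(cfg)
}

#' Validate a corpus configuration
#'
#' Checks every probability lies in \[0, 1\], multipliers are positive, the
#' age range sits inside the anthropometric model's support, and model tables
#' are complete. Errors list every offending field at once.
#'
#' @param config A `corpus_config` object.
#' @return The config, invisibly usable, or an error naming the bad fields.
#' @export
validate_corpus_config <- function(config) {
  bad <- character()
  probs <- list(
    female_fraction = config$female_fraction,
    omission_rates = config$omission_rates,
    ambiguity_rate = config$ambiguity_rate,
    baseline_category_rates = config$baseline_category_rates,
    bullying_model.prob = config$bullying_model$prob,
    annotation_positive_rate = config$annotation_positive_rate
  )
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (any(!is.finite(p) | p < 0 | p > 1)) bad <- c(bad, nm)
  }
  if (config$n_askers < 0) bad <- c(bad, "n_askers")
  if (length(config$age_range) != 2 || config$age_range[1] > config$age_range[2] ||
    config$age_range[1] < 13) {
    bad <- c(bad, "age_range")
  }
  if (nrow(config$effect_table) > 0 &&
    any(!is.finite(config$effect_table$multiplier) | config$effect_table$multiplier < 0)) {
    bad <- c(bad, "effect_table.multiplier")
  }
  im <- config$inquiry_model
  if (any(abs(rowSums(im[, inquiry_terms()]) - 1) > 1e-8)) bad <- c(bad, "inquiry_model")
  if (!all(c("age", "gender", "weight", "height") %in% names(config$omission_rates))) {
    bad <- c(bad, "omission_rates.names")
  }
  if (length(bad) > 0) {
    abort(paste0("invalid corpus config field(s): ", paste(unique(bad), collapse = ", ")))
  }
  config
}
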