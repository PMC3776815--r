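# Precision-first rule-based extraction from free-text posts.
#
# Design contract: a field is populated only when an unambiguous
# number-plus-unit (or keyword) pattern matches; anything ambiguous is
# omitted, never guessed. "I weigh 128" (no unit) therefore never yields a
# weight, and bare numbers are never read as heights or ages.

#' Match a weight-inquiry phrase
#'
#' Detects the literal phrase `"am I <term>"` (case-insensitive, trailing
#' punctuation optional) with term one of skinny, thin, fat, obese. Posts
#' matching several distinct terms get the marker `"multiple"` and are
#' excluded from stratified analyses downstream.
#'
#' @param text Character vector (title and body already concatenated).
#' @return Character vector: the matched term, `"multiple"`, or `NA` when no
#'   inquiry phrase occurs.
#' @export
#' @examples
#' match_inquiry("Am I skinny? I am female, 5 foot 4 and weigh 110 pounds?")
#' match_inquiry("Do you think obesity is rising?")
#' match_inquiry("Am I fat? or am I obese?")
match_inquiry <- function(text) {
  hits <- stringr::str_match_all(
    text, stringr::regex("\\bam\\s+i\\s+(skinny|thin|fat|obese)\\b", ignore_case = TRUE)
  )
  vapply(hits, function(h) {
    terms <- unique(tolower(h[, 2]))
    if (length(terms) == 0) NA_character_
    else if (length(terms) > 1) "multiple"
    else terms
  }, character(1))
}

# first numeric capture of `pattern`; NA if no match or conflicting values
match_unique_number <- function(text, pattern, group = 2) {
  m <- stringr::str_match_all(text, stringr::regex(pattern, ignore_case = TRUE))
  vals <- lapply(m, function(h) unique(as.numeric(h[, group])))
  num <- vapply(vals, function(v) {
    if (length(v) == 1) v else NA_real_
  }, numeric(1))
  first <- stringr::str_extract(text, stringr::regex(pattern, ignore_case = TRUE))
  list(value = num, src = ifelse(is.na(num), NA_character_, first))
}

extract_weight <- function(text) {
  lb <- match_unique_number(
    text, "\\b(\\d{2,3}(?:\\.\\d+)?)\\s*(?:pounds?|lbs?)\\b"
  )
  kg <- match_unique_number(
    text, "\\b(\\d{2,3}(?:\\.\\d+)?)\\s*(?:kilograms?|kilos?|kgs?)\\b"
  )
  both <- !is.na(lb$value) & !is.na(kg$value)
  value <- ifelse(!is.na(lb$value), lb$value, kg$value * 2.20462)
  value[both] <- NA_real_ # conflicting units: omit
  src <- ifelse(!is.na(lb$value), lb$src, kg$src)
  src[both] <- NA_character_
  list(value = value, src = src)
}

extract_height <- function(text) {
  # feet-inches forms: "5 foot 9 inches", "5 ft 9 in", "5'9\"", "5 foot"
  p_words <- "\\b(\\d)\\s*(?:foot|feet|ft\\.?)(?:\\s*(?:and\\s+)?(\\d{1,2})\\b(?:\\s*(?:inches|inch|in)\\b)?)?"
  p_tick <- "\\b(\\d)\\s*'\\s*(\\d{1,2})\\s*(?:\"|''|\u201d)?"
  p_cm <- "\\b(1\\d{2}(?:\\.\\d+)?)\\s*(?:cm|centimet(?:er|re)s?)\\b"
  pull_fi <- function(pattern) {
    m <- stringr::str_match_all(text, stringr::regex(pattern, ignore_case = TRUE))
    vals <- lapply(m, function(h) {
      if (nrow(h) == 0) {
        return(numeric(0))
      }
      inch <- suppressWarnings(as.numeric(h[, 3]))
      inch[is.na(inch)] <- 0
      unique(12 * as.numeric(h[, 2]) + inch)
    })
    num <- vapply(vals, function(v) if (length(v) == 1) v else NA_real_, numeric(1))
    src <- stringr::str_extract(text, stringr::regex(pattern, ignore_case = TRUE))
    list(value = num, src = ifelse(is.na(num), NA_character_, src))
  }
  fw <- pull_fi(p_words)
  ft <- pull_fi(p_tick)
  cm <- match_unique_number(text, p_cm)
  cm$value <- cm$value / 2.54
  # prefer in order; conflicting distinct candidates -> omit
  cand <- cbind(fw$value, ft$value, cm$value)
  value <- apply(cand, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 0 && length(unique(round(v, 1))) == 1) v[1] else NA_real_
  })
  src <- dplyr::coalesce(fw$src, ft$src, cm$src)
  src[is.na(value)] <- NA_character_
  list(value = value, src = src)
}

extract_age <- function(text) {
  p <- "\\b(\\d{1,2})\\s*(?:years?[- ]old|years?\\s+of\\s+age|yrs?[- ]old|y\\.?/?o\\b)"
  p2 <- "\\bage[:\\s]\\s*(\\d{1,2})\\b"
  a1 <- match_unique_number(text, p)
  a2 <- match_unique_number(text, p2)
  conflict <- !is.na(a1$value) & !is.na(a2$value) & a1$value != a2$value
  value <- ifelse(!is.na(a1$value), a1$value, a2$value)
  value[conflict] <- NA_real_
  src <- ifelse(!is.na(a1$value), a1$src, a2$src)
  src[conflict] <- NA_character_
  list(value = as.integer(round(value)), src = src)
}

extract_gender <- function(text) {
  # explicit tokens only; pronouns and slang are never used
  f <- stringr::str_extract(
    text, stringr::regex("\\b(female|woman|girl)\\b", ignore_case = TRUE)
  )
  m <- stringr::str_extract(
    text, stringr::regex("\\b(male|man|boy)\\b", ignore_case = TRUE)
  )
  both <- !is.na(f) & !is.na(m)
  value <- ifelse(!is.na(f), "female", ifelse(!is.na(m), "male", NA_character_))
  value[both] <- NA_character_
  src <- ifelse(!is.na(f), f, m)
  src[both] <- NA_character_
  list(value = value, src = src)
}

#' Extract self-reported anthropometrics from post text
#'
#' Scans free text for the asker's age, gender, weight and height using an
#' explicit rule inventory tuned for precision rather than recall: a value is
#' reported only when a number carries its unit or keyword context
#' ("180 pounds", "5 foot 9", "15 years old", an explicit gender token).
#' Ambiguous or conflicting mentions yield an absent field — absence is an
#' explicit state, never zero. Heights are normalised to inches, weights to
#' pounds (1 kg = 2.20462 lb, 1 in = 2.54 cm), ages to integer years.
#'
#' @param text Character vector of post texts.
#' @return A tibble with one row per input: `age`, `gender`, `weight_lb`,
#'   `height_in`, plus per-field provenance columns (`age_src`,
#'   `gender_src`, `weight_src`, `height_src`) holding the matched span.
#' @export
#' @examples
#' extract_profile("I am a male, 15 years old. I weigh 180 pounds, and am 5 foot 9 inches tall.")
#' extract_profile("I weigh 128") # no unit: weight stays absent
extract_profile <- function(text) {
  a <- extract_age(text)
  g <- extract_gender(text)
  w <- extract_weight(text)
  h <- extract_height(text)
  tibble::tibble(
    age = a$value, gender = g$value,
    weight_lb = w$value, height_in = h$value,
    age_src = a$src, gender_src = g$src,
    weight_src = w$src, height_src = h$src
  )
}

#' Flag bullying-related posts by term matching
#'
#' True when the text contains "bully"/"bullied"/"bullying" (word boundary,
#' case-insensitive). This is intentionally a high-recall term matcher: it
#' admits posts that merely mention bullying (e.g. about a dog); separating
#' genuinely-bullied askers is the annotation layer's job.
#'
#' @param text Character vector.
#' @return Logical vector.
#' @export
#' @examples
#' match_bullying("How can I make new friends after having been bullied?")
#' match_bullying("My friends are mean to me")
match_bullying <- function(text) {
  stringr::str_detect(
    text, stringr::regex("\\bbull(?:y|ies|ied|ying)\\b", ignore_case = TRUE)
  )
}

#' Run the extractor over a corpus of posts
#'
#' Applies [match_inquiry()] and [extract_profile()] to the concatenated
#' title and body of every post, keeping only posts containing an inquiry
#' phrase. Multi-term posts are retained here with `term = "multiple"` so
#' that exclusion accounting can see them.
#'
#' @param posts Tibble of posts (`post_id`, `user_id`, `timestamp`, `title`,
#'   `body`, `zip`).
#' @return A tibble of inquiry posts with the extracted profile columns.
#' @export
extract_posts <- function(posts) {
  text <- stringr::str_c(posts$title, " ", posts$body)
  term <- match_inquiry(text)
  keep <- !is.na(term)
  out <- posts[keep, c("post_id", "user_id", "timestamp", "zip")]
  out$term <- term[keep]
  dplyr::bind_cols(tibble::as_tibble(out), extract_profile(text[keep]))
}

#' Validate the extractor against ground truth
#'
#' Samples `sample_n` inquiry posts and classifies each field as correct,
#' error or omission against the generator's truth: an omission is a field
#' the truth rendered but the extractor left absent; an error is a
#' disagreeing value. The report mirrors a manual-inspection audit and for a
#' precision-first extractor should show errors far below omissions.
#'
#' @param extracted Output of [extract_posts()].
#' @param truth Asker truth tibble (from [generate_corpus()]).
#' @param render_truth Per-post rendering truth (from [generate_corpus()]).
#' @param sample_n Number of posts to audit.
#' @param seed Seed for the audit sample.
#' @param tol Numeric tolerance for weight (lb) and height (in) agreement,
#'   absorbing metric-dialect rounding.
#' @return A tibble of class `extraction_validation`: one row per field with
#'   `n`, `correct`, `errors`, `omissions` and `mae_errors` (mean absolute
#'   error among errors, numeric fields).
#' @export
validate_extraction <- function(extracted, truth, render_truth, sample_n,
                                seed = 1L, tol = 0.25) {
  if (sample_n > nrow(extracted)) {
    abort(sprintf(
      "sample_n (%d) exceeds the number of extracted posts (%d)",
      sample_n, nrow(extracted)
    ))
  }
  set.seed(seed)
  idx <- sample.int(nrow(extracted), sample_n)
  sub <- extracted[idx, ]
  tr <- truth[match(sub$post_id, truth$inquiry_post_id), ]
  rt <- render_truth |>
    dplyr::filter(.data$post_id %in% sub$post_id) |>
    tidyr::pivot_wider(
      id_cols = "post_id", names_from = "field", values_from = "state"
    )
  rt <- rt[match(sub$post_id, rt$post_id), ]

  field_report <- function(field, ext_val, true_val, numeric_field = TRUE) {
    rendered <- rt[[field]] != "omitted" # ambiguous counts as rendered
    absent <- if (numeric_field) is.na(ext_val) else is.na(ext_val)
    omission <- rendered & absent
    agree <- if (numeric_field) {
      !absent & abs(ext_val - true_val) <= tol
    } else {
      !absent & ext_val == true_val
    }
    error <- !absent & !agree # includes values extracted from unrendered fields
    correct <- agree | (!rendered & absent)
    mae <- if (numeric_field && any(error)) {
      mean(abs(ext_val[error] - true_val[error]))
    } else {
      NA_real_
    }
    tibble::tibble(
      field = field, n = length(ext_val),
      correct = sum(correct), errors = sum(error), omissions = sum(omission),
      mae_errors = mae
    )
  }
  out <- dplyr::bind_rows(
    field_report("age", sub$age, tr$age),
    field_report("gender", sub$gender, tr$gender, numeric_field = FALSE),
    field_report("weight", sub$weight_lb, tr$weight_lb),
    field_report("height", sub$height_in, tr$height_in)
  )
  class(out) <- c("extraction_validation", class(out))
  out
}
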