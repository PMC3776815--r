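# BMI computation, adult bands, teen LMS percentiles, congruence, and the
# analytic-sample contingency table with exclusion accounting.

#' Load the bundled LMS BMI-for-age reference
#'
#' A compact CDC-style growth reference (Box-Cox L, median M, coefficient of
#' variation S) on a 6-month age grid from 156 to 240 months (13-19 years),
#' both sexes. The bundled table is *synthetic*: a smooth surrogate with
#' realistic magnitudes, shipped so the package is self-contained; swap in a
#' real reference CSV (columns `sex`, `agemos`, `L`, `M`, `S`) for
#' substantive use.
#'
#' @param path CSV path; defaults to the bundled synthetic fixture.
#' @return A tibble with columns `sex`, `agemos`, `L`, `M`, `S`, sorted by
#'   age within sex.
#' @export
lms_reference <- function(path = weightask_file("lms_bmi_synthetic.csv")) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("sex", "agemos", "L", "M", "S") %in% names(df)))
  if (any(df$M <= 0) || any(df$S <= 0)) abort("LMS table requires M > 0 and S > 0")
  dplyr::arrange(df, .data$sex, .data$agemos)
}

#' Compute body mass index from imperial units
#'
#' `BMI = 703 * weight / height^2` with weight in pounds and height in
#' inches (equivalent to kg/m^2).
#'
#' @param weight_lb Weight in pounds (> 0).
#' @param height_in Height in inches (> 0).
#' @return Numeric BMI values.
#' @export
#' @examples
#' compute_bmi(180, 69) # 26.58
compute_bmi <- function(weight_lb, height_in) {
  if (any(!is.finite(weight_lb) | weight_lb <= 0) ||
    any(!is.finite(height_in) | height_in <= 0)) {
    abort("weight and height must be positive and finite")
  }
  703 * weight_lb / height_in^2
}

#' Classify adult BMI into standard categories
#'
#' Half-open bands: \[0, 18.5) underweight, \[18.5, 25) normal, \[25, 30)
#' overweight, \[30, Inf) obese. The boundary values 25 and 30 fall in the
#' higher band.
#'
#' @param bmi Positive finite BMI values.
#' @return A factor with levels underweight/normal/overweight/obese.
#' @export
#' @examples
#' classify_adult(c(24.9, 25, 30))
classify_adult <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) abort("bmi must be positive and finite")
  cut(bmi,
    breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
    labels = weight_classes()
  )
}

#' BMI-for-age percentile via the LMS method
#'
#' Interpolates L, M and S linearly in age, computes the Box-Cox z-score
#' `z = ((bmi/M)^L - 1) / (L * S)` (or `log(bmi/M)/S` when `L = 0`) and
#' returns `100 * pnorm(z)`.
#'
#' @param bmi Positive BMI values.
#' @param agemos Age in months; must lie within the reference table support.
#' @param sex `"male"`/`"female"` (recycled).
#' @param lms Reference table, see [lms_reference()].
#' @return Percentiles in \[0, 100\].
#' @export
teen_percentile <- function(bmi, agemos, sex, lms = lms_reference()) {
  n <- max(length(bmi), length(agemos), length(sex))
  bmi <- rep_len(bmi, n)
  agemos <- rep_len(agemos, n)
  sex <- rep_len(sex, n)
  out <- numeric(n)
  for (s in unique(sex)) {
    tab <- lms[lms$sex == s, ]
    if (nrow(tab) == 0) abort(sprintf("sex '%s' not present in LMS table", s))
    idx <- sex == s
    rng <- range(tab$agemos)
    bad <- agemos[idx] < rng[1] | agemos[idx] > rng[2]
    if (any(bad)) {
      abort(sprintf(
        "age(s) %s months outside LMS support [%s, %s] for sex '%s'",
        paste(unique(agemos[idx][bad]), collapse = ", "), rng[1], rng[2], s
      ))
    }
    L <- approx(tab$agemos, tab$L, xout = agemos[idx])$y
    M <- approx(tab$agemos, tab$M, xout = agemos[idx])$y
    S <- approx(tab$agemos, tab$S, xout = agemos[idx])$y
    z <- ifelse(
      abs(L) < 1e-12,
      log(bmi[idx] / M) / S,
      ((bmi[idx] / M)^L - 1) / (L * S)
    )
    out[idx] <- 100 * pnorm(z)
  }
  out
}

#' Band a BMI-for-age percentile
#'
#' Half-open bands `<5`, `5-85`, `85-95` and `95+` (the 95th percentile and
#' above is `95+`; band edges fall in the higher band).
#'
#' @param percentile Values in \[0, 100\].
#' @return A factor with the four band levels.
#' @export
#' @examples
#' classify_teen(c(50, 85, 97))
classify_teen <- function(percentile) {
  if (any(!is.finite(percentile) | percentile < 0 | percentile > 100)) {
    abort("percentile must lie in [0, 100]")
  }
  # right = FALSE + include.lowest closes the top interval, so 100 is 95+
  cut(percentile,
    breaks = c(0, 5, 85, 95, 100), right = FALSE,
    include.lowest = TRUE, labels = teen_bands()
  )
}

#' Map a teen percentile band to the four-level weight class
#'
#' `<5` is underweight, `5-85` normal, `85-95` overweight, `95+` obese —
#' the teen analogue of the adult BMI bands.
#'
#' @param band Factor or character of teen bands.
#' @return Character vector of weight classes.
#' @export
band_to_class <- function(band) {
  setNames(weight_classes(), teen_bands())[as.character(band)]
}

#' Default inquiry-congruence mapping
#'
#' High-weight terms (fat, obese) are congruent with an actual class of
#' overweight or obese; low-weight terms (skinny, thin) with underweight or
#' normal. The mapping is an explicit object so alternatives can be passed
#' to [assess_congruence()].
#'
#' @return A list with `high_terms`, `high_classes`, `low_terms`,
#'   `low_classes`.
#' @export
congruence_mapping <- function() {
  list(
    high_terms = high_terms(), high_classes = c("overweight", "obese"),
    low_terms = low_terms(), low_classes = c("underweight", "normal")
  )
}

#' Does the inquired term agree with the actual weight class?
#'
#' @param term Inquiry terms.
#' @param actual Actual weight classes (teen bands already mapped through
#'   [band_to_class()]).
#' @param mapping See [congruence_mapping()].
#' @return Logical vector.
#' @export
#' @examples
#' assess_congruence("fat", "obese") # TRUE
#' assess_congruence("obese", "normal") # FALSE
assess_congruence <- function(term, actual, mapping = congruence_mapping()) {
  actual <- as.character(actual)
  ifelse(term %in% mapping$high_terms, actual %in% mapping$high_classes,
    ifelse(term %in% mapping$low_terms, actual %in% mapping$low_classes, NA)
  )
}

#' Build asker records from extracted inquiry posts
#'
#' Applies the study's inclusion rules: complete profiles only (age, gender,
#' weight and height all present), a single inquiry term, and age at least
#' 13. Computes BMI, splits teens (13-19, classified by LMS percentile band)
#' from adults (20+, classified by BMI band), maps both onto the four-level
#' weight class, and flags congruence between inquired and actual category.
#' Users with several retained inquiry posts keep the earliest.
#'
#' @param extracted Output of [extract_posts()].
#' @param lms LMS reference, see [lms_reference()].
#' @param mapping Congruence mapping, see [congruence_mapping()].
#' @return A tibble of asker records (one per user) with columns `user_id`,
#'   `inquiry_post_id`, `timestamp`, `term`, profile fields, `bmi`,
#'   `age_class`, `teen_percentile`, `teen_band`, `actual` and `congruent`.
#'   Exclusion accounting (per-term extracted/excluded/retained counts) is
#'   attached as attribute `accounting`.
#' @export
build_asker_records <- function(extracted, lms = lms_reference(),
                                mapping = congruence_mapping()) {
  complete <- !is.na(extracted$age) & !is.na(extracted$gender) &
    !is.na(extracted$weight_lb) & !is.na(extracted$height_in)
  single <- extracted$term %in% inquiry_terms()
  of_age <- !is.na(extracted$age) & extracted$age >= 13
  keep <- complete & single & of_age
  kept <- extracted[keep, ]
  kept <- kept |>
    dplyr::arrange(.data$timestamp) |>
    dplyr::distinct(.data$user_id, .keep_all = TRUE)

  if (nrow(kept) > 0) {
    bmi <- compute_bmi(kept$weight_lb, kept$height_in)
    age_class <- ifelse(kept$age <= 19, "teen", "adult")
    pct <- rep(NA_real_, nrow(kept))
    is_teen <- age_class == "teen"
    if (any(is_teen)) {
      pct[is_teen] <- teen_percentile(
        bmi[is_teen], 12 * kept$age[is_teen] + 6, kept$gender[is_teen], lms
      )
    }
    band <- rep(NA_character_, nrow(kept))
    band[is_teen] <- as.character(classify_teen(pct[is_teen]))
    actual <- ifelse(is_teen, band_to_class(band),
      as.character(classify_adult(bmi))
    )
    records <- kept |>
      dplyr::rename(inquiry_post_id = "post_id") |>
      dplyr::mutate(
        bmi = bmi, age_class = age_class, teen_percentile = pct,
        teen_band = band, actual = actual,
        congruent = assess_congruence(.data$term, actual, mapping)
      )
  } else {
    records <- kept |>
      dplyr::rename(inquiry_post_id = "post_id") |>
      dplyr::mutate(
        bmi = numeric(0), age_class = character(0),
        teen_percentile = numeric(0), teen_band = character(0),
        actual = character(0), congruent = logical(0)
      )
  }

  per_term_ext <- as.integer(table(factor(
    ifelse(extracted$term == "multiple", NA, extracted$term),
    levels = inquiry_terms()
  )))
  per_term_ret <- as.integer(table(factor(records$term, levels = inquiry_terms())))
  accounting <- tibble::tibble(
    term = inquiry_terms(),
    extracted = per_term_ext,
    retained = per_term_ret,
    excluded = per_term_ext - per_term_ret
  )
  attr(records, "accounting") <- accounting
  records
}

#' Per-term exclusion accounting
#'
#' Retained askers per inquiry term as extracted minus excluded, with a
#' grand total; errors if any retained count would be negative (a sign of
#' inconsistent inputs).
#'
#' @param extracted Named (by term) or ordered counts of extracted askers.
#' @param excluded Counts of excluded askers, same shape.
#' @return A tibble with columns `term`, `extracted`, `excluded`,
#'   `retained`; the total retained is attached as attribute `total`.
#' @export
#' @examples
#' asker_accounting(
#'   c(skinny = 6189, thin = 17541, fat = 51988, obese = 7353),
#'   c(skinny = 5965, thin = 16769, fat = 49352, obese = 7059)
#' )
asker_accounting <- function(extracted, excluded) {
  retained <- extracted - excluded
  if (any(retained < 0)) {
    abort("negative retained count: excluded exceeds extracted for some term")
  }
  out <- tibble::tibble(
    term = if (!is.null(names(extracted))) names(extracted) else inquiry_terms(),
    extracted = as.integer(extracted),
    excluded = as.integer(excluded),
    retained = as.integer(retained)
  )
  attr(out, "total") <- sum(out$retained)
  out
}

# shared summariser: given long counts (section,row,gender,term,count)
# produce the contingency tables and derived percentages
summarise_asker_counts <- function(counts, accounting = NULL) {
  section <- function(s) {
    counts |>
      dplyr::filter(.data$section == s) |>
      tidyr::pivot_wider(
        id_cols = "row", names_from = c("gender", "term"),
        values_from = "count", values_fill = 0L
      ) |>
      dplyr::mutate(total = as.integer(rowSums(dplyr::across(-"row"))))
  }
  high_share <- function(s, g, high_rows) {
    df <- counts[counts$section == s & counts$gender == g &
      counts$term %in% high_terms(), ]
    denom <- sum(df$count)
    if (denom == 0) {
      return(NA_real_)
    }
    100 * sum(df$count[df$row %in% high_rows]) / denom
  }
  summary <- tibble::tibble(
    group = c("adult_male", "adult_female", "teen_male", "teen_female"),
    description = c(
      "adult men inquiring fat/obese who are actually overweight/obese (%)",
      "adult women inquiring fat/obese who are actually overweight/obese (%)",
      "teen boys inquiring fat/obese in the 85th+ percentile (%)",
      "teen girls inquiring fat/obese in the 85th+ percentile (%)"
    ),
    pct = c(
      high_share("adult_bmi", "male", c("25-30", "30+")),
      high_share("adult_bmi", "female", c("25-30", "30+")),
      high_share("teen_pct", "male", c("85-95", "95+")),
      high_share("teen_pct", "female", c("85-95", "95+"))
    )
  )
  structure(
    list(
      accounting = accounting,
      age = section("age"),
      adult_bmi = section("adult_bmi"),
      teen_pct = section("teen_pct"),
      summary = summary
    ),
    class = "asker_table"
  )
}

#' Build the analytic-sample contingency table
#'
#' From asker records, produces (a) per-term exclusion accounting (when
#' `extracted_counts`/`excluded_counts` are supplied or derivable from the
#' records' accounting attribute), (b) age-range x gender x term counts,
#' (c) adult-BMI-band x gender x term and teen-percentile-band x gender x
#' term counts, and (d) the derived percentages of high-term inquirers who
#' are actually overweight/obese, by gender and age class.
#'
#' @param records Asker records from [build_asker_records()], or `NULL` when
#'   building purely from keyed-in counts via [asker_table_from_counts()].
#' @param extracted_counts,excluded_counts Optional per-term totals for the
#'   accounting block (named by term).
#' @return An object of class `asker_table`: a list with elements
#'   `accounting`, `age`, `adult_bmi`, `teen_pct` and `summary`.
#' @export
build_asker_table <- function(records, extracted_counts = NULL,
                              excluded_counts = NULL) {
  if (is.null(extracted_counts) && !is.null(attr(records, "accounting"))) {
    acc0 <- attr(records, "accounting")
    extracted_counts <- setNames(acc0$extracted, acc0$term)
    excluded_counts <- setNames(acc0$excluded, acc0$term)
  }
  accounting <- if (!is.null(extracted_counts)) {
    asker_accounting(extracted_counts, excluded_counts)
  }
  age_bands <- c("13-15", "16-18", "19-25", "25+")
  if (nrow(records) > 0) {
    rec <- records |>
      dplyr::mutate(
        age_row = cut(.data$age,
          breaks = c(13, 16, 19, 26, Inf), right = FALSE,
          labels = age_bands
        ),
        adult_row = ifelse(.data$age_class == "adult",
          as.character(cut(.data$bmi,
            breaks = c(0, 18.5, 25, 30, Inf),
            right = FALSE, labels = c("<18.5", "18.5-25", "25-30", "30+")
          )), NA
        ),
        teen_row = .data$teen_band
      )
    long <- dplyr::bind_rows(
      rec |> dplyr::count(row = .data$age_row, .data$gender, .data$term) |>
        dplyr::mutate(section = "age"),
      rec |> dplyr::filter(!is.na(.data$adult_row)) |>
        dplyr::count(row = .data$adult_row, .data$gender, .data$term) |>
        dplyr::mutate(section = "adult_bmi"),
      rec |> dplyr::filter(!is.na(.data$teen_row)) |>
        dplyr::count(row = .data$teen_row, .data$gender, .data$term) |>
        dplyr::mutate(section = "teen_pct")
    ) |>
      dplyr::mutate(row = as.character(.data$row)) |>
      dplyr::rename(count = "n")
  } else {
    long <- tibble::tibble(
      section = character(), row = character(), gender = character(),
      term = character(), count = integer()
    )
  }
  # complete all cells so empty strata appear as zero
  grid <- dplyr::bind_rows(
    tidyr::crossing(section = "age", row = age_bands),
    tidyr::crossing(section = "adult_bmi", row = c("<18.5", "18.5-25", "25-30", "30+")),
    tidyr::crossing(section = "teen_pct", row = teen_bands())
  ) |>
    tidyr::crossing(gender = c("male", "female"), term = inquiry_terms())
  long <- grid |>
    dplyr::left_join(long, by = c("section", "row", "gender", "term")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  summarise_asker_counts(long, accounting)
}

#' Load the bundled printed analytic-sample counts
#'
#' The keyed-in published contingency table (age x gender x term, adult BMI
#' band x gender x term, teen percentile band x gender x term) and the
#' per-term extraction/exclusion totals, shipped as plain-CSV fixtures.
#'
#' @return A list with `counts` (long tibble: section, row, gender, term,
#'   count) and `accounting` (term, extracted, excluded).
#' @export
table1_fixture <- function() {
  counts <- tibble::as_tibble(
    read.csv(weightask_file("table1_counts.csv"), stringsAsFactors = FALSE)
  )
  accounting <- tibble::as_tibble(
    read.csv(weightask_file("table1_accounting.csv"), stringsAsFactors = FALSE)
  )
  list(counts = counts, accounting = accounting)
}

#' Asker table from keyed-in counts
#'
#' Builds the same `asker_table` object as [build_asker_table()] but from a
#' long table of printed counts rather than from records — used to verify
#' the table arithmetic against the published numbers.
#'
#' @param fixture A list like [table1_fixture()]'s return value.
#' @return An `asker_table` object.
#' @export
asker_table_from_counts <- function(fixture = table1_fixture()) {
  accounting <- asker_accounting(
    setNames(fixture$accounting$extracted, fixture$accounting$term),
    setNames(fixture$accounting$excluded, fixture$accounting$term)
  )
  summarise_asker_counts(fixture$counts, accounting)
}

#' @export
print.asker_table <- function(x, digits = 1, ...) {
  cat("Analytic-sample table\n")
  if (!is.null(x$accounting)) {
    cat("\nExclusion accounting (retained = extracted - excluded):\n")
    print(as.data.frame(x$accounting), row.names = FALSE)
    cat(sprintf("Total retained: %d\n", attr(x$accounting, "total")))
  }
  for (s in c("age", "adult_bmi", "teen_pct")) {
    cat(sprintf(
      "\n%s:\n",
      c(
        age = "Age range", adult_bmi = "Adult BMI band",
        teen_pct = "Teen BMI percentile band"
      )[s]
    ))
    print(as.data.frame(x[[s]]), row.names = FALSE)
  }
  cat("\nShare of fat/obese inquirers actually overweight/obese:\n")
  df <- x$summary
  df$pct <- round(df$pct, digits)
  print(as.data.frame(df[, c("group", "pct")]), row.names = FALSE)
  invisible(x)
}
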