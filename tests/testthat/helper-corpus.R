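# Shared fixtures: small corpora built in code, memoised per test session.

.corpus_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.corpus_cache[[key]])) .corpus_cache[[key]] <- builder()
  .corpus_cache[[key]]
}

# lossless rendering: every field canonical, so extraction recovers truth
lossless_config <- function(seed, n_askers, ...) {
  corpus_config(
    seed = seed, n_askers = n_askers,
    omission_rates = c(age = 0, gender = 0, weight = 0, height = 0),
    ambiguity_rate = 0, ...
  )
}

flat_baseline <- function(rate = 0.01) {
  setNames(rep(rate, length(taxonomy_categories())), taxonomy_categories())
}

# the planted-effects study corpus used by the recovery checks
planted_corpus <- function() {
  cached("planted", function() {
    eff <- dplyr::bind_rows(
      planted_effect("Health/Diseases/Diabetes", 4.6,
        gender = "male", actual = "overweight|obese"
      ),
      planted_effect("Pregnancy & Parenting/Trying to Conceive", 3.1,
        gender = "female", actual = "overweight|obese"
      )
    )
    generate_corpus(lossless_config(
      seed = 42, n_askers = 20000,
      effect_table = eff, baseline_category_rates = flat_baseline()
    ))
  })
}

planted_records <- function() {
  cached("planted_records", function() {
    build_asker_records(extract_posts(planted_corpus()$posts))
  })
}

small_corpus <- function() {
  cached("small", function() generate_corpus(corpus_config(seed = 7, n_askers = 800)))
}

# brute-force BH step-up oracle, independent of stats::p.adjust
bh_oracle <- function(p, threshold = 0.05) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  list(q = q, significant = q <= threshold)
}

# numerical inversion of the LMS quantile function: the percentile p such
# that M (1 + L S z_p)^(1/L) equals the observed bmi
lms_percentile_oracle <- function(bmi, agemos, sex, lms = lms_reference()) {
  tab <- lms[lms$sex == sex, ]
  L <- approx(tab$agemos, tab$L, xout = agemos)$y
  M <- approx(tab$agemos, tab$M, xout = agemos)$y
  S <- approx(tab$agemos, tab$S, xout = agemos)$y
  qfun <- function(z) {
    if (abs(L) < 1e-12) M * exp(S * z) else M * (1 + L * S * z)^(1 / L)
  }
  # for L < 0 the quantile function only exists for z < -1/(L*S)
  z_hi <- if (L < 0) min(8, -1 / (L * S) - 1e-9) else 8
  z_lo <- if (L > 0) max(-8, -1 / (L * S) + 1e-9) else -8
  root <- uniroot(function(z) qfun(z) - bmi, lower = z_lo, upper = z_hi, tol = 1e-12)
  100 * pnorm(root$root)
}

# hand 2x2 chi-squared (no continuity correction)
chisq_2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# delta-method SE of a log posting ratio (stratum nested in pool)
ratio_log_se <- function(k_s, n_s, k_all, n_all) {
  sqrt(1 / k_s - 1 / n_s + 1 / k_all - 1 / n_all)
}
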