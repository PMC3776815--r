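# Internal helpers shared across modules.

weightask_file <- function(...) {
  path <- system.file("extdata", ..., package = "weightask", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) system.file resolves differently
    path <- file.path("inst", "extdata", ...)
  }
  path
}

# closed enumerations used throughout
inquiry_terms <- function() c("skinny", "thin", "fat", "obese")
weight_classes <- function() c("underweight", "normal", "overweight", "obese")
teen_bands <- function() c("<5", "5-85", "85-95", "95+")

low_terms <- function() c("skinny", "thin")
high_terms <- function() c("fat", "obese")

#' Forum category taxonomy used in the analyses
#'
#' Slash-separated category paths covering the topical areas examined when
#' looking at askers' future posts: diabetes, heart disease, mental health,
#' alternative medicine, skin & body, fertility/pregnancy/parenting topics,
#' relationships, makeup and weddings.
#'
#' @return A character vector of category paths.
#' @export
#' @examples
#' taxonomy_categories()
taxonomy_categories <- function() {
  c(
    "Health/Diseases/Diabetes",
    "Health/Diseases/Heart Diseases",
    "Health/Mental Health",
    "Health/Alternative Medicine",
    "Beauty & Style/Skin & Body",
    "Beauty & Style/Makeup",
    "Pregnancy & Parenting/Trying to Conceive",
    "Pregnancy & Parenting/Pregnancy",
    "Pregnancy & Parenting/Parenting",
    "Pregnancy & Parenting/Toddler & Preschooler",
    "Pregnancy & Parenting/Newborn & Baby",
    "Family & Relationships/Marriage & Divorce",
    "Family & Relationships/Singles & Dating",
    "Weddings"
  )
}

inquiry_category <- function() "Health/Diet & Fitness"

assert_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1]", name))
  }
  invisible(x)
}

# format POSIXct as ISO-8601 UTC
iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_time <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
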