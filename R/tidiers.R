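# broom-style tidiers for fitted/result objects.

#' @method tidy bullying_assoc
#' @export
tidy.bullying_assoc <- function(x, ...) {
  x$fractions
}

#' @method glance bullying_assoc
#' @export
glance.bullying_assoc <- function(x, ...) {
  if (is.null(x$interaction)) {
    return(tibble::tibble(
      statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
      method = "no bullying events"
    ))
  }
  tibble::tibble(
    statistic = x$interaction$statistic,
    df = x$interaction$df,
    p_value = x$interaction$p_value,
    method = x$interaction$method
  )
}

#' @method tidy income_assoc
#' @export
tidy.income_assoc <- function(x, ...) {
  if (!x$evaluable) {
    return(tibble::tibble())
  }
  x$groups
}

#' @method glance income_assoc
#' @export
glance.income_assoc <- function(x, ...) {
  tibble::tibble(
    direction = x$direction, slope = x$slope,
    p_value = x$p_value, evaluable = x$evaluable
  )
}

#' @method tidy overexpression_result
#' @export
tidy.overexpression_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "overexpression_result")
  out
}

#' @method tidy county_accuracy
#' @export
tidy.county_accuracy <- function(x, ...) {
  x$congruence
}

#' @method glance extraction_validation
#' @export
glance.extraction_validation <- function(x, ...) {
  tibble::tibble(
    n = x$n[1],
    error_rate = sum(x$errors) / sum(x$n),
    omission_rate = sum(x$omissions) / sum(x$n)
  )
}
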