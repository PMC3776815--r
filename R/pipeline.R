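# End-to-end orchestration with reproducible configuration and artifacts.

write_csv_utf8 <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) if (is.list(df[[nm]])) df[[nm]] <- vapply(df[[nm]], paste, character(1), collapse = ";")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' Run the analysis pipeline end to end
#'
#' Stages: `simulate` (generate the synthetic corpus and ground truth),
#' `extract` (inquiry matching + profile extraction), `classify` (asker
#' records and the analytic-sample table), `analyze` (over-expression
#' screen, bullying association, county analyses) and `report` (aggregate
#' human-readable summary). Later stages consume the in-memory results of
#' earlier ones; every artifact directory gets a `run_info.json` provenance
#' record (config hash, seed, package version).
#'
#' @param config A [corpus_config()]; its seed drives all randomness.
#' @param out_dir Output directory for artifacts; `NULL` for none.
#' @param stages Character vector of stages to run (in canonical order).
#' @param n_bins Bins for the county bullying curve.
#' @param q_threshold FDR threshold for the over-expression screen.
#' @param strata Strata table for the screen, see [default_strata()].
#' @return A list with the stage outputs that were produced: `corpus`,
#'   `extracted`, `records`, `asker_table`, `overexpression`, `bullying`,
#'   `curve`, `accuracy`, `income`.
#' @export
#' @examples
#' res <- run_pipeline(corpus_config(seed = 7, n_askers = 300))
#' res$asker_table$summary
run_pipeline <- function(config = corpus_config(),
                         out_dir = NULL,
                         stages = c("simulate", "extract", "classify", "analyze", "report"),
                         n_bins = 10, q_threshold = 0.05,
                         strata = default_strata()) {
  stages <- match.arg(stages, several.ok = TRUE)
  res <- list()
  t_start <- Sys.time()
  say <- function(fmt, ...) message(sprintf(paste0("[weightask] ", fmt), ...))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if ("simulate" %in% stages) {
    say("simulate: generating %d askers (seed %d)", config$n_askers, config$seed)
    res$corpus <- generate_corpus(config)
    say("simulate: %d posts", nrow(res$corpus$posts))
    if (!is.null(out_dir)) write_corpus(res$corpus, file.path(out_dir, "corpus"))
  }
  if ("extract" %in% stages) {
    if (is.null(res$corpus)) abort("extract stage needs a corpus; run simulate first")
    res$extracted <- extract_posts(res$corpus$posts)
    say("extract: %d inquiry posts", nrow(res$extracted))
    if (!is.null(out_dir)) {
      write_csv_utf8(res$extracted, file.path(out_dir, "extracted.csv"))
    }
  }
  if ("classify" %in% stages) {
    if (is.null(res$extracted)) abort("classify stage needs extraction output")
    res$records <- build_asker_records(res$extracted)
    res$records <- link_counties(
      res$records, config$county_table$zip_map, config$county_table$counties
    )
    res$asker_table <- build_asker_table(res$records)
    say("classify: %d asker records retained", nrow(res$records))
    if (!is.null(out_dir)) {
      write_csv_utf8(res$records, file.path(out_dir, "asker_records.csv"))
      utils::capture.output(print(res$asker_table),
        file = file.path(out_dir, "table1_report.txt")
      )
      write_csv_utf8(res$asker_table$summary, file.path(out_dir, "table1_summary.csv"))
    }
  }
  if ("analyze" %in% stages) {
    if (is.null(res$records)) abort("analyze stage needs asker records")
    res$overexpression <- category_overexpression(
      res$records, res$corpus$posts,
      strata = strata, q_threshold = q_threshold
    )
    flags <- bullying_flags_from_posts(res$records, res$corpus$posts)
    res$bullying <- bullying_association(res$records, flags)
    linked <- res$records |>
      dplyr::mutate(bullied = flags$bullied[match(.data$user_id, flags$user_id)])
    res$curve <- bullying_fraction_curve(linked, n_bins = n_bins)
    res$accuracy <- accuracy_by_county(linked)
    res$income <- income_bullying_association(linked)
    say(
      "analyze: %d over-expressed stratum-category pairs",
      sum(res$overexpression$overexpressed, na.rm = TRUE)
    )
    if (!is.null(out_dir)) {
      write_csv_utf8(res$overexpression, file.path(out_dir, "overexpression.csv"))
      write_csv_utf8(res$bullying$fractions, file.path(out_dir, "bullying_fractions.csv"))
      write_csv_utf8(res$curve, file.path(out_dir, "bullying_curve.csv"))
      write_csv_utf8(res$accuracy$congruence, file.path(out_dir, "accuracy_by_county.csv"))
    }
  }
  if ("report" %in% stages && !is.null(out_dir)) {
    lines <- c(
      "weightask pipeline report",
      sprintf("seed: %d, askers: %d", config$seed, config$n_askers),
      ""
    )
    if (!is.null(res$asker_table)) {
      lines <- c(lines, utils::capture.output(print(res$asker_table)), "")
    }
    if (!is.null(res$overexpression)) {
      over <- res$overexpression[
        !is.na(res$overexpression$overexpressed) & res$overexpression$overexpressed,
      ]
      lines <- c(
        lines, "Over-expressed categories (ratio > 1, BH-FDR 5%):",
        if (nrow(over) > 0) {
          sprintf(
            "  %s | %s | ratio %.2f (q = %.3g)",
            over$stratum, over$category, over$ratio, over$q_value
          )
        } else "  none",
        ""
      )
    }
    if (!is.null(res$bullying)) {
      lines <- c(lines, utils::capture.output(print(res$bullying)), "")
    }
    if (!is.null(res$income)) {
      lines <- c(lines, utils::capture.output(print(res$income)))
    }
    writeLines(lines, file.path(out_dir, "report.txt"))
    say("report: written to %s", file.path(out_dir, "report.txt"))
  }
  if (!is.null(out_dir)) {
    cfg <- config[!vapply(config, is.function, logical(1))]
    run_info <- list(
      package = "weightask",
      version = as.character(utils::packageVersion("weightask")),
      seed = config$seed,
      config_hash = rlang::hash(cfg),
      stages = stages,
      elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
    )
    jsonlite::write_json(run_info, file.path(out_dir, "run_info.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(res)
}
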