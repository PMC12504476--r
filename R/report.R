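#' Run configurations
#'
#' Reporting entry points take a plain named list (or a YAML file read with
#' [read_run_config()]) with fields: `schema` (path; omit for the bundled
#' smart elder-care schema), `scores` (path), `dialect` (score-table
#' dialect, default `"long"`), `mode` (`"rounded2"`/`"exact"`),
#' `breakpoints`/`labels` (grade scale; omit for defaults), `policies`
#' (optional metadata CSV with a `level` column for group means), `out_dir`
#' (output directory), `upsample` and `colormap` (figure options), and
#' `verbose` (logical).
#'
#' @param path YAML config file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

log_line <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

config_inputs <- function(config) {
  schema <- if (is.null(config$schema)) {
    eldercare_schema()
  } else {
    read_pmc_schema(config$schema)
  }
  scores <- if (is.null(config$scores)) {
    eldercare_scores()
  } else {
    read_score_table(config$scores, schema,
                     dialect = config$dialect %||% "long")
  }
  scale <- if (is.null(config$breakpoints)) {
    pmc_grade_scale()
  } else {
    pmc_grade_scale(config$breakpoints, config$labels)
  }
  list(schema = schema, scores = scores, scale = scale,
       mode = config$mode %||% "rounded2")
}

#' Evaluate a score table and write result files
#'
#' Computes the full evaluation (indices, grades, ranks, variable means,
#' group means when policy metadata with a `level` column is supplied, and
#' improvement paths) and writes `results.csv`, `results.json`,
#' `variable_means.csv`, `improvement_paths.csv`, and a human-readable
#' `report.md` into `out_dir`. All computation happens before the first
#' byte is written, so a validation failure leaves no partial outputs.
#' Reruns on identical inputs overwrite byte-identical tabular outputs.
#'
#' @param config a run configuration list; see [read_run_config()].
#' @return the `pmc_result`, invisibly; files as a side effect.
#' @export
pmc_report <- function(config = list()) {
  inp <- config_inputs(config)
  out_dir <- config$out_dir %||% "."
  log_line(config$verbose, "evaluating %d policies (mode %s)",
           nrow(inp$scores), inp$mode)
  result <- pmc_evaluate(inp$scores, mode = inp$mode, scale = inp$scale)
  means <- pmc_variable_means(result)
  paths <- pmc_improvement_path(result)
  summ <- glance(result)
  groups <- NULL
  meta_path <- config$policies
  if (!is.null(meta_path) || is.null(config$scores)) {
    meta <- if (is.null(meta_path)) {
      eldercare_policies()
    } else {
      readr::read_csv(meta_path, show_col_types = FALSE)
    }
    if ("level" %in% names(meta)) {
      groups <- meta |>
        dplyr::filter(.data$policy %in% result$policy) |>
        dplyr::group_by(level = .data$level) |>
        dplyr::summarise(
          mean_index = pmc_group_mean(result, .data$policy),
          n = dplyr::n(), .groups = "drop")
    }
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(result), file.path(out_dir, "results.csv"))
  jsonlite::write_json(tibble::as_tibble(result),
                       file.path(out_dir, "results.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  readr::write_csv(means, file.path(out_dir, "variable_means.csv"))
  readr::write_csv(paths, file.path(out_dir, "improvement_paths.csv"))
  writeLines(report_markdown(result, means, paths, summ, groups),
             file.path(out_dir, "report.md"), useBytes = TRUE)
  log_line(config$verbose, "wrote results to %s", out_dir)
  invisible(result)
}

report_markdown <- function(result, means, paths, summ, groups) {
  ranked <- dplyr::arrange(tibble::as_tibble(result), .data$rank)
  path_str <- paths |>
    dplyr::group_by(.data$policy) |>
    dplyr::summarise(path = paste(.data$primary, collapse = " -> "),
                     .groups = "drop")
  c("# PMC evaluation report", "",
    sprintf("Policies evaluated: %d; mean PMC index: %.2f.",
            summ$n_policies, summ$mean_index), "",
    "## Ranking", "",
    "| Rank | Policy | PMC index | Grade |",
    "| ---- | ------ | --------- | ----- |",
    sprintf("| %d | %s | %.2f | %s |",
            ranked$rank, ranked$policy, ranked$pmc_index, ranked$grade), "",
    "## Primary-variable means", "",
    "| Variable | Mean |", "| -------- | ---- |",
    sprintf("| %s | %.2f |", means$primary, means$mean), "",
    if (!is.null(groups)) {
      c("## Group means by administrative level", "",
        "| Level | Mean PMC index | n |", "| ----- | -------------- | - |",
        sprintf("| %s | %.2f | %d |", groups$level, groups$mean_index,
                groups$n), "")
    },
    "## Improvement paths", "",
    if (nrow(path_str)) {
      sprintf("- %s: %s", path_str$policy, path_str$path)
    } else {
      "- (no policy scores below the cross-policy means)"
    })
}

#' Render surface and radar figures
#'
#' Writes one PMC surface image per policy (`surface_<policy>.png`) and one
#' radar chart (`radar.png`) into `out_dir`.
#'
#' @inheritParams pmc_report
#' @return character vector of written paths, invisibly.
#' @export
pmc_render_figures <- function(config = list()) {
  inp <- config_inputs(config)
  result <- pmc_evaluate(inp$scores, mode = inp$mode, scale = inp$scale)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (pol in result$policy) {
    f <- file.path(out_dir, sprintf("surface_%s.png", pol))
    render_plot(plot_pmc_surface(result, pol,
                                 upsample = config$upsample %||% 20,
                                 colormap = config$colormap %||% "viridis"), f)
    written <- c(written, f)
    log_line(config$verbose, "wrote %s", f)
  }
  f <- file.path(out_dir, "radar.png")
  render_plot(plot_pmc_radar(result), f)
  log_line(config$verbose, "wrote %s", f)
  invisible(c(written, f))
}

#' Mine a corpus and write term statistics and the semantic network
#'
#' Reads a pre-tokenized corpus, counts term frequencies, builds the
#' keyword co-occurrence network over the `top_n` most frequent terms, and
#' writes `term_frequencies.csv`, `network_edgelist.csv`, and
#' `network.graphml` into `out_dir`. A stopword list that removes every
#' token yields empty outputs with a warning.
#'
#' @param corpus_paths text files, one document per file, one unit per line.
#' @param stopwords_path optional file with one stopword per line.
#' @param top_n nodes to keep in the network.
#' @param out_dir output directory.
#' @param verbose log progress lines.
#' @return the `pmc_network`, invisibly.
#' @export
pmc_mine <- function(corpus_paths, stopwords_path = NULL, top_n = 50,
                     out_dir = ".", verbose = FALSE) {
  corpus <- read_corpus(corpus_paths)
  stopwords <- if (is.null(stopwords_path)) {
    character()
  } else {
    readr::read_lines(stopwords_path)
  }
  stats <- term_frequencies(corpus, stopwords)
  if (nrow(stats) == 0) {
    warning("no terms survive stopword filtering; outputs are empty",
            call. = FALSE)
  }
  network <- build_cooccurrence(corpus, stopwords, top_n)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(stats, file.path(out_dir, "term_frequencies.csv"))
  write_network(network, file.path(out_dir, "network_edgelist.csv"),
                format = "edgelist")
  write_network(network, file.path(out_dir, "network.graphml"),
                format = "graphml")
  log_line(verbose, "mined %d terms, %d nodes, %d edges",
           nrow(stats), nrow(network$nodes), nrow(network$edges))
  invisible(network)
}
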