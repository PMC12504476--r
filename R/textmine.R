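#' Policy corpora
#'
#' A corpus is a tidy tibble with columns `doc`, `unit`, and `token`: one
#' row per token occurrence, grouped into co-occurrence units (by default
#' one sentence/line per unit). Keyword co-occurrence is counted within
#' units, so the unit choice sets the semantic window.
#'
#' @param df a data frame with columns `doc`, `unit`, `token`.
#' @return a validated `pmc_corpus` tibble.
#' @export
pmc_corpus <- function(df) {
  df <- tibble::as_tibble(df)
  problems <- character()
  need <- setdiff(c("doc", "unit", "token"), names(df))
  if (length(need)) {
    problems <- c(problems, sprintf("missing column '%s'", need))
  } else if (nrow(df) && (anyNA(df$token) || any(!nzchar(df$token)))) {
    problems <- c(problems, "tokens must be nonempty strings")
  }
  if (length(problems)) abort_invalid(problems, "corpus")
  tibble::new_tibble(df[c("doc", "unit", "token")], class = "pmc_corpus")
}

#' Read a corpus from pre-tokenized text files
#'
#' Each file is one document; each line one co-occurrence unit. The default
#' tokenizer splits on whitespace, which suits pre-segmented text (for
#' Chinese policy text, segment upstream and join tokens with spaces); pass
#' any `function(line) -> character vector` to plug in another tokenizer.
#'
#' @param paths one or more text files (UTF-8).
#' @param tokenize tokenizer applied per line.
#' @return a `pmc_corpus` tibble.
#' @export
read_corpus <- function(paths, tokenize = whitespace_tokenizer) {
  rows <- purrr::list_rbind(purrr::map(paths, function(p) {
    lines <- readr::read_lines(p)
    toks <- lapply(lines, tokenize)
    tibble::tibble(
      doc = basename(p),
      unit = rep(seq_along(lines), lengths(toks)),
      token = unlist(toks, use.names = FALSE) %||% character())
  }))
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(doc = character(), unit = integer(),
                           token = character())
  }
  pmc_corpus(rows)
}

#' @rdname read_corpus
#' @param line one line of text.
#' @export
whitespace_tokenizer <- function(line) {
  t <- strsplit(trimws(line), "\\s+")[[1]]
  t[nzchar(t)]
}

#' Term frequencies
#'
#' Occurrence counts over all tokens not in the stopword set, sorted by
#' descending count then term.
#'
#' @param corpus a `pmc_corpus`.
#' @param stopwords character vector of terms to drop before counting.
#' @return a tibble with columns `term` and `n`.
#' @export
term_frequencies <- function(corpus, stopwords = character()) {
  corpus |>
    tibble::as_tibble() |>
    dplyr::filter(!.data$token %in% stopwords) |>
    dplyr::count(term = .data$token) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$term)
}

#' Keyword co-occurrence network
#'
#' Builds the weighted undirected semantic network over the `top_n` most
#' frequent non-stopword terms (frequency ties broken lexicographically).
#' Node weight is term frequency; the weight of edge \{a, b\} is the number
#' of units in which both terms occur. No self-loops; zero-weight pairs are
#' absent.
#'
#' @inheritParams term_frequencies
#' @param top_n how many terms to keep as nodes (>= 1).
#' @return a `pmc_network`: a list with tibbles `nodes` (`term`, `weight`)
#'   and `edges` (`from`, `to`, `weight`; `from < to` lexicographically).
#' @export
build_cooccurrence <- function(corpus, stopwords = character(), top_n = 50) {
  stopifnot(top_n >= 1)
  freq <- term_frequencies(corpus, stopwords)
  nodes <- utils::head(freq, top_n)
  names(nodes) <- c("term", "weight")
  present <- corpus |>
    tibble::as_tibble() |>
    dplyr::filter(.data$token %in% nodes$term) |>
    dplyr::distinct(.data$doc, .data$unit, .data$token)
  edges <- present |>
    dplyr::inner_join(present, by = c("doc", "unit"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$token.x < .data$token.y) |>
    dplyr::count(from = .data$token.x, to = .data$token.y, name = "weight") |>
    dplyr::arrange(.data$from, .data$to)
  new_pmc_network(nodes, edges)
}

new_pmc_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "pmc_network")
}

#' @export
print.pmc_network <- function(x, ...) {
  cat(sprintf("<pmc_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Weighted degree centrality
#'
#' The sum of incident edge weights per node — the centrality statistic
#' reported for the semantic network (closeness to the drawn center is a
#' layout property, not a statistic).
#'
#' @param network a `pmc_network`.
#' @return a tibble with columns `term` and `degree`, descending.
#' @export
weighted_degree <- function(network) {
  inc <- dplyr::bind_rows(
    network$edges[c("from", "weight")] |> dplyr::rename(term = "from"),
    network$edges[c("to", "weight")] |> dplyr::rename(term = "to"))
  network$nodes["term"] |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(inc, .data$term),
                       degree = sum(.data$weight), .groups = "drop"),
      by = "term") |>
    dplyr::mutate(degree = dplyr::coalesce(.data$degree, 0L)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$term)
}

#' Convert a co-occurrence network to igraph
#'
#' @param network a `pmc_network`.
#' @return an undirected [igraph::graph][igraph] with vertex attribute
#'   `weight` (term frequency) and weighted edges.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = as.data.frame(network$nodes))
}

#' Export / import a co-occurrence network
#'
#' Two lossless formats: `"edgelist"`, a single CSV with a `type` column
#' holding both node rows (`from` = term, `weight` = frequency) and edge
#' rows; and `"graphml"`, written through igraph. Both round-trip nodes,
#' node weights, and edge weights exactly.
#'
#' @param network a `pmc_network`.
#' @param path output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path` invisibly (`write_network`); a `pmc_network`
#'   (`read_network`).
#' @export
write_network <- function(network, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    rows <- dplyr::bind_rows(
      tibble::tibble(type = "node", from = network$nodes$term,
                     to = NA_character_, weight = network$nodes$weight),
      tibble::tibble(type = "edge", from = network$edges$from,
                     to = network$edges$to, weight = network$edges$weight))
    readr::write_csv(rows, path, na = "")
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    rows <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = "cccd")
    nodes <- rows |>
      dplyr::filter(.data$type == "node") |>
      dplyr::transmute(term = .data$from, weight = as.integer(.data$weight))
    edges <- rows |>
      dplyr::filter(.data$type == "edge") |>
      dplyr::transmute(from = .data$from, to = .data$to,
                       weight = as.integer(.data$weight))
    new_pmc_network(nodes, edges)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::tibble(
      term = igraph::vertex_attr(g, "name"),
      weight = as.integer(igraph::vertex_attr(g, "weight")))
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble::tibble(
      from = pmin(el$from, el$to),
      to = pmax(el$from, el$to),
      weight = as.integer(el$weight)) |>
      dplyr::arrange(.data$from, .data$to)
    nodes <- dplyr::arrange(nodes, dplyr::desc(.data$weight), .data$term)
    new_pmc_network(nodes, edges)
  }
}
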