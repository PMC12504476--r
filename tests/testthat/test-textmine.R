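toy_corpus <- function() {
  pmc_corpus(tibble::tibble(
    doc = c(rep("d1", 5), rep("d2", 4)),
    unit = c(1, 1, 1, 2, 2, 1, 1, 2, 2),
    token = c("service", "older", "service",
              "service", "care",
              "older", "care",
              "service", "older")))
}

test_that("term frequencies count tokens and honour stopwords", {
  tf <- term_frequencies(toy_corpus())
  expect_equal(tf$n[tf$term == "service"], 4L)
  expect_equal(tf$n[tf$term == "older"], 3L)
  tf2 <- term_frequencies(toy_corpus(), stopwords = c("older"))
  expect_false("older" %in% tf2$term)
  expect_equal(tf2$n[tf2$term == "service"], 4L)
  empty <- pmc_corpus(tibble::tibble(doc = character(), unit = integer(),
                                     token = character()))
  expect_equal(nrow(term_frequencies(empty)), 0)
})

test_that("co-occurrence edges count units containing both terms", {
  net <- build_cooccurrence(toy_corpus(), top_n = 10)
  # service & older share units (d1,1) and (d2,2)
  e <- net$edges
  expect_equal(e$weight[e$from == "older" & e$to == "service"], 2L)
  expect_equal(e$weight[e$from == "care" & e$to == "service"], 1L)
  # undirected with from < to, no self-loops
  expect_true(all(e$from < e$to))
  expect_true(all(e$weight >= 1))
  # adjacency through igraph is symmetric with zero diagonal
  adj <- igraph::as_adjacency_matrix(as_igraph(net), attr = "weight",
                                     sparse = FALSE)
  expect_equal(adj, t(adj))
  expect_true(all(diag(adj) == 0))
  # kept-node frequencies sum to the matching term_frequencies restriction
  tf <- term_frequencies(toy_corpus())
  expect_equal(sum(net$nodes$weight),
               sum(tf$n[tf$term %in% net$nodes$term]))
  # edge weight cannot exceed either endpoint's per-unit presence count
  presence <- dplyr::distinct(tibble::as_tibble(toy_corpus()),
                              doc, unit, token) |>
    dplyr::count(token)
  for (i in seq_len(nrow(e))) {
    cap <- min(presence$n[presence$token %in% c(e$from[i], e$to[i])])
    expect_lte(e$weight[i], cap)
  }
})

test_that("top_n limits nodes and stopword filtering commutes with selection", {
  net1 <- build_cooccurrence(toy_corpus(), top_n = 1)
  expect_equal(net1$nodes$term, "service")
  expect_equal(nrow(net1$edges), 0)
  # filtering stopwords first equals dropping them from an unfiltered top set
  net_a <- build_cooccurrence(toy_corpus(), stopwords = "service", top_n = 2)
  tf <- term_frequencies(toy_corpus(), stopwords = "service")
  expect_equal(net_a$nodes$term, utils::head(tf$term, 2))
})

test_that("a planted hub dominates weighted degree", {
  corpus <- simulate_corpus(
    vocabulary = c("hub", paste0("w", 1:20)), hub_terms = "hub",
    n_documents = 4, units_per_document = 10, unit_length = 4, seed = 5)
  net <- build_cooccurrence(corpus, top_n = 10)
  deg <- weighted_degree(net)
  expect_equal(deg$term[1], "hub")
  expect_true(all(deg$degree[deg$term == "hub"] >=
                    deg$degree[deg$term != "hub"]))
})

test_that("network exports round-trip nodes, node weights, and edge weights", {
  net <- build_cooccurrence(toy_corpus(), top_n = 10)
  for (fmt in c("edgelist", "graphml")) {
    path <- withr::local_tempfile(
      fileext = if (fmt == "graphml") ".graphml" else ".csv")
    write_network(net, path, format = fmt)
    back <- read_network(path, format = fmt)
    expect_equal(back$nodes, net$nodes, info = fmt)
    expect_equal(back$edges, net$edges, info = fmt)
  }
  # empty network exports a header-only edge-list document
  empty <- build_cooccurrence(
    pmc_corpus(tibble::tibble(doc = character(), unit = integer(),
                              token = character())), top_n = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(empty, path, format = "edgelist")
  expect_length(readLines(path), 1)
})

test_that("corpus files read one unit per line with pluggable tokenization", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("service older service", "care  service", ""), path)
  corpus <- read_corpus(path)
  expect_equal(max(corpus$unit), 2) # empty line contributes no tokens
  expect_equal(sum(corpus$token == "service"), 3)
  upper <- read_corpus(path, tokenize = function(l) toupper(whitespace_tokenizer(l)))
  expect_true(all(grepl("^[A-Z]+$", upper$token)))
  expect_valid_error(pmc_corpus(tibble::tibble(doc = "d", unit = 1, token = "")))
})
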