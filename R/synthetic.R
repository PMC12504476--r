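#' Simulate a binary score table
#'
#' Draws every (policy, secondary variable) bit independently from a
#' Bernoulli distribution, emulating the statistical shape of a real
#' multi-input–output table. Success probabilities can be a single number,
#' one value per primary variable (broadcast to its secondaries), or one
#' value per secondary id (named, in schema order). Generation is fully
#' reproducible: the RNG is Mersenne-Twister, seeded from `seed`, and the
#' caller's RNG state is untouched.
#'
#' Real score tables show strong dependence between criteria (some are
#' satisfied by every policy); the generator deliberately models none of
#' it — every probability is a free parameter and draws are independent.
#'
#' @param schema a `pmc_schema`.
#' @param n_policies number of synthetic policies (>= 0); ids are
#'   `"S1"`..`"Sn"`.
#' @param prob Bernoulli probabilities in `[0, 1]`: length 1, one per
#'   primary, or one per secondary.
#' @param seed integer seed.
#' @return a `pmc_scores` tibble.
#' @examples
#' sim <- simulate_score_table(eldercare_schema(), 5, prob = 0.8, seed = 42)
#' pmc_evaluate(sim)
#' @export
simulate_score_table <- function(schema, n_policies, prob = 0.5, seed = 1) {
  if (any(prob < 0 | prob > 1)) {
    abort_invalid("probabilities must lie in [0, 1]", "generator spec")
  }
  if (n_policies < 0) abort_invalid("n_policies must be >= 0", "generator spec")
  n_sec <- nrow(schema)
  n_pri <- length(primary_ids(schema))
  p <- if (length(prob) == 1) {
    rep(prob, n_sec)
  } else if (length(prob) == n_pri) {
    rep(prob, schema_sizes(schema))
  } else if (length(prob) == n_sec) {
    if (!is.null(names(prob))) prob[schema$id] else prob
  } else {
    abort_invalid(sprintf(
      "prob must have length 1, %d (per primary) or %d (per secondary)",
      n_pri, n_sec), "generator spec")
  }
  # column-major fill: repeat each secondary's probability once per policy
  bits <- with_seed(seed, matrix(
    stats::rbinom(n_policies * n_sec, 1, rep(p, each = n_policies)),
    nrow = n_policies, ncol = n_sec))
  df <- tibble::as_tibble(stats::setNames(
    as.data.frame(bits, stringsAsFactors = FALSE), schema$id))
  df <- dplyr::bind_cols(
    tibble::tibble(policy = paste0("S", seq_len(n_policies))), df)
  pmc_score_table(df, schema)
}

#' Simulate a corpus with planted co-occurrence structure
#'
#' Generates documents of fixed-length token units. Every unit contains
#' every hub term plus `unit_length` tokens sampled uniformly (with
#' replacement) from the non-hub vocabulary. Because each hub co-occurs
#' with every other term in every unit where that term appears, hubs
#' dominate the weighted degree of the resulting co-occurrence network by
#' construction — a known ground truth for testing network code.
#'
#' @param vocabulary character vector of terms.
#' @param hub_terms subset of `vocabulary` planted into every unit.
#' @param n_documents,units_per_document corpus dimensions.
#' @param unit_length non-hub tokens drawn per unit.
#' @param seed integer seed (Mersenne-Twister; caller's RNG untouched).
#' @return a `pmc_corpus` tibble.
#' @export
simulate_corpus <- function(vocabulary, hub_terms = character(),
                            n_documents = 10, units_per_document = 20,
                            unit_length = 5, seed = 1) {
  if (!all(hub_terms %in% vocabulary)) {
    abort_invalid("hub_terms must be a subset of vocabulary", "generator spec")
  }
  if (n_documents > 0 && units_per_document > 0 && unit_length > 0 &&
      length(vocabulary) == 0) {
    abort_invalid("empty vocabulary with nonzero units", "generator spec")
  }
  filler <- setdiff(vocabulary, hub_terms)
  rows <- with_seed(seed, {
    purrr::list_rbind(purrr::map(seq_len(n_documents), function(d) {
      purrr::list_rbind(purrr::map(seq_len(units_per_document), function(u) {
        toks <- c(hub_terms,
                  if (length(filler) && unit_length > 0) {
                    sample(filler, unit_length, replace = TRUE)
                  })
        tibble::tibble(doc = paste0("doc", d), unit = u, token = toks)
      }))
    }))
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(doc = character(), unit = integer(),
                           token = character())
  }
  pmc_corpus(rows)
}
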