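#' Grade scales for PMC indices
#'
#' A grade scale is an ordered set of strictly increasing breakpoints and
#' one more label than breakpoints. Intervals are left-open/right-closed on
#' the breakpoints, applied to the two-decimal reported index: with the
#' default scale, `index <= 6.50` is "Weak applicability",
#' `6.50 < index <= 7.50` is "Focused", and `index > 7.50` is
#' "Reasonable and Complete".
#'
#' @param breakpoints increasing numeric thresholds.
#' @param labels grade names, one more than `breakpoints`.
#' @return a `pmc_grade_scale` object.
#' @export
pmc_grade_scale <- function(breakpoints = c(6.50, 7.50),
                            labels = c("Weak applicability", "Focused",
                                       "Reasonable and Complete")) {
  problems <- character()
  if (length(labels) != length(breakpoints) + 1) {
    problems <- c(problems, "labels must number one more than breakpoints")
  }
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    problems <- c(problems, "breakpoints must be strictly increasing")
  }
  if (length(problems)) abort_invalid(problems, "grade scale")
  structure(list(breakpoints = breakpoints, labels = labels),
            class = "pmc_grade_scale")
}

#' @export
print.pmc_grade_scale <- function(x, ...) {
  lo <- c("", sprintf("%.2f < ", x$breakpoints))
  hi <- c(sprintf("PMC <= %.2f", x$breakpoints), "PMC")
  hi[length(hi)] <- sprintf("PMC > %.2f", x$breakpoints[length(x$breakpoints)])
  cat("<pmc_grade_scale>\n")
  cat(sprintf("  %s%s: %s\n", lo[-length(lo)], hi[-length(hi)],
              x$labels[-length(x$labels)]), sep = "")
  cat(sprintf("  %s: %s\n", hi[length(hi)], x$labels[length(x$labels)]))
  invisible(x)
}

#' Classify PMC indices into grades
#'
#' @param pmc numeric vector of (reported, two-decimal) PMC indices.
#' @param scale a [pmc_grade_scale()].
#' @param max_index upper bound of the valid index range (the number of
#'   primary variables); indices outside `[0, max_index]` are an error.
#' @return character vector of grade labels.
#' @examples
#' pmc_classify(c(7.49, 6.23, 7.50, 9.00))
#' @export
pmc_classify <- function(pmc, scale = pmc_grade_scale(), max_index = 9) {
  if (any(pmc < 0 | pmc > max_index)) {
    abort_invalid(sprintf("PMC index %s outside [0, %s]",
                          pmc[pmc < 0 | pmc > max_index], max_index),
                  "PMC index")
  }
  idx <- findInterval(pmc, scale$breakpoints, left.open = TRUE) + 1L
  scale$labels[idx]
}

#' Primary-variable scores of each policy
#'
#' The score of primary variable i is the mean of its binary secondary
#' variables: the count of criteria the policy meets divided by the number
#' of criteria under that primary. In `"rounded2"` mode (the default, which
#' reproduces published PMC tables) each score is rounded half-up to two
#' decimals *before* any downstream use — summation, means, gap ordering.
#' `"exact"` mode keeps the raw fractions.
#'
#' @param scores a `pmc_scores` table.
#' @param policies policies to score; default all, in table order.
#' @param mode `"rounded2"` or `"exact"`.
#' @return a tibble with `policy` and one column per primary id (`X1`..`XP`).
#' @examples
#' pmc_primary_scores(eldercare_scores())
#' @export
pmc_primary_scores <- function(scores, policies = NULL,
                               mode = c("rounded2", "exact")) {
  mode <- match.arg(mode)
  schema <- attr(scores, "schema")
  if (is.null(policies)) policies <- scores$policy
  unknown <- setdiff(policies, scores$policy)
  if (length(unknown)) {
    abort_invalid(sprintf("unknown policy '%s'", unknown), "policy selection")
  }
  rows <- scores[match(policies, scores$policy), ]
  long <- tibble::as_tibble(rows) |>
    tidyr::pivot_longer(-"policy", names_to = "id", values_to = "bit") |>
    dplyr::left_join(tibble::as_tibble(schema)[c("id", "primary")], by = "id") |>
    dplyr::group_by(.data$policy, .data$primary) |>
    dplyr::summarise(score = mean(.data$bit), .groups = "drop")
  if (mode == "rounded2") long$score <- round_half_up(long$score, 2)
  long |>
    dplyr::mutate(primary = paste0("X", .data$primary)) |>
    tidyr::pivot_wider(names_from = "primary", values_from = "score") |>
    dplyr::arrange(match(.data$policy, policies))
}

#' Evaluate all policies of a score table
#'
#' Runs the full PMC pipeline: primary-variable scores, PMC index (the sum
#' of the primary scores, reported to two decimals), grade classification,
#' and ranking (rank 1 = highest index; ties keep input order).
#'
#' @inheritParams pmc_primary_scores
#' @param scale a [pmc_grade_scale()].
#' @return a `pmc_result` tibble with columns `policy`, `X1`..`XP`,
#'   `pmc_index`, `grade`, `rank`, carrying the schema, mode, and scale as
#'   attributes.
#' @examples
#' res <- pmc_evaluate(eldercare_scores())
#' res[c("policy", "pmc_index", "grade", "rank")]
#' @export
pmc_evaluate <- function(scores, mode = c("rounded2", "exact"),
                         scale = pmc_grade_scale()) {
  mode <- match.arg(mode)
  if (nrow(scores) == 0) {
    abort_invalid("score table has no policies", "evaluation input")
  }
  schema <- attr(scores, "schema")
  p <- length(primary_ids(schema))
  sv <- pmc_primary_scores(scores, mode = mode)
  idx <- round_half_up(rowSums(sv[primary_ids(schema)]), 2)
  out <- sv |>
    dplyr::mutate(
      pmc_index = idx,
      grade = pmc_classify(idx, scale, max_index = p),
      rank = rank(-idx, ties.method = "first"))
  tibble::new_tibble(out, schema = schema, mode = mode, scale = scale,
                     class = "pmc_result")
}

#' @export
print.pmc_result <- function(x, ...) {
  cat(sprintf("<pmc_result> %d policies, mode '%s'\n",
              nrow(x), attr(x, "mode")))
  NextMethod()
}

#' Cross-policy mean of each primary variable
#'
#' The mean, over policies, of each primary-variable score, reported to two
#' decimals (half-up). These means anchor the improvement-path gaps.
#'
#' @param result a `pmc_result` from [pmc_evaluate()].
#' @return a tibble with columns `primary` and `mean`.
#' @examples
#' pmc_variable_means(pmc_evaluate(eldercare_scores()))
#' @export
pmc_variable_means <- function(result) {
  if (nrow(result) == 0) abort_invalid("no policies", "result set")
  ids <- primary_ids(attr(result, "schema"))
  tibble::tibble(
    primary = ids,
    mean = unname(round_half_up(colMeans(result[ids]), 2)))
}

#' Mean PMC index of a policy subset
#'
#' The arithmetic mean of the reported (two-decimal) PMC indices of a
#' subset of policies — e.g. all provincial-level policies — reported to
#' two decimals.
#'
#' @param result a `pmc_result`.
#' @param policies policy identifiers to average over.
#' @return a single number.
#' @examples
#' pmc_group_mean(pmc_evaluate(eldercare_scores()), c("P3", "P4", "P5", "P6"))
#' @export
pmc_group_mean <- function(result, policies) {
  unknown <- setdiff(policies, result$policy)
  if (length(unknown) || length(policies) == 0) {
    abort_invalid(c(sprintf("unknown policy '%s'", unknown),
                    if (length(policies) == 0) "empty policy subset"),
                  "group-mean subset")
  }
  round_half_up(mean(result$pmc_index[match(policies, result$policy)]), 2)
}

#' Improvement paths
#'
#' For each policy, the primary variables scoring strictly below the
#' cross-policy mean, ordered by gap (mean minus score) from largest to
#' smallest: the suggested order in which to strengthen the policy. Equal
#' gaps are broken by ascending primary index, a deterministic documented
#' rule.
#'
#' @param result a `pmc_result`.
#' @param policies policies to build paths for; default all.
#' @param means per-primary means as from [pmc_variable_means()]; defaults
#'   to the means of `result` itself.
#' @return a tibble with columns `policy`, `step`, `primary`, `score`,
#'   `mean`, `gap`; policies at or above the mean everywhere contribute no
#'   rows.
#' @examples
#' res <- pmc_evaluate(eldercare_scores())
#' pmc_improvement_path(res, "P3")
#' @export
pmc_improvement_path <- function(result, policies = NULL,
                                 means = pmc_variable_means(result)) {
  if (is.null(policies)) policies <- result$policy
  unknown <- setdiff(policies, result$policy)
  if (length(unknown)) {
    abort_invalid(sprintf("unknown policy '%s'", unknown), "path selection")
  }
  ids <- primary_ids(attr(result, "schema"))
  result |>
    tibble::as_tibble() |>
    dplyr::filter(.data$policy %in% policies) |>
    dplyr::select("policy", dplyr::all_of(ids)) |>
    tidyr::pivot_longer(-"policy", names_to = "primary", values_to = "score") |>
    dplyr::left_join(means, by = "primary") |>
    dplyr::mutate(gap = round_half_up(.data$mean - .data$score, 2),
                  pidx = as.integer(sub("^X", "", .data$primary))) |>
    dplyr::filter(.data$score < .data$mean) |>
    dplyr::arrange(match(.data$policy, policies),
                   dplyr::desc(.data$gap), .data$pidx) |>
    dplyr::group_by(.data$policy) |>
    dplyr::mutate(step = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("policy", "step", "primary", "score", "mean", "gap")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PMC result into long form
#'
#' One row per (policy, primary variable) with the score and the policy's
#' index, grade, and rank repeated — convenient for ggplot2 and joins.
#'
#' @param x a `pmc_result`.
#' @param ... unused.
#' @return a long tibble with columns `policy`, `primary`, `score`,
#'   `pmc_index`, `grade`, `rank`.
#' @method tidy pmc_result
#' @export
tidy.pmc_result <- function(x, ...) {
  ids <- primary_ids(attr(x, "schema"))
  x |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(ids), names_to = "primary",
                        values_to = "score") |>
    dplyr::select("policy", "primary", "score", "pmc_index", "grade", "rank")
}

#' One-row summary of a PMC evaluation
#'
#' @param x a `pmc_result`.
#' @param ... unused.
#' @return a tibble with `n_policies`, `mean_index` (two decimals, half-up),
#'   `min_index`, `max_index`, and one `n_<grade>` count column per grade
#'   label of the scale.
#' @method glance pmc_result
#' @export
glance.pmc_result <- function(x, ...) {
  scale <- attr(x, "scale")
  counts <- table(factor(x$grade, levels = scale$labels))
  grade_cols <- stats::setNames(
    as.list(as.integer(counts)),
    paste0("n_", gsub("[^a-z0-9]+", "_", tolower(scale$labels))))
  tibble::tibble(
    n_policies = nrow(x),
    mean_index = round_half_up(mean(x$pmc_index), 2),
    min_index = min(x$pmc_index),
    max_index = max(x$pmc_index),
    !!!grade_cols)
}
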