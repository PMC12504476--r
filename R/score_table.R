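#' Binary score tables
#'
#' A score table (the "multi-input–output table" of the PMC model) records,
#' for each policy, one bit per secondary variable: 1 when the policy text
#' meets the criterion, 0 otherwise. In the package it is a tibble with a
#' `policy` column followed by one integer column per secondary id in schema
#' order, carrying the schema in the `"schema"` attribute.
#'
#' @param bits a data frame with a `policy` column and one 0/1 column per
#'   secondary id of `schema`.
#' @param schema the `pmc_schema` the bits are scored against.
#' @return a validated `pmc_scores` tibble.
#' @seealso [read_score_table()], [eldercare_scores()]
#' @export
pmc_score_table <- function(bits, schema) {
  bits <- tibble::as_tibble(bits)
  problems <- character()
  if (!"policy" %in% names(bits)) {
    abort_invalid("no 'policy' column", "score table")
  }
  missing_cols <- setdiff(schema$id, names(bits))
  if (length(missing_cols)) {
    problems <- c(problems, sprintf("missing secondary variable '%s'", missing_cols))
  }
  extra <- setdiff(names(bits), c("policy", schema$id))
  if (length(extra)) {
    problems <- c(problems,
                  sprintf("column '%s' is not a secondary id of the schema", extra))
  }
  dup <- unique(bits$policy[duplicated(bits$policy)])
  if (length(dup)) problems <- c(problems, sprintf("duplicate policy '%s'", dup))
  for (id in intersect(schema$id, names(bits))) {
    v <- bits[[id]]
    if (anyNA(v)) {
      problems <- c(problems, sprintf("missing cell(s) in '%s'", id))
    }
    bad <- stats::na.omit(v[!v %in% c(0, 1)])
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "non-binary value '%s' in '%s'", unique(as.character(bad)), id))
    }
  }
  if (length(problems)) abort_invalid(problems, "score table")
  out <- bits[c("policy", schema$id)]
  out$policy <- as.character(out$policy)
  out[schema$id] <- lapply(out[schema$id], as.integer)
  tibble::new_tibble(out, schema = schema, class = "pmc_scores")
}

#' @export
print.pmc_scores <- function(x, ...) {
  cat(sprintf("<pmc_scores> %d policies x %d secondary variables\n",
              nrow(x), nrow(attr(x, "schema"))))
  NextMethod()
}

#' Read a binary score table
#'
#' Three tabular dialects are supported:
#' \describe{
#'   \item{`"long"`}{CSV with columns `policy`, `id`, `value`; one row per
#'     (policy, secondary) bit. The canonical storage form.}
#'   \item{`"wide"`}{CSV with a `policy` column and one 0/1 column per
#'     secondary id.}
#'   \item{`"compact"`}{CSV mirroring the printed presentation of such
#'     tables: one row per primary variable, one column per policy, each cell
#'     a bitstring such as `"110"` whose characters follow the schema's
#'     secondary order within that primary.}
#'   \item{`"json"`}{an array of wide-shaped records, one object per policy.}
#' }
#'
#' @param path file to read.
#' @param schema the `pmc_schema` to validate against.
#' @param dialect one of `"long"`, `"wide"`, `"compact"`, `"json"`.
#' @return a validated `pmc_scores` tibble.
#' @examples
#' path <- system.file("extdata", "eldercare_scores_compact.csv",
#'                     package = "pmcindex")
#' scores <- read_score_table(path, eldercare_schema(), dialect = "compact")
#' @export
read_score_table <- function(path, schema,
                             dialect = c("long", "wide", "compact", "json")) {
  dialect <- match.arg(dialect)
  wide <- switch(dialect,
    long = {
      df <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
      df$value <- suppressWarnings(as.numeric(df$value))
      tidyr::pivot_wider(df, id_cols = "policy", names_from = "id",
                         values_from = "value")
    },
    wide = readr::read_csv(path, show_col_types = FALSE),
    compact = compact_to_wide(
      readr::read_csv(path, show_col_types = FALSE,
                      col_types = readr::cols(.default = readr::col_character())),
      schema),
    json = tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  )
  if (nrow(wide) == 0) {
    # a header-only long document pivots to no bit columns at all
    for (id in setdiff(schema$id, names(wide))) wide[[id]] <- integer()
  }
  pmc_score_table(wide, schema)
}

# The compact dialect is transposed (rows = primaries, columns = policies)
# and packs each primary's bits into one string.
compact_to_wide <- function(df, schema) {
  if (names(df)[1] != "primary") {
    abort_invalid("compact dialect needs a leading 'primary' column",
                  "score table")
  }
  long <- tidyr::pivot_longer(df, -"primary", names_to = "policy",
                              values_to = "bits")
  sizes <- stats::setNames(schema_sizes(schema), primary_ids(schema))
  bad_len <- long$bits[nchar(long$bits) != sizes[long$primary]]
  if (length(bad_len)) {
    abort_invalid(sprintf(
      "bitstring '%s' does not match its primary's secondary count", bad_len),
      "score table")
  }
  if (any(grepl("[^01]", long$bits))) {
    abort_invalid(sprintf(
      "non-binary bitstring '%s'", grep("[^01]", long$bits, value = TRUE)),
      "score table")
  }
  long |>
    dplyr::mutate(bit = stringr::str_split(.data$bits, "")) |>
    tidyr::unnest("bit") |>
    dplyr::mutate(
      pos = stats::ave(seq_len(dplyr::n()),
                       paste(.data$policy, .data$primary), FUN = seq_along),
      id = paste0(.data$primary, .data$pos),
      value = as.integer(.data$bit)) |>
    tidyr::pivot_wider(id_cols = "policy", names_from = "id",
                       values_from = "value") |>
    # restore the column order of the source file
    dplyr::arrange(match(.data$policy, names(df)[-1]))
}

#' Write a binary score table
#'
#' Round-trips losslessly with [read_score_table()] in every dialect.
#'
#' @param scores a `pmc_scores` table.
#' @param path output file.
#' @inheritParams read_score_table
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path,
                              dialect = c("long", "wide", "compact", "json")) {
  dialect <- match.arg(dialect)
  schema <- attr(scores, "schema")
  switch(dialect,
    long = {
      out <- tidyr::pivot_longer(tibble::as_tibble(scores), -"policy",
                                 names_to = "id", values_to = "value")
      readr::write_csv(out, path)
    },
    wide = readr::write_csv(tibble::as_tibble(scores), path),
    compact = {
      out <- tibble::as_tibble(scores) |>
        tidyr::pivot_longer(-"policy", names_to = "id", values_to = "value") |>
        dplyr::left_join(tibble::as_tibble(schema)[c("id", "primary")], by = "id") |>
        dplyr::group_by(.data$policy, .data$primary) |>
        dplyr::summarise(bits = paste(.data$value, collapse = ""),
                         .groups = "drop") |>
        dplyr::mutate(primary = paste0("X", .data$primary)) |>
        tidyr::pivot_wider(id_cols = "primary", names_from = "policy",
                           values_from = "bits")
      # preserve policy order
      out <- out[c("primary", intersect(scores$policy, names(out)))]
      readr::write_csv(out, path)
    },
    json = jsonlite::write_json(tibble::as_tibble(scores), path,
                                dataframe = "rows", auto_unbox = TRUE)
  )
  invisible(path)
}

#' The bundled 10-policy smart elder-care score table
#'
#' The complete binary multi-input–output table for the 10 bundled Chinese
#' smart older-adults-care policies (P1–P10): 330 bits scored against
#' [eldercare_schema()].
#'
#' @return a `pmc_scores` tibble with 10 rows and 33 bit columns.
#' @examples
#' scores <- eldercare_scores()
#' pmc_evaluate(scores)
#' @export
eldercare_scores <- function() {
  read_score_table(
    system.file("extdata", "eldercare_scores_compact.csv",
                package = "pmcindex", mustWork = TRUE),
    eldercare_schema(), dialect = "compact")
}

#' Metadata for the bundled policies
#'
#' Name, issuing organ, release date, and administrative level
#' (central/provincial/municipal) of the 10 bundled policies. Metadata is
#' annotation only: no computation except group means uses it.
#'
#' @return a tibble with columns `policy`, `name`, `organ`, `released`, `level`.
#' @export
eldercare_policies <- function() {
  readr::read_csv(
    system.file("extdata", "eldercare_policies.csv",
                package = "pmcindex", mustWork = TRUE),
    show_col_types = FALSE)
}
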