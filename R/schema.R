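#' Evaluation schemas
#'
#' A PMC evaluation schema is an ordered system of primary variables
#' (policy dimensions such as "Policy Nature" or "Policy Tool"), each holding
#' an ordered set of binary secondary variables with a yes/no criterion text.
#' Secondary variables under a primary are equally weighted by construction:
#' no weight field exists anywhere in the schema.
#'
#' Within the package a schema is a tibble with one row per secondary
#' variable and columns `primary` (1-based index of the parent dimension),
#' `primary_label`, `id` (e.g. `"X53"`), `label`, and `criterion`. The schema
#' name is kept in the `"name"` attribute. Secondary ids encode their parent:
#' `X<primary><position>`, e.g. `X53` is the 3rd criterion of primary 5.
#'
#' @param name schema name.
#' @param primaries list of primaries, each a list with fields `index`,
#'   `label`, and `secondaries` (a list of lists with `id`, `label`,
#'   `criterion`). This mirrors the YAML/JSON document layout accepted by
#'   [read_pmc_schema()].
#' @return a `pmc_schema` tibble.
#' @seealso [read_pmc_schema()], [eldercare_schema()]
#' @export
pmc_schema <- function(name, primaries) {
  rows <- purrr::list_rbind(purrr::map(primaries, function(p) {
    secs <- p$secondaries %||% list()
    tibble::tibble(
      primary = as.integer(p$index),
      primary_label = as.character(p$label %||% paste0("X", p$index)),
      id = purrr::map_chr(secs, ~ as.character(.x$id)),
      label = purrr::map_chr(secs, ~ as.character(.x$label %||% .x$id)),
      criterion = purrr::map_chr(secs, ~ as.character(.x$criterion %||% ""))
    )
  }))
  new_pmc_schema(rows, name = name, n_primaries = length(primaries))
}

new_pmc_schema <- function(rows, name, n_primaries) {
  schema <- tibble::new_tibble(rows, name = as.character(name),
                               class = "pmc_schema")
  validate_pmc_schema(schema, n_primaries = n_primaries)
  schema
}

# Enumerates every violation before aborting.
validate_pmc_schema <- function(schema, n_primaries = NULL) {
  problems <- character()
  declared <- unique(schema$primary)
  if (!is.null(n_primaries) && n_primaries > length(declared)) {
    empty <- setdiff(seq_len(n_primaries), declared)
    problems <- c(problems, sprintf(
      "primary variable %d has no secondary variables", empty))
  }
  dup <- unique(schema$id[duplicated(schema$id)])
  if (length(dup)) {
    problems <- c(problems, sprintf("duplicate secondary id '%s'", dup))
  }
  bad_pattern <- schema$id[!grepl("^X[0-9]+$", schema$id)]
  if (length(bad_pattern)) {
    problems <- c(problems, sprintf(
      "secondary id '%s' does not match the X<primary><position> pattern",
      bad_pattern))
  }
  # id must encode parent index + 1-based position within the parent
  ok <- grepl("^X[0-9]+$", schema$id)
  if (any(ok)) {
    expected <- paste0(
      "X", schema$primary,
      stats::ave(seq_along(schema$id), schema$primary, FUN = seq_along))
    mismatch <- which(ok & schema$id != expected)
    if (length(mismatch)) {
      problems <- c(problems, sprintf(
        "secondary id '%s' does not encode its position under primary %d (expected '%s')",
        schema$id[mismatch], schema$primary[mismatch], expected[mismatch]))
    }
  }
  if (length(problems)) abort_invalid(problems, "evaluation schema")
  invisible(schema)
}

#' @export
print.pmc_schema <- function(x, ...) {
  counts <- dplyr::count(tibble::as_tibble(x), .data$primary)
  cat(sprintf("<pmc_schema> '%s': %d primary / %d secondary variables\n",
              attr(x, "name"), nrow(counts), nrow(x)))
  NextMethod()
}

#' Read an evaluation schema from YAML or JSON
#'
#' The document layout is `{name, primaries: [{index, label, secondaries:
#' [{id, label, criterion}]}]}`. The format is chosen from the file
#' extension (`.yaml`/`.yml` vs `.json`); YAML is the default otherwise.
#' All validation failures (duplicate ids, empty primaries, malformed id
#' patterns) are reported together.
#'
#' @param path path to the schema document.
#' @return a `pmc_schema` tibble.
#' @export
read_pmc_schema <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$primaries)) {
    rlang::abort("schema document has no 'primaries' field",
                 class = "pmcindex_validation_error")
  }
  pmc_schema(doc$name %||% "unnamed", doc$primaries)
}

#' Write an evaluation schema to YAML or JSON
#'
#' Round-trips losslessly with [read_pmc_schema()].
#'
#' @param schema a `pmc_schema`.
#' @param path output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_pmc_schema <- function(schema, path) {
  doc <- list(
    name = attr(schema, "name"),
    primaries = schema |>
      tibble::as_tibble() |>
      dplyr::group_by(.data$primary, .data$primary_label) |>
      dplyr::group_map(function(rows, key) list(
        index = key$primary,
        label = key$primary_label,
        secondaries = purrr::pmap(
          rows[c("id", "label", "criterion")],
          function(id, label, criterion) {
            list(id = id, label = label, criterion = criterion)
          })
      ))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' The bundled smart older-adults-care evaluation schema
#'
#' The packaged indicator system for Chinese smart older-adults-care (smart
#' elder-care) policies: 9 primary variables — Policy Nature (X1), Policy
#' Area (X2), Policy Timeliness (X3), Policy Aim (X4), Policy Content (X5),
#' Policy Object (X6), Policy Evaluation (X7), Policy Measure (X8), Policy
#' Tool (X9) — holding 33 binary secondary variables
#' (3, 3, 3, 3, 5, 4, 3, 5, 4 per primary), each with its judgment criterion.
#'
#' @return a `pmc_schema` with 9 primaries and 33 secondaries.
#' @examples
#' sch <- eldercare_schema()
#' dplyr::count(sch, primary, primary_label)
#' @export
eldercare_schema <- function() {
  read_pmc_schema(
    system.file("extdata", "eldercare_schema.yaml", package = "pmcindex",
                mustWork = TRUE))
}

# Secondary counts per primary, in primary order.
schema_sizes <- function(schema) {
  tab <- table(schema$primary)
  as.integer(tab[order(as.integer(names(tab)))])
}

# Primary ids "X1".."XP" in order.
primary_ids <- function(schema) {
  paste0("X", sort(unique(schema$primary)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
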