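#' The 3x3 PMC surface matrix
#'
#' Arranges the nine primary-variable scores of one policy row-major into a
#' 3x3 matrix (row 1 = X1, X2, X3; row 2 = X4, X5, X6; row 3 = X7, X8, X9),
#' the arrangement rendered as a PMC surface. Flattening the matrix
#' row-major recovers X1..X9 exactly.
#'
#' @param x a `pmc_result` (with `policy` naming one of its rows) or a
#'   numeric vector of nine scores in `[0, 1]`.
#' @param policy the policy to extract when `x` is a `pmc_result`.
#' @return a 3x3 numeric matrix with `X1`..`X9` as cell dimnames helpers
#'   (`dimnames` give row/column position; use [pmc_concavity()] for a
#'   labelled tibble).
#' @examples
#' pmc_surface_matrix(pmc_evaluate(eldercare_scores()), "P1")
#' @export
pmc_surface_matrix <- function(x, policy = NULL) {
  v <- surface_scores(x, policy)
  matrix(v, nrow = 3, ncol = 3, byrow = TRUE,
         dimnames = list(paste0("row", 1:3), paste0("col", 1:3)))
}

surface_scores <- function(x, policy = NULL) {
  if (inherits(x, "pmc_result")) {
    ids <- primary_ids(attr(x, "schema"))
    if (length(ids) != 9) {
      abort_invalid(sprintf("surface matrix needs 9 primary variables, got %d",
                            length(ids)), "surface input")
    }
    if (is.null(policy) || !policy %in% x$policy) {
      abort_invalid(sprintf("unknown policy '%s'", policy %||% "<missing>"),
                    "surface input")
    }
    v <- as.numeric(x[x$policy == policy, ids][1, ])
  } else {
    v <- as.numeric(x)
  }
  if (length(v) != 9) {
    abort_invalid(sprintf("expected 9 scores, got %d", length(v)),
                  "surface input")
  }
  if (any(v < 0 | v > 1)) {
    abort_invalid("scores must lie in [0, 1]", "surface input")
  }
  v
}

#' Bilinear upsampling of a score grid
#'
#' Refines an m x n grid by bilinear interpolation to
#' `((m-1) * factor + 1)` x `((n-1) * factor + 1)` points. Bilinear
#' interpolation is a convex combination of the four surrounding corners,
#' so the upsampled grid never leaves `[min(m), max(m)]` of the input —
#' the rendered surface cannot overshoot the scores. `factor = 1` returns
#' the grid unchanged.
#'
#' @param m numeric matrix.
#' @param factor integer upsampling factor (>= 1).
#' @return the upsampled matrix.
#' @export
bilinear_upsample <- function(m, factor = 10) {
  stopifnot(is.matrix(m), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1) return(m)
  xs <- seq(1, nrow(m), length.out = (nrow(m) - 1) * factor + 1)
  ys <- seq(1, ncol(m), length.out = (ncol(m) - 1) * factor + 1)
  out <- matrix(0, length(xs), length(ys))
  for (a in seq_along(xs)) {
    x0 <- min(floor(xs[a]), nrow(m) - 1); fx <- xs[a] - x0
    for (b in seq_along(ys)) {
      y0 <- min(floor(ys[b]), ncol(m) - 1); fy <- ys[b] - y0
      out[a, b] <-
        m[x0, y0] * (1 - fx) * (1 - fy) + m[x0 + 1, y0] * fx * (1 - fy) +
        m[x0, y0 + 1] * (1 - fx) * fy + m[x0 + 1, y0 + 1] * fx * fy
    }
  }
  out
}

#' Concavity (depression) report of a surface matrix
#'
#' Quantifies the visual "concavity" reading of a PMC surface: the
#' depression of each cell is `1 - score`, the shortfall of that primary
#' variable from its maximum. Total depression over the nine cells equals
#' `9 - sum(scores)`. The deepest cell(s) mark where the policy is weakest.
#'
#' @inheritParams pmc_surface_matrix
#' @return a tibble with columns `primary`, `row`, `col`, `score`,
#'   `depression`, plus a `"deepest"` attribute holding the primary id(s)
#'   of maximal depression.
#' @examples
#' rep <- pmc_concavity(pmc_evaluate(eldercare_scores()), "P1")
#' attr(rep, "deepest")
#' @export
pmc_concavity <- function(x, policy = NULL) {
  v <- surface_scores(x, policy)
  out <- tibble::tibble(
    primary = paste0("X", 1:9),
    row = rep(1:3, each = 3),
    col = rep(1:3, times = 3),
    score = v,
    depression = 1 - v)
  attr(out, "deepest") <- out$primary[out$depression == max(out$depression)]
  out
}

#' Plot a PMC surface
#'
#' Renders the 3x3 surface matrix of one policy as a bilinearly upsampled
#' filled heatmap: depressions (low scores) show as dark basins. The look
#' is deterministic for fixed options.
#'
#' @param result a `pmc_result`.
#' @param policy which policy to plot.
#' @param upsample bilinear upsampling factor (1 = raw 3x3 grid).
#' @param colormap a viridis option name passed to
#'   [ggplot2::scale_fill_viridis_c()].
#' @return a ggplot object.
#' @export
plot_pmc_surface <- function(result, policy, upsample = 20,
                             colormap = "viridis") {
  m <- bilinear_upsample(pmc_surface_matrix(result, policy), upsample)
  grid <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  grid$score <- m[cbind(grid$row, grid$col)]
  labs <- tibble::tibble(
    primary = paste0("X", 1:9),
    row = (rep(1:3, each = 3) - 1) * (nrow(m) - 1) / 2 + 1,
    col = (rep(1:3, times = 3) - 1) * (ncol(m) - 1) / 2 + 1)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$score)) +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$primary),
                       color = "white", size = 3.4) +
    ggplot2::scale_fill_viridis_c(option = colormap, limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = sprintf("PMC surface: %s", policy), fill = "score",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Radar chart of primary-variable scores
#'
#' One closed nine-axis polygon per policy over axes X1..X9 with radial
#' range `[0, 1]` — the standard side-by-side comparison of policies on
#' every dimension at once.
#'
#' @param result a `pmc_result` with at least one policy.
#' @return a ggplot object.
#' @export
plot_pmc_radar <- function(result) {
  if (nrow(result) == 0) abort_invalid("no policies to plot", "radar input")
  ids <- primary_ids(attr(result, "schema"))
  long <- tidy(result) |>
    dplyr::mutate(axis = match(.data$primary, ids))
  closed <- dplyr::bind_rows(long, dplyr::mutate(
    dplyr::filter(long, .data$axis == 1), axis = length(ids) + 1))
  ggplot2::ggplot(closed, ggplot2::aes(x = .data$axis, y = .data$score,
                                       color = .data$policy,
                                       group = .data$policy)) +
    ggplot2::geom_path(linewidth = 0.5) +
    ggplot2::scale_x_continuous(breaks = seq_along(ids), labels = ids,
                                limits = c(1, length(ids) + 1)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = NULL, color = "policy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a PMC result as a radar chart
#'
#' @param object a `pmc_result`.
#' @param ... unused.
#' @return a ggplot object; see [plot_pmc_radar()].
#' @method autoplot pmc_result
#' @export
autoplot.pmc_result <- function(object, ...) plot_pmc_radar(object)

#' Render a plot to a raster file
#'
#' Thin deterministic wrapper over [ggplot2::ggsave()] with fixed size and
#' dpi so repeated renders of identical inputs are pixel-identical.
#'
#' @param plot a ggplot object.
#' @param path output file (`.png` or `.svg`).
#' @return `path`, invisibly.
#' @export
render_plot <- function(plot, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ggplot2::ggsave(path, plot, width = 6, height = 5, dpi = 120)
  invisible(path)
}
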