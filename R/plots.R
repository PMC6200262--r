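# ggplot2 displays for the fitted objects and spatial inputs.

#' Plot a log-log resource-area fit
#'
#' Scatter of ln(a/A) against ln(A) with the fitted line; the x-axis
#' intercept (where a = A) back-transforms to the minimum-area estimate.
#'
#' @param object A `rada_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rada_fit <- function(object, ...) {
  if (!object$defined) stop("cannot plot an undefined fit", call. = FALSE)
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$b, intercept = object$c,
                         linetype = 2) +
    ggplot2::labs(
      x = "ln A (core area, ha)",
      y = if (object$handling == "beta")
        sprintf("ln(%.3g + a/A)", object$beta) else "ln(a/A)",
      title = sprintf("category %s: r = %.2f, b = %.2f",
                      object$label, object$r, object$b)
    )
}

#' Plot a core-size scan
#'
#' The a/|b| ratio against core percentage, with the selected core marked.
#'
#' @param object A `rada_core_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rada_core_scan <- function(object, ...) {
  df <- object$scan[!is.na(object$scan$ratio), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$core_pct, y = .data$ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected, linetype = 3) +
    ggplot2::labs(x = "core %", y = "a / |b| (ha)",
                  title = sprintf("core scan: selected %g%%", object$selected))
}

#' Plot a randomization null distribution
#'
#' Replicate correlation distributions per category.
#'
#' @param object A `rada_null`.
#' @param observed Optional named vector of observed r values (names =
#'   category codes) drawn as vertical lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rada_null <- function(object, observed = NULL, ...) {
  df <- object$replicates[object$replicates$defined, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~code) +
    ggplot2::labs(x = "replicate r", y = "count",
                  title = sprintf("randomization null (%d replicates)",
                                  object$n_rand))
  if (!is.null(observed)) {
    od <- tibble::tibble(code = as.integer(names(observed)),
                         r = as.numeric(observed))
    p <- p + ggplot2::geom_vline(data = od,
                                 ggplot2::aes(xintercept = .data$r),
                                 linetype = 2)
  }
  p
}

#' Map patches and range outlines
#'
#' @param map A vector `categorical_map` (raster maps are drawn as tiles).
#' @param outlines Optional outline tibble to overlay.
#' @return A ggplot.
#' @export
plot_landscape <- function(map, outlines = NULL) {
  stopifnot(inherits(map, "categorical_map"))
  if (map$type == "vector") {
    df <- purrr::map_dfr(seq_len(nrow(map$patches)), function(i) {
      m <- map$patches$geometry[[i]]
      tibble::tibble(x = m[, 1], y = m[, 2], id = i,
                     code = factor(map$patches$code[i]))
    })
    p <- ggplot2::ggplot(df) +
      ggplot2::geom_polygon(ggplot2::aes(x = .data$x, y = .data$y,
                                         group = .data$id,
                                         fill = .data$code))
  } else {
    g <- map$grid
    df <- expand.grid(col = seq_len(ncol(g)), row = seq_len(nrow(g)))
    df$code <- factor(g[cbind(df$row, df$col)])
    df$x <- map$x0 + (df$col - 0.5) * map$pixel_size
    df$y <- map$y0 + (df$row - 0.5) * map$pixel_size
    p <- ggplot2::ggplot(df) +
      ggplot2::geom_tile(ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$code))
  }
  if (!is.null(outlines)) {
    od <- purrr::map_dfr(seq_len(nrow(outlines)), function(i) {
      purrr::map_dfr(seq_along(outlines$geometry[[i]]), function(k) {
        m <- outlines$geometry[[i]][[k]]
        tibble::tibble(x = m[, 1], y = m[, 2],
                       id = paste(outlines$animal_id[i], k))
      })
    })
    p <- p + ggplot2::geom_polygon(
      data = od,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
      fill = NA, colour = "black")
  }
  p + ggplot2::coord_equal() + ggplot2::labs(x = "x (m)", y = "y (m)")
}
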