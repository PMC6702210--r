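#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Eigenvalue summary of a reference PCA
#'
#' @param x A [reference_pca()] result.
#' @param ... Unused.
#' @return One-row tibble with the variance explained by each component.
#' @export
glance.ref_pca <- function(x, ...) {
  ev <- x$eigenvalues
  out <- as.list(ev / sum(ev))
  names(out) <- paste0("prop_var_PC", seq_along(ev))
  tibble::as_tibble(c(list(n_snps = length(x$snp_ids)), out))
}

#' Tidy the in-sample scores of a reference PCA
#'
#' @param x A [reference_pca()] result.
#' @param ... Unused.
#' @return The `scores` tibble (`sample`, `pop`, PC columns).
#' @export
tidy.ref_pca <- function(x, ...) x$scores

#' Plot a reference PCA with optional projected samples
#'
#' @param object A [reference_pca()] result.
#' @param projected Optional tibble from [lsq_project()] (optionally with a
#'   `group` column) drawn as larger points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ref_pca <- function(object, projected = NULL, ...) {
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pop), alpha = 0.6) +
    ggplot2::labs(colour = "reference") +
    ggplot2::theme_minimal()
  if (!is.null(projected)) {
    proj <- projected[projected$projected %in% TRUE, , drop = FALSE]
    if ("group" %in% names(proj)) {
      p <- p + ggplot2::geom_point(
        data = proj,
        ggplot2::aes(shape = .data$group), size = 3)
    } else {
      p <- p + ggplot2::geom_point(data = proj, shape = 17, size = 3)
    }
  }
  p
}

#' Plot a calibrated radiocarbon date
#'
#' Posterior density over calendar years with the HPD interval set shaded.
#'
#' @param object A [calibrate_c14()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibrated_date <- function(object, ...) {
  dens <- object$density
  in_hpd <- purrr::map_lgl(dens$year_ce, function(y) {
    any(y >= object$intervals$from &
          (y <= object$intervals$to | object$intervals$open_ended))
  })
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$year_ce, y = .data$density)) +
    ggplot2::geom_area(data = dens[in_hpd, ], fill = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "calendar year (CE)", y = "posterior density",
                  title = sprintf("%s: %.0f ± %.0f BP", object$sample,
                                  object$age_bp, object$sigma)) +
    ggplot2::theme_minimal()
}

#' Plot calibrated intervals for a set of samples
#'
#' Horizontal bars of the 95.4% intervals, ordered by midpoint; the
#' standard figure for judging depositional-event structure.
#'
#' @param intervals Tibble: `sample`, `from`, `to`, optional `open_ended`,
#'   optional `group` (colour).
#' @param recent_limit Bar end substituted for open-ended intervals.
#' @return A ggplot.
#' @export
plot_date_intervals <- function(intervals, recent_limit = 1950) {
  iv <- tibble::as_tibble(intervals)
  if (!"open_ended" %in% names(iv)) iv$open_ended <- is.na(iv$to)
  iv$to[iv$open_ended %in% TRUE | is.na(iv$to)] <- recent_limit
  iv$sample <- factor(iv$sample, levels = iv$sample[order((iv$from + iv$to) / 2)])
  p <- ggplot2::ggplot(iv, ggplot2::aes(y = .data$sample))
  if ("group" %in% names(iv)) {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(x = .data$from, xend = .data$to, yend = .data$sample,
                   colour = .data$group), linewidth = 2)
  } else {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(x = .data$from, xend = .data$to, yend = .data$sample),
      linewidth = 2)
  }
  p + ggplot2::labs(x = "calendar year (CE)", y = NULL) +
    ggplot2::theme_minimal()
}
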