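heat_scale <- function(limits, midpoint = 0) {
  # light-yellow = excess sharing, black = deficit, orange = neutral,
  # matching the conventions of comparative-mapping heat plots
  ggplot2::scale_fill_gradient2(low = "black", mid = "orange",
                                high = "lightyellow",
                                midpoint = midpoint, limits = limits)
}

#' Heat map of sharing discrepancy or intensity
#'
#' Renders region-pair matrices as tile plots. In `"discrepancy"` mode the
#' fill is the signed discrepancy `sign(O - E) * (O - E)^2 / E` of a
#' [sharing_test()]; in `"intensity"` mode it is the posterior mean
#' sharing intensity of a [fit_intensity_model()] fit. High values render
#' light, low values dark; neutral values (0 discrepancy, intensity 1) sit
#' at the orange midpoint.
#'
#' @param x A `sharing_test` or `intensity_fit` object.
#' @param mode `"discrepancy"` or `"intensity"` (default chosen from the
#'   object class).
#' @return A ggplot object.
#' @export
plot_sharing_heatmap <- function(x, mode = NULL) {
  if (inherits(x, "sharing_test")) {
    mode <- mode %||% "discrepancy"
    tab <- tidy(x)
  } else if (inherits(x, "intensity_fit")) {
    mode <- mode %||% "intensity"
    tab <- tidy(x)
  } else {
    stop("x must be a sharing_test or intensity_fit")
  }
  if (nrow(tab) == 0) stop("empty matrix")
  if (mode == "discrepancy") {
    if (!"D" %in% names(tab)) stop("discrepancy mode needs a sharing_test")
    tab$fill <- tab$sign * tab$D
    lab <- "signed\n(O-E)^2/E"
    mid <- 0
  } else {
    tab$fill <- tab$estimate
    lab <- "posterior\nmean gamma"
    mid <- 1
  }
  lim <- range(tab$fill)
  if (diff(lim) == 0) lim <- lim + c(-0.5, 0.5)  # constant-matrix fallback
  lim <- range(c(lim, 2 * mid - lim))  # symmetric about the neutral value
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$region2, y = .data$region1,
                                    fill = .data$fill)) +
    ggplot2::geom_tile() +
    heat_scale(lim, mid) +
    ggplot2::labs(x = "species 2 region", y = "species 1 region",
                  fill = lab) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sharing_test <- function(object, ...) {
  plot_sharing_heatmap(object, mode = "discrepancy")
}

#' @exportS3Method ggplot2::autoplot
autoplot.intensity_fit <- function(object, ...) {
  plot_sharing_heatmap(object, mode = "intensity")
}

#' Posterior density of the disruption summary z per arm
#'
#' Kernel-density curves (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth, fixed for reproducibility) of the per-arm posterior draws of
#' `z = lambda_diff * gamma_diff / L` on a shared axis. Degenerate
#' (constant) samples fall back to a vertical line.
#'
#' @param rank_tbl Output of [rank_disruption()] (carries the draws), or a
#'   named list of numeric `z` sample vectors.
#' @return A ggplot object.
#' @export
plot_disruption_density <- function(rank_tbl) {
  zs <- if (is.list(rank_tbl) && !is.data.frame(rank_tbl)) rank_tbl
        else attr(rank_tbl, "z_samples")
  if (is.null(zs)) stop("no z samples attached")
  if (any(vapply(zs, length, 0L) < 2)) stop("need >= 2 samples per arm")
  dens <- purrr::imap_dfr(zs, function(x, arm) {
    if (stats::sd(x) == 0) {
      return(tibble::tibble(arm = arm, z = x[1], density = NA_real_,
                            degenerate = TRUE))
    }
    d <- density(x, bw = "nrd0")
    tibble::tibble(arm = arm, z = d$x, density = d$y, degenerate = FALSE)
  })
  p <- ggplot2::ggplot()
  solid <- dens[!dens$degenerate, ]
  if (nrow(solid) > 0) {
    p <- p + ggplot2::geom_line(
      data = solid,
      ggplot2::aes(x = .data$z, y = .data$density, colour = .data$arm))
  }
  deg <- dens[dens$degenerate, ]
  if (nrow(deg) > 0) {
    p <- p + ggplot2::geom_vline(
      data = deg,
      ggplot2::aes(xintercept = .data$z, colour = .data$arm),
      linetype = "dashed")
  }
  p + ggplot2::labs(x = "z = lambda_diff * gamma_diff / L",
                    y = "posterior density") +
    ggplot2::theme_minimal()
}
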