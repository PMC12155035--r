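#' Scatter plot of two spectral components
#'
#' @param object A [spectral_basis].
#' @param dims Length-2 integer: which components to plot.
#' @param labels Optional deme labels (`sample_id`, `row`, `col`) used to
#'   colour points by deme of origin.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_basis <- function(object, dims = c(1, 2), labels = NULL,
                                    ...) {
  df <- tidy(object)
  xn <- paste0("SPC", dims[1])
  yn <- paste0("SPC", dims[2])
  if (!is.null(labels)) {
    df <- left_join(df, labels, by = "sample_id")
    df$deme <- factor(paste0(df$row, "_", df$col))
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data[[xn]], y = .data[[yn]], colour = .data$deme
    ))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xn]], y = .data[[yn]]))
  }
  p + ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = xn, y = yn) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of association p-values
#'
#' Observed versus expected `-log10(p)` under the uniform null, with the
#' genomic inflation factor in the subtitle.
#'
#' @param res A [gwas_linear()] result (or a list of them, named by model).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_gwas_qq <- function(res, ...) {
  if (inherits(res, "gwas_result")) res <- list(model = res)
  df <- purrr::map_dfr(names(res), function(nm) {
    p <- sort(res[[nm]]$p[!res[[nm]]$monomorphic])
    m <- length(p)
    tibble(
      model = nm,
      expected = -log10(stats::ppoints(m)),
      observed = -log10(p)
    )
  })
  lambdas <- purrr::map_chr(names(res), function(nm) {
    sprintf("%s: lambda = %.3f", nm,
            genomic_inflation(res[[nm]], n_boot = 10)$lambda)
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$expected, y = .data$observed, colour = .data$model
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = paste(lambdas, collapse = "; ")
    ) +
    ggplot2::theme_minimal()
}

#' Eigenvalue scree plot of a spectral basis
#'
#' @param basis A [spectral_basis].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(basis) {
  df <- tibble(component = seq_along(basis$eigenvalues),
               eigenvalue = basis$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "component", y = "eigenvalue of L_sym") +
    ggplot2::theme_minimal()
}
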