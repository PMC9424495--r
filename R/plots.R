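# ggplot2 views of the main result types.

#' @rdname autoplot-thkinetics
#' @export
autoplot.th_volcano <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$correlation_index,
                                       y = .data$neg_log10_q,
                                       colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      "kinetic" = "grey60", "quantitative DEG" = "black", "qualitative DEG" = "red"
    )) +
    ggplot2::labs(x = "correlation index (1 - r)",
                  y = expression(-log[10] ~ FDR),
                  colour = NULL,
                  title = paste(attr(object, "pair"), collapse = " vs ")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-thkinetics
#' @export
autoplot.th_pca <- function(object, components = c(1, 2), ...) {
  cols <- paste0("PC", components)
  ev <- round(100 * object$explained_variance[components], 1)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[cols[1]]], y = .data[[cols[2]]],
                               colour = .data$time_h, shape = .data$condition)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = paste0(cols[1], " (", ev[1], "%)"),
                  y = paste0(cols[2], " (", ev[2], "%)"),
                  colour = "time (h)", shape = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-thkinetics
#' @export
autoplot.th_trajectories <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$delta_pc,
                                       colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "time (h)",
                  y = paste0("ΔPC", attr(object, "component"),
                             " vs ", attr(object, "reference")),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-thkinetics
#' @export
autoplot.th_clusters <- function(object, ...) {
  cen <- object$centroids
  df <- tibble::tibble(
    cluster = rep(rownames(cen), times = ncol(cen)),
    time_h = rep(as.numeric(colnames(cen)), each = nrow(cen)),
    value = as.vector(cen)
  )
  if (!is.null(object$archetypes)) {
    df$cluster <- object$archetypes$archetype[
      match(df$cluster, paste0("cluster_", object$archetypes$cluster))]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$value,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "time (h)", y = "mean log2 expression",
                  colour = "cluster",
                  title = paste0("Kinetic cluster centroids (", object$condition, ")")) +
    ggplot2::theme_minimal()
}

#' Plot methods for thkinetics result objects
#'
#' `autoplot()` methods returning ggplot objects: the correlation volcano
#' (`th_volcano`), the sample PCA (`th_pca`), PC-difference trajectories
#' (`th_trajectories`), cluster centroid curves (`th_clusters`) and the
#' hybrid coefficient plane (`th_hybrid_fits` / `th_hybrid_result`).
#'
#' @param object A result object.
#' @param components For `th_pca`, which two components to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name autoplot-thkinetics
NULL

#' @rdname autoplot-thkinetics
#' @export
autoplot.th_hybrid_fits <- function(object, ...) {
  df <- dplyr::filter(object, !.data$collinear)
  aes <- if ("category" %in% names(df)) {
    ggplot2::aes(x = .data$beta_th1, y = .data$beta_th2, colour = .data$category)
  } else {
    ggplot2::aes(x = .data$beta_th1, y = .data$beta_th2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(x = expression(beta[Th1]), y = expression(beta[Th2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-thkinetics
#' @export
autoplot.th_hybrid_result <- function(object, ...) {
  autoplot.th_hybrid_fits(object$fits, ...)
}
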