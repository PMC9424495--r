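# broom-style accessors for fitted result objects.

#' Tidy a hybrid decomposition result
#'
#' @param x A `th_hybrid_result` from [decompose_all()].
#' @param ... Ignored.
#' @return The per-gene fit/classification tibble.
#' @export
tidy.th_hybrid_result <- function(x, ...) {
  tibble::as_tibble(x$fits)
}

#' One-row summary of a hybrid decomposition
#'
#' @param x A `th_hybrid_result`.
#' @param ... Ignored.
#' @return One row: gene counts, target, alpha and the four category
#'   fractions in wide form.
#' @export
glance.th_hybrid_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::select(x$fractions, "category", "fraction"),
    names_from = "category", values_from = "fraction", names_prefix = "frac_"
  )
  dplyr::bind_cols(
    tibble::tibble(
      n_genes = nrow(x$fits), n_unfit = length(x$unfit),
      target = x$target, alpha = x$alpha
    ),
    wide
  )
}

#' Tidy PCA sample scores
#'
#' @param x A `th_pca` from [pca_timecourse()].
#' @param ... Ignored.
#' @return The annotated score tibble.
#' @export
tidy.th_pca <- function(x, ...) {
  tibble::as_tibble(x$scores)
}

#' One-row-per-component PCA summary
#'
#' @param x A `th_pca`.
#' @param ... Ignored.
#' @return Tibble with `component` and `explained_variance`.
#' @export
glance.th_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    explained_variance = x$explained_variance
  )
}

#' Tidy a cluster assignment
#'
#' @param x A `th_clusters` from [cluster_profiles()].
#' @param ... Ignored.
#' @return The assignment tibble (with archetypes when labeled).
#' @export
tidy.th_clusters <- function(x, ...) {
  tibble::as_tibble(x$assignment)
}
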