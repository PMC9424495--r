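#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, m, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `m` are annotated. Computed via the
#' log-space distribution function for numerical stability.
#'
#' @param k Observed overlap.
#' @param m Annotated (in-set) genes in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The upper-tail p-value.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_upper_tail <- function(k, m, n, N) {
  if (any(k < 0) || any(k > pmin(m, n)) || any(m > N) || any(n > N)) {
    abort("Require 0 <= k <= min(m, n) <= N.")
  }
  exp(phyper(k - 1, m, N - m, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests each gene set for overlap with a query list against a universe of
#' expressed genes. Sets are first intersected with the universe; the size
#' filter (`[min_size, max_size]`, defaults 3 and 1000) applies to the
#' within-universe sizes since those are the `m` entering the test. P-values
#' are Benjamini-Hochberg corrected across all tested sets pooled over
#' sources, and significance is called at `q < fdr` (default 0.1).
#'
#' @param query Character vector of genes of interest. Genes outside the
#'   universe are dropped with a warning.
#' @param universe Character vector of background (expressed) genes.
#' @param sets Gene-set collection from [read_gmt()] (rows with list-column
#'   `genes`).
#' @param min_size,max_size Within-universe set-size bounds.
#' @param fdr FDR level for the `significant` flag.
#' @return Tibble sorted by q-value: `set_name`, `source`, `k`, `m`, `n`,
#'   `N`, `p_value`, `q_value`, `significant`, and list-column `overlap`.
#' @export
run_ora <- function(query, universe, sets, min_size = 3L, max_size = 1000L,
                    fdr = 0.1) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` is empty.")
  if (length(query) == 0) abort("`query` is empty.")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " query gene(s) outside the universe were dropped."))
    query <- intersect(query, universe)
    if (length(query) == 0) abort("No query genes remain inside the universe.")
  }
  members <- lapply(sets$genes, intersect, y = universe)
  m <- lengths(members)
  keep <- m >= min_size & m <= max_size
  if (!any(keep)) {
    return(tibble::tibble(
      set_name = character(), source = character(), k = integer(),
      m = integer(), n = integer(), N = integer(), p_value = numeric(),
      q_value = numeric(), significant = logical(), overlap = list()
    ))
  }
  members <- members[keep]
  overlap <- lapply(members, intersect, y = query)
  k <- lengths(overlap)
  n <- length(query)
  N <- length(universe)
  p <- hypergeom_upper_tail(k, m[keep], n, N)
  out <- tibble::tibble(
    set_name = sets$set_name[keep], source = sets$source[keep],
    k = k, m = m[keep], n = n, N = N,
    p_value = p, q_value = benjamini_hochberg(p),
    overlap = overlap
  )
  out$significant <- out$q_value < fdr
  dplyr::arrange(out, .data$q_value, .data$p_value, .data$set_name)
}
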