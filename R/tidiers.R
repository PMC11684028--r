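# broom-style verbs for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fragment clustering
#'
#' @param x A `cki_hclust` from [hierarchical_cluster()] or
#'   [cluster_fragments()].
#' @param ... Unused.
#' @return Tibble with one row per clustered item: `item`, `cluster`
#'   (and `count` when multiplicities were supplied).
#' @export
tidy.cki_hclust <- function(x, ...) {
  as_tibble(x$labels)
}

#' One-row summary of a fragment clustering
#'
#' @param x A `cki_hclust`.
#' @param ... Unused.
#' @return Tibble with `n`, `k`, `n_merges`, `max_height`,
#'   `cut_height` (height of the last merge kept at the current cut).
#' @export
glance.cki_hclust <- function(x, ...) {
  h <- x$merges$height
  kept <- x$n - x$k
  tibble(
    n = x$n,
    k = x$k,
    n_merges = length(h),
    max_height = if (length(h)) max(h) else NA_real_,
    cut_height = if (kept >= 1) h[kept] else NA_real_
  )
}

#' Tidy a density summary
#'
#' @param x A `cki_density` from [density_summary()].
#' @param ... Unused.
#' @return The one-row summary tibble.
#' @export
tidy.cki_density <- function(x, ...) {
  as_tibble(unclass(x)[c("min", "max", "mode", "mean", "n")])
}
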