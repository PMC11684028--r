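# Structural clustering of adjacent fragments: Morgan fingerprints,
# pairwise cosine similarity, and average-linkage agglomeration on the
# derived dissimilarity 1 - similarity.

#' Morgan fingerprints of fragments
#'
#' Circular (Morgan) fingerprints, radius 2, folded to 2048 bits:
#' deterministic binary vectors where identical SMILES give identical
#' rows.
#'
#' @param smiles Character vector of SMILES, or a data frame with a
#'   `smiles` or `fragment_smiles_clean` column.
#' @param radius Circular radius (default 2).
#' @param n_bits Folded length (default 2048).
#' @return Integer 0/1 matrix, one row per input, `rownames` = SMILES.
#' @export
morgan_fingerprints <- function(smiles, radius = 2L, n_bits = 2048L) {
  if (is.data.frame(smiles)) {
    smiles <- smiles[["fragment_smiles_clean"]] %||% smiles[["smiles"]]
  }
  stopifnot(is.character(smiles), length(smiles) > 0)
  res <- chem_backend("morgan", list(
    smiles = as.list(smiles), radius = radius, n_bits = n_bits
  ))$results
  bad <- smiles[!map_lgl(res, ~ isTRUE(.x$ok))]
  if (length(bad) > 0) {
    abort(sprintf(
      "unparseable SMILES for fingerprinting: %s",
      paste(unique(bad), collapse = ", ")
    ))
  }
  fp <- matrix(0L, nrow = length(smiles), ncol = n_bits, dimnames = list(smiles, NULL))
  for (i in seq_along(res)) {
    bits <- as.integer(unlist(res[[i]]$bits))
    fp[i, bits + 1L] <- 1L
  }
  fp
}

#' Pairwise cosine similarity of fingerprint rows
#'
#' For binary vectors this equals `|A n B| / sqrt(|A| * |B|)`. The
#' result is symmetric with unit diagonal; all-zero rows have no
#' defined cosine and raise an error.
#'
#' @param fp Fingerprint matrix ([morgan_fingerprints()]).
#' @return Symmetric similarity matrix in `[0, 1]`.
#' @export
cosine_similarity <- function(fp) {
  fp <- as.matrix(fp)
  norms <- sqrt(rowSums(fp^2))
  if (any(norms == 0)) {
    abort("cosine similarity undefined for all-zero fingerprint row(s)")
  }
  s <- tcrossprod(fp / norms)
  s[s > 1] <- 1
  s[s < 0] <- 0
  diag(s) <- 1
  s
}

#' Average-linkage hierarchical clustering of a similarity matrix
#'
#' Agglomerates on the dissimilarity `1 - similarity` with
#' average-linkage (UPGMA) updates. Candidate merges within `1e-12` of
#' the minimal height are treated as tied (exact ties are common for
#' binary-fingerprint cosines) and break deterministically on the
#' lowest slot pair `(i, j)`, where each cluster's slot is the smallest
#' original item index it contains; reruns are therefore
#' byte-identical.
#'
#' @param sim Symmetric similarity matrix, e.g. [cosine_similarity()].
#' @param k Number of clusters to cut (default 7).
#' @return An object of class `cki_hclust`: list with `labels` (tibble
#'   `item`, `cluster`), `merges` (tibble `step`, `cluster_a`,
#'   `cluster_b`, `height`, negative values denoting singletons as in
#'   [stats::hclust()]), `heights`, `k` and `n`. Re-cut at any k with
#'   [cut_clusters()].
#' @export
hierarchical_cluster <- function(sim, k = 7L) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  stopifnot(n >= 1, ncol(sim) == n)
  if (k > n) {
    abort(sprintf("k = %d exceeds the number of items (%d)", k, n))
  }
  items <- rownames(sim) %||% as.character(seq_len(n))
  d <- 1 - sim
  diag(d) <- Inf
  size <- rep(1L, n)
  alive <- rep(TRUE, n)
  # hclust-style merge encoding: negative = singleton, positive = step
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(max(n - 1L, 0L))
  member <- as.list(seq_len(n))
  assign_steps <- vector("list", max(n - 1L, 0L))
  if (n > 1) {
    for (step in seq_len(n - 1L)) {
      dm <- d
      dm[!alive, ] <- Inf
      dm[, !alive] <- Inf
      dm[lower.tri(dm, diag = TRUE)] <- Inf
      best <- min(dm)
      # distances within 1e-12 of the minimum count as tied: exact ties
      # are common for binary-vector cosines and iterated linkage
      # updates only reproduce them to within rounding error
      cand <- which(dm <= best + 1e-12, arr.ind = TRUE)
      # lowest (i, j): smallest row index, then smallest column index
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      i <- cand[1, 1]
      j <- cand[1, 2]
      merge[step, ] <- c(code[i], code[j])
      height[step] <- best
      # Lance-Williams average-linkage update, stored in slot i
      upd <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
      d[i, ] <- upd
      d[, i] <- upd
      d[i, i] <- Inf
      alive[j] <- FALSE
      size[i] <- size[i] + size[j]
      member[[i]] <- c(member[[i]], member[[j]])
      assign_steps[[step]] <- member[[i]]
      code[i] <- step
    }
  }
  out <- structure(
    list(
      items = items,
      merges = tibble(
        step = seq_len(max(n - 1L, 0L)),
        cluster_a = merge[, 1], cluster_b = merge[, 2],
        height = height
      ),
      members = assign_steps,
      n = n,
      k = as.integer(k)
    ),
    class = "cki_hclust"
  )
  out$labels <- cut_clusters(out, k)
  out
}

#' Cut a cluster tree at k clusters
#'
#' Undoes the last `k - 1` merges and labels the resulting groups
#' `1..k` in order of first item appearance (as [stats::cutree()]
#' does).
#'
#' @param x A `cki_hclust` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Tibble `item`, `cluster`.
#' @export
cut_clusters <- function(x, k) {
  stopifnot(inherits(x, "cki_hclust"))
  n <- x$n
  if (k < 1 || k > n) {
    abort(sprintf("k = %d outside 1..%d", k, n))
  }
  lab <- seq_len(n)
  n_merge <- n - k
  for (step in seq_len(n_merge)) {
    mem <- x$members[[step]]
    lab[mem] <- min(lab[mem])
  }
  relabel <- match(lab, unique(lab))
  tibble(item = x$items, cluster = relabel)
}

#' @export
print.cki_hclust <- function(x, ...) {
  cat(sprintf(
    "<cki_hclust> %d items, average linkage, cut at k = %d\n", x$n, x$k
  ))
  print(count(x$labels, .data$cluster))
  invisible(x)
}

#' Cluster the fragments of a library
#'
#' Fingerprints the unique fragments, computes cosine similarities and
#' cuts the average-linkage tree at `k` clusters (default 7). Duplicate
#' fragments are clustered once; their multiplicity is carried as a
#' weight column of the assignment.
#'
#' @param library A [build_fragment_library()] result, data frame with
#'   `fragment_smiles_clean` (and optionally `count`), or character
#'   vector of fragment SMILES.
#' @param k Number of clusters (default 7).
#' @param radius,n_bits Fingerprint parameters.
#' @return A `cki_hclust` whose `labels` also carry the `count` weight.
#' @export
cluster_fragments <- function(library, k = 7L, radius = 2L, n_bits = 2048L) {
  if (is.data.frame(library)) {
    frags <- library$fragment_smiles_clean
    weight <- library[["count"]] %||% rep(1L, length(frags))
  } else {
    frags <- library
    weight <- rep(1L, length(frags))
  }
  keep_first <- !duplicated(frags)
  frags <- frags[keep_first]
  weight <- weight[keep_first]
  fp <- morgan_fingerprints(frags, radius = radius, n_bits = n_bits)
  res <- hierarchical_cluster(cosine_similarity(fp), k = k)
  res$labels <- left_join(res$labels, tibble(item = frags, count = weight), by = "item")
  res
}
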