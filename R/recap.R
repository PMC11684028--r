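# RECAP decomposition: retrosynthetic fragmentation into a hierarchy of
# nodes, each a dummy-marked fragment of its parent.

#' Decompose molecules with the RECAP retrosynthetic rules
#'
#' Fragments each molecule along RECAP-cleavable bonds (amides, amines,
#' esters, ethers, aromatic couplings, ...) into a hierarchy: the root
#' is the whole molecule and children are the single-rule cleavage
#' products of their parent, recursively, down to leaves that no rule
#' cleaves further. A molecule with no cleavable bond yields a
#' root-only tree.
#'
#' Each node carries its fragment both dummy-marked (`*` attachment
#' points) and hydrogen-capped/canonicalised (`smiles_clean`), the
#' attachment count `n_dummies`, and — for leaves — the list-column
#' `placements`: the embeddings of the marked leaf back into the root
#' molecule (dummies acting as wildcards), each a list with 0-based
#' root atom indices `covered` (all mapped atoms) and `real` (mapped
#' atoms excluding the wildcard positions). Placements are what lets
#' the fragment-extraction step decide which leaf holds the warhead.
#'
#' @param smiles Character vector of SMILES (ideally canonical; atom
#'   indices in `placements` refer to the string as given), or a data
#'   frame with a `smiles` column.
#' @return A tibble of class `recap_tree`: `smiles` (input), `node_id`,
#'   `parent_id`, `depth`, `smiles_marked`, `smiles_clean`,
#'   `n_dummies`, `n_heavy`, `is_leaf`, `placements`.
#' @export
#' @examples
#' \dontrun{
#' recap_decompose("CC(=O)Nc1ccccc1")
#' }
recap_decompose <- function(smiles) {
  if (is.data.frame(smiles)) {
    smiles <- smiles$smiles
  }
  stopifnot(is.character(smiles))
  empty <- tibble(
    smiles = character(), node_id = integer(), parent_id = integer(),
    depth = integer(), smiles_marked = character(), smiles_clean = character(),
    n_dummies = integer(), n_heavy = integer(), is_leaf = logical(),
    placements = list()
  )
  if (length(smiles) == 0) {
    class(empty) <- c("recap_tree", class(empty))
    return(empty)
  }
  res <- chem_backend("recap", list(smiles = as.list(unique(smiles))))$results
  names(res) <- unique(smiles)
  rows <- imap(res, function(r, smi) {
    if (!isTRUE(r$ok)) {
      abort(sprintf("unparseable SMILES: %s", smi))
    }
    tibble(
      smiles = smi,
      node_id = map_int(r$nodes, ~ as.integer(.x$node_id)),
      parent_id = map_int(r$nodes, ~ as.integer(.x$parent_id %||% NA_integer_)),
      depth = map_int(r$nodes, ~ as.integer(.x$depth)),
      smiles_marked = map_chr(r$nodes, ~ .x$smiles),
      smiles_clean = map_chr(r$nodes, ~ .x$clean %||% NA_character_),
      n_dummies = map_int(r$nodes, ~ as.integer(.x$n_dummies)),
      n_heavy = map_int(r$nodes, ~ as.integer(.x$n_heavy)),
      is_leaf = map_lgl(r$nodes, ~ isTRUE(.x$is_leaf)),
      placements = map(r$nodes, function(n) {
        map(n$placements %||% list(), function(p) {
          list(
            covered = as.integer(unlist(p$covered)),
            real = as.integer(unlist(p$real))
          )
        })
      })
    )
  })
  out <- bind_rows(rows[smiles])
  class(out) <- c("recap_tree", class(out))
  out
}
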