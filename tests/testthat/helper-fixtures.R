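# Shared fixtures and independent oracles. Everything chemistry-heavy is
# built once per test run and memoised, so each file stays fast.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(fixture_env[[name]])) {
    fixture_env[[name]] <- builder()
  }
  fixture_env[[name]]
}

test_lib <- function() memo("lib", function() warhead_library())

# a small seeded batch shared across extraction/profiling/pipeline tests
test_batch <- function() {
  memo("batch", function() generate_cki_batch(40, seed = 101L, library = test_lib()))
}

test_hits <- function() {
  memo("hits", function() {
    extract_fragments(test_batch()$smiles, test_lib())
  })
}

# ---- independent oracles ------------------------------------------------

# priority resolution oracle: raw substructure placements straight from
# the RDKit worker, resolved by a plain loop kept independent of the
# package's implementation
oracle_resolved_ids <- function(smiles, lib) {
  raw <- ckifrags:::chem_backend("match", list(
    smiles = list(smiles),
    patterns = unname(purrr::pmap(lib[c("id", "smarts")], function(id, smarts) {
      list(id = id, smarts = smarts)
    }))
  ))$results[[1]]$matches
  if (length(raw) == 0) {
    return(integer(0))
  }
  prio <- setNames(lib$priority, as.character(lib$id))
  ids <- vapply(raw, function(m) as.integer(m$id), integer(1))
  atom_sets <- lapply(raw, function(m) as.integer(unlist(m$atoms)))
  ord <- order(prio[as.character(ids)], vapply(atom_sets, paste, "", collapse = ","))
  taken <- integer(0)
  out <- integer(0)
  for (i in ord) {
    if (length(intersect(atom_sets[[i]], taken)) == 0) {
      out <- c(out, ids[i])
      taken <- c(taken, atom_sets[[i]])
    }
  }
  sort(out)
}

# average-linkage oracle: cluster distances recomputed from scratch from
# the original dissimilarity at every step (no Lance-Williams update),
# merged cluster kept in the lower slot. Same documented tie rule as the
# implementation: distances within 1e-12 of the minimum are tied and the
# lowest (i, j) pair wins (the cluster list stays ordered by smallest
# original member, so list positions equal the implementation's slots).
oracle_average_linkage <- function(d, k) {
  n <- nrow(d)
  members <- lapply(seq_len(n), identity)
  while (length(members) > k) {
    m <- length(members)
    pair_d <- matrix(Inf, m, m)
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        pair_d[i, j] <- mean(d[members[[i]], members[[j]], drop = FALSE])
      }
    }
    best <- min(pair_d)
    hit <- which(pair_d <= best + 1e-12, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    bi <- hit[1, 1]
    bj <- hit[1, 2]
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
  }
  lab <- integer(n)
  for (c_id in seq_along(members)) lab[members[[c_id]]] <- c_id
  lab
}

# canonical form of a partition: label clusters by first appearance
canon_partition <- function(lab) match(lab, unique(lab))

# closed-form cosine for binary vectors via set operations on bit indices
oracle_cosine <- function(bits_a, bits_b) {
  length(intersect(bits_a, bits_b)) / sqrt(length(bits_a) * length(bits_b))
}

# KDE mode oracle: explicit Gaussian kernel sum over the same grid
# convention, written without stats::density
oracle_kde_mode <- function(x, h) {
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) sum(exp(-0.5 * ((g - x) / h)^2)), numeric(1))
  grid[which.max(dens)]
}

# deterministic random binary fingerprints for clustering tests
random_fp_matrix <- function(n, n_bits = 2048L, density = 0.04, seed = 1L) {
  set.seed(seed)
  m <- matrix(0L, n, n_bits)
  for (i in seq_len(n)) {
    on_bits <- sample.int(n_bits, size = max(1L, rpois(1, n_bits * density)))
    m[i, on_bits] <- 1L
  }
  rownames(m) <- sprintf("fp%03d", seq_len(n))
  m
}

write_activity_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}
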