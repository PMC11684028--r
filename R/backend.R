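# Bridge to the bundled RDKit batch worker (inst/python/chem_backend.py).
#
# Every chemistry primitive (SMILES parsing/canonicalisation, SMARTS
# substructure matching, RECAP decomposition, descriptors, Morgan
# fingerprints) is computed by one short-lived python process per batch;
# all R-side functions therefore accept vectors so that a whole data set
# costs a single process launch.

the <- new.env(parent = emptyenv())

#' Locate the python interpreter used for chemistry primitives
#'
#' Resolution order: `options(ckifrags.python=)`, the `CKIFRAGS_PYTHON`
#' environment variable, then `python3`/`python` on `PATH`. The choice is
#' cached for the session.
#'
#' @return Path to the interpreter.
#' @export
ckifrags_python <- function() {
  if (!is.null(the$python)) {
    return(the$python)
  }
  cand <- c(
    getOption("ckifrags.python", ""),
    Sys.getenv("CKIFRAGS_PYTHON", ""),
    Sys.which("python3"),
    Sys.which("python")
  )
  cand <- cand[nzchar(cand)]
  if (length(cand) == 0) {
    abort("no python interpreter found; set options(ckifrags.python=)")
  }
  the$python <- cand[[1]]
  the$python
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "ckifrags")
  if (!nzchar(path)) {
    abort("chem_backend.py not found; is ckifrags installed correctly?")
  }
  path
}

#' @noRd
chem_backend <- function(op, payload) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(
    ckifrags_python(),
    c(backend_script(), op, shQuote(infile), shQuote(outfile)),
    stdout = FALSE, stderr = ""
  )
  if (!identical(status, 0L)) {
    abort(sprintf("chemistry backend op '%s' failed (exit status %s)", op, status))
  }
  jsonlite::read_json(outfile)
}

#' Canonicalise SMILES, keeping the largest organic component
#'
#' Counterions and solvents are stripped by retaining the component with
#' the most heavy atoms (carbon-bearing components are preferred;
#' remaining ties break on the lexicographically smallest canonical
#' SMILES). Unparseable inputs yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param desalt Keep only the largest organic component (default `TRUE`).
#' @return A tibble with columns `smiles`, `canonical_smiles`, `n_heavy`,
#'   `ok`.
#' @export
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("C=CC(=O)Nc1ccccc1.Cl", "not-a-smiles"))
#' }
canonicalize_smiles <- function(smiles, desalt = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    return(tibble(
      smiles = character(), canonical_smiles = character(),
      n_heavy = integer(), ok = logical()
    ))
  }
  res <- chem_backend("canonical", list(smiles = as.list(smiles), desalt = desalt))$results
  tibble(
    smiles = smiles,
    canonical_smiles = map_chr(res, ~ .x$canonical %||% NA_character_),
    n_heavy = map_int(res, ~ as.integer(.x$n_heavy %||% NA_integer_)),
    ok = map_lgl(res, ~ isTRUE(.x$ok))
  )
}

#' @noRd
backend_match <- function(smiles, patterns) {
  chem_backend("match", list(
    smiles = as.list(smiles),
    patterns = unname(pmap(patterns[c("id", "smarts")], function(id, smarts) {
      list(id = id, smarts = smarts)
    }))
  ))$results
}

#' @noRd
backend_substruct <- function(query, target) {
  if (length(query) == 0) {
    return(logical(0))
  }
  res <- chem_backend("substruct", list(
    pairs = map2(query, target, ~ list(query = .x, target = .y))
  ))$results
  map_lgl(res, ~ isTRUE(.x$found))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
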