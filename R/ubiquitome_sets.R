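#' Two-set Venn counts
#'
#' Partition of the union of two key sets into unique-to-A, shared and
#' unique-to-B, with the member sets kept for downstream use.
#'
#' @param setA,setB Character vectors (deduplicated internally).
#' @return List with counts `unique_a`, `shared`, `unique_b` and member sets
#'   `members_a_only`, `members_shared`, `members_b_only`.
#' @examples
#' venn_counts(c("p1", "p2"), c("p2", "p3"))
#' @export
venn_counts <- function(setA, setB) {
  a <- unique(as.character(setA))
  b <- unique(as.character(setB))
  shared <- intersect(a, b)
  a_only <- setdiff(a, b)
  b_only <- setdiff(b, a)
  list(
    unique_a = length(a_only), shared = length(shared), unique_b = length(b_only),
    members_a_only = a_only, members_shared = shared, members_b_only = b_only
  )
}

#' Read a peptidoform observation table
#'
#' TSV with columns `sample`, `condition`, `mg132` (0/1) and `peptidoform`
#' (modified-peptide string in any supported dialect). Each row is normalized
#' to a peptidoform identity key.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `sample`, `condition`, `mg132`
#'   (logical) and `key`.
#' @export
read_ub_events <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "mg132", "peptidoform")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("read_ub_events: missing columns: ", paste(miss, collapse = ", "))
  data.frame(
    sample = as.character(tab$sample),
    condition = as.character(tab$condition),
    mg132 = as.integer(tab$mg132) == 1L,
    key = vapply(tab$peptidoform, function(s) peptidoform_key(parse_peptidoform(s)),
                 character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Peptidoform keys unique to one condition
#'
#' Keys observed in the target condition and strictly absent from the
#' reference condition, within the requested MG132 stratum. Presence/absence
#' only; no abundance tolerance.
#'
#' @param events `data.frame` with columns `condition`, `mg132` (logical) and
#'   `key` (see [read_ub_events()]).
#' @param target,reference Condition labels; both must occur in `events`.
#' @param require_mg132 If `TRUE` (default) only MG132-treated observations
#'   are considered; if `FALSE`, only untreated ones.
#' @return Character vector of peptidoform keys.
#' @export
unique_to_condition <- function(events, target, reference, require_mg132 = TRUE) {
  stopifnot(all(c("condition", "mg132", "key") %in% names(events)))
  known <- unique(events$condition)
  for (lab in c(target, reference)) {
    if (!lab %in% known) {
      stop("unique_to_condition: unknown condition label '", lab,
           "' (have: ", paste(known, collapse = ", "), ")")
    }
  }
  ev <- events[events$mg132 == isTRUE(require_mg132), , drop = FALSE]
  tgt <- unique(ev$key[ev$condition == target])
  ref <- unique(ev$key[ev$condition == reference])
  setdiff(tgt, ref)
}

#' Collapse peptidoform keys to protein IDs
#'
#' Union of protein IDs over all mapped loci of the given keys; each protein
#' is counted once, and ambiguous peptides contribute every matched protein.
#' Unmapped keys are counted and reported via the `"unmapped"` attribute, not
#' silently dropped.
#'
#' @param keys Character vector of peptidoform keys.
#' @param annotations Site map as returned by [map_keys_to_proteins()]
#'   (columns `key`, `protein_id`).
#' @return Character vector of protein IDs with attribute `unmapped`.
#' @export
collapse_to_proteins <- function(keys, annotations) {
  stopifnot(all(c("key", "protein_id") %in% names(annotations)))
  keys <- unique(as.character(keys))
  hit <- annotations[annotations$key %in% keys, , drop = FALSE]
  prot <- unique(hit$protein_id)
  attr(prot, "unmapped") <- setdiff(keys, unique(hit$key))
  prot
}

#' Hypergeometric overlap test for two protein sets
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap when `|candidates|` proteins are drawn from a universe containing
#' `|interactors|` successes. This is the enrichment test behind the
#' candidate-vs-interactor comparison.
#'
#' @param candidates,interactors Character vectors of protein IDs.
#' @param universe_size Universe size `N`; must be at least
#'   `|candidates U interactors|`. A sensible default is the number of
#'   proteins in the search FASTA.
#' @return List of class `"overlap_result"`: `n_universe`, `n_set_a`
#'   (candidates), `n_set_b` (interactors), `n_overlap`, `p_value` and the
#'   overlap members.
#' @export
interactor_overlap <- function(candidates, interactors, universe_size) {
  a <- unique(as.character(candidates))
  b <- unique(as.character(interactors))
  n_union <- length(union(a, b))
  universe_size <- as.integer(universe_size)
  if (is.na(universe_size) || universe_size < 1L) {
    stop("interactor_overlap: universe_size must be a positive integer")
  }
  if (universe_size < n_union) {
    stop("interactor_overlap: universe_size (", universe_size,
         ") smaller than |candidates U interactors| (", n_union, ")")
  }
  ov <- intersect(a, b)
  p <- hypergeom_upper(length(ov), length(b), length(a), universe_size)
  structure(
    list(
      n_universe = universe_size, n_set_a = length(a), n_set_b = length(b),
      n_overlap = length(ov), p_value = p, members_overlap = ov
    ),
    class = "overlap_result"
  )
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: `k` successes when drawing
#' `n` items without replacement from a universe of `N` containing `K`
#' successes.
#'
#' @param k Observed overlap.
#' @param K Number of successes in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= max(K, n))
  if (k <= max(0L, n + K - N)) return(1)  # at or below the minimum possible overlap
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> ", x$n_overlap, " of ", x$n_set_a, " candidates in ",
      x$n_set_b, " interactors (universe ", x$n_universe, "), p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
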