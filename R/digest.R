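#' Read a proteome from FASTA
#'
#' Plain-header FASTA; the protein ID is the first whitespace-delimited token
#' of each header. All residues are uppercased.
#'
#' @param path FASTA file.
#' @return Named character vector, ID -> amino-acid sequence.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("read_proteome: duplicate protein IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  validate_proteome(seqs)
  seqs
}

#' Write a proteome to FASTA
#' @param proteome Named character vector, ID -> sequence.
#' @param path Output file.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path, width = 60L) {
  validate_proteome(proteome)
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Validate a proteome container
#'
#' @param proteome Named character vector, ID -> uppercase amino-acid
#'   sequence (20-letter alphabet, `X` allowed).
#' @return `proteome`, invisibly; errors describe every violation found.
#' @export
validate_proteome <- function(proteome) {
  if (!is.character(proteome) || is.null(names(proteome)) || any(!nzchar(names(proteome)))) {
    stop("proteome must be a named character vector of sequences")
  }
  if (anyDuplicated(names(proteome))) {
    stop("proteome has duplicate IDs: ",
         paste(unique(names(proteome)[duplicated(names(proteome))]), collapse = ", "))
  }
  if (any(!nzchar(proteome))) {
    stop("empty sequence for: ", paste(names(proteome)[!nzchar(proteome)], collapse = ", "))
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", proteome)
  if (any(bad)) {
    stop("non amino-acid characters in: ", paste(names(proteome)[bad], collapse = ", "))
  }
  invisible(proteome)
}

# 1-based positions after which trypsin cleaves: C-terminal to K/R, suppressed
# when the next residue is P or when the K is diGly-modified (blocked).
.cleavage_points <- function(sequence, blocked_positions = integer()) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("tryptic_digest: empty sequence")
  pos <- which(chars %in% c("K", "R"))
  pos <- pos[pos < n]                      # protein C-terminus is not a cut
  pos <- pos[chars[pos + 1L] != "P"]       # no cleavage before proline
  setdiff(pos, as.integer(blocked_positions))
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K and R, suppressed before P and at blocked
#' (diGly-modified) lysines, and emits every peptide with `0..max_missed`
#' missed cleavages. With `max_missed = 0` and no blocked sites the emitted
#' peptides tile the protein exactly once.
#'
#' @param sequence Protein sequence string (or a single named element of a
#'   proteome vector).
#' @param max_missed Maximum number of internal missed cleavage sites
#'   (non-negative integer; default 1, the usual search-engine setting).
#' @param blocked_positions 1-based protein positions of modified K residues
#'   at which cleavage is suppressed. Must be K positions of the sequence.
#' @return `data.frame` with columns `peptide`, `start` (1-based protein
#'   position), `missed` (missed-cleavage count), ordered by `start` then
#'   `missed`.
#' @examples
#' tryptic_digest("AKRPKG", max_missed = 0)
#' @export
tryptic_digest <- function(sequence, max_missed = 1L, blocked_positions = integer()) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) stop("tryptic_digest: max_missed must be >= 0")
  n <- nchar(sequence)
  if (n == 0L) stop("tryptic_digest: empty sequence")
  blocked_positions <- as.integer(blocked_positions)
  if (length(blocked_positions)) {
    res <- substring(sequence, blocked_positions, blocked_positions)
    if (any(res != "K")) {
      stop("tryptic_digest: blocked positions must be K residues (offending: ",
           paste(blocked_positions[res != "K"], collapse = ", "), ")")
    }
  }
  cuts <- .cleavage_points(sequence, blocked_positions)
  # fragment boundaries: starts follow each cut; ends are cuts plus C-terminus
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  k <- length(starts)
  out_pep <- character()
  out_start <- integer()
  out_miss <- integer()
  for (i in seq_len(k)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > k) break
      out_pep <- c(out_pep, substr(sequence, starts[i], ends[j]))
      out_start <- c(out_start, starts[i])
      out_miss <- c(out_miss, m)
    }
  }
  data.frame(peptide = out_pep, start = out_start, missed = out_miss,
             stringsAsFactors = FALSE)
}

#' Map a peptidoform onto protein coordinates
#'
#' Exact substring search of the bare sequence against every protein in the
#' proteome. Each match locus yields one row per modified position, carrying
#' the 1-based protein residue position of the ubiquitinated lysine
#' (`site_pos = peptide_start + mod_position - 1`). A peptide matching more
#' than one locus (across or within proteins) is flagged `ambiguous`, never
#' dropped. An unmatched peptide yields zero rows.
#'
#' @param pf A [peptidoform()] (or a modified-peptide string, parsed on the
#'   fly).
#' @param proteome Named character vector, ID -> sequence.
#' @return `data.frame` with columns `protein_id`, `peptide_start`,
#'   `site_pos` (NA when the peptidoform carries no modification), `peptide`
#'   (bare sequence) and `ambiguous`.
#' @examples
#' map_peptide_to_protein(peptidoform("ACKD", 3), c(P1 = "AACKDE"))
#' @export
map_peptide_to_protein <- function(pf, proteome) {
  if (is.character(pf)) pf <- parse_peptidoform(pf)
  stopifnot(inherits(pf, "peptidoform"))
  validate_proteome(proteome)
  if (length(proteome) == 0L) stop("map_peptide_to_protein: empty proteome")
  hits_id <- character()
  hits_start <- integer()
  for (id in names(proteome)) {
    m <- gregexpr(pf$bare_sequence, proteome[[id]], fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      hits_id <- c(hits_id, rep(id, length(m)))
      hits_start <- c(hits_start, as.integer(m))
    }
  }
  ambiguous <- length(hits_start) > 1L
  nmod <- max(1L, length(pf$mod_positions))
  rows <- lapply(seq_along(hits_start), function(i) {
    sites <- if (length(pf$mod_positions)) {
      hits_start[i] + pf$mod_positions - 1L
    } else {
      NA_integer_
    }
    data.frame(
      protein_id = rep(hits_id[i], nmod),
      peptide_start = rep(hits_start[i], nmod),
      site_pos = sites,
      peptide = rep(pf$bare_sequence, nmod),
      ambiguous = rep(ambiguous, nmod),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), peptide_start = integer(),
               site_pos = integer(), peptide = character(),
               ambiguous = logical(), stringsAsFactors = FALSE)
  # every non-NA site must land on a K of the matched protein
  ok <- is.na(out$site_pos) |
    substring(proteome[out$protein_id], out$site_pos, out$site_pos) == "K"
  stopifnot(all(ok))
  out
}

#' Map many peptidoform keys at once
#'
#' Convenience wrapper: maps each key with [map_peptide_to_protein()] and
#' binds the results, keeping the key alongside. Unmapped keys are counted in
#' the `"unmapped"` attribute.
#'
#' @param keys Character vector of [peptidoform_key()] strings.
#' @param proteome Named character vector, ID -> sequence.
#' @return `data.frame` with a leading `key` column plus the columns of
#'   [map_peptide_to_protein()]; attribute `unmapped` holds keys with no
#'   match.
#' @export
map_keys_to_proteins <- function(keys, proteome) {
  keys <- unique(as.character(keys))
  pieces <- lapply(keys, function(k) {
    ann <- map_peptide_to_protein(peptidoform_from_key(k), proteome)
    if (nrow(ann)) cbind(key = k, ann, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(key = character(), protein_id = character(),
                      peptide_start = integer(), site_pos = integer(),
                      peptide = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "unmapped") <- setdiff(keys, out$key)
  out
}
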