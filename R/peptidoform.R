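#' Construct a peptidoform
#'
#' A peptidoform is a bare peptide sequence together with the exact set of
#' diGly-modified lysine positions within it (1-based). Two site-isomers of
#' the same sequence are distinct peptidoforms.
#'
#' @param bare_sequence Uppercase amino-acid string (no modification markup).
#' @param mod_positions Integer vector of 1-based positions into
#'   `bare_sequence`; every position must point at a `K` residue. May be empty
#'   (an unmodified peptide).
#' @param mod_tag Modification label; the diGly remnant `"GG"` is the only one
#'   used in this pipeline.
#' @return An object of class `"peptidoform"`: a list with fields
#'   `bare_sequence`, `mod_positions` (sorted, unique) and `mod_tag`.
#' @examples
#' peptidoform("LAPVYQKLLER", 7L)
#' @export
peptidoform <- function(bare_sequence, mod_positions = integer(), mod_tag = "GG") {
  stopifnot(is.character(bare_sequence), length(bare_sequence) == 1L)
  bare_sequence <- toupper(bare_sequence)
  if (nchar(bare_sequence) == 0L) {
    stop("peptidoform: empty bare sequence")
  }
  if (grepl("[^A-Z]", bare_sequence)) {
    stop("peptidoform: bare sequence contains non-letter characters: ", bare_sequence)
  }
  mod_positions <- sort(unique(as.integer(mod_positions)))
  n <- nchar(bare_sequence)
  if (length(mod_positions)) {
    if (any(mod_positions < 1L | mod_positions > n)) {
      stop("peptidoform: modification position outside peptide (length ", n, ")")
    }
    res <- substring(bare_sequence, mod_positions, mod_positions)
    bad <- mod_positions[res != "K"]
    if (length(bad)) {
      stop(
        "peptidoform: modification attached to non-K residue at position ",
        paste(bad, collapse = ", "), " of ", bare_sequence
      )
    }
  }
  structure(
    list(bare_sequence = bare_sequence, mod_positions = mod_positions, mod_tag = mod_tag),
    class = "peptidoform"
  )
}

# Dialect table: regex matching the marker that FOLLOWS a residue letter, one
# entry per supported notation. Extend here to accept a new search-engine style.
.pf_dialects <- list(
  gg = list(open = "[", rx = "^\\[gg\\]",  render = "[gg]"),
  gl = list(open = "(", rx = "^\\(gl\\)",  render = "(gl)"),
  ub = list(open = "^", rx = "^\\^ub\\^",  render = "^ub^")
)

#' Parse a modified-peptide string into a peptidoform
#'
#' Accepts the bracket dialects `"K[gg]"`, `"K(gl)"` and `"K^ub^"` used by
#' common diGly search-engine exports. All dialects of the same peptidoform
#' normalize to an identical object; the marker must follow a lysine.
#' Unknown bracketed tags and unbalanced brackets are errors, never ignored.
#'
#' @param text Modified-peptide string, e.g. `"LAPVYQK[gg]LLER"`.
#' @return A [peptidoform()].
#' @examples
#' parse_peptidoform("LAPVYQK[gg]LLER")
#' parse_peptidoform("GHTPLDLTCSTK^ub^VK")
#' @export
parse_peptidoform <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("parse_peptidoform: empty input")
  bare <- character()
  mods <- integer()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch %in% c("[", "(", "^")) {
      rest <- substr(text, i, n)
      hit <- NULL
      for (d in .pf_dialects) {
        if (d$open == ch && grepl(d$rx, rest)) { hit <- d; break }
      }
      if (is.null(hit)) {
        # distinguish an unknown tag from a dangling bracket
        close_ch <- c("[" = "]", "(" = ")", "^" = "^")[[ch]]
        close_at <- regexpr(close_ch, substr(text, i + 1L, n), fixed = TRUE)
        if (close_at < 0L) {
          stop("parse_peptidoform: unbalanced '", ch, "' at position ", i, " in ", text)
        }
        tag <- substr(text, i + 1L, i + close_at - 1L)
        stop("parse_peptidoform: unknown modification tag '", tag, "' in ", text)
      }
      if (length(bare) == 0L) {
        stop("parse_peptidoform: modification marker before any residue in ", text)
      }
      pos <- length(bare)
      if (bare[pos] != "K") {
        stop(
          "parse_peptidoform: modification attached to non-K residue '",
          bare[pos], "' at peptide position ", pos, " in ", text
        )
      }
      mods <- c(mods, pos)
      i <- i + nchar(hit$render)
    } else if (grepl("^[A-Za-z]$", ch)) {
      bare <- c(bare, toupper(ch))
      i <- i + 1L
    } else {
      stop("parse_peptidoform: unexpected character '", ch, "' at position ", i, " in ", text)
    }
  }
  peptidoform(paste(bare, collapse = ""), mods)
}

#' Render a peptidoform in a given dialect
#'
#' Inverse of [parse_peptidoform()]: `parse_peptidoform(render_peptidoform(pf, d))`
#' recovers `pf` for every supported dialect `d`.
#'
#' @param pf A [peptidoform()].
#' @param dialect One of `"gg"`, `"gl"`, `"ub"`.
#' @return Modified-peptide string.
#' @export
render_peptidoform <- function(pf, dialect = "gg") {
  stopifnot(inherits(pf, "peptidoform"))
  d <- .pf_dialects[[dialect]]
  if (is.null(d)) stop("render_peptidoform: unknown dialect '", dialect, "'")
  chars <- strsplit(pf$bare_sequence, "")[[1]]
  out <- chars
  out[pf$mod_positions] <- paste0(chars[pf$mod_positions], d$render)
  paste(out, collapse = "")
}

#' Canonical identity key of a peptidoform
#'
#' Bare sequence plus exact modified positions; used to deduplicate
#' ubiquitination events and to compare sets across conditions.
#'
#' @param pf A [peptidoform()].
#' @return A single string, e.g. `"LAPVYQKLLER@7"`.
#' @export
peptidoform_key <- function(pf) {
  stopifnot(inherits(pf, "peptidoform"))
  paste0(pf$bare_sequence, "@", paste(pf$mod_positions, collapse = "+"))
}

#' Recover a peptidoform from its identity key
#' @param key String produced by [peptidoform_key()].
#' @return A [peptidoform()].
#' @export
peptidoform_from_key <- function(key) {
  parts <- strsplit(key, "@", fixed = TRUE)[[1]]
  mods <- if (length(parts) < 2L || !nzchar(parts[2])) integer() else
    as.integer(strsplit(parts[2], "+", fixed = TRUE)[[1]])
  peptidoform(parts[1], mods)
}

#' @export
print.peptidoform <- function(x, ...) {
  cat("<peptidoform> ", render_peptidoform(x, "gg"), "\n", sep = "")
  invisible(x)
}

#' Peptide length histogram
#'
#' Tabulates bare-sequence lengths of a set of peptidoforms (or plain peptide
#' strings). Tryptic diGly peptides with one missed cleavage are expected to
#' fall mostly in the 7-31 residue band.
#'
#' @param pfs List of [peptidoform()] objects, or a character vector of
#'   peptide sequences.
#' @return A list with `counts` (named integer vector, length -> count),
#'   `min` and `max` (NA for empty input).
#' @export
peptide_length_summary <- function(pfs) {
  lens <- if (is.character(pfs)) {
    nchar(pfs)
  } else {
    vapply(pfs, function(p) {
      if (inherits(p, "peptidoform")) nchar(p$bare_sequence) else nchar(as.character(p))
    }, integer(1))
  }
  if (length(lens) == 0L) {
    return(list(counts = integer(), min = NA_integer_, max = NA_integer_))
  }
  tab <- table(lens)
  list(
    counts = stats::setNames(as.integer(tab), names(tab)),
    min = min(lens),
    max = max(lens)
  )
}
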