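#' Packaged site-mapping fixture proteome (synthetic stand-ins)
#'
#' Two synthetic stand-in sequences for the validated substrates TGFBI and
#' NFKB2, at the canonical lengths (683 and 900 residues). They are not the
#' real UniProt records (Q15582 / Q00653): the filler residues are random
#' tryptic-structured sequence, but the experimentally observed ubiquitinated
#' peptides LAPVYQKLLER, YGCEGPSHGGLPGASSEKGR and GHTPLDLTCSTKVK are embedded
#' at the published coordinates, so mapping them must recover the published
#' sites K676 (TGFBI) and K72 / K741 (NFKB2) by ordinary index arithmetic.
#'
#' @return Named character vector with elements `TGFBI` and `NFKB2`.
#' @export
load_site_fixture_proteome <- function() {
  path <- system.file("extdata", "synthetic_site_fixture.fasta",
                      package = "ubinom", mustWork = TRUE)
  read_proteome(path)
}
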