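# protein-change notation: short tokens like G12A, C303*, E2366fs

# the 20 standard one-letter amino-acid codes
AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a short protein-change token
#'
#' Parses compact substitution notation of the form `<ref><position><alt>`,
#' e.g. `"G12A"` (glycine 12 to alanine), `"C303*"` (cysteine 303 to a stop
#' codon) or `"E2366fs"` (frameshift at glutamate 2366). This is the notation
#' used by cancer mutation catalogues for amino-acid level matching; full
#' HGVS grammar (`p.Gly12Ala`, delins, extensions) is deliberately out of
#' scope.
#'
#' @param token character scalar, e.g. `"G12A"`.
#' @return A list with elements `aa_ref` (one-letter code), `aa_pos`
#'   (integer >= 1) and `aa_alt` (one-letter code, `"*"` for stop, `"fs"`
#'   for frameshift).
#' @details The reference amino acid must be one of the 20 standard
#'   one-letter codes and must differ from the alternate. Frameshift (`fs`)
#'   tokens parse, but downstream exact-change tier matching skips them;
#'   position-level matching still applies.
#' @examples
#' parse_protein_change("G12A")
#' parse_protein_change("C303*")
#' parse_protein_change("N642H")
#' @seealso [format_protein_change()] for the inverse.
#' @export
parse_protein_change <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token)) {
    stop_alltriage("protein-change token must be a single string",
                   "alltriage_parse_error")
  }
  m <- regexec("^([A-Z])([0-9]+)(fs|\\*|[A-Z])$", token)
  parts <- regmatches(token, m)[[1]]
  bad <- function(why) {
    stop_alltriage(sprintf("cannot parse protein change '%s': %s", token, why),
                   "alltriage_parse_error")
  }
  if (length(parts) != 4L) bad("expected <AA><digits><AA|*|fs>")
  aa_ref <- parts[2]
  aa_pos <- suppressWarnings(as.integer(parts[3]))
  aa_alt <- parts[4]
  if (!aa_ref %in% AA_CODES) bad(sprintf("'%s' is not an amino-acid code", aa_ref))
  if (is.na(aa_pos) || aa_pos < 1L) bad("position must be >= 1")
  if (!(aa_alt %in% AA_CODES || aa_alt %in% c("*", "fs"))) {
    bad(sprintf("'%s' is not an amino-acid code, '*' or 'fs'", aa_alt))
  }
  if (identical(aa_ref, aa_alt)) bad("reference and alternate are identical")
  list(aa_ref = aa_ref, aa_pos = aa_pos, aa_alt = aa_alt)
}

#' Format a protein change back to its short token
#'
#' @param aa_ref,aa_pos,aa_alt components as returned by
#'   [parse_protein_change()].
#' @return character scalar, e.g. `"G12A"`.
#' @export
format_protein_change <- function(aa_ref, aa_pos, aa_alt) {
  paste0(aa_ref, aa_pos, aa_alt)
}

# vectorised, lenient parse: returns a data.frame with NA components for
# tokens that do not parse (those variants keep the raw string and are
# excluded from tier matching)
parse_protein_changes <- function(tokens, warn = TRUE) {
  n <- length(tokens)
  out <- data.frame(aa_ref = rep(NA_character_, n),
                    aa_pos = rep(NA_integer_, n),
                    aa_alt = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  ok <- !is.na(tokens) & nzchar(tokens)
  for (i in which(ok)) {
    pv <- tryCatch(parse_protein_change(tokens[i]), error = function(e) NULL)
    if (is.null(pv)) {
      if (warn) {
        warning(sprintf("unparseable protein change '%s'; kept as raw string",
                        tokens[i]), call. = FALSE)
      }
    } else {
      out$aa_ref[i] <- pv$aa_ref
      out$aa_pos[i] <- pv$aa_pos
      out$aa_alt[i] <- pv$aa_alt
    }
  }
  out
}
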