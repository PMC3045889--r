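#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement; names are preserved.
#'
#' @param x Character vector of DNA sequences (IUPAC codes allowed).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("CATGAA")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# A valid tag: exactly 26 bases, uppercase ACGT, starting with the NlaIII
# anchor CATG.
is_valid_tag <- function(x) {
  grepl("^CATG[ACGT]{22}$", x)
}

assert_valid_tags <- function(x, what = "tag") {
  bad <- which(!is_valid_tag(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "%d %s(s) violate the 26 bp CATG-anchored tag invariant (first offender: '%s')",
      length(bad), what, x[bad[1]]
    ))
  }
  invisible(x)
}

iupac_ok <- function(x) grepl("^[ACGTRYSWKMBDHVN]*$", x)

# positions (1-based) at which two equal-length sequences differ
mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}
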