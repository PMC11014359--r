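#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over the A/C/G/T/N alphabet. Ns are
#' preserved. Applying it twice returns the input (involution), which the
#' read-orientation step relies on.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("AACGT", "NNAT"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

dna_alphabet_ok <- function(x) {
  !stringr::str_detect(x, "[^ACGTN]")
}

#' Random DNA strings
#'
#' @param n number of strings.
#' @param width string length.
#' @return character vector of `n` random A/C/G/T strings.
#' @keywords internal
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# mean Phred quality from an ASCII (offset 33) quality string
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}
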