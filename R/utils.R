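#' Reverse complement of a nucleotide string
#'
#' Vectorised over its argument. The alphabet is restricted to A/C/G/T/N;
#' case is preserved upward (output is uppercase).
#'
#' @param seq character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (length(seq) > 50L && !any(is.na(seq))) {
    ## bulk path through Biostrings
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(toupper(seq)))))
  }
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""),
         character(1))
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character scalar (ASCII-encoded qualities).
#' @param offset integer ASCII offset, 33 for standard Illumina 1.8+.
#' @return integer vector of Phred scores.
#' @export
phred_decode <- function(qual, offset = 33L) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - as.integer(offset)
}

#' Encode integer Phred scores as a quality string
#'
#' @param phred integer vector of Phred scores.
#' @param offset integer ASCII offset.
#' @return character scalar.
#' @export
phred_encode <- function(phred, offset = 33L) {
  if (length(phred) == 0L) return("")
  intToUtf8(as.integer(phred) + as.integer(offset))
}

## Seeded RNG scoped to a block; leaves the global RNG state untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Stop unless all conditions hold; messages name the failing condition.
stopifnot_named <- function(...) {
  conds <- list(...)
  nms <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) stop(nms[i], call. = FALSE)
  }
  invisible(TRUE)
}

## 1-based inclusive label used in figures/reports, e.g. "chr7:11021999-11030474".
## `start` is internal 0-based half-open.
span_label <- function(chrom, start0, end0) {
  sprintf("%s:%d-%d", chrom, start0 + 1L, end0)
}
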