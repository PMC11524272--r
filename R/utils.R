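#' @importFrom stats rbinom rnbinom rnorm rpois runif aov TukeyHSD p.adjust
#'   fisher.test dhyper sd cor setNames
#' @importFrom utils write.table read.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-precision rounding used for every reported percentage in the
#' package.  Unlike [base::round()] (banker's rounding), ties are rounded
#' away from zero, the convention used for printed genome-report ratios.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

DNA_BASES <- c("A", "C", "G", "T")

## integer codes 0..3 for A,C,G,T; NA for anything else
.base_code_table <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A") + 1L] <- 0L
  tab[utf8ToInt("C") + 1L] <- 1L
  tab[utf8ToInt("G") + 1L] <- 2L
  tab[utf8ToInt("T") + 1L] <- 3L
  tab[utf8ToInt("a") + 1L] <- 0L
  tab[utf8ToInt("c") + 1L] <- 1L
  tab[utf8ToInt("g") + 1L] <- 2L
  tab[utf8ToInt("t") + 1L] <- 3L
  tab
})

seq_to_codes <- function(seq) {
  .base_code_table[utf8ToInt(seq) + 1L]
}

codes_to_seq <- function(codes) {
  paste(DNA_BASES[codes + 1L], collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## coerce character/DNAStringSet input to a named character vector
as_seq_char <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    s <- as.character(sequences)
  } else if (methods::is(sequences, "DNAString")) {
    s <- stats::setNames(as.character(sequences), "seq1")
  } else {
    s <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(s) && is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  s
}

## GC fraction over unambiguous bases
gc_fraction <- function(seqs) {
  seqs <- as_seq_char(seqs)
  gc <- 0; acgt <- 0
  for (s in seqs) {
    codes <- seq_to_codes(s)
    codes <- codes[!is.na(codes)]
    gc <- gc + sum(codes == 1L | codes == 2L)
    acgt <- acgt + length(codes)
  }
  gc / acgt
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Write sequences to FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(as_seq_char(seqs))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
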