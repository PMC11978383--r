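#' Read a FASTA file into a DNAStringSet
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions to the first whitespace-delimited word, so sequences can
#' be addressed by name.
#'
#' @param path FASTA file (plain or gzip-compressed).
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#' @param x a named [Biostrings::DNAStringSet], or a named character
#'   vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# accept a DNAStringSet or a file path wherever a genome is needed
as_fasta <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(read_fasta(x))
  if (is.character(x) && !is.null(names(x))) return(Biostrings::DNAStringSet(x))
  stop("expected a DNAStringSet, a named character vector, or a FASTA path")
}

#' Fetch a genomic interval as a string
#'
#' @param fasta a [Biostrings::DNAStringSet] (or FASTA path / named
#'   character vector).
#' @param name sequence name.
#' @param start,end 0-based half-open interval on the forward strand.
#' @param strand `"+"` returns the forward substring, `"-"` its reverse
#'   complement.
#' @return A plain character string of `end - start` bases.
#' @export
fasta_fetch <- function(fasta, name, start, end, strand = "+") {
  fasta <- as_fasta(fasta)
  strand <- match.arg(strand, c("+", "-"))
  if (!name %in% names(fasta)) stop("sequence ", sQuote(name), " not in FASTA")
  n <- Biostrings::width(fasta)[match(name, names(fasta))]
  if (start < 0 || end > n || start >= end) {
    stop("interval [", start, ",", end, ") out of bounds for ",
         sQuote(name), " of length ", n)
  }
  s <- Biostrings::subseq(fasta[[name]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Lengths of the sequences in a genome
#' @param fasta see [fasta_fetch()].
#' @return Named numeric vector of sequence lengths.
#' @export
fasta_sizes <- function(fasta) {
  fasta <- as_fasta(fasta)
  stats::setNames(as.numeric(Biostrings::width(fasta)), names(fasta))
}
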