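#' Construct a genome from named chromosome sequences
#'
#' A genome is a named character vector of uppercase A/C/G/T chromosome
#' sequences. Sequences containing any other letter (including N) are
#' rejected at construction, so downstream codon arithmetic never has to
#' handle ambiguity codes.
#'
#' @param sequences Named character vector, one element per chromosome.
#' @return A validated named character vector of class `poolseg_genome`.
#' @export
#' @examples
#' genome(c(chrI = "ATGGAATAA"))
genome <- function(sequences) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("every chromosome sequence must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate chromosome names", call. = FALSE)
  }
  nm <- names(sequences)
  sequences <- toupper(as.character(sequences))
  names(sequences) <- nm
  if (any(nchar(sequences) == 0L)) {
    stop("chromosome sequences must be non-empty", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", sequences))) {
    stop("genome sequences are restricted to A/C/G/T", call. = FALSE)
  }
  structure(sequences, class = c("poolseg_genome", "character"))
}

#' @export
print.poolseg_genome <- function(x, ...) {
  cat("<poolseg_genome> ", length(x), " chromosome(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A [genome()] object.
#' @return A tibble with columns `chrom` and `length`.
#' @export
genome_lengths <- function(genome) {
  tibble::tibble(chrom = names(genome), length = nchar(unname(genome)))
}

#' Read or write a genome as FASTA
#'
#' Thin wrappers around Biostrings; sequences are validated on the way in.
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta()` returns a [genome()]; `write_genome_fasta()`
#'   returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  genome(stats::setNames(as.character(seqs), names(seqs)))
}

#' @rdname read_genome_fasta
#' @param genome A [genome()] object.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(genome)), path
  )
  invisible(path)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

subseq_chr <- function(genome, chrom, start, end) {
  substr(unclass(genome)[[chrom]], start, end)
}
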