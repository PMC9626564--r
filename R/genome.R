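#' Genome sequence with declared topology
#'
#' Light container for a single replicon: an identifier, its nucleotide
#' sequence and whether the molecule is circular (bacterial chromosomes,
#' plasmids) or linear (phage lambda, restriction fragments).
#'
#' @param id Character label, typically an accession such as "NC_000913.3".
#' @param sequence Nucleotide string; alphabet restricted to A, C, G, T, N.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `genome_sequence`.
#' @examples
#' g <- genome_sequence("toy", "AAACAGCTGAAA", "linear")
#' genome_length(g)
#' @export
genome_sequence <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("genome sequence must be non-empty")
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop("genome sequence contains non-ACGTN characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
  }
  structure(list(id = id, sequence = sequence, topology = topology),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s (%s), %s bp\n",
              x$id, x$topology, format(genome_length(x), big.mark = ",")))
  invisible(x)
}

#' @rdname genome_sequence
#' @param x A `genome_sequence`.
#' @export
genome_length <- function(x) nchar(x$sequence)

#' Read a genome from a FASTA file
#'
#' Each record becomes one `genome_sequence`. Topology cannot be encoded in
#' FASTA, so it is supplied by the caller (the default, circular, matches
#' bacterial chromosomes).
#'
#' @param path FASTA file.
#' @param topology Topology applied to every record.
#' @return A list of `genome_sequence` objects, named by record id
#'   (first whitespace-delimited token of the header).
#' @export
read_genome_fasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(ss), function(i) {
    genome_sequence(ids[i], as.character(ss[[i]]), topology)
  })
  names(out) <- ids
  out
}

## reverse complement for plain character vectors (IUPAC-aware)
revcomp_chr <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- NULL
  out
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}
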