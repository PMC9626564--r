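#' Locate restriction cut sites on a genome
#'
#' Scans both strands for the enzyme's IUPAC-degenerate recognition pattern
#' and returns the distinct 0-based coordinates immediately before which the
#' blunt cut falls, sorted ascending. On a circular genome, windows spanning
#' the origin are scanned by extending the sequence with its own first
#' `patlen - 1` bases and reducing coordinates modulo the genome length.
#' Overlapping recognition windows that imply the same coordinate are counted
#' once; overlapping windows implying different coordinates are counted
#' separately. Windows containing N in the genome never match.
#'
#' @param genome A [genome_sequence()].
#' @param enzyme A [recognition_site()].
#' @return Sorted integer vector of distinct 0-based cut coordinates.
#' @examples
#' g <- genome_sequence("toy", "AAACAGCTGAAA", "linear")
#' find_cut_sites(g, recognition_site("PvuII", "CAG^CTG"))  # 6
#' @export
find_cut_sites <- function(genome, enzyme) {
  stopifnot(inherits(genome, "genome_sequence"),
            inherits(enzyme, "recognition_site"))
  len <- genome_length(genome)
  patlen <- nchar(enzyme$pattern)
  if (patlen > len) return(integer(0))

  circular <- genome$topology == "circular"
  subject_chr <- if (circular) {
    paste0(genome$sequence, substr(genome$sequence, 1L, patlen - 1L))
  } else {
    genome$sequence
  }
  subject <- Biostrings::DNAString(subject_chr)

  match_starts <- function(pat) {
    m <- Biostrings::matchPattern(pat, subject, fixed = "subject")
    s <- BiocGenerics::start(m)
    if (circular) s <- s[s <= len]
    if (length(s)) {
      # genome Ns are hard-masked: a window touching one never matches
      win <- substring(subject_chr, s, s + patlen - 1L)
      s <- s[!grepl("N", win, fixed = TRUE)]
    }
    s
  }

  fwd <- match_starts(enzyme$pattern)
  cuts <- (fwd - 1L) + enzyme$cut_offset
  rc <- revcomp_chr(enzyme$pattern)
  if (!identical(rc, enzyme$pattern)) {
    rev <- match_starts(rc)
    cuts <- c(cuts, (rev - 1L) + (patlen - enzyme$cut_offset))
  }
  if (circular) {
    cuts <- cuts %% len
  } else {
    cuts <- cuts[cuts > 0L & cuts < len]
  }
  sort(unique(as.integer(cuts)))
}

#' Digest a genome into predicted restriction fragments
#'
#' Cuts the genome at every coordinate returned by [find_cut_sites()] and
#' inventories the fragments. A circular genome with n >= 1 cuts yields
#' exactly n fragments (the last wraps past the origin, represented with
#' `end > genome length` and interpreted modulo the genome length); a linear
#' genome with n cuts yields n + 1 fragments; with no cuts the whole genome
#' is returned as a single fragment. Fragment sequences concatenated in
#' genome order (with wrap) restore the genome.
#'
#' Each fragment carries the 3' terminal-base classes of its two blunt,
#' double-stranded ends (see [terminal_classes()]) and `copy_count = 1`;
#' use [collapse_unique()] to merge indistinguishable fragments.
#'
#' @inheritParams find_cut_sites
#' @return A `fragment_inventory`: a data.frame with columns `fragment_id`,
#'   `genome_id`, `start`, `end`, `length`, `sequence`, `end_bases_3p`,
#'   `end_dinucs_3p`, `copy_count`, plus attributes `genome_id`,
#'   `genome_length` and `topology`.
#' @export
digest <- function(genome, enzyme) {
  cuts <- find_cut_sites(genome, enzyme)
  len <- genome_length(genome)
  circular <- genome$topology == "circular"

  if (length(cuts) == 0L) {
    starts <- 0L; ends <- len
  } else if (circular) {
    starts <- cuts
    ends <- c(cuts[-1L], cuts[1L] + len)
  } else {
    starts <- c(0L, cuts)
    ends <- c(cuts, len)
  }
  doubled <- if (circular) paste0(genome$sequence, genome$sequence) else
    genome$sequence
  seqs <- substring(doubled, starts + 1L, ends)

  tc <- terminal_classes_chr(seqs)
  inv <- data.frame(
    fragment_id = sprintf("%s:%d-%d", genome$id, starts, ends),
    genome_id = genome$id,
    start = as.integer(starts),
    end = as.integer(ends),
    length = as.integer(ends - starts),
    sequence = seqs,
    end_bases_3p = tc$end_bases_3p,
    end_dinucs_3p = tc$end_dinucs_3p,
    copy_count = 1L,
    stringsAsFactors = FALSE
  )
  attr(inv, "genome_id") <- genome$id
  attr(inv, "genome_length") <- len
  attr(inv, "topology") <- genome$topology
  class(inv) <- c("fragment_inventory", "data.frame")
  inv
}

## vectorized terminal-class computation on fragment sequences
terminal_classes_chr <- function(seqs) {
  first <- substr(seqs, 1L, 1L)
  last <- substr(seqs, nchar(seqs), nchar(seqs))
  left <- unname(complement_base(first))   # 3' base of the bottom strand
  single <- ifelse(left <= last, paste0(left, last), paste0(last, left))
  n <- nchar(seqs)
  left2 <- revcomp_chr(substr(seqs, 1L, 2L))
  right2 <- substr(seqs, n - 1L, n)
  dinuc <- ifelse(n >= 2L,
                  ifelse(left2 <= right2, paste0(left2, "/", right2),
                         paste0(right2, "/", left2)),
                  NA_character_)
  list(end_bases_3p = single, end_dinucs_3p = dinuc)
}

#' 3' terminal-base classes of a blunt fragment
#'
#' A blunt double-stranded fragment exposes two 3' termini: on the left end
#' the 3' base of the bottom strand (the complement of the fragment's first
#' base) and on the right end the 3' base of the top strand (the fragment's
#' last base). Because left/right orientation is arbitrary, the pair is
#' unordered; over four bases this yields exactly 10 distinct classes.
#' The analogous unordered pair of terminal 2-mers is returned alongside.
#'
#' @param sequence Fragment sequence (character) or a one-row slice of a
#'   `fragment_inventory`.
#' @return List with `end_bases_3p` (e.g. `"AC"`, alphabetically ordered)
#'   and `end_dinucs_3p` (e.g. `"AG/CT"`).
#' @export
terminal_classes <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 2L) {
    stop("fragment shorter than 2 bp: terminal dinucleotide class undefined")
  }
  tc <- terminal_classes_chr(sequence)
  list(end_bases_3p = tc$end_bases_3p, end_dinucs_3p = tc$end_dinucs_3p)
}

#' Collapse indistinguishable fragments
#'
#' Fragments whose sequences are identical up to reverse complement (as
#' happens within ribosomal repeat regions) produce reads that cannot be
#' assigned to a single locus. They are grouped by canonical sequence (the
#' lexicographic minimum of the sequence and its reverse complement); one
#' representative per group is kept, carrying `copy_count` equal to the group
#' size. The sum of `copy_count` equals the input fragment count.
#'
#' @param fragments A `fragment_inventory` from [digest()].
#' @return A `fragment_inventory` of unique fragments.
#' @export
collapse_unique <- function(fragments) {
  stopifnot(inherits(fragments, "fragment_inventory"))
  canon <- pmin(fragments$sequence, revcomp_chr(fragments$sequence))
  grp <- match(canon, canon)           # index of first occurrence
  counts <- tapply(fragments$copy_count, grp, sum)
  keep <- as.integer(names(counts))
  out <- fragments[keep, , drop = FALSE]
  out$copy_count <- as.integer(counts)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("genome_id", "genome_length", "topology")) {
    attr(out, a) <- attr(fragments, a)
  }
  class(out) <- c("fragment_inventory", "data.frame")
  out
}

#' Write fragments to FASTA
#'
#' One record per fragment with header
#' `"{genome_id}:{start}-{end}|len={length}|copies={copy_count}"`, parseable
#' back with [read_fragment_fasta()]. This per-fragment FASTA is the
#' alignment reference: reads are mapped against it so that each reference
#' entry is one predicted fragment.
#'
#' @param fragments A non-empty `fragment_inventory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragment_fasta <- function(fragments, path) {
  if (!is.data.frame(fragments) || nrow(fragments) == 0L) {
    stop("no fragments to write")
  }
  ss <- Biostrings::DNAStringSet(fragments$sequence)
  names(ss) <- sprintf("%s:%d-%d|len=%d|copies=%d",
                       fragments$genome_id, fragments$start, fragments$end,
                       fragments$length, fragments$copy_count)
  ok <- tryCatch({ Biostrings::writeXStringSet(ss, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write fragment FASTA '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a fragment FASTA written by [write_fragment_fasta()]
#'
#' @param path FASTA file with `genome:start-end|len=..|copies=..` headers.
#' @return A `fragment_inventory` (without genome-level attributes beyond
#'   `genome_id`).
#' @export
read_fragment_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  h <- names(ss)
  m <- regmatches(h, regexec(
    "^(.+):([0-9]+)-([0-9]+)\\|len=([0-9]+)\\|copies=([0-9]+)$", h))
  bad <- vapply(m, length, integer(1)) != 6L
  if (any(bad)) stop("unparseable fragment FASTA header(s): ",
                     paste(utils::head(h[bad], 3), collapse = "; "))
  gid <- vapply(m, `[`, character(1), 2L)
  starts <- as.integer(vapply(m, `[`, character(1), 3L))
  ends <- as.integer(vapply(m, `[`, character(1), 4L))
  seqs <- as.character(ss)
  tc <- terminal_classes_chr(seqs)
  inv <- data.frame(
    fragment_id = sprintf("%s:%d-%d", gid, starts, ends),
    genome_id = gid, start = starts, end = ends,
    length = as.integer(vapply(m, `[`, character(1), 5L)),
    sequence = unname(seqs),
    end_bases_3p = tc$end_bases_3p, end_dinucs_3p = tc$end_dinucs_3p,
    copy_count = as.integer(vapply(m, `[`, character(1), 6L)),
    stringsAsFactors = FALSE
  )
  attr(inv, "genome_id") <- gid[1L]
  class(inv) <- c("fragment_inventory", "data.frame")
  inv
}

#' Write / read the fragment inventory TSV
#'
#' The TSV carries all metadata except the sequence itself and is the
#' exchange format consumed by the counting, bias and calibration steps.
#' Genome length and topology are preserved in a `#` header line.
#'
#' @param fragments A `fragment_inventory`.
#' @param path TSV path.
#' @return `path` (writer) or a `fragment_inventory` without sequences
#'   (reader).
#' @export
write_fragment_inventory <- function(fragments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# genome_id=%s genome_length=%s topology=%s",
                     attr(fragments, "genome_id"),
                     attr(fragments, "genome_length"),
                     attr(fragments, "topology")), con)
  cols <- c("fragment_id", "genome_id", "start", "end", "length",
            "end_bases_3p", "end_dinucs_3p", "copy_count")
  utils::write.table(as.data.frame(fragments)[, cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_inventory
#' @export
read_fragment_inventory <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- regmatches(first, regexec(
    "^# genome_id=(\\S+) genome_length=(\\S+) topology=(\\S+)", first))[[1]]
  inv <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (length(meta) == 4L) {
    attr(inv, "genome_id") <- meta[2L]
    attr(inv, "genome_length") <- as.integer(meta[3L])
    attr(inv, "topology") <- meta[4L]
  }
  class(inv) <- c("fragment_inventory", "data.frame")
  inv
}
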