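#' Restriction enzyme recognition sites
#'
#' A recognition site couples an IUPAC-degenerate pattern with the 0-based
#' offset within the pattern after which the top strand is cleaved. The
#' conventional caret notation writes the cut inside the site, e.g.
#' `"GAANN^NNTTC"` for XmnI. Only blunt cutters (both strands cleaved at the
#' same position, which for a palindromic-degenerate site means the cut sits
#' at the pattern midpoint) are modelled; overhang chemistry is an extension
#' point, not supported here.
#'
#' @param name Enzyme name.
#' @param pattern IUPAC pattern, optionally containing a single `^` marking
#'   the cut. If no caret is present, `cut_offset` must be given.
#' @param cut_offset 0-based position within the pattern after which the top
#'   strand is cut; ignored when the pattern carries a caret.
#' @return An object of class `recognition_site` with fields `name`,
#'   `pattern` (caret-free) and `cut_offset`.
#' @examples
#' recognition_site("PvuII", "CAG^CTG")
#' recognition_site("XmnI", "GAANNNNTTC", cut_offset = 5)
#' @export
recognition_site <- function(name, pattern, cut_offset = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  pattern <- toupper(gsub("\\s", "", pattern))
  if (grepl("\\^", pattern)) {
    if (lengths(regmatches(pattern, gregexpr("\\^", pattern))) != 1L) {
      stop("pattern may contain at most one '^' cut mark")
    }
    cut_offset <- regexpr("\\^", pattern) - 1L
    pattern <- gsub("\\^", "", pattern)
  }
  if (is.null(cut_offset)) {
    stop("cut_offset required when the pattern has no '^' mark")
  }
  cut_offset <- as.integer(cut_offset)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  letters_ok <- strsplit(pattern, "")[[1]] %in% iupac
  if (!nzchar(pattern) || !all(letters_ok)) {
    stop("invalid enzyme '", name, "': pattern must be non-empty IUPAC (",
         pattern, ")")
  }
  if (cut_offset <= 0L || cut_offset >= nchar(pattern)) {
    stop("invalid enzyme '", name, "': cut_offset must fall strictly inside ",
         "the pattern")
  }
  structure(list(name = name, pattern = pattern, cut_offset = cut_offset),
            class = "recognition_site")
}

#' @export
print.recognition_site <- function(x, ...) {
  cat(sprintf("<recognition_site> %s %s^%s\n", x$name,
              substr(x$pattern, 1L, x$cut_offset),
              substr(x$pattern, x$cut_offset + 1L, nchar(x$pattern))))
  invisible(x)
}

#' Is the site palindromic as a degenerate pattern?
#'
#' True when the pattern equals its own reverse complement under IUPAC
#' semantics, so a single-strand scan finds every double-stranded site.
#' @param site A `recognition_site`.
#' @export
is_palindromic <- function(site) {
  identical(site$pattern, revcomp_chr(site$pattern))
}

#' Built-in enzyme table
#'
#' The four blunt cutters used to turn the E. coli chromosome into an
#' equimolar fragment ladder: AleI, PshAI and XmnI carry degenerate (NN)
#' positions flanking the cut, producing all possible blunt terminal bases,
#' while PvuII yields a uniform CAG/CTG end.
#'
#' @return A data.frame with columns `name`, `pattern` (caret notation) and
#'   `cut_offset`.
#' @export
restriction_enzymes <- function() {
  data.frame(
    name = c("AleI", "PshAI", "XmnI", "PvuII"),
    pattern = c("CACNN^NNGTG", "GACNN^NNGTC", "GAANN^NNTTC", "CAG^CTG"),
    cut_offset = c(5L, 5L, 5L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Look up an enzyme by name
#'
#' Searches the built-in table ([restriction_enzymes()]) and, optionally, a
#' user table read with [read_enzyme_tsv()].
#' @param name Enzyme name (case sensitive).
#' @param extra Optional data.frame with columns `name` and `pattern`
#'   (caret notation), as returned by [read_enzyme_tsv()].
#' @return A `recognition_site`.
#' @export
get_enzyme <- function(name, extra = NULL) {
  tab <- restriction_enzymes()[, c("name", "pattern")]
  if (!is.null(extra)) tab <- rbind(tab, extra[, c("name", "pattern")])
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown enzyme '", name, "'; known: ",
         paste(tab$name, collapse = ", "))
  }
  recognition_site(tab$name[i], tab$pattern[i])
}

#' Read user enzyme definitions from TSV
#'
#' @param path Two-column TSV (`name`, `pattern`); the pattern uses caret
#'   notation, e.g. `GAANN^NNTTC`.
#' @return A data.frame suitable for the `extra` argument of [get_enzyme()].
#' @export
read_enzyme_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(tab))) {
    stop("enzyme TSV must have columns 'name' and 'pattern': ", path)
  }
  # validate eagerly so bad rows fail at load time
  invisible(lapply(seq_len(nrow(tab)),
                   function(i) recognition_site(tab$name[i], tab$pattern[i])))
  tab
}
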