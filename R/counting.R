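#' Load read-to-fragment alignments
#'
#' Reads a SAM or BAM file whose reference entries are predicted restriction
#' fragments and classifies every record as primary, secondary,
#' supplementary or unmapped from its FLAG. The observed read length is the
#' query sequence length (the full molecule for ligation-style long reads);
#' the aligned span on the fragment is recorded separately.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param fragments Optional `fragment_inventory`; records aligned to a
#'   reference name absent from it are warned about and flagged
#'   `unassigned`.
#' @return A data.frame of alignments: `read_id`, `fragment_id`,
#'   `read_length`, `alignment_type`, `ref_start`, `ref_end` (0-based
#'   half-open), `unassigned`.
#' @export
load_alignments <- function(path, fragments = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "cigar", "qwidth")
  p <- Rsamtools::ScanBamParam(what = what)
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  flag <- rec$flag
  type <- rep("primary", n)
  type[bitwAnd(flag, 256L) != 0L] <- "secondary"
  type[bitwAnd(flag, 2048L) != 0L] <- "supplementary"
  type[bitwAnd(flag, 4L) != 0L] <- "unmapped"
  ref_width <- rep(NA_integer_, n)
  mapped <- type != "unmapped" & !is.na(rec$cigar)
  ref_width[mapped] <-
    GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[mapped])
  out <- data.frame(
    read_id = rec$qname,
    fragment_id = as.character(rec$rname),
    read_length = rec$qwidth,
    alignment_type = type,
    ref_start = ifelse(mapped, rec$pos - 1L, NA_integer_),
    ref_end = ifelse(mapped, rec$pos - 1L + ref_width, NA_integer_),
    stringsAsFactors = FALSE
  )
  out$unassigned <- logical(n)
  if (!is.null(fragments)) {
    miss <- !is.na(out$fragment_id) &
      !(out$fragment_id %in% fragments$fragment_id)
    if (any(miss)) {
      warning(sum(miss), " alignment(s) to reference names absent from the ",
              "fragment inventory; flagged unassigned")
      out$unassigned[miss] <- TRUE
    }
  }
  out
}

#' Remove reads carrying supplementary alignments
#'
#' A read with one or more supplementary alignments spans more than one
#' predicted fragment -- the signature of incomplete digestion (a chimeric
#' molecule) -- so the entire read is discarded, not just the supplementary
#' record. Secondary and unmapped records are never counted. Every surviving
#' read contributes exactly one primary record; a read with two primary
#' records is malformed input.
#'
#' Filtering is a projection: applying it twice equals applying it once.
#'
#' @param reads Alignments from [load_alignments()].
#' @return The subset of countable primary alignments.
#' @export
filter_reads <- function(reads) {
  prim_per_read <- table(reads$read_id[reads$alignment_type == "primary"])
  if (any(prim_per_read > 1L)) {
    stop("malformed input: read(s) with more than one primary alignment: ",
         paste(utils::head(names(prim_per_read)[prim_per_read > 1L], 3),
               collapse = ", "))
  }
  chimeric <- unique(reads$read_id[reads$alignment_type == "supplementary"])
  keep <- reads$alignment_type == "primary" &
    !(reads$read_id %in% chimeric) & !reads$unassigned
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count reads per fragment and normalize
#'
#' Produces the per-fragment count table with the three normalizations used
#' throughout: percent of library (`freq_pct`, summing to 100), reads per
#' million (`rpm`) and reads per kilobase per million (`rpkm = rpm /
#' (L/1000)`). Fragments with zero reads are retained with count 0 so the
#' full inventory is always the denominator. Observed-length statistics
#' (mean and median query length of the counted reads) support
#' shear diagnostics via [length_concordance()].
#'
#' @param reads Filtered alignments from [filter_reads()].
#' @param fragments The `fragment_inventory` the reads were aligned to.
#' @return A `fragment_count_table`: data.frame with columns `fragment_id`,
#'   `length`, `count`, `freq_pct`, `rpm`, `rpkm`, `mean_obs_len`,
#'   `median_obs_len`, `end_bases_3p`, `end_dinucs_3p`, `copy_count`,
#'   `start`, `end`; inventory attributes are propagated.
#' @export
count_and_normalize <- function(reads, fragments) {
  stopifnot(is.data.frame(reads), is.data.frame(fragments))
  total <- nrow(reads)
  if (total == 0L) stop("zero counted reads: normalization undefined")
  idx <- factor(reads$fragment_id, levels = fragments$fragment_id)
  if (anyNA(idx)) stop("reads aligned to fragments missing from inventory")
  count <- as.integer(tabulate(idx, nbins = nrow(fragments)))
  mean_len <- tapply(reads$read_length, idx, mean)
  med_len <- tapply(reads$read_length, idx, stats::median)
  tab <- data.frame(
    fragment_id = fragments$fragment_id,
    length = fragments$length,
    count = count,
    freq_pct = 100 * count / total,
    rpm = 1e6 * count / total,
    rpkm = (1e6 * count / total) / (fragments$length / 1000),
    mean_obs_len = as.numeric(mean_len[fragments$fragment_id]),
    median_obs_len = as.numeric(med_len[fragments$fragment_id]),
    end_bases_3p = fragments$end_bases_3p,
    end_dinucs_3p = fragments$end_dinucs_3p,
    copy_count = fragments$copy_count,
    start = fragments$start,
    end = fragments$end,
    stringsAsFactors = FALSE
  )
  for (a in c("genome_id", "genome_length", "topology")) {
    attr(tab, a) <- attr(fragments, a)
  }
  attr(tab, "total_reads") <- total
  class(tab) <- c("fragment_count_table", "data.frame")
  tab
}

#' Observed versus expected fragment length
#'
#' Random shearing during handling truncates long molecules: the mean
#' observed length plateaus while the expected length keeps growing, and the
#' median resists longer. Fragments whose median observed length falls below
#' `threshold * length` are flagged shear-suspect.
#'
#' @param table A `fragment_count_table`.
#' @param threshold Fraction of the expected length below which the median
#'   observed length marks a fragment as shear-suspect (default 0.9).
#' @return Data.frame `fragment_id`, `length`, `mean_obs_len`,
#'   `median_obs_len`, `shear_suspect`.
#' @export
length_concordance <- function(table, threshold = 0.9) {
  out <- table[, c("fragment_id", "length", "mean_obs_len", "median_obs_len")]
  out$shear_suspect <- !is.na(out$median_obs_len) &
    out$median_obs_len < threshold * out$length
  out <- as.data.frame(out)
  rownames(out) <- NULL
  out
}

#' Normalized positional coverage across fragments
#'
#' Computes read depth in `n_bins` equal-width bins over each fragment,
#' divides by the maximum depth observed over the declared DNA source (all
#' fragments of one genome; set `normalize = "fragment"` for per-fragment
#' scaling) and reports bin midpoints on a 0-1 axis. Sheared long molecules
#' lose their middles preferentially, producing a mid-fragment coverage dip.
#'
#' @param reads Filtered alignments (must carry `ref_start`/`ref_end`).
#' @param fragments `fragment_inventory` (or count table) giving lengths.
#' @param n_bins Number of bins per fragment.
#' @param normalize `"source"` (default) or `"fragment"`.
#' @return Data.frame `fragment_id`, `bin` (1-based), `x` (normalized bin
#'   midpoint), `depth`, `depth_norm`.
#' @export
coverage_profile <- function(reads, fragments, n_bins = 100L,
                             normalize = c("source", "fragment")) {
  normalize <- match.arg(normalize)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  res <- lapply(seq_len(nrow(fragments)), function(i) {
    L <- fragments$length[i]
    fid <- fragments$fragment_id[i]
    r <- reads[reads$fragment_id == fid & !is.na(reads$ref_start), ,
               drop = FALSE]
    edges <- seq(0, L, length.out = n_bins + 1L)
    depth <- numeric(n_bins)
    if (nrow(r)) {
      for (b in seq_len(n_bins)) {
        # overlap of each read interval with the bin, as mean depth in bin
        ov <- pmax(0, pmin(r$ref_end, edges[b + 1L]) -
                     pmax(r$ref_start, edges[b]))
        depth[b] <- sum(ov) / (edges[b + 1L] - edges[b])
      }
    }
    data.frame(fragment_id = fid, bin = seq_len(n_bins),
               x = (seq_len(n_bins) - 0.5) / n_bins, depth = depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (normalize == "fragment") {
    mx <- tapply(out$depth, out$fragment_id, max)
    denom <- as.numeric(mx[out$fragment_id])
  } else {
    denom <- max(out$depth)
  }
  out$depth_norm <- ifelse(denom > 0, out$depth / denom, 0)
  out
}

#' Library summary: fragments above frequency thresholds and top-20 lengths
#'
#' For each threshold, counts fragments whose library frequency strictly
#' exceeds it; also reports the median and range of expected lengths of the
#' 20 most frequent fragments (ties broken toward longer fragments), the
#' most effective sequencing range of the protocol.
#'
#' @param table A `fragment_count_table`.
#' @param thresholds Frequencies in percent (default 0.001, 0.01, 0.1).
#' @param top_k Number of top fragments to summarize (default 20).
#' @return List: `n_fragments`, `n_above` (named by threshold), `max_pct`,
#'   `top_k`, `top_median_length`, `top_length_range`, `top_truncated`.
#' @export
threshold_summary <- function(table, thresholds = c(0.001, 0.01, 0.1),
                              top_k = 20L) {
  n_above <- vapply(thresholds, function(t) sum(table$freq_pct > t),
                    numeric(1))
  names(n_above) <- paste0(">", thresholds, "%")
  truncated <- nrow(table) < top_k
  k <- min(top_k, nrow(table))
  ord <- order(-table$freq_pct, -table$length)
  top <- table[ord[seq_len(k)], , drop = FALSE]
  list(
    n_fragments = nrow(table),
    n_above = n_above,
    max_pct = max(table$freq_pct),
    top_k = k,
    top_median_length = stats::median(top$length),
    top_length_range = range(top$length),
    top_truncated = truncated
  )
}

#' Per-fragment ratio of normalized frequencies between two libraries
#'
#' Because both libraries are normalized within themselves, the ratio is
#' invariant to sequencing depth; it isolates differential behavior such as
#' the consensus-pass requirement depressing long molecules. Fragments with
#' zero frequency in the denominator library are reported with `NA` and
#' excluded from the binned summary.
#'
#' @param table_a,table_b `fragment_count_table`s sharing a fragment
#'   inventory.
#' @param bin_width Optional length-bin width (bp) for the aggregated mean
#'   ratio (default 500; `NULL` to skip).
#' @return List with `per_fragment` (fragment_id, length, freq_a, freq_b,
#'   ratio) and `binned` (bin_lo, bin_hi, n, mean_ratio), plus
#'   `n_undefined`.
#' @export
count_ratio <- function(table_a, table_b, bin_width = 500) {
  if (!setequal(table_a$fragment_id, table_b$fragment_id)) {
    stop("count tables do not share a fragment inventory")
  }
  b <- table_b[match(table_a$fragment_id, table_b$fragment_id), ]
  ratio <- ifelse(b$freq_pct > 0, table_a$freq_pct / b$freq_pct, NA_real_)
  per <- data.frame(fragment_id = table_a$fragment_id,
                    length = table_a$length,
                    freq_a = table_a$freq_pct, freq_b = b$freq_pct,
                    ratio = ratio, stringsAsFactors = FALSE)
  binned <- NULL
  if (!is.null(bin_width)) {
    ok <- !is.na(ratio) & table_a$freq_pct > 0
    if (any(ok)) {
      bin <- floor(per$length[ok] / bin_width)
      mean_r <- tapply(per$ratio[ok], bin, mean)
      n <- tapply(per$ratio[ok], bin, length)
      lo <- as.numeric(names(mean_r)) * bin_width
      binned <- data.frame(bin_lo = lo, bin_hi = lo + bin_width,
                           n = as.integer(n), mean_ratio = as.numeric(mean_r))
      rownames(binned) <- NULL
    }
  }
  list(per_fragment = per, binned = binned, n_undefined = sum(is.na(ratio)))
}

#' Write / read a fragment count table TSV
#' @param table A `fragment_count_table`.
#' @param path TSV path.
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# genome_id=%s genome_length=%s topology=%s total_reads=%s",
                     attr(table, "genome_id"), attr(table, "genome_length"),
                     attr(table, "topology"), attr(table, "total_reads")), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- regmatches(first, regexec(
    "^# genome_id=(\\S+) genome_length=(\\S+) topology=(\\S+) total_reads=(\\S+)",
    first))[[1]]
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (length(meta) == 5L) {
    attr(tab, "genome_id") <- meta[2L]
    attr(tab, "genome_length") <- as.integer(meta[3L])
    attr(tab, "topology") <- meta[4L]
    attr(tab, "total_reads") <- as.integer(meta[5L])
  }
  class(tab) <- c("fragment_count_table", "data.frame")
  tab
}
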