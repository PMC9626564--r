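#' Coefficient of variation of fragment frequency by length bin
#'
#' Within each length bin the coefficient of variation (sample SD / mean) of
#' the per-fragment library frequency measures how reproducibly same-sized
#' molecules are sequenced. Digests with degenerate cut sites (mixed 3'
#' ends) show systematically higher CV than the uniform-ended PvuII digest,
#' implicating terminal bases in ligation efficiency.
#'
#' @param table A `fragment_count_table`.
#' @param bin_width Bin width in bp (default 500).
#' @param value `"freq_pct"` (default) or `"count"`.
#' @return Data.frame `bin_lo`, `bin_hi`, `n`, `mean`, `cv`; bins with fewer
#'   than 2 members are omitted (CV undefined).
#' @export
cv_by_length <- function(table, bin_width = 500, value = c("freq_pct", "count")) {
  value <- match.arg(value)
  v <- table[[value]]
  bin <- floor(table$length / bin_width)
  n <- tapply(v, bin, length)
  keep <- n >= 2L
  m <- tapply(v, bin, mean)[keep]
  s <- tapply(v, bin, stats::sd)[keep]
  lo <- as.numeric(names(m)) * bin_width
  out <- data.frame(bin_lo = lo, bin_hi = lo + bin_width,
                    n = as.integer(n[keep]), mean = as.numeric(m),
                    cv = ifelse(m > 0, as.numeric(s / m), NA_real_))
  out <- out[order(out$bin_lo), ]
  rownames(out) <- NULL
  out
}

default_end_bias_edges <- function() {
  # 401-1000, then 1000-wide bins up to 10,000 bp
  c(400, seq(1000, 10000, by = 1000))
}

#' Mean count and CV per 3' terminal-base class and length bin
#'
#' Groups fragments by the unordered pair of 3' terminal bases (10 classes;
#' or terminal dinucleotide pairs with `mode = "dinuc"`) within length bins
#' and reports the mean raw read count and its coefficient of variation.
#' Cells supported by 5 or fewer fragments are suppressed as unreliable.
#' Fragments with two 3' A ends ligate worst and sequence least; fragments
#' with no 3' A are the most efficient.
#'
#' @param table A `fragment_count_table` carrying end classes.
#' @param bin_edges Length-bin edges in bp; bin i is `(edges[i], edges[i+1]]`.
#'   Default: 401-1000 then 1000-wide bins to 10,000.
#' @param mode `"single"` (3' bases) or `"dinuc"` (3' 2-mers).
#' @param min_fragments Cells require strictly more members than this
#'   (default 5).
#' @param value `"count"` (default, raw reads) or `"freq_pct"`.
#' @return Data.frame `end_class`, `bin_lo`, `bin_hi`, `n_fragments`,
#'   `mean_count`, `cv`, `rank_in_bin` (1 = highest mean in its bin).
#' @export
end_bias_table <- function(table, bin_edges = default_end_bias_edges(),
                           mode = c("single", "dinuc"), min_fragments = 5L,
                           value = c("count", "freq_pct")) {
  mode <- match.arg(mode)
  value <- match.arg(value)
  cls <- if (mode == "single") table$end_bases_3p else table$end_dinucs_3p
  v <- table[[value]]
  bin <- cut(table$length, breaks = bin_edges, labels = FALSE)
  ok <- !is.na(bin) & !is.na(cls)
  df <- data.frame(cls = cls[ok], bin = bin[ok], v = v[ok],
                   stringsAsFactors = FALSE)
  agg_n <- stats::aggregate(v ~ cls + bin, df, length)
  agg_m <- stats::aggregate(v ~ cls + bin, df, mean)
  agg_s <- stats::aggregate(v ~ cls + bin, df, stats::sd)
  out <- data.frame(end_class = agg_n$cls,
                    bin_lo = bin_edges[agg_n$bin] + 1,
                    bin_hi = bin_edges[agg_n$bin + 1L],
                    n_fragments = agg_n$v,
                    mean_count = agg_m$v,
                    cv = ifelse(agg_m$v > 0, agg_s$v / agg_m$v, NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[out$n_fragments > min_fragments, , drop = FALSE]
  out <- out[order(out$bin_lo, -out$mean_count), ]
  out$rank_in_bin <- stats::ave(-out$mean_count, out$bin_lo,
                                FUN = function(x) rank(x, ties.method = "first"))
  rownames(out) <- NULL
  out
}

#' Aggregate end-class bias across length bins
#'
#' Combines the per-bin cells of [end_bias_table()] into one mean count per
#' end class, weighting each bin cell by its fragment support, and reports
#' all pairwise between-class ratios. In dinucleotide mode this is where a
#' multiplicative per-base ligation penalty shows up as, e.g., an AA:CC
#' deficit near the square of the single-base A:C ratio.
#'
#' @param cells Output of [end_bias_table()].
#' @return List with `class_means` (end_class, weighted mean_count, total
#'   n_fragments) and `pairwise` (class_a, class_b, ratio = mean_a/mean_b;
#'   `NA` when a class is absent).
#' @export
end_bias_summary <- function(cells) {
  if (nrow(cells) == 0L) stop("no end-bias cells to summarize")
  w <- cells$n_fragments
  m <- tapply(cells$mean_count * w, cells$end_class, sum) /
    tapply(w, cells$end_class, sum)
  n <- tapply(cells$n_fragments, cells$end_class, sum)
  class_means <- data.frame(end_class = names(m), mean_count = as.numeric(m),
                            n_fragments = as.integer(n),
                            stringsAsFactors = FALSE)
  class_means <- class_means[order(-class_means$mean_count), ]
  rownames(class_means) <- NULL
  cmb <- expand.grid(class_a = class_means$end_class,
                     class_b = class_means$end_class,
                     stringsAsFactors = FALSE)
  cmb <- cmb[cmb$class_a != cmb$class_b, ]
  ma <- class_means$mean_count[match(cmb$class_a, class_means$end_class)]
  mb <- class_means$mean_count[match(cmb$class_b, class_means$end_class)]
  cmb$ratio <- ifelse(is.na(mb) | mb == 0, NA_real_, ma / mb)
  rownames(cmb) <- NULL
  list(class_means = class_means, pairwise = cmb)
}
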