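#' Per-fragment frequency ratio between two growth conditions
#'
#' In replicating cells, sequence near the replication origin is present in
#' more copies than sequence near the terminus, so the ratio of
#' within-sample-normalized read frequencies (condition A over condition B,
#' e.g. exponential over stationary phase) traces a gradient across the
#' circular chromosome. Within-sample normalization makes the ratio
#' invariant to sequencing depth.
#'
#' @param table_a,table_b `fragment_count_table`s over the same inventory.
#' @param fragments `fragment_inventory` carrying `start`/`end` genome
#'   coordinates.
#' @param genome_length Genome length in bp; defaults to the inventory
#'   attribute.
#' @param digest_label Optional label recorded per row (for pooling several
#'   digests).
#' @return Data.frame `fragment_id`, `midpoint` (bp, modulo genome length),
#'   `length`, `ratio`, `digest`; attribute `n_excluded` counts fragments
#'   with zero frequency in either condition.
#' @export
per_fragment_ratio <- function(table_a, table_b, fragments,
                               genome_length = attr(fragments, "genome_length"),
                               digest_label = NA_character_) {
  if (!setequal(table_a$fragment_id, table_b$fragment_id) ||
      !all(table_a$fragment_id %in% fragments$fragment_id)) {
    stop("count tables and fragment inventory disagree")
  }
  if (is.null(genome_length)) stop("genome_length unknown")
  a <- table_a
  b <- table_b[match(a$fragment_id, table_b$fragment_id), ]
  f <- fragments[match(a$fragment_id, fragments$fragment_id), ]
  ok <- a$freq_pct > 0 & b$freq_pct > 0
  mid <- (f$start + f$length / 2) %% genome_length
  out <- data.frame(fragment_id = a$fragment_id[ok],
                    midpoint = mid[ok],
                    length = f$length[ok],
                    ratio = a$freq_pct[ok] / b$freq_pct[ok],
                    digest = digest_label,
                    stringsAsFactors = FALSE)
  out <- out[order(out$midpoint), ]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!ok)
  attr(out, "genome_length") <- genome_length
  out
}

#' Bin-averaged ratio track around the chromosome
#'
#' Pools per-fragment ratios (possibly from several digests) and averages
#' them in fixed genomic bins by fragment midpoint; the circular wrap is
#' respected (the last bin may be shorter). Empty bins are reported with
#' `NA`.
#'
#' @param ratios One data.frame from [per_fragment_ratio()] or a list of
#'   them (multiple digests pooled).
#' @param bin_width Bin width in bp (default 100,000).
#' @param genome_length Genome length; defaults to the ratios attribute.
#' @return Data.frame `bin_start`, `bin_end`, `n_fragments`, `mean_ratio`,
#'   `peak_midpoint` (midpoint of the member fragment with the largest
#'   ratio, `NA` when empty).
#' @export
rolling_bin_average <- function(ratios, bin_width = 1e5,
                                genome_length = NULL) {
  if (is.data.frame(ratios)) ratios <- list(ratios)
  if (is.null(genome_length)) {
    genome_length <- attr(ratios[[1]], "genome_length")
  }
  if (is.null(genome_length)) stop("genome_length unknown")
  pooled <- do.call(rbind, lapply(ratios, function(r)
    r[, c("midpoint", "ratio")]))
  starts <- seq(0, genome_length - 1, by = bin_width)
  bin <- findInterval(pooled$midpoint, starts)
  mean_r <- rep(NA_real_, length(starts))
  n <- integer(length(starts))
  peak <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    sel <- bin == i
    n[i] <- sum(sel)
    if (n[i]) {
      mean_r[i] <- mean(pooled$ratio[sel])
      peak[i] <- pooled$midpoint[sel][which.max(pooled$ratio[sel])]
    }
  }
  data.frame(bin_start = starts,
             bin_end = pmin(starts + bin_width, genome_length),
             n_fragments = n, mean_ratio = mean_r, peak_midpoint = peak)
}

#' Length-weighted rolling average over adjacent fragments
#'
#' Alternative smoothing that slides a window of `k` adjacent fragments
#' (ordered by genomic midpoint, with circular adjacency) and reports the
#' fragment-length-weighted mean ratio anchored at the window-center
#' midpoint. Unlike fixed bins, resolution follows the local fragment
#' density.
#'
#' @param ratios Data.frame from [per_fragment_ratio()] (single digest or
#'   pre-pooled and sorted by midpoint).
#' @param k Window size in fragments (odd values center exactly; default 50).
#' @param genome_length Genome length; defaults to the ratios attribute.
#' @return Data.frame `midpoint`, `mean_ratio`, `k`.
#' @export
weighted_rolling_average <- function(ratios, k = 50L,
                                     genome_length = attr(ratios, "genome_length")) {
  n <- nrow(ratios)
  if (k > n) stop("window k = ", k, " exceeds fragment count ", n)
  ord <- order(ratios$midpoint)
  r <- ratios$ratio[ord]
  w <- ratios$length[ord]
  mid <- ratios$midpoint[ord]
  half <- (k - 1L) %/% 2L
  idx <- function(i) ((i - 1L) %% n) + 1L
  out_mid <- numeric(n)
  out_r <- numeric(n)
  for (i in seq_len(n)) {
    win <- idx(seq(i - half, i - half + k - 1L))
    out_mid[i] <- mid[i]
    out_r[i] <- sum(r[win] * w[win]) / sum(w[win])
  }
  data.frame(midpoint = out_mid, mean_ratio = out_r, k = k)
}

#' Extremes of a ratio track
#'
#' Reports where along the chromosome the mean ratio is highest (replication
#' origin neighborhood) and lowest (terminus), and their quotient, the
#' peak-to-trough copy-number contrast. Positions are reported both as bin
#' starts and as the midpoint of the strongest member fragment when
#' available.
#'
#' @param track Data.frame from [rolling_bin_average()] (columns
#'   `bin_start`, `mean_ratio`, optionally `peak_midpoint`) or from
#'   [weighted_rolling_average()] (column `midpoint`).
#' @return List `max_position`, `max_ratio`, `min_position`, `min_ratio`,
#'   `max_min_ratio`, and (for binned tracks) `max_bin_start`,
#'   `min_bin_start`.
#' @export
extremum_report <- function(track) {
  r <- track$mean_ratio
  ok <- which(!is.na(r))
  if (!length(ok)) stop("empty ratio track")
  imax <- ok[which.max(r[ok])]
  imin <- ok[which.min(r[ok])]
  pos <- function(i) {
    if (!is.null(track$peak_midpoint) && !is.na(track$peak_midpoint[i])) {
      track$peak_midpoint[i]
    } else if (!is.null(track$midpoint)) {
      track$midpoint[i]
    } else {
      track$bin_start[i]
    }
  }
  out <- list(max_position = pos(imax), max_ratio = r[imax],
              min_position = pos(imin), min_ratio = r[imin],
              max_min_ratio = r[imax] / r[imin])
  if (!is.null(track$bin_start)) {
    out$max_bin_start <- track$bin_start[imax]
    out$min_bin_start <- track$bin_start[imin]
  }
  out
}

#' Permutation test for regional copy-number difference
#'
#' Compares mean per-fragment ratios between two genomic neighborhoods
#' (e.g. around the origin and around the terminus), selected either as all
#' fragments within a fixed distance of a center or as a fixed number of
#' nearest fragments. Significance is assessed by a two-sided permutation
#' test on region labels -- chosen because per-fragment ratios are neither
#' normal nor length-independent -- with a Mann-Whitney U alternative.
#'
#' @param ratios Data.frame from [per_fragment_ratio()].
#' @param center_a,center_b Genomic positions (bp) of the two regions.
#' @param mode `"fixed_distance"` (members within `size` bp of the center,
#'   circularly) or `"fixed_count"` (`size` nearest fragments).
#' @param size Half-width in bp, or fragment count, depending on `mode`.
#' @param n_perm Number of permutations (default 10,000).
#' @param statistic `"permutation"` (default) or `"wilcoxon"`.
#' @param genome_length Genome length; defaults to the ratios attribute.
#' @return List `statistic` (difference of means), `p_value`, `n_a`, `n_b`,
#'   `mode`, `n_perm`.
#' @export
region_significance <- function(ratios, center_a, center_b,
                                mode = c("fixed_distance", "fixed_count"),
                                size = 2e5, n_perm = 10000L,
                                statistic = c("permutation", "wilcoxon"),
                                genome_length = attr(ratios, "genome_length")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  if (is.null(genome_length)) stop("genome_length unknown")
  circ_dist <- function(x, c) {
    d <- abs(x - c) %% genome_length
    pmin(d, genome_length - d)
  }
  members <- function(center) {
    d <- circ_dist(ratios$midpoint, center)
    if (mode == "fixed_distance") which(d <= size)
    else order(d)[seq_len(min(size, length(d)))]
  }
  ia <- members(center_a)
  ib <- members(center_b)
  if (length(intersect(ia, ib))) stop("regions overlap; choose smaller size")
  va <- ratios$ratio[ia]
  vb <- ratios$ratio[ib]
  obs <- mean(va) - mean(vb)
  if (statistic == "wilcoxon") {
    p <- stats::wilcox.test(va, vb, exact = FALSE)$p.value
  } else {
    pool <- c(va, vb)
    na <- length(va)
    perm <- replicate(n_perm, {
      s <- sample.int(length(pool), na)
      mean(pool[s]) - mean(pool[-s])
    })
    p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  }
  list(statistic = obs, p_value = p, n_a = length(va), n_b = length(vb),
       mode = mode, n_perm = if (statistic == "permutation") n_perm else NA)
}
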