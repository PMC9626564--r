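# Independent brute-force oracle for cut-site prediction: IUPAC pattern ->
# regex character classes, overlapping matches via lookahead, both strands
# scanned explicitly. Shares no code with fragquant::find_cut_sites().

iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(pattern, "")[[1]]], collapse = "")
}

revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_cut_sites <- function(genome, enzyme) {
  len <- nchar(genome$sequence)
  patlen <- nchar(enzyme$pattern)
  if (patlen > len) return(integer(0))
  circular <- genome$topology == "circular"
  subj <- if (circular) {
    paste0(genome$sequence, substr(genome$sequence, 1, patlen - 1))
  } else {
    genome$sequence
  }
  scan <- function(pat) {
    hits <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), subj,
                     perl = TRUE)[[1]]
    s <- as.integer(hits)
    s <- s[s > 0]
    if (circular) s <- s[s <= len]
    s
  }
  cuts <- (scan(enzyme$pattern) - 1L) + enzyme$cut_offset
  rc <- revcomp_oracle(enzyme$pattern)
  if (!identical(rc, enzyme$pattern)) {
    cuts <- c(cuts, (scan(rc) - 1L) + (patlen - enzyme$cut_offset))
  }
  cuts <- if (circular) cuts %% len else cuts[cuts > 0 & cuts < len]
  sort(unique(as.integer(cuts)))
}

# Minimal hand-built count table for deterministic unit tests.
make_count_table <- function(counts, lengths,
                             end_bases = rep("CG", length(counts)),
                             end_dinucs = rep("AG/CT", length(counts)),
                             copy_count = rep(1L, length(counts)),
                             start = cumsum(c(0, lengths[-length(lengths)])),
                             genome_length = sum(lengths),
                             ids = sprintf("f%03d", seq_along(counts))) {
  total <- sum(counts)
  tab <- data.frame(
    fragment_id = ids, length = lengths, count = counts,
    freq_pct = 100 * counts / total, rpm = 1e6 * counts / total,
    rpkm = (1e6 * counts / total) / (lengths / 1000),
    mean_obs_len = as.numeric(lengths), median_obs_len = as.numeric(lengths),
    end_bases_3p = end_bases, end_dinucs_3p = end_dinucs,
    copy_count = copy_count, start = start, end = start + lengths,
    stringsAsFactors = FALSE)
  attr(tab, "genome_length") <- genome_length
  attr(tab, "total_reads") <- total
  class(tab) <- c("fragment_count_table", "data.frame")
  tab
}

# Random enzymes (some non-palindromic) for property tests.
random_enzyme <- function() {
  iupac <- c("A", "C", "G", "T", "N", "R", "Y", "W", "S")
  repeat {
    plen <- sample(4:10, 1)
    pat <- paste(sample(iupac, plen, replace = TRUE,
                        prob = c(rep(0.2, 4), 0.12, rep(0.02, 4))),
                 collapse = "")
    # avoid patterns so degenerate they cut everywhere
    if (sum(strsplit(pat, "")[[1]] %in% c("A", "C", "G", "T")) >= 3) break
  }
  recognition_site("rand", pat, cut_offset = sample(seq_len(plen - 1), 1))
}
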