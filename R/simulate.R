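## run expr with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a random genome sequence
#'
#' I.i.d. bases at the requested GC content; deterministic under `seed`.
#'
#' @param length Genome length in bp (>= 100).
#' @param gc GC fraction in (0, 1).
#' @param topology `"circular"` or `"linear"`.
#' @param id Sequence label.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A [genome_sequence()].
#' @export
simulate_genome <- function(length, gc = 0.5,
                            topology = c("circular", "linear"),
                            id = "simgenome", seed = NULL) {
  topology <- match.arg(topology)
  if (length < 100) stop("genome length must be >= 100")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly inside (0, 1)")
  with_seed(seed, {
    b <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    genome_sequence(id, paste(b, collapse = ""), topology)
  })
}

length_efficiency_curve <- function(curve) {
  if (is.function(curve)) return(curve)
  unimodal <- function(peak, sigma = 0.6, floor = 0.05) {
    force(peak)
    function(L) floor + exp(-(log(L / peak))^2 / (2 * sigma^2))
  }
  switch(curve,
    flat = function(L) rep(1, length(L)),
    short_prep = unimodal(4000),
    long_prep = unimodal(10000),
    stop("unknown length_efficiency preset '", curve, "'"))
}

#' Declare a library bias model
#'
#' Bundles the mechanisms that distort per-fragment read counts away from
#' equimolarity:
#' * `length_efficiency`: recovery/sequencing efficiency versus molecule
#'   length. Presets: `"flat"`; `"short_prep"`, unimodal with its peak near
#'   4 kb (bead ratios retaining short DNA); `"long_prep"`, peak near 10 kb.
#'   A custom function of length is accepted.
#' * `end_efficiency_3p`: multiplicative ligation efficiency per 3'
#'   terminal base, applied once per end. The default ordering A < T < G < C
#'   (A = 0.41) reproduces the observed several-fold deficit of A-ended
#'   fragments.
#' * `shear_rate`: per-base probability of a random break per molecule;
#'   breaks are Poisson along the length, so long molecules shear more and
#'   their mean observed length plateaus near `1 / shear_rate`.
#' * `incomplete_digest_rate`: probability a sampled molecule is an uncut
#'   chimera spanning two adjacent fragments; such reads produce a
#'   supplementary alignment and are removed by [filter_reads()].
#' * `mode`: `"ligation"` reads span the whole (possibly sheared) molecule;
#'   `"transposase"` reads start at a random internal insertion point and
#'   end at a random downstream position, and the sampling weight gains a
#'   factor of length.
#' * `copy_number`: optional function of genomic midpoint modelling a
#'   replication gradient (see [copy_number_gradient()]).
#'
#' @param length_efficiency Preset name or function of length.
#' @param end_efficiency_3p Named numeric multipliers for A, C, G, T.
#' @param shear_rate Per-base break probability (default 0).
#' @param incomplete_digest_rate Chimera probability (default 0; ~0.01
#'   matches complete digests, ~0.07 a methylation-blocked enzyme).
#' @param mode `"ligation"` or `"transposase"`.
#' @param copy_number `NULL` (uniform) or a function of position (bp).
#' @return A `bias_model`.
#' @export
bias_model <- function(length_efficiency = "flat",
                       end_efficiency_3p = c(A = 0.41, C = 1.0, G = 0.9,
                                             T = 0.8),
                       shear_rate = 0, incomplete_digest_rate = 0,
                       mode = c("ligation", "transposase"),
                       copy_number = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(end_efficiency_3p > 0),
            shear_rate >= 0, shear_rate <= 1,
            incomplete_digest_rate >= 0, incomplete_digest_rate <= 1)
  if (!all(c("A", "C", "G", "T") %in% names(end_efficiency_3p))) {
    stop("end_efficiency_3p needs entries for A, C, G, T")
  }
  structure(list(
    length_efficiency = length_efficiency_curve(length_efficiency),
    length_efficiency_name =
      if (is.character(length_efficiency)) length_efficiency else "custom",
    end_efficiency_3p = end_efficiency_3p,
    shear_rate = shear_rate,
    incomplete_digest_rate = incomplete_digest_rate,
    mode = mode, copy_number = copy_number
  ), class = "bias_model")
}

#' Linear replication copy-number gradient
#'
#' Copy number `fold_origin` at the origin declining linearly (in circular
#' genomic distance) to `fold_terminus` at the diametrically opposite
#' terminus -- the profile of an unsynchronized replicating population.
#'
#' @param origin Origin position (bp).
#' @param genome_length Genome length (bp).
#' @param fold_origin,fold_terminus Copy numbers at origin and terminus.
#' @return Function of position.
#' @export
copy_number_gradient <- function(origin, genome_length, fold_origin = 2,
                                 fold_terminus = 1) {
  force(origin); force(genome_length)
  function(pos) {
    d <- abs(pos - origin) %% genome_length
    d <- pmin(d, genome_length - d)
    t <- d / (genome_length / 2)
    fold_origin + (fold_terminus - fold_origin) * t
  }
}

## expected counted-read weight per fragment under a bias model (intact
## molecules): copy number x length efficiency x both end efficiencies,
## times length in transposase mode
fragment_weights <- function(fragments, bias, length_efficiency = TRUE) {
  L <- fragments$length
  first <- substr(fragments$sequence, 1L, 1L)
  last <- substr(fragments$sequence, L, L)
  left3 <- unname(complement_base(first))
  eff <- bias$end_efficiency_3p
  w <- fragments$copy_count * eff[left3] * eff[last]
  if (length_efficiency) w <- w * bias$length_efficiency(L)
  if (!is.null(bias$copy_number)) {
    gl <- attr(fragments, "genome_length")
    if (is.null(gl)) gl <- max(fragments$end)
    mid <- (fragments$start + L / 2) %% gl
    w <- w * bias$copy_number(mid)
  }
  if (bias$mode == "transposase") w <- w * L
  unname(as.numeric(w))
}

#' Simulate a biased long-read library over a fragment inventory
#'
#' Samples `n_reads` molecules by abundance and end chemistry
#' (`copy_number(midpoint) * end_efficiency(left 3') * end_efficiency(right
#' 3')`, times `L` in transposase mode), then applies the molecule-level
#' mechanisms: incomplete-digest chimeras spanning two adjacent fragments
#' (emitting a primary plus a supplementary alignment), Poisson random
#' shearing whose pieces tile the molecule, and transposase-mode random
#' internal starts/ends. The length-efficiency curve enters as a retention
#' probability `le(len)/max(le)` applied to each molecule -- or, for sheared
#' ligation molecules, to each piece independently -- so that for an
#' unsheared library the expected counted frequency per fragment is exactly
#' the composite weight `copy_number * le(L) * end efficiencies` reported in
#' the `truth` table, while under shearing the longest (mid-fragment) pieces
#' of molecules past the efficiency peak are lost preferentially,
#' reproducing the mid-fragment coverage dip of long fragments. With a flat
#' curve every piece is retained and the pieces of each molecule tile its
#' interval exactly.
#'
#' @param fragments A `fragment_inventory` (sequences required for SAM
#'   output and end classes).
#' @param bias A [bias_model()].
#' @param n_reads Number of molecules to sample (> 0).
#' @param seed Optional integer seed; the same seed reproduces the library
#'   exactly.
#' @return A `simulated_library`: list with `reads` (read_id, fragment_id,
#'   start, end, read_length, is_chimeric, chimera_partner), `truth`
#'   (fragment_id, weight, prob, molecules), `bias`, `n_reads`, `seed`.
#' @export
simulate_library <- function(fragments, bias, n_reads, seed = NULL) {
  stopifnot(inherits(bias, "bias_model"))
  if (n_reads <= 0) stop("n_reads must be positive")
  n_reads <- as.integer(n_reads)
  # molecules are drawn by abundance x end chemistry; the length-efficiency
  # curve instead acts as a retention probability on each molecule or piece
  # entering the library, so that for unsheared libraries the expected
  # counted frequency is exactly the composite weight reported in `truth`
  w_sample <- fragment_weights(fragments, bias, length_efficiency = FALSE)
  w <- fragment_weights(fragments, bias)
  prob <- w_sample / sum(w_sample)
  le_max <- max(bias$length_efficiency(
    c(seq(1, 2 * max(fragments$length) + 2, length.out = 1024),
      fragments$length)))
  le_keep <- function(len) {
    pmin(1, bias$length_efficiency(len) / le_max)
  }
  nf <- nrow(fragments)
  ord <- order(fragments$start)           # genomic neighbours for chimeras
  nxt <- integer(nf)
  nxt[ord] <- ord[c(seq_len(nf)[-1L], 1L)]

  with_seed(seed, {
    fr <- sample.int(nf, n_reads, replace = TRUE, prob = prob)
    chim <- stats::runif(n_reads) < bias$incomplete_digest_rate & nf > 1L
    L <- fragments$length[fr]
    rid <- sprintf("mol%06d", seq_len(n_reads))
    if (bias$mode == "transposase") {
      s <- floor(stats::runif(n_reads, 0, L))
      e <- s + ceiling(stats::runif(n_reads, 0, L - s))
    } else {
      s <- rep(0L, n_reads)
      e <- L
    }
    span <- e - s
    nb <- stats::rpois(n_reads, bias$shear_rate * span)
    nb[span <= 1L] <- 0L
    nb[chim] <- 0L
    # molecule-level retention: intact ligation molecules and transposase
    # molecules survive with probability le(L)/le_max; chimeras likewise at
    # their joint length; sheared ligation molecules are thinned per piece
    mol_len <- L
    mol_len[chim] <- L[chim] + fragments$length[nxt[fr]][chim]
    mol_keep <- stats::runif(n_reads) < le_keep(mol_len)
    piece_thinned <- !chim & nb > 0L & bias$mode == "ligation"

    cols <- list()
    plain <- which(!chim & nb == 0L & mol_keep)
    if (length(plain)) {
      cols[[1L]] <- data.frame(
        read_id = rid[plain],
        fragment_id = fragments$fragment_id[fr[plain]],
        start = as.integer(s[plain]), end = as.integer(e[plain]),
        read_length = as.integer(span[plain]),
        is_chimeric = FALSE, chimera_partner = NA_character_,
        supplementary = FALSE, stringsAsFactors = FALSE)
    }
    sheared <- which(!chim & nb > 0L & (piece_thinned | mol_keep))
    if (length(sheared)) {
      # per-molecule break positions; pieces tile [s, e) exactly, then each
      # piece survives library prep with probability proportional to the
      # length-efficiency curve at its own length (a broken molecule's
      # middle pieces are the longest, so on the far side of the efficiency
      # peak they are lost preferentially -- the mid-fragment coverage dip)
      id_l <- vector("list", length(sheared))
      st_l <- vector("list", length(sheared))
      en_l <- vector("list", length(sheared))
      for (q in seq_along(sheared)) {
        m <- sheared[q]
        breaks <- sort(sample.int(span[m] - 1L, min(nb[m], span[m] - 1L))) +
          s[m]
        bounds <- c(s[m], breaks, e[m])
        plen <- diff(bounds)
        keep <- if (piece_thinned[m]) {
          stats::runif(length(plen)) < le_keep(plen)
        } else {
          rep(TRUE, length(plen))      # transposase: molecule already kept
        }
        k <- sum(keep)
        id_l[[q]] <- if (k) sprintf("%s_p%d", rid[m], which(keep))
        st_l[[q]] <- bounds[-length(bounds)][keep]
        en_l[[q]] <- bounds[-1L][keep]
      }
      st <- unlist(st_l)
      if (length(st)) {
        en <- unlist(en_l)
        reps <- vapply(st_l, length, integer(1))
        cols[[2L]] <- data.frame(
          read_id = unlist(id_l),
          fragment_id = rep(fragments$fragment_id[fr[sheared]], reps),
          start = as.integer(st), end = as.integer(en),
          read_length = as.integer(en - st),
          is_chimeric = FALSE, chimera_partner = NA_character_,
          supplementary = FALSE, stringsAsFactors = FALSE)
      }
    }
    ch <- which(chim & mol_keep)
    if (length(ch)) {
      i <- fr[ch]
      j <- nxt[i]
      cols[[3L]] <- data.frame(
        read_id = rep(rid[ch], each = 2L),
        fragment_id = as.vector(rbind(fragments$fragment_id[i],
                                      fragments$fragment_id[j])),
        start = 0L,
        end = as.vector(rbind(fragments$length[i], fragments$length[j])),
        read_length = rep(fragments$length[i] + fragments$length[j],
                          each = 2L),
        is_chimeric = TRUE,
        chimera_partner = as.vector(rbind(fragments$fragment_id[j],
                                          fragments$fragment_id[i])),
        supplementary = rep(c(FALSE, TRUE), length(ch)),
        stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, cols[!vapply(cols, is.null, logical(1))])
    rownames(reads) <- NULL
    truth <- data.frame(fragment_id = fragments$fragment_id,
                        weight = w, prob = prob,
                        molecules = tabulate(fr, nbins = nf),
                        stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth, bias = bias,
                   n_reads = n_reads, seed = seed),
              class = "simulated_library")
  })
}

#' @export
print.simulated_library <- function(x, ...) {
  cat(sprintf("<simulated_library> %d molecules -> %d read records (%s mode)\n",
              x$n_reads, nrow(x$reads), x$bias$mode))
  invisible(x)
}

#' Write a simulated library as SAM
#'
#' Minimal valid SAM: one `@SQ` line per fragment, quality strings `"*"`.
#' Chimeric molecules emit a full-length primary on their first fragment
#' (partner soft-clipped) plus a supplementary record on the partner, which
#' is exactly the signature [filter_reads()] removes. Sheared pieces map to
#' their sub-intervals.
#'
#' @param lib A `simulated_library`.
#' @param fragments The inventory it was simulated from (for sequences).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(lib, fragments, path) {
  seqs <- fragments$sequence
  names(seqs) <- fragments$fragment_id
  lens <- fragments$length
  names(lens) <- fragments$fragment_id
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", fragments$fragment_id,
                   fragments$length))
  r <- lib$reads
  flag <- ifelse(r$supplementary, 2048L, 0L)
  n <- nrow(r)
  cigar <- character(n)
  seq_out <- character(n)
  own_len <- r$end - r$start
  plain <- !r$is_chimeric
  cigar[plain] <- sprintf("%dM", own_len[plain])
  seq_out[plain] <- substr(seqs[r$fragment_id[plain]], r$start[plain] + 1L,
                           r$end[plain])
  if (any(!plain)) {
    ci <- which(!plain)
    for (i in ci) {
      Lown <- own_len[i]
      Lpart <- lens[[r$chimera_partner[i]]]
      full <- if (r$supplementary[i]) {
        paste0(seqs[[r$chimera_partner[i]]], seqs[[r$fragment_id[i]]])
      } else {
        paste0(seqs[[r$fragment_id[i]]], seqs[[r$chimera_partner[i]]])
      }
      cigar[i] <- if (r$supplementary[i]) sprintf("%dS%dM", Lpart, Lown)
                  else sprintf("%dM%dS", Lown, Lpart)
      seq_out[i] <- full
    }
  }
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  r$read_id, flag, r$fragment_id, r$start + 1L, cigar,
                  seq_out)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the simulation truth table
#' @param lib A `simulated_library`.
#' @param path TSV path.
#' @export
write_truth_tsv <- function(lib, path) {
  utils::write.table(lib$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
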