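#' Classify one read pair against one adjacent intron pair
#'
#' An intermediate read is a paired-end read in which one mate spans a
#' spliced exon-exon junction — its alignment contains a gap exactly equal to
#' one intron of the pair (that intron is removed) — while the other mate
#' overlaps the interval of the pair's other intron (that intron is
#' retained). Such a read witnesses which intron of the pair was removed
#' first: `upstream_first` when the gap matches the upstream intron,
#' `downstream_first` when it matches the downstream intron, otherwise
#' `uninformative`. Classification is symmetric in the two mates. A mate
#' whose gap matches one intron while the other mate overlaps only exonic
#' sequence is uninformative, as is a read pair simultaneously satisfying
#' both orientations.
#'
#' @param record one-row data.frame with `read_id`, `chrom`, `mate1_blocks`,
#'   `mate2_blocks` (block strings, see [parse_blocks()]).
#' @param pair one-row data.frame with the pair's coordinates
#'   (`chrom`, `up_start`, `up_end`, `dn_start`, `dn_end`).
#' @param min_overlap minimum overlap (nt) of the intronic mate with the
#'   retained intron (default 1).
#' @param junction_slop tolerance (nt) on junction-gap vs intron coordinate
#'   equality (default 0: exact).
#' @return one of `"upstream_first"`, `"downstream_first"`, `"uninformative"`.
#' @export
classify_read_pair <- function(record, pair, min_overlap = 1,
                               junction_slop = 0) {
  ev <- classify_read_pairs(record, pair, min_overlap = min_overlap,
                            junction_slop = junction_slop)
  if (nrow(ev) == 0) return("uninformative")
  ev$call[1]
}

# gaps of a block matrix: two-column matrix of (end_i, start_{i+1})
mate_gaps <- function(m) {
  if (nrow(m) < 2) return(matrix(integer(0), ncol = 2))
  cbind(m[-nrow(m), 2], m[-1, 1])
}

# total overlap (nt) of blocks with [s, e)
mate_overlap <- function(m, s, e) {
  if (nrow(m) == 0) return(0L)
  sum(pmax(0L, pmin(m[, 2], e) - pmax(m[, 1], s)))
}

#' Classify a stream of read pairs against a table of adjacent intron pairs
#'
#' Vectorized engine behind [classify_read_pair()]. A read pair informative
#' for two different adjacent pairs (the junction intron shared between them)
#' is counted once per pair it informs.
#'
#' @param reads data.frame with `read_id`, `chrom`, `mate1_blocks`,
#'   `mate2_blocks`.
#' @param pairs data.frame from [enumerate_adjacent_pairs()].
#' @inheritParams classify_read_pair
#' @return data.frame of evidence: `read_id`, `pair_id`, `call`
#'   (`upstream_first` / `downstream_first`); reads informing no pair yield
#'   no rows (they are uninformative by definition).
#' @export
classify_read_pairs <- function(reads, pairs, min_overlap = 1,
                                junction_slop = 0) {
  empty <- data.frame(read_id = character(0), pair_id = character(0),
                      call = character(0))
  if (nrow(reads) == 0 || nrow(pairs) == 0) return(empty)
  b1 <- parse_blocks(reads$mate1_blocks)
  b2 <- parse_blocks(reads$mate2_blocks)
  # gap table: one row per junction gap per mate per read
  gap_rows <- list()
  for (i in seq_len(nrow(reads))) {
    for (mate in 1:2) {
      g <- mate_gaps(if (mate == 1) b1[[i]] else b2[[i]])
      if (nrow(g) > 0)
        gap_rows[[length(gap_rows) + 1L]] <-
          data.frame(ri = i, mate = mate, gs = g[, 1], ge = g[, 2])
    }
  }
  if (length(gap_rows) == 0) return(empty)
  gaps <- do.call(rbind, gap_rows)
  upairs <- pairs[!duplicated(pairs$pair_id), ]
  out <- list()
  # exact (or slop-tolerant) matching of gap against an intron interval, per pair
  for (p in seq_len(nrow(upairs))) {
    pr <- upairs[p, ]
    onchr <- reads$chrom[gaps$ri] == pr$chrom
    up_hit <- onchr & abs(gaps$gs - pr$up_start) <= junction_slop &
      abs(gaps$ge - pr$up_end) <= junction_slop
    dn_hit <- onchr & abs(gaps$gs - pr$dn_start) <= junction_slop &
      abs(gaps$ge - pr$dn_end) <= junction_slop
    if (!any(up_hit) && !any(dn_hit)) next
    cand <- unique(gaps$ri[up_hit | dn_hit])
    for (ri in cand) {
      blocks <- list(b1[[ri]], b2[[ri]])
      uf <- FALSE; df_ <- FALSE
      for (mate in 1:2) {
        other <- blocks[[3 - mate]]
        if (any(up_hit & gaps$ri == ri & gaps$mate == mate) &&
            mate_overlap(other, pr$dn_start, pr$dn_end) >= min_overlap)
          uf <- TRUE
        if (any(dn_hit & gaps$ri == ri & gaps$mate == mate) &&
            mate_overlap(other, pr$up_start, pr$up_end) >= min_overlap)
          df_ <- TRUE
      }
      if (xor(uf, df_))
        out[[length(out) + 1L]] <- data.frame(
          read_id = reads$read_id[ri], pair_id = pr$pair_id,
          call = if (uf) "upstream_first" else "downstream_first")
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate order evidence into per-pair counts
#'
#' @param evidence data.frame from [classify_read_pairs()].
#' @param pairs optional pairs table; when given, all its pair_ids appear in
#'   the output (zero counts for pairs with no evidence).
#' @return data.frame `pair_id`, `n_upstream_first`, `n_downstream_first`,
#'   `n_total`, `fraction_downstream_first` (NA when no informative reads).
#' @export
accumulate_counts <- function(evidence, pairs = NULL) {
  ids <- if (!is.null(pairs)) unique(pairs$pair_id) else
    sort(unique(evidence$pair_id))
  nu <- table(factor(evidence$pair_id[evidence$call == "upstream_first"],
                     levels = ids))
  nd <- table(factor(evidence$pair_id[evidence$call == "downstream_first"],
                     levels = ids))
  out <- data.frame(pair_id = ids,
                    n_upstream_first = as.integer(nu),
                    n_downstream_first = as.integer(nd))
  out$n_total <- out$n_upstream_first + out$n_downstream_first
  out$fraction_downstream_first <-
    ifelse(out$n_total > 0, out$n_downstream_first / out$n_total, NA_real_)
  out
}

#' Retain pairs with at least `min_reads` intermediate reads
#'
#' Pairs with fewer informative reads than `min_reads` are discarded;
#' the default of 10 keeps pairs with 10 or more intermediate reads.
#'
#' @param counts data.frame from [accumulate_counts()].
#' @param min_reads minimum informative-read total (default 10).
#' @return `counts` with `passes_depth` set, filtered to retained pairs.
#' @export
apply_depth_filter <- function(counts, min_reads = 10) {
  counts$passes_depth <- counts$n_total >= min_reads
  counts[counts$passes_depth, , drop = FALSE]
}

#' Bin downstream-first fractions into an order distribution
#'
#' Equal-width bins over \[0, 1\]; the last bin is right-closed so a fraction
#' of exactly 1 is counted.
#'
#' @param fractions numeric vector in \[0, 1\] (NAs dropped).
#' @param n_bins number of bins (default 20).
#' @return `order_distribution` object: list with `bin_edges`
#'   (length `n_bins + 1`) and integer `counts`.
#' @export
bin_distribution <- function(fractions, n_bins = 20) {
  fractions <- fractions[!is.na(fractions)]
  stop_if(length(fractions) > 0 && (min(fractions) < 0 || max(fractions) > 1),
          "fractions must lie in [0, 1]")
  idx <- pmin(floor(fractions * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = seq(0, 1, length.out = n_bins + 1),
                 counts = counts),
            class = "order_distribution")
}

#' @export
print.order_distribution <- function(x, ...) {
  cat(sprintf("<order_distribution> %d bins, %s events\n",
              length(x$counts), format(sum(x$counts))))
  invisible(x)
}

#' Call always-first pairs at a fraction threshold
#'
#' A pair is downstream-always-first when its downstream intron was removed
#' first in at least `threshold` of its intermediate reads
#' (`fraction_downstream_first >= threshold`); upstream-always-first is the
#' mirror (`fraction <= 1 - threshold`). At the default 0.95 and the minimum
#' retained depth of 10 this is a 19:1 margin.
#'
#' @param counts depth-filtered counts from [apply_depth_filter()].
#' @param threshold always-first fraction threshold (default 0.95).
#' @return `counts` with logical `downstream_always_first` and
#'   `upstream_always_first` columns.
#' @export
call_always_first <- function(counts, threshold = 0.95) {
  counts$downstream_always_first <-
    counts$fraction_downstream_first >= threshold
  counts$upstream_always_first <-
    counts$fraction_downstream_first <= 1 - threshold
  counts
}

#' Call local-slowpoke introns
#'
#' An intron observed to splice after both its upstream and its downstream
#' neighbor is a local slowpoke — a candidate for dependency on neighboring
#' splicing events. For intron `i` of a transcript, "after its upstream
#' neighbor" means the pair `(i-1, i)` has `fraction_downstream_first <=
#' 1 - threshold` (the upstream member spliced first nearly always), and
#' "after its downstream neighbor" means the pair `(i, i+1)` has
#' `fraction_downstream_first >= threshold`. Both pairs must pass the depth
#' filter; first and last introns (a single neighbor) are not callable.
#'
#' @param counts depth-filtered counts from [apply_depth_filter()].
#' @param pairs pairs table carrying `transcript_id`, `up_index`, `dn_index`.
#' @param threshold always-first threshold (default 0.95).
#' @return data.frame per (transcript, intron): `transcript_id`, `index`,
#'   `after_upstream_neighbor`, `after_downstream_neighbor` (NA when the
#'   flanking pair is missing or unretained), `callable`, `local_slowpoke`.
#' @export
call_local_slowpokes <- function(counts, pairs, threshold = 0.95) {
  pc <- merge(pairs, counts, by = "pair_id")
  rows <- list()
  for (tid in unique(pc$transcript_id)) {
    d <- pc[pc$transcript_id == tid, ]
    n_introns <- d$n_introns[1]
    for (i in seq_len(n_introns)) {
      up_pair <- d[d$dn_index == i, ]   # pair (i-1, i): intron i is downstream
      dn_pair <- d[d$up_index == i, ]   # pair (i, i+1): intron i is upstream
      after_up <- if (nrow(up_pair) == 1)
        up_pair$fraction_downstream_first <= 1 - threshold else NA
      after_dn <- if (nrow(dn_pair) == 1)
        dn_pair$fraction_downstream_first >= threshold else NA
      callable <- !is.na(after_up) && !is.na(after_dn)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid, index = i,
        after_upstream_neighbor = after_up,
        after_downstream_neighbor = after_dn,
        callable = callable,
        local_slowpoke = if (callable) after_up && after_dn else NA)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), index = integer(0),
                      after_upstream_neighbor = logical(0),
                      after_downstream_neighbor = logical(0),
                      callable = logical(0), local_slowpoke = logical(0))
  rownames(out) <- NULL
  out
}

#' Summarize intron-level order calls
#'
#' Counts introns that nearly always spliced after their upstream neighbor,
#' after their downstream neighbor, and after both (local slowpokes), over
#' the callable introns of a cohort.
#'
#' @param slowpokes data.frame from [call_local_slowpokes()].
#' @return named list of counts.
#' @export
summarize_intron_calls <- function(slowpokes) {
  list(n_after_upstream = sum(slowpokes$after_upstream_neighbor, na.rm = TRUE),
       n_after_downstream = sum(slowpokes$after_downstream_neighbor, na.rm = TRUE),
       n_local_slowpokes = sum(slowpokes$local_slowpoke, na.rm = TRUE),
       n_callable = sum(slowpokes$callable))
}
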