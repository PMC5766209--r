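#' Build gene models from an exon table
#'
#' A gene model is one transcript's ordered exons plus the introns derived as
#' the gaps between consecutive exons, indexed in transcription order (on the
#' minus strand, transcription order runs from high to low genomic
#' coordinate). All coordinates are 0-based half-open.
#'
#' @param exon_table data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand` (one row per exon; order irrelevant).
#' @return list of `gene_model` objects (class `gene_model_list`). Transcripts
#'   whose exons overlap one another are skipped with a warning; malformed
#'   rows (start >= end, bad strand) raise an error naming the offending rows.
#' @examples
#' tab <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'                   start = c(100, 300, 500), end = c(200, 400, 600),
#'                   strand = "+")
#' m <- build_gene_models(tab)
#' m[[1]]$introns  # two introns: [200,300) and [400,500)
#' @export
build_gene_models <- function(exon_table) {
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  stop_if(!all(req %in% names(exon_table)),
          "exon_table must have columns: ", paste(req, collapse = ", "))
  bad <- which(exon_table$start >= exon_table$end |
                 !exon_table$strand %in% c("+", "-"))
  stop_if(length(bad) > 0,
          "malformed exon records at rows: ", paste(utils::head(bad, 5), collapse = ", "))
  models <- list()
  for (tid in unique(exon_table$transcript_id)) {
    ex <- exon_table[exon_table$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$end[-nrow(ex)] > ex$start[-1])) {
      warning("transcript ", tid, " has overlapping exons; skipped")
      next
    }
    models[[tid]] <- new_gene_model(tid, ex$gene_id[1], ex$chrom[1],
                                    ex$strand[1], ex$start, ex$end)
  }
  structure(models, class = "gene_model_list")
}

# exon starts/ends in ascending genomic order
new_gene_model <- function(transcript_id, gene_id, chrom, strand,
                           exon_starts, exon_ends) {
  n <- length(exon_starts)
  exons <- data.frame(start = exon_starts, end = exon_ends)
  if (n > 1) {
    istart <- exon_ends[-n]
    iend <- exon_starts[-1]
    # transcription order: ascending genomic for '+', descending for '-'
    ord <- if (strand == "+") seq_len(n - 1) else rev(seq_len(n - 1))
    introns <- data.frame(
      start = istart[ord], end = iend[ord],
      index = seq_len(n - 1),
      ss5 = if (strand == "+") istart[ord] else iend[ord],
      ss3 = if (strand == "+") iend[ord] else istart[ord])
  } else {
    introns <- data.frame(start = integer(0), end = integer(0),
                          index = integer(0), ss5 = integer(0),
                          ss3 = integer(0))
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 introns = introns),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s%s: %d exons, %d introns\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Collect the genome-wide intron table from a set of gene models
#'
#' @param models `gene_model_list` from [build_gene_models()].
#' @return data.frame with one row per (transcript, intron): `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `index`, `ss5`, `ss3`.
#' @export
all_introns <- function(models) {
  out <- lapply(models, function(m) {
    if (nrow(m$introns) == 0) return(NULL)
    data.frame(transcript_id = m$transcript_id, gene_id = m$gene_id,
               chrom = m$chrom, strand = m$strand, m$introns)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0), index = integer(0),
                      ss5 = integer(0), ss3 = integer(0))
  rownames(out) <- NULL
  out
}

#' Enumerate adjacent intron pairs
#'
#' The adjacent intron pair — two consecutive introns of one transcript
#' separated by a single internal exon — is the unit of pairwise
#' order-of-splicing measurement. One row is produced per consecutive intron
#' couple per transcript (`intron count - 1` rows per transcript). Pairs with
#' identical coordinates arising from different transcripts share a
#' coordinate-derived `pair_id`, so read counting downstream aggregates over
#' isoforms while `transcript_id` records the contributors.
#'
#' @param models `gene_model_list`.
#' @return data.frame with columns `pair_id`, `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `up_index`, `dn_index`, `n_introns`, upstream /
#'   internal-exon / downstream coordinates (`up_start`, `up_end`,
#'   `exon_start`, `exon_end`, `dn_start`, `dn_end`), splice sites and lengths
#'   (`up_len`, `dn_len`, `exon_len`).
#' @export
enumerate_adjacent_pairs <- function(models) {
  rows <- lapply(models, function(m) {
    n <- nrow(m$introns)
    if (n < 2) return(NULL)
    up <- m$introns[seq_len(n - 1), ]
    dn <- m$introns[2:n, ]
    # internal exon lies between the pair's introns in genomic space
    exon_start <- if (m$strand == "+") up$end else dn$end
    exon_end <- if (m$strand == "+") dn$start else up$start
    data.frame(
      pair_id = paste(m$chrom, m$strand, up$start, up$end, dn$start, dn$end,
                      sep = ":"),
      transcript_id = m$transcript_id, gene_id = m$gene_id,
      chrom = m$chrom, strand = m$strand,
      up_index = up$index, dn_index = dn$index, n_introns = n,
      up_start = up$start, up_end = up$end,
      exon_start = exon_start, exon_end = exon_end,
      dn_start = dn$start, dn_end = dn$end,
      up_ss5 = up$ss5, up_ss3 = up$ss3, dn_ss5 = dn$ss5, dn_ss3 = dn$ss3,
      up_len = up$end - up$start, dn_len = dn$end - dn$start,
      exon_len = exon_end - exon_start)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_pairs())
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(pair_id = character(0), transcript_id = character(0),
             gene_id = character(0), chrom = character(0),
             strand = character(0), up_index = integer(0),
             dn_index = integer(0), n_introns = integer(0),
             up_start = integer(0), up_end = integer(0),
             exon_start = integer(0), exon_end = integer(0),
             dn_start = integer(0), dn_end = integer(0),
             up_ss5 = integer(0), up_ss3 = integer(0), dn_ss5 = integer(0),
             dn_ss3 = integer(0), up_len = integer(0), dn_len = integer(0),
             exon_len = integer(0))
}

#' Flag pairs whose introns have genome-wide unique splice sites
#'
#' A pair is `unique` when neither of its introns shares a 5' or 3'
#' splice-site coordinate with any other annotated intron. By default the
#' comparison is over the full coordinate multiset of `intron_set`, so an
#' intron annotated identically in two transcripts of the same gene is
#' non-unique; `unique_scope = "gene"` first collapses duplicate intron
#' records within a gene.
#'
#' @param pairs data.frame from [enumerate_adjacent_pairs()].
#' @param intron_set genome-wide intron table from [all_introns()].
#' @param unique_scope `"transcript"` (strict multiset, default) or `"gene"`.
#' @return `pairs` with a logical `unique` column added.
#' @export
flag_unique_introns <- function(pairs, intron_set,
                                unique_scope = c("transcript", "gene")) {
  unique_scope <- match.arg(unique_scope)
  ii <- intron_set
  if (unique_scope == "gene")
    ii <- ii[!duplicated(ii[, c("gene_id", "chrom", "strand", "start", "end")]), ]
  k5 <- table(interval_key(ii$chrom, ii$ss5, "5", ii$strand))
  k3 <- table(interval_key(ii$chrom, ii$ss3, "3", ii$strand))
  site_unique <- function(chrom, strand, ss5, ss3) {
    u5 <- as.integer(k5[interval_key(chrom, ss5, "5", strand)]) == 1L
    u3 <- as.integer(k3[interval_key(chrom, ss3, "3", strand)]) == 1L
    u5 & u3
  }
  pairs$unique <- site_unique(pairs$chrom, pairs$strand, pairs$up_ss5, pairs$up_ss3) &
    site_unique(pairs$chrom, pairs$strand, pairs$dn_ss5, pairs$dn_ss3)
  pairs$unique[is.na(pairs$unique)] <- FALSE
  pairs
}

#' Assign first / middle / last positional categories
#'
#' Pairs containing the first and second introns of a transcript are `first`
#' pairs; pairs containing the second-to-last and last introns are `last`;
#' everything else is `middle`. Only transcripts with more than two introns
#' are labeled; pairs of shorter transcripts get `NA`.
#'
#' @param pairs data.frame from [enumerate_adjacent_pairs()].
#' @return `pairs` with a `positional` factor column (`first`/`middle`/`last`).
#' @export
assign_positional_category <- function(pairs) {
  pos <- rep(NA_character_, nrow(pairs))
  eligible <- pairs$n_introns > 2
  pos[eligible & pairs$up_index == 1] <- "first"
  pos[eligible & pairs$dn_index == pairs$n_introns] <- "last"
  pos[eligible & is.na(pos)] <- "middle"
  pairs$positional <- factor(pos, levels = c("first", "middle", "last"))
  pairs
}

#' Find skippable exons: annotated introns matching an exon-skipping junction
#'
#' An annotated intron is a skipping intron when its 5' splice site exactly
#' matches the 5' splice site of one intron and its 3' splice site the 3'
#' splice site of a following consecutive intron of some transcript (the
#' inclusion isoform), excising the intervening exon(s). Events spanning up to
#' `max_skipped` exons are reported.
#'
#' @param models `gene_model_list`.
#' @param max_skipped maximum number of skipped exons per event (default 2).
#' @return data.frame of events: `transcript_id` (inclusion isoform), `chrom`,
#'   `strand`, `skip_start`/`skip_end` (the skipping intron's interval),
#'   `first_index`/`last_index` (transcription-order indices of the flanked
#'   introns), `n_skipped`, `skip_transcript_id` (a transcript carrying the
#'   skipping intron), `skipped_exons` (collapsed `start-end` list).
#' @export
find_skippable_exons <- function(models, max_skipped = 2) {
  ii <- all_introns(models)
  ikey <- interval_key(ii$chrom, ii$start, ii$end, ii$strand)
  events <- list()
  for (m in models) {
    n <- nrow(m$introns)
    if (n < 2) next
    for (s in seq_len(min(max_skipped, n - 1))) {
      for (i in seq_len(n - s)) {
        a <- m$introns[i, ]; b <- m$introns[i + s, ]
        # outer genomic interval joining ss5(first) to ss3(last)
        if (m$strand == "+") { st <- a$start; en <- b$end }
        else { st <- b$start; en <- a$end }
        key <- interval_key(m$chrom, st, en, m$strand)
        hit <- which(ikey == key & ii$transcript_id != m$transcript_id)
        if (length(hit) == 0) next
        inner <- m$introns[i:(i + s), ]
        ex_lo <- if (m$strand == "+") inner$end[-nrow(inner)] else inner$end[-1]
        ex_hi <- if (m$strand == "+") inner$start[-1] else inner$start[-nrow(inner)]
        events[[length(events) + 1L]] <- data.frame(
          transcript_id = m$transcript_id, chrom = m$chrom, strand = m$strand,
          skip_start = st, skip_end = en,
          first_index = i, last_index = i + s, n_skipped = s,
          skip_transcript_id = ii$transcript_id[hit[1]],
          skipped_exons = paste(paste0(ex_lo, "-", ex_hi), collapse = ","))
      }
    }
  }
  if (length(events) == 0)
    return(data.frame(transcript_id = character(0), chrom = character(0),
                      strand = character(0), skip_start = integer(0),
                      skip_end = integer(0), first_index = integer(0),
                      last_index = integer(0), n_skipped = integer(0),
                      skip_transcript_id = character(0),
                      skipped_exons = character(0)))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

# append a label to the semicolon-separated categories column
add_label <- function(categories, idx, label) {
  cur <- categories[idx]
  has <- vapply(strsplit(cur, ";", fixed = TRUE), function(v) label %in% v,
                logical(1))
  categories[idx][!has] <- ifelse(cur[!has] == "", label,
                                  paste(cur[!has], label, sep = ";"))
  categories
}

#' Label pairs of inclusion isoforms around exon-skipping events
#'
#' For single-exon skipping between introns `(i, i+1)` of the inclusion
#' isoform: the pair around the exon upstream of the skipped exon (`i-1, i`)
#' gets `skip_before`, the pair flanking the skipped exon (`i, i+1`) gets
#' `skip_internal`, and the pair around the downstream exon (`i+1, i+2`) gets
#' `skip_after`. For multi-exon events spanning introns `i..i+s` (s >= 2),
#' pairs wholly inside the event get `multi_skip_middle` and the pairs
#' immediately outside (`i-1, i` and `i+s, i+s+1`) get `multi_skip_flank`.
#'
#' @param pairs data.frame from [enumerate_adjacent_pairs()] (a `categories`
#'   column is created if absent).
#' @param events data.frame from [find_skippable_exons()].
#' @return `pairs` with updated `categories`.
#' @export
label_skip_categories <- function(pairs, events) {
  if (!"categories" %in% names(pairs)) pairs$categories <- ""
  for (r in seq_len(nrow(events))) {
    e <- events[r, ]
    tid <- e$transcript_id; i <- e$first_index; j <- e$last_index
    prow <- function(a, b) which(pairs$transcript_id == tid &
                                   pairs$up_index == a & pairs$dn_index == b)
    if (e$n_skipped == 1) {
      pairs$categories <- add_label(pairs$categories, prow(i - 1, i), "skip_before")
      pairs$categories <- add_label(pairs$categories, prow(i, j), "skip_internal")
      pairs$categories <- add_label(pairs$categories, prow(j, j + 1), "skip_after")
    } else {
      for (k in i:(j - 1))
        pairs$categories <- add_label(pairs$categories, prow(k, k + 1),
                                      "multi_skip_middle")
      pairs$categories <- add_label(pairs$categories, prow(i - 1, i),
                                    "multi_skip_flank")
      pairs$categories <- add_label(pairs$categories, prow(j, j + 1),
                                    "multi_skip_flank")
    }
  }
  pairs
}

#' Group introns by alternative 5' / 3' splice-site usage
#'
#' An alternative-5'ss group is a set of introns sharing an identical 3'
#' splice site but differing in 5' splice site; the representative used in
#' pair analysis is the shortest intron of the group. Alternative-3'ss groups
#' are symmetric (shared 5'ss, differing 3'ss; shortest representative).
#'
#' @param intron_set genome-wide intron table from [all_introns()].
#' @return list with `alt5` and `alt3` data.frames (`group_id`, intron
#'   coordinates, `len`, logical `representative`), deduplicated by coordinate.
#' @export
collapse_alt_ss <- function(intron_set) {
  ii <- intron_set[!duplicated(intron_set[, c("chrom", "strand", "start", "end")]), ]
  ii$len <- ii$end - ii$start
  group_by_site <- function(shared, varying) {
    key <- interval_key(ii$chrom, ii[[shared]], shared, ii$strand)
    grp <- split(seq_len(nrow(ii)), key)
    grp <- grp[vapply(grp, function(idx) length(unique(ii[[varying]][idx])) >= 2,
                      logical(1))]
    if (length(grp) == 0)
      return(data.frame(group_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), len = integer(0),
                        representative = logical(0)))
    out <- do.call(rbind, lapply(names(grp), function(g) {
      d <- ii[grp[[g]], c("chrom", "strand", "start", "end", "len")]
      d$group_id <- g
      d$representative <- d$len == min(d$len)
      # ties broken by genomic position for determinism
      if (sum(d$representative) > 1) {
        w <- which(d$representative)
        d$representative[w[-which.min(d$start[w])]] <- FALSE
      }
      d
    }))
    rownames(out) <- NULL
    out[, c("group_id", "chrom", "strand", "start", "end", "len", "representative")]
  }
  list(alt5 = group_by_site("ss3", "ss5"), alt3 = group_by_site("ss5", "ss3"))
}

#' Label pairs containing alternative-splice-site representative introns
#'
#' Pairs in which either intron is the representative (shortest) member of an
#' alternative-5'ss group get `alt5_flank`; likewise `alt3_flank`.
#'
#' @param pairs data.frame from [enumerate_adjacent_pairs()].
#' @param alt result of [collapse_alt_ss()].
#' @return `pairs` with updated `categories`.
#' @export
label_alt_ss_categories <- function(pairs, alt) {
  if (!"categories" %in% names(pairs)) pairs$categories <- ""
  upk <- interval_key(pairs$chrom, pairs$up_start, pairs$up_end, pairs$strand)
  dnk <- interval_key(pairs$chrom, pairs$dn_start, pairs$dn_end, pairs$strand)
  for (side in c("alt5", "alt3")) {
    g <- alt[[side]]
    rep_keys <- interval_key(g$chrom[g$representative], g$start[g$representative],
                             g$end[g$representative], g$strand[g$representative])
    idx <- which(upk %in% rep_keys | dnk %in% rep_keys)
    pairs$categories <- add_label(pairs$categories, idx, paste0(side, "_flank"))
  }
  pairs
}

#' Match back-splice circles to adjacent intron pairs
#'
#' A circle's transcription-order beginning coordinate is matched to the
#' internal-exon boundary contributed by a pair's upstream intron (`before`
#' pairs: splicing order upstream of the circle); its end coordinate to the
#' 5' splice site of a pair's downstream intron (`after` pairs). Matching is
#' exact coordinate equality by default; `slop` tolerates off-by-n annotation
#' drift.
#'
#' @param circles data.frame with `chrom`, `start`, `end` (BED3 convention,
#'   same 0-based half-open coordinates as introns).
#' @param pairs data.frame from [enumerate_adjacent_pairs()].
#' @param slop integer tolerance in nt (default 0).
#' @return list with `before` and `after` integer vectors of pair row indices,
#'   `pairs` (with `circle_before`/`circle_after` added to `categories`), and
#'   `n_unmatched` circles matching no pair.
#' @export
match_circles <- function(circles, pairs, slop = 0) {
  if (!"categories" %in% names(pairs)) pairs$categories <- ""
  before <- integer(0); after <- integer(0)
  matched <- rep(FALSE, nrow(circles))
  near <- function(a, b) abs(a - b) <= slop
  for (r in seq_len(nrow(circles))) {
    cc <- circles[r, ]
    onchr <- pairs$chrom == cc$chrom
    plus <- onchr & pairs$strand == "+"
    minus <- onchr & pairs$strand == "-"
    # transcription-order circle start = genomic start on '+', end on '-'
    b_idx <- which((plus & near(cc$start, pairs$up_end)) |
                     (minus & near(cc$end, pairs$up_start)))
    a_idx <- which((plus & near(cc$end, pairs$dn_start)) |
                     (minus & near(cc$start, pairs$dn_end)))
    if (length(b_idx) || length(a_idx)) matched[r] <- TRUE
    before <- c(before, b_idx); after <- c(after, a_idx)
  }
  before <- sort(unique(before)); after <- sort(unique(after))
  pairs$categories <- add_label(pairs$categories, before, "circle_before")
  pairs$categories <- add_label(pairs$categories, after, "circle_after")
  n_unmatched <- sum(!matched)
  if (n_unmatched > 0)
    message(n_unmatched, " circle(s) matched no pair and were dropped")
  list(before = before, after = after, pairs = pairs,
       n_unmatched = n_unmatched)
}

#' Predict circle-candidate exons from flanking intron length
#'
#' Internal exons whose two flanking introns are both at least
#' `min_flank_len` nt long are candidates for exon circularization; an
#' optional whitelist of exon identifiers (`chrom:start-end`) stands in for
#' annotation-based filters such as conserved CDS starts. The complementary
#' negative predicate (both flanks shorter than `neg_max_flank`) is also
#' reported.
#'
#' @param models `gene_model_list`.
#' @param min_flank_len minimum flanking intron length in nt (default 10000).
#' @param exon_whitelist optional character vector of `chrom:start-end` keys.
#' @param neg_max_flank flank length below which an exon matches the negative
#'   (not-a-circle) predicate (default 250).
#' @return data.frame of internal exons with flanking intron lengths,
#'   `candidate` and `negative_prediction` logicals.
#' @export
predict_circle_candidates <- function(models, min_flank_len = 10000,
                                      exon_whitelist = NULL,
                                      neg_max_flank = 250) {
  rows <- lapply(models, function(m) {
    n <- nrow(m$introns)
    if (n < 2) return(NULL)
    # internal exon k (transcription order) sits between introns k-1 and k
    ord <- order(m$introns$index)
    intr <- m$introns[ord, ]
    k <- 2:n
    ex_start <- if (m$strand == "+") intr$end[k - 1] else intr$end[k]
    ex_end <- if (m$strand == "+") intr$start[k] else intr$start[k - 1]
    data.frame(transcript_id = m$transcript_id, chrom = m$chrom,
               strand = m$strand, exon_start = ex_start, exon_end = ex_end,
               up_flank_len = intr$end[k - 1] - intr$start[k - 1],
               dn_flank_len = intr$end[k] - intr$start[k])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(transcript_id = character(0), chrom = character(0),
                      strand = character(0), exon_start = integer(0),
                      exon_end = integer(0), up_flank_len = integer(0),
                      dn_flank_len = integer(0), exon_key = character(0),
                      candidate = logical(0), negative_prediction = logical(0)))
  rownames(out) <- NULL
  out$exon_key <- paste0(out$chrom, ":", out$exon_start, "-", out$exon_end)
  out$candidate <- out$up_flank_len >= min_flank_len &
    out$dn_flank_len >= min_flank_len
  if (!is.null(exon_whitelist))
    out$candidate <- out$candidate & out$exon_key %in% exon_whitelist
  out$negative_prediction <- out$up_flank_len < neg_max_flank &
    out$dn_flank_len < neg_max_flank
  out
}

#' Annotate pairs with every structural / alternative-splicing category
#'
#' Convenience wrapper running [assign_positional_category()],
#' [find_skippable_exons()] + [label_skip_categories()], [collapse_alt_ss()] +
#' [label_alt_ss_categories()], and — when `circles` is supplied —
#' [match_circles()].
#'
#' @param pairs data.frame from [enumerate_adjacent_pairs()].
#' @param models the `gene_model_list` the pairs came from.
#' @param circles optional BED3 data.frame of back-splice junction spans.
#' @param max_skipped maximum skipped exons per event.
#' @param circle_slop matching tolerance passed to [match_circles()].
#' @return `pairs` with `positional`, `categories` and `unique` columns.
#' @export
annotate_pairs <- function(pairs, models, circles = NULL, max_skipped = 2,
                           circle_slop = 0) {
  pairs <- assign_positional_category(pairs)
  pairs <- flag_unique_introns(pairs, all_introns(models))
  pairs$categories <- ""
  pairs <- label_skip_categories(pairs, find_skippable_exons(models, max_skipped))
  pairs <- label_alt_ss_categories(pairs, collapse_alt_ss(all_introns(models)))
  if (!is.null(circles)) pairs <- match_circles(circles, pairs, circle_slop)$pairs
  pairs
}
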