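#' Intron length-difference analysis of splicing order
#'
#' For each pair the length difference is the upstream intron's length minus
#' the downstream intron's length (negative = longer downstream intron).
#' Pairs are binned by length difference and, per bin, the fraction of pairs
#' in which the downstream intron spliced first at least `always_threshold`
#' of the time is reported; the per-bin downstream-first fractions are kept
#' for histogramming.
#'
#' @param pairs_counts pairs joined with depth-filtered counts: needs
#'   `up_len`, `dn_len`, `fraction_downstream_first`.
#' @param bin_width bin width in nt (default 500).
#' @param range inner binning range; differences outside fall into open outer
#'   bins (default c(-10000, 10000)).
#' @param always_threshold downstream-always-first threshold (default 0.95).
#' @return list: `bins` data.frame (`diff_lo`, `diff_hi`, `n_pairs`,
#'   `frac_downstream_always_first` — NA for empty bins) and
#'   `fractions_by_bin` (list of per-bin fraction vectors).
#' @export
length_difference_analysis <- function(pairs_counts, bin_width = 500,
                                       range = c(-10000, 10000),
                                       always_threshold = 0.95) {
  d <- pairs_counts[!is.na(pairs_counts$fraction_downstream_first), ,
                    drop = FALSE]
  diff <- d$up_len - d$dn_len
  inner <- seq(range[1], range[2], by = bin_width)
  edges <- c(-Inf, inner, Inf)
  idx <- findInterval(diff, inner) + 1L  # 1 = below range, length(inner)+1 = above
  n_bins <- length(edges) - 1
  bins <- data.frame(diff_lo = edges[-length(edges)], diff_hi = edges[-1])
  fr_by_bin <- lapply(seq_len(n_bins), function(b)
    d$fraction_downstream_first[idx == b])
  bins$n_pairs <- vapply(fr_by_bin, length, integer(1))
  bins$frac_downstream_always_first <- vapply(fr_by_bin, function(f)
    if (length(f) == 0) NA_real_ else mean(f >= always_threshold), numeric(1))
  list(bins = bins, fractions_by_bin = fr_by_bin)
}

#' Motif match density in a sequence
#'
#' Exact matches of the motif on the sense strand, counted non-overlapping by
#' default (`overlapping = TRUE` counts every start position), divided by the
#' sequence length. U is mapped to T on both sides; matching is
#' case-insensitive. A sequence shorter than the motif has density 0.
#'
#' @param sequence character (or `DNAString`) sense-strand sequence.
#' @param motif motif string (ACGTU alphabet, length >= 4).
#' @param overlapping count overlapping occurrences (default FALSE).
#' @return matches per nt.
#' @export
motif_density <- function(sequence, motif, overlapping = FALSE) {
  seq_ <- chartr("Uu", "Tt", toupper(as.character(sequence)))
  motif <- chartr("U", "T", toupper(as.character(motif)))
  stop_if(nchar(motif) < 4, "motif length must be >= 4")
  n <- nchar(seq_)
  if (n < nchar(motif) || n == 0) return(0)
  count <- if (overlapping) {
    length(Biostrings::matchPattern(motif, Biostrings::DNAString(seq_)))
  } else {
    hits <- gregexpr(motif, seq_, fixed = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }
  count / n
}

#' Motif density enrichment between always-first and always-last introns
#'
#' For each motif of a panel, per-intron sense-strand match densities are
#' compared between the two groups with a Wilcoxon rank-sum test; p-values
#' are corrected across the panel by Benjamini-Hochberg. The effect direction
#' (enriched in first- vs last-splicing introns) is the sign of the group
#' mean difference.
#'
#' @param first_seqs,last_seqs named character vectors (or `DNAStringSet`s)
#'   of intron sequences for the always-first and always-last groups.
#' @param motifs data.frame with `motif` and `rbp_name` columns.
#' @param overlapping passed to [motif_density()].
#' @return data.frame per motif: `motif`, `rbp_name`, `density_first`,
#'   `density_last` (group means), `statistic` (rank-sum W), `p_value`,
#'   `fdr`, `enriched_in` (`first`/`last`/`none`), `low_power` (TRUE when
#'   either group has fewer than 5 sequences).
#' @export
motif_enrichment <- function(first_seqs, last_seqs, motifs,
                             overlapping = FALSE) {
  first_seqs <- as.character(first_seqs)
  last_seqs <- as.character(last_seqs)
  stop_if(length(first_seqs) == 0 || length(last_seqs) == 0,
          "both intron groups must be non-empty")
  low_power <- min(length(first_seqs), length(last_seqs)) < 5
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- motifs$motif[i]
    df <- vapply(first_seqs, motif_density, numeric(1), motif = m,
                 overlapping = overlapping)
    dl <- vapply(last_seqs, motif_density, numeric(1), motif = m,
                 overlapping = overlapping)
    if (length(unique(c(df, dl))) == 1L) {
      w <- NA_real_; p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(df, dl, exact = FALSE))
      w <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(motif = m, rbp_name = motifs$rbp_name[i],
               density_first = mean(df), density_last = mean(dl),
               statistic = w, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched_in <- ifelse(out$density_first > out$density_last, "first",
                            ifelse(out$density_first < out$density_last,
                                   "last", "none"))
  out$low_power <- low_power
  out
}

#' Per-category order-of-splicing histograms
#'
#' Builds one order distribution per category label (positional
#' first/middle/last, skipping, alternative splice site, circle-flanking)
#' plus the all-pairs background. A pair carrying several labels contributes
#' to each of their histograms.
#'
#' @param pairs_counts pairs joined with depth-filtered counts: needs
#'   `fraction_downstream_first` plus `positional` and/or `categories`.
#' @param n_bins histogram bins (default 20).
#' @return named list of `order_distribution`s; element `all` is the
#'   background. Labels present in the annotation but carried by zero
#'   retained pairs yield empty histograms with a warning.
#' @export
category_histograms <- function(pairs_counts, n_bins = 20) {
  d <- pairs_counts[!is.na(pairs_counts$fraction_downstream_first), ,
                    drop = FALSE]
  out <- list(all = bin_distribution(d$fraction_downstream_first, n_bins))
  if ("positional" %in% names(d)) {
    for (lv in levels(d$positional)) {
      f <- d$fraction_downstream_first[!is.na(d$positional) & d$positional == lv]
      if (length(f) == 0) warning("positional category '", lv, "' has 0 pairs")
      out[[lv]] <- bin_distribution(f, n_bins)
    }
  }
  if ("categories" %in% names(d)) {
    labs <- sort(unique(unlist(strsplit(d$categories, ";", fixed = TRUE))))
    labs <- labs[nzchar(labs)]
    for (lb in labs) {
      has <- vapply(strsplit(d$categories, ";", fixed = TRUE),
                    function(v) lb %in% v, logical(1))
      out[[lb]] <- bin_distribution(d$fraction_downstream_first[has], n_bins)
    }
  }
  out
}
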