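#' Specification of a synthetic co-transcriptionally spliced locus
#'
#' Describes one synthetic transcript: alternating exon/intron lengths, true
#' per-intron splicing rates (or `NULL` to draw them from the kinetic rate
#' distribution), optional directed dependency edges `i -> j` meaning intron
#' `j` cannot splice until intron `i` has been removed, and read-emission
#' settings. The dependency graph must be acyclic.
#'
#' @param exon_lengths integer vector of exon lengths (nt), transcription
#'   order.
#' @param intron_lengths integer vector, one fewer than exons.
#' @param rates per-intron splicing rates (introns/min) or NULL to draw.
#' @param dependencies list of length-2 integer vectors `c(parent, child)`.
#' @param n_molecules molecules to simulate (default 1000).
#' @param read_length length of each mate (nt, default 100).
#' @param capture_rate probability an intermediate passage emits a read pair
#'   (default 1).
#' @param background_rate per-molecule rate of uninformative exonic read
#'   pairs (default 0).
#' @param harvest `"steady_state"` (molecules initiated continuously,
#'   observed at a common endpoint) or `"endpoint"` (all molecules observed
#'   at age `harvest_time`).
#' @param harvest_time observation age in minutes for endpoint harvest.
#' @param seed RNG seed used by [generate_locus()] when drawing rates.
#' @return object of class `synthetic_locus_spec`.
#' @export
synthetic_locus_spec <- function(exon_lengths, intron_lengths, rates = NULL,
                                 dependencies = list(), n_molecules = 1000,
                                 read_length = 100, capture_rate = 1,
                                 background_rate = 0,
                                 harvest = c("steady_state", "endpoint"),
                                 harvest_time = NULL, seed = NULL) {
  harvest <- match.arg(harvest)
  n_int <- length(intron_lengths)
  stop_if(n_int != length(exon_lengths) - 1,
          "need |intron_lengths| = |exon_lengths| - 1")
  stop_if(any(exon_lengths <= 0) || any(intron_lengths <= 0),
          "lengths must be positive")
  stop_if(!is.null(rates) && (length(rates) != n_int || any(rates <= 0)),
          "rates must be one positive value per intron")
  for (e in dependencies)
    stop_if(length(e) != 2 || any(e < 1) || any(e > n_int) || e[1] == e[2],
            "dependency edges must be c(parent, child) over intron indices")
  topo_order(n_int, dependencies)  # errors on cycles
  stop_if(harvest == "endpoint" && is.null(harvest_time),
          "endpoint harvest requires harvest_time")
  structure(list(exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 rates = rates,
                 dependencies = lapply(dependencies, as.integer),
                 n_molecules = as.integer(n_molecules),
                 read_length = as.integer(read_length),
                 capture_rate = capture_rate,
                 background_rate = background_rate,
                 harvest = harvest, harvest_time = harvest_time,
                 seed = seed),
            class = "synthetic_locus_spec")
}

# Kahn topological sort; errors on cycles.
topo_order <- function(n, edges) {
  indeg <- integer(n)
  adj <- vector("list", n)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    indeg[e[2]] <- indeg[e[2]] + 1L
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  stop_if(length(out) != n, "dependency graph contains a cycle")
  out
}

#' Generate a synthetic gene model and its order-of-splicing truth table
#'
#' Lays the locus out on the plus strand of a synthetic chromosome, resolves
#' splicing rates (drawing from `params` when the spec leaves them `NULL`),
#' and computes the analytic expected downstream-first fraction for every
#' adjacent pair: the closed-form kinetic probability when the pair is free
#' of dependencies, 0 or 1 when a dependency path forces the order, and `NA`
#' (flagged `dependent`) when other dependencies touch the pair without
#' fully determining it.
#'
#' @param spec `synthetic_locus_spec`.
#' @param params `kinetic_params` used for rate draws and the truth delays.
#' @param chrom synthetic chromosome name (default "synth1").
#' @param origin genomic start of the first exon (default 0).
#' @param transcript_id,gene_id identifiers.
#' @return list: `model` (`gene_model`), `pairs`
#'   (from [enumerate_adjacent_pairs()]), `truth`
#'   (see [truth_report()]), `rates` (resolved per-intron rates), `spec`
#'   (with rates filled in).
#' @export
generate_locus <- function(spec, params = kinetic_params(), chrom = "synth1",
                           origin = 0, transcript_id = "synthT1",
                           gene_id = "synthG1") {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_int <- length(spec$intron_lengths)
  if (is.null(spec$rates)) spec$rates <- draw_splicing_rate(n_int, params)
  seg <- integer(0)
  for (i in seq_along(spec$exon_lengths)) {
    seg <- c(seg, spec$exon_lengths[i])
    if (i <= n_int) seg <- c(seg, spec$intron_lengths[i])
  }
  bounds <- origin + cumsum(c(0L, seg))
  exon_idx <- seq(1, length(seg), by = 2)
  model <- new_gene_model(transcript_id, gene_id, chrom, "+",
                          bounds[exon_idx], bounds[exon_idx + 1])
  models <- structure(stats::setNames(list(model), transcript_id),
                      class = "gene_model_list")
  pairs <- enumerate_adjacent_pairs(models)
  truth <- truth_report(spec, params)
  truth$pair_id <- pairs$pair_id
  list(model = model, pairs = pairs, truth = truth, rates = spec$rates,
       spec = spec)
}

#' Analytic expected order-of-splicing per adjacent pair of a synthetic locus
#'
#' @param spec `synthetic_locus_spec` with `rates` resolved.
#' @param params `kinetic_params` (transcription rate for delays).
#' @return data.frame per adjacent pair: `up_index`, `dn_index`,
#'   `expected_fraction_downstream_first`, `dependent` (TRUE when a
#'   dependency involves the pair), `forced` (TRUE when the expected
#'   fraction is exactly 0 or 1 by dependency).
#' @export
truth_report <- function(spec, params = kinetic_params()) {
  stop_if(is.null(spec$rates),
          "spec$rates must be resolved (see generate_locus)")
  n_int <- length(spec$intron_lengths)
  n_pairs <- max(0L, n_int - 1L)
  reach <- dependency_reachability(n_int, spec$dependencies)
  has_parent <- rep(FALSE, n_int)
  for (e in spec$dependencies) has_parent[e[2]] <- TRUE
  out <- data.frame(up_index = seq_len(n_pairs),
                    dn_index = seq_len(n_pairs) + 1L)
  out$expected_fraction_downstream_first <- NA_real_
  out$dependent <- FALSE
  out$forced <- FALSE
  for (p in seq_len(n_pairs)) {
    i <- p; j <- p + 1L
    if (reach[i, j]) {          # upstream must splice first
      out$expected_fraction_downstream_first[p] <- 0
      out$dependent[p] <- TRUE; out$forced[p] <- TRUE
    } else if (reach[j, i]) {   # downstream must splice first
      out$expected_fraction_downstream_first[p] <- 1
      out$dependent[p] <- TRUE; out$forced[p] <- TRUE
    } else if (!has_parent[i] && !has_parent[j]) {
      delay <- pair_delay(spec$exon_lengths[j], spec$intron_lengths[j],
                          params$txn_rate)
      out$expected_fraction_downstream_first[p] <-
        1 - p_upstream_first(spec$rates[i], spec$rates[j], delay)
    } else {
      out$dependent[p] <- TRUE  # influenced but not order-forced: no closed form
    }
  }
  out
}

dependency_reachability <- function(n, edges) {
  reach <- matrix(FALSE, n, n)
  for (e in edges) reach[e[1], e[2]] <- TRUE
  for (k in seq_len(n)) for (i in seq_len(n)) if (reach[i, k])
    reach[i, ] <- reach[i, ] | reach[k, ]
  reach
}

#' Simulate co-transcriptional splicing trajectories of a synthetic locus
#'
#' The polymerase advances at the transcription rate; intron `i` becomes
#' available once fully transcribed (`a_i` = position of its 3' end divided
#' by the rate) and, once its dependency parents have been removed, splices
#' after an exponential waiting time with its rate. Splice times are computed
#' in topological order as
#' `s_i = max(a_i, max(s_parents)) + Exp(rate_i)`. Snapshot states are
#' harvested at a per-molecule observation age: uniform over a window of 10
#' times the slowest expected completion time for steady-state harvest
#' (continuous initiation), or a fixed age for endpoint harvest.
#'
#' @param locus result of [generate_locus()].
#' @param params `kinetic_params`.
#' @param seed optional RNG seed.
#' @return list: `splice_times` (`n_molecules` x introns matrix, minutes),
#'   `avail` (per-intron availability times), `age` (per-molecule observation
#'   age), `spliced` (logical snapshot matrix at `age`),
#'   `transcribed_up_to` (nt, per molecule), `up_first` (`n_molecules` x
#'   pairs logical: upstream intron of pair removed first).
#' @export
simulate_molecules <- function(locus, params = kinetic_params(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- locus$spec
  n_int <- length(spec$intron_lengths)
  n_mol <- spec$n_molecules
  pos_end <- cumsum(spec$exon_lengths[seq_len(n_int)] +
                      spec$intron_lengths[seq_len(n_int)])
  avail <- pos_end / (params$txn_rate * 1000)
  s <- matrix(NA_real_, n_mol, n_int)
  ord <- topo_order(n_int, spec$dependencies)
  parents <- lapply(seq_len(n_int), function(j)
    vapply(Filter(function(e) e[2] == j, spec$dependencies),
           function(e) e[1], integer(1)))
  for (i in ord) {
    ready <- rep(avail[i], n_mol)
    for (p in parents[[i]]) ready <- pmax(ready, s[, p])
    s[, i] <- ready + stats::rexp(n_mol, locus$rates[i])
  }
  total_len <- sum(spec$exon_lengths) + sum(spec$intron_lengths)
  if (spec$harvest == "steady_state") {
    window <- 10 * (max(avail) + 1 / min(locus$rates))
    age <- stats::runif(n_mol, 0, window)
  } else {
    age <- rep(spec$harvest_time, n_mol)
  }
  spliced <- sweep(s, 1, age, "<=")
  up_first <- if (n_int >= 2)
    s[, seq_len(n_int - 1), drop = FALSE] < s[, 2:n_int, drop = FALSE]
  else matrix(logical(0), n_mol, 0)
  list(splice_times = s, avail = avail, age = age, spliced = spliced,
       transcribed_up_to = pmin(total_len, params$txn_rate * 1000 * age),
       up_first = up_first)
}

#' Emit paired-end intermediate reads from simulated molecules
#'
#' Every molecule that removes both introns of an adjacent pair passes
#' through exactly one partially spliced intermediate (one intron removed,
#' the other retained). For each such passage a read pair is emitted with
#' probability `capture_rate`: one mate spans the spliced exon-exon junction
#' (two blocks flanking the removed intron, half the read length on each
#' side, clipped to the flanking exons) and the other mate is placed
#' uniformly inside the retained intron (truncated to the intron when it is
#' shorter than a mate). Which physical mate carries the junction is
#' randomized. Uninformative exonic read pairs are added at
#' `background_rate` per molecule.
#'
#' Because emission is per passage, the emitted reads estimate the order
#' probability of the pair directly — the quantity the classification
#' pipeline and the kinetic null model are defined on.
#'
#' @param sim result of [simulate_molecules()].
#' @param locus result of [generate_locus()].
#' @param seed optional RNG seed.
#' @return data.frame of read records (`read_id`, `chrom`, `mate1_blocks`,
#'   `mate2_blocks`) plus a `truth_call` column (`upstream_first` /
#'   `downstream_first` / `background`) for validation.
#' @export
emit_read_pairs <- function(sim, locus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- locus$spec
  model <- locus$model
  n_int <- nrow(model$introns)
  n_mol <- spec$n_molecules
  half <- max(1L, spec$read_length %/% 2L)
  intr <- model$introns[order(model$introns$index), ]
  ex <- model$exons
  rows <- list()
  emit_one <- function(removed, retained, id, truth) {
    # junction mate: blocks flanking the removed intron (plus strand locus)
    left_ex <- ex[removed, ]; right_ex <- ex[removed + 1, ]
    jb <- rbind(c(max(left_ex$start, intr$start[removed] - half),
                  intr$start[removed]),
                c(intr$end[removed],
                  min(right_ex$end, intr$end[removed] + half)))
    ilen <- intr$end[retained] - intr$start[retained]
    mlen <- min(spec$read_length, ilen)
    istart <- intr$start[retained] +
      if (ilen > mlen) sample.int(ilen - mlen + 1L, 1L) - 1L else 0L
    ib <- rbind(c(istart, istart + mlen))
    swap <- stats::runif(1) < 0.5
    data.frame(read_id = id, chrom = model$chrom,
               mate1_blocks = format_blocks(list(if (swap) ib else jb)),
               mate2_blocks = format_blocks(list(if (swap) jb else ib)),
               truth_call = truth)
  }
  for (p in seq_len(max(0L, n_int - 1L))) {
    up <- p; dn <- p + 1L
    captured <- which(stats::runif(n_mol) < spec$capture_rate)
    for (m in captured) {
      if (sim$up_first[m, p]) {
        rows[[length(rows) + 1L]] <-
          emit_one(up, dn, sprintf("pair%d_mol%d", p, m), "upstream_first")
      } else {
        rows[[length(rows) + 1L]] <-
          emit_one(dn, up, sprintf("pair%d_mol%d", p, m), "downstream_first")
      }
    }
  }
  if (spec$background_rate > 0) {
    n_bg <- stats::rpois(1, spec$background_rate * n_mol)
    for (b in seq_len(n_bg)) {
      e <- ex[sample.int(nrow(ex), 1L), ]
      len <- min(spec$read_length, e$end - e$start)
      st <- e$start + sample.int(e$end - e$start - len + 1L, 1L) - 1L
      blk <- format_blocks(list(rbind(c(st, st + len))))
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("bg%d", b), chrom = model$chrom,
        mate1_blocks = blk, mate2_blocks = blk, truth_call = "background")
    }
  }
  if (length(rows) == 0)
    return(data.frame(read_id = character(0), chrom = character(0),
                      mate1_blocks = character(0), mate2_blocks = character(0),
                      truth_call = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a genome-scale synthetic cohort of two-intron loci
#'
#' Builds `n_pairs` independent adjacent intron pairs — each a three-exon,
#' two-intron locus — under the co-transcriptional kinetic model, optionally
#' forcing a dependency on a fraction of pairs (direction chosen at random:
#' upstream-requires-downstream or the reverse), simulates `n_molecules`
#' molecules per pair, and captures intermediate reads per molecule with
#' probability `capture_rate`. Internal exon lengths are log-normal around
#' 150 nt and intron lengths log-normal with median about 1.5 kb (truncated
#' to 70–50,000 nt), matching typical human internal exon and intron size
#' distributions.
#'
#' @param n_pairs number of pairs.
#' @param params `kinetic_params`.
#' @param dep_fraction fraction of pairs with a forced dependency
#'   (default 0).
#' @param n_molecules molecules simulated per pair (default 60).
#' @param capture_rate per-molecule read capture probability (default 0.5).
#' @param seed RNG seed.
#' @return list: `pairs` (pair_id, lengths, `n_total`, `unique`,
#'   `truth_fraction`, `forced`, `forced_direction`), `counts`
#'   (as from [accumulate_counts()], with `n_total` > 0).
#' @export
generate_cohort <- function(n_pairs, params = kinetic_params(),
                            dep_fraction = 0, n_molecules = 60,
                            capture_rate = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  exon_len <- pmax(30L, round(stats::rlnorm(n_pairs, log(150), 0.4)))
  up_len <- pmin(50000L, pmax(70L, round(stats::rlnorm(n_pairs, log(1500), 1.0))))
  dn_len <- pmin(50000L, pmax(70L, round(stats::rlnorm(n_pairs, log(1500), 1.0))))
  k_up <- draw_splicing_rate(n_pairs, params)
  k_dn <- draw_splicing_rate(n_pairs, params)
  delay <- pair_delay(exon_len, dn_len, params$txn_rate)
  p_up <- p_upstream_first(k_up, k_dn, delay)
  n_dep <- round(dep_fraction * n_pairs)
  forced_dir <- rep("none", n_pairs)
  if (n_dep > 0) {
    idx <- sample.int(n_pairs, n_dep)
    forced_dir[idx] <- sample(c("up_first", "down_first"), n_dep,
                              replace = TRUE)
  }
  truth <- ifelse(forced_dir == "up_first", 0,
                  ifelse(forced_dir == "down_first", 1, 1 - p_up))
  # per-molecule order outcomes, then per-molecule capture
  up_first_mat <- matrix(stats::runif(n_pairs * n_molecules), n_pairs) <
    (1 - truth)
  cap <- matrix(stats::runif(n_pairs * n_molecules), n_pairs) < capture_rate
  n_up <- rowSums(up_first_mat & cap)
  n_dn <- rowSums(!up_first_mat & cap)
  pair_id <- sprintf("synthpair%05d", seq_len(n_pairs))
  pairs <- data.frame(pair_id = pair_id, exon_len = exon_len,
                      up_len = up_len, dn_len = dn_len,
                      n_total = n_up + n_dn, unique = TRUE,
                      truth_fraction = truth,
                      forced = forced_dir != "none",
                      forced_direction = forced_dir)
  counts <- data.frame(pair_id = pair_id, n_upstream_first = n_up,
                       n_downstream_first = n_dn, n_total = n_up + n_dn)
  counts$fraction_downstream_first <-
    ifelse(counts$n_total > 0, n_dn / counts$n_total, NA_real_)
  keep <- counts$n_total > 0
  list(pairs = pairs[keep, , drop = FALSE],
       counts = counts[keep, , drop = FALSE])
}
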