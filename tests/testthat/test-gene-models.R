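test_that("introns are derived as inter-exon gaps in transcription order", {
  m <- build_gene_models(data.frame(
    transcript_id = "t1", gene_id = "g1", chrom = "chr1",
    start = c(100, 300, 500), end = c(200, 400, 600), strand = "+"))$t1
  expect_equal(m$introns$start, c(200, 400))
  expect_equal(m$introns$end, c(300, 500))
  expect_equal(m$introns$index, c(1, 2))
  expect_equal(m$introns$ss5, c(200, 400))
  expect_equal(m$introns$ss3, c(300, 500))

  # minus strand: same intervals, transcription order reversed
  mm <- three_exon_models("-")$t1
  expect_equal(mm$introns$start[mm$introns$index == 1], 400)
  expect_equal(mm$introns$end[mm$introns$index == 1], 500)
  expect_equal(mm$introns$ss5[mm$introns$index == 1], 500)
  expect_equal(mm$introns$ss3[mm$introns$index == 1], 400)

  # single-exon transcript has no introns
  s <- build_gene_models(data.frame(
    transcript_id = "s", gene_id = "g", chrom = "chr1", start = 10,
    end = 50, strand = "+"))$s
  expect_equal(nrow(s$introns), 0)
})

test_that("exons and introns tile the transcript span without overlap", {
  for (strand in c("+", "-")) {
    m <- build_gene_models(five_exon_table(strand))$t1
    segs <- rbind(as.matrix(m$exons), as.matrix(m$introns[, c("start", "end")]))
    segs <- segs[order(segs[, 1]), ]
    expect_equal(unname(segs[1, 1]), min(m$exons$start))
    expect_equal(unname(segs[nrow(segs), 2]), max(m$exons$end))
    expect_true(all(segs[-nrow(segs), 2] == segs[-1, 1]))
  }
})

test_that("malformed and overlapping exon records are handled per contract", {
  expect_error(build_gene_models(data.frame(
    transcript_id = "t", gene_id = "g", chrom = "c", start = 100, end = 50,
    strand = "+")), "malformed")
  expect_warning(m <- build_gene_models(data.frame(
    transcript_id = "t", gene_id = "g", chrom = "c",
    start = c(100, 150), end = c(200, 250), strand = "+")), "overlapping")
  expect_length(m, 0)
})

test_that("adjacent pair enumeration yields intron_count - 1 pairs per transcript", {
  m <- build_gene_models(five_exon_table())
  p <- enumerate_adjacent_pairs(m)
  expect_equal(nrow(p), 3)
  expect_equal(p$up_index, 1:3)
  expect_equal(p$dn_index, 2:4)
  # 1-intron transcript: no pairs
  p1 <- enumerate_adjacent_pairs(build_gene_models(data.frame(
    transcript_id = "t", gene_id = "g", chrom = "c", start = c(0, 100),
    end = c(50, 150), strand = "+")))
  expect_equal(nrow(p1), 0)
  # two transcripts x 4 introns -> 6 pairs
  two <- rbind(five_exon_table(tid = "a"),
               transform(five_exon_table(tid = "b", chrom = "chr2")))
  expect_equal(nrow(enumerate_adjacent_pairs(build_gene_models(two))), 6)
})

test_that("strand relabeling reverses pair order but preserves intervals", {
  pp <- enumerate_adjacent_pairs(build_gene_models(five_exon_table("+")))
  pm <- enumerate_adjacent_pairs(build_gene_models(five_exon_table("-")))
  n <- pp$n_introns[1]
  for (r in seq_len(nrow(pp))) {
    mirror <- pm[pm$up_index == n - pp$dn_index[r] + 1, ]
    expect_equal(sort(c(mirror$up_start, mirror$dn_start)),
                 sort(c(pp$up_start[r], pp$dn_start[r])))
    expect_equal(mirror$exon_start, pp$exon_start[r])
    expect_equal(mirror$exon_len, pp$exon_len[r])
  }
})

test_that("splice-site uniqueness follows the strict coordinate-multiset rule", {
  # isolated transcript: all four splice sites of every pair occur once
  solo <- build_gene_models(five_exon_table())
  ps <- flag_unique_introns(enumerate_adjacent_pairs(solo), all_introns(solo))
  expect_true(all(ps$unique))
  # tA shares sites with tB's skip intron and tC's alt-5'ss intron
  models <- build_gene_models(annotation_with_events())
  pairs <- flag_unique_introns(enumerate_adjacent_pairs(models),
                               all_introns(models))
  expect_false(any(pairs$unique[pairs$transcript_id == "tA"]))
  # identical intron annotated in two transcripts of the same gene:
  # non-unique by default, unique under gene scope
  dup <- rbind(data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                          start = c(100, 300, 500), end = c(200, 400, 600),
                          strand = "+"),
               data.frame(transcript_id = "t2", gene_id = "g1", chrom = "chr1",
                          start = c(100, 300, 500), end = c(200, 400, 600),
                          strand = "+"))
  md <- build_gene_models(dup)
  pd <- flag_unique_introns(enumerate_adjacent_pairs(md), all_introns(md))
  expect_false(any(pd$unique))
  pg <- flag_unique_introns(enumerate_adjacent_pairs(md), all_introns(md),
                            unique_scope = "gene")
  expect_true(all(pg$unique))
})

test_that("first/middle/last labels partition pairs of >2-intron transcripts", {
  p <- assign_positional_category(
    enumerate_adjacent_pairs(build_gene_models(five_exon_table())))
  expect_equal(as.character(p$positional), c("first", "middle", "last"))
  expect_equal(sum(!is.na(p$positional)), p$n_introns[1] - 1)
  # 2-intron transcript: excluded
  p2 <- assign_positional_category(
    enumerate_adjacent_pairs(three_exon_models()))
  expect_true(all(is.na(p2$positional)))
})

test_that("skipping introns are found by exact outer splice-site match", {
  models <- build_gene_models(annotation_with_events())
  ev <- find_skippable_exons(models)
  hit <- ev[ev$transcript_id == "tA", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$skip_start, 200)
  expect_equal(hit$skip_end, 500)
  expect_equal(hit$n_skipped, 1)
  expect_equal(hit$skipped_exons, "300-400")
  # skip-intron coordinates reconstruct as flanked introns + internal exon
  expect_equal(hit$skip_end - hit$skip_start, (300 - 200) + (400 - 300) + (500 - 400))

  pairs <- label_skip_categories(enumerate_adjacent_pairs(models), ev)
  pa <- pairs[pairs$transcript_id == "tA", ]
  expect_match(pa$categories[pa$up_index == 1], "skip_internal")
  expect_match(pa$categories[pa$up_index == 2], "skip_after")

  # no matching intron anywhere -> no events
  expect_equal(nrow(find_skippable_exons(build_gene_models(five_exon_table()))), 0)
})

test_that("multi-exon skipping labels middle and flank pairs", {
  # inclusion isoform with 4 introns; skip intron joins ss5(intron 2) to
  # ss3(intron 4), skipping two exons
  inc <- five_exon_table(tid = "inc")
  skp <- data.frame(transcript_id = "skp", gene_id = "g1", chrom = "chr1",
                    start = c(100, 300, 900), end = c(200, 400, 1000),
                    strand = "+")
  models <- build_gene_models(rbind(inc, skp))
  ev <- find_skippable_exons(models)
  multi <- ev[ev$n_skipped == 2 & ev$transcript_id == "inc", ]
  expect_equal(nrow(multi), 1)
  expect_equal(c(multi$first_index, multi$last_index), c(2, 4))
  pairs <- label_skip_categories(enumerate_adjacent_pairs(models), ev)
  pi <- pairs[pairs$transcript_id == "inc", ]
  expect_match(pi$categories[pi$up_index == 2], "multi_skip_middle")
  expect_match(pi$categories[pi$up_index == 3], "multi_skip_middle")
  expect_match(pi$categories[pi$up_index == 1], "multi_skip_flank")
})

test_that("alternative splice sites group by shared site, shortest representative", {
  ii <- data.frame(
    transcript_id = c("a", "b", "c", "d"), gene_id = "g", chrom = "chr1",
    strand = "+",
    start = c(100, 200, 100, 100), end = c(500, 500, 400, 500),
    index = 1, ss5 = c(100, 200, 100, 100), ss3 = c(500, 500, 400, 500))
  alt <- collapse_alt_ss(ii)
  # [100,500) and [200,500) share ss3 -> alt5 group, shortest = [200,500)
  a5 <- alt$alt5
  expect_equal(nrow(a5), 2)
  expect_true(a5$representative[a5$start == 200])
  expect_false(a5$representative[a5$start == 100])
  # [100,400) and [100,500) share ss5 -> alt3 group, shortest = [100,400)
  a3 <- alt$alt3
  expect_true(a3$representative[a3$end == 400])
  # an intron with unique splice sites joins no group
  solo <- collapse_alt_ss(ii[3, , drop = FALSE])
  expect_equal(nrow(solo$alt5), 0)
  expect_equal(nrow(solo$alt3), 0)
})

test_that("circles match pair boundaries exactly and slop relaxes matching", {
  p <- enumerate_adjacent_pairs(build_gene_models(five_exon_table()))
  # pair (1,2): up [200,300), exon [300,400), dn [400,500)
  res <- match_circles(data.frame(chrom = "chr1", start = 300, end = 400), p)
  expect_equal(res$before, 1)
  expect_equal(res$after, 1)
  expect_match(res$pairs$categories[1], "circle_before")
  expect_match(res$pairs$categories[1], "circle_after")
  # unaligned circle matches nothing
  expect_message(
    res2 <- match_circles(data.frame(chrom = "chr1", start = 310, end = 390), p),
    "no pair")
  expect_equal(res2$n_unmatched, 1)
  expect_length(res2$before, 0)
  # ...unless slop allows it
  res3 <- match_circles(data.frame(chrom = "chr1", start = 310, end = 390), p,
                        slop = 10)
  expect_equal(res3$before, 1)
})

test_that("circle candidates require both flanking introns above threshold", {
  tab <- data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
                    start = c(0, 12100, 27300, 35500),
                    end = c(100, 12300, 27400, 35600), strand = "+")
  cand <- predict_circle_candidates(build_gene_models(tab))
  # flanks: 12000/15000 (exon 2) and 15000/8100 (exon 3)
  expect_equal(cand$candidate, c(TRUE, FALSE))
  # whitelist filter
  cand_wl <- predict_circle_candidates(build_gene_models(tab),
                                       exon_whitelist = "nothing")
  expect_false(any(cand_wl$candidate))
  # negative predicate: two short flanks
  short <- data.frame(transcript_id = "s", gene_id = "g", chrom = "chr1",
                      start = c(0, 300, 600), end = c(100, 400, 700),
                      strand = "+")
  neg <- predict_circle_candidates(build_gene_models(short))
  expect_true(neg$negative_prediction)
  expect_false(neg$candidate)
})
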