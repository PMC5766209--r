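# Fixture builders shared across test files. Everything is constructed in
# code; coordinates are 0-based half-open throughout.

# one transcript, five exons of 100 nt separated by 100 nt introns
five_exon_table <- function(strand = "+", tid = "t1", chrom = "chr1") {
  data.frame(transcript_id = tid, gene_id = "g1", chrom = chrom,
             start = seq(100, 900, by = 200),
             end = seq(200, 1000, by = 200), strand = strand)
}

# inclusion isoform tA plus a skip isoform tB whose first intron joins
# ss5 of tA intron 1 to ss3 of tA intron 2 (skipping exon [300,400));
# tC contributes an alternative 5'ss partner to tA intron 3
annotation_with_events <- function() {
  tA <- five_exon_table(tid = "tA")
  tB <- data.frame(transcript_id = "tB", gene_id = "g1", chrom = "chr1",
                   start = c(100, 500, 700, 900),
                   end = c(200, 600, 800, 1000), strand = "+")
  tC <- data.frame(transcript_id = "tC", gene_id = "g2", chrom = "chr1",
                   start = c(100, 700), end = c(640, 1000), strand = "+")
  rbind(tA, tB, tC)
}

# read records exercising every call type for the middle pair of a
# three-exon transcript (introns [200,300) and [400,500))
three_exon_models <- function(strand = "+") {
  build_gene_models(data.frame(
    transcript_id = "t1", gene_id = "g1", chrom = "chr1",
    start = c(100, 300, 500), end = c(200, 400, 600), strand = strand))
}

make_reads <- function(ids, mate1, mate2, chrom = "chr1") {
  data.frame(read_id = ids, chrom = chrom, mate1_blocks = mate1,
             mate2_blocks = mate2)
}

# counts table with chosen totals and fractions
make_counts <- function(n_up, n_dn, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%02d", seq_along(n_up))
  out <- data.frame(pair_id = ids, n_upstream_first = n_up,
                    n_downstream_first = n_dn, n_total = n_up + n_dn)
  out$fraction_downstream_first <-
    ifelse(out$n_total > 0, n_dn / out$n_total, NA_real_)
  out
}
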