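test_that("dedup_alignments collapses PCR duplicates on the documented key", {
  r <- aln_row("a", "chr1", "+", 1000, 1050, 100, 150)
  trip <- rbind(r, r, r)
  trip$read_id <- c("a", "b", "c")            # read_id ignored in the key
  expect_equal(nrow(dedup_alignments(trip)), 1L)

  two <- rbind(r, aln_row("a", "chr1", "+", 1000, 1050, 100, 151))
  expect_equal(nrow(dedup_alignments(two)), 2L)

  ## set-based oracle on a duplicated fixture
  set.seed(31)
  base <- random_alignments(100)
  dup <- base[sample.int(nrow(base), 100, replace = TRUE)]
  mixed <- rbind(base, dup)[sample.int(nrow(base) + 100)]
  keycols <- c("sample_id", "chrom", "strand", "seg1_start", "seg1_end",
               "seg2_start", "seg2_end")
  n_distinct <- nrow(unique(mixed[, ..keycols]))
  expect_equal(nrow(dedup_alignments(mixed)), n_distinct)
})

test_that("detect_candidates applies the reversed-order and 100 kb rules", {
  cand <- detect_candidates(aln_row("r", "chr1", "+", 10200, 10300, 5000, 5080))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$acceptor, 5000L)
  expect_equal(cand$donor, 10300L)
  expect_equal(cand$support, 1L)

  ## genomic order -> linear read, no candidate
  expect_equal(nrow(detect_candidates(
    aln_row("r", "chr1", "+", 5000, 5080, 10200, 10300))), 0L)
  ## reversed but 150 kb apart -> rejected by distance
  expect_equal(nrow(detect_candidates(
    aln_row("r", "chr1", "+", 155000, 155080, 5000, 5080))), 0L)
  ## exactly at the 100 kb boundary -> kept
  expect_equal(nrow(detect_candidates(
    aln_row("r", "chr1", "+", 104920, 105000, 5000, 5080))), 1L)
})

test_that("detect_candidates equals the brute-force oracle on random inputs", {
  set.seed(7)
  for (rep in 1:25) {
    aln <- random_alignments(200)
    got <- detect_candidates(dedup_alignments(aln))
    want <- candidates_oracle(dedup_alignments(aln))
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("refine_splice_sites recovers exact and displaced GT/AG junctions", {
  g <- tiny_genome(2000)
  ## circle [500, 800) on +: AG just left of 500, GT just right of 800
  g <- poke(g, "chr1", 498, "AG")
  g <- poke(g, "chr1", 800, "GT")
  cand <- data.table(chrom = "chr1", strand = "+", acceptor = 500L,
                     donor = 800L, support = 3L)
  ref <- refine_splice_sites(cand, g)
  expect_equal(ref$shift, 0L)
  expect_equal(ref$acceptor, 500L)
  expect_equal(ref$donor, 800L)
  expect_equal(ref$motif, "GTAG")

  ## breakpoints displaced +3 from the planted pair -> shift -3 recovers
  cand3 <- data.table(chrom = "chr1", strand = "+", acceptor = 503L,
                      donor = 803L, support = 1L)
  ref3 <- refine_splice_sites(cand3, g)
  expect_equal(ref3$shift, -3L)
  expect_equal(ref3$acceptor, 500L)
  expect_equal(ref3$donor, 800L)

  ## displaced beyond the 10-nt window -> rejected
  cand12 <- data.table(chrom = "chr1", strand = "+", acceptor = 512L,
                       donor = 812L, support = 1L)
  expect_equal(nrow(refine_splice_sites(cand12, g)), 0L)

  ## scrubbed background (flat CCT genome has no GT/AG) -> rejected
  flat <- tiny_genome(2000)
  expect_equal(nrow(refine_splice_sites(cand, flat)), 0L)
})

test_that("refine_splice_sites handles the minus strand (AC...CT on reference)", {
  g <- tiny_genome(2000)
  g <- poke(g, "chr1", 498, "AC")   # donor arm left of acceptor
  g <- poke(g, "chr1", 800, "CT")   # acceptor arm right of donor
  cand <- data.table(chrom = "chr1", strand = "-", acceptor = 501L,
                     donor = 801L, support = 1L)
  ref <- refine_splice_sites(cand, g)
  expect_equal(ref$shift, -1L)
  expect_equal(ref$acceptor, 500L)
  expect_equal(ref$donor, 800L)
  ## the motif read on the minus strand is GT..AG
  expect_equal(revcomp_dna(substr(g$seq[["chr1"]], 801, 802)), "AG")
  expect_equal(revcomp_dna(substr(g$seq[["chr1"]], 499, 500)), "GT")
})

test_that("coupled shifts prefer zero then negative on ties", {
  g <- tiny_genome(2000)
  ## valid pairs at shift -2 and +2, none at 0
  g <- poke(g, "chr1", 496, "AG"); g <- poke(g, "chr1", 798, "GT")
  g <- poke(g, "chr1", 500, "AG"); g <- poke(g, "chr1", 802, "GT")
  cand <- data.table(chrom = "chr1", strand = "+", acceptor = 500L,
                     donor = 800L, support = 1L)
  ref <- refine_splice_sites(cand, g)
  expect_equal(ref$shift, -2L)
})

test_that("annotate_circrnas classifies exonic/intronic and terminal exons", {
  ## 6-exon plus-strand gene: exons every 700 bp from 1000, width 200
  starts <- 1000L + (0:5) * 700L
  ts <- one_tx("tx1", "chr1", "+", cbind(starts, starts + 200L),
               gene = "geneA", biotype = "coding")
  ## junction spanning exons 2-4
  jx <- data.table(chrom = "chr1", strand = "+",
                   acceptor = starts[2], donor = starts[4] + 200L,
                   motif = "GTAG", shift = 0L, support = 2L)
  rec <- annotate_circrnas(jx, ts)
  expect_equal(rec$circ_class, "exonic")
  expect_equal(rec$host_gene, "geneA")
  expect_false(rec$uses_first_exon)
  expect_false(rec$uses_last_exon)
  expect_equal(rec$strand_relation, "sense")

  ## first/last exon usage
  jx2 <- data.table(chrom = "chr1", strand = "+",
                    acceptor = starts[1], donor = starts[6] + 200L,
                    motif = "GTAG", shift = 0L, support = 1L)
  rec2 <- annotate_circrnas(jx2, ts)
  expect_true(rec2$uses_first_exon)
  expect_true(rec2$uses_last_exon)

  ## wholly inside intron 1
  jx3 <- data.table(chrom = "chr1", strand = "+",
                    acceptor = starts[1] + 300L, donor = starts[1] + 600L,
                    motif = "GTAG", shift = 0L, support = 1L)
  expect_equal(annotate_circrnas(jx3, ts)$circ_class, "intronic")

  ## no host
  jx4 <- data.table(chrom = "chr1", strand = "+",
                    acceptor = 50000L, donor = 50400L,
                    motif = "GTAG", shift = 0L, support = 1L)
  rec4 <- annotate_circrnas(jx4, ts)
  expect_equal(rec4$circ_class, "intergenic")
  expect_true(is.na(rec4$host_gene))

  ## antisense relation on a minus-strand junction over the plus gene
  jx5 <- copy(jx); jx5$strand <- "-"
  expect_equal(annotate_circrnas(jx5, ts)$strand_relation, "antisense")
})

test_that("minus-strand transcription order flips first/last exon flags", {
  starts <- 1000L + (0:5) * 700L
  ts <- one_tx("tx1", "chr1", "-", cbind(starts, starts + 200L),
               gene = "geneB", biotype = "coding")
  ## genomically leftmost exon is the LAST exon of a minus-strand gene
  jx <- data.table(chrom = "chr1", strand = "-",
                   acceptor = starts[1], donor = starts[3] + 200L,
                   motif = "GTAG", shift = 0L, support = 1L)
  rec <- annotate_circrnas(jx, ts)
  expect_true(rec$uses_last_exon)
  expect_false(rec$uses_first_exon)
})

test_that("summarize_circ_stats computes counts and percentages", {
  mk <- function(n, class, first, last, rel) {
    data.table(circ_id = sprintf("c%d", seq_len(n)), circ_class = class,
               uses_first_exon = first, uses_last_exon = last,
               strand_relation = rel)
  }
  recs <- rbind(mk(6, "exonic", FALSE, FALSE, "sense"),
                mk(2, "exonic", TRUE, FALSE, "antisense"),
                mk(2, "intronic", NA, NA, "sense"))
  s <- summarize_circ_stats(recs)
  expect_equal(s$n, 10L)
  expect_equal(s$n_exonic, 8L)
  expect_equal(s$n_intronic, 2L)
  expect_equal(s$pct_sense, 80)
  ## 2 use a terminal exon -> 8 of 10 missed
  expect_equal(s$pct_missed_terminal, 80)

  e <- summarize_circ_stats(recs[0])
  expect_true(e$empty)
  expect_true(is.na(e$pct_sense))
})

test_that("caller recovers planted junctions from the simulator", {
  sim <- cached_sim()
  circ <- call_circrnas(sim$alignments, sim$genome, sim$annotation)
  truth <- sim$truth$circ_junctions
  got <- circ[, paste(chrom, acceptor, donor, strand)]
  want <- truth[, paste(chrom, acceptor, donor, strand)]
  expect_setequal(got, want)
  ## hosting-gene map equals truth
  m <- merge(circ, truth, by = c("chrom", "strand", "acceptor", "donor"))
  expect_equal(m$host_gene.x, m$host_gene.y)
  ## every retained junction re-verifies GT/AG independently
  for (i in seq_len(nrow(circ))) {
    s <- sim$genome$seq[[circ$chrom[i]]]
    left <- substr(s, circ$acceptor[i] - 1, circ$acceptor[i])
    right <- substr(s, circ$donor[i] + 1, circ$donor[i] + 2)
    if (circ$strand[i] == "+") {
      expect_equal(right, "GT"); expect_equal(left, "AG")
    } else {
      expect_equal(right, "CT"); expect_equal(left, "AC")
    }
  }
  expect_true(all(circ$donor - circ$acceptor <= 100000))
})

test_that("decoy-only simulation yields zero junctions", {
  cfg <- simulation_config(seed = 5, n_autosomes = 2,
                           chrom_length_bp = 150000L, n_coding_genes = 10L,
                           n_lnc_per_class = 1L, n_circ_junctions = 0L,
                           n_mirnas = 0L, n_cerna_triples = 0L,
                           n_coexpressed_pairs = 0L, n_negative_pairs = 0L)
  g <- simulate_genome_annotation(cfg)
  rd <- simulate_backsplice_reads(g$genome, g$truth, cfg)
  expect_gt(nrow(rd$alignments), 0L)
  circ <- call_circrnas(rd$alignments, rd$genome, g$annotation)
  expect_equal(nrow(circ), 0L)
})
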