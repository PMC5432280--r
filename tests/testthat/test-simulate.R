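test_that("simulation_config validates its fields", {
  expect_s3_class(small_sim_config(), "sim_config")
  expect_error(simulation_config(nb_dispersion = 0), "dispersion")
  expect_error(simulation_config(pcr_dup_rate = 1.5), "pcr_dup_rate")
  expect_error(simulation_config(read_len = 30, min_seg_len = 20),
               "min_seg_len")
  expect_error(simulation_config(n_coding_genes = 5000,
                                 chrom_length_bp = 100000), "too short")
  expect_error(simulation_config(n_first_exon_circ = 99,
                                 n_circ_junctions = 5), "n_first_exon_circ")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(cached_sim(11), d1)
  write_simulation(simulate_dataset(cfg), d2)
  for (f in c("genome.fa", "annotation.gtf", "assembled.gtf", "known.gtf",
              "alignments.tsv", "counts.tsv", "mirnas.fa", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("every planted intron is GT..AG on its template strand", {
  ## derived check: scan all introns of the emitted annotation against the
  ## emitted genome, independently of the construction code
  sim <- cached_sim()
  ann <- sim$annotation
  for (id in ann$transcripts$transcript_id) {
    tr <- ann$transcripts[transcript_id == id]
    ex <- ann$exons[transcript_id == id][order(start)]
    if (nrow(ex) < 2L) next
    s <- sim$genome$seq[[tr$chrom]]
    for (e in seq_len(nrow(ex) - 1L)) {
      intron <- substr(s, ex$end[e] + 1L, ex$start[e + 1L])
      if (tr$strand == "-") intron <- revcomp_dna(intron)
      expect_equal(substr(intron, 1, 2), "GT",
                   info = paste(id, "intron", e))
      expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG",
                   info = paste(id, "intron", e))
    }
  }
})

test_that("planted truth ids all resolve in the emitted annotation", {
  sim <- cached_sim()
  tx <- sim$annotation$transcripts$transcript_id
  circ <- sim$truth$circ_junctions$circ_id
  expect_true(all(sim$truth$lnc_classes$transcript_id %in% tx))
  expect_true(all(sim$truth$circ_junctions$host_transcript %in% tx))
  expect_true(all(sim$truth$coexpressed_pairs$noncoding_id %in% tx))
  expect_true(all(sim$truth$coexpressed_pairs$mrna_id %in% tx))
  expect_true(all(sim$truth$cerna_triples$sponge_id %in% c(tx, circ)))
  expect_true(all(sim$truth$cerna_triples$mrna_id %in% tx))
  expect_true(all(sim$truth$sex_biased$transcript_id %in%
                    c(tx, circ)))
  ## all four positional classes are planted
  expect_setequal(unique(sim$truth$lnc_classes$class),
                  c("sense", "antisense", "bidirectional", "intergenic"))
})

test_that("internal-exon circles avoid terminal exons; first-exon count works", {
  cfg <- small_sim_config()
  sim <- cached_sim()
  expect_true(all(!sim$truth$circ_junctions$uses_first_exon))
  expect_true(all(!sim$truth$circ_junctions$uses_last_exon))

  cfg2 <- simulation_config(seed = 12, n_autosomes = 2,
                            chrom_length_bp = 150000L, n_coding_genes = 12L,
                            n_lnc_per_class = 1L, n_circ_junctions = 6L,
                            n_first_exon_circ = 2L, n_mirnas = 0L,
                            n_cerna_triples = 0L, n_coexpressed_pairs = 0L,
                            n_negative_pairs = 0L)
  g2 <- simulate_genome_annotation(cfg2)
  expect_equal(sum(g2$truth$circ_junctions$uses_first_exon), 2L)
  ## first-exon junctions must still be callable
  rd <- simulate_backsplice_reads(g2$genome, g2$truth, cfg2)
  circ <- call_circrnas(rd$alignments, rd$genome, g2$annotation)
  got <- circ[, paste(chrom, acceptor, donor, strand)]
  want <- g2$truth$circ_junctions[, paste(chrom, acceptor, donor, strand)]
  expect_setequal(got, want)
})

test_that("PCR duplicates are byte-identical copies of original rows", {
  cfg <- simulation_config(seed = 13, n_autosomes = 2,
                           chrom_length_bp = 150000L, n_coding_genes = 12L,
                           n_lnc_per_class = 1L, n_circ_junctions = 5L,
                           pcr_dup_rate = 0.5, n_mirnas = 0L,
                           n_cerna_triples = 0L, n_coexpressed_pairs = 0L,
                           n_negative_pairs = 0L)
  g <- simulate_genome_annotation(cfg)
  rd <- simulate_backsplice_reads(g$genome, g$truth, cfg)
  aln <- rd$alignments
  ## injected duplicates are full-row copies: with duplicated read_ids, the
  ## whole row (including read_id) must be identical to its original
  expect_gt(sum(duplicated(aln)), 0L)
  expect_equal(sum(duplicated(aln)), sum(duplicated(aln$read_id)))
  ## dedup returns exactly the distinct keys
  expect_equal(nrow(dedup_alignments(aln)),
               nrow(unique(aln[, -"read_id"])))
})

test_that("NB marginals match mean/dispersion parameterization", {
  ## var = mu + d mu^2 within 5% over >= 1e4 draws
  set.seed(77)
  mu <- 50; d <- 0.2
  x <- rnbinom(2e4, mu = mu, size = 1 / d)
  expect_equal(mean(x), mu, tolerance = 0.03)
  expect_equal(var(x), mu + d * mu^2, tolerance = 0.05)
})

test_that("null configuration produces a global null count table", {
  cfg <- simulation_config(seed = 14, n_autosomes = 2,
                           chrom_length_bp = 150000L, n_coding_genes = 12L,
                           n_lnc_per_class = 1L, n_circ_junctions = 2L,
                           fold_change_planted = 1, frac_male_biased = 0,
                           frac_female_biased = 0, n_mirnas = 0L,
                           n_cerna_triples = 0L, n_coexpressed_pairs = 0L,
                           n_negative_pairs = 0L)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$sex_biased), 0L)
  et <- sim_expression(sim)
  de <- nb_differential_test(et)
  expect_equal(nrow(de[call != "ns"]), 0L)
})

test_that("female-biased transcripts are preferentially on the X", {
  sim <- cached_sim()
  chrom_of <- c(stats::setNames(sim$annotation$transcripts$chrom,
                                sim$annotation$transcripts$transcript_id),
                stats::setNames(sim$truth$circ_junctions$chrom,
                                sim$truth$circ_junctions$circ_id))
  fem <- sim$truth$sex_biased[direction == "female_biased", transcript_id]
  frac_x_fem <- mean(chrom_of[fem] == "chrX")
  frac_x_all <- mean(chrom_of == "chrX")
  expect_gt(frac_x_fem, frac_x_all)
})

test_that("planted seed sites are found exactly and backgrounds are clean", {
  sim <- cached_sim()
  tri <- sim$truth$cerna_triples
  expect_gt(nrow(tri), 0L)
  get_seq <- function(id) {
    tr <- sim$annotation$transcripts[transcript_id == id]
    ex <- sim$annotation$exons[transcript_id == id][order(start)]
    transcript_sequence(sim$genome, ex, tr$chrom, tr$strand)
  }
  circ_seq <- function(cid) {
    cj <- sim$truth$circ_junctions[circ_id == cid]
    ex <- sim$annotation$exons[transcript_id == cj$host_transcript][order(start)]
    transcript_sequence(sim$genome, ex[cj$exon_i:cj$exon_j], cj$chrom,
                        cj$strand)
  }
  for (i in seq_len(nrow(tri))) {
    mi <- sim$mirnas[[tri$mirna_id[i]]]
    s_sites <- if (tri$sponge_type[i] == "circRNA")
      find_seed_sites_circular(circ_seq(tri$sponge_id[i]), mi)
    else find_seed_sites(get_seq(tri$sponge_id[i]), mi)
    expect_equal(s_sites$pos, tri$sponge_pos[i])
    m_sites <- find_seed_sites(get_seq(tri$mrna_id[i]), mi)
    expect_equal(m_sites$pos, tri$mrna_pos[i])
  }
  ## scrubbed background: transcripts outside the triples carry no sites
  ## for any simulated miRNA
  planted <- unique(c(tri$mrna_id,
                      tri[sponge_type == "lncRNA", sponge_id],
                      sim$truth$circ_junctions[sponge == TRUE,
                                               host_transcript]))
  others <- setdiff(sim$annotation$transcripts$transcript_id, planted)
  for (id in others[seq_len(min(20, length(others)))]) {
    s <- get_seq(id)
    for (mi in sim$mirnas)
      expect_equal(nrow(find_seed_sites(s, mi)), 0L, info = id)
  }
})

test_that("decoy-only output with no miRNAs and no triples is clean", {
  cfg <- simulation_config(seed = 15, n_autosomes = 2,
                           chrom_length_bp = 150000L, n_coding_genes = 12L,
                           n_lnc_per_class = 1L, n_circ_junctions = 3L,
                           n_mirnas = 2L, n_cerna_triples = 0L,
                           n_coexpressed_pairs = 0L, n_negative_pairs = 0L)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$cerna_triples), 0L)
  ## background scrubbed for the simulated miRNAs even without triples
  for (id in sim$annotation$transcripts$transcript_id[1:10]) {
    tr <- sim$annotation$transcripts[transcript_id == id]
    ex <- sim$annotation$exons[transcript_id == id][order(start)]
    s <- transcript_sequence(sim$genome, ex, tr$chrom, tr$strand)
    for (mi in sim$mirnas)
      expect_equal(nrow(find_seed_sites(s, mi)), 0L)
  }
})

test_that("co-expressed pairs reach |PCC| >= 0.99 with the planted sign", {
  sim <- cached_sim()
  et <- sim_expression(sim)
  lfpkm <- log2(compute_fpkm(et) + 1)
  tp <- sim$truth$coexpressed_pairs
  expect_gt(nrow(tp), 0L)
  for (i in seq_len(nrow(tp))) {
    r <- cor(lfpkm[tp$noncoding_id[i], ], lfpkm[tp$mrna_id[i], ])
    expect_gte(abs(r), 0.99)
    expect_equal(tp$sign[i], if (r > 0) "positive" else "negative")
  }
})
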