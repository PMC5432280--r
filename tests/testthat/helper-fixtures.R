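## Shared fixture builders. Everything is generated in code; no data files.

library(data.table)

`%||%` <- function(a, b) if (is.null(a)) b else a

## a tiny deterministic genome: one chromosome of repeated "CCT" (no ATG,
## no GT/AG anywhere) that specific motifs can be written into
flat_chrom <- function(len, unit = "CCT") {
  paste(rep(unit, ceiling(len / nchar(unit))), collapse = "") |>
    substr(1, len)
}

tiny_genome <- function(len = 10000, chroms = "chr1") {
  seqs <- stats::setNames(rep(flat_chrom(len), length(chroms)), chroms)
  gsc_genome(seqs)
}

## overwrite bases of a genome chromosome at a 0-based position
poke <- function(genome, chrom, pos, what) {
  s <- genome$seq[[chrom]]
  genome$seq[[chrom]] <- paste0(substr(s, 1, pos), what,
                                substr(s, pos + nchar(what) + 1, nchar(s)))
  genome
}

## single-transcript transcript_set
one_tx <- function(id, chrom, strand, exons, gene = paste0("g_", id),
                   biotype = "unknown", cov = 10) {
  transcript_set(
    data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
               strand = strand, biotype = biotype, read_coverage = cov),
    data.frame(transcript_id = id, start = exons[, 1], end = exons[, 2]))
}

## combine transcript sets
bind_tx <- function(...) {
  parts <- list(...)
  transcript_set(data.table::rbindlist(lapply(parts, function(p) p$transcripts)),
                 data.table::rbindlist(lapply(parts, function(p)
                   p$exons[, c("transcript_id", "start", "end")])))
}

## split-alignment row builder
aln_row <- function(read_id, chrom, strand, s1, e1, s2, e2,
                    sample_id = "SSC_1") {
  data.table::data.table(read_id = read_id, sample_id = sample_id,
                         chrom = chrom, strand = strand,
                         seg1_start = as.integer(s1), seg1_end = as.integer(e1),
                         seg2_start = as.integer(s2), seg2_end = as.integer(e2))
}

## small default simulation shared by several test files (cached per session)
small_sim_config <- function(seed = 11) {
  simulation_config(seed = seed, n_autosomes = 4, chrom_length_bp = 150000L,
                    n_coding_genes = 25L, n_lnc_per_class = 2L,
                    n_circ_junctions = 8L, n_mirnas = 3L,
                    n_cerna_triples = 2L, n_coexpressed_pairs = 2L,
                    n_negative_pairs = 1L)
}

.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(small_sim_config(seed))
  .sim_cache[[key]]
}

## brute-force ORF oracle: enumerate every (start, frame) pair directly
orf_oracle <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n && !(substr(seq, j, j + 2) %in% stops)) j <- j + 3L
    if (j + 2L <= n) best <- max(best, j + 2L - i + 1L)
  }
  best
}

sim_expression <- function(sim) {
  m <- as.matrix(sim$counts[, -1, with = FALSE])
  rownames(m) <- sim$counts$transcript_id
  expression_table(m, sim$condition, sim$effective_length,
                   library_size = sim$library_size)
}
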