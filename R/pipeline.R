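## End-to-end orchestration: simulate -> circ call -> lnc identify ->
## expr de -> bias or -> net cnc/cerna. Every stage reads the files the
## previous stage wrote, so each is runnable standalone on a pipeline
## directory; the manifest records per-stage counts and output hashes.

#' Default pipeline configuration
#'
#' Thresholds default to the study's stated cutoffs: 200 bp / 3 reads /
#' FPKM 0.01 for the lncRNA cascade, 100 kb span and 10-nt motif windows
#' for circRNA calling, p-adjust 0.05 and |log2FC| 1 for differential
#' expression, PCC 0.99 / p 0.01 / FDR 0.01 for the co-expression network,
#' and PCC 0.9 for the ceRNA gate.
#'
#' @param seed RNG seed for the simulation stage.
#' @param sim a `sim_config` (built from `seed` when `NULL`).
#' @param ... threshold overrides stored in the config.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L, sim = NULL, ...) {
  cfg <- list(seed = seed,
              sim = sim %||% simulation_config(seed = seed),
              min_len = LNC_MIN_LEN, min_coverage = LNC_MIN_COVERAGE,
              min_fpkm = LNC_MIN_FPKM,
              padj_threshold = DE_PADJ, lfc_threshold = DE_LFC,
              cnc_min_pcc = CNC_MIN_PCC, cnc_max_p = CNC_MAX_P,
              cnc_max_fdr = CNC_MAX_FDR, cerna_min_pcc = CERNA_MIN_PCC,
              min_support = 1L)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

read_stage <- function(dir, file, reader, stage) {
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop("pipeline error: stage '", stage, "' needs missing input ", path,
         " (run the upstream stage first)")
  reader(path)
}

#' Pipeline stage: circRNA calling on a pipeline directory
#' @param dir pipeline directory containing `genome.fa`, `annotation.gtf`,
#'   `alignments.tsv`.
#' @param min_support support threshold.
#' @return the circRNA table (also written to `circrnas.tsv`).
#' @export
stage_circ <- function(dir, min_support = 1L) {
  genome <- read_stage(dir, "genome.fa", read_fasta, "circ")
  ts <- read_stage(dir, "annotation.gtf", read_gtf, "circ")
  aln <- read_stage(dir, "alignments.tsv", read_split_alignments, "circ")
  circ <- call_circrnas(aln, genome, ts, min_support = min_support)
  fwrite(circ, file.path(dir, "circrnas.tsv"), sep = "\t")
  circ
}

#' Pipeline stage: lncRNA identification
#' @param dir pipeline directory.
#' @param ... threshold overrides for [identify_lncrnas()].
#' @return verdict table (written to `lnc_verdicts.tsv`, novel models to
#'   `novel_lncrnas.gtf`).
#' @export
stage_lnc <- function(dir, ...) {
  genome <- read_stage(dir, "genome.fa", read_fasta, "lnc")
  assembled <- read_stage(dir, "assembled.gtf", read_gtf, "lnc")
  known <- read_stage(dir, "known.gtf", read_gtf, "lnc")
  et <- load_expression(dir)
  fpkm <- compute_fpkm(et)
  fpkm <- fpkm[rownames(fpkm) %in% assembled$transcripts$transcript_id, ,
               drop = FALSE]
  verdicts <- identify_lncrnas(assembled, genome, known, fpkm, ...)
  fwrite(verdicts, file.path(dir, "lnc_verdicts.tsv"), sep = "\t")
  nov <- verdicts[status == "novel_lncRNA", transcript_id]
  novts <- transcript_set(assembled$transcripts[transcript_id %in% nov],
                          assembled$exons[transcript_id %in% nov,
                                          .(transcript_id, start, end)])
  if (length(nov) > 0L) write_gtf(novts, file.path(dir, "novel_lncrnas.gtf"))
  verdicts
}

load_expression <- function(dir) {
  counts <- read_stage(dir, "counts.tsv", read_count_table, "expr")
  cond <- read_stage(dir, "condition.tsv",
                     function(p) fread(p, sep = "\t"), "expr")
  ts <- read_stage(dir, "annotation.gtf", read_gtf, "expr")
  lens <- spliced_lengths(ts)
  ## circRNA effective lengths from the called table when present
  circ_path <- file.path(dir, "circrnas.tsv")
  if (file.exists(circ_path)) {
    cc <- fread(circ_path, sep = "\t")
    if (nrow(cc) > 0L)
      lens <- c(lens, stats::setNames(cc$donor - cc$acceptor, cc$circ_id))
  }
  m <- as.matrix(counts[, -1, with = FALSE])
  rownames(m) <- counts$transcript_id
  keep <- rownames(m) %in% names(lens)
  m <- m[keep, , drop = FALSE]
  gm <- stats::setNames(ts$transcripts$gene_id, ts$transcripts$transcript_id)
  libsz <- if ("library_size" %in% names(cond))
    stats::setNames(cond$library_size, cond$library_id) else NULL
  expression_table(m, stats::setNames(cond$condition, cond$library_id),
                   lens, library_size = libsz, gene_map = gm)
}

#' Pipeline stage: FPKM + differential expression
#' @param dir pipeline directory.
#' @param padj_threshold,lfc_threshold call thresholds.
#' @return DE table (written to `de_results.tsv`; FPKM to `fpkm.tsv`).
#' @export
stage_expr <- function(dir, padj_threshold = DE_PADJ, lfc_threshold = DE_LFC) {
  et <- load_expression(dir)
  fpkm <- compute_fpkm(et)
  fw <- data.table(transcript_id = rownames(fpkm))
  for (cc in colnames(fpkm)) fw[[cc]] <- fpkm[, cc]
  fwrite(fw, file.path(dir, "fpkm.tsv"), sep = "\t")
  de <- nb_differential_test(et, padj_threshold = padj_threshold,
                             lfc_threshold = lfc_threshold)
  fwrite(de, file.path(dir, "de_results.tsv"), sep = "\t")
  de
}

## molecule class per id: coding transcripts are mRNA, called circRNAs are
## circRNA, everything else lncRNA-like noncoding
molecule_classes <- function(dir, ids) {
  ts <- read_gtf(file.path(dir, "annotation.gtf"))
  cls <- stats::setNames(rep("lncRNA", length(ids)), ids)
  coding <- ts$transcripts[biotype == "coding", transcript_id]
  cls[ids %in% coding] <- "mRNA"
  circ_path <- file.path(dir, "circrnas.tsv")
  if (file.exists(circ_path)) {
    cc <- fread(circ_path, sep = "\t")
    cls[ids %in% cc$circ_id] <- "circRNA"
  }
  cls
}

#' Pipeline stage: autosome/X odds ratios for sex-biased sets
#' @param dir pipeline directory.
#' @return odds-ratio summary (written to `sex_bias_or.tsv`).
#' @export
stage_bias <- function(dir) {
  de <- read_stage(dir, "de_results.tsv",
                   function(p) fread(p, sep = "\t"), "bias")
  genome <- read_stage(dir, "genome.fa", read_fasta, "bias")
  ts <- read_gtf(file.path(dir, "annotation.gtf"))
  chrom_of <- stats::setNames(ts$transcripts$chrom, ts$transcripts$transcript_id)
  circ_path <- file.path(dir, "circrnas.tsv")
  if (file.exists(circ_path)) {
    cc <- fread(circ_path, sep = "\t")
    if (nrow(cc) > 0L)
      chrom_of <- c(chrom_of, stats::setNames(cc$chrom, cc$circ_id))
  }
  chrom_class <- genome$chrom_class[chrom_of]
  names(chrom_class) <- names(chrom_of)
  cls <- molecule_classes(dir, de$transcript_id)
  out <- sex_bias_summary(de, chrom_class, class_map = cls)
  fwrite(out, file.path(dir, "sex_bias_or.tsv"), sep = "\t")
  out
}

#' Pipeline stage: coding-noncoding co-expression network
#' @param dir pipeline directory.
#' @param min_pcc,max_p,max_fdr,top_k_mrnas edge thresholds.
#' @return edge table (written to `cnc_edges.tsv`).
#' @export
stage_net_cnc <- function(dir, min_pcc = CNC_MIN_PCC, max_p = CNC_MAX_P,
                          max_fdr = CNC_MAX_FDR, top_k_mrnas = NULL) {
  de <- read_stage(dir, "de_results.tsv",
                   function(p) fread(p, sep = "\t"), "net")
  fw <- fread(file.path(dir, "fpkm.tsv"), sep = "\t")
  fpkm <- as.matrix(fw[, -1, with = FALSE]); rownames(fpkm) <- fw$transcript_id
  ts <- read_gtf(file.path(dir, "annotation.gtf"))
  cls <- molecule_classes(dir, rownames(fpkm))
  gm <- stats::setNames(ts$transcripts$gene_id, ts$transcripts$transcript_id)
  biased <- de[call != "ns", transcript_id]
  nc <- fpkm[cls[rownames(fpkm)] == "lncRNA", , drop = FALSE]
  mr <- fpkm[cls[rownames(fpkm)] == "mRNA", , drop = FALSE]
  biased_genes <- unique(gm[intersect(biased, rownames(mr))])
  edges <- build_cnc_network(nc, mr, mrna_gene_map = gm[rownames(mr)],
                             biased_noncoding = intersect(biased, rownames(nc)),
                             biased_coding = biased_genes,
                             top_k_mrnas = top_k_mrnas,
                             min_pcc = min_pcc, max_p = max_p,
                             max_fdr = max_fdr)
  write_edge_list(data.table(source = edges$noncoding_id,
                             target = edges$mrna_id,
                             weight = edges$pcc, sign = edges$sign),
                  file.path(dir, "cnc_edges.tsv"))
  edges
}

## sequence of an exonic circRNA record, from the host transcript's exons
circ_record_sequence <- function(genome, ts, circ_chrom, circ_strand,
                                 acceptor, donor) {
  tids <- ts$transcripts[chrom == circ_chrom & strand == circ_strand,
                         transcript_id]
  for (tid in tids) {
    te <- ts$exons[transcript_id == tid][order(start)]
    i <- which(te$start == acceptor); j <- which(te$end == donor)
    if (length(i) == 1L && length(j) == 1L && i <= j)
      return(transcript_sequence(genome, te[i:j], circ_chrom, circ_strand))
  }
  NA_character_
}

#' Pipeline stage: ceRNA network
#' @param dir pipeline directory.
#' @param min_pcc correlation gate.
#' @return link table (written to `cerna_links.tsv`).
#' @export
stage_net_cerna <- function(dir, min_pcc = CERNA_MIN_PCC) {
  de <- read_stage(dir, "de_results.tsv",
                   function(p) fread(p, sep = "\t"), "net")
  genome <- read_fasta(file.path(dir, "genome.fa"))
  ts <- read_gtf(file.path(dir, "annotation.gtf"))
  mirna_path <- file.path(dir, "mirnas.fa")
  if (!file.exists(mirna_path)) {
    empty <- data.table(sponge_id = character(), mirna_id = character(),
                        mrna_id = character())
    fwrite(empty, file.path(dir, "cerna_links.tsv"), sep = "\t")
    return(empty)
  }
  mi <- Biostrings::readBStringSet(mirna_path)
  mirnas <- stats::setNames(as.character(mi), sub("\\s.*$", "", names(mi)))
  fw <- fread(file.path(dir, "fpkm.tsv"), sep = "\t")
  fpkm <- as.matrix(fw[, -1, with = FALSE]); rownames(fpkm) <- fw$transcript_id

  cls <- molecule_classes(dir, de$transcript_id)
  biased <- de[call != "ns", transcript_id]
  sponge_ids <- biased[cls[biased] %in% c("lncRNA", "circRNA")]
  mrna_ids <- biased[cls[biased] == "mRNA"]
  sponge_seqs <- character(0); circular <- logical(0)
  cc <- if (file.exists(file.path(dir, "circrnas.tsv")))
    fread(file.path(dir, "circrnas.tsv"), sep = "\t") else NULL
  for (sp in sponge_ids) {
    if (cls[[sp]] == "circRNA") {
      rec <- cc[circ_id == sp]
      sq <- circ_record_sequence(genome, ts, rec$chrom[1], rec$strand[1],
                                 rec$acceptor[1], rec$donor[1])
      if (is.na(sq)) next
      sponge_seqs[sp] <- sq; circular[sp] <- TRUE
    } else {
      tr <- ts$transcripts[transcript_id == sp]
      exn <- ts$exons[transcript_id == sp][order(start)]
      sponge_seqs[sp] <- transcript_sequence(genome, exn, tr$chrom, tr$strand)
      circular[sp] <- FALSE
    }
  }
  mrna_seqs <- vapply(mrna_ids, function(id) {
    tr <- ts$transcripts[transcript_id == id]
    exn <- ts$exons[transcript_id == id][order(start)]
    transcript_sequence(genome, exn, tr$chrom, tr$strand)
  }, character(1))
  links <- build_cerna_network(sponge_seqs, mrna_seqs, mirnas, fpkm,
                               circular = circular, min_pcc = min_pcc)
  out <- links[, .(sponge_id, mirna_id, mrna_id,
                   pcc = if (.N) round(pcc, 6) else numeric(0),
                   n_sponge_sites, n_mrna_sites)]
  fwrite(out, file.path(dir, "cerna_links.tsv"), sep = "\t")
  links
}

#' Run the whole pipeline on synthetic data
#'
#' Simulates a dataset into `dir`, then runs every downstream stage on the
#' written files and writes `manifest.json` with per-stage record counts
#' and md5 hashes of all outputs. Rerunning with the same config is
#' byte-identical.
#'
#' @param config a `pipeline_config`.
#' @param dir output directory.
#' @return the manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config$sim)
  write_simulation(sim, dir)
  circ <- stage_circ(dir, min_support = config$min_support)
  verdicts <- stage_lnc(dir, min_len = config$min_len,
                        min_coverage = config$min_coverage,
                        min_fpkm = config$min_fpkm)
  de <- stage_expr(dir, padj_threshold = config$padj_threshold,
                   lfc_threshold = config$lfc_threshold)
  bias <- stage_bias(dir)
  cnc <- stage_net_cnc(dir, min_pcc = config$cnc_min_pcc,
                       max_p = config$cnc_max_p,
                       max_fdr = config$cnc_max_fdr)
  cerna <- stage_net_cerna(dir, min_pcc = config$cerna_min_pcc)
  if (nrow(verdicts[status == "novel_lncRNA"]) == 0L)
    warning("pipeline: no novel lncRNAs survived the cascade")

  outs <- sort(list.files(dir, full.names = TRUE))
  outs <- outs[basename(outs) != "manifest.json"]
  manifest <- list(
    seed = config$sim$seed,
    counts = list(simulated_transcripts = nrow(sim$annotation$transcripts),
                  simulated_alignments = nrow(sim$alignments),
                  circrnas = nrow(circ),
                  novel_lncrnas = nrow(verdicts[status == "novel_lncRNA"]),
                  known_lncrnas = nrow(verdicts[status == "known_lncRNA"]),
                  sex_biased = nrow(de[call != "ns"]),
                  cnc_edges = nrow(cnc),
                  cerna_links = nrow(cerna)),
    md5 = as.list(stats::setNames(unname(tools::md5sum(outs)),
                                  basename(outs))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
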