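## Synthetic data with planted ground truth.
##
## The generator emulates the structure of a two-condition (SSC vs FGSC,
## 3 libraries each) germline stem cell RNA-seq study: multi-exon coding
## genes on autosomes plus an X chromosome, lncRNAs planted in all four
## positional classes, backsplice junctions on internal exons, split-read
## alignments supporting them (plus decoys and PCR duplicates), NB count
## matrices with planted sex-biased fold changes, co-expressed pairs
## sharing a latent log-normal factor, and ceRNA triples with planted
## miRNA seed sites. Everything is deterministic under the config seed.

SIM_EXON_LEN   <- 200L
SIM_INTRON_LEN <- 500L
SIM_N_EXONS    <- 6L
SIM_GENE_SPAN  <- SIM_N_EXONS * SIM_EXON_LEN +
  (SIM_N_EXONS - 1L) * SIM_INTRON_LEN               # 3700
SIM_GENE_SLOT  <- 8000L
SIM_HEAD_MARGIN <- 5000L
SIM_TAIL_MARGIN <- 5000L

## internal-exon (i, j) combinations tried per host, in assignment order;
## (3, 4) is reserved for sponge circles and tried last
SIM_CIRC_COMBOS <- list(c(2L, 4L), c(3L, 5L), c(2L, 3L), c(4L, 5L),
                        c(2L, 5L), c(2L, 2L), c(3L, 3L), c(4L, 4L),
                        c(5L, 5L), c(3L, 4L))

#' Simulation configuration
#'
#' Defaults describe the stated world: a mouse-like karyotype (19 autosomes
#' plus X, so ~5% of genes are X-linked), 3 libraries per condition, NB
#' counts with dispersion 0.1, planted 4-fold sex-biased changes with 40%
#' of female-biased transcripts on the X chromosome, 100-bp reads split
#' into exact-match segments of at least 20 bp.
#'
#' @param seed integer RNG seed.
#' @param n_autosomes,include_X,chrom_length_bp genome layout.
#' @param n_coding_genes number of 6-exon coding genes.
#' @param n_lnc_per_class lncRNAs planted per positional class (sense,
#'   antisense, bidirectional, intergenic).
#' @param n_circ_junctions,n_first_exon_circ planted backsplice junctions,
#'   and how many of them use the (transcription-order) first exon.
#' @param n_libraries_per_condition replicates per condition (3).
#' @param nb_dispersion NB dispersion d in var = mu + d mu^2.
#' @param mean_expression baseline mean fragment count scale.
#' @param fold_change_planted planted fold change for biased transcripts.
#' @param frac_male_biased,frac_female_biased fractions of transcripts
#'   planted as biased.
#' @param frac_female_biased_on_X fraction of female-biased transcripts
#'   drawn from the X chromosome.
#' @param read_len,min_seg_len,circ_read_depth,pcr_dup_rate split-read
#'   simulation parameters.
#' @param n_decoy_linear,n_decoy_far,n_decoy_nomotif decoy read counts:
#'   genomic-order splits, reversed-order pairs > 100 kb apart, and
#'   reversed-order pairs with motif-scrubbed windows.
#' @param n_mirnas,n_cerna_triples miRNA/ceRNA planting.
#' @param n_coexpressed_pairs,n_negative_pairs planted lncRNA-mRNA
#'   co-expressed pairs (the last `n_negative_pairs` anti-correlated).
#' @param pair_expression,pair_dispersion,pair_factor_sdlog latent-factor
#'   planting parameters for co-expressed pairs and ceRNA gate pairs.
#' @param frac_known_lnc fraction of planted lncRNAs also emitted in the
#'   known annotation (as known lncRNAs).
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_autosomes = 19L, include_X = TRUE,
                              chrom_length_bp = 150000L,
                              n_coding_genes = 60L,
                              n_lnc_per_class = 3L,
                              n_circ_junctions = 12L,
                              n_first_exon_circ = 0L,
                              n_libraries_per_condition = 3L,
                              nb_dispersion = 0.1,
                              mean_expression = 100,
                              fold_change_planted = 4,
                              frac_male_biased = 0.1,
                              frac_female_biased = 0.1,
                              frac_female_biased_on_X = 0.4,
                              read_len = 100L, min_seg_len = 20L,
                              circ_read_depth = 5L, pcr_dup_rate = 0.1,
                              n_decoy_linear = 20L, n_decoy_far = 5L,
                              n_decoy_nomotif = 5L,
                              n_mirnas = 4L, n_cerna_triples = 2L,
                              n_coexpressed_pairs = 3L,
                              n_negative_pairs = 1L,
                              pair_expression = 5000,
                              pair_dispersion = 5e-4,
                              pair_factor_sdlog = 0.3,
                              frac_known_lnc = 0.25) {
  cfg <- as.list(environment())
  counts <- c("n_autosomes", "chrom_length_bp", "n_coding_genes",
              "n_lnc_per_class", "n_circ_junctions", "n_first_exon_circ",
              "n_libraries_per_condition", "read_len", "min_seg_len",
              "circ_read_depth", "n_decoy_linear", "n_decoy_far",
              "n_decoy_nomotif", "n_mirnas", "n_cerna_triples",
              "n_coexpressed_pairs", "n_negative_pairs")
  for (f in counts) if (cfg[[f]] < 0) stop("config error: ", f, " must be >= 0")
  for (f in c("pcr_dup_rate", "frac_male_biased", "frac_female_biased",
              "frac_female_biased_on_X", "frac_known_lnc"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("config error: ", f, " must be in [0, 1]")
  if (cfg$nb_dispersion <= 0) stop("config error: dispersion must be > 0")
  if (cfg$read_len < 2L * cfg$min_seg_len)
    stop("config error: read_len must be at least 2 * min_seg_len")
  if (cfg$read_len - cfg$min_seg_len > SIM_EXON_LEN)
    stop("config error: read_len too long for the simulated exon size")
  if (cfg$n_first_exon_circ > cfg$n_circ_junctions)
    stop("config error: n_first_exon_circ exceeds n_circ_junctions")
  n_chrom <- cfg$n_autosomes + as.integer(cfg$include_X)
  slots_per_chrom <- max(0L, (cfg$chrom_length_bp - SIM_HEAD_MARGIN -
                                SIM_TAIL_MARGIN) %/% SIM_GENE_SLOT)
  if (cfg$n_coding_genes > n_chrom * slots_per_chrom)
    stop("config error: chromosomes too short for the requested gene count")
  n_special <- 3L * cfg$n_lnc_per_class +           # sense/antisense hosts
    cfg$n_lnc_per_class +                           # intergenic anchors
    (cfg$n_cerna_triples %/% 2L)                    # circ-sponge hosts
  n_generic_needed <- cfg$n_cerna_triples + cfg$n_coexpressed_pairs
  if (cfg$n_coding_genes < n_special + n_generic_needed)
    stop("config error: n_coding_genes too small for the requested planting")
  if ((cfg$n_cerna_triples > 0L || cfg$n_coexpressed_pairs > 0L) &&
      cfg$n_lnc_per_class < 1L)
    stop("config error: ceRNA triples and co-expressed pairs need lncRNAs")
  if (cfg$n_negative_pairs > cfg$n_coexpressed_pairs)
    stop("config error: n_negative_pairs exceeds n_coexpressed_pairs")
  structure(cfg, class = "sim_config")
}

## dinucleotides flanking a planted intron on the reference, per strand
intron_dinucs <- function(strand) {
  if (strand == "+") c(left = "GT", right = "AG") else
    c(left = "CT", right = "AC")  # reverse complement on the reference
}

# ---- genome and annotation --------------------------------------------

#' Simulate genome, annotation and planted structural truth
#'
#' Lays out 6-exon coding genes (with GT/AG introns and planted >= 300 bp
#' ORFs), lncRNAs in the four positional classes (multi-exon, >= 200 bp,
#' ORF-scrubbed so they are noncoding), and backsplice junctions on
#' internal exons (plus a configurable count on the first exon).
#'
#' @param config a `sim_config`.
#' @return list: `genome` (`gsc_genome`), `annotation` (truth
#'   `transcript_set` with biotypes), `assembled` (cascade input, biotype
#'   unknown, cov attribute set), `known_db` (`transcript_set` of known
#'   mRNAs and a fraction of the lncRNAs), `truth` (partial planted
#'   truth).
#' @export
simulate_genome_annotation <- function(config) {
  set.seed(config$seed)
  n_chrom <- config$n_autosomes + as.integer(config$include_X)
  chroms <- c(paste0("chr", seq_len(config$n_autosomes)),
              if (config$include_X) "chrX")
  ## chromosomes held as base vectors during construction (fast in-place
  ## writes), collapsed to strings at the end
  seqs <- stats::setNames(
    lapply(seq_len(n_chrom), function(i)
      sample(c("A", "C", "G", "T"), config$chrom_length_bp, replace = TRUE)),
    chroms)

  ## --- gene placement: round-robin across chromosomes ---
  ng <- config$n_coding_genes
  gene_chrom <- chroms[((seq_len(ng) - 1L) %% n_chrom) + 1L]
  gene_slot <- ((seq_len(ng) - 1L) %/% n_chrom)      # per-chrom slot index
  gene_start <- SIM_HEAD_MARGIN + gene_slot * SIM_GENE_SLOT
  gene_strand <- sample(c("+", "-"), ng, replace = TRUE)
  gene_ids <- sprintf("gene_%03d", seq_len(ng))
  tx_ids <- sprintf("mrna_%03d", seq_len(ng))

  exon_tabs <- lapply(seq_len(ng), function(k) {
    st <- gene_start[k] + (0:(SIM_N_EXONS - 1L)) * (SIM_EXON_LEN + SIM_INTRON_LEN)
    data.table(transcript_id = tx_ids[k], start = st, end = st + SIM_EXON_LEN)
  })

  ## --- host allocation ---
  nl <- config$n_lnc_per_class
  n_csp <- config$n_cerna_triples %/% 2L             # circ-sponge hosts
  idx <- seq_len(ng)
  sense_hosts     <- idx[seq_len(nl)]
  antisense_hosts <- idx[nl + seq_len(nl)]
  csp_hosts       <- if (n_csp > 0L) idx[2L * nl + seq_len(n_csp)] else integer(0)
  bidir_hosts     <- idx[2L * nl + n_csp + seq_len(nl)]
  inter_anchors   <- idx[3L * nl + n_csp + seq_len(nl)]
  generic_pool    <- setdiff(idx, c(sense_hosts, antisense_hosts, csp_hosts,
                                    bidir_hosts, inter_anchors))

  ## batched genome writes: one vectorized assignment per chromosome
  mods <- stats::setNames(vector("list", n_chrom), chroms)
  queue_write <- function(ch, pos0, bases) {
    mods[[ch]][[length(mods[[ch]]) + 1L]] <<- list(pos = pos0, base = bases)
  }
  queue_str <- function(ch, pos0, s) {
    queue_write(ch, pos0 + seq_len(nchar(s)) - 1L,
                strsplit(s, "", fixed = TRUE)[[1]])
  }

  ## --- plant intron dinucleotides for coding genes ---
  for (k in seq_len(ng)) {
    din <- intron_dinucs(gene_strand[k])
    ex <- exon_tabs[[k]]
    for (e in seq_len(SIM_N_EXONS - 1L)) {
      queue_str(gene_chrom[k], ex$end[e], din[["left"]])
      queue_str(gene_chrom[k], ex$start[e + 1L] - 2L, din[["right"]])
    }
  }

  ## --- plant coding ORFs (transcription-order exons 1-2, 330 bp) ---
  mrna_len <- SIM_N_EXONS * SIM_EXON_LEN
  orf_start_t <- 30L; orf_len <- 330L                # ATG + 108 codons + TAA
  sense_codons <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                            c("A","C","G","T")), 1, paste, collapse = ""),
                          c("TAA", "TAG", "TGA"))
  for (k in seq_len(ng)) {
    body <- paste(sample(sense_codons, (orf_len - 6L) / 3L, replace = TRUE),
                  collapse = "")
    tseq <- random_dna(mrna_len)
    tseq <- paste0(substr(tseq, 1L, orf_start_t), "ATG", body, "TAA",
                   substr(tseq, orf_start_t + orf_len + 1L, mrna_len))
    ex <- exon_tabs[[k]]
    gpos <- unlist(lapply(seq_len(SIM_N_EXONS),
                          function(e) ex$start[e]:(ex$end[e] - 1L)))
    gbase <- strsplit(if (gene_strand[k] == "-") revcomp_dna(tseq) else tseq,
                      "", fixed = TRUE)[[1]]
    queue_write(gene_chrom[k], gpos, gbase)
  }

  ## --- lncRNAs ---
  lnc_tr <- list(); lnc_ex <- list(); lnc_classes <- list()
  lnc_allowed <- list()   # genomic intervals where ORF scrubbing may write
  add_lnc <- function(id, chrom, strand, exons, class, allowed) {
    lnc_tr[[id]] <<- data.table(transcript_id = id,
                                gene_id = paste0("g_", id), chrom = chrom,
                                strand = strand, biotype = "unknown",
                                read_coverage = 10)
    lnc_ex[[id]] <<- data.table(transcript_id = id,
                                start = exons$start, end = exons$end)
    lnc_classes[[id]] <<- class
    lnc_allowed[[id]] <<- allowed
    ## plant the lncRNA's own intron dinucleotides
    din <- intron_dinucs(strand)
    for (e in seq_len(nrow(exons) - 1L)) {
      queue_str(chrom, exons$end[e], din[["left"]])
      queue_str(chrom, exons$start[e + 1L] - 2L, din[["right"]])
    }
  }

  for (z in seq_len(nl)) {
    ## sense / antisense: nested in host intron 2 with a 10-bp overlap of
    ## host exon 2 (exon-level overlap drives the classification)
    for (mode in c("sense", "antisense")) {
      k <- if (mode == "sense") sense_hosts[z] else antisense_hosts[z]
      e2end <- exon_tabs[[k]]$end[2L]
      exons <- data.table(start = c(e2end - 10L, e2end + 200L),
                          end   = c(e2end + 60L, e2end + 420L))
      strand <- if (mode == "sense") gene_strand[k] else
        setdiff(c("+", "-"), gene_strand[k])
      add_lnc(sprintf("lnc_%s_%d", mode, z), gene_chrom[k], strand, exons,
              mode, allowed = c(e2end + 200L, e2end + 420L))
    }
    ## bidirectional: divergent, 5' end 200 bp from the host TSS
    k <- bidir_hosts[z]
    if (gene_strand[k] == "+") {
      G <- gene_start[k]
      exons <- data.table(start = c(G - 900L, G - 450L),
                          end   = c(G - 650L, G - 200L))
      strand <- "-"
    } else {
      E <- exon_tabs[[k]]$end[SIM_N_EXONS]
      exons <- data.table(start = c(E + 200L, E + 650L),
                          end   = c(E + 450L, E + 900L))
      strand <- "+"
    }
    add_lnc(sprintf("lnc_bidirectional_%d", z), gene_chrom[k], strand, exons,
            "bidirectional",
            allowed = c(min(exons$start), max(exons$end)))
    ## intergenic: in the gap upstream of the anchor, > 1 kb from anything
    k <- inter_anchors[z]
    G <- gene_start[k]
    exons <- data.table(start = c(G - 2600L, G - 2250L),
                        end   = c(G - 2400L, G - 1950L))
    add_lnc(sprintf("lnc_intergenic_%d", z), gene_chrom[k],
            sample(c("+", "-"), 1L), exons, "intergenic",
            allowed = c(min(exons$start), max(exons$end)))
  }

  ## apply all queued writes, one assignment per chromosome
  for (ch in chroms) {
    if (length(mods[[ch]]) == 0L) next
    pos <- unlist(lapply(mods[[ch]], `[[`, "pos"))
    base <- unlist(lapply(mods[[ch]], `[[`, "base"))
    seqs[[ch]][pos + 1L] <- base
  }

  ## --- scrub lncRNA ORFs so every planted lncRNA is noncoding ---
  for (id in names(lnc_tr)) {
    tr <- lnc_tr[[id]]; ex <- lnc_ex[[id]]
    seqs[[tr$chrom]] <- scrub_orfs(seqs[[tr$chrom]], ex, tr$strand,
                                   lnc_allowed[[id]])
  }

  ## --- planted circRNA junctions ---
  circ <- list()
  used <- character(0)
  n_internal <- config$n_circ_junctions - config$n_first_exon_circ
  host_cycle <- c(generic_pool, csp_hosts, sense_hosts, antisense_hosts,
                  bidir_hosts, inter_anchors)
  ci <- 0L; combo_ptr <- stats::setNames(rep(1L, ng), as.character(idx))
  while (ci < n_internal) {
    placed <- FALSE
    for (k in host_cycle) {
      p <- combo_ptr[[as.character(k)]]
      while (p <= length(SIM_CIRC_COMBOS)) {
        ij <- SIM_CIRC_COMBOS[[p]]
        p <- p + 1L
        key <- paste(k, ij[1], ij[2])
        if (key %in% used) next
        if (k %in% csp_hosts && identical(ij, c(3L, 4L))) next  # reserved
        used <- c(used, key)
        ci <- ci + 1L
        circ[[ci]] <- list(host = k, i = ij[1], j = ij[2])
        placed <- TRUE
        break
      }
      combo_ptr[[as.character(k)]] <- p
      if (ci >= n_internal) break
    }
    if (!placed) stop("config error: not enough hosts for n_circ_junctions")
  }
  for (f in seq_len(config$n_first_exon_circ)) {
    k <- host_cycle[((f - 1L) %% length(host_cycle)) + 1L]
    ij <- if (gene_strand[k] == "+") c(1L, 3L) else c(4L, 6L)
    key <- paste(k, ij[1], ij[2])
    if (key %in% used) { k <- host_cycle[(f %% length(host_cycle)) + 1L]
    ij <- if (gene_strand[k] == "+") c(1L, 3L) else c(4L, 6L) }
    used <- c(used, paste(k, ij[1], ij[2]))
    circ[[length(circ) + 1L]] <- list(host = k, i = ij[1], j = ij[2])
    ## a terminal exon has no flanking intron on one side; plant the
    ## missing dinucleotide just outside the gene so the junction is
    ## refinable
    ex <- exon_tabs[[k]]
    if (gene_strand[k] == "+") {
      seqs[[gene_chrom[k]]] <- write_seq0(seqs[[gene_chrom[k]]],
                                          ex$start[1L] - 2L, "AG")
    } else {
      seqs[[gene_chrom[k]]] <- write_seq0(seqs[[gene_chrom[k]]],
                                          ex$end[SIM_N_EXONS], "CT")
    }
  }
  ## sponge circles on their reserved hosts, genomic exons 3-4
  for (h in csp_hosts)
    circ[[length(circ) + 1L]] <- list(host = h, i = 3L, j = 4L, sponge = TRUE)

  circ_template <- data.table(
    circ_id = character(), chrom = character(), strand = character(),
    acceptor = integer(), donor = integer(), host_gene = character(),
    host_transcript = character(), exon_i = integer(), exon_j = integer(),
    sponge = logical(), uses_first_exon = logical(),
    uses_last_exon = logical())
  circ_dt <- rbindlist(lapply(circ, function(cc) {
    k <- cc$host; ex <- exon_tabs[[k]]
    acc <- ex$start[cc$i]; don <- ex$end[cc$j]
    data.table(circ_id = sprintf("circ_%s_%d_%d_%s", gene_chrom[k], acc, don,
                                 gene_strand[k]),
               chrom = gene_chrom[k], strand = gene_strand[k],
               acceptor = acc, donor = don,
               host_gene = gene_ids[k], host_transcript = tx_ids[k],
               exon_i = cc$i, exon_j = cc$j,
               sponge = isTRUE(cc$sponge),
               uses_first_exon = if (gene_strand[k] == "+") cc$i == 1L else
                 cc$j == SIM_N_EXONS,
               uses_last_exon = if (gene_strand[k] == "+") cc$j == SIM_N_EXONS else
                 cc$i == 1L)
  }))
  if (nrow(circ_dt) == 0L) circ_dt <- circ_template

  ## --- decoy regions: scrub reversed-order no-motif decoys in the tail ---
  decoy_regions <- lapply(chroms, function(ch)
    c(config$chrom_length_bp - SIM_TAIL_MARGIN + 1000L,
      config$chrom_length_bp - 1000L))
  names(decoy_regions) <- chroms

  ## --- assemble transcript sets ---
  cod_tr <- data.table(transcript_id = tx_ids, gene_id = gene_ids,
                       chrom = gene_chrom, strand = gene_strand,
                       biotype = "coding", read_coverage = 10)
  cod_ex <- rbindlist(exon_tabs)
  ltr <- if (length(lnc_tr)) rbindlist(lnc_tr) else
    data.table(transcript_id = character(), gene_id = character(),
               chrom = character(), strand = character(),
               biotype = character(), read_coverage = numeric())
  lex <- if (length(lnc_ex)) rbindlist(lnc_ex) else
    data.table(transcript_id = character(), start = integer(),
               end = integer())
  annotation <- transcript_set(rbind(cod_tr, ltr),
                               rbind(cod_ex, lex)[, .(transcript_id, start, end)])
  asm_tr <- copy(rbind(cod_tr, ltr))[, biotype := "unknown"]
  assembled <- transcript_set(asm_tr,
                              rbind(cod_ex, lex)[, .(transcript_id, start, end)])
  ## known annotation: all mRNAs, plus a fraction of the lncRNAs
  n_known <- round(config$frac_known_lnc * nrow(ltr))
  known_lnc <- if (n_known > 0L) sort(ltr$transcript_id)[seq_len(n_known)] else
    character(0)
  kn_tr <- rbind(copy(cod_tr)[, transcript_id := paste0("known_", transcript_id)],
                 copy(ltr[transcript_id %in% known_lnc])[
                   , `:=`(transcript_id = paste0("known_", transcript_id),
                          biotype = "known_lncRNA")])
  kn_ex <- rbind(copy(cod_ex), copy(lex[transcript_id %in% known_lnc]))
  kn_ex[, transcript_id := paste0("known_", transcript_id)]
  known_db <- transcript_set(kn_tr, kn_ex[, .(transcript_id, start, end)])

  ## --- co-expressed pairs and ceRNA triple skeletons ---
  all_lnc <- sort(ltr$transcript_id)
  pool_tx <- tx_ids[generic_pool]
  triples <- list()
  sponge_circs <- circ_dt[sponge == TRUE, circ_id]
  lnc_sponges <- grep("^lnc_intergenic", all_lnc, value = TRUE)
  for (t in seq_len(config$n_cerna_triples)) {
    if (t %% 2L == 1L) {
      sp <- lnc_sponges[((t - 1L) %/% 2L) %% max(1L, length(lnc_sponges)) + 1L]
      sptype <- "lncRNA"
    } else {
      sp <- sponge_circs[((t %/% 2L - 1L) %% max(1L, length(sponge_circs))) + 1L]
      sptype <- "circRNA"
    }
    triples[[t]] <- data.table(sponge_id = sp, sponge_type = sptype,
                               mrna_id = pool_tx[t])
  }
  pair_mrnas <- pool_tx[config$n_cerna_triples + seq_len(config$n_coexpressed_pairs)]
  pair_lncs <- grep("^lnc_(sense|antisense|bidirectional)", all_lnc, value = TRUE)
  pairs <- if (config$n_coexpressed_pairs > 0L)
    data.table(noncoding_id = pair_lncs[((seq_len(config$n_coexpressed_pairs) - 1L) %%
                                           max(1L, length(pair_lncs))) + 1L],
               mrna_id = pair_mrnas,
               sign = c(rep("positive", config$n_coexpressed_pairs -
                              config$n_negative_pairs),
                        rep("negative", config$n_negative_pairs)))
  else data.table(noncoding_id = character(), mrna_id = character(),
                  sign = character())

  genome <- gsc_genome(vapply(seqs, paste, character(1), collapse = ""))
  truth <- list(circ_junctions = circ_dt,
                lnc_classes = if (length(lnc_classes))
                  data.table(transcript_id = names(lnc_classes),
                             class = unlist(lnc_classes))
                else data.table(transcript_id = character(),
                                class = character()),
                known_lnc_ids = known_lnc,
                coexpressed_pairs = pairs,
                cerna_triples = if (length(triples)) rbindlist(triples) else
                  data.table(sponge_id = character(), sponge_type = character(),
                             mrna_id = character()),
                decoy_regions = decoy_regions,
                coding_ids = tx_ids)
  list(genome = genome, annotation = annotation, assembled = assembled,
       known_db = known_db, truth = truth)
}

## iteratively insert in-frame stops until the sequence is noncoding under
## the cascade's two ORF rules; mutations restricted to `allowed` genomic
## interval c(start, end) (0-based half-open)
scrub_orfs <- function(chrom_seq, exons, strand, allowed) {
  for (iter in 1:100) {
    tseq <- transcript_sequence(list(seq = list(x = chrom_seq)),
                                exons, "x", strand)
    cp <- coding_potential(tseq)
    if (!cp$is_coding) return(chrom_seq)
    orf <- longest_orf(tseq)
    cand <- seq.int(orf$orf_start + 3L, orf$orf_start + orf$max_orf_bp - 6L,
                    by = 3L)
    done <- FALSE
    for (cc in cand) {
      g <- sort(transcript_to_genome(exons, strand, c(cc, cc + 1L, cc + 2L)))
      if (g[3] - g[1] != 2L) next                       # straddles an intron
      if (g[1] < allowed[1] || g[3] >= allowed[2]) next # outside allowed
      ## write only the 3 changed bases (reference-strand order)
      bases <- strsplit(if (strand == "-") revcomp_dna("TAA") else "TAA",
                        "", fixed = TRUE)[[1]]
      if (length(chrom_seq) > 1L) {
        chrom_seq[g + 1L] <- bases
      } else {
        for (bi in 1:3)
          chrom_seq <- write_seq0(chrom_seq, g[bi], bases[bi])
      }
      done <- TRUE
      break
    }
    if (!done) stop("simulation error: cannot scrub ORF within allowed region")
  }
  stop("simulation error: ORF scrubbing did not converge")
}

# ---- split reads -------------------------------------------------------

#' Simulate backsplice-supporting split reads plus decoys
#'
#' For each planted junction, `circ_read_depth` reads are emitted whose 5'
#' segment ends at the donor (rightmost circle boundary) and whose 3'
#' segment starts at the acceptor (leftmost boundary) — the reversed-order
#' signature of a backsplice. Decoys: genomic-order (linear splice) reads,
#' reversed-order pairs > 100 kb apart, and reversed-order pairs whose
#' flanking windows are scrubbed of GT/AG (these also mutate the genome
#' tail regions; the scrubbed genome is returned). PCR duplicates are
#' injected as byte-identical rows at `pcr_dup_rate`.
#'
#' @param genome `gsc_genome`.
#' @param truth planted truth from [simulate_genome_annotation()].
#' @param config `sim_config`.
#' @return list: `alignments` (split-alignment data.table), `genome`
#'   (possibly motif-scrubbed).
#' @export
simulate_backsplice_reads <- function(genome, truth, config) {
  set.seed(config$seed + 30000L)
  if (config$read_len < 2L * config$min_seg_len)
    stop("config error: read_len must be at least 2 * min_seg_len")
  libs <- c(paste0("SSC_", seq_len(config$n_libraries_per_condition)),
            paste0("FGSC_", seq_len(config$n_libraries_per_condition)))
  rows <- list()
  jx <- truth$circ_junctions
  rid <- 0L
  for (i in seq_len(nrow(jx))) {
    for (r in seq_len(config$circ_read_depth)) {
      L1 <- sample(config$min_seg_len:(config$read_len - config$min_seg_len), 1L)
      L2 <- config$read_len - L1
      rid <- rid + 1L
      rows[[length(rows) + 1L]] <- data.table(
        read_id = sprintf("bs_%05d", rid),
        sample_id = sample(libs, 1L),
        chrom = jx$chrom[i], strand = jx$strand[i],
        seg1_start = jx$donor[i] - L1, seg1_end = jx$donor[i],
        seg2_start = jx$acceptor[i], seg2_end = jx$acceptor[i] + L2)
    }
  }
  ## linear-splice decoys: segments in genomic order across a real intron
  if (config$n_decoy_linear > 0L && nrow(jx) >= 0L) {
    chroms <- names(genome$seq)
    for (d in seq_len(config$n_decoy_linear)) {
      ch <- chroms[((d - 1L) %% length(chroms)) + 1L]
      base <- SIM_HEAD_MARGIN + SIM_EXON_LEN  # inside first gene region
      L1 <- sample(config$min_seg_len:(config$read_len - config$min_seg_len), 1L)
      rows[[length(rows) + 1L]] <- data.table(
        read_id = sprintf("decoy_lin_%03d", d), sample_id = sample(libs, 1L),
        chrom = ch, strand = sample(c("+", "-"), 1L),
        seg1_start = base - L1, seg1_end = base,
        seg2_start = base + SIM_INTRON_LEN,
        seg2_end = base + SIM_INTRON_LEN + (config$read_len - L1))
    }
  }
  ## reversed-order decoys > 100 kb apart (where the chromosome allows)
  span_needed <- 110000L + 2L * config$read_len
  if (config$n_decoy_far > 0L && config$chrom_length_bp > span_needed) {
    chroms <- names(genome$seq)
    for (d in seq_len(config$n_decoy_far)) {
      ch <- chroms[((d - 1L) %% length(chroms)) + 1L]
      span <- sample(110000:min(140000L, config$chrom_length_bp - 200L), 1L)
      x <- sample(0:(config$chrom_length_bp - span - 200L), 1L)
      L1 <- 40L; L2 <- config$read_len - L1
      rows[[length(rows) + 1L]] <- data.table(
        read_id = sprintf("decoy_far_%03d", d), sample_id = sample(libs, 1L),
        chrom = ch, strand = "+",
        seg1_start = x + span - L1, seg1_end = x + span,
        seg2_start = x, seg2_end = x + L2)
    }
  }
  ## reversed-order decoys with scrubbed motif windows, in the tail region
  if (config$n_decoy_nomotif > 0L) {
    chroms <- names(genome$seq)
    for (d in seq_len(config$n_decoy_nomotif)) {
      ch <- chroms[((d - 1L) %% length(chroms)) + 1L]
      reg <- truth$decoy_regions[[ch]]
      acc <- reg[1] + 200L + d * 40L
      don <- acc + 1000L
      st <- sample(c("+", "-"), 1L)
      genome$seq[[ch]] <- scrub_motif_windows(genome$seq[[ch]], st, acc, don)
      L1 <- 40L; L2 <- config$read_len - L1
      rows[[length(rows) + 1L]] <- data.table(
        read_id = sprintf("decoy_nm_%03d", d), sample_id = sample(libs, 1L),
        chrom = ch, strand = st,
        seg1_start = don - L1, seg1_end = don,
        seg2_start = acc, seg2_end = acc + L2)
    }
  }
  if (length(rows) == 0L) {
    empty <- data.table(read_id = character(), sample_id = character(),
                        chrom = character(), strand = character(),
                        seg1_start = integer(), seg1_end = integer(),
                        seg2_start = integer(), seg2_end = integer())
    return(list(alignments = empty, genome = genome))
  }
  aln <- rbindlist(rows)
  ## PCR duplicates: identical rows appended
  if (config$pcr_dup_rate > 0 && nrow(aln) > 0L) {
    dup <- aln[runif(.N) < config$pcr_dup_rate]
    aln <- rbind(aln, dup)
  }
  list(alignments = aln, genome = genome)
}

## destroy every coupled GT/AG (or CT/AC) pairing within the +/-10 windows
## of a decoy junction
scrub_motif_windows <- function(seq, strand, acceptor, donor,
                                window = MOTIF_WINDOW) {
  din <- if (strand == "+") c("GT", "AG") else c("CT", "AC")
  repeat {
    hit <- NA_integer_
    for (d in seq.int(-window, window)) {
      if (subseq0(seq, donor + d, donor + d + 2L) == din[1] &&
          subseq0(seq, acceptor - 2L + d, acceptor + d) == din[2]) {
        hit <- d; break
      }
    }
    if (is.na(hit)) return(seq)
    b <- subseq0(seq, donor + hit, donor + hit + 1L)
    seq <- write_seq0(seq, donor + hit,
                      setdiff(c("A", "C", "G", "T"), b)[1])
  }
}

# ---- miRNAs and seed sites --------------------------------------------

#' Simulate miRNA sequences
#'
#' 22-nt RNA sequences with pairwise distinct seeds (nucleotides 2-8).
#'
#' @param config `sim_config`.
#' @return named character vector (`miR_1`, ...), RNA alphabet.
#' @export
simulate_mirnas <- function(config) {
  set.seed(config$seed + 10000L)
  out <- character(0); seeds <- character(0)
  while (length(out) < config$n_mirnas) {
    s <- paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
               collapse = "")
    sd7 <- substr(s, 2L, 8L)
    if (sd7 %in% seeds) next
    seeds <- c(seeds, sd7)
    out <- c(out, s)
  }
  stats::setNames(out, if (config$n_mirnas > 0L)
    paste0("miR_", seq_len(config$n_mirnas)) else character(0))
}

#' Plant miRNA seed sites and scrub spurious matches
#'
#' For each ceRNA triple the reverse complement of the miRNA seed (nt 2-8)
#' is written into the sponge sequence and into the 3' region of the target
#' mRNA at recorded positions; afterwards every transcript (and sponge
#' circle, junction-aware) is scrubbed of spurious seed matches for all
#' simulated miRNAs, preserving coding/noncoding status and planted sites.
#'
#' @param genome `gsc_genome` (mutated copy returned).
#' @param annotation truth `transcript_set`.
#' @param mirnas named miRNA vector from [simulate_mirnas()].
#' @param truth planted truth (triple skeletons filled in).
#' @param config `sim_config`.
#' @return list: `genome`, `truth` (with `cerna_triples` carrying
#'   `mirna_id`, `sponge_pos`, `mrna_pos`).
#' @export
plant_seed_sites <- function(genome, annotation, mirnas, truth, config) {
  set.seed(config$seed + 20000L)
  ## work on base vectors; restored to strings on return
  genome$seq <- lapply(genome$seq, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  tri <- copy(truth$cerna_triples)
  if (nrow(tri) > 0L && length(mirnas) == 0L)
    stop("config error: ceRNA triples need n_mirnas > 0")
  tri[, `:=`(mirna_id = NA_character_, sponge_pos = NA_integer_,
             mrna_pos = NA_integer_)]
  planted <- list()  # seq_key -> integer positions (0-based starts)
  mark <- function(key, pos) planted[[key]] <<- c(planted[[key]], pos)

  get_tx <- function(id) {
    tr <- annotation$transcripts[transcript_id == id]
    ex <- annotation$exons[transcript_id == id][order(start)]
    list(tr = tr, ex = ex)
  }
  write_at <- function(id, tpos, what) {
    tx <- get_tx(id)
    seq <- transcript_sequence(genome, tx$ex, tx$tr$chrom, tx$tr$strand)
    seq <- paste0(substr(seq, 1L, tpos), what,
                  substr(seq, tpos + nchar(what) + 1L, nchar(seq)))
    genome$seq[[tx$tr$chrom]] <<- write_transcript_seq(genome$seq[[tx$tr$chrom]],
                                                       tx$ex, tx$tr$strand, seq)
  }
  circ_exons <- function(cid) {
    cj <- truth$circ_junctions[circ_id == cid]
    tx <- get_tx(cj$host_transcript)
    list(tr = tx$tr, ex = tx$ex[cj$exon_i:cj$exon_j])
  }
  write_circ_at <- function(cid, cpos, what) {
    cx <- circ_exons(cid)
    seq <- transcript_sequence(genome, cx$ex, cx$tr$chrom, cx$tr$strand)
    seq <- paste0(substr(seq, 1L, cpos), what,
                  substr(seq, cpos + nchar(what) + 1L, nchar(seq)))
    genome$seq[[cx$tr$chrom]] <<- write_transcript_seq(genome$seq[[cx$tr$chrom]],
                                                       cx$ex, cx$tr$strand, seq)
  }

  if (nrow(tri) > 0L) for (t in seq_len(nrow(tri))) {
    mi <- names(mirnas)[((t - 1L) %% length(mirnas)) + 1L]
    site <- revcomp_dna(chartr("Uu", "TT", substr(mirnas[[mi]], 2L, 8L)))
    if (tri$sponge_type[t] == "lncRNA") {
      spos <- 100L                       # inside the lncRNA's second exon
      write_at(tri$sponge_id[t], spos, site)
      mark(tri$sponge_id[t], spos)
    } else {
      spos <- 30L                        # inside the circle's first exon
      write_circ_at(tri$sponge_id[t], spos, site)
      mark(tri$sponge_id[t], spos)
      ## the same bases belong to the host mRNA; protect them there too
      cj <- truth$circ_junctions[circ_id == tri$sponge_id[t]]
      off <- if (cj$strand == "+") (cj$exon_i - 1L) * SIM_EXON_LEN else
        (SIM_N_EXONS - cj$exon_j) * SIM_EXON_LEN
      mark(cj$host_transcript, off + spos)
    }
    mpos <- 850L                         # 3' UTR region (transcription exon 5)
    write_at(tri$mrna_id[t], mpos, site)
    mark(tri$mrna_id[t], mpos)
    tri[t, `:=`(mirna_id = mi, sponge_pos = spos, mrna_pos = mpos)]
  }

  ## global scrub: no spurious seed matches for any simulated miRNA, while
  ## keeping mRNAs coding and lncRNAs noncoding
  if (length(mirnas) > 0L) {
    lnc_ids <- truth$lnc_classes$transcript_id
    scan_ids <- annotation$transcripts$transcript_id
    sponge_circ_ids <- truth$circ_junctions[sponge == TRUE, circ_id]
    orf_iv <- c(30L, 360L)  # planted ORF interval in transcript coords
    ## a sponge circle shares genome bases with its host transcript; a
    ## mutation in one dirties the other
    partner <- list()
    for (cid in sponge_circ_ids) {
      h <- truth$circ_junctions[circ_id == cid, host_transcript]
      partner[[cid]] <- h; partner[[h]] <- cid
    }
    dirty <- c(scan_ids, sponge_circ_ids)
    for (iter in 1:60) {
      next_dirty <- character(0)
      for (id in intersect(scan_ids, dirty)) {
        tx <- get_tx(id)
        seq <- transcript_sequence(genome, tx$ex, tx$tr$chrom, tx$tr$strand)
        is_lnc <- id %in% lnc_ids
        touched <- FALSE
        for (mi in names(mirnas)) {
          repeat {
            sites <- find_seed_sites(seq, mirnas[[mi]])
            spurious <- setdiff(sites$pos, planted[[id]])
            if (length(spurious) == 0L) break
            seq <- break_site(seq, spurious[1], planted[[id]],
                              orf = if (!is_lnc) orf_iv else NULL)
            touched <- TRUE
          }
        }
        if (touched) {
          write_at(id, 0L, seq)
          next_dirty <- c(next_dirty, id, partner[[id]])
        }
      }
      for (cid in intersect(sponge_circ_ids, dirty)) {
        cx <- circ_exons(cid)
        seq <- transcript_sequence(genome, cx$ex, cx$tr$chrom, cx$tr$strand)
        touched <- FALSE
        for (mi in names(mirnas)) {
          repeat {
            sites <- find_seed_sites_circular(seq, mirnas[[mi]])
            spurious <- setdiff(sites$pos, planted[[cid]])
            if (length(spurious) == 0L) break
            seq <- break_site(seq, spurious[1], planted[[cid]], orf = NULL)
            touched <- TRUE
          }
        }
        if (touched) {
          write_circ_at(cid, 0L, seq)
          next_dirty <- c(next_dirty, cid, partner[[cid]])
        }
      }
      ## re-establish noncoding status of lncRNAs (a scrub mutation or a
      ## planted site can create an ORF)
      for (id in intersect(lnc_ids, dirty)) {
        tx <- get_tx(id)
        seq <- transcript_sequence(genome, tx$ex, tx$tr$chrom, tx$tr$strand)
        if (coding_potential(seq)$is_coding) {
          allowed <- lnc_scrub_interval(tx$ex, planted[[id]], tx$tr$strand)
          genome$seq[[tx$tr$chrom]] <- scrub_orfs(genome$seq[[tx$tr$chrom]],
                                                  tx$ex, tx$tr$strand, allowed)
          next_dirty <- c(next_dirty, id)
        }
      }
      if (length(next_dirty) == 0L) break
      dirty <- unique(next_dirty)
      if (iter == 60L) stop("simulation error: seed-site scrubbing did not converge")
    }
  }
  truth$cerna_triples <- tri
  genome$seq <- vapply(genome$seq, paste, character(1), collapse = "")
  list(genome = genome, truth = truth)
}

## mutate one base of a spurious seed site, avoiding planted-site positions
## and (inside an mRNA ORF) avoiding stop-codon creation
break_site <- function(seq, site_pos, protected, orf = NULL) {
  stops <- c("TAA", "TAG", "TGA")
  for (off in c(3L, 2L, 4L, 1L, 5L, 0L, 6L)) {
    p <- site_pos + off                  # 0-based
    if (p >= nchar(seq)) next
    if (length(protected) > 0L &&
        any(p >= protected & p < protected + 7L)) next
    cur <- substr(seq, p + 1L, p + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), cur)) {
      cand <- paste0(substr(seq, 1L, p), alt, substr(seq, p + 2L, nchar(seq)))
      if (!is.null(orf) && p >= orf[1] && p < orf[2]) {
        cstart <- orf[1] + ((p - orf[1]) %/% 3L) * 3L
        codon <- substr(cand, cstart + 1L, cstart + 3L)
        if (codon %in% stops) next
        if (cstart == orf[1] && codon != "ATG") next
      }
      return(cand)
    }
  }
  stop("simulation error: cannot break spurious seed site")
}

## interval (genomic) where ORF-scrubbing of a lncRNA may mutate: the whole
## transcript footprint minus planted seed sites; planted sites are
## protected per-base via the exclusion in scrub_orfs' allowed window, so
## here we simply keep the widest safe window away from planted sites
lnc_scrub_interval <- function(exons, protected_tpos, strand) {
  ## conservative: allow the second (genomically later) exon, which never
  ## carries host splice dinucleotides; planted lncRNA sites sit at
  ## transcript position 100 which maps into exon 2 only for plus-strand
  ## nested lncRNAs -- shrink the window to dodge them
  lo <- exons$start[nrow(exons)] + 8L
  hi <- exons$end[nrow(exons)] - 2L
  if (length(protected_tpos) > 0L) {
    g <- sort(transcript_to_genome(exons, strand,
                                   as.integer(protected_tpos[1] + 0:6)))
    if (g[1] >= lo && g[7] <= hi) {
      ## split: keep the larger side
      left <- c(lo, g[1]); right <- c(g[7] + 1L, hi)
      if (diff(left) >= diff(right)) return(left) else return(right)
    }
  }
  c(lo, hi)
}

# ---- counts ------------------------------------------------------------

#' Simulate NB fragment counts with planted structure
#'
#' Counts are NB(mu, dispersion) per transcript and library. Planted
#' male-biased ids get mu multiplied by the fold change in SSC libraries
#' (symmetrically for female-biased ids, which are preferentially drawn
#' from the X chromosome). Co-expressed pairs and ceRNA gate pairs share a
#' per-library latent log-normal factor at high expression and low
#' dispersion so their FPKM correlation exceeds 0.99 / 0.9 in expectation;
#' pair members are forced male-biased so they survive the sex-biased
#' screens downstream.
#'
#' @param annotation truth `transcript_set`.
#' @param truth planted truth (circ junction table used for circ ids).
#' @param config `sim_config`.
#' @return list: `counts` (data.table, transcript_id + one column per
#'   library), `condition` (named vector), `effective_length` (named
#'   vector), `truth` (with `sex_biased` filled in).
#' @export
simulate_counts <- function(annotation, truth, config) {
  set.seed(config$seed + 40000L)
  if (config$nb_dispersion <= 0) stop("config error: dispersion must be > 0")
  nlib <- config$n_libraries_per_condition
  libs <- c(paste0("SSC_", seq_len(nlib)), paste0("FGSC_", seq_len(nlib)))
  condition <- stats::setNames(rep(c("SSC", "FGSC"), each = nlib), libs)

  slen <- spliced_lengths(annotation)
  ids <- sort(names(slen))
  chrom_of <- stats::setNames(annotation$transcripts$chrom,
                              annotation$transcripts$transcript_id)
  cj <- truth$circ_junctions
  if (nrow(cj) > 0L) {
    clen <- (cj$exon_j - cj$exon_i + 1L) * SIM_EXON_LEN
    slen <- c(slen, stats::setNames(clen, cj$circ_id))
    chrom_of <- c(chrom_of, stats::setNames(cj$chrom, cj$circ_id))
    ids <- c(ids, sort(cj$circ_id))
  }
  n <- length(ids)

  ## pair membership (co-expressed pairs + ceRNA gate pairs)
  pairs <- truth$coexpressed_pairs
  gate <- truth$cerna_triples
  pair_list <- list()
  if (nrow(pairs) > 0L) for (i in seq_len(nrow(pairs)))
    pair_list[[length(pair_list) + 1L]] <-
    list(a = pairs$noncoding_id[i], b = pairs$mrna_id[i],
         sign = pairs$sign[i])
  if (nrow(gate) > 0L) for (i in seq_len(nrow(gate)))
    pair_list[[length(pair_list) + 1L]] <-
    list(a = gate$sponge_id[i], b = gate$mrna_id[i], sign = "positive")
  pair_ids <- unique(unlist(lapply(pair_list, function(p) c(p$a, p$b))))

  ## sex-biased assignment
  free <- setdiff(ids, pair_ids)
  on_x <- free[chrom_of[free] == "chrX"]
  off_x <- setdiff(free, on_x)
  n_fem <- round(config$frac_female_biased * n)
  n_fem_x <- min(round(config$frac_female_biased_on_X * n_fem), length(on_x))
  fem <- c(if (n_fem_x > 0L) sample(on_x, n_fem_x),
           if (n_fem - n_fem_x > 0L)
             sample(off_x, min(n_fem - n_fem_x, length(off_x))))
  rest <- setdiff(free, fem)
  n_male <- min(round(config$frac_male_biased * n), length(rest))
  male <- if (n_male > 0L) sample(rest, n_male) else character(0)
  ## pair members must survive the sex-biased screens: the noncoding side
  ## is male-biased; the mRNA side male-biased for positive pairs and
  ## female-biased for negative pairs (so the planted anti-correlation is
  ## not cancelled by a shared condition effect)
  for (p in pair_list) {
    male <- union(male, p$a)
    if (p$sign == "negative") fem <- union(fem, p$b) else
      male <- union(male, p$b)
  }

  fc <- config$fold_change_planted
  base <- pmax(rlnorm(n, meanlog = log(config$mean_expression), sdlog = 1), 20)
  names(base) <- ids
  base[pair_ids] <- config$pair_expression
  disp <- stats::setNames(rep(config$nb_dispersion, n), ids)
  disp[pair_ids] <- config$pair_dispersion

  mu <- matrix(rep(base, length(libs)), nrow = n,
               dimnames = list(ids, libs))
  mu[male, condition[libs] == "SSC"] <- mu[male, condition[libs] == "SSC"] * fc
  mu[fem, condition[libs] == "FGSC"] <- mu[fem, condition[libs] == "FGSC"] * fc
  ## shared latent factor per pair and library; together with the shared
  ## (or opposed) condition fold change this drives |FPKM PCC| above 0.99
  ## while keeping within-condition variance NB-like
  for (p in pair_list) {
    f <- rlnorm(length(libs), 0, config$pair_factor_sdlog)
    mu[p$a, ] <- mu[p$a, ] * f
    mu[p$b, ] <- mu[p$b, ] * (if (p$sign == "negative") 1 / f else f)
  }
  counts <- matrix(0L, nrow = n, ncol = length(libs),
                   dimnames = list(ids, libs))
  for (i in seq_len(n))
    counts[i, ] <- rnbinom(length(libs), mu = mu[i, ], size = 1 / disp[[i]])

  mk_dir <- function(ids, dir) {
    if (length(ids) == 0L)
      return(data.table(transcript_id = character(), direction = character()))
    data.table(transcript_id = sort(ids), direction = dir)
  }
  truth$sex_biased <- rbind(mk_dir(male, "male_biased"),
                            mk_dir(fem, "female_biased"))
  ct <- data.table(transcript_id = ids)
  for (lb in libs) ct[[lb]] <- counts[, lb]
  ## libraries are sequenced to equal depth; the simulated transcripts are
  ## a subset of each library, so the mapped-fragment total is a constant
  ## larger than the column sum
  list(counts = ct, condition = condition,
       library_size = stats::setNames(rep(1e6, length(libs)), libs),
       effective_length = slen[ids], truth = truth)
}

# ---- orchestration -----------------------------------------------------

#' Run the full simulator
#'
#' @param config `sim_config`.
#' @return list with `genome`, `annotation`, `assembled`, `known_db`,
#'   `alignments`, `mirnas`, `counts`, `condition`, `effective_length`,
#'   `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  g <- simulate_genome_annotation(config)
  mirnas <- simulate_mirnas(config)
  pl <- plant_seed_sites(g$genome, g$annotation, mirnas, g$truth, config)
  rd <- simulate_backsplice_reads(pl$genome, pl$truth, config)
  cn <- simulate_counts(g$annotation, pl$truth, config)
  list(genome = rd$genome, annotation = g$annotation,
       assembled = g$assembled, known_db = g$known_db,
       alignments = rd$alignments, mirnas = mirnas,
       counts = cn$counts, condition = cn$condition,
       library_size = cn$library_size,
       effective_length = cn$effective_length,
       truth = cn$truth, config = config)
}

#' Write a simulated dataset to a directory
#'
#' Emits genome FASTA, truth/assembled/known GTFs, split-alignment TSV,
#' count TSV, condition TSV, miRNA FASTA, truth JSON and config JSON.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$genome, p("genome.fa"))
  write_gtf(sim$annotation, p("annotation.gtf"))
  write_gtf(sim$assembled, p("assembled.gtf"))
  write_gtf(sim$known_db, p("known.gtf"))
  write_split_alignments(sim$alignments, p("alignments.tsv"))
  write_count_table(sim$counts, p("counts.tsv"))
  fwrite(data.table(library_id = names(sim$condition),
                    condition = unname(sim$condition),
                    library_size = unname(sim$library_size[names(sim$condition)])),
         p("condition.tsv"), sep = "\t")
  if (length(sim$mirnas) > 0L) {
    writeLines(paste0(">", names(sim$mirnas), "\n",
                      chartr("Uu", "TT", sim$mirnas)), p("mirnas.fa"))
  }
  truth <- sim$truth
  truth$decoy_regions <- NULL
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(sim$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("genome.fa", "annotation.gtf", "assembled.gtf", "known.gtf",
             "alignments.tsv", "counts.tsv", "condition.tsv", "truth.json",
             "config.json")
  stats::setNames(file.path(dir, files), files)
}
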