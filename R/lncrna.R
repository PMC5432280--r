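## Six-step lncRNA identification cascade.
##
## Order of application (first failure recorded as the reject reason):
##   1. structure: single exon OR spliced length < 200 bp
##   2. evidence:  read coverage < 3, then max FPKM over libraries < 0.01
##   3. known lncRNA by intron-chain congruence -> known_lncRNA
##   4. housekeeping-RNA overlap (rRNA/tRNA/snRNA/snoRNA/pre-miRNA/
##      pseudogene, >= 1 bp, same strand) -> rejected
##   5. intron chain identical to a known mRNA -> rejected
##   6. coding potential: two ORF rules intersected; noncoding only when
##      BOTH call noncoding (stand-in for CNCI/CPC intersection)
## Survivors are novel lncRNAs and get a positional class.

LNC_MIN_LEN      <- 200L
LNC_MIN_COVERAGE <- 3
LNC_MIN_FPKM     <- 0.01
ORF_CODING_BP    <- 300L
ORF_CODING_FRAC  <- 0.5
BIDIR_WINDOW     <- 1000L
HOUSEKEEPING     <- c("rRNA", "tRNA", "snRNA", "snoRNA", "pre_miRNA",
                      "pseudogene")

## ordered internal splice sites (intron chain) per transcript, as a single
## key string "chrom:strand:e1|s2,e2|s3,..." -- empty for monoexonic
intron_chain_keys <- function(ts) {
  ex <- merge(ts$exons, ts$transcripts[, .(transcript_id, chrom, strand)],
              by = "transcript_id")
  setorder(ex, transcript_id, start)
  ch <- ex[, .(chain = if (.N < 2L)
    NA_character_
  else paste0(chrom[1L], ":", strand[1L], ":",
              paste(end[-.N], start[-1L], sep = "|", collapse = ",")),
  chrom = chrom[1L], strand = strand[1L]), by = transcript_id]
  ch
}

#' Structural and evidence filters (cascade steps 1-2)
#'
#' Rejects monoexonic or sub-200-bp transcripts, then transcripts with read
#' coverage below 3, then transcripts whose FPKM never reaches 0.01 in any
#' library.
#'
#' @param ts assembled `transcript_set` (with `read_coverage`).
#' @param fpkm numeric matrix, transcripts x libraries, rownames =
#'   transcript ids. Every transcript in `ts` must be present.
#' @param min_len,min_coverage,min_fpkm thresholds (defaults 200 bp, 3
#'   reads, 0.01).
#' @return data.table `transcript_id`, `status` (`"candidate"` or
#'   `"rejected"`), `reject_reason`.
#' @export
filter_structure <- function(ts, fpkm, min_len = LNC_MIN_LEN,
                             min_coverage = LNC_MIN_COVERAGE,
                             min_fpkm = LNC_MIN_FPKM) {
  ids <- ts$transcripts$transcript_id
  if (!all(ids %in% rownames(fpkm)))
    stop("configuration error: FPKM missing for some transcripts")
  nex <- ts$exons[, .N, by = transcript_id]
  nexv <- stats::setNames(nex$N, nex$transcript_id)[ids]
  slen <- spliced_lengths(ts)[ids]
  cov <- stats::setNames(ts$transcripts$read_coverage, ids)[ids]
  maxfpkm <- apply(fpkm[ids, , drop = FALSE], 1, max)

  reason <- rep(NA_character_, length(ids))
  reason[is.na(reason) & (nexv == 1L | slen < min_len)] <- "short_or_monoexonic"
  reason[is.na(reason) & cov < min_coverage] <- "low_coverage"
  reason[is.na(reason) & maxfpkm < min_fpkm] <- "low_fpkm"
  data.table(transcript_id = ids,
             status = ifelse(is.na(reason), "candidate", "rejected"),
             reject_reason = reason)
}

#' Known-transcript matching (cascade steps 3-5)
#'
#' A candidate whose intron chain (ordered internal splice sites on the same
#' chromosome and strand) is identical to a known lncRNA becomes
#' `known_lncRNA`. Candidates overlapping a housekeeping RNA (>= 1 bp exon
#' overlap, same strand) are rejected; candidates whose intron chain matches
#' a known coding mRNA are rejected. Monoexonic known transcripts have no
#' intron chain and never match.
#'
#' @param ts candidate `transcript_set`.
#' @param verdicts verdict table from [filter_structure()]; only
#'   `"candidate"` rows are touched.
#' @param known_db `transcript_set` of known annotation (biotypes
#'   `known_lncRNA`, `coding`, housekeeping classes).
#' @return updated verdict table.
#' @export
match_known <- function(ts, verdicts, known_db) {
  v <- copy(verdicts)
  cand <- v[status == "candidate", transcript_id]
  if (length(cand) == 0L) return(v)

  chains <- intron_chain_keys(ts)
  kchains <- intron_chain_keys(known_db)
  kb <- merge(kchains, known_db$transcripts[, .(transcript_id, biotype)],
              by = "transcript_id")
  lnc_chains  <- kb[biotype == "known_lncRNA" & !is.na(chain), chain]
  mrna_chains <- kb[biotype == "coding" & !is.na(chain), chain]

  ## housekeeping overlap via IRanges, per chrom+strand
  hk_ids <- known_db$transcripts[biotype %in% HOUSEKEEPING, transcript_id]
  hk_ex <- merge(known_db$exons[transcript_id %in% hk_ids],
                 known_db$transcripts[, .(transcript_id, chrom, strand)],
                 by = "transcript_id")
  cand_ex <- merge(ts$exons[transcript_id %in% cand],
                   ts$transcripts[, .(transcript_id, chrom, strand)],
                   by = "transcript_id")
  hk_overlap <- character(0)
  if (nrow(hk_ex) > 0L && nrow(cand_ex) > 0L) {
    for (grp in split(seq_len(nrow(cand_ex)),
                      paste(cand_ex$chrom, cand_ex$strand))) {
      ch <- cand_ex$chrom[grp[1]]; st <- cand_ex$strand[grp[1]]
      hk_sub <- hk_ex[chrom == ch & strand == st]
      if (nrow(hk_sub) == 0L) next
      q <- IRanges::IRanges(cand_ex$start[grp] + 1L, cand_ex$end[grp])
      s <- IRanges::IRanges(hk_sub$start + 1L, hk_sub$end)
      hits <- IRanges::findOverlaps(q, s, minoverlap = 1L)
      hk_overlap <- union(hk_overlap,
                          cand_ex$transcript_id[grp[S4Vectors::queryHits(hits)]])
    }
  }

  cmap <- merge(data.table(transcript_id = cand), chains,
                by = "transcript_id")
  for (i in seq_len(nrow(cmap))) {
    id <- cmap$transcript_id[i]; chn <- cmap$chain[i]
    if (!is.na(chn) && chn %in% lnc_chains) {
      v[transcript_id == id, status := "known_lncRNA"]
    } else if (id %in% hk_overlap) {
      v[transcript_id == id,
        `:=`(status = "rejected", reject_reason = "housekeeping_overlap")]
    } else if (!is.na(chn) && chn %in% mrna_chains) {
      v[transcript_id == id,
        `:=`(status = "rejected", reject_reason = "mrna_match")]
    }
  }
  v
}

#' Coding-potential stand-in (cascade step 6)
#'
#' Two independent ORF-based rules replace the external CNCI/CPC
#' classifiers while preserving the intersection structure: a transcript is
#' noncoding only when BOTH rules call it noncoding — rule A: longest ORF
#' < 300 bp; rule B: ORF fraction of transcript length < 0.5.
#'
#' @param seq transcript sequence (transcript orientation, DNA alphabet).
#' @param min_orf_bp,min_orf_frac thresholds for rules A and B.
#' @return list `max_orf_bp`, `orf_fraction`, `is_coding`.
#' @export
coding_potential <- function(seq, min_orf_bp = ORF_CODING_BP,
                             min_orf_frac = ORF_CODING_FRAC) {
  orf <- longest_orf(seq)
  list(max_orf_bp = orf$max_orf_bp,
       orf_fraction = orf$orf_fraction,
       is_coding = (orf$max_orf_bp >= min_orf_bp) ||
         (orf$orf_fraction >= min_orf_frac))
}

#' Positional classification of a lncRNA
#'
#' Precedence sense > antisense > bidirectional > intergenic:
#' exon-overlapping a coding gene on the same strand is `sense`; on the
#' opposite strand, `antisense`; a non-overlapping transcript whose 5' end
#' lies within `window` bp of a coding gene's 5' end on the opposite strand
#' is `bidirectional`; otherwise `intergenic`.
#'
#' @param lnc_exons exon table of one transcript (0-based half-open).
#' @param lnc_chrom,lnc_strand location of the transcript.
#' @param coding `transcript_set` restricted (internally) to biotype
#'   `coding`.
#' @param window bidirectional promoter window (default 1000 bp).
#' @return one of `"sense"`, `"antisense"`, `"bidirectional"`,
#'   `"intergenic"`.
#' @export
classify_position <- function(lnc_exons, lnc_chrom, lnc_strand, coding,
                              window = BIDIR_WINDOW) {
  cod_tr <- coding$transcripts[biotype == "coding"]
  cod_ex <- merge(coding$exons[transcript_id %in% cod_tr$transcript_id],
                  cod_tr[, .(transcript_id, chrom, strand)],
                  by = "transcript_id")
  cod_ex <- cod_ex[chrom == lnc_chrom]
  if (nrow(cod_ex) > 0L) {
    q <- IRanges::IRanges(lnc_exons$start + 1L, lnc_exons$end)
    for (st in c(lnc_strand, setdiff(c("+", "-"), lnc_strand))) {
      sub <- cod_ex[strand == st]
      if (nrow(sub) == 0L) next
      s <- IRanges::IRanges(sub$start + 1L, sub$end)
      if (length(IRanges::findOverlaps(q, s, minoverlap = 1L)) > 0L)
        return(if (st == lnc_strand) "sense" else "antisense")
    }
  }
  ## bidirectional: 5' ends within window, opposite strands, no overlap
  lnc5 <- if (lnc_strand == "+") min(lnc_exons$start) else max(lnc_exons$end)
  opp <- cod_tr[chrom == lnc_chrom & strand != lnc_strand]
  if (nrow(opp) > 0L) {
    spans <- merge(coding$exons[transcript_id %in% opp$transcript_id],
                   opp[, .(transcript_id, strand)], by = "transcript_id")
    tss <- spans[, .(tss = if (strand[1L] == "+") min(start) else max(end)),
                 by = transcript_id]
    if (any(abs(tss$tss - lnc5) <= window)) return("bidirectional")
  }
  "intergenic"
}

#' Run the full lncRNA identification cascade
#'
#' @param ts assembled `transcript_set`.
#' @param genome `gsc_genome` (for ORF scanning).
#' @param known_db known annotation `transcript_set`.
#' @param fpkm FPKM matrix (transcripts x libraries).
#' @param coding_annotation `transcript_set` holding coding gene models for
#'   positional classification (defaults to `known_db`).
#' @param ... threshold overrides passed to the stage functions.
#' @return verdict data.table: `transcript_id`, `status`
#'   (`rejected`/`known_lncRNA`/`novel_lncRNA`), `reject_reason`,
#'   `positional_class`, `max_orf_bp`, `orf_fraction`.
#' @export
identify_lncrnas <- function(ts, genome, known_db, fpkm,
                             coding_annotation = known_db, ...) {
  dots <- list(...)
  v <- filter_structure(ts, fpkm,
                        min_len = dots$min_len %||% LNC_MIN_LEN,
                        min_coverage = dots$min_coverage %||% LNC_MIN_COVERAGE,
                        min_fpkm = dots$min_fpkm %||% LNC_MIN_FPKM)
  v <- match_known(ts, v, known_db)
  v[, `:=`(max_orf_bp = NA_integer_, orf_fraction = NA_real_,
           positional_class = NA_character_)]

  cand <- v[status == "candidate", transcript_id]
  for (id in cand) {
    tr <- ts$transcripts[transcript_id == id]
    exn <- ts$exons[transcript_id == id][order(start)]
    seq <- transcript_sequence(genome, exn, tr$chrom, tr$strand)
    cp <- coding_potential(seq,
                           min_orf_bp = dots$min_orf_bp %||% ORF_CODING_BP,
                           min_orf_frac = dots$min_orf_frac %||% ORF_CODING_FRAC)
    v[transcript_id == id,
      `:=`(max_orf_bp = cp$max_orf_bp, orf_fraction = cp$orf_fraction)]
    if (cp$is_coding) {
      v[transcript_id == id,
        `:=`(status = "rejected", reject_reason = "coding_potential")]
    } else {
      v[transcript_id == id, status := "novel_lncRNA"]
    }
  }
  lncs <- v[status %in% c("novel_lncRNA", "known_lncRNA"), transcript_id]
  for (id in lncs) {
    tr <- ts$transcripts[transcript_id == id]
    exn <- ts$exons[transcript_id == id][order(start)]
    v[transcript_id == id,
      positional_class := classify_position(exn, tr$chrom, tr$strand,
                                            coding_annotation,
                                            window = dots$bidir_window %||% BIDIR_WINDOW)]
  }
  v[]
}

#' Summarize lncRNA cascade verdicts
#'
#' @param verdicts output of [identify_lncrnas()].
#' @param ts the `transcript_set` the verdicts refer to (for lengths and
#'   chromosomes).
#' @return list of count tables (by status, reject reason, positional
#'   class, chromosome) plus mean spliced length and mean longest-ORF size
#'   for novel lncRNAs.
#' @export
summarize_lncrnas <- function(verdicts, ts) {
  slen <- spliced_lengths(ts)
  chrom <- stats::setNames(ts$transcripts$chrom, ts$transcripts$transcript_id)
  nov <- verdicts[status == "novel_lncRNA"]
  list(
    n_by_status = table(verdicts$status),
    n_by_reason = table(verdicts$reject_reason[!is.na(verdicts$reject_reason)]),
    n_by_class = table(nov$positional_class),
    n_by_chrom = table(chrom[nov$transcript_id]),
    mean_novel_length = if (nrow(nov)) mean(slen[nov$transcript_id]) else NA_real_,
    mean_novel_orf_bp = if (nrow(nov)) mean(nov$max_orf_bp) else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
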