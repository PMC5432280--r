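## circRNA backsplice calling from split-read alignments.
##
## A backsplice-supporting read has its 5' part (seg1) mapping genomically
## DOWNSTREAM of its 3' part (seg2): the circle joins a downstream donor to
## an upstream acceptor. Junction coordinates are strand-normalised:
## acceptor_pos is the leftmost (genomic) circle boundary, donor_pos the
## rightmost, for both strands.

MAX_CIRC_SPAN <- 100000L   # "no more than 100 kb away from each other"
MOTIF_WINDOW  <- 10L       # GT/AG searched within +/- 10 nt of each end

#' Remove PCR-duplicate split alignments
#'
#' Rows identical in `(sample_id, chrom, strand, seg1, seg2)` collapse to
#' their first occurrence; `read_id` is ignored in the key.
#'
#' @param aln split-alignment data.table (see [read_split_alignments()]).
#' @return deduplicated data.table, original order preserved.
#' @export
dedup_alignments <- function(aln) {
  keycols <- c("sample_id", "chrom", "strand",
               "seg1_start", "seg1_end", "seg2_start", "seg2_end")
  aln[!duplicated(aln, by = keycols)]
}

#' Detect raw backsplice candidates
#'
#' A deduplicated alignment yields a candidate iff both segments share one
#' chromosome and strand (guaranteed by the input dialect), the 3' read part
#' lies genomically upstream of the 5' part (`seg2_end <= seg1_start`), and
#' the outer span `seg1_end - seg2_start` is at most 100 kb. The raw
#' acceptor is `seg2_start`, the raw donor `seg1_end`. Identical raw
#' junctions merge; `support` counts merged reads.
#'
#' @param aln deduplicated split alignments.
#' @return data.table with columns `chrom`, `strand`, `acceptor`, `donor`,
#'   `support`, sorted by chrom, acceptor, donor, strand.
#' @export
detect_candidates <- function(aln) {
  cand <- aln[seg2_end <= seg1_start &
                (seg1_end - seg2_start) <= MAX_CIRC_SPAN]
  out <- cand[, .(support = .N),
              by = .(chrom, strand, acceptor = seg2_start, donor = seg1_end)]
  setorder(out, chrom, acceptor, donor, strand)
  out[]
}

## search for the coupled donor/acceptor motif pair around a raw junction.
## plus strand:  donor arm "GT" at [donor+d, donor+d+2),
##               acceptor arm "AG" at [acceptor-2+d, acceptor+d).
## minus strand: reference shows the reverse complement -- "AC" left of the
##               acceptor (leftmost) boundary and "CT" right of the donor
##               (rightmost) boundary.
## The two arms share one shift d in [-10, 10]; smallest |d| wins, ties
## prefer 0 then the negative shift.
find_motif_shift <- function(seq, strand, acceptor, donor, window = MOTIF_WINDOW) {
  n <- nchar(seq)
  if (strand == "+") { don_m <- "GT"; acc_m <- "AG" } else {
    don_m <- "CT"; acc_m <- "AC"   # reference-strand dinucleotides
  }
  shifts <- order(abs(seq.int(-window, window)),
                  seq.int(-window, window))  # 0, -1, 1, -2, 2, ...
  for (i in shifts) {
    d <- seq.int(-window, window)[i]
    dpos <- donor + d        # dinucleotide right of the right boundary
    apos <- acceptor - 2L + d  # dinucleotide left of the left boundary
    if (apos < 0L || dpos + 2L > n) next
    right_din <- subseq0(seq, dpos, dpos + 2L)
    left_din  <- subseq0(seq, apos, apos + 2L)
    ok <- if (strand == "+") {
      right_din == don_m && left_din == acc_m
    } else {
      right_din == don_m && left_din == acc_m
    }
    if (ok) return(d)
  }
  NA_integer_
}

#' Refine backsplice junctions to GT/AG splice sites
#'
#' GT and AG dinucleotides are searched within 10-nt windows flanking the
#' donor and acceptor ends of each raw junction; both arms move together by
#' one shared shift (the alignment-ambiguity offset). Candidates with no
#' valid GT/AG pair in the window are rejected; window positions outside the
#' chromosome are treated as no-hit.
#'
#' @param candidates output of [detect_candidates()].
#' @param genome a `gsc_genome`.
#' @return data.table of retained junctions with refined `acceptor`,
#'   `donor`, `motif` (always `"GTAG"` on the assigned strand), `shift`,
#'   `support`. Junctions refined to the same coordinates merge, summing
#'   support.
#' @export
refine_splice_sites <- function(candidates, genome) {
  if (nrow(candidates) == 0L)
    return(data.table(chrom = character(), strand = character(),
                      acceptor = integer(), donor = integer(),
                      motif = character(), shift = integer(),
                      support = integer()))
  shifts <- vapply(seq_len(nrow(candidates)), function(i) {
    ch <- candidates$chrom[i]
    if (!ch %in% names(genome$seq)) return(NA_integer_)
    find_motif_shift(genome$seq[[ch]], candidates$strand[i],
                     candidates$acceptor[i], candidates$donor[i])
  }, integer(1))
  ref <- candidates[!is.na(shifts)]
  sh <- shifts[!is.na(shifts)]
  ref[, `:=`(acceptor = acceptor + sh, donor = donor + sh,
             motif = "GTAG", shift = sh)]
  ref <- ref[donor - acceptor <= MAX_CIRC_SPAN & acceptor < donor]
  out <- ref[, .(support = sum(support), shift = shift[which.min(abs(shift))]),
             by = .(chrom, strand, acceptor, donor, motif)]
  setorder(out, chrom, acceptor, donor, strand)
  out[]
}

#' Annotate circRNA junctions against gene models
#'
#' The hosting gene is the gene whose genomic span contains the junction
#' interval (ties broken by largest reciprocal overlap, then lexicographic
#' gene_id). A junction is `exonic` when both boundaries coincide exactly
#' with exon boundaries of one transcript of the host, `intronic` when the
#' interval lies wholly inside one intron, and `intergenic` when no gene
#' hosts it. First/last-exon flags follow transcription order (the first
#' exon of a minus-strand transcript is the genomically rightmost one).
#'
#' @param junctions refined junctions from [refine_splice_sites()].
#' @param ts a `transcript_set` (the gene annotation).
#' @return data.table of circRNA records: junction columns plus `circ_id`,
#'   `host_gene`, `circ_class`, `uses_first_exon`, `uses_last_exon`,
#'   `strand_relation`.
#' @export
annotate_circrnas <- function(junctions, ts) {
  jx <- copy(junctions)
  jx[, circ_id := sprintf("circ_%s_%d_%d_%s", chrom, acceptor, donor, strand)]
  ex <- merge(ts$exons, ts$transcripts[, .(transcript_id, gene_id, chrom, strand)],
              by = "transcript_id")
  genes <- ex[, .(gstart = min(start), gend = max(end), strand = strand[1L]),
              by = .(gene_id, chrom)]

  host <- character(nrow(jx)); cls <- rep("intergenic", nrow(jx))
  ufe <- rep(NA, nrow(jx)); ule <- rep(NA, nrow(jx)); rel <- rep(NA_character_, nrow(jx))
  for (i in seq_len(nrow(jx))) {
    a <- jx$acceptor[i]; d <- jx$donor[i]; ch <- jx$chrom[i]
    cand <- genes[chrom == ch & gstart <= a & gend >= d]
    if (nrow(cand) == 0L) { host[i] <- NA_character_; next }
    if (nrow(cand) > 1L) {
      cand[, rec_olap := (d - a) / (gend - gstart)]  # junction fully inside
      setorder(cand, -rec_olap, gene_id)
    }
    g <- cand$gene_id[1L]
    host[i] <- g
    rel[i] <- if (jx$strand[i] == cand$strand[1L]) "sense" else "antisense"

    gex <- ex[gene_id == g]
    cls_i <- "intergenic"; ufe_i <- FALSE; ule_i <- FALSE
    for (tid in unique(gex$transcript_id)) {
      te <- gex[transcript_id == tid][order(start)]
      hit_a <- which(te$start == a); hit_d <- which(te$end == d)
      if (length(hit_a) == 1L && length(hit_d) == 1L && hit_a <= hit_d) {
        cls_i <- "exonic"
        n <- nrow(te)
        if (te$strand[1L] == "+") {
          ufe_i <- hit_a == 1L; ule_i <- hit_d == n
        } else {  # transcription order reversed
          ufe_i <- hit_d == n; ule_i <- hit_a == 1L
        }
        break
      }
    }
    if (cls_i != "exonic") {
      ## wholly inside one intron of some transcript of the host
      for (tid in unique(gex$transcript_id)) {
        te <- gex[transcript_id == tid][order(start)]
        if (nrow(te) < 2L) next
        istart <- te$end[-nrow(te)]; iend <- te$start[-1L]
        if (any(istart <= a & iend >= d)) { cls_i <- "intronic"; break }
      }
    }
    cls[i] <- cls_i
    if (cls_i == "exonic") { ufe[i] <- ufe_i; ule[i] <- ule_i }
  }
  jx[, `:=`(host_gene = host, circ_class = cls,
            uses_first_exon = ufe, uses_last_exon = ule,
            strand_relation = rel)]
  jx[is.na(host_gene), circ_class := "intergenic"]
  jx[]
}

#' Summarize a set of circRNA records
#'
#' @param records output of [annotate_circrnas()], or a data.frame with the
#'   same columns.
#' @return list with `n`, per-class counts, sense/antisense counts and
#'   fractions, and the fraction of all circRNAs missing the first or last
#'   exon of their hosting transcript (non-exonic circRNAs use no terminal
#'   exon by definition). With zero records all counts are 0 and `empty` is
#'   `TRUE` (fractions `NA`).
#' @export
summarize_circ_stats <- function(records) {
  records <- as.data.table(records)
  n <- nrow(records)
  if (n == 0L)
    return(list(n = 0L, empty = TRUE,
                n_exonic = 0L, n_intronic = 0L, n_intergenic = 0L,
                n_sense = 0L, n_antisense = 0L,
                pct_sense = NA_real_, pct_missed_terminal = NA_real_))
  uses_term <- (records$uses_first_exon %in% TRUE) |
    (records$uses_last_exon %in% TRUE)
  n_sense <- sum(records$strand_relation %in% "sense")
  list(
    n = n, empty = FALSE,
    n_exonic = sum(records$circ_class == "exonic"),
    n_intronic = sum(records$circ_class == "intronic"),
    n_intergenic = sum(records$circ_class == "intergenic"),
    n_sense = n_sense,
    n_antisense = sum(records$strand_relation %in% "antisense"),
    n_missed_terminal = sum(!uses_term),
    pct_sense = 100 * n_sense / n,
    pct_missed_terminal = 100 * sum(!uses_term) / n)
}

#' Call circRNAs end to end
#'
#' Convenience wrapper: deduplicate, detect candidates, refine against the
#' genome, annotate against the gene models, and apply the support
#' threshold.
#'
#' @param aln split alignments.
#' @param genome a `gsc_genome`.
#' @param ts annotation `transcript_set`.
#' @param min_support minimum read support (default 1).
#' @return annotated circRNA data.table.
#' @export
call_circrnas <- function(aln, genome, ts, min_support = 1L) {
  jx <- refine_splice_sites(detect_candidates(dedup_alignments(aln)), genome)
  jx <- jx[support >= min_support]
  annotate_circrnas(jx, ts)
}
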