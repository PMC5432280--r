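## External representations. Internal coordinates are 0-based half-open
## everywhere; GTF (1-based inclusive) is converted exactly once, here.

# ---- genome ------------------------------------------------------------

#' Construct a genome object
#'
#' A genome is a set of named chromosome sequences plus an autosome/X label
#' per chromosome, used by the odds-ratio stage and the splice-motif search.
#'
#' @param seq named character vector of uppercase DNA sequences.
#' @param chrom_class optional named character vector mapping chromosome name
#'   to `"autosome"` or `"X"`. Defaults to the name rule: `"chrX"` or `"X"`
#'   is X, everything else autosome.
#' @return an object of class `gsc_genome` with elements `seq` and
#'   `chrom_class`.
#' @export
gsc_genome <- function(seq, chrom_class = NULL) {
  if (is.null(names(seq)) || anyDuplicated(names(seq)))
    stop("genome format error: chromosome names must be unique and non-empty")
  if (any(nchar(seq) == 0L))
    stop("genome format error: empty sequence record")
  seq <- toupper(seq)
  if (is.null(chrom_class)) {
    chrom_class <- ifelse(names(seq) %in% c("chrX", "X"), "X", "autosome")
    names(chrom_class) <- names(seq)
  }
  if (!all(names(seq) %in% names(chrom_class)))
    stop("genome format error: every chromosome needs a chrom_class entry")
  if (!all(chrom_class %in% c("autosome", "X")))
    stop("genome format error: chrom_class values must be 'autosome' or 'X'")
  structure(list(seq = seq, chrom_class = chrom_class[names(seq)]),
            class = "gsc_genome")
}

#' @export
print.gsc_genome <- function(x, ...) {
  cat(sprintf("gsc_genome: %d chromosome(s), %d bp total (%d X-linked)\n",
              length(x$seq), sum(nchar(x$seq)), sum(x$chrom_class == "X")))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @param chrom_class optional explicit class map, see [gsc_genome()].
#' @return a `gsc_genome`; sequences uppercased, headers truncated at the
#'   first whitespace.
#' @export
read_fasta <- function(path, chrom_class = NULL) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("FASTA format error: duplicate header '", nm[duplicated(nm)][1], "'")
  if (any(Biostrings::width(ss) == 0L))
    stop("FASTA format error: empty record")
  seqs <- stats::setNames(toupper(as.character(ss)), nm)
  gsc_genome(seqs, chrom_class)
}

#' Write a genome to FASTA
#'
#' @param genome a `gsc_genome`.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# ---- transcript models -------------------------------------------------

VALID_BIOTYPES <- c("coding", "known_lncRNA", "rRNA", "tRNA", "snRNA",
                    "snoRNA", "pre_miRNA", "pseudogene", "unknown")

#' Construct a transcript set
#'
#' The in-memory form of an annotation: a table of transcripts and a table
#' of exons in 0-based half-open coordinates.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype`, `read_coverage`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open). Exons are sorted per transcript; overlap within a
#'   transcript is an error.
#' @return object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons) {
  tr <- as.data.table(transcripts)
  ex <- as.data.table(exons)
  if (anyDuplicated(tr$transcript_id))
    stop("annotation error: duplicate transcript_id")
  if (!all(tr$strand %in% c("+", "-")))
    stop("annotation error: strand must be '+' or '-'")
  if (!all(tr$biotype %in% VALID_BIOTYPES))
    stop("annotation error: unknown biotype")
  if (!all(ex$transcript_id %in% tr$transcript_id))
    stop("annotation error: exon for unknown transcript")
  if (!all(tr$transcript_id %in% ex$transcript_id))
    stop("annotation error: transcript without exons")
  if (any(ex$end <= ex$start))
    stop("annotation error: exon end must exceed start")
  setorder(ex, transcript_id, start)
  bad <- ex[, any(start[-1L] < end[-.N]), by = transcript_id][V1 == TRUE]
  if (nrow(bad) > 0L)
    stop("annotation error: overlapping exons in transcript ",
         bad$transcript_id[1])
  ex[, exon_rank := seq_len(.N), by = transcript_id]  # genomic order
  structure(list(transcripts = tr, exons = ex), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d genes, %d exons\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$exons)))
  invisible(x)
}

#' Spliced lengths of all transcripts in a set
#' @param ts a `transcript_set`.
#' @return named integer vector, transcript_id -> spliced length in bp.
#' @export
spliced_lengths <- function(ts) {
  sl <- ts$exons[, .(len = sum(end - start)), by = transcript_id]
  stats::setNames(sl$len, sl$transcript_id)
}

#' Read transcript models from GTF
#'
#' Exon features are grouped per transcript; 1-based inclusive GTF
#' coordinates become 0-based half-open. The optional attributes `cov`
#' (read coverage, default 0) and `biotype` (default `"unknown"`) are parsed.
#'
#' @param path GTF file.
#' @return a `transcript_set`.
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF format error: ",
                                          conditionMessage(e)))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("GTF format error: no exon features")
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id))
    stop("GTF format error: exon without transcript_id")
  if (is.null(mc$gene_id) || anyNA(mc$gene_id))
    stop("GTF format error: exon without gene_id")
  cov <- if ("cov" %in% names(mc)) suppressWarnings(as.numeric(mc$cov)) else
    rep(0, length(gr))
  cov[is.na(cov)] <- 0
  biot <- if ("biotype" %in% names(mc)) as.character(mc$biotype) else
    rep("unknown", length(gr))
  ex <- data.table(
    transcript_id = as.character(mc$transcript_id),
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end   = BiocGenerics::end(gr),
    gene_id = as.character(mc$gene_id),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    biotype = biot, read_coverage = cov)
  if (!all(ex$strand %in% c("+", "-")))
    stop("GTF format error: exon with missing strand")
  tr <- ex[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
               biotype = biotype[1L], read_coverage = read_coverage[1L]),
           by = transcript_id]
  transcript_set(tr, ex[, .(transcript_id, start, end)])
}

#' Write a transcript set to GTF
#'
#' Emits one exon feature per exon with `gene_id`, `transcript_id`, `cov`
#' and `biotype` attributes, converting back to 1-based inclusive
#' coordinates. Output is deterministic (ordered by transcript then start).
#'
#' @param ts a `transcript_set`.
#' @param path output file.
#' @export
write_gtf <- function(ts, path) {
  ex <- merge(ts$exons, ts$transcripts, by = "transcript_id")
  setorder(ex, transcript_id, start)
  lines <- sprintf(
    '%s\tgscrna\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; cov "%.6g"; biotype "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id,
    ex$transcript_id, ex$read_coverage, ex$biotype)
  writeLines(lines, path)
  invisible(path)
}

# ---- split alignments --------------------------------------------------

SPLIT_COLS <- c("read_id", "sample_id", "chrom", "strand",
                "seg1_start", "seg1_end", "seg2_start", "seg2_end")

validate_split_alignments <- function(dt) {
  intcols <- c("seg1_start", "seg1_end", "seg2_start", "seg2_end")
  for (cc in intcols) {
    v <- dt[[cc]]
    if (!(is.integer(v) || (is.numeric(v) && all(v == floor(v)))))
      stop("split-alignment format error: non-integer coordinate in ", cc)
    set(dt, j = cc, value = as.integer(v))
  }
  if (!all(dt$strand %in% c("+", "-")))
    stop("split-alignment format error: strand must be '+' or '-'")
  if (any(dt$seg1_end <= dt$seg1_start) || any(dt$seg2_end <= dt$seg2_start))
    stop("split-alignment format error: segment end must exceed start")
  dt
}

#' Read split-read alignments
#'
#' The dialect is an 8-column TSV with header:
#' `read_id, sample_id, chrom, strand, seg1_start, seg1_end, seg2_start,
#' seg2_end`, coordinates 0-based half-open. `seg1` is the 5' part of the
#' read, `seg2` the 3' part; both segments are exact matches on `chrom`.
#' No filtering is applied here.
#'
#' @param path TSV file.
#' @return data.table in file order.
#' @export
read_split_alignments <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("read_id", "sample_id",
                                              "chrom", "strand")))
  if (!identical(names(dt), SPLIT_COLS))
    stop("split-alignment format error: expected columns ",
         paste(SPLIT_COLS, collapse = ", "))
  validate_split_alignments(dt)
}

#' Write split-read alignments
#' @param aln data.table with the 8 dialect columns.
#' @param path output file.
#' @export
write_split_alignments <- function(aln, path) {
  fwrite(aln[, SPLIT_COLS, with = FALSE], path, sep = "\t")
  invisible(path)
}

# ---- count tables ------------------------------------------------------

#' Read a fragment-count table
#'
#' TSV with a `transcript_id` column followed by one integer column per
#' library.
#'
#' @param path TSV file.
#' @return data.table, first column `transcript_id`.
#' @export
read_count_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "transcript_id")
    stop("count-table format error: first column must be transcript_id")
  dt
}

#' Write a fragment-count table
#' @param counts data.table with `transcript_id` first.
#' @param path output file.
#' @export
write_count_table <- function(counts, path) {
  fwrite(counts, path, sep = "\t")
  invisible(path)
}

# ---- edge lists --------------------------------------------------------

#' Write a network edge list (Cytoscape-loadable TSV)
#'
#' Rows are ordered lexicographically by source then target so repeated
#' writes of the same edge set are byte-identical.
#'
#' @param edges data.frame with columns `source`, `target`, `weight`,
#'   `sign`.
#' @param path output file.
#' @export
write_edge_list <- function(edges, path) {
  ed <- as.data.table(edges)[, .(source = as.character(source),
                                 target = as.character(target),
                                 weight = sprintf("%.6g", weight),
                                 sign = as.character(sign))]
  setorder(ed, source, target)
  fwrite(ed, path, sep = "\t")
  invisible(path)
}
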