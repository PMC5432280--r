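## Sequence-level helpers shared by the simulator, the circRNA caller and the
## lncRNA cascade. All genomic coordinates in this package are 0-based
## half-open; conversion to/from 1-based inclusive happens only in io.R.

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (alphabet ACGTN, any case).
#' @return character vector of reverse complements, uppercase.
#' @export
revcomp_dna <- function(x) {
  vapply(chartr("ACGTNacgtn", "TGCANTGCAN", x), function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

## substring of a chromosome in 0-based half-open coordinates; chromosomes
## may be held as a single string or (during simulation, for speed) as a
## character vector of single bases
subseq0 <- function(seq, start, end) {
  if (length(seq) > 1L)
    paste(seq[(start + 1L):end], collapse = "")
  else substr(seq, start + 1L, end)
}

## overwrite genome bases at 0-based position `start` with `replacement`
write_seq0 <- function(seq, start, replacement) {
  n <- nchar(replacement)
  if (length(seq) > 1L) {
    seq[(start + 1L):(start + n)] <- strsplit(replacement, "", fixed = TRUE)[[1]]
    seq
  } else {
    paste0(substr(seq, 1L, start), replacement,
           substr(seq, start + n + 1L, nchar(seq)))
  }
}

#' Spliced sequence of a transcript in transcript orientation
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for minus-strand transcripts.
#'
#' @param genome a `gsc_genome` object (see [read_fasta()]).
#' @param exons data.frame/data.table with 0-based half-open `start`, `end`,
#'   sorted ascending.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @return single uppercase DNA string, 5' to 3' of the transcript.
#' @export
transcript_sequence <- function(genome, exons, chrom, strand) {
  s <- genome$seq[[chrom]]
  pieces <- vapply(seq_len(nrow(exons)),
                   function(i) subseq0(s, exons$start[i], exons$end[i]),
                   character(1))
  out <- paste(pieces, collapse = "")
  if (strand == "-") out <- revcomp_dna(out)
  out
}

## map a 0-based position in transcript coordinates to a 0-based genomic
## position; exons genomic-sorted, strand-aware
transcript_to_genome <- function(exons, strand, tpos) {
  widths <- exons$end - exons$start
  if (strand == "-") {
    exo <- rev(seq_len(nrow(exons)))  # transcription order for minus strand
  } else {
    exo <- seq_len(nrow(exons))
  }
  offs <- cumsum(c(0L, widths[exo]))
  vapply(tpos, function(p) {
    i <- findInterval(p, offs, rightmost.closed = FALSE)
    e <- exo[i]
    within <- p - offs[i]
    as.integer(if (strand == "-") exons$end[e] - 1L - within else
      exons$start[e] + within)
  }, integer(1))
}

## write a transcript-orientation sequence back into the genome across exons
write_transcript_seq <- function(seq, exons, strand, tseq) {
  widths <- exons$end - exons$start
  stopifnot(nchar(tseq) == sum(widths))
  if (strand == "-") tseq <- revcomp_dna(tseq)
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    piece <- substr(tseq, off + 1L, off + widths[i])
    seq <- write_seq0(seq, exons$start[i], piece)
    off <- off + widths[i]
  }
  seq
}

#' Longest open reading frame across the three forward frames
#'
#' An ORF runs from an ATG to the first in-frame stop codon (TAA/TAG/TGA);
#' its length in bp includes the stop codon. Codons containing characters
#' outside ACGT never act as start or stop.
#'
#' @param seq DNA string in transcript orientation.
#' @return list with `max_orf_bp` (0 when no complete ORF exists),
#'   `orf_fraction` (`max_orf_bp / nchar(seq)`; 0 for empty input) and
#'   `orf_start` (0-based transcript position of the ATG, `NA` if none).
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  best_start <- NA_integer_
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    if (f + 3L > n) next
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    open <- NA_integer_  # index of earliest ATG with no stop since
    for (i in seq_along(codons)) {
      cd <- codons[i]
      if (is.na(open) && cd == "ATG") open <- i
      if (cd %in% stops && !is.na(open)) {
        len <- (i - open + 1L) * 3L
        if (len > best) {
          best <- len
          best_start <- starts[open] - 1L
        }
        open <- NA_integer_
      }
    }
  }
  list(max_orf_bp = best,
       orf_fraction = if (n > 0L) best / n else 0,
       orf_start = best_start)
}

## sample n bases uniformly, as one string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
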