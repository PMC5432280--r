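## Coding-noncoding co-expression (CNC) network and the ceRNA network.

CNC_MIN_PCC <- 0.99
CNC_MAX_P   <- 0.01
CNC_MAX_FDR <- 0.01
CERNA_MIN_PCC <- 0.9
CIRC_JUNCTION_FLANK <- 6L

#' Pearson correlation with a t-distribution p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list `pcc`, `p_value` (two-sided, n-2 df). Constant input gives
#'   `pcc = NA` and `undefined = TRUE`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("correlation error: need equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pcc = NA_real_, p_value = NA_real_, undefined = TRUE))
  r <- cor(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(pcc = r, p_value = p, undefined = FALSE)
}

#' Build the coding-noncoding co-expression network
#'
#' Coding gene expression is the per-library median over the gene's
#' transcripts; both sides are restricted to the supplied sex-biased lists;
#' all noncoding x coding pairs are tested; edges pass `|PCC| >= 0.99`,
#' `p < 0.01` and BH FDR `< 0.01` (FDR computed over all tested pairs). An
#' optional `top_k` keeps only the `k` coding genes with the smallest best
#' edge p-value.
#'
#' @param noncoding_fpkm FPKM matrix of noncoding transcripts (rownames =
#'   ids).
#' @param mrna_fpkm FPKM matrix of coding transcripts.
#' @param mrna_gene_map named vector transcript -> gene for the coding side
#'   (identity when `NULL`).
#' @param biased_noncoding,biased_coding sex-biased id lists (noncoding
#'   transcript ids; coding gene ids). `NULL` keeps all rows.
#' @param top_k_mrnas optional cap on coding genes (paper's figure used
#'   10).
#' @param min_pcc,max_p,max_fdr edge thresholds.
#' @param log_transform correlate `log2(FPKM + 1)` instead of raw FPKM
#'   (default `TRUE`, the usual scale for expression correlation).
#' @return data.table of edges: `noncoding_id`, `mrna_id`, `pcc`,
#'   `p_value`, `fdr`, `sign`.
#' @export
build_cnc_network <- function(noncoding_fpkm, mrna_fpkm,
                              mrna_gene_map = NULL,
                              biased_noncoding = NULL, biased_coding = NULL,
                              top_k_mrnas = NULL,
                              min_pcc = CNC_MIN_PCC, max_p = CNC_MAX_P,
                              max_fdr = CNC_MAX_FDR, log_transform = TRUE) {
  if (!identical(colnames(noncoding_fpkm), colnames(mrna_fpkm)))
    stop("network error: FPKM matrices must share library columns")
  if (ncol(noncoding_fpkm) < 3L)
    stop("network error: need at least 3 shared libraries")
  ## step (i): gene value = median across the gene's transcripts
  if (!is.null(mrna_gene_map)) {
    g <- mrna_gene_map[rownames(mrna_fpkm)]
    mrna_fpkm <- do.call(rbind, lapply(split(seq_len(nrow(mrna_fpkm)), g),
                                       function(ix) apply(mrna_fpkm[ix, , drop = FALSE], 2, median)))
  }
  ## step (ii): restrict to the sex-biased lists
  if (!is.null(biased_noncoding))
    noncoding_fpkm <- noncoding_fpkm[rownames(noncoding_fpkm) %in% biased_noncoding, , drop = FALSE]
  if (!is.null(biased_coding))
    mrna_fpkm <- mrna_fpkm[rownames(mrna_fpkm) %in% biased_coding, , drop = FALSE]
  if (nrow(noncoding_fpkm) == 0L || nrow(mrna_fpkm) == 0L)
    return(data.table(noncoding_id = character(), mrna_id = character(),
                      pcc = numeric(), p_value = numeric(), fdr = numeric(),
                      sign = character()))
  if (log_transform) {
    noncoding_fpkm <- log2(noncoding_fpkm + 1)
    mrna_fpkm <- log2(mrna_fpkm + 1)
  }
  ## step (iii): all pairs
  pairs <- CJ(noncoding_id = rownames(noncoding_fpkm),
              mrna_id = rownames(mrna_fpkm))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pearson_cc(noncoding_fpkm[pairs$noncoding_id[i], ],
               mrna_fpkm[pairs$mrna_id[i], ])
  })
  pairs[, pcc := vapply(res, `[[`, numeric(1), "pcc")]
  pairs[, p_value := vapply(res, `[[`, numeric(1), "p_value")]
  pairs <- pairs[!is.na(pcc)]
  pairs[, fdr := p.adjust(p_value, method = "BH")]
  ## step (iv): thresholds
  edges <- pairs[abs(pcc) >= min_pcc & p_value < max_p & fdr < max_fdr]
  edges[, sign := ifelse(pcc > 0, "positive", "negative")]
  if (!is.null(top_k_mrnas) && nrow(edges) > 0L) {
    best <- edges[, .(minp = min(p_value)), by = mrna_id]
    setorder(best, minp, mrna_id)
    keep <- head(best$mrna_id, top_k_mrnas)
    edges <- edges[mrna_id %in% keep]
  }
  setorder(edges, noncoding_id, mrna_id)
  edges[]
}

#' Find miRNA seed sites on a target sequence
#'
#' The seed is miRNA nucleotides 2-8; a site is a target match (DNA
#' alphabet, transcript orientation) to the reverse complement of the seed.
#' Site classes follow the canonical rules: `7mer_m8` = full 2-8 match;
#' `8mer` = 2-8 match plus an `A` opposite miRNA position 1 (the base 3' of
#' the match); `7mer_A1` = 2-7 match plus the A anchor where position 8
#' does not pair. Overlapping sites are all reported; positions 0-based.
#'
#' @param target_seq DNA string.
#' @param mirna_seq 22-nt miRNA sequence (RNA or DNA alphabet).
#' @return data.table `pos`, `site_type` (empty for no sites).
#' @export
find_seed_sites <- function(target_seq, mirna_seq) {
  target_seq <- toupper(target_seq)
  mseq <- chartr("Uu", "TT", toupper(mirna_seq))
  seed28 <- substr(mseq, 2L, 8L)
  m8 <- substr(mseq, 8L, 8L)
  rc28 <- revcomp_dna(seed28)            # 7-mer; pairs miRNA 8..2 left-to-right
  rc27 <- substr(rc28, 2L, 7L)           # 6-mer for positions 2-7
  out <- list()
  n <- nchar(target_seq)

  hit_starts <- function(pat) {
    if (nchar(pat) > n) return(integer(0))
    ## zero-width lookahead finds overlapping matches
    m <- gregexpr(paste0("(?=", pat, ")"), target_seq, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }

  for (p in hit_starts(rc28)) {          # p is 1-based start of 7-mer
    a1 <- if (p + 7L <= n) substr(target_seq, p + 7L, p + 7L) else ""
    out[[length(out) + 1L]] <- data.table(
      pos = p - 1L, site_type = if (a1 == "A") "8mer" else "7mer_m8")
  }
  for (q in hit_starts(rc27)) {          # 6-mer (positions 2-7)
    if (q + 6L > n || substr(target_seq, q + 6L, q + 6L) != "A") next
    m8_pairs <- q > 1L &&
      substr(target_seq, q - 1L, q - 1L) == revcomp_dna(m8)
    if (!m8_pairs)                        # otherwise already an 8mer above
      out[[length(out) + 1L]] <- data.table(pos = q - 1L,
                                            site_type = "7mer_A1")
  }
  if (length(out) == 0L)
    return(data.table(pos = integer(), site_type = character()))
  res <- rbindlist(out)
  setorder(res, pos, site_type)
  res[]
}

#' Linearized scanning sequence for a circular RNA
#'
#' Appends the first `flank` nucleotides to the end of the exonic sequence
#' so seed sites crossing the backsplice junction are found once; callers
#' should keep only sites starting before the original length (handled by
#' [find_seed_sites_circular()]).
#'
#' @param seq exonic circle sequence.
#' @param flank junction window size (default 6).
#' @return extended sequence string.
#' @export
circular_scan_sequence <- function(seq, flank = CIRC_JUNCTION_FLANK) {
  paste0(seq, substr(seq, 1L, min(flank, nchar(seq))))
}

#' Seed sites on a circular sequence (junction-aware)
#'
#' @inheritParams find_seed_sites
#' @param flank junction window size.
#' @return data.table of sites with positions modulo the circle length.
#' @export
find_seed_sites_circular <- function(target_seq, mirna_seq,
                                     flank = CIRC_JUNCTION_FLANK) {
  ext <- circular_scan_sequence(target_seq, flank)
  sites <- find_seed_sites(ext, mirna_seq)
  sites[pos < nchar(target_seq)]
}

#' Build the ceRNA network
#'
#' A link `sponge - miRNA - mRNA` is emitted when the sponge (lncRNA or
#' circRNA) and the mRNA each carry at least one seed site for the same
#' miRNA and the expression correlation between sponge and mRNA passes the
#' gate (`|PCC| >= min_pcc`, default 0.9).
#'
#' @param sponge_seqs named character vector of sponge sequences.
#' @param mrna_seqs named character vector of mRNA sequences.
#' @param mirnas named character vector of 22-nt miRNA sequences.
#' @param fpkm FPKM matrix containing all sponge and mRNA ids as rows.
#' @param circular named logical: is each sponge circular? (default all
#'   linear).
#' @param min_pcc correlation gate.
#' @param log_transform correlate `log2(FPKM + 1)` (default `TRUE`).
#' @return data.table: `sponge_id`, `mirna_id`, `mrna_id`, `pcc`,
#'   `n_sponge_sites`, `n_mrna_sites`, plus list columns `sponge_sites`,
#'   `mrna_sites`. Deterministic order.
#' @export
build_cerna_network <- function(sponge_seqs, mrna_seqs, mirnas, fpkm,
                                circular = NULL, min_pcc = CERNA_MIN_PCC,
                                log_transform = TRUE) {
  if (log_transform) fpkm <- log2(fpkm + 1)
  if (is.null(circular))
    circular <- stats::setNames(rep(FALSE, length(sponge_seqs)),
                                names(sponge_seqs))
  site_cache_sponge <- list(); site_cache_mrna <- list()
  for (mi in names(mirnas)) {
    site_cache_sponge[[mi]] <- lapply(names(sponge_seqs), function(sp) {
      if (isTRUE(circular[[sp]]))
        find_seed_sites_circular(sponge_seqs[[sp]], mirnas[[mi]])
      else find_seed_sites(sponge_seqs[[sp]], mirnas[[mi]])
    })
    names(site_cache_sponge[[mi]]) <- names(sponge_seqs)
    site_cache_mrna[[mi]] <- lapply(names(mrna_seqs), function(mr)
      find_seed_sites(mrna_seqs[[mr]], mirnas[[mi]]))
    names(site_cache_mrna[[mi]]) <- names(mrna_seqs)
  }
  links <- list()
  for (sp in sort(names(sponge_seqs))) for (mr in sort(names(mrna_seqs))) {
    if (!sp %in% rownames(fpkm) || !mr %in% rownames(fpkm)) next
    pc <- pearson_cc(fpkm[sp, ], fpkm[mr, ])
    if (pc$undefined || abs(pc$pcc) < min_pcc) next
    for (mi in sort(names(mirnas))) {
      s_sites <- site_cache_sponge[[mi]][[sp]]
      m_sites <- site_cache_mrna[[mi]][[mr]]
      if (nrow(s_sites) == 0L || nrow(m_sites) == 0L) next
      links[[length(links) + 1L]] <- data.table(
        sponge_id = sp, mirna_id = mi, mrna_id = mr, pcc = pc$pcc,
        n_sponge_sites = nrow(s_sites), n_mrna_sites = nrow(m_sites),
        sponge_sites = list(s_sites), mrna_sites = list(m_sites))
    }
  }
  if (length(links) == 0L)
    return(data.table(sponge_id = character(), mirna_id = character(),
                      mrna_id = character(), pcc = numeric(),
                      n_sponge_sites = integer(), n_mrna_sites = integer()))
  rbindlist(links)
}
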