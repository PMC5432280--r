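## FPKM quantification and the negative-binomial sex-biased expression test.
##
## The NB test replaces Cuffdiff: median-of-ratios size factors, a pooled
## method-of-moments common dispersion (variance = mu + d * mu^2), then an
## exact conditional NB test on the two condition sums (normal
## approximation above a total of 2000). Calls use the operative thresholds
## p-adjust < 0.05 and |log2 fold change| > 1.

DE_PADJ   <- 0.05
DE_LFC    <- 1
EXACT_MAX_TOTAL <- 2000L

#' Construct an expression table
#'
#' @param counts integer matrix, transcripts x libraries (rownames,
#'   colnames required).
#' @param condition named character vector library -> `"SSC"`/`"FGSC"`.
#' @param effective_length named numeric vector, transcript -> spliced
#'   length in bp.
#' @param library_size optional named vector of total mapped fragments;
#'   defaults to column sums.
#' @param gene_map optional named vector transcript -> gene id (for
#'   gene-level FPKM).
#' @return object of class `expression_table`.
#' @export
expression_table <- function(counts, condition, effective_length,
                             library_size = NULL, gene_map = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("expression error: counts need row and column names")
  if (any(counts < 0)) stop("expression error: negative count")
  if (!all(colnames(counts) %in% names(condition)))
    stop("expression error: condition missing for some library")
  if (!all(rownames(counts) %in% names(effective_length)))
    stop("expression error: effective length missing for some transcript")
  if (any(effective_length[rownames(counts)] <= 0))
    stop("expression error: effective lengths must be positive")
  if (is.null(library_size)) library_size <- colSums(counts)
  if (any(library_size <= 0)) stop("expression error: zero library size")
  structure(list(counts = counts,
                 condition = condition[colnames(counts)],
                 effective_length = effective_length[rownames(counts)],
                 library_size = library_size[colnames(counts)],
                 gene_map = gene_map),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d transcripts x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(names(table(x$condition)), table(x$condition),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Compute FPKM
#'
#' `FPKM = count / ((effective_length/1000) * (library_size/1e6))`.
#' Gene-level FPKM (when a gene map is present) is the sum of the FPKMs of
#' the gene's transcripts.
#'
#' @param et an `expression_table`.
#' @param gene_level sum transcript FPKMs per gene?
#' @return numeric matrix of FPKM values (transcripts, or genes, x
#'   libraries).
#' @export
compute_fpkm <- function(et, gene_level = FALSE) {
  fpkm <- sweep(et$counts, 1, et$effective_length / 1000, "/")
  fpkm <- sweep(fpkm, 2, et$library_size / 1e6, "/")
  if (gene_level) {
    if (is.null(et$gene_map))
      stop("expression error: gene-level FPKM requires a gene map")
    g <- et$gene_map[rownames(fpkm)]
    fpkm <- rowsum(fpkm, group = g)
  }
  fpkm
}

#' Median-of-ratios size factors
#'
#' @param counts count matrix.
#' @return named numeric vector of size factors (geometric-mean reference,
#'   rows with any zero excluded from the reference).
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  keep <- rowSums(!is.finite(lg)) == 0
  if (!any(keep)) return(stats::setNames(rep(1, ncol(counts)),
                                         colnames(counts)))
  ref <- rowMeans(lg[keep, , drop = FALSE])
  sf <- apply(lg[keep, , drop = FALSE], 2,
              function(cl) exp(median(cl - ref)))
  stats::setNames(sf, colnames(counts))
}

#' Common NB dispersion by method of moments
#'
#' One dispersion shared by all transcripts: within each condition the
#' excess of the sample variance of normalized counts over the mean
#' estimates `d * mu^2`; summing numerators and denominators over
#' transcripts and conditions pools the estimate. Transcripts whose
#' per-transcript moment estimate lies above the Tukey upper fence
#' (Q3 + 3 IQR) are excluded from the pool, so a handful of rows with
#' extra non-NB variation (e.g. transcripts driven by a shared latent
#' factor) cannot inflate the common estimate.
#'
#' @param norm normalized count matrix.
#' @param condition condition labels per column.
#' @return non-negative scalar dispersion (floored at 1e-8).
#' @export
common_dispersion <- function(norm, condition) {
  num <- rep(0, nrow(norm)); den <- rep(0, nrow(norm))
  for (cond in unique(condition)) {
    sub <- norm[, condition == cond, drop = FALSE]
    if (ncol(sub) < 2L) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    ok <- m > 0
    num[ok] <- num[ok] + (v[ok] - m[ok])
    den[ok] <- den[ok] + m[ok]^2
  }
  keep <- den > 0
  if (!any(keep)) return(1e-8)
  di <- num[keep] / den[keep]
  qs <- stats::quantile(di, c(0.25, 0.75), names = FALSE)
  fence <- qs[2] + 3 * (qs[2] - qs[1])
  sel <- di <= fence
  max(sum(num[keep][sel]) / sum(den[keep][sel]), 1e-8)
}

## two-sided exact conditional NB test on condition sums kA, kB given the
## common mean mu (per normalized unit), size factors sA, sB and dispersion
nb_exact_p <- function(kA, kB, sA, sB, disp) {
  total <- kA + kB
  if (total == 0L) return(1)
  size_A <- sA / disp; size_B <- sB / disp   # sum of iid NB approximated by
  mu_hat <- total / (sA + sB)                # NB with scaled size
  muA <- mu_hat * sA; muB <- mu_hat * sB
  ks <- 0:total
  lp <- dnbinom(ks, mu = muA, size = size_A, log = TRUE) +
    dnbinom(total - ks, mu = muB, size = size_B, log = TRUE)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  pobs <- pr[kA + 1L]
  min(1, sum(pr[pr <= pobs * (1 + 1e-8)]))
}

## normal approximation for large totals: z on the difference of
## per-size-factor rates with NB variances
nb_approx_p <- function(kA, kB, sfA, sfB, disp) {
  mu_hat <- (kA + kB) / (sum(sfA) + sum(sfB))
  vA <- sum(mu_hat * sfA + disp * (mu_hat * sfA)^2)
  vB <- sum(mu_hat * sfB + disp * (mu_hat * sfB)^2)
  d <- kA / sum(sfA) - kB / sum(sfB)
  se <- sqrt(vA / sum(sfA)^2 + vB / sum(sfB)^2)
  if (se == 0) return(1)
  2 * pnorm(-abs(d) / se)
}

#' Negative-binomial differential expression between SSC and FGSC
#'
#' @param et an `expression_table` with >= 2 replicates per condition.
#' @param padj_threshold,lfc_threshold call thresholds (defaults 0.05, 1).
#' @param dispersion optional fixed dispersion; estimated from the data by
#'   default.
#' @return data.table: `transcript_id`, `mean_SSC`, `mean_FGSC`
#'   (normalized condition means), `log2_fold_change`
#'   (`log2((SSC+1)/(FGSC+1))`), `p_value`, `p_adjust` (BH), `call`
#'   (`male_biased` / `female_biased` / `ns`).
#' @export
nb_differential_test <- function(et, padj_threshold = DE_PADJ,
                                 lfc_threshold = DE_LFC,
                                 dispersion = NULL) {
  cond <- et$condition
  if (sum(cond == "SSC") < 2L || sum(cond == "FGSC") < 2L)
    stop("expression error: need >= 2 replicates per condition")
  sf <- size_factors(et$counts)
  norm <- sweep(et$counts, 2, sf, "/")
  disp <- if (is.null(dispersion)) common_dispersion(norm, cond) else dispersion
  if (disp <= 0) stop("config error: dispersion must be positive")

  ssc <- cond == "SSC"; fgsc <- cond == "FGSC"
  sfA <- sf[ssc]; sfB <- sf[fgsc]
  mA <- rowMeans(norm[, ssc, drop = FALSE])
  mB <- rowMeans(norm[, fgsc, drop = FALSE])
  kA <- rowSums(et$counts[, ssc, drop = FALSE])
  kB <- rowSums(et$counts[, fgsc, drop = FALSE])

  pv <- vapply(seq_len(nrow(et$counts)), function(i) {
    tot <- kA[i] + kB[i]
    if (tot == 0) return(1)
    if (tot <= EXACT_MAX_TOTAL)
      nb_exact_p(kA[i], kB[i], sum(sfA), sum(sfB), disp)
    else
      nb_approx_p(kA[i], kB[i], sfA, sfB, disp)
  }, numeric(1))
  padj <- p.adjust(pv, method = "BH")
  lfc <- log2((mA + 1) / (mB + 1))
  call <- rep("ns", length(pv))
  sig <- padj < padj_threshold & abs(lfc) > lfc_threshold
  call[sig & mA > mB] <- "male_biased"
  call[sig & mA < mB] <- "female_biased"
  data.table(transcript_id = rownames(et$counts),
             mean_SSC = mA, mean_FGSC = mB,
             log2_fold_change = lfc, p_value = pv, p_adjust = padj,
             call = call)
}

#' Row-normalized matrix of called transcripts for heatmap export
#'
#' Selects called transcripts additionally passing the figure thresholds
#' (fold change >= 2, raw p < 0.05, FDR < 0.05) and returns per-row
#' z-scores of `log2(FPKM + 1)`, rows ordered by log2 fold change
#' descending.
#'
#' @param fpkm FPKM matrix.
#' @param de result of [nb_differential_test()].
#' @param min_fc,max_p,max_fdr the figure thresholds.
#' @return numeric matrix (possibly 0-row, with a warning).
#' @export
heatmap_matrix <- function(fpkm, de, min_fc = 2, max_p = 0.05,
                           max_fdr = 0.05) {
  sel <- de[call != "ns" & abs(log2_fold_change) >= log2(min_fc) &
              p_value < max_p & p_adjust < max_fdr]
  if (nrow(sel) == 0L) {
    warning("heatmap_matrix: no transcripts pass the figure thresholds")
    return(matrix(numeric(0), nrow = 0, ncol = ncol(fpkm),
                  dimnames = list(NULL, colnames(fpkm))))
  }
  setorder(sel, -log2_fold_change)
  m <- log2(fpkm[sel$transcript_id, , drop = FALSE] + 1)
  t(apply(m, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
}
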