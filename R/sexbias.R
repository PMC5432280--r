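## Autosome-vs-X enrichment of sex-biased transcripts.
##
## The 2x2 table is (rows: biased / non-biased; columns: autosomal /
## X-linked); odds ratio = (a/b)/(c/d), so OR > 1 means the biased set is
## enriched on autosomes and OR < 1 means X enrichment.

#' Two-sided Fisher's exact test by hypergeometric enumeration
#'
#' With margins fixed, sums the probabilities of all tables whose
#' hypergeometric probability does not exceed that of the observed table.
#'
#' @param a,b,c,d cell counts: biased-autosomal, biased-X, nonbiased-
#'   autosomal, nonbiased-X.
#' @return two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  m <- a + c          # autosomal total
  n <- b + d          # X total
  k <- a + b          # biased total
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  pr <- dhyper(xs, m, n, k)
  pobs <- dhyper(a, m, n, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

#' Chromosomal odds ratio for a biased transcript set
#'
#' @param biased_ids ids called sex-biased (one direction).
#' @param universe_ids all expressed ids of the same class (must contain
#'   `biased_ids`).
#' @param chrom_class named character vector id -> `"autosome"`/`"X"`.
#' @return list with cells `a`,`b`,`c`,`d`, `odds_ratio` (`NA` with
#'   `or_undefined = TRUE` when `b` or `d` is 0), and two-sided `fisher_p`.
#' @export
chromosome_odds_ratio <- function(biased_ids, universe_ids, chrom_class) {
  if (length(universe_ids) == 0L) stop("odds-ratio error: empty universe")
  if (!all(biased_ids %in% universe_ids))
    stop("odds-ratio error: biased ids must be a subset of the universe")
  if (!all(universe_ids %in% names(chrom_class)))
    stop("odds-ratio error: missing chrom_class for some ids")
  cls <- chrom_class[universe_ids]
  isb <- universe_ids %in% biased_ids
  a <- sum(isb & cls == "autosome")
  b <- sum(isb & cls == "X")
  c <- sum(!isb & cls == "autosome")
  d <- sum(!isb & cls == "X")
  undef <- (b == 0L || d == 0L)
  or <- if (undef) NA_real_ else (a / b) / (c / d)
  list(a = a, b = b, c = c, d = d,
       odds_ratio = or, or_undefined = undef,
       fisher_p = fisher_exact_p(a, b, c, d))
}

#' Odds-ratio summary for both directions and classes
#'
#' @param de differential result table (from [nb_differential_test()]).
#' @param chrom_class named id -> class vector.
#' @param class_map optional named id -> molecule class (e.g. `"mRNA"`,
#'   `"lncRNA"`) to stratify; single stratum when `NULL`.
#' @return data.table with one row per (class, direction).
#' @export
sex_bias_summary <- function(de, chrom_class, class_map = NULL) {
  strata <- if (is.null(class_map)) list(all = de$transcript_id) else
    split(de$transcript_id, class_map[de$transcript_id])
  rows <- list()
  for (cl in names(strata)) {
    ids <- strata[[cl]]
    sub <- de[transcript_id %in% ids]
    for (dir in c("male_biased", "female_biased")) {
      biased <- sub[call == dir, transcript_id]
      ct <- chromosome_odds_ratio(biased, ids, chrom_class)
      rows[[length(rows) + 1L]] <- data.table(
        class = cl, direction = dir, a = ct$a, b = ct$b, c = ct$c, d = ct$d,
        odds_ratio = ct$odds_ratio, fisher_p = ct$fisher_p)
    }
  }
  rbindlist(rows)
}
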