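## independent oracle: literal per-row rule with explicit conditionals,
## O(n^2) merge of identical raw junctions
candidates_oracle <- function(aln) {
  df <- as.data.frame(aln)               # plain vectors for fast row access
  keep_ch <- character(0); keep_st <- character(0)
  keep_a <- integer(0); keep_d <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (!(df$seg2_end[i] <= df$seg1_start[i])) next   # reversed order
    if (!((df$seg1_end[i] - df$seg2_start[i]) <= 100000)) next
    keep_ch <- c(keep_ch, df$chrom[i]); keep_st <- c(keep_st, df$strand[i])
    keep_a <- c(keep_a, df$seg2_start[i]); keep_d <- c(keep_d, df$seg1_end[i])
  }
  if (length(keep_a) == 0L)
    return(data.table(chrom = character(), strand = character(),
                      acceptor = integer(), donor = integer(),
                      support = integer()))
  m <- length(keep_a)
  taken <- rep(FALSE, m)
  och <- character(0); ost <- character(0)
  oa <- integer(0); od <- integer(0); osup <- integer(0)
  for (i in seq_len(m)) {                # O(n^2) merge of identical keys
    if (taken[i]) next
    n <- 1L
    for (j in seq_len(m)) {
      if (j <= i || taken[j]) next
      if (keep_ch[j] == keep_ch[i] && keep_st[j] == keep_st[i] &&
          keep_a[j] == keep_a[i] && keep_d[j] == keep_d[i]) {
        taken[j] <- TRUE; n <- n + 1L
      }
    }
    och <- c(och, keep_ch[i]); ost <- c(ost, keep_st[i])
    oa <- c(oa, keep_a[i]); od <- c(od, keep_d[i]); osup <- c(osup, n)
  }
  res <- data.table(chrom = och, strand = ost, acceptor = oa, donor = od,
                    support = osup)
  setorder(res, chrom, acceptor, donor, strand)
  res[]
}

random_alignments <- function(n, chroms = c("chr1", "chr2")) {
  s1 <- sample.int(200000L, n)
  l1 <- sample(20:80, n, TRUE)
  ## mix of reversed-order, genomic-order, and borderline-distance pairs
  off <- sample(c(-150000L, -60000L, -90L, 500L, 99000L, 101000L), n, TRUE)
  s2 <- pmax(0L, s1 + off)
  l2 <- sample(20:80, n, TRUE)
  keep <- s2 + l2 <= s1 | s1 + l1 <= s2   # segments must not be degenerate
  data.table(read_id = sprintf("r%d", seq_len(n)),
             sample_id = sample(c("SSC_1", "FGSC_2"), n, TRUE),
             chrom = sample(chroms, n, TRUE),
             strand = sample(c("+", "-"), n, TRUE),
             seg1_start = s1, seg1_end = s1 + l1,
             seg2_start = s2, seg2_end = s2 + l2)
}

## ---- hand-built 12-transcript cascade fixture --------------------------
## Genome is a flat CCT repeat (no A or G anywhere): no ORFs, so coding
## potential is controlled entirely by what the fixture writes in.

lnc_fixture <- function() {
  g <- tiny_genome(20000, "chrT")

  asm <- bind_tx(
    one_tx("t01", "chrT", "+", cbind(1000L, 1500L)),              # monoexonic
    one_tx("t02", "chrT", "+", cbind(c(1600L, 1750L), c(1680L, 1830L))),  # 160 bp
    one_tx("t03", "chrT", "+", cbind(c(2000L, 2400L), c(2200L, 2600L)), cov = 1),
    one_tx("t04", "chrT", "+", cbind(c(12000L, 12400L), c(12200L, 12600L))),
    one_tx("t05", "chrT", "+", cbind(c(2900L, 3600L), c(3200L, 3900L))),
    one_tx("t06", "chrT", "+", cbind(c(6900L, 7400L), c(7050L, 7500L))),
    one_tx("t07", "chrT", "+", cbind(c(4900L, 5600L), c(5200L, 5900L))),
    one_tx("t08", "chrT", "+", cbind(c(14000L, 14400L), c(14200L, 14600L))),
    one_tx("t09", "chrT", "+", cbind(c(15000L, 15400L), c(15120L, 15520L))),
    one_tx("t10", "chrT", "+", cbind(c(9100L, 9400L), c(9250L, 9500L))),
    one_tx("t11", "chrT", "-", cbind(c(9050L, 9350L), c(9200L, 9450L))),
    one_tx("t12", "chrT", "+", cbind(c(17000L, 17300L), c(17150L, 17450L))))

  known <- bind_tx(
    one_tx("kl1", "chrT", "+", cbind(c(3000L, 3600L), c(3200L, 3800L)),
           biotype = "known_lncRNA"),
    one_tx("km1", "chrT", "+", cbind(c(5000L, 5600L), c(5200L, 5800L)),
           biotype = "coding"),
    one_tx("ktr", "chrT", "+", cbind(7000L, 7100L), biotype = "tRNA"),
    one_tx("kc1", "chrT", "+", cbind(c(9000L, 9700L), c(9300L, 10000L)),
           biotype = "coding"))

  ## t08: planted 399-bp ORF across its two exons (spliced length 400)
  orf8 <- paste0("ATG", strrep("AAA", 131), "TAA", "C")
  g <- poke(g, "chrT", 14000, substr(orf8, 1, 200))
  g <- poke(g, "chrT", 14400, substr(orf8, 201, 400))
  ## t09: 150-bp ORF in a 240-bp transcript (fraction 0.625 >= 0.5)
  seq9 <- paste0(strrep("C", 10), "ATG", strrep("AAA", 48), "TAA",
                 strrep("C", 80))
  g <- poke(g, "chrT", 15000, substr(seq9, 1, 120))
  g <- poke(g, "chrT", 15400, substr(seq9, 121, 240))

  ids <- asm$transcripts$transcript_id
  fpkm <- matrix(1, nrow = length(ids), ncol = 2,
                 dimnames = list(ids, c("L1", "L2")))
  fpkm["t04", ] <- 0.005
  list(genome = g, asm = asm, known = known, fpkm = fpkm)
}

lnc_expected <- data.table(
  transcript_id = sprintf("t%02d", 1:12),
  status = c("rejected", "rejected", "rejected", "rejected", "known_lncRNA",
             "rejected", "rejected", "rejected", "rejected",
             "novel_lncRNA", "novel_lncRNA", "novel_lncRNA"),
  reject_reason = c("short_or_monoexonic", "short_or_monoexonic",
                    "low_coverage", "low_fpkm", NA, "housekeeping_overlap",
                    "mrna_match", "coding_potential", "coding_potential",
                    NA, NA, NA),
  positional_class = c(NA, NA, NA, NA, "intergenic", NA, NA, NA, NA,
                       "sense", "antisense", "intergenic"))
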