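test_that("pearson_cc matches a from-scratch covariance computation", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.4, 0.3)
  y <- c(2.0, 3.1, 2.5, 6.2, 3.9, 1.1)
  ## direct formula oracle
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pc <- pearson_cc(x, y)
  expect_equal(pc$pcc, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt(4 / (1 - r_oracle^2))
  expect_equal(pc$p_value, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)

  expect_equal(pearson_cc(x, x)$pcc, 1.0)
  expect_equal(pearson_cc(x, x)$p_value, 0)
  expect_equal(pearson_cc(x, -x)$pcc, -1.0)
  expect_true(pearson_cc(x, rep(1, 6))$undefined)
  expect_error(pearson_cc(1:2, 1:2), "length")
})

test_that("find_seed_sites classifies 7mer-m8, 8mer and 7mer-A1", {
  mirna <- "UGAGGUAGUAGGUUGUAUAGUU"        # seed (2-8): GAGGUAG
  rc <- revcomp_dna(chartr("U", "T", substr(mirna, 2, 8)))  # CTACCTC
  expect_equal(rc, "CTACCTC")

  ## bare 7mer match followed by non-A -> 7mer_m8
  s1 <- paste0("GGGG", rc, "GGGG")
  got1 <- find_seed_sites(s1, mirna)
  expect_equal(got1$pos, 4L)
  expect_equal(got1$site_type, "7mer_m8")

  ## 7mer match + A opposite position 1 -> 8mer
  s2 <- paste0("GGGG", rc, "A", "GGG")
  got2 <- find_seed_sites(s2, mirna)
  expect_equal(got2$site_type, "8mer")

  ## seed 2-7 match + A anchor, position 8 mismatching -> 7mer_A1
  s3 <- paste0("GGGG", "G", substr(rc, 2, 7), "A", "GGG")
  got3 <- find_seed_sites(s3, mirna)
  expect_equal(got3$site_type, "7mer_A1")
  expect_equal(got3$pos, 5L)

  expect_equal(nrow(find_seed_sites("", mirna)), 0L)
  expect_equal(nrow(find_seed_sites("GGGG", mirna)), 0L)
})

test_that("overlapping sites are all reported", {
  ## artificial miRNA whose seed revcomp is AAAAAAA: overlapping matches
  mirna <- paste0("U", "UUUUUUU", "GGGGGGGGGGGGGG")
  s <- strrep("A", 9)                      # positions 0..2 all match
  got <- find_seed_sites(s, mirna)
  expect_equal(got[site_type == "7mer_m8" | site_type == "8mer", pos],
               0:2)
})

test_that("seed scanning is orientation-specific", {
  mirna <- "UGAGGUAGUAGGUUGUAUAGUU"
  rc <- "CTACCTC"
  s <- paste0("GGGG", rc, "GGGG")
  expect_equal(nrow(find_seed_sites(s, mirna)), 1L)
  ## the reverse complement of the target carries no site (not palindromic)
  expect_equal(nrow(find_seed_sites(revcomp_dna(s), mirna)), 0L)
})

test_that("circular scanning finds junction-spanning sites once", {
  mirna <- "UGAGGUAGUAGGUUGUAUAGUU"
  rc <- "CTACCTC"                          # 7 nt
  ## place the site across the backsplice: last 3 nt + first 4 nt
  circ <- paste0(substr(rc, 4, 7), strrep("G", 50), substr(rc, 1, 3))
  lin <- find_seed_sites(circ, mirna)
  expect_equal(nrow(lin), 0L)              # invisible on the linear sequence
  got <- find_seed_sites_circular(circ, mirna)
  expect_equal(got$pos, 54L)               # starts 3 nt before the junction
  ## a site fully inside the sequence is not double-counted
  circ2 <- paste0(rc, strrep("G", 20))
  expect_equal(nrow(find_seed_sites_circular(circ2, mirna)), 1L)
})

test_that("build_cnc_network applies median, screen, and thresholds", {
  set.seed(20)
  libs <- paste0("L", 1:6)
  base <- 2^seq(0, 5)                       # strong shared profile
  nc <- rbind(lnc1 = base * exp(rnorm(6, 0, 0.001)),
              lnc2 = 1e6 / (base + 1),    # affine in -log2(base + 1)
              lnc3 = runif(6, 50, 60))
  ## coding gene g1 has two transcripts; median over them tracks base
  mr <- rbind(t1 = base * 1.1, t2 = base * 0.9,
              t3 = runif(6, 10, 20))
  colnames(nc) <- libs; colnames(mr) <- libs
  gm <- c(t1 = "g1", t2 = "g1", t3 = "g2")
  edges <- build_cnc_network(nc, mr, mrna_gene_map = gm,
                             biased_noncoding = c("lnc1", "lnc2"),
                             biased_coding = c("g1", "g2"))
  expect_setequal(edges$noncoding_id, c("lnc1", "lnc2"))
  expect_equal(edges[noncoding_id == "lnc1", sign], "positive")
  expect_equal(edges[noncoding_id == "lnc2", sign], "negative")
  expect_true(all(edges$mrna_id == "g1"))
  ## lnc3 was excluded by the sex-biased screen
  expect_false("lnc3" %in% edges$noncoding_id)
  ## every emitted edge re-validates its thresholds from the FPKM input
  for (i in seq_len(nrow(edges))) {
    r <- cor(log2(nc[edges$noncoding_id[i], ] + 1),
             log2(apply(mr[gm == edges$mrna_id[i], , drop = FALSE], 2,
                        median) + 1))
    expect_gte(abs(r), 0.99)
    expect_equal(r, edges$pcc[i], tolerance = 1e-12)
  }
  expect_true(all(edges$p_value < 0.01 & edges$fdr < 0.01))
  ## top_k filter keeps the most significant coding genes
  e1 <- build_cnc_network(nc, mr, mrna_gene_map = gm, top_k_mrnas = 1)
  expect_lte(length(unique(e1$mrna_id)), 1L)
  expect_error(build_cnc_network(nc[, 1:2], mr[, 1:2]), "3")
})

test_that("independent NB rows produce no CNC edges (Monte-Carlo null)", {
  set.seed(30)
  libs <- paste0("L", 1:6)
  nc <- matrix(rnbinom(600, mu = 100, size = 10), nrow = 100,
               dimnames = list(paste0("n", 1:100), libs))
  mr <- matrix(rnbinom(600, mu = 100, size = 10), nrow = 100,
               dimnames = list(paste0("m", 1:100), libs))
  edges <- build_cnc_network(nc, mr)       # 10^4 independent pairs
  expect_equal(nrow(edges), 0L)
})

test_that("build_cerna_network equals a nested-loop oracle", {
  set.seed(40)
  mirnas <- simulate_mirnas(simulation_config(seed = 40, n_mirnas = 3))
  seed_rc <- vapply(mirnas, function(m)
    revcomp_dna(chartr("U", "T", substr(m, 2, 8))), character(1))
  libs <- paste0("L", 1:6)
  prof <- 2^seq(0, 5)
  flat40 <- function() paste(sample(c("C", "T"), 300, TRUE), collapse = "")
  sponges <- c(sp1 = paste0(flat40(), seed_rc[1], flat40()),
               sp2 = paste0(flat40(), seed_rc[2], flat40()),
               sp3 = flat40())
  mrnas <- c(m1 = paste0(flat40(), seed_rc[1], flat40()),
             m2 = paste0(flat40(), seed_rc[2], flat40()),
             m3 = paste0(flat40(), seed_rc[1], substr(flat40(), 1, 100),
                         seed_rc[2], flat40()))
  fpkm <- rbind(sp1 = prof, sp2 = prof, sp3 = prof,
                m1 = prof * 1.05, m2 = rev(prof), m3 = prof * 0.95)
  colnames(fpkm) <- libs
  links <- build_cerna_network(sponges, mrnas, mirnas, fpkm)

  ## oracle: nested loops over sponge x mRNA x miRNA with direct scans
  oracle <- list()
  lf <- log2(fpkm + 1)
  for (sp in sort(names(sponges))) for (mr in sort(names(mrnas))) {
    r <- cor(lf[sp, ], lf[mr, ])
    if (abs(r) < 0.9) next
    for (mi in sort(names(mirnas))) {
      ns <- nrow(find_seed_sites(sponges[[sp]], mirnas[[mi]]))
      nm <- nrow(find_seed_sites(mrnas[[mr]], mirnas[[mi]]))
      if (ns > 0 && nm > 0)
        oracle[[length(oracle) + 1L]] <- paste(sp, mi, mr)
    }
  }
  expect_setequal(links[, paste(sponge_id, mirna_id, mrna_id)],
                  unlist(oracle))
  ## sp1-miR1-m1 must be present; sp2-miR2-m2 fails the correlation gate
  ## only if |r| < 0.9 -- m2 is anti-correlated, |r| ~ 1, so it passes
  expect_true("sp1 miR_1 m1" %in% links[, paste(sponge_id, mirna_id, mrna_id)])
  ## sponge without a site never links
  expect_false("sp3" %in% links$sponge_id)
  ## two sponges sharing one miRNA-mRNA pair yield two links
  sponges2 <- c(a = sponges[["sp1"]], b = sponges[["sp1"]])
  fp2 <- rbind(a = prof, b = prof, m1 = prof)
  colnames(fp2) <- libs
  l2 <- build_cerna_network(sponges2, mrnas["m1"], mirnas[1], fp2)
  expect_equal(nrow(l2), 2L)
})

test_that("junction-spanning sites are honoured in the ceRNA network", {
  mirnas <- c(miR_x = "UGAGGUAGUAGGUUGUAUAGUU")
  rc <- "CTACCTC"
  circ <- paste0(substr(rc, 4, 7), strrep("G", 60), substr(rc, 1, 3))
  mrna <- paste0(strrep("G", 30), rc, strrep("G", 30))
  prof <- 2^seq(0, 5)
  fpkm <- rbind(circ1 = prof, m1 = prof)
  colnames(fpkm) <- paste0("L", 1:6)
  ## linear scan of the sponge finds nothing...
  l_lin <- build_cerna_network(c(circ1 = circ), c(m1 = mrna), mirnas, fpkm,
                               circular = c(circ1 = FALSE))
  expect_equal(nrow(l_lin), 0L)
  ## ...the circular scan finds the backsplice-spanning site
  l_circ <- build_cerna_network(c(circ1 = circ), c(m1 = mrna), mirnas, fpkm,
                                circular = c(circ1 = TRUE))
  expect_equal(nrow(l_circ), 1L)
  expect_equal(l_circ$n_sponge_sites, 1L)
})
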