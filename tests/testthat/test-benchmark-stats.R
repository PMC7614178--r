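test_that("feature-repeat overlap matches the per-base set oracle", {
  f1 <- genomic_intervals("c", 0, 100)
  r1 <- repeat_intervals("c", 50, 150)
  ov <- intersect_overlap(f1, r1)
  expect_equal(ov$per_feature$overlap_bp, 50)
  expect_equal(ov$covered_fraction, 0.5)

  expect_equal(intersect_overlap(genomic_intervals("c", 0, 100),
                                 repeat_intervals("c", 200, 300)
                                 )$per_feature$overlap_bp, 0)

  set.seed(61)
  n <- 200
  fs <- sort(sample(0:9500, n)); rs <- sort(sample(0:9500, n))
  feats <- genomic_intervals(rep("c", n), fs, fs + sample(10:400, n, TRUE))
  reps <- repeat_intervals(rep("c", n), rs, rs + sample(10:400, n, TRUE))
  ov2 <- intersect_overlap(feats, reps)
  oracle <- vapply(seq_len(n), function(i)
    per_base_overlap(feats[i, ], reps), numeric(1))
  expect_equal(ov2$per_feature$overlap_bp, oracle)

  expect_error(intersect_overlap(feats[c(2, 1), ], reps), "sorted")
})

test_that("overlaps below min_overlap report zero", {
  f <- genomic_intervals(c("c", "c"), c(0, 1000), c(100, 1100))
  r <- repeat_intervals(c("c", "c"), c(60, 1050), c(100, 1100))  # 40, 50 bp
  ov <- intersect_overlap(f, r, min_overlap = 50)
  expect_equal(ov$per_feature$overlap_bp, c(0, 50))
})

test_that("flanking windows are strand-oriented, clipped and neighbor-subtracted", {
  cl <- c(chr1 = 10000)
  g <- data.frame(gene_id = "g1", seq_id = "chr1", start = 1000, end = 2000,
                  strand = "+", stringsAsFactors = FALSE)
  fw <- flanking_windows(g, size = 500, chrom_lengths = cl)
  expect_equal(fw$upstream[, c("start", "end")],
               data.frame(start = 500, end = 1000), ignore_attr = TRUE)
  expect_equal(fw$downstream[, c("start", "end")],
               data.frame(start = 2000, end = 2500), ignore_attr = TRUE)

  # a neighbor gene truncates the window at its boundary
  g2 <- rbind(g, data.frame(gene_id = "g2", seq_id = "chr1", start = 2100,
                            end = 2300, strand = "+"))
  fw2 <- flanking_windows(g2, size = 500, chrom_lengths = cl)
  d1 <- fw2$downstream[fw2$downstream$gene_id == "g1", ]
  expect_equal(c(d1$start, d1$end), c(2000, 2100))

  # chromosome-bound clipping
  g3 <- data.frame(gene_id = "g3", seq_id = "chr1", start = 200, end = 600,
                   strand = "+", stringsAsFactors = FALSE)
  fw3 <- flanking_windows(g3, size = 500, chrom_lengths = cl)
  expect_equal(c(fw3$upstream$start, fw3$upstream$end), c(0, 200))

  # '-' strand: upstream lies to the right of the gene
  g4 <- data.frame(gene_id = "g4", seq_id = "chr1", start = 1000, end = 2000,
                   strand = "-", stringsAsFactors = FALSE)
  fw4 <- flanking_windows(g4, size = 500, chrom_lengths = cl)
  expect_equal(c(fw4$upstream$start, fw4$upstream$end), c(2000, 2500))
  expect_equal(c(fw4$downstream$start, fw4$downstream$end), c(500, 1000))

  # a window fully inside a neighbor disappears
  g5 <- rbind(g, data.frame(gene_id = "g5", seq_id = "chr1", start = 2000,
                            end = 2600, strand = "+"))
  fw5 <- flanking_windows(g5, size = 500, chrom_lengths = cl)
  expect_false("g1" %in% fw5$downstream$gene_id)
})

test_that("NLR masking odds ratio follows its closed form", {
  g <- c(chr = strrep("A", 10000))
  # NLRmasked 100, Genmasked 1000, NLR 400, Gen 10000 -> OR 2.5
  nlr <- genomic_intervals("chr", 0, 400)
  reps <- repeat_intervals("chr", c(0, 5000), c(100, 5900))
  st <- nlr_masking_odds_ratio(nlr, reps, g)
  expect_equal(st$NLRmasked, 100)
  expect_equal(st$Genmasked, 1000)
  expect_equal(st$OR, 2.5)

  # uniform masking density -> OR = 1, over random constructions
  set.seed(62)
  for (rep_i in 1:5) {
    w <- sample(c(100, 200, 500), 1)
    starts <- seq(0, 9000, by = 1000)
    reps_u <- repeat_intervals(rep("chr", length(starts)), starts,
                               starts + w)
    nlr_u <- genomic_intervals(c("chr", "chr"), c(0, 5000),
                               c(1000, 7000))  # unions of whole periods
    st_u <- nlr_masking_odds_ratio(nlr_u, reps_u, g)
    expect_equal(st_u$OR, 1.0)
  }

  # a locus overlapping exactly min_overlap bp contributes nothing
  nlr50 <- genomic_intervals("chr", c(0, 2000), c(400, 2400))
  reps50 <- repeat_intervals("chr", c(0, 2000, 5000), c(100, 2050, 5850))
  st50 <- nlr_masking_odds_ratio(nlr50, reps50, g)
  expect_equal(st50$NLRmasked, 100)  # the 50 bp overlap is excluded

  expect_error(nlr_masking_odds_ratio(nlr, repeat_intervals(), g),
               "undefined")
})

test_that("repeats avoiding NLR loci give an odds ratio below 1", {
  sim <- simulate_genome(simulation_params(genome_length = 2e5,
                                           n_families = 3,
                                           copies_per_family = 8,
                                           family_length_range = c(500, 1500),
                                           n_genes = 10, n_nlr = 8,
                                           seed = 23))
  det <- detect_repeats(sim$genome)
  st <- nlr_masking_odds_ratio(sim$nlr, det$intervals, sim$genome)
  expect_lt(st$OR, 1)
})

test_that("Fisher exact p matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(0, 0, 5, 7), 1)       # degenerate margin
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)       # balanced table
  expect_warning(p0 <- fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")

  expect_lt(abs(fisher_exact_2x2(2, 8, 10, 80) - fisher_enum(2, 8, 10, 80)),
            1e-12)
  set.seed(63)
  for (i in 1:25) {
    cells <- sample(0:25, 4, replace = TRUE)
    p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    q <- fisher_enum(cells[1], cells[2], cells[3], cells[4])
    expect_lt(abs(p - q), 1e-12)
    expect_true(p > 0 && p <= 1)
  }
})

test_that("BH adjustment is step-up with order preserved", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(64)
  p <- stats::runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("domain enrichment flags the planted TE-domain family only", {
  # 20 genes carrying the TE domain all overlap repeats; 180 others do not
  fg <- paste0("te", 1:20)
  bg <- paste0("hk", 1:180)
  overlaps <- data.frame(gene_id = c(fg, bg),
                         overlap_bp = c(rep(400, 20), rep(0, 180)))
  g2d <- rbind(data.frame(gene_id = fg, domain = "PF03184"),
               data.frame(gene_id = c(fg, bg), domain = "PF00001"),
               data.frame(gene_id = sample(bg, 40), domain = "PF00069"))
  enr <- domain_enrichment(overlaps, g2d)
  te <- enr[enr$domain == "PF03184", ]
  expect_true(te$enriched)
  expect_lt(te$fdr, 0.05)
  expect_lt(abs(te$p - fisher_enum(te$a, te$b, te$c, te$d)), 1e-12)
  # a domain present in every gene is not enriched (odds ratio 1)
  ubiq <- enr[enr$domain == "PF00001", ]
  expect_false(ubiq$enriched)
  expect_equal(ubiq$odds_ratio, 1)

  # a gene with exactly 50 bp of overlap stays out of the foreground
  ov2 <- data.frame(gene_id = c("g1", "g2"), overlap_bp = c(50, 51))
  g2d2 <- data.frame(gene_id = c("g1", "g2"), domain = "PF1")
  enr2 <- domain_enrichment(ov2, g2d2)
  expect_equal(enr2$a, 1)
  expect_equal(enr2$b, 1)

  expect_warning(e0 <- domain_enrichment(
    data.frame(gene_id = "g1", overlap_bp = 10), g2d2), "foreground")
  expect_identical(nrow(e0), 0L)
})

test_that("canonical k-mer census agrees with the naive oracle", {
  expect_equal(kmer_census("ACGTACG", 16)$census, 0)  # shorter than k

  s <- paste(rep("ACGT", 100), collapse = "")
  cen <- kmer_census(s, 16, min_count = 20)
  oracle <- naive_kmer_counts(s, 16)
  expect_equal(cen$census, sum(oracle >= 20))
  expect_equal(cen$census, 3)  # complementary rotations share one key

  set.seed(65)
  r <- random_dna_str(800)
  cen1 <- kmer_census(c(r, s), 16, min_count = 1)
  tab <- count_kmers(c(a = r, b = s), 16)
  expect_equal(cen1$census, length(tab$kmers))  # cross-module consistency
})
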