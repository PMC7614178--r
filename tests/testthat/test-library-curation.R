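test_that("library merging applies inclusive length bounds and tag prefixes", {
  set.seed(51)
  s1 <- c("a#LTR/Gypsy" = random_dna_str(89),   # below the 90 bp minimum
          "b#LTR/Gypsy" = random_dna_str(90),   # at the minimum: kept
          "c" = random_dna_str(200))
  s2 <- c("d#DNA/Mutator" = random_dna_str(300),
          "e#DNA/Mutator" = random_dna_str(150))
  src <- data.frame(path = c(write_tmp_fasta(s1), write_tmp_fasta(s2)),
                    tag = c("L1", "L2"), kind = "TE",
                    stringsAsFactors = FALSE)
  merged <- merge_libraries(src)
  expect_identical(nrow(merged), 4L)  # 89 bp entry dropped
  expect_setequal(merged$lib_id, c("L1:b", "L1:c", "L2:d", "L2:e"))
  expect_identical(merged$te_class[merged$lib_id == "L1:c"], "UNCLASSIFIED")
  expect_setequal(unique(merged$source_library), c("L1", "L2"))

  src_dup <- src
  src_dup$tag <- "L1"
  expect_error(merge_libraries(src_dup), "tag collision")
})

test_that("the 55 kb maximum-length bound is inclusive", {
  # exercised at a scaled-down maximum so the fixture stays tiny
  set.seed(52)
  s <- c("at#X" = random_dna_str(500), "over#X" = random_dna_str(501))
  src <- data.frame(path = write_tmp_fasta(s), tag = "L", kind = "TE",
                    stringsAsFactors = FALSE)
  merged <- merge_libraries(src, clustering_params(min_len = 90,
                                                   max_len = 500))
  expect_identical(merged$lib_id, "L:at")
  expect_error(clustering_params(min_len = 500, max_len = 400))
})

test_that("pairwise similarity reports identity and coverage on the shorter sequence", {
  set.seed(53)
  a <- random_dna_str(200)
  sim_id <- pairwise_similarity(a, a)
  expect_equal(unname(sim_id), c(100, 100))

  long <- random_dna_str(200)
  sub <- substr(long, 26, 175)  # 150 bp exact substring
  sim_sub <- pairwise_similarity(sub, long)
  expect_equal(unname(sim_sub), c(100, 100))

  for (i in 1:3) {
    b <- random_dna_str(200)
    m <- mutate_dna(b, 0.05)
    sim_m <- pairwise_similarity(m, b)
    expect_lt(abs(sim_m[["identity"]] - 100 * sw_identity(m, b)), 0.5)
    expect_gt(sim_m[["coverage"]], 90)
  }
})

test_that("clustering equals the brute-force all-pairs component oracle", {
  set.seed(54)
  fams <- vapply(1:5, function(i) random_dna_str(300), character(1))
  # 1% per copy from the consensus, so copies sit ~2% apart pairwise
  seqs_chr <- unlist(lapply(seq_along(fams), function(f) {
    out <- vapply(1:4, function(cp) mutate_dna(fams[f], 0.01), character(1))
    names(out) <- paste0("f", f, "c", 1:4)
    out
  }))
  seqs <- data.frame(lib_id = names(seqs_chr), residues = unname(seqs_chr),
                     length = nchar(seqs_chr), te_class = "X",
                     source_library = "L", kind = "TE",
                     host_gene_flag = FALSE, stringsAsFactors = FALSE)
  cl <- cluster_sequences(seqs)
  expect_identical(length(cl), 5L)
  members <- lapply(cl, `[[`, "member_ids")

  # oracle: edges from Smith-Waterman identity/coverage, components by
  # label propagation over an explicit adjacency matrix
  n <- nrow(seqs)
  adj <- diag(n) == 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- seqs$residues[i]; b <- seqs$residues[j]
      sh <- if (nchar(a) <= nchar(b)) a else b
      pa <- Biostrings::pairwiseAlignment(sh,
                                          if (nchar(a) <= nchar(b)) b else a,
                                          type = "local")
      idp <- Biostrings::pid(pa, type = "PID1")
      cov <- 100 * Biostrings::nchar(pa) / nchar(sh)
      if (idp >= 95 && cov >= 75) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  lab <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(lab[adj[i, ]]), numeric(1))
    if (identical(new, lab)) break
    lab <- new
  }
  oracle_members <- lapply(split(seqs$lib_id, lab), sort)
  canon <- function(x) sort(vapply(x, paste, character(1), collapse = ","))
  expect_identical(canon(members), canon(unname(oracle_members)))

  # permutation invariance: same partition and representatives
  perm <- seqs[sample(n), ]
  cl2 <- cluster_sequences(perm)
  expect_identical(lapply(cl2, `[[`, "member_ids"), members)
  expect_identical(vapply(cl2, `[[`, character(1), "representative"),
                   vapply(cl, `[[`, character(1), "representative"))
})

test_that("sequences below the similarity cutoffs stay singletons", {
  set.seed(55)
  a <- random_dna_str(300)
  b <- mutate_dna(a, 0.10)  # ~90% identity, below the 95% cutoff
  seqs <- data.frame(lib_id = c("a", "b"), residues = c(a, b),
                     length = 300, te_class = "X", source_library = "L",
                     kind = "TE", host_gene_flag = FALSE,
                     stringsAsFactors = FALSE)
  cl <- cluster_sequences(seqs)
  expect_identical(length(cl), 2L)

  ident3 <- data.frame(lib_id = c("x", "y", "z"), residues = a,
                       length = 300, te_class = "X", source_library = "L",
                       kind = "TE", host_gene_flag = FALSE,
                       stringsAsFactors = FALSE)
  cl3 <- cluster_sequences(ident3)
  expect_identical(length(cl3), 1L)
  expect_identical(cl3[[1]]$member_ids, c("x", "y", "z"))
})

test_that("representatives are the longest member with lexicographic ties", {
  seqs <- data.frame(lib_id = c("m1", "m2", "m3"),
                     residues = c(strrep("A", 100), strrep("A", 300),
                                  strrep("A", 200)),
                     length = c(100, 300, 200), stringsAsFactors = FALSE)
  expect_identical(pick_representative(c("m1", "m2", "m3"), seqs), "m2")
  expect_identical(pick_representative("m1", seqs), "m1")
  ties <- data.frame(lib_id = c("z", "a"), residues = strrep("A", 50),
                     length = c(50, 50), stringsAsFactors = FALSE)
  expect_identical(pick_representative(c("z", "a"), ties), "a")
})

test_that("mixed-cluster filtering follows the six-library and host-gene rules", {
  mk <- function(n_libs, host_frac, transcripts = TRUE) {
    list(member_ids = "m", has_transcripts = transcripts,
         te_libraries_present = if (n_libs > 0) paste0("L", seq_len(n_libs))
         else character(0),
         host_gene_fraction = host_frac, representative = "m")
  }
  expect_length(filter_clusters(list(mk(6, 0.0))), 1)   # kept
  expect_length(filter_clusters(list(mk(5, 0.0))), 0)   # too few libraries
  expect_length(filter_clusters(list(mk(6, 0.1))), 0)   # host genes present
  expect_length(filter_clusters(list(mk(3, 0.0, transcripts = FALSE))), 1)
  expect_length(filter_clusters(list(mk(0, 0.0, transcripts = TRUE))), 0)
  # monotone in min_libraries
  for (ml in 1:8) {
    kept <- length(filter_clusters(list(mk(5, 0)), min_libraries = ml))
    kept_next <- length(filter_clusters(list(mk(5, 0)),
                                        min_libraries = ml + 1))
    expect_true(kept >= kept_next)
  }
})

test_that("six-frame translation follows the standard code and frame lengths", {
  expect_identical(six_frame_translate("ATGAAATAG")[1], "MK*")
  expect_identical(six_frame_translate("TTA")[4], "*")  # revcomp TAA
  expect_identical(six_frame_translate("AT"), rep("", 6))
  set.seed(56)
  for (L in c(3L, 10L, 17L, 60L)) {
    s <- random_dna_str(L)
    tr <- six_frame_translate(s)
    for (f in 1:3) {
      expect_identical(nchar(tr[f]), (L - (f - 1L)) %/% 3L)
      expect_identical(nchar(tr[f + 3]), (L - (f - 1L)) %/% 3L)
    }
  }
})

test_that("control benchmark reproduces confusion counts and rates", {
  pos <- paste0("P", 1:22)
  neg <- paste0("N", 1:38)
  found <- c(paste0("P", 1:20), paste0("N", 1:2))
  cm <- evaluate_controls(found, pos, neg)
  expect_identical(c(cm$TP, cm$FN, cm$TN, cm$FP), c(20L, 2L, 36L, 2L))
  expect_equal(unname(cm$report["sensitivity"]), 0.91)
  expect_equal(unname(cm$report["specificity"]), 0.95)
  expect_identical(cm$TP + cm$FN, length(pos))
  expect_identical(cm$TN + cm$FP, length(neg))

  perfect <- evaluate_controls(pos, pos, neg)
  expect_equal(unname(perfect$report), c(1.00, 1.00))

  expect_error(evaluate_controls(found, character(0), neg), "non-empty")
  expect_warning(evaluate_controls("P1", c("P1", "Z1"), c("Z1", "N1")),
                 "overlap")
})

test_that("domain-hit tables are parsed with version suffixes stripped", {
  p <- tempfile(fileext = ".domtbl")
  writeLines(c(
    "# hmmscan domtblout",
    "zf-BED  PF02892.12  60  lib1:seq1  -  300  1e-10 55.0",
    "RVT_1   PF00078.5   200 lib1:seq2  -  900  1e-30 120.2",
    "Pkinase PF00069.28  260 cdna:tx1   -  800  1e-25 99.9",
    "orphan  -           50  lib2:seq3  -  100  1e-05 20.0",
    "zf-BED  PF02892.12  60  lib1:seq1  -  300  1e-08 40.0"
  ), p)
  hits <- read_domain_hits(p)
  expect_identical(nrow(hits), 4L)  # duplicate pair collapsed
  expect_setequal(hits$accession[hits$lib_id == "lib1:seq1"], "PF02892")
  expect_identical(hits$accession[hits$lib_id == "lib2:seq3"], "orphan")

  writeLines("# only comments", p)
  expect_identical(nrow(read_domain_hits(p)), 0L)

  writeLines(c("ok PF1.1 10 q1", "bad line"), p)
  expect_error(read_domain_hits(p), "line 2")
})

test_that("end-to-end curation keeps the five family representatives and drops host genes", {
  src <- make_curation_sources(seed = 11)
  expect_identical(nrow(src), 7L)
  hits <- data.frame(lib_id = paste0("lib1:fam", 1:5, "_lib1"),
                     accession = paste0("P", 1:5),
                     stringsAsFactors = FALSE)
  res <- curate_library(src, domain_hits = hits,
                        positive_list = paste0("P", 1:5),
                        negative_list = "N1")
  expect_identical(nrow(res$library), 5L)
  expect_false(any(grepl("host", res$library$lib_id)))
  expect_setequal(sub(".*:fam(\\d)_.*", "\\1", res$library$lib_id),
                  as.character(1:5))
  expect_s3_class(res$benchmark, "confusion_matrix")

  # written library headers carry the id#class convention
  p <- tempfile(fileext = ".fa")
  write_library(res$library, p)
  lib <- read_library(p)
  expect_identical(nrow(lib), 5L)
  expect_true(all(lib$te_class == "LTR/Gypsy"))
})
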