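# Independent brute-force oracles and tiny fixture builders shared across
# the test files. These deliberately avoid the package's own code paths:
# k-mers are canonicalised word by word, overlaps are computed on per-base
# integer sets, alignment identities come from Biostrings' Smith-Waterman,
# and Fisher p-values from exhaustive hypergeometric enumeration.

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitution-only mutation (keeps alignment gapless for oracle tests)
mutate_dna <- function(s, rate) {
  b <- strsplit(s, "")[[1]]
  i <- which(stats::runif(length(b)) < rate)
  b[i] <- vapply(b[i], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  paste(b, collapse = "")
}

rc_word <- function(w) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", w), "")[[1]]),
        collapse = "")
}

# naive per-position canonical k-mer counter
naive_kmer_counts <- function(seqs, k) {
  words <- character(0)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s) - k + 1
    if (n < 1) next
    for (i in seq_len(n)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      r <- rc_word(w)
      words <- c(words, if (r < w) r else w)
    }
  }
  if (length(words) == 0) return(integer(0))
  table(words)
}

# per-base set intersection: overlap bp of one feature with a repeat set
per_base_overlap <- function(feature, repeats) {
  fb <- seq(feature$start, feature$end - 1)
  rb <- unlist(lapply(seq_len(nrow(repeats)), function(i) {
    if (repeats$seq_id[i] != feature$seq_id) return(integer(0))
    seq(repeats$start[i], repeats$end[i] - 1)
  }))
  length(intersect(fb, unique(rb)))
}

# local Smith-Waterman identity (matches / aligned columns), fraction
sw_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local")
  Biostrings::pid(pa, type = "PID1") / 100
}

# exhaustive two-sided Fisher p: sum hypergeometric probabilities of all
# tables with the observed margins at most as probable as the observed one
fisher_enum <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  if (lo > hi || (m + n) == 0) return(1)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# write a named character vector as a FASTA file, return the path
write_tmp_fasta <- function(seqs) {
  path <- tempfile("seqs", fileext = ".fa")
  repeatkit::write_fasta(seqs, path)
  path
}

# curation fixture: 5 TE families spread over 6 TE source libraries plus a
# transcript source carrying 2 host-gene sequences that also sit in lib1
# (flagged as potential host genes there): 7 source tags in total
make_curation_sources <- function(seed = 11) {
  set.seed(seed)
  fams <- vapply(1:5, function(i) random_dna_str(400), character(1))
  hosts <- vapply(1:2, function(i) random_dna_str(400), character(1))
  dir <- tempfile("curation")
  dir.create(dir)
  te_tags <- paste0("lib", 1:6)
  rows <- list()
  for (t in seq_along(te_tags)) {
    seqs <- vapply(fams, mutate_dna, character(1), rate = 0.01)
    names(seqs) <- paste0("fam", 1:5, "_", te_tags[t], "#LTR/Gypsy")
    if (t == 1) {
      hseqs <- hosts
      names(hseqs) <- paste0("host", 1:2, "#UNKNOWN")
      seqs <- c(seqs, hseqs)
    }
    p <- file.path(dir, paste0(te_tags[t], ".fa"))
    repeatkit::write_fasta(seqs, p)
    rows[[t]] <- data.frame(path = p, tag = te_tags[t], kind = "TE",
                            host_flags = NA_character_,
                            stringsAsFactors = FALSE)
  }
  # host flags for lib1
  flags <- file.path(dir, "lib1_host.tsv")
  write.table(data.frame(id = paste0("host", 1:2), flag = 1), flags,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  rows[[1]]$host_flags <- flags
  # transcript source: the two host genes again, plus one unrelated cDNA
  tr <- c(vapply(hosts, mutate_dna, character(1), rate = 0.01),
          random_dna_str(400))
  names(tr) <- c("cdna_host1", "cdna_host2", "cdna_other")
  p <- file.path(dir, "cdna.fa")
  repeatkit::write_fasta(tr, p)
  rows[[7]] <- data.frame(path = p, tag = "cdna", kind = "transcript",
                          host_flags = NA_character_,
                          stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
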