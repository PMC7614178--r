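# De novo repeat calling by canonical k-mer counting, and genome
# soft-masking. The detector scores every position of the genome with the
# genome-wide count of the canonical k-mer starting there; maximal runs of
# high-count positions become repeat intervals. Counting is canonical
# (lexicographic min of a word and its reverse complement) so inverted TE
# copies share one count.

#' Detector configuration
#'
#' @param k word size (integer in `[1, 31]`) or `"AUTO"` to derive it from
#'   genome length via [select_k()].
#' @param count_threshold minimum genome-wide occurrence count for a
#'   position to be considered repetitive (default 3: with
#'   `k = floor(log4 L)` a unique k-mer is expected 1-4 times by chance).
#' @param min_repeat_len minimum repeat interval length in bp; default
#'   `max(2k, 30)`, resolved once `k` is known.
#' @param merge_dist intervals separated by at most this many bp are merged;
#'   default `k`, resolved once `k` is known.
#' @param k_min,k_max clamp for the automatic word-size choice (defaults 13
#'   and 16, the range observed on plant genomes of increasing length).
#' @return list of class `detector_config`.
#' @export
detector_config <- function(k = "AUTO", count_threshold = 3,
                            min_repeat_len = NULL, merge_dist = NULL,
                            k_min = 13, k_max = 16) {
  if (!identical(k, "AUTO")) {
    k <- as.integer(k)
    if (is.na(k) || k < 1 || k > 31) stop("k must be in [1, 31] or \"AUTO\"")
  }
  if (count_threshold < 2) stop("count_threshold must be >= 2")
  if (k_min > k_max) stop("k_min must be <= k_max")
  structure(list(k = k, count_threshold = as.integer(count_threshold),
                 min_repeat_len = min_repeat_len, merge_dist = merge_dist,
                 k_min = as.integer(k_min), k_max = as.integer(k_max)),
            class = "detector_config")
}

resolve_config <- function(config, genome_length) {
  k <- if (identical(config$k, "AUTO")) select_k(genome_length, config)
       else config$k
  list(k = k,
       count_threshold = config$count_threshold,
       min_repeat_len = if (is.null(config$min_repeat_len))
         max(2L * k, 30L) else as.integer(config$min_repeat_len),
       merge_dist = if (is.null(config$merge_dist)) k
         else as.integer(config$merge_dist))
}

#' Choose the k-mer word size from genome length
#'
#' `k = floor(log4(genome_length))`, clamped to `[k_min, k_max]`
#' (defaults 13-16). An explicit `config$k` overrides the computation.
#'
#' @param genome_length total genome length in bp (`>= 1`).
#' @param config a [detector_config()].
#' @return integer word size.
#' @export
select_k <- function(genome_length, config = detector_config()) {
  if (genome_length < 1) stop("genome_length must be >= 1")
  if (!identical(config$k, "AUTO")) return(config$k)
  k <- floor(log(genome_length) / log(4) + 1e-9)
  as.integer(min(max(k, config$k_min), config$k_max))
}

# Canonical k-mer at each start position of one sequence (uppercased);
# windows containing a non-ACGT residue yield NA. Length max(0, L - k + 1).
canonical_kmers <- function(seq, k) {
  s <- toupper(seq)
  L <- nchar(s)
  n <- L - k + 1
  if (n < 1) return(character(0))
  i <- seq_len(n)
  fwd <- substring(s, i, i + k - 1)
  rc <- revcomp(s)
  rck <- substring(rc, L - i - k + 2, L - i + 1)
  use_rc <- rck < fwd
  canon <- fwd
  canon[use_rc] <- rck[use_rc]
  canon[grepl("[^ACGT]", fwd)] <- NA_character_
  canon
}

#' Count canonical k-mers over a genome set
#'
#' Every position carrying an N-free word of length `k` contributes one
#' count to its canonical key, so total count mass equals the number of
#' valid positions.
#'
#' @param genomes named character vector of sequences.
#' @param k word size.
#' @return list of class `kmer_table`: `$k`, `$kmers` (unique canonical
#'   words) and `$counts` (parallel integer counts).
#' @export
count_kmers <- function(genomes, k) {
  stopifnot(k >= 1)
  words <- unlist(lapply(genomes, canonical_kmers, k = k), use.names = FALSE)
  words <- words[!is.na(words)]
  u <- unique(words)
  counts <- tabulate(match(words, u), nbins = length(u))
  structure(list(k = as.integer(k), kmers = u, counts = counts),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("kmer_table: k =", x$k, "|", length(x$kmers), "distinct canonical",
      "k-mers | count mass", sum(x$counts), "\n")
  invisible(x)
}

#' Per-position k-mer count scores for one sequence
#'
#' `score[i]` is the genome-wide canonical count of the word starting at
#' position `i` (1-based vector over 0-based positions `i - 1`); windows
#' containing N score 0.
#'
#' @param genome a single sequence (character scalar).
#' @param table a `kmer_table` built with the same `k` over the genome set.
#' @return numeric vector of length `max(0, L - k + 1)`.
#' @export
score_positions <- function(genome, table) {
  canon <- canonical_kmers(genome[[1]], table$k)
  sc <- table$counts[match(canon, table$kmers)]
  sc[is.na(sc)] <- 0
  as.numeric(sc)
}

#' Call repeat intervals from a position score vector
#'
#' Maximal runs of word-start positions scoring at least `count_threshold`
#' become intervals extended by the full last word (`+ k`, clipped to the
#' sequence end); intervals separated by at most `merge_dist` bp are merged;
#' intervals shorter than `min_repeat_len` are dropped. The interval score
#' is the mean position score over the word starts it covers.
#'
#' @param scores vector from [score_positions()].
#' @param k word size the scores were computed with.
#' @param seq_id sequence name for the output intervals.
#' @param seq_length sequence length in bp.
#' @param count_threshold,merge_dist,min_repeat_len see [detector_config()].
#' @return repeat interval data.frame, sorted and non-overlapping.
#' @export
call_repeats <- function(scores, k, seq_id, seq_length,
                         count_threshold = 3, merge_dist = k,
                         min_repeat_len = max(2 * k, 30)) {
  if (length(scores) == 0) return(repeat_intervals())
  r <- rle(scores >= count_threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values)
  if (length(hit) == 0) return(repeat_intervals())
  # 0-based word starts [a, b] -> interval [a, b + k), clipped
  a <- starts[hit] - 1
  b <- ends[hit] - 1
  ir <- IRanges::IRanges(a + 1L, pmin(b + k, seq_length))
  ir <- IRanges::reduce(ir, min.gapwidth = merge_dist + 1L)
  ir <- ir[IRanges::width(ir) >= min_repeat_len]
  if (length(ir) == 0) return(repeat_intervals())
  sc <- vapply(seq_along(ir), function(i) {
    from <- IRanges::start(ir)[i]
    to <- min(IRanges::end(ir)[i] - k + 1L, length(scores))
    mean(scores[from:to])
  }, numeric(1))
  repeat_intervals(seq_id = rep(seq_id, length(ir)),
                   start = IRanges::start(ir) - 1,
                   end = IRanges::end(ir), score = sc)
}

#' Detect repeats over a genome set
#'
#' Orchestrates word-size selection, canonical counting, position scoring
#' and interval calling for every sequence.
#'
#' @param genomes named character vector of sequences.
#' @param config a [detector_config()].
#' @return list: `$intervals` (repeat data.frame over all sequences), `$k`,
#'   `$table` (the `kmer_table`), `$masked_fraction`.
#' @export
detect_repeats <- function(genomes, config = detector_config()) {
  stopifnot(length(genomes) > 0, !is.null(names(genomes)))
  total_len <- sum(genome_lengths(genomes))
  cfg <- resolve_config(config, total_len)
  table <- count_kmers(genomes, cfg$k)
  calls <- lapply(names(genomes), function(id) {
    sc <- score_positions(genomes[[id]], table)
    call_repeats(sc, cfg$k, id, nchar(genomes[[id]]),
                 count_threshold = cfg$count_threshold,
                 merge_dist = cfg$merge_dist,
                 min_repeat_len = cfg$min_repeat_len)
  })
  intervals <- do.call(rbind, calls)
  list(intervals = intervals, k = cfg$k, table = table,
       masked_fraction = masked_fraction(genomes, intervals))
}

#' Soft-mask a genome with repeat intervals
#'
#' Residues inside the intervals are lowercased; everything else (and the
#' sequence length) is unchanged.
#'
#' @param genomes named character vector of sequences.
#' @param intervals interval data.frame on those sequences.
#' @return named character vector of soft-masked sequences.
#' @export
soft_mask <- function(genomes, intervals) {
  validate_intervals(intervals, chrom_lengths = genome_lengths(genomes))
  out <- genomes
  for (i in seq_len(nrow(intervals))) {
    id <- intervals$seq_id[i]
    s <- intervals$start[i] + 1
    e <- intervals$end[i]
    substr(out[[id]], s, e) <- tolower(substr(out[[id]], s, e))
  }
  out
}

#' Fraction of the genome covered by repeat intervals
#'
#' @param genomes named character vector of sequences.
#' @param intervals non-overlapping interval data.frame (merge first if
#'   needed); overlap raises an error.
#' @return fraction in `[0, 1]`: total interval bp over total genome bp.
#' @export
masked_fraction <- function(genomes, intervals) {
  validate_intervals(intervals, chrom_lengths = genome_lengths(genomes))
  if (has_overlaps_within(intervals)) {
    stop("intervals overlap; merge them before computing the masked fraction")
  }
  total_interval_bp(intervals) / sum(genome_lengths(genomes))
}
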