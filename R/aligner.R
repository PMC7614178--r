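# Internal local aligner used for repeat classification and library
# clustering: exact shared words seed gapless blocks on each diagonal,
# blocks are X-drop extended, then chained collinearly with a small
# diagonal-shift (indel) penalty. It is deliberately simple so that its
# identities can be checked against a full Smith-Waterman oracle; an
# adapter for externally produced PAF alignments covers production use
# with a long-read mapper.

# 1-based positions of all N-free words of length w in s (uppercased).
seq_words <- function(s, w, max_occ = 50) {
  s <- toupper(s)
  L <- nchar(s)
  n <- L - w + 1
  if (n < 1) return(data.frame(word = character(), pos = integer()))
  words <- substring(s, seq_len(n), w:L)
  ok <- !grepl("[^ACGT]", words)
  df <- data.frame(word = words[ok], pos = which(ok),
                   stringsAsFactors = FALSE)
  # drop hyper-abundant (low-complexity) seed words
  tab <- table(df$word)
  df[df$word %in% names(tab)[tab <= max_occ], , drop = FALSE]
}

# X-drop extension score: given logical match vector along one direction,
# number of steps to extend so that score (+1 match / -1 mismatch) is
# maximal, stopping once the running score drops `xdrop` below its maximum.
xdrop_extent <- function(eq, xdrop = 10) {
  if (length(eq) == 0) return(0L)
  sc <- cumsum(ifelse(eq, 1L, -1L))
  run_max <- cummax(sc)
  stop_at <- which(sc < run_max - xdrop)
  lim <- if (length(stop_at) == 0) length(sc) else stop_at[1] - 1L
  if (lim == 0) return(0L)
  best <- which.max(sc[seq_len(lim)])
  if (sc[best] <= 0) 0L else best
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Gapless blocks between query and target for one orientation.
gapless_blocks <- function(qc, tc, seeds, w, seed_join = 50, xdrop = 10) {
  if (nrow(seeds) == 0) return(NULL)
  seeds$diag <- seeds$qpos - seeds$tpos
  blocks <- list()
  for (d in unique(seeds$diag)) {
    sp <- sort(seeds$qpos[seeds$diag == d])
    grp <- cumsum(c(1, diff(sp) > seed_join))
    for (g in unique(grp)) {
      qs <- min(sp[grp == g]); qe <- max(sp[grp == g]) + w - 1
      ts <- qs - d; te <- qe - d
      # extend left
      nleft <- min(qs, ts) - 1
      if (nleft > 0) {
        eq <- rev(qc[(qs - nleft):(qs - 1)]) == rev(tc[(ts - nleft):(ts - 1)])
        ext <- xdrop_extent(eq, xdrop)
        qs <- qs - ext; ts <- ts - ext
      }
      # extend right
      nright <- min(length(qc) - qe, length(tc) - te)
      if (nright > 0) {
        eq <- qc[(qe + 1):(qe + nright)] == tc[(te + 1):(te + nright)]
        ext <- xdrop_extent(eq, xdrop)
        qe <- qe + ext; te <- te + ext
      }
      m <- sum(qc[qs:qe] == tc[ts:te])
      blocks[[length(blocks) + 1]] <-
        c(qs = qs, qe = qe, ts = ts, te = te, len = qe - qs + 1,
          matches = m, diag = d)
    }
  }
  bl <- as.data.frame(do.call(rbind, blocks))
  # deduplicate blocks that extended into the same extent
  bl <- unique(bl)
  bl[order(bl$qs, bl$ts), , drop = FALSE]
}

# Collinear chaining of gapless blocks (O(n^2) DP, n is small). X-drop
# extension can push blocks on neighboring diagonals past each other, so
# chaining tolerates small block overlaps (`ov_tol`); overlapping columns
# are trimmed from both the match and column totals.
chain_blocks <- function(bl, band = 200, max_gap = 500, ov_tol = 60) {
  if (is.null(bl) || nrow(bl) == 0) return(NULL)
  n <- nrow(bl)
  bscore <- 2 * bl$matches - bl$len
  dp <- bscore
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      qgap <- bl$qs[i] - bl$qe[j] - 1
      tgap <- bl$ts[i] - bl$te[j] - 1
      if (qgap < -ov_tol || tgap < -ov_tol) next
      if (bl$qs[i] <= bl$qs[j] || bl$ts[i] <= bl$ts[j]) next
      shift <- abs(bl$diag[i] - bl$diag[j])
      ov <- max(0, -qgap, -tgap)
      if (shift > band || max(qgap, tgap) > max_gap) next
      cand <- dp[j] + bscore[i] - shift - max(qgap, tgap, 0) - ov
      if (cand > dp[i]) {
        dp[i] <- cand
        prev[i] <- j
      }
    }
  }
  best <- which.max(dp)
  path <- integer(0)
  i <- best
  while (!is.na(i)) {
    path <- c(i, path)
    i <- prev[i]
  }
  ch <- bl[path, , drop = FALSE]
  matches <- sum(ch$matches)
  overlaps <- 0
  gaps <- 0
  if (nrow(ch) > 1) {
    qg <- ch$qs[-1] - ch$qe[-nrow(ch)] - 1
    tg <- ch$ts[-1] - ch$te[-nrow(ch)] - 1
    gaps <- sum(pmax(qg, tg, 0))
    overlaps <- sum(pmax(0, -qg, -tg))
  }
  matches <- max(0, matches - overlaps)
  columns <- sum(ch$len) - overlaps + gaps
  list(qstart = ch$qs[1], qend = ch$qe[nrow(ch)],
       tstart = ch$ts[1], tend = ch$te[nrow(ch)],
       matches = matches, columns = columns,
       aligned_q = sum(ch$len) - overlaps,
       identity = matches / columns,
       span = ch$qe[nrow(ch)] - ch$qs[1] + 1,
       score = dp[best], blocks = ch)
}

# Best local chain between query and target on one orientation, or NULL.
align_pair <- function(query, target, seed_len = 11, seed_join = 50,
                       xdrop = 10) {
  qw <- seq_words(query, seed_len)
  tw <- seq_words(target, seed_len)
  if (nrow(qw) == 0 || nrow(tw) == 0) return(NULL)
  seeds <- merge(qw, tw, by = "word")
  if (nrow(seeds) == 0) return(NULL)
  names(seeds)[names(seeds) == "pos.x"] <- "qpos"
  names(seeds)[names(seeds) == "pos.y"] <- "qpos2"
  seeds <- data.frame(qpos = seeds$qpos, tpos = seeds$qpos2)
  qc <- chars(toupper(query))
  tc <- chars(toupper(target))
  bl <- gapless_blocks(qc, tc, seeds, seed_len, seed_join, xdrop)
  chain_blocks(bl)
}

# Best chain over both orientations of the query; adds $strand.
align_pair_bothstrands <- function(query, target, seed_len = 11) {
  fwd <- align_pair(query, target, seed_len)
  rev <- align_pair(revcomp(query), target, seed_len)
  if (is.null(fwd) && is.null(rev)) return(NULL)
  if (is.null(rev) || (!is.null(fwd) && fwd$score >= rev$score)) {
    fwd$strand <- "+"
    fwd
  } else {
    rev$strand <- "-"
    rev
  }
}

#' Align a repeat sequence against a classified repeat library
#'
#' Seed-chain-extend local alignment of `repeat_seq` against every library
#' sequence, both orientations. Alignments reaching `min_identity` and
#' `min_span` aligned bp are reported, best first (score, then aligned bp,
#' then lib_id).
#'
#' @param repeat_seq DNA string (non-empty).
#' @param library library data.frame from [read_library()] /
#'   [merge_libraries()] (columns `lib_id`, `residues`, `te_class`).
#' @param min_identity minimum alignment identity (fraction, default 0.70).
#' @param min_span minimum aligned span in bp (default 90).
#' @param seed_len exact-word seed length (default 11).
#' @return data.frame with columns `lib_id`, `te_class`, `strand`,
#'   `identity`, `aligned_bp`, `score`.
#' @export
align_to_library <- function(repeat_seq, library, min_identity = 0.70,
                             min_span = 90, seed_len = 11) {
  stopifnot(nchar(repeat_seq) > 0)
  empty <- data.frame(lib_id = character(), te_class = character(),
                      strand = character(), identity = numeric(),
                      aligned_bp = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(library) || nrow(library) == 0) return(empty)
  hits <- lapply(seq_len(nrow(library)), function(i) {
    ch <- align_pair_bothstrands(repeat_seq, library$residues[i], seed_len)
    if (is.null(ch)) return(NULL)
    data.frame(lib_id = library$lib_id[i], te_class = library$te_class[i],
               strand = ch$strand, identity = ch$identity,
               aligned_bp = ch$span, score = ch$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) return(empty)
  out <- out[out$identity >= min_identity & out$aligned_bp >= min_span, ,
             drop = FALSE]
  out[order(-out$score, -out$aligned_bp, out$lib_id), , drop = FALSE]
}

#' Pairwise identity and coverage between two library sequences
#'
#' Local alignment (both strands, shorter sequence as query); coverage is
#' the fraction of the shorter sequence inside aligned blocks, identity the
#' match fraction over the combined aligned columns. These are the
#' similarity measures the clustering graph is built on.
#'
#' @param a,b DNA strings (non-empty).
#' @param seed_len exact-word seed length (default 11).
#' @return named numeric vector `c(identity = , coverage = )`, in percent.
#' @export
pairwise_similarity <- function(a, b, seed_len = 11) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (nchar(a) <= nchar(b)) {
    query <- a; target <- b
  } else {
    query <- b; target <- a
  }
  ch <- align_pair_bothstrands(query, target, seed_len)
  if (is.null(ch)) return(c(identity = 0, coverage = 0))
  c(identity = 100 * ch$matches / ch$columns,
    coverage = 100 * ch$aligned_q / nchar(query))
}
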