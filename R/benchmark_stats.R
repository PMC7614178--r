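# Statistics quantifying how a masking strategy intersects genes, flanks
# and NLR disease-resistance loci, and Fisher-exact domain enrichment with
# FDR control. All interval arithmetic is 0-based half-open on the package
# surface; IRanges/GenomicRanges do the set operations internally.

check_sorted <- function(df, what) {
  if (nrow(df) < 2) return(invisible(TRUE))
  for (id in unique(df$seq_id)) {
    s <- df$start[df$seq_id == id]
    if (is.unsorted(s)) stop(what, " must be sorted by start within ", id)
  }
  invisible(TRUE)
}

#' Per-feature overlap with repeat intervals
#'
#' bedtools-intersect-style: for each feature, the overlap is the union of
#' its intersections with the (merged) repeat intervals; features with
#' overlap below `min_overlap` bp report 0.
#'
#' @param features interval data.frame, sorted by start within each
#'   `seq_id`.
#' @param repeats repeat interval data.frame, sorted likewise.
#' @param min_overlap minimum bp to report a non-zero overlap (default 1).
#' @return list: `$per_feature` (features plus `overlap_bp` and `fraction`
#'   columns), `$covered_fraction` (total reported overlap bp over total
#'   feature bp).
#' @export
intersect_overlap <- function(features, repeats, min_overlap = 1) {
  check_sorted(features, "features")
  check_sorted(repeats, "repeats")
  out <- features
  out$overlap_bp <- 0
  if (nrow(features) > 0 && nrow(repeats) > 0) {
    fgr <- as_granges0(features)
    rgr <- GenomicRanges::reduce(as_granges0(repeats), ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(fgr, rgr, ignore.strand = TRUE)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(fgr)[qh],
        IRanges::ranges(rgr)[S4Vectors::subjectHits(hits)]))
      agg <- tapply(ov, qh, sum)
      out$overlap_bp[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  out$overlap_bp[out$overlap_bp < min_overlap] <- 0
  out$fraction <- ifelse(out$end > out$start,
                         out$overlap_bp / (out$end - out$start), 0)
  covered <- if (nrow(out) == 0 || total_interval_bp(out) == 0) 0
             else sum(out$overlap_bp) / total_interval_bp(out)
  list(per_feature = out, covered_fraction = covered)
}

#' Proximal upstream and downstream windows of genes
#'
#' Strand-oriented windows of `size` bp next to each gene (upstream of a
#' `-` gene lies to its right; unstranded genes are treated as `+`),
#' clipped at chromosome bounds. Base pairs intersecting ANY gene interval
#' are subtracted and only the fragment contiguous with the focal gene edge
#' is kept; empty windows are dropped.
#'
#' @param genes gene data.frame (`gene_id`, `seq_id`, `start`, `end`,
#'   `strand`), sorted by start within each `seq_id`.
#' @param size window size in bp (default 500).
#' @param chrom_lengths named numeric vector of sequence lengths.
#' @return list with `$upstream` and `$downstream` interval data.frames
#'   (columns `gene_id`, `seq_id`, `start`, `end`).
#' @export
flanking_windows <- function(genes, size = 500, chrom_lengths) {
  check_sorted(genes, "genes")
  gene_space <- if (nrow(genes) > 0)
    GenomicRanges::reduce(as_granges0(genes), ignore.strand = TRUE)
  else GenomicRanges::GRanges()
  clip_window <- function(seq_id, start, end, anchor) {
    start <- max(start, 0)
    end <- min(end, chrom_lengths[[seq_id]])
    if (start >= end) return(NULL)
    win <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(start + 1, end))
    frag <- GenomicRanges::setdiff(win, gene_space, ignore.strand = TRUE)
    if (length(frag) == 0) return(NULL)
    fdf <- as_bed_df(frag)
    # keep the fragment touching the gene-adjacent bp
    keep <- fdf$start <= anchor & anchor < fdf$end
    if (!any(keep)) return(NULL)
    fdf[keep, c("seq_id", "start", "end"), drop = FALSE]
  }
  up <- list(); down <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    plus <- !identical(g$strand, "-")
    if (plus) {
      u <- clip_window(g$seq_id, g$start - size, g$start, g$start - 1)
      d <- clip_window(g$seq_id, g$end, g$end + size, g$end)
    } else {
      u <- clip_window(g$seq_id, g$end, g$end + size, g$end)
      d <- clip_window(g$seq_id, g$start - size, g$start, g$start - 1)
    }
    if (!is.null(u)) up[[length(up) + 1]] <- cbind(gene_id = g$gene_id, u)
    if (!is.null(d)) down[[length(down) + 1]] <- cbind(gene_id = g$gene_id, d)
  }
  empty <- data.frame(gene_id = character(), seq_id = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  list(upstream = if (length(up)) do.call(rbind, up) else empty,
       downstream = if (length(down)) do.call(rbind, down) else empty)
}

#' Odds ratio of NLR locus masking
#'
#' `OR = (NLRmasked / Genmasked) / (NLR / Gen)`: the masked density inside
#' NLR space relative to the genome-wide masked density. Only NLR loci
#' whose repeat overlap exceeds `min_overlap` bp (default 50, strict)
#' contribute to `NLRmasked`.
#'
#' @param nlr_loci interval data.frame of NLR loci (sorted within seq_id).
#' @param repeats repeat interval data.frame (sorted within seq_id).
#' @param genomes named character vector of genome sequences.
#' @param min_overlap minimum per-locus overlap in bp (strict, default 50).
#' @return list of class `nlr_masking_stats`: `NLRmasked`, `Genmasked`,
#'   `NLR`, `Gen` (all bp) and `OR`.
#' @export
nlr_masking_odds_ratio <- function(nlr_loci, repeats, genomes,
                                   min_overlap = 50) {
  Gen <- sum(genome_lengths(genomes))
  NLR <- total_interval_bp(nlr_loci)
  Genmasked <- total_interval_bp(merge_bed_df(repeats))
  if (Genmasked == 0 || NLR == 0) {
    stop("odds ratio undefined: Genmasked and NLR space must be positive")
  }
  ov <- intersect_overlap(nlr_loci, repeats, min_overlap = min_overlap + 1)
  NLRmasked <- sum(ov$per_feature$overlap_bp)
  OR <- (NLRmasked / Genmasked) / (NLR / Gen)
  structure(list(NLRmasked = NLRmasked, Genmasked = Genmasked,
                 NLR = NLR, Gen = Gen, OR = OR),
            class = "nlr_masking_stats")
}

#' @export
print.nlr_masking_stats <- function(x, ...) {
  cat(sprintf("NLRmasked=%g Genmasked=%g NLR=%g Gen=%g | OR = %.3f\n",
              x$NLRmasked, x$Genmasked, x$NLR, x$Gen, x$OR))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed the observed
#' table's. Degenerate margins give p = 1 (all-zero tables with a warning).
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`).
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (all(cells == 0)) {
    warning("all-zero table; p = 1")
    return(1)
  }
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values, same order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Domain enrichment among repeat-overlapped genes
#'
#' Genes whose repeat overlap strictly exceeds `min_overlap` bp form the
#' foreground; the whole gene-to-domain table is the background. For each
#' domain a 2x2 table of gene-level presence/absence (a gene carrying a
#' domain twice counts once) is tested with the Fisher exact test and
#' adjusted by Benjamini-Hochberg across all tested domains; domains with
#' `fdr < alpha` and odds ratio > 1 are flagged enriched.
#'
#' @param gene_overlaps data.frame with columns `gene_id` and `overlap_bp`
#'   (e.g. `$per_feature` from [intersect_overlap()] on gene intervals).
#' @param gene_domain_table data.frame mapping `gene_id` to `domain`
#'   accession (whole-proteome background).
#' @param min_overlap foreground threshold in bp (strict, default 50).
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame: `domain`, `a`, `b`, `c`, `d` (counts:
#'   domain-and-overlapping, domain-not-overlapping, other-overlapping,
#'   other-not), `odds_ratio`, `p`, `fdr`, `enriched`.
#' @export
domain_enrichment <- function(gene_overlaps, gene_domain_table,
                              min_overlap = 50, alpha = 0.05) {
  empty <- data.frame(domain = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p = numeric(), fdr = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE)
  fg <- unique(gene_overlaps$gene_id[gene_overlaps$overlap_bp > min_overlap])
  universe <- unique(gene_domain_table$gene_id)
  fg <- intersect(fg, universe)
  if (length(fg) == 0) {
    warning("no foreground genes exceed the overlap threshold")
    return(empty)
  }
  bg <- setdiff(universe, fg)
  domains <- sort(unique(gene_domain_table$domain))
  rows <- lapply(domains, function(dom) {
    with_dom <- unique(gene_domain_table$gene_id[
      gene_domain_table$domain == dom])
    a <- length(intersect(fg, with_dom))
    b <- length(intersect(bg, with_dom))
    cc <- length(fg) - a
    d <- length(bg) - b
    or <- if (a * d == 0 && b * cc == 0) {
      # degenerate table: equal presence rates mean no enrichment
      p1 <- if (a + cc > 0) a / (a + cc) else NA_real_
      p2 <- if (b + d > 0) b / (b + d) else NA_real_
      if (!is.na(p1) && !is.na(p2) && p1 == p2) 1 else NaN
    } else {
      (a * d) / (b * cc)
    }
    data.frame(domain = dom, a = a, b = b, c = cc, d = d,
               odds_ratio = or,
               p = fisher_exact_2x2(a, b, cc, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$enriched <- out$fdr < alpha & out$odds_ratio > 1 &
    !is.na(out$odds_ratio)
  out
}

#' Canonical k-mer census
#'
#' Counts canonical k-mers over a set of sequences and reports how many
#' distinct canonical words occur at least `min_count` times (the
#' jellyfish `count -C` / `dump -L` style census used on repeats in gene
#' flanks; typical `k` is 16, 21 or 31 with `min_count = 20`).
#'
#' @param sequences character vector of DNA strings.
#' @param k word size.
#' @param min_count census abundance threshold (default 20).
#' @return list: `$census` (number of canonical words with count
#'   `>= min_count`), `$table` (the full `kmer_table`).
#' @export
kmer_census <- function(sequences, k, min_count = 20) {
  stopifnot(k >= 1)
  seqs <- as.character(sequences)
  names(seqs) <- paste0("s", seq_along(seqs))
  table <- count_kmers(seqs, k)
  list(census = sum(table$counts >= min_count), table = table)
}
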