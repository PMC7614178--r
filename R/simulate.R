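# Synthetic genome simulator: an i.i.d. background at a given GC content
# with interspersed, independently mutated copies of random TE family
# consensus sequences (either strand), plus gene models, NLR loci and a
# gene-to-domain table, so every pipeline stage can be exercised and scored
# against a recorded truth without downloads. Copies replace background
# residues at non-overlapping positions, so planted-fraction bookkeeping is
# exact.

#' Simulation parameters
#'
#' Defaults describe the standard test genome: 1 Mbp, 5 TE families of 20
#' copies each, copy lengths 300-3000 bp, 2% substitution divergence and a
#' low single-bp indel rate.
#'
#' @param genome_length genome size in bp.
#' @param n_families number of TE families.
#' @param copies_per_family copies planted per family.
#' @param family_length_range consensus length range in bp.
#' @param substitution_rate per-bp substitution probability per copy.
#' @param indel_rate per-bp single-bp insertion/deletion probability.
#' @param n_genes number of protein-coding genes placed outside repeats.
#' @param n_te_genes number of genes placed overlapping planted repeats
#'   (carry a TE-associated domain, creating enrichment signal).
#' @param n_nlr number of NLR loci placed outside repeats.
#' @param nlr_length_range NLR locus length range in bp.
#' @param gc_content background GC fraction.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(genome_length = 1e6, n_families = 5,
                              copies_per_family = 20,
                              family_length_range = c(300, 3000),
                              substitution_rate = 0.02, indel_rate = 0.002,
                              n_genes = 100, n_te_genes = 0, n_nlr = 15,
                              nlr_length_range = c(2000, 5000),
                              gc_content = 0.4, seed = 42) {
  stopifnot(genome_length >= 1000, n_families >= 0, copies_per_family >= 0,
            length(family_length_range) == 2,
            family_length_range[1] <= family_length_range[2],
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            gc_content > 0, gc_content < 1, !is.null(seed))
  structure(as.list(environment()), class = "simulation_params")
}

sim_classes <- c("LTR/Gypsy", "LTR/Copia", "DNA/Mutator", "LINE/L1")

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitutions to a different base, then single-bp indels.
mutate_seq <- function(seq, sub_rate, indel_rate) {
  b <- chars(seq)
  n <- length(b)
  subs <- which(stats::runif(n) < sub_rate)
  if (length(subs) > 0) {
    b[subs] <- vapply(b[subs], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  }
  if (indel_rate > 0) {
    ev <- which(stats::runif(n) < indel_rate)
    if (length(ev) > 0) {
      del <- stats::runif(length(ev)) < 0.5
      out <- as.list(b)
      out[ev[del]] <- list(character(0))
      ins <- ev[!del]
      for (i in ins) out[[i]] <- c(b[i], sample(c("A", "C", "G", "T"), 1))
      b <- unlist(out)
    }
  }
  paste(b, collapse = "")
}

# Sample `length(widths)` non-overlapping placements with >= gap bp between
# them, within [margin, genome_length - margin].
place_nonoverlapping <- function(widths, genome_length, occupied = NULL,
                                 gap = 20, margin = 100, max_tries = 5000) {
  occ <- if (is.null(occupied)) IRanges::IRanges() else occupied
  starts <- numeric(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- floor(stats::runif(1, margin, genome_length - margin - w))
      cand <- IRanges::IRanges(s + 1 - gap, s + w + gap)
      if (IRanges::countOverlaps(cand, occ) == 0) {
        occ <- c(occ, IRanges::IRanges(s + 1, s + w))
        starts[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place all elements; genome too crowded")
  }
  list(starts = starts, occupied = occ)
}

#' Simulate a genome with planted TE families and annotation
#'
#' Produces, fully in memory (and optionally on disk), a genome FASTA, the
#' truth repeat BED, a classified truth library FASTA (`famN#Class`
#' headers), gene models in GFF3, NLR locus BED and a gene-to-domain
#' table. Identical seeds give identical outputs.
#'
#' @param params a [simulation_params()].
#' @param out_dir optional directory; when given, all components are
#'   written as plain-text files.
#' @return list: `$genome` (named character vector, one sequence `chr1`),
#'   `$repeats` (truth repeat data.frame with `family` column),
#'   `$library` (truth consensus library data.frame), `$genes`
#'   (`gene_features`), `$nlr` (interval data.frame), `$gene2dom`
#'   (data.frame `gene_id`, `domain`), `$planted_fraction`, `$params`.
#' @export
simulate_genome <- function(params = simulation_params(), out_dir = NULL) {
  set.seed(params$seed)
  L <- params$genome_length

  # family consensus sequences
  fam_len <- if (params$n_families > 0)
    floor(stats::runif(params$n_families, params$family_length_range[1],
                       params$family_length_range[2] + 1)) else integer(0)
  consensus <- vapply(fam_len, random_dna, character(1), gc = params$gc_content)
  fam_ids <- if (params$n_families > 0)
    paste0("fam", seq_len(params$n_families)) else character(0)
  fam_class <- rep_len(sim_classes, max(params$n_families, 1))[
    seq_len(params$n_families)]

  # mutated copies
  copies <- list()
  for (f in seq_len(params$n_families)) {
    for (cp in seq_len(params$copies_per_family)) {
      s <- mutate_seq(consensus[f], params$substitution_rate,
                      params$indel_rate)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") s <- revcomp(s)
      copies[[length(copies) + 1]] <-
        list(seq = s, family = fam_ids[f], te_class = fam_class[f],
             strand = strand)
    }
  }
  planted_bp <- sum(vapply(copies, function(x) nchar(x$seq), numeric(1)))
  if (planted_bp > 0.9 * L) {
    stop("requested repeat bp exceeds 90% of the genome length")
  }

  genome <- random_dna(L, params$gc_content)
  occupied <- IRanges::IRanges()
  repeats <- repeat_intervals()
  if (length(copies) > 0) {
    widths <- vapply(copies, function(x) nchar(x$seq), numeric(1))
    pl <- place_nonoverlapping(widths, L)
    occupied <- pl$occupied
    for (i in seq_along(copies)) {
      s <- pl$starts[i]
      substr(genome, s + 1, s + widths[i]) <- copies[[i]]$seq
    }
    repeats <- repeat_intervals(
      seq_id = rep("chr1", length(copies)),
      start = pl$starts, end = pl$starts + widths,
      te_class = vapply(copies, `[[`, character(1), "te_class"),
      strand = vapply(copies, `[[`, character(1), "strand"))
    repeats$family <- vapply(copies, `[[`, character(1), "family")
    ord <- order(repeats$start)
    repeats <- repeats[ord, , drop = FALSE]
    rownames(repeats) <- NULL
  }

  # genes: background genes clear of repeats, TE genes overlapping a copy
  n_bg <- params$n_genes
  n_te <- min(params$n_te_genes, nrow(repeats))
  gene_len <- floor(stats::runif(n_bg, 900, 3000))
  pl_g <- place_nonoverlapping(gene_len, L, occupied = occupied)
  gene_rows <- list(); exon_rows <- list(); g2d <- list()
  housekeeping <- c("PF00069", "PF00067", "PF00076", "PF03106", "PF00249")
  make_gene <- function(gid, gstart, glen, domain) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:3, 1)
    # partition the gene into exons separated by introns
    cuts <- sort(sample(seq(50, glen - 50, by = 10), 2 * n_ex - 2))
    bounds <- c(0, cuts, glen)
    ex_s <- bounds[seq(1, length(bounds), by = 2)]
    ex_e <- bounds[seq(2, length(bounds), by = 2)]
    list(gene = data.frame(gene_id = gid, seq_id = "chr1", start = gstart,
                           end = gstart + glen, strand = strand,
                           stringsAsFactors = FALSE),
         exons = data.frame(gene_id = gid, seq_id = "chr1",
                            start = gstart + ex_s, end = gstart + ex_e,
                            stringsAsFactors = FALSE),
         dom = data.frame(gene_id = gid, domain = domain,
                          stringsAsFactors = FALSE))
  }
  gi <- 0
  for (i in seq_len(n_bg)) {
    gi <- gi + 1
    g <- make_gene(sprintf("gene%03d", gi), pl_g$starts[i], gene_len[i],
                   sample(housekeeping, 1))
    gene_rows[[gi]] <- g$gene; exon_rows[[gi]] <- g$exons; g2d[[gi]] <- g$dom
  }
  if (n_te > 0) {
    host <- sample(seq_len(nrow(repeats)), n_te)
    for (j in seq_along(host)) {
      gi <- gi + 1
      r <- repeats[host[j], ]
      glen <- min(1500, (r$end - r$start) + 400)
      gstart <- max(0, r$start - 200)
      g <- make_gene(sprintf("gene%03d", gi), gstart,
                     min(glen, L - gstart - 1), "PF03184")
      gene_rows[[gi]] <- g$gene; exon_rows[[gi]] <- g$exons; g2d[[gi]] <- g$dom
    }
  }
  genes_df <- do.call(rbind, gene_rows)
  exons_df <- do.call(rbind, exon_rows)
  gene2dom <- do.call(rbind, g2d)
  ordg <- order(genes_df$start)
  genes <- structure(list(genes = genes_df[ordg, , drop = FALSE],
                          exons = exons_df), class = "gene_features")
  rownames(genes$genes) <- NULL

  # NLR loci clear of repeats (and of placed genes)
  nlr <- genomic_intervals()
  if (params$n_nlr > 0) {
    nlr_len <- floor(stats::runif(params$n_nlr, params$nlr_length_range[1],
                                  params$nlr_length_range[2]))
    pl_n <- place_nonoverlapping(nlr_len, L, occupied = pl_g$occupied)
    nlr <- genomic_intervals(seq_id = rep("chr1", params$n_nlr),
                             start = sort(pl_n$starts),
                             end = sort(pl_n$starts) +
                               nlr_len[order(pl_n$starts)])
  }

  library <- data.frame(lib_id = fam_ids, residues = unname(consensus),
                        length = fam_len, te_class = fam_class,
                        source_library = rep("truth", length(fam_ids)),
                        stringsAsFactors = FALSE)
  out <- list(genome = c(chr1 = genome), repeats = repeats,
              library = library, genes = genes, nlr = nlr,
              gene2dom = gene2dom,
              planted_fraction = planted_bp / L, params = params)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$genome, file.path(out_dir, "genome.fa"))
    write_bed(repeats, file.path(out_dir, "repeats.bed"))
    if (nrow(library) > 0) {
      write_library(library, file.path(out_dir, "library.fa"))
    }
    write_gff_genes(genes, file.path(out_dir, "genes.gff3"))
    write_bed(cbind(nlr, score = 0, te_class = "NLR"),
              file.path(out_dir, "nlr.bed"))
    utils::write.table(gene2dom, file.path(out_dir, "gene2dom.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Base-level recall, precision and F1 against truth intervals
#'
#' Computed on per-base sets: recall is the intersected bp over truth bp,
#' precision the intersected bp over called bp. An empty truth set is an
#' error; an empty call set reports precision 1 (with a warning) and
#' recall 0.
#'
#' @param called called repeat interval data.frame.
#' @param truth truth interval data.frame on the same genome.
#' @return named numeric vector `recall`, `precision`, `f1`.
#' @export
evaluate_against_truth <- function(called, truth) {
  if (total_interval_bp(truth) == 0) {
    stop("truth interval set is empty; recall undefined")
  }
  if (nrow(called) == 0) {
    warning("no called intervals; precision reported as 1")
    return(c(recall = 0, precision = 1, f1 = 0))
  }
  cg <- GenomicRanges::reduce(as_granges0(called), ignore.strand = TRUE)
  tg <- GenomicRanges::reduce(as_granges0(truth), ignore.strand = TRUE)
  inter <- sum(IRanges::width(GenomicRanges::intersect(cg, tg,
                                                       ignore.strand = TRUE)))
  recall <- inter / sum(IRanges::width(tg))
  precision <- inter / sum(IRanges::width(cg))
  f1 <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  c(recall = recall, precision = precision, f1 = f1)
}
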