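# Readers and writers for the formats the toolkit touches: FASTA, BED,
# GFF3 gene models and PAF alignments. Genomes are held as named character
# vectors so that residue case (the soft-masking state) survives a
# read/modify/write cycle.

#' Read a FASTA file into a named character vector
#'
#' The header token before the first whitespace becomes the sequence id; the
#' full header line is retained in the `"description"` attribute. Residue
#' case is preserved (lowercase encodes soft-masking). Gzip-compressed input
#' is handled transparently.
#'
#' @param path path to a FASTA file (optionally `.gz`).
#' @return named character vector of sequences, with a `description`
#'   attribute carrying the full headers.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(ss)
  names(seqs) <- ids
  attr(seqs, "description") <- stats::setNames(headers, ids)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path (gzip-compressed when it ends in `.gz`).
#' @param width line width for wrapping residues.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write repeat intervals to a BED file
#'
#' BED6 layout: `seq_id  start  end  te_class  score  strand`, 0-based
#' half-open. Round-trips losslessly through [read_bed()].
#'
#' @param intervals data.frame from [repeat_intervals()] (or any interval
#'   data frame; missing score/class/strand columns are filled with
#'   defaults).
#' @param path output path (gzip-compressed when it ends in `.gz`).
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  df <- intervals
  if (is.null(df$te_class)) df$te_class <- "UNANNOTATED"
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "."
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(df) > 0) {
    lines <- paste(df$seq_id, format(df$start, scientific = FALSE, trim = TRUE),
                   format(df$end, scientific = FALSE, trim = TRUE),
                   df$te_class, format(df$score, scientific = FALSE, trim = TRUE),
                   df$strand, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a BED file of (repeat) intervals
#'
#' Accepts 3- to 6-column BED; columns 4-6 populate `te_class`, `score`
#' and `strand` when present.
#'
#' @param path path to a BED file (optionally `.gz`).
#' @return data.frame as produced by [repeat_intervals()].
#' @export
read_bed <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(repeat_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop("BED line ", which(ncol < 3)[1], " has fewer than 3 columns")
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  repeat_intervals(seq_id = get(1, ""),
                   start = as.numeric(get(2, "0")),
                   end = as.numeric(get(3, "0")),
                   te_class = get(4, "UNANNOTATED"),
                   score = as.numeric(get(5, "0")),
                   strand = get(6, "."))
}

#' Read gene models from a GFF3 file
#'
#' One feature per gene. Exons are taken from a single transcript: the one
#' flagged canonical (a `canonical=1` attribute or an Ensembl_canonical tag)
#' or, absent a flag, the transcript with the largest summed exon length
#' (ties broken by transcript id). GFF 1-based closed coordinates are
#' converted to 0-based half-open.
#'
#' @param path path to a GFF3 file (optionally `.gz`).
#' @return list with class `gene_features`: `$genes`, a data.frame with
#'   columns `gene_id`, `seq_id`, `start`, `end`, `strand`; and `$exons`,
#'   a data.frame with columns `gene_id`, `seq_id`, `start`, `end`.
#' @export
read_gff_genes <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff$type <- as.character(gff$type)
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x)) as.character(x)[1] else NA_character_,
           character(1))
  }
  genes <- gff[gff$type == "gene", , drop = FALSE]
  tx <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  ex <- gff[gff$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path)
  tx$parent_gene <- first_parent(tx$Parent)
  ex$parent_tx <- first_parent(ex$Parent)

  is_canonical <- rep(FALSE, nrow(tx))
  if ("canonical" %in% names(gff)) {
    is_canonical <- !is.na(tx$canonical) & tx$canonical %in% c("1", "true", "TRUE")
  }
  if ("tag" %in% names(gff)) {
    tagged <- grepl("canonical", vapply(tx$tag, function(x)
      paste(as.character(x), collapse = ","), character(1)), ignore.case = TRUE)
    is_canonical <- is_canonical | tagged
  }

  gene_rows <- list()
  exon_rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- as.character(g$ID)
    g0 <- c(g$start - 1, g$end)
    gtx <- which(tx$parent_gene == gid)
    chosen_exons <- NULL
    if (length(gtx) > 0) {
      exlen <- vapply(gtx, function(j) {
        e <- ex[ex$parent_tx == as.character(tx$ID[j]), , drop = FALSE]
        sum(e$end - e$start + 1)
      }, numeric(1))
      canon <- gtx[is_canonical[gtx]]
      pick <- if (length(canon) > 0) canon[1] else {
        ord <- order(-exlen, as.character(tx$ID[gtx]))
        gtx[ord[1]]
      }
      chosen_exons <- ex[ex$parent_tx == as.character(tx$ID[pick]), ,
                         drop = FALSE]
    }
    if (is.null(chosen_exons) || nrow(chosen_exons) == 0) {
      chosen_exons <- data.frame(seqid = g$seqid, start = g$start, end = g$end)
    }
    if (any(chosen_exons$start < g$start | chosen_exons$end > g$end)) {
      stop("exon outside gene bounds for gene ", gid)
    }
    gene_rows[[i]] <- data.frame(gene_id = gid,
                                 seq_id = as.character(g$seqid),
                                 start = g0[1], end = g0[2],
                                 strand = as.character(g$strand),
                                 stringsAsFactors = FALSE)
    exon_rows[[i]] <- data.frame(gene_id = gid,
                                 seq_id = as.character(chosen_exons$seqid),
                                 start = chosen_exons$start - 1,
                                 end = chosen_exons$end,
                                 stringsAsFactors = FALSE)
  }
  structure(list(genes = do.call(rbind, gene_rows),
                 exons = do.call(rbind, exon_rows)),
            class = "gene_features")
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns; spans are 0-based half-open and an
#' `identity` column (`matches / block_len`) is added.
#'
#' @param path path to a PAF file (optionally `.gz`).
#' @return data.frame with columns `query_id`, `query_len`, `query_start`,
#'   `query_end`, `strand`, `target_id`, `target_len`, `target_start`,
#'   `target_end`, `matches`, `block_len`, `mapq`, `identity`.
#' @export
read_paf <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(query_id = character(), query_len = numeric(),
                      query_start = numeric(), query_end = numeric(),
                      strand = character(), target_id = character(),
                      target_len = numeric(), target_start = numeric(),
                      target_end = numeric(), matches = numeric(),
                      block_len = numeric(), mapq = numeric(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12)
  if (length(bad) > 0) {
    stop("PAF line ", bad[1], " has fewer than 12 columns")
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  num <- function(i) as.numeric(col(i))
  out <- data.frame(query_id = col(1), query_len = num(2),
                    query_start = num(3), query_end = num(4),
                    strand = col(5), target_id = col(6),
                    target_len = num(7), target_start = num(8),
                    target_end = num(9), matches = num(10),
                    block_len = num(11), mapq = num(12),
                    stringsAsFactors = FALSE)
  out$identity <- ifelse(out$block_len > 0, out$matches / out$block_len, 0)
  out
}

#' Write gene features to a GFF3 file
#'
#' Inverse of [read_gff_genes()] for the single-transcript gene models the
#' simulator produces; each gene gets one mRNA flagged `canonical=1`.
#'
#' @param features a `gene_features` list (`$genes`, `$exons`).
#' @param path output path.
#' @export
write_gff_genes <- function(features, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- features$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$seq_id[i], g$start[i] + 1, g$end[i], g$strand[i], gid),
               con)
    writeLines(sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;canonical=1",
                       g$seq_id[i], g$start[i] + 1, g$end[i], g$strand[i],
                       tid, gid), con)
    e <- features$exons[features$exons$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         e$seq_id[j], e$start[j] + 1, e$end[j], g$strand[i],
                         tid, j, tid), con)
    }
  }
  invisible(path)
}
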