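# Classification of de novo repeat calls against a classified repeat
# library. Only repeats longer than 90 bp are processed; each gets the
# class of its best library hit (ties: larger aligned span, then smallest
# lib_id) or stays UNANNOTATED.

#' Parse a TE classification from a library FASTA header
#'
#' The header is split at the FIRST `#`: left part is the library id, right
#' part the classification (which may itself contain `/` or further `#`).
#' Headers without a `#` are `"UNCLASSIFIED"`; a trailing `#` yields
#' `"UNCLASSIFIED"` with a warning.
#'
#' @param header FASTA header string (id token, without the `>`).
#' @return list with `lib_id` and `te_class`.
#' @export
parse_classification <- function(header) {
  stopifnot(nzchar(header))
  hash <- regexpr("#", header, fixed = TRUE)
  if (hash == -1) {
    return(list(lib_id = header, te_class = "UNCLASSIFIED"))
  }
  lib_id <- substr(header, 1, hash - 1)
  te_class <- substr(header, hash + 1, nchar(header))
  if (!nzchar(te_class)) {
    warning("header ends in '#', classification missing: ", header)
    te_class <- "UNCLASSIFIED"
  }
  list(lib_id = lib_id, te_class = te_class)
}

#' Read a classified repeat library from FASTA
#'
#' Headers follow the `id#Class/Subclass` convention; the text after the
#' first `#` becomes `te_class`.
#'
#' @param path path to a library FASTA (optionally `.gz`).
#' @param source_library tag recorded for provenance (default the file
#'   name).
#' @return data.frame with columns `lib_id`, `residues`, `length`,
#'   `te_class`, `source_library`.
#' @export
read_library <- function(path, source_library = basename(path)) {
  seqs <- read_fasta(path)
  parsed <- lapply(names(seqs), parse_classification)
  data.frame(lib_id = vapply(parsed, `[[`, character(1), "lib_id"),
             residues = unname(as.character(seqs)),
             length = unname(nchar(seqs)),
             te_class = vapply(parsed, `[[`, character(1), "te_class"),
             source_library = source_library,
             stringsAsFactors = FALSE)
}

#' Keep only repeats long enough to annotate
#'
#' Strictly longer than `min_len` bp (default 90): a 90 bp repeat is
#' excluded, a 91 bp repeat kept.
#'
#' @param repeats repeat interval data.frame.
#' @param min_len length threshold in bp.
#' @return filtered data.frame.
#' @export
filter_annotatable <- function(repeats, min_len = 90) {
  repeats[(repeats$end - repeats$start) > min_len, , drop = FALSE]
}

extract_interval_seq <- function(genomes, seq_id, start, end) {
  substr(genomes[[seq_id]], start + 1, end)
}

#' Annotate repeat calls against a classified library
#'
#' For every annotatable repeat (length > `min_len`), the repeat sequence
#' is aligned to the library; the best hit (maximal score, ties broken by
#' larger aligned span then lexicographically smallest `lib_id`) supplies
#' the classification. Repeats without a qualifying hit, and repeats below
#' the length cut-off, are reported `UNANNOTATED`.
#'
#' @param repeats repeat interval data.frame from the detector.
#' @param genomes named character vector of genome sequences.
#' @param library classified library data.frame (see [read_library()]).
#' @param min_len annotatable length threshold in bp (strict, default 90).
#' @param min_identity,min_span alignment acceptance thresholds
#'   (see [align_to_library()]).
#' @param paf optional data.frame from [read_paf()]: externally computed
#'   alignments (query names `seq_id:start-end`) used instead of the
#'   internal aligner.
#' @return data.frame: the repeat columns plus `best_target`, `identity`
#'   and `aligned_bp` (`best_target` is `NA` for unannotated repeats).
#' @export
annotate_repeats <- function(repeats, genomes, library, min_len = 90,
                             min_identity = 0.70, min_span = 90,
                             paf = NULL) {
  out <- repeats
  out$te_class <- "UNANNOTATED"
  out$best_target <- NA_character_
  out$identity <- NA_real_
  out$aligned_bp <- NA_real_
  if (nrow(out) == 0) return(out)
  annotatable <- which((out$end - out$start) > min_len)
  for (i in annotatable) {
    if (is.null(paf)) {
      rs <- extract_interval_seq(genomes, out$seq_id[i], out$start[i],
                                 out$end[i])
      hits <- align_to_library(rs, library, min_identity = min_identity,
                               min_span = min_span)
    } else {
      qname <- sprintf("%s:%d-%d", out$seq_id[i], out$start[i], out$end[i])
      hits <- paf_hits(paf, qname, library, min_identity, min_span)
    }
    if (nrow(hits) == 0) next
    best <- hits[1, ]
    out$te_class[i] <- best$te_class
    out$best_target[i] <- best$lib_id
    out$identity[i] <- best$identity
    out$aligned_bp[i] <- best$aligned_bp
  }
  out
}

# Alignments for one query from an external PAF, in align_to_library form.
paf_hits <- function(paf, qname, library, min_identity, min_span) {
  empty <- data.frame(lib_id = character(), te_class = character(),
                      strand = character(), identity = numeric(),
                      aligned_bp = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  rec <- paf[paf$query_id == qname, , drop = FALSE]
  if (nrow(rec) == 0) return(empty)
  cls <- library$te_class[match(rec$target_id, library$lib_id)]
  cls[is.na(cls)] <- "UNCLASSIFIED"
  out <- data.frame(lib_id = rec$target_id, te_class = cls,
                    strand = rec$strand, identity = rec$identity,
                    aligned_bp = rec$query_end - rec$query_start,
                    score = rec$matches, stringsAsFactors = FALSE)
  out <- out[out$identity >= min_identity & out$aligned_bp >= min_span, ,
             drop = FALSE]
  out[order(-out$score, -out$aligned_bp, out$lib_id), , drop = FALSE]
}

#' Annotated fraction of the genome and of the repeat space
#'
#' @param annotations data.frame from [annotate_repeats()].
#' @param genomes named character vector of genome sequences.
#' @return named numeric vector: `genome_fraction` (annotated repeat bp
#'   over genome bp) and `repeat_fraction` (annotated repeat bp over total
#'   repeat bp, annotatable or not). Zero repeat bp reports 0 with a
#'   warning.
#' @export
annotated_fraction <- function(annotations, genomes) {
  repeat_bp <- total_interval_bp(annotations)
  genome_bp <- sum(genome_lengths(genomes))
  if (repeat_bp == 0) {
    warning("no repeat bp; annotated fractions reported as 0")
    return(c(genome_fraction = 0, repeat_fraction = 0))
  }
  ann <- annotations[annotations$te_class != "UNANNOTATED", , drop = FALSE]
  annotated_bp <- total_interval_bp(ann)
  c(genome_fraction = annotated_bp / genome_bp,
    repeat_fraction = annotated_bp / repeat_bp)
}
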