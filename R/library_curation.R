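# Construction of a nonredundant, control-benchmarked repeat library from
# multiple source collections: merge with length bounds, cluster at 95%
# identity / 75% coverage of the shorter sequence, keep the longest member
# of each cluster as representative, and filter mixed TE/transcript
# clusters by library support and host-gene contamination. A Pfam-domain
# control benchmark (TE-associated positives, disease-resistance-gene
# negatives) summarises library quality as sensitivity and specificity.

#' Clustering parameters
#'
#' @param min_identity minimum percent identity for an edge (default 95).
#' @param min_coverage minimum percent coverage of the shorter sequence
#'   (default 75).
#' @param min_len,max_len admissible sequence length bounds in bp,
#'   inclusive (defaults 90 and 55000).
#' @return list of class `clustering_params`.
#' @export
clustering_params <- function(min_identity = 95, min_coverage = 75,
                              min_len = 90, max_len = 55000) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 100,
            min_len < max_len)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 min_len = min_len, max_len = max_len),
            class = "clustering_params")
}

#' Merge source repeat collections into one working set
#'
#' Sequences outside `[min_len, max_len]` bp (inclusive bounds) are
#' dropped; ids are prefixed with the source tag so they stay unique; a
#' per-source host-gene annotation table (TSV: id, 0/1 flag) marks entries
#' suspected to derive from cellular genes.
#'
#' @param sources data.frame with columns `path` (FASTA), `tag` (unique
#'   source label), `kind` (`"TE"` or `"transcript"`), and optionally
#'   `host_flags` (path to the flag table, `NA` for none).
#' @param params a [clustering_params()] supplying the length bounds.
#' @return data.frame with columns `lib_id`, `residues`, `length`,
#'   `te_class`, `source_library`, `kind`, `host_gene_flag`.
#' @export
merge_libraries <- function(sources, params = clustering_params()) {
  stopifnot(nrow(sources) >= 1,
            all(c("path", "tag", "kind") %in% names(sources)))
  if (anyDuplicated(sources$tag)) {
    stop("source tag collision: ",
         paste(unique(sources$tag[duplicated(sources$tag)]), collapse = ", "))
  }
  stopifnot(all(sources$kind %in% c("TE", "transcript")))
  parts <- lapply(seq_len(nrow(sources)), function(i) {
    lib <- read_library(sources$path[i], source_library = sources$tag[i])
    lib$kind <- sources$kind[i]
    lib$host_gene_flag <- FALSE
    if ("host_flags" %in% names(sources) && !is.na(sources$host_flags[i])) {
      fl <- utils::read.table(sources$host_flags[i], header = FALSE,
                              sep = "\t", stringsAsFactors = FALSE,
                              col.names = c("id", "flag"))
      lib$host_gene_flag <- lib$lib_id %in% fl$id[fl$flag != 0]
    }
    lib$lib_id <- paste0(sources$tag[i], ":", lib$lib_id)
    lib
  })
  out <- do.call(rbind, parts)
  out <- out[out$length >= params$min_len & out$length <= params$max_len, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster library sequences by identity and coverage
#'
#' An undirected edge joins two sequences when [pairwise_similarity()]
#' reaches both `min_identity` and `min_coverage`; clusters are the
#' connected components of that graph (singletons included). Deterministic
#' and invariant under input order.
#'
#' @param seqs merged library data.frame (see [merge_libraries()]).
#' @param params a [clustering_params()].
#' @return list of clusters; each a list with `member_ids` (sorted),
#'   `te_libraries_present`, `has_transcripts`, `host_gene_fraction`,
#'   `representative`.
#' @export
cluster_sequences <- function(seqs, params = clustering_params()) {
  stopifnot(nrow(seqs) >= 1)
  n <- nrow(seqs)
  ord <- order(seqs$lib_id)
  seqs <- seqs[ord, , drop = FALSE]
  edges <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        sim <- pairwise_similarity(seqs$residues[i], seqs$residues[j])
        if (sim[["identity"]] >= params$min_identity &&
            sim[["coverage"]] >= params$min_coverage) {
          edges[[length(edges) + 1]] <- c(seqs$lib_id[i], seqs$lib_id[j])
        }
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(seqs$lib_id)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  membership <- comp$membership[seqs$lib_id]
  lapply(sort(unique(membership)), function(m) {
    ids <- sort(names(membership)[membership == m])
    rows <- seqs[match(ids, seqs$lib_id), , drop = FALSE]
    list(member_ids = ids,
         te_libraries_present =
           sort(unique(rows$source_library[rows$kind == "TE"])),
         has_transcripts = any(rows$kind == "transcript"),
         host_gene_fraction = mean(rows$host_gene_flag),
         representative = pick_representative(ids, seqs))
  })
}

#' Pick the representative of a cluster
#'
#' The longest member; length ties go to the lexicographically smallest
#' `lib_id`.
#'
#' @param member_ids character vector of cluster member ids.
#' @param seqs merged library data.frame.
#' @return single `lib_id`.
#' @export
pick_representative <- function(member_ids, seqs) {
  stopifnot(length(member_ids) > 0)
  rows <- seqs[match(member_ids, seqs$lib_id), , drop = FALSE]
  rows$lib_id[order(-rows$length, rows$lib_id)][1]
}

#' Filter clusters into the nonredundant library
#'
#' TE-only clusters are kept unconditionally; transcript-only clusters are
#' dropped; mixed TE/transcript clusters are kept only when supported by at
#' least `min_libraries` distinct TE source libraries AND their host-gene
#' member fraction does not exceed `max_host_fraction` (default 0: no
#' member flagged as a potential host gene).
#'
#' @param clusters list from [cluster_sequences()].
#' @param min_libraries minimum distinct TE libraries for a mixed cluster
#'   (default 6).
#' @param max_host_fraction maximum host-gene member fraction for a mixed
#'   cluster (default 0).
#' @return the kept clusters (same structure).
#' @export
filter_clusters <- function(clusters, min_libraries = 6,
                            max_host_fraction = 0.0) {
  keep <- vapply(clusters, function(cl) {
    n_te <- length(cl$te_libraries_present)
    if (!cl$has_transcripts) return(n_te > 0)  # TE-only kept, if any TE
    if (n_te == 0) return(FALSE)               # transcript-only dropped
    n_te >= min_libraries && cl$host_gene_fraction <= max_host_fraction
  }, logical(1))
  clusters[keep]
}

#' Build the representative library from kept clusters
#'
#' @param clusters kept clusters (see [filter_clusters()]).
#' @param seqs merged library data.frame.
#' @return library data.frame of representatives (columns as
#'   [read_library()]), `te_class` inherited from each representative.
#' @export
cluster_representatives <- function(clusters, seqs) {
  reps <- vapply(clusters, `[[`, character(1), "representative")
  out <- seqs[match(reps, seqs$lib_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Six-frame translation of a DNA sequence
#'
#' Frames +1, +2, +3 on the sequence followed by +1, +2, +3 on its reverse
#' complement; standard genetic code, stops rendered `*`, trailing partial
#' codons dropped, ambiguous codons rendered `X`. Sequences shorter than
#' 3 bp yield six empty strings.
#'
#' @param seq DNA string.
#' @return character vector of six peptides.
#' @export
six_frame_translate <- function(seq) {
  s <- toupper(seq)
  L <- nchar(s)
  one_frame <- function(x, f) {
    n <- nchar(x) - f + 1
    if (n < 3) return("")
    len <- 3 * (n %/% 3)
    sub <- substr(x, f, f + len - 1)
    as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "X"))
  }
  if (L < 3) return(rep("", 6))
  rc <- revcomp(s)
  c(vapply(1:3, function(f) one_frame(s, f), character(1)),
    vapply(1:3, function(f) one_frame(rc, f), character(1)))
}

#' Control-domain confusion matrix for a library
#'
#' Compares the set of Pfam accessions found in the library with a positive
#' control list (domains expected in TEs) and a negative control list
#' (domains of disease-resistance genes): `TP = |positive & found|`,
#' `FN = |positive \ found|`, `FP = |negative & found|`,
#' `TN = |negative \ found|`. Overlap between the two control lists is
#' reported rather than resolved.
#'
#' @param found_domains character vector of accessions found.
#' @param positive_list,negative_list character vectors of control
#'   accessions (non-empty).
#' @return list of class `confusion_matrix`: `TP`, `FN`, `TN`, `FP`,
#'   `sensitivity`, `specificity` (2-dp rounded reporting values in
#'   `$report`), and `$control_overlap`.
#' @export
evaluate_controls <- function(found_domains, positive_list, negative_list) {
  if (length(positive_list) == 0 || length(negative_list) == 0) {
    stop("positive and negative control lists must be non-empty")
  }
  found <- unique(found_domains)
  pos <- unique(positive_list)
  neg <- unique(negative_list)
  overlap <- intersect(pos, neg)
  if (length(overlap) > 0) {
    warning("control lists overlap on: ", paste(overlap, collapse = ", "))
  }
  TP <- length(intersect(pos, found))
  FN <- length(setdiff(pos, found))
  FP <- length(intersect(neg, found))
  TN <- length(setdiff(neg, found))
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP,
                 sensitivity = sens, specificity = spec,
                 report = c(sensitivity = round(sens, 2),
                            specificity = round(spec, 2)),
                 control_overlap = overlap),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP=%d FN=%d TN=%d FP=%d | sensitivity %.2f specificity %.2f\n",
              x$TP, x$FN, x$TN, x$FP, x$report["sensitivity"],
              x$report["specificity"]))
  if (length(x$control_overlap) > 0) {
    cat("control lists overlap:", paste(x$control_overlap, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read a Pfam domain hit table
#'
#' Parses an hmmscan `--domtblout`-dialect table (whitespace- or
#' tab-separated): field 2 is the domain accession (field 1 when field 2 is
#' `-`), field 4 the query/library sequence id. Version suffixes are
#' stripped (`PF02892.12` becomes `PF02892`); `#` comment lines are
#' ignored.
#'
#' @param path path to the hit table (optionally `.gz`).
#' @return data.frame with columns `lib_id` and `accession` (unique pairs).
#' @export
read_domain_hits <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  empty <- data.frame(lib_id = character(), accession = character(),
                      stringsAsFactors = FALSE)
  if (!any(keep)) return(empty)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(lengths(fields) < 4)
  if (length(bad) > 0) {
    stop("malformed domain-hit line ", idx[bad[1]], " (fewer than 4 fields)")
  }
  acc <- vapply(fields, `[`, character(1), 2)
  name <- vapply(fields, `[`, character(1), 1)
  acc[acc == "-"] <- name[acc == "-"]
  acc <- sub("\\.\\d+$", "", acc)
  unique(data.frame(lib_id = vapply(fields, `[`, character(1), 4),
                    accession = acc, stringsAsFactors = FALSE))
}

#' End-to-end library curation
#'
#' Merge sources, cluster, filter, and extract representatives; when a
#' domain-hit table and control lists are supplied the control benchmark is
#' evaluated on the kept library.
#'
#' @param sources source table (see [merge_libraries()]).
#' @param params a [clustering_params()].
#' @param min_libraries,max_host_fraction mixed-cluster filters
#'   (see [filter_clusters()]).
#' @param domain_hits optional data.frame from [read_domain_hits()].
#' @param positive_list,negative_list optional control accession vectors.
#' @return list: `$library` (representative data.frame), `$clusters` (all),
#'   `$kept` (kept clusters), `$benchmark` (confusion matrix or `NULL`).
#' @export
curate_library <- function(sources, params = clustering_params(),
                           min_libraries = 6, max_host_fraction = 0.0,
                           domain_hits = NULL, positive_list = NULL,
                           negative_list = NULL) {
  seqs <- merge_libraries(sources, params)
  clusters <- cluster_sequences(seqs, params)
  kept <- filter_clusters(clusters, min_libraries, max_host_fraction)
  library <- cluster_representatives(kept, seqs)
  benchmark <- NULL
  if (!is.null(domain_hits) && !is.null(positive_list) &&
      !is.null(negative_list)) {
    found <- unique(domain_hits$accession[domain_hits$lib_id %in%
                                            library$lib_id])
    benchmark <- evaluate_controls(found, positive_list, negative_list)
  }
  list(library = library, clusters = clusters, kept = kept,
       benchmark = benchmark)
}

#' Write a classified library to FASTA
#'
#' Headers follow the `id#Class/Subclass` convention.
#'
#' @param library library data.frame.
#' @param path output path.
#' @export
write_library <- function(library, path) {
  seqs <- library$residues
  names(seqs) <- paste0(library$lib_id, "#", library$te_class)
  write_fasta(seqs, path)
}
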