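#' Read an expression matrix from a TSV file
#'
#' Expects a header row of sample ids and a first column of gene ids; the
#' body must be fully numeric. Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  genes <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body), dimnames = list(NULL, colnames(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop_tfmapr(sprintf("non-numeric expression cell at gene '%s', sample '%s' (value '%s')",
                        genes[bad[1L, 1L]], colnames(body)[bad[1L, 2L]],
                        body[bad[1L, 1L], bad[1L, 2L]]))
  }
  rownames(num) <- genes
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#' @param expr An expression matrix.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a perturbation map from TSV
#'
#' Columns: `sample`, `perturbed_tf`, `mechanism`, optional `time_point`.
#' @param path Path to a tab-separated file.
#' @return A [perturbation_map()].
#' @export
load_perturbation_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  tp <- if ("time_point" %in% names(df)) as.numeric(df$time_point) else rep(NA_real_, nrow(df))
  ptf <- df$perturbed_tf
  ptf[ptf %in% c("", "NA", ".")] <- NA_character_
  perturbation_map(df$sample, ptf, df$mechanism, tp)
}

#' Write a perturbation map to TSV
#' @param pmap A perturbation map.
#' @param path Output path.
#' @export
write_perturbation_map <- function(pmap, path) {
  utils::write.table(pmap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a (TF, gene, score) edge list into a dense network
#'
#' Unmentioned (TF, gene) pairs over the union of ids are filled with 0.
#' Self-edges are dropped with a warning: a TF is never allowed to regulate
#' itself.
#'
#' @param path Path to a tab-separated file with columns (tf, gene, score);
#'   a header row is detected and skipped if its third field is non-numeric.
#' @param kind `"weighted"` (real scores) or `"binary"` (labels must be 0/1).
#' @return A weighted or binary network.
#' @export
load_edge_list <- function(path, kind = c("weighted", "binary")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 3L) stop_tfmapr("edge list needs 3 columns (tf, gene, score)")
  if (is.character(df[[3L]]) && is.na(suppressWarnings(as.numeric(df[1L, 3L])))) {
    df <- df[-1L, , drop = FALSE]
  }
  tf <- as.character(df[[1L]]); gene <- as.character(df[[2L]])
  score <- suppressWarnings(as.numeric(df[[3L]]))
  if (any(is.na(score))) stop_tfmapr("non-numeric score in edge list: ", path)
  if (kind == "binary" && !all(score %in% c(0, 1))) {
    stop_tfmapr("binary edge list contains a score other than 0/1: ",
                format(score[!(score %in% c(0, 1))][1L]))
  }
  self <- tf == gene
  if (any(self)) {
    warning(sprintf("dropping %d self-edge(s) (e.g. %s -> %s): a TF may not regulate itself",
                    sum(self), tf[self][1L], tf[self][1L]), call. = FALSE)
    tf <- tf[!self]; gene <- gene[!self]; score <- score[!self]
  }
  tfs <- sort(unique(tf)); genes <- sort(unique(gene))
  m <- matrix(0, nrow = length(tfs), ncol = length(genes),
              dimnames = list(tfs, genes))
  m[cbind(tf, gene)] <- score
  if (kind == "binary") binary_network(m) else weighted_network(m)
}

#' Write a network as a (TF, gene, score) edge list
#'
#' Edges are sorted lexicographically by (tf, gene); self-edges and missing
#' scores are omitted; scores are formatted to 6 significant digits.
#'
#' @param network A weighted or binary network.
#' @param path Output path.
#' @param keep_zero Keep zero-score edges (default TRUE, so dense round-trips
#'   are exact).
#' @export
write_edge_list <- function(network, path, keep_zero = TRUE) {
  idx <- which(!is.na(network), arr.ind = TRUE)
  tf <- rownames(network)[idx[, 1L]]
  gene <- colnames(network)[idx[, 2L]]
  score <- network[idx]
  if (!keep_zero) {
    keep <- score != 0
    tf <- tf[keep]; gene <- gene[keep]; score <- score[keep]
  }
  ord <- order(tf, gene, method = "radix")
  lines <- paste(tf[ord], gene[ord], format_score(score[ord]), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Merge per-technology binding-label networks with fixed precedence
#'
#' For TFs profiled by more than one binding technology, labels are taken
#' from exactly one source: a Calling Cards experiment if there is one,
#' otherwise a ChIP-Exo experiment, otherwise the base (ChIP-Chip-style
#' curated) network. The output records which source supplied each TF's row.
#'
#' @param base Binary network of curated/ChIP-Chip-style labels (may be NULL).
#' @param callingcards Binary network of Calling Cards labels (may be NULL).
#' @param chipexo Binary network of ChIP-Exo labels (may be NULL).
#' @return A binary network over the intersection of the gene universes, with
#'   one row per TF present in any source and a per-TF `source` tag.
#' @export
merge_binding_sources <- function(base = NULL, callingcards = NULL, chipexo = NULL) {
  inputs <- list(callingcards = callingcards, chipexo = chipexo, base = base)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  if (length(inputs) == 0L) stop_tfmapr("at least one binding source required")
  genes <- Reduce(intersect, lapply(inputs, colnames))
  if (length(genes) == 0L) stop_tfmapr("binding sources share no genes")
  genes <- sort(genes)
  tfs <- sort(unique(unlist(lapply(inputs, rownames))))
  m <- matrix(NA_real_, length(tfs), length(genes), dimnames = list(tfs, genes))
  src <- stats::setNames(rep(NA_character_, length(tfs)), tfs)
  # precedence: callingcards > chipexo > base (list order above)
  for (name in names(inputs)) {
    net <- inputs[[name]]
    take <- setdiff(rownames(net), tfs[!is.na(src)])
    if (length(take) > 0) {
      m[take, ] <- net[take, genes]
      src[take] <- name
    }
  }
  m[is.na(m)] <- 0
  binary_network(m, source = src)
}

#' Read a gene-to-term annotation table
#'
#' @param path Two-column TSV (gene, term), no header required; a header row
#'   is skipped if present.
#' @return An [annotation_map()].
#' @export
load_annotation <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  if (identical(tolower(df[1L, 1L]), "gene")) df <- df[-1L, , drop = FALSE]
  annotation_map(split(as.character(df[[2L]]), as.character(df[[1L]])))
}

#' Read a STRING-style protein-interaction table
#'
#' @param path TSV with columns (proteinA, proteinB, score); header detected.
#' @param scale `"unit"` when scores are already in \[0,1\], `"string1000"`
#'   for STRING exports whose combined score runs 0-1000.
#' @return An [interaction_table()].
#' @export
load_interactions <- function(path, scale = c("unit", "string1000")) {
  scale <- match.arg(scale)
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  if (is.na(suppressWarnings(as.numeric(df[1L, 3L])))) df <- df[-1L, , drop = FALSE]
  score <- as.numeric(df[[3L]])
  if (scale == "string1000") score <- score / 1000
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop_tfmapr("interaction score outside [0, 1] after scaling")
  }
  interaction_table(df[[1L]], df[[2L]], score)
}

#' Write an interaction table to TSV (unit scale)
#' @param table An interaction table.
#' @param path Output path.
#' @export
write_interactions <- function(table, path) {
  keys <- names(table$scores)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  ord <- order(a, b, method = "radix")
  writeLines(paste(a[ord], b[ord], format_score(unname(table$scores)[ord]),
                   sep = "\t"), path)
  invisible(path)
}

#' Read promoters from a FASTA file
#' @param path FASTA path; record ids are gene ids.
#' @return A [promoter_set()].
#' @export
load_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  promoter_set(seqs)
}

#' Write promoters to FASTA
#' @param promoters A promoter set.
#' @param path Output path.
#' @export
write_promoters <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(unclass(promoters))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Extract promoters from a genome FASTA and GFF3 annotation
#'
#' Takes `upstream` bases 5' of each feature's start (strand-aware; GFF3
#' coordinates are 1-based inclusive), clipped at contig boundaries.
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param gff3 Path to a GFF3 file; features of type `feature_type` are used
#'   and gene ids taken from the `ID=` attribute.
#' @param upstream Promoter length in bases (default 500).
#' @param feature_type GFF3 feature type to extract around (default "gene").
#' @return A [promoter_set()].
#' @export
extract_promoters <- function(genome_fasta, gff3, upstream = 500,
                              feature_type = "gene") {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  lines <- readLines(gff3)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[vapply(fields, length, 0L) >= 9L]
  out <- character(0)
  for (f in fields) {
    if (f[3L] != feature_type) next
    id <- sub("^.*ID=([^;]+).*$", "\\1", f[9L])
    contig <- f[1L]
    if (!contig %in% names(genome)) next
    clen <- Biostrings::width(genome[contig])
    start <- as.integer(f[4L]); end <- as.integer(f[5L]); strand <- f[7L]
    if (identical(strand, "-")) {
      from <- min(end + 1L, clen); to <- min(end + upstream, clen)
      if (from > to) next
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[contig]], from, to)))
    } else {
      from <- max(1L, start - upstream); to <- start - 1L
      if (to < from) next
      seq <- as.character(Biostrings::subseq(genome[[contig]], from, to))
    }
    out[id] <- seq
  }
  promoter_set(out)
}
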