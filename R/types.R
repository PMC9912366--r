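#' Domain containers for TF network mapping
#'
#' The package passes data between modules in a small set of validated
#' containers:
#'
#' * **expression matrix** — numeric genes x samples matrix (log2 scale),
#'   built by [expression_matrix()].
#' * **perturbation map** — data frame linking each sample to the TF that was
#'   perturbed in it and the mechanism, built by [perturbation_map()].
#' * **weighted network** — numeric TFs x genes score matrix where larger
#'   magnitude means stronger evidence for a regulatory edge; the universal
#'   currency of features and predictions. Self-edges (a TF scoring its own
#'   gene) are held as `NA` and never ranked. Built by [weighted_network()].
#' * **binary network** — 0/1 binding labels on the same axes, with a per-TF
#'   source tag recording which binding technology the labels came from.
#'   Built by [binary_network()].
#'
#' @name tfmapr-types
NULL

#' Construct a validated expression matrix
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty dimnames. Values are expected on a log2 scale.
#' @return The matrix with class `"expr_matrix"`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_tfmapr("expression values must be a numeric matrix")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop_tfmapr("expression matrix needs gene rownames and sample colnames")
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop_tfmapr("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  dup <- unique(samples[duplicated(samples)])
  if (length(dup) > 0) {
    stop_tfmapr("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  }
  if (ncol(values) < 2L) stop_tfmapr("expression matrix needs at least 2 samples")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_tfmapr(sprintf("non-finite expression value at gene '%s', sample '%s'",
                        genes[bad[1L]], samples[bad[2L]]))
  }
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Construct a perturbation map
#'
#' Describes, for every sample of a companion expression matrix, which TF was
#' perturbed and how. Samples with mechanism `"none"` are the unperturbed
#' controls against which fold-changes are computed.
#'
#' @param sample Character vector of sample ids.
#' @param perturbed_tf Character vector of perturbed TF gene ids (`NA` for
#'   controls).
#' @param mechanism One of `"deletion"`, `"overexpression"`, `"none"` per
#'   sample.
#' @param time_point Optional numeric minutes (NA when not a time course).
#' @return A data frame with class `"perturbation_map"`.
#' @export
perturbation_map <- function(sample, perturbed_tf, mechanism,
                             time_point = rep(NA_real_, length(sample))) {
  mechanism <- match.arg(mechanism, c("deletion", "overexpression", "none"),
                         several.ok = TRUE)
  if (length(mechanism) == 1L) mechanism <- rep(mechanism, length(sample))
  if (length(sample) != length(perturbed_tf) ||
      length(sample) != length(mechanism) ||
      length(sample) != length(time_point)) {
    stop_tfmapr("perturbation map columns must have equal length")
  }
  if (anyDuplicated(sample)) stop_tfmapr("duplicate sample ids in perturbation map")
  if (!any(mechanism == "none")) {
    stop_tfmapr("perturbation map must contain at least one control sample (mechanism 'none')")
  }
  pm <- data.frame(sample = as.character(sample),
                   perturbed_tf = as.character(perturbed_tf),
                   mechanism = mechanism,
                   time_point = as.numeric(time_point),
                   stringsAsFactors = FALSE)
  class(pm) <- c("perturbation_map", class(pm))
  pm
}

# Shared axis validation for score/label matrices.
check_network_axes <- function(scores) {
  tfs <- rownames(scores)
  genes <- colnames(scores)
  if (is.null(tfs) || is.null(genes)) {
    stop_tfmapr("network matrix needs TF rownames and gene colnames")
  }
  if (anyDuplicated(tfs)) stop_tfmapr("duplicate TF ids in network")
  if (anyDuplicated(genes)) stop_tfmapr("duplicate gene ids in network")
  invisible(NULL)
}

#' Construct a weighted network
#'
#' A real-valued score for every (TF, gene) pair. A TF is never allowed to
#' regulate itself: whenever a TF id also appears among the gene columns, the
#' (tf, tf) cell is forced to `NA` and excluded from all downstream ranking.
#'
#' @param scores Numeric matrix, TFs x genes, with dimnames.
#' @return The matrix with class `"weighted_network"`.
#' @export
weighted_network <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop_tfmapr("network scores must be a numeric matrix")
  }
  check_network_axes(scores)
  common <- intersect(rownames(scores), colnames(scores))
  if (length(common) > 0) scores[cbind(common, common)] <- NA_real_
  if (any(is.infinite(scores))) stop_tfmapr("network scores must be finite or NA")
  structure(scores, class = c("weighted_network", "matrix"))
}

#' Construct a binary binding-label network
#'
#' @param labels Matrix of 0/1 labels, TFs x genes, with dimnames.
#' @param source Character scalar or named per-TF vector tagging the binding
#'   technology each row's labels came from (e.g. `"callingcards"`,
#'   `"chipexo"`, `"base"`).
#' @return The matrix with class `"binary_network"` and a `source` attribute.
#' @export
binary_network <- function(labels, source = "base") {
  if (!is.matrix(labels)) stop_tfmapr("labels must be a matrix")
  check_network_axes(labels)
  storage.mode(labels) <- "double"
  common <- intersect(rownames(labels), colnames(labels))
  if (length(common) > 0) labels[cbind(common, common)] <- NA_real_
  vals <- labels[!is.na(labels)]
  if (!all(vals %in% c(0, 1))) {
    stop_tfmapr("binding labels must be 0 or 1; found value ",
                format(vals[!(vals %in% c(0, 1))][1L]))
  }
  tfs <- rownames(labels)
  if (length(source) == 1L && is.null(names(source))) {
    source <- stats::setNames(rep(source, length(tfs)), tfs)
  }
  if (!all(tfs %in% names(source))) {
    stop_tfmapr("every TF needs a source tag")
  }
  structure(labels, source = source[tfs], class = c("binary_network", "matrix"))
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted network: %d TFs x %d genes; %d non-missing scores\n",
              nrow(x), ncol(x), sum(!is.na(x))))
  invisible(x)
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary network: %d TFs x %d genes; %d positive labels\n",
              nrow(x), ncol(x), sum(x == 1, na.rm = TRUE)))
  invisible(x)
}

#' Per-TF source tags of a binary network
#' @param labels A binary network.
#' @return Named character vector, one tag per TF.
#' @export
label_sources <- function(labels) attr(labels, "source")

#' Construct an annotation map (gene -> functional terms)
#'
#' @param gene_terms Named list mapping gene id to a character vector of term
#'   ids (e.g. GO biological process terms).
#' @return List with class `"annotation_map"`: `gene_terms` plus `term_sizes`,
#'   the number of annotated genes per term in the full annotation.
#' @export
annotation_map <- function(gene_terms) {
  if (is.null(names(gene_terms)) || anyDuplicated(names(gene_terms))) {
    stop_tfmapr("gene_terms must be a uniquely named list")
  }
  gene_terms <- lapply(gene_terms, function(x) unique(as.character(x)))
  term_sizes <- table(unlist(gene_terms, use.names = FALSE))
  structure(list(gene_terms = gene_terms,
                 term_sizes = stats::setNames(as.integer(term_sizes),
                                              names(term_sizes))),
            class = "annotation_map")
}

#' Construct a protein-interaction table
#'
#' Holds symmetric pairwise interaction confidences on the unit scale, as
#' exported from STRING-style databases. Self-pairs are dropped; duplicate
#' unordered pairs keep the maximum confidence.
#'
#' @param a,b Character vectors of interacting protein ids.
#' @param score Numeric confidences in \[0, 1\].
#' @return List with class `"interaction_table"`.
#' @export
interaction_table <- function(a, b, score) {
  a <- as.character(a); b <- as.character(b); score <- as.numeric(score)
  if (length(a) != length(b) || length(a) != length(score)) {
    stop_tfmapr("interaction columns must have equal length")
  }
  if (any(score < 0 | score > 1, na.rm = TRUE) || any(!is.finite(score))) {
    stop_tfmapr("interaction scores must be finite and within [0, 1]")
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  score <- if (length(key) > 0) {
    s <- tapply(score, key, max)
    stats::setNames(as.numeric(s), names(s))
  } else stats::setNames(numeric(0), character(0))
  structure(list(scores = score), class = "interaction_table")
}

#' Look up interaction confidence for a protein pair
#' @param table An interaction table.
#' @param a,b Protein ids.
#' @return Confidence in \[0, 1\]; 0 when the pair is absent or a self-pair.
#' @export
interaction_score <- function(table, a, b) {
  if (length(table$scores) == 0L) return(rep(0, length(a)))
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  out <- unname(table$scores[key])
  out[is.na(out)] <- 0
  out[a == b] <- 0
  out
}

#' Construct a promoter set
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet` of
#'   promoter sequences keyed by gene id. Sequences are uppercased; only
#'   A, C, G, T, N are allowed.
#' @return Named character vector with class `"promoter_set"`.
#' @export
promoter_set <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop_tfmapr("promoters must be uniquely named by gene id")
  }
  sequences <- stats::setNames(toupper(as.character(sequences)),
                               names(sequences))
  if (any(nchar(sequences) == 0L)) stop_tfmapr("empty promoter sequence")
  if (any(grepl("[^ACGTN]", sequences))) {
    stop_tfmapr("promoter sequences may only contain A, C, G, T, N")
  }
  structure(sequences, class = "promoter_set")
}
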