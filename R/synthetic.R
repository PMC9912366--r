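# Planted-truth benchmark generator. Emulates the structure of a
# TF-perturbation compendium: one perturbation per sample, a sparse signed
# regulatory network, promoters carrying planted motifs for true targets,
# and noisy binary binding labels — so the whole mapping pipeline can be
# exercised and scored against a known ground truth without any downloads.

#' Synthetic benchmark configuration
#'
#' Defaults define the package's reference benchmark: 50 TFs regulating a
#' 500-gene genome, about 20 targets per TF, unit-magnitude signed effects,
#' one knockout sample per TF (expression shift -2 in log2) plus controls,
#' observation noise 0.5 SD, and binding labels that miss 30% of true edges
#' (false-negative rate 0.3) while adding spurious positives at rate 0.01.
#'
#' @param n_tfs Number of TFs (default 50).
#' @param n_genes Number of genes, TFs included (default 500).
#' @param targets_per_tf Mean of the Poisson out-degree distribution
#'   (default 20).
#' @param effect_mean,effect_sd Magnitude distribution of planted regulatory
#'   effects, sign drawn +/- with equal probability (default N(1, 0.25)).
#' @param noise_sd Observation noise SD in log2 units (default 0.5).
#' @param mechanism `"deletion"` (sets the perturbed TF's log2 level to 0)
#'   or `"overexpression"` (sets it to `perturbation_shift`).
#' @param perturbation_shift Log2 level of an overexpressed TF (default 2).
#' @param n_controls Control samples (default 3).
#' @param n_timepoints Samples per perturbed TF (default 1; >1 emulates a
#'   time course where later time points respond more strongly).
#' @param fp_rate,fn_rate Binding-label false-positive/false-negative rates
#'   (defaults 0.01 and 0.3).
#' @param motif_length Planted motif length (default 8).
#' @param motif_planting_rate Fraction of true targets whose promoter
#'   carries the TF's motif (default 0.8).
#' @param promoter_length Promoter length in bases (default 500).
#' @param n_complexes TF pairs given overlapping target sets and a strong
#'   interaction, so the PPI metric has signal (default 5).
#' @param seed Integer seed.
#' @return List with class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_tfs = 50L, n_genes = 500L,
                             targets_per_tf = 20,
                             effect_mean = 1, effect_sd = 0.25,
                             noise_sd = 0.5,
                             mechanism = c("deletion", "overexpression"),
                             perturbation_shift = 2,
                             n_controls = 3L, n_timepoints = 1L,
                             fp_rate = 0.01, fn_rate = 0.3,
                             motif_length = 8L, motif_planting_rate = 0.8,
                             promoter_length = 500L,
                             n_complexes = 5L, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (n_tfs >= n_genes) stop_tfmapr("n_tfs must be < n_genes")
  if (fp_rate < 0 || fp_rate > 1 || fn_rate < 0 || fn_rate > 1) {
    stop_tfmapr("label noise rates must be in [0, 1]")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

synthetic_ids <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  list(genes = genes, tfs = genes[seq_len(cfg$n_tfs)])
}

#' Simulate the planted regulatory network
#'
#' Each TF regulates a Poisson-distributed number of targets drawn uniformly
#' from the other genes; effects are signed with magnitude ~
#' N(effect_mean, effect_sd). Self-edges are never planted. TF pairs chosen
#' as "complexes" share 80% of their target sets.
#'
#' @param cfg A [synthetic_config()].
#' @return List with class `"ground_truth"`: `network` (signed weighted
#'   network), `motifs` (named per-TF consensus strings), `complexes`
#'   (2-column matrix of TF pairs), and `config`.
#' @export
simulate_ground_truth <- function(cfg = synthetic_config()) {
  ids <- synthetic_ids(cfg)
  with_local_seed(cfg$seed, {
    m <- matrix(0, cfg$n_tfs, cfg$n_genes, dimnames = list(ids$tfs, ids$genes))
    for (tf in ids$tfs) {
      k <- max(1L, stats::rpois(1L, cfg$targets_per_tf))
      k <- min(k, cfg$n_genes - 1L)
      targets <- sample(setdiff(ids$genes, tf), k)
      mag <- abs(stats::rnorm(k, cfg$effect_mean, cfg$effect_sd))
      m[tf, targets] <- mag * sample(c(-1, 1), k, replace = TRUE)
    }
    complexes <- NULL
    if (cfg$n_complexes > 0 && cfg$n_tfs >= 2L * cfg$n_complexes) {
      picked <- sample(ids$tfs, 2L * cfg$n_complexes)
      complexes <- matrix(picked, ncol = 2L, byrow = TRUE)
      for (i in seq_len(nrow(complexes))) {
        a <- complexes[i, 1L]; b <- complexes[i, 2L]
        # partner b inherits 80% of a's targets (plus its own extras)
        ta <- ids$genes[m[a, ] != 0]
        share <- sample(ta, max(1L, round(0.8 * length(ta))))
        share <- setdiff(share, b)
        mag <- abs(stats::rnorm(length(share), cfg$effect_mean, cfg$effect_sd))
        m[b, share] <- mag * sign(m[a, share])
      }
    }
    motifs <- vapply(ids$tfs, function(tf) {
      paste(sample(c("A", "C", "G", "T"), cfg$motif_length, replace = TRUE),
            collapse = "")
    }, "")
  })
  structure(list(network = weighted_network(m), motifs = motifs,
                 complexes = complexes, config = cfg),
            class = "ground_truth")
}

#' Simulate perturbation-response expression from a planted network
#'
#' Gene baselines are drawn N(0, 1) in log2 units. Each TF gets
#' `n_timepoints` perturbation samples: a deletion sets the TF's own log2
#' level to 0, an overexpression to `+perturbation_shift`; the TF-level
#' change `delta = new level - baseline` then shifts each target gene by
#' `effect(tf, gene) x delta`. N(0, noise_sd) observation noise is added to
#' every value. Controls carry baseline plus noise only. Note that under
#' deletion the response strength varies across TFs with their baseline
#' level — TFs sitting near baseline 0 barely move, as in real knockout
#' compendia where lowly expressed TFs yield weak signatures.
#'
#' @param truth A `"ground_truth"`.
#' @param cfg Defaults to `truth$config`.
#' @return List: `expr` (expression matrix) and `pmap` (perturbation map).
#' @export
simulate_expression <- function(truth, cfg = truth$config) {
  ids <- synthetic_ids(cfg)
  net <- unclass(truth$network)
  samples <- c(paste0("ctrl", seq_len(cfg$n_controls)),
               unlist(lapply(ids$tfs, function(tf) {
                 paste0(tf, "_p", seq_len(cfg$n_timepoints))
               })))
  with_local_seed(derive_seed(cfg$seed, 2L), {
    baseline <- stats::rnorm(cfg$n_genes, 0, 1)
    names(baseline) <- ids$genes
    m <- matrix(baseline, cfg$n_genes, length(samples),
                dimnames = list(ids$genes, samples))
    ptf <- rep(NA_character_, length(samples))
    mech <- rep("none", length(samples))
    tpt <- rep(NA_real_, length(samples))
    col <- cfg$n_controls
    for (tf in ids$tfs) {
      eff <- net[tf, ]
      eff[is.na(eff)] <- 0
      new_level <- if (cfg$mechanism == "deletion") 0 else cfg$perturbation_shift
      delta <- new_level - baseline[tf]
      for (tp in seq_len(cfg$n_timepoints)) {
        col <- col + 1L
        # later time points respond at full strength, earlier ones weaker
        frac <- tp / cfg$n_timepoints
        m[, col] <- m[, col] + eff * delta * frac
        m[tf, col] <- baseline[tf] + delta * frac
        ptf[col] <- tf
        mech[col] <- cfg$mechanism
        tpt[col] <- if (cfg$n_timepoints > 1L) 15 * tp else NA_real_
      }
    }
    if (cfg$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd), nrow(m))
    }
  })
  list(expr = expression_matrix(m),
       pmap = perturbation_map(samples, ptf, mech, tpt))
}

#' Simulate noisy binary binding labels from the planted network
#'
#' Every planted edge is labeled 1 with probability `1 - fn_rate`; every
#' non-edge is labeled 1 with probability `fp_rate` — the synthetic analogue
#' of binding-location experiments that miss real sites and report
#' non-functional ones.
#'
#' @param truth A `"ground_truth"`.
#' @param fp_rate,fn_rate Override the config rates.
#' @param seed Override the config seed.
#' @return A binary network with source tag `"synthetic"`.
#' @export
simulate_binding_labels <- function(truth,
                                    fp_rate = truth$config$fp_rate,
                                    fn_rate = truth$config$fn_rate,
                                    seed = derive_seed(truth$config$seed, 3L)) {
  net <- unclass(truth$network)
  with_local_seed(seed, {
    u <- matrix(stats::runif(length(net)), nrow(net))
    lab <- ifelse(!is.na(net) & net != 0,
                  as.numeric(u > fn_rate),
                  as.numeric(u < fp_rate))
    lab[is.na(net)] <- NA_real_
  })
  dimnames(lab) <- dimnames(net)
  binary_network(lab, source = "synthetic")
}

#' Simulate promoter sequences with planted motifs
#'
#' Promoters are uniform-random sequences; each true target of a TF carries
#' that TF's planted motif at a uniform position with probability
#' `motif_planting_rate`.
#'
#' @param truth A `"ground_truth"`.
#' @param cfg Defaults to `truth$config`.
#' @return A [promoter_set()] covering all genes.
#' @export
simulate_promoters <- function(truth, cfg = truth$config) {
  ids <- synthetic_ids(cfg)
  net <- unclass(truth$network)
  L <- cfg$promoter_length
  with_local_seed(derive_seed(cfg$seed, 4L), {
    seqs <- vapply(ids$genes, function(g) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    # genes regulated by several TFs carry several motifs; plantings must
    # not overwrite one another, so occupied windows are tracked per gene
    occupied <- stats::setNames(vector("list", length(seqs)), names(seqs))
    for (tf in ids$tfs) {
      motif <- truth$motifs[[tf]]
      w <- nchar(motif)
      targets <- ids$genes[!is.na(net[tf, ]) & net[tf, ] != 0]
      for (g in targets) {
        if (stats::runif(1) > cfg$motif_planting_rate) next
        for (try in 1:50) {
          pos <- sample.int(L - w + 1L, 1L)
          clash <- any(vapply(occupied[[g]], function(iv) {
            pos <= iv[2L] && (pos + w - 1L) >= iv[1L]
          }, logical(1)))
          if (!clash) {
            substr(seqs[g], pos, pos + w - 1L) <- motif
            occupied[[g]] <- c(occupied[[g]], list(c(pos, pos + w - 1L)))
            break
          }
        }
      }
    }
  })
  promoter_set(seqs)
}

#' Simulate a functional annotation with planted signal
#'
#' Terms are built as unions of 1-3 TFs' planted target sets (so term
#' over-representation among well-predicted targets is real), plus noise
#' genes, plus a number of random terms.
#'
#' @param truth A `"ground_truth"`.
#' @param n_random_terms Random (signal-free) terms to add (default 20).
#' @param noise_genes Random extra genes appended to each term (default 5).
#' @return An [annotation_map()].
#' @export
simulate_annotation <- function(truth, n_random_terms = 20L, noise_genes = 5L) {
  cfg <- truth$config
  ids <- synthetic_ids(cfg)
  net <- unclass(truth$network)
  with_local_seed(derive_seed(cfg$seed, 5L), {
    terms <- list()
    tf_pool <- ids$tfs
    i <- 0L
    while (length(tf_pool) > 0L) {
      i <- i + 1L
      take <- min(sample(1:3, 1L), length(tf_pool))
      grp <- tf_pool[seq_len(take)]
      tf_pool <- tf_pool[-seq_len(take)]
      members <- unique(unlist(lapply(grp, function(tf) {
        ids$genes[!is.na(net[tf, ]) & net[tf, ] != 0]
      })))
      members <- union(members, sample(ids$genes, noise_genes))
      terms[[sprintf("TERM%03d", i)]] <- members
    }
    for (j in seq_len(n_random_terms)) {
      i <- i + 1L
      terms[[sprintf("TERM%03d", i)]] <- sample(ids$genes,
                                                sample(10:40, 1L))
    }
    gene_terms <- split(rep(names(terms), lengths(terms)),
                        unlist(terms, use.names = FALSE))
  })
  annotation_map(gene_terms)
}

#' Simulate a protein-interaction table with planted signal
#'
#' Strong interactions (confidence ~0.9) between the planted complex TF
#' pairs (which share most targets), weak ones (~0.3) between random other
#' pairs.
#'
#' @param truth A `"ground_truth"`.
#' @param n_noise_pairs Weak random pairs to add (default 30).
#' @return An [interaction_table()].
#' @export
simulate_interactions <- function(truth, n_noise_pairs = 30L) {
  cfg <- truth$config
  ids <- synthetic_ids(cfg)
  with_local_seed(derive_seed(cfg$seed, 6L), {
    a <- character(0); b <- character(0); s <- numeric(0)
    if (!is.null(truth$complexes)) {
      a <- truth$complexes[, 1L]
      b <- truth$complexes[, 2L]
      s <- stats::runif(length(a), 0.85, 0.95)
    }
    for (i in seq_len(n_noise_pairs)) {
      p <- sample(ids$tfs, 2L)
      a <- c(a, p[1L]); b <- c(b, p[2L])
      s <- c(s, stats::runif(1, 0.1, 0.5))
    }
  })
  interaction_table(a, b, s)
}

#' Generate a complete benchmark bundle
#'
#' Ground truth plus every input the pipeline consumes. With
#' `n_datasets = 2`, a second expression dataset (different noise
#' realization and opposite perturbation mechanism) is generated from the
#' same planted truth, supporting cross-trained and multi-dataset feature
#' analyses.
#'
#' @param cfg A [synthetic_config()].
#' @param n_datasets 1 or 2 expression datasets (default 1).
#' @return List with class `"benchmark"`: `truth`, `datasets` (each with
#'   `expr` and `pmap`), `labels`, `promoters`, `annotation`,
#'   `interactions`, `config`.
#' @export
make_benchmark <- function(cfg = synthetic_config(), n_datasets = 1L) {
  truth <- simulate_ground_truth(cfg)
  datasets <- list(simulate_expression(truth, cfg))
  if (n_datasets >= 2L) {
    cfg2 <- cfg
    cfg2$seed <- derive_seed(cfg$seed, 7L)
    cfg2$mechanism <- if (cfg$mechanism == "deletion") "overexpression" else "deletion"
    datasets[[2L]] <- simulate_expression(truth, cfg2)
  }
  structure(list(truth = truth,
                 datasets = datasets,
                 labels = simulate_binding_labels(truth),
                 promoters = simulate_promoters(truth),
                 annotation = simulate_annotation(truth),
                 interactions = simulate_interactions(truth),
                 config = cfg),
            class = "benchmark")
}

#' Write a benchmark bundle to standard-format files
#'
#' Emits the expression TSV(s), perturbation map(s), binding-label edge
#' list, promoter FASTA, annotation TSV, interaction TSV, planted-truth
#' edge list, and a JSON manifest of the configuration.
#'
#' @param benchmark A `"benchmark"` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(benchmark$datasets)) {
    suffix <- if (length(benchmark$datasets) > 1L) paste0("_", i) else ""
    write_expression(benchmark$datasets[[i]]$expr,
                     file.path(dir, paste0("expression", suffix, ".tsv")))
    write_perturbation_map(benchmark$datasets[[i]]$pmap,
                           file.path(dir, paste0("perturbations", suffix, ".tsv")))
  }
  write_edge_list(benchmark$labels, file.path(dir, "binding_labels.tsv"))
  write_edge_list(benchmark$truth$network, file.path(dir, "truth.tsv"),
                  keep_zero = FALSE)
  write_promoters(benchmark$promoters, file.path(dir, "promoters.fasta"))
  gt <- benchmark$annotation$gene_terms
  ann <- data.frame(gene = rep(names(gt), lengths(gt)),
                    term = unlist(gt, use.names = FALSE))
  ann <- ann[order(ann$gene, ann$term), ]
  utils::write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_interactions(benchmark$interactions, file.path(dir, "interactions.tsv"))
  manifest <- benchmark$config
  class(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
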