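# Motif machinery: k-mer-seeded, EM-refined position weight matrices
# inferred from the promoters of a TF's top predicted targets, then scanned
# over all promoters as a log-odds score against a 0-order background.

BASES <- c("A", "C", "G", "T")

# promoter string -> integer codes (A=1..T=4, N/other = NA)
encode_seq <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1L]], BASES)
  v
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, ""))
}

#' Motif inference configuration
#'
#' @param top_targets Number of top predicted targets whose promoters form
#'   the motif foreground (default 50).
#' @param seed_kmer_length Length of the overrepresented k-mer used to seed
#'   the motif (default 7).
#' @param width_min,width_max Candidate motif widths (default 8-12).
#' @param em_iterations EM refinement iterations per width (default 50).
#' @param pseudocount Dirichlet pseudocount added to base counts.
#' @return List with class `"motif_config"`.
#' @export
motif_config <- function(top_targets = 50L, seed_kmer_length = 7L,
                         width_min = 8L, width_max = 12L,
                         em_iterations = 50L, pseudocount = 0.5) {
  if (top_targets < 5L) stop_tfmapr("top_targets must be >= 5")
  if (width_min < seed_kmer_length) {
    stop_tfmapr("motif width must be >= seed k-mer length")
  }
  structure(list(top_targets = as.integer(top_targets),
                 seed_kmer_length = as.integer(seed_kmer_length),
                 width_min = as.integer(width_min),
                 width_max = as.integer(width_max),
                 em_iterations = as.integer(em_iterations),
                 pseudocount = pseudocount),
            class = "motif_config")
}

#' Top predicted targets per TF from a preliminary network
#'
#' Ranks each TF's genes by absolute score (ties broken lexicographically by
#' gene id) and keeps the top K with nonzero score. The preliminary network
#' is typically the tree-ensemble evidence score, but any weighted network
#' works.
#'
#' @param network A weighted network.
#' @param k Targets to keep per TF.
#' @return Named list: TF -> character vector of target gene ids.
#' @export
preliminary_targets <- function(network, k) {
  genes <- colnames(network)
  lapply(stats::setNames(rownames(network), rownames(network)), function(tf) {
    s <- network[tf, ]
    keep <- !is.na(s) & s != 0
    g <- genes[keep]
    if (length(g) == 0L) return(character(0))
    ord <- order(-abs(s[keep]), g, method = "radix")
    g[ord][seq_len(min(k, length(g)))]
  })
}

# 0-order background base frequencies from a promoter set.
background_model <- function(promoters) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(unclass(promoters)))[, BASES, drop = FALSE])
  p <- counts / sum(counts)
  p[p == 0] <- 1e-9
  p / sum(p)
}

# Fraction of sequences containing each k-mer on either strand.
kmer_coverage <- function(seqs, k) {
  seqs <- seqs[nchar(seqs) >= k]
  fwd <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                              width = k)
  rev <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(unname(revcomp(seqs))), width = k)
  colMeans((fwd + rev) > 0)
}

#' Construct a position weight matrix
#' @param mat Numeric w x 4 matrix of base probabilities, columns A,C,G,T;
#'   rows must each sum to 1.
#' @return Matrix with class `"pwm"`.
#' @export
pwm <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) != 4L) stop_tfmapr("pwm needs a w x 4 matrix")
  colnames(mat) <- BASES
  if (any(mat <= 0)) stop_tfmapr("pwm probabilities must be positive (use a pseudocount)")
  if (any(abs(rowSums(mat) - 1) > 1e-9)) stop_tfmapr("pwm rows must sum to 1")
  structure(mat, class = c("pwm", "matrix"))
}

#' Consensus string of a PWM
#' @param x A pwm.
#' @return Character scalar of most-probable bases.
#' @export
pwm_consensus <- function(x) paste(BASES[apply(x, 1L, which.max)], collapse = "")

#' Per-position information content of a PWM (bits)
#' @param x A pwm.
#' @return Numeric vector, one value per position, in \[0, 2\].
#' @export
pwm_information <- function(x) {
  apply(x, 1L, function(p) 2 + sum(p * log2(p)))
}

# score every window of an integer-coded sequence against log-odds matrix lo
# (w x 4); N bases (NA codes) contribute 0. Returns vector of window scores.
scan_windows <- function(codes, lo) {
  w <- nrow(lo)
  L <- length(codes)
  if (L < w) return(numeric(0))
  npos <- L - w + 1L
  sc <- numeric(npos)
  for (i in seq_len(w)) {
    contrib <- lo[i, codes[i:(i + npos - 1L)]]
    contrib[is.na(contrib)] <- 0
    sc <- sc + contrib
  }
  sc
}

# EM refinement (one occurrence per sequence, both strands) of a starting
# PWM over foreground sequences. Returns list(pwm, loglik_ratio).
refine_pwm_em <- function(start, fg_codes, bg, iterations, pseudocount) {
  w <- nrow(start)
  mat <- start
  usable <- fg_codes[vapply(fg_codes, function(p) length(p$fwd) >= w, logical(1))]
  if (length(usable) == 0L) return(NULL)
  for (it in seq_len(iterations + 1L)) {
    lo <- log2(mat / rep(bg, each = w))
    counts <- matrix(0, w, 4L)
    total_ll <- 0
    for (p in usable) {
      sf <- scan_windows(p$fwd, lo)
      sr <- scan_windows(p$rev, lo)
      # hard strand choice (keeps near-palindromic motifs from collapsing
      # into a strand mixture), soft posterior over window positions: each
      # window contributes in proportion to its odds versus background
      codes <- if (max(sf) >= max(sr)) p$fwd else p$rev
      sc <- if (max(sf) >= max(sr)) sf else sr
      post <- 2^(sc - max(sc))
      post <- post / sum(post)
      total_ll <- total_ll + max(sc)
      npos <- length(sc)
      for (i in seq_len(w)) {
        b <- codes[i:(i + npos - 1L)]
        for (bb in 1:4) {
          counts[i, bb] <- counts[i, bb] + sum(post[which(b == bb)])
        }
      }
    }
    if (it > iterations) return(list(pwm = pwm(mat), score = total_ll))
    counts <- counts + pseudocount
    mat <- counts / rowSums(counts)
  }
}

#' Infer a binding motif from foreground promoters
#'
#' Seeds from the k-mer most overrepresented in the foreground relative to
#' the background (both strands), extends it symmetrically to each candidate
#' width with uniform flanks, refines by EM over a one-occurrence-per-sequence
#' alignment, and returns the width whose refined motif has the highest total
#' best-window log-odds across foreground promoters (normalized per
#' position). Deterministic given the seed.
#'
#' @param foreground A promoter set for the TF's top predicted targets
#'   (>= 5 sequences).
#' @param background A promoter set used for the 0-order background model
#'   (typically all promoters).
#' @param cfg A [motif_config()].
#' @param seed Integer seed (tie-breaking only; the algorithm is otherwise
#'   deterministic).
#' @return A [pwm()].
#' @export
infer_pwm <- function(foreground, background, cfg = motif_config(), seed = 1L) {
  fg <- unclass(foreground)
  if (length(fg) < 5L) {
    stop_tfmapr("need >= 5 foreground promoters; increase the number of top targets")
  }
  bg <- background_model(background)
  k <- cfg$seed_kmer_length
  # seed on per-sequence coverage (fraction of sequences containing the
  # k-mer on either strand) — far more robust to occurrence-count noise
  # than raw frequency ratios
  fg_cov <- kmer_coverage(fg, k)
  bg_cov <- kmer_coverage(unclass(background), k)
  ratio <- (fg_cov + 0.05) /
    (ifelse(is.na(bg_cov[names(fg_cov)]), 0, bg_cov[names(fg_cov)]) + 0.05)
  ratio[fg_cov < 0.25] <- 0
  if (max(ratio) < 1.5) {
    # no k-mer is meaningfully enriched over the background: report a
    # background-frequency (information-free) motif rather than refining
    # noise into a sharp one
    return(pwm(matrix(rep(bg, each = cfg$width_min), cfg$width_min, 4L)))
  }
  seed_kmer <- names(ratio)[order(-ratio, names(ratio), method = "radix")][1L]
  fg_codes <- lapply(fg, function(s) {
    list(fwd = encode_seq(s), rev = encode_seq(unname(revcomp(s))))
  })
  best <- NULL
  for (w in seq(cfg$width_min, cfg$width_max)) {
    start <- matrix(rep(bg, each = w), w, 4L)
    pad_left <- (w - k) %/% 2L
    core <- match(strsplit(seed_kmer, "", fixed = TRUE)[[1L]], BASES)
    for (i in seq_len(k)) {
      # strong anchor on the seed consensus so the first E-step posterior
      # concentrates on genuine occurrences rather than background windows
      row <- pad_left + i
      start[row, ] <- 0.1
      start[row, core[i]] <- 0.7
    }
    fit <- refine_pwm_em(start, fg_codes, bg, cfg$em_iterations, cfg$pseudocount)
    if (is.null(fit)) next
    norm <- fit$score / w
    if (is.null(best) || norm > best$norm) {
      best <- list(pwm = fit$pwm, norm = norm)
    }
  }
  if (is.null(best)) stop_tfmapr("all foreground promoters shorter than the minimum width")
  best$pwm
}

#' Scan a PWM over promoters
#'
#' The score of a promoter is the best log2-odds window score over both
#' strands: `max over windows of sum_i log2(pwm_i(base) / bg(base))`, with N
#' bases contributing 0. Promoters shorter than the motif get `NA`.
#'
#' @param x A [pwm()].
#' @param promoters A promoter set.
#' @param background Optional 0-order background (named A/C/G/T vector);
#'   defaults to base frequencies of `promoters`.
#' @return Named numeric vector of scores, one per promoter.
#' @export
scan_promoters <- function(x, promoters, background = NULL) {
  bg <- background %||% background_model(promoters)
  bg <- bg[BASES]
  w <- nrow(x)
  lo <- log2(unclass(x) / rep(bg, each = w))
  vapply(unclass(promoters), function(s) {
    if (nchar(s) < w) return(NA_real_)
    fwd <- scan_windows(encode_seq(s), lo)
    rev <- scan_windows(encode_seq(unname(revcomp(s))), lo)
    max(c(fwd, rev))
  }, numeric(1))
}

#' PWM evidence score for all TFs
#'
#' For each TF: take the top predicted targets from a preliminary network,
#' infer a motif from their promoters, and scan it over every promoter to
#' produce the (TF, gene) PWM evidence score.
#'
#' @param preliminary A weighted network used to pick each TF's foreground
#'   (typically tree-ensemble scores).
#' @param promoters A promoter set covering the genes.
#' @param cfg A [motif_config()].
#' @param seed Integer seed.
#' @return List: `network` (weighted network of scan scores) and `pwms`
#'   (named list of per-TF PWMs; TFs with too few targets are absent and get
#'   an all-`NA` row).
#' @export
pwm_scores <- function(preliminary, promoters, cfg = motif_config(), seed = 1L) {
  targets <- preliminary_targets(preliminary, cfg$top_targets)
  genes <- intersect(colnames(preliminary), names(promoters))
  tfs <- rownames(preliminary)
  m <- matrix(NA_real_, length(tfs), length(genes), dimnames = list(tfs, genes))
  bg <- background_model(promoters)
  pwms <- list()
  for (i in seq_along(tfs)) {
    tf <- tfs[i]
    fg_genes <- intersect(targets[[tf]], names(promoters))
    if (length(fg_genes) < 5L) next
    fg <- promoter_set(unclass(promoters)[fg_genes])
    p <- infer_pwm(fg, promoters, cfg, seed = derive_seed(seed, i))
    pwms[[tf]] <- p
    m[tf, genes] <- scan_promoters(p, promoter_set(unclass(promoters)[genes]),
                                   background = bg)
  }
  list(network = weighted_network(m), pwms = pwms)
}

#' Write PWMs in MEME minimal motif format
#' @param pwms Named list of [pwm()] objects.
#' @param path Output path.
#' @param background Optional named A/C/G/T background frequencies.
#' @export
write_meme <- function(pwms, path, background = NULL) {
  bg <- background %||% stats::setNames(rep(0.25, 4), BASES)
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", BASES, bg[BASES]), collapse = " "), "")
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    lines <- c(lines,
               sprintf("MOTIF %s", nm),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(p)),
               apply(p, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read PWMs from MEME minimal motif format
#' @param path Input path.
#' @return Named list of [pwm()] objects.
#' @export
load_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      nm <- strsplit(trimws(lines[i]), "\\s+")[[1L]][2L]
      j <- i + 1L
      while (j <= length(lines) && !startsWith(lines[j], "letter-probability")) j <- j + 1L
      w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[j]))
      rows <- do.call(rbind, lapply(lines[(j + 1L):(j + w)], function(l) {
        as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
      }))
      rows <- rows / rowSums(rows)
      out[[nm]] <- pwm(rows)
      i <- j + w
    }
    i <- i + 1L
  }
  out
}
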