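# Synthetic benchmark generator: ground-truth regulatory networks, replicated
# time courses, promoters with planted binding sites, conserved intervals,
# partial reference networks, and recovery metrics.

#' Simulate a random TF -> gene regulatory topology
#'
#' Draws `n_edges` distinct TF -> gene edges uniformly at random (no
#' self-edges); weights are signed, uniform in magnitude on [0.5, 1.5]. The
#' first `n_tf` genes are the transcription factors.
#'
#' @param n_tf number of transcription factors.
#' @param n_gene total number of genes (including the TFs).
#' @param n_edges number of true edges (capped at the maximum possible).
#' @param seed integer RNG seed; runs are bitwise reproducible.
#' @return object of class `SyntheticGRN`: `tf_ids`, `gene_ids`, `adjacency`
#'   (n_tf x n_gene weight matrix, nonzero exactly on true edges), `edges`
#'   (data.frame regulator/target/weight), `seed`.
#' @export
simulate_topology <- function(n_tf, n_gene, n_edges, seed = 1L) {
  if (n_tf < 1L || n_gene < n_tf) stop("need 1 <= n_tf <= n_gene")
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_gene))
  tf_ids <- gene_ids[seq_len(n_tf)]
  pairs <- expand.grid(regulator = tf_ids, target = gene_ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
  n_edges <- min(n_edges, nrow(pairs))
  W <- matrix(0, n_tf, n_gene, dimnames = list(tf_ids, gene_ids))
  edges <- pairs[0, ]
  if (n_edges > 0L) {
    pick <- sample(nrow(pairs), n_edges)
    edges <- pairs[pick, , drop = FALSE]
    edges$weight <- sample(c(-1, 1), n_edges, replace = TRUE) *
      stats::runif(n_edges, 0.5, 1.5)
    W[cbind(edges$regulator, edges$target)] <- edges$weight
  }
  rownames(edges) <- NULL
  structure(list(tf_ids = tf_ids, gene_ids = gene_ids, adjacency = W,
                 edges = edges, seed = seed),
            class = "SyntheticGRN")
}

#' @export
print.SyntheticGRN <- function(x, ...) {
  cat("SyntheticGRN:", length(x$tf_ids), "TFs,", length(x$gene_ids),
      "genes,", nrow(x$edges), "true edges (seed", x$seed, ")\n")
  invisible(x)
}

#' Simulate replicated expression time courses from a network
#'
#' Each experiment starts from an independent standard-normal state; the
#' state advances as
#' x_{t+1,g} = persistence * x_{t,g} + f(sum_r W_rg x_{t,r}) + noise
#' with f = tanh (default, saturating regulation) or identity (`linear`)
#' and noise Normal(0, noise_sd^2). The autoregressive persistence term
#' emulates the strong serial correlation of expression trajectories
#' sampled every 30 minutes (transcript levels decay over hours, they do
#' not re-randomize between arrays); without it regulator series would be
#' white noise and carry no recoverable signal into the simultaneous pairs
#' that the information estimators see. The lag-1 regulatory coupling is
#' what directed information is designed to pick up.
#'
#' @param grn a [simulate_topology()] result.
#' @param n_experiments number of replicate experiments (default 19).
#' @param n_timepoints points per experiment (default 4).
#' @param noise_sd process noise standard deviation (default 0.3).
#' @param seed integer RNG seed.
#' @param dynamics `"tanh"` or `"linear"`.
#' @param persistence AR(1) carry-over coefficient in [0, 1) (default 0.8).
#' @param time_step minutes between samples (default 30, giving the
#'   0/30/60/90 grid).
#' @return a [time_course_dataset()].
#' @export
simulate_timecourses <- function(grn, n_experiments = 19L, n_timepoints = 4L,
                                 noise_sd = 0.3, seed = 1L,
                                 dynamics = c("tanh", "linear"),
                                 persistence = 0.8, time_step = 30) {
  stopifnot(inherits(grn, "SyntheticGRN"))
  dynamics <- match.arg(dynamics)
  f <- if (dynamics == "tanh") tanh else identity
  set.seed(seed)
  G <- length(grn$gene_ids)
  tf_idx <- match(grn$tf_ids, grn$gene_ids)
  experiments <- list()
  for (e in seq_len(n_experiments)) {
    m <- matrix(0, G, n_timepoints,
                dimnames = list(grn$gene_ids, NULL))
    m[, 1L] <- stats::rnorm(G)
    for (t in seq_len(n_timepoints - 1L)) {
      drive <- as.vector(crossprod(grn$adjacency, m[tf_idx, t]))
      m[, t + 1L] <- persistence * m[, t] + f(drive) +
        stats::rnorm(G, 0, noise_sd)
    }
    colnames(m) <- paste0("t", (seq_len(n_timepoints) - 1L) * time_step)
    experiments[[sprintf("exp%02d", e)]] <- m
  }
  time_course_dataset(experiments, (seq_len(n_timepoints) - 1L) * time_step)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_site <- function(site, rate) {
  b <- strsplit(site, "")[[1L]]
  hit <- stats::runif(length(b)) < rate
  if (any(hit))
    b[hit] <- vapply(b[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1L))
  paste(b, collapse = "")
}

#' Generate promoters with planted, optionally conserved binding sites
#'
#' Every gene in `gene_ids` receives a `width`-bp i.i.d. uniform-background
#' promoter window. For each gene in `plant_ids`, a mutated copy of the
#' consensus (per-base substitution rate `mutation_rate`) is planted at a
#' random offset; with probability `conserve_fraction` the conserved interval
#' of that gene covers the planted site entirely (with random flanking
#' padding), otherwise -- and for unplanted genes -- it covers a random
#' window elsewhere. A set of `n_known_sites` independently mutated consensus
#' copies plays the role of the known binding sites.
#'
#' @param gene_ids promoter owners.
#' @param plant_ids subset of `gene_ids` to receive a planted site.
#' @param consensus the true binding-site consensus (ACGT string).
#' @param conserve_fraction probability a planted site is conserved.
#' @param seed integer RNG seed.
#' @param width promoter window size in bp (default 400).
#' @param mutation_rate per-base substitution rate for planted/known copies.
#' @param n_known_sites number of known-site copies (default 10).
#' @return list: `promoters` (named character vector), `sites` (character
#'   vector), `conserved` (data.frame `seq_id`/`start`/`end`, window-local
#'   0-based half-open), `manifest` (data.frame of planted genes, offsets and
#'   conservation flags).
#' @export
synthesize_promoters <- function(gene_ids, plant_ids, consensus,
                                 conserve_fraction = 0.8, seed = 1L,
                                 width = 400L, mutation_rate = 0.1,
                                 n_known_sites = 10L) {
  stopifnot(all(plant_ids %in% gene_ids))
  if (!grepl("^[ACGT]+$", consensus)) stop("consensus must be ACGT only")
  w <- nchar(consensus)
  if (width < 2L * w) stop("promoter width too small for the site")
  set.seed(seed)
  promoters <- character(length(gene_ids)); names(promoters) <- gene_ids
  cons_rows <- list(); man_rows <- list()
  for (g in gene_ids) {
    p <- .random_dna(width)
    planted <- g %in% plant_ids
    if (planted) {
      off <- sample(0:(width - w), 1L)  # 0-based offset
      site <- .mutate_site(consensus, mutation_rate)
      substr(p, off + 1L, off + w) <- site
      conserved_here <- stats::runif(1L) < conserve_fraction
      if (conserved_here) {
        pad_l <- sample(0:20, 1L); pad_r <- sample(0:20, 1L)
        s <- max(0L, off - pad_l); e <- min(width, off + w + pad_r)
      } else {
        # an unrelated window that misses the planted site
        repeat {
          len <- sample(20:60, 1L)
          s <- sample(0:(width - len), 1L); e <- s + len
          if (e <= off || s >= off + w) break
        }
      }
      man_rows[[g]] <- data.frame(gene = g, start = off, end = off + w,
                                  conserved = conserved_here,
                                  site = site, stringsAsFactors = FALSE)
    } else {
      len <- sample(20:60, 1L)
      s <- sample(0:(width - len), 1L); e <- s + len
    }
    promoters[g] <- p
    cons_rows[[g]] <- data.frame(seq_id = g, start = s, end = e,
                                 stringsAsFactors = FALSE)
  }
  sites <- vapply(seq_len(n_known_sites),
                  function(i) .mutate_site(consensus, mutation_rate),
                  character(1L))
  manifest <- if (length(man_rows)) do.call(rbind, man_rows) else
    data.frame(gene = character(), start = integer(), end = integer(),
               conserved = logical(), site = character())
  rownames(manifest) <- NULL
  conserved <- do.call(rbind, cons_rows)
  rownames(conserved) <- NULL
  list(promoters = promoters, sites = sites, conserved = conserved,
       manifest = manifest)
}

#' Promoters for a synthetic network
#'
#' Convenience wrapper over [synthesize_promoters()]: plants the consensus in
#' (a fraction of) the true-target genes of `grn`.
#'
#' @param grn a [simulate_topology()] result.
#' @param consensus binding-site consensus string.
#' @param plant_fraction fraction of true-target genes receiving a site.
#' @inheritParams synthesize_promoters
#' @return as [synthesize_promoters()].
#' @export
simulate_promoters <- function(grn, consensus = "TGACCTAGATCGGTCA",
                               plant_fraction = 1, conserve_fraction = 0.8,
                               seed = 1L, width = 400L, mutation_rate = 0.1,
                               n_known_sites = 10L) {
  stopifnot(inherits(grn, "SyntheticGRN"))
  true_targets <- sort(unique(grn$edges$target))
  set.seed(seed)
  n_plant <- round(plant_fraction * length(true_targets))
  plant_ids <- sort(sample(true_targets, n_plant))
  synthesize_promoters(grn$gene_ids, plant_ids, consensus,
                       conserve_fraction, seed = seed + 1L, width = width,
                       mutation_rate = mutation_rate,
                       n_known_sites = n_known_sites)
}

#' Sample a partial reference network from the truth
#'
#' Emulates the incompleteness of curated interaction databases by keeping a
#' uniform fraction of the true edges as "known".
#'
#' @param grn a [simulate_topology()] result.
#' @param known_fraction fraction of true edges to expose.
#' @param seed integer RNG seed.
#' @return a [reference_network()].
#' @export
make_reference <- function(grn, known_fraction, seed = 1L) {
  stopifnot(inherits(grn, "SyntheticGRN"))
  set.seed(seed)
  n <- nrow(grn$edges)
  k <- round(known_fraction * n)
  keep <- if (k > 0L) sort(sample(n, k)) else integer()
  reference_network(grn$edges[keep, c("regulator", "target"), drop = FALSE])
}

#' Precision/recall/AUPR of an edge ranking against the true network
#'
#' For a ranked edge list (or a z-score matrix, ranked by decreasing z with
#' lexicographic tie-breaks), walks the ranking and reports precision and
#' recall at the end plus the area under the precision-recall curve by
#' trapezoidal interpolation over the ranked prefix points.
#'
#' @param ranked data.frame with `regulator`, `target` in rank order, or a
#'   `ZScoreMatrix`.
#' @param grn a [simulate_topology()] result (full truth).
#' @return list `precision`, `recall`, `aupr`, `n_edges`.
#' @export
evaluate_recovery <- function(ranked, grn) {
  stopifnot(inherits(grn, "SyntheticGRN"))
  if (inherits(ranked, "ZScoreMatrix"))
    ranked <- edges_top_k(ranked, sum(!is.na(ranked$z)))
  truth <- paste(grn$edges$regulator, grn$edges$target, sep = "\r")
  P <- length(truth)
  if (nrow(ranked) == 0L)
    return(list(precision = NA_real_, recall = 0, aupr = 0, n_edges = 0L))
  is_tp <- paste(ranked$regulator, ranked$target, sep = "\r") %in% truth
  tp <- cumsum(is_tp)
  prec <- tp / seq_along(tp)
  rec <- tp / P
  r_pts <- c(0, rec)
  p_pts <- c(prec[1L], prec)
  aupr <- sum(diff(r_pts) * (utils::head(p_pts, -1L) + p_pts[-1L]) / 2)
  list(precision = prec[length(prec)], recall = rec[length(rec)],
       aupr = aupr, n_edges = nrow(ranked))
}

#' Random operon structures over non-TF genes
#'
#' Groups a fraction of the genes into small ordered operons (2-4 genes),
#' for exercising [operon_expand()].
#'
#' @param grn a [simulate_topology()] result.
#' @param n_operons number of operons to form.
#' @param seed integer RNG seed.
#' @return list of ordered character vectors.
#' @export
simulate_operons <- function(grn, n_operons = 10L, seed = 1L) {
  stopifnot(inherits(grn, "SyntheticGRN"))
  set.seed(seed)
  pool <- setdiff(grn$gene_ids, grn$tf_ids)
  ops <- list()
  for (i in seq_len(n_operons)) {
    size <- sample(2:4, 1L)
    if (length(pool) < size) break
    member <- sample(pool, size)
    pool <- setdiff(pool, member)
    ops[[i]] <- member
  }
  ops
}
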