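# Sequence-level validation of inferred interactions: PWM built from known
# binding sites, log-odds promoter scan, phylogenetic-conservation overlap
# rule, and operon expansion of accepted edges.

.DNA_BASES <- c("A", "C", "G", "T")

.site_chars <- function(sites) {
  if (methods::is(sites, "XStringSet")) sites <- as.character(sites)
  toupper(as.character(sites))
}

#' Build a position weight matrix from aligned binding sites
#'
#' Per-position probability (count + pseudocount) / (n_sites + 4 pseudocount).
#'
#' @param sites character vector or `DNAStringSet` of >= 2 equal-length
#'   ACGT-only sequences (ambiguity codes are rejected).
#' @param pseudocount nonnegative pseudocount added per base (default 0.5).
#' @return object of class `PositionWeightMatrix` with fields `probs`
#'   (4 x width, rows ACGT), `width`, `pseudocount`, `n_sites`, `sites`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5) {
  sites <- .site_chars(sites)
  if (length(sites) < 2L) stop("need at least 2 binding sites")
  w <- unique(nchar(sites))
  if (length(w) != 1L)
    stop("binding sites must have equal lengths (got ",
         paste(sort(w), collapse = ", "), ")")
  if (w < 4L) stop("PWM width must be >= 4")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (!all(grepl("^[ACGT]+$", sites)))
    stop("binding sites must contain only A, C, G, T")
  counts <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sites))
  counts <- counts[.DNA_BASES, , drop = FALSE]
  probs <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  structure(list(probs = probs, width = w, pseudocount = pseudocount,
                 n_sites = length(sites), sites = sites),
            class = "PositionWeightMatrix")
}

#' @export
print.PositionWeightMatrix <- function(x, ...) {
  cat("PositionWeightMatrix: width", x$width, "from", x$n_sites,
      "sites (pseudocount", x$pseudocount, ")\n")
  invisible(x)
}

#' Per-position information content of a PWM
#'
#' 2 + sum_b p_b log2 p_b per position (0 log 0 = 0); the quantity plotted
#' as letter heights in a sequence logo.
#'
#' @param pwm a [build_pwm()] result.
#' @return numeric vector, bits per position.
#' @export
pwm_information_content <- function(pwm) {
  stopifnot(inherits(pwm, "PositionWeightMatrix"))
  apply(pwm$probs, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

.encode_dna <- function(seq) {
  if (methods::is(seq, "XString") || methods::is(seq, "XStringSet"))
    seq <- as.character(seq)
  idx <- match(strsplit(toupper(seq), "")[[1L]], .DNA_BASES)
  idx
}

# log-odds score of a full-width string against the PWM (plus strand)
.score_site <- function(pwm, site, background) {
  idx <- .encode_dna(site)
  sum(log(pwm$probs[cbind(idx, seq_len(pwm$width))] / background[idx]))
}

.scan_one_strand <- function(L, idx, n_pos) {
  w <- ncol(L)
  sc <- numeric(n_pos)
  for (j in seq_len(w)) {
    lj <- L[, j][idx[j:(j + n_pos - 1L)]]
    lj[is.na(lj)] <- 0  # non-ACGT position scored as background
    sc <- sc + lj
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores the log-odds sum log(p_pos(base) / q(base)) at every offset; the
#' minus strand scores the reverse complement of each window. Non-ACGT
#' characters are scored as background (contribution 0) with a warning.
#'
#' @param pwm a [build_pwm()] result.
#' @param seq DNA string (character or `DNAString`), length >= PWM width.
#' @param background base probabilities for A, C, G, T (default uniform).
#' @param seq_id identifier recorded in the hits (default "seq").
#' @return data.frame of hits: `seq_id`, `start`, `end` (0-based half-open),
#'   `strand`, `score`, sorted by decreasing score, ties by start then
#'   strand (+ before -).
#' @export
scan_sequence <- function(pwm, seq, background = rep(0.25, 4),
                          seq_id = "seq") {
  stopifnot(inherits(pwm, "PositionWeightMatrix"))
  idx <- .encode_dna(seq)
  if (length(idx) < pwm$width)
    stop("sequence shorter than PWM width")
  if (anyNA(idx))
    warning(sum(is.na(idx)), " non-ACGT position(s) scored as background")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 probabilities summing to 1")
  L <- log(pwm$probs / background)
  n_pos <- length(idx) - pwm$width + 1L
  # minus strand: score the reverse complement of each window, i.e. the
  # complemented, column-reversed PWM applied to the forward sequence
  Lrc <- L[4:1, pwm$width:1, drop = FALSE]
  hits <- data.frame(
    seq_id = seq_id,
    start = rep(0:(n_pos - 1L), 2L),
    end = rep(pwm$width:(length(idx)), 2L) - 1L + 1L,
    strand = rep(c("+", "-"), each = n_pos),
    score = c(.scan_one_strand(L, idx, n_pos),
              .scan_one_strand(Lrc, idx, n_pos)),
    stringsAsFactors = FALSE
  )
  hits$end <- hits$start + pwm$width
  hits <- hits[order(-hits$score, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Default acceptance threshold of a PWM
#'
#' The minimum log-odds score of the PWM's own training sites. By default
#' each site is scored leave-one-out, against the PWM rebuilt from the
#' remaining sites: scoring a site under a model that contains its own
#' counts inflates the score (every mutated base contributes its own
#' pseudo-evidence), so the resubstitution minimum is systematically higher
#' than what an unseen genuine site can reach. The leave-one-out minimum is
#' an unbiased floor while still guaranteeing that every known site passes
#' the full PWM (a site's full-model score always exceeds its leave-one-out
#' score). `method = "resubstitution"` scores sites under the full PWM.
#'
#' @inheritParams scan_sequence
#' @param method `"loo"` (default) or `"resubstitution"`.
#' @return numeric score threshold (nats).
#' @export
pwm_site_threshold <- function(pwm, background = rep(0.25, 4),
                               method = c("loo", "resubstitution")) {
  stopifnot(inherits(pwm, "PositionWeightMatrix"))
  method <- match.arg(method)
  if (method == "resubstitution" || length(pwm$sites) <= 2L)
    return(min(vapply(pwm$sites, .score_site, numeric(1L),
                      pwm = pwm, background = background)))
  min(vapply(seq_along(pwm$sites), function(i) {
    .score_site(build_pwm(pwm$sites[-i], pwm$pseudocount),
                pwm$sites[i], background)
  }, numeric(1L)))
}

#' Best PWM hit above a score threshold
#'
#' @inheritParams scan_sequence
#' @param threshold minimum acceptable log-odds score; defaults to
#'   [pwm_site_threshold()].
#' @return single-row hit data.frame, or `NULL` if no hit reaches the
#'   threshold.
#' @export
best_hit <- function(pwm, seq, threshold = NULL, background = rep(0.25, 4),
                     seq_id = "seq") {
  if (is.null(threshold)) threshold <- pwm_site_threshold(pwm, background)
  hits <- scan_sequence(pwm, seq, background, seq_id)
  top <- hits[1L, , drop = FALSE]
  if (top$score >= threshold) top else NULL
}

#' Fraction of a motif hit covered by conserved intervals
#'
#' Intersects the hit interval with the union of conserved intervals on the
#' same sequence and reports covered length / hit length.
#'
#' @param hit single-row hit data.frame (`seq_id`, `start`, `end`; 0-based
#'   half-open).
#' @param conserved data.frame of conserved intervals with columns `seq_id`,
#'   `start`, `end` in the same window-local 0-based half-open coordinates.
#' @return fraction in [0, 1].
#' @export
conservation_fraction <- function(hit, conserved) {
  if (is.null(conserved) || nrow(conserved) == 0L) return(0)
  cons <- conserved[conserved$seq_id == hit$seq_id, , drop = FALSE]
  if (nrow(cons) == 0L) return(0)
  if (any(cons$start < 0 | cons$start >= cons$end))
    stop("conserved intervals must satisfy 0 <= start < end")
  # 0-based half-open [s, e) maps to the 1-based closed IRanges [s + 1, e]
  cov <- IRanges::reduce(IRanges::IRanges(cons$start + 1L, cons$end))
  hit_ir <- IRanges::IRanges(hit$start + 1L, hit$end)
  sum(IRanges::width(IRanges::intersect(cov, hit_ir))) /
    IRanges::width(hit_ir)
}

#' Validate one inferred interaction against promoter sequence evidence
#'
#' Builds (or reuses) a PWM from the regulator's known binding sites, finds
#' the best-scoring site in the target's promoter, and accepts the
#' interaction iff a site exists above the score threshold and strictly more
#' than 50% of it is covered by phylogenetically conserved intervals.
#'
#' @param regulator,target identifiers recorded in the decision.
#' @param sites known binding sites (passed to [build_pwm()]) or an existing
#'   `PositionWeightMatrix`.
#' @param promoter the target's promoter sequence (400-bp upstream window,
#'   oriented 5'->3' toward the gene start).
#' @param conserved conserved intervals in window-local coordinates (see
#'   [conservation_fraction()]); `seq_id` must match `target`.
#' @param pseudocount passed to [build_pwm()] when `sites` are raw sequences.
#' @param threshold score threshold; default [pwm_site_threshold()].
#' @param background base probabilities (default uniform).
#' @return one-row data.frame: `regulator`, `target`, `accepted`,
#'   `hit_start`, `hit_end`, `strand`, `score`, `conservation_fraction`,
#'   `reason` ("ok", "no_site" or "low_conservation").
#' @export
validate_interaction <- function(regulator, target, sites, promoter,
                                 conserved, pseudocount = 0.5,
                                 threshold = NULL,
                                 background = rep(0.25, 4)) {
  pwm <- if (inherits(sites, "PositionWeightMatrix")) sites
         else build_pwm(sites, pseudocount)
  hit <- best_hit(pwm, promoter, threshold, background, seq_id = target)
  if (is.null(hit)) {
    return(data.frame(regulator = regulator, target = target,
                      accepted = FALSE, hit_start = NA_integer_,
                      hit_end = NA_integer_, strand = NA_character_,
                      score = NA_real_, conservation_fraction = NA_real_,
                      reason = "no_site", stringsAsFactors = FALSE))
  }
  frac <- conservation_fraction(hit, conserved)
  accepted <- frac > 0.5  # strictly more than half the site conserved
  data.frame(regulator = regulator, target = target, accepted = accepted,
             hit_start = hit$start, hit_end = hit$end, strand = hit$strand,
             score = hit$score, conservation_fraction = frac,
             reason = if (accepted) "ok" else "low_conservation",
             stringsAsFactors = FALSE)
}

#' Validate a set of inferred edges
#'
#' Applies [validate_interaction()] to each edge, looking up the regulator's
#' binding sites and the target's promoter by name. Edges whose regulator has
#' no sites or whose target has no promoter are rejected with reasons
#' "no_sites_for_tf" / "no_promoter".
#'
#' @param edges data.frame with columns `regulator`, `target`.
#' @param sites_by_tf named list of binding-site sets (or a single
#'   site set / PWM applied to every regulator).
#' @param promoters named character vector or `DNAStringSet` of promoter
#'   windows keyed by target gene.
#' @param conserved data.frame of conserved intervals (`seq_id` = gene).
#' @inheritParams validate_interaction
#' @return decision data.frame, one row per edge.
#' @export
validate_edges <- function(edges, sites_by_tf, promoters, conserved,
                           pseudocount = 0.5, threshold = NULL,
                           background = rep(0.25, 4)) {
  shared_pwm <- NULL
  if (!is.list(sites_by_tf) || inherits(sites_by_tf, "PositionWeightMatrix") ||
      methods::is(sites_by_tf, "XStringSet")) {
    shared_pwm <- if (inherits(sites_by_tf, "PositionWeightMatrix"))
      sites_by_tf else build_pwm(sites_by_tf, pseudocount)
  }
  pwm_cache <- list()
  if (methods::is(promoters, "XStringSet")) {
    pn <- names(promoters)
    promoters <- as.character(promoters)
    names(promoters) <- pn
  }
  rows <- vector("list", nrow(edges))
  reject <- function(r, t, why) {
    data.frame(regulator = r, target = t, accepted = FALSE,
               hit_start = NA_integer_, hit_end = NA_integer_,
               strand = NA_character_, score = NA_real_,
               conservation_fraction = NA_real_, reason = why,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(edges))) {
    r <- edges$regulator[i]; t <- edges$target[i]
    pwm <- shared_pwm
    if (is.null(pwm)) {
      if (is.null(sites_by_tf[[r]])) { rows[[i]] <- reject(r, t, "no_sites_for_tf"); next }
      if (is.null(pwm_cache[[r]]))
        pwm_cache[[r]] <- build_pwm(sites_by_tf[[r]], pseudocount)
      pwm <- pwm_cache[[r]]
    }
    if (is.na(promoters[t]) || is.null(promoters[[t]])) {
      rows[[i]] <- reject(r, t, "no_promoter"); next
    }
    rows[[i]] <- validate_interaction(r, t, pwm, promoters[[t]], conserved,
                                      pseudocount, threshold, background)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand accepted edges across operons
#'
#' A binding site validated in front of an operon's promoter-proximal (first)
#' gene implies regulation of every downstream gene of that operon: for each
#' accepted edge (r, t) with t leading an operon, edges (r, g) are added for
#' the downstream members g, flagged `operon_derived`.
#'
#' @param accepted data.frame of accepted edges (`regulator`, `target`).
#' @param operons list of ordered character vectors of gene ids (first =
#'   promoter-proximal).
#' @return `accepted` plus the derived edges, with a logical
#'   `operon_derived` column.
#' @export
operon_expand <- function(accepted, operons) {
  accepted$operon_derived <- FALSE
  if (nrow(accepted) == 0L || length(operons) == 0L) return(accepted)
  extra <- list()
  have <- paste(accepted$regulator, accepted$target)
  for (op in operons) {
    if (length(op) < 2L) next
    lead <- op[1L]
    hits <- accepted[accepted$target == lead & !accepted$operon_derived, ,
                     drop = FALSE]
    for (r in unique(hits$regulator)) {
      for (g in op[-1L]) {
        if (paste(r, g) %in% have) next
        row <- hits[hits$regulator == r, , drop = FALSE][1L, ]
        row$target <- g
        row$operon_derived <- TRUE
        extra[[length(extra) + 1L]] <- row
        have <- c(have, paste(r, g))
      }
    }
  }
  out <- rbind(accepted, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}
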