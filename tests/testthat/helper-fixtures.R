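# Shared fixture builders; everything is generated in code.

# bivariate Gaussian sample with correlation rho
gauss_pair <- function(n, rho, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y)
}

# tiny dataset: E experiments x N time points for a handful of genes
toy_dataset <- function(genes = c("tfA", "tfB", "g1", "g2"),
                        E = 12L, N = 4L, seed = 11L) {
  set.seed(seed)
  exps <- list()
  for (e in seq_len(E)) {
    m <- matrix(rnorm(length(genes) * N), length(genes), N,
                dimnames = list(genes, paste0("t", (seq_len(N) - 1) * 30)))
    exps[[paste0("exp", e)]] <- m
  }
  time_course_dataset(exps, (seq_len(N) - 1) * 30)
}

# independent plug-in MI from a plain frequency table (no package code)
oracle_mi_table <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  as.numeric(s)
}

# independent entropy from a frequency table
oracle_entropy <- function(...) {
  p <- table(...) / length(..1)
  p <- p[p > 0]
  -sum(p * log(p))
}

# exhaustive union-length of 0-based half-open intervals via position flags
oracle_union_overlap <- function(hit_start, hit_end, starts, ends) {
  covered <- logical(hit_end - hit_start)
  for (k in seq_along(starts)) {
    lo <- max(starts[k], hit_start); hi <- min(ends[k], hit_end)
    if (hi > lo) covered[(lo - hit_start + 1):(hi - hit_start)] <- TRUE
  }
  mean(covered)
}

# random z-score "matrix" fixture for thresholding tests
toy_zmatrix <- function(n_reg, n_tgt, seed) {
  set.seed(seed)
  z <- matrix(abs(rnorm(n_reg * n_tgt)), n_reg, n_tgt,
              dimnames = list(sprintf("r%02d", seq_len(n_reg)),
                              sprintf("t%02d", seq_len(n_tgt))))
  structure(list(regulator_ids = rownames(z), target_ids = colnames(z),
                 z = z, provenance = list(kind = "DTI",
                                          config = estimator_config())),
            class = "ZScoreMatrix")
}

# brute-force threshold sweep: smallest observed z whose cut reaches the
# target precision on the reduced graph (quadratic, assertion-grade)
oracle_threshold_sweep <- function(zmat, reference, target) {
  idx <- which(!is.na(zmat$z), arr.ind = TRUE)
  e <- data.frame(regulator = zmat$regulator_ids[idx[, 1]],
                  target = zmat$target_ids[idx[, 2]],
                  z = zmat$z[idx])
  known <- paste(reference$known_edges$regulator,
                 reference$known_edges$target)
  best <- NULL
  for (tau in sort(unique(e$z))) {
    sel <- e[e$z >= tau, ]
    red <- sel[sel$regulator %in% reference$regulators_with_targets &
                 sel$target %in% reference$targets_with_regulators, ]
    if (nrow(red) == 0) next
    prec <- mean(paste(red$regulator, red$target) %in% known)
    if (prec >= target) { best <- tau; break }
  }
  best
}

# Independent brute-force oracle for the pairwise directed-information form:
# builds the pooled sample sets explicitly and evaluates plug-in MI from raw
# frequency tables, entirely outside the package's estimator code.
oracle_dti <- function(x, y, match_samples) {
  N <- ncol(x)
  total <- 0
  for (n in 2:N) {
    now_t <- if (match_samples) 2:n else 1:n
    total <- total +
      oracle_mi_table(as.vector(x[, now_t]), as.vector(y[, now_t])) -
      oracle_mi_table(as.vector(x[, 2:n]), as.vector(y[, 1:(n - 1)]))
  }
  total
}

# conditional-entropy chain H(X|Y_lag) - H(X|Y_now) per step, pooled
oracle_dti_cond <- function(x, y) {
  N <- ncol(x)
  total <- 0
  for (n in 2:N) {
    xs <- as.vector(x[, 2:n])
    y_now <- as.vector(y[, 2:n]); y_lag <- as.vector(y[, 1:(n - 1)])
    h_cond <- function(a, b) oracle_entropy(a, b) - oracle_entropy(b)
    total <- total + h_cond(xs, y_lag) - h_cond(xs, y_now)
  }
  total
}

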