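revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("build_pwm count arithmetic and validation", {
  pwm <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0)
  expect_equal(unname(pwm$probs["A", 1]), 1.0)
  expect_equal(unname(pwm$probs["C", 2]), 1.0)
  pwm2 <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0.5)
  expect_equal(unname(pwm2$probs["A", 1]), 2.5 / 4)
  expect_equal(colSums(pwm2$probs), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(build_pwm(c("ACGT", "ACGTA")), "equal lengths")
  expect_error(build_pwm("ACGT"), "at least 2")
  expect_error(build_pwm(c("ACNT", "ACGT")), "only A, C, G, T")
})

test_that("information content: uniform 0, deterministic 2, half-half 1", {
  sites <- c("AACA", "AACC", "ACGA", "ACGC")  # pos1 A; pos2 A/C; pos4 A/C
  pwm <- build_pwm(sites, pseudocount = 0)
  ic <- pwm_information_content(pwm)
  expect_equal(ic[1], 2)
  expect_equal(ic[2], 1)
  uniform <- build_pwm(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 0)
  expect_equal(pwm_information_content(uniform), rep(0, 4),
               ignore_attr = TRUE)
})

consensus16 <- "TGACCTAGATCGGTCA"
site_set <- c(consensus16, "TGACCTAGATCGGTCA", "TGACCAAGATCGGTCA",
              "TGTCCTAGATCGGTCA", "TGACCTAGATCGGACA", "CGACCTAGATCGGTCA")

test_that("scan finds a planted consensus and respects strand symmetry", {
  set.seed(17)
  bg <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  seq_plus <- paste0(substr(bg, 1, 7), consensus16, substr(bg, 8, 37))
  pwm <- build_pwm(site_set)
  hits <- scan_sequence(pwm, seq_plus)
  expect_equal(hits$start[1], 7)
  expect_equal(hits$strand[1], "+")
  # reverse complement of the whole sequence: mirrored top hit, same score
  rc_hits <- scan_sequence(pwm, revcomp(seq_plus))
  expect_equal(rc_hits$score[1], hits$score[1], tolerance = 1e-12)
  expect_equal(rc_hits$strand[1], "-")
  expect_equal(rc_hits$start[1], nchar(seq_plus) - hits$end[1])
  # full mirrored list scores agree as multisets
  expect_equal(sort(rc_hits$score), sort(hits$score), tolerance = 1e-12)
})

test_that("scan equals an exhaustive offset-by-offset oracle", {
  set.seed(23)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  pwm <- build_pwm(site_set)
  hits <- scan_sequence(pwm, s)
  expect_equal(nrow(hits), 2 * (100 - 16 + 1))
  chars <- strsplit(s, "")[[1]]
  for (k in sample(nrow(hits), 25)) {
    h <- hits[k, ]
    win <- paste(chars[(h$start + 1):h$end], collapse = "")
    if (h$strand == "-") win <- revcomp(win)
    idx <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
    oracle <- sum(log(pwm$probs[cbind(idx, 1:16)] / 0.25))
    expect_equal(h$score, oracle, tolerance = 1e-12)
  }
  # sorted by score, ties by start then strand
  expect_true(all(diff(hits$score) <= 1e-12))
})

test_that("best_hit honors the threshold and defaults to the site floor", {
  pwm <- build_pwm(site_set)
  set.seed(29)
  noise <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  expect_null(best_hit(pwm, noise))  # background stays under the floor
  planted <- paste0(substr(noise, 1, 100), consensus16,
                    substr(noise, 117, 400))
  h <- best_hit(pwm, planted)
  expect_equal(h$start, 100)
  # threshold -Inf returns the top of the full scan
  expect_equal(best_hit(pwm, noise, threshold = -Inf)$score,
               scan_sequence(pwm, noise)$score[1])
  # every training site passes the full PWM at the default threshold
  thr <- pwm_site_threshold(pwm)
  for (s in site_set)
    expect_gte(scan_sequence(pwm, s)$score[1], thr)
  expect_gte(pwm_site_threshold(pwm, method = "resubstitution"), thr)
})

test_that("conservation_fraction equals the interval-union oracle", {
  hit <- data.frame(seq_id = "g", start = 100, end = 120)
  cons <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(seq_id = "g", start = m[, 1], end = m[, 2])
  }
  expect_equal(conservation_fraction(hit, cons(100, 120)), 1.0)
  expect_equal(conservation_fraction(hit, cons(110, 130)), 0.5)
  expect_equal(conservation_fraction(hit, cons(100, 105, 115, 130)), 0.5)
  # splitting an interval into adjacent pieces changes nothing
  expect_equal(conservation_fraction(hit, cons(100, 110, 110, 120)), 1.0)
  # randomized agreement with a positional-flags oracle
  set.seed(41)
  for (i in 1:200) {
    hs <- sample(0:300, 1); he <- hs + sample(8:30, 1)
    k <- sample(1:4, 1)
    st <- sample(0:320, k); en <- st + sample(1:60, k, replace = TRUE)
    df <- data.frame(seq_id = "g", start = st, end = en)
    expect_equal(
      conservation_fraction(data.frame(seq_id = "g", start = hs, end = he), df),
      oracle_union_overlap(hs, he, st, en), tolerance = 1e-12)
  }
  # intervals on another sequence are ignored
  other <- data.frame(seq_id = "h", start = 100, end = 120)
  expect_equal(conservation_fraction(hit, other), 0)
})

test_that("validate_interaction applies the strict >50% rule", {
  set.seed(53)
  noise <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  prom <- paste0(substr(noise, 1, 200), consensus16, substr(noise, 217, 400))
  cons_full <- data.frame(seq_id = "gX", start = 195, end = 230)
  d <- validate_interaction("tfQ", "gX", site_set, prom, cons_full)
  expect_true(d$accepted)
  expect_identical(d$reason, "ok")
  expect_equal(d$hit_start, 200)
  # exactly 50% covered: rejected (strict inequality)
  cons_half <- data.frame(seq_id = "gX", start = 208, end = 300)
  d2 <- validate_interaction("tfQ", "gX", site_set, prom, cons_half)
  expect_false(d2$accepted)
  expect_identical(d2$reason, "low_conservation")
  expect_equal(d2$conservation_fraction, 0.5)
  # no site above threshold
  d3 <- validate_interaction("tfQ", "gX", site_set, noise, cons_full)
  expect_false(d3$accepted)
  expect_identical(d3$reason, "no_site")
})

test_that("validated edges are a subset of the input edges", {
  grn <- simulate_topology(4, 30, 20, seed = 61)
  prom <- simulate_promoters(grn, plant_fraction = 0.5, seed = 61)
  edges <- grn$edges[, c("regulator", "target")]
  dec <- validate_edges(edges, prom$sites, prom$promoters, prom$conserved)
  expect_equal(nrow(dec), nrow(edges))
  acc <- dec[dec$accepted, ]
  expect_true(all(paste(acc$regulator, acc$target) %in%
                    paste(edges$regulator, edges$target)))
})

test_that("operon expansion adds downstream genes of led operons only", {
  accepted <- data.frame(regulator = c("A", "B"), target = c("g1", "g5"))
  operons <- list(c("g1", "g2", "g3"), c("g4", "g5"))
  out <- operon_expand(accepted, operons)
  added <- out[out$operon_derived, ]
  expect_setequal(paste(added$regulator, added$target), c("A g2", "A g3"))
  # g5 is mid-operon: no expansion from it
  expect_false("B g4" %in% paste(out$regulator, out$target))
  # target in no operon: unchanged
  out2 <- operon_expand(data.frame(regulator = "A", target = "q"), operons)
  expect_equal(nrow(out2), 1)
})
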