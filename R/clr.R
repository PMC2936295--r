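# Context likelihood of relatedness: background-correct the directed score
# matrix into cumulative z-scores, computed within the TF x gene matrix only.

#' Combine row and column z-scores into the cumulative z-score
#'
#' Negative components are clamped to zero before combining (only positive
#' deviations from the background indicate interaction); the cumulative score
#' is the quadratic mean sqrt((z_row^2 + z_col^2) / 2).
#'
#' @param z_row,z_col finite numerics (vectorized).
#' @return nonnegative cumulative z-score.
#' @export
combine_z <- function(z_row, z_col) {
  sqrt((pmax(z_row, 0)^2 + pmax(z_col, 0)^2) / 2)
}

#' CLR cumulative z-scores of a score matrix
#'
#' The null distribution for a regulator is taken to be its empirical row of
#' scores against all candidate targets, and symmetrically the column of a
#' target against all candidate regulators; both are restricted to the
#' TF x gene matrix. Each entry is z-scored against its row and its column
#' (sample standard deviation), components clamped at zero, and combined by
#' [combine_z()]. Rows or columns with fewer than 2 valid entries or zero
#' spread contribute a component of 0. Excluded (NA) entries, e.g.
#' self-pairs, take no part in the nulls and remain excluded.
#'
#' @param scores a [score_matrix()].
#' @return object of class `ZScoreMatrix` with fields `z` (matrix, NA where
#'   the source was excluded), `regulator_ids`, `target_ids` and `provenance`
#'   (the source kind and estimator settings).
#' @export
clr_zscores <- function(scores) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  s <- scores$scores
  if (length(s) == 0L || all(is.na(s))) stop("empty score matrix")

  zdim <- function(m) {
    mu <- apply(m, 1L, mean, na.rm = TRUE)
    sdev <- apply(m, 1L, stats::sd, na.rm = TRUE)
    nval <- rowSums(!is.na(m))
    z <- (m - mu) / sdev
    z[nval < 2L | !is.finite(sdev) | sdev == 0, ] <- 0
    pmax(z, 0)
  }
  zr <- zdim(s)
  zc <- t(zdim(t(s)))
  z <- combine_z(zr, zc)
  z[is.na(s)] <- NA_real_
  structure(list(regulator_ids = scores$regulator_ids,
                 target_ids = scores$target_ids,
                 z = z,
                 provenance = list(kind = scores$kind,
                                   config = scores$config)),
            class = "ZScoreMatrix")
}

#' @export
print.ZScoreMatrix <- function(x, ...) {
  cat("ZScoreMatrix:", length(x$regulator_ids), "regulators x",
      length(x$target_ids), "targets; source:", x$provenance$kind, "\n")
  invisible(x)
}
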