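# Time-course container and equidistant experiment selection.

#' Replicated equidistant time-course dataset
#'
#' Bundles one expression matrix (genes x time points) per experiment on a
#' shared, equidistant time grid. This is the input container for directed
#' information: each gene contributes one short series per experiment and the
#' series are pooled across experiments during estimation.
#'
#' @param experiments named list of numeric matrices, one per experiment, each
#'   genes x time points with rownames giving gene identifiers. All matrices
#'   must share the same genes (order included) and the same number of columns.
#' @param time_grid numeric vector of time stamps in minutes, strictly
#'   increasing and equidistant, length >= 2.
#'
#' @return an object of class `TimeCourseDataset` with fields `gene_ids`,
#'   `experiments` (list of matrices) and `time_grid`.
#' @export
time_course_dataset <- function(experiments, time_grid) {
  if (!is.list(experiments) || length(experiments) == 0L)
    stop("'experiments' must be a non-empty named list of matrices")
  if (is.null(names(experiments)) || anyDuplicated(names(experiments)))
    stop("experiments must have unique names")
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 2L)
    stop("time grid must have at least 2 points")
  d <- diff(time_grid)
  if (any(d <= 0) || max(abs(d - d[1L])) > 1e-8 * max(abs(d)))
    stop("time grid must be strictly increasing and equidistant")
  genes <- rownames(experiments[[1L]])
  if (is.null(genes) || anyDuplicated(genes))
    stop("experiment matrices need unique gene rownames")
  for (nm in names(experiments)) {
    m <- experiments[[nm]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("experiment '", nm, "' is not a numeric matrix")
    if (ncol(m) != length(time_grid))
      stop("experiment '", nm, "' has ", ncol(m),
           " columns but the time grid has ", length(time_grid), " points")
    if (!identical(rownames(m), genes))
      stop("experiment '", nm, "' does not share the common gene set/order")
    if (!all(is.finite(m)))
      stop("experiment '", nm, "' contains non-finite expression values")
  }
  structure(
    list(gene_ids = genes, experiments = experiments, time_grid = time_grid),
    class = "TimeCourseDataset"
  )
}

#' @export
print.TimeCourseDataset <- function(x, ...) {
  cat("TimeCourseDataset:", length(x$gene_ids), "genes,",
      length(x$experiments), "experiments,",
      length(x$time_grid), "time points (",
      paste(x$time_grid, collapse = ", "), "min )\n")
  invisible(x)
}

#' Extract one gene's series across all experiments
#'
#' @param dataset a [time_course_dataset()].
#' @param gene gene identifier.
#' @return numeric matrix, experiments x time points.
#' @export
gene_series <- function(dataset, gene) {
  stopifnot(inherits(dataset, "TimeCourseDataset"))
  if (!gene %in% dataset$gene_ids) stop("unknown gene id: ", gene)
  t(vapply(dataset$experiments, function(m) m[gene, ],
           numeric(length(dataset$time_grid))))
}

#' Not-a-knot cubic spline interpolation at a single point
#'
#' Solves the moment (second-derivative) system of the interpolating cubic
#' spline with not-a-knot end conditions: the third derivative is continuous
#' across the second and the second-to-last knot. With exactly 4 points this
#' is the unique interpolating cubic, so the routine reproduces polynomials
#' of degree <= 3 exactly; this property is what the test suite pins down.
#'
#' @param times numeric vector of distinct time stamps (minutes), any order.
#' @param values numeric vector of observations, same length.
#' @param target_time time at which to evaluate, inside `[min(times), max(times)]`.
#'
#' @return interpolated value (length-1 numeric). With fewer than 4 points the
#'   routine falls back to linear interpolation with a warning.
#' @export
spline_interpolate <- function(times, values, target_time) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (anyDuplicated(times)) stop("time points must be distinct")
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("non-finite input")
  o <- order(times); x <- times[o]; y <- values[o]
  n <- length(x)
  if (target_time < x[1L] || target_time > x[n])
    stop("target time ", target_time, " outside the observed range [",
         x[1L], ", ", x[n], "]; extrapolation is not supported")
  hit <- which(abs(x - target_time) < 1e-12)
  if (length(hit)) return(y[hit[1L]])
  if (n < 4L) {
    warning("fewer than 4 points; falling back to linear interpolation")
    return(stats::approx(x, y, xout = target_time)$y)
  }
  h <- diff(x)
  A <- matrix(0, n, n); b <- numeric(n)
  for (i in 2:(n - 1L)) {
    A[i, i - 1L] <- h[i - 1L]
    A[i, i]      <- 2 * (h[i - 1L] + h[i])
    A[i, i + 1L] <- h[i]
    b[i] <- 6 * ((y[i + 1L] - y[i]) / h[i] - (y[i] - y[i - 1L]) / h[i - 1L])
  }
  # not-a-knot: M''' continuous at x[2] and x[n-1]
  A[1L, 1:3] <- c(h[2L], -(h[1L] + h[2L]), h[1L])
  A[n, (n - 2L):n] <- c(h[n - 1L], -(h[n - 2L] + h[n - 1L]), h[n - 2L])
  M <- solve(A, b)
  i <- findInterval(target_time, x, rightmost.closed = TRUE)
  hi <- h[i]; dx0 <- target_time - x[i]; dx1 <- x[i + 1L] - target_time
  M[i] * dx1^3 / (6 * hi) + M[i + 1L] * dx0^3 / (6 * hi) +
    (y[i] - M[i] * hi^2 / 6) * dx1 / hi +
    (y[i + 1L] - M[i + 1L] * hi^2 / 6) * dx0 / hi
}

#' Select experiments on a required equidistant time grid
#'
#' Keeps experiments whose annotated arrays cover every required time point.
#' An experiment missing exactly the final required time is rescued when a
#' later time point (`interpolation_source`) is available and the experiment
#' has at least 4 time points in total: the missing value is then estimated
#' per gene by [spline_interpolate()]. All other experiments are dropped with
#' a message. Columns beyond the required grid are discarded.
#'
#' @param expr numeric matrix genes x arrays, colnames = array ids.
#' @param annotation data.frame with columns `array_id`, `experiment_id`,
#'   `time_min` mapping each array to an experiment and a time stamp.
#' @param required_times equidistant numeric vector of required times (minutes).
#' @param interpolation_source optional single time (minutes) usable to
#'   interpolate a missing final required time.
#'
#' @return a [time_course_dataset()] on `required_times`.
#' @export
select_equidistant <- function(expr, annotation, required_times,
                               interpolation_source = NULL) {
  required_times <- sort(as.numeric(required_times))
  if (length(required_times) < 2L)
    stop("need at least 2 required time points")
  d <- diff(required_times)
  if (max(abs(d - d[1L])) > 1e-8 * d[1L])
    stop("required times must be equidistant")
  need <- c("array_id", "experiment_id", "time_min")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  annotation$time_min <- as.numeric(annotation$time_min)
  if (anyDuplicated(annotation[, c("experiment_id", "time_min")]))
    stop("duplicate (experiment, time) annotation rows")
  missing_arrays <- setdiff(annotation$array_id, colnames(expr))
  if (length(missing_arrays))
    stop("annotated arrays absent from expression matrix: ",
         paste(missing_arrays, collapse = ", "))

  target <- required_times[length(required_times)]
  kept <- list()
  for (ex in unique(annotation$experiment_id)) {
    ann <- annotation[annotation$experiment_id == ex, , drop = FALSE]
    ann <- ann[order(ann$time_min), , drop = FALSE]
    times <- ann$time_min
    if (all(required_times %in% times)) {
      idx <- match(required_times, times)
      kept[[as.character(ex)]] <-
        expr[, ann$array_id[idx], drop = FALSE]
    } else if (!is.null(interpolation_source) &&
               identical(setdiff(required_times, times), target) &&
               interpolation_source %in% times &&
               length(times) >= 4L) {
      m <- expr[, ann$array_id, drop = FALSE]
      interp <- apply(m, 1L, function(v)
        spline_interpolate(times, v, target))
      head_idx <- match(required_times[-length(required_times)], times)
      kept[[as.character(ex)]] <-
        cbind(m[, head_idx, drop = FALSE], interp)
      message("experiment '", ex, "': interpolated t=", target,
              " min from ", length(times), " observed points")
    } else {
      message("experiment '", ex, "' dropped: times {",
              paste(times, collapse = ","), "} cannot satisfy the grid")
    }
  }
  if (length(kept) == 0L)
    stop("no experiment satisfies the required time grid")
  kept <- lapply(kept, function(m) {
    colnames(m) <- paste0("t", required_times)
    m
  })
  time_course_dataset(kept, required_times)
}
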