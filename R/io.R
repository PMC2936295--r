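# Readers and writers for the package's file dialects: expression +
# annotation TSV, score/z matrices, reference and edge lists, FASTA
# (via Biostrings), BED (via rtracklayer, converted to window-local 0-based
# half-open coordinates), operon lists and decision records.

.stop_at <- function(path, line, ...) {
  stop(path, if (!is.na(line)) paste0(":", line), ": ", ..., call. = FALSE)
}

.config_header <- function(config, kind = NULL) {
  paste0("# dtinet", if (!is.null(kind)) paste0(" kind=", kind),
         " method=", config$method, " bins=", config$bins,
         " order=", config$order, " bandwidth=", config$bandwidth)
}

#' Read an expression matrix (genes x arrays TSV)
#'
#' First column `gene_id`, remaining columns one per array.
#'
#' @param path TSV path.
#' @return numeric matrix, gene rownames, array colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id")
    .stop_at(path, 1L, "first column must be 'gene_id'")
  if (anyDuplicated(df$gene_id))
    .stop_at(path, NA, "duplicate gene ids: ",
             paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) .stop_at(path, NA, "non-numeric expression values")
  rownames(m) <- df$gene_id
  m
}

#' Read an array annotation table
#'
#' Columns `array_id`, `experiment_id`, `time_min` (integer minutes).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("array_id", "experiment_id", "time_min")
  if (!all(need %in% names(df)))
    .stop_at(path, 1L, "annotation needs columns: ",
             paste(need, collapse = ", "))
  if (anyDuplicated(df$array_id))
    .stop_at(path, NA, "duplicate array ids")
  df$time_min <- as.numeric(df$time_min)
  if (anyNA(df$time_min)) .stop_at(path, NA, "non-numeric time_min")
  df
}

#' Write expression matrix and annotation
#'
#' @param dataset a [time_course_dataset()].
#' @param expr_path,annot_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(dataset, expr_path, annot_path) {
  stopifnot(inherits(dataset, "TimeCourseDataset"))
  cols <- list(); ann <- list()
  for (ex in names(dataset$experiments)) {
    m <- dataset$experiments[[ex]]
    ids <- paste0(ex, "_t", dataset$time_grid)
    colnames(m) <- ids
    cols[[ex]] <- m
    ann[[ex]] <- data.frame(array_id = ids, experiment_id = ex,
                            time_min = dataset$time_grid)
  }
  full <- do.call(cbind, cols)
  df <- data.frame(gene_id = rownames(full), full, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(do.call(rbind, ann), annot_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, annot_path))
}

#' Read a reference network (two-column TSV: regulator, target)
#'
#' @param path TSV path.
#' @return a [reference_network()].
#' @export
read_reference <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("regulator", "target") %in% names(df)))
    .stop_at(path, 1L, "reference needs columns 'regulator' and 'target'")
  reference_network(df)
}

#' Write a reference network
#' @param reference a [reference_network()].
#' @param path output TSV path.
#' @export
write_reference <- function(reference, path) {
  utils::write.table(reference$known_edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(seqs)))
    .stop_at(path, NA, "duplicate FASTA headers: ",
             paste(unique(names(seqs)[duplicated(names(seqs))]),
                   collapse = ", "))
  out <- as.character(seqs)
  names(out) <- names(seqs)
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read conserved intervals from 3-column BED
#'
#' BED is 0-based half-open; the coordinates are kept in that convention,
#' window-local to each promoter sequence.
#'
#' @param path BED path.
#' @return data.frame `seq_id`, `start`, `end`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  # GRanges is 1-based closed; back to 0-based half-open
  df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad))
    .stop_at(path, bad[1L], "invalid interval (start >= end)")
  df
}

#' Write conserved intervals to 3-column BED
#' @param intervals data.frame `seq_id`, `start`, `end` (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  bad <- which(intervals$start < 0 | intervals$start >= intervals$end)
  if (length(bad))
    stop("invalid interval at row ", bad[1L], " (start >= end)")
  gr <- GenomicRanges::GRanges(
    intervals$seq_id,
    IRanges::IRanges(intervals$start + 1L, intervals$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read operons (one comma-separated ordered gene list per line)
#' @param path TSV path.
#' @return list of character vectors.
#' @export
read_operons <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  ops <- lapply(strsplit(lines, ","), trimws)
  for (i in seq_along(ops))
    if (length(ops[[i]]) < 1L || any(!nzchar(ops[[i]])))
      .stop_at(path, i, "empty gene id in operon")
  ops
}

#' Write operons
#' @param operons list of ordered character vectors.
#' @param path output path.
#' @export
write_operons <- function(operons, path) {
  writeLines(vapply(operons, paste, character(1L), collapse = ","), path)
  invisible(path)
}

#' Write a score or z matrix as TSV with a provenance header
#' @param mat a `ScoreMatrix` or `ZScoreMatrix`.
#' @param path output path.
#' @export
write_score_matrix <- function(mat, path) {
  if (inherits(mat, "ScoreMatrix")) {
    m <- mat$scores; hdr <- .config_header(mat$config, mat$kind)
  } else if (inherits(mat, "ZScoreMatrix")) {
    m <- mat$z
    hdr <- paste0(.config_header(mat$provenance$config,
                                 mat$provenance$kind), " stat=clr_z")
  } else stop("not a ScoreMatrix or ZScoreMatrix")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(regulator = rownames(m), m, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score/z matrix TSV written by [write_score_matrix()]
#' @param path input path.
#' @return list `matrix`, `header` (the provenance line).
#' @export
read_score_matrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$regulator
  list(matrix = m, header = hdr)
}

#' Write an edge list (regulator, target, z, known as 0/1)
#' @param edges data.frame from the thresholding layer.
#' @param path output path.
#' @param config optional [estimator_config()] recorded in the header.
#' @export
write_edges <- function(edges, path, config = NULL) {
  out <- edges
  if ("known" %in% names(out)) out$known <- as.integer(out$known)
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(config)) writeLines(.config_header(config), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edges()]
#' @param path input path.
#' @return data.frame with logical `known` (if present).
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if ("known" %in% names(df)) df$known <- df$known == 1
  df
}

#' Write motif-validation decision records
#' @param decisions data.frame from [validate_edges()].
#' @param path output path.
#' @export
write_decisions <- function(decisions, path) {
  out <- decisions
  out$accepted <- as.integer(out$accepted)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
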