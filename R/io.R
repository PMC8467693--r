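#' Read a feature-by-sample expression matrix
#'
#' Parses a tab-separated table whose first column holds feature identifiers
#' and whose header row holds sample identifiers. Empty cells, `NA`, `NaN`
#' and `nan` are treated as missing; any other non-numeric cell is an error
#' that names the offending feature and sample. Duplicated feature or sample
#' identifiers are rejected.
#'
#' @param path Path to a tab-separated file (UTF-8, `.` decimal separator).
#' @param datatype One of `"mRNA"` or `"protein"`; stored as the matrix's
#'   `datatype` attribute and used downstream to pick default significance
#'   thresholds.
#' @param transpose If `TRUE` the file is read as samples-in-rows and
#'   transposed to the package's features-in-rows orientation.
#' @return A numeric matrix (features x samples) with `NA` for missing
#'   entries and a `datatype` attribute.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, datatype = c("mRNA", "protein"),
                                   transpose = FALSE) {
  datatype <- match.arg(datatype)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a feature id column plus >=1 sample column", call. = FALSE)
  feature_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) stop(sprintf("duplicated feature id '%s' in %s", dup[1L], path), call. = FALSE)
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) stop(sprintf("duplicated sample id '%s' in %s", dup_s[1L], path), call. = FALSE)
  mat <- parse_numeric_cells(raw[, -1L, drop = FALSE], feature_ids, sample_ids)
  if (transpose) {
    mat <- t(mat)
  }
  attr(mat, "datatype") <- datatype
  mat
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written at full double precision so write-then-read is the
#' identity, including the missingness mask (`NA` cells round-trip as `NA`).
#'
#' @param mat Numeric matrix, features in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  chr <- matrix(format_full(mat), nrow = nrow(mat))
  lines <- c(paste(c("feature_id", colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i) {
               paste(c(rownames(mat)[i], chr[i, ]), collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical event-free-survival table
#'
#' Expects tab-separated columns `sample_id`, `time_months`, `event`.
#' Patients whose follow-up time or censoring status is missing are dropped
#' and counted (the count is reported via a message and the `n_dropped`
#' attribute), mirroring the usual cohort pre-processing in which patients
#' without survival annotation are removed before analysis.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with columns `sample_id` (character), `time_months`
#'   (positive numeric) and `event` (integer 0/1), plus attribute
#'   `n_dropped`.
#' @export
read_clinical_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  missing_cols <- setdiff(need, colnames(raw))
  if (length(missing_cols)) {
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  incomplete <- raw$time_months %in% MISSING_SPELLINGS | raw$event %in% MISSING_SPELLINGS
  n_dropped <- sum(incomplete)
  if (n_dropped > 0L) {
    message(sprintf("read_clinical_table: dropped %d patient(s) with missing survival annotation", n_dropped))
  }
  raw <- raw[!incomplete, , drop = FALSE]
  time_months <- suppressWarnings(as.numeric(raw$time_months))
  event_num <- suppressWarnings(as.numeric(raw$event))
  if (anyNA(time_months)) stop("non-numeric time_months entry", call. = FALSE)
  if (any(time_months <= 0)) stop("time_months must be strictly positive", call. = FALSE)
  if (anyNA(event_num) || !all(event_num %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (event observed)", call. = FALSE)
  }
  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup)) stop(sprintf("duplicated sample id '%s' in clinical table", dup[1L]), call. = FALSE)
  out <- data.frame(sample_id = raw$sample_id,
                    time_months = time_months,
                    event = as.integer(event_num),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a clinical table
#' @param clinical Data.frame as returned by [read_clinical_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  stopifnot(all(c("sample_id", "time_months", "event") %in% colnames(clinical)))
  lines <- c("sample_id\ttime_months\tevent",
             sprintf("%s\t%s\t%d", clinical$sample_id,
                     format_full(clinical$time_months), clinical$event))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. The
#' description is ignored and members are de-duplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return A named list mapping pathway name to a character vector of unique
#'   member identifiers.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty gene-set file: ", path, call. = FALSE)
    return(structure(list(), names = character(0)))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    name <- fields[[1L]]
    if (name %in% names(sets)) stop(sprintf("duplicated gene-set name '%s'", name), call. = FALSE)
    sets[[name]] <- unique(fields[-c(1L, 2L)])
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-pathway coefficient matrix
#'
#' Tab-separated, genes in rows and pathways in columns; the weights are the
#' "z-coefficients" that map responsive-gene expression onto pathway
#' activity. Zeros are kept (a zero weight means the gene is not responsive
#' for that pathway); a pathway column that is entirely zero is retained but
#' flagged with a warning. Missing or non-numeric cells are errors.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes x pathways) with finite entries.
#' @export
read_coefficient_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("coefficient matrix needs a gene id column plus >=1 pathway column", call. = FALSE)
  gene_ids <- raw[[1L]]
  pathway_ids <- colnames(raw)[-1L]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop(sprintf("duplicated gene id '%s' in %s", dup[1L], path), call. = FALSE)
  W <- parse_numeric_cells(raw[, -1L, drop = FALSE], gene_ids, pathway_ids,
                           allow_missing = FALSE)
  if (!all(is.finite(W))) stop("coefficient matrix must be finite", call. = FALSE)
  zero_cols <- colnames(W)[colSums(W != 0) == 0L]
  if (length(zero_cols)) {
    warning("pathway column(s) with all-zero weights: ",
            paste(zero_cols, collapse = ", "), call. = FALSE)
  }
  W
}

#' Write a coefficient matrix as tab-separated text
#' @param W Numeric matrix, genes in rows, pathways in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficient_matrix <- function(W, path) {
  stopifnot(is.matrix(W), !is.null(rownames(W)), !is.null(colnames(W)))
  chr <- matrix(format_full(W), nrow = nrow(W))
  lines <- c(paste(c("gene_id", colnames(W)), collapse = "\t"),
             vapply(seq_len(nrow(W)), function(i) {
               paste(c(rownames(W)[i], chr[i, ]), collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

# Align an expression matrix and a clinical table on their shared sample ids,
# preserving the matrix's sample order and logging discarded ids.
align_samples <- function(mat, clinical, quiet = FALSE) {
  shared <- intersect(colnames(mat), clinical$sample_id)
  if (!length(shared)) stop("no shared sample ids between expression and clinical data", call. = FALSE)
  dropped <- setdiff(union(colnames(mat), clinical$sample_id), shared)
  if (length(dropped) && !quiet) {
    message(sprintf("align_samples: %d id(s) absent from one table discarded", length(dropped)))
  }
  shared <- colnames(mat)[colnames(mat) %in% shared]
  list(matrix = mat[, shared, drop = FALSE],
       clinical = clinical[match(shared, clinical$sample_id), , drop = FALSE],
       dropped = dropped)
}
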