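#' Read a tab-delimited log2 expression matrix
#'
#' First column holds probe identifiers, the header row holds sample
#' identifiers. All cells must be finite numerics; duplicate probe or sample
#' identifiers are an error (no collapse policy — upstream summarisation is
#' assumed done).
#'
#' @param path Path to a tab-delimited text file.
#' @return Numeric matrix, probes in rows (rownames), samples in columns
#'   (colnames), log2 scale.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) stop("expression file needs a probe column plus >= 1 sample column")
  probes <- as.character(df[[1L]])
  dup <- probes[duplicated(probes)]
  if (length(dup)) stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite value at probe row %d ('%s'), sample column '%s'",
                   bad[1L], probes[bad[1L]], names(vals)[j]))
    }
    vals[[j]] <- v
  }
  mat <- as.matrix(vals)
  rownames(mat) <- probes
  dupc <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dupc)) stop("duplicate sample id(s): ", paste(unique(dupc), collapse = ", "))
  mat
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression()]; values are written with 15 significant
#' digits so a read/write round trip is exact to at least 12.
#'
#' @param mat Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @param comment Optional character vector of header comment lines
#'   (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, comment = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("probe_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(format(mat, digits = 15, trim = TRUE, scientific = FALSE), 1L,
                paste, collapse = "\t")
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

.receptor_levels <- c("parental", "TRA", "TRB")
.ligand_levels <- c("vehicle", "T3")

#' Validate a sample design sheet
#'
#' A design is a data.frame with one row per sample and columns
#' `sample_id`, `cell_line`, `receptor` (parental/TRA/TRB), `ligand`
#' (vehicle/T3), `dose_nM`, `time_hr`, `chx` (logical), `replicate`.
#'
#' @param design Data frame to validate.
#' @return The design, with factor-like columns normalised to character,
#'   invisibly usable downstream.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "cell_line", "receptor", "ligand", "dose_nM",
            "time_hr", "chx", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         design$sample_id[duplicated(design$sample_id)][1L])
  design$receptor <- as.character(design$receptor)
  design$ligand <- as.character(design$ligand)
  if (!all(design$receptor %in% .receptor_levels))
    stop("receptor must be one of ", paste(.receptor_levels, collapse = "/"))
  if (!all(design$ligand %in% .ligand_levels))
    stop("ligand must be one of ", paste(.ligand_levels, collapse = "/"))
  if (!is.logical(design$chx)) design$chx <- as.logical(design$chx)
  if (anyNA(design$chx)) stop("chx must be logical")
  if (any(design$dose_nM < 0)) stop("dose_nM must be >= 0")
  if (any(design$time_hr < 0)) stop("time_hr must be >= 0")
  if (any(design$ligand == "vehicle" & design$dose_nM != 0))
    stop("vehicle samples must have dose_nM = 0")
  if (any(design$replicate < 1)) stop("replicate must be a positive integer")
  design
}

#' Read / write a design sheet
#'
#' Tab-delimited, one row per sample, columns as in [validate_design()].
#'
#' @param path File path.
#' @rdname design_io
#' @return `read_design`: validated design data.frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_design(df)
}

#' @param design Design data.frame.
#' @param comment Optional `#`-prefixed header lines.
#' @rdname design_io
#' @export
write_design <- function(design, path, comment = NULL) {
  design <- validate_design(design)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(design, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a matrix and a design describe the same samples
#'
#' @param mat Expression matrix (samples in columns).
#' @param design Design sheet.
#' @return The design reordered to match the matrix columns.
#' @export
align_design <- function(mat, design) {
  design <- validate_design(design)
  if (!setequal(colnames(mat), design$sample_id))
    stop("matrix sample ids and design sample_id differ: ",
         paste(union(setdiff(colnames(mat), design$sample_id),
                     setdiff(design$sample_id, colnames(mat))), collapse = ", "))
  design[match(colnames(mat), design$sample_id), , drop = FALSE]
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the row-wise mean of the per-column sorted values. Within-column ranks
#' are preserved; tied values all receive the mean of the reference values
#' their rank span covers.
#'
#' @param mat Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape; every column has the identical sorted
#'   value multiset (up to tie averaging).
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 samples")
  if (any(!is.finite(mat))) stop("matrix contains non-finite values")
  ref <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    o <- order(mat[, j])
    xs <- mat[o, j]
    grp <- cumsum(c(TRUE, diff(xs) != 0))
    out[o, j] <- as.numeric(tapply(ref, grp, mean))[grp]
  }
  out
}
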