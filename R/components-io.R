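#' Write spectral or principal components in .eigenvec layout
#'
#' Writes a whitespace-delimited, header-free table with one row per sample:
#' `FID IID <prefix>1 ... <prefix>k`, FID duplicated from IID, at full
#' precision (15 significant digits) — the layout PC-consuming GWAS tools
#' expect as a covariate file.
#'
#' @param x A [spectral_basis] object, a covariate tibble whose first column
#'   is `sample_id`, or a plain matrix with rownames.
#' @param path Output path.
#' @param label_prefix Column label prefix, e.g. `"SPC"` or `"PC"`.
#' @return `path`, invisibly.
#' @export
write_components <- function(x, path, label_prefix = "SPC") {
  if (inherits(x, "spectral_basis")) {
    ids <- x$sample_ids
    mat <- x$vectors
  } else if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    mat <- as.matrix(x[, -1, drop = FALSE])
  } else {
    ids <- rownames(x)
    if (is.null(ids)) abort("matrix input needs rownames as sample ids.")
    mat <- x
  }
  if (nrow(mat) != length(ids)) abort("component row count != sample count.")
  df <- data.frame(FID = ids, IID = ids)
  if (ncol(mat) > 0) {
    vals <- as.data.frame(format(mat, digits = 15, scientific = TRUE,
                                 trim = TRUE))
    names(vals) <- paste0(label_prefix, seq_len(ncol(mat)))
    df <- cbind(df, vals)
  }
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read a .eigenvec-style component file
#'
#' @param path Path written by [write_components()] or PLINK.
#' @param label_prefix Prefix used to name the component columns.
#' @return A tibble: `sample_id` followed by the component columns.
#' @export
read_components <- function(path, label_prefix = "SPC") {
  df <- utils::read.table(path, header = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  k <- ncol(df) - 2
  out <- tibble(sample_id = as.character(df[[2]]))
  if (k > 0) {
    comps <- as_tibble(df[, -(1:2), drop = FALSE])
    names(comps) <- paste0(label_prefix, seq_len(k))
    out <- dplyr::bind_cols(out, comps)
  }
  out
}

#' Read a PLINK-convention phenotype or covariate table
#'
#' Whitespace-delimited `FID IID value...` with or without a header row.
#'
#' @param path File path.
#' @param value_names Optional names for the value columns (used when the
#'   file has no header).
#' @return A tibble: `sample_id` followed by value columns.
#' @export
read_phenotypes <- function(path, value_names = NULL) {
  first <- readLines(path, n = 1)
  toks <- strsplit(trimws(first), "\\s+")[[1]]
  has_header <- toupper(toks[1]) %in% c("FID", "IID", "#FID")
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  out <- tibble(sample_id = as.character(df[[2]]))
  vals <- as_tibble(df[, -(1:2), drop = FALSE])
  if (!is.null(value_names)) names(vals) <- value_names
  if (!has_header && is.null(value_names)) {
    names(vals) <- paste0("value", seq_len(ncol(vals)))
    if (ncol(vals) == 1) names(vals) <- "value"
  }
  dplyr::bind_cols(out, vals)
}
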