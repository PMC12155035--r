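#' Read an IBD segment file
#'
#' Parses a delimited text file of pairwise IBD segments into a tidy segment
#' table. Self-pairs (`id_a == id_b`, e.g. the two haplotypes of one diploid
#' individual) are dropped with a message, as are records on non-autosomal
#' chromosomes; both counts are attached as attributes. Coordinates are
#' 1-based inclusive base pairs and the genetic length is taken verbatim from
#' the file, never recomputed.
#'
#' @param path Path to the segment file (plain text or gzipped).
#' @param dialect An [ibd_dialect()] object or preset name
#'   (`"ilash"`, `"generic6"`).
#'
#' @return A tibble with columns `id_a`, `id_b` (character), `chromosome`
#'   (integer, 1-22), `start_bp`, `end_bp` (double), `length_cM` (double),
#'   one row per retained segment. Attributes `n_self_dropped` and
#'   `n_nonautosomal_dropped` record filtered rows.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("S1\tS2\t7\t1000000\t9000000\t6.5",
#'              "S1\tS1\t7\t1000000\t9000000\t6.5"), f)
#' seg <- read_ibd_segments(f, "generic6")
#' nrow(seg)  # 1; the self-pair is dropped
#' @export
read_ibd_segments <- function(path, dialect = "generic6") {
  if (!file.exists(path)) abort(sprintf("IBD file not found: '%s'", path))
  dialect <- as_ibd_dialect(dialect)
  cm <- dialect$column_map

  sep <- if (identical(dialect$delimiter, "")) "auto" else dialect$delimiter
  dt <- data.table::fread(
    path,
    sep = sep, header = FALSE, skip = if (isTRUE(dialect$has_header)) 1L else 0L,
    colClasses = "character", data.table = FALSE, showProgress = FALSE
  )
  if (nrow(dt) == 0) {
    return(empty_segments())
  }
  if (ncol(dt) < max(cm)) {
    abort(sprintf(
      "IBD file has %d columns but dialect requires at least %d.",
      ncol(dt), max(cm)
    ))
  }

  seg <- tibble(
    id_a = as.character(dt[[cm["id_a"]]]),
    id_b = as.character(dt[[cm["id_b"]]]),
    chromosome_raw = dt[[cm["chromosome"]]],
    start_bp = suppressWarnings(as.numeric(dt[[cm["start_bp"]]])),
    end_bp = suppressWarnings(as.numeric(dt[[cm["end_bp"]]])),
    length_cM = suppressWarnings(as.numeric(dt[[cm["length_cM"]]]))
  )

  bad <- which(
    is.na(seg$start_bp) | is.na(seg$end_bp) | is.na(seg$length_cM) |
      seg$length_cM < 0 | seg$end_bp <= seg$start_bp
  )
  if (length(bad) > 0) {
    abort(sprintf(
      paste0("Malformed IBD record at data row %d: coordinates must be ",
             "numeric with end_bp > start_bp and length_cM >= 0."),
      bad[1]
    ))
  }

  # tolerate "chr7"-style prefixes; non-autosomes (X, Y, MT, 23+) are dropped
  chrom <- suppressWarnings(as.integer(sub("^[Cc]hr", "", seg$chromosome_raw)))
  autosomal <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  self <- seg$id_a == seg$id_b

  n_self <- sum(self & autosomal)
  n_nonauto <- sum(!autosomal)
  keep <- autosomal & !self
  if (n_self > 0) {
    inform(sprintf("Dropped %d self-pair segment(s).", n_self))
  }
  if (n_nonauto > 0) {
    inform(sprintf("Dropped %d non-autosomal segment(s).", n_nonauto))
  }

  out <- seg[keep, c("id_a", "id_b", "start_bp", "end_bp", "length_cM")]
  out$chromosome <- chrom[keep]
  out <- out[, c("id_a", "id_b", "chromosome", "start_bp", "end_bp", "length_cM")]
  attr(out, "n_self_dropped") <- n_self
  attr(out, "n_nonautosomal_dropped") <- n_nonauto
  out
}

empty_segments <- function() {
  out <- tibble(
    id_a = character(), id_b = character(), chromosome = integer(),
    start_bp = double(), end_bp = double(), length_cM = double()
  )
  attr(out, "n_self_dropped") <- 0L
  attr(out, "n_nonautosomal_dropped") <- 0L
  out
}

#' Write IBD segments in the generic six-column layout
#'
#' Companion writer for [read_ibd_segments()] using the `"generic6"` dialect
#' (`id_a id_b chromosome start_bp end_bp length_cM`, tab separated, no
#' header).
#'
#' @param segments Segment tibble as returned by [read_ibd_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibd_segments <- function(segments, path) {
  df <- as.data.frame(segments[, c(
    "id_a", "id_b", "chromosome", "start_bp", "end_bp", "length_cM"
  )])
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
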