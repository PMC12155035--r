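#' Describe the column layout of an IBD segment file
#'
#' IBD detection tools write segment tables in tool-specific column orders.
#' An `ibd_dialect` maps the six roles the relatedness-graph pipeline needs
#' (`id_a`, `id_b`, `chromosome`, `start_bp`, `end_bp`, `length_cM`) to
#' 1-based column positions of a delimited text file.
#'
#' Two presets ship with the package:
#' \describe{
#'   \item{`"ilash"`}{the 11-column iLASH layout
#'     (`fam_a id_a fam_b id_b chr start_bp end_bp snp_a snp_b length_cM score`);
#'     family-ID columns are ignored because the graph is keyed by individual.}
#'   \item{`"generic6"`}{the six roles in order
#'     (`id_a id_b chromosome start_bp end_bp length_cM`), the layout the
#'     simulation module writes.}
#' }
#'
#' @param preset Name of a built-in preset, or `NULL` when supplying
#'   `column_map` directly.
#' @param column_map Named integer vector mapping all six roles to distinct
#'   1-based column indices. Overrides `preset`.
#' @param delimiter Field delimiter; default any whitespace (`""`).
#' @param has_header Does the file carry a header row to skip?
#'
#' @return An object of class `ibd_dialect`.
#' @examples
#' ibd_dialect("ilash")
#' ibd_dialect(column_map = c(
#'   id_a = 2, id_b = 1, chromosome = 3,
#'   start_bp = 4, end_bp = 5, length_cM = 6
#' ))
#' @export
ibd_dialect <- function(preset = "generic6", column_map = NULL,
                        delimiter = "", has_header = FALSE) {
  roles <- c("id_a", "id_b", "chromosome", "start_bp", "end_bp", "length_cM")
  if (is.null(column_map)) {
    presets <- ibd_dialect_presets()
    if (!preset %in% names(presets)) {
      abort(sprintf(
        "Unknown IBD dialect preset '%s'. Available presets: %s.",
        preset, paste(names(presets), collapse = ", ")
      ))
    }
    return(presets[[preset]])
  }
  if (!all(roles %in% names(column_map))) {
    abort(paste0(
      "column_map must name all six roles: ",
      paste(roles, collapse = ", ")
    ))
  }
  column_map <- as.integer(column_map[roles])
  if (anyNA(column_map) || any(column_map < 1)) {
    abort("column_map entries must be positive integers.")
  }
  if (anyDuplicated(column_map)) {
    abort("column_map must assign distinct columns to the six roles.")
  }
  structure(
    list(
      column_map = setNames(column_map, roles),
      delimiter = delimiter,
      has_header = has_header,
      preset_name = if (is.null(preset)) NA_character_ else preset
    ),
    class = "ibd_dialect"
  )
}

#' Built-in IBD dialect presets
#'
#' @return Named list of `ibd_dialect` objects.
#' @export
ibd_dialect_presets <- function() {
  list(
    ilash = structure(
      list(
        column_map = c(
          id_a = 2L, id_b = 4L, chromosome = 5L,
          start_bp = 6L, end_bp = 7L, length_cM = 10L
        ),
        delimiter = "\t", has_header = FALSE, preset_name = "ilash"
      ),
      class = "ibd_dialect"
    ),
    generic6 = structure(
      list(
        column_map = c(
          id_a = 1L, id_b = 2L, chromosome = 3L,
          start_bp = 4L, end_bp = 5L, length_cM = 6L
        ),
        delimiter = "", has_header = FALSE, preset_name = "generic6"
      ),
      class = "ibd_dialect"
    )
  )
}

#' @export
print.ibd_dialect <- function(x, ...) {
  cat("<ibd_dialect", if (!is.na(x$preset_name)) paste0("'", x$preset_name, "'"),
      ">\n")
  cat("  columns:",
      paste(names(x$column_map), x$column_map, sep = "=", collapse = " "), "\n")
  invisible(x)
}

as_ibd_dialect <- function(x) {
  if (inherits(x, "ibd_dialect")) return(x)
  if (is.character(x) && length(x) == 1) return(ibd_dialect(x))
  abort("dialect must be an ibd_dialect object or a preset name.")
}
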