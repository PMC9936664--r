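#' Assemble an analysis dataset from report and metadata
#'
#' Binds a peak report and its sample metadata into the container all pipeline
#' steps operate on: a peak annotation table, a peaks-by-samples raw intensity
#' matrix, and the normalization state.
#'
#' @param report An `ftms_report` from [read_report()] (or the equivalent
#'   tibble from [generate_report()]).
#' @param metadata Tibble from [read_metadata()] with `sample_id` plus 1-2
#'   grouping columns.
#' @param grouping Character vector of grouping column names; defaults to all
#'   non-`sample_id` columns of `metadata`.
#' @return An object of class `ftms_data`: a list with elements `peaks`
#'   (tibble), `intensities` (raw matrix, peaks x samples), `normalized`
#'   (matrix or `NULL`), `normalization` (`"raw"` or a method label),
#'   `metadata`, `grouping`.
#' @export
ftms_data <- function(report, metadata, grouping = NULL) {
  if (is.null(grouping)) grouping <- setdiff(names(metadata), "sample_id")
  if (length(grouping) < 1L || length(grouping) > 2L) {
    stop("grouping must name 1 or 2 metadata columns", call. = FALSE)
  }
  missing <- setdiff(grouping, names(metadata))
  if (length(missing)) {
    stop("grouping column(s) not in metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- metadata$sample_id
  available <- attr(report, "sample_ids") %||% setdiff(
    names(report),
    c("peak_id", "mass", "C", "H", "N", "O", "P", "S", "has_c13", "error_ppm",
      "has_formula")
  )
  absent <- setdiff(samples, available)
  if (length(absent)) {
    stop("metadata sample(s) absent from report: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  peaks <- report[, c("peak_id", "mass", "C", "H", "N", "O", "P", "S",
                      "has_c13", "error_ppm", "has_formula")]
  peaks <- tibble::as_tibble(peaks)
  mat <- as.matrix(report[, samples, drop = FALSE])
  mode(mat) <- "double"
  rownames(mat) <- peaks$peak_id
  structure(
    list(
      peaks = peaks,
      intensities = mat,
      normalized = NULL,
      normalization = "raw",
      metadata = metadata,
      grouping = grouping,
      filter_audit = NULL
    ),
    class = "ftms_data"
  )
}

#' @export
print.ftms_data <- function(x, ...) {
  cat("<ftms_data> ", nrow(x$peaks), " peaks x ", ncol(x$intensities),
      " samples\n", sep = "")
  cat("  formulas assigned: ", sum(x$peaks$has_formula), "\n", sep = "")
  cat("  normalization: ", x$normalization, "\n", sep = "")
  cat("  grouping: ", paste(x$grouping, collapse = ", "), "\n", sep = "")
  if (!is.null(x$filter_audit)) {
    cat("  filtered (removed ", sum(x$filter_audit$removed), " peaks)\n", sep = "")
  }
  invisible(x)
}

# group label vector aligned with sample columns, for a single grouping column
group_of <- function(x, column = x$grouping[1]) {
  idx <- match(colnames(x$intensities), x$metadata$sample_id)
  as.character(x$metadata[[column]][idx])
}

# matrix to use for distance-based statistics
active_matrix <- function(x) {
  if (is.null(x$normalized)) x$intensities else x$normalized
}
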