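#' Normalize an intensity matrix column-by-column
#'
#' Applies one of the six supported normalization methods to each sample
#' column independently. Zeros encode "peak not detected in this sample":
#' they are excluded from the column statistics (max, min, mean, median, sum,
#' sd) and remain exactly 0 after normalization, so absences never drag the
#' location estimates and stay recognizable downstream.
#'
#' Per detected value x in a sample column (v = detected values of the
#' column):
#' \itemize{
#'   \item `max`: x / max(v)
#'   \item `minmax`: (x - min(v)) / (max(v) - min(v))
#'   \item `mean`: (x - mean(v)) / (max(v) - min(v))
#'   \item `median`: (x - median(v)) / (max(v) - min(v))
#'   \item `sum`: x / sum(v) (detected values then sum to 1)
#'   \item `zscore`: (x - mean(v)) / sd(v)
#' }
#'
#' @param mat Non-negative numeric matrix, peaks x samples.
#' @param method One of `"max"`, `"minmax"`, `"mean"`, `"median"`, `"sum"`,
#'   `"zscore"`.
#' @return Matrix of the same shape.
#' @export
normalize_columns <- function(mat, method) {
  method <- match.arg(method, NORM_METHODS)
  if (any(mat < 0)) stop("raw intensities must be non-negative", call. = FALSE)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    det <- x > 0
    if (!any(det)) next  # empty sample: nothing to scale
    v <- x[det]
    rng <- max(v) - min(v)
    if (method %in% c("minmax", "mean", "median") && rng == 0) {
      stop("constant intensity column (division by zero) in sample '",
           colnames(mat)[j], "' under method '", method, "'", call. = FALSE)
    }
    y <- switch(method,
      max = v / max(v),
      minmax = (v - min(v)) / rng,
      mean = (v - mean(v)) / rng,
      median = (v - median(v)) / rng,
      sum = v / sum(v),
      zscore = {
        if (length(v) < 2L || sd(v) == 0) {
          stop("cannot z-score sample '", colnames(mat)[j],
               "': fewer than 2 distinct detected intensities", call. = FALSE)
        }
        (v - mean(v)) / sd(v)
      }
    )
    x[det] <- y
    out[, j] <- x
  }
  out
}

#' Normalize the intensities of a dataset
#'
#' @param x An `ftms_data` object with `normalization == "raw"`.
#' @param method Normalization method, see [normalize_columns()]. Defaults to
#'   the method in `config` if supplied.
#' @param config Optional `ftms_config`.
#' @return `x` with `x$normalized` filled and `x$normalization` set.
#' @export
normalize_intensities <- function(x, method = NULL, config = NULL) {
  stopifnot(inherits(x, "ftms_data"))
  if (!identical(x$normalization, "raw")) {
    stop("data already normalized with method '", x$normalization, "'",
         call. = FALSE)
  }
  method <- method %||% config$normalization_method
  x$normalized <- normalize_columns(x$intensities, method)
  x$normalization <- method
  x
}
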