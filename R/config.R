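#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#'
#' @param mass_window Numeric length-2, closed mass window in Da used by the
#'   peak filter. Default `c(200, 900)`, the m/z range where direct-injection
#'   FT-ICR MS of natural organic matter is typically informative.
#' @param error_max_ppm Maximum absolute formula-assignment error in ppm
#'   (inclusive). Default 0.5.
#' @param presence_min Minimum number of samples a peak must be detected in
#'   (intensity > 0). An integer, or a fraction in (0, 1) of the number of
#'   samples (rounded up). Default 1.
#' @param normalization_method One of `"max"`, `"minmax"`, `"mean"`,
#'   `"median"`, `"sum"`, `"zscore"`.
#' @param grouping Character vector (length 1-2) of metadata column names.
#' @param transformation_key Path to a transformation key CSV or `"builtin"`.
#' @param ppm_tolerance Mass-difference matching tolerance in ppm (relative to
#'   the key's mass difference). Default 1.
#' @param rng_seed Integer seed governing every stochastic step (permutations,
#'   NMDS restarts). Default 1.
#' @return A list of class `ftms_config`.
#' @export
run_config <- function(mass_window = c(200, 900),
                       error_max_ppm = 0.5,
                       presence_min = 1,
                       normalization_method = "max",
                       grouping = "Group1",
                       transformation_key = "builtin",
                       ppm_tolerance = 1,
                       rng_seed = 1L) {
  stopifnot(
    is.numeric(mass_window), length(mass_window) == 2L,
    mass_window[1] < mass_window[2],
    is.numeric(error_max_ppm), error_max_ppm > 0,
    is.numeric(presence_min), presence_min > 0,
    is.numeric(ppm_tolerance), ppm_tolerance > 0
  )
  normalization_method <- match.arg(normalization_method, NORM_METHODS)
  if (length(grouping) < 1L || length(grouping) > 2L) {
    stop("grouping must name 1 or 2 metadata columns", call. = FALSE)
  }
  structure(
    list(
      mass_window = as.numeric(mass_window),
      error_max_ppm = error_max_ppm,
      presence_min = presence_min,
      normalization_method = normalization_method,
      grouping = grouping,
      transformation_key = transformation_key,
      ppm_tolerance = ppm_tolerance,
      rng_seed = as.integer(rng_seed)
    ),
    class = "ftms_config"
  )
}

# canonical method order; also the tie-break order for recommendations
NORM_METHODS <- c("max", "minmax", "mean", "median", "sum", "zscore")
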