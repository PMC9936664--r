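#' Score normalization methods for group bias (SPANS-style grid)
#'
#' For every combination of a peak-subset method and a normalization method,
#' measures how strongly the per-sample normalization factors computed from
#' that subset are associated with the experimental groups. A normalization
#' whose factors track the groups would remove (or inject) biological signal,
#' so less association is better.
#'
#' Subset methods, applied to log10 intensities of detected peaks:
#' \itemize{
#'   \item `all`: every peak;
#'   \item `top` with fraction L in 0.05/0.10/0.20/0.50: the union over
#'     samples of each sample's top-L order statistics;
#'   \item `presence` with proportion p in 0.5/0.75/1.0: peaks detected in at
#'     least p of the samples.
#' }
#' For each cell the per-sample factors implied by the normalization method
#' (its location statistic, plus the scale statistic for `zscore`) are
#' computed on the subset, each factor vector is tested against the group
#' labels with a Kruskal-Wallis test (midranks, tie-corrected chi-square
#' approximation), and the score is the mean of log10 p over the method's
#' factors: 0 means no detectable bias, large negative means the factors
#' separate the groups. This scoring is a reimplementation in the spirit of
#' the SPANS procedure, not a port of any existing code.
#'
#' @param x An `ftms_data` object (raw intensities are used).
#' @param grouping Metadata column to test against; defaults to the first
#'   grouping variable.
#' @param top_fractions,presence_props Subset parameter grids.
#' @param methods Normalization methods to score.
#' @return Tibble with columns `subset_method`, `parameter`,
#'   `normalization_method`, `n_subset_peaks`, `score` (NA for empty
#'   subsets).
#' @export
spans_grid <- function(x, grouping = x$grouping[1],
                       top_fractions = c(0.05, 0.10, 0.20, 0.50),
                       presence_props = c(0.5, 0.75, 1.0),
                       methods = NORM_METHODS) {
  stopifnot(inherits(x, "ftms_data"))
  groups <- group_of(x, grouping)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups for SPANS scoring", call. = FALSE)
  if (any(tab < 2L)) {
    stop("every group needs at least 2 samples (offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), ")", call. = FALSE)
  }

  mat <- x$intensities
  lmat <- log10(ifelse(mat > 0, mat, NA))  # NA = not detected
  n_samples <- ncol(mat)

  subsets <- list(list(method = "all", parameter = NA_real_,
                       peaks = seq_len(nrow(mat))))
  for (L in top_fractions) {
    sel <- logical(nrow(mat))
    for (j in seq_len(n_samples)) {
      v <- lmat[, j]
      det <- which(!is.na(v))
      if (!length(det)) next
      k <- ceiling(L * length(det))
      sel[det[order(v[det], decreasing = TRUE)[seq_len(k)]]] <- TRUE
    }
    subsets <- c(subsets, list(list(method = "top", parameter = L,
                                    peaks = which(sel))))
  }
  for (p in presence_props) {
    need <- ceiling(p * n_samples)
    sel <- which(rowSums(!is.na(lmat)) >= need)
    subsets <- c(subsets, list(list(method = "presence", parameter = p,
                                    peaks = sel)))
  }

  rows <- list()
  for (sub in subsets) {
    sub_l <- lmat[sub$peaks, , drop = FALSE]
    for (m in methods) {
      factors <- norm_factors(sub_l, m)
      score <- if (is.null(factors)) {
        NA_real_
      } else {
        ps <- vapply(factors, kw_pvalue, numeric(1), groups = groups)
        if (anyNA(ps)) NA_real_ else mean(log10(ps))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subset_method = sub$method, parameter = sub$parameter,
        normalization_method = m, n_subset_peaks = length(sub$peaks),
        score = score
      )
    }
  }
  dplyr::bind_rows(rows)
}

# per-sample normalization factors on a log10 submatrix (NA = absent).
# Returns a list of factor vectors (one per factor the method defines), or
# NULL when the subset is empty / some sample has no detected peak in it.
norm_factors <- function(sub_l, method) {
  if (nrow(sub_l) == 0L) return(NULL)
  det_per_sample <- colSums(!is.na(sub_l))
  if (any(det_per_sample == 0L)) return(NULL)
  loc <- switch(method,
    max = apply(sub_l, 2, max, na.rm = TRUE),
    minmax = apply(sub_l, 2, min, na.rm = TRUE),
    mean = colMeans(sub_l, na.rm = TRUE),
    median = apply(sub_l, 2, median, na.rm = TRUE),
    sum = log10(colSums(10^sub_l, na.rm = TRUE)),
    zscore = colMeans(sub_l, na.rm = TRUE)
  )
  if (method == "zscore") {
    if (any(det_per_sample < 2L)) return(NULL)
    scl <- apply(sub_l, 2, sd, na.rm = TRUE)
    list(location = loc, scale = scl)
  } else {
    list(location = loc)
  }
}

# Kruskal-Wallis p-value of a factor vector vs group labels; constant
# factors carry no group information, so p = 1 (the no-bias limit).
kw_pvalue <- function(f, groups) {
  if (anyNA(f)) return(NA_real_)
  if (length(unique(f)) == 1L) return(1)
  kruskal.test(f, factor(groups))$p.value
}

#' Recommend a normalization method from a SPANS-style grid
#'
#' @param grid Output of [spans_grid()].
#' @return The normalization method of the highest-scoring cell. Ties are
#'   broken by the canonical method order (max, minmax, mean, median, sum,
#'   zscore).
#' @export
recommend_method <- function(grid) {
  ok <- !is.na(grid$score)
  if (!any(ok)) stop("no defined SPANS scores in grid", call. = FALSE)
  g <- grid[ok, ]
  ord <- order(-g$score, match(g$normalization_method, NORM_METHODS))
  g$normalization_method[ord[1]]
}
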