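#' Between-sample distance matrix
#'
#' Computes sample-by-sample dissimilarities from the active (normalized if
#' available, else raw) intensity matrix via `vegan::vegdist`. When no metric
#' is given it is chosen from the normalization state: signed normalizations
#' (`zscore`, `mean`, `median`) force Euclidean distances, non-negative ones
#' (`max`, `minmax`, `sum`, raw) use Bray-Curtis; Jaccard (on
#' presence/absence) is available on request only.
#'
#' @param x An `ftms_data` object.
#' @param metric `"bray_curtis"`, `"euclidean"` or `"jaccard"`, or `NULL` to
#'   choose from the normalization method.
#' @return A `stats::dist` object with attribute `metric`.
#' @export
compute_distance <- function(x, metric = NULL) {
  stopifnot(inherits(x, "ftms_data"))
  if (is.null(metric)) {
    metric <- if (x$normalization %in% c("zscore", "mean", "median"))
      "euclidean" else "bray_curtis"
  }
  metric <- match.arg(metric, c("bray_curtis", "euclidean", "jaccard"))
  m <- t(active_matrix(x))  # samples in rows
  d <- switch(metric,
    bray_curtis = {
      if (any(m < 0)) {
        stop("Bray-Curtis requires non-negative intensities; the '",
             x$normalization, "' normalization produces signed values - use ",
             "metric = \"euclidean\"", call. = FALSE)
      }
      vegan::vegdist(m, method = "bray")
    },
    euclidean = vegan::vegdist(m, method = "euclidean"),
    jaccard = vegan::vegdist(m > 0, method = "jaccard", binary = TRUE)
  )
  attr(d, "metric") <- metric
  d
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson's pseudo-F on
#' the partitioned squared distances), delegated to `vegan::adonis2` with
#' sequential (type I) sums of squares. With two grouping variables the model
#' includes both main effects and their interaction, in the order given.
#' Permutations are free permutations of rows; the p-value is
#' (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param d A `dist` object from [compute_distance()].
#' @param metadata Sample metadata tibble (must cover all samples of `d`).
#' @param grouping Character vector (1-2) of metadata columns.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return Tibble with one row per model term plus residual/total: `term`,
#'   `df`, `sum_sq`, `r2`, `pseudo_f`, `p_perm`; attribute `n_perm`.
#' @export
permanova <- function(d, metadata, grouping, n_perm = 999, seed = 1L) {
  stopifnot(inherits(d, "dist"), n_perm >= 99)
  if (all(d == 0)) stop("degenerate distance matrix: all distances are zero",
                        call. = FALSE)
  ids <- attr(d, "Labels")
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all samples", call. = FALSE)
  for (g in grouping) {
    tab <- table(meta[[g]])
    if (length(tab) < 2L || any(tab < 2L)) {
      stop("PERMANOVA needs >= 2 groups with >= 2 samples each in '", g, "'",
           call. = FALSE)
    }
  }
  rhs <- if (length(grouping) == 2L) {
    paste(grouping[1], "*", grouping[2])
  } else {
    grouping[1]
  }
  df <- as.data.frame(meta)
  set.seed(seed)
  fit <- vegan::adonis2(as.formula(paste("d ~", rhs)), data = df,
                        permutations = n_perm, by = "terms")
  out <- tibble::tibble(
    term = rownames(fit),
    df = fit$Df,
    sum_sq = fit$SumOfSqs,
    r2 = fit$R2,
    pseudo_f = fit$F,
    p_perm = fit$`Pr(>F)`
  )
  attr(out, "n_perm") <- n_perm
  out
}

#' Magnitude-averaged thermodynamic indices per sample
#'
#' Intensity-weighted mean of each index over the detected formula-bearing
#' peaks of every sample: sum(I_i * index_i) / sum(I_i) on raw intensities.
#'
#' @param x An annotated `ftms_data` object.
#' @param indices Index columns to average.
#' @return Tibble `sample_id` + one column per index.
#' @export
magnitude_averaged_indices <- function(x, indices = c("NOSC", "GFE", "AImod", "DBE")) {
  stopifnot(inherits(x, "ftms_data"), all(indices %in% names(x$peaks)))
  f <- x$peaks$has_formula
  mat <- x$intensities[f, , drop = FALSE]
  out <- tibble::tibble(sample_id = colnames(mat))
  for (ix in indices) {
    vals <- x$peaks[[ix]][f]
    out[[ix]] <- vapply(seq_len(ncol(mat)), function(j) {
      w <- mat[, j]
      keep <- w > 0 & !is.na(vals)
      if (!any(keep)) return(NA_real_)
      sum(w[keep] * vals[keep]) / sum(w[keep])
    }, numeric(1))
  }
  out
}

# per-sample compound-class percentages (of detected formula peaks)
class_percent_by_sample <- function(x) {
  f <- x$peaks$has_formula
  cls <- x$peaks$compound_class[f]
  det <- x$intensities[f, , drop = FALSE] > 0
  classes <- sort(unique(cls))
  out <- sapply(classes, function(cl) colSums(det[cls == cl, , drop = FALSE]))
  out <- out / pmax(rowSums(out), 1) * 100
  tibble::as_tibble(cbind(tibble::tibble(sample_id = colnames(det)),
                          as.data.frame(out)))
}

run_pca <- function(tbl, what) {
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  const <- apply(m, 2, function(v) var(v) == 0 || anyNA(v))
  if (any(const)) {
    warning("dropping constant/NA variable(s) from ", what, " PCA: ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) == 0L) {
    # identical samples: no variance anywhere, scores collapse to the origin
    return(list(method = "PCA",
                scores = matrix(0, nrow(m), 1,
                                dimnames = list(rownames(m), "PC1")),
                loadings = matrix(numeric(), 0, 1, dimnames = list(NULL, "PC1")),
                explained_variance = numeric(0)))
  }
  fit <- prcomp(m, center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2
  list(
    method = "PCA",
    scores = fit$x,
    loadings = fit$rotation,
    explained_variance = ev / sum(ev)
  )
}

#' PCA summaries of composition and magnitude-averaged indices
#'
#' Two principal component analyses of the samples: one on the per-sample
#' compound-class percentage table, one on the per-sample magnitude-averaged
#' NOSC/GFE/AImod/DBE. Variables are standardized to zero mean and unit
#' variance before the eigendecomposition; constant variables are dropped
#' with a warning.
#'
#' @param x An annotated `ftms_data` object with >= 3 samples.
#' @return List of two PCA results (`composition`, `indices`), each a list
#'   with `scores`, `loadings` and `explained_variance` (fractions summing
#'   to 1).
#' @export
pca_summaries <- function(x) {
  stopifnot(inherits(x, "ftms_data"))
  if (ncol(x$intensities) < 3L) stop("PCA needs at least 3 samples", call. = FALSE)
  list(
    composition = run_pca(class_percent_by_sample(x), "composition"),
    indices = run_pca(magnitude_averaged_indices(x), "index")
  )
}
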