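#' Relative abundances of detected peaks in one sample
#'
#' Sum-normalizes the raw intensities of the peaks detected in a sample.
#' Chemodiversity always works from raw intensities, whatever normalization
#' the rest of the pipeline uses: diversity indices are defined on relative
#' abundances, and location-shifting normalizations would destroy them.
#'
#' @param x An `ftms_data` object.
#' @param sample_id Sample to extract.
#' @return Named numeric vector p (names = peak ids) with `sum(p) == 1`.
#' @export
relative_abundance <- function(x, sample_id) {
  stopifnot(inherits(x, "ftms_data"))
  if (!sample_id %in% colnames(x$intensities)) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  v <- x$intensities[, sample_id]
  det <- v > 0
  if (!any(det)) stop("sample '", sample_id, "' has no detected peaks", call. = FALSE)
  p <- v[det] / sum(v[det])
  setNames(p, x$peaks$peak_id[det])
}

#' Bias-corrected Chao1 richness estimator
#'
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)), where F1 and F2 are the numbers of
#' singleton and doubleton species.
#'
#' @param counts Vector of positive integer counts (one per observed species).
#' @return Estimated richness (always >= the observed richness).
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 1))
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Abundance-based diversity of one abundance vector
#'
#' Shannon index (nats), Gini-Simpson index and the bias-corrected Chao1
#' richness estimator. Chao1 is defined for counts; raw intensities are
#' converted to pseudo-counts by dividing by the smallest positive intensity
#' of the sample and rounding, so the faintest detected peak plays the role
#' of a singleton.
#'
#' @param p Probability vector from [relative_abundance()].
#' @param raw Raw intensity vector over the same peaks (for Chao1
#'   pseudo-counts). If omitted, Chao1 falls back to the richness.
#' @return Tibble with `richness`, `shannon`, `gini_simpson`, `chao1`.
#' @export
abundance_diversity <- function(p, raw = NULL) {
  stopifnot(all(p > 0), abs(sum(p) - 1) < 1e-8)
  s <- length(p)
  shannon <- -sum(p * log(p))
  gini <- 1 - sum(p^2)
  ch <- s
  if (!is.null(raw)) {
    stopifnot(length(raw) == s, all(raw > 0))
    ch <- chao1(pmax(1, round(raw / min(raw))))
  }
  tibble::tibble(richness = s, shannon = shannon, gini_simpson = gini,
                 chao1 = ch)
}

#' Rao's quadratic entropy of one sample for a trait set
#'
#' Q = sum_ij d_ij p_i p_j, the expected trait distance between two peaks
#' drawn with replacement by relative abundance. Distances are Gower
#' dissimilarities (equal trait weights, per-trait range scaling, so d is in
#' \[0, 1\]). Abundances are restricted to formula-bearing peaks (traits are
#' undefined otherwise) and renormalized.
#'
#' @param p Named probability vector ([relative_abundance()]).
#' @param traits Data frame of numeric traits with rownames = peak ids.
#' @return The scalar Q (0 when all traits are identical or fewer than 2
#'   peaks carry traits, with a warning in the latter case).
#' @export
rao_entropy <- function(p, traits) {
  common <- intersect(names(p), rownames(traits))
  if (length(common) < 2L) {
    warning("fewer than 2 peaks with traits; Rao Q = 0", call. = FALSE)
    return(0)
  }
  p <- p[common] / sum(p[common])
  tr <- traits[common, , drop = FALSE]
  keep <- vapply(tr, function(v) length(unique(v)) > 1L, logical(1))
  if (!any(keep)) return(0)  # all traits constant: zero functional diversity
  d <- as.matrix(cluster::daisy(tr[, keep, drop = FALSE], metric = "gower"))
  drop(p %*% d %*% p)
}

# trait tables per trait set, rownames = peak_id, formula peaks only
trait_table <- function(x, trait_set) {
  f <- x$peaks$has_formula
  cols <- switch(trait_set,
    elemental_composition = c("C", "H", "O", "N", "S", "P"),
    insaturation_aromaticity = c("DBE", "AImod"),
    reactivity = "GFE",
    stop("unknown trait set: ", trait_set, call. = FALSE)
  )
  missing <- setdiff(cols, names(x$peaks))
  if (length(missing)) stop("annotate_peaks() required before trait-based diversity",
                            call. = FALSE)
  tr <- as.data.frame(x$peaks[f, cols, drop = FALSE])
  rownames(tr) <- x$peaks$peak_id[f]
  tr
}

#' Chemodiversity summary of every sample
#'
#' Per sample: richness, Shannon, Gini-Simpson and Chao1 on sum-normalized
#' raw intensities, plus Rao's quadratic entropy for the three trait sets
#' (elemental composition C/H/O/N/S/P; insaturation and aromaticity DBE +
#' AImod; reactivity GFE).
#'
#' @param x An annotated `ftms_data` object.
#' @return List with `abundance` (tibble: sample_id + abundance metrics) and
#'   `functional` (long tibble: sample_id, trait_set, rao_q).
#' @export
diversity_summary <- function(x) {
  stopifnot(inherits(x, "ftms_data"))
  samples <- colnames(x$intensities)
  traits <- lapply(
    c(elemental_composition = "elemental_composition",
      insaturation_aromaticity = "insaturation_aromaticity",
      reactivity = "reactivity"),
    function(ts) trait_table(x, ts)
  )
  ab_rows <- list(); fn_rows <- list()
  for (s in samples) {
    v <- x$intensities[, s]
    if (!any(v > 0)) {
      ab_rows[[s]] <- tibble::tibble(sample_id = s, richness = 0L, shannon = 0,
                                     gini_simpson = 0, chao1 = 0)
      next
    }
    p <- relative_abundance(x, s)
    ab_rows[[s]] <- dplyr::bind_cols(tibble::tibble(sample_id = s),
                                     abundance_diversity(p, raw = v[v > 0]))
    for (ts in names(traits)) {
      q <- suppressWarnings(rao_entropy(p, traits[[ts]]))
      fn_rows[[paste(s, ts)]] <- tibble::tibble(sample_id = s, trait_set = ts,
                                                rao_q = q)
    }
  }
  list(abundance = dplyr::bind_rows(ab_rows), functional = dplyr::bind_rows(fn_rows))
}

#' Rank-abundance table
#'
#' @param x An `ftms_data` object.
#' @return Tibble `sample_id`, `rank`, `peak_id`, `rel_abundance`, sorted by
#'   decreasing relative abundance within each sample.
#' @export
rank_abundance <- function(x) {
  rows <- lapply(colnames(x$intensities), function(s) {
    v <- x$intensities[, s]
    if (!any(v > 0)) return(NULL)
    p <- sort(relative_abundance(x, s), decreasing = TRUE)
    tibble::tibble(sample_id = s, rank = seq_along(p), peak_id = names(p),
                   rel_abundance = unname(p))
  })
  dplyr::bind_rows(rows)
}
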