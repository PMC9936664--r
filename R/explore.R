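#' Per-sample diagnostic counts
#'
#' Counts, for each sample, the number of peaks detected after filtering and
#' how many of them carry an assigned molecular formula. A sample with an
#' unusually low formula count relative to the rest of the run is a candidate
#' outlier.
#'
#' @param x A filtered `ftms_data` object.
#' @return Tibble `sample_id`, `n_peaks`, `n_with_formula`, `is_min_formula`
#'   (flags the sample(s) with the fewest assigned formulas).
#' @export
diagnostics_counts <- function(x) {
  stopifnot(inherits(x, "ftms_data"))
  det <- x$intensities > 0
  n_peaks <- colSums(det)
  n_formula <- colSums(det & x$peaks$has_formula)
  tibble::tibble(
    sample_id = colnames(x$intensities),
    n_peaks = as.integer(n_peaks),
    n_with_formula = as.integer(n_formula),
    is_min_formula = unname(n_formula == min(n_formula))
  )
}

#' Assignment-error distribution per sample
#'
#' Long table of (mass, assignment error) for every detected formula-bearing
#' peak, backing per-sample error scatterplots.
#'
#' @param x An `ftms_data` object.
#' @return Tibble `sample_id`, `peak_id`, `mass`, `error_ppm`.
#' @export
assignment_error_table <- function(x) {
  stopifnot(inherits(x, "ftms_data"))
  f <- x$peaks$has_formula & !is.na(x$peaks$error_ppm)
  det <- x$intensities[f, , drop = FALSE] > 0
  idx <- which(det, arr.ind = TRUE)
  tibble::tibble(
    sample_id = colnames(det)[idx[, 2]],
    peak_id = x$peaks$peak_id[f][idx[, 1]],
    mass = x$peaks$mass[f][idx[, 1]],
    error_ppm = x$peaks$error_ppm[f][idx[, 1]]
  ) |> dplyr::arrange(.data$sample_id, .data$mass)
}

# peak x group detection (TRUE if detected in >= 1 sample of the group, or in
# all samples when rule = "all")
group_membership <- function(x, grouping = x$grouping[1], rule = c("any", "all")) {
  rule <- match.arg(rule)
  groups <- group_of(x, grouping)
  det <- x$intensities > 0
  cols <- lapply(unique(groups), function(g) {
    sub <- det[, groups == g, drop = FALSE]
    if (rule == "any") rowSums(sub) > 0 else rowSums(sub) == ncol(sub)
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(x$peaks$peak_id, unique(groups))
  out
}

#' Molecular and elemental composition per group
#'
#' For every group, the percentage of detected formula-bearing peaks falling
#' in each compound class and in each element class (CHO, CHON, ...).
#' Percentages within a group sum to 100.
#'
#' @param x An annotated `ftms_data` object (see [annotate_peaks()]).
#' @param grouping Metadata column; defaults to the first grouping variable.
#' @return List of two tibbles, `compound_class` and `element_class`, each
#'   with columns `group`, the class label, `n` and `percent`.
#' @export
composition_summary <- function(x, grouping = x$grouping[1]) {
  stopifnot(inherits(x, "ftms_data"), "compound_class" %in% names(x$peaks))
  member <- group_membership(x, grouping)
  f <- x$peaks$has_formula
  one <- function(class_col) {
    rows <- lapply(colnames(member), function(g) {
      classes <- x$peaks[[class_col]][f & member[, g]]
      if (!length(classes)) return(NULL)
      tab <- table(classes)
      out <- tibble::tibble(group = g, class = names(tab), n = as.integer(tab),
                            percent = 100 * as.integer(tab) / sum(tab))
      names(out)[2] <- class_col
      out
    })
    dplyr::bind_rows(rows)
  }
  list(compound_class = one("compound_class"), element_class = one("element_class"))
}

#' Pairwise shared/unique peak comparisons between groups
#'
#' A peak belongs to a group when it is detected in at least one sample of
#' that group (or in all samples, with `rule = "all"`). For every unordered
#' pair of groups the shared and unique peak sets are reported, together with
#' a compound-class breakdown per set and the full presence/absence
#' membership matrix for upset-style plotting.
#'
#' @param x An annotated `ftms_data` object.
#' @param grouping Metadata column.
#' @param rule Group-membership rule, `"any"` (default) or `"all"`.
#' @return List with `comparisons` (tibble with list-columns `shared`,
#'   `unique_a`, `unique_b` and counts), `class_breakdown` (long tibble) and
#'   `membership` (peaks x groups logical tibble). With a single group the
#'   comparison table is empty (with a warning).
#' @export
pairwise_compare <- function(x, grouping = x$grouping[1], rule = c("any", "all")) {
  stopifnot(inherits(x, "ftms_data"))
  rule <- match.arg(rule)
  member <- group_membership(x, grouping, rule)
  groups <- colnames(member)
  membership_tbl <- dplyr::bind_cols(
    tibble::tibble(peak_id = rownames(member)),
    tibble::as_tibble(as.data.frame(member))
  )
  if (length(groups) < 2L) {
    warning("only one group; no pairwise comparisons", call. = FALSE)
    return(list(comparisons = tibble::tibble(), class_breakdown = tibble::tibble(),
                membership = membership_tbl))
  }
  class_of <- setNames(
    if ("compound_class" %in% names(x$peaks)) x$peaks$compound_class
    else rep(NA_character_, nrow(x$peaks)),
    x$peaks$peak_id
  )
  pairs <- combn(groups, 2)
  comp_rows <- list(); class_rows <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    in_a <- member[, a]; in_b <- member[, b]
    sets <- list(
      shared = rownames(member)[in_a & in_b],
      unique_a = rownames(member)[in_a & !in_b],
      unique_b = rownames(member)[!in_a & in_b]
    )
    comp_rows[[k]] <- tibble::tibble(
      group_a = a, group_b = b,
      n_shared = length(sets$shared),
      n_unique_a = length(sets$unique_a),
      n_unique_b = length(sets$unique_b),
      shared = list(sets$shared),
      unique_a = list(sets$unique_a),
      unique_b = list(sets$unique_b)
    )
    for (set_name in names(sets)) {
      cls <- class_of[sets[[set_name]]]
      cls <- cls[!is.na(cls) & cls != "Unassigned"]
      if (length(cls)) {
        tab <- table(cls)
        class_rows[[length(class_rows) + 1L]] <- tibble::tibble(
          group_a = a, group_b = b, set = set_name,
          compound_class = names(tab), n = as.integer(tab)
        )
      }
    }
  }
  list(
    comparisons = dplyr::bind_rows(comp_rows),
    class_breakdown = dplyr::bind_rows(class_rows),
    membership = membership_tbl
  )
}

#' Group tests on thermodynamic indices (ANOVA + Tukey HSD)
#'
#' The observation unit is one (peak, sample) occurrence: every detected
#' formula-bearing peak contributes its index value once per sample it is
#' detected in, unweighted by intensity. Each index is tested with a one-way
#' ANOVA across groups followed by Tukey's honest significant difference over
#' all group pairs (family-wise adjusted p per index).
#'
#' @param x An annotated `ftms_data` object.
#' @param grouping Metadata column.
#' @param indices Which indices to test.
#' @return List with `anova` (tibble: index, df_between, df_within, F, p) and
#'   `tukey` (tibble: index, group_a, group_b, diff, lwr, upr, p_adj).
#'   Indices where some group has fewer than 2 observations are skipped with
#'   a warning.
#' @export
index_group_tests <- function(x, grouping = x$grouping[1],
                              indices = c("NOSC", "GFE", "AImod", "DBE")) {
  stopifnot(inherits(x, "ftms_data"), all(indices %in% names(x$peaks)))
  groups <- group_of(x, grouping)
  f <- x$peaks$has_formula
  det <- x$intensities[f, , drop = FALSE] > 0
  idx_long <- which(det, arr.ind = TRUE)
  obs_group <- factor(groups[idx_long[, 2]])
  anova_rows <- list(); tukey_rows <- list()
  for (ix in indices) {
    vals <- x$peaks[[ix]][f][idx_long[, 1]]
    ok <- !is.na(vals)
    tab <- table(obs_group[ok])
    if (length(tab) < 2L || any(tab < 2L)) {
      warning("index ", ix, " skipped: a group has fewer than 2 observations",
              call. = FALSE)
      next
    }
    d <- data.frame(value = vals[ok], group = droplevels(obs_group[ok]))
    fit <- aov(value ~ group, data = d)
    s <- summary(fit)[[1]]
    anova_rows[[ix]] <- tibble::tibble(
      index = ix, df_between = s$Df[1], df_within = s$Df[2],
      anova_F = s$`F value`[1], anova_p = s$`Pr(>F)`[1]
    )
    tk <- TukeyHSD(fit)$group
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    tukey_rows[[ix]] <- tibble::tibble(
      index = ix,
      group_a = vapply(cmp, `[`, "", 1),
      group_b = vapply(cmp, `[`, "", 2),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"]
    )
  }
  list(anova = dplyr::bind_rows(anova_rows), tukey = dplyr::bind_rows(tukey_rows))
}

#' Van Krevelen scatter data
#'
#' O/C, H/C, class and group for every detected formula-bearing peak; the
#' data behind van Krevelen diagrams.
#'
#' @param x An annotated `ftms_data` object.
#' @param grouping Metadata column.
#' @return Tibble `peak_id`, `group`, `OC`, `HC`, `compound_class`, `NOSC`,
#'   `GFE`.
#' @export
van_krevelen_data <- function(x, grouping = x$grouping[1]) {
  member <- group_membership(x, grouping)
  f <- x$peaks$has_formula
  rows <- lapply(colnames(member), function(g) {
    sel <- f & member[, g]
    tibble::tibble(
      peak_id = x$peaks$peak_id[sel], group = g,
      OC = x$peaks$OC[sel], HC = x$peaks$HC[sel],
      compound_class = x$peaks$compound_class[sel],
      NOSC = x$peaks$NOSC[sel], GFE = x$peaks$GFE[sel]
    )
  })
  dplyr::bind_rows(rows)
}
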