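#' Specification for a synthetic Formularity-style report
#'
#' Defines the ground truth of a synthetic direct-injection FT-ICR MS report:
#' random CHNOPS formulas with exact monoisotopic masses, log-normal
#' intensities with optional per-group fold changes, per-cell dropout,
#' carbon-13 isotopologue rows and formula-less rows to exercise the filters,
#' and planted transformation ladders (e.g. a CH2 homologous series) that
#' guarantee known network edges.
#'
#' @param n_samples Number of samples (default 12).
#' @param groups Character vector of group labels per sample (default an even
#'   A/B split).
#' @param groups2 Optional second grouping variable (labels per sample).
#' @param n_peaks Number of random formula-bearing peaks (default 800).
#' @param formula_bounds Named list of `c(min, max)` count bounds for C, H,
#'   O, N, S, P.
#' @param planted_series List of `list(base = , key = , length = )` entries:
#'   `base` a formula string or named count vector, `key` a transformation
#'   name from the builtin key, `length` the number of successive additions.
#' @param group_effect Named numeric: log10 fold change applied to each
#'   group's intensities (default all 0).
#' @param effect_fraction Fraction of peaks carrying the group effect
#'   (default 1 = a global per-group scaling).
#' @param noise_sd Log10-intensity standard deviation (default 0.4).
#' @param dropout_rate Probability that a peak is absent from a sample
#'   (default 0.1).
#' @param frac_no_formula Fraction (of `n_peaks`) of extra rows without an
#'   assigned formula (default 0.05).
#' @param frac_c13 Fraction of random peaks flagged as 13C isotopologues
#'   (default 0.05).
#' @param frac_bad_error Fraction of random peaks given an assignment error
#'   beyond 0.5 ppm (default 0.02).
#' @param mass_jitter_ppm Uniform mass jitter in ppm applied to random peaks
#'   (default 0; planted series are never jittered so their edges stay
#'   exact). Must be <= 0.2.
#' @param seed Integer seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples = 12,
                         groups = rep(c("A", "B"), length.out = n_samples),
                         groups2 = NULL,
                         n_peaks = 800,
                         formula_bounds = list(C = c(4, 40), O = c(0, 25),
                                               N = c(0, 3), S = c(0, 2), P = c(0, 1)),
                         planted_series = list(),
                         group_effect = setNames(rep(0, length(unique(groups))),
                                                 unique(groups)),
                         effect_fraction = 1,
                         noise_sd = 0.4,
                         dropout_rate = 0.1,
                         frac_no_formula = 0.05,
                         frac_c13 = 0.05,
                         frac_bad_error = 0.02,
                         mass_jitter_ppm = 0,
                         seed = 1L) {
  stopifnot(
    length(groups) == n_samples,
    is.null(groups2) || length(groups2) == n_samples,
    dropout_rate >= 0, dropout_rate <= 1,
    frac_no_formula >= 0, frac_no_formula <= 1,
    frac_c13 >= 0, frac_c13 <= 1,
    effect_fraction >= 0, effect_fraction <= 1,
    mass_jitter_ppm >= 0, mass_jitter_ppm <= 0.2
  )
  structure(as.list(environment()), class = "fixture_spec")
}

resolve_counts <- function(base) {
  if (is.character(base)) parse_formula(base)
  else {
    counts <- setNames(integer(length(ELEMENTS)), ELEMENTS)
    counts[names(base)] <- as.integer(base)
    counts
  }
}

#' Generate a synthetic report with known ground truth
#'
#' Draws the dataset described by a [fixture_spec()]. Masses are computed
#' from the element counts with IUPAC monoisotopic atomic masses; planted
#' transformation ladders are appended with exact masses and no dropout so
#' that the matcher's expected edges are known by construction. Regenerating
#' with the same spec is deterministic.
#'
#' @param spec A [fixture_spec()].
#' @return List with `report` (an `ftms_report` tibble, directly usable by
#'   [ftms_data()] or writable with [write_report()]), `metadata` (tibble),
#'   and `truth` (list: `series` tibble of planted ladder peaks/edges,
#'   `affected_peaks`, `group_effect`).
#' @export
generate_report <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_peaks
  b <- spec$formula_bounds

  C <- sample(b$C[1]:b$C[2], n, replace = TRUE)
  O <- pmin(vapply(C, function(cc) sample(0:min(b$O[2], cc), 1), integer(1)), b$O[2])
  N <- sample(b$N[1]:b$N[2], n, replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)[seq_len(b$N[2] - b$N[1] + 1)])
  S <- sample(b$S[1]:b$S[2], n, replace = TRUE, prob = c(0.85, 0.10, 0.05)[seq_len(b$S[2] - b$S[1] + 1)])
  P <- sample(b$P[1]:b$P[2], n, replace = TRUE, prob = c(0.9, 0.1)[seq_len(b$P[2] - b$P[1] + 1)])
  H <- pmax(1L, pmin(round(C * runif(n, 0.4, 2.2)), 2L * C + 2L + N + P))

  peaks <- tibble::tibble(C = C, H = H, N = N, O = O, P = P, S = S)
  peaks$mass <- formula_mass(C, H, N, O, P, S)
  if (spec$mass_jitter_ppm > 0) {
    peaks$mass <- peaks$mass *
      (1 + runif(n, -spec$mass_jitter_ppm, spec$mass_jitter_ppm) * 1e-6)
  }
  peaks$has_c13 <- seq_len(n) %in% sample.int(n, floor(spec$frac_c13 * n))
  peaks$error_ppm <- pmax(pmin(rnorm(n, 0, 0.15), 0.45), -0.45)
  bad <- sample.int(n, floor(spec$frac_bad_error * n))
  peaks$error_ppm[bad] <- sample(c(-1, 1), length(bad), replace = TRUE) *
    runif(length(bad), 0.55, 1.5)

  # planted transformation ladders: exact masses, appended after random peaks
  key <- read_transformation_key("builtin")
  series_rows <- list(); series_truth <- list()
  for (si in seq_along(spec$planted_series)) {
    ps <- spec$planted_series[[si]]
    counts <- resolve_counts(ps$base)
    krow <- key[key$name == ps$key, ]
    if (nrow(krow) != 1L) stop("unknown key entry in planted series: ", ps$key,
                               call. = FALSE)
    delta <- resolve_counts(krow$formula)
    dir <- if (is.null(ps$direction)) 1L else as.integer(ps$direction)
    for (step in 0:ps$length) {
      cc <- counts + dir * step * delta
      if (any(cc < 0)) stop("infeasible planted chain: negative element count",
                            call. = FALSE)
      series_rows[[length(series_rows) + 1L]] <- tibble::tibble(
        C = cc[["C"]], H = cc[["H"]], N = cc[["N"]], O = cc[["O"]],
        P = cc[["P"]], S = cc[["S"]],
        mass = formula_mass(cc[["C"]], cc[["H"]], cc[["N"]], cc[["O"]],
                            cc[["P"]], cc[["S"]]),
        has_c13 = FALSE, error_ppm = 0
      )
      series_truth[[length(series_truth) + 1L]] <- tibble::tibble(
        series = si, step = step, key = ps$key
      )
    }
  }
  n_series <- length(series_rows)
  if (n_series) {
    peaks <- dplyr::bind_rows(peaks, dplyr::bind_rows(series_rows))
  }

  n_noformula <- floor(spec$frac_no_formula * n)
  if (n_noformula) {
    peaks <- dplyr::bind_rows(peaks, tibble::tibble(
      C = 0L, H = 0L, N = 0L, O = 0L, P = 0L, S = 0L,
      mass = runif(n_noformula, 200, 800),
      has_c13 = FALSE, error_ppm = NA_real_
    ))
  }

  total <- nrow(peaks)
  peaks$peak_id <- sprintf("peak_%05d", seq_len(total))
  peaks$has_formula <- peaks$C > 0L & peaks$H > 0L
  planted_idx <- if (n_series) n + seq_len(n_series) else integer()

  # intensities: log-normal baseline, group effect on a peak subset, dropout
  sample_ids <- sprintf("S%02d", seq_len(spec$n_samples))
  base_log <- rnorm(total, mean = 6, sd = 0.8)
  n_affected <- ceiling(spec$effect_fraction * total)
  affected <- sort(sample.int(total, n_affected))
  eff <- setNames(rep(0, length(unique(spec$groups))), unique(spec$groups))
  eff[names(spec$group_effect)] <- spec$group_effect
  mat <- matrix(0, total, spec$n_samples, dimnames = list(peaks$peak_id, sample_ids))
  for (j in seq_len(spec$n_samples)) {
    shift <- ifelse(seq_len(total) %in% affected, eff[[spec$groups[j]]], 0)
    lg <- base_log + shift + rnorm(total, 0, spec$noise_sd)
    v <- 10^lg
    drop <- runif(total) < spec$dropout_rate
    drop[planted_idx] <- FALSE  # planted ladders detected everywhere
    v[drop] <- 0
    mat[, j] <- v
  }

  report <- dplyr::bind_cols(
    peaks[, c("peak_id", "mass", "C", "H", "N", "O", "P", "S", "has_c13",
              "error_ppm", "has_formula")],
    tibble::as_tibble(as.data.frame(mat))
  )
  attr(report, "sample_ids") <- sample_ids
  class(report) <- c("ftms_report", class(report))

  metadata <- tibble::tibble(sample_id = sample_ids, Group1 = spec$groups)
  if (!is.null(spec$groups2)) metadata$Group2 <- spec$groups2

  truth_series <- if (n_series) {
    dplyr::bind_cols(dplyr::bind_rows(series_truth),
                     tibble::tibble(peak_id = peaks$peak_id[planted_idx],
                                    mass = peaks$mass[planted_idx]))
  } else {
    tibble::tibble(series = integer(), step = integer(), key = character(),
                   peak_id = character(), mass = numeric())
  }

  list(
    report = report,
    metadata = metadata,
    truth = list(series = truth_series,
                 affected_peaks = peaks$peak_id[affected],
                 group_effect = eff)
  )
}

#' Write a generated fixture to disk in the Formularity dialect
#'
#' @param fix Output of [generate_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`report`, `metadata`, `series`).
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    report = file.path(dir, "report.csv"),
    metadata = file.path(dir, "metadata.csv"),
    series = file.path(dir, "truth_series.csv")
  )
  write_report(fix$report, paths$report)
  md <- fix$metadata
  names(md)[1] <- "SampleID"
  write.csv(md, paths$metadata, row.names = FALSE, quote = FALSE)
  write.csv(fix$truth$series, paths$series, row.names = FALSE, quote = FALSE)
  invisible(paths)
}
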