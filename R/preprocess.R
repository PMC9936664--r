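#' Van Krevelen compound-class regions
#'
#' Ordered rectangular regions in the (O/C, H/C) plane used to assign putative
#' compound classes to assigned molecular formulas. Regions are checked top to
#' bottom; the first match wins; lower bounds are inclusive and upper bounds
#' exclusive so that region borders are assigned deterministically. Peaks
#' matching no region are labelled `"Other"`. The numeric bounds follow the
#' boundary set in wide use for natural organic matter van Krevelen analysis.
#'
#' @return Tibble with columns `compound_class`, `oc_min`, `oc_max`, `hc_min`,
#'   `hc_max`.
#' @export
compound_class_table <- function() {
  tibble::tribble(
    ~compound_class,           ~oc_min, ~oc_max, ~hc_min, ~hc_max,
    "Lipid-like",                 0,      0.3,     1.5,    2.5,
    "Protein-like",               0.3,    0.67,    1.5,    2.3,
    "Carbohydrate-like",          0.67,   1.2,     1.5,    2.5,
    "Unsaturated hydrocarbon",    0,      0.1,     0.7,    1.5,
    "Lignin-like",                0.1,    0.67,    0.7,    1.5,
    "Tannin-like",                0.67,   1.2,     0.5,    1.5,
    "Condensed aromatic",         0,      0.67,    0.2,    0.7
  )
}

#' Assign a van Krevelen compound class from O/C and H/C ratios
#'
#' @param oc,hc Numeric vectors of O/C and H/C elemental ratios (same length).
#' @return Character vector of class labels (`"Other"` when no region
#'   matches). See [compound_class_table()] for regions and tie-breaking.
#' @examples
#' assign_compound_class(c(1.0, 0.1), c(2.0, 1.9))
#' @export
assign_compound_class <- function(oc, hc) {
  stopifnot(length(oc) == length(hc))
  tab <- compound_class_table()
  out <- rep("Other", length(oc))
  unmatched <- !is.na(oc) & !is.na(hc)
  out[!unmatched] <- NA_character_
  for (i in seq_len(nrow(tab))) {
    hit <- unmatched &
      oc >= tab$oc_min[i] & oc < tab$oc_max[i] &
      hc >= tab$hc_min[i] & hc < tab$hc_max[i]
    out[hit] <- tab$compound_class[i]
    unmatched <- unmatched & !hit
  }
  out
}

#' Thermodynamic and molecular indices from elemental composition
#'
#' Computes, per formula, the nominal oxidation state of carbon (NOSC), the
#' Gibbs free energy of the carbon oxidation half-reaction (GFE, kJ per mol
#' C), the double-bond equivalents (DBE) and the modified aromaticity index
#' (AImod):
#' \deqn{NOSC = 4 - (4C + H - 3N - 2O + 5P - 2S)/C}
#' \deqn{GFE = 60.3 - 28.5 \cdot NOSC}
#' \deqn{DBE = 1 + (2C - H + N + P)/2}
#' \deqn{AImod = \frac{1 + C - O/2 - S - (N + P + H)/2}{C - O/2 - N - S - P}}
#' NOSC assumes neutral molecules (net charge 0). AImod is reported as 0 when
#' its denominator is non-positive or the ratio is negative, the usual
#' convention for aromaticity indices (a negative bond density is not
#' meaningful).
#'
#' @param C,H,N,O,P,S Element-count vectors; `C` must be positive everywhere
#'   (indices are undefined without carbon).
#' @return Tibble with columns `NOSC`, `GFE`, `DBE`, `AImod`.
#' @examples
#' compute_indices(C = 6, H = 12, O = 6) # glucose: NOSC 0, GFE 60.3, DBE 1
#' @export
compute_indices <- function(C, H, N = 0, O = 0, P = 0, S = 0) {
  n <- length(C)
  args <- list(C = C, H = H, N = rep_len(N, n), O = rep_len(O, n),
               P = rep_len(P, n), S = rep_len(S, n))
  if (any(args$C <= 0)) {
    stop("indices are undefined for formulas without carbon (C = 0)", call. = FALSE)
  }
  with(args, {
    nosc <- 4 - (4 * C + H - 3 * N - 2 * O + 5 * P - 2 * S) / C
    gfe <- 60.3 - 28.5 * nosc
    dbe <- 1 + 0.5 * (2 * C - H + N + P)
    denom <- C - O / 2 - N - S - P
    num <- 1 + C - O / 2 - S - (N + P + H) / 2
    aimod <- ifelse(denom <= 0, 0, pmax(0, num / denom))
    tibble::tibble(NOSC = nosc, GFE = gfe, DBE = dbe, AImod = aimod)
  })
}

# element-class label: which of C,H,O,N,S,P occur, in that canonical order
element_class <- function(C, H, N = 0, O = 0, P = 0, S = 0) {
  counts <- cbind(C = C, H = H, O = O, N = N, S = S, P = P)
  apply(counts, 1, function(r) paste(colnames(counts)[r > 0], collapse = ""))
}

#' Annotate peaks with ratios, indices and compound classes
#'
#' Adds O/C, H/C, NOSC, GFE, DBE, AImod, the compound class and the element
#' class to every formula-bearing peak. Peaks without an assigned formula get
#' `NA` ratios/indices and the class `"Unassigned"`; they stay in the table
#' (and in diagnostics counts) but are excluded from exploration, diversity
#' traits and networks downstream.
#'
#' @param x An `ftms_data` object.
#' @return `x` with annotation columns added to `x$peaks`.
#' @export
annotate_peaks <- function(x) {
  stopifnot(inherits(x, "ftms_data"))
  p <- x$peaks
  f <- p$has_formula
  p$OC <- ifelse(f, p$O / p$C, NA_real_)
  p$HC <- ifelse(f, p$H / p$C, NA_real_)
  idx <- tibble::tibble(NOSC = rep(NA_real_, nrow(p)), GFE = NA_real_,
                        DBE = NA_real_, AImod = NA_real_)
  if (any(f)) {
    idx[f, ] <- compute_indices(p$C[f], p$H[f], p$N[f], p$O[f], p$P[f], p$S[f])
  }
  p <- dplyr::bind_cols(p, idx)
  p$compound_class <- ifelse(f, assign_compound_class(p$OC, p$HC), "Unassigned")
  p$element_class <- ifelse(f, element_class(p$C, p$H, p$N, p$O, p$P, p$S),
                            NA_character_)
  x$peaks <- p
  x
}

#' Filter peaks by mass window, isotope flag, assignment error and presence
#'
#' Applies the four pre-processing filters in a fixed order:
#' \enumerate{
#'   \item mass window: keep peaks with mass inside the closed window;
#'   \item isotopes: drop carbon-13 isotopologue peaks;
#'   \item assignment error: drop formula-bearing peaks whose absolute error
#'     exceeds the threshold (inclusive bound; peaks without a formula, or
#'     without a recorded error, pass);
#'   \item presence: keep peaks detected (intensity > 0) in at least
#'     `presence_min` samples.
#' }
#' The removal audit (one count per rule, in application order) is stored in
#' `x$filter_audit`; its counts always sum to `input - kept`.
#'
#' @param x An `ftms_data` object.
#' @param config An `ftms_config` from [run_config()].
#' @return The filtered `ftms_data` with `filter_audit` set.
#' @export
filter_peaks <- function(x, config) {
  stopifnot(inherits(x, "ftms_data"), inherits(x, "ftms_data"))
  n_samples <- ncol(x$intensities)
  presence_n <- config$presence_min
  if (presence_n < 1) presence_n <- ceiling(presence_n * n_samples)
  presence_n <- as.integer(presence_n)
  if (presence_n > n_samples) {
    stop("presence_min (", presence_n, ") exceeds the number of samples (",
         n_samples, ")", call. = FALSE)
  }

  keep <- rep(TRUE, nrow(x$peaks))
  audit <- integer(4)
  w <- config$mass_window

  drop_mass <- keep & (x$peaks$mass < w[1] | x$peaks$mass > w[2])
  audit[1] <- sum(drop_mass); keep <- keep & !drop_mass

  drop_iso <- keep & x$peaks$has_c13
  audit[2] <- sum(drop_iso); keep <- keep & !drop_iso

  err <- x$peaks$error_ppm
  drop_err <- keep & x$peaks$has_formula & !is.na(err) &
    abs(err) > config$error_max_ppm
  audit[3] <- sum(drop_err); keep <- keep & !drop_err

  detected_in <- rowSums(x$intensities > 0)
  drop_pres <- keep & detected_in < presence_n
  audit[4] <- sum(drop_pres); keep <- keep & !drop_pres

  x$peaks <- x$peaks[keep, ]
  x$intensities <- x$intensities[keep, , drop = FALSE]
  if (!is.null(x$normalized)) x$normalized <- x$normalized[keep, , drop = FALSE]
  x$filter_audit <- tibble::tibble(
    rule = c("mass_window", "isotope", "assignment_error", "sample_presence"),
    removed = audit
  )
  x
}
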