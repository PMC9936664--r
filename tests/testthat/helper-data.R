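# Build an ftms_data object directly from components, bypassing file IO.
toy_data <- function(intensities, mass = NULL, C = NULL, H = NULL,
                     N = 0L, O = 0L, P = 0L, S = 0L,
                     has_c13 = FALSE, error_ppm = 0,
                     groups = NULL, groups2 = NULL) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("S%02d", seq_len(ncol(intensities)))
  }
  if (is.null(C)) C <- rep(10L, n)
  if (is.null(H)) H <- rep(16L, n)
  rec <- function(v) rep_len(as.integer(v), n)
  C <- rec(C); H <- rec(H); N <- rec(N); O <- rec(O); P <- rec(P); S <- rec(S)
  if (is.null(mass)) mass <- formula_mass(C, H, N, O, P, S)
  mass[mass <= 0] <- 100 + seq_len(sum(mass <= 0))  # formula-less rows
  report <- tibble::tibble(
    peak_id = sprintf("peak_%05d", seq_len(n)),
    mass = mass, C = C, H = H, N = N, O = O, P = P, S = S,
    has_c13 = rep_len(has_c13, n),
    error_ppm = rep_len(error_ppm, n),
    has_formula = C > 0L & H > 0L
  )
  report <- dplyr::bind_cols(report, tibble::as_tibble(as.data.frame(intensities)))
  attr(report, "sample_ids") <- colnames(intensities)
  class(report) <- c("ftms_report", class(report))
  if (is.null(groups)) {
    groups <- rep(c("A", "B"), length.out = ncol(intensities))
  }
  metadata <- tibble::tibble(sample_id = colnames(intensities), Group1 = groups)
  if (!is.null(groups2)) metadata$Group2 <- groups2
  ftms_data(report, metadata)
}

# random CHNOPS formula table for property-style tests
random_formulas <- function(n, seed = 1) {
  set.seed(seed)
  C <- sample(1:40, n, replace = TRUE)
  tibble::tibble(
    C = C,
    H = pmax(1L, pmin(as.integer(round(C * runif(n, 0.3, 2.2))), 2L * C + 2L)),
    N = sample(0:3, n, replace = TRUE),
    O = sample(0:20, n, replace = TRUE),
    P = sample(0:1, n, replace = TRUE),
    S = sample(0:2, n, replace = TRUE)
  )
}

# one-entry transformation key with an exact mass
single_key <- function(name = "CH2", formula = "CH2") {
  counts <- parse_formula(formula)
  tibble::tibble(name = name, formula = formula,
                 mass_difference = do.call(formula_mass, as.list(counts)),
                 category = "biotic")
}

# brute-force O(n^2 K) mass-difference matcher (the oracle)
brute_force_edges <- function(masses, key, ppm_tolerance = 1) {
  ids <- names(masses)
  rows <- list()
  for (i in seq_along(masses)) {
    for (j in seq_along(masses)) {
      if (masses[i] >= masses[j]) next
      dm <- masses[j] - masses[i]
      for (k in seq_len(nrow(key))) {
        delta <- key$mass_difference[k]
        if (abs(dm - delta) <= delta * ppm_tolerance * 1e-6) {
          rows[[length(rows) + 1L]] <- data.frame(
            peak_lo = ids[i], peak_hi = ids[j], key_name = key$name[k],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(peak_lo = character(),
                                      peak_hi = character(),
                                      key_name = character())
  out[order(out$peak_lo, out$peak_hi, out$key_name), , drop = FALSE]
}

edge_signature <- function(edges) {
  sort(paste(edges$peak_lo, edges$peak_hi, edges$key_name))
}
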