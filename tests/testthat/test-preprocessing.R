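# Hand-computed index values for reference formulas (frozen oracles).
index_oracles <- tibble::tribble(
  ~name,            ~C, ~H, ~N, ~O, ~P, ~S, ~NOSC,         ~DBE, ~AImod,
  "glucose",         6, 12,  0,  6,  0,  0,  0,             1,    0,
  "benzene",         6,  6,  0,  0,  0,  0, -1,             4,    2 / 3,
  "methane",         1,  4,  0,  0,  0,  0, -4,             0,    0,
  "palmitic acid",  16, 32,  0,  2,  0,  0, -1.75,          1,    0,
  "carbon dioxide",  1,  0,  0,  2,  0,  0,  4,             2,    0,
  "ethanol",         2,  6,  0,  1,  0,  0, -2,             0,    0,
  "acetic acid",     2,  4,  0,  2,  0,  0,  0,             1,    0,
  "urea",            1,  4,  2,  1,  0,  0,  4,             1,    0,
  "benzoic acid",    7,  6,  0,  2,  0,  0, -0.2857142857142857, 5, 2 / 3,
  "cysteine",        3,  7,  1,  2,  0,  1,  0.6666666666666667, 1, 0,
  "methanol",        1,  4,  0,  1,  0,  0, -2,             0,    0
)

test_that("thermodynamic indices match hand calculations for reference formulas", {
  got <- compute_indices(index_oracles$C, index_oracles$H, index_oracles$N,
                         index_oracles$O, index_oracles$P, index_oracles$S)
  expect_equal(got$NOSC, index_oracles$NOSC, tolerance = 1e-9)
  expect_equal(got$GFE, 60.3 - 28.5 * index_oracles$NOSC, tolerance = 1e-9)
  expect_equal(got$DBE, index_oracles$DBE, tolerance = 1e-9)
  expect_equal(got$AImod, index_oracles$AImod, tolerance = 1e-9)
  expect_error(compute_indices(C = 0, H = 2), "C = 0")
})

test_that("GFE is affine in NOSC and NOSC stays within the CH4..CO2 bracket", {
  f <- random_formulas(100, seed = 11)
  got <- compute_indices(f$C, f$H, f$N, f$O, f$P, f$S)
  expect_equal(got$GFE, 60.3 - 28.5 * got$NOSC, tolerance = 1e-12)
  # most-reduced and most-oxidized carbon limits
  expect_equal(compute_indices(1, 4)$NOSC, -4)
  expect_equal(compute_indices(1, 0, O = 2)$NOSC, 4)
  # CHO formulas with O <= C stay inside the CH4..CO2 bracket
  cho <- compute_indices(f$C, f$H, O = pmin(f$O, f$C))
  expect_true(all(cho$NOSC >= -4 - 1e-12))
  expect_true(all(cho$NOSC <= 4 + 1e-12))
})

test_that("compound classes follow the ordered van Krevelen regions", {
  expect_equal(assign_compound_class(1.0, 2.0), "Carbohydrate-like")
  expect_equal(assign_compound_class(0.1, 1.9), "Lipid-like")
  expect_equal(assign_compound_class(0.05, 0.9), "Unsaturated hydrocarbon")
  expect_equal(assign_compound_class(0.4, 1.0), "Lignin-like")
  expect_equal(assign_compound_class(0.8, 1.0), "Tannin-like")
  expect_equal(assign_compound_class(0.3, 0.5), "Condensed aromatic")
  expect_equal(assign_compound_class(1.5, 3.0), "Other")
  # boundary: lower bounds inclusive, upper exclusive, checked in fixed order
  expect_equal(assign_compound_class(0.3, 1.6), "Protein-like")
  expect_equal(assign_compound_class(0.3 - 1e-9, 1.6), "Lipid-like")
  expect_equal(assign_compound_class(0.1, 1.2), "Lignin-like")
})

test_that("peaks without formulas are annotated as Unassigned with NA indices", {
  mat <- matrix(1, 2, 2)
  x <- toy_data(mat, C = c(6L, 0L), H = c(12L, 0L), O = c(6L, 0L))
  x <- annotate_peaks(x)
  expect_equal(x$peaks$compound_class, c("Carbohydrate-like", "Unassigned"))
  expect_true(is.na(x$peaks$NOSC[2]))
  expect_equal(x$peaks$element_class[1], "CHO")
})

test_that("the peak filter applies rules in order and audits removals exactly", {
  # 10 peaks: 2 outside the mass window, 3 with 13C, 1 with error 0.9 ppm
  mat <- matrix(10, 10, 3)
  x <- toy_data(
    mat,
    mass = c(100, 950, 500, 500, 500, 500, 500, 500, 500, 500),
    has_c13 = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    error_ppm = c(0, 0, 0, 0, 0, 0.9, 0.5, -0.5, 0.1, 0)
  )
  cfg <- run_config(mass_window = c(200, 900), presence_min = 1)
  out <- filter_peaks(x, cfg)
  expect_equal(out$filter_audit$removed, c(2L, 3L, 1L, 0L))
  expect_equal(nrow(out$peaks), 4L)
  expect_equal(sum(out$filter_audit$removed), 10L - nrow(out$peaks))
  # inclusive error bound: +0.5 and -0.5 ppm survive
  expect_true(all(c("peak_00007", "peak_00008") %in% out$peaks$peak_id))
})

test_that("13C isotopologues are removed by the isotope rule regardless of mass", {
  x <- toy_data(matrix(5, 2, 2), mass = c(500, 500), has_c13 = c(TRUE, FALSE))
  out <- filter_peaks(x, run_config())
  expect_equal(out$filter_audit$removed[2], 1L)
  expect_equal(nrow(out$peaks), 1L)
})

test_that("presence threshold accepts fractions and rejects impossible values", {
  mat <- cbind(c(1, 1, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1, 0))
  x <- toy_data(mat, mass = rep(500, 3))
  out <- filter_peaks(x, run_config(presence_min = 0.5))  # >= 2 of 4 samples
  expect_equal(nrow(out$peaks), 2L)
  expect_error(filter_peaks(x, run_config(presence_min = 9)), "exceeds")
})

test_that("peaks without formulas pass the error filter", {
  x <- toy_data(matrix(5, 2, 2), mass = c(500, 500), C = c(0L, 10L),
                H = c(0L, 16L), error_ppm = c(NA, 2))
  out <- filter_peaks(x, run_config())
  expect_equal(out$peaks$has_formula, FALSE)  # formula peak dropped, bare mass kept
})

test_that("normalization formulas hold per sample column", {
  m <- matrix(c(2, 4, 10), 3, 1, dimnames = list(NULL, "S01"))
  expect_equal(as.vector(normalize_columns(m, "sum")), c(0.125, 0.25, 0.625))
  expect_equal(as.vector(normalize_columns(matrix(5, 1, 1), "max")), 1)
  set.seed(42)
  m <- matrix(10^rnorm(60, 5), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[sample(60, 10)] <- 0
  z <- normalize_columns(m, "zscore")
  for (j in 1:3) {
    v <- z[m[, j] > 0, j]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  mm <- normalize_columns(m, "minmax")
  expect_true(all(mm >= 0 & mm <= 1))
  sm <- normalize_columns(m, "sum")
  expect_equal(unname(colSums(sm)), rep(1, 3), tolerance = 1e-12)
})

test_that("zeros are treated as absence: excluded from statistics, preserved as zeros", {
  m <- matrix(c(0, 2, 4, 10), 4, 1, dimnames = list(NULL, "S01"))
  for (method in c("max", "minmax", "mean", "median", "sum", "zscore")) {
    out <- normalize_columns(m, method)
    expect_identical(unname(out[1, 1]), 0)
  }
  # with the zero excluded, sum-normalization is over detected values only
  expect_equal(as.vector(normalize_columns(m, "sum")), c(0, 0.125, 0.25, 0.625))
})

test_that("invertible normalizations round-trip and degenerate columns error", {
  set.seed(7)
  m <- matrix(10^rnorm(40, 5), 20, 2, dimnames = list(NULL, c("a", "b")))
  m[sample(40, 6)] <- 0
  for (method in c("max", "sum")) {
    nm <- normalize_columns(m, method)
    fac <- vapply(seq_len(ncol(m)), function(j) {
      v <- m[m[, j] > 0, j]
      if (method == "max") max(v) else sum(v)
    }, numeric(1))
    back <- sweep(nm, 2, fac, "*")
    expect_equal(back, m, tolerance = 1e-9)
  }
  const <- matrix(c(3, 3, 3), 3, 1, dimnames = list(NULL, "flat"))
  expect_error(normalize_columns(const, "minmax"), "flat")
  expect_error(normalize_intensities(
    normalize_intensities(toy_data(matrix(1:4, 2)), "sum"), "max"
  ), "already normalized")
})
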