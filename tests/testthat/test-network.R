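test_that("exact and out-of-tolerance mass differences match as expected", {
  key <- tibble::tibble(name = "CH2", formula = "CH2",
                        mass_difference = 14.015650, category = "biotic")
  e <- match_transformations(c(a = 100.000000, b = 114.015650), key, 1)
  expect_equal(nrow(e), 1L)
  expect_equal(e$error_ppm, 0, tolerance = 1e-6)
  expect_equal(e$observed_delta, 14.015650)
  # 0.0001 Da off on a 14 Da delta is ~7 ppm: no edge at 1 ppm
  e2 <- match_transformations(c(a = 100.000000, b = 114.015750), key, 1)
  expect_equal(nrow(e2), 0L)
  e3 <- match_transformations(c(a = 100.000000, b = 114.015750), key, 10)
  expect_equal(nrow(e3), 1L)
})

test_that("the sweep matcher equals the brute force on random instances", {
  key <- read_transformation_key("builtin")
  set.seed(23)
  for (i in 1:5) {
    masses <- setNames(runif(120, 200, 800), sprintf("p%03d", 1:120))
    # seed some true matches so the instances are not trivially empty
    base <- sample(masses, 10)
    extra <- base + sample(key$mass_difference, 10, replace = TRUE)
    masses <- c(masses, setNames(extra, sprintf("q%03d", 1:10)))
    got <- match_transformations(masses, key, 1)
    want <- brute_force_edges(masses, key, 1)
    expect_identical(edge_signature(got), edge_signature(want))
  }
})

test_that("edges grow monotonically with tolerance and survive relabeling", {
  key <- read_transformation_key("builtin")
  set.seed(29)
  masses <- setNames(runif(150, 200, 700), sprintf("p%03d", 1:150))
  masses <- c(masses, masses[1:20] + 14.015650)
  names(masses)[151:170] <- sprintf("q%03d", 1:20)
  e1 <- match_transformations(masses, key, 1)
  e2 <- match_transformations(masses, key, 2)
  expect_true(all(edge_signature(e1) %in% edge_signature(e2)))
  shuffled <- sample(masses)
  e3 <- match_transformations(shuffled, key, 1)
  expect_identical(edge_signature(e1), edge_signature(e3))
})

test_that("a planted CH2 ladder forms a path; disjoint ladders split components", {
  key <- single_key()
  ladder <- c(a = 300, b = 300 + 14.0156501, c = 300 + 2 * 14.0156501,
              d = 300 + 3 * 14.0156501)
  e <- match_transformations(ladder, key, 1)
  expect_equal(nrow(e), 3L)
  nw <- build_network(e, n_detected = 4L)
  expect_equal(nw$stats$n_nodes, 4L)
  expect_equal(nw$stats$n_edges, 3L)
  expect_equal(nw$stats$n_components, 1L)
  expect_equal(nw$stats$n_isolated, 0L)
  expect_equal(nw$stats$density, 2 * 3 / (4 * 3))

  two <- c(ladder, e2a = 600, e2b = 600 + 14.0156501)
  nw2 <- build_network(match_transformations(two, key, 1), n_detected = 6L)
  expect_equal(nw2$stats$n_components, 2L)

  empty <- build_network(match_transformations(c(a = 100, b = 200), key, 1),
                         n_detected = 2L)
  expect_equal(empty$stats$n_nodes, 0L)
  expect_equal(empty$stats$n_edges, 0L)
  expect_equal(empty$stats$density, 0)
})

test_that("multi-key matches keep parallel edges unless best-match is requested", {
  key <- tibble::tibble(
    name = c("K1", "K2"), formula = NA_character_,
    mass_difference = c(14.015650, 14.0156502), category = "biotic"
  )
  masses <- c(a = 100, b = 114.015650)
  all_edges <- match_transformations(masses, key, 1)
  expect_equal(nrow(all_edges), 2L)
  best <- match_transformations(masses, key, 1, multi = "best")
  expect_equal(nrow(best), 1L)
  expect_equal(best$key_name, "K1")
})

test_that("per-sample networks and summaries compute percentages correctly", {
  edges <- list(
    S1 = tibble::tibble(
      peak_lo = c("a", "b", "c"), peak_hi = c("b", "c", "d"),
      mass_lo = 1:3, mass_hi = 2:4,
      key_name = c("CH2", "CH2", "H2O"),
      category = c("biotic", "biotic", "abiotic"),
      observed_delta = 1, error_ppm = 0
    ),
    S2 = tibble::tibble(
      peak_lo = character(), peak_hi = character(), mass_lo = numeric(),
      mass_hi = numeric(), key_name = character(), category = character(),
      observed_delta = numeric(), error_ppm = numeric()
    )
  )
  summ <- transformation_summary(edges)
  s1 <- summ$per_sample[summ$per_sample$sample_id == "S1", ]
  expect_equal(s1$percent[s1$key_name == "CH2"], 200 / 3, tolerance = 1e-9)
  expect_equal(s1$percent[s1$key_name == "H2O"], 100 / 3, tolerance = 1e-9)
  expect_equal(sum(s1$percent), 100, tolerance = 1e-9)
  expect_equal(summ$top_keys[1], "CH2")
  expect_true(summ$totals$no_edges[summ$totals$sample_id == "S2"])
  cat1 <- summ$category_split[summ$category_split$sample_id == "S1", ]
  expect_equal(cat1$percent[cat1$category == "biotic"], 200 / 3, tolerance = 1e-9)
})

test_that("node annotation and formula-only restriction propagate to networks", {
  key <- single_key()
  mass <- c(300, 300 + 14.0156501, 500, 500 + 14.0156501)
  x <- toy_data(matrix(10, 4, 2), mass = mass,
                C = c(10L, 11L, 0L, 20L), H = c(16L, 18L, 0L, 30L),
                O = c(2L, 2L, 0L, 4L))
  x <- annotate_peaks(x)
  nets <- sample_networks(x, key, ppm_tolerance = 1)
  # the 500-Da pair involves a formula-less peak: excluded from the network
  expect_equal(nets$stats$n_edges, c(1, 1))
  g <- nets$networks$S01$graph
  expect_true(all(!is.na(igraph::V(g)$compound_class)))
})
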