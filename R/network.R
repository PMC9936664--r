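#' Match pairwise mass differences against a transformation key
#'
#' For every unordered pair of peaks in a sample, tests whether their mass
#' difference equals one of the reference biochemical mass differences within
#' a ppm tolerance: a pair (lo, hi) matches key entry delta when
#' |(m_hi - m_lo) - delta| <= delta * tol * 1e-6 (`mode = "key"`, default;
#' with `mode = "mz"` the tolerance is taken relative to the heavier peak's
#' mass, which is far more permissive for small deltas). A pair may match
#' several key entries; all matches are kept as parallel edges unless
#' `multi = "best"` keeps only the minimum-error match per pair.
#'
#' The matcher sorts the masses once and runs a windowed two-pointer sweep
#' per key entry; it is exactly equivalent to the O(n^2 K) brute force over
#' all pairs and entries.
#'
#' @param masses Named numeric vector of peak masses (names = peak ids),
#'   strictly positive.
#' @param key Transformation key tibble ([read_transformation_key()]).
#' @param ppm_tolerance Tolerance in ppm (default 1).
#' @param mode Tolerance denominator: `"key"` (the key's mass difference) or
#'   `"mz"` (the heavier peak mass).
#' @param multi `"all"` (parallel edges) or `"best"` (minimum error per pair).
#' @return Tibble: `peak_lo`, `peak_hi`, `mass_lo`, `mass_hi`, `key_name`,
#'   `category`, `observed_delta`, `error_ppm`.
#' @export
match_transformations <- function(masses, key, ppm_tolerance = 1,
                                  mode = c("key", "mz"), multi = c("all", "best")) {
  mode <- match.arg(mode)
  multi <- match.arg(multi)
  stopifnot(is.numeric(masses), all(masses > 0), nrow(key) >= 1L)
  if (is.null(names(masses))) names(masses) <- sprintf("m%04d", seq_along(masses))
  o <- order(masses)
  m <- masses[o]
  ids <- names(masses)[o]
  n <- length(m)
  rows <- list()
  if (n >= 2L) {
    for (k in seq_len(nrow(key))) {
      delta <- key$mass_difference[k]
      # upper bound on the absolute tolerance for the window sweep
      tol_max <- if (mode == "key") delta * ppm_tolerance * 1e-6
                 else max(m) * ppm_tolerance * 1e-6
      lo <- 1L
      for (hi in 2:n) {
        while (m[hi] - m[lo] > delta + tol_max && lo < hi) lo <- lo + 1L
        if (lo >= hi) next
        cand <- lo:(hi - 1L)
        dm <- m[hi] - m[cand]
        tol <- if (mode == "key") delta * ppm_tolerance * 1e-6
               else m[hi] * ppm_tolerance * 1e-6
        ok <- abs(dm - delta) <= tol & dm > 0
        if (any(ok)) {
          sel <- cand[ok]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            peak_lo = ids[sel], peak_hi = ids[hi],
            mass_lo = unname(m[sel]), mass_hi = unname(m[hi]),
            key_name = key$name[k], category = key$category[k],
            observed_delta = unname(dm[ok]),
            error_ppm = abs(unname(dm[ok]) - delta) / delta * 1e6
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(peak_lo = character(), peak_hi = character(),
                          mass_lo = numeric(), mass_hi = numeric(),
                          key_name = character(), category = character(),
                          observed_delta = numeric(), error_ppm = numeric()))
  }
  out <- dplyr::arrange(out, .data$mass_lo, .data$mass_hi, .data$key_name)
  if (multi == "best") {
    out <- out |>
      dplyr::group_by(.data$peak_lo, .data$peak_hi) |>
      dplyr::slice_min(.data$error_ppm, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$mass_lo, .data$mass_hi, .data$key_name)
  }
  out
}

#' Build a transformation network from matched edges
#'
#' Nodes are the peaks participating in at least one edge, annotated with
#' mass, compound class and indices when available; isolated detected peaks
#' are excluded from the graph but counted in the statistics.
#'
#' @param edges Edge tibble from [match_transformations()].
#' @param peaks Optional annotated peak tibble (`x$peaks`) for node
#'   attributes.
#' @param n_detected Optional number of detected peaks in the sample, to
#'   report the isolated-peak count.
#' @return List with `graph` (igraph, undirected, possibly with parallel
#'   edges), `stats` (one-row tibble: n_nodes, n_edges, density, mean_degree,
#'   n_components, n_isolated), `per_key` and `per_category` count tibbles.
#' @export
build_network <- function(edges, peaks = NULL, n_detected = NA_integer_) {
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    stats <- tibble::tibble(n_nodes = 0L, n_edges = 0L, density = 0,
                            mean_degree = 0, n_components = 0L,
                            n_isolated = n_detected)
    return(list(graph = g, stats = stats,
                per_key = tibble::tibble(key_name = character(), n = integer()),
                per_category = tibble::tibble(category = character(), n = integer())))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("peak_lo", "peak_hi", "key_name", "category", "observed_delta",
              "error_ppm")],
    directed = FALSE
  )
  if (!is.null(peaks)) {
    idx <- match(igraph::V(g)$name, peaks$peak_id)
    igraph::V(g)$mass <- peaks$mass[idx]
    if ("compound_class" %in% names(peaks)) {
      igraph::V(g)$compound_class <- peaks$compound_class[idx]
      igraph::V(g)$NOSC <- peaks$NOSC[idx]
      igraph::V(g)$GFE <- peaks$GFE[idx]
    }
  }
  nn <- igraph::vcount(g); ne <- igraph::ecount(g)
  stats <- tibble::tibble(
    n_nodes = nn,
    n_edges = ne,
    density = if (nn >= 2) 2 * ne / (nn * (nn - 1)) else 0,
    mean_degree = mean(igraph::degree(g)),
    n_components = igraph::components(g)$no,
    n_isolated = if (is.na(n_detected)) NA_integer_ else n_detected - nn
  )
  per_key <- edges |> dplyr::count(.data$key_name, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$key_name)
  per_category <- edges |> dplyr::count(.data$category, name = "n")
  list(graph = g, stats = stats, per_key = per_key, per_category = per_category)
}

#' Per-sample transformation networks for a whole dataset
#'
#' Runs the mass-difference matcher on every sample's detected peaks
#' (formula-bearing peaks only by default, since node class annotation is
#' undefined otherwise) and assembles the per-sample networks.
#'
#' @param x An annotated `ftms_data` object.
#' @param key Transformation key tibble.
#' @param ppm_tolerance Matching tolerance in ppm.
#' @param formula_only Restrict nodes to formula-bearing peaks (default TRUE).
#' @param ... Passed to [match_transformations()].
#' @return List with `edges` (named list of per-sample edge tibbles),
#'   `networks` (named list from [build_network()]) and `stats` (tibble, one
#'   row per sample).
#' @export
sample_networks <- function(x, key, ppm_tolerance = 1, formula_only = TRUE, ...) {
  stopifnot(inherits(x, "ftms_data"))
  sel <- if (formula_only) x$peaks$has_formula else rep(TRUE, nrow(x$peaks))
  masses <- setNames(x$peaks$mass[sel], x$peaks$peak_id[sel])
  mat <- x$intensities[sel, , drop = FALSE]
  edges <- list(); networks <- list(); stat_rows <- list()
  for (s in colnames(mat)) {
    det <- mat[, s] > 0
    e <- if (sum(det) >= 2L) {
      match_transformations(masses[det], key, ppm_tolerance, ...)
    } else {
      match_transformations(c(a = 1, b = 2), key, ppm_tolerance)[0, ]
    }
    nw <- build_network(e, peaks = x$peaks, n_detected = sum(det))
    edges[[s]] <- e
    networks[[s]] <- nw
    stat_rows[[s]] <- dplyr::bind_cols(tibble::tibble(sample_id = s), nw$stats)
  }
  list(edges = edges, networks = networks, stats = dplyr::bind_rows(stat_rows))
}

#' Transformation composition per sample
#'
#' Converts per-sample edge counts into percentages of each sample's total
#' transformations, selects the globally most abundant keys, and reports the
#' biotic/abiotic split per sample.
#'
#' @param edges Named list of per-sample edge tibbles ([sample_networks()]).
#' @param top_n Number of globally top keys to flag (default 15).
#' @return List with `per_sample` (tibble: sample_id, key_name, category, n,
#'   percent), `top_keys` (character, by summed counts), `category_split`
#'   (tibble: sample_id, category, n, percent) and `totals` (tibble:
#'   sample_id, n_edges, no_edges flag).
#' @export
transformation_summary <- function(edges, top_n = 15) {
  stopifnot(is.list(edges), length(edges) >= 1L)
  per_sample <- dplyr::bind_rows(lapply(names(edges), function(s) {
    e <- edges[[s]]
    if (nrow(e) == 0L) return(NULL)
    e |>
      dplyr::count(.data$key_name, .data$category, name = "n") |>
      dplyr::mutate(sample_id = s, percent = 100 * .data$n / sum(.data$n)) |>
      dplyr::select("sample_id", "key_name", "category", "n", "percent")
  }))
  totals <- tibble::tibble(
    sample_id = names(edges),
    n_edges = vapply(edges, nrow, integer(1)),
    no_edges = vapply(edges, nrow, integer(1)) == 0L
  )
  if (nrow(per_sample) == 0L) {
    return(list(per_sample = per_sample, top_keys = character(),
                category_split = tibble::tibble(), totals = totals))
  }
  top_keys <- per_sample |>
    dplyr::group_by(.data$key_name) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$key_name) |>
    head(top_n)
  category_split <- per_sample |>
    dplyr::group_by(.data$sample_id, .data$category) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop_last") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(per_sample = per_sample, top_keys = top_keys$key_name,
       category_split = category_split, totals = totals)
}
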