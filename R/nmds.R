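#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds the samples in k dimensions so that the rank order of configuration
#' distances matches the rank order of the input dissimilarities, minimizing
#' Kruskal's stress-1
#' \deqn{\sigma_1 = \sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}}
#' where the reference distances \eqn{\hat d} are the isotonic (monotone)
#' regression of the configuration distances on the dissimilarity order
#' (primary treatment of ties). Configurations are updated with a Guttman
#' transform followed by a backtracking step-halving line search, so the
#' recorded stress trace is non-increasing by construction. The first start
#' is the metric (principal coordinates) solution; the remaining starts are
#' random. The best final configuration over all restarts is returned,
#' centered and rotated to its principal axes.
#'
#' @param d A `dist` object of sample dissimilarities.
#' @param k Number of dimensions (default 2).
#' @param n_restarts Number of starts including the metric start (default 20).
#' @param max_iter Maximum iterations per start (default 300).
#' @param tol Stop when the stress improvement falls below this (default 1e-6).
#' @param seed Integer seed for the random starts.
#' @return List of class `ftms_nmds`: `scores` (samples x k), `stress`,
#'   `stress_trace` (best start), `converged`, `k`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-6,
                 seed = 1L) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < k + 1L) stop("NMDS needs at least k + 1 samples", call. = FALSE)
  diss <- as.vector(d)
  ord <- order(diss)
  pair <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)  # dist ordering

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    X <- if (r == 1L) {
      pc <- suppressWarnings(cmdscale(d, k = k))
      if (ncol(pc) < k) pc <- cbind(pc, matrix(0, n, k - ncol(pc)))
      pc + matrix(rnorm(n * k, sd = 1e-8), n, k)  # break exact degeneracies
    } else {
      matrix(runif(n * k, -0.5, 0.5), n, k) * mean(diss)
    }
    run <- nmds_one_run(X, diss, ord, pair, n, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  scores <- scale(best$X, center = TRUE, scale = FALSE)
  if (n > 1L) {
    rot <- prcomp(scores, center = FALSE, scale. = FALSE)
    scores <- rot$x[, seq_len(k), drop = FALSE]
  }
  rownames(scores) <- attr(d, "Labels")
  colnames(scores) <- paste0("NMDS", seq_len(k))
  structure(
    list(scores = scores, stress = best$stress, stress_trace = best$trace,
         converged = best$converged, k = k),
    class = "ftms_nmds"
  )
}

nmds_stress <- function(X, diss, ord, pair) {
  dd <- sqrt(rowSums((X[pair[, 1], , drop = FALSE] - X[pair[, 2], , drop = FALSE])^2))
  dhat <- numeric(length(dd))
  dhat[ord] <- isoreg(dd[ord])$yf
  denom <- sum(dd^2)
  if (denom == 0) return(list(stress = 0, dd = dd, dhat = dhat))
  list(stress = sqrt(sum((dd - dhat)^2) / denom), dd = dd, dhat = dhat)
}

guttman_update <- function(X, dd, dhat, pair, n) {
  B <- matrix(0, n, n)
  ratio <- ifelse(dd > 0, dhat / dd, 0)
  B[pair] <- -ratio
  B[pair[, c(2, 1), drop = FALSE]] <- -ratio
  diag(B) <- -rowSums(B)
  B %*% X / n
}

nmds_one_run <- function(X, diss, ord, pair, n, max_iter, tol) {
  st <- nmds_stress(X, diss, ord, pair)
  trace <- st$stress
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    target <- guttman_update(X, st$dd, st$dhat, pair, n)
    accepted <- FALSE
    alpha <- 1
    for (h in 1:8) {  # backtracking: only accept stress-reducing steps
      Xtry <- X + alpha * (target - X)
      st_try <- nmds_stress(Xtry, diss, ord, pair)
      if (st_try$stress < st$stress) {
        X <- Xtry
        improvement <- st$stress - st_try$stress
        st <- st_try
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) { converged <- TRUE; break }
    trace <- c(trace, st$stress)
    if (improvement < tol) { converged <- TRUE; break }
  }
  list(X = X, stress = st$stress, trace = trace, converged = converged)
}
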