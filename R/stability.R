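## Bootstrap robustness of the partial-correlation network: percentile
## confidence intervals for edge weights and case-drop CS coefficients.

#' Bootstrap confidence intervals for edge weights
#'
#' Resamples respondents with replacement `R` times, re-estimates the network
#' per resample and reports percentile intervals per edge.  Replicates in
#' which the estimator fails are dropped and counted.
#'
#' @param data respondent x dimension matrix.
#' @param estimator function `data -> pcnetwork` (or weights matrix); default
#'   [estimate_network()].
#' @param R number of bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95, i.e. 2.5/97.5 percentiles).
#' @return object of class `edge_bootstrap`: data frame per edge (`node_a`,
#'   `node_b`, `weight`, `lower`, `upper`) plus attributes `replicates`
#'   (successful count) and `failures`.
#' @export
edge_bootstrap <- function(data, estimator = estimate_network, R = 1000,
                           seed = 1, conf = 0.95) {
  stopifnot(R >= 100)
  data <- as.matrix(data)
  n <- nrow(data)
  sds <- apply(data, 2, sd)
  if (any(sds <= 0))
    stop(sprintf("degenerate input: column %s has zero variance; no interval can be computed",
                 paste(colnames(data)[sds <= 0], collapse = ", ")), call. = FALSE)
  point <- network_weights(estimator(data))
  labels <- rownames(point)
  ut <- which(upper.tri(point), arr.ind = TRUE)
  set.seed(seed)
  reps <- matrix(NA_real_, nrow = R, ncol = nrow(ut))
  fail <- 0L
  for (r in seq_len(R)) {
    idx <- sample.int(n, n, replace = TRUE)
    w <- tryCatch(network_weights(estimator(data[idx, , drop = FALSE])),
                  error = function(e) NULL)
    if (is.null(w)) { fail <- fail + 1L; next }
    reps[r, ] <- w[ut]
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  if (nrow(reps) == 0)
    stop("all bootstrap replicates failed", call. = FALSE)
  a <- (1 - conf) / 2
  qs <- apply(reps, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(node_a = labels[ut[, 1]], node_b = labels[ut[, 2]],
                    weight = point[ut], lower = qs[1, ], upper = qs[2, ])
  structure(out, class = c("edge_bootstrap", "data.frame"),
            replicates = nrow(reps), failures = fail, conf = conf)
}

## CS coefficient from a matrix of correlations (grid x replicate):
## the largest drop proportion q such that, at q and every smaller grid
## value, at least `prop` of the replicate correlations reach `threshold`.
## NA correlations (e.g. a constant centrality vector) count as failures.
cs_from_cors <- function(cors, grid, threshold = 0.7, prop = 0.95) {
  stopifnot(nrow(cors) == length(grid))
  ok <- apply(cors, 1, function(r) mean(!is.na(r) & r >= threshold) >= prop)
  cs <- 0
  for (i in order(grid)) {
    if (!ok[i]) break
    cs <- grid[i]
  }
  cs
}

#' Case-drop bootstrap CS coefficients for centrality indices
#'
#' For each drop proportion `q` in the grid, draws `R` subsamples of
#' `ceiling((1 - q) n)` respondents without replacement, re-estimates the
#' network and correlates (Pearson) each subsample centrality vector with the
#' full-sample one.  The CS coefficient per index is the largest `q` at which
#' at least 95% of the correlations reach `cor_threshold`, requiring all
#' smaller grid values to pass as well.
#'
#' @param data respondent x dimension matrix.
#' @param estimator function `data -> pcnetwork`; default [estimate_network()].
#' @param grid drop proportions, each in (0, 0.75].
#' @param R subsamples per proportion (>= 100).
#' @param seed RNG seed.
#' @param cor_threshold correlation level defining stability (default 0.7).
#' @param indices centrality columns to track.
#' @return object of class `casedrop_result`: list with `cs` (named vector of
#'   CS coefficients), `grid`, `correlations` (index -> grid x R matrix),
#'   `cor_threshold`, `skipped` (proportions whose subsamples were too small).
#' @export
casedrop_cs <- function(data, estimator = estimate_network,
                        grid = seq(0.05, 0.75, by = 0.10), R = 1000, seed = 1,
                        cor_threshold = 0.7,
                        indices = c("strength", "closeness", "betweenness",
                                    "expected_influence_1")) {
  stopifnot(R >= 100, all(grid > 0), all(grid <= 0.75))
  data <- as.matrix(data)
  n <- nrow(data)
  p <- ncol(data)
  full <- node_centrality(estimator(data))
  cors <- lapply(indices, function(i) matrix(NA_real_, length(grid), R))
  names(cors) <- indices
  skipped <- numeric(0)
  set.seed(seed)
  for (gi in seq_along(grid)) {
    m <- ceiling((1 - grid[gi]) * n)
    if (m < p + 2) {
      warning(sprintf("drop proportion %.2f leaves %d rows; skipped", grid[gi], m))
      skipped <- c(skipped, grid[gi])
      next
    }
    for (r in seq_len(R)) {
      idx <- sample.int(n, m, replace = FALSE)
      cent <- tryCatch(node_centrality(estimator(data[idx, , drop = FALSE])),
                       error = function(e) NULL)
      if (is.null(cent)) next
      for (ind in indices) {
        cors[[ind]][gi, r] <- suppressWarnings(
          cor(full[[ind]], cent[[ind]], method = "pearson"))
      }
    }
  }
  keep <- !(grid %in% skipped)
  cs <- vapply(indices, function(ind)
    cs_from_cors(cors[[ind]][keep, , drop = FALSE], grid[keep],
                 threshold = cor_threshold), numeric(1))
  structure(list(cs = cs, grid = grid, correlations = cors,
                 cor_threshold = cor_threshold, skipped = skipped,
                 R = R),
            class = "casedrop_result")
}

#' @export
print.casedrop_result <- function(x, ...) {
  cat(sprintf("Case-drop bootstrap (R = %d per proportion, cor threshold %.2f)\n",
              x$R, x$cor_threshold))
  for (ind in names(x$cs))
    cat(sprintf("  CS(cor = %.1f) %s = %.2f\n", x$cor_threshold, ind, x$cs[ind]))
  invisible(x)
}
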