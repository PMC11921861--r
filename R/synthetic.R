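## Synthetic respondent generator with known ground truth.
##
## Three modes: "dimension" draws dimension scores from a zero-mean Gaussian
## with a known sparse precision matrix and rescales to target moments;
## "sem" samples a linear-Gaussian structural equation model over the
## dimensions (ground truth for Bayesian-network recovery); "item" generates
## 1..5 Likert item responses from per-dimension one-factor models calibrated
## so that expected scale-sum means match the targets and inter-item
## correlations approximate a target Cronbach's alpha.

#' Whole-sample calibration targets for the ten dimension scores
#'
#' Published whole-sample descriptives (n = 16,588) used as the generator's
#' default marginal targets: mean, SD and item count per dimension.
#'
#' @return data frame with columns `dimension`, `items`, `mean`, `sd`.
#' @export
table1_targets <- function() {
  data.frame(
    dimension = c("Anx", "Dep", "UHMU", "HMU", "DIF", "DDF", "EOT",
                  "POS", "DES", "ANG"),
    items = c(4L, 6L, 8L, 5L, 7L, 5L, 8L, 4L, 4L, 4L),
    mean = c(7.68, 11.83, 16.54, 16.44, 16.11, 12.83, 22.01,
             14.73, 13.00, 13.06),
    sd = c(2.90, 4.47, 5.94, 4.42, 6.31, 3.37, 3.15, 3.41, 3.54, 3.63),
    stringsAsFactors = FALSE)
}

#' Node labels of an analysis variant
#'
#' The two workflows use nine dimensions each: the healthy variant includes
#' HMU and excludes UHMU; the unhealthy variant vice versa.
#'
#' @param variant `"healthy"` or `"unhealthy"`.
#' @return character vector of nine node labels.
#' @export
variant_nodes <- function(variant = c("healthy", "unhealthy")) {
  variant <- match.arg(variant)
  music <- if (variant == "healthy") "HMU" else "UHMU"
  c(music, "POS", "DES", "ANG", "DIF", "DDF", "EOT", "Anx", "Dep")
}

#' Default sparse precision-matrix ground truth
#'
#' A nine-node partial-correlation structure for recovery testing.  Edge
#' placement and signs qualitatively echo the published networks (positive
#' RESE clique, TAS facet structure with a negative DIF-EOT partial, negative
#' despondency-distress--depression link, positive anxiety-depression link,
#' music-use edges with variant-specific sign pattern); the weights are
#' illustrative values chosen for a well-conditioned, clearly detectable
#' structure, not estimates from any dataset.
#'
#' @param variant `"healthy"` or `"unhealthy"`.
#' @param partial_cors optional data frame (`from`, `to`, `rho`) overriding
#'   the shipped edge set; partial correlations, each |rho| < 1.
#' @return object of class `precision_truth`: list with `labels`,
#'   `precision` (positive-definite, unit diagonal) and `partial_cors`.
#' @export
default_precision_truth <- function(variant = c("healthy", "unhealthy"),
                                    partial_cors = NULL) {
  variant <- match.arg(variant)
  labels <- variant_nodes(variant)
  if (is.null(partial_cors)) {
    music <- labels[1]
    shared <- data.frame(
      from = c("POS", "POS", "DES", "DIF", "DDF", "DES", "Anx", "DIF"),
      to   = c("DES", "ANG", "ANG", "DDF", "EOT", "Dep", "Dep", "Anx"),
      rho  = c(0.25, 0.20, 0.30, 0.30, 0.20, -0.20, 0.30, 0.15),
      stringsAsFactors = FALSE)
    extra <- if (variant == "healthy") {
      data.frame(from = c(music, music),
                 to = c("POS", "EOT"),
                 rho = c(0.20, -0.15), stringsAsFactors = FALSE)
    } else {
      data.frame(from = c(music, music, music),
                 to = c("POS", "Dep", "DIF"),
                 rho = c(-0.15, 0.15, 0.15), stringsAsFactors = FALSE)
    }
    partial_cors <- rbind(shared, extra)
  }
  stopifnot(all(partial_cors$from %in% labels), all(partial_cors$to %in% labels),
            all(abs(partial_cors$rho) < 1))
  p <- length(labels)
  omega <- diag(p)
  dimnames(omega) <- list(labels, labels)
  for (i in seq_len(nrow(partial_cors))) {
    a <- partial_cors$from[i]; b <- partial_cors$to[i]
    omega[a, b] <- omega[b, a] <- -partial_cors$rho[i]
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop("ground-truth precision matrix is not positive definite", call. = FALSE)
  structure(list(labels = labels, precision = omega,
                 partial_cors = partial_cors),
            class = "precision_truth")
}

#' Default linear-Gaussian DAG ground truth
#'
#' A nine-node structural equation model for Bayesian-network recovery
#' testing.  The arc layout qualitatively echoes the published averaged
#' networks (managing despondency-distress upstream; depression feeding the
#' alexithymia facets and anxiety; music use downstream, feeding externally
#' oriented thinking), with coefficients of magnitude >= 0.4 so the structure
#' is detectable at moderate sample sizes.  Values are illustrative, not
#' estimated from any dataset.
#'
#' @param variant `"healthy"` or `"unhealthy"`.
#' @param arcs optional data frame (`from`, `to`, `coef`) overriding the
#'   shipped arc set.
#' @param noise_sd residual standard deviation shared by all nodes (root
#'   nodes get unit variance).
#' @return object of class `dag_truth`: list with `labels`, `arcs`,
#'   `noise_sd`, `intercepts`.
#' @export
default_dag_truth <- function(variant = c("healthy", "unhealthy"),
                              arcs = NULL, noise_sd = 1) {
  variant <- match.arg(variant)
  labels <- variant_nodes(variant)
  music <- labels[1]
  if (is.null(arcs)) {
    base <- data.frame(
      from = c("DES", "DES", "DES", "DES", "Dep", "Dep", "Dep", "DIF"),
      to   = c("POS", "ANG", "Dep", "EOT", "DIF", "DDF", "Anx", "Anx"),
      coef = c(0.50, 0.55, -0.50, 0.40, 0.55, 0.50, 0.45, 0.40),
      stringsAsFactors = FALSE)
    extra <- if (variant == "healthy") {
      data.frame(from = c("ANG", "POS", music),
                 to = c(music, music, "EOT"),
                 coef = c(0.45, 0.40, -0.40), stringsAsFactors = FALSE)
    } else {
      data.frame(from = c("Dep", "Anx", "DIF", music),
                 to = c(music, music, music, "EOT"),
                 coef = c(0.40, 0.40, 0.40, 0.40), stringsAsFactors = FALSE)
    }
    arcs <- rbind(base, extra)
  }
  stopifnot(all(arcs$from %in% labels), all(arcs$to %in% labels))
  if (is.null(topological_order(labels, arcs[, c("from", "to")])))
    stop("ground-truth arc set is cyclic", call. = FALSE)
  structure(list(labels = labels, arcs = arcs,
                 noise_sd = setNames(rep(noise_sd, length(labels)), labels),
                 intercepts = setNames(rep(0, length(labels)), labels)),
            class = "dag_truth")
}

#' Generator configuration
#'
#' @param n number of respondents (>= 2).
#' @param seed integer RNG seed; every generator call is deterministic given
#'   the config.
#' @param mode `"dimension"` (Gaussian dimension scores from a precision
#'   truth), `"sem"` (linear-Gaussian DAG truth) or `"item"` (Likert items).
#' @param variant `"healthy"` or `"unhealthy"` (selects the music-use node).
#' @param target_means,target_sds named per-dimension calibration targets;
#'   default: the whole-sample column of [table1_targets()].
#' @param truth ground truth object ([default_precision_truth()] or
#'   [default_dag_truth()]); defaults by mode.
#' @param alpha_target per-instrument reliability targets for item mode,
#'   named vector over `k10`, `tas20`, `rese`, `hums`; defaults to the
#'   published alphas (0.801, 0.945, 0.82, 0.827).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n = 16588, seed = 1,
                             mode = c("dimension", "sem", "item"),
                             variant = c("healthy", "unhealthy"),
                             target_means = NULL, target_sds = NULL,
                             truth = NULL, alpha_target = NULL) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  stopifnot(n >= 2, is.numeric(seed), length(seed) == 1)
  tab <- table1_targets()
  tm <- setNames(tab$mean, tab$dimension)
  ts <- setNames(tab$sd, tab$dimension)
  if (!is.null(target_means)) tm[names(target_means)] <- target_means
  if (!is.null(target_sds)) ts[names(target_sds)] <- target_sds
  stopifnot(all(ts > 0))
  if (is.null(truth)) {
    truth <- switch(mode,
                    dimension = default_precision_truth(variant),
                    sem = default_dag_truth(variant),
                    item = NULL)
  }
  if (is.null(alpha_target))
    alpha_target <- c(k10 = 0.801, tas20 = 0.945, rese = 0.82, hums = 0.827)
  if (any(alpha_target <= 0 | alpha_target >= 1))
    stop("alpha_target values must lie in (0, 1)", call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed), mode = mode,
                 variant = variant, target_means = tm, target_sds = ts,
                 truth = truth, alpha_target = alpha_target),
            class = "generator_config")
}

#' Generate dimension scores from a sparse-precision Gaussian truth
#'
#' Draws `n` rows from the zero-mean Gaussian with covariance
#' \eqn{\Omega^{-1}}, standardizes each column by its population SD and
#' affinely rescales to the target means/SDs.  Deterministic given the
#' config's seed.
#'
#' @param config a [generator_config()] with `mode = "dimension"`.
#' @return list with `data` (n x 9 matrix, columns labeled) and `truth`.
#' @export
generate_dimension_scores <- function(config) {
  stopifnot(inherits(config, "generator_config"), config$mode == "dimension",
            inherits(config$truth, "precision_truth"))
  truth <- config$truth
  labels <- truth$labels
  sigma <- solve(truth$precision)
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("ground-truth precision matrix could not be decomposed", call. = FALSE))
  set.seed(config$seed)
  z <- matrix(rnorm(config$n * length(labels)), nrow = config$n) %*% ch
  z <- sweep(z, 2, sqrt(diag(sigma)), "/")
  x <- sweep(sweep(z, 2, config$target_sds[labels], "*"),
             2, config$target_means[labels], "+")
  colnames(x) <- labels
  list(data = x, truth = truth)
}

#' Sample from a linear-Gaussian structural equation model
#'
#' Nodes are sampled in topological order:
#' child = intercept + sum(coef * parent) + Gaussian noise.  Scores stay on
#' the structural (roughly standardized) scale; no moment rescaling is
#' applied, so the arc coefficients remain the regression truth.
#'
#' @param config a [generator_config()] with `mode = "sem"`.
#' @return list with `data` (n x 9 matrix) and `truth`.
#' @export
sample_from_sem <- function(config) {
  stopifnot(inherits(config, "generator_config"), config$mode == "sem",
            inherits(config$truth, "dag_truth"))
  truth <- config$truth
  labels <- truth$labels
  ord <- topological_order(labels, truth$arcs[, c("from", "to")])
  if (is.null(ord)) stop("arc set is cyclic", call. = FALSE)
  set.seed(config$seed)
  x <- matrix(0, nrow = config$n, ncol = length(labels),
              dimnames = list(NULL, labels))
  for (node in ord) {
    e <- rnorm(config$n, 0, truth$noise_sd[node])
    mu <- truth$intercepts[node]
    inc <- truth$arcs[truth$arcs$to == node, , drop = FALSE]
    pred <- if (nrow(inc))
      x[, inc$from, drop = FALSE] %*% inc$coef else 0
    x[, node] <- mu + pred + e
  }
  list(data = x, truth = truth)
}

## Per-item expected value given a common threshold shift c:
## item = 1 + #{j : latent > t_j - c}, latent ~ N(0,1).
item_mean_at_shift <- function(c, thresholds) {
  1 + sum(pnorm(c - thresholds))
}

## Solve the common threshold shift so that k * E[item] = target sum mean.
solve_threshold_shift <- function(target_sum_mean, k, thresholds) {
  target <- target_sum_mean / k
  if (target <= 1 || target >= 5)
    stop("target mean per item must lie strictly in (1, 5)", call. = FALSE)
  uniroot(function(c) item_mean_at_shift(c, thresholds) - target,
          interval = c(-10, 10), tol = 1e-10)$root
}

#' Generate Likert item responses from calibrated one-factor models
#'
#' For each dimension, items load on a single latent factor with equal
#' loadings solved from the instrument's target Cronbach's alpha
#' (\eqn{\lambda^2 = \alpha / (k - \alpha (k - 1))} on the latent scale;
#' discretization attenuates the realized alpha slightly).  Item latents are
#' cut at four thresholds -- equal-probability quintiles shifted by a common
#' offset solved so the expected scale-sum mean equals the target mean.
#' Dimensions are generated independently; item mode is meant for scoring and
#' reliability tests, not for network recovery.
#'
#' @param config a [generator_config()] with `mode = "item"`.
#' @return list with `data` (matrix of integer responses 1..5, columns named
#'   `<dimension>_<item>`) and `item_map` (instrument -> column names, in
#'   instrument order).
#' @export
generate_item_responses <- function(config) {
  stopifnot(inherits(config, "generator_config"), config$mode == "item")
  tab <- table1_targets()
  instrument <- c(Anx = "k10", Dep = "k10", DIF = "tas20", DDF = "tas20",
                  EOT = "tas20", POS = "rese", DES = "rese", ANG = "rese",
                  HMU = "hums", UHMU = "hums")
  base_thresholds <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  set.seed(config$seed)
  blocks <- list()
  for (d in tab$dimension) {
    k <- tab$items[tab$dimension == d]
    alpha <- config$alpha_target[[instrument[[d]]]]
    lam2 <- alpha / (k - alpha * (k - 1))
    lam2 <- min(max(lam2, 0), 0.999)
    shift <- solve_threshold_shift(config$target_means[[d]], k, base_thresholds)
    f <- rnorm(config$n)
    y <- sqrt(lam2) * f +
      sqrt(1 - lam2) * matrix(rnorm(config$n * k), nrow = config$n)
    cuts <- base_thresholds - shift
    items <- matrix(1L, nrow = config$n, ncol = k)
    for (t in cuts) items <- items + (y > t)
    colnames(items) <- paste0(d, "_", seq_len(k))
    blocks[[d]] <- items
  }
  data <- do.call(cbind, blocks)
  item_map <- list(
    k10 = c(colnames(blocks$Anx), colnames(blocks$Dep)),
    tas20 = c(colnames(blocks$DIF), colnames(blocks$DDF), colnames(blocks$EOT)),
    rese = c(colnames(blocks$POS), colnames(blocks$DES), colnames(blocks$ANG)),
    hums = c(colnames(blocks$HMU), colnames(blocks$UHMU)))
  list(data = data, item_map = item_map)
}
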