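## Data transforms and regularized partial-correlation network estimation.

#' Column-wise z-standardization
#'
#' @param x numeric matrix or data frame.
#' @return matrix with each column centered and scaled to unit sample SD;
#'   carries attribute `transform_log = "zscore"`.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd)
  if (any(sds <= 0)) {
    bad <- colnames(x)[which(sds <= 0)[1]]
    if (is.null(bad)) bad <- which(sds <= 0)[1]
    stop(sprintf("column %s is constant and cannot be standardized", bad),
         call. = FALSE)
  }
  out <- scale(x)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "transform_log") <- c(attr(x, "transform_log"), "zscore")
  out
}

#' Winsorization bound of the nonparanormal transform
#'
#' \eqn{\delta_n = 1 / (4 n^{1/4} \sqrt{\pi \log n})}, the truncation level
#' of the shrunken empirical CDF.
#'
#' @param n sample size.
#' @return the truncation level.
#' @export
npn_delta <- function(n) {
  1 / (4 * n^0.25 * sqrt(pi * log(n)))
}

#' Nonparanormal (copula) transform
#'
#' Rank-based Gaussianization: each column's empirical CDF (ranks / n,
#' average ranks for ties) is winsorized to
#' \eqn{[\delta_n, 1 - \delta_n]} with \eqn{\delta_n} from [npn_delta()],
#' mapped through the standard-normal quantile function and rescaled to unit
#' sample variance.  Invariant under strictly increasing transformations of
#' any column.
#'
#' @param x numeric matrix or data frame with at least 2 rows.
#' @return transformed matrix with attribute `transform_log` extended by
#'   `"npn"`.
#' @export
npn_transform <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("nonparanormal transform needs at least 2 rows", call. = FALSE)
  delta <- npn_delta(n)
  out <- apply(x, 2, function(col) {
    u <- rank(col, ties.method = "average") / n
    q <- qnorm(pmin(pmax(u, delta), 1 - delta))
    q / sd(q)
  })
  dimnames(out) <- dimnames(x)
  attr(out, "transform_log") <- c(attr(x, "transform_log"), "npn")
  out
}

#' Graphical-lasso regularization path
#'
#' Estimates the sparse precision matrix at a decreasing log-spaced grid of
#' penalties from \eqn{\lambda_{max}} (the largest absolute off-diagonal
#' sample correlation, at which the graph is empty) down to
#' \eqn{\lambda_{max} \cdot} `lambda_min_ratio`.  Each fit solves the
#' graphical-lasso objective
#' \eqn{-\log\det\Omega + tr(S\Omega) + \lambda \|\Omega\|_{1,off}}
#' by block coordinate descent with warm starts (off-diagonal penalty only).
#'
#' @param x standardized data matrix (rows = respondents).
#' @param n_lambdas number of penalty values (>= 2).
#' @param lambda_min_ratio smallest penalty as a fraction of
#'   \eqn{\lambda_{max}}.
#' @param S optional correlation matrix overriding `cor(x)` (then `n` must
#'   be given).
#' @param n sample size (defaults to `nrow(x)`).
#' @return object of class `glasso_path`: list with `lambda`, `omega` (list
#'   of precision matrices), `edges` (edge counts), `loglik`, `labels`, `n`,
#'   `p`, `converged`.
#' @export
glasso_path <- function(x = NULL, n_lambdas = 100, lambda_min_ratio = 0.01,
                        S = NULL, n = NULL) {
  if (is.null(S)) {
    x <- as.matrix(x)
    S <- cor(x)
    n <- nrow(x)
  }
  stopifnot(n_lambdas >= 2, !is.null(n), nrow(S) == ncol(S))
  p <- nrow(S)
  labels <- colnames(S)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max <= 0) lambda_max <- lambda_min_ratio  # fully independent data
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambdas))
  omegas <- vector("list", n_lambdas)
  edges <- integer(n_lambdas)
  loglik <- numeric(n_lambdas)
  conv <- logical(n_lambdas)
  W <- matrix(0, 0, 0)
  B <- matrix(0, 0, 0)
  for (i in seq_along(lambdas)) {
    fit <- .glasso_cd(S, lambdas[i], W, B)
    W <- fit$W
    B <- fit$B
    om <- fit$Omega
    om[abs(om) < 1e-10] <- 0
    dimnames(om) <- list(labels, labels)
    omegas[[i]] <- om
    edges[i] <- sum(om[upper.tri(om)] != 0)
    loglik[i] <- gaussian_loglik(om, S, n)
    conv[i] <- fit$converged
  }
  structure(list(lambda = lambdas, omega = omegas, edges = edges,
                 loglik = loglik, labels = labels, n = n, p = p,
                 converged = conv),
            class = "glasso_path")
}

## Gaussian log-likelihood of precision matrix Omega given sample
## correlation S at sample size n.
gaussian_loglik <- function(omega, S, n) {
  ld <- determinant(omega, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  p <- nrow(omega)
  n / 2 * (as.numeric(ld$modulus) - sum(S * omega) - p * log(2 * pi))
}

#' Partial correlations from a precision matrix
#'
#' \eqn{\rho_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}}}, with a
#' zero diagonal.
#'
#' @param omega symmetric precision matrix.
#' @return symmetric matrix of partial correlations.
#' @export
precision_to_parcor <- function(omega) {
  d <- sqrt(diag(omega))
  rho <- -omega / tcrossprod(d)
  diag(rho) <- 0
  rho
}

#' Select a network from a glasso path by EBIC
#'
#' Extended Bayesian information criterion
#' \eqn{EBIC(\lambda) = -2\,\ell(\hat\Omega) + E \log n + 4 \gamma E \log p}
#' with \eqn{E} the edge count; the minimizing model is returned (ties go to
#' the sparser model, i.e. the larger penalty).
#'
#' @param path a [glasso_path()] object.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @return object of class `pcnetwork`: list with `labels`, `weights`
#'   (partial-correlation matrix), `precision`, `lambda_selected`,
#'   `ebic_value`, `gamma`, `n`, `ebic` (full criterion curve).
#' @export
select_by_ebic <- function(path, gamma = 0.5) {
  stopifnot(inherits(path, "glasso_path"))
  ok <- path$converged & is.finite(path$loglik)
  if (!any(ok)) stop("no converged model on the path", call. = FALSE)
  ebic <- -2 * path$loglik + path$edges * log(path$n) +
    4 * gamma * path$edges * log(path$p)
  ebic[!ok] <- Inf
  best <- which.min(ebic)  # first index = largest lambda on ties
  omega <- path$omega[[best]]
  structure(list(labels = path$labels,
                 weights = precision_to_parcor(omega),
                 precision = omega,
                 lambda_selected = path$lambda[best],
                 ebic_value = ebic[best],
                 gamma = gamma, n = path$n, ebic = ebic),
            class = "pcnetwork")
}

#' Estimate a regularized partial-correlation network
#'
#' Convenience wrapper: nonparanormal transform (optional), graphical-lasso
#' path, EBIC selection.
#'
#' @param x data matrix (rows = respondents, columns = dimensions).
#' @param npn apply [npn_transform()] first (default TRUE).
#' @param gamma EBIC hyperparameter.
#' @param n_lambdas,lambda_min_ratio see [glasso_path()].
#' @return a `pcnetwork` object.
#' @export
estimate_network <- function(x, npn = TRUE, gamma = 0.5, n_lambdas = 100,
                             lambda_min_ratio = 0.01) {
  x <- as.matrix(x)
  if (npn) x <- npn_transform(x)
  select_by_ebic(glasso_path(x, n_lambdas, lambda_min_ratio), gamma = gamma)
}

#' @export
print.pcnetwork <- function(x, ...) {
  e <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("Regularized partial-correlation network: %d nodes, %d edges\n",
              length(x$labels), e))
  cat(sprintf("  lambda = %.4g, EBIC = %.2f (gamma = %.2f), n = %d\n",
              x$lambda_selected, x$ebic_value, x$gamma, x$n))
  invisible(x)
}

## Coerce a pcnetwork or plain symmetric matrix to a weights matrix.
network_weights <- function(network) {
  w <- if (inherits(network, "pcnetwork")) network$weights else as.matrix(network)
  stopifnot(nrow(w) == ncol(w), isTRUE(all.equal(w, t(w), tolerance = 1e-8)))
  if (is.null(colnames(w)))
    dimnames(w) <- list(paste0("V", seq_len(ncol(w))), paste0("V", seq_len(ncol(w))))
  diag(w) <- 0
  w
}
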