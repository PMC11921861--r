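## Gaussian Bayesian networks: BIC scoring, hill-climbing structure search,
## bootstrap arc-strength averaging and per-child linear models.

## Kahn's algorithm; returns a topological order of `labels` under the arc
## data frame (columns from, to), or NULL if the arc set is cyclic.
topological_order <- function(labels, arcs) {
  indeg <- setNames(integer(length(labels)), labels)
  if (nrow(arcs)) {
    tab <- table(arcs$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  ready <- labels[indeg == 0]
  arcs_left <- arcs
  while (length(ready)) {
    node <- ready[1]
    ready <- ready[-1]
    out <- c(out, node)
    childs <- arcs_left$to[arcs_left$from == node]
    arcs_left <- arcs_left[arcs_left$from != node, , drop = FALSE]
    for (ch in childs) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(out) == length(labels)) out else NULL
}

## Directed path from `from` to `to` in a logical adjacency matrix
## (amat[i, j] = TRUE means arc i -> j)?  Iterative DFS.
has_directed_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(amat))
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    nxt <- which(amat[v, ])
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt[!seen[nxt]])
  }
  FALSE
}

## Locate one directed cycle; returns the ordered node index vector of the
## cycle, or NULL if the graph is acyclic.
find_cycle <- function(amat) {
  p <- nrow(amat)
  color <- integer(p)  # 0 white, 1 grey, 2 black
  parent <- integer(p)
  cyc <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    for (u in which(amat[v, ])) {
      if (!is.null(cyc)) return()
      if (color[u] == 0L) {
        parent[u] <<- v
        visit(u)
      } else if (color[u] == 1L) {
        path <- v
        while (path[1] != u) path <- c(parent[path[1]], path)
        cyc <<- path
        return()
      }
    }
    color[v] <<- 2L
  }
  for (v in seq_len(p)) {
    if (color[v] == 0L && is.null(cyc)) visit(v)
  }
  cyc
}

## Maximum-likelihood covariance (divisor n) of a data matrix.
mle_cov <- function(data) {
  data <- as.matrix(data)
  xc <- sweep(data, 2, colMeans(data))
  crossprod(xc) / nrow(data)
}

## BIC contribution of one node given its parent set, computed from the MLE
## covariance: loglik of the Gaussian child | parents regression minus
## (|parents| + 2)/2 * log n (intercept + coefficients + residual variance).
node_bic <- function(S, n, child, parents, cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  sigma2 <- if (length(parents) == 0) {
    S[child, child]
  } else {
    sp <- tryCatch(solve(S[parents, parents, drop = FALSE],
                         S[parents, child]),
                   error = function(e) NULL)
    if (is.null(sp)) NA_real_ else S[child, child] - sum(S[child, parents] * sp)
  }
  val <- if (is.na(sigma2) || sigma2 <= 1e-12) {
    -Inf
  } else {
    -n / 2 * (log(2 * pi * sigma2) + 1) -
      (length(parents) + 2) / 2 * log(n)
  }
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Gaussian BIC score of a directed acyclic graph
#'
#' Decomposable network score: for each node, the Gaussian log-likelihood of
#' the child given its parents at the OLS/MLE fit minus
#' \eqn{(|parents| + 2)/2 \cdot \log n} (intercept, coefficients and residual
#' variance all count as parameters).  Markov-equivalent DAGs receive equal
#' scores.
#'
#' @param data respondent x node matrix with columns matching `dag` labels.
#' @param dag a `bn_dag` object or a data frame of arcs (`from`, `to`).
#' @return the total score (sum over nodes); `-Inf` if any node's parent
#'   design is singular.
#' @export
bic_g_score <- function(data, dag) {
  data <- as.matrix(data)
  labels <- colnames(data)
  arcs <- if (inherits(dag, "bn_dag")) dag$arcs else as.data.frame(dag)
  stopifnot(all(arcs$from %in% labels), all(arcs$to %in% labels))
  if (is.null(topological_order(labels, arcs)))
    stop("graph is cyclic", call. = FALSE)
  S <- mle_cov(data)
  n <- nrow(data)
  sum(vapply(labels, function(ch)
    node_bic(S, n, ch, arcs$from[arcs$to == ch]), numeric(1)))
}

## Build a bn_dag object from an adjacency matrix and per-node scores.
amat_to_dag <- function(amat, labels, score) {
  idx <- which(amat, arr.ind = TRUE)
  arcs <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                     stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(nodes = labels, arcs = arcs, score = score),
            class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("Gaussian Bayesian network: %d nodes, %d arcs, score %.3f\n",
              length(x$nodes), nrow(x$arcs), x$score))
  if (nrow(x$arcs))
    cat(paste0("  ", x$arcs$from, " -> ", x$arcs$to, collapse = "\n"), "\n")
  invisible(x)
}

## Greedy local search over add/delete/reverse moves from a starting
## adjacency matrix.  Moves are enumerated in a fixed (parent, child) order
## and the first strictly best improvement is taken, so the search is
## deterministic.  Returns list(amat, node_scores).
hc_local_search <- function(S, n, amat, cache, max_iter = 1000L) {
  p <- nrow(S)
  labels <- rownames(S)
  ns <- vapply(seq_len(p), function(j)
    node_bic(S, n, labels[j], labels[amat[, j]], cache), numeric(1))
  for (iter in seq_len(max_iter)) {
    best_delta <- 1e-10
    best <- NULL
    for (from in seq_len(p)) for (to in seq_len(p)) {
      if (from == to) next
      if (amat[from, to]) {
        # delete from -> to
        d <- node_bic(S, n, labels[to],
                      labels[amat[, to] & seq_len(p) != from], cache) - ns[to]
        if (d > best_delta) { best_delta <- d; best <- c(1L, from, to) }
        # reverse from -> to: legal unless another from ~> to path remains
        amat[from, to] <- FALSE
        legal <- !has_directed_path(amat, from, to)
        amat[from, to] <- TRUE
        if (legal) {
          d_to <- node_bic(S, n, labels[to],
                           labels[amat[, to] & seq_len(p) != from], cache) - ns[to]
          d_from <- node_bic(S, n, labels[from],
                             labels[amat[, from] | seq_len(p) == to], cache) - ns[from]
          d <- d_to + d_from
          if (d > best_delta) { best_delta <- d; best <- c(3L, from, to) }
        }
      } else if (!amat[to, from]) {
        # add from -> to: legal unless a to ~> from path exists
        if (!has_directed_path(amat, to, from)) {
          d <- node_bic(S, n, labels[to],
                        labels[amat[, to] | seq_len(p) == from], cache) - ns[to]
          if (d > best_delta) { best_delta <- d; best <- c(2L, from, to) }
        }
      }
    }
    if (is.null(best)) break
    op <- best[1]; from <- best[2]; to <- best[3]
    if (op == 1L) {
      amat[from, to] <- FALSE
    } else if (op == 2L) {
      amat[from, to] <- TRUE
    } else {
      amat[from, to] <- FALSE
      amat[to, from] <- TRUE
      ns[from] <- node_bic(S, n, labels[from], labels[amat[, from]], cache)
    }
    ns[to] <- node_bic(S, n, labels[to], labels[amat[, to]], cache)
  }
  list(amat = amat, node_scores = ns)
}

## Apply k random legal arc insertions/deletions/reversals to amat.
hc_perturb <- function(amat, k) {
  p <- nrow(amat)
  for (i in seq_len(k)) {
    for (try in 1:20) {
      from <- sample.int(p, 1)
      to <- sample.int(p, 1)
      if (from == to) next
      if (amat[from, to]) {
        if (runif(1) < 0.5) {
          amat[from, to] <- FALSE
          break
        }
        amat[from, to] <- FALSE
        if (!has_directed_path(amat, from, to)) {
          amat[to, from] <- TRUE
          break
        }
        amat[from, to] <- TRUE
      } else if (!amat[to, from] && !has_directed_path(amat, to, from)) {
        amat[from, to] <- TRUE
        break
      }
    }
  }
  amat
}

#' Hill-climbing structure learning for Gaussian Bayesian networks
#'
#' Greedy search over single-arc additions, deletions and reversals under the
#' decomposable Gaussian BIC score ([bic_g_score()]), accepting the best
#' strictly improving move until a local optimum is reached.  The search is
#' then restarted `restarts` times from the incumbent best graph perturbed by
#' `perturbations` random legal moves, and the best-scoring DAG found overall
#' is returned.  With a fixed `seed` the result is fully deterministic.
#'
#' @param data respondent x node matrix.
#' @param restarts number of random restarts (default 50).
#' @param perturbations random legal moves applied to the incumbent before
#'   each restart (default 100).
#' @param seed optional RNG seed set before the first perturbation.
#' @param max_iter cap on accepted moves per local search.
#' @return a `bn_dag` object (nodes, arcs, score).
#' @export
hill_climb <- function(data, restarts = 50, perturbations = 100, seed = NULL,
                       max_iter = 1000L) {
  stopifnot(restarts >= 0)
  data <- as.matrix(data)
  labels <- colnames(data)
  if (is.null(labels)) {
    labels <- paste0("V", seq_len(ncol(data)))
    colnames(data) <- labels
  }
  S <- mle_cov(data)
  n <- nrow(data)
  if (n <= ncol(data) + 2)
    stop("too few rows for structure learning", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  p <- length(labels)
  if (!is.null(seed)) set.seed(seed)
  best <- hc_local_search(S, n, matrix(FALSE, p, p), cache, max_iter)
  best_score <- sum(best$node_scores)
  for (r in seq_len(restarts)) {
    start <- hc_perturb(best$amat, perturbations)
    cand <- hc_local_search(S, n, start, cache, max_iter)
    cand_score <- sum(cand$node_scores)
    if (cand_score > best_score + 1e-10) {
      best <- cand
      best_score <- cand_score
    }
  }
  dimnames(best$amat) <- list(labels, labels)
  amat_to_dag(best$amat, labels, best_score)
}

#' Tally adjacency and direction frequencies over replicate DAGs
#'
#' @param dags list of `bn_dag` objects (or arc data frames) over the same
#'   node set.
#' @param labels node labels.
#' @return object of class `arc_confidence`: data frame per unordered pair
#'   (`node_a` < `node_b` in label order) with `strength` (fraction of
#'   replicates in which the pair is adjacent) and `dir_ab`/`dir_ba`
#'   (orientation fractions among adjacency-containing replicates).
#' @export
arc_frequencies <- function(dags, labels) {
  R <- length(dags)
  stopifnot(R > 0)
  p <- length(labels)
  adj <- matrix(0, p, p, dimnames = list(labels, labels))   # ordered counts
  for (d in dags) {
    arcs <- if (inherits(d, "bn_dag")) d$arcs else as.data.frame(d)
    if (nrow(arcs))
      for (i in seq_len(nrow(arcs)))
        adj[arcs$from[i], arcs$to[i]] <- adj[arcs$from[i], arcs$to[i]] + 1
  }
  ut <- which(upper.tri(adj), arr.ind = TRUE)
  n_ab <- adj[ut]
  n_ba <- t(adj)[ut]
  n_adj <- n_ab + n_ba
  out <- data.frame(node_a = labels[ut[, 1]], node_b = labels[ut[, 2]],
                    strength = n_adj / R,
                    dir_ab = ifelse(n_adj > 0, n_ab / n_adj, 0),
                    dir_ba = ifelse(n_adj > 0, n_ba / n_adj, 0))
  structure(out, class = c("arc_confidence", "data.frame"),
            labels = labels, replicates = R)
}

#' Bootstrap arc strengths and directions
#'
#' Draws `R` bootstrap resamples of the rows (with replacement, size n),
#' learns a DAG on each by [hill_climb()] and tallies, per unordered node
#' pair, the adjacency frequency (arc strength) and the orientation
#' frequency among replicates containing the adjacency (direction).
#' Replicates in which learning fails are dropped and counted.
#'
#' @param data respondent x node matrix.
#' @param R number of bootstrap replicates (>= 50).
#' @param restarts,perturbations hill-climb settings per replicate; default 1
#'   restart without perturbations (the signal the averaged network keeps is
#'   carried by the resampling, and one greedy run per replicate keeps the
#'   bootstrap tractable).
#' @param seed RNG seed for the whole bootstrap.
#' @param max_iter see [hill_climb()].
#' @return an `arc_confidence` object (see [arc_frequencies()]) with a
#'   `failures` attribute.
#' @export
bootstrap_arcs <- function(data, R = 1000, restarts = 1, perturbations = 0,
                           seed = 1, max_iter = 1000L) {
  stopifnot(R >= 50)
  data <- as.matrix(data)
  n <- nrow(data)
  labels <- colnames(data)
  set.seed(seed)
  dags <- vector("list", R)
  fail <- 0L
  for (r in seq_len(R)) {
    idx <- sample.int(n, n, replace = TRUE)
    dag <- tryCatch(hill_climb(data[idx, , drop = FALSE], restarts = restarts,
                               perturbations = perturbations, seed = NULL,
                               max_iter = max_iter),
                    error = function(e) NULL)
    if (is.null(dag)) fail <- fail + 1L
    dags[[r]] <- dag
  }
  dags <- dags[!vapply(dags, is.null, logical(1))]
  if (length(dags) == 0) stop("all bootstrap replicates failed", call. = FALSE)
  out <- arc_frequencies(dags, labels)
  attr(out, "failures") <- fail
  out
}

#' Averaged network from bootstrap arc confidences
#'
#' Retains every node pair whose arc strength reaches `strength_threshold`
#' and orients it by the majority direction (strictly above
#' `direction_threshold`; pairs split exactly 50/50 are excluded and logged
#' as ambiguous).  If the retained arcs contain a directed cycle, the
#' lowest-strength arc in each cycle is dropped until the graph is acyclic.
#' Arcs are reported in descending order of strength.
#'
#' @param conf an `arc_confidence` object.
#' @param strength_threshold minimum adjacency frequency (default 0.85).
#' @param direction_threshold orientation frequency that must be exceeded
#'   (default 0.5).
#' @return object of class `averaged_network`: list with `arcs` (data frame
#'   `from`, `to`, `strength`, `direction`), `thresholds`, `ambiguous`
#'   (excluded 50/50 pairs), `removed` (arcs dropped to break cycles) and
#'   `labels`.
#' @export
averaged_network <- function(conf, strength_threshold = 0.85,
                             direction_threshold = 0.5) {
  stopifnot(inherits(conf, "arc_confidence"),
            strength_threshold > 0, strength_threshold < 1,
            direction_threshold > 0, direction_threshold < 1)
  labels <- attr(conf, "labels")
  keep <- conf[conf$strength >= strength_threshold, , drop = FALSE]
  arcs <- data.frame(from = character(0), to = character(0),
                     strength = numeric(0), direction = numeric(0))
  ambiguous <- keep[0, , drop = FALSE]
  for (i in seq_len(nrow(keep))) {
    row <- keep[i, ]
    if (row$dir_ab > direction_threshold) {
      arcs <- rbind(arcs, data.frame(from = row$node_a, to = row$node_b,
                                     strength = row$strength,
                                     direction = row$dir_ab))
    } else if (row$dir_ba > direction_threshold) {
      arcs <- rbind(arcs, data.frame(from = row$node_b, to = row$node_a,
                                     strength = row$strength,
                                     direction = row$dir_ba))
    } else {
      ambiguous <- rbind(ambiguous, row)
    }
  }
  removed <- arcs[0, , drop = FALSE]
  amat <- matrix(FALSE, length(labels), length(labels),
                 dimnames = list(labels, labels))
  for (i in seq_len(nrow(arcs))) amat[arcs$from[i], arcs$to[i]] <- TRUE
  repeat {
    cyc <- find_cycle(amat)
    if (is.null(cyc)) break
    cyc_arcs <- data.frame(from = labels[cyc],
                           to = labels[c(cyc[-1], cyc[1])])
    in_cycle <- paste(arcs$from, arcs$to) %in% paste(cyc_arcs$from, cyc_arcs$to)
    cand <- arcs[in_cycle, , drop = FALSE]
    cand <- cand[order(cand$strength, cand$from, cand$to), , drop = FALSE]
    drop <- cand[1, ]
    removed <- rbind(removed, drop)
    amat[drop$from, drop$to] <- FALSE
    arcs <- arcs[!(arcs$from == drop$from & arcs$to == drop$to), , drop = FALSE]
  }
  arcs <- arcs[order(-arcs$strength, arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(arcs = arcs, labels = labels,
                 thresholds = c(strength = strength_threshold,
                                direction = direction_threshold),
                 ambiguous = ambiguous, removed = removed),
            class = "averaged_network")
}

#' @export
print.averaged_network <- function(x, ...) {
  cat(sprintf("Averaged Bayesian network: %d arcs (strength >= %.2f, direction > %.2f)\n",
              nrow(x$arcs), x$thresholds["strength"], x$thresholds["direction"]))
  if (nrow(x$arcs))
    print(x$arcs)
  if (nrow(x$ambiguous))
    cat(sprintf("  %d pair(s) excluded as direction-ambiguous\n", nrow(x$ambiguous)))
  if (nrow(x$removed))
    cat(sprintf("  %d arc(s) removed to break cycles\n", nrow(x$removed)))
  invisible(x)
}

#' Linear models for each child node of an averaged network
#'
#' Fits, per node with at least one parent, the ordinary-least-squares
#' regression of the child on its parents (via `lm`) and reports the
#' intercept, per-parent estimate, standard error and two-sided t-test
#' p-value, together with the model R-squared, residual standard error
#' (\eqn{\sqrt{RSS/(n - k - 1)}}) and overall F-test p-value.  Parentless
#' nodes yield no regression.
#'
#' @param data respondent x node matrix or data frame.
#' @param avg an `averaged_network` object (or data frame of arcs).
#' @return list of class `child_regressions`; each element has `child`,
#'   `parents`, `intercept`, `coefficients` (data frame `parent`, `beta`,
#'   `se`, `p`), `r_squared`, `rse`, `f_p`, `n`.
#' @export
fit_child_regressions <- function(data, avg) {
  data <- as.data.frame(data)
  arcs <- if (inherits(avg, "averaged_network")) avg$arcs else as.data.frame(avg)
  children <- unique(arcs$to)
  out <- list()
  for (child in children) {
    parents <- arcs$from[arcs$to == child]
    df <- data[, c(child, parents), drop = FALSE]
    fit <- lm(stats::reformulate(sprintf("`%s`", parents),
                                 response = sprintf("`%s`", child)),
              data = df)
    if (anyNA(coef(fit)))
      stop(sprintf("collinear parents for child node %s", child), call. = FALSE)
    s <- summary(fit)
    cf <- s$coefficients
    out[[child]] <- list(
      child = child, parents = parents,
      intercept = unname(cf[1, 1]),
      coefficients = data.frame(parent = parents,
                                beta = cf[-1, 1],
                                se = cf[-1, 2],
                                p = cf[-1, 4],
                                row.names = NULL),
      r_squared = s$r.squared,
      rse = s$sigma,
      f_p = unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                      lower.tail = FALSE)),
      n = nrow(df))
  }
  structure(out, class = "child_regressions")
}

#' @export
print.child_regressions <- function(x, ...) {
  for (m in x) {
    cat(sprintf("%s ~ %s:  R2 = %.3f, RSE = %.3f, p = %.3g\n",
                m$child, paste(m$parents, collapse = " + "),
                m$r_squared, m$rse, m$f_p))
    for (i in seq_len(nrow(m$coefficients)))
      cat(sprintf("    %-6s beta = %8.4f  SE = %.4f  p = %.3g\n",
                  m$coefficients$parent[i], m$coefficients$beta[i],
                  m$coefficients$se[i], m$coefficients$p[i]))
  }
  invisible(x)
}
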