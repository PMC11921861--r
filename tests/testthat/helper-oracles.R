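# Independent oracles used across the suite.  Each deliberately takes a
# different algorithmic route than the package implementation it checks.

# Proximal-gradient (ISTA) solver for the graphical-lasso objective
#   -log det(Omega) + tr(S Omega) + lambda * ||Omega||_{1,off}
# Gradient steps on the smooth part, soft-thresholding of the off-diagonal,
# with a positive-definiteness backtracking safeguard.
ista_glasso <- function(S, lambda, iters = 30000, step = 0.05) {
  p <- nrow(S)
  omega <- diag(p)
  soft <- function(m, th) sign(m) * pmax(abs(m) - th, 0)
  for (i in seq_len(iters)) {
    grad <- S - solve(omega)
    cand <- omega - step * grad
    nxt <- soft(cand, step * lambda)
    diag(nxt) <- diag(cand)
    ev <- min(eigen(nxt, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) { step <- step / 2; next }
    omega <- nxt
  }
  omega
}

# All simple paths between two nodes of a weighted graph, by depth-first
# enumeration.  Returns a list of node-index vectors.
enumerate_simple_paths <- function(w, from, to) {
  p <- nrow(w)
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (nxt in seq_len(p)) {
      if (w[last, nxt] != 0 && !(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(from)
  paths
}

# Brute-force node and bridge centrality by exhaustive path enumeration
# (distance = 1/|w| per edge).  Only for tiny graphs.
oracle_centrality <- function(w, communities = NULL) {
  p <- nrow(w)
  len <- function(path) {
    if (length(path) < 2) return(0)
    sum(1 / abs(w[cbind(path[-length(path)], path[-1])]))
  }
  dist <- matrix(Inf, p, p); diag(dist) <- 0
  npaths <- matrix(0, p, p)
  through <- array(0, c(p, p, p))  # [u, v, i] shortest u-v paths via i
  for (u in 1:p) for (v in 1:p) {
    if (u == v) next
    ps <- enumerate_simple_paths(w, u, v)
    if (!length(ps)) next
    ls <- vapply(ps, len, numeric(1))
    dist[u, v] <- min(ls)
    short <- ps[abs(ls - min(ls)) < 1e-10]
    npaths[u, v] <- length(short)
    for (sp in short)
      for (i in setdiff(sp, c(u, v))) through[u, v, i] <- through[u, v, i] + 1
  }
  strength <- rowSums(abs(w))
  ei1 <- rowSums(w)
  dsum <- rowSums(dist)
  closeness <- ifelse(is.finite(dsum) & dsum > 0, 1 / dsum, 0)
  betw <- numeric(p)
  for (i in 1:p) for (u in 1:(p - 1)) for (v in (u + 1):p)
    if (i != u && i != v && npaths[u, v] > 0)
      betw[i] <- betw[i] + through[u, v, i] / npaths[u, v]
  out <- list(strength = strength, closeness = closeness,
              betweenness = betw, expected_influence_1 = ei1)
  if (!is.null(communities)) {
    cross <- outer(communities, communities, "!=")
    out$bridge_strength <- rowSums(abs(w) * cross)
    out$bridge_expected_influence_1 <- rowSums(w * cross)
    bc <- numeric(p); bb <- numeric(p)
    for (i in 1:p) {
      outside <- which(communities != communities[i])
      md <- mean(dist[i, outside])
      bc[i] <- if (is.finite(md) && md > 0) 1 / md else 0
      for (u in 1:(p - 1)) for (v in (u + 1):p)
        if (i != u && i != v && communities[u] != communities[v])
          bb[i] <- bb[i] + through[u, v, i]
    }
    out$bridge_closeness <- bc
    out$bridge_betweenness <- bb
  }
  out
}

# Every DAG on the given labels (all acyclic orientations of all arc
# subsets), as a list of arc data frames.  3 nodes -> 25 DAGs.
enumerate_dags <- function(labels) {
  p <- length(labels)
  pairs <- t(combn(p, 2))
  states <- expand.grid(rep(list(0:2), nrow(pairs)))  # 0 none, 1 a->b, 2 b->a
  dags <- list()
  for (r in seq_len(nrow(states))) {
    arcs <- data.frame(from = character(0), to = character(0))
    for (k in seq_len(nrow(pairs))) {
      s <- states[r, k]
      if (s == 1) arcs <- rbind(arcs, data.frame(from = labels[pairs[k, 1]],
                                                 to = labels[pairs[k, 2]]))
      if (s == 2) arcs <- rbind(arcs, data.frame(from = labels[pairs[k, 2]],
                                                 to = labels[pairs[k, 1]]))
    }
    if (!is.null(musenet:::topological_order(labels, arcs)))
      dags[[length(dags) + 1]] <- arcs
  }
  dags
}

# OLS by explicit normal equations, with classical SE, R2, RSE.
normal_equations_ols <- function(y, X) {
  X1 <- cbind(1, X)
  xtx <- t(X1) %*% X1
  beta <- solve(xtx, t(X1) %*% y)
  res <- y - X1 %*% beta
  n <- length(y); k <- ncol(X)
  s2 <- sum(res^2) / (n - k - 1)
  se <- sqrt(diag(s2 * solve(xtx)))
  list(beta = unname(drop(beta)), se = se,
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       rse = sqrt(s2))
}

# Integer Likert row of k items summing to s (items in 1..5).
likert_row_with_sum <- function(k, s) {
  base <- s %/% k; rem <- s %% k
  stopifnot(base >= 1, base + (rem > 0) <= 5)
  c(rep(base + 1, rem), rep(base, k - rem))
}
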