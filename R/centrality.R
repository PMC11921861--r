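## Node and bridge centrality on signed weighted networks.
##
## Distance convention: shortest paths run over edge lengths 1/|w_ij|
## (stronger association = shorter distance).  Unreachable nodes make the
## relevant distance sum infinite, so closeness-type indices fall to 0.

## Shortest-path distance matrix under the 1/|w| length convention.
path_distances <- function(w) {
  aw <- abs(w)
  g <- igraph::graph_from_adjacency_matrix(aw, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  dimnames(d) <- dimnames(w)
  d
}

## Counts of shortest paths between every ordered pair, from the distance
## matrix: sigma[u, v] = number of distinct shortest u-v paths.  Lengths are
## compared at an absolute tolerance so equal-weight ties are credited.
shortest_path_counts <- function(w, d, tol = 1e-10) {
  p <- nrow(w)
  len <- 1 / abs(w)  # Inf where no edge
  sigma <- matrix(0, p, p)
  for (u in seq_len(p)) {
    ord <- order(d[u, ])
    sigma[u, u] <- 1
    for (v in ord) {
      if (v == u || !is.finite(d[u, v])) next
      pred <- which(is.finite(len[, v]) &
                      abs(d[u, ] + len[, v] - d[u, v]) < tol)
      sigma[u, v] <- sum(sigma[u, pred])
    }
  }
  sigma
}

## For intermediate i and pair (u, v): is i on a shortest u-v path, and how
## many / what fraction of them pass through i.
on_path_credit <- function(d, sigma, u, v, i, tol = 1e-10) {
  if (i == u || i == v || sigma[u, v] == 0) return(c(count = 0, fraction = 0))
  if (abs(d[u, i] + d[i, v] - d[u, v]) < tol) {
    cnt <- sigma[u, i] * sigma[i, v]
    c(count = cnt, fraction = cnt / sigma[u, v])
  } else c(count = 0, fraction = 0)
}

#' Node centrality of a signed weighted network
#'
#' Computes, per node: strength (sum of absolute incident weights),
#' one-step expected influence (sum of signed incident weights), closeness
#' (inverse of the summed shortest-path distances to all other nodes, with
#' distances 1/|w|; 0 if any node is unreachable) and betweenness (Brandes
#' shortest-path counting with fractional credit for equal-length ties,
#' compared at 1e-10).  Z-standardized columns are appended for profile
#' plots.
#'
#' @param network a `pcnetwork` or symmetric weights matrix.
#' @return data frame with columns `node`, `strength`, `closeness`,
#'   `betweenness`, `expected_influence_1` and their `_z` versions.
#' @export
node_centrality <- function(network) {
  w <- network_weights(network)
  p <- nrow(w)
  d <- path_distances(w)
  sigma <- shortest_path_counts(w, d)
  strength <- rowSums(abs(w))
  ei1 <- rowSums(w)
  dsum <- rowSums(d) # includes Inf when unreachable
  closeness <- ifelse(is.finite(dsum) & dsum > 0, 1 / dsum, 0)
  betweenness <- numeric(p)
  for (i in seq_len(p)) {
    acc <- 0
    for (u in seq_len(p - 1)) for (v in seq((u + 1), p)) {
      if (u == i || v == i) next
      acc <- acc + on_path_credit(d, sigma, u, v, i)[["fraction"]]
    }
    betweenness[i] <- acc
  }
  out <- data.frame(node = rownames(w), strength = strength,
                    closeness = closeness, betweenness = betweenness,
                    expected_influence_1 = ei1, row.names = NULL)
  for (col in c("strength", "closeness", "betweenness", "expected_influence_1")) {
    s <- sd(out[[col]])
    out[[paste0(col, "_z")]] <-
      if (is.na(s) || s == 0) rep(0, p) else (out[[col]] - mean(out[[col]])) / s
  }
  out
}

#' Instrument-based community assignment
#'
#' The default partition for bridge centrality: the music-use node is its own
#' community, and the RESE, TAS-20 and K10 dimensions form one community per
#' instrument.
#'
#' @param labels node labels.
#' @return named character vector node -> community.
#' @export
instrument_communities <- function(labels) {
  map <- c(HMU = "MusicUse", UHMU = "MusicUse",
           POS = "RESE", DES = "RESE", ANG = "RESE",
           DIF = "TAS", DDF = "TAS", EOT = "TAS",
           Anx = "K10", Dep = "K10")
  unknown <- setdiff(labels, names(map))
  if (length(unknown))
    stop(sprintf("no instrument community for node(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  setNames(map[labels], labels)
}

#' Bridge centrality of a signed weighted network
#'
#' Given a community assignment, computes per node: bridge strength (sum of
#' absolute weights of edges to other communities), bridge expected influence
#' (one-step; same edge set, signed sum), bridge closeness (inverse of the
#' mean shortest-path distance to all nodes outside the node's community) and
#' bridge betweenness (number of shortest paths between cross-community node
#' pairs passing through the node).
#'
#' @param network a `pcnetwork` or symmetric weights matrix.
#' @param communities named vector node -> community covering every node;
#'   default [instrument_communities()] on the network's labels.
#' @return data frame with columns `node`, `bridge_strength`,
#'   `bridge_closeness`, `bridge_betweenness`,
#'   `bridge_expected_influence_1`.
#' @export
bridge_centrality <- function(network, communities = NULL) {
  w <- network_weights(network)
  labels <- rownames(w)
  if (is.null(communities)) communities <- instrument_communities(labels)
  missing <- setdiff(labels, names(communities))
  if (length(missing))
    stop(sprintf("node(s) without community assignment: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  comm <- communities[labels]
  p <- nrow(w)
  cross <- outer(comm, comm, "!=")
  bs <- rowSums(abs(w) * cross)
  bei <- rowSums(w * cross)
  d <- path_distances(w)
  sigma <- shortest_path_counts(w, d)
  bc <- numeric(p)
  bb <- numeric(p)
  for (i in seq_len(p)) {
    outside <- which(comm != comm[i])
    if (length(outside)) {
      md <- mean(d[i, outside])
      bc[i] <- if (is.finite(md) && md > 0) 1 / md else 0
    }
    acc <- 0
    for (u in seq_len(p - 1)) for (v in seq((u + 1), p)) {
      if (u == i || v == i || comm[u] == comm[v]) next
      acc <- acc + on_path_credit(d, sigma, u, v, i)[["count"]]
    }
    bb[i] <- acc
  }
  data.frame(node = labels, bridge_strength = bs, bridge_closeness = bc,
             bridge_betweenness = bb, bridge_expected_influence_1 = bei,
             row.names = NULL)
}
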