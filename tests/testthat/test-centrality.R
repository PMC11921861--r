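# Small labeled weight matrices used throughout.
wmat <- function(edges, labels) {
  w <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_len(nrow(edges))) {
    w[edges$a[i], edges$b[i]] <- w[edges$b[i], edges$a[i]] <- edges$w[i]
  }
  w
}

test_that("strength and expected influence are signed/absolute degree sums", {
  w <- wmat(data.frame(a = c("X", "X"), b = c("Y", "Z"), w = c(0.3, -0.2)),
            c("X", "Y", "Z"))
  cent <- node_centrality(w)
  expect_equal(cent$strength[cent$node == "X"], 0.5)
  expect_equal(cent$expected_influence_1[cent$node == "X"], 0.1,
               tolerance = 1e-12)
})

test_that("path graph closeness/betweenness match hand enumeration", {
  w <- wmat(data.frame(a = c("A", "B"), b = c("B", "C"), w = c(0.5, 0.5)),
            c("A", "B", "C"))
  cent <- node_centrality(w)
  expect_equal(cent$closeness[cent$node == "B"], 0.25)  # 1/(2 + 2)
  expect_equal(cent$betweenness[cent$node == "B"], 1)
  expect_equal(cent$betweenness[cent$node == "A"], 0)
})

test_that("isolated nodes get zero strength, closeness and betweenness", {
  w <- wmat(data.frame(a = "A", b = "B", w = 0.4), c("A", "B", "Iso"))
  cent <- node_centrality(w)
  iso <- cent[cent$node == "Iso", ]
  expect_equal(iso$strength, 0)
  expect_equal(iso$closeness, 0)
  expect_equal(iso$betweenness, 0)
  # neighbors of an unreachable node also have closeness 0 by convention
  expect_equal(cent$closeness[cent$node == "A"], 0)
})

test_that("bridge indices separate cross-community from within-community edges", {
  comm <- c(N = "c1", M = "c1", P = "c2", Q = "c2")
  w <- wmat(data.frame(a = c("N", "N"), b = c("P", "M"), w = c(0.2, 0.4)),
            names(comm))
  b <- bridge_centrality(w, comm)
  expect_equal(b$bridge_strength[b$node == "N"], 0.2)
  w2 <- wmat(data.frame(a = c("N", "N"), b = c("P", "Q"), w = c(0.2, -0.1)),
             names(comm))
  b2 <- bridge_centrality(w2, comm)
  expect_equal(b2$bridge_strength[b2$node == "N"], 0.3)
  expect_equal(b2$bridge_expected_influence_1[b2$node == "N"], 0.1,
               tolerance = 1e-12)
})

test_that("all node and bridge indices match the exhaustive-path oracle", {
  labels <- c("A", "B", "C", "D")
  comm <- setNames(c("c1", "c1", "c2", "c2"), labels)
  w <- wmat(data.frame(a = c("A", "B", "C", "A"),
                       b = c("B", "C", "D", "C"),
                       w = c(0.5, 0.3, -0.4, 0.2)), labels)
  oracle <- oracle_centrality(w, comm)
  cent <- node_centrality(w)
  b <- bridge_centrality(w, comm)
  expect_equal(cent$strength, oracle$strength, ignore_attr = TRUE)
  expect_equal(cent$closeness, oracle$closeness, ignore_attr = TRUE)
  expect_equal(cent$betweenness, oracle$betweenness, ignore_attr = TRUE)
  expect_equal(cent$expected_influence_1, oracle$expected_influence_1,
               ignore_attr = TRUE)
  expect_equal(b$bridge_strength, oracle$bridge_strength, ignore_attr = TRUE)
  expect_equal(b$bridge_closeness, oracle$bridge_closeness, ignore_attr = TRUE)
  expect_equal(b$bridge_betweenness, oracle$bridge_betweenness,
               ignore_attr = TRUE)
  expect_equal(b$bridge_expected_influence_1,
               oracle$bridge_expected_influence_1, ignore_attr = TRUE)
})

test_that("centrality invariants: single community, scaling, relabeling", {
  set.seed(51)
  labels <- paste0("V", 1:5)
  w <- matrix(0, 5, 5, dimnames = list(labels, labels))
  w[upper.tri(w)] <- sample(c(0, 0.2, -0.3, 0.5), 10, replace = TRUE)
  w <- w + t(w)
  # all nodes in one community: every bridge strength is zero
  one <- setNames(rep("all", 5), labels)
  expect_equal(bridge_centrality(w, one)$bridge_strength, rep(0, 5))
  # scaling weights by c > 0 scales strength/EI1 by c, keeps betweenness
  cent <- node_centrality(w)
  cent3 <- node_centrality(3 * w)
  expect_equal(cent3$strength, 3 * cent$strength)
  expect_equal(cent3$expected_influence_1, 3 * cent$expected_influence_1)
  expect_equal(cent3$betweenness, cent$betweenness)
  # permutation equivariance under node relabeling
  perm <- c(3, 1, 4, 5, 2)
  wp <- w[perm, perm]
  cp <- node_centrality(wp)
  expect_equal(cp$strength, cent$strength[perm], ignore_attr = TRUE)
  expect_equal(cp$betweenness, cent$betweenness[perm], ignore_attr = TRUE)
})

test_that("community assignment must cover the node set", {
  w <- wmat(data.frame(a = "A", b = "B", w = 0.5), c("A", "B"))
  expect_error(bridge_centrality(w, c(A = "c1")), "without community")
  expect_error(instrument_communities(c("HMU", "XYZ")), "XYZ")
  expect_equal(unname(instrument_communities(c("POS", "Anx"))),
               c("RESE", "K10"))
})
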