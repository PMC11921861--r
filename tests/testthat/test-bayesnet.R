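empty_arcs <- data.frame(from = character(0), to = character(0))

test_that("Gaussian BIC matches the closed form and is decomposable", {
  set.seed(71)
  d <- cbind(A = rnorm(500), B = rnorm(500), C = rnorm(500))
  n <- nrow(d)
  # empty graph: sum of univariate closed forms
  s2 <- apply(d, 2, function(col) mean((col - mean(col))^2))
  closed <- sum(-n / 2 * (log(2 * pi * s2) + 1) - log(n))
  expect_equal(bic_g_score(d, empty_arcs), closed, tolerance = 1e-10)
  # adding an arc leaves the other nodes' terms unchanged
  with_arc <- bic_g_score(d, data.frame(from = "A", to = "B"))
  S <- musenet:::mle_cov(d)
  delta_b <- musenet:::node_bic(S, n, "B", "A") - musenet:::node_bic(S, n, "B", character(0))
  expect_equal(with_arc - closed, delta_b, tolerance = 1e-10)
  # score equivalence on two nodes
  expect_equal(bic_g_score(d, data.frame(from = "A", to = "B")),
               bic_g_score(d, data.frame(from = "B", to = "A")),
               tolerance = 1e-10)
  expect_error(bic_g_score(d, data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cyclic")
})

test_that("Markov-equivalent three-node structures score equally", {
  set.seed(72)
  A <- rnorm(1000); B <- 0.7 * A + rnorm(1000); C <- 0.7 * B + rnorm(1000)
  d <- cbind(A = A, B = B, C = C)
  chains <- list(data.frame(from = c("A", "B"), to = c("B", "C")),
                 data.frame(from = c("C", "B"), to = c("B", "A")),
                 data.frame(from = c("B", "B"), to = c("A", "C")))
  scores <- vapply(chains, function(a) bic_g_score(d, a), numeric(1))
  expect_equal(scores[2], scores[1], tolerance = 1e-8)
  expect_equal(scores[3], scores[1], tolerance = 1e-8)
})

test_that("hill climbing finds the exhaustive-enumeration optimum", {
  set.seed(73)
  d2 <- cbind(X = rnorm(2000), Y = rnorm(2000))
  hc2 <- hill_climb(d2, restarts = 5, perturbations = 10, seed = 1)
  expect_equal(nrow(hc2$arcs), 0)  # independent noise -> empty graph
  best2 <- max(vapply(enumerate_dags(c("X", "Y")),
                      function(a) bic_g_score(d2, a), numeric(1)))
  expect_equal(hc2$score, best2, tolerance = 1e-10)
  # strong 3-node chain: score-equal to the best of all 25 DAGs
  set.seed(74)
  A <- rnorm(2000); B <- 0.8 * A + rnorm(2000); C <- 0.8 * B + rnorm(2000)
  d3 <- cbind(A = A, B = B, C = C)
  all_dags <- enumerate_dags(c("A", "B", "C"))
  expect_length(all_dags, 25)
  best3 <- max(vapply(all_dags, function(a) bic_g_score(d3, a), numeric(1)))
  hc3 <- hill_climb(d3, restarts = 10, perturbations = 20, seed = 2)
  expect_equal(hc3$score, best3, tolerance = 1e-10)
  # seeded determinism
  hc3b <- hill_climb(d3, restarts = 10, perturbations = 20, seed = 2)
  expect_identical(hc3$arcs, hc3b$arcs)
  # returned score never falls below the empty graph
  expect_gte(hc3$score, bic_g_score(d3, empty_arcs))
  # result is acyclic
  expect_false(is.null(musenet:::topological_order(hc3$nodes, hc3$arcs)))
})

test_that("arc strengths and directions are replicate frequencies", {
  labels <- c("U", "V", "W")
  mk <- function(from, to) data.frame(from = from, to = to)
  dags <- c(replicate(6, mk("U", "V"), simplify = FALSE),
            replicate(3, mk("V", "U"), simplify = FALSE),
            list(empty_arcs))
  conf <- arc_frequencies(dags, labels)
  uv <- conf[conf$node_a == "U" & conf$node_b == "V", ]
  expect_equal(uv$strength, 0.9)
  expect_equal(uv$dir_ab, 2 / 3)
  expect_equal(uv$dir_ba, 1 / 3)
  expect_equal(conf$strength[conf$node_b == "W"], c(0, 0))
})

test_that("bootstrapped arcs on independent noise stay weak", {
  set.seed(75)
  d <- matrix(rnorm(1000 * 3), 1000, 3, dimnames = list(NULL, c("A", "B", "C")))
  conf <- bootstrap_arcs(d, R = 200, seed = 3)
  expect_true(all(conf$strength < 0.3))
  conf2 <- bootstrap_arcs(d, R = 200, seed = 3)
  expect_identical(as.data.frame(conf), as.data.frame(conf2))
})

test_that("averaged network applies thresholds and resolves cycles", {
  labels <- c("A", "B", "C")
  inject <- function(df) {
    structure(df, class = c("arc_confidence", "data.frame"),
              labels = labels, replicates = 100)
  }
  conf <- inject(data.frame(node_a = c("A", "A", "B"),
                            node_b = c("B", "C", "C"),
                            strength = c(0.80, 0.90, 0.84),
                            dir_ab = c(1, 1, 0.5),
                            dir_ba = c(0, 0, 0.5)))
  avg <- averaged_network(conf)
  expect_equal(nrow(avg$arcs), 1)  # 0.80 below threshold, 0.5/0.5 ambiguous
  expect_equal(avg$arcs$from, "A")
  expect_equal(avg$arcs$to, "C")
  expect_equal(nrow(avg$ambiguous), 0)  # B~C already excluded by strength
  # a retained 50/50 pair is logged as ambiguous
  conf2 <- inject(data.frame(node_a = "A", node_b = "B", strength = 0.9,
                             dir_ab = 0.5, dir_ba = 0.5))
  avg2 <- averaged_network(conf2)
  expect_equal(nrow(avg2$arcs), 0)
  expect_equal(nrow(avg2$ambiguous), 1)
  # three-cycle: the weakest arc is dropped until acyclic
  conf3 <- inject(data.frame(node_a = c("A", "B", "A"),
                             node_b = c("B", "C", "C"),
                             strength = c(0.95, 0.90, 0.86),
                             dir_ab = c(1, 1, 0),
                             dir_ba = c(0, 0, 1)))
  avg3 <- averaged_network(conf3)   # arcs A->B, B->C, C->A
  expect_equal(nrow(avg3$arcs), 2)
  expect_equal(avg3$removed$from, "C")
  expect_equal(avg3$removed$to, "A")
  expect_false(is.null(musenet:::topological_order(labels, avg3$arcs)))
  # arcs come out sorted by descending strength
  expect_equal(avg3$arcs$strength, sort(avg3$arcs$strength, decreasing = TRUE))
})

test_that("child regressions match lm semantics and the contract", {
  x <- c(1, 2, 3, 4, 5, 6)
  d <- data.frame(P = x, Ch = 2 * x)
  avg <- data.frame(from = "P", to = "Ch")
  reg <- suppressWarnings(fit_child_regressions(d, avg))  # perfect fit
  expect_length(reg, 1)  # parentless node P yields no regression
  m <- reg$Ch
  expect_equal(m$coefficients$beta, 2)
  expect_equal(m$r_squared, 1)
  expect_equal(m$rse, 0, tolerance = 1e-12)
  # collinear parents are a rank-deficiency error naming the child
  d2 <- data.frame(P1 = x, P2 = x, Ch = 2 * x + rnorm(6))
  expect_error(fit_child_regressions(d2, data.frame(from = c("P1", "P2"),
                                                    to = c("Ch", "Ch"))),
               "Ch")
})

test_that("child regressions agree with the normal-equations oracle", {
  d <- data.frame(P1 = c(1.2, 0.4, -0.8, 2.1, -1.5, 0.3),
                  P2 = c(0.5, -1.1, 0.9, 0.2, -0.4, 1.8),
                  Ch = c(2.0, -0.7, 0.3, 2.9, -2.2, 1.4))
  reg <- fit_child_regressions(d, data.frame(from = c("P1", "P2"),
                                             to = c("Ch", "Ch")))$Ch
  oracle <- normal_equations_ols(d$Ch, as.matrix(d[, c("P1", "P2")]))
  expect_equal(reg$intercept, oracle$beta[1], tolerance = 1e-10)
  expect_equal(reg$coefficients$beta, unname(oracle$beta[2:3]),
               tolerance = 1e-10)
  expect_equal(reg$coefficients$se, unname(oracle$se[2:3]), tolerance = 1e-10)
  expect_equal(reg$r_squared, oracle$r_squared, tolerance = 1e-10)
  expect_equal(reg$rse, oracle$rse, tolerance = 1e-10)
})
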