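test_that("dimension generator hits target moments and respects the truth", {
  # identity precision -> mutually uncorrelated columns
  labels <- variant_nodes("healthy")
  id_truth <- default_precision_truth(
    "healthy", partial_cors = data.frame(from = character(0),
                                         to = character(0),
                                         rho = numeric(0)))
  g <- generator_config(n = 50000, seed = 5, mode = "dimension", truth = id_truth)
  sim <- generate_dimension_scores(g)
  cc <- cor(sim$data)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)
  # column means within 1% of the calibration targets at the study n
  g2 <- generator_config(n = 16588, seed = 6, mode = "dimension")
  sim2 <- generate_dimension_scores(g2)
  tab <- table1_targets()
  targets <- setNames(tab$mean, tab$dimension)[colnames(sim2$data)]
  expect_true(all(abs(colMeans(sim2$data) - targets) / targets < 0.01))
  sds <- setNames(tab$sd, tab$dimension)[colnames(sim2$data)]
  expect_true(all(abs(apply(sim2$data, 2, sd) - sds) / sds < 0.05))
})

test_that("generators are bit-identical under a fixed seed", {
  g <- generator_config(n = 2, seed = 99, mode = "dimension")
  expect_identical(generate_dimension_scores(g)$data,
                   generate_dimension_scores(g)$data)
  gi <- generator_config(n = 50, seed = 99, mode = "item")
  expect_identical(generate_item_responses(gi)$data,
                   generate_item_responses(gi)$data)
  gs <- generator_config(n = 20, seed = 99, mode = "sem")
  expect_identical(sample_from_sem(gs)$data, sample_from_sem(gs)$data)
})

test_that("SEM sampling follows the structural equations", {
  labels <- variant_nodes("healthy")
  # zero noise: child is exactly the linear map of its parent
  tr <- default_dag_truth("healthy",
                          arcs = data.frame(from = "POS", to = "DES", coef = 2))
  tr$noise_sd["DES"] <- 0
  g <- generator_config(n = 100, seed = 7, mode = "sem", truth = tr)
  sim <- sample_from_sem(g)
  expect_equal(sim$data[, "DES"], 2 * sim$data[, "POS"])
  # empty arc set: columns mutually independent
  tr0 <- default_dag_truth("healthy",
                           arcs = data.frame(from = character(0),
                                             to = character(0),
                                             coef = numeric(0)))
  g0 <- generator_config(n = 20000, seed = 8, mode = "sem", truth = tr0)
  cc <- cor(sample_from_sem(g0)$data)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.03)
  # chain A -> B -> C: partial correlation of A, C given B vanishes
  trc <- default_dag_truth("healthy",
                           arcs = data.frame(from = c("POS", "DES"),
                                             to = c("DES", "ANG"),
                                             coef = c(0.8, 0.8)))
  gc <- generator_config(n = 20000, seed = 9, mode = "sem", truth = trc)
  d <- sample_from_sem(gc)$data
  ra <- resid(lm(d[, "POS"] ~ d[, "DES"]))
  rc <- resid(lm(d[, "ANG"] ~ d[, "DES"]))
  expect_lt(abs(cor(ra, rc)), 0.02)
  # cyclic arc sets are rejected
  expect_error(default_dag_truth("healthy",
                                 arcs = data.frame(from = c("POS", "DES"),
                                                   to = c("DES", "POS"),
                                                   coef = c(1, 1))),
               "cyclic")
})

test_that("SEM-implied covariance matches the sample covariance", {
  g <- generator_config(n = 50000, seed = 10, mode = "sem")
  sim <- sample_from_sem(g)
  tr <- sim$truth
  p <- length(tr$labels)
  # implied covariance: Sigma = (I - B)^-T D (I - B)^-1 with B[i, j] = coef i->j
  B <- matrix(0, p, p, dimnames = list(tr$labels, tr$labels))
  for (i in seq_len(nrow(tr$arcs))) B[tr$arcs$from[i], tr$arcs$to[i]] <- tr$arcs$coef[i]
  iv <- solve(diag(p) - B)
  implied <- t(iv) %*% diag(tr$noise_sd^2) %*% iv
  expect_lt(max(abs(implied - cov(sim$data))), 0.06)
})

test_that("item generator calibrates scale means and reliability", {
  g <- generator_config(n = 5000, seed = 12, mode = "item",
                        alpha_target = c(k10 = 0.99, tas20 = 0.99,
                                         rese = 0.99, hums = 0.99))
  gi <- generate_item_responses(g)
  expect_true(all(gi$data %in% 1:5))
  anx_items <- gi$data[, gi$item_map$k10[1:4]]
  expect_gt(cronbach_alpha(anx_items), 0.95)
  # near-zero loadings -> near-zero alpha
  g0 <- generator_config(n = 5000, seed = 13, mode = "item",
                         alpha_target = c(k10 = 1e-4, tas20 = 1e-4,
                                          rese = 1e-4, hums = 1e-4))
  gi0 <- generate_item_responses(g0)
  expect_lt(abs(cronbach_alpha(gi0$data[, gi0$item_map$k10[1:4]])), 0.05)
  expect_error(generator_config(alpha_target = c(k10 = 1.2)), "alpha_target")
})
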