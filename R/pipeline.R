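## End-to-end orchestration of the two analysis workflows (healthy /
## unhealthy music use) from a CSV of dimension scores or item responses --
## or from the synthetic generator -- to a report bundle on disk.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default.  Exactly one of `input`
#' (a CSV path) or `generator` (a [generator_config()]) feeds the pipeline.
#'
#' @param variant `"healthy"` or `"unhealthy"`; selects the music-use node
#'   (HMU xor UHMU) and the 9-node analysis set.
#' @param input path to a CSV with a header: either the 10 dimension-score
#'   columns (matched case-insensitively against HMU, UHMU, POS, DES, ANG,
#'   DIF, DDF, EOT, Anx, Dep) or raw item columns plus an `item_map`.
#' @param generator a [generator_config()] used when `input` is NULL.
#' @param item_map instrument -> item columns, for CSVs of raw items (see
#'   [score_scales()]).
#' @param npn apply the nonparanormal transform before the GGM (default TRUE).
#' @param gamma,n_lambdas,lambda_min_ratio see [glasso_path()] /
#'   [select_by_ebic()].
#' @param communities node -> community map for bridge centrality; default
#'   [instrument_communities()].
#' @param edge_boot_R,casedrop_R,casedrop_grid stability settings.
#' @param bn_R,bn_restarts,bn_perturbations,hc_restarts,hc_perturbations
#'   Bayesian-network settings: bootstrap replicates and per-replicate
#'   hill-climb effort, plus the single optimal-network search effort.
#' @param strength_threshold,direction_threshold averaged-network thresholds.
#' @param seeds named list of integer seeds for the stochastic stages
#'   (`edge_boot`, `casedrop`, `bn_boot`, `hc`).
#' @param run_stability,run_bn stage switches (both TRUE by default).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(variant = c("healthy", "unhealthy"),
                            input = NULL, generator = NULL, item_map = NULL,
                            npn = TRUE, gamma = 0.5, n_lambdas = 100,
                            lambda_min_ratio = 0.01, communities = NULL,
                            edge_boot_R = 1000, casedrop_R = 1000,
                            casedrop_grid = seq(0.05, 0.75, by = 0.10),
                            bn_R = 1000, bn_restarts = 1,
                            bn_perturbations = 0,
                            hc_restarts = 50, hc_perturbations = 100,
                            strength_threshold = 0.85,
                            direction_threshold = 0.5,
                            seeds = list(), run_stability = TRUE,
                            run_bn = TRUE) {
  variant <- match.arg(variant)
  if (is.null(input) && is.null(generator))
    generator <- generator_config(variant = variant)
  seeds <- modifyList(list(edge_boot = 101L, casedrop = 102L, bn_boot = 103L,
                           hc = 104L), seeds)
  structure(list(variant = variant, input = input, generator = generator,
                 item_map = item_map, npn = npn, gamma = gamma,
                 n_lambdas = n_lambdas, lambda_min_ratio = lambda_min_ratio,
                 communities = communities, edge_boot_R = edge_boot_R,
                 casedrop_R = casedrop_R, casedrop_grid = casedrop_grid,
                 bn_R = bn_R, bn_restarts = bn_restarts,
                 bn_perturbations = bn_perturbations,
                 hc_restarts = hc_restarts,
                 hc_perturbations = hc_perturbations,
                 strength_threshold = strength_threshold,
                 direction_threshold = direction_threshold,
                 seeds = seeds, run_stability = run_stability,
                 run_bn = run_bn),
            class = "pipeline_config")
}

## Resolve input data to the 9 dimension columns of the variant.
## Accepts dimension-score CSVs (case-insensitive abbreviation match),
## raw-item CSVs (scored first via item_map) or the synthetic generator.
resolve_input <- function(config) {
  nodes <- variant_nodes(config$variant)
  if (!is.null(config$input)) {
    raw <- read.csv(config$input, check.names = FALSE)
    if (!is.null(config$item_map)) {
      raw <- score_scales(raw, config$item_map, na_action = "listwise")
    }
    hit <- match(tolower(nodes), tolower(names(raw)))
    if (anyNA(hit))
      stop(sprintf("input is missing dimension column(s): %s",
                   paste(nodes[is.na(hit)], collapse = ", ")), call. = FALSE)
    x <- as.matrix(raw[, hit, drop = FALSE])
    colnames(x) <- nodes
    storage.mode(x) <- "double"
    if (anyNA(x)) x <- x[stats::complete.cases(x), , drop = FALSE]
    return(x)
  }
  gen <- config$generator
  out <- switch(gen$mode,
                dimension = generate_dimension_scores(gen)$data,
                sem = sample_from_sem(gen)$data,
                item = {
                  g <- generate_item_responses(gen)
                  as.matrix(score_generated_items(g))
                })
  out[, nodes, drop = FALSE]
}

#' Score generated item responses back to dimension scores
#'
#' Helper for item-mode generator output: applies the positional item maps
#' used by [generate_item_responses()] (anxiety items first within K10, no
#' reverse keying, facet blocks in DIF/DDF/EOT order).
#'
#' @param gen result of [generate_item_responses()].
#' @return data frame of the ten dimension scores.
#' @export
score_generated_items <- function(gen) {
  x <- as.data.frame(gen$data)
  k10 <- score_k10(x[, gen$item_map$k10], anxiety_items = 1:4,
                   depression_items = 5:10)
  tas <- score_tas20(x[, gen$item_map$tas20], reverse_items = integer(0),
                     facets = list(DIF = 1:7, DDF = 8:12, EOT = 13:20))
  rese <- score_rese(x[, gen$item_map$rese])
  hums <- score_hums(x[, gen$item_map$hums])
  data.frame(Anx = k10$anxiety, Dep = k10$depression,
             DIF = tas$dif, DDF = tas$ddf, EOT = tas$eot,
             POS = rese$pos, DES = rese$des, ANG = rese$ang,
             HMU = hums$hmu, UHMU = hums$uhmu)
}

#' Run the full dual-network pipeline
#'
#' Executes, for the configured variant: input resolution (CSV, scored items
#' or synthetic generation), descriptive summary, nonparanormal transform,
#' graphical-lasso path with EBIC selection, node and bridge centrality,
#' bootstrap stability (edge-weight intervals, case-drop CS coefficients),
#' hill-climbing Bayesian network with bootstrap arc averaging and per-child
#' linear models.  All randomness is governed by the seeds in the config, so
#' a fixed config reproduces the bundle exactly.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `descriptives`,
#'   `network`, `centrality`, `bridge`, `edge_boot`, `casedrop`, `bn_conf`,
#'   `bn_avg`, `bn_regressions`, `manifest`, `data`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- resolve_input(config)
  nodes <- variant_nodes(config$variant)
  descriptives <- data.frame(
    dimension = colnames(x), n = nrow(x),
    mean = round(colMeans(x), 2),
    sd = round(apply(x, 2, sd), 2), row.names = NULL)
  estimator <- function(d)
    estimate_network(d, npn = config$npn, gamma = config$gamma,
                     n_lambdas = config$n_lambdas,
                     lambda_min_ratio = config$lambda_min_ratio)
  network <- estimator(x)
  centrality <- node_centrality(network)
  communities <- if (is.null(config$communities))
    instrument_communities(nodes) else config$communities
  bridge <- bridge_centrality(network, communities)
  edge_boot <- NULL
  casedrop <- NULL
  if (config$run_stability) {
    edge_boot <- edge_bootstrap(x, estimator, R = config$edge_boot_R,
                                seed = config$seeds$edge_boot)
    casedrop <- casedrop_cs(x, estimator, grid = config$casedrop_grid,
                            R = config$casedrop_R,
                            seed = config$seeds$casedrop)
  }
  bn_conf <- NULL; bn_avg <- NULL; bn_reg <- NULL; bn_hc <- NULL
  if (config$run_bn) {
    xs <- zscore(x)
    bn_hc <- hill_climb(xs, restarts = config$hc_restarts,
                        perturbations = config$hc_perturbations,
                        seed = config$seeds$hc)
    bn_conf <- bootstrap_arcs(xs, R = config$bn_R,
                              restarts = config$bn_restarts,
                              perturbations = config$bn_perturbations,
                              seed = config$seeds$bn_boot)
    bn_avg <- averaged_network(bn_conf,
                               strength_threshold = config$strength_threshold,
                               direction_threshold = config$direction_threshold)
    bn_reg <- fit_child_regressions(as.data.frame(xs), bn_avg)
  }
  manifest <- list(
    package = "musenet",
    version = as.character(utils::packageVersion("musenet")),
    variant = config$variant,
    n = nrow(x), nodes = nodes,
    source = if (is.null(config$input)) "generator" else config$input,
    generator_seed = if (is.null(config$generator)) NULL else config$generator$seed,
    parameters = list(npn = config$npn, gamma = config$gamma,
                      n_lambdas = config$n_lambdas,
                      lambda_min_ratio = config$lambda_min_ratio,
                      edge_boot_R = config$edge_boot_R,
                      casedrop_R = config$casedrop_R,
                      casedrop_grid = config$casedrop_grid,
                      bn_R = config$bn_R, bn_restarts = config$bn_restarts,
                      bn_perturbations = config$bn_perturbations,
                      hc_restarts = config$hc_restarts,
                      hc_perturbations = config$hc_perturbations,
                      strength_threshold = config$strength_threshold,
                      direction_threshold = config$direction_threshold),
    seeds = config$seeds,
    stage_failures = list(
      edge_boot = if (is.null(edge_boot)) NULL else attr(edge_boot, "failures"),
      bn_boot = if (is.null(bn_conf)) NULL else attr(bn_conf, "failures")))
  structure(list(descriptives = descriptives, network = network,
                 centrality = centrality, bridge = bridge,
                 edge_boot = edge_boot, casedrop = casedrop,
                 bn_hc = bn_hc, bn_conf = bn_conf, bn_avg = bn_avg,
                 bn_regressions = bn_reg, manifest = manifest, data = x),
            class = "pipeline_result")
}

## Edge list (node_a, node_b, weight) of the nonzero upper-triangle edges.
network_edge_list <- function(network) {
  w <- network_weights(network)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  keep <- w[ut] != 0
  data.frame(node_a = rownames(w)[ut[keep, 1]],
             node_b = rownames(w)[ut[keep, 2]],
             weight = w[ut][keep])
}

#' Read an edge list back into a weights matrix
#'
#' @param path TSV with columns `node_a`, `node_b`, `weight`.
#' @param labels node labels fixing matrix order (defaults to the labels in
#'   file order of appearance).
#' @return symmetric weights matrix with zero diagonal.
#' @export
read_edge_list <- function(path, labels = NULL) {
  e <- read.csv(path, sep = "\t")
  if (is.null(labels)) labels <- unique(c(e$node_a, e$node_b))
  w <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_len(nrow(e))) {
    w[e$node_a[i], e$node_b[i]] <- e$weight[i]
    w[e$node_b[i], e$node_a[i]] <- e$weight[i]
  }
  w
}

## DOT serialization of an averaged network.
dag_to_dot <- function(avg, name = "averaged_network") {
  lines <- c(sprintf("digraph %s {", name),
             sprintf("  \"%s\";", avg$labels))
  if (nrow(avg$arcs))
    lines <- c(lines,
               sprintf("  \"%s\" -> \"%s\" [label=\"%.3f\"];",
                       avg$arcs$from, avg$arcs$to, avg$arcs$strength))
  c(lines, "}")
}

#' Write a pipeline report bundle
#'
#' Serializes a [run_pipeline()] result to `dir`: descriptives, edge list
#' (TSV), centrality and bridge tables, edge-weight bootstrap intervals, CS
#' coefficients, Bayesian-network arc table, child-node regression tables, a
#' DOT export of the averaged DAG and a JSON manifest of every seed and
#' parameter.  Running the same config twice yields byte-identical bundles.
#'
#' @param results a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(results, dir) {
  stopifnot(inherits(results, "pipeline_result"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory %s", dir), call. = FALSE)
  paths <- character(0)
  wcsv <- function(df, file) {
    path <- file.path(dir, file)
    write.csv(df, path, row.names = FALSE)
    paths <<- c(paths, path)
  }
  wcsv(results$descriptives, "descriptives.csv")
  edges <- network_edge_list(results$network)
  path <- file.path(dir, "edge_list.tsv")
  utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, path)
  wcsv(results$centrality, "centrality.csv")
  wcsv(results$bridge, "bridge_centrality.csv")
  if (!is.null(results$edge_boot))
    wcsv(as.data.frame(results$edge_boot), "edge_bootstrap.csv")
  if (!is.null(results$casedrop))
    wcsv(data.frame(index = names(results$casedrop$cs),
                    cs = unname(results$casedrop$cs),
                    cor_threshold = results$casedrop$cor_threshold),
         "cs_coefficients.csv")
  if (!is.null(results$bn_conf))
    wcsv(as.data.frame(results$bn_conf), "bn_arc_confidence.csv")
  if (!is.null(results$bn_avg)) {
    wcsv(results$bn_avg$arcs, "bn_averaged_arcs.csv")
    dot <- file.path(dir, "averaged_dag.dot")
    writeLines(dag_to_dot(results$bn_avg), dot)
    paths <- c(paths, dot)
  }
  if (!is.null(results$bn_regressions)) {
    coefs <- do.call(rbind, lapply(results$bn_regressions, function(m)
      data.frame(child = m$child, parent = m$coefficients$parent,
                 beta = m$coefficients$beta, se = m$coefficients$se,
                 p = m$coefficients$p)))
    models <- do.call(rbind, lapply(results$bn_regressions, function(m)
      data.frame(child = m$child, intercept = m$intercept,
                 r_squared = m$r_squared, rse = m$rse, f_p = m$f_p,
                 n = m$n)))
    rownames(coefs) <- rownames(models) <- NULL
    wcsv(coefs, "bn_regression_coefficients.csv")
    wcsv(models, "bn_regression_models.csv")
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(results$manifest, manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths <- c(paths, manifest)
  invisible(paths)
}
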