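## Scoring of the four instruments (K10, TAS-20, RESE, HUMS).
## All items are 5-point Likert responses coded 1..5.

#' Validate a block of Likert item responses
#'
#' Checks that a response block has the expected number of item columns and
#' that every entry is an integer in 1..5.  Missing responses are handled per
#' `na_action`: `"error"` (default) rejects them, `"listwise"` drops incomplete
#' respondents, `"impute.mean"` replaces each missing entry by the rounded
#' mean of its item.
#'
#' @param x matrix or data frame of item responses (respondents x items).
#' @param n_items expected number of columns (NULL to skip the check).
#' @param scale scale name used in error messages.
#' @param na_action one of `"error"`, `"listwise"`, `"impute.mean"`.
#' @return list with `values` (numeric matrix) and `kept` (row indices of `x`
#'   retained after listwise deletion).
#' @export
validate_likert <- function(x, n_items = NULL, scale = "scale",
                            na_action = c("error", "listwise", "impute.mean")) {
  na_action <- match.arg(na_action)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(n_items) && ncol(x) != n_items)
    stop(sprintf("%s requires %d item columns, got %d", scale, n_items, ncol(x)),
         call. = FALSE)
  kept <- seq_len(nrow(x))
  if (anyNA(x)) {
    if (na_action == "error") {
      bad <- which(is.na(x), arr.ind = TRUE)[1, ]
      stop(sprintf("missing %s response for respondent %d, item %d",
                   scale, bad[1], bad[2]), call. = FALSE)
    } else if (na_action == "listwise") {
      kept <- which(stats::complete.cases(x))
      x <- x[kept, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(x))) {
        miss <- is.na(x[, j])
        if (any(miss)) x[miss, j] <- round(mean(x[!miss, j]))
      }
    }
  }
  bad <- which(!(x %in% 1:5) | x != round(x))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(x)) + 1
    j <- ((bad[1] - 1) %/% nrow(x)) + 1
    stop(sprintf("invalid %s response %s for respondent %d, item %d (must be an integer in 1..5)",
                 scale, format(x[i, j]), kept[i], j), call. = FALSE)
  }
  list(values = x, kept = kept)
}

#' Score the 10-item Kessler Psychological Distress Scale (K10)
#'
#' Sums the anxiety and depression subscales and classifies the total into
#' the four published risk levels: 10-19 (level 1, low risk), 20-24 (level 2),
#' 25-29 (level 3), 30-50 (level 4, high risk).  The item-to-subscale split is
#' not part of the scale's published scoring key in every translation; the
#' default (anxiety: items 2,3,5,6; depression: items 1,4,7,8,9,10) is the
#' widely used assignment and is configurable.
#'
#' @param x respondents x 10 matrix/data frame of K10 items.
#' @param anxiety_items,depression_items column indices of the two subscales.
#' @param na_action see [validate_likert()].
#' @return data frame with columns `anxiety` (4-20), `depression` (6-30),
#'   `k10_total` (10-50) and `k10_level` (1-4).
#' @export
score_k10 <- function(x, anxiety_items = c(2, 3, 5, 6),
                      depression_items = c(1, 4, 7, 8, 9, 10),
                      na_action = "error") {
  v <- validate_likert(x, 10, "K10", na_action)$values
  anx <- rowSums(v[, anxiety_items, drop = FALSE])
  dep <- rowSums(v[, depression_items, drop = FALSE])
  total <- anx + dep
  level <- k10_level(total)
  data.frame(anxiety = anx, depression = dep, k10_total = total,
             k10_level = level)
}

#' K10 risk-level classification
#'
#' @param total K10 total scores (10-50).
#' @return integer level 1-4 per the cutoffs 10-19 / 20-24 / 25-29 / 30-50.
#' @export
k10_level <- function(total) {
  stopifnot(all(total >= 10 & total <= 50))
  findInterval(total, c(10, 20, 25, 30))
}

#' Score the 20-item Toronto Alexithymia Scale (TAS-20)
#'
#' Reverse-keys the configured items (default: the standard set 4, 5, 10, 18,
#' 19), sums the three facets -- difficulty identifying feelings (DIF, 7
#' items), difficulty describing feelings (DDF, 5 items), externally oriented
#' thinking (EOT, 8 items) -- and classifies the total with the published
#' cutoffs: <= 51 no alexithymia, 52-60 possible, >= 61 present.  The dominant
#' facet is the facet with the highest per-item mean; exact ties are reported
#' as all tied facets joined by "/" in the fixed order DIF, DDF, EOT.
#'
#' @param x respondents x 20 matrix/data frame of TAS-20 items.
#' @param reverse_items items recoded as 6 - response before summation; use
#'   `integer(0)` to disable reverse keying.
#' @param facets named list of item indices for DIF, DDF and EOT.
#' @param na_action see [validate_likert()].
#' @return data frame with `dif` (7-35), `ddf` (5-25), `eot` (8-40),
#'   `tas_total` (20-100), `tas_category` and `dominant_facet`.
#' @export
score_tas20 <- function(x, reverse_items = c(4, 5, 10, 18, 19),
                        facets = list(DIF = c(1, 3, 6, 7, 9, 13, 14),
                                      DDF = c(2, 4, 11, 12, 17),
                                      EOT = c(5, 8, 10, 15, 16, 18, 19, 20)),
                        na_action = "error") {
  v <- validate_likert(x, 20, "TAS-20", na_action)$values
  stopifnot(identical(sort(names(facets)), sort(c("DIF", "DDF", "EOT"))))
  if (length(reverse_items))
    v[, reverse_items] <- 6 - v[, reverse_items]
  sums <- sapply(c("DIF", "DDF", "EOT"),
                 function(f) rowSums(v[, facets[[f]], drop = FALSE]))
  if (!is.matrix(sums)) sums <- matrix(sums, nrow = 1,
                                       dimnames = list(NULL, c("DIF", "DDF", "EOT")))
  total <- rowSums(sums)
  means <- sweep(sums, 2, lengths(facets[c("DIF", "DDF", "EOT")]), "/")
  dominant <- apply(means, 1, function(m) {
    top <- m >= max(m) - 1e-9
    paste(c("DIF", "DDF", "EOT")[top], collapse = "/")
  })
  data.frame(dif = sums[, "DIF"], ddf = sums[, "DDF"], eot = sums[, "EOT"],
             tas_total = total, tas_category = tas_category(total),
             dominant_facet = dominant)
}

#' TAS-20 alexithymia classification
#'
#' @param total TAS-20 total scores (20-100).
#' @return factor with levels `none` (<= 51), `possible` (52-60),
#'   `present` (>= 61).
#' @export
tas_category <- function(total) {
  stopifnot(all(total >= 20 & total <= 100))
  cut(total, breaks = c(0, 51.5, 60.5, 100.5),
      labels = c("none", "possible", "present"))
}

#' Score the Regulatory Emotional Self-Efficacy (RESE) scale
#'
#' Sums the three four-item dimensions: expressing positive affect (POS),
#' managing despondency-distress (DES) and managing anger-irritation (ANG).
#' Each dimension score ranges 4-20 (four items, responses 1-5).  The
#' positional item assignment is configurable.
#'
#' @param x respondents x 12 matrix/data frame of RESE items.
#' @param pos_items,des_items,ang_items item indices per dimension.
#' @param na_action see [validate_likert()].
#' @return data frame with columns `pos`, `des`, `ang`, each in 4-20.
#' @export
score_rese <- function(x, pos_items = 1:4, des_items = 5:8, ang_items = 9:12,
                       na_action = "error") {
  v <- validate_likert(x, 12, "RESE", na_action)$values
  data.frame(pos = rowSums(v[, pos_items, drop = FALSE]),
             des = rowSums(v[, des_items, drop = FALSE]),
             ang = rowSums(v[, ang_items, drop = FALSE]))
}

#' Score the Healthy-Unhealthy Music Scale (HUMS)
#'
#' Sums healthy music use (HMU, 5 items, range 5-25) and unhealthy music use
#' (UHMU, 8 items, range 8-40).  The default positional assignment puts the
#' healthy items first; pass explicit indices for other layouts.
#'
#' @param x respondents x 13 matrix/data frame of HUMS items.
#' @param hmu_items,uhmu_items item indices of the two subscales.
#' @param na_action see [validate_likert()].
#' @return data frame with columns `hmu` (5-25) and `uhmu` (8-40).
#' @export
score_hums <- function(x, hmu_items = 1:5, uhmu_items = 6:13,
                       na_action = "error") {
  v <- validate_likert(x, 13, "HUMS", na_action)$values
  data.frame(hmu = rowSums(v[, hmu_items, drop = FALSE]),
             uhmu = rowSums(v[, uhmu_items, drop = FALSE]))
}

#' Score all four instruments from one response matrix
#'
#' @param x matrix/data frame holding all item columns.
#' @param item_map named list giving, for each of `k10`, `tas20`, `rese`,
#'   `hums`, the column indices (or names) of that instrument's items in
#'   instrument order.  Instruments absent from the map are skipped.
#' @param na_action see [validate_likert()]; `"listwise"` drops respondents
#'   with any missing item across the mapped instruments.
#' @return data frame of dimension scores named with the standard
#'   abbreviations (Anx, Dep, POS, DES, ANG, DIF, DDF, EOT, HMU, UHMU) plus
#'   the classification columns.
#' @export
score_scales <- function(x, item_map, na_action = "error") {
  x <- as.data.frame(x)
  cols <- unlist(item_map, use.names = FALSE)
  if (na_action == "listwise") {
    x <- x[stats::complete.cases(x[, cols, drop = FALSE]), , drop = FALSE]
    na_action <- "error"
  }
  out <- list()
  if (!is.null(item_map$k10)) {
    s <- score_k10(x[, item_map$k10, drop = FALSE], na_action = na_action)
    out$k10 <- data.frame(Anx = s$anxiety, Dep = s$depression,
                          k10_total = s$k10_total, k10_level = s$k10_level)
  }
  if (!is.null(item_map$tas20)) {
    s <- score_tas20(x[, item_map$tas20, drop = FALSE], na_action = na_action)
    out$tas20 <- data.frame(DIF = s$dif, DDF = s$ddf, EOT = s$eot,
                            tas_total = s$tas_total,
                            tas_category = s$tas_category,
                            dominant_facet = s$dominant_facet)
  }
  if (!is.null(item_map$rese)) {
    s <- score_rese(x[, item_map$rese, drop = FALSE], na_action = na_action)
    out$rese <- data.frame(POS = s$pos, DES = s$des, ANG = s$ang)
  }
  if (!is.null(item_map$hums)) {
    s <- score_hums(x[, item_map$hums, drop = FALSE], na_action = na_action)
    out$hums <- data.frame(HMU = s$hmu, UHMU = s$uhmu)
  }
  do.call(cbind, unname(out))
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2} are
#' the item variances and \eqn{s_T^2} the variance of the total score.
#'
#' @param x respondents x items numeric matrix restricted to one scale.
#' @return alpha in \eqn{(-\infty, 1]}.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  k <- ncol(x)
  if (k < 2) stop("cronbach_alpha needs at least 2 items", call. = FALSE)
  if (nrow(x) < 3) stop("cronbach_alpha needs at least 3 respondents", call. = FALSE)
  vt <- var(rowSums(x))
  if (vt <= 0)
    stop("total-score variance is zero; alpha is undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / vt)
}
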