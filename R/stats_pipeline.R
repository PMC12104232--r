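#' Paired observer-versus-standard comparison
#'
#' Chooses between the paired t-test and the Wilcoxon signed-rank test by a
#' Shapiro-Wilk normality test on the paired differences (alpha configurable,
#' default 0.05); the chosen test is reported so either convention can be
#' audited. Degenerate inputs (all differences zero, or differences too
#' uniform for Shapiro-Wilk) fall through to the distribution-free branch.
#'
#' @param observer_values,standard_values matched numeric vectors (one entry
#'   per patient), length >= 3.
#' @param alpha_normality Shapiro-Wilk significance level steering the test
#'   choice.
#' @return list: `test` (`"paired t"`, `"wilcoxon"`, or `"none"` when all
#'   differences are zero, with `p_value = 1` by convention), `statistic`,
#'   `p_value`, `n`, `no_difference` flag.
#' @export
paired_compare <- function(observer_values, standard_values,
                           alpha_normality = 0.05) {
  if (length(observer_values) != length(standard_values))
    stop("paired samples must have equal length")
  n <- length(observer_values)
  if (n < 3) stop("paired comparison needs n >= 3")
  d <- observer_values - standard_values
  if (all(d == 0))
    return(list(test = "none", statistic = NA_real_, p_value = 1,
                n = n, no_difference = TRUE))
  normal <- FALSE
  if (length(unique(d)) > 1 && n >= 3) {
    sw <- try(shapiro.test(d), silent = TRUE)
    normal <- !inherits(sw, "try-error") && sw$p.value >= alpha_normality
  }
  if (normal) {
    ht <- t.test(observer_values, standard_values, paired = TRUE)
    list(test = "paired t", statistic = unname(ht$statistic),
         p_value = ht$p.value, n = n, no_difference = FALSE)
  } else {
    ht <- suppressWarnings(
      wilcox.test(observer_values, standard_values, paired = TRUE,
                  exact = n < 25))
    list(test = "wilcoxon", statistic = unname(ht$statistic),
         p_value = ht$p.value, n = n, no_difference = FALSE)
  }
}

#' Spearman rank correlation with the field's p-value conventions
#'
#' Rank correlation with average ranks for ties. The p-value comes from the
#' exact permutation distribution for n <= 10 (where feasible) and the
#' t-approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: `r`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("spearman correlation needs n >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("spearman correlation undefined for a constant vector")
  r <- cor(rank(x), rank(y))
  exact <- n <= 10
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  list(r = unname(r), p_value = ht$p.value, n = n,
       method = if (exact) "exact permutation (n <= 10)" else "t approximation")
}

#' Correlation matrix between geometric metrics and dosimetric/prognostic deltas
#'
#' Pools all (patient, observer) pairs per metric into one vector (the
#' default, matching a cohort-times-observers scatter) or stratifies by
#' observer, then computes the Spearman correlation of every x-metric
#' against every y-metric and applies the predictor-selection gate
#' `p < 0.05 and |r| > 0.4`.
#'
#' @param records metric-record data.frame (columns `patient_id`,
#'   `observer_id`, `structure_label`, `metric_name`, `value`).
#' @param x_metrics,y_metrics data.frames or lists of `c(structure_label,
#'   metric_name)` pairs; a character vector `"label:metric"` is also
#'   accepted.
#' @param pooling `"pooled"` (all observer-patient pairs in one vector) or
#'   `"by_observer"` (one correlation per observer, rows repeated per
#'   observer).
#' @return data.frame: `x_name`, `y_name`, (`observer_id` when stratified,)
#'   `n`, `r`, `p`, `selected`. Missing (patient, observer) cells are
#'   dropped pairwise with a warning.
#' @export
correlation_matrix <- function(records, x_metrics, y_metrics,
                               pooling = c("pooled", "by_observer")) {
  pooling <- match.arg(pooling)
  parse_spec <- function(s) {
    if (is.character(s) && length(s) == 1) s <- strsplit(s, ":", fixed = TRUE)[[1]]
    list(label = s[[1]], metric = s[[2]],
         name = paste0(s[[2]], "(", s[[1]], ")"))
  }
  if (is.character(x_metrics)) x_metrics <- as.list(x_metrics)
  if (is.character(y_metrics)) y_metrics <- as.list(y_metrics)
  xs <- lapply(x_metrics, parse_spec)
  ys <- lapply(y_metrics, parse_spec)
  pull <- function(spec) {
    sub <- records[records$structure_label == spec$label &
                     records$metric_name == spec$metric, ]
    sub[, c("patient_id", "observer_id", "value")]
  }
  out <- list()
  for (sx in xs) for (sy in ys) {
    a <- pull(sx); b <- pull(sy)
    m <- merge(a, b, by = c("patient_id", "observer_id"),
               suffixes = c("_x", "_y"))
    if (nrow(m) < max(nrow(a), nrow(b)))
      warning(sprintf("%d (patient, observer) cells missing for %s vs %s; excluded pairwise",
                      max(nrow(a), nrow(b)) - nrow(m), sx$name, sy$name))
    groups <- if (pooling == "pooled") list(all = m) else split(m, m$observer_id)
    for (gname in names(groups)) {
      g <- groups[[gname]]
      sc <- tryCatch(spearman_cor(g$value_x, g$value_y),
                     error = function(e) {
                       warning(sprintf("correlation %s vs %s undefined (%s); reported as NA",
                                       sx$name, sy$name, conditionMessage(e)))
                       list(r = NA_real_, p_value = NA_real_, n = nrow(g))
                     })
      row <- data.frame(x_name = sx$name, y_name = sy$name,
                        n = sc$n, r = sc$r, p = sc$p_value,
                        selected = isTRUE(sc$p_value < 0.05 &&
                                            abs(sc$r) > 0.4),
                        stringsAsFactors = FALSE)
      if (pooling == "by_observer") row$observer_id <- gname
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Select delineation-risk predictors from correlation results
#'
#' The selection rule: a geometric metric is designated a risk predictor of
#' delineation discrepancy when its correlation with the dosimetric or
#' prognostic delta is significant (`p < 0.05`) and strong enough
#' (`|r| > 0.4`). Results are sorted by decreasing `|r|`.
#'
#' @param results data.frame from [correlation_matrix()].
#' @param r_threshold,p_threshold the two gates (defaults 0.4 and 0.05).
#' @return the selected subset (possibly empty), sorted by `|r|` descending.
#' @export
select_predictors <- function(results, r_threshold = 0.4,
                              p_threshold = 0.05) {
  sel <- results[which(results$p < p_threshold & abs(results$r) > r_threshold),
                 , drop = FALSE]
  sel[order(-abs(sel$r)), , drop = FALSE]
}
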