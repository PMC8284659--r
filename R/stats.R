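## Nonparametric statistics layer: parallel-control normalisation,
## tie-corrected Kruskal-Wallis with post hoc Dunn's test, Mann-Whitney
## (exact enumeration for small untied samples), Spearman correlation
## (exact for n <= 9 without ties), repeat-level summaries and bootstrap
## confidence intervals.

#' Validate a per-neuron condition table
#'
#' A condition table has one row per (neuron, metric): columns
#' `neuron_id`, `genotype`, `biological_repeat`, `metric`, `value`.
#'
#' @param table a data.frame.
#' @return The table, invisibly; errors describe any violation.
#' @export
validate_condition_table <- function(table) {
  need <- c("neuron_id", "genotype", "biological_repeat", "metric", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("condition table lacks columns: ", paste(miss, collapse = ", "))
  key <- paste(table$neuron_id, table$metric)
  if (anyDuplicated(key))
    stop("condition table: duplicate (neuron_id, metric) rows")
  if (!is.numeric(table$value) || any(!is.finite(table$value)))
    stop("condition table: values must be finite numerics")
  invisible(table)
}

#' Normalise a metric to parallel controls
#'
#' Divides each value of `metric` by the centre (median or mean) of the
#' control genotype's values from the same biological repeat, so the
#' control centre is 1 in every repeat.
#'
#' @param table a condition table (see [validate_condition_table()]).
#' @param metric metric name to normalise.
#' @param control genotype name of the parallel control.
#' @param center `"median"` or `"mean"`.
#' @return The table with the metric's values normalised; per-repeat
#'   control centres attached as attribute `"control_centers"`.
#' @export
normalise_to_control <- function(table, metric, control = "control",
                                 center = c("median", "mean")) {
  validate_condition_table(table)
  center <- match.arg(center)
  cfun <- if (center == "median") median else mean
  sel <- table$metric == metric
  reps <- unique(table$biological_repeat[sel])
  centers <- setNames(numeric(length(reps)), as.character(reps))
  for (r in reps) {
    ctl <- sel & table$biological_repeat == r & table$genotype == control
    if (!any(ctl))
      stop("normalise_to_control: repeat '", r,
           "' has no parallel control rows for metric '", metric, "'")
    centers[as.character(r)] <- cfun(table$value[ctl])
    here <- sel & table$biological_repeat == r
    table$value[here] <- table$value[here] / centers[as.character(r)]
  }
  attr(table, "control_centers") <- centers
  table
}

## ---- rank tests -----------------------------------------------------------

tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Kruskal-Wallis test with post hoc Dunn's test
#'
#' Tie-corrected Kruskal-Wallis H with chi-squared p-value, plus Dunn's
#' pairwise z tests on the shared ranks (raw two-sided p and
#' Holm-adjusted p). When every value is identical across groups the
#' result is flagged degenerate with H = 0, p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   non-empty, total n >= 3).
#' @return List with `H`, `df`, `p`, `pairwise` (data.frame `group1`,
#'   `group2`, `z`, `p_raw`, `p_adj`), `degenerate`.
#' @export
kruskal_wallis_dunn <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 1L))
    stop("kruskal_wallis_dunn: need >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (N < 3L) stop("kruskal_wallis_dunn: total n must be >= 3")
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  if (length(unique(x)) == 1L) {
    pw <- pairwise_grid(names2(groups))
    pw$z <- 0; pw$p_raw <- 1; pw$p_adj <- 1
    return(list(H = 0, df = length(groups) - 1L, p = 1, pairwise = pw,
                degenerate = TRUE))
  }
  rbar <- tapply(r, g, mean)
  n_i <- as.numeric(lengths(groups))
  H <- (12 / (N * (N + 1))) * sum(n_i * (rbar - (N + 1) / 2)^2)
  C <- 1 - tie_term(x) / (N^3 - N)
  H <- H / C
  p <- pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  ## Dunn's z on the same ranks, tie-corrected
  s2 <- N * (N + 1) / 12 - tie_term(x) / (12 * (N - 1))
  pw <- pairwise_grid(names2(groups))
  pw$z <- NA_real_; pw$p_raw <- NA_real_
  for (k in seq_len(nrow(pw))) {
    i <- pw$i[k]; j <- pw$j[k]
    se <- sqrt(s2 * (1 / n_i[i] + 1 / n_i[j]))
    pw$z[k] <- (rbar[i] - rbar[j]) / se
    pw$p_raw[k] <- 2 * pnorm(-abs(pw$z[k]))
  }
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = "holm")
  pw$i <- NULL; pw$j <- NULL
  list(H = H, df = length(groups) - 1L, p = p, pairwise = pw,
       degenerate = FALSE)
}

names2 <- function(groups) {
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  nm
}

pairwise_grid <- function(nm) {
  k <- length(nm)
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  data.frame(group1 = nm[idx[, 1]], group2 = nm[idx[, 2]],
             i = idx[, 1], j = idx[, 2], stringsAsFactors = FALSE)
}

#' Mann-Whitney rank-sum test (two-sided)
#'
#' Exact enumeration p (via the null distribution of the U statistic)
#' when `min(n1, n2) <= 8` and there are no ties; tie-corrected normal
#' approximation otherwise.
#'
#' @param a,b numeric samples.
#' @return List with `U`, `p`, `exact` (logical).
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b))
    stop("mann_whitney: both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  ties <- anyDuplicated(c(a, b)) > 0L
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2    # wilcoxon W for sample a
  if (!ties && min(n1, n2) <= 8L) {
    p <- if (U > n1 * n2 / 2)
      2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      2 * pwilcox(U, n1, n2)
    return(list(U = U, p = min(1, p), exact = TRUE))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term(c(a, b)) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

#' Spearman rank correlation
#'
#' Tie-corrected rho (Pearson correlation of ranks). Exact permutation
#' p-value for n <= 9 without ties; t-approximation otherwise. Constant
#' input yields `r = NA` with `degenerate = TRUE`.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return List with `r`, `p`, `exact`, `degenerate`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_cor: x and y must be paired")
  n <- length(x)
  if (n < 4L) stop("spearman_cor: need n >= 4")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(r = NA_real_, p = NA_real_, exact = FALSE,
                degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (!ties && n <= 9L) {
    S_obs <- sum((rx - ry)^2)
    S_all <- spearman_S_distribution(n)
    p1 <- if (S_obs > (n^3 - n) / 6)         # below-centre rho: upper S tail
      mean(S_all >= S_obs)
    else
      mean(S_all <= S_obs)
    return(list(r = r, p = min(1, 2 * p1), exact = TRUE,
                degenerate = FALSE))
  }
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (!is.finite(t_stat)) 0 else 2 * pt(-abs(t_stat), df = n - 2)
  list(r = r, p = min(1, p), exact = FALSE, degenerate = FALSE)
}

## All values of S = sum((1:n - perm)^2) over permutations (cached).
spearman_S_env <- new.env(parent = emptyenv())
spearman_S_distribution <- function(n) {
  key <- as.character(n)
  if (!is.null(spearman_S_env[[key]])) return(spearman_S_env[[key]])
  P <- permutations_matrix(n)
  S <- rowSums((P - matrix(seq_len(n), nrow(P), n, byrow = TRUE))^2)
  spearman_S_env[[key]] <- S
  S
}

permutations_matrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- permutations_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, p + (p >= k))))
}

## ---- summaries ------------------------------------------------------------

#' Percentile bootstrap confidence interval
#'
#' @param x numeric sample.
#' @param stat summary function (default median).
#' @param B number of resamples.
#' @param conf confidence level.
#' @param seed RNG seed for the resampling.
#' @return List with `estimate`, `lower`, `upper`, `B`, `seed`.
#' @export
boot_ci <- function(x, stat = median, B = 10000L, conf = 0.95, seed = 1L) {
  n <- length(x)
  est <- stat(x)
  with_seed(seed, {
    m <- matrix(sample(x, n * B, replace = TRUE), nrow = B)
    bs <- if (identical(stat, stats::median)) {
      ## vectorised row medians: sort within rows in one order() call
      ms <- matrix(m[order(row(m), m)], B, n, byrow = TRUE)
      if (n %% 2L == 1L) ms[, (n + 1L) %/% 2L]
      else (ms[, n %/% 2L] + ms[, n %/% 2L + 1L]) / 2
    } else if (identical(stat, base::mean)) {
      rowMeans(m)
    } else apply(m, 1L, stat)
    qs <- quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    list(estimate = est, lower = qs[1], upper = qs[2], B = B, seed = seed)
  })
}

#' Default centre convention per metric
#'
#' Median for comet amounts, lengths, intensities, velocities, lifetimes
#' and axon lengths; mean for MDI and comet counts.
#'
#' @param metric metric name.
#' @return `"median"` or `"mean"`.
#' @export
default_center <- function(metric) {
  if (grepl("mdi|count|swelling", metric, ignore.case = TRUE)) "mean"
  else "median"
}

#' Per-repeat centres and pooled summary with bootstrap CI
#'
#' Summarises one metric "superplot"-style: a centre per biological
#' repeat alongside the pooled per-neuron centre with a percentile
#' bootstrap confidence interval.
#'
#' @param table a condition table.
#' @param metric metric name.
#' @param genotype optional genotype filter.
#' @param center `"median"`, `"mean"`, or `NULL` for [default_center()].
#' @param B,conf,seed bootstrap settings (see [boot_ci()]).
#' @return List with `center`, `repeat_centers` (named vector), `pooled`
#'   (estimate), `ci` (lower/upper), `n`.
#' @export
repeat_summary <- function(table, metric, genotype = NULL, center = NULL,
                           B = 10000L, conf = 0.95, seed = 1L) {
  validate_condition_table(table)
  center <- center %||% default_center(metric)
  cfun <- if (center == "median") median else mean
  sel <- table$metric == metric
  if (!is.null(genotype)) sel <- sel & table$genotype == genotype
  vals <- table$value[sel]
  reps <- table$biological_repeat[sel]
  if (!length(vals)) stop("repeat_summary: no rows for metric '", metric, "'")
  rc <- tapply(vals, reps, cfun)
  rc <- setNames(as.numeric(rc), names(rc))
  ci <- boot_ci(vals, cfun, B = B, conf = conf, seed = seed)
  list(center = center, repeat_centers = rc, pooled = ci$estimate,
       ci = c(lower = ci$lower, upper = ci$upper), n = length(vals))
}
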