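cond_table <- function(values_by_geno, metric = "m", repeats = 1) {
  rows <- list()
  for (g in names(values_by_geno)) {
    vals <- values_by_geno[[g]]
    for (i in seq_along(vals))
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = paste(g, repeats, i, sep = "_"), genotype = g,
        biological_repeat = repeats, metric = metric, value = vals[i])
  }
  do.call(rbind, rows)
}

test_that("control normalisation divides by the per-repeat control centre", {
  t1 <- cond_table(list(control = c(2, 4, 6), mut = c(2, 3)))
  n1 <- normalise_to_control(t1, "m")
  expect_equal(n1$value[n1$genotype == "mut"], c(0.5, 0.75))
  expect_equal(median(n1$value[n1$genotype == "control"]), 1)

  ## per-repeat: identical raw mutant values, control medians 4 vs 8
  t2 <- rbind(cond_table(list(control = c(2, 4, 6), mut = 4), repeats = 1),
              cond_table(list(control = c(6, 8, 10), mut = 4), repeats = 2))
  n2 <- normalise_to_control(t2, "m")
  vals <- n2$value[n2$genotype == "mut"]
  expect_equal(vals[1] / vals[2], 2)

  t3 <- rbind(cond_table(list(control = c(2, 4), mut = 3), repeats = 1),
              cond_table(list(mut = 5), repeats = 2))
  expect_error(normalise_to_control(t3, "m"), "repeat '2'")
})

test_that("condition tables reject duplicate neuron-metric rows", {
  t1 <- cond_table(list(control = c(1, 2)))
  expect_silent(validate_condition_table(t1))
  t1$neuron_id[2] <- t1$neuron_id[1]
  expect_error(validate_condition_table(t1), "duplicate")
})

test_that("Kruskal-Wallis matches the rank-sum formula and flags ties-only", {
  deg <- kruskal_wallis_dunn(list(a = c(3, 3), b = c(3, 3), c = c(3, 3)))
  expect_true(deg$degenerate)
  expect_equal(deg$H, 0)
  expect_equal(deg$p, 1)

  ## exhaustive rank computation for {1,2},{3,4},{5,6}: rank means
  ## 1.5/3.5/5.5 give H = 12/(6*7) * 2*(2^2 + 0 + 2^2) = 32/7
  res <- kruskal_wallis_dunn(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(res$H, 32 / 7)
  expect_false(res$degenerate)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
})

test_that("rank tests agree with reference implementations", {
  set.seed(8)
  for (r in 1:10) {
    g <- lapply(1:3, function(i) round(runif(sample(4:9, 1)) * 8, 1))
    res <- kruskal_wallis_dunn(g)
    ref <- kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
    expect_equal(res$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)

    a <- runif(6); b <- runif(7)
    expect_equal(mann_whitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)

    at <- round(runif(15) * 4); bt <- round(runif(12) * 4)
    expect_equal(mann_whitney(at, bt)$p,
                 wilcox.test(at, bt, exact = FALSE, correct = FALSE)$p.value,
                 tolerance = 1e-12)

    x <- runif(14); y <- runif(14)
    sp <- spearman_cor(x, y)
    ref2 <- cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(sp$r, unname(ref2$estimate), tolerance = 1e-12)
    expect_equal(sp$p, ref2$p.value, tolerance = 1e-12)
  }
})

test_that("the exact Mann-Whitney p matches direct enumeration", {
  ## all C(4,2)=6 rank splits of {1,2} vs {3,4}: only one is as extreme,
  ## doubled for the two-sided test
  combos <- combn(4, 2)
  U_obs <- sum(rank(c(1, 2, 3, 4))[1:2]) - 3
  U_all <- apply(combos, 2, function(ix) sum(ix) - 3)
  p_enum <- 2 * mean(U_all <= U_obs)
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$p, p_enum)
  expect_equal(res$p, 1 / 3)
  expect_true(res$exact)

  expect_equal(mann_whitney(c(5, 6, 7), c(5, 6, 7))$p, 1)
  a <- rnorm(5); b <- rnorm(6)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(b, a)$p)
})

test_that("Spearman handles monotone, exact and degenerate cases", {
  x <- c(1, 2, 5, 7, 11)
  expect_equal(spearman_cor(x, x^2)$r, 1)
  expect_equal(spearman_cor(x, -x^3)$r, -1)
  d <- spearman_cor(rep(3, 5), x)
  expect_true(d$degenerate)
  expect_true(is.na(d$r))

  set.seed(2)
  for (r in 1:5) {
    x <- runif(8); y <- runif(8)
    sp <- spearman_cor(x, y)
    expect_true(sp$exact)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(sp$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("two-group Kruskal-Wallis orders p like Mann-Whitney", {
  set.seed(13)
  p_kw <- p_mw <- numeric(12)
  for (r in 1:12) {
    a <- rnorm(12, 0); b <- rnorm(11, runif(1, 0, 1.5))
    p_kw[r] <- kruskal_wallis_dunn(list(a, b))$p
    p_mw[r] <- mann_whitney(a, b)$p
  }
  expect_equal(order(p_kw), order(p_mw))
})

test_that("bootstrap intervals are percentile-based and seed-stable", {
  ci <- boot_ci(c(5, 5, 5, 5))
  expect_equal(c(ci$lower, ci$upper), c(5, 5))

  x <- rnorm(30, 10)
  a <- boot_ci(x, median, B = 500, seed = 9)
  b <- boot_ci(x, median, B = 500, seed = 9)
  expect_identical(a, b)
  ## fast median path equals the generic path
  g <- boot_ci(x, function(v) median(v), B = 500, seed = 9)
  expect_equal(a[c("estimate", "lower", "upper")],
               g[c("estimate", "lower", "upper")])
  expect_lte(a$lower, a$estimate)
  expect_gte(a$upper, a$estimate)
})

test_that("repeat summaries centre per repeat and pool per neuron", {
  t1 <- cond_table(list(control = c(1, 3, 5)), metric = "comet_amount")
  s1 <- repeat_summary(t1, "comet_amount", B = 200)
  expect_equal(unname(s1$repeat_centers), s1$pooled)
  expect_equal(s1$center, "median")

  expect_equal(default_center("mdi"), "mean")
  expect_equal(default_center("comet_amount"), "median")
  expect_equal(default_center("swelling_count"), "mean")

  t2 <- rbind(cond_table(list(control = c(1, 2, 3)), "mdi", 1),
              cond_table(list(control = c(5, 6, 7)), "mdi", 2))
  s2 <- repeat_summary(t2, "mdi", B = 200)
  expect_equal(unname(s2$repeat_centers), c(2, 6))
  expect_equal(s2$pooled, 4)        # mean convention for MDI
})
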