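test_that("group summary computes n, mean and sample SD", {
  s <- group_summary(c(10, 20, 30))
  expect_identical(s$n, 3L)
  expect_equal(s$mean, 20)
  expect_equal(s$sd, 10)
  expect_equal(group_summary(c(5, 5, 5, 5))$sd, 0)
  expect_error(group_summary(7), "at least 2")
  set.seed(1); v <- runif(9, 0, 100)
  expect_true(group_summary(v)$mean >= min(v) && group_summary(v)$mean <= max(v))
})

test_that("pooled means reproduce the published overall rows", {
  expect_equal(pooled_mean(list(c(5, 32.4), c(6, 53.5), c(4, 45.7))), 44.4)
  expect_equal(pooled_mean(list(c(5, 51.3), c(6, 62.0), c(4, 51.8))), 55.7)
  expect_equal(pooled_mean(list(c(3, 12.5), c(9, 12.5))), 12.5)
})

test_that("exact Mann-Whitney matches the enumeration and wilcox oracle", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_identical(r$method, "exact")

  expect_equal(mann_whitney(5, 5)$p, 1)

  set.seed(20)
  for (rep in 1:12) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    vals <- sample(seq_len(500), n + m)    # tie-free pooled draw
    a <- vals[seq_len(n)]; b <- vals[-seq_len(n)]
    ours <- mann_whitney(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mann_whitney(b, a)$p, ours$p)
  }
})

test_that("exact test holds its nominal size under the permutation null", {
  set.seed(33)
  reps <- 2000
  rej <- vapply(seq_len(reps), function(i) {
    x <- rnorm(10)
    mann_whitney(x[1:5], x[6:10])$p <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("Levene W matches its definition and the car implementation", {
  same <- list(c(1, 2, 3), c(3, 1, 2))
  r <- levene(same)
  expect_equal(r$W, 0); expect_equal(r$p, 1)
  # equal absolute deviations in every group
  r2 <- levene(list(c(0, 2), c(10, 12), c(-5, -3)))
  expect_equal(r2$W, 0)

  g <- list(c(14, 18, 22, 27), c(9, 12, 12, 14, 18), c(22, 28, 30))
  ours <- levene(g)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(seq_along(g), lengths(g))))
  ref <- car::leveneTest(y ~ grp, data = df, center = mean)
  expect_equal(ours$W, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(levene(list(1, c(2, 3))), "at least 2")
})

test_that("correlation recovers exact linear relations and population rho", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_error(correlate(rep(2, 5), x), "variance")
  expect_equal(correlate(x, c(2, 1, 5, 8, 9), method = "spearman")$r,
               cor(x, c(2, 1, 5, 8, 9), method = "spearman"))

  set.seed(41)
  rho <- 0.7; n <- 15
  est <- vapply(1:400, function(i) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    correlate(x, y)$r
  }, numeric(1))
  expect_lt(abs(mean(est) - rho), 0.1)
})

test_that("study reports summarize groups, methods and their agreement", {
  tab <- group_table(
    specimen = rep(sprintf("s%02d", 1:9), 2),
    group = rep(rep(c("uncoated", "PPAAm", "PPEDA"), each = 3), 2),
    method = rep(c("histo", "uCT"), each = 9),
    bic = c(30, 35, 40, 50, 55, 60, 45, 50, 55,
            42, 47, 52, 60, 65, 70, 55, 60, 65))
  rep_ <- study_report(tab)
  expect_identical(nrow(rep_$summary), 6L)   # 3 groups x 2 methods
  expect_equal(sort(names(rep_$pooled)), c("histo", "uCT"))
  expect_equal(unname(rep_$pooled["histo"]),
               round(mean(tab$bic[tab$method == "histo"]), 1))
  expect_identical(nrow(rep_$pairwise), 6L)  # 3 pairs x 2 methods
  expect_false(is.null(rep_$correlation))
  expect_gt(rep_$correlation$r, 0.9)         # construction is nearly affine

  const <- group_table(rep(sprintf("c%d", 1:6), 2),
                       rep(rep(c("a", "b"), each = 3), 2),
                       rep(c("histo", "uCT"), each = 6), rep(50, 12))
  expect_warning(rc <- study_report(const), "correlation omitted")
  expect_true(all(rc$pairwise$p == 1))
  expect_true(all(rc$summary$sd == 0))

  expect_error(group_table(c("s1", "s1"), c("a", "a"), c("histo", "histo"),
                           c(10, 20)), "unique")
})

test_that("pooled mean from group summaries equals the raw-data mean", {
  set.seed(5)
  gs <- list(runif(4, 0, 100), runif(6, 0, 100), runif(5, 0, 100))
  pm <- pooled_mean(lapply(gs, function(g) c(length(g), mean(g))))
  expect_equal(pm, round(mean(unlist(gs)), 1))
})
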