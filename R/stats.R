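#' Group summary: n, mean, SD
#'
#' @param values Numeric vector (n >= 2 for the SD).
#' @return List with `n`, `mean`, `sd` (sample SD, n-1 denominator).
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values for a standard deviation")
  list(n = length(values), mean = mean(values), sd = stats::sd(values))
}

#' Sample-size-weighted pooled mean
#'
#' Combines per-group means into the overall mean,
#' `sum(n_i * mean_i) / sum(n_i)`, reported to one decimal as printed in
#' study tables.
#'
#' @param groups List of `c(n, mean)` pairs (or a 2-column matrix).
#' @return Pooled mean, rounded to 1 decimal.
#' @export
pooled_mean <- function(groups) {
  m <- if (is.matrix(groups)) groups else do.call(rbind, groups)
  stopifnot(ncol(m) == 2, all(m[, 1] >= 1))
  round(sum(m[, 1] * m[, 2]) / sum(m[, 1]), 1)
}

# U statistic of group a against group b from the ranks of the pooled data
# (average ranks under ties): U_a = R_a - n_a(n_a+1)/2.
u_stat <- function(rank_sum_a, n_a) rank_sum_a - n_a * (n_a + 1) / 2

#' Mann-Whitney U test for two independent groups
#'
#' Reports `U` (the smaller of the two group statistics) and a two-sided p
#' value. For combined sample sizes up to `exact_limit` the p value is exact:
#' all assignments of the pooled observations to the two groups are
#' enumerated and p is the probability, under that permutation null, of a
#' `min(U1, U2)` at least as extreme as observed. Larger samples fall back
#' to the normal approximation with tie correction. Exact enumeration is the
#' appropriate choice at the group sizes (4-6) typical of implant studies.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_limit Largest combined n for which the exact test is used.
#' @return List with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b, exact_limit = 20L) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1, length(b) >= 1)
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U_a <- u_stat(sum(rk[seq_len(n_a)]), n_a)
  U_b <- n_a * n_b - U_a
  U_obs <- min(U_a, U_b)

  if (n_a + n_b <= exact_limit) {
    combs <- utils::combn(n_a + n_b, n_a)
    u_min <- apply(combs, 2, function(idx) {
      u <- u_stat(sum(rk[idx]), n_a)
      min(u, n_a * n_b - u)
    })
    p <- mean(u_min <= U_obs + 1e-9)
    return(list(U = U_obs, p = p, method = "exact"))
  }
  # normal approximation with tie correction
  N <- n_a + n_b
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n_a * n_b / 12 * (N + 1 - tie_term)
  mu <- n_a * n_b / 2
  if (sigma2 <= 0) return(list(U = U_obs, p = 1, method = "normal"))
  z <- (abs(U_obs - mu) - 0.5) / sqrt(sigma2)   # continuity correction
  list(U = U_obs, p = min(1, 2 * stats::pnorm(-z)), method = "normal")
}

#' Levene's test for homogeneity of variance
#'
#' Classic Levene W with group means as centres: a one-way ANOVA F statistic
#' on the absolute deviations `|x_ij - mean_i|`, with p from the F
#' distribution on (k-1, N-k) degrees of freedom.
#'
#' @param groups List of numeric vectors, at least 2 groups of n >= 2.
#' @return List with `W`, `df`, and `p`.
#' @export
levene <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 observations")
  k <- length(groups)
  z <- lapply(groups, function(g) abs(g - mean(g)))
  N <- sum(lengths(z))
  zbar <- mean(unlist(z))
  zbar_i <- vapply(z, mean, numeric(1))
  n_i <- lengths(z)
  ss_between <- sum(n_i * (zbar_i - zbar)^2)
  ss_within <- sum(vapply(z, function(zi) sum((zi - mean(zi))^2), numeric(1)))
  if (ss_within == 0) {
    W <- if (ss_between == 0) 0 else Inf
  } else {
    W <- (N - k) / (k - 1) * ss_between / ss_within
  }
  p <- if (is.infinite(W)) 0 else if (W == 0) 1 else
    stats::pf(W, k - 1, N - k, lower.tail = FALSE)
  list(W = W, df = c(k - 1, N - k), p = p)
}

#' Correlation between paired measurements
#'
#' Pearson product-moment correlation by default (Spearman rank correlation
#' via `method`), with the two-sided p value from the t transform, as used
#' to compare 3D and 2D contact estimates on the same specimens.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p`, and `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Build a specimen-level BIC table
#'
#' @param specimen Specimen identifiers.
#' @param group Group labels (e.g. surface treatments).
#' @param method Measurement method per row (e.g. `"histo"`, `"uCT"`).
#' @param bic Contact percentage in \[0, 100\].
#' @return A `group_table` data frame.
#' @export
group_table <- function(specimen, group, method, bic) {
  stopifnot(all(bic >= 0 & bic <= 100))
  df <- data.frame(specimen = as.character(specimen),
                   group = as.character(group),
                   method = as.character(method), bic = as.numeric(bic),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("specimen", "method")]))
    stop("(specimen, method) pairs must be unique")
  class(df) <- c("group_table", "data.frame")
  df
}

#' Full comparison report for a BIC study table
#'
#' Per group and method: n, mean, SD. Per method: pooled (overall) mean, all
#' pairwise Mann-Whitney comparisons between groups, Levene's homogeneity
#' test across groups. Between methods: Pearson correlation over specimens
#' measured by both. No multiple-testing correction is applied by default
#' (`p_adjust = "holm"` turns it on).
#'
#' @param table A [group_table()].
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A `study_report` list with elements `summary` (data frame),
#'   `pooled`, `pairwise`, `levene`, and `correlation` (NULL with a warning
#'   if complete pairs are missing).
#' @export
study_report <- function(table, p_adjust = "none") {
  stopifnot(inherits(table, "group_table") || is.data.frame(table))
  methods <- sort(unique(table$method))
  groups <- sort(unique(table$group))

  summary_df <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(groups, function(g) {
      v <- table$bic[table$method == m & table$group == g]
      if (length(v) == 0) return(NULL)
      data.frame(method = m, group = g, n = length(v), mean = mean(v),
                 sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
    }))
  }))

  pooled <- vapply(methods, function(m) {
    sm <- summary_df[summary_df$method == m, ]
    pooled_mean(cbind(sm$n, sm$mean))
  }, numeric(1))
  names(pooled) <- methods

  pairs <- if (length(groups) >= 2) utils::combn(groups, 2) else
    matrix(character(0), 2, 0)
  pairwise <- do.call(rbind, lapply(methods, function(m) {
    if (ncol(pairs) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(c_i) {
      g1 <- pairs[1, c_i]; g2 <- pairs[2, c_i]
      v1 <- table$bic[table$method == m & table$group == g1]
      v2 <- table$bic[table$method == m & table$group == g2]
      if (length(v1) == 0 || length(v2) == 0) return(NULL)
      mw <- mann_whitney(v1, v2)
      data.frame(method = m, group1 = g1, group2 = g2, U = mw$U, p = mw$p)
    }))
  }))
  if (!is.null(pairwise) && p_adjust != "none")
    pairwise$p_adjusted <- stats::p.adjust(pairwise$p, method = p_adjust)

  lev <- lapply(methods, function(m) {
    gs <- lapply(groups, function(g) table$bic[table$method == m &
                                                 table$group == g])
    gs <- gs[lengths(gs) >= 2]
    if (length(gs) >= 2) levene(gs) else NULL
  })
  names(lev) <- methods

  correlation <- NULL
  if (length(methods) == 2) {
    wide <- merge(table[table$method == methods[1], c("specimen", "bic")],
                  table[table$method == methods[2], c("specimen", "bic")],
                  by = "specimen")
    if (nrow(wide) >= 3) {
      correlation <- tryCatch({
        ct <- correlate(wide$bic.x, wide$bic.y)
        ct$methods <- methods
        ct
      }, error = function(e) {
        warning("correlation omitted: ", conditionMessage(e))
        NULL
      })
    } else warning("too few complete specimen pairs; correlation omitted")
  }

  structure(list(summary = summary_df, pooled = pooled, pairwise = pairwise,
                 levene = lev, correlation = correlation),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("BIC study report\n")
  s <- x$summary
  s$`mean±SD` <- sprintf("%.1f ± %.1f", s$mean, s$sd)
  print(s[c("method", "group", "n", "mean±SD")], row.names = FALSE)
  cat("overall (pooled):",
      paste(sprintf("%s %.1f", names(x$pooled), x$pooled), collapse = ", "),
      "\n")
  if (!is.null(x$correlation))
    cat(sprintf("method correlation: r = %.2f (p = %.4g, n = %d)\n",
                x$correlation$r, x$correlation$p, x$correlation$n))
  invisible(x)
}

#' Write a study report to CSV and JSON
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$pairwise))
    utils::write.csv(report$pairwise, file.path(dir, "pairwise_tests.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, pooled = as.list(report$pooled),
         pairwise = report$pairwise, levene = report$levene,
         correlation = report$correlation),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
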