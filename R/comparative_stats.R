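# The three inferential analyses: introduced-vs-native contrast (Welch),
# genus size vs sharing incidence (Spearman), and among-family heterogeneity
# of sharing (Pearson chi-square).

.test_result <- function(method, statistic, df, p_value, groups = NULL,
                         warning = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, groups = groups, warning = warning),
            class = "audit_test")
}

#' @export
print.audit_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  if (!is.null(x$groups)) print(x$groups, row.names = FALSE)
  if (!is.null(x$warning)) cat("note:", x$warning, "\n")
  invisible(x)
}

#' Welch (unequal-variance) two-sample t test
#'
#' Statistic \eqn{t = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch–Satterthwaite degrees of freedom and a two-sided p value.  With
#' `balance = TRUE` both groups are first subsampled to the smaller n (the
#' "random sampling of cases" device for very unequal group sizes); off by
#' default, seeded by the caller's RNG state.
#'
#' @param x,y numeric vectors, each of length at least 2 with nonzero
#'   variance.
#' @param balance subsample both groups to `min(length(x), length(y))`.
#' @return an `audit_test` with per-group n and mean.
#' @export
welch_t_test <- function(x, y, balance = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values")
  }
  if (balance) {
    m <- min(length(x), length(y))
    if (length(x) > m) x <- sample(x, m)
    if (length(y) > m) y <- sample(y, m)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0) stop("group 'x' has zero variance")
  if (vy == 0) stop("group 'y' has zero variance")
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  .test_result("Welch two-sample t-test", t, df, p,
               groups = data.frame(group = c("x", "y"), n = c(nx, ny),
                                   mean = c(mean(x), mean(y))))
}

#' Spearman rank correlation (mid-rank ties, t approximation)
#'
#' @param x,y numeric vectors of equal length, at least 3 pairs.
#' @return an `audit_test`; `statistic` is rho.  A constant vector gives an
#'   `NA` result with a warning (undefined, reported).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman correlation undefined")
    return(.test_result("Spearman rank correlation", NA_real_,
                        NA_real_, NA_real_,
                        warning = "constant input vector"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  .test_result("Spearman rank correlation", rho, n - 2, p,
               groups = data.frame(group = "pairs", n = n,
                                   mean = NA_real_))
}

#' Pearson chi-square homogeneity test on an r x 2 count table
#'
#' Tests homogeneity of the column proportions (e.g. sharing vs diagnostic)
#' across rows (e.g. families), with `r - 1` degrees of freedom.
#'
#' @param table numeric matrix of counts, at least 2 rows, 2 columns.
#' @return an `audit_test`; a warning is attached when more than 20% of
#'   expected counts fall below 5.
#' @export
chi_square_homogeneity <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) != 2) {
    stop("need an r x 2 count table with r >= 2")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column total")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  x2 <- sum((table - expected)^2 / expected)
  df <- nrow(table) - 1
  p <- stats::pchisq(x2, df, lower.tail = FALSE)
  warn <- NULL
  if (mean(expected < 5) > 0.2) {
    warn <- "more than 20% of expected counts are below 5"
  }
  .test_result("Pearson chi-square homogeneity", x2, df, p, warning = warn)
}

#' Write a stats report as JSON
#' @param tests named list of `audit_test` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(tests, path) {
  payload <- lapply(tests, function(t) {
    list(method = t$method, statistic = t$statistic, df = t$df,
         p_value = t$p_value, groups = t$groups, warning = t$warning)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
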