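#' @include AllClasses.R
NULL

#' Summarize per-cell values as mean +/- SEM
#'
#' Summary convention for condition tables: mean and standard error of the
#' mean over the supplied per-cell values, with the animal (`n`) and cell
#' (`c`) counts recorded from the unit identifiers. Cells are the
#' statistical unit; animal ids are carried so a per-animal re-aggregation
#' remains possible.
#'
#' @param values numeric vector of per-cell values (length >= 2).
#' @param animals optional vector of animal ids, one per value.
#' @param cells optional vector of cell ids, one per value (defaults to one
#'   cell per value).
#' @return data.frame with `mean`, `sem`, `n_animals`, `n_cells`.
#' @examples
#' summarizeGroup(c(1, 2, 3))  # sem = sd/sqrt(3) = 1/sqrt(3)
#' @export
summarizeGroup <- function(values, animals = NULL, cells = NULL) {
  if (length(values) < 2L)
    stop("need at least 2 values to summarize")
  nC <- if (is.null(cells)) length(values) else length(unique(cells))
  nA <- if (is.null(animals)) NA_integer_ else length(unique(animals))
  data.frame(mean = mean(values),
             sem = stats::sd(values) / sqrt(length(values)),
             n_animals = nA, n_cells = nC)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The omnibus K2 test combining the transformed sample skewness
#' (D'Agostino's Z of \eqn{\sqrt{b_1}}) and kurtosis (Anscombe-Glynn's Z of
#' \eqn{b_2}); `K2 = Z1^2 + Z2^2` is chi-squared with 2 df under
#' normality. Requires at least 8 observations.
#'
#' @param x numeric vector, `length(x) >= 8`.
#' @return A list with `statistic` (K2), `p.value`, `z.skew`, `z.kurt`.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), The American
#'   Statistician 44, 316-321.
#' @examples
#' dagostinoPearsonTest(rnorm(50))$p.value
#' @export
dagostinoPearsonTest <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("the omnibus normality test needs at least 8 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  ## skewness: D'Agostino (1970) transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  ## kurtosis: Anscombe & Glynn (1983) transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z.skew = z1, z.kurt = z2)
}

#' Star coding of p values
#'
#' The conventional significance coding: `p < 0.0001` four stars,
#' `p < 0.001` three, `p < 0.01` two, `p < 0.05` one (strict
#' inequalities; `p = 0.05` is `"ns"`).
#'
#' @param p p value(s) in `[0, 1]`.
#' @return character vector over `{"ns", "*", "**", "***", "****"}`.
#' @examples
#' starCode(c(0.03, 9e-5, 0.05))
#' @export
starCode <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  vapply(p, function(pi) {
    if (pi < 0.0001) "****"
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Compare condition groups with the study's testing conventions
#'
#' Two groups are compared with a two-sided Student's t-test (paired or
#' unpaired); more than two with a one-way ANOVA. Each group is first
#' screened with the D'Agostino-Pearson omnibus normality test (skipped,
#' with a flag, for groups smaller than 8); the parametric test is run
#' regardless, and a `non_normal` flag is raised when any screen fails at
#' 0.05 -- the parametric result is what is reported either way, matching
#' the field's practice. A paired contrast with all-zero differences has an
#' undefined t statistic and is reported as `p = 1` with the
#' `zero_variance` flag rather than `NaN`. No multiple-testing correction
#' is applied.
#'
#' @param ... two or more numeric vectors, or a single list of them.
#' @param paired for two groups, treat them as paired (equal lengths
#'   required).
#' @return A list of class `"TestResult"`: `test`, `statistic`, `df`, `p`,
#'   `stars`, `normality_p` (per group, `NA` when skipped), `non_normal`,
#'   `normality_skipped`, `zero_variance`.
#' @examples
#' compareGroups(rnorm(10), rnorm(10) + 2)
#' @export
compareGroups <- function(..., paired = FALSE) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1L]])) groups <- groups[[1L]]
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 3L)) stop("each group needs at least 3 values")
  if (paired && length(groups) == 2L &&
      length(groups[[1L]]) != length(groups[[2L]]))
    stop("paired comparison requires equal group lengths")

  normP <- vapply(groups, function(g) {
    if (length(g) >= 8L) dagostinoPearsonTest(g)$p.value else NA_real_
  }, numeric(1))
  skipped <- any(is.na(normP))
  nonNormal <- any(normP < 0.05, na.rm = TRUE)

  zeroVar <- FALSE
  if (length(groups) == 2L) {
    degenerate <- if (paired)
      stats::sd(groups[[1L]] - groups[[2L]]) == 0
    else
      stats::sd(unlist(groups)) == 0
    if (degenerate) {
      zeroVar <- TRUE
      test <- if (paired) "paired t-test" else "unpaired t-test"
      statistic <- 0
      df <- length(groups[[1L]]) - 1L
      p <- 1
    } else {
      tt <- stats::t.test(groups[[1L]], groups[[2L]], paired = paired,
                          var.equal = TRUE)
      test <- if (paired) "paired t-test" else "unpaired t-test"
      statistic <- unname(tt$statistic)
      df <- unname(tt$parameter)
      p <- tt$p.value
    }
  } else {
    vals <- unlist(groups, use.names = FALSE)
    grp <- factor(rep.int(seq_along(groups), lengths(groups)))
    if (stats::sd(vals) == 0) {
      zeroVar <- TRUE
      test <- "one-way ANOVA"
      statistic <- 0
      df <- c(length(groups) - 1L, length(vals) - length(groups))
      p <- 1
    } else {
      fit <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
      test <- "one-way ANOVA"
      statistic <- unname(fit$statistic)
      df <- unname(fit$parameter)
      p <- fit$p.value
    }
  }
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 stars = starCode(p), normality_p = normP,
                 non_normal = nonNormal, normality_skipped = skipped,
                 zero_variance = zeroVar),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g [%s]%s%s\n", x$test,
              x$statistic, x$p, x$stars,
              if (x$non_normal) " (normality screen failed)" else "",
              if (x$zero_variance) " (zero-variance contrast)" else ""))
  invisible(x)
}
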