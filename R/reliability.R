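# Agreement statistics for paired measurement sources (human vs human,
# human vs AI): mean difference with 95% CI and SD, RMSE, Pearson r with
# two-sided p, and the single-measure absolute-agreement intraclass
# correlation ICC(A,1) from the two-way ANOVA decomposition, with the
# F-distribution confidence interval.

#' Paired agreement statistics
#'
#' For paired measurements `a` and `b`, computes the differences
#' `d = a - b` and reports mean error, its 95% t-interval, the sample SD
#' (n - 1 denominator) and `RMSE = sqrt(mean(d^2))`. Pairs with a missing
#' value on either side are dropped.
#'
#' @param a,b numeric vectors of equal length.
#' @return list with `n`, `mean_error`, `ci` (length 2), `sd`, `rmse`.
#' @export
#' @examples
#' agreement_stats(c(1, 2, 3), c(2, 2, 2))$rmse
agreement_stats <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  me <- mean(d)
  s <- stats::sd(d)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  list(n = n, mean_error = me, ci = c(me - half, me + half), sd = s,
       rmse = sqrt(mean(d^2)))
}

#' Single-measure absolute-agreement ICC with 95% CI
#'
#' Two-way model, absolute agreement, single measure:
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' from the two-way ANOVA mean squares (subjects x k sources), with the
#' F-distribution confidence interval of McGraw & Wong. Rows with missing
#' values are dropped.
#'
#' @param ratings n x k numeric matrix (k = 2 for a pair of raters).
#' @param conf confidence level.
#' @return list with `icc`, `ci`, `n`, `k` and the mean squares.
#' @export
icc_a1 <- function(ratings, conf = 0.95) {
  m <- as.matrix(ratings)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 sources", call. = FALSE)
  grand <- mean(m)
  if (sum((m - grand)^2) < 1e-24) {
    stop("undefined ICC: zero total variance", call. = FALSE)
  }
  row_m <- rowMeans(m); col_m <- colMeans(m)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  alpha <- 1 - conf
  # McGraw & Wong (1996) interval for ICC(A,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  if (!is.finite(a) || !is.finite(b)) {
    ci <- c(icc, icc)  # degenerate perfect-agreement case
  } else {
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci = ci, n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; p from `t = r sqrt((n-2)/(1-r^2))` with
#' n - 2 degrees of freedom (the null of zero correlation).
#'
#' @param a,b numeric vectors (n >= 3, both non-constant).
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Construct a rater table
#'
#' Wide per-source measurement table: one row per subject, one column per
#' alignment parameter. A long table (columns `subject`, `parameter`,
#' `value`) is reshaped automatically.
#'
#' @param df data.frame, wide (subject + parameter columns) or long.
#' @return data.frame of class `rater_table` with a `subject` column and
#'   one numeric column per known parameter.
#' @export
rater_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (all(c("subject", "parameter", "value") %in% names(df))) {
    wide <- stats::reshape(df[, c("subject", "parameter", "value")],
                           idvar = "subject", timevar = "parameter",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    df <- wide
  }
  if (!"subject" %in% names(df)) stop("rater table needs a 'subject' column",
                                      call. = FALSE)
  keep <- c("subject", intersect(ANGLE_NAMES, names(df)))
  if (length(keep) < 2) stop("rater table contains no known parameters",
                             call. = FALSE)
  out <- df[, keep, drop = FALSE]
  class(out) <- c("rater_table", "data.frame")
  out
}

#' Pairwise reliability report for two measurement sources
#'
#' One row per alignment parameter, pairwise-complete over the overlapping
#' subjects (so n can differ between parameters): ICC(A,1) with 95% CI,
#' mean error with 95% CI, SD, RMSE, Pearson r with p.
#'
#' @param source_a,source_b [rater_table()]s (or data.frames coercible to
#'   one).
#' @return data.frame of class `reliability_report`.
#' @export
reliability_report <- function(source_a, source_b) {
  a <- rater_table(source_a); b <- rater_table(source_b)
  merged <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
  if (nrow(merged) < 2) stop("fewer than 2 overlapping subjects", call. = FALSE)
  params <- intersect(intersect(ANGLE_NAMES, names(a)), names(b))
  rows <- lapply(params, function(p) {
    va <- merged[[paste0(p, "_a")]]
    vb <- merged[[paste0(p, "_b")]]
    ok <- stats::complete.cases(va, vb)
    if (sum(ok) < 2) {
      return(data.frame(parameter = p, n = sum(ok), icc = NA, icc_lo = NA,
                        icc_hi = NA, mean_error = NA, me_lo = NA, me_hi = NA,
                        sd = NA, rmse = NA, pearson_r = NA, p_value = NA))
    }
    ag <- agreement_stats(va[ok], vb[ok])
    ic <- tryCatch(icc_a1(cbind(va[ok], vb[ok])),
                   error = function(e) list(icc = NA, ci = c(NA, NA)))
    pr <- tryCatch(pearson(va[ok], vb[ok]),
                   error = function(e) list(r = NA, p = NA))
    data.frame(parameter = p, n = ag$n,
               icc = ic$icc, icc_lo = ic$ci[1], icc_hi = ic$ci[2],
               mean_error = ag$mean_error, me_lo = ag$ci[1], me_hi = ag$ci[2],
               sd = ag$sd, rmse = ag$rmse,
               pearson_r = pr$r, p_value = pr$p)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_report", "data.frame")
  out
}

## ---- printed-cell reconstruction ------------------------------------------

#' Reconstruct printed RMSE cells from mean error and SD
#'
#' For differences d over n pairs, `RMSE^2 = mean(d)^2 + SD^2 (n-1)/n`
#' exactly. Applied to the printed mean-error and SD cells of a published
#' reliability table, the identity reproduces the printed RMSE up to the
#' table's rounding.
#'
#' @param mean_error,sd printed cells.
#' @param n paired count of the row.
#' @return reconstructed RMSE.
#' @export
rmse_from_me_sd <- function(mean_error, sd, n) {
  sqrt(mean_error^2 + sd^2 * (n - 1) / n)
}

#' Check the RMSE identity on the bundled printed table cells
#'
#' Loads the packaged reference rows (printed mean error, SD, RMSE and
#' per-parameter n of published inter-rater tables) and compares the
#' reconstructed RMSE against the printed value at the printed precision.
#'
#' @return data.frame with columns `comparison`, `parameter`, `n`,
#'   `reconstructed`, `printed`, `deviation`, `ok`.
#' @export
check_printed_rmse_identity <- function() {
  path <- system.file("extdata", "printed_reliability_cells.csv",
                      package = "limbalign")
  cells <- utils::read.csv(path, colClasses = c(rmse_printed = "character"))
  rec <- rmse_from_me_sd(cells$mean_error, cells$sd, cells$n)
  digits <- nchar(sub("^[^.]*\\.?", "", cells$rmse_printed))
  printed <- as.numeric(cells$rmse_printed)
  data.frame(
    comparison = cells$comparison, parameter = cells$parameter, n = cells$n,
    reconstructed = rec, printed = printed,
    deviation = rec - printed,
    ok = round(rec, digits) == printed
  )
}
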