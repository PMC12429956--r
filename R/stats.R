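#' Chi-square test of independence on a contingency table
#'
#' Pearson's chi-square for an r x c table of counts: statistic
#' \eqn{\sum (O - E)^2 / E} with expected counts from the row/column
#' margins, `(r-1)(c-1)` degrees of freedom and an upper-tail p-value. The
#' Yates continuity correction is off by default and only meaningful for
#' 2 x 2 tables.
#'
#' @param table matrix of non-negative counts, at least 2 x 2.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `dof`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("contingency table must have at least 2 rows and 2 columns")
  }
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row/column marginal; merge or drop the empty category")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    stop("expected cell count of zero; merge categories before testing")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p_value = unname(res$p.value), expected = unname(res$expected))
}

#' Balanced three-way ANOVA on a rate table
#'
#' Fits the fully crossed three-factor design with one percentage
#' observation per cell: factors DISEASE, PHASE (drug-development phase)
#' and TARGET (target category), main effects and all two-way interactions,
#' with the three-way interaction serving as the error term — the standard
#' convention for a single-observation-per-cell factorial, in which a
#' genuine three-way interaction is not estimable. Percentages are analyzed
#' untransformed.
#'
#' Degenerate decompositions are flagged rather than hidden: an effect with
#' zero sum of squares reports `F = 0`, and a zero residual sum of squares
#' (exactly additive data) reports `F = Inf` for non-null effects; both set
#' the `degenerate` flag.
#'
#' @param rates a [rate_table()] or any data.frame with columns `disease`,
#'   `phase`, `category` (the TARGET factor) and `percent`, one row per
#'   cell of the complete crossing.
#' @return object of class `anova_result`: list with `table` (data.frame of
#'   term, df, sum_sq, mean_sq, f, p, stars), `residual_df`, `ms_error`,
#'   `cell_means` (per factor), `n_per_mean`, `degenerate`, and the fitted
#'   `aov` object.
#' @export
three_way_anova <- function(rates) {
  df <- as.data.frame(rates)[, c("disease", "phase", "category", "percent")]
  names(df) <- c("DISEASE", "PHASE", "TARGET", "percent")
  # re-derive factors so unused levels of a subsetted rate table drop out
  df$DISEASE <- factor(as.character(df$DISEASE))
  df$PHASE <- factor(as.character(df$PHASE))
  df$TARGET <- factor(as.character(df$TARGET))
  lev <- vapply(df[c("DISEASE", "PHASE", "TARGET")], nlevels, integer(1))
  if (any(lev < 2L)) {
    stop("factor(s) with fewer than 2 levels: ",
         paste(names(lev)[lev < 2L], collapse = ", "))
  }
  tab <- table(df$DISEASE, df$PHASE, df$TARGET)
  if (any(tab != 1L)) {
    off <- which(tab != 1L, arr.ind = TRUE)[1L, ]
    stop("design is not one observation per cell; first offending cell: ",
         paste(dimnames(tab)[[1]][off[1]], dimnames(tab)[[2]][off[2]],
               dimnames(tab)[[3]][off[3]], sep = " / "))
  }
  fit <- stats::aov(percent ~ (DISEASE + PHASE + TARGET)^2, data = df)
  an <- summary(fit)[[1]]
  term <- trimws(rownames(an))
  res_row <- term == "Residuals"
  residual_df <- an[res_row, "Df"]
  ss_res <- an[res_row, "Sum Sq"]
  ms_error <- ss_res / residual_df
  eff <- an[!res_row, , drop = FALSE]
  ss <- eff[, "Sum Sq"]
  dfe <- eff[, "Df"]
  ms <- ss / dfe
  degenerate <- FALSE
  f <- numeric(length(ss))
  p <- numeric(length(ss))
  for (i in seq_along(ss)) {
    if (ss[i] <= .Machine$double.eps * max(1, sum(an[, "Sum Sq"]))) {
      f[i] <- 0; p[i] <- 1; degenerate <- TRUE
    } else if (ms_error <= .Machine$double.eps * max(1, sum(an[, "Sum Sq"]))) {
      f[i] <- Inf; p[i] <- 0; degenerate <- TRUE
    } else {
      f[i] <- ms[i] / ms_error
      p[i] <- stats::pf(f[i], dfe[i], residual_df, lower.tail = FALSE)
    }
  }
  out <- data.frame(term = trimws(rownames(eff)), df = dfe, sum_sq = ss,
                    mean_sq = ms, f = f, p = p,
                    stars = significance_stars(p), row.names = NULL)
  cell_means <- lapply(c("DISEASE", "PHASE", "TARGET"), function(fac)
    tapply(df$percent, df[[fac]], mean))
  names(cell_means) <- c("DISEASE", "PHASE", "TARGET")
  n_per_mean <- vapply(c("DISEASE", "PHASE", "TARGET"), function(fac)
    nrow(df) / nlevels(df[[fac]]), numeric(1))
  structure(list(table = out, residual_df = residual_df, ms_error = ms_error,
                 ss_residual = ss_res, ss_total = sum(an[, "Sum Sq"]),
                 cell_means = cell_means, n_per_mean = n_per_mean,
                 degenerate = degenerate, fit = fit),
            class = "anova_result")
}

significance_stars <- function(p) {
  # the usual convention: * <0.05, ** <0.01, *** <0.001, **** <0.0001
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**" else if (pp < 5e-2) "*" else ""
  }, character(1))
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Three-way ANOVA (three-way interaction as error term)\n")
  tb <- x$table
  tb$sum_sq <- signif(tb$sum_sq, 5)
  tb$mean_sq <- signif(tb$mean_sq, 5)
  tb$f <- signif(tb$f, 4)
  tb$p <- signif(tb$p, 3)
  print(tb, row.names = FALSE)
  cat(sprintf("Residual df = %d, MS error = %.5g%s\n", x$residual_df,
              x$ms_error,
              if (x$degenerate) " [degenerate decomposition flagged]" else ""))
  invisible(x)
}

#' Tukey HSD pairwise comparisons from cell means
#'
#' Pairwise mean differences between the levels of one factor, with
#' p-values adjusted by the studentized range distribution:
#' \eqn{q = |m_a - m_b| / \sqrt{MS_{error} / n}} referred to
#' \eqn{q(k, df_{error})}, for `k` balanced groups of `n` observations
#' each.
#'
#' @param cell_means named numeric vector of level means.
#' @param ms_error error mean square from the ANOVA.
#' @param df_error error degrees of freedom; must be positive.
#' @param n_per_mean number of observations behind each mean (balanced).
#' @return data.frame with `k(k-1)/2` rows: `level_a`, `level_b`, `diff`,
#'   `se`, `q`, `p_adj`, `stars`.
#' @export
tukey_hsd <- function(cell_means, ms_error, df_error, n_per_mean) {
  if (df_error <= 0) stop("df_error must be positive")
  k <- length(cell_means)
  if (k < 2L) stop("need at least two level means")
  lev <- names(cell_means)
  if (is.null(lev)) lev <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  se <- sqrt(ms_error / n_per_mean)
  out <- data.frame(
    level_a = lev[pairs[1, ]], level_b = lev[pairs[2, ]],
    diff = cell_means[pairs[2, ]] - cell_means[pairs[1, ]],
    row.names = NULL)
  out$se <- se
  out$q <- abs(out$diff) / se
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = df_error,
                             lower.tail = FALSE)
  out$stars <- significance_stars(out$p_adj)
  out
}

#' Tukey HSD on one factor of a fitted three-way ANOVA
#'
#' Convenience wrapper running [tukey_hsd()] on the marginal level means of
#' one factor of an [three_way_anova()] result, using its error term.
#'
#' @param result an `anova_result`.
#' @param factor one of `"DISEASE"`, `"PHASE"`, `"TARGET"`.
#' @return data.frame as from [tukey_hsd()].
#' @export
anova_tukey <- function(result, factor = c("PHASE", "TARGET", "DISEASE")) {
  factor <- match.arg(factor)
  stopifnot(inherits(result, "anova_result"))
  tukey_hsd(result$cell_means[[factor]], result$ms_error,
            result$residual_df, result$n_per_mean[[factor]])
}
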