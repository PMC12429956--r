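test_that("chi-square matches the closed-form 2x2 formula", {
  # independent oracle: chi2 = n (ad - bc)^2 / (r1 r2 c1 c2)
  closed_form <- function(m) {
    n <- sum(m)
    n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
  }
  res <- chi_square_independence(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(res$statistic, 6.667, tolerance = 5e-4)
  expect_equal(res$dof, 1)
  expect_equal(res$statistic,
               closed_form(matrix(c(10, 20, 20, 10), 2, byrow = TRUE)),
               tolerance = 1e-12)

  set.seed(1)
  for (r in 1:500) {
    m <- matrix(as.numeric(sample(1:80, 4, replace = TRUE)), 2)
    res <- chi_square_independence(m)
    expect_equal(res$statistic, closed_form(m), tolerance = 1e-9)
    expect_equal(res$p_value,
                 stats::pchisq(closed_form(m), 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("chi-square handles exact independence and rejects zero marginals", {
  res <- chi_square_independence(matrix(5, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)),
               "marginal")
  expect_error(chi_square_independence(matrix(1:3, 1, 3)), "at least 2")
})

test_that("chi-square statistic is invariant under row/column permutation", {
  m <- matrix(c(12, 7, 3, 22, 9, 14), 2, byrow = TRUE)
  s <- chi_square_independence(m)$statistic
  expect_equal(chi_square_independence(m[2:1, ])$statistic, s)
  expect_equal(chi_square_independence(m[, c(3, 1, 2)])$statistic, s)
})

make_rates <- function(values) {
  # values: array dim (disease, phase, target)
  dn <- list(paste0("d", seq_len(dim(values)[1])),
             paste0("p", seq_len(dim(values)[2])),
             paste0("t", seq_len(dim(values)[3])))
  df <- expand.grid(disease = dn[[1]], phase = dn[[2]], category = dn[[3]],
                    stringsAsFactors = FALSE)
  df$percent <- as.vector(values)
  df
}

test_that("three-way ANOVA conserves the sum-of-squares decomposition", {
  set.seed(7)
  for (r in 1:20) {
    vals <- array(stats::runif(27, 0, 100), dim = c(3, 3, 3))
    res <- three_way_anova(make_rates(vals))
    ss_total_direct <- sum((as.vector(vals) - mean(vals))^2)
    expect_equal(sum(res$table$sum_sq) + res$ss_residual, ss_total_direct,
                 tolerance = 1e-9)
    expect_equal(res$residual_df, 8)  # (3-1)(3-1)(3-1)
    expect_true(all(res$table$f >= 0))
  }
})

test_that("a pure phase effect loads only on the PHASE term and is flagged", {
  vals <- array(10, dim = c(3, 3, 3))
  vals[, 3, ] <- vals[, 3, ] + 5  # additive shift of the third phase
  res <- three_way_anova(make_rates(vals))
  tb <- res$table
  expect_true(res$degenerate)
  expect_identical(tb$f[tb$term == "PHASE"], Inf)
  expect_equal(tb$sum_sq[tb$term == "DISEASE"], 0, tolerance = 1e-20)
  expect_equal(tb$sum_sq[tb$term == "TARGET"], 0, tolerance = 1e-20)
  expect_equal(res$ss_residual, 0, tolerance = 1e-20)

  flat <- three_way_anova(make_rates(array(10, dim = c(3, 3, 3))))
  expect_true(flat$degenerate)
  expect_true(all(flat$table$f == 0))
})

test_that("ANOVA validates the design and factor levels", {
  df <- make_rates(array(stats::runif(27), dim = c(3, 3, 3)))
  expect_error(three_way_anova(df[-1, ]), "one observation per cell")
  expect_error(three_way_anova(rbind(df, df[1, ])),
               "one observation per cell")
  one_level <- df[df$phase == "p1", ]
  expect_error(three_way_anova(one_level), "fewer than 2 levels")
})

test_that("ANOVA F for one factor is invariant to relabeling other factors", {
  set.seed(11)
  vals <- array(stats::runif(36, 0, 50), dim = c(3, 4, 3))
  df <- make_rates(vals)
  f1 <- three_way_anova(df)
  df2 <- df
  df2$disease <- c(d1 = "dX", d2 = "dY", d3 = "dZ")[df2$disease]
  f2 <- three_way_anova(df2)
  expect_equal(f1$table$f[f1$table$term == "PHASE"],
               f2$table$f[f2$table$term == "PHASE"], tolerance = 1e-9)
  expect_equal(f1$table$f[f1$table$term == "TARGET"],
               f2$table$f[f2$table$term == "TARGET"], tolerance = 1e-9)
})

test_that("tukey_hsd reproduces stats::TukeyHSD on a balanced one-way design", {
  set.seed(3)
  df <- data.frame(g = factor(rep(letters[1:4], each = 6)),
                   y = stats::rnorm(24, rep(c(0, 1, 1, 3), each = 6)))
  fit <- stats::aov(y ~ g, data = df)
  ref <- stats::TukeyHSD(fit)$g
  means <- tapply(df$y, df$g, mean)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  mine <- tukey_hsd(means, mse, fit$df.residual, 6)
  key <- paste0(mine$level_b, "-", mine$level_a)
  expect_equal(unname(mine$diff), unname(ref[key, "diff"]), tolerance = 1e-9)
  expect_equal(unname(mine$p_adj), unname(ref[key, "p adj"]),
               tolerance = 1e-7)
})

test_that("tukey_hsd degenerate and monotonicity properties", {
  means <- c(a = 5, b = 5, c = 7)
  out <- tukey_hsd(means, ms_error = 2, df_error = 10, n_per_mean = 4)
  expect_identical(nrow(out), 3L)  # k(k-1)/2
  expect_equal(out$p_adj[out$level_a == "a" & out$level_b == "b"], 1)
  # p rises monotonically as the difference shrinks, all else fixed
  ps <- vapply(seq(4, 0.5, by = -0.5), function(d)
    tukey_hsd(c(a = 0, b = d), 2, 10, 4)$p_adj, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_error(tukey_hsd(means, 2, 0, 4), "df_error")
})

test_that("significance stars follow the conventional thresholds", {
  an <- three_way_anova(make_rates(array(stats::runif(27, 0, 100),
                                         dim = c(3, 3, 3))))
  expect_true(all(an$table$stars %in% c("", "*", "**", "***", "****")))
  expect_identical(netdrugmap:::significance_stars(c(0.2, 0.04, 0.009,
                                                     0.0009, 0.00009)),
                   c("", "*", "**", "***", "****"))
})

test_that("a factor with no effect reduces the fit to the two-way decomposition", {
  # replicate one disease x target pattern identically across phases: the
  # DISEASE, TARGET and DISEASE:TARGET sums of squares must equal the
  # phase-level multiple of the two-way decomposition, and every
  # phase-involving term must vanish
  set.seed(13)
  pat <- matrix(stats::runif(9, 0, 40), 3, 3)  # disease x target
  vals <- array(NA_real_, dim = c(3, 3, 3))
  for (p in 1:3) vals[, p, ] <- pat
  res3 <- three_way_anova(make_rates(vals))
  two <- summary(stats::aov(y ~ d * t, data = data.frame(
    y = as.vector(pat), d = factor(rep(1:3, 3)),
    t = factor(rep(1:3, each = 3)))))[[1]]
  ss2 <- two[, "Sum Sq"]
  names(ss2) <- trimws(rownames(two))
  tb <- res3$table
  expect_equal(tb$sum_sq[tb$term == "DISEASE"], 3 * ss2[["d"]],
               tolerance = 1e-9)
  expect_equal(tb$sum_sq[tb$term == "TARGET"], 3 * ss2[["t"]],
               tolerance = 1e-9)
  expect_equal(tb$sum_sq[tb$term == "DISEASE:TARGET"],
               3 * ss2[["d:t"]], tolerance = 1e-9)
  expect_equal(tb$sum_sq[tb$term == "PHASE"], 0, tolerance = 1e-12)
  expect_equal(tb$sum_sq[tb$term == "DISEASE:PHASE"], 0, tolerance = 1e-12)
  expect_equal(res3$ss_residual, 0, tolerance = 1e-12)
})
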