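test_that("column means reproduce the printed table cells", {
  tb <- cohort_tables()
  expect_equal(column_mean(tb$table2$pre_LCCA, 2), 0.21)
  expect_equal(column_mean(tb$table2$pre_AAo, 2), 5.18)
  expect_equal(column_mean(tb$table2$pre_DAo, 2), 4.10) # 4.095 rounds up
  expect_equal(column_mean(tb$table2$post_AAo, 2), 4.60)
  expect_equal(column_mean(tb$table2$post_LCCA, 2), 0.61)
  expect_equal(column_mean(tb$table2$post_DAo, 2), 3.29)
  expect_equal(column_mean(tb$table4$pre_LCCA, 1), 44.9) # 44.85 rounds up
  expect_equal(column_mean(tb$table4$post_LCCA, 1), 72.6)
  expect_equal(column_mean(tb$table4$pre_BCT, 1), 47.8) # 47.75 rounds up
  expect_equal(column_mean(tb$table3$pre_LSA, 2), 1.61) # 1.605 rounds up
  expect_equal(column_mean(tb$table5$pre_dia, 0), 58) # 57.5 rounds up
  expect_equal(column_mean(tb$table5$post_dia, 0), 61) # 60.5 rounds up
  expect_equal(column_mean(rep(3.7, 4), 2), 3.7) # identity
  expect_error(column_mean(numeric(0)), "empty")
})

test_that("half-away-from-zero rounding is exact where doubles would misround", {
  # 16.38 / 4 = 4.095: binary doubles hold 4.09499...; exact decimals give 4.10
  expect_equal(column_mean(c(5.26, 5.01, 3.85, 2.26), 2), 4.10)
  expect_identical(sprintf("%.2f", mean(c(5.26, 5.01, 3.85, 2.26))), "4.09")
  # 179.4 / 4 = 44.85
  expect_equal(column_mean(c(89.3, 27.0, 33.8, 29.3), 1), 44.9)
})

test_that("percent changes match the published differences", {
  expect_equal(percent_change(44.9, 72.6), 62)
  expect_equal(percent_change(4.10, 3.29), -20)
  expect_equal(percent_change(5.18, 4.60), -11)
  expect_equal(percent_change(3.16, 3.19), 1)
  expect_equal(percent_change(0.94, 1.02), 9)
  expect_equal(percent_change(2.5, 2.5), 0)
  expect_error(percent_change(0, 1), "zero baseline")
})

test_that("mass conservation residuals stay within print rounding", {
  recs <- cohort_fixture()
  expect_equal(conservation_residual(recs[[2]], "pre"), 0.01)
  expect_equal(conservation_residual(recs[[1]], "post"), 0.00)
  for (r in recs) {
    expect_lte(conservation_residual(r, "pre"), 0.02)
    expect_lte(conservation_residual(r, "post"), 0.02)
  }
})

test_that("fixture records carry the printed patient characteristics", {
  recs <- cohort_fixture()
  expect_length(recs, 4L)
  expect_equal(recs[[1]]$flows_lpm$pre_AAo, 6.31)
  expect_equal(recs[[4]]$graft_components_mm,
               c("42-42-200", "46-46-200", "46-46-150"))
  expect_equal(recs[[3]]$pressures_mmhg$pre_sys, 117)
  expect_equal(recs[[1]]$age, 48L)
  expect_equal(recs[[2]]$disease, "PAU")
  # all numeric cells nonnegative
  for (r in recs) {
    vals <- unlist(c(r$flows_lpm, r$areas_cm2, r$velocities_cms,
                     r$pressures_mmhg))
    expect_true(all(vals >= 0))
  }
})

test_that("Pearson correlation p-values follow the t distribution on n-2 df", {
  res <- pearson_with_p(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)

  # r = 0.95 at n = 4 sits at the two-sided 5% critical value (t = 4.303)
  x <- c(-3, -1, 1, 3)
  z <- c(1, -1, -1, 1) # orthogonal to x, mean zero
  y <- 0.95 * x / sqrt(sum(x^2)) + sqrt(1 - 0.95^2) * z / sqrt(sum(z^2))
  res <- pearson_with_p(x, y)
  expect_equal(res$r, 0.95, tolerance = 1e-12)
  expect_equal(res$t, 4.3027, tolerance = 1e-4)
  expect_equal(res$p, 0.05, tolerance = 1e-3)

  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "degenerate variance")
  expect_error(pearson_with_p(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("pearson_with_p agrees with cor.test and permutation ranking", {
  set.seed(303)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    mine <- pearson_with_p(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  # permutation oracle at n = 4: all 24 permutations; the t-based p must
  # rank pairs the same way the exact permutation p does
  perm_p <- function(x, y) {
    perms <- rbind(
      c(1,2,3,4),c(1,2,4,3),c(1,3,2,4),c(1,3,4,2),c(1,4,2,3),c(1,4,3,2),
      c(2,1,3,4),c(2,1,4,3),c(2,3,1,4),c(2,3,4,1),c(2,4,1,3),c(2,4,3,1),
      c(3,1,2,4),c(3,1,4,2),c(3,2,1,4),c(3,2,4,1),c(3,4,1,2),c(3,4,2,1),
      c(4,1,2,3),c(4,1,3,2),c(4,2,1,3),c(4,2,3,1),c(4,3,1,2),c(4,3,2,1))
    r0 <- abs(cor(x, y))
    mean(apply(perms, 1, function(p) abs(cor(x, y[p])) >= r0 - 1e-12))
  }
  set.seed(304)
  pairs <- replicate(20, list(x = rnorm(4), y = rnorm(4)), simplify = FALSE)
  p_t <- vapply(pairs, function(d) pearson_with_p(d$x, d$y)$p, 0)
  p_perm <- vapply(pairs, function(d) perm_p(d$x, d$y), 0)
  # each dataset has its own permutation distribution, so the two p-values
  # need not order every pair identically; they must agree strongly in rank
  expect_gt(cor(p_t, p_perm, method = "spearman"), 0.8)
  # and the t-based p must be monotone in |r| (same n throughout)
  r_abs <- vapply(pairs, function(d) abs(cor(d$x, d$y)), 0)
  expect_true(all(diff(p_t[order(r_abs)]) < 0))
})

test_that("cohort_report computes means within ranges and flags discrepancies", {
  summ <- cohort_report()
  expect_s3_class(summ, "cohort_summary")
  expect_true(all(summ$means$mean >= summ$means$min))
  expect_true(all(summ$means$mean <= summ$means$max))
  # the known printed-vs-recomputed disagreements are flagged, no others
  dis <- summ$means[!summ$means$agrees, c("table", "column")]
  expect_setequal(paste(dis$table, dis$column),
                  c("table2 pre_BCT", "table2 pre_LSA",
                    "table3 pre_BCT", "table4 post_BCT"))
  pc <- summ$percent_changes
  expect_equal(pc$change_pct[pc$quantity == "LCCA velocity"], 62)
  expect_equal(pc$change_pct[pc$quantity == "AAo flow"], -11)
  expect_equal(pc$change_pct[pc$quantity == "DAo flow"], -20)
  expect_equal(pc$change_pct[pc$quantity == "BCT area"], 1)
  expect_equal(pc$change_pct[pc$quantity == "LCCA area"], 9)
  expect_true(all(summ$conservation$residual_lpm <= 0.02))
})

test_that("percent changes from unrounded means stay consistent for the headline values", {
  summ <- cohort_report(percent_from = "unrounded")
  pc <- summ$percent_changes
  expect_equal(pc$change_pct[pc$quantity == "LCCA velocity"], 62)
  expect_equal(pc$change_pct[pc$quantity == "DAo flow"], -20)
  expect_equal(pc$change_pct[pc$quantity == "BCT area"], 1)
})
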