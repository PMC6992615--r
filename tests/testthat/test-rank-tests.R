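test_that("signed-rank test handles the extreme and degenerate cases", {
  # eight pairs all improving by distinct amounts: W+ = 0, exact p = 2/256
  pre <- c(1.0, 1.2, 0.9, 1.5, 2.0, 0.8, 1.1, 1.7)
  post <- pre - c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  res <- wilcoxon_signed_rank(post, pre)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_exact, 2 / 256)
  expect_true(res$exact)

  # antisymmetric differences sit at the null centre: p = 1
  d <- c(0.3, -0.3, 0.8, -0.8, 1.1, -1.1)
  expect_equal(wilcoxon_signed_rank(d)$p_value, 1)

  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "non-zero")
})

test_that("postoperative acuity comparison reproduces the exact enumeration", {
  t2 <- utils::read.csv(gt_table_path("table2"))
  res <- wilcoxon_signed_rank(t2$bcva_postop_logmar, t2$bcva_preop_logmar)
  d <- t2$bcva_postop_logmar - t2$bcva_preop_logmar
  expect_equal(res$p_exact, oracle_signed_rank_p(d))
  # one tied pair of |differences|: W+ is the mid-rank 1.5 of the lone
  # worsening eye, exact two-sided p = 6/256
  expect_equal(unname(res$statistic), 1.5)
  expect_equal(res$p_exact, 6 / 256)
  expect_lt(res$p_exact, 0.05)
  # the normal approximation is reported alongside
  expect_true(is.finite(res$p_approx))
})

test_that("Mann-Whitney test handles the extreme and degenerate cases", {
  a <- 1:8; b <- 11:18
  res <- mann_whitney_u(a, b)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_exact, 2 / choose(16, 8))
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  expect_error(mann_whitney_u(1, c(2, 3)), "at least 2")
})

test_that("prone and supine gas volumes do not differ (printed p of 1)", {
  t3 <- utils::read.csv(gt_table_path("table3"))
  res <- mann_whitney_u(t3$gas_volume_prone_pct, t3$gas_volume_supine_pct)
  expect_equal(res$p_exact,
               oracle_mwu_p(t3$gas_volume_prone_pct, t3$gas_volume_supine_pct))
  expect_gt(res$p_value, 0.9)
  # the supraduction angle does differ
  expect_lt(mann_whitney_u(t3$angle_prone_deg, t3$angle_supine_deg)$p_value,
            0.05)
})

test_that("exact p-values equal brute-force enumeration on random instances", {
  set.seed(7)
  for (i in 1:100) {
    m <- sample(3:10, 1)
    d <- round(rnorm(m), sample(0:1, 1))   # rounding provokes ties and zeros
    if (sum(d != 0) < 2) d <- c(d, 0.7, -1.3)
    expect_equal(wilcoxon_signed_rank(d)$p_exact, oracle_signed_rank_p(d))

    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- round(rnorm(na), 1); b <- round(rnorm(nb, 0.3), 1)
    expect_equal(mann_whitney_u(a, b)$p_exact, oracle_mwu_p(a, b))
  }
})

test_that("exact p matches base R on tie-free data", {
  set.seed(21)
  a <- rnorm(7); b <- rnorm(9, 0.8)
  expect_equal(mann_whitney_u(a, b)$p_exact,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
  d <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(d)$p_exact,
               stats::wilcox.test(d, exact = TRUE)$p.value)
})

test_that("shifting one group upward never raises its one-sided tail", {
  set.seed(3)
  a <- rnorm(6); b <- rnorm(6)
  u_at <- function(shift) unname(mann_whitney_u(a, b + shift)$statistic)
  us <- vapply(seq(0, 3, by = 0.25), u_at, numeric(1))
  expect_true(all(diff(us) <= 0))
})

test_that("zero-difference handling supports both conventions", {
  d <- c(0, 0.5, -0.3, 1.2, 0.8)
  w <- wilcoxon_signed_rank(d, zero_method = "wilcox")
  p <- wilcoxon_signed_rank(d, zero_method = "pratt")
  expect_equal(w$n, 4)
  expect_equal(p$n, 4)
  # Pratt ranks |zeros| too, so the positive ranks differ
  expect_gt(unname(p$statistic), unname(w$statistic))
})

test_that("cohort summaries reproduce the printed means and errors", {
  t1 <- utils::read.csv(gt_table_path("table1"))
  s1 <- cohort_summary(t1)
  pick <- function(s, col) s[s$column == col, ]
  expect_lt(abs(pick(s1, "age_years")$mean - 59.8), 0.051)
  expect_lt(abs(pick(s1, "age_years")$se - 1.8), 0.051)
  expect_lt(abs(pick(s1, "axial_length_mm")$mean - 25.4), 0.051)
  expect_lt(abs(pick(s1, "axial_length_mm")$se - 0.4), 0.051)
  expect_lt(abs(pick(s1, "quadrants")$mean - 1.9), 0.051)
  expect_lt(abs(pick(s1, "n_breaks")$mean - 2.8), 0.051)
  expect_lt(abs(pick(s1, "n_breaks")$se - 0.8), 0.051)

  t2 <- utils::read.csv(gt_table_path("table2"))
  s2 <- cohort_summary(t2, c("bcva_preop_logmar", "bcva_postop_logmar"))
  expect_true(all(abs(s2$mean - c(0.82, 0.11)) < 0.0051))
  expect_true(all(abs(s2$se - c(0.27, 0.07)) < 0.0051))

  t3 <- utils::read.csv(gt_table_path("table3"))
  s3 <- cohort_summary(t3)
  expect_lt(abs(pick(s3, "gas_volume_prone_pct")$mean - 60.1), 0.051)
  expect_lt(abs(pick(s3, "gas_volume_supine_pct")$mean - 60.0), 0.051)
  expect_lt(abs(pick(s3, "gas_volume_prone_pct")$se - 4.0), 0.051)
  expect_lt(abs(pick(s3, "angle_prone_deg")$mean - 16.1), 0.051)
  expect_lt(abs(pick(s3, "angle_prone_deg")$se - 2.8), 0.051)
  expect_lt(abs(pick(s3, "angle_supine_deg")$mean - 1.8), 0.051)
  expect_lt(abs(pick(s3, "angle_supine_deg")$se - 3.5), 0.051)

  # degenerate and malformed inputs
  const <- data.frame(x = rep(4, 5))
  expect_equal(cohort_summary(const)$se, 0)
  expect_error(cohort_summary(t1, "sex"), "non-numeric")
  expect_error(cohort_summary(t1, "nope"), "no such column")
})
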