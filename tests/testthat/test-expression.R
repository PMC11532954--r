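make_expr <- function(values, condition = NULL, patient = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", 1:n)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  }
  if (is.null(condition)) condition <- rep("normal", n)
  if (is.null(patient)) patient <- sprintf("p%d", 1:n)
  expression_matrix(values, data.frame(sample = colnames(values),
                                       tissue = "t", condition = condition,
                                       patient = patient))
}

test_that("log-mean expression averages log2(fpkm + 1)", {
  m <- make_expr(matrix(c(1, 3, 0, 0), 2L, 2L, byrow = TRUE))
  lm <- log_mean_expression(m)
  expect_equal(unname(lm), c(1.5, 0))
  expect_error(log_mean_expression(m, samples = character(0)), "empty")

  set.seed(2)
  v <- matrix(rexp(200 * 20), 200L, 20L)
  m2 <- make_expr(v)
  expect_equal(unname(log_mean_expression(m2)),
               apply(log2(v + 1), 1L, mean))
})

test_that("group comparison matches exact rank-sum enumeration", {
  x <- c(1, 2, 3); y <- c(11, 12, 13)
  res <- group_compare(x, y)
  expect_equal(res$p, 0.1)
  expect_equal(res$p, enumerate_ranksum_p(x, y))

  set.seed(8)
  for (i in 1:10) {
    a <- runif(sample(4:8, 1)); b <- runif(sample(4:8, 1))
    expect_equal(group_compare(a, b)$p, enumerate_ranksum_p(a, b),
                 tolerance = 1e-10)
  }

  expect_warning(res_t <- group_compare(c(2, 2), c(2, 2)), "tied")
  expect_equal(res_t$p, 1)
  expect_error(group_compare(1, c(1, 2)), "at least 2")

  # strongly shifted log-normal groups are detected
  set.seed(3)
  g1 <- exp(rnorm(500)); g2 <- exp(rnorm(500) + 1)
  expect_lt(group_compare(g1, g2)$p, 1e-10)
})

test_that("tumor/normal log2 fold change is analytic and antisymmetric", {
  v <- matrix(c(3, 3, 1, 1,
                2, 2, 2, 2), 2L, 4L, byrow = TRUE)
  m <- make_expr(v, condition = c("tumor", "tumor", "normal", "normal"),
                 patient = c("p1", "p2", "p1", "p2"))
  fc <- tumor_normal_log2fc(m)
  expect_equal(unname(fc$log2fc), c(1, 0))

  flipped <- make_expr(v, condition = c("normal", "normal", "tumor",
                                        "tumor"),
                       patient = c("p1", "p2", "p1", "p2"))
  expect_equal(unname(tumor_normal_log2fc(flipped)$log2fc),
               -unname(fc$log2fc))
  only_n <- make_expr(v)
  expect_error(tumor_normal_log2fc(only_n), "tumor")
})

test_that("indiv-CV is the percent SD/mean with zero-mean exclusion", {
  v <- rbind(c(5, 5, 5), c(1, 2, 3), c(2, 4, 6), c(0, 0, 0))
  m <- make_expr(v)
  cv <- indiv_cv(m)
  expect_equal(unname(cv$cv), c(0, 50, 50))  # scale invariance: rows 2,3
  expect_equal(cv$n_excluded, 1L)
  expect_error(indiv_cv(make_expr(matrix(1, 2, 1))), "at least 2")

  # invariance to positive rescaling
  cv2 <- indiv_cv(make_expr(v * 7))
  expect_equal(cv$cv, cv2$cv)
})

test_that("g-CV works per sample across a gene set", {
  v <- rbind(g1 = c(1, 4), g2 = c(2, 4), g3 = c(3, 4))
  m <- make_expr(v)
  gc <- g_cv(m, c("g1", "g2", "g3"))
  expect_equal(unname(gc$cv), c(50, 0))
  expect_error(g_cv(m, character(0)), "non-empty")
  expect_error(g_cv(m, "nope"), "unknown genes")
})

test_that("paired test enforces the 15-pair inclusion rule", {
  expect_error(paired_condition_test(rnorm(14), rnorm(14)), "15")
  x <- rnorm(20)
  same <- paired_condition_test(x, x)
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")
  expect_warning(res <- paired_condition_test(x, x - 5), "zero-variance")
  expect_true(is.na(res$p))

  set.seed(5)
  a <- rnorm(20, 50, 1)
  b <- a - 5 + rnorm(20, 0, 1)
  det <- paired_condition_test(a, b)
  expect_lt(det$p, 0.001)
  expect_equal(det$direction, "down")
})

test_that("synthetic generator recovers target CVs and g-CV ordering", {
  cfg <- sim_config(seed = 4)
  m <- gen_expression(cfg)
  pg4 <- attr(m, "pg4_genes"); non <- attr(m, "non_pg4_genes")
  cv <- indiv_cv(m, "normal")
  expect_lt(abs(stats::median(cv$cv[pg4]) - 30) / 30, 0.1)
  expect_lt(abs(stats::median(cv$cv[non]) - 60) / 60, 0.1)

  ord <- vapply(1:20, function(s) {
    mi <- gen_expression(sim_config(seed = s))
    p <- attr(mi, "pg4_genes"); np <- attr(mi, "non_pg4_genes")
    stats::median(g_cv(mi, p, "normal")$cv) <
      stats::median(g_cv(mi, np, "normal")$cv)
  }, logical(1))
  expect_true(all(ord))
})
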