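test_that("BH adjustment matches hand-evaluated step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment equals brute-force prefix scan and p.adjust", {
  set.seed(81)
  for (rep in 1:40) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # NA passthrough: missing tests do not count towards the family
  p <- c(0.01, NA, 0.04)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.04)))
})

test_that("spearman screen recovers monotone relations and handles rank data", {
  v <- cbind(x = c(1, 2, 3, 4, 5), y = c(2, 4, 6, 8, 10),
             z = c(10, 8, 6, 4, 2), w = c(2, 1, 4, 3, 5))
  rownames(v) <- sprintf("P%d", 1:5)
  ct <- clinical_table(v)
  scr <- spearman_screen(ct, min_pairs = 3)
  get <- function(a, b) scr$coefficient[scr$item_a == a & scr$item_b == b]
  expect_equal(get("x", "y"), 1)
  expect_equal(get("x", "z"), -1)
  expect_equal(get("x", "w"), 0.8)   # 1 - 6*sum(d^2)/(n(n^2-1)), d^2 sum = 4
})

test_that("spearman screen applies pairwise deletion and min_pairs rule", {
  set.seed(91)
  v <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("P%d", 1:20),
                                                c("a", "b", "c")))
  v[1:18, 3] <- NA                      # only 2 complete pairs with c
  ct <- clinical_table(v)
  scr <- spearman_screen(ct, min_pairs = 5)
  row_ab <- scr[scr$item_a == "a" & scr$item_b == "b", ]
  row_ac <- scr[scr$item_a == "a" & scr$item_b == "c", ]
  expect_equal(row_ab$n_used, 20L)
  expect_equal(row_ac$n_used, 2L)
  expect_true(is.na(row_ac$coefficient))      # untested, not p = 1
  expect_true(is.na(row_ac$q))                # excluded from the BH family
  expect_false(is.na(row_ab$q))
  expect_error(spearman_screen(ct, phenotypes = c("a", "nope")), "unknown")
})

test_that("spearman coefficient is invariant under increasing transforms", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(c(8, 15, 40), 1)
    x <- rnorm(n); y <- rnorm(n)
    v <- cbind(a = x, b = y, a2 = exp(2 * x + 1), b2 = y^3)
    rownames(v) <- sprintf("P%d", seq_len(n))
    scr <- spearman_screen(clinical_table(v), min_pairs = 3)
    get <- function(a, b) scr$coefficient[scr$item_a == a & scr$item_b == b]
    expect_equal(get("a", "b"), get("a2", "b2"), tolerance = 1e-12)
  }
})

test_that("group comparison: Mann-Whitney exact and approximate branches", {
  v <- cbind(score = c(1, 2, 3, 4))
  rownames(v) <- sprintf("P%d", 1:4)
  ct <- clinical_table(v)
  gc <- compare_groups(ct, c("P1", "P2"), c("P3", "P4"), "score")
  expect_equal(gc$test, "mann_whitney")
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p, 2 / 6, tolerance = 1e-12)    # enumeration of C(4,2)

  # identical multisets: U sits at n_a * n_b / 2, p = 1
  v2 <- cbind(score = c(5, 7, 9, 5, 7, 9))
  rownames(v2) <- sprintf("P%d", 1:6)
  gc2 <- compare_groups(clinical_table(v2), sprintf("P%d", 1:3),
                        sprintf("P%d", 4:6), "score")
  expect_equal(gc2$p, 1)
  expect_error(compare_groups(ct, c("P1", "P2"), c("P2", "P3"), "score"),
               "disjoint")
})

test_that("Mann-Whitney exact p equals enumeration over rank assignments", {
  set.seed(111)
  for (rep in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(100, na + nb)             # distinct values, no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    v <- cbind(ph = c(a, b))
    rownames(v) <- sprintf("P%d", seq_along(x))
    gc <- compare_groups(clinical_table(v), sprintf("P%d", seq_len(na)),
                         sprintf("P%d", na + seq_len(nb)), "ph")
    # enumerate all C(na+nb, na) group assignments of the observed values
    u_obs <- sum(outer(a, b, ">"))
    combos <- combn(na + nb, na)
    u_all <- apply(combos, 2, function(idx)
      sum(outer(x[idx], x[-idx], ">")))
    p_enum <- mean(pmin(u_all, na * nb - u_all) <= min(u_obs, na * nb - u_obs))
    expect_equal(gc$p, p_enum, tolerance = 1e-12)
  }
})

test_that("group comparison is symmetric in its groups", {
  set.seed(121)
  v <- cbind(ph = rnorm(14))
  rownames(v) <- sprintf("P%d", 1:14)
  ct <- clinical_table(v)
  a <- sprintf("P%d", 1:6); b <- sprintf("P%d", 7:14)
  g1 <- compare_groups(ct, a, b, "ph")
  g2 <- compare_groups(ct, b, a, "ph")
  expect_equal(g1$statistic + g2$statistic, 6 * 8)
  expect_equal(g1$p, g2$p, tolerance = 1e-12)
})

test_that("binary comparison: chi-squared without correction plus Fisher", {
  # cohort diabetes split: 0/9 vs 42/109 positives
  v <- cbind(diabetes = c(rep(0, 9), rep(1, 42), rep(0, 67)))
  rownames(v) <- sprintf("P%03d", 1:118)
  ct <- clinical_table(v, kinds = c(diabetes = "binary"))
  gc <- compare_groups(ct, sprintf("P%03d", 1:9), sprintf("P%03d", 10:118),
                       "diabetes")
  # N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on [[0,9],[42,67]]
  expect_equal(gc$statistic, 118 * (0 * 67 - 9 * 42)^2 /
                 (9 * 109 * 42 * 76), tolerance = 1e-9)
  expect_equal(round(gc$statistic, 2), 5.38)
  expect_equal(gc$test, "chi_squared+fisher_exact")  # expected cell < 5
  expect_equal(gc$fisher_p, fisher.test(rbind(c(0, 9), c(42, 67)))$p.value)
  expect_equal(gc$group_summaries$a$percent, 0)
  expect_equal(gc$group_summaries$b$percent, 38.5)
})

test_that("count_percent reports cohort-table percentages", {
  expect_equal(count_percent(59, 109)$percent, 54.1)
  expect_equal(count_percent(9, 9)$percent, 100)
  expect_equal(count_percent(0, 42)$percent, 0)
  expect_error(count_percent(5, 4), "count <= total")
})

test_that("one-sample Wilcoxon matches sign-pattern enumeration", {
  r <- one_sample_wilcoxon(c(-1, 1), 0)
  expect_equal(r$p, 1)
  r <- one_sample_wilcoxon(c(1, 2, 3), 0)
  expect_equal(r$statistic, 6)
  expect_equal(r$p, 0.25)       # 2/8 of the 2^3 sign patterns
  r <- one_sample_wilcoxon(5, 0)
  expect_equal(r$p, 1)          # 2 * (1/2)
  expect_error(one_sample_wilcoxon(c(3, 3), 3), "degenerate")
  # zeros dropped before ranking
  r2 <- one_sample_wilcoxon(c(0, 1, 2, 3), 0)
  expect_equal(r2$p, 0.25)
})

test_that("paired Wilcoxon reduces to the one-sample test on differences", {
  expect_error(paired_wilcoxon(c(1, 2), c(1, 2)), "degenerate")
  a <- c(4, 7, 9); b <- c(3, 5, 6)
  expect_equal(paired_wilcoxon(a, b)$p,
               one_sample_wilcoxon(a - b, 0)$p)
  r <- paired_wilcoxon(c(0, 2, 3, 0), c(1, 1, 1, 2))  # diffs -1, 1, 2, -2
  expect_equal(r$p, 1)
  # missing pairs dropped
  r2 <- paired_wilcoxon(c(1, 2, 3, NA), c(0, 0, 0, 5))
  expect_equal(r2$p, 0.25)
})

test_that("delta-delta-Ct relative expression", {
  expect_equal(ddct_relative_expression(10, 7, 12, 7), 4)    # dCt 3 vs 5
  expect_equal(ddct_relative_expression(12, 7, 12, 7), 1)
  expect_equal(ddct_relative_expression(13, 7, 12, 7), 0.5)  # dCt 6 vs 5
  expect_error(ddct_relative_expression(NA, 1, 1, 1), "finite")
})

test_that("correlation screen files round-trip the matrices", {
  ct <- small_clinical()
  scr <- spearman_screen(ct, c("height", "weight", "glucose"), min_pairs = 3)
  prefix <- file.path(withr::local_tempdir(), "scr")
  write_correlation_screen(scr, prefix)
  long <- read.delim(paste0(prefix, "_long.tsv"))
  expect_equal(nrow(long), 3)
  cm <- read.delim(paste0(prefix, "_coef.tsv"), row.names = 1)
  expect_equal(as.matrix(cm), attr(scr, "coef_matrix"), tolerance = 1e-6)
})
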