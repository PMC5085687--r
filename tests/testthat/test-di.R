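test_that("pair_fold normalises a pair to fold and direction", {
  pf <- pair_fold(25, 10, 0)
  expect_equal(pf$fold, 2.5)
  expect_equal(pf$sign, 1L)
  pf <- pair_fold(5, 5, 0)
  expect_equal(pf$fold, 1)
  expect_equal(pf$sign, 0L)
  pf <- pair_fold(10, 25, 0)
  expect_equal(pf$fold, 2.5)
  expect_equal(pf$sign, -1L)
  expect_error(pair_fold(0, 0, 0), "undefined")
  expect_error(pair_fold(-1, 1, 0), "non-negative")
})

test_that("DI and adjusted fold change are mutual inverses", {
  expect_identical(fc_from_di(0.6), 2.5)
  expect_identical(di_from_fc(2.5), 0.6)
  expect_equal(fc_from_di(0), 1)
  expect_equal(di_from_fc(1), 0)
  expect_equal(fc_from_di(-0.75), 4)
  expect_equal(di_from_fc(4), 0.75)
  expect_error(fc_from_di(1), "< 1")
  expect_error(di_from_fc(0.5), ">= 1")
  set.seed(21)
  di <- runif(200, -0.999, 0.999)
  expect_equal(di_from_fc(fc_from_di(di)), abs(di))
  fc <- 1 / runif(200)
  expect_equal(fc_from_di(di_from_fc(fc)), fc)
})

test_that("di_fit reproduces hand-evaluated cohorts", {
  # all pairs identical -> DI 0
  fx <- make_paired_expr(matrix(7, 1, 9), matrix(7, 1, 9))
  fit <- di_fit(fx$expr, fx$design, di_params(pseudocount = 0))
  expect_equal(fit$results$di, 0)
  expect_equal(fit$results$adjusted_fc, 1)
  expect_equal(fit$results$direction, "none")
  expect_false(fit$results$passed)

  # 9 pairs at exactly fold 2.5: DI 0.6 but strict thresholds exclude it
  fx <- make_paired_expr(matrix(25, 1, 9), matrix(10, 1, 9))
  fit <- di_fit(fx$expr, fx$design, di_params(pseudocount = 0))
  expect_equal(fit$results$di, 0.6)
  expect_equal(fit$results$adjusted_fc, 2.5)
  expect_equal(fit$results$coverage, 0L)   # strict > tau
  expect_false(fit$results$passed)

  # 9 pairs at fold 4: DI 0.75, FC 4, covered by all pairs
  fx <- make_paired_expr(matrix(40, 1, 9), matrix(10, 1, 9))
  fit <- di_fit(fx$expr, fx$design, di_params(pseudocount = 0))
  expect_equal(fit$results$di, 0.75)
  expect_equal(fit$results$adjusted_fc, 4)
  expect_equal(fit$results$coverage, 9L)
  expect_true(fit$results$passed)
  expect_equal(fit$min_coverage, 6L)       # ceil(2 * 9 / 3)

  expect_error(di_fit(fx$expr, fx$design, genes = "nope"), "unknown gene")
  bad_design <- paired_design("P1", "X_T", "X_N")
  expect_error(di_fit(fx$expr, bad_design), "unknown sample")
})

test_that("signed and literal modes agree when all pairs move one way", {
  set.seed(31)
  tumor <- matrix(runif(45, 20, 80), 5, 9)
  anpt <- matrix(runif(45, 1, 10), 5, 9)
  fx <- make_paired_expr(tumor, anpt)
  s <- di_fit(fx$expr, fx$design, di_params(pseudocount = 0, mode = "signed"))
  l <- di_fit(fx$expr, fx$design, di_params(pseudocount = 0, mode = "literal"))
  expect_equal(s$results$di, l$results$di)
})

test_that("literal mode inflates |DI| under conflicting pairs, signed cancels", {
  tumor <- matrix(c(40, 40, 10), 1, 3)
  anpt <- matrix(c(10, 10, 40), 1, 3)
  fx <- make_paired_expr(tumor, anpt)
  s <- di_fit(fx$expr, fx$design, di_params(pseudocount = 0, mode = "signed"))
  l <- di_fit(fx$expr, fx$design, di_params(pseudocount = 0, mode = "literal"))
  expect_equal(s$results$di, (0.75 + 0.75 - 0.75) / 3)
  expect_equal(l$results$di, 0.75)         # sign of summed log ratios is +
  # exact balance: sigma = 0 forces DI 0 in literal mode
  fx2 <- make_paired_expr(matrix(c(40, 10), 1, 2), matrix(c(10, 40), 1, 2))
  l2 <- di_fit(fx2$expr, fx2$design, di_params(pseudocount = 0, mode = "literal"))
  expect_equal(l2$results$di, 0)
  expect_equal(l2$results$direction, "none")
})

test_that("signed DI equals the brute-force pair_fold composition", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(3:9, 1)
    tumor <- runif(n, 0, 50)
    anpt <- runif(n, 0, 50)
    c0 <- sample(c(0.1, 0.5, 1), 1)
    fx <- make_paired_expr(matrix(tumor, 1), matrix(anpt, 1))
    fit <- di_fit(fx$expr, fx$design, di_params(pseudocount = c0))
    expect_equal(fit$results$di, brute_di(tumor, anpt, c0), tolerance = 1e-12)
  }
})

test_that("DI is antisymmetric under swapping tumor and control", {
  set.seed(51)
  tumor <- matrix(runif(36, 0, 30), 4, 9)
  anpt <- matrix(runif(36, 0, 30), 4, 9)
  for (mode in c("signed", "literal")) {
    p <- di_params(pseudocount = 0.1, mode = mode)
    a <- di_fit(make_paired_expr(tumor, anpt)$expr,
                make_paired_expr(tumor, anpt)$design, p)
    b <- di_fit(make_paired_expr(anpt, tumor)$expr,
                make_paired_expr(anpt, tumor)$design, p)
    expect_equal(a$results$di, -b$results$di, tolerance = 1e-12)
  }
})

test_that("DI is scale-invariant at zero pseudocount and bounded by pair values", {
  set.seed(61)
  tumor <- matrix(runif(27, 1, 30), 3, 9)
  anpt <- matrix(runif(27, 1, 30), 3, 9)
  p0 <- di_params(pseudocount = 0)
  a <- di_fit(make_paired_expr(tumor, anpt)$expr,
              make_paired_expr(tumor, anpt)$design, p0)
  b <- di_fit(make_paired_expr(tumor * 7.3, anpt * 7.3)$expr,
              make_paired_expr(tumor * 7.3, anpt * 7.3)$design, p0)
  expect_equal(a$results$di, b$results$di, tolerance = 1e-12)
  # |DI| <= max |v_i| in signed mode; equals mean |v_i| in literal mode
  expect_true(all(abs(a$results$di) <= apply(abs(a$v), 1, max) + 1e-12))
  l <- di_fit(make_paired_expr(tumor, anpt)$expr,
              make_paired_expr(tumor, anpt)$design,
              di_params(pseudocount = 0, mode = "literal"))
  expect_equal(abs(l$results$di), rowMeans(abs(l$v)), ignore_attr = TRUE)
})

test_that("select_de_genes applies the DI and coverage criteria", {
  fit <- structure(list(
    results = data.frame(gene_id = c("A", "B", "C"),
                         di = c(0.75, 0.75, -0.9),
                         adjusted_fc = c(4, 4, 10),
                         direction = c("up", "up", "down"),
                         coverage = c(9L, 5L, 8L),
                         passed = c(TRUE, FALSE, TRUE)),
    params = di_params(), n_pairs = 9L, min_coverage = 6L),
    class = "di_fit")
  sel <- select_de_genes(fit)
  expect_equal(sel$up, "A")        # B fails coverage
  expect_equal(sel$down, "C")
  empty <- fit
  empty$results <- fit$results[0, ]
  expect_equal(select_de_genes(empty), list(up = character(),
                                            down = character()))
  # ordering: |di| descending then gene id
  fit$results$coverage <- c(9L, 9L, 8L)
  fit$results$di <- c(0.75, 0.9, -0.9)
  sel <- select_de_genes(fit)
  expect_equal(sel$up, c("B", "A"))
})

test_that("expressed gene counts use strict thresholds", {
  m <- expression_matrix(matrix(c(0, 0, 0.5, 0.2, 2, 1),
                                3, 2, byrow = TRUE,
                                dimnames = list(c("G1", "G2", "G3"),
                                                c("S1", "S2"))))
  expect_equal(expressed_gene_counts(m, c(0, 1)),
               c(">0" = 2L, ">1" = 1L))
  expect_length(expressed_gene_counts(m, numeric()), 0)
  z <- expression_matrix(matrix(0, 2, 2,
                                dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(unname(expressed_gene_counts(z, 0)), 0L)
  set.seed(71)
  thr <- sort(runif(4, 0, 3))
  counts <- expressed_gene_counts(m, thr)
  expect_true(all(diff(counts) <= 0))
})

test_that("di_fit results serialize with parameter metadata", {
  fx <- make_paired_expr(matrix(40, 2, 9), matrix(10, 2, 9))
  fit <- di_fit(fx$expr, fx$design)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_di_results(fit, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# mode=signed", lines)))
  expect_true(any(grepl("^# n_pairs=9", lines)))
  tab <- read.delim(path, comment.char = "#")
  expect_equal(tab$gene_id, fit$results$gene_id)
  expect_equal(tab$di, fit$results$di, tolerance = 1e-6)
})
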