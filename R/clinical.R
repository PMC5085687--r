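# Clinical phenotype statistics: the Spearman phenotype-phenotype screen with
# BH FDR masking, cohort group comparisons (Mann-Whitney / chi-squared /
# Fisher), one-sample and paired Wilcoxon signed-rank tests, and delta-delta-Ct
# relative quantification.

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in input order: on the sorted scale,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`; `NA`s are passed
#'   through and do not count towards the family size.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(pvals))
  ok <- which(!is.na(pvals))
  m <- length(ok)
  if (m == 0) return(q)
  p <- pvals[ok]
  o <- order(p, decreasing = TRUE)
  qs <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  q[ok[o]] <- qs
  q
}

# Spearman rho and two-sided p on pairwise-complete data. Exact null
# distribution (via cor.test) when n < 10 and there are no ties; otherwise the
# t approximation with n - 2 df.
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n < 10 && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    r <- max(min(rho, 1), -1)
    if (abs(r) == 1) {
      p <- 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Spearman correlation screen over clinical phenotypes
#'
#' Computes Spearman's rank correlation for every unordered pair of the named
#' phenotypes on pairwise-complete patients. Pairs with fewer than `min_pairs`
#' complete observations are reported with missing coefficient and excluded
#' from the Benjamini-Hochberg family; q-values are computed over all tested
#' pairs as one family, and the significance mask flags pairs with
#' `q < alpha`.
#'
#' @param clinical a [clinical_table()].
#' @param phenotypes phenotype names to screen (default: all continuous
#'   phenotypes; binary phenotypes take part only when listed explicitly).
#' @param min_pairs minimum pairwise-complete sample size (default 5).
#' @param alpha FDR level for the significance mask (default 0.05).
#' @return an object of class `pheno_corr`: data.frame with columns `item_a`,
#'   `item_b`, `coefficient`, `p`, `q`, `n_used`, `method`, `significant`;
#'   attributes `coef_matrix` and `mask_matrix` hold the square coefficient and
#'   significance matrices, `alpha` the level used.
#' @export
spearman_screen <- function(clinical, phenotypes = NULL, min_pairs = 5,
                            alpha = 0.05) {
  stopifnot(inherits(clinical, "clinical_table"), min_pairs >= 3)
  if (is.null(phenotypes)) phenotypes <- phenotype_names(clinical, "continuous")
  unknown <- setdiff(phenotypes, colnames(clinical$values))
  if (length(unknown))
    stop("unknown phenotype(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(phenotypes) < 2)
    stop("need at least two phenotypes", call. = FALSE)
  v <- clinical$values[, phenotypes, drop = FALSE]
  k <- length(phenotypes)
  pairs <- utils::combn(k, 2)
  np <- ncol(pairs)
  res <- data.frame(item_a = phenotypes[pairs[1, ]],
                    item_b = phenotypes[pairs[2, ]],
                    coefficient = NA_real_, p = NA_real_, q = NA_real_,
                    n_used = 0L, method = "spearman",
                    stringsAsFactors = FALSE)
  for (i in seq_len(np)) {
    st <- spearman_test(v[, pairs[1, i]], v[, pairs[2, i]])
    res$n_used[i] <- st$n
    if (st$n >= min_pairs) {
      res$coefficient[i] <- st$rho
      res$p[i] <- st$p
    }
  }
  res$q <- bh_adjust(res$p)
  res$significant <- !is.na(res$q) & res$q < alpha
  cm <- matrix(NA_real_, k, k, dimnames = list(phenotypes, phenotypes))
  mm <- matrix(FALSE, k, k, dimnames = list(phenotypes, phenotypes))
  diag(cm) <- 1
  for (i in seq_len(np)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    cm[a, b] <- cm[b, a] <- res$coefficient[i]
    mm[a, b] <- mm[b, a] <- res$significant[i]
  }
  structure(res, class = c("pheno_corr", "data.frame"),
            coef_matrix = cm, mask_matrix = mm, alpha = alpha)
}

#' @export
print.pheno_corr <- function(x, ...) {
  cat(sprintf("Spearman phenotype screen: %d pairs, %d tested, %d significant (q < %g)\n",
              nrow(x), sum(!is.na(x$p)), sum(x$significant),
              attr(x, "alpha")))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$q), , drop = FALSE]
    print.data.frame(utils::head(sig, 10), row.names = FALSE, digits = 3)
    if (nrow(sig) > 10) cat("...\n")
  }
  invisible(x)
}

#' Write a correlation screen: long table plus square matrices
#'
#' Writes `<prefix>_long.tsv` (item_a, item_b, coefficient, p, q, n_used),
#' `<prefix>_coef.tsv` (square coefficient matrix) and `<prefix>_mask.tsv`
#' (0/1 significance mask), suitable for external heatmap rendering.
#'
#' @param x a `pheno_corr`.
#' @param prefix output path prefix.
#' @return paths written, invisibly.
#' @export
write_correlation_screen <- function(x, prefix) {
  long_path <- paste0(prefix, "_long.tsv")
  utils::write.table(as.data.frame(x)[, c("item_a", "item_b", "coefficient",
                                          "p", "q", "n_used")],
                     long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- attr(x, "coef_matrix"); mm <- attr(x, "mask_matrix")
  coef_path <- paste0(prefix, "_coef.tsv")
  mask_path <- paste0(prefix, "_mask.tsv")
  utils::write.table(cbind(item = rownames(cm), as.data.frame(cm)), coef_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(item = rownames(mm), as.data.frame(mm + 0)),
                     mask_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(long_path, coef_path, mask_path))
}

#' Percentage summary of a count
#'
#' Formats `count` of `total` as a percentage rounded to `digits` decimals, the
#' presentation used in cohort characteristic tables (e.g. 59 of 109 is
#' 54.1\%).
#'
#' @param count,total non-negative counts, `count <= total`, `total > 0`.
#' @param digits decimals for the percentage (default 1).
#' @return list with `count`, `total`, `percent`.
#' @examples
#' count_percent(59, 109)$percent # 54.1
#' @export
count_percent <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0, count <= total)
  list(count = count, total = total,
       percent = round(100 * count / total, digits))
}

describe_values <- function(v) {
  v <- v[!is.na(v)]
  list(n = length(v), mean = mean(v), sd = stats::sd(v),
       median = stats::median(v), iqr = stats::IQR(v))
}

#' Compare a phenotype between two patient groups
#'
#' Continuous (measurement) phenotypes are compared with the two-sided
#' Mann-Whitney U test: the exact distribution when both groups have at most 8
#' non-missing values and no ties, otherwise the normal approximation with tie
#' correction. Binary (enumeration) phenotypes are compared with the Pearson
#' chi-squared test on the 2x2 table without continuity correction; Fisher's
#' exact test is additionally reported when any expected cell count is below 5.
#'
#' @param clinical a [clinical_table()].
#' @param group_a,group_b disjoint, non-empty character vectors of patient ids.
#' @param phenotype phenotype name.
#' @return an object of class `group_comparison`: list with `phenotype`,
#'   `test`, `statistic`, `p`, `group_summaries` and, for small-count binary
#'   phenotypes, `fisher_p`.
#' @export
compare_groups <- function(clinical, group_a, group_b, phenotype) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (!phenotype %in% colnames(clinical$values))
    stop("unknown phenotype: ", phenotype, call. = FALSE)
  if (!length(group_a) || !length(group_b))
    stop("groups must be non-empty", call. = FALSE)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint", call. = FALSE)
  unknown <- setdiff(c(group_a, group_b), patient_ids(clinical))
  if (length(unknown))
    stop("unknown patient id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  kind <- clinical$kinds[[phenotype]]
  xa <- clinical$values[group_a, phenotype]
  xb <- clinical$values[group_b, phenotype]
  if (all(is.na(xa)) || all(is.na(xb)))
    stop("phenotype '", phenotype, "' entirely missing in one group",
         call. = FALSE)
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (kind == "continuous") {
    ex <- length(xa) <= 8 && length(xb) <= 8 &&
      !anyDuplicated(c(xa, xb))
    wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = ex,
                                              correct = FALSE))
    out <- list(phenotype = phenotype, test = "mann_whitney",
                statistic = unname(wt$statistic), p = wt$p.value,
                group_summaries = list(a = describe_values(xa),
                                       b = describe_values(xb)))
  } else {
    tab <- rbind(c(sum(xa == 1), sum(xa == 0)),
                 c(sum(xb == 1), sum(xb == 0)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out <- list(phenotype = phenotype, test = "chi_squared",
                statistic = unname(ct$statistic), p = ct$p.value,
                group_summaries = list(
                  a = count_percent(sum(xa == 1), length(xa)),
                  b = count_percent(sum(xb == 1), length(xb))))
    if (any(ct$expected < 5)) {
      out$fisher_p <- stats::fisher.test(tab)$p.value
      out$test <- "chi_squared+fisher_exact"
    }
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g, p = %.4g\n", x$phenotype, x$test,
              x$statistic, x$p))
  if (!is.null(x$fisher_p)) cat(sprintf("  Fisher exact p = %.4g\n", x$fisher_p))
  invisible(x)
}

# Shared signed-rank machinery: differences with zeros dropped, tied absolute
# differences average-ranked; exact two-sided p for <= 25 nonzero untied
# differences, else normal approximation with tie correction.
signed_rank_test <- function(d, phenotype, test_name) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (!length(d))
    stop("all differences are zero: signed-rank test degenerate", call. = FALSE)
  ex <- length(d) <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = ex, correct = FALSE))
  structure(list(phenotype = phenotype, test = test_name,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 group_summaries = list(differences = describe_values(d))),
            class = "group_comparison")
}

#' One-sample Wilcoxon signed-rank test against a reference value
#'
#' Tests whether `values` are symmetric about `reference` (e.g. a population
#' normal reference for a clinical parameter). Zero differences are dropped;
#' the two-sided p-value is exact for up to 25 nonzero untied differences and
#' uses the tie-corrected normal approximation otherwise.
#'
#' @param values numeric vector (missing values dropped).
#' @param reference reference value.
#' @param phenotype optional label for the output.
#' @return a `group_comparison` (test `"wilcoxon_one_sample"`).
#' @export
one_sample_wilcoxon <- function(values, reference, phenotype = "") {
  signed_rank_test(values - reference, phenotype, "wilcoxon_one_sample")
}

#' Paired-sample Wilcoxon signed-rank test
#'
#' Tests paired differences `a - b` (e.g. tumor vs ANPT expression of one
#' gene); pairs with either member missing are dropped. Identical contract to
#' [one_sample_wilcoxon()] applied to the differences.
#'
#' @param a,b numeric vectors of equal length.
#' @param phenotype optional label for the output.
#' @return a `group_comparison` (test `"wilcoxon_paired"`).
#' @export
paired_wilcoxon <- function(a, b, phenotype = "") {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (!sum(ok)) stop("no usable pairs", call. = FALSE)
  signed_rank_test(a[ok] - b[ok], phenotype, "wilcoxon_paired")
}

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-((Ct_target_sample - Ct_ref_sample) - (Ct_target_calibrator -
#' Ct_ref_calibrator))`: qPCR relative quantification normalised to a reference
#' gene (e.g. GAPDH) and a calibrator sample.
#'
#' @param ct_target_sample,ct_ref_sample Ct values of target and reference
#'   gene in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the calibrator.
#' @return positive relative expression ratio.
#' @examples
#' ddct_relative_expression(10, 7, 12, 7) # sample dCt 3, calibrator dCt 5 -> 4
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator, ct_ref_calibrator) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_calibrator), is.finite(ct_ref_calibrator))
  dct_sample <- ct_target_sample - ct_ref_sample
  dct_cal <- ct_target_calibrator - ct_ref_calibrator
  2^(-(dct_sample - dct_cal))
}
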