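# The paired differential-index (DI) statistic.
#
# For each patient pair i the tumor/ANPT fold change is normalised to a 0-1
# value v_i = 1 - 1/fold_i, signed by the direction of change, and the DI is
# the average over the n pairs. |DI| maps back to a fold-change scale via the
# adjusted fold change FC = 1/(1 - |DI|), so DI = 0.6 corresponds to FC = 2.5.

#' Per-pair fold change and direction
#'
#' Normalises one tumor/control pair to a symmetric fold: with pseudocount `c`,
#' `r = (tumor + c)/(anpt + c)`, `fold = max(r, 1/r) >= 1`, and the sign is +1
#' for up-regulation in tumor, -1 for down, 0 for no change.
#'
#' @param tumor,anpt non-negative FPKM values (vectorised).
#' @param pseudocount non-negative value added to both members before the
#'   ratio; must be positive when both members can be zero.
#' @return list with numeric `fold` (>= 1, possibly `Inf`) and integer `sign`
#'   in \{-1, 0, 1\}.
#' @examples
#' pair_fold(25, 10, 0) # fold 2.5, sign +1
#' @export
pair_fold <- function(tumor, anpt, pseudocount = 0.1) {
  if (any(tumor < 0, na.rm = TRUE) || any(anpt < 0, na.rm = TRUE))
    stop("FPKM values must be non-negative", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be non-negative", call. = FALSE)
  t <- tumor + pseudocount
  a <- anpt + pseudocount
  if (any(t == 0 & a == 0))
    stop("fold change undefined: both pair members zero with pseudocount 0",
         call. = FALSE)
  r <- t / a
  fold <- pmax(r, 1 / r)
  list(fold = fold, sign = as.integer(sign(r - 1)))
}

#' Adjusted fold change from a differential index
#'
#' `FC = 1 / (1 - |DI|)`; the inverse of [di_from_fc()]. `DI = 0.6` maps to
#' `FC = 2.5`.
#'
#' @param di differential index, `|di| < 1` (vectorised).
#' @return adjusted fold change, `>= 1`.
#' @export
fc_from_di <- function(di) {
  if (any(abs(di) >= 1))
    stop("fc_from_di requires |di| < 1", call. = FALSE)
  1 / (1 - abs(di))
}

#' Differential index magnitude from a fold change
#'
#' `DI = 1 - 1/FC`; the inverse of [fc_from_di()] (`FC = 2.5` maps to 0.6).
#'
#' @param fc fold change, `>= 1` (vectorised).
#' @return DI magnitude in `[0, 1)`.
#' @export
di_from_fc <- function(fc) {
  if (any(fc < 1))
    stop("di_from_fc requires fc >= 1", call. = FALSE)
  1 - 1 / fc
}

#' Parameters of the differential-index analysis
#'
#' @param pseudocount added to both pair members before the ratio (FPKM units);
#'   default 0.1, which keeps zero-FPKM cells well defined.
#' @param mode `"signed"` (default) averages signed per-pair normalised values,
#'   so pairs changing in opposite directions cancel; `"literal"` averages
#'   unsigned values and affixes one overall sign (the sign of the summed
#'   log-ratios), which inflates |DI| when pair directions conflict.
#' @param di_threshold DE calls require `|DI|` strictly above this (default
#'   0.6, i.e. adjusted fold change > 2.5).
#' @param tau per-pair coverage threshold on the normalised fold `1 - 1/fold`
#'   (default 0.6, i.e. pair fold > 2.5).
#' @param min_coverage minimum number of covering pairs for a DE call; the
#'   default `"two_thirds"` resolves to `ceiling(2n/3)` (6 when n = 9).
#' @return a list of class `di_params`.
#' @export
di_params <- function(pseudocount = 0.1, mode = c("signed", "literal"),
                      di_threshold = 0.6, tau = 0.6,
                      min_coverage = "two_thirds") {
  mode <- match.arg(mode)
  stopifnot(pseudocount >= 0, di_threshold > 0, di_threshold < 1,
            tau > 0, tau < 1)
  if (!identical(min_coverage, "two_thirds")) {
    min_coverage <- as.integer(min_coverage)
    stopifnot(length(min_coverage) == 1, min_coverage >= 1)
  }
  structure(list(pseudocount = pseudocount, mode = mode,
                 di_threshold = di_threshold, tau = tau,
                 min_coverage = min_coverage),
            class = "di_params")
}

resolve_min_coverage <- function(params, n) {
  if (identical(params$min_coverage, "two_thirds")) as.integer(ceiling(2 * n / 3))
  else params$min_coverage
}

#' Fit the differential index over a paired cohort
#'
#' Computes, for every gene, the per-pair signed normalised fold changes
#' `v_i = sign_i * (1 - 1/fold_i)`, the differential index DI (their average;
#' see `mode` in [di_params()]), the adjusted fold change `1/(1 - |DI|)`, the
#' direction of change, and the coverage: the number of pairs whose direction
#' matches `sign(DI)` and whose normalised fold strictly exceeds `tau`. A gene
#' passes when `|DI|` strictly exceeds `di_threshold` and coverage reaches
#' `min_coverage`.
#'
#' @param expr expression matrix (genes x samples, FPKM scale).
#' @param design a [paired_design()]; all its sample ids must be columns of
#'   `expr`.
#' @param params a [di_params()] object.
#' @param genes optional subset of gene ids to fit (default: all).
#' @return an object of class `di_fit`: list with `results` (data.frame with
#'   columns `gene_id`, `di`, `adjusted_fc`, `direction`, `coverage`,
#'   `passed`), `v` (genes x pairs matrix of signed normalised values),
#'   `params`, `n_pairs`, `min_coverage`.
#' @examples
#' expr <- expression_matrix(matrix(c(40, 10), 1, 2,
#'   dimnames = list("G1", c("P1_T", "P1_N"))))
#' fit <- di_fit(expr, paired_design("P1", "P1_T", "P1_N"),
#'               di_params(pseudocount = 0))
#' coef(fit) # DI = 0.75
#' @export
di_fit <- function(expr, design, params = di_params(), genes = NULL) {
  validate_expression_matrix(expr)
  if (!inherits(design, "paired_design"))
    design <- paired_design(design$patient_id, design$tumor_id, design$anpt_id)
  missing_s <- setdiff(c(design$tumor_id, design$anpt_id), colnames(expr))
  if (length(missing_s))
    stop("design references unknown sample(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  if (is.null(genes)) genes <- rownames(expr)
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g))
    stop("unknown gene(s): ", paste(utils::head(missing_g, 5), collapse = ", "),
         call. = FALSE)
  n <- nrow(design)
  c0 <- params$pseudocount
  tmat <- expr[genes, design$tumor_id, drop = FALSE] + c0
  amat <- expr[genes, design$anpt_id, drop = FALSE] + c0
  if (any(tmat == 0 & amat == 0))
    stop("fold change undefined: zero pair with pseudocount 0; set pseudocount > 0",
         call. = FALSE)
  r <- tmat / amat
  fold <- pmax(r, 1 / r)
  s <- sign(r - 1)
  normfold <- 1 - 1 / fold          # in [0, 1]; 0 when fold == 1
  v <- s * normfold
  if (params$mode == "signed") {
    di <- rowMeans(v)
  } else {
    sigma <- sign(rowSums(log(r)))
    di <- sigma * rowMeans(abs(v))  # sigma 0 (exact balance) forces di = 0
  }
  di_sign <- sign(di)
  coverage <- as.integer(rowSums(s == di_sign & normfold > params$tau & s != 0))
  min_cov <- resolve_min_coverage(params, n)
  adjusted_fc <- 1 / (1 - abs(di))
  direction <- c("down", "none", "up")[di_sign + 2]
  passed <- abs(di) > params$di_threshold & coverage >= min_cov
  res <- data.frame(gene_id = genes, di = unname(di),
                    adjusted_fc = unname(adjusted_fc),
                    direction = direction, coverage = coverage,
                    passed = unname(passed),
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(v) <- design$patient_id
  structure(list(results = res, v = v, params = params, n_pairs = n,
                 min_coverage = min_cov),
            class = "di_fit")
}

#' @export
print.di_fit <- function(x, ...) {
  cat(sprintf("Differential-index fit: %d genes, %d pairs (mode %s, pseudocount %g)\n",
              nrow(x$results), x$n_pairs, x$params$mode, x$params$pseudocount))
  cat(sprintf("DE criteria: |DI| > %g (FC > %g) and coverage >= %d (tau = %g)\n",
              x$params$di_threshold, fc_from_di(x$params$di_threshold),
              x$min_coverage, x$params$tau))
  up <- sum(x$results$passed & x$results$direction == "up")
  dn <- sum(x$results$passed & x$results$direction == "down")
  cat(sprintf("Selected: %d genes (%d up, %d down)\n", up + dn, up, dn))
  invisible(x)
}

#' @export
summary.di_fit <- function(object, ...) {
  r <- object$results
  out <- list(n_genes = nrow(r), n_pairs = object$n_pairs,
              params = object$params, min_coverage = object$min_coverage,
              n_up = sum(r$passed & r$direction == "up"),
              n_down = sum(r$passed & r$direction == "down"),
              di_quantiles = stats::quantile(r$di, c(0, .25, .5, .75, 1)))
  class(out) <- "summary.di_fit"
  out
}

#' @export
print.summary.di_fit <- function(x, ...) {
  cat(sprintf("DI fit over %d genes, %d pairs\n", x$n_genes, x$n_pairs))
  cat(sprintf("DE genes: %d up, %d down (|DI| > %g, coverage >= %d)\n",
              x$n_up, x$n_down, x$params$di_threshold, x$min_coverage))
  cat("DI quantiles:\n"); print(round(x$di_quantiles, 4))
  invisible(x)
}

#' @export
coef.di_fit <- function(object, ...) {
  stats::setNames(object$results$di, object$results$gene_id)
}

#' @export
as.data.frame.di_fit <- function(x, ...) x$results

#' @export
plot.di_fit <- function(x, ...) {
  r <- x$results
  plot(r$di, r$coverage, xlab = "differential index",
       ylab = "coverage (pairs)", pch = 16, cex = 0.5,
       col = ifelse(r$passed, "firebrick", "grey50"), ...)
  graphics::abline(v = c(-1, 1) * x$params$di_threshold, lty = 2)
  graphics::abline(h = x$min_coverage - 0.5, lty = 3)
  invisible(x)
}

#' Select differentially expressed genes from a DI fit
#'
#' Applies the selection rule: up-regulated genes have
#' `di > di_threshold` and `coverage >= min_coverage`; down-regulated genes
#' mirror it with `di < -di_threshold`. Each list is sorted by `|di|`
#' descending, ties broken by gene id.
#'
#' @param fit a `di_fit` object (or its `results` data.frame plus `params`
#'   and `n_pairs`).
#' @return list with character vectors `up` and `down` (disjoint).
#' @export
select_de_genes <- function(fit) {
  stopifnot(inherits(fit, "di_fit"))
  r <- fit$results
  thr <- fit$params$di_threshold
  keep_up <- r$di > thr & r$coverage >= fit$min_coverage
  keep_dn <- r$di < -thr & r$coverage >= fit$min_coverage
  ord <- function(idx) {
    sub <- r[idx, , drop = FALSE]
    sub$gene_id[order(-abs(sub$di), sub$gene_id)]
  }
  list(up = ord(keep_up), down = ord(keep_dn))
}

#' Count genes expressed above thresholds
#'
#' For each threshold, counts genes whose maximum FPKM across samples strictly
#' exceeds it (e.g. the number of genes with FPKM > 0, FPKM > 1).
#'
#' @param expr expression matrix.
#' @param thresholds non-negative numeric vector.
#' @return named integer vector, one count per threshold (names `">t"`);
#'   counts are non-increasing in the threshold.
#' @export
expressed_gene_counts <- function(expr, thresholds) {
  stopifnot(all(thresholds >= 0))
  if (!length(thresholds))
    return(stats::setNames(integer(0), character(0)))
  mx <- apply(expr, 1, max)
  if (nrow(expr) == 0) mx <- numeric(0)
  stats::setNames(vapply(thresholds, function(t) sum(mx > t), 0L),
                  paste0(">", thresholds))
}

#' Write a DI fit as annotated TSV
#'
#' Metadata header lines (prefixed `#`) record mode, pseudocount, thresholds
#' and the number of pairs, followed by the per-gene results table.
#'
#' @param fit a `di_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_di_results <- function(fit, path) {
  stopifnot(inherits(fit, "di_fit"))
  con <- file(path, "w"); on.exit(close(con))
  p <- fit$params
  writeLines(c(sprintf("# mode=%s", p$mode),
               sprintf("# pseudocount=%g", p$pseudocount),
               sprintf("# di_threshold=%g", p$di_threshold),
               sprintf("# tau=%g", p$tau),
               sprintf("# min_coverage=%d", fit$min_coverage),
               sprintf("# n_pairs=%d", fit$n_pairs)), con)
  utils::write.table(fit$results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
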