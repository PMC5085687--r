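# Gene-expression vs clinical-phenotype Pearson association screen: the
# phenotype-genotype link. Per-patient expression summaries are correlated
# against clinical parameters (BMD Z-scores, hormones) and genes with at least
# one significant phenotype are selected.

#' Parameters of the association screen
#'
#' @param expression_transform per-patient expression summary entering the
#'   correlation: `"log2_tumor"` (default) uses `log2(tumor FPKM + c)`;
#'   `"log2_fold"` uses `log2((tumor + c)/(anpt + c))`.
#' @param pseudocount `c` above (default 0.1 FPKM).
#' @param alpha significance level (default 0.05).
#' @param adjust `"bh"` (default) applies Benjamini-Hochberg over the whole
#'   gene x phenotype family and selects on q; `"none"` selects on raw p.
#' @param min_pairs minimum pairwise-complete patients per test (default 3).
#' @return a list of class `assoc_params`.
#' @export
assoc_params <- function(expression_transform = c("log2_tumor", "log2_fold"),
                         pseudocount = 0.1, alpha = 0.05,
                         adjust = c("bh", "none"), min_pairs = 3) {
  expression_transform <- match.arg(expression_transform)
  adjust <- match.arg(adjust)
  stopifnot(pseudocount >= 0, alpha > 0, alpha < 1, min_pairs >= 3)
  structure(list(expression_transform = expression_transform,
                 pseudocount = pseudocount, alpha = alpha, adjust = adjust,
                 min_pairs = min_pairs),
            class = "assoc_params")
}

#' Per-patient gene-expression values for the association screen
#'
#' @param expr expression matrix.
#' @param design a [paired_design()].
#' @param genes gene ids to extract.
#' @param params an [assoc_params()] (controls transform and pseudocount).
#' @return numeric matrix, patients x genes.
#' @export
patient_gene_values <- function(expr, design, genes, params = assoc_params()) {
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g))
    stop("unknown gene(s): ", paste(utils::head(missing_g, 5), collapse = ", "),
         call. = FALSE)
  c0 <- params$pseudocount
  tmat <- t(expr[genes, design$tumor_id, drop = FALSE]) + c0
  rownames(tmat) <- design$patient_id
  if (params$expression_transform == "log2_tumor") {
    out <- log2(tmat)
  } else {
    amat <- t(expr[genes, design$anpt_id, drop = FALSE]) + c0
    out <- log2(tmat / amat)
  }
  colnames(out) <- genes
  out
}

#' Pearson association screen of genes against phenotypes
#'
#' For every (gene, phenotype) combination computes Pearson's r on
#' pairwise-complete patients and a two-sided p-value from the t transform
#' with `n_used - 2` degrees of freedom. Tests with zero variance in either
#' vector are flagged undefined (not an error) and excluded, with tests on
#' fewer than `min_pairs` patients, from the single Benjamini-Hochberg family
#' spanning all gene x phenotype tests.
#'
#' @param values patients x genes matrix from [patient_gene_values()].
#' @param clinical a [clinical_table()] whose patients match the rows of
#'   `values`.
#' @param phenotypes phenotype names to test against.
#' @param params an [assoc_params()].
#' @return object of class `gene_pheno_assoc`: data.frame with columns
#'   `gene_id`, `phenotype`, `coefficient`, `p`, `q`, `n_used`, `method`,
#'   `undefined`; attribute `params`.
#' @export
pearson_assoc <- function(values, clinical, phenotypes,
                          params = assoc_params()) {
  stopifnot(inherits(clinical, "clinical_table"))
  unknown <- setdiff(phenotypes, colnames(clinical$values))
  if (length(unknown))
    stop("unknown phenotype(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  common <- intersect(rownames(values), patient_ids(clinical))
  if (!length(common))
    stop("no patients shared between expression values and clinical table",
         call. = FALSE)
  values <- values[common, , drop = FALSE]
  genes <- colnames(values)
  res <- vector("list", length(phenotypes))
  for (j in seq_along(phenotypes)) {
    ph <- phenotypes[j]
    y <- clinical$values[common, ph]
    block <- data.frame(gene_id = genes, phenotype = ph,
                        coefficient = NA_real_, p = NA_real_,
                        n_used = 0L, undefined = FALSE,
                        stringsAsFactors = FALSE)
    for (i in seq_along(genes)) {
      x <- values[, i]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      block$n_used[i] <- n
      if (n < params$min_pairs) next
      xs <- x[ok]; ys <- y[ok]
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
        block$undefined[i] <- TRUE
        next
      }
      r <- stats::cor(xs, ys)
      block$coefficient[i] <- r
      r <- max(min(r, 1), -1)
      if (abs(r) == 1) {
        block$p[i] <- 0
      } else {
        tval <- r * sqrt((n - 2) / (1 - r^2))
        block$p[i] <- 2 * stats::pt(-abs(tval), df = n - 2)
      }
    }
    res[[j]] <- block
  }
  res <- do.call(rbind, res)
  res$q <- if (params$adjust == "bh") bh_adjust(res$p) else rep(NA_real_, nrow(res))
  res$method <- "pearson"
  res <- res[, c("gene_id", "phenotype", "coefficient", "p", "q", "n_used",
                 "method", "undefined")]
  structure(res, class = c("gene_pheno_assoc", "data.frame"), params = params)
}

#' @export
print.gene_pheno_assoc <- function(x, ...) {
  params <- attr(x, "params")
  sig <- significant_assoc_rows(x, params)
  cat(sprintf("Pearson gene-phenotype screen: %d tests (%d genes x %d phenotypes)\n",
              nrow(x), length(unique(x$gene_id)), length(unique(x$phenotype))))
  cat(sprintf("  significant (%s < %g): %d tests, %d genes\n",
              if (params$adjust == "bh") "q" else "p", params$alpha,
              sum(sig), length(unique(x$gene_id[sig]))))
  invisible(x)
}

significant_assoc_rows <- function(x, params) {
  crit <- if (params$adjust == "bh") x$q else x$p
  !is.na(crit) & crit < params$alpha & !x$undefined
}

#' Select genes associated with at least one phenotype
#'
#' A gene is selected when at least one tested phenotype meets the
#' significance rule (`q < alpha` under BH adjustment, else `p < alpha`).
#' The list is sorted by each gene's best q (or p) ascending, ties broken by
#' gene id.
#'
#' @param assoc a `gene_pheno_assoc` from [pearson_assoc()].
#' @return character vector of gene ids.
#' @export
select_associated_genes <- function(assoc) {
  stopifnot(inherits(assoc, "gene_pheno_assoc"))
  params <- attr(assoc, "params")
  sig <- significant_assoc_rows(assoc, params)
  if (!any(sig)) return(character())
  crit <- if (params$adjust == "bh") assoc$q else assoc$p
  best <- tapply(crit[sig], assoc$gene_id[sig], min)
  names(best)[order(unname(best), names(best))]
}

#' Write an association screen as TSV
#' @param assoc a `gene_pheno_assoc`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assoc_results <- function(assoc, path) {
  utils::write.table(as.data.frame(assoc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
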