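#' Construct and validate an FPKM-scale expression matrix
#'
#' The expression container is a plain numeric matrix with gene identifiers as
#' row names and sample identifiers as column names. Values are on the FPKM
#' scale and must be non-negative and dense: FPKM is defined for every gene in
#' every sample, so missing cells are not allowed.
#'
#' @param values numeric matrix (genes x samples), or an object coercible to one.
#' @param gene_ids,sample_ids optional identifier vectors overriding the dimnames.
#' @return the validated numeric matrix, with dimnames set.
#' @examples
#' m <- expression_matrix(matrix(c(1, 2, 0, 4.5), 2,
#'   dimnames = list(c("G1", "G2"), c("S1", "S2"))))
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  validate_expression_matrix(values)
  values
}

validate_expression_matrix <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene (row) and sample (column) identifiers",
         call. = FALSE)
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "), call. = FALSE)
  bad <- which(is.na(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("missing or negative expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  }
  invisible(values)
}

#' Construct a paired tumor/control design
#'
#' Maps each patient to one tumor sample and one adjacent-nontumorous (ANPT)
#' control sample. The pairing defines the index set of the differential-index
#' statistic: `n` in the DI average is the number of pairs.
#'
#' @param patient_id,tumor_id,anpt_id character vectors of equal length.
#' @return a data.frame of class `paired_design` with columns
#'   `patient_id`, `tumor_id`, `anpt_id`.
#' @examples
#' paired_design(c("P1", "P2"), c("P1_T", "P2_T"), c("P1_N", "P2_N"))
#' @export
paired_design <- function(patient_id, tumor_id, anpt_id) {
  d <- data.frame(patient_id = as.character(patient_id),
                  tumor_id = as.character(tumor_id),
                  anpt_id = as.character(anpt_id),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$patient_id))
    stop("duplicate patient identifier in design", call. = FALSE)
  if (any(d$tumor_id == d$anpt_id))
    stop("tumor and ANPT sample must differ within a pair", call. = FALSE)
  samples <- c(d$tumor_id, d$anpt_id)
  if (anyDuplicated(samples))
    stop("sample identifier appears in more than one role or pair: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  class(d) <- c("paired_design", "data.frame")
  d
}

#' Construct a clinical characteristics table
#'
#' Patients by phenotypes, numeric with missing values allowed. Each phenotype
#' carries a kind tag: `"continuous"` (measurement data) or `"binary"`
#' (enumeration data coded 0/1). An optional per-patient group label (e.g.
#' training/validation) may be attached.
#'
#' @param values numeric matrix or data.frame, patients as rows (rownames =
#'   patient ids), phenotypes as columns.
#' @param kinds named character vector mapping phenotype names to
#'   `"continuous"` or `"binary"`; unnamed phenotypes default to continuous.
#' @param group optional character vector of per-patient labels, one per row.
#' @return an object of class `clinical_table`: a list with elements
#'   `values`, `kinds`, `group`.
#' @export
clinical_table <- function(values, kinds = NULL, group = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("clinical table requires patient (row) and phenotype (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate patient identifier: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate phenotype name: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  k <- rep("continuous", ncol(values))
  names(k) <- colnames(values)
  if (!is.null(kinds)) {
    unknown <- setdiff(names(kinds), colnames(values))
    if (length(unknown))
      stop("kind declared for unknown phenotype: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    bad <- setdiff(kinds, c("continuous", "binary"))
    if (length(bad)) stop("unknown phenotype kind: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    k[names(kinds)] <- kinds
  }
  for (ph in names(k)[k == "binary"]) {
    v <- values[, ph]
    if (any(!is.na(v) & !(v %in% c(0, 1))))
      stop(sprintf("binary phenotype '%s' contains values outside {0, 1}", ph),
           call. = FALSE)
  }
  if (!is.null(group)) {
    if (length(group) != nrow(values))
      stop("group labels must have one entry per patient", call. = FALSE)
    group <- as.character(group)
    names(group) <- rownames(values)
  }
  structure(list(values = values, kinds = k, group = group),
            class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("clinical_table: %d patients x %d phenotypes (%d binary)\n",
              nrow(x$values), ncol(x$values), sum(x$kinds == "binary")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Patient identifiers of a clinical table
#' @param x a `clinical_table`.
#' @return character vector of patient ids.
#' @export
patient_ids <- function(x) rownames(x$values)

#' Phenotype names of a clinical table
#' @param x a `clinical_table`.
#' @param kind optional filter, `"continuous"` or `"binary"`.
#' @return character vector of phenotype names.
#' @export
phenotype_names <- function(x, kind = NULL) {
  nm <- colnames(x$values)
  if (!is.null(kind)) nm <- nm[x$kinds[nm] == kind]
  nm
}

#' Construct an undirected protein-interaction graph
#'
#' Edges are unordered pairs of distinct gene identifiers; self-loops are
#' dropped (the analysis concerns between-gene connectivity) and duplicate
#' edges under either orientation are collapsed.
#'
#' @param edges two-column character matrix or data.frame of endpoints;
#'   may be empty.
#' @param nodes optional additional isolated nodes to include.
#' @return an object of class `interaction_graph`: list with `nodes`
#'   (character) and `edges` (two-column character matrix, canonically ordered
#'   within and across rows).
#' @export
interaction_graph <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(), 0, 2, dimnames = list(NULL, c("a", "b")))
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2) stop("edges must have two columns", call. = FALSE)
    storage.mode(em) <- "character"
    em <- em[em[, 1] != em[, 2], , drop = FALSE]          # drop self-loops
    a <- pmin(em[, 1], em[, 2]); b <- pmax(em[, 1], em[, 2])
    em <- unique(cbind(a = unname(a), b = unname(b)))
    em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
    dimnames(em) <- list(NULL, c("a", "b"))
  }
  nodes <- sort(unique(c(as.character(nodes), as.vector(em))))
  structure(list(nodes = nodes, edges = em), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene identifiers; genes are
#'   deduplicated within each set preserving first occurrence.
#' @param descriptions optional character vector of per-set descriptions.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %s\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)
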