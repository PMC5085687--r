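# Readers and writers for the external text formats: TSV expression matrix,
# CSV/TSV clinical table (+ optional kinds sidecar), 2-column edge list, GMT.

#' Read an FPKM expression matrix from tab-delimited text
#'
#' Expected layout: header row of sample identifiers with first column header
#' `gene_id`, one row per gene. Cells must be non-negative numbers; missing
#' cells are not allowed (FPKM is defined for every gene).
#'
#' @param path file path.
#' @return validated expression matrix (see [expression_matrix()]),
#'   row/column order as in the file.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty expression file: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  samples <- trimws(header[-1])
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  genes <- character(length(rows))
  vals <- matrix(NA_real_, length(rows), length(samples))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != length(header))
      stop(sprintf("line %d has %d fields, expected %d", i + 1L, length(f),
                   length(header)), call. = FALSE)
    genes[i] <- trimws(f[1])
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                   genes[i], samples[bad[1]]), call. = FALSE)
    neg <- which(v < 0)
    if (length(neg))
      stop(sprintf("negative value %g at gene '%s', sample '%s'",
                   v[neg[1]], genes[i], samples[neg[1]]), call. = FALSE)
    vals[i, ] <- v
  }
  expression_matrix(vals, gene_ids = genes, sample_ids = samples)
}

#' Write an expression matrix as tab-delimited text
#' @param x expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(v) paste(format(v, trim = TRUE, digits = 15,
                                               scientific = FALSE),
                                        collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a paired design table
#'
#' Tab-delimited with header `patient_id`, `tumor_id`, `anpt_id`.
#' @param path file path.
#' @return a [paired_design()].
#' @export
read_paired_design <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  need <- c("patient_id", "tumor_id", "anpt_id")
  if (!all(need %in% names(d)))
    stop("design file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  paired_design(trimws(d$patient_id), trimws(d$tumor_id), trimws(d$anpt_id))
}

#' Write a paired design table
#' @param design a `paired_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_paired_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical characteristics table
#'
#' Patients as rows, phenotypes as columns; first column header `patient_id`.
#' The delimiter (comma or tab) is sniffed from the header line. `missing_token`
#' cells and empty cells become missing. An optional sidecar declares phenotype
#' kinds (two tab-separated columns: phenotype name, `continuous`/`binary`);
#' undeclared phenotypes are continuous. A column named `group` (if present) is
#' taken as the per-patient group label, not a phenotype.
#'
#' @param path file path.
#' @param kinds_path optional path to the kinds sidecar.
#' @param missing_token token marking missing cells (default `"NA"`).
#' @return a [clinical_table()].
#' @export
read_clinical_table <- function(path, kinds_path = NULL, missing_token = "NA") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                         colClasses = "character", na.strings = character())
  if (names(d)[1] != "patient_id")
    stop("first column must be 'patient_id'", call. = FALSE)
  pid <- trimws(d[[1]])
  if (anyDuplicated(pid))
    stop("duplicate patient identifier: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  d <- d[, -1, drop = FALSE]
  group <- NULL
  if ("group" %in% names(d)) {
    group <- trimws(d[["group"]])
    d <- d[, names(d) != "group", drop = FALSE]
  }
  vals <- matrix(NA_real_, nrow = length(pid), ncol = ncol(d),
                 dimnames = list(pid, names(d)))
  for (j in seq_len(ncol(d))) {
    cell <- trimws(d[[j]])
    miss <- cell == missing_token | cell == ""
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at patient '%s', phenotype '%s'",
                   cell[bad[1]], pid[bad[1]], names(d)[j]), call. = FALSE)
    v[miss] <- NA_real_
    vals[, j] <- v
  }
  kinds <- NULL
  if (!is.null(kinds_path)) {
    ks <- utils::read.delim(kinds_path, header = FALSE, colClasses = "character")
    kinds <- stats::setNames(trimws(ks[[2]]), trimws(ks[[1]]))
  }
  clinical_table(vals, kinds = kinds, group = group)
}

#' Write a clinical table (CSV) and optionally its kinds sidecar
#' @param x a `clinical_table`.
#' @param path output CSV path.
#' @param kinds_path optional path for the kinds sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(x, path, kinds_path = NULL) {
  d <- as.data.frame(x$values, check.names = FALSE)
  out <- cbind(patient_id = rownames(x$values), d)
  if (!is.null(x$group)) out$group <- x$group
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(kinds_path))
    utils::write.table(data.frame(names(x$kinds), unname(x$kinds)), kinds_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Two whitespace- or tab-delimited fields per line, one edge per line.
#' Self-loops are dropped (their count is reported via a message) and duplicate
#' edges in either orientation are collapsed.
#'
#' @param path file path.
#' @return an [interaction_graph()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(interaction_graph())
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 2))
    stop(sprintf("line %d has %d fields, expected 2", which(nf != 2)[1],
                 nf[nf != 2][1]), call. = FALSE)
  em <- do.call(rbind, parts)
  loops <- sum(em[, 1] == em[, 2])
  if (loops > 0)
    message(sprintf("read_edge_list: dropped %d self-loop(s)", loops))
  g <- interaction_graph(em)
  # self-loop endpoints stay as isolated nodes
  interaction_graph(g$edges, nodes = unique(c(g$nodes, as.vector(em))))
}

#' Write an interaction graph as a 2-column edge list
#'
#' Isolated nodes have no representation in an edge list and are not written.
#' @param graph an `interaction_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(graph$edges))
    writeLines(paste(graph$edges[, 1], graph$edges[, 2], sep = "\t"), con)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Tab-separated: set name, description, then one or more genes. Genes are
#' deduplicated within a set preserving first occurrence.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("GMT line %d has %d fields; need name, description and >=1 gene",
                 which(nf < 3)[1], nf[nf < 3][1]), call. = FALSE)
  nms <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  sets <- lapply(parts, function(f) trimws(f[-(1:2)]))
  names(sets) <- nms
  gene_set_collection(sets, vapply(parts, `[[`, "", 2))
}

#' Write a gene-set collection in GMT format
#' @param x a `gene_set_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(x$sets))
    writeLines(paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t"),
               con)
  invisible(path)
}

#' Read / write a plain gene list (one identifier per line)
#' @param path file path.
#' @return character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines)]
}

#' @rdname read_gene_list
#' @param genes character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
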