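# Shared fixture builders. Everything is generated in code; no data files.

# paired expression fixture: one row per gene, columns interleaved T/N
make_paired_expr <- function(tumor, anpt, genes = NULL) {
  tumor <- as.matrix(tumor); anpt <- as.matrix(anpt)
  n <- ncol(tumor)
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(nrow(tumor)))
  patients <- sprintf("P%d", seq_len(n))
  vals <- cbind(tumor, anpt)
  colnames(vals) <- c(paste0(patients, "_T"), paste0(patients, "_N"))
  rownames(vals) <- genes
  list(expr = expression_matrix(vals),
       design = paired_design(patients, paste0(patients, "_T"),
                              paste0(patients, "_N")))
}

# brute-force DI via pair_fold composition (the independent oracle)
brute_di <- function(tumor, anpt, pseudocount) {
  v <- vapply(seq_along(tumor), function(i) {
    pf <- pair_fold(tumor[i], anpt[i], pseudocount)
    pf$sign * (1 - 1 / pf$fold)
  }, 0)
  mean(v)
}

# brute-force BH: for each p, scan all prefixes of the sorted scale
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)          # rank of p[i]
    cand <- vapply(r:m, function(j) m * p[o[j]] / j, 0)
    q[i] <- min(1, min(cand))
  }
  q
}

# brute-force connected components by transitive closure over an edge matrix
brute_components <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      if (comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

random_graph_edges <- function(n_nodes, n_edges) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  if (n_edges == 0) return(list(nodes = nodes,
                                edges = matrix(character(), 0, 2)))
  a <- sample(nodes, n_edges, replace = TRUE)
  b <- sample(nodes, n_edges, replace = TRUE)
  keep <- a != b
  list(nodes = nodes, edges = cbind(a[keep], b[keep]))
}

small_clinical <- function() {
  set.seed(11)
  v <- cbind(height = rnorm(12, 160, 5), weight = rnorm(12, 60, 8),
             glucose = rnorm(12, 5, 1), diabetes = rep(c(0, 1), 6))
  rownames(v) <- sprintf("P%02d", 1:12)
  clinical_table(v, kinds = c(diabetes = "binary"),
                 group = rep(c("a", "b"), each = 6))
}
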