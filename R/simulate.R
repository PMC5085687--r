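# Seeded synthetic-cohort generators. They emulate the data structure the
# analysis assumes: a small paired tumor/ANPT FPKM matrix with a minority of
# planted fold-change genes, a clinical table whose hormone and bone-density
# phenotypes carry a planted correlation structure, a latent-factor link
# between bone-density Z-scores and a subset of DE genes, and a PPI edge list
# with one planted connected cluster. Every generator is deterministic given
# (seed, config) and returns its ground truth alongside the data.

#' Configuration of the synthetic cohort generators
#'
#' Defaults reproduce the study conditions the pipeline is designed for: nine
#' paired female tumor/ANPT profiles, a 118-patient clinical table with 35
#' characteristics including ten BMD Z-scores, a minority of genes
#' differentially expressed at fold 4, and lognormal FPKM noise.
#'
#' @param seed integer RNG seed.
#' @param n_pairs number of tumor/ANPT pairs in the expression cohort
#'   (default 9).
#' @param n_patients number of patients in the clinical table (default 118).
#' @param n_genes number of genes (default 2000).
#' @param frac_de fraction of genes planted as differentially expressed
#'   (default 0.05).
#' @param de_fold planted fold change of DE genes (default 4).
#' @param noise_sd lognormal noise SD on the log2 scale (default 0.5).
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline abundance
#'   distribution on the log2 FPKM scale (defaults 3 and 2: median FPKM 8 with
#'   a wide dynamic range).
#' @param n_phenotypes number of clinical phenotypes (default 35; must cover
#'   the named hormone/size phenotypes plus `n_bmd` Z-scores).
#' @param n_bmd number of BMD Z-score phenotypes (default 10).
#' @param planted_pheno_corr optional data.frame (`item_a`, `item_b`,
#'   `target`) of pairwise phenotype correlation targets; unlisted pairs are
#'   zero. Default `NULL` uses a latent factor model (severity, bone, gonadal
#'   factors) that yields positive tumor-size/ACTH/cortisol correlations,
#'   negative tumor-size/BMD correlations and positive LH/E2/lumbar-BMD
#'   correlations, and is positive semidefinite by construction.
#' @param missing_rate MCAR missingness rate in the clinical table
#'   (default 0.1).
#' @param bmd_gene_loading latent-factor loading tying BMD Z-scores to linked
#'   gene expression (default 0.8).
#' @param ppi_background_edge_prob Erdos-Renyi background edge probability of
#'   the synthetic PPI (default 0.001).
#' @param planted_cluster_size size of the planted connected PPI cluster
#'   (default 20).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pairs = 9L, n_patients = 118L,
                       n_genes = 2000L, frac_de = 0.05, de_fold = 4,
                       noise_sd = 0.5, baseline_log2_mean = 3,
                       baseline_log2_sd = 2, n_phenotypes = 35L,
                       n_bmd = 10L, planted_pheno_corr = NULL,
                       missing_rate = 0.1, bmd_gene_loading = 0.8,
                       ppi_background_edge_prob = 0.001,
                       planted_cluster_size = 20L) {
  stopifnot(frac_de > 0, frac_de < 1, de_fold > 1, noise_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            ppi_background_edge_prob >= 0, ppi_background_edge_prob <= 1,
            n_pairs >= 1, n_genes >= 1, n_bmd >= 1)
  if (abs(bmd_gene_loading) >= 1)
    stop("bmd_gene_loading must lie in (-1, 1)", call. = FALSE)
  if (round(frac_de * n_genes) < 1)
    stop("degenerate config: frac_de * n_genes < 1", call. = FALSE)
  structure(list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes), frac_de = frac_de,
                 de_fold = de_fold, noise_sd = noise_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 n_phenotypes = as.integer(n_phenotypes),
                 n_bmd = as.integer(n_bmd),
                 planted_pheno_corr = planted_pheno_corr,
                 missing_rate = missing_rate,
                 bmd_gene_loading = bmd_gene_loading,
                 ppi_background_edge_prob = ppi_background_edge_prob,
                 planted_cluster_size = as.integer(planted_cluster_size)),
            class = "sim_config")
}

bmd_phenotype_names <- function(n_bmd) {
  base <- c("BMD_Z_L1", "BMD_Z_L2", "BMD_Z_L3", "BMD_Z_L4", "BMD_Z_L1_2",
            "BMD_Z_L1_4", "BMD_Z_L2_4", "BMD_Z_femoral_neck",
            "BMD_Z_trochanter", "BMD_Z_total_hip")
  if (n_bmd <= length(base)) base[seq_len(n_bmd)]
  else c(base, sprintf("BMD_Z_extra_%02d", seq_len(n_bmd - length(base))))
}

sim_phenotype_names <- function(config) {
  core <- c("tumor_size", "ACTH", "cortisol", "LH", "E2",
            bmd_phenotype_names(config$n_bmd))
  n_extra <- config$n_phenotypes - length(core)
  if (n_extra < 0)
    stop("n_phenotypes must be at least ", length(core),
         " to hold the named hormone and BMD phenotypes", call. = FALSE)
  c(core, sprintf("marker_%02d", seq_len(n_extra)))
}

# Latent-factor loadings for the default phenotype correlation structure.
# Columns: disease severity, shared bone density, gonadal axis.
default_phenotype_loadings <- function(phenos, n_bmd) {
  bmd <- bmd_phenotype_names(n_bmd)
  lumbar <- bmd[grepl("_L", bmd, fixed = TRUE)]
  L <- matrix(0, length(phenos), 3,
              dimnames = list(phenos, c("severity", "bone", "gonadal")))
  L[c("tumor_size", "ACTH", "cortisol"), "severity"] <- 0.7
  L[c("LH", "E2"), "severity"] <- -0.4
  L[bmd, "severity"] <- -0.55
  L[bmd, "bone"] <- 0.55
  L[c("LH", "E2"), "gonadal"] <- 0.6
  L[lumbar, "gonadal"] <- 0.25
  L
}

# Build the target phenotype correlation matrix, erroring on non-PSD explicit
# targets (naming an offending triple when one can be isolated).
phenotype_corr_matrix <- function(config, phenos) {
  k <- length(phenos)
  if (is.null(config$planted_pheno_corr)) {
    L <- default_phenotype_loadings(phenos, config$n_bmd)
    C <- L %*% t(L)
    diag(C) <- 1
    return(C)
  }
  tgt <- config$planted_pheno_corr
  stopifnot(all(c("item_a", "item_b", "target") %in% names(tgt)))
  unknown <- setdiff(c(tgt$item_a, tgt$item_b), phenos)
  if (length(unknown))
    stop("planted correlation names unknown phenotype(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  build <- function(rows) {
    C <- diag(k); dimnames(C) <- list(phenos, phenos)
    for (i in seq_len(nrow(rows))) {
      a <- rows$item_a[i]; b <- rows$item_b[i]
      C[a, b] <- C[b, a] <- rows$target[i]
    }
    C
  }
  is_psd <- function(C) min(eigen(C, symmetric = TRUE,
                                  only.values = TRUE)$values) > -1e-8
  C <- build(tgt)
  if (!is_psd(C)) {
    for (i in seq_len(nrow(tgt))) {
      if (is_psd(build(tgt[-i, , drop = FALSE])))
        stop(sprintf(
          "planted correlation targets are not positive semidefinite; offending triple: (%s, %s, %g)",
          tgt$item_a[i], tgt$item_b[i], tgt$target[i]), call. = FALSE)
    }
    stop("planted correlation targets are not positive semidefinite",
         call. = FALSE)
  }
  C
}

corr_pair_table <- function(C) {
  idx <- which(upper.tri(C) & abs(C) > 1e-12, arr.ind = TRUE)
  data.frame(item_a = rownames(C)[idx[, 1]], item_b = colnames(C)[idx[, 2]],
             target = C[idx], stringsAsFactors = FALSE)
}

# Plausible marginal units per phenotype (mean, sd).
phenotype_marginals <- function(phenos) {
  m <- matrix(c(0, 1), length(phenos), 2, byrow = TRUE,
              dimnames = list(phenos, c("mean", "sd")))
  known <- list(tumor_size = c(8.4, 7.2), ACTH = c(85.1, 59.2),
                cortisol = c(34.4, 11.5), LH = c(5, 3), E2 = c(40, 25))
  for (nm in intersect(names(known), phenos)) m[nm, ] <- known[[nm]]
  m[grepl("^BMD_Z", phenos), ] <- rep(c(-1.3, 1.1),
                                      each = sum(grepl("^BMD_Z", phenos)))
  m
}

new_truth <- function(de_genes = NULL, bmd_linked_genes = character(),
                      phenotype_corr_targets = NULL,
                      planted_cluster = character()) {
  structure(list(de_genes = de_genes, bmd_linked_genes = bmd_linked_genes,
                 phenotype_corr_targets = phenotype_corr_targets,
                 planted_cluster = planted_cluster),
            class = "synthetic_truth")
}

#' Simulate a paired tumor/ANPT FPKM expression cohort
#'
#' Per gene, a baseline log2 abundance is drawn from
#' `N(baseline_log2_mean, baseline_log2_sd)`; ANPT values are
#' `2^(baseline + N(0, noise_sd))` and tumor values multiply the baseline by
#' the planted fold (up: x `de_fold`, down: / `de_fold`) for DE genes before
#' the same noise. `round(frac_de * n_genes)` genes are planted, half up and
#' half down (remainder to up).
#'
#' @param config a [sim_config()].
#' @return list with `expr` (expression matrix), `design`
#'   ([paired_design()]) and `truth` (with `de_genes`: data.frame `gene_id`,
#'   `direction`, `fold`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_g <- config$n_genes; n_p <- config$n_pairs
  genes <- sprintf("g%05d", seq_len(n_g))
  patients <- sprintf("P%03d", seq_len(n_p))
  design <- paired_design(patients, paste0(patients, "_T"),
                          paste0(patients, "_N"))
  n_de <- round(config$frac_de * n_g)
  n_up <- ceiling(n_de / 2)
  de_idx <- sample.int(n_g, n_de)
  dir_vec <- rep(0, n_g)
  dir_vec[de_idx[seq_len(n_up)]] <- 1
  if (n_de > n_up) dir_vec[de_idx[(n_up + 1):n_de]] <- -1
  baseline <- stats::rnorm(n_g, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  shift <- dir_vec * log2(config$de_fold)
  anpt_log2 <- baseline + matrix(stats::rnorm(n_g * n_p, 0, config$noise_sd),
                                 n_g, n_p)
  tumor_log2 <- (baseline + shift) +
    matrix(stats::rnorm(n_g * n_p, 0, config$noise_sd), n_g, n_p)
  vals <- cbind(2^tumor_log2, 2^anpt_log2)
  colnames(vals) <- c(design$tumor_id, design$anpt_id)
  rownames(vals) <- genes
  expr <- expression_matrix(vals[, c(rbind(design$tumor_id, design$anpt_id))])
  de_genes <- data.frame(gene_id = genes[de_idx],
                         direction = ifelse(dir_vec[de_idx] > 0, "up", "down"),
                         fold = config$de_fold, stringsAsFactors = FALSE)
  de_genes <- de_genes[order(de_genes$gene_id), ]
  rownames(de_genes) <- NULL
  list(expr = expr, design = design, truth = new_truth(de_genes = de_genes))
}

#' Simulate a clinical characteristics table
#'
#' Phenotypes are drawn from a multivariate Gaussian whose correlation matrix
#' embeds the planted targets (see [sim_config()]), rescaled marginally to
#' plausible clinical units, with missingness applied completely at random.
#'
#' @param config a [sim_config()].
#' @return list with `clinical` (a [clinical_table()]) and `truth` (with
#'   `phenotype_corr_targets`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phenos <- sim_phenotype_names(config)
  C <- phenotype_corr_matrix(config, phenos)
  set.seed(config$seed + 1L)
  n <- config$n_patients
  k <- length(phenos)
  eg <- eigen(C, symmetric = TRUE)
  Lr <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), k)
  X <- matrix(stats::rnorm(n * k), n, k) %*% t(Lr)
  marg <- phenotype_marginals(phenos)
  X <- sweep(sweep(X, 2, marg[, "sd"], "*"), 2, marg[, "mean"], "+")
  dimnames(X) <- list(sprintf("P%03d", seq_len(n)), phenos)
  if (config$missing_rate > 0)
    X[matrix(stats::runif(n * k) < config$missing_rate, n, k)] <- NA_real_
  list(clinical = clinical_table(X),
       truth = new_truth(phenotype_corr_targets = corr_pair_table(C)))
}

#' Simulate a cohort with a latent link between BMD Z-scores and DE genes
#'
#' Generates a paired expression cohort and a matching clinical table
#' (patients = the paired patients), then plants a per-patient latent factor
#' that drives both the BMD Z-score phenotypes (loading `bmd_gene_loading`)
#' and the expression of the linked genes (scaled so each linked gene's log2
#' tumor expression correlates with the factor at the same loading). The
#' factor is a patient-level effect and multiplies both tissues of a patient,
#' so it shifts per-patient expression without disturbing the within-pair
#' fold change: linked genes stay exactly as differentially expressed as
#' their planted fold. Linked genes are drawn from the planted DE genes with
#' high control-tissue expression (median ANPT FPKM > 1), emulating a study
#' whose phenotype-related genes sit among the robustly detectable DE genes.
#'
#' @param config a [sim_config()].
#' @param linked_gene_count number of DE genes tied to the factor
#'   (default `min(planted_cluster_size, number of DE genes)`).
#' @return list with `expr`, `design`, `clinical`, `truth` (with `de_genes`
#'   and `bmd_linked_genes`).
#' @export
simulate_bmd_gene_link <- function(config, linked_gene_count = NULL) {
  stopifnot(inherits(config, "sim_config"))
  es <- simulate_expression(config)
  cohort_config <- config
  cohort_config$n_patients <- config$n_pairs
  cs <- simulate_cohort(cohort_config)
  clinical <- cs$clinical
  # patient ids of the cohort match the paired design by construction
  stopifnot(identical(patient_ids(clinical), es$design$patient_id))
  n_de <- nrow(es$truth$de_genes)
  if (is.null(linked_gene_count))
    linked_gene_count <- min(config$planted_cluster_size, n_de)
  if (linked_gene_count > n_de)
    stop("linked_gene_count exceeds the number of planted DE genes",
         call. = FALSE)
  set.seed(config$seed + 2L)
  f <- stats::rnorm(config$n_pairs)
  lam <- config$bmd_gene_loading
  bmd_cols <- grep("^BMD_Z", colnames(clinical$values), value = TRUE)
  marg <- phenotype_marginals(colnames(clinical$values))
  for (ph in bmd_cols) {
    z <- lam * f + sqrt(1 - lam^2) * stats::rnorm(config$n_pairs)
    v <- marg[ph, "mean"] + marg[ph, "sd"] * z
    v[is.na(clinical$values[, ph])] <- NA_real_    # keep the MCAR mask
    clinical$values[, ph] <- v
  }
  anpt_med <- apply(es$expr[es$truth$de_genes$gene_id, es$design$anpt_id,
                            drop = FALSE], 1, stats::median)
  linkable <- es$truth$de_genes$gene_id[anpt_med > 1]
  if (linked_gene_count > length(linkable))
    stop("linked_gene_count exceeds the number of well-expressed DE genes",
         call. = FALSE)
  linked <- sort(sample(linkable, linked_gene_count))
  alpha <- lam / sqrt(1 - lam^2) * config$noise_sd
  bump <- 2^(alpha * f)
  for (g in linked) {
    es$expr[g, es$design$tumor_id] <- es$expr[g, es$design$tumor_id] * bump
    es$expr[g, es$design$anpt_id] <- es$expr[g, es$design$anpt_id] * bump
  }
  truth <- es$truth
  truth$bmd_linked_genes <- linked
  truth$phenotype_corr_targets <- cs$truth$phenotype_corr_targets
  list(expr = es$expr, design = es$design, clinical = clinical, truth = truth)
}

# map 1-based upper-triangle pair indices to endpoint indices for m nodes
unrank_pairs <- function(x, m) {
  offsets <- cumsum(c(0, (m - 1):1))    # offsets[i] = pairs before row i
  i <- findInterval(x - 1, offsets, rightmost.closed = FALSE)
  j <- x - offsets[i] + i
  cbind(i, j)
}

#' Simulate a protein-interaction edge list with one planted cluster
#'
#' Background edges follow an Erdos-Renyi model at
#' `ppi_background_edge_prob` over the gene universe; on top, a connected
#' planted cluster (random spanning tree plus extra in-cluster edges) is laid
#' over the cluster genes. With background probability 0 the graph contains
#' exactly the planted cluster.
#'
#' @param config a [sim_config()].
#' @param genes character vector: the gene universe.
#' @param cluster_genes genes of the planted cluster (default: a random
#'   sample of `planted_cluster_size` universe genes).
#' @return list with `graph` (an [interaction_graph()]) and `truth` (with
#'   `planted_cluster`).
#' @export
simulate_ppi <- function(config, genes, cluster_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- unique(as.character(genes))
  set.seed(config$seed + 3L)
  if (is.null(cluster_genes)) {
    if (config$planted_cluster_size > length(genes))
      stop("planted_cluster_size exceeds the gene universe", call. = FALSE)
    cluster_genes <- sample(genes, config$planted_cluster_size)
  }
  stopifnot(all(cluster_genes %in% genes))
  m <- length(genes)
  edges <- matrix(character(), 0, 2)
  p <- config$ppi_background_edge_prob
  if (p > 0 && m >= 2) {
    M <- m * (m - 1) / 2
    n_bg <- stats::rbinom(1, M, p)
    if (n_bg > 0) {
      idx <- sample(M, n_bg)
      ij <- unrank_pairs(idx, m)
      edges <- cbind(genes[ij[, 1]], genes[ij[, 2]])
    }
  }
  cl <- sample(cluster_genes)          # spanning-tree order
  if (length(cl) >= 2) {
    parent <- vapply(2:length(cl), function(k) cl[sample.int(k - 1, 1)], "")
    tree <- cbind(parent, cl[-1])
    extra <- NULL
    if (length(cl) >= 3) {
      a <- sample(cl, length(cl), replace = TRUE)
      b <- sample(cl, length(cl), replace = TRUE)
      keep <- a != b
      extra <- cbind(a[keep], b[keep])
    }
    edges <- rbind(edges, tree, extra)
  }
  graph <- interaction_graph(edges, nodes = genes)
  list(graph = graph,
       truth = new_truth(planted_cluster = sort(cluster_genes)))
}

#' Write a complete synthetic study to a directory
#'
#' Generates a linked expression/clinical cohort ([simulate_bmd_gene_link()])
#' and a PPI graph whose planted cluster sits inside the BMD-linked genes,
#' plus a small gene-set collection, and writes everything in the package's
#' external formats: `expression.tsv`, `design.tsv`, `clinical.csv`,
#' `ppi.tsv`, `genesets.gmt`, and ground truth under `truth/` (TSV files whose
#' first line is `#truth` so they cannot be mistaken for inputs).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
simulate_to_dir <- function(config, dir) {
  sim <- simulate_bmd_gene_link(config)
  cluster_genes <- sim$truth$bmd_linked_genes[
    seq_len(min(config$planted_cluster_size,
                length(sim$truth$bmd_linked_genes)))]
  ppi <- simulate_ppi(config, rownames(sim$expr), cluster_genes)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  de <- sim$truth$de_genes
  set.seed(config$seed + 4L)
  sets <- gene_set_collection(
    list(planted_up = de$gene_id[de$direction == "up"],
         planted_down = de$gene_id[de$direction == "down"],
         bmd_linked = sim$truth$bmd_linked_genes,
         random_background = sample(rownames(sim$expr),
                                    min(100, nrow(sim$expr)))),
    descriptions = c("planted up-regulated genes",
                     "planted down-regulated genes",
                     "genes tied to the BMD latent factor",
                     "random gene set"))
  paths <- c(expression = file.path(dir, "expression.tsv"),
             design = file.path(dir, "design.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             ppi = file.path(dir, "ppi.tsv"),
             genesets = file.path(dir, "genesets.gmt"),
             truth_de = file.path(dir, "truth", "de_genes.tsv"),
             truth_linked = file.path(dir, "truth", "bmd_linked_genes.tsv"),
             truth_cluster = file.path(dir, "truth", "planted_cluster.tsv"),
             truth_corr = file.path(dir, "truth", "phenotype_corr_targets.tsv"))
  write_expression_matrix(sim$expr, paths["expression"])
  write_paired_design(sim$design, paths["design"])
  write_clinical_table(sim$clinical, paths["clinical"])
  write_edge_list(ppi$graph, paths["ppi"])
  write_gmt(sets, paths["genesets"])
  write_truth_table <- function(x, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("#truth", con)
    utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_truth_table(sim$truth$de_genes, paths["truth_de"])
  write_truth_table(data.frame(gene_id = sim$truth$bmd_linked_genes),
                    paths["truth_linked"])
  write_truth_table(data.frame(gene_id = ppi$truth$planted_cluster),
                    paths["truth_cluster"])
  write_truth_table(sim$truth$phenotype_corr_targets, paths["truth_corr"])
  invisible(paths)
}
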