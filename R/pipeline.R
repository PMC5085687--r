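# End-to-end orchestration: DE -> phenotype screen -> gene-phenotype
# association -> PPI subnetwork -> enrichment, each stage feeding its selected
# gene list to the next, with a machine-readable run report.

#' Pipeline configuration
#'
#' Collects input paths, output directory and stage parameters for
#' [run_all()]. Input files must exist when the pipeline runs.
#'
#' @param expr_path,design_path,clinical_path paths to the expression matrix,
#'   paired design and clinical table.
#' @param ppi_path path to the PPI edge list (optional; network stage skipped
#'   without it).
#' @param gmt_path path to a GMT gene-set file (optional; enrichment stage
#'   skipped without it).
#' @param out_dir output directory.
#' @param di a [di_params()] object.
#' @param assoc an [assoc_params()] object.
#' @param screen_phenotypes phenotypes for the Spearman phenotype screen
#'   (default: all continuous phenotypes).
#' @param assoc_phenotypes phenotypes for the gene association screen
#'   (default: all phenotypes whose name starts with `BMD_Z`).
#' @param alpha FDR level of the phenotype screen (default 0.05).
#' @param min_pairs minimum pairwise-complete observations in the phenotype
#'   screen (default 5).
#' @param enrich_alpha_p,enrich_alpha_q enrichment cutoffs (defaults 0.05,
#'   0.1).
#' @param force overwrite existing outputs (default `FALSE`).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr_path, design_path, clinical_path,
                            ppi_path = NULL, gmt_path = NULL,
                            out_dir = "phenogeno_out",
                            di = di_params(), assoc = assoc_params(),
                            screen_phenotypes = NULL, assoc_phenotypes = NULL,
                            alpha = 0.05, min_pairs = 5,
                            enrich_alpha_p = 0.05, enrich_alpha_q = 0.1,
                            force = FALSE) {
  stopifnot(inherits(di, "di_params"), inherits(assoc, "assoc_params"))
  structure(list(expr_path = expr_path, design_path = design_path,
                 clinical_path = clinical_path, ppi_path = ppi_path,
                 gmt_path = gmt_path, out_dir = out_dir, di = di,
                 assoc = assoc, screen_phenotypes = screen_phenotypes,
                 assoc_phenotypes = assoc_phenotypes, alpha = alpha,
                 min_pairs = min_pairs, enrich_alpha_p = enrich_alpha_p,
                 enrich_alpha_q = enrich_alpha_q, force = force),
            class = "pipeline_config")
}

#' Default pipeline parameters
#'
#' Returns every tunable default of the pipeline as a flat named list, so a
#' run can be fully self-documented.
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  di <- di_params(); ap <- assoc_params()
  c(list(alpha = 0.05, min_pairs = 5, enrich_alpha_p = 0.05,
         enrich_alpha_q = 0.1),
    stats::setNames(unclass(di), paste0("di.", names(di))),
    stats::setNames(unclass(ap), paste0("assoc.", names(ap))))
}

check_outputs <- function(paths, force) {
  existing <- paths[file.exists(paths)]
  if (length(existing) && !force)
    stop("output file(s) already exist (use force = TRUE to overwrite): ",
         paste(existing, collapse = ", "), call. = FALSE)
}

#' Run the full phenotype-genotype association pipeline
#'
#' Executes, in order: differential-index DE analysis, the clinical Spearman
#' phenotype screen, the Pearson gene-phenotype association screen on the DE
#' genes, PPI induced-subgraph/component analysis on the associated genes,
#' and hypergeometric enrichment of the associated genes. Each stage writes
#' its outputs under `config$out_dir` and a machine-readable `report.json`
#' records per-stage input/output counts and parameters. A stage failure
#' aborts the run; the report then lists the stages completed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default `FALSE`).
#' @return the run report, invisibly: list with `stages` (per-stage records)
#'   and `completed`.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  needed <- c(expr = config$expr_path, design = config$design_path,
              clinical = config$clinical_path)
  missing_in <- needed[!file.exists(needed)]
  if (length(missing_in))
    stop("missing input file(s): ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(stages = list(), completed = character(),
                 parameters = pipeline_params_record(config))
  out <- function(name) file.path(config$out_dir, name)

  finish <- function(report) {
    report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(report)
  }
  run_stage <- function(name, fun) {
    say("stage %s ...", name)
    rec <- tryCatch(fun(), error = function(e) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      finish(report)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    rec$status <- "ok"
    report$stages[[name]] <<- rec
    report$completed <<- c(report$completed, name)
    rec
  }

  expr <- read_expression_matrix(config$expr_path)
  design <- read_paired_design(config$design_path)
  clinical <- read_clinical_table(config$clinical_path)
  de_selected <- character()
  assoc_selected <- character()

  run_stage("de", function() {
    fit <- di_fit(expr, design, config$di)
    sel <- select_de_genes(fit)
    check_outputs(c(out("de_results.tsv"), out("de_genes_up.txt"),
                    out("de_genes_down.txt")), config$force)
    write_di_results(fit, out("de_results.tsv"))
    write_gene_list(sel$up, out("de_genes_up.txt"))
    write_gene_list(sel$down, out("de_genes_down.txt"))
    de_selected <<- c(sel$up, sel$down)
    list(n_input = nrow(expr), n_output = length(sel$up) + length(sel$down),
         n_up = length(sel$up), n_down = length(sel$down))
  })

  run_stage("pheno_corr", function() {
    screen <- spearman_screen(clinical, config$screen_phenotypes,
                              min_pairs = config$min_pairs,
                              alpha = config$alpha)
    check_outputs(paste0(out("pheno_corr"),
                         c("_long.tsv", "_coef.tsv", "_mask.tsv")),
                  config$force)
    write_correlation_screen(screen, out("pheno_corr"))
    list(n_input = length(unique(c(screen$item_a, screen$item_b))),
         n_output = nrow(screen), n_significant = sum(screen$significant))
  })

  run_stage("assoc", function() {
    phenos <- config$assoc_phenotypes
    if (is.null(phenos))
      phenos <- grep("^BMD_Z", phenotype_names(clinical), value = TRUE)
    if (!length(phenos)) stop("no association phenotypes available")
    if (!length(de_selected)) stop("no DE genes to test")
    vals <- patient_gene_values(expr, design, de_selected, config$assoc)
    assoc <- pearson_assoc(vals, clinical, phenos, config$assoc)
    sel <- select_associated_genes(assoc)
    check_outputs(c(out("assoc_results.tsv"), out("assoc_genes.txt")),
                  config$force)
    write_assoc_results(assoc, out("assoc_results.tsv"))
    write_gene_list(sel, out("assoc_genes.txt"))
    assoc_selected <<- sel
    list(n_input = length(de_selected), n_output = length(sel),
         n_phenotypes = length(phenos))
  })

  if (!is.null(config$ppi_path)) {
    run_stage("network", function() {
      graph <- read_edge_list(config$ppi_path)
      sub <- induced_subgraph(graph, assoc_selected)
      parts <- connected_components(sub)
      cs <- connectivity_summary(graph, assoc_selected)
      check_outputs(c(out("subnetwork_edges.tsv"), out("components.tsv")),
                    config$force)
      write_edge_list(sub, out("subnetwork_edges.tsv"))
      write_components(parts, out("components.tsv"))
      list(n_input = length(assoc_selected),
           n_output = cs$n_with_interaction,
           largest_component_size = cs$largest_component_size,
           n_components = length(parts$components))
    })
  }

  if (!is.null(config$gmt_path)) {
    run_stage("enrich", function() {
      sets <- read_gmt(config$gmt_path)
      universe <- names(which(apply(expr, 1, max) > 0))
      query <- intersect(assoc_selected, universe)
      enr <- hypergeometric_enrichment(query, universe, sets,
                                       config$enrich_alpha_p,
                                       config$enrich_alpha_q)
      check_outputs(out("enrichment.tsv"), config$force)
      utils::write.table(as.data.frame(enr), out("enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_input = length(query), n_output = nrow(enr),
           n_sets_tested = nrow(attr(enr, "all_rows")))
    })
  }

  say("pipeline complete: %s", paste(report$completed, collapse = " -> "))
  finish(report)
}

pipeline_params_record <- function(config) {
  list(di = unclass(config$di), assoc = unclass(config$assoc),
       alpha = config$alpha, min_pairs = config$min_pairs,
       enrich_alpha_p = config$enrich_alpha_p,
       enrich_alpha_q = config$enrich_alpha_q)
}
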