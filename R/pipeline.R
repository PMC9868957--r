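#' Default pipeline configuration
#'
#' A nested list with one block per stage; \code{\link{run_all}} validates it
#' against a small schema. All robustness toggles of the modelling layer are
#' exposed: age numeric vs categorical, TSM as summed patient counts vs mean
#' per-cohort rate, all vs protein-changing mutations, and the optional driver
#' covariate.
#'
#' @param out output directory.
#' @param seed master seed.
#' @param n_genes convenience override of the synthetic gene count.
#' @return Configuration list.
#' @export
default_config <- function(out = "germscore_run", seed = 1L, n_genes = 2000L) {
  list(
    mode = "synthetic",
    out = out,
    seed = as.integer(seed),
    synthetic = list(n_genes = as.integer(n_genes), n_terms = 80L,
                     n_tumor_types = 33L, n_diseases = 40L),
    features = list(mutation_mode = "all", tsm_variant = "sum"),
    models = list(age_mode = "numeric", driver_covariate = FALSE,
                  paradigm = "random_forest", min_genes = 100L, folds = 10L),
    disease = list(n_randomizations = 100L, n_bins = 20L, alpha = 0.01,
                   low_cutoff = 0.15)
  )
}

#' Read and validate a YAML pipeline configuration
#'
#' Missing keys fall back to \code{\link{default_config}} values; unknown
#' top-level keys and invalid value types raise an error of class
#' \code{config_error}.
#'
#' @param path YAML file path, or a configuration list.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop(config_error(paste("unknown configuration key(s):",
                            paste(unknown, collapse = ", "))))
  }
  for (k in names(base)) {
    if (is.list(base[[k]]) && !is.null(cfg[[k]])) {
      cfg[[k]] <- utils::modifyList(base[[k]], cfg[[k]])
    } else if (is.null(cfg[[k]])) cfg[[k]] <- base[[k]]
  }
  ok <- function(cond, msg) if (!cond) stop(config_error(msg))
  ok(cfg$mode %in% c("synthetic"), "mode must be 'synthetic'")
  ok(is.numeric(cfg$seed), "seed must be numeric")
  ok(cfg$features$mutation_mode %in% c("all", "protein_changing"),
     "features$mutation_mode must be all|protein_changing")
  ok(cfg$features$tsm_variant %in% c("sum", "mean_rate"),
     "features$tsm_variant must be sum|mean_rate")
  ok(cfg$models$age_mode %in% c("numeric", "categorical"),
     "models$age_mode must be numeric|categorical")
  ok(cfg$models$paradigm %in% list_paradigms(),
     paste("models$paradigm must be one of:", paste(list_paradigms(), collapse = ", ")))
  ok(is.numeric(cfg$disease$n_randomizations) && cfg$disease$n_randomizations >= 1,
     "disease$n_randomizations must be >= 1")
  cfg
}

config_error <- function(msg) {
  structure(class = c("config_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

stage_error <- function(stage, index, parent) {
  structure(class = c("stage_error", "error", "condition"),
            list(message = paste0("stage '", stage, "' failed: ",
                                  conditionMessage(parent)),
         stage = stage, stage_index = index, call = NULL))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: simulate the inputs, expand the
#' annotations with neoplasm-subtree exclusion, assemble the feature table,
#' fit the multivariable logistic model and the per-phenotype classifiers,
#' generate the disease catalog from the model probabilities and score it
#' against the permutation null. Every stage writes TSV/JSON outputs under
#' \code{config$out} and the run ends with a manifest recording the
#' configuration, seeds, input checksums, row counts and timings. A completed
#' output directory is only overwritten with \code{force = TRUE}.
#'
#' @param config a configuration list or YAML path (see
#'   \code{\link{load_config}}).
#' @param force overwrite an existing completed run.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config, force = FALSE, quiet = FALSE) {
  cfg <- load_config(config)
  out <- cfg$out
  manifest_path <- file.path(out, "run_manifest.json")
  if (file.exists(manifest_path) && !force) {
    stop("output directory already holds a completed run; use force = TRUE")
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  timings <- list(); rows <- list()
  stage <- function(name, index, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) stop(stage_error(name, index, e)))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    res
  }

  sim <- stage("simulate", 1L, {
    scfg <- do.call(synthetic_config, c(cfg$synthetic, list(seed = cfg$seed)))
    o <- gen_ontology(scfg)
    genes <- gen_genes(scfg)
    labels <- gen_labels_and_annotations(scfg, genes, o)
    paths <- write_synthetic_inputs(file.path(out, "inputs"), scfg, o, genes, labels)
    rows$simulate <- length(genes$genes)
    list(cfg = scfg, o = o, genes = genes, labels = labels, paths = paths)
  })

  expanded <- stage("expand", 2L, {
    o <- load_obo(sim$paths[["obo"]])
    direct <- read_annotation_tsv(sim$paths[["annotations"]])
    ex <- expand_annotations(direct, o, exclude_root = attr(sim$o, "neoplasm_root"))
    write_annotation_tsv(ex, file.path(out, "annotations_expanded.tsv"))
    rows$expand <- nrow(ex)
    list(o = o, expanded = ex)
  })

  table <- stage("features", 3L, {
    records <- read_maf(sim$paths[["maf"]], tumor_col = "Cohort")
    tsm <- if (cfg$features$tsm_variant == "sum") {
      count_tsm(records, mode = cfg$features$mutation_mode,
                genes = sim$genes$genes)$total
    } else {
      mean_mutation_rate(records, sim$genes$samples_per_tumor,
                         mode = cfg$features$mutation_mode, genes = sim$genes$genes)
    }
    age <- utils::read.delim(sim$paths[["age"]], header = FALSE,
                             col.names = c("gene", "age"))
    feats <- utils::read.delim(sim$paths[["features"]], check.names = FALSE)
    ipa_genes <- unique(expanded$expanded$gene[expanded$expanded$term == expanded$o$root])
    ipa <- stats::setNames(as.integer(sim$genes$genes %in% ipa_genes), sim$genes$genes)
    tab <- assemble_feature_table(tsm, age, feats, ipa = ipa)
    utils::write.table(as.data.frame(tab), file.path(out, "feature_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rows$features <- nrow(tab)
    tab
  })

  models <- stage("train", 4L, {
    pcs <- standardize_and_pca(table)
    logit <- fit_multivariable(table$tsm, table$age, pcs, table$ipa,
                               age_mode = cfg$models$age_mode)
    utils::write.table(summary(logit), file.path(out, "logistic_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pms <- train_per_phenotype(table, expanded$expanded,
                               min_genes = cfg$models$min_genes,
                               paradigm = cfg$models$paradigm,
                               folds = cfg$models$folds, seed = cfg$seed)
    probs <- phenotype_probabilities(pms)
    long <- data.frame(gene = rep(rownames(probs), ncol(probs)),
                       term = rep(colnames(probs), each = nrow(probs)),
                       probability = signif(as.vector(probs), 8))
    utils::write.table(long, file.path(out, "phenotype_probabilities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    metrics <- lapply(pms$models, function(m) {
      list(term = m$term, n_positives = m$n_positives,
           mean_auroc = m$cv$mean_auroc, mean_auprc = m$cv$mean_auprc,
           baseline_auprc = m$cv$baseline_auprc, auprc_gain = m$cv$auprc_gain)
    })
    jsonlite::write_json(list(paradigm = pms$paradigm, seed = cfg$seed,
                              terms = unname(metrics)),
                         file.path(out, "model_metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rows$train <- length(pms$models)
    list(logistic = logit, phenotype = pms, probabilities = probs)
  })

  scores <- stage("score_diseases", 5L, {
    catalog <- gen_disease_catalog(sim$cfg, models$probabilities)
    write_disease_catalog(catalog, file.path(out, "disease_phenotypes.tsv"),
                          file.path(out, "disease_genes.tsv"))
    ranks <- rank_table(models$probabilities)
    res <- score_diseases(ranks, catalog, o = expanded$o,
                          n_randomizations = cfg$disease$n_randomizations,
                          n_bins = cfg$disease$n_bins, alpha = cfg$disease$alpha,
                          low_cutoff = cfg$disease$low_cutoff, seed = cfg$seed)
    tab <- res$scores_table
    tab$score <- signif(tab$score, 8)
    utils::write.table(tab, file.path(out, "disease_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(bin_counts = res$bin_counts,
                              null_mean = colMeans(res$null_bin_counts),
                              bin_pvalues = res$bin_pvalues,
                              flagged_bins = res$flagged_bins,
                              low_score = res$low_score),
                         file.path(out, "disease_null_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rows$score_diseases <- nrow(tab)
    res
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("germscore")),
    config = cfg,
    seed = cfg$seed,
    input_checksums = as.list(stats::setNames(unname(tools::md5sum(unname(sim$paths))),
                                              names(sim$paths))),
    stage_rows = rows,
    stage_timings_seconds = timings
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("run complete: ", out)
  invisible(list(sim = sim, expanded = expanded, table = table, models = models,
                 scores = scores, manifest = manifest))
}
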