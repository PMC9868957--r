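#' Configuration of the synthetic study generator
#'
#' Defines every knob of the simulated inputs: the ontology size and shape,
#' the mutation model, the planted effect sizes of the label model, the
#' feature correlation structure, and the disease catalog. Defaults mirror
#' the real study conditions the pipeline targets: 18,170 genes, 33 tumor
#' cohorts, a planted somatic-mutation odds ratio of 1.9 per SD, and a
#' positive-label prevalence of 22.75\%. Counts are reducible for desk-scale
#' runs; effect sizes are the planted truth that recovery tests measure
#' against.
#'
#' @param n_genes number of genes.
#' @param n_terms ontology size (>= 3).
#' @param dag_branching probability that a non-root term draws a second
#'   parent (multi-parent DAG density).
#' @param neoplasm_subtree_fraction fraction of terms inside the designated
#'   neoplasm-like subtree whose annotations are excluded.
#' @param or_tsm_per_sd planted odds ratio of the somatic-mutation count per
#'   one standard deviation.
#' @param age_effect_per_level planted log-odds increment per age level
#'   (levels ordered so larger = evolutionarily older).
#' @param n_tumor_types number of tumor cohorts.
#' @param tsm_dispersion negative-binomial dispersion of per-tumor mutation
#'   counts (variance = mu + dispersion * mu^2; 0 gives Poisson).
#' @param mean_mutations_per_tumor expected patients-with-mutation per
#'   (gene, tumor) cell for a gene of average length.
#' @param feature_correlation equicorrelation of the continuous feature block.
#' @param prevalence target positive-label fraction (sets the intercept).
#' @param terms_per_gene_max positive genes annotate to 1..this many leaves.
#' @param neoplasm_annotation_fraction fraction of genes given additional
#'   annotations inside the neoplasm-like subtree (exercises the exclusion).
#' @param n_diseases,phenotypes_per_disease,genes_per_disease catalog shape.
#' @param causal_gene_sharpness softmax sharpness with which causal genes are
#'   drawn from the top of the model ranking (0 = uniform null catalog).
#' @param seed master seed; every generator derives its stream from it.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 18170L, n_terms = 150L, dag_branching = 0.3,
                             neoplasm_subtree_fraction = 0.15,
                             or_tsm_per_sd = 1.9, age_effect_per_level = 0.1,
                             n_tumor_types = 33L, tsm_dispersion = 1,
                             mean_mutations_per_tumor = 2,
                             feature_correlation = 0.3, prevalence = 0.2275,
                             terms_per_gene_max = 5L,
                             neoplasm_annotation_fraction = 0.1,
                             n_diseases = 60L, phenotypes_per_disease = 4L,
                             genes_per_disease = 2L, causal_gene_sharpness = 100,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_terms = as.integer(n_terms),
              dag_branching = dag_branching,
              neoplasm_subtree_fraction = neoplasm_subtree_fraction,
              or_tsm_per_sd = or_tsm_per_sd,
              age_effect_per_level = age_effect_per_level,
              n_tumor_types = as.integer(n_tumor_types),
              tsm_dispersion = tsm_dispersion,
              mean_mutations_per_tumor = mean_mutations_per_tumor,
              feature_correlation = feature_correlation, prevalence = prevalence,
              terms_per_gene_max = as.integer(terms_per_gene_max),
              neoplasm_annotation_fraction = neoplasm_annotation_fraction,
              n_diseases = as.integer(n_diseases),
              phenotypes_per_disease = as.integer(phenotypes_per_disease),
              genes_per_disease = as.integer(genes_per_disease),
              causal_gene_sharpness = causal_gene_sharpness,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0, cfg$n_terms >= 3L, cfg$or_tsm_per_sd > 0,
            cfg$tsm_dispersion >= 0, cfg$n_tumor_types > 0,
            cfg$prevalence > 0, cfg$prevalence < 1)
  structure(cfg, class = "synthetic_config")
}

#' Generate a random rooted phenotype ontology
#'
#' Terms are added in order; each non-root term draws one parent (and, with
#' probability \code{dag_branching}, a second) from earlier terms of its own
#' branch, so the graph is acyclic by construction. One child of the root is
#' designated the neoplasm-like subtree and receives approximately the
#' configured fraction of terms; the two branches share no edges, so subtree
#' exclusion has exact expected semantics.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return An \code{\link{ontology}} with attributes \code{neoplasm_root}.
#' @export
gen_ontology <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_terms
  ids <- sprintf("ST:%06d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  parents[[1L]] <- character()
  labels <- c("phenotypic abnormality (synthetic)", "neoplasm (synthetic)",
              sprintf("synthetic term %d", seq_len(max(0L, n - 2L)) + 2L))
  if (n == 3L) {
    parents[[2L]] <- ids[1L]; parents[[3L]] <- ids[1L]
  } else {
    parents[[2L]] <- ids[1L]; parents[[3L]] <- ids[1L]
    k <- max(1L, round(cfg$neoplasm_subtree_fraction * (n - 3L)))
    neo_terms <- c(2L, if (k >= 1L) 4L:(3L + k))
    norm_terms <- c(3L, if (3L + k + 1L <= n) (3L + k + 1L):n)
    assign_parents <- function(members) {
      for (j in seq_along(members)[-1L]) {
        i <- members[[j]]
        pool <- members[seq_len(j - 1L)]
        np <- 1L + (length(pool) > 1L && stats::runif(1) < cfg$dag_branching)
        np <- min(np, length(pool))
        parents[[i]] <<- ids[pool[sample.int(length(pool), np)]]
      }
    }
    assign_parents(neo_terms)
    assign_parents(norm_terms)
  }
  o <- ontology(ids, parents, labels = stats::setNames(labels[seq_len(n)], ids))
  attr(o, "neoplasm_root") <- ids[2L]
  o
}

# equicorrelated standard-normal block: X = sqrt(rho) z0 + sqrt(1-rho) Z
equicorr_normal <- function(n, p, rho) {
  z0 <- stats::rnorm(n)
  sqrt(rho) * matrix(z0, n, p) + sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
}

#' Generate genes: lengths, mutation counts, age and features
#'
#' Gene lengths are log-normal; per-tumor patients-with-mutation counts are
#' negative-binomial with mean proportional to gene length (planting the
#' length confounding of real cancer mutation data; dispersion 0 recovers
#' Poisson). Age is a 20-level categorical skewed towards old genes. The
#' continuous feature block is multivariate normal with configurable
#' equicorrelation (fraction-type features are mapped through the logistic
#' function into [0, 1]); trinucleotide frequencies are computed from
#' generated CDS strings through the production counter, so the feature table
#' satisfies the same invariants as real data.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param records also expand counts into per-patient mutation records
#'   (needed when the MAF path is exercised; off for large pure-regression
#'   runs).
#' @param cds also generate CDS strings and their trinucleotide frequencies.
#' @return A list: \code{genes}, \code{gene_length}, \code{counts}
#'   (gene x tumor matrix), \code{tsm} (named vector), \code{age} (data
#'   frame), \code{features} (data frame, 81 columns when \code{cds}),
#'   \code{samples_per_tumor}, \code{records} (data frame or NULL),
#'   \code{cds} (character or NULL).
#' @export
gen_genes <- function(cfg, records = TRUE, cds = TRUE) {
  set.seed(cfg$seed + 2L)
  n <- cfg$n_genes
  genes <- sprintf("G%06d", seq_len(n))
  gene_length <- pmax(1000, round(stats::rlnorm(n, log(2e4), 0.8)))
  cds_length <- pmax(150L, as.integer(round(gene_length * stats::rbeta(n, 4, 40))))
  tumors <- sprintf("TT%02d", seq_len(cfg$n_tumor_types))
  mu <- cfg$mean_mutations_per_tumor * gene_length / mean(gene_length)
  counts <- vapply(tumors, function(tt) {
    as.integer(if (cfg$tsm_dispersion == 0) stats::rpois(n, mu)
               else stats::rnbinom(n, mu = mu, size = 1 / cfg$tsm_dispersion))
  }, integer(n))
  rownames(counts) <- genes
  tsm <- rowSums(counts)
  names(tsm) <- genes
  age <- sample.int(20L, n, replace = TRUE, prob = exp(0.12 * (1:20)))
  cont <- equicorr_normal(n, 16L, cfg$feature_correlation)
  cont_names <- setdiff(genomic_feature_names()[1:17], "cds_length")
  colnames(cont) <- cont_names
  frac_cols <- c("dnase_gene", "dnase_cds", "h3k4me1_gene", "h3k4me1_cds",
                 "h3k4me3_gene", "h3k4me3_cds", "h3k27ac_gene", "h3k27ac_cds",
                 "laminb1_gene", "repeat_gene", "repeat_cds")
  cont[, frac_cols] <- stats::plogis(cont[, frac_cols])
  features <- data.frame(gene = genes, cds_length = cds_length, cont,
                         stringsAsFactors = FALSE)
  cds_seq <- NULL
  if (cds) {
    bases <- c("A", "C", "G", "T")
    probs <- matrix(stats::rgamma(n * 4L, shape = 5), n, 4L)
    probs <- probs / rowSums(probs)
    cds_seq <- vapply(seq_len(n), function(i) {
      paste(sample(bases, cds_length[i], replace = TRUE, prob = probs[i, ]),
            collapse = "")
    }, "")
    tri <- Biostrings::trinucleotideFrequency(
      Biostrings::DNAStringSet(cds_seq), step = 1L)
    tri <- tri / rowSums(tri)
    colnames(tri) <- paste0("tri_", colnames(tri))
    features <- cbind(features, as.data.frame(tri))
  }
  recs <- NULL
  samples_per_tumor <- stats::setNames(
    pmax(50L, as.integer(ceiling(apply(counts, 2L, max) * 1.5))), tumors)
  if (records) recs <- counts_to_records(counts, samples_per_tumor, seed = cfg$seed + 20L)
  list(genes = genes, gene_length = gene_length, counts = counts, tsm = tsm,
       age = data.frame(gene = genes, age = age, stringsAsFactors = FALSE),
       features = features, samples_per_tumor = samples_per_tumor,
       records = recs, cds = cds_seq)
}

# expand a gene x tumor patient-count matrix into per-mutation records; a
# random tenth of patients carry a second record in the same gene (the
# per-patient deduplication must absorb it) and silent mutations appear at a
# fixed rate so the protein-changing filter bites
counts_to_records <- function(counts, samples_per_tumor, seed = 1L) {
  set.seed(seed)
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
               "Splice_Site", "Translation_Start_Site", "Silent")
  wts <- c(55, 6, 6, 4, 2, 2, 5, 1, 19)
  idx <- which(counts > 0L, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(mutation_records(character(), character(), character(), character()))
  }
  per_cell <- counts[idx]
  gene <- rep(rownames(counts)[idx[, 1L]], per_cell)
  tumor <- rep(colnames(counts)[idx[, 2L]], per_cell)
  patient <- unlist(lapply(seq_len(nrow(idx)), function(r) {
    tt <- colnames(counts)[idx[r, 2L]]
    sprintf("%s-P%05d", tt, sample.int(samples_per_tumor[[tt]], counts[idx[r, 1L], idx[r, 2L]]))
  }), use.names = FALSE)
  cls <- sample(classes, length(gene), replace = TRUE, prob = wts)
  rec <- mutation_records(gene, patient, tumor, cls)
  dup <- which(stats::runif(nrow(rec)) < 0.1)
  if (length(dup)) {
    extra <- rec[dup, , drop = FALSE]
    extra$classification <- sample(classes, length(dup), replace = TRUE, prob = wts)
    rec <- rbind(rec, extra)
  }
  rec[sample.int(nrow(rec)), , drop = FALSE]
}

#' Generate phenotype-involvement labels and direct annotations
#'
#' The involvement probability of each gene is a logistic model with the
#' planted effects: \code{plogis(b0 + log(or_tsm_per_sd) * z(TSM) +
#' age_effect_per_level * (age - mean(age)))}, with the intercept solved so
#' the expected prevalence matches the configuration. Positive genes are
#' annotated to 1..\code{terms_per_gene_max} random leaf terms outside the
#' neoplasm-like subtree; a configurable fraction of all genes additionally
#' receives annotations inside that subtree, so the exclusion rule is
#' exercised by construction.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param genes result of \code{\link{gen_genes}}.
#' @param o ontology from \code{\link{gen_ontology}}; may be \code{NULL} with
#'   \code{annotations = FALSE}.
#' @param annotations also draw the direct annotation set (disable for
#'   regression-only studies that need labels alone).
#' @return A list: \code{ipa} (named 0/1 vector), \code{probability} (named),
#'   \code{direct} (an \code{\link{annotation_set}}, or NULL).
#' @export
gen_labels_and_annotations <- function(cfg, genes, o, annotations = TRUE) {
  set.seed(cfg$seed + 3L)
  z_tsm <- as.numeric(scale(genes$tsm))
  age <- genes$age$age
  eta <- log(cfg$or_tsm_per_sd) * z_tsm + cfg$age_effect_per_level * (age - mean(age))
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - cfg$prevalence,
                       interval = c(-30, 30))$root
  p <- stats::plogis(b0 + eta)
  ipa <- stats::rbinom(length(p), 1L, p)
  names(ipa) <- names(p) <- genes$genes
  if (!annotations) return(list(ipa = ipa, probability = p, direct = NULL))
  neo <- c(attr(o, "neoplasm_root"), descendants(o, attr(o, "neoplasm_root")))
  leaves <- o$terms[vapply(o$children, length, 1L) == 0L]
  normal_leaves <- setdiff(leaves, neo)
  if (!length(normal_leaves)) stop("ontology has no leaf outside the neoplasm-like subtree")
  pos <- genes$genes[ipa == 1L]
  k <- sample.int(cfg$terms_per_gene_max, length(pos), replace = TRUE)
  g_dir <- rep(pos, k)
  t_dir <- unlist(lapply(k, function(m) sample(normal_leaves, min(m, length(normal_leaves)))),
                  use.names = FALSE)
  extra <- genes$genes[stats::runif(length(genes$genes)) < cfg$neoplasm_annotation_fraction]
  if (length(extra) && length(neo)) {
    g_dir <- c(g_dir, extra)
    t_dir <- c(t_dir, sample(neo, length(extra), replace = TRUE))
  }
  list(ipa = ipa, probability = p,
       direct = annotation_set(g_dir, t_dir, state = "direct"))
}

#' Split planted labels into an old and a new annotation release
#'
#' Hides \code{n_new} of the positive genes from the old release, emulating
#' gene-phenotype associations discovered between two ontology releases.
#'
#' @param ipa named 0/1 label vector.
#' @param n_new number of positives hidden from the old release.
#' @param seed RNG seed.
#' @return A list with character vectors \code{old_genes} and
#'   \code{new_genes} (new is a superset of old).
#' @export
gen_release_pair <- function(ipa, n_new, seed = 1L) {
  pos <- names(ipa)[ipa == 1L]
  if (n_new >= length(pos)) stop("cannot hide ", n_new, " of ", length(pos), " positives")
  set.seed(seed)
  hidden <- sample(pos, n_new)
  list(old_genes = setdiff(pos, hidden), new_genes = pos)
}

#' Generate a disease catalog with planted causal genes
#'
#' Each disease draws a fixed number of distinct scored phenotype terms; its
#' causal genes are drawn without replacement with probability proportional
#' to \code{softmax(sharpness * mean model probability over the disease's
#' terms)}. Sharpness 0 yields a uniform (null) catalog in which gene labels
#' carry no signal; large sharpness concentrates causal genes at the top of
#' the model ranking, which the disease score must recover as low-score
#' enrichment.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param prob_matrix genes x scored-terms matrix of model probabilities.
#' @return A \code{\link{disease_catalog}}.
#' @export
gen_disease_catalog <- function(cfg, prob_matrix) {
  set.seed(cfg$seed + 4L)
  genes <- rownames(prob_matrix)
  terms <- colnames(prob_matrix)
  if (length(terms) < cfg$phenotypes_per_disease) {
    stop("fewer scored terms than phenotypes_per_disease")
  }
  ph <- list(); asc <- list()
  for (d in seq_len(cfg$n_diseases)) {
    id <- sprintf("DIS:%04d", d)
    tset <- sample(terms, cfg$phenotypes_per_disease)
    m <- rowMeans(prob_matrix[, tset, drop = FALSE])
    w <- exp(cfg$causal_gene_sharpness * (m - max(m)))
    causal <- sample(genes, cfg$genes_per_disease, prob = w / sum(w))
    ph[[d]] <- data.frame(disease = id, term = tset, stringsAsFactors = FALSE)
    asc[[d]] <- data.frame(disease = id, gene = causal, stringsAsFactors = FALSE)
  }
  disease_catalog(do.call(rbind, ph), do.call(rbind, asc))
}

#' Write every synthetic input in its production file dialect
#'
#' Emits the OBO ontology, the direct annotation TSV, a MAF per study (one
#' file, cohort column included), the gene-age TSV, the gene-feature TSV, the
#' disease catalog TSVs and a manifest JSON recording the full configuration.
#' Every file parses through the corresponding production reader.
#'
#' @param dir output directory (created if needed).
#' @param cfg a \code{\link{synthetic_config}}.
#' @param o,genes,labels,catalog generated pieces; \code{catalog} may be NULL.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(dir, cfg, o, genes, labels, catalog = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(obo = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             maf = file.path(dir, "mutations.maf"),
             age = file.path(dir, "gene_age.tsv"),
             features = file.path(dir, "features.tsv"),
             samples = file.path(dir, "samples_per_tumor.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_obo(o, paths[["obo"]])
  write_annotation_tsv(labels$direct, paths[["annotations"]])
  maf <- data.frame(Hugo_Symbol = genes$records$gene,
                    Variant_Classification = genes$records$classification,
                    Tumor_Sample_Barcode = genes$records$patient,
                    Cohort = genes$records$tumor_type)
  utils::write.table(maf, paths[["maf"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genes$age, paths[["age"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  feat <- genes$features
  feat[-1L] <- lapply(feat[-1L], function(v) if (is.double(v)) signif(v, 10) else v)
  utils::write.table(feat, paths[["features"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(tumor = names(genes$samples_per_tumor),
                                n = genes$samples_per_tumor),
                     paths[["samples"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(catalog)) {
    paths <- c(paths, disease_phenotypes = file.path(dir, "disease_phenotypes.tsv"),
               disease_genes = file.path(dir, "disease_genes.tsv"))
    write_disease_catalog(catalog, paths[["disease_phenotypes"]], paths[["disease_genes"]])
  }
  jsonlite::write_json(list(config = unclass(cfg),
                            neoplasm_root = attr(o, "neoplasm_root"),
                            n_records = nrow(genes$records %||% data.frame()),
                            prevalence = mean(labels$ipa)),
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
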