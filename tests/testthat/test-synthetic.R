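test_that("identical configurations generate byte-identical outputs", {
  cfg <- synthetic_config(n_genes = 120L, n_terms = 30L, n_diseases = 10L, seed = 77)
  a <- gen_genes(cfg); b <- gen_genes(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$features, b$features)
  expect_identical(a$records, b$records)
  oa <- gen_ontology(cfg); ob <- gen_ontology(cfg)
  expect_identical(oa$parents, ob$parents)
  la <- gen_labels_and_annotations(cfg, a, oa)
  lb <- gen_labels_and_annotations(cfg, b, ob)
  expect_identical(la$ipa, lb$ipa)
  expect_identical(as.data.frame(la$direct), as.data.frame(lb$direct))
})

test_that("generated ontologies are acyclic DAGs with the configured subtree share", {
  for (seed in 1:20) {
    cfg <- synthetic_config(n_terms = sample(3:120, 1L), n_genes = 10L, seed = seed)
    o <- gen_ontology(cfg) # the constructor runs Kahn's algorithm: no cycle
    expect_s3_class(o, "ontology")
    expect_length(o$root, 1L)
    f <- tempfile(fileext = ".obo")
    write_obo(o, f)
    o2 <- load_obo(f)
    expect_identical(lapply(o2$parents, sort), lapply(o$parents, sort))
  }
  cfg <- synthetic_config(n_terms = 100L, n_genes = 10L,
                          neoplasm_subtree_fraction = 0.2, seed = 5)
  o <- gen_ontology(cfg)
  neo <- attr(o, "neoplasm_root")
  share <- (1 + length(descendants(o, neo))) / cfg$n_terms
  expect_equal(share, 0.2, tolerance = 0.05)
})

test_that("mutation counts follow the configured negative-binomial model", {
  # dispersion -> 0 recovers Poisson: variance/mean ratio near 1
  cfg0 <- synthetic_config(n_genes = 3000L, n_terms = 10L, tsm_dispersion = 0,
                           seed = 21)
  g0 <- gen_genes(cfg0, records = FALSE, cds = FALSE)
  cnt <- as.vector(g0$counts[g0$gene_length > stats::quantile(g0$gene_length, 0.45) &
                               g0$gene_length < stats::quantile(g0$gene_length, 0.55), ])
  expect_equal(stats::var(cnt) / mean(cnt), 1, tolerance = 0.15)

  # overdispersed: ratio well above 1
  cfg1 <- synthetic_config(n_genes = 3000L, n_terms = 10L, tsm_dispersion = 1,
                           seed = 22)
  g1 <- gen_genes(cfg1, records = FALSE, cds = FALSE)
  cnt1 <- as.vector(g1$counts[g1$gene_length > stats::quantile(g1$gene_length, 0.45) &
                                g1$gene_length < stats::quantile(g1$gene_length, 0.55), ])
  expect_gt(stats::var(cnt1) / mean(cnt1), 1.5)

  # empirical mean TSM matches the closed-form mean within sampling error
  mu <- cfg1$mean_mutations_per_tumor * g1$gene_length / mean(g1$gene_length)
  expect_equal(mean(g1$tsm), cfg1$n_tumor_types * mean(mu), tolerance = 0.03)

  # length confounding is planted: longer genes carry more mutations
  expect_gt(stats::cor(g1$gene_length, g1$tsm, method = "spearman"), 0.3)
})

test_that("feature correlation knob controls the continuous block", {
  cfg <- synthetic_config(n_genes = 2000L, n_terms = 10L,
                          feature_correlation = 0, seed = 31)
  g <- gen_genes(cfg, records = FALSE, cds = FALSE)
  cols <- c("repli_timing_gene", "nucleosome_gene", "transcription_gene",
            "recombination_gene")
  cm <- stats::cor(as.matrix(g$features[, cols]))
  off <- cm[upper.tri(cm)]
  expect_lt(max(abs(off)), 3.5 / sqrt(cfg$n_genes)) # ~3 SE of a null correlation
  cfg2 <- synthetic_config(n_genes = 2000L, n_terms = 10L,
                           feature_correlation = 0.5, seed = 32)
  g2 <- gen_genes(cfg2, records = FALSE, cds = FALSE)
  cm2 <- stats::cor(as.matrix(g2$features[, cols]))
  expect_gt(mean(cm2[upper.tri(cm2)]), 0.4)
})

test_that("labels follow the planted logistic model and annotations respect the DAG", {
  cfg <- synthetic_config(n_genes = 3000L, n_terms = 60L, seed = 41)
  o <- gen_ontology(cfg)
  g <- gen_genes(cfg, records = FALSE, cds = FALSE)
  lab <- gen_labels_and_annotations(cfg, g, o)
  expect_equal(mean(lab$probability), cfg$prevalence, tolerance = 1e-4)
  expect_lt(abs(mean(lab$ipa) - cfg$prevalence), 0.03)

  neo <- c(attr(o, "neoplasm_root"), descendants(o, attr(o, "neoplasm_root")))
  leaves <- o$terms[vapply(o$children, length, 1L) == 0L]
  pos_terms <- unique(lab$direct$term[lab$direct$gene %in% names(lab$ipa)[lab$ipa == 1]])
  expect_true(all(setdiff(pos_terms, neo) %in% leaves))

  # the planted label equals root membership after exclusion and expansion
  ex <- expand_annotations(lab$direct, o, exclude_root = attr(o, "neoplasm_root"))
  ipa_from_graph <- as.integer(g$genes %in% unique(ex$gene[ex$term == o$root]))
  expect_identical(ipa_from_graph, unname(lab$ipa))

  # prevalence responds monotonically to the planted intercept via the target
  cfg_lo <- synthetic_config(n_genes = 3000L, n_terms = 60L, prevalence = 0.1, seed = 41)
  lab_lo <- gen_labels_and_annotations(cfg_lo, g, o, annotations = FALSE)
  expect_lt(mean(lab_lo$probability), mean(lab$probability))
})

test_that("every generated file parses through the production readers", {
  cfg <- synthetic_config(n_genes = 150L, n_terms = 30L, n_diseases = 8L,
                          phenotypes_per_disease = 3L, seed = 51)
  o <- gen_ontology(cfg)
  g <- gen_genes(cfg)
  lab <- gen_labels_and_annotations(cfg, g, o)
  set.seed(52)
  probs <- matrix(stats::runif(150 * 6), 150, 6,
                  dimnames = list(g$genes, sample(o$terms, 6)))
  catalog <- gen_disease_catalog(cfg, probs)
  dir <- tempfile(); paths <- write_synthetic_inputs(dir, cfg, o, g, lab, catalog)
  expect_true(all(file.exists(paths)))

  o2 <- load_obo(paths[["obo"]])
  expect_identical(sort(o2$terms), sort(o$terms))
  direct2 <- read_annotation_tsv(paths[["annotations"]])
  expect_identical(pair_keys(direct2), pair_keys(lab$direct))
  rec2 <- read_maf(paths[["maf"]], tumor_col = "Cohort")
  got <- count_tsm(rec2, "all", genes = g$genes)
  expect_identical(got$by_tumor[rownames(g$counts), colnames(g$counts)], g$counts)
  cat2 <- read_disease_catalog(paths[["disease_phenotypes"]], paths[["disease_genes"]])
  expect_equal(sort(unique(cat2$phenotypes$disease)), sort(unique(catalog$phenotypes$disease)))
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$config$seed, cfg$seed)
})

test_that("disease catalogs have the configured shape and sharpness drives causality", {
  cfg <- synthetic_config(n_genes = 200L, n_terms = 20L, n_diseases = 15L,
                          phenotypes_per_disease = 4L, genes_per_disease = 2L,
                          causal_gene_sharpness = 200, seed = 61)
  set.seed(62)
  probs <- matrix(stats::runif(200 * 8), 200, 8,
                  dimnames = list(sprintf("G%06d", 1:200), sprintf("ST:%06d", 1:8)))
  catalog <- gen_disease_catalog(cfg, probs)
  counts <- table(catalog$phenotypes$disease)
  expect_true(all(counts == 4L))
  expect_equal(nrow(catalog$associations), 30L)
  # high sharpness: causal genes sit near the top of their disease's ranking
  ranks <- rank_table(probs)
  mean_rank <- mean(vapply(seq_len(nrow(catalog$associations)), function(i) {
    d <- catalog$associations$disease[i]
    terms <- catalog$phenotypes$term[catalog$phenotypes$disease == d]
    mean(ranks[catalog$associations$gene[i], terms])
  }, numeric(1)))
  expect_lt(mean_rank, 0.15)
})
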