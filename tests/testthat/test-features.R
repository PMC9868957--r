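test_that("TSM counting deduplicates patients and filters mutation classes", {
  rec <- mutation_records(rep("G", 3L), rep("P1", 3L), rep("T", 3L),
                          rep("Missense_Mutation", 3L))
  expect_equal(count_tsm(rec)$by_tumor["G", "T"], 1L)

  empty <- mutation_records(character(), character(), character(), character())
  expect_equal(sum(count_tsm(empty, genes = "G")$total), 0L)

  # unknown classes are skipped with a reported count
  rec2 <- rbind(rec, mutation_records("G", "P2", "T", "3'Flank"))
  expect_message(out <- count_tsm(rec2), "1 record")
  expect_equal(out$n_skipped, 1L)
  expect_equal(unname(out$total["G"]), 1L)

  # Silent counts in all mode, not in protein_changing mode
  rec3 <- rbind(rec, mutation_records("G", "P3", "T", "Silent"))
  expect_equal(unname(count_tsm(rec3, "all")$total["G"]), 2L)
  expect_equal(unname(count_tsm(rec3, "protein_changing")$total["G"]), 1L)
})

test_that("TSM counts equal the nested-loop oracle and are order invariant", {
  for (seed in 1:10) {
    rec <- random_maf(seed)
    for (mode in c("all", "protein_changing")) {
      got <- suppressMessages(count_tsm(rec, mode))
      want <- oracle_tsm(rec, mode)
      expect_identical(got$by_tumor[rownames(want), colnames(want)], want)
    }
    allc <- suppressMessages(count_tsm(rec, "all"))$total
    pc <- suppressMessages(count_tsm(rec, "protein_changing", genes = names(allc)))$total
    expect_true(all(allc[names(pc)] >= pc))
    shuffled <- rec[sample.int(nrow(rec)), , drop = FALSE]
    expect_identical(suppressMessages(count_tsm(shuffled, "all"))$total, allc)
  }
})

test_that("mean mutation rate averages per-tumor rates with equal weight", {
  rec <- mutation_records(c("G", "G"), c("P1", "P2"), c("T1", "T1"),
                          rep("Missense_Mutation", 2L))
  expect_equal(unname(mean_mutation_rate(rec, c(T1 = 4))["G"]), 0.5)
  # absent gene gets rate zero
  expect_equal(unname(mean_mutation_rate(rec, c(T1 = 4), genes = c("G", "H"))["H"]), 0)
  expect_error(mean_mutation_rate(rec, c(T1 = 0)), "sample count")

  for (seed in 1:5) {
    rec <- random_maf(seed, n_records = 80L)
    spt <- stats::setNames(sample(5:20, 3L), sprintf("TT%d", 1:3))
    got <- suppressMessages(mean_mutation_rate(rec, spt))
    want <- oracle_tsm(rec, "all")
    for (g in rownames(want)) {
      expect_equal(unname(got[g]), mean(want[g, names(spt)] / spt))
    }
  }
})

test_that("overlap fraction merges the track and matches the per-base oracle", {
  expect_equal(overlap_fraction(c(0, 100), rbind(c(0, 50))), 0.5)
  expect_equal(overlap_fraction(c(0, 100), rbind(c(0, 60), c(40, 100))), 1.0)
  expect_error(overlap_fraction(c(5, 5), rbind(c(0, 10))), "positive length")

  set.seed(31)
  for (rep in 1:20) {
    region <- sort(sample(0:200, 2L)); if (diff(region) == 0) region[2] <- region[2] + 1
    track <- cbind(start = sample(0:190, 8L))
    track <- cbind(track, end = track[, 1] + sample(1:30, 8L, replace = TRUE))
    covered <- logical(region[2] - region[1])
    for (i in 1:8) {
      lo <- max(track[i, 1], region[1]); hi <- min(track[i, 2], region[2])
      if (hi > lo) covered[(lo - region[1] + 1):(hi - region[1])] <- TRUE
    }
    expect_equal(overlap_fraction(region, track), mean(covered))
  }
})

test_that("mean signal is base-weighted within cell lines, equal-weighted across", {
  sig <- data.frame(cell_line = c("A", "B", "C"), start = 0, end = 100,
                    value = c(2, 2, 2))
  expect_equal(mean_signal(c(0, 100), sig), 2.0)
  sig2 <- data.frame(cell_line = c("A", "B"), start = 0, end = 100, value = c(1, 3))
  expect_equal(mean_signal(c(0, 100), sig2), 2.0)
  # no coverage anywhere -> missing value
  expect_true(is.na(mean_signal(c(200, 300), sig2)))

  set.seed(5)
  for (rep in 1:10) {
    region <- c(10, 90)
    pieces <- do.call(rbind, lapply(c("A", "B"), function(cl) {
      breaks <- sort(sample(0:100, 5L))
      data.frame(cell_line = cl, start = breaks[-5], end = breaks[-1],
                 value = round(stats::runif(4L), 3))
    }))
    got <- mean_signal(region, pieces)
    per_line <- sapply(c("A", "B"), function(cl) {
      base_vals <- rep(NA_real_, 80)
      s <- pieces[pieces$cell_line == cl, ]
      for (i in seq_len(nrow(s))) {
        lo <- max(s$start[i], 10); hi <- min(s$end[i], 90)
        if (hi > lo) base_vals[(lo - 9):(hi - 10)] <- s$value[i]
      }
      mean(base_vals, na.rm = TRUE)
    })
    expect_equal(got, mean(per_line, na.rm = TRUE), tolerance = 1e-9)
  }
})

test_that("trinucleotide frequencies skip invalid windows and sum to one", {
  f <- trinucleotide_frequencies("AAAA")
  expect_equal(unname(f["AAA"]), 1.0)
  expect_equal(sum(f), 1.0)
  f2 <- trinucleotide_frequencies("ACGT")
  expect_equal(unname(f2[c("ACG", "CGT")]), c(0.5, 0.5))
  # windows containing N are dropped from the denominator
  f3 <- trinucleotide_frequencies("AANACGT")
  expect_equal(unname(f3[c("ACG", "CGT")]), c(0.5, 0.5))
  expect_equal(sum(f3), 1.0)
  expect_error(trinucleotide_frequencies("AC"), "shorter")
  expect_error(trinucleotide_frequencies("NNNNN"), "valid")

  set.seed(13)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300L, replace = TRUE), collapse = "")
    got <- trinucleotide_frequencies(s)
    win <- substring(s, 1:298, 3:300)
    want <- table(factor(win, levels = names(got))) / 298
    expect_equal(unname(got), as.vector(want))
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("feature assembly drops incomplete genes listwise", {
  cfg <- synthetic_config(n_genes = 5L, n_terms = 10L, seed = 2)
  g <- gen_genes(cfg, records = FALSE)
  age <- g$age[-3L, ] # one gene lacks age
  expect_message(tab <- assemble_feature_table(g$tsm, age, g$features), "1 gene")
  expect_equal(nrow(tab), 4L)
  expect_equal(attr(tab, "n_dropped"), 1L)
  expect_error(assemble_feature_table(g$tsm, data.frame(gene = "ZZ", age = 1),
                                      g$features), "no gene")
})

test_that("standardize-and-PCA drops TTT, retains 80 orthonormal components", {
  cfg <- synthetic_config(n_genes = 200L, n_terms = 10L, seed = 3)
  g <- gen_genes(cfg, records = FALSE)
  pv <- standardize_and_pca(g$features)
  expect_equal(dim(pv$loadings), c(80L, 80L))
  expect_equal(ncol(pv$scores), 80L)
  expect_false("tri_TTT" %in% pv$feature_names)
  # orthonormal loadings and zero-mean scores
  expect_equal(crossprod(pv$loadings), diag(80), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(pv$scores))), 1e-10)
  # reconstruction of the standardized matrix
  z <- sweep(sweep(as.matrix(g$features[, pv$feature_names]), 2, pv$center),
             2, pv$scale, "/")
  expect_equal(pv$scores %*% t(pv$loadings), z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # explained variances equal the eigenvalues of the standardized covariance
  ev <- sort(eigen(stats::cov(z), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(pv$sdev^2, ev, tolerance = 1e-8)
  # scores are uncorrelated
  cors <- stats::cor(pv$scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)

  # a perfectly collinear feature pair pushes the smallest eigenvalue to zero
  feats <- g$features
  feats$dnase_gene <- 2 * feats$dnase_cds + 1
  pv2 <- standardize_and_pca(feats)
  expect_lt(min(pv2$sdev^2), 1e-10)

  feats$dnase_gene <- 1
  expect_error(standardize_and_pca(feats), "dnase_gene")
})

test_that("MAF reader enforces required columns and patient truncation", {
  f <- tempfile()
  writeLines(c("Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode",
               "BRCA1\tMissense_Mutation\tTCGA-AB-1234-01A",
               "TP53\tSilent\tTCGA-CD-5678-01A"), f)
  rec <- read_maf(f, tumor_type = "COHORT")
  expect_equal(rec$tumor_type, rep("COHORT", 2L))
  expect_equal(rec$patient[1L], "TCGA-AB-1234-01A")
  rec2 <- read_maf(f, tumor_type = "COHORT", patient_id = "patient")
  expect_equal(rec2$patient, c("TCGA-AB-1234", "TCGA-CD-5678"))
  bad <- tempfile(); writeLines("Hugo_Symbol\tOther", bad)
  expect_error(read_maf(bad, tumor_type = "X"), "missing required column")
})
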