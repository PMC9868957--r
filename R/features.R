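#' Somatic mutation classes counted towards TSM
#'
#' The nine variant classifications that contribute to the total
#' somatic-mutation count. Both the "Nonsense_Mutation" and the hyphenated
#' "Non-sense_Mutation" spellings seen in the wild are accepted. In
#' \code{protein_changing} mode \code{Silent} is additionally excluded.
#'
#' @return Character vector of classification strings.
#' @export
tsm_mutation_classes <- function() {
  c("Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Missense_Mutation", "Nonsense_Mutation", "Non-sense_Mutation",
    "Silent", "Splice_Site", "Translation_Start_Site")
}

#' Read a MAF-like somatic mutation table
#'
#' Requires the columns \code{Hugo_Symbol}, \code{Variant_Classification} and
#' \code{Tumor_Sample_Barcode}. The cohort (tumor type) label is taken from
#' \code{tumor_col} when present, else from the per-file \code{tumor_type}
#' argument. Patient identity defaults to the full sample barcode; with
#' \code{patient_id = "patient"} the barcode is truncated to its first three
#' dash-separated fields (TCGA patient convention).
#'
#' @param path path to a tab-separated MAF file (comment lines start with #).
#' @param tumor_type cohort label applied to every record in the file.
#' @param tumor_col optional name of a column holding per-record cohort labels.
#' @param patient_id \code{"barcode"} (default) or \code{"patient"}.
#' @return A data frame of mutation records with columns \code{gene},
#'   \code{patient}, \code{tumor_type}, \code{classification}.
#' @export
read_maf <- function(path, tumor_type = NULL, tumor_col = NULL,
                     patient_id = c("barcode", "patient")) {
  patient_id <- match.arg(patient_id)
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                          check.names = FALSE)
  need <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MAF is missing required column(s): ", paste(miss, collapse = ", "))
  tumor <- if (!is.null(tumor_col)) {
    if (!tumor_col %in% names(df)) stop("tumor_col not found: ", tumor_col)
    df[[tumor_col]]
  } else if (!is.null(tumor_type)) rep(tumor_type, nrow(df)) else
    stop("supply tumor_type or tumor_col")
  patient <- df$Tumor_Sample_Barcode
  if (patient_id == "patient") {
    patient <- vapply(strsplit(patient, "-", fixed = TRUE),
                      function(p) paste(p[seq_len(min(3L, length(p)))], collapse = "-"), "")
  }
  mutation_records(df$Hugo_Symbol, patient, tumor, df$Variant_Classification)
}

#' @rdname read_maf
#' @param gene,patient,tumor,classification parallel vectors building records
#'   directly (the in-memory constructor used by the synthetic generator).
#' @export
mutation_records <- function(gene, patient, tumor, classification) {
  data.frame(gene = as.character(gene), patient = as.character(patient),
             tumor_type = as.character(tumor),
             classification = as.character(classification),
             stringsAsFactors = FALSE)
}

#' Count patients with somatic mutations per gene and tumor type
#'
#' TSM (total somatic mutations) for a gene is the number of distinct patients
#' carrying at least one somatic mutation in the gene, summed over tumor
#' types: a patient contributes at most one count to a (gene, tumor) cell no
#' matter how many mutation records they have there. Only the recognised
#' mutation classes (\code{\link{tsm_mutation_classes}}) are counted; in
#' \code{protein_changing} mode records classified \code{Silent} are also
#' excluded. Records with an unrecognised classification are skipped and their
#' number reported.
#'
#' @param records mutation record data frame (see \code{\link{read_maf}}).
#' @param mode \code{"all"} or \code{"protein_changing"}.
#' @param genes optional gene universe; genes without records get zero counts.
#' @return A list with \code{by_tumor} (gene x tumor integer matrix),
#'   \code{total} (named integer vector, the TSM variable) and
#'   \code{n_skipped} (records with unknown classification).
#' @export
count_tsm <- function(records, mode = c("all", "protein_changing"), genes = NULL) {
  mode <- match.arg(mode)
  ok <- records$classification %in% tsm_mutation_classes()
  n_skipped <- sum(!ok)
  if (n_skipped) message(n_skipped, " record(s) with unknown classification skipped")
  keep <- records[ok, , drop = FALSE]
  if (mode == "protein_changing") keep <- keep[keep$classification != "Silent", , drop = FALSE]
  keep <- unique(keep[, c("gene", "patient", "tumor_type")])
  gene_levels <- sort(unique(c(keep$gene, genes)))
  tumor_levels <- sort(unique(c(keep$tumor_type, records$tumor_type)))
  by_tumor <- table(factor(keep$gene, levels = gene_levels),
                    factor(keep$tumor_type, levels = tumor_levels))
  by_tumor <- matrix(as.integer(by_tumor), nrow = length(gene_levels),
                     dimnames = list(gene_levels, tumor_levels))
  list(by_tumor = by_tumor, total = rowSums(by_tumor), n_skipped = n_skipped)
}

#' Per-gene mutation rate averaged over tumor types
#'
#' The robustness variant of TSM that weighs all tumor types equally
#' regardless of cohort size: for each tumor type the rate is the number of
#' patients with a mutation in the gene divided by the cohort's sample count;
#' the returned value is the unweighted mean of these rates across all tumor
#' types in \code{samples_per_tumor}.
#'
#' @inheritParams count_tsm
#' @param samples_per_tumor named numeric vector of cohort sample counts; must
#'   cover every tumor type present in \code{records}, all counts positive.
#' @return Named numeric vector of mean rates (0 for genes without records).
#' @export
mean_mutation_rate <- function(records, samples_per_tumor, mode = "all", genes = NULL) {
  if (any(samples_per_tumor <= 0)) stop("zero or negative sample count for tumor type(s): ",
                                        paste(names(samples_per_tumor)[samples_per_tumor <= 0], collapse = ", "))
  missing_t <- setdiff(unique(records$tumor_type), names(samples_per_tumor))
  if (length(missing_t)) stop("no sample count for tumor type(s): ", paste(missing_t, collapse = ", "))
  cnt <- count_tsm(records, mode = mode, genes = genes)
  tumors <- names(samples_per_tumor)
  mat <- matrix(0L, nrow = nrow(cnt$by_tumor), ncol = length(tumors),
                dimnames = list(rownames(cnt$by_tumor), tumors))
  shared <- intersect(colnames(cnt$by_tumor), tumors)
  mat[, shared] <- cnt$by_tumor[, shared]
  rates <- sweep(mat, 2L, samples_per_tumor[tumors], "/")
  rowMeans(rates)
}

as_iranges <- function(x) {
  if (inherits(x, "IRanges")) return(x)
  if (is.numeric(x) && length(x) == 2L) x <- matrix(x, nrow = 1L)
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  # 0-based half-open [start, end) -> IRanges 1-based closed
  IRanges::IRanges(start = as.integer(x[, 1L]) + 1L, end = as.integer(x[, 2L]))
}

#' Fraction of a region covered by an interval track
#'
#' Track intervals are merged before intersection so overlapping track
#' entries are never double counted. Coordinates are 0-based half-open
#' (BED convention); intervals must already be on the same chromosome.
#'
#' @param region numeric \code{c(start, end)} or a one-row interval.
#' @param track intervals as a two-column matrix/data frame or an
#'   \code{IRanges}.
#' @return Covered bases divided by region length, in [0, 1].
#' @export
overlap_fraction <- function(region, track) {
  r <- as_iranges(region)
  if (length(r) != 1L || IRanges::width(r) < 1L) stop("region must be a single interval of positive length")
  tr <- IRanges::reduce(as_iranges(track))
  sum(IRanges::width(IRanges::intersect(tr, r))) / IRanges::width(r)
}

#' Base-weighted mean signal over a region, averaged across cell lines
#'
#' Within each cell line the signal is averaged over the bases of the region
#' it covers (base-weighted); the per-cell-line means are then averaged with
#' equal weight. Cell lines with no coverage of the region are dropped; if no
#' cell line covers the region the result is \code{NA} (the caller flags the
#' gene).
#'
#' @param region numeric \code{c(start, end)}, 0-based half-open.
#' @param signal data frame with columns \code{cell_line}, \code{start},
#'   \code{end}, \code{value} (bedGraph-style intervals).
#' @param cell_lines cell lines to average over; defaults to those present.
#' @return A single numeric value, or \code{NA_real_} if uncovered.
#' @export
mean_signal <- function(region, signal, cell_lines = unique(signal$cell_line)) {
  r <- as_iranges(region)
  per_line <- vapply(cell_lines, function(cl) {
    s <- signal[signal$cell_line == cl, , drop = FALSE]
    if (!nrow(s)) return(NA_real_)
    iv <- as_iranges(s[, c("start", "end")])
    ov <- IRanges::pintersect(IRanges::findOverlapPairs(iv, r))
    if (!length(ov)) return(NA_real_)
    w <- IRanges::width(ov)
    hits <- S4Vectors::queryHits(IRanges::findOverlaps(iv, r))
    sum(s$value[hits] * w) / sum(w)
  }, numeric(1))
  if (all(is.na(per_line))) return(NA_real_)
  mean(per_line, na.rm = TRUE)
}

#' Trinucleotide frequencies of a coding sequence
#'
#' Overlapping windows of width 3 at step 1 on the gene strand; windows
#' containing any non-ACGT character are skipped and the denominator reduced,
#' so the 64 frequencies always sum to 1 when at least one valid window
#' exists.
#'
#' @param cds a nucleotide string (or \code{DNAString}).
#' @return Named numeric vector of 64 frequencies (Biostrings order).
#' @export
trinucleotide_frequencies <- function(cds) {
  s <- Biostrings::DNAString(as.character(cds))
  if (length(s) < 3L) stop("CDS shorter than 3 nt")
  counts <- Biostrings::trinucleotideFrequency(s, step = 1L)
  n <- sum(counts)
  if (n == 0L) stop("no valid ACGT trinucleotide window in CDS")
  counts / n
}

#' Canonical genomic/epigenomic feature schema
#'
#' The 81 per-gene variables: coding-sequence length; DNase accessibility at
#' gene and CDS level; H3K4me1/H3K4me3/H3K27ac overlap at gene and CDS level;
#' lamin B1 association; replication timing; nucleosome signal at gene and CDS
#' level; transcription; simple-repeat overlap at gene and CDS level;
#' recombination rate; and the 64 CDS trinucleotide frequencies
#' (\code{tri_AAA} ... \code{tri_TTT}).
#'
#' @return Character vector of 81 column names in canonical order.
#' @export
genomic_feature_names <- function() {
  c("cds_length", "dnase_gene", "dnase_cds",
    "h3k4me1_gene", "h3k4me1_cds", "h3k4me3_gene", "h3k4me3_cds",
    "h3k27ac_gene", "h3k27ac_cds", "laminb1_gene", "repli_timing_gene",
    "nucleosome_gene", "nucleosome_cds", "transcription_gene",
    "repeat_gene", "repeat_cds", "recombination_gene",
    paste0("tri_", Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3L)))
}

#' Assemble the gene-by-feature table
#'
#' Joins TSM counts, gene age, the genomic/epigenomic features and (optionally)
#' a cancer-driver flag and the binary phenotype-involvement label on gene
#' symbol. Genes missing any required variable are dropped listwise (never
#' imputed) and the number of drops is reported.
#'
#' @param tsm named numeric vector of per-gene TSM (or mean mutation rate).
#' @param age data frame with columns \code{gene}, \code{age} (integers 1-20).
#' @param features data frame with a \code{gene} column plus the 81 columns of
#'   \code{\link{genomic_feature_names}}.
#' @param driver optional named binary vector (cancer driver status).
#' @param ipa optional named binary vector of labels.
#' @return A data frame (class \code{gene_feature_table}) with columns
#'   \code{gene}, \code{tsm}, \code{age}, the 81 features, then \code{driver}
#'   and \code{ipa} when supplied; attribute \code{n_dropped} records the
#'   listwise deletions.
#' @export
assemble_feature_table <- function(tsm, age, features, driver = NULL, ipa = NULL) {
  fn <- genomic_feature_names()
  miss <- setdiff(fn, names(features))
  if (length(miss)) stop("features table missing column(s): ", paste(utils::head(miss, 5L), collapse = ", "))
  universe <- unique(c(names(tsm), age$gene, features$gene))
  genes <- intersect(intersect(names(tsm), age$gene), features$gene)
  if (!is.null(driver)) genes <- intersect(genes, names(driver))
  if (!is.null(ipa)) genes <- intersect(genes, names(ipa))
  tab <- data.frame(gene = genes,
                    tsm = as.numeric(tsm[genes]),
                    age = as.integer(age$age[match(genes, age$gene)]),
                    features[match(genes, features$gene), fn, drop = FALSE],
                    stringsAsFactors = FALSE)
  if (!is.null(driver)) tab$driver <- as.integer(driver[genes])
  if (!is.null(ipa)) tab$ipa <- as.integer(ipa[genes])
  complete <- stats::complete.cases(tab)
  n_dropped <- length(universe) - sum(complete)
  if (n_dropped) message(n_dropped, " gene(s) dropped for missing variables")
  tab <- tab[complete, , drop = FALSE]
  if (!nrow(tab)) stop("no gene has all required variables")
  rownames(tab) <- NULL
  structure(tab, n_dropped = n_dropped,
            class = c("gene_feature_table", "data.frame"))
}

#' @export
print.gene_feature_table <- function(x, ...) {
  cat("Gene feature table:", nrow(x), "genes,",
      length(intersect(genomic_feature_names(), names(x))), "genomic features",
      if ("ipa" %in% names(x)) sprintf("| positives: %d (%.1f%%)", sum(x$ipa), 100 * mean(x$ipa)) else "",
      "\n")
  invisible(x)
}

#' Standardize the genomic features and rotate to principal components
#'
#' Drops the \code{tri_TTT} frequency (exactly collinear with the other 63
#' trinucleotide frequencies), standardizes the remaining 80 features to zero
#' mean and unit standard deviation, and rotates them to principal components.
#' All 80 components are retained: the rotation removes collinearity for the
#' multivariable logistic model without discarding variance.
#'
#' @param table a \code{\link{assemble_feature_table}} result, or a numeric
#'   matrix/data frame of the 81 genomic features.
#' @return An object of class \code{pc_view}: \code{scores} (genes x 80),
#'   \code{loadings} (80 x 80 orthonormal), \code{sdev}, \code{center},
#'   \code{scale}, \code{dropped_feature}, \code{feature_names}.
#' @export
standardize_and_pca <- function(table) {
  fn <- genomic_feature_names()
  m <- as.matrix(as.data.frame(table)[, intersect(fn, colnames(table)), drop = FALSE])
  if (!all(fn %in% colnames(m))) stop("input lacks the canonical 81 genomic features")
  m <- m[, setdiff(fn, "tri_TTT"), drop = FALSE]
  if (nrow(m) <= ncol(m)) stop("need more genes than features (>= ", ncol(m) + 1L, ")")
  if (anyNA(m)) stop("missing values in feature matrix")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) stop("constant feature column(s): ",
                          paste(colnames(m)[sds == 0], collapse = ", "))
  ctr <- colMeans(m)
  z <- sweep(sweep(m, 2L, ctr), 2L, sds, "/")
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  structure(list(scores = p$x, loadings = p$rotation, sdev = p$sdev,
                 center = ctr, scale = sds,
                 dropped_feature = "tri_TTT", feature_names = colnames(m)),
            class = "pc_view")
}

#' @export
print.pc_view <- function(x, ...) {
  ev <- x$sdev^2
  cat("PCA view: ", nrow(x$scores), " genes x ", ncol(x$scores),
      " components (dropped ", x$dropped_feature, ")\n", sep = "")
  cat("  variance explained by PC1-PC5: ",
      paste(sprintf("%.1f%%", 100 * ev[1:5] / sum(ev)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project new genes onto an existing principal-component basis
#'
#' @param object a \code{pc_view}.
#' @param newdata data frame or matrix holding the 81 genomic features.
#' @param ... unused.
#' @return Matrix of component scores for the new genes.
#' @export
predict.pc_view <- function(object, newdata, ...) {
  m <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  z <- sweep(sweep(m, 2L, object$center), 2L, object$scale, "/")
  z %*% object$loadings
}
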