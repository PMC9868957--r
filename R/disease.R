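#' Rank-transform model probabilities
#'
#' Genes are ranked by decreasing model probability, so the gene with the
#' highest probability receives rank 1, and ranks are normalized by the
#' number of genes: a normalized rank in (0, 1], lower meaning a stronger
#' predicted gene-phenotype association. Ties receive midranks.
#'
#' @param probabilities named numeric vector of per-gene probabilities for one
#'   phenotype.
#' @return Named numeric vector of normalized ranks in (0, 1].
#' @export
rank_transform <- function(probabilities) {
  if (!length(probabilities)) stop("empty probability vector")
  rank(-probabilities, ties.method = "average") / length(probabilities)
}

#' Normalized-rank table for a set of phenotype models
#'
#' @param prob_matrix genes x terms matrix of probabilities (e.g.
#'   \code{\link{phenotype_probabilities}}).
#' @return Matrix of normalized ranks, same shape.
#' @export
rank_table <- function(prob_matrix) {
  apply(as.matrix(prob_matrix), 2L, rank_transform)
}

#' Disease catalog of phenotype and gene associations
#'
#' @param phenotypes data frame with columns \code{disease}, \code{term}.
#' @param associations data frame with columns \code{disease}, \code{gene}.
#' @return An object of class \code{disease_catalog}.
#' @export
disease_catalog <- function(phenotypes, associations) {
  phen <- unique(data.frame(disease = as.character(phenotypes$disease),
                            term = as.character(phenotypes$term)))
  asc <- data.frame(disease = as.character(associations$disease),
                    gene = as.character(associations$gene))
  if (!nrow(phen)) stop("empty phenotype list")
  no_phen <- setdiff(unique(asc$disease), unique(phen$disease))
  if (length(no_phen)) stop("association(s) to disease(s) without phenotypes: ",
                            paste(utils::head(no_phen, 5L), collapse = ", "))
  structure(list(phenotypes = phen, associations = asc), class = "disease_catalog")
}

#' @export
print.disease_catalog <- function(x, ...) {
  cat("Disease catalog:", length(unique(x$phenotypes$disease)), "diseases,",
      nrow(x$phenotypes), "disease-phenotype pairs,",
      nrow(x$associations), "gene-disease associations\n")
  invisible(x)
}

#' Read / write a disease catalog as two TSV files
#'
#' Dialects match OMIM/Orphanet phenotype-annotation exports after column
#' selection: tab-separated (disease_id, term_id) and (disease_id,
#' gene_symbol), no header.
#'
#' @param phenotype_path,association_path file paths.
#' @return \code{read_disease_catalog}: a \code{\link{disease_catalog}}.
#' @export
read_disease_catalog <- function(phenotype_path, association_path) {
  ph <- utils::read.delim(phenotype_path, header = FALSE, colClasses = "character")
  as <- utils::read.delim(association_path, header = FALSE, colClasses = "character")
  disease_catalog(data.frame(disease = ph[[1L]], term = ph[[2L]]),
                  data.frame(disease = as[[1L]], gene = as[[2L]]))
}

#' @rdname read_disease_catalog
#' @param catalog a \code{\link{disease_catalog}}.
#' @export
write_disease_catalog <- function(catalog, phenotype_path, association_path) {
  utils::write.table(catalog$phenotypes, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(catalog$associations, association_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

# map a disease's phenotype terms to scored terms, collapsing duplicates and
# dropping terms with no scored ancestor (with a warning)
map_disease_terms <- function(catalog, scored, o = NULL, gene_counts = NULL) {
  diseases <- unique(catalog$phenotypes$disease)
  dropped <- 0L
  out <- lapply(diseases, function(d) {
    terms <- unique(catalog$phenotypes$term[catalog$phenotypes$disease == d])
    mapped <- vapply(terms, function(t) {
      if (t %in% scored) t
      else if (is.null(o)) NA_character_
      else closest_scored_ancestor(t, scored, o, gene_counts)
    }, "")
    dropped <<- dropped + sum(is.na(mapped))
    unique(mapped[!is.na(mapped)])
  })
  if (dropped) warning(dropped, " disease phenotype(s) had no scored ancestor and were dropped")
  stats::setNames(out, diseases)
}

#' Geometric-mean disease score for one gene-disease pair
#'
#' Each phenotype of the disease is mapped to the closest term with a trained
#' model (itself when scored); duplicates after mapping are collapsed; the
#' score is the geometric mean of the gene's normalized ranks over the mapped
#' terms. Low scores mean strong predicted involvement. Improving (lowering)
#' any constituent rank can only lower the score.
#'
#' @param gene gene symbol.
#' @param disease disease identifier present in the catalog.
#' @param ranks genes x terms matrix of normalized ranks
#'   (\code{\link{rank_table}}).
#' @param catalog a \code{\link{disease_catalog}}.
#' @param o ontology used for closest-term mapping (may be \code{NULL} when
#'   every catalog term is scored).
#' @param gene_counts optional tie-break counts for the mapping.
#' @return The score in (0, 1], or \code{NA} if no phenotype maps.
#' @export
disease_score <- function(gene, disease, ranks, catalog, o = NULL, gene_counts = NULL) {
  if (!disease %in% catalog$phenotypes$disease) stop("unknown disease: ", disease)
  terms <- map_disease_terms(
    disease_catalog(catalog$phenotypes[catalog$phenotypes$disease == disease, , drop = FALSE],
                    data.frame(disease = character(), gene = character())),
    scored = colnames(ranks), o = o, gene_counts = gene_counts)[[disease]]
  if (!length(terms)) return(NA_real_)
  geometric_mean(ranks[gene, terms])
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Score every gene-disease association in a catalog
#'
#' @inheritParams disease_score
#' @return Data frame with columns \code{gene}, \code{disease}, \code{score},
#'   \code{n_phenotypes_used} (associations whose disease has no mappable
#'   phenotype get \code{NA} scores and are excluded from enrichment).
#' @export
score_disease_associations <- function(ranks, catalog, o = NULL, gene_counts = NULL) {
  mapped <- map_disease_terms(catalog, scored = colnames(ranks), o = o,
                              gene_counts = gene_counts)
  asc <- catalog$associations
  score <- score_mapped_genes(asc$gene, split(seq_len(nrow(asc)), asc$disease),
                              mapped, ranks)
  npx <- vapply(asc$disease, function(d) length(mapped[[d]]) %||% 0L, 1L)
  data.frame(gene = asc$gene, disease = asc$disease, score = score,
             n_phenotypes_used = as.integer(npx), stringsAsFactors = FALSE)
}

# geometric-mean scores for an association gene vector given fixed per-disease
# mapped term sets and a fixed disease->row grouping
score_mapped_genes <- function(genes, rows_by_disease, mapped, ranks) {
  score <- rep(NA_real_, length(genes))
  for (d in names(rows_by_disease)) {
    terms <- mapped[[d]]
    idx <- rows_by_disease[[d]]
    if (is.null(terms) || !length(terms)) next
    lr <- log(ranks[genes[idx], terms, drop = FALSE])
    score[idx] <- exp(rowMeans(lr))
  }
  score
}

#' Randomize gene-disease associations
#'
#' Permutes the gene column of the association list uniformly without
#' replacement, preserving per-disease association counts and the global gene
#' multiset (both marginals of the association bipartite graph). Each
#' permutation is independently seeded from the master seed.
#'
#' @param catalog a \code{\link{disease_catalog}}.
#' @param n_randomizations number of permuted catalogs (default 100).
#' @param seed master seed.
#' @return List of \code{disease_catalog}s with permuted gene columns.
#' @export
randomize_associations <- function(catalog, n_randomizations = 100L, seed = 1L) {
  if (!nrow(catalog$associations)) stop("empty association list")
  lapply(seq_len(n_randomizations), function(i) {
    set.seed(seed + i)
    perm <- catalog
    perm$associations$gene <- sample(perm$associations$gene)
    perm
  })
}

#' Permutation-null enrichment of disease scores
#'
#' Observed and permuted score sets are binned into \code{n_bins} equal-width
#' intervals on [0, 1]. For each bin the empirical p-value is
#' (1 + number of null sets whose count reaches the observed count) /
#' (1 + number of null sets) — the add-one correction keeps p positive with
#' finite permutations — and bins with p below \code{alpha} are flagged as
#' enriched. The aggregate count of scores below \code{low_cutoff} is tested
#' the same way: true gene-disease associations concentrate at low scores.
#'
#' @param observed_scores numeric scores in (0, 1] (NAs dropped).
#' @param null_score_sets list of numeric score vectors from permuted
#'   catalogs, each the same cardinality as the observed set.
#' @param n_bins number of bins (default 20).
#' @param alpha flagging threshold on the empirical p (default 0.01).
#' @param low_cutoff low-score aggregate cutoff (default 0.15).
#' @return An object of class \code{disease_score_result}: \code{bin_counts},
#'   \code{null_bin_counts} (matrix sets x bins), \code{bin_pvalues},
#'   \code{flagged_bins}, \code{low_score} (observed count, null mean and p
#'   below the cutoff), \code{breaks}, plus the inputs.
#' @export
bin_enrichment <- function(observed_scores, null_score_sets, n_bins = 20L,
                           alpha = 0.01, low_cutoff = 0.15) {
  obs <- observed_scores[!is.na(observed_scores)]
  if (any(obs <= 0 | obs > 1)) stop("scores must lie in (0, 1]")
  if (!length(null_score_sets)) stop("need at least one null score set")
  bin_of <- function(s) pmin(pmax(ceiling(s * n_bins), 1L), n_bins)
  count_bins <- function(s) tabulate(bin_of(s[!is.na(s)]), nbins = n_bins)
  obs_counts <- count_bins(obs)
  null_counts <- t(vapply(null_score_sets, count_bins, integer(n_bins)))
  R <- nrow(null_counts)
  pvals <- vapply(seq_len(n_bins), function(b) {
    (1 + sum(null_counts[, b] >= obs_counts[b])) / (1 + R)
  }, numeric(1))
  low_obs <- sum(obs < low_cutoff)
  low_null <- vapply(null_score_sets, function(s) sum(s[!is.na(s)] < low_cutoff), integer(1))
  low_p <- (1 + sum(low_null >= low_obs)) / (1 + R)
  structure(list(bin_counts = obs_counts, null_bin_counts = null_counts,
                 bin_pvalues = pvals, flagged_bins = which(pvals < alpha),
                 breaks = seq(0, 1, length.out = n_bins + 1L),
                 low_score = list(cutoff = low_cutoff, observed = low_obs,
                                  null_mean = mean(low_null), p_value = low_p,
                                  flagged = low_p < alpha),
                 observed_scores = obs, n_randomizations = R, alpha = alpha),
            class = "disease_score_result")
}

#' @export
print.disease_score_result <- function(x, ...) {
  cat("Disease-score enrichment:", length(x$observed_scores), "scored associations,",
      x$n_randomizations, "randomizations,", length(x$bin_counts), "bins\n")
  cat(sprintf("  flagged bins (p < %.2g): %s\n", x$alpha,
              if (length(x$flagged_bins)) paste(x$flagged_bins, collapse = ", ") else "none"))
  cat(sprintf("  scores < %.2f: observed %d vs null mean %.1f (p = %.3g%s)\n",
              x$low_score$cutoff, x$low_score$observed, x$low_score$null_mean,
              x$low_score$p_value, if (x$low_score$flagged) ", enriched" else ""))
  invisible(x)
}

#' @export
plot.disease_score_result <- function(x, ...) {
  mids <- (x$breaks[-1L] + x$breaks[-length(x$breaks)]) / 2
  ylim <- c(0, max(x$bin_counts, colMeans(x$null_bin_counts)) * 1.15)
  graphics::barplot(x$bin_counts, names.arg = sprintf("%.2f", mids), las = 2,
                    col = "grey85", border = "grey40", ylim = ylim,
                    xlab = "disease score", ylab = "associations", ...)
  at <- seq_along(mids) * 1.2 - 0.5
  graphics::points(at, colMeans(x$null_bin_counts), pch = 16)
  if (length(x$flagged_bins)) {
    graphics::points(at[x$flagged_bins],
                     x$bin_counts[x$flagged_bins] + 0.05 * ylim[2L],
                     pch = 17, col = "red")
  }
  invisible(x)
}

#' End-to-end disease scoring with a permutation null
#'
#' Scores every catalogued gene-disease association, generates
#' \code{n_randomizations} permuted catalogs, rescales them identically and
#' runs \code{\link{bin_enrichment}}.
#'
#' @inheritParams score_disease_associations
#' @inheritParams bin_enrichment
#' @param n_randomizations number of catalog permutations.
#' @param seed master seed for the permutations.
#' @return A \code{disease_score_result} with the per-association score table
#'   attached as \code{$scores_table}.
#' @export
score_diseases <- function(ranks, catalog, o = NULL, gene_counts = NULL,
                           n_randomizations = 100L, n_bins = 20L, alpha = 0.01,
                           low_cutoff = 0.15, seed = 1L) {
  mapped <- map_disease_terms(catalog, scored = colnames(ranks), o = o,
                              gene_counts = gene_counts)
  asc <- catalog$associations
  rows_by_disease <- split(seq_len(nrow(asc)), asc$disease)
  obs_score <- score_mapped_genes(asc$gene, rows_by_disease, mapped, ranks)
  tab <- data.frame(gene = asc$gene, disease = asc$disease, score = obs_score,
                    n_phenotypes_used = vapply(asc$disease, function(d)
                      length(mapped[[d]]) %||% 0L, 1L),
                    stringsAsFactors = FALSE)
  perms <- randomize_associations(catalog, n_randomizations, seed = seed)
  null_sets <- lapply(perms, function(p) {
    score_mapped_genes(p$associations$gene, rows_by_disease, mapped, ranks)
  })
  res <- bin_enrichment(tab$score, null_sets, n_bins = n_bins, alpha = alpha,
                        low_cutoff = low_cutoff)
  res$scores_table <- tab
  res
}
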