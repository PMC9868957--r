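# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own graph/statistics code paths.

# random rooted DAG: term i > 1 draws 1-2 parents uniformly among 1..i-1
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[1L]] <- character()
  for (i in seq_len(n_terms)[-1L]) {
    np <- min(i - 1L, sample(1:2, 1L))
    pool <- seq_len(i - 1L)
    parents[[i]] <- ids[pool[sample.int(length(pool), np)]]
  }
  ontology(ids, parents)
}

# descendants by repeated one-step expansion to fixpoint
oracle_descendants <- function(o, t) {
  out <- character()
  repeat {
    step <- unique(unlist(lapply(c(t, out), function(x) o$children[[x]]), use.names = FALSE))
    nxt <- union(out, step)
    if (setequal(nxt, out)) return(setdiff(out, t))
    out <- nxt
  }
}

oracle_ancestors <- function(o, t) {
  out <- character()
  repeat {
    step <- unique(unlist(lapply(c(t, out), function(x) o$parents[[x]]), use.names = FALSE))
    nxt <- union(out, step)
    if (setequal(nxt, out)) return(setdiff(out, t))
    out <- nxt
  }
}

# delete-then-transitively-close expansion oracle over explicit pair loops
oracle_expand <- function(direct, o, exclude_root) {
  excluded <- c(exclude_root, oracle_descendants(o, exclude_root))
  keys <- character()
  for (i in seq_len(nrow(direct))) {
    t <- direct$term[i]
    if (t %in% excluded) next
    for (tt in c(t, oracle_ancestors(o, t))) {
      keys <- c(keys, paste0(direct$gene[i], "\r", tt))
    }
  }
  sort(unique(keys))
}

pair_keys <- function(ann) {
  if (!length(ann$gene)) return(character(0))
  sort(unique(paste0(ann$gene, "\r", ann$term)))
}

# BFS distance to the nearest scored ancestor (Inf if none)
oracle_scored_distance <- function(o, t, scored) {
  if (t %in% scored) return(0L)
  dist <- 0L
  frontier <- t
  seen <- t
  repeat {
    frontier <- setdiff(unique(unlist(o$parents[frontier], use.names = FALSE)), seen)
    if (!length(frontier)) return(Inf)
    dist <- dist + 1L
    if (length(intersect(frontier, scored))) return(dist)
    seen <- c(seen, frontier)
  }
}

# nested-loop set-cardinality TSM oracle
oracle_tsm <- function(records, mode) {
  allowed <- tsm_mutation_classes()
  if (mode == "protein_changing") allowed <- setdiff(allowed, "Silent")
  keep <- records[records$classification %in% allowed, , drop = FALSE]
  genes <- sort(unique(keep$gene)); tumors <- sort(unique(records$tumor_type))
  m <- matrix(0L, length(genes), length(tumors), dimnames = list(genes, tumors))
  for (g in genes) for (tt in tumors) {
    m[g, tt] <- length(unique(keep$patient[keep$gene == g & keep$tumor_type == tt]))
  }
  m
}

random_maf <- function(seed, n_records = 50L, n_genes = 5L, n_tumors = 3L,
                       n_patients = 10L) {
  set.seed(seed)
  classes <- c(tsm_mutation_classes(), "Weird_Class", "3'UTR")
  mutation_records(
    gene = sample(sprintf("G%d", seq_len(n_genes)), n_records, replace = TRUE),
    patient = sample(sprintf("P%02d", seq_len(n_patients)), n_records, replace = TRUE),
    tumor = sample(sprintf("TT%d", seq_len(n_tumors)), n_records, replace = TRUE),
    classification = sample(classes, n_records, replace = TRUE,
                            prob = c(rep(5, 10), 1, 1)))
}

# O(n^2) pairwise AUROC oracle with half-credit ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# tiny three-term chain C is_a B is_a A as an OBO file
write_chain_obo <- function(path) {
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: A", "name: a", "",
               "[Term]", "id: B", "name: b", "is_a: A", "",
               "[Term]", "id: C", "name: c", "is_a: B", ""), path)
  path
}

chain_ontology <- function() {
  ontology(c("A", "B", "C"), list(A = character(), B = "A", C = "B"))
}
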