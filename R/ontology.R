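#' Construct a phenotype ontology
#'
#' An ontology is a rooted directed acyclic graph of phenotype terms linked by
#' is-a edges (child to parent). Annotation propagation, subtree exclusion and
#' closest-scored-term mapping are all defined over this graph.
#'
#' @param terms character vector of term identifiers.
#' @param parents named list mapping each term to the character vector of its
#'   parent term identifiers (empty for the root).
#' @param labels optional named character vector of human-readable term names.
#' @return An object of class \code{ontology} with elements \code{terms},
#'   \code{parents}, \code{children}, \code{root} and \code{labels}.
#' @export
ontology <- function(terms, parents, labels = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicated term identifiers")
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) as.character(p %||% character()))
  bad <- setdiff(unlist(parents, use.names = FALSE), terms)
  if (length(bad)) {
    stop("is_a reference to undeclared term(s): ", paste(unique(bad), collapse = ", "))
  }
  roots <- terms[vapply(parents, length, 1L) == 0L]
  if (length(roots) == 0L) {
    stop("ontology has no root (every term has a parent); graph cannot be a rooted DAG")
  }
  if (length(roots) > 1L) {
    stop("ontology has multiple roots: ", paste(roots, collapse = ", "))
  }
  check_acyclic(terms, parents)
  children <- split_children(terms, parents)
  structure(
    list(terms = terms, parents = parents, children = children,
         root = roots, labels = labels),
    class = "ontology"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kahn's algorithm over child->parent edges; on failure, names one edge on a cycle.
check_acyclic <- function(terms, parents) {
  indeg <- vapply(parents, length, 1L) # number of outgoing is_a edges, used as in-degree
  children <- split_children(terms, parents)
  queue <- terms[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) {
    left <- terms[indeg > 0L]
    t <- left[[1L]]
    p <- intersect(parents[[t]], left)[[1L]]
    stop("cycle detected in ontology; edge on a cycle: ", t, " is_a ", p)
  }
  invisible(TRUE)
}

split_children <- function(terms, parents) {
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (i in seq_along(terms)) children[[i]] <- character()
  for (t in terms) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  children
}

#' @export
print.ontology <- function(x, ...) {
  n_leaf <- sum(vapply(x$children, length, 1L) == 0L)
  cat("Phenotype ontology:", length(x$terms), "terms,",
      sum(vapply(x$parents, length, 1L)), "is-a edges\n")
  cat("  root:", x$root, if (!is.null(x$labels)) paste0("(", x$labels[[x$root]], ")") else "", "\n")
  cat("  leaves:", n_leaf, "\n")
  invisible(x)
}

#' Read an ontology from an OBO 1.2 flat file
#'
#' Supports the subset of OBO used by phenotype ontologies: \code{[Term]}
#' stanzas with \code{id}, \code{name}, \code{is_a}, \code{alt_id} and
#' \code{is_obsolete} lines. Obsolete terms are dropped with a warning;
#' alternate identifiers are resolved to primary identifiers, including when
#' they appear as is-a targets. Trailing \code{!} comments on is_a lines are
#' ignored.
#'
#' @param path path to an OBO file.
#' @return An \code{\link{ontology}}.
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas in ", path)
  ends <- c(stanza_starts[-1L] - 1L, length(lines))
  ids <- character(); nm <- character(); alt <- character(); alt_of <- character()
  parents <- list(); obsolete <- 0L
  for (s in term_starts) {
    e <- ends[match(s, stanza_starts)]
    block <- lines[(s + 1L):e]
    get <- function(key) sub(paste0("^", key, ":\\s*"), "", grep(paste0("^", key, ":"), block, value = TRUE))
    id <- get("id")
    if (length(id) != 1L) stop("[Term] stanza without a single id line near line ", s)
    if (any(grepl("^is_obsolete:\\s*true", block))) { obsolete <- obsolete + 1L; next }
    isa <- trimws(sub("!.*$", "", get("is_a")))
    name <- get("name")
    a <- get("alt_id")
    ids <- c(ids, id)
    nm <- c(nm, if (length(name)) name[[1L]] else NA_character_)
    parents[[id]] <- isa
    if (length(a)) { alt <- c(alt, a); alt_of <- c(alt_of, rep(id, length(a))) }
  }
  if (obsolete) warning(obsolete, " obsolete term(s) dropped")
  alt_map <- stats::setNames(alt_of, alt)
  parents <- lapply(parents, function(p) {
    hit <- p %in% names(alt_map)
    p[hit] <- alt_map[p[hit]]
    unique(p)
  })
  ontology(ids, parents, labels = stats::setNames(nm, ids))
}

#' Write an ontology to an OBO 1.2 flat file
#'
#' Emits the minimal stanza subset that \code{\link{load_obo}} reads, so
#' generated ontologies round-trip through the production parser.
#'
#' @param o an \code{\link{ontology}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_obo <- function(o, path) {
  stopifnot(inherits(o, "ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in o$terms) {
    lab <- if (!is.null(o$labels) && !is.na(o$labels[[t]])) o$labels[[t]] else t
    writeLines(c("[Term]", paste0("id: ", t), paste0("name: ", lab),
                 paste0("is_a: ", o$parents[[t]], recycle0 = TRUE), ""), con)
  }
  invisible(path)
}

#' Descendants of a term
#'
#' Transitive closure of the child relation, excluding the term itself.
#'
#' @param o an \code{\link{ontology}}.
#' @param t a term identifier.
#' @return Character vector of descendant terms (possibly empty).
#' @export
descendants <- function(o, t) {
  stopifnot(inherits(o, "ontology"))
  if (!t %in% o$terms) stop("unknown term: ", t)
  out <- character(); frontier <- o$children[[t]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(o$children[frontier], use.names = FALSE))
  }
  out
}

#' Ancestors of a term
#'
#' Transitive closure of the parent relation, excluding the term itself.
#'
#' @inheritParams descendants
#' @return Character vector of ancestor terms (possibly empty for the root).
#' @export
ancestors <- function(o, t) {
  stopifnot(inherits(o, "ontology"))
  if (!t %in% o$terms) stop("unknown term: ", t)
  out <- character(); frontier <- o$parents[[t]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(o$parents[frontier], use.names = FALSE))
  }
  out
}

#' Create a gene-term annotation set
#'
#' @param gene character vector of gene symbols.
#' @param term character vector of term identifiers, parallel to \code{gene}.
#' @param state \code{"direct"} (as curated) or \code{"expanded"} (closed under
#'   the ancestor relation).
#' @return A data frame of unique (gene, term) pairs with class
#'   \code{annotation_set} and a \code{state} attribute.
#' @export
annotation_set <- function(gene, term, state = c("direct", "expanded")) {
  state <- match.arg(state)
  df <- unique(data.frame(gene = as.character(gene), term = as.character(term),
                          stringsAsFactors = FALSE))
  df <- df[order(df$gene, df$term), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, state = state, class = c("annotation_set", "data.frame"))
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set (", attr(x, "state"), "): ", nrow(x), " gene-term pairs, ",
      length(unique(x$gene)), " genes, ", length(unique(x$term)), " terms\n", sep = "")
  invisible(x)
}

#' Read / write gene-term annotations as two-column TSV
#'
#' The dialect matches gene-to-phenotype exports after column selection:
#' tab-separated \code{gene_symbol}, \code{term_id}; a header line is detected
#' and skipped if its second field does not look like a term identifier
#' (no colon or digit).
#'
#' @param path file path.
#' @param state annotation state to stamp on the result.
#' @return \code{read_annotation_tsv}: an \code{\link{annotation_set}}.
#' @export
read_annotation_tsv <- function(path, state = "direct") {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("annotation TSV needs >= 2 columns")
  if (nrow(df) && !grepl("[:0-9]", df[1L, 2L])) df <- df[-1L, , drop = FALSE]
  annotation_set(df[[1L]], df[[2L]], state = state)
}

#' @rdname read_annotation_tsv
#' @param x an \code{\link{annotation_set}}.
#' @export
write_annotation_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("gene", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Expand annotations to ancestors, excluding a designated subtree
#'
#' Every pair whose term lies at or below \code{exclude_root} is removed first;
#' each surviving pair is then propagated to all ancestors of its term. A gene
#' annotated only inside the excluded subtree therefore loses all annotations,
#' while a gene that also reaches an ancestor through a non-excluded term keeps
#' that path. Applied to a neoplasm-like subtree this implements the rule that
#' cancer phenotype annotations must not count as evidence of germline
#' phenotype involvement.
#'
#' @param direct an \code{\link{annotation_set}} in \code{"direct"} state.
#' @param o an \code{\link{ontology}}.
#' @param exclude_root term identifier of the subtree to remove, or \code{NULL}
#'   to expand without exclusion.
#' @return An \code{\link{annotation_set}} in \code{"expanded"} state.
#' @export
expand_annotations <- function(direct, o, exclude_root = NULL) {
  stopifnot(inherits(direct, "annotation_set"), inherits(o, "ontology"))
  if (attr(direct, "state") != "direct") {
    # idempotence: expanding an expanded set is the identity by construction,
    # but we re-derive it to honour the contract
    direct <- annotation_set(direct$gene, direct$term, state = "direct")
  }
  excluded <- character()
  if (!is.null(exclude_root)) {
    if (!exclude_root %in% o$terms) stop("exclude_root not in ontology: ", exclude_root)
    excluded <- c(exclude_root, descendants(o, exclude_root))
  }
  keep <- direct[!(direct$term %in% excluded) & direct$term %in% o$terms, , drop = FALSE]
  if (!nrow(keep)) return(annotation_set(character(), character(), state = "expanded"))
  anc <- ancestor_closure(o)
  genes <- rep(keep$gene, lengths(anc[keep$term]) + 1L)
  terms <- unlist(Map(function(t) c(t, anc[[t]]), keep$term), use.names = FALSE)
  annotation_set(genes, terms, state = "expanded")
}

# ancestor sets for all terms at once, memoized along a topological order
ancestor_closure <- function(o) {
  order <- topo_order(o)
  anc <- stats::setNames(vector("list", length(o$terms)), o$terms)
  for (t in order) {
    ps <- o$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

topo_order <- function(o) {
  indeg <- vapply(o$parents, length, 1L)
  queue <- o$terms[indeg == 0L]
  out <- character(length(o$terms)); k <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    k <- k + 1L; out[[k]] <- t
    for (ch in o$children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Map a term to the closest term that has a trained model
#'
#' Returns \code{t} itself when scored; otherwise the scored ancestor at
#' minimal upward edge distance (breadth-first search over parent edges).
#' Ties at equal distance are broken by the larger associated-gene count when
#' \code{gene_counts} is supplied, then by lexicographic term identifier, so
#' the mapping is deterministic on multi-parent graphs.
#'
#' @param t query term identifier.
#' @param scored character vector of terms that have models.
#' @param o an \code{\link{ontology}}.
#' @param gene_counts optional named numeric vector of associated-gene counts
#'   used for tie-breaking.
#' @return A term identifier, or \code{NA_character_} if no scored ancestor
#'   exists.
#' @export
closest_scored_ancestor <- function(t, scored, o, gene_counts = NULL) {
  stopifnot(inherits(o, "ontology"))
  if (!t %in% o$terms) stop("unknown term: ", t)
  if (t %in% scored) return(t)
  visited <- t
  frontier <- o$parents[[t]]
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), visited)
    hit <- intersect(frontier, scored)
    if (length(hit)) {
      if (length(hit) > 1L) {
        cnt <- if (is.null(gene_counts)) rep(0, length(hit)) else {
          v <- gene_counts[hit]; v[is.na(v)] <- 0; as.numeric(v)
        }
        hit <- hit[order(-cnt, hit)]
      }
      return(hit[[1L]])
    }
    visited <- c(visited, frontier)
    frontier <- unlist(o$parents[frontier], use.names = FALSE)
  }
  NA_character_
}
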