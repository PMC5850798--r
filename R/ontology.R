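#' @importFrom stats fisher.test p.adjust phyper lm median pnorm quantile
#'   rbinom rlnorm runif setNames coef uniroot sd
#' @importFrom utils read.delim write.table head tail
NULL

# ---------------------------------------------------------------------------
# Ontology graph: a DAG of anatomical terms linked by is_a / part_of edges.
# Internal representation: character vector of term ids, named label vector,
# an edge data.frame (child, parent, relation) and a cached igraph object
# with edges oriented child -> parent.
# ---------------------------------------------------------------------------

#' Construct an ontology graph
#'
#' Builds the DAG of anatomical terms used throughout the package. Edges are
#' oriented child -> parent and typed by relation (`is_a` or `part_of`).
#' Other relation types are dropped with a warning (or an error in strict
#' mode); the graph must be acyclic over the union of the kept relations.
#'
#' @param terms character vector of term ids.
#' @param names named character vector of term labels (names = term ids);
#'   terms without a label get their id as label.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @param strict logical; if `TRUE`, edges whose endpoints are not in
#'   `terms` raise an error instead of being dropped.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, names = NULL, edges = NULL, strict = FALSE) {
  terms <- unique(as.character(terms))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  edges <- edges[, c("child", "parent", "relation")]
  known_rel <- edges$relation %in% c("is_a", "part_of")
  if (any(!known_rel)) {
    warning(sprintf("dropping %d edge(s) with unsupported relation type(s): %s",
                    sum(!known_rel),
                    paste(unique(edges$relation[!known_rel]), collapse = ", ")))
    edges <- edges[known_rel, , drop = FALSE]
  }
  dangling <- !(edges$child %in% terms) | !(edges$parent %in% terms)
  if (any(dangling)) {
    if (strict) {
      bad <- edges[dangling, , drop = FALSE][1, ]
      stop(sprintf("dangling edge endpoint: %s -> %s", bad$child, bad$parent))
    }
    edges <- edges[!dangling, , drop = FALSE]
  }
  lab <- setNames(terms, terms)
  if (!is.null(names)) {
    hit <- intersect(base::names(names), terms)
    lab[hit] <- names[hit]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = terms, stringsAsFactors = FALSE))
  igraph::E(g)$relation <- edges$relation
  if (!igraph::is_dag(g)) {
    sc <- igraph::components(g, mode = "strong")
    comp <- terms[sc$membership == which.max(sc$csize)]
    stop(sprintf("ontology graph is cyclic; one cycle involves: %s",
                 paste(head(comp, 10), collapse = " -> ")))
  }
  structure(list(terms = terms, labels = lab, edges = edges, graph = g),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, %d edges (%s)\n",
              length(x$terms), nrow(x$edges),
              paste(sprintf("%s: %d", names(table(x$edges$relation)),
                            table(x$edges$relation)), collapse = ", ")))
  invisible(x)
}

root_terms <- function(onto) {
  setdiff(onto$terms, unique(onto$edges$child))
}

rel_subgraph <- function(onto, relations) {
  keep <- which(igraph::E(onto$graph)$relation %in% relations)
  igraph::subgraph_from_edges(onto$graph, keep, delete.vertices = FALSE)
}

#' Ancestors of a set of terms
#'
#' Terms reachable upward (child to parent) from `terms` via the given
#' relations, excluding the query terms themselves unless `include_self`.
#'
#' @param onto an [ontology_graph()].
#' @param terms character vector of term ids.
#' @param relations which edge types to traverse.
#' @param include_self include the query terms in the result.
#' @return character vector of term ids.
#' @export
ancestors <- function(onto, terms, relations = c("is_a", "part_of"),
                      include_self = FALSE) {
  stopifnot(inherits(onto, "ontology_graph"))
  unknown <- setdiff(terms, onto$terms)
  if (length(unknown))
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  if (!length(terms)) return(character())
  g <- rel_subgraph(onto, relations)
  out <- unique(unlist(lapply(terms, function(t)
    names(igraph::subcomponent(g, t, mode = "out")))))
  if (!include_self) out <- setdiff(out, terms)
  out
}

#' Descendants of a set of root terms
#'
#' Returns the roots plus every term reachable downward (parent to child)
#' via the given relations. This is the substructure query used to resolve
#' anatomical system lists (e.g. every structure under "nervous system").
#'
#' @inheritParams ancestors
#' @param roots character vector of term ids to expand.
#' @return character vector of term ids (includes `roots`).
#' @export
descendants <- function(onto, roots, relations = c("is_a", "part_of")) {
  stopifnot(inherits(onto, "ontology_graph"))
  unknown <- setdiff(roots, onto$terms)
  if (length(unknown))
    stop("unknown root term(s): ", paste(unknown, collapse = ", "))
  if (!length(roots)) return(character())
  g <- rel_subgraph(onto, relations)
  unique(unlist(lapply(roots, function(t)
    names(igraph::subcomponent(g, t, mode = "in")))))
}

# ---------------------------------------------------------------------------
# OBO 1.2 parsing / serialisation
# ---------------------------------------------------------------------------

#' Parse an OBO 1.2 ontology
#'
#' Reads `[Term]` stanzas with `id`, `name`, `is_a` and
#' `relationship: part_of` lines. Obsolete terms are dropped, as are edges
#' pointing outside the parsed term set (unless `strict`).
#'
#' @param file path to an OBO file, or a character vector of OBO lines.
#' @param strict logical; error on dangling edges instead of dropping them.
#' @return An [ontology_graph()].
#' @export
parse_obo <- function(file, strict = FALSE) {
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file))
    readLines(file, warn = FALSE) else unlist(strsplit(file, "\n"))
  lines <- sub("!.*$", "", lines)       # strip comments
  lines <- trimws(lines)

  in_term <- FALSE
  cur <- NULL
  terms <- character(); labels <- character()
  ec <- character(); ep <- character(); er <- character()
  flush <- function() {
    if (is.null(cur) || cur$obsolete || is.na(cur$id)) return()
    terms[[length(terms) + 1L]] <<- cur$id
    labels[[cur$id]] <<- if (is.na(cur$name)) cur$id else cur$name
    for (p in cur$isa) { ec <<- c(ec, cur$id); ep <<- c(ep, p); er <<- c(er, "is_a") }
    for (p in cur$partof) { ec <<- c(ec, cur$id); ep <<- c(ep, p); er <<- c(er, "part_of") }
    for (p in cur$other) { ec <<- c(ec, cur$id); ep <<- c(ep, p$parent); er <<- c(er, p$rel) }
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur <- list(id = NA_character_, name = NA_character_, obsolete = FALSE,
                  isa = character(), partof = character(), other = list())
      next
    }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; cur <- NULL; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
    else if (grepl("^is_a:", ln))
      cur$isa <- c(cur$isa, strsplit(trimws(sub("^is_a:", "", ln)), "\\s+")[[1]][1])
    else if (grepl("^relationship:", ln)) {
      f <- strsplit(trimws(sub("^relationship:", "", ln)), "\\s+")[[1]]
      if (length(f) >= 2) {
        if (f[1] == "part_of") cur$partof <- c(cur$partof, f[2])
        else cur$other <- c(cur$other, list(list(rel = f[1], parent = f[2])))
      }
    }
  }
  flush()
  edges <- data.frame(child = ec, parent = ep, relation = er,
                      stringsAsFactors = FALSE)
  # edges to obsolete/unseen terms: handled by ontology_graph (drop or error)
  ontology_graph(terms, unlist(labels), edges, strict = strict)
}

#' Serialise an ontology graph to OBO text
#'
#' Inverse of [parse_obo()] for round-trip testing and for writing
#' synthetic ontologies to disk.
#'
#' @param onto an [ontology_graph()].
#' @param file optional path; if `NULL` the lines are returned invisibly.
#' @return character vector of OBO lines, invisibly.
#' @export
write_obo <- function(onto, file = NULL) {
  stopifnot(inherits(onto, "ontology_graph"))
  out <- c("format-version: 1.2", "")
  for (t in sort(onto$terms)) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", onto$labels[[t]]))
    e <- onto$edges[onto$edges$child == t, , drop = FALSE]
    e <- e[order(e$parent), , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[i] == "is_a")
        paste0("is_a: ", e$parent[i])
        else paste0("relationship: part_of ", e$parent[i]))
    }
    out <- c(out, "")
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

# ---------------------------------------------------------------------------
# Annotation sets
# ---------------------------------------------------------------------------

#' Construct an annotation set
#'
#' A gene-to-anatomical-term expression mapping. Annotations are typically
#' read raw (unpropagated) and closed over the ontology with [propagate()]
#' before counting or testing.
#'
#' @param gene2terms named list, gene id -> character vector of term ids.
#' @param propagated logical flag; set by [propagate()].
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(gene2terms, propagated = FALSE) {
  stopifnot(is.list(gene2terms))
  gene2terms <- lapply(gene2terms, function(x) unique(as.character(x)))
  structure(list(gene2terms = gene2terms, propagated = propagated),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d annotations%s\n",
              length(x$gene2terms), sum(lengths(x$gene2terms)),
              if (x$propagated) " (propagated)" else ""))
  invisible(x)
}

#' Read gene-term annotations from TSV
#'
#' Two-column TSV (gene_id, term_id), optional header.
#'
#' @param file path to the TSV.
#' @return An unpropagated [annotation_set()].
#' @export
read_annotations <- function(file) {
  df <- read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("gene_id", "term_id"))
  if (nrow(df) && (df$gene_id[1] == "gene_id" || df$term_id[1] == "term_id"))
    df <- df[-1, , drop = FALSE]
  annotation_set(split(df$term_id, df$gene_id))
}

#' Propagate annotations to ancestor terms
#'
#' Implements the transitive closure used in anatomical enrichment tests:
#' a gene expressed in a structure is also considered expressed in all of
#' its parents (over `is_a` and `part_of` by default), e.g. expression in
#' the hindbrain implies expression in the brain. The operation is
#' idempotent.
#'
#' @param ann an [annotation_set()].
#' @param onto the companion [ontology_graph()].
#' @param relations relations to close over; `develops_from`-style edges are
#'   never present in the graph (see [ontology_graph()]).
#' @return A propagated [annotation_set()].
#' @export
propagate <- function(ann, onto, relations = c("is_a", "part_of")) {
  stopifnot(inherits(ann, "annotation_set"), inherits(onto, "ontology_graph"))
  used <- unique(unlist(ann$gene2terms))
  missing <- setdiff(used, onto$terms)
  if (length(missing)) {
    offending <- unlist(lapply(names(ann$gene2terms), function(g) {
      bad <- intersect(ann$gene2terms[[g]], missing)
      if (length(bad)) paste0("(", g, ", ", bad, ")") else character()
    }))
    stop("annotation term(s) missing from ontology: ",
         paste(head(offending, 10), collapse = ", "))
  }
  g <- rel_subgraph(onto, relations)
  # closure per distinct term, then union per gene
  clos <- lapply(setNames(used, used), function(t)
    names(igraph::subcomponent(g, t, mode = "out")))
  annotation_set(lapply(ann$gene2terms, function(ts)
    unique(unlist(clos[ts]))), propagated = TRUE)
}

# term -> character vector of genes (inverse index)
term_genesets <- function(ann) {
  pairs <- data.frame(
    gene = rep(names(ann$gene2terms), lengths(ann$gene2terms)),
    term = unlist(ann$gene2terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  split(pairs$gene, pairs$term)
}

#' Terms testable for enrichment
#'
#' Terms annotated (post-propagation) with at least `min_genes` distinct
#' genes. Counting on unpropagated annotations is refused because parent
#' terms would be undercounted.
#'
#' @param ann a propagated [annotation_set()].
#' @param min_genes minimum number of distinct annotated genes (default 5).
#' @return character vector of term ids.
#' @export
testable_terms <- function(ann, min_genes = 5) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!ann$propagated)
    stop("annotations must be propagated before counting testable terms")
  gs <- term_genesets(ann)
  names(gs)[vapply(gs, function(g) length(unique(g)), 1L) >= min_genes]
}

# ---------------------------------------------------------------------------
# Structure lists
# ---------------------------------------------------------------------------

#' Build named anatomical-system structure lists
#'
#' Resolves a configuration of root terms, excluded roots, and extra root
#' additions into concrete term sets. The canonical use is the nervous
#' system: the strict list is every substructure of the nervous-system root
#' minus the sensory system and its substructures; the broad list adds back
#' the sensory system plus presumptive neural and other configured roots.
#' Generic system lists (digestive, circulatory, ...) are plain descendant
#' sets of one high-level root.
#'
#' @param onto an [ontology_graph()].
#' @param config named list; each element is a list with character fields
#'   `roots`, and optionally `exclusions` and `additions`.
#' @param testable optional character vector; when given, each member set is
#'   intersected with it (structures actually tested for enrichment).
#' @return named list of `structure_list` objects with fields `name`,
#'   `roots`, `exclusions`, `additions`, `members`.
#' @export
build_system_list <- function(onto, config, testable = NULL) {
  stopifnot(inherits(onto, "ontology_graph"), is.list(config))
  out <- lapply(names(config), function(nm) {
    cfg <- config[[nm]]
    roots <- as.character(cfg$roots %||% character())
    excl <- as.character(cfg$exclusions %||% character())
    adds <- as.character(cfg$additions %||% character())
    bad <- intersect(roots, excl)
    if (length(bad))
      stop(sprintf("list '%s': root(s) also listed as exclusion: %s",
                   nm, paste(bad, collapse = ", ")))
    members <- setdiff(descendants(onto, roots),
                       if (length(excl)) descendants(onto, excl) else character())
    if (length(adds)) members <- union(members, descendants(onto, adds))
    members <- sort(members)
    if (!is.null(testable)) members <- intersect(members, testable)
    structure(list(name = nm, roots = roots, exclusions = excl,
                   additions = adds, members = members),
              class = "structure_list")
  })
  setNames(out, names(config))
}

#' @export
print.structure_list <- function(x, ...) {
  cat(sprintf("structure_list '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Write a structure list (one term id per line)
#' @param x a `structure_list`.
#' @param file output path.
#' @export
write_structure_list <- function(x, file) {
  writeLines(x$members, file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
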