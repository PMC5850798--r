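# ---------------------------------------------------------------------------
# Per-term expression enrichment with ontology decorrelation.
#
# classic: independent one-sided hypergeometric tests per term.
# elim:    bottom-up; genes of significant terms are removed from ancestors.
# weight:  bottom-up gene down-weighting against child terms (sigRatio =
#          ratio of p-values); weighted tables are rounded before the exact
#          test so the statistic stays a hypergeometric tail.
# ---------------------------------------------------------------------------

# one-sided hypergeometric p-values for a 2x2 (a = fg in term, K = ref in
# term, n_fg, n_ref); enrichment = upper tail P(X >= a), depletion = lower.
hyper_p <- function(a, K, n_fg, n_ref, direction = c("enrich", "deplete")) {
  direction <- match.arg(direction)
  if (direction == "enrich")
    phyper(a - 1, K, n_ref - K, n_fg, lower.tail = FALSE)
  else
    phyper(a, K, n_ref - K, n_fg, lower.tail = TRUE)
}

#' Fold enrichment
#'
#' Observed over expected counts; the tabular output convention is two
#' decimals (e.g. 121 observed vs 57.06 expected prints as 2.12).
#'
#' @param observed observed foreground count (vectorised).
#' @param expected expected count under proportional sampling; must be > 0.
#' @return numeric, `observed / expected` (unrounded).
#' @export
fold_enrichment <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected count must be > 0")
  observed / expected
}

#' Benjamini-Hochberg false discovery rate
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

# node depth (longest path from any root), used to order bottom-up passes
term_depths <- function(onto) {
  g <- onto$graph
  topo <- names(igraph::topo_sort(g, mode = "in"))  # parents before children
  depth <- setNames(integer(length(onto$terms)), onto$terms)
  prnts <- lapply(setNames(onto$terms, onto$terms), function(t)
    onto$edges$parent[onto$edges$child == t])
  for (t in topo) {
    p <- prnts[[t]]
    depth[t] <- if (length(p)) max(depth[p]) + 1L else 0L
  }
  depth
}

test_term_counts <- function(a, K, n_fg, n_ref) {
  c(enrich = hyper_p(a, K, n_fg, n_ref, "enrich"),
    deplete = hyper_p(a, K, n_fg, n_ref, "deplete"))
}

#' Anatomical expression enrichment test
#'
#' Tests each testable term for enrichment (and depletion) of a foreground
#' gene list against a reference, with optional decorrelation of the
#' ontology structure. `classic` tests every term independently; `elim`
#' removes the genes of significantly enriched terms from their ancestors
#' before the ancestors are tested; `weight` down-weights genes shared with
#' more significant child terms. Expected counts and folds are always
#' computed from raw (unweighted) counts.
#'
#' @param foreground character vector of genes of interest (must be a subset
#'   of `reference`).
#' @param reference character vector; all genes with expression data in at
#'   least one structure.
#' @param ann propagated [annotation_set()].
#' @param onto companion [ontology_graph()].
#' @param algorithm one of `"classic"`, `"elim"`, `"weight"`.
#' @param min_genes minimum annotated genes for a term to be tested.
#' @param elim_cutoff p-value below which a term's genes are eliminated
#'   from its ancestors (elim only).
#' @return data.frame of class `enrichment_result`, one row per testable
#'   term: `term_id`, `term_name`, `n_expressed`, `n_observed`,
#'   `n_expected`, `fold`, `p_enrich`, `p_deplete`, `fdr_enrich`,
#'   `fdr_deplete`, sorted by `p_enrich` (ties by term id). Attributes
#'   record the algorithm and set sizes.
#' @export
run_enrichment <- function(foreground, reference, ann, onto,
                           algorithm = c("weight", "elim", "classic"),
                           min_genes = 5, elim_cutoff = 0.01) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(ann, "annotation_set"), inherits(onto, "ontology_graph"))
  if (!ann$propagated) stop("annotations must be propagated")
  foreground <- unique(as.character(foreground))
  reference <- unique(as.character(reference))
  extra <- setdiff(foreground, reference)
  if (length(extra))
    stop("foreground gene(s) not in reference: ",
         paste(head(extra, 5), collapse = ", "))

  gs <- term_genesets(ann)
  gs <- lapply(gs, intersect, reference)     # restrict annotation universe
  testable <- names(gs)[lengths(gs) >= min_genes]
  testable <- intersect(testable, onto$terms)
  if (!length(testable)) {
    warning("no testable terms at min_genes = ", min_genes)
    return(empty_enrichment(algorithm, length(foreground), length(reference)))
  }

  n_fg <- length(foreground)
  n_ref <- length(reference)
  raw_K <- vapply(gs[testable], length, 1L)
  raw_a <- vapply(gs[testable], function(g) sum(g %in% foreground), 1L)

  p <- switch(algorithm,
    classic = p_classic(testable, gs, foreground, n_fg, n_ref),
    elim = p_elim(testable, gs, foreground, n_fg, n_ref, onto, elim_cutoff),
    weight = p_weight(testable, gs, foreground, n_fg, n_ref, onto))

  expected <- raw_K * n_fg / n_ref
  res <- data.frame(
    term_id = testable,
    term_name = unname(onto$labels[testable]),
    n_expressed = unname(raw_K),
    n_observed = unname(raw_a),
    n_expected = unname(expected),
    fold = unname(raw_a / expected),
    p_enrich = unname(p[testable, "enrich"]),
    p_deplete = unname(p[testable, "deplete"]),
    stringsAsFactors = FALSE)
  res$fdr_enrich <- bh_fdr(res$p_enrich)
  res$fdr_deplete <- bh_fdr(res$p_deplete)
  res <- res[order(res$p_enrich, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "algorithm") <- algorithm
  attr(res, "n_foreground") <- n_fg
  attr(res, "n_reference") <- n_ref
  class(res) <- c("enrichment_result", "data.frame")
  res
}

empty_enrichment <- function(algorithm, n_fg, n_ref) {
  res <- data.frame(term_id = character(), term_name = character(),
                    n_expressed = integer(), n_observed = integer(),
                    n_expected = numeric(), fold = numeric(),
                    p_enrich = numeric(), p_deplete = numeric(),
                    fdr_enrich = numeric(), fdr_deplete = numeric(),
                    stringsAsFactors = FALSE)
  attr(res, "algorithm") <- algorithm
  attr(res, "n_foreground") <- n_fg
  attr(res, "n_reference") <- n_ref
  class(res) <- c("enrichment_result", "data.frame")
  res
}

p_classic <- function(testable, gs, foreground, n_fg, n_ref) {
  out <- t(vapply(testable, function(t) {
    K <- length(gs[[t]])
    a <- sum(gs[[t]] %in% foreground)
    test_term_counts(a, K, n_fg, n_ref)
  }, c(enrich = 0, deplete = 0)))
  rownames(out) <- testable
  out
}

# elim: deepest terms first; a term significant at elim_cutoff removes its
# annotated genes from every ancestor before the ancestor is tested.
p_elim <- function(testable, gs, foreground, n_fg, n_ref, onto, elim_cutoff) {
  depth <- term_depths(onto)
  ord <- testable[order(-depth[testable], testable)]
  removed <- lapply(setNames(ord, ord), function(t) character())
  out <- matrix(NA_real_, length(testable), 2,
                dimnames = list(testable, c("enrich", "deplete")))
  for (t in ord) {
    genes <- setdiff(gs[[t]], removed[[t]])
    K <- length(genes)
    a <- sum(genes %in% foreground)
    out[t, ] <- test_term_counts(a, K, n_fg, n_ref)
    if (out[t, "enrich"] < elim_cutoff) {
      anc <- intersect(ancestors(onto, t), names(removed))
      for (an in anc) removed[[an]] <- union(removed[[an]], gs[[t]])
    }
  }
  out
}

# weight: children-before-parents; per-term per-gene weights start at 1.
# A term's p-value comes from a table whose cells are weight sums (rounded
# to the nearest integer to keep an exact hypergeometric test). Children
# more significant than the parent down-weight their genes in the parent
# and all its ancestors by p_child / p_parent; less significant children
# have their genes down-weighted locally by p_parent / p_child.
p_weight <- function(testable, gs, foreground, n_fg, n_ref, onto) {
  depth <- term_depths(onto)
  ord <- testable[order(-depth[testable], testable)]
  w <- lapply(setNames(testable, testable), function(t)
    setNames(rep(1, length(gs[[t]])), gs[[t]]))
  is_fg <- lapply(setNames(testable, testable),
                  function(t) gs[[t]] %in% foreground)

  weighted_p <- function(t) {
    K <- round(sum(w[[t]]))
    a <- round(sum(w[[t]][is_fg[[t]]]))
    K <- max(K, 0); a <- min(max(a, 0), K)
    test_term_counts(a, K, n_fg, n_ref)
  }

  child_map <- split(onto$edges$child, onto$edges$parent)
  out <- matrix(NA_real_, length(testable), 2,
                dimnames = list(testable, c("enrich", "deplete")))
  for (t in ord) {
    p_t <- weighted_p(t)["enrich"]
    kids <- intersect(child_map[[t]] %||% character(), testable)
    for (k in kids) {
      p_k <- out[k, "enrich"]
      if (is.na(p_k)) next
      if (p_k < p_t) {
        ratio <- p_k / max(p_t, .Machine$double.xmin)
        shared_up <- intersect(gs[[k]], gs[[t]])
        targets <- c(t, intersect(ancestors(onto, t), testable))
        for (an in targets) {
          sh <- intersect(shared_up, names(w[[an]]))
          if (length(sh)) w[[an]][sh] <- w[[an]][sh] * ratio
        }
        p_t <- weighted_p(t)["enrich"]   # re-test the parent
      } else {
        ratio <- p_t / max(p_k, .Machine$double.xmin)
        sh <- intersect(gs[[t]], names(w[[k]]))
        if (length(sh)) w[[k]][sh] <- w[[k]][sh] * ratio
        out[k, ] <- weighted_p(k)
      }
    }
    out[t, ] <- weighted_p(t)
  }
  out
}

#' Format an enrichment result like a published organ table
#'
#' Returns (and optionally writes) the result with `n_expected` and `fold`
#' rounded to two decimals, the column order used in tabular reports.
#'
#' @param res an `enrichment_result`.
#' @param file optional output TSV path.
#' @param direction report p/fdr for `"enrich"` or `"deplete"`.
#' @return data.frame with columns term_id, term_name, n_expressed,
#'   n_observed, n_expected, fold, p, fdr.
#' @export
format_enrichment <- function(res, file = NULL,
                              direction = c("enrich", "deplete")) {
  direction <- match.arg(direction)
  out <- data.frame(
    term_id = res$term_id, term_name = res$term_name,
    n_expressed = res$n_expressed, n_observed = res$n_observed,
    n_expected = round(res$n_expected, 2), fold = round(res$fold, 2),
    p = res[[paste0("p_", direction)]],
    fdr = res[[paste0("fdr_", direction)]],
    stringsAsFactors = FALSE)
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Overrepresentation of a structure category among enrichment hits
#'
#' Given the set of significantly enriched terms (`hits`) among all tested
#' terms, tests whether membership in an anatomical category (e.g. the
#' broad nervous-system list) is overrepresented among hits, via a
#' two-sided Fisher exact test on the 2x2 table. The reported odds ratio is
#' the sample odds ratio ad/bc (infinite when bc = 0), not the conditional
#' MLE.
#'
#' @param hits character vector of hit term ids (subset of `tested`).
#' @param tested character vector of all tested term ids.
#' @param category a `structure_list` or character vector of term ids.
#' @return list with `odds_ratio`, `p_value`, and the 2x2 `table`.
#' @export
overrepresentation_test <- function(hits, tested, category) {
  if (inherits(category, "structure_list")) category <- category$members
  hits <- unique(hits); tested <- unique(tested)
  if (length(setdiff(hits, tested)))
    stop("hits must be a subset of tested terms")
  a <- sum(hits %in% category)
  b <- length(hits) - a
  non <- setdiff(tested, hits)
  c_ <- sum(non %in% category)
  d <- length(non) - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("hit", "non_hit"),
                                c("in_category", "not_in_category")))
  p <- fisher.test(tab)$p.value
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  list(odds_ratio = or, p_value = p, table = tab)
}
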