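test_that("parse_obo reads term stanzas, drops obsolete terms and dangling edges", {
  obo <- c(
    "[Term]", "id: A", "name: alpha", "is_a: B", "",
    "[Term]", "id: B", "name: beta", "is_a: C", "",
    "[Term]", "id: C", "name: gamma", "",
    "[Term]", "id: D", "name: gone", "is_obsolete: true", "is_a: C", "",
    "[Term]", "id: E", "name: eps", "is_a: D", "")
  g <- parse_obo(paste(obo, collapse = "\n"))
  expect_setequal(g$terms, c("A", "B", "C", "E"))
  expect_equal(nrow(g$edges), 2)           # E -> D dangling, dropped
  expect_equal(unname(g$labels["A"]), "alpha")
  expect_error(parse_obo(paste(obo, collapse = "\n"), strict = TRUE),
               "dangling")
})

test_that("parse_obo reads part_of relationships and rejects cycles", {
  obo <- c("[Term]", "id: X", "relationship: part_of Y", "",
           "[Term]", "id: Y", "is_a: X", "")
  expect_error(parse_obo(paste(obo, collapse = "\n")), "cyclic")
  ok <- parse_obo("[Term]\nid: X\nrelationship: part_of Y\n\n[Term]\nid: Y\n")
  expect_equal(ok$edges$relation, "part_of")
})

test_that("OBO round-trip preserves term and edge sets of a synthetic ontology", {
  d <- gen_ontology_annotations(synth_config(seed = 42))
  lines <- write_obo(d$onto)
  g2 <- parse_obo(paste(lines, collapse = "\n"))
  expect_setequal(g2$terms, d$onto$terms)
  key <- function(e) sort(paste(e$child, e$parent, e$relation))
  expect_equal(key(g2$edges), key(d$onto$edges))
  expect_equal(g2$labels[sort(names(g2$labels))],
               d$onto$labels[sort(names(d$onto$labels))])
})

test_that("propagate closes annotations over is_a and part_of and is idempotent", {
  g <- toy_ontology()
  ann <- annotation_set(list(g1 = "L2", g2 = c("L3", "L1")))
  p <- propagate(ann, g)
  expect_true(p$propagated)
  expect_setequal(p$gene2terms$g1, c("L2", "M1", "R"))
  expect_setequal(p$gene2terms$g2, c("L3", "M2", "L1", "M1", "R"))
  expect_identical(propagate(p, g)$gene2terms, p$gene2terms)
  expect_error(propagate(annotation_set(list(g1 = "NOPE")), g),
               "missing from ontology")
})

test_that("propagation closure matches brute-force BFS on random DAGs", {
  for (seed in 1:5) {
    dag <- random_dag(40, seed)
    g <- ontology_graph(dag$terms, edges = dag$edges)
    genes <- paste0("g", 1:30)
    ann <- annotation_set(setNames(
      lapply(genes, function(.) sample(dag$terms, sample(1:3, 1))), genes))
    p <- propagate(ann, g)
    for (gn in genes) {
      expected <- unique(unlist(lapply(ann$gene2terms[[gn]], function(t)
        c(t, bfs_ancestors(dag$edges, t)))))
      expect_setequal(p$gene2terms[[gn]], expected)
    }
  }
})

test_that("descendants matches reverse reachability and handles edge cases", {
  g <- toy_ontology()
  expect_setequal(descendants(g, "L1"), "L1")
  expect_setequal(descendants(g, "R"), g$terms)
  expect_error(descendants(g, "ZZ"), "unknown root")
  # 3-level binary tree: 7 terms under the root
  ed <- data.frame(child = c("b1","b2","c1","c2","c3","c4"),
                   parent = c("a","a","b1","b1","b2","b2"),
                   relation = "is_a", stringsAsFactors = FALSE)
  bt <- ontology_graph(c("a","b1","b2","c1","c2","c3","c4"), edges = ed)
  expect_length(descendants(bt, "a"), 7)
  for (seed in 6:8) {
    dag <- random_dag(35, seed)
    g2 <- ontology_graph(dag$terms, edges = dag$edges)
    roots <- sample(dag$terms, 2)
    expect_setequal(descendants(g2, roots),
                    unique(c(bfs_descendants(dag$edges, roots[1]),
                             bfs_descendants(dag$edges, roots[2]))))
  }
})

test_that("after propagation every parent geneset contains its child's", {
  d <- gen_ontology_annotations(synth_config(seed = 9))
  p <- propagate(d$ann, d$onto)
  gs <- lapply(split(
    rep(names(p$gene2terms), lengths(p$gene2terms)),
    unlist(p$gene2terms, use.names = FALSE)), unique)
  getset <- function(t) if (is.null(gs[[t]])) character() else gs[[t]]
  for (i in seq_len(nrow(d$onto$edges))) {
    ch <- d$onto$edges$child[i]; pa <- d$onto$edges$parent[i]
    expect_true(all(getset(ch) %in% getset(pa)),
                label = paste("edge", ch, "->", pa))
  }
})

test_that("build_system_list resolves strict/broad nervous-style lists", {
  # eye sits under both sensory and nervous systems
  ed <- data.frame(
    child = c("nervous", "sensory", "brain", "eye", "eye", "retina", "gut",
              "digestive"),
    parent = c("body", "body", "nervous", "sensory", "nervous", "eye",
               "digestive", "body"),
    relation = "is_a", stringsAsFactors = FALSE)
  g <- ontology_graph(c("body", "nervous", "sensory", "brain", "eye",
                        "retina", "gut", "digestive"), edges = ed)
  lists <- build_system_list(g, list(
    nervous_strict = list(roots = "nervous", exclusions = "sensory"),
    nervous_broad = list(roots = "nervous"),
    digestive = list(roots = "digestive")))
  expect_setequal(lists$nervous_strict$members, c("nervous", "brain"))
  expect_setequal(lists$nervous_broad$members,
                  c("nervous", "brain", "eye", "retina"))
  expect_true(all(lists$nervous_strict$members %in%
                    lists$nervous_broad$members))
  expect_setequal(lists$digestive$members, c("digestive", "gut"))
  # additions re-include exclusion subtrees (broad-list mechanism)
  broad2 <- build_system_list(g, list(
    b = list(roots = "nervous", exclusions = "sensory", additions = "eye")))
  expect_setequal(broad2$b$members, c("nervous", "brain", "eye", "retina"))
  expect_error(
    build_system_list(g, list(x = list(roots = "eye", exclusions = "eye"))),
    "exclusion")
})

test_that("build_system_list is deterministic and order-independent", {
  d <- gen_ontology_annotations(synth_config(seed = 4))
  roots <- sort(d$onto$terms)[2:4]
  a <- build_system_list(d$onto, list(x = list(roots = roots)))
  b <- build_system_list(d$onto, list(x = list(roots = rev(roots))))
  expect_identical(a$x$members, b$x$members)
})

test_that("testable_terms applies the five-gene floor on propagated counts", {
  g <- toy_ontology()
  genes <- paste0("g", 1:5)
  ann <- propagate(annotation_set(c(
    setNames(lapply(1:4, function(.) "L1"), genes[1:4]),
    list(g5 = "L2"))), g)
  # L1 has 4 genes, M1 and R have 5
  expect_setequal(testable_terms(ann, min_genes = 5), c("M1", "R"))
  expect_true("L1" %in% testable_terms(ann, min_genes = 4))
  expect_error(testable_terms(annotation_set(list(g1 = "L1")), 5),
               "propagated")
  # counting oracle on generated annotations
  d <- gen_ontology_annotations(synth_config(seed = 12))
  p <- propagate(d$ann, d$onto)
  counts <- table(unlist(lapply(p$gene2terms, unique)))
  expect_setequal(testable_terms(p, 5), names(counts)[counts >= 5])
})
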