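test_that("parse_nhx reads events, taxa and confidence scales", {
  t2 <- parse_nhx("(a[&&NHX:S=sp1],b[&&NHX:S=sp2])[&&NHX:S=X:D=N];")
  expect_false(t2$leaf)
  expect_equal(t2$event, "speciation")
  expect_equal(t2$taxon, "X")
  expect_equal(vapply(t2$children, `[[`, "", "gene"), c("a", "b"))
  d <- parse_nhx("(a[&&NHX:S=sp1],b[&&NHX:S=sp1])[&&NHX:S=X:D=Y:B=51];")
  expect_equal(d$conf, 0.51)
  expect_warning(
    nb <- parse_nhx("(a[&&NHX:S=sp1],b[&&NHX:S=sp1])[&&NHX:S=X:D=Y];"),
    "confidence")
  expect_equal(nb$conf, 0)
  expect_error(parse_nhx("(a[&&NHX:S=sp1],b[&&NHX:S=sp2])[&&NHX:S=X];"),
               "event tag")
  expect_error(parse_nhx("(a[&&NHX:S=x],b[&&NHX:S=x]"),
               "syntax error at position")
})

test_that("NHX serialisation round-trips topology and metadata", {
  gt <- gen_gene_trees(synth_config(seed = 14, n_trees = 100))
  for (tr in gt$trees) {
    s <- write_nhx(tr)
    expect_identical(write_nhx(parse_nhx(s)), s)
  }
})

test_that("stripped newick agrees with ape's reading of the same tree", {
  skip_if_not_installed("ape")
  gt <- gen_gene_trees(synth_config(seed = 15, n_trees = 20))
  for (tr in gt$trees) {
    s <- gsub("\\[[^]]*\\]", "", write_nhx(tr))
    ph <- ape::read.tree(text = s)
    expect_setequal(ph$tip.label,
                    vapply(ohnologR:::tree_leaves(tr), `[[`, "", "gene"))
  }
})

test_that("classify_3r follows the duplication-topology rules strictly", {
  mk <- function(conf) paste0(
    "(mg1[&&NHX:S=mus_musculus],(gar1[&&NHX:S=sp_gar],((dA[&&NHX:S=danio_rerio],",
    "f1[&&NHX:S=sp_fish1])[&&NHX:S=Clupeocephala:D=N],(dB[&&NHX:S=danio_rerio],",
    "f2[&&NHX:S=sp_fish2])[&&NHX:S=Clupeocephala:D=N])[&&NHX:S=Clupeocephala:D=Y:B=",
    conf, "])[&&NHX:S=Neopterygii:D=N])[&&NHX:S=Euteleostomi:D=N];")
  res <- classify_3r(parse_nhx(mk(90)))
  expect_setequal(res$gene_id[res$label == "ohnolog"], c("dA", "dB"))
  # strictly above 50%: a score of exactly 50 is not confident
  res50 <- classify_3r(parse_nhx(mk(50)))
  expect_true(all(res50$label == "unclassified"))
  expect_true(all(res50$trace == "low_confidence"))
  # child-order invariance
  rev_res <- classify_3r(reverse_children(parse_nhx(mk(90))))
  expect_setequal(rev_res$gene_id[rev_res$label == "ohnolog"], c("dA", "dB"))
  # no focal leaf at all: empty result with warning
  s <- "(a[&&NHX:S=sp_fish1],b[&&NHX:S=sp_fish2])[&&NHX:S=Clupeocephala:D=N];"
  expect_warning(empty <- classify_3r(parse_nhx(s)), "no danio_rerio")
  expect_equal(nrow(empty), 0)
})

test_that("raising min_confidence never converts unclassified to ohnolog", {
  gt <- gen_gene_trees(synth_config(seed = 16, n_trees = 120))
  threer <- gt$meta$tree[gt$meta$family == "3r"]
  for (i in threer) {
    lo <- classify_3r(gt$trees[[i]], min_confidence = 0.5)
    hi <- classify_3r(gt$trees[[i]], min_confidence = 0.9)
    was_uncl <- lo$gene_id[lo$label == "unclassified"]
    expect_false(any(hi$label[match(was_uncl, hi$gene_id)] == "ohnolog"))
  }
})

test_that("classify_2r handles lamprey fallback, two rounds and zero-confidence", {
  clades <- synth_species_clades()
  gt <- gen_gene_trees(synth_config(seed = 17, n_trees = 250))
  meta <- gt$meta
  pick <- function(tmpl, corr = "none") {
    meta$tree[meta$template == tmpl & meta$corruption == corr][1]
  }
  i <- pick("ohnolog_nolamprey")
  expect_false(is.na(i))
  res <- classify_2r(gt$trees[[i]], clades)
  expect_true(all(res$label == "ohnolog"))
  i2 <- pick("ohnolog_twodup")
  expect_false(is.na(i2))
  expect_true(all(classify_2r(gt$trees[[i2]], clades)$label == "ohnolog"))
  i3 <- pick("ohnolog_zeroconf")
  expect_false(is.na(i3))
  expect_true(all(classify_2r(gt$trees[[i3]], clades)$label == "ohnolog"))
  i4 <- pick("ohnolog_nolamprey", "lamprey_fallback")
  expect_false(is.na(i4))
  r4 <- classify_2r(gt$trees[[i4]], clades)
  expect_true(all(r4$label == "unclassified"))
  expect_true(all(r4$trace == "no_wgd_node"))
})

test_that("classify_ssd applies identity bounds and duplication dating", {
  tree <- parse_nhx(paste0(
    "((dA[&&NHX:S=danio_rerio],dB[&&NHX:S=danio_rerio])",
    "[&&NHX:S=Otophysa:D=Y:B=90],f1[&&NHX:S=sp_fish1])",
    "[&&NHX:S=Clupeocephala:D=N];"))
  idt <- function(pct) data.frame(gene_a = "dA", gene_b = "dB",
                                  pct_identity = pct)
  expect_setequal(classify_ssd(tree, idt(55), "danio_rerio"), c("dA", "dB"))
  expect_length(classify_ssd(tree, idt(100), "danio_rerio"), 0)
  expect_length(classify_ssd(tree, idt(9), "danio_rerio"), 0)
  expect_setequal(classify_ssd(tree, idt(10), "danio_rerio"), c("dA", "dB"))
  expect_warning(out <- classify_ssd(tree, idt(55)[0, ], "danio_rerio"),
                 "no identity")
  expect_length(out, 0)
})

test_that("ortholog mapping requires single-copy outgroup genes", {
  gt <- gen_gene_trees(synth_config(seed = 18, n_trees = 150))
  ot <- gt$ortholog_truth
  for (t in unique(ot$tree)) {
    res <- classify_3r(gt$trees[[t]])
    om <- map_orthologs(gt$trees[[t]], res, "danio_rerio", "mus_musculus")
    exp <- ot[ot$tree == t, ]
    expect_equal(om$label[match(exp$gene_id, om$gene_id)], exp$label,
                 label = paste("tree", t))
  }
  # a mouse-lineage duplication (two mouse leaves) maps to none
  two_mice <- parse_nhx(paste0(
    "((m1[&&NHX:S=mus_musculus],m2[&&NHX:S=mus_musculus])",
    "[&&NHX:S=Mammalia:D=Y:B=90],(gar1[&&NHX:S=sp_gar],((dA[&&NHX:S=danio_rerio],",
    "f1[&&NHX:S=sp_fish1])[&&NHX:S=Clupeocephala:D=N],(dB[&&NHX:S=danio_rerio],",
    "f2[&&NHX:S=sp_fish2])[&&NHX:S=Clupeocephala:D=N])",
    "[&&NHX:S=Clupeocephala:D=Y:B=90])[&&NHX:S=Neopterygii:D=N])",
    "[&&NHX:S=Euteleostomi:D=N];"))
  cls <- classify_3r(two_mice)
  om <- map_orthologs(two_mice, cls, "danio_rerio", "mus_musculus")
  expect_true(all(om$label == "none"))
  expect_error(map_orthologs(two_mice, cls[0, ], "danio_rerio",
                             "mus_musculus"), "classify")
})

test_that("no gene is labelled both ohnolog and singleton across a tree set", {
  gt <- gen_gene_trees(synth_config(seed = 19, n_trees = 100))
  for (i in gt$meta$tree[gt$meta$family == "3r"]) {
    res <- classify_3r(gt$trees[[i]])
    expect_equal(anyDuplicated(res$gene_id), 0)
  }
})
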