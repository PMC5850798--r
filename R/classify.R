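# ---------------------------------------------------------------------------
# Phylogenomic classification of ohnologs / singletons / small-scale
# duplicates from event-annotated gene trees.
# ---------------------------------------------------------------------------

# topmost speciation node dated `taxon` (preorder search); NULL if absent
find_subtree_root <- function(tree, taxa) {
  if (is_leaf(tree)) return(NULL)
  if (tree$event == "speciation" && tree$taxon %in% taxa) return(tree)
  for (ch in tree$children) {
    hit <- find_subtree_root(ch, taxa)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

has_taxon_node <- function(tree, taxon) {
  any(vapply(internal_nodes(tree), function(nd)
    identical(nd$taxon, taxon), TRUE))
}

classification_result <- function(genes, label, trace = "") {
  if (!length(genes))
    return(data.frame(gene_id = character(), label = character(),
                      trace = character(), stringsAsFactors = FALSE))
  data.frame(gene_id = genes, label = label, trace = trace,
             stringsAsFactors = FALSE)
}

# checks that `node` subtends exactly one focal leaf reachable without
# crossing a disqualifying duplication node; returns the gene id or a trace
clean_focal_path <- function(node, focal_species, ignore_zero_conf = FALSE) {
  n_focal <- sum(leaf_species(node) == focal_species)
  if (n_focal == 0) return(list(ok = FALSE, trace = "no_focal_leaf"))
  if (n_focal > 1) return(list(ok = FALSE, trace = "multiple_focal_leaves"))
  path <- path_to_species(node, focal_species)
  if (is.null(path)) return(list(ok = FALSE, trace = "multiple_focal_leaves"))
  dups <- vapply(path, function(nd) nd$event == "duplication", TRUE)
  if (ignore_zero_conf)
    dups <- dups & vapply(path, function(nd)
      !is.na(nd$conf) && nd$conf > 0, TRUE)
  if (any(dups)) return(list(ok = FALSE, trace = "dup_on_focal_path"))
  gene <- leaf_genes(node)[leaf_species(node) == focal_species]
  list(ok = TRUE, gene = gene)
}

#' Classify focal genes with respect to the teleost (3R) genome duplication
#'
#' Scans a gene tree for the canonical 3R topology: a basal speciation node
#' dated at the pre-duplication level (Neopterygii, separating the gar-like
#' outgroup), whose teleost-side child is a high-confidence duplication
#' node dated at the post-duplication level (Clupeocephala), followed by
#' two speciation nodes at the same level, each subtending exactly one
#' focal-species gene with no further duplication on the path to it. Genes
#' in such trees are ohnologs. Singletons instead show a single
#' Clupeocephala speciation below the basal node with one clean focal gene.
#' Anything else is unclassified, with a trace naming the first failed
#' condition.
#'
#' @param tree a `gene_tree` (may be rooted above the basal node, e.g. at
#'   Euteleostomi; the topmost speciation node at `root_taxon` is used).
#' @param focal_species focal species id (default `"danio_rerio"`).
#' @param wgd_taxon taxon label dating the duplication (default
#'   `"Clupeocephala"`).
#' @param root_taxon taxon label of the basal speciation node (default
#'   `"Neopterygii"`).
#' @param min_confidence duplication confidence must be strictly above this
#'   (default 0.5, i.e. a score above 50%).
#' @return data.frame `gene_id`, `label` in
#'   `{ohnolog, singleton, unclassified}`, `trace`.
#' @export
classify_3r <- function(tree, focal_species = "danio_rerio",
                        wgd_taxon = "Clupeocephala",
                        root_taxon = "Neopterygii", min_confidence = 0.5) {
  focal <- unique(leaf_genes(tree)[leaf_species(tree) == focal_species])
  if (!length(focal)) {
    warning("tree contains no ", focal_species, " leaf")
    return(classification_result(character(), character()))
  }
  unclass_all <- function(trace) classification_result(focal, "unclassified", trace)

  sub <- find_subtree_root(tree, root_taxon)
  if (is.null(sub)) return(unclass_all("no_root_taxon"))
  if (length(sub$children) != 2) return(unclass_all("polytomy"))

  # the teleost-side child: the one dated at the wgd taxon
  kids <- Filter(function(ch) !is_leaf(ch) && identical(ch$taxon, wgd_taxon),
                 sub$children)
  if (length(kids) != 1) return(unclass_all("no_wgd_node"))
  node <- kids[[1]]

  if (node$event == "duplication") {
    if (is.na(node$conf) || node$conf <= min_confidence)
      return(unclass_all("low_confidence"))
    if (length(node$children) != 2) return(unclass_all("polytomy"))
    spec_ok <- vapply(node$children, function(ch)
      !is_leaf(ch) && ch$event == "speciation" &&
        identical(ch$taxon, wgd_taxon), TRUE)
    if (!all(spec_ok)) return(unclass_all("missing_wgd_speciation"))
    checks <- lapply(node$children, clean_focal_path, focal_species)
    if (!all(vapply(checks, `[[`, TRUE, "ok")))
      return(unclass_all(checks[[which(!vapply(checks, `[[`, TRUE, "ok"))[1]]]$trace))
    genes <- vapply(checks, `[[`, "", "gene")
    res <- classification_result(genes, "ohnolog")
    extra <- setdiff(focal, genes)
    if (length(extra))
      res <- rbind(res, classification_result(extra, "unclassified",
                                              "focal_outside_wgd_subtrees"))
    return(res)
  }

  if (node$event == "speciation") {
    chk <- clean_focal_path(node, focal_species)
    if (!chk$ok) return(unclass_all(chk$trace))
    res <- classification_result(chk$gene, "singleton")
    extra <- setdiff(focal, chk$gene)
    if (length(extra))
      res <- rbind(res, classification_result(extra, "unclassified",
                                              "focal_outside_wgd_subtrees"))
    return(res)
  }
  unclass_all("no_wgd_node")
}

#' Classify focal genes with respect to the vertebrate (2R) duplications
#'
#' As [classify_3r()] but with the rules specific to the base of
#' vertebrates: the basal speciation node is dated at Chordata (Bilateria
#' is used as fallback when the tree has no Chordata node); one or
#' optionally two nested high-confidence duplication nodes dated at
#' Vertebrata follow (Euteleostomi is used instead when no lamprey gene is
#' in the subtree), then two speciation nodes at the same taxon, each
#' subtending exactly one focal (mouse-like) gene plus genes from at least
#' `min_fish_species` distinct fish species. Zero-confidence duplication
#' nodes on the path to the focal gene are ignored, reflecting dubious
#' topology-inconsistency duplications in dense mammalian trees.
#'
#' @inheritParams classify_3r
#' @param root_taxa basal-node taxa, in preference order.
#' @param wgd_taxa duplication-dating taxa: first used when a lamprey leaf
#'   is present, second when not.
#' @param species_clades data.frame (species_id, clade) marking which
#'   leaves are `fish` and which `lamprey`.
#' @param min_fish_species minimum distinct fish species per subtree.
#' @export
classify_2r <- function(tree, species_clades, focal_species = "mus_musculus",
                        root_taxa = c("Chordata", "Bilateria"),
                        wgd_taxa = c("Vertebrata", "Euteleostomi"),
                        min_fish_species = 2, min_confidence = 0.5) {
  focal <- unique(leaf_genes(tree)[leaf_species(tree) == focal_species])
  if (!length(focal)) {
    warning("tree contains no ", focal_species, " leaf")
    return(classification_result(character(), character()))
  }
  unclass_all <- function(trace) classification_result(focal, "unclassified", trace)

  fish_sp <- species_clades$species_id[species_clades$clade == "fish"]
  lamprey_sp <- species_clades$species_id[species_clades$clade == "lamprey"]

  root_use <- if (has_taxon_node(tree, root_taxa[1])) root_taxa[1] else root_taxa[2]
  sub <- find_subtree_root(tree, root_use)
  if (is.null(sub)) return(unclass_all("no_root_taxon"))
  if (length(sub$children) != 2) return(unclass_all("polytomy"))

  has_lamprey <- any(leaf_species(sub) %in% lamprey_sp)
  wgd_taxon <- if (has_lamprey) wgd_taxa[1] else wgd_taxa[2]

  kids <- Filter(function(ch) !is_leaf(ch) && identical(ch$taxon, wgd_taxon),
                 sub$children)
  if (length(kids) != 1) return(unclass_all("no_wgd_node"))
  node <- kids[[1]]

  subtree_ok <- function(ch) {
    if (is_leaf(ch) || ch$event != "speciation" ||
        !identical(ch$taxon, wgd_taxon))
      return(list(ok = FALSE, trace = "missing_wgd_speciation"))
    nf <- length(unique(leaf_species(ch)[leaf_species(ch) %in% fish_sp]))
    if (nf < min_fish_species)
      return(list(ok = FALSE, trace = "too_few_fish_species"))
    clean_focal_path(ch, focal_species, ignore_zero_conf = TRUE)
  }

  if (node$event == "duplication") {
    if (is.na(node$conf) || node$conf <= min_confidence)
      return(unclass_all("low_confidence"))
    # optional second nested duplication at the same taxon
    inner <- Filter(function(ch) !is_leaf(ch) && ch$event == "duplication" &&
                      identical(ch$taxon, wgd_taxon), node$children)
    if (length(inner) == 1) {
      if (is.na(inner[[1]]$conf) || inner[[1]]$conf <= min_confidence)
        return(unclass_all("low_confidence"))
      node <- inner[[1]]
    }
    if (length(node$children) != 2) return(unclass_all("polytomy"))
    checks <- lapply(node$children, subtree_ok)
    ok <- vapply(checks, `[[`, TRUE, "ok")
    if (!all(ok)) return(unclass_all(checks[[which(!ok)[1]]]$trace))
    genes <- vapply(checks, `[[`, "", "gene")
    res <- classification_result(genes, "ohnolog")
    extra <- setdiff(focal, genes)
    if (length(extra))
      res <- rbind(res, classification_result(extra, "unclassified",
                                              "focal_outside_wgd_subtrees"))
    return(res)
  }

  if (node$event == "speciation") {
    chk <- subtree_ok(node)
    if (!chk$ok) return(unclass_all(chk$trace))
    res <- classification_result(chk$gene, "singleton")
    extra <- setdiff(focal, chk$gene)
    if (length(extra))
      res <- rbind(res, classification_result(extra, "unclassified",
                                              "focal_outside_wgd_subtrees"))
    return(res)
  }
  unclass_all("no_wgd_node")
}

#' Identify small-scale duplicates in a gene tree
#'
#' Finds focal-species paralog pairs whose most recent common ancestor is a
#' high-confidence duplication node dated within `allowed_dup_taxa` (e.g.
#' Otophysa for zebrafish, inside Clupeocephala-rooted subtrees), filtered
#' on pairwise sequence identity: pairs at 100% identity are discarded as
#' probable assembly artifacts, pairs below 10% as probable gene splits.
#'
#' @param tree a `gene_tree`.
#' @param identity_table data.frame (gene_a, gene_b, pct_identity in
#'   [0, 100]) for focal paralog pairs; pairs without an entry are skipped
#'   with a warning.
#' @param focal_species focal species id.
#' @param root_taxon required taxon of the basal speciation node.
#' @param allowed_dup_taxa taxa at which the duplication may be dated.
#' @param identity_bounds retained identity interval `[lo, hi)` on the 0-1
#'   scale (default `[0.10, 1.00)`).
#' @param min_confidence duplication confidence strictly above this.
#' @return character vector of focal gene ids in at least one retained pair.
#' @export
classify_ssd <- function(tree, identity_table, focal_species,
                         root_taxon = "Clupeocephala",
                         allowed_dup_taxa = "Otophysa",
                         identity_bounds = c(0.10, 1.00),
                         min_confidence = 0.5) {
  sub <- find_subtree_root(tree, root_taxon)
  if (is.null(sub)) return(character())
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  idmap <- setNames(identity_table$pct_identity / 100,
                    key(identity_table$gene_a, identity_table$gene_b))
  retained <- character()
  walk <- function(node) {
    if (is_leaf(node)) return()
    if (node$event == "duplication" && node$taxon %in% allowed_dup_taxa &&
        !is.na(node$conf) && node$conf > min_confidence &&
        length(node$children) == 2) {
      g1 <- leaf_genes(node$children[[1]])[
        leaf_species(node$children[[1]]) == focal_species]
      g2 <- leaf_genes(node$children[[2]])[
        leaf_species(node$children[[2]]) == focal_species]
      for (a in g1) for (b in g2) {
        i <- idmap[key(a, b)]
        if (is.na(i)) {
          warning(sprintf("no identity for pair (%s, %s); skipped", a, b))
          next
        }
        if (i >= identity_bounds[1] && i < identity_bounds[2])
          retained <<- union(retained, c(a, b))
      }
    }
    for (ch in node$children) walk(ch)
  }
  walk(sub)
  sort(retained)
}

#' Map outgroup genes to ohnolog/singleton orthology classes
#'
#' After classifying the focal species' genes on a tree, labels each
#' outgroup (e.g. mouse) gene by its orthology relationship at
#' `level_taxon` (Euteleostomi): `ortholog_of_ohnolog` when a single
#' outgroup gene is in two-to-one orthology with two classified focal
#' ohnologs; `ortholog_of_singleton` when in one-to-one orthology with a
#' classified singleton; `none` otherwise (e.g. lineage-specific
#' duplications of the outgroup gene).
#'
#' @param tree a `gene_tree` rooted at or above `level_taxon`.
#' @param classification result of [classify_3r()] on this tree.
#' @param focal_species,outgroup_species species ids.
#' @param level_taxon speciation level of the orthology relationship.
#' @return data.frame `gene_id` (outgroup), `label`.
#' @export
map_orthologs <- function(tree, classification, focal_species,
                          outgroup_species, level_taxon = "Euteleostomi") {
  if (is.null(classification) || !nrow(classification))
    stop("classify the focal species' genes on this tree first")
  out_genes <- unique(leaf_genes(tree)[leaf_species(tree) == outgroup_species])
  if (!length(out_genes))
    return(data.frame(gene_id = character(), label = character(),
                      stringsAsFactors = FALSE))
  none <- function() data.frame(gene_id = out_genes, label = "none",
                                stringsAsFactors = FALSE)
  sub <- find_subtree_root(tree, level_taxon)
  if (is.null(sub)) return(none())
  sub_out <- leaf_genes(sub)[leaf_species(sub) == outgroup_species]
  if (length(sub_out) != 1) return(none())
  # no duplication on the path from the level node to the outgroup leaf
  chk <- clean_focal_path(sub, outgroup_species, ignore_zero_conf = TRUE)
  if (!chk$ok) return(none())
  focal_in_sub <- leaf_genes(sub)[leaf_species(sub) == focal_species]
  lab <- setNames(classification$label, classification$gene_id)
  cls <- lab[focal_in_sub]
  label <- if (length(focal_in_sub) == 2 && all(cls == "ohnolog")) {
    "ortholog_of_ohnolog"
  } else if (length(focal_in_sub) == 1 && identical(unname(cls), "singleton")) {
    "ortholog_of_singleton"
  } else "none"
  res <- none()
  res$label[res$gene_id == sub_out] <- label
  res
}

#' Read a species-to-clade table (TSV: species_id, clade)
#' @param file path.
#' @return data.frame with columns `species_id`, `clade`.
#' @export
read_species_clades <- function(file) {
  read.delim(file, stringsAsFactors = FALSE,
             col.names = c("species_id", "clade"))
}

#' Read a pairwise identity table (TSV: gene_a, gene_b, pct_identity)
#' @param file path.
#' @return data.frame.
#' @export
read_identity_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE,
                   col.names = c("gene_a", "gene_b", "pct_identity"))
  df$pct_identity <- as.numeric(df$pct_identity)
  df
}
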