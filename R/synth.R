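# ---------------------------------------------------------------------------
# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of its config: the seed is set locally (the caller's RNG
# state is restored on exit) so identical configs give identical output.
# ---------------------------------------------------------------------------

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic-data configuration
#'
#' Bundles the parameters of all generators; any field can be overridden.
#' Defaults describe the study conditions emulated throughout the test
#' suite (see the methods vignette for the rationale behind each value).
#'
#' @param seed integer RNG seed.
#' @param ... overrides of the default fields.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # ontology / annotations
    n_terms = 50, n_genes = 1000, n_class_genes = 40, dag_branching = 3,
    base_rate = 0.08, enrichment_fold = 5, n_enriched = 1,
    # gene trees
    n_trees = 500, corruption_rate = 0.3,
    family_probs = c(`3r` = 0.40, `2r` = 0.35, ssd = 0.25),
    conf_range = c(0.6, 0.99),
    # codon model
    n_codon_genes = 200, n_codons = 500, conservation_rate = 0.7,
    preferred_freq = 0.5, planted_psi = 2,
    # expression model
    n_expr_genes = 2000, prop_ohnolog = 0.35,
    p1 = 0.6, p0 = 0.3, n_nervous = 6, n_other = 6, samples_per_tissue = 3,
    signal_meanlog = 2, signal_sdlog = 0.5,
    # tpm model
    n_coding = 5000, n_intergenic = 2000,
    coding_meanlog = log(10), coding_sdlog = 1.5,
    intergenic_meanlog = log(0.1), intergenic_sdlog = 1,
    # covariate model
    n_cov_genes = 5000, beta_dn = -0.8, beta_psi = 0.5, beta_expr = 0.5,
    intercept = -1.8)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "synth_config")
}

# ---------------------------------------------------------------------------
# Ontology + annotations
# ---------------------------------------------------------------------------

#' Generate a synthetic ontology with class-biased annotations
#'
#' Builds a random rooted DAG of `n_terms` terms (each non-root term has
#' one or two parents; edges typed is_a or part_of at random), then
#' annotates genes to leaf terms: a planted "retained" gene class is
#' annotated to the enriched leaf terms at `enrichment_fold` times the
#' base rate, all other gene/leaf pairs at the base rate. Annotations are
#' emitted unpropagated.
#'
#' @param cfg a [synth_config()].
#' @return list: `onto` ([ontology_graph()]), `ann` (unpropagated
#'   [annotation_set()]), `truth` (list with `class_genes`,
#'   `enriched_terms`, `fold`), `foreground` (the class genes with at
#'   least one annotation), `reference` (all annotated genes).
#' @export
gen_ontology_annotations <- function(cfg = synth_config()) {
  with_seed(cfg$seed, {
    n <- cfg$n_terms
    b <- cfg$dag_branching
    terms <- sprintf("SYN:%04d", seq_len(n))
    # complete b-ary tree backbone: every internal term has >= 2 children,
    # so no ancestor's propagated gene set can collapse onto a single
    # child's (which would make parent and child statistically identical)
    ec <- character(); ep <- character(); er <- character()
    for (i in 2:n) {
      p <- (i - 2) %/% b + 1
      ec <- c(ec, terms[i]); ep <- c(ep, terms[p])
      er <- c(er, sample(c("is_a", "part_of"), 1))
    }
    internal <- unique(ep)
    for (i in 3:n) {     # extra edges make it a DAG (1-2 parents per term)
      if (runif(1) < 0.25) {
        p1 <- (i - 2) %/% b + 1
        cand <- setdiff(intersect(terms[seq_len(i - 1)], internal),
                        terms[p1])
        if (length(cand)) {
          ec <- c(ec, terms[i]); ep <- c(ep, sample(cand, 1))
          er <- c(er, sample(c("is_a", "part_of"), 1))
        }
      }
    }
    edges <- data.frame(child = ec, parent = ep, relation = er,
                        stringsAsFactors = FALSE)
    onto <- ontology_graph(terms, setNames(paste("structure", seq_len(n)),
                                           terms), edges)
    leaves <- setdiff(terms, edges$parent)
    if (cfg$n_enriched > length(leaves))
      stop("requested more enriched terms than available leaf terms")
    depth <- term_depths(onto)
    # plant the signal on deep leaves with at least one annotated sibling,
    # so the enriched leaf is statistically separable from its ancestors
    backbone_parent <- setNames(terms[(seq_len(n)[-1] - 2) %/% b + 1],
                                terms[-1])
    sib_ok <- vapply(leaves, function(t)
      sum(backbone_parent == backbone_parent[t]) >= 2, TRUE)
    cand <- leaves[sib_ok]
    if (length(cand) < cfg$n_enriched) cand <- leaves
    enriched <- cand[order(-depth[cand], cand)][seq_len(cfg$n_enriched)]

    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    class_genes <- genes[seq_len(cfg$n_class_genes)]
    rate_hi <- min(1, cfg$enrichment_fold * cfg$base_rate)
    g2t <- lapply(setNames(genes, genes), function(g) {
      rates <- ifelse(leaves %in% enriched & g %in% class_genes,
                      rate_hi, cfg$base_rate)
      leaves[runif(length(leaves)) < rates]
    })
    g2t <- g2t[lengths(g2t) > 0]
    list(onto = onto,
         ann = annotation_set(g2t),
         truth = list(class_genes = class_genes, enriched_terms = enriched,
                      fold = cfg$enrichment_fold),
         foreground = intersect(class_genes, names(g2t)),
         reference = names(g2t))
  })
}

# ---------------------------------------------------------------------------
# Gene trees
# ---------------------------------------------------------------------------

leafn <- function(...) gene_tree_leaf(...)
noden <- function(...) gene_tree_node(...)

#' Species-to-clade table used by the synthetic gene trees
#' @return data.frame `species_id`, `clade`.
#' @export
synth_species_clades <- function() {
  data.frame(
    species_id = c("danio_rerio", "sp_fish1", "sp_fish2", "sp_gar",
                   "sp_lamprey", "mus_musculus", "sp_mammal1",
                   "sp_outgroup_chordate"),
    clade = c("fish", "fish", "fish", "holostei", "lamprey", "mammal",
              "mammal", "outgroup"),
    stringsAsFactors = FALSE)
}

# template builders; `gid` generates gene ids unique within the tree
build_3r_tree <- function(gid, conf, template = c("ohnolog", "singleton"),
                          corruption = "none") {
  template <- match.arg(template)
  gA <- gid("danio_rerio"); gB <- gid("danio_rerio")
  mg <- gid("mus_musculus")
  f1 <- leafn(gid("sp_fish1"), "sp_fish1")
  f2 <- leafn(gid("sp_fish2"), "sp_fish2")
  gar <- leafn(gid("sp_gar"), "sp_gar")
  root_taxon <- if (corruption == "wrong_root") "Holostei" else "Neopterygii"
  if (corruption == "conf050") conf <- 0.50
  if (corruption == "conf049") conf <- 0.49
  if (corruption == "conf_low") conf <- 0.30

  danioA <- leafn(gA, "danio_rerio")
  if (corruption == "extra_dup") {
    danioA <- noden("duplication", "Otophysa", 0.9,
                    list(leafn(gA, "danio_rerio"),
                         leafn(gid("sp_fish1"), "sp_fish1")))
  }
  if (corruption == "missing_focal")
    danioA <- leafn(gid("sp_fish1"), "sp_fish1")

  if (template == "ohnolog") {
    subA <- noden("speciation", "Clupeocephala", NA,
                  list(danioA, f1))
    subB <- noden("speciation", "Clupeocephala", NA,
                  list(leafn(gB, "danio_rerio"), f2))
    teleost <- noden("duplication", "Clupeocephala", conf, list(subA, subB))
    genes <- c(gA, gB)
  } else {
    teleost <- noden("speciation", "Clupeocephala", NA, list(danioA, f1))
    genes <- gA
  }
  basal <- noden("speciation", root_taxon, NA, list(gar, teleost))
  tree <- noden("speciation", "Euteleostomi", NA,
                list(leafn(mg, "mus_musculus"), basal))
  class(tree) <- c("gene_tree", class(tree))

  if (corruption == "none") {
    label <- template
    trace <- ""
    ortho <- if (template == "ohnolog") "ortholog_of_ohnolog"
             else "ortholog_of_singleton"
  } else {
    label <- "unclassified"
    trace <- switch(corruption,
                    conf050 = , conf049 = , conf_low = "low_confidence",
                    extra_dup = "dup_on_focal_path",
                    missing_focal = "no_focal_leaf",
                    wrong_root = "no_root_taxon")
    ortho <- "none"
    if (corruption == "missing_focal") genes <- setdiff(genes, gA)
  }
  list(tree = tree, family = "3r", template = template,
       corruption = corruption,
       truth = data.frame(gene_id = genes, label = label, trace = trace,
                          stringsAsFactors = FALSE),
       outgroup = data.frame(gene_id = mg, label = ortho,
                             stringsAsFactors = FALSE))
}

build_2r_tree <- function(gid, conf,
                          template = c("ohnolog_lamprey", "ohnolog_nolamprey",
                                       "ohnolog_twodup", "ohnolog_zeroconf",
                                       "singleton"),
                          corruption = "none") {
  template <- match.arg(template)
  if (corruption == "conf050") conf <- 0.50
  if (corruption == "conf_low") conf <- 0.30
  lamprey_present <- template %in% c("ohnolog_lamprey", "ohnolog_twodup",
                                     "ohnolog_zeroconf", "singleton")
  wgd <- if (lamprey_present) "Vertebrata" else "Euteleostomi"

  fish_clade <- function(n_fish = 2) {
    f1 <- leafn(gid("sp_fish1"), "sp_fish1")
    if (n_fish < 2) return(f1)
    noden("speciation", "Clupeocephala", NA,
          list(f1, leafn(gid("sp_fish2"), "sp_fish2")))
  }

  make_subtree <- function(n_fish = 2, zeroconf_path = FALSE,
                           lamprey_in = lamprey_present,
                           extra_dup = FALSE) {
    mg <- gid("mus_musculus")
    mouse_part <- leafn(mg, "mus_musculus")
    if (zeroconf_path)
      mouse_part <- noden("duplication", "Mammalia", 0,
                          list(mouse_part, leafn(gid("sp_mammal1"),
                                                 "sp_mammal1")))
    if (extra_dup)
      mouse_part <- noden("duplication", "Mammalia", 0.9,
                          list(mouse_part, leafn(gid("sp_mammal1"),
                                                 "sp_mammal1")))
    eut <- noden("speciation", "Euteleostomi", NA,
                 list(mouse_part, fish_clade(n_fish)))
    node <- if (lamprey_in) {
      noden("speciation", wgd, NA,
            list(leafn(gid("sp_lamprey"), "sp_lamprey"), eut))
    } else {
      # without lamprey the wgd-level speciation is the Euteleostomi node
      eut$taxon <- wgd
      eut
    }
    list(node = node, gene = mg)
  }

  s1 <- make_subtree(
    n_fish = if (corruption == "too_few_fish") 1 else 2,
    zeroconf_path = template == "ohnolog_zeroconf",
    extra_dup = corruption == "extra_dup")
  genes <- s1$gene
  if (template == "singleton") {
    vert_part <- s1$node
  } else {
    s2 <- make_subtree()
    genes <- c(genes, s2$gene)
    dup <- noden("duplication", wgd, conf, list(s1$node, s2$node))
    if (template == "ohnolog_twodup") {
      extra <- noden("speciation", wgd, NA,
                     list(leafn(gid("sp_lamprey"), "sp_lamprey"),
                          fish_clade()))
      dup <- noden("duplication", wgd, conf, list(dup, extra))
    }
    vert_part <- dup
  }
  if (corruption == "lamprey_fallback") {
    # a lamprey gene inside a tree whose nodes are dated for the fallback
    vert_part$children[[1]] <- noden(
      "speciation", "Euteleostomi", NA,
      list(leafn(gid("sp_lamprey"), "sp_lamprey"), vert_part$children[[1]]))
  }
  tree <- noden("speciation", "Chordata", NA,
                list(leafn(gid("sp_outgroup_chordate"),
                           "sp_outgroup_chordate"), vert_part))
  class(tree) <- c("gene_tree", class(tree))

  if (corruption == "none") {
    label <- if (template == "singleton") "singleton" else "ohnolog"
    trace <- ""
  } else {
    label <- "unclassified"
    trace <- switch(corruption,
                    conf050 = , conf_low = "low_confidence",
                    too_few_fish = "too_few_fish_species",
                    extra_dup = "dup_on_focal_path",
                    lamprey_fallback = "no_wgd_node")
  }
  list(tree = tree, family = "2r", template = template,
       corruption = corruption,
       truth = data.frame(gene_id = genes, label = label, trace = trace,
                          stringsAsFactors = FALSE),
       outgroup = NULL)
}

build_ssd_tree <- function(gid, conf, corruption = "none") {
  gA <- gid("danio_rerio"); gB <- gid("danio_rerio")
  identity <- round(runif(1, 0.30, 0.95), 3)
  dup_taxon <- "Otophysa"
  if (corruption == "identity_100") identity <- 1.00
  if (corruption == "identity_low") identity <- 0.09
  if (corruption == "conf_low") conf <- 0.40
  if (corruption == "species_specific") dup_taxon <- "Danio rerio"
  dup <- noden("duplication", dup_taxon, conf,
               list(leafn(gA, "danio_rerio"), leafn(gB, "danio_rerio")))
  tree <- noden("speciation", "Clupeocephala", NA,
                list(dup, leafn(gid("sp_fish1"), "sp_fish1")))
  class(tree) <- c("gene_tree", class(tree))
  retained <- corruption == "none"
  list(tree = tree, family = "ssd", template = "ssd", corruption = corruption,
       truth = data.frame(gene_id = c(gA, gB),
                          label = if (retained) "ssd_duplicate" else
                            "ssd_excluded",
                          trace = "", stringsAsFactors = FALSE),
       outgroup = NULL,
       identity = data.frame(gene_a = gA, gene_b = gB,
                             pct_identity = identity * 100,
                             stringsAsFactors = FALSE))
}

#' Generate synthetic gene trees with planted classification truth
#'
#' Draws `n_trees` trees from topology templates for 3R ohnologs and
#' singletons, 2R variants (with/without lamprey, one or two duplication
#' rounds, zero-confidence duplications on the mammalian path), and
#' small-scale duplicates with sampled pairwise identity. A fraction
#' `corruption_rate` of trees receives exactly one rule-violating
#' corruption (low or boundary duplication confidence, extra duplication
#' on the focal path, missing focal leaf, wrong basal taxon, too few fish
#' species, lamprey breaking the Euteleostomi fallback, out-of-bounds SSD
#' identity), tagged in the truth table.
#'
#' @param cfg a [synth_config()].
#' @return list: `trees` (list of `gene_tree`), `meta` (per-tree family /
#'   template / corruption), `truth` (per focal gene: tree, label, trace),
#'   `ortholog_truth` (outgroup labels for 3R-family trees),
#'   `identity` (SSD pairwise identity table), `species_clades`.
#' @export
gen_gene_trees <- function(cfg = synth_config()) {
  with_seed(cfg$seed, {
    corruptions <- list(
      `3r` = c("conf050", "conf049", "conf_low", "extra_dup",
               "missing_focal", "wrong_root"),
      `2r` = c("conf050", "conf_low", "too_few_fish", "extra_dup",
               "lamprey_fallback"),
      ssd = c("identity_100", "identity_low", "conf_low",
              "species_specific"))
    templates_2r <- c("ohnolog_lamprey", "ohnolog_nolamprey",
                      "ohnolog_twodup", "ohnolog_zeroconf", "singleton")
    trees <- vector("list", cfg$n_trees)
    meta <- truth <- ortho <- ident <- list()
    for (i in seq_len(cfg$n_trees)) {
      counter <- 0L
      gid <- function(sp) {
        counter <<- counter + 1L
        sprintf("t%04d_%s_g%d", i, sub("_.*", "", sp), counter)
      }
      fam <- sample(names(cfg$family_probs), 1, prob = cfg$family_probs)
      corr <- if (runif(1) < cfg$corruption_rate)
        sample(corruptions[[fam]], 1) else "none"
      conf <- runif(1, cfg$conf_range[1], cfg$conf_range[2])
      built <- switch(fam,
        `3r` = build_3r_tree(gid, conf,
                             if (corr %in% c("wrong_root", "none"))
                               sample(c("ohnolog", "singleton"), 1)
                             else "ohnolog",
                             corruption = corr),
        `2r` = build_2r_tree(gid, conf,
                             if (corr == "lamprey_fallback")
                               "ohnolog_nolamprey"
                             else if (corr != "none")
                               sample(setdiff(templates_2r, "singleton"), 1)
                             else sample(templates_2r, 1),
                             corruption = corr),
        ssd = build_ssd_tree(gid, conf, corruption = corr))
      trees[[i]] <- built$tree
      meta[[i]] <- data.frame(tree = i, family = built$family,
                              template = built$template,
                              corruption = built$corruption,
                              stringsAsFactors = FALSE)
      tr <- built$truth; tr$tree <- i
      truth[[i]] <- tr
      if (!is.null(built$outgroup)) {
        og <- built$outgroup; og$tree <- i
        ortho[[i]] <- og
      }
      if (!is.null(built$identity)) ident[[i]] <- built$identity
    }
    list(trees = trees,
         meta = do.call(rbind, meta),
         truth = do.call(rbind, truth),
         ortholog_truth = do.call(rbind, ortho),
         identity = if (length(ident)) do.call(rbind, ident) else
           data.frame(gene_a = character(), gene_b = character(),
                      pct_identity = numeric(), stringsAsFactors = FALSE),
         species_clades = synth_species_clades())
  })
}

# ---------------------------------------------------------------------------
# Codon alignments
# ---------------------------------------------------------------------------

synth_codon_families <- function() {
  list(K = c("AAA", "AAG"), N = c("AAT", "AAC"), D = c("GAT", "GAC"),
       E = c("GAA", "GAG"), F = c("TTT", "TTC"), Y = c("TAT", "TAC"),
       H = c("CAT", "CAC"), Q = c("CAA", "CAG"))
}

#' Preferred-codon table of the synthetic codon model
#' @return named list, amino acid -> preferred codon(s).
#' @export
synth_preferred_codons <- function() {
  lapply(synth_codon_families(), `[`, 2)
}

# conserved/variable preferred-use probabilities achieving a 2x2 odds
# ratio `psi` at marginal preferred frequency `q` given conservation rate r
solve_pref_probs <- function(psi, q, r) {
  inv_odds <- function(o) o / (1 + o)
  f <- function(pv) {
    pc <- inv_odds(psi * pv / (1 - pv))
    r * pc + (1 - r) * pv - q
  }
  lo <- 1e-9; hi <- 1 - 1e-9
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf(
      "infeasible (psi = %g, marginal = %g, conservation = %g); achievable marginals span (%.4f, %.4f)",
      psi, q, r, r * inv_odds(psi * lo / (1 - lo)) + (1 - r) * lo,
      r * inv_odds(psi * hi / (1 - hi)) + (1 - r) * hi))
  pv <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  pc <- inv_odds(psi * pv / (1 - pv))
  c(conserved = pc, variable = pv)
}

#' Generate pairwise codon alignments with a planted Akashi association
#'
#' Per gene, each codon site is conserved with probability
#' `conservation_rate`; the focal codon is preferred with a probability
#' depending on conservation status, chosen so that the per-site 2x2
#' (conserved x preferred) odds ratio equals `planted_psi` at the stated
#' marginal preferred-codon frequency. The comparator codon encodes the
#' same amino acid at conserved sites and a different one at variable
#' sites; a terminal stop codon is appended. Only two-codon amino acids
#' are used, so every informative site contributes a stratum cell.
#'
#' @param cfg a [synth_config()].
#' @return list: `alignments` (data.frame gene_id, focal, comparator),
#'   `preferred` (named list), `truth` (planted psi and per-status
#'   preferred-use probabilities).
#' @export
gen_codon_alignments <- function(cfg = synth_config()) {
  fam <- synth_codon_families()
  pref <- synth_preferred_codons()
  probs <- solve_pref_probs(cfg$planted_psi, cfg$preferred_freq,
                            cfg$conservation_rate)
  with_seed(cfg$seed, {
    aas <- names(fam)
    genes <- lapply(seq_len(cfg$n_codon_genes), function(i) {
      m <- cfg$n_codons
      aa <- sample(aas, m, replace = TRUE)
      conserved <- runif(m) < cfg$conservation_rate
      p_use <- ifelse(conserved, probs["conserved"], probs["variable"])
      use_pref <- runif(m) < p_use
      focal <- vapply(seq_len(m), function(s) {
        cods <- fam[[aa[s]]]
        if (use_pref[s]) pref[[aa[s]]] else setdiff(cods, pref[[aa[s]]])[1]
      }, "")
      comp_aa <- ifelse(conserved, aa,
                        vapply(aa, function(a) sample(setdiff(aas, a), 1), ""))
      comp <- vapply(comp_aa, function(a) sample(fam[[a]], 1), "")
      data.frame(gene_id = sprintf("cg%04d", i),
                 focal = paste(c(focal, "TAA"), collapse = ""),
                 comparator = paste(c(comp, "TAA"), collapse = ""),
                 stringsAsFactors = FALSE)
    })
    list(alignments = do.call(rbind, genes), preferred = pref,
         truth = list(planted_psi = cfg$planted_psi,
                      p_conserved = unname(probs["conserved"]),
                      p_variable = unname(probs["variable"])))
  })
}

#' Write paired codon alignments as FASTA
#' @param alignments data.frame from [gen_codon_alignments()].
#' @param file output path.
#' @export
write_paired_fasta <- function(alignments, file) {
  lines <- unlist(lapply(seq_len(nrow(alignments)), function(i) {
    c(paste0(">", alignments$gene_id[i], "_focal"), alignments$focal[i],
      paste0(">", alignments$gene_id[i], "_comparator"),
      alignments$comparator[i])
  }))
  writeLines(lines, file)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Expression matrices and TPM tables
# ---------------------------------------------------------------------------

#' Generate class-biased expression calls, signal matrices and TPM tables
#'
#' Ohnolog-ortholog genes are called present in nervous-tissue samples
#' with probability `p1` and elsewhere with `p0`; singleton-ortholog genes
#' are the reverse. The continuous matrix multiplies the calls by
#' log-normal signal. Coding-gene and intergenic TPM vectors are drawn
#' from the configured log-normal models for present/absent thresholding.
#'
#' @param cfg a [synth_config()].
#' @return list: `calls` (logical genes x samples), `signal` (numeric
#'   matrix), `sample_meta` (sample_id, tissue_id, nervous), `classes`
#'   (named gene -> class vector), `tpm_coding`, `tpm_intergenic`.
#' @export
gen_expression <- function(cfg = synth_config()) {
  if (cfg$p1 < cfg$p0) stop("p1 must be >= p0")
  with_seed(cfg$seed, {
    n <- cfg$n_expr_genes
    genes <- sprintf("eg%04d", seq_len(n))
    n_ohno <- round(cfg$prop_ohnolog * n)
    classes <- setNames(c(rep("ohnolog_ortholog", n_ohno),
                          rep("singleton_ortholog", n - n_ohno)), genes)
    tissues <- c(sprintf("nervous_%02d", seq_len(cfg$n_nervous)),
                 sprintf("other_%02d", seq_len(cfg$n_other)))
    nervous <- rep(c(TRUE, FALSE), c(cfg$n_nervous, cfg$n_other))
    sample_meta <- data.frame(
      sample_id = paste0(rep(tissues, each = cfg$samples_per_tissue), "_s",
                         seq_len(cfg$samples_per_tissue)),
      tissue_id = rep(tissues, each = cfg$samples_per_tissue),
      nervous = rep(nervous, each = cfg$samples_per_tissue),
      stringsAsFactors = FALSE)
    p <- outer(classes == "ohnolog_ortholog", sample_meta$nervous,
               function(o, nv) ifelse(o == nv, cfg$p1, cfg$p0))
    calls <- matrix(runif(length(p)) < p, nrow = n,
                    dimnames = list(genes, sample_meta$sample_id))
    signal <- calls * rlnorm(length(calls), cfg$signal_meanlog,
                             cfg$signal_sdlog)
    dimnames(signal) <- dimnames(calls)
    tpm_coding <- setNames(rlnorm(cfg$n_coding, cfg$coding_meanlog,
                                  cfg$coding_sdlog),
                           sprintf("cg%05d", seq_len(cfg$n_coding)))
    tpm_intergenic <- setNames(rlnorm(cfg$n_intergenic,
                                      cfg$intergenic_meanlog,
                                      cfg$intergenic_sdlog),
                               sprintf("ig%05d", seq_len(cfg$n_intergenic)))
    list(calls = calls, signal = signal, sample_meta = sample_meta,
         classes = classes, tpm_coding = tpm_coding,
         tpm_intergenic = tpm_intergenic)
  })
}

# ---------------------------------------------------------------------------
# Gene covariates with a planted retention model
# ---------------------------------------------------------------------------

#' Generate gene covariates with a planted logistic retention model
#'
#' Draws per-gene dN, Psi, and maximum nervous expression, then assigns
#' the ohnolog-ortholog class with probability
#' `plogis(intercept + beta_dn * z(log10 dN) + beta_psi * z(Psi) +
#' beta_expr * z(max expr))`, so retention decreases with dN and increases
#' with Psi and nervous expression. A `nervous` indicator splits genes for
#' the nervous / non-nervous contrast: the dN and Psi effects are planted
#' for nervous-system genes only, mirroring the headline contrast.
#'
#' @param cfg a [synth_config()].
#' @return data.frame: gene_id, dn, psi, nervous_max_expr, nervous
#'   (logical), label (1 = ohnolog ortholog), class.
#' @export
gen_covariates <- function(cfg = synth_config()) {
  with_seed(cfg$seed, {
    n <- cfg$n_cov_genes
    dn <- rlnorm(n, log(0.05), 1)
    psi <- rlnorm(n, log(1.2), 0.3)
    expr <- rlnorm(n, log(6), 0.5)
    nervous <- runif(n) < 0.8
    z <- function(x) (x - mean(x)) / sd(x)
    eta <- cfg$intercept +
      ifelse(nervous,
             cfg$beta_dn * z(log10(dn)) + cfg$beta_psi * z(psi) +
               cfg$beta_expr * z(expr),
             0)
    label <- as.integer(runif(n) < stats::plogis(eta))
    data.frame(gene_id = sprintf("cv%05d", seq_len(n)),
               dn = dn, psi = psi, nervous_max_expr = expr,
               nervous = nervous, label = label,
               class = ifelse(label == 1, "ohnolog_ortholog",
                              "singleton_ortholog"),
               stringsAsFactors = FALSE)
  })
}
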