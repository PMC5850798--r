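# ---------------------------------------------------------------------------
# Event-annotated gene trees.
#
# Trees are nested lists. Leaves: list(gene, species). Internal nodes:
# list(event = "speciation"|"duplication", taxon, conf, children). NHX tags
# used: S= (taxon / species), D= (Y duplication, N speciation), B= or SIS=
# (duplication confidence on a 0-100 scale, stored as [0,1]), G= (gene id on
# leaves whose label is not the gene id).
# ---------------------------------------------------------------------------

gene_tree_node <- function(event, taxon, conf = NA_real_, children = list()) {
  list(event = event, taxon = taxon, conf = conf, children = children,
       leaf = FALSE)
}

gene_tree_leaf <- function(gene, species) {
  list(gene = gene, species = species, leaf = TRUE)
}

is_leaf <- function(node) isTRUE(node$leaf)

#' Parse a Newick/NHX gene tree
#'
#' Reads one Newick string whose comments carry NHX metadata: `S=` the
#' taxon of an internal node or the species of a leaf, `D=Y/N` the event
#' type, and `B=` (or `SIS=`) the duplication confidence score on a 0-100
#' scale, mapped to [0, 1]. Duplication nodes without a confidence tag get
#' confidence 0 with a warning; internal nodes without a `D=` tag are an
#' error.
#'
#' @param text a single Newick/NHX string (terminal `;` optional).
#' @return A `gene_tree` (nested list with class attribute).
#' @export
parse_nhx <- function(text) {
  s <- trimws(text)
  s <- sub(";\\s*$", "", s)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L

  syntax_err <- function(msg)
    stop(sprintf("newick syntax error at position %d: %s", pos, msg))

  read_label <- function() {
    start <- pos
    while (pos <= n && !substr(s, pos, pos) %in% c("(", ")", ",", ":", "[", ";"))
      advance()
    substr(s, start, pos - 1L)
  }

  read_nhx <- function() {
    if (peek() != "[") return(list())
    close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
    if (close < 0) syntax_err("unterminated NHX comment")
    com <- substr(s, pos, pos + close - 1L)
    pos <<- pos + close
    body <- sub("^\\[&&NHX:?", "", sub("\\]$", "", com))
    if (body == "") return(list())
    kv <- strsplit(strsplit(body, ":", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- lapply(kv, function(x) if (length(x) >= 2) x[2] else "")
    setNames(vals, vapply(kv, `[`, "", 1))
  }

  skip_branchlength <- function() {
    if (peek() == ":") {
      advance()
      while (pos <= n && grepl("[0-9eE.+-]", substr(s, pos, pos))) advance()
    }
  }

  read_clade <- function() {
    if (peek() == "(") {
      advance()
      children <- list(read_clade())
      while (peek() == ",") { advance(); children[[length(children) + 1L]] <- read_clade() }
      if (peek() != ")") syntax_err("expected ')'")
      advance()
      label <- read_label()
      skip_branchlength()
      tags <- read_nhx()
      skip_branchlength()
      if (is.null(tags$D))
        stop("internal node missing event tag (D=) in NHX comment")
      event <- if (toupper(tags$D) == "Y") "duplication" else "speciation"
      conf <- NA_real_
      if (event == "duplication") {
        raw <- tags$B %||% tags$SIS
        if (is.null(raw)) {
          warning("duplication node without confidence tag; defaulting to 0")
          conf <- 0
        } else conf <- as.numeric(raw) / 100
      }
      node <- gene_tree_node(event, tags$S %||% NA_character_, conf, children)
      node
    } else {
      label <- read_label()
      if (label == "") syntax_err("empty leaf label")
      skip_branchlength()
      tags <- read_nhx()
      skip_branchlength()
      gene_tree_leaf(tags$G %||% label, tags$S %||% NA_character_)
    }
  }

  root <- read_clade()
  if (pos <= n) syntax_err(sprintf("trailing characters: '%s'", substr(s, pos, n)))
  class(root) <- c("gene_tree", class(root))
  root
}

#' Read a multi-tree NHX file (one tree per line)
#' @param file path; blank lines and `#` comment lines are skipped.
#' @return list of `gene_tree` objects.
#' @export
read_nhx_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  lapply(lines, parse_nhx)
}

#' Serialise a gene tree to a Newick/NHX string
#' @param tree a `gene_tree`.
#' @return single character string ending in `;`.
#' @export
write_nhx <- function(tree) {
  ser <- function(node) {
    if (is_leaf(node)) {
      sprintf("%s[&&NHX:S=%s]", node$gene, node$species)
    } else {
      kids <- paste(vapply(node$children, ser, ""), collapse = ",")
      tags <- sprintf("S=%s:D=%s", node$taxon,
                      if (node$event == "duplication") "Y" else "N")
      if (node$event == "duplication" && !is.na(node$conf))
        tags <- sprintf("%s:B=%g", tags, node$conf * 100)
      sprintf("(%s)[&&NHX:%s]", kids, tags)
    }
  }
  paste0(ser(tree), ";")
}

# ---- traversal helpers -----------------------------------------------------

tree_leaves <- function(node) {
  if (is_leaf(node)) return(list(node))
  do.call(c, lapply(node$children, tree_leaves))
}

leaf_species <- function(node) vapply(tree_leaves(node), `[[`, "", "species")
leaf_genes <- function(node) vapply(tree_leaves(node), `[[`, "", "gene")

species_leaves <- function(node, species) {
  lv <- tree_leaves(node)
  lv[vapply(lv, function(l) l$species == species, TRUE)]
}

# path of internal nodes from `node` (inclusive) down to the unique leaf of
# `species`; NULL if that species has != 1 leaf below
path_to_species <- function(node, species) {
  if (is_leaf(node)) {
    return(if (identical(node$species, species)) list() else NULL)
  }
  hits <- vapply(node$children, function(ch)
    sum(leaf_species(ch) == species), 1)
  if (sum(hits > 0) != 1 || sum(hits) != 1) return(NULL)
  sub <- path_to_species(node$children[[which(hits == 1)]], species)
  if (is.null(sub)) return(NULL)
  c(list(node), sub)
}

# all internal nodes (preorder)
internal_nodes <- function(node) {
  if (is_leaf(node)) return(list())
  c(list(node), do.call(c, lapply(node$children, internal_nodes)))
}
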