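# ---------------------------------------------------------------------------
# Akashi's test for translational accuracy: association between conserved
# amino-acid sites and preferred codons, stratified per amino acid and
# summarised by a Mantel-Haenszel odds ratio (Psi) and a Z score.
# ---------------------------------------------------------------------------

# standard genetic code, codon -> one-letter amino acid ("*" = stop)
codon_table <- function() {
  gc <- as.character(Biostrings::GENETIC_CODE)
  setNames(gc, names(Biostrings::GENETIC_CODE))
}

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0)
    stop("sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Site conservation mask for a pairwise codon alignment
#'
#' Classifies each aligned codon site: `conserved` when the two codons
#' translate to the same amino acid (synonymous differences still count as
#' conserved), `variable` when both translate but to different amino
#' acids, `excluded` when either codon contains a gap or `N` or encodes a
#' stop. The terminal site is excluded by [akashi_test()].
#'
#' @param focal,comparator in-frame nucleotide sequences of equal length
#'   (alphabet A, C, G, T, -, N).
#' @return character vector, one status per codon site.
#' @export
conserved_mask <- function(focal, comparator) {
  cf <- split_codons(focal)
  cc <- split_codons(comparator)
  if (length(cf) != length(cc))
    stop("aligned sequences differ in codon length")
  ct <- codon_table()
  aa_f <- unname(ct[cf])
  aa_c <- unname(ct[cc])
  bad <- grepl("[^ACGT]", cf) | grepl("[^ACGT]", cc) |
    is.na(aa_f) | is.na(aa_c) | aa_f == "*" | aa_c == "*"
  out <- ifelse(bad, "excluded", ifelse(aa_f == aa_c, "conserved", "variable"))
  out
}

#' Read a preferred-codon table (TSV: amino_acid, codon, preferred)
#'
#' @param file path; `preferred` is 0/1.
#' @return named list, one-letter amino acid -> character vector of
#'   preferred codons.
#' @export
read_preferred_codons <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE,
                   col.names = c("amino_acid", "codon", "preferred"))
  df <- df[df$preferred == 1, , drop = FALSE]
  split(toupper(df$codon), df$amino_acid)
}

#' Per-amino-acid contingency strata for Akashi's test
#'
#' For each amino acid with at least one preferred codon, counts focal
#' codons at informative sites into the 2x2 cells a (conserved,
#' preferred), b (conserved, unpreferred), c (variable, preferred),
#' d (variable, unpreferred). Only sites whose focal codon encodes that
#' amino acid contribute; amino acids absent from the preferred table
#' (single-codon amino acids such as Met and Trp) form no stratum. The
#' terminal codon is dropped.
#'
#' @param focal,comparator aligned in-frame sequences (see
#'   [conserved_mask()]).
#' @param preferred named list, amino acid -> preferred codons.
#' @param mask optional precomputed [conserved_mask()].
#' @return data.frame `amino_acid`, `a`, `b`, `c`, `d` (unsmoothed), one
#'   row per observed stratum.
#' @export
akashi_tables <- function(focal, comparator, preferred, mask = NULL) {
  cf <- split_codons(focal)
  if (is.null(mask)) mask <- conserved_mask(focal, comparator)
  if (length(mask) != length(cf))
    stop("mask length does not match codon length")
  if (length(cf)) {   # drop terminal codon (usually the stop)
    cf <- cf[-length(cf)]
    mask <- mask[-length(mask)]
  }
  ct <- codon_table()
  aa <- unname(ct[cf])
  keep <- mask != "excluded" & aa %in% names(preferred)
  if (!any(keep))
    return(data.frame(amino_acid = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), stringsAsFactors = FALSE))
  aa <- aa[keep]; cf <- cf[keep]; cons <- mask[keep] == "conserved"
  pref_pairs <- paste(rep(names(preferred), lengths(preferred)),
                      unlist(preferred, use.names = FALSE))
  pref <- paste(aa, cf) %in% pref_pairs
  tab <- do.call(rbind, lapply(sort(unique(aa)), function(x) {
    i <- aa == x
    data.frame(amino_acid = x,
               a = sum(i & cons & pref), b = sum(i & cons & !pref),
               c = sum(i & !cons & pref), d = sum(i & !cons & !pref),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

#' Mantel-Haenszel summary of smoothed strata
#'
#' Laplace smoothing adds `pseudocount` to all four cells of a stratum;
#' by default only strata containing a zero cell are smoothed (the
#' smoothing exists to remove problems with counts of zero, and smoothing
#' every stratum makes the Z test noticeably conservative at typical
#' per-gene stratum sizes); `smooth = "all"` smooths unconditionally.
#' Then:
#' Psi = sum_i(a_i d_i / n_i) / sum_i(b_i c_i / n_i), and
#' Z = (sum_i a_i - sum_i E_i) / sqrt(sum_i V_i) with the hypergeometric
#' mean E_i = (a_i + b_i)(a_i + c_i)/n_i and variance
#' V_i = (a_i+b_i)(c_i+d_i)(a_i+c_i)(b_i+d_i) / (n_i^2 (n_i - 1)),
#' both computed on the smoothed tables.
#'
#' @param strata data.frame from [akashi_tables()].
#' @param pseudocount Laplace smoothing constant added per cell.
#' @param smooth `"zero"` (default; smooth only strata with a zero cell)
#'   or `"all"`.
#' @return list `psi`, `z`, `n_strata`, `n_sites`.
#' @export
mantel_haenszel <- function(strata, pseudocount = 1,
                            smooth = c("zero", "all")) {
  smooth <- match.arg(smooth)
  informative <- strata[(strata$a + strata$b + strata$c + strata$d) > 0, ,
                        drop = FALSE]
  n_sites <- sum(informative$a + informative$b + informative$c + informative$d)
  if (!nrow(informative))
    return(list(psi = NA_real_, z = NA_real_, n_strata = 0L, n_sites = 0L))
  add <- if (smooth == "all") rep(pseudocount, nrow(informative)) else
    pseudocount * as.numeric(informative$a == 0 | informative$b == 0 |
                               informative$c == 0 | informative$d == 0)
  a <- informative$a + add
  b <- informative$b + add
  c_ <- informative$c + add
  d <- informative$d + add
  n <- a + b + c_ + d
  psi <- sum(a * d / n) / sum(b * c_ / n)
  E <- (a + b) * (a + c_) / n
  V <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  z <- (sum(a) - sum(E)) / sqrt(sum(V))
  list(psi = psi, z = z, n_strata = nrow(informative), n_sites = n_sites)
}

#' Akashi's test on one pairwise codon alignment
#'
#' @inheritParams akashi_tables
#' @param pseudocount Laplace smoothing constant (default 1).
#' @param smooth smoothing mode, see [mantel_haenszel()].
#' @param gene_id optional gene identifier carried into the result.
#' @return data.frame row: `gene_id`, `psi`, `z`, `n_strata`, `n_sites`.
#'   `psi` is `NA` when no informative stratum exists (such genes are
#'   excluded from downstream binning).
#' @export
akashi_test <- function(focal, comparator, preferred, pseudocount = 1,
                        smooth = c("zero", "all"), gene_id = NA_character_) {
  strata <- akashi_tables(focal, comparator, preferred)
  mh <- mantel_haenszel(strata, pseudocount, smooth)
  data.frame(gene_id = gene_id, psi = mh$psi, z = mh$z,
             n_strata = mh$n_strata, n_sites = mh$n_sites,
             stringsAsFactors = FALSE)
}

#' Akashi's test over a paired FASTA file
#'
#' The FASTA holds two records per gene, `<gene>_focal` then
#' `<gene>_comparator` (suffix convention of the paired-alignment writer).
#'
#' @param file FASTA path.
#' @param preferred named list or path to a preferred-codon TSV.
#' @param pseudocount Laplace smoothing constant.
#' @return data.frame, one row per gene (see [akashi_test()]).
#' @export
akashi_test_file <- function(file, preferred, pseudocount = 1,
                             smooth = c("zero", "all")) {
  if (is.character(preferred) && length(preferred) == 1)
    preferred <- read_preferred_codons(preferred)
  seqs <- Biostrings::readDNAStringSet(file)
  nm <- names(seqs)
  foc <- grepl("_focal$", nm)
  genes <- sub("_focal$", "", nm[foc])
  out <- do.call(rbind, lapply(genes, function(g) {
    akashi_test(as.character(seqs[[paste0(g, "_focal")]]),
                as.character(seqs[[paste0(g, "_comparator")]]),
                preferred, pseudocount, smooth, gene_id = g)
  }))
  rownames(out) <- NULL
  out
}
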