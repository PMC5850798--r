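# ---------------------------------------------------------------------------
# Downstream retention analyses: equal-frequency binning, bin regression of
# ohnolog proportion on gene covariates, expression summaries, tissue
# ranking, protein-complex category priority, and RNA-seq present/absent
# calling against intergenic background.
# ---------------------------------------------------------------------------

#' Equal-frequency bins of a gene covariate
#'
#' Sorts genes by value (ties broken by gene id for determinism) and
#' assigns them to `k` bins whose sizes differ by at most one, bin index
#' increasing with the covariate.
#'
#' @param values named numeric vector (names = gene ids); non-finite
#'   values are dropped.
#' @param k number of bins (default 10).
#' @return named integer vector of bin indices (1..k).
#' @export
equal_bins <- function(values, k = 10) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < k) stop(sprintf("need at least k = %d genes, got %d", k, n))
  ord <- order(values, names(values))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  idx <- rep(seq_len(k), sizes)
  setNames(idx[order(ord)], names(values))
}

#' Regression of per-bin ohnolog proportion on a binned covariate
#'
#' Splits genes into `k` equal-sized bins of the covariate, computes per
#' bin the median (optionally log10-transformed) covariate and the
#' proportion of genes in the retained class, then fits an ordinary least
#' squares line to the k points. The slope (Beta), its two-sided t-test
#' p-value on k-2 degrees of freedom, and R-squared summarise the trend.
#'
#' @param values named numeric covariate (e.g. dN or Psi per gene).
#' @param labels named 0/1 vector: 1 = retained class (e.g. ortholog of an
#'   ohnolog). Only genes present in both vectors are used.
#' @param k number of bins.
#' @param transform `"identity"` or `"log10"`; with `"log10"`,
#'   non-positive values are dropped with a message giving the count.
#' @return list of class `bin_regression`: `bins` (data.frame with per-bin
#'   median x and proportion y), `slope`, `intercept`, `p_value`,
#'   `r_squared`, `transform`, `n_genes`.
#' @export
bin_regression <- function(values, labels, k = 10,
                           transform = c("identity", "log10")) {
  transform <- match.arg(transform)
  genes <- intersect(names(values), names(labels))
  values <- values[genes]; labels <- labels[genes]
  if (transform == "log10") {
    drop <- !is.finite(values) | values <= 0
    if (any(drop))
      message(sum(drop), " gene(s) with non-positive values dropped before log10")
    values <- log10(values[!drop]); labels <- labels[!drop]
  }
  bins <- equal_bins(values, k)
  x <- vapply(seq_len(k), function(b) median(values[bins == b]), 0)
  y <- vapply(seq_len(k), function(b) mean(labels[bins == b]), 0)
  if (any(!is.finite(x))) stop("bin with undefined median covariate")
  pts <- data.frame(bin = seq_len(k), x = x, proportion = y)
  if (sd(y) == 0) {   # degenerate: constant proportion across bins
    return(structure(list(bins = pts, slope = 0, intercept = y[1],
                          p_value = 1, r_squared = NA_real_,
                          transform = transform, n_genes = length(values)),
                     class = "bin_regression"))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  p <- if (nrow(sm$coefficients) < 2 || !is.finite(slope)) NA_real_
       else sm$coefficients[2, 4]
  structure(list(
    bins = pts, slope = slope, intercept = unname(coef(fit)[1]),
    p_value = p, r_squared = sm$r.squared,
    transform = transform, n_genes = length(values)),
    class = "bin_regression")
}

#' @export
print.bin_regression <- function(x, ...) {
  cat(sprintf(
    "bin_regression (%d bins, %s x): Beta = %.4g, P = %.3g, R2 = %.3f\n",
    nrow(x$bins), x$transform, x$slope, x$p_value, x$r_squared))
  invisible(x)
}

#' Choose between a linear and a log-linear bin trend
#'
#' Fits [bin_regression()] under both transforms and returns the one with
#' the higher R-squared (the criterion used to contrast the linear trend
#' of small-scale duplicates with the log-linear trend of ohnologs).
#'
#' @inheritParams bin_regression
#' @param criterion `"r_squared"` (default) or `"aic"`.
#' @return list: `best` (transform name), `identity`, `log10` (both fits).
#' @export
compare_bin_models <- function(values, labels, k = 10,
                               criterion = c("r_squared", "aic")) {
  criterion <- match.arg(criterion)
  fits <- list(identity = bin_regression(values, labels, k, "identity"),
               log10 = suppressMessages(
                 bin_regression(values, labels, k, "log10")))
  score <- if (criterion == "r_squared") {
    vapply(fits, `[[`, 0, "r_squared")
  } else {
    -vapply(fits, function(f) {
      rss <- sum((f$bins$proportion - (f$intercept + f$slope * f$bins$x))^2)
      n <- nrow(f$bins)
      n * log(rss / n) + 2 * 3
    }, 0)
  }
  c(list(best = names(which.max(score))), fits)
}

#' Extreme subsets of a covariate
#'
#' The `floor(fraction * n)` genes with the lowest and highest values
#' (ties broken by gene id); the two sets are disjoint.
#'
#' @param values named numeric vector.
#' @param fraction in (0, 0.5].
#' @return list `low`, `high` of gene id vectors.
#' @export
subset_extremes <- function(values, fraction = 0.2) {
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  values <- values[is.finite(values)]
  n <- length(values)
  m <- floor(fraction * n)
  if (m < 1) stop("too few genes to form disjoint extreme sets")
  if (2 * m > n) stop("extreme sets would overlap at this n and fraction")
  ord <- names(values)[order(values, names(values))]
  list(low = ord[seq_len(m)], high = rev(ord)[seq_len(m)])
}

#' Per-gene expression summaries over a tissue set
#'
#' Mean, median and maximum signal per gene over the samples whose tissue
#' belongs to `tissue_set` (e.g. log2 intensity across nervous-system
#' samples).
#'
#' @param mat numeric matrix, genes x samples (dimnames required).
#' @param sample_tissues named character vector, sample id -> tissue id.
#' @param tissue_set tissues to include.
#' @return data.frame `gene_id`, `mean`, `median`, `max`.
#' @export
expression_summary <- function(mat, sample_tissues, tissue_set) {
  samples <- colnames(mat)[sample_tissues[colnames(mat)] %in% tissue_set]
  if (!length(samples)) stop("no samples from the requested tissues")
  sub <- mat[, samples, drop = FALSE]
  data.frame(gene_id = rownames(mat),
             mean = rowMeans(sub),
             median = apply(sub, 1, median),
             max = apply(sub, 1, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank tissues by the proportion of a gene class among expressed genes
#'
#' For each sample, the proportion of class-of-interest genes among all
#' reference genes called present; tissues are then ranked by the mean
#' proportion over their samples. The reference set should contain only
#' the orthologs of ohnologs and of singletons, so the proportion reads as
#' "fraction of expressed reference genes that are ohnolog orthologs".
#' Samples where no reference gene is present are dropped with a warning.
#'
#' @param calls logical (or 0/1) matrix, genes x samples: present calls.
#' @param gene_classes named character vector, gene -> class label.
#' @param class_of_interest label counted in the numerator.
#' @param reference_classes labels forming the reference set denominator.
#' @param sample_tissues named character vector, sample id -> tissue id.
#' @return list: `samples` (data.frame sample, tissue, proportion),
#'   `tissues` (data.frame tissue, mean_proportion, ranked decreasing).
#' @export
tissue_ranking <- function(calls, gene_classes, class_of_interest,
                           reference_classes = c("ohnolog_ortholog",
                                                 "singleton_ortholog"),
                           sample_tissues) {
  ref_genes <- names(gene_classes)[gene_classes %in% reference_classes]
  ref_genes <- intersect(ref_genes, rownames(calls))
  if (!length(ref_genes)) stop("no reference genes present in the call matrix")
  cls_genes <- names(gene_classes)[gene_classes == class_of_interest]
  sub <- calls[ref_genes, , drop = FALSE] != 0
  denom <- colSums(sub)
  numer <- colSums(sub[rownames(sub) %in% cls_genes, , drop = FALSE])
  bad <- denom == 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with no reference gene present dropped")
  }
  prop <- numer[!bad] / denom[!bad]
  samples <- data.frame(sample = names(prop),
                        tissue = unname(sample_tissues[names(prop)]),
                        proportion = unname(prop), stringsAsFactors = FALSE)
  means <- tapply(samples$proportion, samples$tissue, mean)
  tissues <- data.frame(tissue = names(means),
                        mean_proportion = as.numeric(means),
                        stringsAsFactors = FALSE)
  tissues <- tissues[order(-tissues$mean_proportion, tissues$tissue), ,
                     drop = FALSE]
  rownames(tissues) <- NULL
  list(samples = samples, tissues = tissues)
}

#' Resolve multi-annotated genes to a single protein-complex category
#'
#' Priority (most dosage-sensitive first): hetero_multimer > hetero_dimer >
#' uncharacterized > homo_multimer > monomer. Genes with no annotation get
#' `unannotated`.
#'
#' @param annotations named list, gene -> character vector of categories.
#' @return named character vector, gene -> single category.
#' @export
assign_complex_category <- function(annotations) {
  priority <- c("hetero_multimer", "hetero_dimer", "uncharacterized",
                "homo_multimer", "monomer", "unannotated")
  vapply(annotations, function(cats) {
    cats <- unique(as.character(cats))
    bad <- setdiff(cats, priority)
    if (length(bad))
      stop("unknown complex category: ", paste(bad, collapse = ", "))
    if (!length(cats)) return("unannotated")
    priority[min(match(cats, priority))]
  }, "")
}

#' Present/absent calls from TPM against intergenic background
#'
#' Chooses the smallest TPM threshold `t` (scanning 0 and every distinct
#' observed TPM value) such that the fraction of intergenic regions at or
#' above `t` is at most `target_ratio` times the fraction of coding genes
#' at or above `t`; genes with TPM >= t are called present. When no
#' threshold achieves the ratio, all genes are called absent with a
#' warning.
#'
#' @param tpm_coding named numeric vector of gene TPM.
#' @param tpm_intergenic numeric vector of intergenic-region TPM.
#' @param target_ratio maximum intergenic/coding present-ratio (default
#'   0.05, i.e. 5% background).
#' @return list: `threshold` (NA when unattainable), `present` (named
#'   logical), `achieved_ratio`.
#' @export
rnaseq_present_calls <- function(tpm_coding, tpm_intergenic,
                                 target_ratio = 0.05) {
  if (!length(tpm_coding) || !length(tpm_intergenic))
    stop("both TPM tables must be non-empty")
  if (any(tpm_coding < 0) || any(tpm_intergenic < 0))
    stop("TPM values must be >= 0")
  cand <- sort(unique(c(0, tpm_coding, tpm_intergenic)))
  for (t in cand) {
    fc <- mean(tpm_coding >= t)
    fi <- mean(tpm_intergenic >= t)
    if (fc == 0) break
    if (fi / fc <= target_ratio) {
      return(list(threshold = t,
                  present = setNames(tpm_coding >= t, names(tpm_coding)),
                  achieved_ratio = fi / fc))
    }
  }
  warning("no threshold achieves the target intergenic/coding ratio; ",
          "all genes called absent")
  list(threshold = NA_real_,
       present = setNames(rep(FALSE, length(tpm_coding)), names(tpm_coding)),
       achieved_ratio = NA_real_)
}
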