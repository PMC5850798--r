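test_that("equal_bins yields sizes differing by at most one, ordered by value", {
  v100 <- setNames(runif(100), sprintf("g%03d", 1:100))
  b100 <- equal_bins(v100, 10)
  expect_true(all(table(b100) == 10))
  v103 <- setNames(runif(103), sprintf("g%03d", 1:103))
  b103 <- equal_bins(v103, 10)
  expect_equal(sort(as.integer(table(b103)), decreasing = TRUE),
               c(11, 11, 11, rep(10, 7)))
  expect_error(equal_bins(setNames(1:5, letters[1:5]), 10), "at least k")
  # bin index increases with value; concatenating bins reproduces the sort
  set.seed(41)
  v <- setNames(rnorm(57), sprintf("g%02d", 1:57))
  b <- equal_bins(v, 7)
  srt <- names(v)[order(v, names(v))]
  expect_identical(unlist(lapply(1:7, function(k)
    srt[srt %in% names(b)[b == k]])), srt)
  expect_true(all(diff(vapply(1:7, function(k) max(v[b == k]), 0)) >= 0))
})

test_that("bin_regression recovers exact linear trends and handles constants", {
  genes <- sprintf("g%03d", 1:100)
  v <- setNames(seq(1, 100), genes)
  ones <- setNames(rep(1, 100), genes)
  f1 <- bin_regression(v, ones, 10)
  expect_equal(f1$slope, 0)
  expect_true(all(f1$bins$proportion == 1))
  # bin k gets proportion k/10; per-bin medians are evenly spaced, so the
  # points are exactly collinear and the slope has a closed form
  labs <- setNames(rep(0, 100), genes)
  b <- equal_bins(v, 10)
  for (k in 1:10) {
    idx <- names(b)[b == k]
    labs[idx[seq_len(k)]] <- 1
  }
  # lm warns about the (intentionally) perfect fit
  f2 <- suppressWarnings(bin_regression(v, labs, 10))
  expect_equal(f2$bins$proportion, (1:10) / 10)
  expect_equal(f2$slope, 0.01)           # 0.1 proportion per 10 units of x
  expect_equal(f2$r_squared, 1)
})

test_that("bin_regression is invariant to input permutation and logs drops", {
  set.seed(42)
  genes <- sprintf("g%04d", 1:500)
  v <- setNames(rlnorm(500, -3, 1), genes)
  lab <- setNames(rbinom(500, 1, 0.3), genes)
  f <- bin_regression(v, lab, 10, "log10")
  perm <- sample(500)
  f2 <- bin_regression(v[perm], lab[perm], 10, "log10")
  expect_equal(f$bins, f2$bins)
  expect_equal(f$slope, f2$slope)
  v[1] <- 0
  expect_message(bin_regression(v, lab, 10, "log10"), "dropped")
})

test_that("planted negative dN effect yields a negative significant slope", {
  hits <- 0
  for (seed in 1:20) {
    cov <- gen_covariates(synth_config(seed = seed, n_cov_genes = 5000))
    nerv <- cov[cov$nervous, ]
    f <- suppressMessages(bin_regression(
      setNames(nerv$dn, nerv$gene_id), setNames(nerv$label, nerv$gene_id),
      10, "log10"))
    if (f$slope < 0 && f$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("model comparison picks the better-fitting transform", {
  set.seed(43)
  genes <- sprintf("g%04d", 1:2000)
  v <- setNames(rlnorm(2000, -3, 1), genes)
  # class probability linear in log10(v): log-linear fit should win
  p <- 0.5 + 0.1 * scale(log10(v))
  lab <- setNames(rbinom(2000, 1, pmin(pmax(p, 0), 1)), genes)
  cmp <- compare_bin_models(v, lab, 10)
  expect_equal(cmp$best, "log10")
  expect_true(cmp$log10$r_squared >= cmp$identity$r_squared)
})

test_that("subset_extremes returns disjoint sorted tails", {
  v <- setNames(c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10), letters[1:10])
  ex <- subset_extremes(v, 0.2)
  expect_setequal(ex$low, c("b", "f"))
  expect_setequal(ex$high, c("j", "c"))
  expect_length(intersect(ex$low, ex$high), 0)
  expect_length(subset_extremes(v, 0.1)$low, 1)
  expect_error(subset_extremes(v, 0.6), "fraction")
  expect_error(subset_extremes(setNames(1, "a"), 0.5), "too few genes")
  set.seed(44)
  v2 <- setNames(rnorm(83), sprintf("g%02d", 1:83))
  ex2 <- subset_extremes(v2, 0.2)
  srt <- names(v2)[order(v2, names(v2))]
  expect_identical(sort(ex2$low), sort(srt[1:16]))
  expect_identical(sort(ex2$high), sort(srt[68:83]))
})

test_that("expression_summary reduces over the requested tissue columns", {
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  tiss <- setNames(rep(c("brain", "liver"), each = 10), colnames(m))
  s <- expression_summary(m, tiss, "brain")
  expect_equal(s$mean, unname(rowMeans(m[, 1:10])))
  expect_equal(s$median, unname(apply(m[, 1:10], 1, median)))
  expect_equal(s$max, unname(apply(m[, 1:10], 1, max)))
  one <- expression_summary(m, tiss, "brain")$mean
  s1 <- expression_summary(m[, 1, drop = FALSE], tiss["s01"], "brain")
  expect_equal(s1$mean, s1$median)
  expect_equal(s1$mean, s1$max)
  const <- matrix(3, 2, 4, dimnames = list(c("a", "b"), names(tiss)[1:4]))
  sc <- expression_summary(const, tiss, "brain")
  expect_true(all(sc$mean == 3 & sc$median == 3 & sc$max == 3))
  expect_error(expression_summary(m, tiss, "kidney"), "no samples")
})

test_that("tissue_ranking ranks by class proportion among expressed genes", {
  genes <- sprintf("g%02d", 1:40)
  classes <- setNames(rep(c("ohnolog_ortholog", "singleton_ortholog"),
                          each = 20), genes)
  tiss <- setNames(c("A", "A", "B", "B"), c("s1", "s2", "s3", "s4"))
  all_present <- matrix(TRUE, 40, 4, dimnames = list(genes, names(tiss)))
  r <- tissue_ranking(all_present, classes, "ohnolog_ortholog",
                      sample_tissues = tiss)
  expect_true(all(r$samples$proportion == 0.5))
  # class genes present only in tissue A
  m <- all_present
  m[1:20, c("s3", "s4")] <- FALSE
  r2 <- tissue_ranking(m, classes, "ohnolog_ortholog", sample_tissues = tiss)
  expect_equal(r2$tissues$tissue[1], "A")
  # invariance to genes outside the reference classes
  extra <- rbind(m, matrix(TRUE, 5, 4,
                           dimnames = list(paste0("x", 1:5), names(tiss))))
  classes2 <- c(classes, setNames(rep("other", 5), paste0("x", 1:5)))
  r3 <- tissue_ranking(extra, classes2, "ohnolog_ortholog",
                       sample_tissues = tiss)
  expect_equal(r3$samples, r2$samples)
  # sample with nothing expressed is dropped with a warning
  m2 <- m; m2[, "s4"] <- FALSE
  expect_warning(r4 <- tissue_ranking(m2, classes, "ohnolog_ortholog",
                                      sample_tissues = tiss), "dropped")
  expect_false("s4" %in% r4$samples$sample)
})

test_that("complex category assignment follows the dosage-sensitivity priority", {
  expect_equal(unname(assign_complex_category(
    list(g = c("hetero_dimer", "homo_multimer")))), "hetero_dimer")
  expect_equal(unname(assign_complex_category(
    list(g = c("hetero_multimer", "monomer")))), "hetero_multimer")
  expect_equal(unname(assign_complex_category(list(g = character()))),
               "unannotated")
  expect_error(assign_complex_category(list(g = "dimer_of_dimers")),
               "unknown")
  # exhaustive subset check against a max-by-priority oracle
  cats <- c("monomer", "homo_multimer", "hetero_dimer", "hetero_multimer",
            "uncharacterized")
  rank <- c(hetero_multimer = 1, hetero_dimer = 2, uncharacterized = 3,
            homo_multimer = 4, monomer = 5)
  for (bits in 0:31) {
    subset <- cats[bitwAnd(bits, 2^(0:4)) > 0]
    got <- unname(assign_complex_category(list(g = subset)))
    want <- if (!length(subset)) "unannotated" else
      names(which.min(rank[subset]))
    expect_identical(got, want)
  }
})

test_that("present-call threshold achieves the intergenic/coding ratio", {
  # fully separated distributions: everything is present
  sep <- rnaseq_present_calls(setNames(rep(10, 20), paste0("g", 1:20)),
                              rep(0, 30))
  expect_equal(sep$threshold, 10)
  expect_true(all(sep$present))
  # identical distributions: no threshold can work
  x <- c(1, 2, 3, 4, 5)
  expect_warning(same <- rnaseq_present_calls(setNames(x, paste0("g", 1:5)),
                                              x), "all genes called absent")
  expect_true(is.na(same$threshold))
  expect_false(any(same$present))
  # synthetic log-normal mixtures against an exhaustive scan oracle
  for (seed in 1:5) {
    set.seed(seed)
    coding <- setNames(rlnorm(800, log(10), 1.5), sprintf("g%03d", 1:800))
    inter <- rlnorm(400, log(0.1), 1)
    got <- rnaseq_present_calls(coding, inter, 0.05)
    cand <- sort(unique(c(0, coding, inter)))
    ok <- vapply(cand, function(t) {
      fc <- mean(coding >= t)
      fc > 0 && mean(inter >= t) / fc <= 0.05
    }, TRUE)
    expect_equal(got$threshold, cand[which(ok)[1]])
    expect_lte(got$achieved_ratio, 0.05)
    expect_equal(unname(got$present), unname(coding >= got$threshold))
  }
  expect_error(rnaseq_present_calls(numeric(), 1:3), "non-empty")
  expect_error(rnaseq_present_calls(c(a = -1), 1:3), ">= 0")
})
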