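test_that("benchmark tables load with validated set labels and kinase flags", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "set\tprotein\tsite\tinteractor\teffect\tIE\tf_ID\tf_Cons\tS_switch\tkinase",
    "positive\tP1\tS 10-p\tI1\tenabling\t2.0\t1.0\t0.5\t1.0\t1",
    "positive\tP2\tT 20-p\tI2\tdisabling\t-3.0\t0.9\t0.8\t-2.16\t0",
    "negative\tP1\tS 30-p\tI1\tenabling\t0.1\t1.0\t0.5\t0.05\t0"), path)
  b <- load_benchmark_table(path)
  expect_equal(nrow(b), 3)
  expect_identical(b$kinase, c(TRUE, FALSE, FALSE))
  expect_true(all(b$effect_known))
  # invalid set values are format errors
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("set\tprotein\tsite\tinteractor\teffect",
               "maybe\tP1\tS 1-p\tI1\tenabling"), bad)
  expect_error(load_benchmark_table(bad), "invalid set")
  # missing mandatory columns are format errors
  bad2 <- tempfile(fileext = ".tsv")
  writeLines(c("set\tprotein", "positive\tP1"), bad2)
  expect_error(load_benchmark_table(bad2), "missing column")
})

test_that("negative sets preserve exposure classes and are seed-deterministic", {
  seqs <- c(P1 = "ASTSYASTSYASTSYASTSY")  # many S/T/Y
  sty <- which(strsplit(seqs[["P1"]], "")[[1]] %in% c("S", "T", "Y"))
  expo <- data.frame(protein = "P1", pos = sty,
                     exposure = ifelse(sty <= 10, "exposed", "buried"))
  pos <- data.frame(protein = "P1", pos = 2, interactor = "I1",
                    effect = "enabling")
  neg <- suppressMessages(build_negative_set(pos, seqs, expo,
                                             n_shuffles = 5, seed = 3))
  expect_equal(nrow(neg), 5)
  expect_true(all(neg$pos %in% setdiff(sty[sty <= 10], 2)))
  expect_true(all(neg$effect == "enabling"))
  expect_true(all(neg$interactor == "I1"))
  # without-replacement cap when fewer candidates than shuffles
  neg2 <- suppressMessages(build_negative_set(pos, seqs, expo,
                                              n_shuffles = 10, seed = 3))
  expect_equal(nrow(neg2), length(setdiff(sty[sty <= 10], 2)))
  expect_equal(anyDuplicated(neg2$pos), 0)
  # determinism
  n_a <- suppressMessages(build_negative_set(pos, seqs, expo, 5, seed = 11))
  n_b <- suppressMessages(build_negative_set(pos, seqs, expo, 5, seed = 11))
  expect_identical(n_a, n_b)
  # exposure fallback when no same-class candidate exists
  expo_one <- data.frame(protein = "P1", pos = 2, exposure = "exposed")
  expect_message(
    fb <- build_negative_set(pos, seqs, expo_one, 3, seed = 2),
    "falling back")
  expect_equal(nrow(fb), 3)
  # a protein without alternatives skips the positive with a warning
  expect_warning(
    none <- build_negative_set(data.frame(protein = "P2", pos = 1,
                                          interactor = "I", effect = "x"),
                               c(P2 = "SAAA"), expo, 3, seed = 1),
    "skipped")
  expect_equal(nrow(none), 0)
})

test_that("ROC agrees with pair-enumeration and an independent implementation", {
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  curve <- roc_pr_curves(scores, labels)
  expect_equal(curve$auc, oracle_auc(scores, labels))
  expect_equal(curve$auc, 11 / 12)  # concordant pairs / 12, by hand
  # random score sets, with ties, against the enumeration oracle and pROC
  set.seed(8)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    sc <- round(rnorm(n), 1)
    lb <- runif(n) < 0.4
    if (!any(lb) || all(lb)) next
    cv <- roc_pr_curves(sc, lb)
    expect_equal(cv$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    expect_equal(cv$auc,
                 as.numeric(suppressMessages(pROC::auc(pROC::roc(lb, sc,
                   direction = "<", quiet = TRUE)))),
                 tolerance = 1e-12)
  }
  # degenerate inputs
  expect_error(roc_pr_curves(1:3, c(TRUE, TRUE, TRUE)), "one positive")
  # ties everywhere give AUC 0.5
  expect_equal(roc_pr_curves(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  # perfect separation gives AUC 1
  expect_equal(roc_pr_curves(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  sc <- rnorm(80)
  lb <- runif(80) < 0.5
  a1 <- roc_pr_curves(sc, lb)$auc
  expect_equal(roc_pr_curves(exp(sc), lb)$auc, a1)
  expect_equal(roc_pr_curves(2 * sc + 7, lb)$auc, a1)
})

test_that("absolute-mode ROC ranks by |score|", {
  sc <- c(-3, 2.5, 0.1, -0.2)
  lb <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_pr_curves(sc, lb, direction = "absolute")$auc, 1)
})

test_that("threshold at bounded FPR matches exhaustive search", {
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  op <- threshold_at_fpr(roc_pr_curves(scores, labels), 0.05)
  # 4 negatives: no false positive is allowed at FPR <= 0.05
  expect_equal(op$threshold, 0.8)
  expect_equal(op$tpr, 2 / 3)
  expect_equal(op$fpr, 0)
  # randomised comparison with the exhaustive oracle
  set.seed(12)
  for (i in 1:100) {
    n <- sample(c(20, 200, 1000), 1)
    sc <- round(rnorm(n), 2)
    lb <- runif(n) < 0.3
    if (!any(lb) || all(lb)) next
    bound <- sample(c(0.01, 0.05, 0.2), 1)
    got <- threshold_at_fpr(roc_pr_curves(sc, lb), bound)
    want <- oracle_threshold_at_fpr(sc, lb, bound)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$fpr, want$fpr)
    expect_equal(got$tpr, want$tpr)
  }
  # a bound of 1 admits every score (the most permissive cutpoint)
  op1 <- threshold_at_fpr(roc_pr_curves(scores, labels), 1.0)
  expect_equal(op1$tpr, 1)
})

test_that("Fisher's exact p equals full table enumeration", {
  expect_equal(fisher_exact_p(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1, tolerance = 1e-12)
  expect_lt(fisher_exact_p(10, 0, 0, 10), 1e-4)
  set.seed(3)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(8:30, 1), rep(0.25, 4)))
    if (sum(cells) == 0) next
    expect_equal(fisher_exact_p(cells[1], cells[2], cells[3], cells[4]),
                 oracle_fisher_two_sided(cells[1], cells[2], cells[3],
                                         cells[4]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_p(0, 0, 0, 0), "all-zero")
})

test_that("benchmark filters subset by kinase, template identity and effect", {
  b <- data.frame(set = "positive", protein = paste0("P", 1:5),
                  site = "S 1-p", interactor = "I", effect =
                    c("enabling", "enabling", "disabling", "enabling",
                      "disabling"),
                  f_ID = c(0.98, 0.995, 1.0, 0.7, 0.999),
                  kinase = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(nrow(filter_kinase_interactors(b)), 3)
  expect_equal(nrow(filter_benchmark(b, min_f_ID = 0.99)), 3)
  expect_equal(nrow(filter_benchmark(b, effect = "disabling")), 2)
  expect_equal(nrow(filter_benchmark(b)), 5)
  b2 <- data.frame(f_ID = c(0.98, 0.995))
  expect_equal(filter_benchmark(b2, min_f_ID = 0.99)$f_ID, 0.995)
})

test_that("group comparisons use rank-sum and chi-square appropriately", {
  # identical distributions: not significant
  x <- rep(c(1, 2, 3, 4), 10)
  same <- compare_site_properties(x, x, "continuous")
  expect_gt(same$p_value, 0.9)
  # hand-computed chi-square for (90,10) vs (50,50): 38.095...
  a <- c(rep(1, 90), rep(0, 10))
  b <- c(rep(1, 50), rep(0, 50))
  chi <- compare_site_properties(a, b, "binary")
  expect_equal(chi$statistic, 800 / 21, tolerance = 1e-9)
  # disjoint ranges reach the minimal attainable rank-sum p
  lo <- 1:5
  hi <- 11:15
  rs <- compare_site_properties(lo, hi, "continuous")
  expect_equal(rs$p_value, 2 / choose(10, 5), tolerance = 1e-9)
  expect_error(compare_site_properties(numeric(), 1:3, "continuous"), "empty")
})

test_that("cross-validated logistic regression is balanced, signed and calibrated", {
  bm <- make_synthetic_benchmark(120, 240, 3, seed = 23)
  cv <- logistic_cv(bm, features = c("IE_signed", "f_ID", "f_Cons"),
                    folds = 5, reps = 20, seed = 9)
  # undersampling balances every repeat exactly
  expect_true(all(cv$per_rep$n_pos == cv$per_rep$n_neg))
  expect_true(all(cv$per_rep$n_pos == 120))
  # a strongly planted feature separates well and earns a positive weight
  expect_gte(cv$stat_means[["auc"]], 0.9)
  expect_gt(cv$coef_means[["IE_signed"]], 0)
  # determinism under the master seed
  cv2 <- logistic_cv(bm, features = c("IE_signed", "f_ID", "f_Cons"),
                     folds = 5, reps = 3, seed = 9)
  cv3 <- logistic_cv(bm, features = c("IE_signed", "f_ID", "f_Cons"),
                     folds = 5, reps = 3, seed = 9)
  expect_identical(cv2$per_rep, cv3$per_rep)
  # label-independent features stay near chance
  null_bm <- make_synthetic_benchmark(80, 80, 0, seed = 31)
  cv0 <- logistic_cv(null_bm, features = c("IE_signed", "f_ID", "f_Cons"),
                     folds = 5, reps = 20, seed = 7)
  expect_lt(abs(cv0$stat_means[["auc"]] - 0.5), 0.12)
})

test_that("a planted monotone feature recovers a positive coefficient in nearly all reps", {
  bm <- make_synthetic_benchmark(100, 150, 3, seed = 41)
  cv <- logistic_cv(bm, features = "S_switch_signed", folds = 5, reps = 50,
                    seed = 3)
  # coefficient sign per fold-rep
  expect_gte(mean(cv$per_rep$auc > 0.5), 0.99)
  expect_gt(cv$coef_means[["S_switch_signed"]], 0)
})
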