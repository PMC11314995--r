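# Cross-validation machinery, confusion metrics, ROC/PRC.

test_that("stratified folds reproduce the 80/20 clinical split arithmetic", {
  labels <- rep(c("present", "absent"), c(727, 1545)) # 2272 records
  fold <- stratified_kfold(labels, k = 5, seed = 1)
  sizes <- tabulate(fold, 5)
  expect_equal(sum(sizes), 2272L)
  expect_true(all(abs(sizes - 454.4) <= 1))         # test folds 454/455
  expect_true(all(abs((2272 - sizes) - 1817.6) <= 1)) # train folds 1817/1818
  # per-fold class proportions within one record of proportional
  pos_per_fold <- tapply(labels == "present", fold, sum)
  expect_true(all(abs(pos_per_fold - 727 / 5) <= 1))
})

test_that("folds partition the records and are deterministic", {
  labels <- rep(c("present", "absent"), c(5, 5))
  fold <- stratified_kfold(labels, k = 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(tapply(labels == "present", fold, sum) == 1))
  expect_true(all(tabulate(fold, 5) == 2))
  expect_identical(fold, stratified_kfold(labels, k = 5, seed = 3))
  expect_false(identical(fold, stratified_kfold(labels, k = 5, seed = 4)))
  expect_error(stratified_kfold(rep(c("present", "absent"), c(3, 20)), k = 5),
               "fewer records")
  expect_error(stratified_kfold(rep("absent", 10), k = 5), "both classes")
})

test_that("confusion counts match a per-record loop", {
  truth <- c("present", "present", "present", rep("absent", 7))
  cc <- confusion_counts(truth, rep("absent", 10))
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               list(TP = 0L, FN = 3L, TN = 7L, FP = 0L))
  perfect <- confusion_counts(truth, truth)
  expect_equal(perfect$FP + perfect$FN, 0L)
  set.seed(7)
  for (i in 1:50) {
    tr <- sample(c("present", "absent"), 30, replace = TRUE)
    pr <- sample(c("present", "absent"), 30, replace = TRUE)
    cc <- confusion_counts(tr, pr)
    brute <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (j in 1:30) {
      key <- if (tr[j] == "present" && pr[j] == "present") "TP"
             else if (tr[j] == "absent" && pr[j] == "present") "FP"
             else if (tr[j] == "absent" && pr[j] == "absent") "TN"
             else "FN"
      brute[key] <- brute[key] + 1L
    }
    expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]), brute)
  }
  expect_error(confusion_counts(truth, truth[-1]), "length")
})

test_that("metric formulas evaluate exactly on worked examples", {
  all_right <- compute_metrics(list(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_true(all(unlist(all_right) == 1))
  m <- compute_metrics(list(TP = 8, FP = 2, TN = 88, FN = 2))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$specificity, 88 / 90)
  # the as-printed audit variant swaps FP for FN in the denominator
  m2 <- compute_metrics(list(TP = 8, FP = 2, TN = 88, FN = 4),
                        specificity_as_printed = TRUE)
  expect_equal(m2$specificity, 88 / 92)
  expect_warning(z <- compute_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5)),
                 "0/0")
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
  expect_error(compute_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "empty")
})

test_that("F1 lies between precision and recall (harmonic-mean bound)", {
  set.seed(11)
  for (i in 1:200) {
    cc <- list(TP = sample(0:20, 1), FP = sample(0:20, 1),
               TN = sample(0:20, 1), FN = sample(0:20, 1))
    if (sum(unlist(cc)) == 0 || (cc$TP + cc$FP) == 0 || (cc$TP + cc$FN) == 0) next
    m <- compute_metrics(cc)
    expect_gte(m$f1 + 1e-12, min(m$precision, m$recall))
    expect_lte(m$f1 - 1e-12, max(m$precision, m$recall))
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  }
})

test_that("AUROC equals the exhaustive concordant-pair fraction", {
  # perfectly separating scores
  truth <- rep(c("present", "absent"), c(5, 5))
  perfect <- roc_pr_curves(c(runif(5, 0.8, 1), runif(5, 0, 0.2)), truth)
  expect_equal(perfect$auroc, 1)
  # constant scores: chance
  expect_equal(roc_pr_curves(rep(0.5, 10), truth)$auroc, 0.5)
  # random instances vs brute-force concordance (with tie correction)
  set.seed(23)
  for (i in 1:10) {
    n <- 40
    tr <- sample(c("present", "absent"), n, replace = TRUE,
                 prob = c(0.4, 0.6))
    if (length(unique(tr)) < 2) next
    sc <- round(runif(n), 2) # ties likely
    out <- roc_pr_curves(sc, tr)
    pos <- sc[tr == "present"]
    neg <- sc[tr == "absent"]
    conc <- 0
    for (p in pos) for (q in neg) {
      conc <- conc + (p > q) + 0.5 * (p == q)
    }
    expect_equal(out$auroc, conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  expect_error(roc_pr_curves(runif(5), rep("absent", 5)), "both classes")
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  tr <- sample(c("present", "absent"), 100, replace = TRUE)
  sc <- runif(100)
  ours <- roc_pr_curves(sc, tr)$auroc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = tr, predictor = sc, levels = c("absent", "present"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("cross-validation aggregates fold metrics coherently", {
  ds <- simulate_dataset(40, prevalence = 0.4, seed = 2, duration_s = 5)
  fa2 <- tremor_features(ds, "a2")
  cv <- cross_validate(ds, "a2r", k = 5, seed = 1, features = fa2)
  expect_s3_class(cv, "tremor_cv")
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(sum(cv$folds$n_test), 40L)
  expect_equal(cv$summary$mean[cv$summary$metric == "f1"],
               mean(cv$folds$f1))
  expect_equal(cv$summary$sd[cv$summary$metric == "accuracy"],
               sd(cv$folds$accuracy))
  expect_null(cv$mean_curves) # rule pipelines are single operating points
  expect_error(plot(cv), "single operating")

  cvb <- cross_validate(ds, "b2", k = 5, seed = 1)
  expect_true(all(c("auroc", "auprc") %in% cvb$summary$metric))
  expect_equal(nrow(cvb$mean_curves$roc), 101L)
  expect_true(all(cvb$mean_curves$roc$tpr >= 0 &
                    cvb$mean_curves$roc$tpr <= 1))
  # plotting runs without error on a throwaway device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(cvb))
})
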