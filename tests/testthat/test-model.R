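test_that("AUROC is the tie-averaged rank statistic", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c("P", "P", "B", "B")), 1)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c("P", "P", "B", "B")), 0)
  # reversal symmetry
  set.seed(21)
  s <- runif(60); y <- sample(c("B", "P"), 60, replace = TRUE)
  expect_equal(auroc(-s, y), 1 - auroc(s, y))
  # independent oracle: pROC on random scores with ties
  s2 <- round(runif(200), 1)
  y2 <- sample(c("B", "P"), 200, replace = TRUE)
  oracle <- as.numeric(pROC::auc(pROC::roc(y2, s2, levels = c("B", "P"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(auroc(s2, y2), oracle)
  # label-independent scores hover near 0.5
  s3 <- runif(4000); y3 <- rep(c("B", "P"), 2000)
  expect_lt(abs(auroc(s3, y3) - 0.5), 0.05)
  expect_error(auroc(1:3, c("P", "P", "P")), "both classes")
})

test_that("AUPRC is the step-interpolated precision-recall area", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c("P", "P", "B", "B")), 1)
  # hand-computed: descending thresholds give precision 1 at recall 1/2,
  # then 2/3 at recall 1 -> 0.5 + 0.5 * 2/3
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c("P", "B", "P", "B")),
               0.5 + 0.5 * 2 / 3)
  # tied scores enter the curve together
  expect_equal(auprc(c(1, 1, 1, 1), c("P", "B", "P", "B")), 0.5)
})

test_that("cross-validation folds form a stratified partition", {
  coh <- shared_cohort()
  fold <- stoplossr:::cv_folds(coh$labels, 5L, seed = 3L)
  expect_true(all(fold %in% 1:5))
  expect_identical(length(fold), length(coh$labels))
  for (k in 1:5) {
    frac_p <- mean(coh$labels[fold == k] == "P")
    expect_lt(abs(frac_p - 0.5), 0.05)
  }
})

test_that("training and prediction respect the probability-forest contract", {
  coh <- shared_cohort()
  fit <- shared_model()
  s <- predict(fit, coh$features)
  expect_true(all(s >= 0 & s <= 1))
  # scores separate the planted classes on the training data
  expect_gt(mean(s[coh$labels == "P"]), mean(s[coh$labels == "B"]))
  # identical rows get identical scores
  expect_identical(predict(fit, coh$features[c(1, 1), ]),
                   rep(predict(fit, coh$features[1, , drop = FALSE]), 2))
  # all-missing row scores at the all-medians point
  empty <- coh$features[1, ]
  empty[1, ] <- NA_real_
  medians_row <- as.data.frame(as.list(fit$medians))
  names(medians_row) <- names(coh$features)
  expect_identical(predict(fit, empty), predict(fit, medians_row))
  # registry mismatch is refused
  bad <- coh$features
  names(bad)[1] <- "not_a_feature"
  expect_error(predict(fit, bad), "registry")
  # tiny training sets still fit
  expect_s3_class(train_forest(coh$features[c(1:5, 400:404), ],
                               coh$labels[c(1:5, 400:404)], ntree = 10),
                  "trained_forest")
  expect_error(train_forest(coh$features[1:5, ], rep("P", 5)), "both classes")
})

test_that("the forest score is the mean of per-tree votes", {
  fit <- shared_model()
  coh <- shared_cohort()
  rows <- coh$features[seq(1, 600, length.out = 10), ]
  filled <- apply_medians(rows, fit$medians)
  all_trees <- predict(fit$forest, filled, predict.all = TRUE)
  vote_mean <- rowMeans(all_trees$individual == "P")
  expect_equal(predict(fit, rows), unname(vote_mean))
})

test_that("grid search is deterministic and finds separable structure", {
  coh <- shared_cohort()
  idx <- c(1:60, 311:370)  # 60 P + 60 B subset for speed
  cfg <- forest_config(mtry_grid = c(2, 10), ntree_grid = c(20, 50),
                       max_node_grid = 10, folds = 3)
  gs1 <- grid_search_cv(coh$features[idx, ], coh$labels[idx], cfg, seed = 9)
  gs2 <- grid_search_cv(coh$features[idx, ], coh$labels[idx], cfg, seed = 9)
  expect_identical(gs1$best, gs2$best)
  expect_identical(nrow(gs1$table), 4L)
  expect_gt(gs1$best$cv_auroc, 0.9)
  # full default grid spans 5 x 6 x 4 = 120 hyperparameter combinations
  dflt <- forest_config()
  expect_identical(length(dflt$mtry_grid) * length(dflt$ntree_grid) *
                     length(dflt$max_node_grid), 120L)
})

test_that("Gini importance covers the registry and recovers planted signal", {
  fit <- shared_model()
  imp <- forest_importance(fit)
  expect_identical(nrow(imp), 37L)
  expect_setequal(imp$feature, feature_registry())
  expect_equal(max(imp$importance), 100)
  expect_true(all(imp$importance >= 0))

  # two informative features among pure noise rank on top
  set.seed(42)
  n <- 300
  x <- as.data.frame(matrix(rnorm(n * 10), n,
                            dimnames = list(NULL, paste0("f", 1:10))))
  y <- ifelse(x$f3 + x$f7 > 0, "P", "B")
  fit2 <- train_forest(x, y, mtry = 3, ntree = 100, max_node = 20, seed = 5)
  top5 <- forest_importance(fit2)$feature[1:5]
  expect_true(all(c("f3", "f7") %in% top5))
})

test_that("predicted scores fall with the planted allele-frequency proxy", {
  fit <- shared_model()
  test <- shared_test_cohort()
  s <- predict(fit, test$features)
  expect_lt(spearman_cor(s, test$af_proxy)$rho, -0.3)
})

test_that("model archives round-trip and refuse mismatched registries", {
  fit <- shared_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_forest(fit, path)
  back <- load_forest(path)
  coh <- shared_cohort()
  expect_identical(predict(back, coh$features[1:5, ]),
                   predict(fit, coh$features[1:5, ]))
  # version check
  saveRDS(list(version = 99L, model = fit), path)
  expect_error(load_forest(path), "version")
})
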