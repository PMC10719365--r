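test_that("balanced sampling draws equal per-unit counts deterministically", {
  tab <- tiny_cohort(seed = 1, patients = 3, cells = 30)
  bal <- balance_sample(tab, cells_per_unit = 20, seed = 5)
  expect_equal(as.integer(table(bal$patient_id)), rep(20L, 6))
  bal2 <- balance_sample(tab, cells_per_unit = 20, seed = 5)
  expect_identical(bal, bal2)                       # same seed, same subset
  bal3 <- balance_sample(tab, cells_per_unit = 20, seed = 6)
  expect_false(identical(rownames(bal), rownames(bal3)))
  # units below the floor are excluded
  tab_small <- tab[!(tab$patient_id == "P01" &
                       seq_len(nrow(tab)) %in% which(tab$patient_id == "P01")[1:15]), ]
  bal4 <- balance_sample(tab_small, cells_per_unit = 20, seed = 5)
  expect_false("P01" %in% bal4$patient_id)
  expect_error(balance_sample(tab, cells_per_unit = 1e5, seed = 1), "cell count")
})

test_that("correlation pruning removes only strictly-supra-threshold pairs", {
  set.seed(81)
  n <- 300
  f1 <- rnorm(n)
  tab <- data.frame(patient_id = "p", condition = "c",
                    f1 = f1, f2 = 2 * f1, f3 = rnorm(n))
  pr <- prune_correlated(tab)
  expect_true("f1" %in% names(pr))                  # earlier feature kept
  expect_false("f2" %in% names(pr))
  expect_equal(attr(pr, "removed"), "f2")
  # a pair with |r| = 0.8 exactly is kept (strict > rule); exact r built
  # from an orthogonalized residual
  a <- rnorm(5000)
  b0 <- residuals(lm(rnorm(5000) ~ a))
  b <- 0.8 * scale(a)[, 1] + 0.6 * scale(b0)[, 1]
  tab2 <- data.frame(patient_id = "p", fa = scale(a)[, 1], fb = b)
  expect_equal(abs(cor(tab2$fa, tab2$fb)), 0.8, tolerance = 1e-12)
  pr2 <- prune_correlated(tab2, r_thresh = 0.8)
  expect_true(all(c("fa", "fb") %in% names(pr2)))
  # independent features survive; constant features warn
  tab3 <- data.frame(patient_id = "p",
                     matrix(rnorm(1000 * 5), 1000, 5,
                            dimnames = list(NULL, paste0("g", 1:5))))
  pr3 <- prune_correlated(tab3)
  expect_length(attr(pr3, "removed"), 0)
  tab3$g6 <- 1
  expect_warning(pr4 <- prune_correlated(tab3), "constant")
  expect_false("g6" %in% names(pr4))
  # postcondition: no surviving pair with |r| > 0.8
  tabx <- tiny_cohort(seed = 3)
  prx <- prune_correlated(tabx)
  cm <- abs(cor(as.matrix(prx[feature_columns(prx)])))
  diag(cm) <- 0
  expect_lte(max(cm), 0.8)
})

test_that("balanced accuracy equals hand-computed confusion arithmetic", {
  # confusion [[8,2],[4,6]] -> (0.8 + 0.6) / 2 = 0.7
  truth <- rep(c("a", "b"), c(10, 10))
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 4), rep("b", 6))
  expect_equal(balanced_accuracy(truth, pred), 0.7)
  expect_equal(balanced_accuracy(truth, truth), 1)
  expect_equal(balanced_accuracy(truth, rep("a", 20)), 0.5)
  # three classes
  truth3 <- rep(c("x", "y", "z"), each = 4)
  pred3 <- c(rep("x", 4), rep("x", 4), rep("z", 4))
  expect_equal(balanced_accuracy(truth3, pred3), (1 + 0 + 1) / 3)
})

test_that("LOPO folds never share a patient and detect planted effects", {
  tab <- tiny_cohort(seed = 2, patients = 3, cells = 30, effect = 1.8)
  cv <- lopo_cv_rfc(tab, "condition", config = rf_config(ntree = 80),
                    seed = 1)
  expect_equal(length(cv$patients), 6)              # one fold per patient
  expect_equal(length(cv$fold_accuracy), 6)
  # strong planted effect: high accuracy
  expect_gt(cv$mean_accuracy, 0.9)
  # confusion matrix rows sum to one
  expect_equal(unname(rowSums(cv$confusion)), c(1, 1), tolerance = 1e-9)
  # importances sum to one per fold
  expect_equal(unname(rowSums(cv$importance)), rep(1, 6), tolerance = 1e-9)
  # per-cell predictions cover every cell exactly once
  expect_equal(nrow(cv$predictions), nrow(tab))
  # label leakage check: a patient with two classes errors by default
  tab_bad <- tab
  tab_bad$condition[tab_bad$patient_id == "P01"][1:5] <- "tumor"
  expect_error(lopo_cv_rfc(tab_bad, "condition"), "label leakage")
  expect_s3_class(lopo_cv_rfc(tab_bad, "condition",
                              config = rf_config(ntree = 30),
                              allow_multiclass_patients = TRUE),
                  "chrome_cv")
})

test_that("majority voting aggregates per-cell calls with a tie rule", {
  cv <- list(predictions = data.frame(
    patient_id = rep(c("p1", "p2", "p3"), each = 10),
    truth = rep(c("tumor", "control", "tumor"), each = 10),
    pred = c(rep("tumor", 6), rep("control", 4),      # p1: majority correct
             rep("control", 7), rep("tumor", 3),      # p2: majority correct
             rep("tumor", 5), rep("control", 5)),     # p3: exact tie
    stringsAsFactors = FALSE),
    patients = c("p1", "p2", "p3"), classes = c("control", "tumor"))
  class(cv) <- "chrome_cv"
  mv <- patient_majority_vote(cv)
  expect_equal(mv$per_patient$correct[1:2], c(TRUE, TRUE))
  expect_true(mv$per_patient$ambiguous[3])
  expect_equal(mv$per_patient$call[3], "control")     # class-order tie-break
  expect_equal(mv$patient_accuracy, 2 / 3)
})

test_that("permutation baseline is chance-calibrated and sized n_perm", {
  tab <- simulate_feature_cohort(n_patients_per_condition = 3,
                                 cells_per_patient = 25,
                                 effects = list(), patient_sd = 0,
                                 n_noise_features = 8, seed = 4)
  null <- permutation_baseline(tab, "condition", n_perm = 10,
                               config = rf_config(ntree = 50), seed = 2)
  expect_length(null$null_mean_accuracy, 10)
  expect_lt(abs(null$mean - 0.5), 0.05)
})

test_that("ablation grids behave as learning curves with 10 repetitions", {
  tab <- tiny_cohort(seed = 5, patients = 4, cells = 25, effect = 1.8)
  ab <- ablation_patients(tab, "condition", k_grid = c(1, 3), reps = 3,
                          config = rf_config(ntree = 40), seed = 1)
  expect_equal(dim(ab$accuracy), c(3, 2))
  expect_gte(ab$mean["3"] + 0.1, ab$mean["1"])     # non-decreasing up to noise
  ab2 <- ablation_cells(tab, "condition", p_grid = c(0.2, 1), reps = 3,
                        config = rf_config(ntree = 40), seed = 1)
  expect_equal(dim(ab2$accuracy), c(3, 2))
  expect_gte(ab2$mean["1"] + 0.1, ab2$mean["0.2"])
  expect_error(ablation_patients(tab, "condition", k_grid = 1:9),
               "exceeds")
})

test_that("gini ranking surfaces planted features above noise", {
  tab <- tiny_cohort(seed = 6, patients = 3, cells = 40, effect = 1.8)
  cv <- lopo_cv_rfc(tab, "condition", config = rf_config(ntree = 100),
                    seed = 1)
  gr <- gini_ranking(cv, top_n = 5)
  expect_equal(nrow(gr), 5)
  planted <- c("volume_um3", "hc_volume_fraction", "foci_count")
  expect_true(all(planted %in% gr$feature[1:5]))
  expect_true(all(diff(gr$importance) <= 0))        # descending
  # noise features have near-uniform low importance
  full <- gini_ranking(cv, top_n = 100)
  noise_imp <- full$importance[grepl("noise", full$feature)]
  expect_lt(max(noise_imp), min(full$importance[full$feature %in% planted]))
})

test_that("Welch/BH screen matches hand-computed adjustments and formulas", {
  # identical groups: nothing significant
  set.seed(82)
  x <- rnorm(100)
  tab <- data.frame(patient_id = "p", condition = rep(c("a", "b"), 50),
                    f1 = c(x, x)[1:100], f2 = rnorm(100))
  sc <- welch_screen_bh(tab, "condition")
  expect_false(any(sc$significant))
  # BH step-up on (0.01, 0.02, 0.03), m = 3 -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # screen's adjusted p agree with p.adjust on its own raw p
  tab2 <- tiny_cohort(seed = 7, patients = 3, cells = 30)
  sc2 <- welch_screen_bh(tab2, "condition")
  expect_equal(sc2$p_adj, p.adjust(sc2$p, "BH"))
  expect_true(all(sc2$p_adj >= sc2$p, na.rm = TRUE))
  # monotone in raw-p order
  ord <- order(sc2$p)
  expect_true(all(diff(sc2$p_adj[ord]) >= -1e-12))
  # Welch statistic equals the direct formula
  a <- rnorm(40, 1, 1); b <- rnorm(35, 1.5, 2)
  tab3 <- data.frame(patient_id = "p",
                     condition = rep(c("a", "b"), c(40, 35)),
                     f = c(a, b))
  sc3 <- welch_screen_bh(tab3, "condition")
  t_direct <- (mean(a) - mean(b)) / sqrt(var(a) / 40 + var(b) / 35)
  expect_equal(sc3$statistic, t_direct)
  # zero variance in both groups: flagged undefined
  tab4 <- data.frame(patient_id = "p", condition = rep(c("a", "b"), 20),
                     f = rep(1, 40), g = rnorm(40))
  sc4 <- welch_screen_bh(tab4, "condition")
  expect_true(is.na(sc4$p[sc4$feature == "f"]))
})

test_that("star coding follows the published thresholds", {
  expect_equal(significance_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("control-normalized comparison pins the control mean at one", {
  set.seed(83)
  vals <- c(rnorm(50, 10, 1), rnorm(50, 7, 1))
  grp <- rep(c("control", "tumor"), each = 50)
  cc <- compare_to_control(vals, grp, "control")
  expect_equal(cc$mean[cc$group == "control"], 1)
  expect_lt(cc$mean[cc$group == "tumor"], 1)
  expect_true(cc$stars[cc$group == "tumor"] %in% c("***", "****"))
  expect_error(compare_to_control(vals, grp, "missing"), "control")
})

test_that("embeddings give one 2-D point per cell, deterministically", {
  tab <- tiny_cohort(seed = 8, patients = 3, cells = 20)
  for (m in c("pca", "lda")) {
    emb <- qc_embedding(tab, method = m, seed = 1)
    expect_equal(nrow(emb), nrow(tab))
    expect_true(all(c("dim1", "dim2") %in% names(emb)))
    emb2 <- qc_embedding(tab, method = m, seed = 1)
    expect_identical(emb, emb2)
  }
  sub <- tab[1:60, ]
  emb <- qc_embedding(sub, method = "tsne", seed = 2, perplexity = 10)
  expect_equal(nrow(emb), 60)
  emb2 <- qc_embedding(sub, method = "tsne", seed = 2, perplexity = 10)
  expect_identical(emb, emb2)
  # locality: duplicated cells land near each other
  dup <- rbind(sub, sub[1, ])
  embd <- qc_embedding(dup, method = "tsne", seed = 3, perplexity = 10)
  d_pair <- sqrt((embd$dim1[61] - embd$dim1[1])^2 +
                   (embd$dim2[61] - embd$dim2[1])^2)
  d_all <- sqrt((embd$dim1[2:60] - embd$dim1[1])^2 +
                  (embd$dim2[2:60] - embd$dim2[1])^2)
  expect_lt(d_pair, quantile(d_all, 0.1))
})
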