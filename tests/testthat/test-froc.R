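# small deterministic dataset used throughout: 10 cases / 10 controls
toy_data <- local({
  g <- cbind(sep = c(rep(2L, 10), rep(0L, 10)),        # perfectly separating
             inf = c(rep(0L, 4), rep(1L, 3), rep(2L, 3),
                     rep(0L, 1), rep(1L, 3), rep(2L, 6)),
             nul = rep(c(0L, 1L), 10))
  genotype_dataset(g, c(rep(1L, 10), rep(0L, 10)))
})

test_that("genotype_dataset validates inputs", {
  expect_error(genotype_dataset(matrix(0L, 2, 1), c(1L, 1L)),
               "at least one case and one control")
  expect_error(genotype_dataset(matrix(c(0L, 3L), 2, 1), c(0L, 1L)),
               "invalid genotype code")
  expect_error(genotype_dataset(matrix(0L, 3, 1), c(0L, 1L)),
               "phenotype length")
})

test_that("handle_missing: own_category keeps NA, impute_mode fills the mode", {
  g <- cbind(a = c(0L, 0L, 1L, NA), b = c(2L, NA, NA, 1L))
  d <- genotype_dataset(g, c(1L, 1L, 0L, 0L))
  expect_identical(handle_missing(d, "own_category")$genotypes, d$genotypes)
  imp <- handle_missing(d, "impute_mode")
  expect_equal(imp$genotypes[, "a"], c(0L, 0L, 1L, 0L), ignore_attr = TRUE)
  # column b ties 1 vs 2 -> lower code wins
  expect_equal(imp$genotypes[, "b"], c(2L, 1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(attr(imp, "impute_values"), c(a = 0L, b = 1L))

  allna <- genotype_dataset(cbind(x = c(NA, NA)[1:2]), c(0L, 1L))
  expect_error(handle_missing(allna, "impute_mode"), "SNP x")
  # no missing values: identity under both modes
  expect_identical(handle_missing(toy_data, "impute_mode")$genotypes,
                   toy_data$genotypes)
})

test_that("empirical_lr covers ratios, infinity and smoothing", {
  expect_equal(empirical_lr(5, 5, 50, 50), 1)
  expect_equal(empirical_lr(10, 5, 100, 100), 2)
  expect_identical(empirical_lr(3, 0, 100, 100), Inf)
  expect_error(empirical_lr(0, 0, 10, 10), "empty on both")
  # smoothing makes a zero-control group finite but still top-ranked
  sm0 <- empirical_lr(3, 0, 100, 100, smoothing = 0.5, n_groups = 4)
  sm1 <- empirical_lr(3, 1, 100, 100, smoothing = 0.5, n_groups = 4)
  expect_true(is.finite(sm0))
  expect_gt(sm0, sm1)
})

test_that("split_group counts children per observed category and conserves totals", {
  root <- list(keys = "", idx = 1:20, id = 1L)
  kids <- split_group(root, "inf", toy_data)
  expect_length(kids, 3L)
  expect_equal(sum(vapply(kids, `[[`, numeric(1), "n_case")), 10)
  expect_equal(sum(vapply(kids, `[[`, numeric(1), "n_control")), 10)
  # all samples genotype 0 at one SNP: single child identical to parent
  mono <- genotype_dataset(cbind(z = rep(0L, 6)), c(1L, 1L, 1L, 0L, 0L, 0L))
  one <- split_group(list(keys = "", idx = 1:6, id = 1L), "z", mono)
  expect_length(one, 1L)
  expect_equal(one[[1L]]$n_case, 3)
  # hand-counted lrs: cases (6,3,1) vs controls (1,3,6) at N = 10 each
  g <- cbind(s = c(rep(0L, 6), rep(1L, 3), 2L, 0L, rep(1L, 3), rep(2L, 6)))
  d <- genotype_dataset(g, c(rep(1L, 10), rep(0L, 10)))
  ch <- split_group(list(keys = "", idx = 1:20, id = 1L), "s", d)
  expect_equal(vapply(ch, `[[`, numeric(1), "lr"), c(6, 1, 1 / 6))
})

test_that("own_category missing yields a fourth split category", {
  g <- cbind(s = c(0L, 1L, NA, 2L, 0L, 1L, NA, 2L))
  d <- genotype_dataset(g, c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  ch <- split_group(list(keys = "", idx = 1:8, id = 1L), "s",
                    handle_missing(d, "own_category"))
  expect_length(ch, 4L)
})

test_that("merge_groups merges indistinguishable neighbours and honours the gate", {
  nD <- 100; nDbar <- 100
  leaf <- function(nc, nn, key) list(keys = key, idx = integer(0), n_case = nc,
                                     n_control = nn,
                                     lr = empirical_lr(nc, nn, nD, nDbar),
                                     parents = 1L, id = NA_integer_)
  # identical composition: always merged
  same <- merge_groups(list(leaf(30, 30, "0"), leaf(30, 30, "1"),
                            leaf(40, 40, "2")),
                       alpha_merge = 0.05, nD, nDbar)
  expect_length(same, 1L)
  # strongly different: never merged at 0.05
  diffr <- merge_groups(list(leaf(90, 10, "0"), leaf(10, 90, "1")),
                        alpha_merge = 0.05, nD, nDbar)
  expect_length(diffr, 2L)
  expect_equal(vapply(diffr, `[[`, numeric(1), "lr"), c(9, 1 / 9))
  # alpha_merge = 0 disables merging entirely
  off <- merge_groups(list(leaf(30, 30, "0"), leaf(30, 30, "1"),
                           leaf(40, 40, "2")),
                      alpha_merge = 0, nD, nDbar)
  expect_length(off, 3L)
})

test_that("partition_auc equals the per-sample Mann-Whitney score AUC", {
  set.seed(5)
  for (rep in 1:20) {
    d <- sim_fixture(n_per_group = 150, n_null = 1, seed = rep)
    root <- list(keys = "", idx = seq_along(d$phenotype), id = 1L)
    leaves <- split_group(root, "hit", d)
    a1 <- partition_auc(leaves, 150, 150)
    # independent path: score every sample by its leaf lr
    scores <- numeric(length(d$phenotype))
    for (lf in leaves) scores[lf$idx] <- lf$lr
    a2 <- empirical_auc(scores[d$phenotype == 1L], scores[d$phenotype == 0L])
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("forward_step picks the AUC-maximizing candidate deterministically", {
  root <- list(keys = "", idx = 1:20, id = 1L)
  st <- forward_step(list(root), c("nul", "inf", "sep"), toy_data,
                     alpha_merge = 0)
  expect_equal(st$snp, "sep")
  expect_equal(st$auc, 1)
  # exhaustive check against per-candidate evaluation
  per_cand <- vapply(c("sep", "inf", "nul"), function(s) {
    lv <- merge_groups(split_group(root, s, toy_data), 0, 10, 10)
    partition_auc(lv, 10, 10)
  }, numeric(1))
  expect_equal(st$auc, max(per_cand))
  # single candidate is returned as-is
  expect_equal(forward_step(list(root), "nul", toy_data, 0)$snp, "nul")
})

test_that("fit_froc: stepwise structure, monotone training AUC, determinism", {
  d <- sim_fixture(n_per_group = 400, n_null = 2, seed = 9)
  fit <- fit_froc(d, max_predictors = 3, k_folds = 4, seed = 2)
  expect_s3_class(fit, "froc_fit")
  expect_equal(fit$selected_snps[1], "hit")
  expect_true(all(diff(fit$train_auc_per_step) >= -1e-12))
  expect_length(fit$cv_auc_per_step, length(fit$selected_snps))
  # leaves partition the sample exactly
  idx <- sort(unlist(lapply(fit$leaves, `[[`, "idx")))
  expect_identical(idx, seq_along(d$phenotype))
  # same seed, same result
  fit2 <- fit_froc(d, max_predictors = 3, k_folds = 4, seed = 2)
  expect_identical(fit$cv_auc_per_step, fit2$cv_auc_per_step)
  expect_identical(fit$selected_snps, fit2$selected_snps)
  # max_predictors = 1 stops after one step
  expect_length(fit_froc(d, max_predictors = 1, k_folds = 0)$selected_snps, 1L)
  # fold count validation
  expect_error(fit_froc(d, k_folds = 1), "k_folds")
})

test_that("alpha_merge = 0 step-1 partition has one leaf per observed category", {
  d <- sim_fixture(n_per_group = 300, n_null = 1, seed = 4)
  fit <- fit_froc(d, max_predictors = 1, k_folds = 0, alpha_merge = 0)
  n_cats <- length(unique(d$genotypes[, fit$selected_snps]))
  expect_length(fit$leaves, n_cats)
  # proper tree: children counts sum to the parent's
  walk <- function(node) {
    if (length(node$children) == 0L) return(invisible())
    expect_equal(sum(vapply(node$children, `[[`, numeric(1), "n_case")),
                 node$n_case)
    expect_equal(sum(vapply(node$children, `[[`, numeric(1), "n_control")),
                 node$n_control)
    for (ch in node$children) walk(ch)
  }
  walk(fit$tree)
})

test_that("cross_validated_auc is seeded, stratified and below training on average", {
  d <- sim_fixture(n_per_group = 300, n_null = 2, seed = 21)
  cv_a <- cross_validated_auc(d, max_predictors = 2, k = 5, seed = 7)
  cv_b <- cross_validated_auc(d, max_predictors = 2, k = 5, seed = 7)
  expect_identical(cv_a, cv_b)
  expect_error(cross_validated_auc(d, 2, k = 1, seed = 1), "between 2")

  # optimism: CV AUC does not exceed training AUC on average
  diffs <- vapply(1:10, function(s) {
    ds <- sim_fixture(n_per_group = 150, n_null = 2, seed = 100 + s)
    fit <- fit_froc(ds, max_predictors = 2, k_folds = 5, seed = s)
    fit$auc - fit$cv_auc_per_step[length(fit$cv_auc_per_step)]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("apply_model routes by genotype path and handles unseen paths", {
  d <- sim_fixture(n_per_group = 400, n_null = 1, seed = 13)
  fit <- fit_froc(d, max_predictors = 2, k_folds = 0)
  # self-application reproduces the fitted AUC
  self <- apply_model(fit, d)
  expect_equal(self$auc, fit$auc, tolerance = 1e-12)
  # unseen genotype paths score exactly 1 (here: a code absent from training)
  unseen <- genotype_dataset(
    matrix(NA_integer_, 4, length(d$snp_ids),
           dimnames = list(NULL, d$snp_ids)) ,
    c(1L, 1L, 0L, 0L))
  unseen$genotypes[] <- NA_integer_
  res <- apply_model(fit, unseen)
  expect_equal(res$scores, rep(1, 4))
  expect_equal(res$auc, 0.5)
  # missing selected column is an error naming the SNP
  d2 <- d; d2$genotypes <- d$genotypes[, -1, drop = FALSE]
  d2$snp_ids <- d$snp_ids[-1]
  expect_error(apply_model(fit, d2), "hit")
})

test_that("stop_rule = cv returns the CV-maximizing model size", {
  d <- sim_fixture(n_per_group = 300, n_null = 4, seed = 31)
  fit <- fit_froc(d, max_predictors = 4, k_folds = 5, seed = 2,
                  stop_rule = "cv")
  expect_equal(length(fit$selected_snps), which.max(fit$cv_auc_per_step))
})
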