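#' Construct a case-control genotype dataset
#'
#' @param genotypes integer matrix, individuals in rows and SNPs in
#'   columns; entries in `{0, 1, 2}` (minor-allele count) or `NA` for
#'   missing. Environmental predictors may be supplied as additional
#'   categorical columns with small integer codes.
#' @param phenotype vector of 0 (control) / 1 (case), one per row.
#' @param sample_ids optional row identifiers.
#' @param snp_ids optional column identifiers; defaults to column names.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, phenotype, sample_ids = NULL,
                             snp_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(genotypes)))
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length must equal the number of rows")
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be coded 0 (control) / 1 (case)")
  if (sum(phenotype == 1L) == 0L || sum(phenotype == 0L) == 0L)
    stop("dataset must contain at least one case and one control")
  bad <- which(!(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(genotypes))
    stop(sprintf("invalid genotype code %s at row %d, column %s",
                 genotypes[bad[1L]], rc[1L], snp_ids[rc[2L]]))
  }
  storage.mode(genotypes) <- "integer"
  colnames(genotypes) <- snp_ids
  structure(list(sample_ids = as.character(sample_ids),
                 phenotype = as.integer(phenotype),
                 snp_ids = as.character(snp_ids),
                 genotypes = genotypes),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases / %d controls), %d predictors\n",
              length(x$phenotype), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), length(x$snp_ids)))
  invisible(x)
}

#' Handle missing genotype data
#'
#' `own_category` keeps missing codes and treats "missing" as an
#' additional genotype category during partitioning; `impute_mode`
#' replaces each missing value with the SNP's most frequent non-missing
#' code (ties broken towards the lower code).
#'
#' @param data a `genotype_dataset`.
#' @param mode `"own_category"` or `"impute_mode"`.
#' @return A `genotype_dataset`; under `impute_mode` the filled dataset
#'   carries the per-SNP fill values as attribute `impute_values`.
#' @export
handle_missing <- function(data, mode = c("own_category", "impute_mode")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "genotype_dataset"))
  all_missing <- colSums(!is.na(data$genotypes)) == 0L
  if (any(all_missing))
    stop(sprintf("SNP %s has no observed genotypes",
                 data$snp_ids[which(all_missing)[1L]]))
  if (mode == "own_category" || !anyNA(data$genotypes)) {
    if (mode == "impute_mode")
      attr(data, "impute_values") <-
        stats::setNames(integer(0), character(0))
    return(data)
  }
  g <- data$genotypes
  fills <- integer(ncol(g))
  for (j in seq_len(ncol(g))) {
    tb <- tabulate(g[, j] + 1L, nbins = 3L)     # counts of codes 0,1,2
    fills[j] <- which.max(tb) - 1L               # which.max takes lower tie
    g[is.na(g[, j]), j] <- fills[j]
  }
  out <- genotype_dataset(g, data$phenotype, data$sample_ids, data$snp_ids)
  attr(out, "impute_values") <- stats::setNames(fills, data$snp_ids)
  out
}

# categorical view of the genotype matrix: "0","1","2", and "m" for NA
.geno_categories <- function(genotypes) {
  g <- matrix(as.character(genotypes), nrow = nrow(genotypes),
              dimnames = dimnames(genotypes))
  g[is.na(g)] <- "m"
  g
}

#' Empirical likelihood ratio of a risk group
#'
#' \deqn{LR = \frac{(n_{case} + c)/(N_D + cG)}{(n_{control} + c)/(N_{\bar D} + cG)}}
#' with optional pseudo-count smoothing `c` over `G` groups. With `c = 0`
#' (the default) a group with cases but no controls has infinite LR and is
#' ranked first.
#'
#' @param n_case,n_control group counts.
#' @param n_total_case,n_total_control totals \eqn{N_D}, \eqn{N_{\bar D}}.
#' @param smoothing pseudo-count `c >= 0`; default 0.
#' @param n_groups number of groups `G` at evaluation time (needed when
#'   `smoothing > 0`).
#' @return The empirical likelihood ratio (possibly `Inf`).
#' @export
empirical_lr <- function(n_case, n_control, n_total_case, n_total_control,
                         smoothing = 0, n_groups = 1L) {
  stopifnot(n_total_case > 0, n_total_control > 0,
            n_case <= n_total_case, n_control <= n_total_control,
            smoothing >= 0)
  if (n_case == 0 && n_control == 0 && smoothing == 0)
    stop("risk group is empty on both margins")
  num <- (n_case + smoothing) / (n_total_case + smoothing * n_groups)
  den <- (n_control + smoothing) / (n_total_control + smoothing * n_groups)
  if (den == 0) {
    if (num == 0) stop("risk group is empty on both margins")
    return(Inf)
  }
  num / den
}

# ---- internal leaf machinery ------------------------------------------------
# A leaf is a list: keys (character vector of genotype-path keys over the
# selected SNPs, "/"-joined in selection order), idx (sample row indices),
# n_case, n_control, lr, parents (integer ids at the previous level), id.

.new_leaf <- function(keys, idx, phen, nD, nDbar, smoothing = 0, G = 1L,
                      parents = integer(0)) {
  nc <- sum(phen[idx] == 1L)
  nn <- length(idx) - nc
  list(keys = keys, idx = idx, n_case = nc, n_control = nn,
       lr = empirical_lr(nc, nn, nD, nDbar, smoothing, G),
       parents = parents, id = NA_integer_)
}

# refresh lr for all leaves (G changes as leaves merge)
.refresh_lr <- function(leaves, nD, nDbar, smoothing) {
  G <- length(leaves)
  for (i in seq_along(leaves))
    leaves[[i]]$lr <- empirical_lr(leaves[[i]]$n_case, leaves[[i]]$n_control,
                                   nD, nDbar, smoothing, G)
  leaves
}

#' Split a risk group by a SNP
#'
#' Produces one child group per genotype category observed among the
#' group's samples (up to four when missing values form their own
#' category); empty categories are omitted and children's counts sum to
#' the parent's.
#'
#' @param node a leaf as produced during fitting (list with `idx`, `keys`).
#' @param snp SNP identifier (must not already be on the node's path).
#' @param geno_cat categorical genotype matrix (see internals), or a
#'   `genotype_dataset`.
#' @param phenotype 0/1 vector (taken from `geno_cat` when it is a
#'   dataset).
#' @param smoothing,n_groups passed to [empirical_lr()].
#' @return List of child leaves, ordered by genotype category.
#' @export
split_group <- function(node, snp, geno_cat, phenotype = NULL,
                        smoothing = 0, n_groups = 1L) {
  if (inherits(geno_cat, "genotype_dataset")) {
    phenotype <- geno_cat$phenotype
    geno_cat <- .geno_categories(geno_cat$genotypes)
  }
  nD <- sum(phenotype == 1L); nDbar <- sum(phenotype == 0L)
  cats <- geno_cat[node$idx, snp]
  pieces <- split(node$idx, cats)
  lapply(names(pieces), function(cc) {
    keys <- if (length(node$keys) == 1L && node$keys == "") cc
            else paste(node$keys, cc, sep = "/")
    .new_leaf(keys, pieces[[cc]], phenotype, nD, nDbar, smoothing, n_groups,
              parents = node$id)
  })
}

# p-value of the 2x2 case/control comparison of two leaves: chi-square with
# continuity correction, Fisher exact when any expected count < 5.
.pair_pvalue <- function(a, b) {
  m <- matrix(c(a$n_case, a$n_control, b$n_case, b$n_control), nrow = 2L)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5))
    stats::fisher.test(m)$p.value
  else
    suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
}

#' Merge statistically indistinguishable adjacent risk groups
#'
#' Sorts leaves by empirical likelihood ratio and repeatedly merges the
#' adjacent pair whose 2x2 case/control association test has the largest
#' p-value, while that p-value is at least `alpha_merge`. This collapses
#' genotype categories that carry the same risk (for example three
#' genotypes of one SNP reducing to two risk groups) and limits
#' overfitting. `alpha_merge = 0` disables merging.
#'
#' @param leaves list of leaves from a completed split round.
#' @param alpha_merge merge significance gate in \[0, 1\]; default 0.05.
#' @param n_total_case,n_total_control sample totals.
#' @param smoothing pseudo-count for [empirical_lr()].
#' @return List of leaves sorted by decreasing likelihood ratio.
#' @export
merge_groups <- function(leaves, alpha_merge, n_total_case, n_total_control,
                         smoothing = 0) {
  ord <- order(-vapply(leaves, `[[`, numeric(1), "lr"))
  leaves <- leaves[ord]
  if (alpha_merge <= 0 || length(leaves) < 2L)
    return(.refresh_lr(leaves, n_total_case, n_total_control, smoothing))
  repeat {
    if (length(leaves) < 2L) break
    pv <- vapply(seq_len(length(leaves) - 1L), function(i)
      .pair_pvalue(leaves[[i]], leaves[[i + 1L]]), numeric(1))
    i <- which.max(pv)
    if (pv[i] < alpha_merge) break
    a <- leaves[[i]]; b <- leaves[[i + 1L]]
    merged <- list(keys = c(a$keys, b$keys), idx = c(a$idx, b$idx),
                   n_case = a$n_case + b$n_case,
                   n_control = a$n_control + b$n_control,
                   lr = NA_real_,
                   parents = unique(c(a$parents, b$parents)),
                   id = NA_integer_)
    leaves <- c(leaves[seq_len(i - 1L)], list(merged),
                if (i + 1L < length(leaves)) leaves[seq(i + 2L, length(leaves))])
    leaves <- .refresh_lr(leaves, n_total_case, n_total_control, smoothing)
    leaves <- leaves[order(-vapply(leaves, `[[`, numeric(1), "lr"))]
  }
  .refresh_lr(leaves, n_total_case, n_total_control, smoothing)
}

#' Empirical AUC of a risk-group partition
#'
#' Equals the Mann-Whitney AUC when every sample is scored by its leaf's
#' empirical likelihood ratio; computed here as the optimal-ROC AUC of the
#' empirical group mass table.
#'
#' @param leaves list of leaves covering all samples exactly once.
#' @param n_total_case,n_total_control sample totals.
#' @return AUC in \[0.5, 1\].
#' @export
partition_auc <- function(leaves, n_total_case, n_total_control) {
  mc <- vapply(leaves, `[[`, numeric(1), "n_case") / n_total_case
  mm <- vapply(leaves, `[[`, numeric(1), "n_control") / n_total_control
  auc_from_groups(group_table(mc, mm))
}

#' One F-ROC forward-selection step
#'
#' For each candidate SNP, splits every current leaf by that SNP, merges
#' statistically indistinguishable groups, and computes the partition AUC;
#' the candidate with the largest training AUC wins, ties broken by
#' original column order.
#'
#' @param leaves current leaves.
#' @param candidates character vector of candidate SNP ids, in original
#'   column order.
#' @param geno_cat categorical genotype matrix or `genotype_dataset`.
#' @param phenotype 0/1 vector if `geno_cat` is a matrix.
#' @param alpha_merge merge gate; see [merge_groups()].
#' @param smoothing pseudo-count for [empirical_lr()].
#' @return List with `snp`, `leaves` (post-merge), `auc`.
#' @export
forward_step <- function(leaves, candidates, geno_cat, phenotype = NULL,
                         alpha_merge = 0.05, smoothing = 0) {
  if (length(candidates) < 1L) stop("at least one candidate SNP is required")
  if (inherits(geno_cat, "genotype_dataset")) {
    phenotype <- geno_cat$phenotype
    geno_cat <- .geno_categories(geno_cat$genotypes)
  }
  nD <- sum(phenotype == 1L); nDbar <- sum(phenotype == 0L)
  best <- NULL
  for (snp in candidates) {
    new_leaves <- unlist(lapply(leaves, split_group, snp = snp,
                                geno_cat = geno_cat, phenotype = phenotype,
                                smoothing = smoothing),
                         recursive = FALSE)
    new_leaves <- merge_groups(new_leaves, alpha_merge, nD, nDbar, smoothing)
    auc <- partition_auc(new_leaves, nD, nDbar)
    if (is.null(best) || auc > best$auc + 1e-12)
      best <- list(snp = snp, leaves = new_leaves, auc = auc)
  }
  best
}

# core selection loop: no cross-validation, returns per-step leaves
.froc_select <- function(geno_cat, phenotype, snp_ids, max_predictors,
                         alpha_merge, smoothing) {
  nD <- sum(phenotype == 1L); nDbar <- sum(phenotype == 0L)
  root <- .new_leaf("", seq_along(phenotype), phenotype, nD, nDbar,
                    smoothing, 1L)
  root$id <- 1L
  leaves <- list(root)
  selected <- character(0)
  leaves_per_step <- list()
  train_auc <- numeric(0)
  last_auc <- 0.5
  while (length(selected) < max_predictors &&
         length(setdiff(snp_ids, selected)) > 0L) {
    cand <- setdiff(snp_ids, selected)
    st <- forward_step(leaves, cand, geno_cat, phenotype,
                       alpha_merge, smoothing)
    if (st$auc <= last_auc + 1e-9) break      # no candidate improves
    # assign ids for tree bookkeeping
    for (i in seq_along(st$leaves)) st$leaves[[i]]$id <- i
    selected <- c(selected, st$snp)
    leaves <- st$leaves
    leaves_per_step[[length(selected)]] <- leaves
    train_auc <- c(train_auc, st$auc)
    last_auc <- st$auc
  }
  list(selected = selected, leaves_per_step = leaves_per_step,
       train_auc_per_step = train_auc, root = root,
       n_case = nD, n_control = nDbar)
}

# score rows of a categorical genotype matrix against a fitted leaf set:
# key -> leaf lr; unseen genotype paths score lr = 1 (chance)
.score_by_leaves <- function(leaves, selected, geno_cat) {
  if (length(selected) == 0L) return(rep(1, nrow(geno_cat)))
  keys <- apply(geno_cat[, selected, drop = FALSE], 1L, paste, collapse = "/")
  lrmap <- new.env(parent = emptyenv(), size = 4L * length(leaves))
  for (lf in leaves) for (k in lf$keys) assign(k, lf$lr, envir = lrmap)
  vapply(keys, function(k) {
    v <- mget(k, envir = lrmap, ifnotfound = list(NULL))[[1L]]
    if (is.null(v)) 1 else v
  }, numeric(1), USE.NAMES = FALSE)
}

# stratified fold assignment, seeded
.stratified_folds <- function(phenotype, k, seed) {
  fold <- integer(length(phenotype))
  set.seed(seed)
  for (cls in c(1L, 0L)) {
    idx <- which(phenotype == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' K-fold cross-validated AUC of the F-ROC procedure
#'
#' Folds are stratified by case status with a seeded shuffle. For each
#' fold the full forward-selection procedure is refit on the remaining
#' folds; held-out samples are scored by their matched leaf's training
#' likelihood ratio (unseen genotype paths score 1), and the AUC is
#' computed on the pooled held-out scores.
#'
#' @param data a `genotype_dataset`.
#' @param max_predictors maximum model size refit within each fold.
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param alpha_merge,smoothing,missing as in [fit_froc()].
#' @return Cross-validated AUC. With `per_step = TRUE`, the vector of CV
#'   AUCs for model sizes `1..max_predictors`.
#' @param per_step return the CV AUC after each selection step.
#' @export
cross_validated_auc <- function(data, max_predictors, k = 10L, seed = 1L,
                                alpha_merge = 0.05, smoothing = 0,
                                missing = c("own_category", "impute_mode"),
                                per_step = FALSE) {
  missing <- match.arg(missing)
  phen <- data$phenotype
  if (k < 2L || k > min(sum(phen == 1L), sum(phen == 0L)))
    stop("k must be between 2 and the smaller class count")
  fold <- .stratified_folds(phen, k, seed)
  scores <- matrix(NA_real_, length(phen), max_predictors)
  for (f in seq_len(k)) {
    tr <- fold != f
    dtr <- genotype_dataset(data$genotypes[tr, , drop = FALSE], phen[tr],
                            data$sample_ids[tr], data$snp_ids)
    dtr <- handle_missing(dtr, missing)
    gc_tr <- .geno_categories(dtr$genotypes)
    sel <- .froc_select(gc_tr, dtr$phenotype, dtr$snp_ids, max_predictors,
                        alpha_merge, smoothing)
    ho <- data$genotypes[!tr, , drop = FALSE]
    if (missing == "impute_mode") {
      iv <- attr(dtr, "impute_values")
      for (s in names(iv)) ho[is.na(ho[, s]), s] <- iv[[s]]
    }
    gc_ho <- .geno_categories(ho)
    n_steps <- length(sel$selected)
    for (s in seq_len(max_predictors)) {
      use <- min(s, max(n_steps, 1L))
      scores[!tr, s] <-
        if (n_steps == 0L) 1
        else .score_by_leaves(sel$leaves_per_step[[use]],
                              sel$selected[seq_len(use)], gc_ho)
    }
  }
  cv <- vapply(seq_len(max_predictors), function(s)
    empirical_auc(scores[phen == 1L, s], scores[phen == 0L, s]), numeric(1))
  if (per_step) cv else cv[max_predictors]
}

#' Fit a risk-group partition by F-ROC forward selection
#'
#' Starting from a single root group, repeatedly selects the SNP whose
#' split (followed by merging of statistically indistinguishable groups)
#' maximizes the training AUC of the likelihood-ratio-ordered partition.
#' Selection stops at `max_predictors` or when no candidate improves the
#' training AUC; with `stop_rule = "cv"` the returned model is truncated
#' to the step with the highest cross-validated AUC.
#'
#' @param data a `genotype_dataset`.
#' @param max_predictors maximum number of predictors (default 5).
#' @param k_folds folds for internal cross-validation (default 10); set
#'   `k_folds = 0` to skip the CV trace (only with `stop_rule = "max"`).
#' @param seed integer seed (cross-validation fold assignment).
#' @param alpha_merge merge gate for [merge_groups()]; default 0.05, 0
#'   disables merging.
#' @param stop_rule `"max"` (stop at `max_predictors` / no improvement) or
#'   `"cv"` (return the CV-AUC-maximizing model size).
#' @param missing missing-data mode, see [handle_missing()].
#' @param smoothing pseudo-count for [empirical_lr()]; default 0.
#' @return An object of class `froc_fit` with elements `selected_snps`,
#'   `leaves`, `levels` (leaves after each step), `tree` (root
#'   `risk_node`), `train_auc_per_step`, `cv_auc_per_step`, `auc`,
#'   `k_folds`, `seed`, and bookkeeping needed by [apply_model()].
#' @export
fit_froc <- function(data, max_predictors = 5L, k_folds = 10L, seed = 1L,
                     alpha_merge = 0.05, stop_rule = c("max", "cv"),
                     missing = c("own_category", "impute_mode"),
                     smoothing = 0) {
  stop_rule <- match.arg(stop_rule)
  missing <- match.arg(missing)
  stopifnot(inherits(data, "genotype_dataset"), max_predictors >= 1L)
  phen <- data$phenotype
  do_cv <- k_folds > 0L || stop_rule == "cv"
  if (do_cv && (k_folds < 2L || k_folds > min(sum(phen == 1L), sum(phen == 0L))))
    stop("k_folds must be between 2 and the smaller class count")
  filled <- handle_missing(data, missing)
  geno_cat <- .geno_categories(filled$genotypes)
  sel <- .froc_select(geno_cat, phen, data$snp_ids, max_predictors,
                      alpha_merge, smoothing)
  n_steps <- length(sel$selected)
  cv <- if (do_cv && n_steps > 0L)
    cross_validated_auc(data, max_predictors = n_steps, k = k_folds,
                        seed = seed, alpha_merge = alpha_merge,
                        smoothing = smoothing, missing = missing,
                        per_step = TRUE)
  else numeric(0)
  keep <- n_steps
  if (stop_rule == "cv" && n_steps > 0L) keep <- which.max(cv)
  fit <- structure(list(
    selected_snps = sel$selected[seq_len(keep)],
    levels = sel$leaves_per_step[seq_len(keep)],
    leaves = if (keep > 0L) sel$leaves_per_step[[keep]] else list(sel$root),
    train_auc_per_step = sel$train_auc_per_step[seq_len(keep)],
    cv_auc_per_step = if (length(cv)) cv[seq_len(keep)] else numeric(0),
    auc = if (keep > 0L) sel$train_auc_per_step[keep] else 0.5,
    n_case = sel$n_case, n_control = sel$n_control,
    k_folds = if (do_cv) as.integer(k_folds) else 0L,
    seed = as.integer(seed), alpha_merge = alpha_merge,
    smoothing = smoothing, missing = missing,
    impute_values = attr(filled, "impute_values")),
    class = "froc_fit")
  fit$tree <- .build_tree(fit)
  fit
}

#' @export
print.froc_fit <- function(x, ...) {
  cat("F-ROC risk-group partition\n")
  cat(sprintf("  predictors (in order): %s\n",
              paste(x$selected_snps, collapse = ", ")))
  cat(sprintf("  risk groups: %d   training AUC: %.4f\n",
              length(x$leaves), x$auc))
  if (length(x$cv_auc_per_step))
    cat(sprintf("  %d-fold CV AUC: %.4f\n", x$k_folds,
                x$cv_auc_per_step[length(x$cv_auc_per_step)]))
  invisible(x)
}

# per-SNP category sets of a leaf, for display: position i of each key is
# the category of selected SNP i
.leaf_path <- function(leaf, selected) {
  if (length(selected) == 0L) return(list())
  parts <- strsplit(leaf$keys, "/", fixed = TRUE)
  out <- lapply(seq_along(selected), function(i)
    sort(unique(vapply(parts, `[[`, character(1), i))))
  names(out) <- selected
  out
}

#' Risk node accessor: nested tree of risk groups
#'
#' Builds the `risk_node` tree recorded in a fit: the root covers all
#' samples, and each level's nodes are the (merged) risk groups after the
#' corresponding selection step, linked to the previous level's groups
#' they derive from. When merging joins groups from different parents the
#' structure is a layered directed graph; a node then appears under each
#' of its parents.
#'
#' @param fit a `froc_fit`.
#' @return The root `risk_node`, a list with `path`, `n_case`,
#'   `n_control`, `lr`, `children`.
#' @keywords internal
.build_tree <- function(fit) {
  mk <- function(leaf, depth) {
    structure(list(path = .leaf_path(leaf, fit$selected_snps[seq_len(depth)]),
                   n_case = leaf$n_case, n_control = leaf$n_control,
                   lr = leaf$lr, children = list(),
                   .id = leaf$id, .parents = leaf$parents),
              class = "risk_node")
  }
  root <- structure(list(path = list(), n_case = fit$n_case,
                         n_control = fit$n_control, lr = 1,
                         children = list(), .id = 1L, .parents = integer(0)),
                    class = "risk_node")
  attach_level <- function(nodes, depth) {
    if (depth > length(fit$levels)) return(nodes)
    lvl <- lapply(fit$levels[[depth]], mk, depth = depth)
    lvl <- attach_level(lvl, depth + 1L)
    for (i in seq_along(nodes)) {
      kids <- Filter(function(ch) nodes[[i]]$.id %in% ch$.parents, lvl)
      nodes[[i]]$children <- kids
    }
    nodes
  }
  attach_level(list(root), 1L)[[1L]]
}

#' Apply a fitted F-ROC model to new data
#'
#' Routes each sample down the risk-group partition by its genotypes at
#' the selected SNPs; the sample's score is its group's training
#' likelihood ratio. Samples whose genotype path was never seen in
#' training receive the chance score 1. Missing values are handled as in
#' training (imputation reuses the training fill values).
#'
#' @param fit a `froc_fit`.
#' @param newdata a `genotype_dataset` containing all selected SNPs.
#' @return List with `scores` (per-sample LR) and `auc` (`NA` if `newdata`
#'   lacks one of the classes).
#' @export
apply_model <- function(fit, newdata) {
  stopifnot(inherits(fit, "froc_fit"), inherits(newdata, "genotype_dataset"))
  missing_cols <- setdiff(fit$selected_snps, newdata$snp_ids)
  if (length(missing_cols))
    stop(sprintf("newdata lacks selected SNP column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  g <- newdata$genotypes
  if (fit$missing == "impute_mode" && !is.null(fit$impute_values)) {
    for (s in intersect(names(fit$impute_values), colnames(g)))
      g[is.na(g[, s]), s] <- fit$impute_values[[s]]
  }
  scores <- .score_by_leaves(fit$leaves, fit$selected_snps,
                             .geno_categories(g))
  phen <- newdata$phenotype
  auc <- if (sum(phen == 1L) > 0L && sum(phen == 0L) > 0L)
    empirical_auc(scores[phen == 1L], scores[phen == 0L]) else NA_real_
  list(scores = scores, auc = auc)
}

#' Empirical ROC points of a fitted partition
#'
#' @param fit a `froc_fit`.
#' @return A `roc_points` data frame for the training partition.
#' @export
roc_from_fit <- function(fit) {
  mc <- vapply(fit$leaves, `[[`, numeric(1), "n_case") / fit$n_case
  mm <- vapply(fit$leaves, `[[`, numeric(1), "n_control") / fit$n_control
  roc_from_groups(lr_order(group_table(mc, mm)))
}
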