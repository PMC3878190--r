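#' Simulation configuration for retrospective case-control genotype data
#'
#' Describes a penetrance model over unlinked biallelic SNPs: per-SNP
#' risk-allele frequencies (genotype frequencies follow Hardy-Weinberg
#' equilibrium), genotype relative-risk triples with multiplicative joint
#' effects, optional epistatic multipliers on genotype pairs, a disease
#' prevalence, and a missing-data rate. The baseline penetrance is scaled
#' so that the population risk equals the prevalence.
#'
#' @param n_case,n_control numbers of cases and controls to draw.
#' @param mafs per-SNP risk-allele frequencies in (0, 0.5].
#' @param rr list of per-SNP genotype relative-risk triples (baseline 1),
#'   or a single triple recycled to all SNPs.
#' @param prevalence disease prevalence \eqn{\rho}.
#' @param epistasis optional list of terms
#'   `list(snp_i =, snp_j =, geno_i =, geno_j =, multiplier =)` applied to
#'   the joint relative risk of matching genotype pairs.
#' @param missing_rate probability that any genotype call is masked,
#'   missing completely at random; default 0.
#' @param snp_ids optional SNP names; default `snp1..snpL`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_case, n_control, mafs, rr, prevalence,
                       epistasis = NULL, missing_rate = 0, snp_ids = NULL) {
  if (!is.list(rr)) rr <- rep(list(as.numeric(rr)), length(mafs))
  stopifnot(length(mafs) == length(rr), all(mafs > 0), all(mafs <= 0.5),
            prevalence > 0, prevalence < 1,
            missing_rate >= 0, missing_rate < 1,
            all(vapply(rr, function(r) length(r) == 3L && all(r > 0), logical(1))))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_along(mafs))
  if (!is.null(epistasis))
    for (e in epistasis)
      stopifnot(all(c("snp_i", "snp_j", "geno_i", "geno_j", "multiplier") %in%
                      names(e)), e$multiplier > 0)
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 mafs = as.numeric(mafs), rr = rr,
                 prevalence = prevalence, epistasis = epistasis,
                 missing_rate = missing_rate, snp_ids = snp_ids),
            class = "sim_config")
}

# joint genotype enumeration: matrix of 0/1/2 codes (3^L rows) plus the
# population probability and total relative risk of each row
.joint_model <- function(config) {
  L <- length(config$mafs)
  if (3^L > 3^15) stop("too many SNPs to enumerate the joint distribution")
  grid <- as.matrix(expand.grid(rep(list(0:2), L))[, L:1, drop = FALSE])
  colnames(grid) <- config$snp_ids
  fp <- lapply(config$mafs, hwe_genotype_freq)
  prob <- rep(1, nrow(grid)); risk <- rep(1, nrow(grid))
  for (i in seq_len(L)) {
    prob <- prob * fp[[i]][grid[, i] + 1L]
    risk <- risk * config$rr[[i]][grid[, i] + 1L]
  }
  if (!is.null(config$epistasis)) {
    for (e in config$epistasis) {
      hit <- grid[, e$snp_i] == e$geno_i & grid[, e$snp_j] == e$geno_j
      risk[hit] <- risk[hit] * e$multiplier
    }
  }
  k <- config$prevalence / sum(prob * risk)
  pen <- k * risk
  if (any(pen > 1 + 1e-12))
    stop(sprintf("penetrance %.4g > 1: prevalence/relative-risk combination infeasible",
                 max(pen)))
  list(grid = grid, prob = prob, pen = pmin(pen, 1))
}

#' Ground truth of a simulation configuration
#'
#' Returns the exact case and control genotype distributions implied by
#' the penetrance model, as a joint `group_mass_table`, together with the
#' theoretical optimal-ROC AUC, and (when no epistasis terms are present)
#' the per-SNP conditional frequency margins as `snp_design` objects.
#'
#' @param config a `sim_config`.
#' @return List with `table` (joint `group_mass_table`, one group per
#'   multilocus genotype), `auc` (theoretical optimal-ROC AUC), and
#'   `snps` (per-SNP `snp_design` list; `NULL` when epistasis breaks
#'   independence).
#' @export
truth_spec <- function(config) {
  jm <- .joint_model(config)
  rho <- config$prevalence
  mass_case <- jm$prob * jm$pen / rho
  mass_control <- jm$prob * (1 - jm$pen) / (1 - rho)
  lab <- apply(jm$grid, 1L, paste, collapse = "/")
  keep <- !(mass_case == 0 & mass_control == 0)
  tab <- group_table(mass_case[keep], mass_control[keep], lab[keep])
  snps <- NULL
  if (is.null(config$epistasis)) {
    snps <- lapply(seq_along(config$mafs), function(i) {
      cf <- conditional_freqs_from_rr(hwe_genotype_freq(config$mafs[i]),
                                      config$rr[[i]], rho)
      snp_design(config$snp_ids[i], freq_case = cf$freq_case,
                 freq_control = cf$freq_control)
    })
  }
  list(table = tab, auc = auc_from_groups(tab), snps = snps)
}

#' Simulate a retrospective case-control genotype dataset
#'
#' Cases are drawn i.i.d. from the case joint genotype distribution and
#' controls from the control distribution (retrospective sampling, exact
#' for the case-control design); genotype calls are then masked
#' completely at random at `missing_rate`.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; the same seed reproduces the same dataset.
#' @return A `genotype_dataset` with cases first.
#' @export
simulate_case_control <- function(config, seed = 1L) {
  jm <- .joint_model(config)
  rho <- config$prevalence
  p_case <- jm$prob * jm$pen / rho
  p_control <- jm$prob * (1 - jm$pen) / (1 - rho)
  set.seed(seed)
  rows <- c(sample.int(nrow(jm$grid), config$n_case, replace = TRUE,
                       prob = p_case),
            sample.int(nrow(jm$grid), config$n_control, replace = TRUE,
                       prob = p_control))
  g <- jm$grid[rows, , drop = FALSE]
  phen <- rep(c(1L, 0L), c(config$n_case, config$n_control))
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(g)) < config$missing_rate,
                   nrow = nrow(g))
    g[mask] <- NA_integer_
  }
  genotype_dataset(g, phen,
                   sample_ids = paste0(ifelse(phen == 1L, "case", "ctrl"),
                                       seq_along(phen)),
                   snp_ids = config$snp_ids)
}
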