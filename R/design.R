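#' Expand an allele frequency to genotype frequencies under HWE
#'
#' @param q risk-allele frequency in (0, 1).
#' @return Genotype frequencies `c((1-q)^2, 2q(1-q), q^2)` for 0/1/2 copies
#'   of the risk allele.
#' @export
hwe_genotype_freq <- function(q) {
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

#' Per-SNP design-stage information
#'
#' A SNP enters the design stage either with genotype frequencies observed
#' in cases and controls (`mode = "conditional"`) or with population
#' genotype frequencies plus genotype relative risks
#' (`mode = "population_rr"`), from which conditional frequencies are
#' derived given the disease prevalence. A single allele frequency may be
#' supplied instead of `freq_pop`; it is expanded under Hardy-Weinberg
#' equilibrium.
#'
#' @param id SNP identifier.
#' @param freq_case,freq_control genotype probability triples
#'   (conditional mode).
#' @param freq_pop genotype probability triple, or a single risk-allele
#'   frequency (population_rr mode).
#' @param rr genotype relative-risk triple with baseline genotype fixed at
#'   1 (population_rr mode).
#' @return An object of class `snp_design`.
#' @export
snp_design <- function(id, freq_case = NULL, freq_control = NULL,
                       freq_pop = NULL, rr = NULL) {
  chk_triple <- function(p, what) {
    if (length(p) != 3L) stop(sprintf("%s for %s must have 3 entries", what, id))
    if (any(p < 0)) stop(sprintf("%s for %s has negative entries", what, id))
    if (abs(sum(p) - 1) > 1e-6)
      stop(sprintf("%s for %s sums to %.8g, not 1", what, id, sum(p)))
    p / sum(p)     # renormalize drift below 1e-6
  }
  if (!is.null(freq_case) || !is.null(freq_control)) {
    if (is.null(freq_case) || is.null(freq_control))
      stop(sprintf("SNP %s: conditional mode needs both freq_case and freq_control", id))
    obj <- list(id = id, mode = "conditional",
                freq_case = chk_triple(freq_case, "freq_case"),
                freq_control = chk_triple(freq_control, "freq_control"))
  } else {
    if (is.null(freq_pop) || is.null(rr))
      stop(sprintf("SNP %s: population_rr mode needs freq_pop (or allele frequency) and rr", id))
    if (length(freq_pop) == 1L) freq_pop <- hwe_genotype_freq(freq_pop)
    if (length(rr) != 3L || any(rr <= 0))
      stop(sprintf("SNP %s: rr must be 3 positive values", id))
    obj <- list(id = id, mode = "population_rr",
                freq_pop = chk_triple(freq_pop, "freq_pop"),
                rr = as.numeric(rr))
  }
  structure(obj, class = "snp_design")
}

#' Case/control genotype frequencies from population frequencies and
#' relative risks
#'
#' Under a penetrance model with prevalence \eqn{\rho}, baseline penetrance
#' \eqn{k = \rho / \sum_g f_g r_g} scales the genotype relative risks
#' \eqn{r_g} so that the population risk equals the prevalence. Bayes'
#' rule then gives
#' \deqn{P(g \mid D) = f_g r_g / \sum_h f_h r_h, \qquad
#'       P(g \mid \bar D) = f_g (1 - k r_g) / (1 - \rho).}
#'
#' @param freq_pop population genotype frequency triple.
#' @param rr genotype relative-risk triple (baseline 1).
#' @param prevalence disease prevalence \eqn{\rho} in (0, 1).
#' @return List with `freq_case` and `freq_control`, each summing to 1.
#' @export
conditional_freqs_from_rr <- function(freq_pop, rr, prevalence) {
  stopifnot(length(freq_pop) == 3L, length(rr) == 3L,
            all(rr > 0), prevalence > 0, prevalence < 1)
  denom <- sum(freq_pop * rr)
  k <- prevalence / denom
  if (k * max(rr) > 1 + 1e-12)
    stop(sprintf(paste("impossible penetrance: k * max(rr) = %.4g > 1;",
                       "prevalence %.4g is incompatible with these relative risks"),
                 k * max(rr), prevalence))
  list(freq_case = freq_pop * rr / denom,
       freq_control = freq_pop * (1 - k * rr) / (1 - prevalence))
}

#' Recover genotype relative risks from conditional frequencies
#'
#' Inverse of [conditional_freqs_from_rr()]: the penetrance of genotype g
#' is \eqn{P(D \mid g) = \rho P(g \mid D) / [\rho P(g \mid D) +
#' (1-\rho) P(g \mid \bar D)]}; relative risks are penetrances scaled by
#' the baseline genotype.
#'
#' @param freq_case,freq_control conditional genotype frequency triples.
#' @param prevalence disease prevalence.
#' @return Relative-risk triple with first genotype at 1.
#' @export
rr_from_conditional <- function(freq_case, freq_control, prevalence) {
  pen <- prevalence * freq_case /
    (prevalence * freq_case + (1 - prevalence) * freq_control)
  pen / pen[1L]
}

# coerce any snp_design to conditional mode
.as_conditional <- function(snp, prevalence) {
  if (snp$mode == "conditional") return(snp)
  cf <- conditional_freqs_from_rr(snp$freq_pop, snp$rr, prevalence)
  snp_design(snp$id, freq_case = cf$freq_case, freq_control = cf$freq_control)
}

#' Combine independent SNPs into a multilocus group mass table
#'
#' Forms one risk group per multilocus genotype, with joint masses the
#' products of the per-SNP conditional frequencies. Independence of SNPs
#' within cases and within controls (linkage equilibrium, multiplicative
#' joint effects) is assumed: design-stage inputs are per-marker only, so
#' independence is the only computable default.
#'
#' @param snps list of `snp_design` objects (conditional mode, or
#'   convertible given `prevalence`).
#' @param prevalence prevalence, required if any SNP is in population_rr
#'   mode.
#' @param max_snps refuse more SNPs than this (default 15, i.e. at most
#'   3^15 genotype combinations).
#' @return A `group_mass_table` with up to `3^L` groups, labelled by the
#'   genotype codes joined with `/` in SNP order.
#' @export
combine_independent <- function(snps, prevalence = NULL, max_snps = 15L) {
  L <- length(snps)
  if (L < 1L) stop("at least one SNP is required")
  if (L > max_snps)
    stop(sprintf("%d SNPs would enumerate 3^%d multilocus genotypes; aggregate markers or raise max_snps", L, L))
  snps <- lapply(snps, .as_conditional, prevalence = prevalence)
  mc <- 1; mm <- 1; lab <- ""
  for (s in snps) {
    mc <- as.vector(outer(mc, s$freq_case))
    mm <- as.vector(outer(mm, s$freq_control))
    g <- as.character(0:2)
    lab <- as.vector(outer(lab, g, function(a, b)
      ifelse(a == "", b, paste(a, b, sep = "/"))))
  }
  keep <- !(mc == 0 & mm == 0)
  group_table(mc[keep], mm[keep], lab[keep])
}

#' Design-stage configuration
#'
#' @param prevalence disease prevalence \eqn{\rho} in (0, 1).
#' @param alpha type-I error in (0, 1); default 0.05.
#' @param power target power in (0, 1); default 0.95.
#' @param auc0 null-hypothesis AUC in \[0.5, 1); default 0.5.
#' @param ratio controls per case; default 1.
#' @param two_sided logical; test two-sided instead of the default
#'   one-sided "AUC above `auc0`" alternative.
#' @return An object of class `design_config`.
#' @export
design_config <- function(prevalence, alpha = 0.05, power = 0.95,
                          auc0 = 0.5, ratio = 1, two_sided = FALSE) {
  stopifnot(prevalence > 0, prevalence < 1, alpha > 0, alpha < 1,
            power > 0, power < 1, auc0 >= 0.5, auc0 < 1, ratio > 0)
  structure(list(prevalence = prevalence, alpha = alpha, power = power,
                 auc0 = auc0, ratio = ratio, two_sided = two_sided),
            class = "design_config")
}

#' Estimate the optimal-ROC AUC of a proposed multilocus model
#'
#' Converts population_rr SNPs to conditional form, combines SNPs under
#' independence, orders the multilocus genotypes by likelihood ratio and
#' computes the AUC of the resulting optimal ROC curve, together with the
#' number of distinct risk groups after merging tied likelihood ratios.
#'
#' @param snps list of `snp_design` objects.
#' @param config a `design_config` (prevalence is taken from it).
#' @return List of class `design_result` with `auc`, `roc`
#'   (a `roc_points`), `n_groups`, and the ordered `groups` table.
#' @export
design_auc <- function(snps, config) {
  stopifnot(inherits(config, "design_config"))
  tab <- combine_independent(snps, prevalence = config$prevalence)
  ord <- lr_order(tab)
  structure(list(auc = auc_from_groups(ord), roc = roc_from_groups(ord),
                 n_groups = nrow(ord), groups = ord),
            class = "design_result")
}

#' Variance of the empirical AUC (Hanley-McNeil)
#'
#' \deqn{\mathrm{Var}(\hat A) = \frac{A(1-A) + (n_D-1)(Q_1-A^2) +
#'   (n_{\bar D}-1)(Q_2-A^2)}{n_D\, n_{\bar D}}}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}. This is the
#' standard asymptotic choice for AUC testing; the sample-size routine
#' accepts any function of the same signature via `variance_fn`.
#'
#' @param auc the AUC value.
#' @param n_case,n_control group sizes (each at least 1).
#' @return The variance of the Mann-Whitney AUC estimator.
#' @export
auc_variance <- function(auc, n_case, n_control) {
  stopifnot(auc > 0, auc < 1, n_case >= 1, n_control >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
      (n_control - 1) * (q2 - auc^2)) / (n_case * n_control)
}

#' Power of the asymptotic AUC test at given sample sizes
#'
#' One-sided level-\eqn{\alpha} normal test of \eqn{H_0\!: A = auc_0}
#' against \eqn{H_1\!: A = auc_1 > auc_0}:
#' \deqn{\mathrm{power} = \Phi\!\left(\frac{auc_1 - auc_0 -
#'   z_{1-\alpha}\,sd_0}{sd_1}\right)}
#' with \eqn{sd_i} the standard deviation of the empirical AUC under each
#' hypothesis.
#'
#' @param auc1 alternative AUC.
#' @param auc0 null AUC.
#' @param alpha type-I error.
#' @param n_case,n_control group sizes.
#' @param two_sided if `TRUE`, use \eqn{z_{1-\alpha/2}}.
#' @param variance_fn variance function; default [auc_variance()].
#' @return Power in (0, 1).
#' @export
power_at_n <- function(auc1, auc0, alpha, n_case, n_control,
                       two_sided = FALSE, variance_fn = auc_variance) {
  z <- stats::qnorm(1 - if (two_sided) alpha / 2 else alpha)
  sd0 <- sqrt(variance_fn(auc0, n_case, n_control))
  sd1 <- sqrt(variance_fn(auc1, n_case, n_control))
  stats::pnorm((auc1 - auc0 - z * sd0) / sd1)
}

#' Required sample size for testing an AUC against a threshold
#'
#' Smallest integer number of cases (controls = `ceiling(ratio * cases)`)
#' such that [power_at_n()] reaches the target power, found by doubling
#' followed by bisection.
#'
#' @param auc1 design-stage (alternative) AUC.
#' @param auc0 threshold (null) AUC; must be below `auc1`.
#' @param alpha type-I error; default 0.05.
#' @param power target power; default 0.95.
#' @param ratio controls per case; default 1.
#' @param two_sided logical; default one-sided.
#' @param variance_fn variance function; default [auc_variance()].
#' @return List with `n_cases`, `n_controls`, and the achieved `power`.
#' @export
required_sample_size <- function(auc1, auc0, alpha = 0.05, power = 0.95,
                                 ratio = 1, two_sided = FALSE,
                                 variance_fn = auc_variance) {
  if (auc1 <= auc0)
    stop("auc1 must exceed auc0: the alternative is untestable otherwise")
  pw <- function(n) power_at_n(auc1, auc0, alpha, n,
                               max(1, ceiling(ratio * n)),
                               two_sided, variance_fn)
  hi <- 2L
  while (pw(hi) < power) {
    hi <- hi * 2L
    if (hi > 2^30) stop("sample size search exceeded 2^30 cases")
  }
  lo <- max(1L, hi %/% 2L)
  while (lo < hi - 1L) {             # invariant: pw(hi) >= power > pw(lo)
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= power) hi <- mid else lo <- mid
  }
  n <- if (pw(lo) >= power) lo else hi
  list(n_cases = n, n_controls = as.integer(ceiling(ratio * n)),
       power = pw(n))
}
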