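# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's cumulative-sum code path.

# Pairwise Mann-Whitney AUC over a group mass table: for independent draws
# of one case group and one control group, P(lr_case > lr_ctrl) + ties/2.
oracle_auc_pairs <- function(mass_case, mass_control, lr) {
  auc <- 0
  for (i in seq_along(lr)) {
    for (j in seq_along(lr)) {
      w <- mass_case[i] * mass_control[j]
      if (lr[i] > lr[j]) auc <- auc + w
      else if (lr[i] == lr[j]) auc <- auc + w / 2
    }
  }
  auc
}

# Brute-force empirical AUC by enumerating all case/control pairs.
oracle_auc_scores <- function(case_scores, control_scores) {
  tot <- 0
  for (x in case_scores) for (y in control_scores)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(case_scores) * length(control_scores))
}

# Random valid group mass table (no both-zero groups).
random_group_table <- function(n_groups) {
  repeat {
    mc <- stats::rgamma(n_groups, 1); mm <- stats::rgamma(n_groups, 1)
    if (all(mc + mm > 0)) break
  }
  group_table(mc / sum(mc), mm / sum(mm))
}

# All permutations of 1..n as a matrix (n! rows); small n only.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

# AUC of a group table taken in a fixed group order (no LR sorting):
# trapezoid rule along that order.
auc_in_order <- function(mass_case, mass_control, ord) {
  mc <- mass_case[ord]; mm <- mass_control[ord]
  sum(mm * (cumsum(mc) - mc / 2))
}

# Small deterministic genotype fixture: informative snp plus nulls.
sim_fixture <- function(n_per_group = 500, n_null = 3, seed = 1,
                        rr = c(1, 2, 4), maf = 0.3, missing_rate = 0) {
  cfg <- sim_config(n_per_group, n_per_group,
                    mafs = c(maf, rep(0.25, n_null)),
                    rr = c(list(rr), rep(list(c(1, 1, 1)), n_null)),
                    prevalence = 0.01, missing_rate = missing_rate,
                    snp_ids = c("hit", paste0("null", seq_len(n_null))))
  simulate_case_control(cfg, seed = seed)
}
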