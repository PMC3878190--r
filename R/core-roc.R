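#' Numerical tolerances
#'
#' `mass_tol` is the absolute tolerance used when checking that probability
#' masses sum to one; `lr_tol` is the relative tolerance under which two
#' likelihood ratios are considered exactly tied (and their groups merged).
#'
#' @format A named list with elements `mass_tol` (1e-9) and `lr_tol` (1e-12).
#' @export
riskroc_tol <- list(mass_tol = 1e-9, lr_tol = 1e-12)

#' Construct a group mass table
#'
#' A group mass table holds, for each risk group \eqn{G_j}, its probability
#' mass among cases \eqn{P(G_j \mid D)} and among controls
#' \eqn{P(G_j \mid \bar D)}, together with the likelihood ratio
#' \eqn{LR_j = P(G_j \mid D) / P(G_j \mid \bar D)}. It is the common
#' substrate of theoretical (design-stage) and empirical (build-stage) ROC
#' curves: ordering groups by decreasing LR and accumulating the two margins
#' traces the optimal ROC curve.
#'
#' @param mass_case numeric vector of case masses, summing to 1.
#' @param mass_control numeric vector of control masses, summing to 1.
#' @param label optional character labels; defaults to `g1, g2, ...`.
#' @return A data frame of class `group_mass_table` with columns `label`,
#'   `mass_case`, `mass_control`, `lr`. Groups with zero control mass have
#'   `lr = Inf`.
#' @export
group_table <- function(mass_case, mass_control, label = NULL) {
  if (length(mass_case) == 0L)
    stop("group table must contain at least one risk group")
  if (length(mass_case) != length(mass_control))
    stop("mass_case and mass_control must have equal length")
  if (any(mass_case < 0) || any(mass_control < 0))
    stop("group masses must be non-negative")
  if (any(mass_case == 0 & mass_control == 0))
    stop("a risk group may not have zero mass on both margins")
  tol <- riskroc_tol$mass_tol
  if (abs(sum(mass_case) - 1) > tol)
    stop(sprintf("case masses sum to %.12g, not 1", sum(mass_case)))
  if (abs(sum(mass_control) - 1) > tol)
    stop(sprintf("control masses sum to %.12g, not 1", sum(mass_control)))
  if (is.null(label)) label <- paste0("g", seq_along(mass_case))
  out <- data.frame(label = as.character(label),
                    mass_case = as.numeric(mass_case),
                    mass_control = as.numeric(mass_control),
                    lr = ifelse(mass_control > 0, mass_case / mass_control, Inf),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_mass_table", "data.frame")
  out
}

# TRUE where adjacent (already sorted) lr values are tied within relative
# tolerance; two infinities tie, an infinity never ties a finite value.
.lr_tied <- function(a, b, tol = riskroc_tol$lr_tol) {
  if (is.infinite(a) && is.infinite(b)) return(TRUE)
  if (is.infinite(a) || is.infinite(b)) return(FALSE)
  abs(a - b) <= tol * max(abs(a), abs(b), 1)
}

#' Order risk groups by likelihood ratio
#'
#' Sorts groups by decreasing likelihood ratio (infinite-LR groups first)
#' and merges groups whose LRs are exactly tied (relative tolerance
#' `riskroc_tol$lr_tol`). The optimal ROC curve is defined on LR level
#' sets, so tied groups form a single segment; merging them yields the
#' proper concave curve.
#'
#' @param table a `group_mass_table`.
#' @return A `group_mass_table` sorted by decreasing `lr`, tied groups
#'   merged (masses summed, labels joined with `+`).
#' @export
lr_order <- function(table) {
  stopifnot(inherits(table, "group_mass_table"))
  if (nrow(table) == 0L) stop("no risk groups to order")
  ord <- order(-table$lr)           # Inf sorts first; stable for ties
  tb <- table[ord, , drop = FALSE]
  # merge runs of tied lr
  keep_label <- character(0); mc <- numeric(0); mm <- numeric(0)
  i <- 1L
  while (i <= nrow(tb)) {
    j <- i
    while (j < nrow(tb) && .lr_tied(tb$lr[j], tb$lr[j + 1L])) j <- j + 1L
    keep_label <- c(keep_label, paste(tb$label[i:j], collapse = "+"))
    mc <- c(mc, sum(tb$mass_case[i:j]))
    mm <- c(mm, sum(tb$mass_control[i:j]))
    i <- j + 1L
  }
  group_table(mc, mm, keep_label)
}

#' ROC points from an LR-ordered group mass table
#'
#' Accumulates control mass (false-positive rate) and case mass
#' (true-positive rate) over groups in decreasing-LR order, prepending
#' (0, 0). For an LR-ordered table the resulting curve is concave.
#'
#' @param ordered a `group_mass_table` already ordered by [lr_order()].
#' @return A data frame of class `roc_points` with columns `fpr`, `tpr`.
#' @export
roc_from_groups <- function(ordered) {
  stopifnot(inherits(ordered, "group_mass_table"))
  if (nrow(ordered) > 1L) {
    d <- diff(ordered$lr)
    bad <- !is.na(d) & d > riskroc_tol$lr_tol * pmax(abs(ordered$lr[-1L]), 1)
    if (any(bad))
      stop("groups are not in decreasing likelihood-ratio order; call lr_order() first")
  }
  pts <- data.frame(fpr = c(0, cumsum(ordered$mass_control)),
                    tpr = c(0, cumsum(ordered$mass_case)))
  # guard against accumulation drift at the endpoint
  pts$fpr[nrow(pts)] <- 1
  pts$tpr[nrow(pts)] <- 1
  class(pts) <- c("roc_points", "data.frame")
  pts
}

#' Area under the optimal ROC curve of a group mass table
#'
#' Orders the groups by likelihood ratio and computes the area under the
#' resulting piecewise-linear ROC by the trapezoid rule,
#' \deqn{AUC = \sum_j P(G_j \mid \bar D)\,\bigl(TPR_{j-1} + P(G_j \mid D)/2\bigr),}
#' which equals \eqn{P(LR_{case} > LR_{control}) + \tfrac12 P(LR_{case} =
#' LR_{control})} for independent draws from the two margins.
#'
#' @param table a `group_mass_table` (need not be pre-ordered).
#' @return AUC in \[0.5, 1\] (LR ordering never falls below chance).
#' @export
auc_from_groups <- function(table) {
  ord <- lr_order(table)
  tpr_before <- c(0, cumsum(ord$mass_case))[seq_len(nrow(ord))]
  sum(ord$mass_control * (tpr_before + ord$mass_case / 2))
}

#' Empirical AUC by the Mann-Whitney estimator
#'
#' Tie-corrected two-sample rank estimator:
#' \eqn{(\#\{case > control\} + \tfrac12 \#\{case = control\}) /
#' (n_{case} n_{control})}, computed via midranks.
#'
#' @param case_scores numeric scores of cases.
#' @param control_scores numeric scores of controls.
#' @return AUC in \[0, 1\].
#' @export
empirical_auc <- function(case_scores, control_scores) {
  n1 <- length(case_scores); n0 <- length(control_scores)
  if (n1 == 0L || n0 == 0L)
    stop("both score vectors must be non-empty")
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write ROC points as tab-separated text
#'
#' @param roc a `roc_points` data frame.
#' @param path output file path; a header line `fpr\ttpr` is written first.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(as.data.frame(roc)[, c("fpr", "tpr")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot one or more ROC curves
#'
#' @param roc_sets a named list of `roc_points` objects (names become the
#'   legend) or a single `roc_points`.
#' @param path output image path ending in `.png` or `.svg`; `NULL` plots
#'   to the active device.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plot_roc <- function(roc_sets, path = NULL, main = "ROC curve") {
  if (inherits(roc_sets, "roc_points")) roc_sets <- list(ROC = roc_sets)
  if (!is.null(path)) {
    if (grepl("\\.svg$", path)) grDevices::svg(path, width = 6, height = 6)
    else grDevices::png(path, width = 720, height = 720, res = 120)
    on.exit(grDevices::dev.off())
  }
  cols <- seq_along(roc_sets) + 1L
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
                 ylab = "True positive rate", main = main, asp = 1)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  for (i in seq_along(roc_sets))
    graphics::lines(roc_sets[[i]]$fpr, roc_sets[[i]]$tpr, col = cols[i], lwd = 2)
  if (length(roc_sets) > 1L || !is.null(names(roc_sets)))
    graphics::legend("bottomright", legend = names(roc_sets), col = cols,
                     lwd = 2, bty = "n")
  invisible(path)
}
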