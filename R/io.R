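#' Read a design-stage specification file
#'
#' The specification is JSON with top-level keys `prevalence`, and
#' optionally `alpha`, `power`, `auc0`, `ratio`, `two_sided`, plus a
#' `snps` array. Each SNP entry carries `id`, `mode`
#' (`"conditional"` or `"population_rr"`), and either `freq_case` +
#' `freq_control` triples, or `freq_pop` (triple or single allele
#' frequency, expanded under HWE) + `rr` triple. Probability triples off 1
#' by at most 1e-6 are renormalized with a warning; larger deviations are
#' rejected.
#'
#' @param path path to the JSON specification.
#' @return List with `snps` (list of `snp_design`) and `config`
#'   (`design_config`).
#' @export
read_design_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("design spec not found: %s", path))
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("prevalence", "snps"))
    if (is.null(spec[[key]]))
      stop(sprintf("design spec %s: missing required key '%s'", path, key))
  cfg <- design_config(prevalence = spec$prevalence,
                       alpha = spec$alpha %||% 0.05,
                       power = spec$power %||% 0.95,
                       auc0 = spec$auc0 %||% 0.5,
                       ratio = spec$ratio %||% 1,
                       two_sided = isTRUE(spec$two_sided))
  snps_raw <- spec$snps
  if (is.data.frame(snps_raw))
    snps_raw <- lapply(seq_len(nrow(snps_raw)), function(i)
      lapply(snps_raw, function(col) unlist(col[i])))
  snps <- lapply(seq_along(snps_raw), function(i) {
    s <- snps_raw[[i]]
    if (is.null(s$id)) stop(sprintf("design spec %s: snps[%d] lacks 'id'", path, i))
    mode <- s$mode %||%
      if (!is.null(s$freq_case)) "conditional" else "population_rr"
    warn_renorm <- function(p, what) {
      if (!is.null(p) && length(p) == 3L && abs(sum(p) - 1) > 1e-9 &&
          abs(sum(p) - 1) <= 1e-6)
        warning(sprintf("%s of SNP %s renormalized (sum %.8f)", what, s$id, sum(p)),
                call. = FALSE)
      p
    }
    out <- tryCatch(
      if (mode == "conditional")
        snp_design(s$id,
                   freq_case = warn_renorm(unlist(s$freq_case), "freq_case"),
                   freq_control = warn_renorm(unlist(s$freq_control), "freq_control"))
      else
        snp_design(s$id,
                   freq_pop = warn_renorm(unlist(s$freq_pop %||% s$maf), "freq_pop"),
                   rr = unlist(s$rr)),
      error = function(e)
        stop(sprintf("design spec %s, snps[%d] (%s): %s",
                     path, i, s$id, conditionMessage(e)), call. = FALSE))
    out
  })
  list(snps = snps, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# detect file dialect from the header line
.detect_dialect <- function(header) {
  if (grepl("^FID[ \t]+IID[ \t]+PAT[ \t]+MAT[ \t]+SEX[ \t]+PHENOTYPE", header))
    "plink_raw"
  else "delimited"
}

#' Read a case-control genotype table
#'
#' Two dialects are supported. `delimited`: comma- or tab-separated
#' (auto-detected), header row, a `phenotype` column (case-insensitive)
#' coded 0/1, an optional `id` column, and remaining columns genotypes in
#' `{0, 1, 2}` with `NA`, `-9` or empty cells as missing. `plink_raw`:
#' whitespace-separated PLINK recode-A export (`FID IID PAT MAT SEX
#' PHENOTYPE` followed by per-SNP dosage columns); PHENOTYPE 1/2 is
#' remapped to control/case and samples with phenotype -9 are dropped
#' with a warning.
#'
#' @param path input file.
#' @param dialect `"auto"` (default), `"delimited"` or `"plink_raw"`.
#' @return A `genotype_dataset`.
#' @export
read_genotypes <- function(path, dialect = c("auto", "delimited", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("genotype file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (dialect == "auto") dialect <- .detect_dialect(header)
  if (dialect == "plink_raw") {
    df <- utils::read.table(path, header = TRUE, na.strings = c("NA", "-9"),
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(df)))
      stop(sprintf("%s: not a PLINK .raw file (missing %s)", path,
                   paste(setdiff(need, names(df)), collapse = ", ")))
    phen_raw <- df$PHENOTYPE
    drop <- is.na(phen_raw) | !(phen_raw %in% c(1, 2))
    if (any(drop)) {
      warning(sprintf("%s: dropped %d sample(s) with missing/unknown phenotype",
                      path, sum(drop)), call. = FALSE)
      df <- df[!drop, , drop = FALSE]
      phen_raw <- phen_raw[!drop]
    }
    phen <- as.integer(phen_raw == 2)            # PLINK 1 = control, 2 = case
    ids <- paste(df$FID, df$IID, sep = "_")
    gcols <- setdiff(names(df), need)
    gm <- as.matrix(df[, gcols, drop = FALSE])
  } else {
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            na.strings = c("NA", "-9", ""),
                            check.names = FALSE, stringsAsFactors = FALSE)
    pcol <- which(tolower(names(df)) == "phenotype")
    if (length(pcol) != 1L)
      stop(sprintf("%s: exactly one 'phenotype' column is required", path))
    icol <- which(tolower(names(df)) == "id")
    phen_raw <- df[[pcol]]
    if (!all(phen_raw %in% c(0, 1)))
      stop(sprintf("%s: phenotype must be 0/1 (row %d has '%s')", path,
                   which(!(phen_raw %in% c(0, 1)))[1L],
                   phen_raw[which(!(phen_raw %in% c(0, 1)))[1L]]))
    phen <- as.integer(phen_raw)
    ids <- if (length(icol)) as.character(df[[icol[1L]]]) else NULL
    gcols <- setdiff(seq_along(df), c(pcol, icol))
    gm <- as.matrix(df[, gcols, drop = FALSE])
  }
  bad <- which(!(gm %in% c(0, 1, 2) | is.na(gm)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(gm))
    stop(sprintf("%s: invalid genotype code '%s' at data row %d, column %s",
                 path, gm[bad[1L]], rc[1L], colnames(gm)[rc[2L]]))
  }
  storage.mode(gm) <- "integer"
  genotype_dataset(gm, phen, sample_ids = ids, snp_ids = colnames(gm))
}

#' Export a fitted risk-group tree as Graphviz DOT
#'
#' Nodes are labelled `path | cases/controls | LR`. Levels correspond to
#' selection steps; an edge links each group to the previous-level
#' group(s) it derives from (a merged group may have several parents).
#'
#' @param fit a `froc_fit`.
#' @param path output `.dot` file; `NULL` returns the DOT text.
#' @return The DOT source, invisibly when written to a file.
#' @export
write_tree_dot <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "froc_fit"))
  fmt_lr <- function(lr) if (is.infinite(lr)) "Inf" else sprintf("%.3f", lr)
  lines <- c("digraph risk_groups {",
             "  rankdir=TB;",
             "  node [shape=box, fontname=\"Helvetica\"];",
             sprintf("  root [label=\"all samples | %d/%d | LR 1.000\"];",
                     fit$n_case, fit$n_control))
  node_name <- function(depth, id) sprintf("n%d_%d", depth, id)
  for (depth in seq_along(fit$levels)) {
    for (lf in fit$levels[[depth]]) {
      pth <- .leaf_path(lf, fit$selected_snps[seq_len(depth)])
      plab <- paste(vapply(names(pth), function(s)
        sprintf("%s=%s", s, paste(pth[[s]], collapse = ",")), character(1)),
        collapse = "; ")
      lines <- c(lines, sprintf("  %s [label=\"%s | %d/%d | LR %s\"];",
                                node_name(depth, lf$id), plab,
                                lf$n_case, lf$n_control, fmt_lr(lf$lr)))
      parents <- if (depth == 1L) "root"
      else vapply(lf$parents, function(p) node_name(depth - 1L, p), character(1))
      lines <- c(lines, sprintf("  %s -> %s;", parents, node_name(depth, lf$id)))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# empirical roc_points from per-sample scores
.roc_from_scores <- function(scores, phenotype) {
  nD <- sum(phenotype == 1L); nDbar <- sum(phenotype == 0L)
  lev <- sort(unique(scores), decreasing = TRUE)
  mc <- vapply(lev, function(v) sum(scores == v & phenotype == 1L), numeric(1)) / nD
  mm <- vapply(lev, function(v) sum(scores == v & phenotype == 0L), numeric(1)) / nDbar
  keep <- !(mc == 0 & mm == 0)
  pts <- data.frame(fpr = c(0, cumsum(mm[keep])), tpr = c(0, cumsum(mc[keep])))
  class(pts) <- c("roc_points", "data.frame")
  pts
}

#' Write a run report and associated artifacts
#'
#' Emits a JSON report (`report.json`), a TSV of ROC points per curve
#' (`roc_<name>.tsv`), a PNG overlay plot of all curves (`roc.png`), and,
#' when a fitted tree is supplied, the Graphviz source (`tree.dot`). File
#' contents are deterministic for identical inputs: no timestamps are
#' embedded.
#'
#' @param report named list of results (serialized as JSON).
#' @param roc_sets named list of `roc_points`, possibly empty.
#' @param tree a `froc_fit` or `NULL`.
#' @param out_dir output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(report, roc_sets = list(), tree = NULL, out_dir = ".") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory %s", out_dir))
  files <- character(0)
  rp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "string")
  files <- c(files, rp)
  for (nm in names(roc_sets)) {
    fp <- file.path(out_dir, sprintf("roc_%s.tsv", nm))
    write_roc_tsv(roc_sets[[nm]], fp)
    files <- c(files, fp)
  }
  if (length(roc_sets)) {
    pp <- file.path(out_dir, "roc.png")
    plot_roc(roc_sets, pp)
    files <- c(files, pp)
  }
  if (!is.null(tree)) {
    tp <- file.path(out_dir, "tree.dot")
    write_tree_dot(tree, tp)
    files <- c(files, tp)
  }
  invisible(files)
}

#' Read back a JSON run report
#'
#' @param path path to a `report.json` written by [write_outputs()].
#' @return The report as a list.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
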