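#' Extract a rat-level expression matrix from a presence table
#'
#' Rat-level abundances (the per-rat mean AUC) as a proteins x samples
#' matrix. By default cells where the protein was not present in the rat are
#' `NA`, so each analysis branch can apply its own missing-value rule; with
#' `undetected = "one"` the triage convention (assigned AUC 1) is kept.
#'
#' @param presence a `presence_table` from [call_presence()].
#' @param undetected `"missing"` (default) or `"one"`.
#' @return Numeric matrix with a `stage` attribute `"raw"`.
#' @export
as_expression_matrix <- function(presence, undetected = c("missing", "one")) {
  undetected <- match.arg(undetected)
  m <- presence$rat_mean
  if (undetected == "missing") m[!presence$detected] <- NA_real_
  attr(m, "stage") <- "raw"
  m
}

#' Filter proteins by group-wise presence fraction
#'
#' Keeps proteins observed in at least `fraction` of the samples of at least
#' one comparison group (default grouping Sham versus Irradiated). The
#' group-wise rule deliberately retains group-specific proteins: a protein
#' fully observed in Sham but absent from every irradiated rat passes.
#'
#' @param matrix proteins x samples matrix with `NA` for missing.
#' @param design a [study_design()].
#' @param fraction required presence fraction in (0, 1].
#' @param groups character vector of group labels (cohorts or
#'   `"Irradiated"`).
#' @return The filtered matrix.
#' @export
filter_presence_fraction <- function(matrix, design, fraction = 0.7,
                                     groups = c("Sham", "Irradiated")) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  keep <- rep(FALSE, nrow(matrix))
  for (g in groups) {
    sam <- intersect(cohort_samples(design, g), colnames(matrix))
    if (!length(sam)) next
    frac <- rowMeans(!is.na(matrix[, sam, drop = FALSE]))
    keep <- keep | frac >= fraction
  }
  out <- matrix[keep, , drop = FALSE]
  attr(out, "stage") <- attr(matrix, "stage")
  out
}

#' Impute missing values by a fraction of the per-protein minimum
#'
#' Each missing cell of a protein is replaced by `fraction` (default 1/5) of
#' that protein's minimum observed positive value.
#'
#' @param matrix proteins x samples matrix with `NA` for missing.
#' @param fraction multiplier of the per-protein observed minimum.
#' @return Matrix without missing values, `stage` attribute `"imputed"`.
#' @export
impute_min_fraction <- function(matrix, fraction = 1 / 5) {
  out <- matrix
  for (k in seq_len(nrow(out))) {
    row <- out[k, ]
    if (!anyNA(row)) next
    obs <- row[!is.na(row) & row > 0]
    if (!length(obs))
      stop("protein entirely missing: ", rownames(out)[k])
    out[k, is.na(row)] <- fraction * min(obs)
  }
  attr(out, "stage") <- "imputed"
  out
}

#' Median normalization across samples
#'
#' Divides each sample by its median and (by default) multiplies back by the
#' grand median of sample medians so magnitudes stay on the AUC scale. After
#' the transform every sample median is equal.
#'
#' @param matrix imputed proteins x samples matrix (no missing values).
#' @param rescale multiply back by the grand median (default `TRUE`); with
#'   `FALSE` the sample medians all become 1.
#' @return Normalized matrix, `stage` attribute `"normalized"`.
#' @export
normalize_median <- function(matrix, rescale = TRUE) {
  med <- apply(matrix, 2, stats::median)
  if (any(med == 0)) stop("sample median is 0")
  grand <- if (rescale) stats::median(med) else 1
  out <- sweep(matrix, 2, med, "/") * grand
  attr(out, "stage") <- "normalized"
  out
}

#' Pareto scaling
#'
#' Per protein (variable): subtract the mean and divide by the square root
#' of the n-1 sample standard deviation. Constant proteins are mapped to all
#' zero with a warning.
#'
#' @param matrix imputed proteins x samples matrix.
#' @return Scaled matrix, `stage` attribute `"scaled"`.
#' @export
pareto_scale <- function(matrix) {
  mu <- rowMeans(matrix)
  sd <- apply(matrix, 1, stats::sd)
  const <- sd == 0
  if (any(const))
    warning(sum(const), " constant protein(s) mapped to zero")
  denom <- ifelse(const, 1, sqrt(sd))
  out <- (matrix - mu) / denom
  attr(out, "stage") <- "scaled"
  out
}

#' Principal component analysis of samples
#'
#' Samples are the observations (columns of the protein matrix become rows),
#' mean-centered, no variance scaling -- run this on a Pareto-scaled matrix.
#' Deterministic sign convention: in each component the loading entry of
#' largest magnitude is positive.
#'
#' @param matrix proteins x samples matrix (typically scaled).
#' @param n_components number of components (default 3); must not exceed
#'   `min(n_samples - 1, n_proteins)`.
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `loadings` (proteins x components), `variance_fraction`.
#' @export
pca <- function(matrix, n_components = 3) {
  x <- t(matrix)
  maxk <- min(nrow(x) - 1, ncol(x))
  if (n_components > maxk)
    stop("n_components exceeds min(samples - 1, proteins) = ", maxk)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  load <- pr$rotation[, k, drop = FALSE]
  scores <- pr$x[, k, drop = FALSE]
  for (j in k) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = load,
                 variance_fraction = vf[k]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores),
      "components; variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Welch tests with fold changes and volcano classification
#'
#' Fold change is the ratio of group means on the supplied (normalized,
#' unscaled) matrix; the two-sided t-test runs on the Pareto-scaled values
#' (the t statistic is invariant to the per-variable affine transform, so
#' this equals the test on the normalized scale). P-values are
#' Benjamini-Hochberg adjusted over all tested proteins. The volcano flag
#' requires adjusted p below `fdr` and fold change beyond `fc_cutoff` in
#' either direction.
#'
#' @param matrix normalized, unscaled proteins x samples matrix.
#' @param design a [study_design()].
#' @param groupA,groupB group labels (cohorts or `"Irradiated"`), each with
#'   at least 2 samples.
#' @param fdr adjusted-p cutoff for the volcano flag (default 0.1).
#' @param fc_cutoff fold-change cutoff for the volcano flag (default 1.5).
#' @param equal_var use the pooled-variance t-test instead of Welch.
#' @return A `de_result` data frame: `protein_id`, `fc`, `log2_fc`,
#'   `t_stat`, `raw_p`, `adj_p`, `volcano_flag`.
#' @export
ttest_fc <- function(matrix, design, groupA = "Sham", groupB = "Irradiated",
                     fdr = 0.1, fc_cutoff = 1.5, equal_var = FALSE) {
  sa <- intersect(cohort_samples(design, groupA), colnames(matrix))
  sb <- intersect(cohort_samples(design, groupB), colnames(matrix))
  if (length(intersect(sa, sb))) stop("groups overlap")
  if (length(sa) < 2 || length(sb) < 2) stop("each group needs n >= 2")
  scaled <- suppressWarnings(pareto_scale(matrix))
  fc <- rowMeans(matrix[, sb, drop = FALSE]) /
    rowMeans(matrix[, sa, drop = FALSE])
  n <- nrow(matrix)
  tt <- numeric(n); pp <- numeric(n)
  for (k in seq_len(n)) {
    a <- scaled[k, sa]; b <- scaled[k, sb]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt[k] <- 0; pp[k] <- 1
    } else {
      res <- stats::t.test(b, a, var.equal = equal_var)
      tt[k] <- unname(res$statistic); pp[k] <- res$p.value
    }
  }
  adj <- bh_adjust(pp)
  structure(data.frame(protein_id = rownames(matrix), fc = fc,
                       log2_fc = log2(fc), t_stat = tt, raw_p = pp,
                       adj_p = adj,
                       volcano_flag = adj < fdr &
                         (fc >= fc_cutoff | fc <= 1 / fc_cutoff),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", nrow(x), "proteins;", sum(x$volcano_flag),
      "volcano-flagged\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (monotone, clipped to \[0, 1\]), in the input
#'   order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Select the top-k proteins by test p-value
#'
#' Ranks by smallest raw p, breaking ties by larger absolute log2 fold
#' change, then lexicographic id. When a matrix is supplied, also emits a
#' hierarchical-clustering leaf order (Euclidean distance, complete linkage)
#' over the selected proteins for heatmap display.
#'
#' @param results a `de_result`.
#' @param k how many proteins (default 50); if larger than the table, all
#'   are returned with a warning.
#' @param matrix optional proteins x samples matrix used for the leaf order.
#' @return A list: `ids` (ordered by the ranking) and `leaf_order` (ids in
#'   dendrogram leaf order, or `NULL`).
#' @export
top_k_by_test <- function(results, k = 50, matrix = NULL) {
  if (nrow(results) == 0) stop("empty results")
  if (k > nrow(results)) {
    warning("k exceeds number of proteins; returning all")
    k <- nrow(results)
  }
  ord <- order(results$raw_p, -abs(results$log2_fc), results$protein_id)
  ids <- results$protein_id[ord][seq_len(k)]
  leaf <- NULL
  if (!is.null(matrix) && k >= 2) {
    sub <- matrix[ids, , drop = FALSE]
    hc <- stats::hclust(stats::dist(sub, method = "euclidean"),
                        method = "complete")
    leaf <- ids[hc$order]
  }
  list(ids = ids, leaf_order = leaf)
}

#' Join differential-expression results onto an annotation table
#'
#' Inner join on protein id; per (main_pathway, sub_pathway) category:
#' member count, median log2 fold change, and the count of members with
#' adjusted p below `sig_threshold`. Unannotated proteins are reported
#' separately, not silently dropped.
#'
#' @param results a `de_result`.
#' @param annotation an `annotation_table` from [read_annotation()].
#' @param sig_threshold adjusted-p threshold for the significance count.
#' @return A list: `annotated` (joined rows), `summary` (per-category
#'   summary) and `unannotated` (ids without annotation).
#' @export
annotate_overlap <- function(results, annotation, sig_threshold = 0.1) {
  hit <- results$protein_id %in% annotation$id
  if (!any(hit)) {
    warning("no proteins matched the annotation")
    return(list(annotated = results[0, ],
                summary = data.frame(), unannotated = results$protein_id))
  }
  ann <- merge(results[hit, , drop = FALSE], annotation,
               by.x = "protein_id", by.y = "id", sort = TRUE)
  key <- interaction(ann$main_pathway, ann$sub_pathway, drop = TRUE)
  summ <- do.call(rbind, lapply(levels(key), function(lv) {
    rows <- ann[key == lv, , drop = FALSE]
    data.frame(main_pathway = rows$main_pathway[1],
               sub_pathway = rows$sub_pathway[1],
               n = nrow(rows),
               median_log2_fc = stats::median(rows$log2_fc),
               n_significant = sum(rows$adj_p < sig_threshold),
               stringsAsFactors = FALSE)
  }))
  list(annotated = ann, summary = summ,
       unannotated = results$protein_id[!hit])
}

#' Basic volcano plot
#'
#' Adjusted p (as -log10) against log2 fold change, flagged proteins
#' highlighted.
#'
#' @param results a `de_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_volcano <- function(results, ...) {
  graphics::plot(results$log2_fc, -log10(results$adj_p),
                 xlab = "log2 fold change", ylab = "-log10 adjusted p",
                 pch = 20, col = ifelse(results$volcano_flag, "red", "grey40"),
                 ...)
  invisible(NULL)
}
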