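#' Call per-rat protein presence from technical replicates
#'
#' A protein is "present" in a rat when it was quantified in at least
#' `tech_fraction` of that rat's technical replicates, implemented as
#' `count >= ceiling(tech_fraction * n_reps)` (two of three at the default
#' 2/3 with triplicate injections). The per-rat abundance is the arithmetic
#' mean AUC over the quantified replicates; a rat in which the protein is not
#' present is assigned the constant AUC 1.
#'
#' @param matrix a [quant_matrix()].
#' @param tech_fraction required fraction of technical replicates, in (0, 1].
#' @return A `presence_table`: list with logical matrix `detected` and
#'   numeric matrix `rat_mean` (proteins x samples).
#' @export
call_presence <- function(matrix, tech_fraction = 2 / 3) {
  stopifnot(inherits(matrix, "quant_matrix"))
  if (tech_fraction <= 0 || tech_fraction > 1)
    stop("tech_fraction must be in (0, 1]")
  samples <- unique(matrix$sample)
  np <- nrow(matrix$values)
  detected <- matrix(FALSE, np, length(samples),
                     dimnames = list(rownames(matrix$values), samples))
  rat_mean <- matrix(1, np, length(samples),
                     dimnames = list(rownames(matrix$values), samples))
  for (s in samples) {
    cols <- which(matrix$sample == s)
    sub <- matrix$values[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    need <- ceiling(tech_fraction * length(cols))
    det <- n_obs >= need
    m <- rowMeans(sub, na.rm = TRUE)
    detected[, s] <- det
    rat_mean[det, s] <- m[det]
  }
  structure(list(detected = detected, rat_mean = rat_mean),
            class = "presence_table")
}

#' @export
print.presence_table <- function(x, ...) {
  cat("presence_table:", nrow(x$detected), "proteins x", ncol(x$detected),
      "samples;", round(100 * mean(x$detected), 1), "% detected\n")
  invisible(x)
}

#' Summarize per-rat abundances by cohort
#'
#' For each protein and cohort (plus the pooled "Irradiated" grouping =
#' Functional + Impaired): the number of rats in which the protein is
#' present, a presence flag requiring a strict majority of the cohort's
#' rats, the cohort mean of the per-rat AUC (rats without the protein
#' contribute the assigned value 1), and the standard error of that mean
#' (n-1 sample standard deviation / sqrt(n)). A protein is excluded for a
#' cohort when it is not present in a majority of rats, when the SEM exceeds
#' the mean, or when the cohort has a single rat (SEM undefined).
#'
#' @param presence a `presence_table` from [call_presence()].
#' @param design a [study_design()].
#' @return A `cohort_summary`: list of proteins x group matrices
#'   `n_detected`, `mean_auc`, `sem_auc`, logical `present` and `excluded`,
#'   character `reason`, plus the `rat_mean` matrix and `design` carried
#'   along for downstream statistics. Groups are Sham, Functional, Impaired,
#'   Irradiated.
#' @export
summarize_cohorts <- function(presence, design) {
  stopifnot(inherits(presence, "presence_table"),
            inherits(design, "study_design"))
  if (!all(design$sample_id %in% colnames(presence$rat_mean)))
    stop("presence table does not cover all design samples")
  groups <- c(COHORT_LEVELS, "Irradiated")
  np <- nrow(presence$rat_mean)
  ids <- rownames(presence$rat_mean)
  mk <- function(x) matrix(x, np, length(groups),
                           dimnames = list(ids, groups))
  n_det <- mk(0); mean_a <- mk(NA_real_); sem_a <- mk(NA_real_)
  present <- mk(FALSE); excluded <- mk(TRUE); reason <- mk("")
  for (g in groups) {
    sam <- cohort_samples(design, g)
    n <- length(sam)
    if (n == 0) next
    det <- presence$detected[, sam, drop = FALSE]
    vals <- presence$rat_mean[, sam, drop = FALSE]
    n_det[, g] <- rowSums(det)
    mean_a[, g] <- rowMeans(vals)
    if (n > 1) {
      sem_a[, g] <- apply(vals, 1, stats::sd) / sqrt(n)
    }
    present[, g] <- n_det[, g] > n / 2
    if (n == 1) {
      excluded[, g] <- TRUE
      reason[, g] <- "sem_undefined"
    } else {
      sem_hit <- sem_a[, g] > mean_a[, g]
      excluded[, g] <- !present[, g] | sem_hit
      reason[!present[, g], g] <- "not_majority"
      reason[present[, g] & sem_hit, g] <- "sem_exceeds_mean"
    }
  }
  structure(list(n_detected = n_det, mean_auc = mean_a, sem_auc = sem_a,
                 present = present, excluded = excluded, reason = reason,
                 rat_mean = presence$rat_mean, detected = presence$detected,
                 design = design),
            class = "cohort_summary")
}

#' Classify proteins by cohort presence pattern and fold change
#'
#' Venn class from the per-cohort presence/exclusion pattern:
#' `common` (all three cohorts), `sr_exposure` (both irradiated cohorts but
#' not Sham), `sham_only`, `impaired_only`, `functional_only`, `other`
#' (every remaining non-empty pattern). Proteins qualifying in no cohort are
#' excluded. An `activated` flag marks the umbrella pattern "absent in Sham,
#' present in at least one irradiated cohort" (the union of sr_exposure,
#' impaired_only and functional_only).
#'
#' Fold change versus Sham uses the pooled irradiated rats (Functional +
#' Impaired; per-cohort fold changes are also emitted): `up` at
#' `fc >= fc_threshold`, `down` at `fc <= 1/fc_threshold`, `unchanged`
#' between, `undefined` when the Sham summary is excluded. A two-sided
#' Wilcoxon rank-sum p-value compares Sham versus pooled irradiated per-rat
#' abundances.
#'
#' @param summaries a `cohort_summary` from [summarize_cohorts()].
#' @param fc_threshold fold-change cutoff (default 1.5).
#' @return A `triage_table` data frame, one row per protein: `protein_id`,
#'   `venn_class`, `activated`, `fc_vs_sham`, `fc_functional`, `fc_impaired`,
#'   `fc_class`, `wilcoxon_p`, `excluded`, `reason`.
#' @export
classify_proteins <- function(summaries, fc_threshold = 1.5) {
  stopifnot(inherits(summaries, "cohort_summary"))
  if (!all(COHORT_LEVELS %in% colnames(summaries$present)))
    stop("missing cohort summary")
  ids <- rownames(summaries$present)
  # a cohort "qualifies" when the protein survives its triage there
  q <- !summaries$excluded[, COHORT_LEVELS, drop = FALSE]
  s <- q[, "Sham"]; f <- q[, "Functional"]; i <- q[, "Impaired"]
  venn <- rep("other", length(ids))
  venn[s & f & i] <- "common"
  venn[!s & f & i] <- "sr_exposure"
  venn[s & !f & !i] <- "sham_only"
  venn[!s & !f & i] <- "impaired_only"
  venn[!s & f & !i] <- "functional_only"
  excluded <- !s & !f & !i
  venn[excluded] <- NA_character_
  activated <- !s & (f | i)

  sham_mean <- summaries$mean_auc[, "Sham"]
  irr_mean <- summaries$mean_auc[, "Irradiated"]
  fc <- irr_mean / sham_mean
  fc_class <- rep("unchanged", length(ids))
  fc_class[fc >= fc_threshold] <- paste0("up_", fc_threshold)
  fc_class[fc <= 1 / fc_threshold] <- paste0("down_", fc_threshold)
  sham_bad <- summaries$excluded[, "Sham"]
  fc_class[sham_bad] <- "undefined"
  fc[sham_bad] <- NA_real_

  sham_sam <- cohort_samples(summaries$design, "Sham")
  irr_sam <- cohort_samples(summaries$design, "Irradiated")
  wp <- rep(NA_real_, length(ids))
  if (length(sham_sam) && length(irr_sam)) {
    for (k in seq_along(ids)) {
      wp[k] <- wilcoxon_rank_sum(summaries$rat_mean[k, sham_sam],
                                 summaries$rat_mean[k, irr_sam])
    }
  }
  reason <- rep("", length(ids))
  reason[excluded] <- "excluded_in_all_cohorts"
  structure(data.frame(protein_id = ids, venn_class = venn,
                       activated = activated, fc_vs_sham = fc,
                       fc_functional = summaries$mean_auc[, "Functional"] /
                         sham_mean,
                       fc_impaired = summaries$mean_auc[, "Impaired"] /
                         sham_mean,
                       fc_class = fc_class, wilcoxon_p = wp,
                       excluded = excluded, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("triage_table", "data.frame"))
}

#' @export
print.triage_table <- function(x, ...) {
  cat("triage_table:", nrow(x), "proteins\n")
  print(table(venn_class = x$venn_class, useNA = "ifany"))
  print(table(fc_class = x$fc_class))
  invisible(x)
}

#' Run the full replicate-based triage
#'
#' Convenience wrapper: [call_presence()] then [summarize_cohorts()] then
#' [classify_proteins()].
#'
#' @inheritParams call_presence
#' @inheritParams classify_proteins
#' @param design a [study_design()].
#' @return A `triage_table`.
#' @export
triage_proteins <- function(matrix, design, tech_fraction = 2 / 3,
                            fc_threshold = 1.5) {
  classify_proteins(summarize_cohorts(call_presence(matrix, tech_fraction),
                                      design),
                    fc_threshold = fc_threshold)
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum p-value
#'
#' Exact enumeration of the rank-sum distribution when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. Thin wrapper over
#' [stats::wilcox.test()].
#'
#' @param groupA,groupB numeric vectors, each non-empty.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return Two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(groupA, groupB, mode = c("auto", "exact",
                                                       "normal")) {
  mode <- match.arg(mode)
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("empty group")
  ties <- anyDuplicated(c(groupA, groupB)) > 0
  exact <- switch(mode,
                  auto = (length(groupA) + length(groupB) <= 12) && !ties,
                  exact = TRUE,
                  normal = FALSE)
  res <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  min(1, res$p.value)
}
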