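#' k-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the average of that column over the k
#' proteins nearest to the target protein by Euclidean distance computed on
#' mutually observed columns (distance rescaled to the full column count, as
#' in the conventional kNN imputers). Only neighbours observed in the target
#' column contribute. Rows missing more than `row_cap` of their entries are
#' imputed by their row mean instead, with a warning. Ties in distance break
#' deterministically by row order (protein id).
#'
#' @param matrix proteins x samples matrix with `NA` for missing.
#' @param k number of neighbours (default 10).
#' @param row_cap maximum missing fraction for kNN treatment (default 0.5).
#' @return Matrix without missing values, `stage` attribute `"imputed"`.
#' @export
knn_impute <- function(matrix, k = 10, row_cap = 0.5) {
  out <- matrix
  miss_frac <- rowMeans(is.na(out))
  usable <- which(miss_frac <= row_cap)
  if (k >= length(usable))
    stop("k must be smaller than the number of complete-enough rows")
  over <- which(miss_frac > row_cap & miss_frac < 1)
  if (length(over)) {
    warning(length(over), " row(s) above the missingness cap imputed by ",
            "row mean")
    for (r in over) out[r, is.na(out[r, ])] <- mean(out[r, ], na.rm = TRUE)
  }
  if (any(miss_frac == 1)) stop("row entirely missing")
  targets <- which(rowSums(is.na(matrix)) > 0 & miss_frac <= row_cap)
  nc <- ncol(matrix)
  cand <- matrix[usable, , drop = FALSE]
  for (r in targets) {
    x <- matrix[r, ]
    diffs <- sweep(cand, 2, x)              # candidates minus target
    shared <- rowSums(!is.na(diffs))
    d2 <- rowSums(diffs^2, na.rm = TRUE) * nc / pmax(shared, 1)
    d2[shared == 0] <- Inf
    d2[usable == r] <- Inf                  # never its own neighbour
    ord <- order(d2, seq_along(d2))
    for (j in which(is.na(x))) {
      have <- ord[!is.na(cand[ord, j]) & is.finite(d2[ord])]
      nb <- have[seq_len(min(k, length(have)))]
      if (!length(nb)) {
        out[r, j] <- mean(x, na.rm = TRUE)
      } else {
        out[r, j] <- mean(cand[nb, j])
      }
    }
  }
  attr(out, "stage") <- "imputed"
  out
}

#' log2(x + 1) transform with optional many-to-many id mapping
#'
#' Values become `log2(value + 1)`. With an id map (columns `protein_id`,
#' `gene_id`), rows mapping to the same gene are averaged after the
#' transform; a protein mapping to several genes contributes its row to each;
#' unmapped proteins are dropped with a message stating how many.
#'
#' @param matrix imputed proteins x samples matrix.
#' @param id_map optional data frame with columns `protein_id`, `gene_id`.
#' @return Transformed (and possibly re-keyed) matrix, `stage` attribute
#'   `"transformed"`.
#' @export
transform_and_map <- function(matrix, id_map = NULL) {
  tr <- log2(matrix + 1)
  if (is.null(id_map)) {
    attr(tr, "stage") <- "transformed"
    return(tr)
  }
  stopifnot(all(c("protein_id", "gene_id") %in% names(id_map)))
  map <- id_map[id_map$protein_id %in% rownames(tr), , drop = FALSE]
  n_unmapped <- sum(!rownames(tr) %in% map$protein_id)
  if (n_unmapped)
    message(n_unmapped, " unmapped protein(s) dropped")
  genes <- sort(unique(map$gene_id))
  out <- matrix(NA_real_, length(genes), ncol(tr),
                dimnames = list(genes, colnames(tr)))
  for (g in genes) {
    rows <- map$protein_id[map$gene_id == g]
    out[g, ] <- colMeans(tr[rows, , drop = FALSE])
  }
  attr(out, "stage") <- "transformed"
  out
}

#' Rank genes for enrichment analysis
#'
#' Descending ranking by signal-to-noise ratio
#' `(mean_group - mean_sham) / (sd_group + sd_sham)` with the conventional
#' GSEA variance floor (each sd bounded below by 0.2 x |its mean|), or by
#' the Welch t statistic. Complete deterministic ordering: ties break by id.
#'
#' @param matrix transformed genes x samples matrix.
#' @param design a [study_design()].
#' @param comparison `"Functional_vs_Sham"`, `"Impaired_vs_Sham"` or
#'   `"Irradiated_vs_Sham"`.
#' @param method `"snr"` (default) or `"tstat"`.
#' @return A `ranked_list` data frame (`id`, `stat`) in descending order,
#'   with the comparison label as an attribute.
#' @export
rank_genes <- function(matrix, design, comparison, method = c("snr",
                                                              "tstat")) {
  method <- match.arg(method)
  parts <- strsplit(comparison, "_vs_")[[1]]
  if (length(parts) != 2) stop("comparison must be '<group>_vs_<group>'")
  sa <- intersect(cohort_samples(design, parts[1]), colnames(matrix))
  sb <- intersect(cohort_samples(design, parts[2]), colnames(matrix))
  if (length(sa) < 2 || length(sb) < 2)
    stop("comparison group absent or too small: ", comparison)
  A <- matrix[, sa, drop = FALSE]; B <- matrix[, sb, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  sA <- apply(A, 1, stats::sd); sB <- apply(B, 1, stats::sd)
  if (method == "snr") {
    sA <- pmax(sA, 0.2 * abs(mA)); sB <- pmax(sB, 0.2 * abs(mB))
    denom <- sA + sB
    stat <- ifelse(denom == 0, 0, (mA - mB) / denom)
  } else {
    se <- sqrt(sA^2 / ncol(A) + sB^2 / ncol(B))
    stat <- ifelse(se == 0, 0, (mA - mB) / se)
  }
  ord <- order(-stat, rownames(matrix))
  structure(data.frame(id = rownames(matrix)[ord], stat = stat[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            comparison = comparison,
            class = c("ranked_list", "data.frame"))
}

# enrichment score from sorted hit positions
# pos: sorted hit ranks; w: |stat|^p in rank order; N: universe size
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  wh <- w[pos]
  Nr <- sum(wh)
  cumw <- if (Nr > 0) cumsum(wh) / Nr else seq_len(k) / k
  miss <- (pos - seq_len(k)) / (N - k)
  V <- cumw - miss                 # running value just after each hit
  B <- c(0, cumw[-k]) - miss       # running value just before each hit
  maxV <- max(V); minB <- min(B)
  if (maxV >= -minB) {
    list(es = maxV, peak = pos[which.max(V)], positive = TRUE)
  } else {
    list(es = minB, peak = pos[which.min(B)], positive = FALSE)
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running sum over the ranked list: member hits increment by
#' `|stat|^weight_exponent` (normalized over members), misses decrement by
#' `1 / (N - n_members)`; the enrichment score is the signed maximum
#' deviation from zero. The leading edge is the members at or before the
#' extremum (at or after, for a negative score).
#'
#' @param ranked a `ranked_list` from [rank_genes()].
#' @param members character vector of member ids.
#' @param weight_exponent hit-weight exponent (default 1; 0 gives the
#'   classic unweighted statistic).
#' @return A list: `es` in \[-1, 1\] and `leading_edge`.
#' @export
gsea_es <- function(ranked, members, weight_exponent = 1) {
  ids <- ranked$id
  N <- length(ids)
  pos <- sort(which(ids %in% members))
  if (!length(pos)) stop("no members in the ranked universe")
  if (length(pos) == N) stop("set covers the whole universe")
  w <- abs(ranked$stat)^weight_exponent
  r <- es_from_positions(pos, w, N)
  leading <- if (r$positive) ids[pos[pos <= r$peak]]
             else ids[pos[pos >= r$peak]]
  list(es = r$es, leading_edge = leading)
}

#' Gene-set enrichment with a gene-set-permutation null
#'
#' Sets are filtered to at least `min_size` members present in the ranked
#' universe. The null distribution of each set's enrichment score is built
#' from `n_perm` random member sets of the same size drawn from the universe
#' (gene-set permutation -- with a two-rat cohort a phenotype permutation
#' would be meaningless). `perm_p = (1 + #{|ES_null| >= |ES_obs|}) /
#' (1 + n_perm)`; `fdr_q` is Benjamini-Hochberg over the retained sets of
#' the comparison. `n_significant_members` counts members whose two-sided
#' Welch raw p between the comparison groups is below 0.05.
#'
#' @param matrix transformed genes x samples matrix.
#' @param design a [study_design()].
#' @param sets a `gene_set_collection`.
#' @param comparison comparison label, see [rank_genes()].
#' @param min_size minimum members-in-universe (default 15).
#' @param n_perm permutations per set (default 1000).
#' @param seed RNG seed.
#' @param weight_exponent hit-weight exponent (default 1).
#' @param method ranking metric, see [rank_genes()].
#' @return A `gsea_result` data frame: `set`, `comparison`, `size`, `es`,
#'   `perm_p`, `fdr_q`, `n_significant_members`, with leading edges in the
#'   `leading_edges` attribute and the universe in `universe`.
#' @export
gsea_run <- function(matrix, design, sets, comparison, min_size = 15,
                     n_perm = 1000, seed = 1L, weight_exponent = 1,
                     method = "snr") {
  if (nrow(matrix) < min_size)
    stop("universe smaller than min_size")
  ranked <- rank_genes(matrix, design, comparison, method = method)
  ids <- ranked$id
  N <- length(ids)
  members <- lapply(sets, function(m) intersect(m, ids))
  keep <- names(sets)[lengths(members) >= min_size & lengths(members) < N]
  members <- members[keep]
  w <- abs(ranked$stat)^weight_exponent

  set.seed(seed)
  es <- numeric(length(keep))
  pp <- numeric(length(keep))
  leading <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    pos <- sort(which(ids %in% members[[i]]))
    r <- es_from_positions(pos, w, N)
    es[i] <- r$es
    leading[[i]] <- if (r$positive) ids[pos[pos <= r$peak]]
                    else ids[pos[pos >= r$peak]]
    k <- length(pos)
    null_es <- vapply(seq_len(n_perm), function(b) {
      es_from_positions(sort(sample.int(N, k)), w, N)$es
    }, 0)
    pp[i] <- (1 + sum(abs(null_es) >= abs(es[i]))) / (1 + n_perm)
  }
  # per-gene univariate Welch p-values, shared across sets
  parts <- strsplit(comparison, "_vs_")[[1]]
  sa <- intersect(cohort_samples(design, parts[1]), colnames(matrix))
  sb <- intersect(cohort_samples(design, parts[2]), colnames(matrix))
  gene_p <- vapply(rownames(matrix), function(g) {
    a <- matrix[g, sa]; b <- matrix[g, sb]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    stats::t.test(a, b)$p.value
  }, 0)
  n_sig <- vapply(members, function(m) sum(gene_p[m] < 0.05, na.rm = TRUE),
                  0L)
  names(leading) <- keep
  structure(data.frame(set = keep, comparison = comparison,
                       size = lengths(members), es = es, perm_p = pp,
                       fdr_q = bh_adjust(pp),
                       n_significant_members = as.integer(n_sig),
                       row.names = NULL, stringsAsFactors = FALSE),
            leading_edges = leading, universe = sort(ids),
            class = c("gsea_result", "data.frame"))
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("gsea_result:", nrow(x), "sets,", x$comparison[1], "--",
      sum(x$fdr_q < 0.05), "at FDR q < 0.05\n")
  invisible(x)
}

#' Consensus graph over three enrichment comparisons
#'
#' Nodes are gene sets meeting the inclusion rule in at least one
#' comparison: FDR q below `p_cut` and at least `min_sig_members`
#' individually significant member proteins. Each node carries one
#' significance flag per comparison; an edge joins two included sets sharing
#' at least one member, weighted by the intersection size. Named sets (e.g.
#' disease pathways) can be excluded.
#'
#' @param results list of `gsea_result` objects, one per comparison,
#'   computed on the same universe.
#' @param sets the `gene_set_collection` the results came from.
#' @param p_cut FDR cutoff (default 0.05).
#' @param min_sig_members minimum individually significant members
#'   (default 4).
#' @param exclude_names set names to drop (default none).
#' @return A `consensus_graph`: list with data frames `nodes` (`set`, one
#'   `sig_<comparison>` flag per comparison, `included`) and `edges`
#'   (`a`, `b`, `weight`).
#' @export
build_consensus_graph <- function(results, sets, p_cut = 0.05,
                                  min_sig_members = 4,
                                  exclude_names = character()) {
  unis <- lapply(results, attr, "universe")
  if (length(results) > 1 &&
      !all(vapply(unis[-1], identical, TRUE, unis[[1]])))
    stop("comparisons computed on different universes")
  comps <- vapply(results, function(r) r$comparison[1], "")
  all_sets <- sort(unique(unlist(lapply(results, `[[`, "set"))))
  all_sets <- setdiff(all_sets, exclude_names)
  flags <- matrix(FALSE, length(all_sets), length(comps),
                  dimnames = list(all_sets, comps))
  for (j in seq_along(results)) {
    r <- results[[j]]
    sig <- r$set[r$fdr_q < p_cut & r$n_significant_members >= min_sig_members]
    flags[intersect(sig, all_sets), j] <- TRUE
  }
  included <- rowSums(flags) > 0
  nodes <- data.frame(set = all_sets, flags, included = included,
                      row.names = NULL, stringsAsFactors = FALSE)
  names(nodes)[1 + seq_along(comps)] <- paste0("sig_", comps)
  inc <- all_sets[included]
  mem <- lapply(sets[inc], intersect, unis[[1]])
  ea <- character(0); eb <- character(0); ew <- integer(0)
  if (length(inc) > 1) {
    for (i in seq_len(length(inc) - 1)) {
      for (j in (i + 1):length(inc)) {
        wgt <- length(intersect(mem[[i]], mem[[j]]))
        if (wgt >= 1) {
          ea <- c(ea, inc[i]); eb <- c(eb, inc[j]); ew <- c(ew, wgt)
        }
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(a = ea, b = eb, weight = ew,
                                    stringsAsFactors = FALSE)),
            class = "consensus_graph")
}

#' @export
print.consensus_graph <- function(x, ...) {
  cat("consensus_graph:", sum(x$nodes$included), "included sets,",
      nrow(x$edges), "edges\n")
  invisible(x)
}
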