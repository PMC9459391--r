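#' Impute missing values by half the within-group minimum
#'
#' Per protein and cohort: each missing cell becomes half of the lowest
#' observed value of that protein within the cohort; a cohort in which the
#' protein is entirely missing gets the constant 1 in all its cells.
#'
#' @param matrix raw rat-level proteins x samples matrix with `NA` for
#'   missing.
#' @param design a [study_design()].
#' @return Matrix without missing values, `stage` attribute `"imputed"`.
#' @export
impute_half_group_min <- function(matrix, design) {
  out <- matrix
  for (g in COHORT_LEVELS) {
    sam <- intersect(cohort_samples(design, g), colnames(out))
    if (!length(sam)) next
    sub <- out[, sam, drop = FALSE]
    gmin <- suppressWarnings(apply(sub, 1, min, na.rm = TRUE))
    all_miss <- !is.finite(gmin)
    fill <- ifelse(all_miss, 1, gmin / 2)
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na_idx)) sub[na_idx] <- fill[na_idx[, 1]]
    out[, sam] <- sub
  }
  attr(out, "stage") <- "imputed"
  out
}

#' Select dysregulated proteins by fold change versus Sham
#'
#' Fold change is the ratio of the comparison group's cohort mean to the
#' Sham mean on the imputed matrix. The cutoff is two-sided: up at
#' `fc >= fc_cut`, down at `fc <= 1/fc_cut` (a one-sided upper cutoff is
#' available via `two_sided = FALSE`).
#'
#' @param matrix imputed proteins x samples matrix.
#' @param design a [study_design()].
#' @param comparison `"Impaired"`, `"Functional"` or `"Irradiated"`.
#' @param fc_cut fold-change cutoff (default 1.15).
#' @param two_sided include the down side (default `TRUE`).
#' @return A `dysregulated_set`: list with `comparison`, character vectors
#'   `up` and `down`, and the named numeric vector `fc` over all proteins.
#' @export
select_dysregulated <- function(matrix, design, comparison = "Irradiated",
                                fc_cut = 1.15, two_sided = TRUE) {
  if (!comparison %in% c(COHORT_LEVELS, "Irradiated"))
    stop("unknown comparison: ", comparison)
  sham <- intersect(cohort_samples(design, "Sham"), colnames(matrix))
  grp <- intersect(cohort_samples(design, comparison), colnames(matrix))
  if (!length(sham) || !length(grp)) stop("empty comparison group")
  fc <- rowMeans(matrix[, grp, drop = FALSE]) /
    rowMeans(matrix[, sham, drop = FALSE])
  up <- names(fc)[fc >= fc_cut]
  down <- if (two_sided) names(fc)[fc <= 1 / fc_cut] else character(0)
  structure(list(comparison = comparison, up = up, down = down, fc = fc),
            class = "dysregulated_set")
}

#' @export
print.dysregulated_set <- function(x, ...) {
  cat("dysregulated_set (", x$comparison, " vs Sham): ",
      length(x$up), " up, ", length(x$down), " down\n", sep = "")
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' Per pathway: upper-tail hypergeometric p-value for the observed overlap
#' between the query and the pathway, given the universe; `P(X >= overlap)`
#' with `X ~ Hypergeom(|pathway n universe|, |universe| - |pathway n
#' universe|, |query|)`. Two-sided Fisher's exact test is available as an
#' alternative. P-values are Benjamini-Hochberg adjusted.
#'
#' @param query character vector of ids, a subset of `universe`.
#' @param pathways a `gene_set_collection`.
#' @param universe character vector of background ids.
#' @param fdr_cut significance cutoff on adjusted p (default 0.05).
#' @param method `"hypergeometric"` (default) or `"fisher"`.
#' @return An `ora_result` data frame: `pathway`, `n_pathway`, `n_overlap`,
#'   `p`, `adj_p`, `significant`.
#' @export
ora_enrich <- function(query, pathways, universe, fdr_cut = 0.05,
                       method = c("hypergeometric", "fisher")) {
  method <- match.arg(method)
  if (!length(query) || !length(universe))
    stop("empty query or universe")
  query <- intersect(query, universe)
  if (!length(query)) stop("query has no members in the universe")
  N <- length(universe)
  n <- length(query)
  res <- do.call(rbind, lapply(names(pathways), function(pw) {
    K <- length(intersect(pathways[[pw]], universe))
    ov <- length(intersect(pathways[[pw]], query))
    p <- if (K == 0) 1 else if (method == "hypergeometric") {
      stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(ov, K - ov, n - ov, N - K - n + ov), 2))$
        p.value
    }
    data.frame(pathway = pw, n_pathway = K, n_overlap = ov, p = p,
               stringsAsFactors = FALSE)
  }))
  res$adj_p <- bh_adjust(res$p)
  res$significant <- res$adj_p < fdr_cut
  structure(res[order(res$p, res$pathway), , drop = FALSE],
            class = c("ora_result", "data.frame"))
}

#' Induce the interaction subnetwork over dysregulated proteins
#'
#' Node set is the dysregulated ids (up and down); edges are the supplied
#' interactions with both endpoints in the node set. Isolated nodes are
#' retained. Degree is the count of distinct neighbours (simple graph). An
#' optional annotation table contributes a per-node category tag.
#'
#' @param edges a `ppi_edges` data frame.
#' @param dysregulated a `dysregulated_set`.
#' @param annotation optional `annotation_table`; its `main_pathway` column
#'   becomes the node tag.
#' @return An `interaction_network`: list with data frames `nodes`
#'   (`id`, `fc`, `direction`, `degree`, optional `tag`) and `edges`.
#' @export
induce_subnetwork <- function(edges, dysregulated, annotation = NULL) {
  ids <- sort(c(dysregulated$up, dysregulated$down))
  sub <- edges[edges$a %in% ids & edges$b %in% ids, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub[, c("a", "b"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  deg <- igraph::degree(g)
  nodes <- data.frame(id = ids,
                      fc = unname(dysregulated$fc[ids]),
                      direction = ifelse(ids %in% dysregulated$up, "up",
                                         "down"),
                      degree = as.integer(deg[ids]),
                      stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    nodes$tag <- annotation$main_pathway[match(ids, annotation$id)]
  }
  structure(list(nodes = nodes,
                 edges = data.frame(sub, row.names = NULL)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Rank network hubs by degree
#'
#' @param network an `interaction_network`.
#' @param top_n how many hubs (default 5); fewer nodes than `top_n` returns
#'   all. Ties break lexicographically by id.
#' @return A list: `hubs` (ordered ids) and `degree_table` (full table,
#'   ordered).
#' @export
hub_ranking <- function(network, top_n = 5) {
  nd <- network$nodes
  ord <- order(-nd$degree, nd$id)
  tab <- nd[ord, c("id", "degree"), drop = FALSE]
  rownames(tab) <- NULL
  list(hubs = tab$id[seq_len(min(top_n, nrow(tab)))], degree_table = tab)
}
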