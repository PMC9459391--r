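make_mat <- function(values, ids = sprintf("P%d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(ids, samples)
  values
}

test_that("kNN imputation averages the k nearest neighbours", {
  # X missing in sample 3; two rows identical to X elsewhere with values 4, 6
  m <- make_mat(rbind(c(1, 2, NA, 4),
                      c(1, 2, 4, 4),
                      c(1, 2, 6, 4),
                      c(50, 60, 70, 80)),
                ids = c("X", "N1", "N2", "FAR"))
  out <- knn_impute(m, k = 2)
  expect_equal(unname(out["X", 3]), 5)
  complete <- make_mat(matrix(1:12, 3, 4))
  expect_equal(knn_impute(complete, k = 2), complete, ignore_attr = TRUE)
  expect_error(knn_impute(m, k = 4), "k must be smaller")
})

test_that("kNN beats column-mean imputation on correlated data", {
  rmse <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    set.seed(s)
    base <- rnorm(12)
    truth <- t(vapply(1:60, function(i)
      rnorm(1, 0, 2) + base + rnorm(12, 0, 0.3), numeric(12)))
    truth <- make_mat(truth)
    masked <- truth
    holes <- which(matrix(runif(length(truth)) < 0.1, nrow(truth)))
    masked[holes] <- NA
    knn <- knn_impute(masked, k = 5)
    colmean <- masked
    for (j in seq_len(ncol(colmean)))
      colmean[is.na(colmean[, j]), j] <- mean(colmean[, j], na.rm = TRUE)
    rmse[s, ] <- c(sqrt(mean((knn[holes] - truth[holes])^2)),
                   sqrt(mean((colmean[holes] - truth[holes])^2)))
  }
  expect_true(all(rmse[, 1] < rmse[, 2]))
})

test_that("log2(x+1) transform and id mapping average after transform", {
  m <- make_mat(matrix(c(1, 0, 3, 15), 2, 2), ids = c("A", "B"))
  tr <- transform_and_map(m)
  expect_equal(unname(tr["A", 1]), 1)
  expect_equal(unname(tr["B", 1]), 0)
  expect_equal(unname(tr["B", 2]), 4)
  # two proteins -> one gene: transformed values 2 and 4 average to 3
  m2 <- make_mat(matrix(c(3, 15), 2, 1), ids = c("A", "B"))
  map <- data.frame(protein_id = c("A", "B"), gene_id = c("G", "G"))
  out <- transform_and_map(m2, map)
  expect_equal(unname(out["G", 1]), 3)
  # identity map preserves row count; unmapped rows dropped with a message
  idmap <- data.frame(protein_id = "A", gene_id = "A")
  expect_message(out2 <- transform_and_map(m2, idmap), "1 unmapped")
  expect_equal(rownames(out2), "A")
})

test_that("signal-to-noise ranking applies the variance floor and tie rules", {
  design <- study_design(sprintf("s%d", 1:6),
                         rep(c("Impaired", "Sham"), each = 3))
  m <- make_mat(rbind(c(3, 4, 5, 1, 2, 3),   # means 4 vs 2, sds 1 vs 1
                      c(1, 2, 3, 1, 2, 3)),  # identical groups -> 0
                ids = c("up", "zero"))
  r <- rank_genes(m, design, "Impaired_vs_Sham")
  expect_equal(r$stat[r$id == "up"], 1.0)
  expect_equal(r$stat[r$id == "zero"], 0)
  expect_equal(r$id, c("up", "zero"))
  # flipping the comparison negates every statistic and reverses order
  r2 <- rank_genes(m, design, "Sham_vs_Impaired")
  expect_equal(r2$stat, rev(-r$stat))
  expect_equal(r2$id, rev(r$id))
})

test_that("enrichment score matches closed forms at the extremes", {
  ranked <- structure(data.frame(id = c("a", "b", "c", "d"),
                                 stat = c(3, 2, 1, 0.5)),
                      class = c("ranked_list", "data.frame"))
  expect_equal(gsea_es(ranked, "a")$es, 1.0)
  expect_equal(gsea_es(ranked, "d")$es, -1.0)
  expect_equal(gsea_es(ranked, "d")$leading_edge, "d")
  expect_error(gsea_es(ranked, "nope"), "no members")
})

test_that("enrichment score equals a brute-force running-sum scan", {
  set.seed(55)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    ids <- sprintf("g%03d", 1:N)
    stats <- sort(rnorm(N, 0, 2), decreasing = TRUE)
    ranked <- structure(data.frame(id = ids, stat = stats),
                        class = c("ranked_list", "data.frame"))
    members <- sample(ids, sample(3:min(30, N - 1), 1))
    p <- sample(c(0, 1, 2), 1)
    expect_equal(gsea_es(ranked, members, weight_exponent = p)$es,
                 brute_es(ids, stats, members, p = p))
  }
})

test_that("unit weight exponent zero gives the classic KS statistic", {
  ranked <- structure(data.frame(id = letters[1:6],
                                 stat = c(5, 4, 3, 2, 1, 0.5)),
                      class = c("ranked_list", "data.frame"))
  # set {a, c}: running sum .5, .25, .75, .5, .25, 0 -> max deviation .75
  expect_equal(gsea_es(ranked, c("a", "c"), weight_exponent = 0)$es, 0.75)
})

test_that("gene-set permutation p-values are calibrated and deterministic", {
  ds <- generate_dataset(sim_config(n_proteins = 400, detect_prob = 1,
                                    tech_cv = 0.2, bio_cv = 0.3,
                                    class_fractions = c(), seed = 61))
  pres <- call_presence(ds$quant)
  tr <- transform_and_map(pres$rat_mean)
  gs <- generate_gene_sets(ds$truth, n_sets = 60, n_enriched = 0,
                           size_range = c(15, 40), seed = 62)
  r1 <- gsea_run(tr, ds$design, gs, "Irradiated_vs_Sham", n_perm = 200,
                 seed = 63)
  r2 <- gsea_run(tr, ds$design, gs, "Irradiated_vs_Sham", n_perm = 200,
                 seed = 63)
  expect_identical(r1$perm_p, r2$perm_p)
  expect_true(all(r1$perm_p > 0))
  # the size-14 set is excluded by the >= 15 in-universe filter
  expect_false(names(gs)[1] %in% r1$set)
  expect_true(all(r1$size >= 15))
  # q is monotone in p within the comparison
  ord <- order(r1$perm_p)
  expect_true(all(diff(r1$fdr_q[ord]) >= -1e-12))
})

test_that("planted enriched sets reach small permutation p-values", {
  hits <- vapply(1:10, function(s) {
    ds <- generate_dataset(sim_config(n_proteins = 300, detect_prob = 1,
                                      tech_cv = 0.1,
                                      class_fractions = c(up = 0.15,
                                                          down = 0.15),
                                      seed = s))
    pres <- call_presence(ds$quant)
    tr <- transform_and_map(pres$rat_mean)
    gs <- generate_gene_sets(ds$truth, n_sets = 20, n_enriched = 2,
                             enrichment_odds = 8, seed = s + 100)
    r <- gsea_run(tr, ds$design, gs, "Irradiated_vs_Sham", n_perm = 1000,
                  seed = s + 200)
    min(r$perm_p[grep("ENR", r$set)]) < 0.05
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("consensus graph applies the dual inclusion rule and weights", {
  mk_res <- function(comp, sig_sets, universe, sets) {
    nm <- names(sets)
    structure(data.frame(set = nm, comparison = comp, size = lengths(sets),
                         es = 0.5, perm_p = ifelse(nm %in% sig_sets, 0.001,
                                                   0.9),
                         fdr_q = ifelse(nm %in% sig_sets, 0.001, 0.9),
                         n_significant_members = ifelse(nm %in% sig_sets,
                                                        5L, 0L)),
              universe = universe, class = c("gsea_result", "data.frame"))
  }
  sets <- gene_set_collection(list(S1 = c("a", "b", "c"),
                                   S2 = c("b", "c", "d"),
                                   S3 = c("x", "y", "z")))
  uni <- sort(c("a", "b", "c", "d", "x", "y", "z", "w"))
  res <- list(mk_res("Functional_vs_Sham", character(), uni, sets),
              mk_res("Impaired_vs_Sham", c("S1", "S2", "S3"), uni, sets),
              mk_res("Irradiated_vs_Sham", "S1", uni, sets))
  g <- build_consensus_graph(res, sets)
  expect_equal(sum(g$nodes$included), 3)
  # S1/S2 share {b, c} -> weight 2; S3 is disjoint -> no edge
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 2)
  # flags: S2 significant in exactly one comparison
  s2 <- g$nodes[g$nodes$set == "S2", ]
  expect_equal(unname(unlist(s2[paste0("sig_", c("Functional_vs_Sham",
                                                 "Impaired_vs_Sham",
                                                 "Irradiated_vs_Sham"))])),
               c(FALSE, TRUE, FALSE))
  # a 4-significant-member floor is enforced
  res2 <- res
  res2[[2]]$n_significant_members <- 3L
  g2 <- build_consensus_graph(res2, sets)
  expect_equal(sum(g2$nodes$included), 1)  # only S1 via Irradiated
  # name exclusion removes nodes
  g3 <- build_consensus_graph(res, sets, exclude_names = "S3")
  expect_false("S3" %in% g3$nodes$set)
  # differing universes are an error
  res3 <- res
  attr(res3[[1]], "universe") <- c("a", "b")
  expect_error(build_consensus_graph(res3, sets), "different universes")
})
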