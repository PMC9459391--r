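make_mat <- function(values, ids = sprintf("P%d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(ids, samples)
  values
}

test_that("presence-fraction filter is group-wise", {
  design <- make_design()  # s1..s5 Sham, s6..s7 Functional, s8..s12 Impaired
  m <- make_mat(matrix(1, 3, 12))
  m[1, 6:12] <- NA            # 5/5 sham, 0/7 irradiated -> kept
  m[2, c(1, 2, 9, 10, 11)] <- NA  # 3/5 sham, 4/7 irr -> dropped
  out <- filter_presence_fraction(m, design, 0.7)
  expect_equal(rownames(out), c("P1", "P3"))
  expect_error(filter_presence_fraction(m, design, 0), "fraction")
  full <- make_mat(matrix(1:24, 2, 12))
  expect_equal(filter_presence_fraction(full, design, 1), full,
               ignore_attr = TRUE)
})

test_that("minimum-fraction imputation fills 1/5 of the row minimum", {
  m <- make_mat(matrix(c(NA, 5, 10), 1, 3))
  expect_equal(unname(impute_min_fraction(m)[1, ]), c(1, 5, 10))
  complete <- make_mat(matrix(1:6, 2, 3))
  expect_equal(impute_min_fraction(complete), complete,
               ignore_attr = TRUE)
  all_na <- make_mat(matrix(NA_real_, 1, 3))
  expect_error(impute_min_fraction(all_na), "entirely missing")
  # property: output row minimum = observed minimum / 5 when anything missing
  set.seed(3)
  for (i in 1:100) {
    v <- matrix(exp(rnorm(20)), 4, 5)
    v[sample(20, 4)] <- NA
    out <- impute_min_fraction(make_mat(v))
    for (r in 1:4) {
      obs <- v[r, !is.na(v[r, ])]
      expected <- if (anyNA(v[r, ])) min(obs) / 5 else min(obs)
      expect_equal(min(out[r, ]), min(expected, min(obs)))
    }
  }
})

test_that("median normalization equalizes sample medians", {
  set.seed(8)
  m <- make_mat(matrix(exp(rnorm(50)), 10, 5))
  out <- normalize_median(m)
  meds <- apply(out, 2, median)
  expect_lt(diff(range(meds)), 1e-12)
  expect_equal(unname(meds[1]), median(apply(m, 2, median)))
  out2 <- normalize_median(m, rescale = FALSE)
  expect_equal(unname(apply(out2, 2, median)), rep(1, 5))
})

test_that("Pareto scaling divides centered values by sqrt(sd)", {
  m <- make_mat(matrix(c(1, 2, 3), 1, 3))
  expect_equal(unname(pareto_scale(m)[1, ]), c(-1, 0, 1))
  expect_warning(out <- pareto_scale(make_mat(matrix(5, 1, 3))), "constant")
  expect_equal(unname(out[1, ]), c(0, 0, 0))
  set.seed(12)
  big <- make_mat(matrix(rnorm(200, 10, 3), 20, 10))
  sc <- pareto_scale(big)
  expect_lt(max(abs(rowMeans(sc))), 1e-9)
  # defining property: residual variance equals the original sd
  expect_equal(apply(sc, 1, var), apply(big, 1, sd), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("pca is deterministic in sign and reconstructs at full rank", {
  m <- make_mat(matrix(c(1, 1, 2, 2, 3, 3), 2, 3))  # collinear samples
  res <- pca(m, n_components = 1)
  expect_equal(res$variance_fraction, 1)
  expect_equal(unname(res$loadings[, 1]), c(sqrt(0.5), sqrt(0.5)))
  expect_error(pca(m, n_components = 3), "n_components")

  set.seed(21)
  x <- make_mat(matrix(rnorm(20), 5, 4))  # 5 proteins x 4 samples, rank 3
  full <- pca(x, n_components = 3)
  recon <- sweep(full$scores %*% t(full$loadings), 2, rowMeans(x), "+")
  expect_equal(unname(recon), unname(t(x)), tolerance = 1e-9)
  # loadings orthonormal
  expect_equal(t(full$loadings) %*% full$loadings, diag(3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("pca separates sham from irradiated under a planted global shift", {
  for (s in 1:5) {
    ds <- generate_dataset(sim_config(n_proteins = 150, detect_prob = 1,
                                      tech_cv = 0.1,
                                      class_fractions = c(up = 0.3),
                                      seed = s))
    pres <- call_presence(ds$quant)
    m <- pareto_scale(normalize_median(pres$rat_mean))
    res <- suppressWarnings(pca(m, 3))
    irr <- rownames(res$scores) %in% cohort_samples(ds$design, "Irradiated")
    # mean silhouette of the two groups on the scores must be positive
    d <- as.matrix(dist(res$scores))
    sil <- vapply(seq_len(nrow(d)), function(i) {
      own <- mean(d[i, irr == irr[i] & seq_len(nrow(d)) != i])
      oth <- mean(d[i, irr != irr[i]])
      (oth - own) / max(own, oth)
    }, 0)
    expect_gt(mean(sil), 0)
  }
})

test_that("Welch statistics match the textbook formula", {
  m <- make_mat(matrix(c(1, 2, 3, 2, 3, 4), 1, 6),
                samples = sprintf("s%d", 1:6))
  design <- study_design(sprintf("s%d", 1:6),
                         rep(c("Sham", "Impaired"), each = 3))
  # scaled values are affine per protein, so t equals the raw-scale t
  res <- ttest_fc(rbind(m, m + 1), design, "Sham", "Impaired")
  expect_equal(res$t_stat[1], 1.224745, tolerance = 1e-6)
  expect_equal(res$fc[1], 3 / 2)
  tt <- t.test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(res$raw_p[1], tt$p.value)
  expect_equal(unname(tt$parameter), 4)
  expect_error(ttest_fc(m, design, "Sham", "Functional"), "n >= 2")
})

test_that("log2 fold change is consistent with the ratio", {
  set.seed(14)
  design <- make_design()
  m <- make_mat(matrix(exp(rnorm(240, 5)), 20, 12))
  res <- ttest_fc(m, design)
  expect_equal(res$log2_fc, log2(res$fc), tolerance = 1e-9)
})

test_that("t-test type-I error is nominal on null data", {
  # mildly dispersed log-normal abundances: the Welch test is calibrated
  # for approximately normal data, which is what this step receives after
  # normalization in practice
  set.seed(99)
  design <- make_design()
  m <- make_mat(matrix(exp(rnorm(2000 * 12, 8, 0.25)), 2000, 12))
  res <- ttest_fc(m, design)
  rate <- mean(res$raw_p < 0.05)
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.05) / 2000
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p))
    expect_true(all(adj >= p))
  }
})

test_that("top-k selection ranks by p with |log2FC| and id tie-breaks", {
  res <- structure(data.frame(
    protein_id = c("A", "B", "C"), fc = c(8, 2, 0.5),
    log2_fc = c(3, 1, -1), t_stat = 0, raw_p = c(0.01, 0.01, 0.001),
    adj_p = 1, volcano_flag = FALSE), class = c("de_result", "data.frame"))
  expect_equal(top_k_by_test(res, 1)$ids, "C")
  expect_equal(top_k_by_test(res, 3)$ids, c("C", "A", "B"))
  expect_warning(out <- top_k_by_test(res, 5), "k exceeds")
  expect_equal(length(out$ids), 3)

  # leaf order comes from complete-linkage Euclidean clustering
  set.seed(2)
  m <- make_mat(matrix(rnorm(36), 6, 6), ids = c("A", "B", "C", "D", "E",
                                                 "F"))
  res6 <- structure(data.frame(
    protein_id = rownames(m), fc = 1, log2_fc = 0, t_stat = 0,
    raw_p = seq(0.001, 0.006, by = 0.001), adj_p = 1,
    volcano_flag = FALSE), class = c("de_result", "data.frame"))
  out <- top_k_by_test(res6, 6, matrix = m)
  hc <- hclust(dist(m), method = "complete")
  expect_equal(out$leaf_order, rownames(m)[hc$order])
})

test_that("annotation overlap joins, summarizes and reports the unmatched", {
  res <- structure(data.frame(
    protein_id = c("A", "B", "C", "D", "E"), fc = 2,
    log2_fc = c(-1, -2, -0.5, 1, 1), t_stat = 0, raw_p = 0.01,
    adj_p = c(0.01, 0.2, 0.01, 0.5, 0.5), volcano_flag = FALSE),
    class = c("de_result", "data.frame"))
  ann <- structure(data.frame(id = c("A", "B", "C"),
                              main_pathway = c("OXPHOS", "OXPHOS", "Lipid"),
                              sub_pathway = c("CI", "CI", "Beta"),
                              stringsAsFactors = FALSE),
                   class = c("annotation_table", "data.frame"))
  out <- annotate_overlap(res, ann)
  expect_equal(nrow(out$annotated), 3)
  expect_equal(sort(out$unannotated), c("D", "E"))
  ci <- out$summary[out$summary$sub_pathway == "CI", ]
  expect_equal(ci$n, 2)
  expect_equal(ci$median_log2_fc, -1.5)  # all-negative category stays negative
  expect_equal(ci$n_significant, 1)
  expect_warning(out2 <- annotate_overlap(res[4:5, ], ann), "no proteins")
  expect_equal(out2$unannotated, c("D", "E"))
})
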