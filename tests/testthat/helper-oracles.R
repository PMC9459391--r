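# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package.

# exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(nA+nB, nA) group assignments of the combined sample
brute_wilcoxon_p <- function(a, b) {
  comb <- c(a, b)
  nA <- length(a)
  r <- rank(comb)
  u_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  idx <- utils::combn(length(comb), nA)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - nA * (nA + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Benjamini-Hochberg step-up from the definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(sorted[k:m] * m / (k:m))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# enrichment score by a literal O(N) running-sum scan
brute_es <- function(ranked_ids, ranked_stats, members, p = 1) {
  N <- length(ranked_ids)
  hit <- ranked_ids %in% members
  w <- abs(ranked_stats)^p
  nr <- sum(w[hit])
  inc <- if (nr > 0) ifelse(hit, w / nr, 0) else ifelse(hit, 1 / sum(hit), 0)
  dec <- ifelse(hit, 0, 1 / (N - sum(hit)))
  running <- cumsum(inc - dec)
  i <- which.max(abs(running))
  running[i]
}

# upper-tail hypergeometric p by pmf enumeration
brute_hyper_p <- function(ov, K, N, n) {
  xs <- ov:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# small quant matrix from a proteins x (sample x rep) numeric matrix
make_qm <- function(values, n_reps = 3) {
  ns <- ncol(values) / n_reps
  sample <- rep(sprintf("s%d", seq_len(ns)), each = n_reps)
  repl <- rep(sprintf("r%d", seq_len(n_reps)), times = ns)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("prot%d", seq_len(nrow(values)))
  colnames(values) <- paste(sample, repl, sep = ".")
  quant_matrix(values, sample, repl)
}

# design with the study's default cohort sizes over given sample ids
make_design <- function(n_sham = 5, n_functional = 2, n_impaired = 5) {
  n <- n_sham + n_functional + n_impaired
  study_design(sprintf("s%d", seq_len(n)),
               rep(c("Sham", "Functional", "Impaired"),
                   c(n_sham, n_functional, n_impaired)))
}
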