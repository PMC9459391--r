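#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: three cohorts of
#' rats (Sham / Functional / Impaired, default sizes 5/2/5), three technical
#' replicate injections per rat, log-normal AUC abundances, protein-level
#' detection dropout, and planted protein classes with known fold changes.
#'
#' Abundance model: each protein draws one baseline from
#' log-normal(`baseline_log_mean`, `baseline_log_sd`) (natural log) shared by
#' all rats; a rat's true value is baseline x cohort effect (x an optional
#' rat-level log-normal biological noise at `bio_cv`, off by default);
#' each technical replicate multiplies log-normal noise with coefficient of
#' variation `tech_cv`. Each expressed (protein, rat) pair is detected with
#' probability `detect_prob`; a non-detected pair has all replicates missing.
#' An independent per-replicate dropout (`rep_detect_prob`, default 1 = off)
#' is available to exercise the replicate-level presence rule.
#'
#' Planted classes (mutually exclusive; fractions of `n_proteins`):
#' `sham_only` expressed only in Sham; `sr_exposure` only in the two
#' irradiated cohorts; `impaired_only` / `functional_only` only in that
#' cohort; `up` / `down` expressed everywhere and scaled by `planted_fc`
#' (up) or `1/planted_fc` (down) in both irradiated cohorts. The remainder
#' are null ("common") proteins with fold change 1.
#'
#' @param n_proteins number of proteins.
#' @param cohort_sizes named integer vector `c(Sham=, Functional=, Impaired=)`.
#' @param n_tech_reps technical replicates per rat.
#' @param baseline_log_mean,baseline_log_sd natural-log parameters of the
#'   per-protein baseline abundance.
#' @param tech_cv technical-replicate coefficient of variation.
#' @param bio_cv rat-level biological coefficient of variation (default 0).
#' @param detect_prob per-(protein, rat) detection probability for expressed
#'   pairs, in (0, 1].
#' @param rep_detect_prob independent per-replicate detection probability
#'   (default 1).
#' @param class_fractions named fractions for the planted classes; must be
#'   non-negative and sum to at most 1.
#' @param planted_fc multiplicative effect (> 1) for up/down proteins.
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 1000,
                       cohort_sizes = c(Sham = 5, Functional = 2,
                                        Impaired = 5),
                       n_tech_reps = 3,
                       baseline_log_mean = 12, baseline_log_sd = 1.5,
                       tech_cv = 0.1, bio_cv = 0,
                       detect_prob = 0.9, rep_detect_prob = 1,
                       class_fractions = c(sr_exposure = 0.04,
                                           sham_only = 0.14,
                                           impaired_only = 0.16,
                                           functional_only = 0.05,
                                           up = 0.08, down = 0.08),
                       planted_fc = 2, seed = 1L) {
  known <- c("sr_exposure", "sham_only", "impaired_only", "functional_only",
             "up", "down")
  cf <- stats::setNames(rep(0, length(known)), known)
  if (length(class_fractions)) {
    bad <- setdiff(names(class_fractions), known)
    if (length(bad)) stop("unknown planted class: ", bad[1])
    cf[names(class_fractions)] <- class_fractions
  }
  if (any(cf < 0) || sum(cf) > 1)
    stop("class fractions must be >= 0 and sum to at most 1")
  if (detect_prob <= 0 || detect_prob > 1) stop("detect_prob must be in (0,1]")
  if (planted_fc <= 1) stop("planted_fc must be > 1")
  stopifnot(all(COHORT_LEVELS %in% names(cohort_sizes)))
  structure(list(n_proteins = as.integer(n_proteins),
                 cohort_sizes = cohort_sizes[COHORT_LEVELS],
                 n_tech_reps = as.integer(n_tech_reps),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 tech_cv = tech_cv, bio_cv = bio_cv,
                 detect_prob = detect_prob,
                 rep_detect_prob = rep_detect_prob,
                 class_fractions = cf, planted_fc = planted_fc,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# multiplicative log-normal noise with unit mean and coefficient of
# variation cv; cv = 0 degenerates to exactly 1
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Generate a synthetic quantitation dataset with planted ground truth
#'
#' @param config a [sim_config()].
#' @return A list with elements `quant` ([quant_matrix()]), `design`
#'   ([study_design()]) and `truth` (data frame: `protein_id`, `true_class`,
#'   `true_fc_functional`, `true_fc_impaired` -- fold change versus Sham,
#'   `NA` where the protein is unexpressed in one of the cohorts involved).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cs <- config$cohort_sizes
  cf <- config$class_fractions
  # planted classes referencing an empty cohort are impossible to realize
  if (cs["Functional"] == 0 && cf["functional_only"] > 0)
    stop("functional_only planted but Functional cohort size is 0")
  if (cs["Impaired"] == 0 && cf["impaired_only"] > 0)
    stop("impaired_only planted but Impaired cohort size is 0")
  if (cs["Sham"] == 0 && cf["sham_only"] > 0)
    stop("sham_only planted but Sham cohort size is 0")
  if ((cs["Functional"] == 0 || cs["Impaired"] == 0) && cf["sr_exposure"] > 0)
    stop("sr_exposure planted but an irradiated cohort size is 0")
  if (cs["Functional"] == 0 && cs["Impaired"] == 0 &&
      (cf["up"] > 0 || cf["down"] > 0))
    stop("up/down planted but both irradiated cohort sizes are 0")

  set.seed(config$seed)
  np <- config$n_proteins
  ids <- sprintf("P%05d", seq_len(np))
  counts <- floor(cf * np)
  classes <- rep("common", np)
  pos <- 1L
  for (cl in names(counts)) {
    k <- counts[[cl]]
    if (k > 0) {
      classes[pos:(pos + k - 1L)] <- cl
      pos <- pos + k
    }
  }
  design <- study_design(
    sample_id = sprintf("rat%02d", seq_len(sum(cs))),
    cohort = rep(COHORT_LEVELS, times = cs))
  ns <- nrow(design)

  baseline <- exp(stats::rnorm(np, config$baseline_log_mean,
                               config$baseline_log_sd))
  # per-cohort multiplicative effect; 0 encodes "not expressed"
  eff <- matrix(1, np, 3, dimnames = list(ids, COHORT_LEVELS))
  eff[classes == "sham_only", c("Functional", "Impaired")] <- 0
  eff[classes == "sr_exposure", "Sham"] <- 0
  eff[classes == "impaired_only", c("Sham", "Functional")] <- 0
  eff[classes == "functional_only", c("Sham", "Impaired")] <- 0
  eff[classes == "up", c("Functional", "Impaired")] <- config$planted_fc
  eff[classes == "down", c("Functional", "Impaired")] <- 1 / config$planted_fc

  rat_true <- baseline * eff[, design$cohort, drop = FALSE]
  if (config$bio_cv > 0)
    rat_true <- rat_true * matrix(rlnorm_cv(np * ns, config$bio_cv), np, ns)
  detected <- matrix(stats::runif(np * ns) < config$detect_prob, np, ns) &
    rat_true > 0

  nr <- config$n_tech_reps
  vals <- matrix(NA_real_, np, ns * nr)
  sample_col <- rep(design$sample_id, each = nr)
  rep_col <- rep(sprintf("r%d", seq_len(nr)), times = ns)
  for (j in seq_len(ns)) {
    cols <- ((j - 1L) * nr + 1L):(j * nr)
    on <- detected[, j]
    if (!any(on)) next
    noise <- matrix(rlnorm_cv(sum(on) * nr, config$tech_cv), sum(on), nr)
    vals[on, cols] <- rat_true[on, j] * noise
  }
  if (config$rep_detect_prob < 1) {
    drop <- matrix(stats::runif(np * ns * nr) > config$rep_detect_prob,
                   np, ns * nr)
    vals[drop] <- NA_real_
  }
  rownames(vals) <- ids
  colnames(vals) <- paste(sample_col, rep_col, sep = ".")

  fc_fun <- ifelse(eff[, "Sham"] > 0 & eff[, "Functional"] > 0,
                   eff[, "Functional"] / eff[, "Sham"], NA_real_)
  fc_imp <- ifelse(eff[, "Sham"] > 0 & eff[, "Impaired"] > 0,
                   eff[, "Impaired"] / eff[, "Sham"], NA_real_)
  truth <- data.frame(protein_id = ids, true_class = classes,
                      true_fc_functional = fc_fun, true_fc_impaired = fc_imp,
                      stringsAsFactors = FALSE)
  list(quant = quant_matrix(vals, sample_col, rep_col),
       design = design, truth = truth)
}

#' Generate synthetic gene sets over the simulated protein universe
#'
#' Background sets are uniform draws without replacement; "enriched" sets
#' over-sample planted effect proteins with the given odds, each enriched
#' set drawing towards a single direction class (alternating up / down) so
#' the planted signal is directionally coherent -- a set mixing up- and
#' down-regulated members would have its enrichment score cancel by
#' construction. Set sizes deliberately straddle the conventional
#' minimum-size filter: the first three sets have sizes 14, 15 and 16.
#'
#' @param truth ground-truth data frame from [generate_dataset()] (or any
#'   data frame with `protein_id` and `true_class`).
#' @param n_sets total number of sets.
#' @param n_enriched how many of them over-sample planted up/down proteins.
#' @param size_range inclusive range of set sizes for the remaining sets.
#' @param enrichment_odds sampling odds of a planted up/down protein relative
#'   to a null protein in enriched sets (1 = uniform).
#' @param seed RNG seed.
#' @return A `gene_set_collection`; enriched sets are named `ENR_...`,
#'   background sets `BG_...`.
#' @export
generate_gene_sets <- function(truth, n_sets = 60, n_enriched = 5,
                               size_range = c(15, 50), enrichment_odds = 5,
                               seed = 1L) {
  set.seed(seed)
  universe <- truth$protein_id
  if (max(size_range) > length(universe) || 16 > length(universe))
    stop("requested set size exceeds universe size")
  sizes <- c(14, 15, 16,
             sample(size_range[1]:size_range[2], max(0, n_sets - 3),
                    replace = TRUE))[seq_len(n_sets)]
  w_up <- ifelse(truth$true_class == "up", enrichment_odds, 1)
  w_down <- ifelse(truth$true_class == "down", enrichment_odds, 1)
  enriched_idx <- if (n_enriched > 0)
    seq(n_sets - n_enriched + 1L, n_sets) else integer()
  sets <- vector("list", n_sets)
  nms <- character(n_sets)
  for (i in seq_len(n_sets)) {
    if (i %in% enriched_idx) {
      w <- if (match(i, enriched_idx) %% 2 == 1) w_up else w_down
      sets[[i]] <- sample(universe, sizes[i], prob = w)
      nms[i] <- sprintf("ENR_%03d", i)
    } else {
      sets[[i]] <- sample(universe, sizes[i])
      nms[i] <- sprintf("BG_%03d", i)
    }
  }
  names(sets) <- nms
  gene_set_collection(sets,
                      descriptions = ifelse(seq_len(n_sets) %in% enriched_idx,
                                            "planted_enriched", "background"))
}

#' Generate a synthetic interaction network with planted hubs
#'
#' Erdos-Renyi background at the requested mean degree plus `n_hubs` planted
#' nodes each wired to `hub_degree` distinct random partners.
#'
#' @param node_ids character vector of node identifiers.
#' @param mean_degree target background mean degree.
#' @param n_hubs number of planted hub nodes (the first `n_hubs` ids).
#' @param hub_degree degree wired onto each planted hub; must be
#'   < `length(node_ids)`.
#' @param seed RNG seed.
#' @return A list: `edges` (a `ppi_edges` data frame) and `hubs` (planted
#'   hub ids).
#' @export
generate_interactions <- function(node_ids, mean_degree = 4, n_hubs = 0,
                                  hub_degree = 20, seed = 1L) {
  n <- length(node_ids)
  if (n_hubs > n) stop("n_hubs exceeds number of nodes")
  if (n_hubs > 0 && hub_degree >= n) stop("hub_degree must be < n_nodes")
  set.seed(seed)
  p <- if (n > 1) min(1, mean_degree / (n - 1)) else 0
  a <- character(0); b <- character(0)
  if (p > 0 && n > 1) {
    # sample the upper triangle without materializing it
    m <- stats::rbinom(1, n * (n - 1) / 2, p)
    if (m > 0) {
      pick <- sample(n * (n - 1) / 2, m)
      # map linear index of upper triangle (column-major, i < j) to (i, j)
      j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
      i <- pick - (j - 1) * (j - 2) / 2
      a <- node_ids[i]; b <- node_ids[j]
    }
  }
  hubs <- node_ids[seq_len(n_hubs)]
  for (h in hubs) {
    partners <- sample(setdiff(node_ids, h), hub_degree)
    a <- c(a, rep(h, hub_degree)); b <- c(b, partners)
  }
  edges <- if (length(a)) suppressWarnings(ppi_edges(a, b))
           else ppi_edges(character(), character())
  list(edges = edges, hubs = hubs)
}
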