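#' @keywords internal
"_PACKAGE"

COHORT_LEVELS <- c("Sham", "Functional", "Impaired")

#' Construct a quantitation matrix
#'
#' The sole primary input of the pipeline: area-under-the-curve (AUC)
#' abundance values for proteins measured in repeated technical injections of
#' each biological sample. Values are strictly positive; a cell that was not
#' quantified is `NA`. No imputation or substitution happens at this level --
#' the raw matrix stays rule-agnostic because each analysis branch applies a
#' different missing-value rule.
#'
#' @param values numeric matrix, proteins in rows, one column per
#'   (sample, technical replicate); `NA` marks missing cells.
#' @param sample character vector, the sample (rat) id of each column.
#' @param replicate character vector, the technical-replicate label of each
#'   column.
#' @return An object of class `quant_matrix`: a list with elements `values`,
#'   `sample`, `replicate`.
#' @export
quant_matrix <- function(values, sample, replicate) {
  stopifnot(is.matrix(values), length(sample) == ncol(values),
            length(replicate) == ncol(values))
  if (is.null(rownames(values)))
    stop("quant_matrix requires protein ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein_id: ",
         rownames(values)[anyDuplicated(rownames(values))])
  if (anyDuplicated(paste(sample, replicate, sep = ".")))
    stop("duplicate (sample, replicate) column")
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad))
    stop("non-positive AUC at row ", ((bad[1] - 1) %% nrow(values)) + 1,
         ", column ", ((bad[1] - 1) %/% nrow(values)) + 1)
  structure(list(values = values, sample = as.character(sample),
                 replicate = as.character(replicate)),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("quant_matrix:", nrow(x$values), "proteins x",
      length(unique(x$sample)), "samples,",
      ncol(x$values), "replicate columns;",
      sum(is.na(x$values)), "missing cells\n")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Read a quantitation matrix from TSV
#'
#' Expects a header `protein_id` followed by one column per
#' (sample, replicate) named `<sample>.<rep>` (split at the last dot). Cells
#' are positive decimal numbers or a missing token. Identifiers are
#' case-sensitive and never normalized.
#'
#' @param path file path.
#' @param missing_tokens strings treated as missing (default `""` and `"NA"`).
#' @return A [quant_matrix()].
#' @export
read_quant_matrix <- function(path, missing_tokens = c("", "NA")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "protein_id")
    stop("malformed header: first column must be 'protein_id'")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate protein_id: ", ids[duplicated(ids)][1])
  cols <- names(df)[-1]
  if (!all(grepl(".", cols, fixed = TRUE)))
    stop("malformed header: columns must be named <sample>.<replicate>")
  sample <- sub("\\.[^.]*$", "", cols)
  replicate <- sub("^.*\\.", "", cols)
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals %in% missing_tokens] <- NA
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.na(vals) & is.na(num))
  if (length(bad))
    stop("non-numeric cell at row ", ((bad[1] - 1) %% nrow(vals)) + 1,
         ", column ", ((bad[1] - 1) %/% nrow(vals)) + 2)
  bad <- which(!is.na(num) & num <= 0)
  if (length(bad))
    stop("non-positive AUC at row ", ((bad[1] - 1) %% nrow(num)) + 1,
         ", column ", ((bad[1] - 1) %/% nrow(num)) + 2)
  rownames(num) <- ids
  colnames(num) <- cols
  quant_matrix(num, sample, replicate)
}

#' Write a quantitation matrix to TSV
#'
#' Inverse of [read_quant_matrix()]; writes at full double precision so that
#' write-then-read is the identity.
#'
#' @param x a [quant_matrix()].
#' @param path output file path.
#' @export
write_quant_matrix <- function(x, path) {
  df <- data.frame(protein_id = rownames(x$values),
                   as.data.frame(x$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- paste(x$sample, x$replicate, sep = ".")
  write_table(df, path, digits = NA)
}

#' Read a study design from TSV
#'
#' Two columns, `sample_id` and `cohort`; cohorts must be Sham, Functional or
#' Impaired. The irradiated group is defined downstream as Functional plus
#' Impaired.
#'
#' @param path file path.
#' @return A `study_design` data frame with columns `sample_id`, `cohort`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0) stop("no samples in design file")
  if (ncol(df) < 2) stop("design file needs columns sample_id, cohort")
  study_design(df[[1]], df[[2]])
}

#' Construct a study design
#'
#' @param sample_id character vector of unique sample (rat) ids.
#' @param cohort character vector of cohort labels, one of Sham, Functional,
#'   Impaired.
#' @return A `study_design` data frame.
#' @export
study_design <- function(sample_id, cohort) {
  sample_id <- as.character(sample_id)
  cohort <- as.character(cohort)
  if (length(sample_id) == 0) stop("no samples")
  if (anyDuplicated(sample_id))
    stop("duplicate sample: ", sample_id[duplicated(sample_id)][1])
  bad <- setdiff(unique(cohort), COHORT_LEVELS)
  if (length(bad))
    stop("unknown cohort label '", bad[1], "'; allowed: ",
         paste(COHORT_LEVELS, collapse = ", "))
  structure(data.frame(sample_id = sample_id, cohort = cohort,
                       stringsAsFactors = FALSE),
            class = c("study_design", "data.frame"))
}

#' Samples belonging to a cohort or grouping
#'
#' `"Irradiated"` resolves to Functional plus Impaired.
#'
#' @param design a [study_design()].
#' @param group cohort name or `"Irradiated"`.
#' @return Character vector of sample ids.
#' @export
cohort_samples <- function(design, group) {
  if (group == "Irradiated")
    return(design$sample_id[design$cohort %in% c("Functional", "Impaired")])
  if (!group %in% COHORT_LEVELS)
    stop("unknown cohort label '", group, "'; allowed: ",
         paste(c(COHORT_LEVELS, "Irradiated"), collapse = ", "))
  design$sample_id[design$cohort == group]
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Members are deduplicated; the minimum-size filter is applied downstream,
#' not here.
#'
#' @param path file path.
#' @return A `gene_set_collection`: named list of character member vectors,
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate set name: ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, vapply(fields, `[[`, "", 2))
}

#' Construct a gene set collection
#'
#' @param sets named list of character member vectors.
#' @param descriptions optional character vector of set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = rep("", length(sets))) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1])
  sets <- lapply(sets, function(m) unique(as.character(m)))
  structure(sets, descriptions = as.character(descriptions),
            class = "gene_set_collection")
}

#' Write a gene set collection as GMT
#'
#' @param sets a `gene_set_collection`.
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Read an undirected interaction edge list from TSV
#'
#' At least two columns (idA, idB, optional evidence). Edges are undirected
#' and deduplicated; self-loops are dropped with a warning stating how many.
#'
#' @param path file path.
#' @return A `ppi_edges` data frame with columns `a`, `b` (and `evidence`
#'   when present), each unordered pair appearing once with `a < b`.
#' @export
read_edges <- function(path) {
  df <- tryCatch(utils::read.delim(path, header = TRUE, sep = "\t",
                                   colClasses = "character",
                                   check.names = FALSE),
                 error = function(e) data.frame())
  if (nrow(df) == 0)
    return(structure(data.frame(a = character(), b = character(),
                                stringsAsFactors = FALSE),
                     class = c("ppi_edges", "data.frame")))
  if (ncol(df) < 2) stop("edge file needs at least 2 columns")
  ppi_edges(df[[1]], df[[2]],
            evidence = if (ncol(df) >= 3) df[[3]] else NULL)
}

#' Construct an undirected edge set
#'
#' @param a,b character vectors of endpoint ids.
#' @param evidence optional per-edge evidence strings.
#' @return A `ppi_edges` data frame; self-loops dropped (with a warning),
#'   unordered duplicates collapsed, endpoints stored with `a < b`.
#' @export
ppi_edges <- function(a, b, evidence = NULL) {
  a <- as.character(a); b <- as.character(b)
  loops <- a == b
  if (any(loops))
    warning(sum(loops), " self-loop(s) dropped")
  keep <- !loops
  a2 <- pmin(a[keep], b[keep])
  b2 <- pmax(a[keep], b[keep])
  key <- paste(a2, b2, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(a = a2[first], b = b2[first], stringsAsFactors = FALSE)
  if (!is.null(evidence)) out$evidence <- evidence[keep][first]
  structure(out[order(out$a, out$b), , drop = FALSE],
            class = c("ppi_edges", "data.frame"))
}

#' Read a pathway / localization annotation table from TSV
#'
#' One row per id with non-empty `main_pathway` and `sub_pathway` categories;
#' extra columns are carried along.
#'
#' @param path file path.
#' @return An `annotation_table` data frame keyed by `id`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("id", "main_pathway", "sub_pathway")
  if (!all(need %in% names(df)))
    stop("annotation file needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate annotation id: ", df$id[duplicated(df$id)][1])
  if (any(!nzchar(df$main_pathway)) || any(!nzchar(df$sub_pathway)))
    stop("empty pathway category")
  structure(df, class = c("annotation_table", "data.frame"))
}

#' Write a result table as TSV
#'
#' Deterministic byte output for identical input: stable column order, `NA`
#' for missing, numeric columns formatted with C-locale `%g` at a fixed
#' number of significant digits.
#'
#' @param records a data frame.
#' @param path output file path.
#' @param digits significant digits for numeric columns (default 6);
#'   `NA` writes full double precision (17 significant digits), which makes
#'   write-then-read the identity.
#' @export
write_table <- function(records, path, digits = 6) {
  stopifnot(is.data.frame(records))
  fmt <- if (is.na(digits)) "%.17g" else paste0("%.", digits, "g")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- sprintf(fmt, out[[j]])
      s[is.na(out[[j]])] <- "NA"
      out[[j]] <- s
    } else if (is.logical(out[[j]]) || is.integer(out[[j]])) {
      s <- as.character(out[[j]])
      s[is.na(out[[j]])] <- "NA"
      out[[j]] <- s
    } else {
      s <- as.character(out[[j]])
      s[is.na(s)] <- "NA"
      out[[j]] <- s
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               if (nrow(out)) do.call(paste, c(unname(out), sep = "\t"))),
             con)
  invisible(NULL)
}
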