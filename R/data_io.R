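# On-disk formats: UTF-8 TSV, '#'-prefixed comment lines ignored, no quoting.

read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a normalized expression matrix with group labels
#'
#' The matrix file is a GCT-like TSV: header row of sample ids, first column
#' of gene ids, cells are log-scale normalized intensities. Group labels come
#' from a separate two-column TSV (`sample_id`, `group`) with groups `case`
#' and `control`.
#'
#' @param matrix_path Path to the expression TSV.
#' @param groups_path Path to the two-column group-label TSV.
#' @return An `expression_matrix`: list with `values` (numeric matrix,
#'   genes x samples) and `groups` (named character vector, values
#'   `"case"`/`"control"`).
#' @export
read_expression_matrix <- function(matrix_path, groups_path) {
  df <- read_tsv_strict(matrix_path)
  if (ncol(df) < 3L) stop("expression matrix needs >= 2 sample columns")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression matrix")
  values <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values")
  rownames(values) <- genes
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids in expression matrix")
  gdf <- read_tsv_strict(groups_path)
  if (!all(c("sample_id", "group") %in% names(gdf))) {
    stop("group-label file needs columns sample_id, group")
  }
  groups <- stats::setNames(as.character(gdf$group), as.character(gdf$sample_id))
  expression_matrix(values, groups)
}

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   dimnames set.
#' @param groups Named character vector mapping every sample id to `"case"`
#'   or `"control"`; at least 2 samples per group.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene ids (rownames) and sample ids (colnames)")
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad)) stop("group labels must be 'case'/'control', found: ",
                        paste(bad, collapse = ", "))
  if (any(table(factor(groups, c("case", "control"))) < 2L)) {
    stop("need >= 2 samples per group for differential-expression testing")
  }
  structure(list(values = values, groups = groups), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Write an expression matrix and its group labels
#'
#' @param x An `expression_matrix`.
#' @param matrix_path,groups_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_matrix <- function(x, matrix_path, groups_path) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, matrix_path)
  write_tsv_strict(data.frame(sample_id = names(x$groups), group = unname(x$groups),
                              stringsAsFactors = FALSE), groups_path)
  invisible(matrix_path)
}

#' Construct a compound-perturbation rank database
#'
#' The database holds, for each treatment instance (one compound x dose x
#' cell line experiment), a complete ranking of the gene universe. Rank 1 is
#' the gene most up-regulated by the treatment. Each instance's rank vector
#' must be exactly a permutation of `1..n` over the `n`-gene universe.
#'
#' @param ranks Integer matrix, genes (rows, named) x instances (columns,
#'   named); each column a permutation of `1..nrow(ranks)`.
#' @param meta Data frame with columns `instance_id`, `compound`, `dose`,
#'   `cell_line`, one row per instance.
#' @return An object of class `rank_database`.
#' @export
rank_database <- function(ranks, meta) {
  stopifnot(is.matrix(ranks))
  storage.mode(ranks) <- "integer"
  if (is.null(rownames(ranks)) || is.null(colnames(ranks))) {
    stop("rank matrix needs gene symbols (rownames) and instance ids (colnames)")
  }
  if (anyDuplicated(rownames(ranks))) stop("duplicate gene symbols in rank matrix")
  if (anyDuplicated(colnames(ranks))) stop("duplicate instance ids in rank matrix")
  n <- nrow(ranks)
  for (j in seq_len(ncol(ranks))) {
    col <- unname(ranks[, j])
    if (anyNA(col) || !identical(sort(col), seq_len(n))) {
      stop(sprintf("instance '%s': rank column is not a permutation of 1..%d",
                   colnames(ranks)[j], n))
    }
  }
  need <- c("instance_id", "compound", "dose", "cell_line")
  if (!all(need %in% names(meta))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  meta <- as.data.frame(meta)[, need]
  meta[] <- lapply(meta, as.character)
  if (anyDuplicated(meta$instance_id)) stop("duplicate instance ids in metadata")
  only_ranks <- setdiff(colnames(ranks), meta$instance_id)
  only_meta <- setdiff(meta$instance_id, colnames(ranks))
  if (length(only_ranks) || length(only_meta)) {
    stop("rank matrix and metadata disagree on instances; ",
         "missing from metadata: [", paste(only_ranks, collapse = ", "),
         "]; missing from ranks: [", paste(only_meta, collapse = ", "), "]")
  }
  meta <- meta[match(colnames(ranks), meta$instance_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(ranks = ranks, meta = meta), class = "rank_database")
}

#' @export
print.rank_database <- function(x, ...) {
  cat(sprintf("<rank_database> %d genes x %d instances, %d compounds\n",
              nrow(x$ranks), ncol(x$ranks), length(unique(x$meta$compound))))
  invisible(x)
}

#' Read a rank database from TSV files
#'
#' @param rank_path TSV with a header row of instance ids and a first column
#'   of gene symbols; integer cells.
#' @param meta_path TSV with columns `instance_id`, `compound`, `dose`,
#'   `cell_line`.
#' @return A validated [rank_database].
#' @export
read_rank_database <- function(rank_path, meta_path) {
  df <- read_tsv_strict(rank_path, colClasses = NA)
  genes <- as.character(df[[1L]])
  m <- df[, -1L, drop = FALSE]
  for (j in seq_along(m)) {
    if (!is.integer(m[[j]]) && !(is.numeric(m[[j]]) && all(m[[j]] == round(m[[j]])))) {
      stop(sprintf("non-integer rank cell(s) in instance '%s'", names(m)[j]))
    }
  }
  ranks <- as.matrix(m)
  storage.mode(ranks) <- "integer"
  rownames(ranks) <- genes
  meta <- read_tsv_strict(meta_path)
  rank_database(ranks, meta)
}

#' Write a rank database to TSV files
#'
#' @param db A [rank_database].
#' @param rank_path,meta_path Output paths.
#' @return `rank_path`, invisibly.
#' @export
write_rank_database <- function(db, rank_path, meta_path) {
  df <- data.frame(gene = rownames(db$ranks), db$ranks,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, rank_path)
  write_tsv_strict(db$meta, meta_path)
  invisible(rank_path)
}

#' Construct a survival cohort
#'
#' Per-sample biomarker expression with right-censored follow-up. The time
#' unit is whatever the source table uses (declared in the run config, not
#' interpreted here).
#'
#' @param id Character vector of unique sample ids.
#' @param biomarker Numeric expression values.
#' @param time Non-negative follow-up times.
#' @param event 1 = event occurred, 0 = censored.
#' @return An object of class `survival_cohort` (a data frame).
#' @export
survival_cohort <- function(id, biomarker, time, event) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate sample ids in survival cohort")
  time <- as.numeric(time)
  if (anyNA(time) || any(time < 0)) stop("survival times must be >= 0")
  event <- as.numeric(event)
  if (anyNA(event) || !all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  biomarker <- as.numeric(biomarker)
  if (anyNA(biomarker)) stop("missing biomarker values")
  structure(data.frame(id = id, biomarker = biomarker, time = time,
                       event = event, stringsAsFactors = FALSE),
            class = c("survival_cohort", "data.frame"))
}

#' Read a survival table
#'
#' @param path TSV with columns `id`, `biomarker`, `time`, `event`.
#' @return A [survival_cohort].
#' @export
read_survival_table <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("id", "biomarker", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  }
  survival_cohort(df$id, df$biomarker, df$time, df$event)
}

#' Write a survival table
#'
#' @param cohort A [survival_cohort].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(cohort, path) {
  write_tsv_strict(as.data.frame(cohort), path)
}

#' Read an ortholog mapping table
#'
#' Two-column TSV (`source_id`, `human_symbol`), one record per ortholog
#' pair, emulating a HomoloGene-style cross-species table. Exact duplicate
#' records are rejected.
#'
#' @param path Path to the TSV.
#' @return A data frame with columns `source_id` and `human_symbol`.
#' @export
read_ortholog_map <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("source_id", "human_symbol") %in% names(df))) {
    stop("ortholog map needs columns source_id, human_symbol")
  }
  df <- df[, c("source_id", "human_symbol")]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df)) stop("exact duplicate records in ortholog map")
  df
}
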