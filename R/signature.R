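# Differential-expression signature construction: permutation t-tests with
# BH FDR control, then ortholog mapping into a directional query signature.

welch_t_stats <- function(values, is_case) {
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  x1 <- values[, is_case, drop = FALSE]
  x2 <- values[, !is_case, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  d <- m1 - m2
  t <- d / se
  # zero within-group variance: t = 0 when the difference is also zero,
  # +/-Inf otherwise (a constant-but-separated gene is maximally extreme)
  t[se == 0] <- sign(d[se == 0]) * Inf
  t[se == 0 & d == 0] <- 0
  t
}

#' Permutation t-test for two-group differential expression
#'
#' For each gene, computes the observed Welch (unequal-variance) t statistic
#' (case minus control) and a permutation p-value obtained by shuffling the
#' group labels over samples: `p = (1 + #{|t*| >= |t_obs|}) / (1 + B)`. The
#' add-one correction keeps p-values strictly positive, so every p lies in
#' `[1/(B+1), 1]`. The permutation null makes the reference distribution
#' exact regardless of the variance model.
#'
#' A gene with identical values in every sample has `t = 0` and necessarily
#' `p = 1`; such genes are flagged in the `degenerate` column rather than
#' dropped.
#'
#' @param x An [expression_matrix].
#' @param permutations Number of label permutations B (>= 100).
#' @param seed Integer seed; results are bit-identical for identical inputs
#'   and seed.
#' @return A data frame of class `de_result` with columns `gene`, `t`,
#'   `p_perm`, `q` (BH-adjusted, see [adjust_fdr()]) and `degenerate`.
#' @examples
#' cfg <- sim_config(seed = 1, genes = 50, samples_per_group = 4, planted = 5)
#' sim <- simulate_expression(cfg)
#' de <- permutation_t_test(sim$matrix, permutations = 200, seed = 1)
#' head(de)
#' @export
permutation_t_test <- function(x, permutations = 1000L, seed) {
  stopifnot(inherits(x, "expression_matrix"))
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  permutations <- as.integer(permutations)
  if (permutations < 100L) stop("permutations must be >= 100")
  values <- x$values
  is_case <- x$groups == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("need >= 2 samples per group")
  }
  t_obs <- welch_t_stats(values, is_case)
  abs_obs <- abs(t_obs)
  n_samp <- ncol(values)
  n_case <- sum(is_case)
  count <- integer(nrow(values))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(permutations)) {
    perm_case <- logical(n_samp)
    perm_case[sample.int(n_samp, n_case)] <- TRUE
    t_star <- welch_t_stats(values, perm_case)
    count <- count + (abs(t_star) >= abs_obs)
  }
  p <- (1 + count) / (1 + permutations)
  q <- adjust_fdr(p)
  structure(data.frame(gene = rownames(values), t = t_obs, p_perm = p, q = q,
                       degenerate = abs_obs == 0 &
                         rowSums(values != values[, 1L]) == 0,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("de_result", "data.frame"),
            permutations = permutations, seed = seed)
}

# Save/restore the global RNG state so seeded operations do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at
#' 1 and returned in input order (delegates to [stats::p.adjust()] with
#' `method = "BH"`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Map gene ids to human ortholog symbols
#'
#' Genes with exactly one human partner in the map are translated; genes
#' with zero or more than one partner are dropped (many-to-many orthologs
#' would double-count tags in downstream enrichment scoring). Matching is
#' case-insensitive; the map's human spelling is preserved. Translated
#' symbols are deduplicated case-insensitively.
#'
#' @param genes Character vector of source gene ids.
#' @param map Ortholog map data frame (`source_id`, `human_symbol`), e.g.
#'   from [read_ortholog_map()], or `NULL` for the identity mapping.
#' @return List with `symbols` (human symbols, input order) and `report`
#'   (named counts: `mapped`, `unmapped`, `ambiguous`).
#' @export
map_orthologs <- function(genes, map = NULL) {
  genes <- as.character(genes)
  if (is.null(map)) {
    return(list(symbols = genes[!duplicated(fold(genes))],
                report = c(mapped = length(genes), unmapped = 0L, ambiguous = 0L)))
  }
  if (length(genes) == 0L) {
    return(list(symbols = character(0),
                report = c(mapped = 0L, unmapped = 0L, ambiguous = 0L)))
  }
  src_fold <- fold(map$source_id)
  # distinct human partners per source id, case-insensitively
  partners <- tapply(fold(map$human_symbol), src_fold,
                     function(h) length(unique(h)))
  g_fold <- fold(genes)
  n_part <- partners[g_fold]
  n_part[is.na(n_part)] <- 0L
  unmapped <- sum(n_part == 0L)
  ambiguous <- sum(n_part > 1L)
  ok <- n_part == 1L
  idx <- match(g_fold[ok], src_fold)
  symbols <- map$human_symbol[idx]
  symbols <- symbols[!duplicated(fold(symbols))]
  list(symbols = symbols,
       report = c(mapped = sum(ok), unmapped = unmapped, ambiguous = ambiguous))
}

#' Build a directional gene signature from differential-expression results
#'
#' Genes with `q < fdr_threshold` are split by the sign of the t statistic
#' into up- and down-regulated tag lists, then translated to human symbols
#' via [map_orthologs()]. A signature with one empty side is allowed but
#' flagged with a warning; zero passing genes is an error.
#'
#' @param de A `de_result` from [permutation_t_test()].
#' @param fdr_threshold FDR cutoff in (0, 1); default 0.05.
#' @param map Ortholog map (or `NULL` for identity).
#' @param name Base name for the signature's tag lists.
#' @return A `gene_signature`: list with `up` and `down` [gene_set]s,
#'   `fdr_threshold`, `provenance` and the ortholog `mapping_report`.
#' @export
build_signature <- function(de, fdr_threshold = 0.05, map = NULL,
                            name = "SIGNATURE") {
  stopifnot(inherits(de, "de_result") || all(c("gene", "t", "q") %in% names(de)))
  if (!(fdr_threshold > 0 && fdr_threshold < 1)) {
    stop("fdr_threshold must lie in (0, 1)")
  }
  pass <- de$q < fdr_threshold
  if (!any(pass)) {
    stop("no genes pass FDR < ", fdr_threshold,
         "; inspect the data or relax the threshold")
  }
  up_src <- de$gene[pass & de$t > 0]
  dn_src <- de$gene[pass & de$t < 0]
  up_map <- map_orthologs(up_src, map)
  dn_map <- map_orthologs(dn_src, map)
  report <- up_map$report + dn_map$report
  if (length(up_map$symbols) == 0L && length(dn_map$symbols) == 0L) {
    stop("no signature genes survive ortholog mapping")
  }
  one_sided <- length(up_map$symbols) == 0L || length(dn_map$symbols) == 0L
  if (one_sided) {
    warning("one-sided signature: one direction has no genes")
  }
  mk <- function(genes, suffix) {
    if (length(genes) == 0L) NULL
    else gene_set(paste0(name, suffix), genes,
                  description = sprintf("q < %g, %s-regulated in cases",
                                        fdr_threshold,
                                        if (suffix == "_UP") "up" else "down"))
  }
  structure(list(up = mk(up_map$symbols, "_UP"),
                 down = mk(dn_map$symbols, "_DN"),
                 fdr_threshold = fdr_threshold,
                 provenance = sprintf(
                   "Welch permutation t-test (B = %s, seed = %s), BH FDR < %g; %d up, %d down",
                   attr(de, "permutations") %||% NA,
                   attr(de, "seed") %||% NA, fdr_threshold,
                   length(up_map$symbols), length(dn_map$symbols)),
                 mapping_report = report),
            class = "gene_signature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a gene signature from explicit tag lists
#'
#' For signatures that do not come out of [build_signature()] — e.g. a
#' published gene list. Direction is always explicit: a signature must have
#' at least one of `up`/`down`, and the two must be disjoint
#' (case-insensitively).
#'
#' @param up,down [gene_set]s or character vectors (either may be `NULL`
#'   for a one-sided signature).
#' @param fdr_threshold FDR threshold the lists were derived at, if any.
#' @param provenance Free-text origin description.
#' @return A `gene_signature`.
#' @export
gene_signature <- function(up = NULL, down = NULL, fdr_threshold = NA_real_,
                           provenance = "user-supplied tag lists") {
  mk <- function(x, nm) {
    if (is.null(x)) NULL
    else if (inherits(x, "gene_set")) x
    else gene_set(nm, x)
  }
  up <- mk(up, "SIGNATURE_UP")
  down <- mk(down, "SIGNATURE_DN")
  if (is.null(up) && is.null(down)) {
    stop("a signature needs at least one of up/down tag lists")
  }
  if (!is.null(up) && !is.null(down) &&
      length(intersect(fold(up$genes), fold(down$genes)))) {
    stop("up and down tag lists overlap")
  }
  structure(list(up = up, down = down, fdr_threshold = fdr_threshold,
                 provenance = provenance,
                 mapping_report = c(mapped = NA, unmapped = NA, ambiguous = NA)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> up: %d, down: %d (FDR < %g)\n",
              if (is.null(x$up)) 0L else length(x$up$genes),
              if (is.null(x$down)) 0L else length(x$down$genes),
              x$fdr_threshold))
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Write a signature as a two-set GMT plus a JSON sidecar
#'
#' The GMT carries the `_UP` and `_DN` tag lists; the sidecar records the
#' FDR threshold, provenance string and ortholog mapping report.
#'
#' @param sig A `gene_signature`.
#' @param gmt_path,json_path Output paths (`json_path` defaults to the GMT
#'   path with a `.json` extension).
#' @return `gmt_path`, invisibly.
#' @export
write_signature <- function(sig, gmt_path,
                            json_path = sub("\\.gmt$", ".json", gmt_path)) {
  sets <- Filter(Negate(is.null), list(sig$up, sig$down))
  write_gmt(sets, gmt_path)
  jsonlite::write_json(list(fdr_threshold = sig$fdr_threshold,
                            provenance = sig$provenance,
                            mapping_report = as.list(sig$mapping_report),
                            up = length(sig$up$genes %||% character(0)),
                            down = length(sig$down$genes %||% character(0))),
                       json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(gmt_path)
}

#' Read a signature written by [write_signature()]
#'
#' @param gmt_path Path to the two-set GMT (`*_UP`, `*_DN` suffixes).
#' @return A `gene_signature` (FDR threshold and provenance restored from the
#'   sidecar when present).
#' @export
read_signature <- function(gmt_path) {
  sets <- read_gmt(gmt_path)
  up <- sets[grepl("_UP$", names(sets))]
  dn <- sets[grepl("_DN$", names(sets))]
  if (length(up) + length(dn) == 0L) {
    stop("no _UP/_DN sets found in '", gmt_path,
         "'; signatures must carry explicit direction")
  }
  if (length(up) > 1L || length(dn) > 1L) {
    stop("expected at most one _UP and one _DN set in '", gmt_path, "'")
  }
  json_path <- sub("\\.gmt$", ".json", gmt_path)
  meta <- if (file.exists(json_path)) jsonlite::read_json(json_path) else list()
  structure(list(up = if (length(up)) up[[1L]] else NULL,
                 down = if (length(dn)) dn[[1L]] else NULL,
                 fdr_threshold = meta$fdr_threshold %||% NA_real_,
                 provenance = meta$provenance %||% paste("read from", gmt_path),
                 mapping_report = unlist(meta$mapping_report %||%
                                           c(mapped = NA, unmapped = NA, ambiguous = NA))),
            class = "gene_signature")
}
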