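# KS-based connectivity scoring of a directional signature against a
# compound-perturbation rank database, with permutation p-values and
# reversal-candidate selection.

#' Tag list: signature genes restricted to a database universe
#'
#' Restricts a [gene_set] to the genes present in a rank database's
#' universe (case-insensitive). Absent tags are dropped with a warning; an
#' empty result is an error.
#'
#' @param genes A [gene_set] or character vector of gene symbols.
#' @param universe Character vector of database gene symbols.
#' @param direction `"up"` or `"down"`.
#' @return A `tag_list`: list with `genes` (universe spellings), `direction`
#'   and `n_dropped`.
#' @export
tag_list <- function(genes, universe, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- as.character(genes)
  idx <- match_fold(genes, universe)
  dropped <- sum(is.na(idx))
  if (dropped == length(genes)) {
    stop("no tag genes present in the database universe")
  }
  if (dropped > 0L) {
    warning(sprintf("%d of %d tag genes absent from the universe; dropped",
                    dropped, length(genes)))
  }
  structure(list(genes = universe[idx[!is.na(idx)]], direction = direction,
                 n_dropped = dropped),
            class = "tag_list")
}

# Core KS running-maximum statistic on sorted tag ranks V (1-based positions
# in a list of length n). Exposed via ks_tag_score().
ks_from_ranks <- function(V, n) {
  t <- length(V)
  if (t == n) return(0)  # tags cover the whole list: uninformative
  V <- sort(V)
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' Kolmogorov-Smirnov tag enrichment score
#'
#' Measures whether a tag set concentrates at the top (positive) or bottom
#' (negative) of a ranked list. With the sorted tag ranks
#' `V(1) < ... < V(t)` in a list of length `n`:
#' `a = max_j [ j/t - V(j)/n ]`, `b = max_j [ V(j)/n - (j-1)/t ]`, and the
#' score is `a` if `a >= b`, else `-b`. Always in `[-1, 1]`. A tag list that
#' covers the entire universe (`t = n`) carries no positional information and
#' scores 0.
#'
#' @param tags A [tag_list], [gene_set] or character vector of tag genes.
#' @param ranking Named integer vector: gene symbol -> rank, a permutation of
#'   `1..n` with rank 1 the most up-regulated gene.
#' @return Enrichment score in `[-1, 1]`.
#' @examples
#' ranking <- stats::setNames(1:10, paste0("G", 1:10))
#' ks_tag_score("G1", ranking)   #  0.9: single tag at the top
#' ks_tag_score("G10", ranking)  # -1.0: single tag at the bottom
#' @export
ks_tag_score <- function(tags, ranking) {
  n <- length(ranking)
  stopifnot(n >= 1L, !is.null(names(ranking)))
  if (inherits(tags, "tag_list")) {
    tags <- tags$genes
  } else if (inherits(tags, "gene_set")) {
    tags <- tags$genes
  }
  idx <- match_fold(tags, names(ranking))
  if (all(is.na(idx))) stop("no tag genes present in the ranking")
  if (anyNA(idx)) {
    warning(sprintf("%d tag gene(s) absent from the ranking; dropped",
                    sum(is.na(idx))))
    idx <- idx[!is.na(idx)]
  }
  ks_from_ranks(as.numeric(ranking[idx]), n)
}

#' Connectivity of one instance with a directional signature
#'
#' Scores the up and down tag lists separately against the instance's
#' ranking, then combines: `raw = es_up - es_down` when the two scores have
#' opposite signs (a zero score counts as opposite to either), and `raw = 0`
#' when they share a sign — concordant displacement of both lists is treated
#' as no evidence of connection. `raw` lies in `[-2, 2]`; negative values
#' mean the instance reverses the signature.
#'
#' @param up,down [tag_list]s (or gene vectors); must be disjoint.
#' @param ranking Named rank vector as in [ks_tag_score()].
#' @return List with `es_up`, `es_down`, `raw`.
#' @export
instance_connectivity <- function(up, down, ranking) {
  up_genes <- if (inherits(up, "tag_list")) up$genes else up
  dn_genes <- if (inherits(down, "tag_list")) down$genes else down
  if (length(intersect(fold(up_genes), fold(dn_genes)))) {
    stop("up and down tag lists overlap")
  }
  es_up <- ks_tag_score(up_genes, ranking)
  es_down <- ks_tag_score(dn_genes, ranking)
  raw <- if (es_up != 0 && es_down != 0 && sign(es_up) == sign(es_down)) 0
         else es_up - es_down
  list(es_up = es_up, es_down = es_down, raw = raw)
}

#' Score every instance of a rank database against a signature
#'
#' @param db A [rank_database].
#' @param signature A `gene_signature` (see [build_signature()]); a
#'   one-sided signature scores the missing side as 0.
#' @return Data frame with one row per instance: `instance_id`, `compound`,
#'   `es_up`, `es_down`, `raw`, `scaled` (see [scale_scores()]).
#' @export
score_instances <- function(db, signature) {
  stopifnot(inherits(db, "rank_database"))
  universe <- rownames(db$ranks)
  up <- if (!is.null(signature$up)) tag_list(signature$up, universe, "up") else NULL
  dn <- if (!is.null(signature$down)) tag_list(signature$down, universe, "down") else NULL
  if (is.null(up) && is.null(dn)) stop("signature has no usable tag lists")
  if (!is.null(up) && !is.null(dn) &&
      length(intersect(fold(up$genes), fold(dn$genes)))) {
    stop("up and down tag lists overlap")
  }
  up_idx <- if (is.null(up)) integer(0) else match(up$genes, universe)
  dn_idx <- if (is.null(dn)) integer(0) else match(dn$genes, universe)
  n <- nrow(db$ranks)
  res <- data.frame(instance_id = colnames(db$ranks),
                    compound = db$meta$compound,
                    es_up = 0, es_down = 0, raw = 0, scaled = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(db$ranks))) {
    col <- db$ranks[, i]
    es_up <- if (length(up_idx)) ks_from_ranks(col[up_idx], n) else 0
    es_dn <- if (length(dn_idx)) ks_from_ranks(col[dn_idx], n) else 0
    res$es_up[i] <- es_up
    res$es_down[i] <- es_dn
    res$raw[i] <- if (es_up != 0 && es_dn != 0 && sign(es_up) == sign(es_dn)) 0
                  else es_up - es_dn
  }
  scale_scores(res)
}

#' Scale raw instance connectivity scores to \[-1, 1\]
#'
#' Positive raw scores are divided by the maximum positive raw score,
#' negative scores by the absolute value of the minimum negative score;
#' zeros stay zero. If one side has no values its divisor is 1.
#'
#' @param scores Data frame with a `raw` column (as from
#'   [score_instances()]).
#' @return The same data frame with `scaled` filled in.
#' @export
scale_scores <- function(scores) {
  stopifnot(nrow(scores) >= 1L, "raw" %in% names(scores))
  raw <- scores$raw
  pos_max <- if (any(raw > 0)) max(raw[raw > 0]) else 1
  neg_min <- if (any(raw < 0)) abs(min(raw[raw < 0])) else 1
  scaled <- numeric(length(raw))
  scaled[raw > 0] <- raw[raw > 0] / pos_max
  scaled[raw < 0] <- raw[raw < 0] / neg_min
  scores$scaled <- scaled
  scores
}

# Deterministic instance ordering for compound-level enrichment:
# descending raw score, ties broken by instance id ascending.
instance_order <- function(scores) {
  order(-scores$raw, scores$instance_id)
}

#' Compound-level enrichment score
#'
#' Orders all instances by raw connectivity (descending, ties broken by
#' instance id ascending for bit-reproducibility), treats the compound's
#' instances as tags in that ordering, and returns their [ks_tag_score()].
#' Negative values mean the compound's instances cluster among the strongest
#' signature reversers.
#'
#' @param db A [rank_database].
#' @param scores Instance scores from [score_instances()].
#' @param compound Compound name (must have >= 1 instance).
#' @return Enrichment score in `[-1, 1]`.
#' @export
compound_enrichment <- function(db, scores, compound) {
  ord <- instance_order(scores)
  tag_pos <- which(scores$compound[ord] == compound)
  if (length(tag_pos) == 0L) stop("unknown compound: ", compound)
  ks_from_ranks(as.numeric(tag_pos), nrow(scores))
}

# Vectorized KS over B random tag-position draws (columns of a t x B matrix).
ks_null_distribution <- function(t, N, B) {
  V <- matrix(0, nrow = t, ncol = B)
  for (b in seq_len(B)) V[, b] <- sort.int(sample.int(N, t))
  j <- seq_len(t) / t
  jm1 <- (seq_len(t) - 1) / t
  a <- rep(-Inf, B)
  bb <- rep(-Inf, B)
  for (i in seq_len(t)) {
    a <- pmax(a, j[i] - V[i, ] / N)
    bb <- pmax(bb, V[i, ] / N - jm1[i])
  }
  ifelse(a >= bb, a, -bb)
}

#' Permutation p-value for a compound's enrichment score
#'
#' Draws `permutations` random instance subsets of the same size as the
#' compound's and recomputes the enrichment; the two-sided p-value is
#' `(1 + #{|es*| >= |es_obs|}) / (1 + B)`. Deterministic given the seed.
#'
#' @param db A [rank_database].
#' @param scores Instance scores from [score_instances()].
#' @param compound Compound name.
#' @param permutations Number of random subsets B (>= 100).
#' @param seed Integer seed.
#' @param sided `"two"` (default) or `"one"` (lower tail on the observed
#'   sign: counts `es* <= es_obs` for negative observations, `es* >= es_obs`
#'   for positive ones).
#' @return p-value in `[1/(B+1), 1]`.
#' @export
compound_p_value <- function(db, scores, compound, permutations = 10000L, seed,
                             sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  permutations <- as.integer(permutations)
  if (permutations < 100L) stop("permutations must be >= 100")
  es_obs <- compound_enrichment(db, scores, compound)
  t <- sum(scores$compound == compound)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  es_null <- if (t == nrow(scores)) rep(0, permutations)
             else ks_null_distribution(t, nrow(scores), permutations)
  k <- if (sided == "two") sum(abs(es_null) >= abs(es_obs))
       else if (es_obs < 0) sum(es_null <= es_obs) else sum(es_null >= es_obs)
  (1 + k) / (1 + permutations)
}

#' Screen a rank database for signature-reversing compounds
#'
#' Scores every instance against the signature, aggregates instances to
#' compounds, attaches permutation p-values, and flags compounds with
#' negative enrichment and `p <= alpha` as selected reversal candidates.
#'
#' @param db A [rank_database].
#' @param signature A `gene_signature`.
#' @param alpha Selection threshold on the enrichment p-value (default
#'   0.05).
#' @param permutations Permutations per compound p-value.
#' @param seed Integer seed (per-compound streams are derived from it, so
#'   results do not depend on compound order).
#' @param sided Sidedness of the p-value; see [compound_p_value()].
#' @param selected_only If `TRUE`, return only the selected compounds
#'   (enrichment < 0 and `p <= alpha`).
#' @return A `screen_result` data frame sorted by enrichment ascending (most
#'   negative first) with columns `compound`, `n_instances`,
#'   `enrichment_score`, `p_value`, `selected`. The instance-level score
#'   table is attached as attribute `"instance_scores"`.
#' @export
screen_compounds <- function(db, signature, alpha = 0.05,
                             permutations = 10000L, seed,
                             sided = c("two", "one"), selected_only = FALSE) {
  sided <- match.arg(sided)
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  scores <- score_instances(db, signature)
  compounds <- sort(unique(db$meta$compound))
  res <- data.frame(compound = compounds,
                    n_instances = as.integer(table(db$meta$compound)[compounds]),
                    enrichment_score = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(compounds)) {
    res$enrichment_score[i] <- compound_enrichment(db, scores, compounds[i])
    res$p_value[i] <- compound_p_value(db, scores, compounds[i],
                                       permutations = permutations,
                                       seed = seed + i, sided = sided)
  }
  res$selected <- res$enrichment_score < 0 & res$p_value <= alpha
  res <- res[order(res$enrichment_score, res$compound), , drop = FALSE]
  rownames(res) <- NULL
  if (selected_only) res <- res[res$selected, , drop = FALSE]
  structure(res, class = c("screen_result", "data.frame"),
            instance_scores = scores, alpha = alpha,
            permutations = permutations, seed = seed, sided = sided)
}
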