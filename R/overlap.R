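# Hypergeometric overlap of two gene sets against a protein-coding
# background: observed intersection, expected count, exact point and
# upper-tail probabilities.

#' Default protein-coding background size
#'
#' Number of human protein-coding genes (NCBI CCDS release 21), shipped as a
#' documented default for headless runs when no background universe file is
#' supplied.
#' @export
DEFAULT_BACKGROUND_SIZE <- 20354L

#' Intersect two gene sets within a background
#'
#' Case-insensitive intersection. Genes outside the background are dropped
#' with a warning before intersecting; the result is symmetric in its first
#' two arguments.
#'
#' @param a,b [gene_set] objects (or character vectors).
#' @param background Background [gene_set]/character vector, or `NULL` to
#'   skip membership filtering (set sizes are then taken at face value).
#' @return List with `k` (observed overlap), `genes` (overlap, spelled as in
#'   `a`), and the background-restricted sizes `size_a`, `size_b`.
#' @export
intersect_sets <- function(a, b, background = NULL) {
  ga <- if (inherits(a, "gene_set")) a$genes else as.character(a)
  gb <- if (inherits(b, "gene_set")) b$genes else as.character(b)
  if (!is.null(background)) {
    bg <- if (inherits(background, "gene_set")) background$genes
          else as.character(background)
    if (length(bg) == 0L) stop("empty background")
    drop_a <- is.na(match_fold(ga, bg))
    drop_b <- is.na(match_fold(gb, bg))
    if (any(drop_a) || any(drop_b)) {
      warning(sprintf("dropped genes absent from background: %d from set 1, %d from set 2",
                      sum(drop_a), sum(drop_b)))
    }
    ga <- ga[!drop_a]
    gb <- gb[!drop_b]
  }
  hit <- !is.na(match_fold(ga, gb))
  list(k = sum(hit), genes = ga[hit],
       size_a = length(ga), size_b = length(gb))
}

#' Expected overlap of two sets drawn from a common background
#'
#' Under the hypergeometric model the expected intersection of a `K`-gene
#' set and an `n_draw`-gene set in an `N`-gene background is
#' `K * n_draw / N`.
#'
#' @param K,n_draw Set sizes (within the background).
#' @param N Background size (>= 1).
#' @return Expected number of shared genes.
#' @examples
#' expected_overlap(160, 122, 20354)  # 0.959
#' @export
expected_overlap <- function(K, n_draw, N) {
  if (N < 1) stop("background size N must be >= 1")
  if (K < 0 || n_draw < 0 || K > N || n_draw > N) {
    stop("set sizes must satisfy 0 <= K, n_draw <= N")
  }
  K * n_draw / N
}

check_hyper_params <- function(K, n_draw, N) {
  if (N < 1) stop("background size N must be >= 1")
  if (K < 0 || n_draw < 0 || K > N || n_draw > N) {
    stop("set sizes must satisfy 0 <= K, n_draw <= N")
  }
}

#' Hypergeometric point and tail probabilities for a gene-set overlap
#'
#' `hypergeom_point()` is the probability of exactly `k` shared genes,
#' `C(K,k) C(N-K, n_draw-k) / C(N, n_draw)`; `hypergeom_tail()` the
#' probability of `k` or more. Both are computed in log space (via R's
#' hypergeometric distribution functions) and remain finite and in `[0, 1]`
#' for backgrounds well beyond 10^6 genes. Out-of-support `k` gives point
#' probability 0 and the appropriate degenerate tail (1 below the support,
#' 0 above).
#'
#' @param k Observed overlap count.
#' @param K Size of the first set within the background.
#' @param n_draw Size of the second set within the background.
#' @param N Background size.
#' @return A probability in `[0, 1]`.
#' @examples
#' hypergeom_point(1, 160, 122, 20354)  # 0.37: one shared gene
#' hypergeom_tail(1, 160, 122, 20354)   # 0.62: one or more shared genes
#' @export
hypergeom_point <- function(k, K, n_draw, N) {
  check_hyper_params(K, n_draw, N)
  stats::dhyper(k, m = K, n = N - K, k = n_draw)
}

#' @rdname hypergeom_point
#' @export
hypergeom_tail <- function(k, K, n_draw, N) {
  check_hyper_params(K, n_draw, N)
  stats::phyper(k - 1, m = K, n = N - K, k = n_draw, lower.tail = FALSE)
}

#' Quantify the overlap between two gene sets
#'
#' Full overlap analysis: observed intersection, expected count under the
#' hypergeometric model, and both the point probability of exactly `k`
#' shared genes and the upper-tail probability of `k` or more. Both
#' probabilities are always reported, explicitly labelled — the point mass
#' answers "how likely is exactly this overlap", the tail "how likely is an
#' overlap at least this large" — and neither is silently preferred.
#'
#' @param a,b [gene_set] objects or character vectors.
#' @param background Background gene universe, or `NULL` to use
#'   `background_size` without membership filtering.
#' @param background_size Background size `N` when no explicit universe is
#'   given; defaults to [DEFAULT_BACKGROUND_SIZE].
#' @return An `overlap_result`: list with `k`, `expected`, `p_point`,
#'   `p_tail`, `N`, `K`, `n_draw` and `genes` (the overlapping symbols).
#' @examples
#' r <- overlap_test(paste0("G", 1:122), c("G1", paste0("X", 1:159)),
#'                   background_size = 20354)
#' r$k          # 1
#' r$p_point    # 0.37
#' @export
overlap_test <- function(a, b, background = NULL,
                         background_size = DEFAULT_BACKGROUND_SIZE) {
  inter <- intersect_sets(a, b, background)
  N <- if (!is.null(background)) {
    length(if (inherits(background, "gene_set")) background$genes else background)
  } else as.integer(background_size)
  K <- inter$size_b
  n_draw <- inter$size_a
  check_hyper_params(K, n_draw, N)
  structure(list(k = inter$k,
                 expected = expected_overlap(K, n_draw, N),
                 p_point = hypergeom_point(inter$k, K, n_draw, N),
                 p_tail = hypergeom_tail(inter$k, K, n_draw, N),
                 N = N, K = K, n_draw = n_draw, genes = inter$genes),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> k = %d of (K = %d, n = %d, N = %d)\n",
              x$k, x$K, x$n_draw, x$N))
  cat(sprintf("  expected by chance: %.3f\n", x$expected))
  cat(sprintf("  P(exactly %d)  = %.4g (hypergeometric point probability)\n",
              x$k, x$p_point))
  cat(sprintf("  P(>= %d)       = %.4g (hypergeometric upper tail)\n",
              x$k, x$p_tail))
  if (x$k > 0) cat("  overlap:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}
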