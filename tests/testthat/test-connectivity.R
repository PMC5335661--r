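test_that("KS tag score matches direct substitution on worked examples", {
  ranking <- make_ranking(1:10, paste0("G", 1:10))
  expect_equal(ks_tag_score("G1", ranking), 0.9)    # single tag at the top
  expect_equal(ks_tag_score("G10", ranking), -1.0)  # single tag at the bottom

  # n = 4, tags at ranks {1, 2}: a = max(0.25, 0.5), b = max(0.25, 0)
  ranking4 <- make_ranking(1:4, paste0("G", 1:4))
  expect_equal(ks_tag_score(c("G1", "G2"), ranking4), 0.5)

  # absent tags dropped with warning; all absent is an error
  expect_warning(es <- ks_tag_score(c("G1", "ZZZ"), ranking), "absent")
  expect_equal(es, 0.9)
  expect_error(ks_tag_score(c("AA", "BB"), ranking), "no tag genes")
})

test_that("KS tag score equals the position-walking oracle for all n <= 8, t <= 3", {
  for (n in 1:8) {
    genes <- paste0("G", seq_len(n))
    for (t in 1:min(3, n)) {
      combos <- utils::combn(n, t)
      for (j in seq_len(ncol(combos))) {
        V <- combos[, j]
        ranking <- make_ranking(seq_len(n), genes)
        expect_identical(ks_tag_score(genes[V], ranking), ks_oracle(V, n))
      }
    }
  }
})

test_that("KS tag score stays in [-1, 1] and is antisymmetric under reversal", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    t <- sample.int(n - 1, 1)
    perm <- sample.int(n)
    genes <- paste0("G", seq_len(n))
    ranking <- make_ranking(perm, genes)
    tags <- sample(genes, t)
    es <- ks_tag_score(tags, ranking)
    expect_true(es >= -1 && es <= 1)
    expect_equal(es, ks_oracle(sort(perm[match(tags, genes)]), n))
  }
  # single-tag reversal: a tag at rank k against a tag at rank n+1-k flips
  # sign up to an exact -1/n shift, because the running maxima use j/t on
  # the hit side but (j-1)/t on the miss side: ES(k) + ES(n+1-k) = -1/n
  n <- 20
  genes <- paste0("G", 1:n)
  for (k in c(1, 2, 7, 10, 13, 20)) {
    fwd <- ks_tag_score(genes[k], make_ranking(1:n, genes))
    rev <- ks_tag_score(genes[n + 1 - k], make_ranking(1:n, genes))
    expect_equal(fwd + rev, -1 / n, tolerance = 1e-12)
  }
})

test_that("instance connectivity applies the same-sign zero rule", {
  # build rankings realizing the stated (es_up, es_down) combinations
  n <- 10
  genes <- paste0("G", 1:n)
  up <- genes[1]   # rank 1 -> es_up = 0.9
  dn <- genes[10]  # rank 10 -> es_down = -1
  r <- instance_connectivity(up, dn, make_ranking(1:n, genes))
  expect_gt(r$es_up, 0)
  expect_lt(r$es_down, 0)
  expect_equal(r$raw, r$es_up - r$es_down)  # opposite signs combine

  # both tags near the top: same sign, raw = 0
  r2 <- instance_connectivity(genes[1], genes[2], make_ranking(1:n, genes))
  expect_gt(r2$es_up, 0)
  expect_gt(r2$es_down, 0)
  expect_equal(r2$raw, 0)

  # reversed signature: up at the bottom, down at the top -> raw < 0
  r3 <- instance_connectivity(genes[10], genes[1], make_ranking(1:n, genes))
  expect_equal(r3$raw, r3$es_up - r3$es_down)
  expect_lt(r3$raw, 0)

  expect_error(instance_connectivity(c("G1", "G2"), c("g2", "G3"),
                                     make_ranking(1:n, genes)),
               "overlap")
})

test_that("raw score scaling is per-side with zeros preserved", {
  df <- data.frame(instance_id = c("a", "b", "c"), raw = c(1.8, 0.9, -0.6))
  out <- scale_scores(df)
  expect_equal(out$scaled, c(1.0, 0.5, -1.0))

  df0 <- data.frame(instance_id = "a", raw = 0)
  expect_equal(scale_scores(df0)$scaled, 0)

  df1 <- data.frame(instance_id = "a", raw = -0.3)
  expect_equal(scale_scores(df1)$scaled, -1.0)

  dfz <- data.frame(instance_id = c("a", "b"), raw = c(0, 0))
  expect_equal(scale_scores(dfz)$scaled, c(0, 0))
})

# A tiny database where instance raw scores are controlled by construction:
# instance k has the signature's up-gene at rank k (of n), so raw scores are
# strictly decreasing in k and the instance ordering is known.
make_controlled_db <- function(n_genes = 11, n_inst = 10) {
  genes <- paste0("G", seq_len(n_genes))
  ranks <- matrix(0L, n_genes, n_inst,
                  dimnames = list(genes, sprintf("i%02d", seq_len(n_inst))))
  for (k in seq_len(n_inst)) {
    others <- setdiff(seq_len(n_genes), 1L)
    ranks[1L, k] <- k
    ranks[others, k] <- setdiff(seq_len(n_genes), k)
  }
  meta <- data.frame(instance_id = colnames(ranks),
                     compound = sprintf("cmp%02d", seq_len(n_inst)),
                     dose = "d", cell_line = "c")
  rank_database(ranks, meta)
}

test_that("compound enrichment reduces to KS over the instance ordering", {
  db <- make_controlled_db()
  sig <- gene_signature(up = "G1")
  scores <- score_instances(db, sig)
  # raw scores strictly decreasing in instance index
  expect_true(all(diff(scores$raw) < 0))

  # compound owning the single top instance of N = 10 scores 0.9
  expect_equal(compound_enrichment(db, scores, "cmp01"), 0.9)
  # compound owning the bottom instance scores -1
  expect_equal(compound_enrichment(db, scores, "cmp10"), -1.0)
  expect_error(compound_enrichment(db, scores, "nope"), "unknown compound")

  # a compound owning every instance is degenerate and scores 0
  meta_all <- db$meta
  meta_all$compound <- "only"
  db_all <- rank_database(db$ranks, meta_all)
  scores_all <- score_instances(db_all, sig)
  expect_equal(compound_enrichment(db_all, scores_all, "only"), 0)
})

test_that("compound p-values hit the formula floor and are deterministic", {
  db <- make_controlled_db()
  sig <- gene_signature(up = "G1")
  scores <- score_instances(db, sig)
  # cmp10 is the single most extreme instance: |es| = 1 can only be tied,
  # never beaten, and with t = 1 of N = 10 ties are rare
  p <- compound_p_value(db, scores, "cmp10", permutations = 100, seed = 3)
  expect_gte(p, 1 / 101)
  p2 <- compound_p_value(db, scores, "cmp10", permutations = 100, seed = 3)
  expect_identical(p, p2)
  # one-sided option counts only the observed tail
  p1s <- compound_p_value(db, scores, "cmp10", permutations = 100, seed = 3,
                          sided = "one")
  expect_lte(p1s, p + 1e-12)
})

test_that("screen table has Table-1-style layout and strict selection rule", {
  cfg <- sim_config(seed = 5, genes = 300, instances = 60, compounds = 12,
                    antagonists = 1, strength = 1)
  sig <- gene_signature(up = sprintf("GENE%04d", 1:30),
                        down = sprintf("GENE%04d", 31:60))
  rdb <- simulate_rank_database(cfg, sig)
  res <- screen_compounds(rdb$db, sig, alpha = 0.05, permutations = 200,
                          seed = 5)
  expect_s3_class(res, "screen_result")
  expect_named(res, c("compound", "n_instances", "enrichment_score",
                      "p_value", "selected"))
  # sorted by enrichment ascending; most negative first
  expect_true(all(diff(res$enrichment_score) >= 0))
  expect_identical(res$selected,
                   res$enrichment_score < 0 & res$p_value <= 0.05)
  # the planted antagonist is the top reverser
  expect_equal(res$compound[1L],
               rdb$truth$compound[rdb$truth$role == "antagonist"])
  expect_true(res$selected[1L])

  # a database where no compound passes gives an empty table, not an error
  cfg0 <- sim_config(seed = 6, genes = 300, instances = 20, compounds = 4,
                     antagonists = 0)
  rdb0 <- simulate_rank_database(cfg0, sig)
  res0 <- screen_compounds(rdb0$db, sig, alpha = 1e-3, permutations = 200,
                           seed = 6, selected_only = TRUE)
  expect_equal(nrow(res0), 0L)
})

test_that("screening is reproducible for a fixed seed", {
  cfg <- sim_config(seed = 8, genes = 200, instances = 40, compounds = 8)
  sig <- gene_signature(up = sprintf("GENE%04d", 1:20),
                        down = sprintf("GENE%04d", 21:40))
  rdb <- simulate_rank_database(cfg, sig)
  r1 <- screen_compounds(rdb$db, sig, permutations = 200, seed = 42)
  r2 <- screen_compounds(rdb$db, sig, permutations = 200, seed = 42)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
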