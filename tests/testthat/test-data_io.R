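test_that("GMT parsing handles well-formed sets, dedup, and malformed lines", {
  f <- tmpfile(c("setA\tdesc\tG1\tG2",
                 "# a comment",
                 "setC\td\tX1\tX2\tX3"))
  sets <- read_gmt(f)
  expect_named(sets, c("setA", "setC"))
  expect_equal(sets$setA$genes, c("G1", "G2"))
  expect_equal(length(sets$setC), 3L)

  # case-insensitive dedup collapses with a warning, first spelling kept
  f2 <- tmpfile("setB\td\tG1\tg1")
  expect_warning(sets2 <- read_gmt(f2), "duplicate")
  expect_equal(sets2$setB$genes, "G1")

  # < 3 fields is a parse error naming the line
  f3 <- tmpfile(c("ok\td\tG1", "bad\tonlydesc"))
  expect_error(read_gmt(f3), "line 2")

  # duplicate set names rejected
  f4 <- tmpfile(c("s\td\tG1", "s\td\tG2"))
  expect_error(read_gmt(f4), "duplicate gene set name")
})

test_that("GMT round-trips preserve names, descriptions and gene order", {
  sets <- list(gene_set("up", c("COL1A1", "Acta2", "PDGFRB"), "activation"),
               gene_set("dn", c("C1QTNF2"), "quiescence"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(unname(lapply(back, unclass)), lapply(sets, unclass))
})

test_that("rank database reader validates permutations and metadata consistency", {
  rank_lines <- c("gene\ti1\ti2", "G1\t1\t3", "G2\t2\t1", "G3\t3\t2")
  meta_lines <- c("instance_id\tcompound\tdose\tcell_line",
                  "i1\tapigenin\t10uM\tTWNT4",
                  "i2\tsorafenib\t5uM\tTWNT4")
  db <- read_rank_database(tmpfile(rank_lines), tmpfile(meta_lines))
  expect_s3_class(db, "rank_database")
  expect_equal(dim(db$ranks), c(3L, 2L))
  expect_equal(db$meta$compound, c("apigenin", "sorafenib"))

  # non-permutation column rejected, naming the instance
  bad <- c("gene\ti1\ti2", "G1\t1\t3", "G2\t1\t1", "G3\t3\t2")
  expect_error(read_rank_database(tmpfile(bad), tmpfile(meta_lines)),
               "i1.*permutation")

  # metadata missing an instance is a consistency error
  meta_short <- meta_lines[1:2]
  expect_error(read_rank_database(tmpfile(rank_lines), tmpfile(meta_short)),
               "disagree")

  # non-integer cells are a parse error
  frac <- c("gene\ti1\ti2", "G1\t1.5\t3", "G2\t2\t1", "G3\t3\t2")
  expect_error(read_rank_database(tmpfile(frac), tmpfile(meta_lines)),
               "non-integer")
})

test_that("rank validator rejects random single-cell corruptions", {
  set.seed(42)
  n <- 12L
  for (rep in 1:25) {
    ranks <- cbind(sample.int(n), sample.int(n))
    dimnames(ranks) <- list(paste0("G", 1:n), c("a", "b"))
    meta <- data.frame(instance_id = c("a", "b"), compound = "c",
                       dose = "d", cell_line = "e")
    expect_s3_class(rank_database(ranks, meta), "rank_database")
    # duplicate one entry: no longer a permutation
    col <- sample(2L, 1L)
    i <- sample.int(n, 2L)
    ranks[i[1L], col] <- ranks[i[2L], col]
    expect_error(rank_database(ranks, meta), "permutation")
  }
})

test_that("survival table reader enforces cohort invariants", {
  ok <- c("id\tbiomarker\ttime\tevent",
          "s1\t0.5\t10\t1", "s2\t-0.2\t12\t0",
          "s3\t1.1\t0\t1", "s4\t0\t30\t0")
  cohort <- read_survival_table(tmpfile(ok))
  expect_s3_class(cohort, "survival_cohort")
  expect_equal(nrow(cohort), 4L)

  neg <- c(ok[1:3], "s3\t1\t-1\t1")
  expect_error(read_survival_table(tmpfile(neg)), ">= 0")
  bad_event <- c(ok[1:3], "s3\t1\t5\t2")
  expect_error(read_survival_table(tmpfile(bad_event)), "0 or 1")
  dup <- c(ok[1:3], "s2\t1\t5\t1")
  expect_error(read_survival_table(tmpfile(dup)), "duplicate")
})

test_that("expression matrix reader ties samples to group labels", {
  mat <- c("gene_id\ts1\ts2\ts3\ts4",
           "G1\t0.1\t0.3\t1.2\t1.4",
           "G2\t-0.5\t0.2\t0.1\t0.0")
  grp <- c("sample_id\tgroup", "s1\tcase", "s2\tcase",
           "s3\tcontrol", "s4\tcontrol")
  x <- read_expression_matrix(tmpfile(mat), tmpfile(grp))
  expect_equal(dim(x$values), c(2L, 4L))
  expect_equal(unname(x$groups), c("case", "case", "control", "control"))

  # a sample without a label is an error
  grp_short <- grp[1:4]
  expect_error(read_expression_matrix(tmpfile(mat), tmpfile(grp_short)),
               "without a group label")
  # one sample per group is too few to test
  grp_one <- c("sample_id\tgroup", "s1\tcase", "s2\tcontrol",
               "s3\tcontrol", "s4\tcontrol")
  expect_error(read_expression_matrix(tmpfile(mat), tmpfile(grp_one)),
               ">= 2 samples")
})

test_that("ortholog map reader rejects exact duplicate records", {
  f <- tmpfile(c("source_id\thuman_symbol", "Col1a1\tCOL1A1", "Acta2\tACTA2"))
  map <- read_ortholog_map(f)
  expect_equal(nrow(map), 2L)
  f2 <- tmpfile(c("source_id\thuman_symbol", "Col1a1\tCOL1A1",
                  "Col1a1\tCOL1A1"))
  expect_error(read_ortholog_map(f2), "duplicate")
})

test_that("generated artifacts round-trip through the readers without loss", {
  cfg <- sim_config(seed = 7, genes = 40, samples_per_group = 3, planted = 5,
                    instances = 10, compounds = 5, cohort_size = 20)
  sim <- simulate_expression(cfg)
  d <- tempfile(); dir.create(d)
  write_expression_matrix(sim$matrix, file.path(d, "e.tsv"), file.path(d, "g.tsv"))
  back <- read_expression_matrix(file.path(d, "e.tsv"), file.path(d, "g.tsv"))
  expect_equal(back$values, sim$matrix$values, tolerance = 1e-12)
  expect_equal(back$groups, sim$matrix$groups)

  sig <- gene_signature(up = paste0("GENE", sprintf("%04d", 1:3)),
                        down = paste0("GENE", sprintf("%04d", 4:6)))
  rdb <- simulate_rank_database(cfg, sig)
  write_rank_database(rdb$db, file.path(d, "r.tsv"), file.path(d, "m.tsv"))
  back_db <- read_rank_database(file.path(d, "r.tsv"), file.path(d, "m.tsv"))
  expect_equal(back_db$ranks, rdb$db$ranks)
  expect_equal(back_db$meta, rdb$db$meta)

  sv <- simulate_survival(cfg)
  write_survival_table(sv$cohort, file.path(d, "s.tsv"))
  back_cohort <- read_survival_table(file.path(d, "s.tsv"))
  expect_equal(back_cohort$id, sv$cohort$id)
  expect_equal(back_cohort$time, sv$cohort$time, tolerance = 1e-9)
  expect_equal(back_cohort$event, sv$cohort$event)
})
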