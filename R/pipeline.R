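# End-to-end orchestration: signature -> screen -> overlap -> survival,
# driven by a single YAML config, with atomic outputs and a machine-readable
# run manifest.

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the repurposing pipeline from a YAML config
#'
#' Orchestrates up to five stages — `simulate`, `signature`, `screen`,
#' `overlap`, `survival` — in that order. Each stage is run only if its
#' section is present in the config; stages read the files named in their
#' section, so they can also consume the files a previous stage (or a
#' previous run) wrote. All outputs are written atomically under `out_dir`,
#' and a JSON run manifest records the config digest, seed, package version,
#' input file digests and per-stage summary counts. Reruns with identical
#' config and inputs reproduce identical outputs: every stochastic stage is
#' seeded from the config's single top-level `seed`.
#'
#' Config schema (YAML, `schema: 1`):
#' \preformatted{
#' schema: 1
#' seed: 17
#' out_dir: results/
#' simulate:            # optional; writes the fixture files below
#'   genes: 1000
#'   ...any sim_config() field...
#' signature:
#'   matrix: expr.tsv
#'   groups: groups.tsv
#'   ortholog_map: map.tsv    # optional
#'   fdr_threshold: 0.05
#'   permutations: 1000
#' screen:
#'   ranks: ranks.tsv
#'   meta: meta.tsv
#'   signature: signature.gmt # omit to use the signature stage's output
#'   alpha: 0.05
#'   permutations: 10000
#' overlap:
#'   set_a: hsc.gmt           # first set in each GMT is used
#'   set_b: interactors.gmt
#'   background_size: 20354
#' survival:
#'   table: cohort.tsv
#'   time_unit: months
#' }
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return The run manifest, invisibly (also written to
#'   `manifest.json` in the output directory). Stages not requested are
#'   marked `"absent"` in the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (!identical(as.integer(config$schema %||% 1L), 1L)) {
    stop("unsupported config schema version: ", config$schema)
  }
  if (is.null(config$seed)) stop("config needs a top-level integer seed")
  seed <- as.integer(config$seed)
  out_dir <- out_dir %||% config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stages <- c("simulate", "signature", "screen", "overlap", "survival")
  requested <- stages[vapply(stages, function(s) !is.null(config[[s]]),
                             logical(1L))]
  inpath <- function(p) {
    if (file.exists(p)) p else file.path(out_dir, p)
  }
  # fail fast: every named input must exist before any stage runs
  inputs <- character(0)
  for (s in setdiff(requested, "simulate")) {
    sec <- config[[s]]
    for (key in c("matrix", "groups", "ortholog_map", "ranks", "meta",
                  "signature", "set_a", "set_b", "table")) {
      if (!is.null(sec[[key]])) inputs <- c(inputs, sec[[key]])
    }
  }
  if (!"simulate" %in% requested) {
    missing <- inputs[!vapply(inputs, function(p) file.exists(inpath(p)),
                              logical(1L))]
    if (length(missing)) {
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    }
  }

  manifest <- list(schema = 1L, seed = seed,
                   package_version = as.character(utils::packageVersion("sigreverse")),
                   config_digest = if (!is.null(cfg_path))
                     unname(tools::md5sum(cfg_path)) else NA,
                   stages = stats::setNames(
                     rep(list(list(status = "absent")), length(stages)), stages))
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    out$status <- "ok"
    out$seconds <- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  sig <- NULL

  if ("simulate" %in% requested) {
    sec <- config$simulate
    sim_args <- sec[intersect(names(sec), names(formals(sim_config)))]
    sim_args$seed <- sim_args$seed %||% seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_expression(scfg)
    atomic_write(function(p) write_expression_matrix(sim$matrix, p,
                   file.path(out_dir, "groups.tsv")), file.path(out_dir, "expr.tsv"))
    de0 <- permutation_t_test(sim$matrix,
                              permutations = sec$permutations %||% 1000L,
                              seed = seed)
    sig0 <- build_signature(de0, fdr_threshold = sec$fdr_threshold %||% 0.05)
    rdb <- simulate_rank_database(scfg, sig0)
    atomic_write(function(p) write_rank_database(rdb$db, p,
                   file.path(out_dir, "meta.tsv")), file.path(out_dir, "ranks.tsv"))
    surv <- simulate_survival(scfg)
    atomic_write(function(p) write_survival_table(surv$cohort, p),
                 file.path(out_dir, "cohort.tsv"))
    manifest$stages$simulate <- t_stage(list(
      genes = scfg$genes, planted = scfg$planted,
      instances = scfg$instances, compounds = scfg$compounds,
      cohort_size = scfg$cohort_size))
    log_stage("simulate", manifest$stages$simulate)
  }

  if ("signature" %in% requested) {
    sec <- config$signature
    mat <- read_expression_matrix(inpath(sec$matrix), inpath(sec$groups))
    map <- if (!is.null(sec$ortholog_map)) read_ortholog_map(inpath(sec$ortholog_map))
    de <- permutation_t_test(mat, permutations = sec$permutations %||% 1000L,
                             seed = seed)
    atomic_write(function(p) write_tsv_strict(as.data.frame(de), p),
                 file.path(out_dir, "de_results.tsv"))
    sig <- build_signature(de, fdr_threshold = sec$fdr_threshold %||% 0.05,
                           map = map)
    atomic_write(function(p) write_signature(sig, p,
                   file.path(out_dir, "signature.json")),
                 file.path(out_dir, "signature.gmt"))
    manifest$stages$signature <- t_stage(list(
      genes_tested = nrow(de),
      up = length(sig$up$genes %||% character(0)),
      down = length(sig$down$genes %||% character(0)),
      mapping = as.list(sig$mapping_report)))
    log_stage("signature", manifest$stages$signature)
  }

  if ("screen" %in% requested) {
    sec <- config$screen
    db <- read_rank_database(inpath(sec$ranks), inpath(sec$meta))
    sig_use <- if (!is.null(sec$signature)) read_signature(inpath(sec$signature))
               else sig %||% stop("screen stage needs a signature (file or signature stage)")
    res <- screen_compounds(db, sig_use, alpha = sec$alpha %||% 0.05,
                            permutations = sec$permutations %||% 10000L,
                            seed = seed, sided = sec$p_sided %||% "two")
    atomic_write(function(p) write_tsv_strict(as.data.frame(res), p),
                 file.path(out_dir, "screen_results.tsv"))
    manifest$stages$screen <- t_stage(list(
      compounds_screened = nrow(res), selected = sum(res$selected)))
    log_stage("screen", manifest$stages$screen)
  }

  if ("overlap" %in% requested) {
    sec <- config$overlap
    set_a <- read_gmt(inpath(sec$set_a))[[1L]]
    set_b <- read_gmt(inpath(sec$set_b))[[1L]]
    ov <- overlap_test(set_a, set_b,
                       background_size = sec$background_size %||%
                         DEFAULT_BACKGROUND_SIZE)
    atomic_write(function(p) jsonlite::write_json(
      list(k = ov$k, expected = ov$expected, p_point = ov$p_point,
           p_tail = ov$p_tail, N = ov$N, K = ov$K, n_draw = ov$n_draw,
           genes = ov$genes), p, auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(out_dir, "overlap.json"))
    manifest$stages$overlap <- t_stage(list(
      k = ov$k, expected = ov$expected, p_point = ov$p_point,
      p_tail = ov$p_tail))
    log_stage("overlap", manifest$stages$overlap)
  }

  if ("survival" %in% requested) {
    sec <- config$survival
    cohort <- read_survival_table(inpath(sec$table))
    sa <- survival_analysis(cohort)
    atomic_write(function(p) jsonlite::write_json(
      list(threshold = sa$threshold,
           time_unit = sec$time_unit %||% "unspecified",
           group_sizes = as.list(sa$group_sizes),
           dichotomization = "strict biomarker > mean + 1 sample SD (n-1)",
           curves = lapply(sa$curves, as.data.frame),
           logrank = list(chi_square = sa$logrank$chi_square,
                          df = sa$logrank$df, p = sa$logrank$p,
                          observed = as.list(sa$logrank$observed),
                          expected = as.list(sa$logrank$expected))),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(out_dir, "survival.json"))
    manifest$stages$survival <- t_stage(list(
      n = nrow(cohort), high = unname(sa$group_sizes["high"]),
      low = unname(sa$group_sizes["low"]),
      logrank_p = sa$logrank$p))
    log_stage("survival", manifest$stages$survival)
  }

  manifest$input_digests <- file_digest(vapply(inputs, inpath, character(1L)))
  atomic_write(function(p) jsonlite::write_json(manifest, p,
                 auto_unbox = TRUE, digits = NA, pretty = TRUE),
               file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

log_stage <- function(stage, summary) {
  fields <- summary[setdiff(names(summary), "status")]
  flat <- vapply(fields, function(v) paste(unlist(v), collapse = "/"),
                 character(1L))
  message(sprintf("[sigreverse] stage=%s %s", stage,
                  paste(names(flat), flat, sep = "=", collapse = " ")))
}
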