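# Synthetic-data generators with planted ground truth. Each generator draws
# from its own RNG stream (master seed plus a fixed offset), so adding or
# reordering generators never perturbs another's output.

SEED_OFFSET_EXPRESSION <- 101L
SEED_OFFSET_RANKDB <- 202L
SEED_OFFSET_SURVIVAL <- 303L
SEED_OFFSET_ORTHOLOG <- 404L

#' Simulation configuration
#'
#' One validated configuration object drives all three generators. Defaults
#' describe the study conditions the pipeline is designed for: a two-group
#' microarray comparison (10 vs 10 samples, 1,000 genes, 50 planted
#' differentially expressed genes shifted by 2 noise-SD units), a
#' 200-instance / 40-compound rank database with one planted
#' signature-reversing compound at full strength, and a 216-patient cohort
#' (the size of the HCV cirrhosis cohort the survival stage emulates) with
#' a protective biomarker at hazard ratio 2.5 and 30% censoring.
#'
#' @param seed Master integer seed (mandatory).
#' @param genes Number of genes in the expression/rank universe.
#' @param samples_per_group Samples per group in the expression matrix.
#' @param planted Number of planted differentially expressed genes.
#' @param effect Mean shift of planted genes in cases, in noise-SD units.
#' @param prop_up Fraction of planted genes shifted upward (rest downward).
#' @param noise_sd Residual noise standard deviation (log-intensity units).
#' @param instances Number of instances in the rank database.
#' @param compounds Number of distinct compounds (instances are distributed
#'   round-robin).
#' @param antagonists,agonists Numbers of planted signature-reversing /
#'   signature-mimicking compounds.
#' @param strength Planting strength in `[0, 1]`: 0 = null, 1 = signature
#'   genes fully displaced to the list extremes.
#' @param cohort_size Number of patients in the survival cohort.
#' @param hazard_ratio Hazard of biomarker-low relative to biomarker-high
#'   subjects (> 1 means high expression is protective).
#' @param baseline_hazard Event hazard of the high group, per time unit
#'   (months by convention).
#' @param censoring Target fraction of censored subjects, in `[0, 1)`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genes = 1000L, samples_per_group = 10L,
                       planted = 50L, effect = 2, prop_up = 0.5,
                       noise_sd = 1,
                       instances = 200L, compounds = 40L,
                       antagonists = 1L, agonists = 0L, strength = 1,
                       cohort_size = 216L, hazard_ratio = 2.5,
                       baseline_hazard = 0.02, censoring = 0.3) {
  if (missing(seed)) stop("a master seed is mandatory")
  cfg <- list(seed = as.integer(seed), genes = as.integer(genes),
              samples_per_group = as.integer(samples_per_group),
              planted = as.integer(planted), effect = as.numeric(effect),
              prop_up = as.numeric(prop_up), noise_sd = as.numeric(noise_sd),
              instances = as.integer(instances),
              compounds = as.integer(compounds),
              antagonists = as.integer(antagonists),
              agonists = as.integer(agonists), strength = as.numeric(strength),
              cohort_size = as.integer(cohort_size),
              hazard_ratio = as.numeric(hazard_ratio),
              baseline_hazard = as.numeric(baseline_hazard),
              censoring = as.numeric(censoring))
  stopifnot(cfg$genes >= 1L, cfg$samples_per_group >= 2L, cfg$planted >= 0L,
            cfg$noise_sd > 0, cfg$instances >= 1L, cfg$compounds >= 1L,
            cfg$antagonists >= 0L, cfg$agonists >= 0L,
            cfg$strength >= 0, cfg$strength <= 1,
            cfg$prop_up >= 0, cfg$prop_up <= 1,
            cfg$cohort_size >= 2L, cfg$hazard_ratio > 0,
            cfg$baseline_hazard > 0,
            cfg$censoring >= 0, cfg$censoring < 1)
  if (cfg$planted > cfg$genes) stop("planted genes exceed the gene universe")
  if (cfg$antagonists + cfg$agonists > cfg$compounds) {
    stop("planted compounds exceed the number of compounds")
  }
  if (cfg$compounds > cfg$instances) stop("more compounds than instances")
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("GENE%04d", seq_len(n))

with_stream <- function(seed, offset, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + offset)
  expr
}

#' Simulate a two-group expression matrix with planted DE genes
#'
#' Null genes are `Normal(0, noise_sd)` in both groups; the first `planted`
#' genes get an additional `+/- effect * noise_sd` mean shift in the case
#' group (`prop_up` of them upward). Deterministic given the config seed.
#'
#' @param config A [sim_config].
#' @return List with `matrix` (an [expression_matrix]) and `truth` (data
#'   frame of planted gene ids and directions, `"up"`/`"down"` in cases).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, SEED_OFFSET_EXPRESSION, {
    g <- config$genes
    spg <- config$samples_per_group
    ids <- sim_gene_ids(g)
    samples <- c(sprintf("CASE%02d", seq_len(spg)),
                 sprintf("CTRL%02d", seq_len(spg)))
    groups <- stats::setNames(rep(c("case", "control"), each = spg), samples)
    values <- matrix(stats::rnorm(g * 2 * spg, 0, config$noise_sd),
                     nrow = g, dimnames = list(ids, samples))
    n_up <- round(config$planted * config$prop_up)
    dirs <- rep(c("up", "down"), c(n_up, config$planted - n_up))
    if (config$planted > 0L) {
      shift <- ifelse(dirs == "up", 1, -1) * config$effect * config$noise_sd
      values[seq_len(config$planted), groups == "case"] <-
        values[seq_len(config$planted), groups == "case"] + shift
    }
    list(matrix = expression_matrix(values, groups),
         truth = data.frame(gene = ids[seq_len(config$planted)],
                            direction = dirs, stringsAsFactors = FALSE))
  })
}

#' Simulate a compound-perturbation rank database with planted reversers
#'
#' Null instances are independent uniform random permutations of the gene
#' universe. For a planted antagonist instance, a uniform permutation is
#' deformed by geometric interpolation of the signature genes' ranks toward
#' the list extremes — up-genes toward the bottom (the compound
#' down-regulates them) and down-genes toward the top — with the configured
#' strength (0 = untouched, 1 = fully displaced), then re-ranked (stable
#' ties) to restore a valid permutation. Agonists are the mirror image. The
#' first `antagonists` compounds of the round-robin layout are antagonists,
#' the next `agonists` are agonists.
#'
#' @param config A [sim_config].
#' @param signature A `gene_signature` whose genes all belong to the
#'   simulated universe.
#' @return List with `db` (a [rank_database]) and `truth` (data frame of
#'   compound roles: `"antagonist"`, `"agonist"`, `"null"`).
#' @export
simulate_rank_database <- function(config, signature) {
  stopifnot(inherits(config, "sim_config"))
  universe <- sim_gene_ids(config$genes)
  sig_up <- if (!is.null(signature$up)) signature$up$genes else character(0)
  sig_dn <- if (!is.null(signature$down)) signature$down$genes else character(0)
  up_idx <- match_fold(sig_up, universe)
  dn_idx <- match_fold(sig_dn, universe)
  if (anyNA(up_idx) || anyNA(dn_idx)) {
    stop("signature genes missing from the simulated universe")
  }
  n <- config$genes
  roles <- rep("null", config$compounds)
  if (config$antagonists > 0L) roles[seq_len(config$antagonists)] <- "antagonist"
  if (config$agonists > 0L) {
    roles[config$antagonists + seq_len(config$agonists)] <- "agonist"
  }
  compound_names <- sprintf("compound%03d", seq_len(config$compounds))
  inst_compound <- rep_len(seq_len(config$compounds), config$instances)
  with_stream(config$seed, SEED_OFFSET_RANKDB, {
    ranks <- matrix(0L, nrow = n, ncol = config$instances,
                    dimnames = list(universe,
                                    sprintf("inst%04d", seq_len(config$instances))))
    s <- config$strength
    for (i in seq_len(config$instances)) {
      r <- sample.int(n)
      role <- roles[inst_compound[i]]
      if (role != "null" && s > 0) {
        x <- as.numeric(r)
        if (role == "antagonist") {
          x[up_idx] <- x[up_idx] * (1 - s) + n * s   # up-genes sink to bottom
          x[dn_idx] <- x[dn_idx] * (1 - s) + 1 * s   # down-genes rise to top
        } else {
          x[up_idx] <- x[up_idx] * (1 - s) + 1 * s
          x[dn_idx] <- x[dn_idx] * (1 - s) + n * s
        }
        r <- rank(x, ties.method = "first")
      }
      ranks[, i] <- as.integer(r)
    }
    meta <- data.frame(instance_id = colnames(ranks),
                       compound = compound_names[inst_compound],
                       dose = "10uM", cell_line = "SYN1",
                       stringsAsFactors = FALSE)
    list(db = rank_database(ranks, meta),
         truth = data.frame(compound = compound_names, role = roles,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a right-censored survival cohort with a protective biomarker
#'
#' Biomarker values are standard normal. Subjects whose biomarker exceeds
#' the cohort mean plus one SD ("high") have exponential event times at the
#' baseline hazard; the remaining subjects' hazard is multiplied by the
#' hazard ratio, so a ratio above 1 makes high expression protective
#' (slower progression). Censoring times are uniform on `(0, tau)` with
#' `tau` solved numerically so the expected censored fraction over the
#' two-group mixture equals the configured value.
#'
#' @param config A [sim_config].
#' @return List with `cohort` (a [survival_cohort], times in months) and
#'   `truth` (per-sample `"high"`/`"low"` labels used for generation).
#' @export
simulate_survival <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, SEED_OFFSET_SURVIVAL, {
    n <- config$cohort_size
    biomarker <- stats::rnorm(n)
    high <- biomarker > mean(biomarker) + stats::sd(biomarker)
    lambda <- ifelse(high, config$baseline_hazard,
                     config$baseline_hazard * config$hazard_ratio)
    t_event <- stats::rexp(n, rate = lambda)
    if (config$censoring > 0) {
      w_high <- mean(high)
      rates <- c(config$baseline_hazard,
                 config$baseline_hazard * config$hazard_ratio)
      wts <- c(w_high, 1 - w_high)
      # P(C < T) for C ~ U(0, tau), T ~ Exp(lambda):
      # integral 1/tau * exp(-lambda c) dc = (1 - exp(-lambda tau))/(lambda tau)
      cens_frac <- function(tau) {
        sum(wts * (1 - exp(-rates * tau)) / (rates * tau)) - config$censoring
      }
      tau <- stats::uniroot(cens_frac, c(1e-8, 1e8), tol = 1e-10)$root
      t_cens <- stats::runif(n, 0, tau)
      event <- as.numeric(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1, n)
      time <- t_event
    }
    list(cohort = survival_cohort(sprintf("PT%04d", seq_len(n)), biomarker,
                                  time, event),
         truth = ifelse(high, "high", "low"))
  })
}

#' Simulate an ortholog mapping table
#'
#' Builds a HomoloGene-style table for a source-species universe: each
#' source id `geneXXXX` maps to its human counterpart `GENEXXXX`, except for
#' configurable fractions left unmapped or made ambiguous (a second human
#' partner added).
#'
#' @param gene_ids Character vector of human gene ids (as produced by the
#'   expression generator).
#' @param seed Integer seed.
#' @param unmapped_frac,ambiguous_frac Fractions of source genes with zero
#'   or two human partners.
#' @return List with `map` (data frame `source_id`, `human_symbol`) and
#'   `source_ids` (the source-species spelling of `gene_ids`, in order).
#' @export
simulate_ortholog_map <- function(gene_ids, seed, unmapped_frac = 0,
                                  ambiguous_frac = 0) {
  stopifnot(unmapped_frac >= 0, ambiguous_frac >= 0,
            unmapped_frac + ambiguous_frac <= 1)
  with_stream(as.integer(seed), SEED_OFFSET_ORTHOLOG, {
    src <- paste0("r", casefold(gene_ids))  # rodent-style source spelling
    n <- length(gene_ids)
    n_un <- round(n * unmapped_frac)
    n_amb <- round(n * ambiguous_frac)
    special <- sample.int(n, n_un + n_amb)
    unmapped <- special[seq_len(n_un)]
    ambiguous <- setdiff(special, unmapped)
    keep <- setdiff(seq_len(n), unmapped)
    map <- data.frame(source_id = src[keep], human_symbol = gene_ids[keep],
                      stringsAsFactors = FALSE)
    if (length(ambiguous)) {
      map <- rbind(map, data.frame(source_id = src[ambiguous],
                                   human_symbol = paste0(gene_ids[ambiguous], "B"),
                                   stringsAsFactors = FALSE))
    }
    list(map = map[order(map$source_id, map$human_symbol), ],
         source_ids = src)
  })
}
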