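#' Simulation configuration for synthetic immune/tumor/patient data
#'
#' Builds and validates the configuration object consumed by
#' [generate_immune_panel()], [generate_tumor_panel()] and
#' [generate_patient_cohort()]. Defaults emulate the study design the
#' screening pipeline targets: 19 immune cell types profiled in 115
#' purified samples, 34 tumor cell lines, and a 3477-gene lncRNA universe,
#' with a patient cohort of 300.
#'
#' Expression is simulated on a nonnegative log2-like intensity scale
#' (RMA-style): background values are Gaussian with mean `background_mean`
#' and sd `background_sd`, clipped at zero. Each planted immune gene
#' receives a pan-immune elevation (`immune_effect`, present in every
#' immune sample and absent from tumor lines) plus a cell-type-specific
#' boost (`specific_effect`) in its assigned type, so planted genes are
#' simultaneously top-decile in their own type, cell-type specific by TSI,
#' and upregulated in pooled immune cells versus tumor lines.
#'
#' @param n_cell_types number of immune cell types (default 19).
#' @param replicates_per_type replicate samples per type (default 6,
#'   giving 114 immune samples, close to the 115 of the reference design).
#' @param n_tumor_lines number of tumor cell lines (default 34).
#' @param n_genes size of the lncRNA universe (default 3477).
#' @param n_specific_per_type planted type-specific genes per cell type
#'   (default 5).
#' @param n_prognostic number of planted prognostic genes among the
#'   planted immune genes (default 9).
#' @param specific_effect log-intensity boost in the assigned cell type
#'   (default 4.0).
#' @param immune_effect pan-immune log-intensity elevation of planted
#'   genes, shared by all immune samples and absent in tumor lines
#'   (default 2.0).
#' @param background_mean,background_sd background log-intensity mean and
#'   standard deviation (defaults 5.0 and 1.0).
#' @param n_patients patient cohort size (default 300).
#' @param immune_fraction_range interval in \[0,1\] from which per-patient
#'   immune mixing fractions are drawn uniformly (default c(0.1, 0.6)).
#' @param baseline_hazard exponential baseline hazard per unit time
#'   (default 0.02; mean survival 50 time units at the baseline).
#' @param beta_prognostic per-gene log-hazard weights applied to the
#'   standardized expression of the planted prognostic genes; length
#'   `n_prognostic`. Default alternates -0.5 and +0.5.
#' @param censor_rate rate of the independent exponential censoring time
#'   (default 0.01; 0 disables censoring).
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_cell_types * cfg$replicates_per_type
sim_config <- function(n_cell_types = 19L,
                       replicates_per_type = 6L,
                       n_tumor_lines = 34L,
                       n_genes = 3477L,
                       n_specific_per_type = 5L,
                       n_prognostic = 9L,
                       specific_effect = 4.0,
                       immune_effect = 2.0,
                       background_mean = 5.0,
                       background_sd = 1.0,
                       n_patients = 300L,
                       immune_fraction_range = c(0.1, 0.6),
                       baseline_hazard = 0.02,
                       beta_prognostic = NULL,
                       censor_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_cell_types = as.integer(n_cell_types),
    replicates_per_type = as.integer(replicates_per_type),
    n_tumor_lines = as.integer(n_tumor_lines),
    n_genes = as.integer(n_genes),
    n_specific_per_type = as.integer(n_specific_per_type),
    n_prognostic = as.integer(n_prognostic),
    specific_effect = as.numeric(specific_effect),
    immune_effect = as.numeric(immune_effect),
    background_mean = as.numeric(background_mean),
    background_sd = as.numeric(background_sd),
    n_patients = as.integer(n_patients),
    immune_fraction_range = as.numeric(immune_fraction_range),
    baseline_hazard = as.numeric(baseline_hazard),
    beta_prognostic = if (is.null(beta_prognostic)) {
      rep(c(-0.5, 0.5), length.out = as.integer(n_prognostic))
    } else {
      as.numeric(beta_prognostic)
    },
    censor_rate = as.numeric(censor_rate),
    seed = as.integer(seed)
  )
  counts <- c("n_cell_types", "replicates_per_type", "n_tumor_lines",
              "n_genes", "n_specific_per_type", "n_prognostic", "n_patients")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L) {
      stop("sim_config: field '", f, "' must be a single positive count",
           call. = FALSE)
    }
  }
  if (cfg$n_specific_per_type * cfg$n_cell_types + cfg$n_prognostic >
      cfg$n_genes) {
    stop("sim_config: n_specific_per_type * n_cell_types + n_prognostic ",
         "exceeds n_genes", call. = FALSE)
  }
  if (length(cfg$immune_fraction_range) != 2L ||
      any(is.na(cfg$immune_fraction_range)) ||
      cfg$immune_fraction_range[1] > cfg$immune_fraction_range[2] ||
      cfg$immune_fraction_range[1] < 0 || cfg$immune_fraction_range[2] > 1) {
    stop("sim_config: field 'immune_fraction_range' must be an ordered ",
         "interval within [0, 1]", call. = FALSE)
  }
  if (is.na(cfg$baseline_hazard) || cfg$baseline_hazard <= 0) {
    stop("sim_config: field 'baseline_hazard' must be > 0", call. = FALSE)
  }
  if (is.na(cfg$censor_rate) || cfg$censor_rate < 0) {
    stop("sim_config: field 'censor_rate' must be >= 0", call. = FALSE)
  }
  if (is.na(cfg$background_sd) || cfg$background_sd <= 0) {
    stop("sim_config: field 'background_sd' must be > 0", call. = FALSE)
  }
  if (length(cfg$beta_prognostic) != cfg$n_prognostic ||
      any(!is.finite(cfg$beta_prognostic))) {
    stop("sim_config: field 'beta_prognostic' must hold ", cfg$n_prognostic,
         " finite weights", call. = FALSE)
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop("sim_config: field 'seed' must be a single integer", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched, so generators are pure functions of the seed.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

default_cell_type_names <- function(n) {
  base <- c("B_cell", "memory_B_cell", "plasma_cell", "CD4_T_cell",
            "CD8_T_cell", "Treg", "Tfh", "Th1", "Th2", "Th17",
            "gdT_cell", "NK_cell", "monocyte", "macrophage",
            "myeloid_DC", "plasmacytoid_DC", "neutrophil", "eosinophil",
            "basophil")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("cell_type_%02d", seq_len(n - length(base))))
}

gene_universe <- function(n) sprintf("LNC%05d", seq_len(n))

#' Generate a synthetic immune-cell reference panel with planted truth
#'
#' Simulates a genes x samples log-intensity matrix for
#' `n_cell_types * replicates_per_type` purified immune samples, planting
#' `n_specific_per_type` genes per cell type. Planted genes carry a
#' pan-immune elevation plus a boost in their assigned type; negative
#' values are clipped at zero.
#'
#' @param config a [sim_config()] object.
#' @return A list with `expr` (matrix, gene IDs as rownames, sample IDs as
#'   colnames), `labels` (data.frame `sample_id`, `cell_type`), and
#'   `truth`, a `"synthetic_truth"` list with `specific_genes` (per-type
#'   gene lists), `ti_lncrna_genes` (all planted immune genes),
#'   `prognostic_genes` (named numeric: true log-hazard weights).
#' @export
#' @examples
#' panel <- generate_immune_panel(sim_config(n_genes = 200, seed = 1))
#' dim(panel$expr)
generate_immune_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_universe(config$n_genes)
  types <- default_cell_type_names(config$n_cell_types)
  n_samp <- config$n_cell_types * config$replicates_per_type
  sample_type <- rep(types, each = config$replicates_per_type)
  sample_ids <- paste0(sample_type, "_rep",
                       rep(seq_len(config$replicates_per_type),
                           times = config$n_cell_types))

  n_planted <- config$n_specific_per_type * config$n_cell_types
  specific_idx <- seq_len(n_planted)
  specific_genes <- split(genes[specific_idx],
                          rep(types, each = config$n_specific_per_type))
  specific_genes <- specific_genes[types]

  expr <- with_local_seed(config$seed, {
    m <- matrix(stats::rnorm(config$n_genes * n_samp,
                             mean = config$background_mean,
                             sd = config$background_sd),
                nrow = config$n_genes, ncol = n_samp,
                dimnames = list(genes, sample_ids))
    m[specific_idx, ] <- m[specific_idx, ] + config$immune_effect
    for (k in seq_len(config$n_cell_types)) {
      gi <- ((k - 1L) * config$n_specific_per_type + 1L):
        (k * config$n_specific_per_type)
      si <- which(sample_type == types[k])
      m[gi, si] <- m[gi, si] + config$specific_effect
    }
    pmax(m, 0)
  })

  ti_genes <- genes[specific_idx]
  prog_ids <- with_local_seed(config$seed + 1L,
                              sample(ti_genes, config$n_prognostic))
  prognostic <- stats::setNames(config$beta_prognostic, prog_ids)

  truth <- structure(
    list(specific_genes = specific_genes,
         ti_lncrna_genes = ti_genes,
         prognostic_genes = prognostic,
         patient_immune_fractions = NULL),
    class = "synthetic_truth"
  )
  list(expr = expr,
       labels = data.frame(sample_id = sample_ids, cell_type = sample_type,
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate a synthetic tumor cell-line panel
#'
#' Simulates `n_tumor_lines` profiles over the same gene universe as the
#' immune panel. No gene receives the immune elevations, so planted
#' immune genes have tumor means at background level.
#'
#' @param config the [sim_config()] used for the immune panel.
#' @param truth the `truth` component returned by [generate_immune_panel()].
#' @return A genes x lines expression matrix.
#' @export
generate_tumor_panel <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(truth, "synthetic_truth")) {
    stop("generate_tumor_panel: 'truth' must come from ",
         "generate_immune_panel()", call. = FALSE)
  }
  genes <- gene_universe(config$n_genes)
  if (!all(truth$ti_lncrna_genes %in% genes)) {
    stop("generate_tumor_panel: gene universe mismatch between config and ",
         "truth", call. = FALSE)
  }
  ids <- sprintf("tumor_line_%02d", seq_len(config$n_tumor_lines))
  with_local_seed(config$seed + 2L, {
    m <- matrix(stats::rnorm(config$n_genes * config$n_tumor_lines,
                             mean = config$background_mean,
                             sd = config$background_sd),
                nrow = config$n_genes, ncol = config$n_tumor_lines,
                dimnames = list(genes, ids))
    pmax(m, 0)
  })
}

#' Generate a synthetic patient cohort with survival outcomes
#'
#' Each patient profile is a convex mixture `f * immune + (1 - f) * tumor`
#' of the two population mean profiles plus Gaussian noise, with the
#' immune fraction `f` drawn uniformly from `immune_fraction_range`.
#' Death times are exponential with hazard
#' `baseline_hazard * exp(sum(beta_g * z_g))`, where `z_g` is the
#' patient's standardized expression of prognostic gene `g`; censoring is
#' independent exponential at `censor_rate`.
#'
#' @param config a [sim_config()] object.
#' @param truth truth from the matching [generate_immune_panel()] call.
#' @return A list with `expr` (genes x patients matrix) and `clinical`
#'   (data.frame: `sample_id`, `time`, `event`, `age`, `gender`); the
#'   returned `truth` gains `patient_immune_fractions`.
#' @export
generate_patient_cohort <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(truth, "synthetic_truth")) {
    stop("generate_patient_cohort: 'truth' must come from ",
         "generate_immune_panel()", call. = FALSE)
  }
  genes <- gene_universe(config$n_genes)
  n_planted <- length(truth$ti_lncrna_genes)

  # Population mean profiles implied by the generative model: planted
  # genes average immune_effect + specific_effect / n_cell_types above
  # background across immune samples; tumor lines sit at background.
  imm_mean <- rep(config$background_mean, config$n_genes)
  planted <- match(truth$ti_lncrna_genes, genes)
  imm_mean[planted] <- imm_mean[planted] + config$immune_effect +
    config$specific_effect / config$n_cell_types
  tum_mean <- rep(config$background_mean, config$n_genes)

  ids <- sprintf("patient_%04d", seq_len(config$n_patients))
  out <- with_local_seed(config$seed + 3L, {
    f <- stats::runif(config$n_patients,
                      min = config$immune_fraction_range[1],
                      max = config$immune_fraction_range[2])
    base <- outer(imm_mean, f) + outer(tum_mean, 1 - f)
    noise <- matrix(stats::rnorm(config$n_genes * config$n_patients,
                                 sd = config$background_sd),
                    nrow = config$n_genes)
    expr <- pmax(base + noise, 0)
    dimnames(expr) <- list(genes, ids)

    prog <- names(truth$prognostic_genes)
    z <- scale(t(expr[prog, , drop = FALSE]))
    lp <- as.numeric(z %*% truth$prognostic_genes)
    death <- stats::rexp(config$n_patients,
                         rate = config$baseline_hazard * exp(lp))
    cens <- if (config$censor_rate > 0) {
      stats::rexp(config$n_patients, rate = config$censor_rate)
    } else {
      rep(Inf, config$n_patients)
    }
    clinical <- data.frame(
      sample_id = ids,
      time = pmin(death, cens),
      event = as.integer(death <= cens),
      age = round(stats::rnorm(config$n_patients, 60, 10)),
      gender = sample(c("male", "female"), config$n_patients,
                      replace = TRUE),
      stringsAsFactors = FALSE
    )
    list(expr = expr, clinical = clinical, f = f)
  })
  truth$patient_immune_fractions <- stats::setNames(out$f, ids)
  list(expr = out$expr, clinical = out$clinical, truth = truth)
}

#' Recovery metrics of a screen against planted truth
#'
#' Compares the genes flagged by [run_screen()] (or any screen result with
#' an `is_ti_lncrna` column, or a plain character vector of flagged gene
#' IDs) with the planted immune genes of a synthetic truth.
#'
#' @param truth a `"synthetic_truth"` object.
#' @param result a screen result data.frame (columns `gene`,
#'   `is_ti_lncrna`) or a character vector of flagged gene IDs.
#' @return list with `sensitivity`, `precision` (both in \[0,1\];
#'   `precision` is `NA` when nothing was flagged), `n_flagged`,
#'   `n_planted`, `n_recovered`.
#' @export
evaluate_recovery <- function(truth, result) {
  stopifnot(inherits(truth, "synthetic_truth"))
  flagged <- if (is.character(result)) {
    result
  } else if (is.data.frame(result) &&
             all(c("gene", "is_ti_lncrna") %in% names(result))) {
    result$gene[result$is_ti_lncrna %in% TRUE]
  } else {
    stop("evaluate_recovery: 'result' must be a screen result data.frame ",
         "or a character vector of gene IDs", call. = FALSE)
  }
  planted <- truth$ti_lncrna_genes
  hit <- intersect(flagged, planted)
  list(
    sensitivity = if (length(planted)) length(hit) / length(planted) else NA_real_,
    precision = if (length(flagged)) length(hit) / length(flagged) else NA_real_,
    n_flagged = length(flagged),
    n_planted = length(planted),
    n_recovered = length(hit)
  )
}
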