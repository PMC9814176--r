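#' End-to-end training-set design and prediction pipeline
#'
#' Sequences the full workflow on one dataset: marker QC, hybrid synthesis,
#' relationship matrices, environmental-covariate kernel, stage-1 BLUEs with
#' the ideotype transform and standardization, trait covariance and
#' heritability, composite kernel, APY-sized GA-optimized training design
#' plus a size-matched random control, multi-trait GBLUP fits on both
#' designs, prediction ability on the untrained cells, and the
#' response-per-dollar economics. Every artifact is written as CSV into
#' \code{out_dir} together with a \code{manifest.csv} of MD5 content hashes;
#' identical inputs and seed give an identical manifest.
#'
#' @param data a dataset bundle as returned by
#'   \code{\link{simulate_dataset}} / \code{\link{golden_fixture}}, or NULL
#'   when \code{paths} is given.
#' @param paths optional named list of input files (markers, cross_plan,
#'   phenotypes, weather) read with the package readers.
#' @param out_dir output directory (created).
#' @param kernel_kind "GWT" (enviromic environment factor) or "GET"
#'   (identity environment factor) for the selection kernel.
#' @param model prediction model id (default "M4").
#' @param apy_threshold spectral variance fraction sizing the training set.
#' @param ga a \code{\link{ga_config}} (seed is derived from \code{seed}).
#' @param gibbs a \code{\link{gibbs_config}} (seed derived from
#'   \code{seed}).
#' @param unit_costs,genotyping_usd_per_sample economics settings.
#' @param design "blocks_fixed" or "blocks_random" for stage 1.
#' @param seed global seed fanned out to per-stage seeds.
#' @return invisibly, a list with the key objects and \code{manifest}
#'   (data.frame file/md5).
#' @export
run_pipeline <- function(data = NULL, paths = NULL, out_dir,
                         kernel_kind = c("GWT", "GET"), model = "M4",
                         apy_threshold = 0.98,
                         ga = ga_config(population = 20L, generations = 30L,
                                        patience = 8L, lookahead_cap = 60L),
                         gibbs = gibbs_config(iterations = 1500L,
                                              burn_in = 300L),
                         unit_costs = c(GY = 4, PH = 2, EH = 2),
                         genotyping_usd_per_sample = 20,
                         design = c("blocks_fixed", "blocks_random"),
                         seed = 1L) {
  kernel_kind <- match.arg(kernel_kind)
  design <- match.arg(design)
  if (is.null(data)) data <- read_pipeline_inputs(paths)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    art <<- c(art, path)
    path
  }

  # --- markers: QC on hybrids, relationship matrices --------------------
  qc <- qc_markers(data$markers, call_rate_min = 0.95, min_maf = 0.05)
  put(attr(qc, "qc_log"), "qc_log.csv")
  hyb_ids <- rownames(qc$dosage)[qc$role == "hybrid"]
  st <- allele_stats(qc, subset = hyb_ids)
  hyb <- marker_matrix(qc$dosage[hyb_ids, , drop = FALSE], role = "hybrid")
  g_a <- additive_grm(hyb, st)
  g_d <- dominance_grm(hyb, st)
  put(data.frame(id = rownames(g_a$matrix), g_a$matrix, check.names = FALSE),
      "grm_additive.csv")

  # --- enviromics -------------------------------------------------------
  ec <- if (!is.null(data$ec)) data$ec else
    scale_ec_matrix(summarize_env_covariates(data$weather))
  k_e <- env_kernel(ec)
  put(data.frame(env = rownames(k_e$matrix), k_e$matrix, check.names = FALSE),
      "env_kernel.csv")

  # --- stage 1 ----------------------------------------------------------
  plots <- data$plots
  pl <- plots$data
  if ("EH" %in% plots$traits) pl$EH <- transform_ear_height(pl$EH)
  plots_tr <- plot_records(pl, traits = plots$traits)
  blues <- standardize_traits(fit_stage1_blues(plots_tr, design = design))
  blues$data <- blues$data[blues$data$genotype %in% hyb_ids, , drop = FALSE]
  put(blues$data, "blues.csv")
  h2 <- estimate_heritability(plots_tr)
  put(h2, "heritability.csv")
  tc <- trait_covariance(blues)
  put(data.frame(trait = rownames(tc$covariance), tc$covariance,
                 check.names = FALSE), "trait_covariance.csv")

  # --- composite kernel and training design -----------------------------
  env_part <- if (kernel_kind == "GWT") k_e else length(k_e$environment_ids)
  kern <- composite_kernel(g_a, env_part, tc$covariance, kind = kernel_kind,
                           env_ids = k_e$environment_ids)
  n_core <- apy_core_size(kernel_spectrum(kern), apy_threshold)
  n_core <- min(n_core, n_cells(kern) - length(unique(kern$cells$env)) *
                  length(unique(kern$cells$trait)) - 1L)
  check_g <- data$truth$check_genotype %||% kern$cells$genotype[1]
  ga$seed <- stage_seed(seed, "ga")
  ots <- optimize_training_set(kern, n_core, ga, check_genotype = check_g)
  rnd <- random_design(kern, n_core, seed = stage_seed(seed, "random"),
                       check_genotype = check_g)
  art <- c(art, write_design(ots, kern, file.path(out_dir, "design_ots.csv")),
           write_design(rnd, kern, file.path(out_dir, "design_random.csv")))

  # --- prediction on both designs ---------------------------------------
  gibbs$seed <- stage_seed(seed, "gibbs")
  eval_one <- function(dsg, label) {
    ytr <- restrict_blues(blues, dsg)
    fit <- fit_gblup(ytr, model = model, g_a = g_a, g_d = g_d, k_e = k_e,
                     trait_mode = "multi", trait_cov = tc$covariance,
                     cfg = gibbs)
    test <- kern$cells[-dsg$indices, , drop = FALSE]
    pa <- prediction_ability(predict_cells(fit), blues, test)
    list(fit = fit, pa = pa, label = label)
  }
  res_ots <- eval_one(ots, "OTS1")
  res_rnd <- eval_one(rnd, "RANDOM1")
  put(res_ots$fit$variance_components, "varcomp_ots.csv")
  put(res_ots$fit$cells, "predictions_ots.csv")
  pa_tab <- rbind(
    data.frame(scenario = "OTS1", res_ots$pa$by_trait),
    data.frame(scenario = "RANDOM1", res_rnd$pa$by_trait))
  put(pa_tab, "prediction_ability.csv")

  # --- economics --------------------------------------------------------
  n_parents <- sum(data$markers$role == "parent")
  # accuracy divides PA by sqrt(H2); guard against degenerate stage-1
  # estimates on small panels so the economics stay finite and comparable
  h2v <- stats::setNames(pmin(1, pmax(h2$H2, 0.1)), h2$trait)
  econ <- lapply(list(res_ots, res_rnd), function(r) {
    dsg <- if (r$label == "OTS1") ots else rnd
    cost <- cost_model(dsg, unit_costs = unit_costs,
                       genotyping_usd_per_sample = genotyping_usd_per_sample,
                       n_samples = n_parents)
    rr <- response_per_investment(r$pa, h2v, cost, scenario = r$label)
    data.frame(scenario = r$label, phenotyping_usd = rr$phenotyping_usd,
               genotyping_usd = rr$genotyping_usd, total_usd = rr$total_usd,
               mean_accuracy = rr$mean_accuracy,
               gain_per_10k = rr$gain_per_budget)
  })
  put(do.call(rbind, econ), "economics.csv")

  art <- unique(art)
  manifest <- data.frame(file = basename(art),
                         md5 = unname(tools::md5sum(art)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(kernel = kern, n_core = n_core, ots = ots, random = rnd,
                 blues = blues, h2 = h2, trait_cov = tc,
                 pa = list(ots = res_ots$pa, random = res_rnd$pa),
                 econ = do.call(rbind, econ), manifest = manifest))
}

#' Restrict a BLUE table to the cells of a training design
#'
#' @param blues a \code{blue_table}.
#' @param design a \code{training_design}.
#' @return \code{blue_table} containing only the design's cells.
#' @export
restrict_blues <- function(blues, design) {
  d <- blues$data
  key <- paste(d$genotype, d$env, d$trait)
  dk <- paste(design$cells$genotype, design$cells$env, design$cells$trait)
  blues$data <- d[key %in% dk, , drop = FALSE]
  blues
}

read_pipeline_inputs <- function(paths) {
  need <- c("markers", "cross_plan", "phenotypes", "weather")
  for (nm in need) {
    if (is.null(paths[[nm]]))
      stopf("pipeline input stage '%s': no path configured", nm)
    if (!file.exists(paths[[nm]]))
      stopf("pipeline input stage '%s': file not found: %s", nm, paths[[nm]])
  }
  parents <- read_markers(paths$markers, role = "parent")
  plan <- utils::read.csv(paths$cross_plan, stringsAsFactors = FALSE)
  hybrids <- synthesize_hybrids(parents, plan)
  markers <- marker_matrix(rbind(parents$dosage, hybrids$dosage),
                           role = c(parents$role, hybrids$role))
  ph <- utils::read.csv(paths$phenotypes, stringsAsFactors = FALSE)
  weather <- utils::read.csv(paths$weather, stringsAsFactors = FALSE)
  list(markers = markers, cross_plan = plan, plots = plot_records(ph),
       weather = weather, truth = NULL, ec = NULL)
}
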