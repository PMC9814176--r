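#' CV1 / CV2 cross-validation partitions
#'
#' CV1 emulates predicting never-phenotyped genotypes: whole genotypes are
#' sampled into training (default 70\%), so every test genotype has zero
#' training cells. CV2 emulates incomplete trial networks: cells are
#' sampled, stratified by genotype so that every genotype keeps at least one
#' training cell somewhere.
#'
#' @param cells data.frame of panel cells (genotype, env, trait) or a
#'   \code{composite_kernel}.
#' @param scheme "CV1" or "CV2".
#' @param n_partitions number of random partitions (default 50).
#' @param train_fraction fraction of the sampling unit (genotypes for CV1,
#'   cells for CV2) used for training (default 0.70).
#' @param seed RNG seed.
#' @return list of partitions, each with \code{train} and \code{test}
#'   integer row indices into \code{cells}, plus fields scheme/replicate.
#' @export
make_cv_partitions <- function(cells, scheme = c("CV1", "CV2"),
                               n_partitions = 50L, train_fraction = 0.70,
                               seed = 1L) {
  scheme <- match.arg(scheme)
  if (inherits(cells, "composite_kernel")) cells <- cells$cells
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  genos <- unique(cells$genotype)
  n <- nrow(cells)
  lapply(seq_len(n_partitions), function(rep) {
    if (scheme == "CV1") {
      ng <- max(1L, round(train_fraction * length(genos)))
      tg <- sample_safe(genos, ng)
      train <- which(cells$genotype %in% tg)
    } else {
      ntr <- max(length(genos), round(train_fraction * n))
      train <- sort(sample_safe(seq_len(n), ntr))
      # re-stratify: every genotype keeps >= 1 training cell
      missing_g <- setdiff(genos, unique(cells$genotype[train]))
      for (g in missing_g) {
        own <- which(cells$genotype == g)
        pick <- own[sample.int(length(own), 1L)]
        # swap with a training cell of an over-represented genotype
        cnt <- table(cells$genotype[train])
        rich <- names(cnt)[cnt >= 2]
        if (!length(rich)) stopf("panel too small for CV2 stratification")
        victim <- train[cells$genotype[train] %in% rich]
        train <- sort(c(setdiff(train, victim[sample.int(length(victim), 1L)]),
                        pick))
      }
      train
    }
    test <- setdiff(seq_len(n), train)
    list(scheme = scheme, replicate = rep, train = train, test = test)
  })
}

#' Prediction ability on test cells
#'
#' Pearson correlation between predictions and observed adjusted means
#' (BLUEs), computed within trait x environment groups on the test cells,
#' then averaged over environments per trait and over traits.
#'
#' @param pred data.frame with columns genotype, env, trait, yhat (e.g.
#'   \code{\link{predict_cells}} output).
#' @param observed a \code{blue_table} or data.frame with value column.
#' @param test_cells data.frame (genotype, env, trait) of the test set.
#' @param min_group minimum test cells per trait x env group (default 3;
#'   smaller or zero-variance groups are dropped with a warning).
#' @return a \code{pa_report}: \code{by_env} (trait x env PA), \code{by_trait}
#'   (per-trait mean over environments), \code{overall} (across-trait mean).
#' @export
prediction_ability <- function(pred, observed, test_cells,
                               min_group = 3L) {
  obs <- if (inherits(observed, "blue_table")) observed$data else
    as.data.frame(observed)
  key <- function(d) paste(d$genotype, d$env, d$trait)
  tk <- key(test_cells)
  po <- match(tk, key(obs)); pp <- match(tk, key(pred))
  if (anyNA(pp)) stopf("test cells missing from predictions")
  d <- data.frame(trait = test_cells$trait, env = test_cells$env,
                  obs = obs$value[po], pred = pred$yhat[pp])
  d <- d[!is.na(d$obs), , drop = FALSE]
  grp <- split(d, list(d$trait, d$env), drop = TRUE)
  rows <- lapply(grp, function(g) {
    if (nrow(g) < min_group || stats::sd(g$obs) == 0 || stats::sd(g$pred) == 0) {
      warnf("degenerate PA group %s / %s dropped", g$trait[1], g$env[1])
      return(NULL)
    }
    data.frame(trait = g$trait[1], env = g$env[1],
               pa = stats::cor(g$obs, g$pred), n = nrow(g))
  })
  by_env <- do.call(rbind, rows)
  if (is.null(by_env) || !nrow(by_env)) stopf("no valid PA groups")
  by_trait <- stats::aggregate(pa ~ trait, by_env, mean)
  structure(list(by_env = by_env, by_trait = by_trait,
                 overall = mean(by_trait$pa)), class = "pa_report")
}

#' @export
print.pa_report <- function(x, ...) {
  cat("prediction ability (per trait, mean over environments):\n")
  print(x$by_trait, row.names = FALSE)
  cat(sprintf("across-trait mean: %.2f\n", round_half_up(x$overall, 2)))
  invisible(x)
}

#' Average prediction-ability reports over partitions
#'
#' @param reports list of \code{pa_report}s (one per partition).
#' @return list with \code{by_trait} (mean and sd per trait) and
#'   \code{overall} (mean, sd).
#' @export
summarize_pa <- function(reports) {
  pt <- do.call(rbind, lapply(reports, `[[`, "by_trait"))
  by_trait <- do.call(rbind, lapply(split(pt, pt$trait), function(g)
    data.frame(trait = g$trait[1], pa = mean(g$pa), sd = stats::sd(g$pa))))
  ov <- vapply(reports, `[[`, 0, "overall")
  list(by_trait = by_trait,
       overall = c(mean = mean(ov), sd = stats::sd(ov)))
}

#' Percent change between two reported values
#'
#' \eqn{100 (new - old) / old}, rounded half-up to \code{digits} decimals --
#' the convention used when reporting prediction-ability increases between
#' nested training-set scenarios.
#'
#' @param old,new values (old non-zero).
#' @param digits decimals for the reported percentage (default 1).
#' @return percentage.
#' @export
percent_change <- function(old, new, digits = 1) {
  if (any(old == 0)) stopf("old value must be non-zero")
  round_half_up(100 * (new - old) / old, digits)
}

#' Phenotyping + genotyping cost of a training design
#'
#' Phenotyping cost sums the per-plot trait cost over the design's cells
#' times replicates per cell; genotyping is a flat per-sample rate. Due to
#' the F1 nature of single-cross hybrids only parental inbreds need
#' genotyping, so \code{n_samples} is conventionally the number of parents
#' (an alternative convention counts all hybrids; the argument is explicit).
#'
#' @param design a \code{training_design} or data.frame of cells with a
#'   trait column.
#' @param unit_costs named per-plot phenotyping cost per trait, USD
#'   (default GY 4, PH 2, EH 2).
#' @param genotyping_usd_per_sample USD per genotyped sample (default 20).
#' @param n_samples number of genotyped samples.
#' @param reps_per_cell replicates phenotyped per selected cell (default 1).
#' @return an \code{econ_report} (cost part): phenotyping, genotyping,
#'   total USD, and the inputs.
#' @export
cost_model <- function(design, unit_costs = c(GY = 4, PH = 2, EH = 2),
                       genotyping_usd_per_sample = 20, n_samples,
                       reps_per_cell = 1) {
  cells <- if (inherits(design, "training_design")) design$cells else
    as.data.frame(design)
  unknown <- setdiff(unique(cells$trait), names(unit_costs))
  if (length(unknown)) stopf("no unit cost for trait(s): %s",
                             paste(unknown, collapse = ", "))
  pheno <- sum(unit_costs[cells$trait]) * reps_per_cell
  geno <- genotyping_usd_per_sample * n_samples
  structure(list(phenotyping_usd = as.numeric(pheno),
                 genotyping_usd = as.numeric(geno),
                 total_usd = as.numeric(pheno + geno),
                 reps_per_cell = reps_per_cell, n_samples = n_samples,
                 unit_costs = unit_costs), class = "econ_report")
}

#' Response to selection per 10,000 USD invested
#'
#' Per-trait accuracy is \eqn{PA_t / \sqrt{H^2_t}}; the gain per budget is
#' the mean accuracy divided by total cost, scaled to the budget (default
#' 10,000 USD). Phenotypic-selection mode (\code{ps = TRUE}) follows the
#' conventional recipe of setting \eqn{PA_t = 1} and charging phenotyping
#' only (note this makes accuracy \eqn{1/\sqrt{H^2}} which can exceed 1;
#' \code{ps_accuracy = "sqrt_h2"} offers the alternative of accuracy
#' \eqn{\sqrt{H^2}}).
#'
#' @param pa per-trait prediction abilities: named vector or a
#'   \code{pa_report}.
#' @param h2 named per-trait broad-sense heritabilities in (0, 1].
#' @param costs an \code{econ_report} from \code{\link{cost_model}}.
#' @param budget reporting base, USD (default 10000).
#' @param ps phenotypic-selection mode.
#' @param ps_accuracy "one_over_sqrt_h2" (printed recipe) or "sqrt_h2".
#' @param scenario label carried into the report.
#' @return completed \code{econ_report} with per-trait accuracy,
#'   mean accuracy and \code{gain_per_budget}.
#' @export
response_per_investment <- function(pa, h2, costs, budget = 10000,
                                    ps = FALSE,
                                    ps_accuracy = c("one_over_sqrt_h2",
                                                    "sqrt_h2"),
                                    scenario = "GP") {
  ps_accuracy <- match.arg(ps_accuracy)
  if (inherits(pa, "pa_report"))
    pa <- stats::setNames(pa$by_trait$pa, pa$by_trait$trait)
  stopifnot(all(h2 > 0), all(h2 <= 1))
  h2 <- h2[names(pa)]
  if (anyNA(h2)) stopf("missing heritability for some trait")
  if (ps) {
    acc <- if (ps_accuracy == "one_over_sqrt_h2") 1 / sqrt(h2) else sqrt(h2)
    total <- costs$phenotyping_usd
  } else {
    acc <- pa / sqrt(h2)
    total <- costs$total_usd
  }
  if (total <= 0) stopf("total cost must be positive")
  out <- costs
  out$scenario <- scenario
  out$accuracy <- acc
  out$mean_accuracy <- mean(acc)
  out$total_usd_used <- total
  out$gain_per_budget <- mean(acc) / total * budget
  out
}

#' @export
print.econ_report <- function(x, ...) {
  cat(sprintf("econ_report%s: phenotyping %.0f USD + genotyping %.0f USD = %.0f USD\n",
              if (!is.null(x$scenario)) paste0(" [", x$scenario, "]") else "",
              x$phenotyping_usd, x$genotyping_usd, x$total_usd))
  if (!is.null(x$gain_per_budget))
    cat(sprintf("mean accuracy %.3f; gain per 10,000 USD: %.5f\n",
                x$mean_accuracy, x$gain_per_budget))
  invisible(x)
}
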