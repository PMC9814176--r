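#' Simulation configuration for a synthetic hybrid trial
#'
#' Describes a partial-diallel hybrid panel evaluated in a small
#' multi-environment, multi-trait network: inbred founders genotyped at
#' biallelic SNPs, F1 hybrids from a crossing plan, environments described
#' by daily weather summarized into environmental covariates, three traits
#' with a target genetic correlation structure, additive + dominance + G x E
#' + residual variance components calibrated to target entry-mean
#' heritabilities, and an RCBD or augmented-block plot layout.
#'
#' @param n_parents number of inbred founders.
#' @param n_hybrids number of single-cross hybrids (must not exceed
#'   \code{choose(n_parents, 2)}).
#' @param n_markers number of biallelic SNPs.
#' @param q_env number of environments.
#' @param n_blocks blocks per environment (RCBD) or number of augmented
#'   blocks.
#' @param traits trait ids (defaults GY, PH, EH).
#' @param trait_means,trait_genetic_sd per-trait intercepts and genetic
#'   standard deviations on the observed scale (t/ha for GY, cm for PH/EH).
#' @param genetic_correlation target trait x trait genetic correlation
#'   matrix (PSD, unit diagonal) of the raw traits.
#' @param h2 per-trait target broad-sense heritability on an entry-mean
#'   basis, in (0, 1).
#' @param dominance_ratio dominance share of the genetic main-effect
#'   variance (default 0.15).
#' @param gxe_ratio G x E variance as a multiple of the genetic main-effect
#'   variance (default 0.5; ~1.5 is a strongly interactive network).
#' @param gxe_structure "K_E" draws G x E deviations with environment
#'   covariance equal to the enviromic kernel (so enviromic similarity
#'   genuinely structures the interaction); "compound_symmetry" uses a
#'   constant between-environment effect correlation \code{rho_e}.
#' @param rho_e between-environment correlation for compound symmetry.
#' @param block_design "rcbd" (every hybrid in every block) or "augmented"
#'   (entries unreplicated, two check hybrids in every block).
#' @param block_sd standard deviation of block effects (observed scale).
#' @param maf_range allele-frequency range of founder SNPs.
#' @param seed RNG seed.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_parents = 10L, n_hybrids = 30L, n_markers = 500L,
                       q_env = 3L, n_blocks = 2L,
                       traits = c("GY", "PH", "EH"),
                       trait_means = c(GY = 6, PH = 220, EH = 110),
                       trait_genetic_sd = c(GY = 0.8, PH = 10, EH = 8),
                       genetic_correlation = default_genetic_correlation(),
                       h2 = c(GY = 0.62, PH = 0.78, EH = 0.80),
                       dominance_ratio = 0.15, gxe_ratio = 0.5,
                       gxe_structure = c("K_E", "compound_symmetry"),
                       rho_e = 0.2,
                       block_design = c("rcbd", "augmented"),
                       block_sd = 0.3, maf_range = c(0.05, 0.95),
                       seed = 1L) {
  gxe_structure <- match.arg(gxe_structure)
  block_design <- match.arg(block_design)
  stopifnot(n_hybrids <= choose(n_parents, 2), all(h2 > 0), all(h2 < 1),
            dominance_ratio >= 0, dominance_ratio < 1)
  genetic_correlation <- as.matrix(genetic_correlation)
  if (any(abs(diag(genetic_correlation) - 1) > 1e-12))
    stopf("correlation diagonal must be 1")
  if (min(eigen(genetic_correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-10)
    stopf("infeasible (non-PSD) correlation matrix")
  structure(as.list(environment()), class = "sim_config")
}

#' Default target genetic correlations of the raw traits
#'
#' Moderate positive GY-PH and GY-EH correlations and a strong PH-EH
#' correlation, the typical pattern in tropical maize hybrids (the ideotype
#' transform applied downstream flips the height traits' sign).
#' @return 3 x 3 correlation matrix.
#' @export
default_genetic_correlation <- function() {
  R <- matrix(c(1, 0.55, 0.58,
                0.55, 1, 0.82,
                0.58, 0.82, 1), 3, 3)
  dimnames(R) <- list(c("GY", "PH", "EH"), c("GY", "PH", "EH"))
  R
}

#' Simulate a full synthetic dataset
#'
#' Generates founders, hybrids, daily weather, environmental covariates,
#' plot-level phenotypes and the underlying truth. Genetic main effects are
#' built from centered marker dosages with correlated per-trait marker
#' effects and rescaled so realized variances hit their targets exactly;
#' dominance effects come from heterozygosity codes; G x E deviations are
#' drawn with genotype covariance \eqn{G_a} and environment covariance
#' either the realized enviromic kernel \eqn{K_E} or compound symmetry; the
#' residual variance is solved from the target entry-mean heritability
#' \eqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/n_E + \sigma^2_e /
#' (n_E n_{rep}))}. Seed-deterministic.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{markers} (parents + hybrids
#'   \code{marker_matrix}), \code{cross_plan}, \code{weather},
#'   \code{ec} (scaled \code{enviro_covariates}), \code{k_e}
#'   (\code{env_kernel}), \code{plots} (\code{plot_records}), and
#'   \code{truth} (true cell-level genetic values and variance components).
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  tids <- cfg$traits
  nt <- length(tids)

  # founders: fully inbred, dosage 0/2
  p <- stats::runif(cfg$n_markers, cfg$maf_range[1], cfg$maf_range[2])
  founders <- matrix(2 * (stats::runif(cfg$n_parents * cfg$n_markers) <
                            rep(p, each = cfg$n_parents)),
                     cfg$n_parents, cfg$n_markers,
                     dimnames = list(sprintf("P%02d", seq_len(cfg$n_parents)),
                                     sprintf("m%04d", seq_len(cfg$n_markers))))
  parents <- marker_matrix(founders, role = "parent")

  prs <- utils::combn(rownames(founders), 2)
  take <- sort(sample.int(ncol(prs), cfg$n_hybrids))
  cross_plan <- data.frame(mother = prs[1, take], father = prs[2, take],
                           hybrid = sprintf("H%03d", seq_len(cfg$n_hybrids)),
                           stringsAsFactors = FALSE)
  hybrids <- synthesize_hybrids(parents, cross_plan)
  markers <- marker_matrix(rbind(parents$dosage, hybrids$dosage),
                           role = c(parents$role, hybrids$role))

  weather <- simulate_weather(cfg$q_env, seed = cfg$seed + 7L)
  ec <- scale_ec_matrix(summarize_env_covariates(weather))
  k_e <- env_kernel(ec)
  envs <- k_e$environment_ids

  # genetic machinery on the hybrid panel
  st <- allele_stats(markers, subset = cross_plan$hybrid)
  poly <- !is.na(st$maf) & st$maf > 0
  hyb_qc <- marker_matrix(hybrids$dosage[, poly, drop = FALSE], role = "hybrid")
  st <- st[poly, , drop = FALSE]
  Ga <- additive_grm(hyb_qc, st)$matrix

  Zc <- sweep(hyb_qc$dosage, 2, 2 * st$p, "-")
  B <- matrix(stats::rnorm(ncol(Zc) * nt), ncol(Zc), nt) %*%
    chol(cfg$genetic_correlation + diag(1e-10, nt))
  uA <- Zc %*% B
  # dominance effects independent of the additive ones but sharing the
  # target trait correlation, so the total genetic correlation hits target
  H <- (hyb_qc$dosage == 1) - rep(2 * st$p * (1 - st$p), each = nrow(Zc))
  uD <- H %*% (matrix(stats::rnorm(ncol(H) * nt), ncol(H), nt) %*%
                 chol(cfg$genetic_correlation + diag(1e-10, nt)))

  sdg <- cfg$trait_genetic_sd[tids]
  var_a <- (1 - cfg$dominance_ratio) * sdg^2
  var_d <- cfg$dominance_ratio * sdg^2
  rescale <- function(M, target_var) {
    s <- apply(M, 2, stats::sd)
    sweep(M, 2, sqrt(target_var) / pmax(s, 1e-12), "*")
  }
  uA <- rescale(uA, var_a); uD <- rescale(uD, var_d)
  g_main <- uA + uD
  # recolor the combined main effects to the exact target covariance
  # (diag(sd) R diag(sd)) so realized variances and correlations hit their
  # targets regardless of kinship-induced sampling noise
  g_main <- sweep(g_main, 2, colMeans(g_main), "-")
  Sig_t <- diag(sdg) %*% cfg$genetic_correlation %*% diag(sdg)
  g_main <- g_main %*% solve(chol(stats::cov(g_main))) %*% chol(Sig_t)
  rownames(g_main) <- cross_plan$hybrid
  colnames(g_main) <- tids

  # G x E deviations, cell matrix hybrid x env per trait
  var_ge <- cfg$gxe_ratio * sdg^2
  Ecov <- if (cfg$gxe_structure == "K_E") k_e$matrix else
    (1 - cfg$rho_e) * diag(cfg$q_env) + cfg$rho_e
  Lg <- chol(Ga + diag(1e-6, nrow(Ga)))
  Le <- chol(Ecov + diag(1e-8, cfg$q_env))
  ge <- lapply(seq_len(nt), function(ti) {
    M <- crossprod(Lg, matrix(stats::rnorm(cfg$n_hybrids * cfg$q_env),
                              cfg$n_hybrids, cfg$q_env)) %*% Le
    M <- M - mean(M)
    M * sqrt(var_ge[ti]) / stats::sd(M)
  })
  names(ge) <- tids

  env_eff <- matrix(stats::rnorm(cfg$q_env * nt, 0, sdg / 2), cfg$q_env, nt,
                    dimnames = list(envs, tids))

  # residual variance from the target entry-mean heritability
  n_rep <- if (cfg$block_design == "rcbd") cfg$n_blocks else 1
  var_g <- sdg^2
  var_e <- (var_g / cfg$h2[tids] - var_g - var_ge / cfg$q_env) *
    cfg$q_env * n_rep
  if (any(var_e <= 0))
    stopf("target heritability unattainable with this G x E ratio")

  # plot layout
  hids <- cross_plan$hybrid
  checks <- hids[1:2]
  layout <- list()
  for (e in seq_len(cfg$q_env)) {
    if (cfg$block_design == "rcbd") {
      for (b in seq_len(cfg$n_blocks))
        layout[[length(layout) + 1L]] <-
          data.frame(genotype = hids, env = envs[e], block = paste0("B", b),
                     is_check = hids %in% checks[1])
    } else {
      entries <- setdiff(hids, checks)
      bl <- rep(seq_len(cfg$n_blocks), length.out = length(entries))
      layout[[length(layout) + 1L]] <-
        data.frame(genotype = c(entries, rep(checks, each = cfg$n_blocks)),
                   env = envs[e],
                   block = paste0("B", c(bl, rep(seq_len(cfg$n_blocks),
                                                 times = length(checks)))),
                   is_check = c(rep(FALSE, length(entries)),
                                rep(TRUE, length(checks) * cfg$n_blocks)))
    }
  }
  plots <- do.call(rbind, layout)
  blk_key <- paste(plots$env, plots$block)
  blk_eff <- stats::rnorm(length(unique(blk_key)), 0, cfg$block_sd)
  names(blk_eff) <- unique(blk_key)

  gi <- match(plots$genotype, hids)
  ei <- match(plots$env, envs)
  truth_cells <- expand.grid(trait = tids, env = envs, genotype = hids,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth_cells <- truth_cells[, c("genotype", "env", "trait")]
  for (ti in seq_len(nt)) {
    tr <- tids[ti]
    gcell <- g_main[gi, ti] + ge[[tr]][cbind(gi, ei)]
    plots[[tr]] <- cfg$trait_means[tr] + env_eff[ei, ti] + blk_eff[blk_key] +
      gcell + stats::rnorm(nrow(plots), 0, sqrt(var_e[ti]))
  }
  tgi <- match(truth_cells$genotype, hids)
  tei <- match(truth_cells$env, envs)
  tti <- match(truth_cells$trait, tids)
  truth_cells$genetic_value <- g_main[cbind(tgi, tti)] +
    mapply(function(g, e, t) ge[[t]][g, e], tgi, tei, truth_cells$trait)
  truth_cells$expected_blue <- cfg$trait_means[truth_cells$trait] +
    env_eff[cbind(tei, tti)] + truth_cells$genetic_value

  truth <- list(cells = truth_cells,
                variance_components = data.frame(
                  trait = tids, var_a = as.numeric(var_a),
                  var_d = as.numeric(var_d), var_ge = as.numeric(var_ge),
                  var_e = as.numeric(var_e)),
                genetic_main = g_main, gxe = ge, env_effects = env_eff,
                check_genotype = checks[1])

  list(markers = markers, cross_plan = cross_plan, weather = weather,
       ec = ec, k_e = k_e,
       plots = plot_records(plots, traits = tids), truth = truth,
       config = cfg)
}

#' Simulate daily weather for a trial network
#'
#' 120 days after emergence of rainfall (mm, accumulative), mean air
#' temperature (deg C) and relative humidity (\%) with environment-specific
#' regimes, the minimal variable set the EC summarizer expects.
#'
#' @param q number of environments.
#' @param n_days season length (default 121 days, 0..120).
#' @param seed RNG seed.
#' @return data.frame (env, day, rainfall, temperature, humidity).
#' @export
simulate_weather <- function(q, n_days = 121L, seed = 1L) {
  set.seed(seed)
  out <- lapply(seq_len(q), function(e) {
    base_t <- stats::runif(1, 18, 28)
    wet <- stats::runif(1, 0.2, 0.6)
    data.frame(env = sprintf("E%02d", e), day = 0:(n_days - 1L),
               rainfall = stats::rexp(n_days, 1 / 6) *
                 (stats::runif(n_days) < wet),
               temperature = base_t + 4 * sin(2 * pi * (0:(n_days - 1L)) / n_days) +
                 stats::rnorm(n_days, 0, 1.5),
               humidity = pmin(100, pmax(20, stats::rnorm(n_days, 55 + 40 * wet, 8))))
  })
  do.call(rbind, out)
}

#' Bundled deterministic fixtures
#'
#' Three fixed-seed synthetic datasets used throughout the test-suite and
#' examples: \code{"mini-hel"} (30 hybrids x 3 environments x 3 traits,
#' RCBD, strong K_E-driven G x E), \code{"mini-usp"} (50 hybrids x 4
#' environments x 3 traits, augmented blocks), and \code{"toy6"} (a 6-cell
#' composite kernel -- 3 genotypes x 2 environments x 1 trait -- whose
#' exhaustive PEV-optimal training pair is computed by enumeration and
#' attached).
#'
#' @param name fixture name.
#' @return for the dataset fixtures, the \code{\link{simulate_dataset}}
#'   output; for "toy6", a list with \code{kernel}, \code{best_pair} and
#'   \code{best_fitness}.
#' @export
golden_fixture <- function(name = c("mini-hel", "mini-usp", "toy6")) {
  name <- match.arg(name)
  if (name == "mini-hel") {
    return(simulate_dataset(sim_config(
      n_parents = 10L, n_hybrids = 30L, n_markers = 400L, q_env = 3L,
      n_blocks = 2L, gxe_ratio = 1.5, gxe_structure = "K_E",
      h2 = c(GY = 0.5, PH = 0.6, EH = 0.6), seed = 101L)))
  }
  if (name == "mini-usp") {
    return(simulate_dataset(sim_config(
      n_parents = 11L, n_hybrids = 50L, n_markers = 400L, q_env = 4L,
      n_blocks = 10L, block_design = "augmented", block_sd = 1,
      h2 = c(GY = 0.56, PH = 0.84, EH = 0.89), seed = 202L)))
  }
  # toy6: tiny deterministic kernel; exhaustive optimum by enumeration
  G <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.4,
                0.2, 0.4, 1), 3, 3,
              dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  E <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
              dimnames = list(c("e1", "e2"), c("e1", "e2")))
  T_ <- matrix(1, 1, 1, dimnames = list("t1", "t1"))
  k <- composite_kernel(G, E, T_, kind = "custom")
  pairs <- utils::combn(n_cells(k), 2, simplify = FALSE)
  fits <- vapply(pairs, function(pr) pev_mean(k, pr), 0)
  list(kernel = k, pairs = pairs, fitnesses = fits,
       best_pair = pairs[[which.min(fits)]], best_fitness = min(fits))
}
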