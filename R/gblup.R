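#' Gibbs sampler configuration
#'
#' Defaults follow common practice for Bayesian whole-genome regression:
#' 10,000 iterations, 1,000 burn-in, thinning 2, prior degrees of freedom 5,
#' and prior variance scales that split half the phenotypic variance equally
#' across the random terms (the other half going to the residual).
#'
#' @param iterations total Gibbs iterations.
#' @param burn_in discarded initial iterations (< iterations).
#' @param thin thinning interval (>= 1).
#' @param df0 prior degrees of freedom for every variance component.
#' @param r2 prior fraction of variance attributed to the genetic terms
#'   jointly.
#' @param seed RNG seed (fit is bit-reproducible given the seed).
#' @return a \code{gibbs_config} list.
#' @export
gibbs_config <- function(iterations = 10000L, burn_in = 1000L, thin = 2L,
                         df0 = 5, r2 = 0.5, seed = 1L) {
  stopifnot(burn_in < iterations, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 df0 = df0, r2 = r2, seed = as.integer(seed)),
            class = "gibbs_config")
}

# term catalogue per model id; E-slot structure: J = all-ones (main effect,
# constant across environments), I = identity (environment-specific,
# uncorrelated), K = enviromic kernel (environment similarity)
model_term_table <- function(model) {
  switch(model,
    M1 = list(A = c("G", "J"), D = c("D", "J")),
    M2 = list(A = c("G", "J"), D = c("D", "J"),
              AE = c("G", "I"), DE = c("D", "I")),
    M3 = list(A = c("G", "J"), D = c("D", "J"), W = c("J", "K")),
    M4 = list(A = c("G", "J"), D = c("D", "J"), W = c("J", "K"),
              AE = c("G", "I"), DE = c("D", "I")),
    M5 = list(A = c("G", "J"), D = c("D", "J"), W = c("J", "K"),
              AW = c("G", "K"), DW = c("D", "K")),
    stopf("unknown model id %s (use M1..M5)", model))
}

#' Build the random-term covariance factors of models M1-M5
#'
#' Under genotype-major cell ordering the Hadamard-product covariances of
#' the reaction-norm models reduce to Kronecker forms over (genotype,
#' environment) cells: main additive/dominance effects are \eqn{G_a \otimes
#' J_q} / \eqn{G_d \otimes J_q} (constant across environments), G x E
#' interactions are \eqn{G_a \otimes I_q} / \eqn{G_d \otimes I_q}, the
#' enviromic main effect is \eqn{J_g \otimes K_E}, and G x W interactions
#' are \eqn{G_a \otimes K_E} / \eqn{G_d \otimes K_E}. In multi-trait mode
#' every term additionally carries the trait covariance \eqn{\Sigma_T} in
#' the trait slot.
#'
#' Model term sets: M1 = \{A, D\}; M2 = M1 + \{AE, DE\}; M3 = M1 + \{W\};
#' M4 = M3 + \{AE, DE\}; M5 = M3 + \{AW, DW\}.
#'
#' @param model model id "M1".."M5".
#' @param g_a,g_d additive and dominance \code{genomic_relationship}s (or
#'   bare matrices).
#' @param k_e an \code{env_kernel} (or bare matrix); required for M3-M5.
#' @param env_ids environment ids (required when \code{k_e} absent).
#' @param trait_cov trait covariance matrix for multi-trait terms (NULL for
#'   single-trait).
#' @return named list of terms, each with fields \code{G}, \code{E},
#'   \code{T} (factor matrices).
#' @export
build_model_terms <- function(model, g_a, g_d, k_e = NULL, env_ids = NULL,
                              trait_cov = NULL) {
  Ga <- if (inherits(g_a, "genomic_relationship")) g_a$matrix else as.matrix(g_a)
  Gd <- if (inherits(g_d, "genomic_relationship")) g_d$matrix else as.matrix(g_d)
  Ke <- if (inherits(k_e, "env_kernel")) k_e$matrix else
    if (!is.null(k_e)) as.matrix(k_e) else NULL
  env_ids <- env_ids %||% rownames(Ke)
  if (is.null(env_ids)) stopf("environment ids are required")
  q <- length(env_ids)
  gid <- rownames(Ga)
  tab <- model_term_table(model)
  needs_ke <- any(vapply(tab, function(x) "K" %in% x, TRUE))
  if (needs_ke && is.null(Ke)) stopf("model %s needs an enviromic kernel", model)
  Jq <- matrix(1, q, q, dimnames = list(env_ids, env_ids))
  Iq <- diag(q); dimnames(Iq) <- list(env_ids, env_ids)
  Jg <- matrix(1, nrow(Ga), nrow(Ga), dimnames = list(gid, gid))
  if (!is.null(Ke)) dimnames(Ke) <- list(env_ids, env_ids)
  lapply(tab, function(slots) {
    G <- switch(slots[1], G = Ga, D = Gd, J = Jg)
    E <- switch(slots[2], J = Jq, I = Iq, K = Ke)
    list(G = G, E = E, T = trait_cov)
  })
}

#' Fit a multi-kernel Bayesian GBLUP by Gibbs sampling
#'
#' Linear mixed model over genotype x environment (x trait) cells with
#' fixed environment (x trait) intercepts and the random genetic terms of
#' models M1-M5 (\code{\link{build_model_terms}}). Each random term has
#' covariance (scalar variance) x (Kronecker-structured correlation); terms
#' are sampled in their observed-cell eigenbasis, which keeps every full
#' conditional conjugate; variance components follow scaled-inverse
#' chi-square full conditionals; the residual is one variance (single-trait)
#' or per-trait variances (multi-trait). Missing panel cells are handled by
#' restricting the likelihood to observed cells; predictions for all panel
#' cells come from the kernel relationships.
#'
#' @param y observations: a \code{blue_table} or data.frame with columns
#'   genotype, env, trait, value (one row per observed cell).
#' @param model model id "M1".."M5".
#' @param g_a,g_d additive and dominance relationship matrices.
#' @param k_e enviromic kernel (required for M3-M5).
#' @param env_ids panel environments (default: from \code{k_e} or \code{y}).
#' @param trait_mode "single" fits each trait independently; "multi" fits
#'   all traits jointly with the trait covariance in every genetic term.
#' @param trait_cov known trait covariance matrix (multi-trait mode). When
#'   NULL it is estimated as the sample covariance of the observed cells,
#'   pairwise-complete.
#' @param cfg a \code{\link{gibbs_config}}.
#' @param fixed_variances optional named list fixing variance components at
#'   given values instead of sampling them (term names and/or "residual");
#'   used e.g. to run the sampler at a known variance ratio.
#' @param verbose print progress.
#' @return a \code{gblup_fit}: \code{cells} (all panel cells with posterior
#'   mean/sd of total genetic value and \code{yhat} including fixed
#'   effects), \code{variance_components} (posterior means + effective
#'   sample sizes), \code{beta} (fixed effects), \code{model},
#'   \code{trait_mode}.
#' @export
fit_gblup <- function(y, model = "M1", g_a, g_d, k_e = NULL, env_ids = NULL,
                      trait_mode = c("single", "multi"), trait_cov = NULL,
                      cfg = gibbs_config(), fixed_variances = NULL,
                      verbose = FALSE) {
  trait_mode <- match.arg(trait_mode)
  obs <- if (inherits(y, "blue_table")) y$data else as.data.frame(y)
  stopifnot(all(c("genotype", "env", "trait", "value") %in% names(obs)))
  obs <- obs[!is.na(obs$value), , drop = FALSE]
  if (!nrow(obs)) stopf("no observed cells")
  Ga <- if (inherits(g_a, "genomic_relationship")) g_a$matrix else as.matrix(g_a)
  gid <- rownames(Ga)
  bad <- setdiff(obs$genotype, gid)
  if (length(bad)) stopf("observed genotypes missing from G: %s",
                         paste(utils::head(bad, 3), collapse = ", "))
  env_ids <- env_ids %||%
    (if (inherits(k_e, "env_kernel")) k_e$environment_ids else NULL) %||%
    sort(unique(obs$env))
  traits <- sort(unique(obs$trait))
  if (trait_mode == "multi" && is.null(trait_cov)) {
    trait_cov <- plugin_trait_cov(obs, traits)
  }

  if (trait_mode == "single") {
    fits <- lapply(traits, function(tr) {
      terms <- build_model_terms(model, g_a, g_d, k_e, env_ids, trait_cov = NULL)
      gibbs_run(obs[obs$trait == tr, , drop = FALSE], terms, gid, env_ids,
                tr, cfg, multi = FALSE, fixed_variances = fixed_variances,
                verbose = verbose)
    })
    cells <- do.call(rbind, lapply(fits, `[[`, "cells"))
    vc <- do.call(rbind, lapply(seq_along(fits), function(i) {
      v <- fits[[i]]$variance_components
      v$trait <- traits[i]
      v
    }))
    beta <- do.call(rbind, lapply(seq_along(fits), function(i) {
      b <- fits[[i]]$beta
      b$trait <- traits[i]
      b
    }))
  } else {
    tc <- trait_cov[traits, traits, drop = FALSE]
    check_psd(tc)
    terms <- build_model_terms(model, g_a, g_d, k_e, env_ids, trait_cov = tc)
    one <- gibbs_run(obs, terms, gid, env_ids, traits, cfg, multi = TRUE,
                     fixed_variances = fixed_variances, verbose = verbose)
    cells <- one$cells
    vc <- one$variance_components
    beta <- one$beta
  }
  structure(list(cells = cells, variance_components = vc, beta = beta,
                 model = model, trait_mode = trait_mode,
                 traits = traits, env_ids = env_ids, config = cfg),
            class = "gblup_fit")
}

plugin_trait_cov <- function(obs, traits) {
  key <- paste(obs$genotype, obs$env)
  cells <- unique(key)
  wide <- matrix(NA_real_, length(cells), length(traits),
                 dimnames = list(NULL, traits))
  for (tr in traits) {
    sel <- obs$trait == tr
    wide[match(key[sel], cells), tr] <- obs$value[sel]
  }
  cv <- stats::cov(wide, use = "pairwise.complete.obs")
  if (anyNA(cv)) stopf("cannot estimate trait covariance: disjoint traits")
  # nudge to PSD if pairwise-complete estimate is slightly indefinite
  ev <- eigen(cv, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-8 * max(ev$values))
  cv <- ev$vectors %*% diag(ev$values, length(ev$values)) %*% t(ev$vectors)
  dimnames(cv) <- list(traits, traits)
  cv
}

# core sampler over observed cells; traits: single trait id (multi=FALSE)
# or full trait vector (multi=TRUE)
gibbs_run <- function(obs, terms, gid, env_ids, traits, cfg, multi,
                      fixed_variances = NULL, verbose = FALSE) {
  set.seed(cfg$seed)
  n <- nrow(obs)
  yv <- obs$value
  vy <- stats::var(yv)
  if (!is.finite(vy)) vy <- 0
  t_ids <- if (multi) traits else traits[1]
  # fixed-effect groups: env (single) or env x trait (multi)
  fgrp <- if (multi) factor(paste(obs$env, obs$trait, sep = "\r"),
                            levels = as.vector(outer(env_ids, t_ids,
                                                     paste, sep = "\r")))
          else factor(obs$env, levels = env_ids)
  fidx <- as.integer(fgrp)
  nf <- nlevels(fgrp)
  fobs <- tabulate(fidx, nf)

  # per-term observed-cell covariance eigenstructure
  gi_o <- match(obs$genotype, gid)
  ei_o <- match(obs$env, env_ids)
  ti_o <- match(obs$trait, t_ids)
  prep <- lapply(terms, function(tm) {
    K <- tm$G[gi_o, gi_o] * tm$E[ei_o, ei_o]
    if (multi) K <- K * tm$T[ti_o, ti_o]
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    keep <- eg$values > max(eg$values) * 1e-8
    list(U = eg$vectors[, keep, drop = FALSE], d = eg$values[keep])
  })
  nt <- length(terms)

  # residual variance per trait class (one class when single-trait)
  rgrp <- if (multi) ti_o else rep(1L, n)
  nr <- max(rgrp)
  robs <- tabulate(rgrp, nr)

  df0 <- cfg$df0
  s0_g <- cfg$r2 * max(vy, 1e-6) / nt
  s0_e <- (1 - cfg$r2) * max(vy, 1e-6)

  a <- lapply(prep, function(p) numeric(length(p$d)))
  s2 <- rep(s0_g, nt)
  s2e <- rep(s0_e, nr)
  fixed_s2 <- rep(FALSE, nt); fixed_e <- FALSE
  if (!is.null(fixed_variances)) {
    for (nm in names(fixed_variances)) {
      if (nm == "residual") { s2e[] <- fixed_variances[[nm]]; fixed_e <- TRUE }
      else if (nm %in% names(terms)) {
        i <- match(nm, names(terms)); s2[i] <- fixed_variances[[nm]]
        fixed_s2[i] <- TRUE
      } else stopf("fixed variance for unknown component %s", nm)
    }
  }
  beta <- as.numeric(tapply(yv, fidx, mean)[as.character(seq_len(nf))])
  beta[is.na(beta)] <- 0
  resid <- yv - beta[fidx]

  keep_iters <- seq(cfg$burn_in + 1L, cfg$iterations, by = cfg$thin)
  n_keep <- length(keep_iters)
  a_mu <- lapply(a, identity)
  # posterior means of coefficients are accumulated Rao-Blackwellized (the
  # conditional means given the current state), which cuts the Monte Carlo
  # error of cell-level genetic values substantially
  a_bar <- lapply(a, function(x) x * 0)
  g_obs_sum <- numeric(n); g_obs_sq <- numeric(n)
  s2_draws <- matrix(NA_real_, n_keep, nt,
                     dimnames = list(NULL, names(terms)))
  s2e_draws <- matrix(NA_real_, n_keep, nr)
  beta_sum <- numeric(nf)
  kk <- 0L

  for (it in seq_len(cfg$iterations)) {
    w <- 1 / s2e[rgrp]
    homo <- nr == 1L
    # fixed effects (flat prior)
    ymg <- resid + beta[fidx]          # y minus genetic terms
    sw <- numeric(nf); swy <- numeric(nf)
    tmp <- rowsum(cbind(w, w * ymg), fidx)
    gidx <- as.integer(rownames(tmp))
    sw[gidx] <- tmp[, 1]; swy[gidx] <- tmp[, 2]
    beta_new <- swy / pmax(sw, 1e-12) +
      stats::rnorm(nf) / sqrt(pmax(sw, 1e-12))
    beta_new[fobs == 0] <- 0
    resid <- resid + (beta - beta_new)[fidx]
    beta <- beta_new

    for (m in seq_len(nt)) {
      p <- prep[[m]]
      r_m <- resid + as.numeric(p$U %*% a[[m]])
      if (homo) {
        prec <- 1 / s2e[1] + 1 / (s2[m] * p$d)
        mu <- crossprod(p$U, r_m)[, 1] / s2e[1] / prec
        a_new <- mu + stats::rnorm(length(prec)) / sqrt(prec)
      } else {
        Uw <- p$U * w
        M <- crossprod(p$U, Uw)
        diag(M) <- diag(M) + 1 / (s2[m] * p$d)
        R <- chol(M)
        rhs <- crossprod(Uw, r_m)[, 1]
        mu <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
        a_new <- mu + backsolve(R, stats::rnorm(length(rhs)))
      }
      resid <- r_m - as.numeric(p$U %*% a_new)
      a[[m]] <- a_new
      a_mu[[m]] <- mu
      if (!fixed_s2[m]) {
        ss <- sum(a_new^2 / p$d)
        s2[m] <- (df0 * s0_g + ss) / stats::rchisq(1, df0 + length(p$d))
        if (!is.finite(s2[m])) stopf("divergent variance draw at iteration %d", it)
      }
    }
    if (!fixed_e) for (tcl in seq_len(nr)) {
      sel <- rgrp == tcl
      s2e[tcl] <- (df0 * s0_e + sum(resid[sel]^2)) /
        stats::rchisq(1, df0 + robs[tcl])
    }
    if (any(!is.finite(s2e))) stopf("divergent residual draw at iteration %d", it)

    if (it > cfg$burn_in && (it - cfg$burn_in - 1L) %% cfg$thin == 0L) {
      kk <- kk + 1L
      for (m in seq_len(nt)) a_bar[[m]] <- a_bar[[m]] + a_mu[[m]]
      gg <- 0
      for (m in seq_len(nt)) gg <- gg + as.numeric(prep[[m]]$U %*% a_mu[[m]])
      g_obs_sum <- g_obs_sum + gg
      g_obs_sq <- g_obs_sq + gg^2
      s2_draws[kk, ] <- s2
      s2e_draws[kk, ] <- s2e
      beta_sum <- beta_sum + beta
    }
    if (verbose && it %% 1000L == 0L)
      message(sprintf("iter %d / %d", it, cfg$iterations))
  }

  # posterior-mean genetic values at every panel cell via kernel regression
  # of the eigen-basis coefficients
  panel <- expand.grid(trait = t_ids, env = env_ids, genotype = gid,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  panel <- panel[, c("genotype", "env", "trait")]
  gi_a <- match(panel$genotype, gid)
  ei_a <- match(panel$env, env_ids)
  ti_a <- match(panel$trait, t_ids)
  ghat <- numeric(nrow(panel))
  for (m in seq_len(nt)) {
    tm <- terms[[m]]; p <- prep[[m]]
    Kao <- tm$G[gi_a, gi_o] * tm$E[ei_a, ei_o]
    if (multi) Kao <- Kao * tm$T[ti_a, ti_o]
    ghat <- ghat + as.numeric(Kao %*% (p$U %*% (a_bar[[m]] / kk / p$d)))
  }
  beta_mean <- beta_sum / kk
  fidx_a <- if (multi) match(paste(panel$env, panel$trait, sep = "\r"),
                             levels(fgrp))
            else match(panel$env, env_ids)
  panel$gvalue <- ghat
  panel$yhat <- ghat + beta_mean[fidx_a]
  # posterior sd available only at observed cells (draws retained there)
  panel$gvalue_sd <- NA_real_
  okey <- paste(obs$genotype, obs$env, obs$trait)
  pm <- match(okey, paste(panel$genotype, panel$env, panel$trait))
  panel$gvalue_sd[pm] <- sqrt(pmax(g_obs_sq / kk - (g_obs_sum / kk)^2, 0))
  # at observed cells prefer the direct posterior mean of the sampled values
  panel$gvalue[pm] <- g_obs_sum / kk
  panel$yhat[pm] <- panel$gvalue[pm] + beta_mean[fidx_a[pm]]

  vc <- data.frame(
    component = c(names(terms),
                  if (nr == 1L) "residual" else paste0("residual_", t_ids)),
    estimate = c(colMeans(s2_draws), colMeans(s2e_draws)),
    ess = c(apply(s2_draws, 2, ess), apply(s2e_draws, 2, ess)),
    stringsAsFactors = FALSE)
  bdf <- data.frame(level = levels(fgrp), estimate = as.numeric(beta_mean),
                    stringsAsFactors = FALSE)
  list(cells = panel, variance_components = vc, beta = bdf,
       draws = list(s2 = s2_draws, s2e = s2e_draws))
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("gblup_fit %s (%s-trait): %d panel cells, %d traits\n",
              x$model, x$trait_mode, nrow(x$cells), length(x$traits)))
  print(x$variance_components, row.names = FALSE)
  invisible(x)
}

#' Predictions for panel cells
#'
#' Posterior-mean total genetic value plus fixed environment effect for
#' every requested cell, including genotype x environment x trait
#' combinations that were never observed (predicted through the kernel
#' relationships).
#'
#' @param fit a \code{gblup_fit}.
#' @param cells data.frame (genotype, env, trait) or NULL for all panel
#'   cells.
#' @return data.frame with columns genotype, env, trait, gvalue, yhat.
#' @export
predict_cells <- function(fit, cells = NULL) {
  out <- fit$cells
  if (is.null(cells)) return(out)
  key <- paste(cells$genotype, cells$env, cells$trait)
  idx <- match(key, paste(out$genotype, out$env, out$trait))
  if (anyNA(idx)) stopf("cell ids outside the panel")
  out[idx, , drop = FALSE]
}

#' Write a fit summary and predictions to CSV
#' @param fit a \code{gblup_fit}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_gblup <- function(fit, dir, prefix = "gblup") {
  p1 <- file.path(dir, paste0(prefix, "_varcomp.csv"))
  p2 <- file.path(dir, paste0(prefix, "_predictions.csv"))
  utils::write.csv(fit$variance_components, p1, row.names = FALSE)
  utils::write.csv(fit$cells, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
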