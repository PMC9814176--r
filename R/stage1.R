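#' Ear-height ideotype transform
#'
#' Recodes ear height as the negated absolute distance to an ideal ideotype
#' height (default 80 cm): \eqn{EH_{tr} = -|EH - 80|}. The transform is 0 at
#' the ideotype and increasingly negative away from it, which forces a
#' negative correlation with grain yield so all traits can be selected
#' upward simultaneously.
#'
#' @param eh_cm ear height in cm (non-negative; NA passed through).
#' @param ideotype_cm ideal ear height in cm (default 80).
#' @return transformed ear height (<= 0).
#' @export
transform_ear_height <- function(eh_cm, ideotype_cm = 80) {
  if (any(eh_cm < 0, na.rm = TRUE)) stopf("ear height must be non-negative")
  -abs(eh_cm - ideotype_cm)
}

#' Construct a table of plot-level phenotype records
#'
#' @param df data.frame with columns genotype, env, block, is_check
#'   (logical, optional, default FALSE) and one numeric column per trait.
#' @param traits trait column names; default: all remaining numeric columns.
#' @return a \code{plot_records} object.
#' @export
plot_records <- function(df, traits = NULL) {
  stopifnot(all(c("genotype", "env", "block") %in% names(df)))
  if (is.null(df$is_check)) df$is_check <- FALSE
  traits <- traits %||% setdiff(names(df),
                                c("genotype", "env", "block", "is_check"))
  stopifnot(length(traits) >= 1)
  structure(list(data = df, traits = traits), class = "plot_records")
}

#' Stage-1 genotype BLUEs per environment and trait
#'
#' Two-step analysis, step one: adjusted genotype means (BLUEs) from a
#' linear model with genotype fixed and blocks either fixed (RCBD with few
#' blocks) or random (augmented designs, where the block variance is
#' estimated by REML and checks enter as a separate fixed class).
#'
#' @param p a \code{plot_records} object.
#' @param design "blocks_fixed" or "blocks_random".
#' @param scope "per_environment" (default) fits each environment
#'   separately; "across_environments" fits one model pooling environments
#'   with environment as an additional fixed class.
#' @return a \code{blue_table}: long data.frame (genotype, env, trait,
#'   value), \code{standardized = FALSE}. Attribute \code{block_variance}
#'   holds the REML block-variance estimates for random-block fits.
#' @export
fit_stage1_blues <- function(p, design = c("blocks_fixed", "blocks_random"),
                             scope = c("per_environment", "across_environments")) {
  design <- match.arg(design)
  scope <- match.arg(scope)
  df <- p$data
  out <- list()
  bv <- list()
  env_groups <- if (scope == "per_environment") split(df, df$env) else list(all = df)
  for (envname in names(env_groups)) {
    dat <- env_groups[[envname]]
    dat$genotype <- factor(dat$genotype)
    dat$block <- factor(if (scope == "per_environment") dat$block
                        else paste(dat$env, dat$block, sep = ":"))
    dat$envf <- factor(dat$env)
    for (tr in p$traits) {
      dat$y <- dat[[tr]]
      sub <- dat[!is.na(dat$y), , drop = FALSE]
      if (!nrow(sub)) next
      sub$genotype <- droplevels(sub$genotype)
      sub$block <- droplevels(sub$block)
      multi_env <- scope == "across_environments" && length(unique(sub$env)) > 1
      if (design == "blocks_fixed") {
        fm <- if (multi_env) y ~ genotype + envf + block else y ~ genotype + block
        fit <- stats::lm(fm, data = sub)
        if (any(is.na(stats::coef(fit)[grep("^genotype", names(stats::coef(fit)))])))
          warnf("non-estimable genotype effects in %s/%s", envname, tr)
        grid <- expand.grid(genotype = levels(sub$genotype),
                            block = levels(sub$block),
                            envf = levels(sub$envf), stringsAsFactors = FALSE)
        pr <- stats::predict(fit, newdata = grid)
        blue <- tapply(pr, grid$genotype, mean)
      } else {
        # check genotypes are a fixed class like any other genotype level;
        # their replication across blocks is what identifies the block variance
        fm <- if (multi_env) y ~ genotype + envf + (1 | block)
              else y ~ genotype + (1 | block)
        fit <- suppressMessages(suppressWarnings(
          lme4::lmer(fm, data = sub,
                     control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                 check.nobs.vs.rankZ = "ignore",
                                                 calc.derivs = FALSE))))
        bv[[paste(envname, tr, sep = ".")]] <-
          as.data.frame(lme4::VarCorr(fit))$vcov[1]
        fe <- lme4::fixef(fit)
        gl <- levels(sub$genotype)
        gcoef <- stats::setNames(rep(0, length(gl)), gl)
        hit <- paste0("genotype", gl) %in% names(fe)
        gcoef[gl[hit]] <- fe[paste0("genotype", gl[hit])]
        extra <- 0
        if (multi_env) extra <- extra + mean(c(0, fe[grep("^envf", names(fe))]))
        blue <- fe[["(Intercept)"]] + gcoef + extra
      }
      envcol <- if (scope == "per_environment") envname else
        rep(NA_character_, length(blue))
      out[[length(out) + 1L]] <- data.frame(
        genotype = names(blue), env = envcol, trait = tr,
        value = as.numeric(blue), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  structure(list(data = res, standardized = FALSE,
                 traits = p$traits), class = "blue_table",
            block_variance = unlist(bv))
}

#' Standardize traits in a BLUE table
#'
#' Each trait is mean-centered and scaled to unit sample variance across all
#' its genotype x environment cells; missing cells stay missing. Idempotent
#' up to numerical precision.
#'
#' @param b a \code{blue_table}.
#' @return standardized \code{blue_table}.
#' @export
standardize_traits <- function(b) {
  d <- b$data
  for (tr in unique(d$trait)) {
    sel <- d$trait == tr
    x <- d$value[sel]
    if (sum(!is.na(x)) < 2) stopf("trait %s has fewer than 2 values", tr)
    s <- stats::sd(x, na.rm = TRUE)
    if (s == 0) stopf("trait %s has zero variance", tr)
    d$value[sel] <- (x - mean(x, na.rm = TRUE)) / s
  }
  b$data <- d
  b$standardized <- TRUE
  b
}

#' Broad-sense heritability on an entry-mean basis
#'
#' Companion random-genotype model: \code{y ~ env + (1|genotype) +
#' (1|genotype:env)} (the G x E term requires >= 2 environments), blocks
#' nested in environments as fixed. Heritability is computed on an
#' entry-mean basis, \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/n_E
#' + \sigma^2_e/(n_E n_{rep})),} with \eqn{n_E} and \eqn{n_{rep}} the
#' harmonic means of realized environment and replicate counts.
#'
#' @param p a \code{plot_records} object.
#' @return data.frame (trait, H2, var_g, var_ge, var_e).
#' @export
estimate_heritability <- function(p) {
  df <- p$data
  n_env <- length(unique(df$env))
  out <- lapply(p$traits, function(tr) {
    dat <- df[!is.na(df[[tr]]), , drop = FALSE]
    dat$y <- dat[[tr]]
    dat$genotype <- factor(dat$genotype)
    dat$envblock <- factor(paste(dat$env, dat$block, sep = ":"))
    dat$envf <- factor(dat$env)
    # harmonic means of realized counts per genotype
    ge_counts <- table(dat$genotype, dat$envf) > 0
    nE <- 1 / mean(1 / pmax(rowSums(ge_counts), 1))
    reps <- table(paste(dat$genotype, dat$envf))
    nR <- 1 / mean(1 / reps)
    fm <- if (n_env > 1) y ~ envblock + (1 | genotype) + (1 | genotype:envf)
          else y ~ envblock + (1 | genotype)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fm, data = dat,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.rankZ = "ignore",
                                             calc.derivs = FALSE))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vg <- max(0, vc$vcov[vc$grp == "genotype"])
    vge <- if (n_env > 1) max(0, vc$vcov[vc$grp == "genotype:envf"]) else 0
    ve <- vc$vcov[vc$grp == "Residual"]
    denom <- vg + vge / nE + ve / (nE * nR)
    h2 <- if (denom > 0) min(1, max(0, vg / denom)) else 0
    data.frame(trait = tr, H2 = h2, var_g = vg, var_ge = vge, var_e = ve)
  })
  do.call(rbind, out)
}

#' Trait covariance and correlation from a BLUE table
#'
#' Pairwise-complete Pearson correlations and covariances between traits
#' over genotype x environment cells.
#'
#' @param b a \code{blue_table}.
#' @return list with \code{correlation} and \code{covariance} (trait x
#'   trait matrices).
#' @export
trait_covariance <- function(b) {
  d <- b$data
  traits <- unique(d$trait)
  cells <- unique(d[, c("genotype", "env")])
  wide <- matrix(NA_real_, nrow(cells), length(traits),
                 dimnames = list(NULL, traits))
  key <- paste(d$genotype, d$env)
  ckey <- paste(cells$genotype, cells$env)
  for (tr in traits) {
    sel <- d$trait == tr
    wide[match(key[sel], ckey), tr] <- d$value[sel]
  }
  for (i in seq_along(traits)) for (j in seq_len(i)) {
    n_ok <- sum(stats::complete.cases(wide[, c(i, j)]))
    if (n_ok < 3) stopf("fewer than 3 complete pairs for traits %s and %s",
                        traits[i], traits[j])
  }
  list(correlation = stats::cor(wide, use = "pairwise.complete.obs"),
       covariance = stats::cov(wide, use = "pairwise.complete.obs"))
}

#' Write / read a BLUE table as long CSV
#' @param b a \code{blue_table}.
#' @param path output file.
#' @export
write_blues <- function(b, path) {
  utils::write.csv(b$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blues
#' @param standardized flag recorded on the object read back.
#' @export
read_blues <- function(path, standardized = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(data = d, standardized = standardized,
                 traits = unique(d$trait)), class = "blue_table")
}
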