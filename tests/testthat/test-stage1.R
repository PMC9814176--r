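test_that("ear-height ideotype transform is anchored and symmetric", {
  expect_equal(transform_ear_height(80), 0)
  expect_equal(transform_ear_height(100), -20)
  expect_equal(transform_ear_height(60), -20)
  expect_equal(transform_ear_height(80, ideotype_cm = 90), -10)
  expect_true(all(transform_ear_height(c(0, 40, 80, 130)) <= 0))
  expect_true(is.na(transform_ear_height(NA_real_)))
  expect_error(transform_ear_height(-5), "non-negative")
})

test_that("trait standardization is exact, idempotent and missing-preserving", {
  b <- structure(list(data = data.frame(
    genotype = rep(c("g1", "g2", "g3", "g4"), 2),
    env = "E1",
    trait = rep(c("GY", "PH"), each = 4),
    value = c(1, 2, 3, NA, 10, 20, 30, 40)),
    standardized = FALSE, traits = c("GY", "PH")), class = "blue_table")
  s <- standardize_traits(b)
  expect_equal(s$data$value[1:3], c(-1, 0, 1))   # sd(1,2,3) = 1
  expect_true(is.na(s$data$value[4]))
  expect_true(s$standardized)
  expect_equal(standardize_traits(s)$data$value, s$data$value,
               tolerance = 1e-12)
  bz <- b; bz$data$value[5:8] <- 7
  expect_error(standardize_traits(bz), "zero variance")
})

test_that("fixed-block BLUEs equal plot means in a balanced noiseless RCBD", {
  g <- paste0("g", 1:6)
  true <- c(2, -1, 0, 3, 1, -2)
  df <- expand.grid(genotype = g, env = "E1", block = c("B1", "B2"),
                    stringsAsFactors = FALSE)
  df$is_check <- FALSE
  df$GY <- 10 + true[match(df$genotype, g)]        # zero block effects
  b <- fit_stage1_blues(plot_records(df, "GY"), design = "blocks_fixed")
  pm <- tapply(df$GY, df$genotype, mean)
  expect_equal(b$data$value[match(names(pm), b$data$genotype)],
               as.numeric(pm), tolerance = 1e-10)

  # known block shifts +1 / -1: genotype values recovered exactly
  df$GY <- 10 + true[match(df$genotype, g)] + ifelse(df$block == "B1", 1, -1)
  b2 <- fit_stage1_blues(plot_records(df, "GY"), design = "blocks_fixed")
  v <- b2$data$value[match(g, b2$data$genotype)]
  expect_equal(v - mean(v), true - mean(true), tolerance = 1e-10)
})

test_that("fixed-block BLUE solver agrees with a normal-equations oracle", {
  set.seed(61)
  for (rep in 1:3) {
    ng <- sample(5:12, 1); nb <- sample(2:3, 1)
    df <- expand.grid(genotype = paste0("g", 1:ng), block = paste0("B", 1:nb),
                      stringsAsFactors = FALSE)
    df$env <- "E1"; df$is_check <- FALSE
    df$GY <- rnorm(nrow(df))
    df <- df[-sample(nrow(df), 2), ]               # mild imbalance
    df <- df[df$genotype %in% names(which(table(df$genotype) > 0)), ]
    b <- fit_stage1_blues(plot_records(df, "GY"), design = "blocks_fixed")
    # oracle: explicit least squares through the normal equations, then
    # genotype means averaged over all block levels
    X <- model.matrix(~ 0 + genotype + block, df)
    bt <- solve(crossprod(X), crossprod(X, df$GY))
    gl <- sort(unique(df$genotype))
    bl_cols <- grep("^block", rownames(bt))
    bl_means <- c(0, bt[bl_cols, 1])
    oracle <- bt[paste0("genotype", gl), 1] + mean(bl_means)
    expect_equal(b$data$value[match(gl, b$data$genotype)], unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("random-block REML recovers the block variance in an augmented design", {
  set.seed(71)
  nb <- 200
  ng <- 300
  g <- paste0("g", seq_len(ng))
  checks <- c("c1", "c2")
  entries <- data.frame(genotype = g, env = "E1",
                        block = paste0("B", rep(seq_len(nb), length.out = ng)),
                        is_check = FALSE)
  chk <- expand.grid(genotype = checks, block = paste0("B", seq_len(nb)),
                     stringsAsFactors = FALSE)
  chk$env <- "E1"; chk$is_check <- TRUE
  df <- rbind(entries, chk[, names(entries)])
  geff <- rnorm(ng + 2, 0, 1)
  names(geff) <- c(g, checks)
  beff <- rnorm(nb, 0, 2)                          # block variance 4
  names(beff) <- paste0("B", seq_len(nb))
  df$GY <- 5 + geff[df$genotype] + beff[df$block] + rnorm(nrow(df), 0, 1)
  b <- fit_stage1_blues(plot_records(df, "GY"), design = "blocks_random")
  bv <- attr(b, "block_variance")
  expect_lt(abs(bv[["E1.GY"]] - 4), 0.8)
  # check genotypes get BLUEs like any entry
  expect_true(all(checks %in% b$data$genotype))
})

test_that("the REML optimum beats random profile grid points", {
  set.seed(81)
  nb <- 30
  df <- expand.grid(genotype = paste0("g", 1:15), block = paste0("B", 1:nb),
                    stringsAsFactors = FALSE)
  df$env <- "E1"; df$is_check <- FALSE
  df$GY <- rnorm(nrow(df)) + rnorm(nb, 0, 1.5)[match(df$block,
                                                     paste0("B", 1:nb))]
  df$genotype <- factor(df$genotype); df$block <- factor(df$block)
  fit <- lme4::lmer(GY ~ genotype + (1 | block), data = df, REML = TRUE)
  devfun <- do.call(lme4::mkLmerDevfun,
                    lme4::lFormula(GY ~ genotype + (1 | block), data = df,
                                   REML = TRUE))
  opt_dev <- devfun(lme4::getME(fit, "theta"))
  # the profiled REML criterion at the optimizer beats random grid points
  # of the block-variance-ratio profile
  for (th in runif(50, 0, 5)) expect_gte(devfun(th), opt_dev - 1e-6)
})

test_that("heritability estimation covers the limit cases and recovery", {
  g <- paste0("g", 1:40)
  df <- expand.grid(genotype = g, env = c("E1", "E2"), block = c("B1", "B2"),
                    stringsAsFactors = FALSE)
  df$is_check <- FALSE
  geff <- rnorm(40)
  # (near) zero residual and zero G x E: H2 -> 1
  df$GY <- geff[match(df$genotype, g)] + rnorm(nrow(df), 0, 1e-4)
  h <- estimate_heritability(plot_records(df, "GY"))
  expect_gt(h$H2, 0.99)
  # zero genotypic variance: H2 -> 0
  df$GY <- rnorm(nrow(df))
  h0 <- estimate_heritability(plot_records(df, "GY"))
  expect_lt(h0$H2, 0.15)
  expect_true(all(c(h$H2, h0$H2) >= 0 & c(h$H2, h0$H2) <= 1))
})

test_that("heritability recovery on simulated data hits the target band", {
  d <- simulate_dataset(sim_config(
    n_parents = 26L, n_hybrids = 300L, n_markers = 300L, q_env = 3L,
    n_blocks = 2L, h2 = c(GY = 0.6, PH = 0.6, EH = 0.6), gxe_ratio = 0.5,
    gxe_structure = "compound_symmetry", rho_e = 0, seed = 5L))
  h <- estimate_heritability(d$plots)
  expect_true(all(abs(h$H2 - 0.6) < 0.1))
})

test_that("trait covariance matches hand computations and handles errors", {
  mk <- function(vals) {
    long <- do.call(rbind, lapply(names(vals), function(tr)
      data.frame(genotype = paste0("g", seq_along(vals[[tr]])), env = "E1",
                 trait = tr, value = vals[[tr]])))
    structure(list(data = long, standardized = FALSE,
                   traits = names(vals)), class = "blue_table")
  }
  tc <- trait_covariance(mk(list(GY = 1:4, PH = 1:4)))
  expect_equal(unname(tc$correlation["GY", "PH"]), 1)
  tc2 <- trait_covariance(mk(list(GY = c(1, 2, 3, 4), PH = c(4, 3, 2, 1))))
  expect_equal(unname(tc2$correlation["GY", "PH"]), -1)
  expect_equal(unname(tc2$covariance["GY", "PH"]), -sd(1:4)^2,
               tolerance = 1e-12)
  expect_error(trait_covariance(mk(list(GY = 1:2, PH = 2:1))),
               "fewer than 3")
})

test_that("BLUE tables round-trip through long CSV", {
  dir <- withr::local_tempdir()
  d <- hel_fixture()
  b <- fit_stage1_blues(d$plots, design = "blocks_fixed")
  path <- write_blues(b, file.path(dir, "blues.csv"))
  back <- read_blues(path)
  expect_equal(back$data$value, b$data$value, tolerance = 1e-8)
  expect_equal(back$data$genotype, b$data$genotype)
})
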