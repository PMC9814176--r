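test_that("model term structures reduce to the documented Kronecker forms", {
  set.seed(3)
  Ga <- random_psd(3, "g"); Gd <- random_psd(3, "g")
  Ke <- random_psd(2, "e")
  tm <- build_model_terms("M2", Ga, Gd, env_ids = c("e1", "e2"))
  expect_named(tm, c("A", "D", "AE", "DE"))

  # Hadamard oracle on 3 genotypes x 2 envs: [Z_G Ga Z_G'] o [Z_E Z_E']
  # equals Ga x I_q under genotype-major ordering
  Zg <- kronecker(diag(3), matrix(1, 2, 1))
  Ze <- kronecker(matrix(1, 3, 1), diag(2))
  had <- (Zg %*% Ga %*% t(Zg)) * (Ze %*% t(Ze))
  expect_equal(had, kronecker(Ga, diag(2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(kronecker(unname(tm$AE$G), unname(tm$AE$E)),
               had, tolerance = 1e-12, ignore_attr = TRUE)
  # main effects: [Z_G Ga Z_G'] alone equals Ga x J_q
  expect_equal(Zg %*% Ga %*% t(Zg), kronecker(Ga, matrix(1, 2, 2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(kronecker(unname(tm$A$G), unname(tm$A$E)),
               Zg %*% Ga %*% t(Zg), tolerance = 1e-12, ignore_attr = TRUE)

  # model term sets
  expect_named(build_model_terms("M1", Ga, Gd, env_ids = c("e1", "e2")),
               c("A", "D"))
  m5 <- build_model_terms("M5", Ga, Gd, Ke)
  expect_named(m5, c("A", "D", "W", "AW", "DW"))
  expect_false(any(c("AE", "DE") %in% names(m5)))
  m4 <- build_model_terms("M4", Ga, Gd, Ke)
  expect_named(m4, c("A", "D", "W", "AE", "DE"))
  expect_error(build_model_terms("M9", Ga, Gd, Ke), "unknown model")
  expect_error(build_model_terms("M3", Ga, Gd, env_ids = c("e1", "e2")),
               "needs an enviromic kernel")

  # with K_E = I the G x W structures degenerate to the G x E ones
  Ieq <- diag(2); dimnames(Ieq) <- list(c("e1", "e2"), c("e1", "e2"))
  m5i <- build_model_terms("M5", Ga, Gd, Ieq)
  m2 <- build_model_terms("M2", Ga, Gd, env_ids = c("e1", "e2"))
  expect_equal(m5i$AW$G, m2$AE$G)
  expect_equal(unname(m5i$AW$E), unname(m2$AE$E))
  expect_equal(unname(m5i$DW$E), unname(m2$DE$E))
})

test_that("fixed-variance posterior means match the closed-form ridge solution", {
  set.seed(42)
  n <- 40
  M <- matrix(sample(0:2, n * 120, TRUE), n, 120,
              dimnames = list(sprintf("g%02d", 1:n), NULL))
  G <- tcrossprod(scale(M, scale = FALSE)) / 120
  G <- G / mean(diag(G))
  dimnames(G) <- list(rownames(M), rownames(M))
  u <- as.numeric(t(chol(G + diag(1e-6, n))) %*% rnorm(n))
  y <- u + rnorm(n)
  obs <- data.frame(genotype = rownames(M), env = "E1", trait = "GY",
                    value = y)
  fit <- fit_gblup(obs, model = "M1", g_a = G, g_d = diag(1e-8, n),
                   env_ids = "E1",
                   fixed_variances = list(A = 1, D = 1e-8, residual = 1),
                   cfg = gibbs_config(iterations = 4000, burn_in = 500,
                                      seed = 7))
  pred <- fit$cells[match(rownames(M), fit$cells$genotype), ]
  ghat <- as.numeric(G %*% solve(G + diag(n), y - mean(y)))
  expect_lt(max(abs(pred$gvalue - ghat)), 0.02)
})

test_that("fits are bit-reproducible given the seed", {
  p <- hel_prepared()
  gy <- p$blues; gy$data <- gy$data[gy$data$trait == "GY", ][1:45, ]
  cfg <- gibbs_config(iterations = 400, burn_in = 100, seed = 12)
  f1 <- fit_gblup(gy, model = "M2", g_a = p$g_a, g_d = p$g_d, k_e = p$data$k_e,
                  cfg = cfg)
  f2 <- fit_gblup(gy, model = "M2", g_a = p$g_a, g_d = p$g_d, k_e = p$data$k_e,
                  cfg = cfg)
  expect_identical(f1$cells$gvalue, f2$cells$gvalue)
  expect_identical(f1$variance_components$estimate,
                   f2$variance_components$estimate)
})

test_that("degenerate zero-variance data collapse the genetic values", {
  p <- hel_prepared()
  gy <- p$blues$data[p$blues$data$trait == "GY", ][1:30, ]
  gy$value <- 3
  fit <- fit_gblup(gy, model = "M1", g_a = p$g_a, g_d = p$g_d,
                   env_ids = p$data$k_e$environment_ids,
                   cfg = gibbs_config(iterations = 600, burn_in = 200,
                                      seed = 2))
  expect_lt(max(abs(fit$cells$gvalue)), 0.05)
  expect_true(all(fit$variance_components$estimate >= 0))
})

test_that("unobserved genotypes and duplicates are predicted through the kernel", {
  set.seed(55)
  n <- 12
  A <- matrix(rnorm(n * n), n, n)
  G <- crossprod(A) / n
  G[n, ] <- G[n - 1, ]; G[, n] <- G[, n - 1]; G[n, n] <- G[n - 1, n - 1]
  ids <- paste0("g", 1:n)
  dimnames(G) <- list(ids, ids)
  envs <- c("E1", "E2")
  obs <- expand.grid(genotype = ids[1:(n - 2)], env = envs,
                     stringsAsFactors = FALSE)
  obs$trait <- "GY"
  set.seed(56)
  obs$value <- rnorm(nrow(obs))
  fit <- fit_gblup(obs, model = "M1", g_a = G, g_d = diag(1e-8, n),
                   env_ids = envs,
                   cfg = gibbs_config(iterations = 800, burn_in = 200,
                                      seed = 3))
  # genotype g12 never observed: still predicted everywhere
  pr <- predict_cells(fit, data.frame(genotype = "g12", env = envs,
                                      trait = "GY"))
  expect_equal(nrow(pr), 2)
  expect_true(all(is.finite(pr$yhat)))
  # g11 and g12 are kernel-duplicates; g12 unobserved inherits g11's
  # kernel position, so predictions in the same environment are close
  pr11 <- predict_cells(fit, data.frame(genotype = "g11", env = "E1",
                                        trait = "GY"))
  expect_error(predict_cells(fit, data.frame(genotype = "nope", env = "E1",
                                             trait = "GY")),
               "outside the panel")
})

test_that("observed cells are tracked closely on near-noiseless data", {
  d <- simulate_dataset(sim_config(
    n_parents = 8L, n_hybrids = 20L, n_markers = 200L, q_env = 2L,
    n_blocks = 2L, gxe_ratio = 0.05, h2 = c(GY = 0.9, PH = 0.9, EH = 0.9),
    seed = 77L))
  blues <- fit_stage1_blues(d$plots, design = "blocks_fixed")
  gy <- blues; gy$data <- gy$data[gy$data$trait == "GY", ]
  hyb <- d$cross_plan$hybrid
  gy$data <- gy$data[gy$data$genotype %in% hyb, ]
  st <- allele_stats(d$markers, subset = hyb)
  ok <- !is.na(st$maf) & st$maf > 0
  hm <- marker_matrix(d$markers$dosage[hyb, ok, drop = FALSE], role = "hybrid")
  sth <- allele_stats(hm)
  fit <- fit_gblup(gy, model = "M2", g_a = additive_grm(hm, sth),
                   g_d = dominance_grm(hm, sth), k_e = d$k_e,
                   cfg = gibbs_config(iterations = 1500, burn_in = 300,
                                      seed = 5))
  pred <- predict_cells(fit, gy$data[, c("genotype", "env", "trait")])
  expect_gt(cor(pred$yhat, gy$data$value), 0.9)
})

test_that("multi-trait mode uses the trait covariance and per-trait residuals", {
  p <- hel_prepared()
  dsg <- random_design(p$kern_get, 60, seed = 4,
                       check_genotype = p$data$truth$check_genotype)
  ytr <- restrict_blues(p$blues, dsg)
  fit <- fit_gblup(ytr, model = "M4", g_a = p$g_a, g_d = p$g_d,
                   k_e = p$data$k_e, trait_mode = "multi",
                   trait_cov = p$trait_cov,
                   cfg = gibbs_config(iterations = 600, burn_in = 200,
                                      seed = 6))
  expect_equal(nrow(fit$cells), 270)
  expect_equal(sum(grepl("^residual_", fit$variance_components$component)), 3)
  expect_true(all(is.finite(fit$cells$yhat)))
  # every env x trait combination got a fixed-effect level
  expect_equal(nrow(fit$beta), 9)
})
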