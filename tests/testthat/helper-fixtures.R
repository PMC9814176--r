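# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

hel_fixture <- function() memo("mini_hel", function() golden_fixture("mini-hel"))

# mini-hel with stage-1 and kernel machinery prepared (the expensive shared
# state for gblup / design / acceptance tests)
hel_prepared <- function() memo("mini_hel_prep", function() {
  d <- hel_fixture()
  blues <- standardize_traits(fit_stage1_blues(d$plots, design = "blocks_fixed"))
  hyb <- rownames(d$markers$dosage)[d$markers$role == "hybrid"]
  blues$data <- blues$data[blues$data$genotype %in% hyb, , drop = FALSE]
  qc <- qc_markers(d$markers)
  st <- allele_stats(qc, subset = hyb)
  hm <- marker_matrix(qc$dosage[hyb, , drop = FALSE], role = "hybrid")
  g_a <- additive_grm(hm, st)
  g_d <- dominance_grm(hm, st)
  tc <- trait_covariance(blues)
  list(data = d, blues = blues, hybrids = hyb, g_a = g_a, g_d = g_d,
       trait_cov = tc$covariance,
       kern_get = composite_kernel(g_a, length(d$k_e$environment_ids),
                                   tc$covariance, kind = "GET",
                                   env_ids = d$k_e$environment_ids),
       kern_gwt = composite_kernel(g_a, d$k_e, tc$covariance, kind = "GWT"))
})

toy6_fixture <- function() memo("toy6", function() golden_fixture("toy6"))

# small random PSD matrix with ids
random_psd <- function(n, prefix = "i", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  M <- crossprod(A) / n
  dimnames(M) <- list(paste0(prefix, seq_len(n)), paste0(prefix, seq_len(n)))
  M
}

# brute-force additive GRM oracle: explicit double loop over individuals
# and markers on the centered codes (missing imputed at the marker mean of
# observed codes, the same rule the implementation documents)
additive_grm_oracle <- function(dosage, p) {
  n <- nrow(dosage); m <- ncol(dosage)
  W <- matrix(0, n, m)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      W[i, j] <- if (is.na(dosage[i, j])) NA_real_ else dosage[i, j] - 2 * p[j]
    }
    mu <- mean(W[, j], na.rm = TRUE)
    for (i in seq_len(n)) if (is.na(W[i, j])) W[i, j] <- mu
  }
  denom <- 0
  for (j in seq_len(m)) denom <- denom + 2 * p[j] * (1 - p[j])
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    G[i, k] <- sum(W[i, ] * W[k, ]) / denom
  }
  G
}

# dense PEV oracle computed from an explicitly materialized kernel
pev_oracle <- function(K, train, lambda, eval_cells = NULL) {
  U <- if (is.null(eval_cells)) setdiff(seq_len(nrow(K)), train) else eval_cells
  if (!length(U)) return(0)
  Ktt <- K[train, train, drop = FALSE] + diag(lambda, length(train))
  mean(vapply(U, function(i) {
    K[i, i] - K[i, train, drop = FALSE] %*% solve(Ktt, K[train, i])
  }, 0))
}
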