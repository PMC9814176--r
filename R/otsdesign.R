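#' APY-style spectral training-set size
#'
#' The number of kernel eigen-components needed to explain a target fraction
#' of total variation (default 98\%): the smallest n such that the n largest
#' eigenvalues sum to at least \code{threshold} times the trace. This plays
#' the role of the "core" size in APY-type relationship-matrix inversion and
#' is used here purely to size the optimized training set; which cells fill
#' the budget is decided by the genetic algorithm.
#'
#' @param s a \code{kernel_spectrum} or a numeric vector of eigenvalues.
#' @param threshold fraction of variation to capture, in (0, 1].
#' @return integer core size.
#' @export
apy_core_size <- function(s, threshold = 0.98) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  ev <- if (inherits(s, "kernel_spectrum")) s$values else as.numeric(s)
  if (any(!is.finite(ev))) stopf("non-finite eigenvalues")
  ev <- sort(ev, decreasing = TRUE)
  tot <- sum(ev)
  if (tot <= 0) stopf("kernel has zero total variation")
  as.integer(which(cumsum(ev) >= threshold * tot - 1e-12)[1])
}

#' Mean prediction error variance of untrained cells
#'
#' GBLUP prediction error variance on a unit genetic-variance scale: for the
#' untrained cell set U and training set T,
#' \deqn{PEV_i = K_{ii} - K_{iT} (K_{TT} + \lambda I)^{-1} K_{Ti},}
#' averaged over U. \eqn{\lambda} is the residual-to-genetic variance ratio
#' (default 1, i.e. h2 = 0.5 on the standardized scale). Lower is better;
#' this is the fitness minimized by the training-set genetic algorithm.
#'
#' @param k a \code{composite_kernel}.
#' @param training_cells integer flat cell indices of the training set.
#' @param lambda_ratio positive residual/genetic variance ratio.
#' @param eval_cells cells over which PEV is averaged (default: all cells
#'   not in the training set). Returns 0 when that set is empty.
#' @return mean PEV (numeric scalar).
#' @export
pev_mean <- function(k, training_cells, lambda_ratio = 1, eval_cells = NULL) {
  if (!length(training_cells)) stopf("training set is empty")
  tr <- sort(unique(as.integer(training_cells)))
  if (any(tr < 1 | tr > n_cells(k))) stopf("training cell index out of range")
  U <- eval_cells %||% setdiff(seq_len(n_cells(k)), tr)
  if (!length(U)) return(0)
  Ktt <- kernel_block(k, tr, tr)
  diag(Ktt) <- diag(Ktt) + lambda_ratio
  R <- tryCatch(chol(Ktt), error = function(e)
    stopf("singular training covariance (lambda_ratio too small?)"))
  Kut <- kernel_block(k, U, tr)
  X <- backsolve(R, t(Kut), transpose = TRUE)  # R^-T Ktu
  Kuu_diag <- kernel_block_diag(k, U)
  mean(Kuu_diag - colSums(X^2))
}

# diagonal entries of K over a cell index set, without the full block
kernel_block_diag <- function(k, idx) {
  gi <- match(k$cells$genotype, rownames(k$factors$G))[idx]
  ei <- match(k$cells$env, rownames(k$factors$E))[idx]
  ti <- match(k$cells$trait, rownames(k$factors$T))[idx]
  diag(k$factors$G)[gi] * diag(k$factors$E)[ei] * diag(k$factors$T)[ti]
}

#' Genetic-algorithm configuration
#'
#' @param population population size (>= 2).
#' @param generations maximum generations.
#' @param patience generations without improvement before stopping.
#' @param elite number of elite solutions carried over unchanged.
#' @param mutation_rate per-cell swap probability.
#' @param tabu_size bounded capacity of the tabu set (FIFO eviction).
#' @param lookahead_cap maximum number of candidate swaps scored by the
#'   steepest-swap look-ahead each generation.
#' @param seed RNG seed.
#' @return a \code{ga_config} list.
#' @export
ga_config <- function(population = 30L, generations = 100L, patience = 15L,
                      elite = 2L, mutation_rate = 0.1, tabu_size = 10000L,
                      lookahead_cap = 200L, seed = 1L) {
  stopifnot(population >= 2, mutation_rate >= 0, mutation_rate <= 1,
            elite >= 1, elite < population)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 patience = as.integer(patience), elite = as.integer(elite),
                 mutation_rate = mutation_rate,
                 tabu_size = as.integer(tabu_size),
                 lookahead_cap = as.integer(lookahead_cap),
                 seed = as.integer(seed)), class = "ga_config")
}

sample_safe <- function(x, size) x[sample.int(length(x), size)]

design_new <- function(k, sel_idx, check_idx, scenario, seed,
                       fitness = NA_real_) {
  sel_idx <- sort(unique(as.integer(sel_idx)))
  all_idx <- sort(unique(c(sel_idx, check_idx)))
  structure(list(cells = k$cells[all_idx, , drop = FALSE],
                 indices = all_idx, budget_indices = sel_idx,
                 check_indices = sort(check_idx),
                 provenance = list(kernel = k$kind, seed = seed,
                                   scenario = scenario),
                 fitness = fitness),
            class = "training_design")
}

#' @export
print.training_design <- function(x, ...) {
  cat(sprintf("training_design [%s, %s]: %d cells (%d budget + %d check), fitness %s\n",
              x$provenance$scenario, x$provenance$kernel,
              length(x$indices), length(x$budget_indices),
              length(x$check_indices),
              if (is.na(x$fitness)) "NA" else sprintf("%.5f", x$fitness)))
  invisible(x)
}

check_cell_indices <- function(k, check_genotype) {
  if (is.null(check_genotype)) return(integer())
  if (!check_genotype %in% k$cells$genotype) stopf("check genotype not in panel")
  which(k$cells$genotype == check_genotype)
}

#' Optimize a training set with a look-ahead genetic algorithm and tabu list
#'
#' Searches cell subsets of size \code{n} minimizing \code{\link{pev_mean}}.
#' Generational loop with elitism; crossover is the union of two parents
#' uniformly down-sampled to size n; mutation swaps each selected cell with
#' a random unselected one with probability \code{mutation_rate}; a bounded
#' tabu set of visited solutions diverts duplicates to a perturbed
#' neighbour; the look-ahead step applies one steepest single-swap local
#' improvement to the incumbent each generation. The check genotype's full
#' environment x trait cells are always included on top of the n budget.
#' Deterministic given \code{cfg$seed}.
#'
#' @param k a \code{composite_kernel}.
#' @param n training budget (cells, excluding check cells).
#' @param cfg a \code{\link{ga_config}}.
#' @param check_genotype id of the fully-phenotyped connectivity check
#'   (optional).
#' @param lambda_ratio passed to \code{\link{pev_mean}}.
#' @return a \code{training_design} with attribute \code{trajectory}, the
#'   per-generation incumbent fitness (non-increasing).
#' @export
optimize_training_set <- function(k, n, cfg = ga_config(),
                                  check_genotype = NULL, lambda_ratio = 1) {
  chk <- check_cell_indices(k, check_genotype)
  cand <- setdiff(seq_len(n_cells(k)), chk)
  if (n <= 0 || n > length(cand)) stopf("n must be in 1..%d", length(cand))
  set.seed(cfg$seed)

  cache <- new.env(parent = emptyenv())
  tabu <- character(0)
  fitness_of <- function(sel) {
    key <- paste(sel, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- pev_mean(k, c(sel, chk), lambda_ratio)
    cache[[key]] <- val
    tabu <<- c(tabu, key)
    if (length(tabu) > cfg$tabu_size) tabu <<- tabu[-1L]
    val
  }
  in_tabu <- function(sel) paste(sel, collapse = ",") %in% tabu
  perturb <- function(sel) {
    out <- setdiff(cand, sel)
    if (!length(out)) return(sel)
    sel[sample.int(length(sel), 1L)] <- out[sample.int(length(out), 1L)]
    sort(sel)
  }

  pop <- replicate(cfg$population, sort(sample_safe(cand, n)), simplify = FALSE)
  fit <- vapply(pop, fitness_of, 0)
  best <- pop[[which.min(fit)]]; best_fit <- min(fit)
  traj <- best_fit
  stall <- 0L

  for (gen in seq_len(cfg$generations)) {
    ord <- order(fit)
    pop <- pop[ord]; fit <- fit[ord]
    newpop <- pop[seq_len(cfg$elite)]
    while (length(newpop) < cfg$population) {
      # rank-weighted parent choice
      w <- rev(seq_along(pop))
      ps <- sample.int(length(pop), 2L, prob = w)
      u <- union(pop[[ps[1]]], pop[[ps[2]]])
      child <- if (length(u) > n) sort(sample(u, n)) else
        sort(c(u, sample_safe(setdiff(cand, u), n - length(u))))
      swap <- stats::runif(n) < cfg$mutation_rate
      if (any(swap)) {
        out <- setdiff(cand, child)
        take <- sample_safe(out, min(sum(swap), length(out)))
        child[which(swap)[seq_along(take)]] <- take
        child <- sort(child)
      }
      if (in_tabu(child)) child <- perturb(child)
      newpop[[length(newpop) + 1L]] <- child
    }
    pop <- newpop
    fit <- vapply(pop, fitness_of, 0)

    # look-ahead: steepest single swap on the incumbent
    inc <- pop[[which.min(fit)]]
    if (min(fit) <= best_fit) { best <- inc; best_fit <- min(fit) }
    la <- steepest_swap(best, cand, fitness_of, cfg$lookahead_cap)
    if (la$fitness < best_fit) {
      best <- la$sel; best_fit <- la$fitness
      pop[[which.max(fit)]] <- best
      fit[which.max(fit)] <- best_fit
    }
    improved <- best_fit < traj[length(traj)] - 1e-14
    traj <- c(traj, best_fit)
    stall <- if (improved) 0L else stall + 1L
    if (stall >= cfg$patience) break
  }
  d <- design_new(k, best, chk, "OTS", cfg$seed, fitness = best_fit)
  attr(d, "trajectory") <- traj
  d
}

steepest_swap <- function(sel, cand, fitness_of, cap) {
  out <- setdiff(cand, sel)
  pairs <- expand.grid(i = seq_along(sel), j = seq_along(out))
  if (nrow(pairs) > cap) pairs <- pairs[sample.int(nrow(pairs), cap), ]
  best_fit <- fitness_of(sel); best_sel <- sel
  for (r in seq_len(nrow(pairs))) {
    trial <- sel
    trial[pairs$i[r]] <- out[pairs$j[r]]
    trial <- sort(trial)
    f <- fitness_of(trial)
    if (f < best_fit) { best_fit <- f; best_sel <- trial }
  }
  list(sel = best_sel, fitness = best_fit)
}

#' Random training design of matched size
#'
#' Uniform sample of n candidate cells without replacement, plus the check
#' genotype's cells; the size-matched control for optimized designs.
#'
#' @inheritParams optimize_training_set
#' @param seed RNG seed.
#' @return a \code{training_design} (scenario "RANDOM").
#' @export
random_design <- function(k, n, seed = 1L, check_genotype = NULL) {
  chk <- check_cell_indices(k, check_genotype)
  cand <- setdiff(seq_len(n_cells(k)), chk)
  if (n <= 0 || n > length(cand)) stopf("n must be in 1..%d", length(cand))
  set.seed(seed)
  design_new(k, sample_safe(cand, n), chk, "RANDOM", seed)
}

#' Combine optimized training samples into larger scenarios
#'
#' Three independent GA samples form scenario OTS1; their pairwise unions
#' form OTS2 (three designs about twice the size); the full union forms the
#' single larger OTS3 design. Check cells are preserved; unions are
#' deduplicated, so they are smaller than the sum of sizes when samples
#' overlap.
#'
#' @param samples list of \code{training_design}s sharing kernel provenance.
#' @param mode "pairwise_union" or "full_union".
#' @param k the \code{composite_kernel} the designs were built on.
#' @return list of \code{training_design}s.
#' @export
combine_designs <- function(samples, mode = c("pairwise_union", "full_union"),
                            k) {
  mode <- match.arg(mode)
  kinds <- unique(vapply(samples, function(d) d$provenance$kernel, ""))
  if (length(kinds) > 1) stopf("designs come from different kernels")
  chk <- sort(unique(unlist(lapply(samples, `[[`, "check_indices"))))
  mk <- function(ds, label) {
    idx <- sort(unique(unlist(lapply(ds, `[[`, "budget_indices"))))
    design_new(k, idx, chk, label,
               seed = ds[[1]]$provenance$seed)
  }
  if (mode == "full_union") return(list(mk(samples, "OTS3")))
  prs <- utils::combn(length(samples), 2, simplify = FALSE)
  lapply(prs, function(ij) mk(samples[ij], "OTS2"))
}

#' Write / read a training design as long CSV
#'
#' Long-format tabular analogue of a selection heatmap: one row per panel
#' cell with a 0/1 \code{selected} column and a \code{check} column.
#'
#' @param design a \code{training_design}.
#' @param k the \code{composite_kernel} it indexes.
#' @param path output file.
#' @export
write_design <- function(design, k, path) {
  d <- k$cells
  d$selected <- as.integer(seq_len(nrow(d)) %in% design$indices)
  d$check <- as.integer(seq_len(nrow(d)) %in% design$check_indices)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, k) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  idx <- cell_index(k, d$genotype[d$selected == 1], d$env[d$selected == 1],
                    d$trait[d$selected == 1])
  chk <- cell_index(k, d$genotype[d$check == 1], d$env[d$check == 1],
                    d$trait[d$check == 1])
  design_new(k, setdiff(idx, chk), chk, "file", seed = NA_integer_)
}
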