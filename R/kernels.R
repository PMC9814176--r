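#' Kronecker composite kernel over (genotype, environment, trait) cells
#'
#' Covariance over all genotype x environment x trait cells, stored as its
#' Kronecker factors: \eqn{\Sigma_G \otimes \Sigma_E \otimes \Sigma_T}. The
#' GET kernel uses the identity for the environment factor (environments
#' assumed unrelated); the GWT kernel substitutes the enviromic kernel
#' \eqn{K_E} so that environmental similarity informs cell selection. Cells
#' are ordered genotype-major, environment next, trait fastest; the full
#' matrix is never materialized unless explicitly requested.
#'
#' @param g a \code{genomic_relationship} (or bare PSD matrix with dimnames)
#'   for the genotype factor.
#' @param env_part an \code{env_kernel}, a bare matrix, or the number of
#'   environments (interpreted as an identity factor, the GET convention).
#' @param t trait covariance matrix (PSD, dimnames = trait ids).
#' @param kind label: "GET", "GWT" or "custom".
#' @param env_ids,trait_ids ids used when the corresponding factor is given
#'   without dimnames.
#' @return a \code{composite_kernel} with fields \code{factors} (named list
#'   of matrices), \code{cells} (data.frame genotype/env/trait in flat cell
#'   order) and \code{kind}.
#' @export
composite_kernel <- function(g, env_part, t, kind = c("custom", "GET", "GWT"),
                             env_ids = NULL, trait_ids = NULL) {
  kind <- match.arg(kind)
  G <- if (inherits(g, "genomic_relationship")) g$matrix else as.matrix(g)
  E <- if (inherits(env_part, "env_kernel")) env_part$matrix
       else if (length(env_part) == 1L && is.numeric(env_part)) {
         q <- as.integer(env_part)
         diag(q)
       } else as.matrix(env_part)
  T_ <- as.matrix(t)
  gid <- rownames(G) %||% paste0("g", seq_len(nrow(G)))
  eid <- rownames(E) %||% env_ids %||% paste0("env", seq_len(nrow(E)))
  tid <- rownames(T_) %||% trait_ids %||% paste0("trait", seq_len(nrow(T_)))
  dimnames(G) <- list(gid, gid); dimnames(E) <- list(eid, eid)
  dimnames(T_) <- list(tid, tid)
  for (f in list(G = G, E = E, T = T_)) check_psd(f)
  cells <- expand.grid(trait = tid, env = eid, genotype = gid,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("genotype", "env", "trait")]
  rownames(cells) <- NULL
  structure(list(factors = list(G = G, E = E, T = T_), cells = cells,
                 kind = kind), class = "composite_kernel")
}

check_psd <- function(mat, tol = 1e-8) {
  if (max(abs(mat - t(mat))) > 1e-10) stopf("factor is not symmetric")
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) stopf("factor is not PSD (min eigenvalue %.3g)", min(ev))
  invisible(TRUE)
}

#' @export
print.composite_kernel <- function(x, ...) {
  d <- vapply(x$factors, nrow, 0L)
  cat(sprintf("composite_kernel (%s): %d x %d x %d = %d cells\n",
              x$kind, d[1], d[2], d[3], prod(d)))
  invisible(x)
}

#' Number of cells of a composite kernel
#' @param k a \code{composite_kernel}.
#' @return integer cell count.
#' @export
n_cells <- function(k) nrow(k$cells)

#' Extract a sub-block of a composite kernel
#'
#' Computes \code{K[rows, cols]} entry-wise from the factors:
#' \code{K[(g,e,t),(g',e',t')] = G[g,g'] E[e,e'] T[t,t']}. With both index
#' arguments missing the full dense Kronecker matrix is returned (only
#' sensible for small panels).
#'
#' @param k a \code{composite_kernel}.
#' @param rows,cols integer flat cell indices (default: all cells).
#' @return dense numeric matrix of the requested block.
#' @export
kernel_block <- function(k, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(n_cells(k))
  cols <- cols %||% seq_len(n_cells(k))
  gi <- match(k$cells$genotype, rownames(k$factors$G))
  ei <- match(k$cells$env, rownames(k$factors$E))
  ti <- match(k$cells$trait, rownames(k$factors$T))
  k$factors$G[gi[rows], gi[cols], drop = FALSE] *
    k$factors$E[ei[rows], ei[cols], drop = FALSE] *
    k$factors$T[ti[rows], ti[cols], drop = FALSE]
}

#' Flat cell index from id triples
#' @param k a \code{composite_kernel}.
#' @param genotype,env,trait id vectors (recycled to common length).
#' @return integer flat indices into \code{k$cells}.
#' @export
cell_index <- function(k, genotype, env, trait) {
  key <- paste(genotype, env, trait, sep = "\r")
  allkey <- paste(k$cells$genotype, k$cells$env, k$cells$trait, sep = "\r")
  idx <- match(key, allkey)
  if (anyNA(idx)) stopf("cell ids outside the panel")
  idx
}

#' Eigenvalue spectrum of a composite kernel
#'
#' Eigenvalues of a Kronecker product are all products of factor
#' eigenvalues; the full matrix is never formed. Sum of the spectrum equals
#' the product of factor traces.
#'
#' @param k a \code{composite_kernel}.
#' @return a \code{kernel_spectrum}: list with \code{values} (descending)
#'   and \code{factor_eigen} (per-factor eigendecompositions).
#' @export
kernel_spectrum <- function(k) {
  fe <- lapply(k$factors, function(f) eigen(f, symmetric = TRUE))
  vals <- 1
  for (f in fe) vals <- as.numeric(outer(vals, f$values))
  structure(list(values = sort(pmax(vals, 0), decreasing = TRUE),
                 factor_eigen = fe), class = "kernel_spectrum")
}
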