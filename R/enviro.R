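#' Summarize daily weather into phenology-window environmental covariates
#'
#' Each weather variable is aggregated inside fixed phenology windows
#' (days after emergence), producing one environmental covariate (EC) per
#' variable x window, named \code{<variable>_<start>_<end>}. Intensive
#' variables (temperatures, humidity, day length) are averaged within the
#' window; accumulative variables (rainfall, radiation totals) are summed.
#'
#' @param weather data.frame with columns \code{env}, \code{day} (integer
#'   days after emergence, unique per environment) and one numeric column
#'   per weather variable.
#' @param windows list of length-2 integer vectors (start, end), inclusive,
#'   non-overlapping, ordered. Default: the five maize phenology windows
#'   0-14, 15-35, 36-60, 61-90, 91-120.
#' @param sum_variables variable names aggregated by sum; all others by mean.
#' @return an \code{enviro_covariates} object: fields \code{W} (q x m
#'   matrix, environments in rows), \code{scaled} (FALSE).
#' @export
summarize_env_covariates <- function(weather,
                                     windows = default_windows(),
                                     sum_variables = c("rainfall", "radiation")) {
  stopifnot(all(c("env", "day") %in% names(weather)))
  vars <- setdiff(names(weather), c("env", "day"))
  if (!length(vars)) stopf("no weather variable columns")
  starts <- vapply(windows, `[`, 0, 1)
  ends <- vapply(windows, `[`, 0, 2)
  if (is.unsorted(starts) || any(starts[-1] <= ends[-length(ends)]))
    stopf("windows must be ordered and non-overlapping")
  envs <- unique(weather$env)
  W <- matrix(NA_real_, length(envs), length(vars) * length(windows),
              dimnames = list(envs, NULL))
  cn <- character(ncol(W))
  k <- 0L
  for (v in vars) for (w in seq_along(windows)) {
    k <- k + 1L
    cn[k] <- sprintf("%s_%d_%d", v, starts[w], ends[w])
    for (e in envs) {
      sel <- weather$env == e & weather$day >= starts[w] & weather$day <= ends[w]
      if (!any(sel))
        stopf("environment %s has no days in window %d-%d", e, starts[w], ends[w])
      x <- weather[[v]][sel]
      W[e, k] <- if (v %in% sum_variables) sum(x) else mean(x)
    }
  }
  colnames(W) <- cn
  structure(list(W = W, scaled = FALSE), class = "enviro_covariates")
}

#' Default maize phenology windows (days after emergence)
#' @return list of five (start, end) windows.
#' @export
default_windows <- function() {
  list(c(0L, 14L), c(15L, 35L), c(36L, 60L), c(61L, 90L), c(91L, 120L))
}

#' Center and scale an EC matrix
#'
#' Columns are centered and scaled to unit sample variance; constant columns
#' are dropped (logged in attribute \code{dropped}). Idempotent.
#'
#' @param w an \code{enviro_covariates} object or bare q x m matrix.
#' @return scaled \code{enviro_covariates}.
#' @export
scale_ec_matrix <- function(w) {
  W <- if (inherits(w, "enviro_covariates")) w$W else as.matrix(w)
  if (nrow(W) < 2) stopf("need at least 2 environments to scale")
  sds <- apply(W, 2, stats::sd)
  dropped <- colnames(W)[sds == 0]
  if (length(dropped) == ncol(W)) stopf("all EC columns are constant")
  W <- W[, sds > 0, drop = FALSE]
  W <- scale(W)
  attr(W, "scaled:center") <- NULL
  attr(W, "scaled:scale") <- NULL
  structure(list(W = W, scaled = TRUE, dropped = dropped),
            class = "enviro_covariates")
}

#' Enviromic similarity kernel between environments
#'
#' Linear environmental kernel \eqn{K_E = W W' / (tr(W W') / q)} where W is
#' the (scaled) environment x EC matrix and q the number of environments.
#' The normalization forces \eqn{tr(K_E) = q}, making kernels comparable
#' across EC sets; the kernel is invariant to rescaling W by a scalar.
#'
#' @param w an \code{enviro_covariates} object (warns when unscaled) or
#'   bare matrix.
#' @return an \code{env_kernel} object: fields \code{environment_ids},
#'   \code{matrix} (q x q, symmetric, PSD, trace q).
#' @export
env_kernel <- function(w) {
  if (inherits(w, "enviro_covariates")) {
    if (!isTRUE(w$scaled)) warnf("EC matrix is not scaled; K_E will be dominated by high-variance covariates")
    W <- w$W
  } else W <- as.matrix(w)
  q <- nrow(W)
  if (q < 2) stopf("need at least 2 environments")
  G <- tcrossprod(W)
  K <- G / (sum(diag(G)) / q)
  K <- (K + t(K)) / 2
  ids <- rownames(W) %||% paste0("env", seq_len(q))
  dimnames(K) <- list(ids, ids)
  structure(list(environment_ids = ids, matrix = K), class = "env_kernel")
}

#' @export
print.env_kernel <- function(x, ...) {
  cat(sprintf("env_kernel: %d environments, trace %.4f\n",
              nrow(x$matrix), sum(diag(x$matrix))))
  invisible(x)
}

#' Write / read an EC matrix as CSV (environments in rows)
#' @param w an \code{enviro_covariates} object.
#' @param path output file.
#' @export
write_ec_matrix <- function(w, path) {
  utils::write.csv(data.frame(env = rownames(w$W), w$W, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ec_matrix
#' @param scaled flag recorded on the object read back.
#' @export
read_ec_matrix <- function(path, scaled = FALSE) {
  tab <- utils::read.csv(path, check.names = FALSE)
  W <- as.matrix(tab[, -1, drop = FALSE])
  rownames(W) <- as.character(tab$env)
  structure(list(W = W, scaled = scaled), class = "enviro_covariates")
}
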