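#' Construct a marker dosage matrix
#'
#' Container for SNP dosages of a hybrid panel: parental inbred lines,
#' in-silico hybrids, and check genotypes. Dosages count copies of one
#' allele (0, 1, 2); \code{NA} marks missing calls.
#'
#' @param dosage numeric matrix, individuals in rows, markers in columns,
#'   entries in \{0, 1, 2, NA\}.
#' @param role character vector, one of "parent", "hybrid", "check" per
#'   individual. Defaults to "parent" for all.
#' @param individual_ids,marker_ids optional id vectors; taken from dimnames
#'   when absent.
#' @return an object of class \code{marker_matrix}.
#' @export
marker_matrix <- function(dosage, role = NULL, individual_ids = NULL,
                          marker_ids = NULL) {
  dosage <- as.matrix(dosage)
  individual_ids <- individual_ids %||% rownames(dosage) %||%
    paste0("ind", seq_len(nrow(dosage)))
  marker_ids <- marker_ids %||% colnames(dosage) %||%
    paste0("m", seq_len(ncol(dosage)))
  if (anyDuplicated(individual_ids)) stopf("duplicated individual ids")
  if (anyDuplicated(marker_ids)) stopf("duplicated marker ids")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stopf("dosages must be 0, 1, 2 or NA (%d offending cells)",
                      sum(bad))
  role <- role %||% rep("parent", nrow(dosage))
  if (length(role) == 1L) role <- rep(role, nrow(dosage))
  if (!all(role %in% c("parent", "hybrid", "check")))
    stopf("role must be parent, hybrid or check")
  stopifnot(length(role) == nrow(dosage))
  dimnames(dosage) <- list(individual_ids, marker_ids)
  structure(list(dosage = dosage, role = role), class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d markers (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(sprintf("%d %s", table(x$role), names(table(x$role))),
                    collapse = ", ")))
  invisible(x)
}

#' Per-marker allele statistics
#'
#' Allele frequency of the counted allele, call rate and minor allele
#' frequency, computed over a subset of individuals (by convention the
#' hybrid panel, whose frequencies parameterize the relationship matrices).
#'
#' @param m a \code{marker_matrix}.
#' @param subset individual ids to compute over; default all.
#' @return data.frame with columns marker_id, p, call_rate, maf. Markers
#'   with no calls get call_rate 0 and \code{NA} frequency.
#' @export
allele_stats <- function(m, subset = NULL) {
  ids <- subset %||% rownames(m$dosage)
  if (!length(ids)) stopf("empty subset")
  miss <- setdiff(ids, rownames(m$dosage))
  if (length(miss)) stopf("unknown individuals: %s", paste(miss, collapse = ", "))
  d <- m$dosage[ids, , drop = FALSE]
  nn <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  p[nn == 0] <- NA_real_
  data.frame(marker_id = colnames(d), p = unname(p),
             call_rate = unname(nn / nrow(d)),
             maf = unname(pmin(p, 1 - p)),
             stringsAsFactors = FALSE)
}

#' Marker quality control
#'
#' Filters markers in a fixed order -- call rate, parental heterozygosity,
#' monomorphism, minor allele frequency -- and attaches a log of counts
#' removed per rule. A marker survives the call-rate rule only when its call
#' rate is strictly greater than \code{max_missing_call_rate}; it survives
#' the MAF rule only when MAF is strictly greater than \code{min_maf}
#' (markers at or below the thresholds are removed).
#'
#' @param m a \code{marker_matrix}.
#' @param call_rate_min markers with call rate <= this are removed
#'   (default 0.95).
#' @param min_maf markers with MAF <= this are removed (default 0.05).
#' @param drop_het_parents drop markers heterozygous in any parent
#'   (default TRUE).
#' @param stats_subset individual ids over which frequencies are computed
#'   (default: hybrids when present, else all individuals).
#' @return filtered \code{marker_matrix} with attribute \code{qc_log}, a
#'   data.frame of (rule, removed, remaining).
#' @export
qc_markers <- function(m, call_rate_min = 0.95, min_maf = 0.05,
                       drop_het_parents = TRUE, stats_subset = NULL) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1, min_maf >= 0, min_maf <= 1)
  if (!ncol(m$dosage)) stopf("empty marker matrix")
  if (is.null(stats_subset)) {
    hyb <- rownames(m$dosage)[m$role == "hybrid"]
    stats_subset <- if (length(hyb)) hyb else rownames(m$dosage)
  }
  log <- list()
  keepm <- function(m, keep, rule) {
    log[[length(log) + 1L]] <<- data.frame(rule = rule, removed = sum(!keep),
                                           remaining = sum(keep))
    m$dosage <- m$dosage[, keep, drop = FALSE]
    m
  }
  st <- allele_stats(m, stats_subset)
  m <- keepm(m, st$call_rate > call_rate_min, "call_rate")

  if (drop_het_parents) {
    par <- m$dosage[m$role == "parent", , drop = FALSE]
    het <- if (nrow(par)) colSums(par == 1, na.rm = TRUE) > 0 else
      rep(FALSE, ncol(m$dosage))
    m <- keepm(m, !het, "parent_heterozygosity")
  }
  st <- allele_stats(m, stats_subset)
  mono <- is.na(st$maf) | st$maf == 0
  m <- keepm(m, !mono, "monomorphic")
  st <- allele_stats(m, stats_subset)
  m <- keepm(m, st$maf > min_maf, "maf")

  if (!ncol(m$dosage)) stopf("empty after QC: every marker was removed")
  attr(m, "qc_log") <- do.call(rbind, log)
  m
}

#' Synthesize single-cross hybrid genotypes in silico
#'
#' F1 hybrids of fully inbred parents are genetically determined: the hybrid
#' dosage at each marker is the mean of the two parental dosages
#' (0x0 -> 0, 0x2 -> 1, 2x2 -> 2). Missing in either parent propagates.
#'
#' @param parents a \code{marker_matrix} of homozygous parents.
#' @param cross_plan data.frame with columns mother, father, hybrid.
#' @return \code{marker_matrix} of the hybrids (role "hybrid").
#' @export
synthesize_hybrids <- function(parents, cross_plan) {
  stopifnot(all(c("mother", "father", "hybrid") %in% names(cross_plan)))
  d <- parents$dosage
  miss <- setdiff(unique(c(cross_plan$mother, cross_plan$father)), rownames(d))
  if (length(miss)) stopf("parents absent from marker matrix: %s",
                          paste(miss, collapse = ", "))
  het <- which(d == 1, arr.ind = TRUE)
  if (nrow(het)) stopf("heterozygous parent dosage: parent %s at marker %s",
                       rownames(d)[het[1, 1]], colnames(d)[het[1, 2]])
  hyb <- (d[cross_plan$mother, , drop = FALSE] +
          d[cross_plan$father, , drop = FALSE]) / 2
  rownames(hyb) <- cross_plan$hybrid
  marker_matrix(hyb, role = rep("hybrid", nrow(hyb)))
}

# Shared machinery for both relationship matrices: code the dosage matrix,
# impute missing cells to the observed per-marker mean code (for the
# additive coding this equals the 2p rule because p comes from the same
# subset), and normalize the Gram matrix.
grm_from_codes <- function(codes, denom, ids, kind) {
  if (denom <= 0) stopf("zero denominator: all markers monomorphic")
  mu <- colMeans(codes, na.rm = TRUE)
  idx <- which(is.na(codes))
  if (length(idx)) codes[idx] <- mu[((idx - 1L) %/% nrow(codes)) + 1L]
  G <- tcrossprod(codes) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(ids, ids)
  structure(list(individual_ids = ids, matrix = G, effect_kind = kind),
            class = "genomic_relationship")
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat(sprintf("%s genomic relationship: %d individuals, mean diag %.3f\n",
              x$effect_kind, nrow(x$matrix), mean(diag(x$matrix))))
  invisible(x)
}

#' Additive genomic relationship matrix
#'
#' VanRaden's first method: columns centered at twice the allele frequency,
#' Gram matrix scaled by \eqn{2 \sum_i p_i (1 - p_i)}. Frequencies come from
#' \code{stats} (conventionally computed on the hybrid panel). Missing
#' dosages are imputed at their marker mean. With \code{center = FALSE} the
#' raw 0/1/2 codes enter the cross-product instead; the centered form is the
#' default because only it has the mean-diagonal-near-one property that
#' makes relationship coefficients interpretable.
#'
#' @param m a \code{marker_matrix} (QC'd, no monomorphic markers).
#' @param stats output of \code{\link{allele_stats}} aligned to \code{m}'s
#'   markers; computed on all individuals of \code{m} when omitted.
#' @param center center dosages at 2p (default TRUE).
#' @return a \code{genomic_relationship} (additive).
#' @export
additive_grm <- function(m, stats = NULL, center = TRUE) {
  stats <- stats %||% allele_stats(m)
  stopifnot(identical(stats$marker_id, colnames(m$dosage)))
  p <- stats$p
  if (anyNA(p)) stopf("markers with undefined allele frequency; run QC first")
  codes <- if (center) sweep(m$dosage, 2, 2 * p, "-") else m$dosage
  grm_from_codes(codes, 2 * sum(p * (1 - p)), rownames(m$dosage), "additive")
}

#' Dominance genomic relationship matrix
#'
#' Vitezica's natural-and-orthogonal parameterization: genotype classes
#' 0/1/2 coded \eqn{-2q^2}, \eqn{2pq}, \eqn{-2p^2} (q = 1 - p), Gram matrix
#' scaled by \eqn{4 \sum_i (p_i q_i)^2}.
#'
#' @inheritParams additive_grm
#' @return a \code{genomic_relationship} (dominance).
#' @export
dominance_grm <- function(m, stats = NULL) {
  stats <- stats %||% allele_stats(m)
  stopifnot(identical(stats$marker_id, colnames(m$dosage)))
  p <- stats$p
  if (anyNA(p)) stopf("markers with undefined allele frequency; run QC first")
  q <- 1 - p
  d <- m$dosage
  codes <- matrix(NA_real_, nrow(d), ncol(d), dimnames = dimnames(d))
  for (v in 0:2) {
    idx <- which(d == v)
    cols <- ((idx - 1L) %/% nrow(d)) + 1L
    codes[idx] <- switch(as.character(v),
                         "0" = -2 * q[cols]^2,
                         "1" =  2 * p[cols] * q[cols],
                         "2" = -2 * p[cols]^2)
  }
  grm_from_codes(codes, 4 * sum((p * q)^2), rownames(m$dosage), "dominance")
}

#' Read a marker matrix from tabular text or VCF
#'
#' Tabular format: rows = individuals (first column id), remaining columns
#' markers, cells 0/1/2/NA. VCF: unphased or phased diploid GT fields are
#' converted to alternate-allele dosage.
#'
#' @param path file path (".vcf" suffix switches to VCF parsing).
#' @param role per-individual role vector or single value.
#' @return a \code{marker_matrix}.
#' @export
read_markers <- function(path, role = "parent") {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "##")]
    hdr <- strsplit(sub("^#", "", ln[1]), "\t")[[1]]
    body <- strsplit(ln[-1], "\t")
    ids <- hdr[-(1:9)]
    gt2dose <- function(g) {
      g <- sub(":.*", "", g)
      ifelse(g %in% c("./.", ".|.", "."), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 0))
    }
    dos <- vapply(body, function(f) gt2dose(f[-(1:9)]), numeric(length(ids)))
    dos <- matrix(dos, nrow = length(ids),
                  dimnames = list(ids, vapply(body, function(f)
                    if (f[3] == ".") paste0(f[1], "_", f[2]) else f[3], "")))
    marker_matrix(dos, role = role)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    dos <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dos) <- as.character(tab[[1]])
    marker_matrix(dos, role = role)
  }
}
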