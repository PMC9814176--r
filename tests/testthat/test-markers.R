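test_that("qc filters by call rate, parental heterozygosity, monomorphism and MAF in order", {
  set.seed(11)
  n <- 40
  dos <- matrix(sample(c(0, 2), n * 10, TRUE), n, 10,
                dimnames = list(paste0("h", 1:n), paste0("m", 1:10)))
  # two rare markers (MAF ~0.01): one carrier copy only
  dos[, 1] <- 0; dos[1, 1] <- 2
  dos[, 2] <- 2; dos[2, 2] <- 0
  dos[, 3] <- 0                      # monomorphic
  m <- marker_matrix(dos, role = "hybrid")
  out <- qc_markers(m, call_rate_min = 0, min_maf = 0.05)
  expect_equal(ncol(out$dosage), 7)
  log <- attr(out, "qc_log")
  expect_equal(log$rule, c("call_rate", "parent_heterozygosity",
                           "monomorphic", "maf"))
  expect_equal(log$removed, c(0, 0, 1, 2))

  # no-op case: complete data, min_maf 0 keeps everything but monomorphic
  keep <- qc_markers(m, call_rate_min = 0, min_maf = 0)
  expect_equal(colnames(keep$dosage), setdiff(colnames(dos), "m3"))

  # idempotence
  twice <- qc_markers(out, call_rate_min = 0, min_maf = 0.05)
  expect_identical(out$dosage, twice$dosage)

  # heterozygous parent removal
  par <- marker_matrix(rbind(P1 = c(0, 1), P2 = c(2, 2)),
                       marker_ids = c("mA", "mB"))
  mixed <- marker_matrix(rbind(par$dosage, dos[, 1:2]),
                         role = c("parent", "parent", rep("hybrid", n)),
                         marker_ids = c("mA", "mB"))
  flt <- qc_markers(mixed, call_rate_min = 0, min_maf = 0,
                    drop_het_parents = TRUE)
  expect_false("mB" %in% colnames(flt$dosage))

  # everything removed -> explicit error
  expect_error(qc_markers(marker_matrix(matrix(2, 4, 2), role = "hybrid"),
                          call_rate_min = 0, min_maf = 0),
               "empty after QC")
})

test_that("call-rate and MAF thresholds are strict (at threshold = removed)", {
  dos <- matrix(c(0, 2, 2, 2, 2, NA,
                  0, 2, 2, 2, 2, 2), 6, 2,
                dimnames = list(paste0("h", 1:6), c("mCR", "mOK")))
  m <- marker_matrix(dos, role = "hybrid")
  # mCR call rate 5/6; threshold exactly 5/6 removes it
  out <- qc_markers(m, call_rate_min = 5 / 6, min_maf = 0)
  expect_equal(colnames(out$dosage), "mOK")
  # MAF exactly at min_maf is removed: p = 5/6 on mOK so MAF = 1/6
  out2 <- qc_markers(m, call_rate_min = 0, min_maf = 1 / 6)
  expect_equal(colnames(out2$dosage), "mCR")
})

test_that("hybrid synthesis follows the Mendelian cross of inbreds", {
  par <- marker_matrix(rbind(P1 = c(0, 2, 0, NA), P2 = c(2, 2, 0, 2)),
                       marker_ids = paste0("m", 1:4))
  hy <- synthesize_hybrids(par, data.frame(mother = "P1", father = "P2",
                                           hybrid = "H1"))
  expect_equal(unname(hy$dosage["H1", ]), c(1, 2, 0, NA))
  expect_equal(hy$role, "hybrid")

  het <- marker_matrix(rbind(P1 = c(1, 2), P2 = c(2, 2)))
  expect_error(synthesize_hybrids(het, data.frame(mother = "P1",
                                                  father = "P2",
                                                  hybrid = "H1")),
               "P1.*m1")
})

test_that("allele statistics match direct arithmetic", {
  dos <- rbind(a = c(0, 2, 0), b = c(1, 2, 0), c = c(2, 2, 2),
               d = c(NA, 2, NA))
  colnames(dos) <- c("m1", "m2", "m3")
  st <- allele_stats(marker_matrix(dos, role = "hybrid"))
  expect_equal(st$p[1], 0.5)             # dosages 0,1,2
  expect_equal(st$p[2], 1)               # all 2
  expect_equal(st$maf[2], 0)
  expect_equal(st$call_rate[3], 0.75)    # 0,0,2,NA
  expect_equal(st$p[3], 1 / 3)

  # all-missing marker: call rate 0, p undefined
  dos2 <- cbind(dos, mX = c(NA, NA, NA, NA))
  st2 <- allele_stats(marker_matrix(dos2, role = "hybrid"))
  expect_equal(st2$call_rate[4], 0)
  expect_true(is.na(st2$p[4]))
})

test_that("additive GRM matches the hand example and the double-loop oracle", {
  m1 <- marker_matrix(rbind(a = 2, b = 0), marker_ids = "m1")
  st1 <- data.frame(marker_id = "m1", p = 0.5, call_rate = 1, maf = 0.5)
  G <- additive_grm(m1, st1)$matrix
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  set.seed(21)
  dos <- matrix(sample(0:2, 8 * 30, TRUE, prob = c(.3, .4, .3)), 8, 30,
                dimnames = list(paste0("h", 1:8), paste0("m", 1:30)))
  dos[sample(length(dos), 15)] <- NA
  keep <- colSums(dos, na.rm = TRUE) > 0 &
    colSums(2 - dos, na.rm = TRUE) > 0 & colSums(!is.na(dos)) > 0
  dos <- dos[, keep]
  m <- marker_matrix(dos, role = "hybrid")
  st <- allele_stats(m)
  expect_equal(unname(additive_grm(m, st)$matrix),
               additive_grm_oracle(dos, st$p), tolerance = 1e-10)

  # duplicate individuals: identical rows, off-diagonal equals diagonal
  dup <- marker_matrix(rbind(a = dos[1, ], b = dos[1, ]), role = "hybrid")
  std <- allele_stats(dup)
  ok <- !is.na(std$p) & std$p > 0 & std$p < 1
  dup <- marker_matrix(dup$dosage[, ok, drop = FALSE], role = "hybrid")
  Gd <- additive_grm(dup, allele_stats(dup))$matrix
  expect_equal(Gd[1, 1], Gd[1, 2], tolerance = 1e-12)

  # PSD (Gram property)
  ev <- eigen(additive_grm(m, st)$matrix, symmetric = TRUE)$values
  expect_gt(min(ev), -1e-8)

  # uncentered variant equals the raw-code Gram matrix
  Gr <- additive_grm(m, st, center = FALSE)$matrix
  d2 <- dos
  for (j in seq_len(ncol(d2))) d2[is.na(d2[, j]), j] <- mean(d2[, j], na.rm = TRUE)
  expect_equal(unname(Gr),
               unname(tcrossprod(d2) / (2 * sum(st$p * (1 - st$p)))),
               tolerance = 1e-10)
})

test_that("mean GRM diagonal is near 1 on Hardy-Weinberg data", {
  set.seed(31)
  nm <- 5000; n <- 150
  p <- runif(nm, 0.1, 0.9)
  dos <- matrix(rbinom(n * nm, 2, rep(p, each = n)), n, nm,
                dimnames = list(paste0("i", 1:n), paste0("m", 1:nm)))
  m <- marker_matrix(dos, role = "hybrid")
  G <- additive_grm(m, allele_stats(m))$matrix
  expect_lt(abs(mean(diag(G)) - 1), 0.1)
})

test_that("dominance GRM matches the hand example and is PSD", {
  m1 <- marker_matrix(rbind(a = 1, b = 0), marker_ids = "m1", role = "hybrid")
  st1 <- data.frame(marker_id = "m1", p = 0.5, call_rate = 1, maf = 0.5)
  # codes 2pq = 0.5 (het) and -2q^2 = -0.5 (hom); denominator 4 (pq)^2 = 0.25
  G <- dominance_grm(m1, st1)$matrix
  expect_equal(unname(G), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)

  # population with no heterozygotes at p = 0.5: all codes -0.5
  m2 <- marker_matrix(rbind(a = 0, b = 2), marker_ids = "m1", role = "hybrid")
  G2 <- dominance_grm(m2, st1)$matrix
  expect_equal(G2[1, 1], G2[1, 2], tolerance = 1e-12)

  set.seed(41)
  dos <- matrix(sample(0:2, 10 * 40, TRUE), 10, 40,
                dimnames = list(paste0("h", 1:10), paste0("m", 1:40)))
  m <- marker_matrix(dos, role = "hybrid")
  st <- allele_stats(m)
  ok <- st$maf > 0
  m <- marker_matrix(dos[, ok], role = "hybrid")
  ev <- eigen(dominance_grm(m, allele_stats(m))$matrix,
              symmetric = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("marker IO round-trips tabular and VCF formats", {
  dir <- withr::local_tempdir()
  dos <- matrix(c(0, 2, 1, NA, 2, 0), 2, 3,
                dimnames = list(c("A", "B"), c("m1", "m2", "m3")))
  tab <- file.path(dir, "mk.csv")
  write.csv(data.frame(id = rownames(dos), dos, check.names = FALSE), tab,
            row.names = FALSE)
  m <- read_markers(tab, role = "hybrid")
  expect_equal(m$dosage, dos)

  vcf <- file.path(dir, "mk.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
               "1\t100\ts1\tA\tG\t.\t.\t.\tGT\t0/0\t1/1",
               "1\t200\ts2\tA\tG\t.\t.\t.\tGT\t0|1\t./."), vcf)
  mv <- read_markers(vcf)
  expect_equal(unname(mv$dosage["A", ]), c(0, 1))
  expect_equal(unname(mv$dosage["B", ]), c(2, NA))
})
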