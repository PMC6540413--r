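test_that("background flooring uses mean(neg) + 2 sd(neg) per sample", {
  counts <- matrix(c(11, 20, 0, 2, 4, 6, 8, 10), ncol = 1,
                   dimnames = list(c("G1", "G2", "G3", paste0("NEG_", 1:5)),
                                   "S1"))
  x <- rcc_set(counts, c(rep("Endogenous", 3), rep("Negative", 5)))
  fl <- background_floor(x)
  m <- 6
  thr <- m + 2 * sd(c(2, 4, 6, 8, 10)) # 12.32...
  expect_lt(11, thr)
  expect_gt(20, thr)
  expect_equal(unname(fl$counts["G1", 1]), 6)   # below threshold -> mean
  expect_equal(unname(fl$counts["G2", 1]), 20)  # detected, untouched
  expect_equal(unname(fl$counts["G3", 1]), 6)   # zero floors to mean
  expect_equal(fl$counts[paste0("NEG_", 1:5), 1],
               x$counts[paste0("NEG_", 1:5), 1]) # controls untouched
  expect_true("background_floored" %in% fl$provenance)
  expect_error(background_floor(rcc_set(counts[1:4, , drop = FALSE],
                                        c(rep("Endogenous", 3), "Negative"))),
               ">= 2 Negative")
})

test_that("background flooring is monotone in each count", {
  x <- tiny_rcc_set(n = 4, seed = 1)
  fl1 <- background_floor(x)
  for (i in 1:20) {
    y <- x
    probe <- sample(which(y$probes$CodeClass == "Endogenous"), 1)
    j <- sample(ncol(y$counts), 1)
    y$counts[probe, j] <- y$counts[probe, j] + sample(1:50, 1)
    fl2 <- background_floor(y)
    expect_gte(fl2$counts[probe, j], fl1$counts[probe, j])
  }
})

test_that("positive-control factors rescale to the cohort mean geomean", {
  counts <- rbind(G1 = c(10, 10), POS_A = c(50, 200), POS_B = c(200, 800),
                  NEG_A = c(1, 1), NEG_B = c(2, 2))
  x <- rcc_set(counts, c("Endogenous", "Positive", "Positive",
                         "Negative", "Negative"))
  pn <- positive_control_normalize(x)
  # geomeans 100 and 400; cohort mean 250 -> factors 2.5 and 0.625
  expect_equal(unname(pn$norm_factors), c(2.5, 0.625))
  expect_equal(unname(pn$counts["G1", ]), c(25, 6.25))
  # post-scaling positive geomeans equal across samples
  geo <- exp(colMeans(log(pn$counts[c("POS_A", "POS_B"), ])))
  expect_equal(unname(geo), rep(250, 2))
  # negatives untouched
  expect_equal(pn$counts["NEG_A", ], x$counts["NEG_A", ])

  # identical positives -> identity; single sample -> factor 1
  same <- rcc_set(rbind(G1 = c(7, 9), POS_A = c(100, 100)),
                  c("Endogenous", "Positive"))
  expect_equal(positive_control_normalize(same)$counts, same$counts)
  single <- rcc_set(rbind(G1 = 7, POS_A = 123), c("Endogenous", "Positive"))
  expect_equal(unname(positive_control_normalize(single)$norm_factors), 1)

  zero <- rcc_set(rbind(G1 = c(7, 9), POS_A = c(0, 100)),
                  c("Endogenous", "Positive"))
  expect_error(positive_control_normalize(zero), "geometric mean")
  expect_silent(positive_control_normalize(zero, pseudo_count = 0.5))
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 3), b = c(2, 6))
  expect_equal(unname(quantile_normalize(m)),
               matrix(c(1.5, 4.5, 1.5, 4.5), ncol = 2))
  ident <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  expect_equal(quantile_normalize(ident), ident)

  set.seed(4)
  r <- matrix(rnorm(60), ncol = 5)
  qn <- quantile_normalize(r)
  sorted <- apply(qn, 2, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1])
  # idempotent up to the tie rule
  expect_equal(quantile_normalize(qn), qn)
})

test_that("quantile normalization matches the brute-force oracle on small matrices", {
  set.seed(11)
  for (i in 1:25) {
    nr <- sample(2:5, 1)
    nc <- sample(2:5, 1)
    m <- matrix(sample(0:4, nr * nc, replace = TRUE) + 0, nrow = nr)
    expect_equal(quantile_normalize(m), qn_oracle(m))
    m2 <- matrix(rnorm(nr * nc), nrow = nr)
    expect_equal(quantile_normalize(m2), qn_oracle(m2))
  }
})

test_that("log2 + quantile normalization keeps only biological probes", {
  x <- tiny_rcc_set(n = 4)
  norm <- log2_quantile_normalize(positive_control_normalize(
    background_floor(x)))
  expect_setequal(rownames(norm),
                  x$probes$Name[x$probes$CodeClass %in%
                                  c("Endogenous", "Housekeeping")])
  # equals the brute-force sort/average oracle (ties included)
  pn <- positive_control_normalize(background_floor(x))
  bio <- pn$counts[pn$probes$CodeClass %in% c("Endogenous", "Housekeeping"), ]
  expect_equal(unname(norm), unname(qn_oracle(log2(bio))), tolerance = 1e-12,
               ignore_attr = TRUE)
  cs <- colSums(norm)
  expect_equal(unname(cs), rep(cs[[1]], 4), tolerance = 1e-9)
  expect_true(all(c("log2", "quantile_normalized") %in%
                    attr(norm, "provenance")))

  zero <- rcc_set(rbind(G1 = c(0, 2), NEG_A = c(1, 1), NEG_B = c(1, 1),
                        POS_A = c(9, 9)),
                  c("Endogenous", "Negative", "Negative", "Positive"))
  expect_error(log2_quantile_normalize(zero), "log2")
  expect_silent(log2_quantile_normalize(zero, offset = 1))
})

test_that("FPKM follows the closed form and its invariances", {
  counts <- matrix(c(10, 999990), ncol = 1, dimnames = list(c("A", "B"), "s"))
  lengths <- c(A = 1000, B = 500)
  f <- counts_to_fpkm(counts, lengths)
  expect_equal(unname(f["A", 1]), 10)      # 10 * 1e9 / (1000 * 1e6)
  expect_equal(attr(f, "unit"), "FPKM")
  expect_equal(unname(counts_to_fpkm(counts * 2, lengths)), unname(f))
  zero <- counts
  zero["A", 1] <- 0
  expect_equal(unname(counts_to_fpkm(zero, lengths)["A", 1]), 0)
  expect_error(counts_to_fpkm(counts, c(A = 1000)), "B")
})

test_that("TPM renormalizes FPKM columns to one million", {
  f <- matrix(c(1, 3), ncol = 1, dimnames = list(c("A", "B"), "s"))
  attr(f, "unit") <- "FPKM"
  tpm <- fpkm_to_tpm(f)
  expect_equal(unname(tpm[, 1]), c(2.5e5, 7.5e5))
  one <- matrix(42, dimnames = list("A", "s"))
  attr(one, "unit") <- "FPKM"
  expect_equal(unname(fpkm_to_tpm(one)[1, 1]), 1e6)
  set.seed(2)
  r <- matrix(rexp(40), ncol = 4, dimnames = list(paste0("g", 1:10), NULL))
  expect_equal(unname(colSums(fpkm_to_tpm(r))), rep(1e6, 4))
  bad <- matrix(c(0, 0, 1, 2), ncol = 2, dimnames = list(c("A", "B"), NULL))
  expect_error(fpkm_to_tpm(bad), "all-zero")
  attr(f, "unit") <- "TPM"
  expect_error(fpkm_to_tpm(f), "unit")
})

test_that("log2 FPKM applies and records the offset", {
  f <- matrix(c(0, 3, 15), ncol = 1, dimnames = list(c("A", "B", "C"), "s"))
  lf <- log2_fpkm(f, offset = 1)
  expect_equal(unname(lf[, 1]), c(0, 2, 4))
  expect_equal(attr(lf, "log2_offset"), 1)
  expect_equal(attr(lf, "unit"), "log2FPKM")
  expect_error(log2_fpkm(f, offset = 0), "zero")
})

test_that("RCC files, count TSVs and matrix TSVs round-trip", {
  cfg <- simulation_config(n_samples = 3, n_endogenous = 60,
                           genes_per_cell_type = 2, n_category_specific = 0,
                           seed = 13)
  co <- simulate_cohort(cfg)

  dir <- withr::local_tempdir()
  write_rcc_files(co, dir)
  back <- read_rcc_files(dir)
  expect_equal(back$counts, co$raw$counts)
  expect_equal(back$probes$CodeClass, co$raw$probes$CodeClass)

  tsv <- file.path(dir, "counts.tsv")
  write_counts_tsv(co, tsv)
  back2 <- read_counts_tsv(tsv)
  expect_equal(back2$counts, co$raw$counts)

  gmt <- file.path(dir, "sigs.gmt")
  write_gmt(co$signatures, gmt)
  reg <- read_gmt(gmt)
  expect_equal(names(reg), names(co$signatures))
  expect_equal(lapply(reg, `[[`, "genes"),
               lapply(co$signatures, `[[`, "genes"))
  expect_equal(signature_kinds(reg), signature_kinds(co$signatures))

  csv <- file.path(dir, "ann.csv")
  write_annotation_csv(co$annotation, csv)
  ann <- read_annotation_csv(csv)
  expect_equal(ann$sample_id, co$annotation$sample_id)
  expect_equal(unclass(ann$foci), unclass(co$annotation$foci),
               ignore_attr = TRUE)

  m <- matrix(rnorm(6), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  attr(m, "provenance") <- c("log2", "quantile_normalized")
  mp <- file.path(dir, "mat.tsv")
  write_matrix_tsv(m, mp)
  m2 <- read_matrix_tsv(mp)
  expect_equal(unname(m2), unname(m), tolerance = 1e-12)
  expect_equal(attr(m2, "provenance"), attr(m, "provenance"))
})
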