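test_that("Wilcoxon rank-sum handles exact and approximate paths", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4), "less")
  expect_true(r$exact)
  expect_equal(r$W, 3) # ranks 1 + 2
  expect_equal(r$p, 1 / 6, tolerance = 1e-12)

  # identical multisets force the tie-corrected approximation: p = 1
  r2 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), "two_sided")
  expect_false(r2$exact)
  expect_equal(r2$p, 1)

  # swapping groups mirrors W about its null mean, two-sided p unchanged
  set.seed(8)
  x <- rnorm(6)
  y <- rnorm(9) + 0.5
  a <- wilcoxon_rank_sum(x, y, "two_sided")
  b <- wilcoxon_rank_sum(y, x, "two_sided")
  n <- length(x); m <- length(y)
  expect_equal(a$W - n * (n + m + 1) / 2, -(b$W - m * (n + m + 1) / 2))
  expect_equal(a$p, b$p)
  expect_equal(wilcoxon_rank_sum(x, y, "less")$p,
               wilcoxon_rank_sum(y, x, "greater")$p)

  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact Wilcoxon matches full enumeration for all tie-free sizes", {
  set.seed(19)
  for (n in 1:4) {
    for (m in 1:(8 - n)) {
      for (rep in 1:3) {
        x <- sample(seq_len(50), n)
        y <- setdiff(seq_len(50), x)[seq_len(m)]
        for (alt in c("two_sided", "less", "greater")) {
          got <- wilcoxon_rank_sum(x, y, alt)
          expect_true(got$exact)
          expect_equal(got$p, wilcox_enum_p(x, y, alt), tolerance = 1e-12,
                       label = sprintf("n=%d m=%d alt=%s", n, m, alt))
        }
      }
    }
  }
})

test_that("mean Z differences are signed recurrent minus non-recurrent", {
  z <- cbind(A = c(1, -1, 2, -2), B = c(0.5, 0.5, -0.5, -0.5))
  rec <- c(TRUE, TRUE, FALSE, FALSE)
  d <- mean_z_difference(z, rec)
  expect_equal(unname(d["A"]), 0)
  expect_equal(unname(d["B"]), 1)
  expect_equal(mean_z_difference(z, !rec), -d)
  expect_error(mean_z_difference(z, rep(TRUE, 4)), "non-empty")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("DEG filter applies strict fold-change and FDR thresholds", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    fold_change = c(1.5, 2.0, 0.5, 3.0),
                    q = c(0.1, 0.29, 0.2, 0.31))
  kept <- deg_filter(rec)
  expect_setequal(kept$gene, c("b", "c")) # 1.5 exact fails strict >, q .31 fails
  expect_true(all(kept$reported))
})

test_that("moderated t reduces to the pooled t when the prior df is zero", {
  set.seed(23)
  mat <- matrix(rnorm(50 * 10), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
  rec <- rep(c(TRUE, FALSE), each = 5)
  mt <- moderated_t(mat, rec, d0 = 0)
  ref <- t(apply(mat, 1, function(v) {
    ht <- t.test(v[rec], v[!rec], var.equal = TRUE)
    c(t = unname(ht$statistic), p = ht$p.value)
  }))
  expect_equal(mt$t, unname(ref[, "t"]), tolerance = 1e-10)
  expect_equal(mt$p, unname(ref[, "p"]), tolerance = 1e-10)
  expect_equal(mt$df, rep(8, 50))
})

test_that("infinite prior df shares one variance across genes", {
  set.seed(24)
  mat <- matrix(rnorm(20 * 8, sd = rep(c(1, 3), each = 10 * 8)), nrow = 20)
  rownames(mat) <- sprintf("g%02d", 1:20)
  rec <- rep(c(TRUE, FALSE), each = 4)
  mt <- moderated_t(mat, rec, d0 = Inf, s0_2 = 2)
  expect_equal(mt$s2_post, rep(2, 20))
  expect_equal(mt$t, mt$log2fc / sqrt(2 * (1 / 4 + 1 / 4)))
})

test_that("moderated log2FC equals the difference of group means", {
  set.seed(25)
  mat <- matrix(rnorm(30 * 12), nrow = 30,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
  rec <- rep(c(TRUE, FALSE), 6)
  mt <- moderated_t(mat, rec)
  expect_equal(mt$log2fc,
               unname(rowMeans(mat[, rec]) - rowMeans(mat[, !rec])))
  expect_gt(attr(mt, "prior")$d0, 0)
  expect_error(moderated_t(mat, rep(c(TRUE, FALSE), c(1, 11))), ">= 2")
})

test_that("moderated t agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(26)
  mat <- matrix(rnorm(200 * 14, sd = sqrt(1 / rgamma(200, 4, 4))), nrow = 200)
  rownames(mat) <- sprintf("g%03d", 1:200)
  rec <- rep(c(TRUE, FALSE), each = 7)
  mt <- moderated_t(mat, rec)
  design <- cbind(1, as.numeric(rec))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(attr(mt, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mt, "prior")$s0_2, fit$s2.prior, tolerance = 1e-6)
  expect_equal(mt$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("deg_table reports linear fold changes of group means", {
  mat <- rbind(up = c(4, 4.2, 1, 1.2), flat = c(2, 2.1, 2, 2.1),
               down = c(0.9, 1.2, 3, 3.3))
  colnames(mat) <- paste0("s", 1:4)
  rec <- c(TRUE, TRUE, FALSE, FALSE)
  tab <- deg_table(mat, rec)
  expect_equal(tab$fold_change[tab$gene == "up"],
               mean(2^c(4, 4.2)) / mean(2^c(1, 1.2)))
  expect_equal(tab$log2fc[tab$gene == "up"], 3)
  log2fc_scale <- deg_table(mat, rec, fc_scale = "log2")
  expect_equal(log2fc_scale$fold_change[1], 2^log2fc_scale$log2fc[1])
})

test_that("signature associations plant the expected direction", {
  sim <- simulate_and_score(401, effect_map = list("T-cell" = -1))
  assoc <- signature_association(sim$scores, sim$recurrent)
  row <- assoc[assoc$signature == "T-cell", ]
  expect_lt(row$mean_z_diff, 0)
  expect_lt(row$p_one_sided_less, 0.05)
})
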