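test_that("method-of-moments dispersion recovers simulated truth", {
  raw0 <- fix_nb_two_group(2000, 6, 100, phi = 0, seed = 31)
  est0 <- estimate_dispersion(raw0)
  expect_lte(est0$common_dispersion, 0.02)

  raw2 <- fix_nb_two_group(2000, 6, 100, phi = 0.2, seed = 32)
  est2 <- estimate_dispersion(raw2)
  expect_gte(est2$common_dispersion, 0.1)
  expect_lte(est2$common_dispersion, 0.3)

  ## full shrinkage collapses every gene onto the common value
  est_full <- estimate_dispersion(raw2, shrink_weight = 1)
  expect_true(all(est_full$per_gene == est_full$common_dispersion))

  ## a group with a single replicate is rejected
  one_rep <- fix_matrix(raw2$values[, 1:3], c("a", "a", "b"))
  expect_error(estimate_dispersion(one_rep), "< 2 replicates")
})

test_that("exact test is symmetric in the tissue pair and handles zeros", {
  raw <- fix_nb_two_group(150, 3, 60, phi = 0.1, seed = 33,
                          fold = 4, n_up = 20)
  raw$values[1, ] <- 0   # all-zero gene is reported, not an error
  f <- compute_tmm_factors(raw)
  disp <- estimate_dispersion(raw, f)
  ab <- exact_nb_test(raw, f, disp, "a", "b")
  ba <- exact_nb_test(raw, f, disp, "b", "a")
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$logFC, -ba$logFC, tolerance = 1e-12)
  expect_equal(ab$p_value[1], 1)
  expect_equal(ab$logFC[1], 0)
})

test_that("balanced equal group sums give p = 1", {
  ## identical groups: the observed outcome is the modal, central one
  y <- matrix(rep(c(40, 10, 25), 4), ncol = 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  raw <- fix_matrix(y, c("a", "a", "b", "b"))
  de <- exact_nb_test(raw, fix_unit_factors(raw),
                      fix_constant_dispersion(raw, 0.1), "a", "b")
  expect_equal(de$p_value, rep(1, 3))
})

test_that("dispersion zero reduces the conditional law to the binomial", {
  set.seed(34)
  for (i in 1:100) {
    ra <- sample(2:6, 1); rb <- sample(2:6, 1)
    n <- sample(5:400, 1); sa <- sample(0:n, 1)
    p_impl <- tissuespec:::nb_condsum_pvalue(sa, n - sa, ra, rb,
                                             phi = 0, enum_limit = 1e4)
    w <- ra / (ra + rb)
    d <- dbinom(0:n, n, w)
    p_oracle <- min(1, sum(d[d <= d[sa + 1] * (1 + 1e-12)]))
    expect_equal(p_impl, p_oracle, tolerance = 1e-10)
  }
})

test_that("windowed enumeration agrees with the doubled tail at large totals", {
  ## same instance evaluated with and without truncation
  p_full <- tissuespec:::nb_condsum_pvalue(11000, 9500, 5, 5, 0.05,
                                           enum_limit = 30000)
  p_win <- tissuespec:::nb_condsum_pvalue(11000, 9500, 5, 5, 0.05,
                                          enum_limit = 100)
  expect_lt(abs(p_full - p_win) / p_full, 0.05)
  expect_lte(p_win, 1)
})

test_that("null NB counts give nominal type-I error", {
  raw <- fix_nb_two_group(2000, 6, 100, phi = 0.15, seed = 35)
  f <- compute_tmm_factors(raw)
  de <- exact_nb_test(raw, f, fix_constant_dispersion(raw, 0.15),
                      "a", "b")
  expect_gte(mean(de$p_value <= 0.05), 0.03)
  expect_lte(mean(de$p_value <= 0.05), 0.07)
})

test_that("step-up FDR adjustment matches hand computations", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(adjust_fdr(0.123), 0.123)
  ## monotone non-decreasing in p rank
  set.seed(36)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= 0 & q <= 1))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("PUR requires FDR and a positive TMM log-ratio in every comparison", {
  tissues <- c("a", "b", "c")
  genes <- c("g1", "g2", "g3")
  ## TMM matrix: g1 high in a; g2 high in a; g3 flat
  v <- rbind(g1 = c(30, 30, 2, 2, 2, 2),
             g2 = c(20, 20, 3, 3, 1, 1),
             g3 = c(5, 5, 5, 5, 5, 5))
  colnames(v) <- paste0("s", 1:6)
  tmm <- fix_matrix(v, rep(tissues, each = 2), kind = "tmm")
  pairs <- combn(tissues, 2)
  de <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    data.frame(gene_id = genes, tissue_a = pairs[1, j],
               tissue_b = pairs[2, j], logFC = 0,
               p_value = 0.001, fdr = 0.01, stringsAsFactors = FALSE)
  }))
  ## g2 fails the FDR condition in one of a's comparisons
  de$fdr[de$gene_id == "g2" & de$tissue_a == "a" & de$tissue_b == "c"] <- 0.2
  pur <- classify_pur(de, tmm)

  g1a <- pur[pur$gene_id == "g1" & pur$tissue == "a", ]
  expect_true(g1a$is_pur)
  expect_equal(g1a$n_comparisons_passed, 2L)
  ## positive ratios everywhere but one failed FDR -> not PUR, one short
  g2a <- pur[pur$gene_id == "g2" & pur$tissue == "a", ]
  expect_false(g2a$is_pur)
  expect_equal(g2a$n_comparisons_passed, 1L)
  ## flat gene is PUR nowhere
  expect_false(any(pur$is_pur[pur$gene_id == "g3"]))
  ## a gene is PUR in at most one tissue
  expect_lte(max(tapply(pur$is_pur, pur$gene_id, sum)), 1)
  ## missing pair rows are an error
  expect_error(classify_pur(de[de$tissue_a != "a", ], tmm), "missing")
})

test_that("planted upregulated genes are recovered with few false calls", {
  set.seed(37)
  ng <- 800; r <- 6
  base <- rlnorm(ng, log(80), 1)
  tissues <- c("a", "b", "c")
  up <- 1:60   # planted 8-fold in tissue a
  mu <- sapply(tissues, function(t) {
    m <- base
    if (t == "a") m[up] <- m[up] * 8
    m
  })
  y <- do.call(cbind, lapply(tissues, function(t) {
    matrix(rnbinom(ng * r, mu = rep(mu[, t], r), size = 10), ng)
  }))
  rownames(y) <- sprintf("g%04d", 1:ng)
  colnames(y) <- paste0(rep(tissues, each = r), 1:r)
  raw <- fix_matrix(y, rep(tissues, each = r))
  f <- compute_tmm_factors(raw)
  disp <- estimate_dispersion(raw, f)
  de <- run_pairwise_de(raw, f, disp)
  tmm <- apply_tmm(tpm_from_counts(raw), f)
  pur <- classify_pur(de, tmm)
  calls <- pur[pur$is_pur, ]
  recovered <- sum(calls$gene_id %in% rownames(y)[up] &
                     calls$tissue == "a")
  expect_gte(recovered, 0.8 * length(up))
  false_calls <- sum(!(calls$gene_id %in% rownames(y)[up]))
  expect_lte(false_calls, max(1, 0.05 * nrow(calls)))
})

test_that("sensitivity never drops when the planted fold-change grows", {
  recover_rate <- function(fold) {
    raw <- fix_nb_two_group(400, 6, 80, phi = 0.1, seed = 38,
                            fold = fold, n_up = 40)
    f <- compute_tmm_factors(raw)
    de <- exact_nb_test(raw, f, fix_constant_dispersion(raw, 0.1),
                        "a", "b")
    fdr <- adjust_fdr(de$p_value)
    mean(fdr[1:40] <= 0.05)
  }
  expect_lte(recover_rate(2), recover_rate(8))
})
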