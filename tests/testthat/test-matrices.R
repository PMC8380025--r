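test_that("gene aggregation sums reads and restores the per-million scale", {
  sheet <- sample_sheet("s1", "a", "r1")
  quant <- list(s1 = data.frame(
    transcript_id = c("t1", "t2", "t3"),
    length = 100, effective_length = 60,
    tpm = c(700000, 300000, 0),
    num_reads = c(4, 6, 0), stringsAsFactors = FALSE))
  map <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    gene_id = c("g1", "g1", "g2"))
  out <- aggregate_to_genes(quant, map, sheet)
  expect_equal(out$raw$values["g1", "s1"], 10)
  expect_equal(out$tpm$values["g1", "s1"], 1e6)
  ## total reads conserved
  expect_equal(sum(out$raw$values), sum(quant$s1$num_reads))

  ## two equal genes left after removing a 50% contaminant: rescaled
  quant2 <- list(s1 = data.frame(
    transcript_id = c("t1", "t2"), length = 100, effective_length = 60,
    tpm = c(250000, 250000), num_reads = c(5, 5),
    stringsAsFactors = FALSE))
  map2 <- data.frame(transcript_id = c("t1", "t2"),
                     gene_id = c("g1", "g2"))
  out2 <- aggregate_to_genes(quant2, map2, sheet)
  expect_equal(unname(out2$tpm$values[, "s1"]), c(500000, 500000))

  ## unmapped transcript is an error
  expect_error(aggregate_to_genes(quant, map2, sheet), "t3")
})

test_that("TPM columns always sum to one million", {
  sim <- simulate_quant_files(sim_config(n_genes = 120, seed = 3,
                                         n_specific_per_tissue = 5,
                                         n_pur_per_tissue = 5),
                              isoforms_per_gene = 2)
  out <- aggregate_to_genes(sim$quants, sim$map, sim$sim$sheet)
  expect_equal(unname(colSums(out$tpm$values)),
               rep(1e6, ncol(out$tpm$values)), tolerance = 1e-6)
  ## and raw aggregation conserves per-sample totals exactly
  tx_totals <- vapply(sim$quants, function(q) sum(q$num_reads),
                      numeric(1))
  expect_equal(unname(colSums(out$raw$values)), unname(tx_totals),
               tolerance = 1e-9)
})

test_that("TMM factors are 1 under pure library-size differences", {
  set.seed(21)
  base <- rpois(400, rlnorm(400, log(50), 1))
  y <- unname(cbind(base, base * 3, base * 2, base * 0.5))
  raw <- fix_matrix(y, c("a", "a", "b", "b"))
  f <- compute_tmm_factors(raw)
  expect_equal(f$norm_factor, rep(1, 4), tolerance = 1e-6)
  expect_equal(exp(mean(log(f$norm_factor))), 1, tolerance = 1e-8)

  ## identical columns -> factors exactly 1
  y2 <- matrix(rep(base, 3), ncol = 3)
  f2 <- compute_tmm_factors(fix_matrix(y2, c("a", "a", "b")))
  expect_equal(f2$norm_factor, rep(1, 3))
})

test_that("TMM factors match the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(22)
  ng <- 800
  mu <- rlnorm(ng, log(120), 1.2)
  scale <- rep(c(1, 2, 1, 3, 1.5, 1), each = ng)
  y <- matrix(rnbinom(ng * 6, mu = rep(mu, 6) * scale, size = 8), ng)
  y[1:25, 3] <- y[1:25, 3] * 10
  raw <- fix_matrix(y, rep(c("a", "b", "c"), each = 2))
  ours <- compute_tmm_factors(raw)$norm_factor
  ref <- unname(edgeR::calcNormFactors(raw$values, method = "TMM"))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("composition spike perturbs only the spiked sample, near the null-subset oracle", {
  set.seed(23)
  ng <- 1000
  mu <- rlnorm(ng, log(200), 1)
  y <- matrix(rpois(ng * 4, rep(mu, 4)), ng)
  spiked <- 1:30
  y[spiked, 1] <- y[spiked, 1] * 16
  raw <- fix_matrix(y, c("a", "a", "b", "b"))
  f <- compute_tmm_factors(raw)

  ## oracle: untrimmed precision-weighted mean over the known-null genes,
  ## against the same upper-quartile reference the method selects
  lib <- colSums(y)
  uq <- apply(y, 2, function(col) quantile(col / sum(col), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  nullg <- setdiff(seq_len(ng), spiked)
  oracle <- vapply(1:4, function(s) {
    if (s == ref) return(1)
    ys <- y[nullg, s]; yr <- y[nullg, ref]
    keep <- ys > 0 & yr > 0
    ys <- ys[keep]; yr <- yr[keep]
    m <- log2((ys / lib[s]) / (yr / lib[ref]))
    w <- 1 / (1 / ys - 1 / lib[s] + 1 / yr - 1 / lib[ref])
    2^(sum(w * m) / sum(w))
  }, numeric(1))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_lt(abs(f$norm_factor[1] - oracle[1]) / oracle[1], 0.05)
  expect_equal(f$norm_factor[-1], oracle[-1], tolerance = 0.02)
})

test_that("applying TMM factors rescales columns and re-normalizes to ~1", {
  set.seed(24)
  y <- matrix(rpois(600 * 4, rlnorm(600, log(100), 1)), 600)
  raw <- fix_matrix(y, c("a", "a", "b", "b"))
  tpm <- tpm_from_counts(raw)
  f <- compute_tmm_factors(raw)
  tmm <- apply_tmm(tpm, f)
  expect_equal(tmm$values,
               sweep(tpm$values, 2, f$norm_factor, "/"),
               tolerance = 1e-12)

  ## unit factors -> identity
  tmm_id <- apply_tmm(tpm, fix_unit_factors(raw))
  expect_equal(tmm_id$values, tpm$values)

  ## factors recomputed on the normalized matrix are ~1
  renorm <- count_matrix(round(sweep(raw$values, 2, f$norm_factor, "/")),
                         "raw", raw$sheet)
  f2 <- compute_tmm_factors(renorm)
  expect_equal(f2$norm_factor, rep(1, 4), tolerance = 0.01)

  ## factor application commutes with gene subsetting (factors fixed)
  expect_equal(tmm$values[1:100, ],
               sweep(tpm$values[1:100, ], 2, f$norm_factor, "/"),
               tolerance = 1e-12)
  expect_error(apply_tmm(tpm, f[-1, ]), "mismatch")
})

test_that("log2 transform maps with the pseudocount convention", {
  y <- matrix(c(0, 7, 3, 1), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tmm <- fix_matrix(y, c("a", "b"), kind = "tmm")
  lg <- log2_transform(tmm, pseudocount = 1)
  expect_equal(lg$values["g1", "s1"], 0)
  expect_equal(lg$values["g2", "s1"], 3)  # log2(8)
  expect_equal(lg$kind, "log2tmm")
  expect_error(log2_transform(fix_matrix(y, c("a", "b"))), "tmm")
})

test_that("replicate QC recovers planted tissue separation", {
  set.seed(25)
  ng <- 300
  base <- rlnorm(ng, log(80), 1)
  shift <- base * c(rep(6, 60), rep(1, ng - 60))
  y <- cbind(matrix(rpois(ng * 3, rep(base, 3)), ng),
             matrix(rpois(ng * 3, rep(shift, 3)), ng))
  raw <- fix_matrix(y, rep(c("a", "b"), each = 3))
  qc <- qc_replicates(raw)
  expect_true(all(qc$clusters_with_tissue))
  expect_equal(dim(qc$correlation), c(6, 6))
  expect_gte(ncol(qc$pca), 2)

  ## duplicate samples correlate exactly
  y2 <- cbind(y[, 1], y[, 1], y[, 4])
  qc2 <- qc_replicates(fix_matrix(y2, c("a", "a", "b")))
  expect_equal(qc2$correlation[1, 2], 1)

  ## PC coordinates invariant (up to sign) under gene reordering
  perm <- sample(nrow(y))
  qc3 <- qc_replicates(fix_matrix(y[perm, ], rep(c("a", "b"), each = 3)))
  expect_equal(abs(qc3$pca), abs(qc$pca), tolerance = 1e-8)

  expect_error(qc_replicates(fix_matrix(matrix(5, 4, 3),
                                        c("a", "a", "b"))),
               "constant")
})
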