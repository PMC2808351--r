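test_that("reproducibility filter keeps exactly the >= 5-of-6 clones in order", {
  vals <- matrix(rnorm(4 * 6), 4, 6)
  vals[2, 1] <- NA                 # 5 of 6: retained
  vals[3, 1:2] <- NA               # 4 of 6: removed
  vals[4, 1:3] <- NA               # 3 of 6: removed
  m <- ratio_matrix(vals, clone_ids = c("a", "b", "c", "d"))
  f <- reproducibility_filter(m, 5)
  expect_identical(rownames(f$values), c("a", "b"))
  expect_equal(attr(f, "n_filtered_out"), 2L)
  expect_error(reproducibility_filter(m, 7), "exceeds the replicate count")
})

test_that("the d statistic matches its definition and an independent mean/SE oracle", {
  null_row <- ratio_matrix(matrix(0, 1, 6), clone_ids = "z")
  expect_equal(unname(compute_d(null_row, s0 = 0.5)$d), 0)

  const <- ratio_matrix(matrix(1, 1, 6), clone_ids = "c")
  expect_error(compute_d(const, s0 = 0), "s0 must be > 0")
  expect_equal(unname(compute_d(const, s0 = 0.1)$d), 10)

  set.seed(4)
  vals <- matrix(rnorm(50 * 6), 50, 6)
  vals[sample(300, 20)] <- NA
  m <- ratio_matrix(vals, clone_ids = sprintf("c%02d", 1:50))
  got <- compute_d(m, s0 = 0.2)
  want <- oracle_row_stats(vals)
  expect_equal(unname(got$d), want$m / (want$s + 0.2))
  expect_equal(unname(got$s), want$s)

  neg <- compute_d(negate_matrix(m), s0 = 0.2)
  expect_identical(neg$d, -got$d)  # exact antisymmetry
})

test_that("clones with fewer than two present replicates are excluded with a warning", {
  vals <- matrix(rnorm(12), 2, 6)
  vals[2, 2:6] <- NA
  m <- ratio_matrix(vals, clone_ids = c("ok", "sparse"))
  expect_warning(got <- compute_d(m, 0.1), "< 2 present")
  expect_identical(names(got$d), "ok")
})

test_that("s0 estimation honours its strategy and matches a brute-force grid oracle", {
  s_const <- rep(0.3, 30)
  d_num <- rnorm(30)
  s0 <- estimate_s0(s_const, d_num, strategy = "median_s")
  expect_equal(as.numeric(s0), 0.3)
  expect_equal(attr(s0, "strategy"), "median_s")

  expect_warning(fb <- estimate_s0(rep(0.2, 10), rnorm(10),
                                   strategy = "cv_minimization"),
                 "fewer than 20")
  expect_equal(attr(fb, "strategy"), "median_s")

  # heteroscedastic fixture: brute-force oracle re-evaluates every
  # candidate percentile with plain loops
  set.seed(9)
  s_vals <- sqrt(rchisq(200, df = 5) / 5) * 0.2 * rep(c(1, 3), each = 100)
  d_num <- rnorm(200, sd = s_vals * sqrt(6))
  got <- estimate_s0(s_vals, d_num, strategy = "cv_minimization")

  candidates <- unname(quantile(s_vals, probs = seq(0, 1, by = 0.05)))
  win <- cut(rank(s_vals, ties.method = "first"), breaks = 10,
             labels = FALSE)
  cvs <- sapply(candidates, function(a) {
    spreads <- sapply(split(d_num / (s_vals + a), win), mad)
    sd(spreads) / mean(spreads)
  })
  expect_equal(as.numeric(got), candidates[which.min(cvs)])
})

test_that("the exhaustive sign-flip null is exact, symmetric, and contains the identity", {
  m <- noise_matrix(n = 40, seed = 2)
  null <- permutation_null(m, s0 = 0.1)
  expect_equal(nrow(null), 64)  # 2^6 assignments

  idrow <- attr(null, "identity_row")
  obs <- compute_d(m, s0 = 0.1)$d
  expect_equal(unname(null[idrow, ]), unname(sort(obs)))

  # assignments come in +/- pairs: the multiset of rows is closed under
  # negation-and-reversal
  rows_txt <- apply(round(null, 10), 1, paste, collapse = ",")
  mirrored <- apply(round(-null[, ncol(null):1, drop = FALSE], 10), 1,
                    paste, collapse = ",")
  expect_setequal(rows_txt, mirrored)

  expect_error(
    permutation_null(ratio_matrix(matrix(rnorm(42), 2, 21),
                                  clone_ids = c("a", "b")), 0.1),
    "sampled mode")
})

test_that("sampled permutation mode is seeded and respects n_perm", {
  m <- noise_matrix(n = 30, seed = 6)
  p <- sam_params(permutation_mode = "sampled", n_perm = 37, perm_seed = 5)
  n1 <- permutation_null(m, 0.1, p)
  n2 <- permutation_null(m, 0.1, p)
  expect_equal(nrow(n1), 37)
  expect_identical(n1, n2)
})

test_that("planted signal is recovered at the target FDR", {
  m <- planted_matrix(n = 1000, n_planted = 50, effect = 1.5, sd = 0.5,
                      seed = 42)
  de <- sam_de(m)
  planted <- sprintf("cl%04d", 1:50)
  expect_gte(sum(planted %in% de$down_clones), 45)
  expect_lte(de$fdr_achieved, 0.10)
  expect_length(intersect(de$up_clones, de$down_clones), 0)
})

test_that("negating the matrix swaps up and down calls exactly", {
  m <- planted_matrix(n = 400, n_planted = 25, seed = 13)
  m$values[sample(2400, 60)] <- NA  # exercise the missing-value path too
  de <- sam_de(m)
  de_neg <- sam_de(negate_matrix(m))
  expect_setequal(de$up_clones, de_neg$down_clones)
  expect_setequal(de$down_clones, de_neg$up_clones)
  expect_equal(de_neg$s0, de$s0)
  expect_equal(de_neg$fdr_achieved, de$fdr_achieved)
})

test_that("calls are invariant to clone row order", {
  m <- planted_matrix(n = 300, n_planted = 20, seed = 17)
  set.seed(1)
  perm <- sample(nrow(m$values))
  m_perm <- ratio_matrix(m$values[perm, ], orientation = m$orientation)
  de <- sam_de(m)
  de_perm <- sam_de(m_perm)
  expect_setequal(de$up_clones, de_perm$up_clones)
  expect_setequal(de$down_clones, de_perm$down_clones)
})

test_that("the per-delta FDR curve is non-increasing", {
  m <- planted_matrix(n = 500, n_planted = 30, seed = 21)
  de <- sam_de(m)
  tab <- de$fdr_table
  f <- tab$fdr_monotone[!is.na(tab$fdr_monotone)]
  expect_true(all(diff(f) <= 1e-12))
})

test_that("filtering commutes with row subsetting", {
  cfg <- small_config(missing_rate = 0.15, seed = 29)
  st <- simulate_study(cfg)
  m <- st$ratios$MPP
  keep <- seq(1, nrow(m$values), by = 2)
  sub <- ratio_matrix(m$values[keep, ], orientation = m$orientation)
  f_then_sub <- reproducibility_filter(m, 5)
  a <- intersect(rownames(f_then_sub$values), rownames(sub$values))
  b <- rownames(reproducibility_filter(sub, 5)$values)
  expect_identical(a, b)
})

test_that("a pure-noise matrix yields few calls with a controlled FDR estimate", {
  m <- noise_matrix(n = 1000, seed = 101)
  de <- sam_de(m)
  n_calls <- length(de$up_clones) + length(de$down_clones)
  expect_lt(n_calls, 50)  # far fewer than the 1000 clones
  if (n_calls > 0) expect_lte(de$fdr_achieved, 0.10)
})

test_that("DE calls serialize to TSV plus JSON provenance", {
  m <- planted_matrix(n = 200, n_planted = 15, seed = 33)
  de <- sam_de(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_calls(de, path)
  tsv <- read.delim(path, stringsAsFactors = FALSE)
  expect_setequal(tsv$clone_id[tsv$call == "down"], de$down_clones)
  prov <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(prov$s0, de$s0)
  expect_equal(prov$target_fdr, 0.10)
})
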