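test_that("patterning z-scores separate blocky from well-mixed sequences", {
  cfg <- patterning_config(n_scrambles = 300)
  # homopolymer: scrambling changes nothing, all 36 z-scores are zero
  z0 <- patterning_zscores(strrep("A", 30), cfg, seed = 1)
  expect_length(z0, 36)
  expect_true(all(z0 == 0))
  # diblock of 20 K then 20 E: maximally blocky for pos-neg
  zb <- patterning_zscores(paste0(strrep("K", 20), strrep("E", 20)), cfg,
                           seed = 1)
  expect_gt(zb[["pos-neg"]], 2)
  expect_gt(zb[["pos-pos"]], 2)
  # strict alternation is more well-mixed than random scrambles
  za <- patterning_zscores(strrep("KE", 20), cfg, seed = 1)
  expect_lt(za[["pos-neg"]], 0)
  # reproducibility under the seed
  expect_identical(zb, patterning_zscores(
    paste0(strrep("K", 20), strrep("E", 20)), cfg, seed = 1))
  # pairs involving absent groups are zero
  expect_true(all(zb[grep("aro", names(zb))] == 0))
})

test_that("patterning z of scrambles is centred near zero", {
  cfg <- patterning_config(n_scrambles = 200)
  base <- strsplit("KKEEKAKEEAAKEKEAEKAKEAKKEAEAKE", "")[[1]]
  set.seed(99)
  zz <- replicate(50, {
    s <- paste(sample(base), collapse = "")
    patterning_zscores(s, cfg, seed = sample.int(1e6, 1))[["pos-neg"]]
  })
  expect_lt(abs(mean(zz)), 0.35)
})

test_that("patch finder matches the brute-force enumeration oracle", {
  # definitional cases
  p <- find_patches("AAAA", "A")
  expect_equal(unname(p$intervals), cbind(1L, 4L))
  expect_equal(p$coverage, 1)
  expect_equal(nrow(find_patches("AAQQQAA", "A")$intervals), 0L)
  prg <- find_patches("RGARG", "RG")
  expect_equal(unname(prg$intervals), cbind(1L, 5L))
  expect_equal(prg$coverage, 1)
  # interruptions inside a patch are bounded by two
  expect_equal(unname(find_patches("AVVAVAQQA", "A")$intervals), cbind(1L, 9L))
  # 500 random 60-mers against the oracle (skewed alphabet so patches occur)
  set.seed(77)
  alph <- c(rep("A", 5), rep("R", 4), rep("G", 4), strsplit("CDEFHIKLMNPQSTVWY", "")[[1]])
  for (k in 1:500) {
    s <- paste(sample(alph, 60, replace = TRUE), collapse = "")
    for (tg in c("A", "R", "RG")) {
      got <- find_patches(s, tg)$intervals
      want <- oracle_patches(s, tg)
      expect_equal(unname(got), unname(want), info = paste(s, tg))
    }
  }
})

test_that("composition panel has 55 features with the documented values", {
  cf <- composition_features("RGRGAAAA")
  expect_length(cf, 55)
  expect_equal(unname(cf["patch_RG"]), 0.5)   # RG patch covers residues 1-4
  expect_equal(unname(cf["patch_A"]), 0.5)    # A patch covers residues 5-8
  # poly-R: composition extremes and the flagged R/K ratio
  pr <- composition_features(strrep("R", 12))
  expect_equal(unname(pr["frac_R"]), 1)
  expect_equal(unname(pr["ncpr"]), 1)
  expect_equal(unname(pr["ratio_RK"]), 12)    # K absent: numerator count
  expect_true(attr(pr, "sentinel")["ratio_RK"])
  expect_equal(unname(pr["count_RY"]), 12)
  # acidic homopolymer has a low isoelectric point, basic a high one
  expect_lt(composition_features(strrep("D", 20))["isoelectric_point"], 4.5)
  expect_gt(composition_features(strrep("K", 20))["isoelectric_point"], 9)
  # fractions live in [0, 1]
  fr <- cf[grep("^frac_|^patch_", names(cf))]
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("full grammar matrix counts 91 sequence features and 92 z-scores", {
  pr <- gen_proteome_and_abundance(n_proteins = 8, seed = 2)
  fm <- grammar_feature_matrix(pr$sequences,
                               pattern_cfg = patterning_config(n_scrambles = 100),
                               seed = 5)
  expect_equal(ncol(fm), 91)   # 36 patterning + 55 composition
  expect_equal(nrow(fm), 8)
  expect_equal(sum(grepl("^patch_", colnames(fm))), 19)
  z <- reference_zscores(fm)
  n_dropped <- length(attr(z, "dropped_features"))
  z <- cbind(z, abundance_z = abundance_zscore(pr$abundance)[rownames(z)])
  expect_equal(ncol(z), 92 - n_dropped)
})

test_that("reference z-scoring centres the reference set and drops constants", {
  set.seed(8)
  m <- cbind(a = rnorm(20), b = rnorm(20, 5, 2), const = rep(3, 20))
  rownames(m) <- sprintf("p%02d", 1:20)
  z <- reference_zscores(m)
  expect_equal(attr(z, "dropped_features"), "const")
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  # a protein sitting at the reference mean scores zero
  m2 <- rbind(m, at_mean = c(mean(m[, 1]), mean(m[, 2]), 3))
  z2 <- reference_zscores(m2, reference_ids = rownames(m))
  expect_equal(unname(z2["at_mean", ]), c(0, 0), tolerance = 1e-12)
})

test_that("abundance z-scores respond to planted enrichment and ignore order", {
  ab <- matrix(10, 6, 8, dimnames = list(sprintf("p%d", 1:6), NULL))
  expect_true(all(abundance_zscore(ab) == 0))      # uniform table
  ab[3, ] <- 30                                     # 3-fold enriched protein
  z <- abundance_zscore(ab)
  expect_gt(z[["p3"]], 1)
  expect_identical(z, abundance_zscore(ab[, sample(ncol(ab))]))
  expect_error(abundance_zscore(ab, "missing_protein"), "not in abundance")
})

test_that("KS enrichment flags planted features with the right sign", {
  set.seed(12)
  nf <- 30
  bg <- matrix(rnorm(80 * nf), 80, nf,
               dimnames = list(sprintf("b%02d", 1:80), paste0("f", 1:nf)))
  st <- matrix(rnorm(15 * nf), 15, nf,
               dimnames = list(sprintf("s%02d", 1:15), paste0("f", 1:nf)))
  st[, 1] <- st[, 1] + 2    # enriched feature
  st[, 2] <- st[, 2] - 2    # depleted feature
  enr <- ks_feature_enrichment(st, bg)
  expect_true(enr$significant[1] && enr$signed_log_p[1] > 0)
  expect_true(enr$significant[2] && enr$signed_log_p[2] < 0)
  # identical distributions: p = 1, nothing recorded
  same <- ks_feature_enrichment(bg[1:40, , drop = FALSE],
                                bg[41:80, , drop = FALSE])
  expect_true(all(is.na(same$signed_log_p[same$p_value > 0.9])))
  expect_error(ks_feature_enrichment(bg[1:5, ], bg), "disjoint")
  expect_warning(ks_feature_enrichment(st[1, , drop = FALSE], bg), "single")
})
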