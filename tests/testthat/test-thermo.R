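test_that("fraction unfolded obeys the two-state identities", {
  cfg <- thermo_config()
  expect_identical(fraction_unfolded(0, cfg), 0.5)
  # logistic symmetry p(dG) + p(-dG) = 1, with well-behaved tails over the
  # physically meaningful stability range
  for (dG in c(-60, -30, -2.7, 0.4, 13, 30, 60)) {
    p <- fraction_unfolded(dG, cfg)
    expect_gt(p, 0); expect_lt(p, 1)
    expect_equal(p + fraction_unfolded(-dG, cfg), 1)
  }
  # strictly decreasing in dG
  grid <- fraction_unfolded(seq(-20, 20, by = 0.5), cfg)
  expect_true(all(diff(grid) < 0))
  # 13 kJ/mol at 293 K: over 99% folded, under both gas-constant conventions
  expect_gt(1 - fraction_unfolded(13, thermo_config(R = 8.314)), 0.99)
  expect_gt(1 - fraction_unfolded(13, thermo_config(R = 8.131)), 0.99)
})

test_that("predicted c_sat follows c*/p_U with its limits", {
  cfg <- thermo_config()
  # p_U = 0.5 doubles c*
  expect_equal(predict_csat(0, c_star = 10.83), 2 * 10.83)
  expect_equal(predict_csat(12.9, c_star = 10.83, shift = -12.9), 2 * 10.83)
  # deeply unstable limit: c_sat -> c*
  expect_equal(predict_csat(-200, c_star = 10.83), 10.83, tolerance = 1e-12)
  # monotone in dG
  v <- predict_csat(seq(-10, 25, by = 1), c_star = 5, shift = -12.9)
  expect_true(all(diff(v) > 0))
  # cap reports divergence as Inf
  expect_identical(predict_csat(100, c_star = 1, cap = 1e6), Inf)
})

test_that("c*/offset fit recovers planted parameters exactly on noiseless data", {
  v <- gen_variant_table(noise_cv = 0, seed = 5)
  # generated values satisfy csat * p_U = c* to machine precision
  expect_equal(v$csat_measured * v$p_U_true, rep(10.83, nrow(v)),
               tolerance = 1e-12)
  fit <- fit_cstar_shift(v)
  expect_equal(fit$c_star, 10.83, tolerance = 1e-4)
  expect_equal(fit$dG_shift, -12.9, tolerance = 1e-4)
  expect_gt(fit$r2, 0.9999)
})

test_that("c*/offset fit is invariant to row order and rescales with units", {
  v <- gen_variant_table(noise_cv = 0.05, seed = 8)
  fit <- fit_cstar_shift(v)
  perm <- v[sample.int(nrow(v)), ]
  fit_p <- fit_cstar_shift(perm)
  expect_equal(fit_p$c_star, fit$c_star, tolerance = 1e-8)
  expect_equal(fit_p$dG_shift, fit$dG_shift, tolerance = 1e-8)
  # uniform intensity rescaling: c* rescales, offset untouched
  v2 <- v; v2$csat_measured <- v2$csat_measured * 37
  fit_s <- fit_cstar_shift(v2)
  expect_equal(fit_s$c_star, 37 * fit$c_star, tolerance = 1e-6)
  expect_equal(fit_s$dG_shift, fit$dG_shift, tolerance = 1e-6)
})

test_that("degenerate fit inputs are rejected with informative errors", {
  v <- gen_variant_table(noise_cv = 0, seed = 1)
  expect_error(fit_cstar_shift(v[1, ]), "at least 3")
  same <- v[1:4, ]; same$dG_U <- 5
  expect_error(fit_cstar_shift(same), "identifiab")
})

test_that("offset converts to the printed kcal/mol value", {
  expect_equal(kj_to_kcal(-12.9), -3.1, tolerance = 0.01)
})

test_that("blob detection matches brute-force window enumeration", {
  # poly-Ile: maximally hydrophobic, one blob spanning the chain
  prof <- detect_blobs(strrep("I", 30))
  expect_equal(nrow(prof$hydrophobic_blobs), 1L)
  expect_equal(unname(prof$hydrophobic_blobs[1, ]), c(1L, 30L))
  expect_equal(nrow(prof$hydrophilic_blobs), 0L)
  # poly-Asn: scaled KD 0.111, one hydrophilic blob spanning the chain
  prof2 <- detect_blobs(strrep("N", 30))
  expect_equal(nrow(prof2$hydrophilic_blobs), 1L)
  expect_equal(unname(prof2$hydrophilic_blobs[1, ]), c(1L, 30L))
  # hand-built alternating tracts agree with the enumeration oracle
  seqs <- c(paste0(strrep("I", 8), strrep("N", 8), strrep("I", 8)),
            vapply(1:100, function(i) random_seq(50, seed = 400 + i),
                   character(1)))
  for (s in seqs) {
    got <- detect_blobs(s)
    want <- oracle_blobs(s)
    expect_equal(unname(got$hydrophobic_blobs), unname(want$hydrophobic))
    expect_equal(unname(got$hydrophilic_blobs), unname(want$hydrophilic))
    expect_equal(unname(got$window_scores), unname(want$windows),
                 tolerance = 1e-12)
  }
})

test_that("blob change scores losses of hydrophobic and gains of hydrophilic blobs", {
  a <- detect_blobs(paste0(strrep("I", 10), strrep("N", 14)))
  expect_equal(blob_change(a, a), 0)
  b <- detect_blobs(strrep("N", 24))
  # hand count: a has a hydrophobic blob over residues 1-12 (windows 1-10,
  # the last mixed window I,N,N still averages 0.407 > 0.37) and a
  # hydrophilic blob over 11-24 (14 residues); b has only hydrophilic 1-24.
  # change = (12 - 0) + (24 - 14)
  expect_equal(blob_change(b, a), 22)
  # the reverse direction only counts decreases/gains, floored at zero
  expect_equal(blob_change(a, b), 0)
  expect_error(blob_change(a, detect_blobs(strrep("N", 30))), "length")
})

test_that("short sequences yield an empty blob profile with a warning", {
  expect_warning(p <- detect_blobs("ILKAG"), "shorter")
  expect_length(p$window_scores, 0)
})

test_that("blob-weighted bootstrap is tight on noiseless data and floors weights", {
  v <- gen_variant_table(noise_cv = 0, seed = 3)
  ci <- cstar_confidence_interval(v, reference_sequence = v$sequence[1],
                                  n_trials = 60L, seed = 9)
  # exact data: every resample refits the same curve
  expect_lt(ci$c_star_sd / ci$c_star_mean, 1e-6)
  expect_lt(abs(ci$c_star_mean - 10.83), 1e-3)
  expect_lt(abs(ci$dG_shift_mean + 12.9), 1e-3)
  expect_true(all(ci$weights >= 0.05))
  # envelope curves bracket the central prediction
  dG <- seq(-5, 15, by = 1)
  expect_true(all(ci$envelope(dG, "upper") >=
                    predict_csat(dG, ci$c_star_mean, ci$dG_shift_mean) - 1e-6))
})
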