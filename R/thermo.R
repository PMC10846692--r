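#' Thermodynamic configuration
#'
#' Holds the gas constant and temperature used by the two-state unfolding
#' model. The default gas constant is the CODATA value 8.314 J/(mol K);
#' pass `R = 8.131` to reproduce analyses run with that alternative value.
#' Free energies throughout the package are in kJ/mol.
#'
#' @param R gas constant in J/(mol K).
#' @param T absolute temperature in K.
#' @return An object of class `thermo_config`.
#' @examples
#' cfg <- thermo_config()
#' fraction_unfolded(0, cfg)   # 0.5
#' @export
thermo_config <- function(R = 8.314, T = 293) {
  stopifnot(is.numeric(R), R > 0, is.numeric(T), T > 0)
  structure(list(R = R, T = T), class = "thermo_config")
}

#' Equilibrium fraction of unfolded molecules
#'
#' Two-state model: `p_U = exp(-dG/RT) / (1 + exp(-dG/RT))`, i.e. the logistic
#' function of `-(dG + shift)/RT`. `shift` is the constant cellular stability
#' offset (ΔG°S) added to the in vitro standard free energy of unfolding.
#' Computed via [stats::plogis()], which is overflow-safe for large `|dG|`.
#'
#' @param dG standard free energy of unfolding ΔG°U, kJ/mol. Vectorised.
#' @param cfg a [thermo_config()].
#' @param shift constant offset ΔG°S, kJ/mol (default 0).
#' @return Fraction unfolded in (0, 1), strictly decreasing in `dG`.
#' @export
fraction_unfolded <- function(dG, cfg = thermo_config(), shift = 0) {
  stopifnot(is.numeric(dG), all(is.finite(dG)), is.finite(shift))
  # dG in kJ/mol -> J/mol; p_U = plogis(-dG/RT)
  stats::plogis(-(dG + shift) * 1000 / (cfg$R * cfg$T))
}

#' Predicted saturation concentration from the critical unfolded concentration
#'
#' Under polyphasic linkage with a single unfolded saturating species,
#' `c_sat = c* / p_U(dG + shift)`: phase separation occurs when the unfolded
#' subpopulation alone reaches the critical concentration c*. As `p_U -> 0`
#' the prediction diverges; values above `cap` are returned as `Inf`,
#' signalling no phase separation at accessible concentrations.
#'
#' @param dG ΔG°U in kJ/mol (vectorised).
#' @param c_star critical unfolded concentration, arbitrary intensity units.
#' @param shift ΔG°S offset, kJ/mol.
#' @param cfg a [thermo_config()].
#' @param cap concentrations above this are reported as `Inf` (default `Inf`,
#'   i.e. no capping).
#' @return Predicted c_sat in the same units as `c_star`.
#' @export
predict_csat <- function(dG, c_star, shift = 0, cfg = thermo_config(), cap = Inf) {
  stopifnot(is.numeric(c_star), c_star > 0)
  out <- c_star / fraction_unfolded(dG, cfg, shift)
  out[out > cap] <- Inf
  out
}

#' Fit the critical unfolded concentration and stability offset
#'
#' Global two-parameter nonlinear least-squares fit of measured saturation
#' concentrations to `c_sat = c* / p_U(dG + shift)`. Residuals are taken on
#' log c_sat, which stabilises the diverging `1/p_U` branch and makes the
#' fitted c* rescale linearly under a change of intensity units while leaving
#' the offset untouched. Internally c* is parameterised on the log scale so
#' positivity is structural; a small grid of starting offsets guards against
#' local minima of the logistic model.
#'
#' @param variants data frame with numeric columns `dG_U` (kJ/mol) and
#'   `csat_measured` (a.u.; rows with `NA` are dropped).
#' @param cfg a [thermo_config()].
#' @return An object of class `thermo_fit`: list with `c_star`, `dG_shift`,
#'   `c_star_sd`, `dG_shift_sd` (asymptotic standard errors), `r2` (on log
#'   c_sat), `n` and the underlying `nls` fit.
#' @export
fit_cstar_shift <- function(variants, cfg = thermo_config()) {
  stopifnot(is.data.frame(variants),
            all(c("dG_U", "csat_measured") %in% names(variants)))
  d <- variants[is.finite(variants$dG_U) & is.finite(variants$csat_measured), ]
  if (nrow(d) < 3L)
    stop("need at least 3 variants with a measured c_sat")
  if (any(d$csat_measured <= 0))
    stop("measured c_sat values must be positive")
  if (length(unique(d$dG_U)) < 2L)
    stop("non-identifiable input: all dG_U values are equal, ",
         "c* and the offset cannot be separated")

  y <- log(d$csat_measured)
  model <- function(log_cstar, shift) {
    log_cstar - log(fraction_unfolded(d$dG_U, cfg, shift))
  }
  best <- NULL
  for (s0 in seq(-40, 40, by = 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ model(log_cstar, shift),
        start = list(log_cstar = stats::median(y) +
                       log(fraction_unfolded(stats::median(d$dG_U), cfg, s0)),
                     shift = s0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("c*/offset fit failed to converge from all starts")
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  c_star <- exp(cf[["log_cstar"]])
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  structure(list(
    c_star = c_star,
    dG_shift = cf[["shift"]],
    # delta method for SE of c* = exp(log_cstar)
    c_star_sd = c_star * se[[1]],
    dG_shift_sd = se[[2]],
    r2 = r2,
    n = nrow(d),
    fit = fit), class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat("Two-state polyphasic-linkage fit\n")
  cat(sprintf("  c*       = %.4g a.u. (se %.3g)\n", x$c_star, x$c_star_sd))
  cat(sprintf("  offset   = %.4g kJ/mol (se %.3g)\n", x$dG_shift, x$dG_shift_sd))
  cat(sprintf("  R2 (log c_sat) = %.3f on %d variants\n", x$r2, x$n))
  invisible(x)
}

#' Convert kJ/mol to kcal/mol
#'
#' Thermochemical calorie: 1 kcal = 4.184 kJ.
#'
#' @param x energy in kJ/mol.
#' @return energy in kcal/mol.
#' @export
kj_to_kcal <- function(x) x / 4.184

# Kyte-Doolittle hydropathy, scaled linearly from [-4.5, 4.5] onto [0, 1]
kd_scale <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
kd_scaled <- (kd_scale + 4.5) / 9

#' Hydrophobic and hydrophilic blob detection
#'
#' Scans a sequence with overlapping 3-residue windows of scaled
#' Kyte-Doolittle hydropathy (linear map of the scale onto 0-1). Four or more
#' contiguous windows scoring above 0.37 form a hydrophobic blob; four or more
#' contiguous windows scoring at or below 0.37 form a hydrophilic blob. Blob
#' sizes are counted in residues covered by the contributing windows (a run of
#' windows `a..b` covers residues `a..b+2`).
#'
#' @param sequence amino-acid string (standard 20-letter alphabet).
#' @param threshold window-score threshold separating hydrophobic from
#'   hydrophilic (default 0.37, i.e. raw Kyte-Doolittle about -1.17).
#' @param min_windows minimum contiguous windows per blob (default 4).
#' @return An object of class `blob_profile`: `window_scores`, and
#'   `hydrophobic_blobs` / `hydrophilic_blobs` as two-column matrices of
#'   residue start/end positions.
#' @export
detect_blobs <- function(sequence, threshold = 0.37, min_windows = 4L) {
  aa <- validate_sequence(sequence)
  n <- length(aa)
  if (n < 6L) {
    warning("sequence shorter than 6 residues: no blob windows")
    return(structure(list(window_scores = numeric(0),
                          hydrophobic_blobs = empty_intervals(),
                          hydrophilic_blobs = empty_intervals(),
                          length = n), class = "blob_profile"))
  }
  s <- kd_scaled[aa]
  w <- (s[1:(n - 2)] + s[2:(n - 1)] + s[3:n]) / 3
  runs_to_blobs <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_windows
    if (!any(keep)) return(empty_intervals())
    cbind(start = starts[keep], end = ends[keep] + 2L)  # window -> residue span
  }
  structure(list(
    window_scores = w,
    hydrophobic_blobs = runs_to_blobs(w > threshold),
    hydrophilic_blobs = runs_to_blobs(w <= threshold),
    length = n), class = "blob_profile")
}

empty_intervals <- function() {
  cbind(start = integer(0), end = integer(0))
}

blob_total <- function(intervals) {
  if (nrow(intervals) == 0L) return(0L)
  sum(intervals[, "end"] - intervals[, "start"] + 1L)
}

#' Blob change of a variant relative to a reference sequence
#'
#' The change score is the magnitude of the decrease in total hydrophobic blob
#' size plus the increase in total hydrophilic blob size, in residues; each
#' term is floored at zero (gains of hydrophobic blobs and losses of
#' hydrophilic blobs are not counted).
#'
#' @param variant,reference [detect_blobs()] profiles of same-length sequences.
#' @return Non-negative change in residues.
#' @export
blob_change <- function(variant, reference) {
  stopifnot(inherits(variant, "blob_profile"), inherits(reference, "blob_profile"))
  if (variant$length != reference$length)
    stop("blob profiles come from sequences of different length")
  dec_hphob <- max(0, blob_total(reference$hydrophobic_blobs) -
                      blob_total(variant$hydrophobic_blobs))
  inc_hphil <- max(0, blob_total(variant$hydrophilic_blobs) -
                      blob_total(reference$hydrophilic_blobs))
  dec_hphob + inc_hphil
}

#' Bootstrap confidence envelope for the c* fit
#'
#' Variants are resampled with picking weights that favour sequences whose
#' hydrophobic/hydrophilic blob architecture is close to the reference
#' (typically wild type): weight = (10 - blob_change)/10, floored at
#' `weight_floor` so every variant remains drawable. Each of `n_trials`
#' bootstrap trials draws `n_pick` variants by weight (with replacement) and
#' refits [fit_cstar_shift()]; the envelope pairs mean(c*)+sd(c*) with
#' mean(shift)-sd(shift) and vice versa, the two curves that bracket the
#' predicted c_sat-vs-dG relation.
#'
#' @param variants data frame with columns `dG_U`, `csat_measured`, `sequence`.
#' @param reference_sequence sequence against which blob changes are scored;
#'   default the first variant's sequence.
#' @param cfg a [thermo_config()].
#' @param n_trials bootstrap trials (default 1000).
#' @param n_pick sequences drawn per trial (default 10).
#' @param weight_floor minimum picking weight (default 0.05).
#' @param seed integer seed.
#' @return List with `c_star_mean`, `c_star_sd`, `dG_shift_mean`,
#'   `dG_shift_sd`, per-trial estimates, the picking weights, and an
#'   `envelope` function `(dG, which = "upper"|"lower")` returning the two
#'   bracketing c_sat curves.
#' @export
cstar_confidence_interval <- function(variants, reference_sequence = NULL,
                                      cfg = thermo_config(), n_trials = 1000L,
                                      n_pick = 10L, weight_floor = 0.05,
                                      seed = 1L) {
  stopifnot(is.data.frame(variants), nrow(variants) >= n_pick,
            all(c("dG_U", "csat_measured", "sequence") %in% names(variants)))
  if (is.null(reference_sequence)) reference_sequence <- variants$sequence[[1L]]
  ref_prof <- detect_blobs(reference_sequence)
  change <- vapply(variants$sequence,
                   function(s) blob_change(detect_blobs(s), ref_prof), numeric(1))
  weights <- pmax((10 - change) / 10, weight_floor)

  with_seed(seed, {
    trials <- matrix(NA_real_, nrow = n_trials, ncol = 2,
                     dimnames = list(NULL, c("c_star", "dG_shift")))
    for (t in seq_len(n_trials)) {
      idx <- sample.int(nrow(variants), n_pick, replace = TRUE, prob = weights)
      fit <- tryCatch(fit_cstar_shift(variants[idx, , drop = FALSE], cfg),
                      error = function(e) NULL)
      if (!is.null(fit)) trials[t, ] <- c(fit$c_star, fit$dG_shift)
    }
    ok <- stats::complete.cases(trials)
    if (!any(ok)) stop("every bootstrap trial failed to fit")
    cs <- trials[ok, "c_star"]; sh <- trials[ok, "dG_shift"]
    res <- list(
      c_star_mean = mean(cs), c_star_sd = stats::sd(cs),
      dG_shift_mean = mean(sh), dG_shift_sd = stats::sd(sh),
      trials = trials[ok, , drop = FALSE],
      weights = weights, blob_change = change,
      n_failed = sum(!ok))
    res$envelope <- local({
      cm <- res$c_star_mean; csd <- res$c_star_sd
      sm <- res$dG_shift_mean; ssd <- res$dG_shift_sd
      function(dG, which = c("upper", "lower")) {
        which <- match.arg(which)
        if (which == "upper")
          predict_csat(dG, cm + csd, sm - ssd, cfg)
        else
          predict_csat(dG, max(cm - csd, .Machine$double.eps), sm + ssd, cfg)
      }
    })
    res
  })
}
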