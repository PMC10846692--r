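#' Patterning configuration
#'
#' Residue groups and scramble settings for the patterning z-scores. The
#' eight groups partition the alphabet: pol (S,T,N,Q,C,H), hyd (I,L,M,V),
#' pos (K,R), neg (E,D), aro (F,W,Y), ala (A), pro (P), gly (G). Blockiness
#' is evaluated at sliding-window sizes 5 and 6 and the two z-scores are
#' averaged; the null distribution comes from 1000 composition-preserving
#' scrambles.
#'
#' @param n_scrambles scrambles per sequence.
#' @param window_sizes sliding-window sizes g.
#' @param residue_groups named list of residue groups (must be disjoint).
#' @return An object of class `patterning_config`.
#' @export
patterning_config <- function(n_scrambles = 1000L, window_sizes = c(5L, 6L),
                              residue_groups = list(
                                pol = c("S", "T", "N", "Q", "C", "H"),
                                hyd = c("I", "L", "M", "V"),
                                pos = c("K", "R"),
                                neg = c("E", "D"),
                                aro = c("F", "W", "Y"),
                                ala = "A", pro = "P", gly = "G")) {
  stopifnot(n_scrambles >= 2L, all(window_sizes >= 2L))
  res <- unlist(residue_groups)
  if (anyDuplicated(res) > 0L) stop("residue_groups must be disjoint")
  structure(list(n_scrambles = as.integer(n_scrambles),
                 window_sizes = as.integer(window_sizes),
                 residue_groups = residue_groups),
            class = "patterning_config")
}

#' Patch definition configuration
#'
#' A patch is a maximal region containing at least `min_occurrences` of a
#' residue (or `min_occurrences_rg` occurrences of the RG dipeptide) in
#' which consecutive occurrences are separated by at most
#' `max_interruptions` non-target positions.
#'
#' @param min_occurrences minimum occurrences for single-residue patches.
#' @param min_occurrences_rg minimum occurrences for RG patches.
#' @param max_interruptions maximum non-target positions between consecutive
#'   occurrences inside a patch.
#' @return An object of class `patch_config`.
#' @export
patch_config <- function(min_occurrences = 4L, min_occurrences_rg = 2L,
                         max_interruptions = 2L) {
  stopifnot(min_occurrences >= 1L, min_occurrences_rg >= 1L,
            max_interruptions >= 0L)
  structure(list(min_occurrences = as.integer(min_occurrences),
                 min_occurrences_rg = as.integer(min_occurrences_rg),
                 max_interruptions = as.integer(max_interruptions)),
            class = "patch_config")
}

# Patch targets retained under the study condition: all 20 residues plus the
# RG dipeptide, minus M and W (no Met or Trp patches occur in the reference
# proteome), leaving 19 patch features.
default_retained_patches <- function() c(setdiff(AA20, c("M", "W")), "RG")

# Definitional residue sets for composition features. Distinct from the
# six-category sticker grouping and from the patterning groups; each is a
# documented, overridable constant.
composition_sets <- list(
  positive = c("R", "K"),
  negative = c("D", "E"),
  polar = c("S", "T", "N", "Q", "C", "H", "G"),
  aliphatic = c("A", "I", "L", "M", "V"),
  aromatic = c("F", "W", "Y"),
  charged = c("R", "K", "D", "E"),
  chain_expanding = c("E", "D", "R", "K", "P"),
  disorder_promoting = c("A", "G", "R", "D", "H", "Q", "K", "S", "E", "P"),
  RY = c("R", "Y"))

# Per-residue polyproline-II propensity scale (experimental host-guest
# values; pinned package constant).
ppii_scale <- c(
  A = 0.37, C = 0.25, D = 0.30, E = 0.42, F = 0.30, G = 0.13, H = 0.20,
  I = 0.39, K = 0.56, L = 0.24, M = 0.36, N = 0.27, P = 1.00, Q = 0.53,
  R = 0.44, S = 0.24, T = 0.32, V = 0.39, W = 0.24, Y = 0.25)

# Side-chain and terminal pKa values (EMBOSS set) for the isoelectric point.
pka_set <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1, H = 6.5,
             K = 10.8, R = 12.5, Y = 10.1)

net_charge_at_ph <- function(counts, pH) {
  pos <- 1 / (1 + 10^(pH - pka_set["Nterm"])) +
    counts["K"] / (1 + 10^(pH - pka_set["K"])) +
    counts["R"] / (1 + 10^(pH - pka_set["R"])) +
    counts["H"] / (1 + 10^(pH - pka_set["H"]))
  neg <- 1 / (1 + 10^(pka_set["Cterm"] - pH)) +
    counts["D"] / (1 + 10^(pka_set["D"] - pH)) +
    counts["E"] / (1 + 10^(pka_set["E"] - pH)) +
    counts["C"] / (1 + 10^(pka_set["C"] - pH)) +
    counts["Y"] / (1 + 10^(pka_set["Y"] - pH))
  unname(pos - neg)
}

isoelectric_point <- function(counts) {
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (net_charge_at_ph(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# --- patterning -------------------------------------------------------------

# Blockiness of one group pair at window size g from per-window group counts.
# For distinct groups x, y the window statistic is (fx - fy)^2 / (fx + fy)
# (0 where both are absent); for a self pair it is fx, so the blockiness
# reduces to the windowed compositional variance of that group. Blockiness
# is the mean squared deviation of the window statistic from its whole-
# sequence value.
pair_blockiness <- function(win_frac, global_frac, gi, gj) {
  if (gi == gj) {
    sw <- win_frac[, gi]
    s0 <- global_frac[gi]
  } else {
    fx <- win_frac[, gi]; fy <- win_frac[, gj]
    den <- fx + fy
    sw <- ifelse(den > 0, (fx - fy)^2 / den, 0)
    d0 <- global_frac[gi] + global_frac[gj]
    s0 <- if (d0 > 0) (global_frac[gi] - global_frac[gj])^2 / d0 else 0
  }
  mean((sw - s0)^2)
}

# Per-window group fractions for all groups at window size g, from a vector
# of group ids (one per residue).
window_fractions <- function(gid, n_groups, g) {
  L <- length(gid)
  nw <- L - g + 1L
  out <- matrix(0, nw, n_groups)
  for (k in seq_len(n_groups)) {
    cs <- cumsum(c(0L, gid == k))
    out[, k] <- (cs[(g + 1L):(L + 1L)] - cs[1L:nw]) / g
  }
  out
}

all_pair_blockiness <- function(gid, n_groups, g, global_frac, pairs) {
  wf <- window_fractions(gid, n_groups, g)
  vapply(seq_len(nrow(pairs)), function(p)
    pair_blockiness(wf, global_frac, pairs[p, 1], pairs[p, 2]), numeric(1))
}

#' Patterning z-scores against composition-preserving scrambles
#'
#' For each unordered pair of residue groups (including self pairs; 36 in
#' all for the default eight groups) a nonnegative blockiness statistic is
#' computed at each window size and z-scored against `n_scrambles` scrambles
#' of the sequence; the per-window-size z-scores are averaged. Negative
#' z-scores mean the sequence is more well-mixed with respect to the group
#' pair than its scrambles, positive z-scores mean blockier. Pairs involving
#' a group absent from the sequence (whose patterning scrambling cannot
#' change) are reported as 0.
#'
#' @param sequence amino-acid string.
#' @param cfg a [patterning_config()].
#' @param seed integer seed for the scrambles.
#' @return Named numeric vector of 36 z-scores (`pol-pol`, `pol-hyd`, ...).
#' @export
patterning_zscores <- function(sequence, cfg = patterning_config(), seed = 1L) {
  aa <- validate_sequence(sequence)
  L <- length(aa)
  if (L < max(cfg$window_sizes))
    stop("sequence shorter than the largest window size")
  groups <- cfg$residue_groups
  ng <- length(groups)
  gid <- integer(L)
  for (k in seq_len(ng)) gid[aa %in% groups[[k]]] <- k
  pairs <- cbind(rep(seq_len(ng), times = ng), rep(seq_len(ng), each = ng))
  pairs <- pairs[pairs[, 1] <= pairs[, 2], , drop = FALSE]
  pair_names <- paste(names(groups)[pairs[, 1]], names(groups)[pairs[, 2]],
                      sep = "-")
  global_frac <- vapply(seq_len(ng), function(k) mean(gid == k), numeric(1))
  present <- global_frac > 0
  pair_ok <- present[pairs[, 1]] & present[pairs[, 2]]

  with_seed(seed, {
    z_by_g <- matrix(0, nrow(pairs), length(cfg$window_sizes))
    scrambles <- replicate(cfg$n_scrambles, sample(gid), simplify = FALSE)
    for (wi in seq_along(cfg$window_sizes)) {
      g <- cfg$window_sizes[wi]
      obs <- all_pair_blockiness(gid, ng, g, global_frac, pairs)
      null <- vapply(scrambles, all_pair_blockiness, numeric(nrow(pairs)),
                     n_groups = ng, g = g, global_frac = global_frac,
                     pairs = pairs)
      null <- matrix(null, nrow = nrow(pairs))
      mu <- rowMeans(null)
      sd0 <- apply(null, 1, stats::sd)
      z <- ifelse(sd0 > 0, (obs - mu) / sd0, 0)
      z[!pair_ok] <- 0
      z_by_g[, wi] <- z
    }
    stats::setNames(rowMeans(z_by_g), pair_names)
  })
}

# --- patches ----------------------------------------------------------------

#' Locate residue or RG patches
#'
#' Finds maximal patches: regions containing at least `min_occurrences` of
#' the target residue (or `min_occurrences_rg` occurrences of the RG
#' dipeptide) in which consecutive occurrences are separated by at most
#' `max_interruptions` non-target positions. Patches start and end on target
#' positions.
#'
#' @param sequence amino-acid string.
#' @param target a single residue letter, or `"RG"` for the dipeptide.
#' @param cfg a [patch_config()].
#' @return List with `intervals` (two-column matrix of residue start/end)
#'   and `coverage` (total patch residues / sequence length).
#' @export
find_patches <- function(sequence, target, cfg = patch_config()) {
  aa <- validate_sequence(sequence)
  L <- length(aa)
  if (identical(target, "RG")) {
    starts <- which(aa[-L] == "R" & aa[-1L] == "G")
    ends <- starts + 1L
    min_occ <- cfg$min_occurrences_rg
  } else {
    stopifnot(is.character(target), nchar(target) == 1L, target %in% AA20)
    starts <- which(aa == target)
    ends <- starts
    min_occ <- cfg$min_occurrences
  }
  if (length(starts) == 0L)
    return(list(intervals = empty_intervals(), coverage = 0))
  gaps <- if (length(starts) > 1L) starts[-1L] - ends[-length(ends)] - 1L
    else integer(0)
  chain <- cumsum(c(0L, gaps > cfg$max_interruptions))
  iv <- do.call(rbind, lapply(split(seq_along(starts), chain), function(ix) {
    if (length(ix) < min_occ) return(NULL)
    cbind(start = starts[ix[1L]], end = ends[ix[length(ix)]])
  }))
  if (is.null(iv)) iv <- empty_intervals()
  list(intervals = iv,
       coverage = blob_total(iv) / L)
}

# --- composition ------------------------------------------------------------

#' Composition feature panel
#'
#' Computes the composition half of the grammar engine: 20 amino-acid
#' fractions; 9 residue-set fractions (positive, negative, polar, aliphatic,
#' aromatic, charged, chain-expanding, disorder-promoting, R+Y); the R/K and
#' E/D ratios; net charge per residue, mean scaled Kyte-Doolittle
#' hydrophobicity, isoelectric point, polyproline-II propensity, and the
#' count of R+Y residues; plus one patch-coverage fraction per retained
#' patch target. With the default 19 retained patch targets (no M or W
#' patches) the panel has exactly 55 features.
#'
#' A ratio with a zero denominator is reported as the numerator count (kept
#' finite so downstream z-scoring works); which ratios were substituted is
#' recorded in the `sentinel` attribute.
#'
#' @param sequence amino-acid string.
#' @param patch_cfg a [patch_config()].
#' @param retained_patches character vector of patch targets to report
#'   (default [default_retained_patches()]).
#' @return Named numeric vector with attribute `sentinel` (named logical for
#'   the two ratio features).
#' @export
composition_features <- function(sequence, patch_cfg = patch_config(),
                                 retained_patches = default_retained_patches()) {
  aa <- validate_sequence(sequence)
  L <- length(aa)
  counts <- stats::setNames(vapply(AA20, function(a) sum(aa == a), numeric(1)),
                            AA20)
  frac <- counts / L

  set_frac <- vapply(composition_sets, function(s) sum(frac[s]), numeric(1))
  names(set_frac) <- paste0("frac_", names(composition_sets))

  sentinel <- c(ratio_RK = FALSE, ratio_ED = FALSE)
  ratio_RK <- if (counts["K"] > 0) counts["R"] / counts["K"] else {
    sentinel["ratio_RK"] <- TRUE; counts["R"]
  }
  ratio_ED <- if (counts["D"] > 0) counts["E"] / counts["D"] else {
    sentinel["ratio_ED"] <- TRUE; counts["E"]
  }

  scalars <- c(
    ncpr = unname((counts["R"] + counts["K"] - counts["D"] - counts["E"]) / L),
    mean_hydrophobicity = mean(kd_scaled[aa]),
    isoelectric_point = isoelectric_point(counts),
    ppii_propensity = mean(ppii_scale[aa]),
    count_RY = unname(counts["R"] + counts["Y"]))

  patch <- vapply(retained_patches, function(tg)
    find_patches(sequence, tg, patch_cfg)$coverage, numeric(1))
  names(patch) <- paste0("patch_", retained_patches)

  out <- c(stats::setNames(frac, paste0("frac_", AA20)),
           set_frac,
           ratio_RK = unname(ratio_RK), ratio_ED = unname(ratio_ED),
           scalars, patch)
  attr(out, "sentinel") <- sentinel
  out
}

#' Full sequence-grammar feature matrix
#'
#' Stacks the 36 patterning z-scores and the 55 composition features into a
#' 91-feature row per protein.
#'
#' @param sequences named character vector of sequences.
#' @param pattern_cfg a [patterning_config()].
#' @param patch_cfg a [patch_config()].
#' @param retained_patches patch targets to report.
#' @param seed integer seed (scramble seeds derive per protein).
#' @return Numeric matrix, proteins x 91 features.
#' @export
grammar_feature_matrix <- function(sequences, pattern_cfg = patterning_config(),
                                   patch_cfg = patch_config(),
                                   retained_patches = default_retained_patches(),
                                   seed = 1L) {
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            !is.null(names(sequences)))
  rows <- lapply(seq_along(sequences), function(i) {
    c(patterning_zscores(sequences[[i]], pattern_cfg,
                         seed = derive_seed(seed, names(sequences)[i])),
      composition_features(sequences[[i]], patch_cfg, retained_patches))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(sequences)
  out
}

# --- z-scoring and enrichment ----------------------------------------------

#' Z-score features against a reference protein set
#'
#' Each feature is centred and scaled by the mean and standard deviation of
#' the reference rows. Features with zero variance across the reference are
#' dropped (recorded in attribute `dropped_features`) rather than returned
#' as NaN.
#'
#' @param features proteins x features numeric matrix.
#' @param reference_ids row names forming the reference set (default: all
#'   rows).
#' @return Z-score matrix over all input proteins.
#' @export
reference_zscores <- function(features, reference_ids = rownames(features)) {
  stopifnot(is.matrix(features), !is.null(rownames(features)),
            length(reference_ids) >= 2L,
            all(reference_ids %in% rownames(features)))
  ref <- features[reference_ids, , drop = FALSE]
  mu <- colMeans(ref)
  sd0 <- apply(ref, 2, stats::sd)
  keep <- sd0 > 0
  z <- sweep(sweep(features[, keep, drop = FALSE], 2, mu[keep]),
             2, sd0[keep], "/")
  attr(z, "dropped_features") <- colnames(features)[!keep]
  z
}

#' Abundance z-scores over the mapped protein set
#'
#' Each protein's mean abundance (over all groups and replicates) is
#' z-scored against the distribution of mean abundances across all proteins
#' in the table.
#'
#' @param abundance proteins x samples matrix with row names.
#' @param proteins protein ids to return (default all).
#' @return Named numeric vector of z-scores.
#' @export
abundance_zscore <- function(abundance, proteins = rownames(abundance)) {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)))
  missing_p <- setdiff(proteins, rownames(abundance))
  if (length(missing_p))
    stop("protein(s) not in abundance table: ",
         paste(utils::head(missing_p, 3), collapse = ", "))
  means <- rowMeans(abundance)
  sd0 <- stats::sd(means)
  z <- if (is.na(sd0) || sd0 == 0) stats::setNames(rep(0, length(means)),
                                                   names(means))
    else (means - mean(means)) / sd0
  z[proteins]
}

#' Kolmogorov-Smirnov feature enrichment between protein sets
#'
#' For every feature (column) the z-score distribution of the enriched set
#' is compared to the background set by a two-sample KS test. Features with
#' p below `alpha` get a signed log10 p-value: positive when the enriched
#' set's median exceeds the background median, negative otherwise.
#'
#' @param set_z z-score matrix of the enriched set.
#' @param background_z z-score matrix of the background set (same columns,
#'   disjoint proteins).
#' @param alpha significance threshold (default 0.05).
#' @return Data frame with `feature`, `p_value`, `significant`,
#'   `signed_log_p` (`NA` where not significant).
#' @export
ks_feature_enrichment <- function(set_z, background_z, alpha = 0.05) {
  stopifnot(is.matrix(set_z), is.matrix(background_z),
            identical(colnames(set_z), colnames(background_z)),
            nrow(set_z) >= 1L, nrow(background_z) >= 1L)
  if (length(intersect(rownames(set_z), rownames(background_z))))
    stop("enriched set and background must be disjoint")
  if (nrow(set_z) == 1L)
    warning("enriched set has a single protein: the KS test has low power")
  res <- lapply(colnames(set_z), function(f) {
    p <- suppressWarnings(
      stats::ks.test(set_z[, f], background_z[, f])$p.value)
    sig <- is.finite(p) && p < alpha
    # |log10 p| carries the sign of the median comparison
    s <- if (stats::median(set_z[, f]) > stats::median(background_z[, f])) 1 else -1
    data.frame(feature = f, p_value = p, significant = sig,
               signed_log_p = if (sig) s * abs(log10(p)) else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
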