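#' Synthetic optoDroplet pixel tables
#'
#' Emulates segmented per-cell confocal pixel intensities before and after
#' light activation. Each cell draws a total intensity uniformly from
#' `total_intensity_range`. Before activation, pixels carry lognormal
#' multiplicative noise around that total (micrograph intensities are positive
#' and right-skewed; `noise_cv` is the coefficient of variation on the natural
#' scale). After activation: below `csat_true` the cell stays in the
#' one-to-one regime and pixels are redrawn from the same distribution; above
#' it, pixels are a two-component mixture with dilute component centred at
#' `csat_true` and dense component centred at `dense_fold * total`. The dense
#' mixing fraction is not a free parameter: it solves intensity conservation,
#' `(1 - f) csat + f dense_fold total = total`, so the planted `csat_true` is
#' the single ground-truth knob. All pixels are clipped at `max_intensity`.
#'
#' On top of the pixel noise, every cell carries a multiplicative
#' acquisition-gain factor (lognormal, coefficient of variation
#' `cell_gain_cv`) applied identically to both channels: fluorescence is an
#' arbitrary-unit proxy for concentration, and optical path, focal plane and
#' illumination vary cell to cell. This leaves within-cell intensity
#' conservation and the mixture centring (in concentration units) intact but
#' gives the measured dilute plateau the cell-level scatter real data shows.
#' Set `cell_gain_cv = 0` for fully idealised tables.
#'
#' @param n_cells number of cells.
#' @param csat_true planted saturation concentration, a.u.
#' @param total_intensity_range length-2 range for per-cell totals, a.u.
#' @param dense_fold dense-phase mean as a multiple of the cell total (> 1).
#' @param pixel_count_per_cell pixels per cell.
#' @param noise_cv lognormal pixel-noise coefficient of variation, in
#'   (0, 1); 0 allowed for exact noiseless tables.
#' @param cell_gain_cv coefficient of variation of the per-cell acquisition
#'   gain (default 0.05).
#' @param max_intensity detector saturation value, a.u.
#' @param seed integer seed.
#' @return A data frame with columns `cell_id`, `pixel_id`,
#'   `intensity_before`, `intensity_after` and attribute `ground_truth`
#'   (planted c_sat, per-cell totals and dense fractions).
#' @export
gen_optodroplet_cells <- function(n_cells = 200L, csat_true = 1000,
                                  total_intensity_range = c(200, 3000),
                                  dense_fold = 5, pixel_count_per_cell = 400L,
                                  noise_cv = 0.05, cell_gain_cv = 0.05,
                                  max_intensity = 65535, seed = 1L) {
  stopifnot(n_cells >= 1L, pixel_count_per_cell >= 1L, csat_true > 0,
            dense_fold > 1, noise_cv >= 0, noise_cv < 1,
            cell_gain_cv >= 0, cell_gain_cv < 1,
            length(total_intensity_range) == 2L,
            total_intensity_range[1] > 0,
            diff(total_intensity_range) >= 0, max_intensity > 0)
  npx <- as.integer(pixel_count_per_cell)
  with_seed(seed, {
    totals <- stats::runif(n_cells, total_intensity_range[1], total_intensity_range[2])
    dense_frac <- ifelse(
      totals > csat_true,
      (totals - csat_true) / (dense_fold * totals - csat_true),
      0)
    # Median-centred multiplicative noise: the stated centre is the
    # distribution's median, so planted intensities sit where the histogram
    # is centred (what downstream Gaussian histogram fits estimate). Both
    # channels share the same parameterisation, so within-cell intensity
    # conservation is unaffected.
    lognoise <- function(n, cv) {
      if (cv == 0) return(rep(1, n))
      exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
    }
    gain <- lognoise(n_cells, cell_gain_cv)
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      before <- totals[i] * lognoise(npx, noise_cv)
      if (dense_frac[i] == 0) {
        after <- totals[i] * lognoise(npx, noise_cv)
      } else {
        dense <- stats::runif(npx) < dense_frac[i]
        centre <- ifelse(dense, dense_fold * totals[i], csat_true)
        after <- centre * lognoise(npx, noise_cv)
      }
      rows[[i]] <- data.frame(
        cell_id = sprintf("cell_%03d", i),
        pixel_id = seq_len(npx),
        intensity_before = pmin(gain[i] * before, max_intensity),
        intensity_after = pmin(gain[i] * after, max_intensity))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "ground_truth") <- list(
      csat_true = csat_true, totals = totals, dense_fraction = dense_frac,
      dense_fold = dense_fold, cell_gain = gain,
      max_intensity = max_intensity)
    out
  })
}

# Deterministic 100-residue base sequence used when generating variant
# sequences: a mixed hydrophobic/hydrophilic globular-like composition.
base_variant_sequence <- function() {
  paste0("MKTAYIAKQRLDSEVLKQHFNAGELITVFGDAIELSPYAVQWLKNELGVTS",
         "GKIDRLIFQTNSEAWKHYGMPLVEDFITRAVSQGNKELIDYWSTKAGFQR")
}

#' Synthetic variant table from the c*/p_U law
#'
#' Generates a table of folding variants whose measured saturation
#' concentrations obey `c_sat = c* / p_U(dG + shift) * (1 + eps)` with
#' mean-zero Gaussian relative noise of coefficient `noise_cv`. With
#' `noise_cv = 0` the identity `c_sat * p_U(dG + shift) = c*` holds to
#' machine precision, which the fitting stage must recover exactly. Each
#' variant also carries a sequence (point mutations of a fixed base
#' sequence) so the blob-weighted bootstrap has material to work on.
#'
#' @param dG_list ΔG°U values, kJ/mol.
#' @param c_star_true planted critical unfolded concentration, a.u.
#' @param dG_shift_true planted stability offset, kJ/mol.
#' @param noise_cv relative noise on c_sat.
#' @param n_mutations point mutations per variant sequence.
#' @param cfg a [thermo_config()].
#' @param seed integer seed.
#' @return Data frame with columns `name`, `sequence`, `dG_U`,
#'   `csat_measured`, `p_U_true`; attribute `ground_truth`.
#' @export
gen_variant_table <- function(dG_list = seq(-4, 18, length.out = 12),
                              c_star_true = 10.83, dG_shift_true = -12.9,
                              noise_cv = 0, n_mutations = 3L,
                              cfg = thermo_config(), seed = 1L) {
  stopifnot(c_star_true > 0, noise_cv >= 0, length(dG_list) >= 1L)
  base <- validate_sequence(base_variant_sequence())
  with_seed(seed, {
    n <- length(dG_list)
    p_U <- fraction_unfolded(dG_list, cfg, dG_shift_true)
    eps <- if (noise_cv == 0) rep(0, n) else stats::rnorm(n, 0, noise_cv)
    csat <- c_star_true / p_U * (1 + eps)
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- base
      pos <- sample.int(length(s), n_mutations)
      s[pos] <- sample(AA20, n_mutations, replace = TRUE)
      seqs[i] <- paste(s, collapse = "")
    }
    out <- data.frame(
      name = sprintf("variant_%02d", seq_len(n)),
      sequence = seqs, dG_U = dG_list,
      csat_measured = csat, p_U_true = p_U)
    attr(out, "ground_truth") <- list(
      c_star_true = c_star_true, dG_shift_true = dG_shift_true,
      noise_cv = noise_cv)
    out
  })
}

#' Synthetic unfolded-state conformational ensemble
#'
#' Target ensembles are bead-per-residue semiflexible chains with
#' hard-sphere excluded volume, sampled by a Metropolis pivot sampler.
#' Local stiffness (successive bond vectors confined to a forward
#' hemisphere, `min_bond_cos`) emulates the short-range geometry a real
#' polypeptide backbone imposes. Planted sticker residues attract each
#' other through a square well of range equal to the 5 Å contact cutoff
#' and depth `attraction_strength` (kT); excluded volume keeps spacers from
#' condensing into the sticker cluster, so sticker contact enrichment stays
#' localised.
#'
#' With `reference = TRUE` the ensemble emulates a Flory random coil: a
#' chain whose chain-chain and chain-solvent interactions are
#' counterbalanced, i.e. ideal-chain statistics with the same local
#' stiffness but no nonlocal interactions, sampled directly as independent
#' walks. An ideal chain is more contact-rich than a self-avoiding one, so
#' the reference maximum is a conservative sticker threshold: attraction-
#' free targets fall well below it, and only strongly bound stickers
#' exceed it.
#'
#' @param sequence amino-acid string (length >= 5).
#' @param sticker_positions integer vector of 1-based sticker residue indices.
#' @param attraction_strength square-well depth in kT (>= 0).
#' @param n_conformations conformations to record.
#' @param bond_length bond length in Angstrom.
#' @param reference logical; if `TRUE`, sample an ideal (Flory-random-coil
#'   style) chain with no nonlocal interactions, labelled `"reference"`.
#' @param contact_range square-well / contact range in Angstrom.
#' @param hs_diameter hard-sphere diameter for non-bonded pairs of the
#'   target chain, Angstrom (ignored for the reference).
#' @param min_bond_cos lower bound on the cosine between successive bond
#'   vectors (local stiffness; default 0, a forward hemisphere).
#' @param moves_per_frame pivot moves between recorded conformations.
#' @param burnin_frames frames discarded before recording starts.
#' @param seed integer seed.
#' @return An object of class `conform_ensemble`: list with `sequence`,
#'   `conformations` (list of n x 3 coordinate matrices, Angstrom), `label`,
#'   `sticker_positions` and the sampler's acceptance rate.
#' @export
gen_ensemble <- function(sequence, sticker_positions = integer(0),
                         attraction_strength = 0, n_conformations = 200L,
                         bond_length = 3.8, reference = FALSE,
                         contact_range = 5, hs_diameter = 3.5,
                         min_bond_cos = 0, moves_per_frame = NULL,
                         burnin_frames = 25L, seed = 1L) {
  aa <- validate_sequence(sequence)
  n <- length(aa)
  stopifnot(n >= 5L, n_conformations >= 1L, attraction_strength >= 0,
            bond_length > 0)
  sticker_positions <- as.integer(sticker_positions)
  if (any(sticker_positions < 1L | sticker_positions > n))
    stop("sticker_positions outside the sequence")
  eps <- if (reference) 0 else attraction_strength
  if (is.null(moves_per_frame)) moves_per_frame <- 2L * n

  # semiflexible ideal walk: successive bond vectors are constrained to a
  # forward hemisphere (dot >= min_bond_cos), emulating the local chain
  # stiffness that dipeptide geometry imparts to a real unfolded chain and
  # keeping short-range contact probabilities realistic
  stiff_walk <- function() {
    u <- matrix(0, n - 1L, 3L)
    v <- stats::rnorm(3); u[1L, ] <- v / sqrt(sum(v^2))
    for (k in 2:(n - 1L)) {
      repeat {
        w <- stats::rnorm(3); w <- w / sqrt(sum(w^2))
        if (sum(w * u[k - 1L, ]) >= min_bond_cos) break
      }
      u[k, ] <- w
    }
    rbind(c(0, 0, 0), apply(u * bond_length, 2, cumsum))
  }

  if (reference) {
    # Flory random coil analogue: chain-chain and chain-solvent interactions
    # counterbalanced, so conformations are independent semiflexible ideal
    # walks with no attraction
    return(with_seed(seed, {
      confs <- replicate(n_conformations, stiff_walk(), simplify = FALSE)
      structure(list(
        sequence = paste(aa, collapse = ""),
        conformations = confs,
        label = "reference",
        sticker_positions = integer(0),
        acceptance_rate = NA_real_,
        bond_length = bond_length), class = "conform_ensemble")
    }))
  }

  is_sticker <- rep(FALSE, n); is_sticker[sticker_positions] <- TRUE
  stick_idx <- which(is_sticker)

  # cross-pair squared distances between two coordinate blocks
  cross_d2 <- function(a, b) {
    outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  }
  # sticker-sticker energy restricted to pairs (i in head, j in tail);
  # a pivot move changes only head-tail cross pairs, so the energy delta
  # needs nothing else
  cross_energy <- function(xyz, head, tail) {
    if (eps == 0) return(0)
    si <- stick_idx[stick_idx %in% head]
    sj <- stick_idx[stick_idx %in% tail]
    if (length(si) == 0L || length(sj) == 0L) return(0)
    d2 <- cross_d2(xyz[si, , drop = FALSE], xyz[sj, , drop = FALSE])
    sep <- abs(outer(si, sj, "-"))
    -eps * sum(d2 <= contact_range^2 & sep > 2L)
  }
  cross_clash <- function(xyz, head, tail) {
    if (hs_diameter <= 0) return(FALSE)
    d2 <- cross_d2(xyz[head, , drop = FALSE], xyz[tail, , drop = FALSE])
    sep <- abs(outer(head, tail, "-"))
    any(d2 < hs_diameter^2 & sep >= 2L)
  }
  rand_rotation <- function() {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, -pi, pi)
    c_ <- cos(th); s_ <- sin(th); C <- 1 - c_
    x <- ax[1]; y <- ax[2]; z <- ax[3]
    matrix(c(x*x*C + c_,  x*y*C - z*s_, x*z*C + y*s_,
             y*x*C + z*s_, y*y*C + c_,  y*z*C - x*s_,
             z*x*C - y*s_, z*y*C + x*s_, z*z*C + c_), 3, 3, byrow = TRUE)
  }
  full_clash <- function(xyz) {
    if (hs_diameter <= 0) return(FALSE)
    d <- as.matrix(stats::dist(xyz))
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))
    any(d[sep >= 2L] < hs_diameter)
  }
  grow_chain <- function() {
    repeat {
      xyz <- stiff_walk()
      if (!full_clash(xyz)) return(xyz)
    }
  }

  with_seed(seed, {
    xyz <- grow_chain()
    confs <- vector("list", n_conformations)
    n_acc <- 0L; n_try <- 0L
    total_frames <- burnin_frames + n_conformations
    for (fr in seq_len(total_frames)) {
      for (mv in seq_len(moves_per_frame)) {
        n_try <- n_try + 1L
        p <- sample(2:(n - 1L), 1L)
        Rm <- rand_rotation()
        head_idx <- 1L:p
        tail_idx <- (p + 1L):n
        new_tail <- sweep(
          sweep(xyz[tail_idx, , drop = FALSE], 2, xyz[p, ]) %*% t(Rm),
          2, xyz[p, ], "+")
        cand <- xyz; cand[tail_idx, ] <- new_tail
        # stiffness: the pivot only alters the bond angle at the joint
        u_prev <- (cand[p, ] - cand[p - 1L, ]) / bond_length
        u_new <- (cand[p + 1L, ] - cand[p, ]) / bond_length
        if (sum(u_prev * u_new) < min_bond_cos) next
        # a pivot changes only head-tail cross pairs: clash and energy
        # delta are evaluated on those alone
        if (cross_clash(cand, head_idx, tail_idx)) next
        dE <- cross_energy(cand, head_idx, tail_idx) -
          cross_energy(xyz, head_idx, tail_idx)
        if (dE <= 0 || stats::runif(1) < exp(-dE)) {
          xyz <- cand; n_acc <- n_acc + 1L
        }
      }
      if (fr > burnin_frames) confs[[fr - burnin_frames]] <- xyz
    }
    acc <- n_acc / n_try
    if (acc < 0.05)
      warning(sprintf(
        "pivot acceptance rate %.3f: attraction may be too strong for the sampler to decorrelate (n = %d, strength = %.2f kT)",
        acc, n, eps))
    structure(list(
      sequence = paste(aa, collapse = ""),
      conformations = confs,
      label = if (reference || eps == 0) "reference" else "target",
      sticker_positions = sticker_positions,
      acceptance_rate = acc,
      bond_length = bond_length), class = "conform_ensemble")
  })
}

#' @export
print.conform_ensemble <- function(x, ...) {
  cat(sprintf("conform_ensemble: %d residues, %d conformations, label '%s'\n",
              nchar(x$sequence), length(x$conformations), x$label))
  invisible(x)
}

# Background amino-acid frequencies (approximately Swiss-Prot averages),
# ordered to match AA20.
background_aa_freq <- c(
  A = 0.083, R = 0.055, N = 0.041, D = 0.055, C = 0.014, Q = 0.039,
  E = 0.067, G = 0.071, H = 0.023, I = 0.059, K = 0.058, L = 0.097,
  M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.054, V = 0.069,
  W = 0.011, Y = 0.029)[AA20]

#' Synthetic proteome with planted compositional and abundance biases
#'
#' Background sequences are drawn from fixed proteome-average residue
#' frequencies. Proteins listed in `planted_enriched` for a group have (a)
#' their composition shifted by `planted_bias` (absolute additions to residue
#' frequencies, other residues renormalised) and (b) their abundance
#' multiplied by `fold_change` in that group across replicates. Unless
#' `allow_MW_patches = TRUE`, generated sequences are scrubbed of Met and Trp
#' patches so the study's patch-retention condition (19 retained patch
#' features) holds on synthetic data.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer range of sequence lengths.
#' @param groups character vector of group labels (>= 2).
#' @param planted_enriched named list: group label -> integer protein indices.
#' @param planted_bias named numeric vector: residue -> absolute frequency
#'   addition (e.g. `c(R = 0.10)`).
#' @param n_replicates replicates per group (>= 2).
#' @param fold_change abundance fold change for planted proteins.
#' @param abundance_cv lognormal replicate noise on abundances.
#' @param allow_MW_patches keep Met/Trp patches if they arise.
#' @param seed integer seed.
#' @return List with `sequences` (named character vector), `abundance`
#'   (proteins x samples matrix), `groups` and `replicate` (per column),
#'   and `truth`.
#' @export
gen_proteome_and_abundance <- function(n_proteins = 120L,
                                       length_range = c(80L, 200L),
                                       groups = c("grpA", "grpB", "grpC"),
                                       planted_enriched = list(),
                                       planted_bias = numeric(0),
                                       n_replicates = 4L, fold_change = 4,
                                       abundance_cv = 0.1,
                                       allow_MW_patches = FALSE, seed = 1L) {
  stopifnot(n_proteins >= 2L, length(groups) >= 2L, n_replicates >= 2L,
            all(names(planted_enriched) %in% groups))
  if (length(planted_bias) > 0L) {
    stopifnot(!is.null(names(planted_bias)), all(names(planted_bias) %in% AA20))
    if (any(background_aa_freq[names(planted_bias)] + planted_bias > 1) ||
        sum(pmax(planted_bias, 0)) >= 1)
      stop("infeasible planted_bias: residue fractions would exceed 1")
  }
  planted_idx <- sort(unique(unlist(planted_enriched)))
  if (length(planted_idx) && any(planted_idx < 1L | planted_idx > n_proteins))
    stop("planted_enriched indices outside 1..n_proteins")
  if (length(planted_enriched) > 1L &&
      anyDuplicated(unlist(planted_enriched)) > 0L)
    stop("planted_enriched sets must be disjoint across groups")

  biased_freq <- background_aa_freq
  if (length(planted_bias) > 0L) {
    biased_freq[names(planted_bias)] <- biased_freq[names(planted_bias)] + planted_bias
    others <- setdiff(AA20, names(planted_bias))
    biased_freq[others] <- biased_freq[others] *
      (1 - sum(biased_freq[names(planted_bias)])) / sum(biased_freq[others])
  }

  scrub_mw <- function(aa) {
    for (res in c("M", "W")) {
      repeat {
        p <- find_patches(paste(aa, collapse = ""), res)
        if (nrow(p$intervals) == 0L) break
        pos <- which(aa[p$intervals[1, "start"]:p$intervals[1, "end"]] == res) +
          p$intervals[1, "start"] - 1L
        aa[pos[2L]] <- "L"   # break the patch at its second occurrence
      }
    }
    aa
  }

  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
    seqs <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      fr <- if (i %in% planted_idx) biased_freq else background_aa_freq
      aa <- sample(AA20, lens[i], replace = TRUE, prob = fr[AA20])
      if (!allow_MW_patches) aa <- scrub_mw(aa)
      seqs[i] <- paste(aa, collapse = "")
    }
    names(seqs) <- sprintf("prot_%04d", seq_len(n_proteins))

    n_samples <- length(groups) * n_replicates
    sample_group <- rep(groups, each = n_replicates)
    sample_rep <- rep(seq_len(n_replicates), times = length(groups))
    base_ab <- stats::rlnorm(n_proteins, meanlog = log(1e4), sdlog = 1)
    sdl <- sqrt(log(1 + abundance_cv^2))
    ab <- matrix(0, n_proteins, n_samples,
                 dimnames = list(names(seqs),
                                 paste0(sample_group, "_r", sample_rep)))
    for (j in seq_len(n_samples)) {
      mult <- rep(1, n_proteins)
      g <- sample_group[j]
      if (!is.null(planted_enriched[[g]]))
        mult[planted_enriched[[g]]] <- fold_change
      ab[, j] <- base_ab * mult * exp(stats::rnorm(n_proteins, -sdl^2 / 2, sdl))
    }
    list(sequences = seqs, abundance = ab,
         groups = sample_group, replicate = sample_rep,
         truth = list(planted_enriched = planted_enriched,
                      planted_bias = planted_bias,
                      fold_change = fold_change,
                      biased_freq = biased_freq))
  })
}
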