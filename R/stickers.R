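# Six residue categories used for sticker typing. Note this grouping is
# specific to the contact analysis; the grammar module uses different,
# independently configurable sets.
sticker_groups <- list(
  aliphatic = c("A", "I", "L", "M", "V"),
  aromatic  = c("F", "W", "Y"),
  unique    = c("C", "P"),
  acidic    = c("D", "E"),
  basic     = c("H", "K", "R"),
  polar     = c("G", "N", "Q", "S", "T"))

#' Pool replicate ensembles
#'
#' Combines independent replicate ensembles of the same sequence into one,
#' weighting every conformation equally (replicas need not have equal
#' conformation counts). Sampling by short Monte Carlo runs can linger in
#' one contact topology; pooling independent replicas restores coverage,
#' mirroring the practice of averaging several independent simulations.
#'
#' @param ensembles list of `conform_ensemble` objects with identical
#'   sequences.
#' @return A single `conform_ensemble`.
#' @export
pool_ensembles <- function(ensembles) {
  stopifnot(length(ensembles) >= 1L,
            all(vapply(ensembles, inherits, logical(1), "conform_ensemble")))
  seqs <- vapply(ensembles, `[[`, character(1), "sequence")
  if (length(unique(seqs)) != 1L)
    stop("cannot pool ensembles with different sequences")
  structure(list(
    sequence = seqs[[1L]],
    conformations = do.call(c, lapply(ensembles, `[[`, "conformations")),
    label = ensembles[[1L]]$label,
    sticker_positions = ensembles[[1L]]$sticker_positions,
    acceptance_rate = mean(vapply(ensembles, function(e)
      if (is.null(e$acceptance_rate)) NA_real_ else e$acceptance_rate,
      numeric(1))),
    bond_length = ensembles[[1L]]$bond_length), class = "conform_ensemble")
}

#' Binary residue contact matrix of a single conformation
#'
#' Entry (i, j) is 1 when residues i and j are separated by more than
#' `exclude_neighbors` positions in sequence and their representative points
#' lie within `cutoff` Angstrom. The diagonal is 0 and the matrix symmetric.
#'
#' @param conformation n x 3 coordinate matrix (one point per residue, A).
#' @param cutoff contact distance cutoff in Angstrom (default 5).
#' @param exclude_neighbors nearest sequence neighbours excluded on each side
#'   (default 2: first and second neighbours never count as contacts).
#' @return n x n binary integer matrix.
#' @export
contact_matrix <- function(conformation, cutoff = 5, exclude_neighbors = 2L) {
  stopifnot(is.matrix(conformation), ncol(conformation) == 3L,
            nrow(conformation) >= 5L, all(is.finite(conformation)))
  n <- nrow(conformation)
  d <- as.matrix(stats::dist(conformation))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  out <- (d <= cutoff & sep > exclude_neighbors) * 1L
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Per-residue mean contact probability of an ensemble
#'
#' For each residue, the contact indicator with every eligible partner
#' (sequence separation beyond `exclude_neighbors`) is averaged jointly over
#' partners and conformations. The result is invariant to rigid-body motion
#' of any conformation.
#'
#' @param ensemble a `conform_ensemble` (see [gen_ensemble()],
#'   [read_ensemble()]).
#' @param cutoff,exclude_neighbors as in [contact_matrix()].
#' @return Numeric vector in `[0, 1]`, one value per residue.
#' @export
mean_contact_probability <- function(ensemble, cutoff = 5,
                                     exclude_neighbors = 2L) {
  stopifnot(inherits(ensemble, "conform_ensemble"),
            length(ensemble$conformations) >= 1L)
  n <- nchar(ensemble$sequence)
  n_eligible <- vapply(seq_len(n), function(i)
    sum(abs(seq_len(n) - i) > exclude_neighbors), numeric(1))
  acc <- numeric(n)
  for (xyz in ensemble$conformations)
    acc <- acc + rowSums(contact_matrix(xyz, cutoff, exclude_neighbors))
  acc / (n_eligible * length(ensemble$conformations))
}

#' Contact profile with sticker calls against a reference ensemble
#'
#' A residue is called a strong sticker when its mean contact probability in
#' the target ensemble exceeds the maximum mean contact probability observed
#' anywhere in the matched reference ensemble (the attraction-free / Flory
#' random coil null for the same sequence). The profile also reports, for
#' six residue categories, the fraction of total mean contact probability
#' carried by each category next to the fraction expected from residue
#' counts alone; categories whose observed fraction exceeds expectation are
#' candidate predominant stickers.
#'
#' @param target target `conform_ensemble`.
#' @param reference reference `conform_ensemble` for the same sequence. This
#'   is required: without a matched null there is no sticker threshold (use
#'   [gen_ensemble()] with `reference = TRUE` to build a synthetic one).
#' @param cutoff,exclude_neighbors as in [contact_matrix()].
#' @return An object of class `contact_profile`: `mcp`, `reference_max`,
#'   `sticker_flags`, `group_fractions`, `expected_fractions`,
#'   `predominant_stickers`, `sequence`.
#' @export
call_stickers <- function(target, reference, cutoff = 5,
                          exclude_neighbors = 2L) {
  if (missing(reference) || is.null(reference))
    stop("a reference ensemble is required for sticker calls; ",
         "generate one with gen_ensemble(..., reference = TRUE)")
  stopifnot(inherits(target, "conform_ensemble"),
            inherits(reference, "conform_ensemble"))
  if (target$sequence != reference$sequence)
    stop("target and reference ensembles have different sequences")
  mcp <- mean_contact_probability(target, cutoff, exclude_neighbors)
  ref_mcp <- mean_contact_probability(reference, cutoff, exclude_neighbors)
  ref_max <- max(ref_mcp)
  gf <- group_contact_fractions(mcp, target$sequence)
  structure(list(
    sequence = target$sequence,
    mcp = mcp,
    reference_max = ref_max,
    sticker_flags = mcp > ref_max,
    group_fractions = gf$group_fractions,
    expected_fractions = gf$expected_fractions,
    predominant_stickers = gf$predominant_stickers),
    class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("contact_profile: %d residues, %d stickers (reference max %.3f)\n",
              length(x$mcp), sum(x$sticker_flags), x$reference_max))
  if (length(x$predominant_stickers))
    cat("  predominant sticker categories:",
        paste(x$predominant_stickers, collapse = ", "), "\n")
  invisible(x)
}

#' Contact-probability fractions per residue category
#'
#' Splits the total mean contact probability across six residue categories
#' (aliphatic A/I/L/M/V, aromatic F/W/Y, unique C/P, acidic D/E, basic
#' H/K/R, polar G/N/Q/S/T) and compares each category's share to the share
#' expected from its residue count. Categories with an observed fraction
#' above expectation and above the uniform share are labelled predominant
#' stickers.
#'
#' @param mcp per-residue mean contact probabilities.
#' @param sequence the matching amino-acid sequence.
#' @return List with `group_fractions`, `expected_fractions` (both named,
#'   summing to 1) and `predominant_stickers`.
#' @export
group_contact_fractions <- function(mcp, sequence) {
  aa <- validate_sequence(sequence)
  stopifnot(length(mcp) == length(aa), all(mcp >= 0))
  total <- sum(mcp)
  if (total <= 0) stop("total mean contact probability is zero")
  grp <- vapply(sticker_groups, function(g) sum(mcp[aa %in% g]), numeric(1))
  expd <- vapply(sticker_groups, function(g) sum(aa %in% g), numeric(1)) /
    length(aa)
  obs <- grp / total
  predominant <- names(obs)[obs > expd & obs > 1 / length(sticker_groups)]
  list(group_fractions = obs, expected_fractions = expd,
       predominant_stickers = predominant)
}
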