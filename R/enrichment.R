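#' Abundance table constructor
#'
#' Bundles a proteins x samples abundance matrix with its sample group
#' labels and replicate indices.
#'
#' @param abundance numeric matrix (proteins x samples, row and column
#'   names set); missing values as `NA`, abundances otherwise `>= 0`.
#' @param groups character vector of group labels, one per column.
#' @param replicate integer replicate index per column (default: numbered
#'   within group).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(abundance, groups, replicate = NULL) {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)),
            length(groups) == ncol(abundance))
  if (any(abundance < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  tab <- table(groups)
  if (any(tab < 2L)) stop("every group needs at least 2 replicates")
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  structure(list(abundance = abundance, groups = as.character(groups),
                 replicate = as.integer(replicate)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d proteins x %d samples (%s)\n",
              nrow(x$abundance), ncol(x$abundance),
              paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

#' Total-abundance normalization
#'
#' Divides every sample column by its total abundance (missing values
#' ignored), so each column sums to one. Idempotent.
#'
#' @param tbl an [abundance_table()].
#' @return The normalized table.
#' @export
normalize_abundance <- function(tbl) {
  stopifnot(inherits(tbl, "abundance_table"))
  tot <- colSums(tbl$abundance, na.rm = TRUE)
  if (any(tot <= 0)) stop("a sample has zero total abundance")
  tbl$abundance <- sweep(tbl$abundance, 2, tot, "/")
  tbl
}

#' Normalize, presence-filter and mean-fill an abundance table
#'
#' Columns are divided by their totals; proteins failing the presence rule
#' are removed; proteins missing exactly one replicate within a group have
#' that value filled with the group mean of the observed replicates.
#'
#' Two presence rules are available. The default, `"reachable"`, retains
#' proteins detected in at least `n_replicates - 1` replicates of every
#' group, which is the reading under which the one-missing-replicate fill
#' rule is ever exercised. `"literal"` requires detection in every replicate
#' of every group (excluding proteins identified in three or fewer
#' replicates of any group when there are four), under which no missing
#' values survive to be filled.
#'
#' @param tbl an [abundance_table()].
#' @param presence_rule `"reachable"` (default) or `"literal"`.
#' @return Filtered, filled [abundance_table()] with attribute
#'   `removed_proteins`.
#' @export
normalize_and_filter <- function(tbl, presence_rule = c("reachable", "literal")) {
  presence_rule <- match.arg(presence_rule)
  tbl <- normalize_abundance(tbl)
  ab <- tbl$abundance
  gset <- unique(tbl$groups)
  detected <- is.finite(ab) & ab > 0
  ab[!detected] <- NA

  n_det <- sapply(gset, function(g)
    rowSums(detected[, tbl$groups == g, drop = FALSE]))
  n_rep <- vapply(gset, function(g) sum(tbl$groups == g), integer(1))
  min_required <- if (presence_rule == "reachable") n_rep - 1L else n_rep
  keep <- apply(n_det >= rep(min_required, each = nrow(ab)), 1, all)
  removed <- data.frame(
    protein = rownames(ab)[!keep],
    reason = ifelse(rowSums(n_det[!keep, , drop = FALSE]) == 0,
                    "all_missing", "presence_filter"))
  ab <- ab[keep, , drop = FALSE]

  for (g in gset) {
    cols <- which(tbl$groups == g)
    miss <- rowSums(is.na(ab[, cols, drop = FALSE]))
    fillable <- which(miss == 1L)
    for (i in fillable) {
      j <- cols[is.na(ab[i, cols])]
      ab[i, j] <- mean(ab[i, cols], na.rm = TRUE)
    }
  }
  tbl$abundance <- ab
  attr(tbl, "removed_proteins") <- removed
  tbl
}

# Fisher LSD pairwise p-values for one protein: pooled-MSE t-tests with the
# ANOVA error degrees of freedom.
lsd_pairwise <- function(y, groups, epsilon = 1e-12) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- tapply(y, g, length)
  means <- tapply(y, g, mean)
  sse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df_err <- length(y) - k
  mse <- max(sse / df_err, epsilon)  # exact ties handled with a floor
  p <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    tstat <- (means[i] - means[j]) / sqrt(mse * (1 / n[i] + 1 / n[j]))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), df_err)
  }
  list(p = p, means = means, mse = mse, df_err = df_err)
}

anova_p_value <- function(y, groups, epsilon = 1e-12) {
  g <- factor(groups)
  n <- length(y)
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  ssb <- sum(tapply(y, g, length) * (means - mean(y))^2)
  sse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (sse < epsilon) {
    return(if (ssb < epsilon) 1 else 0)  # exact ties
  }
  f <- (ssb / (k - 1)) / (sse / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' One-way ANOVA with Fisher LSD enrichment sets
#'
#' Per protein, a one-way ANOVA across sample groups; proteins significant
#' at `alpha` are assigned an enrichment set from the Fisher LSD pattern:
#' group means are ordered and the smallest leading block whose members are
#' all significantly higher than every group outside the block becomes the
#' "enriched in" set (proteins with no clean block are labelled
#' `"ambiguous"`). LSD p-values are pairwise t-tests using the pooled ANOVA
#' mean-square error. Significant proteins are ranked by ANOVA p; `top_n`
#' optionally caps the reported top set.
#'
#' @param tbl a filtered [abundance_table()] (no missing values).
#' @param alpha significance level (default 0.05).
#' @param top_n optional cap on the ranked top set.
#' @param epsilon variance floor for exact-tie handling.
#' @return An object of class `enrichment_sets`: data frame `table`
#'   (`protein`, `anova_p`, `enriched_set`, `top_set`) plus the per-protein
#'   LSD p matrices in `lsd`.
#' @export
anova_lsd <- function(tbl, alpha = 0.05, top_n = Inf, epsilon = 1e-12) {
  stopifnot(inherits(tbl, "abundance_table"))
  ab <- tbl$abundance
  if (anyNA(ab)) stop("run normalize_and_filter() first: table has missing values")
  groups <- tbl$groups
  res <- vector("list", nrow(ab))
  lsd_list <- vector("list", nrow(ab))
  names(lsd_list) <- rownames(ab)
  for (i in seq_len(nrow(ab))) {
    y <- ab[i, ]
    p_anova <- anova_p_value(y, groups, epsilon)
    set_label <- NA_character_
    lsd <- lsd_pairwise(y, groups, epsilon)
    lsd_list[[i]] <- lsd$p
    if (p_anova < alpha) {
      ord <- order(lsd$means, decreasing = TRUE)
      lv <- names(lsd$means)[ord]
      set_label <- "ambiguous"
      for (csize in seq_len(length(lv) - 1L)) {
        inset <- lv[seq_len(csize)]; outset <- lv[-seq_len(csize)]
        ok <- all(outer(inset, outset, Vectorize(function(a, b)
          lsd$means[a] > lsd$means[b] && lsd$p[a, b] < alpha)))
        if (ok) { set_label <- paste(sort(inset), collapse = "+"); break }
      }
    }
    res[[i]] <- data.frame(protein = rownames(ab)[i], anova_p = p_anova,
                           enriched_set = set_label)
  }
  out <- do.call(rbind, res)
  sig <- which(out$anova_p < alpha)
  rank_sig <- sig[order(out$anova_p[sig])]
  out$top_set <- FALSE
  out$top_set[utils::head(rank_sig, top_n)] <- TRUE
  structure(list(table = out, lsd = lsd_list, alpha = alpha),
            class = "enrichment_sets")
}

#' @export
print.enrichment_sets <- function(x, ...) {
  cat(sprintf("enrichment_sets: %d proteins, %d significant at alpha = %g\n",
              nrow(x$table), sum(x$table$top_set), x$alpha))
  invisible(x)
}

#' Replicate-level abundance z-scores
#'
#' Per protein, each sample's abundance is z-scored against the mean and
#' standard deviation over all replicates and all groups of that protein
#' (the convention used for abundance heat maps).
#'
#' @param tbl an [abundance_table()] without missing values.
#' @return Proteins x samples z-score matrix.
#' @export
replicate_zscores <- function(tbl) {
  stopifnot(inherits(tbl, "abundance_table"))
  ab <- tbl$abundance
  mu <- rowMeans(ab)
  sd0 <- apply(ab, 1, stats::sd)
  sd0[sd0 == 0] <- 1  # constant protein: z identically 0
  sweep(sweep(ab, 1, mu), 1, sd0, "/")
}

#' P-value-smoothed z-score matrix for display
#'
#' For each protein and group the displayed value is the mean replicate
#' z-score scaled by `(1 - p)`, where `p` is the one-sample t-test p-value
#' of the replicate z-scores against zero: values supported by consistent
#' replicates pass through almost unchanged, values indistinguishable from
#' zero shrink towards zero. This is a display transform only and is never
#' fed back into the statistics. Groups with a single replicate pass
#' through unscaled and are flagged in the `unscaled` attribute.
#'
#' @param z proteins x samples replicate-level z-score matrix
#'   (see [replicate_zscores()]).
#' @param groups group label per column.
#' @return Proteins x groups matrix of smoothed values.
#' @export
smooth_zscores <- function(z, groups) {
  stopifnot(is.matrix(z), length(groups) == ncol(z))
  gset <- unique(groups)
  out <- matrix(NA_real_, nrow(z), length(gset),
                dimnames = list(rownames(z), gset))
  unscaled <- matrix(FALSE, nrow(z), length(gset),
                     dimnames = dimnames(out))
  for (g in gset) {
    cols <- which(groups == g)
    for (i in seq_len(nrow(z))) {
      v <- z[i, cols]
      if (length(v) < 2L) {
        out[i, g] <- mean(v); unscaled[i, g] <- TRUE
      } else if (stats::sd(v) == 0) {
        # identical replicates: p is 0 for nonzero mean, 1 for zero mean
        out[i, g] <- if (mean(v) == 0) 0 else mean(v)
      } else {
        p <- stats::t.test(v, mu = 0)$p.value
        out[i, g] <- mean(v) * (1 - p)
      }
    }
  }
  attr(out, "unscaled") <- unscaled
  out
}
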