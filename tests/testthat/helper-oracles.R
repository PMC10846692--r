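# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and textbook formulas, not the package's
# own code paths.

# Pairwise contact matrix by explicit double loop.
oracle_contact_matrix <- function(xyz, cutoff = 5, excl = 2L) {
  n <- nrow(xyz)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) > excl &&
        sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff)
      out[i, j] <- 1L
  }
  out
}

# Cook's distance by leave-one-out refitting.
oracle_cooks <- function(x, y) {
  n <- length(x)
  full <- stats::lm(y ~ x)
  yhat <- stats::fitted(full)
  p <- 2L
  mse <- sum(stats::resid(full)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    fi <- stats::lm(y[-i] ~ x[-i])
    yhat_i <- stats::coef(fi)[1] + stats::coef(fi)[2] * x
    sum((yhat - yhat_i)^2) / (p * mse)
  }, numeric(1))
}

# Blob detection by explicit window enumeration and run scanning.
oracle_blobs <- function(sequence, threshold = 0.37, min_windows = 4L) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
          G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
          P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  aa <- strsplit(sequence, "")[[1]]
  s <- (kd[aa] + 4.5) / 9
  n <- length(aa)
  w <- numeric(n - 2)
  for (i in seq_len(n - 2)) w[i] <- mean(s[i:(i + 2)])
  scan_runs <- function(flag) {
    res <- NULL
    i <- 1L
    while (i <= length(flag)) {
      if (flag[i]) {
        j <- i
        while (j < length(flag) && flag[j + 1L]) j <- j + 1L
        if (j - i + 1L >= min_windows)
          res <- rbind(res, c(start = i, end = j + 2L))
        i <- j + 1L
      } else i <- i + 1L
    }
    if (is.null(res)) res <- cbind(start = integer(0), end = integer(0))
    res
  }
  list(hydrophobic = scan_runs(w > threshold),
       hydrophilic = scan_runs(w <= threshold),
       windows = w)
}

# Patch finding by enumerating candidate intervals between occurrence
# positions and keeping maximal valid ones.
oracle_patches <- function(sequence, target, min_occ = NULL, max_gap = 2L) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  if (identical(target, "RG")) {
    starts <- which(aa[-L] == "R" & aa[-1] == "G")
    ends <- starts + 1L
    if (is.null(min_occ)) min_occ <- 2L
  } else {
    starts <- ends <- which(aa == target)
    if (is.null(min_occ)) min_occ <- 4L
  }
  k <- length(starts)
  valid <- NULL
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b < a) next
    if (b - a + 1L < min_occ) next
    gaps_ok <- TRUE
    if (b > a) for (t in a:(b - 1L)) {
      if (starts[t + 1L] - ends[t] - 1L > max_gap) gaps_ok <- FALSE
    }
    if (gaps_ok) valid <- rbind(valid, c(starts[a], ends[b]))
  }
  if (is.null(valid)) return(cbind(start = integer(0), end = integer(0)))
  keep <- rep(TRUE, nrow(valid))
  for (i in seq_len(nrow(valid))) for (j in seq_len(nrow(valid))) {
    if (i != j && valid[j, 1] <= valid[i, 1] && valid[i, 2] <= valid[j, 2] &&
        !(valid[j, 1] == valid[i, 1] && valid[j, 2] == valid[i, 2]))
      keep[i] <- FALSE
  }
  out <- valid[keep, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out[, 1]), , drop = FALSE]
  colnames(out) <- c("start", "end")
  out
}

# Fisher LSD pairwise p-value by the textbook pooled-variance formula,
# written independently of the package.
oracle_lsd_p <- function(y, groups, g1, g2) {
  gs <- split(y, groups)
  k <- length(gs)
  ns <- vapply(gs, length, numeric(1))
  mse <- sum(vapply(gs, function(v) sum((v - mean(v))^2), numeric(1))) /
    (length(y) - k)
  tval <- (mean(gs[[g1]]) - mean(gs[[g2]])) /
    sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
  2 * stats::pt(-abs(tval), length(y) - k)
}

# Random amino-acid sequence.
random_seq <- function(n, seed = NULL, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
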