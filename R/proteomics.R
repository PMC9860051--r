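as_intensity_matrix <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("intensities must be a numeric matrix (proteins x samples)",
         call. = FALSE)
  }
  if (any(mat < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  mat
}

check_metadata <- function(mat, metadata) {
  check_columns(metadata, c("sample_id", "condition"), "sample metadata")
  if (!setequal(metadata$sample_id, colnames(mat)) ||
      anyDuplicated(metadata$sample_id)) {
    stop("metadata sample ids must match the matrix columns exactly",
         call. = FALSE)
  }
  metadata[match(colnames(mat), metadata$sample_id), , drop = FALSE]
}

#' Relative iBAQ (percent riBAQ) per sample
#'
#' Rescales every sample (column) so that protein intensities sum to 100:
#' `riBAQ[i, j] = 100 * iBAQ[i, j] / sum_k iBAQ[k, j]`. Missing values are
#' treated as zero in the denominator and stay missing in the output, so a
#' column without missing values sums to exactly 100 and a column with
#' missing values sums to at most 100.
#'
#' @param mat Non-negative proteins x samples matrix (`NA` = missing).
#' @return Matrix of percent riBAQ values with the same dimensions.
#' @export
#' @examples
#' compute_ribaq(cbind(s1 = c(3, 1)))
compute_ribaq <- function(mat) {
  mat <- as_intensity_matrix(mat)
  cs <- colSums(mat, na.rm = TRUE)
  bad <- !is.finite(cs) | cs <= 0
  if (any(bad)) {
    nm <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
    stop(sprintf("sample(s) with no positive intensities: %s",
                 paste(nm[bad], collapse = ", ")), call. = FALSE)
  }
  sweep(mat, 2, cs, "/") * 100
}

#' Detection filter
#'
#' A protein is considered identified when it was detected (non-missing) in
#' at least `min_detected` replicates of at least one condition (default
#' scope), mirroring the "at least two of three replicates" rule.
#'
#' @param mat Proteins x samples matrix.
#' @param metadata Data frame with `sample_id` and `condition`.
#' @param min_detected Minimum detections (default 2).
#' @param scope `"per_condition"` (default) or `"overall"` (count across
#'   all samples).
#' @return Character vector of retained protein ids (rownames of `mat`).
#' @export
detection_filter <- function(mat, metadata, min_detected = 2L,
                             scope = c("per_condition", "overall")) {
  scope <- match.arg(scope)
  mat <- as_intensity_matrix(mat)
  check_count(min_detected, "min_detected")
  metadata <- check_metadata(mat, metadata)
  det <- !is.na(mat)
  keep <- if (scope == "overall") {
    rowSums(det) >= min_detected
  } else {
    counts <- vapply(unique(metadata$condition), function(cc) {
      rowSums(det[, metadata$condition == cc, drop = FALSE])
    }, numeric(nrow(mat)))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
    apply(counts >= min_detected, 1L, any)
  }
  rn <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  rn[keep]
}

#' Welch's two-sample t statistic
#'
#' `t = (mean(a) - mean(b)) / sqrt(var(a)/n_a + var(b)/n_b)` with
#' Welch-Satterthwaite degrees of freedom. When both groups have zero
#' variance and equal means, `t = 0` by convention (with pooled residual
#' degrees of freedom `n_a + n_b - 2`).
#'
#' @param a,b Numeric vectors; missing values are dropped; at least two
#'   non-missing values per group are required.
#' @return Named numeric vector `c(t = ..., df = ...)`.
#' @export
#' @examples
#' welch_t(c(10, 11, 12), c(1, 2, 3))
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("welch_t needs at least two non-missing values per group",
         call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    return(c(t = t, df = na + nb - 2))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  c(t = t, df = df)
}

# vectorized Welch t over matrix rows; returns list(t, df); rows with fewer
# than 2 non-missing values per group get NA
welch_rows <- function(X, ia, ib) {
  xa <- X[, ia, drop = FALSE]; xb <- X[, ib, drop = FALSE]
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- rowSums((xa - ma)^2, na.rm = TRUE) / (na - 1)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  zero <- se2 == 0 & !is.na(se2)
  t[zero & ma == mb] <- 0
  t[zero & ma != mb] <- sign(ma - mb)[zero & ma != mb] * Inf
  df <- se2^2 / ((va / na)^2 / pmax(na - 1, 1) + (vb / nb)^2 / pmax(nb - 1, 1))
  df[zero] <- na[zero] + nb[zero] - 2
  bad <- na < 2L | nb < 2L
  t[bad] <- NA_real_; df[bad] <- NA_real_
  list(t = t, df = df, mean_a = ma, mean_b = mb)
}

# all two-group label assignments as column-index sets for group A;
# excludes the observed assignment and its group-swap complement, which
# reproduce the observed statistics and therefore carry no null information
null_assignments <- function(n, ia, n_perm, seed) {
  n_a <- length(ia)
  total <- choose(n, n_a)
  if (total <= 2) {
    stop("fewer than 2 distinct label permutations are available",
         call. = FALSE)
  }
  if (total <= n_perm + 2) {
    combs <- combn(n, n_a)
    keep <- vapply(seq_len(ncol(combs)), function(i) {
      s <- combs[, i]
      !setequal(s, ia) && !setequal(s, setdiff(seq_len(n), ia))
    }, logical(1))
    asn <- combs[, keep, drop = FALSE]
    list(assignments = asn, exhaustive = TRUE)
  } else {
    with_seed(seed, {
      seen <- character(0)
      out <- list()
      while (length(out) < n_perm) {
        s <- sort(sample.int(n, n_a))
        key <- paste(s, collapse = ",")
        if (key %in% seen) next
        if (setequal(s, ia) || setequal(s, setdiff(seq_len(n), ia))) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- s
      }
      list(assignments = do.call(cbind, out), exhaustive = FALSE)
    })
  }
}

#' Differential abundance by Welch tests with permutation-based FDR
#'
#' Computes per-protein Welch t statistics between two conditions and
#' controls the false discovery rate by group-label permutations with null
#' statistics pooled across proteins: for every candidate cutoff `c` (the
#' observed absolute t values),
#' `FDR(c) = mean over permutations of #\{null |t| >= c\} / max(1, #\{observed |t| >= c\})`,
#' and the significant set is the largest set with `FDR <= alpha`. All
#' distinct label assignments are enumerated when there are at most
#' `n_perm` of them (3 vs 3 gives 20, so the default is exhaustive and
#' deterministic); otherwise `n_perm` distinct assignments are sampled
#' using `seed`. The observed assignment and its group-swap complement are
#' never counted as null.
#'
#' @param mat Proteins x samples matrix (typically percent riBAQ).
#' @param metadata Data frame with `sample_id`, `condition`.
#' @param conditions Length-2 character vector naming the two conditions to
#'   compare (default: first two in `metadata`).
#' @param alpha FDR level in `[0, 1]`; `alpha = 0` returns an empty
#'   significant set.
#' @param n_perm Maximum number of permutations (default 250).
#' @param seed Seed for permutation sampling (unused when exhaustive).
#' @param transform `"log2"` (default): the test is applied to
#'   log2-transformed values, zeros treated as missing; `"raw"`: values
#'   are tested unchanged. Missing values are excluded groupwise.
#' @return Data frame of class `pul_test_result` with one row per testable
#'   protein: `protein_id`, `t`, `df`, `mean_a`, `mean_b` (group means on
#'   the input scale), `fold_change` (`mean_a / mean_b`), `significant`.
#'   Attributes: `conditions`, `cutoff` (|t| threshold, `Inf` when nothing
#'   is significant), `n_perm_used`, `exhaustive`, `alpha`.
#' @export
permutation_fdr <- function(mat, metadata, conditions = NULL, alpha = 0.05,
                            n_perm = 250L, seed = 1L,
                            transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  mat <- as_intensity_matrix(mat)
  metadata <- check_metadata(mat, metadata)
  if (is.null(conditions)) conditions <- unique(metadata$condition)[1:2]
  if (length(conditions) != 2L || !all(conditions %in% metadata$condition)) {
    stop("`conditions` must name two conditions present in the metadata",
         call. = FALSE)
  }
  check_fraction(alpha, "alpha")
  check_count(n_perm, "n_perm", 2L)

  sel <- metadata$condition %in% conditions
  sub <- mat[, sel, drop = FALSE]
  cond <- metadata$condition[sel]
  ia <- which(cond == conditions[1L])
  ib <- which(cond == conditions[2L])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each condition needs at least two replicates", call. = FALSE)
  }

  X <- sub
  if (transform == "log2") {
    X[!is.na(X) & X == 0] <- NA_real_
    X <- log2(X)
  }

  obs <- welch_rows(X, ia, ib)
  testable <- !is.na(obs$t)
  ids <- (rownames(sub) %||% as.character(seq_len(nrow(sub))))

  perms <- null_assignments(ncol(X), ia, n_perm, seed)
  asn <- perms$assignments
  nperm <- ncol(asn)
  null_abs <- abs(unlist(lapply(seq_len(nperm), function(i) {
    s <- asn[, i]
    welch_rows(X, s, setdiff(seq_len(ncol(X)), s))$t[testable]
  })))
  null_abs <- null_abs[!is.na(null_abs)]

  obs_abs <- abs(obs$t[testable])
  cand <- sort(unique(obs_abs), decreasing = TRUE)
  ns <- sort(null_abs)
  n_null_ge <- length(ns) - findInterval(cand, ns, left.open = TRUE)
  os <- sort(obs_abs)
  n_obs_ge <- length(os) - findInterval(cand, os, left.open = TRUE)
  fdr <- (n_null_ge / nperm) / pmax(1, n_obs_ge)

  cutoff <- Inf
  if (alpha > 0) {
    ok <- which(fdr <= alpha)
    if (length(ok)) cutoff <- cand[max(ok)]
  }

  raw_means <- welch_rows(sub, ia, ib)  # means/fold change on input scale
  res <- data.frame(
    protein_id = ids[testable],
    t = obs$t[testable],
    df = obs$df[testable],
    mean_a = raw_means$mean_a[testable],
    mean_b = raw_means$mean_b[testable],
    fold_change = raw_means$mean_a[testable] / raw_means$mean_b[testable],
    significant = obs_abs >= cutoff,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("pul_test_result", "data.frame")
  attr(res, "conditions") <- conditions
  attr(res, "cutoff") <- cutoff
  attr(res, "n_perm_used") <- nperm
  attr(res, "exhaustive") <- perms$exhaustive
  attr(res, "alpha") <- alpha
  res
}

#' Condition fold changes relative to a reference condition
#'
#' For every protein and every non-reference condition the ratio of mean
#' values `mean(reference) / mean(other)` is reported. A zero denominator
#' with a positive numerator is flagged infinite; only ratios greater than
#' one are marked positive.
#'
#' @param mat Proteins x samples matrix (typically percent riBAQ).
#' @param metadata Data frame with `sample_id`, `condition`.
#' @param reference Reference condition label.
#' @return Data frame with `protein_id`, `condition`, `ratio`, `positive`,
#'   `infinite`.
#' @export
fold_changes <- function(mat, metadata, reference) {
  mat <- as_intensity_matrix(mat)
  metadata <- check_metadata(mat, metadata)
  if (!reference %in% metadata$condition) {
    stop("`reference` must be a condition in the metadata", call. = FALSE)
  }
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  ref_mean <- rowMeans(mat[, metadata$condition == reference, drop = FALSE],
                       na.rm = TRUE)
  others <- setdiff(unique(metadata$condition), reference)
  out <- lapply(others, function(cc) {
    m <- rowMeans(mat[, metadata$condition == cc, drop = FALSE], na.rm = TRUE)
    ratio <- ref_mean / m
    data.frame(protein_id = ids, condition = cc, ratio = ratio,
               positive = !is.na(ratio) & ratio > 1,
               infinite = is.infinite(ratio),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
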