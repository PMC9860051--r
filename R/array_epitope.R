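spot_cols <- c("extract_id", "probe_id", "treatment", "replicate", "signal")

#' Mean signal per (extract, probe, treatment) cell
#'
#' Arithmetic mean of replicate spot signals. Cells with fewer than
#' `min_spots` replicates violate the replicate rule ("a minimum of two
#' replicates"): they are excluded from the returned table and reported in
#' the `flagged` attribute.
#'
#' @param spots Spot table with columns `extract_id`, `probe_id`,
#'   `treatment`, `replicate`, `signal` (signals must be non-negative).
#' @param min_spots Minimum replicate spots per cell (default 2).
#' @return Data frame with `extract_id`, `probe_id`, `treatment`,
#'   `mean_signal`, `n_spots`; attribute `flagged` holds the excluded
#'   cells.
#' @export
mean_replicates <- function(spots, min_spots = 2L) {
  check_columns(spots, spot_cols, "spot table")
  check_count(min_spots, "min_spots")
  if (any(spots$signal < 0, na.rm = TRUE)) {
    stop("spot signals must be non-negative", call. = FALSE)
  }
  agg <- aggregate(signal ~ extract_id + probe_id + treatment, data = spots,
                   FUN = mean)
  n <- aggregate(signal ~ extract_id + probe_id + treatment, data = spots,
                 FUN = length)
  agg$n_spots <- n$signal[match(
    paste(agg$extract_id, agg$probe_id, agg$treatment),
    paste(n$extract_id, n$probe_id, n$treatment))]
  names(agg)[names(agg) == "signal"] <- "mean_signal"
  ok <- agg$n_spots >= min_spots
  out <- agg[ok, c("extract_id", "probe_id", "treatment", "mean_signal",
                   "n_spots"), drop = FALSE]
  out <- out[order_stable(out$treatment, out$extract_id, out$probe_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- agg[!ok, , drop = FALSE]
  out
}

#' Max-to-100 normalization per dataset
#'
#' Within each dataset the highest mean signal is set to 100 and all other
#' values are scaled accordingly. By default each treatment block is one
#' dataset (one physical array / sub-heatmap); `scope = "global"` treats
#' the whole table as one dataset.
#'
#' @param means Output of [mean_replicates()].
#' @param scope `"treatment"` (default) or `"global"`.
#' @return The input with an added `normalized` column; the maximum of
#'   every non-empty dataset is exactly 100.
#' @export
normalize_dataset <- function(means, scope = c("treatment", "global")) {
  scope <- match.arg(scope)
  check_columns(means, c("extract_id", "probe_id", "treatment",
                         "mean_signal"), "mean signal table")
  if (!nrow(means)) stop("empty mean table", call. = FALSE)
  grp <- if (scope == "treatment") means$treatment else rep("all", nrow(means))
  mx <- tapply(means$mean_signal, grp, max)
  if (any(mx <= 0)) {
    stop(sprintf("dataset(s) with no positive signal: %s",
                 paste(names(mx)[mx <= 0], collapse = ", ")), call. = FALSE)
  }
  means$normalized <- as.vector(means$mean_signal / unname(mx[grp])) * 100
  means
}

#' Epitope deletion score against the buffer control
#'
#' Percent signal reduction of an enzyme treatment relative to the buffer
#' control on the same (extract, probe) cell:
#' `100 * (1 - treated / control)`, floored at zero (signal increases are
#' reported as 0 with the raw ratio preserved). Cells whose control signal
#' is zero are undefined and flagged.
#'
#' @param normalized Output of [normalize_dataset()].
#' @param treatment Treatment label to score.
#' @param control Control treatment label (default `"buffer"`).
#' @return Data frame with `extract_id`, `probe_id`, `deletion_score`,
#'   `raw_ratio` (treated/control), `undefined`.
#' @export
epitope_deletion_score <- function(normalized, treatment,
                                   control = "buffer") {
  check_columns(normalized, c("extract_id", "probe_id", "treatment",
                              "normalized"), "normalized table")
  tr <- normalized[normalized$treatment == treatment, , drop = FALSE]
  ct <- normalized[normalized$treatment == control, , drop = FALSE]
  if (!nrow(tr) || !nrow(ct)) {
    stop("both the treatment and the control must be present", call. = FALSE)
  }
  key_tr <- paste(tr$extract_id, tr$probe_id, sep = "\r")
  key_ct <- paste(ct$extract_id, ct$probe_id, sep = "\r")
  common <- intersect(key_tr, key_ct)
  tr <- tr[match(common, key_tr), , drop = FALSE]
  ct <- ct[match(common, key_ct), , drop = FALSE]
  ratio <- tr$normalized / ct$normalized
  undefined <- ct$normalized == 0
  score <- pmax(0, 100 * (1 - ratio))
  score[undefined] <- NA_real_
  out <- data.frame(extract_id = tr$extract_id, probe_id = tr$probe_id,
                    deletion_score = score, raw_ratio = ratio,
                    undefined = undefined, stringsAsFactors = FALSE)
  out <- out[order_stable(out$extract_id, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
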