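#' Score called intervals against planted truth
#'
#' Greedy one-to-one matching: each truth QTL is matched to the nearest
#' unmatched interval on its chromosome that overlaps the window
#' `[pos - tolerance, pos + tolerance]` (distance measured from the truth
#' position to the interval, 0 if contained). Matched truths are true
#' positives, unmatched truths false negatives, unmatched intervals false
#' positives.
#'
#' @param intervals a [merge_intervals()] table.
#' @param truth data.frame `chrom`, `pos` (and optionally `effect`).
#' @param tolerance matching window half-width in bp.
#' @return object of class `recovery_report`: list with `tp`, `fp`, `fn`,
#'   `power`, `fdr` and `matches` (data.frame truth index -> interval index).
#' @export
match_intervals <- function(intervals, truth, tolerance = 50000) {
  assert_scalar_num(tolerance, "tolerance", lower = 0)
  n_truth <- nrow(truth)
  n_int <- nrow(intervals)
  # distance from each truth to each interval (Inf if no overlap in window)
  pair <- expand.grid(ti = seq_len(n_truth), ii = seq_len(n_int))
  if (nrow(pair)) {
    d <- mapply(function(ti, ii) {
      if (truth$chrom[ti] != intervals$chrom[ii]) return(Inf)
      dist <- max(intervals$start[ii] - truth$pos[ti],
                  truth$pos[ti] - intervals$end[ii], 0)
      if (dist > tolerance) Inf else dist
    }, pair$ti, pair$ii)
    pair <- pair[order(d), , drop = FALSE]
    pair <- pair[is.finite(sort(d)), , drop = FALSE]
  }
  used_t <- logical(n_truth); used_i <- logical(n_int)
  matches <- data.frame(truth = integer(), interval = integer())
  for (r in seq_len(nrow(pair))) {
    ti <- pair$ti[r]; ii <- pair$ii[r]
    if (used_t[ti] || used_i[ii]) next
    used_t[ti] <- TRUE; used_i[ii] <- TRUE
    matches <- rbind(matches, data.frame(truth = ti, interval = ii))
  }
  tp <- sum(used_t); fn <- n_truth - tp; fp <- n_int - sum(used_i)
  structure(list(tp = tp, fp = fp, fn = fn,
                 power = if (n_truth) tp / n_truth else NA_real_,
                 fdr = fp / max(1, tp + fp), matches = matches),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery: tp %d, fp %d, fn %d (power %.2f, fdr %.2f)\n",
              x$tp, x$fp, x$fn, x$power, x$fdr))
  invisible(x)
}

#' Sweep the allele-frequency-change threshold
#'
#' Re-runs site calling, interval assembly and truth matching over a grid
#' of `delta_threshold` values, contextualising the conventional fixed 0.1.
#'
#' @param deltas a [delta_af()] table.
#' @param truth planted-truth data.frame (`chrom`, `pos`).
#' @param thresholds grid of thresholds in (0, 1].
#' @param max_gap,min_sites interval-assembly parameters.
#' @param tolerance matching window in bp.
#' @return data.frame: threshold, power, fdr, n_intervals.
#' @export
threshold_sweep <- function(deltas, truth, thresholds = seq(0.05, 0.5, by = 0.05),
                            max_gap = 25000, min_sites = 3L, tolerance = 50000) {
  if (!length(thresholds) || any(thresholds <= 0 | thresholds > 1))
    stop_bsa("thresholds must lie in (0, 1]")
  thresholds <- sort(thresholds)
  do.call(rbind, lapply(thresholds, function(th) {
    cfg <- filter_config(delta_threshold = th)
    iv <- merge_intervals(call_qtl_sites(deltas, cfg),
                          max_gap = max_gap, min_sites = min_sites)
    rep <- match_intervals(iv, truth, tolerance)
    data.frame(threshold = th, power = rep$power, fdr = rep$fdr,
               n_intervals = nrow(iv))
  }))
}
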