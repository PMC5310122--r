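#' QTL-caller filter configuration
#'
#' The three published site rules, all thresholds inclusive: a site must be
#' covered by at least `min_depth` reads in the initial pool and in every
#' selected pool, must segregate at 30-70% parent-A frequency in the
#' initial (unselected) pool, and is called a QTL site when its allele
#' frequency changes by at least `delta_threshold` in the same direction in
#' every replicate.
#'
#' @param min_depth minimum reads per site per pool (default 30).
#' @param af_band inclusive initial allele-frequency band (default
#'   `c(0.30, 0.70)`).
#' @param delta_threshold minimum absolute allele-frequency change
#'   (default 0.1).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 30, af_band = c(0.30, 0.70),
                          delta_threshold = 0.1) {
  assert_scalar_num(min_depth, "min_depth", lower = 0)
  if (length(af_band) != 2L || af_band[1] < 0 || af_band[2] > 1 ||
      af_band[1] > af_band[2])
    stop_bsa("af_band must be 0 <= low <= high <= 1")
  assert_scalar_num(delta_threshold, "delta_threshold", lower = 1e-12, upper = 1)
  structure(list(min_depth = min_depth, af_band = as.numeric(af_band),
                 delta_threshold = delta_threshold),
            class = "filter_config")
}

#' Per-site allele frequencies of a pool
#'
#' `af = count_A / (count_A + count_B)`; zero-depth sites are carried with
#' `af = NA` and removed later by the coverage filter.
#'
#' @param counts a `pool_counts`.
#' @return data.frame: chrom, pos, af, depth.
#' @export
allele_frequency <- function(counts) {
  stopifnot(inherits(counts, "pool_counts"))
  depth <- counts$count_A + counts$count_B
  data.frame(chrom = counts$chrom, pos = counts$pos,
             af = ifelse(depth > 0, counts$count_A / depth, NA_real_),
             depth = depth)
}

site_key <- function(df) paste(df$chrom, df$pos, sep = ":")

# Outer-join a list of AF tables on (chrom, pos); missing sites get depth 0.
join_af_tables <- function(tables) {
  keys <- unique(do.call(rbind, lapply(tables, function(t) t[c("chrom", "pos")])))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  rownames(keys) <- NULL
  cols <- lapply(tables, function(t) {
    i <- match(site_key(keys), site_key(t))
    data.frame(af = t$af[i], depth = ifelse(is.na(i), 0, t$depth[i]))
  })
  list(sites = keys, pools = cols)
}

#' Apply the coverage and allele-frequency-band site filters
#'
#' A site is retained iff its depth is at least `cfg$min_depth` in the
#' initial pool AND in every selected pool, and its initial-pool allele
#' frequency lies inside `cfg$af_band` (inclusive). Pools are outer-joined
#' on the site universe; a site absent from a pool counts as depth 0.
#'
#' @param initial AF table of the unselected pool ([allele_frequency()]).
#' @param selected_pools list of AF tables of the selected pools.
#' @param cfg a [filter_config()].
#' @return data.frame of retained sites: chrom, pos, af_initial,
#'   depth_initial, then af_sel_r1, depth_sel_r1, ... per selected pool.
#' @export
filter_sites <- function(initial, selected_pools, cfg = filter_config()) {
  if (!length(selected_pools)) stop_bsa("need at least one selected pool")
  j <- join_af_tables(c(list(initial), selected_pools))
  if (nrow(j$sites) == 0L) stop_bsa("empty site universe")
  ini <- j$pools[[1]]
  keep <- ini$depth >= cfg$min_depth & !is.na(ini$af) &
    ini$af >= cfg$af_band[1] & ini$af <= cfg$af_band[2]
  for (p in j$pools[-1]) keep <- keep & p$depth >= cfg$min_depth
  out <- data.frame(j$sites, af_initial = ini$af, depth_initial = ini$depth)
  for (r in seq_along(selected_pools)) {
    out[[paste0("af_sel_r", r)]] <- j$pools[[r + 1]]$af
    out[[paste0("depth_sel_r", r)]] <- j$pools[[r + 1]]$depth
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Signed allele-frequency change per retained site
#'
#' `delta = af_selected - af_initial` in parent-A orientation, computed for
#' every `af_sel_r*` column of a [filter_sites()] table.
#'
#' @param retained the data.frame returned by [filter_sites()].
#' @return the same data.frame with one `delta_r*` column per replicate.
#' @export
delta_af <- function(retained) {
  reps <- grep("^af_sel_r[0-9]+$", names(retained), value = TRUE)
  if (!length(reps)) stop_bsa("no selected-pool columns present")
  for (r in reps) {
    if (anyNA(retained[[r]]))
      stop_bsa("selected pool has undefined AF at a retained site")
    retained[[sub("^af_sel_", "delta_", r)]] <- retained[[r]] - retained$af_initial
  }
  retained
}

#' Call QTL sites from replicate allele-frequency changes
#'
#' A site is called iff every replicate shows `|delta| >=
#' cfg$delta_threshold` and all replicate deltas share one sign. The shared
#' direction is recorded as +1 (parent-A allele rises) or -1.
#'
#' @param deltas a [delta_af()] table (columns `delta_r*`).
#' @param cfg a [filter_config()].
#' @return data.frame of called sites: chrom, pos, delta_r*, direction.
#' @export
call_qtl_sites <- function(deltas, cfg = filter_config()) {
  reps <- grep("^delta_r[0-9]+$", names(deltas), value = TRUE)
  if (!length(reps)) stop_bsa("no replicate delta columns present")
  d <- as.matrix(deltas[reps])
  pass <- rowSums(d >= cfg$delta_threshold) == length(reps) |
    rowSums(d <= -cfg$delta_threshold) == length(reps)
  out <- deltas[pass, c("chrom", "pos", reps), drop = FALSE]
  out$direction <- if (nrow(out)) ifelse(rowMeans(as.matrix(out[reps])) > 0, 1L, -1L)
                   else integer(0)
  rownames(out) <- NULL
  out
}

#' Merge called sites into QTL intervals
#'
#' Single linear pass per chromosome: consecutive same-direction calls
#' whose inter-site gap is at most `max_gap` bp join one cluster; clusters
#' with fewer than `min_sites` member sites are discarded. Interval bounds
#' are the first and last member site (1-based inclusive).
#'
#' @param calls a [call_qtl_sites()] table.
#' @param max_gap maximum gap between member sites in bp.
#' @param min_sites minimum sites per reported interval.
#' @return data.frame: chrom, start, end, n_sites, mean_abs_delta,
#'   direction.
#' @export
merge_intervals <- function(calls, max_gap = 25000, min_sites = 3L) {
  reps <- grep("^delta_r[0-9]+$", names(calls), value = TRUE)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_sites = integer(),
                      mean_abs_delta = numeric(), direction = integer())
  if (nrow(calls) == 0L) return(empty)
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  new_cluster <- c(TRUE, diff(calls$pos) > max_gap |
                     calls$chrom[-1] != calls$chrom[-nrow(calls)] |
                     calls$direction[-1] != calls$direction[-nrow(calls)])
  cl <- cumsum(new_cluster)
  out <- do.call(rbind, lapply(split(seq_len(nrow(calls)), cl), function(i) {
    if (length(i) < min_sites) return(NULL)
    data.frame(chrom = calls$chrom[i[1]],
               start = min(calls$pos[i]), end = max(calls$pos[i]),
               n_sites = length(i),
               mean_abs_delta = mean(abs(as.matrix(calls[i, reps]))),
               direction = calls$direction[i[1]])
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Flag subtelomeric intervals
#'
#' An interval is subtelomeric when it enters either chromosome-end window
#' of `window` bp: `start <= window` or `end >= length - window + 1`. The
#' default window matches the ~20-30 kb subtelomeric gene region convention
#' for S. cerevisiae.
#'
#' @param intervals a [merge_intervals()] table.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window subtelomere window size in bp.
#' @return `intervals` with a logical `subtelomeric` column.
#' @export
annotate_subtelomeric <- function(intervals, chrom_lengths, window = 30000) {
  if (nrow(intervals) == 0L) {
    intervals$subtelomeric <- logical(0)
    return(intervals)
  }
  len <- chrom_lengths[intervals$chrom]
  if (anyNA(len)) stop_bsa("interval on chromosome without a known length")
  if (any(intervals$end > len)) stop_bsa("interval extends beyond chromosome end")
  intervals$subtelomeric <- intervals$start <= window |
    intervals$end >= len - window + 1
  intervals
}

#' Export QTL intervals as BED
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive,
#' so `start - 1` / `end`. Score is `1000 * mean |delta AF|` capped at 1000.
#'
#' @param intervals annotated interval table.
#' @param path output file.
#' @param name track/feature name (e.g. the condition label).
#' @export
write_intervals_bed <- function(intervals, path, name = "qtl") {
  bed <- data.frame(chrom = intervals$chrom,
                    start = as.integer(intervals$start - 1),
                    end = as.integer(intervals$end),
                    name = name,
                    score = pmin(1000, round(1000 * intervals$mean_abs_delta)),
                    strand = ifelse(intervals$direction > 0, "+", "-"))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' One-call QTL mapping from counts tables
#'
#' Convenience wrapper chaining [allele_frequency()], [filter_sites()],
#' [delta_af()], [call_qtl_sites()], [merge_intervals()] and
#' [annotate_subtelomeric()].
#'
#' @param initial_counts `pool_counts` of the unselected pool.
#' @param selected_counts list of `pool_counts`, one per replicate.
#' @param chrom_lengths named chromosome lengths (bp) for the subtelomere
#'   flag; `NULL` skips annotation.
#' @param cfg a [filter_config()].
#' @param max_gap,min_sites,window interval-assembly and annotation knobs.
#' @return list: `retained`, `calls`, `intervals`.
#' @export
map_qtl <- function(initial_counts, selected_counts, chrom_lengths = NULL,
                    cfg = filter_config(), max_gap = 25000, min_sites = 3L,
                    window = 30000) {
  retained <- filter_sites(allele_frequency(initial_counts),
                           lapply(selected_counts, allele_frequency), cfg)
  deltas <- delta_af(retained)
  calls <- call_qtl_sites(deltas, cfg)
  intervals <- merge_intervals(calls, max_gap = max_gap, min_sites = min_sites)
  if (!is.null(chrom_lengths))
    intervals <- annotate_subtelomeric(intervals, chrom_lengths, window)
  list(retained = deltas, calls = calls, intervals = intervals)
}
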