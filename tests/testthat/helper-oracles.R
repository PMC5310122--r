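# Independent reference implementations used as oracles. Deliberately
# written as plain site-by-site / case-by-case loops, sharing no code with
# the package's vectorised paths.

# The three published site rules, applied literally one site at a time.
# pools: list of data.frames (chrom, pos, count_A, count_B); first = initial.
oracle_caller <- function(initial, selected, min_depth = 30,
                          band = c(0.30, 0.70), delta = 0.1) {
  key <- function(df) paste(df$chrom, df$pos)
  all_keys <- unique(unlist(lapply(c(list(initial), selected), key)))
  retained <- character(); called <- character(); direction <- integer()
  for (k in all_keys) {
    look <- function(df) {
      i <- which(key(df) == k)
      if (!length(i)) return(c(0, NA))
      d <- df$count_A[i] + df$count_B[i]
      c(d, if (d > 0) df$count_A[i] / d else NA)
    }
    ini <- look(initial)
    ok <- ini[1] >= min_depth && !is.na(ini[2]) &&
      ini[2] >= band[1] && ini[2] <= band[2]
    sels <- lapply(selected, look)
    for (s in sels) ok <- ok && s[1] >= min_depth
    if (!ok) next
    retained <- c(retained, k)
    deltas <- vapply(sels, function(s) s[2] - ini[2], numeric(1))
    if (all(deltas >= delta)) {
      called <- c(called, k); direction <- c(direction, 1L)
    } else if (all(deltas <= -delta)) {
      called <- c(called, k); direction <- c(direction, -1L)
    }
  }
  o <- order(called)
  list(retained = sort(retained),
       called = called[o],
       direction = direction[o])
}

# Single-pass clustering of called sites, written independently.
oracle_clusters <- function(chrom, pos, direction, max_gap, min_sites) {
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]; direction <- direction[o]
  out <- list(); cur <- NULL
  flush <- function(cur, out) {
    if (!is.null(cur) && length(cur$pos) >= min_sites)
      out[[length(out) + 1]] <- data.frame(chrom = cur$chrom,
                                           start = min(cur$pos),
                                           end = max(cur$pos),
                                           n_sites = length(cur$pos))
    out
  }
  for (i in seq_along(pos)) {
    if (is.null(cur) || chrom[i] != cur$chrom || direction[i] != cur$dir ||
        pos[i] - max(cur$pos) > max_gap) {
      out <- flush(cur, out)
      cur <- list(chrom = chrom[i], dir = direction[i], pos = pos[i])
    } else cur$pos <- c(cur$pos, pos[i])
  }
  out <- flush(cur, out)
  if (!length(out)) data.frame(chrom = character(), start = numeric(),
                               end = numeric(), n_sites = integer())
  else do.call(rbind, out)
}

# Exhaustive one-to-one truth/interval assignment: maximise matched pairs,
# break ties by total distance. Feasible for tiny inputs only.
oracle_match <- function(intervals, truth, tolerance) {
  n_t <- nrow(truth); n_i <- nrow(intervals)
  dist <- matrix(Inf, n_t, n_i)
  for (t in seq_len(n_t)) for (i in seq_len(n_i)) {
    if (truth$chrom[t] != intervals$chrom[i]) next
    d <- max(intervals$start[i] - truth$pos[t],
             truth$pos[t] - intervals$end[i], 0)
    if (d <= tolerance) dist[t, i] <- d
  }
  best <- list(n = -1, d = Inf)
  assign_rec <- function(t, used, n, d) {
    if (t > n_t) {
      if (n > best$n || (n == best$n && d < best$d)) best <<- list(n = n, d = d)
      return()
    }
    assign_rec(t + 1, used, n, d)  # leave truth t unmatched
    for (i in seq_len(n_i)) {
      if (used[i] || !is.finite(dist[t, i])) next
      used[i] <- TRUE
      assign_rec(t + 1, used, n + 1, d + dist[t, i])
      used[i] <- FALSE
    }
  }
  assign_rec(1, rep(FALSE, n_i), 0, 0)
  list(tp = best$n, fn = n_t - best$n, fp = n_i - best$n)
}

# A tiny yeast-like test map: explicit marker grid, no randomness.
grid_map <- function(n_chrom = 2, n_markers = 30, length_bp = 3e5,
                     cM_per_Mb = 380 / 12) {
  pos <- round(seq(5000, length_bp - 5000, length.out = n_markers))
  markers <- do.call(rbind, lapply(seq_len(n_chrom), function(i)
    data.frame(chrom = paste0("chr", as.roman(i)), pos = pos,
               cM = pos * cM_per_Mb / 1e6)))
  bsaqtl:::new_marker_map(
    data.frame(name = paste0("chr", as.roman(seq_len(n_chrom))),
               length = length_bp), markers)
}

# Counts table constructor for hand-built caller fixtures.
counts_df <- function(chrom, pos, a, b, id = "pool") {
  bsaqtl:::new_pool_counts(
    data.frame(chrom = chrom, pos = pos, count_A = a, count_B = b), id)
}
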