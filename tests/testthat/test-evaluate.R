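iv_row <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, n_sites = 3L,
             mean_abs_delta = 0.2, direction = 1L)
}

test_that("match_intervals counts tp/fp/fn with one-to-one matching", {
  truth <- data.frame(chrom = c("chrI", "chrII", "chrIII"),
                      pos = c(1e5, 2e5, 3e5))
  r <- match_intervals(iv_row("chrI", 1, 2)[0, ], truth)
  expect_equal(c(r$tp, r$fn, r$power), c(0, 3, 0))

  r <- match_intervals(iv_row("chrI", 9e4, 1.2e5), truth)
  expect_equal(c(r$tp, r$fp, r$fdr), c(1, 0, 0))

  # outside the tolerance window: no match
  r <- match_intervals(iv_row("chrI", 2e5, 2.5e5), truth, tolerance = 50000)
  expect_equal(c(r$tp, r$fp), c(0, 1))
  # on the wrong chromosome: never a match
  r <- match_intervals(iv_row("chrIV", 9e4, 1.2e5), truth)
  expect_equal(r$tp, 0)
})

test_that("greedy matching equals exhaustive assignment on puzzles", {
  for (s in 1:15) {
    layout <- withr::with_seed(s, {
      truth <- data.frame(chrom = sample(c("chrI", "chrII"), 3, TRUE),
                          pos = sample.int(5e5, 3))
      iv <- do.call(rbind, lapply(1:4, function(i) {
        st <- sample.int(5e5, 1)
        iv_row(sample(c("chrI", "chrII"), 1), st, st + 3e4)
      }))
      list(truth = truth, iv = iv)
    })
    got <- match_intervals(layout$iv, layout$truth, tolerance = 50000)
    orc <- oracle_match(layout$iv, layout$truth, tolerance = 50000)
    expect_equal(got$tp, orc$tp)
    expect_equal(got$fp, orc$fp)
    expect_equal(got$fn, orc$fn)
  }
})

test_that("matching is stable under truth permutation", {
  truth <- data.frame(chrom = c("chrI", "chrI", "chrII"),
                      pos = c(1e5, 3e5, 2e5))
  iv <- rbind(iv_row("chrI", 0.8e5, 1.2e5), iv_row("chrI", 2.9e5, 3.2e5),
              iv_row("chrII", 4e5, 4.5e5))
  a <- match_intervals(iv, truth)
  b <- match_intervals(iv, truth[c(3, 1, 2), ])
  expect_equal(c(a$tp, a$fp, a$fn), c(b$tp, b$fp, b$fn))
  expect_equal(a$tp + a$fn, nrow(truth))
})

test_that("threshold_sweep is consistent and monotone in power", {
  deltas <- withr::with_seed(2, {
    pos <- sort(sample.int(5e5, 120))
    data.frame(chrom = "chrI", pos = pos, af_initial = 0.5,
               depth_initial = 100,
               delta_r1 = rnorm(120, ifelse(abs(pos - 2.5e5) < 5e4, 0.25, 0), 0.05),
               delta_r2 = rnorm(120, ifelse(abs(pos - 2.5e5) < 5e4, 0.25, 0), 0.05))
  })
  truth <- data.frame(chrom = "chrI", pos = 2.5e5)
  sw <- threshold_sweep(deltas, truth, thresholds = c(0.1, 0.2, 0.9, 1))
  expect_equal(sw$threshold, c(0.1, 0.2, 0.9, 1))
  expect_true(all(diff(sw$power) <= 0))
  expect_equal(sw$n_intervals[4], 0)  # |dAF| = 1 needs fixation
  # consistency with a direct run at the default 0.1
  direct <- merge_intervals(call_qtl_sites(deltas, filter_config()))
  expect_equal(sw$n_intervals[1], nrow(direct))
  expect_error(threshold_sweep(deltas, truth, thresholds = numeric(0)))
  expect_error(threshold_sweep(deltas, truth, thresholds = c(0, 0.5)))
})

test_that("run_config validates sections and rejects unknown keys", {
  cfg <- run_config(selection = list(rounds = 4), seed = 9)
  expect_equal(cfg$selection$rounds, 4)
  expect_equal(cfg$selection$n_replicates, 2L)  # untouched defaults remain
  expect_error(run_config(nonsense = list(a = 1)), "unknown config section")
  expect_error(run_config(selection = list(round = 4)), "unknown key")
})

small_cfg <- function(seed, qtls = list(n = 1L, effect = 0.05), rounds = 8L) {
  run_config(
    map = list(chrom_lengths = c(chrA = 4e5, chrB = 4e5, chrC = 4e5),
               markers_per_chrom = 40L),
    cross = list(pop_size = 400L),
    trait = list(qtls = qtls),
    selection = list(rounds = rounds, bottleneck_size = 400L),
    phenotype = list(n_segregants = 60L),
    seed = seed)
}

test_that("run_pipeline writes a complete, reproducible run directory", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(small_cfg(5), out_dir = d1)
  r2 <- run_pipeline(small_cfg(5), out_dir = d2)
  files <- c("marker_map.tsv", "truth.tsv", "counts_initial.tsv",
             "counts_sel_r1.tsv", "counts_sel_r2.tsv", "retained_sites.tsv",
             "qtl_calls.tsv", "qtl_intervals.tsv", "summary.json",
             "pipeline.log")
  for (f in files) expect_true(file.exists(file.path(d1, f)), label = f)
  # identical config + seed: byte-identical outputs end to end
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # a different seed changes the simulated data
  r3 <- run_pipeline(small_cfg(6))
  expect_false(identical(r1$counts$initial$count_A, r3$counts$initial$count_A))
  # the summary reports what the objects contain
  expect_equal(r1$summary$recovery$tp, r1$recovery$tp)
  expect_equal(r1$summary$n_retained, nrow(r1$qtl$retained))
  expect_true(is.numeric(r1$phenotype$h2_percent))
})

test_that("zero planted QTLs give tp = 0; zero rounds give no enrichment", {
  r <- run_pipeline(small_cfg(11, qtls = list(n = 0L, effect = 0)))
  expect_equal(r$recovery$tp, 0)
  # with no selection rounds the selected pools are resequencings of F13:
  # same-direction calls are pure pool-noise coincidences, a small fraction
  r0 <- run_pipeline(small_cfg(12, qtls = list(n = 1L, effect = 0.05),
                               rounds = 0L))
  expect_lt(nrow(r0$qtl$calls) / max(1, nrow(r0$qtl$retained)), 0.10)
})
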