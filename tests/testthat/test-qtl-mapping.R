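test_that("allele_frequency is count arithmetic with NA at zero depth", {
  cnt <- counts_df("chrI", c(100, 200, 300, 400), c(0, 30, 7, 0),
                   c(50, 30, 13, 0))
  af <- allele_frequency(cnt)
  expect_equal(af$af, c(0, 0.5, 0.35, NA))
  expect_equal(af$depth, c(50, 60, 20, 0))
})

test_that("filter_sites applies inclusive coverage and band rules", {
  mk <- function(a, b) counts_df("chrI", 100, a, b)
  sel <- list(allele_frequency(mk(50, 50)))
  cfg <- filter_config()
  # 29 reads in the initial pool: dropped; 30: retained
  expect_equal(nrow(filter_sites(allele_frequency(mk(15, 14)), sel, cfg)), 0)
  expect_equal(nrow(filter_sites(allele_frequency(mk(15, 15)), sel, cfg)), 1)
  # initial AF 0.29 dropped, 0.30 and 0.70 retained, 0.71 dropped
  expect_equal(nrow(filter_sites(allele_frequency(mk(29, 71)), sel, cfg)), 0)
  expect_equal(nrow(filter_sites(allele_frequency(mk(30, 70)), sel, cfg)), 1)
  expect_equal(nrow(filter_sites(allele_frequency(mk(70, 30)), sel, cfg)), 1)
  expect_equal(nrow(filter_sites(allele_frequency(mk(71, 29)), sel, cfg)), 0)
  # depth rule applies to every selected pool too
  sel29 <- list(allele_frequency(mk(50, 50)),
                allele_frequency(counts_df("chrI", 100, 14, 15)))
  expect_equal(nrow(filter_sites(allele_frequency(mk(40, 60)), sel29, cfg)), 0)
  # a site missing from a selected pool counts as depth 0
  selmiss <- list(allele_frequency(counts_df("chrI", 999, 50, 50)))
  expect_equal(nrow(filter_sites(allele_frequency(mk(40, 60)), selmiss, cfg)), 0)
})

test_that("delta_af is the signed parent-A change and flips with labels", {
  ini <- allele_frequency(counts_df("chrI", c(1, 2), c(40, 50), c(60, 50)))
  sel <- allele_frequency(counts_df("chrI", c(1, 2), c(55, 50), c(45, 50)))
  d <- delta_af(filter_sites(ini, list(sel), filter_config()))
  expect_equal(d$delta_r1, c(0.15, 0))
  # swapping A/B in both pools flips the sign exactly
  ini2 <- allele_frequency(counts_df("chrI", c(1, 2), c(60, 50), c(40, 50)))
  sel2 <- allele_frequency(counts_df("chrI", c(1, 2), c(45, 50), c(55, 50)))
  d2 <- delta_af(filter_sites(ini2, list(sel2), filter_config()))
  expect_equal(d2$delta_r1, -d$delta_r1)
})

test_that("call_qtl_sites enforces threshold and shared direction", {
  base <- data.frame(chrom = "chrI", pos = 1:4, af_initial = 0.5,
                     depth_initial = 100)
  base$delta_r1 <- c(0.12, 0.12, 0.10, 0.09)
  base$delta_r2 <- c(0.11, -0.11, 0.10, 0.30)
  calls <- call_qtl_sites(base, filter_config())
  # +0.12/+0.11 called; sign conflict not called; boundary 0.10/0.10 called
  # (inclusive); 0.09 fails in one replicate
  expect_equal(calls$pos, c(1, 3))
  expect_equal(calls$direction, c(1L, 1L))
  neg <- base
  neg$delta_r1 <- -neg$delta_r1; neg$delta_r2 <- -neg$delta_r2
  expect_equal(call_qtl_sites(neg, filter_config())$direction, c(-1L, -1L))
})

test_that("caller equals brute-force enumeration on random toy tables", {
  for (s in 1:25) {
    tab <- withr::with_seed(s, {
      n <- sample(5:40, 1)
      pos <- sort(sample.int(3e5, n))
      mk <- function() counts_df(
        "chrI", pos, rpois(n, sample(c(10, 25, 40, 80), 1) * runif(n, 0.2, 0.8)),
        rpois(n, 40 * runif(n, 0.2, 0.8)))
      list(ini = mk(), s1 = mk(), s2 = mk())
    })
    res <- map_qtl(tab$ini, list(tab$s1, tab$s2))
    orc <- oracle_caller(tab$ini, list(tab$s1, tab$s2))
    expect_identical(sort(paste(res$retained$chrom, res$retained$pos)),
                     orc$retained)
    expect_identical(sort(paste(res$calls$chrom, res$calls$pos)),
                     sort(orc$called))
    if (nrow(res$calls)) {
      o <- order(paste(res$calls$chrom, res$calls$pos))
      expect_identical(res$calls$direction[o], orc$direction)
    }
  }
})

test_that("threshold filters are monotone", {
  tab <- withr::with_seed(3, {
    n <- 200
    pos <- sort(sample.int(1e6, n))
    list(ini = counts_df("chrI", pos, rpois(n, 50), rpois(n, 50)),
         s1 = counts_df("chrI", pos, rpois(n, 60), rpois(n, 40)),
         s2 = counts_df("chrI", pos, rpois(n, 60), rpois(n, 40)))
  })
  ini <- allele_frequency(tab$ini)
  sels <- list(allele_frequency(tab$s1), allele_frequency(tab$s2))
  r30 <- filter_sites(ini, sels, filter_config(min_depth = 30))
  r60 <- filter_sites(ini, sels, filter_config(min_depth = 60))
  expect_true(all(r60$pos %in% r30$pos))
  rn <- filter_sites(ini, sels, filter_config(af_band = c(0.4, 0.6)))
  expect_true(all(rn$pos %in% r30$pos))
  d <- delta_af(r30)
  c1 <- call_qtl_sites(d, filter_config(delta_threshold = 0.05))
  c2 <- call_qtl_sites(d, filter_config(delta_threshold = 0.15))
  expect_true(all(c2$pos %in% c1$pos))
})

test_that("merge_intervals clusters same-direction calls within max_gap", {
  calls <- data.frame(chrom = "chrI", pos = c(1e4, 2e4, 3e4),
                      delta_r1 = 0.2, delta_r2 = 0.2, direction = 1L)
  iv <- merge_intervals(calls, max_gap = 25000, min_sites = 3)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$end, iv$n_sites), c(1e4, 3e4, 3))
  expect_equal(iv$mean_abs_delta, 0.2)

  # 30 kb apart under a 25 kb gap: two singleton clusters, both dropped
  calls2 <- data.frame(chrom = "chrI", pos = c(1e4, 4e4),
                       delta_r1 = 0.2, delta_r2 = 0.2, direction = 1L)
  expect_equal(nrow(merge_intervals(calls2, 25000, 3)), 0L)
  # direction change splits a run
  calls3 <- data.frame(chrom = "chrI", pos = c(1:6) * 1e4,
                       delta_r1 = rep(c(0.2, -0.2), each = 3),
                       delta_r2 = rep(c(0.2, -0.2), each = 3),
                       direction = rep(c(1L, -1L), each = 3))
  iv3 <- merge_intervals(calls3, 25000, 3)
  expect_equal(nrow(iv3), 2L)
  expect_equal(iv3$direction, c(1L, -1L))
})

test_that("merge_intervals equals independent single-pass clustering", {
  for (s in 1:20) {
    calls <- withr::with_seed(s, {
      n <- sample(3:50, 1)
      data.frame(chrom = sample(c("chrI", "chrII"), n, TRUE),
                 pos = sample.int(5e5, n),
                 delta_r1 = 0.2, delta_r2 = 0.2,
                 direction = sample(c(1L, -1L), n, TRUE))
    })
    calls <- calls[!duplicated(calls[c("chrom", "pos")]), ]
    iv <- merge_intervals(calls, max_gap = 30000, min_sites = 2)
    orc <- oracle_clusters(calls$chrom, calls$pos, calls$direction, 30000, 2)
    expect_equal(nrow(iv), nrow(orc))
    if (nrow(iv)) {
      o1 <- order(iv$chrom, iv$start); o2 <- order(orc$chrom, orc$start)
      expect_equal(iv$start[o1], orc$start[o2])
      expect_equal(iv$end[o1], orc$end[o2])
      expect_equal(iv$n_sites[o1], orc$n_sites[o2])
    }
  }
})

test_that("subtelomere annotation uses inclusive end windows", {
  iv <- data.frame(chrom = "chrI", start = c(5000, 400000, 969001, 940000),
                   end = c(12000, 410000, 980000, 971000),
                   n_sites = 3L, mean_abs_delta = 0.2, direction = 1L)
  ann <- annotate_subtelomeric(iv, c(chrI = 1e6), window = 30000)
  # start in the left window; interior; end in the right window; end exactly
  # at length - window + 1 (inclusive boundary)
  expect_equal(ann$subtelomeric, c(TRUE, FALSE, TRUE, TRUE))
  iv$end[1] <- 2e6
  expect_error(annotate_subtelomeric(iv, c(chrI = 1e6)), "beyond")
  expect_error(annotate_subtelomeric(ann[, -7], c(other = 1e6)), "without")
})

test_that("BED export is 0-based half-open with capped scores", {
  iv <- data.frame(chrom = "chrI", start = 1001, end = 2000, n_sites = 3L,
                   mean_abs_delta = 1.5, direction = -1L, subtelomeric = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_intervals_bed(iv, path, name = "15C-SM")
  bed <- read.delim(path, header = FALSE)
  expect_equal(unlist(bed[1, 1:3], use.names = FALSE), c("chrI", "1000", "2000"))
  expect_equal(bed[[5]], 1000)  # capped
  expect_equal(bed[[6]], "-")
})
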