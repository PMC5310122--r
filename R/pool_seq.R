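#' Pooled-sequencing specification
#'
#' Minimal model of whole-genome sequencing of a segregant pool: read depth
#' per site is Poisson (optionally negative-binomial for overdispersion
#' stress tests), reads sample alleles binomially from the pool's true
#' frequency, and a symmetric per-read miscall turns each allele into the
#' other with probability `error_rate`.
#'
#' @param mean_depth expected reads per site (> 0).
#' @param error_rate per-read miscall probability toward the other allele,
#'   in `[0, 0.5)`.
#' @param overdispersion negative-binomial size parameter; `Inf` (default)
#'   gives pure Poisson depth.
#' @param seed optional integer seed.
#' @param pool_id label carried through to the counts table.
#' @return object of class `pool_spec`.
#' @export
pool_spec <- function(mean_depth = 100, error_rate = 0.005,
                      overdispersion = Inf, seed = NULL, pool_id = "pool") {
  assert_scalar_num(mean_depth, "mean_depth", lower = 1e-12)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5)
    stop_bsa("error_rate must be in [0, 0.5)")
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 overdispersion = overdispersion, seed = seed,
                 pool_id = pool_id),
            class = "pool_spec")
}

#' Simulate pooled-sequencing allele counts
#'
#' Per site: depth `d ~ Poisson(mean_depth)` (or negative binomial if
#' `overdispersion` is finite); `count_A ~ Binomial(d, p')` with
#' `p' = p(1 - e) + (1 - p)e`, the true parent-A frequency pushed toward
#' 0.5 by the symmetric error rate `e`; `count_B = d - count_A`. Sites with
#' `d = 0` are emitted with zero counts.
#'
#' @param true_freqs data.frame `chrom`, `pos`, `freq` (e.g. from
#'   [allele_dosage_frequencies()]).
#' @param spec a [pool_spec()].
#' @return object of class `pool_counts`: data.frame `chrom`, `pos`,
#'   `count_A`, `count_B` with attribute `pool_id`.
#' @export
simulate_pool_counts <- function(true_freqs, spec = pool_spec()) {
  stopifnot(all(c("chrom", "pos", "freq") %in% names(true_freqs)))
  p <- true_freqs$freq
  if (any(p < -1e-12 | p > 1 + 1e-12)) stop_bsa("true frequencies must be in [0, 1]")
  p <- pmin(pmax(p, 0), 1)
  m <- length(p)
  with_seed(spec$seed, {
    d <- if (is.finite(spec$overdispersion))
      rnbinom(m, size = spec$overdispersion, mu = spec$mean_depth)
    else rpois(m, spec$mean_depth)
    p2 <- p * (1 - spec$error_rate) + (1 - p) * spec$error_rate
    a <- rbinom(m, d, p2)
    new_pool_counts(data.frame(chrom = true_freqs$chrom, pos = true_freqs$pos,
                               count_A = a, count_B = d - a),
                    spec$pool_id)
  })
}

new_pool_counts <- function(records, pool_id = "pool") {
  stopifnot(all(c("chrom", "pos", "count_A", "count_B") %in% names(records)))
  if (any(records$count_A < 0) || any(records$count_B < 0))
    stop_bsa("negative counts")
  if (anyDuplicated(records[c("chrom", "pos")]))
    stop_bsa("duplicate sites in counts table")
  records <- records[order(records$chrom, records$pos), ]
  rownames(records) <- NULL
  structure(records, class = c("pool_counts", "data.frame"),
            pool_id = pool_id)
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts '%s': %d sites, mean depth %.1f\n",
              attr(x, "pool_id"), nrow(x), mean(x$count_A + x$count_B)))
  invisible(x)
}

#' Write / read a pool counts table as TSV
#'
#' Canonical format: header `chrom`, `pos`, `count_A`, `count_B`; rows
#' sorted by chromosome then position. The reader validates counts and
#' uniqueness and reports the offending line on failure.
#'
#' @param counts a `pool_counts` object.
#' @param path file path.
#' @param pool_id pool label to attach on read.
#' @return `read_counts_table` returns a `pool_counts`.
#' @export
write_counts_table <- function(counts, path) {
  stopifnot(inherits(counts, "pool_counts"))
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path, pool_id = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1L || !identical(strsplit(lines[1], "\t")[[1]],
                                       c("chrom", "pos", "count_A", "count_B")))
    stop_bsa("counts TSV must have header chrom\\tpos\\tcount_A\\tcount_B: ", path)
  if (length(lines) == 1L)
    return(new_pool_counts(data.frame(chrom = character(), pos = numeric(),
                                      count_A = integer(), count_B = integer()),
                           pool_id %||% basename(path)))
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) stop_bsa("malformed row at line ", bad[1] + 1L, " of ", path)
  df <- data.frame(chrom = vapply(fields, `[`, "", 1),
                   pos = suppressWarnings(as.numeric(vapply(fields, `[`, "", 2))),
                   count_A = suppressWarnings(as.integer(vapply(fields, `[`, "", 3))),
                   count_B = suppressWarnings(as.integer(vapply(fields, `[`, "", 4))))
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) stop_bsa("unparseable row at line ", bad[1] + 1L, " of ", path)
  bad <- which(df$count_A < 0 | df$count_B < 0)
  if (length(bad)) stop_bsa("negative count at line ", bad[1] + 1L, " of ", path)
  dup <- which(duplicated(df[c("chrom", "pos")]))
  if (length(dup)) stop_bsa("duplicate site at line ", dup[1] + 1L, " of ", path)
  new_pool_counts(df, pool_id %||% basename(path))
}

#' Read pool counts from a VCF with per-sample allelic depths
#'
#' Interoperability shim: a biallelic VCF whose FORMAT includes `AD`
#' (ref,alt allele depths) maps onto a `pool_counts` table, reading the REF
#' allele as parent A. One sample column = one pool. The TSV format of
#' [write_counts_table()] remains canonical.
#'
#' @param path VCF file (uncompressed).
#' @param sample sample name; default first sample.
#' @return a `pool_counts`.
#' @export
read_counts_vcf <- function(path, sample = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM"))
    stop_bsa("not a VCF: missing #CHROM header")
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  samples <- hdr[-(1:9)]
  if (!length(samples)) stop_bsa("VCF has no sample columns")
  sample <- sample %||% samples[1]
  sc <- match(sample, samples)
  if (is.na(sc)) stop_bsa("sample not in VCF: ", sample)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  rec <- lapply(rows, function(f) {
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    adi <- match("AD", fmt)
    if (is.na(adi)) stop_bsa("FORMAT lacks AD field")
    ad <- as.integer(strsplit(strsplit(f[9 + sc], ":", fixed = TRUE)[[1]][adi],
                              ",", fixed = TRUE)[[1]])
    if (length(ad) != 2L) stop_bsa("site ", f[1], ":", f[2], " is not biallelic")
    data.frame(chrom = f[1], pos = as.numeric(f[2]),
               count_A = ad[1], count_B = ad[2])
  })
  new_pool_counts(do.call(rbind, rec), sample)
}
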