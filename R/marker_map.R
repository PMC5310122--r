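#' Build a random biallelic marker map
#'
#' Places markers uniformly at random along each chromosome, sorts and
#' deduplicates them, and assigns genetic positions on a constant
#' recombination-rate scale. The map is the coordinate backbone for the
#' cross simulator, the pool-seq simulator and the QTL caller: it stands in
#' for the segregating SNP sites that distinguish two nearly isogenic
#' diploid parents.
#'
#' @param chrom_lengths named (or unnamed) numeric vector of chromosome
#'   lengths in bp; unnamed chromosomes are labelled `chrI`, `chrII`, ...
#' @param markers_per_chrom number of marker sites drawn per chromosome
#'   (duplicates collapse, so a chromosome may end up with fewer).
#' @param cM_per_Mb genetic map scale in cM per Mb. The yeast genome is
#'   roughly 380 cM over 12 Mb, i.e. ~31.7 cM/Mb.
#' @param seed integer seed; identical seeds give identical maps.
#' @return an object of class `marker_map`: list with `chromosomes`
#'   (data.frame: name, length) and `markers` (data.frame: chrom, pos, cM,
#'   sorted by chromosome then position).
#' @export
build_marker_map <- function(chrom_lengths, markers_per_chrom,
                             cM_per_Mb = 380 / 12, seed = NULL) {
  if (length(chrom_lengths) < 1L || any(chrom_lengths <= 0))
    stop_bsa("chrom_lengths must be positive")
  assert_scalar_num(markers_per_chrom, "markers_per_chrom", lower = 1)
  assert_scalar_num(cM_per_Mb, "cM_per_Mb", lower = 1e-12)
  nm <- names(chrom_lengths)
  if (is.null(nm)) nm <- paste0("chr", as.roman(seq_along(chrom_lengths)))
  if (anyDuplicated(nm)) stop_bsa("duplicate chromosome names")
  chrom_lengths <- as.numeric(chrom_lengths)
  markers <- with_seed(seed, {
    do.call(rbind, lapply(seq_along(chrom_lengths), function(i) {
      pos <- sort(unique(sample.int(chrom_lengths[i], markers_per_chrom,
                                    replace = TRUE)))
      data.frame(chrom = nm[i], pos = pos, cM = pos * cM_per_Mb / 1e6)
    }))
  })
  new_marker_map(data.frame(name = nm, length = chrom_lengths), markers)
}

new_marker_map <- function(chromosomes, markers) {
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            all(c("chrom", "pos", "cM") %in% names(markers)))
  markers$chrom <- as.character(markers$chrom)
  if (!all(markers$chrom %in% chromosomes$name))
    stop_bsa("marker on unknown chromosome")
  ord <- order(match(markers$chrom, chromosomes$name), markers$pos)
  markers <- markers[ord, c("chrom", "pos", "cM"), drop = FALSE]
  rownames(markers) <- NULL
  for (cn in chromosomes$name) {
    sub <- markers[markers$chrom == cn, ]
    if (nrow(sub) == 0) next
    if (anyDuplicated(sub$pos)) stop_bsa("duplicate marker positions on ", cn)
    if (min(sub$pos) < 1 ||
        max(sub$pos) > chromosomes$length[chromosomes$name == cn])
      stop_bsa("marker position outside chromosome ", cn)
    if (any(diff(sub$cM) < 0)) stop_bsa("genetic positions must be non-decreasing")
    if (any(sub$cM < 0)) stop_bsa("genetic positions must be >= 0")
  }
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "marker_map")
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d chromosomes, %d markers, %.1f cM total\n",
              nrow(x$chromosomes), nrow(x$markers), total_cM(x)))
  invisible(x)
}

n_markers <- function(map) nrow(map$markers)

total_cM <- function(map) {
  sum(vapply(split(map$markers$cM, map$markers$chrom), function(cm)
    if (length(cm)) max(cm) - min(cm) else 0, numeric(1)))
}

# Integer chromosome index (in map order) per marker, plus 0-based start
# offsets into the concatenated marker vector -- layout used by the C++ kernel.
map_layout <- function(map) {
  idx <- match(map$markers$chrom, map$chromosomes$name)
  counts <- tabulate(idx, nbins = nrow(map$chromosomes))
  starts <- cumsum(c(0L, head(counts, -1L)))
  list(chrom_idx = idx, counts = as.integer(counts), starts = as.integer(starts))
}

#' Write / read a marker map as TSV
#'
#' Canonical plain-text exchange format: header `chrom`, `pos` (1-based bp),
#' `cM`. Chromosome lengths are recorded as `##chrom=<name>,<length>` header
#' comments so the map round-trips exactly.
#'
#' @param map a `marker_map`.
#' @param path file path.
#' @return `read_marker_map` returns a `marker_map`.
#' @export
write_marker_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##chrom=%s,%d", map$chromosomes$name,
                     as.integer(map$chromosomes$length)), con)
  writeLines("chrom\tpos\tcM", con)
  writeLines(sprintf("%s\t%d\t%.10g", map$markers$chrom,
                     as.integer(map$markers$pos), map$markers$cM), con)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^##chrom=", lines)
  chrom <- do.call(rbind, lapply(sub("^##chrom=", "", lines[hdr]), function(s) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    data.frame(name = parts[1], length = as.numeric(parts[2]))
  }))
  body <- lines[!hdr]
  if (length(body) < 1L || body[1] != "chrom\tpos\tcM")
    stop_bsa("marker map TSV must start with header 'chrom\\tpos\\tcM'")
  markers <- read.delim(text = body, header = TRUE, stringsAsFactors = FALSE)
  new_marker_map(chrom, markers)
}
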