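#' Population and individual containers
#'
#' A population stores the two haplotypes of every diploid individual as
#' integer matrices (`n_individuals x n_markers`, allele code 0 = parent A,
#' 1 = parent B), together with non-negative abundance weights and a
#' generation label. The matrix layout keeps meiosis and allele-frequency
#' arithmetic vectorised; [diploid_individual()] gives the single-individual
#' view used by the trait and meiosis operations.
#'
#' @param hap1,hap2 integer matrices of allele codes in `{0,1}` with one row
#'   per individual and one column per marker of `map`.
#' @param map a [build_marker_map()] `marker_map`.
#' @param weights non-negative relative abundances, one per individual.
#' @param generation_label free-text label such as `"F13"` or `"SP-15C"`.
#' @param generation integer generation counter (F1 = 1).
#' @param ids individual labels.
#' @param validate check allele codes element-wise (disable only for
#'   kernel-generated matrices that are 0/1 by construction).
#' @return an object of class `bsa_population`.
#' @export
new_population <- function(hap1, hap2, map, weights = NULL,
                           generation_label = "F1", generation = 1L,
                           ids = NULL, validate = TRUE) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  n <- nrow(hap1)
  if (!identical(dim(hap1), dim(hap2)))
    stop_bsa("hap1 and hap2 must have identical dimensions")
  if (ncol(hap1) != n_markers(map))
    stop_bsa("haplotype width does not match marker count of the map")
  if (validate && (!all(hap1 %in% c(0L, 1L)) || !all(hap2 %in% c(0L, 1L))))
    stop_bsa("allele codes must be 0 or 1")
  weights <- weights %||% rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop_bsa("weights must be non-negative, one per individual, with positive sum")
  ids <- ids %||% sprintf("ind%04d", seq_len(n))
  structure(list(hap1 = hap1, hap2 = hap2, map = map,
                 weights = as.numeric(weights),
                 generation_label = generation_label,
                 generation = as.integer(generation), ids = as.character(ids)),
            class = "bsa_population")
}

#' @export
print.bsa_population <- function(x, ...) {
  cat(sprintf("bsa_population '%s': %d individuals x %d markers\n",
              x$generation_label, nrow(x$hap1), ncol(x$hap1)))
  invisible(x)
}

n_individuals <- function(pop) nrow(pop$hap1)

#' @param pop a `bsa_population`.
#' @param i individual row index.
#' @rdname new_population
#' @export
diploid_individual <- function(pop, i) {
  structure(list(hap1 = pop$hap1[i, ], hap2 = pop$hap2[i, ],
                 map = pop$map, id = pop$ids[i]),
            class = "diploid_individual")
}

#' Construct the two homozygous-divergent parents
#'
#' Parent A (the superior strain) is homozygous for allele code 0 at every
#' marker, parent B (the inferior strain) homozygous for code 1 — the
#' idealisation of two nearly isogenic wine strains that differ at all
#' segregating marker sites.
#'
#' @param map a `marker_map`.
#' @return list with elements `A` and `B`, each a `diploid_individual`.
#' @export
make_parents <- function(map) {
  m <- n_markers(map)
  list(A = structure(list(hap1 = rep(0L, m), hap2 = rep(0L, m), map = map,
                          id = "parentA"), class = "diploid_individual"),
       B = structure(list(hap1 = rep(1L, m), hap2 = rep(1L, m), map = map,
                          id = "parentB"), class = "diploid_individual"))
}

#' The F1 hybrid population
#'
#' Every F1 individual is the same genotype: heterozygous at all markers
#' (one gamete from each fully homozygous parent).
#'
#' @param map a `marker_map`.
#' @param n number of (identical) F1 individuals.
#' @return a `bsa_population` labelled `"F1"`.
#' @export
f1_population <- function(map, n = 2L) {
  m <- n_markers(map)
  new_population(matrix(0L, n, m), matrix(1L, n, m), map,
                 generation_label = "F1", generation = 1L)
}

#' Single meiosis of a diploid individual
#'
#' Haldane model: the crossover count on each chromosome is Poisson with
#' mean equal to the chromosome's genetic length (marker span) in Morgans,
#' crossover positions are uniform in genetic coordinates, the starting
#' phase is a fair coin, and there is no interference or obligate chiasma.
#'
#' @param ind a `diploid_individual` (see [diploid_individual()]).
#' @param map the `marker_map` the individual is defined on.
#' @param seed optional integer seed.
#' @return integer vector of allele codes (the gamete), with attribute
#'   `crossovers`: crossover count per chromosome.
#' @export
meiosis <- function(ind, map = ind$map, seed = NULL) {
  lay <- map_layout(map)
  res <- with_seed(seed,
    sim_gametes_cpp(matrix(ind$hap1, ncol = 1), matrix(ind$hap2, ncol = 1),
                    1L, map$markers$cM, lay$starts, lay$counts))
  structure(as.integer(res$gametes), crossovers = as.integer(res$crossovers))
}

# Vectorised meioses: one gamete (row) per entry of parent_idx. The C++
# kernel works marker-major, so transpose going in and out.
sim_gametes <- function(pop, parent_idx) {
  lay <- map_layout(pop$map)
  t(sim_gametes_cpp(t(pop$hap1), t(pop$hap2), as.integer(parent_idx),
                    pop$map$markers$cM, lay$starts, lay$counts)$gametes)
}

#' Advance a population by random intercrossing
#'
#' Each offspring is produced by drawing two distinct parents with
#' probability proportional to their weights and combining one gamete from
#' each ([meiosis()]). Repeated for `target_generation - pop$generation`
#' rounds; offspring get equal weights. This is the advanced-intercross-line
#' design that expands the genetic map through repeated rounds of
#' recombination (F1 -> F13 by default elsewhere in the package).
#'
#' @param pop starting `bsa_population`.
#' @param target_generation generation to advance to (>= `pop$generation`).
#' @param pop_size offspring per generation (>= 2).
#' @param seed optional integer seed.
#' @return a `bsa_population` labelled `"F<target_generation>"`.
#' @export
advance_intercross <- function(pop, target_generation, pop_size = 5000L,
                               seed = NULL) {
  stopifnot(inherits(pop, "bsa_population"))
  target_generation <- as.integer(target_generation)
  if (target_generation < pop$generation)
    stop_bsa("target_generation is before the population's generation")
  if (target_generation == pop$generation) return(pop)
  if (pop_size < 2L) stop_bsa("pop_size must be >= 2 to draw distinct parents")
  rounds <- target_generation - pop$generation
  seeds <- derive_seeds(seed, rounds)
  for (r in seq_len(rounds)) {
    pop <- with_seed(seeds[r], {
      n <- n_individuals(pop)
      prob <- pop$weights / sum(pop$weights)
      p1 <- sample.int(n, pop_size, replace = TRUE, prob = prob)
      p2 <- sample.int(n, pop_size, replace = TRUE, prob = prob)
      while (any(clash <- p2 == p1 & n > 1L))
        p2[clash] <- sample.int(n, sum(clash), replace = TRUE, prob = prob)
      lay <- map_layout(pop$map)
      gam <- sim_gametes_cpp(t(pop$hap1), t(pop$hap2), c(p1, p2),
                             pop$map$markers$cM, lay$starts,
                             lay$counts)$gametes
      # kernel output is 0/1 by construction; skip the element-wise check
      new_population(t(gam[, seq_len(pop_size), drop = FALSE]),
                     t(gam[, pop_size + seq_len(pop_size), drop = FALSE]),
                     pop$map,
                     generation_label = paste0("F", pop$generation + 1L),
                     generation = pop$generation + 1L, validate = FALSE)
    })
  }
  pop$generation_label <- paste0("F", target_generation)
  pop
}

#' Weighted parent-A allele dosage frequencies
#'
#' The population's true allele-frequency table: per marker, the
#' weight-averaged parent-A dosage divided by 2. This is the ground truth
#' the pooled-sequencing simulator samples from.
#'
#' @param pop a `bsa_population`.
#' @return data.frame with columns `chrom`, `pos`, `freq` (parent-A
#'   frequency in `[0, 1]`).
#' @export
allele_dosage_frequencies <- function(pop) {
  stopifnot(inherits(pop, "bsa_population"))
  if (n_individuals(pop) == 0L) stop_bsa("empty population")
  w <- pop$weights
  if (sum(w) <= 0) stop_bsa("population weights sum to zero")
  # dosage of parent-A allele = number of code-0 alleles = 2 - (hap1 + hap2)
  dosB <- crossprod(w, pop$hap1 + pop$hap2)  # weighted parent-B dosage
  freq <- 1 - as.numeric(dosB) / (2 * sum(w))
  data.frame(chrom = pop$map$markers$chrom, pos = pop$map$markers$pos,
             freq = freq)
}

#' Dump population genotypes as a TSV snapshot
#'
#' Long format: `id`, `chrom`, `pos`, `dosage` (parent-A allele count 0/1/2).
#'
#' @param pop a `bsa_population`.
#' @param path output file.
#' @export
write_population_snapshot <- function(pop, path) {
  dosA <- 2L - (pop$hap1 + pop$hap2)
  df <- data.frame(
    id = rep(pop$ids, times = ncol(dosA)),
    chrom = rep(pop$map$markers$chrom, each = nrow(dosA)),
    pos = rep(pop$map$markers$pos, each = nrow(dosA)),
    dosage = as.vector(dosA))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
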