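#' Additive trait architecture
#'
#' The simulated growth-rate trait is additive: each QTL contributes
#' `effect` h^-1 per copy of the parent-A allele on top of baseline `mu0`,
#' plus Normal environmental noise with SD `sigma_e`. A synthetic stand-in
#' for the polygenic low-temperature growth-rate trait segregating between
#' the two parent strains.
#'
#' @param map a `marker_map`.
#' @param qtls data.frame with columns `chrom`, `pos` (an existing marker
#'   position) and `effect` (h^-1 per parent-A allele copy).
#' @param mu0 baseline maximum specific growth rate (h^-1).
#' @param sigma_e environmental SD (h^-1), `>= 0`.
#' @return object of class `trait_arch` with the QTLs resolved to marker
#'   column indices.
#' @export
trait_architecture <- function(map, qtls = NULL, mu0 = 0.25, sigma_e = 0) {
  assert_scalar_num(mu0, "mu0")
  assert_scalar_num(sigma_e, "sigma_e", lower = 0)
  if (is.null(qtls) || nrow(qtls) == 0) {
    qtls <- data.frame(chrom = character(), pos = numeric(),
                       effect = numeric(), marker = integer())
  } else {
    stopifnot(all(c("chrom", "pos", "effect") %in% names(qtls)))
    key <- paste(map$markers$chrom, map$markers$pos)
    idx <- match(paste(qtls$chrom, qtls$pos), key)
    if (anyNA(idx)) stop_bsa("QTL position is not a marker on the map")
    qtls <- data.frame(chrom = as.character(qtls$chrom), pos = qtls$pos,
                       effect = qtls$effect, marker = idx)
  }
  structure(list(qtls = qtls, mu0 = mu0, sigma_e = sigma_e, map = map),
            class = "trait_arch")
}

# Genetic values (h^-1) for all individuals: mu0 + sum_k a_k * dosageA_k.
genetic_values <- function(pop, arch) {
  gv <- rep(arch$mu0, n_individuals(pop))
  for (k in seq_len(nrow(arch$qtls))) {
    j <- arch$qtls$marker[k]
    dosA <- 2L - (pop$hap1[, j] + pop$hap2[, j])
    gv <- gv + arch$qtls$effect[k] * dosA
  }
  gv
}

#' Trait value of individuals
#'
#' `mu = mu0 + sum_k a_k d_k + eps` with `d_k` the parent-A allele dosage
#' (0, 1, 2) at QTL `k` and `eps ~ Normal(0, sigma_e^2)`. The genetic part
#' is deterministic given the genotype.
#'
#' @param ind a `diploid_individual`.
#' @param arch a [trait_architecture()].
#' @param seed optional integer seed for the environmental draw.
#' @return maximum specific growth rate in h^-1.
#' @export
trait_value <- function(ind, arch, seed = NULL) {
  gv <- arch$mu0
  for (k in seq_len(nrow(arch$qtls))) {
    j <- arch$qtls$marker[k]
    gv <- gv + arch$qtls$effect[k] * (2L - (ind$hap1[j] + ind$hap2[j]))
  }
  gv + with_seed(seed, rnorm(1, 0, arch$sigma_e))
}

#' @param pop a `bsa_population`.
#' @rdname trait_value
#' @return `trait_values`: numeric vector, one value per individual.
#' @export
trait_values <- function(pop, arch, seed = NULL) {
  genetic_values(pop, arch) +
    with_seed(seed, rnorm(n_individuals(pop), 0, arch$sigma_e))
}

#' Set the environmental SD to hit a target broad-sense heritability
#'
#' Computes the realised additive genetic variance of `arch` in `pop` and
#' returns a copy of `arch` with `sigma_e = sigma_g * sqrt((1 - H2) / H2)`,
#' so that genetic variance / total variance equals `h2` in this population.
#'
#' @param arch a `trait_arch`.
#' @param pop the population whose genetic variance defines the target.
#' @param h2 target heritability as a fraction in (0, 1].
#' @return `arch` with `sigma_e` replaced.
#' @export
tune_environmental_sd <- function(arch, pop, h2) {
  assert_scalar_num(h2, "h2", lower = 1e-9, upper = 1)
  vg <- var(genetic_values(pop, arch))
  arch$sigma_e <- sqrt(vg * (1 - h2) / h2)
  arch
}

#' Write the planted-QTL truth table as TSV
#'
#' Columns `chrom`, `pos`, `effect` — ground truth for [match_intervals()].
#'
#' @param arch a `trait_arch`.
#' @param path output file.
#' @export
write_truth_table <- function(arch, path) {
  write.table(arch$qtls[, c("chrom", "pos", "effect")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "effect") %in% names(df)))
  df
}
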