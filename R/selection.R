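#' Serial-dilution selection experiment configuration
#'
#' Defaults mirror the study design this package emulates: 8 rounds of
#' batch serial dilution, about 6.25 generations of clonal doubling per
#' round, so the whole experiment spans approximately 50 generations.
#'
#' @param rounds number of dilution rounds (>= 0).
#' @param generations_per_round clonal doublings per round (> 0).
#' @param bottleneck_size census after each dilution (>= 1); `Inf` disables
#'   the bottleneck (deterministic weight propagation).
#' @param seed optional integer seed.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(rounds = 8L, generations_per_round = 6.25,
                             bottleneck_size = 5000L, seed = NULL) {
  assert_scalar_num(rounds, "rounds", lower = 0)
  assert_scalar_num(generations_per_round, "generations_per_round", lower = 1e-12)
  if (!(is.numeric(bottleneck_size) && length(bottleneck_size) == 1L &&
        (is.infinite(bottleneck_size) || bottleneck_size >= 1)))
    stop_bsa("bottleneck_size must be >= 1 (or Inf to disable)")
  structure(list(rounds = as.integer(rounds),
                 generations_per_round = generations_per_round,
                 bottleneck_size = bottleneck_size, seed = seed),
            class = "selection_config")
}

#' Asexual batch serial-dilution selection
#'
#' Models competitive clonal growth between dilutions: in each round every
#' individual's abundance weight is multiplied by `exp(mu_i * g * ln 2)`
#' (`g` = generations per round), i.e. faster growers enrich exponentially,
#' and the culture is then bottlenecked by multinomial resampling to
#' `bottleneck_size` with weight-proportional probabilities. No mating
#' occurs during selection; the individuals are fixed clonal lineages and
#' only their weights change. Environmental noise (`arch$sigma_e`) is
#' redrawn independently every round, emulating batch-to-batch
#' micro-environment variation.
#'
#' @param pop a `bsa_population` (typically the F13 intercross).
#' @param arch a [trait_architecture()] giving each lineage's growth rate.
#' @param cfg a [selection_config()].
#' @return the post-selection `bsa_population` with updated weights and a
#'   `"+sel<rounds>"` suffix on its label.
#' @export
serial_dilution_selection <- function(pop, arch, cfg = selection_config()) {
  stopifnot(inherits(pop, "bsa_population"), inherits(arch, "trait_arch"),
            inherits(cfg, "selection_config"))
  if (cfg$rounds == 0L) return(pop)
  gv <- genetic_values(pop, arch)
  n <- n_individuals(pop)
  seeds <- derive_seeds(cfg$seed, cfg$rounds)
  w <- pop$weights
  for (r in seq_len(cfg$rounds)) {
    w <- with_seed(seeds[r], {
      mu <- gv + rnorm(n, 0, arch$sigma_e)
      # rescale by the max first: exp(mu * g * ln2) overflows for large g*mu
      lw <- log(w) + mu * cfg$generations_per_round * log(2)
      w2 <- exp(lw - max(lw[is.finite(lw)]))
      w2[w == 0] <- 0
      if (sum(w2) <= 0) stop_bsa("population extinct in selection round ", r)
      if (is.finite(cfg$bottleneck_size))
        w2 <- as.numeric(rmultinom(1, cfg$bottleneck_size, w2 / sum(w2)))
      if (sum(w2) <= 0) stop_bsa("population extinct in selection round ", r)
      w2
    })
  }
  pop$weights <- w
  pop$generation_label <- paste0(pop$generation_label, "+sel", cfg$rounds)
  pop
}
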