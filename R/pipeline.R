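#' Build and validate a pipeline run configuration
#'
#' A single nested list drives the end-to-end pipeline: map geometry,
#' intercross design, trait architecture, selection experiment, pooled
#' sequencing, QTL-caller thresholds, interval assembly and truth matching.
#' Unknown keys are rejected so config typos fail loudly. All defaults are
#' the package's stated experimental world: F13 intercross of 5000
#' diploids, 8 selection rounds of ~6.25 generations, pools at 100x depth,
#' the published site filters (30 reads, 30-70% band, delta 0.1), and 2
#' replicate selection lines.
#'
#' @param ... overrides for any section; see Details in the package
#'   vignette. Each section is itself a list, e.g.
#'   `selection = list(rounds = 4)`.
#' @param seed master integer seed; all stage seeds derive from it.
#' @return validated config (class `run_config`).
#' @export
run_config <- function(..., seed = 1L) {
  defaults <- list(
    map = list(chrom_lengths = setNames(rep(1e6, 16),
                                        paste0("chr", as.roman(1:16))),
               markers_per_chrom = 100L, cM_per_Mb = 380 / 12),
    cross = list(target_generation = 13L, pop_size = 5000L),
    trait = list(qtls = list(n = 3L, effect = 0.03), mu0 = 0.25,
                 h2 = 0.65),
    selection = list(rounds = 8L, generations_per_round = 6.25,
                     bottleneck_size = 5000L, n_replicates = 2L),
    pools = list(mean_depth = 100, error_rate = 0.005),
    filter = list(min_depth = 30, af_band = c(0.30, 0.70),
                  delta_threshold = 0.1),
    intervals = list(max_gap = 25000, min_sites = 3L,
                     subtelomere_window = 30000),
    evaluate = list(tolerance = 50000),
    phenotype = list(n_segregants = 96L, parent_replicates = 3L)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop_bsa("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(overrides)) {
    bad <- setdiff(names(overrides[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop_bsa("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
    defaults[[sec]][names(overrides[[sec]])] <- overrides[[sec]]
  }
  defaults$seed <- as.integer(seed)
  structure(defaults, class = "run_config")
}

# Resolve the trait section against a concrete map: either explicit QTLs
# (list/data.frame with chrom, pos, effect) or auto-placement of n QTLs at
# a random marker on n distinct chromosomes.
resolve_trait <- function(cfg, map, pop, seed) {
  tr <- cfg$trait
  q <- tr$qtls
  if (!is.null(q$n)) {
    qtls <- with_seed(seed, {
      chroms <- sample(map$chromosomes$name, q$n)
      do.call(rbind, lapply(chroms, function(cn) {
        sub <- map$markers[map$markers$chrom == cn, ]
        i <- sample.int(nrow(sub), 1)
        data.frame(chrom = cn, pos = sub$pos[i], effect = q$effect)
      }))
    })
  } else {
    qtls <- as.data.frame(do.call(rbind, lapply(q, function(x)
      data.frame(chrom = x$chrom, pos = x$pos, effect = x$effect))))
  }
  arch <- trait_architecture(map, qtls, mu0 = tr$mu0, sigma_e = 0)
  if (!is.null(tr$h2) && nrow(arch$qtls) > 0 && tr$h2 < 1)
    arch <- tune_environmental_sd(arch, pop, tr$h2)
  arch
}

#' Run the full simulation-to-evaluation pipeline
#'
#' Stages: build map -> F1 -> advanced intercross to F13 -> resolve trait
#' architecture (optionally tuning `sigma_e` to the target heritability)
#' -> N replicate serial-dilution selection lines -> pooled sequencing of
#' the initial and selected pools -> site filtering, delta-AF calling,
#' interval assembly, subtelomere annotation -> truth matching, plus a
#' phenotype panel (heritability, transgression) measured on simulated
#' segregants. Every stage writes its table under `out_dir`, a structured
#' log records stage, seed and row counts, and `summary.json` holds the
#' machine-readable results. Identical config (including seed) reproduces
#' byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output and just returns the results.
#' @return invisible list: `map`, `arch`, `f13`, `selected`, `counts`,
#'   `qtl` (retained/calls/intervals), `recovery`, `phenotype`, `summary`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  logf <- function(stage, ...) {
    line <- sprintf("stage=%s seed=%d %s", stage, cfg$seed,
                    paste(..., collapse = " "))
    log_lines <<- c(log_lines, line)
  }
  seeds <- derive_seeds(cfg$seed, 8L + cfg$selection$n_replicates * 2L)

  map <- build_marker_map(cfg$map$chrom_lengths, cfg$map$markers_per_chrom,
                          cfg$map$cM_per_Mb, seed = seeds[1])
  logf("map", sprintf("markers=%d", n_markers(map)))

  f13 <- advance_intercross(f1_population(map), cfg$cross$target_generation,
                            cfg$cross$pop_size, seed = seeds[2])
  logf("intercross", sprintf("generation=%d n=%d", f13$generation,
                             n_individuals(f13)))

  arch <- resolve_trait(cfg, map, f13, seeds[3])
  logf("trait", sprintf("qtls=%d sigma_e=%.4g", nrow(arch$qtls), arch$sigma_e))

  nrep <- cfg$selection$n_replicates
  selected <- lapply(seq_len(nrep), function(r) {
    scfg <- selection_config(cfg$selection$rounds,
                             cfg$selection$generations_per_round,
                             cfg$selection$bottleneck_size,
                             seed = seeds[8L + r])
    serial_dilution_selection(f13, arch, scfg)
  })
  logf("selection", sprintf("replicates=%d rounds=%d", nrep,
                            cfg$selection$rounds))

  pool_of <- function(pop, id, seed)
    simulate_pool_counts(allele_dosage_frequencies(pop),
                         pool_spec(cfg$pools$mean_depth, cfg$pools$error_rate,
                                   seed = seed, pool_id = id))
  counts <- c(list(initial = pool_of(f13, "F13", seeds[4])),
              setNames(lapply(seq_len(nrep), function(r)
                pool_of(selected[[r]], paste0("sel_r", r), seeds[8L + nrep + r])),
                paste0("sel_r", seq_len(nrep))))
  logf("poolseq", sprintf("pools=%d depth=%g", length(counts),
                          cfg$pools$mean_depth))

  fcfg <- filter_config(cfg$filter$min_depth, cfg$filter$af_band,
                        cfg$filter$delta_threshold)
  chrom_lengths <- setNames(map$chromosomes$length, map$chromosomes$name)
  qtl <- map_qtl(counts$initial, counts[-1], chrom_lengths, fcfg,
                 max_gap = cfg$intervals$max_gap,
                 min_sites = cfg$intervals$min_sites,
                 window = cfg$intervals$subtelomere_window)
  logf("map_qtl", sprintf("retained=%d calls=%d intervals=%d",
                          nrow(qtl$retained), nrow(qtl$calls),
                          nrow(qtl$intervals)))

  recovery <- match_intervals(qtl$intervals, arch$qtls,
                              tolerance = cfg$evaluate$tolerance)
  logf("evaluate", sprintf("tp=%d fp=%d fn=%d", recovery$tp, recovery$fp,
                           recovery$fn))

  phenotype <- NULL
  if (!is.null(cfg$phenotype)) {
    phenotype <- with_seed(seeds[5], {
      idx <- sample.int(n_individuals(f13), cfg$phenotype$n_segregants,
                        replace = cfg$phenotype$n_segregants > n_individuals(f13))
      seg <- genetic_values(f13, arch)[idx] +
        rnorm(length(idx), 0, arch$sigma_e)
      parents <- make_parents(map)
      pa <- replicate(cfg$phenotype$parent_replicates,
                      trait_value(parents$A, arch))
      pb <- replicate(cfg$phenotype$parent_replicates,
                      trait_value(parents$B, arch))
      panel <- phenotype_panel(seg, pa, pb)
      tg <- transgression(panel)
      h2 <- tryCatch(suppressWarnings(heritability(panel)),
                     error = function(e) NA_real_)
      list(h2_percent = h2, transgression = tg)
    })
    logf("phenotype", sprintf("n_seg=%d h2=%.1f", cfg$phenotype$n_segregants,
                              phenotype$h2_percent))
  }

  summary <- list(
    config = unclass(cfg),
    n_markers = n_markers(map),
    truth = arch$qtls[, c("chrom", "pos", "effect")],
    n_retained = nrow(qtl$retained),
    n_calls = nrow(qtl$calls),
    intervals = qtl$intervals,
    recovery = list(tp = recovery$tp, fp = recovery$fp, fn = recovery$fn,
                    power = recovery$power, fdr = recovery$fdr),
    phenotype = phenotype)

  if (!is.null(out_dir)) {
    write_marker_map(map, file.path(out_dir, "marker_map.tsv"))
    write_truth_table(arch, file.path(out_dir, "truth.tsv"))
    for (nm in names(counts))
      write_counts_table(counts[[nm]], file.path(out_dir, paste0("counts_", nm, ".tsv")))
    write.table(qtl$retained, file.path(out_dir, "retained_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(qtl$calls, file.path(out_dir, "qtl_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(qtl$intervals, file.path(out_dir, "qtl_intervals.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(qtl$intervals))
      write_intervals_bed(qtl$intervals, file.path(out_dir, "qtl_intervals.bed"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(list(map = map, arch = arch, f13 = f13, selected = selected,
                 counts = counts, qtl = qtl, recovery = recovery,
                 phenotype = phenotype, summary = summary, log = log_lines))
}
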