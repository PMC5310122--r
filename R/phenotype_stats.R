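#' Phenotype panel: segregant values plus parental replicates
#'
#' Container for the segregant-phenotyping statistics. Parental replicate
#' lists estimate the environmental variance; the segregant distribution
#' carries both genetic and environmental variance.
#'
#' @param segregants numeric vector of segregant phenotypes (e.g. `mu_max`
#'   in h^-1), non-empty.
#' @param parent_a,parent_b numeric replicate measurements of each parent,
#'   at least 2 each.
#' @return object of class `phenotype_panel`.
#' @export
phenotype_panel <- function(segregants, parent_a, parent_b) {
  if (!length(segregants)) stop_bsa("segregant list must be non-empty")
  if (length(parent_a) < 2L || length(parent_b) < 2L)
    stop_bsa("need >= 2 replicates per parent to estimate variance")
  structure(list(segregants = as.numeric(segregants),
                 parent_a = as.numeric(parent_a),
                 parent_b = as.numeric(parent_b)),
            class = "phenotype_panel")
}

# df-weighted pooled variance of the two parental replicate sets
pooled_parent_var <- function(panel) {
  n1 <- length(panel$parent_a); n2 <- length(panel$parent_b)
  ((n1 - 1) * var(panel$parent_a) + (n2 - 1) * var(panel$parent_b)) /
    (n1 + n2 - 2)
}

#' Broad-sense heritability from a segregant panel
#'
#' `H2 = ((Var_seg - Var_env) / Var_seg) * 100`, where `Var_env` is the
#' pooled (df-weighted) variance among parental replicate measurements and
#' `Var_seg` the variance among segregant phenotypes. Can be negative when
#' sampling noise makes `Var_env > Var_seg`; a negative value is returned
#' with a warning rather than clamped.
#'
#' @param panel a [phenotype_panel()].
#' @return heritability in percent.
#' @export
heritability <- function(panel) {
  stopifnot(inherits(panel, "phenotype_panel"))
  var_seg <- var(panel$segregants)
  if (!isTRUE(var_seg > 0)) stop_bsa("Var_seg is zero: heritability undefined")
  h2 <- (var_seg - pooled_parent_var(panel)) / var_seg * 100
  if (h2 < 0) warning("negative heritability estimate (Var_env > Var_seg)")
  h2
}

#' Transgressive segregation counts
#'
#' A segregant is transgressive if its phenotype lies at least two pooled
#' parental standard deviations above the mean of the higher parent, or at
#' least 2 sigma below the mean of the lower parent (thresholds inclusive).
#'
#' @param panel a [phenotype_panel()].
#' @return list: `n_high`, `n_low`, `frac_high`, `frac_low`.
#' @export
transgression <- function(panel) {
  stopifnot(inherits(panel, "phenotype_panel"))
  sigma <- sqrt(pooled_parent_var(panel))
  mA <- mean(panel$parent_a); mB <- mean(panel$parent_b)
  hi <- max(mA, mB) + 2 * sigma
  lo <- min(mA, mB) - 2 * sigma
  n_high <- sum(panel$segregants >= hi)
  n_low <- sum(panel$segregants <= lo)
  n <- length(panel$segregants)
  list(n_high = n_high, n_low = n_low,
       frac_high = n_high / n, frac_low = n_low / n)
}

#' Number of generations between two OD readings
#'
#' `n = log(Nt / N0) / log(2)` — doublings between inoculation and time t.
#'
#' @param N0 initial OD600 (> 0).
#' @param Nt OD600 at time t (> 0).
#' @return generations (may be fractional or negative).
#' @export
generations <- function(N0, Nt) {
  if (any(N0 <= 0) || any(Nt <= 0)) stop_bsa("OD values must be > 0")
  log(Nt / N0) / log(2)
}

#' Fermentation completion time (T100)
#'
#' The time at which must density first drops to the completion threshold
#' (995 g/L by convention: all sugars consumed), linearly interpolated
#' between the bracketing samples. Returns `NA` (a stuck fermentation) if
#' the threshold is never reached.
#'
#' @param times hours, strictly increasing.
#' @param density must density in g/L aligned to `times`.
#' @param threshold completion density in g/L.
#' @return object of class `fermentation_summary`: list with `t100` (hours
#'   or `NA`) and `stuck` flag.
#' @export
t100 <- function(times, density, threshold = 995) {
  if (length(times) != length(density)) stop_bsa("times and density differ in length")
  if (length(times) < 2L) stop_bsa("need at least 2 samples")
  if (any(diff(times) <= 0)) stop_bsa("times must be strictly increasing")
  if (density[1] <= threshold)
    stop_bsa("density series starts at or below the threshold: already complete")
  idx <- which(density <= threshold)
  if (!length(idx))
    return(structure(list(t100 = NA_real_, stuck = TRUE),
                     class = "fermentation_summary"))
  i <- idx[1]
  # linear interpolation on the bracketing segment [i-1, i]
  t <- times[i - 1] + (times[i] - times[i - 1]) *
    (density[i - 1] - threshold) / (density[i - 1] - density[i])
  structure(list(t100 = t, stuck = FALSE), class = "fermentation_summary")
}

#' @export
print.fermentation_summary <- function(x, ...) {
  if (x$stuck) cat("fermentation: STUCK (threshold never reached)\n")
  else cat(sprintf("fermentation: T100 = %.2f h\n", x$t100))
  invisible(x)
}

#' Relative T100 against a control strain
#'
#' The strain's completion time normalised by the control's (control vs
#' itself = 1). A stuck strain propagates as stuck (`NA` ratio, rendered as
#' the "#" flag in figures); a stuck control is an error.
#'
#' @param strain,control [t100()] summaries.
#' @return `fermentation_summary` whose `t100` field holds the ratio.
#' @export
relative_t100 <- function(strain, control) {
  stopifnot(inherits(strain, "fermentation_summary"),
            inherits(control, "fermentation_summary"))
  if (control$stuck) stop_bsa("control fermentation is stuck: ratio undefined")
  if (strain$stuck)
    return(structure(list(t100 = NA_real_, stuck = TRUE),
                     class = "fermentation_summary"))
  structure(list(t100 = strain$t100 / control$t100, stuck = FALSE),
            class = "fermentation_summary")
}

#' Compare replicate groups against a control with Bonferroni correction
#'
#' Two-tailed two-sample Student t-test (pooled variance; set
#' `var_equal = FALSE` for Welch) of every strain against the control
#' group. Raw p-values are Bonferroni-corrected within the family of all
#' non-control strains; a strain is flagged significant when its adjusted
#' p-value is at most `alpha`.
#'
#' @param groups named list of numeric replicate vectors (>= 2 each).
#' @param control_label name of the control group in `groups`.
#' @param alpha significance level after correction.
#' @param var_equal use the classical pooled-variance t-test (default).
#' @return data.frame: strain, mean, t, p_raw, p_adj, significant.
#' @export
compare_to_control <- function(groups, control_label, alpha = 0.05,
                               var_equal = TRUE) {
  if (!control_label %in% names(groups))
    stop_bsa("control group '", control_label, "' not found")
  if (any(lengths(groups) < 2L)) stop_bsa("every group needs >= 2 replicates")
  ctrl <- groups[[control_label]]
  strains <- setdiff(names(groups), control_label)
  res <- do.call(rbind, lapply(strains, function(s) {
    x <- groups[[s]]
    if (sd(x) == 0 && sd(ctrl) == 0) {
      # degenerate: no variance anywhere; equal means are "no evidence"
      tt <- list(statistic = if (mean(x) == mean(ctrl)) 0 else Inf * sign(mean(x) - mean(ctrl)),
                 p.value = if (mean(x) == mean(ctrl)) 1 else 0)
    } else {
      tt <- t.test(x, ctrl, var.equal = var_equal)
    }
    data.frame(strain = s, mean = mean(x),
               t = unname(tt$statistic), p_raw = tt$p.value)
  }))
  res$p_adj <- pmin(1, res$p_raw * length(strains))
  res$significant <- res$p_adj <= alpha
  res
}
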