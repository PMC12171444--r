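#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic study: the 3 x 4 factorial split-plot
#' design (three green-manure patterns x four nitrogen levels x replicates),
#' the community-assembly regime, and the gas-curve parameters. Defaults
#' mirror the field design: patterns NG/OVG/VVG, levels N0..N3 (0/50/75/100%
#' of the conventional 225 kg N ha^-1), three replicates, 36 plots.
#'
#' @param seed master integer RNG seed; every artifact derives its own stream
#'   from it, so a fixed seed gives byte-identical outputs.
#' @param n_asvs number of ASVs in simulated communities (>= 10 for realistic
#'   tables; >= 1 accepted for degenerate test cases).
#' @param depth sequencing depth per sample (reads).
#' @param regime community-assembly regime: \code{"neutral"},
#'   \code{"selection"} or \code{"dispersal_limited"}.
#' @param migration_m migration rate m in (0, 1] for the neutral regime.
#' @param pool_size effective source-pool size used to set the log-series
#'   shape (individuals).
#' @param fisher_alpha Fisher's alpha of the log-series source pool.
#' @param gradient_strength precision of the Gaussian niche kernel
#'   (0 = no selection, i.e. the neutral limit).
#' @param patterns,n_levels,replicates factor levels of the split-plot design.
#' @param flux_params named list of gas-curve parameters, see
#'   \code{\link{simulate_gas_series}} for fields and defaults.
#' @return An object of class \code{synth_config}.
#' @examples
#' cfg <- synth_config(seed = 1, n_asvs = 40, migration_m = 0.3)
#' @export
synth_config <- function(seed = 1L,
                         n_asvs = 50L,
                         depth = 5000L,
                         regime = c("neutral", "selection", "dispersal_limited"),
                         migration_m = 0.3,
                         pool_size = 1e5,
                         fisher_alpha = 20,
                         gradient_strength = 30,
                         patterns = c("NG", "OVG", "VVG"),
                         n_levels = c("N0", "N1", "N2", "N3"),
                         replicates = 3L,
                         flux_params = list()) {
  regime <- match.arg(regime)
  .check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
         "`seed` must be a single finite number")
  .check(n_asvs >= 1, "`n_asvs` must be >= 1")
  .check(depth >= 1, "`depth` must be >= 1")
  .check(migration_m > 0 && migration_m <= 1,
         "`migration_m` must lie in (0, 1]")
  .check(gradient_strength >= 0, "`gradient_strength` must be >= 0")
  .check(fisher_alpha > 0 && pool_size > 1,
         "`fisher_alpha` must be > 0 and `pool_size` > 1")
  structure(list(
    seed = as.integer(seed), n_asvs = as.integer(n_asvs),
    depth = as.integer(depth), regime = regime,
    migration_m = migration_m, pool_size = pool_size,
    fisher_alpha = fisher_alpha, gradient_strength = gradient_strength,
    patterns = patterns, n_levels = n_levels,
    replicates = as.integer(replicates),
    flux_params = flux_params
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic study configuration\n")
  cat(sprintf("  design: %d patterns x %d N levels x %d reps (%d plots)\n",
              length(x$patterns), length(x$n_levels), x$replicates,
              length(x$patterns) * length(x$n_levels) * x$replicates))
  cat(sprintf("  community: %d ASVs, depth %d, regime '%s' (m = %.3g, s = %.3g)\n",
              x$n_asvs, x$depth, x$regime, x$migration_m, x$gradient_strength))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Sample metadata for the factorial design
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return A data.frame with columns \code{sample_id}, \code{pattern},
#'   \code{n_level}, \code{replicate} (one row per plot).
#' @export
design_metadata <- function(cfg) {
  g <- expand.grid(replicate = seq_len(cfg$replicates),
                   n_level = cfg$n_levels, pattern = cfg$patterns,
                   stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s%s_r%d", g$pattern, g$n_level, g$replicate),
    pattern = g$pattern, n_level = g$n_level, replicate = g$replicate,
    stringsAsFactors = FALSE
  )
}
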