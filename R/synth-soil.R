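# Soil-property table simulation anchored on the field study's treatment
# means (end-of-season 0-20 cm soil, 12 treatments x 3 replicates).

.soil_properties <- c("pH", "NH4_N", "NO3_N", "MBN", "MBC",
                      "SOC", "TN", "AP", "AK")

#' Published treatment means and SDs of the nine soil properties
#'
#' The per-treatment means and standard deviations of pH, NH4+-N, NO3--N,
#' MBN, MBC, SOC, TN, AP and AK measured at cotton harvest in the
#' green-manure x nitrogen-reduction field trial (12 treatment cells).
#' Shipped as a plain-text table; used as the default anchor of
#' \code{\link{simulate_soil_table}} and as the deterministic input for the
#' factorial effect statistics.
#'
#' @return data.frame with \code{pattern}, \code{n_level} and
#'   \code{<property>_mean} / \code{<property>_sd} columns.
#' @export
soil_field_means <- function() {
  path <- system.file("extdata", "soil_field_means.csv",
                      package = "soilNweb", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate per-plot soil property values
#'
#' Draws replicate values as treatment mean + Gaussian error. By default the
#' means and SDs are the field study's; both can be overridden. With
#' \code{sd_scale = 0} the replicates equal the cell means exactly, which
#' makes the factorial effect statistics deterministic.
#'
#' @param cfg a \code{\link{synth_config}} (design and seed).
#' @param means data.frame shaped like \code{\link{soil_field_means}}.
#' @param sd_scale multiplier on the published SDs (0 = noise-free).
#' @param properties which of the nine properties to generate.
#' @return data.frame of class \code{soil_table}: one row per plot with
#'   \code{sample_id, pattern, n_level, replicate} and one column per
#'   property.
#' @export
simulate_soil_table <- function(cfg, means = soil_field_means(),
                                sd_scale = 1,
                                properties = .soil_properties) {
  bad <- setdiff(properties, .soil_properties)
  .check(length(bad) == 0,
         sprintf("unknown soil properties: %s. Valid names: %s",
                 paste(bad, collapse = ", "),
                 paste(.soil_properties, collapse = ", ")))
  meta <- design_metadata(cfg)
  .check(all(paste(meta$pattern, meta$n_level) %in%
               paste(means$pattern, means$n_level)),
         "means table must cover every treatment cell of the design")
  idx <- match(paste(meta$pattern, meta$n_level),
               paste(means$pattern, means$n_level))
  out <- meta
  .with_stream(cfg$seed, "soil_table", {
    for (pr in properties) {
      mu <- means[[paste0(pr, "_mean")]][idx]
      sd <- means[[paste0(pr, "_sd")]][idx] * sd_scale
      v <- stats::rnorm(nrow(meta), mu, sd)
      out[[pr]] <- pmax(v, 0)  # concentrations cannot be negative
    }
  })
  class(out) <- c("soil_table", "data.frame")
  out
}
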