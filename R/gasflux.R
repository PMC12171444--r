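# Chamber gas-flux equations and cumulative-emission integration.
#
# NH3 is collected with the ventilation-chamber (sponge) method: one sponge
# extract concentration per deployment. N2O is collected with closed static
# chambers: four concentrations at 15/30/45/60 min after sealing, turned
# into a flux through the OLS slope of concentration vs time.

#' One chamber deployment's raw measurements
#'
#' @param plot_id plot identifier.
#' @param analyte \code{"NH3"} or \code{"N2O"}.
#' @param date sampling time in days since season start (real-valued).
#' @param A chamber cross-section area, m^2 (> 0).
#' @param V extract volume in L (NH3) or chamber volume in m^3 (N2O) (> 0).
#' @param temperature mean chamber air temperature, deg C (N2O only;
#'   must exceed -100).
#' @param P_ratio chamber pressure over standard pressure P/P0 (N2O only;
#'   defaults to 1 when unrecorded).
#' @param D days covered by the sponge (NH3 only, >= 1).
#' @param readings for NH3 a single extract NH4+-N concentration (mg/L);
#'   for N2O a data.frame with columns \code{minutes} (strictly increasing,
#'   >= 2 rows) and \code{conc} (chamber N2O concentration).
#' @return object of class \code{chamber_series}.
#' @export
chamber_series <- function(plot_id, analyte = c("NH3", "N2O"), date,
                           A, V, readings, temperature = NA_real_,
                           P_ratio = 1, D = NA_real_) {
  analyte <- match.arg(analyte)
  .check(is.finite(A) && A > 0, "chamber area A must be > 0")
  .check(is.finite(V) && V > 0, "volume V must be > 0")
  if (analyte == "NH3") {
    .check(is.finite(D) && D >= 1, "sponge coverage D must be >= 1 day")
    .check(is.numeric(readings) && length(readings) == 1,
           "NH3 readings must be a single extract concentration")
    .check(readings >= 0, "extract concentration C must be >= 0")
  } else {
    .check(is.data.frame(readings) &&
             all(c("minutes", "conc") %in% names(readings)),
           "N2O readings must be a data.frame with `minutes` and `conc`")
    .check(nrow(readings) >= 2,
           "N2O needs >= 2 timed concentration readings")
    .check(all(diff(readings$minutes) > 0),
           "N2O reading times must be strictly increasing")
    .check(is.finite(temperature) && temperature > -100,
           "chamber temperature must be a deg-C value > -100")
  }
  structure(list(plot_id = plot_id, analyte = analyte, date = date,
                 A = A, V = V, temperature = temperature,
                 P_ratio = P_ratio, D = D, readings = readings),
            class = "chamber_series")
}

#' NH3 flux from a ventilation-chamber sponge extract
#'
#' F = C x V / (A x D) x 10^-2, giving kg NH4+-N hm^-2 d^-1 from the extract
#' concentration C (mg/L), extract volume V (L), chamber cross-section A
#' (m^2) and sponge coverage D (d).
#'
#' @param series a \code{\link{chamber_series}} with analyte NH3.
#' @return one-row data.frame (a flux record): \code{plot_id, analyte, date,
#'   flux, fit_r2} (fit_r2 is 1 by convention for the single-point method).
#' @examples
#' s <- chamber_series("p1", "NH3", date = 1, A = 0.0177, V = 0.5,
#'                     readings = 2, D = 1)
#' nh3_flux(s)$flux  # 0.565 kg/hm2/d
#' @export
nh3_flux <- function(series) {
  .check(inherits(series, "chamber_series") && series$analyte == "NH3",
         "`series` must be an NH3 chamber_series")
  flux <- series$readings * series$V / (series$A * series$D) * 1e-2
  data.frame(plot_id = series$plot_id, analyte = "NH3",
             date = series$date, flux = flux, fit_r2 = 1,
             stringsAsFactors = FALSE)
}

#' N2O flux from a static-chamber concentration time series
#'
#' F = rho x (P/P0) x (V/A) x 273/(273+T) x dc/dt, with dc/dt the OLS slope
#' of chamber concentration against time converted to per-hour. The slope
#' regression R^2 is recorded; records below the QC threshold are flagged
#' (\code{qc_pass = FALSE}), never silently dropped.
#'
#' @param series a \code{\link{chamber_series}} with analyte N2O.
#' @param rho gas density at standard conditions, kg m^-3
#'   (default 1.964 = 44 g/mol / 22.414 L/mol for N2O).
#' @param qc_r2 minimum slope R^2 regarded as a clean chamber closure.
#' @return one-row data.frame: \code{plot_id, analyte, date, flux, fit_r2,
#'   qc_pass}; flux in the concentration-unit scale per m^2 per h
#'   (micrograms m^-2 h^-1 when conc is in mg m^-3 equivalents).
#' @export
n2o_flux <- function(series, rho = 1.964, qc_r2 = 0.90) {
  .check(inherits(series, "chamber_series") && series$analyte == "N2O",
         "`series` must be an N2O chamber_series")
  r <- series$readings
  .check(nrow(r) >= 2, "need >= 2 readings for a slope")
  .check(all(diff(r$minutes) > 0), "degenerate slope: identical timestamps")
  hours <- r$minutes / 60
  fit <- stats::lm(conc ~ hours, data = data.frame(conc = r$conc,
                                                   hours = hours))
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((r$conc - mean(r$conc))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  flux <- rho * series$P_ratio * (series$V / series$A) *
    273 / (273 + series$temperature) * slope
  data.frame(plot_id = series$plot_id, analyte = "N2O",
             date = series$date, flux = flux, fit_r2 = r2,
             qc_pass = r2 >= qc_r2, stringsAsFactors = FALSE)
}

#' Cumulative seasonal emission by trapezoidal integration
#'
#' NH3: CF = 1/2 sum (F_i + F_(i-1)) (T_i - T_(i-1)) in kg NH4+-N hm^-2.
#' N2O: CF = 1/2 x 24 x 10^-5 x sum (F_i + F_(i-1)) (T_i - T_(i-1)), the
#' 24 converting the hourly flux to daily and 10^-5 the microgram m^-2 to
#' kg hm^-2; with \code{n_basis = "N"} (the default) the gas mass is further
#' converted to N mass by 28/44. Use \code{n_basis = "gas"} to integrate on
#' the gas-mass basis.
#'
#' @param fluxes data.frame of flux records for one plot and one analyte
#'   (rbind of \code{\link{nh3_flux}} / \code{\link{n2o_flux}} outputs),
#'   sorted by date with no duplicates.
#' @param n_basis \code{"N"} or \code{"gas"} (N2O only; NH3 is already on
#'   the NH4+-N basis).
#' @param strict_qc drop N2O records flagged by slope QC before integrating
#'   (default keeps them).
#' @return one-row data.frame: \code{plot_id, analyte, cumulative,
#'   n_samplings}.
#' @export
cumulative_emission <- function(fluxes, n_basis = c("N", "gas"),
                                strict_qc = FALSE) {
  n_basis <- match.arg(n_basis)
  .check(is.data.frame(fluxes) && nrow(fluxes) >= 2,
         "need >= 2 dated flux records to integrate")
  .check(length(unique(fluxes$analyte)) == 1,
         "mixed analytes in one integration")
  .check(length(unique(fluxes$plot_id)) == 1,
         "mixed plots in one integration")
  if (strict_qc && "qc_pass" %in% names(fluxes))
    fluxes <- fluxes[fluxes$qc_pass, , drop = FALSE]
  .check(nrow(fluxes) >= 2, "fewer than 2 records after QC")
  .check(!is.unsorted(fluxes$date, strictly = TRUE),
         "flux records must be sorted by date without duplicates")
  f <- fluxes$flux
  tt <- fluxes$date
  trap <- 0.5 * sum((f[-1] + f[-length(f)]) * diff(tt))
  analyte <- fluxes$analyte[1]
  cf <- if (analyte == "NH3") {
    trap
  } else {
    out <- 24e-5 * trap
    if (n_basis == "N") out * 28 / 44 else out
  }
  data.frame(plot_id = fluxes$plot_id[1], analyte = analyte,
             cumulative = cf, n_samplings = nrow(fluxes),
             stringsAsFactors = FALSE)
}

#' Per-treatment emission means and percentage effects
#'
#' Aggregates per-plot cumulative emissions into treatment-cell means and
#' standard errors, adds the NH3 + N2O total gaseous N per cell, and reports
#' percentage change of every cell (and factor marginal) against a named
#' reference level.
#'
#' @param summaries data.frame of per-plot cumulative emissions (rbind of
#'   \code{\link{cumulative_emission}} rows, both analytes).
#' @param meta sample metadata mapping \code{plot_id}/\code{sample_id} to
#'   \code{pattern} and \code{n_level}.
#' @param reference named list with the reference levels, e.g.
#'   \code{list(pattern = "NG", n_level = "N3")}.
#' @return list with \code{cells} (per pattern x n_level x analyte mean, se,
#'   n), \code{marginals} (per-factor-level means and percentage change vs
#'   the reference level) and \code{totals} (total gaseous N per cell).
#' @export
treatment_emissions <- function(summaries, meta,
                                reference = list(pattern = "NG",
                                                 n_level = "N3")) {
  id_col <- if ("sample_id" %in% names(meta)) "sample_id" else "plot_id"
  .check(all(summaries$plot_id %in% meta[[id_col]]),
         "every plot must be mapped to a treatment cell")
  m <- meta[match(summaries$plot_id, meta[[id_col]]), ]
  d <- cbind(summaries, m[c("pattern", "n_level")])
  agg <- function(df, by) {
    sp <- split(df$cumulative, df[by], drop = TRUE, sep = "|")
    out <- do.call(rbind, lapply(names(sp), function(k) {
      v <- sp[[k]]
      kk <- strsplit(k, "|", fixed = TRUE)[[1]]
      cbind(as.data.frame(as.list(stats::setNames(kk, by)),
                          stringsAsFactors = FALSE),
            data.frame(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
                       n = length(v)))
    }))
    rownames(out) <- NULL
    out
  }
  cells <- agg(d, c("pattern", "n_level", "analyte"))
  # total gaseous N per plot = NH3-N + N2O-N
  tot <- stats::aggregate(cumulative ~ plot_id + pattern + n_level,
                          data = d, FUN = sum)
  totals <- agg(cbind(tot, analyte = "totalN"),
                c("pattern", "n_level", "analyte"))
  marg <- list()
  for (fac in c("pattern", "n_level")) {
    ma <- agg(d, c(fac, "analyte"))
    ref <- reference[[fac]]
    .check(ref %in% ma[[fac]],
           sprintf("reference level '%s' absent from %s", ref, fac))
    ma$pct_change <- NA_real_
    for (an in unique(ma$analyte)) {
      sel <- ma$analyte == an
      base <- ma$mean[sel & ma[[fac]] == ref]
      ma$pct_change[sel] <- 100 * (ma$mean[sel] - base) / base
    }
    marg[[fac]] <- ma
  }
  list(cells = cells, marginals = marg, totals = totals)
}
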