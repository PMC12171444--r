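# Umbrella pipeline: synthetic data -> gas flux / community / assembly /
# network -> drivers, with a checksum manifest for reproducibility.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stage derives its own stream.
#' @param cfg a \code{\link{synth_config}} for the generated inputs.
#' @param stages which stages to run.
#' @param n_null null-model randomizations for the assembly stage.
#' @param nmds_restarts NMDS random restarts.
#' @param cor_threshold,net_alpha,min_prevalence network construction knobs.
#' @param qc_r2,n_basis,rho gas-flux knobs.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = tempfile("soilNweb_run_"),
                            seed = 1,
                            cfg = synth_config(seed = seed),
                            stages = c("synth", "gasflux", "community",
                                       "assembly", "network", "drivers"),
                            n_null = 199, nmds_restarts = 10,
                            cor_threshold = 0.6, net_alpha = 0.05,
                            min_prevalence = 1 / 3,
                            qc_r2 = 0.90, n_basis = "N", rho = 1.964) {
  structure(list(out_dir = out_dir, seed = seed, cfg = cfg,
                 stages = stages, n_null = n_null,
                 nmds_restarts = nmds_restarts,
                 cor_threshold = cor_threshold, net_alpha = net_alpha,
                 min_prevalence = min_prevalence, qc_r2 = qc_r2,
                 n_basis = n_basis, rho = rho),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes the configured stages in dependency order: generate inputs
#' (community table, tree, gas series, soil table), compute fluxes and
#' cumulative emissions, diversity, assembly partitioning, co-occurrence
#' network and driver statistics. Every output table is written under
#' \code{config$out_dir} and checksummed into a manifest; identical
#' configurations yield identical checksums.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisible list with the in-memory results of each stage plus the
#'   \code{manifest} data.frame (file, md5).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  .check(inherits(config, "pipeline_config"),
         "`config` must be a pipeline_config")
  if ("assembly" %in% config$stages)
    .check(config$cfg$n_asvs >= 2,
           "assembly stage needs a tree: n_asvs must be >= 2")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  p <- function(f) file.path(config$out_dir, f)

  cfg <- config$cfg
  tbl <- if (cfg$regime == "neutral") simulate_neutral_community(cfg)
         else simulate_selected_community(cfg)
  phy <- simulate_phylogeny(cfg)
  gas <- simulate_gas_series(cfg)
  soil <- simulate_soil_table(cfg)
  if ("synth" %in% config$stages) {
    write_counts(tbl, p("asv_counts.tsv"), p("taxonomy.tsv"),
                 p("metadata.tsv"))
    write_tree(phy, p("tree.nwk"))
    write_gas(gas, p("gas_series.csv"))
    write_soil(soil, p("soil.csv"))
    res$synth <- list(table = tbl, phylogeny = phy, gas = gas,
                      soil = soil)
  }
  if ("gasflux" %in% config$stages) {
    em <- emission_pipeline(gas$series, n_basis = config$n_basis,
                            rho = config$rho, qc_r2 = config$qc_r2)
    eff <- treatment_emissions(em$cumulative, gas$meta)
    utils::write.csv(em$fluxes, p("fluxes.csv"), row.names = FALSE)
    utils::write.csv(em$cumulative, p("cumulative_emissions.csv"),
                     row.names = FALSE)
    utils::write.csv(eff$cells, p("emission_cells.csv"),
                     row.names = FALSE)
    res$gasflux <- list(emissions = em, effects = eff)
  }
  if ("community" %in% config$stages) {
    phyl <- aggregate_taxa(tbl, "phylum")
    alpha <- alpha_diversity(tbl)
    beta <- beta_diversity(tbl, n_restarts = config$nmds_restarts,
                           seed = config$seed)
    utils::write.csv(alpha, p("alpha_diversity.csv"), row.names = FALSE)
    utils::write.table(beta$bray, p("bray_curtis.tsv"), sep = "\t",
                       quote = FALSE)
    utils::write.csv(data.frame(sample_id = rownames(beta$points),
                                beta$points),
                     p("nmds_coords.csv"), row.names = FALSE)
    res$community <- list(phylum = phyl, alpha = alpha, beta = beta)
  }
  if ("assembly" %in% config$stages) {
    ncm <- fit_ncm(tbl)
    bn <- beta_nti(tbl, phy, n_null = config$n_null, seed = config$seed)
    rcm <- rc_bray(tbl, n_null = config$n_null, seed = config$seed)
    asm <- classify_processes(bn$bnti, rcm)
    nb <- niche_breadth(tbl)
    jsonlite::write_json(
      list(m = ncm$m, r2 = ncm$r2, N = ncm$N,
           class_counts = as.list(ncm$class_counts),
           fractions = as.list(asm$fractions),
           niche_breadth = list(mean_weighted = nb$mean_weighted,
                                sum = nb$sum)),
      p("assembly.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(asm$pairs, p("assembly_pairs.csv"),
                     row.names = FALSE)
    res$assembly <- list(ncm = ncm, bnti = bn, rc = rcm,
                         partition = asm, niche = nb)
  }
  if ("network" %in% config$stages) {
    net <- build_network(tbl, min_prevalence = config$min_prevalence,
                         cor_threshold = config$cor_threshold,
                         alpha = config$net_alpha, seed = config$seed)
    topo <- topology(net)
    roles <- if (nrow(net$nodes) > 0) zi_pi(net) else data.frame()
    keys <- if (nrow(roles) > 0) keystone_report(roles, tbl$taxonomy)
            else list(keystones = data.frame(), counts = table(character()))
    utils::write.csv(net$edges, p("network_edges.csv"),
                     row.names = FALSE)
    if (nrow(roles) > 0)
      utils::write.csv(roles, p("network_roles.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(topo), p("network_topology.json"),
                         auto_unbox = TRUE, digits = NA)
    res$network <- list(net = net, topology = topo, roles = roles,
                        keystones = keys)
  }
  if ("drivers" %in% config$stages) {
    effects <- lapply(stats::setNames(nm = c("pH", "NH4_N", "NO3_N",
                                             "MBN", "MBC")),
                      function(pr) factorial_effects(soil, pr, "pattern"))
    corr <- correlation_matrix(soil[intersect(.soil_properties,
                                              names(soil))])
    utils::write.csv(
      do.call(rbind, lapply(names(effects), function(k)
        cbind(property = k, effects[[k]]$levels))),
      p("soil_effects.csv"), row.names = FALSE)
    utils::write.csv(corr$r, p("soil_correlations.csv"))
    res$drivers <- list(effects = effects, correlations = corr)
  }
  files <- sort(list.files(config$out_dir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  res$manifest <- manifest
  invisible(res)
}
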