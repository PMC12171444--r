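# Shared fixtures, built in code at test time.

# small community table with known structure
toy_table <- function(counts = NULL, meta = TRUE) {
  if (is.null(counts)) {
    counts <- rbind(
      s1 = c(10, 5, 0, 1),
      s2 = c(8, 6, 1, 0),
      s3 = c(0, 2, 9, 4),
      s4 = c(1, 0, 10, 5))
    colnames(counts) <- paste0("ASV", 1:4)
  }
  m <- NULL
  if (meta) {
    m <- data.frame(sample_id = rownames(counts),
                    pattern = rep(c("NG", "OVG"),
                                  length.out = nrow(counts)),
                    n_level = "N1",
                    replicate = seq_len(nrow(counts)))
  }
  tax <- data.frame(asv_id = colnames(counts),
                    phylum = rep(c("Proteobacteria", "Chloroflexi"),
                                 length.out = ncol(counts)),
                    genus = paste0("g", seq_len(ncol(counts))))
  community_table(counts, tax, m)
}

# deterministic NH3 chamber deployment
nh3_series <- function(C = 2, V = 0.5, A = 0.0177, D = 1, date = 1,
                       plot = "p1") {
  chamber_series(plot, "NH3", date = date, A = A, V = V, readings = C,
                 D = D)
}

# N2O closure with an exact linear concentration rise
n2o_series <- function(slope_per_h = 0.2, c0 = 0.3, temperature = 25,
                       V_over_A = 0.295, date = 1, plot = "p1") {
  mins <- c(15, 30, 45, 60)
  chamber_series(plot, "N2O", date = date, A = 1, V = V_over_A,
                 readings = data.frame(minutes = mins,
                                       conc = c0 + slope_per_h * mins / 60),
                 temperature = temperature)
}

# tiny two-group selection config for assembly tests
assembly_cfg <- function(seed, n_asvs = 80, depth = 400, s = 80,
                         fisher_alpha = 8) {
  synth_config(seed = seed, n_asvs = n_asvs, depth = depth,
               regime = "selection", gradient_strength = s,
               fisher_alpha = fisher_alpha,
               patterns = c("A", "B"), n_levels = "L1", replicates = 6)
}
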