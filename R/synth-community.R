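# Source-pool and community generators with known assembly ground truth.

# Draw n log-series abundances with parameter x (P(k) ~ x^k / k), truncated
# at kmax; returns integer abundances >= 1.
.rlogseries <- function(n, x, kmax = 1e6) {
  .check(x > 0 && x < 1, "log-series x must be in (0,1)")
  u <- stats::runif(n)
  # inverse CDF by the analytic quantile trick of Kemp (1981):
  # with prob related to a second uniform the value is 1, else geometric-like.
  # We use the straightforward numeric inversion on a capped support.
  kcap <- min(kmax, max(1000, ceiling(50 / (1 - x))))
  k <- seq_len(kcap)
  pmf <- x^k / k
  cdf <- cumsum(pmf) / sum(pmf)
  findInterval(u, cdf) + 1L
}

#' Source-pool relative abundances under a log-series model
#'
#' The regional species pool of the neutral model: \code{n_asvs} taxa with
#' abundances drawn from a log-series with Fisher's alpha
#' \code{cfg$fisher_alpha} and pool size \code{cfg$pool_size}
#' (x = J / (J + alpha)).
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return named numeric vector of pool proportions (sums to 1).
#' @export
source_pool <- function(cfg) {
  x <- cfg$pool_size / (cfg$pool_size + cfg$fisher_alpha)
  .with_stream(cfg$seed, "pool", {
    ab <- .rlogseries(cfg$n_asvs, x)
    p <- sort(ab, decreasing = TRUE) / sum(ab)
    names(p) <- sprintf("ASV%04d", seq_len(cfg$n_asvs))
    p
  })
}

# One local community of J individuals assembled under migration rate m:
# each individual is, with probability m, a migrant drawn from the source
# pool, and otherwise a copy of a uniformly chosen earlier resident
# (sequential replacement sampling). m = 1 collapses to i.i.d. multinomial
# sampling from the pool.
.assemble_local <- function(pool, J, m) {
  S <- length(pool)
  if (m >= 1) {
    return(as.vector(stats::rmultinom(1, J, pool)))
  }
  mig <- stats::runif(J) < m
  mig[1] <- TRUE
  draws <- sample.int(S, sum(mig), replace = TRUE, prob = pool)
  copy_idx <- floor(stats::runif(J) * (seq_len(J) - 1)) + 1L
  sp <- integer(J)
  j <- 0L
  for (k in seq_len(J)) {
    if (mig[k]) {
      j <- j + 1L
      sp[k] <- draws[j]
    } else {
      sp[k] <- sp[copy_idx[k]]
    }
  }
  tabulate(sp, nbins = S)
}

#' Simulate a neutral (dispersal-assembled) community table
#'
#' Generates one local community per plot of the factorial design by neutral
#' assembly from a shared log-series source pool with migration rate
#' \code{cfg$migration_m}. The true m is stored as an attribute so that the
#' Sloan neutral-model fit can be tested for parameter recovery.
#'
#' @param cfg a \code{\link{synth_config}} with \code{regime = "neutral"}.
#' @return A \code{\link{community_table}}; attributes \code{true_m} and
#'   \code{pool} hold the ground truth.
#' @examples
#' tbl <- simulate_neutral_community(synth_config(seed = 7, migration_m = 1))
#' @export
simulate_neutral_community <- function(cfg) {
  .check(cfg$regime == "neutral",
         "cfg$regime must be 'neutral' for this generator")
  .check(cfg$migration_m > 0 && cfg$migration_m <= 1,
         "migration_m must lie in (0, 1]")
  pool <- source_pool(cfg)
  meta <- design_metadata(cfg)
  counts <- .with_stream(cfg$seed, "neutral_community", {
    do.call(rbind, lapply(seq_len(nrow(meta)), function(i)
      .assemble_local(pool, cfg$depth, cfg$migration_m)))
  })
  dimnames(counts) <- list(meta$sample_id, names(pool))
  tax <- .with_stream(cfg$seed, "taxonomy", random_taxonomy(names(pool)))
  out <- community_table(counts, tax, meta)
  attr(out, "true_m") <- cfg$migration_m
  attr(out, "pool") <- pool
  out
}

#' Simulate a selection-structured (niche-assembled) community table
#'
#' Each ASV carries a niche optimum on a one-dimensional environmental
#' gradient in [0, 1]; expected abundance in a sample is the pool abundance
#' weighted by a Gaussian fitness kernel
#' \eqn{\exp(-s (e - o)^2)} with precision \code{s = cfg$gradient_strength}
#' and sample environment \code{e}. \code{s = 0} is the neutral limit (pure
#' pool sampling). Environments equal across all samples emulate homogeneous
#' selection; environments diverging between groups emulate heterogeneous
#' selection.
#'
#' @param cfg a \code{\link{synth_config}} with \code{regime = "selection"}.
#' @param env sample environment values: either a single value (homogeneous),
#'   a named vector over patterns (one value per group), or a vector with one
#'   value per sample.
#' @param optima optional named niche optima per ASV (e.g. evolved on the
#'   tree by \code{\link{simulate_phylogeny}}); drawn uniform in [0,1]
#'   otherwise.
#' @param drift optional Dirichlet concentration adding ecological drift on
#'   top of selection: each sample's multinomial probabilities are drawn
#'   from Dirichlet(drift x selection weights), so expected abundances are
#'   unchanged but dominance shifts randomly between samples (smaller =
#'   stronger drift; NULL = none).
#' @return A \code{\link{community_table}}; metadata gains an
#'   \code{environment} column; attribute \code{optima} stores ground truth.
#' @export
simulate_selected_community <- function(cfg, env = NULL, optima = NULL,
                                        drift = NULL) {
  .check(cfg$regime == "selection",
         "cfg$regime must be 'selection' for this generator")
  .check(cfg$gradient_strength >= 0, "gradient_strength must be >= 0")
  pool <- source_pool(cfg)
  meta <- design_metadata(cfg)
  if (is.null(optima)) {
    optima <- .with_stream(cfg$seed, "optima",
                           stats::setNames(stats::runif(cfg$n_asvs),
                                           names(pool)))
  }
  .check(all(names(pool) %in% names(optima)),
         "`optima` must name every ASV in the pool")
  optima <- optima[names(pool)]
  if (is.null(env)) env <- 0.5
  if (length(env) == 1 && is.null(names(env))) {
    env_s <- rep(env, nrow(meta))
  } else if (!is.null(names(env))) {
    .check(all(meta$pattern %in% names(env)),
           "named `env` must cover every pattern")
    env_s <- unname(env[meta$pattern])
  } else {
    .check(length(env) == nrow(meta),
           "`env` must have one value per sample (or per pattern)")
    env_s <- env
  }
  .check(is.null(drift) || drift > 0, "`drift` must be positive or NULL")
  s <- cfg$gradient_strength
  counts <- .with_stream(cfg$seed, "selected_community", {
    do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
      w <- pool * exp(-s * (env_s[i] - optima)^2)
      w <- w / sum(w)
      if (!is.null(drift)) {
        w <- stats::rgamma(length(w), shape = drift * w)
        w <- w / sum(w)
      }
      as.vector(stats::rmultinom(1, cfg$depth, w))
    }))
  })
  dimnames(counts) <- list(meta$sample_id, names(pool))
  meta$environment <- env_s
  tax <- .with_stream(cfg$seed, "taxonomy", random_taxonomy(names(pool)))
  out <- community_table(counts, tax, meta)
  attr(out, "optima") <- optima
  attr(out, "pool") <- pool
  out
}

#' Simulate a rooted phylogeny over the ASV pool
#'
#' A pure-birth (Yule) tree with tips labelled ASV0001..ASVnnnn, plus niche
#' optima evolved along the tree by Brownian motion (rank-rescaled to [0,1])
#' so that phylogenetic signal in habitat preference exists — the premise of
#' nearest-taxon null models.
#'
#' @param cfg a \code{\link{synth_config}} (\code{n_asvs >= 2}).
#' @param brownian evolve niche optima on the tree (default TRUE).
#' @param trait_model \code{"BM"}: plain Brownian motion on every branch;
#'   \code{"clade_BM"}: Brownian increments on internal branches only, so
#'   the optimum is conserved within terminal clades — the maximal
#'   phylogenetic-signal end member used when habitat filtering must act on
#'   whole clades (the premise of clade-level selection signatures).
#' @return list with elements \code{tree} (class \code{phylo}, rooted,
#'   branch lengths > 0) and \code{optima} (named numeric in [0,1], NULL if
#'   \code{brownian = FALSE}).
#' @export
simulate_phylogeny <- function(cfg, brownian = TRUE,
                               trait_model = c("BM", "clade_BM")) {
  trait_model <- match.arg(trait_model)
  .check(cfg$n_asvs >= 2, "need n_asvs >= 2 for a tree")
  .with_stream(cfg$seed, "phylogeny", {
    tree <- ape::rphylo(cfg$n_asvs, birth = 1, death = 0)
    tree$tip.label <- sprintf("ASV%04d", seq_len(cfg$n_asvs))
    optima <- NULL
    if (brownian) {
      sim_tree <- tree
      if (trait_model == "clade_BM") {
        el <- sim_tree$edge.length
        el[sim_tree$edge[, 2] <= ape::Ntip(sim_tree)] <- 0
        sim_tree$edge.length <- el
      }
      x <- ape::rTraitCont(sim_tree, model = "BM", sigma = 1)
      # min-max rescale to [0,1]: preserves the metric clade structure of
      # the trait (a rank transform would stretch the tails apart)
      optima <- (x - min(x)) / (max(x) - min(x))
    }
    list(tree = tree, optima = optima)
  })
}
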