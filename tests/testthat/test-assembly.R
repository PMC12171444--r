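# Neutral-model fit, null-model metrics and the process classifier.

test_that("betaMNTD matches a brute-force oracle on an 8-taxon toy", {
  set.seed(17)
  tree <- ape::rphylo(8, 1, 0)
  tree$tip.label <- paste0("t", 1:8)
  D <- ape::cophenetic.phylo(tree)
  cnt <- rbind(a = c(4, 2, 0, 0, 1, 0, 3, 0),
               b = c(0, 1, 5, 2, 0, 2, 0, 1))
  colnames(cnt) <- tree$tip.label
  got <- soilNweb:::.bmntd_pairs(cnt, D, weighted = TRUE)
  # brute force: for every individual-weighted taxon, nearest taxon in the
  # opposite community
  rel <- cnt / rowSums(cnt)
  one_way <- function(from, to) {
    i_from <- which(rel[from, ] > 0)
    w <- rel[from, i_from] / sum(rel[from, i_from])
    sum(w * sapply(i_from, function(i)
      min(D[i, which(rel[to, ] > 0)])))
  }
  oracle <- 0.5 * (one_way("a", "b") + one_way("b", "a"))
  expect_equal(got["a", "b"], oracle, tolerance = 1e-12)
  # independent implementation: picante
  pic <- as.matrix(picante::comdistnt(cnt, D, abundance.weighted = TRUE))
  expect_equal(got["a", "b"], pic["a", "b"], tolerance = 1e-10)
})

test_that("betaNTI standardization behaves as a z-score", {
  set.seed(23)
  cfg <- assembly_cfg(23)
  phy <- simulate_phylogeny(cfg)
  tbl <- simulate_selected_community(cfg, env = 0.5, optima = phy$optima)
  bn <- suppressWarnings(beta_nti(tbl, phy, n_null = 99, seed = 2))
  ut <- upper.tri(bn$bnti)
  expect_equal(bn$bnti[ut],
               ((bn$bmntd_obs - bn$null_mean) / bn$null_sd)[ut])
  # affine branch-length scaling leaves betaNTI unchanged
  phy2 <- phy
  phy2$tree$edge.length <- phy2$tree$edge.length * 3.7
  bn2 <- suppressWarnings(beta_nti(tbl, phy2, n_null = 99, seed = 2))
  expect_equal(bn$bnti[ut], bn2$bnti[ut], tolerance = 1e-8)
  # a sample paired with itself has betaMNTD exactly 0; because shared
  # taxa keep zero distance under every tip shuffle the null is constant
  # too, so the pair is flagged (NA) rather than given a fake z-score
  dup <- tbl$counts[c(1, 1, 2, 3, 4), ]
  rownames(dup) <- paste0("s", 1:5)
  tb2 <- community_table(dup)
  expect_warning(bn3 <- beta_nti(tb2, phy, n_null = 99, seed = 2),
                 "zero null sd")
  expect_equal(bn3$bmntd_obs["s1", "s2"], 0)
  expect_true(is.na(bn3$bnti["s1", "s2"]))
  # missing tips are a coverage error
  small_tree <- ape::drop.tip(phy$tree, phy$tree$tip.label[1])
  expect_error(beta_nti(tbl, small_tree, n_null = 99), "missing tips")
  # star-like tree with all equal tip distances: degenerate null
  star <- ape::stree(ncol(tbl$counts), "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- colnames(tbl$counts)
  expect_error(suppressWarnings(beta_nti(tbl, star, n_null = 99)),
               "degenerate")
})

test_that("RC_bray matches exhaustive enumeration on a tiny toy", {
  # two samples, 3 taxa, small depths: enumerate the null distribution
  cnt <- rbind(x = c(2, 1, 0), y = c(0, 2, 2))
  colnames(cnt) <- c("A", "B", "C")
  tbl <- community_table(cnt)
  occ <- colMeans(cnt > 0)
  reg <- colSums(cnt) / sum(cnt)
  # enumeration oracle: all (taxa subset, filling) outcomes with their
  # probabilities under the sequential-selection + multinomial-fill null
  subsets <- combn(3, 2)
  sel_prob <- function(sel) {
    perms <- list(sel, rev(sel))
    sum(sapply(perms, function(p) {
      pr <- 1
      rem <- occ
      for (i in p) {
        pr <- pr * rem[i] / sum(rem)
        rem[i] <- 0
      }
      pr
    }))
  }
  fills <- function(total, k) {
    if (k == 1) return(matrix(total, 1, 1))
    out <- NULL
    for (i in 0:total) out <- rbind(out, cbind(i, fills(total - i, k - 1)))
    out
  }
  null_bc_dist <- function(rich, depth) {
    # distribution of one null community
    outs <- list()
    for (s in seq_len(ncol(subsets))) {
      sel <- subsets[, s]
      ps <- sel_prob(sel)
      extra <- depth - rich
      fl <- fills(extra, rich)
      pr_fill <- apply(fl, 1, function(f)
        stats::dmultinom(f, prob = reg[sel] / sum(reg[sel])))
      for (r in seq_len(nrow(fl))) {
        v <- numeric(3)
        v[sel] <- 1 + fl[r, ]
        outs[[length(outs) + 1]] <- list(v = v, p = ps * pr_fill[r])
      }
    }
    outs
  }
  ox <- null_bc_dist(2, 3)
  oy <- null_bc_dist(2, 4)
  obs <- soilNweb:::.bc_pair(cnt["x", ], cnt["y", ])
  less <- 0; equal <- 0
  for (a in ox) for (b in oy) {
    bc <- soilNweb:::.bc_pair(a$v, b$v)
    pp <- a$p * b$p
    if (bc < obs - 1e-12) less <- less + pp
    else if (abs(bc - obs) <= 1e-12) equal <- equal + pp
  }
  rc_exact <- 2 * (less + 0.5 * equal) - 1
  rc_mc <- rc_bray(tbl, n_null = 20000, seed = 4)["x", "y"]
  expect_equal(rc_mc, rc_exact, tolerance = 0.03)
  expect_true(all(abs(rc_bray(tbl, n_null = 99, seed = 1)) <= 1))
})

test_that("process classifier applies the threshold rules exactly", {
  # enumerated grid spanning all five regions
  bnti <- c(3, -3, 0, 0, 0, 2.5, -2.5, 1.9, -1.9)
  rc <- c(0, 0, 0.96, -0.96, 0.5, 0, 0, 0.96, -0.96)
  cp <- classify_processes(bnti, rc)
  expect_equal(cp$pairs$process,
               c("heterogeneous_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal",
                 "undominated", "heterogeneous_selection",
                 "homogeneous_selection", "dispersal_limitation",
                 "homogenizing_dispersal"))
  expect_equal(sum(cp$fractions), 100, tolerance = 1e-9)
  # worked example: (-3, -3, 1) with RC 0.99 on the stochastic pair
  cp2 <- classify_processes(c(-3, -3, 1), c(0, 0, 0.99))
  expect_equal(as.numeric(cp2$fractions),
               c(0, 200 / 3, 100 / 3, 0, 0), tolerance = 1e-9)
  # all strongly positive
  cp3 <- classify_processes(rep(3.5, 4), rep(0, 4))
  expect_equal(unname(cp3$fractions["heterogeneous_selection"]), 100)
  expect_error(classify_processes(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("Sloan model recovers migration rate from neutral simulations", {
  fits <- lapply(1:20, function(seed) {
    cfg <- synth_config(seed = seed, n_asvs = 60, depth = 5000,
                        migration_m = 0.3)
    fit_ncm(simulate_neutral_community(cfg))
  })
  m_err <- sapply(fits, function(f) abs(f$m - 0.3))
  r2 <- sapply(fits, function(f) f$r2)
  expect_lt(median(m_err), 0.1)
  expect_gt(median(r2), 0.5)
  # point classes partition the fitted ASVs
  f1 <- fits[[1]]
  expect_equal(sum(f1$class_counts), nrow(f1$points))
  expect_true(all(f1$points$class %in% c("above", "within", "below")))
  expect_true(f1$m > 0 && f1$m <= 1 && f1$r2 <= 1)
})

test_that("strong selection degrades the neutral fit relative to neutral data", {
  r2s <- sapply(1:5, function(seed) {
    ncfg <- synth_config(seed = seed, n_asvs = 60, depth = 2000,
                         migration_m = 0.3)
    scfg <- synth_config(seed = seed, n_asvs = 60, depth = 2000,
                         regime = "selection", gradient_strength = 100,
                         fisher_alpha = 8)
    phy <- simulate_phylogeny(scfg)
    set.seed(seed)
    env <- runif(36)  # strongly divergent environments
    sel <- simulate_selected_community(scfg, env = env,
                                       optima = phy$optima)
    c(neutral = fit_ncm(simulate_neutral_community(ncfg))$r2,
      selected = fit_ncm(sel)$r2)
  })
  expect_gt(mean(r2s["neutral", ] > r2s["selected", ]), 0.5)
})

test_that("degenerate neutral fits are rejected", {
  cnt <- matrix(5, 6, 4, dimnames = list(paste0("s", 1:6),
                                         paste0("A", 1:4)))
  expect_error(fit_ncm(community_table(cnt)), "every sample")
})

test_that("Levins niche breadth equals the closed form and its bounds", {
  # taxon in exactly one sample: B = 1; uniform over n samples: B = n
  cnt <- rbind(s1 = c(5, 3, 0), s2 = c(0, 3, 2), s3 = c(0, 3, 1),
               s4 = c(0, 3, 1))
  colnames(cnt) <- c("only1", "uniform", "mixed")
  nb <- niche_breadth(community_table(cnt))
  B <- setNames(nb$per_asv$B, nb$per_asv$asv_id)
  expect_equal(unname(B["only1"]), 1)
  expect_equal(unname(B["uniform"]), 4)
  expect_true(all(B >= 1 & B <= 4))
  # random-table oracle
  set.seed(3)
  cnt2 <- matrix(rpois(50, 4), 5, 10,
                 dimnames = list(paste0("s", 1:5), paste0("A", 1:10)))
  cnt2[, 1] <- pmax(cnt2[, 1], 1)
  keep <- colSums(cnt2) > 0
  nb2 <- niche_breadth(community_table(cnt2))
  P <- sweep(cnt2[, keep], 2, colSums(cnt2[, keep]), "/")
  expect_equal(nb2$per_asv$B, unname(1 / colSums(P^2)), tolerance = 1e-12)
  expect_equal(nb2$sum, sum(1 / colSums(P^2)), tolerance = 1e-12)
})

test_that("directional selection regimes recover the planted process", {
  # scaled-down study conditions: 400-taxon pool with clade-conserved
  # niche optima, 12 samples, filtering + drift (see methods vignette)
  run <- function(seed, het) {
    cfg <- synth_config(seed = seed, n_asvs = 400, depth = 200,
                        regime = "selection", gradient_strength = 120,
                        fisher_alpha = 10000,
                        patterns = c("A", "B"), n_levels = "L1",
                        replicates = 6)
    phy <- simulate_phylogeny(cfg, trait_model = "clade_BM")
    set.seed(seed + 500)
    env0 <- if (het) c(A = 0.1, B = 0.9)[rep(c("A", "B"), each = 6)]
            else rep(0.1, 12)
    env <- pmin(pmax(env0 + rnorm(12, 0, 0.08), 0), 1)
    tbl <- simulate_selected_community(cfg, env = env,
                                       optima = phy$optima, drift = 50)
    bn <- suppressWarnings(beta_nti(tbl, phy, n_null = 99, seed = seed))
    rcm <- rc_bray(tbl, n_null = 99, seed = seed)
    if (het) {
      g <- tbl$meta$pattern
      ut <- upper.tri(bn$bnti)
      cross <- outer(g, g, "!=")[ut]
      cp <- classify_processes(bn$bnti[ut][cross], rcm[ut][cross])
    } else {
      cp <- classify_processes(bn$bnti, rcm)
    }
    names(which.max(cp$fractions))
  }
  # light 2-seed sanity check; the 10-seed version runs in the acceptance
  # suite
  expect_equal(run(7, het = FALSE), "homogeneous_selection")
  expect_equal(run(7, het = TRUE), "heterogeneous_selection")
})
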