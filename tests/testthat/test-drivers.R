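# Factorial effects on the published grid, ANOVA + LSD letters,
# correlations, random-forest importance, PLS path model.

test_that("factorial effects reproduce the published percentage changes", {
  grid <- soil_field_means()
  # green-manure effects vs NG (marginal over N levels)
  gm <- function(prop) factorial_effects(grid, prop, "pattern", "NG")
  expect_equal(gm("pH")$levels$pct_change[gm("pH")$levels$level == "OVG"],
               1.36, tolerance = 0.5)
  expect_equal(gm("pH")$levels$pct_change[gm("pH")$levels$level == "VVG"],
               1.06, tolerance = 0.5)
  expect_equal(gm("MBN")$levels$pct_change[gm("MBN")$levels$level == "OVG"],
               68.47, tolerance = 0.5)
  expect_equal(gm("MBC")$levels$pct_change[gm("MBC")$levels$level == "OVG"],
               79.27, tolerance = 0.5)
  expect_equal(gm("MBC")$levels$pct_change[gm("MBC")$levels$level == "VVG"],
               80.13, tolerance = 0.5)
  expect_equal(gm("NH4_N")$levels$pct_change[
    gm("NH4_N")$levels$level == "OVG"], -30.71, tolerance = 0.5)
  expect_equal(gm("NO3_N")$levels$pct_change[
    gm("NO3_N")$levels$level == "OVG"], -65.21, tolerance = 0.5)
  # N-reduction averages vs N3
  nf <- function(prop) factorial_effects(grid, prop, "n_level",
                                         "N3")$avg_reduction_pct
  expect_equal(nf("NH4_N"), -22.83, tolerance = 0.5)
  expect_equal(nf("NO3_N"), -35.24, tolerance = 0.5)
  expect_equal(nf("MBN"), -32.49, tolerance = 0.5)
  expect_equal(nf("AP"), -30.18, tolerance = 0.5)
  # reference change is zero; all-equal table gives all-zero changes
  expect_equal(gm("pH")$levels$pct_change[gm("pH")$levels$level == "NG"], 0)
  flat <- grid
  flat$MBC_mean <- 100
  f <- factorial_effects(flat, "MBC", "pattern", "NG")
  expect_true(all(abs(f$levels$pct_change) < 1e-12))
  expect_error(factorial_effects(grid, "MBC", "pattern", "XX"),
               "reference")
  expect_error(factorial_effects(grid, "water", "pattern", "NG"),
               "absent")
})

test_that("noise-free simulated soil tables give deterministic effects", {
  cfg <- synth_config(seed = 1)
  soil <- simulate_soil_table(cfg, sd_scale = 0)
  f <- factorial_effects(soil, "MBC", "pattern", "NG")
  expect_equal(f$levels$pct_change[f$levels$level == "OVG"], 79.27,
               tolerance = 0.5)
  expect_error(simulate_soil_table(cfg, properties = "humidity"),
               "Valid names")
})

test_that("ANOVA F matches the sum-of-squares oracle and LSD letters behave", {
  cfg <- synth_config(seed = 8)
  soil <- simulate_soil_table(cfg, sd_scale = 1)
  out <- anova_lsd(soil, "MBC", error_structure = "fixed")
  # oracle: brute-force two-way fixed-effects decomposition
  y <- soil$MBC
  gm_f <- factor(soil$pattern)
  nf_f <- factor(soil$n_level)
  fit <- lm(y ~ gm_f * nf_f)
  an <- anova(fit)
  expect_equal(out$two_way$F, an$`F value`[1:3], tolerance = 1e-10)
  expect_equal(out$two_way$p, an$`Pr(>F)`[1:3], tolerance = 1e-10)
  expect_true(is.finite(out$levene_p))
  # split-plot mode reports the three F tests too
  sp <- anova_lsd(soil, "MBC", error_structure = "split_plot")
  expect_equal(sp$two_way$term, c("GM", "NF", "GM:NF"))
  expect_true(all(is.finite(sp$two_way$F)))
  # identical groups share a letter
  soil2 <- soil
  soil2$MBC <- rep(c(10, 10.1, 10.2), 12)  # same in every cell
  l2 <- anova_lsd(soil2, "MBC", error_structure = "fixed")
  w <- l2$within_pattern[["NG"]]
  expect_true(length(unique(w$letter)) == 1)
})

test_that("MBC letter separation OVG vs NG is stable across seeds", {
  hits <- sapply(1:60, function(seed) {
    cfg <- synth_config(seed = seed)
    soil <- simulate_soil_table(cfg, sd_scale = 1)
    res <- anova_lsd(soil, "MBC", error_structure = "fixed")
    all(sapply(res$within_level, function(d) {
      d$letter[d$level == "OVG"] != d$letter[d$level == "NG"]
    }))
  })
  expect_gt(mean(hits), 0.9)
})

test_that("correlation matrix carries correct r, p and stars", {
  set.seed(3)
  x <- rnorm(30)
  d <- data.frame(x = x, negx = -x, y = rnorm(30))
  cm <- correlation_matrix(d)
  expect_equal(cm$r["x", "x"], 1)
  expect_equal(cm$r["x", "negx"], -1, tolerance = 1e-12)
  expect_equal(cm$stars["x", "negx"], "***")
  ct <- cor.test(d$x, d$y)
  expect_equal(cm$r["x", "y"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$p["x", "y"], ct$p.value, tolerance = 1e-12)
  expect_warning(correlation_matrix(data.frame(a = rnorm(10),
                                               b = rep(1, 10))),
                 "constant")
  # calibration: independent normals flagged at ~5%
  set.seed(11)
  hits <- replicate(400, {
    cm2 <- correlation_matrix(data.frame(u = rnorm(36), v = rnorm(36)))
    cm2$p["u", "v"] < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("random-forest importance finds planted signal, not noise", {
  set.seed(2)
  n <- 36
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- c("MBC", paste0("p", 2:6))
  y <- 2 * X$MBC + rnorm(n, 0, 0.5)
  imp <- rf_importance(X, y, n_perm = 49, ntree = 300, seed = 1)
  expect_equal(imp$predictor[1], "MBC")
  expect_lt(imp$p_perm[imp$predictor == "MBC"], 0.05)
  # column order invariance of the top predictor
  imp2 <- rf_importance(X[, c(4, 1, 2, 3, 5, 6)], y, n_perm = 49,
                        ntree = 300, seed = 1)
  expect_equal(imp2$predictor[1], "MBC")
  # pure-noise response: planted predictor not called significant
  y0 <- rnorm(n)
  imp0 <- rf_importance(X, y0, n_perm = 49, ntree = 300, seed = 3)
  expect_gt(min(imp0$p_perm), 0.01)
  expect_error(rf_importance(X, rep(1, n)), "constant")
  expect_error(rf_importance(X[1:10, ], y[1:10]), "n >= 20")
})

test_that("PLS path model collapses to Pearson r for single indicators", {
  set.seed(5)
  n <- 80
  a <- rnorm(n)
  b <- 0.6 * a + rnorm(n, 0, 0.8)
  d <- data.frame(a = a, b = b)
  fit <- fit_plspm(d, blocks = list(A = "a", B = "b"),
                   paths = cbind("A", "B"), n_boot = 0)
  expect_equal(fit$paths$estimate, cor(a, b), tolerance = 1e-6)
  expect_true(fit$gof >= 0 && fit$gof <= 1)
})

test_that("PLS path model recovers a planted soil->community->gas chain", {
  # generating chain: soil -(0.9)-> community -(-0.1)-> N2O
  recov <- sapply(1:10, function(seed) {
    set.seed(seed)
    n <- 150
    soil_lv <- rnorm(n)
    comm_lv <- 0.9 * soil_lv + rnorm(n, 0, sqrt(1 - 0.81))
    n2o_lv <- -0.1 * comm_lv + rnorm(n, 0, sqrt(1 - 0.01))
    mk_ind <- function(lv, k, lam = 0.95)
      sapply(1:k, function(j) lam * lv + rnorm(n, 0, sqrt(1 - lam^2)))
    d <- data.frame(mk_ind(soil_lv, 3), mk_ind(comm_lv, 3),
                    mk_ind(n2o_lv, 2))
    names(d) <- c(paste0("s", 1:3), paste0("c", 1:3), paste0("g", 1:2))
    fit <- fit_plspm(
      d,
      blocks = list(soil = paste0("s", 1:3),
                    community = paste0("c", 1:3),
                    n2o = paste0("g", 1:2)),
      paths = rbind(c("soil", "community"), c("community", "n2o")),
      n_boot = 0)
    est <- setNames(fit$paths$estimate,
                    paste(fit$paths$from, fit$paths$to))
    c(est["soil community"], est["community n2o"])
  })
  expect_lt(abs(median(recov[1, ]) - 0.9), 0.1)
  expect_lt(abs(median(recov[2, ]) - (-0.1)), 0.1)
})

test_that("PLS path model on orthogonal blocks returns near-zero paths", {
  ests <- sapply(1:9, function(seed) {
    set.seed(seed)
    n <- 200
    d <- data.frame(a1 = rnorm(n), a2 = rnorm(n),
                    b1 = rnorm(n), b2 = rnorm(n))
    f1 <- fit_plspm(d, blocks = list(A = "a1", B = "b1"),
                    paths = cbind("A", "B"), n_boot = 0)
    f2 <- fit_plspm(d, blocks = list(A = c("a1", "a2"),
                                     B = c("b1", "b2")),
                    paths = cbind("A", "B"), n_boot = 0)
    c(single = f1$paths$estimate, multi = f2$paths$estimate,
      gof = f2$gof_acceptable)
  })
  expect_lt(median(abs(ests["single", ])), 0.1)
  # multi-indicator blocks capitalize on chance (outer weights chase the
  # top singular pair of a noise cross-covariance); small but not zero
  expect_lt(median(abs(ests["multi", ])), 0.2)
  expect_false(any(ests["gof", ] == 1))
})

test_that("PLS path model reports GoF, bootstrap p and indirect effects", {
  set.seed(7)
  n <- 100
  s <- rnorm(n)
  cmm <- 0.8 * s + rnorm(n, 0, 0.6)
  g <- 0.7 * cmm + rnorm(n, 0, 0.7)
  d <- data.frame(s1 = s + rnorm(n, 0, 0.3), s2 = s + rnorm(n, 0, 0.3),
                  c1 = cmm + rnorm(n, 0, 0.3),
                  c2 = cmm + rnorm(n, 0, 0.3),
                  g1 = g + rnorm(n, 0, 0.3))
  fit <- fit_plspm(d, blocks = list(S = c("s1", "s2"), C = c("c1", "c2"),
                                    G = "g1"),
                   paths = rbind(c("S", "C"), c("C", "G")),
                   n_boot = 200, seed = 9)
  expect_true(all(abs(fit$loadings$loading) <= 1))
  expect_true(fit$gof > 0.6 && fit$gof_acceptable)
  expect_true(all(fit$paths$p < 0.05))
  expect_equal(unname(fit$indirect["S -> C -> G"]),
               prod(fit$paths$estimate), tolerance = 1e-10)
  # cyclic inner models are rejected
  expect_error(fit_plspm(d, blocks = list(S = "s1", C = "c1"),
                         paths = rbind(c("S", "C"), c("C", "S"))),
               "cyclic")
})
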