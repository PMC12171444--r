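# Soil-property -> community -> emission driver statistics: factorial
# effects on the treatment-mean grid, ANOVA + LSD letters, correlation
# matrix with significance stars, permutation random-forest importance.

#' Factorial percentage effects from a soil table
#'
#' Marginal means per level of one factor (averaging across the other
#' factor's levels) and the percentage change of every level against a named
#' reference. For nitrogen-reduction summaries the headline number is the
#' mean of the reduced levels' percentage changes versus the conventional
#' rate: \code{avg_reduction_pct} averages the changes of all non-reference
#' levels.
#'
#' @param soil a soil table (per-plot rows) or a treatment-mean grid shaped
#'   like \code{\link{soil_field_means}} (then the \code{<prop>_mean}
#'   columns are used directly).
#' @param property one of the nine soil property names.
#' @param factor_name \code{"pattern"} (green manure, GM) or
#'   \code{"n_level"} (N fertilization, NF).
#' @param reference reference level (\code{"NG"} for GM, \code{"N3"} for
#'   NF).
#' @return list: \code{levels} (data.frame level, mean, pct_change),
#'   \code{avg_reduction_pct} (mean change of non-reference levels).
#' @export
factorial_effects <- function(soil, property,
                              factor_name = c("pattern", "n_level"),
                              reference = NULL) {
  factor_name <- match.arg(factor_name)
  if (is.null(reference))
    reference <- if (factor_name == "pattern") "NG" else "N3"
  mean_col <- paste0(property, "_mean")
  if (mean_col %in% names(soil)) {
    vals <- soil[[mean_col]]
  } else {
    .check(property %in% names(soil),
           sprintf("property '%s' absent from the soil table", property))
    vals <- soil[[property]]
  }
  .check(factor_name %in% names(soil),
         sprintf("factor '%s' absent from the soil table", factor_name))
  other <- setdiff(c("pattern", "n_level"), factor_name)
  # mean within cells first, then across the other factor's levels, so the
  # marginal is balanced even with unequal replication
  cell <- stats::aggregate(vals,
                           by = list(f = soil[[factor_name]],
                                     o = soil[[other]]),
                           FUN = mean)
  marg <- stats::aggregate(cell$x, by = list(level = cell$f), FUN = mean)
  .check(reference %in% marg$level,
         sprintf("reference level '%s' not present", reference))
  base <- marg$x[marg$level == reference]
  out <- data.frame(level = marg$level, mean = marg$x,
                    pct_change = 100 * (marg$x - base) / base,
                    stringsAsFactors = FALSE)
  nonref <- out$pct_change[out$level != reference]
  list(levels = out, reference = reference,
       avg_reduction_pct = mean(nonref))
}

#' One-way ANOVA with LSD letter groups, Levene test and split-plot F tests
#'
#' For one property: (i) one-way ANOVA across N levels within each
#' green-manure pattern with LSD letters at alpha = 0.05 (the lowercase
#' letters of a factorial soil table), (ii) across patterns within each N
#' level (uppercase letters), (iii) Levene's test for homogeneity of
#' variance, and (iv) the two-way F table — split-plot by default (the
#' main-plot factor tested against the pattern x replicate error stratum),
#' or simple fixed-effects.
#'
#' @param soil per-plot soil table (needs \code{pattern, n_level,
#'   replicate}).
#' @param property property name.
#' @param alpha LSD significance level.
#' @param error_structure \code{"split_plot"} or \code{"fixed"}.
#' @return list: \code{within_pattern} (letters across N levels, per
#'   pattern), \code{within_level} (letters across patterns, per N level),
#'   \code{levene_p}, \code{two_way} (data.frame term, F, p).
#' @export
anova_lsd <- function(soil, property, alpha = 0.05,
                      error_structure = c("split_plot", "fixed")) {
  error_structure <- match.arg(error_structure)
  .check(property %in% names(soil), "unknown property")
  y <- soil[[property]]
  lsd_letters <- function(yy, grp) {
    grp <- factor(grp)
    .check(nlevels(grp) >= 2 && all(table(grp) >= 2),
           "need >= 2 groups with >= 2 replicates each")
    means <- tapply(yy, grp, mean)
    ns <- tapply(yy, grp, length)
    fit <- stats::aov(yy ~ grp)
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    lv <- levels(grp)
    dm <- matrix(FALSE, nlevels(grp), nlevels(grp),
                 dimnames = list(lv, lv))
    if (mse <= 1e-12) {
      # exact ties: groups differ iff their means differ
      for (a in lv) for (b in lv)
        dm[a, b] <- abs(means[a] - means[b]) > 1e-12
    } else {
      tcrit <- stats::qt(1 - alpha / 2, fit$df.residual)
      for (a in lv) for (b in lv) {
        lsd <- tcrit * sqrt(mse * (1 / ns[a] + 1 / ns[b]))
        dm[a, b] <- abs(means[a] - means[b]) > lsd
      }
    }
    data.frame(level = lv, mean = as.numeric(means[lv]),
               letter = .assign_letters(means, dm)[lv],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  within_pattern <- lapply(split(seq_along(y), soil$pattern), function(ix)
    lsd_letters(y[ix], soil$n_level[ix]))
  within_level <- lapply(split(seq_along(y), soil$n_level), function(ix)
    lsd_letters(y[ix], soil$pattern[ix]))
  cellg <- interaction(soil$pattern, soil$n_level)
  lev <- tryCatch(car::leveneTest(y, cellg)[["Pr(>F)"]][1],
                  error = function(e) NA_real_)
  d <- data.frame(y = y, GM = factor(soil$pattern),
                  NF = factor(soil$n_level),
                  rep = factor(soil$replicate))
  if (error_structure == "split_plot") {
    # the rep:GM stratum is aliased with rep by construction; aov warns
    # about the singular Error() model but estimates the strata correctly
    fit <- suppressWarnings(stats::aov(y ~ GM * NF + Error(rep:GM),
                                       data = d))
    s <- summary(fit)
    main <- as.data.frame(s[["Error: rep:GM"]][[1]])
    sub <- as.data.frame(s[["Error: Within"]][[1]])
    rownames(main) <- trimws(rownames(main))
    rownames(sub) <- trimws(rownames(sub))
    two_way <- data.frame(
      term = c("GM", "NF", "GM:NF"),
      F = c(main["GM", "F value"], sub["NF", "F value"],
            sub["GM:NF", "F value"]),
      p = c(main["GM", "Pr(>F)"], sub["NF", "Pr(>F)"],
            sub["GM:NF", "Pr(>F)"]))
  } else {
    s <- as.data.frame(stats::anova(stats::lm(y ~ GM * NF, data = d)))
    two_way <- data.frame(term = c("GM", "NF", "GM:NF"),
                          F = s[c("GM", "NF", "GM:NF"), "F value"],
                          p = s[c("GM", "NF", "GM:NF"), "Pr(>F)"])
  }
  list(within_pattern = within_pattern, within_level = within_level,
       levene_p = lev, two_way = two_way)
}

#' Pearson correlation matrix with significance stars
#'
#' @param data data.frame or matrix of numeric columns (soil properties,
#'   community attributes, emissions).
#' @return list of matrices: \code{r}, \code{p}, \code{stars} ("*", "**",
#'   "***" at 0.05 / 0.01 / 0.001; constant columns give NA and are
#'   flagged).
#' @export
correlation_matrix <- function(data) {
  x <- as.matrix(data)
  .check(is.numeric(x), "all columns must be numeric")
  v <- apply(x, 2, stats::var, na.rm = TRUE)
  if (any(v == 0, na.rm = TRUE))
    warning("constant columns give undefined correlations: ",
            paste(colnames(x)[which(v == 0)], collapse = ", "))
  m <- ncol(x)
  r <- matrix(NA_real_, m, m, dimnames = list(colnames(x), colnames(x)))
  p <- r
  for (i in seq_len(m)) for (j in i:m) {
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ok <- stats::complete.cases(x[, i], x[, j])
    if (sum(ok) >= 3 && v[i] > 0 && v[j] > 0) {
      ct <- stats::cor.test(x[ok, i], x[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.001, "***",
           ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  diag(stars) <- ""
  list(r = r, p = p, stars = stars)
}

#' Permutation random-forest importance of soil properties
#'
#' A seeded regression forest predicts a community attribute from the soil
#' properties; importance is the permutation increase in MSE (%IncMSE).
#' Significance is assessed by refitting the forest on \code{n_perm}
#' response permutations and locating each observed importance in its null
#' distribution.
#'
#' @param predictors data.frame of predictor columns (n >= 20 rows).
#' @param response numeric response vector.
#' @param n_perm response permutations (>= 99).
#' @param ntree trees per forest.
#' @param seed RNG seed.
#' @return data.frame ranked by importance: predictor, importance
#'   (%IncMSE), p_perm; attribute \code{r2} holds the forest's explained
#'   variance.
#' @export
rf_importance <- function(predictors, response, n_perm = 99,
                          ntree = 500, seed = 1) {
  X <- as.data.frame(predictors)
  .check(nrow(X) >= 20, "need n >= 20 observations")
  .check(length(response) == nrow(X), "response length mismatch")
  .check(stats::var(response) > 0, "constant response")
  obs_imp <- NULL
  null_imp <- NULL
  r2 <- NA_real_
  .with_stream(seed, "rf", {
    fit <- randomForest::randomForest(X, response, ntree = ntree,
                                      importance = TRUE)
    obs_imp <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
    r2 <- fit$rsq[length(fit$rsq)]
    null_imp <- matrix(NA_real_, n_perm, ncol(X))
    for (b in seq_len(n_perm)) {
      yp <- sample(response)
      fb <- randomForest::randomForest(X, yp, ntree = ntree,
                                       importance = TRUE)
      null_imp[b, ] <- randomForest::importance(fb, type = 1,
                                                scale = TRUE)[, 1]
    }
  })
  pp <- vapply(seq_len(ncol(X)), function(j)
    (sum(null_imp[, j] >= obs_imp[j]) + 1) / (n_perm + 1), numeric(1))
  out <- data.frame(predictor = colnames(X),
                    importance = as.numeric(obs_imp), p_perm = pp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "r2") <- r2
  out
}
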