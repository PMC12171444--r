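# Community-assembly inference: Sloan neutral community model, betaNTI and
# RC_bray null models, the five-way ecological process classification, and
# Levins niche breadth.

#' Fit the Sloan neutral community model
#'
#' For each ASV the observed occurrence frequency (fraction of samples in
#' which it is detected) is compared with the frequency predicted by the
#' Sloan model: with community size N (mean sample depth), migration rate m
#' and mean relative abundance p, the local relative abundance follows a
#' Beta(N m p, N m (1 - p)) distribution and the predicted detection
#' frequency is 1 - pbeta(d) at the detection limit d = 1/N. m is estimated
#' by bounded nonlinear least squares on the frequencies; R^2 = 1 - SSE/SST.
#' A 95% Wilson binomial envelope around the prediction classifies each ASV
#' as above / within / below the neutral expectation.
#'
#' @param tbl a \code{\link{community_table}} with >= 5 samples.
#' @param detection_limit override for d (default 1/N).
#' @return list of class \code{ncm_fit}: \code{m}, \code{r2}, \code{N},
#'   \code{points} (per-ASV p, observed and predicted frequency, envelope,
#'   class), \code{class_counts}.
#' @export
fit_ncm <- function(tbl, detection_limit = NULL) {
  cnt <- tbl$counts
  .check(nrow(cnt) >= 5, "need >= 5 samples to fit the neutral model")
  N <- mean(rowSums(cnt))
  d <- if (is.null(detection_limit)) 1 / N else detection_limit
  rel <- .rel_abund(cnt)
  p <- colMeans(rel)
  keep <- p > 0
  p <- p[keep]
  freq <- colMeans(cnt[, keep, drop = FALSE] > 0)
  .check(any(freq < 1),
         "degenerate fit: every ASV occurs in every sample")
  pred_freq <- function(m) {
    stats::pbeta(d, N * m * p, N * m * (1 - p), lower.tail = FALSE)
  }
  sse <- function(m) sum((freq - pred_freq(m))^2)
  opt <- stats::optimise(sse, interval = c(1e-6, 1))
  m_hat <- opt$minimum
  pr <- pred_freq(m_hat)
  sst <- sum((freq - mean(freq))^2)
  r2 <- 1 - opt$objective / sst
  # Wilson 95% interval on the predicted frequency at n = number of samples
  n <- nrow(cnt)
  z <- stats::qnorm(0.975)
  ctr <- (pr + z^2 / (2 * n)) / (1 + z^2 / n)
  hw <- z * sqrt(pr * (1 - pr) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  lo <- pmax(ctr - hw, 0)
  hi <- pmin(ctr + hw, 1)
  cls <- ifelse(freq > hi, "above", ifelse(freq < lo, "below", "within"))
  pts <- data.frame(asv_id = names(p), mean_rel_abund = as.numeric(p),
                    freq_obs = as.numeric(freq), freq_pred = as.numeric(pr),
                    lower = as.numeric(lo), upper = as.numeric(hi),
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(m = m_hat, r2 = r2, N = N, points = pts,
                 class_counts = table(factor(cls, c("above", "within",
                                                    "below")))),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model: m = %.4f, R2 = %.3f, N = %.0f\n",
              x$m, x$r2, x$N))
  print(x$class_counts)
  invisible(x)
}

# Abundance-weighted beta mean nearest-taxon distance between all sample
# pairs. `D` is a patristic distance matrix over (at least) the table's
# ASVs; comm is a counts or relative-abundance matrix (samples x taxa).
.bmntd_pairs <- function(comm, D, weighted = TRUE) {
  rel <- .rel_abund(comm)
  n <- nrow(rel)
  ids <- colnames(rel)
  pres <- lapply(seq_len(n), function(i) which(rel[i, ] > 0))
  out <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ia <- pres[[a]]; ib <- pres[[b]]
    Dab <- D[ids[ia], ids[ib], drop = FALSE]
    mins_a <- apply(Dab, 1, min)   # nearest taxon in b for each taxon in a
    mins_b <- apply(Dab, 2, min)
    if (weighted) {
      wa <- rel[a, ia] / sum(rel[a, ia])
      wb <- rel[b, ib] / sum(rel[b, ib])
      v <- 0.5 * (sum(wa * mins_a) + sum(wb * mins_b))
    } else {
      v <- 0.5 * (mean(mins_a) + mean(mins_b))
    }
    out[a, b] <- out[b, a] <- v
  }
  out
}

#' Beta nearest-taxon index (betaNTI) under a tip-shuffling null model
#'
#' Observed abundance-weighted betaMNTD for every sample pair, standardized
#' against \code{n_null} randomizations in which tip labels are shuffled
#' across the whole phylogeny ("taxa.labels" null):
#' betaNTI = (obs - mean(null)) / sd(null). Values above +2 indicate
#' phylogenetic overdispersion between the pair (heterogeneous selection),
#' below -2 clustering (homogeneous selection).
#'
#' @param tbl a \code{\link{community_table}}.
#' @param tree rooted \code{phylo} whose tips cover every ASV of the table
#'   (or a list as returned by \code{\link{simulate_phylogeny}}).
#' @param n_null number of null randomizations (>= 99).
#' @param weighted abundance-weighted betaMNTD (default) or presence-based.
#' @param seed RNG seed for the null draws.
#' @return list: \code{bnti} (pairwise matrix), \code{bmntd_obs},
#'   \code{null_mean}, \code{null_sd}.
#' @export
beta_nti <- function(tbl, tree, n_null = 999, weighted = TRUE, seed = 1) {
  if (is.list(tree) && !inherits(tree, "phylo")) tree <- tree$tree
  .check(inherits(tree, "phylo"), "`tree` must be a phylo object")
  .check(n_null >= 99, "n_null must be >= 99")
  missing_tips <- setdiff(colnames(tbl$counts), tree$tip.label)
  .check(length(missing_tips) == 0,
         sprintf("tree is missing tips for: %s",
                 paste(utils::head(missing_tips, 5), collapse = ", ")))
  D <- ape::cophenetic.phylo(tree)
  ids <- colnames(tbl$counts)
  D <- D[ids, ids]
  obs <- .bmntd_pairs(tbl$counts, D, weighted)
  n <- nrow(obs)
  null_sum <- matrix(0, n, n)
  null_sq <- matrix(0, n, n)
  .with_stream(seed, "bnti_null", {
    for (r in seq_len(n_null)) {
      perm <- sample(ncol(D))
      Dn <- D[perm, perm]
      dimnames(Dn) <- dimnames(D)
      bn <- .bmntd_pairs(tbl$counts, Dn, weighted)
      null_sum <- null_sum + bn
      null_sq <- null_sq + bn^2
    }
  })
  mu <- null_sum / n_null
  sd_ <- sqrt(pmax(null_sq / n_null - mu^2, 0) * n_null / (n_null - 1))
  # scale-aware degeneracy cut: a constant null differs from 0 only by
  # floating-point noise proportional to its magnitude
  tiny <- 1e-8 * pmax(1, mu)
  degen <- sd_ <= tiny
  .check(!all(degen[upper.tri(degen)]),
         "degenerate null: zero standard deviation (all tip distances equal?)")
  if (any(degen[upper.tri(degen)]))
    warning(sum(degen[upper.tri(degen)]),
            " sample pair(s) with zero null sd set to NA ",
            "(fully overlapping communities)")
  bnti <- (obs - mu) / ifelse(degen, NA, sd_)
  diag(bnti) <- 0
  dimnames(bnti) <- dimnames(obs)
  list(bnti = bnti, bmntd_obs = obs, null_mean = mu, null_sd = sd_)
}

# One null community preserving richness s and depth J: taxa chosen without
# replacement with probability ~ occurrence frequency; one individual seeded
# per chosen taxon, the remaining J - s filled multinomially ~ regional
# relative abundance of the chosen taxa (Stegen-style Raup-Crick null).
.rc_null_sample <- function(s, J, occ_freq, reg_ab) {
  S <- length(occ_freq)
  sel <- sample.int(S, s, replace = FALSE, prob = occ_freq)
  x <- numeric(S)
  x[sel] <- 1
  if (J > s) {
    pr <- reg_ab[sel]
    if (sum(pr) <= 0) pr <- rep(1, length(sel))
    fill <- stats::rmultinom(1, J - s, pr)
    x[sel] <- x[sel] + fill
  }
  x
}

.bc_pair <- function(x, y) {
  px <- x / sum(x); py <- y / sum(y)
  sum(abs(px - py)) / sum(px + py)
}

#' Raup-Crick index on Bray-Curtis dissimilarity (RC_bray)
#'
#' For every sample pair, \code{n_null} pairs of null communities are drawn
#' preserving each sample's richness and total abundance (taxa chosen with
#' probability proportional to occurrence frequency, individuals filled
#' proportionally to regional relative abundance), and the observed
#' Bray-Curtis is located within the null distribution:
#' RC = 2 [P(null < obs) + 1/2 P(null = obs)] - 1, in [-1, 1].
#'
#' @param tbl a \code{\link{community_table}}.
#' @param n_null number of null draws per pair (>= 99).
#' @param seed RNG seed.
#' @return pairwise RC matrix.
#' @export
rc_bray <- function(tbl, n_null = 999, seed = 1) {
  .check(n_null >= 99, "n_null must be >= 99")
  cnt <- tbl$counts
  n <- nrow(cnt)
  occ <- colMeans(cnt > 0)
  reg <- colSums(cnt) / sum(cnt)
  rich <- rowSums(cnt > 0)
  depth <- rowSums(cnt)
  obs <- bray_curtis(cnt)
  rc <- matrix(0, n, n, dimnames = dimnames(obs))
  .with_stream(seed, "rc_null", {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      less <- 0; equal <- 0
      for (r in seq_len(n_null)) {
        xa <- .rc_null_sample(rich[a], depth[a], occ, reg)
        xb <- .rc_null_sample(rich[b], depth[b], occ, reg)
        bc <- .bc_pair(xa, xb)
        if (bc < obs[a, b] - 1e-12) less <- less + 1
        else if (abs(bc - obs[a, b]) <= 1e-12) equal <- equal + 1
      }
      rc[a, b] <- rc[b, a] <- 2 * ((less + 0.5 * equal) / n_null) - 1
    }
  })
  rc
}

#' Classify pairwise assembly processes from betaNTI and RC_bray
#'
#' The standard two-stage null-model partition: betaNTI > +2 heterogeneous
#' selection; betaNTI < -2 homogeneous selection; otherwise (stochastic
#' pairs) RC_bray > +0.95 dispersal limitation, RC_bray < -0.95 homogenizing
#' dispersal, |RC_bray| <= 0.95 undominated (drift).
#'
#' @param bnti pairwise betaNTI matrix (or vector).
#' @param rc pairwise RC_bray matrix (or vector) over the same pairs.
#' @return list of class \code{assembly_result}: \code{pairs} (long
#'   data.frame with bnti, rc, process) and \code{fractions} (percentages
#'   over the five processes, summing to 100).
#' @export
classify_processes <- function(bnti, rc) {
  if (is.matrix(bnti)) {
    .check(is.matrix(rc) && all(dim(rc) == dim(bnti)),
           "betaNTI and RC matrices must cover the same pairs")
    ut <- upper.tri(bnti)
    idx <- which(ut, arr.ind = TRUE)
    pairs <- data.frame(
      sample_a = rownames(bnti)[idx[, 1]],
      sample_b = colnames(bnti)[idx[, 2]],
      bnti = bnti[ut], rc = rc[ut], stringsAsFactors = FALSE)
  } else {
    .check(length(bnti) == length(rc),
           "betaNTI and RC vectors must have equal length")
    pairs <- data.frame(sample_a = NA, sample_b = NA,
                        bnti = as.numeric(bnti), rc = as.numeric(rc))
  }
  proc <- with(pairs, ifelse(
    bnti > 2, "heterogeneous_selection",
    ifelse(bnti < -2, "homogeneous_selection",
           ifelse(rc > 0.95, "dispersal_limitation",
                  ifelse(rc < -0.95, "homogenizing_dispersal",
                         "undominated")))))
  pairs$process <- proc
  ok <- !is.na(proc)
  .check(any(ok), "no classifiable pairs (all betaNTI/RC values NA)")
  lev <- c("heterogeneous_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "undominated")
  fr <- 100 * table(factor(proc[ok], lev)) / sum(ok)
  structure(list(pairs = pairs, fractions = fr),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly partition over %d sample pairs (%%):\n",
              nrow(x$pairs)))
  print(round(x$fractions, 2))
  invisible(x)
}

#' Levins niche breadth
#'
#' B_j = 1 / sum_i P_ij^2, with P_ij taxon j's proportion of its own total
#' across samples i: the effective number of samples a taxon occupies
#' (1 <= B <= n samples). Community-level aggregates are reported both as
#' the abundance-weighted mean and as the sum over retained taxa (the two
#' conventions in circulation).
#'
#' @param tbl a \code{\link{community_table}} with >= 2 samples.
#' @return list: \code{per_asv} (data.frame asv_id, B), \code{mean_weighted}
#'   (abundance-weighted mean B), \code{sum} (sum of B over taxa),
#'   \code{n_excluded} (taxa with zero total, dropped).
#' @export
niche_breadth <- function(tbl) {
  cnt <- tbl$counts
  .check(nrow(cnt) >= 2, "need >= 2 samples for niche breadth")
  tot <- colSums(cnt)
  zero <- tot == 0
  if (any(zero))
    message(sum(zero), " taxa with zero total abundance excluded")
  cnt <- cnt[, !zero, drop = FALSE]
  P <- sweep(cnt, 2, colSums(cnt), "/")
  B <- 1 / colSums(P^2)
  w <- colSums(cnt) / sum(cnt)
  list(per_asv = data.frame(asv_id = colnames(cnt), B = as.numeric(B),
                            stringsAsFactors = FALSE),
       mean_weighted = sum(w * B), sum = sum(B),
       n_excluded = sum(zero))
}
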