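# Composition and diversity layer: taxonomic aggregation, alpha diversity,
# Bray-Curtis / NMDS beta diversity, ternary enrichment of top ASVs.

#' Aggregate a community table to a taxonomic rank
#'
#' @param tbl a \code{\link{community_table}}.
#' @param rank one of phylum, class, order, family, genus.
#' @return list with \code{rel} (samples x taxa relative abundances, rows
#'   summing to 1), \code{group_means} (mean relative abundance per pattern,
#'   if metadata has one) and \code{overall} (grand mean per taxon).
#' @export
aggregate_taxa <- function(tbl, rank = "phylum") {
  ranks <- c("phylum", "class", "order", "family", "genus")
  .check(rank %in% ranks,
         sprintf("unknown rank '%s'; valid ranks: %s", rank,
                 paste(ranks, collapse = ", ")))
  lab <- tbl$taxonomy[[rank]][match(colnames(tbl$counts),
                                    tbl$taxonomy$asv_id)]
  agg <- t(rowsum(t(tbl$counts), group = lab))
  rel <- .rel_abund(agg)
  group_means <- NULL
  if (!is.null(tbl$meta) && "pattern" %in% names(tbl$meta)) {
    g <- tbl$meta$pattern[match(rownames(rel), tbl$meta$sample_id)]
    group_means <- rowsum(rel, g) / as.vector(table(g)[sort(unique(g))])
  }
  list(rel = rel, group_means = group_means, overall = colMeans(rel))
}

# Chao1 with the bias-corrected fallback when no doubletons exist.
.chao1 <- function(x) {
  x <- x[x > 0]
  S <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) S + f1^2 / (2 * f2) else S + f1 * (f1 - 1) / 2
}

# ACE with the standard rare/abundant split at `cut` reads.
.ace <- function(x, cut = 10) {
  x <- x[x > 0]
  rare <- x[x <= cut]
  S_ab <- sum(x > cut)
  S_rare <- length(rare)
  N_rare <- sum(rare)
  f1 <- sum(rare == 1)
  if (N_rare == 0) return(S_ab)
  if (N_rare == f1) return(.chao1(x))  # all rare reads are singletons
  C_ace <- 1 - f1 / N_rare
  fi <- vapply(seq_len(cut), function(i) sum(rare == i), numeric(1))
  g2 <- max(S_rare / C_ace * sum(seq_len(cut) * (seq_len(cut) - 1) * fi) /
              (N_rare * (N_rare - 1)) - 1, 0)
  S_ab + S_rare / C_ace + f1 / C_ace * g2
}

#' Per-sample alpha diversity (Shannon, Chao1, ACE)
#'
#' Shannon H = -sum p ln p; Chao1 = S_obs + F1^2/(2 F2) (bias-corrected when
#' F2 = 0); ACE with the rare/abundant split at 10 reads. Chao1 and ACE are
#' count-based and refuse non-integer input; Shannon is computed regardless.
#'
#' @param tbl a \code{\link{community_table}} (integer counts).
#' @return data.frame with columns \code{sample_id, shannon, chao1, ace,
#'   s_obs}.
#' @export
alpha_diversity <- function(tbl) {
  cnt <- tbl$counts
  integer_counts <- max(abs(cnt - round(cnt))) < 1e-8
  shannon <- apply(.rel_abund(cnt), 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  if (!integer_counts)
    stop("Chao1/ACE need integer counts; Shannon of the supplied table: ",
         paste(signif(shannon, 4), collapse = ", "), call. = FALSE)
  data.frame(sample_id = rownames(cnt),
             shannon = shannon,
             chao1 = apply(cnt, 1, .chao1),
             ace = apply(cnt, 1, .ace),
             s_obs = rowSums(cnt > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x - y| / sum (x + y) on total-sum-scaled abundances.
#'
#' @param counts samples x taxa matrix.
#' @return symmetric dissimilarity matrix in [0, 1] with zero diagonal.
#' @export
bray_curtis <- function(counts) {
  p <- .rel_abund(as.matrix(counts))
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sum(p[i, ] + p[j, ])
    d[i, j] <- d[j, i] <- if (s == 0) 0 else sum(abs(p[i, ] - p[j, ])) / s
  }
  d
}

#' Beta diversity: Bray-Curtis NMDS with a group permutation test
#'
#' Non-metric multidimensional scaling (Kruskal stress-1) of the Bray-Curtis
#' matrix, run from \code{n_restarts} seeded random starts plus the metric
#' (PCoA) start; the configuration with the lowest final stress is reported.
#' Group separation is summarized by a PERMANOVA permutation F test on the
#' distance matrix.
#'
#' @param tbl a \code{\link{community_table}}.
#' @param k embedding dimension (default 2).
#' @param n_restarts random restarts (default 20).
#' @param seed RNG seed for the restarts and permutations.
#' @param group metadata column used for the permutation test (NULL skips).
#' @param n_perm permutations for the PERMANOVA test.
#' @return list with \code{bray} (dissimilarity matrix), \code{points}
#'   (samples x k NMDS coordinates), \code{stress} (Kruskal stress-1 of the
#'   best restart, in [0,1]), \code{permanova} (data.frame with F, R2, p).
#' @export
beta_diversity <- function(tbl, k = 2, n_restarts = 20, seed = 1,
                           group = "pattern", n_perm = 999) {
  .check(nrow(tbl$counts) >= 3, "need >= 3 samples for NMDS")
  d <- bray_curtis(tbl$counts)
  .check(any(d > 0),
         "all samples identical: degenerate NMDS configuration; jitter or drop duplicates")
  dd <- stats::as.dist(d + 1e-12 * (d == 0))  # isoMDS needs positive dists
  n <- nrow(d)
  best <- NULL
  .with_stream(seed, "nmds", {
    starts <- c(list(stats::cmdscale(dd, k = k)),
                lapply(seq_len(n_restarts), function(i)
                  matrix(stats::rnorm(n * k), n, k)))
    for (st in starts) {
      fit <- tryCatch(
        suppressMessages(MASS::isoMDS(dd, y = st, k = k, trace = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$stress < best$stress))
        best <- fit
    }
  })
  .check(!is.null(best), "NMDS failed from every start")
  pts <- best$points
  rownames(pts) <- rownames(d)
  perm <- NULL
  if (!is.null(group) && !is.null(tbl$meta) && group %in% names(tbl$meta)) {
    g <- factor(tbl$meta[[group]][match(rownames(d), tbl$meta$sample_id)])
    if (nlevels(g) > 1) {
      av <- .with_stream(seed, "permanova",
                         vegan::adonis2(stats::as.dist(d) ~ g,
                                        permutations = n_perm))
      perm <- data.frame(F = av$F[1], R2 = av$R2[1],
                         p = av$`Pr(>F)`[1])
    }
  }
  list(bray = d, points = pts, stress = best$stress / 100,
       permanova = perm)
}

#' Ternary enrichment of the most abundant ASVs across three patterns
#'
#' For each of the \code{top_n} most abundant ASVs: its barycentric
#' coordinates (mean relative-abundance fractions across the three
#' green-manure patterns, summing to 1) and an enrichment call — the pattern
#' with the highest mean abundance when a Kruskal-Wallis test across the
#' patterns is significant, otherwise "unenriched".
#'
#' @param tbl a \code{\link{community_table}} whose metadata has exactly 3
#'   patterns.
#' @param top_n number of top ASVs to assess.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: \code{asv_id}, one barycentric column per pattern,
#'   \code{p_value}, \code{enriched}.
#' @export
ternary_enrichment <- function(tbl, top_n = 500, alpha = 0.05) {
  .check(!is.null(tbl$meta) && "pattern" %in% names(tbl$meta),
         "metadata with a `pattern` column is required")
  pats <- sort(unique(tbl$meta$pattern))
  .check(length(pats) == 3,
         sprintf("ternary enrichment needs exactly 3 patterns, got %d",
                 length(pats)))
  .check(top_n <= ncol(tbl$counts), "top_n exceeds the number of ASVs")
  rel <- .rel_abund(tbl$counts)
  ord <- order(colSums(tbl$counts), decreasing = TRUE)[seq_len(top_n)]
  g <- factor(tbl$meta$pattern[match(rownames(rel), tbl$meta$sample_id)],
              levels = pats)
  out <- lapply(ord, function(j) {
    x <- rel[, j]
    mu <- tapply(x, g, mean)
    bc <- if (sum(mu) == 0) rep(1 / 3, 3) else mu / sum(mu)
    p <- if (stats::var(x) == 0) 1 else
      suppressWarnings(stats::kruskal.test(x, g)$p.value)
    enr <- if (!is.na(p) && p < alpha) names(which.max(mu)) else "unenriched"
    c(list(asv_id = colnames(rel)[j]),
      as.list(stats::setNames(as.numeric(bc), pats)),
      list(p_value = as.numeric(p), enriched = enr))
  })
  do.call(rbind, lapply(out, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
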