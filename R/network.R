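# Co-occurrence networks: Spearman construction with BH-FDR edge filtering,
# the topology panel, and Zi-Pi keystone classification.

#' Build a co-occurrence network from a community table
#'
#' ASVs below the prevalence cutoff are dropped; pairwise Spearman rank
#' correlations are computed on relative abundances; edges are kept when
#' |rho| >= \code{cor_threshold} and the Benjamini-Hochberg adjusted p-value
#' is < \code{alpha} (p from the t approximation to the Spearman statistic,
#' as in the common correlation-matrix implementations). Isolated nodes are
#' dropped; edge sign is sign(rho). Modules are detected by seeded greedy
#' modularity maximization.
#'
#' @param tbl a \code{\link{community_table}} (>= 6 samples), or a subset of
#'   its samples via \code{samples}.
#' @param samples optional character vector restricting to a sample group.
#' @param min_prevalence minimum fraction of samples an ASV must occupy
#'   (default 1/3).
#' @param cor_threshold minimum |Spearman rho| for an edge (default 0.6).
#' @param alpha BH-FDR level for edge retention (default 0.05).
#' @param seed RNG seed for module detection.
#' @return list of class \code{co_network}: \code{graph} (igraph, possibly
#'   empty), \code{edges} (data.frame i, j, rho, p, q, sign),
#'   \code{membership} (node -> module), \code{nodes} (with phylum labels),
#'   \code{params}.
#' @export
build_network <- function(tbl, samples = NULL, min_prevalence = 1 / 3,
                          cor_threshold = 0.6, alpha = 0.05, seed = 1) {
  .check(min_prevalence > 0 && min_prevalence < 1 &&
           cor_threshold > 0 && cor_threshold < 1 &&
           alpha > 0 && alpha < 1, "thresholds must lie in (0, 1)")
  cnt <- tbl$counts
  if (!is.null(samples)) {
    .check(all(samples %in% rownames(cnt)), "unknown sample IDs")
    cnt <- cnt[samples, , drop = FALSE]
  }
  .check(nrow(cnt) >= 6, "need >= 6 samples to build a network")
  prev <- colMeans(cnt > 0)
  cnt <- cnt[, prev >= min_prevalence, drop = FALSE]
  rel <- .rel_abund(cnt)
  n <- nrow(rel)
  empty <- function(msg) {
    message("empty network: ", msg)
    structure(list(graph = igraph::make_empty_graph(0, directed = FALSE),
                   edges = data.frame(), membership = integer(0),
                   nodes = data.frame(),
                   params = list(min_prevalence = min_prevalence,
                                 cor_threshold = cor_threshold,
                                 alpha = alpha, n_samples = n)),
              class = "co_network")
  }
  if (ncol(rel) < 2) return(empty("fewer than 2 ASVs pass prevalence"))
  rho <- suppressWarnings(stats::cor(rel, method = "spearman"))
  rho[is.na(rho)] <- 0
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[upper.tri(rho)]
  tstat <- r * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0
  q <- stats::p.adjust(p, method = "BH")
  keep <- abs(r) >= cor_threshold & q < alpha
  if (!any(keep)) return(empty("no edge passes |rho| and FDR thresholds"))
  ed <- data.frame(i = colnames(rel)[ut[keep, 1]],
                   j = colnames(rel)[ut[keep, 2]],
                   rho = r[keep], p = p[keep], q = q[keep],
                   sign = ifelse(r[keep] > 0, "positive", "negative"),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed[c("i", "j")], directed = FALSE)
  igraph::E(g)$rho <- ed$rho
  igraph::E(g)$sign <- ed$sign
  memb <- .with_stream(seed, "modules", {
    cl <- igraph::cluster_fast_greedy(g)
    igraph::membership(cl)
  })
  phy <- tbl$taxonomy$phylum[match(igraph::V(g)$name,
                                   tbl$taxonomy$asv_id)]
  genus <- tbl$taxonomy$genus[match(igraph::V(g)$name,
                                    tbl$taxonomy$asv_id)]
  nodes <- data.frame(node = igraph::V(g)$name,
                      phylum = ifelse(is.na(phy), "unclassified", phy),
                      genus = ifelse(is.na(genus), "unclassified", genus),
                      module = as.integer(memb),
                      stringsAsFactors = FALSE)
  structure(list(graph = g, edges = ed,
                 membership = stats::setNames(as.integer(memb),
                                              igraph::V(g)$name),
                 nodes = nodes,
                 params = list(min_prevalence = min_prevalence,
                               cor_threshold = cor_threshold,
                               alpha = alpha, n_samples = n)),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Topology panel of a co-occurrence network
#'
#' Computes the standard descriptive panel: node and edge counts, percentage
#' of positive/negative edges, average local clustering coefficient (nodes
#' with degree < 2 contribute 0), average shortest-path distance over
#' connected pairs, Newman modularity of the module partition, geodesic
#' efficiency (mean of 1/d over all pairs, disconnected pairs contributing
#' 0) and Krackhardt connectedness (fraction of node pairs joined by a
#' path). All values are defined on fragmented and empty graphs.
#'
#' @param net a \code{\link{build_network}} result, or a bare igraph (then
#'   modules are detected greedily first).
#' @return one-row data.frame with the panel.
#' @export
topology <- function(net) {
  if (inherits(net, "igraph")) {
    g <- net
    memb <- if (igraph::vcount(g) > 0)
      igraph::membership(igraph::cluster_fast_greedy(g)) else integer(0)
    ed <- data.frame(sign = rep("positive", igraph::ecount(g)))
  } else {
    g <- net$graph
    memb <- net$membership
    ed <- net$edges
  }
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (nv == 0) {
    return(data.frame(n_nodes = 0, n_edges = 0, pct_positive = NA_real_,
                      pct_negative = NA_real_, avg_clustering = NA_real_,
                      avg_path_distance = NA_real_, modularity = NA_real_,
                      geodesic_efficiency = NA_real_,
                      connectedness = NA_real_))
  }
  pctp <- if (ne > 0) 100 * mean(ed$sign == "positive") else NA_real_
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  avg_clust <- mean(loc)
  dmat <- igraph::distances(g)
  ut <- dmat[upper.tri(dmat)]
  conn_pairs <- is.finite(ut)
  avg_path <- if (any(conn_pairs)) mean(ut[conn_pairs]) else NA_real_
  eff <- if (length(ut)) mean(ifelse(conn_pairs, 1 / ut, 0)) else NA_real_
  connectedness <- if (length(ut)) mean(conn_pairs) else NA_real_
  modr <- if (ne > 0) igraph::modularity(g, memb) else NA_real_
  data.frame(n_nodes = nv, n_edges = ne, pct_positive = pctp,
             pct_negative = if (is.na(pctp)) NA_real_ else 100 - pctp,
             avg_clustering = avg_clust, avg_path_distance = avg_path,
             modularity = modr, geodesic_efficiency = eff,
             connectedness = connectedness)
}

#' Zi-Pi node roles
#'
#' Within-module degree z-score Zi = (k_is - mean_s) / sd_s over the nodes
#' of module s (0 when sd_s = 0 or the module is a singleton) and
#' among-module connectivity Pi = 1 - sum_t (k_it / k_i)^2. Roles by the
#' conventional thresholds: network hub (Zi > 2.5 and Pi > 0.62), module
#' hub (Zi > 2.5, Pi < 0.62), connector (Zi < 2.5, Pi > 0.62), else
#' peripheral.
#'
#' @param net a \code{\link{build_network}} result, or an igraph plus
#'   \code{membership}.
#' @param membership optional named module assignment overriding the one in
#'   \code{net}.
#' @param zi_threshold,pi_threshold role thresholds (2.5 and 0.62).
#' @return data.frame: node, module, degree, Zi, Pi, role.
#' @export
zi_pi <- function(net, membership = NULL, zi_threshold = 2.5,
                  pi_threshold = 0.62) {
  g <- if (inherits(net, "igraph")) net else net$graph
  memb <- if (!is.null(membership)) membership else net$membership
  .check(!is.null(memb) && length(memb) == igraph::vcount(g),
         "module assignment must cover every node")
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  memb <- memb[nodes]
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- rowSums(A)
  mods <- sort(unique(memb))
  # k_it: edges from each node into each module
  kit <- vapply(mods, function(s) rowSums(A[, memb == s, drop = FALSE]),
                numeric(length(nodes)))
  if (is.null(dim(kit))) kit <- matrix(kit, nrow = length(nodes))
  kis <- kit[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  for (s in mods) {
    in_s <- memb == s
    mu <- mean(kis[in_s])
    sd_ <- stats::sd(kis[in_s])
    zi[in_s] <- if (sum(in_s) < 2 || is.na(sd_) || sd_ == 0) 0
    else (kis[in_s] - mu) / sd_
  }
  pi_ <- ifelse(k > 0, 1 - rowSums((kit / pmax(k, 1))^2), 0)
  role <- ifelse(zi > zi_threshold & pi_ > pi_threshold, "network hub",
          ifelse(zi > zi_threshold, "module hub",
          ifelse(pi_ > pi_threshold, "connector", "peripheral")))
  data.frame(node = nodes, module = as.integer(memb), degree = k,
             Zi = zi, Pi = pi_, role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Keystone taxa report
#'
#' Annotates every non-peripheral node (network hub, module hub, connector)
#' with its genus and phylum and tabulates keystone counts.
#'
#' @param roles output of \code{\link{zi_pi}}.
#' @param taxonomy taxonomy data.frame with \code{asv_id}, \code{phylum},
#'   \code{genus} (missing taxa labelled "unclassified").
#' @return list: \code{keystones} (data.frame node, role, Zi, Pi, phylum,
#'   genus), \code{counts} (per-role counts).
#' @export
keystone_report <- function(roles, taxonomy = NULL) {
  ks <- roles[roles$role != "peripheral", , drop = FALSE]
  if (nrow(ks) == 0)
    return(list(keystones = data.frame(), counts = table(character(0))))
  if (!is.null(taxonomy)) {
    idx <- match(ks$node, taxonomy$asv_id)
    ks$phylum <- ifelse(is.na(idx), "unclassified", taxonomy$phylum[idx])
    ks$genus <- ifelse(is.na(idx), "unclassified", taxonomy$genus[idx])
  } else {
    ks$phylum <- "unclassified"
    ks$genus <- "unclassified"
  }
  rownames(ks) <- NULL
  list(keystones = ks, counts = table(ks$role))
}
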