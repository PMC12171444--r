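# Partial least squares path modeling (mode A outer estimation, centroid
# inner scheme) for latent soil/community/emission blocks.

#' Fit a PLS path model
#'
#' Latent variables are estimated by the classical iterative PLS-PM
#' algorithm: standardized indicators, mode A outer weights (indicator to
#' inner-proxy correlations), centroid inner scheme (proxy = sum of
#' sign-of-correlation weighted adjacent latents), iterated to convergence.
#' Inner path coefficients are OLS regressions of each endogenous latent on
#' its predecessors; loadings are indicator-latent correlations; goodness of
#' fit GoF = sqrt(mean communality x mean inner R^2), with fits above 0.60
#' regarded as acceptable. Path significance comes from a seeded bootstrap.
#'
#' @param data data.frame holding every indicator column.
#' @param blocks named list: latent name -> character vector of indicator
#'   columns (each block >= 1 indicator).
#' @param paths two-column matrix or data.frame of directed inner edges
#'   (from, to); the inner model must be acyclic.
#' @param max_iter,tol iteration cap and convergence tolerance on the outer
#'   weights.
#' @param n_boot bootstrap draws for path significance (0 skips).
#' @param seed RNG seed for the bootstrap.
#' @return list of class \code{plspm_fit}: \code{scores}, \code{loadings},
#'   \code{outer_weights}, \code{paths} (with estimate, boot se, p),
#'   \code{r2}, \code{gof}, \code{gof_acceptable}, \code{iterations},
#'   \code{indirect} (products over every directed chain).
#' @export
fit_plspm <- function(data, blocks, paths, max_iter = 300, tol = 1e-6,
                      n_boot = 500, seed = 1) {
  paths <- as.matrix(paths)
  .check(ncol(paths) == 2, "`paths` needs two columns (from, to)")
  lat <- names(blocks)
  .check(!is.null(lat) && all(paths %in% lat),
         "paths must reference named blocks")
  .check(all(lengths(blocks) >= 1), "each block needs >= 1 indicator")
  .check(all(unlist(blocks) %in% names(data)),
         "every indicator must be a column of `data`")
  # acyclicity via topological sort
  order_ok <- local({
    remaining <- lat
    edges <- paths
    topo <- character(0)
    while (length(remaining)) {
      free <- remaining[!remaining %in% edges[, 2]]
      if (!length(free)) return(NULL)
      topo <- c(topo, free)
      remaining <- setdiff(remaining, free)
      edges <- edges[!(edges[, 1] %in% free), , drop = FALSE]
    }
    topo
  })
  .check(!is.null(order_ok), "cyclic inner model rejected")

  X <- lapply(blocks, function(cols) scale(as.matrix(data[cols])))
  n <- nrow(data)
  adj <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  adj[paths] <- 1
  nb <- adj + t(adj)   # centroid scheme uses undirected adjacency

  core <- function(X) {
    W <- lapply(X, function(x) rep(1, ncol(x)))
    scores <- function(W) {
      Y <- mapply(function(x, w) scale(x %*% w), X, W,
                  SIMPLIFY = FALSE)
      do.call(cbind, Y)
    }
    Y <- scores(W)
    it <- 0
    repeat {
      it <- it + 1
      R <- stats::cor(Y)
      E <- sign(R) * nb
      Z <- Y %*% E   # inner proxy for block b = sum_c e_bc Y_c
      Wn <- lapply(seq_along(X), function(b)
        as.numeric(stats::cor(X[[b]], Z[, b])))
      delta <- max(mapply(function(a, b)
        max(abs(abs(a) / sqrt(sum(a^2)) - abs(b) / sqrt(sum(b^2)))),
        Wn, W))
      W <- Wn
      Y <- scores(W)
      if (delta < tol) break
      if (it >= max_iter)
        stop("PLS-PM failed to converge after ", max_iter,
             " iterations (last weight change ", signif(delta, 3), ")",
             call. = FALSE)
    }
    colnames(Y) <- lat
    # inner paths: OLS of each endogenous latent on its predecessors
    est <- numeric(nrow(paths))
    r2 <- stats::setNames(rep(NA_real_, length(lat)), lat)
    for (to in unique(paths[, 2])) {
      from <- paths[paths[, 2] == to, 1]
      fit <- stats::lm.fit(cbind(1, Y[, from, drop = FALSE]), Y[, to])
      est[paths[, 2] == to] <- fit$coefficients[-1][from]
      r2[to] <- 1 - sum(fit$residuals^2) / sum((Y[, to] -
                                                  mean(Y[, to]))^2)
    }
    loadings <- lapply(seq_along(X), function(b)
      as.numeric(stats::cor(X[[b]], Y[, b])))
    names(loadings) <- lat
    list(Y = Y, W = W, est = est, r2 = r2, loadings = loadings, it = it)
  }

  fit <- core(X)
  communality <- unlist(fit$loadings)^2
  gof <- sqrt(mean(communality) * mean(fit$r2, na.rm = TRUE))
  path_df <- data.frame(from = paths[, 1], to = paths[, 2],
                        estimate = fit$est, stringsAsFactors = FALSE)
  if (n_boot > 0) {
    bt <- matrix(NA_real_, n_boot, nrow(paths))
    .with_stream(seed, "plspm_boot", {
      for (b in seq_len(n_boot)) {
        ix <- sample.int(n, n, replace = TRUE)
        Xb <- lapply(blocks, function(cols)
          scale(as.matrix(data[ix, cols, drop = FALSE])))
        res <- tryCatch(core(Xb), error = function(e) NULL)
        if (!is.null(res)) {
          # align latent orientation with the full-sample solution
          flip <- vapply(seq_along(lat), function(k)
            sign(sum(res$loadings[[k]] * fit$loadings[[k]])), numeric(1))
          flip[flip == 0] <- 1
          bt[b, ] <- res$est * flip[match(paths[, 1], lat)] *
            flip[match(paths[, 2], lat)]
        }
      }
    })
    se <- apply(bt, 2, stats::sd, na.rm = TRUE)
    path_df$boot_se <- se
    path_df$p <- 2 * stats::pnorm(abs(fit$est) / se, lower.tail = FALSE)
  }
  # indirect effects: products along every directed chain of length >= 2
  chains <- list()
  walk <- function(node, prefix, coefprod) {
    outs <- which(paths[, 1] == node)
    for (o in outs) {
      nxt <- paths[o, 2]
      cp <- coefprod * fit$est[o]
      pth <- c(prefix, nxt)
      if (length(pth) > 2)
        chains[[paste(pth, collapse = " -> ")]] <<- cp
      walk(nxt, pth, cp)
    }
  }
  for (l in lat) walk(l, l, 1)
  ld <- do.call(rbind, lapply(lat, function(b)
    data.frame(block = b, indicator = blocks[[b]],
               loading = fit$loadings[[b]], stringsAsFactors = FALSE)))
  structure(list(scores = fit$Y, loadings = ld,
                 outer_weights = fit$W, paths = path_df, r2 = fit$r2,
                 gof = gof, gof_acceptable = gof > 0.60,
                 iterations = fit$it,
                 indirect = unlist(chains)),
            class = "plspm_fit")
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("PLS path model: GoF = %.3f (%s), %d iterations\n",
              x$gof, if (x$gof_acceptable) "acceptable (> 0.60)"
              else "below the 0.60 acceptability rule", x$iterations))
  print(x$paths)
  invisible(x)
}
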