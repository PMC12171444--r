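#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with the caller-supplied message.
.check <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed for one artifact from a master seed
#'
#' Each simulated artifact (count table, tree, gas series, soil table) draws
#' from its own RNG stream derived from the master seed and a stream label,
#' so adding a new output never perturbs existing ones.
#'
#' @param seed master integer seed.
#' @param stream character label of the artifact stream.
#' @return An integer seed in [0, 2^31).
#' @keywords internal
.stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Evaluate `expr` under a local, restored RNG state seeded from (seed, stream).
.with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.stream_seed(seed, stream))
  expr
}

# Compact multiple-comparison letter assignment (insert-and-absorb).
# `means` named numeric, `diff_mat` logical matrix: TRUE where the pair is
# significantly different. Letters assigned in order of decreasing mean.
.assign_letters <- function(means, diff_mat) {
  ord <- order(-means)
  g <- names(means)[ord]
  sets <- list()
  for (gi in g) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (all(!diff_mat[gi, sets[[k]]])) {
        sets[[k]] <- c(sets[[k]], gi)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- gi
  }
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) for (b in seq_along(sets)) {
    if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]))
      keep[a] <- FALSE
  }
  sets <- sets[keep]
  lab <- stats::setNames(rep("", length(means)), names(means))
  for (k in seq_along(sets))
    for (gi in sets[[k]]) lab[gi] <- paste0(lab[gi], letters[k])
  lab[g][lab[g] == ""] <- letters[length(sets) + 1L]
  lab
}
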