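# Readers and writers for the pipeline's plain-text formats: counts TSV
# (samples as rows), taxonomy TSV, metadata TSV, Newick trees, long-format
# gas CSV and the soil CSV. All tabular files are UTF-8, header row, "."
# decimal; IDs are opaque strings and joins are by ID.

#' Write / read an ASV count table (TSV, samples as rows)
#'
#' @param tbl a \code{\link{community_table}}; or for the reader, paths to
#'   the counts TSV and optional taxonomy/metadata TSVs.
#' @param counts_path,taxonomy_path,meta_path file paths.
#' @return \code{read_counts} returns a \code{\link{community_table}}.
#' @export
write_counts <- function(tbl, counts_path, taxonomy_path = NULL,
                         meta_path = NULL) {
  df <- data.frame(sample_id = rownames(tbl$counts), tbl$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(taxonomy_path))
    utils::write.table(tbl$taxonomy, taxonomy_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path) && !is.null(tbl$meta))
    utils::write.table(tbl$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, taxonomy_path = NULL,
                        meta_path = NULL) {
  df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  .check("sample_id" %in% names(df),
         "counts TSV must have a `sample_id` column")
  cnt <- as.matrix(df[setdiff(names(df), "sample_id")])
  .check(is.numeric(cnt), "count columns must be numeric")
  .check(all(cnt >= 0), "negative entry in counts file")
  rownames(cnt) <- df$sample_id
  tax <- if (!is.null(taxonomy_path))
    utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  meta <- if (!is.null(meta_path))
    utils::read.table(meta_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  community_table(cnt, tax, meta)
}

#' Write / read a phylogeny (Newick)
#'
#' Thin validated wrappers around the ape Newick parser.
#'
#' @param tree a \code{phylo} (or \code{\link{simulate_phylogeny}} result).
#' @param path file path.
#' @param tips optional ASV IDs that must all be present as tips.
#' @export
write_tree <- function(tree, path) {
  if (is.list(tree) && !inherits(tree, "phylo")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path, tips = NULL) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e)
    stop("Newick parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  .check(inherits(tree, "phylo"),
         sprintf("Newick parse error: no tree read from '%s'", path))
  if (!is.null(tips)) {
    missing <- setdiff(tips, tree$tip.label)
    .check(length(missing) == 0,
           sprintf("tree lacks tips for: %s",
                   paste(utils::head(missing, 5), collapse = ", ")))
  }
  tree
}

#' Write / read chamber gas series (long-format CSV)
#'
#' Schema: \code{plot_id, date, analyte, chamber_minutes, value, A, V,
#' temperature, P_ratio, D}. NH3 rows have one record per deployment
#' (chamber_minutes empty); N2O rows one record per timed reading.
#'
#' @param series list of \code{\link{chamber_series}} (or a
#'   \code{gas_simulation}).
#' @param path file path.
#' @export
write_gas <- function(series, path) {
  if (inherits(series, "gas_simulation")) series <- series$series
  rows <- lapply(series, function(s) {
    if (s$analyte == "NH3") {
      data.frame(plot_id = s$plot_id, date = s$date, analyte = "NH3",
                 chamber_minutes = NA_real_, value = s$readings,
                 A = s$A, V = s$V, temperature = NA_real_,
                 P_ratio = NA_real_, D = s$D, stringsAsFactors = FALSE)
    } else {
      data.frame(plot_id = s$plot_id, date = s$date, analyte = "N2O",
                 chamber_minutes = s$readings$minutes,
                 value = s$readings$conc, A = s$A, V = s$V,
                 temperature = s$temperature, P_ratio = s$P_ratio,
                 D = NA_real_, stringsAsFactors = FALSE)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gas
#' @export
read_gas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "date", "analyte", "chamber_minutes", "value",
            "A", "V")
  miss <- setdiff(need, names(df))
  .check(length(miss) == 0,
         sprintf("gas CSV lacks column(s): %s", paste(miss, collapse = ", ")))
  out <- list()
  key <- paste(df$plot_id, df$analyte, df$date)
  for (k in unique(key)) {
    g <- df[key == k, , drop = FALSE]
    if (g$analyte[1] == "NH3") {
      for (r in seq_len(nrow(g)))
        out[[length(out) + 1L]] <- chamber_series(
          g$plot_id[r], "NH3", g$date[r], A = g$A[r], V = g$V[r],
          readings = g$value[r], D = g$D[r])
    } else {
      g <- g[order(g$chamber_minutes), ]
      out[[length(out) + 1L]] <- chamber_series(
        g$plot_id[1], "N2O", g$date[1], A = g$A[1], V = g$V[1],
        readings = data.frame(minutes = g$chamber_minutes,
                              conc = g$value),
        temperature = g$temperature[1],
        P_ratio = ifelse(is.na(g$P_ratio[1]), 1, g$P_ratio[1]))
    }
  }
  out
}

#' Write / read a soil property table (CSV)
#'
#' @param soil a soil table data.frame.
#' @param path file path.
#' @export
write_soil <- function(soil, path) {
  utils::write.csv(soil, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_soil
#' @export
read_soil <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pattern", "n_level")
  miss <- setdiff(need, names(df))
  .check(length(miss) == 0,
         sprintf("soil CSV lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  props <- intersect(.soil_properties, names(df))
  for (pr in props)
    .check(all(df[[pr]] >= 0 | pr == "pH"),
           sprintf("negative concentration in column %s", pr))
  class(df) <- c("soil_table", "data.frame")
  df
}
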