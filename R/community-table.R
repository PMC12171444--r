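#' Construct a community table
#'
#' The central container of the pipeline: a samples x ASVs matrix of
#' non-negative integer counts, a taxonomy table and the sample metadata.
#' Joins are by ID, never positional.
#'
#' @param counts numeric matrix, samples in rows, ASVs in columns; rownames
#'   are sample IDs and colnames ASV IDs. All entries non-negative integers.
#' @param taxonomy data.frame with column \code{asv_id} plus any of
#'   \code{phylum, class, order, family, genus}; ASVs absent from it are
#'   filled in as "unclassified".
#' @param meta data.frame with columns \code{sample_id, pattern, n_level,
#'   replicate} covering every sample in \code{counts}.
#' @return An object of class \code{community_table} with elements
#'   \code{counts}, \code{taxonomy}, \code{meta}.
#' @export
community_table <- function(counts, taxonomy = NULL, meta = NULL) {
  counts <- as.matrix(counts)
  .check(!is.null(rownames(counts)) && !is.null(colnames(counts)),
         "`counts` needs sample rownames and ASV colnames")
  .check(!anyDuplicated(rownames(counts)), "sample IDs must be unique")
  .check(!anyDuplicated(colnames(counts)), "ASV IDs must be unique")
  .check(all(is.finite(counts)) && all(counts >= 0),
         "counts must be finite and non-negative")
  .check(max(abs(counts - round(counts))) < 1e-8,
         "counts must be integers")
  storage.mode(counts) <- "double"
  ranks <- c("phylum", "class", "order", "family", "genus")
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(asv_id = colnames(counts),
                           stringsAsFactors = FALSE)
  }
  .check("asv_id" %in% names(taxonomy), "taxonomy needs an `asv_id` column")
  missing_tax <- setdiff(colnames(counts), taxonomy$asv_id)
  if (length(missing_tax)) {
    add <- data.frame(asv_id = missing_tax, stringsAsFactors = FALSE)
    taxonomy <- merge(taxonomy, add, all = TRUE, sort = FALSE)
  }
  for (r in ranks) {
    if (!r %in% names(taxonomy)) taxonomy[[r]] <- NA_character_
    taxonomy[[r]][is.na(taxonomy[[r]])] <- "unclassified"
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$asv_id),
                       c("asv_id", ranks)]
  rownames(taxonomy) <- NULL
  if (!is.null(meta)) {
    .check("sample_id" %in% names(meta), "meta needs a `sample_id` column")
    .check(all(rownames(counts) %in% meta$sample_id),
           "meta must cover every sample in counts")
    meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy, meta = meta),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d ASVs (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$meta) && "pattern" %in% names(x$meta))
    cat("  groups:", paste(unique(x$meta$pattern), collapse = ", "), "\n")
  invisible(x)
}

# relative abundances (rows sum to 1); all-zero rows stay zero
.rel_abund <- function(counts) {
  rs <- rowSums(counts)
  rs[rs == 0] <- 1
  sweep(counts, 1, rs, "/")
}

#' Generate a plausible bacterial taxonomy for simulated ASVs
#'
#' Assigns each ASV to a phylum (drawn from the phyla that dominate arable
#' soils) and a synthetic genus label. Purely for fixture realism; the labels
#' carry no biological meaning.
#'
#' @param asv_ids character vector of ASV IDs.
#' @param phylum_prob optional named probability vector over phyla.
#' @return taxonomy data.frame suitable for \code{\link{community_table}}.
#' @export
random_taxonomy <- function(asv_ids,
                            phylum_prob = c(Proteobacteria = 0.25,
                                            Actinobacteriota = 0.21,
                                            Acidobacteriota = 0.19,
                                            Chloroflexi = 0.10,
                                            Gemmatimonadota = 0.08,
                                            Bacteroidota = 0.07,
                                            Myxococcota = 0.05,
                                            Firmicutes = 0.05)) {
  phylum_prob <- phylum_prob / sum(phylum_prob)
  ph <- sample(names(phylum_prob), length(asv_ids), replace = TRUE,
               prob = phylum_prob)
  data.frame(asv_id = asv_ids, phylum = ph,
             class = paste0(ph, "_c"), order = paste0(ph, "_o"),
             family = paste0(ph, "_f"),
             genus = paste0("g_", substr(ph, 1, 4), "_",
                            seq_along(asv_ids)),
             stringsAsFactors = FALSE)
}
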