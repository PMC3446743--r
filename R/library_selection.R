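#' Read library metadata
#'
#' Metadata TSV columns: `accession`, `description`, `cluster` (one of
#' C = cancer tissue, N = normal tissue and cells, IV = cells cultured in
#' vitro, D = nontumorous disease tissue and cells), `genetically_altered`
#' (0/1) and `complete_dataset` (0/1). The genetic-alteration and
#' completeness judgements are curation inputs, not inferred from sample
#' text.
#'
#' @param path Metadata TSV path.
#' @return Data frame of library metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  validate_metadata(df)
}

CLUSTER_CODES <- c("C", "N", "IV", "D")

validate_metadata <- function(df) {
  needed <- c("accession", "description", "cluster", "genetically_altered",
              "complete_dataset")
  if (!all(needed %in% names(df))) {
    stop("metadata is missing column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$accession)) {
    stop("duplicate accession in metadata: ",
         df$accession[duplicated(df$accession)][1])
  }
  bad <- which(!df$cluster %in% CLUSTER_CODES)
  if (length(bad)) {
    stop("invalid cluster code '", df$cluster[bad[1]], "' for ",
         df$accession[bad[1]], " (must be C, N, IV or D)")
  }
  df$genetically_altered <- as.logical(df$genetically_altered)
  df$complete_dataset <- as.logical(df$complete_dataset)
  df
}

#' Select SAGE libraries for analysis
#'
#' Applies the three selection criteria: a library is kept iff it represents
#' (i) a genetically unaltered/unmodified sample, (ii) a catalogue with at
#' least `min_tags` reliable tags (inclusive threshold), and (iii) a
#' complete dataset. Excluded libraries are reported with the first failing
#' criterion, checked in the order i, ii, iii.
#'
#' @param catalogues List of cleaned [sage_catalogue()] objects.
#' @param metadata Metadata data frame (see [read_metadata()]); every
#'   catalogue accession must be present.
#' @param min_tags Minimum reliable tag total (default 20,000).
#' @return An object of class `selection_report`: list with `kept`
#'   (accessions), `excluded` (named character vector accession ->
#'   criterion code in i/ii/iii), `per_cluster_counts`, `per_cluster_tags`,
#'   `total_tags`.
#' @export
select_libraries <- function(catalogues, metadata, min_tags = 20000) {
  metadata <- validate_metadata(metadata)
  accs <- vapply(catalogues, function(x) x$accession, character(1))
  cleaned <- vapply(catalogues, function(x) isTRUE(x$cleaned), logical(1))
  if (!all(cleaned)) {
    stop("all catalogues must be cleaned before selection (reliable totals)")
  }
  missing <- setdiff(accs, metadata$accession)
  if (length(missing)) {
    stop("no metadata for accession(s): ", paste(missing, collapse = ", "))
  }
  md <- metadata[match(accs, metadata$accession), ]
  totals <- vapply(catalogues, function(x) as.numeric(x$reliable_total),
                   numeric(1))
  code <- rep(NA_character_, length(accs))
  code[is.na(code) & md$genetically_altered] <- "i"
  code[is.na(code) & totals < min_tags] <- "ii"
  code[is.na(code) & !md$complete_dataset] <- "iii"
  kept <- accs[is.na(code)]
  excluded <- stats::setNames(code[!is.na(code)], accs[!is.na(code)])
  cl <- factor(md$cluster[is.na(code)], levels = CLUSTER_CODES)
  structure(
    list(
      kept = kept,
      excluded = excluded,
      per_cluster_counts = stats::setNames(as.integer(table(cl)),
                                           CLUSTER_CODES),
      per_cluster_tags = stats::setNames(
        as.numeric(tapply(totals[is.na(code)], cl, sum, default = 0)),
        CLUSTER_CODES),
      total_tags = sum(totals[is.na(code)])
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection report: %d kept, %d excluded, %s tags>\n",
              length(x$kept), length(x$excluded),
              format(x$total_tags, big.mark = ",")))
  if (length(x$excluded)) {
    tb <- table(factor(x$excluded, levels = c("i", "ii", "iii")))
    cat("  exclusions by criterion:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize selected libraries by cluster
#'
#' Produces the per-cluster table of catalogue counts and tag totals with a
#' grand-total row. Accepts either a [select_libraries()] report or a data
#' frame that already carries columns `cluster`, `n_catalogues`, `n_tags`
#' (e.g. a published summary whose totals are to be checked).
#'
#' @param x A `selection_report` or data frame.
#' @return Data frame with columns `cluster`, `n_catalogues`, `n_tags`; the
#'   final row is `Total` and equals the column sums.
#' @export
summarize_clusters <- function(x) UseMethod("summarize_clusters")

#' @export
summarize_clusters.selection_report <- function(x) {
  df <- data.frame(cluster = CLUSTER_CODES,
                   n_catalogues = as.integer(x$per_cluster_counts),
                   n_tags = as.numeric(x$per_cluster_tags),
                   stringsAsFactors = FALSE)
  add_totals_row(df)
}

#' @export
summarize_clusters.data.frame <- function(x) {
  needed <- c("cluster", "n_catalogues", "n_tags")
  if (!all(needed %in% names(x))) {
    stop("data frame must have columns cluster, n_catalogues, n_tags")
  }
  add_totals_row(x[x$cluster != "Total", needed])
}

add_totals_row <- function(df) {
  out <- rbind(df, data.frame(cluster = "Total",
                              n_catalogues = sum(df$n_catalogues),
                              n_tags = sum(df$n_tags),
                              stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Write a selection report to JSON
#'
#' @param report A `selection_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  jsonlite::write_json(
    list(kept = report$kept,
         excluded = as.list(report$excluded),
         per_cluster_counts = as.list(report$per_cluster_counts),
         per_cluster_tags = as.list(report$per_cluster_tags),
         total_tags = report$total_tags),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
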