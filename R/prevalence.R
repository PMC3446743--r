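#' Build a libraries-by-genes expression matrix for a gene panel
#'
#' Each cell is the tpm of the gene's SAGE tag in the library (0 when the
#' tag is absent). When two panel genes share a tag, both columns receive
#' that tag's tpm and a shared-tag warning is emitted; downstream cumulative
#' sums count each distinct tag once, so shared tags do not inflate the
#' panel's transcriptome share.
#'
#' @param catalogues List of `normalized_catalogue` objects.
#' @param panel A `gene_tag_catalogue` (columns `gene_symbol`, `tag`).
#' @return Numeric matrix (libraries x genes) with accession row names and
#'   gene-symbol column names; the gene -> tag map is kept in the `tag_of`
#'   attribute.
#' @export
build_matrix <- function(catalogues, panel) {
  stopifnot(is.data.frame(panel),
            all(c("gene_symbol", "tag") %in% names(panel)))
  if (!all(grepl("^[ACGT]{10}$", panel$tag))) {
    stop("panel tags must be 10-nt A/C/G/T strings")
  }
  shared <- unique(panel$tag[duplicated(panel$tag)])
  if (length(shared)) {
    warning("panel tag(s) shared by multiple genes: ",
            paste(shared, collapse = ", "),
            " (each gene is credited; cumulative sums count the tag once)")
  }
  accs <- vapply(catalogues, function(x) x$accession, character(1))
  m <- matrix(0, nrow = length(catalogues), ncol = nrow(panel),
              dimnames = list(accs, panel$gene_symbol))
  for (i in seq_along(catalogues)) {
    m[i, ] <- tpm_of(catalogues[[i]], panel$tag)
  }
  attr(m, "tag_of") <- stats::setNames(panel$tag, panel$gene_symbol)
  m
}

#' Build the matching raw-count matrix
#'
#' Raw (unnormalized) counts of the panel tags per library, used to decide
#' whether detections are at the minimum level (single tag).
#'
#' @param catalogues List of cleaned [sage_catalogue()] objects.
#' @param panel A `gene_tag_catalogue`.
#' @return Integer matrix (libraries x genes).
#' @export
build_raw_matrix <- function(catalogues, panel) {
  accs <- vapply(catalogues, function(x) x$accession, character(1))
  m <- matrix(0, nrow = length(catalogues), ncol = nrow(panel),
              dimnames = list(accs, panel$gene_symbol))
  for (i in seq_along(catalogues)) {
    v <- catalogues[[i]]$counts[panel$tag]
    v[is.na(v)] <- 0
    m[i, ] <- v
  }
  m
}

#' Summarize the panel's expression in one library
#'
#' Computes the cumulative (Sum), Average and Max tpm of the panel in a
#' library, the panel's percent of the transcriptome (Sum / 10^6 x 100) and
#' the single-gene dominance (Max / Sum). The average divides by the full
#' panel size including undetected genes. When a tag map is supplied, genes
#' sharing a tag contribute that tag's tpm once to the cumulative sum.
#'
#' @param values Named numeric vector of per-gene tpm (one matrix row).
#' @param n_panel_genes Panel size used for the average (default:
#'   `length(values)`).
#' @param tags Optional character vector of the genes' tags (same order),
#'   used to count shared tags once in the sum.
#' @param accession,cluster Optional identifiers carried into the summary.
#' @return One-row data frame with columns `accession`, `cluster`,
#'   `sum_tpm`, `avg_tpm`, `max_tpm`, `max_gene`,
#'   `percent_of_transcriptome`, `dominance`.
#' @export
summarize_library <- function(values, n_panel_genes = length(values),
                              tags = NULL, accession = NA_character_,
                              cluster = NA_character_) {
  stopifnot(n_panel_genes > 0)
  sum_vals <- if (is.null(tags)) values else values[!duplicated(tags)]
  sum_tpm <- sum(sum_vals)
  max_tpm <- if (length(values)) max(values) else 0
  max_gene <- NA_character_
  if (length(values) && max_tpm > 0 && !is.null(names(values))) {
    cand <- names(values)[values == max_tpm]
    max_gene <- sort(cand)[1]
  }
  data.frame(
    accession = accession, cluster = cluster,
    sum_tpm = sum_tpm,
    avg_tpm = sum_tpm / n_panel_genes,
    max_tpm = max_tpm,
    max_gene = max_gene,
    percent_of_transcriptome = sum_tpm / 1e6 * 100,
    dominance = if (sum_tpm > 0) max_tpm / sum_tpm else 0,
    stringsAsFactors = FALSE
  )
}

#' Summarize every library of an expression matrix
#'
#' @param matrix Matrix from [build_matrix()].
#' @param metadata Optional metadata data frame supplying cluster labels.
#' @param n_panel_genes Panel size for the average (default: number of
#'   matrix columns).
#' @return Data frame with one [summarize_library()] row per library.
#' @export
summarize_matrix <- function(matrix, metadata = NULL,
                             n_panel_genes = ncol(matrix)) {
  tags <- attr(matrix, "tag_of")
  if (!is.null(tags)) tags <- as.character(tags[colnames(matrix)])
  clusters <- rep(NA_character_, nrow(matrix))
  if (!is.null(metadata)) {
    clusters <- metadata$cluster[match(rownames(matrix), metadata$accession)]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(matrix)), function(i) {
    summarize_library(matrix[i, ], n_panel_genes = n_panel_genes, tags = tags,
                      accession = rownames(matrix)[i], cluster = clusters[i])
  }))
  rownames(out) <- NULL
  out
}

#' Single-gene dominance as a percentage
#'
#' Fraction of the panel's cumulative expression contributed by its single
#' most abundant gene, in percent.
#'
#' @param summary A data frame with columns `max_tpm` and `sum_tpm` (one or
#'   more rows, e.g. from [summarize_matrix()]).
#' @return Numeric vector of `max_tpm / sum_tpm * 100`.
#' @export
dominance_report <- function(summary) {
  stopifnot(is.data.frame(summary),
            all(c("max_tpm", "sum_tpm") %in% names(summary)))
  if (any(summary$sum_tpm == 0)) {
    stop("dominance is undefined for libraries with zero cumulative tpm")
  }
  summary$max_tpm / summary$sum_tpm * 100
}

#' Libraries with the most and least cumulative panel expression
#'
#' @param summaries Data frame of library summaries (needs `sum_tpm` and
#'   `accession`).
#' @param fraction Fraction of libraries in each extreme list (default 0.10);
#'   list length is `ceiling(fraction * n)`.
#' @return List with data frames `top` (sorted by decreasing `sum_tpm`) and
#'   `bottom` (increasing); ties broken by accession.
#' @export
rank_deciles <- function(summaries, fraction = 0.10) {
  stopifnot(fraction > 0, fraction < 0.5)
  if (nrow(summaries) == 0L) {
    return(list(top = summaries, bottom = summaries))
  }
  n <- ceiling(fraction * nrow(summaries))
  top <- summaries[order(-summaries$sum_tpm, summaries$accession), ][seq_len(n), ]
  bottom <- summaries[order(summaries$sum_tpm, summaries$accession), ][seq_len(n), ]
  rownames(top) <- rownames(bottom) <- NULL
  list(top = top, bottom = bottom)
}

#' Per-gene detection profiles across libraries
#'
#' For each panel gene, counts the libraries in which its tag was detected
#' and whether every detection was at the minimum level, i.e. a raw count
#' of one tag (a library's smallest nonzero observation).
#'
#' @param matrix tpm matrix from [build_matrix()].
#' @param raw_counts Matching raw-count matrix from [build_raw_matrix()]
#'   (same dimensions and dimnames).
#' @return Data frame with columns `gene_symbol`, `n_libraries_detected`,
#'   `min_level_only` (vacuously `TRUE` for genes never detected).
#' @export
detection_profiles <- function(matrix, raw_counts) {
  stopifnot(identical(dim(matrix), dim(raw_counts)),
            identical(colnames(matrix), colnames(raw_counts)))
  detected <- matrix > 0
  data.frame(
    gene_symbol = colnames(matrix),
    n_libraries_detected = colSums(detected),
    min_level_only = vapply(seq_len(ncol(matrix)), function(j) {
      all(raw_counts[detected[, j], j] == 1)
    }, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Cohort-level mean transcriptome share of the panel
#'
#' Unweighted arithmetic mean of `percent_of_transcriptome` per cluster and
#' over all libraries (libraries are equally weighted regardless of
#' sequencing depth).
#'
#' @param summaries Data frame of library summaries carrying `cluster` and
#'   `percent_of_transcriptome`.
#' @return List with `per_cluster` (named numeric, empty clusters omitted)
#'   and `overall` (numeric).
#' @export
cohort_statistics <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("cluster", "percent_of_transcriptome") %in% names(summaries)))
  per <- tapply(summaries$percent_of_transcriptome, summaries$cluster, mean)
  per <- per[!is.na(per)]
  list(per_cluster = stats::setNames(as.numeric(per), names(per)),
       overall = mean(summaries$percent_of_transcriptome))
}

#' Write an expression matrix as TSV
#'
#' @param matrix Matrix from [build_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(accession = rownames(matrix), as.data.frame(matrix),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
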