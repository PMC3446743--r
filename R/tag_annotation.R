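#' Locate anchoring-enzyme recognition sites on a transcript sequence
#'
#' Scans a sequence (given 5' to 3' in mRNA sense orientation) for exact,
#' possibly overlapping occurrences of the enzyme's recognition site.
#' Matching is case-insensitive; `N` bases never match.
#'
#' @param sequence A single DNA string over the alphabet A, C, G, T, N.
#' @param enzyme An [anchoring_enzyme()] object or enzyme name.
#' @return An increasing integer vector of 1-based start positions of the
#'   recognition site. Zero-length when the sequence carries no site.
#' @examples
#' find_sites("AACATGTT", "NlaIII")  # site starts at position 3
#' @export
find_sites <- function(sequence, enzyme = "NlaIII") {
  enzyme <- as_enzyme(enzyme)
  sequence <- check_sequence(sequence)
  # lookahead so overlapping occurrences are all reported
  hits <- gregexpr(paste0("(?=", enzyme$site, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits)
}

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("sequence must be a single character string")
  }
  if (nchar(sequence) == 0L) stop("sequence is empty")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside the A/C/G/T/N alphabet")
  }
  sequence
}

#' Extract the SAGE tag of a transcript
#'
#' Implements the virtual SAGE tag rule: the tag is the `tag_length`
#' nucleotides immediately 3' of the 3'-most anchoring-enzyme recognition
#' site that has at least `tag_length` downstream nucleotides. When the
#' 3'-most site is too close to the transcript end (or its downstream window
#' contains an `N`), extraction falls back to the next site upstream and the
#' result is flagged. A tag equal to the poly-A run `AAAAAAAAAA` is flagged
#' noninformative (such tags arise from poly-A tails, not coding sequence).
#'
#' @param sequence Transcript sequence, 5' to 3', mRNA sense.
#' @param enzyme An [anchoring_enzyme()] object or enzyme name.
#' @return A list with elements `tag` (10-nt string), `site` (1-based start
#'   of the recognition site used), `from_fallback_site` (logical: the
#'   3'-most site could not yield a tag) and `noninformative` (logical:
#'   tag equals the poly-A tag).
#' @section Errors:
#' Signals a condition of class `sage_no_site_error` when the sequence
#' carries no recognition site at all (the case of transcripts that cannot
#' be assayed by SAGE with this enzyme), and `sage_insufficient_downstream_error`
#' when sites exist but none has a full clean downstream tag window.
#' @examples
#' extract_tag("AAAACATGTTTTTTTTTTGG", "NlaIII")$tag
#' @export
extract_tag <- function(sequence, enzyme = "NlaIII") {
  enzyme <- as_enzyme(enzyme)
  sequence <- check_sequence(sequence)
  sites <- find_sites(sequence, enzyme)
  if (length(sites) == 0L) {
    stop(no_site_error(enzyme))
  }
  L <- enzyme$tag_length
  for (i in rev(seq_along(sites))) {
    start <- sites[i] + nchar(enzyme$site)
    end <- start + L - 1L
    if (end > nchar(sequence)) next
    tag <- substr(sequence, start, end)
    if (grepl("N", tag, fixed = TRUE)) next  # tags must be exact 10-mers
    return(list(
      tag = tag,
      site = sites[i],
      from_fallback_site = i < length(sites),
      noninformative = identical(tag, POLYA_TAG)
    ))
  }
  stop(insufficient_downstream_error(enzyme))
}

no_site_error <- function(enzyme) {
  structure(
    class = c("sage_no_site_error", "error", "condition"),
    list(message = sprintf("no %s recognition site (%s) in sequence",
                           enzyme$name, enzyme$site),
         call = NULL)
  )
}

insufficient_downstream_error <- function(enzyme) {
  structure(
    class = c("sage_insufficient_downstream_error", "error", "condition"),
    list(message = sprintf(
      "no %s site with %d clean downstream nucleotides", enzyme$name,
      enzyme$tag_length),
      call = NULL)
  )
}

#' Annotate a gene panel with SAGE tags
#'
#' Runs [extract_tag()] over a set of transcript sequences and assembles a
#' gene-tag catalogue. Genes whose sequence has no recognition site are
#' excluded from the catalogue and reported (transcripts invisible to SAGE
#' with this enzyme). When a set of expected tags is supplied, disagreements
#' are reported without overriding the extracted tags.
#'
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`)
#'   of transcript sequences; names are gene symbols and must be unique.
#' @param enzyme An [anchoring_enzyme()] object or enzyme name.
#' @param expected_tags Optional named character vector of tags to compare
#'   against.
#' @return A list with elements `catalogue` (a `gene_tag_catalogue`
#'   data frame: `gene_symbol`, `tag`, `from_fallback_site`,
#'   `noninformative`), `no_site_genes` and `mismatch_genes`.
#' @export
annotate_panel <- function(sequences, enzyme = "NlaIII", expected_tags = NULL) {
  enzyme <- as_enzyme(enzyme)
  if (inherits(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) > 0L &&
      (is.null(names(sequences)) || anyNA(names(sequences)) ||
       any(names(sequences) == ""))) {
    stop("all sequences must be named with a gene symbol")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate gene symbol(s): ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  }
  rows <- list()
  no_site <- character(0)
  for (gene in names(sequences)) {
    res <- tryCatch(extract_tag(sequences[[gene]], enzyme),
                    sage_no_site_error = function(e) NULL)
    if (is.null(res)) {
      no_site <- c(no_site, gene)
      next
    }
    rows[[gene]] <- data.frame(
      gene_symbol = gene, tag = res$tag,
      from_fallback_site = res$from_fallback_site,
      noninformative = res$noninformative,
      stringsAsFactors = FALSE
    )
  }
  catalogue <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(gene_symbol = character(0), tag = character(0),
                  from_fallback_site = logical(0), noninformative = logical(0))
  mismatch <- character(0)
  if (!is.null(expected_tags) && nrow(catalogue) > 0L) {
    common <- intersect(catalogue$gene_symbol, names(expected_tags))
    got <- catalogue$tag[match(common, catalogue$gene_symbol)]
    mismatch <- common[got != expected_tags[common]]
  }
  attr(catalogue, "enzyme") <- enzyme
  class(catalogue) <- c("gene_tag_catalogue", "data.frame")
  list(catalogue = catalogue, no_site_genes = no_site,
       mismatch_genes = mismatch)
}

#' Load the packaged imprinted-gene tag catalogue
#'
#' Reads the packaged panel of 173 established and candidate human imprinted
#' genes with their NlaIII SAGE tags, cytogenetic locations, expressed-allele
#' annotations and reliability flags (`multi` = tag also maps to other genes,
#' `repetitive` = highly repetitive tag, `replaced` = an unreliable internal
#' tag was replaced by the reliable 3' end tag).
#'
#' @param path Path to a catalogue TSV; defaults to the packaged fixture.
#' @return A `gene_tag_catalogue` data frame with columns `gene_symbol`,
#'   `gene_name`, `aliases`, `location`, `status` (Imprinted/Candidate),
#'   `expressed_allele`, `tag`, `multi_mapping`, `repetitive`,
#'   `replaced_unreliable`, `accession`.
#' @examples
#' panel <- load_panel_fixture()
#' nrow(panel)            # 173
#' table(panel$status)    # 53 Imprinted, 120 Candidate
#' @export
load_panel_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "imprinted_panel.tsv",
                        package = "imprintSAGE", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          na.strings = NULL)
  needed <- c("gene_symbol", "gene_name", "aliases", "location", "status",
              "expressed_allele", "tag", "flags", "accession")
  if (!all(needed %in% names(df))) {
    stop("panel catalogue is missing column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  bad <- which(!grepl("^[ACGT]{10}$", df$tag))
  if (length(bad)) {
    stop("malformed tag in panel catalogue row ", bad[1], " (",
         df$gene_symbol[bad[1]], "): '", df$tag[bad[1]], "'")
  }
  bad_status <- which(!df$status %in% c("Imprinted", "Candidate"))
  if (length(bad_status)) {
    stop("invalid status in panel catalogue row ", bad_status[1])
  }
  if (any(df$tag == POLYA_TAG)) {
    stop("panel catalogue contains the noninformative poly-A tag")
  }
  if (anyDuplicated(df$gene_symbol)) {
    stop("duplicate gene symbol in panel catalogue: ",
         df$gene_symbol[duplicated(df$gene_symbol)][1])
  }
  flag_set <- strsplit(ifelse(is.na(df$flags), "", df$flags), ",", fixed = TRUE)
  df$multi_mapping <- vapply(flag_set, function(f) "multi" %in% f, logical(1))
  df$repetitive <- vapply(flag_set, function(f) "repetitive" %in% f, logical(1))
  df$replaced_unreliable <- vapply(flag_set, function(f) "replaced" %in% f,
                                   logical(1))
  df$flags <- NULL
  attr(df, "enzyme") <- anchoring_enzyme("NlaIII")
  class(df) <- c("gene_tag_catalogue", "data.frame")
  df
}

#' @export
print.gene_tag_catalogue <- function(x, ...) {
  cat(sprintf("<gene-tag catalogue: %d genes", nrow(x)))
  if ("status" %in% names(x)) {
    tb <- table(x$status)
    cat(" (", paste(sprintf("%d %s", tb, names(tb)), collapse = ", "), ")",
        sep = "")
  }
  enz <- attr(x, "enzyme")
  if (!is.null(enz)) cat(", enzyme ", enz$name, sep = "")
  cat(">\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a multi-record FASTA file of transcript sequences
#'
#' Record identifiers (the first whitespace-delimited word of each header)
#' are taken as gene symbols.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' Write transcript sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
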