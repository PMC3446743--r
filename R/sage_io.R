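#' Construct a SAGE catalogue object
#'
#' A SAGE catalogue is one library's map from 10-nt tag to raw occurrence
#' count. Catalogues start out "raw"; [clean_catalogue()] removes the
#' noninformative poly-A tag (and optionally rare tags) and establishes the
#' reliable tag total that tpm normalization divides by.
#'
#' @param counts Named non-negative integer vector; names are 10-nt tags.
#' @param accession Library accession (e.g. a GEO GSM identifier).
#' @return An object of class `sage_catalogue`.
#' @export
sage_catalogue <- function(counts, accession = NA_character_) {
  counts <- validate_counts(counts)
  structure(
    list(accession = accession, counts = counts,
         reliable_total = NA_integer_, noninformative_removed = NA_integer_,
         cleaned = FALSE),
    class = "sage_catalogue"
  )
}

validate_counts <- function(counts) {
  if (length(counts) == 0L) return(stats::setNames(numeric(0), character(0)))
  tags <- names(counts)
  if (is.null(tags) || any(tags == "")) stop("counts must be named by tag")
  bad <- which(!grepl("^[ACGT]{10}$", tags))
  if (length(bad)) {
    stop("malformed tag '", tags[bad[1]], "': tags must be 10-nt A/C/G/T")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (anyDuplicated(tags)) {
    counts <- tapply(counts, tags, sum)  # aggregate repeated tag rows
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  counts[order(names(counts))]
}

#' @export
print.sage_catalogue <- function(x, ...) {
  cat(sprintf("<SAGE catalogue %s: %d distinct tags, %s total tags%s>\n",
              x$accession, length(x$counts),
              format(sum(x$counts), big.mark = ","),
              if (x$cleaned) sprintf(", cleaned (reliable total %s)",
                                     format(x$reliable_total, big.mark = ","))
              else ", raw"))
  invisible(x)
}

#' Read a SAGE catalogue from disk
#'
#' Two dialects are supported: plain two-column TSV (`TAG<TAB>COUNT`, with an
#' optional header line), and the GEO SOFT GSM sample format, in which the
#' tag-count table sits between `!sample_table_begin` and
#' `!sample_table_end` markers (only the first two table columns are used;
#' header metadata lines are kept as an attribute).
#'
#' @param path File to read.
#' @param dialect `"tsv"` or `"soft"`.
#' @param accession Accession to record; for SOFT files it defaults to the
#'   `^SAMPLE` / `!Sample_geo_accession` header, for TSV to the file name.
#' @return A raw (uncleaned) [sage_catalogue()].
#' @export
read_catalogue <- function(path, dialect = c("tsv", "soft"),
                           accession = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "soft") {
    acc_line <- grep("^(\\^SAMPLE\\s*=|!Sample_geo_accession\\s*=)", lines,
                     value = TRUE)
    if (is.null(accession) && length(acc_line)) {
      accession <- trimws(sub("^[^=]*=", "", acc_line[1]))
    }
    begin <- grep("^!sample_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!sample_table_end", lines, ignore.case = TRUE)
    if (length(begin) != 1L || length(end) != 1L || end <= begin) {
      stop("no !sample_table_begin/!sample_table_end block in ", path)
    }
    meta <- lines[seq_len(begin - 1L)]
    table_lines <- lines[(begin + 1L):(end - 1L)]
    offset <- begin
  } else {
    meta <- character(0)
    table_lines <- lines
    offset <- 0L
  }
  if (is.null(accession)) {
    accession <- sub("\\.[^.]*$", "", basename(path))
  }
  keep <- nzchar(trimws(table_lines))
  table_lines <- table_lines[keep]
  line_no <- (seq_along(keep)[keep]) + offset
  if (length(table_lines) == 0L) {
    cat_obj <- sage_catalogue(numeric(0), accession)
    attr(cat_obj, "soft_metadata") <- meta
    return(cat_obj)
  }
  fields <- strsplit(table_lines, "\t", fixed = TRUE)
  # a header line has neither a tag-like first field nor an integer count
  first <- trimws(fields[[1]])
  has_header <- !grepl("^[ACGTacgt]{10}$", first[1]) &&
    (length(first) < 2 || !grepl("^[0-9]+$", first[2]))
  if (has_header) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  if (length(fields) == 0L) {
    cat_obj <- sage_catalogue(numeric(0), accession)
    attr(cat_obj, "soft_metadata") <- meta
    return(cat_obj)
  }
  tags <- toupper(vapply(fields, function(f) trimws(f[1]), character(1)))
  count_str <- vapply(fields, function(f) {
    if (length(f) < 2) NA_character_ else trimws(f[2])
  }, character(1))
  bad <- which(!grepl("^[ACGT]{10}$", tags))
  if (length(bad)) {
    stop("line ", line_no[bad[1]], ": malformed tag '", tags[bad[1]],
         "' (must be 10-nt A/C/G/T)")
  }
  bad <- which(is.na(count_str) | !grepl("^[0-9]+$", count_str))
  if (length(bad)) {
    stop("line ", line_no[bad[1]], ": count '", count_str[bad[1]],
         "' is not a non-negative integer")
  }
  counts <- stats::setNames(as.numeric(count_str), tags)
  cat_obj <- sage_catalogue(counts, accession)
  attr(cat_obj, "soft_metadata") <- meta
  cat_obj
}

#' Write a SAGE catalogue as canonical two-column TSV
#'
#' Tags are written in lexicographic order with a `TAG<TAB>COUNT` header, so
#' a read/write round trip of a canonical file is byte-stable.
#'
#' @param cat A [sage_catalogue()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(cat, path) {
  stopifnot(inherits(cat, "sage_catalogue"))
  counts <- cat$counts[order(names(cat$counts))]
  writeLines(c("TAG\tCOUNT",
               sprintf("%s\t%d", names(counts), as.integer(counts))), path)
  invisible(path)
}

#' Remove noninformative and (optionally) rare tags from a catalogue
#'
#' The poly-A tag `AAAAAAAAAA` — a by-product of oligo(dT) priming carrying
#' no gene information — is removed and its count recorded. An optional
#' minimum-count filter drops tags observed fewer than `min_count` times;
#' `min_count = 5` emulates, at tag level, the clone-level "clean-up" that
#' discarded sequencing clones containing four or fewer tags (clone
#' composition is not recoverable from published tag tables). The remaining
#' counts form the pool of reliable tags used for tpm normalization.
#' Cleaning an already-clean catalogue is a no-op.
#'
#' @param cat A [sage_catalogue()].
#' @param min_count Minimum raw count for a tag to be retained (default 1,
#'   i.e. no count filter).
#' @return A cleaned `sage_catalogue` with `reliable_total` and
#'   `noninformative_removed` filled in.
#' @export
clean_catalogue <- function(cat, min_count = 1) {
  stopifnot(inherits(cat, "sage_catalogue"))
  counts <- cat$counts
  removed <- if (is.na(cat$noninformative_removed)) 0
             else cat$noninformative_removed
  if (POLYA_TAG %in% names(counts)) {
    removed <- removed + counts[[POLYA_TAG]]
    counts <- counts[names(counts) != POLYA_TAG]
  }
  counts <- counts[counts >= min_count]
  cat$counts <- counts
  cat$noninformative_removed <- removed
  cat$reliable_total <- sum(counts)
  cat$cleaned <- TRUE
  cat
}

#' Normalize a cleaned catalogue to tags per million
#'
#' tpm of a tag is its raw count divided by the library's reliable tag total,
#' multiplied by 1,000,000, so tpm values sum to one million in every
#' non-empty library and are directly comparable across libraries of
#' different sequencing depth.
#'
#' @param cat A cleaned [sage_catalogue()].
#' @return An object of class `normalized_catalogue` with elements
#'   `accession`, `tpm` (named numeric) and `reliable_total`.
#' @export
normalize_catalogue <- function(cat) {
  stopifnot(inherits(cat, "sage_catalogue"))
  if (!isTRUE(cat$cleaned)) {
    stop("catalogue must be cleaned (clean_catalogue) before normalization")
  }
  if (cat$reliable_total == 0 && length(cat$counts) > 0) {
    stop("internal inconsistency: zero reliable total with non-empty counts")
  }
  tpm <- if (length(cat$counts) == 0L) stats::setNames(numeric(0), character(0))
         else cat$counts / cat$reliable_total * 1e6
  structure(
    list(accession = cat$accession, tpm = tpm,
         reliable_total = cat$reliable_total),
    class = "normalized_catalogue"
  )
}

#' @export
print.normalized_catalogue <- function(x, ...) {
  cat(sprintf("<normalized SAGE catalogue %s: %d tags, reliable total %s>\n",
              x$accession, length(x$tpm),
              format(x$reliable_total, big.mark = ",")))
  invisible(x)
}

#' Look up the tpm of a tag in a normalized catalogue
#'
#' @param ncat A `normalized_catalogue`.
#' @param tags Character vector of 10-nt tags.
#' @return Numeric vector of tpm values; tags absent from the library
#'   return 0.
#' @export
tpm_of <- function(ncat, tags) {
  stopifnot(inherits(ncat, "normalized_catalogue"))
  out <- ncat$tpm[tags]
  out[is.na(out)] <- 0
  stats::setNames(as.numeric(out), tags)
}

#' Write a normalized catalogue as TSV (TAG, COUNT omitted, TPM)
#'
#' @param ncat A `normalized_catalogue`.
#' @param path Output path.
#' @param digits Decimal places used for display rounding of tpm (internal
#'   values are full precision; tables print 2 decimals).
#' @return `path`, invisibly.
#' @export
write_normalized <- function(ncat, path, digits = 2) {
  stopifnot(inherits(ncat, "normalized_catalogue"))
  tpm <- ncat$tpm[order(names(ncat$tpm))]
  writeLines(c("TAG\tTPM",
               sprintf("%s\t%.*f", names(tpm), digits, tpm)), path)
  invisible(path)
}

#' Exclude duplicate SAGE catalogues
#'
#' Public SAGE repositories carry many duplicate entries for the same
#' library under different accessions. Two rules are applied: (1) for each
#' known equivalence pair, the first-listed accession is kept and the second
#' removed; (2) any catalogues whose tag-count maps are identical in content
#' are collapsed to the first in input order.
#'
#' @param catalogues List of [sage_catalogue()] objects with unique
#'   accessions.
#' @param known_pairs Optional equivalences: a two-column data frame or
#'   matrix (keep, remove), or a list of length-2 character vectors. A pair
#'   naming an absent accession raises a warning, not an error.
#' @return A list with elements `catalogues` (the survivors, input order
#'   preserved) and `removed` (data frame with columns `kept`, `removed`,
#'   `rule`).
#' @export
deduplicate_catalogues <- function(catalogues, known_pairs = NULL) {
  accs <- vapply(catalogues, function(x) x$accession, character(1))
  if (anyDuplicated(accs)) stop("input accessions must be unique")
  drop <- logical(length(catalogues))
  kept_of <- character(0)
  removed_of <- character(0)
  rule_of <- character(0)
  if (!is.null(known_pairs)) {
    if (is.data.frame(known_pairs) || is.matrix(known_pairs)) {
      known_pairs <- lapply(seq_len(nrow(known_pairs)),
                            function(i) as.character(known_pairs[i, 1:2]))
    }
    for (p in known_pairs) {
      keep <- p[[1]]; remove <- p[[2]]
      if (!keep %in% accs || !remove %in% accs) {
        warning("equivalence pair (", keep, ", ", remove,
                ") references an absent accession; skipped")
        next
      }
      i <- match(remove, accs)
      if (!drop[i]) {
        drop[i] <- TRUE
        kept_of <- c(kept_of, keep)
        removed_of <- c(removed_of, remove)
        rule_of <- c(rule_of, "pair")
      }
    }
  }
  # content identity: identical tag->count maps collapse to first occurrence
  keys <- vapply(catalogues, function(x) {
    cc <- x$counts[order(names(x$counts))]
    paste(names(cc), cc, sep = ":", collapse = ";")
  }, character(1))
  seen_keys <- character(0)
  seen_accs <- character(0)
  for (i in seq_along(catalogues)) {
    if (drop[i]) next
    j <- match(keys[i], seen_keys)
    if (is.na(j)) {
      seen_keys <- c(seen_keys, keys[i])
      seen_accs <- c(seen_accs, accs[i])
    } else {
      drop[i] <- TRUE
      kept_of <- c(kept_of, seen_accs[j])
      removed_of <- c(removed_of, accs[i])
      rule_of <- c(rule_of, "content")
    }
  }
  list(
    catalogues = catalogues[!drop],
    removed = data.frame(kept = kept_of, removed = removed_of, rule = rule_of,
                         stringsAsFactors = FALSE)
  )
}
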