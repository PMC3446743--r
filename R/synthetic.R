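#' Configuration for the synthetic SAGE cohort generator
#'
#' The generator emulates the statistical structure of public NlaIII SAGE
#' catalogues: heavy-tailed background tag abundances, library depths from
#' twenty thousand to several hundred thousand tags, a noninformative
#' poly-A tag component, duplicate database entries, and a controllable
#' cumulative transcriptome fraction for a gene panel (the observed range
#' for the imprinted panel spans roughly 0.0008 to 0.045 of the reliable
#' transcriptome).
#'
#' @param n_libraries Number of regular libraries (default 50).
#' @param library_size_range Integer range of reliable (informative) tags
#'   per library, the quantity the selection threshold and tpm
#'   normalization operate on (default 20,000 to 400,000); poly-A
#'   contamination is added on top.
#' @param background_tag_pool Number of distinct background tags
#'   (default 5,000).
#' @param abundance_model `"zipf"` (rank-frequency power law) or
#'   `"lognormal"` for background abundances.
#' @param shape Shape parameter: the Zipf exponent (default 1.1) or the
#'   log-normal sdlog.
#' @param panel_fraction Target cumulative fraction of the reliable
#'   transcriptome carried by panel tags: a single number or a named
#'   per-cluster vector over C/N/IV/D (default 0.01).
#' @param dominance_concentration Dirichlet concentration for partitioning
#'   the panel share over genes; small values (< 0.1) produce single-gene
#'   dominated profiles, large values balanced ones (default 0.5).
#' @param polyA_fraction Expected fraction of raw tags that are the
#'   noninformative poly-A tag (default 0.02).
#' @param duplicate_rate Fraction of libraries duplicated verbatim under a
#'   new accession (default 0).
#' @param cluster_proportions Named proportions of the C/N/IV/D clusters;
#'   the default mirrors the composition of the public NlaIII catalogue set
#'   (185/166/112/29 out of 492).
#' @param n_undersized,n_altered,n_incomplete Numbers of extra libraries
#'   planted to violate selection criteria ii, i and iii respectively.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_libraries = 50,
                       library_size_range = c(20000L, 400000L),
                       background_tag_pool = 5000,
                       abundance_model = c("zipf", "lognormal"),
                       shape = 1.1,
                       panel_fraction = 0.01,
                       dominance_concentration = 0.5,
                       polyA_fraction = 0.02,
                       duplicate_rate = 0,
                       cluster_proportions = c(C = 185, N = 166,
                                               IV = 112, D = 29) / 492,
                       n_undersized = 0, n_altered = 0, n_incomplete = 0,
                       seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_libraries >= 1, library_size_range[1] >= 1,
            library_size_range[1] <= library_size_range[2],
            all(panel_fraction >= 0), all(panel_fraction < 1),
            polyA_fraction >= 0, polyA_fraction < 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            abs(sum(cluster_proportions) - 1) < 1e-8,
            all(names(cluster_proportions) %in% CLUSTER_CODES))
  if (!is.null(names(panel_fraction)) &&
      !all(CLUSTER_CODES %in% names(panel_fraction))) {
    stop("per-cluster panel_fraction must name all of C, N, IV, D")
  }
  structure(
    list(n_libraries = as.integer(n_libraries),
         library_size_range = as.integer(library_size_range),
         background_tag_pool = as.integer(background_tag_pool),
         abundance_model = abundance_model, shape = shape,
         panel_fraction = panel_fraction,
         dominance_concentration = dominance_concentration,
         polyA_fraction = polyA_fraction,
         duplicate_rate = duplicate_rate,
         cluster_proportions = cluster_proportions,
         n_undersized = as.integer(n_undersized),
         n_altered = as.integer(n_altered),
         n_incomplete = as.integer(n_incomplete),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

random_tags <- function(n, exclude = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need * 2L), function(i) {
      paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
    }, character(1))
    cand <- setdiff(unique(cand), c(exclude, out, POLYA_TAG))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Simulate a cohort of SAGE catalogues with known ground truth
#'
#' Per library, the reliable tag count is drawn uniformly from the
#' configured size range and noninformative poly-A tags are added on top so
#' that an expected `polyA_fraction` of the raw library is poly-A; a
#' binomial share of the reliable tags at the library's target panel
#' fraction is partitioned over the panel genes by a Dirichlet-multinomial
#' draw, and the rest is drawn from the heavy-tailed background model over
#' a fixed background tag pool. Optional exact
#' duplicate libraries and libraries planted to violate each selection
#' criterion are appended. Everything is reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param panel A `gene_tag_catalogue` supplying the panel tags (default:
#'   the packaged imprinted panel).
#' @return List with elements `catalogues` (raw [sage_catalogue()]s),
#'   `metadata` (data frame in [read_metadata()] layout) and `truth` (list:
#'   `panel_fraction` realized per library on reliable tags,
#'   `target_fraction`, `duplicate_pairs`, `intended_exclusions` named
#'   accession -> criterion code).
#' @export
simulate_cohort <- function(config, panel = load_panel_fixture()) {
  stopifnot(inherits(config, "sim_config"))
  panel_tags <- unique(panel$tag)
  withr::with_seed(config$seed, {
    pool <- random_tags(config$background_tag_pool, exclude = panel_tags)
    bg_prob <- switch(config$abundance_model,
      zipf = {
        p <- seq_along(pool)^(-config$shape)
        p / sum(p)
      },
      lognormal = {
        p <- sort(stats::rlnorm(length(pool), meanlog = 0,
                                sdlog = config$shape), decreasing = TRUE)
        p / sum(p)
      })

    n <- config$n_libraries
    clusters <- sample(rep(CLUSTER_CODES,
                           times = largest_remainder(
                             config$cluster_proportions[CLUSTER_CODES], n)))
    target_of <- function(cl) {
      if (is.null(names(config$panel_fraction))) config$panel_fraction
      else config$panel_fraction[[cl]]
    }

    make_library <- function(acc, cluster, reliable, target) {
      # poly-A tags ride on top of the reliable pool so that the expected
      # poly-A share of the raw library is polyA_fraction
      polyA_odds <- config$polyA_fraction / (1 - config$polyA_fraction)
      n_polyA <- stats::rbinom(1, reliable, polyA_odds)
      n_panel <- stats::rbinom(1, reliable, target)
      w <- stats::rgamma(length(panel_tags),
                         shape = config$dominance_concentration)
      if (sum(w) == 0) w <- rep(1, length(panel_tags))
      panel_counts <- as.numeric(stats::rmultinom(1, n_panel, w / sum(w)))
      bg_counts <- as.numeric(stats::rmultinom(1, reliable - n_panel, bg_prob))
      counts <- c(stats::setNames(panel_counts, panel_tags),
                  stats::setNames(bg_counts, pool))
      if (n_polyA > 0) counts <- c(counts, stats::setNames(n_polyA, POLYA_TAG))
      counts <- counts[counts > 0]
      list(cat = sage_catalogue(counts, acc),
           realized = sum(panel_counts) / reliable)
    }

    catalogues <- list()
    realized <- numeric(0)
    meta <- list()
    excl <- character(0)

    sizes <- sample_range(config$library_size_range, n)
    for (i in seq_len(n)) {
      acc <- sprintf("SYN%04d", i)
      lib <- make_library(acc, clusters[i], sizes[i], target_of(clusters[i]))
      catalogues[[acc]] <- lib$cat
      realized[acc] <- lib$realized
      meta[[acc]] <- data.frame(
        accession = acc, description = sprintf("synthetic sample %d", i),
        cluster = clusters[i], genetically_altered = FALSE,
        complete_dataset = TRUE, stringsAsFactors = FALSE)
    }

    plant <- function(kind, count, code) {
      for (j in seq_len(count)) {
        acc <- sprintf("SYN_%s%02d", toupper(kind), j)
        cl <- sample(CLUSTER_CODES, 1)
        total <- if (kind == "undersized") {
          sample_range(c(5000L, 19000L), 1)
        } else {
          sample_range(config$library_size_range, 1)
        }
        lib <- make_library(acc, cl, total, target_of(cl))
        catalogues[[acc]] <<- lib$cat
        realized[acc] <<- lib$realized
        meta[[acc]] <<- data.frame(
          accession = acc,
          description = sprintf("synthetic %s sample %d", kind, j),
          cluster = cl,
          genetically_altered = kind == "altered",
          complete_dataset = kind != "incomplete",
          stringsAsFactors = FALSE)
        excl[acc] <<- code
      }
    }
    plant("altered", config$n_altered, "i")
    plant("undersized", config$n_undersized, "ii")
    plant("incomplete", config$n_incomplete, "iii")

    dup_pairs <- NULL
    n_dup <- round(config$duplicate_rate * n)
    if (n_dup > 0) {
      originals <- sample(sprintf("SYN%04d", seq_len(n)), n_dup)
      for (j in seq_len(n_dup)) {
        src <- originals[j]
        acc <- sprintf("SYNDUP%02d", j)
        dup <- catalogues[[src]]
        dup$accession <- acc
        catalogues[[acc]] <- dup
        realized[acc] <- realized[src]
        md <- meta[[src]]
        md$accession <- acc
        md$description <- paste0(md$description, " (duplicate entry)")
        meta[[acc]] <- md
      }
      dup_pairs <- data.frame(kept = originals,
                              removed = sprintf("SYNDUP%02d", seq_len(n_dup)),
                              stringsAsFactors = FALSE)
    }

    list(
      catalogues = unname(catalogues),
      metadata = do.call(rbind, c(unname(meta), make.row.names = FALSE)),
      truth = list(panel_fraction = realized,
                   target_fraction = config$panel_fraction,
                   duplicate_pairs = dup_pairs,
                   intended_exclusions = excl)
    )
  })
}

# uniform integer draw on a closed range (safe for degenerate min == max)
sample_range <- function(range, n) {
  if (range[1] == range[2]) return(rep(as.integer(range[1]), n))
  sample(range[1]:range[2], n, replace = TRUE)
}

# integer allocation of n across proportions (largest remainder method)
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Simulate transcript sequences that carry a panel's SAGE tags
#'
#' For each gene, a random background sequence is emitted whose 3'-most
#' usable recognition site is immediately followed by the gene's tag, so
#' that [extract_tag()] inverts the construction exactly. The short 3'
#' remainder after the tag guarantees no downstream site can carry a full
#' tag window. Designated genes can instead be built without any
#' recognition site, emulating transcripts invisible to the enzyme.
#'
#' @param panel A `gene_tag_catalogue` (columns `gene_symbol`, `tag`).
#' @param enzyme An [anchoring_enzyme()] object or name.
#' @param seed Integer seed.
#' @param no_site_genes Gene symbols to emit without any recognition site.
#' @param flank_range Length range of the random 5' flank.
#' @return Named character vector of sequences (FASTA-ready via
#'   [write_fasta()]).
#' @export
simulate_panel_sequences <- function(panel, enzyme = "NlaIII", seed = 1L,
                                     no_site_genes = character(0),
                                     flank_range = c(60L, 240L)) {
  enzyme <- as_enzyme(enzyme)
  withr::with_seed(as.integer(seed), {
    out <- character(0)
    alphabet <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(panel))) {
      gene <- panel$gene_symbol[i]
      if (gene %in% no_site_genes) next
      flank <- paste(sample(alphabet, sample(flank_range[1]:flank_range[2], 1),
                            replace = TRUE), collapse = "")
      suffix <- paste(sample(alphabet, 3, replace = TRUE), collapse = "")
      out[gene] <- paste0(flank, enzyme$site, panel$tag[i], suffix)
    }
    for (gene in no_site_genes) {
      seq <- paste(sample(alphabet, sample(flank_range[1]:flank_range[2], 1),
                          replace = TRUE), collapse = "")
      while (grepl(enzyme$site, seq, fixed = TRUE)) {
        seq <- sub(enzyme$site, strip_site(enzyme$site), seq, fixed = TRUE)
      }
      out[gene] <- seq
    }
    out
  })
}

# change the last base of a site so the motif is destroyed
strip_site <- function(site) {
  last <- substr(site, nchar(site), nchar(site))
  repl <- setdiff(c("A", "C", "G", "T"), last)[1]
  paste0(substr(site, 1, nchar(site) - 1), repl)
}
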