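# Independent brute-force oracles used to validate the implementations.
# These deliberately use the most naive possible algorithms.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive 4-mer comparison at every offset
oracle_sites <- function(sequence, site = "CATG") {
  sequence <- toupper(sequence)
  w <- nchar(site)
  hits <- integer(0)
  for (p in seq_len(max(nchar(sequence) - w + 1L, 0L))) {
    if (substr(sequence, p, p + w - 1L) == site) hits <- c(hits, p)
  }
  hits
}

# enumerate all sites, take the last one whose 10-nt downstream window is
# complete and N-free; NULL when nothing qualifies
oracle_extract <- function(sequence, site = "CATG", tag_length = 10L) {
  sequence <- toupper(sequence)
  sites <- oracle_sites(sequence, site)
  if (length(sites) == 0) return(NULL)
  best <- NULL
  for (p in sites) {
    start <- p + nchar(site)
    end <- start + tag_length - 1L
    if (end > nchar(sequence)) next
    tag <- substr(sequence, start, end)
    if (grepl("N", tag, fixed = TRUE)) next
    best <- list(tag = tag, site = p, last = p == sites[length(sites)])
  }
  best
}

# naive UPGMA: recompute every cluster-pair average from the original
# distance matrix at each step
oracle_upgma <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in (a + 1L):length(clusters)) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        key <- c(min(clusters[[a]][1], clusters[[b]][1]),
                 max(clusters[[a]][1], clusters[[b]][1]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = d, a = a, b = b, key = key)
        }
      }
    }
    heights <- c(heights, best$d)
    merges <- c(merges, list(sort(c(min(clusters[[best$a]]),
                                    min(clusters[[best$b]])))))
    clusters[[best$a]] <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters[[best$b]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# exhaustive best 2-partition by summed correlation distance to the
# arithmetic-mean centroid
oracle_kmeans2 <- function(m) {
  n <- nrow(m)
  cost <- function(members) {
    if (length(members) == 0) return(Inf)
    centroid <- colMeans(m[members, , drop = FALSE])
    sum(vapply(members, function(i) {
      suppressWarnings(imprintSAGE::correlation_distance(m[i, ], centroid))
    }, numeric(1)))
  }
  best <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {   # fix item n in group B to kill symmetry
    a <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    b <- setdiff(seq_len(n), a)
    val <- cost(a) + cost(b)
    if (is.null(best) || val < best$val) best <- list(val = val, a = a, b = b)
  }
  best
}

# small random catalogue for io/normalization properties
random_catalogue <- function(n_tags = 50, max_count = 200,
                             accession = "SYNTEST") {
  tags <- unique(vapply(seq_len(n_tags * 2), function(i) random_dna(10),
                        character(1)))
  tags <- setdiff(tags, "AAAAAAAAAA")[seq_len(min(n_tags, length(tags)))]
  counts <- stats::setNames(sample(1:max_count, length(tags), replace = TRUE),
                            tags)
  sage_catalogue(counts, accession)
}
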