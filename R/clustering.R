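#' Correlation-based distance between two expression profiles
#'
#' Distance is `1 - r` where `r` is the Pearson correlation, giving values
#' in [0, 2]: 0 for identical shape, 1 for uncorrelated, 2 for perfectly
#' anticorrelated profiles. A profile with zero variance has no defined
#' correlation; its distance is set to 1 (the uncorrelated convention) with
#' a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single distance in [0, 2].
#' @export
correlation_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance profile: correlation distance set to 1")
    return(1)
  }
  1 - stats::cor(x, y)
}

# Pairwise correlation-distance matrix over the rows of m.
# Zero-variance rows get distance 1 to everything (0 to themselves).
cor_dist_matrix <- function(m, warn = TRUE) {
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0
  if (any(flat) && warn) {
    warning(sum(flat), " zero-variance profile(s): distances set to 1")
  }
  d <- matrix(1, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (any(!flat)) {
    r <- stats::cor(t(m[!flat, , drop = FALSE]))
    d[!flat, !flat] <- 1 - r
  }
  diag(d) <- 0
  d
}

# distance of rows of m to a single centroid profile
dist_to_profile <- function(m, centroid) {
  vapply(seq_len(nrow(m)), function(i) {
    suppressWarnings(correlation_distance(m[i, ], centroid))
  }, numeric(1))
}

#' K-means clustering of expression profiles under correlation distance
#'
#' Deterministic K-means in the style of the EPCLUST analyses: the first
#' seed is the profile farthest (by correlation distance) from the grand
#' mean profile; each further seed is the profile maximizing its average
#' distance to the seeds already chosen ("most distant (average)"
#' initialization). Assignment uses correlation distance to the arithmetic
#' mean profile of each cluster; iteration stops when labels stabilize, the
#' iteration cap is reached, or a step fails to decrease the objective (the
#' summed within-cluster distance to centroid), whichever comes first. All
#' ties break toward the lowest row/cluster index, so results are fully
#' deterministic for a given input.
#'
#' @param m Numeric matrix; rows are the items to cluster (libraries, after
#'   transposing a genes-by-libraries matrix).
#' @param k Number of clusters, `1 <= k <= nrow(m)`.
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (named integer vector), `sizes`, `singleton_clusters`, `centroids`,
#'   `objective_trace` (objective after each assignment pass) and `k`.
#' @export
kmeans_profiles <- function(m, k, max_iter = 100) {
  n <- nrow(m)
  if (k > n) stop("k (", k, ") exceeds the number of rows (", n, ")")
  stopifnot(k >= 1, max_iter >= 1)
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(n))

  # --- most-distant (average) seeding ---
  grand <- colMeans(m)
  d_grand <- dist_to_profile(m, grand)
  seeds <- which.max(d_grand)          # ties: lowest index (which.max rule)
  D <- cor_dist_matrix(m, warn = FALSE)
  while (length(seeds) < k) {
    avg_d <- colMeans(D[seeds, , drop = FALSE])
    avg_d[seeds] <- -Inf
    seeds <- c(seeds, which.max(avg_d))
  }
  centroids <- m[seeds, , drop = FALSE]

  assign_rows <- function(centroids) {
    dmat <- vapply(seq_len(nrow(centroids)),
                   function(j) dist_to_profile(m, centroids[j, ]),
                   numeric(n))
    dmat <- matrix(dmat, nrow = n)
    labels <- max.col(-dmat, ties.method = "first")
    list(labels = labels,
         objective = sum(dmat[cbind(seq_len(n), labels)]))
  }

  labels <- rep(NA_integer_, n)
  trace <- numeric(0)
  best_obj <- Inf
  for (iter in seq_len(max_iter)) {
    step <- assign_rows(centroids)
    if (step$objective > best_obj + 1e-12) break  # objective must not rise
    trace <- c(trace, step$objective)
    best_obj <- step$objective
    if (identical(step$labels, labels)) break
    labels <- step$labels
    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (length(members)) {
        centroids[j, ] <- colMeans(m[members, , drop = FALSE])
      }  # empty cluster keeps its previous centroid
    }
  }
  sizes <- tabulate(labels, nbins = k)
  structure(
    list(labels = stats::setNames(labels, rownames(m)),
         sizes = stats::setNames(sizes, seq_len(k)),
         singleton_clusters = which(sizes == 1L),
         centroids = centroids,
         objective_trace = trace,
         k = k),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<k-means assignment: k = %d, sizes %s%s>\n", x$k,
              paste(x$sizes, collapse = "/"),
              if (length(x$singleton_clusters))
                paste0(", singleton cluster(s) ",
                       paste(x$singleton_clusters, collapse = ","))
              else ""))
  invisible(x)
}

#' Choose k by the solitary-entry rule
#'
#' Runs [kmeans_profiles()] for increasing k and returns the smallest k
#' whose partition contains at least one cluster with a single member. This
#' reproduces the rule of setting the cluster number to the lowest value
#' that isolates one solitary database entry. If no k up to `k_max`
#' produces a singleton, `k_max` is returned with a warning.
#'
#' @param m Matrix of profiles (rows = items).
#' @param k_max Largest k to try (`<= nrow(m)`).
#' @param max_iter Iteration cap passed to [kmeans_profiles()].
#' @return List with elements `k` and `assignment`.
#' @export
choose_k <- function(m, k_max = nrow(m), max_iter = 100) {
  stopifnot(k_max <= nrow(m), k_max >= 1)
  for (k in seq_len(k_max)) {
    a <- kmeans_profiles(m, k, max_iter = max_iter)
    if (length(a$singleton_clusters) > 0) {
      return(list(k = k, assignment = a))
    }
  }
  warning("no k up to ", k_max, " yields a singleton cluster; returning k_max")
  list(k = k_max, assignment = a)
}

#' Average-linkage hierarchical clustering under correlation distance
#'
#' UPGMA-style agglomeration: the pair of clusters with the smallest
#' average pairwise correlation distance is merged repeatedly, recording
#' merge heights. Ties break toward the pair with the smallest original row
#' indices. Average linkage is reducible, so merge heights are
#' non-decreasing and the result is a valid ultrametric tree.
#'
#' @param m Matrix of profiles (rows = items, >= 2 rows).
#' @return An object of classes `sage_dendrogram` and `hclust` (fields
#'   `merge`, `height`, `order`, `labels`, `method`, `dist.method`), usable
#'   with [stats::cutree()], [stats::cophenetic()] and [ape::as.phylo()].
#' @export
hierarchical_profiles <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("hierarchical clustering needs at least 2 rows")
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(n))
  D <- cor_dist_matrix(m)

  active <- seq_len(n)              # current cluster ids
  id <- -seq_len(n)                 # hclust merge coding: negatives = leaves
  size <- rep(1L, n)
  rep_idx <- seq_len(n)             # smallest original row index per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    # find minimal average distance among active pairs, lexicographic tie-break
    best <- NULL
    for (ai in seq_along(active)[-length(active)]) {
      for (bi in (ai + 1L):length(active)) {
        i <- active[ai]; j <- active[bi]
        dij <- D[i, j]
        key <- sort(c(rep_idx[i], rep_idx[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = dij, i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[s, ] <- sort(c(id[i], id[j]))
    height[s] <- best$d
    # Lance-Williams update for unweighted average linkage
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    rep_idx[i] <- min(rep_idx[i], rep_idx[j])
    id[i] <- s
    active <- setdiff(active, j)
  }

  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(merge[node, 1]), leaf_order(merge[node, 2]))
  }
  structure(
    list(merge = merge, height = height, order = leaf_order(n - 1L),
         labels = rownames(m), method = "average",
         dist.method = "correlation", call = match.call()),
    class = c("sage_dendrogram", "hclust")
  )
}

#' Export a dendrogram as a newick tree
#'
#' Branch lengths derive from the merge heights (cophenetic depths), so the
#' tree is ultrametric.
#'
#' @param dend A dendrogram from [hierarchical_profiles()] (or any
#'   `hclust`).
#' @param path Output newick file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "hclust"))
  hc <- dend
  class(hc) <- "hclust"
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a cluster assignment as TSV
#'
#' @param assignment A `cluster_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  utils::write.table(
    data.frame(accession = names(assignment$labels),
               cluster_index = as.integer(assignment$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
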