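#' Average identity matrix over shared clusters
#'
#' Entry `(g, h)` is the mean percent protein identity over all
#' within-cluster gene pairs spanning genomes `g` and `h` (the hit store of
#' [build_similarity_graph()] supplies the identities). Genome pairs sharing
#' no cluster are imputed with the matrix minimum (least-similar semantics)
#' with a warning. Diagonal is 100 by definition.
#'
#' @param clusters a `ClusterSet`.
#' @param hits hit store data.frame (`q`, `s`, `pident`), e.g.
#'   `graph$hits`.
#' @return Symmetric genome x genome matrix of class `IdentityMatrix`
#'   (percent, 0--100).
#' @export
average_identity_matrix <- function(clusters, hits) {
  stopifnot(inherits(clusters, "ClusterSet"))
  genome_of <- clusters$genome_of
  genomes <- sort(unique(unname(genome_of)))
  cluster_of <- stats::setNames(
    rep(names(clusters$clusters), times = lengths(clusters$clusters)),
    unlist(clusters$clusters, use.names = FALSE))
  h <- hits[!is.na(cluster_of[hits$q]) & !is.na(cluster_of[hits$s]), ]
  h <- h[cluster_of[h$q] == cluster_of[h$s], ]
  gq <- unname(genome_of[h$q]); gs <- unname(genome_of[h$s])
  keep <- gq != gs
  h <- h[keep, ]; gq <- gq[keep]; gs <- gs[keep]

  n <- length(genomes)
  acc <- matrix(0, n, n, dimnames = list(genomes, genomes))
  cnt <- matrix(0L, n, n, dimnames = list(genomes, genomes))
  if (nrow(h)) {
    key <- paste(pmin(gq, gs), pmax(gq, gs))
    sums <- tapply(h$pident, key, sum)
    cnts <- tapply(h$pident, key, length)
    parts <- strsplit(names(sums), " ", fixed = TRUE)
    for (i in seq_along(sums)) {
      a <- parts[[i]][1L]; b <- parts[[i]][2L]
      acc[a, b] <- acc[b, a] <- sums[[i]]
      cnt[a, b] <- cnt[b, a] <- cnts[[i]]
    }
  }
  im <- acc / ifelse(cnt == 0, NA, cnt)
  diag(im) <- 100
  if (any(is.na(im))) {
    warning(sprintf("%d genome pairs share no cluster; imputing matrix minimum",
                    sum(is.na(im[upper.tri(im)]))))
    im[is.na(im)] <- min(im, na.rm = TRUE)
  }
  structure(im, class = c("IdentityMatrix", "matrix"))
}

#' Gower distance between the rows of a matrix
#'
#' `d(i, j) = mean_k |x_ik - x_jk| / range_k`, with zero-range columns
#' contributing 0. Distances lie in `[0, 1]` and the result is a metric on
#' the rows whenever all ranges are positive.
#'
#' @param matrix numeric matrix (e.g. an `IdentityMatrix`).
#' @return Symmetric row x row distance matrix.
#' @export
gower_distance <- function(matrix) {
  m <- unclass(matrix)
  assert_that(is.matrix(m) && nrow(m) >= 2, "need a matrix with >= 2 rows")
  rng <- apply(m, 2L, function(col) diff(range(col)))
  scale <- ifelse(rng == 0, 1, rng)     # zero-range columns contribute 0
  active <- rng > 0
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      contrib <- abs(m[i, ] - m[j, ]) / scale
      contrib[!active] <- 0
      d[i, j] <- d[j, i] <- mean(contrib)
    }
  }
  d
}

#' Agglomerative hierarchical clustering with a deterministic tie rule
#'
#' Plain agglomeration under single, complete or average (UPGMA-style,
#' size-weighted) linkage. Ties in the minimum inter-cluster distance are
#' broken by the lexicographically smallest pair of cluster representative
#' names (the smallest member name of each cluster), making the dendrogram
#' reproducible. The result is `stats::hclust`-compatible, so
#' [stats::cutree()] and `ape::as.phylo()` work on it.
#'
#' @param dist symmetric distance matrix with row/col names.
#' @param linkage "average" (default), "single" or "complete".
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(dist, linkage = c("average", "single",
                                                   "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(dist)
  assert_that(isSymmetric(unname(d), tol = 1e-8),
              "distance matrix must be symmetric")
  labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  n <- nrow(d)
  assert_that(n >= 2, "need >= 2 items")

  id <- -seq_len(n)                    # hclust convention: leaves negative
  rep_name <- labels                   # smallest member name per cluster
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL; best_d <- Inf
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in (ii + 1L):length(act)) {
        i <- act[ii]; j <- act[jj]
        dij <- D[i, j]
        if (dij < best_d - 1e-12) {
          best_d <- dij; best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-12 && !is.null(best)) {
          cand <- sort(c(rep_name[i], rep_name[j]))
          cur <- sort(c(rep_name[best[1L]], rep_name[best[2L]]))
          if (cand[1L] < cur[1L] ||
              (cand[1L] == cur[1L] && cand[2L] < cur[2L]))
            best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_d
    for (k in act) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- switch(linkage,
        single = min(D[i, k], D[j, k]),
        complete = max(D[i, k], D[j, k]),
        average = (size[i] * D[i, k] + size[j] * D[j, k]) /
          (size[i] + size[j]))
    }
    size[i] <- size[i] + size[j]
    rep_name[i] <- min(rep_name[i], rep_name[j])
    id[i] <- step
    active[j] <- FALSE
  }

  order <- dendro_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = linkage,
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

# leaf order by left-to-right traversal of the merge tree
dendro_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

#' Cut a dendrogram into k clades
#'
#' @param dendro an `hclust` object (e.g. from [hierarchical_cluster()]).
#' @param k number of groups, `1 <= k <= n`.
#' @return Named integer vector genome -> clade label (1..k, numbered by
#'   order of first appearance in the label order).
#' @export
extract_clades <- function(dendro, k) {
  stopifnot(inherits(dendro, "hclust"))
  n <- length(dendro$labels)
  assert_that(is_count(k) && k >= 1 && k <= n,
              sprintf("k must lie in [1, %d]", n))
  stats::cutree(dendro, k = k)
}

#' Export a dendrogram as Newick
#'
#' @param dendro an `hclust` object.
#' @param path file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  phy <- ape::as.phylo(dendro)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
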