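#' Markov clustering of the similarity graph into orthologous families
#'
#' Standard MCL: the weighted adjacency matrix gains self-loops equal to
#' each column's maximum, is column-normalized to a stochastic matrix, and
#' is then alternately expanded (matrix self-multiplication) and inflated
#' (entrywise power `inflation` followed by column renormalization), pruning
#' entries below `prune` each round, until the maximum entrywise change
#' falls below `tol`. Clusters are the connected components of the limit
#' matrix's support; genes with no edges become singletons.
#'
#' @param graph a `SimilarityGraph` from [build_similarity_graph()].
#' @param inflation inflation exponent (> 1; 1.5 by default, the customary
#'   ortholog-clustering setting).
#' @param max_iter iteration cap; non-convergence is an error naming it.
#' @param tol convergence threshold on the max entry change.
#' @param prune entries below this are zeroed each iteration.
#' @return An object of class `ClusterSet`: list with `clusters` (named list
#'   of gene-id vectors, ids `CL00001`, ...) and `genome_of`.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, max_iter = 200L,
                        tol = 1e-6, prune = 1e-6) {
  stopifnot(inherits(graph, "SimilarityGraph"))
  assert_that(inflation > 1, "inflation must be > 1")
  verts <- graph$vertices
  nv <- length(verts)
  e <- graph$edges
  assert_that(all(e$weight > 0), "edge weights must be positive")

  # vertices with any incident edge enter the MCL iteration; the rest are
  # singletons by definition
  touched <- sort(unique(c(e$from, e$to)))
  membership <- stats::setNames(seq_len(nv), verts)  # singleton default
  if (length(touched) >= 2 && nrow(e) > 0) {
    idx <- stats::setNames(seq_along(touched), touched)
    i <- idx[e$from]; j <- idx[e$to]
    M <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = rep(e$weight, 2L),
                              dims = c(length(touched), length(touched)))
    # self-loops: each column's maximum, then column-normalize
    loops <- apply_colmax(M)
    Matrix::diag(M) <- loops
    M <- normalize_cols(M)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      M2 <- M %*% M                      # expansion
      M2@x <- M2@x^inflation             # inflation
      M2 <- Matrix::drop0(M2, tol = prune)
      M2 <- normalize_cols(M2)
      delta <- max(abs(M2 - M))
      M <- M2
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf("MCL did not converge within %d iterations", max_iter))
    comp <- support_components(M)
    membership[touched] <- nv + comp     # offset keeps ids disjoint
  }
  cl <- split(verts, membership)
  # deterministic cluster order/ids: by smallest member gene id
  cl <- cl[order(vapply(cl, min, character(1L)))]
  names(cl) <- sprintf("CL%05d", seq_along(cl))
  structure(list(clusters = cl, genome_of = graph$genome_of),
            class = "ClusterSet")
}

apply_colmax <- function(M) {
  cs <- Matrix::summary(M)
  out <- numeric(ncol(M))
  agg <- tapply(cs$x, cs$j, max)
  out[as.integer(names(agg))] <- agg
  out[out == 0] <- 1
  out
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

# connected components of the nonzero support of a (column-stochastic)
# matrix, symmetrized; plain union-find
support_components <- function(M) {
  s <- Matrix::summary(M)
  n <- nrow(M)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(s))) {
    a <- find(s$i[r]); b <- find(s$j[r])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' @export
print.ClusterSet <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<ClusterSet> %d clusters over %d genes (largest %d, singletons %d)\n",
              length(sizes), sum(sizes), max(sizes), sum(sizes == 1L)))
  invisible(x)
}

#' Flat table view of a ClusterSet
#'
#' @param clusters a `ClusterSet`.
#' @return data.frame with columns `cluster_id`, `gene_id`, `genome_id` (the
#'   TSV interchange shape).
#' @export
cluster_table <- function(clusters) {
  stopifnot(inherits(clusters, "ClusterSet"))
  cid <- rep(names(clusters$clusters), times = lengths(clusters$clusters))
  gid <- unlist(clusters$clusters, use.names = FALSE)
  data.frame(cluster_id = cid, gene_id = gid,
             genome_id = unname(clusters$genome_of[gid]),
             stringsAsFactors = FALSE)
}

#' Write / read a ClusterSet as TSV
#'
#' @param clusters a `ClusterSet`.
#' @param path TSV file path.
#' @return `write_clusters` returns the path invisibly; `read_clusters`
#'   returns a `ClusterSet`.
#' @export
write_clusters <- function(clusters, path) {
  write_tsv(cluster_table(clusters), path)
}

#' Write one protein FASTA per cluster
#'
#' Mirrors the per-family FASTA output shape of classic ortholog-clustering
#' pipelines: one `<cluster_id>.faa` per cluster, headers
#' `genomeID|geneID`.
#'
#' @param clusters a `ClusterSet`.
#' @param genomes the `GenomeSet` holding the member sequences.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cluster_fastas <- function(clusters, genomes, dir) {
  stopifnot(inherits(clusters, "ClusterSet"), inherits(genomes, "GenomeSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- stats::setNames(seq_len(nrow(genomes$genes)),
                         genomes$genes$gene_id)
  paths <- vapply(names(clusters$clusters), function(cid) {
    gid <- clusters$clusters[[cid]]
    sub <- genomes$genes[idx[gid], , drop = FALSE]
    path <- file.path(dir, paste0(cid, ".faa"))
    writeLines(paste0(">", sub$genome_id, "|", sub$gene_id, "\n",
                      sub$protein), path)
    path
  }, "")
  invisible(unname(paths))
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  tab <- read_tsv(path)
  cl <- split(tab$gene_id, tab$cluster_id)
  structure(list(clusters = cl,
                 genome_of = stats::setNames(tab$genome_id, tab$gene_id)),
            class = "ClusterSet")
}
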