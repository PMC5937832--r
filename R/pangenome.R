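#' Gene-count quality filter (+/- k sigma)
#'
#' Excludes genomes whose gene count lies outside
#' `[mean - k*sigma, mean + k*sigma]`, with mean and *population* (divide by
#' n) standard deviation computed once over all input genomes. This is the
#' customary guard against poorly assembled genomes deflating the
#' core-genome.
#'
#' @param gene_counts named numeric vector, genome -> gene count.
#' @param k_sigma band half-width in standard deviations (default 2).
#' @return list with `kept` and `excluded` (character vectors of genome
#'   ids), plus `mean` and `sd` used.
#' @export
quality_filter <- function(gene_counts, k_sigma = 2) {
  assert_that(length(gene_counts) >= 1, "need at least one genome")
  assert_that(!is.null(names(gene_counts)), "gene_counts must be named")
  if (length(gene_counts) < 3)
    warning("fewer than 3 genomes: all kept, filter not meaningful")
  mu <- mean(gene_counts)
  sdv <- if (length(gene_counts) < 3) 0 else pop_sd(gene_counts)
  bad <- if (length(gene_counts) < 3) rep(FALSE, length(gene_counts)) else
    gene_counts < mu - k_sigma * sdv | gene_counts > mu + k_sigma * sdv
  list(kept = names(gene_counts)[!bad], excluded = names(gene_counts)[bad],
       mean = mu, sd = sdv)
}

#' Build the clusters x genomes copy-count matrix
#'
#' Entry `(c, g)` is the number of members of cluster `c` found in genome
#' `g` (paralog copies counted); singleton clusters are included, so every
#' cluster of the pan-genome appears as a row.
#'
#' @param clusters a `ClusterSet`.
#' @param genomes a `GenomeSet`; every clustered gene must belong to it.
#' @return Integer matrix with cluster ids as rownames and genome ids (in
#'   `GenomeSet` order) as colnames.
#' @export
build_presence_matrix <- function(clusters, genomes) {
  stopifnot(inherits(clusters, "ClusterSet"), inherits(genomes, "GenomeSet"))
  tab <- cluster_table(clusters)
  missing <- setdiff(tab$gene_id, genomes$genes$gene_id)
  assert_that(length(missing) == 0,
              sprintf("clustered genes absent from GenomeSet: %s",
                      paste(utils::head(missing, 3), collapse = ", ")))
  m <- table(factor(tab$cluster_id, levels = names(clusters$clusters)),
             factor(tab$genome_id, levels = genomes$genome_ids))
  m <- matrix(as.integer(m), nrow = nrow(m),
              dimnames = stats::setNames(dimnames(m), NULL))
  m
}

#' Partition the pan-genome into core / softcore / shell / cloud
#'
#' Occupancy `o(c)` is the number of genomes carrying at least one copy of
#' cluster `c`. Classes: core `o = n`; softcore `o >= ceil(0.95 n)` (core is
#' a subset of softcore); cloud `o <= 2`; shell otherwise. By construction
#' `|softcore| + |shell| + |cloud| = |pan|`.
#'
#' @param matrix presence matrix from [build_presence_matrix()].
#' @return An object of class `PartitionReport`: list with `class`
#'   (named factor per cluster, levels core/softcore/shell/cloud, where
#'   core clusters are labelled `core`), `sizes` (named vector with
#'   `core`, `softcore` (incl. core), `shell`, `cloud`, `pan`),
#'   `n_genomes`, `softcore_min`.
#' @export
partition_pangenome <- function(matrix) {
  n <- ncol(matrix)
  assert_that(n >= 3, "partitioning needs at least 3 genomes")
  occ <- rowSums(matrix > 0)
  assert_that(all(occ >= 1), "every cluster must occur in >= 1 genome")
  softcore_min <- ceiling(0.95 * n)
  cls <- classify_occupancy(occ, n_genomes = n)
  cls <- factor(cls, levels = c("core", "softcore", "shell", "cloud"))
  names(cls) <- rownames(matrix)
  sizes <- c(core = sum(cls == "core"),
             softcore = sum(cls %in% c("core", "softcore")),
             shell = sum(cls == "shell"),
             cloud = sum(cls == "cloud"),
             pan = length(cls))
  structure(list(class = cls, sizes = sizes, n_genomes = n,
                 softcore_min = softcore_min),
            class = "PartitionReport")
}

#' @export
print.PartitionReport <- function(x, ...) {
  s <- x$sizes
  cat(sprintf(paste0("<PartitionReport> %d genomes: core %d, softcore %d ",
                     "(threshold >= %d), shell %d, cloud %d, pan %d\n"),
              x$n_genomes, s[["core"]], s[["softcore"]], x$softcore_min,
              s[["shell"]], s[["cloud"]], s[["pan"]]))
  invisible(x)
}

#' Randomized pan/core rarefaction curves
#'
#' For each of `n_permutations` random genome orderings, `pan_k` is the
#' number of clusters present in the first `k` genomes and `core_k` the
#' number present in all of them. The customary choice for
#' `n_permutations` is the number of genomes.
#'
#' @param matrix presence matrix.
#' @param n_permutations number of random orderings (>= 1).
#' @param seed integer seed.
#' @return data.frame of class `RarefactionCurve` with columns
#'   `permutation`, `step`, `pan`, `core`; attribute `seed`.
#' @export
rarefaction_curves <- function(matrix, n_permutations = ncol(matrix),
                               seed = 1L) {
  assert_that(is_count(n_permutations) && n_permutations >= 1,
              "n_permutations must be >= 1")
  pres <- matrix > 0
  n <- ncol(pres)
  res <- with_seed(derive_seed(seed, "rarefaction"), {
    out <- vector("list", n_permutations)
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(n)
      seen <- rep(FALSE, nrow(pres))
      inall <- rep(TRUE, nrow(pres))
      pan <- core <- integer(n)
      for (k in seq_len(n)) {
        col <- pres[, ord[k]]
        seen <- seen | col
        inall <- inall & col
        pan[k] <- sum(seen); core[k] <- sum(inall)
      }
      out[[p]] <- data.frame(permutation = p, step = seq_len(n),
                             pan = pan, core = core)
    }
    do.call(rbind, out)
  })
  structure(res, class = c("RarefactionCurve", "data.frame"), seed = seed)
}

#' Open/closed pan-genome call from rarefaction tail slopes
#'
#' The tail slope is the mean marginal pan-genome gain (genes per added
#' genome) over the last `tail_window` steps, averaged over permutations. A
#' pan-genome still gaining ~50 genes per genome is open; one gaining only
#' 4--5 is closed. The decision threshold `closed_slope` defaults to 5
#' genes/genome.
#'
#' @param curves a `RarefactionCurve`.
#' @param tail_window steps in the tail; default `max(5, floor(n/5))`.
#' @param closed_slope closed iff tail slope <= this.
#' @return list with `status` ("open"/"closed"), `slope`, `tail_window`.
#' @export
classify_openness <- function(curves, tail_window = NULL, closed_slope = 5.0) {
  stopifnot(inherits(curves, "RarefactionCurve") || is.data.frame(curves))
  n <- max(curves$step)
  if (is.null(tail_window)) tail_window <- max(5L, floor(n / 5))
  assert_that(n >= tail_window + 1,
              "too few genomes for the requested tail window")
  slopes <- vapply(split(curves, curves$permutation), function(d) {
    d <- d[order(d$step), ]
    gains <- diff(d$pan)
    mean(utils::tail(gains, tail_window))
  }, 0)
  slope <- mean(slopes)
  list(status = if (slope <= closed_slope) "closed" else "open",
       slope = slope, tail_window = tail_window)
}

#' Clade-specific genes and gene-family expansions
#'
#' *Specific* clusters have at least one copy in every genome of clade A and
#' none in any genome of clade B. *Expansions* are clusters present in every
#' A genome whose minimum copy number over A strictly exceeds the maximum
#' over B.
#'
#' @param matrix presence matrix.
#' @param cladeA,cladeB disjoint, non-empty genome id sets (columns of the
#'   matrix).
#' @return list with `specific` and `expansions` (cluster id vectors).
#' @export
clade_specific_genes <- function(matrix, cladeA, cladeB) {
  assert_that(length(cladeA) > 0 && length(cladeB) > 0,
              "clades must be non-empty")
  assert_that(length(intersect(cladeA, cladeB)) == 0,
              "clades must be disjoint")
  assert_that(all(c(cladeA, cladeB) %in% colnames(matrix)),
              "clade genomes missing from the matrix")
  A <- matrix[, cladeA, drop = FALSE]
  B <- matrix[, cladeB, drop = FALSE]
  in_all_A <- rowSums(A > 0) == length(cladeA)
  specific <- in_all_A & rowSums(B > 0) == 0
  expansions <- in_all_A & apply(A, 1L, min) > apply(B, 1L, max)
  list(specific = rownames(matrix)[specific],
       expansions = rownames(matrix)[expansions])
}

#' Screen for horizontal gene transfer candidates (30--70% rule)
#'
#' A cluster is a candidate iff in *every* clade its presence fraction
#' (genomes with >= 1 copy / clade size) lies in `[low, high]` inclusive —
#' patchy presence in all clades being the signature of genes moving
#' between them.
#'
#' @param matrix presence matrix.
#' @param clades named vector genome -> clade covering the matrix columns;
#'   every clade needs >= 2 genomes.
#' @param low,high presence-fraction band (inclusive).
#' @return data.frame with `cluster_id`, one presence-fraction column per
#'   clade, and `candidate` (logical).
#' @export
hgt_screen <- function(matrix, clades, low = 0.30, high = 0.70) {
  assert_that(!is.null(names(clades)), "clades must be a named vector")
  assert_that(all(colnames(matrix) %in% names(clades)),
              "every matrix genome needs a clade label")
  clades <- clades[colnames(matrix)]
  sizes <- table(clades)
  assert_that(length(sizes) >= 2, "need >= 2 clades")
  assert_that(all(sizes >= 2), "every clade needs >= 2 genomes")
  fr <- sapply(names(sizes), function(cl) {
    g <- names(clades)[clades == cl]
    rowSums(matrix[, g, drop = FALSE] > 0) / length(g)
  })
  cand <- apply(fr >= low & fr <= high, 1L, all)
  out <- data.frame(cluster_id = rownames(matrix), fr, candidate = cand,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
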