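#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, of every table whose probability
#' does not exceed the observed table's (computed in log space; a relative
#' tolerance of 1e-7 guards against floating-point ties, as is customary).
#'
#' @param a,b,c,d non-negative integer cells of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  assert_that(all(is.finite(cells)) && all(cells >= 0) &&
                all(cells == floor(cells)),
              "cells must be non-negative integers")
  assert_that(sum(cells) > 0, "at least one cell must be positive")
  m <- a + b          # row-1 margin
  n <- c + d          # row-2 margin
  k <- a + c          # column-1 margin
  support <- max(0, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  logp_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= logp_obs + 1e-7]))
  min(p, 1)
}

#' Core-vs-pan functional-category enrichment table
#'
#' For every functional category, reports the fold increase of its gene
#' count from core to pan and from softcore to pan (computed on unrounded
#' counts, displayed rounded half-up to one decimal), and a two-sided
#' Fisher's exact p-value comparing the category against the pooled
#' remainder between the two gene sets
#' (`rbind(c(category in core, other core), c(category in pan, other pan))`
#' and likewise for softcore). A `Total` row over all categories is
#' appended. Categories with a zero core (or softcore) count get an `NA`
#' fold and an undefined-fold flag.
#'
#' @param counts data.frame with columns `category`, `core`, `softcore`,
#'   `pan` (non-negative integer gene counts; categories may overlap, as
#'   annotation schemes allow multi-category genes).
#' @param alpha significance threshold for the flag (default 0.01).
#' @return data.frame of class `EnrichmentTable`: `category`, `core`,
#'   `softcore`, `pan`, `fold_core_pan`, `fold_softcore_pan`,
#'   `p_core_pan`, `p_softcore_pan`, `sig_core_pan`, `sig_softcore_pan`,
#'   `fold_undefined`.
#' @export
fold_increase_table <- function(counts, alpha = 0.01) {
  need <- c("category", "core", "softcore", "pan")
  assert_that(is.data.frame(counts) && all(need %in% names(counts)),
              "counts needs columns category, core, softcore, pan")
  num <- c("core", "softcore", "pan")
  for (f in num)
    assert_that(all(counts[[f]] >= 0) && all(counts[[f]] == floor(counts[[f]])),
                "counts must be non-negative integers")
  tot <- vapply(counts[num], sum, 0)
  assert_that(all(tot > 0), "set totals must be > 0")
  full <- rbind(counts[, need],
                data.frame(category = "Total", core = tot[["core"]],
                           softcore = tot[["softcore"]], pan = tot[["pan"]]))
  fold <- function(x, y) ifelse(x > 0, round_half_up(y / x, 1L), NA_real_)
  full$fold_core_pan <- fold(full$core, full$pan)
  full$fold_softcore_pan <- fold(full$softcore, full$pan)
  full$p_core_pan <- mapply(function(cc, pp)
    fisher_exact(cc, tot[["core"]] - cc, pp, tot[["pan"]] - pp),
    full$core, full$pan)
  full$p_softcore_pan <- mapply(function(sc, pp)
    fisher_exact(sc, tot[["softcore"]] - sc, pp, tot[["pan"]] - pp),
    full$softcore, full$pan)
  full$sig_core_pan <- full$p_core_pan < alpha
  full$sig_softcore_pan <- full$p_softcore_pan < alpha
  full$fold_undefined <- full$core == 0 | full$softcore == 0
  rownames(full) <- NULL
  structure(full, class = c("EnrichmentTable", "data.frame"))
}

#' Category counts from an annotation table and a partition
#'
#' Crosses a gene -> category annotation (many-to-many allowed) with the
#' partition classes of the genes' clusters to produce the per-category
#' core/softcore/pan counts consumed by [fold_increase_table()].
#'
#' @param annotation data.frame with columns `gene_id`, `category`.
#' @param clusters a `ClusterSet`.
#' @param partition a `PartitionReport` for the clusters.
#' @return data.frame with `category`, `core`, `softcore`, `pan` counting
#'   annotated *clusters* (a cluster is annotated with the categories of
#'   its member genes).
#' @export
category_counts <- function(annotation, clusters, partition) {
  need <- c("gene_id", "category")
  assert_that(is.data.frame(annotation) && all(need %in% names(annotation)),
              "annotation needs columns gene_id, category")
  cluster_of <- stats::setNames(
    rep(names(clusters$clusters), times = lengths(clusters$clusters)),
    unlist(clusters$clusters, use.names = FALSE))
  ann <- annotation[annotation$gene_id %in% names(cluster_of), , drop = FALSE]
  ann$cluster <- unname(cluster_of[ann$gene_id])
  ann <- unique(ann[, c("cluster", "category")])
  cls <- partition$class[ann$cluster]
  cats <- sort(unique(ann$category))
  out <- data.frame(
    category = cats,
    core = vapply(cats, function(cc)
      length(unique(ann$cluster[ann$category == cc & cls == "core"])), 0L),
    softcore = vapply(cats, function(cc)
      length(unique(ann$cluster[ann$category == cc &
                                  cls %in% c("core", "softcore")])), 0L),
    pan = vapply(cats, function(cc)
      length(unique(ann$cluster[ann$category == cc])), 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
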