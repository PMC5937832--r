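#' Jukes--Cantor distance matrix from an alignment
#'
#' For each pair of rows, `p` is the mismatch fraction over columns where
#' both rows are ungapped (pairwise deletion) and
#' `d = -(3/4) ln(1 - 4p/3)`. The model is undefined for `p >= 0.75`; such
#' pairs are capped at `d_max` and flagged rather than erroring, as distance
#' software conventionally does.
#'
#' @param alignment an [msa()] with >= 2 rows.
#' @param d_max cap for saturated pairs (default 5.0 substitutions/site).
#' @return Symmetric distance matrix with a logical `"capped"` attribute
#'   marking saturated pairs (a warning is raised if any).
#' @export
jc_distance_matrix <- function(alignment, d_max = 5.0) {
  stopifnot(inherits(alignment, "MSA"))
  m <- as.matrix(alignment)
  assert_that(nrow(m) >= 2, "need >= 2 rows")
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(alignment$names, alignment$names))
  capped <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      assert_that(nc > 0, sprintf(
        "rows '%s' and '%s' share no comparable columns",
        alignment$names[i], alignment$names[j]))
      p <- sum(m[i, comp] != m[j, comp]) / nc
      if (p >= 0.75) {
        d[i, j] <- d[j, i] <- d_max
        capped[i, j] <- capped[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  if (any(capped)) warning("some pairs are saturated (p >= 0.75); capped")
  attr(d, "capped") <- capped
  d
}

#' Neighbor-joining tree
#'
#' Saitou--Nei agglomeration with a deterministic tie rule (ties in the
#' Q-criterion go to the lexicographically smallest pair of node names,
#' internal nodes being named by their smallest leaf). Negative branch
#' length estimates are clamped to 0. The result is unrooted (trifurcating
#' root node).
#'
#' @param dist symmetric distance matrix over >= 3 taxa with dimnames.
#' @return An `ape` `phylo` tree.
#' @export
nj_tree <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  assert_that(n >= 3, "neighbor joining needs >= 3 taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  nwk <- labels          # growing newick fragment per active node
  nname <- labels        # smallest contained leaf, for tie-breaking
  active <- rep(TRUE, n)
  fmt <- function(x) sprintf("%.10g", max(0, x))

  while (sum(active) > 3L) {
    act <- which(active)
    na <- length(act)
    r <- rowSums(D[act, act])
    best <- NULL; bestq <- Inf
    for (ii in seq_len(na - 1L)) {
      for (jj in (ii + 1L):na) {
        q <- (na - 2) * D[act[ii], act[jj]] - r[ii] - r[jj]
        pick <- FALSE
        if (q < bestq - 1e-12) pick <- TRUE
        else if (abs(q - bestq) <= 1e-12 && !is.null(best)) {
          cand <- sort(c(nname[act[ii]], nname[act[jj]]))
          cur <- sort(c(nname[best[1L]], nname[best[2L]]))
          pick <- cand[1L] < cur[1L] ||
            (cand[1L] == cur[1L] && cand[2L] < cur[2L])
        }
        if (pick) { bestq <- q; best <- c(act[ii], act[jj]) }
      }
    }
    i <- best[1L]; j <- best[2L]
    ri <- sum(D[i, act]); rj <- sum(D[j, act])
    li <- D[i, j] / 2 + (ri - rj) / (2 * (na - 2))
    lj <- D[i, j] - li
    u_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    # new node reuses slot i
    for (k in act) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- (D[i, k] + D[j, k] - D[i, j]) / 2
    }
    D[i, i] <- 0
    nwk[i] <- u_nwk
    nname[i] <- min(nname[i], nname[j])
    active[j] <- FALSE
  }

  act <- which(active)
  a <- act[1L]; b <- act[2L]; c3 <- act[3L]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[a], fmt(la), nwk[b], fmt(lb), nwk[c3], fmt(lc))
  ape::read.tree(text = txt)
}

# canonical keys for the non-trivial bipartitions of an unrooted tree:
# each split is represented by the sorted tip set on the side NOT holding
# the alphabetically first tip
bipartition_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    side <- tree$tip.label[cl]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (anchor %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_replicates` times,
#' rebuilds the Jukes--Cantor/NJ tree for each replicate, and reports for
#' every internal edge of the original tree the percentage of replicates
#' containing the same bipartition.
#'
#' @param alignment an [msa()].
#' @param n_replicates bootstrap replicates (default 100).
#' @param seed integer seed (same seed, same supports).
#' @param d_max passed to [jc_distance_matrix()].
#' @return The original tree (`phylo`) with `node.label` holding supports in
#'   `[0, 100]` (root label empty).
#' @export
bootstrap_support <- function(alignment, n_replicates = 100L, seed = 1L,
                              d_max = 5.0) {
  stopifnot(inherits(alignment, "MSA"))
  tree0 <- nj_tree(jc_distance_matrix(alignment, d_max = d_max))
  L <- nchar(alignment$seqs[1L])
  counts <- new.env(parent = emptyenv())
  with_seed(derive_seed(seed, "bootstrap"), {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rows <- vapply(strsplit(alignment$seqs, "", fixed = TRUE),
                     function(ch) paste0(ch[cols], collapse = ""), "")
      rep_msa <- msa(alignment$names, rows, alignment$cluster_id)
      rep_tree <- suppressWarnings(
        nj_tree(jc_distance_matrix(rep_msa, d_max = d_max)))
      for (k in bipartition_keys(rep_tree)) {
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      }
    }
  })
  # attach supports to tree0's internal nodes (prop.part order = node order)
  pp <- ape::prop.part(tree0)
  tips <- sort(tree0$tip.label); anchor <- tips[1L]
  labs <- character(tree0$Nnode)
  for (i in seq_along(pp)) {
    side <- tree0$tip.label[pp[[i]]]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) {
      labs[i] <- ""
      next
    }
    if (anchor %in% side) side <- setdiff(tips, side)
    k <- paste(sort(side), collapse = "|")
    labs[i] <- sprintf("%g", 100 * (counts[[k]] %||% 0L) / n_replicates)
  }
  tree0$node.label <- labs
  tree0
}

#' Nodal distance between two trees
#'
#' Path lengths are counted in edges on the unrooted topology (branch
#' lengths ignored); the score is the root-mean-square difference of the
#' two leaf-pair path-length matrices:
#' `sqrt( sum_{i<j} (p1(i,j) - p2(i,j))^2 / P )` with `P` the number of
#' leaf pairs. Identical topologies score 0; the higher the score, the less
#' alike the trees.
#'
#' @param t1,t2 `phylo` trees on identical leaf sets.
#' @return Non-negative numeric score.
#' @export
nodal_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    stop(sprintf("leaf sets differ; only in tree 1: {%s}; only in tree 2: {%s}",
                 paste(setdiff(l1, l2), collapse = ","),
                 paste(setdiff(l2, l1), collapse = ",")))
  }
  p1 <- path_length_matrix(t1)[l1, l1]
  p2 <- path_length_matrix(t2)[l1, l1]
  P <- length(l1) * (length(l1) - 1) / 2
  sqrt(sum((p1 - p2)[upper.tri(p1)]^2) / P)
}

path_length_matrix <- function(tree) {
  t2 <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  n <- length(t2$tip.label)
  D <- ape::dist.nodes(t2)[seq_len(n), seq_len(n)]
  dimnames(D) <- list(t2$tip.label, t2$tip.label)
  D
}

#' Random-topology nodal-distance baseline
#'
#' Generates `n_random` uniformly random unrooted binary topologies on the
#' focal tree's leaf set and reports the mean and standard deviation of
#' their nodal distances to it — the scale against which a gene tree's
#' distance can be judged.
#'
#' @param tree focal `phylo` tree with >= 4 leaves.
#' @param n_random number of random topologies (default 10).
#' @param seed integer seed.
#' @return list with `mean`, `sd` and the individual `distances`.
#' @export
random_tree_baseline <- function(tree, n_random = 10L, seed = 1L) {
  leaves <- tree$tip.label
  assert_that(length(leaves) >= 4, "need >= 4 leaves")
  dists <- with_seed(derive_seed(seed, "baseline"), {
    vapply(seq_len(n_random), function(i) {
      rt <- ape::rtopology(length(leaves), rooted = FALSE,
                           tip.label = sample(leaves))
      nodal_distance(tree, rt)
    }, 0)
  })
  list(mean = mean(dists), sd = stats::sd(dists), distances = dists)
}

#' Screen gene trees against a reference topology by nodal distance
#'
#' Builds a Jukes--Cantor/NJ tree for every core-gene alignment, scores its
#' nodal distance to the reference tree (pruned to the gene's strains when
#' needed), adds a random-topology baseline per gene, and extracts the genes
#' below the 5% and above the 95% percentile of the distance distribution
#' (linear interpolation between order statistics). Each gene is annotated
#' with its consensus-based SNP statistics.
#'
#' @param alignments named list of [msa()] objects (core genes).
#' @param reference reference `phylo` tree (e.g. the pan-genome dendrogram
#'   topology via `ape::as.phylo`); genes whose strains are not covered by
#'   it are skipped with a message.
#' @param lower,upper tail percentiles (defaults 0.05 / 0.95).
#' @param n_random random trees per gene baseline.
#' @param seed integer seed.
#' @return An object of class `NodalReport`: list with `table` (per-gene
#'   data.frame: gene, n_leaves, nodal, baseline_mean, baseline_sd,
#'   normalized, sum_snp, snp_per_base, polyvariable, length), `q_lower`,
#'   `q_upper`, `lower_tail`, `upper_tail` (gene ids), `tail_summary`
#'   (mean/sd nodal, mean length, mean SNP density per tail) and `skipped`.
#' @export
gene_tree_screen <- function(alignments, reference, lower = 0.05,
                             upper = 0.95, n_random = 10L, seed = 1L) {
  stopifnot(is.list(alignments), inherits(reference, "phylo"))
  if (is.null(names(alignments)))
    names(alignments) <- paste0("gene", seq_along(alignments))
  rows <- list(); skipped <- character(0)
  for (gi in seq_along(alignments)) {
    g <- names(alignments)[gi]
    al <- alignments[[gi]]
    extra <- setdiff(al$names, reference$tip.label)
    if (length(extra) > 0 || length(al$names) < 4) {
      message(sprintf("skipping gene '%s': %s", g,
                      if (length(extra)) "strains missing from reference"
                      else "fewer than 4 strains"))
      skipped <- c(skipped, g)
      next
    }
    ref_g <- if (length(al$names) < length(reference$tip.label))
      ape::keep.tip(reference, al$names) else reference
    gt <- suppressWarnings(nj_tree(jc_distance_matrix(al)))
    nd <- nodal_distance(gt, ref_g)
    bl <- random_tree_baseline(ref_g, n_random = n_random,
                               seed = derive_seed(seed, gi))
    cons <- build_consensus(al)
    snp <- call_snps(al, cons)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, n_leaves = length(al$names), nodal = nd,
      baseline_mean = bl$mean, baseline_sd = bl$sd,
      normalized = if (bl$mean > 0) nd / bl$mean else NA_real_,
      sum_snp = snp$sum_snp, snp_per_base = snp$snp_per_base,
      polyvariable = snp$n_polyvariable, length = snp$length,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  assert_that(!is.null(tab) && nrow(tab) >= 2, "not enough usable genes")
  q <- stats::quantile(tab$nodal, c(lower, upper), type = 7, names = FALSE)
  degenerate <- q[1L] == q[2L]
  if (degenerate)
    warning("nodal distances are degenerate (identical percentile cutoffs); tails empty")
  lower_tail <- if (degenerate) character(0) else tab$gene[tab$nodal <= q[1L]]
  upper_tail <- if (degenerate) character(0) else tab$gene[tab$nodal >= q[2L]]
  tail_summary <- do.call(rbind, lapply(
    list(lower = lower_tail, upper = upper_tail), function(ids) {
      s <- tab[tab$gene %in% ids, , drop = FALSE]
      data.frame(n = nrow(s), mean_nodal = mean(s$nodal),
                 sd_nodal = stats::sd(s$nodal),
                 mean_length = mean(s$length),
                 mean_snp_per_kb = mean(1000 * s$sum_snp / s$length))
    }))
  structure(list(table = tab, q_lower = q[1L], q_upper = q[2L],
                 lower_tail = lower_tail, upper_tail = upper_tail,
                 tail_summary = tail_summary, skipped = skipped),
            class = "NodalReport")
}

#' @export
print.NodalReport <- function(x, ...) {
  cat(sprintf(paste0("<NodalReport> %d genes (%d skipped); cutoffs %.3f / ",
                     "%.3f; tails %d / %d\n"),
              nrow(x$table), length(x$skipped), x$q_lower, x$q_upper,
              length(x$lower_tail), length(x$upper_tail)))
  invisible(x)
}
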