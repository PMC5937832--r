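test_that("center-star alignment handles the canonical cases", {
  al <- center_star_align(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT"))
  expect_identical(al$seqs, rep("ACGT", 3))      # identical -> gap-free
  al2 <- center_star_align(c(a = "ACGT", b = "ACG"))
  m <- as.matrix(al2)
  expect_identical(ncol(m), 4L)
  expect_identical(sum(m == "-"), 1L)            # exactly one gap column
  expect_identical(gsub("-", "", al2$seqs[1]), "ACGT")
  expect_identical(gsub("-", "", al2$seqs[2]), "ACG")
  expect_error(center_star_align(c("ACGT", "")), "empty")
  expect_error(center_star_align("ACGT"), ">= 2")
})

test_that("center-star rows ungap back to the inputs (property)", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      seqs <- vapply(1:4, function(i) {
        n <- sample(40:60, 1)
        paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      }, "")
      names(seqs) <- paste0("s", 1:4)
      al <- center_star_align(seqs)
      expect_length(unique(nchar(al$seqs)), 1L)  # equal row lengths
      expect_identical(gsub("-", "", al$seqs), unname(seqs))
    }
  })
})

test_that("Jukes-Cantor distances match the closed form", {
  al <- msa(c("a", "b"), c("AAAAAAAAAA", "AAAAAAAAAG"))  # p = 0.1
  d <- jc_distance_matrix(al)
  expect_equal(d["a", "b"], -0.75 * log(1 - 4 * 0.1 / 3))
  expect_equal(d["a", "b"], 0.1073256, tolerance = 1e-6)
  same <- msa(c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(jc_distance_matrix(same)["a", "b"], 0)
  # saturation: p = 0.8 -> capped with flag and warning
  sat <- msa(c("a", "b"), c("AAAAAAAAAA", "GGGGGGGGAA"))
  expect_warning(ds <- jc_distance_matrix(sat, d_max = 5), "saturated")
  expect_equal(ds["a", "b"], 5)
  expect_true(attr(ds, "capped")["a", "b"])
  # pairwise deletion: gap columns are skipped per pair
  gap <- msa(c("a", "b"), c("A-AAAAAAAAA", "AGAAAAAAAAG"))
  expect_equal(jc_distance_matrix(gap)["a", "b"],
               -0.75 * log(1 - 4 * 0.1 / 3))
  none <- msa(c("a", "b"), c("A---", "-AAA"))
  expect_error(jc_distance_matrix(none), "comparable")
})

test_that("NJ reconstructs the worked additive quartet exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)): the additive distances
  lab <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(lab, lab))
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, lab)
  # topology AB|CD: path A-B has 2 edges, A-C has 3
  tu <- tr
  tu$edge.length <- rep(1, nrow(tu$edge))
  p <- ape::dist.nodes(tu)[1:4, 1:4]
  dimnames(p) <- list(tr$tip.label, tr$tip.label)
  expect_equal(unname(p["A", "B"]), 2)
  expect_equal(unname(p["A", "C"]), 3)
  # additivity: cophenetic distances reproduce the input exactly
  expect_equal(ape::cophenetic.phylo(tr)[lab, lab], D, tolerance = 1e-9)
  # least-squares oracle: AB|CD fits with zero residual, alternatives do not
  fit_q <- function(split) {
    # sum of squared residuals of the best edge-length fit for a quartet
    # topology (closed form via the four-point condition)
    s1 <- D["A", split[1]] + D[split[2], split[3]]
    s2 <- D["A", split[2]] + D[split[1], split[3]]
    s3 <- D["A", split[3]] + D[split[1], split[2]]
    c(s1, s2, s3)
  }
  sums <- fit_q(c("B", "C", "D"))  # pairings AB|CD, AC|BD, AD|BC
  expect_true(sums[1] < sums[2] && sums[1] < sums[3])
})

test_that("NJ handles the 3-taxon star and preserves leaf sets", {
  lab <- c("x", "y", "z")
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(lab, lab))
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, lab)
  expect_identical(tr$Nnode, 1L)
  # branch lengths from the three-point formulas
  el <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("x", "y", "z")]), c(0.5, 1.5, 2.5))
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers random additive trees (oracle: ape cophenetic)", {
  withr::with_seed(17, {
    for (n in 4:6) {
      for (rep in 1:5) {
        ref <- ape::rtree(n, rooted = FALSE,
                          br = function(k) runif(k, 0.1, 1))
        D <- ape::cophenetic.phylo(ref)
        tr <- nj_tree(D)
        expect_equal(nodal_distance(tr, ref), 0)
        expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)],
                     D, tolerance = 1e-8)
      }
    }
  })
})

test_that("nodal distance: identity, the NNI quartet, and leaf-set errors", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(nodal_distance(t1, t1), 0)
  expect_equal(nodal_distance(t1, t2), sqrt(4 / 6))
  expect_equal(nodal_distance(t2, t1), nodal_distance(t1, t2))
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(nodal_distance(t1, t3), "only in tree 2: \\{E\\}")
})

test_that("nodal distance is zero iff topologies agree on 4-5 leaves", {
  # exhaustive: all unrooted topologies on 4 and 5 leaves
  skip_if_not_installed("phangorn")
  for (n in 4:5) {
    tl <- phangorn::allTrees(n, rooted = FALSE, tip.label = letters[1:n])
    for (i in seq_along(tl)) {
      for (j in seq_along(tl)) {
        d <- nodal_distance(tl[[i]], tl[[j]])
        if (i == j) expect_equal(d, 0) else expect_gt(d, 0)
        expect_equal(d, nodal_distance(tl[[j]], tl[[i]]))
      }
    }
  }
})

test_that("random baseline is seeded, sized and non-negative", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  b1 <- random_tree_baseline(tr, seed = 3)
  b2 <- random_tree_baseline(tr, seed = 3)
  expect_identical(b1, b2)
  expect_length(b1$distances, 10L)            # default n_random = 10
  expect_gte(b1$mean, 0)
  expect_error(random_tree_baseline(ape::read.tree(text = "((A,B),C);")),
               ">= 4")
})

test_that("bootstrap supports are percentages, seeded, and high for a clean quartet", {
  # deep AB|CD divergence over 10 kb
  withr::with_seed(23, {
    anc <- random_dna(10000)
    left <- mutate_sequence(anc, 0.15, seed = 101)
    al <- msa(c("A", "B", "C", "D"),
              c(mutate_sequence(left, 0.01, seed = 1),
                mutate_sequence(left, 0.01, seed = 2),
                mutate_sequence(anc, 0.01, seed = 3),
                mutate_sequence(anc, 0.01, seed = 4)))
  })
  tr <- bootstrap_support(al, n_replicates = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_gte(max(sup), 95)                     # the AB|CD split
  tr2 <- bootstrap_support(al, n_replicates = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("gene-tree screen flags a planted discordant family", {
  # 12 concordant genes + 1 whose clade labels are swapped
  withr::with_seed(41, {
    n_strain <- 8
    strains <- sprintf("s%02d", 1:n_strain)
    cladeA <- strains[1:4]
    mk_gene <- function(swap = FALSE) {
      anc <- random_dna(600)
      va <- mutate_sequence(anc, 0.08, seed = sample.int(1e6, 1))
      vb <- mutate_sequence(anc, 0.08, seed = sample.int(1e6, 1))
      rows <- vapply(strains, function(s) {
        base <- if (xor(s %in% cladeA, swap)) va else vb
        mutate_sequence(base, 0.01, seed = sample.int(1e6, 1))
      }, "")
      # swap = TRUE scrambles which strains carry which clade variant
      if (swap) {
        scramble <- c(1, 5, 2, 6, 3, 7, 4, 8)
        rows <- stats::setNames(rows[scramble], strains)
      }
      msa(strains, unname(rows))
    }
    aligns <- c(lapply(1:12, function(i) mk_gene()), list(mk_gene(swap = TRUE)))
    names(aligns) <- c(sprintf("conc%02d", 1:12), "discordant")
  })
  ref <- suppressWarnings(nj_tree(jc_distance_matrix(aligns[[1]])))
  rep <- gene_tree_screen(aligns, ref, seed = 2)
  expect_true("discordant" %in% rep$upper_tail)
  expect_false("discordant" %in% rep$lower_tail)
  expect_identical(nrow(rep$table), 13L)
  expect_true(all(rep$table$nodal >= 0))
  expect_true(rep$q_lower <= rep$q_upper)
  # tails disjoint
  expect_length(intersect(rep$lower_tail, rep$upper_tail), 0L)
})

test_that("degenerate screens warn and skip uncovered genes", {
  al <- msa(c("A", "B", "C", "D"), rep("ACGTACGTACGT", 4))
  aligns <- list(g1 = al, g2 = al, g3 = al)
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  expect_warning(rep <- gene_tree_screen(aligns, ref, seed = 1),
                 "degenerate")
  expect_length(rep$lower_tail, 0L)
  # a gene with an unknown strain is skipped with a message
  bad <- msa(c("A", "B", "C", "Z"), rep("ACGTACGTACGT", 4))
  expect_message(
    expect_warning(r2 <- gene_tree_screen(c(aligns, list(gz = bad)), ref,
                                          seed = 1)),
    "skipping")
  expect_identical(r2$skipped, "gz")
})
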