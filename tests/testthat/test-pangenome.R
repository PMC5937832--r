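test_that("quality filter matches the direct arithmetic oracle", {
  counts <- c(100, 101, 99, 100, 100, 100, 100, 100, 100, 160)
  names(counts) <- paste0("g", 1:10)
  # oracle: mean 106, population sd sqrt(3242/10) ~= 18.006
  expect_equal(mean(counts), 106)
  expect_equal(sqrt(mean((counts - 106)^2)), 18.0055, tolerance = 1e-4)
  qf <- quality_filter(counts)
  expect_identical(qf$excluded, "g10")
  expect_length(qf$kept, 9L)
})

test_that("quality filter edge cases", {
  eq <- stats::setNames(rep(50, 6), paste0("g", 1:6))
  expect_length(quality_filter(eq)$excluded, 0L)   # sigma = 0
  expect_warning(qf1 <- quality_filter(c(a = 10)), "fewer than 3")
  expect_identical(qf1$kept, "a")
})

test_that("presence matrix counts copies and conserves genes", {
  gs <- genome_set(data.frame(
    genome_id = c("g1", "g1", "g2", "g2", "g2"),
    gene_id = paste0("x", 1:5),
    nucleotide = rep("ATG", 5), protein = rep("M", 5)))
  cl <- structure(list(
    clusters = list(CL1 = c("x1", "x3", "x4"),   # paralogs in g2
                    CL2 = c("x2"),               # private to g1
                    CL3 = c("x5")),
    genome_of = stats::setNames(gs$genes$genome_id, gs$genes$gene_id)),
    class = "ClusterSet")
  m <- build_presence_matrix(cl, gs)
  expect_identical(m["CL1", "g2"], 2L)            # copy count
  expect_identical(rowSums(m > 0)[["CL1"]], 2)    # occupancy counts once
  expect_true("CL2" %in% rownames(m))             # singleton cluster kept
  expect_identical(sum(m), nrow(gs$genes))        # conservation
  bad <- cl; bad$clusters$CL1 <- c(bad$clusters$CL1, "ghost")
  expect_error(build_presence_matrix(bad, gs), "absent")
})

test_that("partition bands follow the occupancy definitions at n = 100", {
  m <- occupancy_matrix(c(100, 96, 94, 3, 2), 100, seed = 3)
  part <- partition_pangenome(m)
  cls <- as.character(part$class)
  expect_identical(cls, c("core", "softcore", "shell", "shell", "cloud"))
  expect_identical(part$softcore_min, 95)
  # softcore size includes core; conservation holds
  expect_identical(part$sizes[["softcore"]], 2L)
  expect_identical(part$sizes[["softcore"]] + part$sizes[["shell"]] +
                     part$sizes[["cloud"]], part$sizes[["pan"]])
  expect_error(partition_pangenome(m[, 1:2]), "at least 3")
})

test_that("partition conservation holds on random matrices", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      n <- sample(3:60, 1)
      occ <- sample.int(n, sample(5:40, 1), replace = TRUE)
      part <- partition_pangenome(occupancy_matrix(occ, n, seed = rep))
      expect_identical(part$sizes[["softcore"]] + part$sizes[["shell"]] +
                         part$sizes[["cloud"]], part$sizes[["pan"]])
      expect_identical(part$sizes[["pan"]], length(occ))
    }
  })
})

test_that("rarefaction matches set enumeration and is monotone", {
  # genomes with families {a,b,c}, {b,c,d}, {c,d,e}
  m <- matrix(c(1, 1, 1, 0, 0,
                0, 1, 1, 1, 0,
                0, 0, 1, 1, 1), ncol = 3,
              dimnames = list(letters[1:5], c("G1", "G2", "G3")))
  # oracle: enumerate all 6 orderings by hand with sets
  sets <- list(G1 = c("a", "b", "c"), G2 = c("b", "c", "d"),
               G3 = c("c", "d", "e"))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  oracle <- lapply(perms, function(p) {
    pan <- core <- integer(3); acc <- character(0); common <- NULL
    for (k in 1:3) {
      s <- sets[[p[k]]]
      acc <- union(acc, s)
      common <- if (is.null(common)) s else intersect(common, s)
      pan[k] <- length(acc); core[k] <- length(common)
    }
    paste(c(pan, core), collapse = ",")
  })
  curves <- rarefaction_curves(m, n_permutations = 30, seed = 4)
  for (d in split(curves, curves$permutation)) {
    d <- d[order(d$step), ]
    expect_true(paste(c(d$pan, d$core), collapse = ",") %in% oracle)
    expect_true(all(diff(d$pan) >= 0))
    expect_true(all(diff(d$core) <= 0))
    # identity-order permutation exists in the oracle set with pan (3,4,5),
    # core (3,2,1); final step is permutation-invariant
    expect_identical(d$pan[3], 5L)
    expect_identical(d$core[3], 1L)
  }
  expect_identical(as.data.frame(rarefaction_curves(m, 5, seed = 9)),
                   as.data.frame(rarefaction_curves(m, 5, seed = 9)))
})

test_that("openness calls follow the tail-slope thresholds", {
  mk_curves <- function(gain) {
    # one permutation, 30 steps, constant marginal gain in the tail
    structure(data.frame(permutation = 1, step = 1:30,
                         pan = cumsum(c(1000, rep(gain, 29))),
                         core = rep(300, 30)),
              class = c("RarefactionCurve", "data.frame"))
  }
  expect_identical(classify_openness(mk_curves(50))$status, "open")
  expect_identical(classify_openness(mk_curves(4.5))$status, "closed")
  flat <- mk_curves(0)
  op <- classify_openness(flat)
  expect_identical(op$status, "closed")
  expect_equal(op$slope, 0)
  expect_error(classify_openness(mk_curves(1), tail_window = 30), "tail")
})

test_that("clade-specific genes and expansions follow the strict rules", {
  m <- rbind(
    spec     = c(1, 2, 1, 0, 0),   # in all A, absent in B -> specific
    leak     = c(1, 1, 1, 1, 0),   # present in one B genome -> not specific
    exp_yes  = c(2, 2, 3, 1, 1),   # min A (2) > max B (1) -> expansion
    exp_no   = c(2, 1, 2, 1, 1))   # min A (1) = max B (1) -> not
  colnames(m) <- c("a1", "a2", "a3", "b1", "b2")
  res <- clade_specific_genes(m, cladeA = c("a1", "a2", "a3"),
                              cladeB = c("b1", "b2"))
  expect_identical(res$specific, "spec")
  expect_setequal(res$expansions, c("spec", "exp_yes"))
  expect_error(clade_specific_genes(m, c("a1", "b1"), c("b1", "b2")),
               "disjoint")
  expect_error(clade_specific_genes(m, character(0), "b1"), "non-empty")
})

test_that("HGT screen applies the inclusive 30-70% band per clade", {
  clades <- stats::setNames(rep(c("A", "B"), each = 10),
                            c(paste0("a", 1:10), paste0("b", 1:10)))
  mk_row <- function(na, nb) c(rep(1, na), rep(0, 10 - na),
                               rep(1, nb), rep(0, 10 - nb))
  m <- rbind(cand = mk_row(5, 3),     # 0.5 / 0.3 -> candidate
             rej  = mk_row(5, 2),     # 0.5 / 0.2 -> rejected
             edge = mk_row(7, 7))     # 0.7 / 0.7 -> candidate (inclusive)
  colnames(m) <- names(clades)
  out <- hgt_screen(m, clades)
  expect_identical(out$cluster_id[out$candidate], c("cand", "edge"))
  expect_equal(out[out$cluster_id == "cand", "A"], 0.5)
  small <- stats::setNames(c("A", "A", "B"), c("a1", "a2", "b1"))
  expect_error(hgt_screen(m[, c("a1", "a2", "b1")], small), ">= 2 genomes")
})

test_that("screen recovers exactly the planted HGT families", {
  w <- tiny_world()
  out <- hgt_screen(w$matrix, w$truth$clade_of[colnames(w$matrix)])
  fams <- cluster_families(w$clusters, w$truth)
  expect_setequal(unname(fams[out$cluster_id[out$candidate]]),
                  w$truth$hgt_families)
})

test_that("partition classes match the simulator truth exactly", {
  w <- tiny_world()
  part <- partition_pangenome(w$matrix)
  fams <- cluster_families(w$clusters, w$truth)
  expect_identical(unname(as.character(part$class)),
                   unname(w$truth$family_class[fams]))
})
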