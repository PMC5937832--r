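test_that("identical seeds give byte-identical genome sets", {
  a <- simulate_pangenome(tiny_config(seed = 7))
  b <- simulate_pangenome(tiny_config(seed = 7))
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth, b$truth)
  c <- simulate_pangenome(tiny_config(seed = 8))
  expect_false(identical(a$genomes$genes$nucleotide,
                         c$genomes$genes$nucleotide))
})

test_that("realized occupancies match the truth class bands", {
  w <- tiny_world()
  truth <- w$truth
  reg <- setdiff(names(truth$clade_of), truth$outlier_genomes)
  n <- length(reg)
  # recount occupancy per family directly from the emitted genes
  genes <- w$sim$genomes$genes
  genes <- genes[genes$genome_id %in% reg, ]
  fam <- unname(truth$family_of_gene[genes$gene_id])
  occ <- vapply(split(genes$genome_id, fam), function(g) length(unique(g)), 0L)
  softcore_min <- ceiling(0.95 * n)
  for (f in names(occ)) {
    cls <- truth$family_class[[f]]
    o <- occ[[f]]
    switch(cls,
      core = expect_identical(o, n),
      softcore = expect_true(o >= softcore_min && o < n),
      shell = expect_true(o >= 3 && o < softcore_min),
      cloud = expect_lte(o, 2))
  }
  # every gene traces to exactly one family
  expect_true(all(w$sim$genomes$genes$gene_id %in%
                    names(truth$family_of_gene)))
})

test_that("planted HGT families sit inside the 30-70% band in every clade", {
  cfg <- tiny_config(seed = 11)
  sim <- simulate_pangenome(cfg)
  truth <- sim$truth
  expect_length(truth$hgt_families, cfg$n_hgt)
  reg <- setdiff(names(truth$clade_of), truth$outlier_genomes)
  genes <- sim$genomes$genes[sim$genomes$genes$genome_id %in% reg, ]
  fam <- unname(truth$family_of_gene[genes$gene_id])
  for (f in truth$hgt_families) {
    g <- unique(genes$genome_id[fam == f])
    for (cl in unique(truth$clade_of[reg])) {
      members <- reg[truth$clade_of[reg] == cl]
      frac <- length(intersect(g, members)) / length(members)
      expect_true(frac >= 0.30 && frac <= 0.70,
                  label = sprintf("family %s fraction %.2f in %s", f, frac, cl))
    }
  }
})

test_that("mutate_sequence honors rate semantics", {
  s <- random_dna(500, seed = 3)
  expect_identical(mutate_sequence(s, 0, seed = 1), s)
  expect_error(mutate_sequence(s, 0.75, seed = 1), "rate")
  expect_error(mutate_sequence(s, -0.1, seed = 1), "rate")
  # same seed, same outcome; same length always
  m1 <- mutate_sequence(s, 0.2, seed = 5)
  expect_identical(m1, mutate_sequence(s, 0.2, seed = 5))
  expect_identical(nchar(m1), nchar(s))
  # binomial oracle: observed mismatch fraction within 3 sd of the rate
  long <- random_dna(10000, seed = 4)
  mut <- mutate_sequence(long, 0.05, seed = 9)
  p_hat <- mean(strsplit(long, "")[[1]] != strsplit(mut, "")[[1]])
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("planted ecoSNP columns are dimorphic and clade-partitioning", {
  w <- tiny_world()
  truth <- w$truth
  planted <- truth$ecosnps[truth$ecosnps$planted, ]
  expect_true(all(planted$family %in% truth$ecosnp_families))
  reg <- setdiff(names(truth$clade_of), truth$outlier_genomes)
  genes <- w$sim$genomes$genes
  fam <- truth$family_of_gene
  for (key in unique(paste(planted$family, planted$column))) {
    f <- strsplit(key, " ")[[1]][1]
    col <- as.integer(strsplit(key, " ")[[1]][2])
    sub <- genes[genes$genome_id %in% reg &
                   unname(fam[genes$gene_id]) == f, ]
    base <- substring(sub$nucleotide, col, col)
    expect_length(unique(base), 2L)  # dimorphic by construction
    # the base partition equals the clade partition
    split_by_base <- split(unname(truth$clade_of[sub$genome_id]), base)
    expect_true(all(vapply(split_by_base,
                           function(x) length(unique(x)) == 1L, TRUE)))
  }
})

test_that("n_ecosnp = 0 leaves the genome set unchanged", {
  sim0 <- simulate_pangenome(tiny_config(seed = 5, n_ecosnp = 0,
                                         n_ecosnp_families = 0))
  expect_true(all(!sim0$truth$ecosnps$planted))
})

test_that("outlier genomes violate the quality band; others do not", {
  w <- tiny_world()
  qf <- w$filter
  expect_setequal(qf$excluded, w$truth$outlier_genomes)
})

test_that("between-clade divergence exceeds within-clade divergence", {
  cfg <- tiny_config(seed = 13, within_clade_mut_rate = 0.01,
                     between_clade_mut_rate = 0.08, n_outlier_genomes = 0)
  sim <- simulate_pangenome(cfg)
  truth <- sim$truth
  genes <- sim$genomes$genes
  fam <- unname(truth$family_of_gene[genes$gene_id])
  core <- names(truth$family_class)[truth$family_class == "core"]
  mismatch <- function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  within <- c(); between <- c()
  for (f in core[1:10]) {
    sub <- genes[fam == f, ]
    cl <- unname(truth$clade_of[sub$genome_id])
    for (i in 1:(nrow(sub) - 1)) {
      for (j in (i + 1):nrow(sub)) {
        d <- mismatch(sub$nucleotide[i], sub$nucleotide[j])
        if (cl[i] == cl[j]) within <- c(within, d) else between <- c(between, d)
      }
    }
  }
  expect_gt(mean(between), mean(within))
})

test_that("configuration errors are caught", {
  expect_error(simulation_config(n_clades = 0), "at least one clade")
  expect_error(simulation_config(within_clade_mut_rate = 0.8), "0.75")
  expect_error(simulation_config(within_clade_mut_rate = 0.2,
                                 between_clade_mut_rate = 0.1), ">=")
  # 8 genomes: softcore band empty
  expect_error(simulation_config(n_clades = 2, genomes_per_clade = 4,
                                 n_softcore = 5), "softcore band")
  # 3 genomes: softcore_min = 3, so the shell band [3, 2] is empty
  expect_error(simulation_config(n_clades = 1, genomes_per_clade = 3,
                                 n_softcore = 0, n_shell = 1, n_hgt = 0,
                                 n_ecosnp = 0, n_ecosnp_families = 0),
               "shell band")
  expect_error(simulation_config(n_clades = 1, genomes_per_clade = 10,
                                 n_softcore = 0, n_ecosnp = 0, n_hgt = 1),
               "clades")
})

test_that("FASTA export round-trips losslessly and guards collisions", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  write_genome_fastas(w$sim$genomes, dir)
  back <- read_genome_fastas(dir)
  reindex <- function(df) {
    df <- df[order(df$gene_id), ]
    rownames(df) <- NULL
    df
  }
  expect_identical(reindex(back$genes), reindex(w$sim$genomes$genes))
  expect_setequal(back$genome_ids, w$sim$genomes$genome_ids)
  expect_error(write_genome_fastas(w$sim$genomes, dir), "exists")
  expect_silent(write_genome_fastas(w$sim$genomes, dir, overwrite = TRUE))
  # headers parse back to (genome, gene)
  first <- readLines(list.files(dir, pattern = "\\.fna$",
                                full.names = TRUE)[1], n = 1)
  expect_match(first, "^>[^|]+\\|[^|]+$")
})

test_that("a genome with zero genes writes an empty FASTA with a warning", {
  gs <- genome_set(data.frame(genome_id = "g1", gene_id = "g1_x",
                              nucleotide = "ATGAAA", protein = "MK"),
                   genome_ids = c("g1", "g2"))
  dir <- withr::local_tempdir()
  expect_warning(write_genome_fastas(gs, dir), "no genes")
  expect_identical(length(readLines(file.path(dir, "g2.fna"))), 0L)
})

test_that("proteins are the frame-1 standard-code translation", {
  w <- tiny_world()
  g <- w$sim$genomes$genes
  idx <- seq(1, nrow(g), length.out = 25)
  expect_identical(g$protein[idx], translate_cds(g$nucleotide[idx]))
})
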