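# Shared fixtures, built in code at test time.

# A small clade-structured world that exercises every planted feature but
# stays fast (2 clades x 4 genomes, ~40 families). n_softcore is 0 because
# with 8 genomes the softcore-not-core occupancy band [ceil(0.95*8), 7] is
# empty.
tiny_config <- function(seed = 7, ...) {
  args <- list(n_clades = 2, genomes_per_clade = 4, n_core = 20,
               n_softcore = 0, n_shell = 10, n_cloud = 8, n_hgt = 3,
               n_ecosnp = 2, n_ecosnp_families = 2,
               n_outlier_genomes = 1, gene_length_mean = 360,
               gene_length_sd = 60, seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# memoised tiny simulation + clustering, shared within a test file run
.fixture_cache <- new.env(parent = emptyenv())
tiny_world <- function() {
  if (is.null(.fixture_cache$world)) {
    sim <- simulate_pangenome(tiny_config())
    qf <- quality_filter(gene_counts(sim$genomes))
    kept <- genome_set(
      sim$genomes$genes[sim$genomes$genes$genome_id %in% qf$kept, ],
      genome_ids = qf$kept)
    graph <- build_similarity_graph(kept)
    clusters <- mcl_cluster(graph)
    .fixture_cache$world <- list(
      sim = sim, truth = sim$truth, filter = qf, kept = kept,
      graph = graph, clusters = clusters,
      matrix = build_presence_matrix(clusters, kept))
  }
  .fixture_cache$world
}

# map each cluster to the (unique) simulated family of its members
cluster_families <- function(clusters, truth) {
  vapply(clusters$clusters, function(g)
    paste(sort(unique(unname(truth$family_of_gene[g]))), collapse = "+"),
    "")
}

# build a SimilarityGraph object directly from an edge list (unit tests of
# the MCL stage without the alignment machinery)
graph_fixture <- function(edges, vertices = NULL, genome_of = NULL) {
  if (is.null(vertices))
    vertices <- sort(unique(c(edges$from, edges$to)))
  if (is.null(genome_of))
    genome_of <- stats::setNames(vertices, vertices)
  structure(list(edges = edges, vertices = vertices,
                 genome_of = genome_of,
                 hits = data.frame()),
            class = "SimilarityGraph")
}

# draw k occupancies uniformly from [lo, hi] (safe when lo == hi: base
# sample() would treat the scalar as 1:lo)
sample_band <- function(lo, hi, k) {
  if (k == 0) return(integer(0))
  if (lo >= hi) return(rep(as.integer(lo), k))
  sample(seq.int(lo, hi), k, replace = TRUE)
}

# unit-weight clique-union graph over the given vertex blocks
unit_clique_graph <- function(groups) {
  verts <- unlist(groups)
  edges <- do.call(rbind, lapply(groups, function(g) {
    if (length(g) < 2) return(NULL)
    p <- t(utils::combn(g, 2))
    data.frame(from = p[, 1], to = p[, 2], weight = 1)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  graph_fixture(edges, vertices = verts)
}

# presence matrix realizing given per-class occupancies; genomes are filled
# deterministically from a seeded order
occupancy_matrix <- function(occupancies, n_genomes, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0L, length(occupancies), n_genomes,
                dimnames = list(sprintf("c%05d", seq_along(occupancies)),
                                sprintf("g%03d", seq_len(n_genomes))))
    for (i in seq_along(occupancies))
      m[i, sample.int(n_genomes, occupancies[i])] <- 1L
    m
  })
}

# random nucleotide string
random_dna <- function(n, seed = NULL) {
  draw <- function() paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
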