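#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one validated object. Input
#' is either a simulation block (`simulate`) or a directory of per-genome
#' FASTA pairs (`input_dir`) plus a genome -> clade TSV (`clades_path`);
#' clades may instead be inferred by cutting the identity dendrogram into
#' `k_clades` groups.
#'
#' @param simulate optional [simulation_config()]; if given, input data are
#'   generated.
#' @param input_dir directory of `<genome>.fna`/`<genome>.faa` pairs (used
#'   when `simulate` is NULL).
#' @param clades_path optional TSV (columns `genome`, `clade`).
#' @param annotation_path optional gene -> category TSV (columns `gene_id`,
#'   `category`) enabling the enrichment stage.
#' @param k_clades groups for the dendrogram cut when no clade table is
#'   given.
#' @param e_max,cov_min similarity-graph gates.
#' @param inflation MCL inflation.
#' @param k_sigma quality-filter band.
#' @param hgt_low,hgt_high HGT presence band.
#' @param closed_slope rarefaction openness threshold (genes/genome).
#' @param n_permutations rarefaction orderings; default = genome count.
#' @param lower,upper nodal-screen percentiles.
#' @param n_random random trees per nodal baseline.
#' @param n_bootstrap bootstrap replicates for the reference-gene trees
#'   (0 disables bootstrapping in the pipeline).
#' @param linkage dendrogram linkage.
#' @param out_dir output directory for all artifacts.
#' @param seed master seed (mandatory; all stochastic stages derive from
#'   it).
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            clades_path = NULL, annotation_path = NULL,
                            k_clades = 2L, e_max = 1e-5, cov_min = 0.75,
                            inflation = 1.5, k_sigma = 2,
                            hgt_low = 0.30, hgt_high = 0.70,
                            closed_slope = 5.0, n_permutations = NULL,
                            lower = 0.05, upper = 0.95, n_random = 10L,
                            n_bootstrap = 0L, linkage = "average",
                            out_dir = tempfile("pancora_run_"), seed = 1L) {
  assert_that(!is.null(simulate) || !is.null(input_dir),
              "either a simulate block or an input_dir is required")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "SimulationConfig"))
  assert_that(is.numeric(seed) && length(seed) == 1L, "seed is mandatory")
  assert_that(e_max > 0 && cov_min >= 0 && cov_min <= 1, "invalid gates")
  assert_that(inflation > 1, "inflation must be > 1")
  assert_that(hgt_low >= 0 && hgt_high <= 1 && hgt_low <= hgt_high,
              "invalid HGT band")
  assert_that(lower > 0 && upper < 1 && lower < upper, "invalid percentiles")
  structure(list(simulate = simulate, input_dir = input_dir,
                 clades_path = clades_path, annotation_path = annotation_path,
                 k_clades = k_clades, e_max = e_max, cov_min = cov_min,
                 inflation = inflation, k_sigma = k_sigma, hgt_low = hgt_low,
                 hgt_high = hgt_high, closed_slope = closed_slope,
                 n_permutations = n_permutations, lower = lower,
                 upper = upper, n_random = n_random,
                 n_bootstrap = n_bootstrap, linkage = linkage,
                 out_dir = out_dir, seed = seed),
            class = "PipelineConfig")
}

#' Run the full pan/core-genome analysis pipeline
#'
#' Stages: simulate (optional) -> quality filter -> similarity graph ->
#' MCL clustering -> presence matrix -> partition -> rarefaction/openness ->
#' identity matrix/Gower/dendrogram/clades -> per-core-gene trees and nodal
#' screen -> SNP and ecoSNP reports -> HGT screen -> enrichment (optional).
#' Every stage writes its artifact as TSV/FASTA/Newick into
#' `config$out_dir`, so any stage can be rerun from files, and a JSON
#' manifest records parameters, seed and per-artifact MD5 checksums.
#' Reruns with the same config and seed are bit-identical apart from the
#' manifest timestamp.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    art <<- c(art, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage '%s': %s", name,
                         conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", simulate_pangenome(cfg$simulate))
    genomes <- sim$genomes; truth <- sim$truth
    stage("simulate", write_truth_tables(truth, file.path(cfg$out_dir, "truth")))
  } else {
    genomes <- stage("read_input", read_genome_fastas(cfg$input_dir))
  }

  clade_map <- NULL
  if (!is.null(cfg$clades_path)) {
    ct <- stage("read_clades", read_tsv(cfg$clades_path))
    clade_map <- stats::setNames(as.character(ct$clade), ct$genome)
  }

  qf <- stage("quality_filter", quality_filter(gene_counts(genomes),
                                               k_sigma = cfg$k_sigma))
  emit("quality_filter.tsv", function(p) write_tsv(
    data.frame(genome = c(qf$kept, qf$excluded),
               status = rep(c("kept", "excluded"),
                            c(length(qf$kept), length(qf$excluded)))), p))
  kept_genes <- genomes$genes[genomes$genes$genome_id %in% qf$kept, ]
  genomes_f <- genome_set(kept_genes, genome_ids = qf$kept)

  graph <- stage("similarity_graph",
                 build_similarity_graph(genomes_f, e_max = cfg$e_max,
                                        cov_min = cfg$cov_min))
  clusters <- stage("mcl", mcl_cluster(graph, inflation = cfg$inflation))
  emit("clusters.tsv", function(p) write_clusters(clusters, p))

  mat <- stage("presence_matrix", build_presence_matrix(clusters, genomes_f))
  emit("presence_matrix.tsv", function(p) write_presence_matrix(mat, p))
  part <- stage("partition", partition_pangenome(mat))
  emit("partition.tsv", function(p) write_tsv(
    data.frame(cluster_id = names(part$class),
               class = as.character(part$class)), p))

  curves <- stage("rarefaction", rarefaction_curves(
    mat, n_permutations = cfg$n_permutations %||% ncol(mat),
    seed = derive_seed(cfg$seed, "rarefy")))
  emit("rarefaction.tsv", function(p) write_tsv(as.data.frame(curves), p))
  openness <- stage("openness", classify_openness(
    curves, closed_slope = cfg$closed_slope))

  im <- stage("identity", suppressWarnings(
    average_identity_matrix(clusters, graph$hits)))
  emit("identity_matrix.tsv", function(p) write_tsv(
    data.frame(genome = rownames(im), as.data.frame(unclass(im)),
               check.names = FALSE), p))
  gd <- stage("gower", gower_distance(im))
  dendro <- stage("dendrogram", hierarchical_cluster(gd,
                                                     linkage = cfg$linkage))
  emit("dendrogram.nwk", function(p) dendrogram_newick(dendro, p))
  if (is.null(clade_map)) {
    cut <- extract_clades(dendro, cfg$k_clades)
    clade_map <- stats::setNames(sprintf("clade%02d", cut), names(cut))
  }
  clade_map <- clade_map[names(clade_map) %in% colnames(mat)]
  emit("clades_used.tsv", function(p) write_tsv(
    data.frame(genome = names(clade_map), clade = unname(clade_map)), p))

  # per-core-gene alignments (families present once in every genome give
  # one row per genome, named by genome)
  core_ids <- names(part$class)[part$class == "core"]
  aligns <- stage("core_alignments", {
    out <- list()
    for (cid in core_ids) {
      gid <- clusters$clusters[[cid]]
      gsub <- genomes_f$genes[match(gid, genomes_f$genes$gene_id), ]
      if (anyDuplicated(gsub$genome_id)) next  # paralogous core: skip MSA
      out[[cid]] <- center_star_align(
        stats::setNames(gsub$nucleotide, gsub$genome_id), cluster_id = cid)
    }
    out
  })
  msa_dir <- file.path(cfg$out_dir, "core_alignments")
  dir.create(msa_dir, showWarnings = FALSE)
  for (cid in names(aligns))
    emit(file.path("core_alignments", paste0(cid, ".fasta")),
         function(p) write_msa_fasta(aligns[[cid]], p))
  if (length(aligns) >= 1 && ncol(mat) >= 4) {
    trees <- stage("gene_trees", {
      tl <- lapply(names(aligns), function(cid) {
        if (cfg$n_bootstrap > 0)
          bootstrap_support(aligns[[cid]], n_replicates = cfg$n_bootstrap,
                            seed = derive_seed(cfg$seed, cid))
        else suppressWarnings(nj_tree(jc_distance_matrix(aligns[[cid]])))
      })
      names(tl) <- names(aligns)
      tl
    })
    emit("gene_trees.nwk", function(p) {
      txt <- vapply(names(trees), function(cid)
        paste0(cid, "\t", ape::write.tree(trees[[cid]])), "")
      writeLines(txt, p)
    })
  }

  nodal <- NULL
  if (length(aligns) >= 2 && ncol(mat) >= 4) {
    ref <- ape::as.phylo(dendro)
    nodal <- stage("nodal_screen", gene_tree_screen(
      aligns, ref, lower = cfg$lower, upper = cfg$upper,
      n_random = cfg$n_random, seed = derive_seed(cfg$seed, "nodal")))
    emit("nodal_report.tsv", function(p) write_tsv(nodal$table, p))
  }

  snp_rows <- list(); eco_rows <- list()
  two_clades <- length(unique(clade_map)) >= 2 &&
    all(table(clade_map) >= 2)
  for (cid in names(aligns)) {
    al <- aligns[[cid]]
    cons <- build_consensus(al)
    snp <- call_snps(al, cons)
    snp_rows[[cid]] <- data.frame(
      gene = cid, sum_snp = snp$sum_snp, snp_per_base = snp$snp_per_base,
      n_variable = snp$n_variable, polyvariable = snp$n_polyvariable,
      length = snp$length, stringsAsFactors = FALSE)
    if (two_clades) {
      eco <- detect_ecosnps(al, clade_map)
      if (nrow(eco)) eco_rows[[cid]] <- data.frame(gene = cid,
                                                   as.data.frame(eco))
    }
  }
  snp_report <- do.call(rbind, snp_rows)
  emit("snp_report.tsv", function(p) write_tsv(
    snp_report %||% data.frame(), p))
  eco_report <- if (length(eco_rows)) do.call(rbind, eco_rows) else
    data.frame(gene = character(0), column = integer(0),
               clade = character(0), base = character(0))
  rownames(eco_report) <- NULL
  emit("ecosnps_detected.tsv", function(p) write_tsv(eco_report, p))

  hgt <- NULL
  if (two_clades) {
    hgt <- stage("hgt_screen", hgt_screen(mat, clade_map,
                                          low = cfg$hgt_low,
                                          high = cfg$hgt_high))
    emit("hgt_candidates.tsv", function(p) write_tsv(hgt, p))
  }

  enrich <- NULL
  if (!is.null(cfg$annotation_path)) {
    ann <- stage("enrichment", read_tsv(cfg$annotation_path))
    enrich <- stage("enrichment", fold_increase_table(
      category_counts(ann, clusters, part)))
    emit("enrichment.tsv", function(p) write_tsv(as.data.frame(enrich), p))
  }

  manifest <- list(
    package = "pancora",
    version = as.character(utils::packageVersion("pancora")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("simulate", "out_dir"))],
    n_genomes = length(genomes$genome_ids),
    n_genomes_kept = length(qf$kept),
    n_clusters = length(clusters$clusters),
    partition_sizes = as.list(part$sizes),
    openness = openness,
    checksums = as.list(tools::md5sum(sort(art))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(genomes = genomes, truth = truth, filter = qf,
                 graph = graph, clusters = clusters, matrix = mat,
                 partition = part, curves = curves, openness = openness,
                 identity = im, gower = gd, dendrogram = dendro,
                 clades = clade_map, alignments = aligns, nodal = nodal,
                 snp_report = snp_report, ecosnps = eco_report, hgt = hgt,
                 enrichment = enrich, manifest = manifest))
}
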