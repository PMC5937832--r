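#' Simulation configuration for synthetic pan-genomes
#'
#' Describes a clade-structured bacterial pan-genome with planted,
#' recoverable ground truth: universal (core) gene families, families with
#' occupancies drawn from the softcore/shell/cloud bands, clade-diagnostic
#' ecoSNP columns, horizontally transferred families at 30--70% presence in
#' every clade, and gene-count outlier genomes far outside the +/- 2 sigma
#' quality band.
#'
#' Defaults describe the world used by the package's acceptance suite:
#' 2 clades of 10 genomes, 400 gene families (150 core / 50 softcore /
#' 110 shell / 80 cloud / 10 HGT), zero within-clade noise and 5% nucleotide
#' divergence between clades.
#'
#' @param n_clades number of clades (>= 1; >= 2 required for ecoSNPs/HGT).
#' @param genomes_per_clade genomes per clade.
#' @param n_core,n_softcore,n_shell,n_cloud family counts per occupancy
#'   class.
#' @param n_hgt families planted at 30--70% presence in every clade.
#' @param n_ecosnp planted clade-diagnostic columns per flagged core family.
#' @param n_ecosnp_families number of core families flagged for ecoSNP
#'   planting.
#' @param n_outlier_genomes genomes given gene counts far outside the
#'   quality band.
#' @param gene_length_mean,gene_length_sd CDS length distribution in
#'   nucleotides (normal, truncated at 300 nt, rounded down to a multiple
#'   of 3).
#' @param within_clade_mut_rate per-site substitution probability applied to
#'   each genome's copy of its clade's sequence; in `[0, 0.75)`.
#' @param between_clade_mut_rate per-site substitution probability applied
#'   once per clade to the family ancestor; must be >= the within rate.
#' @param seed integer master seed; all stage seeds are derived from it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_clades = 2L,
                              genomes_per_clade = 10L,
                              n_core = 150L,
                              n_softcore = 50L,
                              n_shell = 110L,
                              n_cloud = 80L,
                              n_hgt = 10L,
                              n_ecosnp = 3L,
                              n_ecosnp_families = 5L,
                              n_outlier_genomes = 2L,
                              gene_length_mean = 450,
                              gene_length_sd = 120,
                              within_clade_mut_rate = 0,
                              between_clade_mut_rate = 0.05,
                              seed = 42L) {
  cfg <- list(n_clades = n_clades, genomes_per_clade = genomes_per_clade,
              n_core = n_core, n_softcore = n_softcore, n_shell = n_shell,
              n_cloud = n_cloud, n_hgt = n_hgt, n_ecosnp = n_ecosnp,
              n_ecosnp_families = n_ecosnp_families,
              n_outlier_genomes = n_outlier_genomes,
              gene_length_mean = gene_length_mean,
              gene_length_sd = gene_length_sd,
              within_clade_mut_rate = within_clade_mut_rate,
              between_clade_mut_rate = between_clade_mut_rate,
              seed = seed)
  counts <- c("n_clades", "genomes_per_clade", "n_core", "n_softcore",
              "n_shell", "n_cloud", "n_hgt", "n_ecosnp", "n_ecosnp_families",
              "n_outlier_genomes")
  for (f in counts)
    assert_that(is_count(cfg[[f]]), sprintf("%s must be a non-negative integer", f))
  assert_that(cfg$n_clades >= 1 && cfg$genomes_per_clade >= 1,
              "need at least one clade with at least one genome")
  for (f in c("within_clade_mut_rate", "between_clade_mut_rate"))
    assert_that(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] < 0.75,
                sprintf("%s must lie in [0, 0.75)", f))
  assert_that(cfg$between_clade_mut_rate >= cfg$within_clade_mut_rate,
              "between-clade rate must be >= within-clade rate")
  assert_that(cfg$gene_length_mean >= 300,
              "gene_length_mean must be >= 300 nt")

  n <- cfg$n_clades * cfg$genomes_per_clade
  softcore_min <- ceiling(0.95 * n)
  if (cfg$n_core > 0)
    assert_that(n >= 3, "core families need at least 3 genomes")
  if (cfg$n_softcore > 0)
    assert_that(softcore_min <= n - 1,
                "softcore band [ceil(0.95 n), n-1] is empty for this genome count")
  if (cfg$n_shell > 0)
    assert_that(softcore_min - 1 >= 3,
                "shell band [3, ceil(0.95 n) - 1] is empty for this genome count")
  if (cfg$n_cloud > 0)
    assert_that(n >= 1, "cloud families impossible with no genomes")
  if (cfg$n_hgt > 0) {
    assert_that(cfg$n_clades >= 2, "HGT planting needs >= 2 clades")
    lo <- ceiling(0.30 * cfg$genomes_per_clade)
    hi <- floor(0.70 * cfg$genomes_per_clade)
    assert_that(lo <= hi && lo >= 1,
                "no per-clade presence count realizes the 30-70% band")
  }
  if (cfg$n_ecosnp > 0 && cfg$n_ecosnp_families > 0) {
    assert_that(cfg$n_clades >= 2, "ecoSNP planting needs >= 2 clades")
    assert_that(cfg$n_ecosnp_families <= cfg$n_core,
                "more ecoSNP-flagged families than core families")
  }
  structure(cfg, class = "SimulationConfig")
}

DNA_BASES <- c("A", "C", "G", "T")

# The 61 sense codons of the standard code (family ancestors are built from
# these so translations are stop-free; downstream mutation may still create
# internal stops, which the aligner's alphabet tolerates).
sense_codons <- function() {
  all3 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste0,
                collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

random_cds <- function(len) {
  paste0(sample(sense_codons(), len / 3, replace = TRUE), collapse = "")
}

#' Mutate a nucleotide sequence
#'
#' Each site is independently substituted, with probability `rate`, to a
#' uniformly chosen different base.
#'
#' @param seq nucleotide string.
#' @param rate per-site substitution probability in `[0, 0.75)`.
#' @param seed integer seed; identical seeds give identical output.
#' @return The mutated string (same length as the input).
#' @export
mutate_sequence <- function(seq, rate, seed) {
  assert_that(is.numeric(rate) && length(rate) == 1L && rate >= 0 && rate < 0.75,
              "rate must lie in [0, 0.75)")
  if (rate == 0) return(seq)
  with_seed(seed, mutate_one(seq, rate))
}

# RNG-stream version used inside simulate (caller manages the seed).
mutate_one <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit) {
      alt <- DNA_BASES[DNA_BASES != chars[i]]
      chars[i] <- alt[sample.int(3L, 1L)]
    }
  }
  paste0(chars, collapse = "")
}

empty_truth <- function() {
  structure(list(
    clade_of = character(0),
    family_class = character(0),
    hgt_families = character(0),
    ecosnp_families = character(0),
    ecosnps = data.frame(family = character(0), column = integer(0),
                         clade = character(0), base = character(0),
                         planted = logical(0), stringsAsFactors = FALSE),
    outlier_genomes = character(0),
    family_of_gene = character(0)),
    class = "TruthSet")
}

#' @export
print.TruthSet <- function(x, ...) {
  cat(sprintf(paste0("<TruthSet> %d genomes (%d outliers), %d families ",
                     "(%d HGT), %d ecoSNP records\n"),
              length(x$clade_of), length(x$outlier_genomes),
              length(x$family_class), length(x$hgt_families),
              nrow(x$ecosnps)))
  invisible(x)
}

# genome ids of non-outlier genomes, in genome order
regular_genomes <- function(truth) {
  setdiff(names(truth$clade_of), truth$outlier_genomes)
}

# family -> named character vector (genome -> sequence); reconstructed from
# the gene table and the truth's gene->family map.
family_sequences <- function(genomes, truth, family) {
  idx <- which(truth$family_of_gene[genomes$genes$gene_id] == family)
  sub <- genomes$genes[idx, , drop = FALSE]
  stats::setNames(sub$nucleotide, sub$genome_id)
}

#' Simulate a clade-structured pan-genome with planted ground truth
#'
#' Generates genomes clade by clade: every family has a random stop-free
#' ancestor CDS; each clade receives one mutated copy of the ancestor (the
#' between-clade rate), and each genome one mutated copy of its clade's
#' sequence (the within-clade rate). Family occupancies are drawn inside the
#' partition bands of [partition_pangenome()]; HGT families, ecoSNP columns
#' and outlier genomes are planted by [plant_hgt_genes()],
#' [plant_ecosnps()] and [plant_outlier_genomes()]. The returned truth also
#' records every *emergent* clade-diagnostic dimorphic column of the core
#' families (flagged `planted = FALSE`), so that ecoSNP detection can be
#' compared against the complete diagnostic set.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `genomes` (a `GenomeSet`) and `truth` (a
#'   `TruthSet`).
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  n <- cfg$n_clades * cfg$genomes_per_clade
  clades <- sprintf("clade%02d", seq_len(cfg$n_clades))
  genome_ids <- as.vector(vapply(seq_len(cfg$n_clades), function(k)
    sprintf("C%02d_G%02d", k, seq_len(cfg$genomes_per_clade)),
    character(cfg$genomes_per_clade)))
  clade_of <- stats::setNames(rep(clades, each = cfg$genomes_per_clade),
                              genome_ids)
  softcore_min <- ceiling(0.95 * n)

  nf <- cfg$n_core + cfg$n_softcore + cfg$n_shell + cfg$n_cloud
  fam_ids <- sprintf("F%04d", seq_len(nf))
  fam_class <- rep(c("core", "softcore", "shell", "cloud"),
                   times = c(cfg$n_core, cfg$n_softcore, cfg$n_shell,
                             cfg$n_cloud))
  names(fam_class) <- fam_ids

  truth <- empty_truth()
  truth$clade_of <- clade_of
  truth$family_class <- fam_class

  # ecoSNP-flagged core families skip between-clade background mutation so
  # their only clade-diagnostic columns are the planted ones.
  if (cfg$n_ecosnp > 0 && cfg$n_ecosnp_families > 0) {
    core_ids <- fam_ids[fam_class == "core"]
    truth$ecosnp_families <- with_seed(
      derive_seed(cfg$seed, "ecoflag"),
      sort(sample(core_ids, cfg$n_ecosnp_families)))
  }

  members <- with_seed(derive_seed(cfg$seed, "occupancy"), {
    lapply(fam_ids, function(f) {
      cls <- fam_class[[f]]
      if (cls == "core") return(genome_ids)
      if (cls == "softcore") {
        occ <- sample_range(softcore_min, n - 1L)
        return(sort(sample(genome_ids, occ)))
      }
      if (cls == "shell") {
        # Fill whole clades in a random order: guarantees at least one clade
        # has presence fraction 0 or 1, so no background family can satisfy
        # the 30-70% HGT band in every clade.
        occ <- sample_range(3L, softcore_min - 1L)
        ord <- sample(clades)
        out <- character(0)
        for (cl in ord) {
          g <- genome_ids[clade_of == cl]
          take <- min(length(g), occ - length(out))
          if (take > 0) out <- c(out, sample(g, take))
          if (length(out) >= occ) break
        }
        return(sort(out))
      }
      # cloud: 1-2 genomes, confined to a single clade (fraction <= 2/size,
      # and 0 elsewhere, keeping it out of the HGT band for >= 2 clades)
      occ <- sample_range(1L, 2L)
      cl <- sample(clades, 1L)
      g <- genome_ids[clade_of == cl]
      sort(sample(g, min(occ, length(g))))
    })
  })
  names(members) <- fam_ids

  seqs <- with_seed(derive_seed(cfg$seed, "sequences"), {
    lens <- pmax(300, round(stats::rnorm(nf, cfg$gene_length_mean,
                                         cfg$gene_length_sd)))
    lens <- lens - lens %% 3
    out <- vector("list", nf)
    names(out) <- fam_ids
    for (i in seq_len(nf)) {
      f <- fam_ids[i]
      anc <- random_cds(lens[i])
      skip_between <- f %in% truth$ecosnp_families
      clade_seq <- stats::setNames(vapply(clades, function(cl) {
        if (skip_between) anc else mutate_one(anc, cfg$between_clade_mut_rate)
      }, character(1L)), clades)
      gm <- members[[f]]
      out[[i]] <- stats::setNames(vapply(gm, function(g) {
        mutate_one(clade_seq[[clade_of[[g]]]], cfg$within_clade_mut_rate)
      }, character(1L)), gm)
    }
    out
  })

  genomes <- assemble_genome_set(seqs, genome_ids, truth)
  truth$family_of_gene <- stats::setNames(
    rep(names(seqs), times = lengths(seqs)),
    unlist(lapply(names(seqs), function(f)
      paste0(names(seqs[[f]]), "_", f)), use.names = FALSE))

  res <- plant_hgt_genes(genomes, truth, cfg)
  res <- plant_ecosnps(res$genomes, res$truth, cfg)
  res <- plant_outlier_genomes(res$genomes, res$truth, cfg)
  res$truth <- scan_emergent_ecosnps(res$genomes, res$truth)
  res
}

# Build a GenomeSet from family -> (genome -> sequence) maps. Gene ids are
# "<genome>_<family>".
assemble_genome_set <- function(seqs, genome_ids, truth) {
  rows <- lapply(names(seqs), function(f) {
    s <- seqs[[f]]
    data.frame(genome_id = names(s),
               gene_id = paste0(names(s), "_", f),
               nucleotide = unname(s), stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  genes$protein <- translate_cds(genes$nucleotide)
  genes <- genes[order(match(genes$genome_id, genome_ids), genes$gene_id), ]
  rownames(genes) <- NULL
  genome_set(genes[, c("genome_id", "gene_id", "nucleotide", "protein")],
             genome_ids = genome_ids)
}

#' Plant horizontally transferred families at 30--70% presence in every clade
#'
#' Adds `config$n_hgt` new families whose per-clade presence counts are drawn
#' uniformly from the integers realizing a presence fraction in
#' `[0.30, 0.70]`, mirroring the screen of [hgt_screen()].
#'
#' @param genomes a `GenomeSet` (non-outlier genomes).
#' @param truth the matching `TruthSet`.
#' @param config a [simulation_config()].
#' @return list(genomes, truth) with the planted families appended.
#' @export
plant_hgt_genes <- function(genomes, truth, config) {
  cfg <- config
  if (cfg$n_hgt == 0) return(list(genomes = genomes, truth = truth))
  assert_that(cfg$n_clades >= 2, "HGT planting needs >= 2 clades")
  clade_of <- truth$clade_of
  clades <- unique(unname(clade_of))
  reg <- regular_genomes(truth)
  n_prev <- length(truth$family_class)
  fam_ids <- sprintf("F%04d", n_prev + seq_len(cfg$n_hgt))
  lo <- ceiling(0.30 * cfg$genomes_per_clade)
  hi <- floor(0.70 * cfg$genomes_per_clade)

  new_seqs <- with_seed(derive_seed(cfg$seed, "hgt"), {
    lens <- pmax(300, round(stats::rnorm(cfg$n_hgt, cfg$gene_length_mean,
                                         cfg$gene_length_sd)))
    lens <- lens - lens %% 3
    out <- vector("list", cfg$n_hgt)
    names(out) <- fam_ids
    for (i in seq_len(cfg$n_hgt)) {
      anc <- random_cds(lens[i])
      s <- character(0)
      for (cl in clades) {
        cl_seq <- mutate_one(anc, cfg$between_clade_mut_rate)
        g <- reg[clade_of[reg] == cl]
        take <- sample_range(lo, hi)
        pick <- sort(sample(g, take))
        s <- c(s, stats::setNames(vapply(pick, function(gg)
          mutate_one(cl_seq, cfg$within_clade_mut_rate), character(1L)), pick))
      }
      out[[i]] <- s
    }
    out
  })

  add <- assemble_genome_set(new_seqs, genomes$genome_ids, truth)
  genes <- rbind(genomes$genes, add$genes)
  gs <- genome_set(genes, genome_ids = genomes$genome_ids)
  occ <- vapply(new_seqs, length, 0L)
  truth$family_class <- c(truth$family_class, classify_occupancy(
    occ, n_genomes = length(reg), named = fam_ids))
  truth$hgt_families <- c(truth$hgt_families, fam_ids)
  truth$family_of_gene <- c(truth$family_of_gene, stats::setNames(
    rep(fam_ids, times = lengths(new_seqs)),
    unlist(lapply(fam_ids, function(f)
      paste0(names(new_seqs[[f]]), "_", f)), use.names = FALSE)))
  list(genomes = gs, truth = truth)
}

# occupancy -> partition class under the pangenome module's band definitions
classify_occupancy <- function(occ, n_genomes, named = NULL) {
  softcore_min <- ceiling(0.95 * n_genomes)
  cls <- ifelse(occ == n_genomes, "core",
         ifelse(occ >= softcore_min, "softcore",
         ifelse(occ <= 2, "cloud", "shell")))
  if (!is.null(named)) names(cls) <- named
  cls
}

#' Plant clade-diagnostic ecoSNP columns into flagged core families
#'
#' For each flagged core family, `config$n_ecosnp` distinct columns are
#' chosen; at each, every genome of one focal clade receives base `x` and
#' every other genome base `y != x`, making the column dimorphic and
#' perfectly clade-partitioning.
#'
#' @inheritParams plant_hgt_genes
#' @return list(genomes, truth) with planted columns recorded in
#'   `truth$ecosnps` (one row per clade per column, `planted = TRUE`).
#' @export
plant_ecosnps <- function(genomes, truth, config) {
  cfg <- config
  if (cfg$n_ecosnp == 0 || length(truth$ecosnp_families) == 0)
    return(list(genomes = genomes, truth = truth))
  assert_that(length(unique(truth$clade_of)) >= 2,
              "ecoSNP planting needs >= 2 clades")
  clade_of <- truth$clade_of
  clades <- unique(unname(clade_of))
  genes <- genomes$genes
  fam_of <- truth$family_of_gene
  recs <- list()

  planted <- with_seed(derive_seed(cfg$seed, "ecosnp"), {
    for (f in truth$ecosnp_families) {
      idx <- which(fam_of[genes$gene_id] == f)
      len <- nchar(genes$nucleotide[idx[1L]])
      assert_that(cfg$n_ecosnp <= len, sprintf(
        "family %s: requested %d ecoSNP columns but only %d sites", f,
        cfg$n_ecosnp, len))
      cols <- sort(sample.int(len, cfg$n_ecosnp))
      for (j in seq_along(cols)) {
        col <- cols[j]
        focal <- clades[1L + (j - 1L) %% length(clades)]
        xy <- sample(DNA_BASES, 2L)
        for (i in idx) {
          b <- if (clade_of[[genes$genome_id[i]]] == focal) xy[1L] else xy[2L]
          substr(genes$nucleotide[i], col, col) <- b
        }
        recs[[length(recs) + 1L]] <- data.frame(
          family = f, column = col, clade = clades,
          base = ifelse(clades == focal, xy[1L], xy[2L]),
          planted = TRUE, stringsAsFactors = FALSE)
      }
    }
    TRUE
  })

  genes$protein <- translate_cds(genes$nucleotide)
  gs <- genome_set(genes, genome_ids = genomes$genome_ids)
  truth$ecosnps <- rbind(truth$ecosnps, do.call(rbind, recs))
  list(genomes = gs, truth = truth)
}

#' Plant gene-count outlier genomes
#'
#' Each outlier is a copy of an existing genome inflated by whole-family
#' duplications until its gene count exceeds the non-outlier mean by
#' `max(4 sigma, 30%)`, guaranteeing that the +/- 2 sigma filter of
#' [quality_filter()] excludes it even after the outliers themselves inflate
#' the pooled mean and standard deviation.
#'
#' @inheritParams plant_hgt_genes
#' @return list(genomes, truth) with outlier genomes appended.
#' @export
plant_outlier_genomes <- function(genomes, truth, config) {
  cfg <- config
  if (cfg$n_outlier_genomes == 0) return(list(genomes = genomes, truth = truth))
  reg <- regular_genomes(truth)
  cnt <- gene_counts(genomes)[reg]
  mu <- mean(cnt); sdv <- pop_sd(cnt)
  target <- mu + max(4 * sdv, 0.3 * mu)
  genes <- genomes$genes
  fam_of <- truth$family_of_gene

  out <- with_seed(derive_seed(cfg$seed, "outlier"), {
    added <- list(); new_map <- character(0); ids <- character(0)
    for (j in seq_len(cfg$n_outlier_genomes)) {
      oid <- sprintf("OUT_%02d", j)
      src <- reg[1L + (j - 1L) %% length(reg)]
      sub <- genes[genes$genome_id == src, , drop = FALSE]
      fams <- unname(fam_of[sub$gene_id])
      base <- data.frame(genome_id = oid,
                         gene_id = paste0(oid, "_", fams),
                         nucleotide = sub$nucleotide, protein = sub$protein,
                         stringsAsFactors = FALSE)
      map <- stats::setNames(fams, base$gene_id)
      k <- 2L
      while (nrow(base) <= target) {
        pick <- sample.int(nrow(sub), min(nrow(sub), ceiling(target) + 1L - nrow(base)))
        dup <- sub[pick, , drop = FALSE]
        dfam <- unname(fam_of[dup$gene_id])
        dup2 <- data.frame(genome_id = oid,
                           gene_id = paste0(oid, "_", dfam, "_p", k),
                           nucleotide = dup$nucleotide, protein = dup$protein,
                           stringsAsFactors = FALSE)
        map <- c(map, stats::setNames(dfam, dup2$gene_id))
        base <- rbind(base, dup2)
        k <- k + 1L
      }
      added[[j]] <- base
      new_map <- c(new_map, map)
      ids <- c(ids, oid)
      truth$clade_of[[oid]] <- truth$clade_of[[src]]
    }
    list(genes = do.call(rbind, added), map = new_map, ids = ids,
         truth = truth)
  })
  truth <- out$truth
  truth$outlier_genomes <- c(truth$outlier_genomes, out$ids)
  truth$family_of_gene <- c(truth$family_of_gene, out$map)
  gs <- genome_set(rbind(genes, out$genes),
                   genome_ids = c(genomes$genome_ids, out$ids))
  list(genomes = gs, truth = truth)
}

# Record every clade-diagnostic dimorphic column of every core family
# (ignoring outlier genomes) into truth$ecosnps; planted columns keep their
# planted flag, emergent ones are added with planted = FALSE. This uses the
# generator's own family bookkeeping, not the pipeline's clustering/MSA
# machinery, so downstream detection can be scored against it.
scan_emergent_ecosnps <- function(genomes, truth) {
  clade_of <- truth$clade_of
  clades <- unique(unname(clade_of[regular_genomes(truth)]))
  if (length(clades) < 2) return(truth)
  core_fams <- names(truth$family_class)[truth$family_class == "core"]
  reg <- regular_genomes(truth)
  planted_key <- paste(truth$ecosnps$family, truth$ecosnps$column)
  recs <- list()
  for (f in core_fams) {
    s <- family_sequences(genomes, truth, f)
    s <- s[names(s) %in% reg]
    m <- do.call(rbind, strsplit(unname(s), "", fixed = TRUE))
    cl <- unname(clade_of[names(s)])
    hits <- ecosnp_columns(m, cl)
    if (!nrow(hits)) next
    hits <- hits[!(paste(f, hits$column) %in% planted_key), , drop = FALSE]
    if (!nrow(hits)) next
    recs[[length(recs) + 1L]] <- data.frame(
      family = f, column = hits$column, clade = hits$clade,
      base = hits$base, planted = FALSE, stringsAsFactors = FALSE)
  }
  if (length(recs))
    truth$ecosnps <- rbind(truth$ecosnps, do.call(rbind, recs))
  truth$ecosnps <- truth$ecosnps[order(truth$ecosnps$family,
                                       truth$ecosnps$column,
                                       truth$ecosnps$clade), ]
  rownames(truth$ecosnps) <- NULL
  truth
}

#' Write the simulator's ground-truth tables as TSV
#'
#' Writes `clades.tsv` (genome, clade), `family_class.tsv` (family, class),
#' `ecosnps.tsv`, `hgt.tsv` and `outliers.tsv` into `dir`.
#'
#' @param truth a `TruthSet`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_truth_tables <- function(truth, dir) {
  stopifnot(inherits(truth, "TruthSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(
    write_tsv(data.frame(genome = names(truth$clade_of),
                         clade = unname(truth$clade_of)),
              file.path(dir, "clades.tsv")),
    write_tsv(data.frame(family = names(truth$family_class),
                         class = unname(truth$family_class)),
              file.path(dir, "family_class.tsv")),
    write_tsv(truth$ecosnps, file.path(dir, "ecosnps.tsv")),
    write_tsv(data.frame(family = truth$hgt_families),
              file.path(dir, "hgt.tsv")),
    write_tsv(data.frame(genome = truth$outlier_genomes),
              file.path(dir, "outliers.tsv")))
  invisible(p)
}
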