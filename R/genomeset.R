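#' Genome sets
#'
#' A `GenomeSet` holds an ordered collection of genomes, each a list of genes
#' with paired nucleotide (CDS) and protein sequences. It is the common input
#' container for quality filtering, ortholog clustering and all downstream
#' stages.
#'
#' @param genes data.frame with columns `genome_id`, `gene_id`, `nucleotide`,
#'   `protein`. `gene_id` must be globally unique; sequences must be
#'   non-empty and `protein` must be the frame-1 standard-code translation of
#'   `nucleotide`.
#' @param genome_ids optional character vector fixing genome order; defaults
#'   to order of first appearance.
#'
#' @return An object of class `GenomeSet`: a list with elements `genes`
#'   (the validated data.frame) and `genome_ids`.
#' @export
genome_set <- function(genes, genome_ids = NULL) {
  need <- c("genome_id", "gene_id", "nucleotide", "protein")
  assert_that(is.data.frame(genes) && all(need %in% names(genes)),
              "genes must be a data.frame with columns genome_id, gene_id, nucleotide, protein")
  genes <- as.data.frame(genes[, need], stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(genes$gene_id), "gene ids must be globally unique")
  assert_that(all(nchar(genes$nucleotide) > 0) && all(nchar(genes$protein) > 0),
              "empty sequences are not allowed")
  if (is.null(genome_ids)) genome_ids <- unique(genes$genome_id)
  assert_that(all(genes$genome_id %in% genome_ids),
              "genes reference genomes missing from genome_ids")
  structure(list(genes = genes, genome_ids = as.character(genome_ids)),
            class = "GenomeSet")
}

#' @export
print.GenomeSet <- function(x, ...) {
  cat(sprintf("<GenomeSet> %d genomes, %d genes\n",
              length(x$genome_ids), nrow(x$genes)))
  cnt <- gene_counts(x)
  cat(sprintf("  genes/genome: min %d, median %s, max %d\n",
              min(cnt), format(stats::median(cnt)), max(cnt)))
  invisible(x)
}

#' Per-genome gene counts
#'
#' @param genomes a `GenomeSet`.
#' @return Named integer vector in genome order (genomes with zero genes
#'   included as 0).
#' @export
gene_counts <- function(genomes) {
  stopifnot(inherits(genomes, "GenomeSet"))
  tab <- table(factor(genomes$genes$genome_id, levels = genomes$genome_ids))
  stats::setNames(as.integer(tab), names(tab))
}

#' Translate coding sequences (frame 1, standard code)
#'
#' @param nucleotide character vector of CDS strings with length a multiple
#'   of three.
#' @return Character vector of protein sequences (internal stops kept as
#'   `*`).
#' @export
translate_cds <- function(nucleotide) {
  assert_that(all(nchar(nucleotide) %% 3 == 0),
              "CDS lengths must be multiples of 3")
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nucleotide),
                                     if.fuzzy.codon = "X"))
}

#' Write per-genome FASTA files
#'
#' Writes one protein (`.faa`) and one nucleotide (`.fna`) FASTA per genome,
#' with headers of the form `genomeID|geneID`. The files round-trip
#' losslessly through [read_genome_fastas()].
#'
#' @param genomes a `GenomeSet`.
#' @param dir writable directory.
#' @param overwrite overwrite existing files? Default `FALSE`: collision with
#'   an existing file is an error.
#' @return Invisibly, a character vector of the file paths written.
#' @export
write_genome_fastas <- function(genomes, dir, overwrite = FALSE) {
  stopifnot(inherits(genomes, "GenomeSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (g in genomes$genome_ids) {
    sub <- genomes$genes[genomes$genes$genome_id == g, , drop = FALSE]
    if (nrow(sub) == 0L)
      warning(sprintf("genome '%s' has no genes; writing empty FASTA", g))
    hdr <- paste0(g, "|", sub$gene_id)
    for (ext in c("fna", "faa")) {
      path <- file.path(dir, paste0(g, ".", ext))
      if (file.exists(path) && !overwrite)
        stop(sprintf("file '%s' exists; use overwrite = TRUE", path))
      seqs <- if (ext == "fna") sub$nucleotide else sub$protein
      writeLines(if (nrow(sub)) paste0(">", hdr, "\n", seqs) else character(0),
                 path)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Read per-genome FASTA files back into a GenomeSet
#'
#' Expects the `<genome>.fna` / `<genome>.faa` pairs and `genomeID|geneID`
#' headers produced by [write_genome_fastas()].
#'
#' @param dir directory holding the FASTA pairs.
#' @return A `GenomeSet`.
#' @export
read_genome_fastas <- function(dir) {
  fna <- sort(list.files(dir, pattern = "\\.fna$", full.names = TRUE))
  assert_that(length(fna) > 0, sprintf("no .fna files found in '%s'", dir))
  rows <- lapply(fna, function(fp) {
    gid <- sub("\\.fna$", "", basename(fp))
    ap <- file.path(dir, paste0(gid, ".faa"))
    assert_that(file.exists(ap), sprintf("missing protein FASTA for '%s'", gid))
    nt <- Biostrings::readDNAStringSet(fp)
    aa <- Biostrings::readAAStringSet(ap)
    if (length(nt) == 0L)
      return(data.frame(genome_id = character(0), gene_id = character(0),
                        nucleotide = character(0), protein = character(0)))
    parts <- strsplit(names(nt), "|", fixed = TRUE)
    assert_that(all(lengths(parts) == 2L),
                "FASTA headers must have the form genomeID|geneID")
    data.frame(genome_id = vapply(parts, `[[`, "", 1L),
               gene_id   = vapply(parts, `[[`, "", 2L),
               nucleotide = as.character(nt),
               protein    = as.character(aa)[match(names(nt), names(aa))],
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  genome_ids <- sub("\\.fna$", "", basename(fna))
  genome_set(genes, genome_ids = genome_ids)
}
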