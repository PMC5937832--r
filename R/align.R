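#' Optimal local alignment of two protein sequences
#'
#' Smith--Waterman alignment with affine gaps under a substitution matrix
#' (BLOSUM62 with gap open 11 / extend 1 by default, the blastp defaults).
#' Identity and coverages are computed over the aligned region.
#'
#' @param a,b protein sequence strings (amino-acid alphabet; `*` allowed).
#' @param substitution_matrix name of a matrix shipped with Biostrings.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return A one-row data.frame (a *similarity hit*): `query`, `subject`
#'   (the inputs), `score` (raw, substitution-matrix units), `pident`
#'   (percent identity over the aligned region, 0--100), `qcov`, `scov`
#'   (aligned fraction of each sequence, 0--1).
#' @export
align_pair <- function(a, b, substitution_matrix = "BLOSUM62",
                       gap_open = 11, gap_extend = 1) {
  validate_protein(a); validate_protein(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  qr <- range(c(Biostrings::start(Biostrings::pattern(aln)),
                Biostrings::end(Biostrings::pattern(aln))))
  sr <- range(c(Biostrings::start(Biostrings::subject(aln)),
                Biostrings::end(Biostrings::subject(aln))))
  data.frame(query = a, subject = b,
             score = Biostrings::score(aln),
             pident = Biostrings::pid(aln, type = "PID1"),
             qcov = (qr[2L] - qr[1L] + 1) / nchar(a),
             scov = (sr[2L] - sr[1L] + 1) / nchar(b),
             stringsAsFactors = FALSE)
}

validate_protein <- function(x) {
  assert_that(is.character(x) && length(x) == 1L && nchar(x) > 0,
              "sequences must be non-empty strings")
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYBZXUJO*]+$", x)
  assert_that(ok, "sequence contains non-amino-acid characters")
  invisible(TRUE)
}

#' Karlin--Altschul E-value for a raw alignment score
#'
#' `E = K * m * db_residues * exp(-lambda * S)`: the expected number of
#' chance local alignments scoring at least `S` when a query of length `m`
#' is compared against `db_residues` letters of database. The default
#' constants are published gapped-BLOSUM62 values, giving blastp-scale
#' E-values without BLAST's statistics fitting.
#'
#' @param score raw alignment score (>= 0).
#' @param m query length in residues (> 0).
#' @param n subject length in residues (> 0).
#' @param db_residues total residues searched; defaults to `n` (single-pair
#'   search). E scales linearly in this argument.
#' @param K,lambda Karlin--Altschul constants.
#' @return The E-value (non-negative numeric).
#' @export
estimate_evalue <- function(score, m, n, db_residues = n,
                            K = 0.041, lambda = 0.267) {
  assert_that(all(score >= 0), "score must be >= 0")
  assert_that(all(m > 0) && all(n > 0) && all(db_residues > 0),
              "lengths must be > 0")
  K * m * db_residues * exp(-lambda * score)
}

# Candidate gene pairs sharing >= min_shared amino-acid k-mers. All-vs-all
# Smith-Waterman is quadratic in the gene count, so the similarity graph
# only aligns pairs passing this seed filter (lossless for the high-identity
# families the simulator emits; a documented limitation for remote
# homology).
kmer_candidate_pairs <- function(proteins, k = 5L, min_shared = 3L) {
  ids <- names(proteins)
  stopifnot(!is.null(ids))
  km <- lapply(proteins, function(p) {
    n <- nchar(p)
    if (n < k) return(character(0))
    unique(substring(p, 1:(n - k + 1L), k:n))
  })
  dt <- data.table::data.table(
    kmer = unlist(km, use.names = FALSE),
    gene = rep(seq_along(km), times = lengths(km)))
  # drop non-discriminating k-mers shared by very many genes (repeat-like)
  dt <- dt[, if (.N <= 200L) .SD, by = "kmer"]
  pairs <- dt[dt, on = "kmer", allow.cartesian = TRUE
              ][gene < i.gene, .N, by = c("gene", "i.gene")]
  pairs <- pairs[pairs$N >= min_shared, ]
  data.frame(q = ids[pairs$gene], s = ids[pairs$i.gene],
             shared = pairs$N, stringsAsFactors = FALSE)
}

#' Build the gated protein-similarity graph of a genome set
#'
#' Aligns candidate gene pairs (shared k-mer prefilter, then
#' [align_pair()]), estimates E-values against the whole dataset's residue
#' count, and keeps an undirected edge for every pair with
#' `E < e_max` and both coverages `>= cov_min`. Edge weight is
#' `-log10(max(E, 1e-200))`.
#'
#' @param genomes a `GenomeSet` (typically after [quality_filter()]).
#' @param e_max E-value gate (edges require `E < e_max`).
#' @param cov_min coverage gate applied to query *and* subject.
#' @param k,min_shared k-mer prefilter parameters.
#' @param verbose print progress?
#' @return An object of class `SimilarityGraph`: list with `edges`
#'   (data.frame `from`, `to`, `weight`), `vertices` (all gene ids),
#'   `genome_of` (named vector), and `hits` (all aligned candidate pairs
#'   with score, pident, coverages and evalue, before gating — the hit
#'   store consumed by [average_identity_matrix()]).
#' @export
build_similarity_graph <- function(genomes, e_max = 1e-5, cov_min = 0.75,
                                   k = 5L, min_shared = 3L, verbose = FALSE) {
  stopifnot(inherits(genomes, "GenomeSet"))
  genes <- genomes$genes
  assert_that(nrow(genes) >= 2, "need at least 2 genes")
  prot <- stats::setNames(genes$protein, genes$gene_id)
  genome_of <- stats::setNames(genes$genome_id, genes$gene_id)

  cand <- kmer_candidate_pairs(prot, k = k, min_shared = min_shared)
  if (verbose)
    message(sprintf("aligning %d candidate pairs (of %d genes)",
                    nrow(cand), length(prot)))
  hits <- align_pairs_batch(prot, cand)
  db <- sum(nchar(prot))
  hits$evalue <- estimate_evalue(hits$score, m = nchar(prot[hits$q]),
                                 n = nchar(prot[hits$s]), db_residues = db)
  keep <- hits$evalue < e_max & hits$qcov >= cov_min & hits$scov >= cov_min
  edges <- data.frame(from = hits$q[keep], to = hits$s[keep],
                      weight = -log10(pmax(hits$evalue[keep], 1e-200)),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, vertices = names(prot),
                 genome_of = genome_of, hits = hits),
            class = "SimilarityGraph")
}

# Vectorized Smith-Waterman over a candidate pair table: group by subject
# gene and align all its partners in one pairwiseAlignment call.
align_pairs_batch <- function(prot, cand) {
  if (nrow(cand) == 0L)
    return(data.frame(q = character(0), s = character(0), score = numeric(0),
                      pident = numeric(0), qcov = numeric(0),
                      scov = numeric(0), stringsAsFactors = FALSE))
  parts <- split(cand$q, cand$s)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    sid <- names(parts)[i]
    qids <- parts[[i]]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(prot[qids]), Biostrings::AAString(prot[[sid]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    pat <- Biostrings::pattern(aln)
    sub <- Biostrings::subject(aln)
    out[[i]] <- data.frame(
      q = qids, s = sid,
      score = Biostrings::score(aln),
      pident = Biostrings::pid(aln, type = "PID1"),
      qcov = (Biostrings::end(pat) - Biostrings::start(pat) + 1) /
        nchar(prot[qids]),
      scov = (Biostrings::end(sub) - Biostrings::start(sub) + 1) /
        nchar(prot[[sid]]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.SimilarityGraph <- function(x, ...) {
  cat(sprintf("<SimilarityGraph> %d genes, %d edges (%d candidate hits)\n",
              length(x$vertices), nrow(x$edges), nrow(x$hits)))
  invisible(x)
}
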