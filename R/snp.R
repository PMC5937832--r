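#' Consensus sequence of an alignment
#'
#' Per column, the most frequent ungapped base, ties broken alphabetically
#' (A < C < G < T); columns that are all gaps become `N`.
#'
#' @param alignment an [msa()] with >= 2 rows.
#' @return An object of class `ConsensusProfile`: list with `consensus`
#'   (string of MSA length), `counts` (4 x L matrix of per-column base
#'   counts) and `n_rows`.
#' @export
build_consensus <- function(alignment) {
  stopifnot(inherits(alignment, "MSA"))
  m <- as.matrix(alignment)
  assert_that(nrow(m) >= 2, "need >= 2 rows")
  counts <- do.call(rbind, lapply(DNA_BASES, function(b) colSums(m == b)))
  rownames(counts) <- DNA_BASES
  top <- apply(counts, 2L, which.max)  # first maximum = alphabetical tie
  cons <- ifelse(colSums(counts) == 0L, "N", DNA_BASES[top])
  structure(list(consensus = paste0(cons, collapse = ""),
                 counts = counts, n_rows = nrow(m)),
            class = "ConsensusProfile")
}

#' Call SNPs against a consensus
#'
#' A SNP is an ungapped position where a strain differs from the consensus.
#' Two gene-level summaries are reported side by side: the per-strain
#' mismatch total (*sum SNP*) and the count of variable columns (>= 2
#' distinct ungapped bases), since published SNP totals are often ambiguous
#' between the two. Columns with >= 3 distinct bases are *polyvariable*.
#'
#' @param alignment the [msa()] the consensus was built from.
#' @param consensus a `ConsensusProfile` of matching length.
#' @return An object of class `SNPReport`: list with `per_strain` (named
#'   mismatch counts), `sum_snp`, `n_variable`, `n_polyvariable`, `length`
#'   (alignment columns), `snp_per_base` (`sum_snp / length`) and the two
#'   per-kb densities `density_sum_per_kb`, `density_variable_per_kb`.
#' @export
call_snps <- function(alignment, consensus) {
  stopifnot(inherits(alignment, "MSA"), inherits(consensus, "ConsensusProfile"))
  m <- as.matrix(alignment)
  L <- ncol(m)
  assert_that(nchar(consensus$consensus) == L,
              "consensus length does not match the alignment")
  cons <- strsplit(consensus$consensus, "")[[1L]]
  ung <- matrix(m %in% DNA_BASES, nrow = nrow(m))
  mism <- ung & (m != matrix(cons, nrow(m), L, byrow = TRUE))
  per_strain <- stats::setNames(as.integer(rowSums(mism)), alignment$names)
  n_states <- Reduce(`+`, lapply(DNA_BASES, function(b) colSums(m == b) > 0L))
  n_variable <- as.integer(sum(n_states >= 2L))
  n_polyvariable <- as.integer(sum(n_states >= 3L))
  sum_snp <- as.integer(sum(per_strain))
  structure(list(per_strain = per_strain, sum_snp = sum_snp,
                 n_variable = n_variable, n_polyvariable = n_polyvariable,
                 length = L, snp_per_base = sum_snp / L,
                 density_sum_per_kb = sum_snp / (L / 1000),
                 density_variable_per_kb = n_variable / (L / 1000)),
            class = "SNPReport")
}

#' @export
print.SNPReport <- function(x, ...) {
  cat(sprintf(paste0("<SNPReport> %d bp: sum SNP %d (%.2f/kb), variable ",
                     "columns %d (%.2f/kb), polyvariable %d\n"),
              x$length, x$sum_snp, x$density_sum_per_kb, x$n_variable,
              x$density_variable_per_kb, x$n_polyvariable))
  invisible(x)
}

#' Detect clade-diagnostic ecoSNP columns
#'
#' A column is an ecoSNP iff every strain is ungapped there, exactly two
#' bases occur, and no clade is split across the two bases — i.e. the
#' dimorphism is specific to clades (for two clades this means the state
#' partition equals the clade partition exactly).
#'
#' @param alignment an [msa()].
#' @param clades named vector strain -> clade; >= 2 clades with >= 2 strains
#'   each, covering all rows.
#' @return An object of class `EcoSNPReport`: data.frame with columns
#'   `column`, `clade`, `base` (one row per clade per detected column).
#' @export
detect_ecosnps <- function(alignment, clades) {
  stopifnot(inherits(alignment, "MSA"))
  missing <- setdiff(alignment$names, names(clades))
  assert_that(length(missing) == 0,
              sprintf("strains without clade label: %s",
                      paste(utils::head(missing, 3), collapse = ", ")))
  cl <- unname(clades[alignment$names])
  tab <- table(cl)
  assert_that(length(tab) >= 2, "need >= 2 clades")
  assert_that(all(tab >= 2), "every clade needs >= 2 strains")
  m <- as.matrix(alignment)
  out <- ecosnp_columns(m, cl)
  structure(out, class = c("EcoSNPReport", "data.frame"))
}

# vectorized scan for gap-free, dimorphic, clade-concordant columns of a
# character matrix (rows = strains); returns long-format records
ecosnp_columns <- function(m, cl) {
  L <- ncol(m)
  gapless <- colSums(matrix(!(m %in% DNA_BASES), nrow(m), L)) == 0L
  nstates <- Reduce(`+`, lapply(DNA_BASES, function(b) colSums(m == b) > 0L))
  clades <- unique(cl)
  first_base <- matrix("", length(clades), L,
                       dimnames = list(clades, NULL))
  mono <- rep(TRUE, L)
  for (cc in clades) {
    sub <- m[cl == cc, , drop = FALSE]
    first_base[cc, ] <- sub[1L, ]
    mono <- mono & colSums(sub != matrix(sub[1L, ], nrow(sub), L,
                                         byrow = TRUE)) == 0L
  }
  hit <- which(gapless & nstates == 2L & mono)
  if (!length(hit))
    return(data.frame(column = integer(0), clade = character(0),
                      base = character(0), stringsAsFactors = FALSE))
  out <- data.frame(
    column = rep(hit, each = length(clades)),
    clade = rep(clades, times = length(hit)),
    base = as.vector(first_base[, hit, drop = FALSE]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
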