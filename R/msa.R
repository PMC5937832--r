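#' Multiple sequence alignments
#'
#' A lightweight container for aligned nucleotide sequences: ordered names,
#' equal-length rows over `{A, C, G, T, -}` and the source cluster id.
#'
#' @param names sequence names (unique).
#' @param seqs aligned rows (equal `nchar`).
#' @param cluster_id optional source cluster/gene family id.
#' @return An object of class `MSA`.
#' @export
msa <- function(names, seqs, cluster_id = NA_character_) {
  assert_that(length(names) == length(seqs) && length(seqs) >= 1,
              "names and seqs must have equal, positive length")
  assert_that(!anyDuplicated(names), "MSA names must be unique")
  assert_that(length(unique(nchar(seqs))) == 1L,
              "all MSA rows must have the same length")
  structure(list(names = as.character(names), seqs = as.character(seqs),
                 cluster_id = cluster_id), class = "MSA")
}

#' @export
print.MSA <- function(x, ...) {
  cat(sprintf("<MSA> %d sequences x %d columns (cluster %s)\n",
              length(x$seqs), nchar(x$seqs[1L]), x$cluster_id))
  invisible(x)
}

#' @export
as.matrix.MSA <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$names
  m
}

#' Center-star multiple alignment
#'
#' Global pairwise alignment (Needleman--Wunsch, affine gaps) of every
#' sequence against the *center* — the sequence minimizing the summed
#' pairwise alignment distance (columns differing, gaps included) — merged
#' under the "once a gap, always a gap" rule. Deterministic: center ties go
#' to the earliest input sequence.
#'
#' @param seqs named character vector of >= 2 non-empty nucleotide
#'   sequences.
#' @param cluster_id carried into the result.
#' @param match,mismatch,gap_open,gap_extend pairwise scoring parameters.
#' @return An [msa()] whose rows ungap to the input sequences.
#' @export
center_star_align <- function(seqs, cluster_id = NA_character_,
                              match = 2, mismatch = -1,
                              gap_open = 4, gap_extend = 1) {
  assert_that(length(seqs) >= 2, "need >= 2 sequences")
  assert_that(all(nchar(seqs) > 0), "empty sequences are not allowed")
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  nms <- names(seqs)

  # all rows identical: gap-free by construction, skip alignment entirely
  if (length(unique(seqs)) == 1L)
    return(msa(nms, unname(seqs), cluster_id))

  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  align2 <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = sm, gapOpening = gap_open,
      gapExtension = gap_extend)
    c(as.character(Biostrings::alignedPattern(aln)),
      as.character(Biostrings::alignedSubject(aln)))
  }

  # duplicate sequences are collapsed for all alignment work (exact:
  # identical rows have identical distances and identical aligned rows)
  uniq <- unique(unname(seqs))
  rep_of <- match(unname(seqs), uniq)
  mult <- tabulate(rep_of, nbins = length(uniq))
  nu <- length(uniq)

  pair_aln <- vector("list", nu * nu)  # cached alignments among uniques
  dmat <- matrix(0, nu, nu)
  for (i in seq_len(nu - 1L)) {
    for (j in (i + 1L):nu) {
      p <- align2(uniq[[i]], uniq[[j]])
      dmat[i, j] <- dmat[j, i] <-
        sum(strsplit(p[1L], "")[[1L]] != strsplit(p[2L], "")[[1L]])
      pair_aln[[(i - 1L) * nu + j]] <- p
    }
  }
  # summed distance of each original row to all other rows
  dist_sum <- vapply(seq_along(seqs), function(i)
    sum(dmat[rep_of[i], rep_of] ) , 0)
  ci <- which.min(dist_sum)            # earliest index on ties
  cu <- rep_of[ci]
  other_u <- setdiff(seq_len(nu), cu)

  # master alignment over the unique sequences: rows x columns char matrix;
  # col_map gives the center position of each column (0 = inserted gap)
  master <- matrix(strsplit(uniq[[cu]], "")[[1L]], nrow = 1L)
  col_map <- seq_len(nchar(uniq[[cu]]))
  row_u <- cu

  for (ou in other_u) {
    p <- if (cu < ou) pair_aln[[(cu - 1L) * nu + ou]] else
      rev(pair_aln[[(ou - 1L) * nu + cu]])
    cc <- strsplit(p[1L], "")[[1L]]
    ss <- strsplit(p[2L], "")[[1L]]
    if (!any(cc == "-") && !any(ss == "-") && !any(col_map == 0L)) {
      # gap-free against a gap-free master: plain positional stack
      master <- rbind(master, ss)
      row_u <- c(row_u, ou)
      next
    }
    pair_map <- ifelse(cc == "-", 0L, cumsum(cc != "-"))
    mi <- 1L; pj <- 1L
    new_cols <- list(); new_row <- character(0)
    nm <- ncol(master); np <- length(cc)
    while (mi <= nm || pj <= np) {
      m_ins <- mi <= nm && col_map[mi] == 0L
      p_ins <- pj <= np && pair_map[pj] == 0L
      if (mi <= nm && m_ins) {
        new_cols[[length(new_cols) + 1L]] <- list(col = master[, mi], map = 0L)
        new_row <- c(new_row, "-")
        mi <- mi + 1L
      } else if (pj <= np && p_ins) {
        new_cols[[length(new_cols) + 1L]] <-
          list(col = rep("-", nrow(master)), map = 0L)
        new_row <- c(new_row, ss[pj])
        pj <- pj + 1L
      } else {
        new_cols[[length(new_cols) + 1L]] <-
          list(col = master[, mi], map = col_map[mi])
        new_row <- c(new_row, ss[pj])
        mi <- mi + 1L; pj <- pj + 1L
      }
    }
    master <- do.call(cbind, lapply(new_cols, `[[`, "col"))
    if (is.null(dim(master))) master <- matrix(master, nrow = 1L)
    col_map <- vapply(new_cols, `[[`, 0L, "map")
    master <- rbind(master, new_row)
    row_u <- c(row_u, ou)
  }

  urows <- apply(master, 1L, paste0, collapse = "")
  rows <- urows[match(rep_of, row_u)]
  msa(nms, unname(rows), cluster_id)
}
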