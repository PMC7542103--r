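# Global pairwise alignment of ortholog candidates.
#
# Needleman-Wunsch with BLOSUM62 and affine gaps (a gap run of length k
# costs open + k*extend; defaults 11/1, the community BLASTP defaults) via
# Biostrings. Externally aligned pairs can be supplied downstream instead;
# the built-in aligner is a single-gene stand-in for a production MSA tool.

#' Global pairwise protein alignment
#'
#' @param ref,tgt amino-acid sequences (single strings). Rare/ambiguity
#'   codes J, U, O are scored as X but preserved in the output.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution matrix name (a scoring matrix shipped with
#'   Biostrings, default `"BLOSUM62"`).
#' @return An object of class `pairwise_alignment`: `ref_aligned`,
#'   `tgt_aligned` (equal-length gapped strings) and `score`.
#' @export
nw_align <- function(ref, tgt, gap_open = 11, gap_extend = 1,
                     matrix = "BLOSUM62") {
  stopifnot(nzchar(ref), nzchar(tgt))
  sub_mat <- get_scoring_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(mask_rare(ref)),
    Biostrings::AAString(mask_rare(tgt)),
    substitutionMatrix = sub_mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ra <- restore_rare(as.character(Biostrings::alignedPattern(pa)), ref)
  ta <- restore_rare(as.character(Biostrings::alignedSubject(pa)), tgt)
  pairwise_alignment(ra, ta, Biostrings::score(pa))
}

#' Construct a pairwise alignment object
#'
#' @param ref_aligned,tgt_aligned equal-length gapped sequences.
#' @param score alignment score (`NA` for externally aligned input).
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(ref_aligned, tgt_aligned, score = NA_real_) {
  if (nchar(ref_aligned) != nchar(tgt_aligned)) {
    stop("aligned sequences differ in length")
  }
  structure(list(ref_aligned = ref_aligned, tgt_aligned = tgt_aligned,
                 score = score),
            class = "pairwise_alignment")
}

get_scoring_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# J/U/O are absent from BLOSUM62; score them as X, restore afterwards.
mask_rare <- function(s) chartr("JUO", "XXX", s)

restore_rare <- function(aligned, original) {
  chars <- strsplit(aligned, "")[[1L]]
  res <- chars != "-"
  chars[res] <- strsplit(original, "")[[1L]]
  paste(chars, collapse = "")
}

#' Ungapped percent identity of an alignment
#'
#' Identity over columns where both rows carry a residue (gap columns
#' excluded from the denominator).
#'
#' @param aln a [pairwise_alignment].
#' @return Fraction identical in `[0, 1]` (`NaN` if no ungapped columns).
#' @export
alignment_identity <- function(aln) {
  r <- strsplit(aln$ref_aligned, "")[[1L]]
  t <- strsplit(aln$tgt_aligned, "")[[1L]]
  both <- r != "-" & t != "-"
  mean(r[both] == t[both])
}

#' Reciprocal-best-hit ortholog pairing between two proteomes
#'
#' Scores every cross-proteome pair with [nw_align()] and pairs `p` with
#' `q` when each is the other's highest-scoring hit; score ties are broken
#' toward the lexicographically smallest protein id. Intended for the
#' two-genome synthetic setting; multi-genome studies should ingest a
#' cluster table from a dedicated clustering tool instead.
#'
#' @param ref,tgt [proteome] objects.
#' @inheritParams nw_align
#' @return A [cluster_table] of two-genome single-copy pairs, cluster ids
#'   `rbh_0001 ...` ordered by reference protein id.
#' @export
rbh_orthologs <- function(ref, tgt, gap_open = 11, gap_extend = 1,
                          matrix = "BLOSUM62") {
  stopifnot(inherits(ref, "proteome"), inherits(tgt, "proteome"))
  sub_mat <- get_scoring_matrix(matrix)
  tgt_set <- Biostrings::AAStringSet(vapply(tgt$records$sequence, mask_rare,
                                            character(1L)))
  scores <- t(vapply(ref$records$sequence, function(s) {
    Biostrings::pairwiseAlignment(
      tgt_set, Biostrings::AAString(mask_rare(s)),
      substitutionMatrix = sub_mat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global", scoreOnly = TRUE)
  }, numeric(nrow(tgt$records))))
  ref_ids <- ref$records$protein_id
  tgt_ids <- tgt$records$protein_id
  # best hit with lexicographic tie-break
  best_of <- function(v, ids) {
    cand <- which(v == max(v))
    cand[order(ids[cand])][1L]
  }
  best_tgt <- apply(scores, 1L, best_of, ids = tgt_ids)
  best_ref <- apply(scores, 2L, best_of, ids = ref_ids)
  mutual <- which(best_ref[best_tgt] == seq_along(ref_ids))
  mutual <- mutual[order(ref_ids[mutual])]
  clusters <- lapply(mutual, function(i) {
    m <- list(ref_ids[i], tgt_ids[best_tgt[i]])
    names(m) <- c(ref$genome_id, tgt$genome_id)
    m
  })
  names(clusters) <- sprintf("rbh_%04d", seq_along(clusters))
  cluster_table(clusters)
}
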