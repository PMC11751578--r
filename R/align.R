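# Residue mappings between a reference and a model. When the sequences
# are identical the mapping is the diagonal; otherwise a global
# Needleman-Wunsch alignment under BLOSUM62 with affine gaps supplies the
# aligned residue pairs.

new_residue_mapping <- function(ref_idx, model_idx, identity = NA_real_,
                                coverage = NA_real_) {
  stopifnot(length(ref_idx) == length(model_idx))
  if (length(ref_idx) > 1) {
    stopifnot(all(diff(ref_idx) > 0), all(diff(model_idx) > 0))
  }
  structure(
    tibble::tibble(ref_idx = as.integer(ref_idx),
                   model_idx = as.integer(model_idx)),
    class = c("residue_mapping", class(tibble::tibble())),
    identity = identity, coverage = coverage
  )
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("# residue mapping: %d pair(s), identity %.3f, coverage %.3f\n",
              nrow(x), attr(x, "identity"), attr(x, "coverage")))
  NextMethod()
}

# BLOSUM62 with 'X' neutral (scores 0 against everything).
blosum62_xneutral <- function() {
  mat <- get_blosum62()
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Global sequence alignment (Needleman-Wunsch, BLOSUM62)
#'
#' Optimal global alignment of two protein sequences under BLOSUM62 with
#' affine gap costs, returning the aligned residue pairs as a mapping.
#' `'X'` scores 0 against every letter. Gap costs are positive penalties;
#' the defaults (open 10, extend 0.5) are a widely used global-alignment
#' default and are exposed because tools differ in their "default"
#' parameters.
#'
#' @param ref_seq,model_seq 1-letter amino-acid strings (non-empty).
#' @param gap_open,gap_extend positive gap penalties.
#' @return A `residue_mapping`: tibble of `(ref_idx, model_idx)` pairs with
#'   `identity` (fraction of aligned columns with equal letters) and
#'   `coverage` (aligned columns / reference length) attributes, plus the
#'   alignment `score`.
#' @export
nw_align <- function(ref_seq, model_seq, gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(ref_seq) || !nzchar(model_seq)) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref_seq), Biostrings::AAString(model_seq),
    substitutionMatrix = blosum62_xneutral(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_i <- cumsum(pat != "-")
  mod_i <- cumsum(sub != "-")
  both <- pat != "-" & sub != "-"
  n_pairs <- sum(both)
  identity <- if (n_pairs > 0) sum(pat[both] == sub[both]) / n_pairs else 0
  m <- new_residue_mapping(ref_i[both], mod_i[both],
                           identity = identity,
                           coverage = n_pairs / nchar(ref_seq))
  attr(m, "score") <- Biostrings::score(pa)
  m
}

#' Build a residue mapping between two structures
#'
#' Residues are indexed in chain order (the order of
#' [residue_table()]). Identical sequences map diagonally; differing
#' sequences are aligned globally with [nw_align()].
#'
#' @param ref,model structure tibbles.
#' @param gap_open,gap_extend gap penalties forwarded to [nw_align()].
#' @return A `residue_mapping`.
#' @export
map_residues <- function(ref, model, gap_open = 10, gap_extend = 0.5) {
  rs <- paste(extract_sequence(ref)$sequence, collapse = "")
  ms <- paste(extract_sequence(model)$sequence, collapse = "")
  if (identical(rs, ms)) {
    n <- nchar(rs)
    return(new_residue_mapping(seq_len(n), seq_len(n),
                               identity = 1, coverage = 1))
  }
  nw_align(rs, ms, gap_open = gap_open, gap_extend = gap_extend)
}

#' Identity mapping over n residues
#'
#' @param n residue count.
#' @return A diagonal `residue_mapping`.
#' @export
identity_mapping <- function(n) {
  new_residue_mapping(seq_len(n), seq_len(n), identity = 1, coverage = 1)
}
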