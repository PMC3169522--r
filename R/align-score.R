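# Local-alignment scoring: the desk-scale stand-in for blastp.  Raw scores
# are Smith-Waterman with affine gaps (C implementation, identical to
# Biostrings::pairwiseAlignment local scores); normalized scores divide by
# the smaller self-score, giving a database-size-independent similarity in
# [0, 1] that replaces E-values.

#' Local-alignment scoring scheme
#'
#' @param matrix 20x20 integer substitution matrix with residue dimnames;
#'   defaults to BLOSUM62 (from Biostrings' embedded matrices)
#' @param gap_open,gap_extend negative integers; a gap of length k costs
#'   `gap_open + k * gap_extend`
#' @return a list of class `scoring_scheme`
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = -10L,
                           gap_extend = -1L) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            isTRUE(all.equal(matrix, t(matrix))),
            gap_open < 0, gap_extend < 0)
  storage.mode(matrix) <- "integer"
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 alphabet = rownames(matrix)),
            class = "scoring_scheme")
}

# encode residues as 0-based indices into the scheme's matrix
encode_residues <- function(seq, scheme) {
  if (!nzchar(seq)) stop("empty sequence")
  ch <- strsplit(toupper(seq), "")[[1]]
  code <- match(ch, scheme$alphabet) - 1L
  if (anyNA(code))
    stop("unknown residue symbol: ", ch[which(is.na(code))[1]])
  code
}

self_score <- function(code, scheme) {
  sum(diag(scheme$matrix)[code + 1L])
}

#' Local alignment score of two sequences
#'
#' @param a,b residue sequences (non-empty strings)
#' @param scheme a [scoring_scheme()]
#' @return `c(raw = , normalized = )`; the raw score is the optimal local
#'   alignment score (>= 0, the empty alignment scoring 0) and the
#'   normalized score divides by the smaller of the two self-scores
#' @export
local_align_score <- function(a, b, scheme = scoring_scheme()) {
  ca <- encode_residues(a, scheme); cb <- encode_residues(b, scheme)
  raw <- .sw_score_int(ca, cb, scheme$matrix, scheme$gap_open,
                       scheme$gap_extend)
  c(raw = raw,
    normalized = raw / min(self_score(ca, scheme), self_score(cb, scheme)))
}

# vectorized raw scores of many encoded queries against one encoded subject
local_align_raw_many <- function(codes, subject_code, scheme) {
  .sw_score_many(codes, subject_code, scheme$matrix, scheme$gap_open,
                 scheme$gap_extend)
}

# ---- k-mer word prefilter --------------------------------------------------

# integer k-mer codes of an encoded sequence (base-20 words)
kmer_codes <- function(code, k) {
  n <- length(code)
  if (n < k) return(integer())
  out <- code[seq_len(n - k + 1L)]
  for (j in seq_len(k - 1L)) {
    out <- out + 20L^j * code[(1L + j):(n - k + 1L + j)]
  }
  out
}

# Number of query positions whose k-mer occurs anywhere in the subject.
# Used to skip full alignment of clearly unrelated pairs, like word
# seeding in BLAST; the threshold scales with the chance expectation
# n*m/20^k so longer pairs are not let through by background matches.
kmer_hits <- function(qcodes_list, subject_code, k) {
  pres <- logical(20L^k)
  sk <- kmer_codes(subject_code, k)
  pres[sk + 1L] <- TRUE
  vapply(qcodes_list, function(qc) {
    kc <- kmer_codes(qc, k)
    if (!length(kc)) return(0L)
    sum(pres[kc + 1L])
  }, integer(1))
}

kmer_threshold <- function(nq, ns, k) {
  pmax(4, 2 * (nq * ns) / 20^k)
}
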