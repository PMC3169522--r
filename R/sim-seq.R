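# Sequence evolution under the uniform 20-state amino-acid model and the
# alignment container shared by the phylogenetic code.

#' Residue alphabet used throughout the package
#'
#' The 20 amino acids in the row order of the embedded BLOSUM62 matrix,
#' plus `-` (gap) and `X` (unknown) as non-residue symbols.
#' @export
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Alignment block
#'
#' A rectangular multiple alignment: a character matrix with one row per
#' sequence (unique rownames are the row ids) over the amino-acid alphabet
#' plus `-`/`X`.
#'
#' @param mat character matrix with rownames
#' @return the validated matrix with class `alignment_block`
#' @export
alignment_block <- function(mat) {
  stopifnot(is.matrix(mat), is.character(mat), !is.null(rownames(mat)))
  if (anyDuplicated(rownames(mat)))
    stop("duplicate row ids in alignment")
  bad <- !(mat %in% c(AA_ALPHABET20, "-", "X"))
  if (any(bad)) stop("unknown residue symbol: ", mat[bad][1])
  class(mat) <- c("alignment_block", class(mat))
  mat
}

#' @rdname alignment_block
#' @param seqs named character vector of equal-length sequences
#' @export
as_alignment_block <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  alignment_block(mat)
}

#' @rdname alignment_block
#' @param ab an `alignment_block`
#' @export
ab_strings <- function(ab) {
  setNames(apply(unclass(ab), 1, paste, collapse = ""), rownames(ab))
}

#' @rdname alignment_block
#' @export
n_positions <- function(ab) ncol(ab)

#' Evolve sequences along a gene tree
#'
#' Uniform 20-state substitution process: the root sequence is uniform over
#' the alphabet, and along a branch of length `t` each site changes with
#' probability `(19/20)(1 - exp(-(20/19) r t))`, the replacement being
#' uniform over the other 19 residues.  This is the exact transition kernel
#' of the continuous-time uniform-exchange chain, so the expected
#' proportion of differing sites between two tips at path distance `d`
#' (in substitutions per site, `d = r * path length`) is
#' `(19/20)(1 - exp(-(20/19) d))`, which [pairwise_distance()] inverts.
#' There are no indels, so rows are aligned by construction.
#'
#' @param gene_tree `phylo` with branch lengths (time units)
#' @param seq_length number of sites (>= 1)
#' @param subst_rate substitutions per site per unit branch length
#' @param seed integer seed
#' @return an [alignment_block()] over the tip labels
#' @export
evolve_sequences <- function(gene_tree, seq_length, subst_rate, seed) {
  if (seq_length < 1) stop("seq_length must be >= 1")
  with_substream(seed, "sequences", {
    nt <- ape::Ntip(gene_tree)
    nn <- nt + gene_tree$Nnode
    seqs <- vector("list", nn)
    root <- nt + 1L
    seqs[[root]] <- sample.int(20L, seq_length, replace = TRUE)
    ord <- ape::reorder.phylo(gene_tree, "cladewise")
    for (i in seq_len(nrow(ord$edge))) {
      par <- ord$edge[i, 1]; child <- ord$edge[i, 2]
      t <- ord$edge.length[i]
      p <- (19 / 20) * (1 - exp(-(20 / 19) * subst_rate * t))
      s <- seqs[[par]]
      hit <- runif(seq_length) < p
      if (any(hit)) {
        shift <- sample.int(19L, sum(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1L + shift) %% 20L) + 1L
      }
      seqs[[child]] <- s
    }
    mat <- do.call(rbind, lapply(seq_len(nt), function(i)
      AA_ALPHABET20[seqs[[i]]]))
    rownames(mat) <- gene_tree$tip.label
    alignment_block(mat)
  })
}

#' Evolve a single sequence along one lineage
#'
#' Used for families with a single surviving copy, where no gene tree
#' exists: mutates a fresh root sequence along a path of the given length.
#'
#' @param path_length time from gain to the tip
#' @inheritParams evolve_sequences
#' @param label row id of the resulting one-row alignment
#' @export
evolve_single_sequence <- function(path_length, seq_length, subst_rate,
                                   seed, label = "copy") {
  with_substream(seed, "sequences", {
    s <- sample.int(20L, seq_length, replace = TRUE)
    p <- (19 / 20) * (1 - exp(-(20 / 19) * subst_rate * path_length))
    hit <- runif(seq_length) < p
    if (any(hit)) {
      shift <- sample.int(19L, sum(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 20L) + 1L
    }
    mat <- matrix(AA_ALPHABET20[s], 1, seq_length,
                  dimnames = list(label, NULL))
    alignment_block(mat)
  })
}

#' Random background protein sequences
#'
#' Filler-gene proteomes: i.i.d. uniform residues.
#'
#' @param n number of sequences
#' @param len length of each
#' @param seed integer seed
#' @param prefix id prefix
#' @return named character vector
#' @export
random_proteins <- function(n, len, seed, prefix = "bg") {
  with_substream(seed, "background_seqs", {
    setNames(vapply(seq_len(n), function(i)
      paste(AA_ALPHABET20[sample.int(20L, len, replace = TRUE)],
            collapse = ""), character(1)),
      sprintf("%s%04d", prefix, seq_len(n)))
  })
}
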