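#' Read a protein FASTA file
#'
#' @param path path to a FASTA file
#' @return a named character vector mapping identifier to uppercased
#'   residue sequence, in file order
#' @details Identifiers are the full header lines (after `>`), trimmed.
#'   Duplicate identifiers and empty files are errors: parsing never
#'   silently drops records.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  ids <- trimws(names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of residue sequences
#' @param path output path
#' @param width line width for wrapping
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a newick tree
#'
#' Wraps [ape::read.tree()] with an explicit balanced-parenthesis check so
#' malformed input fails with the offending position rather than an opaque
#' parser state.  Branch lengths absent from the file default to 1.
#'
#' @param path path to a newick file (first tree is used)
#' @return an [ape::phylo] tree; `attr(, "was_rooted")` records rootedness
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  read_newick_text(txt)
}

#' @rdname read_newick
#' @param text newick text
#' @export
read_newick_text <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("newick parse error: unmatched ')' at position ", i)
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of input")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error: unreadable tree")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  attr(tr, "was_rooted") <- ape::is.rooted(tr)
  tr
}

#' Write a tree to newick
#'
#' Support values, when present in `tree$node.label`, are written as
#' internal node labels.
#'
#' @param tree an [ape::phylo] tree
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---- gene tables -----------------------------------------------------------

.gene_table_cols <- c("genome_id", "locus_tag", "ordinal_index", "strand",
                      "clade_path")

#' Read a gene-coordinate table
#'
#' The table is tab-separated with header columns `genome_id`, `locus_tag`,
#' `ordinal_index` (0-based position in the genome's gene order), `strand`
#' (`+`, `-` or `unknown`) and `clade_path` (clade labels from the root,
#' joined by `/`).  Optional columns `taxon_name`, `family_id` and `product`
#' are preserved.  Rows are returned sorted by `(genome_id, ordinal_index)`.
#'
#' @param path path to a TSV file
#' @return a `data.frame` of class `gene_table`
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  as_gene_table(df)
}

#' Validate and normalize a gene table
#'
#' When `ordinal_index` is absent it is derived from the rank of the
#' numeric suffix of the locus tag within each genome (locus tags encode
#' chromosomal order).
#'
#' @param df data.frame with the gene-table columns
#' @return the validated, sorted `gene_table`
#' @export
as_gene_table <- function(df) {
  if (!"ordinal_index" %in% names(df)) {
    suf <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1",
                                           df$locus_tag)))
    if (anyNA(suf))
      stop("cannot derive ordinal_index: locus tag without numeric ",
           "suffix: ", df$locus_tag[which(is.na(suf))[1]])
    df$ordinal_index <- NA_integer_
    for (g in unique(df$genome_id)) {
      sel <- df$genome_id == g
      df$ordinal_index[sel] <- rank(suf[sel], ties.method = "first") - 1L
    }
  }
  miss <- setdiff(.gene_table_cols, names(df))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  idx <- suppressWarnings(as.numeric(df$ordinal_index))
  bad <- is.na(idx) | idx != floor(idx)
  if (any(bad))
    stop("non-integer ordinal_index for locus ",
         paste(df$locus_tag[bad], collapse = ", "))
  df$ordinal_index <- as.integer(idx)
  key <- paste(df$genome_id, df$ordinal_index)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (genome_id, ordinal_index): ", d)
  }
  keyl <- paste(df$genome_id, df$locus_tag)
  if (anyDuplicated(keyl))
    stop("duplicate locus_tag within genome: ", keyl[duplicated(keyl)][1])
  df <- df[order(df$genome_id, df$ordinal_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

#' @rdname read_gene_table
#' @param gene_tab a `gene_table`
#' @export
write_gene_table <- function(gene_tab, path) {
  write.table(gene_tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a gene table into per-genome records
#'
#' @param gene_tab a `gene_table`
#' @return a named list with one element per genome: `genome_id`,
#'   `taxon_name`, `clade_path` (character vector) and `loci` (data.frame
#'   ordered by `ordinal_index`)
#' @export
genome_records <- function(gene_tab) {
  sp <- split(as.data.frame(gene_tab), gene_tab$genome_id)
  lapply(sp, function(g) {
    g <- g[order(g$ordinal_index), , drop = FALSE]
    cp <- strsplit(g$clade_path[1], "/", fixed = TRUE)[[1]]
    if (!length(cp)) stop("empty clade_path for genome ", g$genome_id[1])
    list(genome_id = g$genome_id[1],
         taxon_name = if ("taxon_name" %in% names(g)) g$taxon_name[1]
                      else g$genome_id[1],
         clade_path = cp,
         loci = g)
  })
}

# ---- feature tables --------------------------------------------------------

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- trimws(as.character(x))
  out <- x %in% c("TRUE", "T", "1", "+", "yes")
  out[is.na(x)] <- NA
  out
}

#' Read a per-gene feature table
#'
#' Tab-separated with columns `genome_id`, `locus_tag`, `signal_peptide`,
#' `lipoprotein_signal`, `tm_count`, `interaction_motif` (TPR or
#' coiled-coil), `domain_names` (comma-joined, may be empty) and
#' `length_aa`.  Boolean columns accept `TRUE/FALSE`, `1/0` or `+/-`.
#'
#' @param path path to a TSV file
#' @return a `data.frame` of class `feature_table`
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  as_feature_table(df)
}

#' @rdname read_feature_table
#' @param df data.frame with feature-table columns
#' @export
as_feature_table <- function(df) {
  need <- c("genome_id", "locus_tag", "signal_peptide", "lipoprotein_signal",
            "tm_count", "interaction_motif")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("signal_peptide", "lipoprotein_signal", "interaction_motif"))
    df[[col]] <- .as_flag(df[[col]])
  df$tm_count <- as.integer(df$tm_count)
  if (any(is.na(df$tm_count)) || any(df$tm_count < 0))
    stop("tm_count must be a non-negative integer")
  if (!"domain_names" %in% names(df)) df$domain_names <- ""
  if (!"length_aa" %in% names(df)) df$length_aa <- NA_integer_
  else df$length_aa <- as.integer(df$length_aa)
  if (anyDuplicated(paste(df$genome_id, df$locus_tag)))
    stop("duplicate locus in feature table")
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @rdname read_feature_table
#' @param feat a `feature_table`
#' @export
write_feature_table <- function(feat, path) {
  write.table(feat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- pipeline configuration ------------------------------------------------

#' Default pipeline configuration
#'
#' Free parameters of the inference pipeline, with the package defaults.
#' `merge_rules` is a list of character vectors of locus tags to be fused
#' into one putative gene during cluster extension; `discard` lists locus
#' tags dropped after extension (both mirror curated pseudogene handling).
#'
#' @param ... named overrides of the defaults
#' @return a list of class `pipeline_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    max_gap = 3L,              # intervening loci allowed within a cluster
    sim_score_threshold = 0.3, # normalized local-alignment score cut-off
    max_iters = 5L,            # homologue-expansion rounds
    max_reps = 4L,             # representatives scored per expansion round
    kmer_prefilter = 4L,       # word size for the shared-word prefilter (0 = off)
    min_family_size = 2L,      # families smaller than this are not pursued
    distance_model = "poisson",
    gamma_alpha = 1.0,
    mask_max_missing = 0.5,
    n_bootstrap = 100L,
    support_min = 50,
    rf_congruence_max = 2L,
    min_shared_taxa = 4L,
    focal_clades = character(),
    outgroup_clade = NULL,     # top-level clade used to root gene trees
    random_seed = 1L,
    merge_rules = list(),
    discard = character()
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_config(cfg)
}

#' @rdname default_config
#' @param cfg a configuration list
#' @export
validate_config <- function(cfg) {
  stopifnot(cfg$max_gap >= 0,
            cfg$sim_score_threshold > 0, cfg$sim_score_threshold <= 1,
            cfg$max_iters >= 1,
            cfg$distance_model %in% c("p", "poisson", "gamma"),
            cfg$gamma_alpha > 0,
            cfg$mask_max_missing >= 0, cfg$mask_max_missing <= 1,
            cfg$n_bootstrap >= 1,
            cfg$support_min >= 0,
            cfg$rf_congruence_max >= 0)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Fields map 1:1 to [default_config()]; unspecified fields keep their
#' defaults.
#'
#' @param path path to a YAML file
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_config, y)
}
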