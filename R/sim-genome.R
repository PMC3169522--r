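# Genome assembly with synteny (linked gene modules among background
# loci) and feature annotation for the simulated proteomes.

#' Assemble simulated genomes with optional gene-module linkage
#'
#' For every genome, the copies of the families of one module are grouped
#' into copy-sets (the k-th copy of each family, by copy id — with a shared
#' module history these are the co-duplicated cluster copies).  With
#' probability `p_linkage` per genome each copy-set is placed as a block of
#' consecutive loci among the background genes, emulating an operon;
#' otherwise all copies are scattered uniformly.  Ordinal indices are
#' contiguous from 0 and locus tags encode the gene order
#' (`<genome>_<index+1>`), mirroring locus-tag conventions.
#'
#' @param tip_copies named list (per family) of data.frames with columns
#'   `genome`, `copy_id` (from [evolve_gene_content()])
#' @param modules named list: module id -> character vector of family ids
#' @param clade_paths named character vector genome -> `/`-joined clade path
#' @param p_linkage probability in `[0, 1]` that a genome keeps its module
#'   blocks intact
#' @param n_background background (filler) loci per genome
#' @param seed integer seed
#' @param force_linked genomes whose module blocks are always intact (the
#'   study organism is selected for showing the clustered machinery)
#' @param genomes optional genome universe (defaults to genomes seen in
#'   `tip_copies` plus names of `clade_paths`)
#' @return a `gene_table` with truth columns `family_id` and `copy_id`
#'   (`NA` for background loci)
#' @export
assemble_genomes <- function(tip_copies, modules, clade_paths,
                             p_linkage = 0.9, n_background = 40L,
                             seed = 1L, force_linked = character(),
                             genomes = NULL) {
  stopifnot(p_linkage >= 0, p_linkage <= 1)
  if (is.null(genomes)) genomes <- names(clade_paths)
  fam2mod <- unlist(lapply(names(modules), function(m)
    setNames(rep(m, length(modules[[m]])), modules[[m]])))
  rows <- list()
  with_substream(seed, "assemble_genomes", {
    for (g in genomes) {
      # copies per family present in this genome
      fam_copies <- lapply(tip_copies, function(df)
        sort(df$copy_id[df$genome == g]))
      fam_copies <- fam_copies[vapply(fam_copies, length, 1L) > 0]
      units <- list()   # each unit: data.frame(family_id, copy_id)
      linked <- (g %in% force_linked) || (runif(1) < p_linkage)
      for (m in names(modules)) {
        fams <- intersect(modules[[m]], names(fam_copies))
        if (!length(fams)) next
        nset <- max(vapply(fam_copies[fams], length, 1L))
        for (k in seq_len(nset)) {
          have <- fams[vapply(fam_copies[fams], length, 1L) >= k]
          blk <- data.frame(
            family_id = have,
            copy_id = vapply(have, function(f) fam_copies[[f]][k], ""),
            stringsAsFactors = FALSE)
          if (linked) units[[length(units) + 1L]] <- blk
          else for (r in seq_len(nrow(blk)))
            units[[length(units) + 1L]] <- blk[r, , drop = FALSE]
        }
        fam_copies <- fam_copies[setdiff(names(fam_copies), fams)]
      }
      # families outside any module are always placed individually
      for (f in names(fam_copies)) for (cid in fam_copies[[f]])
        units[[length(units) + 1L]] <- data.frame(
          family_id = f, copy_id = cid, stringsAsFactors = FALSE)
      filler <- replicate(n_background,
        data.frame(family_id = NA_character_, copy_id = NA_character_,
                   stringsAsFactors = FALSE), simplify = FALSE)
      all_units <- c(units, filler)
      ord <- sample.int(length(all_units))
      loci <- do.call(rbind, all_units[ord])
      n <- nrow(loci)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      rows[[g]] <- data.frame(
        genome_id = g,
        locus_tag = sprintf("%s_%04d", g, seq_len(n)),
        ordinal_index = seq_len(n) - 1L,
        strand = strand,
        clade_path = unname(clade_paths[g]),
        family_id = loci$family_id,
        copy_id = loci$copy_id,
        stringsAsFactors = FALSE)
    }
  })
  as_gene_table(do.call(rbind, rows))
}

#' Default feature templates for simulated machinery families
#'
#' Envelope-flavoured templates in the style of the Glt/Agl components: a
#' mix of exported TPR proteins, bitopic membrane proteins and lipoproteins.
#' Recycled in order when more families than templates are requested.
#'
#' @param families character vector of family ids
#' @return named list of per-family templates
#' @export
default_feature_templates <- function(families) {
  pool <- list(
    list(signal_peptide = TRUE,  lipoprotein_signal = FALSE, tm_count = 0L,
         interaction_motif = TRUE,  domain_names = "TPR"),
    list(signal_peptide = FALSE, lipoprotein_signal = FALSE, tm_count = 1L,
         interaction_motif = FALSE, domain_names = "FHA;TonB"),
    list(signal_peptide = TRUE,  lipoprotein_signal = FALSE, tm_count = 0L,
         interaction_motif = FALSE, domain_names = ""),
    list(signal_peptide = FALSE, lipoprotein_signal = TRUE,  tm_count = 0L,
         interaction_motif = FALSE, domain_names = ""),
    list(signal_peptide = FALSE, lipoprotein_signal = FALSE, tm_count = 3L,
         interaction_motif = FALSE, domain_names = "MotA_ExbB"),
    list(signal_peptide = TRUE,  lipoprotein_signal = FALSE, tm_count = 1L,
         interaction_motif = FALSE, domain_names = "Autotransporter"))
  setNames(lapply(seq_along(families), function(i)
    pool[[(i - 1L) %% length(pool) + 1L]]), families)
}

#' Annotate simulated loci with envelope/interaction features
#'
#' Family loci copy their family's template, each boolean flipping
#' independently with probability `flip_noise`; `tm_count` moves by one
#' with the same probability (never below 0).  Background loci draw from
#' the stated background frequencies.
#'
#' @param gene_tab `gene_table` with a `family_id` column
#' @param templates named list per family (see
#'   [default_feature_templates()])
#' @param flip_noise flip probability in `[0, 0.5)`
#' @param background list with `p_signal`, `p_lipo`, `p_tm`,
#'   `p_interaction` (background feature frequencies)
#' @param seq_lengths named vector family -> protein length; background
#'   loci get `filler_len`
#' @param filler_len background protein length
#' @param seed integer seed
#' @return a `feature_table` covering every locus
#' @export
annotate_features <- function(gene_tab, templates, flip_noise = 0.05,
                              background = list(p_signal = 0.12,
                                                p_lipo = 0.03,
                                                p_tm = 0.25,
                                                p_interaction = 0.06),
                              seq_lengths = NULL, filler_len = 60L,
                              seed = 1L) {
  if (flip_noise < 0 || flip_noise >= 0.5)
    stop("flip_noise must be in [0, 0.5)")
  n <- nrow(gene_tab)
  with_substream(seed, "features", {
    sp <- lp <- im <- logical(n)
    tm <- integer(n)
    dom <- character(n)
    len <- integer(n)
    flip <- function(x) xor(x, runif(length(x)) < flip_noise)
    isfam <- !is.na(gene_tab$family_id)
    # background loci
    nb <- sum(!isfam)
    sp[!isfam] <- runif(nb) < background$p_signal
    lp[!isfam] <- runif(nb) < background$p_lipo
    tm[!isfam] <- ifelse(runif(nb) < background$p_tm,
                         1L + stats::rpois(nb, 0.7), 0L)
    im[!isfam] <- runif(nb) < background$p_interaction
    len[!isfam] <- filler_len
    # family loci
    for (f in unique(gene_tab$family_id[isfam])) {
      sel <- which(isfam & gene_tab$family_id == f)
      tp <- templates[[f]]
      if (is.null(tp)) stop("no feature template for family ", f)
      m <- length(sel)
      sp[sel] <- flip(rep(tp$signal_peptide, m))
      lp[sel] <- flip(rep(tp$lipoprotein_signal, m))
      im[sel] <- flip(rep(tp$interaction_motif, m))
      dtm <- ifelse(runif(m) < flip_noise, sample(c(-1L, 1L), m, TRUE), 0L)
      tm[sel] <- pmax(0L, tp$tm_count + dtm)
      dom[sel] <- tp$domain_names %||% ""
      len[sel] <- if (!is.null(seq_lengths)) seq_lengths[[f]] else filler_len
    }
    as_feature_table(data.frame(
      genome_id = gene_tab$genome_id, locus_tag = gene_tab$locus_tag,
      signal_peptide = sp, lipoprotein_signal = lp, tm_count = tm,
      interaction_motif = im, domain_names = dom, length_aa = len,
      stringsAsFactors = FALSE))
  })
}
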