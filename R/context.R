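# Gene-neighborhood scanning: windows around anchor genes, detection of
# compact Se gene islands (operon-like clusters of known Se families), and
# nomination of candidate families that recur inside island neighborhoods
# across phylogenetically distant genomes.
#
# Adjacency is ordinal: a window of radius r around an anchor holds the genes
# whose rank is within r of the anchor's rank on the same replicon, truncated
# at replicon ends (replicons are treated as linear). Strand is recorded but
# does not affect membership.

#' Gene window around an anchor
#'
#' @param comp a `compendium`.
#' @param anchor_gene_id gene id of the anchor.
#' @param radius window half-width in genes (default 10, i.e. ten genes
#'   upstream and downstream).
#' @return data.frame of member genes with a signed `offset` column
#'   (0 = anchor), ordered by offset.
#' @export
gene_window <- function(comp, anchor_gene_id, radius = 10L) {
  if (!is.numeric(radius) || radius < 1L) stop("radius must be >= 1")
  idx <- match(anchor_gene_id, comp$genes$gene_id)
  if (is.na(idx)) stop("anchor gene not found: ", anchor_gene_id)
  anchor <- comp$genes[idx, ]
  members <- comp$genes[comp$genes$genome_id == anchor$genome_id &
                          comp$genes$replicon_id == anchor$replicon_id &
                          abs(comp$genes$rank - anchor$rank) <= radius, ,
                        drop = FALSE]
  members$offset <- members$rank - anchor$rank
  members <- members[order(members$offset), , drop = FALSE]
  rownames(members) <- NULL
  members
}

#' Detect Se gene islands
#'
#' An island is a maximal run of genes carrying known Se families in which
#' consecutive Se genes are separated by at most `max_gap` non-Se genes.
#' Islands are built deterministically left to right per replicon, never
#' overlap, and begin and end on an Se gene.
#'
#' @param comp a `compendium`.
#' @param known_families character vector of known Se family ids.
#' @param max_gap maximal number of interleaved non-Se genes (default 3).
#' @param genome_ids optional subset of genomes to scan.
#' @return data.frame with one row per island: `genome_id`, `replicon_id`,
#'   `start_rank`, `end_rank`, `start_bp`, `end_bp`, `n_se_genes`,
#'   `families` (`;`-joined known families contained).
#' @export
find_islands <- function(comp, known_families, max_gap = 3L,
                         genome_ids = NULL) {
  if (!is.numeric(max_gap) || max_gap < 0L) stop("max_gap must be >= 0")
  genes <- comp$genes
  if (!is.null(genome_ids)) {
    genes <- genes[genes$genome_id %in% genome_ids, , drop = FALSE]
  }
  fam_list <- split_families(genes$families)
  is_se <- vapply(fam_list, function(f) any(f %in% known_families), logical(1))
  se <- genes[is_se, , drop = FALSE]
  se_fams <- fam_list[is_se]
  if (nrow(se) == 0L) {
    return(data.frame(genome_id = character(0), replicon_id = character(0),
                      start_rank = integer(0), end_rank = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_se_genes = integer(0), families = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(se$genome_id, se$replicon_id, sep = "\r")
  rows <- list()
  for (k in split(seq_len(nrow(se)), key)) {
    k <- k[order(se$rank[k])]
    ranks <- se$rank[k]
    breaks <- c(0L, which(diff(ranks) - 1L > max_gap), length(ranks))
    for (j in seq_len(length(breaks) - 1L)) {
      run <- k[(breaks[j] + 1L):breaks[j + 1L]]
      fams <- sort(unique(unlist(se_fams[run])))
      fams <- fams[fams %in% known_families]
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = se$genome_id[run[1L]],
        replicon_id = se$replicon_id[run[1L]],
        start_rank = se$rank[run[1L]],
        end_rank = se$rank[run[length(run)]],
        start_bp = se$start[run[1L]],
        end_bp = se$end[run[length(run)]],
        n_se_genes = length(run),
        families = paste(fams, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$genome_id, out$replicon_id, out$start_rank), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write islands as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `chromStart = start_bp - 1`, `chromEnd = end_bp`.
#'
#' @param islands output of [find_islands()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  bed <- data.frame(chrom = islands$replicon_id,
                    chromStart = islands$start_bp - 1L,
                    chromEnd = islands$end_bp,
                    name = paste0(islands$genome_id, "_island_",
                                  seq_len(nrow(islands))),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Nominate candidate Se-related families from genomic context
#'
#' Around every Se island, a window of `radius` genes is taken on each side
#' of the island span and unioned per genome. Every non-excluded family seen
#' inside such a neighborhood is scored by the number of distinct genomes in
#' which it is linked (per-genome counting: paralogs count once). Families
#' linked in at least `min_recurrence` genomes — spanning at least
#' `min_phyla` phyla when lineage information exists — are retained, their
#' presence/absence co-occurrence with the anchor family (SelD by default) is
#' tested with a 2x2 chi-square over all genomes, and the list is ranked by
#' linkage count, then chi-square statistic, then family id.
#'
#' @param comp a `compendium`.
#' @param known_families known Se families that define islands.
#' @param radius neighborhood half-width in genes (default 10).
#' @param max_gap island gap tolerance (default 3).
#' @param min_recurrence minimal number of distinct linked genomes
#'   (default 3).
#' @param exclusions families never nominated (default: `known_families`).
#' @param min_phyla minimal number of distinct phyla among linked genomes,
#'   applied only when lineages are populated (default 2).
#' @param anchor_family family whose presence anchors the co-occurrence test
#'   (default `"SelD"`).
#' @param presence optional precomputed presence matrix (must contain the
#'   anchor family and all nominated families as columns).
#' @param yates use the Yates-corrected chi-square statistic (default TRUE).
#' @return data.frame of class `candidate_scores`, ranked: `rank`,
#'   `family_id`, `n_linked_genomes`, `n_phyla`, `chi2`, `p_value`,
#'   `direction`, `genomes`, `offsets`.
#' @export
nominate_candidates <- function(comp, known_families, radius = 10L,
                                max_gap = 3L, min_recurrence = 3L,
                                exclusions = known_families, min_phyla = 2L,
                                anchor_family = "SelD", presence = NULL,
                                yates = TRUE) {
  if (min_recurrence < 2L) stop("min_recurrence must be >= 2")
  empty <- data.frame(rank = integer(0), family_id = character(0),
                      n_linked_genomes = integer(0), n_phyla = integer(0),
                      chi2 = numeric(0), p_value = numeric(0),
                      direction = integer(0), genomes = character(0),
                      offsets = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("candidate_scores", "data.frame")
  islands <- find_islands(comp, known_families, max_gap = max_gap)
  if (nrow(islands) == 0L) {
    warning("no Se islands found; nothing to nominate")
    return(empty)
  }
  genes <- comp$genes
  fam_list <- split_families(genes$families)
  # linked occurrences: family, genome, signed offset from the island span
  occ <- list()
  key_genes <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  for (i in seq_len(nrow(islands))) {
    isl <- islands[i, ]
    sel <- key_genes == paste(isl$genome_id, isl$replicon_id, sep = "\r") &
      genes$rank >= isl$start_rank - radius &
      genes$rank <= isl$end_rank + radius
    idx <- which(sel)
    if (length(idx) == 0L) next
    off <- ifelse(genes$rank[idx] < isl$start_rank,
                  genes$rank[idx] - isl$start_rank,
                  ifelse(genes$rank[idx] > isl$end_rank,
                         genes$rank[idx] - isl$end_rank, 0L))
    for (j in seq_along(idx)) {
      fams <- setdiff(fam_list[[idx[j]]], exclusions)
      for (f in fams) {
        occ[[length(occ) + 1L]] <- data.frame(
          family_id = f, genome_id = isl$genome_id, offset = off[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(occ) == 0L) return(empty)
  occ <- do.call(rbind, occ)
  # per-genome: keep the occurrence closest to the island (|offset| minimal)
  occ <- occ[order(occ$family_id, occ$genome_id, abs(occ$offset)), ,
             drop = FALSE]
  occ <- occ[!duplicated(paste(occ$family_id, occ$genome_id, sep = "\r")), ,
             drop = FALSE]

  lineages_known <- any(comp$genomes$lineage != "")
  phylum <- vapply(strsplit(comp$genomes$lineage, ";", fixed = TRUE),
                   function(l) if (length(l) == 0L) "" else l[1L], character(1))
  names(phylum) <- comp$genomes$genome_id

  if (is.null(presence)) {
    presence <- build_presence_matrix(comp)
  }
  if (!anchor_family %in% colnames(presence)) {
    stop("anchor family not in presence matrix: ", anchor_family)
  }
  anchor_vec <- presence[, anchor_family]

  rows <- list()
  for (f in unique(occ$family_id)) {
    sub <- occ[occ$family_id == f, , drop = FALSE]
    n_linked <- nrow(sub)
    if (n_linked < min_recurrence) next
    ph <- unique(phylum[sub$genome_id])
    ph <- ph[ph != ""]
    if (lineages_known && length(ph) < min_phyla) next
    if (!f %in% colnames(presence)) next
    ct <- cooccurrence_test(presence[, f], anchor_vec, yates = yates)
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = f, n_linked_genomes = n_linked,
      n_phyla = length(ph),
      chi2 = ct$test$statistic, p_value = ct$test$p.value,
      direction = ct$test$direction,
      genomes = paste(sub$genome_id, collapse = ";"),
      offsets = paste(sub$offset, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_linked_genomes, -out$chi2, out$family_id), ,
             drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("candidate_scores", "data.frame")
  out
}
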