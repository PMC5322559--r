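# Rule-based classification of genomes into Se-utilization traits, orphan
# SelD flagging, Venn-region overlap counts, taxon and habitat summaries.
#
# A trait is a pure AND over required families. The three defaults are the
# known SelD-dependent traits: selenocysteine decoding (SelA+SelB+SelD),
# selenouridine (SelD+YbbB), and the putative Se-containing cofactor pathway
# (SelD+YqeB+YqeC). SelD, the selenophosphate synthetase shared by all
# three, is the universal signature of Se utilization.

#' Trait definitions
#'
#' Each trait is defined by the set of families that must ALL be present.
#' User-defined traits may be added or substituted; definitions must be
#' non-empty.
#'
#' @param ... named character vectors of required families. Defaults to the
#'   three known SelD-dependent traits.
#' @return named list of class `trait_definitions`.
#' @export
trait_definitions <- function(...) {
  defs <- list(...)
  if (length(defs) == 0L) {
    defs <- list(Sec = c("SelA", "SelB", "SelD"),
                 SeU = c("SelD", "YbbB"),
                 SeCofactor = c("SelD", "YqeB", "YqeC"))
  }
  if (is.null(names(defs)) || any(names(defs) == "")) {
    stop("every trait definition must be named")
  }
  if (any(lengths(defs) == 0L)) stop("trait definitions must be non-empty")
  defs <- lapply(defs, as.character)
  structure(defs, class = "trait_definitions")
}

# Families shared by every definition (the universal signature, SelD under
# the defaults) and the trait-specific remainder, derived from the
# definitions rather than hard-coded so user-defined traits extend them.
trait_signature <- function(defs) Reduce(intersect, defs)
trait_specific <- function(defs) setdiff(unique(unlist(defs)), trait_signature(defs))

#' Classify genomes into Se utilization traits
#'
#' A trait is assigned iff all of its required families are present; traits
#' are evaluated independently, so a genome may carry several. A genome is an
#' orphan-SelD genome when it has the universal signature (SelD) but none of
#' the trait-specific families, i.e. it encodes the Se donor pathway without
#' any known downstream user.
#'
#' @param matrix presence matrix from [build_presence_matrix()].
#' @param defs a [trait_definitions()] object.
#' @return data.frame of class `trait_profile`: `genome_id`, one logical
#'   column per trait, `n_traits`, `selD_present`, `orphan_selD`. The
#'   definitions are attached as `attr(, "definitions")`.
#' @export
classify_traits <- function(matrix, defs = trait_definitions()) {
  needed <- unique(unlist(defs))
  missing_fams <- setdiff(needed, colnames(matrix))
  if (length(missing_fams) > 0L) {
    stop("presence matrix lacks required family column(s): ",
         paste(missing_fams, collapse = ", "))
  }
  prof <- data.frame(genome_id = rownames(matrix), stringsAsFactors = FALSE)
  for (tr in names(defs)) {
    fams <- defs[[tr]]
    prof[[tr]] <- rowSums(matrix[, fams, drop = FALSE]) == length(fams)
  }
  sig <- trait_signature(defs)
  spec_fams <- trait_specific(defs)
  prof$n_traits <- rowSums(prof[, names(defs), drop = FALSE])
  prof$selD_present <- if (length(sig) > 0L) {
    rowSums(matrix[, sig, drop = FALSE]) == length(sig)
  } else {
    rep(NA, nrow(prof))
  }
  prof$orphan_selD <- prof$selD_present &
    rowSums(matrix[, spec_fams, drop = FALSE]) == 0L
  attr(prof, "definitions") <- defs
  class(prof) <- c("trait_profile", "data.frame")
  prof
}

#' Genomes with orphan SelD
#'
#' Orphan SelD genomes contain SelD but lack every trait-specific family of
#' the known Se utilization traits.
#'
#' @inheritParams classify_traits
#' @return character vector of genome ids.
#' @export
flag_orphan_selD <- function(matrix, defs = trait_definitions()) {
  prof <- classify_traits(matrix, defs)
  prof$genome_id[prof$orphan_selD]
}

#' Venn-region counts over the assigned traits
#'
#' Partitions trait-positive genomes into mutually exclusive regions (one per
#' non-empty trait combination; 7 regions for the three default traits) and
#' counts orphan-SelD genomes separately.
#'
#' @param profile a `trait_profile`.
#' @return list of class `venn_summary` with `regions` (named counts, names
#'   are `&`-joined trait combinations), `orphan_selD`, `n_trait_positive`
#'   and `n_genomes`.
#' @export
venn_counts <- function(profile) {
  defs <- attr(profile, "definitions")
  traits <- names(defs)
  combos <- unlist(lapply(seq_along(traits), function(k) {
    apply(utils::combn(traits, k), 2L, paste, collapse = "&")
  }))
  regions <- stats::setNames(integer(length(combos)), combos)
  tm <- as.matrix(profile[, traits, drop = FALSE])
  pos <- rowSums(tm) > 0L
  if (any(pos)) {
    labels <- apply(tm[pos, , drop = FALSE], 1L, function(r) {
      paste(traits[as.logical(r)], collapse = "&")
    })
    tab <- table(labels)
    regions[names(tab)] <- as.integer(tab)
  }
  stopifnot(sum(regions) == sum(pos))
  structure(list(regions = regions,
                 orphan_selD = sum(profile$orphan_selD),
                 n_trait_positive = sum(pos),
                 n_genomes = nrow(profile)),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("<venn_summary> %d/%d genomes trait-positive, %d orphan SelD\n",
              x$n_trait_positive, x$n_genomes, x$orphan_selD))
  print(x$regions)
  invisible(x)
}

#' Per-taxon occurrence of SelD and the Se utilization traits
#'
#' Tallies, per taxon at the requested lineage depth, the number of genomes,
#' SelD-containing genomes, genomes per trait, and orphan-SelD genomes.
#' Genomes whose lineage is shorter than `level` are grouped under their
#' deepest available taxon and flagged in `level_truncated`.
#'
#' @param profile a `trait_profile`.
#' @param comp the `compendium` the profile was computed from.
#' @param level 1-based lineage depth (1 = phylum).
#' @param min_genomes taxa with fewer genomes are dropped from the table
#'   (e.g. `min_genomes = 2` removes single-genome phyla).
#' @return data.frame with one row per taxon, sorted by descending genome
#'   count.
#' @export
taxon_distribution <- function(profile, comp, level = 1L, min_genomes = 1L) {
  defs <- attr(profile, "definitions")
  g <- comp$genomes[match(profile$genome_id, comp$genomes$genome_id), ,
                    drop = FALSE]
  lin <- strsplit(g$lineage, ";", fixed = TRUE)
  taxon <- vapply(lin, function(l) {
    if (length(l) == 0L || all(l == "")) return("unclassified")
    l[min(level, length(l))]
  }, character(1))
  truncated <- vapply(lin, function(l) length(l) < level && length(l) > 0L &&
                        !all(l == ""), logical(1))
  out <- do.call(rbind, lapply(split(seq_along(taxon), taxon), function(idx) {
    row <- data.frame(taxon = taxon[idx[1L]], n_genomes = length(idx),
                      n_selD = sum(profile$selD_present[idx]),
                      stringsAsFactors = FALSE)
    for (tr in names(defs)) {
      row[[paste0("n_", tr)]] <- sum(profile[[tr]][idx])
    }
    row$n_orphan_selD <- sum(profile$orphan_selD[idx])
    row$n_any_trait <- sum(profile$n_traits[idx] > 0L)
    row$level_truncated <- any(truncated[idx])
    row
  }))
  out <- out[out$n_genomes >= min_genomes, , drop = FALSE]
  out <- out[order(-out$n_genomes, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Habitat summary: fraction of Se-utilizing genomes per habitat class
#'
#' Reports, for the aquatic and nonaquatic classes, how many genomes carry at
#' least one Se utilization trait. Genomes of unknown habitat are excluded
#' from all denominators; a habitat class with no genomes is absent from the
#' table rather than reported as 0%.
#'
#' @param profile a `trait_profile`.
#' @param comp the matching `compendium`.
#' @return data.frame with columns `habitat`, `n_genomes`, `n_with_trait`,
#'   `percent`.
#' @export
habitat_summary <- function(profile, comp) {
  g <- comp$genomes[match(profile$genome_id, comp$genomes$genome_id), ,
                    drop = FALSE]
  known <- g$habitat %in% c("aquatic", "nonaquatic")
  if (!any(known)) stop("all genomes have unknown habitat")
  out <- do.call(rbind, lapply(split(which(known), g$habitat[known]),
    function(idx) {
      data.frame(habitat = g$habitat[idx[1L]], n_genomes = length(idx),
                 n_with_trait = sum(profile$n_traits[idx] > 0L),
                 stringsAsFactors = FALSE)
    }))
  out$percent <- 100 * out$n_with_trait / out$n_genomes
  rownames(out) <- NULL
  out
}

#' Partial-machinery diagnostic
#'
#' Lists genomes carrying a strict, non-empty subset of a trait's required
#' families (e.g. SelA+SelD without SelB). Such genomes are never counted as
#' trait-positive; this table exists for quality control and biological
#' follow-up.
#'
#' @inheritParams classify_traits
#' @return data.frame with `genome_id`, `trait`, `present`, `missing`.
#' @export
partial_traits <- function(matrix, defs = trait_definitions()) {
  rows <- list()
  for (tr in names(defs)) {
    fams <- defs[[tr]]
    sub <- matrix[, fams, drop = FALSE]
    n_present <- rowSums(sub)
    partial <- which(n_present > 0L & n_present < length(fams))
    for (i in partial) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = rownames(matrix)[i], trait = tr,
        present = paste(fams[sub[i, ]], collapse = ";"),
        missing = paste(fams[!sub[i, ]], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(genome_id = character(0), trait = character(0),
                      present = character(0), missing = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
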