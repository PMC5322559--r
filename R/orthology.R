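# Homology-hit filtering, best hits, bidirectional-best-hit (BBH) orthology
# and family assignment combining BBH with conserved-domain evidence.
#
# A hit table is a data.frame with columns
#   query_id, genome_id, subject_gene_id, evalue, bitscore
# In the forward direction query_id is a reference protein searched against a
# genome; in the reverse direction query_id is a genome gene searched back
# against the reference proteome (subject_gene_id then holds the reference
# protein id). Both directions share one schema so the same operations apply.

validate_hits <- function(hits) {
  req <- c("query_id", "genome_id", "subject_gene_id", "evalue", "bitscore")
  missing_cols <- setdiff(req, names(hits))
  if (length(missing_cols) > 0L) {
    stop("hit table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  hits <- as.data.frame(hits)
  hits$query_id <- as.character(hits$query_id)
  hits$genome_id <- as.character(hits$genome_id)
  hits$subject_gene_id <- as.character(hits$subject_gene_id)
  hits$evalue <- as.numeric(hits$evalue)
  hits$bitscore <- as.numeric(hits$bitscore)
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0)) {
    stop("evalue must be numeric and >= 0")
  }
  if (any(!is.finite(hits$bitscore)) || any(hits$bitscore < 0)) {
    stop("bitscore must be finite and >= 0")
  }
  hits
}

#' Filter homology hits by E-value
#'
#' Retains hits with `evalue <= evalue_max`; the boundary is inclusive
#' (a hit exactly at the cutoff is kept). Input row order is preserved.
#'
#' @param hits hit table (`query_id`, `genome_id`, `subject_gene_id`,
#'   `evalue`, `bitscore`).
#' @param evalue_max positive E-value cutoff; default 0.1.
#' @return the retained rows, in input order.
#' @export
filter_hits <- function(hits, evalue_max = 0.1) {
  if (!is.numeric(evalue_max) || length(evalue_max) != 1L ||
      is.na(evalue_max) || evalue_max <= 0) {
    stop("evalue_max must be a single positive number")
  }
  hits <- validate_hits(hits)
  hits[hits$evalue <= evalue_max, , drop = FALSE]
}

#' Best hit for one query within one genome
#'
#' Minimal E-value wins; ties are broken by maximal bitscore, then by
#' lexicographically smallest `subject_gene_id`, so the result is
#' deterministic and independent of row order.
#'
#' @param hits hit table whose rows all share one `query_id` and one
#'   `genome_id`.
#' @return the winning `subject_gene_id`, or `NA_character_` on empty input.
#' @export
best_hit <- function(hits) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0L) return(NA_character_)
  if (length(unique(hits$genome_id)) > 1L) {
    stop("best_hit: hits span multiple genomes")
  }
  if (length(unique(hits$query_id)) > 1L) {
    stop("best_hit: hits span multiple queries")
  }
  ord <- order(hits$evalue, -hits$bitscore, hits$subject_gene_id,
               method = "radix")
  hits$subject_gene_id[ord[1L]]
}

# Best subject per (query, genome) group for a whole table, vectorised.
# Returns a data.frame(query_id, genome_id, subject_gene_id).
best_hits_by_group <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(0), genome_id = character(0),
                      subject_gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(hits$query_id, hits$genome_id, hits$evalue, -hits$bitscore,
               hits$subject_gene_id, method = "radix")
  h <- hits[ord, , drop = FALSE]
  key <- paste(h$query_id, h$genome_id, sep = "\r")
  first <- !duplicated(key)
  data.frame(query_id = h$query_id[first], genome_id = h$genome_id[first],
             subject_gene_id = h$subject_gene_id[first],
             stringsAsFactors = FALSE)
}

#' Bidirectional best hits
#'
#' A pair (query q, gene g in genome G) is an ortholog pair iff g is the best
#' hit of q within G (forward table) and q is the best hit of g against the
#' reference proteome (reverse table). Output is sorted by query then genome
#' and is independent of input row order.
#'
#' @param forward hit table of reference proteins vs genomes.
#' @param reverse hit table of genome genes vs the reference proteome
#'   (`query_id` = gene id, `subject_gene_id` = reference protein id,
#'   `genome_id` = the gene's genome). Both tables are expected to be
#'   pre-filtered with [filter_hits()].
#' @return data.frame with columns `query_id`, `genome_id`,
#'   `subject_gene_id`, `evidence` (`"bbh"`).
#' @export
bbh_orthologs <- function(forward, reverse) {
  forward <- validate_hits(forward)
  reverse <- validate_hits(reverse)
  fb <- best_hits_by_group(forward)
  rb <- best_hits_by_group(reverse)
  # reciprocal check: reverse best of (gene = fb$subject, genome) must be query
  key_f <- paste(fb$subject_gene_id, fb$genome_id, sep = "\r")
  key_r <- paste(rb$query_id, rb$genome_id, sep = "\r")
  back <- rb$subject_gene_id[match(key_f, key_r)]
  keep <- !is.na(back) & back == fb$query_id
  out <- fb[keep, , drop = FALSE]
  out <- out[order(out$query_id, out$genome_id, method = "radix"), ,
             drop = FALSE]
  out$evidence <- rep("bbh", nrow(out))
  rownames(out) <- NULL
  out
}

#' Assign families to genes from BBH pairs plus domain evidence
#'
#' Each ortholog pair proposes the query protein's family for the hit gene.
#' When the gene carries conserved-domain annotations, agreement upgrades the
#' evidence to `"bbh+domain"`; if `require_domain` is set, an annotated gene
#' lacking the expected domain is not assigned (genes without any annotation
#' are assigned on BBH evidence alone either way). A second gene acquiring a
#' marker family already present in the same genome triggers a paralog
#' warning but both assignments are kept.
#'
#' @param comp a `compendium`.
#' @param pairs output of [bbh_orthologs()].
#' @param query_families named character vector, query protein id -> family id.
#' @param domain_annotations optional data.frame (`gene_id`, `family_id`) of
#'   conserved-domain calls.
#' @param require_domain if `TRUE`, annotated genes must carry the expected
#'   domain to be assigned.
#' @return list with `compendium` (families merged onto genes) and
#'   `assignments` (per-pair decision table with evidence).
#' @export
assign_families <- function(comp, pairs, query_families,
                            domain_annotations = NULL,
                            require_domain = FALSE) {
  if (nrow(pairs) > 0L && !all(pairs$subject_gene_id %in% comp$genes$gene_id)) {
    bad <- setdiff(pairs$subject_gene_id, comp$genes$gene_id)
    stop("ortholog pairs reference unknown gene(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  unknown_q <- setdiff(pairs$query_id, names(query_families))
  if (length(unknown_q) > 0L) {
    stop("no family mapping for query protein(s): ",
         paste(unknown_q, collapse = ", "))
  }
  ann <- NULL
  if (!is.null(domain_annotations)) {
    ann <- as.data.frame(domain_annotations)
    ann$gene_id <- as.character(ann$gene_id)
    ann$family_id <- as.character(ann$family_id)
  }
  assignments <- data.frame(
    query_id = pairs$query_id, genome_id = pairs$genome_id,
    gene_id = pairs$subject_gene_id,
    family_id = unname(query_families[pairs$query_id]),
    evidence = NA_character_, assigned = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(assignments))) {
    fam <- assignments$family_id[i]
    gene <- assignments$gene_id[i]
    gene_ann <- if (is.null(ann)) character(0) else ann$family_id[ann$gene_id == gene]
    if (length(gene_ann) == 0L) {
      assignments$evidence[i] <- "bbh"
      assignments$assigned[i] <- TRUE
    } else if (fam %in% gene_ann) {
      assignments$evidence[i] <- "bbh+domain"
      assignments$assigned[i] <- TRUE
    } else if (require_domain) {
      assignments$evidence[i] <- "domain-mismatch"
      assignments$assigned[i] <- FALSE
    } else {
      assignments$evidence[i] <- "bbh"
      assignments$assigned[i] <- TRUE
    }
  }
  genes <- comp$genes
  fam_list <- split_families(genes$families)
  marker_roles <- if (!is.null(comp$family_catalog)) {
    comp$family_catalog$family_id[comp$family_catalog$role == "known-Se-marker"]
  } else {
    unique(unname(query_families))
  }
  acc <- assignments[assignments$assigned, , drop = FALSE]
  for (i in seq_len(nrow(acc))) {
    fam <- acc$family_id[i]
    genome <- acc$genome_id[i]
    idx <- match(acc$gene_id[i], genes$gene_id)
    in_genome <- genes$genome_id == genome & genes$gene_id != acc$gene_id[i]
    if (fam %in% marker_roles &&
        any(vapply(fam_list[in_genome], function(f) fam %in% f, logical(1)))) {
      warning("family ", fam, " already assigned in genome ", genome,
              "; keeping both copies (paralogs)")
    }
    fam_list[[idx]] <- union(fam_list[[idx]], fam)
  }
  genes$families <- join_families(fam_list)
  list(compendium = compendium(genes, comp$genomes, comp$family_catalog),
       assignments = assignments)
}

#' Read / write homology hit tables as TSV
#'
#' The TSV columns are `query_id`, `genome_id`, `subject_gene_id`, `evalue`,
#' `bitscore`. BLAST tabular output (`-outfmt 6`) can be imported by giving
#' `col_map` the positions of these five fields in the BLAST columns
#' (defaults: qseqid=1, sseqid=2, evalue=11, bitscore=12, with `genome_id`
#' supplied as a constant).
#'
#' @param path file path.
#' @param blast if `TRUE`, parse 12-column BLAST outfmt-6 input.
#' @param genome_id constant genome id for BLAST input.
#' @param col_map named integer vector mapping fields to column positions for
#'   BLAST input.
#' @return a validated hit table.
#' @export
read_hit_table <- function(path, blast = FALSE, genome_id = NULL,
                           col_map = c(query_id = 1L, subject_gene_id = 2L,
                                       evalue = 11L, bitscore = 12L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (blast) {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (is.null(genome_id)) stop("genome_id required for BLAST tabular input")
    hits <- data.frame(query_id = raw[[col_map[["query_id"]]]],
                       genome_id = genome_id,
                       subject_gene_id = raw[[col_map[["subject_gene_id"]]]],
                       evalue = raw[[col_map[["evalue"]]]],
                       bitscore = raw[[col_map[["bitscore"]]]],
                       stringsAsFactors = FALSE)
  } else {
    hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  validate_hits(hits)
}

#' @rdname read_hit_table
#' @param hits hit table to write.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(validate_hits(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
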