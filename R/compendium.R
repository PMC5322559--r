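# Genome compendium: gene tables, metadata, presence/absence matrix.
#
# Internal layout of a `compendium`:
#   $genes          data.frame: genome_id, replicon_id, gene_id, start, end,
#                   strand, families (";"-joined, "" = none), rank (0-based
#                   along the replicon by ascending start)
#   $genomes        data.frame: genome_id, species, domain, lineage
#                   (";"-joined, phylum first), habitat
#   $family_catalog data.frame: family_id, description, role

HABITATS <- c("aquatic", "nonaquatic", "unknown")

#' Split and join semicolon-delimited family sets
#'
#' Gene family annotations are stored as a single `;`-joined character column;
#' these helpers convert to and from lists of family-id vectors.
#'
#' @param x character vector of `;`-joined family ids (`""` = no family).
#' @return `split_families()`: a list of character vectors;
#'   `join_families()`: a character vector.
#' @export
split_families <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

#' @rdname split_families
#' @param fams list of character vectors of family ids.
#' @export
join_families <- function(fams) {
  vapply(fams, function(f) paste(f, collapse = ";"), character(1))
}

#' Construct a genome compendium
#'
#' Validates gene coordinates (1-based inclusive, GFF convention), checks
#' identifier uniqueness, and computes the 0-based `rank` of every gene along
#' its replicon (ascending start; ties broken by end, then `gene_id`). Ranks,
#' not base-pair distances, drive all downstream neighborhood analysis.
#'
#' @param genes data.frame with columns `genome_id`, `replicon_id`, `gene_id`,
#'   `start`, `end`, `strand` (`+`/`-`) and `families` (`;`-joined family ids,
#'   `""` or `NA` for none).
#' @param genomes optional data.frame of per-genome metadata with columns
#'   `genome_id`, `species`, `domain` (`bacteria`/`archaea`), `lineage`
#'   (`;`-joined, phylum first, `""` if unknown) and `habitat`
#'   (`aquatic`/`nonaquatic`/`unknown`). Missing genomes get stub rows.
#' @param family_catalog optional data.frame with columns `family_id`,
#'   `description`, `role` (`known-Se-marker`, `candidate` or `background`).
#' @return an object of class `compendium`.
#' @export
compendium <- function(genes, genomes = NULL, family_catalog = NULL) {
  req <- c("genome_id", "replicon_id", "gene_id", "start", "end", "strand",
           "families")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes)[req]
  for (col in c("genome_id", "replicon_id", "gene_id", "strand", "families")) {
    genes[[col]] <- as.character(genes[[col]])
  }
  genes$families[is.na(genes$families)] <- ""
  suppressWarnings({
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
  })
  bad <- which(is.na(genes$start) | is.na(genes$end))
  if (length(bad) > 0L) {
    stop("non-numeric coordinates in gene table row(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- which(genes$start < 1L)
  if (length(bad) > 0L) {
    stop("start < 1 (coordinates are 1-based) in gene table row(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- which(genes$start > genes$end)
  if (length(bad) > 0L) {
    stop("start > end in gene table row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop("strand must be '+' or '-' in gene table row(s): ",
         paste(bad, collapse = ", "))
  }
  dup <- tapply(genes$gene_id, genes$genome_id,
                function(ids) unique(ids[duplicated(ids)]))
  dup <- unlist(dup)
  if (length(dup) > 0L) {
    stop("duplicate gene_id within a genome: ",
         paste(unique(dup), collapse = ", "))
  }

  ord <- order(genes$genome_id, genes$replicon_id, genes$start, genes$end,
               genes$gene_id, method = "radix")
  genes <- genes[ord, , drop = FALSE]
  key <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  genes$rank <- stats::ave(rep(1L, nrow(genes)), key,
                           FUN = function(x) seq_along(x) - 1L)
  rownames(genes) <- NULL

  gids <- unique(genes$genome_id)
  if (is.null(genomes)) {
    genomes <- data.frame(genome_id = gids, stringsAsFactors = FALSE)
  }
  genomes <- as.data.frame(genomes)
  if (!"genome_id" %in% names(genomes)) stop("genomes table needs genome_id")
  genomes$genome_id <- as.character(genomes$genome_id)
  if (anyDuplicated(genomes$genome_id)) {
    stop("duplicate genome_id in genomes table")
  }
  absent <- setdiff(gids, genomes$genome_id)
  if (length(absent) > 0L) {
    genomes <- rbind(genomes,
                     data.frame(genome_id = absent,
                                stringsAsFactors = FALSE)[
                       , names(genomes), drop = FALSE])
  }
  if (is.null(genomes$species)) genomes$species <- genomes$genome_id
  if (is.null(genomes$domain)) genomes$domain <- "bacteria"
  if (is.null(genomes$lineage)) genomes$lineage <- ""
  if (is.null(genomes$habitat)) genomes$habitat <- "unknown"
  genomes$species <- as.character(genomes$species)
  genomes$lineage <- as.character(genomes$lineage)
  genomes$lineage[is.na(genomes$lineage)] <- ""
  genomes$habitat <- as.character(genomes$habitat)
  genomes$habitat[is.na(genomes$habitat)] <- "unknown"
  bad <- which(!genomes$habitat %in% HABITATS)
  if (length(bad) > 0L) {
    stop("habitat must be one of ", paste(HABITATS, collapse = "/"),
         " for genome(s): ", paste(genomes$genome_id[bad], collapse = ", "))
  }
  genomes <- genomes[order(genomes$genome_id, method = "radix"), , drop = FALSE]
  rownames(genomes) <- NULL

  if (!is.null(family_catalog)) {
    family_catalog <- as.data.frame(family_catalog)
    if (!"family_id" %in% names(family_catalog)) {
      stop("family_catalog needs family_id")
    }
    family_catalog$family_id <- as.character(family_catalog$family_id)
    if (is.null(family_catalog$description)) family_catalog$description <- ""
    if (is.null(family_catalog$role)) family_catalog$role <- "background"
    if (anyDuplicated(family_catalog$family_id)) {
      stop("duplicate family_id in catalog")
    }
    rownames(family_catalog) <- NULL
  }

  structure(list(genes = genes, genomes = genomes,
                 family_catalog = family_catalog),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("<compendium> %d genomes, %d genes, %d families\n",
              nrow(x$genomes), nrow(x$genes),
              length(observed_families(x))))
  invisible(x)
}

#' Family ids observed on any gene in a compendium
#' @param comp a `compendium`.
#' @return sorted character vector of family ids.
#' @export
observed_families <- function(comp) {
  sort(unique(unlist(split_families(comp$genes$families))))
}

#' Read a gene-coordinate table
#'
#' Reads per-genome ordered gene records either from the package TSV dialect
#' (columns `genome_id`, `replicon_id`, `gene_id`, `start`, `end`, `strand`,
#' `families` with `;`-separated family ids) or from GFF3 (features of type
#' `gene` or `CDS`; family ids taken from the attribute key `family`, `;` is
#' the GFF attribute separator so multiple families use comma within the
#' value, e.g. `family=SelA,SelD`). Coordinates are 1-based inclusive.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @param genome_id genome identifier for GFF3 input (a GFF3 file holds one
#'   genome); default is the file name without extension.
#' @param genomes,family_catalog passed to [compendium()].
#' @return a `compendium`.
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3"), genome_id = NULL,
                            genomes = NULL, family_catalog = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
    if (length(nf) == 0L) stop("empty gene table: ", path)
    bad <- which(nf != nf[1L])
    if (length(bad) > 0L) {
      stop("malformed line ", bad[1L], " in ", path, ": expected ", nf[1L],
           " tab-separated fields, found ", nf[bad[1L]])
    }
    genes <- utils::read.delim(path, colClasses = "character", quote = "",
                               comment.char = "", stringsAsFactors = FALSE)
    suppressWarnings({
      s <- as.integer(genes$start)
      e <- as.integer(genes$end)
    })
    bad <- which(is.na(s) | is.na(e))
    if (length(bad) > 0L) {
      stop("malformed line ", bad[1L] + 1L, " in ", path,
           ": non-integer coordinates")
    }
    bad <- which(s > e)
    if (length(bad) > 0L) {
      stop("coordinate error at line ", bad[1L] + 1L, " in ", path,
           ": start > end")
    }
  } else {
    if (is.null(genome_id)) {
      genome_id <- sub("\\.[^.]*$", "", basename(path))
    }
    g <- ape::read.gff(path)
    g <- g[g$type %in% c("gene", "CDS"), , drop = FALSE]
    if (nrow(g) == 0L) stop("no gene/CDS features in ", path)
    attr_value <- function(attrs, key) {
      m <- regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs)
      out <- character(length(attrs))
      hit <- m > 0L
      out[hit] <- sub(paste0("^.*", key, "="), "", regmatches(attrs, m))
      out
    }
    attrs <- as.character(g$attributes)
    ids <- attr_value(attrs, "ID")
    ids[ids == ""] <- paste0("feature_", which(ids == ""))
    fams <- gsub(",", ";", attr_value(attrs, "family"), fixed = TRUE)
    bad <- which(g$start > g$end)
    if (length(bad) > 0L) {
      stop("coordinate error in ", path, " (feature line ", bad[1L],
           " of gene/CDS records): start > end")
    }
    genes <- data.frame(genome_id = genome_id,
                        replicon_id = as.character(g$seqid),
                        gene_id = ids,
                        start = g$start, end = g$end,
                        strand = as.character(g$strand),
                        families = fams,
                        stringsAsFactors = FALSE)
  }
  compendium(genes, genomes = genomes, family_catalog = family_catalog)
}

#' Write a gene table in the package TSV dialect
#' @param comp a `compendium`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(comp, path) {
  cols <- c("genome_id", "replicon_id", "gene_id", "start", "end", "strand",
            "families")
  utils::write.table(comp$genes[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Keep one genome per species
#'
#' Mirrors the one-strain-per-species convention of comparative surveys: when
#' several genomes share a species name, a single representative is retained —
#' the one named in `representative`, otherwise the lexicographically smallest
#' `genome_id`.
#'
#' @param comp a `compendium`.
#' @param representative optional named character vector, `species -> genome_id`.
#' @return a deduplicated `compendium`; the selection is recorded in
#'   `attr(, "dedup_log")` (one row per species with the kept and dropped ids).
#' @export
dedup_species <- function(comp, representative = NULL) {
  g <- comp$genomes
  if (!is.null(representative)) {
    absent <- setdiff(unname(representative), g$genome_id)
    if (length(absent) > 0L) {
      stop("representative genome_id not in compendium: ",
           paste(absent, collapse = ", "))
    }
  }
  keep <- vapply(split(g$genome_id, g$species), function(ids) {
    sp <- g$species[match(ids[1L], g$genome_id)]
    if (!is.null(representative) && sp %in% names(representative)) {
      rep_id <- unname(representative[[sp]])
      if (!rep_id %in% ids) {
        stop("representative for species '", sp, "' (", rep_id,
             ") is not a genome of that species")
      }
      rep_id
    } else {
      min(ids)
    }
  }, character(1))
  log <- data.frame(
    species = names(keep),
    kept = unname(keep),
    dropped = vapply(names(keep), function(sp) {
      ids <- g$genome_id[g$species == sp]
      paste(setdiff(ids, keep[[sp]]), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  out <- compendium(comp$genes[comp$genes$genome_id %in% keep, , drop = FALSE],
                    genomes = g[g$genome_id %in% keep, , drop = FALSE],
                    family_catalog = comp$family_catalog)
  attr(out, "dedup_log") <- log
  out
}

#' Build the genomes-by-families presence/absence matrix
#'
#' The phylogenetic profile: a cell is `TRUE` iff the genome encodes at least
#' one gene assigned to the family (multi-copy families collapse to a single
#' `TRUE`).
#'
#' @param comp a `compendium`.
#' @param families ordered family ids for the columns; defaults to the
#'   catalog's families if a catalog is present, else all observed families.
#' @return logical matrix with `rownames` = genome ids, `colnames` = family ids.
#' @export
build_presence_matrix <- function(comp, families = NULL) {
  known <- union(observed_families(comp),
                 if (!is.null(comp$family_catalog))
                   comp$family_catalog$family_id else character(0))
  if (is.null(families)) {
    families <- if (!is.null(comp$family_catalog)) {
      comp$family_catalog$family_id
    } else {
      observed_families(comp)
    }
  }
  unknown <- setdiff(families, known)
  if (length(unknown) > 0L) {
    stop("unknown family id(s): ", paste(unknown, collapse = ", "))
  }
  gids <- comp$genomes$genome_id
  m <- matrix(FALSE, nrow = length(gids), ncol = length(families),
              dimnames = list(gids, families))
  fam_list <- split_families(comp$genes$families)
  n_per_gene <- lengths(fam_list)
  if (sum(n_per_gene) > 0L) {
    pairs <- data.frame(
      genome_id = rep(comp$genes$genome_id, n_per_gene),
      family_id = unlist(fam_list, use.names = FALSE),
      stringsAsFactors = FALSE)
    pairs <- pairs[pairs$family_id %in% families, , drop = FALSE]
    if (nrow(pairs) > 0L) {
      m[cbind(match(pairs$genome_id, gids), match(pairs$family_id, families))] <- TRUE
    }
  }
  m
}

#' Write / read a presence matrix as TSV (0/1 cells)
#' @param m logical matrix (genomes x families).
#' @param path file path.
#' @return `write_presence_matrix()`: `path` invisibly;
#'   `read_presence_matrix()`: a logical matrix.
#' @export
write_presence_matrix <- function(m, path) {
  df <- data.frame(genome_id = rownames(m), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m * 1L, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE]) == 1
  rownames(m) <- df[[1L]]
  m
}
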