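# Statistics and tree computation: 2x2 chi-square and Fisher exact tests,
# protein distances (p and Poisson-corrected), neighbor joining,
# clade-enrichment scanning, and conserved-residue / motif scans on MSAs.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
GAP_CHARS <- c("-", ".")

as_2x2 <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("table must be 2x2")
    x <- c(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
  }
  if (length(x) != 4L) stop("supply a 2x2 matrix or 4 counts (a, b, c, d)")
  if (any(is.na(x)) || any(x < 0)) stop("counts must be nonnegative")
  as.numeric(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' The uncorrected statistic is `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`;
#' with Yates continuity correction `n/2` is subtracted from `|ad - bc|`
#' (floored at 0) before squaring. The p-value is the df = 1 chi-square
#' survival function, which equals `erfc(sqrt(statistic / 2))`. A table with
#' any zero margin has no association to test: the statistic is defined as 0,
#' p = 1, and the result is flagged degenerate.
#'
#' @param table a 2x2 matrix or a vector `c(a, b, c, d)` (rows = factor 1
#'   present/absent, columns = factor 2 present/absent).
#' @param yates apply the continuity correction (default TRUE).
#' @return list of class `chisq2x2`: `statistic`, `df`, `p.value`, `yates`,
#'   `direction` (sign of `ad - bc`), `degenerate`, `table`.
#' @export
chisq_2x2 <- function(table, yates = TRUE) {
  x <- as_2x2(table)
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  n <- a + b + cc + d
  if (n < 1) stop("table must contain at least one observation")
  margins <- c(a + b, cc + d, a + cc, b + d)
  direction <- sign(a * d - b * cc)
  if (any(margins == 0)) {
    res <- list(statistic = 0, df = 1L, p.value = 1, yates = yates,
                direction = direction, degenerate = TRUE,
                table = matrix(x, 2L, 2L, byrow = TRUE))
    class(res) <- "chisq2x2"
    return(res)
  }
  delta <- abs(a * d - b * cc)
  if (yates) delta <- max(0, delta - n / 2)
  statistic <- n * delta^2 / prod(margins)
  p <- stats::pchisq(statistic, df = 1L, lower.tail = FALSE)
  res <- list(statistic = statistic, df = 1L, p.value = p, yates = yates,
              direction = direction, degenerate = FALSE,
              table = matrix(x, 2L, 2L, byrow = TRUE))
  class(res) <- "chisq2x2"
  res
}

#' @export
print.chisq2x2 <- function(x, ...) {
  cat(sprintf("chi-square(df=1)%s = %.6g, p = %.6g%s\n",
              if (x$yates) " [Yates]" else "", x$statistic, x$p.value,
              if (x$degenerate) " (degenerate margin)" else ""))
  invisible(x)
}

#' Co-occurrence test for two presence vectors
#'
#' Cross-tabulates two aligned presence/absence vectors (a = both present,
#' b = x only, c = y only, d = neither) and applies [chisq_2x2()]. A positive
#' `direction` means the two families co-occur more than expected.
#'
#' @param x,y logical (or 0/1) vectors over the same genomes, same order.
#' @param yates apply the continuity correction (default TRUE).
#' @return list with `table` (2x2 matrix) and `test` (a `chisq2x2`).
#' @export
cooccurrence_test <- function(x, y, yates = TRUE) {
  if (length(x) != length(y)) stop("presence vectors differ in length")
  x <- as.logical(x); y <- as.logical(y)
  if (any(is.na(x)) || any(is.na(y))) stop("presence vectors contain NA")
  tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)),
                2L, 2L, byrow = TRUE,
                dimnames = list(x = c("present", "absent"),
                                y = c("present", "absent")))
  list(table = tab, test = chisq_2x2(tab, yates = yates))
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric tail with margins fixed. `side = "greater"` sums the
#' upper tail from the observed `a`; `side = "two.sided"` sums all point
#' probabilities not exceeding the observed one (with a 1 + 1e-7 relative
#' tolerance, the usual convention). A zero margin gives p = 1.
#'
#' @param table a 2x2 matrix or `c(a, b, c, d)`.
#' @param side `"greater"` or `"two.sided"`.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(table, side = c("greater", "two.sided")) {
  side <- match.arg(side)
  x <- as_2x2(table)
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m <- a + b       # row-1 total
  n2 <- cc + d     # row-2 total
  k <- a + cc      # column-1 total
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  if (side == "greater") {
    sum(probs[support >= a])
  } else {
    p_obs <- probs[support == a]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

#' Read an MSA (aligned FASTA or Clustal)
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return named character vector of upper-case aligned sequences.
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  stats::setNames(toupper(unlist(aln$seq)), aln$nam)
}

# Named character vector of aligned sequences -> character matrix
# (rows = sequences, columns = alignment columns).
msa_matrix <- function(msa) {
  if (is.matrix(msa)) {
    return(`dimnames<-`(toupper(msa), dimnames(msa)))
  }
  if (is.null(names(msa))) names(msa) <- paste0("seq", seq_along(msa))
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length")
  }
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Pairwise protein distances from an alignment
#'
#' The p-distance is the mismatch fraction over pairwise-complete columns
#' (columns where neither sequence has a gap); the Poisson correction
#' `d = -ln(1 - p)` estimates expected replacements per site. A saturated
#' pair (p = 1) is capped at `max_distance` and recorded in
#' `attr(, "capped")`.
#'
#' @param msa named character vector of aligned sequences, or a character
#'   matrix.
#' @param model `"poisson"` (default) or `"p"`.
#' @param max_distance cap for saturated pairs (default 10).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
protein_distances <- function(msa, model = c("poisson", "p"),
                              max_distance = 10) {
  model <- match.arg(model)
  m <- msa_matrix(msa)
  if (nrow(m) < 2L) stop("need at least two sequences")
  n <- nrow(m)
  ids <- rownames(m)
  gap <- matrix(m %in% GAP_CHARS, nrow = n)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  capped <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("no comparable columns between ", ids[i], " and ", ids[j])
      }
      p <- mean(m[i, ok] != m[j, ok])
      d <- if (model == "p") {
        p
      } else if (p >= 1) {
        capped <- c(capped, paste(ids[i], ids[j], sep = "|"))
        max_distance
      } else {
        min(-log(1 - p), max_distance)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "capped") <- capped
  D
}

#' Read / write a PHYLIP square distance matrix
#'
#' The format: first line holds the number of taxa; each following record is
#' a taxon name followed by the full row of distances (wrapped lines are
#' accepted on read).
#'
#' @param path file path.
#' @return `read_phylip_dist()`: a named symmetric matrix.
#' @export
read_phylip_dist <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE)
  n <- as.integer(tokens[1L])
  if (is.na(n) || n < 2L) stop("invalid PHYLIP distance file: bad taxon count")
  if (length(tokens) != 1L + n * (n + 1L)) {
    stop("invalid PHYLIP square matrix: expected ", 1L + n * (n + 1L),
         " tokens, found ", length(tokens))
  }
  ids <- character(n)
  D <- matrix(0, n, n)
  pos <- 2L
  for (i in seq_len(n)) {
    ids[i] <- tokens[pos]
    vals <- as.numeric(tokens[(pos + 1L):(pos + n)])
    if (any(is.na(vals))) stop("non-numeric distance in row for ", ids[i])
    D[i, ] <- vals
    pos <- pos + n + 1L
  }
  dimnames(D) <- list(ids, ids)
  D
}

#' @rdname read_phylip_dist
#' @param D named square distance matrix.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

validate_distance_matrix <- function(D, tol = 1e-9) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("t", seq_len(nrow(D))),
                        paste0("t", seq_len(nrow(D))))
  }
  if (any(abs(D - t(D)) > tol)) {
    stop("distance matrix is asymmetric beyond tolerance ", tol)
  }
  if (any(abs(diag(D)) > 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distances must be nonnegative")
  D
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q criterion
#' `Q_ij = (r - 2) d_ij - R_i - R_j`. Ties in Q are broken by the smallest
#' pair of taxon indices (row-major), making the result deterministic.
#' Negative branch-length estimates are clamped to zero; the total clamped
#' deficit is recorded in `attr(, "negative_branch_deficit")`. For two taxa
#' the single connecting path of length `d` is represented as a 2-tip tree
#' with the distance split across its pendant edges; for three taxa the
#' closed-form star solution is used.
#'
#' @param D symmetric distance matrix with taxon names (asymmetry beyond
#'   1e-9 is an error).
#' @return an unrooted `phylo` tree (class from \pkg{ape}).
#' @export
neighbor_joining <- function(D) {
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) {
      deficit <<- deficit - x
      0
    } else x
  }
  if (n == 2L) {
    d <- D[1, 2]
    tree <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);", labels[1],
                                          fmt_len(d / 2), labels[2],
                                          fmt_len(d / 2)))
    attr(tree, "negative_branch_deficit") <- 0
    return(tree)
  }
  frags <- labels
  d <- unname(D)
  r <- n
  while (r > 3L) {
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    best <- c(1L, 2L)
    qbest <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        if (Q[i, j] < qbest) {
          qbest <- Q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(d[i, j] / 2 + (R[j] - R[i]) / (2 * (r - 2)))
    newfrag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt_len(li),
                       frags[j], fmt_len(lj))
    keep <- setdiff(seq_len(r), c(i, j))
    dnew <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    d2 <- matrix(0, r - 1L, r - 1L)
    d2[seq_len(r - 2L), seq_len(r - 2L)] <- d[keep, keep]
    d2[r - 1L, seq_len(r - 2L)] <- dnew
    d2[seq_len(r - 2L), r - 1L] <- dnew
    frags <- c(frags[keep], newfrag)
    d <- d2
    r <- r - 1L
  }
  l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", frags[1], fmt_len(l1),
                    frags[2], fmt_len(l2), frags[3], fmt_len(l3))
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_branch_deficit") <- deficit
  tree
}

# For every node of a phylo tree, the set of tip indices below it.
tips_below <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}

#' Scan every clade of a tree for trait enrichment
#'
#' Every edge of the tree induces a bipartition of the leaves; each side with
#' at least two leaves is a candidate clade and is tested for enrichment of
#' trait-positive leaves with a one-sided Fisher exact test (inside vs
#' outside x trait+ vs trait-). The winner is the minimal-p clade, ties
#' broken by larger inside trait+ count, then by edge id. If all leaves share
#' one label the scan is uninformative (p = 1 everywhere, flagged).
#'
#' @param tree a `phylo` tree with at least 4 leaves.
#' @param labels named logical vector over all tip labels (`TRUE` = trait+),
#'   or a character vector of two levels whose first sorted level is taken as
#'   trait-negative.
#' @return list of class `clade_scan`: `best` (one-row data.frame), `table`
#'   (all candidate clades, ranked), `uninformative`.
#' @export
clade_enrichment_scan <- function(tree, labels) {
  tips <- tree$tip.label
  if (length(tips) < 4L) stop("need at least 4 leaves")
  if (is.character(labels) || is.factor(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) > 2L) stop("labels must have at most two levels")
    labels <- stats::setNames(as.character(labels) == lv[length(lv)],
                              names(labels))
  }
  if (is.null(names(labels)) || !all(tips %in% names(labels))) {
    stop("every leaf must be labeled")
  }
  lab <- labels[tips]
  if (any(is.na(lab))) stop("every leaf must be labeled")
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  uninformative <- n_pos == 0L || n_neg == 0L
  sets <- tips_below(tree)
  rows <- list()
  for (e in seq_len(nrow(tree$edge))) {
    below <- sets[[tree$edge[e, 2L]]]
    for (s in c("below", "above")) {
      inside <- if (s == "below") below else setdiff(seq_along(tips), below)
      if (length(inside) < 2L || length(inside) == length(tips)) next
      in_pos <- sum(lab[inside])
      in_neg <- length(inside) - in_pos
      out_pos <- n_pos - in_pos
      out_neg <- n_neg - in_neg
      p <- if (uninformative) 1 else {
        fisher_exact_2x2(c(in_pos, in_neg, out_pos, out_neg),
                         side = "greater")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        edge = e, side = s, n_leaves = length(inside),
        in_pos = in_pos, in_neg = in_neg,
        out_pos = out_pos, out_neg = out_neg,
        p = p, score = -log10(p),
        leaves = paste(tips[inside], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p, -tab$in_pos, tab$edge), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(best = tab[1L, , drop = FALSE], table = tab,
                 uninformative = uninformative),
            class = "clade_scan")
}

#' @export
print.clade_scan <- function(x, ...) {
  if (x$uninformative) {
    cat("<clade_scan> uninformative (all leaves share one label)\n")
  } else {
    cat(sprintf("<clade_scan> best clade: %d leaves (%d trait+), p = %.3g\n",
                x$best$n_leaves, x$best$in_pos, x$best$p))
  }
  invisible(x)
}

#' Column conservation profile of an alignment
#'
#' Per alignment column, the consensus residue and its frequency among
#' non-gap rows. Columns with more than 50% gaps are skipped (reported but
#' never flagged). A column is flagged when its consensus frequency reaches
#' `min_freq` and, if `residue_filter` is given, the consensus is that
#' residue — e.g. `residue_filter = "C"` restricts flags to conserved
#' cysteines.
#'
#' @param msa named character vector of aligned sequences or a character
#'   matrix.
#' @param min_freq minimal consensus frequency to flag (0 < min_freq <= 1),
#'   default 0.9.
#' @param residue_filter optional single residue restricting flags.
#' @return list with `profile` (per-column data.frame: `column`, `consensus`,
#'   `freq`, `n_non_gap`, `skipped`, `flagged`) and `flagged` (column
#'   indices).
#' @export
conservation_scan <- function(msa, min_freq = 0.9, residue_filter = NULL) {
  if (!is.numeric(min_freq) || min_freq <= 0 || min_freq > 1) {
    stop("min_freq must be in (0, 1]")
  }
  m <- msa_matrix(msa)
  if (nrow(m) < 2L) stop("need at least two sequences")
  if (ncol(m) == 0L) stop("empty alignment")
  prof <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[!col %in% GAP_CHARS]
    skipped <- length(res) < length(col) / 2
    if (length(res) == 0L) {
      return(data.frame(column = j, consensus = NA_character_, freq = NA_real_,
                        n_non_gap = 0L, skipped = TRUE, flagged = FALSE,
                        stringsAsFactors = FALSE))
    }
    tab <- table(res)
    consensus <- names(tab)[which.max(tab)]  # ties: alphabetically first
    freq <- max(tab) / length(res)
    flagged <- !skipped && freq >= min_freq &&
      (is.null(residue_filter) || consensus == residue_filter)
    data.frame(column = j, consensus = consensus, freq = freq,
               n_non_gap = length(res), skipped = skipped, flagged = flagged,
               stringsAsFactors = FALSE)
  }))
  rownames(prof) <- NULL
  list(profile = prof, flagged = prof$column[prof$flagged])
}

#' Scan sequences for a motif pattern
#'
#' The pattern uses the one-letter amino-acid alphabet plus `X` as a
#' wildcard (e.g. `CPXP`, `CGXC`). Matching is performed on the ungapped
#' sequences; matches are reported 1-based on the ungapped sequence together
#' with the alignment column of the first matched residue. Overlapping
#' matches are all reported.
#'
#' @param msa named character vector of (aligned or plain) sequences, or a
#'   character matrix.
#' @param pattern motif pattern.
#' @return data.frame: `seq_id`, `position` (ungapped, 1-based), `column`
#'   (alignment column), `match` (matched substring).
#' @export
motif_scan <- function(msa, pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L) {
    stop("pattern must be a non-empty string")
  }
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, c(AA_ALPHABET, "X"))
  if (length(bad) > 0L) {
    stop("pattern contains non-amino-acid characters: ",
         paste(bad, collapse = ", "))
  }
  m <- msa_matrix(if (is.matrix(msa)) msa else {
    # pad is unnecessary; msa_matrix handles equal-length checks, but plain
    # unaligned sequences of different lengths are legal here
    if (length(unique(nchar(msa))) == 1L) msa else {
      width <- max(nchar(msa))
      stats::setNames(vapply(msa, function(s) {
        paste0(s, strrep("-", width - nchar(s)))
      }, character(1)), names(msa))
    }
  })
  regex <- gsub("X", ".", pattern, fixed = TRUE)
  k <- nchar(pattern)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    cols <- which(!m[i, ] %in% GAP_CHARS)
    seq_ungapped <- paste(m[i, cols], collapse = "")
    hits <- gregexpr(paste0("(?=", regex, ")"), seq_ungapped, perl = TRUE)[[1]]
    if (hits[1L] == -1L) next
    for (pos in as.integer(hits)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = rownames(m)[i], position = pos, column = cols[pos],
        match = substr(seq_ungapped, pos, pos + k - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seq_id = character(0), position = integer(0),
                      column = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
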