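# Independent brute-force oracles and fixture builders. Every oracle here is
# written as a plain enumeration, deliberately sharing no code with the
# package implementation it checks.

# Gene table with random intervals on the given replicons.
random_gene_table <- function(n_genes, genome_id = "G1", replicon_id = "chr",
                              families = character(0), fam_prob = 0.3) {
  starts <- sample.int(100000L, n_genes)
  lens <- sample.int(900L, n_genes)
  fams <- vapply(seq_len(n_genes), function(i) {
    if (length(families) > 0 && runif(1) < fam_prob) {
      paste(sample(families, sample.int(min(2L, length(families)), 1L)),
            collapse = ";")
    } else ""
  }, character(1))
  data.frame(genome_id = genome_id, replicon_id = replicon_id,
             gene_id = sprintf("%s_g%03d", genome_id, seq_len(n_genes)),
             start = starts, end = starts + lens,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             families = fams, stringsAsFactors = FALSE)
}

# Presence matrix by explicit double loop over genomes and genes.
brute_presence <- function(comp, families) {
  gids <- comp$genomes$genome_id
  m <- matrix(FALSE, length(gids), length(families),
              dimnames = list(gids, families))
  for (g in gids) {
    genes <- comp$genes[comp$genes$genome_id == g, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      for (f in strsplit(genes$families[i], ";", fixed = TRUE)[[1]]) {
        if (f %in% families) m[g, f] <- TRUE
      }
    }
  }
  m
}

# Random all-vs-all score tables for one genome: n_q reference proteins vs
# n_s genes, continuous E-values (ties have probability zero). Returns the
# forward table, the reverse table and the E-value matrix.
random_score_tables <- function(n_q, n_s, genome_id = "G1") {
  E <- matrix(10^runif(n_q * n_s, -30, 0), n_q, n_s,
              dimnames = list(paste0("Q", seq_len(n_q)),
                              paste0("s", seq_len(n_s))))
  B <- matrix(runif(n_q * n_s, 30, 300), n_q, n_s, dimnames = dimnames(E))
  fwd <- data.frame(query_id = rep(rownames(E), n_s),
                    genome_id = genome_id,
                    subject_gene_id = rep(colnames(E), each = n_q),
                    evalue = as.vector(E), bitscore = as.vector(B),
                    stringsAsFactors = FALSE)
  rev <- data.frame(query_id = rep(colnames(E), each = n_q),
                    genome_id = genome_id,
                    subject_gene_id = rep(rownames(E), n_s),
                    evalue = as.vector(E), bitscore = as.vector(B),
                    stringsAsFactors = FALSE)
  list(forward = fwd, reverse = rev, E = E)
}

# Mutual-argmax enumeration on an E-value matrix (rows = queries,
# columns = subjects): pair (q, s) iff E[q, s] is the strict row minimum and
# the strict column minimum.
brute_mutual_argmax <- function(E) {
  pairs <- list()
  for (q in seq_len(nrow(E))) {
    for (s in seq_len(ncol(E))) {
      if (E[q, s] == min(E[q, ]) && E[q, s] == min(E[, s])) {
        pairs[[length(pairs) + 1L]] <- c(rownames(E)[q], colnames(E)[s])
      }
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(query_id = character(0),
                      subject_gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind.data.frame, c(pairs, stringsAsFactors = FALSE))
  names(out) <- c("query_id", "subject_gene_id")
  out[order(out$query_id), , drop = FALSE]
}

# df = 1 chi-square survival function through the normal distribution:
# p = erfc(sqrt(x / 2)), erfc(z) = 2 * pnorm(z * sqrt(2), lower.tail = FALSE).
# Independent of pchisq (normal vs gamma code path in R).
chisq1_sf_erfc <- function(x) 2 * pnorm(sqrt(x), lower.tail = FALSE)

# Fisher exact by explicit enumeration of the margin-constrained lattice
# with choose().
brute_fisher <- function(a, b, cc, d, side = "greater") {
  m <- a + b; n2 <- cc + d; k <- a + cc; n <- m + n2
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- vapply(support, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(n, k)
  }, numeric(1))
  if (side == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
  }
}

# Maximal runs of "Se" ranks with gaps <= max_gap, by direct enumeration.
brute_runs <- function(ranks, max_gap) {
  ranks <- sort(ranks)
  runs <- list()
  current <- ranks[1]
  for (r in ranks[-1]) {
    if (r - current[length(current)] - 1 <= max_gap) {
      current <- c(current, r)
    } else {
      runs[[length(runs) + 1L]] <- current
      current <- r
    }
  }
  runs[[length(runs) + 1L]] <- current
  runs
}

# Random additive distance matrix from a random tree with strictly positive
# branch lengths; returns both.
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.1, 2))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# Clade tip sets by edge deletion + breadth-first search on the adjacency
# list (independent of the package's postorder accumulation).
edge_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  adj <- vector("list", n_tip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(seq_len(nrow(tree$edge)), function(e) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    seen <- b
    frontier <- b
    while (length(frontier) > 0L) {
      nxt <- setdiff(unlist(adj[frontier]), c(seen, a))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    sort(seen[seen <= n_tip])
  })
}

# Exhaustive clade-enrichment scan: every edge side with >= 2 leaves, Fisher
# greater via stats::fisher.test.
brute_clade_scan <- function(tree, lab) {
  tips <- tree$tip.label
  lab <- lab[tips]
  parts <- edge_bipartitions(tree)
  best_p <- Inf; best_in_pos <- -1; rows <- list()
  for (e in seq_along(parts)) {
    for (side in list(parts[[e]], setdiff(seq_along(tips), parts[[e]]))) {
      if (length(side) < 2L || length(side) == length(tips)) next
      in_pos <- sum(lab[side]); in_neg <- length(side) - in_pos
      out_pos <- sum(lab) - in_pos; out_neg <- sum(!lab) - in_neg
      tab <- matrix(c(in_pos, out_pos, in_neg, out_neg), 2L)
      p <- if (sum(lab) == 0 || sum(!lab) == 0) 1 else {
        stats::fisher.test(tab, alternative = "greater")$p.value
      }
      rows[[length(rows) + 1L]] <- list(p = p, in_pos = in_pos,
                                        leaves = sort(tips[side]))
    }
  }
  ps <- vapply(rows, `[[`, numeric(1), "p")
  ips <- vapply(rows, `[[`, numeric(1), "in_pos")
  ord <- order(ps, -ips)
  list(best = rows[[ord[1L]]], all = rows)
}

# A tiny hand-buildable compendium: n genomes, each with the given family
# layouts (list of character vectors, one per genome, gene i carries
# layout[[g]][i]).
layout_compendium <- function(layouts, genomes = NULL) {
  rows <- lapply(seq_along(layouts), function(g) {
    fams <- layouts[[g]]
    n <- length(fams)
    data.frame(genome_id = paste0("G", g), replicon_id = "chr",
               gene_id = sprintf("G%d_g%03d", g, seq_len(n)),
               start = (seq_len(n) - 1L) * 1000L + 1L,
               end = (seq_len(n) - 1L) * 1000L + 900L,
               strand = "+", families = fams, stringsAsFactors = FALSE)
  })
  compendium(do.call(rbind, rows), genomes = genomes)
}
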