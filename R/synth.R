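# Synthetic-compendium simulator with full ground truth: Yule species trees,
# binary gain/loss trait evolution, Se gene islands with planted linked
# candidate families, paralogous superfamilies, background families and
# noisy homology score tables. The generator's defaults are the study
# conditions under which the pipeline is validated.

#' Simulate a Yule species tree
#'
#' Pure-birth process with unit per-lineage split rate: while fewer than
#' `n_taxa` lineages exist, all extant branches grow by an Exp(k) hold time
#' (k = current lineage count) and a uniformly chosen lineage splits; a final
#' Exp(n) growth epoch gives the last-born tips positive pendant edges. The
#' tree is ultrametric with expected root-to-tip depth
#' `sum(1/k, k = 2..n)`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed optional integer seed (set before drawing).
#' @return an ultrametric `phylo` tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (!is.numeric(n_taxa) || n_taxa < 2L) stop("n_taxa must be >= 2")
  n_taxa <- as.integer(n_taxa)
  if (!is.null(seed)) set.seed(seed)
  parent <- c(NA_integer_, 1L, 1L)
  edge_len <- c(NA_real_, 0, 0)
  extant <- c(2L, 3L)
  while (length(extant) < n_taxa) {
    k <- length(extant)
    t <- stats::rexp(1L, rate = k)
    edge_len[extant] <- edge_len[extant] + t
    i <- extant[sample.int(k, 1L)]
    a <- length(parent) + 1L
    b <- length(parent) + 2L
    parent <- c(parent, i, i)
    edge_len <- c(edge_len, 0, 0)
    extant <- c(setdiff(extant, i), a, b)
  }
  t <- stats::rexp(1L, rate = n_taxa)
  edge_len[extant] <- edge_len[extant] + t

  tip_label <- character(length(parent))
  tip_label[sort(extant)] <- paste0("t", seq_len(n_taxa))
  children <- split(seq_along(parent)[-1L], parent[-1L])
  newick_of <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) {
      tip_label[node]
    } else {
      paste0("(", paste(vapply(kids, function(ch) {
        paste0(newick_of(ch), ":", fmt_len(edge_len[ch]))
      }, character(1)), collapse = ","), ")")
    }
  }
  ape::read.tree(text = paste0(newick_of(1L), ";"))
}

#' Star tree
#'
#' All tips attached directly to the root with equal branch lengths; under
#' gain/loss evolution the tip states are then independent, which makes the
#' star tree the null model for co-occurrence calibration.
#'
#' @param n_taxa number of tips.
#' @param branch_length pendant edge length (default 10, effectively at the
#'   stationary distribution for unit total rate).
#' @return a `phylo` tree.
#' @export
star_tree <- function(n_taxa, branch_length = 10) {
  tips <- paste0("t", seq_len(n_taxa))
  ape::read.tree(text = paste0(
    "(", paste0(tips, ":", fmt_len(branch_length), collapse = ","), ");"))
}

#' Evolve a binary trait along a tree
#'
#' Two-state continuous-time Markov chain with gain rate `gain`
#' (absent -> present) and loss rate `loss` (present -> absent). Over a
#' branch of length `t`, `P(absent -> present) =
#' gain/(gain+loss) * (1 - exp(-(gain+loss) t))` (closed form), and
#' symmetrically for loss. States are sampled from the root down.
#'
#' @param tree a `phylo` tree.
#' @param gain,loss nonnegative rates, not both zero.
#' @param root_state logical root state (default `TRUE`, i.e. present — an
#'   ancient trait subsequently lost in many lineages).
#' @param seed optional integer seed.
#' @return named logical vector of tip states.
#' @export
evolve_binary_trait <- function(tree, gain, loss, root_state = TRUE,
                                seed = NULL) {
  if (gain < 0 || loss < 0) stop("rates must be nonnegative")
  if (gain + loss <= 0) stop("gain + loss must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- rep(NA, n_tip + tree$Nnode)
  states[root] <- isTRUE(root_state)
  rho <- gain + loss
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]
    child <- edges[e, 2L]
    t <- lens[e]
    decay <- exp(-rho * t)
    p_present <- if (states[parent]) {
      # stay present
      gain / rho + loss / rho * decay
    } else {
      gain / rho * (1 - decay)
    }
    states[child] <- stats::runif(1L) < p_present
  }
  stats::setNames(states[seq_len(n_tip)], tree$tip.label)
}

#' Transition probability of the binary gain/loss chain
#'
#' Closed-form `P(state at time t = present | start state)` for the two-state
#' chain; exposed for oracle tests and power calculations.
#'
#' @param t branch length.
#' @param gain,loss rates.
#' @param from_present logical start state.
#' @return probability of being present at time `t`.
#' @export
transition_prob_present <- function(t, gain, loss, from_present) {
  rho <- gain + loss
  if (rho <= 0) stop("gain + loss must be positive")
  decay <- exp(-rho * t)
  ifelse(from_present, gain / rho + loss / rho * decay,
         gain / rho * (1 - decay))
}

MARKER_FAMILIES <- c("SelA", "SelB", "SelD", "YbbB", "YqeB", "YqeC",
                     "SecLyase", "SirA")

#' Known Se marker families
#'
#' The eight families treated as known Se-utilization machinery throughout
#' the package: the three-trait markers (SelA, SelB, SelD, YbbB, YqeB, YqeC)
#' plus the Se-recycling genes Sec lyase and SirA-like that co-locate with
#' them in Se islands.
#'
#' @return character vector of family ids.
#' @export
known_se_families <- function() MARKER_FAMILIES

default_trait_rates <- function() {
  # Stationary presence frequencies chosen to echo the mosaic occurrence of
  # the Se machinery across sequenced prokaryotes: SelD in roughly half the
  # simulated genomes, the cofactor markers rarer. Total rate 1 on a tree of
  # height ~ H_n - 1 gives strong but incomplete phylogenetic signal.
  pi <- c(SelA = 0.60, SelB = 0.60, SelD = 0.50, YbbB = 0.45,
          YqeB = 0.30, YqeC = 0.30, SecLyase = 0.50, SirA = 0.50)
  data.frame(family_id = names(pi), gain = unname(pi), loss = 1 - unname(pi),
             root_state = TRUE, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic compendium generator with its default
#' study conditions. Defaults: 50 taxa, 8 marker families evolving by
#' gain/loss on a Yule tree (root state present — an ancient trait lost in
#' many lineages), 4 planted candidate families each linked to the Se island
#' with probability 0.9 in island-bearing genomes, 200 background families at
#' 50% presence, 250 genes per genome on one replicon, a 3-paralog LysR-like
#' superfamily whose Se subfamily is island-linked, habitat more often
#' aquatic for SelD-positive genomes, and a 2% spurious homology-hit rate.
#'
#' @param n_taxa number of genomes.
#' @param seed integer seed driving the whole simulation.
#' @param trait_rates data.frame (`family_id`, `gain`, `loss`, `root_state`)
#'   for the marker families.
#' @param island_layout marker families in island gene order.
#' @param candidates named numeric vector of planted candidate families ->
#'   linkage probability `p_link`.
#' @param candidate_background_rate presence probability of a candidate in a
#'   genome without an island.
#' @param n_background_families number of unlinked background families.
#' @param background_presence per-genome presence probability of each
#'   background family.
#' @param genes_per_genome genes per (single-replicon) genome.
#' @param superfamily list: `name`, `n_members`, `subfamily_linked`.
#' @param habitat_model named numeric vector: `aquatic_if_selD`,
#'   `aquatic_if_no_selD`.
#' @param score_noise list: `rate` (spurious-hit probability per
#'   query-genome), `log10_min`, `log10_max` (E-value exponent range of
#'   spurious hits, straddling the 0.1 cutoff).
#' @param window_radius neighborhood half-width used when planting linked
#'   candidates.
#' @param n_phyla number of phylum labels carved from the tree.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 50L,
                       seed = 1L,
                       trait_rates = default_trait_rates(),
                       island_layout = c("SirA", "SecLyase", "SelA", "SelB",
                                         "SelD", "YbbB", "YqeB", "YqeC"),
                       candidates = c(YedE = 0.9, YedF = 0.9,
                                      LysR_Se = 0.9, DUF3343 = 0.9),
                       candidate_background_rate = 0.05,
                       n_background_families = 200L,
                       background_presence = 0.5,
                       genes_per_genome = 250L,
                       superfamily = list(name = "LysR", n_members = 3L,
                                          subfamily_linked = TRUE),
                       habitat_model = c(aquatic_if_selD = 0.6,
                                         aquatic_if_no_selD = 0.3),
                       score_noise = list(rate = 0.02, log10_min = -3,
                                          log10_max = 1),
                       window_radius = 10L,
                       n_phyla = 5L) {
  if (n_taxa < 4L) stop("n_taxa must be >= 4")
  if (any(trait_rates$gain < 0) || any(trait_rates$loss < 0)) {
    stop("rates must be nonnegative")
  }
  if (any(candidates < 0) || any(candidates > 1)) {
    stop("p_link must be in [0, 1]")
  }
  cfg <- list(n_taxa = as.integer(n_taxa), seed = seed,
              trait_rates = trait_rates, island_layout = island_layout,
              candidates = candidates,
              candidate_background_rate = candidate_background_rate,
              n_background_families = as.integer(n_background_families),
              background_presence = background_presence,
              genes_per_genome = as.integer(genes_per_genome),
              superfamily = superfamily, habitat_model = habitat_model,
              score_noise = score_noise,
              window_radius = as.integer(window_radius),
              n_phyla = as.integer(n_phyla))
  class(cfg) <- "sim_config"
  cfg
}

# Phylum/subdivision labels from tree structure: average-linkage clustering
# of the cophenetic distances, cut at n_phyla (and 2*n_phyla) groups.
lineage_from_tree <- function(tree, n_phyla) {
  co <- stats::as.dist(ape::cophenetic.phylo(tree))
  hc <- stats::hclust(co, method = "average")
  phylum <- stats::cutree(hc, k = min(n_phyla, length(tree$tip.label)))
  sub <- stats::cutree(hc, k = min(2L * n_phyla, length(tree$tip.label)))
  stats::setNames(paste0("Phylum", phylum, ";Sub", sub), tree$tip.label)
}

#' Simulate a full synthetic compendium with ground truth
#'
#' Runs the whole generator: Yule tree, per-family gain/loss evolution,
#' lineage and habitat labels, and gene-level layout via
#' [synthesize_compendium()]. The returned truth object carries everything a
#' recovery test needs.
#'
#' @param config a [sim_config()].
#' @return list with `compendium` (a `compendium`) and `truth` (list: `tree`,
#'   `states` family-by-genome logical matrix, `islands`, `placements` of
#'   planted candidates with in-window flags, `habitat`, `lineage`,
#'   `config`).
#' @export
simulate_se_compendium <- function(config = sim_config()) {
  set.seed(config$seed)
  tree <- simulate_tree(config$n_taxa)
  genome_ids <- tree$tip.label
  states <- t(vapply(seq_len(nrow(config$trait_rates)), function(i) {
    r <- config$trait_rates[i, ]
    evolve_binary_trait(tree, r$gain, r$loss, root_state = r$root_state)
  }, logical(config$n_taxa)))
  rownames(states) <- config$trait_rates$family_id
  colnames(states) <- genome_ids
  lineage <- lineage_from_tree(tree, config$n_phyla)
  selD <- states["SelD", ]
  p_aq <- ifelse(selD, config$habitat_model[["aquatic_if_selD"]],
                 config$habitat_model[["aquatic_if_no_selD"]])
  habitat <- stats::setNames(
    ifelse(stats::runif(config$n_taxa) < p_aq, "aquatic", "nonaquatic"),
    genome_ids)
  truth <- list(tree = tree, states = states, habitat = habitat,
                lineage = lineage, config = config)
  comp <- synthesize_compendium(truth, config)
  truth$placements <- attr(comp, "placements")
  truth$islands <- attr(comp, "islands")
  list(compendium = comp, truth = truth)
}

#' Lay out synthetic genomes from simulated trait states
#'
#' Builds the gene-level compendium: each genome gets `genes_per_genome`
#' genes on one replicon; genomes whose SelD state is present receive their
#' present marker families as one contiguous island (in `island_layout`
#' order); each planted candidate is placed inside the island's
#' `window_radius`-gene neighborhood with probability `p_link` (else
#' uniformly anywhere on the replicon) in island-bearing genomes, and at
#' `candidate_background_rate` in the rest; superfamily paralogs are placed
#' in every genome with the Se subfamily copy island-linked when configured;
#' background families fill uniform positions. Deterministic given the RNG
#' state.
#'
#' @param truth list with at least `tree`, `states`, `habitat`, `lineage`
#'   (as built by [simulate_se_compendium()]).
#' @param config the [sim_config()].
#' @return a `compendium`; candidate placements and island spans are attached
#'   as attributes `placements` and `islands`.
#' @export
synthesize_compendium <- function(truth, config) {
  states <- truth$states
  genome_ids <- colnames(states)
  G <- config$genes_per_genome
  radius <- config$window_radius
  n_markers <- length(config$island_layout)
  missing_fams <- setdiff(config$island_layout, rownames(states))
  if (length(missing_fams) > 0L) {
    stop("island_layout families without evolved states: ",
         paste(missing_fams, collapse = ", "))
  }
  n_cand <- length(config$candidates)
  n_super <- config$superfamily$n_members
  need <- n_markers + 2L * radius + n_cand + n_super + 10L
  if (G < need) {
    stop("genes_per_genome (", G, ") too small to host island, window and ",
         "candidates; need >= ", need)
  }
  bg_ids <- sprintf("BG%03d", seq_len(config$n_background_families))
  super_ids <- paste0(config$superfamily$name, "_par",
                      seq_len(max(0L, n_super - 1L)))
  gene_rows <- vector("list", length(genome_ids))
  placements <- list()
  island_rows <- list()
  for (gi in seq_along(genome_ids)) {
    g <- genome_ids[gi]
    fams <- character(G)
    free <- function() which(fams == "")
    selD_here <- states["SelD", g]
    island_span <- NULL
    if (selD_here) {
      markers_here <- config$island_layout[states[config$island_layout, g]]
      L <- length(markers_here)
      start <- sample((radius + 2L):(G - L - radius - 1L), 1L)
      fams[start:(start + L - 1L)] <- markers_here
      island_span <- c(start, start + L - 1L)
      island_rows[[length(island_rows) + 1L]] <- data.frame(
        genome_id = g, start_slot = start, end_slot = start + L - 1L,
        families = paste(markers_here, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    place_uniform <- function(fam, slots) {
      slots <- intersect(slots, free())
      if (length(slots) == 0L) stop("no free gene slot for ", fam, " in ", g)
      slot <- if (length(slots) == 1L) slots else sample(slots, 1L)
      fams[slot] <<- fam
      slot
    }
    window_slots <- if (!is.null(island_span)) {
      max(1L, island_span[1L] - radius):min(G, island_span[2L] + radius)
    } else integer(0)
    for (ci in seq_along(config$candidates)) {
      cand <- names(config$candidates)[ci]
      p_link <- config$candidates[[ci]]
      if (cand == paste0(config$superfamily$name, "_Se") &&
          !isTRUE(config$superfamily$subfamily_linked)) {
        p_link <- 0
      }
      if (selD_here) {
        linked <- stats::runif(1L) < p_link
        slot <- if (linked) {
          place_uniform(cand, window_slots)
        } else {
          # unlinked copies fall anywhere, so they can land in the window by
          # chance at the uniform null rate (window size / genes_per_genome)
          place_uniform(cand, seq_len(G))
        }
        placements[[length(placements) + 1L]] <- data.frame(
          genome_id = g, family_id = cand, slot = slot,
          island_genome = TRUE, in_window = slot %in% window_slots,
          stringsAsFactors = FALSE)
      } else if (stats::runif(1L) < config$candidate_background_rate) {
        slot <- place_uniform(cand, seq_len(G))
        placements[[length(placements) + 1L]] <- data.frame(
          genome_id = g, family_id = cand, slot = slot,
          island_genome = FALSE, in_window = FALSE, stringsAsFactors = FALSE)
      }
    }
    for (sf in super_ids) {
      place_uniform(sf, seq_len(G))
    }
    present_bg <- bg_ids[stats::runif(length(bg_ids)) <
                           config$background_presence]
    for (bg in present_bg) {
      place_uniform(bg, seq_len(G))
    }
    starts <- (seq_len(G) - 1L) * 1000L + 1L
    gene_rows[[gi]] <- data.frame(
      genome_id = g, replicon_id = paste0(g, "_chr"),
      gene_id = sprintf("%s_g%04d", g, seq_len(G)),
      start = starts, end = starts + 899L,
      strand = sample(c("+", "-"), G, replace = TRUE),
      families = fams, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  genomes <- data.frame(
    genome_id = genome_ids,
    species = paste0("Species_", genome_ids),
    domain = "bacteria",
    lineage = unname(truth$lineage[genome_ids]),
    habitat = unname(truth$habitat[genome_ids]),
    stringsAsFactors = FALSE)
  catalog <- data.frame(
    family_id = c(rownames(states), names(config$candidates), super_ids,
                  bg_ids),
    description = "",
    role = c(rep("known-Se-marker", nrow(states)),
             rep("candidate", length(config$candidates)),
             rep("background", length(super_ids) + length(bg_ids))),
    stringsAsFactors = FALSE)
  comp <- compendium(genes, genomes = genomes, family_catalog = catalog)
  attr(comp, "placements") <- if (length(placements) > 0L) {
    do.call(rbind, placements)
  } else {
    data.frame()
  }
  attr(comp, "islands") <- if (length(island_rows) > 0L) {
    do.call(rbind, island_rows)
  } else {
    data.frame()
  }
  comp
}

#' Generate noisy forward/reverse homology score tables
#'
#' One reference protein per marker and candidate family (`REF_<family>`)
#' hits every gene of that family with a low E-value (log-uniform in
#' `[1e-50, 1e-5]`); spurious hits are injected per (query, genome) at the
#' configured rate with E-values log-uniform across a range straddling the
#' 0.1 cutoff. The reverse table maps every true family gene back to its
#' reference protein, plus its own spurious hits.
#'
#' @param comp a synthetic `compendium`.
#' @param config the [sim_config()].
#' @param seed optional integer seed.
#' @return list with `forward`, `reverse` (hit tables) and `truth`
#'   (data.frame of the planted ortholog pairs: `query_id`, `genome_id`,
#'   `subject_gene_id`).
#' @export
generate_score_tables <- function(comp, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fam_list <- split_families(comp$genes$families)
  families <- c(config$trait_rates$family_id, names(config$candidates))
  genome_ids <- comp$genomes$genome_id
  fwd <- list(); rev <- list(); truth <- list()
  rlog_e <- function(n, lo, hi) 10^stats::runif(n, lo, hi)
  for (fam in families) {
    q <- paste0("REF_", fam)
    carrier <- vapply(fam_list, function(f) fam %in% f, logical(1))
    genes <- comp$genes[carrier, , drop = FALSE]
    if (nrow(genes) > 0L) {
      fwd[[length(fwd) + 1L]] <- data.frame(
        query_id = q, genome_id = genes$genome_id,
        subject_gene_id = genes$gene_id,
        evalue = rlog_e(nrow(genes), -50, -5),
        bitscore = stats::runif(nrow(genes), 200, 500),
        stringsAsFactors = FALSE)
      rev[[length(rev) + 1L]] <- data.frame(
        query_id = genes$gene_id, genome_id = genes$genome_id,
        subject_gene_id = q,
        evalue = rlog_e(nrow(genes), -50, -5),
        bitscore = stats::runif(nrow(genes), 200, 500),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        query_id = q, genome_id = genes$genome_id,
        subject_gene_id = genes$gene_id, stringsAsFactors = FALSE)
    }
    # spurious forward hits: random gene of the genome
    spur <- genome_ids[stats::runif(length(genome_ids)) <
                         config$score_noise$rate]
    for (g in spur) {
      pool <- comp$genes$gene_id[comp$genes$genome_id == g]
      fwd[[length(fwd) + 1L]] <- data.frame(
        query_id = q, genome_id = g,
        subject_gene_id = sample(pool, 1L),
        evalue = rlog_e(1L, config$score_noise$log10_min,
                        config$score_noise$log10_max),
        bitscore = stats::runif(1L, 20, 60), stringsAsFactors = FALSE)
    }
  }
  # spurious reverse hits: random gene -> random reference protein
  n_spur_rev <- stats::rpois(1L, config$score_noise$rate * length(genome_ids) *
                               length(families))
  if (n_spur_rev > 0L) {
    idx <- sample.int(nrow(comp$genes), n_spur_rev, replace = TRUE)
    rev[[length(rev) + 1L]] <- data.frame(
      query_id = comp$genes$gene_id[idx],
      genome_id = comp$genes$genome_id[idx],
      subject_gene_id = paste0("REF_", sample(families, n_spur_rev,
                                              replace = TRUE)),
      evalue = rlog_e(n_spur_rev, config$score_noise$log10_min,
                      config$score_noise$log10_max),
      bitscore = stats::runif(n_spur_rev, 20, 60), stringsAsFactors = FALSE)
  }
  list(forward = do.call(rbind, fwd), reverse = do.call(rbind, rev),
       truth = do.call(rbind, truth))
}

#' Generate a synthetic alignment with planted conserved columns
#'
#' Residues are uniform over the 20 amino acids except at the specified
#' columns, which are fixed to the given residue (spell consecutive columns
#' to plant a motif).
#'
#' @param n_seqs number of sequences.
#' @param length alignment length.
#' @param conserved_columns named character vector, column index (as name) ->
#'   residue. Conflicting duplicate specifications are an error.
#' @param seed optional integer seed.
#' @return named character vector of aligned sequences `seq1..seqN`.
#' @export
generate_msa <- function(n_seqs, length, conserved_columns = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(conserved_columns)) {
    cols <- as.integer(names(conserved_columns))
    if (any(is.na(cols)) || any(cols < 1L) || any(cols > length)) {
      stop("conserved column indices must lie within the alignment")
    }
    if (anyDuplicated(cols)) {
      dup <- cols[duplicated(cols)]
      conflicting <- vapply(unique(dup), function(cl) {
        length(unique(conserved_columns[names(conserved_columns) ==
                                          as.character(cl)])) > 1L
      }, logical(1))
      if (any(conflicting)) {
        stop("conflicting residue specifications for column(s): ",
             paste(unique(dup)[conflicting], collapse = ", "))
      }
    }
  }
  m <- matrix(sample(AA_ALPHABET, n_seqs * length, replace = TRUE),
              nrow = n_seqs)
  if (!is.null(conserved_columns)) {
    for (k in seq_along(conserved_columns)) {
      m[, as.integer(names(conserved_columns)[k])] <-
        toupper(conserved_columns[[k]])
    }
  }
  stats::setNames(apply(m, 1L, paste, collapse = ""),
                  paste0("seq", seq_len(n_seqs)))
}
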