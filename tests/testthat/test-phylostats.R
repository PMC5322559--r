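test_that("chi-square 2x2 matches the closed form, stats::chisq.test and the erfc oracle", {
  # no association: statistic 0, p 1
  flat <- chisq_2x2(c(10, 10, 10, 10), yates = FALSE)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  # hand-evaluated closed form: n|ad-bc|^2 / product of margins
  strong <- chisq_2x2(c(30, 5, 5, 30), yates = FALSE)
  expect_equal(strong$statistic, 70 * 875^2 / (35 * 35 * 35 * 35),
               tolerance = 1e-12)
  expect_equal(strong$statistic, 35.71, tolerance = 1e-3)
  yates <- chisq_2x2(c(30, 5, 5, 30), yates = TRUE)
  expect_equal(yates$statistic, 70 * 840^2 / (35 * 35 * 35 * 35),
               tolerance = 1e-12)
  expect_equal(yates$statistic, 32.91, tolerance = 1e-3)
  expect_equal(strong$direction, 1)
  expect_equal(chisq_2x2(c(5, 30, 30, 5))$direction, -1)

  # degenerate margin
  degen <- chisq_2x2(c(0, 0, 5, 7))
  expect_true(degen$degenerate)
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p.value, 1)

  set.seed(1001)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 15) + 1, 2, 2)
    mine_u <- chisq_2x2(tab, yates = FALSE)
    mine_y <- chisq_2x2(tab, yates = TRUE)
    ref_u <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    ref_y <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(mine_u$statistic, unname(ref_u$statistic), tolerance = 1e-10)
    expect_equal(mine_u$p.value, ref_u$p.value, tolerance = 1e-10)
    expect_equal(mine_y$statistic, unname(ref_y$statistic), tolerance = 1e-10)
    # erfc-route survival function
    expect_equal(mine_u$p.value, chisq1_sf_erfc(mine_u$statistic),
                 tolerance = 1e-10)
    # Yates never exceeds the uncorrected statistic
    expect_lte(mine_y$statistic, mine_u$statistic)
    # invariant under transpose and under swapping both labels
    expect_equal(chisq_2x2(t(tab), yates = FALSE)$statistic,
                 mine_u$statistic, tolerance = 1e-12)
    swapped <- tab[2:1, 2:1]
    expect_equal(chisq_2x2(swapped, yates = FALSE)$statistic,
                 mine_u$statistic, tolerance = 1e-12)
  }
})

test_that("co-occurrence tables equal brute-force pair counting", {
  set.seed(1002)
  for (i in 1:10) {
    x <- runif(60) < 0.5
    y <- runif(60) < 0.4
    ct <- cooccurrence_test(x, y)
    brute <- c(0, 0, 0, 0)
    for (j in 1:60) {
      k <- if (x[j] && y[j]) 1 else if (x[j]) 2 else if (y[j]) 3 else 4
      brute[k] <- brute[k] + 1
    }
    expect_equal(as.vector(t(ct$table)), brute)
  }
  x <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  ident <- cooccurrence_test(x, x, yates = FALSE)
  expect_equal(ident$test$direction, 1)
  expect_equal(ident$test$statistic, 5)  # maximal for these margins: n
  compl <- cooccurrence_test(x, !x)
  expect_equal(compl$test$direction, -1)
  expect_error(cooccurrence_test(x, x[-1]), "length")
})

test_that("Fisher exact matches enumeration and stats::fisher.test", {
  # 1 / choose(6, 3)
  expect_equal(fisher_exact_2x2(c(3, 0, 0, 3), side = "greater"), 0.05)
  expect_equal(fisher_exact_2x2(c(0, 0, 3, 3)), 1)  # zero margin

  set.seed(1003)
  for (i in 1:60) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2, 2)
    if (sum(tab) == 0) next
    for (side in c("greater", "two.sided")) {
      mine <- fisher_exact_2x2(tab, side = side)
      expect_equal(mine, brute_fisher(tab[1, 1], tab[1, 2], tab[2, 1],
                                      tab[2, 2], side = side),
                   tolerance = 1e-12)
      alt <- if (side == "greater") "greater" else "two.sided"
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        expect_equal(mine, stats::fisher.test(tab, alternative = alt)$p.value,
                     tolerance = 1e-9)
      }
    }
    # point probabilities over the support sum to 1
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    if (m > 0 && n2 > 0) {
      support <- max(0, k - n2):min(k, m)
      expect_equal(sum(stats::dhyper(support, m, n2, k)), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("protein distances: closed forms, gap handling, caps, brute force", {
  msa <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL")
  D <- protein_distances(msa)
  expect_equal(D["a", "b"], 0)

  # p = 0.1 -> Poisson distance -ln(0.9)
  msa2 <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC")
  expect_equal(protein_distances(msa2, model = "p")["a", "b"], 0.1)
  expect_equal(protein_distances(msa2)["a", "b"], -log(0.9),
               tolerance = 1e-12)

  # pairwise-complete columns: gaps excluded per pair
  msa3 <- c(a = "AC-EF", b = "ACDE-", cc = "GCDEF")
  D3 <- protein_distances(msa3, model = "p")
  expect_equal(D3["a", "b"], 0)        # columns 1,2,4 compared, all equal
  expect_equal(D3["a", "cc"], 0.25)    # columns 1,2,4,5; mismatch at 1

  # saturated pair capped and flagged
  msa4 <- c(a = "AAAA", b = "CCCC")
  D4 <- protein_distances(msa4, max_distance = 10)
  expect_equal(D4["a", "b"], 10)
  expect_equal(attr(D4, "capped"), "a|b")

  # a pair with zero comparable columns errors, naming the pair
  expect_error(protein_distances(c(a = "A---", b = "-CCC")), "a and b")

  # 5 random sequences vs per-pair manual count
  set.seed(1004)
  seqs <- generate_msa(5, 40)
  gappy <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[runif(40) < 0.15] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  D5 <- protein_distances(gappy, model = "p")
  mats <- do.call(rbind, strsplit(gappy, ""))
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- mats[i, ] != "-" & mats[j, ] != "-"
    expect_equal(D5[i, j], sum(mats[i, ok] != mats[j, ok]) / sum(ok))
  }
  expect_true(isSymmetric(unname(D5)))
  expect_equal(diag(D5), setNames(rep(0, 5), rownames(D5)))
})

test_that("PHYLIP square distance matrices round-trip", {
  set.seed(1005)
  ra <- random_additive(6)
  path <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(ra$D, path)
  back <- read_phylip_dist(path)
  expect_equal(back, ra$D, tolerance = 1e-5)
  expect_equal(rownames(back), rownames(ra$D))
})

test_that("neighbor joining: closed forms for 2 and 3 taxa", {
  # 3 taxa with distances 3, 4, 5 -> pendant branches 1, 2, 3
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len, c(A = 1, B = 2, C = 3))

  # 2 taxa: the connecting path has length d
  D2 <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- neighbor_joining(D2)
  expect_equal(unname(ape::cophenetic.phylo(tr2)["A", "B"]), 7)

  # asymmetry beyond tolerance rejected
  D3 <- D
  D3[1, 2] <- 3.001
  expect_error(neighbor_joining(D3), "asymmetric")
})

test_that("neighbor joining recovers additive trees and agrees with ape::nj", {
  set.seed(1006)
  for (rep in 1:15) {
    ra <- random_additive(sample(5:10, 1))
    tr <- neighbor_joining(ra$D)
    # topology identical to the generating tree
    expect_equal(ape::dist.topo(ape::unroot(ra$tree), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    # all pairwise path lengths reproduced
    co <- ape::cophenetic.phylo(tr)
    expect_equal(co[rownames(ra$D), colnames(ra$D)], ra$D, tolerance = 1e-9)
    # independent implementation agrees on topology
    ref <- ape::nj(ra$D)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("neighbor joining output is invariant under taxon permutation", {
  set.seed(1007)
  ra <- random_additive(7)
  tr1 <- neighbor_joining(ra$D)
  perm <- sample(7)
  tr2 <- neighbor_joining(ra$D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  co1 <- ape::cophenetic.phylo(tr1)
  co2 <- ape::cophenetic.phylo(tr2)
  expect_equal(co2[rownames(co1), colnames(co1)], co1, tolerance = 1e-9)
})

test_that("negative NJ branch estimates are clamped and logged", {
  # a deliberately non-additive matrix that produces a negative estimate
  D <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D[1, 2] <- D[2, 1] <- 8  # inflate within-pair distance
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "negative_branch_deficit"), 0)
})

test_that("clade enrichment scan equals exhaustive edge enumeration", {
  # planted: one 5-leaf clade all trait+, 10 other leaves trait-
  clade <- ape::read.tree(text = "((p1:1,p2:1):1,(p3:1,(p4:1,p5:1):1):1):1;")
  rest <- paste0("(n", 1:10, ":1", collapse = ",")
  tree <- ape::read.tree(text = paste0(
    "(", paste0("((p1:1,p2:1):1,(p3:1,(p4:1,p5:1):1):1):1,",
                paste(paste0("n", 1:10, ":1"), collapse = ","), ");")))
  lab <- setNames(grepl("^p", tree$tip.label), tree$tip.label)
  scan <- clade_enrichment_scan(tree, lab)
  expect_false(scan$uninformative)
  expect_setequal(strsplit(scan$best$leaves, ";")[[1]], paste0("p", 1:5))
  expect_equal(scan$best$in_pos, 5)
  expect_equal(scan$best$in_neg, 0)

  # all leaves one label -> uninformative, p = 1 everywhere
  uni <- clade_enrichment_scan(tree, setNames(rep(TRUE, 15), tree$tip.label))
  expect_true(uni$uninformative)
  expect_true(all(uni$table$p == 1))

  # random labels on random trees vs BFS + fisher.test oracle
  set.seed(1008)
  for (rep in 1:8) {
    n <- sample(6:14, 1)
    tr <- ape::rtree(n)
    lab <- setNames(runif(n) < 0.5, tr$tip.label)
    if (sum(lab) == 0 || sum(!lab) == 0) next
    scan <- clade_enrichment_scan(tr, lab)
    oracle <- brute_clade_scan(tr, lab)
    expect_equal(scan$best$p, oracle$best$p, tolerance = 1e-9)
    # the full ranking agrees on the attained p-values
    expect_equal(sort(scan$table$p),
                 sort(vapply(oracle$all, `[[`, numeric(1), "p")),
                 tolerance = 1e-9)
  }

  expect_error(clade_enrichment_scan(ape::rtree(3),
                                     setNames(c(TRUE, TRUE, FALSE),
                                              paste0("t", 1:3))),
               "4 leaves")
})

test_that("conservation scan flags conserved columns and skips gappy ones", {
  msa <- c(s1 = "CAC-", s2 = "CAS-", s3 = "CCC-", s4 = "CAC-")
  res <- conservation_scan(msa, min_freq = 0.75, residue_filter = "C")
  # column 1: all C (freq 1); column 2: A 0.75 but residue filter blocks;
  # column 3: C 0.75; column 4: all gaps -> skipped
  expect_equal(res$flagged, c(1L, 3L))
  expect_true(res$profile$skipped[4])
  expect_equal(res$profile$freq[2], 0.75)
  res_nofilter <- conservation_scan(msa, min_freq = 0.75)
  expect_equal(res_nofilter$flagged, 1:3)
  res_strict <- conservation_scan(msa, min_freq = 0.76)
  expect_equal(res_strict$flagged, 1L)

  # > 50% gaps skipped even if the remainder is invariant
  msa2 <- c(s1 = "C-", s2 = "C-", s3 = "C-", s4 = "CA", s5 = "CA")
  res2 <- conservation_scan(msa2, min_freq = 0.9)
  expect_true(res2$profile$skipped[2])
  expect_false(2L %in% res2$flagged)

  # random MSA vs brute-force column counting
  set.seed(1009)
  msa3 <- generate_msa(10, 60, conserved_columns = c(`7` = "C", `30` = "W"))
  res3 <- conservation_scan(msa3, min_freq = 0.9)
  mats <- do.call(rbind, strsplit(msa3, ""))
  brute_flags <- which(vapply(seq_len(60), function(j) {
    max(table(mats[, j])) / 10 >= 0.9
  }, logical(1)))
  expect_equal(res3$flagged, brute_flags)
  expect_true(all(c(7L, 30L) %in% res3$flagged))

  expect_error(conservation_scan(msa, min_freq = 0), "min_freq")
})

test_that("motif scan finds wildcard motifs on ungapped coordinates", {
  expect_equal(motif_scan(c(s = "ACPAPD"), "CPXP")$position, 2L)
  expect_equal(motif_scan(c(s = "ACGTC"), "CGXC")$position, 2L)

  # positions are 1-based on the ungapped sequence; column maps to alignment
  hit <- motif_scan(c(s = "--ACPAPD--"), "CPXP")
  expect_equal(hit$position, 2L)
  expect_equal(hit$column, 4L)

  # overlapping matches all reported
  expect_equal(motif_scan(c(s = "CACAC"), "CXC")$position, c(1L, 3L))

  expect_error(motif_scan(c(s = "ACDEF"), "CPZP"), "Z")
  expect_error(motif_scan(c(s = "ACDEF"), ""), "non-empty")

  # random sequences vs naive sliding window
  set.seed(1010)
  seqs <- generate_msa(50, 30)
  hits <- motif_scan(seqs, "CGXC")
  for (id in names(seqs)) {
    s <- strsplit(seqs[[id]], "")[[1]]
    naive <- integer(0)
    for (p in 1:(30 - 3)) {
      if (s[p] == "C" && s[p + 1] == "G" && s[p + 3] == "C") {
        naive <- c(naive, p)
      }
    }
    expect_equal(hits$position[hits$seq_id == id], naive)
  }
})
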