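test_that("tree simulation is deterministic and matches the Yule depth", {
  t1 <- simulate_tree(12, seed = 9)
  t2 <- simulate_tree(12, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 12L)

  t_small <- simulate_tree(2, seed = 9)
  expect_equal(length(t_small$tip.label), 2L)
  expect_error(simulate_tree(1), "n_taxa")

  # trees are ultrametric; mean root-to-tip depth matches the harmonic sum
  # E[depth] = sum_{k=2..n} 1/k within 3 standard errors over 200 replicates
  set.seed(10)
  n <- 50
  depths <- replicate(200, {
    tr <- simulate_tree(n)
    max(ape::node.depth.edgelength(tr))
  })
  expected <- sum(1 / (2:n))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
  tr <- simulate_tree(20, seed = 4)
  tip_depths <- ape::node.depth.edgelength(tr)[1:20]
  expect_lt(diff(range(tip_depths)), 1e-8)  # ultrametric
})

test_that("binary trait evolution follows the closed-form transition law", {
  tr <- simulate_tree(30, seed = 11)
  # loss rate 0, root present -> presence is absorbing
  expect_true(all(evolve_binary_trait(tr, gain = 1, loss = 0,
                                      root_state = TRUE, seed = 1)))
  # gain rate 0, root absent -> absence is absorbing
  expect_false(any(evolve_binary_trait(tr, gain = 0, loss = 1,
                                       root_state = FALSE, seed = 1)))
  expect_error(evolve_binary_trait(tr, 0, 0), "positive")

  # long branches: leaf frequency approaches the stationary gain/(gain+loss)
  star <- star_tree(400, branch_length = 50)
  set.seed(12)
  states <- evolve_binary_trait(star, gain = 1, loss = 3, root_state = TRUE)
  p_hat <- mean(states)
  se <- sqrt(0.25 * 0.75 / 400)
  expect_lt(abs(p_hat - 0.25), 3 * se)

  # closed-form transition probability vs a fine-grained event simulation
  # on a single branch
  gain <- 0.7; loss <- 1.4; t_branch <- 0.9
  p_closed <- transition_prob_present(t_branch, gain, loss,
                                      from_present = FALSE)
  set.seed(13)
  n_rep <- 4000
  dt <- t_branch / 2000
  ends <- replicate(n_rep, {
    s <- FALSE
    for (step in 1:2000) {
      rate <- if (s) loss else gain
      if (runif(1) < rate * dt) s <- !s
    }
    s
  })
  se_mc <- sqrt(p_closed * (1 - p_closed) / n_rep)
  # small-step discretisation bias is O(dt); allow it on top of MC error
  expect_lt(abs(mean(ends) - p_closed), 3 * se_mc + 2 * dt * (gain + loss))

  # stationary frequency recovered from many leaves (parameter recovery)
  star2 <- star_tree(200, branch_length = 50)
  set.seed(14)
  states2 <- evolve_binary_trait(star2, gain = 2, loss = 2, root_state = FALSE)
  expect_lt(abs(mean(states2) - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("compendium layout honors linkage probabilities", {
  # p_link = 1: every island-bearing genome has the candidate in-window
  cfg1 <- sim_config(n_taxa = 15, seed = 21, candidates = c(YedE = 1),
                     n_background_families = 20, genes_per_genome = 120)
  sim1 <- simulate_se_compendium(cfg1)
  pl1 <- sim1$truth$placements
  expect_true(all(pl1$in_window[pl1$island_genome & pl1$family_id == "YedE"]))

  # p_link = 0: placement is uniform, so the in-window rate follows the
  # null window-size / genes_per_genome rate (binomial 3-sigma band)
  cfg0 <- sim_config(n_taxa = 60, seed = 22, candidates = c(YedE = 0),
                     n_background_families = 10, genes_per_genome = 200)
  sim0 <- simulate_se_compendium(cfg0)
  pl0 <- sim0$truth$placements
  pl0 <- pl0[pl0$island_genome, ]
  isl <- sim0$truth$islands
  n_isl <- nrow(isl)
  # expected null rate: mean window span / genome length
  span <- mean(2 * cfg0$window_radius + (isl$end_slot - isl$start_slot + 1))
  p_null <- span / cfg0$genes_per_genome
  rate <- mean(pl0$in_window)
  se <- sqrt(p_null * (1 - p_null) / nrow(pl0))
  expect_lt(abs(rate - p_null), 3 * se + 0.02)

  # island genes are contiguous and in layout order
  one <- isl[1, ]
  genes <- sim0$compendium$genes
  g <- genes[genes$genome_id == one$genome_id, ]
  island_fams <- g$families[g$rank >= one$start_slot - 1 &
                              g$rank <= one$end_slot - 1]
  expect_equal(island_fams[island_fams != ""],
               strsplit(one$families, ";")[[1]])
})

test_that("score tables recover planted orthologs", {
  cfg <- sim_config(n_taxa = 12, seed = 31, n_background_families = 20,
                    genes_per_genome = 120)
  sim <- simulate_se_compendium(cfg)

  # noiseless: BBH recovers the planted ortholog map exactly
  cfg0 <- cfg
  cfg0$score_noise$rate <- 0
  st0 <- generate_score_tables(sim$compendium, cfg0, seed = 32)
  pairs0 <- bbh_orthologs(filter_hits(st0$forward), filter_hits(st0$reverse))
  got <- paste(pairs0$query_id, pairs0$genome_id, pairs0$subject_gene_id)
  want <- paste(st0$truth$query_id, st0$truth$genome_id,
                st0$truth$subject_gene_id)
  expect_setequal(got, want)

  # spurious hits entirely above the cutoff are removed by the filter
  cfg_hi <- cfg
  cfg_hi$score_noise <- list(rate = 0.3, log10_min = log10(0.2),
                             log10_max = 1)
  st_hi <- generate_score_tables(sim$compendium, cfg_hi, seed = 33)
  spurious <- st_hi$forward$evalue > 1e-5
  expect_true(any(spurious))
  kept <- filter_hits(st_hi$forward, 0.1)
  expect_true(all(kept$evalue <= 1e-5))

  # moderate noise: precision and recall vs truth both >= 0.95
  cfg_mid <- sim_config(n_taxa = 30, seed = 34, n_background_families = 20,
                        genes_per_genome = 120)
  sim_mid <- simulate_se_compendium(cfg_mid)
  st <- generate_score_tables(sim_mid$compendium, cfg_mid, seed = 35)
  pairs <- bbh_orthologs(filter_hits(st$forward), filter_hits(st$reverse))
  got <- paste(pairs$query_id, pairs$genome_id, pairs$subject_gene_id)
  want <- paste(st$truth$query_id, st$truth$genome_id,
                st$truth$subject_gene_id)
  precision <- mean(got %in% want)
  recall <- mean(want %in% got)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("generated MSAs plant conserved columns and motifs", {
  msa <- generate_msa(8, 50, conserved_columns = c(`12` = "C"), seed = 41)
  scan <- conservation_scan(msa, min_freq = 1, residue_filter = "C")
  expect_true(12L %in% scan$flagged)

  # planted CPXP motif found at its position
  msa2 <- generate_msa(6, 40,
                       conserved_columns = c(`5` = "C", `6` = "P", `8` = "P"),
                       seed = 42)
  hits <- motif_scan(msa2, "CPXP")
  expect_true(all(5L %in% hits$position[!duplicated(hits$seq_id)]))
  expect_equal(length(unique(hits$seq_id)), 6L)

  expect_error(generate_msa(5, 20, conserved_columns = c(`3` = "C", `3` = "W")),
               "conflicting")
  expect_error(generate_msa(5, 20, conserved_columns = c(`25` = "C")),
               "within the alignment")

  # uniform columns: count of columns where 'A' appears >= 4 times out of 20
  # follows Binomial(200, P(Binom(20, 1/20) >= 4)) — 3-sigma band
  set.seed(43)
  msa3 <- generate_msa(20, 200)
  mats <- do.call(rbind, strsplit(msa3, ""))
  n_hit <- sum(colSums(mats == "A") >= 4)
  p <- 1 - pbinom(3, 20, 1 / 20)
  expect_lt(abs(n_hit - 200 * p), 3 * sqrt(200 * p * (1 - p)) + 1)
})

test_that("simulation is end-to-end deterministic for a fixed seed", {
  run_once <- function() {
    sim <- simulate_se_compendium(sim_config(n_taxa = 14, seed = 51,
                                             n_background_families = 25,
                                             genes_per_genome = 120))
    cand <- nominate_candidates(sim$compendium, known_se_families(),
                                min_recurrence = 2, min_phyla = 1)
    list(genes = sim$compendium$genes, cand = as.data.frame(cand),
         newick = ape::write.tree(sim$truth$tree))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$genes, b$genes)
  expect_identical(a$cand, b$cand)
  expect_identical(a$newick, b$newick)
})

test_that("habitat labels follow the configured trait association", {
  cfg <- sim_config(n_taxa = 200, seed = 61, n_background_families = 5,
                    genes_per_genome = 80,
                    habitat_model = c(aquatic_if_selD = 0.8,
                                      aquatic_if_no_selD = 0.2))
  sim <- simulate_se_compendium(cfg)
  selD <- sim$truth$states["SelD", ]
  habitat <- sim$truth$habitat
  p_aq_selD <- mean(habitat[selD] == "aquatic")
  p_aq_no <- mean(habitat[!selD] == "aquatic")
  expect_lt(abs(p_aq_selD - 0.8), 3 * sqrt(0.16 / sum(selD)))
  expect_lt(abs(p_aq_no - 0.2), 3 * sqrt(0.16 / sum(!selD)))

  # habitat_summary recovers the planted association from the compendium
  pm <- build_presence_matrix(sim$compendium)
  prof <- classify_traits(pm)
  hs <- habitat_summary(prof, sim$compendium)
  expect_gt(hs$percent[hs$habitat == "aquatic"],
            hs$percent[hs$habitat == "nonaquatic"])
})
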