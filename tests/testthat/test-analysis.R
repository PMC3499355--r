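# reusable 4-tip setup: two clades of two genomes
setup_small <- function(combos_by_genome,
                        newick = "((A,B)AB,(C,D)CD)R;") {
  tree <- read_tree(text = newick)
  reps <- reps_from_combos(combos_by_genome)
  X <- build_character_matrix(reps, tree, "combinations")
  results <- reconstruct_characters(tree, X, "fitch")
  list(tree = tree, reps = reps, results = results,
       summary = summarize_origins(results, reps))
}

test_that("origin counts distinguish inherited from reappearing combinations", {
  s <- setup_small(list(A = c("X~Y", "Q~R"), B = "X~Y",
                        C = c("X~Y", "S~T"), D = "X~Y"))
  per <- s$summary$per_combination
  # X~Y present everywhere -> ancestral, one appearance at the root
  expect_equal(per$n_origins[per$combination == "X~Y"], 1)
  # species-specific combos gain once at their tip
  expect_true(all(per$species_specific[per$combination %in% c("Q~R", "S~T")]))
  expect_equal(per$n_origins[per$combination == "Q~R"], 1)
  expect_equal(s$results[["Q~R"]]$gain_nodes, "A")
  expect_equal(s$summary$n_distinct, 3)
  expect_equal(s$summary$n_reappearing, 0)

  # disjoint double presence -> two independent origins
  s2 <- setup_small(list(A = "U~V", B = "B~Z", C = "U~V", D = "W~Z"))
  expect_equal(s2$summary$per_combination$n_origins[
    s2$summary$per_combination$combination == "U~V"], 2)
  expect_equal(s2$summary$n_reappearing, 1)

  # a result must exist for every observed combination
  expect_error(summarize_origins(s$results["X~Y"], s$reps), "no parsimony result")
})

test_that("histogram conservation: counts sum to the distinct total", {
  sim <- simulate_evolution(params = sim_params(
    n_tips = 15, gain_rate = 2, loss_rate = 2, seed = 37))
  reps <- build_repertoires(build_architectures(
    resolve_overlaps_by_protein(sim$hits)))
  X <- build_character_matrix(reps, sim$tree, "combinations")
  results <- reconstruct_characters(sim$tree, X, "fitch")
  summ <- summarize_origins(results, reps)
  expect_equal(sum(summ$histogram), summ$n_distinct)
  expect_equal(sum(summ$histogram[as.integer(names(summ$histogram)) >= 2]),
               summ$n_reappearing)
  # species-specific combinations have exactly one gain at their own tip
  per <- summ$per_combination
  for (cmb in per$combination[per$species_specific]) {
    r <- results[[cmb]]
    expect_equal(r$n_gains, 1)
    carrier <- names(which(vapply(reps, function(x) cmb %in% x$combinations,
                                  TRUE)))
    expect_equal(r$gain_nodes, carrier)
  }
})

test_that("parallel-evolution percentages follow their definitions", {
  # synthetic totals: 100 distinct, 40 species-specific, 30 reappearing
  fake <- structure(list(n_distinct = 100L, n_species_specific = 40L,
                         n_reappearing = 30L), class = "origin_summary")
  p <- percent_parallel(fake)
  expect_equal(p$pct_of_total, 30)
  expect_equal(p$pct_of_recurring, 50)
  all_single <- structure(list(n_distinct = 50L, n_species_specific = 0L,
                               n_reappearing = 0L), class = "origin_summary")
  p0 <- percent_parallel(all_single)
  expect_equal(p0$pct_of_total, 0)
  expect_equal(p0$pct_of_recurring, 0)
  degenerate <- structure(list(n_distinct = 5L, n_species_specific = 5L,
                               n_reappearing = 0L), class = "origin_summary")
  expect_true(is.na(percent_parallel(degenerate)$pct_of_recurring))
})

test_that("per-genome ratios count combinations with off-lineage origins", {
  # all species-specific -> ratio 0
  s <- setup_small(list(A = c("Q~R", "Q~S"), B = "T~U", C = "V~W", D = "X~Y"))
  pg <- per_genome_parallel_ratio(s$results, s$reps, s$tree)
  expect_true(all(pg$ratio == 0))

  # two disjoint tip gains count toward both carrier genomes' ratios
  four <- read_tree(text = "((A,B)AB,(C,D)CD)R;")
  reps2 <- reps_from_combos(list(A = "X~Y", C = "X~Y"))
  X2 <- build_character_matrix(reps2, four, "combinations")
  res2 <- reconstruct_characters(four, X2, "fitch")
  expect_equal(res2[["X~Y"]]$n_gains, 2)
  pg2 <- per_genome_parallel_ratio(res2, reps2, four)
  expect_equal(pg2$ratio, c(1, 1))

  # an ancestral (root) combination does not count as parallel
  anc <- setup_small(list(A = "X~Y", B = "X~Y", C = "X~Y", D = "X~Y"))
  pg3 <- per_genome_parallel_ratio(anc$results, anc$reps, anc$tree)
  expect_true(all(pg3$ratio == 0))

  bad_reps <- reps_from_combos(list(NOPE = "X~Y"))
  expect_error(per_genome_parallel_ratio(s$results, bad_reps, s$tree),
               "not a tip")
})

test_that("per-genome ratios equal a direct truth-log recount", {
  sim <- simulate_evolution(params = sim_params(
    n_tips = 12, gain_rate = 2, loss_rate = 1, seed = 41))
  reps <- build_repertoires(build_architectures(sim$hits))
  X <- build_character_matrix(reps, sim$tree, "combinations")
  results <- reconstruct_characters(sim$tree, X, "fitch")
  pg <- per_genome_parallel_ratio(results, reps, sim$tree)
  nm <- node_names(sim$tree)
  for (i in seq_len(nrow(pg))) {
    g <- pg$genome_id[i]
    lineage <- nm[node_ancestors(sim$tree, g)]
    recount <- sum(vapply(reps[[g]]$combinations, function(cmb) {
      r <- results[[cmb]]
      r$n_gains >= 2 && any(!(r$gain_nodes %in% lineage))
    }, TRUE))
    expect_equal(pg$n_parallel[i], recount)
  }
})

test_that("clade-specific and core sets obey their set algebra", {
  tree <- read_tree(text = "((A,B)AB,(C,D)CD)R;")
  reps <- reps_from_combos(list(
    A = c("X~Y", "P~Q"), B = c("X~Y"),          # X~Y core+specific to AB
    C = c("P~Q", "M~N"), D = c("K~L")))         # P~Q crosses clades
  cs <- clade_sets(reps, tree, c("AB", "CD"))
  expect_equal(cs$clades$AB$specific_combinations, "X~Y")
  expect_equal(cs$clades$AB$core_combinations, "X~Y")
  expect_setequal(cs$clades$CD$specific_combinations, c("M~N", "K~L"))
  expect_equal(cs$clades$CD$core_combinations, character(0))  # not in all
  expect_equal(unname(cs$species_specific_counts),
               c(0, 0, 1, 1))    # M~N in C, K~L in D
  expect_error(clade_sets(reps, tree, "ZZ"), "unknown")

  # brute-force recomputation on random repertoires over a 10-tip tree
  set.seed(43)
  tr10 <- ape::rtree(10)
  tr10$node.label <- paste0("n", seq_len(tr10$Nnode))
  pool <- apply(expand.grid(sprintf("D%d", 1:5), sprintf("D%d", 6:9)), 1,
                paste, collapse = "~")
  combos <- lapply(tr10$tip.label, function(g)
    sample(pool, sample(3:10, 1)))
  names(combos) <- tr10$tip.label
  reps10 <- reps_from_combos(combos)
  clades <- c("n2", "n5")
  cs10 <- clade_sets(reps10, tr10, clades)
  for (cl in clades) {
    members <- clade_tips(tr10, cl)
    outside <- setdiff(tr10$tip.label, members)
    for (cmb in pool) {
      inside_n <- sum(vapply(members, function(g) cmb %in% combos[[g]], TRUE))
      outside_n <- sum(vapply(outside, function(g) cmb %in% combos[[g]], TRUE))
      expect_equal(cmb %in% cs10$clades[[cl]]$specific_combinations,
                   inside_n >= 1 && outside_n == 0)
      expect_equal(cmb %in% cs10$clades[[cl]]$core_combinations,
                   inside_n == length(members) && outside_n == 0)
    }
    # core is always a subset of specific
    expect_true(all(cs10$clades[[cl]]$core_combinations %in%
                      cs10$clades[[cl]]$specific_combinations))
  }
})

test_that("supergroup buckets partition the distinct combinations", {
  reps <- reps_from_combos(list(
    A = c("X~Y"), B = c("X~Y", "P~Q"), C = c("P~Q", "M~N"), D = c("M~N")))
  mapping <- data.frame(genome_id = c("A", "B", "C", "D"),
                        supergroup = c("G1", "G1", "G2", "G2"))
  sg <- supergroup_distribution(reps, mapping)
  expect_equal(unname(sg$exclusive["G1"]), 1L)     # X~Y
  expect_equal(unname(sg$exclusive["G2"]), 1L)     # M~N
  expect_equal(sg$shared, 1L)                      # P~Q
  expect_equal(sg$in_all_groups, 1L)
  expect_equal(sum(sg$exclusive) + sg$shared, sg$n_distinct)
  expect_error(supergroup_distribution(
    reps, mapping[1:3, ]), "unmapped")

  # conservation on simulated data with the generator's mapping
  sim <- simulate_evolution(params = sim_params(n_tips = 10, seed = 47))
  reps_s <- build_repertoires(build_architectures(sim$hits))
  sg_s <- supergroup_distribution(reps_s, sim$supergroups)
  expect_equal(sum(sg_s$exclusive) + sg_s$shared, sg_s$n_distinct)
})

test_that("LCA rates distribute gain-node pairs with leaf normalization", {
  tree <- read_tree(text = "(((A,B)AB,C)ABC,D)R;")
  # two gains at the tips of the cherry -> one pair at AB, rate 1/2
  reps <- reps_from_combos(list(A = "X~Y", B = "X~Y"))
  res <- reconstruct_characters(
    tree, build_character_matrix(reps, tree, "combinations"), "fitch")
  expect_equal(res[["X~Y"]]$gain_nodes, "AB")  # single clade gain, no pairs
  lr0 <- lca_rates(res, tree)
  expect_true(all(lr0$n_lca_pairs == 0))

  reps2 <- reps_from_combos(list(A = "X~Y", C = c("X~Y")))
  res2 <- reconstruct_characters(
    tree, build_character_matrix(reps2, tree, "combinations"), "fitch")
  expect_equal(res2[["X~Y"]]$n_gains, 2)
  lr <- lca_rates(res2, tree)
  expect_equal(lr$n_lca_pairs[lr$node == "ABC"], 1)
  expect_equal(lr$normalized_rate[lr$node == "ABC"], 1 / 3)

  # three tip gains (A, C, E) -> pairs at ABCD (A,C) and R (A,E), (C,E)
  six <- read_tree(text = "(((A,B)AB,(C,D)CD)ABCD,(E,F)EF)R;")
  reps3 <- reps_from_combos(list(A = "X~Y", C = "X~Y", E = "X~Y"))
  res3 <- reconstruct_characters(
    six, build_character_matrix(reps3, six, "combinations"), "fitch")
  expect_equal(res3[["X~Y"]]$n_gains, 3)
  lr3 <- lca_rates(res3, six)
  expect_equal(lr3$n_lca_pairs[lr3$node == "ABCD"], 1)
  expect_equal(lr3$n_lca_pairs[lr3$node == "R"], 2)
  expect_equal(lr3$normalized_rate[lr3$node == "R"], 2 / 6)
  # total pairs equals sum over combinations of choose(n_origins, 2)
  expect_equal(sum(lr3$n_lca_pairs), choose(3, 2))
})

test_that("pair counts across a simulated dataset conserve choose(g, 2)", {
  sim <- simulate_evolution(params = sim_params(
    n_tips = 12, gain_rate = 2, loss_rate = 2, seed = 53))
  reps <- build_repertoires(build_architectures(sim$hits))
  results <- reconstruct_characters(
    sim$tree, build_character_matrix(reps, sim$tree, "combinations"), "fitch")
  lr <- lca_rates(results, sim$tree)
  expected <- sum(vapply(results, function(r) choose(r$n_gains, 2), 1))
  expect_equal(sum(lr$n_lca_pairs), expected)
})

test_that("clan collapse merges same-clan pairs and keeps clanless domains", {
  clan_map <- c(X = "C1", Y = "C1", Q = "C2")
  # [X,Y] -> same clan -> self-pair -> no combination
  archs <- arch_table(list(g1 = list(c("X", "Y"))))
  collapsed <- collapse_to_clans(archs, clan_map)
  expect_equal(collapsed$domains[[1]], c("C1", "C1"))
  expect_equal(decompose(collapsed$domains[[1]]), character(0))
  # clan + clanless domain keep a combination, renamed
  archs2 <- arch_table(list(g1 = list(c("X", "Z"))))
  expect_equal(decompose(collapse_to_clans(archs2, clan_map)$domains[[1]]),
               "C1~Z")

  # identity collapse (no domain has a clan) reproduces the domain level
  sim <- simulate_evolution(params = sim_params(
    n_tips = 10, gain_rate = 1.5, loss_rate = 1.5, seed = 59))
  archs_s <- build_architectures(sim$hits)
  domain_level <- clan_collapse_rerun(archs_s, sim$tree, character(0))
  reps_ref <- build_repertoires(archs_s)
  res_ref <- reconstruct_characters(
    sim$tree, build_character_matrix(reps_ref, sim$tree, "combinations"),
    "fitch")
  summ_ref <- summarize_origins(res_ref, reps_ref)
  expect_equal(domain_level$summary$per_combination, summ_ref$per_combination)

  # a real collapse never increases the distinct-combination count
  clan_level <- clan_collapse_rerun(archs_s, sim$tree, sim$clans)
  expect_lte(clan_level$summary$n_distinct, summ_ref$n_distinct)
})
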