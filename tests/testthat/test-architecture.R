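test_that("architectures order domains N- to C-terminally", {
  hits <- hit_table(
    hit_row(domain_acc = "Y", env_start = 60, env_end = 100),
    hit_row(domain_acc = "X", env_start = 10, env_end = 50))
  expect_equal(build_architecture(hits)$domains, c("X", "Y"))
  expect_equal(build_architecture(hit_row(domain_acc = "Z"))$domains, "Z")

  # permutation invariance
  set.seed(3)
  four <- do.call(rbind, lapply(1:4, function(i)
    hit_row(domain_acc = paste0("D", i), env_start = i * 100,
            env_end = i * 100 + 50)))
  for (k in 1:5) {
    shuffled <- four[sample(4), ]
    expect_equal(build_architecture(shuffled)$domains,
                 build_architecture(four)$domains)
  }
  expect_error(build_architecture(rbind(
    hit_row(protein_id = "p1"), hit_row(protein_id = "p2"))), "single protein")
})

test_that("decomposition follows the directed binary combination model", {
  expect_setequal(decompose(c("A", "B", "C")), c("A~B", "A~C", "B~C"))
  expect_equal(decompose(c("A", "B", "B")), "A~B")
  expect_setequal(decompose(c("A", "B", "C"),
                            combination_model(adjacent_only = TRUE)),
                  c("A~B", "B~C"))
  expect_equal(decompose("A"), character(0))
  expect_equal(decompose(character(0)), character(0))
  # both orders genuinely occur in A-B-A
  expect_setequal(decompose(c("A", "B", "A")), c("A~B", "B~A"))
  # undirected model canonicalizes
  expect_equal(decompose(c("B", "A"), combination_model(directed = FALSE)),
               "A~B")
  expect_error(combination_model(directed = FALSE, adjacent_only = TRUE))
})

test_that("decomposition counts and inclusions hold on fuzzed architectures", {
  set.seed(5)
  adj <- combination_model(adjacent_only = TRUE)
  undir <- combination_model(directed = FALSE)
  for (i in 1:30) {
    k <- sample(2:8, 1)
    distinct <- sprintf("D%02d", sample(1:50, k))
    expect_length(decompose(distinct), k * (k - 1) / 2)
    expect_length(decompose(distinct, adj), k - 1)
    # with repeats: adjacent subset of default; never a self-pair
    with_rep <- sample(sprintf("D%02d", sample(1:5, 3)), sample(2:7, 1),
                       replace = TRUE)
    d_all <- decompose(with_rep)
    d_adj <- decompose(with_rep, adj)
    expect_true(all(d_adj %in% d_all))
    parts <- if (length(d_all) > 0) split_combination(d_all) else NULL
    if (!is.null(parts)) expect_true(all(parts[, 1] != parts[, 2]))
    # undirected distinct count never exceeds directed
    expect_lte(length(decompose(with_rep, undir)), length(d_all))
  }
})

test_that("repertoires aggregate per-protein decompositions by presence", {
  archs <- arch_table(list(g1 = list(c("A", "B"), c("B", "A"))))
  rep <- build_repertoire(archs)
  expect_setequal(rep$combinations, c("A~B", "B~A"))
  expect_equal(rep$n_multidomain_proteins, 2)
  rep_u <- build_repertoire(archs, combination_model(directed = FALSE))
  expect_equal(rep_u$combinations, "A~B")

  # repeated pairs count once (presence/absence semantics)
  rep2 <- build_repertoire(arch_table(list(g1 = list(
    c("A", "B", "A", "B"), c("A", "B")))))
  expect_setequal(rep2$combinations, c("A~B", "B~A"))

  expect_error(build_repertoire(arch_table(list(g1 = list("A"),
                                                g2 = list("B")))),
               "single genome")
  expect_error(build_repertoire(archs, n_proteins = 1), "smaller")
})

test_that("simulated repertoires match the generator's bookkeeping", {
  sim <- simulate_evolution(params = sim_params(n_tips = 8, seed = 19))
  reps <- build_repertoires(build_architectures(
    resolve_overlaps_by_protein(sim$hits)))
  for (g in names(reps))
    expect_equal(reps[[g]]$combinations, sim$truth$tip_repertoires[[g]])
})

test_that("genome summaries report coverage fractions and the squared ratio", {
  # 10 domains, 25 distinct ordered pairs -> ratio 25/100
  set.seed(9)
  doms <- sprintf("D%02d", 1:10)
  pairs <- expand.grid(a = doms, b = doms, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ][1:25, ]
  protein_archs <- c(lapply(seq_len(25), function(i)
    c(pairs$a[i], pairs$b[i])), lapply(doms, identity))
  rep <- build_repertoire(arch_table(list(g1 = protein_archs)))
  s <- genome_summary(rep)
  expect_equal(s$n_domains, 10)
  expect_equal(s$n_combinations, 25)
  expect_equal(s$combinations_per_domains_sq, 0.25)
  expect_equal(s$frac_matched, 1)
  expect_equal(s$frac_multidomain, 25 / 35)

  # all-single-domain genome: no combinations, zero multidomain fraction
  rep1 <- build_repertoire(arch_table(list(g1 = list("A", "B"))))
  s1 <- genome_summary(rep1)
  expect_equal(s1$frac_multidomain, 0)
  expect_equal(s1$n_combinations, 0)

  # mean domains per matched protein equals a direct recount
  sim <- simulate_evolution(params = sim_params(n_tips = 5, seed = 2))
  archs <- build_architectures(sim$hits)
  g <- archs$genome_id[1]
  rep_g <- build_repertoire(archs[archs$genome_id == g, ])
  expect_equal(genome_summary(rep_g)$mean_domains_per_matched,
               mean(lengths(archs$domains[archs$genome_id == g])))
})

test_that("domains partition into single-only / multi-only / both contexts", {
  reps <- build_repertoires(arch_table(list(
    g1 = list(c("A", "X"), "A", "S"),
    g2 = list(c("M", "N"), "S"))))
  part <- partition_domains_by_context(reps)
  expect_equal(part$both, "A")                      # alone in g1 and in [A,X]
  expect_equal(part$single_only, "S")
  expect_setequal(part$multi_only, c("X", "M", "N"))
  # disjoint and exhaustive
  all_obs <- sort(unique(unlist(lapply(reps, `[[`, "domains"))))
  expect_equal(sort(c(part$single_only, part$multi_only, part$both)), all_obs)

  # generator truth: recount contexts directly from the hit table
  sim <- simulate_evolution(params = sim_params(n_tips = 10, seed = 23))
  archs <- build_architectures(sim$hits)
  reps_sim <- build_repertoires(archs)
  part_sim <- partition_domains_by_context(reps_sim)
  nd <- lengths(archs$domains)
  in_single <- unique(unlist(archs$domains[nd == 1]))
  in_multi <- unique(unlist(archs$domains[nd > 1]))
  expect_setequal(part_sim$single_only, setdiff(in_single, in_multi))
  expect_setequal(part_sim$multi_only, setdiff(in_multi, in_single))
  expect_setequal(part_sim$both, intersect(in_single, in_multi))
})

test_that("architecture and repertoire TSV exports round-trip", {
  dir <- withr::local_tempdir()
  archs <- arch_table(list(g1 = list(c("A", "B", "C"), "D"),
                           g2 = list(c("B", "A"))))
  write_architectures_tsv(archs, file.path(dir, "a.tsv"))
  back <- read_architectures_tsv(file.path(dir, "a.tsv"))
  expect_equal(back$genome_id, archs$genome_id)
  expect_equal(unclass(back$domains), unclass(archs$domains),
               ignore_attr = TRUE)
})
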