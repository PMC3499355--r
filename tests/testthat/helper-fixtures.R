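# Shared fixture builders. Everything is generated in code; no binary data.

# random rooted tree, optionally with polytomies (collapse short edges)
random_tree <- function(n_tips, polytomies = TRUE) {
  tr <- ape::rtree(n_tips)
  if (polytomies && n_tips > 3) {
    internal <- which(tr$edge[, 2] > length(tr$tip.label))
    collapse <- internal[stats::runif(length(internal)) < 0.3]
    tr$edge.length[collapse] <- 0
    tr <- ape::di2multi(tr)
  }
  tr
}

random_tip_states <- function(tree, p = 0.5) {
  stats::setNames(as.integer(stats::runif(length(tree$tip.label)) < p),
                  tree$tip.label)
}

# one hit-table row with defaults
hit_row <- function(genome_id = "g1", protein_id = "p1", domain_acc = "D001",
                    env_start = 1L, env_end = 50L, bit_score = 50,
                    i_evalue = 1e-10, domain_name = domain_acc,
                    clan_acc = NA_character_) {
  data.frame(genome_id = genome_id, protein_id = protein_id,
             domain_acc = domain_acc, domain_name = domain_name,
             env_start = as.integer(env_start), env_end = as.integer(env_end),
             bit_score = bit_score, i_evalue = i_evalue, clan_acc = clan_acc,
             stringsAsFactors = FALSE)
}

hit_table <- function(...) do.call(rbind, list(...))

# architecture table from a named list genome -> list of domain vectors
arch_table <- function(by_genome) {
  rows <- list()
  for (g in names(by_genome)) {
    doms <- by_genome[[g]]
    rows[[g]] <- data.frame(
      genome_id = g,
      protein_id = sprintf("%s_p%03d", g, seq_along(doms)),
      domains = I(doms), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# repertoires straight from per-genome combination presence (one two-domain
# protein per combination)
reps_from_combos <- function(combos_by_genome) {
  by_g <- lapply(combos_by_genome, function(cmb)
    lapply(cmb, function(x) as.vector(split_combination(x)[1, ])))
  build_repertoires(arch_table(by_g))
}
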