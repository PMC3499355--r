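# Synthetic evolution of domain-combination repertoires along a tree, with a
# complete truth log. The generator emulates the process the parsimony model
# assumes: combinations are created by domain fusion and removed by fission
# along branches; the domain content itself is held constant so that every
# fusion draws from the same ordered-pair pool. Outputs are emitted in the
# pipeline's own input formats so the entire analysis path is exercised.

#' Simulation parameters
#'
#' Defaults describe a desk-scale study: 20 genomes, a 40-domain pool,
#' 60 ancestral combinations, and equal fusion and fission rates of 0.5
#' expected events per branch — the equal-rates regime that unweighted
#' parsimony assumes. The `"fusion_biased"` preset (gain 0.6, loss 0.4)
#' mirrors the reported tendency of fusion to outpace fission.
#'
#' @param n_tips number of genomes (tree tips).
#' @param n_root_domains size of the domain pool (all present at the root).
#' @param n_root_combinations combinations present at the root; at most
#'   `n_root_domains * (n_root_domains - 1)`.
#' @param gain_rate expected fusion events per branch (Poisson mean).
#' @param loss_rate expected fission/loss events per branch (Poisson mean).
#' @param clan_fraction fraction of domains assigned to a clan.
#' @param proteins_per_combination proteins materialized per present
#'   combination at each tip.
#' @param seed RNG seed (integer).
#' @param preset `"equal_rates"` (default) or `"fusion_biased"`.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_tips = 20, n_root_domains = 40,
                       n_root_combinations = 60,
                       gain_rate = 0.5, loss_rate = 0.5,
                       clan_fraction = 0.5, proteins_per_combination = 1,
                       seed = 1, preset = c("equal_rates", "fusion_biased")) {
  preset <- match.arg(preset)
  if (preset == "fusion_biased" &&
      missing(gain_rate) && missing(loss_rate)) {
    gain_rate <- 0.6
    loss_rate <- 0.4
  }
  stopifnot(n_tips >= 2, n_root_domains >= 2,
            gain_rate >= 0, loss_rate >= 0,
            clan_fraction >= 0, clan_fraction <= 1,
            proteins_per_combination >= 1)
  if (n_root_combinations > n_root_domains * (n_root_domains - 1))
    stop("n_root_combinations exceeds the number of ordered domain pairs")
  structure(list(n_tips = n_tips, n_root_domains = n_root_domains,
                 n_root_combinations = n_root_combinations,
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 clan_fraction = clan_fraction,
                 proteins_per_combination = proteins_per_combination,
                 seed = as.integer(seed)), class = "sim_params")
}

#' Generate a random rooted binary tree (Yule process)
#'
#' @param n_tips number of tips (>= 2).
#' @param seed RNG seed; the same seed always yields the same tree.
#' @return a rooted binary `phylo` with tips `g001..gN` and internal nodes
#'   named `n<k>`.
#' @export
generate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("g%03d", seq_len(n_tips))
  tree$node.label <- paste0("n", seq_len(tree$Nnode))
  validate_tree(tree)
}

all_ordered_pairs <- function(domains) {
  g <- expand.grid(second = domains, first = domains,
                   stringsAsFactors = FALSE)
  g <- g[g$first != g$second, ]
  comb_string(g$first, g$second)
}

#' Simulate combination gain/loss evolution along a tree
#'
#' Samples an ancestral repertoire, then walks each branch applying
#' Poisson-distributed fusion (gain) and fission (loss) events in random
#' interleaved order: a fusion creates an ordered pair currently absent on
#' the lineage (re-gain of a previously lost combination is allowed — this
#' is what generates parallel evolution across lineages); a fission removes
#' a present combination. Tip repertoires are materialized as two-domain
#' proteins (plus single-domain proteins for domains unused at that tip) and
#' emitted as a hit table whose scores pass the accompanying synthetic
#' cutoff table in every mode.
#'
#' The truth-log replay invariant (re-applying all events from the root
#' state reproduces every tip repertoire) is asserted before returning.
#'
#' @param tree rooted `phylo`; if `NULL`, one is generated from the params.
#' @param params a [sim_params()] object.
#' @return a `simulation` list: `tree`, `hits` (generic hit table for all
#'   genomes), `clans` (named vector), `cutoffs` (data.frame), `truth`
#'   (list: `events` data.frame, `origin_counts`, `tip_repertoires`,
#'   `root_combinations`), `supergroups` (genome -> group mapping derived
#'   from the root split), `params`.
#' @export
simulate_evolution <- function(tree = NULL, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(tree)) tree <- generate_tree(params$n_tips, params$seed)
  validate_tree(tree)
  set.seed(params$seed + 104729L)   # decouple from tree generation
  domains <- sprintf("D%03d", seq_len(params$n_root_domains))
  pairs <- all_ordered_pairs(domains)
  root_combos <- sort(sample(pairs, params$n_root_combinations))

  nm <- node_names(tree)
  n_tip <- length(tree$tip.label)
  pre <- stats::reorder(tree, "cladewise")$edge   # parents before children
  state <- vector("list", n_tip + tree$Nnode)
  state[[root_id(tree)]] <- root_combos
  ev_node <- character(0); ev_type <- character(0); ev_comb <- character(0)

  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; ch <- pre[i, 2]
    cur <- state[[p]]
    n_gain <- stats::rpois(1, params$gain_rate)
    n_loss <- stats::rpois(1, params$loss_rate)
    types <- c(rep("gain", n_gain), rep("loss", n_loss))
    if (length(types) > 1) types <- sample(types)
    for (tp in types) {
      if (tp == "gain") {
        absent <- setdiff(pairs, cur)
        if (length(absent) == 0) {
          warning("domain pool exhausted; gain event skipped on branch to ",
                  nm[ch])
          next
        }
        cmb <- sample(absent, 1)
        cur <- c(cur, cmb)
      } else {
        if (length(cur) == 0) next
        cmb <- sample(cur, 1)
        cur <- setdiff(cur, cmb)
      }
      ev_node <- c(ev_node, nm[ch])
      ev_type <- c(ev_type, tp)
      ev_comb <- c(ev_comb, cmb)
    }
    state[[ch]] <- sort(cur)
  }

  events <- data.frame(node = ev_node, event = ev_type, combination = ev_comb,
                       stringsAsFactors = FALSE)
  tip_repertoires <- stats::setNames(state[seq_len(n_tip)], tree$tip.label)

  # true independent origins: root presence counts as one appearance
  gain_tab <- table(events$combination[events$event == "gain"])
  all_seen <- sort(unique(c(root_combos, names(gain_tab))))
  origin_counts <- stats::setNames(integer(length(all_seen)), all_seen)
  origin_counts[names(gain_tab)] <- as.integer(gain_tab)
  origin_counts[root_combos] <- origin_counts[root_combos] + 1L

  # clan assignment: clans of two domains each
  n_clan_dom <- floor(params$clan_fraction * length(domains) / 2) * 2
  clans <- character(0)
  if (n_clan_dom >= 2) {
    members <- sample(domains, n_clan_dom)
    clans <- stats::setNames(
      rep(sprintf("CL%03d", seq_len(n_clan_dom / 2)), each = 2), members)
  }

  hits <- materialize_hits(tip_repertoires, domains,
                           params$proteins_per_combination)
  cutoffs <- data.frame(pfam_acc = domains, GA = 25, TC = 30, NC = 20,
                        stringsAsFactors = FALSE)

  # supergroup mapping from the root split (one group per root child)
  kids <- tree_children(tree)[[root_id(tree)]]
  supergroups <- do.call(rbind, lapply(seq_along(kids), function(k)
    data.frame(genome_id = tree$tip.label[tips_under(tree, kids[k])],
               supergroup = sprintf("SG%d", k), stringsAsFactors = FALSE)))

  truth <- list(events = events, origin_counts = origin_counts,
                tip_repertoires = tip_repertoires,
                root_combinations = root_combos)
  stopifnot(identical(replay_truth(tree, truth), tip_repertoires))
  structure(list(tree = tree, hits = hits, clans = clans, cutoffs = cutoffs,
                 truth = truth, supergroups = supergroups, params = params),
            class = "simulation")
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf("<simulation: %d genomes, %d root combinations, %d events, %d hit rows>\n",
              length(x$tree$tip.label),
              length(x$truth$root_combinations),
              nrow(x$truth$events), nrow(x$hits)))
  invisible(x)
}

# Tip repertoires -> generic hit table. Each present combination becomes
# proteins with a two-domain architecture at fixed, non-overlapping
# coordinates; domains unused in any combination at a tip become
# single-domain proteins. Scores pass the synthetic cutoffs in every mode.
materialize_hits <- function(tip_repertoires, domains, per_comb) {
  per_tip <- lapply(names(tip_repertoires), function(g) {
    combos <- tip_repertoires[[g]]
    n_c <- length(combos) * per_comb
    if (length(combos) > 0) {
      parts <- split_combination(combos)
      first <- rep(parts[, "first"], each = per_comb)
      second <- rep(parts[, "second"], each = per_comb)
      used <- unique(c(parts[, "first"], parts[, "second"]))
    } else {
      first <- second <- character(0)
      used <- character(0)
    }
    singles <- setdiff(domains, used)
    pid <- sprintf("%s_p%04d", g, seq_len(n_c + length(singles)))
    acc <- c(as.vector(rbind(first, second)), singles)
    data.frame(
      genome_id = g,
      protein_id = c(rep(pid[seq_len(n_c)], each = 2),
                     pid[n_c + seq_along(singles)]),
      domain_acc = acc, domain_name = acc,
      env_start = c(rep(c(10L, 150L), n_c), rep(10L, length(singles))),
      env_end = c(rep(c(110L, 250L), n_c), rep(110L, length(singles))),
      bit_score = 50, i_evalue = 1e-10, clan_acc = NA_character_,
      stringsAsFactors = FALSE)
  })
  validate_hits(do.call(rbind, c(per_tip, list(make.row.names = FALSE))))
}

#' Replay a truth log from the root state
#'
#' Re-applies every logged event along the tree and returns the resulting
#' tip repertoires; used to assert the replay invariant.
#'
#' @param tree the simulation tree.
#' @param truth the `truth` element of a simulation.
#' @return named list of sorted combination vectors per tip.
#' @export
replay_truth <- function(tree, truth) {
  nm <- node_names(tree)
  n_tip <- length(tree$tip.label)
  pre <- stats::reorder(tree, "cladewise")$edge
  state <- vector("list", n_tip + tree$Nnode)
  state[[root_id(tree)]] <- sort(truth$root_combinations)
  ev <- truth$events
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; ch <- pre[i, 2]
    cur <- state[[p]]
    sel <- which(ev$node == nm[ch])
    for (j in sel) {
      if (ev$event[j] == "gain") cur <- c(cur, ev$combination[j])
      else cur <- setdiff(cur, ev$combination[j])
    }
    state[[ch]] <- sort(unique(cur))
  }
  stats::setNames(state[seq_len(n_tip)], tree$tip.label)
}

#' Plant a deterministic presence pattern on named clades
#'
#' Builds a tip-state map with state 1 exactly on the tips of the requested
#' clades — used for worked-example characters such as a combination present
#' in two disjoint parts of the tree.
#'
#' @param tree a `phylo` object.
#' @param clades character vector of clade names (internal node names or tip
#'   labels).
#' @return named 0/1 integer vector over all tips.
#' @export
plant_pattern <- function(tree, clades) {
  present <- unique(unlist(lapply(clades, function(cl) clade_tips(tree, cl))))
  st <- stats::setNames(rep(0L, length(tree$tip.label)), tree$tip.label)
  st[present] <- 1L
  st
}

#' Write all simulation outputs in the pipeline's input formats
#'
#' Emits `hits.tsv` (generic hit table), `clans.tsv`, `cutoffs.tsv`,
#' `exclusions.txt` (empty), `tree.nwk`, `supergroups.tsv` and
#' `truth_events.tsv` into a directory.
#'
#' @param sim a `simulation` object.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_hits_tsv(sim$hits, file.path(dir, "hits.tsv"))
  clan_doms <- if (length(sim$clans) > 0) names(sim$clans) else character(0)
  clans_df <- data.frame(pfam_acc = clan_doms,
                         clan_acc = as.character(unname(sim$clans)),
                         clan_id = as.character(unname(sim$clans)),
                         pfam_id = clan_doms,
                         description = rep("synthetic clan", length(sim$clans)),
                         stringsAsFactors = FALSE)
  utils::write.table(clans_df, file.path(dir, "clans.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$cutoffs, file.path(dir, "cutoffs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(character(0), file.path(dir, "exclusions.txt"))
  write_tree_newick(sim$tree, file.path(dir, "tree.nwk"))
  utils::write.table(sim$supergroups, file.path(dir, "supergroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, file.path(dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' The packaged eukaryote reference topology
#'
#' A rooted tree of the major eukaryote clades (supergroups down to the
#' phylum-level groups discussed in worked examples: Bilateria split into
#' Deuterostomia and Protostomia with Neoptera, Dikarya split into
#' Ascomycota and Basidiomycota, Micromonas within Chlorophyta,
#' Dictyostelium within Amoebozoa). Tips stand for clades of genomes, not
#' individual genomes; users supply their own full species tree for real
#' analyses.
#'
#' @return a rooted `phylo` object with named internal nodes.
#' @export
eukaryote_tree <- function() {
  path <- system.file("extdata", "eukaryote_clades.nwk", package = "combevol")
  read_tree(path, format = "newick")
}
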