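# Dataset-level analytics over parsimony results and genome repertoires:
# independent-origin counting, parallel-evolution percentages, clade-specific
# and core repertoires, supergroup distributions and LCA-normalized rates.

#' Count independent origins of every combination
#'
#' A combination's number of origins is its number of gain nodes under the
#' Fitch reconstruction (an inferred presence at the root counts as one
#' appearance). Combinations present in exactly one genome are
#' species-specific; combinations with two or more origins evolved in
#' parallel.
#'
#' @param results named list of `parsimony_result`, one per combination
#'   observed in the repertoires.
#' @param reps named list of `genome_repertoire` objects.
#' @return an `origin_summary`: per-combination table (`combination`,
#'   `n_origins`, `n_genomes`, `species_specific`), the origins histogram,
#'   and totals `n_distinct`, `n_species_specific`, `n_reappearing`.
#' @export
summarize_origins <- function(results, reps) {
  observed <- sort(unique(unlist(lapply(reps, `[[`, "combinations"),
                                 use.names = FALSE)))
  miss <- setdiff(observed, names(results))
  if (length(miss) > 0)
    stop("no parsimony result for combination(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5) else "")
  n_genomes <- table(unlist(lapply(reps, `[[`, "combinations"), use.names = FALSE))
  n_origins <- vapply(results[observed], `[[`, integer(1), "n_gains")
  per <- data.frame(
    combination = observed,
    n_origins = unname(n_origins),
    n_genomes = as.integer(n_genomes[observed]),
    stringsAsFactors = FALSE)
  per$species_specific <- per$n_genomes == 1L
  hist_tab <- table(per$n_origins)
  histogram <- stats::setNames(as.integer(hist_tab), names(hist_tab))
  structure(list(
    per_combination = per,
    histogram = histogram,
    n_distinct = nrow(per),
    n_species_specific = sum(per$species_specific),
    n_reappearing = sum(per$n_origins >= 2L)), class = "origin_summary")
}

#' @export
print.origin_summary <- function(x, ...) {
  cat(sprintf("<origin_summary: %d distinct combinations, %d species-specific, %d with >=2 independent origins>\n",
              x$n_distinct, x$n_species_specific, x$n_reappearing))
  invisible(x)
}

#' Parallel-evolution percentages
#'
#' @param summary an `origin_summary`.
#' @return list with `pct_of_total` (share of all distinct combinations with
#'   two or more independent origins, in percent) and `pct_of_recurring`
#'   (the same count as a share of non-species-specific, i.e. recurring,
#'   combinations; `NA` when there are none).
#' @export
percent_parallel <- function(summary) {
  stopifnot(inherits(summary, "origin_summary"), summary$n_distinct > 0)
  recurring <- summary$n_distinct - summary$n_species_specific
  list(pct_of_total = 100 * summary$n_reappearing / summary$n_distinct,
       pct_of_recurring = if (recurring > 0)
         100 * summary$n_reappearing / recurring else NA_real_)
}

#' Per-genome parallel-evolution ratios
#'
#' For each genome: the fraction of its combinations that also evolved
#' independently elsewhere, i.e. that have at least two gain nodes of which
#' at least one lies off the genome's root path (is neither the genome's tip
#' nor one of its ancestors).
#'
#' @param results named list of `parsimony_result` per combination.
#' @param reps named list of `genome_repertoire` objects.
#' @param tree the species tree; every repertoire genome must be a tip.
#' @return data.frame: `genome_id`, `n_combinations`, `n_parallel`, `ratio`.
#' @export
per_genome_parallel_ratio <- function(results, reps, tree) {
  nm <- node_names(tree)
  rows <- lapply(names(reps), function(g) {
    if (!g %in% tree$tip.label) stop("genome is not a tip: ", g)
    lineage <- nm[node_ancestors(tree, g)]
    combos <- reps[[g]]$combinations
    par_flag <- vapply(combos, function(cmb) {
      r <- results[[cmb]]
      if (is.null(r)) stop("no parsimony result for combination: ", cmb)
      r$n_gains >= 2L && any(!(r$gain_nodes %in% lineage))
    }, logical(1))
    data.frame(genome_id = g, n_combinations = length(combos),
               n_parallel = sum(par_flag),
               ratio = if (length(combos) > 0) mean(par_flag) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Clade-specific and core domain/combination sets
#'
#' A character (combination or domain) is specific to a clade when it occurs
#' in at least one member genome and in no genome outside the clade; it is a
#' core character when it is additionally present in every member genome.
#'
#' @param reps named list of `genome_repertoire` objects.
#' @param tree the species tree.
#' @param clades character vector of named internal nodes (clade names).
#' @return a `clade_sets` object: per clade, the specific/core combination
#'   and domain sets; plus `species_specific_counts`, the per-genome counts
#'   of combinations found in that genome only.
#' @export
clade_sets <- function(reps, tree, clades) {
  genome_ids <- names(reps)
  presence <- function(what) {
    lapply(reps, `[[`, what)
  }
  comb_by_g <- presence("combinations")
  dom_by_g <- presence("domains")
  sets_for <- function(by_g, members) {
    outside <- setdiff(genome_ids, members)
    inside_any <- unique(unlist(by_g[members], use.names = FALSE))
    outside_any <- unique(unlist(by_g[outside], use.names = FALSE))
    specific <- setdiff(inside_any, outside_any)
    core <- specific
    for (g in members) core <- intersect(core, by_g[[g]])
    list(specific = sort(specific), core = sort(core))
  }
  per_clade <- lapply(clades, function(cl) {
    members <- intersect(clade_tips(tree, cl), genome_ids)
    if (length(members) == 0)
      stop("clade has no analyzed genomes: ", cl)
    cmb <- sets_for(comb_by_g, members)
    dom <- sets_for(dom_by_g, members)
    list(clade = cl, n_genomes = length(members),
         specific_combinations = cmb$specific, core_combinations = cmb$core,
         specific_domains = dom$specific, core_domains = dom$core)
  })
  names(per_clade) <- clades
  # species-specific counts per genome
  tab <- table(unlist(comb_by_g, use.names = FALSE))
  singletons <- names(tab)[tab == 1L]
  ss_counts <- vapply(genome_ids, function(g)
    sum(comb_by_g[[g]] %in% singletons), integer(1))
  structure(list(clades = per_clade,
                 species_specific_counts = ss_counts),
            class = "clade_sets")
}

#' @export
print.clade_sets <- function(x, ...) {
  for (cl in x$clades)
    cat(sprintf("%s (%d genomes): %d specific / %d core combinations; %d specific / %d core domains\n",
                cl$clade, cl$n_genomes,
                length(cl$specific_combinations), length(cl$core_combinations),
                length(cl$specific_domains), length(cl$core_domains)))
  invisible(x)
}

#' Distribution of combinations over supergroups
#'
#' Assigns every combination the set of supergroups in which it occurs and
#' tabulates: exclusive-to-one-group counts, combinations shared between two
#' or more groups, and combinations present in every group.
#'
#' @param reps named list of `genome_repertoire` objects.
#' @param mapping data.frame with columns `genome_id`, `supergroup` (every
#'   repertoire genome must be mapped).
#' @return list with `exclusive` (named counts per supergroup), `shared`
#'   (count in >= 2 groups), `in_all_groups` (count present in every group),
#'   `n_groups`, `n_distinct`.
#' @export
supergroup_distribution <- function(reps, mapping) {
  stopifnot(all(c("genome_id", "supergroup") %in% names(mapping)))
  grp <- stats::setNames(mapping$supergroup, mapping$genome_id)
  unmapped <- setdiff(names(reps), names(grp))
  if (length(unmapped) > 0)
    stop("unmapped genome(s): ", paste(unmapped, collapse = ", "))
  groups <- sort(unique(unname(grp[names(reps)])))
  # combination -> set of groups
  long <- do.call(rbind, lapply(names(reps), function(g) {
    if (length(reps[[g]]$combinations) == 0) return(NULL)
    data.frame(combination = reps[[g]]$combinations,
               supergroup = unname(grp[g]), stringsAsFactors = FALSE)
  }))
  by_comb <- split(long$supergroup, long$combination)
  n_grp <- vapply(by_comb, function(s) length(unique(s)), integer(1))
  one_grp <- vapply(by_comb, function(s) unique(s)[1], "")
  exclusive <- vapply(groups, function(g) sum(n_grp == 1L & one_grp == g),
                      integer(1))
  list(exclusive = exclusive,
       shared = sum(n_grp >= 2L),
       in_all_groups = sum(n_grp == length(groups)),
       n_groups = length(groups),
       n_distinct = length(by_comb))
}

#' LCA-normalized rates of independent combination evolution
#'
#' For every combination with \eqn{g \ge 2} gain nodes, each of the
#' \eqn{g(g-1)/2} unordered pairs of gain nodes contributes one count to the
#' pair's last common ancestor (when one gain node is ancestral to the
#' other, the LCA is the ancestral gain node itself). Counts are normalized
#' by the number of extant genomes descending from the node.
#'
#' @param results named list of `parsimony_result` per combination.
#' @param tree the species tree.
#' @return data.frame per internal (and tip) node with at least one pair:
#'   `node`, `n_lca_pairs`, `n_leaves`, `normalized_rate`; nodes with zero
#'   pairs are included with rate 0.
#' @export
lca_rates <- function(results, tree) {
  nm <- node_names(tree)
  counts <- stats::setNames(integer(length(nm)), nm)
  for (r in results) {
    g <- r$gain_nodes
    if (length(g) < 2) next
    ids <- node_id(tree, g)
    for (i in seq_len(length(ids) - 1))
      for (j in (i + 1):length(ids)) {
        anc <- nm[lca(tree, ids[c(i, j)])]
        counts[anc] <- counts[anc] + 1L
      }
  }
  leaves <- vapply(seq_along(nm), function(i) leaf_count(tree, i), integer(1))
  data.frame(node = nm, n_lca_pairs = unname(counts), n_leaves = leaves,
             normalized_rate = unname(counts) / leaves,
             stringsAsFactors = FALSE)
}

#' Collapse domains to their Pfam clans in architectures
#'
#' Every domain token that belongs to a clan is replaced by the clan
#' accession; domains without a clan are kept as-is.
#'
#' @param archs architecture data.frame.
#' @param clan_map named character vector domain -> clan.
#' @return architecture data.frame with collapsed `domains`.
#' @export
collapse_to_clans <- function(archs, clan_map) {
  archs$domains <- I(lapply(archs$domains, function(d) {
    cl <- unname(clan_map[d])
    ifelse(is.na(cl), d, cl)
  }))
  archs
}

#' Re-run origin counting at the Pfam-clan level
#'
#' Replaces domains by their clans, re-decomposes every architecture (pairs
#' that collapse onto the same clan become self-pairs and are excluded, as in
#' the domain-level analysis), rebuilds repertoires, reconstructs the
#' clan-level combinations under Fitch parsimony and summarizes origins.
#'
#' @param archs architecture data.frame (all genomes).
#' @param tree the species tree.
#' @param clan_map named character vector domain -> clan.
#' @param model a [combination_model()].
#' @param root_preference tie-break for the Fitch root state.
#' @return list with `summary` (an `origin_summary`), `results`, `reps` at
#'   the clan level.
#' @export
clan_collapse_rerun <- function(archs, tree, clan_map,
                                model = combination_model(),
                                root_preference = c("absent", "present")) {
  collapsed <- collapse_to_clans(archs, clan_map)
  reps <- build_repertoires(collapsed, model = model)
  X <- build_character_matrix(reps, tree, "combinations")
  results <- reconstruct_characters(tree, X, "fitch", root_preference)
  list(summary = summarize_origins(results, reps),
       results = results, reps = reps)
}

#' Export the origin histogram as TSV
#' @param summary an `origin_summary`.
#' @param path output file.
#' @export
write_origin_histogram_tsv <- function(summary, path) {
  df <- data.frame(n_origins = as.integer(names(summary$histogram)),
                   n_combinations = unname(summary$histogram))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
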