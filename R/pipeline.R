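# End-to-end pipeline: ingest -> filter -> resolve overlaps -> architectures
# -> repertoires -> parsimony -> analytics -> report bundle. All outputs are
# plain TSV/Newick/phyloXML plus a JSON run manifest; identical inputs and
# config yield identical outputs.

#' Assemble a pipeline run configuration
#'
#' @param hits path to a hit table — generic TSV (default) or HMMER3
#'   domtblout via `hits_format = "domtblout"`.
#' @param tree path to the rooted species tree (Newick or phyloXML).
#' @param out_dir output directory for the report bundle.
#' @param cutoffs,clans,exclusions optional Pfam metadata file paths.
#' @param supergroups optional genome -> supergroup TSV.
#' @param cutoff_mode `"GA"`, `"TC"`, `"NC"` or `"EVALUE"`.
#' @param evalue_threshold threshold when `cutoff_mode = "EVALUE"`.
#' @param model `"directed"`, `"undirected"` or `"adjacent"`.
#' @param clan_level collapse domains to clans before decomposition?
#' @param keep_overlaps skip overlap resolution (sensitivity switch)?
#' @param root_preference Fitch root tie-break, `"absent"` or `"present"`.
#' @param clades clade names for specific/core set reports.
#' @param hits_format `"tsv"` or `"domtblout"`.
#' @param genome_id genome label when reading a single-genome domtblout.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(hits, tree, out_dir,
                       cutoffs = NULL, clans = NULL, exclusions = NULL,
                       supergroups = NULL,
                       cutoff_mode = "GA", evalue_threshold = NULL,
                       model = c("directed", "undirected", "adjacent"),
                       clan_level = FALSE, keep_overlaps = FALSE,
                       root_preference = c("absent", "present"),
                       clades = character(), hits_format = c("tsv", "domtblout"),
                       genome_id = NA_character_, seed = 1L) {
  model <- match.arg(model)
  root_preference <- match.arg(root_preference)
  hits_format <- match.arg(hits_format)
  for (p in c(hits, tree, cutoffs, clans, exclusions, supergroups))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  structure(list(hits = hits, tree = tree, out_dir = out_dir,
                 cutoffs = cutoffs, clans = clans, exclusions = exclusions,
                 supergroups = supergroups, cutoff_mode = cutoff_mode,
                 evalue_threshold = evalue_threshold, model = model,
                 clan_level = clan_level, keep_overlaps = keep_overlaps,
                 root_preference = root_preference, clades = clades,
                 hits_format = hits_format, genome_id = genome_id,
                 seed = as.integer(seed)), class = "run_config")
}

#' Read a run configuration from a key=value text file
#'
#' Recognized keys mirror the arguments of [run_config()]; list-valued keys
#' (`clades`) are comma-separated. Lines starting with `#` are ignored.
#'
#' @param path config file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  opt <- stats::setNames(as.list(vals), keys)
  get <- function(k, default = NULL) if (!is.null(opt[[k]])) opt[[k]] else default
  run_config(
    hits = get("hits"), tree = get("tree"), out_dir = get("out_dir", "combevol_out"),
    cutoffs = get("cutoffs"), clans = get("clans"),
    exclusions = get("exclusions"), supergroups = get("supergroups"),
    cutoff_mode = get("cutoff_mode", "GA"),
    evalue_threshold = if (!is.null(opt$evalue_threshold))
      as.numeric(opt$evalue_threshold) else NULL,
    model = get("model", "directed"),
    clan_level = as.logical(get("clan_level", "FALSE")),
    keep_overlaps = as.logical(get("keep_overlaps", "FALSE")),
    root_preference = get("root_preference", "absent"),
    clades = if (!is.null(opt$clades))
      trimws(strsplit(opt$clades, ",")[[1]]) else character(),
    hits_format = get("hits_format", "tsv"),
    genome_id = get("genome_id", NA_character_),
    seed = as.integer(get("seed", "1")))
}

config_model <- function(config) {
  switch(config$model,
         directed = combination_model(),
         undirected = combination_model(directed = FALSE),
         adjacent = combination_model(adjacent_only = TRUE))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes ingest, filtering, overlap resolution, architecture building,
#' (optional) clan collapse, repertoire construction, Fitch reconstruction
#' of combinations, Dollo reconstruction of individual domains, and the
#' downstream analytics, writing a report bundle into the output directory:
#' `repertoires.tsv`, `parsimony_combinations.tsv`, `parsimony_domains.tsv`,
#' `origin_histogram.tsv`, `origins_per_combination.tsv`,
#' `per_genome_ratios.tsv`, `lca_rates.tsv`, `genome_summaries.tsv`,
#' `clade_sets.tsv` (when clades are configured), `supergroups.tsv` (when a
#' mapping is configured), `annotated_tree.xml` and `manifest.json`.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the in-memory results (`reps`, `results`,
#'   `summary`, `pct`, `per_genome`, `lca_rates`, paths of written files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message(sprintf(...))

  tree <- stage("read_tree", read_tree(config$tree))
  hits <- stage("ingest", {
    if (config$hits_format == "domtblout")
      parse_domtblout(config$hits, genome_id = config$genome_id)
    else read_hits_tsv(config$hits)
  })
  log_line("ingest: %d hit rows, %d genomes", nrow(hits),
           length(unique(hits$genome_id)))

  clan_map <- if (!is.null(config$clans)) read_clans_tsv(config$clans)
              else character(0)
  meta <- pfam_metadata(
    cutoffs = if (!is.null(config$cutoffs)) read_cutoffs_tsv(config$cutoffs),
    clans = clan_map,
    exclusions = if (!is.null(config$exclusions))
      read_exclusions(config$exclusions) else character())
  policy <- if (config$cutoff_mode == "EVALUE")
    cutoff_policy("EVALUE", config$evalue_threshold)
  else cutoff_policy(config$cutoff_mode)

  hits <- stage("filter", filter_hits(hits, meta, policy))
  log_line("filter [%s]: %d hit rows retained", config$cutoff_mode, nrow(hits))
  if (!config$keep_overlaps) {
    hits <- stage("resolve_overlaps", resolve_overlaps_by_protein(hits))
    log_line("resolve_overlaps: %d hit rows retained", nrow(hits))
  }

  archs <- stage("architectures", build_architectures(hits))
  if (config$clan_level && length(clan_map) > 0)
    archs <- collapse_to_clans(archs, clan_map)
  model <- config_model(config)
  reps <- stage("repertoires", build_repertoires(archs, model = model))
  log_line("repertoires: %d genomes, %d distinct combinations",
           length(reps),
           length(unique(unlist(lapply(reps, `[[`, "combinations")))))

  Xc <- build_character_matrix(reps, tree, "combinations")
  results <- stage("fitch", reconstruct_characters(
    tree, Xc, "fitch", config$root_preference))
  Xd <- build_character_matrix(reps, tree, "domains")
  dom_results <- stage("dollo", reconstruct_characters(tree, Xd, "dollo"))

  summary <- stage("origins", summarize_origins(results, reps))
  pct <- percent_parallel(summary)
  per_genome <- stage("per_genome", per_genome_parallel_ratio(results, reps, tree))
  rates <- stage("lca_rates", lca_rates(results, tree))
  log_line("analyze: %.1f%% of combinations with >=2 origins", pct$pct_of_total)

  od <- function(f) file.path(config$out_dir, f)
  write_repertoires_tsv(reps, od("repertoires.tsv"), model_tag = config$model)
  write_parsimony_tsv(results, od("parsimony_combinations.tsv"))
  write_parsimony_tsv(dom_results, od("parsimony_domains.tsv"))
  write_origin_histogram_tsv(summary, od("origin_histogram.tsv"))
  per_comb <- summary$per_combination
  utils::write.table(per_comb, od("origins_per_combination.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pg <- per_genome
  pg$ratio_pct <- round(100 * pg$ratio, 1)
  utils::write.table(pg, od("per_genome_ratios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rates_out <- rates
  rates_out$normalized_rate_rounded <- round(rates$normalized_rate, 3)
  utils::write.table(rates_out, od("lca_rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summaries <- do.call(rbind, c(lapply(reps, genome_summary),
                                list(make.row.names = FALSE)))
  utils::write.table(summaries, od("genome_summaries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cl_sets <- NULL
  if (length(config$clades) > 0) {
    cl_sets <- stage("clade_sets", clade_sets(reps, tree, config$clades))
    cl_df <- do.call(rbind, lapply(cl_sets$clades, function(cl)
      data.frame(clade = cl$clade, n_genomes = cl$n_genomes,
                 n_specific_combinations = length(cl$specific_combinations),
                 n_core_combinations = length(cl$core_combinations),
                 n_specific_domains = length(cl$specific_domains),
                 n_core_domains = length(cl$core_domains),
                 stringsAsFactors = FALSE)))
    utils::write.table(cl_df, od("clade_sets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sg <- NULL
  if (!is.null(config$supergroups)) {
    mapping <- utils::read.delim(config$supergroups, stringsAsFactors = FALSE)
    sg <- stage("supergroups", supergroup_distribution(reps, mapping))
    sg_df <- data.frame(bucket = c(names(sg$exclusive), "shared", "in_all_groups"),
                        n_combinations = c(unname(sg$exclusive), sg$shared,
                                           sg$in_all_groups),
                        stringsAsFactors = FALSE)
    utils::write.table(sg_df, od("supergroups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  annotations <- list()
  for (r in results) {
    for (n in r$gain_nodes)
      annotations[[n]]$gains <- c(annotations[[n]]$gains, r$character)
    for (n in r$loss_nodes)
      annotations[[n]]$losses <- c(annotations[[n]]$losses, r$character)
  }
  write_annotated_tree(tree, od("annotated_tree.xml"), annotations)

  manifest <- list(
    package = "combevol",
    version = as.character(utils::packageVersion("combevol")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_genomes = length(reps),
    n_distinct_combinations = summary$n_distinct,
    pct_parallel_of_total = pct$pct_of_total,
    pct_parallel_of_recurring = pct$pct_of_recurring,
    config_hash = sum(utf8ToInt(paste(
      vapply(config[setdiff(names(config), "out_dir")],
             function(x) paste(format(x), collapse = ","), ""),
      collapse = ";"))))
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  invisible(list(tree = tree, reps = reps, results = results,
                 dom_results = dom_results, summary = summary, pct = pct,
                 per_genome = per_genome, lca_rates = rates,
                 clade_sets = cl_sets, supergroups = sg,
                 out_dir = config$out_dir))
}
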