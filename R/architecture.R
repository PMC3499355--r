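# Combinations are represented throughout as strings "A~B" (N-side ~ C-side).
COMB_SEP <- "~"

comb_string <- function(first, second) paste(first, second, sep = COMB_SEP)

#' Split combination strings into their member domains
#' @param combs character vector of `"A~B"` combination identifiers.
#' @return two-column character matrix (`first`, `second`).
#' @export
split_combination <- function(combs) {
  parts <- strsplit(combs, COMB_SEP, fixed = TRUE)
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  colnames(m) <- c("first", "second")
  m
}

#' Choose a domain-combination model
#'
#' Three operational definitions of a binary domain combination are
#' supported: directed non-adjacent pairs (the default — every ordered pair
#' of distinct domains with the first N-terminal to the second), undirected
#' pairs (A~B collapsed with B~A), and directed adjacent-only pairs
#' (neighbouring domains only).
#'
#' @param directed keep domain order (A~B distinct from B~A)?
#' @param adjacent_only restrict to neighbouring domain pairs?
#' @return an object of class `combination_model`.
#' @export
combination_model <- function(directed = TRUE, adjacent_only = FALSE) {
  if (!directed && adjacent_only)
    stop("supported models: directed, undirected, directed adjacent-only")
  structure(list(directed = directed, adjacent_only = adjacent_only),
            class = "combination_model")
}

#' Build the ordered domain architecture of one protein
#'
#' @param hits resolved (pairwise non-overlapping) hits of a single protein.
#' @return list with `genome_id`, `protein_id` and `domains`, the domain
#'   accessions ordered N-terminus to C-terminus (ascending `env_start`).
#' @export
build_architecture <- function(hits) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0) stop("cannot build an architecture from zero hits")
  if (length(unique(hits$protein_id)) > 1)
    stop("build_architecture expects hits of a single protein")
  ord <- order(hits$env_start)
  list(genome_id = hits$genome_id[1], protein_id = hits$protein_id[1],
       domains = hits$domain_acc[ord])
}

#' Build architectures for every protein in a resolved hit table
#'
#' @param hits resolved hit data.frame (see [resolve_overlaps_by_protein()]).
#' @return data.frame with columns `genome_id`, `protein_id` and a
#'   list-column `domains` (ordered accessions per protein).
#' @export
build_architectures <- function(hits) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0)
    return(data.frame(genome_id = character(), protein_id = character(),
                      domains = I(list()), stringsAsFactors = FALSE))
  ord <- order(hits$genome_id, hits$protein_id, hits$env_start)
  hits <- hits[ord, , drop = FALSE]
  key <- paste(hits$genome_id, hits$protein_id, sep = "\r")
  idx <- split(seq_len(nrow(hits)), factor(key, levels = unique(key)))
  first <- vapply(idx, `[`, integer(1), 1L)
  data.frame(genome_id = hits$genome_id[first],
             protein_id = hits$protein_id[first],
             domains = I(unname(lapply(idx, function(i) hits$domain_acc[i]))),
             stringsAsFactors = FALSE)
}

#' Decompose a domain architecture into binary domain combinations
#'
#' An architecture of domains A, B, C (N- to C-terminus) yields the directed
#' combinations A~B, A~C and B~C under the default model. Pairs of identical
#' domains are never emitted (a repeat such as A-B-B contributes only A~B),
#' and each distinct combination is reported once per protein.
#'
#' @param domains character vector of ordered domain accessions, or an
#'   architecture list from [build_architecture()].
#' @param model a [combination_model()].
#' @return character vector of distinct combination identifiers `"A~B"`.
#' @export
decompose <- function(domains, model = combination_model()) {
  if (is.list(domains) && !is.null(domains$domains)) domains <- domains$domains
  stopifnot(inherits(model, "combination_model"))
  n <- length(domains)
  if (n < 2) return(character(0))
  if (model$adjacent_only) {
    i <- seq_len(n - 1)
    first <- domains[i]; second <- domains[i + 1]
  } else {
    pairs <- utils::combn(n, 2)
    first <- domains[pairs[1, ]]; second <- domains[pairs[2, ]]
  }
  keep <- first != second
  first <- first[keep]; second <- second[keep]
  if (length(first) == 0) return(character(0))
  if (!model$directed) {
    lo <- pmin(first, second); hi <- pmax(first, second)
    first <- lo; second <- hi
  }
  unique(comb_string(first, second))
}

#' Aggregate one genome's architectures into its repertoire
#'
#' The repertoire records the genome's distinct domains, its distinct binary
#' domain combinations under the chosen model, and the bookkeeping counters
#' used in coverage summaries. Domains are additionally partitioned by the
#' protein context they occur in (single-domain vs multidomain proteins).
#'
#' @param archs architecture data.frame ([build_architectures()]) of a single
#'   genome.
#' @param model a [combination_model()].
#' @param n_proteins total proteins in the genome, if known (defaults to the
#'   number of matched proteins, i.e. proteins with at least one accepted
#'   domain).
#' @return an object of class `genome_repertoire`: a list with `genome_id`,
#'   `domains`, `combinations`, `domains_single`, `domains_multi`,
#'   `n_proteins`, `n_matched_proteins`, `n_multidomain_proteins`,
#'   `n_domain_instances`.
#' @export
build_repertoire <- function(archs, model = combination_model(),
                             n_proteins = NULL) {
  g <- unique(archs$genome_id)
  if (length(g) > 1)
    stop("build_repertoire expects a single genome; got: ",
         paste(g, collapse = ", "))
  if (length(g) == 0) stop("no architectures supplied")
  doms <- archs$domains
  nd <- lengths(doms)
  multi <- nd > 1
  combos <- unique(unlist(lapply(doms[multi], decompose, model = model),
                          use.names = FALSE))
  if (is.null(combos)) combos <- character(0)
  rep <- list(
    genome_id = g,
    domains = sort(unique(unlist(doms, use.names = FALSE))),
    combinations = sort(combos),
    domains_single = sort(unique(unlist(doms[!multi], use.names = FALSE))),
    domains_multi = sort(unique(unlist(doms[multi], use.names = FALSE))),
    n_proteins = if (is.null(n_proteins)) nrow(archs) else n_proteins,
    n_matched_proteins = nrow(archs),
    n_multidomain_proteins = sum(multi),
    n_domain_instances = sum(nd))
  if (rep$n_matched_proteins > rep$n_proteins)
    stop("n_proteins smaller than the number of matched proteins")
  structure(rep, class = "genome_repertoire")
}

#' @export
print.genome_repertoire <- function(x, ...) {
  cat(sprintf("<genome_repertoire %s: %d domains, %d combinations, %d/%d proteins matched>\n",
              x$genome_id, length(x$domains), length(x$combinations),
              x$n_matched_proteins, x$n_proteins))
  invisible(x)
}

#' Build repertoires for all genomes in an architecture table
#'
#' @param archs architecture data.frame for any number of genomes.
#' @param model a [combination_model()].
#' @param n_proteins optional named vector of total protein counts per genome.
#' @return named list of `genome_repertoire` objects, one per genome.
#' @export
build_repertoires <- function(archs, model = combination_model(),
                              n_proteins = NULL) {
  parts <- split(archs, archs$genome_id)
  out <- lapply(names(parts), function(g) {
    np <- if (!is.null(n_proteins)) unname(n_proteins[g]) else NULL
    build_repertoire(parts[[g]], model = model, n_proteins = np)
  })
  stats::setNames(out, names(parts))
}

#' Per-genome summary statistics
#'
#' @param rep a `genome_repertoire`.
#' @return one-row data.frame: matched-protein fraction, multidomain
#'   fraction, mean domains per matched protein, distinct domain and
#'   combination counts, and the ratio
#'   \eqn{|combinations| / |domains|^2} (reported as `NA` when the genome
#'   has no domains).
#' @export
genome_summary <- function(rep) {
  stopifnot(inherits(rep, "genome_repertoire"))
  nd <- length(rep$domains)
  data.frame(
    genome_id = rep$genome_id,
    n_proteins = rep$n_proteins,
    frac_matched = rep$n_matched_proteins / rep$n_proteins,
    frac_multidomain = if (rep$n_matched_proteins > 0)
      rep$n_multidomain_proteins / rep$n_matched_proteins else NA_real_,
    mean_domains_per_matched = if (rep$n_matched_proteins > 0)
      rep$n_domain_instances / rep$n_matched_proteins else NA_real_,
    n_domains = nd,
    n_combinations = length(rep$combinations),
    combinations_per_domains_sq = if (nd > 0)
      length(rep$combinations) / nd^2 else NA_real_,
    stringsAsFactors = FALSE)
}

#' Partition observed domains by protein context
#'
#' Splits the union of all observed domains into those found exclusively in
#' single-domain proteins, those found exclusively in multidomain proteins,
#' and those found in both contexts (across all genomes).
#'
#' @param reps list of `genome_repertoire` objects.
#' @return list with character vectors `single_only`, `multi_only`, `both`.
#' @export
partition_domains_by_context <- function(reps) {
  single <- unique(unlist(lapply(reps, `[[`, "domains_single"), use.names = FALSE))
  multi <- unique(unlist(lapply(reps, `[[`, "domains_multi"), use.names = FALSE))
  list(single_only = sort(setdiff(single, multi)),
       multi_only = sort(setdiff(multi, single)),
       both = sort(intersect(single, multi)))
}

#' Export architectures as TSV (genome_id, protein_id, comma-joined domains)
#' @param archs architecture data.frame.
#' @param path output file.
#' @export
write_architectures_tsv <- function(archs, path) {
  df <- data.frame(genome_id = archs$genome_id, protein_id = archs$protein_id,
                   domains = vapply(archs$domains, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an architecture TSV written by [write_architectures_tsv()]
#' @param path TSV file.
#' @return architecture data.frame with a `domains` list-column.
#' @export
read_architectures_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(genome_id = df$genome_id, protein_id = df$protein_id,
             domains = I(strsplit(df$domains, ",", fixed = TRUE)),
             stringsAsFactors = FALSE)
}

#' Export per-genome combination repertoires as TSV
#' @param reps named list of `genome_repertoire` objects.
#' @param path output file.
#' @param model_tag label recorded in the `model` column.
#' @export
write_repertoires_tsv <- function(reps, path, model_tag = "directed") {
  rows <- lapply(reps, function(r) {
    if (length(r$combinations) == 0) return(NULL)
    data.frame(genome_id = r$genome_id, combination = r$combinations,
               model = model_tag, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df))
    df <- data.frame(genome_id = character(), combination = character(),
                     model = character(), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
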