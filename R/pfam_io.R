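# Canonical column order of a hit table. All hit-handling functions return
# data frames with exactly these columns.
HIT_COLUMNS <- c("genome_id", "protein_id", "domain_acc", "domain_name",
                 "env_start", "env_end", "bit_score", "i_evalue", "clan_acc")

empty_hits <- function() {
  data.frame(genome_id = character(), protein_id = character(),
             domain_acc = character(), domain_name = character(),
             env_start = integer(), env_end = integer(),
             bit_score = numeric(), i_evalue = numeric(),
             clan_acc = character(), stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(HIT_COLUMNS %in% names(hits)))
  if (nrow(hits) > 0) {
    if (any(hits$env_start < 1L)) stop("env_start must be >= 1")
    if (any(hits$env_end < hits$env_start)) stop("env_end must be >= env_start")
    if (any(hits$i_evalue < 0)) stop("i_evalue must be >= 0")
  }
  hits[, HIT_COLUMNS]
}

#' Parse HMMER3 per-domain tabular output (domtblout)
#'
#' Reads the whitespace-separated per-domain table written by
#' `hmmscan --domtblout` (hmmscan orientation: the target is the profile HMM,
#' the query is the protein). Envelope coordinates are taken as the extent of
#' each hit; the per-domain independent E-value and per-domain bit score are
#' retained for filtering and overlap resolution.
#'
#' @param path path to a domtblout file, or a character vector of lines via
#'   `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @param genome_id genome identifier to stamp on every hit (domtblout does
#'   not carry one).
#' @return a data.frame of domain hits with columns `genome_id`, `protein_id`,
#'   `domain_acc`, `domain_name`, `env_start`, `env_end`, `bit_score`,
#'   `i_evalue`, `clan_acc` (all `clan_acc` `NA`; clans are attached later
#'   from Pfam metadata).
#' @examples
#' lines <- c(
#'  "# comment",
#'  paste("Kinase PF00069.1 260 prot1 - 500 1e-40 140.0 0.1 1 1",
#'        "1e-38 1e-36 120.5 0.1 1 250 10 255 5 260 0.95 kinase domain"))
#' parse_domtblout(text = lines, genome_id = "g001")
#' @export
parse_domtblout <- function(path = NULL, text = NULL, genome_id = NA_character_) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0) return(empty_hits())

  parse_one <- function(line, lineno) {
    f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(f) < 22)
      stop(sprintf("domtblout line %d: expected >= 22 fields, got %d",
                   lineno, length(f)))
    num <- suppressWarnings(as.numeric(f[c(13, 14, 20, 21)]))
    if (anyNA(num))
      stop(sprintf("domtblout line %d: unparseable numeric field", lineno))
    # strip Pfam accession version suffix (PF00069.26 -> PF00069)
    acc <- sub("\\.\\d+$", "", f[2])
    if (acc == "-") acc <- f[1]
    data.frame(genome_id = genome_id, protein_id = f[4],
               domain_acc = acc, domain_name = f[1],
               env_start = as.integer(num[3]), env_end = as.integer(num[4]),
               bit_score = num[2], i_evalue = num[1],
               clan_acc = NA_character_, stringsAsFactors = FALSE)
  }
  rows <- mapply(parse_one, lines, seq_along(lines), SIMPLIFY = FALSE)
  validate_hits(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Write hits as an HMMER3 domtblout table
#'
#' Emits one domtblout-formatted row per hit (hmmscan orientation), suitable
#' for re-reading with [parse_domtblout()]. Fields the hit table does not
#' carry (alignment coordinates, biases, full-sequence scores) are filled
#' with placeholder values.
#'
#' @param hits a hit data.frame.
#' @param path output file.
#' @export
write_domtblout <- function(hits, path) {
  hits <- validate_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# --- domain hits (domtblout dialect) ---", con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    writeLines(paste(h$domain_name, h$domain_acc, 999L, h$protein_id, "-",
                     9999L, format(h$i_evalue, digits = 3), h$bit_score, 0.0,
                     1L, 1L, format(h$i_evalue, digits = 3),
                     format(h$i_evalue, digits = 3), h$bit_score, 0.0,
                     1L, 999L, h$env_start, h$env_end, h$env_start, h$env_end,
                     0.99, "-", sep = " "), con)
  }
  invisible(path)
}

#' Read a generic tab-separated hit table
#'
#' Accepts the package's plain TSV hit dialect with header columns
#' `genome_id, protein_id, domain_acc, env_start, env_end, bit_score,
#' i_evalue` and optional `domain_name`, `clan_acc`. This is the format the
#' synthetic-evolution generator emits.
#'
#' @param path TSV file path.
#' @return hit data.frame (see [parse_domtblout()] for columns).
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "protein_id", "domain_acc", "env_start", "env_end",
            "bit_score", "i_evalue")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("hit TSV is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$domain_name)) df$domain_name <- df$domain_acc
  if (is.null(df$clan_acc)) df$clan_acc <- NA_character_
  df$env_start <- as.integer(df$env_start)
  df$env_end <- as.integer(df$env_end)
  validate_hits(df)
}

#' Write the generic hit TSV
#' @param hits hit data.frame.
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(validate_hits(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundle Pfam metadata: score cutoffs, clan membership, exclusions
#'
#' @param cutoffs data.frame with columns `pfam_acc`, `GA`, `TC`, `NC`
#'   (per-domain bit-score thresholds; TC >= GA >= NC is enforced where all
#'   three are present).
#' @param clans named character vector mapping domain accession to clan
#'   accession (domains without a clan are simply absent, or mapped to `NA`).
#' @param exclusions character vector of domain accessions to drop outright
#'   (e.g. viral, transposon and bacteriophage-associated families).
#' @return an object of class `pfam_metadata`.
#' @export
pfam_metadata <- function(cutoffs = NULL, clans = character(), exclusions = character()) {
  if (is.null(cutoffs))
    cutoffs <- data.frame(pfam_acc = character(), GA = numeric(),
                          TC = numeric(), NC = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("pfam_acc", "GA", "TC", "NC") %in% names(cutoffs)))
  ok <- stats::complete.cases(cutoffs[, c("GA", "TC", "NC")])
  bad <- ok & !(cutoffs$TC >= cutoffs$GA & cutoffs$GA >= cutoffs$NC)
  if (any(bad))
    stop("cutoff ordering TC >= GA >= NC violated for: ",
         paste(cutoffs$pfam_acc[bad], collapse = ", "))
  clans <- clans[!is.na(clans)]
  structure(list(cutoffs = cutoffs, clans = clans,
                 exclusions = unique(as.character(exclusions))),
            class = "pfam_metadata")
}

#' @export
print.pfam_metadata <- function(x, ...) {
  cat("Pfam metadata:", nrow(x$cutoffs), "cutoff entries,",
      length(x$clans), "clan memberships,",
      length(x$exclusions), "excluded accessions\n")
  invisible(x)
}

#' Read a per-domain cutoff table (TSV: pfam_acc, GA, TC, NC)
#' @param path TSV file.
#' @return data.frame usable as the `cutoffs` slot of [pfam_metadata()].
#' @export
read_cutoffs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pfam_acc", "GA", "TC", "NC") %in% names(df)))
  df
}

#' Read a Pfam clans table
#'
#' Pfam-A clans TSV dialect: columns `pfam_acc`, `clan_acc`, `clan_id`,
#' `pfam_id`, `description` (only the first two are used); an empty
#' `clan_acc` means the family belongs to no clan.
#'
#' @param path TSV file.
#' @return named character vector domain accession -> clan accession,
#'   covering only domains that have a clan.
#' @export
read_clans_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pfam_acc", "clan_acc") %in% names(df)))
  keep <- !is.na(df$clan_acc) & nzchar(df$clan_acc)
  stats::setNames(df$clan_acc[keep], df$pfam_acc[keep])
}

#' Read an exclusion list (one domain accession per line)
#' @param path text file.
#' @return character vector of accessions.
#' @export
read_exclusions <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Define a score-filtering policy
#'
#' Hits can be filtered by one of Pfam's per-domain bit-score thresholds —
#' the gathering (`GA`), trusted (`TC`) or noise (`NC`) cutoff — or by a
#' uniform independent E-value threshold (`EVALUE`).
#'
#' @param mode one of `"GA"`, `"TC"`, `"NC"`, `"EVALUE"`.
#' @param evalue_threshold required when `mode = "EVALUE"`; hits with
#'   `i_evalue <= evalue_threshold` are retained.
#' @return an object of class `cutoff_policy`.
#' @export
cutoff_policy <- function(mode = c("GA", "TC", "NC", "EVALUE"),
                          evalue_threshold = NULL) {
  mode <- match.arg(mode)
  if (mode == "EVALUE") {
    if (is.null(evalue_threshold) || evalue_threshold <= 0)
      stop("EVALUE mode requires evalue_threshold > 0")
  } else if (!is.null(evalue_threshold)) {
    stop("evalue_threshold only applies to EVALUE mode")
  }
  structure(list(mode = mode, evalue_threshold = evalue_threshold),
            class = "cutoff_policy")
}

#' Filter domain hits by score policy and exclusion list
#'
#' Retains hits whose bit score reaches the per-domain cutoff of the chosen
#' mode (or whose independent E-value passes the uniform threshold), then
#' drops hits on excluded accessions. Input order is preserved.
#'
#' @param hits hit data.frame.
#' @param meta a [pfam_metadata()] object.
#' @param policy a [cutoff_policy()] object.
#' @return the retained hits, with `clan_acc` filled in from the metadata.
#' @export
filter_hits <- function(hits, meta, policy) {
  hits <- validate_hits(hits)
  stopifnot(inherits(meta, "pfam_metadata"), inherits(policy, "cutoff_policy"))
  if (nrow(hits) == 0) return(hits)
  if (policy$mode == "EVALUE") {
    keep <- hits$i_evalue <= policy$evalue_threshold
  } else {
    idx <- match(hits$domain_acc, meta$cutoffs$pfam_acc)
    cut <- meta$cutoffs[[policy$mode]][idx]
    if (anyNA(cut)) {
      missing <- unique(hits$domain_acc[is.na(cut)])
      stop(sprintf("no %s cutoff for accession(s): %s", policy$mode,
                   paste(missing, collapse = ", ")))
    }
    keep <- hits$bit_score >= cut
  }
  keep <- keep & !(hits$domain_acc %in% meta$exclusions)
  out <- hits[keep, , drop = FALSE]
  cl <- unname(meta$clans[out$domain_acc])
  out$clan_acc <- ifelse(is.na(cl), out$clan_acc, cl)
  rownames(out) <- NULL
  out
}

#' Resolve overlapping hits on one protein
#'
#' Among hits on the same protein, overlapping matches (sharing at least one
#' residue under 1-based inclusive envelope coordinates) are resolved by
#' keeping the hit with the lowest independent E-value: hits are accepted
#' greedily in ascending E-value order (ties broken by descending bit score,
#' then lexicographic accession, then ascending start) and a hit is rejected
#' iff it overlaps an already-accepted hit.
#'
#' @param hits hit data.frame for a single protein.
#' @return the accepted, pairwise non-overlapping hits, sorted by `env_start`.
#' @export
resolve_overlaps <- function(hits) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$protein_id)) > 1)
    stop("resolve_overlaps expects hits of a single protein; got: ",
         paste(unique(hits$protein_id), collapse = ", "))
  ord <- order(hits$i_evalue, -hits$bit_score, hits$domain_acc, hits$env_start)
  hits <- hits[ord, , drop = FALSE]
  acc_start <- integer(0)
  acc_end <- integer(0)
  take <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- hits$env_start[i]; e <- hits$env_end[i]
    if (!any(s <= acc_end & e >= acc_start)) {
      take[i] <- TRUE
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
    }
  }
  out <- hits[take, , drop = FALSE]
  out <- out[order(out$env_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlaps for every protein in a hit table
#'
#' Applies [resolve_overlaps()] within each (genome, protein) group.
#'
#' @param hits hit data.frame covering any number of proteins.
#' @return non-overlapping hits, grouped by genome and protein, each group
#'   sorted by `env_start`.
#' @export
resolve_overlaps_by_protein <- function(hits) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0) return(hits)
  key <- paste(hits$genome_id, hits$protein_id, sep = "\r")
  parts <- split(hits, factor(key, levels = unique(key)))
  out <- do.call(rbind, c(lapply(parts, resolve_overlaps),
                          list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
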