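# Ancestral presence/absence reconstruction of binary characters on a rooted
# tree. The Fitch engine is a unit-cost dynamic program over node states
# (Sankoff recursion restricted to {0,1}), which generalizes the two-child
# Fitch rule correctly to multifurcations (Hartigan). The bottom-up pass is
# vectorized across characters so thousands of combinations are processed in
# one sweep.

BIG_COST <- 1e9

new_parsimony_result <- function(character, node_states, gain_nodes, loss_nodes,
                                 total_changes, method, tree) {
  nm <- node_names(tree)
  root <- root_id(tree)
  structure(list(
    character = character,
    node_states = stats::setNames(as.integer(node_states), nm),
    gain_nodes = nm[gain_nodes],
    loss_nodes = nm[loss_nodes],
    n_gains = length(gain_nodes),
    n_losses = length(loss_nodes),
    total_changes = as.integer(total_changes),
    total_events = length(gain_nodes) + length(loss_nodes),
    root_state = as.integer(node_states[root]),
    method = method), class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("<parsimony_result [%s] %s: %d gain(s) at {%s}, %d loss(es) at {%s}, %d edge change(s)>\n",
              x$method, if (is.null(x$character)) "" else x$character,
              x$n_gains, paste(x$gain_nodes, collapse = ","),
              x$n_losses, paste(x$loss_nodes, collapse = ","),
              x$total_changes))
  invisible(x)
}

check_tip_states <- function(tree, tip_states) {
  if (is.null(names(tip_states)))
    stop("tip_states must be named by tip label")
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss) > 0)
    stop("tip_states missing for tips: ", paste(miss, collapse = ", "))
  st <- as.integer(tip_states[tree$tip.label])
  if (!all(st %in% c(0L, 1L))) stop("tip states must be 0 or 1")
  stats::setNames(st, tree$tip.label)
}

# Core vectorized reconstruction. X: integer matrix, rows = characters,
# columns named by tip label. Returns resolved state matrix plus per-edge
# bookkeeping.
fitch_engine <- function(tree, X, root_preference = c("absent", "present")) {
  root_preference <- match.arg(root_preference)
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  if (!all(tree$tip.label %in% colnames(X)))
    stop("character matrix missing tips: ",
         paste(setdiff(tree$tip.label, colnames(X)), collapse = ", "))
  Xs <- X[, tree$tip.label, drop = FALSE]
  storage.mode(Xs) <- "integer"
  if (!all(Xs %in% c(0L, 1L))) stop("tip states must be 0 or 1")
  k <- nrow(Xs)
  po <- stats::reorder(tree, "postorder")$edge

  cost0 <- matrix(0, k, n_all)
  cost1 <- matrix(0, k, n_all)
  cost0[, seq_len(n_tip)] <- ifelse(Xs == 0L, 0, BIG_COST)
  cost1[, seq_len(n_tip)] <- ifelse(Xs == 1L, 0, BIG_COST)
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    cost0[, p] <- cost0[, p] + pmin(cost0[, ch], cost1[, ch] + 1)
    cost1[, p] <- cost1[, p] + pmin(cost1[, ch], cost0[, ch] + 1)
  }

  S <- matrix(NA_integer_, k, n_all)
  root <- n_tip + 1L
  S[, root] <- if (root_preference == "absent")
    as.integer(cost1[, root] < cost0[, root])
  else
    as.integer(cost1[, root] <= cost0[, root])
  for (i in rev(seq_len(nrow(po)))) {
    p <- po[i, 1]; ch <- po[i, 2]
    ps <- S[, p]
    keep_cost <- ifelse(ps == 1L, cost1[, ch], cost0[, ch])
    switch_cost <- ifelse(ps == 1L, cost0[, ch], cost1[, ch]) + 1
    S[, ch] <- ifelse(keep_cost <= switch_cost, ps, 1L - ps)
  }

  min_changes <- pmin(cost0[, root], cost1[, root])
  list(states = S, edges = tree$edge, root = root,
       min_changes = as.integer(min_changes))
}

#' Fitch (unweighted) parsimony for one binary character
#'
#' Reconstructs ancestral presence/absence minimizing the number of state
#' changes along edges; gains and losses cost equally. Multifurcations are
#' handled exactly (the recursion is a unit-cost dynamic program over node
#' states, not the two-child set rule). Among equally parsimonious
#' reconstructions one is chosen deterministically: with
#' `root_preference = "absent"` (default) the root is scored absent on a
#' tie — a character absent from all extant genomes would trivially be
#' ancestrally absent — and each ambiguous child adopts its parent's
#' resolved state.
#'
#' @param tree rooted `phylo` object (polytomies allowed).
#' @param tip_states named 0/1 vector covering every tip.
#' @param root_preference `"absent"` or `"present"`; which state the root
#'   takes when both are equally parsimonious.
#' @param character optional character identifier stored in the result.
#' @return a `parsimony_result`: resolved `node_states`, `gain_nodes` (nodes
#'   whose state is 1 while the parent's is 0, plus the root when its state
#'   is 1), `loss_nodes` (1 -> 0), `total_changes` (edge changes — the global
#'   minimum; a root gain is an appearance, not an edge change) and
#'   `total_events` (`n_gains + n_losses`).
#' @export
fitch_binary <- function(tree, tip_states, root_preference = c("absent", "present"),
                         character = NULL) {
  st <- check_tip_states(tree, tip_states)
  eng <- fitch_engine(tree, matrix(st, 1, dimnames = list(NULL, names(st))),
                      root_preference)
  s <- eng$states[1, ]
  e <- eng$edges
  changed <- s[e[, 1]] != s[e[, 2]]
  gains <- e[changed & s[e[, 2]] == 1L, 2]
  losses <- e[changed & s[e[, 2]] == 0L, 2]
  if (s[eng$root] == 1L) gains <- c(eng$root, gains)
  stopifnot(sum(changed) == eng$min_changes)
  new_parsimony_result(character, s, gains, losses, eng$min_changes,
                       "fitch", tree)
}

#' Dollo parsimony for one binary character
#'
#' A character may be gained exactly once — at the last common ancestor of
#' all tips carrying it — and subsequently lost any number of times. Losses
#' are the minimal set explaining all absent descendants: one per maximal
#' subtree of the gain clade containing no carrier tip.
#'
#' @inheritParams fitch_binary
#' @return a `parsimony_result` (method `"dollo"`). A character absent from
#'   every tip yields zero gains and zero losses.
#' @export
dollo_binary <- function(tree, tip_states, character = NULL) {
  st <- check_tip_states(tree, tip_states)
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  present_tips <- which(st == 1L)
  if (length(present_tips) == 0)
    return(new_parsimony_result(character, rep(0L, n_all), integer(0),
                                integer(0), 0L, "dollo", tree))
  gain <- lca(tree, present_tips)

  # carriers[v]: does subtree(v) contain a present tip?
  carriers <- rep(FALSE, n_all)
  carriers[present_tips] <- TRUE
  po <- stats::reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    carriers[po[i, 1]] <- carriers[po[i, 1]] || carriers[po[i, 2]]

  in_gain_clade <- rep(FALSE, n_all)
  in_gain_clade[gain] <- TRUE
  for (i in rev(seq_len(nrow(po))))   # preorder
    if (in_gain_clade[po[i, 1]]) in_gain_clade[po[i, 2]] <- TRUE

  states <- as.integer(in_gain_clade & carriers)
  e <- tree$edge
  losses <- e[states[e[, 1]] == 1L & states[e[, 2]] == 0L, 2]
  total_changes <- length(losses) + as.integer(gain != root_id(tree))
  new_parsimony_result(character, states, gain, losses, total_changes,
                       "dollo", tree)
}

#' Exact minimum change count by exhaustive enumeration (test oracle)
#'
#' Enumerates every assignment of states to internal nodes and returns the
#' smallest number of edges whose endpoints disagree. Exponential in the
#' number of internal nodes; refuses trees with more than 20.
#'
#' @inheritParams fitch_binary
#' @return integer: the global minimum number of edge changes.
#' @export
brute_force_min_changes <- function(tree, tip_states) {
  st <- check_tip_states(tree, tip_states)
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  if (n_int > 20) stop("brute_force_min_changes: > 20 internal nodes")
  e <- tree$edge
  states <- c(st, rep(0L, n_int))
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    states[n_tip + seq_len(n_int)] <- bitwAnd(bitwShiftR(mask, seq_len(n_int) - 1L), 1L)
    best <- min(best, sum(states[e[, 1]] != states[e[, 2]]))
  }
  as.integer(best)
}

#' Build a presence/absence character matrix from genome repertoires
#'
#' @param reps named list of `genome_repertoire` objects.
#' @param tree a `phylo` object; every repertoire genome must be a tip.
#'   Tips without a repertoire get state 0 for every character.
#' @param what `"combinations"` or `"domains"`.
#' @param characters optional character subset/ordering; defaults to the
#'   union observed across repertoires.
#' @return integer 0/1 matrix, rows = characters, columns = tips.
#' @export
build_character_matrix <- function(reps, tree, what = c("combinations", "domains"),
                                   characters = NULL) {
  what <- match.arg(what)
  bad <- setdiff(names(reps), tree$tip.label)
  if (length(bad) > 0)
    stop("repertoire genomes not on the tree: ", paste(bad, collapse = ", "))
  if (is.null(characters))
    characters <- sort(unique(unlist(lapply(reps, `[[`, what), use.names = FALSE)))
  X <- matrix(0L, length(characters), length(tree$tip.label),
              dimnames = list(characters, tree$tip.label))
  for (g in names(reps)) {
    obs <- intersect(reps[[g]][[what]], characters)
    X[obs, g] <- 1L
  }
  X
}

#' Reconstruct every character of a matrix
#'
#' Runs [fitch_binary()] (vectorized across characters) or [dollo_binary()]
#' on each row of a presence/absence matrix.
#'
#' @param tree rooted `phylo` object.
#' @param X 0/1 matrix, rows = characters (rownames required), columns = tips.
#' @param method `"fitch"` (domain combinations) or `"dollo"` (individual
#'   domains).
#' @param root_preference tie-break for the Fitch root state.
#' @return named list of `parsimony_result`, one per character, in row order.
#' @export
reconstruct_characters <- function(tree, X, method = c("fitch", "dollo"),
                                   root_preference = c("absent", "present")) {
  method <- match.arg(method)
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  if (method == "dollo") {
    res <- lapply(rownames(X), function(ch)
      dollo_binary(tree, X[ch, ], character = ch))
    return(stats::setNames(res, rownames(X)))
  }
  eng <- fitch_engine(tree, X, root_preference)
  e <- eng$edges
  res <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    s <- eng$states[i, ]
    changed <- s[e[, 1]] != s[e[, 2]]
    gains <- e[changed & s[e[, 2]] == 1L, 2]
    losses <- e[changed & s[e[, 2]] == 0L, 2]
    if (s[eng$root] == 1L) gains <- c(eng$root, gains)
    res[[i]] <- new_parsimony_result(rownames(X)[i], s, gains, losses,
                                     eng$min_changes[i], "fitch", tree)
  }
  stats::setNames(res, rownames(X))
}

#' Export parsimony results as TSV
#' @param results named list of `parsimony_result`.
#' @param path output file.
#' @export
write_parsimony_tsv <- function(results, path) {
  df <- data.frame(
    character = vapply(results, function(r) r$character %||% "", ""),
    n_gains = vapply(results, `[[`, integer(1), "n_gains"),
    n_losses = vapply(results, `[[`, integer(1), "n_losses"),
    total_changes = vapply(results, `[[`, integer(1), "total_changes"),
    gain_nodes = vapply(results, function(r) paste(r$gain_nodes, collapse = ","), ""),
    loss_nodes = vapply(results, function(r) paste(r$loss_nodes, collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
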