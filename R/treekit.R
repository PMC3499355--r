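# Trees are rooted ape "phylo" objects. Tips are genome identifiers; internal
# nodes may carry clade names (e.g. "Metazoa") in tree$node.label. Nodes are
# addressed by ape node number internally and by name at the interfaces.

#' Read a rooted species tree (Newick or phyloXML)
#'
#' @param path file path, or Newick text via `text`.
#' @param format `"auto"` (by extension/content), `"newick"` or `"phyloxml"`.
#' @param text optional Newick string instead of a file.
#' @return a rooted `phylo` object; internal node names and polytomies are
#'   preserved. Duplicate tip labels are an error.
#' @export
read_tree <- function(path = NULL, format = c("auto", "newick", "phyloxml"),
                      text = NULL) {
  format <- match.arg(format)
  if (!is.null(text)) {
    tree <- ape::read.tree(text = text)
  } else {
    if (format == "auto") {
      format <- if (grepl("\\.(xml|phyloxml)$", path, ignore.case = TRUE))
        "phyloxml" else "newick"
    }
    tree <- if (format == "phyloxml") read_phyloxml(path)$tree
            else ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse tree")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  # the basal node is taken as the root; a basal polytomy is a root polytomy
  tree
}

#' Human-readable name of every node
#'
#' Tips keep their labels; internal nodes use their clade name when present
#' and a stable `"node<N>"` placeholder otherwise.
#'
#' @param tree a `phylo` object.
#' @return character vector indexed by ape node number
#'   (1..Ntip are tips, Ntip+1.. are internal nodes).
#' @export
node_names <- function(tree) {
  n_tip <- length(tree$tip.label)
  inner <- if (!is.null(tree$node.label)) tree$node.label
           else rep("", tree$Nnode)
  blank <- !nzchar(inner) | is.na(inner)
  inner[blank] <- paste0("node", (n_tip + 1):(n_tip + tree$Nnode))[blank]
  c(tree$tip.label, inner)
}

#' Resolve a node reference (name or number) to an ape node number
#' @param tree a `phylo` object.
#' @param node node name (tip label or internal/clade name) or node number.
#' @return integer node number.
#' @export
node_id <- function(tree, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (any(node < 1 | node > length(tree$tip.label) + tree$Nnode))
      stop("node number out of range: ", node)
    return(node)
  }
  id <- match(node, node_names(tree))
  if (anyNA(id)) stop("unknown node(s): ", paste(node[is.na(id)], collapse = ", "))
  id
}

tree_children <- function(tree) {
  # adjacency list: children[[node]] = integer vector of child node numbers
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  e <- tree$edge
  for (i in seq_len(nrow(e))) kids[[e[i, 1]]] <- c(kids[[e[i, 1]]], e[i, 2])
  kids
}

tree_parent <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

root_id <- function(tree) length(tree$tip.label) + 1L

#' Root path of a node (the node itself, its ancestors, up to the root)
#' @param tree a `phylo` object.
#' @param node node name or number.
#' @return integer vector of node numbers, deepest first.
#' @export
node_ancestors <- function(tree, node) {
  id <- node_id(tree, node)
  parent <- tree_parent(tree)
  path <- id
  while (!is.na(parent[id])) {
    id <- parent[id]
    path <- c(path, id)
  }
  path
}

#' Last common ancestor of a set of nodes
#'
#' Accepts tips and/or internal nodes; the LCA of a single node is the node
#' itself, and the LCA of an ancestor-descendant pair is the ancestor.
#'
#' @param tree a `phylo` object.
#' @param nodes non-empty vector of node names or numbers.
#' @return node number of the LCA.
#' @export
lca <- function(tree, nodes) {
  if (length(nodes) == 0) stop("lca of an empty node set is undefined")
  paths <- lapply(nodes, function(x) node_ancestors(tree, x))
  common <- Reduce(intersect, paths)
  common[1]
}

#' Tip descendants of a node
#' @param tree a `phylo` object.
#' @param node node name or number (a tip is its own descendant).
#' @return integer vector of tip numbers.
#' @export
tips_under <- function(tree, node) {
  id <- node_id(tree, node)
  n_tip <- length(tree$tip.label)
  if (id <= n_tip) return(id)
  kids <- tree_children(tree)
  out <- integer(0)
  stack <- id
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= n_tip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  sort(out)
}

#' Number of tip descendants of a node
#' @param tree a `phylo` object.
#' @param node node name or number.
#' @return integer count (a tip counts 1).
#' @export
leaf_count <- function(tree, node) length(tips_under(tree, node))

#' Tip labels belonging to a named clade
#' @param tree a `phylo` object.
#' @param clade internal node name (or a tip label, giving that single tip).
#' @return character vector of tip labels.
#' @export
clade_tips <- function(tree, clade) {
  tree$tip.label[tips_under(tree, node_id(tree, clade))]
}

#' Write a tree as Newick
#' @param tree a `phylo` object.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

PHYLOXML_NS <- "http://www.phyloxml.org"

#' Write a phyloXML document, optionally with per-node gain/loss annotations
#'
#' Gains and losses are emitted as phyloXML `<property>` elements
#' (`ref="combevol:gain"` / `ref="combevol:loss"`, one element per character)
#' attached to the clade they occur at, so annotated trees open in standard
#' phyloXML viewers.
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @param annotations named list keyed by node name (see [node_names()]);
#'   each element a list with optional character vectors `gains`, `losses`.
#' @export
write_annotated_tree <- function(tree, path, annotations = list()) {
  validate_tree(tree)
  nm <- node_names(tree)
  bad <- setdiff(names(annotations), nm)
  if (length(bad) > 0) stop("annotation keys are not nodes: ",
                            paste(bad, collapse = ", "))
  kids <- tree_children(tree)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  clade_xml <- function(id) {
    ann <- annotations[[nm[id]]]
    props <- character(0)
    for (ref in c("gain", "loss")) {
      vals <- ann[[c(gain = "gains", loss = "losses")[[ref]]]]
      if (length(vals) > 0)
        props <- c(props, sprintf(
          '<property ref="combevol:%s" datatype="xsd:string" applies_to="clade">%s</property>',
          ref, esc(vals)))
    }
    paste0("<clade><name>", esc(nm[id]), "</name>",
           paste(props, collapse = ""),
           paste(vapply(kids[[id]], clade_xml, ""), collapse = ""),
           "</clade>")
  }
  doc <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<phyloxml xmlns="', PHYLOXML_NS, '">',
                '<phylogeny rooted="true">',
                clade_xml(root_id(tree)),
                "</phylogeny></phyloxml>\n")
  # validate well-formedness before writing
  xml2::read_xml(doc)
  writeLines(doc, path)
  invisible(path)
}

#' Read a phyloXML document
#'
#' @param path phyloXML file.
#' @return list with `tree` (a `phylo` object) and `annotations` (named list
#'   keyed by node name, each with `gains`/`losses` character vectors;
#'   empty when the document carries no gain/loss properties).
#' @export
read_phyloxml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  phylo_node <- xml2::xml_find_first(doc, ".//phylogeny/clade")
  if (inherits(phylo_node, "xml_missing")) stop("no <clade> found in phyloXML")
  annotations <- list()
  build <- function(node) {
    name <- xml2::xml_text(xml2::xml_find_first(node, "./name"))
    if (is.na(name) || !nzchar(name)) stop("phyloXML clade without a <name>")
    props <- xml2::xml_find_all(node, "./property")
    if (length(props) > 0) {
      refs <- xml2::xml_attr(props, "ref")
      vals <- xml2::xml_text(props)
      ann <- list(gains = vals[refs == "combevol:gain"],
                  losses = vals[refs == "combevol:loss"])
      if (length(ann$gains) + length(ann$losses) > 0)
        annotations[[name]] <<- ann
    }
    children <- xml2::xml_find_all(node, "./clade")
    if (length(children) == 0) return(name)
    sub <- vapply(children, build, "")
    paste0("(", paste(sub, collapse = ","), ")", name)
  }
  newick <- paste0(build(phylo_node), ";")
  tree <- validate_tree(ape::read.tree(text = newick))
  list(tree = tree, annotations = annotations)
}
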