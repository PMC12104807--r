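#' Built-in species-tree hypotheses
#'
#' Returns one of the two rooted cladograms over the five terminal clades
#' (Cnidaria, Xenacoelomorpha, Protostomia, Chordata, Ambulacraria) that frame
#' the placement of Xenacoelomorpha:
#'
#' * `nephrozoa` — Xenacoelomorpha sister to all remaining Bilateria
#'   (Protostomia + Deuterostomia):
#'   `(Cnidaria,(Xenacoelomorpha,(Protostomia,(Chordata,Ambulacraria)Deuterostomia)Nephrozoa)Bilateria)Eumetazoa`
#' * `xenambulacraria` — Xenacoelomorpha sister to Ambulacraria, nested inside
#'   Deuterostomia:
#'   `(Cnidaria,(Protostomia,((Ambulacraria,Xenacoelomorpha)Xenambulacraria,Chordata)Deuterostomia)Bilateria)Eumetazoa`
#'
#' Both are cladograms: branch lengths are ignored throughout because the
#' gain/loss argument is purely topological. Cnidaria is the outgroup in both.
#' The `"Bilateria"` internal node is the designated bilaterian-ancestor node
#' in each (attribute `node_of_interest`).
#'
#' @param name `"nephrozoa"` or `"xenambulacraria"`.
#' @return an [ape::phylo] rooted binary tree with unique internal node labels.
#' @export
builtin_tree <- function(name = c("nephrozoa", "xenambulacraria")) {
  name <- match.arg(name)
  nwk <- switch(name,
    nephrozoa = paste0(
      "(Cnidaria,(Xenacoelomorpha,(Protostomia,(Chordata,Ambulacraria)",
      "Deuterostomia)Nephrozoa)Bilateria)Eumetazoa;"),
    xenambulacraria = paste0(
      "(Cnidaria,(Protostomia,((Ambulacraria,Xenacoelomorpha)Xenambulacraria,",
      "Chordata)Deuterostomia)Bilateria)Eumetazoa;"))
  tree <- ape::read.tree(text = nwk)
  tree <- validate_clade_tree(tree)
  attr(tree, "node_of_interest") <- c(bilaterian_ancestor = "Bilateria")
  attr(tree, "hypothesis") <- name
  tree
}

#' Validate a rooted binary clade tree
#'
#' Checks the invariants the reconstruction engine relies on: rooted, fully
#' binary, unique tip labels, unique internal labels. Unlabeled internal nodes
#' are auto-named deterministically `n<i>` by postorder index, with a warning.
#'
#' @param tree an [ape::phylo].
#' @return the validated (possibly relabeled) tree.
#' @export
validate_clade_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be fully binary (no polytomies)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ", tree$tip.label[duplicated(tree$tip.label)][1L])
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  lab[is.na(lab)] <- ""
  if (any(!nzchar(lab))) {
    po <- postorder_nodes(tree)
    internals_po <- po[po > length(tree$tip.label)]
    # rank of each internal node in postorder, used for deterministic names
    rank <- match(seq_len(n_int) + length(tree$tip.label), internals_po)
    need <- which(!nzchar(lab))
    lab[need] <- paste0("n", rank[need])
    warning("unlabeled internal node(s) auto-named: ",
            paste(lab[need], collapse = ", "))
  }
  if (anyDuplicated(lab))
    stop("duplicate internal node label: ", lab[duplicated(lab)][1L])
  if (length(intersect(lab, tree$tip.label)))
    stop("internal label collides with a tip label: ",
         intersect(lab, tree$tip.label)[1L])
  tree$node.label <- lab
  tree
}

#' Read / write a clade tree in Newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that apply
#' [validate_clade_tree()] on the way in and preserve internal node labels on
#' the way out, so a write/read cycle preserves topology and labels.
#'
#' @param path file path.
#' @return `read_clade_tree` returns a validated [ape::phylo].
#' @export
read_clade_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path), collapse = "")
  if (!grepl(";", txt, fixed = TRUE)) stop("malformed Newick: missing ';'")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: unreadable tree")
  validate_clade_tree(tree)
}

#' @rdname read_clade_tree
#' @param tree an [ape::phylo].
#' @export
write_clade_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---- internal tree arithmetic ---------------------------------------------
# Nodes follow ape numbering: tips 1..n, internals (n+1)..(n+Nnode), root n+1.

node_names <- function(tree) c(tree$tip.label, tree$node.label)

node_id <- function(tree, name) {
  id <- match(name, node_names(tree))
  if (is.na(id)) stop("unknown node: ", name)
  id
}

root_id <- function(tree) length(tree$tip.label) + 1L

children_of <- function(tree, node) tree$edge[tree$edge[, 1L] == node, 2L]

parent_of <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2L] == node, 1L]
  if (length(p) == 0L) NA_integer_ else p
}

# all node ids in postorder (children before parents), deterministic
postorder_nodes <- function(tree) {
  res <- integer(0)
  walk <- function(node) {
    for (ch in children_of(tree, node)) walk(ch)
    res[[length(res) + 1L]] <<- node
  }
  walk(root_id(tree))
  unlist(res)
}

# ids of ancestors of `node` from root down to (and including) `node`
root_path <- function(tree, node) {
  path <- node
  while (!is.na(p <- parent_of(tree, node))) {
    path <- c(p, path)
    node <- p
  }
  path
}

tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  walk <- function(nd) {
    if (nd <= n_tip) out[[length(out) + 1L]] <<- nd
    else for (ch in children_of(tree, nd)) walk(ch)
  }
  walk(node)
  unlist(out)
}

#' Last common ancestor of a set of clades
#'
#' @param tree an [ape::phylo] with named nodes.
#' @param names character vector of tip and/or internal node names (length >= 1).
#' @return the name of the LCA node. `clade_lca(tree, x)` with a single name
#'   returns `x` itself (LCA is idempotent).
#' @export
clade_lca <- function(tree, names) {
  stopifnot(length(names) >= 1L)
  ids <- vapply(names, node_id, 0L, tree = tree)
  paths <- lapply(ids, root_path, tree = tree)
  common <- Reduce(intersect, paths)
  node_names(tree)[common[length(common)]]
}

# descendant-or-self test on names
is_descendant_or_self <- function(tree, node, ancestor) {
  node_id(tree, ancestor) %in% root_path(tree, node_id(tree, node))
}
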