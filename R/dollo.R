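#' Per-family reconstruction configuration
#'
#' Optional evidence that modifies the default single-gain reconstruction of
#' one family:
#'
#' * `gain_override` pins the gain to a named internal node above (or equal
#'   to) the LCA of the family's present terminals. Used when gene-tree
#'   evidence places the origin deeper than the presence pattern alone would
#'   (e.g. the xenacoelomorph-specific opsins pinned to the bilaterian
#'   ancestor).
#' * `surrogate_of` names a second family assumed homologous to this one:
#'   absence of this family in a lineage that retains the surrogate is
#'   explained by that homology and recorded as a *suppressed* loss, not
#'   counted. This is the minimal-steps assumption linking the
#'   xenacoelomorph-specific opsins to the canonical r-opsins.
#' * `duplication_parent` records that the family arose by duplication of
#'   another family; this is gain bookkeeping only (duplications are tallied
#'   separately and never enter the loss-parsimony comparison).
#'
#' @param family family identifier.
#' @param gain_override optional internal-node name.
#' @param surrogate_of optional family identifier (must differ from `family`).
#' @param duplication_parent optional family identifier.
#' @return object of class `family_config`.
#' @export
family_config <- function(family, gain_override = NULL, surrogate_of = NULL,
                          duplication_parent = NULL) {
  if (!is.null(surrogate_of) && identical(surrogate_of, family))
    stop("surrogate_of must name a distinct family")
  structure(list(family = family, gain_override = gain_override,
                 surrogate_of = surrogate_of,
                 duplication_parent = duplication_parent),
            class = "family_config")
}

#' Packaged opsin family configurations
#'
#' The reconstruction settings used for the shipped opsin matrices: the
#' xenacoelomorph-specific opsin family is pinned to the bilaterian ancestor
#' and treated as homologous to the canonical r-opsins (so its absence in
#' clades retaining canonical r-opsins is suppressed rather than counted as
#' loss), and the noncanonical r-opsins are bookkept as a duplication of the
#' canonical lineage. All other families use plain single-gain defaults.
#'
#' @return named list of [family_config()] objects, one per opsin family.
#' @export
opsin_family_configs <- function() {
  fams <- opsin_families()
  cfg <- lapply(fams, family_config)
  names(cfg) <- fams
  cfg$xeno_specific <- family_config(
    "xeno_specific", gain_override = "Bilateria",
    surrogate_of = "r_opsin_canonical")
  cfg$r_opsin_noncanonical <- family_config(
    "r_opsin_noncanonical", duplication_parent = "r_opsin_canonical")
  cfg
}

check_matrix_tree <- function(matrix, tree) {
  if (!setequal(matrix$clades, tree$tip.label))
    stop("leaf-set mismatch between matrix clades and tree tips: matrix has {",
         paste(matrix$clades, collapse = ", "), "}, tree has {",
         paste(tree$tip.label, collapse = ", "), "}")
}

#' Infer the gain node of a family under single-gain parsimony
#'
#' The gain is the LCA of the terminals where the family is present (after
#' applying the uncertainty policy), unless the family's configuration pins it
#' higher with `gain_override`.
#'
#' @param matrix a [presence_matrix()] whose clades match the tree's tips.
#' @param family family identifier in `matrix`.
#' @param tree a validated clade tree ([builtin_tree()], [read_clade_tree()]).
#' @param config optional [family_config()] for the family.
#' @param uncertain policy for uncertain cells (`"present"` default).
#' @return the name of the gain node (an internal node or a terminal).
#' @export
infer_gain_node <- function(matrix, family, tree, config = NULL,
                            uncertain = c("present", "absent")) {
  uncertain <- match.arg(uncertain)
  check_matrix_tree(matrix, tree)
  if (!family %in% matrix$families) stop("unknown family: ", family)
  m <- apply_uncertain_policy(matrix, uncertain)
  present <- m$clades[m$states[family, ] == "present"]
  if (length(present) == 0L)
    stop("no origin inferable for family '", family,
         "': zero present terminals under uncertainty policy '", uncertain, "'")
  lca <- clade_lca(tree, present)
  ov <- config$gain_override
  if (is.null(ov)) return(lca)
  if (!ov %in% node_names(tree)) stop("unknown node: ", ov)
  if (!is_descendant_or_self(tree, lca, ov))
    stop("configuration error for family '", family, "': gain_override '", ov,
         "' is not ancestral to the present terminals (LCA = '", lca, "')")
  ov
}

#' Reconstruct one family's gain/loss history
#'
#' Under the single-gain model the family originates once at its gain node and
#' is then lost irreversibly on a minimal set of branches whose replay
#' reproduces the terminal presence states exactly. A loss on an internal
#' branch covers all descendant terminals, so the minimal set consists of the
#' maximal all-absent subtrees below the gain node. Branches whose subtended
#' terminals are all explained by a surrogate family (see [family_config()])
#' are recorded as suppressed, not counted as losses. Event lists are in
#' postorder; the reconstruction is fully deterministic.
#'
#' @inheritParams infer_gain_node
#' @return list of class `family_events` with elements `family`, `gain`,
#'   `losses` (character vector of branch names, each branch identified by its
#'   child node), `suppressed` (branches explained by the surrogate),
#'   `surrogate`, `duplication` (parent family id or `NA`), `n_losses`.
#' @export
reconstruct_family <- function(matrix, family, tree, config = NULL,
                               uncertain = c("present", "absent")) {
  uncertain <- match.arg(uncertain)
  gain <- infer_gain_node(matrix, family, tree, config, uncertain)
  m <- apply_uncertain_policy(matrix, uncertain)
  states <- m$states[family, ]
  surrogate <- config$surrogate_of
  tips <- tree$tip.label
  absent_tips <- tips[states[tips] == "absent"]
  if (!is.null(surrogate)) {
    if (!surrogate %in% m$families)
      stop("configuration error: surrogate family '", surrogate, "' not in matrix")
    surr_present <- tips[m$states[surrogate, tips] == "present"]
    wildcard <- intersect(absent_tips, surr_present)
  } else {
    wildcard <- character(0)
  }
  hard_absent <- setdiff(absent_tips, wildcard)

  gain_id <- node_id(tree, gain)
  nm <- node_names(tree)
  absent_ids <- match(absent_tips, nm)
  hard_ids <- match(hard_absent, nm)

  # maximal subtrees below the gain node whose terminals are all absent
  loss_ids <- integer(0)
  supp_ids <- integer(0)
  descend <- function(node) {
    for (ch in children_of(tree, node)) {
      below <- tips_below(tree, ch)
      if (all(below %in% absent_ids)) {
        if (any(below %in% hard_ids)) loss_ids[[length(loss_ids) + 1L]] <<- ch
        else supp_ids[[length(supp_ids) + 1L]] <<- ch
      } else {
        descend(ch)
      }
    }
  }
  if (gain_id <= length(tips)) {
    # terminal gain: nothing below to lose
  } else {
    descend(gain_id)
  }
  loss_ids <- unlist(loss_ids)
  supp_ids <- unlist(supp_ids)
  po <- postorder_nodes(tree)
  order_po <- function(ids) if (length(ids)) ids[order(match(ids, po))] else integer(0)
  structure(list(
    family = family,
    gain = gain,
    losses = nm[order_po(loss_ids)],
    suppressed = nm[order_po(supp_ids)],
    surrogate = if (is.null(surrogate)) NA_character_ else surrogate,
    duplication = if (is.null(config$duplication_parent)) NA_character_
                  else config$duplication_parent,
    n_losses = length(loss_ids)
  ), class = "family_events")
}

#' Reconstruct a full gain/loss scenario for a matrix on one tree
#'
#' Runs [reconstruct_family()] for every family and aggregates totals. De novo
#' gains and duplication-derived gains are tallied separately; only losses
#' enter the parsimony comparison between hypotheses.
#'
#' @inheritParams infer_gain_node
#' @param configs named list of [family_config()] objects (families without an
#'   entry get defaults); see [opsin_family_configs()].
#' @return object of class `dollo_scenario`: list with `hypothesis` (tree
#'   attribute, if any), `uncertain` policy, `families` (named list of
#'   `family_events`), and totals `n_losses`, `n_gains`, `n_duplications`.
#' @export
reconstruct_scenario <- function(matrix, tree, configs = list(),
                                 uncertain = c("present", "absent")) {
  uncertain <- match.arg(uncertain)
  check_matrix_tree(matrix, tree)
  recs <- lapply(matrix$families, function(f) {
    tryCatch(
      reconstruct_family(matrix, f, tree, configs[[f]], uncertain),
      error = function(e) stop("family '", f, "': ", conditionMessage(e),
                               call. = FALSE))
  })
  names(recs) <- matrix$families
  dup <- vapply(recs, function(r) !is.na(r$duplication), TRUE)
  structure(list(
    hypothesis = attr(tree, "hypothesis") %||% NA_character_,
    uncertain = uncertain,
    families = recs,
    n_losses = sum(vapply(recs, `[[`, 0L, "n_losses")),
    n_gains = sum(!dup),
    n_duplications = sum(dup)
  ), class = "dollo_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dollo_scenario <- function(x, ...) {
  cat(sprintf("dollo_scenario (%s, uncertain=%s): %d families, %d losses, %d gains, %d duplications\n",
              x$hypothesis, x$uncertain, length(x$families),
              x$n_losses, x$n_gains, x$n_duplications))
  for (r in x$families) {
    cat(sprintf("  %-22s gain=%-14s losses=[%s]%s\n", r$family, r$gain,
                paste(r$losses, collapse = ","),
                if (length(r$suppressed))
                  paste0(" suppressed=[", paste(r$suppressed, collapse = ","),
                         " via ", r$surrogate, "]") else ""))
  }
  invisible(x)
}

#' Per-branch event table for a scenario
#'
#' @param scenario a `dollo_scenario`.
#' @return data.frame with columns `family`, `event`
#'   (`gain`/`duplication`/`loss`/`suppressed_loss`), `node` (gain node, or the
#'   child node identifying the branch), `surrogate`.
#' @export
scenario_events <- function(scenario) {
  stopifnot(inherits(scenario, "dollo_scenario"))
  rows <- lapply(scenario$families, function(r) {
    ev <- data.frame(
      family = r$family,
      event = if (is.na(r$duplication)) "gain" else "duplication",
      node = r$gain, surrogate = NA_character_, stringsAsFactors = FALSE)
    if (length(r$losses))
      ev <- rbind(ev, data.frame(family = r$family, event = "loss",
                                 node = r$losses, surrogate = NA_character_))
    if (length(r$suppressed))
      ev <- rbind(ev, data.frame(family = r$family, event = "suppressed_loss",
                                 node = r$suppressed, surrogate = r$surrogate))
    ev
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replay a scenario down the tree
#'
#' Applies each family's gain and loss events from the root toward the tips
#' and returns the implied terminal states. Used to check replay soundness:
#' the result must reproduce the input presence matrix (suppressed branches
#' reproduce absence).
#'
#' @param scenario a `dollo_scenario`.
#' @param tree the tree the scenario was reconstructed on.
#' @return character matrix (family x tip) with values `"present"`/`"absent"`.
#' @export
replay_scenario <- function(scenario, tree) {
  stopifnot(inherits(scenario, "dollo_scenario"))
  tips <- tree$tip.label
  out <- matrix("absent", length(scenario$families), length(tips),
                dimnames = list(names(scenario$families), tips))
  for (r in scenario$families) {
    cut <- c(r$losses, r$suppressed)
    for (tip in tips) {
      path <- node_names(tree)[root_path(tree, node_id(tree, tip))]
      if (r$gain %in% path && !any(cut %in% path))
        out[r$family, tip] <- "present"
    }
  }
  out
}

#' Ancestral gene repertoire at a node
#'
#' A family belongs to the repertoire at `node` when its gain node lies at or
#' above `node` and no loss falls on the path from the root to `node`.
#' Families whose absence along that path is suppressed by a surrogate (see
#' [family_config()]) are listed with status `"suppressed"` and excluded from
#' the headline size; surrogate families themselves count as distinct members
#' whenever their gain node qualifies.
#'
#' @param scenario a `dollo_scenario`.
#' @param tree the tree the scenario was reconstructed on.
#' @param node a node name (internal or terminal).
#' @return data.frame with columns `family`, `status`
#'   (`"present"`/`"suppressed"`), one row per qualifying family.
#' @export
ancestral_repertoire <- function(scenario, tree, node) {
  stopifnot(inherits(scenario, "dollo_scenario"))
  nm <- node_names(tree)
  if (!node %in% nm) stop("unknown node: ", node)
  path <- nm[root_path(tree, node_id(tree, node))]
  rows <- lapply(scenario$families, function(r) {
    if (!r$gain %in% path) return(NULL)             # gain below or off the path
    if (any(r$losses %in% path)) return(NULL)       # lost on the way down
    status <- if (any(r$suppressed %in% path)) "suppressed" else "present"
    data.frame(family = r$family, status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family = character(0), status = character(0))
  rownames(out) <- NULL
  out
}

#' @rdname ancestral_repertoire
#' @return `repertoire_size` returns the number of families with status
#'   `"present"`.
#' @export
repertoire_size <- function(scenario, tree, node) {
  sum(ancestral_repertoire(scenario, tree, node)$status == "present")
}

#' Compare species-tree hypotheses by loss parsimony
#'
#' Reconstructs the same matrix on each candidate tree and tabulates loss,
#' gain and duplication totals plus the parallel-loss tally (number of
#' families lost independently on more than one branch). The winning
#' hypothesis is the one with fewest losses; ties are reported, not broken.
#'
#' @param matrix a [presence_matrix()].
#' @param configs named list of [family_config()] objects.
#' @param trees named list of trees with identical leaf sets (>= 2).
#' @param uncertain policy for uncertain cells.
#' @return list of class `hypothesis_comparison` with elements `table`
#'   (data.frame: hypothesis, n_losses, n_gains, n_duplications,
#'   n_parallel_loss_families), `parallel_families` (named list of the
#'   families lost more than once under each tree), `winner` (character
#'   vector; length > 1 on ties), and `scenarios`.
#' @export
compare_hypotheses <- function(matrix, configs, trees,
                               uncertain = c("present", "absent")) {
  uncertain <- match.arg(uncertain)
  if (length(trees) < 2L) stop("need at least two trees to compare")
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    stop("`trees` must be a named list")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leafsets, identical, TRUE, leafsets[[1L]])))
    stop("leaf-set mismatch among candidate trees")
  scen <- lapply(trees, function(t)
    reconstruct_scenario(matrix, t, configs, uncertain))
  par_fams <- lapply(scen, function(s)
    names(Filter(function(r) r$n_losses > 1L, s$families)))
  tab <- data.frame(
    hypothesis = names(trees),
    n_losses = vapply(scen, `[[`, 0L, "n_losses"),
    n_gains = vapply(scen, `[[`, 0L, "n_gains"),
    n_duplications = vapply(scen, `[[`, 0L, "n_duplications"),
    n_parallel_loss_families = lengths(par_fams),
    stringsAsFactors = FALSE, row.names = NULL)
  winner <- tab$hypothesis[tab$n_losses == min(tab$n_losses)]
  structure(list(table = tab, parallel_families = par_fams,
                 winner = winner, scenarios = scen),
            class = "hypothesis_comparison")
}

#' @export
print.hypothesis_comparison <- function(x, ...) {
  print(x$table)
  if (length(x$winner) > 1L)
    cat("tie on losses:", paste(x$winner, collapse = ", "), "\n")
  else
    cat("fewest losses:", x$winner, "\n")
  invisible(x)
}
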