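# Independent oracle: exhaustive single-gain reconstruction.
#
# Enumerates every assignment of presence/absence to the internal nodes
# (terminal states fixed by the data), keeps those with exactly one 0->1
# transition counting the root's stem, and returns the minimum number of
# 1->0 transitions. Works directly on the ape edge matrix and shares no code
# with the reconstruction engine.
exhaustive_dollo_min <- function(tree, present_tips) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  tipstate <- as.integer(tree$tip.label %in% present_tips)
  edges <- tree$edge
  best <- Inf
  for (mask in 0:(2^nint - 1L)) {
    intstate <- as.integer(intToBits(mask))[seq_len(nint)]
    state <- c(tipstate, intstate)
    gains <- state[ntip + 1L]  # a present root is the gain on its stem
    losses <- 0L
    for (e in seq_len(nrow(edges))) {
      p <- state[edges[e, 1L]]
      ch <- state[edges[e, 2L]]
      if (p == 0L && ch == 1L) gains <- gains + 1L
      if (p == 1L && ch == 0L) losses <- losses + 1L
    }
    if (gains == 1L) best <- min(best, losses)
  }
  best
}

# random rooted binary cladogram with deterministic labels (RNG-driven;
# callers control the seed)
rand_clade_tree <- function(ntips) {
  tr <- ape::rtree(ntips, br = NULL)
  tr$tip.label <- paste0("t", seq_len(ntips))
  tr$node.label <- paste0("i", seq_len(tr$Nnode))
  tr
}

# presence matrix over a tree's tips from a 0/1 vector
pm_from_states <- function(tree, fam, present01) {
  st <- matrix(ifelse(present01 == 1L, "present", "absent"), nrow = 1,
               dimnames = list(fam, tree$tip.label))
  presence_matrix(st)
}

# the test suite's own bipartition comparison: the set of non-trivial tip
# splits induced by internal edges
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- setdiff(unique(tree$edge[, 2L]), seq_len(ntip))
  splits <- lapply(internal, function(nd) {
    sort(ape::extract.clade(tree, nd)$tip.label)
  })
  unique(Filter(function(s) length(s) > 1L && length(s) < ntip, splits))
}
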