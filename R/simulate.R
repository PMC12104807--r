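#' Simulate a presence matrix under single-gain evolution
#'
#' Each family gains once at a node drawn uniformly over the whole tree
#' (terminals included), then every branch below the gain loses the family
#' independently with probability `loss_prob`; once lost, a lineage never
#' regains it. Families whose terminals end up all-absent are discarded and
#' regenerated, so every emitted family is observable. The full event truth
#' (gain node, realized loss branches) is logged so parsimony reconstructions
#' can be checked against it: the minimal loss count can never exceed the
#' number of simulated loss events.
#'
#' @param tree a validated clade tree.
#' @param n_families number of families to emit.
#' @param loss_prob per-branch loss probability in `[0, 1)`.
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @return list with `matrix` (a [presence_matrix()], families `fam001`...)
#'   and `truth`: `seed`, `tree` (Newick string), per-family `gain` and
#'   `losses` (branch child names), and `n_losses_total`.
#' @export
simulate_dollo_matrix <- function(tree, n_families, loss_prob, seed) {
  if (!is.numeric(loss_prob) || loss_prob < 0 || loss_prob >= 1)
    stop("loss_prob must be in [0, 1)")
  stopifnot(n_families >= 1L)
  set.seed(as.integer(seed))
  tips <- tree$tip.label
  nm <- node_names(tree)
  n_all <- length(nm)
  fam_ids <- sprintf("fam%03d", seq_len(n_families))
  states <- matrix("absent", n_families, length(tips),
                   dimnames = list(fam_ids, tips))
  truth_fams <- vector("list", n_families)
  names(truth_fams) <- fam_ids
  for (f in seq_len(n_families)) {
    repeat {
      gain <- sample.int(n_all, 1L)
      losses <- integer(0)
      present <- character(0)
      walk <- function(node) {
        if (node <= length(tips)) present[[length(present) + 1L]] <<- nm[node]
        for (ch in children_of(tree, node)) {
          if (stats::runif(1L) < loss_prob) losses[[length(losses) + 1L]] <<- ch
          else walk(ch)
        }
      }
      walk(gain)
      present <- unlist(present)
      if (length(present) > 0L) break
    }
    states[f, ] <- "absent"
    states[f, present] <- "present"
    truth_fams[[f]] <- list(gain = nm[gain], losses = nm[unlist(losses)])
  }
  list(matrix = presence_matrix(states),
       truth = list(seed = as.integer(seed),
                    tree = ape::write.tree(tree),
                    families = truth_fams,
                    n_losses_total = sum(lengths(
                      lapply(truth_fams, `[[`, "losses")))))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate an aligned FASTA fixture with a planted lysine column
#'
#' Emits an alignment whose first sequence (`REF`) carries a lysine at the
#' ungapped position mapping to `lysine_column`; every other sequence carries
#' K there too, except `substitute_ids` (a non-K residue: complete but
#' lysine-lacking) and `truncate_ids` (gaps from before the column to the
#' sequence end: incomplete over the site). A few gaps are scattered at
#' random non-column positions. Sequences use a uniform 20-letter amino-acid
#' alphabet: the generator plants identifiable truths, it does not model
#' sequence evolution.
#'
#' @param n_seqs number of non-reference sequences.
#' @param length alignment width (columns).
#' @param lysine_column alignment column carrying the planted lysine.
#' @param truncate_ids,substitute_ids ids among `seq01`..`seqNN` to truncate /
#'   substitute; the two sets must not overlap.
#' @param seed integer seed.
#' @return list with `alignment` ([Biostrings::AAStringSet]),
#'   `reference_id` (`"REF"`), `reference_position` (ungapped index of the
#'   planted lysine on the reference) and `truth` (seed, column, planted
#'   sets).
#' @export
make_alignment_fixture <- function(n_seqs = 6L, length = 40L,
                                   lysine_column = 25L,
                                   truncate_ids = character(0),
                                   substitute_ids = character(0),
                                   seed = 1L) {
  stopifnot(lysine_column >= 1L, lysine_column <= length)
  if (base::length(intersect(truncate_ids, substitute_ids)))
    stop("truncate_ids and substitute_ids must not overlap")
  set.seed(as.integer(seed))
  ids <- sprintf("seq%02d", seq_len(n_seqs))
  bad <- setdiff(c(truncate_ids, substitute_ids), ids)
  if (base::length(bad)) stop("unknown sequence id(s): ", paste(bad, collapse = ", "))

  draw_seq <- function() sample(AA20, length, replace = TRUE)
  gap_positions <- function(n) {
    cand <- setdiff(seq_len(length), lysine_column)
    sort(sample(cand, n))
  }
  ref <- draw_seq()
  ref[lysine_column] <- "K"
  ref[gap_positions(2L)] <- "-"
  seqs <- list(REF = paste(ref, collapse = ""))
  for (id in ids) {
    s <- draw_seq()
    s[lysine_column] <- "K"
    if (id %in% substitute_ids)
      s[lysine_column] <- sample(setdiff(AA20, "K"), 1L)
    s[gap_positions(2L)] <- "-"
    if (id %in% truncate_ids) {
      cut <- sample(seq_len(lysine_column - 1L), 1L)
      s[seq(cut, length)] <- "-"
    }
    seqs[[id]] <- paste(s, collapse = "")
  }
  aln <- Biostrings::AAStringSet(unlist(seqs))
  ref_pos <- sum(ref[seq_len(lysine_column)] != "-")
  list(alignment = aln, reference_id = "REF", reference_position = ref_pos,
       truth = list(seed = as.integer(seed), lysine_column = lysine_column,
                    truncate_ids = truncate_ids,
                    substitute_ids = substitute_ids))
}

#' Generate a synthetic back-hit table with known opsin labels
#'
#' Builds a subject database (opsin and non-opsin references with names,
#' cluster ids and accessions), and for every candidate a ranked list of `k`
#' back-hits with strictly ordered bit scores. True opsin candidates receive
#' at least one opsin subject among their top-`k` with probability
#' `1 - noise_rate`; decoys never do. With `force_ties` the top two hits of
#' each query share a bit score (distinct e-values), to exercise the
#' documented tie-break.
#'
#' @param n_true_opsins,n_decoys numbers of true-opsin and decoy candidates.
#' @param k back-hits emitted per candidate.
#' @param noise_rate probability in `[0, 1)` that a true opsin's top-`k`
#'   lacks an opsin subject.
#' @param seed integer seed.
#' @param force_ties plant bit-score ties (default `FALSE`).
#' @return list with `back_hits` (a `hit_table`), `subjects` (metadata
#'   data.frame) and `truth`: candidate labels (`is_opsin`) and the exact set
#'   `opsin_in_topk` a deterministic top-`k` filter must keep.
#' @export
make_hit_fixture <- function(n_true_opsins, n_decoys, k = 3L, noise_rate = 0,
                             seed = 1L, force_ties = FALSE) {
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate >= 1)
    stop("noise_rate must be in [0, 1)")
  set.seed(as.integer(seed))
  n_ops_subj <- max(4L, k + 1L)
  n_nop_subj <- max(8L, 2L * k)
  subjects <- data.frame(
    subject = c(sprintf("OPS_%02d", seq_len(n_ops_subj)),
                sprintf("NOP_%02d", seq_len(n_nop_subj))),
    name = c(sprintf("opsin-like receptor %d", seq_len(n_ops_subj)),
             sprintf("unrelated GPCR %d", seq_len(n_nop_subj))),
    is_opsin = rep(c(TRUE, FALSE), c(n_ops_subj, n_nop_subj)),
    cluster = c(sprintf("UC_OPS%02d", seq_len(n_ops_subj)),
                sprintf("UC_NOP%02d", seq_len(n_nop_subj))),
    accession = c(sprintf("P%05d", seq_len(n_ops_subj)),
                  sprintf("Q%05d", seq_len(n_nop_subj))),
    stringsAsFactors = FALSE)
  ops_subj <- subjects$subject[subjects$is_opsin]
  nop_subj <- subjects$subject[!subjects$is_opsin]

  queries <- c(sprintf("TRUE_q%03d", seq_len(n_true_opsins)),
               sprintf("DECOY_q%03d", seq_len(n_decoys)))
  is_opsin_q <- rep(c(TRUE, FALSE), c(n_true_opsins, n_decoys))
  opsin_in_topk <- character(0)

  rows <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    if (is_opsin_q[i] && stats::runif(1L) >= noise_rate) {
      slot <- sample.int(k, 1L)
      subj <- sample(nop_subj, k, replace = FALSE)
      subj[slot] <- sample(ops_subj, 1L)
      opsin_in_topk <- c(opsin_in_topk, q)
    } else {
      subj <- sample(nop_subj, k, replace = FALSE)
    }
    bits <- 300 - 10 * seq_len(k)
    ev <- signif(10^(-bits / 10), 3)
    if (force_ties && k >= 2L) {
      # equal bit scores, distinct e-values: exercises the documented tie-break
      bits[2L] <- bits[1L]
      ev[2L] <- signif(ev[1L] * 3, 3)
    }
    rows[[i]] <- data.frame(
      qseqid = q, sseqid = subj,
      pident = round(stats::runif(k, 30, 95), 1), length = 250L,
      mismatch = 10L, gapopen = 1L, qstart = 1L, qend = 250L,
      sstart = 1L, send = 250L, evalue = ev, bitscore = bits,
      stringsAsFactors = FALSE)
  }
  back_hits <- hit_table(do.call(rbind, rows))
  list(back_hits = back_hits, subjects = subjects,
       truth = list(seed = as.integer(seed), k = as.integer(k),
                    noise_rate = noise_rate,
                    labels = stats::setNames(is_opsin_q, queries),
                    opsin_in_topk = sort(opsin_in_topk)))
}
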