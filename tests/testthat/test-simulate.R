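tree5 <- builtin_tree("nephrozoa")

test_that("simulated matrices are deterministic under a fixed seed", {
  s1 <- simulate_dollo_matrix(tree5, 30, 0.2, seed = 13)
  s2 <- simulate_dollo_matrix(tree5, 30, 0.2, seed = 13)
  expect_identical(s1$matrix$states, s2$matrix$states)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dollo_matrix(tree5, 30, 0.2, seed = 14)
  expect_false(identical(s1$matrix$states, s3$matrix$states))
})

test_that("zero loss probability leaves every gained subtree intact", {
  s <- simulate_dollo_matrix(tree5, 25, 0, seed = 3)
  expect_identical(s$truth$n_losses_total, 0L)
  scen <- reconstruct_scenario(s$matrix, tree5)
  expect_identical(scen$n_losses, 0L)
  expect_error(simulate_dollo_matrix(tree5, 5, 1, seed = 1), "loss_prob")
})

test_that("truth replay reproduces the emitted matrix", {
  s <- simulate_dollo_matrix(tree5, 40, 0.3, seed = 21)
  for (f in names(s$truth$families)) {
    tf <- s$truth$families[[f]]
    for (tip in tree5$tip.label) {
      anc <- clade_lca(tree5, c(tip, tf$gain))
      on_path <- anc == tf$gain  # gain is an ancestor-or-self of the tip
      lost <- FALSE
      if (on_path && length(tf$losses)) {
        lost <- any(vapply(tf$losses, function(b)
          clade_lca(tree5, c(tip, b)) == b, TRUE))
      }
      want <- if (on_path && !lost) "present" else "absent"
      expect_identical(s$matrix$states[f, tip], want)
    }
  }
})

test_that("engine loss count never exceeds the simulated truth", {
  for (seed in 1:5) {
    s <- simulate_dollo_matrix(tree5, 50, 0.25, seed = seed)
    scen <- reconstruct_scenario(s$matrix, tree5)
    expect_lte(scen$n_losses, s$truth$n_losses_total)
  }
})

test_that("alignment fixtures plant identifiable truths", {
  fix <- make_alignment_fixture(n_seqs = 8, length = 40, lysine_column = 25,
                                truncate_ids = "seq02",
                                substitute_ids = "seq05", seed = 4)
  expect_identical(
    map_reference_position(fix$alignment, fix$reference_id,
                           fix$reference_position),
    25L)
  calls <- classify_sequences(fix$alignment, fix$reference_id,
                              fix$reference_position)
  expect_identical(calls$seq_id[calls$call == "lysine_absent"], "seq05")
  expect_identical(calls$seq_id[calls$call == "undetermined_truncated"],
                   "seq02")
  expect_identical(sum(calls$call == "lysine_present"), 6L)
  expect_error(make_alignment_fixture(truncate_ids = "seq01",
                                      substitute_ids = "seq01"),
               "must not overlap")
})

test_that("generated files parse back through the package readers", {
  fix <- make_alignment_fixture(seed = 8)
  p <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(fix$alignment, p)
  expect_no_warning(aln <- read_alignment(p))
  expect_identical(length(aln), length(fix$alignment))
  hfx <- make_hit_fixture(5, 5, seed = 8)
  ph <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hfx$back_hits, ph)
  expect_no_warning(h <- read_hit_table(ph))
  expect_identical(nrow(h), nrow(hfx$back_hits))
  s <- simulate_dollo_matrix(tree5, 10, 0.2, seed = 8)
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(s$matrix, pm)
  expect_no_warning(m <- read_matrix(pm))
  expect_identical(m$states, s$matrix$states)
})

test_that("noisy hit fixtures keep exactly the planted opsin-in-top-k set", {
  fix <- make_hit_fixture(100, 50, k = 3, noise_rate = 0.3, seed = 7)
  dec <- reciprocal_opsin_filter(names(fix$truth$labels), fix$back_hits,
                                 fix$subjects, k = 3)
  kept <- sort(dec$protein[dec$status == "annotated"])
  expect_identical(kept, fix$truth$opsin_in_topk)
  # some true opsins were hidden by noise, so the kept set is a strict subset
  expect_lt(length(kept), sum(fix$truth$labels))
})

test_that("forced ties produce a non-empty tie-break log", {
  fix <- make_hit_fixture(4, 2, k = 3, seed = 2, force_ties = TRUE)
  best <- best_hit_per_query(fix$back_hits)
  expect_gt(nrow(attr(best, "tie_log")), 0L)
})
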