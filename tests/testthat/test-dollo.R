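trees <- list(nephrozoa = builtin_tree("nephrozoa"),
              xenambulacraria = builtin_tree("xenambulacraria"))
cfg <- opsin_family_configs()
main <- opsin_matrix("main")

test_that("gain node is the LCA of present terminals unless overridden", {
  expect_identical(
    infer_gain_node(main, "anthozoa_I", trees$nephrozoa),
    "Eumetazoa")
  expect_identical(
    infer_gain_node(main, "xeno_specific", trees$nephrozoa),
    "Xenacoelomorpha")
  expect_identical(
    infer_gain_node(main, "xeno_specific", trees$nephrozoa,
                    cfg$xeno_specific),
    "Bilateria")
  # override must be ancestral to the present terminals
  bad <- family_config("anthozoa_I", gain_override = "Deuterostomia")
  expect_error(infer_gain_node(main, "anthozoa_I", trees$nephrozoa, bad),
               "configuration error")
})

test_that("a family with no present terminal has no inferable origin", {
  st <- matrix("absent", 1, 5,
               dimnames = list("ghost", trees$nephrozoa$tip.label))
  st[1, 1] <- "uncertain"
  m <- presence_matrix(st)
  expect_identical(infer_gain_node(m, "ghost", trees$nephrozoa,
                                   uncertain = "present"),
                   colnames(st)[1])
  expect_error(infer_gain_node(m, "ghost", trees$nephrozoa,
                               uncertain = "absent"),
               "no origin inferable")
})

test_that("per-family reconstructions match the published loss events", {
  a <- reconstruct_family(main, "anthozoa_I", trees$xenambulacraria)
  expect_setequal(a$losses, c("Protostomia", "Chordata", "Ambulacraria"))
  ch <- reconstruct_family(main, "chaopsin", trees$xenambulacraria)
  expect_setequal(ch$losses, c("Protostomia", "Xenacoelomorpha"))
  x <- reconstruct_family(main, "xenopsin", trees$nephrozoa)
  expect_identical(x$losses, "Deuterostomia")
  # family present everywhere loses nothing
  rgr <- reconstruct_family(main, "rgr_retinochrome", trees$nephrozoa)
  expect_identical(rgr$n_losses, 0L)
})

test_that("surrogate homology suppresses losses without hiding them", {
  xs <- reconstruct_family(main, "xeno_specific", trees$nephrozoa,
                           cfg$xeno_specific)
  expect_identical(xs$n_losses, 0L)
  expect_identical(xs$suppressed, "Nephrozoa")
  expect_identical(xs$surrogate, "r_opsin_canonical")
  xs2 <- reconstruct_family(main, "xeno_specific", trees$xenambulacraria,
                            cfg$xeno_specific)
  expect_identical(xs2$n_losses, 0L)
  expect_setequal(xs2$suppressed, c("Protostomia", "Chordata", "Ambulacraria"))
})

test_that("scenario totals separate losses, gains and duplications", {
  s <- reconstruct_scenario(main, trees$xenambulacraria, cfg)
  expect_identical(s$n_losses, 11L)
  expect_identical(s$n_gains + s$n_duplications, 11L)
  expect_identical(s$n_duplications, 1L)  # the canonical/noncanonical split
  ev <- scenario_events(s)
  expect_identical(sum(ev$event == "loss"), 11L)
  expect_identical(sum(ev$event == "duplication"), 1L)
  expect_identical(sum(ev$event == "suppressed_loss"), 3L)
})

test_that("replaying a scenario reproduces the terminal states", {
  for (tr in trees) {
    for (pol in c("present", "absent")) {
      s <- reconstruct_scenario(main, tr, cfg, uncertain = pol)
      got <- replay_scenario(s, tr)
      want <- apply_uncertain_policy(main, pol)$states[, colnames(got)]
      expect_identical(got, want)
    }
  }
})

test_that("repertoire at a terminal equals its present families, surrogates flagged", {
  s <- reconstruct_scenario(main, trees$nephrozoa, cfg)
  rep_prot <- ancestral_repertoire(s, trees$nephrozoa, "Protostomia")
  present_fams <- rep_prot$family[rep_prot$status == "present"]
  m <- apply_uncertain_policy(main, "present")
  expect_setequal(present_fams,
                  m$families[m$states[, "Protostomia"] == "present"])
  expect_identical(rep_prot$status[rep_prot$family == "xeno_specific"],
                   "suppressed")
  expect_error(ancestral_repertoire(s, trees$nephrozoa, "Lophotrochozoa"),
               "unknown node")
})

test_that("hypothesis comparison reports winner, tallies and ties", {
  cmpr <- compare_hypotheses(main, cfg, trees)
  expect_identical(cmpr$winner, "nephrozoa")
  expect_setequal(cmpr$parallel_families$xenambulacraria,
                  c("anthozoa_I", "chaopsin", "xenopsin"))
  expect_identical(cmpr$parallel_families$nephrozoa, "chaopsin")
  tie <- compare_hypotheses(main, cfg,
                            list(a = trees$nephrozoa, b = trees$nephrozoa))
  expect_identical(sort(tie$winner), c("a", "b"))
  shuffled <- trees$nephrozoa
  shuffled$tip.label[1] <- "Porifera"
  expect_error(compare_hypotheses(main, cfg,
                                  list(a = trees$nephrozoa, b = shuffled)),
               "leaf-set mismatch")
})

test_that("engine equals the exhaustive single-gain oracle on random cases", {
  set.seed(202)
  n_checked <- 0L
  for (rep in 1:15) {
    tr <- rand_clade_tree(sample(4:6, 1))
    for (f in 1:4) {
      states01 <- sample(0:1, length(tr$tip.label), replace = TRUE)
      if (sum(states01) == 0L) next
      m <- pm_from_states(tr, "fam", states01)
      eng <- reconstruct_family(m, "fam", tr)$n_losses
      ora <- exhaustive_dollo_min(tr, tr$tip.label[states01 == 1L])
      expect_identical(eng, as.integer(ora))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 30L)
})

test_that("removing all absences yields zero losses", {
  tr <- builtin_tree("nephrozoa")
  m <- pm_from_states(tr, "fam", rep(1L, 5))
  expect_identical(reconstruct_family(m, "fam", tr)$n_losses, 0L)
})
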