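mk_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(qseqid = r[[1]], sseqid = r[[2]], pident = 50, length = 100,
               mismatch = 5, gapopen = 0, qstart = 1, qend = 100, sstart = 1,
               send = 100, evalue = as.numeric(r[[3]]),
               bitscore = as.numeric(r[[4]]), stringsAsFactors = FALSE)
  }))
  hit_table(df)
}

test_that("hit tables read with or without a header and sort per query", {
  p <- withr::local_tempfile(fileext = ".tsv")
  body <- c("q1\ts2\t40.0\t100\t5\t0\t1\t100\t1\t100\t1e-10\t150",
            "q1\ts1\t50.0\t100\t5\t0\t1\t100\t1\t100\t1e-20\t200")
  writeLines(body, p)
  h <- read_hit_table(p)
  expect_identical(nrow(h), 2L)
  expect_identical(h$sseqid[1], "s1")  # normalized to descending bit score
  writeLines(c(paste(c("qseqid","sseqid","pident","length","mismatch","gapopen",
                       "qstart","qend","sstart","send","evalue","bitscore"),
                     collapse = "\t"), body), p)
  expect_identical(read_hit_table(p), h)
})

test_that("e-value prefilter keeps rows at or below the cutoff", {
  h <- mk_hits(list("q1", "s1", 1e-6, 100), list("q1", "s2", 1e-3, 90))
  expect_identical(nrow(evalue_prefilter(h)), 1L)
  expect_identical(nrow(evalue_prefilter(h, Inf)), 2L)
  expect_identical(nrow(evalue_prefilter(h, 1e-30)), 0L)
  expect_error(evalue_prefilter(h, -1), "non-negative")
})

test_that("best hit per query maximizes bit score with documented tie-breaks", {
  h <- mk_hits(list("q1", "s1", 1e-50, 200), list("q1", "s2", 1e-40, 150))
  b <- best_hit_per_query(h)
  expect_identical(b$sseqid, "s1")
  # bit-score tie resolved by lower e-value
  h2 <- mk_hits(list("q1", "s1", 1e-40, 200), list("q1", "s2", 1e-50, 200))
  b2 <- best_hit_per_query(h2)
  expect_identical(b2$sseqid, "s2")
  expect_identical(attr(b2, "tie_log")$decided_by, "e-value")
  # full tie resolved by lexicographic subject id
  h3 <- mk_hits(list("q1", "sB", 1e-50, 200), list("q1", "sA", 1e-50, 200))
  b3 <- best_hit_per_query(h3)
  expect_identical(b3$sseqid, "sA")
  expect_identical(attr(b3, "tie_log")$decided_by, "subject id")
  # empty in, empty out
  empty <- best_hit_per_query(h[0, ])
  expect_identical(nrow(empty), 0L)
})

subjects <- data.frame(
  subject = c("ops1", "ops2", "gpcr1", "gpcr2", "gpcr3"),
  name = c("rhodopsin", "melanopsin", "adenosine receptor", "mGluR", "5HT"),
  is_opsin = c(TRUE, TRUE, FALSE, FALSE, FALSE),
  cluster = c("c_ops", "c_ops", "c_g1", "c_g2", "c_g3"),
  accession = c("P1", "P2", "Q1", "Q2", "Q3"), stringsAsFactors = FALSE)

test_that("reciprocal filter keeps a candidate iff an opsin is in its top-k", {
  bh <- mk_hits(
    list("cand1", "ops1", 1e-50, 200), list("cand1", "gpcr1", 1e-40, 150),
    list("cand1", "gpcr2", 1e-30, 100),
    list("cand2", "gpcr1", 1e-50, 200), list("cand2", "gpcr2", 1e-40, 150),
    list("cand2", "gpcr3", 1e-30, 100),
    # cand3's only opsin hit ranks 4th: removed under k = 3
    list("cand3", "gpcr1", 1e-50, 200), list("cand3", "gpcr2", 1e-40, 150),
    list("cand3", "gpcr3", 1e-35, 120), list("cand3", "ops1", 1e-30, 100))
  dec <- reciprocal_opsin_filter(c("cand1", "cand2", "cand3", "cand4"),
                                 bh, subjects, k = 3)
  status <- setNames(dec$status, dec$protein)
  expect_identical(unname(status["cand1"]), "annotated")
  expect_identical(unname(status["cand2"]), "removed")
  expect_identical(unname(status["cand3"]), "removed")
  expect_identical(unname(status["cand4"]), "removed")
  expect_identical(dec$reason[dec$protein == "cand4"], "no hits")
})

test_that("filter cascade output is byte-deterministic", {
  fix <- make_hit_fixture(6, 6, k = 3, noise_rate = 0.3, seed = 9)
  d1 <- reciprocal_opsin_filter(names(fix$truth$labels), fix$back_hits,
                                fix$subjects, k = 3)
  d2 <- reciprocal_opsin_filter(names(fix$truth$labels), fix$back_hits,
                                fix$subjects, k = 3)
  expect_identical(d1, d2)
})

db <- pathway_db(list(
  K11111 = list(accessions = c("P1", "P9"), names = "rhodopsin",
                clusters = "c_extra"),
  K22222 = list(accessions = "Q7", names = "Adenosine receptor A2a",
                ambiguous = "adenosin A2")))

test_that("tiered annotation fires accession > name > cluster", {
  meta <- data.frame(
    subject = c("s1", "s2", "s3", "s4", "s5"),
    name = c("other", "rhodopsin", "Adenosine receptor A2a", "adenosin A2",
             "other2"),
    is_opsin = TRUE,
    cluster = c("c1", "c2", "c3", "c4", "c2"),
    accession = c("P1", "Z1", "Z2", "Z3", "Z4"), stringsAsFactors = FALSE)
  bh <- mk_hits(list("prot_acc", "s1", 1e-50, 200),
                list("prot_name", "s2", 1e-50, 200),
                list("prot_amb", "s4", 1e-50, 200),
                list("prot_a2a", "s3", 1e-50, 200),
                list("prot_clu", "s5", 1e-50, 200))
  dec <- kegg_tiered_annotation(bh, db, meta)
  by_p <- split(dec, dec$protein)
  expect_identical(by_p$prot_acc$tier, "accession")
  expect_identical(by_p$prot_acc$ko, "K11111")
  expect_identical(by_p$prot_name$tier, "name")
  # the ambiguous name never fires the name tier
  expect_identical(by_p$prot_amb$status, "unresolved")
  expect_identical(by_p$prot_a2a$tier, "name")
  expect_identical(by_p$prot_a2a$ko, "K22222")
  # cluster shared with the tier-2 protein s2 (cluster c2) extends the call
  expect_identical(by_p$prot_clu$tier, "cluster")
  expect_identical(by_p$prot_clu$ko, "K11111")
})

test_that("tier precedence is strict: accession-qualifying hits never land lower", {
  fixmeta <- data.frame(subject = "s1", name = "rhodopsin", is_opsin = TRUE,
                        cluster = "c_extra", accession = "P1",
                        stringsAsFactors = FALSE)
  bh <- mk_hits(list("p1", "s1", 1e-50, 200))
  dec <- kegg_tiered_annotation(bh, db, fixmeta)
  expect_identical(dec$tier, "accession")
})

test_that("pathway db requires accessions and best-hit-reduced input", {
  expect_error(pathway_db(list(K1 = list(names = "x"))), "empty accession set")
  bh <- mk_hits(list("p1", "s1", 1e-50, 200), list("p1", "s2", 1e-40, 150))
  meta <- data.frame(subject = c("s1", "s2"), name = "x", is_opsin = TRUE,
                     cluster = "c", accession = "P1", stringsAsFactors = FALSE)
  expect_error(kegg_tiered_annotation(bh, db, meta), "best_hit_per_query")
})
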