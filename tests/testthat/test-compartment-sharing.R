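# Gut-blood clone sharing detection.

mk_ngs <- function(ids, v, j, cdr3, compartment = "blood") {
  data.frame(sequence_id = ids, v_call = v, j_call = j, junction_aa = cdr3,
             compartment = compartment, stringsAsFactors = FALSE)
}

test_that("sharing rule requires identical V/J genes and 90% CDR-H3 identity", {
  mab <- data.frame(mab_id = "m1", v_call = "TVH3-1*01", j_call = "TVJ1*01",
                    cdr3_aa = "ARDYYGMDVA", isotype = "IGA",
                    polyreactive = TRUE, stringsAsFactors = FALSE)
  # exact match
  sh <- find_shared(mab, mk_ngs("n1", "TVH3-1*02", "TVJ1*01", "ARDYYGMDVA"))
  expect_equal(nrow(sh), 1)
  expect_equal(sh$best_identity, 1.0)
  # 1 difference in 10 = 0.9: still a match
  sh2 <- find_shared(mab, mk_ngs("n1", "TVH3-1*01", "TVJ1*01", "ARDYYGMDVG"))
  expect_equal(nrow(sh2), 1)
  expect_equal(sh2$best_identity, 0.9)
  # 2 differences in 10 = 0.8: no match
  sh3 <- find_shared(mab, mk_ngs("n1", "TVH3-1*01", "TVJ1*01", "ARDYYGMGVG"))
  expect_equal(nrow(sh3), 0)
  # wrong V gene or different CDR-H3 length: no match
  expect_equal(nrow(find_shared(
    mab, mk_ngs("n1", "TVH4-1*01", "TVJ1*01", "ARDYYGMDVA"))), 0)
  expect_equal(nrow(find_shared(
    mab, mk_ngs("n1", "TVH3-1*01", "TVJ1*01", "ARDYYGMDV"))), 0)
  # isotype is not part of the rule
  ngs <- mk_ngs("n1", "TVH3-1*01", "TVJ1*01", "ARDYYGMDVA")
  expect_equal(nrow(find_shared(mab, ngs)), 1)
})

test_that("mAbs lacking a CDR-H3 are skipped with a warning", {
  mab <- data.frame(mab_id = c("m1", "m2"), v_call = "TVH3-1*01",
                    j_call = "TVJ1*01", cdr3_aa = c(NA, "ARDYYGMDVA"),
                    isotype = "IGA", polyreactive = FALSE,
                    stringsAsFactors = FALSE)
  ngs <- mk_ngs("n1", "TVH3-1*01", "TVJ1*01", "ARDYYGMDVA")
  expect_warning(sh <- find_shared(mab, ngs), "m1")
  expect_equal(sh$mab_id, "m2")
})

test_that("the matching relation is symmetric in the mAb/NGS roles", {
  set.seed(103)
  cdr3s <- replicate(12, paste(sample(c("A", "R", "D", "Y", "G"), 10,
                                      replace = TRUE), collapse = ""))
  a <- data.frame(mab_id = sprintf("a%d", 1:12), v_call = "TVH1-1*01",
                  j_call = "TVJ1*01", cdr3_aa = cdr3s, isotype = "IGA",
                  polyreactive = FALSE, stringsAsFactors = FALSE)
  b_cdr3 <- c(cdr3s[1:6], replicate(6, paste(sample(c("A", "R", "D", "Y", "G"),
                                                    10, replace = TRUE),
                                             collapse = "")))
  b <- mk_ngs(sprintf("b%d", 1:12), "TVH1-1*01", "TVJ1*01", b_cdr3)
  fwd <- attr(find_shared(a, b), "links")
  b_as_mab <- data.frame(mab_id = b$sequence_id, v_call = b$v_call,
                         j_call = b$j_call, cdr3_aa = b$junction_aa,
                         isotype = "IGA", polyreactive = FALSE,
                         stringsAsFactors = FALSE)
  a_as_ngs <- mk_ngs(a$mab_id, a$v_call, a$j_call, a$cdr3_aa)
  rev <- attr(find_shared(b_as_mab, a_as_ngs), "links")
  expect_setequal(paste(fwd$mab_id, fwd$ngs_id),
                  paste(rev$ngs_id, rev$mab_id))
})

test_that("raising the identity threshold never adds matches", {
  set.seed(107)
  sim <- simulate_repertoire(sim_config(seed = 107, n_clones = 40))
  gut <- sim$truth[sim$truth$compartment == "gut", ]
  blood <- sim$truth[sim$truth$compartment == "blood", ]
  gut_reps <- gut[!duplicated(gut$clone_id), ]
  mab <- data.frame(mab_id = gut_reps$sequence_id, v_call = gut_reps$v_call,
                    j_call = gut_reps$j_call, cdr3_aa = gut_reps$junction_aa,
                    isotype = gut_reps$isotype,
                    polyreactive = gut_reps$polyreactive,
                    stringsAsFactors = FALSE)
  ngs <- mk_ngs(blood$sequence_id, blood$v_call, blood$j_call,
                blood$junction_aa)
  n_prev <- Inf
  for (th in c(0.8, 0.9, 0.95, 1.0)) {
    n <- nrow(find_shared(mab, ngs, min_identity = th))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("sharing frequencies and Fisher p match the printed comparisons", {
  t1 <- sharing_frequency_test(33, 99, 6, 101)
  expect_equal(t1$freq_a, 100 * 33 / 99, tolerance = 1e-12)
  expect_equal(round(t1$freq_b, 1), 5.9)
  expect_lt(t1$p, 0.0001)
  t2 <- sharing_frequency_test(12, 99, 1, 101)
  expect_equal(signif(t2$p, 2), 0.0012)
  t3 <- sharing_frequency_test(5, 50, 5, 50)
  expect_equal(t3$p, 1)
  expect_error(sharing_frequency_test(1, 0, 1, 10), "positive")
})

test_that("sharing links export is deterministic and round-trips", {
  mab <- data.frame(mab_id = c("m2", "m1", "m3"), v_call = "TVH3-1*01",
                    j_call = "TVJ1*01",
                    cdr3_aa = c("ARDYYGMDVA", "ARDYYGMDVA", "ARDYYGMDVA"),
                    isotype = "IGA", polyreactive = FALSE,
                    stringsAsFactors = FALSE)
  ngs <- mk_ngs("n1", "TVH3-1*01", "TVJ1*01", "ARDYYGMDVA")
  sh <- find_shared(mab, ngs)
  p <- withr::local_tempfile(fileext = ".tsv")
  export_sharing_links(sh, p)
  back <- read.delim(p, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 3)
  expect_equal(back$mab_id, c("m1", "m2", "m3"))   # sorted
  expect_equal(back$ngs_id, rep("n1", 3))
  expect_equal(back$identity, rep(1, 3))
  # empty input -> header-only file
  sh0 <- find_shared(mab[0, ], ngs)
  export_sharing_links(sh0, p)
  expect_equal(length(readLines(p)), 1)
})
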