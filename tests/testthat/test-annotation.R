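# Alignment, segment assignment, CDR-H3 extraction and mutation counting.

test_that("local alignment handles identity and single-mismatch cases", {
  s <- paste(rep(c("A", "C", "G", "T", "G", "A"), 5), collapse = "")  # 30 nt
  a <- align_local(s, s)
  expect_equal(a$score, 30)
  expect_equal(a$identity, 1.0)
  expect_equal(a$subject_start, 1)
  expect_equal(a$subject_end, 30)

  q <- s
  substr(q, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(s, 15, 15))[1]
  a2 <- align_local(q, s)
  expect_equal(a2$score, 29 - 2)
  expect_equal(a2$identity, 29 / 30)
})

test_that("local alignment score equals the naive DP oracle on random pairs", {
  set.seed(101)
  for (i in 1:40) {
    q <- random_dna(1, sample(5:25, 1))
    s <- random_dna(1, sample(5:25, 1))
    expect_equal(align_local(q, s)$score, oracle_local_score(q, s),
                 info = paste(q, s))
  }
  # including gapped cases: a deletion inside a long match
  q <- "ACGTACGTACGTACGTACGT"
  s <- paste0(substr(q, 1, 10), "GG", substr(q, 11, 20))
  expect_equal(align_local(q, s)$score, oracle_local_score(q, s))
})

test_that("V/J assignment is exact on clean simulated records", {
  ref <- load_germline_reference("builtin")
  sim <- simulate_repertoire(sim_config(seed = 23, n_clones = 10,
                                        shm_mean = 0, read_error_rate = 0))
  idx <- sample(nrow(sim$truth), 15)
  for (i in idx) {
    vj <- assign_vj(sim$truth$sequence[i], ref)
    expect_equal(vj$v_call, sim$truth$v_call[i])
    expect_equal(vj$j_call, sim$truth$j_call[i])
    expect_equal(vj$v_germline_start, 1L)
    expect_lt(vj$v_support, 1e-50)
  }
})

test_that("heavily mutated records still recover the true V and J calls", {
  ref <- load_germline_reference("builtin")
  sim <- simulate_repertoire(sim_config(seed = 29, n_clones = 25,
                                        shm_mean = 20, read_error_rate = 0))
  idx <- sample(nrow(sim$truth), 100)
  ok <- 0
  for (i in idx) {
    vj <- assign_vj(sim$truth$sequence[i], ref)
    ok <- ok + (vj$v_call == sim$truth$v_call[i] &&
                  vj$j_call == sim$truth$j_call[i])
  }
  expect_gte(ok / length(idx), 0.99)
})

test_that("shuffled non-Ig input falls below the score floor and fails QC", {
  ref <- load_germline_reference("builtin")
  set.seed(3)
  junk <- random_dna(5, 400)
  # a 400-nt random query over this search space tops out near 20 bits, so
  # the floor mechanism is exercised at a floor clear of the noise peak
  for (s in junk) {
    vj <- assign_vj(s, ref, score_floor_bits = 40)
    expect_equal(vj$v_call, "none")
    expect_equal(vj$v_support, Inf)
  }
  # true V hits sit far above the same floor
  sim <- simulate_repertoire(sim_config(seed = 3, n_clones = 3,
                                        read_error_rate = 0))
  vj_true <- assign_vj(sim$truth$sequence[1], ref, score_floor_bits = 40)
  expect_equal(vj_true$v_call, sim$truth$v_call[1])
  # under default settings random input is still removed, by the E-value QC
  ann <- annotate_rearrangements(data.frame(id = paste0("junk", 1:5),
                                            sequence = junk), ref)
  qc <- apply_qc(ann)
  expect_equal(nrow(qc$pass), 0)
  expect_true(all(grepl("evalue_fail", qc$reject$qc_flags) |
                    qc$reject$v_call == "none"))
})

test_that("CDR-H3 extraction translates the planted junction", {
  ref <- load_germline_reference("builtin")
  v <- ref[ref$segment_type == "V", ][1, ]
  j <- ref[ref$segment_type == "J", ][1, ]
  cseg <- ref[ref$segment_type == "C", ][1, ]
  junction <- "GCGAGAGATTACTAC"             # ARDYY
  s <- paste0(v$sequence, junction, j$sequence, cseg$sequence)
  vj <- assign_vj(s, ref)
  cdr3 <- extract_cdr3(s, vj, ref)
  expect_true(cdr3$motif_ok)
  expect_equal(cdr3$cdr3_nt, junction)
  expect_equal(cdr3$cdr3_aa, "ARDYY")
  expect_true(cdr3$productive)
})

test_that("destroying the W-G-x-G motif flags cdr3_motif_fail", {
  ref <- load_germline_reference("builtin")
  v <- ref[ref$segment_type == "V", ][1, ]
  j <- ref[ref$segment_type == "J", ][1, ]
  jseq <- j$sequence
  substr(jseq, 1, 3) <- "CGG"               # W -> R at the motif start
  s <- paste0(v$sequence, "GCGAGAGATTACTAC", jseq,
              ref[ref$segment_type == "C", ][1, ]$sequence)
  vj <- assign_vj(s, ref)
  cdr3 <- extract_cdr3(s, vj, ref)
  expect_false(cdr3$motif_ok)
  expect_true(is.na(cdr3$cdr3_aa))
})

test_that("clean simulated records yield the exact truth junction", {
  ref <- load_germline_reference("builtin")
  sim <- simulate_repertoire(sim_config(seed = 37, n_clones = 12,
                                        read_error_rate = 0))
  idx <- sample(nrow(sim$truth), 40)
  rec <- data.frame(id = sim$truth$sequence_id[idx],
                    sequence = sim$truth$sequence[idx])
  ann <- annotate_rearrangements(rec, ref)
  expect_equal(ann$junction, sim$truth$junction[idx])
  expect_equal(ann$junction_aa, sim$truth$junction_aa[idx])
})

test_that("mutation counting matches planted counts and excludes N", {
  ref <- load_germline_reference("builtin")
  v <- ref[ref$segment_type == "V", ][2, ]
  j <- ref[ref$segment_type == "J", ][2, ]
  cseg <- ref[ref$segment_type == "C", ][2, ]
  base <- paste0(v$sequence, "TGTACTGGGAGTCCT", j$sequence, cseg$sequence)

  plant <- function(s, pos) {
    for (p in pos) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }
  # 7 substitutions spread over the V region, including position 1
  pos7 <- c(1, 30, 77, 120, 181, 240, 290)
  s7 <- plant(base, pos7)
  vj <- assign_vj(s7, ref)
  mut <- count_vh_mutations(s7, vj, ref)
  expect_equal(mut$count, 7L)
  expect_equal(mut$freq, 100 * 7 / nchar(v$sequence))

  # two substitutions plus one N placed at a third mutated site: N excluded
  s2 <- plant(base, c(50, 100))
  substr(s2, 150, 150) <- "N"
  vj2 <- assign_vj(s2, ref)
  expect_equal(count_vh_mutations(s2, vj2, ref)$count, 2L)

  # unmutated record counts zero
  vj0 <- assign_vj(base, ref)
  expect_equal(count_vh_mutations(base, vj0, ref)$count, 0L)
})

test_that("mutation frequency is invariant to duplicate counts", {
  ref <- load_germline_reference("builtin")
  sim <- simulate_repertoire(sim_config(seed = 41, n_clones = 5,
                                        read_error_rate = 0))
  rec <- data.frame(id = sim$truth$sequence_id[1:5],
                    sequence = sim$truth$sequence[1:5],
                    duplicate_count = c(1L, 10L, 100L, 7L, 3L))
  ann1 <- annotate_rearrangements(rec, ref)
  rec$duplicate_count <- 1L
  ann2 <- annotate_rearrangements(rec, ref)
  expect_equal(ann1$vh_mutation_freq, ann2$vh_mutation_freq)
})

test_that("isotype calls are exact on clean records, unknown when truncated", {
  ref <- load_germline_reference("builtin")
  sim <- simulate_repertoire(sim_config(seed = 43, n_clones = 15,
                                        read_error_rate = 0))
  idx <- sample(nrow(sim$truth), 50)
  calls <- vapply(idx, function(i) call_isotype(sim$truth$sequence[i], ref),
                  character(1))
  expect_equal(calls, sim$truth$isotype[idx])
  # truncate before the constant region
  s <- sim$truth$sequence[idx[1]]
  s_trunc <- substr(s, 1, nchar(s) - 50)
  expect_equal(call_isotype(s_trunc, ref), "unknown")
})
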