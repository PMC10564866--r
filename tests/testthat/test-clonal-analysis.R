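# Dereplication, clonal family inference, mutation networks, expansion.

test_that("identical and 99.33%-identical sequences collapse on dereplication", {
  set.seed(51)
  s <- random_dna(1, 300)
  s2 <- s
  substr(s2, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(s, 50, 50))[1]
  substr(s2, 200, 200) <- setdiff(c("A", "C", "G", "T"), substr(s, 200, 200))[1]
  rec <- data.frame(id = c("a", "b", "c"), sequence = c(s, s, s2),
                    duplicate_count = c(3L, 2L, 1L))
  dr <- dereplicate_99(rec)
  expect_equal(nrow(dr), 1)                 # 2 mismatches in 300 = 99.33%
  expect_equal(dr$duplicate_count, 6L)
  expect_equal(dr$id, "a")
})

test_that("dereplication equals the greedy first-seed oracle on random sets", {
  set.seed(53)
  for (rep in 1:5) {
    base <- random_dna(6, 250)
    seqs <- c(base, vapply(sample(base, 18, replace = TRUE), function(s) {
      k <- sample(0:4, 1)
      if (k > 0) {
        for (p in sample(nchar(s), k)) {
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(s, p, p)), 1)
        }
      }
      s
    }, character(1), USE.NAMES = FALSE))
    rec <- data.frame(id = sprintf("s%02d", seq_along(seqs)),
                      sequence = seqs,
                      duplicate_count = sample(1:5, length(seqs),
                                               replace = TRUE))
    dr <- dereplicate_99(rec)
    got <- split(attr(dr, "cluster_map")$id,
                 attr(dr, "cluster_map")$representative_id)
    want <- oracle_derep(rec)
    got_sets <- lapply(got, sort)
    want_sets <- lapply(want, sort)
    expect_setequal(unname(lapply(got_sets, paste, collapse = ",")),
                    unname(lapply(want_sets, paste, collapse = ",")))
  }
})

test_that("dereplication is idempotent", {
  sim <- simulate_repertoire(sim_config(seed = 57, n_clones = 10))
  rec <- data.frame(sequence_id = sim$truth$sequence_id,
                    sequence = sim$truth$sequence,
                    duplicate_count = sim$truth$duplicate_count)
  dr1 <- dereplicate_99(rec)
  dr2 <- dereplicate_99(dr1)
  # same clusters (rows may be re-ordered by the summed duplicate counts)
  o1 <- order(dr1$sequence); o2 <- order(dr2$sequence)
  expect_equal(dr2$sequence[o2], dr1$sequence[o1])
  expect_equal(dr2$duplicate_count[o2], dr1$duplicate_count[o1])
})

test_that("clonal family rule joins by 0.8 CDR-H3 identity within V/J/length", {
  rec <- data.frame(
    sequence_id = c("a", "b", "c", "d"),
    v_call = "TVH3-1*01", j_call = "TVJ1*01",
    junction_aa = "ARDYYGMDV",
    duplicate_count = c(5L, 1L, 2L, 1L), stringsAsFactors = FALSE)
  fams <- infer_clonal_families(rec)
  expect_equal(nrow(fams), 1)
  expect_equal(fams$representative_id, "a")

  # 3 differences at length 10 = identity 0.7 < 0.8: two families
  rec2 <- data.frame(sequence_id = c("x", "y"),
                     v_call = "TVH3-1*01", j_call = "TVJ1*01",
                     junction_aa = c("ARDYYGMDVW", "ARDAAGMDVA"),
                     duplicate_count = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(infer_clonal_families(rec2)), 2)
  # but different V genes split even identical junctions
  rec3 <- rec2
  rec3$junction_aa <- "ARDYYGMDVW"
  rec3$v_call <- c("TVH3-1*01", "TVH4-1*01")
  expect_equal(nrow(infer_clonal_families(rec3)), 2)
  # allele suffixes are ignored
  rec4 <- rec3
  rec4$v_call <- c("TVH3-1*01", "TVH3-1*02")
  expect_equal(nrow(infer_clonal_families(rec4)), 1)
})

test_that("family inference recovers the simulated partition exactly (ARI 1)", {
  sim <- simulate_repertoire(sim_config(seed = 61, n_clones = 60,
                                        read_error_rate = 0))
  rec <- data.frame(sequence_id = sim$truth$sequence_id,
                    v_call = sim$truth$v_call, j_call = sim$truth$j_call,
                    junction_aa = sim$truth$junction_aa,
                    duplicate_count = sim$truth$duplicate_count,
                    stringsAsFactors = FALSE)
  fams <- infer_clonal_families(rec)
  fam_map <- attr(fams, "family_map")
  expect_setequal(names(fam_map), sim$truth$sequence_id)
  ari <- adjusted_rand_index(fam_map[sim$truth$sequence_id],
                             sim$truth$clone_id)
  expect_equal(ari, 1)
})

test_that("family inference is invariant to input order", {
  sim <- simulate_repertoire(sim_config(seed = 67, n_clones = 15))
  rec <- data.frame(sequence_id = sim$truth$sequence_id,
                    v_call = sim$truth$v_call, j_call = sim$truth$j_call,
                    junction_aa = sim$truth$junction_aa,
                    duplicate_count = sim$truth$duplicate_count,
                    stringsAsFactors = FALSE)
  f1 <- infer_clonal_families(rec)
  f2 <- infer_clonal_families(rec[sample(nrow(rec)), ])
  expect_equal(f1$family_id, f2$family_id)
  expect_equal(f1$representative_id, f2$representative_id)
  # partition property: disjoint and covering
  all_members <- unlist(f1$members)
  expect_setequal(all_members, rec$sequence_id)
  expect_false(anyDuplicated(all_members) > 0)
})

test_that("network edges are exactly the Hamming-1 pairs", {
  rec <- data.frame(sequence_id = c("u", "v", "w"),
                    sequence = c("AAA", "AAT", "ATT"),
                    duplicate_count = c(4L, 2L, 1L), stringsAsFactors = FALSE)
  net <- build_clone_network(rec)
  expect_equal(nrow(net$edges), 2)
  got <- paste(net$edges$from, net$edges$to)
  expect_setequal(got, c("u v", "v w"))
  expect_equal(nrow(net$components), 1)

  # different lengths never connect
  rec2 <- data.frame(sequence_id = c("a", "b"),
                     sequence = c("AAAA", "AAA"), duplicate_count = 1L,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(build_clone_network(rec2)$edges), 0)
})

test_that("network edge set matches the brute-force oracle on 200 sequences", {
  set.seed(71)
  base <- random_dna(12, 40)
  seqs <- unique(c(base, vapply(sample(base, 300, replace = TRUE),
    function(s) {
      p <- sample(40, 1)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
      s
    }, character(1), USE.NAMES = FALSE)))[1:200]
  seqs <- seqs[!is.na(seqs)]
  rec <- data.frame(sequence_id = sprintf("n%03d", seq_along(seqs)),
                    sequence = seqs, duplicate_count = 1L,
                    stringsAsFactors = FALSE)
  net <- build_clone_network(rec)
  oracle <- oracle_hamming1(seqs)
  got <- sort(paste(pmin(net$edges$from, net$edges$to),
                    pmax(net$edges$from, net$edges$to)))
  want <- sort(paste(pmin(rec$sequence_id[oracle[, 1]],
                          rec$sequence_id[oracle[, 2]]),
                     pmax(rec$sequence_id[oracle[, 1]],
                          rec$sequence_id[oracle[, 2]])))
  expect_equal(got, want)
})

test_that("network export preserves vertex sizes and edges", {
  rec <- data.frame(sequence_id = c("u", "v"), sequence = c("ACGT", "ACGA"),
                    duplicate_count = c(9L, 1L), stringsAsFactors = FALSE)
  net <- build_clone_network(rec)
  gml <- withr::local_tempfile(fileext = ".graphml")
  edg <- withr::local_tempfile(fileext = ".tsv")
  export_clone_network(net, gml, edg)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vertex_attr(g2, "size"), c(9, 1))
  expect_equal(nrow(read.delim(edg)), 1)
})

test_that("expansion summary tracks singleton and fully-expanded limits", {
  rec <- data.frame(group = "eART", isotype = "IGA",
                    family_id = sprintf("F%d", 1:10),
                    duplicate_count = 1L, vh_mutation_count = 5L,
                    stringsAsFactors = FALSE)
  es <- expansion_summary(rec)
  expect_equal(es$frac_in_expanded, 0)

  rec2 <- rec; rec2$family_id <- "F1"
  es2 <- expansion_summary(rec2)
  expect_equal(es2$frac_in_expanded, 1)
})

test_that("clone-size tail slope recovers the configured power-law exponent", {
  cfg <- sim_config(seed = 73, n_clones = 400, clone_size_exponent = 2.5)
  sim <- simulate_repertoire(cfg)
  alpha <- powerlaw_exponent(sim$truth$duplicate_count)
  expect_lt(abs(alpha - 2.5) / 2.5, 0.2)
})
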