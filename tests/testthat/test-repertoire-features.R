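# Feature panel and group-comparison statistics.

test_that("CDR3 charge classes count R/K against D/E, excluding histidine", {
  # net = (#R + #K) - (#D + #E)
  expect_equal(cdr3_charge_class(c("GKKYY", "GDDYY", "GDKYY")),
               c("positive", "negative", "neutral"))
  expect_equal(cdr3_charge_class(c("ARKKY", "ARDDY", "ARDKY")),
               c("positive", "negative", "positive"))
  expect_equal(cdr3_charge_class("HHHH"), "neutral")
  expect_error(cdr3_charge_class("ARZ"), "non-amino-acid")
})

test_that("Fisher 2x2 reproduces in-study values and basic symmetries", {
  # printed polyreactive-sharing table: 12/99 vs 1/101
  expect_equal(signif(fisher_exact_2x2(12, 87, 1, 100), 2), 0.0012)
  # printed all-sharing table: 33/99 vs 6/101
  expect_lt(fisher_exact_2x2(33, 66, 6, 95), 0.0001)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
  # invariance to simultaneous row and column swaps
  expect_equal(fisher_exact_2x2(12, 87, 1, 100),
               fisher_exact_2x2(100, 1, 87, 12))
  expect_equal(fisher_exact_2x2(12, 87, 1, 100),
               fisher_exact_2x2(1, 100, 12, 87))
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher 2x2 matches exhaustive enumeration for all small tables", {
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    if (a + b + cc + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, cc, d), oracle_fisher(a, b, cc, d),
                 tolerance = 1e-12, info = paste(a, b, cc, d))
  }
  # larger margins, spot-checked against stats::fisher.test as well
  set.seed(81)
  for (i in 1:25) {
    tb <- sample(0:12, 4, replace = TRUE)
    if (sum(tb) == 0) next
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, oracle_fisher(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    expect_equal(p, fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Welch t handles degenerate and separated samples", {
  w <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  x <- c(0, 0, 0, 0) + c(0, 1e-9, -1e-9, 0)
  y <- c(1, 1, 1, 1) + c(1e-9, 0, 0, -1e-9)
  expect_lt(welch_t(x, y)$p, 1e-6)
  wc <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(wc$p, 1)
})

test_that("Welch t matches the closed-form computation on random samples", {
  set.seed(83)
  for (i in 1:200) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    got <- welch_t(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

make_panel <- function(n, v_fams = c("VH1", "VH3", "VH4"),
                       probs = c(1, 1, 1), seed = 1, mut_mean = 18) {
  set.seed(seed)
  fam <- sample(v_fams, n, replace = TRUE, prob = probs)
  rec <- data.frame(
    sequence_id = sprintf("s%04d", 1:n),
    v_call = paste0("T", fam, "-1*01"),
    j_call = "TVJ1*01", c_call = sample(c("IGA", "IGG"), n, replace = TRUE),
    junction_aa = replicate(n, paste(sample(c("A", "R", "D", "G", "Y"),
                                            12, replace = TRUE),
                                     collapse = "")),
    cdr3_length_aa = 12L,
    vh_mutation_count = rpois(n, mut_mean), stringsAsFactors = FALSE)
  build_feature_panel(rec)
}

test_that("identical panels compare with all p = 1 and nothing significant", {
  p1 <- make_panel(150, seed = 5)
  p2 <- make_panel(150, seed = 5)
  cmp <- compare_repertoires(p1, p2)
  expect_true(all(cmp$p == 1))
  expect_false(any(cmp$significant))
  # bookkeeping identity: categorical rows = enumerated (feature, level)
  # pairs present in either panel, continuous rows = continuous features
  n_cat_levels <- nrow(unique(rbind(p1$cat, p2$cat)))
  expect_equal(sum(cmp$test == "fisher_2x2"), n_cat_levels)
  expect_equal(sum(cmp$test == "welch_t"), length(p1$cont))
})

test_that("a planted 3-fold V-family usage shift is detected with power", {
  hits <- 0; n_seeds <- 40
  for (s in 1:n_seeds) {
    pa <- make_panel(300, probs = c(3, 1, 1), seed = 1000 + s)
    pb <- make_panel(300, probs = c(1, 1, 1), seed = 2000 + s)
    cmp <- compare_repertoires(pa, pb)
    row <- cmp[cmp$feature == "v_family" & cmp$level == "VH1", ]
    hits <- hits + (nrow(row) == 1 && row$significant)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("repertoire comparison is invariant to record order", {
  set.seed(91)
  pa <- make_panel(120, seed = 7)
  rec <- data.frame(sequence_id = sprintf("s%04d", 1:120),
                    v_call = sample(c("TVH1-1*01", "TVH3-1*01"), 120, TRUE),
                    j_call = "TVJ2*01",
                    c_call = sample(c("IGA", "IGG"), 120, TRUE),
                    junction_aa = "ARDYYGMDV", cdr3_length_aa = 9L,
                    vh_mutation_count = rpois(120, 20),
                    stringsAsFactors = FALSE)
  pb1 <- build_feature_panel(rec)
  pb2 <- build_feature_panel(rec[sample(120), ])
  c1 <- compare_repertoires(pa, pb1)
  c2 <- compare_repertoires(pa, pb2)
  expect_equal(c1, c2)
})

test_that("correlation matrix recovers exact linear dependence and BH steps", {
  x <- data.frame(a = 1:20, b = 2 * (1:20) + 1, c = rnorm(20))
  cm <- correlation_matrix(x)
  expect_equal(cm$r["a", "b"], 1, tolerance = 1e-12)
  expect_lt(cm$p["a", "b"], 1e-12)
  # hand-computed BH at q = 0.05 on {0.001, 0.02, 0.03, 0.9}:
  # thresholds 0.0125/0.025/0.0375/0.05 -> first three rejected
  ps <- c(0.001, 0.02, 0.03, 0.9)
  bh <- p.adjust(ps, "BH")
  expect_equal(bh <= 0.05, c(TRUE, TRUE, TRUE, FALSE))
  # BH adjusted p-values are monotone in raw-p order
  set.seed(93)
  for (i in 1:20) {
    p_raw <- runif(sample(5:40, 1))
    adj <- p.adjust(p_raw, "BH")
    o <- order(p_raw)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("null correlations reject at the nominal 5% rate", {
  set.seed(95)
  n_pairs <- 0; n_sig <- 0
  for (s in 1:60) {
    x <- as.data.frame(matrix(rnorm(78 * 6), 78, 6))
    cm <- correlation_matrix(x)
    n_pairs <- n_pairs + nrow(cm$pairs)
    n_sig <- n_sig + sum(cm$pairs$p < 0.05)
  }
  rate <- n_sig / n_pairs
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_pairs))
})

test_that("constant columns yield missing correlations with a warning", {
  x <- data.frame(a = rnorm(10), b = rep(2, 10))
  expect_warning(cm <- correlation_matrix(x), "constant")
  expect_true(is.na(cm$r["a", "b"]))
})

test_that("IgA/IgG ratio counts isotypes and flags the zero-IgG case", {
  rec <- data.frame(c_call = c(rep("IGA", 10), rep("IGG", 5)),
                    group = "eART", stringsAsFactors = FALSE)
  expect_equal(iga_igg_ratio(rec), 2)
  rec2 <- data.frame(c_call = rep("IGG", 5), group = "eART")
  expect_equal(iga_igg_ratio(rec2), 0)
  rec3 <- data.frame(c_call = rep("IGA", 5), group = "eART")
  expect_warning(r <- iga_igg_ratio(rec3), "infinite")
  expect_true(is.infinite(r))
})

test_that("simulated isotype mix yields the expected IgA/IgG ratio", {
  cfg <- sim_config(seed = 97, n_clones = 500, n_members_mean = 3,
                    isotype_mix = list(gut = c(IGA = 0.6, IGG = 0.4),
                                       blood = c(IGA = 0.6, IGG = 0.4)))
  sim <- simulate_repertoire(cfg)
  # isotype is drawn per clone: check the clone-level IgA fraction within
  # 3 binomial SEs of the configured 0.6, and the member-level ratio
  n_cl <- nrow(sim$clones)
  p_hat <- mean(sim$clones$isotype == "IGA")
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / n_cl))
  rec <- data.frame(c_call = sim$truth$isotype, group = sim$truth$group)
  ratio <- iga_igg_ratio(rec)
  expect_lt(abs(ratio - 1.5) / 1.5, 3 * sqrt(0.6 * 0.4 / n_cl) / 0.24)
})
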