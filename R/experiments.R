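# Packaged validation experiments: each runs the pipeline on simulated
# repertoires with known ground truth and measures recovery. They back the
# analysis drivers under analysis/ and the acceptance checks.

#' Clean-limit end-to-end recovery experiment
#'
#' Simulates `n_clones` clones per (group, compartment) with mean V_H
#' mutation load 20 and error-free reads, runs the full pipeline (read
#' emission, merging, annotation, QC, dereplication, clonal families) and
#' compares every call against the generative truth.
#'
#' @param seed integer seed.
#' @param n_clones clones per (group, compartment).
#' @return list: `n_members`, `qc_pass_fraction`, `vj_exact_fraction`,
#'   `junction_exact_fraction`, `mutation_exact_fraction`, `ari`
#'   (adjusted Rand index between the inferred family partition and the
#'   true clone partition).
#' @export
run_clean_limit_experiment <- function(seed = 1L, n_clones = 200L) {
  cfg <- sim_config(seed = derive_seed(seed, "clean"), n_clones = n_clones,
                    shm_mean = 20, read_error_rate = 0)
  ref <- load_germline_reference("builtin")
  sim <- simulate_repertoire(cfg, ref)
  truth <- sim$truth
  dir <- tempfile("cleanlimit"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  r1 <- file.path(dir, "R1.fastq"); r2 <- file.path(dir, "R2.fastq")
  set.seed(derive_seed(seed, "clean_reads"))
  emit_paired_reads(truth, cfg, r1, r2)
  mg <- merge_pairs(read_fastq(r1), read_fastq(r2))
  merged <- data.frame(id = mg$merged$id, sequence = mg$merged$sequence,
                       stringsAsFactors = FALSE)
  merged$duplicate_count <-
    truth$duplicate_count[match(merged$id, truth$sequence_id)]
  rearr <- annotate_rearrangements(merged, ref)
  qc <- apply_qc(rearr)
  tr <- truth[match(qc$pass$sequence_id, truth$sequence_id), ]
  vj_ok <- qc$pass$v_call == tr$v_call & qc$pass$j_call == tr$j_call
  junc_ok <- qc$pass$junction == tr$junction
  mut_ok <- qc$pass$vh_mutation_count == tr$n_mutations
  derep <- dereplicate_99(qc$pass)
  fams <- infer_clonal_families(derep)
  cl_map <- attr(derep, "cluster_map")
  fam_map <- attr(fams, "family_map")
  member_fam <- fam_map[cl_map$representative_id[
    match(truth$sequence_id, cl_map$id)]]
  keep <- !is.na(member_fam)
  ari <- mclust::adjustedRandIndex(member_fam[keep],
                                   truth$clone_id[keep])
  list(n_members = nrow(truth),
       qc_pass_fraction = nrow(qc$pass) / nrow(rearr),
       merged_fraction = mg$report$merged / mg$report$input,
       vj_exact_fraction = mean(vj_ok),
       junction_exact_fraction = mean(junc_ok),
       mutation_exact_fraction = mean(mut_ok),
       ari = ari)
}

#' Somatic hypermutation recovery experiment
#'
#' Simulates repertoires at the default per-stratum mutation means
#' (gut/blood x IgA/IgG x eART/lART), annotates the pre-merged sequences
#' through the pipeline and compares the duplicate-weighted mean V_H
#' mutation count recovered per stratum against the configured target.
#' Clone sizes follow a heavier-tailed law here so that every stratum
#' carries at least `min_sequences` sequences.
#'
#' @param seed integer seed.
#' @param n_clones clones per (group, compartment).
#' @param min_sequences target duplicate-weighted sequences per stratum.
#' @return data.frame: stratum, target, recovered, n_sequences,
#'   rel_error.
#' @export
run_shm_recovery_experiment <- function(seed = 1L, n_clones = 2900L,
                                        min_sequences = 10000L) {
  cfg <- sim_config(seed = derive_seed(seed, "shm"), n_clones = n_clones,
                    clone_size_exponent = 2.3, read_error_rate = 0)
  ref <- load_germline_reference("builtin")
  sim <- simulate_repertoire(cfg, ref)
  truth <- sim$truth
  rec <- data.frame(id = truth$sequence_id, sequence = truth$sequence,
                    duplicate_count = truth$duplicate_count,
                    stringsAsFactors = FALSE)
  rearr <- annotate_rearrangements(rec, ref)
  qc <- apply_qc(rearr)
  pass <- qc$pass
  tr <- truth[match(pass$sequence_id, truth$sequence_id), ]
  stratum <- paste(tr$compartment, pass$c_call, tr$group, sep = ".")
  rows <- lapply(names(cfg$shm_mean), function(st) {
    sel <- stratum == st
    w <- pass$duplicate_count[sel]
    recovered <- sum(w * pass$vh_mutation_count[sel]) / sum(w)
    data.frame(stratum = st, target = cfg$shm_mean[[st]],
               recovered = recovered, n_sequences = sum(w),
               rel_error = abs(recovered - cfg$shm_mean[[st]]) /
                 cfg$shm_mean[[st]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "min_sequences_met") <- all(out$n_sequences >= min_sequences)
  out
}

#' Gut-to-blood sharing recovery experiment
#'
#' For each seed, simulates one repertoire per group with the default
#' sharing fractions (eART 0.049, lART 0.333), takes `n_mabs` gut clones
#' per group as a monoclonal antibody panel, and runs [find_shared()]
#' against the blood repertoire. Reports pooled recovered frequencies and
#' the pooled binomial 95% CI around the configured fractions.
#'
#' @param seed integer base seed.
#' @param n_seeds replicate simulations.
#' @param n_mabs gut clones sampled per group per replicate.
#' @return data.frame per group: configured fraction, recovered fraction,
#'   truly shared fraction, pooled-CI bounds and flag, and the per-seed
#'   95% CI coverage of the recovered frequencies. Per-seed counts are
#'   attached as attribute `"per_seed"`.
#' @export
run_sharing_recovery_experiment <- function(seed = 1L, n_seeds = 50L,
                                            n_mabs = 100L) {
  ref <- load_germline_reference("builtin")
  per_seed <- list()
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(seed = derive_seed(seed, paste0("share", s)),
                      n_clones = n_mabs, n_members_mean = 3)
    sim <- simulate_repertoire(cfg, ref)
    truth <- sim$truth
    blood <- truth[truth$compartment == "blood", ]
    for (g in c("eART", "lART")) {
      gut_clones <- sim$clones[sim$clones$group == g &
                                 sim$clones$home_compartment == "gut", ]
      gut_members <- truth[truth$compartment == "gut" &
                             truth$clone_id %in% gut_clones$clone_id, ]
      reps <- gut_members[!duplicated(gut_members$clone_id), ]
      reps <- reps[seq_len(min(n_mabs, nrow(reps))), ]
      mabs <- data.frame(mab_id = reps$sequence_id, v_call = reps$v_call,
                         j_call = reps$j_call, cdr3_aa = reps$junction_aa,
                         isotype = reps$isotype,
                         polyreactive = reps$polyreactive,
                         stringsAsFactors = FALSE)
      bl <- blood[blood$group == g, ]
      ngs <- data.frame(sequence_id = bl$sequence_id,
                        v_call = bl$v_call, j_call = bl$j_call,
                        junction_aa = bl$junction_aa,
                        compartment = bl$compartment,
                        stringsAsFactors = FALSE)
      sh <- find_shared(mabs, ngs)
      per_seed[[length(per_seed) + 1]] <- data.frame(
        seed = s, group = g, n_mabs = nrow(mabs),
        n_true_shared = sum(reps$clone_id %in%
                              gut_clones$clone_id[grepl("blood",
                                                        gut_clones$compartments)]),
        n_recovered = nrow(sh), stringsAsFactors = FALSE)
    }
  }
  per_seed <- do.call(rbind, per_seed)
  f <- sim_config()$shared_clone_fraction
  out <- do.call(rbind, lapply(c("eART", "lART"), function(g) {
    ps <- per_seed[per_seed$group == g, ]
    tested <- sum(ps$n_mabs)
    p_hat <- sum(ps$n_recovered) / tested
    half <- 1.96 * sqrt(f[[g]] * (1 - f[[g]]) / tested)
    half_seed <- 1.96 * sqrt(f[[g]] * (1 - f[[g]]) / n_mabs)
    cover <- mean(abs(ps$n_recovered / ps$n_mabs - f[[g]]) <= half_seed)
    data.frame(group = g, configured = f[[g]], recovered = p_hat,
               true_shared = sum(ps$n_true_shared) / tested,
               n = tested, ci_lo = f[[g]] - half, ci_hi = f[[g]] + half,
               within_ci = p_hat >= f[[g]] - half & p_hat <= f[[g]] + half,
               per_seed_ci_coverage = cover,
               exact_recovery = all(ps$n_recovered == ps$n_true_shared),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "per_seed") <- per_seed
  out
}

#' Type-I error calibration of the comparison tests
#'
#' Null simulations: Welch t on two N(0,1) samples (n = 30 each) and
#' Fisher 2x2 on two Binomial(`n_per_group`, 0.3) counts. Reports
#' rejection rates at alpha = 0.05 over `n_reps` replicates with the
#' 3-SE binomial band.
#'
#' @param seed integer seed.
#' @param n_reps replicates per test.
#' @param n_per_group group size for the Fisher null.
#' @return list: `welch_rate`, `fisher_rate`, `band` (3-SE half-width).
#' @export
run_calibration_experiment <- function(seed = 1L, n_reps = 1000L,
                                       n_per_group = 150L) {
  set.seed(derive_seed(seed, "calibration"))
  welch_rej <- logical(n_reps); fisher_rej <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    welch_rej[i] <- welch_t(stats::rnorm(30), stats::rnorm(30))$p < 0.05
    a <- rbinom(1, n_per_group, 0.3); b <- rbinom(1, n_per_group, 0.3)
    fisher_rej[i] <- fisher_exact_2x2(a, n_per_group - a,
                                      b, n_per_group - b) < 0.05
  }
  list(welch_rate = mean(welch_rej), fisher_rate = mean(fisher_rej),
       band = 3 * sqrt(0.05 * 0.95 / n_reps))
}
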