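# Synthetic gut/blood IGH repertoire generator. Emulates the study design
# the analysis assumes: two donor groups (eART/lART), two compartments
# (gut/blood), IgA/IgG isotypes with group- and compartment-dependent
# mutation loads, clonally expanded lineages with power-law sizes, a
# group-dependent fraction of gut clones also seeding the blood, and a
# group-dependent fraction of polyreactive clones.

#' Simulation configuration
#'
#' Defaults are the study conditions: per-stratum mean V_H mutation counts
#' (gut IgA 20.5/21.4, gut IgG 22.0/21.9, blood IgA 18.4/19.8, blood IgG
#' 19.8/18.9 for eART/lART), gut isotype mix 36% IgA vs 22% IgG
#' (renormalized), gut-to-blood clone sharing 4.9% (eART) vs 33.3% (lART),
#' and polyreactive clone fractions 18.8% vs 31.3%. The blood isotype mix
#' and the clone-size power law are modelling choices (see the methods
#' vignette).
#'
#' @param seed integer RNG seed.
#' @param n_clones clones per (group, compartment).
#' @param clone_size_exponent power-law exponent for per-member duplicate
#'   counts.
#' @param shm_mean named vector of expected V_H nucleotide mutations per
#'   `compartment.isotype.group` stratum.
#' @param isotype_mix list with per-compartment IGA/IGG probabilities.
#' @param shared_clone_fraction per-group probability that a gut clone also
#'   seeds the blood.
#' @param polyreactive_fraction per-group probability that a clone is
#'   polyreactive.
#' @param read_error_rate per-base substitution probability for simulated
#'   reads.
#' @param read_length read length for paired-end emission.
#' @param fragment_overlap forced read overlap (NULL: overlap follows from
#'   template length and `read_length`).
#' @param n_members_mean mean clone size (unique members; 1 + Poisson).
#' @param shared_mutation_fraction fraction of a member's mutation load
#'   drawn from the clone's shared lineage positions.
#' @param n_donors donors per group.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_clones = 200L,
                       clone_size_exponent = 2.5,
                       shm_mean = c(gut.IGA.eART = 20.5, gut.IGA.lART = 21.4,
                                    gut.IGG.eART = 22.0, gut.IGG.lART = 21.9,
                                    blood.IGA.eART = 18.4, blood.IGA.lART = 19.8,
                                    blood.IGG.eART = 19.8, blood.IGG.lART = 18.9),
                       isotype_mix = list(gut = c(IGA = 36 / 58, IGG = 22 / 58),
                                          blood = c(IGA = 0.5, IGG = 0.5)),
                       shared_clone_fraction = c(eART = 0.049, lART = 0.333),
                       polyreactive_fraction = c(eART = 0.188, lART = 0.313),
                       read_error_rate = 0.001,
                       read_length = 300L,
                       fragment_overlap = NULL,
                       n_members_mean = 4,
                       shared_mutation_fraction = 0.5,
                       n_donors = 3L) {
  if (length(shm_mean) == 1 && is.null(names(shm_mean))) {
    shm_mean <- setNames(rep(shm_mean, 8),
                         c("gut.IGA.eART", "gut.IGA.lART", "gut.IGG.eART",
                           "gut.IGG.lART", "blood.IGA.eART", "blood.IGA.lART",
                           "blood.IGG.eART", "blood.IGG.lART"))
  }
  cfg <- list(seed = as.integer(seed), n_clones = as.integer(n_clones),
              clone_size_exponent = clone_size_exponent, shm_mean = shm_mean,
              isotype_mix = isotype_mix,
              shared_clone_fraction = shared_clone_fraction,
              polyreactive_fraction = polyreactive_fraction,
              read_error_rate = read_error_rate,
              read_length = as.integer(read_length),
              fragment_overlap = fragment_overlap,
              n_members_mean = n_members_mean,
              shared_mutation_fraction = shared_mutation_fraction,
              n_donors = as.integer(n_donors))
  probs <- c(unlist(cfg$isotype_mix), cfg$shared_clone_fraction,
             cfg$polyreactive_fraction, cfg$read_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$shm_mean < 0)) stop("shm_mean must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# non-stop codons, computed from the standard code
nonstop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# discrete power law P(k) proportional to k^-alpha on 1..kmax
rpowerlaw <- function(n, alpha, kmax = 1000L) {
  p <- (1:kmax)^(-alpha)
  sample.int(kmax, n, replace = TRUE, prob = p)
}

# random productive junction of len_aa codons
random_junction <- function(len_aa, codons) {
  paste(sample(codons, len_aa, replace = TRUE), collapse = "")
}

# amino-acid identity between two equal-length junctions
junction_aa_identity <- function(a, b) {
  aa <- translate_nt(a); ab <- translate_nt(b)
  mean(strsplit(aa, "")[[1]] == strsplit(ab, "")[[1]])
}

#' Simulate gut and blood repertoires with ground truth
#'
#' For each (group, compartment), `n_clones` clonal lineages are drawn: a
#' random V and J allele, a random productive junction (3-20 codons), an
#' isotype from the compartment mix, and a polyreactivity flag. Each clone
#' emits 1 + Poisson members; each member carries a Poisson(stratum mean)
#' number of V substitutions, split between clone-shared lineage positions
#' and member-private positions (anchor codons are never mutated, so the
#' clean-limit extraction is exact by construction). Gut clones seed the
#' blood with the per-group sharing probability; blood members of a shared
#' clone carry a junction variant within 10% amino-acid divergence.
#'
#' Junctions are rejection-sampled to be < 70% identical to any existing
#' junction in the same (V gene, J gene, length) bucket, so the generative
#' partition is identifiable by the 0.8 clonal and 0.9 sharing rules.
#'
#' @param config a [sim_config()].
#' @param reference germline reference (default: builtin toy set).
#' @return list of class `"sim_repertoire"` with elements `clones` (one row
#'   per clone), `truth` (one row per unique member sequence, every label
#'   recorded) and `config`.
#' @export
simulate_repertoire <- function(config = sim_config(),
                                reference = load_germline_reference("builtin")) {
  set.seed(config$seed)
  codons <- nonstop_codons()
  vtab <- germline_v(reference)
  jtab <- germline_j(reference)
  ctab <- germline_c(reference)
  cseq <- setNames(ctab$sequence, ctab$isotype_label)

  junction_registry <- new.env(parent = emptyenv())
  draw_junction <- function(v_gene, j_gene) {
    repeat {
      len_aa <- sample(3:20, 1)
      jx <- random_junction(len_aa, codons)
      key <- paste(v_gene, j_gene, len_aa, sep = "|")
      seen <- junction_registry[[key]]
      ok <- TRUE
      if (!is.null(seen)) {
        for (s in seen) {
          if (junction_aa_identity(jx, s) >= 0.7) { ok <- FALSE; break }
        }
      }
      if (ok) {
        junction_registry[[key]] <- c(seen, jx)
        return(jx)
      }
    }
  }

  # junction variant with at most floor(0.1 * len_aa) aa substitutions
  variant_junction <- function(junction, codons) {
    len_aa <- nchar(junction) / 3
    kmax <- floor(0.1 * len_aa)
    k <- if (kmax > 0) sample(0:kmax, 1) else 0L
    if (k == 0) return(junction)
    cod <- substring(junction, seq(1, nchar(junction), 3),
                     seq(3, nchar(junction), 3))
    idx <- sample(len_aa, k)
    for (i in idx) {
      aa_old <- Biostrings::GENETIC_CODE[[cod[i]]]
      repeat {
        cand <- sample(codons, 1)
        if (Biostrings::GENETIC_CODE[[cand]] != aa_old) { cod[i] <- cand; break }
      }
    }
    paste(cod, collapse = "")
  }

  groups <- c("eART", "lART")
  clone_rows <- list(); member_rows <- list()
  clone_n <- 0L

  # members are generated as plain column vectors (one list per clone) and
  # assembled into the truth table once at the end
  make_members <- function(clone, compartment, n_members, shm_mean_val,
                           junction_nt) {
    vseq <- vtab$sequence[vtab$name == clone$v_call]
    cys <- vtab$cys104_offset[vtab$name == clone$v_call]
    shared_pool <- clone$shared_positions[[1]]
    shared_bases <- clone$shared_bases[[1]]
    jseq <- jtab$sequence[jtab$name == clone$j_call]
    const <- cseq[[clone$isotype]]
    vg <- strsplit(vseq, "")[[1]]
    seqs <- character(n_members); muts <- integer(n_members)
    for (mi in seq_len(n_members)) {
      m <- min(rpois(1, shm_mean_val), cys)
      n_shared <- min(m, length(shared_pool))
      pos <- shared_pool[seq_len(n_shared)]
      bases <- shared_bases[seq_len(n_shared)]
      if (m > n_shared) {
        extra <- sample(setdiff(seq_len(cys), shared_pool), m - n_shared)
        ebases <- vapply(extra, function(p) {
          sample(setdiff(DNA_BASES, vg[p]), 1)
        }, character(1))
        pos <- c(pos, extra); bases <- c(bases, ebases)
      }
      vmut <- vg
      if (m > 0) vmut[pos] <- bases
      # functional selection: expressed memory sequences carry no stop
      # codons, so mutated bases creating an in-frame stop are resampled
      # (position stays mutated; only the target base changes)
      if (m > 0) {
        for (iter in 1:50) {
          aa <- translate_nt(paste(vmut, collapse = ""))
          stops <- which(strsplit(aa, "")[[1]] == "*")
          if (length(stops) == 0) break
          for (sc in stops) {
            cod_pos <- (3 * (sc - 1) + 1):(3 * sc)
            mut_here <- intersect(pos, cod_pos)
            p <- mut_here[1]
            vmut[p] <- sample(setdiff(DNA_BASES, c(vg[p], vmut[p])), 1)
          }
        }
      }
      seqs[mi] <- paste0(paste(vmut, collapse = ""), junction_nt, jseq, const)
      muts[mi] <- m
    }
    list(sequence_id = sprintf("%s_%s_c%05d_m%03d", clone$group, compartment,
                               clone$clone_idx, seq_len(n_members)),
         donor = rep(clone$donor, n_members),
         group = rep(clone$group, n_members),
         compartment = rep(compartment, n_members),
         isotype = rep(clone$isotype, n_members),
         clone_id = rep(clone$clone_id, n_members),
         v_call = rep(clone$v_call, n_members),
         j_call = rep(clone$j_call, n_members),
         junction = rep(junction_nt, n_members),
         junction_aa = rep(translate_nt(junction_nt), n_members),
         n_mutations = muts,
         duplicate_count = rpowerlaw(n_members, config$clone_size_exponent),
         polyreactive = rep(clone$polyreactive, n_members),
         sequence = seqs)
  }

  for (g in groups) {
    donors <- sprintf("%s%d", substr(g, 1, 1), seq_len(config$n_donors))
    for (comp in c("gut", "blood")) {
      mix <- config$isotype_mix[[comp]]
      for (ci in seq_len(config$n_clones)) {
        clone_n <- clone_n + 1L
        vi <- sample(nrow(vtab), 1); ji <- sample(nrow(jtab), 1)
        iso <- sample(names(mix), 1, prob = mix)
        v_gene <- gene_of(vtab$name[vi]); j_gene <- gene_of(jtab$name[ji])
        junction_nt <- draw_junction(v_gene, j_gene)
        cys <- vtab$cys104_offset[vi]
        # clone-shared lineage mutations: positions and target bases fixed once
        n_sh <- rpois(1, config$shared_mutation_fraction *
                        mean(config$shm_mean))
        sh_pos <- sample(cys, min(n_sh, cys))
        vchars <- strsplit(vtab$sequence[vi], "")[[1]]
        sh_bases <- vapply(sh_pos, function(p) {
          sample(setdiff(DNA_BASES, vchars[p]), 1)
        }, character(1))
        clone <- list(clone_id = sprintf("%s_%s_T%05d", g, comp, clone_n),
                      clone_idx = clone_n, group = g,
                      donor = sample(donors, 1),
                      v_call = vtab$name[vi], j_call = jtab$name[ji],
                      isotype = iso, junction = junction_nt,
                      polyreactive = runif(1) < config$polyreactive_fraction[[g]],
                      shared_positions = list(sh_pos),
                      shared_bases = list(sh_bases))
        n_members <- 1L + rpois(1, config$n_members_mean - 1)
        key <- paste(comp, iso, g, sep = ".")
        members <- make_members(clone, comp, n_members,
                                config$shm_mean[[key]], junction_nt)
        compartments <- comp
        # gut clones may also seed the blood
        if (comp == "gut" && runif(1) < config$shared_clone_fraction[[g]]) {
          blood_junction <- variant_junction(junction_nt, codons)
          key_b <- paste("blood", iso, g, sep = ".")
          n_b <- 1L + rpois(1, config$n_members_mean - 1)
          blood_members <- make_members(clone, "blood", n_b,
                                        config$shm_mean[[key_b]],
                                        blood_junction)
          members <- mapply(c, members, blood_members, SIMPLIFY = FALSE)
          compartments <- c("gut", "blood")
        }
        clone_rows[[clone_n]] <- list(
          clone_id = clone$clone_id, group = g, donor = clone$donor,
          home_compartment = comp,
          compartments = paste(compartments, collapse = ","),
          v_call = clone$v_call, j_call = clone$j_call,
          junction = junction_nt, isotype = iso,
          polyreactive = clone$polyreactive,
          n_members = length(members$sequence_id))
        member_rows[[clone_n]] <- members
      }
    }
  }

  bind_lists <- function(rows) {
    cols <- lapply(names(rows[[1]]), function(nm) {
      unlist(lapply(rows, `[[`, nm), use.names = FALSE)
    })
    names(cols) <- names(rows[[1]])
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  truth <- bind_lists(member_rows)
  out <- list(clones = bind_lists(clone_rows), truth = truth,
              config = config)
  class(out) <- "sim_repertoire"
  out
}

#' Write per-compartment FASTA files for a simulated repertoire
#'
#' @param sim a [simulate_repertoire()] result.
#' @param dir output directory.
#' @return named vector of written paths.
#' @export
write_sim_fasta <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (comp in unique(sim$truth$compartment)) {
    sub <- sim$truth[sim$truth$compartment == comp, ]
    p <- file.path(dir, paste0(comp, ".fasta"))
    write_fasta(data.frame(id = sub$sequence_id, sequence = sub$sequence), p)
    paths[comp] <- p
  }
  paths
}

#' Emit simulated paired-end reads
#'
#' R1 is the 5' read of each member sequence, R2 the reverse complement of
#' its 3' end. Per-base substitution errors occur at `config$read_error_rate`;
#' bases carrying an error receive lower Phred scores (8-25) than correct
#' bases (33-40). A forced `fragment_overlap` below 10 nt warns, since the
#' merger will drop such pairs.
#'
#' @param truth truth table from [simulate_repertoire()] (or the sim object).
#' @param config the [sim_config()] used.
#' @param r1_path,r2_path output FASTQ paths.
#' @return invisibly, c(r1_path, r2_path).
#' @export
emit_paired_reads <- function(truth, config, r1_path, r2_path) {
  if (inherits(truth, "sim_repertoire")) truth <- truth$truth
  ov <- config$fragment_overlap
  if (!is.null(ov) && ov < 10) {
    warning("fragment_overlap < 10: the merger will drop these pairs")
  }
  n <- nrow(truth)
  s1 <- character(n); s2 <- character(n)
  q1 <- vector("list", n); q2 <- vector("list", n)
  add_errors <- function(s) {
    q <- sample(33:40, nchar(s), replace = TRUE)
    if (config$read_error_rate > 0) {
      err <- which(runif(nchar(s)) < config$read_error_rate)
      if (length(err) > 0) {
        ch <- strsplit(s, "")[[1]]
        ch[err] <- vapply(ch[err], function(b) sample(setdiff(DNA_BASES, b), 1),
                          character(1))
        s <- paste(ch, collapse = "")
        q[err] <- sample(8:25, length(err), replace = TRUE)
      }
    }
    list(seq = s, qual = q)
  }
  for (i in seq_len(n)) {
    tmpl <- truth$sequence[i]
    L <- nchar(tmpl)
    rl <- if (is.null(ov)) min(config$read_length, L)
          else min(L, ceiling((L + ov) / 2))
    e1 <- add_errors(substr(tmpl, 1, rl))
    e2 <- add_errors(revcomp(substr(tmpl, L - rl + 1, L)))
    s1[i] <- e1$seq; q1[[i]] <- e1$qual
    s2[i] <- e2$seq; q2[[i]] <- e2$qual
  }
  write_fastq(data.frame(id = paste0(truth$sequence_id, "/1"), sequence = s1,
                         qualities = I(q1), stringsAsFactors = FALSE), r1_path)
  write_fastq(data.frame(id = paste0(truth$sequence_id, "/2"), sequence = s2,
                         qualities = I(q2), stringsAsFactors = FALSE), r2_path)
  invisible(c(r1_path, r2_path))
}
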