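# Dereplication, clonal family inference and single-nucleotide mutation
# networks.

#' Dereplicate sequences at 99% identity
#'
#' Greedy incremental clustering: records are processed in decreasing
#' (duplicate_count, length, id) order; a record joins the first cluster
#' (in creation order) whose seed it matches at >= `threshold` global
#' identity (matches / alignment length of a global alignment, match +1,
#' mismatch -1, gap -2), otherwise it opens a new cluster. The seed is the
#' cluster representative; duplicate counts are summed.
#'
#' @param records data.frame with `sequence`, an id column (`sequence_id`
#'   or `id`) and optionally `duplicate_count`.
#' @param threshold identity threshold (default 0.99).
#' @return representatives data.frame (seed rows with summed
#'   `duplicate_count`); the id -> representative map is attached as
#'   attribute `"cluster_map"`.
#' @export
dereplicate_99 <- function(records, threshold = 0.99) {
  idcol <- if ("sequence_id" %in% names(records)) "sequence_id" else "id"
  if (!"duplicate_count" %in% names(records)) records$duplicate_count <- 1L
  ord <- order(-records$duplicate_count, -nchar(records$sequence),
               records[[idcol]])
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)
  seq_v <- records$sequence
  len_v <- nchar(seq_v)
  seed_idx <- integer(0)          # row indices of cluster seeds
  assign_to <- integer(n)         # cluster index per row
  for (i in seq_len(n)) {
    hit <- 0L
    for (ci in seq_along(seed_idx)) {
      s <- seed_idx[ci]
      if (min(len_v[i], len_v[s]) / max(len_v[i], len_v[s]) < threshold) next
      if (cpp_identity_at_least(seq_v[i], seq_v[s], threshold)) {
        hit <- ci; break
      }
    }
    if (hit == 0L) {
      seed_idx <- c(seed_idx, i)
      assign_to[i] <- length(seed_idx)
    } else {
      assign_to[i] <- hit
    }
  }
  reps <- records[seed_idx, , drop = FALSE]
  reps$duplicate_count <- as.integer(
    tapply(records$duplicate_count, assign_to, sum)[as.character(seq_along(seed_idx))])
  rownames(reps) <- NULL
  attr(reps, "cluster_map") <- data.frame(
    id = records[[idcol]],
    representative_id = records[[idcol]][seed_idx][assign_to],
    stringsAsFactors = FALSE)
  reps
}

#' Global-alignment identity between two sequences
#'
#' Matches divided by alignment length of the optimal global alignment
#' (match +1, mismatch -1, gap -2, diagonal-preferring traceback); the
#' identity the dereplication threshold is applied to.
#'
#' @param a,b nucleotide strings.
#' @return identity in [0, 1].
#' @export
seq_identity <- function(a, b) {
  r <- cpp_identity(a, b)
  r[["matches"]] / r[["aln_length"]]
}

#' Infer clonal families
#'
#' Sequences are bucketed by (V gene, J gene, CDR-H3 amino-acid length),
#' allele suffixes stripped; within a bucket, records are linked when their
#' CDR-H3 amino-acid identity (matches / length) is at least `threshold`,
#' and families are the connected components (single linkage). Family ids
#' are content hashes of the sorted member ids, so the output is invariant
#' to input order.
#'
#' @param records annotated, QC-passed rearrangement data.frame (needs
#'   `sequence_id`, `v_call`, `j_call`, `junction_aa`, `duplicate_count`).
#' @param threshold CDR-H3 identity cutoff (default 0.8).
#' @return data.frame of families: `family_id`, `v_gene`, `j_gene`,
#'   `cdr3_length_aa`, `n_members`, `total_duplicates`,
#'   `representative_id`, and a list column `members` of member sequence
#'   ids. The id -> family map is attached as attribute `"family_map"`.
#' @export
infer_clonal_families <- function(records, threshold = 0.8) {
  if (!"duplicate_count" %in% names(records)) records$duplicate_count <- 1L
  keep <- !is.na(records$junction_aa) & !is.na(records$v_call) &
    !is.na(records$j_call)
  records <- records[keep, , drop = FALSE]
  v_gene <- gene_of(records$v_call)
  j_gene <- gene_of(records$j_call)
  len <- nchar(records$junction_aa)
  bucket <- paste(v_gene, j_gene, len, sep = "|")
  fam_rows <- list(); map_id <- character(0); map_fam <- character(0)
  for (b in unique(bucket)) {
    idx <- which(bucket == b)
    nb <- length(idx)
    comp <- seq_len(nb)
    if (nb > 1) {
      # union-find over >= threshold pairs
      find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
      aa <- records$junction_aa[idx]
      L <- len[idx[1]]
      for (p in 1:(nb - 1)) for (q in (p + 1):nb) {
        if ((L - cpp_hamming(aa[p], aa[q])) / L >= threshold) {
          rp <- find(p); rq <- find(q)
          if (rp != rq) comp[min(rp, rq)] <- comp[max(rp, rq)] <- min(rp, rq)
        }
      }
      comp <- vapply(seq_len(nb), find, integer(1))
    }
    for (cc in unique(comp)) {
      sel <- idx[comp == cc]
      ids <- sort(records$sequence_id[sel])
      fid <- paste0("F", cpp_fnv1a(paste(ids, collapse = ";")))
      dup <- records$duplicate_count[sel]
      rep_id <- records$sequence_id[sel][order(-dup, records$sequence_id[sel])][1]
      fam_rows[[length(fam_rows) + 1]] <- data.frame(
        family_id = fid, v_gene = v_gene[sel[1]], j_gene = j_gene[sel[1]],
        cdr3_length_aa = len[sel[1]], n_members = length(sel),
        total_duplicates = sum(dup), representative_id = rep_id,
        stringsAsFactors = FALSE)
      fam_rows[[length(fam_rows)]]$members <- list(ids)
      map_id <- c(map_id, records$sequence_id[sel])
      map_fam <- c(map_fam, rep(fid, length(sel)))
    }
  }
  fams <- do.call(rbind, fam_rows)
  fams <- fams[order(fams$v_gene, fams$j_gene, fams$cdr3_length_aa,
                     fams$family_id), , drop = FALSE]
  rownames(fams) <- NULL
  attr(fams, "family_map") <- setNames(map_fam, map_id)
  fams
}

#' Build a single-nucleotide clone network
#'
#' Vertices are unique sequences sized by duplicate count; edges connect
#' pairs of equal-length sequences differing by exactly one (non-indel)
#' nucleotide. Components and per-vertex mean mutation counts are
#' reported.
#'
#' @param records dereplicated rearrangement data.frame (needs
#'   `sequence_id`, `sequence`, `duplicate_count`; `vh_mutation_count`
#'   used when present).
#' @return list of class `"clone_network"`: `graph` (igraph), `vertices`,
#'   `edges`, `components` data.frames.
#' @export
build_clone_network <- function(records) {
  if (!"duplicate_count" %in% names(records)) records$duplicate_count <- 1L
  if (anyDuplicated(records$sequence)) {
    stop("records must be dereplicated (unique sequences)")
  }
  n <- nrow(records)
  lens <- nchar(records$sequence)
  edge_list <- list()
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (length(idx) < 2) next
    pr <- cpp_hamming1_pairs(records$sequence[idx])
    if (nrow(pr) > 0) {
      edge_list[[length(edge_list) + 1]] <- cbind(idx[pr[, 1]], idx[pr[, 2]])
    }
  }
  edges <- if (length(edge_list) > 0) do.call(rbind, edge_list) else
    matrix(integer(0), 0, 2)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = records$sequence_id)
  g <- igraph::set_vertex_attr(g, "size", value = records$duplicate_count)
  if ("vh_mutation_count" %in% names(records)) {
    g <- igraph::set_vertex_attr(g, "mutations",
                                 value = records$vh_mutation_count)
  }
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  vertices <- data.frame(sequence_id = records$sequence_id,
                         size = records$duplicate_count,
                         component = memb, stringsAsFactors = FALSE)
  if ("vh_mutation_count" %in% names(records)) {
    vertices$mutations <- records$vh_mutation_count
  }
  edges_df <- data.frame(
    from = records$sequence_id[edges[, 1]],
    to = records$sequence_id[edges[, 2]], stringsAsFactors = FALSE)
  comp_df <- do.call(rbind, lapply(split(vertices, vertices$component),
    function(v) data.frame(component = v$component[1], n_vertices = nrow(v),
                           total_duplicates = sum(v$size),
                           max_vertex = max(v$size))))
  rownames(comp_df) <- NULL
  structure(list(graph = g, vertices = vertices, edges = edges_df,
                 components = comp_df), class = "clone_network")
}

#' Export a clone network
#'
#' @param network a [build_clone_network()] result.
#' @param graphml_path,edges_path output paths (either may be NULL).
#' @export
export_clone_network <- function(network, graphml_path = NULL,
                                 edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(network)
}

#' Power-law exponent of a clone-size distribution
#'
#' Continuous maximum-likelihood approximation for discrete data:
#' alpha = 1 + n / sum(log(x / (xmin - 0.5))).
#'
#' @param sizes positive integer clone sizes.
#' @param xmin smallest size included in the fit.
#' @return estimated exponent.
#' @export
powerlaw_exponent <- function(sizes, xmin = 1L) {
  x <- sizes[sizes >= xmin]
  1 + length(x) / sum(log(x / (xmin - 0.5)))
}

#' Per-group clonal expansion summary
#'
#' @param records data.frame with `group`, `isotype`, a clone label column
#'   `family_id`, `duplicate_count` and `vh_mutation_count`.
#' @param size_cut clone size (total duplicates) defining "expanded".
#' @return data.frame, one row per (group, isotype): number of clones,
#'   clone-size quantiles, fraction of sequences in clones of size >=
#'   `size_cut`, mean mutation load in singleton vs expanded clones, and
#'   the fitted power-law exponent of the clone-size distribution.
#' @export
expansion_summary <- function(records, size_cut = 2L) {
  rows <- list()
  for (g in unique(records$group)) for (iso in unique(records$isotype)) {
    sub <- records[records$group == g & records$isotype == iso, ,
                   drop = FALSE]
    if (nrow(sub) == 0) next
    clone_sizes <- tapply(sub$duplicate_count, sub$family_id, sum)
    total <- sum(sub$duplicate_count)
    in_big <- sum(clone_sizes[clone_sizes >= size_cut])
    expanded <- names(clone_sizes)[clone_sizes >= size_cut]
    mut_singleton <- mean(sub$vh_mutation_count[!sub$family_id %in% expanded])
    mut_expanded <- mean(sub$vh_mutation_count[sub$family_id %in% expanded])
    qs <- quantile(clone_sizes, c(0.5, 0.9, 1))
    rows[[length(rows) + 1]] <- data.frame(
      group = g, isotype = iso, n_clones = length(clone_sizes),
      size_q50 = unname(qs[1]), size_q90 = unname(qs[2]),
      size_max = unname(qs[3]),
      frac_in_expanded = in_big / total,
      mean_mut_singleton = mut_singleton, mean_mut_expanded = mut_expanded,
      powerlaw_alpha = powerlaw_exponent(as.integer(clone_sizes)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
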