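# Detection of mucosal monoclonal antibody sequences inside bulk blood
# repertoires, and group-wise sharing statistics.

#' Find mucosal mAb sequences shared with an NGS repertoire
#'
#' A monoclonal antibody matches an NGS record iff both carry the same V
#' gene and J gene (allele suffixes stripped), their CDR-H3s have equal
#' amino-acid length, and the CDR-H3 identity (matches / length) is at
#' least `min_identity`. Isotype is not part of the rule: shared clones
#' may appear under either isotype.
#'
#' @param mab_table data.frame with `mab_id`, `v_call` (or `v_gene`),
#'   `j_call` (or `j_gene`), `cdr3_aa`, and optionally `isotype`,
#'   `polyreactive`.
#' @param ngs_records annotated rearrangement data.frame (needs
#'   `sequence_id`, `v_call`, `j_call`, `junction_aa`; `compartment` used
#'   when present).
#' @param min_identity CDR-H3 identity threshold (default 0.9).
#' @return data.frame, one row per mAb with at least one match: `mab_id`,
#'   `v_gene`, `j_gene`, `cdr3_aa`, `n_matches`, `best_identity`,
#'   `match_ids` (comma separated), plus `isotype`/`polyreactive` when
#'   supplied. All (mab, ngs) links with identities are attached as
#'   attribute `"links"`.
#' @export
find_shared <- function(mab_table, ngs_records, min_identity = 0.9) {
  vg <- if ("v_gene" %in% names(mab_table)) mab_table$v_gene else
    gene_of(mab_table$v_call)
  jg <- if ("j_gene" %in% names(mab_table)) mab_table$j_gene else
    gene_of(mab_table$j_call)
  no_cdr3 <- is.na(mab_table$cdr3_aa) | mab_table$cdr3_aa == ""
  if (any(no_cdr3)) {
    warning("skipping ", sum(no_cdr3), " mAb(s) lacking a CDR-H3: ",
            paste(mab_table$mab_id[no_cdr3], collapse = ", "))
  }
  ngs_ok <- !is.na(ngs_records$junction_aa)
  ngs <- ngs_records[ngs_ok, , drop = FALSE]
  ngs_key <- paste(gene_of(ngs$v_call), gene_of(ngs$j_call),
                   nchar(ngs$junction_aa), sep = "|")
  ngs_split <- split(seq_len(nrow(ngs)), ngs_key)
  rows <- list(); links <- list()
  for (i in which(!no_cdr3)) {
    cdr3 <- mab_table$cdr3_aa[i]
    key <- paste(vg[i], jg[i], nchar(cdr3), sep = "|")
    cand <- ngs_split[[key]]
    if (is.null(cand)) next
    ident <- vapply(cand, function(ci) {
      (nchar(cdr3) - cpp_hamming(cdr3, ngs$junction_aa[ci])) / nchar(cdr3)
    }, numeric(1))
    hit <- ident >= min_identity
    if (!any(hit)) next
    match_idx <- cand[hit]
    rows[[length(rows) + 1]] <- data.frame(
      mab_id = mab_table$mab_id[i], v_gene = vg[i], j_gene = jg[i],
      cdr3_aa = cdr3,
      isotype = mab_table$isotype[i] %||% NA_character_,
      polyreactive = mab_table$polyreactive[i] %||% NA,
      n_matches = length(match_idx), best_identity = max(ident[hit]),
      match_ids = paste(ngs$sequence_id[match_idx], collapse = ","),
      stringsAsFactors = FALSE)
    links[[length(links) + 1]] <- data.frame(
      mab_id = mab_table$mab_id[i], ngs_id = ngs$sequence_id[match_idx],
      identity = ident[hit],
      compartment = if ("compartment" %in% names(ngs))
        ngs$compartment[match_idx] else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(mab_id = character(0), v_gene = character(0),
               j_gene = character(0), cdr3_aa = character(0),
               isotype = character(0), polyreactive = logical(0),
               n_matches = integer(0), best_identity = numeric(0),
               match_ids = character(0), stringsAsFactors = FALSE)
  attr(out, "links") <- if (length(links) > 0) do.call(rbind, links) else
    data.frame(mab_id = character(0), ngs_id = character(0),
               identity = numeric(0), compartment = character(0),
               stringsAsFactors = FALSE)
  out
}

#' Compare sharing frequencies between groups
#'
#' @param shared_a,n_a shared count and panel size for the first group.
#' @param shared_b,n_b same for the second group.
#' @return list: `freq_a`, `freq_b` (percent), `p` (two-sided Fisher).
#' @export
sharing_frequency_test <- function(shared_a, n_a, shared_b, n_b) {
  if (n_a == 0 || n_b == 0) stop("group size must be positive")
  list(freq_a = 100 * shared_a / n_a, freq_b = 100 * shared_b / n_b,
       p = fisher_exact_2x2(shared_a, n_a - shared_a,
                            shared_b, n_b - shared_b))
}

#' Export sharing links as a Circos-style table
#'
#' One row per (mAb, matched NGS sequence) link, sorted by mab_id then
#' ngs_id; columns: source_compartment, mab_id, target_compartment,
#' ngs_id, identity.
#'
#' @param shared a [find_shared()] result.
#' @param path output TSV path.
#' @param source_compartment compartment of the mAb panel (default "gut").
#' @export
export_sharing_links <- function(shared, path, source_compartment = "gut") {
  links <- attr(shared, "links")
  out <- data.frame(source_compartment = rep(source_compartment,
                                             nrow(links)),
                    mab_id = links$mab_id,
                    target_compartment = links$compartment,
                    ngs_id = links$ngs_id,
                    identity = links$identity, stringsAsFactors = FALSE)
  out <- out[order(out$mab_id, out$ngs_id), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
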