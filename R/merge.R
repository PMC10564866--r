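# Paired-end merging and the four-filter quality control step.

#' Merge parameters
#'
#' Defaults mirror the stated amplicon pipeline settings: 10 overlapping
#' nucleotides minimum, minimum merged length 300 and quality threshold 20
#' for terminal trimming.
#'
#' @param min_overlap minimum acceptable read overlap (nt).
#' @param min_length minimum merged (and trimmed) sequence length.
#' @param quality_threshold Phred threshold for terminal trimming.
#' @param max_overlap_mismatch_rate maximum mismatch fraction tolerated in
#'   the overlap.
#' @export
merge_params <- function(min_overlap = 10L, min_length = 300L,
                         quality_threshold = 20L,
                         max_overlap_mismatch_rate = 0.25) {
  stopifnot(min_overlap >= 1)
  list(min_overlap = as.integer(min_overlap),
       min_length = as.integer(min_length),
       quality_threshold = as.integer(quality_threshold),
       max_overlap_mismatch_rate = max_overlap_mismatch_rate)
}

#' QC filter parameters
#'
#' @param evalue_max maximum tolerated V-gene alignment E-value (default
#'   1e-3).
#' @param subject_start_max maximum tolerated 1-based start position of the
#'   V alignment in the germline (default 9).
#' @export
qc_params <- function(evalue_max = 1e-3, subject_start_max = 9L) {
  stopifnot(evalue_max > 0)
  list(evalue_max = evalue_max,
       subject_start_max = as.integer(subject_start_max))
}

strip_pair_suffix <- function(id) sub("[/ ._][12]$", "", id)

#' Merge paired-end reads
#'
#' For each pair the reverse read is reverse complemented and the overlap
#' offset maximizing matches is chosen among overlaps of at least
#' `min_overlap` nt with mismatch rate at most `max_overlap_mismatch_rate`.
#' In the overlap the base with the higher quality wins (tie: forward
#' read), and its quality is the maximum of the two. Terminal bases with
#' quality below `quality_threshold` are trimmed from both ends; merged
#' sequences shorter than `min_length` are discarded.
#'
#' @param r1,r2 data.frames from [read_fastq()]; paired by order, ids must
#'   agree after stripping a trailing pair suffix.
#' @param params a [merge_params()] list.
#' @return list with `merged` (data.frame id/sequence/qualities) and
#'   `report` (input, merged, discarded_overlap, discarded_length counts).
#' @export
merge_pairs <- function(r1, r2, params = merge_params()) {
  if (nrow(r1) != nrow(r2)) stop("R1/R2 streams differ in length")
  ids1 <- strip_pair_suffix(r1$id); ids2 <- strip_pair_suffix(r2$id)
  bad <- which(ids1 != ids2)
  if (length(bad) > 0) {
    stop("unpaired read id at record ", bad[1], ": '", r1$id[bad[1]],
         "' vs '", r2$id[bad[1]], "'")
  }
  n <- nrow(r1)
  out_id <- character(n); out_seq <- character(n)
  out_q <- vector("list", n); keep <- logical(n)
  n_ov <- 0L; n_len <- 0L
  for (i in seq_len(n)) {
    s1 <- r1$sequence[i]; q1 <- r1$qualities[[i]]
    s2 <- revcomp(r2$sequence[i]); q2 <- rev(r2$qualities[[i]])
    hit <- cpp_find_overlap(s1, s2, params$min_overlap,
                            params$max_overlap_mismatch_rate)
    if (hit$overlap < 0) { n_ov <- n_ov + 1L; next }
    ov <- hit$overlap
    l1 <- nchar(s1); l2 <- nchar(s2)
    c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
    left_n <- l1 - ov
    ov1 <- c1[(left_n + 1):l1]; ov2 <- c2[1:ov]
    ovq1 <- q1[(left_n + 1):l1]; ovq2 <- q2[1:ov]
    take2 <- ovq2 > ovq1                      # tie -> R1 base
    cons <- ifelse(take2, ov2, ov1)
    consq <- pmax(ovq1, ovq2)
    seq_m <- c(if (left_n > 0) c1[1:left_n], cons,
               if (l2 > ov) c2[(ov + 1):l2])
    q_m <- c(if (left_n > 0) q1[1:left_n], consq,
             if (l2 > ov) q2[(ov + 1):l2])
    # terminal quality trimming, both ends
    good <- q_m >= params$quality_threshold
    if (!any(good)) { n_len <- n_len + 1L; next }
    from <- which(good)[1]; to <- tail(which(good), 1)
    seq_m <- seq_m[from:to]; q_m <- q_m[from:to]
    if (length(seq_m) < params$min_length) { n_len <- n_len + 1L; next }
    keep[i] <- TRUE
    out_id[i] <- ids1[i]
    out_seq[i] <- paste(seq_m, collapse = "")
    out_q[[i]] <- q_m
  }
  merged <- data.frame(id = out_id[keep], sequence = out_seq[keep],
                       qualities = I(out_q[keep]), stringsAsFactors = FALSE)
  list(merged = merged,
       report = list(input = n, merged = sum(keep),
                     discarded_overlap = n_ov, discarded_length = n_len))
}

QC_FLAGS <- c("stop_codon", "evalue_fail", "cdr3_motif_fail",
              "subject_start_fail")

#' Apply the four quality filters to annotated rearrangements
#'
#' A record is rejected iff any of: it is unproductive (stop codon in the
#' V-region reading frame), its V-gene E-value exceeds `evalue_max`, no
#' W-G-x-G motif bounds its CDR-H3, or the V alignment starts after
#' position `subject_start_max` in the germline. All triggered flags are
#' recorded; pass and reject partition the input.
#'
#' @param records annotated rearrangement data.frame (needs `productive`,
#'   `v_support`, `cdr3_motif_ok`, `v_germline_start`).
#' @param params a [qc_params()] list.
#' @return list with `pass`, `reject` (with `qc_flags` filled) and
#'   `report` of per-flag counts.
#' @export
apply_qc <- function(records, params = qc_params()) {
  need <- c("productive", "v_support", "cdr3_motif_ok", "v_germline_start")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records lack annotation fields: ", paste(miss, collapse = ", "))
  }
  flags <- cbind(
    stop_codon = !records$productive | is.na(records$productive),
    evalue_fail = is.na(records$v_support) | records$v_support > params$evalue_max,
    cdr3_motif_fail = !records$cdr3_motif_ok | is.na(records$cdr3_motif_ok),
    subject_start_fail = !is.na(records$v_germline_start) &
      records$v_germline_start > params$subject_start_max)
  rejected <- rowSums(flags) > 0
  records$qc_flags <- apply(flags, 1, function(f) {
    paste(QC_FLAGS[f], collapse = ",")
  })
  list(pass = records[!rejected, , drop = FALSE],
       reject = records[rejected, , drop = FALSE],
       report = list(input = nrow(records), pass = sum(!rejected),
                     reject = sum(rejected),
                     flag_counts = as.list(colSums(flags))))
}
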