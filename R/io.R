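# External formats: FASTQ, FASTA, AIRR-style rearrangement TSV, and the
# germline reference FASTA with key=value anchor annotations.

#' Read a FASTQ file (Phred+33)
#'
#' A strict 4-line-per-record reader. Malformed records (truncated block,
#' missing `@`/`+` markers, quality string length differing from the
#' sequence) raise an error naming the 1-based record index.
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `sequence` and a list column
#'   `qualities` of integer Phred scores.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(data.frame(id = character(0), sequence = character(0),
                      qualities = I(list())))
  }
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: truncated block at record ",
         length(lines) %/% 4 + 1)
  }
  n <- length(lines) %/% 4
  ids <- character(n); seqs <- character(n); quals <- vector("list", n)
  for (i in seq_len(n)) {
    block <- lines[(4 * i - 3):(4 * i)]
    if (!startsWith(block[1], "@")) {
      stop("malformed FASTQ: record ", i, " does not start with '@'")
    }
    if (!startsWith(block[3], "+")) {
      stop("malformed FASTQ: record ", i, " missing '+' separator")
    }
    if (nchar(block[4]) != nchar(block[2])) {
      stop("malformed FASTQ: quality length mismatch at record ", i)
    }
    ids[i] <- sub("^@", "", block[1])
    seqs[i] <- toupper(block[2])
    quals[[i]] <- phred_decode(block[4])
  }
  data.frame(id = ids, sequence = seqs, qualities = I(quals),
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param records data.frame with `id`, `sequence` and list column
#'   `qualities` (integer Phred scores per base).
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  qs <- vapply(records$qualities, phred_encode, character(1))
  out <- rbind(paste0("@", records$id), records$sequence, "+", qs)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Sequences are uppercased on read; duplicate ids and non-IUPAC characters
#' are errors.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id` (full description line) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  seqs <- toupper(as.character(ss))
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "", fixed = TRUE)[[1]] %in% IUPAC_CHARS)
  }, logical(1))
  if (any(bad)) {
    stop("non-IUPAC character in sequence(s): ",
         paste(ids[which(bad)], collapse = ", "))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# canonical column order for rearrangement tables; AIRR names are used where
# a matching schema field exists (junction, v_call, v_support, ...)
REARR_COLUMNS <- c(
  "sequence_id", "sequence", "productive", "v_call", "j_call", "c_call",
  "v_family", "j_family", "junction", "junction_aa", "cdr3_length_aa",
  "v_score", "v_bit_score", "v_support", "v_germline_start",
  "vh_mutation_count", "vh_mutation_freq", "duplicate_count",
  "donor", "group", "compartment", "cdr3_motif_ok", "qc_flags")

#' Write annotated rearrangements as an AIRR-style TSV
#'
#' One row per record; tab separated with a header row. Missing values are
#' serialized as empty strings, doubles at full precision so that
#' [read_rearrangements()] reproduces every field exactly.
#'
#' @param records rearrangement data.frame (see [annotate_rearrangements()]).
#' @param path output path.
#' @export
write_rearrangements <- function(records, path) {
  cols <- c(intersect(REARR_COLUMNS, names(records)),
            setdiff(names(records), REARR_COLUMNS))
  out <- records[, cols, drop = FALSE]
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      v <- sprintf("%.17g", out[[cn]])
      v[is.na(out[[cn]])] <- NA
      out[[cn]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a rearrangement TSV written by [write_rearrangements()]
#'
#' @param path TSV path.
#' @return data.frame with typed columns.
#' @export
read_rearrangements <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "", colClasses = "character")
  num_cols <- c("cdr3_length_aa", "v_score", "v_bit_score", "v_support",
                "v_germline_start", "vh_mutation_count", "vh_mutation_freq",
                "duplicate_count")
  int_cols <- c("cdr3_length_aa", "v_score", "v_germline_start",
                "vh_mutation_count", "duplicate_count")
  for (cn in intersect(num_cols, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  for (cn in intersect(int_cols, names(df))) df[[cn]] <- as.integer(df[[cn]])
  for (cn in intersect(c("productive", "cdr3_motif_ok"), names(df))) {
    df[[cn]] <- as.logical(df[[cn]])
  }
  if ("qc_flags" %in% names(df)) df$qc_flags[is.na(df$qc_flags)] <- ""
  if ("c_call" %in% names(df)) df$c_call[is.na(df$c_call)] <- ""
  df
}

#' Load a germline V/J/C reference set
#'
#' The reference is a FASTA whose description lines carry `key=value`
#' anchor annotations: `segment_type` (V/J/C); `cys104_offset` (0-based
#' nucleotide offset of the conserved CDR3-start cysteine codon, V only);
#' `fr4_motif_offset` (0-based offset of the codon starting the W-G-x-G
#' motif, J only); `isotype` (IGA/IGG, C only). `"builtin"` loads the
#' packaged synthetic toy reference.
#'
#' Validation enforces the anchor invariants: every V encodes Cys at its
#' anchor and translates without a stop codon up to it; every J carries
#' W-G-x-G at its motif offset.
#'
#' @param path FASTA path or `"builtin"`.
#' @return data.frame of segments with class `"germline_reference"`.
#' @export
load_germline_reference <- function(path = "builtin") {
  if (identical(path, "builtin")) {
    path <- system.file("extdata", "germline_toy.fasta", package = "repgut")
  }
  fa <- read_fasta(path)
  parse_kv <- function(desc) {
    toks <- strsplit(desc, "\\s+")[[1]]
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- sub("=.*$", "", kv)
    vals
  }
  name <- sub("\\s.*$", "", fa$id)
  if (anyDuplicated(name)) {
    stop("duplicate segment names in germline reference")
  }
  segs <- data.frame(name = name, sequence = fa$sequence,
                     segment_type = NA_character_, family = family_of(name),
                     cys104_offset = NA_integer_,
                     fr4_motif_offset = NA_integer_,
                     isotype_label = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(segs))) {
    kv <- parse_kv(fa$id[i])
    st <- kv[["segment_type"]]
    if (is.null(st) || !st %in% c("V", "J", "C")) {
      stop("segment ", name[i], ": missing or invalid segment_type")
    }
    segs$segment_type[i] <- st
    if (grepl("[^ACGT]", segs$sequence[i])) {
      stop("segment ", name[i], ": ambiguity characters not allowed in germline")
    }
    if (st == "V") {
      off <- kv["cys104_offset"]
      if (is.na(off)) stop("V segment ", name[i], " lacks cys104_offset")
      off <- as.integer(off)
      segs$cys104_offset[i] <- off
      codon <- substr(segs$sequence[i], off + 1, off + 3)
      if (!codon %in% c("TGT", "TGC")) {
        stop("V segment ", name[i], ": anchor codon '", codon,
             "' does not encode Cys")
      }
      aa <- translate_nt(substr(segs$sequence[i], 1, off + 3))
      if (grepl("*", aa, fixed = TRUE)) {
        stop("V segment ", name[i], ": stop codon upstream of Cys104")
      }
    } else if (st == "J") {
      off <- kv["fr4_motif_offset"]
      if (is.na(off)) stop("J segment ", name[i], " lacks fr4_motif_offset")
      off <- as.integer(off)
      segs$fr4_motif_offset[i] <- off
      aa <- translate_nt(substr(segs$sequence[i], off + 1, off + 12))
      if (nchar(aa) < 4 || substr(aa, 1, 1) != "W" ||
          substr(aa, 2, 2) != "G" || substr(aa, 4, 4) != "G") {
        stop("J segment ", name[i], ": no W-G-x-G motif at offset ", off)
      }
    } else {
      iso <- kv["isotype"]
      if (is.na(iso) || !iso %in% c("IGA", "IGG")) {
        stop("C segment ", name[i], ": isotype must be IGA or IGG")
      }
      segs$isotype_label[i] <- iso
    }
  }
  class(segs) <- c("germline_reference", "data.frame")
  segs
}

# convenience accessors
germline_v <- function(ref) ref[ref$segment_type == "V", , drop = FALSE]
germline_j <- function(ref) ref[ref$segment_type == "J", , drop = FALSE]
germline_c <- function(ref) ref[ref$segment_type == "C", , drop = FALSE]
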