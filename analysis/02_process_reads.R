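#!/usr/bin/env Rscript
# Stage 2: merge the paired-end reads (overlap >= 10 nt, min length 300,
# terminal quality trimming at Q20) and write the merged sequences.

library(repgut)

indir <- "results/sim"; outdir <- "results/processed"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

mg <- merge_pairs(read_fastq(file.path(indir, "reads_R1.fastq")),
                  read_fastq(file.path(indir, "reads_R2.fastq")))
write_fasta(data.frame(id = mg$merged$id, sequence = mg$merged$sequence),
            file.path(outdir, "merged.fasta"))
jsonlite::write_json(mg$report, file.path(outdir, "merge_report.json"),
                     auto_unbox = TRUE, pretty = TRUE)

with(mg$report, cat(sprintf(
  "merged %d/%d pairs (%d overlap failures, %d too short after trimming)\n",
  merged, input, discarded_overlap, discarded_length)))
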