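#!/usr/bin/env Rscript
# Stage 2: concatenate the per-gene alignments into nucleotide and
# amino-acid supermatrices and emit the partition definitions (by gene and
# by codon position).

library(coralphy)

gs <- coralphy:::read_gene_set("results/genes")
sm_nt <- concatenate(stats::setNames(lapply(gs$genes, `[[`, "nt"),
                                     gs$manifest$gene))
sm_aa <- concatenate(stats::setNames(lapply(gs$genes, `[[`, "aa"),
                                     gs$manifest$gene))

write_alignment(sm_nt$alignment, "results/supermatrix_nt.nex", "nexus")
write_alignment(sm_aa$alignment, "results/supermatrix_aa.nex", "nexus")
write_alignment(sm_nt$alignment, "results/supermatrix_nt.phy", "phylip")

for (sch in c("by_gene", "by_codon")) {
  ps <- build_partitions(sm_nt, sch)
  write_partitions(ps, sprintf("results/partitions_nt_%s.txt", sch),
                   "raxml", "DNA")
  write_partitions(ps, sprintf("results/partitions_nt_%s.nex", sch),
                   "nexus")
}
write_partitions(build_partitions(sm_aa, "by_gene"),
                 "results/partitions_aa_by_gene.txt", "raxml", "JTT")

message(sprintf("supermatrices: %d nt columns, %d aa columns, %d genes",
                n_columns(sm_nt$alignment), n_columns(sm_aa$alignment),
                length(sm_nt$charsets)))
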