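#!/usr/bin/env Rscript

## Simulate the study genome: 10 multi-exon genes whose 297 introns carry
## the curated donor-class quota (261 GT, 31 GA, 5 GG), with canonical
## AG|GTAAGT-biased donors, pyrimidine-tract AG acceptors, obligate
## exon-terminal AG before noncanonical introns, and 10 error-free
## junction-spanning reads per intron. Large FASTA/GFF3 artifacts go to
## scratch/sim/; a small per-gene truth summary goes to results/.

suppressMessages(library(gasplice))

dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

config <- sim_config(quota = c(GT = 261L, GC = 0L, GA = 31L, GG = 5L),
                     seed = 1L)
ds <- simulate_dataset(config)

write_genome(ds$genome, "scratch/sim/genome.fasta")
write_gene_models(ds$models, "scratch/sim/models.gff3")
write_genome(ds$reads, "scratch/sim/reads.fasta")
write.table(ds$truth, "scratch/sim/truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ds$provenance, "scratch/sim/read_provenance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d scaffolds, %d nt total\n", length(ds$genome),
            sum(Biostrings::width(ds$genome))))
cat(sprintf("planted: %d introns over %d genes; %d reads\n",
            nrow(ds$truth), length(ds$models), length(ds$reads)))

per_gene <- do.call(rbind, lapply(split(ds$truth, ds$truth$gene_id),
  function(d) data.frame(
    gene_id = d$gene_id[1], introns = nrow(d),
    GT = sum(d$donor_class == "GT"), GC = sum(d$donor_class == "GC"),
    GA = sum(d$donor_class == "GA"), GG = sum(d$donor_class == "GG"))))
print(per_gene, row.names = FALSE)
write.table(per_gene, "results/simulated_truth_per_gene.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote scratch/sim/* and results/simulated_truth_per_gene.tsv\n")
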