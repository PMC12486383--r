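#!/usr/bin/env Rscript
## Simulate the synthetic vertebrate world: an outgroup without genome
## duplications, two lamprey-like species (1R then a genome triplication)
## and two jawed species (1R then 2R), with the pre-1R tandem opsin
## cluster, scripted losses and the lamprey SWS1 translocation. Writes the
## per-species FASTA/GFF3 genomes and the truth ledger.

suppressPackageStartupMessages(library(opsinteny))
seed <- 1
outdir <- "results/world"

sim <- simulate_paper_scenario(paper_scenario_config(), seed = seed)
write_genome_set(sim$genome_set, sim$truth, outdir)
write_run_config(sim$config, file.path(outdir, "config.yaml"))
write_taxon_table(sim$config$taxa, file.path(outdir, "taxa.tsv"))

cc <- chromosome_copy_counts(sim$truth)
cat("Simulated", length(unique(sim$genome_set$genes$species)), "species,",
    nrow(sim$genome_set$genes), "genes.\n")
cat("Chromosome copies per ancestral chromosome:\n")
print(cc)
cat("Jawless genomes are hexaploid relative to the ancestor, jawed",
    "genomes tetraploid, the outgroup unduplicated.\n")
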