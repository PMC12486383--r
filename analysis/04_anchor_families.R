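#!/usr/bin/env Rscript
## Group all proteins into orthogroups (cross-species reciprocal best hits
## plus within-species paralog recruitment) and select the synteny anchor
## families: members on >= 2 opsin-bearing focal chromosomes and >= 3
## lamprey chromosomes overall.

suppressPackageStartupMessages(library(opsinteny))
world <- "results/world"

gs <- read_genome_set(world)
cfg <- read_run_config(file.path(world, "config.yaml"))
asg <- read.delim("results/assignments.tsv")
cg <- classified_genes(gs$genes, asg)

proteomes <- split(setNames(gs$genes$protein, gs$genes$gene_id),
                   gs$genes$species)
groups <- build_orthogroups(proteomes,
                            min_identity = cfg$orthogroups$min_identity)
write.table(orthogroup_table(groups), "results/orthogroups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

focal <- cg[cg$species == cfg$focal_species & !is.na(cg$subtype) &
              cg$subtype %in% c("LWS", "SWS1", "SWS2", "RH1", "RH2"), ]
opsin_chroms <- unique(focal$seq_id)
classified_keys <- paste(cg$species, cg$gene_id, sep = "|")[!is.na(cg$subtype)]
extra_keys <- paste(gs$genes$species, gs$genes$gene_id, sep = "|")[
  gs$genes$family %in% cfg$anchor_extra]
is_candidate <- vapply(groups, function(g)
  !any(g$members %in% c(classified_keys, extra_keys)), TRUE)
selected <- select_anchor_families(
  groups[is_candidate], gs$genes, cfg$focal_species, opsin_chroms,
  min_opsin_chroms = cfg$selection$min_opsin_chroms,
  min_species_chroms = cfg$selection$min_species_chroms,
  jawless_species = cfg$jawless_species)
sel <- data.frame(family_id = c(selected, cfg$anchor_extra),
                  role = c(rep("selected", length(selected)),
                           rep("extra", length(cfg$anchor_extra))))
write.table(sel, "results/selected_families.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(length(groups), "orthogroups;",
    length(selected), "neighbour families selected as synteny anchors",
    "(plus", length(cfg$anchor_extra), "curated extra families:",
    paste(cfg$anchor_extra, collapse = ", "), ").\n")
cat("Focal opsin-bearing chromosomes:", paste(opsin_chroms, collapse = ", "),
    "\n")
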