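#!/usr/bin/env Rscript
## Concatenate the anchor-family alignments by chromosome, infer the
## paralogon tree with bootstrap supports, and root it with the outgroup
## rows. The two basal ingroup clades are the 1R-derived chromosome sets.

suppressPackageStartupMessages(library(opsinteny))
world <- "results/world"

gs <- read_genome_set(world)
cfg <- read_run_config(file.path(world, "config.yaml"))
sel <- read.delim("results/selected_families.tsv")
og_tab <- read.delim("results/orthogroups.tsv")

msas <- list()
for (fid in sel$family_id[sel$role == "selected"]) {
  mem <- og_tab[og_tab$family_id == fid, ]
  keys <- paste(mem$species, mem$gene_id, sep = "|")
  prot <- setNames(gs$genes$protein,
                   paste(gs$genes$species, gs$genes$gene_id, sep = "|"))[keys]
  keep <- nchar(prot) == as.integer(names(sort(table(nchar(prot)),
                                               decreasing = TRUE))[1])
  msas[[fid]] <- prot[keep]
}
for (fam in cfg$anchor_extra) {
  gg <- gs$genes[!is.na(gs$genes$family) & gs$genes$family == fam, ]
  msas[[fam]] <- setNames(gg$protein, paste(gg$species, gg$gene_id, sep = "|"))
}

sm <- build_supermatrix(msas, gs$genes)
write_supermatrix(sm, "results/supermatrix")
st <- bootstrap_tree(sm, n_boot = cfg$tree$n_boot, seed = 2001,
                     threshold = cfg$tree$support_threshold)
og_rows <- names(sm$rows)[startsWith(names(sm$rows),
                                     paste0(cfg$outgroup_species, "|"))]
rooted <- root_tree(st, intersect(og_rows, st$tree$tip.label))
writeLines(support_tree_newick(rooted), "results/paralogon_tree.nwk")
write.table(data.frame(split = names(st$supports),
                       support = unname(st$supports),
                       reliable = unname(st$reliable)),
            "results/splits.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
clades <- paralogon_clades(rooted, outgroup = cfg$outgroup_species)
write.table(data.frame(row = names(clades), clade = unname(clades)),
            "results/paralogon_clades.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Supermatrix:", length(sm$rows), "chromosome rows x",
    nchar(sm$rows[[1]]), "columns over", nrow(sm$partition), "families.\n")
cat(sum(st$reliable), "of", length(st$supports),
    "internal splits reliable at support >=", cfg$tree$support_threshold, "\n")
cat("Clade assignment of each chromosome row written to",
    "results/paralogon_clades.tsv; the two clades are the 1R duplicates.\n")
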