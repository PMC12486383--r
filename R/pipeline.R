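## End-to-end orchestration: simulate -> classify -> scan -> families ->
## paralogon -> scenarios -> report. Stages communicate via plain-text
## files in the run directory so each stage is independently inspectable
## and re-runnable; a manifest with checksums makes reruns comparable.

#' Run the full pipeline
#'
#' @param config configuration list (see [paper_scenario_config()]).
#' @param outdir run directory (created).
#' @param seed master seed; every stochastic stage derives its seed from
#'   it, so reruns are byte-identical.
#' @param stages stages to run, in order.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config = paper_scenario_config(), outdir, seed = 1,
                         stages = c("simulate", "classify", "scan",
                                    "families", "paralogon", "scenarios",
                                    "report")) {
  validate_run_config(config)
  seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "log.txt")
  log_line <- function(stage, msg)
    cat(sprintf("[%s] seed=%d %s\n", stage, seed, msg), file = logf,
        append = TRUE)
  write_run_config(config, file.path(outdir, "config.yaml"))
  write_taxon_table(config$taxa, file.path(outdir, "taxa.tsv"))

  run_stage <- function(stage, fn) {
    if (!stage %in% stages) return(invisible())
    ok <- tryCatch({ fn(); TRUE },
                   error = function(e) {
                     log_line(stage, paste("FAILED:", conditionMessage(e)))
                     stop("stage '", stage, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
    log_line(stage, "done")
  }

  env <- new.env()

  run_stage("simulate", function() {
    sim <- simulate_paper_scenario(config, seed)
    write_genome_set(sim$genome_set, sim$truth, file.path(outdir, "genomes"))
    env$sim <- sim
  })

  run_stage("classify", function() {
    if (is.null(env$sim)) env$sim <- list(
      genome_set = read_genome_set(file.path(outdir, "genomes")))
    genes <- env$sim$genome_set$genes
    asg <- classify_genomes(genes, n_boot = config$classify$n_boot,
                            threshold = config$classify$threshold,
                            seed = seed + 1000L,
                            min_identity = config$classify$min_identity)
    write_tsv(asg, file.path(outdir, "assignments.tsv"))
    env$assignments <- asg
  })

  run_stage("scan", function() {
    genes <- classified_genes(env$sim$genome_set$genes, env$assignments)
    ev <- suppressWarnings(scan_pairs(genes, window = config$window_bp))
    write_tsv(ev, file.path(outdir, "pairs.tsv"))
    sm <- summarize_pairs(ev, config$taxa)
    write_tsv(sm$counts, file.path(outdir, "pair_counts.tsv"))
    write_tsv(sm$group_shares, file.path(outdir, "group_shares.tsv"))
    env$pairs <- ev
  })

  run_stage("families", function() {
    genes <- env$sim$genome_set$genes
    proteomes <- split(setNames(genes$protein, genes$gene_id), genes$species)
    groups <- build_orthogroups(proteomes,
                                min_identity = config$orthogroups$min_identity)
    write_tsv(orthogroup_table(groups), file.path(outdir, "orthogroups.tsv"))
    cg <- classified_genes(genes, env$assignments)
    focal <- cg[cg$species == config$focal_species & !is.na(cg$subtype) &
                  cg$subtype %in% VISUAL_SUBTYPES, ]
    opsin_chroms <- unique(focal$seq_id)
    ## candidate neighbours: exclude orthogroups holding classified opsins
    ## or the independently curated extra anchors (GNAI, parapinopsin)
    classified_keys <- gene_key(cg$species, cg$gene_id)[!is.na(cg$subtype)]
    extra_keys <- gene_key(genes$species, genes$gene_id)[
      genes$family %in% config$anchor_extra]
    is_candidate <- vapply(groups, function(g)
      !any(g$members %in% c(classified_keys, extra_keys)), TRUE)
    selected <- select_anchor_families(
      groups[is_candidate], genes, config$focal_species, opsin_chroms,
      min_opsin_chroms = config$selection$min_opsin_chroms,
      min_species_chroms = config$selection$min_species_chroms,
      jawless_species = config$jawless_species)
    ## curated extra anchors (GNAI, parapinopsin) enter by family symbol
    sel_df <- data.frame(family_id = c(selected, config$anchor_extra),
                         role = c(rep("selected", length(selected)),
                                  rep("extra", length(config$anchor_extra))),
                         stringsAsFactors = FALSE)
    write_tsv(sel_df, file.path(outdir, "selected_families.tsv"))
    env$groups <- groups
    env$selected <- sel_df
    env$opsin_chroms <- opsin_chroms
  })

  run_stage("paralogon", function() {
    genes <- env$sim$genome_set$genes
    sel_ids <- env$selected$family_id[env$selected$role == "selected"]
    msas <- family_msas_from_groups(env$groups, sel_ids, genes)
    for (fam in config$anchor_extra) {
      gg <- genes[!is.na(genes$family) & genes$family == fam, ]
      msas[[fam]] <- setNames(gg$protein, gene_key(gg$species, gg$gene_id))
    }
    sm <- build_supermatrix(msas, genes)
    write_supermatrix(sm, file.path(outdir, "supermatrix"))
    st <- bootstrap_tree(sm, n_boot = config$tree$n_boot, seed = seed + 2000L,
                         threshold = config$tree$support_threshold)
    og_rows <- names(sm$rows)[startsWith(names(sm$rows),
                                         paste0(config$outgroup_species, "|"))]
    og_rows <- intersect(og_rows, st$tree$tip.label)
    rooted <- root_tree(st, og_rows)
    writeLines(support_tree_newick(rooted),
               file.path(outdir, "paralogon_tree.nwk"))
    write_tsv(data.frame(split = names(st$supports),
                         support = unname(st$supports),
                         reliable = unname(st$reliable)),
              file.path(outdir, "splits.tsv"))
    env$support_tree <- st
    env$rooted_tree <- rooted
  })

  run_stage("scenarios", function() {
    genes <- classified_genes(env$sim$genome_set$genes, env$assignments)
    clades <- paralogon_clades(env$rooted_tree,
                               outgroup = config$outgroup_species)
    obs <- arrangement_from_genes(genes, config$representatives, clades)
    write_tsv(obs$table, file.path(outdir, "observed_arrangement.tsv"))
    hyps <- opsin_hypotheses()
    tab <- compare_hypotheses(obs, hyps,
                              weights = config$scenario$weights,
                              max_pre1r_genes = config$scenario$max_pre1r_genes)
    write_tsv(tab, file.path(outdir, "hypothesis_ranking.tsv"))
    bestn <- tab$hypothesis[1]
    best <- min_cost_scenario(obs, hyps[[bestn]],
                              weights = config$scenario$weights,
                              max_pre1r_genes = config$scenario$max_pre1r_genes)
    write_tsv(best$scenarios[[1]]$events,
              file.path(outdir, "scenario_events.tsv"))
    writeLines(scenario_narrative(best), file.path(outdir, "scenario_log.txt"))
  })

  run_stage("report", function() make_report(outdir))

  ## manifest
  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(seed = seed,
                   config_md5 = unname(tools::md5sum(file.path(outdir, "config.yaml"))),
                   n_files = length(files),
                   files = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Merge accepted classifications into a gene table
#'
#' Replaces the `subtype` column with the classifier's accepted calls
#' (NA where unclassified or rejected), leaving truth labels out of all
#' downstream inference.
#' @param genes `gene_records`.
#' @param assignments output of [classify_genomes()].
#' @return `gene_records` with classifier-derived subtypes.
#' @export
classified_genes <- function(genes, assignments) {
  acc <- assignments[assignments$accepted & !is.na(assignments$subtype), ]
  key <- paste(acc$species, acc$gene_id)
  map <- setNames(acc$subtype, key)
  genes$subtype <- unname(map[paste(genes$species, genes$gene_id)])
  genes
}

## family alignments for the supermatrix: per selected orthogroup, the
## member proteins (modal length; deviants are dropped with a warning --
## the generator produces no indels, so honest members are equal-length)
family_msas_from_groups <- function(groups, family_ids, genes) {
  key_of <- gene_key(genes$species, genes$gene_id)
  prot_of <- setNames(genes$protein, key_of)
  fam_of <- setNames(genes$family, key_of)
  msas <- list()
  for (g in groups) {
    if (!g$family_id %in% family_ids) next
    seqs <- prot_of[g$members]
    lens <- nchar(seqs)
    modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    if (any(lens != modal)) {
      warning("dropping ", sum(lens != modal), " length-deviant members of ",
              g$family_id)
      seqs <- seqs[lens == modal]
    }
    fam_name <- names(sort(table(fam_of[g$members]), decreasing = TRUE))[1]
    msas[[paste(g$family_id, fam_name, sep = ":")]] <- seqs
  }
  msas
}

#' Paralogon clade ids from a rooted support tree
#'
#' After outgroup rooting, the ingroup's two basal clades are labelled
#' "1" and "2" (the clade containing the alphabetically first row is "1").
#' @param rooted a rooted `support_tree`.
#' @param outgroup outgroup species name (rows `"<outgroup>|..."`).
#' @return named character vector: row key -> clade id.
#' @export
paralogon_clades <- function(rooted, outgroup) {
  tree <- rooted$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  tipsets <- lapply(kids, function(k) tree$tip.label[phangorn_descendants(tree, k)])
  og <- vapply(tipsets, function(ts)
    all(startsWith(ts, paste0(outgroup, "|"))), TRUE)
  ingroup_sets <- tipsets[!og]
  if (length(ingroup_sets) == 1) {
    ## ingroup is one clade: its two basal subclades are the 1R clades
    in_tips <- ingroup_sets[[1]]
    node <- kids[!og][1]
    sub <- tree$edge[tree$edge[, 1] == node, 2]
    ingroup_sets <- lapply(sub, function(k)
      tree$tip.label[phangorn_descendants(tree, k)])
  }
  ingroup_sets <- ingroup_sets[order(vapply(ingroup_sets,
                                            function(x) sort(x)[1], ""))]
  out <- character()
  for (i in seq_along(ingroup_sets))
    out[ingroup_sets[[i]]] <- as.character(i)
  out
}

#' Observed arrangement for the scenario engine from classified genes
#'
#' Takes one representative species per lineage group, keeps chromosomes
#' carrying accepted visual opsins, orders genes by coordinate, and labels
#' each chromosome with its paralogon clade ("other" when the chromosome
#' carries no anchor row in the paralogon tree).
#' @param genes classifier-labelled `gene_records`.
#' @param representatives named list group -> species.
#' @param clades named clade map from [paralogon_clades()].
#' @return an [observed_arrangement()].
#' @export
arrangement_from_genes <- function(genes, representatives, clades) {
  rows <- list()
  for (g in names(representatives)) {
    sp <- representatives[[g]]
    gg <- genes[genes$species == sp & !is.na(genes$subtype) &
                  genes$subtype %in% VISUAL_SUBTYPES, ]
    for (ch in unique(gg$seq_id)) {
      sub <- gg[gg$seq_id == ch, ]
      sub <- sub[order(sub$start), ]
      clade <- clades[row_key(sp, ch)]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, chrom = ch,
        clade = if (is.na(clade)) "other" else clade,
        pos = seq_len(nrow(sub)), subtype = sub$subtype,
        strand = sub$strand, row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  observed_arrangement(do.call(rbind, rows))
}

scenario_narrative <- function(scen_set) {
  sc <- scen_set$scenarios[[1]]
  ev <- sc$events
  lines <- c(sprintf("hypothesis: %s", scen_set$hypothesis),
             sprintf("minimum cost: %g (%d co-optimal scenario%s)",
                     scen_set$cost, scen_set$n_cooptimal,
                     if (scen_set$n_cooptimal == 1) "" else "s"),
             sprintf("events: %d tandem duplication(s), %d loss(es), %d translocation(s)",
                     sc$breakdown[["TANDEM_DUP"]], sc$breakdown[["LOSS"]],
                     sc$breakdown[["TRANSLOCATION"]]), "")
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    lines <- c(lines, switch(
      e$kind,
      TANDEM_DUP = sprintf("- tandem duplication of %s before 1R (copy %s)",
                           e$uid, e$new_uid),
      LOSS = sprintf("- loss of %s on edge %s", e$uid, e$edge),
      TRANSLOCATION = sprintf("- translocation of %s from %s to %s",
                              e$uid, e$edge, e$to_chrom)))
  }
  lines
}

#' Summarize a completed run directory
#'
#' Tabulates the pair counts and taxon-group shares, the selected anchor
#' families, the paralogon tree with its reliable splits, and the
#' hypothesis cost ranking into `report.md`. Missing stage outputs are
#' listed explicitly rather than failing silently.
#' @param outdir a run directory from [run_pipeline()].
#' @return path to the report, invisibly.
#' @export
make_report <- function(outdir) {
  out <- c("# Pipeline report", "")
  need <- function(f) file.exists(file.path(outdir, f))
  missing <- character()
  fmt_table <- function(df) {
    if (!nrow(df)) return("(empty)")
    header <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    body <- apply(df, 1, function(r) paste(r, collapse = " | "))
    c(header, sep, body)
  }
  if (need("pairs.tsv")) {
    ev <- read_tsv(file.path(outdir, "pairs.tsv"))
    out <- c(out, "## Subtype pairs (same chromosome and strand)", "",
             sprintf("%d pair event(s) detected (%d proximal, %d distal).",
                     nrow(ev), sum(ev$proximal), sum(!ev$proximal)), "")
    if (need("pair_counts.tsv"))
      out <- c(out, fmt_table(read_tsv(file.path(outdir, "pair_counts.tsv"))), "")
    if (need("group_shares.tsv")) {
      gs <- read_tsv(file.path(outdir, "group_shares.tsv"))
      if (nrow(gs)) out <- c(out, fmt_table(gs), "")
    }
  } else missing <- c(missing, "pairs.tsv")
  if (need("selected_families.tsv")) {
    sel <- read_tsv(file.path(outdir, "selected_families.tsv"))
    out <- c(out, "## Anchor families", "",
             sprintf("%d selected + %d curated extra famil%s.",
                     sum(sel$role == "selected"), sum(sel$role == "extra"),
                     if (nrow(sel) == 1) "y" else "ies"),
             "", fmt_table(sel), "")
  } else missing <- c(missing, "selected_families.tsv")
  if (need("paralogon_tree.nwk")) {
    out <- c(out, "## Paralogon tree", "",
             "```", readLines(file.path(outdir, "paralogon_tree.nwk")), "```", "")
    if (need("splits.tsv")) {
      sp <- read_tsv(file.path(outdir, "splits.tsv"))
      out <- c(out, sprintf("%d internal split(s), %d reliable at threshold.",
                            nrow(sp), sum(sp$reliable)), "")
    }
  } else missing <- c(missing, "paralogon_tree.nwk")
  if (need("hypothesis_ranking.tsv")) {
    hr <- read_tsv(file.path(outdir, "hypothesis_ranking.tsv"))
    out <- c(out, "## Hypothesis ranking (event parsimony)", "",
             fmt_table(hr), "")
  } else missing <- c(missing, "hypothesis_ranking.tsv")
  if (length(missing))
    out <- c(out, "## Missing stage outputs", "", paste("-", missing), "")
  writeLines(out, file.path(outdir, "report.md"))
  invisible(file.path(outdir, "report.md"))
}
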