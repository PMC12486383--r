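## Default study conditions: a vertebrate-like synthetic world with an
## outgroup (no WGD), a jawless clade (1R then an independent genome
## triplication) and a jawed clade (1R then 2R). The ancestral
## opsin-bearing chromosome carries a pre-1R tandem opsin cluster
## (SWS1, SWS2, RH, LWS) flanked by anchor gene families; scripted losses
## and the jawless SWS1 translocation reproduce the observed extant
## arrangements: lamprey RH1-LWS and RH2-SWS2 tandems, the jawed LWS-SWS2
## tandem, and SWS1 relocated outside the paralogon in lampreys.

OPSIN_FAMILIES <- c("SWS1", "SWS2", "RH", "LWS", "PP", "OPN3")

#' Default configuration of the synthetic study
#'
#' All tunable parameters of the end-to-end pipeline in one (YAML
#' round-trippable) list: the species tree with its WGD events, the
#' ancestral gene order, scripted events, rate multipliers, and every
#' downstream threshold.
#'
#' @param divergence_scale multiplies all branch lengths (1 = default
#'   conditions).
#' @return nested configuration list.
#' @export
paper_scenario_config <- function(divergence_scale = 1) {
  list(
    newick = paste0("(amphioxus:0.6,((sea_lamprey:0.15,pouched_lamprey:0.15)",
                    "jawless:0.25,(gar:0.15,zebrafish:0.15)jawed:0.25)",
                    "vertebrata:0.08)root;"),
    divergence_scale = divergence_scale,
    wgd_events = list(
      list(branch = "vertebrata", kind = "WGD", label = "1R"),
      list(branch = "jawless", kind = "TRIPLICATION", label = "CyWGD"),
      list(branch = "jawed", kind = "WGD", label = "2R")),
    branch_rates = list(zebrafish = 1.3),
    taxa = data.frame(
      species = c("sea_lamprey", "pouched_lamprey", "gar", "zebrafish",
                  "amphioxus"),
      group = c("jawless", "jawless", "non-teleost jawed", "teleost",
                "outgroup"), stringsAsFactors = FALSE),
    jawless_species = c("sea_lamprey", "pouched_lamprey"),
    focal_species = "sea_lamprey",
    outgroup_species = "amphioxus",
    representatives = list(jawless = "sea_lamprey", jawed = "gar"),
    chromosomes = list(
      chrOps = c("GNAT", "CUEDC1", "SWS1", "SWS2", "RH", "LWS", "GNAI",
                 "PP", "BARHL", "SLC24A", "EFCAB", "TSPAN", "PRDM", "NLGN"),
      chrBg = c("OPN3", "BG1", "BG2", "BG3")),
    gene_lengths = c(
      GNAT = 180, CUEDC1 = 130, SWS1 = 240, SWS2 = 240, RH = 240, LWS = 240,
      GNAI = 180, PP = 240, BARHL = 160, SLC24A = 200, EFCAB = 120,
      TSPAN = 140, PRDM = 170, NLGN = 150, OPN3 = 240, BG1 = 100,
      BG2 = 120, BG3 = 110),
    ## rate multipliers span a ~2.5-fold range; the fastest stay above the
    ## orthology-recovery identity floor at the configured divergences
    per_gene_rates = c(
      GNAT = 0.8, CUEDC1 = 1.25, SWS1 = 1, SWS2 = 1, RH = 1, LWS = 1,
      GNAI = 0.6, PP = 1.1, BARHL = 0.5, SLC24A = 0.9, EFCAB = 1.3,
      TSPAN = 1.2, PRDM = 0.7, NLGN = 1, OPN3 = 0.9, BG1 = 1, BG2 = 1,
      BG3 = 1),
    intergene_gap_bp = 5000,
    ## opsin subtype truth: the RH1/RH2 split happens at 1R
    subtype_map = c(SWS1 = "SWS1", SWS2 = "SWS2", LWS = "LWS",
                    PP = "nonvisual", OPN3 = "nonvisual"),
    subtype_splits = list(RH = list(event = "1R", subtypes = c("RH1", "RH2"))),
    ## opsin-root divergences used to synthesize the ancestral proteome
    opsin_root_divergence = 0.5,
    rates = list(tandem_dup = 0, loss = 0, translocation = 0),
    anchor_extra = c("GNAI", "PP"),
    window_bp = 100000,
    classify = list(n_boot = 200, threshold = 0.95, min_identity = 0.25),
    orthogroups = list(min_identity = 0.3),
    selection = list(min_opsin_chroms = 2, min_species_chroms = 3),
    tree = list(n_boot = 100, support_threshold = 0.95),
    scenario = list(weights = c(TANDEM_DUP = 1, LOSS = 1, TRANSLOCATION = 1),
                    max_pre1r_genes = 5)
  )
}

#' Scripted events of the default scenario
#'
#' The configured losses and the lamprey SWS1 translocation that carve the
#' observed opsin arrangements out of the post-WGD chromosome copies.
#' @return data.frame of scripted events for [simulate_history()].
#' @export
paper_scenario_events <- function() {
  jl <- function(kind, family, chrom, to_chrom = NA, new_strand = NA)
    data.frame(branch = "jawless", kind = kind, family = family,
               chrom = chrom, to_chrom = to_chrom, new_strand = new_strand,
               stringsAsFactors = FALSE)
  jw <- function(kind, family, chrom)
    data.frame(branch = "jawed", kind = kind, family = family, chrom = chrom,
               to_chrom = NA, new_strand = NA, stringsAsFactors = FALSE)
  rbind(
    ## jawless: keep RH1+LWS on chrOps_A_A, RH2+SWS2 on chrOps_B_B,
    ## translocate SWS1 out of the paralogon, drop NLGN to one chromosome
    jl("TRANSLOCATION", "SWS1", "chrOps_A_A", "chrBg_A_A", "+"),
    jl("LOSS", "SWS1", "chrOps_A_B"), jl("LOSS", "SWS1", "chrOps_A_C"),
    jl("LOSS", "SWS1", "chrOps_B_A"), jl("LOSS", "SWS1", "chrOps_B_B"),
    jl("LOSS", "SWS1", "chrOps_B_C"),
    jl("LOSS", "SWS2", "chrOps_A_A"), jl("LOSS", "SWS2", "chrOps_A_B"),
    jl("LOSS", "SWS2", "chrOps_A_C"), jl("LOSS", "SWS2", "chrOps_B_A"),
    jl("LOSS", "SWS2", "chrOps_B_C"),
    jl("LOSS", "RH", "chrOps_A_B"), jl("LOSS", "RH", "chrOps_A_C"),
    jl("LOSS", "RH", "chrOps_B_A"), jl("LOSS", "RH", "chrOps_B_C"),
    jl("LOSS", "LWS", "chrOps_A_B"), jl("LOSS", "LWS", "chrOps_A_C"),
    jl("LOSS", "LWS", "chrOps_B_A"), jl("LOSS", "LWS", "chrOps_B_B"),
    jl("LOSS", "LWS", "chrOps_B_C"),
    jl("LOSS", "NLGN", "chrOps_A_B"), jl("LOSS", "NLGN", "chrOps_A_C"),
    jl("LOSS", "NLGN", "chrOps_B_A"), jl("LOSS", "NLGN", "chrOps_B_B"),
    jl("LOSS", "NLGN", "chrOps_B_C"),
    ## jawed: keep RH1 alone, LWS+SWS2 together, RH2 alone, SWS1 alone
    jw("LOSS", "SWS1", "chrOps_A_A"), jw("LOSS", "SWS1", "chrOps_A_B"),
    jw("LOSS", "SWS1", "chrOps_B_A"),
    jw("LOSS", "SWS2", "chrOps_A_A"), jw("LOSS", "SWS2", "chrOps_B_A"),
    jw("LOSS", "SWS2", "chrOps_B_B"),
    jw("LOSS", "RH", "chrOps_A_B"), jw("LOSS", "RH", "chrOps_B_B"),
    jw("LOSS", "LWS", "chrOps_A_A"), jw("LOSS", "LWS", "chrOps_B_A"),
    jw("LOSS", "LWS", "chrOps_B_B"))
}

#' Build the simulator inputs from a configuration
#' @param config a [paper_scenario_config()] list.
#' @return list: `tree` (species_tree_spec), `ancestor`
#'   (ancestral_genome), `rates` (event_rates), `scripted`.
#' @export
scenario_inputs <- function(config) {
  tree <- species_tree_spec(config$newick, config$wgd_events,
                            unlist(config$branch_rates))
  if (!identical(config$divergence_scale, 1)) {
    tree$tree$edge.length <- tree$tree$edge.length * config$divergence_scale
  }
  chroms <- lapply(config$chromosomes, function(fams)
    data.frame(family = fams, strand = "+", stringsAsFactors = FALSE))
  ancestor <- ancestral_genome(
    chromosomes = chroms, gene_lengths = config$gene_lengths,
    intergene_gap_bp = config$intergene_gap_bp,
    subtype_map = config$subtype_map,
    subtype_splits = config$subtype_splits)
  rates <- event_rates(config$rates$tandem_dup, config$rates$loss,
                       config$rates$translocation)
  list(tree = tree, ancestor = ancestor, rates = rates,
       scripted = paper_scenario_events())
}

#' Synthesize the ancestral proteome
#'
#' Opsin-class families (visual subtyes, parapinopsin, OPN3) descend from
#' one ur-opsin sequence at a configured divergence so they are homologous
#' but clearly separated; every other family is an independent random
#' protein.
#' @param config a [paper_scenario_config()] list.
#' @param seed integer RNG seed.
#' @return named character vector: family -> root protein.
#' @export
root_proteome <- function(config, seed) {
  set.seed(as.integer(seed))
  lens <- config$gene_lengths
  fams <- names(lens)
  out <- setNames(character(length(fams)), fams)
  ur_opsin <- random_protein(max(lens[intersect(fams, OPSIN_FAMILIES)]))
  for (f in fams) {
    if (f %in% OPSIN_FAMILIES) {
      base <- substr(ur_opsin, 1, lens[[f]])
      out[f] <- evolve_protein(base, config$opsin_root_divergence)
    } else {
      out[f] <- random_protein(lens[[f]])
    }
  }
  out
}

#' Simulate the default scenario end to end
#'
#' @param config a [paper_scenario_config()] list.
#' @param seed integer; drives the ancestral proteome, the (scripted)
#'   history and sequence evolution deterministically.
#' @return list: `truth`, `genomes` (skeletons), `genome_set` (with
#'   proteins), `config`.
#' @export
simulate_paper_scenario <- function(config = paper_scenario_config(), seed = 1) {
  seed <- as.integer(seed)
  inp <- scenario_inputs(config)
  roots <- root_proteome(config, seed = seed * 3L + 1L)
  sim <- simulate_history(inp$tree, inp$ancestor, inp$rates,
                          seed = seed, scripted = inp$scripted)
  gs <- evolve_sequences(sim$truth, roots, config$per_gene_rates,
                         seed = seed * 3L + 2L)
  list(truth = sim$truth, genomes = sim$genomes, genome_set = gs,
       config = config, root_proteins = roots)
}

#' Competing pre-1R ancestral hypotheses
#'
#' `stepwise_five`: five pre-1R genes, one per extant subtype (the
#' sequence-phylogeny scenario); `two_gene`: LWS plus a single ancestor of
#' the four other subtypes (the jawed-synteny scenario); `final_model`:
#' four pre-1R genes with the RH1/RH2 split deferred to 1R (the model this
#' package's analyses support).
#' @return named list of [ancestral_hypothesis()] objects.
#' @export
opsin_hypotheses <- function() {
  g <- function(...) data.frame(label = c(...), strand = "+",
                                stringsAsFactors = FALSE)
  list(
    stepwise_five = ancestral_hypothesis(
      "stepwise_five", g("SWS1", "SWS2", "RH2", "RH1", "LWS"),
      mapping = list(SWS1 = "SWS1", SWS2 = "SWS2", RH2 = "RH2",
                     RH1 = "RH1", LWS = "LWS")),
    two_gene = ancestral_hypothesis(
      "two_gene", g("AO", "LWS"),
      mapping = list(AO = c("SWS1", "SWS2", "RH1", "RH2"), LWS = "LWS")),
    final_model = ancestral_hypothesis(
      "final_model", g("SWS1", "SWS2", "RH", "LWS"),
      mapping = list(SWS1 = "SWS1", SWS2 = "SWS2", RH = c("RH1", "RH2"),
                     LWS = "LWS")))
}

#' Write/read a run configuration as YAML
#' @param config configuration list.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  cfg <- config
  cfg$taxa <- as.list(setNames(cfg$taxa$group, cfg$taxa$species))
  ## yaml flattens named atomic vectors to sequences; keep keys via lists
  for (nm in c("gene_lengths", "per_gene_rates", "subtype_map"))
    cfg[[nm]] <- as.list(cfg[[nm]])
  cfg$scenario$weights <- as.list(cfg$scenario$weights)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$taxa <- data.frame(species = names(cfg$taxa),
                         group = unlist(cfg$taxa, use.names = FALSE),
                         stringsAsFactors = FALSE)
  for (nm in c("gene_lengths", "per_gene_rates", "subtype_map"))
    cfg[[nm]] <- unlist(cfg[[nm]])
  cfg$scenario$weights <- unlist(cfg$scenario$weights)
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#' @param config configuration list.
#' @return the config, invisibly; stops on an invalid value.
#' @export
validate_run_config <- function(config) {
  stopifnot(config$window_bp > 0,
            config$classify$threshold > 0, config$classify$threshold <= 1,
            config$tree$support_threshold > 0,
            config$tree$support_threshold <= 1,
            config$orthogroups$min_identity >= 0,
            config$orthogroups$min_identity <= 1,
            all(unlist(config$scenario$weights) > 0),
            config$intergene_gap_bp > 0,
            config$divergence_scale > 0)
  invisible(config)
}
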