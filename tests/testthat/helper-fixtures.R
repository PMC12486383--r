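## Small fixture builders shared across test files. Everything is built
## in code; no data files.

toy_genes <- function(df) {
  defaults <- list(species = "sp1", seq_id = "chr1", strand = "+",
                   subtype = NA_character_, family = NA_character_,
                   protein = NA_character_)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  gene_records(gene_id = df$gene_id, species = df$species,
               seq_id = df$seq_id, start = df$start, end = df$end,
               strand = df$strand, protein = df$protein,
               subtype = df$subtype, family = df$family)
}

## random toy annotation for scanner oracle tests
random_annotation <- function(n_genes, seed) {
  set.seed(seed)
  subtypes <- c("LWS", "SWS1", "SWS2", "RH1", "RH2", NA)
  starts <- sort(sample.int(500000, n_genes))
  toy_genes(data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    species = sample(c("spA", "spB"), n_genes, replace = TRUE),
    seq_id = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    start = starts, end = starts + sample(500:3000, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    subtype = sample(subtypes, n_genes, replace = TRUE),
    stringsAsFactors = FALSE))
}

## a minimal two-chromosome, no-WGD world for orthogroup tests
flat_world <- function(n_fams = 6, len = 200, tip_len = 0.15, seed = 1) {
  fams <- paste0("F", seq_len(n_fams))
  tree <- species_tree_spec(
    sprintf("((spA:%f,spB:%f)ab:%f,spC:%f)root;", tip_len, tip_len,
            tip_len / 2, tip_len * 1.5))
  anc <- ancestral_genome(
    chromosomes = list(c1 = data.frame(family = fams[1:(n_fams %/% 2)],
                                       strand = "+"),
                       c2 = data.frame(family = fams[(n_fams %/% 2 + 1):n_fams],
                                       strand = "+")),
    gene_lengths = setNames(rep(len, n_fams), fams))
  sim <- simulate_history(tree, anc, event_rates(), seed = seed)
  set.seed(seed + 500)
  roots <- setNames(vapply(fams, function(f) random_protein(len), ""), fams)
  gs <- evolve_sequences(sim$truth, roots, seed = seed + 1000)
  list(truth = sim$truth, gs = gs, roots = roots)
}

## tiny reference DB in a shared 30-column space
tiny_ref_db <- function(seed = 42, width = 60) {
  set.seed(seed)
  anc <- list(LWS = random_protein(width), SWS1 = random_protein(width))
  rows <- list()
  for (s in names(anc))
    rows[[s]] <- setNames(vapply(1:3, function(i)
      evolve_protein(anc[[s]], 0.08), ""), paste0(s, 1:3))
  reference_db(rows)
}

expect_same_events <- function(a, b) {
  key <- function(ev) sort(paste(ev$kind, ev$edge, ev$uid))
  expect_identical(key(a), key(b))
}
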