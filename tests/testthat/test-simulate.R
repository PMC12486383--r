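two_chrom_ancestor <- function() {
  ancestral_genome(
    chromosomes = list(
      c1 = data.frame(family = c("F1", "F2", "F3"), strand = c("+", "+", "-")),
      c2 = data.frame(family = c("F4", "F5"), strand = "+")),
    gene_lengths = c(F1 = 100, F2 = 120, F3 = 90, F4 = 150, F5 = 60),
    intergene_gap_bp = 2000)
}

simple_tree <- function(wgd = list()) {
  species_tree_spec("((spA:0.1,spB:0.1)ab:0.1,spC:0.2)root;", wgd)
}

test_that("zero rates and no WGD reproduce the ancestor in every species", {
  sim <- simulate_history(simple_tree(), two_chrom_ancestor(), event_rates(),
                          seed = 1)
  for (sp in c("spA", "spB", "spC")) {
    st <- sim$truth$extant[[sp]]
    expect_equal(sort(unique(st$chrom)), c("c1", "c2"))
    expect_equal(st$family[order(st$chrom, st$pos)],
                 c("F1", "F2", "F3", "F4", "F5"))
  }
  expect_equal(nrow(sim$truth$events), 0)
})

test_that("WGD and triplication multiply chromosome counts (hexaploidy law)", {
  ## shared WGD at the stem, then triplication on one branch and a second
  ## WGD on the other
  tree <- species_tree_spec(
    "((spA:0.1,spB:0.1)ab:0.1,spC:0.2)root;",
    wgd_events = list(list(branch = "ab", kind = "WGD", label = "1R"),
                      list(branch = "spA", kind = "TRIPLICATION", label = "Cy"),
                      list(branch = "spB", kind = "WGD", label = "2R")))
  sim <- simulate_history(tree, two_chrom_ancestor(), event_rates(), seed = 1)
  cc <- chromosome_copy_counts(sim$truth)
  expect_true(all(cc$n_copies[cc$species == "spA"] == 6))
  expect_true(all(cc$n_copies[cc$species == "spB"] == 4))
  expect_true(all(cc$n_copies[cc$species == "spC"] == 1))
  ## copy-number law per family with zero loss
  for (sp in c("spA", "spB", "spC")) {
    st <- sim$truth$extant[[sp]]
    expected <- c(spA = 6, spB = 4, spC = 1)[[sp]]
    expect_true(all(table(st$family) == expected))
  }
  ## WGD copies preserve within-chromosome order and strand
  st <- sim$truth$extant$spB
  anc <- two_chrom_ancestor()
  for (ch in unique(st$chrom)) {
    root <- strsplit(ch, "_")[[1]][1]
    sub <- st[st$chrom == ch, ]
    expect_equal(sub$family[order(sub$pos)], anc$chromosomes[[root]]$family)
    expect_equal(sub$strand[order(sub$pos)], anc$chromosomes[[root]]$strand)
  }
})

test_that("tandem duplicates sit immediately downstream on the same strand", {
  scripted <- data.frame(branch = "spC", kind = "TANDEM_DUP", family = "F3",
                         chrom = "c1", to_chrom = NA, new_strand = NA)
  sim <- simulate_history(simple_tree(), two_chrom_ancestor(), event_rates(),
                          seed = 3, scripted = scripted)
  st <- sim$truth$extant$spC
  c1 <- st[st$chrom == "c1", ]
  expect_equal(nrow(c1), 4)
  src_pos <- c1$pos[c1$family == "F3"]
  expect_equal(diff(sort(src_pos)), 1)  # copy adjacent to source
  expect_equal(unique(c1$strand[c1$family == "F3"]), "-")
  ## physical gap equals the configured intergene gap after layout
  gr <- sim$genomes$spC
  f3 <- gr[gr$family == "F3", ]
  f3 <- f3[order(f3$start), ]
  expect_equal(f3$start[2] - f3$end[1], 2000)
  ## ledger records the event with its product
  ev <- sim$truth$events
  expect_equal(ev$event, "TANDEM_DUP")
  expect_match(ev$result_ids, "^g")
})

test_that("scripted translocations move one gene to the named chromosome", {
  scripted <- data.frame(branch = "spC", kind = "TRANSLOCATION", family = "F1",
                         chrom = "c1", to_chrom = "c2", new_strand = "-")
  sim <- simulate_history(simple_tree(), two_chrom_ancestor(), event_rates(),
                          seed = 3, scripted = scripted)
  st <- sim$truth$extant$spC
  expect_equal(st$chrom[st$family == "F1"], "c2")
  expect_equal(st$strand[st$family == "F1"], "-")
  ## other species untouched
  expect_equal(sim$truth$extant$spA$chrom[sim$truth$extant$spA$family == "F1"],
               "c1")
})

test_that("identical seeds give identical simulations, including sequences", {
  rates <- event_rates(tandem_dup = 2, loss = 0.05, translocation = 0.05)
  roots <- setNames(lapply(c(100, 120, 90, 150, 60), function(n) {
    set.seed(n); random_protein(n)
  }), paste0("F", 1:5))
  roots <- unlist(roots)
  run <- function() {
    sim <- simulate_history(simple_tree(), two_chrom_ancestor(), rates,
                            seed = 11)
    gs <- evolve_sequences(sim$truth, roots, seed = 12)
    gs$genes
  }
  expect_identical(run(), run())
})

test_that("raising the loss rate never raises mean extant gene counts", {
  mean_count <- function(loss) {
    counts <- vapply(1:20, function(s) {
      sim <- simulate_history(simple_tree(), two_chrom_ancestor(),
                              event_rates(loss = loss), seed = 100 + s)
      nrow(sim$truth$extant$spA)
    }, 0)
    mean(counts)
  }
  m <- vapply(c(0, 0.5, 2), mean_count, 0)
  expect_true(all(diff(m) <= 0))
})

test_that("runaway duplication rates are rejected up front", {
  expect_error(
    simulate_history(simple_tree(), two_chrom_ancestor(),
                     event_rates(tandem_dup = 1e6), seed = 1),
    "runaway")
})

test_that("root proteins outside the 20-letter alphabet are rejected", {
  sim <- simulate_history(simple_tree(), two_chrom_ancestor(), event_rates(),
                          seed = 1)
  roots <- setNames(vapply(c(100, 120, 90, 150, 60), strrep, "", x = "M"),
                    paste0("F", 1:5))
  bad <- roots; bad["F1"] <- paste0("BZ", substr(bad["F1"], 3, 100))
  expect_error(evolve_sequences(sim$truth, bad, seed = 1), "unknown amino")
  expect_error(evolve_protein("MKX", 0.1), "unknown amino")
})

test_that("gene ancestry traces every extant gene to one root gene", {
  tree <- species_tree_spec(
    "((spA:0.1,spB:0.1)ab:0.1,spC:0.2)root;",
    wgd_events = list(list(branch = "ab", kind = "WGD", label = "1R")))
  sim <- simulate_history(tree, two_chrom_ancestor(),
                          event_rates(tandem_dup = 3), seed = 5)
  roots <- sim$truth$node_states$root$gene_id
  anc <- sim$truth$gene_ancestry
  for (sp in names(sim$truth$extant))
    expect_true(all(anc[sim$truth$extant[[sp]]$gene_id] %in% roots))
})

test_that("substitution process matches its closed form", {
  set.seed(99)
  base <- random_protein(10000)
  ## zero distance: identity
  expect_identical(evolve_protein(base, 0), base)
  d <- 0.5
  out <- evolve_protein(base, d)
  p_obs <- mean(strsplit(base, "")[[1]] != strsplit(out, "")[[1]])
  p_exp <- expected_p_distance(d)
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("doubling a gene's rate multiplier doubles its expected distance", {
  tree <- species_tree_spec("(spA:0.25,spB:0.25)root;")
  anc <- ancestral_genome(
    chromosomes = list(c1 = data.frame(family = c("slow", "fast"),
                                       strand = "+")),
    gene_lengths = c(slow = 300, fast = 300))
  set.seed(5)
  roots <- c(slow = random_protein(300), fast = random_protein(300))
  sim <- simulate_history(tree, anc, event_rates(), seed = 1)
  dists <- vapply(1:50, function(s) {
    gs <- evolve_sequences(sim$truth, roots,
                           per_gene_rates = c(slow = 1, fast = 2),
                           seed = 1000 + s)
    g <- gs$genes[gs$genes$species == "spA", ]
    p <- vapply(c("slow", "fast"), function(f)
      1 - percent_identity(g$protein[g$family == f], roots[[f]]), 0)
    poisson_distance(p)
  }, c(slow = 0, fast = 0))
  m <- rowMeans(dists)
  ## expected 0.25 and 0.5 substitutions/site; linearity within
  ## Monte-Carlo error
  expect_lt(abs(m[["fast"]] / m[["slow"]] - 2), 0.25)
})

test_that("genome sets round-trip through FASTA/GFF3 exactly", {
  tree <- species_tree_spec(
    "((spA:0.1,spB:0.1)ab:0.1,spC:0.2)root;",
    wgd_events = list(list(branch = "ab", kind = "WGD", label = "1R")))
  sim <- simulate_history(tree, two_chrom_ancestor(), event_rates(), seed = 2)
  set.seed(2)
  roots <- setNames(vapply(c(100, 120, 90, 150, 60), random_protein, ""),
                    paste0("F", 1:5))
  gs <- evolve_sequences(sim$truth, roots, seed = 3)
  tmp <- withr::local_tempdir()
  write_genome_set(gs, sim$truth, tmp)
  back <- read_genome_set(tmp)
  ord <- function(df) {
    df <- df[order(df$species, df$gene_id), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(back$genes)[, c("gene_id", "species", "seq_id", "start",
                                   "end", "strand", "protein", "family")],
               ord(gs$genes)[, c("gene_id", "species", "seq_id", "start",
                                 "end", "strand", "protein", "family")])
  ## truth ledger TSV has one row per event
  ev <- utils::read.delim(file.path(tmp, "truth_events.tsv"))
  expect_equal(nrow(ev), nrow(sim$truth$events))
  ## GFF3 start column is internal start + 1
  lines <- readLines(file.path(tmp, "spA.gff3"))[-1]
  starts_file <- as.integer(vapply(strsplit(lines, "\t"), `[[`, "", 4))
  ga <- gs$genes[gs$genes$species == "spA", ]
  expect_equal(sort(starts_file), sort(as.integer(ga$start) + 1L))
})
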