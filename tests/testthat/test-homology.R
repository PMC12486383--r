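test_that("profile alignment handles identity and single-column cases", {
  msa <- c(r1 = "MKVLW", r2 = "MKVLW", r3 = "MRVLW")
  pa <- profile_align("MKVLW", msa)
  expect_equal(pa$query_in_ref, "MKVLW")
  expect_equal(percent_identity(pa$query_in_ref, msa[["r1"]]), 1)

  one <- profile_align("M", c(r = "M"))
  B <- opsinteny:::get_subst_matrix("BLOSUM62")
  expect_equal(one$score, B["M", "M"])
  expect_equal(one$moves, "M")

  expect_error(profile_align("", msa), "empty query")
  expect_error(profile_align("MKB2", msa), "alphabet")
})

test_that("profile alignment score equals the exhaustive path oracle", {
  params <- opsinteny:::default_align_params()
  set.seed(21)
  for (trial in 1:5) {
    ref <- setNames(vapply(1:3, function(i) random_protein(6), ""), 1:3)
    q <- random_protein(5)
    pa <- profile_align(q, ref, params)
    expect_equal(pa$score, oracle_profile_score(q, ref, params),
                 tolerance = 1e-9)
  }
  ## and never below the all-gap (double indel) alignment
  ref <- setNames(vapply(1:2, function(i) random_protein(8), ""), 1:2)
  q <- random_protein(4)
  worst <- -(params$gap_open + 7 * params$gap_extend) -
    (params$gap_open + 3 * params$gap_extend)
  expect_gte(profile_align(q, ref, params)$score, worst)
})

test_that("percent identity matches the literal column-count oracle", {
  expect_equal(percent_identity("A-C", "AGC"), 1)
  expect_equal(percent_identity("----", "AG--"), 0)
  expect_error(percent_identity("AB", "A"), "length mismatch")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    mk <- function() paste(sample(c("A", "R", "N", "-"), n, TRUE),
                           collapse = "")
    a <- mk(); b <- mk()
    expect_equal(percent_identity(a, b), oracle_identity(a, b))
  }
})

test_that("poisson distance inverts the substitution model", {
  expect_equal(as.numeric(poisson_distance(0)), 0)
  expect_equal(as.numeric(poisson_distance(0.5)),
               -(19 / 20) * log(1 - 10 / 19))
  ## strictly increasing below saturation
  p <- seq(0, 0.94, by = 0.01)
  expect_true(all(diff(as.numeric(poisson_distance(p))) > 0))
  ## saturation returns the ceiling with a flag
  d <- poisson_distance(c(0.2, 0.96), ceiling = 7)
  expect_equal(as.numeric(d[2]), 7)
  expect_equal(attr(d, "saturated"), c(FALSE, TRUE))
  ## round trip with the generator's closed form
  for (d0 in c(0.1, 0.4, 0.9))
    expect_equal(as.numeric(poisson_distance(expected_p_distance(d0))), d0,
                 tolerance = 1e-9)
})

test_that("reciprocal best hits group one-to-one orthologs perfectly", {
  w <- flat_world(n_fams = 6, tip_len = 0.15, seed = 7)
  g <- w$gs$genes
  proteomes <- split(setNames(g$protein, g$gene_id), g$species)
  groups <- build_orthogroups(proteomes)
  tab <- orthogroup_table(groups)
  fam <- setNames(g$family, paste(g$species, g$gene_id))
  tab$family <- fam[paste(tab$species, tab$gene_id)]
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(tab$family_id, tab$family)
  expect_equal(ari, 1)
  ## symmetric in species order
  groups_rev <- build_orthogroups(rev(proteomes))
  expect_equal(lapply(groups, `[[`, "members"),
               lapply(groups_rev, `[[`, "members"))
})

test_that("orthogroup edge cases behave", {
  expect_error(build_orthogroups(list(a = c(g = "MKV"))), "at least 2")
  expect_error(build_orthogroups(list(a = c(g = "MKV"), b = character())),
               "empty proteome")
  set.seed(3)
  two <- list(a = c(g1 = random_protein(80)), b = c(g2 = random_protein(80)))
  ## unrelated randoms fall below the identity floor: two singletons
  grp <- build_orthogroups(two, min_identity = 0.3)
  expect_equal(length(grp), 2)
  ## mutually similar pair: one orthogroup of two
  sim2 <- list(a = c(g1 = two$a[["g1"]]),
               b = c(g2 = evolve_protein(two$a[["g1"]], 0.1)))
  grp2 <- build_orthogroups(sim2, min_identity = 0.3)
  expect_equal(length(grp2), 1)
  expect_equal(grp2[[1]]$members, c("a|g1", "b|g2"))
})

test_that("anchor selection applies both chromosome rules", {
  mk_group <- function(id, members) list(family_id = id, members = members)
  genes <- toy_genes(data.frame(
    gene_id = paste0("g", 1:8),
    species = c("lampA", "lampA", "lampA", "lampB", "lampB", "lampA",
                "lampA", "lampB"),
    seq_id = c("chr1", "chr2", "chr3", "chr4", "chr1", "chr1", "chr2", "chr1"),
    start = 0:7 * 1000, end = 0:7 * 1000 + 500,
    stringsAsFactors = FALSE))
  groups <- list(
    mk_group("famX", c("lampA|g1", "lampA|g2", "lampA|g3")),   # 2 ops, 3 chr
    mk_group("famY", c("lampA|g6", "lampA|g7", "lampB|g8")),   # 2 ops, 2 chr
    mk_group("famZ", c("lampA|g1", "lampB|g4", "lampB|g5")))   # 1 ops chrom
  sel <- select_anchor_families(groups, genes, focal_species = "lampA",
                                opsin_chromosomes = c("chr1", "chr2"),
                                jawless_species = c("lampA", "lampB"))
  expect_equal(sel, "famX")
  ## monotonicity: raising either threshold never adds families
  for (mo in 1:3) for (ms in 1:4) {
    s <- select_anchor_families(groups, genes, "lampA", c("chr1", "chr2"),
                                min_opsin_chroms = mo, min_species_chroms = ms,
                                jawless_species = c("lampA", "lampB"))
    s_tight <- select_anchor_families(groups, genes, "lampA",
                                      c("chr1", "chr2"),
                                      min_opsin_chroms = mo + 1,
                                      min_species_chroms = ms,
                                      jawless_species = c("lampA", "lampB"))
    expect_true(all(s_tight %in% s))
    s_tight2 <- select_anchor_families(groups, genes, "lampA",
                                       c("chr1", "chr2"),
                                       min_opsin_chroms = mo,
                                       min_species_chroms = ms + 1,
                                       jawless_species = c("lampA", "lampB"))
    expect_true(all(s_tight2 %in% s))
  }
  expect_error(select_anchor_families(groups, genes, "lampA", character()),
               "empty opsin_chromosomes")
})

test_that("selection on simulated truth returns exactly the passing families", {
  sim <- simulate_paper_scenario(seed = 4)
  g <- sim$genome_set$genes
  ## truth orthogroups: one per family
  groups <- lapply(sort(unique(g$family)), function(f) {
    m <- g[g$family == f, ]
    list(family_id = f, members = sort(paste(m$species, m$gene_id, sep = "|")))
  })
  ops <- unique(g$seq_id[g$species == "sea_lamprey" & !is.na(g$subtype) &
                           g$subtype %in% c("LWS", "SWS1", "SWS2",
                                            "RH1", "RH2")])
  sel <- select_anchor_families(
    groups, g, "sea_lamprey", ops,
    jawless_species = c("sea_lamprey", "pouched_lamprey"))
  ## truth enumeration of the rule
  truth_pass <- vapply(groups, function(gr) {
    m <- g[paste(g$species, g$gene_id, sep = "|") %in% gr$members, ]
    focal <- unique(m$seq_id[m$species == "sea_lamprey" & m$seq_id %in% ops])
    jl <- unique(m$seq_id[m$species %in% c("sea_lamprey", "pouched_lamprey")])
    length(focal) >= 2 && length(jl) >= 3
  }, TRUE)
  expect_setequal(sel, vapply(groups, `[[`, "", "family_id")[truth_pass])
  ## in the default world the visual-opsin and curated families aside,
  ## exactly seven neighbour candidates pass
  cand <- setdiff(sel, c("SWS1", "SWS2", "RH", "LWS", "PP", "OPN3", "GNAI"))
  expect_equal(length(cand), 7)
})
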