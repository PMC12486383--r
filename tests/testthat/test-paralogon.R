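mini_genes <- function(keys) {
  ## keys: "species|seq_id|gene"
  parts <- strsplit(keys, "|", fixed = TRUE)
  toy_genes(data.frame(
    gene_id = vapply(parts, `[[`, "", 3),
    species = vapply(parts, `[[`, "", 1),
    seq_id = vapply(parts, `[[`, "", 2),
    start = seq_along(keys) * 1000,
    end = seq_along(keys) * 1000 + 500, stringsAsFactors = FALSE))
}

test_that("supermatrix concatenation tiles partitions and gaps absences", {
  genes <- mini_genes(c("s1|c1|g1", "s1|c2|g2", "s2|c1|g3", "s2|c2|g4"))
  msas <- list(
    famA = setNames(rep(strrep("M", 100), 4),
                    c("s1|g1", "s1|g2", "s2|g3", "s2|g4")),
    famB = setNames(rep(strrep("W", 150), 2), c("s1|g1", "s2|g3")))
  sm <- build_supermatrix(msas, genes)
  expect_equal(length(sm$rows), 4)
  expect_equal(unique(nchar(sm$rows)), 250)
  expect_equal(sm$partition$start, c(0, 100))
  expect_equal(sm$partition$end, c(100, 250))
  ## famB absent from the c2 rows: all-gap segment
  expect_equal(substr(sm$rows[["s1|c2"]], 101, 250), strrep("-", 150))
  expect_equal(substr(sm$rows[["s1|c1"]], 101, 250), strrep("W", 150))
  ## column count equals the sum of family alignment widths
  expect_equal(unique(nchar(sm$rows)), sum(vapply(msas, function(m)
    nchar(m[[1]]), 0)))
})

test_that("duplicate members on one chromosome resolve by consensus identity", {
  genes <- mini_genes(c("s1|c1|g1", "s1|c1|g2", "s2|c1|g3", "s2|c2|g4"))
  good <- strrep("M", 50)
  msas <- list(famA = setNames(c(good, strrep("W", 50), good, good),
                               c("s1|g1", "s1|g2", "s2|g3", "s2|g4")))
  sm <- build_supermatrix(msas, genes)
  expect_equal(sm$rows[["s1|c1"]], good)       # majority-like member kept
  expect_equal(sm$excluded$excluded_member, "s1|g2")
  ## ragged family rows are rejected
  bad <- list(famA = setNames(c("MM", "MMM"), c("s1|g1", "s2|g3")))
  expect_error(build_supermatrix(bad, genes), "unequal length")
})

test_that("neighbor joining recovers additive trees exactly", {
  ## ((A:1,B:2):1,(C:3,D:4)) as an additive distance matrix
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  expect_true("C;D" %in% tree_splits(tr))  # the split separating {A,B}|{C,D}
  ## branch lengths recovered: total tree length 1+2+1+3+4
  expect_equal(sum(tr$edge.length), 11)
  pend <- setNames(tr$edge.length[tr$edge[, 2] <= 4][order(tr$edge[tr$edge[, 2] <= 4, 2])],
                   tr$tip.label)
  expect_equal(unname(pend[c("A", "B", "C", "D")]), c(1, 2, 3, 4))
})

test_that("three-taxon trees solve the closed-form branch lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length[order(tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["x"]), (2 + 3 - 5) / 2)
  expect_equal(unname(len["y"]), (2 + 5 - 3) / 2)
  expect_equal(unname(len["z"]), (3 + 5 - 2) / 2)
})

test_that("nj topology is invariant to taxon order and validates input", {
  set.seed(12)
  tr0 <- ape::rtree(6)
  d <- cophenetic(tr0)
  t1 <- nj_tree(d)
  perm <- sample(rownames(d))
  t2 <- nj_tree(d[perm, perm])
  expect_setequal(tree_splits(t1), tree_splits(t2))
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 taxa")
  d_bad <- d; d_bad[1, 2] <- NA; d_bad[2, 1] <- NA
  expect_error(nj_tree(d_bad), "NaN")
  d_neg <- d; d_neg[1, 2] <- d_neg[2, 1] <- -1
  expect_error(nj_tree(d_neg), "negative")
})

test_that("nj recovers random additive trees exactly", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n)
    tr0$edge.length <- tr0$edge.length + 0.1
    d <- cophenetic(tr0)
    tr <- nj_tree(d)
    expect_setequal(tree_splits(tr), tree_splits(ape::unroot(tr0)))
    expect_equal(sum(tr$edge.length), sum(ape::unroot(tr0)$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("forced bipartitions get bootstrap support 1 and reruns reproduce", {
  set.seed(30)
  a <- random_protein(150)
  b <- evolve_protein(a, 1.4)
  rows <- c(p1 = a, p2 = a, q1 = b, q2 = b)
  st <- bootstrap_tree(rows, n_boot = 100, seed = 6)
  sp <- split_support(st, c("p1", "p2"))
  expect_true(sp$present)
  expect_equal(sp$support, 1)
  expect_true(sp$reliable)
  st2 <- bootstrap_tree(rows, n_boot = 100, seed = 6)
  expect_identical(st$supports, st2$supports)
  expect_error(bootstrap_tree(rows[1:3], n_boot = 100, seed = 1), "4 usable")
  expect_error(bootstrap_tree(rows, n_boot = 10, seed = 1), ">= 100")
})

test_that("rows sharing too few columns are dropped with a warning", {
  set.seed(33)
  left <- random_protein(100)
  rows <- c(a = paste0(left, strrep("-", 100)),
            b = paste0(evolve_protein(left, 0.2), strrep("-", 100)),
            c = paste0(evolve_protein(left, 0.5), strrep("-", 100)),
            d = paste0(evolve_protein(left, 0.9), strrep("-", 100)),
            lonely = paste0(strrep("-", 100), random_protein(100)))
  expect_warning(st <- bootstrap_tree(rows, n_boot = 100, seed = 2),
                 "comparable")
  expect_false("lonely" %in% st$tree$tip.label)
})

test_that("outgroup rooting places the root and carries supports", {
  set.seed(40)
  a <- random_protein(120)
  rows <- c(in1 = a, in2 = evolve_protein(a, 0.1),
            in3 = evolve_protein(a, 0.6), og = evolve_protein(a, 1.2))
  st <- bootstrap_tree(rows, n_boot = 100, seed = 3)
  rooted <- root_tree(st, "og")
  expect_true(ape::is.rooted(rooted$tree))
  expect_identical(rooted$supports, st$supports)
  ## rooting then unrooting preserves the bipartition set
  expect_setequal(tree_splits(ape::unroot(rooted$tree)), tree_splits(st$tree))
  expect_error(root_tree(st, names(rows)), "all taxa")
  ## non-monophyletic outgroup is refused with the offending split
  big <- c(p1 = a, p2 = a, q1 = evolve_protein(a, 1), q2 = evolve_protein(a, 1))
  st2 <- bootstrap_tree(big, n_boot = 100, seed = 4)
  expect_error(root_tree(st2, c("p1", "q1")), "not monophyletic")
})

test_that("supports are invariant to leaf-label permutation", {
  set.seed(50)
  a <- random_protein(150)
  rows <- c(m1 = a, m2 = evolve_protein(a, 0.05),
            n1 = evolve_protein(a, 0.8), n2 = evolve_protein(a, 0.85),
            o1 = evolve_protein(a, 1.5))
  st <- bootstrap_tree(rows, n_boot = 100, seed = 8)
  perm <- c(3, 1, 5, 2, 4)
  st_p <- bootstrap_tree(rows[perm], n_boot = 100, seed = 8)
  common <- intersect(names(st$supports), names(st_p$supports))
  expect_setequal(names(st$supports), names(st_p$supports))
  ## same splits found; supports agree up to bootstrap resampling noise
  expect_true(all(abs(st$supports[common] - st_p$supports[common]) <= 0.15))
})
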