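## Chromosome-keyed supermatrix phylogenetics: anchor-family alignments
## are concatenated per (species, chromosome) row, pairwise-deletion
## Poisson distances feed neighbor joining, and nonparametric column
## bootstrap gives per-bipartition supports with a reliability threshold.

row_key <- function(species, seq_id) paste(species, seq_id, sep = "|")

#' Build a chromosome-keyed supermatrix
#'
#' One row per (species, seq_id) with at least one member in any family;
#' each family occupies a fixed column interval (0-based half-open
#' partition table), filled from that chromosome's member and all-gap when
#' the family is absent. When a chromosome carries more than one member of
#' a family, the member with the highest identity to the family consensus
#' is kept (ties broken by gene id) and the exclusions are recorded.
#'
#' @param family_msas named list: family -> named character vector of
#'   equal-length aligned member sequences, names = `"species|gene_id"`.
#' @param genes `gene_records` mapping members to chromosomes.
#' @return object of class `supermatrix`: `rows` (named character vector
#'   keyed `"species|seq_id"`), `partition` (family, start, end),
#'   `excluded` (data.frame of dropped duplicate members).
#' @export
build_supermatrix <- function(family_msas, genes) {
  genes <- validate_gene_records(genes)
  key_of <- gene_key(genes$species, genes$gene_id)
  chrom_of <- setNames(row_key(genes$species, genes$seq_id), key_of)
  fams <- names(family_msas)
  widths <- integer(length(fams))
  for (f in seq_along(fams)) {
    msa <- family_msas[[f]]
    w <- unique(nchar(msa))
    if (length(w) != 1) stop("family MSA rows of unequal length: ", fams[f])
    widths[f] <- w
    if (!all(names(msa) %in% names(chrom_of)))
      stop("aligned sequence without a gene record in family ", fams[f])
  }
  partition <- data.frame(family = fams,
                          start = cumsum(c(0L, widths[-length(widths)])),
                          end = cumsum(widths), stringsAsFactors = FALSE)
  all_rows <- sort(unique(unlist(lapply(family_msas, function(m)
    unname(chrom_of[names(m)])))))
  excluded <- list()
  segs <- matrix("", nrow = length(all_rows), ncol = length(fams),
                 dimnames = list(all_rows, fams))
  for (f in seq_along(fams)) {
    msa <- family_msas[[f]]
    cons <- consensus_sequence(msa)
    rows_of <- unname(chrom_of[names(msa)])
    segs[, f] <- strrep("-", widths[f])
    for (rk in unique(rows_of)) {
      members <- names(msa)[rows_of == rk]
      if (length(members) > 1) {
        ids <- vapply(members, function(m) percent_identity(msa[[m]], cons), 0)
        keep <- sort(members[ids == max(ids)])[1]
        excluded[[length(excluded) + 1L]] <- data.frame(
          family = fams[f], row = rk,
          excluded_member = setdiff(members, keep), stringsAsFactors = FALSE)
      } else keep <- members
      segs[rk, f] <- msa[[keep]]
    }
  }
  rows <- apply(segs, 1, paste, collapse = "")
  structure(list(rows = rows, partition = partition,
                 excluded = if (length(excluded)) do.call(rbind, excluded)
                 else data.frame(family = character(), row = character(),
                                 excluded_member = character())),
            class = "supermatrix")
}

consensus_sequence <- function(msa) {
  chars <- do.call(rbind, strsplit(msa, ""))
  paste(apply(chars, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  }), collapse = "")
}

#' Write/read a supermatrix as aligned FASTA plus a partition TSV
#' @param sm a `supermatrix`.
#' @param prefix file prefix; writes `<prefix>.fasta` and
#'   `<prefix>.partitions.tsv`.
#' @export
write_supermatrix <- function(sm, prefix) {
  write_fasta(sm$rows, paste0(prefix, ".fasta"))
  write_tsv(sm$partition, paste0(prefix, ".partitions.tsv"))
  invisible(prefix)
}

## integer encoding of rows: residue index in AA20, NA for gap
sm_int_matrix <- function(rows) {
  chars <- do.call(rbind, strsplit(rows, ""))
  m <- matrix(match(chars, AA20), nrow = nrow(chars),
              dimnames = list(names(rows), NULL))
  m
}

#' Pairwise-deletion Poisson distance matrix from aligned rows
#'
#' Difference fraction over columns where both rows are non-gap, corrected
#' with [poisson_distance()]; pairs with no comparable column get the
#' saturation ceiling. Match and comparable-column counts are computed as
#' cross-products of a one-hot residue encoding, so bootstrap resamples
#' (`cols`) are cheap.
#' @param rows named character vector of equal-length aligned rows.
#' @param cols optional column index vector (bootstrap resample).
#' @return symmetric distance matrix.
#' @export
alignment_distances <- function(rows, cols = NULL) {
  enc <- distance_encoding(rows)
  alignment_distances_enc(enc, cols)
}

## one-hot encoding reused across bootstrap replicates
distance_encoding <- function(rows) {
  m <- sm_int_matrix(rows)
  n <- nrow(m); L <- ncol(m)
  oh <- matrix(0, n, L * 20L)
  idx <- which(!is.na(m), arr.ind = TRUE)
  oh[cbind(idx[, 1], (idx[, 2] - 1L) * 20L + m[idx])] <- 1
  ng <- matrix(0, n, L)
  ng[!is.na(m)] <- 1
  list(oh = oh, ng = ng, labels = rownames(m), L = L)
}

alignment_distances_enc <- function(enc, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(enc$L)
  oh_cols <- rep((cols - 1L) * 20L, each = 20L) + seq_len(20L)
  match_n <- tcrossprod(enc$oh[, oh_cols, drop = FALSE])
  comp_n <- tcrossprod(enc$ng[, cols, drop = FALSE])
  p <- ifelse(comp_n > 0, 1 - match_n / comp_n, 1)
  d <- matrix(as.numeric(poisson_distance(pmin(pmax(p, 0), 1))),
              nrow(p), ncol(p), dimnames = list(enc$labels, enc$labels))
  diag(d) <- 0
  d
}

#' Neighbor-joining tree with deterministic ordering
#'
#' Canonical NJ (via ape) on the lexicographically ordered taxon set, with
#' negative branch lengths clamped to 0.
#' @param d symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (nrow(d) < 3) stop("need >= 3 taxa")
  if (any(is.na(d)) || any(!is.finite(d))) stop("NaN/Inf entries in distance matrix")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal")
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix not symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

canonical_split <- function(tipset, all_tips) {
  ref <- sort(all_tips)[1]
  side <- if (ref %in% tipset) sort(setdiff(all_tips, tipset)) else sort(tipset)
  paste(side, collapse = ";")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge yields one split, keyed canonically by the side not
#' containing the alphabetically first tip.
#' @param tree a `phylo`.
#' @return character vector of canonical split keys.
#' @export
tree_splits <- function(tree) {
  labs <- tree$tip.label
  ntip <- length(labs)
  pp <- ape::prop.part(tree)
  splits <- character()
  for (s in pp) {
    if (length(s) <= 1 || length(s) >= ntip - 1) next
    splits <- c(splits, canonical_split(labs[s], labs))
  }
  unique(splits)
}

## tip descendants of a node (small trees; simple recursion over edges)
phangorn_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) phangorn_descendants(tree, k)))
}

#' Neighbor-joining tree with column-bootstrap bipartition supports
#'
#' Distances are pairwise-deletion Poisson distances over the supermatrix
#' columns; supports are the fraction of column resamples whose NJ tree
#' contains each bipartition of the full-data tree. Rows with fewer than
#' `min_comparable` comparable columns against some partner are dropped
#' with a warning.
#'
#' @param sm a `supermatrix` (or any named character vector of aligned
#'   rows via `rows =`).
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @param threshold reliability threshold on support (default 0.95).
#' @param min_comparable minimum fraction of mutually non-gap columns.
#' @return object of class `support_tree`: `tree` (unrooted phylo),
#'   `supports` (named numeric by canonical split), `reliable` (named
#'   logical), `threshold`.
#' @export
bootstrap_tree <- function(sm, n_boot = 100, seed = 1, threshold = 0.95,
                           min_comparable = 0.1) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  rows <- if (inherits(sm, "supermatrix")) sm$rows else sm
  m <- sm_int_matrix(rows)
  nongap <- !is.na(m)
  frac <- (nongap %*% t(nongap)) / ncol(m)
  diag(frac) <- 1
  dropped <- character()
  repeat {
    bad <- rowSums(frac < min_comparable)
    if (!any(bad > 0)) break
    ## greedily drop the row with the most low-overlap partners
    worst <- names(sort(bad[bad == max(bad)]))[1]
    dropped <- c(dropped, worst)
    keep <- setdiff(rownames(frac), worst)
    frac <- frac[keep, keep, drop = FALSE]
  }
  if (length(dropped)) {
    warning("dropping rows with <", min_comparable * 100,
            "% comparable columns: ", paste(dropped, collapse = ", "))
    rows <- rows[rownames(frac)]
  }
  if (length(rows) < 4) stop("fewer than 4 usable rows")
  enc <- distance_encoding(rows)
  full <- nj_tree(alignment_distances_enc(enc))
  target <- tree_splits(full)
  counts <- setNames(rep(0L, length(target)), target)
  set.seed(as.integer(seed))
  ncol_total <- nchar(rows[[1]])
  for (b in seq_len(n_boot)) {
    idx <- sample.int(ncol_total, ncol_total, replace = TRUE)
    bt <- nj_tree(alignment_distances_enc(enc, cols = idx))
    bs <- tree_splits(bt)
    hit <- target %in% bs
    counts[hit] <- counts[hit] + 1L
  }
  supports <- counts / n_boot
  structure(list(tree = full, supports = supports,
                 reliable = supports >= threshold, threshold = threshold),
            class = "support_tree")
}

#' Support for a specific bipartition
#' @param st a `support_tree`.
#' @param tipset character vector of tip labels on one side of the split.
#' @return list(support, reliable, present) — `present` says whether the
#'   split is in the full-data tree at all (support 0 otherwise).
#' @export
split_support <- function(st, tipset) {
  key <- canonical_split(tipset, st$tree$tip.label)
  if (!key %in% names(st$supports))
    return(list(support = 0, reliable = FALSE, present = FALSE))
  list(support = unname(st$supports[key]),
       reliable = unname(st$reliable[key]), present = TRUE)
}

#' Root a support tree on an outgroup
#'
#' Places the root on the branch separating the (monophyletic) outgroup
#' from the ingroup; supports carry over unchanged.
#' @param st a `support_tree`.
#' @param outgroup_labels tip labels of the outgroup.
#' @return a `support_tree` whose `tree` is rooted; `supports` unchanged.
#' @export
root_tree <- function(st, outgroup_labels) {
  tree <- st$tree
  tips <- tree$tip.label
  if (!all(outgroup_labels %in% tips)) stop("outgroup labels not in tree")
  if (length(outgroup_labels) >= length(tips))
    stop("outgroup cannot include all taxa")
  if (length(outgroup_labels) > 1 &&
      length(outgroup_labels) < length(tips) - 1) {
    key <- canonical_split(outgroup_labels, tips)
    if (!key %in% tree_splits(tree))
      stop("outgroup not monophyletic; offending bipartition: ", key)
  }
  rooted <- ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE)
  out <- st
  out$tree <- rooted
  out
}

#' Newick string of a support tree with supports as node labels
#' @param st a `support_tree`.
#' @return Newick string.
#' @export
support_tree_newick <- function(st) {
  tree <- st$tree
  ntip <- length(tree$tip.label)
  labs <- character(tree$Nnode)
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[phangorn_descendants(tree, node)]
    if (length(tips) <= 1 || length(tips) >= ntip - 1) { labs[node - ntip] <- ""; next }
    key <- canonical_split(tips, tree$tip.label)
    labs[node - ntip] <- if (key %in% names(st$supports))
      format(st$supports[[key]], digits = 3) else ""
  }
  tree$node.label <- labs
  ape::write.tree(tree)
}
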