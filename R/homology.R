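## Alignment, distance and orthogroup machinery: a query-to-profile
## affine-gap aligner, alignment identity, the 20-state Poisson distance
## correction matching the simulator's substitution model, reciprocal-
## best-hit orthogroups, and the synteny anchor-family selector.

default_align_params <- function() {
  list(substitution_matrix = "BLOSUM62", gap_open = 10, gap_extend = 1)
}

get_subst_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  m[AA20, AA20]
}

#' Column-frequency profile of an alignment
#'
#' Per-column amino-acid frequencies over non-gap residues; columns that
#' are entirely gaps get the uniform distribution. Frequencies sum to 1
#' in every column.
#' @param msa named character vector of equal-length aligned rows.
#' @return 20 x ncol numeric matrix (rows = amino acids).
#' @export
alignment_profile <- function(msa) {
  if (!length(msa)) stop("empty alignment")
  if (length(unique(nchar(msa))) != 1) stop("ragged alignment rows")
  chars <- do.call(rbind, strsplit(msa, ""))
  n <- ncol(chars)
  prof <- matrix(0, nrow = 20, ncol = n, dimnames = list(AA20, NULL))
  for (j in seq_len(n)) {
    col <- chars[, j]
    col <- col[col %in% AA20]
    if (!length(col)) prof[, j] <- 1 / 20
    else prof[, j] <- tabulate(match(col, AA20), 20) / length(col)
  }
  prof
}

#' Align a query protein to an alignment profile
#'
#' Global (end-to-end) affine-gap alignment of `query` against the
#' column-frequency profile of `ref_msa`, maximizing the summed expected
#' substitution score. Ties break deterministically (match > delete >
#' insert).
#'
#' @param query amino-acid string.
#' @param ref_msa named character vector of equal-length aligned rows.
#' @param params list with `substitution_matrix` (name of a Biostrings
#'   matrix), `gap_open`, `gap_extend` (positive penalties).
#' @return list of class `profile_alignment`: `score`, `moves` (string of
#'   M/D/I), `query_row` (query gapped to reference + inserted columns),
#'   `ref_gap_pattern` (positions of inserted columns), and
#'   `query_in_ref` (query projected onto the reference column space,
#'   inserted residues dropped).
#' @export
profile_align <- function(query, ref_msa, params = default_align_params()) {
  if (!nchar(query)) stop("empty query")
  q <- strsplit(query, "")[[1]]
  if (!all(q %in% AA20)) stop("alphabet violation in query")
  prof <- alignment_profile(ref_msa)
  B <- get_subst_matrix(params$substitution_matrix)
  colscores <- B[match(q, AA20), , drop = FALSE] %*% prof
  res <- profile_align_cpp(colscores, params$gap_open, params$gap_extend)
  moves <- strsplit(res$moves, "")[[1]]

  n <- ncol(prof)
  query_row <- character(length(moves))
  in_ref <- rep("-", n)
  inserted_at <- integer()
  qi <- 0L; cj <- 0L
  for (k in seq_along(moves)) {
    mv <- moves[k]
    if (mv == "M") {
      qi <- qi + 1L; cj <- cj + 1L
      query_row[k] <- q[qi]
      in_ref[cj] <- q[qi]
    } else if (mv == "D") {
      cj <- cj + 1L
      query_row[k] <- "-"
    } else {
      qi <- qi + 1L
      query_row[k] <- q[qi]
      inserted_at <- c(inserted_at, cj)
    }
  }
  structure(list(score = res$score, moves = res$moves,
                 query_row = paste(query_row, collapse = ""),
                 inserted_at = inserted_at,
                 query_in_ref = paste(in_ref, collapse = "")),
            class = "profile_alignment")
}

#' Percent identity between two gapped sequences
#'
#' Identical column pairs divided by columns where both sequences are
#' non-gap; 0 when no such column exists.
#' @param a,b equal-length (gapped) sequence strings.
#' @return fraction in [0, 1].
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch")
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  comp <- x != "-" & y != "-"
  if (!any(comp)) return(0)
  mean(x[comp] == y[comp])
}

#' Poisson-corrected distance for the 20-state equal-rates model
#'
#' d = -(19/20) log(1 - (20/19) p), the inverse of
#' [expected_p_distance()]. Saturated inputs (p >= 19/20) return the
#' configured ceiling and are flagged in the `"saturated"` attribute.
#' @param p observed difference fraction(s), in [0, 1].
#' @param ceiling distance returned for saturated p.
#' @return numeric vector of corrected distances.
#' @export
poisson_distance <- function(p, ceiling = 10) {
  stopifnot(all(p >= 0), all(p <= 1))
  sat <- p >= 19 / 20
  d <- numeric(length(p))
  d[!sat] <- -(19 / 20) * log(1 - (20 / 19) * p[!sat])
  d[sat] <- ceiling
  attr(d, "saturated") <- sat
  d
}

## ---- orthogroups ---------------------------------------------------------

gene_key <- function(species, gene_id) paste(species, gene_id, sep = "|")

pairwise_scores <- function(seqs_a, seqs_b, params) {
  ## score matrix (rows = a, cols = b) of global affine-gap alignments
  B <- get_subst_matrix(params$substitution_matrix)
  a_set <- Biostrings::AAStringSet(seqs_a)
  out <- matrix(NA_real_, length(seqs_a), length(seqs_b),
                dimnames = list(names(seqs_a), names(seqs_b)))
  for (j in seq_along(seqs_b)) {
    aln <- Biostrings::pairwiseAlignment(
      a_set, Biostrings::AAString(seqs_b[[j]]), type = "global",
      substitutionMatrix = B, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, scoreOnly = TRUE)
    out[, j] <- aln
  }
  out
}

## identity relative to the longer sequence: identical pairs over
## max(length). Counting only aligned pairs would let gap-chained
## alignments of unrelated proteins pass the identity floor.
pairwise_identity <- function(seq_a, seq_b, params) {
  B <- get_subst_matrix(params$substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b), type = "global",
    substitutionMatrix = B, gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  Biostrings::nmatch(aln) / max(nchar(seq_a), nchar(seq_b))
}

best_hits <- function(score_mat) {
  ## deterministic argmax per row: ties broken by lexicographic column name
  vapply(seq_len(nrow(score_mat)), function(i) {
    s <- score_mat[i, ]
    cand <- colnames(score_mat)[s == max(s)]
    sort(cand)[1]
  }, "")
}

#' Build orthogroups by reciprocal-best-hit clustering
#'
#' Edges are reciprocal best hits by global alignment score between every
#' species pair, filtered at `min_identity` alignment identity;
#' orthogroups are the connected components. To keep whole-genome
#' duplicates together (a reciprocal best hit links only one in-paralog
#' pair), every within-species pair with positive alignment score and
#' identity at least `min_identity` is also an edge (paralog
#' recruitment). The result is deterministic: ties break on lexicographic
#' gene id and orthogroups are numbered by their smallest member key.
#'
#' @param proteomes named list: species -> named character vector of
#'   proteins (names = gene ids).
#' @param min_identity minimum alignment identity for an edge (fraction).
#' @param params alignment parameters, see [default_align_params()].
#' @return list of orthogroups, each `list(family_id, members)` with
#'   members as `"species|gene_id"` keys.
#' @export
build_orthogroups <- function(proteomes, min_identity = 0.3,
                              params = default_align_params()) {
  if (length(proteomes) < 2) stop("need at least 2 species")
  for (sp in names(proteomes))
    if (!length(proteomes[[sp]])) stop("empty proteome: ", sp)
  species <- sort(names(proteomes))
  keyed <- list()
  for (sp in species) {
    v <- proteomes[[sp]]
    names(v) <- gene_key(sp, names(v))
    keyed[[sp]] <- v
  }
  edges <- character()
  seq_of <- function(key) {
    sp <- sub("\\|.*$", "", key); id <- sub("^[^|]*\\|", "", key)
    proteomes[[sp]][[id]]
  }
  id_edge <- function(a, b) {
    pid <- pairwise_identity(seq_of(a), seq_of(b), params)
    if (pid >= min_identity) edges <<- c(edges, a, b)
  }
  add_rbh_edges <- function(sa, sb) {
    m_ab <- pairwise_scores(keyed[[sa]], keyed[[sb]], params)
    bh_ab <- best_hits(m_ab); names(bh_ab) <- rownames(m_ab)
    bh_ba <- best_hits(t(m_ab)); names(bh_ba) <- colnames(m_ab)
    for (a in names(bh_ab)) {
      b <- bh_ab[[a]]
      if (identical(bh_ba[[b]], a) && a < b) id_edge(a, b)
    }
  }
  add_paralog_edges <- function(sp) {
    m <- pairwise_scores(keyed[[sp]], keyed[[sp]], params)
    keys <- rownames(m)
    for (i in seq_along(keys)) for (j in seq_along(keys)) {
      if (j <= i || m[i, j] <= 0) next
      id_edge(keys[i], keys[j])
    }
  }
  for (i in seq_along(species)) {
    add_paralog_edges(species[i])
    if (i < length(species))
      for (j in (i + 1):length(species)) add_rbh_edges(species[i], species[j])
  }
  all_keys <- sort(unlist(lapply(keyed, names), use.names = FALSE))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(all_keys)
  if (length(edges)) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)
  groups <- split(all_keys, comp$membership[all_keys])
  groups <- groups[order(vapply(groups, function(x) sort(x)[1], ""))]
  lapply(seq_along(groups), function(i)
    list(family_id = sprintf("OG%04d", i), members = sort(groups[[i]])))
}

#' Orthogroup membership as a flat table
#' @param groups result of [build_orthogroups()].
#' @return data.frame family_id, species, gene_id.
#' @export
orthogroup_table <- function(groups) {
  do.call(rbind, lapply(groups, function(g) data.frame(
    family_id = g$family_id,
    species = sub("\\|.*$", "", g$members),
    gene_id = sub("^[^|]*\\|", "", g$members),
    stringsAsFactors = FALSE)))
}

#' Select synteny anchor families
#'
#' A family is selected iff (a) its members in the focal species occupy
#' at least `min_opsin_chroms` distinct chromosomes among the
#' opsin-bearing ones, and (b) its members across the jawless-group
#' species (pooled by default, per species with `per_species = TRUE`)
#' occupy at least `min_species_chroms` distinct chromosomes.
#'
#' @param groups orthogroups from [build_orthogroups()] (or truth-derived
#'   groups in the same shape).
#' @param genes `gene_records` covering the member genes.
#' @param focal_species the species whose opsin-bearing chromosomes anchor
#'   the selection (the sea-lamprey role).
#' @param opsin_chromosomes character set of seq_ids carrying accepted
#'   visual opsins in the focal species.
#' @param jawless_species species whose chromosomes count toward (b);
#'   defaults to the focal species only.
#' @param min_opsin_chroms,min_species_chroms selection thresholds.
#' @param per_species count rule (b) per species instead of pooled.
#' @return character vector of selected family_ids.
#' @export
select_anchor_families <- function(groups, genes, focal_species,
                                   opsin_chromosomes,
                                   min_opsin_chroms = 2,
                                   min_species_chroms = 3,
                                   jawless_species = focal_species,
                                   per_species = FALSE) {
  if (!length(opsin_chromosomes)) stop("empty opsin_chromosomes")
  if (!focal_species %in% genes$species) stop("focal species absent from genes")
  key_of <- gene_key(genes$species, genes$gene_id)
  seq_of <- setNames(genes$seq_id, key_of)
  sp_of <- setNames(genes$species, key_of)
  selected <- character()
  for (g in groups) {
    mem <- g$members
    mseq <- seq_of[mem]; msp <- sp_of[mem]
    focal_ops <- unique(mseq[msp == focal_species & mseq %in% opsin_chromosomes])
    if (length(focal_ops) < min_opsin_chroms) next
    jl <- msp %in% jawless_species
    ok_b <- if (per_species) {
      ## strict mode: some single jawless species must reach the threshold
      counts <- tapply(mseq[jl], msp[jl], function(x) length(unique(x)))
      length(counts) > 0 && any(counts >= min_species_chroms)
    } else {
      length(unique(mseq[jl])) >= min_species_chroms
    }
    if (ok_b) selected <- c(selected, g$family_id)
  }
  selected
}
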