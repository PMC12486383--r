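## Synthetic-genome simulator: explicit duplication histories (tandem
## duplications, whole-genome duplications, a cyclostome-style genome
## triplication, losses, translocations) over a species tree, with a full
## truth ledger so every downstream inference can be scored against the
## generating history.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Species tree specification with genome-duplication events
#'
#' Branches are identified by the label of the node/tip they lead to, so
#' the Newick string must carry unique internal node labels. WGD events
#' are applied at the start of their branch; a `WGD` doubles and a
#' `TRIPLICATION` triples every chromosome, preserving gene order and
#' strand on each copy.
#'
#' @param newick rooted Newick string with internal node labels.
#' @param wgd_events list of `list(branch=, kind="WGD"|"TRIPLICATION",
#'   label=)`; `label` names the event (e.g. "1R") and is referenced by
#'   subtype split rules.
#' @param branch_rates named numeric, per-branch substitution-rate
#'   multipliers (default 1 for unnamed branches). All values must be > 0.
#' @return object of class `species_tree_spec`.
#' @export
species_tree_spec <- function(newick, wgd_events = list(), branch_rates = NULL) {
  tree <- ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse newick")
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    stop("all internal nodes must be labelled (branch ids)")
  labels <- c(tree$tip.label, tree$node.label)
  if (any(duplicated(labels))) stop("duplicated node labels")
  valid_branches <- labels[labels != tree$node.label[1]]
  for (ev in wgd_events) {
    stopifnot(all(c("branch", "kind") %in% names(ev)))
    if (!ev$branch %in% valid_branches)
      stop("wgd event on unknown branch: ", ev$branch)
    if (!ev$kind %in% c("WGD", "TRIPLICATION"))
      stop("wgd event kind must be WGD or TRIPLICATION")
    if (is.null(ev$label)) stop("wgd event needs a label")
  }
  if (!is.null(branch_rates)) {
    stopifnot(!is.null(names(branch_rates)), all(branch_rates > 0),
              all(is.finite(branch_rates)))
    unknown <- setdiff(names(branch_rates), valid_branches)
    if (length(unknown)) stop("branch_rates for unknown branches: ",
                              paste(unknown, collapse = ", "))
  }
  structure(list(tree = tree, wgd_events = wgd_events,
                 branch_rates = branch_rates %||% numeric()),
            class = "species_tree_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ancestral genome specification
#'
#' @param chromosomes named list; each element a data.frame with columns
#'   `family` and `strand` giving the ancestral gene order. Chromosome
#'   names must not contain underscores (copy suffixes are appended with
#'   `_` at each WGD).
#' @param gene_lengths named integer vector, protein length (aa) per
#'   family; all >= 50.
#' @param intergene_gap_bp gap laid out between consecutive genes and used
#'   for tandem-duplicate insertion (bp, default 5000).
#' @param subtype_map named character: family -> truth subtype label
#'   (families absent from the map get subtype NA, i.e. non-opsin).
#' @param subtype_splits named list: family -> `list(event=, subtypes=)`;
#'   at the named WGD event, copy k of a gene of that family acquires
#'   truth subtype `subtypes[k]` (e.g. the RH1/RH2 split at 1R).
#' @return object of class `ancestral_genome`.
#' @export
ancestral_genome <- function(chromosomes, gene_lengths,
                             intergene_gap_bp = 5000,
                             subtype_map = character(),
                             subtype_splits = list()) {
  stopifnot(is.list(chromosomes), !is.null(names(chromosomes)))
  if (any(grepl("_", names(chromosomes))))
    stop("chromosome names must not contain '_'")
  fams <- unlist(lapply(chromosomes, function(x) x$family))
  if (any(duplicated(fams))) stop("family labels must be unique in the ancestor")
  if (!all(fams %in% names(gene_lengths)))
    stop("every family needs a gene length")
  if (any(gene_lengths < 50)) stop("gene lengths must be >= 50 aa")
  stopifnot(intergene_gap_bp > 0)
  for (ch in chromosomes) stopifnot(all(ch$strand %in% c("+", "-")))
  structure(list(chromosomes = chromosomes,
                 gene_lengths = gene_lengths,
                 intergene_gap_bp = intergene_gap_bp,
                 subtype_map = subtype_map,
                 subtype_splits = subtype_splits),
            class = "ancestral_genome")
}

#' Per-branch event rates
#'
#' `tandem_dup` is a per-branch rate (expected events per unit branch
#' length); `loss` and `translocation` are per-gene per-unit-branch-length
#' rates. All rates must be finite and >= 0.
#' @param tandem_dup,loss,translocation non-negative rates.
#' @return object of class `event_rates`.
#' @export
event_rates <- function(tandem_dup = 0, loss = 0, translocation = 0) {
  v <- c(tandem_dup = tandem_dup, loss = loss, translocation = translocation)
  stopifnot(all(is.finite(v)), all(v >= 0))
  structure(as.list(v), class = "event_rates")
}

## ---- internal genome-state helpers -------------------------------------

new_gene_counter <- function() {
  env <- new.env()
  env$n <- 0L
  env
}

fresh_gene_id <- function(counter) {
  counter$n <- counter$n + 1L
  sprintf("g%05d", counter$n)
}

root_state <- function(ancestor, counter, parent_env) {
  rows <- list()
  for (chrom in names(ancestor$chromosomes)) {
    ch <- ancestor$chromosomes[[chrom]]
    for (i in seq_len(nrow(ch))) {
      fam <- ch$family[i]
      id <- fresh_gene_id(counter)
      parent_env$parent[[id]] <- NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = i, gene_id = id, family = fam,
        subtype = unname(ancestor$subtype_map[fam]) %||% NA_character_,
        strand = ch$strand[i],
        len_aa = unname(ancestor$gene_lengths[fam]),
        stringsAsFactors = FALSE)
    }
  }
  st <- do.call(rbind, rows)
  st$subtype[!st$family %in% names(ancestor$subtype_map)] <- NA_character_
  st[order(st$chrom, st$pos), ]
}

apply_wgd <- function(state, kind, label, ancestor, counter, parent_env) {
  nfac <- if (kind == "WGD") 2L else 3L
  suffixes <- LETTERS[seq_len(nfac)]
  out <- list()
  for (k in seq_len(nfac)) {
    copy <- state
    copy$chrom <- paste(state$chrom, suffixes[k], sep = "_")
    new_ids <- vapply(seq_len(nrow(copy)), function(i) fresh_gene_id(counter), "")
    for (i in seq_len(nrow(copy))) parent_env$parent[[new_ids[i]]] <- copy$gene_id[i]
    copy$gene_id <- new_ids
    ## subtype resolution at this event (e.g. RH -> RH1 / RH2 at 1R)
    for (fam in names(ancestor$subtype_splits)) {
      rule <- ancestor$subtype_splits[[fam]]
      if (identical(rule$event, label)) {
        hit <- copy$family == fam
        copy$subtype[hit] <- rule$subtypes[k]
      }
    }
    out[[k]] <- copy
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos), ]
}

renumber_pos <- function(state) {
  state <- state[order(state$chrom, state$pos), ]
  for (ch in unique(state$chrom)) {
    idx <- which(state$chrom == ch)
    state$pos[idx] <- seq_along(idx)
  }
  state
}

insert_tandem_copy <- function(state, gene_id, counter, parent_env) {
  i <- which(state$gene_id == gene_id)
  if (length(i) != 1) stop("tandem duplication of unknown gene ", gene_id)
  src <- state[i, ]
  copy <- src
  copy$gene_id <- fresh_gene_id(counter)
  parent_env$parent[[copy$gene_id]] <- src$gene_id
  copy$pos <- src$pos + 0.5  # immediately downstream, same strand
  list(state = renumber_pos(rbind(state, copy)), new_id = copy$gene_id)
}

remove_gene <- function(state, gene_id) {
  renumber_pos(state[state$gene_id != gene_id, , drop = FALSE])
}

move_gene <- function(state, gene_id, to_chrom, new_strand) {
  i <- which(state$gene_id == gene_id)
  if (length(i) != 1) stop("translocation of unknown gene ", gene_id)
  if (!to_chrom %in% state$chrom) stop("translocation target chromosome absent: ", to_chrom)
  state$chrom[i] <- to_chrom
  state$pos[i] <- max(state$pos[state$chrom == to_chrom]) + 1
  state$strand[i] <- new_strand
  renumber_pos(state)
}

## ---- main history simulation -------------------------------------------

#' Simulate a duplication/loss/translocation history over a species tree
#'
#' Events on a branch are applied in a fixed order at the branch start:
#' configured WGD/triplication events, then scripted events, then
#' Poisson-drawn stochastic events (tandem duplications, losses,
#' translocations). Gene ids are stable along lineages; WGD/tandem copies
#' get fresh ids with recorded parents, so every extant gene traces to a
#' single root gene.
#'
#' @param tree a [species_tree_spec()].
#' @param ancestor an [ancestral_genome()].
#' @param rates an [event_rates()].
#' @param seed integer RNG seed.
#' @param scripted optional data.frame of deterministic events with
#'   columns `branch`, `kind` (TANDEM_DUP/LOSS/TRANSLOCATION), `family`,
#'   `chrom` (chromosome id at that point in the history), and for
#'   translocations `to_chrom` and `new_strand` ("+"/"-" or NA = random).
#' @param max_genes cap on expected and realized per-species gene count;
#'   rates implying a larger genome are rejected up front.
#' @return list with `truth` (class `truth_history`) and `genomes`
#'   (skeleton `gene_records` per species: coordinates and strands laid
#'   out, proteins NA until [evolve_sequences()]).
#' @export
simulate_history <- function(tree, ancestor, rates, seed,
                             scripted = NULL, max_genes = 10000) {
  stopifnot(inherits(tree, "species_tree_spec"),
            inherits(ancestor, "ancestral_genome"),
            inherits(rates, "event_rates"))
  check_expected_size(tree, ancestor, rates, max_genes)
  set.seed(as.integer(seed))

  phy <- tree$tree
  ntip <- length(phy$tip.label)
  labels <- c(phy$tip.label, phy$node.label)
  counter <- new_gene_counter()
  parent_env <- new.env(); parent_env$parent <- list()
  events <- list()
  node_states <- list()

  wgd_by_branch <- split(tree$wgd_events,
                         vapply(tree$wgd_events, `[[`, "", "branch"))
  scripted_by_branch <- if (!is.null(scripted) && nrow(scripted))
    split(scripted, scripted$branch) else list()

  record <- function(kind, branch, label, gene_ids, result_ids, chrom, detail = "") {
    events[[length(events) + 1L]] <<- data.frame(
      event = kind, branch = branch, label = label,
      gene_ids = paste(gene_ids, collapse = ","),
      result_ids = paste(result_ids, collapse = ","),
      chrom = chrom, detail = detail, stringsAsFactors = FALSE)
  }

  apply_branch <- function(state, branch, blen) {
    ## 1. genome-duplication events
    for (ev in wgd_by_branch[[branch]] %||% list()) {
      before_ids <- state$gene_id
      state <- apply_wgd(state, ev$kind, ev$label, ancestor, counter, parent_env)
      record(ev$kind, branch, ev$label, before_ids, state$gene_id, "*")
    }
    ## 2. scripted events
    sc <- scripted_by_branch[[branch]]
    if (!is.null(sc)) for (i in seq_len(nrow(sc))) {
      row <- sc[i, ]
      hit <- which(state$family == row$family & state$chrom == row$chrom)
      if (length(hit) != 1)
        stop("scripted event does not identify one gene: ",
             row$family, "@", row$chrom, " on ", branch)
      gid <- state$gene_id[hit]
      if (row$kind == "LOSS") {
        state <- remove_gene(state, gid)
        record("LOSS", branch, "", gid, character(), row$chrom)
      } else if (row$kind == "TANDEM_DUP") {
        res <- insert_tandem_copy(state, gid, counter, parent_env)
        state <- res$state
        record("TANDEM_DUP", branch, "", gid, res$new_id, row$chrom)
      } else if (row$kind == "TRANSLOCATION") {
        strand <- row$new_strand
        if (is.na(strand)) strand <- sample(c("+", "-"), 1)
        state <- move_gene(state, gid, row$to_chrom, strand)
        record("TRANSLOCATION", branch, "", gid, gid, row$to_chrom,
               detail = paste0("from=", row$chrom))
      } else stop("unknown scripted event kind: ", row$kind)
    }
    ## 3. stochastic events
    n_td <- rpois(1, rates$tandem_dup * blen)
    for (k in seq_len(n_td)) {
      if (!nrow(state)) break
      gid <- state$gene_id[sample.int(nrow(state), 1)]
      chrom <- state$chrom[state$gene_id == gid]
      res <- insert_tandem_copy(state, gid, counter, parent_env)
      state <- res$state
      record("TANDEM_DUP", branch, "", gid, res$new_id, chrom)
    }
    n_loss <- rpois(1, rates$loss * blen * nrow(state))
    for (k in seq_len(n_loss)) {
      if (!nrow(state)) break
      gid <- state$gene_id[sample.int(nrow(state), 1)]
      chrom <- state$chrom[state$gene_id == gid]
      state <- remove_gene(state, gid)
      record("LOSS", branch, "", gid, character(), chrom)
    }
    n_tl <- rpois(1, rates$translocation * blen * nrow(state))
    for (k in seq_len(n_tl)) {
      chroms <- unique(state$chrom)
      if (nrow(state) < 1 || length(chroms) < 2) break
      gid <- state$gene_id[sample.int(nrow(state), 1)]
      from <- state$chrom[state$gene_id == gid]
      targets <- setdiff(chroms, from)
      to <- targets[sample.int(length(targets), 1)]
      strand <- sample(c("+", "-"), 1)
      state <- move_gene(state, gid, to, strand)
      record("TRANSLOCATION", branch, "", gid, gid, to,
             detail = paste0("from=", from))
    }
    if (nrow(state) > max_genes)
      stop("runaway duplication: genome exceeded max_genes cap")
    state
  }

  recurse <- function(node, state) {
    lab <- labels[node]
    node_states[[lab]] <<- state
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    for (child in kids) {
      blen <- phy$edge.length[which(phy$edge[, 1] == node & phy$edge[, 2] == child)]
      child_state <- apply_branch(state, labels[child], blen)
      recurse(child, child_state)
    }
  }

  st0 <- root_state(ancestor, counter, parent_env)
  root_node <- ntip + 1L
  recurse(root_node, st0)

  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(event = character(), branch = character(), label = character(),
               gene_ids = character(), result_ids = character(),
               chrom = character(), detail = character())

  ## ancestry maps
  parent <- parent_env$parent
  trace_root <- function(g) {
    while (!is.na(parent[[g]] %||% NA_character_)) g <- parent[[g]]
    g
  }
  tips <- phy$tip.label
  extant <- list()
  gene_ancestry <- character()
  for (sp in tips) {
    st <- node_states[[sp]]
    extant[[sp]] <- st
    for (g in st$gene_id) gene_ancestry[g] <- trace_root(g)
  }
  truth <- structure(list(
    tree_spec = tree, ancestor = ancestor, rates = rates, seed = seed,
    node_states = node_states, events = ev_df, parent = parent,
    gene_ancestry = gene_ancestry, extant = extant
  ), class = "truth_history")

  genomes <- lapply(tips, function(sp) layout_genome(truth, sp))
  names(genomes) <- tips
  list(truth = truth, genomes = genomes)
}

check_expected_size <- function(tree, ancestor, rates, max_genes) {
  phy <- tree$tree
  labels <- c(phy$tip.label, phy$node.label)
  n0 <- sum(vapply(ancestor$chromosomes, nrow, 1L))
  wgd_by_branch <- split(tree$wgd_events,
                         vapply(tree$wgd_events, `[[`, "", "branch"))
  worst <- 0
  walk <- function(node, e) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    if (!length(kids)) { worst <<- max(worst, e); return(invisible()) }
    for (child in kids) {
      blen <- phy$edge.length[which(phy$edge[, 1] == node & phy$edge[, 2] == child)]
      fac <- 1
      for (ev in wgd_by_branch[[labels[child]]] %||% list())
        fac <- fac * if (ev$kind == "WGD") 2 else 3
      walk(child, e * fac + rates$tandem_dup * blen)
    }
  }
  walk(length(phy$tip.label) + 1L, n0)
  if (worst > max_genes)
    stop("rates imply expected genome size ", round(worst),
         " > max_genes cap (runaway duplication)")
  invisible(TRUE)
}

#' Extant chromosome copy counts per ancestral chromosome
#'
#' Parses the copy-path encoding of extant chromosome ids (suffixes
#' appended at each WGD/triplication) against the truth ledger.
#' @param truth a `truth_history`.
#' @return data.frame species, root_chrom, n_copies.
#' @export
chromosome_copy_counts <- function(truth) {
  rows <- list()
  for (sp in names(truth$extant)) {
    ch <- unique(truth$extant[[sp]]$chrom)
    root <- vapply(strsplit(ch, "_"), `[[`, "", 1)
    tab <- table(root)
    rows[[sp]] <- data.frame(species = sp, root_chrom = names(tab),
                             n_copies = as.integer(tab), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## ---- genome layout and sequence evolution ------------------------------

layout_genome <- function(truth, species, jitter_bp = 0) {
  st <- truth$extant[[species]]
  if (!nrow(st)) {
    return(gene_records(character(), character(), character(), numeric(),
                        numeric(), character()))
  }
  gap <- truth$ancestor$intergene_gap_bp
  st <- st[order(st$chrom, st$pos), ]
  start <- numeric(nrow(st)); end <- numeric(nrow(st))
  for (ch in unique(st$chrom)) {
    idx <- which(st$chrom == ch)
    x <- 0
    for (i in idx) {
      start[i] <- x
      end[i] <- x + st$len_aa[i] * 3
      x <- end[i] + gap + if (jitter_bp > 0) sample.int(jitter_bp, 1) else 0
    }
  }
  gene_records(gene_id = st$gene_id, species = species, seq_id = st$chrom,
               start = start, end = end, strand = st$strand,
               subtype = st$subtype, family = st$family)
}

#' Evolve one protein for an expected number of substitutions per site
#'
#' 20-state continuous-time model with equal exchangeabilities and equal
#' equilibrium frequencies: each site stays with probability
#' 1/20 + (19/20) exp(-20 d / 19) and otherwise moves uniformly to one of
#' the 19 other residues. No indels.
#' @param seq amino-acid string (standard 20-letter alphabet).
#' @param d expected substitutions per site (>= 0).
#' @return evolved sequence string.
#' @export
evolve_protein <- function(seq, d) {
  stopifnot(d >= 0)
  if (d == 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  if (!all(x %in% AA20)) stop("unknown amino-acid symbols in sequence")
  p_same <- 1 / 20 + (19 / 20) * exp(-20 * d / 19)
  change <- runif(length(x)) >= p_same
  if (any(change)) {
    idx <- which(change)
    cur <- match(x[idx], AA20)
    ## uniform over the 19 other residues
    off <- sample.int(19, length(idx), replace = TRUE)
    x[idx] <- AA20[((cur - 1 + off) %% 20) + 1]
  }
  paste(x, collapse = "")
}

#' Expected proportion of differing sites at distance d
#'
#' Closed form of the equal-rates 20-state model.
#' @param d expected substitutions per site.
#' @return expected difference proportion in [0, 19/20).
#' @export
expected_p_distance <- function(d) (19 / 20) * (1 - exp(-20 * d / 19))

#' Generate a random protein sequence
#' @param n length (aa).
#' @return amino-acid string.
#' @export
random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Evolve protein sequences along a simulated history
#'
#' Walks the same species tree as [simulate_history()]; genes created on a
#' branch inherit their source sequence at the branch start, then every
#' gene evolves by `branch length x branch multiplier x family multiplier`
#' expected substitutions per site.
#'
#' @param truth a `truth_history`.
#' @param root_proteins named character vector: family -> root protein.
#' @param per_gene_rates named numeric: family -> rate multiplier
#'   (default 1).
#' @param seed integer RNG seed.
#' @return a `genome_set`: list with `genes` (gene_records across species,
#'   proteins filled) and `chrom_lengths`.
#' @export
evolve_sequences <- function(truth, root_proteins, per_gene_rates = NULL, seed = 1) {
  stopifnot(inherits(truth, "truth_history"))
  fams <- unique(unlist(lapply(truth$node_states, function(s) s$family)))
  miss <- setdiff(fams, names(root_proteins))
  if (length(miss)) stop("missing root proteins for: ", paste(miss, collapse = ", "))
  for (s in root_proteins)
    if (!all(strsplit(s, "")[[1]] %in% AA20))
      stop("unknown amino-acid symbols in root proteins")
  if (is.null(per_gene_rates)) per_gene_rates <- setNames(rep(1, length(fams)), fams)
  stopifnot(all(per_gene_rates > 0))
  set.seed(as.integer(seed))

  phy <- truth$tree_spec$tree
  labels <- c(phy$tip.label, phy$node.label)
  brates <- truth$tree_spec$branch_rates
  parent <- truth$parent
  seq_by_species <- list()

  inherit_seq <- function(g, parent_seqs) {
    ## follow parent pointers until a gene with a known sequence
    while (is.null(parent_seqs[[g]])) {
      p <- parent[[g]] %||% NA_character_
      if (is.na(p)) stop("gene without ancestral sequence: ", g)
      g <- p
    }
    parent_seqs[[g]]
  }

  recurse <- function(node, seqs) {
    lab <- labels[node]
    st <- truth$node_states[[lab]]
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    if (!length(kids)) { seq_by_species[[lab]] <<- seqs; return(invisible()) }
    for (child in kids) {
      clab <- labels[child]
      blen <- phy$edge.length[which(phy$edge[, 1] == node & phy$edge[, 2] == child)]
      bmult <- if (clab %in% names(brates)) brates[[clab]] else 1
      cst <- truth$node_states[[clab]]
      cseqs <- list()
      for (i in seq_len(nrow(cst))) {
        g <- cst$gene_id[i]
        s0 <- inherit_seq(g, seqs)
        d <- blen * bmult * unname(per_gene_rates[cst$family[i]])
        cseqs[[g]] <- evolve_protein(s0, d)
      }
      recurse(child, cseqs)
    }
  }

  root_node <- length(phy$tip.label) + 1L
  root_st <- truth$node_states[[labels[root_node]]]
  seqs0 <- list()
  for (i in seq_len(nrow(root_st)))
    seqs0[[root_st$gene_id[i]]] <- unname(root_proteins[root_st$family[i]])
  recurse(root_node, seqs0)

  all_genes <- list(); chrom_lengths <- list()
  for (sp in phy$tip.label) {
    gr <- layout_genome(truth, sp)
    gr$protein <- vapply(gr$gene_id, function(g) seq_by_species[[sp]][[g]], "")
    all_genes[[sp]] <- gr
    agg <- tapply(gr$end, gr$seq_id, max)
    chrom_lengths[[sp]] <- data.frame(
      species = sp, seq_id = names(agg),
      length = as.numeric(agg) + truth$ancestor$intergene_gap_bp,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, c(all_genes, list(make.row.names = FALSE)))
  structure(list(genes = validate_gene_records(genes),
                 chrom_lengths = do.call(rbind, c(chrom_lengths,
                                                  list(make.row.names = FALSE)))),
            class = "genome_set")
}

## ---- genome-set serialization ------------------------------------------

#' Write a genome set and its truth ledger to a directory
#'
#' One protein FASTA and one GFF3 (1-based inclusive) per species, the
#' event ledger and gene-ancestry map as TSV. Re-reading reproduces gene
#' coordinates, strands and sequences exactly.
#' @param gs a `genome_set`.
#' @param truth the matching `truth_history`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_genome_set <- function(gs, truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (sp in unique(gs$genes$species)) {
    g <- gs$genes[gs$genes$species == sp, ]
    write_fasta(setNames(g$protein, g$gene_id),
                file.path(outdir, paste0(sp, ".faa")))
    write_species_gff3(g, file.path(outdir, paste0(sp, ".gff3")))
  }
  write_tsv(truth$events, file.path(outdir, "truth_events.tsv"))
  write_tsv(data.frame(gene_id = names(truth$gene_ancestry),
                       root_gene = unname(truth$gene_ancestry)),
            file.path(outdir, "gene_ancestry.tsv"))
  write_tsv(gs$chrom_lengths, file.path(outdir, "chromosomes.tsv"))
  invisible(outdir)
}

write_species_gff3 <- function(genes, path) {
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(is.na(genes$family), "", paste0(";family=", genes$family)),
                  ifelse(is.na(genes$subtype), "", paste0(";subtype=", genes$subtype)))
  lines <- sprintf("%s\topsinteny\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$seq_id, as.integer(genes$start) + 1L,
                   as.integer(genes$end), genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname write_genome_set
#' @param dir directory written by [write_genome_set()].
#' @export
read_genome_set <- function(dir) {
  faas <- list.files(dir, pattern = "\\.faa$", full.names = TRUE)
  species <- sub("\\.faa$", "", basename(faas))
  all_genes <- list()
  for (sp in species) {
    gr <- read_annotations(file.path(dir, paste0(sp, ".gff3")), species = sp)
    gff <- rtracklayer::import(file.path(dir, paste0(sp, ".gff3")), format = "gff3")
    if (!is.null(gff$subtype)) {
      sub_map <- setNames(as.character(gff$subtype), as.character(gff$ID))
      gr$subtype <- unname(sub_map[gr$gene_id])
    }
    prot <- read_fasta(file.path(dir, paste0(sp, ".faa")))
    gr$protein <- unname(prot[gr$gene_id])
    all_genes[[sp]] <- gr
  }
  genes <- do.call(rbind, c(all_genes, list(make.row.names = FALSE)))
  chrom_lengths <- read_tsv(file.path(dir, "chromosomes.tsv"))
  structure(list(genes = validate_gene_records(genes),
                 chrom_lengths = chrom_lengths),
            class = "genome_set")
}
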