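## Independent oracles: literal-definition reimplementations used to
## cross-check the package's optimized code paths.

## O(n^2) literal scanner: every unordered pair, definition applied as
## written, no grouping tricks
oracle_scan_pairs <- function(genes, window = 100000,
                              subtypes = c("LWS", "SWS1", "SWS2", "RH1", "RH2")) {
  g <- genes[!is.na(genes$subtype) & genes$subtype %in% subtypes, ]
  out <- list()
  n <- nrow(g)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (g$species[i] != g$species[j]) next
    if (g$seq_id[i] != g$seq_id[j]) next
    if (g$strand[i] != g$strand[j]) next
    if (g$subtype[i] == g$subtype[j]) next
    later <- if (g$start[i] >= g$start[j]) i else j
    earlier <- if (later == i) j else i
    gap <- max(0, g$start[later] - g$end[earlier])
    a <- i; b <- j
    if (g$gene_id[b] < g$gene_id[a]) { a <- j; b <- i }
    out[[length(out) + 1L]] <- data.frame(
      species = g$species[i], seq_id = g$seq_id[i],
      gene_a = g$gene_id[a], gene_b = g$gene_id[b],
      subtype_pair = paste(sort(c(g$subtype[i], g$subtype[j])), collapse = "-"),
      gap_bp = gap, proximal = gap < window, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(species = character(),
                                      seq_id = character(),
                                      gene_a = character(),
                                      gene_b = character(),
                                      subtype_pair = character(),
                                      gap_bp = numeric(),
                                      proximal = logical()))
  ev <- do.call(rbind, out)
  ev[order(ev$species, ev$seq_id, ev$gene_a, ev$gene_b), , drop = FALSE]
}

## exhaustive global affine-gap alignment score by enumerating every
## monotone alignment path and scoring it from scratch
oracle_profile_score <- function(query, ref_msa, params) {
  prof <- opsinteny::alignment_profile(ref_msa)
  B <- opsinteny:::get_subst_matrix(params$substitution_matrix)
  q <- strsplit(query, "")[[1]]
  S <- B[match(q, rownames(prof)), , drop = FALSE] %*% prof
  m <- length(q); n <- ncol(prof)
  best <- -Inf
  score_path <- function(moves) {
    sc <- 0; qi <- 0; cj <- 0; prev <- ""
    for (mv in moves) {
      if (mv == "M") { qi <- qi + 1; cj <- cj + 1; sc <- sc + S[qi, cj] }
      else {
        if (mv == "D") cj <- cj + 1 else qi <- qi + 1
        sc <- sc - if (mv == prev) params$gap_extend else params$gap_open
      }
      prev <- mv
    }
    sc
  }
  recur <- function(qi, cj, moves) {
    if (qi == m && cj == n) {
      s <- score_path(moves)
      if (s > best) best <<- s
      return(invisible())
    }
    if (qi < m && cj < n) recur(qi + 1, cj + 1, c(moves, "M"))
    if (cj < n) recur(qi, cj + 1, c(moves, "D"))
    if (qi < m) recur(qi + 1, cj, c(moves, "I"))
  }
  recur(0, 0, character())
  unname(best)
}

## literal column-count identity
oracle_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n_comp <- 0; n_same <- 0
  for (k in seq_along(x)) {
    if (x[k] != "-" && y[k] != "-") {
      n_comp <- n_comp + 1
      if (x[k] == y[k]) n_same <- n_same + 1
    }
  }
  if (n_comp == 0) 0 else n_same / n_comp
}

## ---- scenario oracles ----------------------------------------------------

## every loss edge of the copy tree for a given structure
oracle_all_edges <- function(struct) {
  edges <- "pre1R"
  for (clade in struct$clades) {
    edges <- c(edges, paste0("stem.", clade))
    for (g in names(struct$groups)) {
      edges <- c(edges, paste(g, clade, sep = "."),
                 paste(g, clade, seq_len(struct$groups[[g]]$copies), sep = "."))
    }
  }
  edges
}

## flat event-enumeration oracle: tries every combination of <= max_cost
## loss events (and, optionally, one translocation per observed "other"
## gene) on every placement, accepting a candidate iff a subtype
## assignment exists under which its replay matches the observation.
## Exponential; only for tiny instances.
oracle_min_cost <- function(obs, hyp, struct, max_cost = 4) {
  edges <- oracle_all_edges(struct)
  base_uids <- sprintf("%s#%d", hyp$genes$label, seq_len(nrow(hyp$genes)))
  loss_opts <- expand.grid(edge = edges, uid = base_uids,
                           stringsAsFactors = FALSE)
  obs_df <- obs$table
  other <- obs_df[obs_df$clade == "other", , drop = FALSE]
  leaves <- unlist(lapply(struct$clades, function(cl)
    structure_leaves_oracle(struct, cl)))
  ## translocation candidate events for each observed "other" gene
  tl_opts_per_gene <- lapply(seq_len(nrow(other)), function(i) {
    lv <- leaves[startsWith(leaves, paste0(other$group[i], "."))]
    do.call(rbind, lapply(lv, function(l)
      expand.grid(edge = l, uid = base_uids, to_chrom = other$chrom[i],
                  stringsAsFactors = FALSE)))
  })
  best <- Inf
  n_tl <- nrow(other)
  tl_grids <- if (n_tl) expand.grid(lapply(tl_opts_per_gene, function(x)
    seq_len(nrow(x)))) else data.frame(row.names = 1)
  for (ti in seq_len(nrow(tl_grids))) {
    tl_events <- NULL
    if (n_tl) {
      tl_events <- do.call(rbind, lapply(seq_len(n_tl), function(j) {
        row <- tl_opts_per_gene[[j]][tl_grids[ti, j], ]
        data.frame(kind = "TRANSLOCATION", edge = row$edge, uid = row$uid,
                   new_uid = NA, to_chrom = row$to_chrom, new_strand = "+",
                   stringsAsFactors = FALSE)
      }))
      if (any(duplicated(paste(tl_events$edge, tl_events$uid)))) next
    }
    for (k in 0:(max_cost - n_tl)) {
      if (n_tl + k >= best) break
      combos <- if (k == 0) list(integer()) else
        utils::combn(nrow(loss_opts), k, simplify = FALSE)
      for (cb in combos) {
        losses <- if (length(cb)) data.frame(
          kind = "LOSS", edge = loss_opts$edge[cb], uid = loss_opts$uid[cb],
          new_uid = NA, to_chrom = NA, new_strand = NA,
          stringsAsFactors = FALSE) else NULL
        events <- rbind(losses, tl_events)
        rep_out <- tryCatch(replay(hyp, events, struct),
                            error = function(e) NULL)
        if (is.null(rep_out)) next
        if (oracle_any_assignment_matches(rep_out, obs, hyp, struct, events)) {
          best <- min(best, n_tl + k)
          break
        }
      }
      if (best <= n_tl + k) break
    }
  }
  best
}

structure_leaves_oracle <- function(struct, clade) {
  out <- character()
  for (g in names(struct$groups))
    out <- c(out, paste(g, clade, seq_len(struct$groups[[g]]$copies), sep = "."))
  out
}

## Does any admissible subtype assignment make the replayed output equal
## the observation? Matching goes chromosome by chromosome: within every
## (group, clade) block the non-empty predicted chromosomes must biject to
## the observed ones in some orientation with label-compatible subtypes;
## the assignment is derived from the observed slots and then checked for
## lineage monophyly.
oracle_any_assignment_matches <- function(rep_out, obs, hyp, struct,
                                          events = NULL) {
  base_uids <- sprintf("%s#%d", hyp$genes$label, seq_len(nrow(hyp$genes)))
  dup_ev <- if (!is.null(events))
    events[events$kind == "TANDEM_DUP", , drop = FALSE] else NULL
  if (!is.null(dup_ev) && !nrow(dup_ev)) dup_ev <- NULL
  dup_paths <- opsinteny:::build_dup_paths(base_uids, dup_ev)
  oc <- opsinteny:::obs_chrom_list(obs)
  root_label <- function(uid) sub("#.*$", "", sub("\\.d[0-9]+.*$", "", uid))

  ## pairings of one predicted chromosome (uid/label/strand df) with one
  ## observed gene list; returns list of assignment fragments or NULL
  pair_options <- function(st, leaf, genes) {
    if (nrow(st) != nrow(genes)) return(list())
    ors <- list(genes,
                data.frame(subtype = rev(genes$subtype),
                           strand = ifelse(rev(genes$strand) == "+", "-", "+"),
                           stringsAsFactors = FALSE))
    out <- list()
    for (og in ors) {
      if (!all(st$strand == og$strand)) next
      ok <- all(vapply(seq_len(nrow(st)), function(i)
        og$subtype[i] %in% hyp$mapping[[root_label(st$uid[i])]], TRUE))
      if (ok) out[[length(out) + 1L]] <- data.frame(
        uid = st$uid, leaf = leaf, subtype = og$subtype,
        stringsAsFactors = FALSE)
    }
    out
  }

  for (cm in list(c(`1` = "1", `2` = "2"), c(`1` = "2", `2` = "1"))) {
    block_opts <- list()   # per block: list of assignment fragments
    feasible <- TRUE
    for (g in names(struct$groups)) for (clade in struct$clades) {
      leaves <- paste(g, clade, seq_len(struct$groups[[g]]$copies), sep = ".")
      pred <- Filter(function(lf) nrow(rep_out$leaves[[lf]]) > 0, leaves)
      obs_here <- Filter(function(x) x$group == g && x$clade == cm[[clade]], oc)
      if (length(pred) != length(obs_here)) { feasible <- FALSE; break }
      if (!length(pred)) next
      ## enumerate bijections
      perms <- perms_of_oracle(seq_along(obs_here))
      opts <- list()
      for (pm in perms) {
        frag_sets <- lapply(seq_along(pred), function(i)
          pair_options(rep_out$leaves[[pred[i]]], pred[i],
                       obs_here[[pm[i]]]$genes))
        if (any(!vapply(frag_sets, length, 1L))) next
        grid <- expand.grid(lapply(frag_sets, seq_along))
        for (r in seq_len(nrow(grid)))
          opts[[length(opts) + 1L]] <- do.call(rbind, lapply(
            seq_along(frag_sets), function(i) frag_sets[[i]][[grid[r, i]]]))
      }
      if (!length(opts)) { feasible <- FALSE; break }
      block_opts[[paste(g, clade)]] <- opts
    }
    if (!feasible) next
    ## translocated chromosomes
    obs_other <- Filter(function(x) x$clade == "other", oc)
    pred_other <- names(rep_out$other)
    if (length(obs_other) != length(pred_other)) next
    if (length(pred_other)) {
      perms <- perms_of_oracle(seq_along(obs_other))
      opts <- list()
      for (pm in perms) {
        frags <- lapply(seq_along(pred_other), function(i) {
          om <- rep_out$other[[pred_other[i]]]
          ob <- obs_other[[pm[i]]]
          if (nrow(om) != nrow(ob$genes)) return(NULL)
          if (opsinteny:::leaf_group(om$source_leaf[1]) != ob$group) return(NULL)
          ## order on the target chromosome is not modelled: find a gene
          ## bijection compatible with the mappings
          for (gp in perms_of_oracle(seq_len(nrow(om)))) {
            ok <- all(vapply(seq_len(nrow(om)), function(j)
              ob$genes$subtype[j] %in% hyp$mapping[[root_label(om$uid[gp[j]])]],
              TRUE))
            if (ok) return(data.frame(uid = om$uid[gp],
                                      leaf = om$source_leaf[gp],
                                      subtype = ob$genes$subtype,
                                      stringsAsFactors = FALSE))
          }
          NULL
        })
        if (any(vapply(frags, is.null, TRUE))) next
        opts[[length(opts) + 1L]] <- do.call(rbind, frags)
      }
      if (!length(opts)) next
      block_opts[["other"]] <- opts
    }
    if (!length(block_opts)) return(TRUE)  # nothing observed, nothing left
    ## combine fragments across blocks and test monophyly
    grid <- expand.grid(lapply(block_opts, seq_along))
    for (r in seq_len(nrow(grid))) {
      sdf <- do.call(rbind, lapply(seq_along(block_opts), function(i)
        block_opts[[i]][[grid[r, i]]]))
      if (opsinteny:::subtype_classes_monophyletic(sdf, dup_paths))
        return(TRUE)
    }
  }
  FALSE
}

perms_of_oracle <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of_oracle(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

## structured oracle for larger instances: same decomposition as the
## engine but with loss placement minimized by exhaustive edge-subset
## enumeration per gene instead of the engine's tree-cover rule
oracle_loss_count <- function(absent_leaves, struct) {
  ## minimal number of edges whose descendant-leaf sets exactly tile the
  ## absent set, by brute force over all edge subsets
  edge_leaves <- list()
  for (clade in struct$clades) {
    all_lv <- structure_leaves_oracle(struct, clade)
    edge_leaves[[paste0("stem.", clade)]] <- all_lv
    for (g in names(struct$groups)) {
      gl <- paste(g, clade, seq_len(struct$groups[[g]]$copies), sep = ".")
      edge_leaves[[paste(g, clade, sep = ".")]] <- gl
      for (l in gl) edge_leaves[[l]] <- l
    }
  }
  edge_leaves[["pre1R"]] <- unlist(lapply(struct$clades, function(cl)
    structure_leaves_oracle(struct, cl)))
  if (!length(absent_leaves)) return(0L)
  ids <- names(edge_leaves)
  for (k in 1:length(ids)) {
    for (cb in utils::combn(length(ids), k, simplify = FALSE)) {
      covered <- unique(unlist(edge_leaves[cb]))
      if (setequal(covered, absent_leaves)) return(k)
    }
  }
  Inf
}
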