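## Event-parsimony engine.
##
## The whole-genome duplication structure is fixed from independent
## evidence (1R shared by all vertebrates; an extra WGD on the jawed
## branch; a triplication on the jawless branch) and carries no cost; the
## engine searches over tandem duplications (pre-1R only), gene losses
## (placeable on any edge of the chromosome-copy tree, so a single early
## loss explains absence from every descendant copy) and single-gene
## translocations (terminal edges only, moving a gene to a chromosome
## outside the paralogon). Subtype identities must behave like sequence
## clades: the extant genes assigned one subtype must be monophyletic
## within their ancestral gene's copy tree (in some resolution of the
## triplication polytomy), which is what ties "the RH1/RH2 split happened
## at 1R" to the arrangement data.

#' Fixed whole-genome-duplication structure
#'
#' @param groups named list of lineage groups, each `list(copies = n)`:
#'   the number of post-WGD copies in that lineage (3 = triplication,
#'   2 = WGD). 1R (two clades) is always present.
#' @return object of class `scenario_structure`.
#' @export
scenario_structure <- function(groups = list(jawless = list(copies = 3),
                                             jawed = list(copies = 2))) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  for (g in groups) stopifnot(g$copies >= 1)
  structure(list(groups = groups, clades = c("1", "2")),
            class = "scenario_structure")
}

structure_leaves <- function(struct, clade) {
  out <- character()
  for (g in names(struct$groups))
    out <- c(out, paste(g, clade, seq_len(struct$groups[[g]]$copies), sep = "."))
  out
}

leaf_group <- function(leaf) sub("\\..*$", "", leaf)

#' An ancestral (pre-1R) gene-arrangement hypothesis
#'
#' @param name hypothesis name.
#' @param genes data.frame with columns `label`, `strand`: the pre-1R
#'   tandem gene order.
#' @param mapping named list: ancestral label -> character vector of
#'   extant subtypes that label may give rise to.
#' @return object of class `ancestral_hypothesis`.
#' @export
ancestral_hypothesis <- function(name, genes, mapping) {
  stopifnot(nrow(genes) >= 1, all(genes$strand %in% c("+", "-")),
            all(genes$label %in% names(mapping)))
  structure(list(name = name, genes = genes, mapping = mapping),
            class = "ancestral_hypothesis")
}

#' Observed gene arrangements on paralogon chromosomes
#'
#' @param df data.frame with columns `group` (lineage group name),
#'   `chrom`, `clade` ("1", "2" from the paralogon tree, or "other" for a
#'   chromosome outside the paralogon, e.g. a translocation target),
#'   `pos` (order along the chromosome), `subtype`, `strand`.
#' @return object of class `observed_arrangement`.
#' @export
observed_arrangement <- function(df) {
  req <- c("group", "chrom", "clade", "pos", "subtype", "strand")
  stopifnot(all(req %in% names(df)), all(df$clade %in% c("1", "2", "other")),
            all(df$strand %in% c("+", "-")))
  df <- df[order(df$group, df$chrom, df$pos), req]
  structure(list(table = df), class = "observed_arrangement")
}

obs_chrom_list <- function(obs) {
  df <- obs$table
  keys <- unique(df[, c("group", "chrom", "clade")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$group == keys$group[i] & df$chrom == keys$chrom[i]
    list(group = keys$group[i], chrom = keys$chrom[i], clade = keys$clade[i],
         genes = df[sel, c("subtype", "strand")])
  })
}

## ---- forward replay ------------------------------------------------------

#' Replay an event scenario from an ancestral hypothesis
#'
#' Deterministic forward replay: pre-1R tandem duplications and losses on
#' the ancestral chromosome, 1R (two clades, order and strand preserved),
#' per-clade stem losses, per-group losses, the group WGD/triplication,
#' then terminal-edge losses and translocations. Events reference gene
#' uids (`label#k` for ancestral genes; tandem copies carry the uid given
#' in the event's `new_uid`).
#'
#' @param hyp an [ancestral_hypothesis()].
#' @param events data.frame with columns `kind` (TANDEM_DUP / LOSS /
#'   TRANSLOCATION), `edge` ("pre1R", "stem.<clade>",
#'   "<group>.<clade>" or a leaf "<group>.<clade>.<copy>"), `uid`, and for
#'   duplications `new_uid`, for translocations `to_chrom` and
#'   `new_strand`.
#' @param struct a [scenario_structure()].
#' @return list: `leaves` (named list leaf id -> data.frame uid, label,
#'   strand in chromosome order), `other` (named list chrom -> data.frame
#'   uid, label, strand, source_leaf).
#' @export
replay <- function(hyp, events, struct = scenario_structure()) {
  if (is.null(events) || !nrow(events))
    events <- data.frame(kind = character(), edge = character(),
                         uid = character(), new_uid = character(),
                         to_chrom = character(), new_strand = character())
  for (col in c("new_uid", "to_chrom", "new_strand"))
    if (is.null(events[[col]])) events[[col]] <- NA_character_

  anc <- data.frame(uid = sprintf("%s#%d", hyp$genes$label,
                                  seq_len(nrow(hyp$genes))),
                    label = hyp$genes$label, strand = hyp$genes$strand,
                    stringsAsFactors = FALSE)

  ev_on <- function(edge) events[events$edge == edge, , drop = FALSE]

  apply_events <- function(state, edge, allow_dup = FALSE) {
    ev <- ev_on(edge)
    moved <- list()
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      at <- which(state$uid == e$uid)
      if (!length(at))
        stop("event references gene absent at ", edge, ": ", e$uid)
      if (e$kind == "LOSS") {
        state <- state[-at, , drop = FALSE]
      } else if (e$kind == "TANDEM_DUP") {
        if (!allow_dup) stop("tandem duplication only allowed pre-1R")
        copy <- state[at, ]
        copy$uid <- e$new_uid
        state <- rbind(state[seq_len(at), ], copy,
                       if (at < nrow(state)) state[(at + 1):nrow(state), ])
      } else if (e$kind == "TRANSLOCATION") {
        moved[[length(moved) + 1L]] <- data.frame(
          uid = state$uid[at], label = state$label[at],
          strand = e$new_strand, to_chrom = e$to_chrom,
          source_leaf = edge, stringsAsFactors = FALSE)
        state <- state[-at, , drop = FALSE]
      } else stop("unknown event kind: ", e$kind)
    }
    list(state = state, moved = moved)
  }

  pre <- apply_events(anc, "pre1R", allow_dup = TRUE)
  if (length(pre$moved)) stop("translocations only allowed on terminal edges")
  leaves <- list(); other_rows <- list()
  for (clade in struct$clades) {
    st <- apply_events(pre$state, paste0("stem.", clade))
    if (length(st$moved)) stop("translocations only allowed on terminal edges")
    for (g in names(struct$groups)) {
      gs <- apply_events(st$state, paste(g, clade, sep = "."))
      if (length(gs$moved)) stop("translocations only allowed on terminal edges")
      for (k in seq_len(struct$groups[[g]]$copies)) {
        leaf <- paste(g, clade, k, sep = ".")
        lf <- apply_events(gs$state, leaf)
        leaves[[leaf]] <- lf$state
        for (mv in lf$moved) other_rows[[length(other_rows) + 1L]] <- mv
      }
    }
  }
  other <- list()
  if (length(other_rows)) {
    om <- do.call(rbind, other_rows)
    for (ch in unique(om$to_chrom))
      other[[ch]] <- om[om$to_chrom == ch,
                        c("uid", "label", "strand", "source_leaf")]
  }
  list(leaves = leaves, other = other)
}

canonical_gene_list <- function(subtype, strand) {
  if (!length(subtype)) return("")
  fwd <- paste(subtype, strand, sep = "/", collapse = ";")
  flip <- ifelse(rev(strand) == "+", "-", "+")
  rev_ <- paste(rev(subtype), flip, sep = "/", collapse = ";")
  min(fwd, rev_)
}

#' Check that a replayed scenario reproduces an observed arrangement
#'
#' Compares the replayed leaf chromosomes (with a subtype assignment per
#' surviving gene instance) to the observed arrangement: within every
#' (group, clade) the non-empty predicted chromosomes must match the
#' observed ones as ordered, strand-aware gene lists (chromosome
#' orientation is arbitrary, so reversal with strand flip is allowed),
#' under one global mapping of 1R copies to observed clade ids; observed
#' "other" chromosomes must match the translocated genes.
#'
#' @param rep_out result of [replay()].
#' @param assignment data.frame `uid`, `leaf` ("other:<chrom>" for moved
#'   genes), `subtype`.
#' @param obs an [observed_arrangement()].
#' @param struct a [scenario_structure()].
#' @return TRUE/FALSE.
#' @export
replay_matches <- function(rep_out, assignment, obs,
                           struct = scenario_structure()) {
  akey <- setNames(assignment$subtype, paste(assignment$uid, assignment$leaf))
  oc <- obs_chrom_list(obs)
  for (clade_map in list(c(`1` = "1", `2` = "2"), c(`1` = "2", `2` = "1"))) {
    ok <- TRUE
    for (g in names(struct$groups)) for (clade in struct$clades) {
      pred <- character()
      for (k in seq_len(struct$groups[[g]]$copies)) {
        leaf <- paste(g, clade, k, sep = ".")
        st <- rep_out$leaves[[leaf]]
        if (!nrow(st)) { pred <- c(pred, ""); next }
        subt <- unname(akey[paste(st$uid, leaf)])
        if (any(is.na(subt))) { ok <- FALSE; break }
        pred <- c(pred, canonical_gene_list(subt, st$strand))
      }
      if (!ok) break
      obs_here <- Filter(function(x) x$group == g &&
                           x$clade == clade_map[[clade]], oc)
      obs_canon <- vapply(obs_here, function(x)
        canonical_gene_list(x$genes$subtype, x$genes$strand), "")
      pred_nonempty <- pred[pred != ""]
      if (!identical(sort(unname(obs_canon)), sort(unname(pred_nonempty)))) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      ## translocated ("other") chromosomes: multiset of (group, subtypes)
      obs_other <- Filter(function(x) x$clade == "other", oc)
      obs_sets <- sort(vapply(obs_other, function(x)
        paste(x$group, paste(sort(x$genes$subtype), collapse = ";")), ""))
      pred_sets <- sort(vapply(names(rep_out$other), function(ch) {
        om <- rep_out$other[[ch]]
        paste(leaf_group(om$source_leaf[1]),
              paste(sort(unname(akey[paste(om$uid, paste0("other:", ch))])),
                    collapse = ";"))
      }, character(1)))
      if (identical(unname(obs_sets), unname(pred_sets))) return(TRUE)
    }
  }
  FALSE
}

## ---- lineage-convexity (subtype monophyly) check -------------------------

## The gene genealogy implied by a scenario is a tree: an (unresolved)
## polytomy over the hypothesis's root genes, an unresolved polytomy over
## each root gene's pre-1R tandem copies (the events all happen on the
## same stem, so their branching order is not constrained), then per
## lineage the 1R split (clades), the speciation (groups) and the group
## WGD/triplication (copies). Each surviving instance is one leaf, encoded
## as a root-to-leaf token path. Subtype classes must be monophyletic in
## some resolution of the polytomies: a class spanning several children of
## a node is admissible only if each of those children is pure.
convexity_paths_ok <- function(paths, classes) {
  n <- length(paths)
  if (n <= 1 || length(unique(classes)) == 1) return(TRUE)
  rec <- function(idx, d) {
    if (length(idx) <= 1) return(TRUE)
    toks <- vapply(idx, function(i) paths[[i]][d], "")
    cls <- classes[idx]
    for (s in unique(cls)) {
      kids <- unique(toks[cls == s])
      if (length(kids) > 1)
        for (k in kids) if (any(cls[toks == k] != s)) return(FALSE)
    }
    for (k in unique(toks)) {
      sub <- idx[toks == k]
      if (length(sub) > 1 && !rec(sub, d + 1)) return(FALSE)
    }
    TRUE
  }
  rec(seq_len(n), 1L)
}

## token paths through the pre-1R duplication polytomy: every tandem copy
## of a root gene is a child of that root's (unresolved) node
build_dup_paths <- function(root_uids, dup_events) {
  roots <- setNames(root_uids, root_uids)
  if (!is.null(dup_events)) for (i in seq_len(nrow(dup_events)))
    roots[dup_events$new_uid[i]] <- roots[[dup_events$uid[i]]]
  out <- lapply(names(roots), function(u) c(unname(roots[[u]]), u))
  names(out) <- names(roots)
  out
}

## full leaf path of a surviving instance
survivor_paths <- function(surv, dup_paths) {
  lapply(seq_len(nrow(surv)), function(i) {
    leaf <- surv$leaf[i]
    parts <- strsplit(leaf, ".", fixed = TRUE)[[1]]
    ## leaf = "<group>.<clade>.<copy>"; genealogy order is clade, group, copy
    c(dup_paths[[surv$uid[i]]], parts[2], parts[1], parts[3])
  })
}

## combined admissibility check used by the engine and the test oracles
subtype_classes_monophyletic <- function(surv, dup_paths) {
  if (!nrow(surv)) return(TRUE)
  convexity_paths_ok(survivor_paths(surv, dup_paths), surv$subtype)
}

## ---- minimum-cost search -------------------------------------------------

default_event_weights <- function()
  c(TANDEM_DUP = 1, LOSS = 1, TRANSLOCATION = 1)

## enumerate pre-1R orders reachable by up to max_dups tandem duplications;
## each state: data.frame(uid, label, strand) + n_dups. Deduplicated by the
## resulting label sequence.
enumerate_dup_orders <- function(hyp, max_genes) {
  base <- data.frame(uid = sprintf("%s#%d", hyp$genes$label,
                                   seq_len(nrow(hyp$genes))),
                     label = hyp$genes$label, strand = hyp$genes$strand,
                     stringsAsFactors = FALSE)
  out <- list(list(order = base, n_dups = 0L, dup_events = NULL,
                   paths = build_dup_paths(base$uid, NULL)))
  seen <- paste(base$label, collapse = ";")
  frontier <- out
  ndup <- 0L
  while (length(frontier) && nrow(frontier[[1]]$order) < max_genes) {
    ndup <- ndup + 1L
    nxt <- list()
    for (st in frontier) {
      ord <- st$order
      if (nrow(ord) >= max_genes) next
      for (i in seq_len(nrow(ord))) {
        copy <- ord[i, ]
        copy$uid <- paste0(copy$uid, ".d", ndup)
        new_ord <- rbind(ord[seq_len(i), ], copy,
                         if (i < nrow(ord)) ord[(i + 1):nrow(ord), ])
        ## copies of one root are exchangeable under the duplication
        ## polytomy, so states are keyed by the label sequence alone
        key <- paste(new_ord$label, collapse = ";")
        if (key %in% seen) next
        seen <- c(seen, key)
        dup_ev <- rbind(st$dup_events, data.frame(
          kind = "TANDEM_DUP", edge = "pre1R", uid = ord$uid[i],
          new_uid = copy$uid, to_chrom = NA_character_,
          new_strand = NA_character_, stringsAsFactors = FALSE))
        cand <- list(order = new_ord, n_dups = st$n_dups + 1L,
                     dup_events = dup_ev,
                     paths = build_dup_paths(base$uid, dup_ev))
        nxt[[length(nxt) + 1L]] <- cand
        out[[length(out) + 1L]] <- cand
      }
    }
    frontier <- nxt
  }
  out
}

## all embeddings of an observed (subtype, strand) list into the pre-1R
## order, in a given orientation; returns list of integer position vectors
embed_positions <- function(obs_genes, order, mapping) {
  n_obs <- nrow(obs_genes); n_ord <- nrow(order)
  if (n_obs > n_ord) return(list())
  res <- list()
  recur <- function(k, min_pos, acc) {
    if (k > n_obs) { res[[length(res) + 1L]] <<- acc; return(invisible()) }
    for (p in min_pos:n_ord) {
      if (n_ord - p < n_obs - k) break
      if (order$strand[p] != obs_genes$strand[k]) next
      if (!obs_genes$subtype[k] %in% mapping[[order$label[p]]]) next
      recur(k + 1L, p + 1L, c(acc, p))
    }
  }
  recur(1L, 1L, integer())
  res
}

orientations <- function(genes) {
  fwd <- genes
  rev_ <- data.frame(subtype = rev(genes$subtype),
                     strand = ifelse(rev(genes$strand) == "+", "-", "+"),
                     stringsAsFactors = FALSE)
  if (identical(fwd, rev_)) list(fwd) else list(fwd, rev_)
}

## loss events needed to delete `absent` leaves of one clade, where edges
## are: whole clade (stem), whole group, single leaf
clade_loss_events <- function(absent, struct, clade) {
  all_leaves <- structure_leaves(struct, clade)
  if (!length(absent)) return(data.frame(kind = character(), edge = character(),
                                         uid = character()))
  if (setequal(absent, all_leaves))
    return(data.frame(kind = "LOSS", edge = paste0("stem.", clade),
                      uid = NA_character_, stringsAsFactors = FALSE))
  ev <- list()
  for (g in names(struct$groups)) {
    gl <- paste(g, clade, seq_len(struct$groups[[g]]$copies), sep = ".")
    ga <- intersect(absent, gl)
    if (!length(ga)) next
    if (setequal(ga, gl))
      ev[[length(ev) + 1L]] <- data.frame(kind = "LOSS",
                                          edge = paste(g, clade, sep = "."),
                                          uid = NA_character_)
    else for (lf in ga)
      ev[[length(ev) + 1L]] <- data.frame(kind = "LOSS", edge = lf,
                                          uid = NA_character_)
  }
  do.call(rbind, ev)
}

#' Minimum-cost event scenario for an observed arrangement
#'
#' Exact search, bounded for desk-scale instances: enumerates pre-1R
#' tandem-duplication extensions of the hypothesis order, the global
#' mapping of 1R copies to observed paralogon clades, injective
#' assignments of observed chromosomes to WGD copies, subsequence
#' embeddings of each observed chromosome into the (possibly reversed)
#' ancestral order, and translocation sources for genes observed outside
#' the paralogon; losses are then placed optimally on the copy-tree edges
#' (an absence shared by every descendant of an edge costs one event).
#' Candidate solutions must pass the subtype-monophyly (convexity) check;
#' all co-optimal scenarios are returned.
#'
#' @param obs an [observed_arrangement()].
#' @param hyp an [ancestral_hypothesis()].
#' @param weights named event weights (default 1 each); WGDs cost 0.
#' @param struct a [scenario_structure()] (groups must cover those in
#'   `obs`).
#' @param max_pre1r_genes cap on the pre-1R gene count reachable by
#'   searched tandem duplications.
#' @return list of class `event_scenario_set`: `feasible`, `cost`,
#'   `n_cooptimal`, `scenarios` (each: `events` data.frame, `assignment`,
#'   `cost`, breakdown by kind), `hypothesis`.
#' @export
min_cost_scenario <- function(obs, hyp, weights = default_event_weights(),
                              struct = scenario_structure(),
                              max_pre1r_genes = 5) {
  stopifnot(inherits(obs, "observed_arrangement"),
            inherits(hyp, "ancestral_hypothesis"))
  oc <- obs_chrom_list(obs)
  obs_groups <- unique(vapply(oc, `[[`, "", "group"))
  if (!all(setdiff(obs_groups, "other") %in% c(names(struct$groups))))
    stop("observed groups not covered by the structure")
  ## quick infeasibility: observed subtype not produced by any label
  all_subtypes <- unique(unlist(lapply(oc, function(x) x$genes$subtype)))
  if (!all(all_subtypes %in% unlist(hyp$mapping)))
    return(structure(list(feasible = FALSE, cost = Inf, n_cooptimal = 0L,
                          scenarios = list(), hypothesis = hyp$name),
                     class = "event_scenario_set"))

  other_chroms <- Filter(function(x) x$clade == "other", oc)
  clade_chroms <- Filter(function(x) x$clade != "other", oc)

  best <- Inf
  best_scens <- list()

  for (dup_state in enumerate_dup_orders(hyp, max_pre1r_genes)) {
    ord <- dup_state$order
    dup_cost <- dup_state$n_dups * weights[["TANDEM_DUP"]]
    if (dup_cost > best) next
    for (cm in list(c(`1` = "1", `2` = "2"), c(`1` = "2", `2` = "1"))) {
      res <- search_clades(ord, dup_state, cm, clade_chroms, other_chroms,
                           hyp, struct, weights, best)
      for (sc in res$scenarios) {
        tot <- sc$cost
        if (tot < best - 1e-9) { best <- tot; best_scens <- list(sc) }
        else if (abs(tot - best) <= 1e-9) {
          key <- scenario_key(sc)
          if (!key %in% vapply(best_scens, scenario_key, ""))
            best_scens[[length(best_scens) + 1L]] <- sc
        }
      }
    }
  }
  if (!is.finite(best))
    return(structure(list(feasible = FALSE, cost = Inf, n_cooptimal = 0L,
                          scenarios = list(), hypothesis = hyp$name),
                     class = "event_scenario_set"))
  structure(list(feasible = TRUE, cost = best,
                 n_cooptimal = length(best_scens), scenarios = best_scens,
                 hypothesis = hyp$name),
            class = "event_scenario_set")
}

scenario_key <- function(sc) {
  ev <- sc$events
  paste(sort(paste(ev$kind, ev$edge, ev$uid, ev$to_chrom)), collapse = "|")
}

## enumerate per-clade explanations and combine the two clades
search_clades <- function(ord, dup_state, clade_map, clade_chroms,
                          other_chroms, hyp, struct, weights, best_so_far) {
  ## split observed "other" genes between source clades (each gene moved
  ## exactly once from some leaf of some clade)
  other_genes <- list()
  for (x in other_chroms) for (i in seq_len(nrow(x$genes)))
    other_genes[[length(other_genes) + 1L]] <- list(
      chrom = x$chrom, group = x$group, subtype = x$genes$subtype[i])
  n_other <- length(other_genes)
  splits <- if (n_other) expand.grid(rep(list(c("1", "2")), n_other),
                                     stringsAsFactors = FALSE) else
    data.frame(row.names = 1)

  scens <- list()
  dup_cost <- dup_state$n_dups * weights[["TANDEM_DUP"]]
  for (si in seq_len(nrow(splits))) {
    src_clade <- if (n_other) as.character(unlist(splits[si, ])) else character()
    opts1 <- clade_options(ord, "1", clade_map, clade_chroms,
                           other_genes[src_clade == "1"], hyp, struct,
                           weights, dup_state$paths)
    if (!length(opts1)) next
    opts2 <- clade_options(ord, "2", clade_map, clade_chroms,
                           other_genes[src_clade == "2"], hyp, struct,
                           weights, dup_state$paths)
    if (!length(opts2)) next
    opts1 <- opts1[order(vapply(opts1, `[[`, 0, "cost"))]
    opts2 <- opts2[order(vapply(opts2, `[[`, 0, "cost"))]
    ## stem losses shared by both clades can merge into one pre-1R loss,
    ## saving at most min(#stem losses) events: use that as the bound
    max_stem2 <- max(vapply(opts2, function(o) length(o$stem_loss_pos), 0L))
    wl <- weights[["LOSS"]]
    for (a in opts1) {
      lb_a <- dup_cost + a$cost + opts2[[1]]$cost - max_stem2 * wl
      if (lb_a > best_so_far + 1e-9) break
      for (b in opts2) {
        n_merged <- length(intersect(a$stem_loss_pos, b$stem_loss_pos))
        cost <- dup_cost + a$cost + b$cost - n_merged * wl
        if (cost > best_so_far + 1e-9) next
        if (!convexity_paths_ok(c(a$surv_paths, b$surv_paths),
                                c(a$surv_classes, b$surv_classes))) next
        sc <- combine_clades(ord, dup_state, a, b, hyp, struct, weights)
        scens[[length(scens) + 1L]] <- sc
        if (sc$cost < best_so_far) best_so_far <- sc$cost
      }
    }
  }
  list(scenarios = scens)
}

## all explanations of one clade: which observed chromosomes sit on which
## copies, with which embedding, and where translocated genes come from
clade_options <- function(ord, clade, clade_map, clade_chroms, moved_genes,
                          hyp, struct, weights, dup_paths) {
  target_clade <- clade_map[[clade]]
  leaves <- structure_leaves(struct, clade)
  opts <- list()
  ## per group: observed chromosomes of this clade
  per_group <- list()
  ok <- TRUE
  for (g in names(struct$groups)) {
    oc_g <- Filter(function(x) x$group == g && x$clade == target_clade,
                   clade_chroms)
    copies <- paste(g, clade, seq_len(struct$groups[[g]]$copies), sep = ".")
    if (length(oc_g) > length(copies)) { ok <- FALSE; break }
    per_group[[g]] <- list(chroms = oc_g, copies = copies)
  }
  if (!ok) return(list())

  ## enumerate assignments+embeddings per group, then cross-product
  group_opts <- lapply(per_group, function(pg) {
    enumerate_group(pg$chroms, pg$copies, ord, hyp$mapping)
  })
  if (any(!vapply(group_opts, length, 1L))) return(list())
  idx <- lapply(group_opts, seq_along)
  grid <- expand.grid(idx, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    retained <- list()  # leaf -> data.frame(pos, subtype)
    for (gi in seq_along(group_opts)) {
      ch <- group_opts[[gi]][[grid[r, gi]]]
      retained <- c(retained, ch)
    }
    ## translocation sources for moved genes assigned to this clade
    mv_opts <- enumerate_moves(moved_genes, retained, leaves, ord, hyp$mapping)
    for (mv in mv_opts) {
      cost <- length(moved_genes) * weights[["TRANSLOCATION"]]
      opts[[length(opts) + 1L]] <- list(
        clade = clade, retained = retained, moves = mv, cost = cost)
    }
  }
  ## finalize: losses inside this clade + precomputed survivor table
  for (i in seq_along(opts)) {
    o <- opts[[i]]
    le <- clade_losses(o, ord, leaves, struct, clade)
    opts[[i]]$loss_events <- le$events
    opts[[i]]$cost <- o$cost + le$n_events_no_stemmerge * weights[["LOSS"]]
    opts[[i]]$stem_loss_pos <- le$stem_loss_pos
    uid <- character(); leaf <- character(); subt <- character()
    for (lf in names(o$retained)) {
      df <- o$retained[[lf]]
      if (nrow(df)) {
        uid <- c(uid, ord$uid[df$pos]); leaf <- c(leaf, rep(lf, nrow(df)))
        subt <- c(subt, df$subtype)
      }
    }
    for (m in o$moves) {
      uid <- c(uid, ord$uid[m$pos]); leaf <- c(leaf, m$leaf)
      subt <- c(subt, m$subtype)
    }
    surv <- data.frame(uid = uid, leaf = leaf, subtype = subt,
                       stringsAsFactors = FALSE)
    opts[[i]]$surv <- surv
    opts[[i]]$surv_paths <- survivor_paths(surv, dup_paths)
    opts[[i]]$surv_classes <- subt
  }
  opts
}

## assignments of observed chromosomes to copies with embeddings. The
## copies produced by one WGD/triplication are exchangeable, so only the
## canonical injection (chromosome j -> copy j) is enumerated; scenarios
## are reported up to this copy-relabelling symmetry.
enumerate_group <- function(chroms, copies, ord, mapping) {
  empty <- setNames(lapply(copies, function(x)
    data.frame(pos = integer(), subtype = character())), copies)
  if (!length(chroms)) return(list(empty))
  k <- length(chroms)
  embs_per_chrom <- lapply(chroms, function(x) {
    res <- list()
    for (og in orientations(x$genes)) {
      for (e in embed_positions(og, ord, mapping))
        res[[length(res) + 1L]] <- data.frame(pos = e, subtype = og$subtype,
                                              stringsAsFactors = FALSE)
    }
    unique_embeddings(res)
  })
  if (any(!vapply(embs_per_chrom, length, 1L))) return(list())
  grid <- expand.grid(lapply(embs_per_chrom, seq_along))
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    ass <- empty
    for (j in seq_len(k)) ass[[copies[j]]] <- embs_per_chrom[[j]][[grid[r, j]]]
    out[[r]] <- ass
  }
  out
}

unique_embeddings <- function(lst) {
  if (!length(lst)) return(lst)
  keys <- vapply(lst, function(e) paste(e$pos, e$subtype, collapse = "|"), "")
  lst[!duplicated(keys)]
}

## translocation source choices: each moved gene needs a (leaf, position)
## whose label can produce its subtype and that is not retained at that
## leaf. Sources on leaves with identical retained profiles are equivalent
## (copy exchangeability) and only the first is kept.
enumerate_moves <- function(moved_genes, retained, leaves, ord, mapping) {
  if (!length(moved_genes)) return(list(list()))
  leaf_sig <- vapply(leaves, function(lf) {
    df <- retained[[lf]]
    paste(leaf_group(lf), paste(df$pos, df$subtype, collapse = ","))
  }, "")
  cand_per_gene <- lapply(moved_genes, function(mg) {
    cands <- list()
    seen_sig <- character()
    for (lf in leaves) {
      if (leaf_group(lf) != mg$group) next  # gene stays in its lineage
      if (leaf_sig[[lf]] %in% seen_sig) next
      seen_sig <- c(seen_sig, leaf_sig[[lf]])
      ret_pos <- retained[[lf]]$pos
      for (p in seq_len(nrow(ord))) {
        if (p %in% ret_pos) next
        if (!mg$subtype %in% mapping[[ord$label[p]]]) next
        cands[[length(cands) + 1L]] <- list(leaf = lf, pos = p,
                                            subtype = mg$subtype,
                                            chrom = mg$chrom)
      }
    }
    cands
  })
  if (any(!vapply(cand_per_gene, length, 1L))) return(list())
  grid <- expand.grid(lapply(cand_per_gene, seq_along))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    mv <- lapply(seq_along(cand_per_gene), function(j)
      cand_per_gene[[j]][[grid[r, j]]])
    ## a gene instance can be moved only once: (leaf, pos) pairs distinct
    keys <- vapply(mv, function(m) paste(m$leaf, m$pos), "")
    if (any(duplicated(keys))) next
    out[[length(out) + 1L]] <- mv
  }
  out
}

## optimal loss placement inside one clade (stem merging with the other
## clade via pre-1R losses is applied in combine_clades)
clade_losses <- function(opt, ord, leaves, struct, clade) {
  events <- list()
  n_events <- 0L
  absent_all <- logical(nrow(ord))
  stem_loss_pos <- integer()
  for (p in seq_len(nrow(ord))) {
    present <- vapply(leaves, function(lf) p %in% opt$retained[[lf]]$pos, TRUE)
    moved_here <- vapply(leaves, function(lf)
      any(vapply(opt$moves, function(m) m$leaf == lf && m$pos == p, TRUE)),
      TRUE)
    absent <- leaves[!present & !moved_here]
    if (setequal(absent, leaves)) {
      absent_all[p] <- TRUE
      stem_loss_pos <- c(stem_loss_pos, p)
      n_events <- n_events + 1L   # stem loss, may merge to a pre-1R loss
      ev <- data.frame(kind = "LOSS", edge = paste0("stem.", clade),
                       uid = ord$uid[p], stringsAsFactors = FALSE)
      events[[length(events) + 1L]] <- ev
    } else if (length(absent)) {
      ev <- clade_loss_events(absent, struct, clade)
      ev$uid <- ord$uid[p]
      n_events <- n_events + nrow(ev)
      events[[length(events) + 1L]] <- ev
    }
  }
  list(events = if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), edge = character(), uid = character()),
    n_events_no_stemmerge = n_events, absent_all = absent_all,
    stem_loss_pos = stem_loss_pos)
}

combine_clades <- function(ord, dup_state, a, b, hyp, struct, weights) {
  ## (monophyly of subtype classes was already checked by the caller)
  ## merge stem losses shared by both clades into single pre-1R losses
  merged <- intersect(a$stem_loss_pos, b$stem_loss_pos)
  loss_events <- rbind(a$loss_events, b$loss_events)
  n_events <- nrow(loss_events)
  if (length(merged)) {
    for (p in merged) {
      u <- ord$uid[p]
      loss_events <- loss_events[!(loss_events$uid == u &
                                     grepl("^stem\\.", loss_events$edge)), ]
      loss_events <- rbind(loss_events,
                           data.frame(kind = "LOSS", edge = "pre1R", uid = u,
                                      stringsAsFactors = FALSE))
    }
    n_events <- nrow(loss_events)
  }
  cost <- dup_state$n_dups * weights[["TANDEM_DUP"]] +
    n_events * weights[["LOSS"]] +
    (length(a$moves) + length(b$moves)) * weights[["TRANSLOCATION"]]

  ## assemble full event table + assignment
  mv_events <- list(); assignment <- list()
  for (opt in list(a, b)) {
    for (m in opt$moves) {
      mv_events[[length(mv_events) + 1L]] <- data.frame(
        kind = "TRANSLOCATION", edge = m$leaf, uid = ord$uid[m$pos],
        new_uid = NA_character_, to_chrom = m$chrom, new_strand = "+",
        stringsAsFactors = FALSE)
      assignment[[length(assignment) + 1L]] <- data.frame(
        uid = ord$uid[m$pos], leaf = paste0("other:", m$chrom),
        subtype = m$subtype, stringsAsFactors = FALSE)
    }
    for (lf in names(opt$retained)) {
      df <- opt$retained[[lf]]
      for (i in seq_len(nrow(df)))
        assignment[[length(assignment) + 1L]] <- data.frame(
          uid = ord$uid[df$pos[i]], leaf = lf, subtype = df$subtype[i],
          stringsAsFactors = FALSE)
    }
  }
  le <- loss_events
  if (nrow(le)) { le$new_uid <- NA_character_; le$to_chrom <- NA_character_
  le$new_strand <- NA_character_ }
  events <- rbind(dup_state$dup_events,
                  if (nrow(le)) le,
                  if (length(mv_events)) do.call(rbind, mv_events))
  breakdown <- c(TANDEM_DUP = dup_state$n_dups, LOSS = n_events,
                 TRANSLOCATION = length(a$moves) + length(b$moves))
  list(events = events,
       assignment = if (length(assignment)) do.call(rbind, assignment) else
         data.frame(uid = character(), leaf = character(),
                    subtype = character()),
       cost = unname(cost), breakdown = breakdown, order = ord)
}

#' Rank ancestral hypotheses by minimum event cost
#'
#' @param obs an [observed_arrangement()].
#' @param hyps list of [ancestral_hypothesis()] objects.
#' @param weights named event weights.
#' @param struct a [scenario_structure()].
#' @param max_pre1r_genes search cap, see [min_cost_scenario()].
#' @return data.frame: hypothesis, cost, n_tandem_dup, n_loss,
#'   n_translocation, n_cooptimal, feasible; sorted by cost then name.
#' @export
compare_hypotheses <- function(obs, hyps, weights = default_event_weights(),
                               struct = scenario_structure(),
                               max_pre1r_genes = 5) {
  stopifnot(length(hyps) >= 2)
  rows <- lapply(hyps, function(h) {
    r <- min_cost_scenario(obs, h, weights, struct, max_pre1r_genes)
    bk <- if (r$feasible) r$scenarios[[1]]$breakdown else
      c(TANDEM_DUP = NA, LOSS = NA, TRANSLOCATION = NA)
    data.frame(hypothesis = h$name, cost = r$cost,
               n_tandem_dup = bk[["TANDEM_DUP"]], n_loss = bk[["LOSS"]],
               n_translocation = bk[["TRANSLOCATION"]],
               n_cooptimal = r$n_cooptimal, feasible = r$feasible,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$cost, tab$hypothesis), , drop = FALSE]
}
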