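## Same-chromosome, same-strand subtype pair detection with a
## proximal/distal split at a 100-kbp window: every unordered pair of
## genes with different visual-opsin subtypes on the same species,
## chromosome and strand is one event; the gap is the inter-gene gap
## (nearest ends, 0 for overlapping genes) and proximal means strictly
## less than the window.

#' Scan gene records for same-strand subtype pairs
#'
#' Emits one pair event for every unordered pair of genes with different
#' (accepted) subtypes that share species, chromosome and strand.
#' `gap_bp = max(0, later.start - earlier.end)`; `proximal` iff
#' `gap_bp < window` (strict). Genes without a subtype are skipped with a
#' warning. With `start_to_start = TRUE` the distance is measured between
#' start coordinates instead (sensitivity mode).
#'
#' @param genes `gene_records`; the `subtype` column holds accepted
#'   subtype labels (NA = unclassified).
#' @param window proximal/distal boundary in bp (> 0), default 100000.
#' @param subtypes subtype labels considered; defaults to the five visual
#'   opsin subtypes.
#' @param start_to_start alternative distance definition flag.
#' @return data.frame of pair events: species, seq_id, gene_a, gene_b
#'   (lexicographically ordered), subtype_a, subtype_b, subtype_pair
#'   (unordered label pair, "X-Y" with X < Y), gap_bp, proximal.
#' @export
scan_pairs <- function(genes, window = 100000, subtypes = VISUAL_SUBTYPES,
                       start_to_start = FALSE) {
  stopifnot(window > 0)
  genes <- validate_gene_records(genes)
  if (any(is.na(genes$subtype)))
    warning(sum(is.na(genes$subtype)), " genes lack a subtype; skipped")
  g <- genes[!is.na(genes$subtype) & genes$subtype %in% subtypes, ]
  out <- list()
  if (nrow(g) >= 2) {
    key <- paste(g$species, g$seq_id, g$strand, sep = "\r")
    for (k in unique(key)) {
      gg <- g[key == k, ]
      if (nrow(gg) < 2) next
      for (i in seq_len(nrow(gg) - 1)) for (j in (i + 1):nrow(gg)) {
        if (gg$subtype[i] == gg$subtype[j]) next
        a <- i; b <- j
        if (gg$gene_id[b] < gg$gene_id[a]) { a <- j; b <- i }
        gap <- if (start_to_start) abs(gg$start[i] - gg$start[j]) else
          max(0, max(gg$start[i], gg$start[j]) -
                 min(gg$end[i], gg$end[j]))
        st <- sort(c(gg$subtype[i], gg$subtype[j]))
        out[[length(out) + 1L]] <- data.frame(
          species = gg$species[1], seq_id = gg$seq_id[1],
          gene_a = gg$gene_id[a], gene_b = gg$gene_id[b],
          subtype_a = gg$subtype[a], subtype_b = gg$subtype[b],
          subtype_pair = paste(st, collapse = "-"),
          gap_bp = gap, proximal = gap < window,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(
    species = character(), seq_id = character(), gene_a = character(),
    gene_b = character(), subtype_a = character(), subtype_b = character(),
    subtype_pair = character(), gap_bp = numeric(), proximal = logical()))
  ev <- do.call(rbind, out)
  ev[order(ev$species, ev$seq_id, ev$gene_a, ev$gene_b), , drop = FALSE]
}

#' Summarize pair events by subtype pair and taxon group
#'
#' Counts events per subtype pair split into proximal and distal, plus the
#' percentage share of each taxon group within each distance class.
#' Percentages are only emitted when the class has events; they sum to 100
#' within a class. With `collapse_species = TRUE` each
#' (species, subtype_pair, class) combination counts once, since the unit
#' of published pair counts is not always the gene pair.
#'
#' @param events output of [scan_pairs()].
#' @param taxa data.frame species, group (see [read_taxon_table()]).
#' @param collapse_species count species exhibiting a pair rather than
#'   gene pairs.
#' @return list with `counts` (subtype_pair x proximal/distal) and
#'   `group_shares` (distance class x group percentage).
#' @export
summarize_pairs <- function(events, taxa, collapse_species = FALSE) {
  missing_sp <- setdiff(unique(events$species), taxa$species)
  if (length(missing_sp))
    stop("species missing from taxon table: ", paste(missing_sp, collapse = ", "))
  if (collapse_species)
    events <- unique(events[, c("species", "subtype_pair", "proximal")])
  cls <- ifelse(events$proximal, "proximal", "distal")
  counts <- as.data.frame.matrix(table(
    factor(events$subtype_pair),
    factor(cls, levels = c("proximal", "distal"))))
  counts <- cbind(subtype_pair = rownames(counts), counts,
                  stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  grp <- setNames(taxa$group, taxa$species)
  shares <- list()
  for (cl in c("proximal", "distal")) {
    ev <- events[cls == cl, ]
    if (!nrow(ev)) next
    tab <- table(grp[ev$species])
    shares[[cl]] <- data.frame(class = cl, group = names(tab),
                               percent = 100 * as.numeric(tab) / nrow(ev),
                               stringsAsFactors = FALSE)
  }
  group_shares <- if (length(shares)) do.call(rbind, c(shares, list(make.row.names = FALSE)))
  else data.frame(class = character(), group = character(), percent = numeric())
  list(counts = counts, group_shares = group_shares)
}
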