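## Distance-based opsin subtype classification with column-bootstrap
## support: a query is profile-aligned into the reference column space,
## then bootstrap resamples of the columns vote for the nearest subtype
## by mean Poisson-corrected distance to each subtype's reference rows.
## An explicit "nonvisual" class (OPN3/parapinopsin-like rows) makes
## "not a visual opsin" a possible outcome instead of a forced call.

VISUAL_SUBTYPES <- c("LWS", "SWS1", "SWS2", "RH1", "RH2")

#' Reference subtype database
#'
#' @param subtypes named list: subtype label -> character vector of
#'   aligned reference rows (all rows across all subtypes must share one
#'   column space, i.e. equal length). Every subtype needs >= 2 rows.
#' @return object of class `reference_db`.
#' @export
reference_db <- function(subtypes) {
  stopifnot(is.list(subtypes), !is.null(names(subtypes)))
  lens <- unlist(lapply(subtypes, nchar), use.names = FALSE)
  if (length(unique(lens)) != 1) stop("reference rows are not congruent")
  for (s in names(subtypes))
    if (length(subtypes[[s]]) < 2) stop("subtype needs >= 2 rows: ", s)
  structure(list(subtypes = subtypes, width = lens[1]), class = "reference_db")
}

#' Read/write a reference database directory
#'
#' One aligned FASTA per subtype, named `<subtype>.fasta`.
#' @param dir directory path.
#' @return a `reference_db`.
#' @export
read_reference_db <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(files)) stop("no reference alignments in ", dir)
  subtypes <- lapply(files, read_alignment)
  names(subtypes) <- sub("\\.fasta$", "", basename(files))
  reference_db(subtypes)
}

#' @rdname read_reference_db
#' @param db a `reference_db`.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(db$subtypes))
    write_fasta(db$subtypes[[s]], file.path(dir, paste0(s, ".fasta")))
  invisible(dir)
}

#' Build a reference database from truth-labelled genes
#'
#' Stands in for curated reference alignments: takes all genes with a
#' known subtype from species other than `exclude_species`
#' (leave-one-species-out, so a query is never classified against its own
#' genome). Rows are ungapped and equal-length per construction of the
#' simulator (no indels), hence congruent.
#' @param genes `gene_records` with `protein` and truth `subtype`.
#' @param exclude_species species to leave out.
#' @return a `reference_db`.
#' @export
reference_db_from_genes <- function(genes, exclude_species = character()) {
  g <- genes[!is.na(genes$subtype) & !genes$species %in% exclude_species, ]
  if (!nrow(g)) stop("no labelled reference genes available")
  rows <- split(setNames(g$protein, gene_key(g$species, g$gene_id)), g$subtype)
  reference_db(rows)
}

#' Classify a protein into an opsin subtype with bootstrap support
#'
#' The query is profile-aligned into the reference column space; each of
#' `n_boot` column resamples (with replacement) votes for the subtype with
#' the smallest mean Poisson-corrected distance between the query and the
#' subtype's rows. Support is the modal vote fraction; the assignment is
#' accepted iff support >= `threshold`. A query aligning with < 50%
#' non-gap columns is returned as "unalignable" (subtype NA, not
#' accepted).
#'
#' @param query amino-acid string.
#' @param db a `reference_db`.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer RNG seed.
#' @param threshold acceptance threshold on support (default 0.95,
#'   mirroring a >= 95% ultrafast-bootstrap convention).
#' @param min_identity homology pre-filter: queries whose best identity to
#'   any reference row falls below this are reported as non-opsin
#'   (subtype NA) rather than forced into a nearest class; this mirrors
#'   the homology-search step that precedes classification in practice.
#' @param params alignment parameters.
#' @return list: `subtype`, `support`, `accepted`, `votes` (named numeric
#'   summing to 1), `alignable`.
#' @export
classify_subtype <- function(query, db, n_boot = 1000, seed = 1,
                             threshold = 0.95, min_identity = 0.25,
                             params = default_align_params()) {
  stopifnot(inherits(db, "reference_db"))
  if (n_boot < 100) stop("n_boot must be >= 100")
  all_rows <- unlist(db$subtypes, use.names = FALSE)
  pal <- profile_align(query, setNames(all_rows, seq_along(all_rows)), params)
  qvec <- strsplit(pal$query_in_ref, "")[[1]]
  n <- db$width
  empty_votes <- setNames(rep(0, length(db$subtypes)), names(db$subtypes))
  if (mean(qvec != "-") < 0.5) {
    return(list(subtype = NA_character_, support = 0, accepted = FALSE,
                votes = empty_votes, alignable = FALSE))
  }
  best_id <- max(vapply(all_rows, function(r)
    percent_identity(pal$query_in_ref, r), 0))
  if (best_id < min_identity) {
    return(list(subtype = NA_character_, support = 0, accepted = FALSE,
                votes = empty_votes, alignable = TRUE))
  }
  ## per reference row: comparable / mismatch indicators per column
  labs <- rep(names(db$subtypes), vapply(db$subtypes, length, 1L))
  refchar <- do.call(rbind, strsplit(all_rows, ""))
  qmat <- matrix(qvec, nrow = nrow(refchar), ncol = n, byrow = TRUE)
  comparable <- refchar != "-" & qmat != "-"
  mismatch <- comparable & refchar != qmat

  set.seed(as.integer(seed))
  classes <- sort(unique(labs))
  votes <- setNames(rep(0L, length(classes)), classes)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ncomp <- rowSums(comparable[, idx, drop = FALSE])
    nmis <- rowSums(mismatch[, idx, drop = FALSE])
    p <- ifelse(ncomp > 0, nmis / ncomp, 19 / 20)
    d <- poisson_distance(pmin(p, 1))
    md <- tapply(as.numeric(d), labs, mean)
    win <- sort(names(md)[md == min(md)])[1]
    votes[win] <- votes[win] + 1L
  }
  votes <- votes / n_boot
  win <- sort(names(votes)[votes == max(votes)])[1]
  list(subtype = win, support = unname(votes[win]),
       accepted = unname(votes[win]) >= threshold, votes = votes,
       alignable = TRUE)
}

#' Classify every gene of every species, leave-one-species-out
#'
#' For each species, builds a reference database from the truth-labelled
#' genes of the other species and classifies all of that species' genes.
#' @param genes `gene_records` with proteins and truth subtypes (the
#'   subtypes are used only to build the reference panels, never to score
#'   the focal species' own genes).
#' @param n_boot,threshold,seed,params passed to [classify_subtype()].
#' @return data.frame: species, gene_id, subtype, support, accepted.
#' @export
classify_genomes <- function(genes, n_boot = 200, threshold = 0.95,
                             seed = 1, min_identity = 0.25,
                             params = default_align_params()) {
  out <- list()
  for (sp in sort(unique(genes$species))) {
    db <- reference_db_from_genes(genes, exclude_species = sp)
    g <- genes[genes$species == sp, ]
    for (i in seq_len(nrow(g))) {
      cl <- classify_subtype(g$protein[i], db, n_boot = n_boot,
                             seed = seed + i, threshold = threshold,
                             min_identity = min_identity, params = params)
      out[[length(out) + 1L]] <- data.frame(
        species = sp, gene_id = g$gene_id[i], subtype = cl$subtype,
        support = cl$support, accepted = cl$accepted,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
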