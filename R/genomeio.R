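#' @useDynLib opsinteny, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import ape
#' @importFrom stats setNames rpois runif rlnorm
#' @importFrom utils combn read.delim write.table head tail
NULL

## Internal convention: all gene coordinates are 0-based, half-open
## [start, end).  Conversion to/from 1-based inclusive happens only at
## file boundaries (GFF3); BED is already 0-based half-open.

#' Construct a validated gene record table
#'
#' The central flat container of the package: one row per annotated gene.
#' Coordinates are 0-based half-open; `strand` must be `"+"` or `"-"`.
#' `protein`, `subtype` and `family` are optional annotations (NA when
#' unknown).
#'
#' @param gene_id character vector, unique within each species.
#' @param species character vector of species identifiers.
#' @param seq_id character vector of chromosome/scaffold identifiers.
#' @param start,end numeric, 0-based half-open; `start < end`.
#' @param strand character, `"+"` or `"-"`.
#' @param protein optional amino-acid strings.
#' @param subtype optional subtype labels (e.g. "LWS", "RH1").
#' @param family optional gene-family labels.
#' @return data.frame with class `c("gene_records", "data.frame")`.
#' @export
gene_records <- function(gene_id, species, seq_id, start, end, strand,
                         protein = NA_character_, subtype = NA_character_,
                         family = NA_character_) {
  n <- length(gene_id)
  recycle <- function(x) if (length(x) == 1 && n != 1) rep(x, n) else x
  species <- recycle(species); seq_id <- recycle(seq_id)
  strand <- recycle(strand)
  protein <- recycle(protein); subtype <- recycle(subtype)
  family <- recycle(family)
  df <- data.frame(
    gene_id = as.character(gene_id), species = as.character(species),
    seq_id = as.character(seq_id), start = as.numeric(start),
    end = as.numeric(end), strand = as.character(strand),
    protein = as.character(protein), subtype = as.character(subtype),
    family = as.character(family), stringsAsFactors = FALSE
  )
  validate_gene_records(df)
}

validate_gene_records <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("gene_id", "species", "seq_id", "start", "end", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("gene records missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(!df$strand %in% c("+", "-")))
      stop("missing strand: every gene needs strand '+' or '-'")
    if (any(df$start < 0)) stop("negative start coordinate")
    if (any(df$end <= df$start)) stop("end <= start in gene records")
    dup <- duplicated(df[, c("species", "gene_id")])
    if (any(dup)) stop("duplicate gene_id within species: ",
                       paste(unique(df$gene_id[dup]), collapse = ", "))
  }
  for (opt in c("protein", "subtype", "family"))
    if (is.null(df[[opt]])) df[[opt]] <- NA_character_
  class(df) <- unique(c("gene_records", class(df)))
  df
}

#' Read gene annotations from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; BED is passed through. Only `gene`-type
#' features are kept from GFF3. The `ID` attribute becomes `gene_id`; a
#' `family` attribute, when present, is carried over.
#'
#' @param path file path.
#' @param species species label to attach to every record.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return a `gene_records` data.frame.
#' @export
read_annotations <- function(path, species, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3")
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st == "*")) stop("missing strand in ", path)
  if (format == "gff3") {
    type <- as.character(gr$type)
    keep <- type == "gene"
    gr <- gr[keep]
    st <- st[keep]
    ids <- gr$ID
    fam <- if (!is.null(gr$family)) as.character(gr$family) else NA_character_
  } else {
    ids <- gr$name
    fam <- NA_character_
  }
  if (is.null(ids) || any(is.na(ids))) stop("every feature needs an ID/name")
  ## GRanges is 1-based inclusive for both dialects after import
  gene_records(
    gene_id = as.character(ids), species = species,
    seq_id = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
    strand = st, family = fam
  )
}

#' Write gene records as GFF3
#'
#' Emits minimal GFF3 (version 3 header, `gene` features, `ID=` and
#' `family=` attributes). Internal 0-based starts are written as
#' 1-based inclusive. Output is byte-stable for a given input.
#'
#' @param genes a `gene_records` data.frame (single species).
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  genes <- validate_gene_records(genes)
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(is.na(genes$family), "",
                         paste0(";family=", genes$family)))
  lines <- sprintf("%s\topsinteny\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$seq_id, as.integer(genes$start) + 1L,
                   as.integer(genes$end), genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read/write protein FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as named character
#' vectors so they interoperate with the simulator and aligner.
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but enforces equal row lengths.
#' @param path aligned FASTA file.
#' @return named character vector, all elements the same nchar.
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path)
  if (length(unique(nchar(seqs))) > 1)
    stop("ragged alignment: rows have unequal lengths in ", path)
  seqs
}

#' Read/write Newick trees
#'
#' ape wrappers; node annotations (e.g. bootstrap supports stored as
#' internal node labels) survive the round trip.
#' @param path file path.
#' @return an ape `phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree an ape `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a species/taxon-group table
#'
#' Two-column TSV `species`, `group`; groups follow the study design:
#' teleost, non-teleost jawed, jawless, outgroup.
#' @param path TSV file.
#' @return data.frame with columns species, group.
#' @export
read_taxon_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "group") %in% names(df)))
  if (any(duplicated(df$species))) stop("duplicate species in taxon table")
  df
}

#' @rdname read_taxon_table
#' @param taxa data.frame with columns species, group.
#' @export
write_taxon_table <- function(taxa, path) {
  write.table(taxa, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
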