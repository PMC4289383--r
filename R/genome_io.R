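#' Construct a genome annotation from in-memory components
#'
#' The core container for one genome: a table of representative gene models
#' plus their CDS and protein sequences. Gene-order ranks (0-based, per
#' chromosome/scaffold, ordered by ascending start with ties broken by end
#' then gene id) are assigned here; all tandem and synteny logic downstream
#' works in rank coordinates only, so the base-coordinate convention never
#' leaks past this module.
#'
#' Validation enforces one representative model per locus (duplicate gene
#' ids are an error), `start <= end`, CDS length equal to three times the
#' protein length after stripping a terminal stop codon, and agreement of
#' the translated CDS with the supplied protein under the standard genetic
#' code (internal stops are an error).
#'
#' @param species_tag short species identifier, e.g. `"Ath"`
#' @param genes data.frame with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates, strand `+`/`-`)
#' @param cds named character vector of CDS sequences (names = gene ids)
#' @param protein named character vector of protein sequences
#' @param syntenic_depth positive integer: expected genome multiplicity
#'   relative to the ancestral genome (product of successive WGD/WGT
#'   multipliers); metadata used by depth screening
#' @return an object of class `genome_annotation`
#' @export
genome_annotation <- function(species_tag, genes, cds, protein,
                              syntenic_depth = 1L) {
  stopifnot(is.character(species_tag), length(species_tag) == 1L)
  req <- c("gene_id", "seq_id", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    stop("genes table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  genes <- genes[req]
  genes$gene_id <- as.character(genes$gene_id)
  genes$seq_id <- as.character(genes$seq_id)
  genes$strand <- as.character(genes$strand)

  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop("duplicate gene_id (one representative model per locus required): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(genes$start > genes$end))
    stop("start > end for gene(s): ",
         paste(genes$gene_id[genes$start > genes$end], collapse = ", "),
         call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)

  for (g in genes$gene_id) {
    if (is.na(cds[g]) || is.null(cds[[g]]))
      stop("missing CDS sequence for gene ", g, call. = FALSE)
    if (is.na(protein[g]) || is.null(protein[[g]]))
      stop("missing protein sequence for gene ", g, call. = FALSE)
  }
  cds <- toupper(cds[genes$gene_id])
  protein <- toupper(protein[genes$gene_id])

  stripped <- vapply(cds, strip_terminal_stop, character(1))
  bad_len <- nchar(stripped) != 3L * nchar(protein)
  if (any(bad_len))
    stop("CDS/protein length mismatch for gene(s): ",
         paste(genes$gene_id[bad_len], collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(genes))) {
    tr <- translate_cds(stripped[i])
    if (grepl("*", tr, fixed = TRUE))
      stop("internal stop codon in CDS of gene ", genes$gene_id[i],
           call. = FALSE)
    if (tr != protein[i])
      stop("CDS translation disagrees with protein for gene ",
           genes$gene_id[i], call. = FALSE)
  }

  # rank per seq_id: ascending start, ties by end then gene_id
  ord <- order(genes$seq_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- NA_integer_
  for (s in unique(genes$seq_id)) {
    ix <- which(genes$seq_id == s)
    genes$rank[ix] <- seq_along(ix) - 1L
  }
  rownames(genes) <- NULL

  structure(list(species_tag = species_tag, genes = genes,
                 cds = cds, protein = protein,
                 syntenic_depth = as.integer(syntenic_depth)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %d genes on %d sequence(s), syntenic depth %d\n",
              x$species_tag, nrow(x$genes), length(unique(x$genes$seq_id)),
              x$syntenic_depth))
  invisible(x)
}

#' Load a genome from GFF3 gene features plus CDS and protein FASTA
#'
#' Reads gene features from a GFF3 file, matches each gene's `ID` attribute
#' (configurable) to records in the CDS and protein FASTA files, and returns
#' a validated [genome_annotation()]. FASTA headers are matched on the first
#' whitespace-delimited token.
#'
#' @param gff_file path to a GFF3 file
#' @param cds_file path to a FASTA file of coding sequences
#' @param protein_file path to a FASTA file of protein sequences
#' @param species_tag short species identifier
#' @param id_attr GFF3 attribute holding the gene identifier (default `ID`)
#' @param feature_type GFF3 feature type to load (default `gene`)
#' @param syntenic_depth see [genome_annotation()]
#' @return a `genome_annotation`
#' @export
load_genome <- function(gff_file, cds_file, protein_file, species_tag,
                        id_attr = "ID", feature_type = "gene",
                        syntenic_depth = 1L) {
  gr <- rtracklayer::import(gff_file, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
  if (length(gr) == 0L)
    stop("no '", feature_type, "' features in ", gff_file, call. = FALSE)
  ids <- as.character(S4Vectors::mcols(gr)[[id_attr]])
  if (anyNA(ids))
    stop("gene feature without '", id_attr, "' attribute in ", gff_file,
         call. = FALSE)
  genes <- data.frame(
    gene_id = ids,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    stringsAsFactors = FALSE
  )
  cds_set <- Biostrings::readDNAStringSet(cds_file)
  prot_set <- Biostrings::readAAStringSet(protein_file)
  first_token <- function(x) sub("\\s.*$", "", x)
  cds <- setNames(as.character(cds_set), first_token(names(cds_set)))
  protein <- setNames(as.character(prot_set), first_token(names(prot_set)))
  missing_cds <- setdiff(genes$gene_id, names(cds))
  if (length(missing_cds))
    stop("no CDS record for gene(s): ",
         paste(missing_cds, collapse = ", "), call. = FALSE)
  missing_prot <- setdiff(genes$gene_id, names(protein))
  if (length(missing_prot))
    stop("no protein record for gene(s): ",
         paste(missing_prot, collapse = ", "), call. = FALSE)
  genome_annotation(species_tag, genes, cds, protein, syntenic_depth)
}

#' Write a genome annotation back to GFF3 + FASTA
#'
#' Inverse of [load_genome()]: round-tripping a loaded annotation through
#' `write_genome()`/`load_genome()` reproduces the same gene models.
#'
#' @param ann a `genome_annotation`
#' @param gff_file,cds_file,protein_file output paths
#' @return `ann`, invisibly
#' @export
write_genome <- function(ann, gff_file, cds_file, protein_file) {
  g <- ann$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$seq_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "famscape"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  rtracklayer::export(gr, gff_file, format = "gff3")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(ann$cds[g$gene_id], g$gene_id)),
    cds_file)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(ann$protein[g$gene_id], g$gene_id)),
    protein_file)
  invisible(ann)
}

.gene_row <- function(ann, gene_id) {
  ix <- match(gene_id, ann$genes$gene_id)
  if (is.na(ix))
    stop("unknown gene_id '", gene_id, "' in genome ", ann$species_tag,
         call. = FALSE)
  ann$genes[ix, , drop = FALSE]
}

#' Number of annotated gene models between two genes
#'
#' The gene-spacer count used by the tandem-array window: the number of
#' intervening gene models between two genes on the same
#' chromosome/scaffold (all annotated genes count as spacers; adjacent
#' genes have 0 spacers). Undefined (`NA`) when the genes lie on different
#' sequences.
#'
#' @param ann a `genome_annotation`
#' @param gene_a,gene_b gene ids present in `ann`
#' @return integer spacer count, or `NA_integer_` if the genes are on
#'   different sequences
#' @export
spacer_count <- function(ann, gene_a, gene_b) {
  a <- .gene_row(ann, gene_a)
  b <- .gene_row(ann, gene_b)
  if (a$seq_id != b$seq_id) return(NA_integer_)
  abs(a$rank - b$rank) - 1L
}
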