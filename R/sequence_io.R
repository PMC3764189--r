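# Genome/annotation/ortholog readers and strand-aware upstream extraction.
#
# Coordinate conventions: everything internal is 0-based half-open.
# GFF3 is read as 1-based inclusive and converted on the way in; BED is
# written 0-based half-open on the way out.

#' Read a genome FASTA
#'
#' Loads all records, uppercases them (lowercase repeat masking is
#' discarded) and enforces the A/C/G/T/N alphabet.
#'
#' @param path FASTA file.
#' @param species_id short species label attached to the genome.
#' @return a `genome_seqs` object: list with `species_id` and `records`, a
#'   named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path, species_id = basename(path)) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- names(ss)
  # keep only the first whitespace-delimited token of each header
  nm <- sub("\\s.*$", "", nm)
  if (anyNA(nm) || any(!nzchar(nm))) stop("FASTA record with empty header in ", path)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  for (i in seq_along(seqs)) {
    bad <- gsub("[ACGTN]", "", seqs[[i]])
    if (nzchar(bad)) {
      stop("record '", nm[i], "': disallowed character(s) ",
           paste(unique(strsplit(bad, "", fixed = TRUE)[[1]]), collapse = ", "),
           " (alphabet is A/C/G/T/N)")
    }
  }
  structure(list(species_id = species_id, records = seqs), class = "genome_seqs")
}

#' Construct a genome object from in-memory sequences
#' @param species_id short species label.
#' @param records named character vector of sequences.
#' @export
genome_seqs <- function(species_id, records) {
  stopifnot(is.character(records), !is.null(names(records)))
  if (anyDuplicated(names(records))) stop("duplicate sequence names")
  records <- toupper(records)
  bad <- gsub("[ACGTN]", "", paste(records, collapse = ""))
  if (nzchar(bad)) stop("disallowed character(s) in sequences (alphabet A/C/G/T/N)")
  structure(list(species_id = species_id, records = records), class = "genome_seqs")
}

#' Read gene annotations from GFF3
#'
#' Keeps rows of one feature type (default `"gene"`), converts GFF3
#' 1-based inclusive coordinates to 0-based half-open, and requires a
#' strand and a unique `ID` attribute per gene. Strandless rows are
#' dropped with a warning; a duplicated ID or start > end is fatal.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep.
#' @return data.frame with columns `gene_id`, `seq_name`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(0), seq_name = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids)) stop("gene feature(s) without an ID attribute in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  keep <- strand %in% c("+", "-")
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) without strand dropped: ",
            paste(utils::head(ids[!keep], 5), collapse = ", "))
  }
  gr <- gr[keep]; ids <- ids[keep]; strand <- strand[keep]
  if (anyDuplicated(ids)) {
    stop("duplicate gene ID(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # GRanges is 1-based inclusive; convert to 0-based half-open
  data.frame(
    gene_id = ids,
    seq_name = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Read a three-column ortholog table
#'
#' TSV with header `focal_gene, species_id, ortholog_gene`, one row per
#' (focal gene, species). Focal genes listed twice for the same species
#' are not single-ortholog genes and are excluded entirely; focal genes
#' with orthologs in fewer than `min_other_species` other genomes are
#' dropped. Both removals are reported via message.
#'
#' @param path TSV file.
#' @param min_other_species minimum number of other species with a single
#'   ortholog (default 2).
#' @return data.frame `focal_gene`, `species_id`, `ortholog_gene` for the
#'   retained focal genes, with attributes `n_dropped_few_orthologs` and
#'   `n_dropped_non_single`.
#' @export
read_ortholog_table <- function(path, min_other_species = 2L) {
  if (!file.exists(path)) stop("ortholog table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("focal_gene", "species_id", "ortholog_gene")
  if (!all(need %in% names(df))) {
    stop("ortholog table must have header columns: ", paste(need, collapse = ", "))
  }
  filter_ortholog_map(df[need], min_other_species = min_other_species)
}

#' Apply the single-ortholog / minimum-species filter to an ortholog map
#'
#' @param df data.frame with `focal_gene`, `species_id`, `ortholog_gene`.
#' @param min_other_species minimum other-species count (default 2).
#' @export
filter_ortholog_map <- function(df, min_other_species = 2L) {
  key <- paste(df$focal_gene, df$species_id, sep = "\r")
  non_single <- unique(df$focal_gene[key %in% key[duplicated(key)]])
  df1 <- df[!(df$focal_gene %in% non_single), , drop = FALSE]
  cnt <- table(df1$focal_gene)
  few <- names(cnt)[cnt < min_other_species]
  out <- df1[!(df1$focal_gene %in% few), , drop = FALSE]
  rownames(out) <- NULL
  if (length(non_single) > 0L) {
    message(length(non_single), " focal gene(s) excluded as non-single-ortholog")
  }
  if (length(few) > 0L) {
    message(length(few), " focal gene(s) dropped with orthologs in < ",
            min_other_species, " other species")
  }
  attr(out, "n_dropped_non_single") <- length(non_single)
  attr(out, "n_dropped_few_orthologs") <- length(few)
  out
}

#' Extract the strand-aware upstream region of a gene
#'
#' For a plus-strand gene the window is `[max(0, start - window_bp), start)`;
#' for a minus-strand gene it is `[end, min(L, end + window_bp))`
#' reverse-complemented. The returned sequence is oriented 5'→3' toward the
#' gene, so its final base abuts the gene start. Windows are truncated at
#' contig edges; a zero-length window returns an empty region with a warning.
#'
#' @param gene one row of [read_gene_annotation()] output (or an equivalent
#'   list with `gene_id`, `seq_name`, `start`, `end`, `strand`).
#' @param genome a `genome_seqs` object.
#' @param window_bp upstream window length (default 5000).
#' @return an `upstream_region`: list with `gene_id`, `species_id`, `seq`,
#'   `seq_name`, `gstart`, `gend` (genomic 0-based half-open), `strand`,
#'   `window_bp`.
#' @export
extract_upstream <- function(gene, genome, window_bp = 5000L) {
  stopifnot(inherits(genome, "genome_seqs"), window_bp >= 1L)
  seq_name <- gene$seq_name
  if (!seq_name %in% names(genome$records)) {
    stop("sequence '", seq_name, "' not present in genome '", genome$species_id, "'")
  }
  contig <- genome$records[[seq_name]]
  L <- nchar(contig)
  if (!(gene$start >= 0 && gene$start < gene$end && gene$end <= L)) {
    stop("gene '", gene$gene_id, "' does not lie within sequence '", seq_name, "'")
  }
  if (gene$strand == "+") {
    gstart <- max(0L, gene$start - as.integer(window_bp))
    gend <- gene$start
    seq <- substr(contig, gstart + 1L, gend)
  } else if (gene$strand == "-") {
    gstart <- gene$end
    gend <- min(L, gene$end + as.integer(window_bp))
    seq <- revcomp_dna(substr(contig, gstart + 1L, gend))
  } else {
    stop("gene '", gene$gene_id, "' has no strand")
  }
  if (gend <= gstart) {
    warning("gene '", gene$gene_id, "': upstream window collapses to length 0 at contig edge")
    seq <- ""
    gstart <- gend
  }
  structure(list(
    gene_id = gene$gene_id,
    species_id = genome$species_id,
    seq = seq,
    seq_name = seq_name,
    gstart = as.integer(gstart),
    gend = as.integer(gend),
    strand = gene$strand,
    window_bp = as.integer(window_bp)
  ), class = "upstream_region")
}

#' Map a region-coordinate interval to genomic coordinates
#'
#' Position `w` in region coordinates (0-based along the oriented 5'→3'
#' upstream sequence) maps back to the genome; for minus-strand genes the
#' mapping reverses and the motif strand flips.
#'
#' @param region an `upstream_region`.
#' @param offset 0-based start offset within the region sequence.
#' @param width interval width in bp.
#' @param strand_rel strand of the feature relative to the region (`+`/`-`).
#' @return list with `seq_name`, `gstart`, `gend` (0-based half-open) and
#'   `gstrand` (genomic strand of the feature).
#' @export
region_to_genomic <- function(region, offset, width, strand_rel = "+") {
  stopifnot(inherits(region, "upstream_region"))
  n <- nchar(region$seq)
  stopifnot(offset >= 0, offset + width <= n)
  if (region$strand == "+") {
    gstart <- region$gstart + offset
    gstrand <- strand_rel
  } else {
    gstart <- region$gend - offset - width
    gstrand <- if (strand_rel == "+") "-" else "+"
  }
  list(seq_name = region$seq_name, gstart = as.integer(gstart),
       gend = as.integer(gstart + width), gstrand = gstrand)
}

#' Write site calls as BED6
#'
#' 0-based half-open; the strand column is the genomic strand of the motif
#' match; the name column carries the gene id, with two ids joined by a
#' comma when one site lies in the shared upstream window of head-to-head
#' genes. Rows at identical genomic coordinates for different genes are
#' merged into one record.
#'
#' @param sites data.frame with columns `seq_name`, `gstart`, `gend`,
#'   `gene_id`, `gstrand` (as produced by [run_screen()]'s site table).
#' @param path output file.
#' @export
write_sites_bed <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6: chrom start end name score strand (0-based half-open)", con)
  if (is.null(sites) || nrow(sites) == 0L) return(invisible(path))
  key <- paste(sites$seq_name, sites$gstart, sites$gend, sites$gstrand, sep = "\r")
  first <- !duplicated(key)
  name <- vapply(key[first], function(k) {
    paste(unique(sites$gene_id[key == k]), collapse = ",")
  }, character(1L))
  out <- sites[first, , drop = FALSE]
  writeLines(paste(out$seq_name, out$gstart, out$gend, name, ".", out$gstrand,
                   sep = "\t"), con)
  invisible(path)
}
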