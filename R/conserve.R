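# Conservation calls for focal-genome motif hits, and the combinatorial
# two-motif proximity filter.
#
# A focal hit is supported by another species when (i) the hit lies fully
# inside a conserved block on the focal side of the focal-vs-that-species
# alignment and (ii) the block's interval on the other species' region
# contains at least one occurrence of the same motif on either strand.
# "Anywhere inside the block" is the default reading; `strict_position`
# instead requires a partner occurrence within the partner-side interval
# that the hit's own alignment columns map to.

#' Call conservation for focal-genome motif hits
#'
#' @param hits data.frame of focal-region hits from [scan_motif()].
#' @param blocks data.frame of conserved blocks from
#'   [extract_conserved_blocks()], accumulated over the focal-vs-other
#'   alignments of this gene (focal species on side "a").
#' @param other_regions named list (by species_id) of the other species'
#'   `upstream_region` objects.
#' @param pattern the [compile_motif()] pattern that produced `hits`.
#' @param min_species minimum number of supporting other species for a
#'   hit to be called conserved (default 2).
#' @param alignments optional named list (by species_id) of
#'   `pairwise_alignment` objects; required for `strict_position`.
#' @param strict_position if `TRUE`, the partner-side motif must lie
#'   within the partner interval spanned by the hit's own alignment
#'   columns, not merely anywhere in the block.
#' @return `hits` with added columns `n_support`, `supporting_species`
#'   (comma-separated), `conserved`.
#' @export
conserve_hits <- function(hits, blocks, other_regions, pattern,
                          min_species = 2L, alignments = NULL,
                          strict_position = FALSE) {
  stopifnot(inherits(pattern, "motif_pattern"))
  n_support <- integer(nrow(hits))
  supporting <- character(nrow(hits))
  if (nrow(hits) > 0L) {
    for (h in seq_len(nrow(hits))) {
      lo <- hits$offset[h]
      hi <- lo + hits$width[h]
      supp <- character(0)
      for (sp in names(other_regions)) {
        bl <- blocks[blocks$species_b == sp, , drop = FALSE]
        if (nrow(bl) == 0L) next
        inside <- !is.na(bl$start_a) & bl$start_a <= lo & hi <= bl$end_a
        if (!any(inside)) next
        found <- FALSE
        for (b in which(inside)) {
          win <- .partner_window(bl[b, ], lo, hi, sp, alignments, strict_position)
          if (is.null(win)) next
          sub <- substr(other_regions[[sp]]$seq, win[1] + 1L, win[2])
          if (nchar(sub) >= pattern$length && has_motif(sub, pattern)) {
            found <- TRUE
            break
          }
        }
        if (found) supp <- c(supp, sp)
      }
      n_support[h] <- length(supp)
      supporting[h] <- paste(sort(supp), collapse = ",")
    }
  }
  hits$n_support <- n_support
  hits$supporting_species <- supporting
  hits$conserved <- n_support >= min_species
  hits
}

# Partner-side search window for one (block, hit) pair: the whole block
# interval by default, or the mapped image of the hit's columns under
# strict positioning.
.partner_window <- function(block, lo, hi, sp, alignments, strict_position) {
  if (!strict_position) return(c(block$start_b, block$end_b))
  aln <- alignments[[sp]]
  if (is.null(aln)) stop("strict_position requires the per-species alignments")
  cols <- which(!is.na(aln$off_a) & aln$off_a >= lo & aln$off_a < hi)
  if (length(cols) == 0L) return(NULL)
  ob <- aln$off_b[min(cols):max(cols)]
  ob <- ob[!is.na(ob)]
  if (length(ob) == 0L) return(NULL)
  c(min(ob), max(ob) + 1L)
}

#' Pair conserved primary sites with nearby conserved secondary sites
#'
#' Every (primary, secondary) pair of *conserved* calls on the same focal
#' region whose nearest-edge gap is at most `max_distance` bp (inclusive;
#' overlapping or adjacent motifs have distance 0). Both strands are
#' eligible. Sorted by primary offset.
#'
#' @param primary_calls,secondary_calls [conserve_hits()] outputs for the
#'   same focal gene/region.
#' @param max_distance maximum nearest-edge gap in bp (default 110).
#' @return data.frame with `gene_id`, `primary_offset`, `primary_strand`,
#'   `secondary_offset`, `secondary_strand`, `distance_bp`.
#' @export
composite_filter <- function(primary_calls, secondary_calls, max_distance = 110L) {
  p <- primary_calls[primary_calls$conserved, , drop = FALSE]
  s <- secondary_calls[secondary_calls$conserved, , drop = FALSE]
  out <- list()
  if (nrow(p) > 0L && nrow(s) > 0L) {
    for (i in seq_len(nrow(p))) {
      e1 <- p$offset[i] + p$width[i]
      gap <- pmax(0L, pmax(s$offset - e1, p$offset[i] - (s$offset + s$width)))
      keep <- which(gap <= max_distance)
      if (length(keep) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = p$gene_id[i],
          primary_offset = p$offset[i], primary_strand = p$strand[i],
          secondary_offset = s$offset[keep], secondary_strand = s$strand[keep],
          distance_bp = as.integer(gap[keep]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0), primary_offset = integer(0),
                      primary_strand = character(0), secondary_offset = integer(0),
                      secondary_strand = character(0), distance_bp = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$primary_offset, res$secondary_offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-gene tallies of hits, conserved calls and composite sites
#'
#' One row per gene; a gene is counted once however many sites it
#' carries, and the counts obey `n_composite <= n_conserved <= n_hits`
#' at the gene-presence level (every composite gene is a conserved gene).
#'
#' @param calls accumulated primary-motif [conserve_hits()] output.
#' @param composites accumulated [composite_filter()] output.
#' @param all_genes optional character vector of gene ids to include even
#'   with zero hits (`include_empty` behaviour).
#' @return data.frame with `gene_id`, `n_hits`, `n_conserved`,
#'   `n_composite` (distinct conserved primary sites with a qualifying
#'   secondary partner, so `n_composite <= n_conserved`),
#'   `first_conserved_offset`.
#' @export
summarize_genes <- function(calls, composites, all_genes = NULL) {
  genes <- if (is.null(all_genes)) unique(calls$gene_id) else all_genes
  rows <- lapply(genes, function(g) {
    cg <- calls[calls$gene_id == g, , drop = FALSE]
    comp <- composites[composites$gene_id == g, , drop = FALSE]
    off <- cg$offset[cg$conserved]
    data.frame(gene_id = g,
               n_hits = nrow(cg),
               n_conserved = sum(cg$conserved),
               n_composite = nrow(unique(comp[, c("primary_offset", "primary_strand")])),
               first_conserved_offset = if (length(off)) min(off) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_hits = integer(0),
                      n_conserved = integer(0), n_composite = integer(0),
                      first_conserved_offset = integer(0), stringsAsFactors = FALSE)
  }
  out
}
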