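# End-to-end orchestration: extract upstream regions of focal genes and
# their orthologs, scan the focal regions for the primary and secondary
# motifs, align focal vs each other species, extract conserved blocks,
# call conservation, apply the proximity filter, and tally genes.

#' Build and validate a pipeline configuration
#'
#' Unspecified fields take the screen's defaults: 5 kb upstream windows,
#' primary motif RTGGGAA (CSL/LAG-1), secondary motif TRTTKRY (FoxA),
#' conserved blocks of >= 14 nt at >= 70% identity, conservation support
#' from >= 2 other genomes, composite sites within 110 bp, both strands.
#' All violations are reported together.
#'
#' @param config named list (or path handled by [read_pipeline_config()])
#'   overriding any defaults.
#' @return validated config list.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    window_bp = 5000L,
    primary_motif = c(label = "LAG1", iupac = "RTGGGAA"),
    secondary_motif = c(label = "FOXA", iupac = "TRTTKRY"),
    min_block_len = 14L,
    min_block_identity = 0.70,
    identity_denominator = "all",
    min_species = 2L,
    max_composite_distance = 110L,
    strands = "both",
    strict_position = FALSE,
    feature = "gene",
    include_empty = FALSE,
    alignment = alignment_params()
  )
  unknown <- setdiff(names(config), c(names(defaults),
                                      "focal_species", "paths", "seed"))
  cfg <- utils::modifyList(defaults, config)
  errs <- character(0)
  if (length(unknown) > 0L) {
    errs <- c(errs, paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  }
  num_pos <- c("window_bp", "min_block_len", "min_species", "max_composite_distance")
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      errs <- c(errs, paste0(f, " must be a positive number (got ",
                             paste(cfg[[f]], collapse = ","), ")"))
    }
  }
  if (!is.numeric(cfg$min_block_identity) || cfg$min_block_identity <= 0 ||
      cfg$min_block_identity > 1) {
    errs <- c(errs, paste0("min_block_identity must lie in (0, 1] (got ",
                           cfg$min_block_identity, ")"))
  }
  if (!cfg$strands %in% c("both", "+", "-")) {
    errs <- c(errs, paste0("unknown strands value '", cfg$strands, "'"))
  }
  if (!cfg$identity_denominator %in% c("all", "ungapped")) {
    errs <- c(errs, paste0("unknown identity_denominator '", cfg$identity_denominator, "'"))
  }
  for (m in c("primary_motif", "secondary_motif")) {
    v <- cfg[[m]]
    if (is.null(v)) next
    if (is.character(v) && length(v) == 1L && grepl(":", v)) {
      parts <- strsplit(v, ":", fixed = TRUE)[[1]]
      v <- c(label = parts[1], iupac = parts[2])
    }
    if (!all(c("label", "iupac") %in% names(v))) {
      errs <- c(errs, paste0(m, " must be c(label=, iupac=) or 'LABEL:IUPAC'"))
    } else {
      cfg[[m]] <- v
    }
  }
  if (!inherits(cfg$alignment, "alignment_params")) {
    cfg$alignment <- tryCatch(do.call(alignment_params, as.list(cfg$alignment)),
                              error = function(e) e)
    if (inherits(cfg$alignment, "error")) {
      errs <- c(errs, paste("invalid alignment parameters:",
                            conditionMessage(cfg$alignment)))
    }
  }
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  cfg$window_bp <- as.integer(cfg$window_bp)
  cfg$min_block_len <- as.integer(cfg$min_block_len)
  cfg$min_species <- as.integer(cfg$min_species)
  cfg$max_composite_distance <- as.integer(cfg$max_composite_distance)
  cfg
}

#' Read a YAML pipeline configuration file
#' @param path YAML file; keys as in [validate_config()].
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the conservation screen on in-memory objects
#'
#' @param genomes named list (by species_id) of `genome_seqs`; must
#'   include the focal species.
#' @param annotations named list (by species_id) of gene annotation
#'   data.frames ([read_gene_annotation()] layout).
#' @param orthologs data.frame `focal_gene`, `species_id`,
#'   `ortholog_gene`; filtered through [filter_ortholog_map()].
#' @param focal_species species_id of the focal genome.
#' @param config list from [validate_config()] (re-validated here).
#' @return list with `sites` (per-site conservation calls, genomic
#'   coordinates, shared head-to-head flag), `composites`, `summary`
#'   (per-gene tallies), `report` (funnel counts and config echo).
#' @export
run_screen <- function(genomes, annotations, orthologs, focal_species,
                       config = list()) {
  cfg <- validate_config(config)
  if (!focal_species %in% names(genomes)) {
    stop("focal species '", focal_species, "' absent from genome set")
  }
  miss <- setdiff(unique(orthologs$species_id), names(genomes))
  if (length(miss) > 0L) {
    stop("species in ortholog table absent from genome set: ",
         paste(miss, collapse = ", "))
  }
  # gene eligibility (single orthologs in >= 2 other genomes) is a fixed
  # property of the input set, independent of the conservation threshold
  orthologs <- suppressMessages(filter_ortholog_map(orthologs, min_other_species = 2L))
  primary <- compile_motif(cfg$primary_motif[["label"]], cfg$primary_motif[["iupac"]])
  secondary <- if (!is.null(cfg$secondary_motif)) {
    compile_motif(cfg$secondary_motif[["label"]], cfg$secondary_motif[["iupac"]])
  } else NULL

  focal_ann <- annotations[[focal_species]]
  n_genes_in <- nrow(focal_ann)
  focal_genes <- intersect(unique(orthologs$focal_gene), focal_ann$gene_id)
  n_genes_with_orthologs <- length(focal_genes)
  if (n_genes_with_orthologs == 0L) {
    warning("zero retained genes; outputs are empty")
  }

  ann_index <- lapply(annotations, function(a) setNames(seq_len(nrow(a)), a$gene_id))
  all_calls <- list(); all_calls2 <- list(); all_comps <- list()
  n_genes_with_hits <- 0L

  for (g in focal_genes) {
    grow <- focal_ann[ann_index[[focal_species]][[g]], ]
    region <- withCallingHandlers(
      extract_upstream(grow, genomes[[focal_species]], cfg$window_bp),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!nzchar(region$seq)) next
    hits1 <- scan_motif(region, primary, cfg$strands)
    if (nrow(hits1) == 0L) next
    n_genes_with_hits <- n_genes_with_hits + 1L
    hits2 <- if (!is.null(secondary)) scan_motif(region, secondary, cfg$strands) else NULL

    orows <- orthologs[orthologs$focal_gene == g, , drop = FALSE]
    other_regions <- list(); alns <- list(); blocks <- list()
    for (r in seq_len(nrow(orows))) {
      sp <- orows$species_id[r]
      og <- orows$ortholog_gene[r]
      idx <- ann_index[[sp]][[og]]
      if (is.null(idx) || is.na(idx)) next
      oreg <- withCallingHandlers(
        extract_upstream(annotations[[sp]][idx, ], genomes[[sp]], cfg$window_bp),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!nzchar(oreg$seq)) next
      aln <- align_pair(region, oreg, cfg$alignment)
      aln$species_b <- sp
      bl <- extract_conserved_blocks(aln, cfg$min_block_len, cfg$min_block_identity,
                                     cfg$identity_denominator)
      other_regions[[sp]] <- oreg
      alns[[sp]] <- aln
      if (nrow(bl) > 0L) blocks[[length(blocks) + 1L]] <- bl
    }
    blocks <- if (length(blocks) > 0L) do.call(rbind, blocks) else
      extract_conserved_blocks(pairwise_alignment("A", "A"))[0, ]

    calls1 <- conserve_hits(hits1, blocks, other_regions, primary,
                            cfg$min_species, alns, cfg$strict_position)
    all_calls[[g]] <- calls1
    if (!is.null(secondary)) {
      calls2 <- conserve_hits(hits2, blocks, other_regions, secondary,
                              cfg$min_species, alns, cfg$strict_position)
      all_calls2[[g]] <- calls2
      comp <- composite_filter(calls1, calls2, cfg$max_composite_distance)
      if (nrow(comp) > 0L) all_comps[[g]] <- comp
    }
    # genomic coordinates for the focal calls
    gc <- lapply(seq_len(nrow(calls1)), function(i) {
      region_to_genomic(region, calls1$offset[i], calls1$width[i], calls1$strand[i])
    })
    all_calls[[g]]$seq_name <- vapply(gc, `[[`, character(1L), "seq_name")
    all_calls[[g]]$gstart <- vapply(gc, `[[`, integer(1L), "gstart")
    all_calls[[g]]$gend <- vapply(gc, `[[`, integer(1L), "gend")
    all_calls[[g]]$gstrand <- vapply(gc, `[[`, character(1L), "gstrand")
  }

  sites <- if (length(all_calls) > 0L) do.call(rbind, all_calls) else NULL
  composites <- if (length(all_comps) > 0L) do.call(rbind, all_comps) else
    composite_filter(data.frame(conserved = logical(0)),
                     data.frame(conserved = logical(0)))
  if (is.null(sites)) {
    sites <- data.frame(pattern_label = character(0), gene_id = character(0),
                        species_id = character(0), offset = integer(0),
                        strand = character(0), width = integer(0),
                        site_seq = character(0), n_support = integer(0),
                        supporting_species = character(0), conserved = logical(0),
                        seq_name = character(0), gstart = integer(0),
                        gend = integer(0), gstrand = character(0),
                        stringsAsFactors = FALSE)
  }
  rownames(sites) <- NULL
  # head-to-head shared sites: same genomic interval claimed by two genes
  key <- paste(sites$seq_name, sites$gstart, sites$gend, sites$gstrand, sep = "\r")
  sites$shared <- vapply(seq_along(key), function(i) {
    length(unique(sites$gene_id[key == key[i]])) > 1L
  }, logical(1L))

  summary <- summarize_genes(
    sites, composites,
    all_genes = if (isTRUE(cfg$include_empty)) focal_genes else NULL)
  report <- list(
    n_genes_in = n_genes_in,
    n_genes_with_orthologs = n_genes_with_orthologs,
    n_genes_with_hits = n_genes_with_hits,
    n_genes_conserved = sum(summary$n_conserved > 0L),
    n_genes_composite = sum(summary$n_composite > 0L),
    config = cfg[setdiff(names(cfg), "alignment")],
    alignment = unclass(cfg$alignment)
  )
  list(sites = sites, composites = composites, summary = summary, report = report)
}

#' Run the full screen from files and write the standard outputs
#'
#' Reads per-species genome FASTAs and GFF3 annotations plus the ortholog
#' TSV, runs [run_screen()], and writes `sites.tsv`, `sites.bed`,
#' `composites.tsv`, `gene_summary.tsv` and `report.json` under
#' `out_dir`. Outputs are deterministic for fixed inputs and config.
#'
#' @param paths list with `genomes` (named vector of FASTA paths by
#'   species), `annotations` (named vector of GFF3 paths), `orthologs`
#'   (TSV path).
#' @param focal_species focal species_id (must name one genome).
#' @param out_dir output directory.
#' @param config config overrides, see [validate_config()].
#' @return the [run_screen()] result, invisibly, with `$files` added.
#' @export
run_pipeline <- function(paths, focal_species, out_dir, config = list()) {
  cfg <- validate_config(config)
  genomes <- lapply(names(paths$genomes), function(s) {
    read_genome_fasta(paths$genomes[[s]], species_id = s)
  })
  names(genomes) <- names(paths$genomes)
  annotations <- lapply(names(paths$annotations), function(s) {
    read_gene_annotation(paths$annotations[[s]], feature = cfg$feature)
  })
  names(annotations) <- names(paths$annotations)
  orthologs <- suppressMessages(
    read_ortholog_table(paths$orthologs, min_other_species = 2L))
  res <- run_screen(genomes, annotations, orthologs, focal_species, cfg)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    sites = file.path(out_dir, "sites.tsv"),
    bed = file.path(out_dir, "sites.bed"),
    composites = file.path(out_dir, "composites.tsv"),
    summary = file.path(out_dir, "gene_summary.tsv"),
    report = file.path(out_dir, "report.json")
  )
  utils::write.table(res$sites, files$sites, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sites_bed(res$sites, files$bed)
  utils::write.table(res$composites, files$composites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$summary, files$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(res$report, files$report, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  res$files <- files
  invisible(res)
}
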