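# Multi-species promoter evolution simulator with planted motif sites.
#
# Each synthetic gene starts from a random ancestral upstream region that
# evolves independently along a star phylogeny to every species: per-site
# substitution to a uniformly chosen different base with probability d
# (a single-step Jukes-Cantor-like replacement, chosen for its closed-form
# expected pairwise identity (1-d)^2 + d^2/3), plus optional geometric
# indels. Genes come in three classes:
#
#   conserved — a concrete instance of the primary motif planted in the
#     ancestor and held invariant in every species, with invariant flanks
#     wide enough that the enclosing alignment block passes the
#     length/identity criterion; composite genes additionally plant an
#     invariant secondary-motif instance nearby.
#   decayed — the site is planted in the focal species only; the
#     orthologous window in every other species is scrambled.
#   negative — no site; chance occurrences removed by rejection.
#
# Chance occurrences of the primary motif are rejection-scrubbed from all
# species' regions of every gene (outside planted windows), so the truth
# table is exact: at low divergence an entire upstream alignment can be a
# single conserved block, and a chance primary-motif occurrence anywhere
# in the partner block would otherwise lend false support to a decayed
# site under the anywhere-in-block conservation rule.

#' Parameters for the synthetic ortholog-set generator
#'
#' Defaults are the screen's study conditions: 20 genes (7 conserved, all
#' composite-positive, 5 decayed, 8 negative), a focal species plus three
#' others, 5 kb regions, per-branch per-site substitution probability
#' 0.05, no indels, the CSL/LAG-1 primary motif RTGGGAA and the FoxA
#' secondary motif TRTTKRY, secondary sites planted within 110 bp.
#'
#' @param n_genes total gene count.
#' @param species_ids character vector of species labels; the first is
#'   the focal species.
#' @param region_len upstream region length in bp.
#' @param divergence per-branch per-site substitution probability `d`.
#' @param indel_rate per-site indel initiation probability.
#' @param indel_len_mean mean of the geometric indel length distribution.
#' @param n_planted_conserved,n_planted_decayed,n_negative gene counts per
#'   class; they must sum to `n_genes`.
#' @param primary_motif,secondary_motif [compile_motif()] objects;
#'   `secondary_motif = NULL` disables composite planting.
#' @param plant_secondary_within maximum planted nearest-edge gap (bp)
#'   between primary and secondary sites in composite genes.
#' @param flank_bp invariant flank width on each side of a planted
#'   conserved site (default 20, enough for the enclosing block to pass
#'   the 14 nt / 70% criterion at moderate divergence).
#' @param seed integer seed; the full output is reproducible from it.
#' @export
simulation_params <- function(n_genes = 20L,
                              species_ids = c("focal", "spB", "spC", "spD"),
                              region_len = 5000L,
                              divergence = 0.05,
                              indel_rate = 0,
                              indel_len_mean = 2,
                              n_planted_conserved = 7L,
                              n_planted_decayed = 5L,
                              n_negative = 8L,
                              primary_motif = compile_motif("LAG1", "RTGGGAA"),
                              secondary_motif = compile_motif("FOXA", "TRTTKRY"),
                              plant_secondary_within = 110L,
                              flank_bp = 20L,
                              seed = 1L) {
  stopifnot(n_planted_conserved + n_planted_decayed + n_negative == n_genes,
            divergence >= 0, divergence < 1, indel_rate >= 0,
            length(species_ids) >= 3L, region_len >= 1L)
  structure(as.list(environment()), class = "simulation_params")
}

#' Closed-form expected pairwise identity between two evolved branches
#'
#' Under the substitution model (each site independently replaced by a
#' uniformly chosen different base with probability `d` on each branch),
#' two descendants of one ancestor agree at a site with probability
#' `(1 - d)^2 + d^2 / 3`.
#'
#' @param d per-branch per-site substitution probability.
#' @export
expected_pairwise_identity <- function(d) (1 - d)^2 + d^2 / 3

#' Evolve a sequence one branch under the substitution+indel model
#'
#' @param ancestor nucleotide string.
#' @param divergence substitution probability per site.
#' @param indel_rate indel initiation probability per site.
#' @param indel_len_mean geometric mean indel length.
#' @param protect_sub,protect_indel optional matrices of 0-based half-open
#'   windows (columns `start`, `end`) shielded from substitutions /
#'   overlapping indels.
#' @return list with `seq` (descendant string) and `map` (integer vector:
#'   for each ancestor position, its 0-based position in the descendant,
#'   or NA if deleted).
#' @export
evolve_sequence <- function(ancestor, divergence, indel_rate = 0,
                            indel_len_mean = 2,
                            protect_sub = NULL, protect_indel = NULL) {
  chars <- strsplit(toupper(ancestor), "", fixed = TRUE)[[1]]
  L <- length(chars)
  shielded <- function(windows) {
    mask <- rep(FALSE, L)
    if (!is.null(windows) && nrow(windows) > 0L) {
      for (w in seq_len(nrow(windows))) {
        s <- max(windows[w, 1] + 1L, 1L)
        e <- min(windows[w, 2], L)
        if (e >= s) mask[s:e] <- TRUE
      }
    }
    mask
  }
  sub_mask <- shielded(protect_sub)
  hit <- runif(L) < divergence & !sub_mask
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(bases, chars[i]), 1L)
    }
  }
  map <- seq_len(L) - 1L
  if (indel_rate > 0) {
    indel_mask <- shielded(protect_indel)
    sites <- which(runif(L) < indel_rate & !indel_mask)
    # apply right to left so earlier coordinates stay valid
    for (i in rev(sites)) {
      len <- rgeom(1L, 1 / indel_len_mean) + 1L
      if (runif(1L) < 0.5) {  # deletion of [i, i+len)
        del <- i:min(i + len - 1L, length(chars))
        if (any(indel_mask[del])) next
        chars <- chars[-del]
        map[del] <- NA_integer_
        shift <- map > (i - 1L)
        shift[is.na(shift)] <- FALSE
        map[shift] <- map[shift] - length(del)
      } else {  # insertion after position i
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        chars <- append(chars, ins, after = i)
        shift <- map > (i - 1L)
        shift[is.na(shift)] <- FALSE
        map[shift] <- map[shift] + len
      }
    }
    # deletions invalidate the simple mask bookkeeping above only for map;
    # indel_mask itself indexes ancestor coordinates throughout, as needed.
  }
  list(seq = paste(chars, collapse = ""), map = map)
}

# Rejection-scrub chance occurrences of `pattern` from `seq`. Matches
# fully inside a `keep` window (0-based half-open matrix) are planted
# sites and stay; positions inside `avoid` windows are never overwritten
# (so scrubbing a match that brushes a planted site only resamples the
# bases outside it). Returns the scrubbed sequence.
.scrub_motif <- function(seq, pattern, keep = NULL, avoid = NULL) {
  k <- pattern$length
  keep_ok <- function(off) {
    if (is.null(keep) || nrow(keep) == 0L) return(FALSE)
    any(keep[, 1] <= off & off + k <= keep[, 2])
  }
  avoided <- function(pos) {  # 0-based position
    if (is.null(avoid) || nrow(avoid) == 0L) return(FALSE)
    any(avoid[, 1] <= pos & pos < avoid[, 2])
  }
  for (iter in 1:500) {
    hits <- scan_motif(seq, pattern, "both")
    hits <- hits[!vapply(hits$offset, keep_ok, logical(1L)), , drop = FALSE]
    if (nrow(hits) == 0L) return(seq)
    off <- hits$offset[1]
    free <- (off:(off + k - 1L))[!vapply(off:(off + k - 1L), avoided, logical(1L))]
    if (length(free) == 0L) stop("chance motif occurrence entirely inside a planted window")
    for (p in free) {
      substr(seq, p + 1L, p + 1L) <- sample(c("A", "C", "G", "T"), 1L)
    }
  }
  stop("failed to scrub chance motif occurrences after 500 rounds")
}

#' Simulate a multi-species orthologous promoter set with planted sites
#'
#' See the class descriptions at the top of this file. Output genomes put
#' each gene on its own contig: for plus-strand genes the upstream region
#' occupies the contig start and the 200 bp gene body follows; strands
#' alternate by gene index to exercise strand-aware extraction (for
#' minus-strand genes the region is stored reverse-complemented after the
#' gene body). All planted offsets in the truth table are focal-region
#' coordinates (0-based, along the oriented 5'-to-3' upstream sequence).
#'
#' @param params a [simulation_params()] object.
#' @return list with `genomes` (named list of `genome_seqs` per species),
#'   `annotations` (named list of gene data.frames per species),
#'   `orthologs` (3-column data.frame), `truth` (per-gene truth table),
#'   `params`.
#' @export
simulate_ortholog_set <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  sp <- params$species_ids
  focal <- sp[1]
  others <- sp[-1]
  L <- params$region_len
  k1 <- params$primary_motif$length
  flank <- params$flank_bp
  gene_len <- 200L
  do_secondary <- !is.null(params$secondary_motif)
  k2 <- if (do_secondary) params$secondary_motif$length else 0L
  max_span <- flank + k1 + (if (do_secondary) params$plant_secondary_within + k2 + flank else flank)
  if (L < max_span + 2L * flank + 10L) {
    stop("region_len ", L, " too short for the requested plants (need > ",
         max_span + 2L * flank + 10L, ")")
  }

  classes <- c(rep("conserved", params$n_planted_conserved),
               rep("decayed", params$n_planted_decayed),
               rep("negative", params$n_negative))
  n <- params$n_genes
  gene_ids <- sprintf("g%03d", seq_len(n))
  bases <- c("A", "C", "G", "T")

  records <- lapply(sp, function(s) character(0))
  names(records) <- sp
  ann <- lapply(sp, function(s) NULL)
  names(ann) <- sp
  ortho <- list()
  truth <- list()

  for (gi in seq_len(n)) {
    g <- gene_ids[gi]
    cls <- classes[gi]
    ancestor <- paste(sample(bases, L, replace = TRUE), collapse = "")
    # remove ancestral chance occurrences before planting, so that at low
    # divergence the per-species scrub below has (almost) nothing to do
    # and the d = 0 limit leaves every species identical to the ancestor
    ancestor <- .scrub_motif(ancestor, params$primary_motif)
    protect <- NULL      # invariant windows (sub+indel shielded), ancestor coords
    site_keep <- NULL    # exact planted-site windows exempt from scrubbing
    off1 <- NA_integer_; off2 <- NA_integer_
    inst1 <- NA_character_; inst2 <- NA_character_
    composite <- FALSE

    if (cls %in% c("conserved", "decayed")) {
      inst1 <- .expand_iupac_instance(params$primary_motif$iupac)
      lo <- flank
      hi <- L - max_span
      off1 <- sample(lo:hi, 1L)
    }
    if (cls == "conserved") {
      substr(ancestor, off1 + 1L, off1 + k1) <- inst1
      protect <- rbind(protect, c(off1 - flank, off1 + k1 + flank))
      site_keep <- rbind(site_keep, c(off1, off1 + k1))
      if (do_secondary) {
        composite <- TRUE
        inst2 <- .expand_iupac_instance(params$secondary_motif$iupac)
        gap <- sample(0:params$plant_secondary_within, 1L)
        off2 <- off1 + k1 + gap
        substr(ancestor, off2 + 1L, off2 + k2) <- inst2
        protect <- rbind(protect, c(off2 - flank, off2 + k2 + flank))
      }
    }

    regions <- list()
    off1_f <- NA_integer_; off2_f <- NA_integer_
    for (s in sp) {
      ev <- evolve_sequence(ancestor, params$divergence, params$indel_rate,
                            params$indel_len_mean,
                            protect_sub = protect,
                            protect_indel = if (cls == "decayed") {
                              rbind(protect, c(off1, off1 + k1))
                            } else protect)
      seq_s <- ev$seq
      # planted-site windows in this species' coordinates
      keep_s <- NULL; avoid_s <- NULL
      if (cls == "conserved") {
        m1 <- ev$map[off1 + 1L]
        keep_s <- rbind(keep_s, c(m1, m1 + k1))
        avoid_s <- rbind(avoid_s, c(m1, m1 + k1))
        if (do_secondary) {
          m2 <- ev$map[off2 + 1L]
          avoid_s <- rbind(avoid_s, c(m2, m2 + k2))
        }
        if (s == focal) {
          off1_f <- m1
          if (do_secondary) off2_f <- m2
        }
      }
      if (cls == "decayed") {
        m1 <- ev$map[off1 + 1L]
        if (s == focal) {
          substr(seq_s, m1 + 1L, m1 + k1) <- inst1
          keep_s <- rbind(keep_s, c(m1, m1 + k1))
          avoid_s <- keep_s
          off1_f <- m1
        } else {
          # scramble the orthologous window so the site has decayed
          repeat {
            repl <- paste(sample(bases, k1, replace = TRUE), collapse = "")
            if (!has_motif(repl, params$primary_motif)) break
          }
          substr(seq_s, m1 + 1L, m1 + k1) <- repl
        }
      }
      seq_s <- .scrub_motif(seq_s, params$primary_motif, keep = keep_s,
                            avoid = avoid_s)
      regions[[s]] <- seq_s
    }
    off1 <- off1_f
    off2 <- off2_f

    # place each gene on its own contig; strands alternate by index
    strand <- if (gi %% 2L == 1L) "+" else "-"
    for (s in sp) {
      gid <- if (s == focal) g else paste0(g, "_", s)
      contig <- paste0("ctg_", g)
      rseq <- regions[[s]]
      rl <- nchar(rseq)
      body <- paste(sample(bases, gene_len, replace = TRUE), collapse = "")
      if (strand == "+") {
        contig_seq <- paste0(rseq, body)
        row <- data.frame(gene_id = gid, seq_name = contig,
                          start = rl, end = rl + gene_len, strand = "+",
                          stringsAsFactors = FALSE)
      } else {
        contig_seq <- paste0(body, revcomp_dna(rseq))
        row <- data.frame(gene_id = gid, seq_name = contig,
                          start = 0L, end = gene_len, strand = "-",
                          stringsAsFactors = FALSE)
      }
      records[[s]][contig] <- contig_seq
      ann[[s]] <- rbind(ann[[s]], row)
      if (s != focal) {
        ortho[[length(ortho) + 1L]] <- data.frame(
          focal_gene = g, species_id = s, ortholog_gene = gid,
          stringsAsFactors = FALSE)
      }
    }
    truth[[gi]] <- data.frame(
      gene_id = g, class = cls, composite = composite,
      primary_offset = off1, primary_seq = inst1,
      secondary_offset = off2, secondary_seq = inst2,
      stringsAsFactors = FALSE)
  }

  genomes <- lapply(sp, function(s) genome_seqs(s, records[[s]]))
  names(genomes) <- sp
  list(genomes = genomes,
       annotations = ann,
       orthologs = do.call(rbind, ortho),
       truth = do.call(rbind, truth),
       params = params)
}

# One concrete instance of a degenerate pattern (random expansion).
.expand_iupac_instance <- function(iupac) {
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    s <- .IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1L)), collapse = "")
}

#' Write a simulated ortholog set to standard files
#'
#' One FASTA and one GFF3 per species, a 3-column ortholog TSV, and the
#' truth TSV, all under `dir`.
#'
#' @param sim output of [simulate_ortholog_set()].
#' @param dir output directory (created if missing).
#' @return named list of written paths.
#' @export
write_ortholog_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = character(0), gff = character(0))
  for (s in names(sim$genomes)) {
    fa <- file.path(dir, paste0(s, ".fa"))
    ss <- Biostrings::DNAStringSet(sim$genomes[[s]]$records)
    Biostrings::writeXStringSet(ss, fa)
    paths$fasta[s] <- fa
    gff <- file.path(dir, paste0(s, ".gff3"))
    a <- sim$annotations[[s]]
    con <- file(gff, "w")
    writeLines("##gff-version 3", con)
    writeLines(paste(a$seq_name, "cisfoot", "gene", a$start + 1L, a$end, ".",
                     a$strand, ".", paste0("ID=", a$gene_id), sep = "\t"), con)
    close(con)
    paths$gff[s] <- gff
  }
  paths$orthologs <- file.path(dir, "orthologs.tsv")
  utils::write.table(sim$orthologs, paths$orthologs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson Eulerian-path shuffle: the returned sequence has
#' exactly the dinucleotide (and hence mononucleotide) counts of the
#' input, with motif placement destroyed. A run of one repeated base is
#' returned unchanged. Uses the current RNG state; seed with `set.seed()`
#' for reproducibility.
#'
#' @param seq nucleotide string.
#' @return shuffled string.
#' @export
shuffle_dinucleotide <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n <= 2L) return(seq)
  last <- chars[n]
  verts <- unique(chars)
  edges <- split(chars[-1], factor(chars[-n], levels = verts))
  # pick terminal edges forming paths into the final vertex
  for (attempt in 1:1000) {
    term <- sapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0L) NA_character_
      else sample(edges[[v]], 1L)
    })
    ok <- TRUE
    for (v in verts) {
      if (v == last || length(edges[[v]]) == 0L) next
      cur <- v
      steps <- 0L
      while (cur != last && steps <= length(verts)) {
        cur <- term[[cur]]
        steps <- steps + 1L
        if (is.na(cur)) break
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) stop("failed to find a terminal-edge arborescence")
  # order each adjacency list: random permutation of non-terminal edges,
  # terminal edge last
  adj <- list()
  for (v in verts) {
    e <- edges[[v]]
    if (length(e) == 0L) { adj[[v]] <- character(0); next }
    if (v == last) {
      adj[[v]] <- if (length(e) > 1L) sample(e) else e
    } else {
      e2 <- e
      drop_i <- match(term[[v]], e2)
      e2 <- e2[-drop_i]
      adj[[v]] <- c(if (length(e2) > 1L) sample(e2) else e2, term[[v]])
    }
  }
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- adj[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
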