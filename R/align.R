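# Pairwise alignment of orthologous upstream regions and extraction of
# conserved sequence blocks (>= min_len alignment columns at >= min_identity).
#
# The alignment itself is standard affine-gap dynamic programming
# (Biostrings); the block criterion on top of it is what the conservation
# screen depends on, and is implemented here with an oracle-checkable
# maximality convention: report maximal intervals meeting both thresholds
# that cannot be extended by one column on either side without dropping
# below the identity threshold, resolving overlaps greedily left to right
# (earlier start, then longer block).

#' Alignment scoring parameters
#'
#' Affine gap model: a gap of length L costs `gap_open + L * gap_extend`.
#' `global_free_ends` (ends-free overlap alignment) is the default mode;
#' `local` gives Smith-Waterman.
#'
#' @param match_score,mismatch_penalty,gap_open,gap_extend scoring values
#'   (penalties given as positive magnitudes).
#' @param mode `"global_free_ends"` or `"local"`.
#' @export
alignment_params <- function(match_score = 1, mismatch_penalty = 1,
                             gap_open = 2, gap_extend = 1,
                             mode = c("global_free_ends", "local")) {
  mode <- match.arg(mode)
  stopifnot(match_score > 0, mismatch_penalty >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match_score = match_score, mismatch_penalty = mismatch_penalty,
                 gap_open = gap_open, gap_extend = gap_extend, mode = mode),
            class = "alignment_params")
}

# Substitution matrix over A/C/G/T/N where N mismatches everything,
# including N: assembly gaps never look conserved.
.submat <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-params$mismatch_penalty, 5, 5, dimnames = list(b, b))
  diag(m) <- params$match_score
  m["N", "N"] <- -params$mismatch_penalty
  m
}

#' Pairwise-align two upstream regions
#'
#' Deterministic optimal alignment under `params` (ties broken by the
#' dynamic program's fixed traceback rule). Returns the aligned strings
#' plus per-column coordinate maps into each region's 0-based offsets.
#'
#' @param region_a,region_b `upstream_region` objects (or plain strings).
#' @param params an [alignment_params()] object.
#' @return a `pairwise_alignment`: list with `gene_id`, `species_a`,
#'   `species_b`, `aligned_a`, `aligned_b` (gapped strings of equal
#'   length), `off_a`, `off_b` (per-column 0-based region offsets, NA at
#'   gaps), `score`.
#' @export
align_pair <- function(region_a, region_b, params = alignment_params()) {
  a_seq <- if (inherits(region_a, "upstream_region")) region_a$seq else region_a
  b_seq <- if (inherits(region_b, "upstream_region")) region_b$seq else region_b
  if (!nzchar(a_seq) || !nzchar(b_seq)) stop("cannot align an empty region")
  type <- if (params$mode == "local") "local" else "overlap"
  aln <- Biostrings::pairwiseAlignment(
    pattern = a_seq, subject = b_seq,
    substitutionMatrix = .submat(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = type
  )
  al_a <- as.character(Biostrings::pattern(aln))
  al_b <- as.character(Biostrings::subject(aln))
  start_a <- Biostrings::start(Biostrings::pattern(aln)) - 1L  # 0-based
  start_b <- Biostrings::start(Biostrings::subject(aln)) - 1L
  ca <- strsplit(al_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al_b, "", fixed = TRUE)[[1]]
  off_a <- ifelse(ca == "-", NA_integer_, start_a + cumsum(ca != "-") - 1L)
  off_b <- ifelse(cb == "-", NA_integer_, start_b + cumsum(cb != "-") - 1L)
  structure(list(
    gene_id = if (inherits(region_a, "upstream_region")) region_a$gene_id else NA_character_,
    species_a = if (inherits(region_a, "upstream_region")) region_a$species_id else "a",
    species_b = if (inherits(region_b, "upstream_region")) region_b$species_id else "b",
    aligned_a = al_a, aligned_b = al_b,
    off_a = as.integer(off_a), off_b = as.integer(off_b),
    score = Biostrings::score(aln)
  ), class = "pairwise_alignment")
}

#' Build a pairwise_alignment from pre-aligned gapped strings
#'
#' Mainly for tests and for reading alignments produced elsewhere; offsets
#' start at `start_a`/`start_b`.
#'
#' @param aligned_a,aligned_b equal-length gapped strings (`-` = gap).
#' @param start_a,start_b 0-based region offset of the first aligned base.
#' @param gene_id,species_a,species_b identifiers.
#' @export
pairwise_alignment <- function(aligned_a, aligned_b, start_a = 0L, start_b = 0L,
                               gene_id = NA_character_,
                               species_a = "a", species_b = "b") {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  ca <- strsplit(toupper(aligned_a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(aligned_b), "", fixed = TRUE)[[1]]
  if (any(ca == "-" & cb == "-")) stop("column with gaps on both sides")
  off_a <- ifelse(ca == "-", NA_integer_, start_a + cumsum(ca != "-") - 1L)
  off_b <- ifelse(cb == "-", NA_integer_, start_b + cumsum(cb != "-") - 1L)
  structure(list(gene_id = gene_id, species_a = species_a, species_b = species_b,
                 aligned_a = toupper(aligned_a), aligned_b = toupper(aligned_b),
                 off_a = as.integer(off_a), off_b = as.integer(off_b),
                 score = NA_real_),
            class = "pairwise_alignment")
}

# Per-column identity (1 = identical A/C/G/T base both sides) and
# denominator weights under the chosen convention.
.column_stats <- function(aln, identity_denominator) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  ident <- as.numeric(ca == cb & ca %in% c("A", "C", "G", "T"))
  den <- if (identity_denominator == "all") {
    rep(1, length(ca))
  } else {
    as.numeric(ca != "-" & cb != "-")
  }
  list(ident = ident, den = den)
}

#' Extract conserved blocks from a pairwise alignment
#'
#' Reports maximal alignment intervals with at least `min_len` columns and
#' identity at least `min_identity`, where identity is the fraction of
#' identical-base columns over all columns of the interval (gap columns
#' count against identity by default; set
#' `identity_denominator = "ungapped"` to exclude them from the
#' denominator). A reported block cannot be extended by one column on
#' either side without dropping below the identity threshold; overlapping
#' candidates are resolved greedily left to right, preferring earlier
#' start then longer block, so the result is a sorted, non-overlapping
#' set.
#'
#' @param aln a `pairwise_alignment`.
#' @param min_len minimum number of alignment columns (default 14).
#' @param min_identity minimum identity fraction (default 0.70).
#' @param identity_denominator `"all"` (default) or `"ungapped"`.
#' @return data.frame with one row per block: `gene_id`, `species_a`,
#'   `species_b`, `col_start`, `col_end` (1-based inclusive alignment
#'   columns), `start_a`, `end_a`, `start_b`, `end_b` (0-based half-open
#'   region offsets), `length_nt` (columns), `identity`.
#' @export
extract_conserved_blocks <- function(aln, min_len = 14L, min_identity = 0.70,
                                     identity_denominator = c("all", "ungapped")) {
  identity_denominator <- match.arg(identity_denominator)
  stopifnot(inherits(aln, "pairwise_alignment"), min_len >= 1, min_identity > 0,
            min_identity <= 1)
  cs <- .column_stats(aln, identity_denominator)
  n <- length(cs$ident)
  empty <- data.frame(gene_id = character(0), species_a = character(0),
                      species_b = character(0), col_start = integer(0),
                      col_end = integer(0), start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      length_nt = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < min_len) return(empty)
  eps <- 1e-9
  # interval [i, j] satisfies the identity threshold iff P[j+1] - P[i] >= -eps
  P <- c(0, cumsum(cs$ident - min_identity * cs$den))
  rows <- list()
  i <- 1L
  while (i <= n - min_len + 1L) {
    j <- seq.int(i + min_len - 1L, n)
    valid <- P[j + 1L] - P[i] >= -eps
    # not extendable leftward: extending to i-1 violates identity (or i == 1)
    if (i > 1L) valid <- valid & (P[j + 1L] - P[i - 1L] < -eps)
    # not extendable rightward: extending to j+1 violates identity (or j == n)
    right_ok <- c(P[j[-length(j)] + 2L] - P[i] < -eps, TRUE)
    valid <- valid & right_ok
    if (any(valid)) {
      jj <- max(j[valid])  # earliest start, then longest
      rows[[length(rows) + 1L]] <- c(i, jj)
      i <- jj + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, lapply(rows, function(r) {
    i <- r[1]; j <- r[2]
    oa <- aln$off_a[i:j]; ob <- aln$off_b[i:j]
    oa <- oa[!is.na(oa)]; ob <- ob[!is.na(ob)]
    idx <- i:j
    data.frame(
      gene_id = aln$gene_id, species_a = aln$species_a, species_b = aln$species_b,
      col_start = i, col_end = j,
      start_a = if (length(oa)) min(oa) else NA_integer_,
      end_a = if (length(oa)) max(oa) + 1L else NA_integer_,
      start_b = if (length(ob)) min(ob) else NA_integer_,
      end_b = if (length(ob)) max(ob) + 1L else NA_integer_,
      length_nt = j - i + 1L,
      identity = sum(cs$ident[idx]) / max(sum(cs$den[idx]), 1),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Map a conserved block to ungapped region offsets
#'
#' @param block one row of [extract_conserved_blocks()] output.
#' @param side `"a"` or `"b"`.
#' @return integer vector `c(start, end)`, a 0-based half-open offset
#'   interval in the chosen region.
#' @export
map_block_to_region <- function(block, side = c("a", "b")) {
  side <- match.arg(side)
  if (side == "a") c(block$start_a, block$end_a) else c(block$start_b, block$end_b)
}
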