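# Independent brute-force oracles used to validate the fast paths.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

random_dna <- function(n, with_n = FALSE) {
  alpha <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# naive reverse complement of an IUPAC string via per-symbol set expansion:
# complement each position's allowed set, find the symbol with that set,
# and reverse — fully independent of the package's complement table
oracle_revcomp_iupac <- function(iupac) {
  comp_base <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- rev(strsplit(iupac, "")[[1]])
  vapply(chars, function(ch) {
    comp_set <- sort(unname(comp_base[IUPAC_ORACLE[[ch]]]))
    names(Filter(function(s) identical(sort(s), comp_set), IUPAC_ORACLE))[1]
  }, character(1)) |> paste(collapse = "")
}

# per-offset, per-strand brute-force motif scan; offsets 0-based on the
# forward text, minus strand = reverse-complement pattern on forward text
oracle_scan <- function(seq, iupac) {
  chars <- strsplit(toupper(seq), "")[[1]]
  match_one <- function(pat_chars, off) {
    all(vapply(seq_along(pat_chars), function(i) {
      chars[off + i] %in% IUPAC_ORACLE[[pat_chars[i]]]
    }, logical(1)))
  }
  k <- nchar(iupac)
  n <- length(chars)
  if (n < k) return(data.frame(offset = integer(0), strand = character(0)))
  pat_p <- strsplit(toupper(iupac), "")[[1]]
  pat_m <- strsplit(oracle_revcomp_iupac(toupper(iupac)), "")[[1]]
  rows <- list()
  for (off in 0:(n - k)) {
    if (match_one(pat_p, off)) rows[[length(rows) + 1]] <- c(off, "+")
    if (match_one(pat_m, off)) rows[[length(rows) + 1]] <- c(off, "-")
  }
  if (length(rows) == 0) return(data.frame(offset = integer(0), strand = character(0)))
  m <- do.call(rbind, rows)
  data.frame(offset = as.integer(m[, 1]), strand = m[, 2], stringsAsFactors = FALSE)
}

# exhaustive conserved-block oracle: enumerate every alignment interval,
# filter by both thresholds, keep intervals not extendable by one column
# on either side, then sweep left to right (earlier start, longer first)
oracle_blocks <- function(aligned_a, aligned_b, min_len = 14, min_identity = 0.70,
                          denominator = "all") {
  ca <- strsplit(toupper(aligned_a), "")[[1]]
  cb <- strsplit(toupper(aligned_b), "")[[1]]
  n <- length(ca)
  ident <- as.numeric(ca == cb & ca %in% c("A", "C", "G", "T"))
  den <- if (denominator == "all") rep(1, n) else as.numeric(ca != "-" & cb != "-")
  idy <- function(i, j) sum(ident[i:j]) / max(sum(den[i:j]), 1)
  meets <- function(i, j) (j - i + 1) >= min_len && idy(i, j) >= min_identity - 1e-9
  cand <- list()
  if (n >= min_len) {
    for (i in 1:(n - min_len + 1)) {
      for (j in (i + min_len - 1):n) {
        if (!meets(i, j)) next
        left_ext <- i > 1 && idy(i - 1, j) >= min_identity - 1e-9
        right_ext <- j < n && idy(i, j + 1) >= min_identity - 1e-9
        if (!left_ext && !right_ext) cand[[length(cand) + 1]] <- c(i, j)
      }
    }
  }
  if (length(cand) == 0) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, cand)
  m <- m[order(m[, 1], -(m[, 2] - m[, 1])), , drop = FALSE]
  kept <- matrix(integer(0), ncol = 2)
  last_end <- 0
  for (r in seq_len(nrow(m))) {
    if (m[r, 1] > last_end) {
      kept <- rbind(kept, m[r, ])
      last_end <- m[r, 2]
    }
  }
  unname(kept)
}

# random gapped alignment pair for block-oracle tests: a pair of strings
# with tunable per-column identity and gap probability
random_alignment <- function(n_cols, p_match = 0.7, p_gap = 0.1) {
  bases <- c("A", "C", "G", "T")
  a <- character(n_cols); b <- character(n_cols)
  for (i in seq_len(n_cols)) {
    u <- runif(1)
    if (u < p_gap / 2) { a[i] <- "-"; b[i] <- sample(bases, 1) }
    else if (u < p_gap) { a[i] <- sample(bases, 1); b[i] <- "-" }
    else if (u < p_gap + (1 - p_gap) * p_match) { a[i] <- b[i] <- sample(bases, 1) }
    else { a[i] <- sample(bases, 1); b[i] <- sample(setdiff(bases, a[i]), 1) }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# exhaustive conservation-call checker: enumerates every
# (hit, species, block) triple directly from the data frames
oracle_call_conserved <- function(hits, blocks, other_regions, iupac, min_species) {
  vapply(seq_len(nrow(hits)), function(h) {
    lo <- hits$offset[h]; hi <- lo + hits$width[h]
    supp <- 0L
    for (sp in names(other_regions)) {
      sp_ok <- FALSE
      bl <- blocks[blocks$species_b == sp, , drop = FALSE]
      for (b in seq_len(nrow(bl))) {
        if (is.na(bl$start_a[b]) || bl$start_a[b] > lo || bl$end_a[b] < hi) next
        win <- substr(other_regions[[sp]]$seq, bl$start_b[b] + 1, bl$end_b[b])
        if (nrow(oracle_scan(win, iupac)) > 0) { sp_ok <- TRUE; break }
      }
      if (sp_ok) supp <- supp + 1L
    }
    supp >= min_species
  }, logical(1))
}

# small upstream_region stand-in for unit tests
make_region <- function(seq, gene_id = "g", species_id = "sp",
                        seq_name = "chr", gstart = 0L, strand = "+") {
  structure(list(gene_id = gene_id, species_id = species_id, seq = seq,
                 seq_name = seq_name, gstart = as.integer(gstart),
                 gend = as.integer(gstart + nchar(seq)), strand = strand,
                 window_bp = nchar(seq)),
            class = "upstream_region")
}
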