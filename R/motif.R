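# Degenerate IUPAC motif compilation and exhaustive scanning.
#
# Matching is deliberately strict: an N (assembly gap) in the *text* never
# matches any pattern symbol, including pattern N, so gaps cannot create
# sites. Both strands are scanned by default; minus-strand hits are found
# by matching the reverse-complement pattern against the forward text, and
# their offsets refer to the forward text.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Reverse-complement an IUPAC string
#'
#' Works on fully degenerate IUPAC nucleotide strings (so the reverse
#' complement of `RTGGGAA` is `TTCCCAY`). Applying it twice is the identity.
#'
#' @param x a single IUPAC nucleotide string.
#' @return the reverse-complement IUPAC string.
#' @export
#' @examples
#' revcomp_iupac("RTGGGAA")
revcomp_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.IUPAC_COMPLEMENT))
  if (length(bad) > 0L) {
    stop("non-IUPAC character(s) in sequence: ", paste(unique(bad), collapse = ", "))
  }
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Compile a degenerate IUPAC motif pattern
#'
#' Builds a `motif_pattern`: per-position allowed-base sets for the pattern
#' and its reverse complement. The allowed sets contain only A/C/G/T, so N
#' in the scanned text never matches (see [scan_motif()]).
#'
#' @param label motif name, e.g. `"LAG1"`.
#' @param iupac degenerate pattern string, e.g. `"RTGGGAA"`.
#' @return an object of class `motif_pattern` with elements `label`,
#'   `iupac`, `length`, `revcomp_iupac`, `sets`, `rc_sets`.
#' @export
#' @examples
#' lag1 <- compile_motif("LAG1", "RTGGGAA")
#' lag1$revcomp_iupac  # "TTCCCAY"
compile_motif <- function(label, iupac) {
  stopifnot(is.character(iupac), length(iupac) == 1L, nzchar(iupac))
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("motif '", label, "': non-IUPAC character(s): ",
         paste(unique(bad), collapse = ", "))
  }
  rc <- revcomp_iupac(iupac)
  rc_chars <- strsplit(rc, "", fixed = TRUE)[[1]]
  structure(list(
    label = label,
    iupac = iupac,
    length = length(chars),
    revcomp_iupac = rc,
    sets = lapply(chars, function(ch) .IUPAC_SETS[[ch]]),
    rc_sets = lapply(rc_chars, function(ch) .IUPAC_SETS[[ch]])
  ), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (revcomp %s), length %d\n",
              x$label, x$iupac, x$revcomp_iupac, x$length))
  invisible(x)
}

#' Test a motif at one position of a sequence
#'
#' Plus-strand test only: `TRUE` iff every base of `seq` at `pos + i` lies
#' in the allowed set of pattern position `i`. Any N in the text fails.
#'
#' @param seq nucleotide string.
#' @param pattern a [compile_motif()] object.
#' @param pos 0-based offset into `seq`.
#' @export
#' @examples
#' matches_at("GTGGGAA", compile_motif("LAG1", "RTGGGAA"), 0)  # TRUE
matches_at <- function(seq, pattern, pos) {
  stopifnot(inherits(pattern, "motif_pattern"), length(pos) == 1L)
  n <- nchar(seq)
  k <- pattern$length
  if (pos < 0L || pos > n - k) {
    stop("position ", pos, " out of range for sequence of length ", n,
         " and pattern of length ", k)
  }
  chars <- strsplit(toupper(substr(seq, pos + 1L, pos + k)), "", fixed = TRUE)[[1]]
  all(vapply(seq_len(k), function(i) chars[i] %in% pattern$sets[[i]], logical(1L)))
}

# Vectorised single-strand scan of a character string; returns 0-based offsets.
.scan_one_strand <- function(chars, sets) {
  k <- length(sets)
  n <- length(chars)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  ok <- rep(TRUE, m)
  for (i in seq_len(k)) {
    ok <- ok & (chars[i:(i + m - 1L)] %in% sets[[i]])
  }
  which(ok) - 1L
}

#' Scan a sequence or upstream region for all motif occurrences
#'
#' Finds every occurrence of a degenerate pattern, overlapping occurrences
#' included. Minus-strand hits are matches of the reverse-complement
#' pattern on the forward text; their `offset` refers to the forward text.
#' A palindromic pattern matching both strands at one offset yields two
#' hits (no de-duplication at this stage). Hits are sorted by offset, plus
#' strand before minus at equal offset.
#'
#' @param region an `upstream_region` (see [extract_upstream()]) or a plain
#'   nucleotide string.
#' @param pattern a [compile_motif()] object.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return data.frame with columns `pattern_label`, `gene_id`, `species_id`,
#'   `offset` (0-based), `strand`, `width`, `site_seq` (forward-text slice).
#' @export
scan_motif <- function(region, pattern, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  stopifnot(inherits(pattern, "motif_pattern"))
  if (inherits(region, "upstream_region")) {
    seq <- region$seq
    gene_id <- region$gene_id
    species_id <- region$species_id
  } else {
    seq <- region
    gene_id <- NA_character_
    species_id <- NA_character_
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  off_p <- if (strands %in% c("both", "+")) .scan_one_strand(chars, pattern$sets) else integer(0)
  off_m <- if (strands %in% c("both", "-")) .scan_one_strand(chars, pattern$rc_sets) else integer(0)
  offset <- c(off_p, off_m)
  strand <- c(rep("+", length(off_p)), rep("-", length(off_m)))
  ord <- order(offset, strand)  # "+" < "-" in C locale sorts + first
  offset <- offset[ord]
  strand <- strand[ord]
  data.frame(
    pattern_label = rep(pattern$label, length(offset)),
    gene_id = rep(gene_id, length(offset)),
    species_id = rep(species_id, length(offset)),
    offset = as.integer(offset),
    strand = strand,
    width = rep(pattern$length, length(offset)),
    site_seq = if (length(offset) == 0L) character(0) else
      substring(seq, offset + 1L, offset + pattern$length),
    stringsAsFactors = FALSE
  )
}

#' Does a sequence carry the motif on either strand?
#'
#' @param seq nucleotide string.
#' @param pattern a [compile_motif()] object.
#' @return `TRUE` iff at least one occurrence on either strand.
#' @export
has_motif <- function(seq, pattern) {
  nrow(scan_motif(seq, pattern, "both")) > 0L
}

#' Check a designed site-abrogating mutation
#'
#' Validates reporter-mutagenesis designs: reports whether the wild-type
#' and mutant sequences each still match the pattern on either strand
#' (e.g. `GTGGGAA` matches `RTGGGAA` but the abrogating mutation `GAGGCAA`
#' does not).
#'
#' @param pattern a [compile_motif()] object.
#' @param wild,mutant equal-length sequences, each of the pattern's length.
#' @return list with logical elements `wild_matches`, `mutant_matches`.
#' @export
check_mutant <- function(pattern, wild, mutant) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (nchar(wild) != pattern$length || nchar(mutant) != pattern$length) {
    stop("wild and mutant must both have the pattern length (",
         pattern$length, ")")
  }
  list(
    wild_matches = has_motif(wild, pattern),
    mutant_matches = has_motif(mutant, pattern)
  )
}

#' Reverse-complement a plain A/C/G/T/N sequence
#' @param x nucleotide string.
#' @export
revcomp_dna <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "", fixed = TRUE)[[1]]), collapse = ""))
}
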