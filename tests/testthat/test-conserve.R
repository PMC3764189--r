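# Conservation calling and the composite proximity filter.

lag1 <- compile_motif("LAG1", "RTGGGAA")

# hand-built gene bundle: focal region with one planted site, two other
# species whose aligned block does or does not carry the motif
make_bundle <- function(partner_has_motif = c(TRUE, TRUE)) {
  set.seed(77)
  flank <- random_dna(30)
  site <- "GTGGGAA"
  focal_seq <- paste0(flank, site, random_dna(30))
  other_regions <- list()
  blocks <- list()
  for (i in seq_along(partner_has_motif)) {
    sp <- paste0("sp", i)
    oseq <- if (partner_has_motif[i]) focal_seq else
      paste0(flank, "GAGGCAA", random_dna(30))  # site decayed
    other_regions[[sp]] <- make_region(oseq, species_id = sp)
    aln <- align_pair(focal_seq, oseq)
    aln$species_b <- sp
    blocks[[i]] <- extract_conserved_blocks(aln)
  }
  list(focal_seq = focal_seq, other_regions = other_regions,
       blocks = do.call(rbind, blocks))
}

test_that("a site backed by motif-bearing blocks in two other genomes is conserved", {
  b <- make_bundle(c(TRUE, TRUE))
  hits <- scan_motif(make_region(b$focal_seq), lag1)
  calls <- conserve_hits(hits, b$blocks, b$other_regions, lag1, min_species = 2)
  expect_identical(calls$n_support, 2L)
  expect_true(calls$conserved)
  expect_identical(calls$supporting_species, "sp1,sp2")
})

test_that("support from a single genome is below the conservation threshold", {
  b <- make_bundle(c(TRUE, FALSE))
  hits <- scan_motif(make_region(b$focal_seq), lag1)
  calls <- conserve_hits(hits, b$blocks, b$other_regions, lag1, min_species = 2)
  expect_identical(calls$n_support, 1L)
  expect_false(calls$conserved)
  # the same data passes at min_species = 1
  calls1 <- conserve_hits(hits, b$blocks, b$other_regions, lag1, min_species = 1)
  expect_true(calls1$conserved)
})

test_that("a block whose partner side lacks the motif lends no support", {
  b <- make_bundle(c(FALSE, FALSE))
  hits <- scan_motif(make_region(b$focal_seq), lag1)
  calls <- conserve_hits(hits, b$blocks, b$other_regions, lag1, min_species = 2)
  expect_identical(calls$n_support, 0L)
  expect_false(calls$conserved)
})

test_that("a hit outside every block is never conserved", {
  b <- make_bundle(c(TRUE, TRUE))
  # restrict blocks to an interval that excludes the hit
  bl <- b$blocks
  bl$start_a <- 0L; bl$end_a <- 10L
  hits <- scan_motif(make_region(b$focal_seq), lag1)
  calls <- conserve_hits(hits, bl, b$other_regions, lag1, min_species = 2)
  expect_identical(calls$n_support, 0L)
  # no alignments at all
  calls <- conserve_hits(hits, b$blocks[0, ], list(), lag1, min_species = 2)
  expect_false(calls$conserved)
})

test_that("conservation calls equal the exhaustive (hit, species, block) checker", {
  set.seed(91)
  for (rep in 1:15) {
    n_sp <- sample(2:3, 1)
    focal_seq <- random_dna(250)
    # plant 1-3 sites at random positions
    for (s in 1:sample(1:3, 1)) {
      off <- sample(0:(250 - 7), 1)
      substr(focal_seq, off + 1, off + 7) <- sample(c("GTGGGAA", "ATGGGAA", "TTCCCAT"), 1)
    }
    other_regions <- list(); blocks <- list()
    for (i in 1:n_sp) {
      sp <- paste0("sp", i)
      ev <- evolve_sequence(focal_seq, divergence = runif(1, 0, 0.4))
      other_regions[[sp]] <- make_region(ev$seq, species_id = sp)
      aln <- align_pair(focal_seq, ev$seq)
      aln$species_b <- sp
      blocks[[i]] <- extract_conserved_blocks(aln)
    }
    blocks <- do.call(rbind, blocks)
    hits <- scan_motif(make_region(focal_seq), lag1)
    if (nrow(hits) == 0) next
    calls <- conserve_hits(hits, blocks, other_regions, lag1, min_species = 2)
    want <- oracle_call_conserved(hits, blocks, other_regions, "RTGGGAA", 2)
    expect_identical(calls$conserved, want)
  }
})

test_that("strict positioning is at least as stringent as anywhere-in-block", {
  set.seed(95)
  for (rep in 1:10) {
    focal_seq <- random_dna(200)
    off <- sample(20:150, 1)
    substr(focal_seq, off + 1, off + 7) <- "GTGGGAA"
    ev <- evolve_sequence(focal_seq, divergence = 0.1)
    oreg <- make_region(ev$seq, species_id = "sp1")
    aln <- align_pair(focal_seq, ev$seq)
    aln$species_b <- "sp1"
    blocks <- extract_conserved_blocks(aln)
    hits <- scan_motif(make_region(focal_seq), lag1)
    loose <- conserve_hits(hits, blocks, list(sp1 = oreg), lag1, 1,
                           alignments = list(sp1 = aln), strict_position = FALSE)
    strict <- conserve_hits(hits, blocks, list(sp1 = oreg), lag1, 1,
                            alignments = list(sp1 = aln), strict_position = TRUE)
    expect_true(all(loose$n_support >= strict$n_support))
  }
})

make_call <- function(offset, conserved = TRUE, width = 7L, gene = "g1") {
  data.frame(pattern_label = "x", gene_id = gene, species_id = "focal",
             offset = as.integer(offset), strand = "+", width = width,
             site_seq = "NNNNNNN", n_support = 2L, supporting_species = "a,b",
             conserved = conserved, stringsAsFactors = FALSE)
}

test_that("the composite filter bounds the nearest-edge gap at 110 bp inclusive", {
  p <- make_call(1000)
  # LAG-1 at [1000,1007), FoxA at [1117,1124): gap exactly 110 -> included
  expect_identical(nrow(composite_filter(p, make_call(1117))), 1L)
  expect_identical(composite_filter(p, make_call(1117))$distance_bp, 110L)
  # gap 111 -> excluded
  expect_identical(nrow(composite_filter(p, make_call(1118))), 0L)
  # overlap -> distance 0, included
  cf <- composite_filter(p, make_call(1003))
  expect_identical(cf$distance_bp, 0L)
  # secondary upstream of primary also counts
  expect_identical(composite_filter(p, make_call(883))$distance_bp, 110L)
  # non-conserved calls never pair
  expect_identical(nrow(composite_filter(make_call(1000, FALSE), make_call(1050))), 0L)
  expect_identical(nrow(composite_filter(p, make_call(1050, FALSE))), 0L)
})

test_that("widening the distance bound never loses composite pairs", {
  set.seed(8)
  p <- do.call(rbind, lapply(sample(0:500, 5), make_call))
  s <- do.call(rbind, lapply(sample(0:500, 8), make_call))
  n_prev <- -1L
  for (d in c(0, 25, 50, 110, 200, 600)) {
    n <- nrow(composite_filter(p, s, d))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("gene summaries tally sites with composite <= conserved <= hits", {
  calls <- rbind(make_call(10, TRUE), make_call(100, FALSE), make_call(200, FALSE))
  comps <- composite_filter(make_call(10), make_call(30))
  s <- summarize_genes(calls, comps)
  expect_identical(s$n_hits, 3L)
  expect_identical(s$n_conserved, 1L)
  expect_identical(s$n_composite, 1L)
  expect_true(s$n_composite <= s$n_conserved && s$n_conserved <= s$n_hits)
  # one conserved primary with two nearby secondaries is still one composite site
  comps2 <- composite_filter(make_call(10), rbind(make_call(30), make_call(60)))
  expect_identical(nrow(comps2), 2L)
  s2 <- summarize_genes(make_call(10), comps2)
  expect_identical(s2$n_composite, 1L)
  # genes with no hits are omitted unless requested
  expect_identical(nrow(summarize_genes(calls[0, ], comps[0, ])), 0L)
  s3 <- summarize_genes(calls[0, ], comps[0, ], all_genes = "gX")
  expect_identical(s3$n_hits, 0L)
})
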