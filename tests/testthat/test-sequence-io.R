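# FASTA/GFF3/ortholog readers, upstream extraction, BED writing.

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("FASTA reading normalizes case and enforces the A/C/G/T/N alphabet", {
  f <- write_tmp(c(">chrI", "ACGT"), ".fa")
  g <- read_genome_fasta(f, "cel")
  expect_identical(unname(g$records["chrI"]), "ACGT")
  f <- write_tmp(c(">c", "acgtn"), ".fa")
  expect_identical(unname(read_genome_fasta(f)$records["c"]), "ACGTN")
  f <- write_tmp(c(">c", "ACXGT"), ".fa")
  expect_error(read_genome_fasta(f), "disallowed character")
  f <- write_tmp(c(">c", "ACGT", ">c", "TTTT"), ".fa")
  expect_error(read_genome_fasta(f), "duplicate")
})

test_that("GFF3 coordinates convert to 0-based half-open and IDs must be unique", {
  f <- write_tmp(c("##gff-version 3",
                   "chrI\t.\tgene\t101\t200\t.\t+\t.\tID=g1",
                   "chrI\t.\tgene\t101\t200\t.\t-\t.\tID=g2",
                   "chrI\t.\tmRNA\t101\t150\t.\t+\t.\tID=t1"), ".gff3")
  ann <- read_gene_annotation(f)
  expect_identical(nrow(ann), 2L)  # mRNA row filtered out
  expect_identical(ann$start, c(100L, 100L))
  expect_identical(ann$end, c(200L, 200L))
  expect_identical(ann$strand, c("+", "-"))
  f <- write_tmp(c("##gff-version 3",
                   "chrI\t.\tgene\t1\t50\t.\t+\t.\tID=g1",
                   "chrI\t.\tgene\t60\t90\t.\t+\t.\tID=g1"), ".gff3")
  expect_error(read_gene_annotation(f), "duplicate")
  f <- write_tmp(c("##gff-version 3",
                   "chrI\t.\tgene\t1\t50\t.\t.\t.\tID=g1",
                   "chrI\t.\tgene\t60\t90\t.\t+\t.\tID=g2"), ".gff3")
  expect_warning(ann <- read_gene_annotation(f), "without strand")
  expect_identical(ann$gene_id, "g2")
})

test_that("ortholog table keeps single-ortholog genes with >= 2 other species", {
  f <- write_tmp(c("focal_gene\tspecies_id\tortholog_gene",
                   "g1\tsp1\ta1", "g1\tsp2\tb1",      # retained: 2 species
                   "g2\tsp1\ta2",                     # dropped: 1 species
                   "g3\tsp1\ta3", "g3\tsp1\ta3b",     # excluded: non-single
                   "g3\tsp2\tb3"), ".tsv")
  suppressMessages(om <- read_ortholog_table(f))
  expect_setequal(unique(om$focal_gene), "g1")
  expect_identical(attr(om, "n_dropped_few_orthologs"), 1L)
  expect_identical(attr(om, "n_dropped_non_single"), 1L)
})

test_that("upstream extraction follows the strand conventions with edge truncation", {
  contig <- random_dna(10000)
  g <- genome_seqs("sp", c(chrI = contig))
  # plus strand, full window
  r <- extract_upstream(list(gene_id = "g1", seq_name = "chrI", start = 6000L,
                             end = 6500L, strand = "+"), g, 5000L)
  expect_identical(c(r$gstart, r$gend), c(1000L, 6000L))
  expect_identical(r$seq, substr(contig, 1001, 6000))
  # plus strand, truncated at contig start
  r <- extract_upstream(list(gene_id = "g2", seq_name = "chrI", start = 2000L,
                             end = 2500L, strand = "+"), g, 5000L)
  expect_identical(c(r$gstart, r$gend), c(0L, 2000L))
  expect_identical(nchar(r$seq), 2000L)
  # minus strand: window downstream in genome coords, reverse complemented
  r <- extract_upstream(list(gene_id = "g3", seq_name = "chrI", start = 0L,
                             end = 100L, strand = "-"), g, 5000L)
  expect_identical(c(r$gstart, r$gend), c(100L, 5100L))
  expect_identical(r$seq, revcomp_dna(substr(contig, 101, 5100)))
  # zero-length window at contig edge
  expect_warning(
    r <- extract_upstream(list(gene_id = "g4", seq_name = "chrI", start = 0L,
                               end = 100L, strand = "+"), g, 5000L),
    "length 0")
  expect_identical(r$seq, "")
})

test_that("region positions map back to the genome and re-slice to the same sequence", {
  set.seed(5)
  contig <- random_dna(3000)
  g <- genome_seqs("sp", c(c1 = contig))
  for (strand in c("+", "-")) {
    gene <- if (strand == "+") {
      list(gene_id = "g", seq_name = "c1", start = 2500L, end = 2700L, strand = "+")
    } else {
      list(gene_id = "g", seq_name = "c1", start = 100L, end = 300L, strand = "-")
    }
    r <- extract_upstream(gene, g, 2000L)
    # re-slice the genome through region_to_genomic at several offsets/widths
    for (i in 1:20) {
      off <- sample(0:(nchar(r$seq) - 10L), 1)
      w <- sample(1:10, 1)
      loc <- region_to_genomic(r, off, w, "+")
      gslice <- substr(contig, loc$gstart + 1, loc$gend)
      rslice <- substr(r$seq, off + 1, off + w)
      if (strand == "+") expect_identical(gslice, rslice)
      else expect_identical(revcomp_dna(gslice), rslice)
    }
    # whole-region round trip
    loc <- region_to_genomic(r, 0L, nchar(r$seq), "+")
    gslice <- substr(contig, loc$gstart + 1, loc$gend)
    expect_identical(if (strand == "+") gslice else revcomp_dna(gslice), r$seq)
  }
})

test_that("BED output is 0-based half-open and merges head-to-head shared sites", {
  sites <- data.frame(
    seq_name = c("chrI", "chrI"), gstart = c(1234L, 1234L), gend = c(1241L, 1241L),
    gene_id = c("g1", "g2"), gstrand = c("+", "+"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_sites_bed(sites, f)
  lines <- readLines(f)
  expect_match(lines[1], "^#")
  expect_identical(lines[2], "chrI\t1234\t1241\tg1,g2\t.\t+")
  expect_identical(length(lines), 2L)
  # empty input: header comment only
  write_sites_bed(sites[0, ], f)
  expect_identical(length(readLines(f)), 1L)
})

test_that("a GFF3 feature at (101,200) emerges in BED as (100,200)", {
  f <- write_tmp(c("##gff-version 3",
                   "chrI\t.\tgene\t101\t200\t.\t+\t.\tID=g1"), ".gff3")
  ann <- read_gene_annotation(f)
  sites <- data.frame(seq_name = ann$seq_name, gstart = ann$start, gend = ann$end,
                      gene_id = ann$gene_id, gstrand = ann$strand,
                      stringsAsFactors = FALSE)
  bed <- tempfile(fileext = ".bed")
  write_sites_bed(sites, bed)
  fields <- strsplit(readLines(bed)[2], "\t")[[1]]
  expect_identical(fields[2:3], c("100", "200"))
})
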