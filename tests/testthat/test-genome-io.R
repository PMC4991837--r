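write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FASTA parsing loads records, normalizes case and keeps descriptions", {
  f <- write_lines_tmp(c(">chr1 first chromosome", "ACGT", ">chr2", "GG"))
  g <- read_genome_fasta(f)
  expect_equal(genome_lengths(g),
               tibble::tibble(seqid = c("chr1", "chr2"), length_bp = c(4L, 2L)))
  expect_equal(attr(g, "desc")[["chr1"]], "first chromosome")

  f2 <- write_lines_tmp(c(">chr1", "acgt"))
  expect_equal(unname(unclass(read_genome_fasta(f2))[1]), "ACGT")
})

test_that("FASTA parsing rejects duplicates, empties and ambiguity codes", {
  f <- write_lines_tmp(c(">chr1", "ACGT", ">chr1", "GG"))
  expect_error(read_genome_fasta(f), "chr1")
  f2 <- write_lines_tmp(character())
  expect_error(read_genome_fasta(f2), "empty")
  f3 <- write_lines_tmp(c(">chr1", "ACGTR"))
  expect_error(read_genome_fasta(f3), "ambiguity|ACGTN")
  # N itself is fine
  f4 <- write_lines_tmp(c(">chr1", "ACGTN"))
  expect_silent(read_genome_fasta(f4))
})

gff_lines <- function(body) {
  c("##gff-version 3", body)
}

test_that("GFF3 models assemble hierarchically with strand-aware CDS order", {
  f <- write_lines_tmp(gff_lines(c(
    "chr1\tsrc\tgene\t100\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t300\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t100\t150\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t200\t250\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t100\t150\t.\t+\t0\tParent=t1",
    "chr1\tsrc\tCDS\t200\t250\t.\t+\t0\tParent=t1"
  )))
  m <- read_gff3(f)
  expect_equal(nrow(m), 1L)
  expect_equal(nrow(m$cds[[1]]), 2L)
  expect_equal(m$cds[[1]]$start, c(100L, 200L))

  fm <- write_lines_tmp(gff_lines(c(
    "chr1\tsrc\tgene\t100\t250\t.\t-\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t250\t.\t-\t.\tID=t1;Parent=g1",
    "chr1\tsrc\tCDS\t100\t150\t.\t-\t0\tParent=t1",
    "chr1\tsrc\tCDS\t200\t250\t.\t-\t0\tParent=t1"
  )))
  mm <- read_gff3(fm)
  # translation order on the minus strand: downstream block first
  expect_equal(mm$cds[[1]]$start, c(200L, 100L))
})

test_that("GFF3 orphans are skipped with a warning, bad coordinates error", {
  f <- write_lines_tmp(gff_lines(c(
    "chr1\tsrc\tgene\t100\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t300\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\tCDS\t100\t150\t.\t+\t0\tParent=t1",
    "chr1\tsrc\tmRNA\t400\t500\t.\t+\t.\tID=t9;Parent=ghost"
  )))
  expect_warning(m <- read_gff3(f), "t9")
  expect_equal(m$transcript_id, "t1")

  g <- wrkyscan:::new_genome(c(chr1 = strrep("A", 120)))
  expect_error(suppressWarnings(read_gff3(f, g)), "bounds")
})

test_that("protein extraction translates, strips the stop, flags trouble", {
  loc <- list(gene_seq = "ATGGCTTAA",
              exons = tibble::tibble(start = 1L, end = 9L))
  fx <- locus_model(loc)
  p <- extract_proteins(fx$model, fx$genome)
  expect_equal(p$protein, "MA")

  fx2 <- locus_model(loc, strand = "-")
  p2 <- extract_proteins(fx2$model, fx2$genome)
  expect_equal(p2$protein, "MA")

  loc3 <- list(gene_seq = "ATGTAAGCT",
               exons = tibble::tibble(start = 1L, end = 9L))
  fx3 <- locus_model(loc3)
  p3 <- extract_proteins(fx3$model, fx3$genome)
  expect_true(p3$internal_stop)

  loc4 <- list(gene_seq = "ATGGCTTA",
               exons = tibble::tibble(start = 1L, end = 8L))
  fx4 <- locus_model(loc4)
  expect_error(extract_proteins(fx4$model, fx4$genome), "divisible")
  fx4$model$partial <- TRUE
  expect_equal(extract_proteins(fx4$model, fx4$genome)$protein, "MA")
})

test_that("promoter windows sit 5' of the gene on the coding strand", {
  chrom <- paste(rep(c("A", "C", "G", "T"), 500), collapse = "")
  g <- wrkyscan:::new_genome(c(chr1 = chrom))
  m <- tibble::tibble(
    gene_id = "g1", transcript_id = "t1", protein_id = "p1", seqid = "chr1",
    strand = "+", gene_start = 1001L, gene_end = 1200L,
    exons = list(data.frame(start = 1001L, end = 1200L)),
    cds = list(data.frame(start = 1001L, end = 1200L)), partial = FALSE
  )
  pr <- extract_promoters(m, g, 1000L)
  expect_equal(pr$promoter, substr(chrom, 1, 1000))
  expect_false(pr$truncated)

  m$strand <- "-"
  m$gene_start <- 301L
  m$gene_end <- 500L
  pr2 <- extract_promoters(m, g, 1000L)
  expect_equal(pr2$promoter, revcomp_test(substr(chrom, 501, 1500)))

  m$strand <- "+"
  m$gene_start <- 200L
  m$gene_end <- 400L
  pr3 <- extract_promoters(m, g, 1000L)
  expect_true(pr3$truncated)
  expect_equal(nchar(pr3$promoter), 199L)
})

test_that("writing then reading a cohort reproduces sequences and coordinates", {
  co <- gen_cohort(
    cohort_config(n_genes = 15, n_chrom = 3,
                  clusters = tibble::tibble(seqid = "Chr01", n = 4L, span = 150000L)),
    seed = 21
  )
  d <- withr::local_tempdir()
  write_cohort(co, d)
  g2 <- read_genome_fasta(file.path(d, "genome.fasta"))
  expect_identical(unclass(g2)[names(co$genome)], unclass(co$genome)[names(co$genome)])
  m2 <- read_gff3(file.path(d, "annotation.gff3"), g2)
  m1 <- co$models[order(co$models$transcript_id), ]
  m2 <- m2[order(m2$transcript_id), ]
  expect_equal(m2$gene_start, m1$gene_start)
  expect_equal(m2$gene_end, m1$gene_end)
  for (i in seq_len(nrow(m1))) {
    expect_equal(as.data.frame(m2$cds[[i]]), as.data.frame(m1$cds[[i]]),
                 ignore_attr = TRUE)
  }
  # strand symmetry of translation over the whole synthetic set
  pr <- extract_proteins(m2[m2$transcript_id %in% co$proteins$transcript_id, ], g2)
  expect_equal(sort(pr$protein), sort(co$proteins$protein))
})
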