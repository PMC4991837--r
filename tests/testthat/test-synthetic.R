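test_that("protein generation is deterministic and label-faithful", {
  p1 <- gen_protein("IId", seed = 101)
  p2 <- gen_protein("IId", seed = 101)
  expect_identical(p1$protein, p2$protein)
  # the planted finger trails PARKHVE after its second cysteine
  z <- scan_zinc_fingers(p1$protein)
  expect_equal(substr(z$trailing, 1, 7), "PARKHVE")

  pa <- gen_protein("Ia", seed = 102)
  za <- scan_zinc_fingers(pa$protein)
  expect_equal(za$type, c("C2H2", "C2H2"))
})

test_that("locus generation realizes planned intron offsets and phases", {
  set.seed(60)
  p <- gen_protein("III")
  d <- p$domains
  loc <- gen_locus(p$protein, tibble::tibble(residue = d$pr_residue[1],
                                             phase = 2L, type = "PR"))
  expect_equal(loc$truth$phase, 2L)
  expect_equal(loc$truth$coding_offset, (d$pr_residue[1] - 1L) * 3L + 2L)
  expect_equal(nrow(loc$exons), 2L)
  # exon lengths sum to the CDS length; introns = exons - 1
  expect_equal(sum(loc$exons$end - loc$exons$start + 1L), loc$cds_len)
  # plan violations are rejected
  notR <- which(strsplit(p$protein, "")[[1]] != "R")[1]
  expect_error(gen_locus(p$protein, tibble::tibble(residue = notR, phase = 2L,
                                                   type = "PR")), "not R")
  expect_error(gen_locus(p$protein, tibble::tibble(residue = c(5L, 5L),
                                                   phase = c(0L, 0L),
                                                   type = "none")), "duplicate")
})

test_that("no-intron plans produce single-exon loci", {
  set.seed(61)
  loc <- gen_locus(gen_protein("IIe")$protein)
  expect_equal(nrow(loc$exons), 1L)
  expect_equal(loc$exons$end, loc$cds_len)
})

test_that("cohort generation is reproducible from (seed, config)", {
  cfg <- cohort_config(n_genes = 12, n_chrom = 2,
                       clusters = tibble::tibble(seqid = "Chr01", n = 4L,
                                                 span = 120000L))
  c1 <- gen_cohort(cfg, seed = 77)
  c2 <- gen_cohort(cfg, seed = 77)
  expect_identical(unclass(c1$genome)[], unclass(c2$genome)[])
  expect_identical(c1$truth$genes, c2$truth$genes)
  expect_identical(c1$expression, c2$expression)
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(nonsense = 1), "unknown")
  expect_error(
    gen_cohort(cohort_config(n_genes = 12, n_chrom = 2,
                             clusters = tibble::tibble(seqid = "Chr09", n = 4L,
                                                       span = 1e5)),
               seed = 1),
    "unknown chromosome"
  )
  expect_error(
    gen_cohort(cohort_config(n_genes = 6, n_chrom = 2,
                             clusters = tibble::tibble(seqid = "Chr01", n = 9L,
                                                       span = 1e5)),
               seed = 1),
    "exceeds cohort size"
  )
})

test_that("minus-strand emission yields the same typed introns", {
  set.seed(62)
  p <- gen_protein("IIb")
  d <- p$domains
  loc <- gen_locus(p$protein, tibble::tibble(residue = d$vqr_residue[1],
                                             phase = 0L, type = "VQR"))
  spans <- tibble::tibble(transcript_id = "g1.t1",
                          aa_start = d$hep_start[1], aa_end = d$zf_end[1])
  for (strand in c("+", "-")) {
    fx <- locus_model(loc, strand)
    typed <- type_domain_introns(intron_phases(fx$model, fx$genome), spans)
    expect_equal(typed$type[typed$in_cds], "VQR")
  }
})

test_that("generated cohorts expose consistent truth tables", {
  co <- gen_cohort(
    cohort_config(n_genes = 20, n_chrom = 3,
                  clusters = tibble::tibble(seqid = "Chr02", n = 4L,
                                            span = 150000L)),
    seed = 63
  )
  tr <- co$truth
  expect_equal(nrow(tr$genes), 20L)
  expect_setequal(tr$genes$gene_id, co$proteins$gene_id)
  # every planted intron references a real transcript
  expect_true(all(tr$introns$transcript_id %in% co$models$transcript_id))
  # planted elements lie inside the promoter window
  expect_true(all(tr$elements$start >= 1 &
                    tr$elements$start <= nchar(co$promoters$promoter[1])))
  # expression matrix covers every gene with non-negative values
  expect_setequal(co$expression$gene_id, tr$genes$gene_id)
  vals <- as.matrix(co$expression[setdiff(names(co$expression), "gene_id")])
  expect_true(all(vals >= 0))
  # exon/intron bookkeeping: introns = exons - 1 for the main transcripts
  main <- co$models[co$models$transcript_id %in% tr$genes$transcript_id, ]
  n_introns <- vapply(main$exons, nrow, integer(1)) - 1L
  planted <- table(factor(tr$introns$transcript_id,
                          levels = main$transcript_id))
  expect_equal(unname(n_introns), as.integer(planted))
})
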