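test_that("exon counts come straight from the models", {
  set.seed(1)
  p <- gen_protein("IIc")
  loc0 <- gen_locus(p$protein)
  loc2 <- gen_locus(p$protein,
                    tibble::tibble(residue = c(5L, 10L), phase = c(0L, 1L),
                                   type = c("none", "none")))
  fx <- locus_model(loc0)
  fx2 <- locus_model(loc2, gene_id = "g2")
  m <- dplyr::bind_rows(fx$model, fx2$model)
  expect_equal(exon_counts(m)$n_exons, c(1L, 3L))
})

test_that("intron phase equals coding offset mod 3, with residue context", {
  set.seed(2)
  p <- gen_protein("IIc")
  plan <- tibble::tibble(residue = c(3L, 4L, 5L), phase = c(0L, 1L, 2L),
                         type = "none")
  loc <- gen_locus(p$protein, plan)
  fx <- locus_model(loc)
  ip <- intron_phases(fx$model, fx$genome)
  expect_equal(ip$coding_offset, c(6L, 10L, 14L))
  expect_equal(ip$phase, c(0L, 1L, 2L))
  res <- strsplit(p$protein, "", fixed = TRUE)[[1]]
  expect_equal(ip$interrupted_residue, c(NA, res[4], res[5]))
  expect_equal(ip$following_context[1], paste(res[3:5], collapse = ""))
})

test_that("phases and offsets are invariant under strand mirroring", {
  set.seed(3)
  for (i in 1:5) {
    p <- gen_protein(sample(c("IIc", "IId", "III"), 1))
    n <- nchar(p$protein)
    k <- sample(2:4, 1)
    plan <- tibble::tibble(residue = sort(sample(2:(n - 2), k)),
                           phase = sample(0:2, k, replace = TRUE),
                           type = "none")
    loc <- gen_locus(p$protein, plan)
    plus <- locus_model(loc, "+")
    minus <- locus_model(loc, "-")
    ip_p <- intron_phases(plus$model, plus$genome)
    ip_m <- intron_phases(minus$model, minus$genome)
    expect_equal(ip_p$coding_offset, ip_m$coding_offset)
    expect_equal(ip_p$phase, ip_m$phase)
    expect_equal(ip_p$interrupted_residue, ip_m$interrupted_residue)
  }
})

test_that("domain residues map to genomic codon intervals (closed form)", {
  # single-exon CDS starting at genomic 101: residues 10-60 span
  # nucleotides (10-1)*3+1 .. 60*3 of the CDS, i.e. 128..280 genomically
  prot <- strrep("M", 120)
  loc <- gen_locus(prot)
  chrom <- paste0(strrep("A", 100), loc$gene_seq, strrep("A", 100))
  model <- tibble::tibble(
    gene_id = "g", transcript_id = "t", protein_id = "p", seqid = "c",
    strand = "+", gene_start = 101L, gene_end = as.integer(100 + nchar(loc$gene_seq)),
    exons = list(data.frame(start = 101L, end = as.integer(100 + nchar(loc$gene_seq)))),
    cds = list(data.frame(start = 101L, end = as.integer(100 + nchar(loc$gene_seq)))),
    partial = FALSE
  )
  iv <- map_domain_to_cds(model[1, ], 10L, 60L)
  expect_equal(iv$start, 128L)
  expect_equal(iv$end, 280L)
  expect_error(map_domain_to_cds(model[1, ], 100L, 130L), "beyond")
})

test_that("split-domain mapping agrees with a per-residue oracle", {
  set.seed(4)
  p <- gen_protein("IId")
  n <- nchar(p$protein)
  plan <- tibble::tibble(residue = sort(sample(5:(n - 5), 3)), phase = 0L,
                         type = "none")
  loc <- gen_locus(p$protein, plan)
  for (strand in c("+", "-")) {
    fx <- locus_model(loc, strand)
    tx <- fx$model[1, ]
    d <- p$domains
    iv <- map_domain_to_cds(tx, d$hep_start[1], d$zf_end[1])
    want_len <- 3L * (d$zf_end[1] - d$hep_start[1] + 1L)
    expect_equal(sum(iv$end - iv$start + 1L), want_len)
    # per-residue oracle: the union of per-codon intervals equals the map
    per <- lapply(d$hep_start[1]:d$zf_end[1],
                  function(r) map_domain_to_cds(tx, r, r))
    per_pos <- sort(unlist(lapply(per, function(b) {
      unlist(mapply(seq, b$start, b$end, SIMPLIFY = FALSE))
    })))
    got_pos <- sort(unlist(mapply(seq, iv$start, iv$end, SIMPLIFY = FALSE)))
    expect_equal(got_pos, per_pos)
  }
})

test_that("PR and VQR introns are typed from phase, residue and context", {
  set.seed(6)
  p <- gen_protein("IIb")
  d <- p$domains
  # phase-2 PR in the domain's arginine, phase-0 VQR before the valine,
  # plus a neutral intron in the flank
  plan <- tibble::tibble(
    residue = c(d$pr_residue[1], d$vqr_residue[1], 3L),
    phase = c(2L, 0L, 0L),
    type = c("PR", "VQR", "none")
  )
  loc <- gen_locus(p$protein, plan)
  fx <- locus_model(loc)
  ip <- intron_phases(fx$model, fx$genome)
  spans <- tibble::tibble(transcript_id = fx$model$transcript_id,
                          aa_start = d$hep_start[1], aa_end = d$zf_end[1])
  typed <- type_domain_introns(ip, spans)
  got <- typed[order(typed$coding_offset), ]
  want <- loc$truth[order(loc$truth$coding_offset), ]
  expect_equal(got$type, want$type)
  expect_equal(got$within_domain, want$type != "none")

  # phase-1 PR variant (the rare case)
  loc1 <- gen_locus(p$protein, tibble::tibble(residue = d$pr_residue[1],
                                              phase = 1L, type = "PR"))
  fx1 <- locus_model(loc1)
  t1 <- type_domain_introns(intron_phases(fx1$model, fx1$genome), spans)
  expect_equal(t1$type, "PR")
  expect_equal(t1$phase, 1L)

  # VQR typing requires the V context: relaxation flag
  typed_rel <- type_domain_introns(ip, spans, require_vqr_context = FALSE)
  expect_equal(sum(typed_rel$type == "VQR"), 1L)
})

test_that("domain-free genes never yield typed introns", {
  set.seed(7)
  prot <- paste(sample(setdiff(AA20_test(), c("C", "H", "W")), 120,
                       replace = TRUE), collapse = "")
  plan <- tibble::tibble(residue = c(20L, 60L), phase = c(2L, 0L), type = "none")
  loc <- gen_locus(prot, plan)
  fx <- locus_model(loc)
  ip <- intron_phases(fx$model, fx$genome)
  typed <- type_domain_introns(ip, tibble::tibble(transcript_id = character(),
                                                  aa_start = integer(),
                                                  aa_end = integer()))
  expect_true(all(typed$type == "none"))
  expect_false(any(typed$within_domain))
})

test_that("introns outside the CDS are reported untyped", {
  # a two-exon gene whose first exon is UTR only
  chrom <- paste0(strrep("A", 50), "GGGG", strrep("C", 30), "ATGGCTGCTTAA",
                  strrep("A", 50))
  g <- wrkyscan:::new_genome(c(c1 = chrom))
  exons <- data.frame(start = c(51L, 85L), end = c(54L, 96L))
  cds <- data.frame(start = 85L, end = 96L)
  m <- tibble::tibble(
    gene_id = "g", transcript_id = "t", protein_id = "p", seqid = "c1",
    strand = "+", gene_start = 51L, gene_end = 96L,
    exons = list(exons), cds = list(cds), partial = FALSE
  )
  ip <- intron_phases(m, g)
  expect_equal(nrow(ip), 1L)
  expect_false(ip$in_cds)
  expect_true(is.na(ip$phase))
})
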