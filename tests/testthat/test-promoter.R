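bg60 <- function() strrep("A", 60)

test_that("element scan finds IUPAC consensus hits on both strands", {
  prom <- paste0(bg60(), "TTGACC", bg60())
  hits <- scan_cis_elements(tibble::tibble(gene_id = "g", promoter = prom))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$class, "WBOX")
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 61L)
  expect_equal(hits$offset, 61L - nchar(prom) - 1L)

  # reverse complement of the whole promoter: same count, opposite strand
  rc <- revcomp_test(prom)
  hits_rc <- scan_cis_elements(tibble::tibble(gene_id = "g", promoter = rc))
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$class, "WBOX")
  expect_equal(hits_rc$strand, "-")

  # element planted on both strands at the same locus: two hits
  both <- paste0(bg60(), "TTGACC", "GGTCAA", bg60())
  hits_b <- scan_cis_elements(tibble::tibble(gene_id = "g", promoter = both))
  expect_equal(nrow(hits_b), 2L)
  expect_setequal(hits_b$strand, c("+", "-"))
})

test_that("strand symmetry holds for per-class counts on random promoters", {
  set.seed(20)
  for (i in 1:10) {
    prom <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
    f <- scan_cis_elements(tibble::tibble(gene_id = "g", promoter = prom))
    r <- scan_cis_elements(tibble::tibble(gene_id = "g",
                                          promoter = revcomp_test(prom)))
    expect_equal(dplyr::count(f, class)$n[order(unique(f$class))],
                 dplyr::count(r, class)$n[order(unique(r$class))])
  }
})

test_that("ABA responsiveness requires ABRE coupling", {
  mk_hits <- function(...) {
    classes <- c(...)
    tibble::tibble(gene_id = "g", class = classes, strand = "+",
                   start = seq_along(classes) * 20L,
                   offset = -seq_along(classes) * 20L)
  }
  c1 <- categorize_promoters(mk_hits("ABRE"), genes = "g")
  expect_false(c1$aba_responsive)
  expect_equal(c1$category, 6L)

  c2 <- categorize_promoters(mk_hits("ABRE", "ABRE"), genes = "g")
  expect_true(c2$aba_responsive)

  c3 <- categorize_promoters(mk_hits("ABRE", "CE1"), genes = "g")
  expect_true(c3$aba_responsive)

  c4 <- categorize_promoters(mk_hits("ABRE", "DRE"), genes = "g")
  expect_true(c4$aba_responsive)

  all5 <- categorize_promoters(mk_hits("SARE", "ABRE", "CE1", "DRE", "WBOX"),
                               genes = "g")
  expect_true(all(all5$sa_responsive, all5$aba_responsive,
                  all5$drought_responsive, all5$wrky_regulated))
  expect_equal(all5$category, 5L)
})

test_that("flag logic matches exhaustive truth-table enumeration", {
  combos <- expand.grid(ABRE = 0:2, CE1 = 0:1, CE3 = 0:1, DRE = 0:1,
                        SARE = 0:1, WBOX = 0:1)
  for (i in seq_len(nrow(combos))) {
    n <- combos[i, ]
    classes <- rep(names(n), times = as.integer(n))
    hits <- tibble::tibble(gene_id = "g", class = classes, strand = "+",
                           start = seq_along(classes) * 15L,
                           offset = -seq_along(classes) * 15L)
    got <- categorize_promoters(hits, genes = "g")
    # independent statement of the rules
    want_aba <- n$ABRE >= 1 && (n$CE1 + n$CE3 >= 1 || n$ABRE >= 2 || n$DRE >= 1)
    expect_equal(got$aba_responsive, want_aba, info = paste(n, collapse = ","))
    expect_equal(got$sa_responsive, n$SARE >= 1)
    expect_equal(got$drought_responsive, n$DRE >= 1)
    expect_equal(got$wrky_regulated, n$WBOX >= 1)
  }
})

test_that("categories follow the ordered rule table", {
  counts_to_cat <- function(...) {
    classes <- c(...)
    hits <- tibble::tibble(gene_id = "g", class = classes, strand = "+",
                           start = seq_along(classes) * 15L,
                           offset = -15L * seq_along(classes))
    categorize_promoters(hits, genes = "g")$category
  }
  expect_equal(counts_to_cat("SARE"), 1L)
  expect_equal(counts_to_cat("SARE", "ABRE", "ABRE"), 2L)
  expect_equal(counts_to_cat("SARE", "DRE"), 3L)
  expect_equal(counts_to_cat("SARE", "ABRE", "CE1", "DRE"), 4L)
  expect_equal(counts_to_cat("SARE", "ABRE", "CE3", "DRE", "WBOX"), 5L)
  expect_equal(counts_to_cat("WBOX"), 6L)
  expect_equal(counts_to_cat(character()), 6L)
})

test_that("cohort summary totals are consistent", {
  cats <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    sa_responsive = c(TRUE, TRUE, FALSE),
    aba_responsive = c(FALSE, TRUE, FALSE),
    drought_responsive = c(FALSE, FALSE, FALSE),
    wrky_regulated = c(FALSE, FALSE, FALSE),
    category = c(1L, 2L, 6L)
  )
  s <- summarize_promoter_categories(cats)
  expect_equal(sum(s$categories$n), 3L)
  expect_equal(s$flags$n[s$flags$flag == "sa_responsive"], 2L)

  s0 <- summarize_promoter_categories(cats[0, ])
  expect_true(all(s0$categories$n == 0L))
  expect_true(all(s0$flags$n == 0L))
})

test_that("planted promoter plans are recovered exactly", {
  set.seed(21)
  tab <- cis_element_table()
  for (cat in 1:6) {
    p <- wrkyscan:::gen_promoter(cat, 800L, tab)
    hits <- scan_cis_elements(tibble::tibble(gene_id = "g", promoter = p$seq))
    got <- categorize_promoters(hits, genes = "g")
    expect_equal(got$category, cat, info = paste("category", cat))
  }
})
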