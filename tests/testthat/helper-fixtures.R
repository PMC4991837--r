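# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive re-derivations (enumeration, direct character logic)
# kept separate from the implementation paths they check.

# Wrap a gen_locus() result into a one-transcript model tibble on a padded
# chromosome, on either strand.
locus_model <- function(loc, strand = "+", pad = 300L, gene_id = "g1") {
  chrom <- paste0(strrep("A", pad), loc$gene_seq, strrep("A", pad))
  if (strand == "-") chrom <- revcomp_test(chrom)
  L <- nchar(chrom)
  glen <- nchar(loc$gene_seq)
  if (strand == "+") {
    ex <- data.frame(start = loc$exons$start + pad, end = loc$exons$end + pad)
    gs <- pad + 1L
    ge <- pad + glen
    ex <- ex[order(ex$start), , drop = FALSE]
  } else {
    gs <- L - (pad + glen) + 1L
    ge <- L - pad
    ex <- data.frame(
      start = L - (loc$exons$end + pad) + 1L,
      end = L - (loc$exons$start + pad) + 1L
    )
    ex <- ex[order(ex$start, decreasing = TRUE), , drop = FALSE]
  }
  tid <- paste0(gene_id, ".t1")
  list(
    genome = wrkyscan:::new_genome(setNames(chrom, "chrT")),
    model = tibble::tibble(
      gene_id = gene_id, transcript_id = tid, protein_id = paste0(tid, ".p"),
      seqid = "chrT", strand = strand,
      gene_start = as.integer(gs), gene_end = as.integer(ge),
      exons = list(ex), cds = list(ex), partial = FALSE
    )
  )
}

AA20_test <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

revcomp_test <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# --- cluster oracle: exhaustive window enumeration + maximality filter ----
# Enumerates every contiguous gene window; a window qualifies when it has
# enough members and its span fits, and is reported when neither one-gene
# extension still fits the span bound.
oracle_clusters <- function(genes, max_span = 400000L, min_genes = 4L) {
  out <- list()
  for (chrom in unique(genes$seqid)) {
    sub <- genes[genes$seqid == chrom, , drop = FALSE]
    sub <- sub[order(sub$start, sub$gene_id), , drop = FALSE]
    n <- nrow(sub)
    # span(i, j) = running_max_end(i..j) - start(i) + 1, tabulated per i
    span_row <- function(i) cummax(sub$end[i:n]) - sub$start[i] + 1L
    spans <- lapply(seq_len(n), span_row)
    span <- function(i, j) spans[[i]][j - i + 1L]
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1L < min_genes || span(i, j) > max_span) next
        left_ok <- i == 1L || span(i - 1L, j) > max_span
        right_ok <- j == n || span(i, j + 1L) > max_span
        if (left_ok && right_ok) {
          out[[length(out) + 1L]] <- list(seqid = chrom, members = sub$gene_id[i:j])
        }
      }
    }
  }
  out
}

# --- motif oracle: direct character-logic matchers -------------------------
is_phi <- function(ch) ch %in% c("L", "I", "V")

oracle_match <- function(sub, class) {
  ch <- strsplit(sub, "", fixed = TRUE)[[1]]
  n <- length(ch)
  switch(class,
    mapk_minimal = n == 2L && ch[1] %in% c("S", "T") && ch[2] == "P",
    mapk_preferred = n == 4L && ch[1] == "P" && ch[3] %in% c("S", "T") && ch[4] == "P",
    f_site = n == 4L && ch[1] == "F" && ch[3] == "F" && ch[4] == "P",
    d_motif = {
      ok <- FALSE
      if (n >= 6L && n <= 12L && is_phi(ch[n - 2L]) && is_phi(ch[n])) {
        for (k in 1:3) {
          x <- n - k - 3L
          if (x >= 1L && x <= 6L && all(ch[1:k] %in% c("K", "R"))) ok <- TRUE
        }
      }
      ok
    }
  )
}

oracle_scan_class <- function(protein, class, min_len, max_len) {
  n <- nchar(protein)
  hits <- list()
  pos <- 1L
  while (pos + min_len - 1L <= n) {
    found <- 0L
    for (len in seq(min(max_len, n - pos + 1L), min_len)) {
      if (oracle_match(substr(protein, pos, pos + len - 1L), class)) {
        found <- len
        break
      }
    }
    if (found > 0L) {
      hits[[length(hits) + 1L]] <- c(pos, found)
      pos <- pos + found
    } else {
      pos <- pos + 1L
    }
  }
  hits
}

# --- four-point condition oracle for 4-taxon NJ ---------------------------
# Returns which unrooted topology an additive distance matrix supports:
# "12|34", "13|24" or "14|23" by the smallest of the three pair sums.
oracle_quartet <- function(d) {
  s1 <- d[1, 2] + d[3, 4]   # 12|34
  s2 <- d[1, 3] + d[2, 4]   # 13|24
  s3 <- d[1, 4] + d[2, 3]   # 14|23
  c("12|34", "13|24", "14|23")[which.min(c(s1, s2, s3))]
}

# Which quartet split an unrooted 4-taxon phylo contains, by taxon index
# order of `taxa`.
quartet_of_tree <- function(phy, taxa) {
  parts <- ape::prop.part(ape::unroot(phy))
  for (p in parts) {
    tips <- attr(parts, "labels")[p]
    if (length(tips) == 2L) {
      idx <- sort(match(tips, taxa))
      if (!1 %in% idx) idx <- sort(setdiff(1:4, idx))  # canonical side holds taxon 1
      return(paste0(idx[1], idx[2], "|",
                    paste(sort(setdiff(1:4, idx)), collapse = "")))
    }
  }
  NA_character_
}
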