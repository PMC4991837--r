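# Genome and annotation I/O: FASTA, GFF3, coordinate-safe sequence extraction.
#
# Coordinates follow the GFF3 convention throughout: 1-based, inclusive.
# Minus-strand transcripts store their exon/CDS intervals in translation
# order (descending genomic start).

#' Read a genome from a FASTA file
#'
#' Loads a multi-record nucleotide FASTA into a `wrky_genome` object.
#' Sequences are uppercased; record ids are the first whitespace-delimited
#' token of each header and must be unique; the remainder of the header is
#' kept as a description. Only the characters A, C, G, T and N are accepted:
#' other IUPAC ambiguity codes are rejected at parse time so that downstream
#' motif scans operate on a known alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A `wrky_genome`: a named character vector of sequences with a
#'   `desc` attribute holding the header descriptions.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate FASTA record id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    abort(sprintf(
      "non-ACGTN characters in record(s): %s (ambiguity codes other than N are not supported)",
      paste(ids[bad], collapse = ", ")
    ))
  }
  new_genome(setNames(seqs, ids), desc = setNames(desc, ids))
}

new_genome <- function(seqs, desc = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  structure(seqs, desc = desc, class = "wrky_genome")
}

#' @export
print.wrky_genome <- function(x, ...) {
  cat(sprintf("<wrky_genome> %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  print(genome_lengths(x), ...)
  invisible(x)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `wrky_genome`.
#' @return A tibble with columns `seqid` and `length_bp`.
#' @export
genome_lengths <- function(genome) {
  tibble(seqid = names(genome), length_bp = unname(nchar(genome)))
}

#' Write a genome to FASTA
#'
#' @param genome A `wrky_genome`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  desc <- attr(genome, "desc")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome)) {
    d <- if (!is.null(desc) && !is.na(desc[id]) && nzchar(desc[id])) paste0(" ", desc[id]) else ""
    writeLines(paste0(">", id, d), con)
    s <- genome[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a protein FASTA into a tibble
#'
#' @param path Path to an amino-acid FASTA file.
#' @return A tibble with columns `protein_id`, `desc` and `protein`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate FASTA record id(s): %s", paste(dup, collapse = ", ")))
  }
  tibble(
    protein_id = ids,
    desc = ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), ""),
    protein = toupper(as.character(set))
  )
}

#' Write protein sequences to FASTA
#'
#' @param proteins A tibble with columns `protein_id` and `protein` (or a
#'   named character vector).
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  if (is.character(proteins)) {
    proteins <- tibble(protein_id = names(proteins), protein = unname(proteins))
  }
  writeLines(
    paste0(">", proteins$protein_id, "\n", proteins$protein),
    path
  )
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Assembles gene/mRNA/exon/CDS features into one row per transcript.
#' Exon and CDS intervals are stored in translation order: ascending genomic
#' start on the plus strand, descending on the minus strand. Orphan features
#' (an mRNA whose `Parent` gene is absent, or an exon/CDS whose parent
#' transcript is absent) are skipped with a warning. When a genome is
#' supplied, CDS coordinates falling outside their chromosome are an error.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `wrky_genome` used to validate coordinates.
#' @return A tibble with one row per transcript: `gene_id`, `transcript_id`,
#'   `protein_id`, `seqid`, `strand`, `gene_start`, `gene_end`, and
#'   list-columns `exons` and `cds` of two-column data frames
#'   (`start`, `end`), plus a `partial` flag set when the summed CDS length
#'   is not divisible by three.
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$Parent <- vapply(g$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))

  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]

  orphan_tx <- !(mrnas$Parent %in% genes$ID)
  if (any(orphan_tx)) {
    warn(sprintf(
      "skipping %d transcript(s) with unresolvable Parent: %s",
      sum(orphan_tx), paste(mrnas$ID[orphan_tx], collapse = ", ")
    ))
    mrnas <- mrnas[!orphan_tx, , drop = FALSE]
  }
  orphan_part <- !(parts$Parent %in% mrnas$ID)
  if (any(orphan_part)) {
    warn(sprintf("skipping %d exon/CDS feature(s) with unresolvable Parent", sum(orphan_part)))
    parts <- parts[!orphan_part, , drop = FALSE]
  }

  if (nrow(mrnas) == 0L) abort(sprintf("no resolvable transcripts in %s", path))

  rows <- lapply(seq_len(nrow(mrnas)), function(i) {
    tx <- mrnas[i, ]
    gene <- genes[genes$ID == tx$Parent, ][1, ]
    sub <- parts[parts$Parent == tx$ID, , drop = FALSE]
    minus <- as.character(tx$strand) == "-"
    order_iv <- function(d) {
      d <- d[order(d$start, decreasing = minus), c("start", "end"), drop = FALSE]
      rownames(d) <- NULL
      d
    }
    exons <- order_iv(sub[sub$type == "exon", , drop = FALSE])
    cds <- order_iv(sub[sub$type == "CDS", , drop = FALSE])
    if (nrow(exons) == 0L && nrow(cds) > 0L) exons <- cds
    prot <- if ("protein_id" %in% names(tx) && !is.na(tx$protein_id)) {
      as.character(tx$protein_id)
    } else {
      as.character(tx$ID)
    }
    tibble(
      gene_id = as.character(gene$ID),
      transcript_id = as.character(tx$ID),
      protein_id = prot,
      seqid = as.character(tx$seqid),
      strand = as.character(tx$strand),
      gene_start = as.integer(gene$start),
      gene_end = as.integer(gene$end),
      exons = list(exons),
      cds = list(cds),
      partial = sum(cds$end - cds$start + 1L) %% 3L != 0L
    )
  })
  models <- bind_rows(rows)

  if (!is.null(genome)) {
    lens <- setNames(nchar(genome), names(genome))
    for (i in seq_len(nrow(models))) {
      len <- lens[models$seqid[i]]
      if (is.na(len)) {
        abort(sprintf("transcript %s on unknown chromosome %s",
                      models$transcript_id[i], models$seqid[i]))
      }
      cds <- models$cds[[i]]
      if (nrow(cds) > 0L && (min(cds$start) < 1L || max(cds$end) > len)) {
        abort(sprintf("CDS of %s outside chromosome bounds [1, %d]",
                      models$transcript_id[i], len))
      }
    }
  }
  models
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: emits gene, mRNA, exon and CDS features with
#' `ID`/`Parent` attributes. CDS phase columns are computed from cumulative
#' coding length in translation order.
#'
#' @param models A transcript tibble as returned by [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(seqid, type, start, end, strand, phase, attrs) {
    sprintf("%s\twrkyscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            seqid, type, start, end, strand, phase, attrs)
  }
  for (gid in unique(models$gene_id)) {
    sub <- models[models$gene_id == gid, , drop = FALSE]
    g1 <- sub[1, ]
    writeLines(fmt(g1$seqid, "gene", g1$gene_start, g1$gene_end, g1$strand, ".",
                   sprintf("ID=%s", gid)), con)
    for (i in seq_len(nrow(sub))) {
      tx <- sub[i, ]
      exons <- tx$exons[[1]]
      cds <- tx$cds[[1]]
      writeLines(fmt(tx$seqid, "mRNA", min(exons$start), max(exons$end), tx$strand, ".",
                     sprintf("ID=%s;Parent=%s;protein_id=%s",
                             tx$transcript_id, gid, tx$protein_id)), con)
      for (j in seq_len(nrow(exons))) {
        writeLines(fmt(tx$seqid, "exon", exons$start[j], exons$end[j], tx$strand, ".",
                       sprintf("Parent=%s", tx$transcript_id)), con)
      }
      cum <- 0L
      for (j in seq_len(nrow(cds))) {
        phase <- (3L - (cum %% 3L)) %% 3L
        writeLines(fmt(tx$seqid, "CDS", cds$start[j], cds$end[j], tx$strand,
                       as.character(phase),
                       sprintf("Parent=%s", tx$transcript_id)), con)
        cum <- cum + cds$end[j] - cds$start[j] + 1L
      }
    }
  }
  invisible(path)
}

# Assemble the coding sequence of one transcript in translation orientation.
coding_sequence <- function(tx_row, genome) {
  cds <- tx_row$cds[[1]]
  if (nrow(cds) == 0L) abort(sprintf("transcript %s has no CDS", tx_row$transcript_id))
  chrom <- genome[[tx_row$seqid]]
  if (is.null(chrom)) abort(sprintf("unknown chromosome: %s", tx_row$seqid))
  asc <- cds[order(cds$start), , drop = FALSE]
  s <- paste(substring(chrom, asc$start, asc$end), collapse = "")
  if (tx_row$strand == "-") s <- revcomp(s)
  s
}

#' Translate transcript models to protein sequences
#'
#' Concatenates each transcript's CDS in translation order, reverse
#' complementing minus-strand models, and translates with the standard
#' nuclear genetic code (N translates to X). A trailing stop codon is
#' removed; an internal stop is flagged, never silently dropped. A CDS whose
#' length is not divisible by three is an error unless the model carries the
#' `partial` flag, in which case the trailing incomplete codon is dropped.
#'
#' @param models Transcript tibble ([read_gff3()]).
#' @param genome A `wrky_genome`.
#' @return A tibble: `gene_id`, `transcript_id`, `protein_id`, `protein`,
#'   `n_aa`, `internal_stop`, `partial`.
#' @export
extract_proteins <- function(models, genome) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    tx <- models[i, ]
    dna <- coding_sequence(tx, genome)
    if (nchar(dna) < 3L) abort(sprintf("CDS of %s shorter than one codon", tx$transcript_id))
    if (nchar(dna) %% 3L != 0L) {
      if (!isTRUE(tx$partial)) {
        abort(sprintf("CDS length of %s not divisible by 3 (flag it partial to allow)",
                      tx$transcript_id))
      }
      dna <- substr(dna, 1L, nchar(dna) - nchar(dna) %% 3L)
    }
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(dna),
      if.fuzzy.codon = "X", no.init.codon = TRUE
    ))
    if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
    tibble(
      gene_id = tx$gene_id,
      transcript_id = tx$transcript_id,
      protein_id = tx$protein_id,
      protein = aa,
      n_aa = nchar(aa),
      internal_stop = grepl("*", aa, fixed = TRUE),
      partial = isTRUE(tx$partial)
    )
  })
  bind_rows(rows)
}

#' Extract promoter windows upstream of genes
#'
#' Returns the `upstream_bp` bases 5' of each gene's translation-orientation
#' start (the gene span start on the plus strand, the span end on the minus
#' strand), reported on the coding strand. Windows truncated by a chromosome
#' edge are flagged, not fatal.
#'
#' @param models Transcript tibble; one window is produced per distinct gene.
#' @param genome A `wrky_genome`.
#' @param upstream_bp Window size in bp (default 1500).
#' @return A tibble: `gene_id`, `seqid`, `strand`, `win_start`, `win_end`
#'   (genomic, 1-based inclusive), `truncated`, `promoter`.
#' @export
extract_promoters <- function(models, genome, upstream_bp = 1500L) {
  assert_scalar_number(upstream_bp, "upstream_bp")
  genes <- models |>
    distinct(.data$gene_id, .data$seqid, .data$strand, .data$gene_start, .data$gene_end)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    chrom <- genome[[g$seqid]]
    if (is.null(chrom)) abort(sprintf("unknown chromosome: %s", g$seqid))
    len <- nchar(chrom)
    if (g$strand == "+") {
      ws <- g$gene_start - upstream_bp
      we <- g$gene_start - 1L
    } else {
      ws <- g$gene_end + 1L
      we <- g$gene_end + upstream_bp
    }
    truncated <- ws < 1L || we > len
    ws2 <- max(ws, 1L)
    we2 <- min(we, len)
    seq <- if (we2 >= ws2) substr(chrom, ws2, we2) else ""
    if (g$strand == "-" && nzchar(seq)) seq <- revcomp(seq)
    tibble(
      gene_id = g$gene_id, seqid = g$seqid, strand = g$strand,
      win_start = as.integer(ws2), win_end = as.integer(we2),
      truncated = truncated, promoter = seq
    )
  })
  bind_rows(rows)
}
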