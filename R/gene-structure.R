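# Gene structure: exon counts, intron phases, PR/VQR intron typing within
# the WRKY-domain-coding region.
#
# Intron phase is defined relative to codon boundaries of the coding
# sequence: phase 0 introns fall between two codons, phase 1 between the
# first and second nucleotide of a codon, phase 2 between the second and
# third. Equivalently, phase = (coding nucleotides upstream of the intron)
# mod 3. Two intron classes recur in WRKY-domain-coding DNA: the PR-type
# intron interrupts the codon of a conserved arginine inside the domain
# (typically phase 2), and the VQR-type intron sits immediately 5' of the
# codon of a conserved valine (V-Q-R context) and is always phase 0.

#' Exon counts per transcript
#'
#' @param models Transcript tibble ([read_gff3()]).
#' @return A tibble: `transcript_id`, `n_exons`.
#' @export
exon_counts <- function(models) {
  tibble(
    transcript_id = models$transcript_id,
    n_exons = map_int(models$exons, nrow)
  )
}

# Coding-orientation view of a transcript: exon/cds intervals in ascending
# genomic order plus a flag for minus strand.
tx_geometry <- function(tx_row) {
  exons <- tx_row$exons[[1]]
  cds <- tx_row$cds[[1]]
  list(
    minus = tx_row$strand == "-",
    exons = exons[order(exons$start), , drop = FALSE],
    cds = cds[order(cds$start), , drop = FALSE]
  )
}

# Number of coding nucleotides strictly 5' (in translation orientation) of
# a genomic junction point. `junction` is the genomic coordinate of the
# last exonic base before the intron in translation orientation.
coding_nt_upstream <- function(geom, junction) {
  cds <- geom$cds
  if (nrow(cds) == 0L) return(0L)
  if (!geom$minus) {
    sum(pmax(0L, pmin(cds$end, junction) - cds$start + 1L))
  } else {
    sum(pmax(0L, cds$end - pmax(cds$start, junction) + 1L))
  }
}

#' Intron records with coding phase
#'
#' One record per intron of each transcript, indexed 5' to 3' in coding
#' orientation. For introns interrupting the CDS the coding offset (number
#' of coding nucleotides upstream) and phase (`offset mod 3`) are computed;
#' introns outside the CDS (UTR introns) are reported with `in_cds = FALSE`
#' and are never typed. When a genome is supplied, phase-1/2 records carry
#' the interrupted residue and phase-0 records the three following
#' residues.
#'
#' @param models Transcript tibble.
#' @param genome Optional `wrky_genome` for residue context.
#' @return A tibble: `transcript_id`, `index`, `intron_start`, `intron_end`
#'   (genomic), `in_cds`, `coding_offset`, `phase`, `interrupted_residue`,
#'   `following_context`.
#' @export
intron_phases <- function(models, genome = NULL) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    tx <- models[i, ]
    geom <- tx_geometry(tx)
    exons <- geom$exons
    if (nrow(exons) < 2L) return(NULL)
    istart <- exons$end[-nrow(exons)] + 1L
    iend <- exons$start[-1L] - 1L
    ord <- if (geom$minus) rev(seq_along(istart)) else seq_along(istart)

    protein <- NULL
    if (!is.null(genome) && nrow(geom$cds) > 0L) {
      dna <- coding_sequence(tx, genome)
      dna <- substr(dna, 1L, nchar(dna) - nchar(dna) %% 3L)
      protein <- as.character(Biostrings::translate(
        Biostrings::DNAString(dna), if.fuzzy.codon = "X", no.init.codon = TRUE))
    }
    cds_total <- sum(geom$cds$end - geom$cds$start + 1L)

    out <- lapply(seq_along(ord), function(k) {
      j <- ord[k]
      junction <- if (!geom$minus) istart[j] - 1L else iend[j] + 1L
      off <- coding_nt_upstream(geom, junction)
      in_cds <- off > 0L && off < cds_total
      phase <- if (in_cds) off %% 3L else NA_integer_
      interrupted <- NA_character_
      context <- NA_character_
      if (in_cds && !is.null(protein)) {
        if (phase %in% c(1L, 2L)) {
          idx <- off %/% 3L + 1L
          if (idx <= nchar(protein)) interrupted <- substr(protein, idx, idx)
        } else {
          idx <- off %/% 3L + 1L
          context <- substr(protein, idx, min(idx + 2L, nchar(protein)))
        }
      }
      tibble(
        transcript_id = tx$transcript_id, index = k,
        intron_start = istart[j], intron_end = iend[j],
        in_cds = in_cds, coding_offset = if (in_cds) as.integer(off) else NA_integer_,
        phase = phase, interrupted_residue = interrupted,
        following_context = context
      )
    })
    bind_rows(out)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      transcript_id = character(), index = integer(), intron_start = integer(),
      intron_end = integer(), in_cds = logical(), coding_offset = integer(),
      phase = integer(), interrupted_residue = character(),
      following_context = character()
    )
  }
  out
}

#' Map a protein domain to its genomic codon intervals
#'
#' Converts a residue range (1-based, inclusive) of a transcript's protein
#' into the genomic interval(s) covering the corresponding codons, split
#' across exons where necessary and strand-aware.
#'
#' @param tx_row One-row transcript tibble.
#' @param aa_start,aa_end Residue range of the domain.
#' @return A tibble of genomic intervals in translation order: `seqid`,
#'   `start`, `end`, `strand`; interval lengths sum to `3 * (aa_end -
#'   aa_start + 1)`.
#' @export
map_domain_to_cds <- function(tx_row, aa_start, aa_end) {
  stopifnot(aa_start >= 1L, aa_end >= aa_start)
  geom <- tx_geometry(tx_row)
  cds <- geom$cds
  total <- sum(cds$end - cds$start + 1L)
  nt_from <- (aa_start - 1L) * 3L + 1L
  nt_to <- aa_end * 3L
  if (nt_to > total) {
    abort(sprintf("domain residues %d-%d extend beyond the %d-codon CDS of %s",
                  aa_start, aa_end, total %/% 3L, tx_row$transcript_id))
  }
  # Walk CDS blocks in translation order, slicing the coding-coordinate range.
  blocks <- if (!geom$minus) seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  out <- list()
  cum <- 0L
  for (b in blocks) {
    w <- cds$end[b] - cds$start[b] + 1L
    lo <- max(nt_from, cum + 1L)
    hi <- min(nt_to, cum + w)
    if (lo <= hi) {
      if (!geom$minus) {
        gs <- cds$start[b] + (lo - cum - 1L)
        ge <- cds$start[b] + (hi - cum - 1L)
      } else {
        gs <- cds$end[b] - (hi - cum - 1L)
        ge <- cds$end[b] - (lo - cum - 1L)
      }
      out[[length(out) + 1L]] <- tibble(
        seqid = tx_row$seqid, start = as.integer(gs), end = as.integer(ge),
        strand = tx_row$strand
      )
    }
    cum <- cum + w
  }
  bind_rows(out)
}

#' Type introns within WRKY-domain-coding regions
#'
#' Fills the `type` field of intron records: a within-domain intron of
#' phase 1 or 2 interrupting an arginine codon is PR; a within-domain
#' phase-0 intron immediately 5' of a valine codon is VQR (by default the
#' V-Q-R context is required, relaxable to V alone); anything else is
#' `none`. "Within the domain" means the affected residue lies in the
#' domain's residue span.
#'
#' @param introns Intron tibble from [intron_phases()] (with residue
#'   context, i.e. computed with a genome).
#' @param domain_spans Tibble mapping transcripts to domain residue spans:
#'   `transcript_id`, `aa_start`, `aa_end`.
#' @param require_vqr_context If `TRUE` (default) VQR typing demands the
#'   full V-Q-R triplet after the intron; if `FALSE` a V suffices.
#' @return `introns` with `within_domain` and `type` columns added.
#' @export
type_domain_introns <- function(introns, domain_spans, require_vqr_context = TRUE) {
  res <- introns
  res$within_domain <- FALSE
  res$type <- "none"
  for (i in seq_len(nrow(res))) {
    if (!isTRUE(res$in_cds[i])) { res$type[i] <- NA_character_; next }
    spans <- domain_spans[domain_spans$transcript_id == res$transcript_id[i], , drop = FALSE]
    if (nrow(spans) == 0L) next
    idx <- res$coding_offset[i] %/% 3L + 1L
    within <- any(idx >= spans$aa_start & idx <= spans$aa_end)
    res$within_domain[i] <- within
    if (!within) next
    if (res$phase[i] %in% c(1L, 2L) &&
        identical(res$interrupted_residue[i], "R")) {
      res$type[i] <- "PR"
    } else if (res$phase[i] == 0L && !is.na(res$following_context[i])) {
      ctx <- res$following_context[i]
      ok <- if (require_vqr_context) startsWith(ctx, "VQR") || ctx == "VQR" else startsWith(ctx, "V")
      if (ok) res$type[i] <- "VQR"
    }
  }
  res
}

#' Transcript-structure summary table
#'
#' A tidy block table (exons, introns and domain codon intervals) per
#' transcript, suitable for plotting gene-structure figures or export.
#'
#' @param models Transcript tibble.
#' @param domain_spans Optional domain residue spans (`transcript_id`,
#'   `aa_start`, `aa_end`, optionally `feature` labels).
#' @return A tibble: `transcript_id`, `feature`, `seqid`, `start`, `end`,
#'   `strand`.
#' @export
gene_structure_table <- function(models, domain_spans = NULL) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    tx <- models[i, ]
    geom <- tx_geometry(tx)
    exons <- geom$exons
    blocks <- tibble(
      transcript_id = tx$transcript_id, feature = "exon", seqid = tx$seqid,
      start = exons$start, end = exons$end, strand = tx$strand
    )
    if (nrow(exons) >= 2L) {
      blocks <- bind_rows(blocks, tibble(
        transcript_id = tx$transcript_id, feature = "intron", seqid = tx$seqid,
        start = exons$end[-nrow(exons)] + 1L, end = exons$start[-1L] - 1L,
        strand = tx$strand
      ))
    }
    if (!is.null(domain_spans)) {
      spans <- domain_spans[domain_spans$transcript_id == tx$transcript_id, , drop = FALSE]
      for (j in seq_len(nrow(spans))) {
        iv <- map_domain_to_cds(tx, spans$aa_start[j], spans$aa_end[j])
        lab <- if ("feature" %in% names(spans)) spans$feature[j] else "domain"
        blocks <- bind_rows(blocks, tibble(
          transcript_id = tx$transcript_id, feature = lab, seqid = iv$seqid,
          start = iv$start, end = iv$end, strand = iv$strand
        ))
      }
    }
    blocks
  })
  bind_rows(rows)
}
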