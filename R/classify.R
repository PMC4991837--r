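# Group/subgroup classification of WRKY proteins from assembled domains.
#
# The family's standard taxonomy: proteins with two WRKY domains form group
# I (Ia when the fingers are C2H2, Ib when C2HC); single-domain proteins
# with a C2HC finger form group III; single-domain C2H2 proteins split into
# subgroups by the zinc-finger spacer and the signature immediately after
# the second cysteine (IIa CX5C-PVKKK(L/V)Q, IIb CX5C-PVRKQVQ, IIc CX4C,
# IId CX5C-PARKHVE, IIe CX5C-PARK(Q/M)V(E/D)); proteins with an incomplete
# domain are group IV.

WRKY_LABELS <- c("Ia", "Ib", "IIa", "IIb", "IIc", "IId", "IIe", "III", "IV")

#' Classifier rule set
#'
#' Builds the subgroup signature table used by [classify_protein()]. Each
#' signature is a list of allowed residues per position, anchored
#' immediately after the second cysteine; fuzzy matching tolerates up to
#' `fuzzy_max` positions outside their allowed set.
#'
#' @param fuzzy_max Maximum mismatches for a fuzzy signature match
#'   (default 1).
#' @return A list with elements `signatures` (named list of per-position
#'   allowed-residue lists, with a `spacer1` attribute) and `fuzzy_max`.
#' @export
wrky_rules <- function(fuzzy_max = 1L) {
  sig <- function(...) lapply(list(...), identity)
  signatures <- list(
    IIa = sig("P", "V", "K", "K", "K", c("L", "V"), "Q"),
    IIb = sig("P", "V", "R", "K", "Q", "V", "Q"),
    IId = sig("P", "A", "R", "K", "H", "V", "E"),
    IIe = sig("P", "A", "R", "K", c("Q", "M"), "V", c("E", "D"))
  )
  list(signatures = signatures, spacer1 = 5L, fuzzy_max = as.integer(fuzzy_max))
}

# Mismatch count of `trailing` against a per-position allowed-residue list.
signature_mismatches <- function(trailing, sig) {
  k <- length(sig)
  if (nchar(trailing) < k) return(Inf)
  res <- strsplit(substr(trailing, 1L, k), "", fixed = TRUE)[[1]]
  sum(!mapply(function(r, allowed) r %in% allowed, res, sig))
}

# Subgroup of a single C2H2 finger from spacer and trailing signature.
c2h2_subgroup <- function(spacer1, trailing, rules) {
  if (spacer1 == 4L) {
    return(list(label = "IIc", evidence = "CX4C spacer"))
  }
  mm <- vapply(rules$signatures, signature_mismatches, numeric(1), trailing = trailing)
  exact <- names(mm)[mm == 0]
  if (length(exact) > 0L) {
    return(list(label = exact[1],
                evidence = sprintf("exact signature %s", exact[1])))
  }
  fuzzy <- names(mm)[mm <= rules$fuzzy_max]
  if (length(fuzzy) > 0L) {
    best <- fuzzy[which.min(mm[fuzzy])]
    return(list(label = best,
                evidence = sprintf("fuzzy signature %s (%d mismatch)", best, as.integer(mm[best]))))
  }
  list(label = "IIe",
       evidence = "warning: CX5C with unresolved signature, defaulted to IIe")
}

#' Classify one protein from its assembled WRKY domains
#'
#' Applies the group/subgroup rules: two or more complete domains give Ia
#' (all C2H2) or Ib (all C2HC; mixed fingers are labelled by the C-terminal
#' finger with an evidence note); one complete domain gives III for a C2HC
#' finger, or a II subgroup from the signature table for a C2H2 finger
#' (exact match first, then fuzzy within the mismatch budget, else IIc when
#' the first spacer is 4); no complete domain gives IV with an optional
#' secondary label derived from any intact zinc finger.
#'
#' @param domains Tibble of one protein's domains ([assemble_domains()]).
#' @param rules A rule set from [wrky_rules()].
#' @return A one-row tibble: `label`, `secondary`, `evidence`.
#' @export
classify_protein <- function(domains, rules = wrky_rules()) {
  if (nrow(domains) == 0L) abort("not a WRKY protein: no domains supplied")
  complete <- domains[domains$complete, , drop = FALSE]
  evidence <- character()

  if (nrow(complete) >= 2L) {
    types <- complete$zf_type
    if (all(types == "C2H2")) {
      label <- "Ia"
      evidence <- sprintf("%d complete domains, all C2H2 fingers", nrow(complete))
    } else if (all(types == "C2HC")) {
      label <- "Ib"
      evidence <- sprintf("%d complete domains, all C2HC fingers", nrow(complete))
    } else {
      cterm <- types[nrow(complete)]
      label <- if (cterm == "C2H2") "Ia" else "Ib"
      evidence <- sprintf("mixed finger types; labelled by C-terminal %s finger", cterm)
    }
    return(tibble(label = label, secondary = NA_character_,
                  evidence = paste(evidence, collapse = "; ")))
  }

  if (nrow(complete) == 1L) {
    d <- complete[1, ]
    if (d$zf_type == "C2HC") {
      return(tibble(label = "III", secondary = NA_character_,
                    evidence = "single complete domain with C2HC finger"))
    }
    sub <- c2h2_subgroup(d$spacer1, d$trailing, rules)
    return(tibble(label = sub$label, secondary = NA_character_,
                  evidence = paste("single complete C2H2 domain;", sub$evidence)))
  }

  # Incomplete domain(s) only: group IV, secondary from an intact finger.
  fingered <- domains[!is.na(domains$zf_type), , drop = FALSE]
  if (nrow(fingered) > 0L) {
    f <- fingered[1, ]
    if (f$zf_type == "C2HC") {
      sec <- "III"
      ev <- "incomplete domain; intact C2HC finger suggests III"
    } else {
      sub <- c2h2_subgroup(f$spacer1, f$trailing, rules)
      sec <- sub$label
      ev <- paste("incomplete domain; intact C2H2 finger suggests", sub$label)
    }
    return(tibble(label = "IV", secondary = sec, evidence = ev))
  }
  tibble(label = "IV", secondary = NA_character_,
         evidence = "incomplete domain without intact zinc finger")
}

#' Classify a cohort of proteins
#'
#' @param domains Tibble from [scan_wrky_domains()] (multiple proteins).
#' @param rules Rule set from [wrky_rules()].
#' @return A tibble with one row per protein: `protein_id`, `label`,
#'   `secondary`, `evidence`.
#' @export
classify_wrky <- function(domains, rules = wrky_rules()) {
  stopifnot("protein_id" %in% names(domains))
  domains |>
    group_by(.data$protein_id) |>
    group_modify(~ classify_protein(.x, rules)) |>
    ungroup()
}

#' Select the representative isoform per locus
#'
#' For a gene with several alternative transcripts, keeps the transcript
#' encoding the longest protein; ties break to the lexicographically
#' smallest transcript id, so selection is deterministic.
#'
#' @param proteins Tibble from [extract_proteins()] (needs `gene_id`,
#'   `transcript_id`, `n_aa`).
#' @return The input filtered to one row per gene.
#' @export
select_isoforms <- function(proteins) {
  stopifnot(all(c("gene_id", "transcript_id", "n_aa") %in% names(proteins)))
  if (nrow(proteins) == 0L) abort("no translatable transcripts supplied")
  proteins |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$n_aa), .data$transcript_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
}

#' Tally group assignments
#'
#' @param assignments Tibble with a `label` column.
#' @return A tibble of `label`, `n` counts over the observed labels.
#' @export
tally_groups <- function(assignments) {
  if (nrow(assignments) == 0L) return(tibble(label = character(), n = integer()))
  assignments |> count(.data$label)
}

#' Zinc-finger tail-triplet report
#'
#' One row per classified finger with its X-V-E-style triplet (e.g. HVE,
#' KVE, RVE), used for cross-subgroup evolutionary comparisons. Fingers too
#' short to yield a triplet are flagged with an empty triplet.
#'
#' @param assignments Classification tibble ([classify_wrky()]).
#' @param domains Domain tibble ([scan_wrky_domains()]).
#' @return A tibble: `protein_id`, `label`, `domain_idx`, `tail_triplet`,
#'   `flagged`.
#' @export
tail_triplet_report <- function(assignments, domains) {
  domains |>
    filter(!is.na(.data$zf_type)) |>
    left_join(assignments |> select("protein_id", "label"), by = "protein_id") |>
    transmute(
      .data$protein_id, .data$label, .data$domain_idx,
      tail_triplet = ifelse(is.na(.data$tail_triplet), "", .data$tail_triplet),
      flagged = is.na(.data$tail_triplet) | .data$tail_triplet == ""
    )
}
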