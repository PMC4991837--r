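# Linear-motif scanning: MAPK phosphorylation sites and docking motifs.
#
# MAPKs are proline-directed kinases: the minimal phosphoacceptor site is
# (S/T)P and the preferred site P-X-(S/T)-P. Substrate selection is guided
# by docking motifs: the D-motif (K/R)1-3 - X1-6 - Phi-X-Phi with
# Phi in {L, I, V}, and the F-site F-X-F-P. The grammar ships as data so a
# different literature source can be dropped in.

#' Default linear-motif grammar
#'
#' @return A tibble: `class`, `pattern` (anchored regular expression body),
#'   `min_len`, `max_len`.
#' @export
motif_grammar <- function() {
  tibble(
    class = c("mapk_minimal", "mapk_preferred", "d_motif", "f_site"),
    pattern = c("[ST]P", "P.[ST]P", "[KR]{1,3}.{1,6}[LIV].[LIV]", "F.FP"),
    min_len = c(2L, 4L, 6L, 4L),
    max_len = c(2L, 4L, 12L, 4L)
  )
}

#' Read a motif grammar from a TSV file
#'
#' @param path TSV with columns `class`, `pattern`, `min_len`, `max_len`.
#' @return A grammar tibble as from [motif_grammar()].
#' @export
read_motif_grammar <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("class", "pattern", "min_len", "max_len") %in% names(g)))
  g
}

# Leftmost-longest non-overlapping matches of one anchored pattern.
scan_one_class <- function(protein, pattern, min_len, max_len) {
  protein <- unname(protein)
  n <- nchar(protein)
  anchored <- paste0("^(?:", pattern, ")$")
  starts <- integer()
  matches <- character()
  pos <- 1L
  while (pos + min_len - 1L <= n) {
    hit_len <- 0L
    for (len in seq(min(max_len, n - pos + 1L), min_len)) {
      if (grepl(anchored, substr(protein, pos, pos + len - 1L), perl = TRUE)) {
        hit_len <- len
        break
      }
    }
    if (hit_len > 0L) {
      starts <- c(starts, pos)
      matches <- c(matches, substr(protein, pos, pos + hit_len - 1L))
      pos <- pos + hit_len
    } else {
      pos <- pos + 1L
    }
  }
  tibble(start = starts, match = matches)
}

#' Scan proteins for MAPK-related linear motifs
#'
#' Each grammar class is scanned independently (so hits of different
#' classes may overlap); within a class, matches are non-overlapping and
#' resolved leftmost-first, taking the longest admissible match at each
#' position.
#'
#' @param proteins Tibble with `protein_id` and `protein` columns, or a
#'   single protein string.
#' @param grammar Grammar tibble ([motif_grammar()]).
#' @return A tibble: `protein_id`, `class`, `start`, `match`.
#' @export
scan_protein_motifs <- function(proteins, grammar = motif_grammar()) {
  if (is.character(proteins)) {
    proteins <- tibble(protein_id = names(proteins) %||% paste0("p", seq_along(proteins)),
                       protein = proteins)
  }
  out <- list()
  for (i in seq_len(nrow(proteins))) {
    for (k in seq_len(nrow(grammar))) {
      hits <- scan_one_class(proteins$protein[i], grammar$pattern[k],
                             grammar$min_len[k], grammar$max_len[k])
      if (nrow(hits) > 0L) {
        hits$protein_id <- proteins$protein_id[i]
        hits$class <- grammar$class[k]
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(protein_id = character(), class = character(),
                  start = integer(), match = character()))
  }
  bind_rows(out) |> select("protein_id", "class", "start", "match")
}

#' Summarize phosphorylation-site and docking-motif content
#'
#' Per-protein counts plus cohort rollups: the fraction of proteins with at
#' least one phosphorylation site, the maximum site count and its protein,
#' the fraction of site-bearing proteins with at least one D-motif, and
#' (when group assignments are given) zero-site counts per subgroup.
#'
#' @param hits Motif hits ([scan_protein_motifs()]).
#' @param proteins Tibble with `protein_id` (the full cohort, so that
#'   proteins without hits are counted).
#' @param assignments Optional classification tibble with `protein_id` and
#'   `label`.
#' @return A list: `per_protein` (tibble `protein_id`, `n_sites`,
#'   `n_dmotif`, `n_fsite`, `has_docking`), `cohort` (one-row tibble) and
#'   `zero_sites_by_group` (tibble or `NULL`).
#' @export
summarize_phospho <- function(hits, proteins, assignments = NULL) {
  counts <- hits |> count(.data$protein_id, .data$class)
  per <- tibble(protein_id = proteins$protein_id) |>
    left_join(
      counts |> pivot_wider(names_from = "class", values_from = "n", values_fill = 0L),
      by = "protein_id"
    )
  for (cl in c("mapk_minimal", "d_motif", "f_site")) {
    if (!cl %in% names(per)) per[[cl]] <- 0L
  }
  per <- per |>
    transmute(
      .data$protein_id,
      n_sites = replace_na(.data$mapk_minimal, 0L),
      n_dmotif = replace_na(.data$d_motif, 0L),
      n_fsite = replace_na(.data$f_site, 0L),
      has_docking = .data$n_dmotif + .data$n_fsite > 0L
    )
  with_sites <- per |> filter(.data$n_sites > 0L)
  cohort <- tibble(
    n_proteins = nrow(per),
    frac_with_site = if (nrow(per)) nrow(with_sites) / nrow(per) else NA_real_,
    max_sites = if (nrow(per)) max(per$n_sites) else NA_integer_,
    max_site_protein = if (nrow(per) && max(per$n_sites) > 0L) {
      per$protein_id[which.max(per$n_sites)]
    } else {
      NA_character_
    },
    frac_sites_with_dmotif = if (nrow(with_sites)) {
      mean(with_sites$n_dmotif > 0L)
    } else {
      NA_real_
    },
    n_without_docking = sum(!per$has_docking)
  )
  by_group <- NULL
  if (!is.null(assignments)) {
    by_group <- per |>
      filter(.data$n_sites == 0L) |>
      left_join(assignments |> select("protein_id", "label"), by = "protein_id") |>
      count(.data$label, name = "n_zero_site")
  }
  list(per_protein = per, cohort = cohort, zero_sites_by_group = by_group)
}
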