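# WRKY domain detection: heptamer scan, zinc-finger scan, domain assembly.
#
# A WRKY domain is a ~60-aa DNA-binding module: a seven-residue core motif
# beginning W-R-K-Y (the "heptamer", canonically WRKYGQK) followed, a short
# linker downstream, by a C2H2 (C-X4-5-C-X22-23-H-X1-H) or C2HC
# (C-X5-7-C-X23-H-X1-C) zinc finger. Positions are 1-based.

DEFAULT_VARIANT_HEPTAMERS <- c("WSKY", "WVKY", "WRMC")

#' Scan a protein for WRKY heptamers
#'
#' Reports every match of the canonical consensus `W(R/K)(K/R)Y` as a
#' canonical-tier hit, and every exact four-mer match from a configurable
#' variant table (default WSKY, WVKY, WRMC) as a variant-tier hit. Each hit
#' carries the full 7-mer starting at the match; matches with fewer than
#' seven residues remaining are dropped.
#'
#' @param protein A single amino-acid string.
#' @param variant_table Character vector of accepted variant four-mers.
#' @return A tibble sorted by position: `start`, `core` (4 aa),
#'   `heptamer` (7 aa), `tier` (`"canonical"` or `"variant"`).
#' @export
scan_heptamers <- function(protein, variant_table = DEFAULT_VARIANT_HEPTAMERS) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein)) {
    abort("`protein` must be a single non-empty string")
  }
  n <- nchar(protein)
  canon <- str_locate_all(protein, "W[RK][KR]Y")[[1]]
  starts <- canon[, 1]
  tiers <- rep("canonical", length(starts))
  for (v in variant_table) {
    vs <- str_locate_all(protein, fixed(v))[[1]][, 1]
    vs <- setdiff(vs, starts)
    starts <- c(starts, vs)
    tiers <- c(tiers, rep("variant", length(vs)))
  }
  keep <- starts + 6L <= n
  starts <- starts[keep]
  tiers <- tiers[keep]
  ord <- order(starts)
  tibble(
    start = as.integer(starts[ord]),
    core = str_sub(protein, starts[ord], starts[ord] + 3L),
    heptamer = str_sub(protein, starts[ord], starts[ord] + 6L),
    tier = tiers[ord]
  )
}

# Admissible spacer combinations, shortest total length first.
ZF_PATTERNS <- local({
  c2h2 <- expand.grid(s1 = 4:5, s2 = 22:23)
  c2h2$type <- "C2H2"
  c2h2$last <- "H"
  c2hc <- expand.grid(s1 = 5:7, s2 = 23)
  c2hc$type <- "C2HC"
  c2hc$last <- "C"
  p <- rbind(c2h2, c2hc)
  p$len <- p$s1 + p$s2 + 5L   # C + s1 + C + s2 + H + X + H/C
  p[order(p$len, p$type), ]
})

#' Scan a protein for C2H2 / C2HC zinc fingers
#'
#' Finds all non-overlapping matches of the C2H2 (`C-X4-5-C-X22-23-H-X-H`)
#' and C2HC (`C-X5-7-C-X23-H-X-C`) patterns, scanning left to right and
#' trying shorter admissible spacers first (ties prefer C2H2); each match
#' consumes its span, so overlap resolution is deterministic.
#'
#' @param protein A single amino-acid string.
#' @param tail_offset Number of residues after the second cysteine skipped
#'   before the 3-aa "tail triplet" (the X-V-E-style window, e.g. HVE/KVE,
#'   used for cross-subgroup comparisons). Default 4, so the triplet is
#'   residues 5-7 after the second cysteine.
#' @return A tibble: `start`, `end`, `type`, `spacer1` (residues between the
#'   two cysteines), `signature` (first C through final H/C), `trailing`
#'   (residues after the second cysteine, before the final histidine) and
#'   `tail_triplet`.
#' @export
scan_zinc_fingers <- function(protein, tail_offset = 4L) {
  if (!is.character(protein) || length(protein) != 1L) {
    abort("`protein` must be a single string")
  }
  n <- nchar(protein)
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  hits <- list()
  pos <- 1L
  while (pos <= n - 30L) {
    if (res[pos] != "C") { pos <- pos + 1L; next }
    matched <- FALSE
    for (k in seq_len(nrow(ZF_PATTERNS))) {
      p <- ZF_PATTERNS[k, ]
      c2 <- pos + p$s1 + 1L
      h1 <- c2 + p$s2 + 1L
      last <- h1 + 2L
      if (last > n) next
      if (res[c2] == "C" && res[h1] == "H" && res[last] == p$last) {
        trailing <- paste(res[(c2 + 1L):(h1 - 1L)], collapse = "")
        tail3 <- if (nchar(trailing) >= tail_offset + 3L) {
          substr(trailing, tail_offset + 1L, tail_offset + 3L)
        } else {
          NA_character_
        }
        hits[[length(hits) + 1L]] <- tibble(
          start = pos, end = as.integer(last), type = p$type,
          spacer1 = as.integer(p$s1),
          signature = paste(res[pos:last], collapse = ""),
          trailing = trailing, tail_triplet = tail3
        )
        pos <- last + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) pos <- pos + 1L
  }
  if (length(hits) == 0L) {
    return(tibble(
      start = integer(), end = integer(), type = character(),
      spacer1 = integer(), signature = character(), trailing = character(),
      tail_triplet = character()
    ))
  }
  bind_rows(hits)
}

#' Assemble heptamer and zinc-finger hits into WRKY domains
#'
#' Pairs each heptamer, left to right, with the nearest unused zinc finger
#' starting within `linkage_window` residues downstream of the heptamer's
#' end; such pairs are complete domains. Unpaired canonical heptamers and
#' unpaired fingers are reported as incomplete domains. Variant-tier
#' heptamers require a confirming finger: unpaired variants are dropped
#' (tier gate). When a protein has two or more complete domains the first is
#' assigned terminal role `N` and the last `C`; a lone domain is `sole`.
#'
#' @param heptamers Tibble from [scan_heptamers()].
#' @param fingers Tibble from [scan_zinc_fingers()].
#' @param linkage_window Maximum residues between heptamer end and the
#'   finger's first cysteine (default 30).
#' @return A tibble, one row per domain, ordered along the protein:
#'   `domain_idx`, `complete`, `terminal_role`, heptamer fields
#'   (`hep_start`, `heptamer`, `tier`) and finger fields (`zf_start`,
#'   `zf_end`, `zf_type`, `spacer1`, `trailing`, `tail_triplet`).
#' @export
assemble_domains <- function(heptamers, fingers, linkage_window = 30L) {
  used <- rep(FALSE, nrow(fingers))
  pair <- rep(NA_integer_, nrow(heptamers))
  for (i in seq_len(nrow(heptamers))) {
    hep_end <- heptamers$start[i] + 6L
    gaps <- fingers$start - hep_end - 1L
    ok <- which(!used & gaps >= 0L & gaps <= linkage_window)
    if (length(ok) > 0L) {
      j <- ok[which.min(gaps[ok])]
      pair[i] <- j
      used[j] <- TRUE
    }
  }

  rows <- list()
  for (i in seq_len(nrow(heptamers))) {
    j <- pair[i]
    if (is.na(j) && heptamers$tier[i] == "variant") next  # tier gate
    rows[[length(rows) + 1L]] <- tibble(
      pos = heptamers$start[i],
      complete = !is.na(j),
      hep_start = heptamers$start[i],
      heptamer = heptamers$heptamer[i],
      tier = heptamers$tier[i],
      zf_start = if (!is.na(j)) fingers$start[j] else NA_integer_,
      zf_end = if (!is.na(j)) fingers$end[j] else NA_integer_,
      zf_type = if (!is.na(j)) fingers$type[j] else NA_character_,
      spacer1 = if (!is.na(j)) fingers$spacer1[j] else NA_integer_,
      trailing = if (!is.na(j)) fingers$trailing[j] else NA_character_,
      tail_triplet = if (!is.na(j)) fingers$tail_triplet[j] else NA_character_
    )
  }
  for (j in which(!used)) {
    rows[[length(rows) + 1L]] <- tibble(
      pos = fingers$start[j], complete = FALSE,
      hep_start = NA_integer_, heptamer = NA_character_, tier = NA_character_,
      zf_start = fingers$start[j], zf_end = fingers$end[j],
      zf_type = fingers$type[j], spacer1 = fingers$spacer1[j],
      trailing = fingers$trailing[j], tail_triplet = fingers$tail_triplet[j]
    )
  }
  if (length(rows) == 0L) {
    return(tibble(
      domain_idx = integer(), complete = logical(), terminal_role = character(),
      hep_start = integer(), heptamer = character(), tier = character(),
      zf_start = integer(), zf_end = integer(), zf_type = character(),
      spacer1 = integer(), trailing = character(), tail_triplet = character()
    ))
  }
  out <- bind_rows(rows) |> arrange(.data$pos)
  out$domain_idx <- seq_len(nrow(out))
  comp <- which(out$complete)
  out$terminal_role <- NA_character_
  if (length(comp) >= 2L) {
    out$terminal_role[comp[1]] <- "N"
    out$terminal_role[comp[length(comp)]] <- "C"
    if (length(comp) > 2L) out$terminal_role[comp[-c(1, length(comp))]] <- "internal"
  } else if (length(comp) == 1L) {
    out$terminal_role[comp] <- "sole"
  } else if (nrow(out) == 1L) {
    out$terminal_role <- "sole"
  }
  out |>
    select("domain_idx", "complete", "terminal_role", "hep_start", "heptamer",
           "tier", "zf_start", "zf_end", "zf_type", "spacer1", "trailing",
           "tail_triplet")
}

#' Read HMMER per-domain tabular output as an alternative hit source
#'
#' Parses a `hmmsearch --domtblout` file and returns envelope coordinates
#' per target, for pipelines that seed domain assembly from a profile
#' search instead of the built-in pattern scan. Only the identifier and
#' envelope columns are consumed; no scores are interpreted.
#'
#' @param path Path to a HMMER3 domain table (`--domtblout`).
#' @param max_evalue Optional independent-E-value cutoff applied to
#'   column 13 (default keeps everything).
#' @return A tibble: `protein_id`, `env_from`, `env_to`, `evalue`.
#' @export
read_hmmer_domtbl <- function(path, max_evalue = Inf) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(protein_id = character(), env_from = integer(),
                  env_to = integer(), evalue = numeric()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  short <- vapply(fields, length, integer(1)) < 21L
  if (any(short)) abort("malformed HMMER domain table: fewer than 21 columns")
  out <- tibble(
    protein_id = vapply(fields, `[`, character(1), 1L),
    env_from = as.integer(vapply(fields, `[`, character(1), 20L)),
    env_to = as.integer(vapply(fields, `[`, character(1), 21L)),
    evalue = as.numeric(vapply(fields, `[`, character(1), 13L))
  )
  out[out$evalue <= max_evalue, , drop = FALSE]
}

#' Scan a protein set for WRKY domains
#'
#' Convenience wrapper running [scan_heptamers()], [scan_zinc_fingers()] and
#' [assemble_domains()] over a protein tibble.
#'
#' @param proteins A tibble with columns `protein_id` and `protein`.
#' @param variant_table,linkage_window,tail_offset Passed through to the
#'   scanners.
#' @return A tibble of domains with a leading `protein_id` column; proteins
#'   without any reportable domain contribute no rows.
#' @export
scan_wrky_domains <- function(proteins, variant_table = DEFAULT_VARIANT_HEPTAMERS,
                              linkage_window = 30L, tail_offset = 4L) {
  stopifnot(all(c("protein_id", "protein") %in% names(proteins)))
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    doms <- assemble_domains(
      scan_heptamers(proteins$protein[i], variant_table),
      scan_zinc_fingers(proteins$protein[i], tail_offset),
      linkage_window
    )
    if (nrow(doms) == 0L) return(NULL)
    mutate(doms, protein_id = proteins$protein_id[i], .before = 1L)
  })
  bind_rows(out)
}
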