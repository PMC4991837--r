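# Synthetic cohorts with planted, machine-readable ground truth.
#
# The generator emulates the conditions of a genome-wide WRKY survey in a
# wild rice genome: ~100 family genes spread over 12 chromosomes, the
# empirical group histogram (group III largest, subgroup IIc next), three
# tandem-duplication clusters under 400 kb, PR/VQR introns planted inside
# domain-coding DNA, promoters carrying planted cis-element categories, and
# a four-tissue RPKM matrix with designated peak tissues. Background
# residues are drawn from an alphabet that cannot seed a heptamer or zinc
# finger, and promoter backgrounds are scrubbed of chance cis-element
# matches, so planted truth is recoverable exactly and recovery failures
# indicate real defects.

# Fixed most-frequent-codon style table for deterministic reverse
# translation. R is CGT (phase-2 split CG|T) and V is GTG.
CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTG"
)

reverse_translate <- function(protein) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(CODON_OF))
  if (length(bad) > 0L) abort(sprintf("cannot reverse-translate residue(s): %s",
                                      paste(bad, collapse = ", ")))
  paste(CODON_OF[res], collapse = "")
}

# A zinc finger with a planted V-Q-R triplet inside the second spacer, so
# intron plans always have a designated V (VQR type) and R (PR type)
# available inside the domain. Returns the string plus relative positions.
make_finger <- function(type = c("C2H2", "C2HC"), spacer1 = NULL, trailing7 = NULL) {
  type <- match.arg(type)
  if (type == "C2H2") {
    s1 <- spacer1 %||% 5L
    s2 <- 22L
    last <- "H"
  } else {
    s1 <- spacer1 %||% 6L
    s2 <- 23L
    last <- "C"
  }
  trailing7 <- trailing7 %||% rand_aa(7L)
  stopifnot(nchar(trailing7) == 7L)
  fill <- s2 - 10L  # trailing7 + VQR + fill = s2
  seq <- paste0("C", rand_aa(s1), "C", trailing7, "VQR", rand_aa(fill),
                "H", rand_aa(1L), last)
  list(
    seq = seq, type = type, spacer1 = s1,
    v_rel = s1 + 10L,   # V of the planted VQR, finger-relative (1-based)
    r_rel = s1 + 12L,   # R of the planted VQR
    len = nchar(seq)
  )
}

subgroup_trailing <- function(label) {
  switch(label,
    IIa = paste0("PVKKK", sample(c("L", "V"), 1L), "Q"),
    IIb = "PVRKQVQ",
    IId = "PARKHVE",
    IIe = paste0("PARK", sample(c("Q", "M"), 1L), "V", sample(c("E", "D"), 1L)),
    IIc = paste0(rand_aa(4L), "KVE"),
    NULL
  )
}

finger_for_label <- function(label) {
  switch(label,
    IIa = make_finger("C2H2", 5L, subgroup_trailing("IIa")),
    IIb = make_finger("C2H2", 5L, subgroup_trailing("IIb")),
    IIc = make_finger("C2H2", 4L, subgroup_trailing("IIc")),
    IId = make_finger("C2H2", 5L, subgroup_trailing("IId")),
    IIe = make_finger("C2H2", 5L, subgroup_trailing("IIe")),
    III = make_finger("C2HC", 6L),
    abort(sprintf("no single-domain finger for label %s", label))
  )
}

# One WRKY domain (heptamer + linker + finger) with positions relative to
# the domain start.
make_domain <- function(finger, heptamer = "WRKYGQK", linker_len = 6L) {
  seq <- paste0(heptamer, rand_aa(linker_len), finger$seq)
  zf_off <- nchar(heptamer) + linker_len
  list(
    seq = seq, heptamer = heptamer, finger = finger,
    hep_rel = 1L, zf_rel = zf_off + 1L,
    v_rel = zf_off + finger$v_rel, r_rel = zf_off + finger$r_rel,
    zf_end_rel = zf_off + finger$len
  )
}

#' Generate a synthetic WRKY protein of a known group
#'
#' Builds random flanks around one or two planted WRKY domains whose zinc
#' finger carries the requested subgroup's spacer and signature. Group I
#' labels get two domains (Ia C2H2, Ib C2HC); group IV gets a deliberately
#' broken domain. Flanks and spacers are drawn from an alphabet without C,
#' H or W, so no spurious heptamers or fingers can arise.
#'
#' @param label Group label in `Ia, Ib, IIa, IIb, IIc, IId, IIe, III, IV`.
#' @param seed Optional integer seed (sets the RNG for this protein only).
#' @param heptamer Heptamer to plant (default the canonical `WRKYGQK`; a
#'   variant such as `WRMCGQK` exercises the variant tier).
#' @param iv_mode For label IV: `"hep_only"` (heptamer without finger),
#'   `"broken_finger"` (heptamer plus truncated finger) or
#'   `"finger_only"` (intact finger without heptamer, yielding a secondary
#'   label).
#' @param iv_secondary Subgroup of the intact finger for
#'   `iv_mode = "finger_only"`.
#' @return A list: `protein`, `label`, `secondary`, `tier`, and `domains`
#'   (tibble of absolute residue coordinates: `hep_start`, `zf_start`,
#'   `zf_end`, `zf_type`, `pr_residue`, `vqr_residue`, `role`).
#' @export
gen_protein <- function(label, seed = NULL, heptamer = "WRKYGQK",
                        iv_mode = c("finger_only", "hep_only", "broken_finger"),
                        iv_secondary = "IIc") {
  if (!label %in% WRKY_LABELS) abort(sprintf("unknown label: %s", label))
  if (!is.null(seed)) set.seed(seed)
  iv_mode <- match.arg(iv_mode)
  tier <- if (grepl("^W[RK][KR]Y", heptamer)) "canonical" else "variant"

  place <- function(parts) {
    # parts: list of domain objects or plain strings; compute absolute coords
    offset <- 0L
    seqs <- character()
    doms <- list()
    for (p in parts) {
      if (is.character(p)) {
        seqs <- c(seqs, p)
        offset <- offset + nchar(p)
      } else {
        doms[[length(doms) + 1L]] <- tibble(
          hep_start = if (is.na(p$hep_rel)) NA_integer_ else offset + p$hep_rel,
          zf_start = if (is.na(p$zf_rel)) NA_integer_ else offset + p$zf_rel,
          zf_end = if (is.na(p$zf_rel)) NA_integer_ else offset + p$zf_end_rel,
          zf_type = p$finger$type %||% NA_character_,
          pr_residue = if (is.na(p$zf_rel)) NA_integer_ else offset + p$r_rel,
          vqr_residue = if (is.na(p$zf_rel)) NA_integer_ else offset + p$v_rel
        )
        seqs <- c(seqs, p$seq)
        offset <- offset + nchar(p$seq)
      }
    }
    list(protein = paste(seqs, collapse = ""), domains = bind_rows(doms))
  }

  secondary <- NA_character_
  if (label %in% c("Ia", "Ib")) {
    ftype <- if (label == "Ia") "C2H2" else "C2HC"
    dN <- make_domain(make_finger(ftype, trailing7 = rand_aa(7L)), heptamer)
    dC <- make_domain(make_finger(ftype, trailing7 = paste0(rand_aa(4L), "HVE")), heptamer)
    built <- place(list(rand_aa(sample(20:40, 1L)), dN,
                        rand_aa(sample(30:60, 1L)), dC,
                        rand_aa(sample(30:60, 1L))))
    built$domains$role <- c("N", "C")
  } else if (label %in% c("IIa", "IIb", "IIc", "IId", "IIe", "III")) {
    d <- make_domain(finger_for_label(label), heptamer)
    built <- place(list(rand_aa(sample(20:40, 1L)), d, rand_aa(sample(30:60, 1L))))
    built$domains$role <- "sole"
  } else {  # IV
    if (iv_mode == "hep_only") {
      built <- place(list(rand_aa(sample(20:40, 1L)), heptamer,
                          rand_aa(sample(30:60, 1L))))
      built$domains <- tibble(
        hep_start = NA_integer_, zf_start = NA_integer_, zf_end = NA_integer_,
        zf_type = NA_character_, pr_residue = NA_integer_,
        vqr_residue = NA_integer_, role = "sole"
      )
    } else if (iv_mode == "broken_finger") {
      stub <- paste0("C", rand_aa(5L), "C", rand_aa(8L))  # never completed
      built <- place(list(rand_aa(sample(20:40, 1L)), heptamer, rand_aa(6L),
                          stub, rand_aa(sample(30:60, 1L))))
      built$domains <- tibble(
        hep_start = NA_integer_, zf_start = NA_integer_, zf_end = NA_integer_,
        zf_type = NA_character_, pr_residue = NA_integer_,
        vqr_residue = NA_integer_, role = "sole"
      )
    } else {  # finger_only: intact finger, no heptamer
      f <- finger_for_label(iv_secondary)
      d <- list(seq = f$seq, finger = f, hep_rel = NA_integer_, zf_rel = 1L,
                v_rel = f$v_rel, r_rel = f$r_rel, zf_end_rel = f$len)
      built <- place(list(rand_aa(sample(20:40, 1L)), d, rand_aa(sample(30:60, 1L))))
      built$domains$role <- "sole"
      secondary <- if (iv_secondary == "III") "III" else iv_secondary
    }
  }
  list(protein = built$protein, label = label, secondary = secondary,
       tier = tier, domains = built$domains)
}

#' Generate a gene locus realizing an intron plan
#'
#' Reverse translates a protein with a fixed codon table, appends a stop
#' codon, and inserts introns at the planned coding offsets. PR plans split
#' the codon of the designated arginine at the requested phase (default 2);
#' VQR plans insert a phase-0 intron immediately before the designated
#' valine codon; `none` plans take an explicit residue and phase.
#'
#' @param protein Amino-acid string (no stop).
#' @param introns Tibble of plans: `residue` (1-based), `phase`, `type`
#'   (`PR`, `VQR`, `none`). May be empty.
#' @param intron_len_range Intron lengths are drawn uniformly from this
#'   range (GT...AG ends, unvalidated spacer).
#' @return A list: `gene_seq` (coding strand), `exons` (tibble of 1-based
#'   intervals relative to the gene), `truth` (tibble `coding_offset`,
#'   `phase`, `type`, `residue`), `cds_len`.
#' @export
gen_locus <- function(protein, introns = NULL, intron_len_range = c(60L, 120L)) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  cds <- paste0(reverse_translate(protein), "TAA")
  cds_len <- nchar(cds)
  if (is.null(introns) || nrow(introns) == 0L) {
    return(list(
      gene_seq = cds,
      exons = tibble(start = 1L, end = cds_len),
      truth = tibble(coding_offset = integer(), phase = integer(),
                     type = character(), residue = integer()),
      cds_len = cds_len
    ))
  }
  plan <- introns
  plan$phase <- as.integer(plan$phase)
  offs <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    r <- plan$residue[i]
    if (r < 1L || r > length(res)) abort("intron plan residue outside protein")
    if (plan$type[i] == "PR") {
      if (res[r] != "R") abort(sprintf("PR intron planned at residue %d, which is %s not R", r, res[r]))
      if (!plan$phase[i] %in% c(1L, 2L)) abort("PR introns must be phase 1 or 2")
      offs[i] <- (r - 1L) * 3L + plan$phase[i]
    } else if (plan$type[i] == "VQR") {
      if (res[r] != "V") abort(sprintf("VQR intron planned at residue %d, which is %s not V", r, res[r]))
      plan$phase[i] <- 0L
      offs[i] <- (r - 1L) * 3L
    } else {
      offs[i] <- (r - 1L) * 3L + plan$phase[i]
    }
  }
  if (anyDuplicated(offs)) abort("duplicate intron coding offsets in plan")
  if (any(offs <= 0L) || any(offs >= cds_len - 3L)) {
    abort("intron offsets must fall strictly inside the coding sequence")
  }
  ord <- order(offs)
  plan <- plan[ord, , drop = FALSE]
  offs <- offs[ord]

  pieces <- character()
  exon_lens <- integer()
  intron_lens <- integer()
  prev <- 0L
  for (i in seq_along(offs)) {
    exon_lens <- c(exon_lens, offs[i] - prev)
    pieces <- c(pieces, substr(cds, prev + 1L, offs[i]))
    ilen <- sample(seq(intron_len_range[1], intron_len_range[2]), 1L)
    intron_lens <- c(intron_lens, ilen)
    pieces <- c(pieces, paste0("GT", rand_dna(ilen - 4L), "AG"))
    prev <- offs[i]
  }
  exon_lens <- c(exon_lens, cds_len - prev)
  pieces <- c(pieces, substr(cds, prev + 1L, cds_len))

  starts <- integer()
  pos <- 1L
  for (i in seq_along(exon_lens)) {
    starts <- c(starts, pos)
    pos <- pos + exon_lens[i]
    if (i <= length(intron_lens)) pos <- pos + intron_lens[i]
  }
  list(
    gene_seq = paste(pieces, collapse = ""),
    exons = tibble(start = starts, end = starts + exon_lens - 1L),
    truth = tibble(coding_offset = offs, phase = offs %% 3L,
                   type = plan$type, residue = plan$residue),
    cds_len = cds_len
  )
}

# ---- promoter planting ----------------------------------------------------

expand_iupac_pick <- function(consensus) {
  codes <- list(R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"),
                M = c("A", "C"), S = c("C", "G"), W = c("A", "T"))
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    if (ch %in% names(codes)) sample(codes[[ch]], 1L) else ch
  }, character(1)), collapse = "")
}

# Background free of chance element matches: resample hit spans until the
# scan comes back empty, then fall back to neutral A-runs.
clean_promoter_background <- function(len, table, max_iter = 25L) {
  seq <- rand_dna(len)
  for (it in seq_len(max_iter)) {
    hits <- scan_cis_elements(tibble(gene_id = "bg", promoter = seq), table)
    if (nrow(hits) == 0L) return(seq)
    for (i in seq_len(nrow(hits))) {
      w <- nchar(table$consensus[table$class == hits$class[i]][1])
      repl <- if (it < max_iter) rand_dna(w) else strrep("A", w)
      substr(seq, hits$start[i], hits$start[i] + w - 1L) <- repl
    }
  }
  seq
}

PROMOTER_CATEGORY_PLANS <- list(
  `1` = c("SARE"),
  `2` = c("SARE", "ABRE", "ABRE"),
  `3` = c("SARE", "DRE"),
  `4` = c("SARE", "ABRE", "CE1", "DRE"),
  `5` = c("SARE", "ABRE", "CE3", "DRE", "WBOX"),
  `6` = c("ABRE")   # a lone, uncoupled ABRE confers nothing
)

# Plant the elements of one category plan into a clean background; verify
# the scan recovers exactly the planted per-class counts, retrying with a
# fresh background if a junction artefact appears.
gen_promoter <- function(category, len, table, max_attempts = 10L) {
  plan <- PROMOTER_CATEGORY_PLANS[[as.character(category)]]
  for (attempt in seq_len(max_attempts)) {
    seq <- clean_promoter_background(len, table)
    offs <- integer(0)
    slots <- seq(50L, len - 60L, by = 40L)
    pos <- sample(slots, length(plan))
    for (i in seq_along(plan)) {
      inst <- expand_iupac_pick(table$consensus[table$class == plan[i]][1])
      substr(seq, pos[i], pos[i] + nchar(inst) - 1L) <- inst
      offs <- c(offs, pos[i])
    }
    got <- scan_cis_elements(tibble(gene_id = "p", promoter = seq), table) |>
      count(.data$class)
    want <- tibble(class = plan) |> count(.data$class)
    ok <- nrow(got) == nrow(want) &&
      all(sort(got$class) == sort(want$class)) &&
      all(got$n[order(got$class)] == want$n[order(want$class)])
    if (ok) {
      return(list(seq = seq,
                  elements = tibble(class = plan, start = pos)))
    }
  }
  abort("could not realize promoter plan without scan artefacts")
}

# ---- expression -----------------------------------------------------------

gen_expression <- function(gene_ids, peak_tissues, expressed, params) {
  tissues <- names(params$tissue_scale)
  n <- length(gene_ids)
  # Expressed genes draw a base level in a range that keeps the baseline
  # tissue (lowest scale) below the 50-RPKM convention for every gene while
  # commonly exceeding the smaller candidate cutoffs, as in the survey the
  # generator emulates; sub-threshold genes sit well below the cutoff in
  # every tissue.
  base <- ifelse(
    expressed,
    pmin(pmax(stats::rlnorm(n, log(80), params$base_sdlog), 40), 140),
    pmin(pmax(stats::rlnorm(n, log(2), params$base_sdlog), 0.5), 6)
  )
  noise <- function(n) exp(params$noise_sd * pmin(pmax(rnorm(n), -1), 1))
  vals <- sapply(tissues, function(t) base * params$tissue_scale[[t]] * noise(n))
  vals <- matrix(vals, nrow = n, dimnames = list(NULL, tissues))
  max_scale <- max(unlist(params$tissue_scale))
  for (i in seq_len(n)) {
    vals[i, peak_tissues[i]] <- base[i] * max_scale * params$peak_effect * noise(1L)
  }
  bind_cols(tibble(gene_id = gene_ids), as_tibble(round(vals, 3)))
}

# ---- cohort ---------------------------------------------------------------

#' Default cohort configuration
#'
#' The defaults mirror the conditions of the rice-family survey the
#' generator emulates: 97 genes with the empirical group histogram (group
#' III largest at 28, subgroup IIc 22, Ia and IIe 11 each, IIb and IId 7,
#' IIa 4, Ib 2, IV 5), 12 chromosomes, three tandem clusters (6, 4 and 7
#' genes spanning roughly 308, 220 and 199 kb), a 1500-bp promoter window,
#' and a four-tissue expression matrix whose panicle tissue is globally
#' lowest and root highest.
#'
#' @param ... Overrides for any configuration entry.
#' @return A named list of generator parameters.
#' @export
cohort_config <- function(...) {
  config <- list(
    groups = c(Ia = 11L, Ib = 2L, IIa = 4L, IIb = 7L, IIc = 22L, IId = 7L,
               IIe = 11L, III = 28L, IV = 5L),
    n_genes = NULL,          # scale `groups` proportionally when set
    n_chrom = 12L,
    clusters = tibble(
      seqid = c("Chr01", "Chr05", "Chr11"),
      n = c(6L, 4L, 7L),
      span = c(308000L, 220000L, 199000L)
    ),
    gap_bp = 420000L,        # scattered genes sit farther apart than max_span
    promoter_len = 1500L,
    category_mix = c(`1` = 0.30, `2` = 0.06, `3` = 0.28, `4` = 0.04,
                     `5` = 0.01, `6` = 0.31),
    n_variant_heptamer = 2L,
    n_alt_transcripts = 5L,
    pr_fraction = 0.9,       # single-domain non-IIa/IIb genes with a PR intron
    extra_intron_prob = 0.5, # chance of one extra phase-0 intron outside domain
    tissue_scale = list(root = 2.0, shoot = 1.2, flag_leaf = 1.0, panicle = 0.25),
    peak_probs = c(root = 0.4, shoot = 0.25, flag_leaf = 0.25, panicle = 0.1),
    peak_effect = 2.5,
    expressed_frac = 0.35,
    base_sdlog = 0.5,
    noise_sd = 0.3
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown cohort_config field(s): %s", paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) config[[nm]] <- overrides[[nm]]
  config
}

#' Generate a full synthetic cohort with ground truth
#'
#' Produces a genome, gene models, proteins, promoters, an expression
#' matrix and an orthologue map, together with truth tables for every
#' planted feature. Regeneration from the same `(seed, config)` is
#' identical.
#'
#' @param config A configuration list ([cohort_config()]).
#' @param seed Integer seed.
#' @return A list: `genome`, `models`, `proteins`, `expression`,
#'   `ortho_map`, `promoters`, and `truth` (list of tibbles: `genes`,
#'   `domains`, `introns`, `clusters`, `elements`), plus `config` and
#'   `seed`.
#' @export
gen_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  groups <- config$groups
  if (!is.null(config$n_genes)) {
    scaled <- round(groups / sum(groups) * config$n_genes)
    scaled[1] <- scaled[1] + (config$n_genes - sum(scaled))
    groups <- scaled
  }
  n_genes <- sum(groups)
  labels <- sample(rep(names(groups), groups))   # shuffled planting order

  chroms <- sprintf("Chr%02d", seq_len(config$n_chrom))
  clusters <- config$clusters
  if (any(!clusters$seqid %in% chroms)) abort("cluster plan names unknown chromosome")
  if (sum(clusters$n) + 1L > n_genes) abort("cluster plan exceeds cohort size")
  if (any(clusters$span > 400000L)) {
    warn("cluster plan spans exceed 400 kb; planted clusters may not be detectable")
  }

  # Assign genes to chromosomes: cluster slots first (preferring group III
  # members, mirroring the group-III-dominated tandem arrays), the rest
  # round-robin across chromosomes.
  gene_ids <- sprintf("SYNG%03d", seq_len(n_genes))
  assign_chrom <- rep(NA_character_, n_genes)
  in_cluster <- rep(NA_character_, n_genes)
  iii_first <- order(labels != "III")  # group III genes first, stable
  cursor <- 1L
  for (ci in seq_len(nrow(clusters))) {
    take <- iii_first[cursor:(cursor + clusters$n[ci] - 1L)]
    assign_chrom[take] <- clusters$seqid[ci]
    in_cluster[take] <- sprintf("plan_%d", ci)
    cursor <- cursor + clusters$n[ci]
  }
  rest <- which(is.na(assign_chrom))
  assign_chrom[rest] <- rep(chroms, length.out = length(rest))

  # Per-gene plans.
  variant_pool <- which(labels == "IIc")
  variant_idx <- head(variant_pool, config$n_variant_heptamer)
  variant_heps <- c("WRMCGQK", "WKKYGQK", "WSKYEQK")
  iv_modes <- c("finger_only", "finger_only", "finger_only", "hep_only", "broken_finger")
  iv_secondaries <- c("IIb", "IIc", "III")
  categories <- sample(as.integer(names(config$category_mix)), n_genes,
                       replace = TRUE, prob = config$category_mix)
  peak_tissues <- sample(names(config$peak_probs), n_genes, replace = TRUE,
                         prob = config$peak_probs)
  expressed <- runif(n_genes) < config$expressed_frac
  # The baseline tissue stays below the expression threshold for every
  # gene: genes peaking in the lowest-scaled tissue are kept sub-threshold,
  # so expressed genes re-draw their peak from the other tissues.
  low_tissue <- names(which.min(unlist(config$tissue_scale)))
  redraw <- expressed & peak_tissues == low_tissue
  if (any(redraw)) {
    others <- setdiff(names(config$peak_probs), low_tissue)
    peak_tissues[redraw] <- sample(others, sum(redraw), replace = TRUE,
                                   prob = config$peak_probs[others])
  }
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)

  element_table <- cis_element_table()

  proteins <- vector("list", n_genes)
  loci <- vector("list", n_genes)
  promoters <- vector("list", n_genes)
  iv_counter <- 0L
  for (i in seq_len(n_genes)) {
    lab <- labels[i]
    hep <- "WRKYGQK"
    if (i %in% variant_idx) hep <- variant_heps[match(i, variant_idx)]
    if (lab == "IV") {
      iv_counter <- iv_counter + 1L
      mode <- iv_modes[(iv_counter - 1L) %% length(iv_modes) + 1L]
      secondary <- iv_secondaries[(iv_counter - 1L) %% length(iv_secondaries) + 1L]
      p <- gen_protein(lab, heptamer = hep, iv_mode = mode, iv_secondary = secondary)
    } else {
      p <- gen_protein(lab, heptamer = hep)
    }
    proteins[[i]] <- p

    # Intron plan: VQR for IIa/IIb; PR (mostly phase 2) for the other
    # domain-bearing groups; Ia only in the C-terminal domain, Ib in both.
    plans <- list()
    doms <- p$domains
    if (lab %in% c("IIa", "IIb")) {
      plans[[1]] <- tibble(residue = doms$vqr_residue[1], phase = 0L, type = "VQR")
    } else if (lab %in% c("IIc", "IId", "IIe", "III")) {
      if (runif(1) < config$pr_fraction) {
        ph <- if (runif(1) < 0.95) 2L else 1L
        plans[[1]] <- tibble(residue = doms$pr_residue[1], phase = ph, type = "PR")
      }
    } else if (lab == "Ia") {
      cdom <- which(doms$role == "C")
      plans[[1]] <- tibble(residue = doms$pr_residue[cdom], phase = 2L, type = "PR")
    } else if (lab == "Ib") {
      plans[[1]] <- tibble(residue = doms$pr_residue[doms$role == "N"], phase = 2L, type = "PR")
      plans[[2]] <- tibble(residue = doms$pr_residue[doms$role == "C"], phase = 2L, type = "PR")
    }
    if (runif(1) < config$extra_intron_prob) {
      # a neutral phase-0 intron in the N-terminal flank, outside any domain
      first_dom <- suppressWarnings(min(c(doms$hep_start, doms$zf_start), na.rm = TRUE))
      if (!is.finite(first_dom)) first_dom <- 15L
      r <- max(2L, min(10L, first_dom - 5L))
      plans[[length(plans) + 1L]] <- tibble(residue = r, phase = 0L, type = "none")
    }
    plan_tbl <- if (length(plans)) bind_rows(plans) else NULL
    loci[[i]] <- gen_locus(p$protein, plan_tbl)
    promoters[[i]] <- gen_promoter(categories[i], config$promoter_len, element_table)
  }

  # Chromosome assembly. Cluster members are laid out with small
  # intra-cluster gaps realizing the planned span; everything else is
  # separated by `gap_bp`, which exceeds the cluster span threshold.
  seqs <- setNames(rep("", config$n_chrom), chroms)
  model_rows <- list()
  gene_coord <- tibble(gene_id = gene_ids, seqid = assign_chrom,
                       start = NA_integer_, end = NA_integer_, strand = strands)
  cluster_truth <- list()

  for (chrom in chroms) {
    members <- which(assign_chrom == chrom)
    parts <- character()
    pos <- 0L
    place_gene <- function(i, gap) {
      gene_seq <- loci[[i]]$gene_seq
      prom <- promoters[[i]]$seq
      if (strands[i] == "+") {
        block <- paste0(strrep("A", gap), prom, gene_seq)
        gstart <- pos + gap + nchar(prom) + 1L
        gend <- gstart + nchar(gene_seq) - 1L
      } else {
        block <- paste0(strrep("A", gap), revcomp(gene_seq), revcomp(prom))
        gstart <- pos + gap + 1L
        gend <- gstart + nchar(gene_seq) - 1L
      }
      parts[[length(parts) + 1L]] <<- block
      pos <<- pos + nchar(block)
      c(gstart, gend)
    }
    ci_here <- unique(stats::na.omit(in_cluster[members]))
    for (ci in ci_here) {
      cmem <- members[!is.na(in_cluster[members]) & in_cluster[members] == ci]
      plan <- clusters[match(ci, sprintf("plan_%d", seq_len(nrow(clusters)))), ]
      glens <- vapply(cmem, function(i) nchar(loci[[i]]$gene_seq), integer(1))
      budget <- plan$span - sum(glens)
      intra <- max(config$promoter_len + 200L,
                   as.integer(floor(budget / max(1L, length(cmem) - 1L))) -
                     config$promoter_len)
      coords <- matrix(0L, length(cmem), 2L)
      for (k in seq_along(cmem)) {
        gap <- if (k == 1L) config$gap_bp else intra
        coords[k, ] <- place_gene(cmem[k], gap)
      }
      gene_coord$start[cmem] <- coords[, 1]
      gene_coord$end[cmem] <- coords[, 2]
      cluster_truth[[length(cluster_truth) + 1L]] <- tibble(
        plan_id = ci, seqid = chrom,
        members = list(gene_ids[cmem]),
        span_bp = max(coords[, 2]) - min(coords[, 1]) + 1L
      )
    }
    for (i in members[is.na(in_cluster[members])]) {
      coords <- place_gene(i, config$gap_bp)
      gene_coord$start[i] <- coords[1]
      gene_coord$end[i] <- coords[2]
    }
    seqs[[chrom]] <- paste0(paste(parts, collapse = ""), strrep("A", 2000L))
  }

  bad_span <- vapply(cluster_truth, function(ct) ct$span_bp > 400000L, logical(1))
  if (any(bad_span)) abort("realized cluster span exceeds 400 kb; reduce plan span")

  # Transcript models (translation-order intervals; minus strand mirrored).
  for (i in seq_len(n_genes)) {
    exons_rel <- loci[[i]]$exons
    gs <- gene_coord$start[i]
    ge <- gene_coord$end[i]
    if (strands[i] == "+") {
      ex <- tibble(start = gs + exons_rel$start - 1L, end = gs + exons_rel$end - 1L)
      ex <- ex[order(ex$start), ]
    } else {
      ex <- tibble(start = ge - exons_rel$end + 1L, end = ge - exons_rel$start + 1L)
      ex <- ex[order(ex$start, decreasing = TRUE), ]
    }
    tid <- paste0(gene_ids[i], ".t1")
    model_rows[[length(model_rows) + 1L]] <- tibble(
      gene_id = gene_ids[i], transcript_id = tid,
      protein_id = paste0(tid, ".p"),
      seqid = assign_chrom[i], strand = strands[i],
      gene_start = gs, gene_end = ge,
      exons = list(as.data.frame(ex)), cds = list(as.data.frame(ex)),
      partial = FALSE
    )
  }

  # Alternative (shorter) transcripts for isoform selection.
  alt_pool <- which(vapply(loci, function(l) nrow(l$exons) == 1L, logical(1)))
  alt_idx <- head(alt_pool, config$n_alt_transcripts)
  for (i in alt_idx) {
    gs <- gene_coord$start[i]
    ge <- gene_coord$end[i]
    keep_nt <- (floor((loci[[i]]$cds_len / 3L) * 0.6)) * 3L
    iv <- if (strands[i] == "+") {
      tibble(start = gs, end = gs + keep_nt - 1L)
    } else {
      tibble(start = ge - keep_nt + 1L, end = ge)
    }
    tid <- paste0(gene_ids[i], ".t2")
    model_rows[[length(model_rows) + 1L]] <- tibble(
      gene_id = gene_ids[i], transcript_id = tid,
      protein_id = paste0(tid, ".p"),
      seqid = assign_chrom[i], strand = strands[i],
      gene_start = gs, gene_end = ge,
      exons = list(as.data.frame(iv)), cds = list(as.data.frame(iv)),
      partial = FALSE
    )
  }
  models <- bind_rows(model_rows) |> arrange(.data$seqid, .data$gene_start,
                                             .data$transcript_id)
  genome <- new_genome(seqs)

  # Orthologue names: cluster members get stable WRKY-style names.
  ortho_map <- tibble(gene_id = gene_ids,
                      ortho_name = sprintf("WRKY%d", seq_len(n_genes)))

  expression <- gen_expression(gene_ids, peak_tissues, expressed, config)

  prot_tbl <- tibble(
    gene_id = gene_ids,
    transcript_id = paste0(gene_ids, ".t1"),
    protein_id = paste0(gene_ids, ".t1.p"),
    protein = vapply(proteins, function(p) p$protein, character(1)),
    n_aa = vapply(proteins, function(p) nchar(p$protein), integer(1))
  )

  truth_genes <- tibble(
    gene_id = gene_ids,
    transcript_id = paste0(gene_ids, ".t1"),
    protein_id = paste0(gene_ids, ".t1.p"),
    label = labels,
    secondary = vapply(proteins, function(p) p$secondary, character(1)),
    tier = vapply(proteins, function(p) p$tier, character(1)),
    seqid = assign_chrom,
    strand = strands,
    start = gene_coord$start,
    end = gene_coord$end,
    cluster_plan = in_cluster,
    category = categories,
    peak_tissue = peak_tissues,
    expressed = expressed,
    n_exons = vapply(loci, function(l) nrow(l$exons), integer(1))
  )
  truth_domains <- bind_rows(lapply(seq_len(n_genes), function(i) {
    d <- proteins[[i]]$domains
    d$gene_id <- gene_ids[i]
    d$protein_id <- paste0(gene_ids[i], ".t1.p")
    d
  }))
  truth_introns <- bind_rows(lapply(seq_len(n_genes), function(i) {
    t <- loci[[i]]$truth
    if (nrow(t) == 0L) return(NULL)
    t$gene_id <- gene_ids[i]
    t$transcript_id <- paste0(gene_ids[i], ".t1")
    t
  }))
  truth_elements <- bind_rows(lapply(seq_len(n_genes), function(i) {
    e <- promoters[[i]]$elements
    e$gene_id <- gene_ids[i]
    e
  }))
  truth_clusters <- bind_rows(cluster_truth)

  list(
    genome = genome,
    models = models,
    proteins = prot_tbl,
    expression = expression,
    ortho_map = ortho_map,
    promoters = tibble(
      gene_id = gene_ids,
      promoter = vapply(promoters, function(p) p$seq, character(1))
    ),
    truth = list(
      genes = truth_genes, domains = truth_domains, introns = truth_introns,
      elements = truth_elements, clusters = truth_clusters
    ),
    config = config, seed = seed
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits the same formats the pipeline consumes: genome FASTA, GFF3,
#' protein FASTA, expression TSV, orthologue-map TSV, plus the truth tables
#' as JSON.
#'
#' @param cohort A cohort from [gen_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome_fasta(cohort$genome, file.path(dir, "genome.fasta"))
  write_gff3(cohort$models, file.path(dir, "annotation.gff3"))
  write_protein_fasta(cohort$proteins, file.path(dir, "proteins.fasta"))
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$ortho_map, file.path(dir, "ortho_map.tsv"))
  jsonlite::write_json(
    lapply(cohort$truth, function(t) t),
    file.path(dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Generate a two-clade test alignment
#'
#' Two strongly divergent clades derived from one random backbone: clade B
#' differs from clade A at `n_diff` fixed columns, and each row carries a
#' few private substitutions. Used to exercise bootstrap support for a
#' planted bipartition.
#'
#' @param n_per_clade Sequences per clade.
#' @param len Alignment length (columns).
#' @param n_diff Number of fixed between-clade differences.
#' @param n_private Private substitutions per sequence.
#' @param seed Integer seed.
#' @return A list: `alignment` (a `wrky_alignment`) and `clades` (named
#'   vector mapping row id to `"A"`/`"B"`).
#' @export
gen_clade_alignment <- function(n_per_clade = 6L, len = 120L, n_diff = 40L,
                                n_private = 2L, seed = 1L) {
  set.seed(seed)
  backbone <- strsplit(rand_aa(len, AA20), "", fixed = TRUE)[[1]]
  altered <- backbone
  diff_cols <- sample(len, n_diff)
  for (j in diff_cols) altered[j] <- sample(setdiff(AA20, altered[j]), 1L)
  mutate_row <- function(base) {
    cols <- sample(len, n_private)
    for (j in cols) base[j] <- sample(setdiff(AA20, base[j]), 1L)
    paste(base, collapse = "")
  }
  rows <- c(
    setNames(vapply(seq_len(n_per_clade), function(i) mutate_row(backbone),
                    character(1)), sprintf("A%02d", seq_len(n_per_clade))),
    setNames(vapply(seq_len(n_per_clade), function(i) mutate_row(altered),
                    character(1)), sprintf("B%02d", seq_len(n_per_clade)))
  )
  list(
    alignment = as_alignment(rows),
    clades = setNames(rep(c("A", "B"), each = n_per_clade), names(rows))
  )
}
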