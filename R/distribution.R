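# Chromosomal distribution: counts, density, tandem-duplication clusters,
# cross-genome cluster comparison via orthologue names.

#' Family gene counts per chromosome
#'
#' @param genes Tibble with a `seqid` column (one row per gene).
#' @param genome Optional `wrky_genome`; when given, chromosomes without
#'   family genes are listed with a zero count.
#' @return A tibble: `seqid`, `n`.
#' @export
chromosome_counts <- function(genes, genome = NULL) {
  counts <- genes |> count(.data$seqid)
  if (!is.null(genome)) {
    counts <- tibble(seqid = names(genome)) |>
      left_join(counts, by = "seqid") |>
      mutate(n = replace_na(.data$n, 0L))
  }
  counts
}

#' Gene density per chromosome
#'
#' Density is defined as gene number per million base pairs.
#'
#' @param counts Tibble from [chromosome_counts()].
#' @param lengths Tibble with `seqid` and `length_bp` ([genome_lengths()]).
#' @return `counts` with `length_bp` and `per_mbp` columns added.
#' @export
gene_density <- function(counts, lengths) {
  missing <- setdiff(counts$seqid, lengths$seqid)
  if (length(missing) > 0L) {
    abort(sprintf("no length for chromosome(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(lengths$length_bp <= 0)) abort("chromosome lengths must be positive")
  counts |>
    left_join(lengths, by = "seqid") |>
    mutate(per_mbp = .data$n / (.data$length_bp / 1e6))
}

#' Detect tandem-duplication gene clusters
#'
#' A cluster is a maximal run of consecutive family genes on one chromosome
#' whose first-to-last span (gene start of the first member to gene end of
#' the last) does not exceed `max_span` and whose size is at least
#' `min_genes`; runs are maximal in the sense that extending them either
#' way violates the span bound. Every maximal qualifying run is reported
#' exactly once.
#'
#' @param genes Tibble with `gene_id`, `seqid`, `start`, `end` and
#'   optionally `label` (group assignment, used for the composition and
#'   the tandem-duplicate flag).
#' @param max_span Maximum cluster span in bp (default 400000).
#' @param min_genes Minimum member count (default 4).
#' @return A tibble, one row per cluster: `cluster_id`, `seqid`,
#'   `n_genes`, `start`, `end`, `span_bp`, `members` (list of gene ids in
#'   chromosomal order), `composition` (list tibble of per-label counts,
#'   when labels are available) and `tandem` (list of member flags: member
#'   shares its group label with another member).
#' @export
detect_clusters <- function(genes, max_span = 400000L, min_genes = 4L) {
  assert_scalar_number(max_span, "max_span")
  assert_scalar_number(min_genes, "min_genes")
  out <- list()
  for (chrom in unique(genes$seqid)) {
    sub <- genes |> filter(.data$seqid == chrom) |> arrange(.data$start, .data$gene_id)
    n <- nrow(sub)
    if (n < min_genes) next
    ends <- cummax(sub$end)
    # Two-pointer sweep: jmax(i) = largest j with span(i, j) <= max_span.
    # jmax is non-decreasing in i, so a window [i, jmax(i)] is maximal on
    # the left iff i == 1 or jmax(i-1) < jmax(i).
    span <- function(i, j) max(sub$end[i:j]) - sub$start[i] + 1L
    jmax <- integer(n)
    j <- 1L
    for (i in seq_len(n)) {
      if (j < i) j <- i
      while (j + 1L <= n && span(i, j + 1L) <= max_span) j <- j + 1L
      jmax[i] <- j
    }
    for (i in seq_len(n)) {
      if (jmax[i] - i + 1L < min_genes) next
      if (i > 1L && jmax[i - 1L] >= jmax[i]) next
      idx <- i:jmax[i]
      members <- sub$gene_id[idx]
      labels <- if ("label" %in% names(sub)) sub$label[idx] else NULL
      out[[length(out) + 1L]] <- tibble(
        seqid = chrom,
        n_genes = length(idx),
        start = sub$start[i],
        end = max(sub$end[idx]),
        span_bp = span(i, jmax[i]),
        members = list(members),
        composition = list(if (!is.null(labels)) {
          tibble(label = labels) |> count(.data$label)
        } else {
          NULL
        }),
        tandem = list(if (!is.null(labels)) {
          stats::ave(seq_along(labels), labels, FUN = length) > 1L
        } else {
          NULL
        })
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(
      cluster_id = character(), seqid = character(), n_genes = integer(),
      start = integer(), end = integer(), span_bp = integer(),
      members = list(), composition = list(), tandem = list()
    ))
  }
  res <- bind_rows(out) |> arrange(.data$seqid, .data$start)
  res |> mutate(cluster_id = sprintf("cluster_%02d", row_number()), .before = 1L)
}

#' Write clusters to BED
#'
#' BED intervals are 0-based, half-open.
#'
#' @param clusters Tibble from [detect_clusters()].
#' @param path Output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   clusters$seqid, clusters$start - 1L, clusters$end,
                   clusters$cluster_id, clusters$n_genes)
  writeLines(lines, path)
  invisible(path)
}

#' Compare gene clusters across two genomes
#'
#' Members are translated to shared orthologue names via the mapping
#' tables; cluster pairs sharing at least two names are reported. A pair is
#' order-identical when the shared names appear in the same relative order
#' in both clusters, allowing a whole-cluster reversal to absorb strand or
#' assembly flips. Many-to-many matches are all reported, never resolved.
#'
#' @param clusters_a,clusters_b Cluster tibbles ([detect_clusters()]).
#' @param ortho_map Tibble mapping `gene_id` to `ortho_name` (covering both
#'   genomes' gene ids).
#' @param min_shared Minimum shared orthologue names to report a pair
#'   (default 2).
#' @return A tibble: `cluster_a`, `cluster_b`, `n_shared`, `shared`,
#'   `order_identical`, `a_only`, `b_only` (list columns of names).
#' @export
compare_clusters <- function(clusters_a, clusters_b, ortho_map, min_shared = 2L) {
  name_of <- setNames(ortho_map$ortho_name, ortho_map$gene_id)
  names_in_order <- function(members) unname(name_of[members])
  out <- list()
  for (i in seq_len(nrow(clusters_a))) {
    na <- names_in_order(clusters_a$members[[i]])
    for (j in seq_len(nrow(clusters_b))) {
      nb <- names_in_order(clusters_b$members[[j]])
      shared <- intersect(na, nb)
      if (length(shared) < min_shared) next
      sa <- na[na %in% shared]
      sb <- nb[nb %in% shared]
      ord <- identical(sa, sb) || identical(sa, rev(sb))
      out[[length(out) + 1L]] <- tibble(
        cluster_a = clusters_a$cluster_id[i],
        cluster_b = clusters_b$cluster_id[j],
        n_shared = length(shared),
        shared = list(shared),
        order_identical = ord,
        a_only = list(setdiff(na, nb)),
        b_only = list(setdiff(nb, na))
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(
      cluster_a = character(), cluster_b = character(), n_shared = integer(),
      shared = list(), order_identical = logical(), a_only = list(),
      b_only = list()
    ))
  }
  bind_rows(out)
}
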