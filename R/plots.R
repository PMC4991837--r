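# ggplot2 views of the main result types.

#' Bar chart of the group/subgroup tally
#'
#' @param tally Tibble from [tally_groups()].
#' @return A ggplot object.
#' @export
plot_group_distribution <- function(tally) {
  tally |>
    mutate(label = factor(.data$label, levels = WRKY_LABELS)) |>
    ggplot(aes(x = .data$label, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "group / subgroup", y = "genes") +
    theme_minimal()
}

#' Chromosome counts and gene density
#'
#' @param density Tibble from [gene_density()].
#' @return A ggplot object with counts as columns and density as points.
#' @export
plot_gene_density <- function(density) {
  scale <- max(density$n) / max(density$per_mbp, 1e-9)
  ggplot(density, aes(x = .data$seqid)) +
    geom_col(aes(y = .data$n), fill = "grey70") +
    geom_point(aes(y = .data$per_mbp * scale), colour = "firebrick", size = 2) +
    scale_y_continuous(
      name = "genes",
      sec.axis = sec_axis(~ . / scale, name = "genes per Mbp")
    ) +
    labs(x = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Expression profiles of the expressed-gene set
#'
#' Line-per-tissue view of genes passing the expression threshold, sorted
#' as returned by [expressed_set()].
#'
#' @param expressed Tibble from [expressed_set()].
#' @return A ggplot object.
#' @export
plot_expression_profiles <- function(expressed) {
  long <- expressed |>
    mutate(gene_id = factor(.data$gene_id, levels = .data$gene_id)) |>
    pivot_longer(-"gene_id", names_to = "tissue", values_to = "rpkm")
  ggplot(long, aes(x = .data$gene_id, y = .data$rpkm,
                   colour = .data$tissue, group = .data$tissue)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = NULL, y = "RPKM") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, hjust = 1, vjust = 0.5, size = 6))
}
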