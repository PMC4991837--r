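# Pipeline orchestration: one entry point running the annotation stages
# over files on disk, with a machine-readable manifest.

#' Pipeline configuration
#'
#' @param genome,gff3,proteins,expression,alignment,ortho_map Input paths
#'   (`proteins` optional: when absent, proteins are translated from the
#'   gene models).
#' @param out_dir Output directory.
#' @param ... Threshold overrides: `promoter_len` (1500), `max_span`
#'   (400000), `min_genes` (4), `expr_threshold` (50), `linkage_window`
#'   (30), `fuzzy_max` (1), `bootstrap_B` (1000), `seed` (1).
#' @return A validated configuration list with a `hash` field.
#' @export
pipeline_config <- function(genome = NULL, gff3 = NULL, proteins = NULL,
                            expression = NULL, alignment = NULL,
                            ortho_map = NULL, out_dir = "wrkyscan_out", ...) {
  config <- modifyList(
    list(
      genome = genome, gff3 = gff3, proteins = proteins,
      expression = expression, alignment = alignment, ortho_map = ortho_map,
      out_dir = out_dir,
      promoter_len = 1500L, max_span = 400000L, min_genes = 4L,
      expr_threshold = 50, linkage_window = 30L, fuzzy_max = 1L,
      bootstrap_B = 1000L, seed = 1L
    ),
    list(...)
  )
  for (f in c("promoter_len", "max_span", "min_genes", "expr_threshold",
              "linkage_window", "bootstrap_B")) {
    assert_scalar_number(config[[f]], f)
  }
  # the hash identifies the analysis (inputs + parameters), not where the
  # outputs land
  config$hash <- rlang::hash(config[setdiff(names(config), c("hash", "out_dir"))])
  config
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stamp_tsv <- function(x, path, config) {
  writeLines(sprintf("# wrkyscan config=%s seed=%d", config$hash, config$seed), path)
  suppressWarnings(readr::write_tsv(x, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

require_input <- function(config, field, stage) {
  if (is.null(config[[field]])) {
    abort(sprintf("stage `%s` requires the `%s` input", stage, field))
  }
  config[[field]]
}

#' Run the annotation pipeline
#'
#' Executes one stage (or all of them) against the configured inputs and
#' writes TSV/BED/Newick/JSON outputs plus a `manifest.json` recording the
#' inputs, parameters, seed and package version. Reruns with the same
#' configuration reproduce identical outputs.
#'
#' @param subcommand One of `identify`, `classify`, `structure`,
#'   `phospho`, `promoters`, `clusters`, `express`, `phylo`, `simulate`,
#'   `all`.
#' @param config A configuration list from [pipeline_config()].
#' @return Invisibly, a named list of the tables computed.
#' @export
run_pipeline <- function(subcommand = "all", config = pipeline_config()) {
  stages <- c("identify", "classify", "structure", "phospho", "promoters",
              "clusters", "express", "phylo", "simulate", "all")
  if (!subcommand %in% stages) {
    abort(sprintf("unknown subcommand `%s` (expected one of %s)",
                  subcommand, paste(stages, collapse = ", ")))
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()

  if (subcommand == "simulate") {
    cohort <- gen_cohort(cohort_config(), seed = config$seed)
    write_cohort(cohort, out_dir)
    write_manifest(config, out_dir, stages_run = "simulate")
    return(invisible(list(cohort = cohort)))
  }

  want <- function(s) subcommand %in% c(s, "all")

  genome <- NULL
  models <- NULL
  proteins <- NULL
  domains <- NULL
  assignments <- NULL
  needs_models <- any(vapply(c("identify", "classify", "structure", "phospho",
                               "promoters", "clusters"), want, logical(1)))
  if (needs_models) {
    genome <- read_genome_fasta(require_input(config, "genome", subcommand))
    models <- read_gff3(require_input(config, "gff3", subcommand), genome)
    proteins <- if (!is.null(config$proteins)) {
      prot <- read_protein_fasta(config$proteins)
      ids <- models |> distinct(.data$gene_id, .data$transcript_id, .data$protein_id)
      prot |>
        inner_join(ids, by = "protein_id") |>
        mutate(n_aa = nchar(.data$protein))
    } else {
      extract_proteins(models, genome)
    }
    proteins <- select_isoforms(proteins)
    domains <- scan_wrky_domains(proteins, linkage_window = config$linkage_window)
    assignments <- classify_wrky(domains, wrky_rules(config$fuzzy_max)) |>
      left_join(proteins |> select("protein_id", "gene_id"), by = "protein_id")
  }

  if (want("identify")) {
    results$domains <- domains
    stamp_tsv(domains |> mutate(across(where(is.list), as.character)),
              file.path(out_dir, "domains.tsv"), config)
  }
  if (want("classify")) {
    results$classification <- assignments
    results$tally <- tally_groups(assignments)
    stamp_tsv(assignments, file.path(out_dir, "classification.tsv"), config)
    stamp_tsv(results$tally, file.path(out_dir, "group_tally.tsv"), config)
    stamp_tsv(tail_triplet_report(assignments, domains),
              file.path(out_dir, "tail_triplets.tsv"), config)
  }
  if (want("structure")) {
    kept <- models |> filter(.data$transcript_id %in% proteins$transcript_id)
    introns <- intron_phases(kept, genome)
    spans <- domains |>
      filter(.data$complete) |>
      left_join(proteins |> select("protein_id", "transcript_id"), by = "protein_id") |>
      transmute(.data$transcript_id, aa_start = .data$hep_start, aa_end = .data$zf_end)
    typed <- type_domain_introns(introns, spans)
    results$introns <- typed
    results$exons <- exon_counts(kept)
    stamp_tsv(typed, file.path(out_dir, "introns.tsv"), config)
    stamp_tsv(results$exons, file.path(out_dir, "exon_counts.tsv"), config)
  }
  if (want("phospho")) {
    hits <- scan_protein_motifs(proteins)
    summ <- summarize_phospho(hits, proteins, assignments)
    results$phospho <- summ
    stamp_tsv(hits, file.path(out_dir, "phospho_hits.tsv"), config)
    stamp_tsv(summ$per_protein, file.path(out_dir, "phospho_summary.tsv"), config)
    jsonlite::write_json(summ$cohort, file.path(out_dir, "phospho_cohort.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (want("promoters")) {
    proms <- extract_promoters(models, genome, config$promoter_len)
    hits <- scan_cis_elements(proms)
    cats <- categorize_promoters(hits, genes = proms$gene_id)
    results$promoters <- cats
    stamp_tsv(hits, file.path(out_dir, "cis_element_hits.tsv"), config)
    stamp_tsv(cats, file.path(out_dir, "promoter_categories.tsv"), config)
  }
  if (want("clusters")) {
    genes <- models |>
      filter(.data$transcript_id %in% proteins$transcript_id) |>
      transmute(.data$gene_id, .data$seqid, start = .data$gene_start,
                end = .data$gene_end) |>
      left_join(assignments |> select("gene_id", "label"), by = "gene_id")
    counts <- chromosome_counts(genes, genome)
    dens <- gene_density(counts, genome_lengths(genome))
    clust <- detect_clusters(genes, config$max_span, config$min_genes)
    results$clusters <- clust
    stamp_tsv(dens, file.path(out_dir, "chromosome_density.tsv"), config)
    stamp_tsv(clust |> select(-"members", -"composition", -"tandem"),
              file.path(out_dir, "clusters.tsv"), config)
    write_clusters_bed(clust, file.path(out_dir, "clusters.bed"))
  }
  if (want("express")) {
    m <- read_rpkm(require_input(config, "expression", subcommand))
    base <- baseline_tissue(m)
    grid <- expression_threshold_grid(m)
    results$expression <- list(
      baseline = base, grid = grid,
      expressed = expressed_set(m, config$expr_threshold),
      peaks = peak_tissue(m)
    )
    stamp_tsv(base, file.path(out_dir, "expression_baseline.tsv"), config)
    stamp_tsv(grid$table, file.path(out_dir, "expression_threshold_grid.tsv"), config)
    stamp_tsv(results$expression$expressed, file.path(out_dir, "expressed_genes.tsv"), config)
    stamp_tsv(results$expression$peaks, file.path(out_dir, "peak_tissues.tsv"), config)
  }
  if (want("phylo") && !is.null(config$alignment)) {
    aln <- read_alignment(config$alignment)
    tree <- bootstrap_support(aln, B = config$bootstrap_B, seed = config$seed)
    results$tree <- tree
    write_tree(tree, file.path(out_dir, "nj_tree.nwk"))
    if (!is.null(assignments)) {
      ids <- names(aln)
      base_ids <- sub("\\.(N|C)$", "", ids)
      lab <- setNames(assignments$label[match(base_ids, assignments$protein_id)], ids)
      if (!anyNA(lab)) {
        comp <- clade_composition(tree, lab)
        results$clades <- comp
        stamp_tsv(comp, file.path(out_dir, "clade_composition.tsv"), config)
      }
    }
  } else if (subcommand == "phylo") {
    require_input(config, "alignment", "phylo")
  }

  write_manifest(config, out_dir, stages_run = subcommand)
  invisible(results)
}

write_manifest <- function(config, out_dir, stages_run) {
  manifest <- list(
    tool = "wrkyscan",
    version = as.character(utils::packageVersion("wrkyscan")),
    config_hash = config$hash,
    seed = config$seed,
    stages = stages_run,
    inputs = config[c("genome", "gff3", "proteins", "expression",
                      "alignment", "ortho_map")],
    parameters = config[c("promoter_len", "max_span", "min_genes",
                          "expr_threshold", "linkage_window", "fuzzy_max",
                          "bootstrap_B")]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(manifest)
}
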