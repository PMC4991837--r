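# Promoter cis-element scanning and responsiveness categorisation.
#
# Promoters are scanned on both strands for IUPAC consensus elements tied
# to hormone and stress response: ABRE (ABA-responsive element) and its
# coupling elements CE1/CE3, the dehydration-responsive element DRE, the
# salicylic-acid response element SARE, and the W-box bound by WRKY
# proteins themselves. A single ABRE does not confer ABA responsiveness: it
# must couple with a CE, a second ABRE, or a DRE.

#' Default cis-element consensus table
#'
#' Read from the package's `cis_elements.tsv` config so the consensus set
#' can be replaced wholesale via [read_element_table()].
#'
#' @return A tibble: `class`, `consensus` (IUPAC), `both_strands`.
#' @export
cis_element_table <- function() {
  read_element_table(system.file("extdata", "cis_elements.tsv", package = "wrkyscan"))
}

#' Read a cis-element table from TSV
#'
#' @param path TSV with columns `class`, `consensus` and optionally
#'   `both_strands`.
#' @return A tibble as from [cis_element_table()].
#' @export
read_element_table <- function(path) {
  t <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("class", "consensus") %in% names(t)))
  if (!"both_strands" %in% names(t)) t$both_strands <- TRUE
  if (any(nchar(t$consensus) < 5L)) abort("every consensus must be at least 5 nt")
  t
}

#' Scan promoters for cis-elements
#'
#' All matches of each IUPAC consensus are reported on both strands
#' (overlapping matches included). Offsets are negative and upstream,
#' relative to the 3' end of the window: the base immediately before the
#' gene start has offset -1.
#'
#' @param promoters Promoter tibble ([extract_promoters()]) or a tibble
#'   with `gene_id` and `promoter` columns.
#' @param table Element table ([cis_element_table()]).
#' @return A tibble: `gene_id`, `class`, `strand` (relative to the
#'   promoter's coding strand), `start` (1-based in the window), `offset`.
#' @export
scan_cis_elements <- function(promoters, table = cis_element_table()) {
  stopifnot(all(c("gene_id", "promoter") %in% names(promoters)))
  out <- list()
  for (i in seq_len(nrow(promoters))) {
    seq <- promoters$promoter[i]
    if (!nzchar(seq)) next
    subject <- Biostrings::DNAString(seq)
    L <- nchar(seq)
    for (k in seq_len(nrow(table))) {
      pat <- Biostrings::DNAString(table$consensus[k])
      fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject, fixed = FALSE))
      if (length(fwd) > 0L) {
        out[[length(out) + 1L]] <- tibble(
          gene_id = promoters$gene_id[i], class = table$class[k],
          strand = "+", start = as.integer(fwd), offset = as.integer(fwd - L - 1L)
        )
      }
      if (isTRUE(table$both_strands[k])) {
        m <- nchar(table$consensus[k])
        rev_hits <- Biostrings::start(Biostrings::matchPattern(
          Biostrings::reverseComplement(pat), subject, fixed = FALSE))
        if (length(rev_hits) > 0L) {
          out[[length(out) + 1L]] <- tibble(
            gene_id = promoters$gene_id[i], class = table$class[k],
            strand = "-", start = as.integer(rev_hits),
            offset = as.integer(rev_hits - L - 1L)
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(gene_id = character(), class = character(),
                  strand = character(), start = integer(), offset = integer()))
  }
  bind_rows(out) |> arrange(.data$gene_id, .data$class, .data$start)
}

#' Default promoter category rules
#'
#' Read from the package's `promoter_categories.yaml` config: an ordered
#' list of rules, each with required and forbidden responsiveness flags;
#' the first matching rule assigns the category, and promoters matching no
#' rule fall into the residual category.
#'
#' @return A list with elements `rules` (list of `category`, `requires`,
#'   `forbids`) and `default_category`.
#' @export
category_rules <- function() {
  read_category_rules(system.file("extdata", "promoter_categories.yaml",
                                  package = "wrkyscan"))
}

#' Read promoter category rules from YAML
#'
#' @param path YAML file with `rules` (ordered list of category/requires/
#'   forbids) and `default_category`.
#' @return A rule list as from [category_rules()].
#' @export
read_category_rules <- function(path) {
  r <- yaml::read_yaml(path)
  stopifnot(is.list(r$rules), is.numeric(r$default_category))
  r
}

# Responsiveness flags from per-class element counts.
promoter_flags <- function(counts) {
  n <- function(cl) sum(counts$n[counts$class == cl])
  abre <- n("ABRE")
  list(
    sa_responsive = n("SARE") >= 1L,
    aba_responsive = abre >= 1L && (n("CE1") + n("CE3") >= 1L || abre >= 2L || n("DRE") >= 1L),
    drought_responsive = n("DRE") >= 1L,
    wrky_regulated = n("WBOX") >= 1L
  )
}

#' Categorize promoters from element hits
#'
#' Computes per-gene element counts, the four responsiveness flags
#' (SA-responsive, ABA-responsive via the ABRE-coupling rule,
#' drought-responsive, WRKY-regulated) and the promoter category from the
#' ordered rule table.
#'
#' @param hits Element hits ([scan_cis_elements()]).
#' @param genes Character vector of all gene ids (so hit-less promoters
#'   are categorized too); defaults to the genes present in `hits`.
#' @param rules Category rules ([category_rules()]).
#' @return A tibble: `gene_id`, one count column per element class,
#'   the four flag columns, `category` and `evidence`.
#' @export
categorize_promoters <- function(hits, genes = NULL, rules = category_rules()) {
  genes <- genes %||% unique(hits$gene_id)
  classes <- c("ABRE", "CE1", "CE3", "DRE", "SARE", "WBOX")
  rows <- lapply(genes, function(g) {
    counts <- hits |> filter(.data$gene_id == g) |> count(.data$class)
    missing <- setdiff(classes, counts$class)
    counts <- bind_rows(counts, tibble(class = missing, n = 0L))
    fl <- promoter_flags(counts)
    cat <- rules$default_category
    ev <- "no rule matched"
    for (r in rules$rules) {
      req <- unlist(r$requires) %||% character()
      forb <- unlist(r$forbids) %||% character()
      if (all(unlist(fl[req])) && !any(unlist(fl[forb]))) {
        cat <- r$category
        ev <- sprintf("requires {%s} met, forbids {%s} clear",
                      paste(req, collapse = ","), paste(forb, collapse = ","))
        break
      }
    }
    wide <- setNames(as.list(counts$n[match(classes, counts$class)]), classes)
    bind_cols(
      tibble(gene_id = g), as_tibble(wide), as_tibble(fl),
      tibble(category = as.integer(cat), evidence = ev)
    )
  })
  bind_rows(rows)
}

#' Cohort summary of promoter categories
#'
#' @param categories Tibble from [categorize_promoters()].
#' @return A list: `categories` (tibble of per-category counts, all six
#'   categories listed) and `flags` (per-flag gene counts).
#' @export
summarize_promoter_categories <- function(categories) {
  cat_counts <- tibble(category = 1:6) |>
    left_join(categories |> count(.data$category), by = "category") |>
    mutate(n = replace_na(.data$n, 0L))
  flags <- c("sa_responsive", "aba_responsive", "drought_responsive", "wrky_regulated")
  flag_counts <- tibble(
    flag = flags,
    n = unname(vapply(flags, function(f) {
      if (nrow(categories) == 0L) 0L else sum(categories[[f]])
    }, integer(1)))
  )
  list(categories = cat_counts, flags = flag_counts)
}
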