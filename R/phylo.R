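# Distance-based phylogenetics of WRKY domains and full-length proteins:
# p-distances, neighbour-joining, bootstrap bipartition support, and
# subgroup clade-composition tests.

#' Construct an alignment object
#'
#' @param x A named character vector of equal-length aligned amino-acid
#'   rows (gap `-`), or a file path handled by [read_alignment()].
#' @return A `wrky_alignment`: the named character vector with a class.
#' @export
as_alignment <- function(x) {
  if (!is.character(x) || is.null(names(x))) {
    abort("alignment must be a named character vector")
  }
  if (length(x) < 3L) abort("an alignment needs at least 3 sequences")
  if (length(unique(nchar(x))) != 1L) abort("alignment rows differ in length")
  if (anyDuplicated(names(x))) abort("duplicate sequence ids in alignment")
  structure(toupper(x), class = "wrky_alignment")
}

#' Read an aligned FASTA file
#'
#' @param path Aligned amino-acid FASTA.
#' @return A `wrky_alignment`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  as_alignment(setNames(as.character(set), sub("\\s.*$", "", names(set))))
}

aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
}

#' Pairwise p-distances of an alignment
#'
#' `d(i, j)` is the fraction of mismatching sites among comparable sites.
#' With pairwise gap deletion (the default) a site is comparable for a pair
#' when neither row has a gap there; with complete deletion, columns
#' containing any gap are removed for all pairs.
#'
#' @param aln A `wrky_alignment` (or named character vector of at least two
#'   equal-length rows).
#' @param gap_mode `"pairwise"` or `"complete"` gap deletion.
#' @return A symmetric numeric matrix with a zero diagonal.
#' @export
p_distance <- function(aln, gap_mode = c("pairwise", "complete")) {
  gap_mode <- match.arg(gap_mode)
  if (length(aln) < 2L) abort("p_distance needs at least 2 sequences")
  if (length(unique(nchar(aln))) != 1L) abort("alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(unclass(aln)), "", fixed = TRUE))
  rownames(m) <- names(aln)
  gap <- m == "-" | m == "."
  if (gap_mode == "complete") {
    keep <- colSums(gap) == 0L
    m <- m[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        abort(sprintf("no comparable sites between %s and %s",
                      rownames(m)[i], rownames(m)[j]))
      }
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Q-matrix criterion) on a symmetric distance
#' matrix. Negative branch-length estimates are clamped to zero and
#' counted.
#'
#' @param d Symmetric numeric matrix with row/column names; at least three
#'   taxa.
#' @return A `wrky_tree`: list with elements `phylo` (an unrooted
#'   [ape::phylo]), `n_clamped`, and `support` (`NULL` until
#'   [bootstrap_support()]).
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (nrow(d) < 3L) abort("NJ needs at least 3 taxa")
  if (is.null(rownames(d))) abort("distance matrix must carry taxon names")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("distance matrix is not symmetric")
  }
  phy <- ape::nj(d)
  clamped <- sum(phy$edge.length < 0)
  phy$edge.length[phy$edge.length < 0] <- 0
  structure(
    list(phylo = phy, n_clamped = as.integer(clamped), support = NULL,
         B = NULL, seed = NULL),
    class = "wrky_tree"
  )
}

#' @export
print.wrky_tree <- function(x, ...) {
  cat(sprintf("<wrky_tree> %d tips%s%s\n",
              length(x$phylo$tip.label),
              if (!is.null(x$support)) sprintf(", bootstrap B=%d", x$B) else "",
              if (x$n_clamped > 0) sprintf(", %d negative branch(es) clamped", x$n_clamped) else ""))
  invisible(x)
}

build_nj_from_alignment <- function(aln, gap_mode = "pairwise") {
  nj_tree(p_distance(aln, gap_mode))
}

#' Bootstrap bipartition support for an NJ tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the
#' p-distance NJ tree for each replicate, and scores each internal edge of
#' the original tree by the percentage of replicates containing the same
#' bipartition. Reproducible for a fixed seed, and invariant to the input
#' order of sequences because columns, not rows, are resampled.
#'
#' @param aln A `wrky_alignment`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param gap_mode Passed to [p_distance()].
#' @return A `wrky_tree` whose `support` is a numeric vector (percent, one
#'   entry per internal node) also written to the tree's node labels.
#' @export
bootstrap_support <- function(aln, B = 1000L, seed = 1L, gap_mode = "pairwise") {
  if (B < 1L) abort("B must be at least 1")
  base <- build_nj_from_alignment(aln, gap_mode)
  m <- aln_char_matrix(aln)
  rownames(m) <- names(aln)
  ncol_a <- ncol(m)
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol_a, ncol_a, replace = TRUE)
    rep_aln <- setNames(apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""),
                        rownames(m))
    reps[[b]] <- build_nj_from_alignment(rep_aln, gap_mode)$phylo
  }
  counts <- ape::prop.clades(base$phylo, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / B
  base$phylo$node.label <- format(support, trim = TRUE, digits = 4)
  base$support <- support
  base$B <- as.integer(B)
  base$seed <- as.integer(seed)
  base
}

#' Write a tree to Newick
#'
#' Bootstrap supports, when present, are written as internal node labels.
#'
#' @param tree A `wrky_tree`.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

# Maximal pure-subtree count for a tip set on an unrooted tree: the number
# of clades (after rooting at a tip outside the set) that contain only set
# members and are not contained in a larger such clade.
pure_subtree_cover <- function(phy, tips_in_set) {
  all_tips <- phy$tip.label
  if (setequal(tips_in_set, all_tips)) return(1L)
  out_tip <- setdiff(all_tips, tips_in_set)[1]
  rooted <- ape::root(phy, outgroup = out_tip, resolve.root = TRUE)
  rooted <- stats::reorder(rooted, "postorder")
  n_tip <- length(rooted$tip.label)
  n_node <- rooted$Nnode
  pure <- logical(n_tip + n_node)
  pure[seq_len(n_tip)] <- rooted$tip.label %in% tips_in_set
  pure[(n_tip + 1L):(n_tip + n_node)] <- TRUE
  has_child <- logical(n_tip + n_node)
  for (e in seq_len(nrow(rooted$edge))) {
    parent <- rooted$edge[e, 1]
    child <- rooted$edge[e, 2]
    has_child[parent] <- TRUE
    pure[parent] <- pure[parent] && pure[child]
  }
  parent_of <- integer(n_tip + n_node)
  parent_of[rooted$edge[, 2]] <- rooted$edge[, 1]
  root_node <- setdiff(rooted$edge[, 1], rooted$edge[, 2])[1]
  maximal <- vapply(seq_len(n_tip + n_node), function(v) {
    if (!pure[v]) return(FALSE)
    if (!has_child[v] && v > n_tip) return(FALSE)  # unused node slot
    if (v == root_node) return(TRUE)
    !pure[parent_of[v]]
  }, logical(1))
  sum(maximal)
}

#' Bootstrap support of one bipartition
#'
#' Looks up the support value attached to the edge that splits `tips` from
#' the rest of the tree (either orientation).
#'
#' @param tree A `wrky_tree` with supports ([bootstrap_support()]).
#' @param tips Character vector of tip labels on one side of the split.
#' @return The support percentage, or `NA` if the tree has no such edge.
#' @export
split_support <- function(tree, tips) {
  if (is.null(tree$support)) abort("tree carries no bootstrap supports")
  phy <- tree$phylo
  all_tips <- phy$tip.label
  parts <- ape::prop.part(phy)
  for (k in seq_along(parts)) {
    clade <- all_tips[parts[[k]]]
    if (setequal(clade, tips) || setequal(clade, setdiff(all_tips, tips))) {
      return(tree$support[k])
    }
  }
  NA_real_
}

#' Clade composition of labelled groups
#'
#' For each group (and for the conventional unions IIa+b, IId+e and
#' III+Ib, when those labels are present) reports whether some edge
#' bipartition of the tree isolates exactly that label set, and otherwise
#' the minimum number of maximal pure subtrees covering it (2 for a group
#' split into two clades, and so on).
#'
#' @param tree A `wrky_tree` (or [ape::phylo]).
#' @param labels Named character vector mapping every tip label to a group.
#' @param unions Named list of label unions to evaluate alongside the
#'   individual groups.
#' @return A tibble: `group`, `n_tips`, `monophyletic`, `cover_number`.
#' @export
clade_composition <- function(tree, labels,
                              unions = list("IIa+b" = c("IIa", "IIb"),
                                            "IId+e" = c("IId", "IIe"),
                                            "III+Ib" = c("III", "Ib"))) {
  phy <- if (inherits(tree, "wrky_tree")) tree$phylo else tree
  tips <- phy$tip.label
  missing <- setdiff(tips, names(labels))
  if (length(missing) > 0L) {
    abort(sprintf("unlabelled leaf(s): %s", paste(missing, collapse = ", ")))
  }
  groups <- as.list(setNames(sort(unique(unname(labels[tips]))),
                             sort(unique(unname(labels[tips])))))
  for (u in names(unions)) {
    if (all(unions[[u]] %in% unlist(groups))) groups[[u]] <- unions[[u]]
  }
  rows <- lapply(names(groups), function(g) {
    set <- tips[labels[tips] %in% groups[[g]]]
    if (length(set) == 0L) return(NULL)
    cover <- if (length(set) == 1L) 1L else pure_subtree_cover(phy, set)
    tibble(group = g, n_tips = length(set),
           monophyletic = cover == 1L, cover_number = as.integer(cover))
  })
  bind_rows(rows)
}

#' Extract domain rows for a domain tree
#'
#' The N- and C-terminal domains of two-domain proteins enter the tree as
#' separate rows, suffixed `.N` and `.C`; single-domain proteins keep their
#' id.
#'
#' @param domains Domain tibble ([scan_wrky_domains()]), complete domains
#'   only are used.
#' @param proteins Tibble with `protein_id` and `protein`.
#' @return A tibble: `id`, `seq` (unaligned domain sequences, heptamer
#'   through finger end).
#' @export
domain_sequences <- function(domains, proteins) {
  seq_of <- setNames(proteins$protein, proteins$protein_id)
  domains |>
    filter(.data$complete) |>
    mutate(
      id = case_when(
        .data$terminal_role == "N" ~ paste0(.data$protein_id, ".N"),
        .data$terminal_role == "C" ~ paste0(.data$protein_id, ".C"),
        .default = .data$protein_id
      ),
      seq = unname(substr(seq_of[.data$protein_id], .data$hep_start, .data$zf_end))
    ) |>
    select("id", "seq")
}

#' Tidy a `wrky_tree` into an edge table
#'
#' @param x A `wrky_tree`.
#' @param ... Unused.
#' @return A tibble with one row per edge: `parent`, `node`,
#'   `branch_length`, `is_tip`, `label` and (after
#'   [bootstrap_support()]) `support`.
#' @method tidy wrky_tree
#' @export
tidy.wrky_tree <- function(x, ...) {
  phy <- x$phylo
  n_tip <- length(phy$tip.label)
  edges <- as_tibble(phy$edge, .name_repair = ~ c("parent", "node"))
  edges$branch_length <- phy$edge.length
  edges$is_tip <- edges$node <= n_tip
  edges$label <- ifelse(edges$is_tip, phy$tip.label[pmin(edges$node, n_tip)], NA)
  if (!is.null(x$support)) {
    edges$support <- NA_real_
    internal <- which(!edges$is_tip)
    edges$support[internal] <- x$support[edges$node[internal] - n_tip]
  }
  edges
}

#' One-row summary of a `wrky_tree`
#'
#' @param x A `wrky_tree`.
#' @param ... Unused.
#' @return A one-row tibble: tip/internal counts, clamped-branch count,
#'   bootstrap replicate count and support summaries.
#' @method glance wrky_tree
#' @export
glance.wrky_tree <- function(x, ...) {
  tibble(
    n_tips = length(x$phylo$tip.label),
    n_internal = x$phylo$Nnode,
    n_clamped = x$n_clamped,
    B = x$B %||% NA_integer_,
    mean_support = if (!is.null(x$support)) mean(x$support) else NA_real_,
    min_support = if (!is.null(x$support)) min(x$support) else NA_real_
  )
}
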