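# Mature-protein distances, UPGMA trees, Newick export and clade
# composition reports.

#' Pairwise distance matrix over mature proteins
#'
#' `d = 1 - identity` from global alignment (BLOSUM62, gap open -10,
#' extend -1); identity is computed over aligned columns excluding
#' terminal-gap columns.
#'
#' @param proteins named character vector (>= 2 non-empty sequences).
#' @return symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
pairwise_distance_matrix <- function(proteins) {
  stopifnot(length(proteins) >= 2L, !is.null(names(proteins)))
  if (any(!nzchar(proteins))) stop("empty sequence in distance matrix")
  n <- length(proteins)
  d <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  set <- Biostrings::AAStringSet(proteins)
  for (j in 2:n) {
    al <- Biostrings::pairwiseAlignment(
      set[seq_len(j - 1L)], set[[j]], type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
    pa <- as.character(Biostrings::alignedPattern(al))
    sb <- as.character(Biostrings::alignedSubject(al))
    for (i in seq_len(j - 1L)) {
      ac <- seq_chars(pa[i]); bc <- seq_chars(sb[i])
      keep <- trim_terminal_gap_cols(ac, bc)
      ident <- if (any(keep)) mean(ac[keep] == bc[keep]) else 0
      d[i, j] <- d[j, i] <- 1 - ident
    }
  }
  d
}

upgma_node <- function(height, children = NULL, label = NULL) {
  list(height = height, children = children, label = label,
       leaves = if (is.null(children)) label
                else sort(unlist(lapply(children, `[[`, "leaves"))))
}

#' UPGMA tree construction
#'
#' Iteratively merges the closest pair of clusters; distances to the merged
#' cluster are arithmetic means weighted by cluster sizes, and the merge
#' node sits at height d/2 (so the tree is ultrametric). Ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' representative labels (each cluster represented by its smallest leaf
#' label), making trees reproducible byte for byte.
#'
#' @param dm symmetric distance matrix with dimnames (or `dist`).
#' @return object of class `upgma_tree`: list with `root` (recursive node:
#'   height, children, leaves) and `leaf_labels`.
#' @export
upgma <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("UPGMA needs at least 2 leaves")
  labels <- rownames(dm)
  stopifnot(!is.null(labels), all(labels == colnames(dm)),
            isTRUE(all.equal(dm, t(dm))), all(diag(dm) == 0))
  nodes <- lapply(labels, function(l) upgma_node(0, label = l))
  sizes <- rep(1L, n)
  reps <- labels
  D <- dm
  active <- seq_len(n)
  while (length(active) > 1L) {
    # minimum off-diagonal distance among active clusters
    sub <- D[active, active, drop = FALSE]
    diag(sub) <- Inf
    mval <- min(sub)
    idx <- which(sub <= mval + 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # tie-break on representative (smallest leaf) labels
    keys <- apply(idx, 1L, function(r) {
      paste(sort(c(reps[active[r[1]]], reps[active[r[2]]])),
            collapse = "\r")
    })
    pick <- idx[order(keys)[1L], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    h <- D[i, j] / 2
    kids <- list(nodes[[i]], nodes[[j]])
    kids <- kids[order(c(reps[i], reps[j]))]
    new <- upgma_node(h, children = kids)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j)))
      D[i, k] <- D[k, i] <- (ni * D[i, k] + nj * D[j, k]) / (ni + nj)
    nodes[[i]] <- new
    sizes[i] <- ni + nj
    reps[i] <- min(reps[i], reps[j])
    active <- setdiff(active, j)
  }
  structure(list(root = nodes[[active]], leaf_labels = sort(labels)),
            class = "upgma_tree")
}

#' Serialize an UPGMA tree to Newick
#'
#' Branch lengths are differences of node heights, so all root-to-leaf
#' paths have equal length (ultrametric).
#'
#' @param tree an `upgma_tree`.
#' @param digits significant digits for branch lengths.
#' @return single Newick string terminated by `;`.
#' @export
tree_newick <- function(tree, digits = 10L) {
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node, parent_height) {
    if (is.null(node$children))
      return(paste0(node$label, ":", fmt(parent_height)))
    inner <- paste(vapply(node$children, rec, character(1),
                          parent_height = node$height), collapse = ",")
    paste0("(", inner, "):", fmt(parent_height - node$height))
  }
  root <- tree$root
  inner <- paste(vapply(root$children, rec, character(1),
                        parent_height = root$height), collapse = ",")
  paste0("(", inner, ");")
}

#' Convert an UPGMA tree to an ape phylo object
#'
#' @param tree an `upgma_tree`.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = tree_newick(tree))
}

#' Leaf-to-leaf cophenetic distances through an UPGMA tree
#'
#' @param tree an `upgma_tree`.
#' @return symmetric matrix of distances (2 x MRCA height).
#' @export
tree_cophenetic <- function(tree) {
  labels <- tree$leaf_labels
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  rec <- function(node) {
    if (is.null(node$children)) return(invisible(NULL))
    sets <- lapply(node$children, `[[`, "leaves")
    for (a in sets[[1]]) for (b in sets[[2]])
      d[a, b] <<- d[b, a] <<- 2 * node$height
    lapply(node$children, rec)
    invisible(NULL)
  }
  rec(tree$root)
  d
}

# enumerate nodes (internal and leaves) with their leaf sets
tree_nodes <- function(tree) {
  out <- list()
  rec <- function(node) {
    out[[length(out) + 1L]] <<- node
    if (!is.null(node$children)) lapply(node$children, rec)
    invisible(NULL)
  }
  rec(tree$root)
  out
}

#' Clade species composition and monophyly report
#'
#' For every internal node, counts the leaves per species and renders the
#' bracket notation `[nA-nB-nC]` in the supplied species order. A type (or
#' species group) is monophyletic when some node's leaf set equals exactly
#' that group's leaves.
#'
#' @param tree an `upgma_tree`.
#' @param species_map named character vector, leaf label -> species; every
#'   leaf must be mapped.
#' @param species_order order of species in the rendered brackets
#'   (defaults to sorted unique species).
#' @return data frame with one row per internal node: `node` (id), `size`,
#'   one count column per species, `bracket`, and `species_specific`
#'   (TRUE when all leaves come from one species).
#' @export
clade_species_composition <- function(tree, species_map,
                                      species_order = NULL) {
  unmapped <- setdiff(tree$leaf_labels, names(species_map))
  if (length(unmapped) > 0L)
    stop(sprintf("unmapped leaf/leaves: %s",
                 paste(unmapped, collapse = ", ")))
  if (is.null(species_order))
    species_order <- sort(unique(unname(species_map)))
  nodes <- Filter(function(n) !is.null(n$children), tree_nodes(tree))
  rows <- lapply(seq_along(nodes), function(i) {
    sp <- species_map[nodes[[i]]$leaves]
    counts <- table(factor(sp, levels = species_order))
    row <- data.frame(node = paste0("N", i),
                      size = length(sp), stringsAsFactors = FALSE)
    for (s in species_order) row[[s]] <- as.integer(counts[[s]])
    row$bracket <- paste0("[", paste(as.integer(counts), collapse = "-"),
                          "]")
    row$species_specific <- length(unique(sp)) == 1L
    row
  })
  do.call(rbind, rows)
}

#' Monophyly of labelled groups
#'
#' @param tree an `upgma_tree`.
#' @param group_map named character vector, leaf label -> group (e.g. nsLTP
#'   type); every leaf must be mapped.
#' @return data frame: group, n_leaves, monophyletic. Singleton groups are
#'   monophyletic by convention (a leaf is a trivial clade).
#' @export
monophyly_report <- function(tree, group_map) {
  unmapped <- setdiff(tree$leaf_labels, names(group_map))
  if (length(unmapped) > 0L)
    stop(sprintf("unmapped leaf/leaves: %s",
                 paste(unmapped, collapse = ", ")))
  leaf_sets <- lapply(tree_nodes(tree), `[[`, "leaves")
  keys <- vapply(leaf_sets, paste, character(1), collapse = "\r")
  groups <- sort(unique(unname(group_map)))
  rows <- lapply(groups, function(g) {
    members <- sort(names(group_map)[group_map == g])
    data.frame(group = g, n_leaves = length(members),
               monophyletic = paste(members, collapse = "\r") %in% keys,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm symmetric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(sprintf("%-10s", rownames(dm)[i]),
                       sprintf("%.6f", dm[i, ])), collapse = " "), con)
  }
  invisible(path)
}
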