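#' Rooted taxonomy objects
#'
#' A `taxonomy` holds a rooted hierarchy of taxa: every node except the root
#' has exactly one parent, and the level of a node is its depth counted from
#' the root, with the root at level 1 and its direct children at level 2.
#' Internally the tree is stored as parallel vectors (id, parent index, level)
#' plus a child index with children ordered canonically by taxon id, so that
#' every traversal of the same tree visits nodes in the same order.
#'
#' @param nodes A data frame with columns `taxon_id`, `parent_id` (NA for the
#'   root) and optionally `rank` and `name`.
#' @return An object of class `taxonomy`.
#' @export
taxonomy <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "parent_id") %in% names(nodes))) {
    abort_validation("`nodes` must have columns taxon_id and parent_id")
  }
  ids <- as.character(nodes$taxon_id)
  parents <- as.character(nodes$parent_id)
  if (anyNA(ids) || any(ids == "")) {
    abort_structure("taxonomy has missing taxon ids")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort_structure(paste0(
      "duplicate taxon id(s): ", paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  root_mask <- is.na(parents) | parents == ids
  if (sum(root_mask) == 0L) {
    abort_structure("taxonomy has no root (no node with parent == self or missing parent)")
  }
  if (sum(root_mask) > 1L) {
    abort_structure(paste0(
      "taxonomy has multiple roots: ",
      paste(utils::head(ids[root_mask], 5), collapse = ", ")
    ))
  }
  parents[root_mask] <- NA_character_
  parent_idx <- match(parents, ids)
  missing_parent <- !is.na(parents) & is.na(parent_idx)
  if (any(missing_parent)) {
    abort_structure(paste0(
      "parent taxon absent from taxonomy: ",
      paste(utils::head(unique(parents[missing_parent]), 5), collapse = ", ")
    ))
  }

  n <- length(ids)
  root <- which(root_mask)
  # levels by breadth-first propagation; unreached nodes indicate a cycle
  level <- rep(NA_integer_, n)
  level[root] <- 1L
  frontier <- root
  kids_of <- split(seq_len(n), factor(parent_idx, levels = seq_len(n)))
  while (length(frontier) > 0L) {
    nxt <- unlist(kids_of[frontier], use.names = FALSE)
    if (length(nxt) == 0L) break
    level[nxt] <- level[frontier[match(parent_idx[nxt], frontier)]] + 1L
    frontier <- nxt
  }
  if (anyNA(level)) {
    abort_structure(paste0(
      "cycle detected: node(s) not reachable from root, e.g. ",
      ids[which(is.na(level))[1]]
    ))
  }

  children <- lapply(kids_of, function(k) k[order_ids(ids[k])])
  names(children) <- NULL

  structure(
    list(
      ids = ids,
      parent = parent_idx,
      level = level,
      children = children,
      root = root,
      rank = if ("rank" %in% names(nodes)) as.character(nodes$rank) else rep(NA_character_, n),
      name = if ("name" %in% names(nodes)) as.character(nodes$name) else rep(NA_character_, n)
    ),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf(
    "<taxonomy> %d taxa, root '%s', max level %d, %d leaves\n",
    length(x$ids), x$ids[x$root], max(x$level), sum(lengths(x$children) == 0L)
  ))
  invisible(x)
}

#' @export
as_tibble.taxonomy <- function(x, ...) {
  tibble(
    taxon_id = x$ids,
    parent_id = ifelse(is.na(x$parent), NA_character_, x$ids[x$parent]),
    level = x$level,
    rank = x$rank,
    name = x$name
  )
}

#' Number of taxa in a taxonomy
#' @param tree A [taxonomy()] object.
#' @return Integer count of nodes.
#' @export
n_taxa <- function(tree) {
  stopifnot(inherits(tree, "taxonomy"))
  length(tree$ids)
}

#' Leaf taxa of a taxonomy
#' @param tree A [taxonomy()] object.
#' @return Character vector of taxon ids with no children, in canonical order.
#' @export
taxonomy_leaves <- function(tree) {
  stopifnot(inherits(tree, "taxonomy"))
  sort_ids(tree$ids[lengths(tree$children) == 0L])
}

taxon_index <- function(tree, taxon_id) {
  idx <- match(as.character(taxon_id), tree$ids)
  if (anyNA(idx)) {
    bad <- unique(as.character(taxon_id)[is.na(idx)])
    abort_lookup(paste0(
      "unknown taxon id(s): ", paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  idx
}

#' Direct children of a taxon
#'
#' Returns the direct children only (never deeper descendants), ordered
#' canonically by taxon id so repeated runs traverse the tree identically.
#'
#' @param tree A [taxonomy()] object.
#' @param taxon_id A single taxon id present in `tree`.
#' @return Character vector of child taxon ids (empty for a leaf).
#' @export
taxon_children <- function(tree, taxon_id) {
  idx <- taxon_index(tree, taxon_id)
  stopifnot(length(idx) == 1L)
  tree$ids[tree$children[[idx]]]
}

#' Parent of a taxon
#' @inheritParams taxon_children
#' @return The parent taxon id, or `NA` for the root.
#' @export
taxon_parent <- function(tree, taxon_id) {
  idx <- taxon_index(tree, taxon_id)
  p <- tree$parent[idx]
  ifelse(is.na(p), NA_character_, tree$ids[p])
}

#' Level of taxa (root = level 1)
#' @param tree A [taxonomy()] object.
#' @param taxon_id Vector of taxon ids.
#' @return Integer vector of levels; the root is level 1 and each child is one
#'   level below its parent.
#' @export
taxon_level <- function(tree, taxon_id) {
  tree$level[taxon_index(tree, taxon_id)]
}

#' Ancestor of a taxon at a given level
#'
#' For each taxon, walks up the parent chain to the unique ancestor sitting at
#' level `level` (a taxon is its own ancestor at its own level). Taxa that are
#' themselves above the requested level have no such ancestor and yield `NA`.
#'
#' @param tree A [taxonomy()] object.
#' @param taxon_id Vector of taxon ids.
#' @param level A single level, `>= 1`.
#' @return Character vector of ancestor taxon ids (`NA` where the taxon sits
#'   above `level`).
#' @export
ancestor_at_level <- function(tree, taxon_id, level) {
  if (length(level) != 1L || is.na(level) || level < 1) {
    abort_validation("`level` must be a single integer >= 1")
  }
  idx <- taxon_index(tree, taxon_id)
  out <- idx
  out[tree$level[idx] < level] <- NA_integer_
  repeat {
    deeper <- which(!is.na(out) & tree$level[out] > level)
    if (length(deeper) == 0L) break
    out[deeper] <- tree$parent[out[deeper]]
  }
  ifelse(is.na(out), NA_character_, tree$ids[out])
}

#' Lineage string of a taxon
#' @inheritParams taxon_children
#' @param sep Separator between lineage elements.
#' @return A single string with the taxon ids from the root down to `taxon_id`.
#' @export
taxon_lineage <- function(tree, taxon_id, sep = ";") {
  idx <- taxon_index(tree, taxon_id)
  stopifnot(length(idx) == 1L)
  path <- character(tree$level[idx])
  i <- idx
  for (k in seq(tree$level[idx], 1L)) {
    path[k] <- tree$ids[i]
    i <- tree$parent[i]
  }
  paste(path, collapse = sep)
}

# integer indices of all nodes in the subtree rooted at idx (incl. idx)
subtree_indices <- function(tree, idx) {
  acc <- integer(0)
  frontier <- idx
  while (length(frontier) > 0L) {
    acc <- c(acc, frontier)
    frontier <- unlist(tree$children[frontier], use.names = FALSE)
  }
  acc
}

#' Read an NCBI taxdump `nodes.dmp` file
#'
#' Parses the pipe-delimited `nodes.dmp` dialect of the NCBI taxonomy dump:
#' field 1 is the taxon id, field 2 the parent id and field 3 the rank. The
#' root row, which NCBI writes with parent equal to itself, is normalised to a
#' parentless root. "no rank" nodes are kept as ordinary levels: the sampler
#' walks the raw hierarchy, not a rank-collapsed one.
#'
#' @param path Path to a `nodes.dmp`-style file.
#' @return A [taxonomy()] object.
#' @export
read_ncbi_nodes <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_structure(paste0("empty nodes.dmp file: ", path))
  parts <- strsplit(lines, "|", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    abort_parse(sprintf("malformed nodes.dmp row at line %d: %s", bad[1], lines[bad[1]]))
  }
  field <- function(k) {
    vapply(parts, function(p) if (length(p) >= k) trimws(p[[k]]) else NA_character_, character(1))
  }
  taxonomy(data.frame(
    taxon_id = field(1L),
    parent_id = field(2L),
    rank = field(3L),
    stringsAsFactors = FALSE
  ))
}

#' Read a child–parent edge list
#'
#' Reads a two-column tab-separated file of `child<TAB>parent` edges (`#`
#' comments and blank lines allowed). The root is the one id that appears only
#' as a parent. Loading the same topology through [read_ncbi_nodes()] or this
#' function yields identical trees.
#'
#' @param path Path to the edge-list file.
#' @return A [taxonomy()] object.
#' @export
read_taxonomy_edges <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) abort_structure(paste0("empty edge list: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    abort_parse(sprintf("malformed edge row (need child<TAB>parent): %s", lines[bad[1]]))
  }
  child <- trimws(vapply(parts, `[[`, character(1), 1L))
  parent <- trimws(vapply(parts, `[[`, character(1), 2L))
  if (anyDuplicated(child)) {
    dup <- unique(child[duplicated(child)])
    abort_structure(paste0(
      "duplicate child row(s) in edge list: ",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  edges_to_taxonomy(child, parent)
}

# build a taxonomy from parallel child/parent id vectors
edges_to_taxonomy <- function(child, parent) {
  roots <- setdiff(unique(parent), child)
  if (length(roots) == 0L) {
    abort_structure("cycle detected: no id appears only as a parent")
  }
  if (length(roots) > 1L) {
    abort_structure(paste0(
      "multiple roots in edge list: ", paste(utils::head(roots, 5), collapse = ", ")
    ))
  }
  taxonomy(data.frame(
    taxon_id = c(roots, child),
    parent_id = c(NA_character_, parent),
    stringsAsFactors = FALSE
  ))
}

#' Write a taxonomy as a Newick string
#'
#' Serialises the topology (no branch lengths) for inspection with standard
#' tree viewers; internal node labels are the taxon ids.
#'
#' @param tree A [taxonomy()] object.
#' @param path Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "taxonomy"))
  build <- function(i) {
    kids <- tree$children[[i]]
    if (length(kids) == 0L) return(tree$ids[i])
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","), ")", tree$ids[i])
  }
  nwk <- paste0(build(tree$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Restrict a taxonomy to selected leaves and their ancestors
#'
#' Keeps the given tip taxa plus every ancestor up to the root. Levels in the
#' restricted tree are inherited from the original tree (the root stays at
#' level 1 and parent links are unchanged), so the level-L ancestor of any
#' kept taxon is the same before and after restriction.
#'
#' @param tree A [taxonomy()] object.
#' @param taxon_id Taxa (typically leaves) to retain.
#' @return A [taxonomy()] object over the retained nodes.
#' @export
restrict_taxonomy <- function(tree, taxon_id) {
  idx <- unique(taxon_index(tree, taxon_id))
  keep <- rep(FALSE, length(tree$ids))
  cur <- idx
  while (length(cur) > 0L) {
    fresh <- cur[!keep[cur]]
    keep[fresh] <- TRUE
    cur <- tree$parent[fresh]
    cur <- cur[!is.na(cur)]
  }
  kept <- which(keep)
  taxonomy(data.frame(
    taxon_id = tree$ids[kept],
    parent_id = ifelse(is.na(tree$parent[kept]), NA_character_, tree$ids[tree$parent[kept]]),
    rank = tree$rank[kept],
    stringsAsFactors = FALSE
  ))
}
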