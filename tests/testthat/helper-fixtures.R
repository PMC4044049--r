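# Shared fixtures: the three-domain toy example, generated tree shapes and
# brute-force oracles. Everything is built in code; no binary fixtures.

toy_domains_tree <- function() {
  taxonomy(data.frame(
    taxon_id = c("C", "A", "B", "E", "A1", "A2", "A3", "B1", "B2"),
    parent_id = c(NA, "C", "C", "C", "A", "A", "A", "B", "B"),
    stringsAsFactors = FALSE
  ))
}

# 11 homologs: 8 archaeal, 3 bacterial, none eukaryotic
toy_domains_pool <- function() {
  homolog_pool(data.frame(
    seq_id = sprintf("s%02d", 1:11),
    taxon_id = c("A1", "A1", "A1", "A1", "A2", "A2", "A2", "A3", "B1", "B1", "B2"),
    score = c(412, 398.5, 371.2, 305.9, 362.4, 344, 290.1, 277.6, 255.8, 213.3, 188),
    stringsAsFactors = FALSE
  ))
}

# level by explicit parent-hop counting, independent of the package's BFS
level_by_walk <- function(tree, taxon_id) {
  vapply(taxon_id, function(t) {
    hops <- 0L
    repeat {
      p <- taxon_parent(tree, t)
      if (is.na(p)) break
      t <- p
      hops <- hops + 1L
    }
    hops + 1L
  }, integer(1))
}

# --- enumeration of all rooted multifurcating tree shapes by leaf count ----
# A shape is "L" for a leaf or a list of child shapes; shapes are enumerated
# up to reordering of children (children chosen as multisets).
.shape_env <- new.env()
tree_shapes <- function(n_leaves) {
  key <- as.character(n_leaves)
  if (!is.null(.shape_env[[key]])) return(.shape_env[[key]])
  out <- if (n_leaves == 1L) list("L") else {
    acc <- list()
    partitions <- function(n, maxp) {
      if (n == 0) return(list(integer(0)))
      res <- list()
      for (p in seq(min(n, maxp), 1)) {
        for (rest in partitions(n - p, p)) res[[length(res) + 1L]] <- c(p, rest)
      }
      res
    }
    for (pt in partitions(n_leaves, n_leaves - 1L)) {
      if (length(pt) < 2L) next
      grps <- rle(pt)
      # for each group of equal part sizes, all multisets of shapes
      combos_per <- mapply(function(sz, cnt) {
        s <- tree_shapes(sz)
        ms <- utils::combn(length(s) + cnt - 1L, cnt)
        apply(ms, 2, function(cc) cc - seq_len(cnt) + 1L, simplify = FALSE)
      }, grps$values, grps$lengths, SIMPLIFY = FALSE)
      grid <- expand.grid(lapply(combos_per, seq_along))
      for (gi in seq_len(nrow(grid))) {
        kids <- list()
        for (g in seq_along(grps$values)) {
          for (ix in combos_per[[g]][[grid[gi, g]]]) {
            kids[[length(kids) + 1L]] <- tree_shapes(grps$values[g])[[ix]]
          }
        }
        acc[[length(acc) + 1L]] <- kids
      }
    }
    acc
  }
  .shape_env[[key]] <- out
  out
}

shape_taxonomy <- function(shape) {
  rows <- list()
  cnt <- 0L
  walk <- function(s, parent) {
    cnt <<- cnt + 1L
    id <- sprintf("n%03d", cnt)
    rows[[length(rows) + 1L]] <<- data.frame(
      taxon_id = id, parent_id = parent, stringsAsFactors = FALSE
    )
    if (!identical(s, "L")) for (k in s) walk(k, id)
    id
  }
  walk(shape, NA_character_)
  taxonomy(do.call(rbind, rows))
}

one_seq_per_leaf <- function(tree) {
  leaves <- taxonomy_leaves(tree)
  homolog_pool(data.frame(
    seq_id = paste0("q_", leaves), taxon_id = leaves, score = 0,
    stringsAsFactors = FALSE
  ))
}

# brute-force maximum level-L coverage over every m-subset of the leaves
brute_max_coverage <- function(anc_L, m) {
  subsets <- utils::combn(length(anc_L), m)
  max(apply(subsets, 2, function(ix) {
    a <- anc_L[ix]
    length(unique(a[!is.na(a)]))
  }))
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
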