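#' Simulated taxonomy benchmarks
#'
#' A simulated benchmark couples a taxonomy (every node of a simulated tree is
#' a taxon, the root at level 1) with a homolog pool holding exactly one
#' record per leaf taxon, emulating a world where each leaf is one sequenced
#' organism. Three topology kinds are available: `symmetric` (complete binary
#' tree), `asymmetric` (a biased leaf selection from a larger complete binary
#' tree) and `random` (Yule growth). Similarity scores are all zero until
#' assigned by [synth_scores()]; taxonomy-aware and random sampling coverage
#' do not depend on them.
#'
#' @name sim_benchmark
NULL

new_benchmark <- function(tree, pool, kind, bias_x = NA_real_, seed = NA_integer_) {
  structure(
    list(tree = tree, pool = pool, kind = kind, bias_x = bias_x, seed = seed),
    class = "astax_benchmark"
  )
}

#' @export
print.astax_benchmark <- function(x, ...) {
  cat(sprintf(
    "<simulated benchmark> kind=%s%s, %d taxa, %d homolog(s), seed=%s\n",
    x$kind,
    if (is.na(x$bias_x)) "" else sprintf(" (x=%.2f)", x$bias_x),
    n_taxa(x$tree), nrow(x$pool),
    if (is.na(x$seed)) "none" else format(x$seed)
  ))
  invisible(x)
}

# zero-padded heap labels: node k of a complete binary tree is "t%0*d"
heap_ids <- function(k, width) sprintf("t%0*d", width, k)

# complete binary taxonomy with n_leaves leaves, heap-numbered so that the
# canonical (lexicographic) child order matches the heap order
complete_binary_taxonomy <- function(n_leaves) {
  n_nodes <- 2L * n_leaves - 1L
  width <- nchar(as.character(n_nodes))
  k <- seq_len(n_nodes)
  parent <- ifelse(k == 1L, NA_character_, heap_ids(k %/% 2L, width))
  taxonomy(data.frame(
    taxon_id = heap_ids(k, width), parent_id = parent,
    stringsAsFactors = FALSE
  ))
}

leaf_pool <- function(tree) {
  leaves <- taxonomy_leaves(tree)
  homolog_pool(tibble(
    seq_id = paste0("seq_", leaves), taxon_id = leaves, score = 0
  ))
}

#' Simulate a symmetric (complete binary) taxonomy
#'
#' Builds a complete binary taxonomy with the requested number of leaves
#' (which must be a power of two) and one homolog per leaf. With 1024 leaves
#' the root sits at level 1, the leaves at level 11, and level L holds
#' `2^(L-1)` taxa.
#'
#' @param n_leaves Number of leaf taxa; a power of two.
#' @return An `astax_benchmark` object (see [sim_benchmark]).
#' @export
simulate_symmetric <- function(n_leaves = 1024) {
  if (length(n_leaves) != 1L || is.na(n_leaves) || n_leaves < 1 ||
      bitwAnd(as.integer(n_leaves), as.integer(n_leaves) - 1L) != 0L) {
    abort_validation("`n_leaves` must be a power of two")
  }
  tree <- complete_binary_taxonomy(as.integer(n_leaves))
  new_benchmark(tree, leaf_pool(tree), "symmetric")
}

#' Simulate an asymmetric (biased) taxonomy
#'
#' Starts from a complete binary base tree with `2 * n_base_leaves`... more
#' precisely, a 2048-leaf complete binary tree by default, and selects
#' `n_select` leaves: a fraction `x` (rounded half-up) uniformly at random
#' from the left root branch and the remaining `1 - x` from the right branch.
#' The benchmark taxonomy is the base tree restricted to the selected leaves
#' and their ancestors, so levels are inherited from the base tree (root at
#' level 1, leaves at level 12 for the default size); the pool holds one
#' record per selected leaf. Small `x` therefore yields a sparsely sampled
#' left branch — a taxonomically biased pool.
#'
#' @param x Bias index in (0, 1); the fraction of selected leaves drawn from
#'   the left branch (0.1–0.4 in the reference simulations).
#' @param n_select Number of leaves to select (default 1024).
#' @param seed Integer seed for the leaf selection.
#' @param n_base_leaves Leaf count of the complete binary base tree (a power
#'   of two, default 2048).
#' @return An `astax_benchmark` object.
#' @export
simulate_asymmetric <- function(x, n_select = 1024, seed = NULL,
                                n_base_leaves = 2048) {
  if (length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort_validation("bias index `x` must lie strictly between 0 and 1")
  }
  base <- complete_binary_taxonomy(as.integer(n_base_leaves))
  half <- n_base_leaves / 2L
  n_left <- floor(x * n_select + 0.5)  # round half up
  n_right <- n_select - n_left
  if (n_left > half || n_right > half) {
    abort_validation(sprintf(
      "selection exceeds branch capacity: %d left / %d right from %d per branch",
      n_left, n_right, half
    ))
  }
  leaves <- taxonomy_leaves(base)
  # heap numbering: the first half of the sorted leaves descends from the
  # left child of the root
  left <- leaves[seq_len(half)]
  right <- leaves[half + seq_len(half)]
  pick <- function() c(
    left[sort(sample.int(length(left), n_left))],
    right[sort(sample.int(length(right), n_right))]
  )
  sel <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  tree <- restrict_taxonomy(base, sel)
  pool <- homolog_pool(tibble(
    seq_id = paste0("seq_", sel), taxon_id = sel, score = 0
  ))
  new_benchmark(tree, pool, "asymmetric", bias_x = x,
                seed = seed %||% NA_integer_)
}

#' Simulate a random (Yule) taxonomy
#'
#' Grows a random binary topology by repeatedly choosing an existing leaf
#' uniformly at random and bifurcating it, until `n_leaves` leaves exist
#' (a Yule process). One homolog is attached to each leaf.
#'
#' @param n_leaves Number of leaf taxa, at least 2.
#' @param seed Integer seed for the topology draw.
#' @return An `astax_benchmark` object.
#' @export
simulate_random <- function(n_leaves = 1024, seed = NULL) {
  if (length(n_leaves) != 1L || is.na(n_leaves) || n_leaves < 2) {
    abort_validation("`n_leaves` must be at least 2")
  }
  n_leaves <- as.integer(n_leaves)
  grow <- function() {
    n_nodes <- 2L * n_leaves - 1L
    parent <- integer(n_nodes)
    parent[1L] <- NA_integer_
    parent[2:3] <- 1L
    n_made <- 3L
    leaves <- c(2L, 3L)
    while (length(leaves) < n_leaves) {
      i <- sample.int(length(leaves), 1L)
      v <- leaves[i]
      parent[n_made + 1:2] <- v
      leaves <- c(leaves[-i], n_made + 1:2)
      n_made <- n_made + 2L
    }
    parent
  }
  parent <- if (is.null(seed)) grow() else withr::with_seed(seed, grow())
  width <- nchar(as.character(length(parent)))
  ids <- heap_ids(seq_along(parent), width)
  tree <- taxonomy(data.frame(
    taxon_id = ids,
    parent_id = ifelse(is.na(parent), NA_character_, ids[parent]),
    stringsAsFactors = FALSE
  ))
  new_benchmark(tree, leaf_pool(tree), "random", seed = seed %||% NA_integer_)
}

#' Assign synthetic similarity scores to a benchmark pool
#'
#' The coverage of taxonomy-aware and random sampling depends only on the
#' topology, but the similarity-sampling baseline needs a score ranking.
#' Two models are provided: `"uniform-random"` draws i.i.d. scores, giving a
#' random ranking; `"depth-correlated"` picks one focal leaf and scores every
#' leaf by the depth of its most recent shared ancestor with the focal leaf
#' plus a little noise, so the best-scoring sequences cluster inside a few
#' subtrees — the qualitative signature of similarity ranks around a real
#' query, which concentrates top hits in the query's own lineage.
#'
#' @param bench An `astax_benchmark` object.
#' @param model `"uniform-random"` or `"depth-correlated"`.
#' @param seed Integer seed.
#' @return The benchmark's pool (`astax_pool` tibble) with scores filled in.
#' @export
synth_scores <- function(bench, model = c("uniform-random", "depth-correlated"),
                         seed = NULL) {
  stopifnot(inherits(bench, "astax_benchmark"))
  model <- tryCatch(match.arg(model),
    error = function(e) abort_validation(paste0("unknown score model: ", model[1]))
  )
  pool <- bench$pool
  tree <- bench$tree
  n <- nrow(pool)
  compute <- function() {
    if (model == "uniform-random") return(stats::runif(n))
    focal <- pool$taxon_id[sample.int(n, 1L)]
    # depth (level) of the most recent common ancestor with the focal leaf
    focal_anc <- strsplit(taxon_lineage(tree, focal), ";", fixed = TRUE)[[1]]
    mrca_level <- vapply(pool$taxon_id, function(t) {
      path <- strsplit(taxon_lineage(tree, t), ";", fixed = TRUE)[[1]]
      k <- min(length(path), length(focal_anc))
      sum(cumprod(path[seq_len(k)] == focal_anc[seq_len(k)]))
    }, numeric(1))
    mrca_level + stats::runif(n, 0, 0.5)
  }
  score <- if (is.null(seed)) compute() else withr::with_seed(seed, compute())
  pool$score <- score
  pool
}

#' Write a benchmark to plain-text files
#'
#' Serialises a benchmark as `<prefix>_edges.tsv` (taxonomy edge list),
#' `<prefix>_homologs.tsv` (pool) and `<prefix>_config.json` (kind, bias,
#' seed); optionally also `<prefix>.nwk` with the topology in Newick form.
#'
#' @param bench An `astax_benchmark` object.
#' @param prefix Output path prefix.
#' @param newick Also write the Newick topology?
#' @return Character vector of the files written, invisibly.
#' @export
write_benchmark <- function(bench, prefix, newick = FALSE) {
  stopifnot(inherits(bench, "astax_benchmark"))
  nodes <- as_tibble(bench$tree)
  edges <- nodes[!is.na(nodes$parent_id), c("taxon_id", "parent_id")]
  f_edges <- paste0(prefix, "_edges.tsv")
  utils::write.table(edges, f_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  f_pool <- paste0(prefix, "_homologs.tsv")
  write_homolog_table(bench$pool, f_pool, header = FALSE)
  f_cfg <- paste0(prefix, "_config.json")
  jsonlite::write_json(
    list(kind = bench$kind,
         bias_x = if (is.na(bench$bias_x)) NULL else bench$bias_x,
         seed = if (is.na(bench$seed)) NULL else bench$seed,
         n_taxa = n_taxa(bench$tree), n_homologs = nrow(bench$pool)),
    f_cfg, auto_unbox = TRUE, digits = NA
  )
  files <- c(f_edges, f_pool, f_cfg)
  if (newick) {
    f_nwk <- paste0(prefix, ".nwk")
    write_newick(bench$tree, f_nwk)
    files <- c(files, f_nwk)
  }
  invisible(files)
}
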