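#' Even allocation of a sample quota over child taxa
#'
#' Splits `m` samples over a set of taxa as evenly as possible, respecting
#' each taxon's capacity. Writing G' for the number of taxa that contain at
#' least one homolog, the taxa are sorted by descending homolog count `n`
#' (ties by ascending taxon id); each of the G' non-empty taxa receives the
#' base quota `int(m/G')`, and the first `m - G' * int(m/G')` taxa in sorted
#' order receive one extra, so all non-zero quotas are equal or differ by 1.
#' Any quota exceeding its taxon's capacity is cut to `n` and the surplus is
#' redistributed one unit at a time, each unit to the smallest quota that
#' still has capacity (ties by the sorted order), until the quotas again sum
#' to `m` — so quotas of non-empty taxa whose capacity does not bind always
#' remain equal or differ by 1. Empty taxa always receive 0.
#'
#' @param counts A data frame with columns `taxon_id` (or `child_id`) and `n`,
#'   or a named integer vector of per-taxon homolog counts.
#' @param m Number of samples to allocate; must not exceed `sum(n)`.
#' @return A tibble with columns `taxon_id`, `n`, `quota`, in allocation order
#'   (descending `n`, ties by ascending taxon id).
#' @export
allocate <- function(counts, m) {
  if (is.data.frame(counts)) {
    idc <- if ("taxon_id" %in% names(counts)) "taxon_id" else "child_id"
    if (!idc %in% names(counts) || !"n" %in% names(counts)) {
      abort_validation("`counts` needs columns taxon_id (or child_id) and n")
    }
    ids <- as.character(counts[[idc]])
    n <- as.numeric(counts$n)
  } else {
    ids <- names(counts)
    n <- as.numeric(counts)
    if (is.null(ids)) abort_validation("`counts` vector must be named by taxon id")
  }
  if (length(m) != 1L || is.na(m) || m < 0 || m %% 1 != 0) {
    abort_validation("`m` must be a single non-negative integer")
  }
  if (any(is.na(n) | n < 0)) abort_validation("counts must be non-negative")
  quota <- allocate_core(as.integer(m), as.integer(round(n)), ids_tie_rank(ids))
  ord <- attr(quota, "alloc_order")
  tibble(taxon_id = ids[ord], n = as.integer(round(n))[ord], quota = as.integer(quota)[ord])
}

# canonical tie rank for a set of ids (numeric-aware, ".self" always last)
ids_tie_rank <- function(ids) {
  r <- integer(length(ids))
  r[order_ids(ids)] <- seq_along(ids)
  r[ids == ".self"] <- length(ids) + 1L
  r
}

# core allocation: quotas aligned to the input order; attr "alloc_order"
# gives the descending-n processing order over all taxa
allocate_core <- function(m, n, tie_rank) {
  total <- sum(n)
  if (m > total) {
    abort_capacity(sprintf(
      "requested sample size m (%d) exceeds available sequences n (%d)", m, total
    ))
  }
  ord <- order(-n, tie_rank, method = "radix")
  quota <- integer(length(n))
  nonempty <- ord[n[ord] > 0L]
  Gp <- length(nonempty)
  if (m > 0L && Gp > 0L) {
    base <- m %/% Gp
    q <- rep(base, Gp)
    extra <- m - Gp * base
    if (extra > 0L) q[seq_len(extra)] <- q[seq_len(extra)] + 1L
    cap <- n[nonempty]
    q <- pmin(q, cap)
    deficit <- m - sum(q)
    # water-filling: each surplus unit goes to the smallest quota that still
    # has capacity (ties by the sorted order), keeping uncapped quotas within
    # one of each other
    while (deficit > 0L) {
      room <- which(q < cap)
      j <- room[which.min(q[room])]
      q[j] <- q[j] + 1L
      deficit <- deficit - 1L
    }
    quota[nonempty] <- q
  }
  structure(quota, alloc_order = ord)
}

# shared validation for the three samplers
check_m <- function(m, n) {
  if (length(m) != 1L || is.na(m) || m %% 1 != 0) {
    abort_validation("`m` must be a single integer")
  }
  if (m < 0) abort_validation("`m` must be non-negative")
  if (m > n) {
    abort_capacity(sprintf(
      "requested sample size m (%d) exceeds pool size n (%d)", m, n
    ))
  }
  as.integer(m)
}

new_sample_result <- function(pool, rows, rules, tree = NULL, method, m, seed = NA) {
  sel <- pool[rows, c("seq_id", "taxon_id", "score"), drop = FALSE]
  lineage <- rep(NA_character_, length(rows))
  if (!is.null(tree) && length(rows) > 0L) {
    u <- unique(sel$taxon_id)
    lin <- vapply(u, function(t) taxon_lineage(tree, t), character(1))
    lineage <- unname(lin[match(sel$taxon_id, u)])
  }
  new_tibble(
    tibble(
      seq_id = sel$seq_id, taxon_id = sel$taxon_id, score = sel$score,
      lineage = lineage, rule = rules
    ),
    method = method, m_requested = m, seed = seed,
    class = "astax_sample"
  )
}

#' @export
print.astax_sample <- function(x, ...) {
  cat(sprintf(
    "<%s sample> %d of %d requested sequence(s)\n",
    attr(x, "method"), nrow(x), attr(x, "m_requested")
  ))
  NextMethod()
}

#' Taxonomy-aware sampling of homologous sequences (AST)
#'
#' Selects `m` of the pool's `n` homologs so that taxonomic diversity is
#' maximised and sampling is as even as possible across taxa. Starting at the
#' root, the quota is split over the direct children of the current taxon
#' with [allocate()]; a child receiving a quota greater than 1 is descended
#' recursively, a leaf taxon contributes its highest-scoring sequences, and a
#' child whose quota reaches exactly 1 contributes the single highest-scoring
#' sequence of its whole subtree. Sequences attached to an internal taxon
#' itself compete as a pseudo-child of that taxon. The procedure is fully
#' deterministic: all ties are broken by ascending taxon or sequence id.
#'
#' @param pool A data frame of homologs (see [homolog_pool()]).
#' @param tree A [taxonomy()] resolving every record's taxon.
#' @param m Number of sequences to select (`0 <= m <= n`).
#' @param root Taxon at which to start; defaults to the tree root. All pool
#'   records must lie in the subtree of `root`.
#' @return A tibble of class `astax_sample` with columns `seq_id`,
#'   `taxon_id`, `score`, `lineage` (root-to-taxon path) and `rule`
#'   (`"leaf-top-similarity"` or `"singleton-best-in-subtree"`).
#' @export
ast_sample <- function(pool, tree, m, root = NULL) {
  pool <- if (inherits(pool, "astax_pool")) pool else homolog_pool(pool)
  stopifnot(inherits(tree, "taxonomy"))
  m <- check_m(m, nrow(pool))
  rec_idx <- match(pool$taxon_id, tree$ids)
  if (anyNA(rec_idx)) {
    bad <- unique(pool$taxon_id[is.na(rec_idx)])
    abort_validation(paste0(
      "homolog taxon id(s) absent from taxonomy: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  root_idx <- if (is.null(root)) tree$root else taxon_index(tree, root)
  if (root_idx != tree$root && nrow(pool) > 0L) {
    anc <- ancestor_at_level(tree, pool$taxon_id, tree$level[root_idx])
    if (any(is.na(anc) | anc != tree$ids[root_idx])) {
      abort_validation("all pool records must lie under the sampling root")
    }
  }
  if (m == 0L || nrow(pool) == 0L) {
    return(new_sample_result(pool, integer(0), character(0), tree,
                             method = "AST", m = m))
  }

  nn <- length(tree$ids)
  self_n <- tabulate(rec_idx, nbins = nn)
  # records per taxon, best first (score desc, seq id asc)
  rec_order <- order_by_score(pool$score, pool$seq_id)
  rec_rank <- integer(nrow(pool))
  rec_rank[rec_order] <- seq_along(rec_order)
  recs_by_taxon <- split(rec_order, factor(rec_idx[rec_order], levels = seq_len(nn)))
  # bottom-up pass: subtree record counts and best record per subtree
  deep_first <- order(tree$level, decreasing = TRUE)
  subtree_n <- self_n
  best <- vapply(recs_by_taxon, function(r) {
    if (length(r) > 0L) r[[1L]] else NA_integer_
  }, integer(1))
  for (i in deep_first) {
    p <- tree$parent[i]
    if (is.na(p)) next
    subtree_n[p] <- subtree_n[p] + subtree_n[i]
    if (!is.na(best[i]) && (is.na(best[p]) || rec_rank[best[i]] < rec_rank[best[p]])) {
      best[p] <- best[i]
    }
  }

  sel_rows <- integer(m)
  sel_rule <- character(m)
  n_sel <- 0L
  emit <- function(rows, rule) {
    k <- length(rows)
    sel_rows[n_sel + seq_len(k)] <<- rows
    sel_rule[n_sel + seq_len(k)] <<- rule
    n_sel <<- n_sel + k
  }
  descend <- function(node, q) {
    if (q == 0L) return(invisible())
    kids <- tree$children[[node]]
    if (length(kids) == 0L) {
      emit(recs_by_taxon[[node]][seq_len(q)], "leaf-top-similarity")
    } else if (q == 1L) {
      emit(best[node], "singleton-best-in-subtree")
    } else {
      n_vec <- c(subtree_n[kids], self_n[node])
      tie <- c(ids_tie_rank(tree$ids[kids]), length(kids) + 1L)
      quota <- allocate_core(q, n_vec, tie)
      for (j in attr(quota, "alloc_order")) {
        if (quota[j] == 0L) next
        if (j > length(kids)) {
          emit(recs_by_taxon[[node]][seq_len(quota[j])], "leaf-top-similarity")
        } else {
          descend(kids[j], quota[j])
        }
      }
    }
    invisible()
  }
  descend(root_idx, m)
  new_sample_result(pool, sel_rows, sel_rule, tree, method = "AST", m = m)
}

#' Similarity sampling (SS baseline)
#'
#' Takes the `m` homologs with the highest similarity score to the query,
#' ties broken by ascending sequence id.
#'
#' @inheritParams ast_sample
#' @param tree Optional taxonomy used only to annotate lineages.
#' @return An `astax_sample` tibble.
#' @export
ss_sample <- function(pool, m, tree = NULL) {
  pool <- if (inherits(pool, "astax_pool")) pool else homolog_pool(pool)
  m <- check_m(m, nrow(pool))
  rows <- order_by_score(pool$score, pool$seq_id)[seq_len(m)]
  new_sample_result(pool, rows, rep("top-similarity", m), tree,
                    method = "SS", m = m)
}

#' Random sampling (RS baseline)
#'
#' Uniform sampling of `m` homologs without replacement. With a `seed` the
#' draw is reproducible and the caller's RNG state is left untouched.
#'
#' @inheritParams ss_sample
#' @param seed Optional integer seed for a self-contained reproducible draw.
#' @return An `astax_sample` tibble.
#' @export
rs_sample <- function(pool, m, seed = NULL, tree = NULL) {
  pool <- if (inherits(pool, "astax_pool")) pool else homolog_pool(pool)
  m <- check_m(m, nrow(pool))
  draw <- function() sample.int(nrow(pool), m)
  rows <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_sample_result(pool, rows, rep("uniform-random", m), tree,
                    method = "RS", m = m, seed = seed %||% NA)
}

#' Write a sample result as TSV
#'
#' @param result An `astax_sample` tibble.
#' @param path Output path.
#' @param config Optional named list echoed as a `# config: {...}` JSON
#'   comment line, so the run can be reproduced from the file alone.
#' @return `path`, invisibly.
#' @export
write_sample_result <- function(result, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(paste0(
      "# config: ",
      jsonlite::toJSON(config, auto_unbox = TRUE, null = "null", digits = NA)
    ), con)
  }
  utils::write.table(as.data.frame(result), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
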