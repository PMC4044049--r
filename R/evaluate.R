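#' Taxonomic coverage of a selection at a given level
#'
#' Counts the distinct level-`level` ancestor taxa represented by a set of
#' sequences (a sample result, a whole homolog pool, or any data frame with a
#' `taxon_id` column). A sequence whose own taxon sits above the requested
#' level contributes nothing.
#'
#' @param selection A data frame with a `taxon_id` column.
#' @param tree A [taxonomy()] object.
#' @param level Taxonomic level (root = 1).
#' @return Integer count of distinct covered taxa at that level.
#' @export
coverage_at_level <- function(selection, tree, level) {
  if (is.data.frame(selection)) {
    if (!"taxon_id" %in% names(selection)) {
      abort_validation("`selection` must have a taxon_id column")
    }
    taxa <- selection$taxon_id
  } else {
    taxa <- as.character(selection)
  }
  if (length(taxa) == 0L) return(0L)
  anc <- ancestor_at_level(tree, taxa, level)
  length(unique(anc[!is.na(anc)]))
}

#' Run a replicate coverage benchmark
#'
#' Generates `n_replicates` simulated benchmarks of the requested kind, runs
#' each sampling method at each sample size `m`, and records the taxonomic
#' coverage at each requested level, together with the coverage of the full
#' pool (`all-seq`), which upper-bounds every sampler. All randomness (leaf
#' selections, random topologies, synthetic scores, random-sampling draws)
#' derives from `base_seed`, so the whole table is reproducible.
#'
#' @param kind `"asymmetric"`, `"symmetric"` or `"random"` (see
#'   [simulate_asymmetric()], [simulate_symmetric()], [simulate_random()]).
#' @param x Bias index for asymmetric benchmarks.
#' @param n_leaves Pool size: leaves selected (asymmetric) or grown
#'   (symmetric/random).
#' @param m_list Sample sizes to evaluate.
#' @param n_replicates Number of replicate trees.
#' @param methods Subset of `c("AST", "RS", "SS", "all-seq")`.
#' @param levels Taxonomic levels at which to measure coverage; `NULL` means
#'   every level of the tree.
#' @param base_seed Integer master seed.
#' @param score_model Score model passed to [synth_scores()] (only the SS
#'   method is sensitive to it).
#' @param sd_type `"population"` (divide by N, the default) or `"sample"`
#'   (divide by N-1) for the summary standard deviations.
#' @return An object of class `astax_coverage`: a list with tibbles
#'   `coverage` (replicate, seed, method, m, level, coverage) and `summary`
#'   (method, m, level, mean, sd, n_replicates), plus the run configuration.
#' @export
run_benchmark <- function(kind = c("asymmetric", "symmetric", "random"),
                          x = 0.1, n_leaves = 1024,
                          m_list = c(50, 100, 200, 300, 400, 500),
                          n_replicates = 100,
                          methods = c("AST", "RS", "SS", "all-seq"),
                          levels = 8, base_seed = 1,
                          score_model = "uniform-random",
                          sd_type = c("population", "sample")) {
  kind <- match.arg(kind)
  sd_type <- match.arg(sd_type)
  methods <- match.arg(methods, c("AST", "RS", "SS", "all-seq"), several.ok = TRUE)
  if (length(n_replicates) != 1L || is.na(n_replicates) || n_replicates < 1) {
    abort_validation("`n_replicates` must be at least 1")
  }
  if (any(m_list > n_leaves)) {
    abort_capacity("every m in `m_list` must be <= the number of leaves")
  }
  seeds <- withr::with_seed(base_seed, {
    matrix(sample.int(.Machine$integer.max, 3L * n_replicates),
           nrow = n_replicates)
  })

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    bench <- switch(kind,
      asymmetric = simulate_asymmetric(x, n_select = n_leaves, seed = seeds[r, 1]),
      symmetric = simulate_symmetric(n_leaves),
      random = simulate_random(n_leaves, seed = seeds[r, 1])
    )
    pool <- synth_scores(bench, model = score_model, seed = seeds[r, 2])
    tree <- bench$tree
    lv <- levels %||% seq_len(max(tree$level))
    per <- list()
    for (method in methods) {
      mm <- if (method == "all-seq") nrow(pool) else m_list
      for (m in mm) {
        sel <- switch(method,
          "AST" = ast_sample(pool, tree, m),
          "SS" = ss_sample(pool, m),
          "RS" = rs_sample(pool, m, seed = seeds[r, 3] %% 2147483646L + m),
          "all-seq" = pool
        )
        cov <- vapply(lv, function(L) coverage_at_level(sel, tree, L), integer(1))
        per[[length(per) + 1L]] <- tibble(
          replicate = r, seed = seeds[r, 1], method = method,
          m = m, level = lv, coverage = cov
        )
      }
    }
    rows[[r]] <- dplyr::bind_rows(per)
  }
  coverage <- dplyr::bind_rows(rows)

  sd_fun <- if (sd_type == "population") {
    function(v) sqrt(mean((v - mean(v))^2))
  } else {
    stats::sd
  }
  summary <- coverage |>
    dplyr::group_by(.data$method, .data$m, .data$level) |>
    dplyr::summarise(
      mean = mean(.data$coverage),
      sd = sd_fun(.data$coverage),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(
      coverage = coverage, summary = summary,
      config = list(
        kind = kind, x = if (kind == "asymmetric") x else NULL,
        n_leaves = n_leaves, m_list = m_list, n_replicates = n_replicates,
        methods = methods, levels = levels, base_seed = base_seed,
        score_model = score_model, sd_type = sd_type
      )
    ),
    class = "astax_coverage"
  )
}

#' @export
print.astax_coverage <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<coverage benchmark> kind=%s%s, %d replicate(s), methods: %s\n",
    cfg$kind, if (is.null(cfg$x)) "" else sprintf(" (x=%.2f)", cfg$x),
    cfg$n_replicates, paste(cfg$methods, collapse = ", ")
  ))
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_benchmark
#' @param x An `astax_coverage` object.
#' @param ... Unused.
#' @export
tidy.astax_coverage <- function(x, ...) x$summary

#' @rdname run_benchmark
#' @export
glance.astax_coverage <- function(x, ...) {
  cfg <- x$config
  tibble(
    kind = cfg$kind, x = cfg$x %||% NA_real_, n_leaves = cfg$n_leaves,
    n_replicates = cfg$n_replicates,
    n_methods = length(cfg$methods), n_m = length(cfg$m_list),
    base_seed = cfg$base_seed
  )
}

#' Plot a coverage benchmark
#'
#' Mean coverage (±1 sd ribbon) against the number of sampled sequences, one
#' line per method, faceted by taxonomic level.
#'
#' @param object An `astax_coverage` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @export
autoplot.astax_coverage <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(
    s[s$method != "all-seq", ],
    ggplot2::aes(x = .data$m, y = .data$mean, colour = .data$method)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd,
                   fill = .data$method),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = s[s$method == "all-seq", ],
      ggplot2::aes(yintercept = .data$mean),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(~level, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "sequences sampled (m)", y = "taxa covered",
      colour = "method", fill = "method"
    ) +
    ggplot2::theme_minimal()
}

#' Write a coverage benchmark to TSV files
#'
#' Writes `<prefix>_coverage.tsv` (tidy per-replicate rows),
#' `<prefix>_summary.tsv` (mean and sd per method, m and level) and
#' `<prefix>_config.json` (the resolved run configuration).
#'
#' @param result An `astax_coverage` object.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_coverage_table <- function(result, prefix) {
  stopifnot(inherits(result, "astax_coverage"))
  f_cov <- paste0(prefix, "_coverage.tsv")
  f_sum <- paste0(prefix, "_summary.tsv")
  f_cfg <- paste0(prefix, "_config.json")
  utils::write.table(as.data.frame(result$coverage), f_cov, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- as.data.frame(result$summary)
  s$mean <- formatC(s$mean, format = "fg", digits = 15)
  s$sd <- formatC(s$sd, format = "fg", digits = 15)
  utils::write.table(s, f_sum, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$config, f_cfg, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(f_cov, f_sum, f_cfg))
}

#' Mann–Whitney rank-sum test
#'
#' Two-sample Mann–Whitney U test. For small problems (combined n of 20 or
#' fewer) the null distribution of U is obtained exactly by enumerating every
#' assignment of the pooled observations to the two groups (which also
#' handles ties correctly, as a permutation test); for larger samples the
#' normal approximation with tie correction and continuity correction is
#' used. `U` is the number of pairs won by `a` (ties count one half).
#'
#' @param a,b Numeric vectors.
#' @param alternative `"two.sided"`, `"less"` (a tends smaller than b) or
#'   `"greater"`.
#' @param exact_max Largest combined sample size for which the exact
#'   enumeration is used.
#' @return An object of class `htest` with components `statistic` (U for the
#'   first sample) and `p.value`.
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "less", "greater"),
                         exact_max = 20) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort_validation("both samples must be non-empty")
  }
  if (anyNA(a) || anyNA(b)) abort_validation("samples must not contain NA")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (N <= exact_max) {
    combos <- utils::combn(N, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p <- switch(alternative,
      less = mean(u_all <= u_obs),
      greater = mean(u_all >= u_obs),
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    )
    method <- "Mann-Whitney rank-sum test (exact enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    z <- u_obs - mu
    correction <- switch(alternative,
      two.sided = sign(z) * 0.5, less = -0.5, greater = 0.5
    )
    z <- (z - correction) / sigma
    p <- switch(alternative,
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE),
      two.sided = min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    )
    method <- "Mann-Whitney rank-sum test (normal approximation)"
  }
  structure(
    list(
      statistic = c(U = u_obs), p.value = p, alternative = alternative,
      method = method, data.name = "a and b"
    ),
    class = "htest"
  )
}
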