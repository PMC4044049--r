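test_that("coverage counts distinct ancestors at the requested level", {
  tree <- toy_domains_tree()
  pool <- toy_domains_pool()
  expect_equal(coverage_at_level(pool, tree, 1), 1L)
  expect_equal(coverage_at_level(pool, tree, 2), 2L) # A and B; E empty
  expect_equal(coverage_at_level(pool, tree, 3), 5L)
  # sequences above the level contribute nothing
  above <- homolog_pool(data.frame(seq_id = "x", taxon_id = "A", score = 1))
  expect_equal(coverage_at_level(above, tree, 3), 0L)
  expect_equal(coverage_at_level(pool[0, ], tree, 2), 0L)
  bad <- data.frame(taxon_id = "nope")
  expect_error(coverage_at_level(bad, tree, 2), class = "astax_lookup_error")
})

test_that("coverage matches an exhaustive ancestor count on a deep tree", {
  tree <- simulate_symmetric(2048)$tree # leaves at level 12
  leaves <- taxonomy_leaves(tree)
  withr::local_seed(31)
  picked <- sample(leaves, 50)
  sel <- data.frame(taxon_id = picked)
  for (L in c(1, 5, 8, 12)) {
    # oracle: climb each taxon with repeated parent lookups
    anc <- vapply(picked, function(t) {
      while (taxon_level(tree, t) > L) t <- taxon_parent(tree, t)
      t
    }, character(1))
    expect_equal(coverage_at_level(sel, tree, L), length(unique(anc)))
  }
})

test_that("replicate benchmarks are deterministic and internally consistent", {
  args <- list(
    kind = "random", n_leaves = 64, m_list = c(8, 16, 32),
    n_replicates = 5, methods = c("AST", "RS", "SS", "all-seq"),
    levels = c(3, 5), base_seed = 77
  )
  r1 <- do.call(run_benchmark, args)
  r2 <- do.call(run_benchmark, args)
  expect_identical(r1$coverage, r2$coverage)
  cov <- r1$coverage

  # all-seq upper-bounds every method per replicate and level
  wide <- merge(
    cov[cov$method != "all-seq", ],
    cov[cov$method == "all-seq", c("replicate", "level", "coverage")],
    by = c("replicate", "level"), suffixes = c("", "_all")
  )
  expect_true(all(wide$coverage <= wide$coverage_all))
  # no sampler covers more taxa than sequences sampled
  expect_true(all(wide$coverage <= wide$m))
  # coverage never exceeds the number of taxa at the level
  expect_true(all(cov$coverage[cov$level == 3] <= 4))

  # coverage is non-decreasing in m for the deterministic samplers
  for (meth in c("AST", "SS")) {
    sub <- cov[cov$method == meth, ]
    agg <- stats::aggregate(coverage ~ replicate + level, data = sub,
                            FUN = function(v) all(diff(v) >= 0))
    expect_true(all(agg$coverage))
  }
})

test_that("taxonomy-aware sampling beats random sampling on average", {
  res <- run_benchmark(
    kind = "random", n_leaves = 128, m_list = c(16, 32),
    n_replicates = 30, methods = c("AST", "RS"), levels = c(4, 6),
    base_seed = 5
  )
  s <- res$summary
  for (m in c(16, 32)) {
    for (L in c(4, 6)) {
      expect_gte(
        s$mean[s$method == "AST" & s$m == m & s$level == L],
        s$mean[s$method == "RS" & s$m == m & s$level == L]
      )
    }
  }
})

test_that("population and sample standard deviations are both available", {
  args <- list(kind = "random", n_leaves = 32, m_list = 8, n_replicates = 10,
               methods = "RS", levels = 3, base_seed = 2)
  pop <- do.call(run_benchmark, c(args, sd_type = "population"))
  smp <- do.call(run_benchmark, c(args, sd_type = "sample"))
  v <- pop$coverage$coverage
  expect_equal(pop$summary$sd, sqrt(mean((v - mean(v))^2)))
  expect_equal(smp$summary$sd, stats::sd(v))
})

test_that("coverage tables expose tidy/glance/autoplot and serialise", {
  res <- run_benchmark(kind = "random", n_leaves = 32, m_list = c(4, 8),
                       n_replicates = 3, methods = c("AST", "all-seq"),
                       levels = 3, base_seed = 9)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("method", "m", "level", "mean", "sd") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")

  prefix <- file.path(withr::local_tempdir(), "cov")
  files <- write_coverage_table(res, prefix)
  expect_true(all(file.exists(files)))
  back <- utils::read.table(paste0(prefix, "_coverage.tsv"), header = TRUE,
                            sep = "\t")
  expect_equal(nrow(back), nrow(res$coverage))
})

test_that("rank-sum test matches exhaustive enumeration on small samples", {
  # fully separated 3 vs 3: one-sided P = 1 / C(6,3) = 0.05
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 1 / 20)
  # identical lists: two-sided exact P = 1
  mw2 <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(mw2$p.value, 1)
  # U counts pairwise wins of the first sample
  mw3 <- mann_whitney(c(10, 20), c(1, 2))
  expect_equal(unname(mw3$statistic), 4)
  expect_error(mann_whitney(numeric(0), 1), class = "astax_validation_error")
})

test_that("rank-sum test agrees with the reference implementation", {
  withr::local_seed(12)
  for (i in 1:20) {
    a <- round(stats::rnorm(sample(3:8, 1)), 2)
    b <- round(stats::rnorm(sample(3:8, 1), mean = 0.5), 2)
    for (alt in c("two.sided", "less", "greater")) {
      mine <- mann_whitney(a, b, alternative = alt)
      ref <- suppressWarnings(stats::wilcox.test(a, b, alternative = alt,
                                                 exact = TRUE))
      expect_equal(unname(mine$statistic), unname(ref$statistic))
      if (!any(duplicated(c(a, b)))) {
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
      }
    }
  }
  # large-sample normal approximation vs reference with continuity correction
  a <- stats::rnorm(30)
  b <- stats::rnorm(35, 0.3)
  for (alt in c("two.sided", "less", "greater")) {
    mine <- mann_whitney(a, b, alternative = alt)
    ref <- stats::wilcox.test(a, b, alternative = alt, exact = FALSE,
                              correct = TRUE)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-8)
  }
})
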