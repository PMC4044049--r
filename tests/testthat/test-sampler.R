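test_that("allocation matches the worked examples", {
  # 11 homologs under {A: 8, B: 3, E: 0}, m = 5: base int(5/2) = 2 to both
  # non-empty taxa, the largest gets the remainder
  a <- allocate(c(A = 8, B = 3, E = 0), 5)
  expect_equal(a$quota[match(c("A", "B", "E"), a$taxon_id)], c(3L, 2L, 0L))
  expect_equal(sum(a$quota), 5L)

  # sampling everything returns the counts themselves
  a2 <- allocate(c(A = 8, B = 3, E = 0), 11)
  expect_equal(a2$quota[match(c("A", "B", "E"), a2$taxon_id)], c(8L, 3L, 0L))

  # capacity capping: base 2 exceeds A and C; surplus flows to B
  a3 <- allocate(c(A = 2, B = 10, C = 1), 6)
  expect_equal(a3$quota[match(c("A", "B", "C"), a3$taxon_id)], c(2L, 3L, 1L))

  # evenness at small m
  a4 <- allocate(c(A = 8, B = 3, E = 0), 2)
  expect_equal(a4$quota[match(c("A", "B", "E"), a4$taxon_id)], c(1L, 1L, 0L))

  # data-frame input, allocation order is descending n with id tie-break
  a5 <- allocate(data.frame(taxon_id = c("z", "y", "x"), n = c(2, 5, 2)), 4)
  expect_equal(a5$taxon_id, c("y", "x", "z"))
  expect_equal(a5$quota, c(2L, 1L, 1L))

  expect_error(allocate(c(A = 1, B = 1), 3), class = "astax_capacity_error")
})

test_that("allocation properties hold over thousands of random instances", {
  withr::local_seed(991)
  for (case in seq_len(2000)) {
    G <- sample(1:9, 1)
    n <- sample(0:12, G, replace = TRUE)
    if (sum(n) == 0) n[sample(G, 1)] <- 1L
    names(n) <- sprintf("T%02d", seq_len(G))
    m <- sample(0:sum(n), 1)
    a <- allocate(n, m)
    expect_equal(sum(a$quota), m)
    expect_true(all(a$quota <= a$n))
    expect_true(all(a$quota[a$n == 0] == 0))
    # among non-empty taxa whose capacity does not bind, quotas are equal
    # or differ by 1
    uncapped <- a$quota[a$n > 0 & a$quota < a$n]
    if (length(uncapped) > 1) {
      expect_lte(max(uncapped) - min(uncapped), 1)
    }
  }
})

test_that("taxonomy-aware sampling follows the recursion on the toy example", {
  tree <- toy_domains_tree()
  pool <- toy_domains_pool()

  # m = n returns everything
  all11 <- ast_sample(pool, tree, 11)
  expect_setequal(all11$seq_id, pool$seq_id)

  # m = 3: both non-empty domains covered, three distinct sub-taxa
  s3 <- ast_sample(pool, tree, 3)
  expect_equal(nrow(s3), 3L)
  expect_equal(coverage_at_level(s3, tree, 2), 2L)
  expect_equal(coverage_at_level(s3, tree, 3), 3L)
  # quota-1 selections take the best sequence of the subtree
  expect_true("s09" %in% s3$seq_id) # top-scoring bacterial sequence
  expect_equal(s3$rule[s3$seq_id == "s09"], "singleton-best-in-subtree")

  # leaf taxa contribute their highest-scoring sequences
  s6 <- ast_sample(pool, tree, 6)
  a1 <- s6$seq_id[s6$taxon_id == "A1"]
  expect_true(all(a1 %in% c("s01", "s02"))) # best of A1 first

  # validation
  expect_error(ast_sample(pool, tree, 12), class = "astax_capacity_error")
  expect_error(ast_sample(pool, tree, -1), class = "astax_validation_error")
  expect_equal(nrow(ast_sample(pool, tree, 0)), 0L)
})

test_that("sampling spreads quota one-per-subtree on a deep balanced taxonomy", {
  bench <- simulate_symmetric(2048)
  s <- ast_sample(bench$pool, bench$tree, 128)
  expect_equal(coverage_at_level(s, bench$tree, 8), 128L)
})

test_that("records on internal taxa stay sampleable via the self bucket", {
  tree <- toy_domains_tree()
  pool <- homolog_pool(data.frame(
    seq_id = c("i1", "i2", "l1"),
    taxon_id = c("A", "A", "B1"),
    score = c(10, 20, 5)
  ))
  s <- ast_sample(pool, tree, 3)
  expect_setequal(s$seq_id, c("i1", "i2", "l1"))
  s2 <- ast_sample(pool, tree, 2)
  expect_equal(nrow(s2), 2L)
  expect_equal(coverage_at_level(s2, tree, 2), 2L)
})

test_that("sampling below a chosen root uses only that subtree", {
  tree <- toy_domains_tree()
  pool <- toy_domains_pool()
  arch <- pool[pool$taxon_id %in% c("A1", "A2", "A3"), ]
  s <- ast_sample(arch, tree, 3, root = "A")
  expect_equal(coverage_at_level(s, tree, 3), 3L)
  expect_error(ast_sample(pool, tree, 3, root = "A"),
               class = "astax_validation_error")
})

test_that("similarity sampling takes the top scores with id tie-break", {
  pool <- homolog_pool(data.frame(
    seq_id = c("s1", "s2", "s3"), taxon_id = c("X", "Y", "Z"),
    score = c(90, 80, 70)
  ))
  tree <- read_taxonomy_edges(write_tmp(c("X\tR", "Y\tR", "Z\tR")))
  expect_equal(ss_sample(pool, 2)$seq_id, c("s1", "s2"))
  expect_equal(nrow(ss_sample(pool, 0)), 0L)
  tied <- homolog_pool(data.frame(
    seq_id = c("s4", "s2", "s3", "s1"), taxon_id = "X", score = 50
  ))
  expect_equal(ss_sample(tied, 2)$seq_id, c("s1", "s2"))
  expect_error(ss_sample(pool, 4), class = "astax_capacity_error")
})

test_that("random sampling is seed-reproducible and uniform over pairs", {
  pool <- homolog_pool(data.frame(
    seq_id = sprintf("s%d", 1:4), taxon_id = "X", score = 1:4
  ))
  expect_setequal(rs_sample(pool, 4, seed = 1)$seq_id, pool$seq_id)
  expect_identical(rs_sample(pool, 2, seed = 7)$seq_id,
                   rs_sample(pool, 2, seed = 7)$seq_id)

  # all C(4,2) = 6 pairs appear with frequency ~ 1/6 over many replicates
  n_rep <- 10000
  pairs <- vapply(seq_len(n_rep), function(i) {
    paste(sort(rs_sample(pool, 2, seed = i)$seq_id), collapse = "+")
  }, character(1))
  freq <- table(pairs) / n_rep
  expect_equal(length(freq), 6L)
  se3 <- 3 * sqrt((1 / 6) * (5 / 6) / n_rep)
  expect_true(all(abs(freq - 1 / 6) < se3))
})

test_that("taxonomy-aware sampling is deterministic", {
  bench <- simulate_random(200, seed = 44)
  pool <- synth_scores(bench, "uniform-random", seed = 9)
  r1 <- ast_sample(pool, bench$tree, 37)
  r2 <- ast_sample(pool, bench$tree, 37)
  expect_identical(r1, r2)
})

test_that("sample results serialise with an embedded config echo", {
  tree <- toy_domains_tree()
  s <- ast_sample(toy_domains_pool(), tree, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_result(s, path, config = list(m = 4, method = "AST", seed = 1))
  lines <- readLines(path)
  expect_match(lines[1], "^# config: \\{")
  re <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(re), 4L)
  expect_equal(re$seq_id, s$seq_id)
})

test_that("per-level coverage is optimal whenever all leaves share one depth", {
  # one sequence per leaf; exhaustive over shapes and subset sizes
  for (nl in 2:7) {
    for (shape in tree_shapes(nl)) {
      tax <- shape_taxonomy(shape)
      pool <- one_seq_per_leaf(tax)
      leaves <- pool$taxon_id
      lvs <- taxon_level(tax, leaves)
      if (length(unique(lvs)) != 1L) next
      lv_max <- max(lvs)
      anc <- lapply(seq_len(lv_max), function(L) ancestor_at_level(tax, leaves, L))
      for (m in seq_len(nl)) {
        sel_idx <- match(ast_sample(pool, tax, m)$taxon_id, leaves)
        for (L in seq_len(lv_max)) {
          cov <- length(unique(anc[[L]][sel_idx]))
          expect_equal(cov, brute_max_coverage(anc[[L]], m))
        }
      }
    }
  }
})
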