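write_pairs <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("pair files parse, deduplicate and validate", {
  ds <- read_interactions(write_pairs(c("D1\tT1", "D1\tT2", "D2\tT1")))
  expect_equal(nrow(ds$pairs), 3)
  expect_equal(ds$drug_ids, c("D1", "D2"))
  expect_equal(ds$target_ids, c("T1", "T2"))

  dup <- read_interactions(write_pairs(c("D1\tT1", "D1\tT1")))
  expect_equal(nrow(dup$pairs), 1)

  expect_error(read_interactions(write_pairs("D1")),
               "line 1", class = "dtiforge_parse_error")
  expect_error(read_interactions(write_pairs(c("# comment", "   "))),
               class = "dtiforge_empty_dataset_error")

  # comments and blank lines are skipped, whitespace dialect accepted
  ds2 <- read_interactions(write_pairs(c("# header", "", "D1   T1")))
  expect_equal(nrow(ds2$pairs), 1)
})

test_that("dataset summaries report counts and full-precision sparsity", {
  ds <- dti_dataset(cyclic_pairs(2, 2, 3))
  s <- dataset_summary(ds)
  expect_equal(s$n_drugs, 2)
  expect_equal(s$n_targets, 2)
  expect_equal(s$n_interactions, 3)
  expect_equal(s$sparsity, 0.75)

  one <- dataset_summary(dti_dataset(cyclic_pairs(1, 1, 1)))
  expect_equal(one$sparsity, 1.0)
})

test_that("summary is invariant to pair-file line shuffling", {
  lines <- sprintf("D%d\tT%d", c(1, 1, 2, 3, 3), c(1, 2, 2, 1, 3))
  s1 <- dataset_summary(read_interactions(write_pairs(lines)))
  s2 <- dataset_summary(read_interactions(write_pairs(rev(lines))))
  expect_equal(s1[c("n_targets", "n_drugs", "n_interactions", "sparsity")],
               s2[c("n_targets", "n_drugs", "n_interactions", "sparsity")])
})

test_that("negative sampling is balanced, disjoint and exhaustive when forced", {
  ds <- dti_dataset(tibble::tibble(drug_id = c("D1", "D2"),
                                   target_id = c("T1", "T2")))
  neg <- sample_negatives(ds, seed = 7)
  expect_equal(nrow(neg), 2)
  expect_setequal(paste(neg$drug_id, neg$target_id),
                  c("D1 T2", "D2 T1"))
  expect_true(all(neg$label == 0L))

  # all cross-product pairs positive -> infeasible
  full <- dti_dataset(cyclic_pairs(2, 2, 4))
  expect_error(sample_negatives(full, seed = 1),
               class = "dtiforge_sampling_error")
})

test_that("negatives are disjoint from positives and reproducible over seeds", {
  ds <- dti_dataset(cyclic_pairs(10, 10, 25))
  pos_keys <- paste(ds$pairs$drug_id, ds$pairs$target_id)
  for (seed in 1:100) {
    neg <- sample_negatives(ds, seed = seed)
    expect_equal(nrow(neg), 25)
    keys <- paste(neg$drug_id, neg$target_id)
    expect_length(unique(keys), 25)
    expect_length(intersect(keys, pos_keys), 0)
  }
  expect_identical(sample_negatives(ds, seed = 42),
                   sample_negatives(ds, seed = 42))
})

test_that("negative sampling is uniform over candidates", {
  ds <- dti_dataset(cyclic_pairs(3, 3, 1),
                    drug_ids = sprintf("D%d", 1:3),
                    target_ids = sprintf("T%d", 1:3))
  counts <- table(vapply(1:10000, function(seed) {
    n <- sample_negatives(ds, seed = seed, n = 1)
    paste(n$drug_id, n$target_id)
  }, character(1)))
  expect_length(counts, 8)
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})
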