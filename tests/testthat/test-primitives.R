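# map / tree-reduce / pipe primitives and the reduce plan.

numbers_ds <- function(values, n_partitions) {
  from_text(paste0(paste0(values, "\n"), collapse = ""), "\n", n_partitions)
}

test_that("plan_reduce follows the geometric schedule and counts invocations", {
  p <- plan_reduce(12, 2)
  expect_equal(p$levels, c(4L, 1L))
  expect_equal(p$invocations, 17L) # 12 + 4 + 1
  expect_equal(p$shuffles, 2L)

  expect_equal(plan_reduce(16, 4)$levels, c(8L, 4L, 2L, 1L))

  p1 <- plan_reduce(1, 2)
  expect_equal(p1$invocations, 1L)
  expect_equal(p1$shuffles, 0L)

  # levels strictly decreasing, ending at 1, for a grid of N and K
  for (n in c(2, 3, 7, 12, 16, 40)) {
    for (k in 1:4) {
      lv <- plan_reduce(n, k)$levels
      expect_true(all(diff(lv) < 0), info = sprintf("n=%d k=%d", n, k))
      expect_equal(lv[length(lv)], 1L)
      expect_lte(length(lv), k)
    }
  }
})

test_that("map transforms every partition, preserving count and order", {
  cfg <- test_config()
  dna <- c("ATGC", "GGCC", "AAAA", "GCGC")
  ds <- numbers_ds(dna, 2) # 2 partitions of 2 one-line records
  out <- map_partitions(ds, gc_step(), cfg)
  expect_equal(n_partitions(out), 2L)
  # per-partition oracle: count G/C characters natively
  oracle <- vapply(ds$partitions, function(p) {
    sum(strsplit(paste(p, collapse = ""), "")[[1]] %in% c("G", "C"))
  }, integer(1))
  expect_identical(collect_records(out), as.character(oracle))

  # identity command: record-wise identity, any partitioning
  ds2 <- numbers_ds(sprintf("r%03d", 1:37), 5)
  out2 <- map_partitions(ds2, identity_step(), cfg)
  expect_identical(out2$partitions, ds2$partitions)

  # empty partitions still reach the command (wc -l emits "0")
  wc <- container_step("ubuntu", "wc -l < /a > /b",
                       text_mount("/a"), text_mount("/b"))
  ds3 <- from_text("x", "\n", 3)
  out3 <- map_partitions(ds3, wc, cfg)
  expect_identical(trimws(collect_records(out3)), c("1", "0", "0"))
})

test_that("map failures report the partition index and fail the stage", {
  cfg <- test_config()
  boom <- container_step("ubuntu", "test -s /a && cp /a /b || exit 9",
                         text_mount("/a"), text_mount("/b"))
  ds <- new_ds(list("x", character(0), "y"))
  expect_error(map_partitions(ds, boom, cfg), "partition 1 failed.*code 9")
})

test_that("tree reduce equals native aggregation for every (N, K) in the grid", {
  cfg <- test_config()
  set.seed(4)
  values <- sample(1:500, 60, replace = TRUE)
  for (n in c(1, 2, 7, 12, 16)) {
    for (k in 1:3) {
      ds <- numbers_ds(values, n)
      out <- reduce_tree(ds, sum_step(), depth = k, cfg = cfg)
      expect_equal(n_partitions(out), 1L)
      expect_identical(collect_records(out), as.character(sum(values)),
                       info = sprintf("N=%d K=%d", n, k))
    }
  }
})

test_that("reduce over a single partition performs one aggregation, no shuffle", {
  cfg <- test_config()
  reset_ledger(cfg)
  ds <- numbers_ds(c(5, 7, 11), 1)
  out <- reduce_tree(ds, sum_step(), depth = 2, cfg = cfg)
  expect_identical(collect_records(out), "23")
  lc <- ledger_counts(cfg)
  expect_equal(lc$invocations, 1L)
  expect_equal(lc$shuffles, 0L)
})

test_that("instrumented N=12 K=2 reduce records 17 invocations and 2 shuffles", {
  cfg <- test_config()
  ds <- numbers_ds(1:12, 12)
  reset_ledger(cfg)
  out <- reduce_tree(ds, sum_step(), depth = 2, cfg = cfg)
  expect_identical(collect_records(out), "78")
  lc <- ledger_counts(cfg)
  expect_equal(lc$invocations, plan_reduce(12, 2)$invocations)
  expect_equal(lc$invocations, 17L)
  expect_equal(lc$shuffles, 2L)
})

test_that("empty partitions are dropped before reduce planning", {
  cfg <- test_config()
  ds <- new_ds(list(c("1", "2"), character(0), "3", character(0)))
  reset_ledger(cfg)
  out <- reduce_tree(ds, sum_step(), depth = 2, cfg = cfg)
  expect_identical(collect_records(out), "6")
  # planned for N=2 non-empty partitions: 2 + 1 invocations, 1 shuffle
  expect_equal(ledger_counts(cfg)$invocations, plan_reduce(2, 2)$invocations)
})

test_that("top-N tree reduce returns the globally best-scoring molecules", {
  cfg <- test_config()
  lib <- gen_sdf_library(300, seed = 7)
  records <- collect_records(from_text(lib, "\n$$$$\n", 1))
  want <- sort(vapply(top_n_records(records, 30), sdf_score, numeric(1),
                      USE.NAMES = FALSE))
  for (k in 1:2) {
    ds <- from_text(lib, "\n$$$$\n", 8)
    out <- reduce_tree(ds, top_n_step(30), depth = k, cfg = cfg)
    got <- collect_records(out)
    expect_length(got, 30)
    expect_equal(sort(vapply(got, sdf_score, numeric(1), USE.NAMES = FALSE)),
                 want, info = sprintf("K=%d", k))
  }
})

test_that("pipe and materialized execution agree for stream-safe commands", {
  cfg <- test_config()
  lines <- random_lines(200, seed = 5)
  ds <- numbers_ds(lines, 4)

  sort_pipe <- container_step("ubuntu", "sort",
                              text_mount("/i"), text_mount("/o"))
  sort_file <- container_step("ubuntu", "sort /i > /o",
                              text_mount("/i"), text_mount("/o"))
  expect_identical(pipe_partitions(ds, sort_pipe, cfg)$partitions,
                   map_partitions(ds, sort_file, cfg)$partitions)

  grep_pipe <- container_step("ubuntu", "grep -c [aeiou] || true",
                              text_mount("/i"), text_mount("/o"))
  grep_file <- container_step("ubuntu", "grep -c [aeiou] /i > /o || true",
                              text_mount("/i"), text_mount("/o"))
  expect_identical(pipe_partitions(ds, grep_pipe, cfg)$partitions,
                   map_partitions(ds, grep_file, cfg)$partitions)

  # cat is the identity under streaming
  cat_pipe <- container_step("ubuntu", "cat",
                             text_mount("/i"), text_mount("/o"))
  expect_identical(pipe_partitions(ds, cat_pipe, cfg)$partitions,
                   ds$partitions)
})

test_that("results are independent of the configured parallelism", {
  dna <- gen_dna(20000, 0.5, seed = 9)
  run_with <- function(workers) {
    cfg <- test_config(parallelism = workers)
    ds <- from_text(dna, "\n", 8)
    counts <- map_partitions(ds, gc_step(), cfg)
    collect_records(reduce_tree(counts, sum_step(), depth = 2, cfg = cfg))
  }
  serial <- run_with(1L)
  expect_identical(run_with(8L), serial)
  expect_identical(serial, as.character(gc_count(dna)))
})

test_that("a map with a binary output mount switches the dataset kind", {
  cfg <- test_config()
  ds <- numbers_ds(c("b", "a", "c"), 2)
  tobin <- container_step(
    "ubuntu", "sort /in.txt | gzip -n > /out/sorted_${TASK_ID}.gz",
    text_mount("/in.txt"), binary_mount("/out")
  )
  out <- map_partitions(ds, tobin, cfg)
  expect_identical(out$kind, "binary")
  expect_equal(n_partitions(out), 2L)
  recs <- collect_records(out)
  expect_length(recs, 2)
  expect_false(any(duplicated(names(recs)))) # TASK_ID keeps names unique
  # payloads are real gzip members holding the sorted lines
  f <- tempfile(fileext = ".gz")
  writeBin(recs[[1]], f)
  expect_identical(readLines(gzfile(f)), c("a", "b"))
})

test_that("cleanup policy 'always' leaves no staging dirs behind, pass or fail", {
  root <- local_dir("cleanroot")
  cfg <- execution_config(temp_space = temp_space(root, cleanup = "always"))
  ds <- from_text("1\n2\n3\n4", "\n", 2)
  invisible(reduce_tree(ds, sum_step(), depth = 2, cfg = cfg))
  expect_length(list.files(root), 0)
  boom <- container_step("ubuntu", "exit 2",
                         text_mount("/a"), text_mount("/b"))
  expect_error(map_partitions(ds, boom, cfg))
  expect_length(list.files(root), 0)

  keep <- execution_config(temp_space = temp_space(root, cleanup = "never"))
  invisible(map_partitions(ds, identity_step(), keep))
  expect_gt(length(list.files(root)), 0)
})
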