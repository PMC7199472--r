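# Partitioned dataset construction, repartitioning and collection.

test_that("from_text splits on the separator with terminator semantics", {
  ds <- from_text("AT\nGC\nTT", "\n", num_partitions = 2)
  expect_equal(ds$partitions, list(c("AT", "GC"), "TT"))

  # trailing terminator adds no empty record
  expect_identical(collect_records(from_text("AT\nGC\n", "\n", 1)),
                   c("AT", "GC"))
  # interior empty records survive
  expect_identical(collect_records(from_text("a\n\nb", "\n", 1)),
                   c("a", "", "b"))
  # empty source -> requested number of empty partitions, no error
  ds0 <- from_text("", "\n", 3)
  expect_equal(n_partitions(ds0), 3L)
  expect_equal(partition_sizes(ds0), c(0L, 0L, 0L))
  # empty separator is invalid
  expect_error(from_text("abc", "", 1), "separator")
})

test_that("SDF-style multi-character terminators give one record per molecule", {
  sdf <- paste0(
    paste0(c("MOL1\nbody1", "MOL2\nbody2", "MOL3\nbody3", "MOL4\nbody4"),
           "\n$$$$\n"),
    collapse = ""
  )
  ds <- from_text(sdf, "\n$$$$\n", num_partitions = 2)
  expect_equal(partition_sizes(ds), c(2L, 2L))
  expect_identical(collect_records(ds)[1], "MOL1\nbody1")
})

test_that("records are assigned to contiguous blocks of size ceiling(R/n)", {
  ds <- from_text(paste0(letters[1:10], collapse = "\n"), "\n", 3)
  expect_equal(partition_sizes(ds), c(4L, 4L, 2L))
  # fewer records than partitions leaves trailing partitions empty
  ds2 <- from_text("a\nb", "\n", 4)
  expect_equal(partition_sizes(ds2), c(1L, 1L, 0L, 0L))
})

test_that("from_binary_dir ingests files in lexicographic order and skips subdirs", {
  dir <- local_dir()
  for (nm in c("b.vcf.gz", "a.vcf.gz", "c.vcf.gz")) {
    writeBin(as.raw(utf8ToInt(nm)), file.path(dir, nm))
  }
  dir.create(file.path(dir, "nested"))
  expect_warning(ds <- from_binary_dir(dir, 2), "nested")
  expect_equal(partition_sizes(ds), c(2L, 1L))
  expect_identical(names(collect_records(ds)),
                   c("a.vcf.gz", "b.vcf.gz", "c.vcf.gz"))
  expect_error(from_binary_dir(file.path(dir, "missing"), 1), "not found")

  empty <- file.path(dir, "empty")
  dir.create(empty)
  ds0 <- from_binary_dir(empty, 1)
  expect_equal(partition_sizes(ds0), 0L)
})

test_that("binary round trip through a directory preserves the record multiset", {
  dir <- local_dir()
  set.seed(99)
  names <- sprintf("file%03d.bin", 1:100)
  payloads <- lapply(1:100, function(i) as.raw(sample(0:255, 50, TRUE)))
  for (i in 1:100) writeBin(payloads[[i]], file.path(dir, names[i]))

  ds <- from_binary_dir(dir, 7)
  expect_equal(n_partitions(ds), 7L)
  got <- collect_records(ds)
  # compare against a direct directory walk
  walk <- lapply(file.path(dir, names), function(p) {
    readBin(p, "raw", file.size(p))
  })
  names(walk) <- names
  expect_identical(got[order(names(got))], walk[order(names(walk))])
})

test_that("repartition re-blocks contiguously and honors the count contract", {
  ds <- new_ds(list(c("a", "b", "c"), c("d", "e", "f"), c("g", "h", "i"), "j"))
  out <- repartition(ds, 2)
  expect_equal(partition_sizes(out), c(5L, 5L))
  expect_identical(collect_records(out), letters[1:10])

  one <- repartition(ds, 1)
  expect_equal(n_partitions(one), 1L)
  expect_identical(collect_records(one), collect_records(ds))

  # identity on a single partition
  solo <- from_text("x\ny", "\n", 1)
  expect_identical(repartition(solo, 1)$partitions, solo$partitions)

  # empty partitions are legal and the count is exact
  expect_equal(n_partitions(repartition(ds, 25)), 25L)
})

test_that("repartition_by colocates equal keys in exactly one partition", {
  recs <- c("A1", "B1", "A2", "C1", "B2", "A3")
  ds <- from_text(paste0(recs, collapse = "\n"), "\n", 2)
  key <- function(r) substr(r, 1, 1)
  out <- repartition_by(ds, key, 3)

  keysets <- lapply(out$partitions, function(p) {
    unique(vapply(p, key, character(1), USE.NAMES = FALSE))
  })
  all_keys <- unlist(keysets)
  expect_false(any(duplicated(all_keys))) # each key in exactly one partition
  # all A records together, in stable origin order
  a_part <- keysets[vapply(keysets, function(k) "A" %in% k, logical(1))]
  expect_length(a_part, 1)
  apart <- out$partitions[[which(vapply(
    keysets, function(k) "A" %in% k, logical(1)
  ))]]
  expect_identical(apart[startsWith(apart, "A")], c("A1", "A2", "A3"))

  # single target partition collects everything
  expect_identical(sort(collect_records(repartition_by(ds, key, 1))),
                   sort(recs))
})

test_that("repartition_by preserves per-key counts for chromosome-tagged reads", {
  reads <- gen_tagged_reads(10000, seed = 11)
  key <- function(r) sub("\t.*", "", r)
  before <- key_histogram(reads, key)
  expect_equal(length(before), 23L)

  ds <- from_text(paste0(paste0(reads, "\n"), collapse = ""), "\n", 8)
  out <- repartition_by(ds, key, 14)
  expect_equal(n_partitions(out), 14L)
  after <- key_histogram(collect_records(out), key)
  expect_identical(before, after)

  # determinism: identical inputs yield byte-identical partitioning
  again <- repartition_by(ds, key, 14)
  expect_identical(out$partitions, again$partitions)
})

test_that("repartition_by reports the offending record when the key function fails", {
  ds <- from_text("ok\nbad\nok", "\n", 2)
  key <- function(r) if (r == "bad") stop("no key") else r
  expect_error(repartition_by(ds, key, 2), "partition 0, offset 1")
})

test_that("multiset conservation holds across chained repartitions", {
  for (seed in 1:5) {
    recs <- random_lines(57, seed)
    ds <- from_text(paste0(paste0(recs, "\n"), collapse = ""), "\n", 4)
    out <- ds
    out <- repartition(out, 9)
    out <- repartition_by(out, function(r) substr(r, 1, 2), 5)
    out <- repartition(out, 3)
    expect_identical(sort(collect_records(out)), sort(recs))
  }
})

test_that("text round trip re-joins to the source modulo trailing terminator", {
  for (seed in 1:5) {
    recs <- random_lines(40, seed + 100)
    src <- paste0(paste0(recs, "\n"), collapse = "")
    ds <- from_text(src, "\n", 6)
    rejoined <- paste0(paste0(collect_records(ds), "\n"), collapse = "")
    expect_identical(rejoined, src)
  }
})
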