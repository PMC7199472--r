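# Shared fixtures: execution configs staging under the test temp dir, and
# the handful of POSIX command steps the suite exercises repeatedly.

test_config <- function(parallelism = 1L, ...) {
  root <- file.path(tempdir(), "cmr-tests")
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  execution_config(
    backend = "subprocess", parallelism = parallelism,
    temp_space = temp_space(root), ...
  )
}

gc_step <- function() {
  container_step(
    "ubuntu", "grep -o [GC] /dna | wc -l > /count",
    input = text_mount("/dna"), output = text_mount("/count")
  )
}

sum_step <- function() {
  container_step(
    "ubuntu", "awk '{s += $1} END {print s + 0}' /counts > /sum",
    input = text_mount("/counts"), output = text_mount("/sum")
  )
}

identity_step <- function(separator = "\n") {
  container_step(
    "ubuntu", "cp /in.txt /out.txt",
    input = text_mount("/in.txt", separator),
    output = text_mount("/out.txt", separator)
  )
}

top_n_step <- function(n = 30) {
  script <- system.file("sh", "top_n.sh", package = "cmr")
  container_step(
    "ubuntu", paste("sh", script, "/in.sdf /out.sdf", n),
    input = text_mount("/in.sdf", "\n$$$$\n"),
    output = text_mount("/out.sdf", "\n$$$$\n")
  )
}

new_ds <- function(partitions, kind = "text", separator = "\n") {
  cmr:::new_dataset(partitions, kind, separator)
}

# fresh scratch directory under the session temp dir
local_dir <- function(prefix = "fixdir") {
  d <- tempfile(prefix)
  dir.create(d, recursive = TRUE)
  d
}

# seeded random line records without touching the caller's RNG
random_lines <- function(n, seed, width = 12L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c(letters, LETTERS, 0:9), width, replace = TRUE),
          collapse = "")
  }, character(1))
}
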