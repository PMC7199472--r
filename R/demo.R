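# Ready-made demo pipelines, one per flagship use case: GC counting over
# DNA text, virtual-screening-shaped top-N selection over an SDF library,
# and SNP-calling-shaped chromosome-wise repartitioning of tagged reads.
# Each demo generates its own seeded fixture, writes a YAML pipeline and
# runs it — `cmr demo gc --out DIR` from the CLI does exactly this.

demo_names <- c("gc", "vs", "snp")

#' Generate and run a demo pipeline
#'
#' Writes a seeded synthetic fixture and a ready YAML pipeline into
#' `out_dir`, runs the pipeline, and returns the run report plus an oracle
#' check computed natively in R:
#'
#' * `"gc"` — DNA text; map `grep -o [GC] | wc -l` per partition, then a
#'   depth-2 tree reduce summing the counts with `awk`. Oracle:
#'   [gc_count()] on the fixture.
#' * `"vs"` — SDF-dialect molecule library; map the toy docking stand-in,
#'   then tree-reduce with the keep-top-30 filter. Oracle:
#'   [top_n_records()] membership of the 30 best scores.
#' * `"snp"` — tagged reads; map a field-extracting parser, repartition by
#'   chromosome key, then per-partition compression to binary records and
#'   a binary-file concatenating reduce (clash-free names via
#'   `${TASK_ID}`). Oracle: per-chromosome [key_histogram()] and
#'   single-partition colocation of every key.
#'
#' @param which One of `"gc"`, `"vs"`, `"snp"`.
#' @param out_dir Directory for fixture, pipeline, output and report
#'   (created if needed).
#' @param seed Integer seed for the fixture and the run.
#' @param size Fixture size: bases for `"gc"` (default 1e6), molecules for
#'   `"vs"` (default 1000), reads for `"snp"` (default 10000).
#' @param engine,parallelism Execution overrides passed to
#'   [run_pipeline()].
#' @param quiet Suppress progress messages.
#' @return A list: `report` (from [run_pipeline()]), `oracle` (list of
#'   reference values and agreement flags), `pipeline` (YAML path),
#'   `fixture` (input path).
#' @export
demo_pipeline <- function(which = c("gc", "vs", "snp"), out_dir,
                          seed = 42L, size = NULL,
                          engine = "subprocess", parallelism = 1L,
                          quiet = FALSE) {
  which <- match.arg(which)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(which,
    gc = demo_gc(out_dir, seed, size %||% 1e6, engine, parallelism, quiet),
    vs = demo_vs(out_dir, seed, size %||% 1000L, engine, parallelism, quiet),
    snp = demo_snp(out_dir, seed, size %||% 10000L, engine, parallelism,
                   quiet)
  )
}

demo_gc <- function(out_dir, seed, bases, engine, parallelism, quiet) {
  fixture <- file.path(out_dir, "dna.txt")
  dna <- gen_dna(bases, gc_fraction = 0.5, seed = seed)
  writeBin(charToRaw(dna), fixture)
  spec <- list(
    input = list(path = fixture, kind = "text", separator = "\n",
                 partitions = 8L),
    steps = list(
      list(op = "map", image = "ubuntu",
           command = "grep -o [GC] /dna | wc -l > /count",
           input_mount = list(path = "/dna"),
           output_mount = list(path = "/count")),
      list(op = "reduce", image = "ubuntu", depth = 2L,
           command = "awk '{s += $1} END {print s}' /counts > /sum",
           input_mount = list(path = "/counts"),
           output_mount = list(path = "/sum"))
    ),
    output = list(path = file.path(out_dir, "gc_total.txt")),
    execution = list(engine = engine, parallelism = parallelism,
                     seed = seed)
  )
  yaml_path <- file.path(out_dir, "gc_pipeline.yaml")
  yaml::write_yaml(spec, yaml_path)
  report <- run_pipeline(yaml_path, quiet = quiet)
  got <- as.integer(readLines(spec$output$path, warn = FALSE)[1])
  want <- gc_count(dna)
  list(
    report = report,
    oracle = list(expected = want, observed = got, agrees = got == want),
    pipeline = yaml_path, fixture = fixture
  )
}

demo_vs <- function(out_dir, seed, n_molecules, engine, parallelism, quiet) {
  fixture <- file.path(out_dir, "library.sdf")
  lib <- gen_sdf_library(n_molecules, seed = seed)
  writeBin(charToRaw(lib), fixture)
  scorer <- system.file("sh", "toy_scorer.sh", package = "cmr")
  top_n <- system.file("sh", "top_n.sh", package = "cmr")
  sdf_sep <- "\n$$$$\n"
  spec <- list(
    input = list(path = fixture, kind = "text", separator = sdf_sep,
                 partitions = 8L),
    steps = list(
      list(op = "map", image = "ubuntu",
           command = paste("sh", scorer, "/in.sdf /out.sdf"),
           input_mount = list(path = "/in.sdf", separator = sdf_sep),
           output_mount = list(path = "/out.sdf", separator = sdf_sep)),
      list(op = "reduce", image = "ubuntu", depth = 2L,
           command = paste("sh", top_n, "/in.sdf /out.sdf 30"),
           input_mount = list(path = "/in.sdf", separator = sdf_sep),
           output_mount = list(path = "/out.sdf", separator = sdf_sep))
    ),
    output = list(path = file.path(out_dir, "top30.sdf"),
                  separator = sdf_sep),
    execution = list(engine = engine, parallelism = parallelism,
                     seed = seed)
  )
  yaml_path <- file.path(out_dir, "vs_pipeline.yaml")
  yaml::write_yaml(spec, yaml_path)
  report <- run_pipeline(yaml_path, quiet = quiet)

  records <- split_records(lib, sdf_sep)
  want <- sort(vapply(top_n_records(records, 30), sdf_score, numeric(1),
                      USE.NAMES = FALSE))
  out <- split_records(
    rawToChar(readBin(spec$output$path, "raw",
                      file.size(spec$output$path))),
    sdf_sep
  )
  got <- sort(vapply(out, sdf_score, numeric(1), USE.NAMES = FALSE))
  list(
    report = report,
    oracle = list(expected = want, observed = got,
                  agrees = length(got) == length(want) &&
                    isTRUE(all.equal(got, want))),
    pipeline = yaml_path, fixture = fixture
  )
}

demo_snp <- function(out_dir, seed, n_reads, engine, parallelism, quiet) {
  fixture <- file.path(out_dir, "reads.txt")
  reads <- gen_tagged_reads(n_reads, seed = seed)
  writeBin(charToRaw(join_records(reads, "\n")), fixture)
  spec <- list(
    input = list(path = fixture, kind = "text", separator = "\n",
                 partitions = 8L),
    steps = list(
      # toy aligner stand-in: normalize records to their three fields
      list(op = "map", image = "ubuntu",
           command = "cut -f1-3 /in.sam > /out.sam",
           input_mount = list(path = "/in.sam"),
           output_mount = list(path = "/out.sam")),
      # colocate all reads of a chromosome in one partition
      list(op = "repartition_by", key_regex = "^(chr[0-9XY]+)\t",
           partitions = 14L),
      # toy caller stand-in: per-chromosome-partition sorted, compressed
      # "calls"; ${TASK_ID} keeps file names clash-free across partitions
      list(op = "map", image = "ubuntu",
           command = "sort /in.sam | gzip -n > /out/calls_${TASK_ID}.gz",
           input_mount = list(path = "/in.sam"),
           output_mount = list(path = "/out", kind = "binary")),
      # binary-file reduce: concatenate gzip members into one archive
      list(op = "reduce", image = "ubuntu", depth = 2L,
           command = "cat /in/*.gz > /out/merged_${TASK_ID}.gz",
           input_mount = list(path = "/in", kind = "binary"),
           output_mount = list(path = "/out", kind = "binary"))
    ),
    output = list(path = file.path(out_dir, "calls"), kind = "binary"),
    execution = list(engine = engine, parallelism = parallelism,
                     seed = seed)
  )
  yaml_path <- file.path(out_dir, "snp_pipeline.yaml")
  yaml::write_yaml(spec, yaml_path)
  report <- run_pipeline(yaml_path, quiet = quiet)

  # colocation oracle: rebuild the repartition natively and check every
  # chromosome occupies exactly one partition with unchanged counts
  key_fn <- regex_key_fn("^(chr[0-9XY]+)\t")
  ds <- repartition_by(from_text(join_records(reads, "\n"), "\n", 8L),
                       key_fn, 14L)
  per_part_keys <- lapply(ds$partitions, function(p) {
    unique(vapply(p, key_fn, character(1), USE.NAMES = FALSE))
  })
  colocated <- !anyDuplicated(unlist(per_part_keys))
  hist_before <- key_histogram(reads, key_fn)
  hist_after <- key_histogram(flatten_records(ds), key_fn)
  list(
    report = report,
    oracle = list(
      colocated = isTRUE(colocated),
      counts_match = identical(hist_before, hist_after),
      agrees = isTRUE(colocated) && identical(hist_before, hist_after)
    ),
    pipeline = yaml_path, fixture = fixture
  )
}
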