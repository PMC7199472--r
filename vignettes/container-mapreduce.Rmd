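---
title: "Container-backed MapReduce: model, semantics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Container-backed MapReduce: model, semantics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmr)
```

## The problem and the model

Bioinformatics tools are overwhelmingly file-in, file-out command-line
programs, increasingly distributed as application containers. Scaling them
over large datasets usually means either rewriting the analysis inside a
data-processing framework (rarely sustainable) or orchestrating them with
a workflow engine through shared storage (which gives up data locality and
partition-level parallelism). `cmr` takes the MapReduce route instead: the
dataset is partitioned, and the *unit of computation is one container
invocation per partition*. The user supplies only an image reference, a
shell command, and mount points describing how a partition is exposed to
the command.

Concretely, a pipeline is a chain over a partitioned dataset:

```
from_text(...) |> map_partitions(step) |> reduce_tree(step, depth) |> collect_records()
```

with `repartition_by()` available when records must be grouped by a key
before a stage (e.g. all reads of a chromosome before variant calling),
and `pipe_partitions()` as a streaming alternative to `map_partitions()`
for stdin/stdout-safe tools.

## Records, partitions and separators

Text records are delimited by a configurable **record terminator**. The
terminator choice is load-bearing: with `"\n"` every line is a record
(DNA text, SAM-like rows); with `"\n$$$$\n"` every `"$$$$"`-terminated
molecule block of an SDF library is a single record, so a docking tool
never sees half a molecule. Terminator semantics are exact:

- splitting drops one trailing empty fragment when the source ends with
  the terminator, so `"AT\nGC\n"` is two records;
- writing re-appends the terminator after *every* record, so an empty
  partition is a zero-length file and `materialize()` → `ingest()` is the
  identity;
- on ingest, a missing terminator after a tool's final record is
  tolerated — many tools do not terminate their last line, and the shape
  of a tool's output is not ours to impose.

Binary datasets treat each file of a flat directory as one record (name +
payload); names must be unique within a partition because they become file
names again at the next mount point. Nested directories are skipped with a
warning rather than walked: recursive layouts are ambiguous to rebuild.

Partition assignment is contiguous blocking: records in origin order,
blocks of `ceiling(R / n)`. This preserves record adjacency for tools that
are sensitive to local order and makes partitioning trivially
reproducible. Empty partitions are legal and preserved — a partition count
is a contract, not a hint. The ingest partition count is a parameter (and
defaults to 2 in YAML pipelines) rather than a storage-derived constant,
since there is no block-sized storage layer underneath this executor.

## Key-based repartitioning and the hash

`repartition_by()` computes a key per record and assigns it to partition
`hash(key) mod n`. The hash is 64-bit FNV-1a over the key's UTF-8 bytes —
fixed, published, and never per-process randomized — so placement is
byte-identical across runs, processes and machines. That determinism is
what the tests (and any user debugging a pipeline) rely on; a seeded or
randomized hash would silently break run-to-run comparability. Within a
target partition, records keep (origin partition, origin offset) order, so
equal-key groups are stable too.

## The tree reduce

`reduce_tree()` aggregates a dataset to a single partition in up to `K`
levels. At each level every partition is aggregated by one command
invocation, then the partition count shrinks to the level target; after
the last level the single remaining partition is aggregated once more.
Level targets follow the geometric schedule

```
levels[i] = ceiling(N^((K - i) / K)),   i = 1..K
```

clamped to be strictly decreasing and truncated at 1. The clamping matters
for small `N`: the raw formula gives `2, 2, 1` for `N = 2, K = 3`, which
would schedule a shuffle that changes nothing. For `N = 12, K = 2` the
schedule is `4, 1`: 12 + 4 + 1 = 17 invocations and exactly 2 shuffles,
which the invocation ledger (`ledger_counts()`) lets you verify on a real
run. A single-partition input degenerates to one aggregation and zero
shuffles. Empty partitions are dropped before planning — invoking an
aggregator on nothing is wasted work — but `map_partitions()` deliberately
*does* run commands on empty partitions, because what an empty input
produces (`wc -l` says `0`) is the tool's decision, not the engine's.

The caller contract — the command is associative and commutative over
records and shrinks its partition — is documented, not verified: it is not
decidable from outside the container. A level that fails to shrink the
data raises a warning, not an error, since small inputs legitimately
bottom out (twelve 1-record partitions cannot shrink below one record
each).

`depth = 2` is the default; depth 1 is a single shuffle straight to one
partition; larger depths trade extra shuffles for smaller aggregation
inputs when one pass cannot reduce enough (e.g. a top-N filter whose
partitions are barely larger than N).

## Data handoff: mount points, temp space, pipes

A partition reaches a container through host files staged under
`<root>/<run-id>/<stage>/<partition-index>/<attempt>/{in,out}` — unique per
task attempt, which is the whole concurrency-isolation story. The staging
root defaults to the session temporary directory (honoring `TMPDIR`;
CLI flag `--tmpdir` takes precedence): point it at a tmpfs mount such as
`/dev/shm` for in-memory staging, or at a disk path when partitions exceed
tmpfs capacity. The engine is agnostic — nothing but the path changes —
and the cleanup policy (`always` / `on_success` / `never`) applies
regardless of how a stage ends.

Two backends execute a step. `docker` runs `docker run --rm --network
none` with the staged input and the pre-created output file/directory
bind-mounted at the step's container paths (docker requires bind sources
to exist, so the engine pre-creates an empty output target; on the
subprocess backend the command itself creates it, e.g. via `>`
redirection). `subprocess` rewrites the container paths occurring in the
command string to the staged host paths (longest path first) and runs the
command under `sh -c` on the host — no isolation, which is exactly what a
test environment without a daemon needs. The documented limitation of path
rewriting is commands that *compute* paths at run time; none of the
shipped pipelines do. For pure POSIX commands the backends are
interchangeable, and the suite asserts that equivalence whenever a daemon
is reachable.

`pipe_partitions()` / `run_step_streaming()` implement the pipe-style
handoff: the whole partition is fed to *one* process instance on standard
input and its standard output is split back into records. The contract —
one process per partition, never one per record — is what distinguishes it
from naive per-record piping; the suite verifies that streaming and
materialized execution agree on stream-safe commands (`cat`, `sort`,
`grep -c`), which is the correctness face of the pipe-vs-filesystem
comparison. Memory-mapped handoff is deliberately not implemented.

Commands receive a `TASK_ID` environment variable, unique per (stage,
partition, attempt) and derived from the config seed. Aggregation commands
that write binary records embed `${TASK_ID}` in output names so files
never clash when tree levels merge partitions. A truly random suffix would
serve the same purpose but would break the reproducibility guarantee
(same pipeline + same seed → byte-identical outputs) that both the CLI
contract and the test suite assert; determinism wins.

## Failure semantics

A nonzero exit fails the task with an error carrying the exit code and the
stderr tail; a failing task fails its stage fail-fast (no retries by
default; `retries` is a config knob), reporting the 0-based partition
index. The YAML runner keeps a partial JSON report on stage failure and
exits nonzero. There is no lineage or speculative re-execution — this is a
single-machine executor by design.

## Synthetic data and what the tests show

The generators produce the three data shapes the pipelines need, all
seeded and byte-reproducible:

- `gen_dna(length, gc_fraction, seed)` — i.i.d. bases in 80-char lines,
  with `P(G) = P(C) = gc_fraction / 2`. Defaults used in the demos: 10 MB
  (10^7 bases) for acceptance runs, GC fraction 0.5 — large enough that
  per-partition work is non-trivial, small enough to run in seconds.
- `gen_sdf_library(n, seed)` — SDF-dialect records with a fake 2-atom
  molecule block and a `> <score>` tag in [0, 100). Scores derive from the
  stable hash of the molecule block; the rare collision is resolved by a
  deterministic index-salted rehash so all scores are distinct and "the
  top 30" has exactly one answer. Demo size: 1,000 molecules.
- `gen_tagged_reads(n, chromosomes, seed)` — `chr<k>\tid\tseq` records over
  a 23-label human-style chromosome alphabet, each label guaranteed present
  when `n ≥ 23`. Demo size: 10,000 reads into 14 partitions, mirroring a
  many-keys-few-workers layout.

These fixtures emulate *structure*, not biology: i.i.d. bases have no
genomic composition, the molecules no chemistry, the reads no reference.
Passing tests therefore demonstrate the engine's semantics — exact
separator handling, colocation, aggregation correctness, determinism,
plan accounting — on realistically shaped data, and say nothing about
docking accuracy or variant-calling quality, which belong to the wrapped
tools. Likewise the single-machine executor makes no scaling-efficiency
claims; scaling behavior is a property of the cluster backend this model
is designed to sit on, and is out of scope here.

The oracles are single-pass native computations (`gc_count()`,
`top_n_records()`, `key_histogram()`) kept deliberately independent of the
partition/engine code paths they check.

## Numerical and interface choices

- Scores are compared at their printed 5-decimal precision; they are exact
  multiples of 10^-5, so formatting round trips without loss.
- `validate_spec()` returns errors as values (`field.path: reason`), never
  throws, and fills defaults (separator `"\n"`, depth 2, engine
  `subprocess`, parallelism 1); field paths are 1-based.
- A reduce returns a 1-partition dataset rather than a bare record, so it
  can feed further stages; `collect_records()` is the terminal step.
- Problem sizes in the test suite (10 MB DNA end-to-end; the
  (N, K) ∈ {1,2,7,12,16} × {1,2,3} reduce grid over 1,000 records; 1,000
  molecules; 10,000 reads; 200+ marshaling round-trip cases) were chosen
  as the smallest scales at which every contract is exercised with real
  shuffles and multi-level trees; the whole suite runs in well under a
  minute on one CPU.

## Known limitations

- Linear pipelines only: no DAG of branching stages, no caching between
  stages, no lazy evaluation.
- No fault tolerance beyond per-task retries; a failed stage fails the
  run.
- Subprocess path substitution cannot follow dynamically computed paths.
- Docker is the only container backend (the engine interface would admit
  Podman/Singularity, but they are not implemented); no image building or
  registry management.
- Text records are handled as byte strings; multi-byte-encoding-aware
  separator splitting is not attempted beyond byte-exact matching.
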