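# cmr — container-backed MapReduce primitives for bioinformatics pipelines

Most bioinformatics tools are command-line programs that read files and
write files, and the community ships them as application containers. Data,
meanwhile, keeps outgrowing the single invocation: counting nucleotides in
a genome, docking a molecule library against a target, calling variants
from tens of gigabytes of reads. `cmr` closes that gap on a single machine:
it brings the MapReduce programming model to *unmodified containerized
tools*, so a shell command becomes the per-partition transformation of a
scalable pipeline — no reimplementation of the tool, no workflow engine,
no cluster stack.

## The model

A dataset is split into **N partitions**. Text datasets use a configurable
record *terminator* (newline by default; the `"$$$$"` line of SDF molecule
files via `"\n$$$$\n"`), and no record is ever split across partitions.
Binary datasets treat each file of a directory as one record. Three
primitives operate on partitions, each handing a partition to exactly one
container (or sandboxed subprocess) invocation through file-based mount
points:

- **map** — partition *i* of the output is the tool's output on
  partition *i* of the input. One stage, no data movement.
- **reduce (tree, depth K)** — for an associative and commutative command
  (sum, top-N, file concatenation), aggregate within each partition, then
  shrink the partition count to `ceiling(N^((K-i)/K))` at level
  `i = 1..K`, and aggregate the final single partition once more. A
  depth-2 reduce over N = 12 partitions runs 12 + 4 + 1 = 17 invocations
  and exactly 2 shuffles. K defaults to 2; deeper trees help when one pass
  cannot shrink partitions enough.
- **repartitionBy** — compute a key per record (e.g. the chromosome of an
  aligned read) and colocate equal keys via a deterministic hash
  partitioner (64-bit FNV-1a), so a tool that must see *all* records of a
  key at once — a variant caller per chromosome — gets them in one
  partition.

A streaming variant (`pipe_partitions()`) feeds a whole partition through
one tool instance on stdin/stdout instead of materializing files — one
process per partition, never one per record.

## Worked example: GC content of a genome

The GC fraction of a DNA sequence has real biological signal (GC-rich
genes tend to be expressed more efficiently), and counting G/C over a
large sequence is the canonical hello-world of this model — `grep` and
`wc` from a stock Ubuntu image become the mapper, `awk` the reducer:

```r
library(cmr)

dna <- gen_dna(8000, gc_fraction = 0.5, seed = 1)   # 80-base lines
ds  <- from_text(dna, "\n", num_partitions = 4)
cfg <- execution_config(backend = "subprocess", parallelism = 4)

count <- container_step("ubuntu", "grep -o [GC] /dna | wc -l > /count",
                        input = text_mount("/dna"),
                        output = text_mount("/count"))
sum   <- container_step("ubuntu", "awk '{s += $1} END {print s}' /counts > /sum",
                        input = text_mount("/counts"),
                        output = text_mount("/sum"))

counts <- map_partitions(ds, count, cfg)
collect_records(counts)
#> [1] "1039" "1027" "976"  "996"
total <- reduce_tree(counts, sum, depth = 2, cfg = cfg)
collect_records(total)
#> [1] "4038"
gc_count(dna)    # native oracle agrees
#> [1] 4038
```

The four intermediate records are the per-partition GC counts; the reduce
aggregates them to the global count, which matches the in-R character
count exactly.

The same pipelines run declaratively from YAML through the CLI
(`inst/cli/cmr`):

```sh
cmr demo gc --out /tmp/gc-demo          # generate fixture + pipeline + run
#> demo gc: oracle agreement = TRUE
cmr run /tmp/gc-demo/gc_pipeline.yaml --parallelism 8
cmr fixtures sdf --out library.sdf --size 1000 --seed 42
```

`cmr demo vs` re-enacts a virtual-screening pipeline (map a toy docking
stand-in over an SDF library, tree-reduce to the 30 best-scoring
molecules) and `cmr demo snp` a variant-calling shape (map, chromosome-wise
repartition, per-chromosome compression to binary records, binary-file
concatenating reduce). Each demo checks itself against a native oracle and
writes a JSON run report with per-stage record counts, container
invocations, shuffles and timings.

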