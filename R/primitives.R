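# The three processing primitives: partition-wise map, tree-shaped reduce,
# and the streaming (pipe) map variant, composed from the dataset, marshal
# and engine layers. Every primitive runs exactly one container/process per
# (stage, partition, attempt) and records it in the config's invocation
# ledger, so tests can audit the execution plan.

#' Execution configuration
#'
#' Bundles the knobs shared by all primitives: which backend runs the
#' commands, how many partition tasks may run concurrently, where staging
#' data lives, the default tree-reduce depth, and the seed used for any
#' derived identifiers. Also carries the invocation ledger (see
#' [ledger_counts()]).
#'
#' @param backend `"subprocess"` (default; no container daemon needed) or
#'   `"docker"`.
#' @param parallelism Maximum concurrent partition tasks (>= 1). Results
#'   are independent of this value; it only controls scheduling.
#' @param temp_space A [temp_space()] for staging.
#' @param default_depth Default tree-reduce depth K (>= 1, default 2: one
#'   intermediate aggregation level, then the final one).
#' @param seed Integer seed for derived identifiers (task IDs).
#' @param retries Extra attempts per failed partition task (default 0:
#'   fail fast).
#' @param timeout Optional per-command timeout in seconds.
#' @return An execution-config object.
#' @export
execution_config <- function(backend = c("subprocess", "docker"),
                             parallelism = 1L,
                             temp_space = cmr::temp_space(),
                             default_depth = 2L,
                             seed = 1L,
                             retries = 0L,
                             timeout = NULL) {
  backend <- match.arg(backend)
  parallelism <- as.integer(parallelism)
  default_depth <- as.integer(default_depth)
  stopifnot(
    parallelism >= 1L, default_depth >= 1L,
    inherits(temp_space, "cmr_temp_space"),
    is.numeric(seed), length(seed) == 1L,
    retries >= 0L
  )
  ledger <- new.env(parent = emptyenv())
  ledger$invocations <- 0L
  ledger$shuffles <- 0L
  ledger$stages <- list()
  structure(
    list(backend = backend, parallelism = parallelism,
         temp_space = temp_space, default_depth = default_depth,
         seed = as.integer(seed), retries = as.integer(retries),
         timeout = timeout, ledger = ledger),
    class = "cmr_config"
  )
}

#' Inspect or reset the invocation ledger
#'
#' Every command invocation and every repartition (shuffle) performed under
#' a config is counted, so a run's execution plan can be audited — e.g. a
#' depth-2 tree reduce over 12 partitions must record exactly 17
#' invocations and 2 shuffles.
#'
#' @param cfg An [execution_config()].
#' @return `ledger_counts()`: list with `invocations`, `shuffles`, and a
#'   per-stage breakdown `stages`. `reset_ledger()`: the config, invisibly.
#' @export
ledger_counts <- function(cfg) {
  stopifnot(inherits(cfg, "cmr_config"))
  list(
    invocations = cfg$ledger$invocations,
    shuffles = cfg$ledger$shuffles,
    stages = cfg$ledger$stages
  )
}

#' @rdname ledger_counts
#' @export
reset_ledger <- function(cfg) {
  stopifnot(inherits(cfg, "cmr_config"))
  cfg$ledger$invocations <- 0L
  cfg$ledger$shuffles <- 0L
  cfg$ledger$stages <- list()
  invisible(cfg)
}

record_stage <- function(cfg, stage, invocations, shuffles = 0L) {
  cfg$ledger$invocations <- cfg$ledger$invocations + as.integer(invocations)
  cfg$ledger$shuffles <- cfg$ledger$shuffles + as.integer(shuffles)
  cfg$ledger$stages[[length(cfg$ledger$stages) + 1L]] <-
    list(stage = stage, invocations = as.integer(invocations),
         shuffles = as.integer(shuffles))
  invisible(cfg)
}

# Deterministic task identifier, exported to commands as $TASK_ID: unique
# per (stage, partition, attempt) within a run so commands can generate
# clash-free output names, yet reproducible for a fixed seed.
task_id <- function(cfg, stage, partition, attempt) {
  sprintf("s%d_%s_p%d_a%d", cfg$seed, gsub("[^A-Za-z0-9]", "", stage),
          partition, attempt)
}

# Apply fn over indices with bounded concurrency; order-preserving.
# Conditions raised in children are collected and re-raised in the parent
# with the partition index attached.
run_tasks <- function(indices, fn, parallelism) {
  results <- if (parallelism > 1L && length(indices) > 1L) {
    parallel::mclapply(indices, function(i) {
      tryCatch(fn(i), error = function(e) e)
    }, mc.cores = parallelism, mc.preschedule = FALSE)
  } else {
    lapply(indices, function(i) tryCatch(fn(i), error = function(e) e))
  }
  for (k in seq_along(results)) {
    if (inherits(results[[k]], "error")) {
      e <- results[[k]]
      stop(sprintf("partition %d failed: %s", indices[k] - 1L,
                   conditionMessage(e)), call. = FALSE)
    }
  }
  results
}

# One materialize -> run -> ingest round for a single partition, with the
# documented staging layout <root>/<run>/<stage>/<partition>/<attempt>/.
run_partition_task <- function(partition, step, cfg, run_dir, stage, index) {
  attempts <- cfg$retries + 1L
  for (attempt in seq_len(attempts)) {
    base <- file.path(run_dir, stage, sprintf("p%05d", index),
                      sprintf("a%d", attempt))
    in_dir <- file.path(base, "in")
    out_dir <- file.path(base, "out")
    dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    host_in <- materialize(partition, step$input, cfg$temp_space, at = in_dir)
    host_out <- file.path(out_dir,
                          if (step$output$kind == "text") "part.txt" else "part")
    if (step$output$kind == "binary") {
      dir.create(host_out, recursive = TRUE, showWarnings = FALSE)
    }
    ans <- tryCatch({
      run_step(step, host_in, host_out, backend = cfg$backend,
               env = c(TASK_ID = task_id(cfg, stage, index, attempt)),
               timeout = cfg$timeout, log_dir = base)
      ingest(step$output, host_out)
    }, error = function(e) e)
    if (!inherits(ans, "error")) return(ans)
    if (attempt == attempts) stop(ans)
  }
}

stage_scope <- function(cfg, stage) {
  run_dir <- new_staging_dir(cfg$temp_space, paste0("run_", stage))
  run_dir
}

#' Transform each partition with one container command
#'
#' The map primitive: partition `i` of the result is the ingested output of
#' `step`'s command run once on the materialized partition `i` of the
#' input. The partition count never changes and no record crosses a
#' partition boundary — a map is a single stage with no shuffle. Partitions
#' run concurrently up to `cfg$parallelism`. Empty partitions are still
#' handed to the command (the tool decides what an empty input produces).
#'
#' The output dataset's kind and separator come from `step$output`, so a
#' map may turn a text dataset into a binary one (e.g. a caller that emits
#' compressed VCF files) or change the record separator.
#'
#' @param ds A partitioned dataset whose kind matches `step$input`.
#' @param step A [container_step()].
#' @param cfg An [execution_config()].
#' @param stage Stage label used in staging paths, logs and the ledger.
#' @return The transformed dataset, same partition count as `ds`.
#' @examples
#' \dontrun{
#' ds <- from_text(gen_dna(8000, 0.5, seed = 1), "\n", 4)
#' gc <- container_step("ubuntu", "grep -o [GC] /dna | wc -l > /count",
#'                      text_mount("/dna"), text_mount("/count"))
#' counts <- map_partitions(ds, gc, execution_config())
#' }
#' @export
map_partitions <- function(ds, step, cfg = execution_config(),
                           stage = "map") {
  stopifnot(inherits(ds, "cmr_dataset"), inherits(step, "cmr_step"),
            inherits(cfg, "cmr_config"))
  if (ds$kind != step$input$kind) {
    stop(sprintf("dataset kind (%s) does not match step input mount (%s)",
                 ds$kind, step$input$kind), call. = FALSE)
  }
  run_dir <- stage_scope(cfg, stage)
  success <- FALSE
  on.exit(cleanup_staging(cfg$temp_space, run_dir, success))

  n <- n_partitions(ds)
  record_stage(cfg, stage, invocations = n)
  parts <- run_tasks(seq_len(n), function(i) {
    run_partition_task(ds$partitions[[i]], step, cfg, run_dir, stage, i - 1L)
  }, cfg$parallelism)
  success <- TRUE
  new_dataset(parts, step$output$kind, step$output$separator)
}

#' Streaming (pipe) variant of the map primitive
#'
#' Same contract as [map_partitions()] but each partition is streamed
#' through a single instance of the tool via standard input/output instead
#' of being materialized at a mount point — one process per partition,
#' never one per record. Only valid for stream-safe commands on text
#' datasets; for such commands the result is identical to
#' [map_partitions()] with the equivalent file-based command.
#'
#' @inheritParams map_partitions
#' @return The transformed dataset, same partition count as `ds`.
#' @export
pipe_partitions <- function(ds, step, cfg = execution_config(),
                            stage = "pipe") {
  stopifnot(inherits(ds, "cmr_dataset"), inherits(step, "cmr_step"),
            inherits(cfg, "cmr_config"))
  if (ds$kind != "text") {
    stop("pipe_partitions supports text datasets only", call. = FALSE)
  }
  n <- n_partitions(ds)
  record_stage(cfg, stage, invocations = n)
  parts <- run_tasks(seq_len(n), function(i) {
    run_step_streaming(step, ds$partitions[[i]], backend = cfg$backend,
                       env = c(TASK_ID = task_id(cfg, stage, i - 1L, 1L)),
                       timeout = cfg$timeout, space = cfg$temp_space)
  }, cfg$parallelism)
  new_dataset(parts, step$output$kind, step$output$separator)
}

#' Plan a tree-shaped reduce
#'
#' Given `n` starting partitions and a depth `k`, the reduce proceeds in
#' levels: at each level every partition is aggregated by one command
#' invocation, then the partition count shrinks to the level's target; a
#' final aggregation of the single remaining partition closes the tree.
#' Targets follow the geometric schedule
#' `levels[i] = ceiling(n^((k - i) / k))` (clamped to stay strictly
#' decreasing and truncated at 1), which balances aggregation work across
#' levels and degenerates at `k = 1` to a single shuffle straight to one
#' partition.
#'
#' @param n Starting partition count (>= 1; empty partitions are dropped
#'   before planning in [reduce_tree()]).
#' @param k Tree depth (>= 1).
#' @return A reduce plan: `depth`, `levels` (target partition counts after
#'   each shuffle; empty when `n == 1`), `shuffles`, and `invocations`
#'   (total expected command runs).
#' @examples
#' plan_reduce(12, 2) # levels 4, 1 — 17 invocations, 2 shuffles
#' plan_reduce(16, 4) # levels 8, 4, 2, 1
#' @export
plan_reduce <- function(n, k) {
  n <- as.integer(n)
  k <- as.integer(k)
  stopifnot(n >= 1L, k >= 1L)
  if (n == 1L) {
    return(structure(
      list(depth = k, levels = integer(0), shuffles = 0L, invocations = 1L),
      class = "cmr_reduce_plan"
    ))
  }
  levels <- integer(0)
  prev <- n
  for (i in seq_len(k)) {
    target <- max(1L, as.integer(ceiling(n^((k - i) / k))))
    target <- min(target, max(1L, prev - 1L)) # keep strictly decreasing
    levels <- c(levels, target)
    prev <- target
    if (target == 1L) break
  }
  structure(
    list(
      depth = k, levels = levels, shuffles = length(levels),
      invocations = n + sum(utils::head(levels, -1L)) + 1L
    ),
    class = "cmr_reduce_plan"
  )
}

#' @export
print.cmr_reduce_plan <- function(x, ...) {
  cat(sprintf(
    "<reduce plan> depth %d, levels [%s], %d shuffles, %d invocations\n",
    x$depth, paste(x$levels, collapse = ", "), x$shuffles, x$invocations
  ))
  invisible(x)
}

#' Aggregate a dataset with a tree-shaped reduce
#'
#' The reduce primitive: iteratively aggregates records, shrinking the
#' partition count until a single result partition remains. At each of up
#' to `depth` levels, every partition is aggregated by one invocation of
#' `step`'s command (as in [map_partitions()]), then the dataset is
#' repartitioned down to the next level of the [plan_reduce()] schedule —
#' each repartition is one shuffle. After the last level the one remaining
#' partition is aggregated once more and returned as a 1-partition dataset.
#'
#' The command must implement an associative and commutative operation over
#' records (e.g. summing numbers, keeping the top-N by score, concatenating
#' files) and should reduce the size of its partition; this caller contract
#' is documented, not verified — a level that fails to shrink the data only
#' raises a warning. Empty partitions are dropped before planning so no
#' invocation is wasted on them. Deeper trees (`depth > 2`) help when one
#' aggregation pass cannot shrink partitions enough.
#'
#' @inheritParams map_partitions
#' @param depth Tree depth K (default: `cfg$default_depth`, i.e. 2).
#' @return A dataset with exactly one partition holding the aggregate.
#' @examples
#' \dontrun{
#' sum_step <- container_step("ubuntu",
#'   "awk '{s += $1} END {print s}' /counts > /sum",
#'   text_mount("/counts"), text_mount("/sum"))
#' total <- reduce_tree(counts, sum_step, cfg = execution_config())
#' collect_records(total)
#' }
#' @export
reduce_tree <- function(ds, step, depth = NULL, cfg = execution_config(),
                        stage = "reduce") {
  stopifnot(inherits(ds, "cmr_dataset"), inherits(step, "cmr_step"),
            inherits(cfg, "cmr_config"))
  depth <- as.integer(depth %||% cfg$default_depth)
  stopifnot(depth >= 1L)
  if (ds$kind != step$input$kind) {
    stop(sprintf("dataset kind (%s) does not match step input mount (%s)",
                 ds$kind, step$input$kind), call. = FALSE)
  }

  # Drop empty partitions before planning: aggregating nothing is a wasted
  # invocation. An all-empty dataset still gets the single final
  # aggregation so the command decides what "empty" reduces to.
  keep <- partition_sizes(ds) > 0L
  parts <- if (any(keep)) ds$partitions[keep] else list(ds$partitions[[1L]][0L])
  current <- new_dataset(parts, ds$kind, ds$separator)

  plan <- plan_reduce(n_partitions(current), depth)
  level_stage <- function(lvl) sprintf("%s_l%d", stage, lvl)

  for (i in seq_along(plan$levels)) {
    before <- sum(partition_sizes(current))
    current <- map_partitions(current, step, cfg, stage = level_stage(i))
    after <- sum(partition_sizes(current))
    if (before > n_partitions(current) && after >= before) {
      warning(sprintf(
        "reduce level %d did not shrink the data (%d -> %d records); the command should reduce partition size",
        i, before, after
      ), call. = FALSE)
    }
    current <- repartition(current, plan$levels[i])
    record_stage(cfg, sprintf("%s_shuffle%d", stage, i), 0L, shuffles = 1L)
  }
  map_partitions(current, step, cfg, stage = paste0(stage, "_final"))
}
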