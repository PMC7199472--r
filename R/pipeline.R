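# Declarative pipeline runner: a YAML document describes the input dataset,
# a linear list of map / reduce / repartition_by / repartition / pipe
# stages, the output location and the execution settings. Driver programs
# (GC counting, virtual-screening top-N, chromosome-wise SNP shaping)
# become short config files runnable from the `cmr` CLI.

pipeline_defaults <- list(
  separator = "\n",
  depth = 2L,
  engine = "subprocess",
  parallelism = 1L,
  seed = 1L,
  partitions = 2L
)

norm_mount <- function(raw, where, errors) {
  if (is.null(raw) || is.null(raw$path)) {
    return(list(value = NULL,
                errors = c(errors, paste0(where, ": missing path"))))
  }
  kind <- raw$kind %||% "text"
  if (!kind %in% c("text", "binary")) {
    return(list(value = NULL,
                errors = c(errors, paste0(where, ".kind: must be text or binary"))))
  }
  if (kind == "text") {
    sep <- raw$separator %||% pipeline_defaults$separator
    if (!is.character(sep) || !nzchar(sep)) {
      return(list(value = NULL,
                  errors = c(errors, paste0(where, ".separator: must be non-empty"))))
    }
    m <- tryCatch(text_mount(raw$path, sep), error = function(e) e)
  } else {
    m <- tryCatch(binary_mount(raw$path), error = function(e) e)
  }
  if (inherits(m, "error")) {
    return(list(value = NULL,
                errors = c(errors, paste0(where, ".path: ", conditionMessage(m)))))
  }
  list(value = m, errors = errors)
}

#' Validate and normalize a pipeline description
#'
#' Checks a raw pipeline config (a YAML file path or an already-parsed
#' list) against the pipeline schema and fills in defaults: record
#' separator `"\n"`, reduce depth 2, engine `"subprocess"`, parallelism 1.
#' Validation never throws — problems come back as a character vector of
#' `field path: reason` messages.
#'
#' @param config Path to a YAML file, or a nested list with elements
#'   `input` (`path`, `kind`, `separator`, `partitions`), `steps` (each
#'   with `op` — one of `map`, `reduce`, `pipe`, `repartition_by`,
#'   `repartition` — and, per op, `image`, `command`, `input_mount`,
#'   `output_mount`, `depth`, `key_regex`, `partitions`), `output`
#'   (`path`, `kind`, `separator`) and optional `execution` (`engine`,
#'   `parallelism`, `tmpdir`, `depth`, `seed`, `timeout`).
#' @return A list with `spec` (the normalized pipeline, or `NULL` when
#'   invalid) and `errors` (character vector, empty when valid).
#' @export
validate_spec <- function(config) {
  raw <- if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      return(list(spec = NULL,
                  errors = paste0("config: file not found: ", config)))
    }
    yaml::read_yaml(config)
  } else {
    config
  }
  errors <- character(0)
  if (!is.list(raw)) {
    return(list(spec = NULL, errors = "config: not a mapping"))
  }

  # -- input --------------------------------------------------------------
  input <- raw$input
  if (is.null(input) || is.null(input$path)) {
    errors <- c(errors, "input.path: required")
  }
  in_kind <- input$kind %||% "text"
  if (!in_kind %in% c("text", "binary")) {
    errors <- c(errors, "input.kind: must be text or binary")
  }
  in_sep <- input$separator %||% pipeline_defaults$separator
  if (in_kind == "text" && (!is.character(in_sep) || !nzchar(in_sep))) {
    errors <- c(errors, "input.separator: must be non-empty")
  }
  in_parts <- as.integer(input$partitions %||% pipeline_defaults$partitions)
  if (is.na(in_parts) || in_parts < 1L) {
    errors <- c(errors, "input.partitions: must be >= 1")
  }

  # -- steps --------------------------------------------------------------
  steps <- raw$steps
  if (is.null(steps) || !length(steps)) {
    errors <- c(errors, "steps: at least one step is required")
    steps <- list()
  }
  norm_steps <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    at <- sprintf("steps[%d]", i)
    op <- st$op %||% NA_character_
    if (!op %in% c("map", "reduce", "pipe", "repartition_by", "repartition")) {
      errors <- c(errors, sprintf("%s.op: unknown op '%s'", at, op))
      next
    }
    ns <- list(op = op)
    if (op %in% c("map", "reduce", "pipe")) {
      if (is.null(st$command) || !nzchar(st$command %||% "")) {
        errors <- c(errors, paste0(at, ".command: required"))
      }
      ns$image <- st$image %||% "ubuntu"
      ns$command <- st$command
      im <- norm_mount(st$input_mount, paste0(at, ".input_mount"), errors)
      errors <- im$errors
      om <- norm_mount(st$output_mount, paste0(at, ".output_mount"), errors)
      errors <- om$errors
      ns$input_mount <- im$value
      ns$output_mount <- om$value
      if (!is.null(im$value) && !is.null(om$value) &&
          identical(im$value$container_path, om$value$container_path)) {
        errors <- c(errors,
                    paste0(at, ".output_mount.path: must differ from input"))
      }
      if (op == "pipe" &&
          (!identical(im$value$kind %||% "text", "text") ||
           !identical(om$value$kind %||% "text", "text"))) {
        errors <- c(errors, paste0(at, ": pipe steps need text mounts"))
      }
      if (op == "reduce") {
        ns$depth <- as.integer(st$depth %||% pipeline_defaults$depth)
        if (is.na(ns$depth) || ns$depth < 1L) {
          errors <- c(errors, paste0(at, ".depth: must be >= 1"))
        }
      }
    } else if (op == "repartition_by") {
      if (is.null(st$key_regex) || !nzchar(st$key_regex %||% "")) {
        errors <- c(errors, paste0(at, ".key_regex: required"))
      } else if (!grepl("\\(", st$key_regex)) {
        errors <- c(errors,
                    paste0(at, ".key_regex: needs one capture group"))
      }
      ns$key_regex <- st$key_regex
      ns$partitions <- as.integer(st$partitions %||% NA_integer_)
      if (is.na(ns$partitions) || ns$partitions < 1L) {
        errors <- c(errors, paste0(at, ".partitions: must be >= 1"))
      }
    } else { # repartition
      ns$partitions <- as.integer(st$partitions %||% NA_integer_)
      if (is.na(ns$partitions) || ns$partitions < 1L) {
        errors <- c(errors, paste0(at, ".partitions: must be >= 1"))
      }
    }
    norm_steps[[i]] <- ns
  }

  # -- output -------------------------------------------------------------
  output <- raw$output
  if (is.null(output) || is.null(output$path)) {
    errors <- c(errors, "output.path: required")
  }
  out_kind <- output$kind %||% "text"
  if (!out_kind %in% c("text", "binary")) {
    errors <- c(errors, "output.kind: must be text or binary")
  }
  out_sep <- output$separator %||% pipeline_defaults$separator
  if (out_kind == "text" &&
      (!is.character(out_sep) || length(out_sep) != 1L || !nzchar(out_sep))) {
    errors <- c(errors, "output.separator: must be non-empty")
  }

  # -- execution ----------------------------------------------------------
  ex <- raw$execution %||% list()
  engine <- ex$engine %||% pipeline_defaults$engine
  if (!engine %in% c("subprocess", "docker")) {
    errors <- c(errors, "execution.engine: must be subprocess or docker")
  }
  parallelism <- as.integer(ex$parallelism %||% pipeline_defaults$parallelism)
  if (is.na(parallelism) || parallelism < 1L) {
    errors <- c(errors, "execution.parallelism: must be >= 1")
  }

  if (length(errors)) {
    return(list(spec = NULL, errors = errors))
  }
  list(
    spec = list(
      input = list(path = input$path, kind = in_kind,
                   separator = in_sep, partitions = in_parts),
      steps = norm_steps,
      output = list(path = output$path, kind = out_kind,
                    separator = if (out_kind == "text") out_sep else NULL),
      execution = list(
        engine = engine, parallelism = parallelism,
        tmpdir = ex$tmpdir %||% NULL,
        depth = as.integer(ex$depth %||% pipeline_defaults$depth),
        seed = as.integer(ex$seed %||% pipeline_defaults$seed),
        timeout = ex$timeout %||% NULL
      )
    ),
    errors = character(0)
  )
}

regex_key_fn <- function(pattern) {
  force(pattern)
  function(record) {
    m <- regmatches(record, regexec(pattern, record))[[1]]
    if (length(m) < 2L) {
      stop(sprintf("key regex '%s' did not match record '%s'",
                   pattern, substr(record, 1, 60)), call. = FALSE)
    }
    m[[2]]
  }
}

# TMPDIR precedence for staging: explicit override > TMPDIR environment
# variable > session default.
resolve_tmpdir <- function(override = NULL) {
  cand <- c(override, Sys.getenv("TMPDIR", unset = NA), tempdir())
  cand <- cand[!is.na(cand) & nzchar(cand)]
  cand[dir.exists(cand)][1]
}

#' Run a declarative pipeline
#'
#' Validates `config` (see [validate_spec()]), loads the input dataset,
#' executes the stages in order with the configured engine, writes the
#' final dataset to the output path (text: one separator-terminated file;
#' binary: a directory of files) and a JSON run report next to it
#' (`<output>.report.json`). The report lists, per stage, the operation,
#' record and partition counts, command invocations, shuffles and wall
#' time.
#'
#' @param config YAML file path or pipeline list (as for
#'   [validate_spec()]).
#' @param engine,parallelism,tmpdir,depth,seed Optional overrides of the
#'   config's execution settings (the CLI flags map onto these; `tmpdir`
#'   takes precedence over the `TMPDIR` environment variable).
#' @param quiet Suppress per-stage log lines.
#' @return The run report, invisibly: a list with `stages`, `output`,
#'   `report_path`, total `invocations` and `shuffles`, and the final
#'   `records` count.
#' @export
run_pipeline <- function(config, engine = NULL, parallelism = NULL,
                         tmpdir = NULL, depth = NULL, seed = NULL,
                         quiet = FALSE) {
  v <- validate_spec(config)
  if (length(v$errors)) {
    stop("invalid pipeline config:\n  ", paste(v$errors, collapse = "\n  "),
         call. = FALSE)
  }
  spec <- v$spec
  ex <- spec$execution
  ex$engine <- engine %||% ex$engine
  ex$parallelism <- as.integer(parallelism %||% ex$parallelism)
  ex$tmpdir <- tmpdir %||% ex$tmpdir
  ex$depth <- as.integer(depth %||% ex$depth)
  ex$seed <- as.integer(seed %||% ex$seed)

  cfg <- execution_config(
    backend = ex$engine, parallelism = ex$parallelism,
    temp_space = temp_space(resolve_tmpdir(ex$tmpdir)),
    default_depth = ex$depth, seed = ex$seed,
    timeout = ex$timeout
  )

  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(fmt, ...))
  }

  ds <- if (spec$input$kind == "text") {
    from_text(spec$input$path, spec$input$separator,
              spec$input$partitions, from_file = TRUE)
  } else {
    from_binary_dir(spec$input$path, spec$input$partitions)
  }
  say("input: %d records in %d partitions (%s)",
      sum(partition_sizes(ds)), n_partitions(ds), spec$input$kind)

  stages <- list()
  for (i in seq_along(spec$steps)) {
    st <- spec$steps[[i]]
    label <- sprintf("s%02d_%s", i, st$op)
    before <- ledger_counts(cfg)
    t0 <- proc.time()[["elapsed"]]
    records_in <- sum(partition_sizes(ds))

    ds <- tryCatch(switch(st$op,
      map = map_partitions(
        ds, container_step(st$image, st$command, st$input_mount,
                           st$output_mount),
        cfg, stage = label
      ),
      pipe = pipe_partitions(
        ds, container_step(st$image, st$command, st$input_mount,
                           st$output_mount),
        cfg, stage = label
      ),
      reduce = reduce_tree(
        ds, container_step(st$image, st$command, st$input_mount,
                           st$output_mount),
        depth = st$depth, cfg = cfg, stage = label
      ),
      repartition_by = {
        record_stage(cfg, label, 0L, shuffles = 1L)
        repartition_by(ds, regex_key_fn(st$key_regex), st$partitions)
      },
      repartition = {
        record_stage(cfg, label, 0L, shuffles = 1L)
        repartition(ds, st$partitions)
      }
    ), error = function(e) e)

    after <- ledger_counts(cfg)
    elapsed <- proc.time()[["elapsed"]] - t0
    failed <- inherits(ds, "error")
    stages[[i]] <- list(
      stage = label, op = st$op,
      records_in = records_in,
      records_out = if (failed) NA_integer_ else sum(partition_sizes(ds)),
      partitions_out = if (failed) NA_integer_ else n_partitions(ds),
      invocations = after$invocations - before$invocations,
      shuffles = after$shuffles - before$shuffles,
      seconds = round(elapsed, 3),
      status = if (failed) "failed" else "ok",
      error = if (failed) conditionMessage(ds) else NULL
    )
    if (failed) {
      report <- finish_report(stages, spec, cfg, output_written = FALSE)
      stop(sprintf("stage %s failed: %s\n(partial report at %s)",
                   label, conditionMessage(ds), report$report_path),
           call. = FALSE)
    }
    say("%s: %d -> %d records, %d partitions, %d invocations, %.2fs",
        label, records_in, stages[[i]]$records_out,
        stages[[i]]$partitions_out, stages[[i]]$invocations, elapsed)
  }

  # write output
  if (spec$output$kind == "text") {
    if (ds$kind != "text") {
      stop("pipeline produced a binary dataset but output.kind is text",
           call. = FALSE)
    }
    writeBin(
      charToRaw(join_records(flatten_records(ds), spec$output$separator)),
      spec$output$path
    )
  } else {
    if (ds$kind != "binary") {
      stop("pipeline produced a text dataset but output.kind is binary",
           call. = FALSE)
    }
    dir.create(spec$output$path, recursive = TRUE, showWarnings = FALSE)
    recs <- flatten_records(ds)
    for (nm in names(recs)) {
      writeBin(recs[[nm]], file.path(spec$output$path, nm))
    }
  }
  report <- finish_report(stages, spec, cfg, output_written = TRUE,
                          records = sum(partition_sizes(ds)))
  say("output: %s (%d records); report: %s",
      spec$output$path, report$records, report$report_path)
  invisible(report)
}

finish_report <- function(stages, spec, cfg, output_written,
                          records = NA_integer_) {
  totals <- ledger_counts(cfg)
  report <- list(
    stages = stages,
    output = if (output_written) spec$output$path else NULL,
    records = records,
    invocations = totals$invocations,
    shuffles = totals$shuffles,
    engine = cfg$backend,
    parallelism = cfg$parallelism,
    seed = cfg$seed
  )
  report$report_path <- paste0(spec$output$path, ".report.json")
  ok <- tryCatch({
    jsonlite::write_json(report[setdiff(names(report), "report_path")],
                         report$report_path, auto_unbox = TRUE, null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) report$report_path <- NA_character_
  report
}
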