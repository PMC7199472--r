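# Execution engine: run one shell command with the staged input/output
# paths bound at the configured container paths. Two backends:
#   * "docker"     — `docker run --rm` with bind mounts (no network),
#   * "subprocess" — no isolation; the container paths occurring in the
#                    command string are rewritten to the staged host paths
#                    and the command runs under `sh -c` on the host.
# The subprocess backend exists so pipelines are testable without a
# container daemon; for pure POSIX commands the two backends are
# interchangeable.

#' Describe one container-based processing step
#'
#' A step is a container image reference plus a shell command plus the
#' input/output mount points the command reads from and writes to. The
#' command runs under `sh -c`, so pipes, redirection and multi-line shell
#' are all available — e.g. the GC-counting step
#' `grep -o [GC] /dna | wc -l > /count` with a text input mount at `/dna`
#' and a text output mount at `/count`.
#'
#' @param image Container image reference (`registry/name:tag`); ignored by
#'   the subprocess backend.
#' @param command Non-empty shell command string.
#' @param input A [text_mount()] or [binary_mount()] the staged partition
#'   is bound at.
#' @param output Mount point the command writes results to (must differ
#'   from the input path). The command itself creates the output file; the
#'   engine pre-creates only the staging area around it.
#' @param env Optional named character vector of extra environment
#'   variables for the command. The engine always adds `TASK_ID`, unique
#'   per (stage, partition, attempt) — commands that need clash-free output
#'   file names (e.g. multi-level binary reduces) should embed
#'   `${TASK_ID}`.
#' @return A container-step object.
#' @examples
#' container_step(
#'   "ubuntu:20.04", "grep -o [GC] /dna | wc -l > /count",
#'   input = text_mount("/dna"), output = text_mount("/count")
#' )
#' @export
container_step <- function(image, command, input, output, env = NULL) {
  stopifnot(inherits(input, "cmr_mount"), inherits(output, "cmr_mount"))
  if (!is.character(command) || length(command) != 1L || !nzchar(command)) {
    stop("command must be a non-empty string", call. = FALSE)
  }
  if (identical(input$container_path, output$container_path)) {
    stop("input and output container paths must be distinct", call. = FALSE)
  }
  if (!is.null(env)) {
    stopifnot(is.character(env), !is.null(names(env)), all(nzchar(names(env))))
  }
  structure(
    list(image = image, command = command, input = input, output = output,
         env = env),
    class = "cmr_step"
  )
}

#' @export
print.cmr_step <- function(x, ...) {
  cat(sprintf("<cmr_step> image %s\n  %s -> %s\n  command: %s\n",
              x$image, x$input$container_path, x$output$container_path,
              x$command))
  invisible(x)
}

#' Is a Docker daemon reachable?
#'
#' @return `TRUE` when the `docker` client is on the `PATH` and the daemon
#'   answers `docker info`.
#' @export
docker_available <- function() {
  if (Sys.which("docker") == "") return(FALSE)
  ok <- suppressWarnings(system2(
    "docker", "info", stdout = FALSE, stderr = FALSE
  ))
  identical(ok, 0L)
}

new_run_result <- function(exit_code, stdout_log, stderr_log, duration) {
  structure(
    list(exit_code = exit_code, stdout_log = stdout_log,
         stderr_log = stderr_log, duration = duration),
    class = "cmr_run_result"
  )
}

step_error <- function(message, result = NULL) {
  structure(
    class = c("cmr_step_error", "error", "condition"),
    list(message = message, call = NULL, result = result)
  )
}

read_log <- function(path) {
  if (file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    ""
  }
}

stderr_tail <- function(log, n = 10L) {
  lines <- strsplit(log, "\n", fixed = TRUE)[[1]]
  paste(utils::tail(lines, n), collapse = "\n")
}

# Rewrite container paths to host paths in a command string, longest path
# first so that e.g. "/out/sub" is never clobbered by a "/out" rewrite.
# Documented limitation: commands that compute paths dynamically at run
# time are not rewritten.
substitute_paths <- function(command, mapping) {
  for (cpath in names(mapping)[order(-nchar(names(mapping)))]) {
    command <- gsub(cpath, mapping[[cpath]], command, fixed = TRUE)
  }
  command
}

run_shell <- function(full_cmd, env = NULL, timeout = NULL, log_dir) {
  out_log <- file.path(log_dir, "stdout.log")
  err_log <- file.path(log_dir, "stderr.log")
  t0 <- proc.time()[["elapsed"]]
  code <- suppressWarnings(system2(
    "sh", c("-c", shQuote(full_cmd)),
    stdout = out_log, stderr = err_log,
    env = if (length(env)) paste0(names(env), "=", shQuote(env)),
    timeout = if (is.null(timeout)) 0 else timeout
  ))
  duration <- proc.time()[["elapsed"]] - t0
  new_run_result(code, read_log(out_log), read_log(err_log), duration)
}

#' Run one step against staged input/output paths
#'
#' Executes `step$command` with the staged partition visible at the step's
#' input container path and the output container path writable. The docker
#' backend bind-mounts `host_in` and a pre-created `host_out` into a
#' `--rm`, network-less container and runs `sh -c <command>` in it; the
#' subprocess backend rewrites the container paths inside the command
#' string to `host_in`/`host_out` and runs `sh -c` on the host.
#'
#' @param step A [container_step()].
#' @param host_in Staged input path (file for a text mount, directory for a
#'   binary mount), as returned by [materialize()].
#' @param host_out Host path where the output container path should land.
#' @param backend `"subprocess"` or `"docker"`.
#' @param env Extra environment variables (named character vector), merged
#'   over `step$env`.
#' @param timeout Seconds before the command is killed (default: no
#'   timeout — bioinformatics tools are long-running).
#' @param log_dir Directory for captured stdout/stderr (default: next to
#'   `host_out`).
#' @return A run result (`exit_code`, `stdout_log`, `stderr_log`,
#'   `duration`), invisibly on success. A nonzero exit raises an error of
#'   class `"cmr_step_error"` carrying the exit code, the stderr tail and
#'   the full run result.
#' @export
run_step <- function(step, host_in, host_out,
                     backend = c("subprocess", "docker"),
                     env = NULL, timeout = NULL, log_dir = NULL) {
  stopifnot(inherits(step, "cmr_step"))
  backend <- match.arg(backend)
  if (!file.exists(host_in)) {
    stop("staged input does not exist: ", host_in, call. = FALSE)
  }
  log_dir <- log_dir %||% dirname(host_out)
  dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
  all_env <- c(step$env, env)
  all_env <- all_env[!duplicated(names(all_env), fromLast = TRUE)]

  res <- if (backend == "subprocess") {
    mapping <- stats::setNames(
      c(host_in, host_out),
      c(step$input$container_path, step$output$container_path)
    )
    run_shell(substitute_paths(step$command, mapping),
              env = all_env, timeout = timeout, log_dir = log_dir)
  } else {
    if (Sys.which("docker") == "") {
      stop("docker backend requested but no docker client on PATH",
           call. = FALSE)
    }
    # Bind targets must exist on the host before `docker run`: pre-create
    # an empty output file (text) or directory (binary); the command then
    # writes through the bind.
    if (step$output$kind == "text") {
      if (!file.exists(host_out)) file.create(host_out)
    } else {
      dir.create(host_out, recursive = TRUE, showWarnings = FALSE)
    }
    args <- c(
      "run", "--rm", "--network", "none", "-w", "/",
      "-v", paste0(host_in, ":", step$input$container_path),
      "-v", paste0(host_out, ":", step$output$container_path),
      unlist(lapply(names(all_env), function(nm) {
        c("-e", paste0(nm, "=", all_env[[nm]]))
      })),
      step$image, "sh", "-c", step$command
    )
    out_log <- file.path(log_dir, "stdout.log")
    err_log <- file.path(log_dir, "stderr.log")
    t0 <- proc.time()[["elapsed"]]
    code <- suppressWarnings(system2(
      "docker", shQuote(args), stdout = out_log, stderr = err_log,
      timeout = if (is.null(timeout)) 0 else timeout
    ))
    new_run_result(code, read_log(out_log), read_log(err_log),
                   proc.time()[["elapsed"]] - t0)
  }

  if (!identical(res$exit_code, 0L)) {
    err <- res$stderr_log
    msg <- if (backend == "docker" && grepl("pull access denied|manifest unknown|Unable to find image", err)) {
      sprintf("failed to pull image '%s': %s", step$image, stderr_tail(err))
    } else if (res$exit_code == 124L && !is.null(timeout)) {
      sprintf("command timed out after %s s", timeout)
    } else {
      sprintf("command failed with exit code %d: %s",
              res$exit_code, stderr_tail(err))
    }
    stop(step_error(msg, res))
  }
  invisible(res)
}

#' Stream a partition through one tool instance
#'
#' Runs the step's command exactly once per partition, feeding all records
#' on the process's standard input and splitting its standard output back
#' into records — the pipe-based data handoff. Unlike a naive per-record
#' pipe, a 1,000-record partition still costs a single process start.
#' Requires a stream-safe command (reads stdin, writes stdout), e.g.
#' `sort`, `wc -l`, or an aligner that accepts reads on stdin.
#'
#' @param step A [container_step()]; the mount points' separators define
#'   how records are joined on stdin and split from stdout (the container
#'   paths are not used).
#' @param records Character vector of input text records.
#' @param backend,env,timeout,space As in [run_step()] / [temp_space()].
#' @return Character vector of output records.
#' @export
run_step_streaming <- function(step, records,
                               backend = c("subprocess", "docker"),
                               env = NULL, timeout = NULL,
                               space = temp_space()) {
  stopifnot(inherits(step, "cmr_step"))
  backend <- match.arg(backend)
  if (step$input$kind != "text" || step$output$kind != "text") {
    stop("streaming execution supports text mounts only", call. = FALSE)
  }
  stage <- new_staging_dir(space, "pipe")
  success <- FALSE
  on.exit(cleanup_staging(space, stage, success))
  stdin_file <- file.path(stage, "stdin.txt")
  stdout_file <- file.path(stage, "stdout.txt")
  writeBin(charToRaw(join_records(records, step$input$separator)), stdin_file)

  if (backend == "subprocess") {
    full <- sprintf("( %s ) < %s > %s", step$command,
                    shQuote(stdin_file), shQuote(stdout_file))
    res <- run_shell(full, env = c(step$env, env), timeout = timeout,
                     log_dir = stage)
  } else {
    inner <- sprintf("( %s ) < /.cmr_stdin > /.cmr_stdout", step$command)
    stream_step <- container_step(
      step$image, inner,
      input = text_mount("/.cmr_stdin", step$input$separator),
      output = text_mount("/.cmr_stdout", step$output$separator),
      env = step$env
    )
    res <- tryCatch(
      run_step(stream_step, stdin_file, stdout_file, backend = "docker",
               env = env, timeout = timeout, log_dir = stage),
      cmr_step_error = function(e) stop(e)
    )
  }
  if (!identical(res$exit_code, 0L)) {
    stop(step_error(sprintf(
      "streaming command failed with exit code %d: %s",
      res$exit_code, stderr_tail(res$stderr_log)
    ), res))
  }
  out <- ingest(text_mount("/.cmr_stdout", step$output$separator),
                stdout_file)
  success <- TRUE
  out
}
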