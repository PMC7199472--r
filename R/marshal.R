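# Marshaling: move one partition into a container-visible host file space
# and read command results back, honoring the TextFile / BinaryFiles mount
# contracts. A TextFile mount exposes the partition as a single file with
# every record followed by the separator; a BinaryFiles mount exposes it as
# a directory with one file per record.

#' Mount points: the partition <-> container file contract
#'
#' A mount point describes how a partition is exposed to (or read back
#' from) a container: `text_mount()` as a single separator-joined file at
#' `container_path`, `binary_mount()` as a directory holding one file per
#' record. Paths must be absolute and not `/`.
#'
#' @param container_path Absolute path inside the container
#'   (e.g. `"/dna"`, `"/out"`).
#' @param separator Record terminator for text mounts (non-empty; default
#'   newline, i.e. one record per line).
#' @return A mount-point object of kind `"text"` or `"binary"`.
#' @examples
#' text_mount("/in.sdf", separator = "\n$$$$\n")
#' binary_mount("/out")
#' @export
text_mount <- function(container_path, separator = "\n") {
  check_container_path(container_path)
  if (!is.character(separator) || length(separator) != 1L ||
      !nzchar(separator)) {
    stop("text mount separator must be a non-empty string", call. = FALSE)
  }
  structure(
    list(kind = "text", container_path = container_path,
         separator = separator),
    class = "cmr_mount"
  )
}

#' @rdname text_mount
#' @export
binary_mount <- function(container_path) {
  check_container_path(container_path)
  structure(
    list(kind = "binary", container_path = container_path, separator = NULL),
    class = "cmr_mount"
  )
}

check_container_path <- function(path) {
  if (!is.character(path) || length(path) != 1L || !startsWith(path, "/") ||
      path == "/") {
    stop("container path must be absolute and not the root directory",
         call. = FALSE)
  }
  invisible(path)
}

#' @export
print.cmr_mount <- function(x, ...) {
  cat(sprintf("<mount:%s> %s", x$kind, x$container_path))
  if (x$kind == "text") cat(sprintf(" (sep %s)", deparse(x$separator)))
  cat("\n")
  invisible(x)
}

#' Temporary staging space for container I/O
#'
#' Container commands read and write through files staged under `root`.
#' Point `root` at a tmpfs mount (e.g. `/dev/shm`) for in-memory staging,
#' or at a disk path when partitions are too large for tmpfs; the engine
#' behaves identically either way. Every run stages under a unique
#' directory `<root>/<run-id>/<stage>/<partition-index>/<attempt>/{in,out}`.
#'
#' @param root Existing writable directory (default: the session temporary
#'   directory, itself controlled by the `TMPDIR` environment variable).
#' @param cleanup When staging areas are removed: `"always"` (after the
#'   stage, pass or fail), `"on_success"`, or `"never"` (keep for
#'   debugging).
#' @return A temp-space object.
#' @export
temp_space <- function(root = tempdir(),
                       cleanup = c("always", "on_success", "never")) {
  cleanup <- match.arg(cleanup)
  if (!dir.exists(root)) {
    stop("temp space root does not exist: ", root, call. = FALSE)
  }
  if (file.access(root, mode = 2L) != 0L) {
    stop("temp space root is not writable: ", root, call. = FALSE)
  }
  structure(
    list(root = normalizePath(root), cleanup = cleanup),
    class = "cmr_temp_space"
  )
}

# Join records with terminator semantics: every record is followed by the
# separator, so an empty partition is a zero-length file and splitting the
# result reproduces the records exactly.
join_records <- function(records, separator) {
  if (length(records) == 0L) return("")
  paste0(paste0(records, separator), collapse = "")
}

#' Stage a partition for a container and read results back
#'
#' `materialize()` writes one partition into host file space in the layout
#' the mount point promises: a text mount yields a single file with each
#' record followed by the separator; a binary mount yields a directory with
#' one file per record, named by the record. `ingest()` is its inverse —
#' it reads a host file (text mount, split on the separator with terminator
#' semantics; a missing terminator on the final record is tolerated) or a
#' host directory (binary mount, byte-wise lexicographic name order) back
#' into a partition. `ingest(mount, materialize(partition, mount, space))`
#' reproduces the partition exactly.
#'
#' @param partition One element of a dataset's `$partitions` (character
#'   vector of text records, or named list of raw payloads).
#' @param mount A [text_mount()] or [binary_mount()] matching the partition
#'   kind.
#' @param space A [temp_space()]; staging happens in a fresh unique
#'   directory beneath its root unless `at` is given.
#' @param at Optional pre-created staging directory to use instead of a
#'   fresh one (the engine passes its per-task directory here).
#' @return `materialize()`: the host path (file or directory) to bind at
#'   `mount$container_path`. `ingest()`: the partition read from
#'   `host_path`.
#' @examples
#' sp <- temp_space()
#' p <- c("AT", "GC")
#' m <- text_mount("/dna")
#' path <- materialize(p, m, sp)
#' readLines(path) # "AT" "GC"
#' identical(ingest(m, path), p) # TRUE
#' @export
materialize <- function(partition, mount, space = temp_space(), at = NULL) {
  stopifnot(inherits(mount, "cmr_mount"))
  kind <- if (is.character(partition)) "text" else "binary"
  if (kind != mount$kind) {
    stop(sprintf("partition kind (%s) does not match mount kind (%s)",
                 kind, mount$kind), call. = FALSE)
  }
  stage <- at %||% new_staging_dir(space, "materialize")
  if (mount$kind == "text") {
    path <- file.path(stage, "part.txt")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(join_records(partition, mount$separator)), con)
    path
  } else {
    nm <- names(partition) %||% character(0)
    if (length(partition) && (is.null(names(partition)) || any(!nzchar(nm)) ||
        any(grepl("/", nm, fixed = TRUE)))) {
      stop("binary records need non-empty, slash-free names", call. = FALSE)
    }
    if (anyDuplicated(nm)) {
      dup <- nm[duplicated(nm)][1]
      clash <- which(nm == dup)
      stop(sprintf(
        "binary record name clash: records %d and %d are both named '%s'",
        clash[1], clash[2], dup
      ), call. = FALSE)
    }
    path <- file.path(stage, "part")
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(partition)) {
      writeBin(partition[[i]], file.path(path, nm[i]))
    }
    path
  }
}

#' @param host_path Host file (text mount) or directory (binary mount) to
#'   read back, typically the output a container command produced.
#' @rdname materialize
#' @export
ingest <- function(mount, host_path) {
  stopifnot(inherits(mount, "cmr_mount"))
  if (mount$kind == "text") {
    if (!file.exists(host_path) || dir.exists(host_path)) {
      stop("no output file at the configured mount: ", host_path,
           call. = FALSE)
    }
    text <- rawToChar(readBin(host_path, "raw", file.size(host_path)))
    split_records(text, mount$separator)
  } else {
    if (!dir.exists(host_path)) {
      stop("no output directory at the configured mount: ", host_path,
           call. = FALSE)
    }
    entries <- sort(list.files(host_path), method = "radix")
    paths <- file.path(host_path, entries)
    keep <- !dir.exists(paths)
    records <- lapply(paths[keep], function(p) {
      readBin(p, "raw", file.size(p))
    })
    names(records) <- entries[keep]
    records
  }
}

# Unique staging directory beneath the temp-space root; uniqueness (via
# tempfile) is what isolates concurrent materializations.
new_staging_dir <- function(space, prefix = "stage") {
  stopifnot(inherits(space, "cmr_temp_space"))
  dir <- tempfile(paste0(prefix, "_"), tmpdir = space$root)
  dir.create(dir, recursive = TRUE)
  dir
}

cleanup_staging <- function(space, dir, success) {
  if (!dir.exists(dir)) return(invisible())
  drop <- switch(space$cleanup,
    always = TRUE,
    on_success = isTRUE(success),
    never = FALSE
  )
  if (drop) unlink(dir, recursive = TRUE, force = TRUE)
  invisible()
}
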