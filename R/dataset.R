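# Partitioned dataset: an ordered list of partitions, each processed as one
# unit by a single container invocation. Text partitions are character
# vectors (one element per record, no embedded separator); binary partitions
# are named lists of raw vectors (one file-like record per element).

new_dataset <- function(partitions, kind, separator = NULL) {
  stopifnot(kind %in% c("text", "binary"), is.list(partitions))
  if (kind == "text" && (is.null(separator) || !nzchar(separator))) {
    stop("a text dataset needs a non-empty record separator", call. = FALSE)
  }
  structure(
    list(partitions = partitions, kind = kind, separator = separator),
    class = "cmr_dataset"
  )
}

#' @export
print.cmr_dataset <- function(x, ...) {
  sizes <- partition_sizes(x)
  cat(sprintf(
    "<cmr_dataset> %s, %d partition%s, %d record%s\n",
    x$kind, length(sizes), if (length(sizes) == 1) "" else "s",
    sum(sizes), if (sum(sizes) == 1) "" else "s"
  ))
  if (x$kind == "text") {
    cat(sprintf("  separator: %s\n", deparse(x$separator)))
  }
  cat(sprintf(
    "  partition sizes: %s\n",
    paste(utils::head(sizes, 20), collapse = " ")
  ))
  invisible(x)
}

#' Number and sizes of partitions
#'
#' @param ds A dataset built with [from_text()] or [from_binary_dir()].
#' @return `n_partitions()`: the partition count; `partition_sizes()`: an
#'   integer vector of per-partition record counts.
#' @export
n_partitions <- function(ds) {
  stopifnot(inherits(ds, "cmr_dataset"))
  length(ds$partitions)
}

#' @rdname n_partitions
#' @export
partition_sizes <- function(ds) {
  stopifnot(inherits(ds, "cmr_dataset"))
  vapply(ds$partitions, length, integer(1))
}

# Terminator-semantics split: the separator terminates records, so a source
# ending with the separator contributes no trailing empty record (base
# strsplit already drops exactly one terminal empty fragment).
split_records <- function(text, separator) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(separator)) {
    stop("record separator must be non-empty", call. = FALSE)
  }
  if (!nzchar(text)) return(character(0))
  strsplit(text, separator, fixed = TRUE, useBytes = TRUE)[[1]]
}

# Contiguous block assignment: blocks of size ceiling(R / n) in record
# order, so record adjacency survives partitioning. Trailing partitions may
# be empty; empty partitions are legal dataset members.
block_partition <- function(records, num_partitions) {
  n <- as.integer(num_partitions)
  stopifnot(length(n) == 1L, !is.na(n), n >= 1L)
  r <- length(records)
  block <- if (r == 0L) 0L else as.integer(ceiling(r / n))
  lapply(seq_len(n) - 1L, function(i) {
    lo <- i * block + 1L
    hi <- min((i + 1L) * block, r)
    if (block == 0L || lo > r) records[0L] else records[lo:hi]
  })
}

#' Build a partitioned text dataset
#'
#' Splits a text source into records on a configurable record separator and
#' distributes the records over `num_partitions` contiguous blocks of size
#' `ceiling(R / num_partitions)`. The separator is treated as a record
#' *terminator*: a source ending with the separator yields no trailing empty
#' record, and writing a partition back out re-appends the separator after
#' every record. The default separator is a newline, so each line is one
#' record; an SDF molecule library uses `"\n$$$$\n"` so each `"$$$$"`
#' -terminated molecule block is one record.
#'
#' @param source A length-one character blob, or (with `from_file = TRUE`) a
#'   path to a text file read as bytes.
#' @param separator Non-empty record separator string.
#' @param num_partitions Number of partitions (>= 1). Empty input still
#'   produces `num_partitions` (empty) partitions.
#' @param from_file Read `source` as a file path instead of a literal blob.
#' @return A partitioned dataset object.
#' @examples
#' ds <- from_text("AT\nGC\nTT", "\n", num_partitions = 2)
#' partition_sizes(ds) # 2 1
#' collect_records(ds)
#' @export
from_text <- function(source, separator = "\n", num_partitions = 1L,
                      from_file = FALSE) {
  if (from_file) {
    if (!file.exists(source)) {
      stop("input file not found: ", source, call. = FALSE)
    }
    source <- rawToChar(readBin(source, "raw", file.size(source)))
  }
  records <- split_records(source, separator)
  new_dataset(block_partition(records, num_partitions), "text", separator)
}

#' Build a partitioned binary dataset from a directory of files
#'
#' Every regular file in `directory` becomes one binary record (name +
#' payload bytes), ordered by byte-wise lexicographic file name and
#' block-partitioned as in [from_text()]. Subdirectories are skipped with a
#' warning.
#'
#' @param directory Existing directory.
#' @param num_partitions Number of partitions (>= 1).
#' @return A partitioned dataset of kind `"binary"`.
#' @export
from_binary_dir <- function(directory, num_partitions = 1L) {
  if (!dir.exists(directory)) {
    stop("directory not found: ", directory, call. = FALSE)
  }
  entries <- sort(list.files(directory, all.files = FALSE), method = "radix")
  paths <- file.path(directory, entries)
  is_dir <- dir.exists(paths)
  if (any(is_dir)) {
    warning(
      "skipping subdirectories: ", paste(entries[is_dir], collapse = ", "),
      call. = FALSE
    )
  }
  entries <- entries[!is_dir]
  paths <- paths[!is_dir]
  records <- lapply(paths, function(p) readBin(p, "raw", file.size(p)))
  names(records) <- entries
  new_dataset(block_partition(records, num_partitions), "binary")
}

# Flatten partitions in index order. Text -> character vector; binary ->
# named list of raw payloads.
flatten_records <- function(ds) {
  stopifnot(inherits(ds, "cmr_dataset"))
  if (ds$kind == "text") {
    unlist(ds$partitions, use.names = FALSE) %||% character(0)
  } else {
    do.call(c, c(list(), ds$partitions))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collect all records of a dataset in partition order
#'
#' @param ds A partitioned dataset.
#' @return For text datasets, a character vector of records; for binary
#'   datasets, a named list of raw payloads.
#' @export
collect_records <- function(ds) {
  flatten_records(ds)
}

#' Change the number of partitions
#'
#' Re-blocks the flattened record sequence (origin partition order, then
#' origin offset) into exactly `num_partitions` contiguous partitions. The
#' record multiset is preserved; no record is ever split. Trailing
#' partitions may be empty — the partition count is a contract, not a hint.
#'
#' @param ds A partitioned dataset.
#' @param num_partitions Target partition count (>= 1).
#' @return A dataset with exactly `num_partitions` partitions.
#' @export
repartition <- function(ds, num_partitions) {
  stopifnot(inherits(ds, "cmr_dataset"))
  new_dataset(
    block_partition(flatten_records(ds), num_partitions),
    ds$kind, ds$separator
  )
}

#' Colocate records by key with a deterministic hash partitioner
#'
#' Computes `key_fn(record)` for every record and assigns the record to
#' partition `stable_hash(key) %% num_partitions` (64-bit FNV-1a, see
#' [stable_hash()]). All records sharing a key therefore land in the same
#' partition — e.g. keying aligned reads by chromosome guarantees a
#' downstream variant caller sees every read of a chromosome at once.
#' Within each output partition, records keep their original order
#' (origin partition index, then origin offset).
#'
#' @param ds A partitioned dataset.
#' @param key_fn Deterministic function of one record returning a single key
#'   string. Text records are passed as length-one character strings; binary
#'   records as `list(name =, payload =)`.
#' @param num_partitions Target partition count (>= 1).
#' @return A dataset with `num_partitions` partitions and equal-key records
#'   colocated.
#' @examples
#' ds <- from_text("chr1\tr1\nchr2\tr2\nchr1\tr3", "\n", 2)
#' out <- repartition_by(ds, function(r) sub("\t.*", "", r), 4)
#' @export
repartition_by <- function(ds, key_fn, num_partitions) {
  stopifnot(inherits(ds, "cmr_dataset"), is.function(key_fn))
  n <- as.integer(num_partitions)
  stopifnot(length(n) == 1L, !is.na(n), n >= 1L)

  sizes <- partition_sizes(ds)
  records <- flatten_records(ds)
  origin_part <- rep(seq_along(sizes) - 1L, sizes)
  origin_off <- unlist(lapply(sizes, seq_len), use.names = FALSE) - 1L

  keys <- character(length(records))
  for (i in seq_along(records)) {
    rec <- if (ds$kind == "text") {
      records[[i]]
    } else {
      list(name = names(records)[[i]], payload = records[[i]])
    }
    key <- tryCatch(key_fn(rec), error = function(e) e)
    if (inherits(key, "error")) {
      stop(sprintf(
        "key function failed on record at partition %d, offset %d: %s",
        origin_part[i], origin_off[i], conditionMessage(key)
      ), call. = FALSE)
    }
    if (!is.character(key) || length(key) != 1L || is.na(key)) {
      stop(sprintf(
        "key function must return one key string (partition %d, offset %d)",
        origin_part[i], origin_off[i]
      ), call. = FALSE)
    }
    keys[i] <- key
  }

  target <- if (length(keys)) .fnv1a64_mod(keys, n) else integer(0)
  parts <- lapply(seq_len(n) - 1L, function(p) records[target == p])
  new_dataset(parts, ds$kind, ds$separator)
}
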