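# Seeded synthetic-data generators and native (in-R) oracles. Every demo
# pipeline and every property test runs offline against these: random DNA
# text with a controllable GC fraction, a toy SDF-dialect molecule library
# with deterministic per-record score tags, and tagged sequencing-read
# records keyed by chromosome. Identical seeds give byte-identical output.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate random DNA text
#'
#' Draws `length` bases i.i.d. over `{A, C, G, T}` with
#' `P(G) = P(C) = gc_fraction / 2`, broken into newline-terminated lines of
#' 80 bases. The realized G+C count is Binomial(`length`, `gc_fraction`),
#' so it falls within a few standard deviations of
#' `length * gc_fraction`.
#'
#' @param length Number of bases (>= 1; 0 returns the empty string).
#' @param gc_fraction Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; same seed, same bytes.
#' @return One character blob of newline-terminated 80-base lines.
#' @examples
#' gc_count(gen_dna(1000, 0.5, seed = 42)) # about 500
#' @export
gen_dna <- function(length, gc_fraction = 0.5, seed = 1L) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L) {
    stop("length must be a non-negative integer", call. = FALSE)
  }
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  if (length == 0L) return("")
  # A=65 C=67 G=71 T=84; draw code points then interleave newline (10)
  # every 80 bases so the whole blob is built in two vectorized calls.
  codes <- with_seed(seed, sample(
    c(65L, 67L, 71L, 84L), length, replace = TRUE,
    prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)
  ))
  line_of <- (seq_len(length) - 1L) %/% 80L
  pos <- seq_len(length) + line_of # shift right by one slot per full line
  out <- integer(length + line_of[length] + 1L)
  out[pos] <- codes
  out[-pos] <- 10L
  out[length(out)] <- 10L # final line terminator
  intToUtf8(out)
}

# Deterministic molecule score: FNV-1a of the molecule block, scaled to
# [0, 100) with 5 decimals.
score_from_block <- function(block) {
  .fnv1a64_mod(block, 10000000L) / 1e5
}

#' Generate a toy SDF-dialect molecule library
#'
#' Emits `n_molecules` molecule records in the Structure-Data File dialect
#' used throughout the package: each record is a small fake molecule block
#' followed by a `> <score>` data tag and the `"$$$$"` terminator line, so
#' the whole library parses with record separator `"\n$$$$\n"`. The score
#' is computed deterministically from the molecule block
#' (`stable_hash(block)` scaled to `[0, 100)`) and nudged with a
#' deterministic per-index salt in the rare case of a collision, so all
#' `n_molecules` scores are distinct — top-N selections are unambiguous.
#' No chemistry is simulated; only the record/tag structure matters.
#'
#' @param n_molecules Number of molecule records (>= 0).
#' @param seed Integer seed; same seed, same bytes.
#' @return One character blob of `"$$$$"`-terminated records.
#' @examples
#' lib <- gen_sdf_library(10, seed = 7)
#' ds <- from_text(lib, "\n$$$$\n", num_partitions = 2)
#' @export
gen_sdf_library <- function(n_molecules, seed = 1L) {
  n <- as.integer(n_molecules)
  stopifnot(!is.na(n), n >= 0L)
  if (n == 0L) return("")
  coords <- with_seed(seed, matrix(round(stats::runif(n * 6, -10, 10), 4),
                                   nrow = n))
  blocks <- vapply(seq_len(n), function(i) {
    paste0(
      sprintf("CMPD%06d", i), "\n",
      "  cmr toy library\n", "\n",
      "  2  1  0  0  0  0  0  0  0  0999 V2000\n",
      sprintf("%10.4f%10.4f%10.4f C   0  0\n",
              coords[i, 1], coords[i, 2], coords[i, 3]),
      sprintf("%10.4f%10.4f%10.4f O   0  0\n",
              coords[i, 4], coords[i, 5], coords[i, 6]),
      "  1  2  1  0\n",
      "M  END"
    )
  }, character(1))
  scores <- score_from_block(blocks)
  # resolve score collisions deterministically (index-salted rehash)
  salt <- 0L
  while (anyDuplicated(scores) && salt < 1000L) {
    salt <- salt + 1L
    dup <- duplicated(scores)
    scores[dup] <- score_from_block(
      paste0(blocks[dup], "#", which(dup), "#", salt)
    )
  }
  records <- sprintf("%s\n> <score>\n%.5f\n", blocks, scores)
  paste0(paste0(records, "\n$$$$\n"), collapse = "")
}

#' Generate tagged sequencing-read records
#'
#' Emits `n_reads` tab-separated text records of the form
#' `chr<k>\t<read id>\t<sequence>` — the shape of an aligned read whose
#' first field is the chromosome it mapped to. When
#' `n_reads >= length(chromosomes)` every chromosome is guaranteed to
#' appear at least once; assignment is otherwise uniform at random.
#'
#' @param n_reads Number of read records (>= 0).
#' @param chromosomes Non-empty character vector of chromosome labels
#'   (default `chr1`..`chr22`, `chrX`).
#' @param seed Integer seed; same seed, same bytes.
#' @param read_length Bases per read sequence (default 36).
#' @return Character vector of records (join with `"\n"` for a text blob).
#' @export
gen_tagged_reads <- function(n_reads,
                             chromosomes = c(paste0("chr", 1:22), "chrX"),
                             seed = 1L, read_length = 36L) {
  n <- as.integer(n_reads)
  stopifnot(!is.na(n), n >= 0L, length(chromosomes) >= 1L,
            is.character(chromosomes))
  if (n == 0L) return(character(0))
  with_seed(seed, {
    keys <- if (n >= length(chromosomes)) {
      sample(c(chromosomes,
               sample(chromosomes, n - length(chromosomes), replace = TRUE)))
    } else {
      sample(chromosomes, n, replace = TRUE)
    }
    seqs <- vapply(seq_len(n), function(i) {
      intToUtf8(sample(c(65L, 67L, 71L, 84L), read_length, replace = TRUE))
    }, character(1))
    sprintf("%s\tread%06d\t%s", keys, seq_len(n), seqs)
  })
}

#' Native oracles: GC count, top-N by score, key histogram
#'
#' Single-pass reference computations used to verify pipeline results:
#' `gc_count()` counts G and C characters in a text blob; `top_n_records()`
#' returns the `n` records with the highest `score_fn` value (all records
#' when fewer than `n`); `key_histogram()` tabulates records by
#' `key_fn(record)`.
#'
#' @param text Character blob (any line structure).
#' @return `gc_count()`: integer count.
#' @examples
#' gc_count("ATGC") # 2
#' @export
gc_count <- function(text) {
  stopifnot(is.character(text))
  sum(nchar(gsub("[^GCgc]", "", text, perl = TRUE)))
}

#' @param records Character vector of records.
#' @param n Number of records to keep.
#' @param score_fn Function from one record to a numeric score (default:
#'   [sdf_score()], the `> <score>` tag value).
#' @return `top_n_records()`: the selected records, highest score first.
#' @rdname gc_count
#' @export
top_n_records <- function(records, n, score_fn = sdf_score) {
  stopifnot(is.character(records), n >= 0)
  scores <- vapply(records, function(r) as.numeric(score_fn(r)), numeric(1),
                   USE.NAMES = FALSE)
  keep <- utils::head(order(scores, decreasing = TRUE), n)
  records[keep]
}

#' @param key_fn Function from one record to a key string.
#' @return `key_histogram()`: named integer vector of per-key counts,
#'   sorted by key.
#' @rdname gc_count
#' @export
key_histogram <- function(records, key_fn) {
  stopifnot(is.character(records), is.function(key_fn))
  keys <- vapply(records, function(r) as.character(key_fn(r)), character(1),
                 USE.NAMES = FALSE)
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))[order(names(tab))]
}

#' Read the score tag of an SDF-dialect record
#'
#' Extracts the numeric value on the line following the `> <score>` data
#' tag of one molecule record (as produced by [gen_sdf_library()]).
#'
#' @param record One molecule record (no `"$$$$"` terminator).
#' @return The score as a numeric scalar (`NA` when no tag is present).
#' @export
sdf_score <- function(record) {
  lines <- strsplit(record, "\n", fixed = TRUE)[[1]]
  at <- grep("^> *<score>", lines)
  if (!length(at) || at[1] == length(lines)) return(NA_real_)
  as.numeric(lines[at[1] + 1L])
}
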