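# Engine: one command per partition, subprocess and docker backends.

run_in_stage <- function(step, records, out_name = "out.txt") {
  sp <- temp_space(local_dir())
  stage <- local_dir("stage")
  host_in <- materialize(records, step$input, sp, at = stage)
  host_out <- file.path(stage, out_name)
  res <- run_step(step, host_in, host_out, backend = "subprocess")
  list(result = res, records = ingest(step$output, host_out))
}

test_that("a grep|wc command counts GC characters of the staged partition", {
  got <- run_in_stage(gc_step(), "ATGC")
  expect_identical(got$records, "2")
  # independent oracle: count G/C characters directly
  expect_identical(got$records,
                   as.character(sum(strsplit("ATGC", "")[[1]] %in% c("G", "C"))))
})

test_that("an identity command reproduces the input records", {
  recs <- c("MOL1\na", "MOL2\nb")
  step <- container_step("ubuntu", "cp /in.sdf /out.sdf",
                         text_mount("/in.sdf", "\n$$$$\n"),
                         text_mount("/out.sdf", "\n$$$$\n"))
  expect_identical(run_in_stage(step, recs)$records, recs)
})

test_that("nonzero exits raise errors carrying the exit code", {
  step <- container_step("ubuntu", "echo oops >&2; exit 3",
                         text_mount("/in"), text_mount("/out"))
  sp <- temp_space(local_dir())
  stage <- local_dir("stage")
  host_in <- materialize("x", step$input, sp, at = stage)
  err <- tryCatch(
    run_step(step, host_in, file.path(stage, "out.txt"),
             backend = "subprocess"),
    cmr_step_error = function(e) e
  )
  expect_s3_class(err, "cmr_step_error")
  expect_equal(err$result$exit_code, 3L)
  expect_match(conditionMessage(err), "exit code 3")
  expect_match(conditionMessage(err), "oops") # stderr tail surfaced
})

test_that("missing staged input and empty commands are rejected up front", {
  step <- container_step("ubuntu", "true",
                         text_mount("/in"), text_mount("/out"))
  expect_error(run_step(step, file.path(tempdir(), "nope"), tempfile()),
               "staged input")
  expect_error(container_step("ubuntu", "", text_mount("/in"),
                              text_mount("/out")), "non-empty")
  expect_error(container_step("ubuntu", "true", text_mount("/same"),
                              text_mount("/same")), "distinct")
})

test_that("commands honor the per-step timeout", {
  step <- container_step("ubuntu", "sleep 30",
                         text_mount("/in"), text_mount("/out"))
  sp <- temp_space(local_dir())
  stage <- local_dir("stage")
  host_in <- materialize("x", step$input, sp, at = stage)
  t0 <- proc.time()[["elapsed"]]
  expect_error(
    run_step(step, host_in, file.path(stage, "out.txt"),
             backend = "subprocess", timeout = 1),
    "timed out|exit code"
  )
  expect_lt(proc.time()[["elapsed"]] - t0, 10)
})

test_that("streaming runs one process per partition with stdin/stdout records", {
  cat_step <- container_step("ubuntu", "cat",
                             text_mount("/i"), text_mount("/o"))
  recs <- sprintf("rec%04d", 1:1000)
  expect_identical(run_step_streaming(cat_step, recs), recs)

  wc_step <- container_step("ubuntu", "wc -l",
                            text_mount("/i"), text_mount("/o"))
  got <- run_step_streaming(wc_step, c("a", "b", "c", "d", "e"))
  expect_identical(trimws(got), "5") # line-count oracle: 5 terminated lines

  sort_step <- container_step("ubuntu", "sort",
                              text_mount("/i"), text_mount("/o"))
  lines <- random_lines(100, seed = 3)
  got <- run_step_streaming(sort_step, lines)
  expect_identical(got, sort(lines, method = "radix"))

  fail <- container_step("ubuntu", "exit 7", text_mount("/i"),
                         text_mount("/o"))
  expect_error(run_step_streaming(fail, "x"), "exit code 7")
})

test_that("docker and subprocess backends agree on a pure POSIX command", {
  skip_if(!docker_available(), "no reachable docker daemon")
  step <- gc_step()
  sp <- temp_space(local_dir())
  stage_s <- local_dir("stage")
  host_in <- materialize(c("ATGC", "GGCC"), step$input, sp, at = stage_s)
  out_s <- file.path(stage_s, "out_sub.txt")
  run_step(step, host_in, out_s, backend = "subprocess")
  out_d <- file.path(stage_s, "out_doc.txt")
  run_step(step, host_in, out_d, backend = "docker")
  expect_identical(ingest(step$output, out_d), ingest(step$output, out_s))
})
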