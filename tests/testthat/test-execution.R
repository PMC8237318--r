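# Environment materialization, script/interpreter/runner execution, logs.

test_that("build_environment exposes declared params, globals and engine vars only", {
  doc <- pipeline_doc(
    params = list(param_def("name", ""), param_def("output", ""),
                  param_def("genome", ""),
                  param_def("shared", "", global = TRUE)),
    tasks = list(task_def("greetings", params = c("name", "output"))))
  env <- build_environment(iteration_unit("greetings"), doc,
                           c(name = "World", output = "/tmp/o",
                             genome = "hg38", shared = "yes"))
  expect_equal(env[["name"]], "World")
  expect_equal(env[["output"]], "/tmp/o")
  expect_equal(env[["shared"]], "yes")
  expect_false("genome" %in% names(env))   # undeclared, not global
  expect_equal(env[["task_id"]], "greetings")
  expect_true("working_dir" %in% names(env))
})

test_that("iteration units bind the item variable; missing values error", {
  doc <- pipeline_doc(tasks = list(foreach_def("f", "list", "x", "sample")))
  env <- build_environment(iteration_unit("f", 0L, "case-1"), doc)
  expect_equal(env[["sample"]], "case-1")

  doc2 <- pipeline_doc(params = list(param_def("p", "")),
                       tasks = list(task_def("t", params = "p")))
  expect_error(build_environment(iteration_unit("t"), doc2),
               class = "dagrun_missing_param")
  # default value fills in; explicit value overrides the default
  doc3 <- pipeline_doc(params = list(param_def("p", "", "dflt")),
                       tasks = list(task_def("t", params = "p")))
  expect_equal(build_environment(iteration_unit("t"), doc3)[["p"]], "dflt")
  expect_equal(build_environment(iteration_unit("t"), doc3,
                                 c(p = "given"))[["p"]], "given")
})

test_that("run_script captures output and exit status without throwing", {
  u <- iteration_unit("t")
  r <- run_script(u, "echo hello", character(), settings = quiet_settings())
  expect_equal(r$exit_status, 0L)
  expect_equal(r$stdout_text, "hello\n")
  r3 <- run_script(u, "exit 3", character(), settings = quiet_settings())
  expect_equal(r3$exit_status, 3L)
  rerr <- run_script(u, "echo oops >&2; false", character(),
                     settings = quiet_settings())
  expect_equal(rerr$exit_status, 1L)
  expect_equal(rerr$stderr_text, "oops\n")
})

test_that("interpreters receive the task code via task_code", {
  u <- iteration_unit("t")
  r <- run_script(u, "echo hi", character(),
                  interpreter = "printf '%s' \"$task_code\" | tr 'a-z' 'A-Z'",
                  settings = quiet_settings())
  expect_equal(r$exit_status, 0L)
  expect_equal(r$stdout_text, "ECHO HI")
  # byte fidelity through the interpreter, including quotes and newlines
  tricky <- "a'b\"c\\d\n$e\ttail"
  r2 <- run_script(u, tricky, character(),
                   interpreter = "printf '%s' \"$task_code\"",
                   settings = quiet_settings())
  expect_identical(r2$stdout_text, tricky)
})

test_that("runners execute assigned tasks and see task_code and task_id", {
  rn <- runner_def("a", "echo \"RUN:$task_id\"; eval \"$task_code\"")
  u <- iteration_unit("a")
  r <- run_with_runner(rn, u, "echo payload", character(),
                       settings = quiet_settings())
  expect_equal(r$exit_status, 0L)
  expect_equal(r$stdout_text, "RUN:a\npayload\n")
  expect_error(run_with_runner(rn, iteration_unit("other"), "true",
                               character(), settings = quiet_settings()),
               class = "dagrun_runner_error")
})

test_that("runner assignment routes listed tasks through the runner only", {
  wd <- tempfile(); dir.create(wd)
  mk <- function(id) task_def(id, params = "wd",
                              code = paste0("echo local >> \"$wd/", id, "\"\n"))
  doc <- pipeline_doc(params = list(param_def("wd", "", global = TRUE)),
                      tasks = list(mk("a"), mk("b"), mk("c")))
  runners <- parse_runners(paste0(
    "<runners><runner tasks=\"a b\"><![CDATA[",
    "echo runner >> \"$wd/$task_id\"\n",
    "eval \"$task_code\"]]></runner></runners>"))
  rep <- run_pipeline(doc, c(wd = wd),
                      quiet_settings(runners = runners))
  expect_true(rep$success)
  expect_equal(readLines(file.path(wd, "a")), c("runner", "local"))
  expect_equal(readLines(file.path(wd, "b")), c("runner", "local"))
  expect_equal(readLines(file.path(wd, "c")), "local")       # not assigned
})

test_that("a cluster-style pass-through runner preserves the task environment", {
  # emulates a submission wrapper that must export all environment variables
  wd <- tempfile(); dir.create(wd)
  doc <- pipeline_doc(
    params = list(param_def("wd", "", global = TRUE),
                  param_def("sample_rate", "")),
    tasks = list(task_def("job", params = "sample_rate",
                          code = "echo \"$sample_rate\" > \"$wd/observed\"\n")))
  runners <- list(runner_def("job",
    "printf '%s' \"$task_code\" | bash -s"))
  rep <- run_pipeline(doc, c(wd = wd, sample_rate = "0.25"),
                      quiet_settings(runners = runners))
  expect_true(rep$success)
  expect_equal(readLines(file.path(wd, "observed")), "0.25")
})

test_that("runner configuration problems are caught before any unit runs", {
  doc <- pipeline_doc(tasks = list(task_def("a", code = "true")))
  expect_error(
    run_pipeline(doc, settings = quiet_settings(
      runners = list(runner_def("ghost", "true")))),
    class = "dagrun_runner_error")
  expect_error(
    run_pipeline(doc, settings = quiet_settings(
      runners = list(runner_def("a", "true"), runner_def("a", "true")))),
    class = "dagrun_runner_error")
  expect_error(parse_runners(tempfile("missing-runners-")),
               class = "dagrun_runner_error")
})

test_that("logging writes exactly three task-prefixed files when enabled", {
  logs <- tempfile(); dir.create(logs)
  doc <- pipeline_doc(tasks = list(
    task_def("hello", code = "echo out_line; echo err_line >&2")))
  rep <- run_pipeline(doc, settings = quiet_settings(log_dir = logs))
  expect_true(rep$success)
  expect_setequal(list.files(logs),
                  c("hello.out.log", "hello.err.log", "hello.params"))
  expect_equal(readLines(file.path(logs, "hello.out.log")), "out_line")
  expect_equal(readLines(file.path(logs, "hello.err.log")), "err_line")
  pl <- readLines(file.path(logs, "hello.params"))
  expect_true("task_id=hello" %in% pl)
  expect_equal(pl, sort(pl))   # name-sorted

  # log_exclude drops the task's files; no log_dir writes nothing
  logs2 <- tempfile(); dir.create(logs2)
  run_pipeline(doc, settings = quiet_settings(log_dir = logs2,
                                              log_exclude = "hello"))
  expect_length(list.files(logs2), 0)
  before <- length(list.files(tempdir(), recursive = TRUE))
  rep3 <- run_pipeline(doc, settings = quiet_settings())
  expect_true(rep3$success)

  expect_error(run_settings(log_only = "a", log_exclude = "b"),
               class = "dagrun_settings_error")
})

test_that("foreach iterations append to the task's log files in unit order", {
  logs <- tempfile(); dir.create(logs)
  doc <- pipeline_doc(tasks = list(
    foreach_def("loop", "list", "x,y,z", "item", code = "echo \"got $item\"")))
  rep <- run_pipeline(doc, settings = quiet_settings(log_dir = logs,
                                                     max_parallel = 3))
  expect_true(rep$success)
  expect_setequal(list.files(logs),
                  c("loop.out.log", "loop.err.log", "loop.params"))
  expect_equal(readLines(file.path(logs, "loop.out.log")),
               c("got x", "got y", "got z"))
})

test_that("environment hygiene holds for a probe task at run time", {
  wd <- tempfile(); dir.create(wd)
  doc <- pipeline_doc(
    params = list(param_def("mine", ""), param_def("other", ""),
                  param_def("everyone", "", global = TRUE),
                  param_def("envfile", "", global = TRUE)),
    tasks = list(task_def("probe", params = "mine",
                          code = "env > \"$envfile\"\n")))
  envfile <- file.path(wd, "env.txt")
  rep <- run_pipeline(doc, c(mine = "1", other = "2", everyone = "3",
                             envfile = envfile), quiet_settings())
  expect_true(rep$success)
  seen <- sub("=.*", "", readLines(envfile))
  expect_true(all(c("mine", "everyone", "envfile", "task_id",
                    "working_dir") %in% seen))
  expect_false("other" %in% seen)
})
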