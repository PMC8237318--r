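# Item resolution, foreach expansion, guards, the run loop, and resume.

test_that("item sources resolve in order for every kind", {
  mk <- function(kind, arg) foreach_def("f", kind, arg, "item")
  expect_equal(resolve_items(mk("list", "case-1,case-2,control-1,control-2")),
               c("case-1", "case-2", "control-1", "control-2"))
  expect_equal(resolve_items(mk("list", " a , b ,c")), c("a", "b", "c"))
  expect_equal(resolve_items(mk("range", "1..4")), c("1", "2", "3", "4"))
  expect_equal(resolve_items(mk("range", "3..1")), c("3", "2", "1"))
  expect_equal(resolve_items(mk("command", "printf 'A\\nB\\nC\\n'")),
               c("A", "B", "C"))
  expect_equal(resolve_items(mk("param_values", "samples"),
                             c(samples = "x, y")), c("x", "y"))

  d <- tempfile(); dir.create(d)
  file.create(file.path(d, c("b.txt", "a.txt")))
  dir.create(file.path(d, "subdir"))  # directories are not items
  got <- resolve_items(mk("files_in_dir", d))
  expect_equal(basename(got), c("a.txt", "b.txt"))

  expect_error(resolve_items(mk("command", "exit 3")),
               class = "dagrun_foreach_error")
  expect_error(resolve_items(mk("files_in_dir", file.path(d, "missing"))),
               class = "dagrun_foreach_error")
  expect_error(resolve_items(mk("param_values", "unset")),
               class = "dagrun_foreach_error")
})

test_that("expand_foreach creates one indexed unit per item", {
  f <- foreach_def("f", "list", "", "item")
  u <- expand_foreach(f, c("case-1", "case-2", "control-1", "control-2"))
  expect_length(u, 4)
  expect_equal(vapply(u, `[[`, 0L, "item_index"), 0:3)
  expect_equal(vapply(u, `[[`, "", "unit_id"),
               sprintf("f[%d]", 0:3))
  expect_length(expand_foreach(f, character()), 0)
  one <- expand_foreach(f, "x")
  expect_equal(one[[1]]$unit_id, "f[0]")
  expect_equal(one[[1]]$item_value, "x")
})

test_that("guards map exit status to run/skip and flag unexecutable guards", {
  present <- tempfile(); file.create(present)
  t1 <- task_def("t", if_guard = paste0("test -f ", present))
  expect_true(evaluate_guard(t1, character(), quiet_settings()))
  t2 <- task_def("t", if_guard = "false")
  expect_false(evaluate_guard(t2, character(), quiet_settings()))
  t3 <- task_def("t", if_guard = "/nonexistent/binary-xyz")
  expect_error(evaluate_guard(t3, character(), quiet_settings()),
               class = "dagrun_guard_error")
})

test_that("a guard-skipped task is recorded and its dependents still run", {
  log <- tempfile()
  doc <- pipeline_doc(
    params = list(param_def("log", "", global = TRUE)),
    tasks = list(
      task_def("a", code = "echo a >> \"$log\"\n"),
      task_def("skipme", code = "echo NO >> \"$log\"\n", after = "a",
               if_guard = "false"),
      task_def("c", code = "echo c >> \"$log\"\n", after = "skipme")
    ))
  rep <- run_pipeline(doc, c(log = log), quiet_settings())
  expect_true(rep$success)
  st <- stats::setNames(rep$units$state, rep$units$unit_id)
  expect_equal(st[["skipme"]], "skipped-by-guard")
  expect_equal(readLines(log), c("a", "c"))
})

test_that("a zero-item foreach completes immediately as done", {
  doc <- pipeline_doc(tasks = list(
    foreach_def("empty", "list", "", "x", code = "exit 9"),
    task_def("next_task", code = "true", after = "empty")))
  rep <- run_pipeline(doc, settings = quiet_settings())
  expect_true(rep$success)
  expect_equal(rep$units$state[rep$units$unit_id == "next_task"], "done")
})

test_that("failure aborts dependents but drains independent branches", {
  log <- tempfile()
  doc <- pipeline_doc(
    params = list(param_def("log", "", global = TRUE)),
    tasks = list(
      task_def("a", code = "echo a >> \"$log\"\n"),
      task_def("boom", code = "exit 3", after = "a"),
      task_def("child", code = "echo child >> \"$log\"\n", after = "boom"),
      task_def("indep", code = "sleep 0.05; echo indep >> \"$log\"\n",
               after = "a")
    ))
  rep <- run_pipeline(doc, c(log = log), quiet_settings())
  expect_false(rep$success)
  st <- stats::setNames(rep$units$state, rep$units$unit_id)
  expect_equal(st[["boom"]], "failed")
  expect_equal(st[["child"]], "aborted")
  expect_equal(st[["indep"]], "done")
  expect_equal(rep$units$exit_status[rep$units$unit_id == "boom"], 3L)
  expect_setequal(readLines(log), c("a", "indep"))
})

test_that("statically mismatched binding cardinalities fail before any unit starts", {
  doc <- pipeline_doc(tasks = list(
    foreach_def("p", "list", "a,b,c", "x", code = "true"),
    foreach_def("q", "list", "a,b", "x", code = "true", after = "*p")))
  expect_error(run_pipeline(doc, settings = quiet_settings()),
               class = "dagrun_binding_cardinality")
})

test_that("command-sourced binding mismatch fails the loop, not the run start", {
  doc <- pipeline_doc(tasks = list(
    foreach_def("p", "list", "a,b,c", "x", code = "true"),
    foreach_def("q", "command", "printf 'a\\nb\\n'", "x", code = "true",
                after = "*p")))
  rep <- run_pipeline(doc, settings = quiet_settings())
  expect_false(rep$success)
  st <- stats::setNames(rep$units$state, rep$units$unit_id)
  expect_equal(unname(st[c("p[0]", "p[1]", "p[2]")]), rep("done", 3))
  expect_equal(st[["q"]], "failed")
})

test_that("with one worker the start order is a topological order (oracle-checked)", {
  gp <- random_dag_pipeline(15, 0.3, seed = 99)
  rep1 <- run_generated(gp, max_parallel = 1)
  expect_true(rep1$success)
  ord <- start_order_tasks(rep1)
  expect_length(ord, 15)
  expect_true(oracle_is_topological(ord, gp$expected_graph))
  expect_lte(max_overlap(rep1), 1)
  # documented tie-break makes single-worker runs deterministic
  rep2 <- run_generated(gp, max_parallel = 1)
  expect_identical(start_order_tasks(rep2), ord)
})

test_that("deferred command items are resolved only when the loop is ready", {
  # the upstream task writes the item list that the foreach later reads:
  # resolving early would find no items (or fail)
  wd <- tempfile(); dir.create(wd)
  listfile <- file.path(wd, "items.txt")
  doc <- pipeline_doc(
    params = list(param_def("listfile", "", global = TRUE),
                  param_def("wd", "", global = TRUE)),
    tasks = list(
      task_def("make_items",
               code = "printf 'u\\nv\\nw\\n' > \"$listfile\"\n"),
      foreach_def("consume", "command", "cat \"$listfile\"", "item",
                  code = "touch \"$wd/got_$item\"\n",
                  after = "make_items")))
  rep <- run_pipeline(doc, c(listfile = listfile, wd = wd), quiet_settings())
  expect_true(rep$success)
  expect_setequal(list.files(wd, pattern = "^got_"),
                  c("got_u", "got_v", "got_w"))
})

test_that("run state round-trips and resume executes only the remainder", {
  wd <- tempfile(); dir.create(wd)
  log <- file.path(wd, "log")
  flag <- file.path(wd, "fail_flag"); file.create(flag)
  doc <- chain_pipeline()
  vals <- c(log = log, fail_flag = flag)
  state <- file.path(wd, "state")

  rep1 <- run_pipeline(doc, vals, quiet_settings())
  expect_false(rep1$success)
  save_state(rep1, state)
  expect_equal(load_state(state), "a")

  unlink(flag)
  rep2 <- resume_pipeline(doc, vals, quiet_settings(), state_path = state)
  expect_true(rep2$success)
  # 'a' was not re-executed: its line appears exactly once
  expect_equal(readLines(log), c("a", "b", "c"))
  resumed <- rep2$units$resumed
  expect_true(rep2$units$unit_id[resumed] == "a")
  # cumulative state after resume covers everything
  save_state(rep2, state)
  expect_setequal(load_state(state), c("a", "b", "c"))

  # all done: a second resume runs nothing new
  rep3 <- resume_pipeline(doc, vals, quiet_settings(), state_path = state)
  expect_true(rep3$success)
  expect_true(all(rep3$units$resumed))
  expect_equal(nrow(rep3$events), 0)
})

test_that("corrupt or mismatched state files refuse to resume", {
  p <- tempfile()
  writeLines("not a unit id!", p)
  expect_error(load_state(p), class = "dagrun_state_error")
  writeLines("ghost[2]", p)
  expect_error(
    resume_pipeline(chain_pipeline(), c(log = tempfile(), fail_flag = ""),
                    quiet_settings(), state_path = p),
    class = "dagrun_state_error")
  expect_error(load_state(tempfile()), class = "dagrun_state_error")
})

test_that("abort-if-warnings blocks execution before any unit starts", {
  marker <- tempfile()
  xml <- paste0(
    "<pipeline><params><param name=\"genome\">g</param>",
    "<param name=\"marker\" global=\"true\">m</param></params>",
    "<tasks><task id=\"t\"><![CDATA[echo $genome > \"$marker\"]]></task>",
    "</tasks></pipeline>")
  doc <- parse_pipeline(xml)
  expect_error(
    run_pipeline(doc, c(marker = marker),
                 quiet_settings(abort_if_warnings = TRUE)),
    class = "dagrun_warning_abort")
  expect_false(file.exists(marker))
  # without the flag the run proceeds (warning only)
  rep <- run_pipeline(doc, c(marker = marker), quiet_settings())
  expect_true(rep$success)
  expect_true(file.exists(marker))
})

test_that("missing parameter values are a pre-flight error naming task and param", {
  doc <- pipeline_doc(params = list(param_def("needed", "")),
                      tasks = list(task_def("t", params = "needed")))
  err <- tryCatch(run_pipeline(doc, settings = quiet_settings()),
                  dagrun_error = function(e) conditionMessage(e))
  expect_match(err, "'t'")
  expect_match(err, "'needed'")
  # a default satisfies it
  doc2 <- pipeline_doc(params = list(param_def("needed", "", "fallback")),
                       tasks = list(task_def("t", params = "needed")))
  expect_true(run_pipeline(doc2, settings = quiet_settings())$success)
})
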