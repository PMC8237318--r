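# Task execution: environment materialization, shell / interpreter / runner
# invocation, and per-task log files.
#
# Parameters reach task scripts exclusively as environment variables; the
# engine never rewrites task code. A unit's process is started through a
# generated wrapper script that exports the environment, runs the task code
# through the shell (or interpreter / runner), captures stdout and stderr to
# files, and finally writes the exit status to a status file — the scheduler
# polls that file, which makes bounded asynchronous execution possible
# without any process-management dependency.

#' One schedulable unit of work
#'
#' A plain task is a single unit; a foreach task expands into one unit per
#' item. Unit ids are `task_id` for plain tasks and `task_id[i]` (0-based)
#' for iterations.
#'
#' @param task_id Task identifier.
#' @param item_index 0-based item position, or `NULL` for plain tasks.
#' @param item_value The item text, or `NULL`.
#' @return An `iteration_unit` object.
#' @export
iteration_unit <- function(task_id, item_index = NULL, item_value = NULL) {
  unit_id <- if (is.null(item_index)) task_id
             else sprintf("%s[%d]", task_id, item_index)
  structure(list(task_id = task_id, item_index = item_index,
                 item_value = item_value, unit_id = unit_id),
            class = "iteration_unit")
}

#' Define an execution-time runner
#'
#' A runner is a shell script, supplied outside the pipeline definition, that
#' replaces direct local execution for its assigned tasks — for example to
#' submit the task to a cluster scheduler or run it inside a container. The
#' runner receives the task's code byte-for-byte in the `task_code`
#' environment variable and the task identifier in `task_id`, on top of the
#' task's ordinary parameter environment.
#'
#' @param task_ids Character vector of task ids the runner executes.
#' @param script Raw shell text of the runner.
#' @return A `runner_def` object.
#' @export
runner_def <- function(task_ids, script) {
  if (!length(task_ids))
    dagrun_error("dagrun_runner_error", "runner must name at least one task")
  structure(list(task_ids = task_ids, script = script), class = "runner_def")
}

#' Parse a runners configuration file
#'
#' Dialect: `<runners><runner tasks="a b"><![CDATA[script]]></runner>
#' </runners>`.
#'
#' @param xml_text Runners XML text, or a file path.
#' @return List of [runner_def()] objects.
#' @export
parse_runners <- function(xml_text) {
  if (length(xml_text) == 1L && !grepl("<", xml_text, fixed = TRUE)) {
    if (!file.exists(xml_text))
      dagrun_error("dagrun_runner_error",
                   sprintf("runners file not found: %s", xml_text))
    xml_text <- read_raw_text(xml_text)
  }
  x <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) dagrun_error(
      "dagrun_runner_error",
      paste0("malformed runners XML: ", conditionMessage(e)))
  )
  if (xml2::xml_name(x) != "runners")
    dagrun_error("dagrun_runner_error", "root element must be <runners>")
  lapply(xml2::xml_find_all(x, "./runner"), function(r) {
    runner_def(split_id_list(xml2::xml_attr(r, "tasks")), node_code(r))
  })
}

# Runner assigned to a task id, or NULL. Overlapping assignments are a
# configuration error caught before the run starts.
runner_for_task <- function(runners, task_id) {
  hits <- Filter(function(r) task_id %in% r$task_ids, runners)
  if (length(hits) > 1L)
    dagrun_error("dagrun_runner_error",
                 sprintf("task '%s' is assigned to more than one runner",
                         task_id))
  if (length(hits)) hits[[1]] else NULL
}

check_runners <- function(runners, doc) {
  ids <- task_ids(doc)
  for (r in runners) {
    unknown <- setdiff(r$task_ids, ids)
    if (length(unknown))
      dagrun_error("dagrun_runner_error",
                   sprintf("runner assigned to unknown task(s): %s",
                           paste(unknown, collapse = ", ")))
  }
  for (id in ids) runner_for_task(runners, id)  # overlap check
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Environment

#' Build the environment a unit's script sees
#'
#' The environment contains exactly: the task's declared parameters (value
#' precedence: supplied values, then the parameter's default), every global
#' parameter, the foreach item variable for iteration units, and the
#' engine-provided variables `task_id` and `working_dir`. Parameters the task
#' did not declare (and that are not global) are deliberately absent — their
#' use inside task code is what the `param-not-accessible` validation warning
#' flags.
#'
#' @param unit An [iteration_unit()].
#' @param doc The `pipeline_doc`.
#' @param param_values Named character vector of externally supplied values
#'   (command line merged over params file).
#' @param working_dir Working directory exported to the task.
#' @return Named character vector of class `task_environment`.
#' @export
build_environment <- function(unit, doc, param_values = character(),
                              working_dir = getwd()) {
  task <- get_task(doc, unit$task_id)
  globals <- param_names(doc)[vapply(doc$params, `[[`, TRUE, "global")]
  wanted <- unique(c(task$params, globals))
  env <- character()
  for (name in wanted) {
    val <- if (name %in% names(param_values)) param_values[[name]]
           else get_param(doc, name)$default_value
    if (is.null(val))
      dagrun_error("dagrun_missing_param",
                   sprintf("task '%s' requires parameter '%s' but no value was supplied and it has no default",
                           task$id, name))
    env[[name]] <- val
  }
  if (!is.null(unit$item_index)) {
    env[[task$foreach$item_var]] <- unit$item_value
  }
  env[["task_id"]] <- task$id
  env[["working_dir"]] <- working_dir
  structure(env, class = "task_environment")
}

resolve_param_value <- function(doc, name, param_values) {
  if (name %in% names(param_values)) return(param_values[[name]])
  p <- get_param(doc, name)
  if (!is.null(p)) p$default_value else NULL
}

# ---------------------------------------------------------------------------
# Wrapper scripts and process spawning

#' The result of executing one unit
#'
#' @param unit_id Unit identifier.
#' @param exit_status Integer exit status; 0 iff the unit counts as done.
#' @param stdout_text,stderr_text Captured output.
#' @param duration Wall-clock seconds.
#' @param env The `task_environment` the unit saw (used for `.params` logs).
#' @return A `task_result` object.
#' @export
task_result <- function(unit_id, exit_status, stdout_text = "",
                        stderr_text = "", duration = NA_real_, env = NULL) {
  structure(list(unit_id = unit_id, exit_status = as.integer(exit_status),
                 stdout_text = stdout_text, stderr_text = stderr_text,
                 duration = duration, env = env),
            class = "task_result")
}

# Prepare a unit's scratch directory with wrapper/code/out/err/status files.
# mode: "shell" (code run directly), "interpreter", or "runner".
prepare_unit_process <- function(dir, code, env, mode = "shell",
                                 interpreter = NULL, runner_script = NULL,
                                 shell = NULL, working_dir = getwd()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shell <- find_shell(shell)
  paths <- list(
    wrapper = file.path(dir, "wrapper.sh"),
    payload = file.path(dir, "payload.sh"),
    out = file.path(dir, "stdout"),
    err = file.path(dir, "stderr"),
    status = file.path(dir, "status")
  )
  lines <- c("#!/bin/sh",
             paste0("cd ", sh_squote(working_dir), " || exit 127"))
  env_to_export <- env
  payload <- code
  if (mode == "interpreter") {
    env_to_export[["task_code"]] <- code
    payload <- interpreter
  } else if (mode == "runner") {
    env_to_export[["task_code"]] <- code
    payload <- runner_script
  }
  for (name in names(env_to_export)) {
    lines <- c(lines, paste0("export ", name, "=",
                             sh_squote(env_to_export[[name]])))
  }
  write_raw_text(payload, paths$payload)
  lines <- c(lines,
             paste0(sh_squote(shell), " ", sh_squote(paths$payload),
                    " > ", sh_squote(paths$out),
                    " 2> ", sh_squote(paths$err)),
             "rc=$?",
             paste0("printf '%s' \"$rc\" > ", sh_squote(paths$status), ".tmp"),
             paste0("mv ", sh_squote(paths$status), ".tmp ",
                    sh_squote(paths$status)))
  writeLines(lines, paths$wrapper)
  paths$shell <- shell
  paths
}

spawn_prepared <- function(paths) {
  system2(paths$shell, shQuote(paths$wrapper), wait = FALSE,
          stdout = FALSE, stderr = FALSE)
  invisible(paths)
}

unit_finished <- function(paths) {
  file.exists(paths$status) && isTRUE(file.info(paths$status)$size > 0)
}

collect_result <- function(paths, unit_id, env, duration = NA_real_) {
  status <- suppressWarnings(as.integer(read_raw_text(paths$status)))
  if (is.na(status)) status <- 127L
  task_result(unit_id, status,
              stdout_text = read_raw_text(paths$out),
              stderr_text = read_raw_text(paths$err),
              duration = duration, env = env)
}

run_prepared_sync <- function(paths, unit_id, env, poll = 0.005) {
  t0 <- Sys.time()
  spawn_prepared(paths)
  while (!unit_finished(paths)) Sys.sleep(poll)
  collect_result(paths, unit_id, env,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Execute one unit's script synchronously
#'
#' The default path runs the task code with the system shell under the unit's
#' environment. When `interpreter` is given, the interpreter text is executed
#' instead, with the task code available byte-for-byte in the `task_code`
#' environment variable — the contract that lets pipelines embed languages
#' other than shell.
#'
#' @param unit An [iteration_unit()].
#' @param code The task's code.
#' @param env A `task_environment` (see [build_environment()]).
#' @param interpreter Optional interpreter shell fragment.
#' @param settings A [run_settings()] (shell override and working dir).
#' @return A [task_result()]; a nonzero exit yields a failed result, not an
#'   error.
#' @export
run_script <- function(unit, code, env, interpreter = NULL,
                       settings = run_settings()) {
  dir <- tempfile("dagrun-unit-")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  mode <- if (is.null(interpreter)) "shell" else "interpreter"
  paths <- prepare_unit_process(dir, code, env, mode = mode,
                                interpreter = interpreter,
                                shell = settings$shell,
                                working_dir = settings$working_dir)
  run_prepared_sync(paths, unit$unit_id, env)
}

#' Execute one unit through a runner
#'
#' The runner script runs under the unit's environment plus `task_code` (the
#' task's code, byte-identical) and `task_id`; the unit's outcome is the
#' runner's exit status. For iteration units the runner is invoked once per
#' unit with the item variable bound.
#'
#' @param runner A [runner_def()] whose `task_ids` include the unit's task.
#' @param unit An [iteration_unit()].
#' @param code The task's code.
#' @param env A `task_environment`.
#' @param settings A [run_settings()].
#' @return A [task_result()].
#' @export
run_with_runner <- function(runner, unit, code, env,
                            settings = run_settings()) {
  if (!unit$task_id %in% runner$task_ids)
    dagrun_error("dagrun_runner_error",
                 sprintf("unit '%s' is not assigned to this runner",
                         unit$unit_id))
  if (!"task_id" %in% names(env)) env[["task_id"]] <- unit$task_id
  dir <- tempfile("dagrun-unit-")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- prepare_unit_process(dir, code, env, mode = "runner",
                                runner_script = runner$script,
                                shell = settings$shell,
                                working_dir = settings$working_dir)
  run_prepared_sync(paths, unit$unit_id, env)
}

# ---------------------------------------------------------------------------
# Logging

log_admitted <- function(task_id, settings) {
  if (is.null(settings$log_dir)) return(FALSE)
  if (length(settings$log_only)) return(task_id %in% settings$log_only)
  !(task_id %in% settings$log_exclude)
}

#' Write per-task log files for a completed unit
#'
#' With a log directory configured and the task admitted by the
#' log-only/log-exclude filters, exactly three files per task are maintained:
#' `<task>.out.log`, `<task>.err.log`, and `<task>.params` (parameter
#' `name=value` lines, sorted by name). Iteration units append to their
#' task's files in unit order. Without a log directory no files are written.
#'
#' @param result A [task_result()] carrying the unit's environment.
#' @param unit The [iteration_unit()] the result belongs to.
#' @param settings A [run_settings()].
#' @return Character vector of file paths written (possibly empty),
#'   invisibly.
#' @export
write_logs <- function(result, unit, settings) {
  if (!log_admitted(unit$task_id, settings)) return(invisible(character()))
  dir <- settings$log_dir
  out <- file.path(dir, paste0(unit$task_id, ".out.log"))
  err <- file.path(dir, paste0(unit$task_id, ".err.log"))
  par <- file.path(dir, paste0(unit$task_id, ".params"))
  cat(result$stdout_text, file = out, append = TRUE)
  cat(result$stderr_text, file = err, append = TRUE)
  env <- result$env
  if (!is.null(env)) {
    nm <- sort(names(env))
    cat(paste0(nm, "=", unlist(env[nm]), "\n", collapse = ""),
        file = par, append = TRUE)
  } else {
    cat("", file = par, append = TRUE)
  }
  invisible(c(out, err, par))
}
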