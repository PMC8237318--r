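# Reactive DAG scheduler: expands foreach tasks into iteration units,
# evaluates guards, and drives execution under a concurrency bound.
#
# Execution is event-driven: whenever a unit finishes, every unit whose
# dependency obligations are now met becomes eligible, and eligible units
# are dispatched while fewer than max_parallel units are in flight.
# Simultaneously eligible units are dispatched in document order of their
# tasks, then by item index — a documented tie-break that makes
# single-worker runs reproducible.

#' Execution settings for a pipeline run
#'
#' @param max_parallel Maximum number of units in flight at any instant
#'   (the `--num-tasks` CLI flag); default 6.
#' @param log_dir Directory for per-task log files; `NULL` (default) disables
#'   task logging entirely.
#' @param log_only,log_exclude Task-id filters for logging; mutually
#'   exclusive.
#' @param quiet Suppress the engine's own progress messages (never affects
#'   task log files).
#' @param show_std_outs Mirror each task's stdout/stderr to the engine's own
#'   streams as units finish.
#' @param abort_if_warnings Refuse to start if validation reports warnings.
#' @param selection A [subgraph_query()] choosing a sub-pipeline.
#' @param runners List of [runner_def()] objects.
#' @param working_dir Directory tasks run in (exported as `working_dir`).
#' @param shell Path to the shell used for all script execution; by default
#'   `bash` located on the search path.
#' @param state_file Path for the resume state file; defaults to
#'   `.dagrun-state` inside the log directory, or in `working_dir` when no
#'   log directory is set.
#' @param poll_interval Seconds between scheduler polls of running units.
#' @return A `run_settings` object.
#' @export
run_settings <- function(max_parallel = 6L, log_dir = NULL,
                         log_only = character(), log_exclude = character(),
                         quiet = FALSE, show_std_outs = FALSE,
                         abort_if_warnings = FALSE,
                         selection = subgraph_query(), runners = list(),
                         working_dir = getwd(), shell = NULL,
                         state_file = NULL, poll_interval = 0.004) {
  if (length(log_only) && length(log_exclude))
    dagrun_error("dagrun_settings_error",
                 "log_only and log_exclude are mutually exclusive")
  max_parallel <- as.integer(max_parallel)
  if (is.na(max_parallel) || max_parallel < 1L)
    dagrun_error("dagrun_settings_error", "max_parallel must be >= 1")
  structure(
    list(max_parallel = max_parallel, log_dir = log_dir,
         log_only = log_only, log_exclude = log_exclude, quiet = quiet,
         show_std_outs = show_std_outs,
         abort_if_warnings = abort_if_warnings, selection = selection,
         runners = runners, working_dir = working_dir, shell = shell,
         state_file = state_file, poll_interval = poll_interval),
    class = "run_settings"
  )
}

state_path_for <- function(settings) {
  settings$state_file %||%
    file.path(settings$log_dir %||% settings$working_dir, ".dagrun-state")
}

engine_msg <- function(settings, ...) {
  if (!isTRUE(settings$quiet)) cat(..., "\n", sep = "", file = stderr())
}

# ---------------------------------------------------------------------------
# Item resolution and expansion

STATIC_KINDS <- c("list", "range", "param_values")

split_trim <- function(x) {
  items <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  items[nzchar(items)]
}

#' Resolve a foreach task's item collection
#'
#' Item sources: `list` — comma-separated values, whitespace-trimmed;
#' `range` — inclusive integer range `a..b` (or `a:b`) rendered as decimal
#' strings; `files_in_dir` — lexicographically sorted files directly in a
#' directory; `param_values` — comma-split value of a named parameter;
#' `command` — stdout lines of a shell command run in the working directory.
#' Deferred sources (`command`, `files_in_dir`) are only evaluated when the
#' loop is about to run, which is what allows the number of parallel
#' iterations to depend on the output of earlier tasks.
#'
#' @param spec A foreach `task_def`.
#' @param param_values Named character vector of resolved parameter values.
#' @param working_dir Directory `command`/`files_in_dir` sources are resolved
#'   relative to.
#' @param env Optional `task_environment` exported to `command` sources.
#' @param shell Shell for `command` sources.
#' @return Ordered character vector of items.
#' @export
resolve_items <- function(spec, param_values = character(),
                          working_dir = getwd(), env = NULL, shell = NULL) {
  if (!is_foreach(spec))
    dagrun_error("dagrun_foreach_error",
                 sprintf("task '%s' is not a foreach task", spec$id))
  fe <- spec$foreach
  switch(fe$source_kind,
    list = split_trim(fe$source_arg),
    range = {
      m <- regmatches(fe$source_arg,
                      regexec("^\\s*(-?[0-9]+)\\s*(\\.\\.|:)\\s*(-?[0-9]+)\\s*$",
                              fe$source_arg))[[1]]
      if (length(m) == 0L)
        dagrun_error("dagrun_foreach_error",
                     sprintf("foreach '%s': cannot parse range '%s' (expected 'a..b')",
                             spec$id, fe$source_arg))
      as.character(seq(as.integer(m[2]), as.integer(m[4])))
    },
    files_in_dir = {
      dir <- fe$source_arg
      if (!dir.exists(dir) && !dir.exists(file.path(working_dir, dir)))
        dagrun_error("dagrun_foreach_error",
                     sprintf("foreach '%s': directory '%s' does not exist",
                             spec$id, dir))
      if (!dir.exists(dir)) dir <- file.path(working_dir, dir)
      entries <- list.files(dir, full.names = TRUE)
      sort(entries[!dir.exists(entries)], method = "radix")
    },
    param_values = {
      val <- if (fe$source_arg %in% names(param_values))
        param_values[[fe$source_arg]] else NULL
      if (is.null(val) || is.na(val))
        dagrun_error("dagrun_foreach_error",
                     sprintf("foreach '%s': parameter '%s' has no value",
                             spec$id, fe$source_arg))
      split_trim(val)
    },
    command = {
      dir <- tempfile("dagrun-items-")
      on.exit(unlink(dir, recursive = TRUE), add = TRUE)
      paths <- prepare_unit_process(dir, fe$source_arg,
                                    env %||% character(), shell = shell,
                                    working_dir = working_dir)
      res <- run_prepared_sync(paths, spec$id, env)
      if (res$exit_status != 0L)
        dagrun_error("dagrun_foreach_error",
                     sprintf("foreach '%s': item source command failed with status %d: %s",
                             spec$id, res$exit_status,
                             trimws(res$stderr_text)))
      lines <- strsplit(res$stdout_text, "\n", fixed = TRUE)[[1]]
      lines
    },
    dagrun_error("dagrun_foreach_error",
                 sprintf("unknown item source kind '%s'", fe$source_kind))
  )
}

#' Expand a foreach task into iteration units
#'
#' @param spec A foreach `task_def`.
#' @param items Resolved items (see [resolve_items()]).
#' @return List of [iteration_unit()]s, one per item in order; empty for an
#'   empty collection (the foreach then completes immediately).
#' @export
expand_foreach <- function(spec, items) {
  lapply(seq_along(items), function(i)
    iteration_unit(spec$id, item_index = i - 1L, item_value = items[[i]]))
}

#' Evaluate a task's `if` guard
#'
#' The guard command runs under the same environment contract as the task
#' itself, just before the task would start. Exit status 0 means run; any
#' other ordinary nonzero status means skip (the task is marked
#' skipped-by-guard and its dependents treat it as satisfied). Statuses 126
#' and 127 — the shell's "not executable" / "not found" — are an execution
#' error that fails the task rather than skipping it.
#'
#' @param task A `task_def` with a non-`NULL` `if_guard`.
#' @param env The task's `task_environment`.
#' @param settings A [run_settings()].
#' @return `TRUE` to run, `FALSE` to skip.
#' @export
evaluate_guard <- function(task, env, settings = run_settings()) {
  if (is.null(task$if_guard))
    dagrun_error("dagrun_guard_error",
                 sprintf("task '%s' has no guard", task$id))
  dir <- tempfile("dagrun-guard-")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- prepare_unit_process(dir, task$if_guard, env,
                                shell = settings$shell,
                                working_dir = settings$working_dir)
  res <- run_prepared_sync(paths, task$id, env)
  if (res$exit_status %in% c(126L, 127L))
    dagrun_error("dagrun_guard_error",
                 sprintf("guard of task '%s' is not executable (status %d): %s",
                         task$id, res$exit_status, trimws(res$stderr_text)))
  res$exit_status == 0L
}

# ---------------------------------------------------------------------------
# The run loop

#' Run a pipeline
#'
#' Validates, builds the dependency graph, selects the requested
#' sub-pipeline, expands foreach tasks, and executes all units reactively:
#' a unit starts only once its dependency obligations are met, and at most
#' `max_parallel` units are in flight at any instant. For an
#' iteration-binding dependency `A -> *B` over collections of equal size,
#' unit `B[i]` becomes eligible as soon as `A[i]` is done, without waiting
#' for the rest of `A`; for an ordinary dependency every unit of `B` waits
#' for all of `A`. On a unit failure no new dependent units start (they are
#' aborted) while independent eligible units run to completion, maximizing
#' the work a later [resume_pipeline()] can reuse.
#'
#' @param doc A `pipeline_doc`.
#' @param param_values Named character vector of parameter values
#'   (command-line values merged over params-file values; defaults apply
#'   last).
#' @param settings A [run_settings()].
#' @param completed Character vector of unit ids already completed in a
#'   previous run (see [load_state()]); they are treated as done and not
#'   re-executed.
#' @return An `execution_report`: unit states, timestamps, exit statuses,
#'   a totally ordered event log, and an overall `success` flag.
#' @export
run_pipeline <- function(doc, param_values = character(),
                         settings = run_settings(),
                         completed = character()) {
  issues <- validate_pipeline(doc)
  if (has_validation_errors(issues))
    dagrun_error("dagrun_validation_error",
                 paste0("pipeline has validation errors:\n",
                        paste(issues$message[issues$severity == "error"],
                              collapse = "\n")))
  warn <- issues[issues$severity == "warning", , drop = FALSE]
  if (nrow(warn)) {
    for (m in warn$message) engine_msg(settings, "WARNING: ", m)
    if (isTRUE(settings$abort_if_warnings))
      dagrun_error("dagrun_warning_abort",
                   paste0("aborted: pipeline validation produced warnings:\n",
                          paste(warn$message, collapse = "\n")))
  }

  graph <- build_graph(doc)
  sel <- select_subgraph(graph, settings$selection)
  check_runners(settings$runners, doc)

  # apply parameter defaults once: externally supplied values win
  for (p in doc$params) {
    if (!p$name %in% names(param_values) && !is.null(p$default_value))
      param_values[[p$name]] <- p$default_value
  }

  if (!is.null(settings$log_dir)) {
    dir.create(settings$log_dir, recursive = TRUE, showWarnings = FALSE)
    probe <- file.path(settings$log_dir,
                       paste0(".dagrun-probe-", Sys.getpid()))
    ok <- tryCatch({ cat("", file = probe); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok)
      dagrun_error("dagrun_log_error",
                   sprintf("log directory '%s' is not writable",
                           settings$log_dir))
    unlink(probe)
  }

  # state-file consistency: every completed unit must map to a current task
  if (length(completed)) {
    ctasks <- sub("\\[[0-9]+\\]$", "", completed)
    unknown <- setdiff(ctasks, task_ids(doc))
    if (length(unknown))
      dagrun_error("dagrun_state_error",
                   sprintf("state file names units of unknown task(s): %s",
                           paste(unique(unknown), collapse = ", ")))
  }

  # pre-flight: every selected task's parameters must be resolvable
  globals <- param_names(doc)[vapply(doc$params, `[[`, TRUE, "global")]
  for (id in sel) {
    t <- get_task(doc, id)
    for (p in unique(c(t$params, globals))) {
      if (is.null(resolve_param_value(doc, p, param_values)))
        dagrun_error("dagrun_missing_param",
                     sprintf("task '%s' requires parameter '%s' but no value was supplied and it has no default",
                             t$id, p))
    }
  }

  # pre-flight: statically resolvable binding edges must agree in cardinality
  for (k in seq_len(nrow(graph$edges))) {
    e <- graph$edges[k, ]
    if (!e$binding || !(e$from %in% sel) || !(e$to %in% sel)) next
    a <- get_task(doc, e$from); b <- get_task(doc, e$to)
    if (a$foreach$source_kind %in% STATIC_KINDS &&
        b$foreach$source_kind %in% STATIC_KINDS) {
      na <- length(resolve_items(a, param_values, settings$working_dir))
      nb <- length(resolve_items(b, param_values, settings$working_dir))
      if (na != nb)
        dagrun_error("dagrun_binding_cardinality",
                     sprintf("iteration-binding '%s' -> '%s': item collections differ in length (%d vs %d)",
                             e$from, e$to, na, nb))
    }
  }

  run_dir <- tempfile("dagrun-run-")
  dir.create(run_dir, recursive = TRUE)
  on.exit(unlink(run_dir, recursive = TRUE), add = TRUE)

  doc_pos <- stats::setNames(seq_along(task_ids(doc)), task_ids(doc))

  # excluded dependencies of selected tasks: assumed satisfied, noticed once
  for (id in sel) {
    t <- get_task(doc, id)
    missing_deps <- setdiff(vapply(t$after, dep_target, ""), sel)
    for (d in missing_deps)
      engine_msg(settings, "NOTICE: dependency '", d, "' of task '", id,
                 "' is outside the selection; assuming its outputs are present")
  }

  # task bookkeeping --------------------------------------------------------
  tasks <- new.env(parent = emptyenv())
  for (id in sel) {
    t <- get_task(doc, id)
    deps <- t$after[vapply(t$after, dep_target, "") %in% sel]
    assign(id, list(
      def = t,
      dep_targets = vapply(deps, dep_target, "", USE.NAMES = FALSE),
      dep_binding = vapply(deps, dep_is_binding, TRUE, USE.NAMES = FALSE),
      status = "waiting",      # waiting/active/done/skipped/failed/aborted
      expanded = FALSE,
      items = NULL
    ), envir = tasks)
  }

  units <- new.env(parent = emptyenv())   # keyed by unit_id
  unit_order <- character()               # creation order for stable output
  events <- list()
  record_event <- function(unit_id, event) {
    events[[length(events) + 1L]] <<- list(time = as.numeric(Sys.time()),
                                           unit_id = unit_id, event = event)
  }
  add_unit <- function(u, status) {
    assign(u$unit_id, list(unit = u, status = status, paths = NULL,
                           t0 = NA_real_, t1 = NA_real_,
                           exit = NA_integer_, result = NULL,
                           resumed = identical(status, "resumed")),
           envir = units)
    unit_order <<- c(unit_order, u$unit_id)
  }
  set_unit <- function(id, ...) {
    rec <- get(id, envir = units)
    mods <- list(...)
    rec[names(mods)] <- mods
    assign(id, rec, envir = units)
    rec
  }

  task_satisfied <- function(id) {
    get(id, envir = tasks)$status %in% c("done", "skipped")
  }
  task_bad <- function(id) {
    get(id, envir = tasks)$status %in% c("failed", "aborted")
  }

  log_buffer <- new.env(parent = emptyenv())  # task_id -> list of results
  flush_task_logs <- function(task_id) {
    buf <- mget(task_id, envir = log_buffer, ifnotfound = list(NULL))[[1]]
    if (is.null(buf)) return()
    # unit order = item index order
    ord <- order(vapply(buf, function(b) b$idx %||% -1L, 0L))
    for (b in buf[ord]) write_logs(b$result, b$unit, settings)
    rm(list = task_id, envir = log_buffer)
  }

  # mark a task terminal once all its units are terminal
  refresh_task_status <- function(task_id) {
    st <- get(task_id, envir = tasks)
    if (st$status != "active") return()
    ids <- unit_order[vapply(unit_order, function(u)
      get(u, envir = units)$unit$task_id == task_id, TRUE)]
    stat <- vapply(ids, function(u) get(u, envir = units)$status, "")
    if (any(stat %in% c("pending", "running"))) return()
    st$status <- if (any(stat == "failed")) "failed"
                 else if (any(stat == "aborted")) "aborted"
                 else "done"
    assign(task_id, st, envir = tasks)
    flush_task_logs(task_id)
    engine_msg(settings, "task '", task_id, "' ", st$status)
  }

  abort_task <- function(id) {
    st <- get(id, envir = tasks)
    st$status <- "aborted"
    assign(id, st, envir = tasks)
    if (!st$expanded) {
      add_unit(iteration_unit(id), "aborted")
      record_event(id, "abort")
    }
  }

  fail_task_prestart <- function(id, msg) {
    st <- get(id, envir = tasks)
    st$status <- "failed"
    assign(id, st, envir = tasks)
    add_unit(iteration_unit(id), "failed")
    record_event(id, "fail")
    engine_msg(settings, "ERROR: ", msg)
  }

  guard_env <- function(t) {
    build_environment(iteration_unit(t$id), doc, param_values,
                      settings$working_dir)
  }

  activate_task <- function(id) {
    st <- get(id, envir = tasks)
    t <- st$def
    prior_units <- completed[startsWith(completed, paste0(id, "[")) |
                               completed == id]

    # whole task already completed in a previous run
    if (!is_foreach(t) && id %in% completed) {
      st$status <- "done"; assign(id, st, envir = tasks)
      add_unit(iteration_unit(id), "resumed")
      return()
    }
    if (is_foreach(t) && id %in% completed) {
      # recorded as a whole (guard-skip or empty collection)
      st$status <- "done"; st$expanded <- TRUE
      assign(id, st, envir = tasks)
      add_unit(iteration_unit(id), "resumed")
      return()
    }

    if (!is.null(t$if_guard) && length(prior_units) == 0L) {
      run_it <- tryCatch(evaluate_guard(t, guard_env(t), settings),
                         dagrun_error = function(e) e)
      if (inherits(run_it, "dagrun_error")) {
        fail_task_prestart(id, conditionMessage(run_it))
        return()
      }
      if (!run_it) {
        st$status <- "skipped"; assign(id, st, envir = tasks)
        add_unit(iteration_unit(id), "skipped")
        record_event(id, "skip")
        engine_msg(settings, "task '", id, "' skipped by its guard")
        return()
      }
    }

    if (!is_foreach(t)) {
      st$status <- "active"; st$expanded <- TRUE
      assign(id, st, envir = tasks)
      add_unit(iteration_unit(id), "pending")
      return()
    }

    # foreach: resolve items now (deferred sources run here, not earlier)
    env <- tryCatch(guard_env(t), dagrun_error = function(e) e)
    items <- if (inherits(env, "dagrun_error")) env else
      tryCatch(resolve_items(t, param_values, settings$working_dir,
                             env = env, shell = settings$shell),
               dagrun_error = function(e) e)
    if (inherits(items, "dagrun_error")) {
      fail_task_prestart(id, conditionMessage(items))
      return()
    }
    # binding cardinality against every expanded binding predecessor
    for (k in which(st$dep_binding)) {
      dep <- get(st$dep_targets[[k]], envir = tasks)
      if (dep$status == "skipped" || !dep$expanded) next
      if (length(dep$items) != length(items)) {
        fail_task_prestart(id, sprintf(
          "iteration-binding '%s' -> '%s': item collections differ in length (%d vs %d)",
          st$dep_targets[[k]], id, length(dep$items), length(items)))
        return()
      }
    }
    st$items <- items
    st$expanded <- TRUE
    if (length(items) == 0L) {
      st$status <- "done"
      assign(id, st, envir = tasks)
      add_unit(iteration_unit(id), "done")  # recorded so resume can skip it
      return()
    }
    st$status <- "active"
    assign(id, st, envir = tasks)
    for (u in expand_foreach(t, items)) {
      add_unit(u, if (u$unit_id %in% completed) "resumed" else "pending")
    }
    refresh_task_status(id)  # all units may be resumed
  }

  # one cascade pass: activations, task-level aborts, unit-level aborts
  cascade <- function() {
    progressed <- FALSE
    for (id in sel) {
      st <- get(id, envir = tasks)
      if (st$status != "waiting") next
      nb <- st$dep_targets[!st$dep_binding]
      bd <- st$dep_targets[st$dep_binding]
      dead <- any(vapply(nb, task_bad, TRUE)) ||
        any(vapply(bd, function(d) {
          ds <- get(d, envir = tasks)
          (ds$status %in% c("failed", "aborted")) && !ds$expanded
        }, TRUE))
      if (dead) {
        abort_task(id); progressed <- TRUE; next
      }
      ready <- all(vapply(nb, task_satisfied, TRUE)) &&
        all(vapply(bd, function(d) {
          ds <- get(d, envir = tasks)
          ds$status == "skipped" || ds$expanded
        }, TRUE))
      if (ready) {
        activate_task(id); progressed <- TRUE
      }
    }
    # unit-level aborts: pending iteration units whose bound predecessor
    # iteration failed or was aborted
    for (uid in unit_order) {
      rec <- get(uid, envir = units)
      if (rec$status != "pending") next
      st <- get(rec$unit$task_id, envir = tasks)
      idx <- rec$unit$item_index
      if (is.null(idx) || !any(st$dep_binding)) next
      for (d in st$dep_targets[st$dep_binding]) {
        ds <- get(d, envir = tasks)
        if (ds$status == "skipped" || !ds$expanded) next
        dep_uid <- sprintf("%s[%d]", d, idx)
        drec <- tryCatch(get(dep_uid, envir = units), error = function(e) NULL)
        if (!is.null(drec) && drec$status %in% c("failed", "aborted")) {
          set_unit(uid, status = "aborted")
          record_event(uid, "abort")
          refresh_task_status(rec$unit$task_id)
          progressed <- TRUE
          break
        }
      }
    }
    progressed
  }

  unit_eligible <- function(rec) {
    st <- get(rec$unit$task_id, envir = tasks)
    if (st$status != "active") return(FALSE)
    idx <- rec$unit$item_index
    if (is.null(idx) || !any(st$dep_binding)) return(TRUE)
    for (d in st$dep_targets[st$dep_binding]) {
      ds <- get(d, envir = tasks)
      if (ds$status == "skipped") next
      dep_uid <- sprintf("%s[%d]", d, idx)
      drec <- tryCatch(get(dep_uid, envir = units), error = function(e) NULL)
      if (is.null(drec) || !drec$status %in% c("done", "resumed"))
        return(FALSE)
    }
    TRUE
  }

  inflight <- function() {
    sum(vapply(unit_order, function(u)
      get(u, envir = units)$status == "running", TRUE))
  }

  spawn_unit <- function(uid) {
    rec <- get(uid, envir = units)
    t <- get(rec$unit$task_id, envir = tasks)$def
    env <- build_environment(rec$unit, doc, param_values,
                             settings$working_dir)
    runner <- runner_for_task(settings$runners, t$id)
    mode <- if (!is.null(runner)) "runner"
            else if (!is.null(t$interpreter)) "interpreter" else "shell"
    dir <- file.path(run_dir, gsub("[^A-Za-z0-9_]", "_", uid))
    paths <- prepare_unit_process(dir, t$code, env, mode = mode,
                                  interpreter = t$interpreter,
                                  runner_script = runner$script,
                                  shell = settings$shell,
                                  working_dir = settings$working_dir)
    set_unit(uid, status = "running", paths = paths,
             t0 = as.numeric(Sys.time()), env = env)
    record_event(uid, "start")
    engine_msg(settings, "running '", uid, "'",
               if (mode != "shell") paste0(" via ", mode))
    spawn_prepared(paths)
  }

  reap_unit <- function(uid) {
    rec <- get(uid, envir = units)
    t1 <- as.numeric(Sys.time())
    res <- collect_result(rec$paths, uid, rec$env, t1 - rec$t0)
    ok <- res$exit_status == 0L
    set_unit(uid, status = if (ok) "done" else "failed",
             t1 = t1, exit = res$exit_status, result = res)
    record_event(uid, if (ok) "end" else "fail")
    if (isTRUE(settings$show_std_outs)) {
      if (nzchar(res$stdout_text)) cat(res$stdout_text)
      if (nzchar(res$stderr_text)) cat(res$stderr_text, file = stderr())
    }
    if (!ok)
      engine_msg(settings, "ERROR: unit '", uid, "' failed with exit status ",
                 res$exit_status)
    if (log_admitted(rec$unit$task_id, settings)) {
      buf <- mget(rec$unit$task_id, envir = log_buffer,
                  ifnotfound = list(list()))[[1]]
      buf[[length(buf) + 1L]] <- list(unit = rec$unit, result = res,
                                      idx = rec$unit$item_index)
      assign(rec$unit$task_id, buf, envir = log_buffer)
    }
    refresh_task_status(rec$unit$task_id)
  }

  # main loop ---------------------------------------------------------------
  repeat {
    while (cascade()) {}

    did <- FALSE
    if (inflight() < settings$max_parallel) {
      pend <- Filter(function(u) get(u, envir = units)$status == "pending",
                     unit_order)
      if (length(pend)) {
        key <- vapply(pend, function(u) {
          rec <- get(u, envir = units)
          doc_pos[[rec$unit$task_id]] * 1e6 + (rec$unit$item_index %||% 0L)
        }, 0)
        for (u in pend[order(key)]) {
          if (inflight() >= settings$max_parallel) break
          if (unit_eligible(get(u, envir = units))) {
            spawn_unit(u); did <- TRUE
          }
        }
      }
    }

    running <- Filter(function(u) get(u, envir = units)$status == "running",
                      unit_order)
    for (u in running) {
      if (unit_finished(get(u, envir = units)$paths)) {
        reap_unit(u); did <- TRUE
      }
    }

    statuses <- vapply(unit_order, function(u) get(u, envir = units)$status,
                       "")
    n_open <- sum(statuses %in% c("pending", "running"))
    all_tasks_settled <- length(sel) == 0L ||
      all(vapply(sel, function(id)
        get(id, envir = tasks)$status != "waiting", TRUE))
    if (n_open == 0L && !did) {
      if (cascade()) next
      if (all_tasks_settled) break
      # defensive: waiting tasks that can never activate are aborted
      for (id in sel) {
        if (get(id, envir = tasks)$status == "waiting") abort_task(id)
      }
      next
    }
    if (!did && !any(statuses == "running")) {
      # pending units that can never become eligible (their bound
      # predecessor iteration failed): the cascade handles these, so just
      # give it another chance before sleeping
      if (cascade()) next
      stuck <- unit_order[statuses == "pending"]
      can_run <- vapply(stuck, function(u)
        unit_eligible(get(u, envir = units)), TRUE)
      if (length(stuck) && !any(can_run)) {
        for (u in stuck) {
          set_unit(u, status = "aborted"); record_event(u, "abort")
          refresh_task_status(get(u, envir = units)$unit$task_id)
        }
        next
      }
    }
    if (!did) Sys.sleep(settings$poll_interval)
  }

  for (id in sel) flush_task_logs(id)

  # assemble the report -----------------------------------------------------
  state_name <- c(pending = "pending", running = "running", done = "done",
                  failed = "failed", aborted = "aborted",
                  skipped = "skipped-by-guard", resumed = "done")
  rows <- lapply(unit_order, function(uid) {
    rec <- get(uid, envir = units)
    data.frame(unit_id = uid, task_id = rec$unit$task_id,
               item_index = rec$unit$item_index %||% NA_integer_,
               item_value = rec$unit$item_value %||% NA_character_,
               state = state_name[[rec$status]],
               resumed = isTRUE(rec$resumed),
               start = rec$t0, end = rec$t1, exit_status = rec$exit,
               stringsAsFactors = FALSE)
  })
  units_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(), task_id = character(),
               item_index = integer(), item_value = character(),
               state = character(), resumed = logical(), start = numeric(),
               end = numeric(), exit_status = integer(),
               stringsAsFactors = FALSE)
  events_df <- if (length(events)) {
    data.frame(time = vapply(events, `[[`, 0, "time"),
               unit_id = vapply(events, `[[`, "", "unit_id"),
               event = vapply(events, `[[`, "", "event"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(time = numeric(), unit_id = character(), event = character(),
               stringsAsFactors = FALSE)
  }
  success <- !any(units_df$state %in% c("failed", "aborted"))
  structure(list(units = units_df, events = events_df, success = success,
                 selected = sel, warnings = warn$message),
            class = "execution_report")
}

#' @export
print.execution_report <- function(x, ...) {
  tab <- table(factor(x$units$state,
                      levels = c("done", "skipped-by-guard", "failed",
                                 "aborted", "pending", "running")))
  cat(sprintf("<execution_report> success=%s\n", x$success))
  for (s in names(tab)) if (tab[[s]] > 0) cat(sprintf("  %s: %d\n", s,
                                                      tab[[s]]))
  invisible(x)
}

#' @export
summary.execution_report <- function(object, ...) {
  print(object)
  invisible(object$units)
}

# ---------------------------------------------------------------------------
# Resume state

#' Save the resume state of a run
#'
#' Writes the ids of every unit that finished `done` or was skipped by its
#' guard, one per line, to a plain-text state file that a later
#' [resume_pipeline()] reads.
#'
#' @param report An `execution_report`.
#' @param path State file path (see [run_settings()] for the default
#'   location).
#' @return `path`, invisibly.
#' @export
save_state <- function(report, path) {
  done <- report$units$unit_id[report$units$state %in%
                                 c("done", "skipped-by-guard")]
  writeLines(done, path)
  invisible(path)
}

#' Load the resume state of a previous run
#'
#' @param path State file path.
#' @return Character vector of completed unit ids.
#' @export
load_state <- function(path) {
  if (!file.exists(path))
    dagrun_error("dagrun_state_error",
                 sprintf("state file '%s' does not exist", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  bad <- !grepl("^[A-Za-z_][A-Za-z0-9_]*(\\[[0-9]+\\])?$", lines)
  if (any(bad))
    dagrun_error("dagrun_state_error",
                 sprintf("state file '%s' is corrupt (unparseable line: %s)",
                         path, lines[bad][1]))
  lines
}

#' Resume a partially completed run
#'
#' Loads the state file written by a previous run, verifies that every
#' recorded unit belongs to a task of the current pipeline, and re-runs only
#' the units not recorded as completed, treating completed dependencies as
#' satisfied.
#'
#' @inheritParams run_pipeline
#' @param state_path State file path; defaults to the location derived from
#'   `settings`.
#' @return An `execution_report` for the resumed run.
#' @export
resume_pipeline <- function(doc, param_values = character(),
                            settings = run_settings(), state_path = NULL) {
  path <- state_path %||% state_path_for(settings)
  completed <- load_state(path)
  run_pipeline(doc, param_values, settings, completed = completed)
}
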