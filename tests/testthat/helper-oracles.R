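# Independent oracles, written before and kept independent of the engine:
# reachability by exhaustive depth-first search over a raw edge list, a
# brute-force topological-order check, and event-log measurement helpers.

# All nodes reachable from `seeds` following edges in `mode` ("out" =
# dependents, "in" = dependencies); seeds included.
oracle_reach <- function(nodes, edges, seeds, mode = "out") {
  nxt <- function(v) {
    if (mode == "out") edges$to[edges$from == v] else edges$from[edges$to == v]
  }
  seen <- character()
  stack <- as.list(seeds)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v %in% seen) next
    seen <- c(seen, v)
    for (w in nxt(v)) if (!w %in% seen) stack[[length(stack) + 1L]] <- w
  }
  nodes[nodes %in% seen]
}

# Brute-force sub-pipeline selection over the raw edge list.
oracle_select <- function(nodes, edges, from = character(),
                          after = character(), until = character(),
                          before = character(), single_task = NULL) {
  if (!is.null(single_task)) return(single_task)
  down <- nodes
  if (length(from) || length(after)) {
    down <- union(oracle_reach(nodes, edges, from, "out"),
                  setdiff(oracle_reach(nodes, edges, after, "out"), after))
  }
  up <- nodes
  if (length(until) || length(before)) {
    up <- union(oracle_reach(nodes, edges, until, "in"),
                setdiff(oracle_reach(nodes, edges, before, "in"), before))
  }
  nodes[nodes %in% intersect(down, up)]
}

# TRUE iff `order` (a vector of task ids, first started first) respects
# every edge of the list: each dependency starts before its dependent.
oracle_is_topological <- function(order, edges) {
  pos <- stats::setNames(seq_along(order), order)
  if (nrow(edges) == 0L) return(TRUE)
  all(vapply(seq_len(nrow(edges)), function(i) {
    f <- edges$from[i]; t <- edges$to[i]
    if (!f %in% order || !t %in% order) return(TRUE)
    pos[[f]] < pos[[t]]
  }, TRUE))
}

# --- event-log helpers ------------------------------------------------------

event_time <- function(report, unit_id, event) {
  ev <- report$events
  t <- ev$time[ev$unit_id == unit_id & ev$event == event]
  if (length(t)) t[[1]] else NA_real_
}

start_order_tasks <- function(report) {
  ev <- report$events[report$events$event == "start", , drop = FALSE]
  sub("\\[[0-9]+\\]$", "", ev$unit_id[order(ev$time)])
}

# Maximum number of simultaneously running units, by interval overlap
# counting on the event log.
max_overlap <- function(report) {
  ev <- report$events
  starts <- ev$time[ev$event == "start"]
  ends <- ev$time[ev$event %in% c("end", "fail")]
  if (!length(starts)) return(0L)
  max(vapply(starts, function(tt)
    sum(starts <= tt) - sum(ends < tt), 0))
}

# No unit starts before its dependency obligations end. Checks every edge of
# the raw list against the report's event log: for a non-binding edge A->B,
# every B start >= every A end; for binding, B[i] start >= A[i] end.
dependency_violations <- function(report, edges) {
  ev <- report$events
  bad <- 0L
  unit_tasks <- sub("\\[[0-9]+\\]$", "", ev$unit_id)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    a_ends <- ev$time[unit_tasks == a & ev$event == "end"]
    b_starts_ids <- ev$unit_id[unit_tasks == b & ev$event == "start"]
    if (!length(a_ends) || !length(b_starts_ids)) next
    if (edges$binding[i]) {
      for (uid in b_starts_ids) {
        idx <- sub("^.*\\[([0-9]+)\\]$", "\\1", uid)
        dep_uid <- sprintf("%s[%s]", a, idx)
        te <- ev$time[ev$unit_id == dep_uid & ev$event == "end"]
        ts <- ev$time[ev$unit_id == uid & ev$event == "start"]
        if (length(te) && ts < te) bad <- bad + 1L
      }
    } else {
      b_starts <- ev$time[unit_tasks == b & ev$event == "start"]
      bad <- bad + sum(min(b_starts) < max(a_ends))
    }
  }
  bad
}

# --- fixtures ---------------------------------------------------------------

quiet_settings <- function(...) run_settings(quiet = TRUE, ...)

run_generated <- function(gp, param_values = character(), ...) {
  doc <- parse_pipeline(gp$xml_text)
  run_pipeline(doc, param_values, quiet_settings(...))
}

# A three-task chain a -> b -> c; each task appends its id to $log and b
# fails while the file $fail_flag exists.
chain_pipeline <- function() {
  doc <- pipeline_doc(
    params = list(param_def("log", "append-log path", global = TRUE),
                  param_def("fail_flag", "b fails while this file exists",
                            global = TRUE)),
    tasks = list(
      task_def("a", code = "echo a >> \"$log\"\n"),
      task_def("b", code = paste0(
        "if [ -e \"$fail_flag\" ]; then exit 1; fi\n",
        "echo b >> \"$log\"\n"), after = "a"),
      task_def("c", code = "echo c >> \"$log\"\n", after = "b")
    )
  )
  doc
}

fig2_doc <- function() parse_pipeline(minimal_pipeline()$xml_text)
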