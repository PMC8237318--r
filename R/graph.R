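# Dependency graph construction, sub-pipeline selection, and DOT export.

#' Build the task dependency graph
#'
#' One node per task and one directed edge per `after` entry, pointing from
#' the dependency to the dependent. The edge's `binding` flag is `TRUE` for
#' `*`-prefixed entries (iteration-level dependencies), which are only legal
#' between two foreach tasks.
#'
#' @param doc A validated `pipeline_doc` ([validate_pipeline()] must report no
#'   errors).
#' @return A `dep_graph`: list with `nodes` (task ids in document order) and
#'   `edges` (data frame `from`, `to`, `binding`).
#' @export
build_graph <- function(doc) {
  issues <- validate_pipeline(doc)
  if (has_validation_errors(issues))
    dagrun_error("dagrun_validation_error",
                 paste0("pipeline has validation errors:\n",
                        paste(issues$message[issues$severity == "error"],
                              collapse = "\n")))
  nodes <- task_ids(doc)
  from <- character(); to <- character(); binding <- logical()
  for (t in doc$tasks) {
    for (ref in t$after) {
      target <- dep_target(ref)
      bind <- dep_is_binding(ref)
      if (bind) {
        src <- get_task(doc, target)
        if (!is_foreach(src) || !is_foreach(t))
          dagrun_error("dagrun_binding_error",
                       sprintf("iteration-binding dependency '%s' of task '%s': both endpoints must be foreach tasks",
                               ref, t$id))
      }
      from <- c(from, target); to <- c(to, t$id); binding <- c(binding, bind)
    }
  }
  edges <- data.frame(from = from, to = to, binding = binding,
                      stringsAsFactors = FALSE)
  g <- structure(list(nodes = nodes, edges = edges), class = "dep_graph")
  if (nrow(edges) > 0L) {
    ig <- as_igraph(g)
    if (!igraph::is_dag(ig)) {
      adj <- stats::setNames(lapply(nodes, function(n)
        edges$from[edges$to == n]), nodes)
      cyc <- find_cycle(nodes, adj)
      dagrun_error("dagrun_cycle_error",
                   sprintf("dependency cycle: %s",
                           paste(rev(cyc), collapse = " -> ")))
    }
  }
  g
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges[, c("from", "to")], directed = TRUE,
                                vertices = g$nodes)
}

#' @export
print.dep_graph <- function(x, ...) {
  cat(sprintf("<dep_graph> %d tasks, %d dependencies\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Describe a sub-pipeline selection
#'
#' Captures the from/after/until/before/single-task execution modifiers.
#' `from`/`until` are inclusive of the named tasks, `after`/`before` are
#' exclusive. `single_task` is incompatible with the other four.
#'
#' @param from,after,until,before Character vectors of task ids (may be
#'   empty).
#' @param single_task Optional single task id.
#' @return A `subgraph_query` object.
#' @export
subgraph_query <- function(from = character(), after = character(),
                           until = character(), before = character(),
                           single_task = NULL) {
  q <- structure(list(from = from, after = after, until = until,
                      before = before, single_task = single_task),
                 class = "subgraph_query")
  if (!is.null(single_task) &&
      (length(from) || length(after) || length(until) || length(before)))
    dagrun_error("dagrun_query_error",
                 "--single-task is not compatible with --from/--after/--until/--before")
  q
}

query_is_empty <- function(q) {
  is.null(q$single_task) && !length(q$from) && !length(q$after) &&
    !length(q$until) && !length(q$before)
}

#' Select the tasks of a sub-pipeline
#'
#' With no modifiers every task is selected. Downstream seeds select the
#' descendants-closure (`from` including the seeds, `after` excluding them);
#' upstream seeds select the ancestors-closure (`until` inclusive, `before`
#' exclusive). When both downstream and upstream seeds are given the result
#' is the intersection of the two closures — on a chain, `from = t1,
#' until = t10` selects the whole path endpoints included, while
#' `after`/`before` select only the interior. `single_task` selects exactly
#' that task.
#'
#' @param g A `dep_graph`.
#' @param q A [subgraph_query()].
#' @return Character vector of selected task ids, in graph node order.
#' @export
select_subgraph <- function(g, q = subgraph_query()) {
  named <- c(q$from, q$after, q$until, q$before, q$single_task)
  unknown <- setdiff(named, g$nodes)
  if (length(unknown))
    dagrun_error("dagrun_selection_error",
                 sprintf("unknown task(s) in selection: %s",
                         paste(unknown, collapse = ", ")))
  if (!is.null(q$single_task)) return(q$single_task)
  if (query_is_empty(q)) return(g$nodes)

  ig <- as_igraph(g)
  reach <- function(seeds, mode) {
    unique(unlist(lapply(seeds, function(s)
      names(igraph::subcomponent(ig, s, mode = mode)))))
  }
  down <- g$nodes
  if (length(q$from) || length(q$after)) {
    down <- union(reach(q$from, "out"),
                  setdiff(reach(q$after, "out"), q$after))
  }
  up <- g$nodes
  if (length(q$until) || length(q$before)) {
    up <- union(reach(q$until, "in"),
                setdiff(reach(q$before, "in"), q$before))
  }
  g$nodes[g$nodes %in% intersect(down, up)]
}

#' Export the dependency graph as Graphviz DOT text
#'
#' One node per task labeled with its id, one edge per dependency. Foreach
#' tasks are drawn with a dashed border; iteration-binding edges carry a `*`
#' label. Output is deterministic: nodes and edges in document order.
#'
#' @param doc A validated `pipeline_doc`.
#' @return DOT digraph text as a single string.
#' @export
export_graph <- function(doc) {
  g <- build_graph(doc)
  lines <- c("digraph pipeline {")
  for (t in doc$tasks) {
    style <- if (is_foreach(t)) " [style=dashed]" else ""
    lines <- c(lines, sprintf("  \"%s\"%s;", t$id, style))
  }
  for (t in doc$tasks) {
    for (ref in t$after) {
      label <- if (dep_is_binding(ref)) " [label=\"*\"]" else ""
      lines <- c(lines,
                 sprintf("  \"%s\" -> \"%s\"%s;", dep_target(ref), t$id,
                         label))
    }
  }
  lines <- c(lines, "}")
  paste(lines, collapse = "\n")
}
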