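# Pipeline definition model: XML dialect parsing, serialization, semantic
# validation, and the plain-text key=value parameters file.
#
# Dialect summary (see the package vignette for the full grammar):
#   <pipeline version="...">
#     <params>
#       <param name="x" global="true|false" defaultValue="...">description</param>
#     </params>
#     <tasks>
#       <task id="a" params="x y" after="b *c" interpreter="..." if="...">
#         <![CDATA[ script ]]>
#       </task>
#       <foreach id="f" of="list|range|files_in_dir|param_values|command"
#                in="..." as="item" params="..." after="..."> ... </foreach>
#     </tasks>
#     <metadata>
#       <task-description id="a">human description</task-description>
#     </metadata>
#   </pipeline>

FOREACH_KINDS <- c("list", "range", "files_in_dir", "param_values", "command")

#' Declare a pipeline parameter
#'
#' @param name Parameter name; must be a shell-safe identifier (letters,
#'   digits, underscore, not starting with a digit) because values are passed
#'   to task scripts as environment variables.
#' @param description Free-text description used for help generation.
#' @param default_value Optional default used when neither the command line
#'   nor a params file supplies a value.
#' @param global If `TRUE` the parameter is visible to every task without
#'   per-task declaration.
#' @return A `param_def` object.
#' @export
param_def <- function(name, description = "", default_value = NULL,
                      global = FALSE) {
  structure(
    list(name = name, description = description,
         default_value = default_value, global = isTRUE(global)),
    class = "param_def"
  )
}

#' Define a pipeline task
#'
#' @param id Task identifier, unique within the pipeline.
#' @param code Raw task script text, preserved byte-for-byte; executed by the
#'   system shell (or the declared interpreter).
#' @param params Character vector of declared parameter names this task uses.
#' @param after Character vector of dependency task ids; a `*` prefix marks an
#'   iteration-level (binding) dependency between two foreach tasks.
#' @param interpreter Optional shell fragment that receives the task code in
#'   the `task_code` environment variable and delegates to another language.
#' @param if_guard Optional shell command evaluated just before the task runs;
#'   exit status 0 runs the task, nonzero skips it.
#' @param description Free-text task description (metadata section).
#' @param foreach For loop tasks, a list with elements `source_kind`,
#'   `source_arg` and `item_var`; `NULL` for plain tasks.
#' @return A `task_def` object.
#' @export
task_def <- function(id, code = "", params = character(), after = character(),
                     interpreter = NULL, if_guard = NULL, description = "",
                     foreach = NULL) {
  structure(
    list(id = id, code = code, params = params, after = after,
         interpreter = interpreter, if_guard = if_guard,
         description = description, foreach = foreach),
    class = "task_def"
  )
}

#' Define a foreach (loop) task
#'
#' A foreach task is expanded at run time into one iteration unit per item of
#' a resolved collection; units run in parallel subject to the concurrency
#' bound. The item value is bound to the environment variable `item_var`.
#'
#' @inheritParams task_def
#' @param source_kind One of `"list"` (comma-separated values), `"range"`
#'   (inclusive integer range `a..b`), `"files_in_dir"` (files directly in a
#'   directory, sorted), `"param_values"` (comma-split value of a parameter),
#'   or `"command"` (stdout lines of a shell command, resolved only when the
#'   loop is about to run).
#' @param source_arg The list text, range bounds, directory, parameter name,
#'   or command line, according to `source_kind`.
#' @param item_var Environment-variable name each item is bound to.
#' @return A `task_def` object with a non-`NULL` `foreach` field.
#' @export
foreach_def <- function(id, source_kind, source_arg, item_var, code = "",
                        params = character(), after = character(),
                        interpreter = NULL, if_guard = NULL,
                        description = "") {
  task_def(id, code, params, after, interpreter, if_guard, description,
           foreach = list(source_kind = source_kind, source_arg = source_arg,
                          item_var = item_var))
}

is_foreach <- function(task) !is.null(task$foreach)

#' Construct a pipeline document
#'
#' @param params List of [param_def()] objects.
#' @param tasks Ordered list of [task_def()] / [foreach_def()] objects.
#' @param version Optional version string.
#' @return A `pipeline_doc` object.
#' @export
pipeline_doc <- function(params = list(), tasks = list(), version = NULL) {
  structure(list(params = params, tasks = tasks, version = version),
            class = "pipeline_doc")
}

#' @export
print.pipeline_doc <- function(x, ...) {
  cat("<pipeline_doc>", if (!is.null(x$version)) paste0("v", x$version), "\n")
  cat("  params:", paste(vapply(x$params, `[[`, "", "name"), collapse = ", "),
      "\n")
  for (t in x$tasks) {
    kind <- if (is_foreach(t)) "foreach" else "task"
    dep <- if (length(t$after)) paste0(" after=", paste(t$after, collapse = ","))
           else ""
    cat(sprintf("  %s %s%s\n", kind, t$id, dep))
  }
  invisible(x)
}

param_names <- function(doc) vapply(doc$params, `[[`, "", "name")
task_ids <- function(doc) vapply(doc$tasks, `[[`, "", "id")

get_task <- function(doc, id) {
  for (t in doc$tasks) if (t$id == id) return(t)
  dagrun_error("dagrun_lookup_error", sprintf("no task '%s' in pipeline", id))
}

get_param <- function(doc, name) {
  for (p in doc$params) if (p$name == name) return(p)
  NULL
}

# Strip the iteration-binding mark from dependency references.
dep_target <- function(ref) sub("^\\*", "", ref)
dep_is_binding <- function(ref) startsWith(ref, "*")

# ---------------------------------------------------------------------------
# Parsing

pipeline_schema <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "pipeline.xsd", package = "dagrun",
                          mustWork = TRUE)
      cache <<- xml2::read_xml(path)
    }
    cache
  }
})

# Extract a task's code: concatenated CDATA sections when present (preserved
# byte-for-byte), otherwise the entity-decoded element text.
node_code <- function(node) {
  kids <- xml2::xml_contents(node)
  if (length(kids) == 0L) return("")
  types <- vapply(kids, function(k) as.character(xml2::xml_type(k)), "")
  if (any(types == "cdata")) {
    return(paste(vapply(kids[types == "cdata"], xml2::xml_text, ""),
                 collapse = ""))
  }
  xml2::xml_text(node)
}

attr_or_null <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

#' Parse a pipeline definition from XML text
#'
#' Reads the XML pipeline dialect into a [pipeline_doc()]. Task code bodies
#' are taken verbatim from CDATA sections (or decoded element text) with no
#' variable substitution or whitespace normalization: the engine never
#' rewrites task code. Section order within the document is irrelevant.
#'
#' @param xml_text Pipeline XML as a single string, or a file path to read.
#' @return A `pipeline_doc`.
#' @seealso [validate_pipeline()] for semantic checks beyond the schema.
#' @export
parse_pipeline <- function(xml_text) {
  if (length(xml_text) != 1L || !nzchar(xml_text))
    dagrun_error("dagrun_parse_error", "empty pipeline document")
  if (!grepl("<", xml_text, fixed = TRUE) && file.exists(xml_text))
    xml_text <- read_raw_text(xml_text)
  x <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) dagrun_error(
      "dagrun_parse_error", paste0("malformed pipeline XML: ",
                                   conditionMessage(e)))
  )
  if (xml2::xml_name(x) != "pipeline")
    dagrun_error("dagrun_schema_error",
                 sprintf("root element must be <pipeline>, found <%s>",
                         xml2::xml_name(x)))
  ok <- xml2::xml_validate(x, pipeline_schema())
  if (!isTRUE(ok))
    dagrun_error("dagrun_schema_error",
                 paste0("pipeline does not match the schema: ",
                        paste(attr(ok, "errors"), collapse = "; ")))

  params <- list()
  for (p in xml2::xml_find_all(x, "./params/param")) {
    params[[length(params) + 1L]] <- param_def(
      name = xml2::xml_attr(p, "name"),
      description = trimws(xml2::xml_text(p)),
      default_value = attr_or_null(p, "defaultValue"),
      global = identical(attr_or_null(p, "global"), "true")
    )
  }

  descriptions <- list()
  for (d in xml2::xml_find_all(x, "./metadata/task-description")) {
    descriptions[[xml2::xml_attr(d, "id")]] <- trimws(xml2::xml_text(d))
  }

  tasks <- list()
  for (t in xml2::xml_find_all(x, "./tasks/*")) {
    id <- xml2::xml_attr(t, "id")
    common <- list(
      id = id,
      code = node_code(t),
      params = split_id_list(attr_or_null(t, "params")),
      after = split_id_list(attr_or_null(t, "after")),
      interpreter = attr_or_null(t, "interpreter"),
      if_guard = attr_or_null(t, "if"),
      description = descriptions[[id]] %||% ""
    )
    task <- if (xml2::xml_name(t) == "foreach") {
      do.call(foreach_def, c(common, list(
        source_kind = xml2::xml_attr(t, "of"),
        source_arg = xml2::xml_attr(t, "in"),
        item_var = xml2::xml_attr(t, "as")
      )))
    } else {
      do.call(task_def, common)
    }
    tasks[[length(tasks) + 1L]] <- task
  }

  pipeline_doc(params = params, tasks = tasks,
               version = attr_or_null(x, "version"))
}

#' Serialize a pipeline document back to XML text
#'
#' Produces XML in the package dialect that parses back to an equal
#' `pipeline_doc`. Task code is emitted inside CDATA sections (an embedded
#' `]]>` is split across two sections, the standard escape).
#'
#' @param doc A `pipeline_doc`.
#' @return A single XML string.
#' @export
serialize_pipeline <- function(doc) {
  out <- character()
  emit <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  version_attr <- if (!is.null(doc$version))
    paste0(" version=\"", xml_escape(doc$version), "\"") else ""
  emit("<pipeline", version_attr, ">")
  emit("  <params>")
  for (p in doc$params) {
    attrs <- paste0(" name=\"", xml_escape(p$name), "\"")
    if (isTRUE(p$global)) attrs <- paste0(attrs, " global=\"true\"")
    if (!is.null(p$default_value))
      attrs <- paste0(attrs, " defaultValue=\"", xml_escape(p$default_value),
                      "\"")
    emit("    <param", attrs, ">", xml_escape(p$description), "</param>")
  }
  emit("  </params>")
  emit("  <tasks>")
  for (t in doc$tasks) {
    el <- if (is_foreach(t)) "foreach" else "task"
    attrs <- paste0(" id=\"", xml_escape(t$id), "\"")
    if (is_foreach(t)) {
      attrs <- paste0(attrs,
                      " of=\"", xml_escape(t$foreach$source_kind), "\"",
                      " in=\"", xml_escape(t$foreach$source_arg), "\"",
                      " as=\"", xml_escape(t$foreach$item_var), "\"")
    }
    if (length(t$params))
      attrs <- paste0(attrs, " params=\"",
                      xml_escape(paste(t$params, collapse = " ")), "\"")
    if (length(t$after))
      attrs <- paste0(attrs, " after=\"",
                      xml_escape(paste(t$after, collapse = " ")), "\"")
    if (!is.null(t$interpreter))
      attrs <- paste0(attrs, " interpreter=\"", xml_escape(t$interpreter),
                      "\"")
    if (!is.null(t$if_guard))
      attrs <- paste0(attrs, " if=\"", xml_escape(t$if_guard), "\"")
    emit("    <", el, attrs, ">", xml_cdata_wrap(t$code), "</", el, ">")
  }
  emit("  </tasks>")
  descs <- Filter(function(t) nzchar(t$description), doc$tasks)
  if (length(descs)) {
    emit("  <metadata>")
    for (t in descs)
      emit("    <task-description id=\"", xml_escape(t$id), "\">",
           xml_escape(t$description), "</task-description>")
    emit("  </metadata>")
  }
  emit("</pipeline>")
  paste(out, collapse = "\n")
}

# ---------------------------------------------------------------------------
# Validation

issue <- function(severity, code, task_id, message, position) {
  data.frame(severity = severity, code = code,
             task_id = if (is.null(task_id)) NA_character_ else task_id,
             message = message, position = position,
             stringsAsFactors = FALSE)
}

# Whole-token occurrence of $name or ${name} in code text.
param_token_in_code <- function(name, code) {
  re <- paste0("\\$", name, "(?![A-Za-z0-9_])|\\$\\{", name, "\\}")
  grepl(re, code, perl = TRUE)
}

# Find one cycle among task dependency references (iterative DFS).
find_cycle <- function(ids, adj) {
  color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  cycle <- NULL
  visit <- function(u) {
    color[[u]] <<- 1L
    for (v in adj[[u]]) {
      if (is.null(cycle) && color[[v]] == 0L) {
        parent[[v]] <<- u
        visit(v)
      } else if (color[[v]] == 1L) {
        # walk back from u to v
        path <- u
        w <- u
        while (!identical(w, v)) {
          w <- parent[[w]]
          path <- c(w, path)
        }
        cycle <<- c(path, v)
        return()
      }
    }
    color[[u]] <<- 2L
  }
  for (u in ids) if (color[[u]] == 0L && is.null(cycle)) visit(u)
  cycle
}

#' Validate a pipeline document
#'
#' Performs the semantic checks that the XML schema cannot express. Errors
#' always block execution; warnings block only under abort-if-warnings.
#'
#' Errors: duplicate task ids or parameter names, invalid identifiers, a
#' task's `params` naming an undeclared parameter, unresolvable or
#' self-referential dependencies, dependency cycles, and a foreach item
#' variable colliding with a parameter name. Warnings: a declared parameter
#' name occurring as a `$name` / `${name}` token in a task's code while the
#' task has no access to it (not declared for the task and not global) — the
#' typical authoring slip of using a parameter without declaring it.
#'
#' @param doc A `pipeline_doc`.
#' @return A data frame of issues with columns `severity`, `code`, `task_id`,
#'   `message`, deterministically ordered by task position then issue code;
#'   zero rows when the pipeline is clean.
#' @export
validate_pipeline <- function(doc) {
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- issue(...)

  pnames <- param_names(doc)
  ids <- task_ids(doc)

  for (p in doc$params) {
    if (!is_identifier(p$name))
      add("error", "invalid-identifier", NULL,
          sprintf("parameter name '%s' is not a shell-safe identifier",
                  p$name), 0L)
  }
  for (dup in unique(pnames[duplicated(pnames)]))
    add("error", "duplicate-param", NULL,
        sprintf("parameter '%s' declared more than once", dup), 0L)
  for (dup in unique(ids[duplicated(ids)]))
    add("error", "duplicate-id", NULL,
        sprintf("task id '%s' declared more than once", dup), 0L)

  globals <- pnames[vapply(doc$params, `[[`, TRUE, "global")]

  for (i in seq_along(doc$tasks)) {
    t <- doc$tasks[[i]]
    if (!is_identifier(t$id))
      add("error", "invalid-identifier", t$id,
          sprintf("task id '%s' is not a shell-safe identifier", t$id), i)
    for (p in setdiff(t$params, pnames))
      add("error", "unknown-param", t$id,
          sprintf("task '%s' declares unknown parameter '%s'", t$id, p), i)
    for (ref in t$after) {
      target <- dep_target(ref)
      if (identical(target, t$id)) {
        add("error", "self-dependency", t$id,
            sprintf("task '%s' depends on itself", t$id), i)
      } else if (!target %in% ids) {
        add("error", "unknown-dependency", t$id,
            sprintf("task '%s' depends on unknown task '%s'", t$id, target),
            i)
      }
    }
    if (is_foreach(t)) {
      fe <- t$foreach
      if (!fe$source_kind %in% FOREACH_KINDS)
        add("error", "invalid-foreach-source", t$id,
            sprintf("foreach '%s' has unknown item source kind '%s'",
                    t$id, fe$source_kind), i)
      if (!is_identifier(fe$item_var))
        add("error", "invalid-identifier", t$id,
            sprintf("foreach '%s' item variable '%s' is not shell-safe",
                    t$id, fe$item_var), i)
      else if (fe$item_var %in% pnames)
        add("error", "item-var-collision", t$id,
            sprintf("foreach '%s' item variable '%s' collides with a pipeline parameter",
                    t$id, fe$item_var), i)
    }
    # inaccessible-parameter warning
    inaccessible <- setdiff(pnames, union(t$params, globals))
    for (p in inaccessible) {
      if (param_token_in_code(p, t$code))
        add("warning", "param-not-accessible", t$id,
            sprintf("parameter '%s' appears in the code of task '%s' but the task has no access to it (not declared for the task and not global)",
                    p, t$id), i)
    }
  }

  # cycle detection over resolvable, non-self dependencies
  if (!any(duplicated(ids))) {
    adj <- stats::setNames(lapply(doc$tasks, function(t) {
      targets <- vapply(t$after, dep_target, "")
      unname(targets[targets %in% ids & targets != t$id])
    }), ids)
    # edge u -> v where u depends on v (visit dependencies)
    cyc <- find_cycle(ids, adj)
    if (!is.null(cyc)) {
      pos <- min(match(cyc, ids))
      add("error", "dependency-cycle", ids[pos],
          sprintf("dependency cycle: %s", paste(rev(cyc), collapse = " -> ")),
          pos)
    }
  }

  if (length(issues) == 0L) {
    return(data.frame(severity = character(), code = character(),
                      task_id = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  out <- out[order(out$position, out$code, out$message), , drop = FALSE]
  rownames(out) <- NULL
  out$position <- NULL
  out
}

has_validation_errors <- function(issues) {
  any(issues$severity == "error")
}

# ---------------------------------------------------------------------------
# Parameters file

#' Parse a plain-text key=value parameters file
#'
#' One `name=value` pair per line; blank lines and `#` comment lines are
#' ignored. The value is everything after the first `=`, whitespace preserved.
#' A later duplicate key overrides an earlier one.
#'
#' @param text File content as a single string (or a path to read).
#' @return A named character vector of parameter values.
#' @export
parse_params_file <- function(text) {
  if (length(text) == 1L && !grepl("[=\n#]", text) && file.exists(text))
    text <- read_raw_text(text)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  out <- character()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || grepl("^[[:space:]]*#", line)) next
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0L)
      dagrun_error("dagrun_params_error",
                   sprintf("line %d of parameters file is not 'name=value': %s",
                           i, line))
    key <- trimws(substr(line, 1L, eq - 1L))
    out[[key]] <- substr(line, eq + 1L, nchar(line))
  }
  out
}
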