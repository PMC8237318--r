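# Example and randomized pipeline generators. These are first-class,
# tested generators: they make the whole engine exercisable with no external
# data or services, and they ship the expected dependency structure alongside
# the XML so tests can check the engine against an independent oracle.

generated_pipeline <- function(xml_text, expected_graph,
                               expected_param_names, seed = NULL) {
  structure(list(xml_text = xml_text, expected_graph = expected_graph,
                 expected_param_names = expected_param_names, seed = seed),
            class = "generated_pipeline")
}

edge_df <- function(from = character(), to = character(),
                    binding = logical()) {
  data.frame(from = from, to = to, binding = binding,
             stringsAsFactors = FALSE)
}

#' A minimal two-task example pipeline
#'
#' Two parameters (`name`, `output`) and two tasks: `greetings`, a plain
#' shell task, and `bye`, which runs after `greetings` and is written in
#' Python, executed through an interpreter that pipes the task code (from
#' the `task_code` environment variable) into the Python interpreter. Both
#' tasks append a line containing the `name` value to the `output` path, so
#' a successful run leaves a two-line file with the `greetings` line first.
#'
#' @return A `generated_pipeline` (fields `xml_text`, `expected_graph`,
#'   `expected_param_names`).
#' @export
minimal_pipeline <- function() {
  doc <- pipeline_doc(
    params = list(
      param_def("name", "Name of the person to greet"),
      param_def("output", "Path of the file greetings are appended to")
    ),
    tasks = list(
      task_def("greetings",
               code = "echo \"hello $name\" >> \"$output\"\n",
               params = c("name", "output"),
               description = "Greet and append the line to the output file"),
      task_def("bye",
               code = paste0(
                 "import os\n",
                 "with open(os.environ[\"output\"], \"a\") as fh:\n",
                 "    fh.write(\"bye \" + os.environ[\"name\"] + \"\\n\")\n"),
               params = c("name", "output"),
               after = "greetings",
               interpreter = "printf '%s' \"$task_code\" | python",
               description = "Say goodbye, in Python, via an interpreter")
    ),
    version = "1.0"
  )
  generated_pipeline(serialize_pipeline(doc),
                     edge_df("greetings", "bye", FALSE),
                     c("name", "output"))
}

#' A two-loop pipeline with iteration-level binding
#'
#' Two consecutive foreach tasks, `preprocess` and `analyze`, iterating over
#' the same list of samples. `analyze` depends on `preprocess` at the
#' iteration level (`after = "*preprocess"`), so iteration i of `analyze`
#' may start as soon as iteration i of `preprocess` finishes, without
#' waiting for the whole loop. Each iteration sleeps a configurable
#' per-sample duration and then touches a marker file
#' (`pre_<sample>` / `an_<sample>`) in the `workdir` directory, which lets
#' tests verify ordering and overlap from the file system and the event log.
#'
#' @param samples Character vector of sample names (non-empty).
#' @param pre_sleeps Numeric vector of per-sample sleep seconds for
#'   `preprocess` (recycled to `length(samples)`).
#' @param analyze_sleep Sleep seconds for every `analyze` iteration.
#' @param binding Use the `*` iteration-binding mark (`TRUE`, default) or a
#'   plain whole-loop dependency (`FALSE`).
#' @return A `generated_pipeline`.
#' @export
foreach_pipeline <- function(samples, pre_sleeps = 0.05,
                             analyze_sleep = 0.02, binding = TRUE) {
  stopifnot(length(samples) >= 1L)
  pre_sleeps <- rep_len(pre_sleeps, length(samples))
  sleep_case <- function(sleeps) {
    paste0("case \"$sample\" in\n",
           paste0("  ", samples, ") s=", format(sleeps, trim = TRUE),
                  " ;;\n", collapse = ""),
           "  *) s=0 ;;\n",
           "esac\nsleep \"$s\"\n")
  }
  list_arg <- paste(samples, collapse = ",")
  doc <- pipeline_doc(
    params = list(
      param_def("workdir", "Directory marker files are written to",
                global = TRUE)
    ),
    tasks = list(
      foreach_def("preprocess", "list", list_arg, "sample",
                  code = paste0(sleep_case(pre_sleeps),
                                "touch \"$workdir/pre_$sample\"\n"),
                  description = "Per-sample preprocessing step"),
      foreach_def("analyze", "list", list_arg, "sample",
                  code = paste0("sleep ",
                                format(analyze_sleep, trim = TRUE), "\n",
                                "touch \"$workdir/an_$sample\"\n"),
                  after = if (binding) "*preprocess" else "preprocess",
                  description = "Per-sample analysis step")
    )
  )
  generated_pipeline(serialize_pipeline(doc),
                     edge_df("preprocess", "analyze", binding),
                     "workdir")
}

#' A random acyclic pipeline for property tests
#'
#' Generates `n` trivial tasks with random forward edges only (task i may
#' depend on task j only for j < i), which guarantees acyclicity by
#' construction. The edge list is returned alongside the XML as the oracle
#' input for reachability and topological-order checks. Deterministic for a
#' given seed; the global RNG state is left untouched.
#'
#' @param n Number of tasks (>= 1).
#' @param edge_prob Probability of each forward edge, in `[0, 1]`.
#' @param seed Integer seed.
#' @param code Task body; the default does nothing and exits 0.
#' @return A `generated_pipeline` with `expected_graph` as its edge oracle.
#' @export
random_dag_pipeline <- function(n, edge_prob = 0.25, seed = 1L,
                                code = "true\n") {
  stopifnot(n >= 1L, edge_prob >= 0, edge_prob <= 1)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  ids <- sprintf("t%02d", seq_len(n))
  from <- character(); to <- character()
  if (n >= 2L) {
    for (i in 2L:n) {
      deps <- which(stats::runif(i - 1L) < edge_prob)
      from <- c(from, ids[deps])
      to <- c(to, rep(ids[i], length(deps)))
    }
  }
  tasks <- lapply(seq_len(n), function(i) {
    task_def(ids[i], code = code, after = from[to == ids[i]])
  })
  doc <- pipeline_doc(tasks = tasks)
  generated_pipeline(serialize_pipeline(doc),
                     edge_df(from, to, rep(FALSE, length(from))),
                     character(), seed = seed)
}
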