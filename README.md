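# dagrun

`dagrun` is an R implementation of a shell-first workflow execution engine:
pipelines are written as a single XML file containing plain shell (or any
other language's) scripts as tasks, and the engine takes care of everything
around them — dependency ordering, bounded parallelism, per-sample loop
scattering, logging, partial execution and restart after failure. It is
aimed at bioinformaticians and data scientists who are comfortable writing
shell scripts that call their tools (`bwa`, `samtools`, `Rscript`, …) but do
not want to adopt a full workflow DSL to get scheduling, logging and
resumability.

## The model

A pipeline is a set of tasks `T` with a dependency relation given by each
task's `after` list; the engine computes the directed acyclic graph
`G = (T, E)` with an edge `(a, b) ∈ E` when `b` lists `a` in `after`, and
refuses cyclic definitions. Execution is reactive: whenever a task finishes,
every task whose dependencies are all complete becomes eligible, and
eligible work is dispatched while fewer than `--num-tasks` units are in
flight.

Two features refine this scheduling skeleton:

* **Foreach (loop) tasks** iterate a script over a collection of items — a
  comma-separated list, an integer range `a..b`, the files in a directory,
  a comma-separated parameter value, or the stdout lines of a command that
  is run only when the loop is about to start. A foreach expands into one
  *iteration unit* per item, each unit receiving its item in an environment
  variable. A dependency between two loops over the same collection may be
  marked `after="*upstream"`: iteration `i` of the downstream loop then
  starts as soon as iteration `i` upstream finishes, instead of waiting for
  the whole upstream loop.
* **Parameters as environment variables.** Pipeline parameters are declared
  once, documented, and passed to task scripts purely through the
  environment — the engine never rewrites task code, which is what makes it
  language-agnostic. A task sees exactly its declared parameters, the
  `global` parameters, its loop item, and the engine variables `task_id` and
  `working_dir`; using an undeclared parameter's `$name` in task code is
  flagged by validation.

Execution can be tailored without touching the pipeline: an `interpreter`
attribute delegates a task's code (delivered byte-for-byte in the
`task_code` environment variable) to another language, and *runners* —
scripts supplied at execution time — replace local execution for assigned
tasks, e.g. wrapping them in `srun`/`qsub` submissions or `docker run`
invocations.

## A worked example

```r
library(dagrun)

writeLines(minimal_pipeline()$xml_text, "pipeline.xml")
status <- dagrun_main(c("run", "--logs", "logs",
                        "--", "name", "Ada", "output", "hello.txt"))
```

The engine prints its progress and exits with status 0:

```
running 'greetings'
task 'greetings' done
running 'bye' via interpreter
task 'bye' done
```

`hello.txt` now contains the two tasks' lines in dependency order —
`greetings` is a plain shell task, `bye` is written in Python and executed
through its declared interpreter:

```
hello Ada
bye Ada
```

and `logs/` holds exactly three files per task:
`greetings.out.log`, `greetings.err.log`, `greetings.params` (and the same
for `bye`), the `.params` file recording the parameter values the task saw.
The same pipeline can be driven from a shell through the installed
`exec/dagrun` script, and `dagrun_main("export-graph")` emits the DAG as
Graphviz DOT. Sub-pipelines are selected with `--from/--after/--until/
--before/--single-task`, and `resume` re-runs only what a previous failed
run did not complete, based on the plain-text state file the run writes.

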