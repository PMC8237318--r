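---
title: "Design of the dagrun workflow engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of the dagrun workflow engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagrun)
```

`dagrun` executes pipelines defined in a single XML file as a directed
acyclic graph of shell-scripted tasks. This vignette documents the model,
the XML dialect, the scheduling semantics, and the design decisions taken
where more than one reasonable behavior existed — together with what the
package's synthetic test pipelines do and do not demonstrate about real
workloads.

## Why XML, and the dialect

Task bodies are arbitrary source code in arbitrary languages. XML's CDATA
sections carry such code without any escaping or whitespace mangling, the
format is parseable everywhere, and an XML Schema gives cheap syntactic
validation; these properties motivated the format choice over JSON (which
must escape newlines and tabs) and YAML (whitespace-sensitive, and
historically loose across parser implementations). The concrete dialect is
fixed by this package and validated against `inst/extdata/pipeline.xsd`:

```
<pipeline version="...">
  <params>
    <param name="threads" global="true" defaultValue="4">CPU threads</param>
  </params>
  <tasks>
    <task id="align" params="genome" after="index" interpreter="..." if="...">
      <![CDATA[bwa mem -t "$threads" "$genome" reads.fq > out.sam]]>
    </task>
    <foreach id="qc" of="list" in="s1,s2" as="sample" after="*align">
      <![CDATA[fastqc "$sample"]]>
    </foreach>
  </tasks>
  <metadata>
    <task-description id="align">Align reads</task-description>
  </metadata>
</pipeline>
```

`params` and `after` attribute values are whitespace- and/or comma-separated
identifier lists. The `global` attribute realizes pipeline-wide parameters;
`defaultValue` is supported as an optional convenience. Sections may appear
in any order; a task without a metadata description simply gets an empty
one. Runners live in a separate file,
`<runners><runner tasks="a b"><![CDATA[...]]></runner></runners>` — note
the attribute is `tasks` (it holds a list) even though it assigns tasks to
one runner.

Parsing guarantees byte fidelity of code bodies: whatever is inside CDATA is
what the task, interpreter (`task_code`), or runner receives, with an
embedded `]]>` handled by the standard two-section split on serialization.
`serialize_pipeline()` inverts `parse_pipeline()` exactly, which the test
suite checks with random printable bodies.

## Validation

`validate_pipeline()` returns issues as data, never as exceptions, ordered
deterministically by task position then code. Errors (duplicate ids,
unknown parameters or dependencies, self-dependencies, cycles, item-variable
collisions) always block execution. The one warning, `param-not-accessible`,
fires when a declared parameter occurs as a whole `$name` or `${name}` token
in a task's code while the task cannot see it; token matching (rather than
substring search) keeps false positives down — `$genome_index` does not
trigger the `genome` warning. `--abort-if-warnings` promotes warnings to a
refusal to start, which is the recommended setting during pipeline
development.

## Scheduling semantics

The engine computes the DAG once, then dispatches reactively. The unit of
scheduling is the *iteration unit*: a plain task is one unit, a foreach task
one unit per item (`id[0]`, `id[1]`, …). The semantics are:

* **Non-binding edge A → B:** every unit of B waits until all units of A
  are done.
* **Binding edge A → \*B:** unit `B[i]` becomes eligible as soon as `A[i]`
  is done. Binding composes index-wise along chains of `*` edges. Both
  endpoints must be foreach tasks, and the two item collections must have
  the same length: mismatches between statically resolvable sources
  (`list`, `range`, `param_values`) are rejected before anything runs,
  while a deferred source (`command`, `files_in_dir`) can only be checked
  when the downstream loop expands — at that point the dependent loop fails
  before any of its units start. This fail-fast choice is deliberate:
  silently pairing mismatched collections would corrupt results.
* **Deferred item resolution:** `command` and `files_in_dir` sources are
  evaluated only when the loop is about to run, so the iteration count can
  depend on the output of earlier tasks (dynamic scheduling). An empty
  collection completes the loop immediately as done.
* **Guards:** a task's `if` command runs under the task's own environment
  just before the task would start; exit 0 runs the task, other ordinary
  statuses skip it (`skipped-by-guard`), and dependents treat a skipped
  task as satisfied. Statuses 126/127 ("not executable"/"not found") fail
  the task instead of skipping — a missing guard binary is a bug, not a
  decision. For a foreach the guard applies once to the whole loop, before
  item resolution.
* **Failure policy:** when a unit fails, no dependent unit starts (they are
  marked aborted, at iteration granularity across binding edges), but
  independent eligible work is drained to completion. This maximizes what a
  later `resume` can reuse. The alternative — cancel everything at first
  failure — was rejected for that reason.
* **Concurrency bound:** at most `max_parallel` units are in flight at any
  instant (default 6, a small fixed value documented in the CLI help).
  Simultaneously eligible units are dispatched in document order of their
  tasks, then by item index; with `max_parallel = 1` this makes runs fully
  deterministic, which the tests rely on.

Sub-pipeline selection (`from`/`after` = inclusive/exclusive
descendants-closure, `until`/`before` = inclusive/exclusive
ancestors-closure, both sides intersected when combined, `single_task`
alone) is computed on the DAG before expansion. On a chain this yields
exactly the documented behavior: `from=t1, until=t10` runs all ten tasks,
`after/before` the eight interior ones. Nodes inside both closures but on no
seed-to-seed path are retained — the simplest rule consistent with the chain
case. When a selection cuts away a dependency of a selected task, the
dependency is assumed satisfied (its outputs presumed present) and a notice
is printed: partial execution is the feature's purpose, and silently
re-adding dependencies would defeat it. Each modifier accepts multiple ids
(closures are unioned per modifier before intersecting).

## Process execution

Every unit runs through a generated POSIX wrapper script that `cd`s to the
working directory, exports the unit's environment (single-quote escaped, so
values round-trip byte-exactly), runs the payload with the configured shell
(`bash` from the search path by default, overridable in `run_settings()` for
testing), captures stdout/stderr to files, and atomically writes the exit
status to a status file. The scheduler spawns wrappers asynchronously with
`system2(wait = FALSE)` and polls status files every few milliseconds; this
plain-files design needs no process-management dependency, and the status
file's write-then-rename makes completion detection race-free. End
timestamps are taken when the scheduler observes completion, so event-log
ordering is consistent with dispatch decisions by construction; timing
assertions in tests use sleeps of tens of milliseconds against this
~4 ms polling granularity.

The three execution routes share the wrapper: direct shell, interpreter
(payload = interpreter text, task code exported as `task_code`), and runner
(payload = runner script, `task_code` and `task_id` exported). A runner is
invoked once per unit, with the item variable bound — matching how a
cluster submission wrapper must see each iteration separately. Runner
configuration problems (unknown tasks, overlapping assignments, unreadable
files) are rejected before any unit runs.

## Logging and resume

With `--logs DIR`, each admitted task maintains exactly three files:
`<task>.out.log`, `<task>.err.log`, `<task>.params` (environment
`name=value` lines, name-sorted for diff stability). Iteration units append
to their task's files in item order — buffered until the loop finishes so
that parallel completion order cannot interleave them. Without `--logs`
nothing is written; `--show-std-outs` mirrors task output to the engine's
streams; `--quiet` silences only the engine's own messages.

The resume state is a plain text file, one completed unit id per line
(`done` and `skipped-by-guard` units), written beside the logs
(`<logdir>/.dagrun-state`, or `.dagrun-state` in the working directory when
logging is off). Resume granularity is the iteration unit, matching the
scheduler's granularity: a half-finished loop resumes at its first
incomplete iteration. `resume` re-validates the state against the current
pipeline and refuses corrupt or mismatched files. No cleanup of a failed
unit's partial outputs is attempted; tasks that are not idempotent in their
outputs should guard against their own leftovers.

## The synthetic pipelines, and what tests do not show

The package generates its own test pipelines in code:
`minimal_pipeline()` (two tasks, one interpreter, the canonical two-line
output file), `foreach_pipeline()` (two list-sourced loops with a binding
edge, per-sample marker files and configurable sleeps for ordering and
overlap assertions), and `random_dag_pipeline()` (n trivial tasks with
random forward edges — acyclic by construction — shipping its edge list as
the oracle for reachability and topological-order checks, deterministic per
seed with the global RNG state restored). Test problem sizes are desk-scale
by design: DAGs up to 25 tasks, 200 randomized runs, sleeps of 20–400 ms.

These fixtures exercise the engine's contracts — ordering, binding,
hygiene, logging, resume — not the behavior of real bioinformatics
workloads: task bodies complete in milliseconds, never contend for memory
or I/O, and runners are stubs rather than real schedulers, so the tests say
nothing about long-haul robustness, cluster queue semantics, or
filesystem-visibility delays on shared storage. The oracles used in tests
(exhaustive DFS reachability, brute-force edge-order checking on event
logs, interval-overlap counting) are implemented independently of the
engine's own igraph-based closures and scheduler bookkeeping.

## Known limitations

* Parallelism is bounded local concurrency; distribution happens only
  through user-supplied runners, whose external effects the engine does not
  supervise beyond their exit status.
* The per-task three-file log contract means iteration outputs are
  concatenated, not separated per item.
* Guard commands and item-source commands run synchronously in the
  scheduler loop; a slow guard delays dispatch.
* The XML dialect is this package's own documented grammar, not a
  compatibility layer for any other engine's files.
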