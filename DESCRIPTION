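Package: dagrun
Title: XML-Defined Shell Pipelines Executed as Dependency Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow execution engine for pipelines defined in a single XML
    file as a set of shell-scripted tasks with declared dependencies. The
    engine computes the directed acyclic graph of task dependencies, runs
    tasks reactively with a bounded number of concurrent subprocesses, expands
    'foreach' loop tasks into per-item iteration units with optional
    iteration-level dependency binding, passes pipeline parameters to task
    scripts as environment variables, supports per-task interpreters and
    execution-time runner scripts (for example cluster submission wrappers),
    writes per-task stdout/stderr/parameter logs, can resume a partially
    completed run from a plain-text state file, selects sub-pipelines with
    from/after/until/before/single-task modifiers, exports the dependency
    graph as Graphviz DOT, and auto-generates a command-line help page from
    the pipeline's parameter and task metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
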