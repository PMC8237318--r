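# Internal helpers shared across modules.

# Shell-safe identifier: letters, digits, underscore, not starting with a digit.
IDENT_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

is_identifier <- function(x) {
  length(x) == 1L && is.character(x) && grepl(IDENT_RE, x)
}

# Single-quote a string for POSIX shells; safe for any byte except NUL.
sh_squote <- function(x) {
  paste0("'", gsub("'", "'\\\\''", x), "'")
}

# Split a whitespace-and/or-comma separated identifier list attribute.
split_id_list <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(character())
  out <- strsplit(trimws(x), "[,[:space:]]+")[[1]]
  out[nzchar(out)]
}

# Escape text for XML element content / attribute values.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# Wrap raw code in CDATA; an embedded "]]>" is split across two sections.
xml_cdata_wrap <- function(code) {
  paste0("<![CDATA[", gsub("]]>", "]]]]><![CDATA[>", code, fixed = TRUE), "]]>")
}

dagrun_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "dagrun_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  ))
}

# Locate the shell used to execute task scripts.  Bash is the documented
# default; an explicit path can be supplied through RunSettings for tests.
find_shell <- function(shell = NULL) {
  if (!is.null(shell) && nzchar(shell)) return(shell)
  p <- Sys.which("bash")
  if (nzchar(p)) return(unname(p))
  "/bin/sh"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a string to a file byte-for-byte (no added trailing newline).
write_raw_text <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nzchar(text)) writeChar(text, con, eos = NULL)
  invisible(path)
}

read_raw_text <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n == 0) return("")
  readChar(path, n, useBytes = TRUE)
}
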