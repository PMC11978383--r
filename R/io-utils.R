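# shared text I/O: gzip auto-detection, stdin/stdout conventions

# read all lines; `path` may be a connection, "-" (stdin) or a file path.
# gzfile() transparently handles plain, gzip and BGZF input.
read_text_lines <- function(path) {
  if (inherits(path, "connection")) return(readLines(path, warn = FALSE))
  stopifnot(is.character(path), length(path) == 1L)
  if (path == "-") return(readLines(file("stdin"), warn = FALSE))
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# write lines; "" or "-" means stdout
write_text_lines <- function(lines, path) {
  if (inherits(path, "connection")) {
    writeLines(lines, path)
  } else if (path %in% c("", "-")) {
    writeLines(lines, stdout())
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

# TRUE when the file starts with the gzip magic bytes
is_gzip_file <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

fmt_num <- function(v) format(v, scientific = FALSE, trim = TRUE)
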