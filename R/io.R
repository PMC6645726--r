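#' Write / read a circuit parameter file
#'
#' Circuits are serialised as a structured key-value text file with blocks
#' `genes`, `maternal`, `R`, `lambda`, `h`, `W`, `E`. Matrices are written
#' row = regulator, column = target, with header rows naming both, and the
#' file carries a mandatory `orientation:` header declaring that convention;
#' a file declaring the transposed orientation is read accordingly. Numbers
#' are written with full double precision, so write-then-read restores every
#' parameter bit-exactly.
#'
#' @param circuit a [gene_circuit()].
#' @param path file path.
#' @param provenance optional character vector prepended as `#` comment
#'   lines.
#' @return `write_circuit()`: `path`, invisibly. `read_circuit()`: a
#'   [gene_circuit()].
#' @export
write_circuit <- function(circuit, path, provenance = NULL) {
  stopifnot(inherits(circuit, "gene_circuit"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    if (!is.null(provenance)) paste0("# ", provenance),
    "format: gapdyn-circuit-1",
    "orientation: rows=regulators cols=targets",
    paste("genes:", paste(circuit$genes, collapse = " ")),
    paste("maternal:", paste(circuit$maternal, collapse = " ")),
    paste("R:", paste(num(circuit$R), collapse = " ")),
    paste("lambda:", paste(num(circuit$lambda), collapse = " ")),
    paste("h:", paste(num(circuit$h), collapse = " ")),
    "W:",
    paste(c(".", circuit$genes), collapse = "\t"),
    vapply(circuit$genes, function(b)
      paste(c(b, num(circuit$W[b, ])), collapse = "\t"), character(1)),
    "E:",
    paste(c(".", circuit$genes), collapse = "\t"),
    if (length(circuit$maternal))
      vapply(circuit$maternal, function(m)
        paste(c(m, num(circuit$E[m, ])), collapse = "\t"), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  fail <- function(i, msg)
    stop(sprintf("%s (line %d of %s)", msg, lineno[i], path), call. = FALSE)

  field <- function(key, required = TRUE) {
    i <- grep(paste0("^", key, ":"), lines)
    if (length(i) != 1L) {
      if (required) stop(sprintf("missing or duplicated `%s:` entry in %s",
                                 key, path), call. = FALSE)
      return(NULL)
    }
    list(i = i, value = trimws(sub(paste0("^", key, ":"), "", lines[i])))
  }

  orient <- field("orientation", required = FALSE)
  if (is.null(orient))
    stop("missing mandatory `orientation:` header in ", path, call. = FALSE)
  transposed <- if (orient$value == "rows=regulators cols=targets") FALSE
    else if (orient$value == "rows=targets cols=regulators") TRUE
    else fail(orient$i, paste0("unrecognised orientation `", orient$value, "`"))

  split_ws <- function(x) strsplit(trimws(x), "\\s+")[[1]]
  genes <- split_ws(field("genes")$value)
  mats <- field("maternal")$value
  mats <- if (nzchar(mats)) split_ws(mats) else character()
  vec <- function(key) {
    f <- field(key)
    v <- suppressWarnings(as.numeric(split_ws(f$value)))
    if (anyNA(v) || length(v) != length(genes))
      fail(f$i, sprintf("block `%s` must hold %d numbers", key, length(genes)))
    v
  }
  R <- vec("R"); lambda <- vec("lambda"); h <- vec("h")

  read_block <- function(key, row_names) {
    i <- grep(paste0("^", key, ":\\s*$"), lines)
    if (length(i) != 1L)
      stop(sprintf("missing matrix block `%s:` in %s", key, path),
           call. = FALSE)
    hdr <- strsplit(lines[i + 1L], "\t")[[1]]
    if (length(hdr) < 2L || hdr[1] != ".")
      fail(i + 1L, sprintf("matrix block `%s` lacks its column header row", key))
    cols <- hdr[-1]
    if (!setequal(cols, genes))
      fail(i + 1L, sprintf("matrix block `%s` column names do not match `genes`", key))
    M <- matrix(NA_real_, length(row_names), length(cols),
                dimnames = list(row_names, cols))
    for (r in seq_along(row_names)) {
      j <- i + 1L + r
      if (j > length(lines)) fail(i, sprintf("matrix block `%s` is truncated", key))
      parts <- strsplit(lines[j], "\t")[[1]]
      if (length(parts) != length(cols) + 1L)
        fail(j, sprintf("matrix block `%s` row has %d fields, expected %d",
                        key, length(parts), length(cols) + 1L))
      if (!parts[1] %in% row_names)
        fail(j, sprintf("matrix block `%s` has unexpected row `%s`", key, parts[1]))
      v <- suppressWarnings(as.numeric(parts[-1]))
      if (anyNA(v)) fail(j, sprintf("non-numeric entry in matrix block `%s`", key))
      M[parts[1], cols] <- v
    }
    M
  }
  # in-file row/col labels follow the declared orientation
  if (!transposed) {
    W <- read_block("W", genes)
    E <- if (length(mats)) read_block("E", mats)
         else matrix(0, 0, length(genes), dimnames = list(NULL, genes))
  } else {
    W <- t(read_block("W", genes))
    E <- if (length(mats)) t(read_block_targets_by_reg("E", mats, genes,
                                                       lines, lineno, path))
         else matrix(0, 0, length(genes), dimnames = list(NULL, genes))
  }
  gene_circuit(genes, mats, R, lambda, h, W[genes, genes, drop = FALSE],
               E[, genes, drop = FALSE])
}

# transposed E block: rows = targets (genes), cols = regulators (maternal)
read_block_targets_by_reg <- function(key, mats, genes, lines, lineno, path) {
  i <- grep(paste0("^", key, ":\\s*$"), lines)
  if (length(i) != 1L)
    stop(sprintf("missing matrix block `%s:` in %s", key, path), call. = FALSE)
  hdr <- strsplit(lines[i + 1L], "\t")[[1]]
  cols <- hdr[-1]
  if (!setequal(cols, mats))
    stop(sprintf("matrix block `%s` column names do not match `maternal` (line %d of %s)",
                 key, lineno[i + 1L], path), call. = FALSE)
  M <- matrix(NA_real_, length(genes), length(cols),
              dimnames = list(genes, cols))
  for (r in seq_along(genes)) {
    parts <- strsplit(lines[i + 1L + r], "\t")[[1]]
    M[parts[1], cols] <- as.numeric(parts[-1])
  }
  M
}

#' Write / read expression tables
#'
#' Expression datasets are exchanged as tab-delimited text with `#` comment
#' headers and columns `position`, `time_class`, `gene`, `concentration`
#' (plus `weight` and any extra columns, which are preserved). Reading
#' validates the column set, non-negative concentrations, and key
#' uniqueness.
#'
#' @param ds an [expression_dataset()] (or compatible data frame).
#' @param path file path.
#' @param provenance optional `#` comment header lines.
#' @return `write_expression_table()`: `path`, invisibly;
#'   `read_expression_table()`: an [expression_dataset()].
#' @export
write_expression_table <- function(ds, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  df <- as.data.frame(ds)
  num_cols <- vapply(df, is.numeric, logical(1))
  df[num_cols] <- lapply(df[num_cols], function(x) sprintf("%.17g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("position", "time_class", "gene", "concentration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("expression table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  expression_dataset(df)
}

#' Write / read maternal profile tables
#'
#' Long-format tab-delimited text with columns `position`, `time_min`,
#' `gene`, `concentration` covering a full position-by-time grid.
#'
#' @param profiles a [maternal_profiles()] object.
#' @param path file path.
#' @param provenance optional `#` comment header lines.
#' @return `write_maternal_table()`: `path`, invisibly;
#'   `read_maternal_table()`: a [maternal_profiles()] object.
#' @export
write_maternal_table <- function(profiles, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  df <- as.data.frame(profiles)
  num_cols <- vapply(df, is.numeric, logical(1))
  df[num_cols] <- lapply(df[num_cols], function(x) sprintf("%.17g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_maternal_table
#' @export
read_maternal_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  maternal_profiles(df)
}

#' Write trajectories as a long table
#'
#' Columns `position`, `time_min`, `time_class`, `gene`, `concentration`.
#'
#' @param trajectories a [trajectory()] or list of them.
#' @param path file path.
#' @param provenance optional `#` comment header lines.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, provenance = NULL) {
  if (inherits(trajectories, "trajectory"))
    trajectories <- list(trajectories)
  df <- do.call(rbind, lapply(trajectories, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  num_cols <- vapply(df, is.numeric, logical(1))
  df[num_cols] <- lapply(df[num_cols], function(x) sprintf("%.17g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Provenance header lines recorded in every CLI output file.
provenance_lines <- function(command, seed = NULL) {
  c(paste("gapdyn", as.character(utils::packageVersion("gapdyn"))),
    paste("command:", command),
    if (!is.null(seed)) paste("seed:", seed))
}
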