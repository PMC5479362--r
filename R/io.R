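#' Read a mixed dataset from CSV plus metadata
#'
#' The data file must have a header row, one row per subject and one column
#' per variable; the metadata file (CSV with columns `variable,type` or a
#' JSON object mapping names to types) flags each column discrete or
#' continuous.  Cells equal to the missing sentinel (or empty) become `NA`.
#'
#' @param csv_path path to the data CSV.
#' @param meta_path path to the metadata CSV/JSON; `NULL` treats every
#'   column as continuous.
#' @param missing_sentinel strings read as missing (empty cells always are).
#' @return a [mixed_data()].
#' @examples
#' d <- read_dataset(
#'   system.file("extdata", "waste_incinerator_sample.csv", package = "causalmix"),
#'   system.file("extdata", "waste_incinerator_meta.csv", package = "causalmix"))
#' print(d)
#' @export
read_dataset <- function(csv_path, meta_path = NULL, missing_sentinel = "NA") {
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        na.strings = c(missing_sentinel, ""))
  if (anyDuplicated(names(df))) stop("duplicate column names in ", csv_path)
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad)) {
    stop("unparseable (non-numeric) cells in column(s): ", paste(bad, collapse = ", "))
  }
  types <- rep("continuous", ncol(df))
  names(types) <- names(df)
  if (!is.null(meta_path)) {
    meta <- read_metadata(meta_path)
    missing_meta <- setdiff(names(df), names(meta))
    if (length(missing_meta)) {
      stop("metadata does not cover column(s): ", paste(missing_meta, collapse = ", "))
    }
    unknown <- setdiff(names(meta), names(df))
    if (length(unknown)) {
      stop("metadata names unknown column(s): ", paste(unknown, collapse = ", "))
    }
    types[names(meta)] <- meta
  }
  mixed_data(as.matrix(df), types)
}

read_metadata <- function(path) {
  if (grepl("[.]json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) stop("jsonlite required for JSON metadata")
    m <- unlist(jsonlite::read_json(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("variable", "type") %in% names(df))) {
      stop("metadata CSV needs columns 'variable' and 'type'")
    }
    m <- stats::setNames(df$type, df$variable)
  }
  ok <- m %in% c("discrete", "continuous")
  if (!all(ok)) stop("metadata types must be 'discrete' or 'continuous'")
  m
}

#' Write a mixed dataset (values + metadata) to CSV
#'
#' @param data a [mixed_data()].
#' @param csv_path,meta_path output paths (metadata skipped when `NULL`).
#' @param missing_sentinel string written for missing cells.
#' @return `csv_path`, invisibly.
#' @export
write_dataset <- function(data, csv_path, meta_path = NULL, missing_sentinel = "NA") {
  utils::write.csv(as.data.frame(data$values), csv_path, row.names = FALSE,
                   na = missing_sentinel)
  if (!is.null(meta_path)) {
    utils::write.csv(data.frame(variable = names(data$types), type = data$types),
                     meta_path, row.names = FALSE)
  }
  invisible(csv_path)
}

#' Write / read a PAG as an edge-list text file
#'
#' One line per edge, `X <mark>-<mark> Y [pct%]` with the endpoint tokens
#' `-` (tail), `o` (circle) and `<`/`>` (arrowhead), e.g. `A o-> B 73%`.
#' Nodes are declared up front so isolated variables survive the round trip.
#'
#' @param p a [pag()] (its `reliability` attribute, if any, is written as
#'   percentages).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pag <- function(p, path) {
  e <- pag_edge_df(p)
  rel <- attr(p, "reliability")
  lines <- c(paste("nodes:", paste(p$nodes, collapse = " ")))
  if (nrow(e)) {
    lab <- paste(e$x, edge_token(e$mark_x, e$mark_y), e$y)
    if (!is.null(rel)) {
      r <- rel[paste(pmin(e$x, e$y), pmax(e$x, e$y))]
      lab <- ifelse(is.na(r), lab, paste0(lab, " ", round(100 * r), "%"))
    }
    lines <- c(lines, lab)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pag
#' @export
read_pag <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!grepl("^nodes:", lines[1])) stop("line 1: expected a 'nodes:' declaration")
  nodes <- strsplit(sub("^nodes:\\s*", "", lines[1]), "\\s+")[[1]]
  p <- pag(nodes)
  rel <- numeric(0)
  mark_of <- c("o" = "circle", "<" = "arrow", ">" = "arrow", "-" = "tail")
  for (ln in seq_along(lines)[-1]) {
    parts <- strsplit(lines[ln], "\\s+")[[1]]
    if (length(parts) < 3) stop("line ", ln, ": malformed edge line")
    tok <- parts[2]
    if (!grepl("^[o<-]-[o>-]$", tok)) stop("line ", ln, ": malformed mark token '", tok, "'")
    x <- parts[1]; y <- parts[3]
    if (!all(c(x, y) %in% nodes)) stop("line ", ln, ": undeclared node")
    p <- pag_set_edge(p, x, y,
                      mark_x = mark_of[[substr(tok, 1, 1)]],
                      mark_y = mark_of[[substr(tok, 3, 3)]])
    if (length(parts) >= 4 && grepl("%$", parts[4])) {
      rel[paste(min(x, y), max(x, y))] <- as.numeric(sub("%$", "", parts[4])) / 100
    }
  }
  if (length(rel)) attr(p, "reliability") <- rel
  p
}

#' Export a PAG to Graphviz DOT
#'
#' Endpoint marks map to Graphviz arrow types (`none` for tails, `normal`
#' for arrowheads, `odot` for circles).
#'
#' @param p a [pag()].
#' @param path optional output file; otherwise the DOT source is returned.
#' @return the DOT source, invisibly when written to a file.
#' @export
pag_to_dot <- function(p, path = NULL) {
  e <- pag_edge_df(p)
  arrow <- c("none", "odot", "normal", "none")
  body <- c(paste0("  \"", p$nodes, "\";"))
  if (nrow(e)) {
    rel <- attr(p, "reliability")
    lab <- if (is.null(rel)) "" else {
      r <- rel[paste(pmin(e$x, e$y), pmax(e$x, e$y))]
      ifelse(is.na(r), "", paste0(", label=\"", round(100 * r), "%\""))
    }
    body <- c(body, paste0(
      "  \"", e$x, "\" -> \"", e$y, "\" [dir=both, arrowtail=", arrow[e$mark_x + 1],
      ", arrowhead=", arrow[e$mark_y + 1], lab, "];"))
  }
  src <- c("digraph pag {", "  edge [dir=both];", body, "}")
  if (is.null(path)) return(paste(src, collapse = "\n"))
  writeLines(src, path)
  invisible(paste(src, collapse = "\n"))
}

#' Write / read a correlation matrix as CSV with a JSON sidecar
#'
#' The matrix goes to CSV with variable names as header and first column;
#' the estimator tag and effective sample size go to `<path>.json`.
#'
#' @param corr a [correlation_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(corr, path) {
  stopifnot(inherits(corr, "cmx_corr"))
  utils::write.csv(corr$matrix, path, row.names = TRUE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(estimator = corr$estimator,
                              sample_size = corr$sample_size),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  meta <- list(estimator = "unknown", sample_size = NA_real_)
  side <- paste0(path, ".json")
  if (file.exists(side) && requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- jsonlite::read_json(side)
  }
  correlation_matrix(m, as.numeric(meta$sample_size), meta$estimator)
}

#' Read background-knowledge rules
#'
#' One rule per line: `forbid X -> Y` (X cannot cause Y) or
#' `forbid * -> Y` (nothing can cause Y).  Blank lines and `#` comments are
#' skipped.
#'
#' @param path rules file.
#' @param nodes optional node universe for validation/expansion.
#' @return a [forbid_cause()] object, or `NULL` if the file has no rules.
#' @export
read_background <- function(path, nodes = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) return(NULL)
  m <- regmatches(lines, regexec("^forbid\\s+(\\S+)\\s*->\\s*(\\S+)$", lines))
  bad <- which(vapply(m, length, integer(1)) != 3)
  if (length(bad)) stop("malformed background rule on line ", bad[1], ": ", lines[bad[1]])
  forbid_cause(vapply(m, `[`, "", 2), vapply(m, `[`, "", 3), nodes)
}
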