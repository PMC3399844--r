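# Readers/writers for expression matrices (TSV and GCT 1.2), model and
# pattern descriptions (JSON), search output (TSV) and run manifests.

#' Read a tab-delimited expression matrix
#'
#' Reads a probesets x samples log2 matrix. The TSV dialect has probeset ids
#' in the first column and a header row of sample ids. The GCT 1.2 dialect
#' (`#1.2` first line, a dimensions line, then a header with `Name` and
#' `Description` columns) is accepted and parsed to the same matrix; the
#' description column is dropped. Values are preserved exactly; ragged rows,
#' non-numeric cells and duplicate probeset ids are rejected with the
#' offending line number or id.
#'
#' @param path Input file.
#' @param dialect `"auto"` (default, sniffs the `#1.2` magic), `"tsv"` or
#'   `"gct"`.
#' @return Numeric matrix with probeset rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, dialect = c("auto", "tsv", "gct")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  if (dialect == "auto")
    dialect <- if (startsWith(lines[1], "#1.2")) "gct" else "tsv"
  offset <- 0L
  if (dialect == "gct") {
    if (length(lines) < 3) stop("truncated GCT file: ", path)
    offset <- 2L                      # "#1.2" and the dimensions line
    lines <- lines[-(1:2)]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  has_desc <- dialect == "gct" && length(header) >= 2 &&
    header[2] == "Description"
  drop_cols <- if (has_desc) 1:2 else 1
  sample_ids <- header[-drop_cols]
  if (!length(sample_ids)) stop("no sample columns in ", path)
  n_fields <- length(header)
  body <- fields[-1]
  ids <- character(length(body))
  vals <- matrix(NA_real_, length(body), length(sample_ids))
  for (i in seq_along(body)) {
    f <- body[[i]]
    line_no <- i + 1L + offset
    if (length(f) != n_fields)
      stop("line ", line_no, ": expected ", n_fields, " fields, found ",
           length(f))
    ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-drop_cols]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("line ", line_no, ": non-numeric value \"",
           f[-drop_cols][bad], "\" in column ", sample_ids[bad])
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(ids))
    stop("duplicate probeset id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dimnames(vals) <- list(ids, sample_ids)
  vals
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' @param mat Numeric matrix with probeset rownames and sample colnames.
#' @param path Output file.
#' @param dialect `"tsv"` (default) or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  # %.17g round-trips doubles exactly
  body <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  if (dialect == "tsv") {
    lines <- c(paste(c("probeset_id", colnames(mat)), collapse = "\t"),
               paste(rownames(mat), body, sep = "\t"))
  } else {
    lines <- c("#1.2",
               paste(nrow(mat), ncol(mat), sep = "\t"),
               paste(c("Name", "Description", colnames(mat)), collapse = "\t"),
               paste(rownames(mat), "na", body, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a model description file
#'
#' JSON naming the model, its populations (each with a name, the sample
#' column ids holding its replicates, and optional metadata), and optional
#' 2-D layout coordinates.
#'
#' @param path JSON file.
#' @return List with `name`, `populations` (list of [population()] objects)
#'   and `layout` (data.frame or NULL).
#' @export
read_model_spec <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$name) || is.null(obj$populations))
    stop("model spec needs 'name' and 'populations'")
  pops <- lapply(obj$populations, function(p) {
    if (is.null(p$name) || is.null(p$samples))
      stop("every population needs 'name' and 'samples'")
    population(p$name, unlist(p$samples),
               metadata = p$metadata %||% list())
  })
  layout <- NULL
  if (!is.null(obj$layout)) {
    layout <- do.call(rbind, lapply(obj$layout, function(l)
      data.frame(population = l$population, x = l$x, y = l$y,
                 stringsAsFactors = FALSE)))
  }
  list(name = obj$name, populations = pops, layout = layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pattern file
#'
#' JSON object mapping population names to `"high"`, `"low"` or `"any"`.
#'
#' @param path JSON file.
#' @return Named character vector.
#' @export
read_pattern <- function(path) {
  obj <- jsonlite::read_json(path)
  p <- vapply(obj, as.character, character(1))
  if (!all(tolower(p) %in% c("high", "low", "any")))
    stop("pattern values must be high, low or any")
  p
}

#' Write pattern-search results as TSV
#'
#' Columns: probeset id, trimmed dynamic range, then one call column per
#' population, in the model's population order.
#'
#' @param results Data.frame from [pattern_search()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_search_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an activity profile as TSV
#'
#' @param profile An `"activity_profile"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_activity_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest next to an output artifact
#'
#' Records the configuration, seed and md5 of every input file, so any
#' artifact can be reproduced from its manifest.
#'
#' @param path Manifest path (conventionally `<output>.manifest.json`).
#' @param config Named list of parameters.
#' @param inputs Character vector of input file paths (hashed).
#' @param outputs Character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config = list(), inputs = character(0),
                               outputs = character(0)) {
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs)
    stats::setNames(as.list(unname(h)), basename(inputs))
  } else list()
  obj <- list(tool = "metaref",
              version = as.character(utils::packageVersion("metaref")),
              config = config,
              input_md5 = hashes,
              outputs = as.list(basename(outputs)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
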