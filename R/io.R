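## Delimited-text reading, TSV/JSON export and run manifests shared by the
## command-line entry points.

.detect_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Read a numeric data matrix from delimited text
#'
#' Comma- or tab-separated values with an optional header row (detected
#' automatically: a first row with any non-numeric cell is treated as a
#' header) and an optional label column selected by name or index, which is
#' extracted and excluded from the matrix. Decimal points only; every other
#' cell must parse as a number.
#'
#' @param path input file.
#' @param labelColumn column name or index holding known labels, or
#'   \code{NULL}.
#' @param sep field separator; \code{NULL} auto-detects comma vs tab from
#'   the first line.
#' @return List with \code{data} (numeric matrix) and \code{labels} (the
#'   extracted column, or \code{NULL}).
#' @export
readDataMatrix <- function(path, labelColumn = NULL, sep = NULL) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- .detect_sep(first)
  probe <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- anyNA(suppressWarnings(as.numeric(probe)))
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character",
                          check.names = FALSE, comment.char = "")
  if (!header) names(df) <- paste0("V", seq_along(df))
  labels <- NULL
  if (!is.null(labelColumn)) {
    idx <- if (is.numeric(labelColumn)) as.integer(labelColumn)
           else match(labelColumn, names(df))
    if (is.na(idx) || idx < 1L || idx > ncol(df))
      stop(sprintf("label column '%s' not found; available: %s",
                   labelColumn, paste(names(df), collapse = ", ")),
           call. = FALSE)
    labels <- df[[idx]]
    df <- df[, -idx, drop = FALSE]
  }
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf(
        "non-numeric value '%s' at row %d, column '%s'",
        df[[j]][bad], bad + header, names(df)[j]), call. = FALSE)
    }
    mat[, j] <- v
  }
  list(data = mat, labels = labels)
}

#' Read a SeCo configuration from YAML or JSON
#'
#' Recognised fields: \code{n_total}, \code{fraction_f}, \code{k_range}
#' (scalar, vector, or \code{[from, to]} pair), \code{master_seed}, plus
#' the pass-through fields \code{input} and \code{label_column}.
#'
#' @param path configuration file; format chosen by extension
#'   (\code{.json} vs \code{.yaml}/\code{.yml}).
#' @return List with \code{config} (a [SeCoConfig-class]) and the
#'   pass-through fields.
#' @export
readSeCoConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
  kr <- raw$k_range
  if (is.null(kr)) stop("config is missing k_range", call. = FALSE)
  kr <- as.integer(unlist(kr))
  if (length(kr) == 2L && kr[2] > kr[1] + 1L) kr <- seq(kr[1], kr[2])
  cfg <- secoConfig(
    kRange = kr,
    nTotal = if (is.null(raw$n_total)) 500L else raw$n_total,
    fractionF = if (is.null(raw$fraction_f)) 0.10 else raw$fraction_f,
    masterSeed = if (is.null(raw$master_seed)) 0L else raw$master_seed
  )
  list(config = cfg, input = raw$input, labelColumn = raw$label_column)
}

#' Export the coordinate table of a SeCo map as TSV
#'
#' Columns k, run_id, seed, delta_ssq, med_cv at full (17 significant
#' digit) precision, so identical configurations reproduce byte-identical
#' files.
#'
#' @param map a [SeCoMap-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeSeCoMapTSV <- function(map, path) {
  stopifnot(methods::is(map, "SeCoMap"))
  pts <- map@points
  df <- data.frame(
    k = pts$k, run_id = pts$runId, seed = pts$seed,
    delta_ssq = format(pts$deltaSSQ, digits = 17, trim = TRUE),
    med_cv = format(pts$medCV, digits = 17, trim = TRUE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a benchmark result: sorted concordance curve and summary
#'
#' @param results a [BenchmarkResult-class] or list of them.
#' @param curvePath TSV of the sorted per-repetition Cramér's V values (one
#'   column per method/k).
#' @param summaryPath TSV with one row per result: method, k, mean and SD
#'   of accuracy, mean CV, affinity.
#' @return Invisibly, the summary data.frame.
#' @export
writeBenchmarkTSV <- function(results, curvePath, summaryPath) {
  if (methods::is(results, "BenchmarkResult")) results <- list(results)
  curves <- lapply(results, function(r) sort(r@cv))
  names(curves) <- vapply(results,
                          function(r) sprintf("%s_k%d", r@method, r@k), "")
  cdf <- data.frame(rank = seq_along(curves[[1]]),
                    lapply(curves, format, digits = 17, trim = TRUE))
  utils::write.table(cdf, curvePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sdf <- do.call(rbind, lapply(results, function(r) data.frame(
    method = r@method, k = r@k,
    accuracy_mean = mean(r@accuracy),
    accuracy_sd = stats::sd(r@accuracy),
    cv_mean = mean(r@cv),
    affinity = r@affinity,
    n_reps = r@nReps
  )))
  out <- sdf
  for (col in c("accuracy_mean", "accuracy_sd", "cv_mean", "affinity"))
    out[[col]] <- format(sdf[[col]], digits = 17, trim = TRUE)
  utils::write.table(out, summaryPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sdf)
}

#' Write a run manifest alongside outputs
#'
#' Records the configuration echo, input fingerprint (row and column
#' counts, checksum), master seed, package version and a timestamp, so
#' every run's provenance is reconstructible.
#'
#' @param outDir output directory (created if needed).
#' @param config a [SeCoConfig-class] or \code{NULL}.
#' @param fingerprint list describing the input data.
#' @param extra named list merged into the manifest.
#' @return The manifest path, invisibly.
#' @export
writeRunManifest <- function(outDir, config = NULL, fingerprint = NULL,
                             extra = list()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(
    package = "SeCoClust",
    version = as.character(utils::packageVersion("SeCoClust")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (is.null(config)) NULL else list(
      n_total = config@nTotal, fraction_f = config@fractionF,
      k_range = config@kRange, master_seed = config@masterSeed),
    input = fingerprint
  ), extra)
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
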