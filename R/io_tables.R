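# Readers and writers for count tables, label files, models and reports.
# Counts are oriented samples x features throughout ("n samples, m features");
# transposed input surfaces as a label-alignment failure, never silently.

#' Construct a count table
#'
#' A count table holds a nonnegative integer matrix of read counts with
#' samples as rows and features (OTUs, taxa, pathways) as columns.
#'
#' @param counts Numeric matrix of nonnegative integers, samples in rows.
#' @param samples,features Identifier vectors; default to the dimnames.
#' @return An object of class `count_table` with fields `samples`,
#'   `features` and `counts`.
#' @export
count_table <- function(counts, samples = rownames(counts),
                        features = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(counts)))
  if (is.null(features)) features <- paste0("F", seq_len(ncol(counts)))
  samples <- as.character(samples)
  features <- as.character(features)
  if (nrow(counts) < 2L) stop("a count table needs at least 2 samples")
  if (ncol(counts) < 1L) stop("a count table needs at least 1 feature")
  if (length(samples) != nrow(counts) || length(features) != ncol(counts))
    stop("identifier lengths do not match the count matrix")
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(features))
    stop("duplicate feature identifiers: ",
         paste(unique(features[duplicated(features)]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(counts)) + 1
    j <- ((bad[1] - 1) %/% nrow(counts)) + 1
    stop(sprintf("invalid count at sample '%s', feature '%s': %s",
                 samples[i], features[j], format(counts[bad[1]])))
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(samples, features)
  structure(list(samples = samples, features = features, counts = counts),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d features, total reads %s\n",
              length(x$samples), length(x$features),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Construct a set of per-sample class labels
#'
#' @param labels Character vector (or factor) of class labels, one per sample.
#' @param samples Sample identifiers; default `names(labels)`.
#' @param classes Ordered class levels; default first-appearance order.
#' @return An object of class `label_set` with fields `samples`, `labels`
#'   and `classes`.
#' @export
label_set <- function(labels, samples = names(labels), classes = NULL) {
  labels <- as.character(labels)
  if (is.null(samples)) samples <- paste0("S", seq_along(labels))
  samples <- as.character(samples)
  if (length(samples) != length(labels))
    stop("labels and sample identifiers differ in length")
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in labels: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (is.null(classes)) classes <- unique(labels)
  classes <- as.character(classes)
  if (!all(labels %in% classes))
    stop("labels outside the class set: ",
         paste(setdiff(unique(labels), classes), collapse = ", "))
  structure(list(samples = samples, labels = labels, classes = classes),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$classes))
  cat(sprintf("label_set: %d samples, %d classes (%s)\n", length(x$labels),
              length(x$classes),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a feature-count table
#'
#' Two plain-text dialects are supported: `plain_tsv` (header row of feature
#' names, first column the sample identifier) and `mothur_shared` (the mothur
#' `.shared` format with `label`, `Group` and `numOtus` columns followed by
#' one column per OTU).  For multi-label shared files only the first label
#' block (first distance cutoff) is kept.
#'
#' @param path Path to the file.
#' @param dialect `"plain_tsv"` or `"mothur_shared"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, dialect = c("plain_tsv", "mothur_shared")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "mothur_shared") {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(raw)))
      stop("mothur_shared file must have columns: ",
           paste(need, collapse = ", "))
    raw <- raw[raw$label == raw$label[1], , drop = FALSE]
    samples <- raw$Group
    num_otus <- unique(as.integer(raw$numOtus))
    body <- raw[, setdiff(names(raw), need), drop = FALSE]
    if (length(num_otus) != 1L || num_otus != ncol(body))
      stop(sprintf("numOtus (%s) inconsistent with %d OTU columns",
                   paste(num_otus, collapse = "/"), ncol(body)))
  } else {
    samples <- raw[[1]]
    body <- raw[, -1, drop = FALSE]
  }
  counts <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop(sprintf("invalid count at sample '%s', feature '%s': '%s'",
                   samples[bad[1]], names(body)[j], body[[j]][bad[1]]))
    counts[, j] <- v
  }
  count_table(counts, samples = samples, features = names(body))
}

#' Write a feature-count table
#'
#' @param x A [count_table()].
#' @param path Output path.
#' @param dialect `"plain_tsv"` or `"mothur_shared"`.
#' @param label Distance-cutoff label written in the mothur dialect.
#' @export
write_count_table <- function(x, path, dialect = c("plain_tsv", "mothur_shared"),
                              label = "0.03") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "count_table"))
  counts <- x$counts
  storage.mode(counts) <- "integer"
  if (dialect == "mothur_shared") {
    df <- data.frame(label = label, Group = x$samples,
                     numOtus = length(x$features), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("label", "Group", "numOtus", x$features)
  } else {
    df <- data.frame(sample = x$samples, counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("sample", x$features)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Expects a two-column tab-separated file: sample identifier, class label.
#'
#' @param path Path to the file.
#' @param header Does the file carry a header row?
#' @return A [label_set()] with classes in first-appearance order.
#' @export
read_labels <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = header, sep = "\t",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs two columns: sample, label")
  label_set(df[[2]], samples = df[[1]])
}

#' Write per-sample class labels
#'
#' @param x A [label_set()].
#' @param path Output path.
#' @export
write_labels <- function(x, path) {
  stopifnot(inherits(x, "label_set"))
  write.table(data.frame(x$samples, x$labels), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Align labels to the sample order of a count table
#'
#' Alignment is by sample identifier, not row order.  Any mismatch in either
#' direction is an error naming the offending samples.
#'
#' @param labels A [label_set()].
#' @param counts A [count_table()].
#' @return The [label_set()] reordered to `counts$samples`.
#' @export
align_labels <- function(labels, counts) {
  stopifnot(inherits(labels, "label_set"), inherits(counts, "count_table"))
  only_labels <- setdiff(labels$samples, counts$samples)
  only_counts <- setdiff(counts$samples, labels$samples)
  if (length(only_labels) || length(only_counts))
    stop("label/count sample mismatch; only in labels: [",
         paste(only_labels, collapse = ", "), "]; only in counts: [",
         paste(only_counts, collapse = ", "), "]")
  idx <- match(counts$samples, labels$samples)
  label_set(labels$labels[idx], samples = labels$samples[idx],
            classes = labels$classes)
}

# ---------------------------------------------------------------- reports ----

REPORT_FORMAT <- "metalinprog-report/1"

serialize_report <- function(report) {
  if (inherits(report, "cv_report")) {
    body <- unclass(report)
    type <- "cv_report"
  } else if (inherits(report, "relevance_report")) {
    body <- unclass(report)
    if (length(body$counts)) {
      ord <- order(-body$counts, names(body$counts))
      body$counts <- as.list(body$counts[ord])
    } else {
      body$counts <- stats::setNames(list(), character(0))
    }
    type <- "relevance_report"
  } else if (is.list(report)) {
    body <- report
    type <- "summary"
  } else {
    stop("unsupported report object of class ", paste(class(report), collapse = "/"))
  }
  list(format = REPORT_FORMAT, type = type, body = body)
}

#' Write an evaluation report as JSON
#'
#' Cross-validation reports, relevance reports and plain summary lists are
#' serialized deterministically at full double precision; relevance counts
#' are ordered by count, descending.
#'
#' @param report A `cv_report`, `relevance_report`, or a named list.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  obj <- serialize_report(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return The deserialized report with its original class.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, REPORT_FORMAT))
    stop("not a metalinprog report: ", path)
  body <- obj$body
  if (obj$type == "relevance_report") {
    body$counts <- unlist(body$counts)
    if (is.null(body$counts)) body$counts <- integer(0)
    class(body) <- "relevance_report"
  } else if (obj$type == "cv_report") {
    class(body) <- "cv_report"
  }
  body
}

#' Write a fitted model as JSON
#'
#' @param model An `lpsvm_binary` or `lpsvm_multiclass` model.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("lpsvm_binary", "lpsvm_multiclass")))
  obj <- list(format = "metalinprog-model/1",
              type = class(model)[1], body = unclass(model))
  if (!is.null(obj$body$beta)) obj$body$beta <- unname(obj$body$beta)
  if (!is.null(obj$body$B)) obj$body$B <- unname(obj$body$B)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a model written by [write_model()]
#'
#' @param path Path to the JSON file.
#' @return The fitted model object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "metalinprog-model/1"))
    stop("not a metalinprog model: ", path)
  body <- obj$body
  if (obj$type == "lpsvm_multiclass") {
    B <- body$B
    if (!is.matrix(B))
      B <- matrix(unlist(B), nrow = length(body$feature_ids), byrow = TRUE)
    dimnames(B) <- list(body$feature_ids, utils::head(body$classes, -1))
    body$B <- B
    body$beta0 <- as.numeric(body$beta0)
  } else {
    body$beta <- stats::setNames(as.numeric(body$beta), body$feature_ids)
  }
  structure(body, class = obj$type)
}
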