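#' Read a table of raw Cq values
#'
#' Imports long- or wide-format instrument exports.  Long format needs
#' columns `sample_id`, `target_id` and `cq` (plus optional `group` and
#' `is_reference` columns); wide format has targets in rows and samples in
#' columns (first column = target ids), or the transpose with
#' `transpose = TRUE`.  Cells matching an undetermined token, and numeric
#' values at or above `lod`, become right-censored observations stored at
#' the LOD.  Cells matching a missing token become missing wells (`NA`),
#' excluded from analysis rather than censored.
#'
#' @param path path to a CSV or TSV file (field separator auto-detected
#'   unless `sep` is given), UTF-8.
#' @param format `"long"` or `"wide"`.
#' @param lod limit of detection, in cycles.
#' @param undeterminedTokens character values encoding undetermined wells.
#' @param missingTokens character values encoding missing wells.
#' @param samples optional sample annotation: a data.frame or file path with
#'   columns `sample_id` and `group`.  Required unless the long table has a
#'   `group` column.
#' @param targets optional target annotation: a data.frame or file path with
#'   columns `target_id` and `is_reference` (0/1 or logical).
#' @param transpose for wide format, set `TRUE` when samples are in rows.
#' @param sep field separator; `NULL` picks tab or comma automatically.
#' @return A [CqExperiment-class].
#' @export
readCqTable <- function(path, format = c("long", "wide"), lod,
                        undeterminedTokens = c("Undetermined",
                                               "undetermined", "NA", ""),
                        missingTokens = "missing",
                        samples = NULL, targets = NULL,
                        transpose = FALSE, sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep)) {
    line1 <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(line1, gregexpr("\t", line1))) >=
               lengths(regmatches(line1, gregexpr(",", line1)))) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    fileEncoding = "UTF-8")

  parse_cq <- function(x, where) {
    x <- trimws(x)
    und <- x %in% undeterminedTokens
    mis <- x %in% missingTokens
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!und & !mis & is.na(val))
    if (length(bad))
      stop("non-numeric cq value ", sQuote(x[bad[1]]), " at ",
           where(bad[1]), " (not an undetermined/missing token)")
    val[und] <- lod          # Eq-style convention: observed as the LOD
    val[mis] <- NA_real_
    list(cq = val, censored = und)
  }

  if (format == "long") {
    need <- c("sample_id", "target_id", "cq")
    if (!all(need %in% names(raw)))
      stop("long format requires columns: ", paste(need, collapse = ", "))
    key <- paste(raw$sample_id, raw$target_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop("duplicate (sample, target) pair: (",
           gsub("\r", ", ", d, fixed = TRUE), ")")
    }
    p <- parse_cq(raw$cq, function(i) paste("row", i + 1L))
    tid <- unique(raw$target_id)
    sid <- unique(raw$sample_id)
    cq <- matrix(NA_real_, length(tid), length(sid),
                 dimnames = list(tid, sid))
    cen <- matrix(NA, length(tid), length(sid), dimnames = list(tid, sid))
    idx <- cbind(match(raw$target_id, tid), match(raw$sample_id, sid))
    cq[idx] <- p$cq
    cen[idx] <- p$censored
    groupcol <- if ("group" %in% names(raw))
      vapply(sid, function(s) raw$group[match(s, raw$sample_id)], character(1))
    else NULL
    refcol <- if ("is_reference" %in% names(raw))
      vapply(tid, function(t) raw$is_reference[match(t, raw$target_id)],
             character(1))
    else NULL
  } else {
    if (transpose) {
      sid <- raw[[1]]
      tid <- names(raw)[-1]
      vals <- t(as.matrix(raw[, -1, drop = FALSE]))
    } else {
      tid <- raw[[1]]
      sid <- names(raw)[-1]
      vals <- as.matrix(raw[, -1, drop = FALSE])
    }
    if (anyDuplicated(tid)) stop("duplicate target id: ",
                                 tid[duplicated(tid)][1])
    if (anyDuplicated(sid)) stop("duplicate sample id: ",
                                 sid[duplicated(sid)][1])
    p <- parse_cq(as.vector(vals), function(i)
      paste0("cell (", tid[(i - 1) %% length(tid) + 1], ", ",
             sid[(i - 1) %/% length(tid) + 1], ")"))
    cq <- matrix(p$cq, length(tid), length(sid), dimnames = list(tid, sid))
    cen <- matrix(p$censored, length(tid), length(sid),
                  dimnames = list(tid, sid))
    cen[is.na(cq)] <- NA
    groupcol <- NULL
    refcol <- NULL
  }

  read_ann <- function(x, what) {
    if (is.character(x)) {
      if (!file.exists(x)) stop(what, " annotation file not found: ", x)
      x <- read.delim(x, sep = if (grepl("\\.csv$", x)) "," else "\t",
                      header = TRUE, colClasses = "character")
    }
    x
  }
  if (!is.null(samples)) {
    ann <- read_ann(samples, "sample")
    if (!all(c("sample_id", "group") %in% names(ann)))
      stop("sample annotation requires columns sample_id, group")
    m <- match(sid, ann$sample_id)
    if (anyNA(m))
      stop("unknown group label: no annotation for sample(s) ",
           paste(sid[is.na(m)], collapse = ", "))
    group <- ann$group[m]
  } else if (!is.null(groupcol)) {
    group <- groupcol
  } else stop("group membership required: supply 'samples' annotation or a ",
              "'group' column")
  if (!is.null(targets)) {
    ann <- read_ann(targets, "target")
    if (!all(c("target_id", "is_reference") %in% names(ann)))
      stop("target annotation requires columns target_id, is_reference")
    m <- match(tid, ann$target_id)
    isref <- !is.na(m) & ann$is_reference[m] %in% c("1", "TRUE", "true")
  } else if (!is.null(refcol)) {
    isref <- refcol %in% c("1", "TRUE", "true")
  } else isref <- rep(FALSE, length(tid))

  CqExperiment(cq, group = group, lod = lod, censored = cen,
               isReference = isref)
}

#' Export a CqExperiment as a long-format table
#'
#' Writes one row per non-empty well with columns `sample_id`, `target_id`,
#' `cq` (censored wells written as `Undetermined`, missing wells as
#' `missing`), `group` and `is_reference`.  [readCqTable()] on the result
#' reproduces the dataset exactly.
#'
#' @param object a [CqExperiment-class].
#' @param path output path; tab-separated.
#' @return Invisibly, the data.frame written.
#' @export
writeCqTable <- function(object, path) {
  cq <- cqValues(object)
  cen <- isCensored(object)
  grp <- as.character(groupLabels(object))
  ref <- as.integer(isReference(object))
  df <- data.frame(
    sample_id = rep(colnames(cq), each = nrow(cq)),
    target_id = rep(rownames(cq), ncol(cq)),
    cq = ifelse(is.na(as.vector(cq)), "missing",
                ifelse(as.vector(cen), "Undetermined",
                       format(as.vector(cq), digits = 15, trim = TRUE,
                              scientific = FALSE))),
    group = rep(grp, each = nrow(cq)),
    is_reference = rep(ref, ncol(cq)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a differential-expression results table
#'
#' Serializes the table produced by [testDE()] or [sequentialTest()] as TSV,
#' preserving numeric values to full double precision so that a write/read
#' cycle is lossless well beyond 10 significant digits.
#'
#' @param result a non-empty data.frame of per-target results.
#' @param path output path.
#' @return Invisibly, `path`.
#' @seealso [readResults()]
#' @export
writeResults <- function(result, path) {
  if (!is.data.frame(result) || nrow(result) == 0L)
    stop("'result' must be a non-empty data.frame")
  out <- result
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    format(x, digits = 17, trim = TRUE, scientific = TRUE))
  status <- try(write.table(out, path, sep = "\t", quote = FALSE,
                            row.names = FALSE, na = "NA"), silent = TRUE)
  if (inherits(status, "try-error"))
    stop("cannot write results to ", path)
  invisible(path)
}

#' Read back a results table written by [writeResults()]
#' @param path path to the TSV.
#' @return A data.frame.
#' @export
readResults <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
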