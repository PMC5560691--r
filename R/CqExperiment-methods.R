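#' Construct a CqExperiment
#'
#' @param cq numeric matrix of quantification cycles, targets in rows and
#'   samples in columns.  Values at or above `lod` are marked censored and
#'   stored at the LOD; `NA` entries are treated as missing wells (excluded
#'   from all analyses), not as undetermined reactions.
#' @param group factor (or coercible) of length `ncol(cq)` with the
#'   experimental group of each sample.
#' @param lod limit of detection, in cycles.
#' @param censored optional logical matrix; by default derived from
#'   `cq >= lod`.  Supplied values are OR-ed with that rule, so an
#'   undetermined well can be flagged even when its numeric value was
#'   already recorded at the LOD.
#' @param isReference optional logical vector flagging reference genes
#'   (length `nrow(cq)`), used by the reference-gene model variant.
#' @param truth optional list of generating parameters (kept in metadata;
#'   used by the simulation machinery to score estimates).
#' @return A [CqExperiment-class] object.
#' @examples
#' m <- matrix(c(24, 31, 28, 25, 33, 40), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' ce <- CqExperiment(m, group = c("A", "B"), lod = 35)
#' censoredFraction(ce)
#' @export
CqExperiment <- function(cq, group, lod, censored = NULL,
                         isReference = NULL, truth = NULL) {
  cq <- as.matrix(cq)
  storage.mode(cq) <- "double"
  if (is.null(rownames(cq))) rownames(cq) <- paste0("target_", seq_len(nrow(cq)))
  if (is.null(colnames(cq))) colnames(cq) <- paste0("sample_", seq_len(ncol(cq)))
  if (length(group) != ncol(cq))
    stop("'group' must have one label per sample (column)")
  group <- factor(group)
  cen <- !is.na(cq) & cq >= lod
  if (!is.null(censored)) {
    censored <- as.matrix(censored)
    if (!identical(dim(censored), dim(cq)))
      stop("'censored' must match the dimensions of 'cq'")
    cen <- cen | (!is.na(censored) & censored)
  }
  cq[cen] <- lod
  cen[is.na(cq)] <- NA
  if (is.null(isReference)) isReference <- rep(FALSE, nrow(cq))
  meta <- list(lod = as.numeric(lod))
  if (!is.null(truth)) meta$truth <- truth
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cq = cq, censored = cen),
    colData = S4Vectors::DataFrame(group = group, row.names = colnames(cq)),
    rowData = S4Vectors::DataFrame(is_reference = as.logical(isReference),
                                   row.names = rownames(cq)),
    metadata = meta)
  new("CqExperiment", se)
}

#' @describeIn CqExperiment The Cq matrix (censored wells at the LOD).
#' @param object a `CqExperiment`.
#' @export
setMethod("cqValues", "CqExperiment", function(object)
  SummarizedExperiment::assay(object, "cq"))

#' @describeIn CqExperiment Logical censoring matrix (`NA` = missing well).
#' @export
setMethod("isCensored", "CqExperiment", function(object)
  SummarizedExperiment::assay(object, "censored"))

#' @describeIn CqExperiment The limit of detection, in cycles.
#' @export
setMethod("lodValue", "CqExperiment", function(object)
  S4Vectors::metadata(object)$lod)

#' @describeIn CqExperiment Per-sample group factor.
#' @export
setMethod("groupLabels", "CqExperiment", function(object)
  SummarizedExperiment::colData(object)$group)

#' @describeIn CqExperiment Logical reference-gene flags per target.
#' @export
setMethod("isReference", "CqExperiment", function(object)
  SummarizedExperiment::rowData(object)$is_reference)

#' @describeIn CqExperiment Fraction of censored wells, overall or split by
#'   target, sample or group.
#' @param by aggregation level for `censoredFraction`.
#' @export
setMethod("censoredFraction", "CqExperiment", function(object,
    by = c("overall", "target", "sample", "group")) {
  by <- match.arg(by)
  cen <- isCensored(object)
  switch(by,
         overall = mean(cen, na.rm = TRUE),
         target = rowMeans(cen, na.rm = TRUE),
         sample = colMeans(cen, na.rm = TRUE),
         group = vapply(split(seq_len(ncol(cen)), groupLabels(object)),
                        function(j) mean(cen[, j, drop = FALSE], na.rm = TRUE),
                        numeric(1)))
})

#' Apply (or tighten) a limit of detection
#'
#' Re-censors a dataset at a new LOD: every well whose stored Cq is at or
#' above `lod`, and every well already censored, becomes censored at the new
#' LOD.  Lowering the LOD therefore never uncensors an observation.
#'
#' @param object a [CqExperiment-class].
#' @param lod the new limit of detection; must not exceed the current one.
#' @return A `CqExperiment` censored at `lod`.
#' @export
censorAtLod <- function(object, lod) {
  if (lod > lodValue(object))
    stop("cannot raise the LOD: censored values above it are unknown")
  cq <- cqValues(object)
  cen <- isCensored(object) | (!is.na(cq) & cq >= lod)
  cq[which(cen)] <- lod
  CqExperiment(cq, group = groupLabels(object), lod = lod, censored = cen,
               isReference = isReference(object),
               truth = S4Vectors::metadata(object)$truth)
}

#' Censor the top fraction of observations
#'
#' Convenience wrapper around [censorAtLod()]: sets the LOD to the empirical
#' (1 - fraction) quantile of the observed Cq values so that approximately
#' `fraction` of the wells become censored (ties at the threshold are all
#' censored, so the realized fraction can slightly exceed the request).
#'
#' @param object a fully observed or partially censored [CqExperiment-class].
#' @param fraction target fraction of censored wells, in (0, 1).
#' @return A `CqExperiment`.
#' @export
censorAtFraction <- function(object, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  v <- cqValues(object)[!is.na(cqValues(object))]
  censorAtLod(object, as.numeric(quantile(v, 1 - fraction)))
}

#' Remove heavily censored targets
#'
#' Drops every target whose overall censoring fraction reaches `threshold`,
#' the common practice when too many data points are undetermined (the
#' default drops targets with 80% or more censored wells).
#'
#' @param object a [CqExperiment-class].
#' @param threshold fraction in (0, 1]; targets with censoring fraction
#'   `>= threshold` are removed.
#' @return A list with elements `data` (the reduced `CqExperiment`) and
#'   `removed` (a data.frame with one row per removed target: its overall
#'   censoring fraction and per-group censored counts).
#' @export
removeHeavilyCensored <- function(object, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  frac <- censoredFraction(object, "target")
  drop <- frac >= threshold
  grp <- groupLabels(object)
  cen <- isCensored(object)
  counts <- sapply(levels(grp), function(g)
    rowSums(cen[, grp == g, drop = FALSE], na.rm = TRUE))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(cen),
                                             dimnames = list(rownames(cen),
                                                             levels(grp)))
  removed <- data.frame(target_id = rownames(object)[drop],
                        fraction = unname(frac[drop]),
                        stringsAsFactors = FALSE)
  for (g in levels(grp))
    removed[[paste0("censored_", g)]] <- unname(counts[drop, g])
  list(data = object[!drop, ], removed = removed)
}
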