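#' End-to-end unified analysis of a Cq table
#'
#' Reads the input, applies the removal rule, fits the unified censored
#' regression, tests each target with a generalized Wald test, adjusts for
#' multiplicity and writes the results table, the normalization factors and
#' a machine-readable JSON metadata file (input hashes, seed, LOD, package
#' version) sufficient to reproduce the run.
#'
#' @param input path to the Cq table (see [readCqTable()]).
#' @param outDir output directory (created if needed).
#' @param lod limit of detection, in cycles.
#' @param samples,targets optional annotation file paths.
#' @param format `"long"` or `"wide"`.
#' @param variant `"global"` or `"reference"`.
#' @param comparison `c(reference_group, comparison_group)`.
#' @param q FDR level (default 0.05).
#' @param removalThreshold censoring fraction at which targets are dropped.
#' @param seed optional RNG seed recorded in the metadata (the fit itself is
#'   deterministic).
#' @return Invisibly, the results data.frame.
#' @export
runFit <- function(input, outDir, lod, samples = NULL, targets = NULL,
                   format = "long", variant = "global", comparison = NULL,
                   q = 0.05, removalThreshold = 0.8, seed = NULL) {
  stopifnot(q > 0, q < 1)
  if (!is.null(seed)) set.seed(seed)
  dat <- readCqTable(input, format = format, lod = lod,
                     samples = samples, targets = targets)
  message(sprintf("read %d targets x %d samples; %.1f%% censored at LOD %g",
                  nrow(dat), ncol(dat),
                  100 * censoredFraction(dat), lod))
  spec <- modelSpec(variant = variant, removalThreshold = removalThreshold)
  fit <- fitUCNR(dat, spec)
  message(sprintf("fit: loglik %.3f, converged %s; %d target(s) removed",
                  fit@loglik, fit@converged, nrow(fit@removed)))
  res <- testDE(fit, comparison = comparison, q = q)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeResults(res, file.path(outDir, "results.tsv"))
  fac <- lmnFactors(fit, absolute = (variant == "reference"))
  write.table(data.frame(sample_id = names(fac), factor = as.numeric(fac)),
              file.path(outDir, "factors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_run_metadata(outDir, input, samples, targets, lod = lod, q = q,
                     seed = seed, variant = variant,
                     removalThreshold = removalThreshold,
                     extra = list(converged = fit@converged,
                                  loglik = fit@loglik,
                                  censored_fraction = censoredFraction(dat),
                                  removed_targets = fit@removed$target_id))
  invisible(res)
}

#' Sequential baseline analyses plus method comparison exports
#'
#' Runs the unified analysis and the requested sequential pipelines on the
#' same input, writing one results table per method, a
#' significant/non-significant concordance table of each baseline against
#' the unified analysis, and a Q-Q export of the paired -log10 p-values.
#'
#' @inheritParams runFit
#' @param methods baselines to run, subset of `c("LOD", "MNV1", "KNN")`.
#' @param k KNN neighbour count.
#' @param test `"t"` or `"wilcoxon"`.
#' @return Invisibly, a named list of result data.frames (including
#'   `UCNR`).
#' @export
runBaselines <- function(input, outDir, lod, samples = NULL, targets = NULL,
                         format = "long", variant = "global",
                         comparison = NULL, q = 0.05,
                         removalThreshold = 0.8,
                         methods = c("LOD", "MNV1", "KNN"), k = 10L,
                         test = "t", seed = NULL) {
  if (!length(methods)) stop("empty method list")
  methods <- match.arg(methods, c("LOD", "MNV1", "KNN"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  dat <- readCqTable(input, format = format, lod = lod,
                     samples = samples, targets = targets)
  spec <- modelSpec(variant = variant, removalThreshold = removalThreshold)
  fit <- fitUCNR(dat, spec)
  ucnr <- testDE(fit, comparison = comparison, q = q)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeResults(ucnr, file.path(outDir, "results_UCNR.tsv"))
  out <- list(UCNR = ucnr)
  qq <- list()
  conc <- list()
  for (meth in methods) {
    res <- baselineDE(dat, method = meth, test = test,
                      comparison = comparison, k = k,
                      removalThreshold = removalThreshold)
    writeResults(res, file.path(outDir, paste0("results_", meth, ".tsv")))
    out[[meth]] <- res
    shared <- intersect(ucnr$target_id, res$target_id)
    pa <- ucnr$p_adj[match(shared, ucnr$target_id)]
    pb <- res$p_adj[match(shared, res$target_id)]
    ct <- concordanceTable(pa, pb, q)
    conc[[meth]] <- data.frame(method = meth,
                               ucnr = rep(rownames(ct), each = 2),
                               baseline = rep(colnames(ct), 2),
                               n = as.vector(t(ct)))
    o <- data.frame(method = meth,
                    neglog10p_ucnr = sort(-log10(ucnr$p_value[
                      match(shared, ucnr$target_id)])),
                    neglog10p_baseline = sort(-log10(res$p_value[
                      match(shared, res$target_id)])))
    qq[[meth]] <- o
  }
  write.table(do.call(rbind, conc), file.path(outDir, "concordance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, qq), file.path(outDir, "qq_pvalues.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_metadata(outDir, input, samples, targets, lod = lod, q = q,
                     seed = seed, variant = variant,
                     removalThreshold = removalThreshold,
                     extra = list(methods = methods, k = k, test = test))
  invisible(out)
}

#' Significant/non-significant concordance of two analyses
#'
#' @param pAdjA,pAdjB adjusted p-values of the same targets under two
#'   methods.
#' @param q FDR level.
#' @return A 2x2 matrix (rows: method A NS/S, columns: method B NS/S).
#' @export
concordanceTable <- function(pAdjA, pAdjB, q = 0.05) {
  sa <- factor(ifelse(!is.na(pAdjA) & pAdjA <= q, "S", "NS"),
               levels = c("NS", "S"))
  sb <- factor(ifelse(!is.na(pAdjB) & pAdjB <= q, "S", "NS"),
               levels = c("NS", "S"))
  table(A = sa, B = sb)
}

write_run_metadata <- function(outDir, input, samples, targets, ...,
                               extra = list()) {
  files <- c(input = input, samples = samples, targets = targets)
  hashes <- as.list(tools::md5sum(files[!vapply(files, is.null,
                                                logical(1))]))
  meta <- c(list(package = "UCNR",
                 version = as.character(packageVersion("UCNR")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 input_md5 = hashes),
            list(...), extra)
  jsonlite::write_json(meta, file.path(outDir, "run_metadata.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(NULL)
}
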