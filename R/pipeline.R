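# End-to-end orchestration: promoters -> scan -> enrichment report, on
# real or synthetic inputs. The numbered scripts under analysis/ are thin
# drivers over these functions.

#' Scan a promoter set and test class enrichment in one call
#'
#' Runs [build_presence()] and [enrichment_report()]; comparisons whose
#' classes are absent from the set are skipped with a message rather than
#' failing the run (a set without a background, say, still yields the
#' Class I vs Class II rows).
#'
#' @param pset A labeled `promoter_set`.
#' @param catalog A `motif_catalog` (default [builtin_catalog()]).
#' @param comparisons List of c(set_A, set_B) class pairs
#'   (default [default_comparisons()]).
#' @return List of class `promoter_analysis`: `scan` (a `motif_scan`) and
#'   `report` (the enrichment data.frame).
#' @export
analyze_promoters <- function(pset, catalog = builtin_catalog(),
                              comparisons = default_comparisons()) {
  stopifnot(inherits(pset, "promoter_set"))
  present_classes <- unique(pset$records$class_label)
  usable <- Filter(function(cmp) all(cmp %in% present_classes), comparisons)
  dropped <- Filter(function(cmp) !all(cmp %in% present_classes), comparisons)
  for (cmp in dropped)
    message("skipping comparison ", cmp[1], " vs ", cmp[2],
            ": class not present in the set")
  if (!length(usable)) stop("no comparison has both classes present")
  scan <- build_presence(pset, catalog)
  report <- enrichment_report(scan, pset, catalog, usable)
  structure(list(scan = scan, report = report), class = "promoter_analysis")
}

#' @export
print.promoter_analysis <- function(x, ...) {
  print(x$scan)
  cat("\nEnrichment report:\n")
  print(x$report, digits = 4)
  invisible(x)
}

#' Simulate a study and analyse it
#'
#' Generates a synthetic study from a design, scans it with the catalog
#' and reports class enrichment — the zero-configuration end-to-end path.
#'
#' @param design A `study_design` (default [study_design()]).
#' @param catalog A `motif_catalog`.
#' @param comparisons Class comparisons to test.
#' @return List of class `synthetic_analysis`: `study`, `scan`, `report`.
#' @export
run_synthetic_analysis <- function(design = study_design(),
                                   catalog = builtin_catalog(),
                                   comparisons = default_comparisons()) {
  study <- generate_study(design, catalog)
  ana <- analyze_promoters(study$promoters, catalog, comparisons)
  structure(list(study = study, scan = ana$scan, report = ana$report),
            class = "synthetic_analysis")
}

#' @export
print.synthetic_analysis <- function(x, ...) {
  print(x$study)
  cat("\nEnrichment report:\n")
  print(x$report, digits = 4)
  invisible(x)
}
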