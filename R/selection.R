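# Criterion-based spheroid selection and summary statistics.
#
# A record is selected iff every bounded interval contains its value
# (inclusive bounds: a spheroid with circularity exactly at a stated minimum
# passes). When a preferred target value is set, the selected set is ranked
# by absolute distance to it (ties broken by ascending label), then capped.

# fixed feature order for reporting the first failed criterion
.reasonOrder <- function(featNames) {
  lead <- intersect(c("area_um2", "circularity"), featNames)
  c(lead, sort(setdiff(featNames, lead)))
}

#' Apply selection criteria to a feature table
#'
#' @param records data.frame of per-object features (e.g. from
#'   [extractFeatures()]).
#' @param criteria a [SelectionCriteria-class].
#' @return a [SelectionReport-class]: `selected` (ordered, capped),
#'   `rejected` (with a `reason` column naming the first failed criterion in
#'   the fixed order area, circularity, then others alphabetically), and a
#'   per-feature mean/sd summary of the selected set.
#' @examples
#' recs <- data.frame(label = 1:3, area_um2 = c(20000, 25000, 30000),
#'                    circularity = 0.9)
#' crit <- selectionCriteria(area_um2 = c(21000, 29000),
#'                           circularity = c(0.815, NA))
#' selected(applyCriteria(recs, crit))$area_um2
#' @export
applyCriteria <- function(records, criteria) {
  stopifnot(is.data.frame(records), is(criteria, "SelectionCriteria"))
  validObject(criteria)
  feats <- names(criteria@intervals)
  unknown <- setdiff(feats, names(records))
  if (length(unknown))
    stop(sprintf("unknown feature(s) %s; known features: %s",
                 paste(sQuote(unknown), collapse = ", "),
                 paste(names(records), collapse = ", ")))
  if (length(criteria@preferredFeature) &&
      !criteria@preferredFeature %in% names(records))
    stop(sprintf("unknown preferred feature '%s'; known features: %s",
                 criteria@preferredFeature,
                 paste(names(records), collapse = ", ")))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  for (f in .reasonOrder(feats)) {
    iv <- criteria@intervals[[f]]
    v <- records[[f]]
    fail <- (!is.na(iv[1]) & v < iv[1]) | (!is.na(iv[2]) & v > iv[2])
    reason[is.na(reason) & fail] <- f
  }
  pass <- is.na(reason)
  sel <- records[pass, , drop = FALSE]
  rej <- records[!pass, , drop = FALSE]
  if (nrow(rej)) rej$reason <- reason[!pass]
  else rej$reason <- character(0)
  # ranking
  if (length(criteria@preferredFeature) && nrow(sel)) {
    d <- abs(sel[[criteria@preferredFeature]] - criteria@preferredValue)
    tie <- if ("label" %in% names(sel)) sel$label else seq_len(nrow(sel))
    sel <- sel[order(d, tie), , drop = FALSE]
  }
  if (length(criteria@maxCount) && nrow(sel) > criteria@maxCount) {
    over <- sel[-seq_len(criteria@maxCount), , drop = FALSE]
    over$reason <- "max_count"
    rej <- rbind(rej, over)
    sel <- sel[seq_len(criteria@maxCount), , drop = FALSE]
  }
  num <- names(sel)[vapply(sel, is.numeric, logical(1))]
  num <- setdiff(num, "label")
  summ <- if (nrow(sel)) data.frame(
    feature = num,
    mean = vapply(num, function(f) mean(sel[[f]]), numeric(1)),
    sd = vapply(num, function(f)
      if (nrow(sel) >= 2) stats::sd(sel[[f]]) else 0, numeric(1)),
    n = nrow(sel), row.names = NULL)
  else data.frame(feature = character(), mean = numeric(), sd = numeric(),
                  n = integer())
  rownames(sel) <- NULL; rownames(rej) <- NULL
  new("SelectionReport", selected = sel, rejected = rej, summary = summ)
}

#' Mean and sample standard deviation of one feature
#'
#' @param records data.frame of features.
#' @param feature feature column name.
#' @return list with `mean`, `sd` (sample sd, n-1 denominator; 0 with
#'   `sdDefined = FALSE` for a single value) and `n`.
#' @examples
#' summarizeFeature(data.frame(a = c(1, 2, 3)), "a")
#' @export
summarizeFeature <- function(records, feature) {
  if (!feature %in% names(records))
    stop(sprintf("unknown feature '%s'", feature))
  v <- records[[feature]]
  if (!length(v)) stop("no records to summarize")
  list(mean = mean(v),
       sd = if (length(v) >= 2) stats::sd(v) else 0,
       sdDefined = length(v) >= 2,
       n = length(v))
}

#' Ratio of two standard deviations
#'
#' Used to compare the spread of a manually selected population against an
#' automatically selected one (e.g. manual-to-automatic area SD ratio).
#' Reported to 3 decimals.
#'
#' @param sdA numerator standard deviation.
#' @param sdB denominator standard deviation (> 0).
#' @return `sdA / sdB`, rounded to 3 decimals.
#' @examples
#' sdRatio(3226.3, 1957.7)  # 1.648
#' @export
sdRatio <- function(sdA, sdB) {
  if (any(sdB <= 0)) stop("'sdB' must be positive")
  round(sdA / sdB, 3)
}
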