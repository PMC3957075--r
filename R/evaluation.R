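#' Score one evaluation point
#'
#' An evaluation point asserts that one FTC category is semantically
#' equivalent to one or more ATC codes (at any level; matching is by code
#' prefix). Over the drug universe — by default the drugs present in both the
#' FTC build and the ATC — it counts:
#' true positives (in the FTC category, direct or indirect, and carrying a
#' matching ATC code), false negatives (matching ATC code but not in the FTC
#' category) and false positives (in the FTC category but no matching code).
#' Drugs outside the universe are never counted, so a drug with no ATC code
#' at all cannot be a false positive.
#'
#' @param point list with `ftc_category_id`, `atc_codes` (prefixes) and
#'   optionally `comment`.
#' @param build an `ftc_build`.
#' @param atc named list from [parse_atc()].
#' @param universe drug ids to score over; default drugs in both resources.
#' @return list with `ftc_category_id`, `tp`, `fp`, `fn`, `n_ftc`, `n_atc`
#'   and the drug id sets `tp_drugs`, `fp_drugs`, `fn_drugs`.
#' @export
evaluate_point <- function(point, build, atc, universe = NULL) {
  cid <- point$ftc_category_id
  if (!(cid %in% build$taxonomy$categories$category_id))
    stop("unknown FTC category in evaluation point: ", cid)
  if (is.null(universe))
    universe <- intersect(build$drugs$drug_id,
                          names(atc)[lengths(atc) > 0])
  m <- build$memberships
  ftc_pos <- intersect(unique(m$drug_id[m$category_id == cid]), universe)
  atc_pos <- universe[vapply(universe, function(d) {
    codes <- atc[[d]]
    if (is.null(codes)) return(FALSE)
    any(vapply(point$atc_codes, function(p) any(startsWith(codes, p)),
               logical(1)))
  }, logical(1))]
  tp <- intersect(ftc_pos, atc_pos)
  list(ftc_category_id = cid,
       tp = length(tp),
       fp = length(setdiff(ftc_pos, atc_pos)),
       fn = length(setdiff(atc_pos, ftc_pos)),
       n_ftc = length(ftc_pos), n_atc = length(atc_pos),
       tp_drugs = sort(tp),
       fp_drugs = sort(setdiff(ftc_pos, atc_pos)),
       fn_drugs = sort(setdiff(atc_pos, ftc_pos)))
}

#' Aggregate per-point confusion counts into an evaluation report
#'
#' Totals are element-wise sums over points (a drug appearing in several
#' points is counted once per point); precision is `tp / (tp + fp)` and
#' recall `tp / (tp + fn)`, both 0 when the denominator is 0. Headline
#' percentages are rounded to the nearest integer; full precision is kept in
#' the report.
#'
#' @param points_results data.frame with columns `tp`, `fp`, `fn`
#'   (one row per point), or a list of [evaluate_point()] results.
#' @param covered_drugs optional count of distinct drugs touched by any
#'   point.
#' @return object of class `ftc_evaluation`: list with `points`, `totals`,
#'   `precision`, `recall`, `precision_pct`, `recall_pct`, `covered_drugs`,
#'   `no_evaluation` flag.
#' @export
aggregate_and_score <- function(points_results, covered_drugs = NA_integer_) {
  if (is.data.frame(points_results)) {
    pts <- points_results
  } else {
    pts <- do.call(rbind, lapply(points_results, function(p)
      data.frame(ftc_category_id = p$ftc_category_id %||% NA_character_,
                 tp = p$tp, fp = p$fp, fn = p$fn,
                 stringsAsFactors = FALSE)))
    if (is.null(pts))
      pts <- data.frame(tp = integer(), fp = integer(), fn = integer())
  }
  totals <- c(tp = sum(pts$tp), fp = sum(pts$fp), fn = sum(pts$fn))
  precision <- if (totals["tp"] + totals["fp"] > 0)
    unname(totals["tp"] / (totals["tp"] + totals["fp"])) else 0
  recall <- if (totals["tp"] + totals["fn"] > 0)
    unname(totals["tp"] / (totals["tp"] + totals["fn"])) else 0
  structure(list(points = pts, totals = totals,
                 precision = precision, recall = recall,
                 precision_pct = round(100 * precision),
                 recall_pct = round(100 * recall),
                 covered_drugs = covered_drugs,
                 no_evaluation = nrow(pts) == 0L),
            class = "ftc_evaluation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ftc_evaluation <- function(x, ...) {
  if (x$no_evaluation) {
    cat("FTC evaluation: no evaluation performed (zero points)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "FTC evaluation over %d point(s): TP=%d FP=%d FN=%d\n",
    nrow(x$points), x$totals["tp"], x$totals["fp"], x$totals["fn"]))
  cat(sprintf("  recall:    %.4f (%d%%)\n", x$recall, x$recall_pct))
  cat(sprintf("  precision: %.4f (%d%%)\n", x$precision, x$precision_pct))
  if (!is.na(x$covered_drugs))
    cat(sprintf("  drugs covered by points: %d\n", x$covered_drugs))
  invisible(x)
}

#' Evaluate an FTC build against ATC gold annotations
#'
#' Runs [evaluate_point()] for every point and aggregates. A point whose FTC
#' category is unknown is reported as an error entry and skipped; the other
#' points are still scored.
#'
#' @param build an `ftc_build`.
#' @param atc named list from [parse_atc()].
#' @param points list from [parse_evaluation_points()].
#' @param universe optional drug universe (default: drugs in both resources).
#' @return an `ftc_evaluation` with an extra `errors` element (named
#'   character vector of per-point failures, possibly empty).
#' @export
evaluate_ftc <- function(build, atc, points, universe = NULL) {
  if (is.null(universe))
    universe <- intersect(build$drugs$drug_id,
                          names(atc)[lengths(atc) > 0])
  results <- list(); errors <- character()
  covered <- character()
  for (p in points) {
    r <- tryCatch(evaluate_point(p, build, atc, universe = universe),
                  error = function(e) e)
    if (inherits(r, "error")) {
      errors[p$ftc_category_id] <- conditionMessage(r)
    } else {
      results[[length(results) + 1L]] <- r
      covered <- union(covered, c(r$tp_drugs, r$fp_drugs, r$fn_drugs))
    }
  }
  rep <- aggregate_and_score(results, covered_drugs = length(covered))
  rep$errors <- errors
  rep$universe_size <- length(universe)
  rep
}
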