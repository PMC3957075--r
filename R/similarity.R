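#' Mode-of-action profiles
#'
#' The MoA profile of a drug is the set of FTC categories it belongs to
#' (direct plus, by default, indirect). Root categories are excluded by
#' default: they are shared by essentially every classified drug and only
#' compress the dynamic range of similarities.
#'
#' @param build an `ftc_build`.
#' @param include_indirect include ancestor-closure memberships
#'   (default `TRUE`).
#' @param include_roots keep the four synthetic roots in profiles
#'   (default `FALSE`).
#' @return named list mapping drug id to a sorted character vector of
#'   category ids; drugs with an empty profile are omitted.
#' @export
moa_profiles <- function(build, include_indirect = TRUE,
                         include_roots = FALSE) {
  m <- build$memberships
  if (!include_indirect) m <- m[m$kind == "direct", , drop = FALSE]
  if (!include_roots) {
    roots <- build$taxonomy$categories$category_id[
      build$taxonomy$categories$is_root]
    m <- m[!(m$category_id %in% roots), , drop = FALSE]
  }
  if (!nrow(m)) return(structure(list(), names = character()))
  lapply(split(m$category_id, m$drug_id), function(x) sort(unique(x)))
}

#' Jaccard similarity of two MoA profiles
#'
#' `|A intersect B| / |A union B|`: 1 exactly when the sets coincide, 0 when
#' they are disjoint. Two empty profiles have no defined similarity; `NA` is
#' returned with a warning so the pair can be excluded from matrices.
#'
#' @param profile_a,profile_b character vectors of category ids.
#' @return a number in `[0, 1]`, or `NA` for two empty profiles.
#' @export
jaccard <- function(profile_a, profile_b) {
  a <- unique(profile_a); b <- unique(profile_b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("Jaccard similarity undefined for two empty profiles",
            call. = FALSE)
    return(NA_real_)
  }
  length(intersect(a, b)) / u
}

#' Pairwise MoA similarity matrix
#'
#' Jaccard similarity between every pair of drugs with a non-empty profile.
#' Row/column order follows the build's drug order restricted to those drugs,
#' so permuting input drugs permutes rows and columns identically without
#' changing any value.
#'
#' @param build an `ftc_build`.
#' @param include_indirect,include_roots passed to [moa_profiles()].
#' @return symmetric numeric matrix with unit diagonal and drug-id dimnames.
#' @export
pairwise_matrix <- function(build, include_indirect = TRUE,
                            include_roots = FALSE) {
  prof <- moa_profiles(build, include_indirect = include_indirect,
                       include_roots = include_roots)
  ids <- intersect(build$drugs$drug_id, names(prof))
  n <- length(ids)
  mat <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(mat)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- jaccard(prof[[ids[i]]], prof[[ids[j]]])
      mat[i, j] <- v
      mat[j, i] <- v
    }
  }
  mat
}

# character length of an ATC code prefix at a classification level (1..5)
ATC_LEVEL_NCHAR <- c(1L, 3L, 4L, 5L, 7L)

#' First-`level` ATC class labels for drugs
#'
#' Truncates each drug's ATC codes to the requested classification level.
#' Drugs whose codes fall into more than one class at that level are labelled
#' `"multiple"`, drugs with no ATC code `"NoCategory"`.
#'
#' @param atc named list from [parse_atc()].
#' @param drug_ids drugs to label.
#' @param level ATC level 1-5 (default 1, i.e. the anatomical main group).
#' @return named character vector of labels.
#' @export
atc_class_labels <- function(atc, drug_ids, level = 1L) {
  stopifnot(level %in% 1:5)
  width <- ATC_LEVEL_NCHAR[level]
  lab <- vapply(drug_ids, function(d) {
    codes <- atc[[d]]
    codes <- codes[nchar(codes) >= width]
    if (is.null(codes) || !length(codes)) return("NoCategory")
    p <- unique(substr(codes, 1L, width))
    if (length(p) > 1L) "multiple" else p
  }, character(1))
  names(lab) <- drug_ids
  lab
}

#' Within-ATC-class permutation test on MoA similarity
#'
#' Tests, per ATC class, whether the mean MoA similarity of drugs sharing the
#' class exceeds what random drug groupings of the same size produce. The
#' null is built by shuffling the drug-to-label assignment `n_perm` times
#' (exchangeability of drugs across labels) and recomputing each class mean;
#' the one-sided p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so p is never exactly 0.
#' The `"multiple"` and `"NoCategory"` pseudo-classes are never tested, and
#' classes with fewer than two drugs are skipped with a warning. Drugs are
#' put in canonical (sorted id) order before permuting, so results do not
#' depend on input ordering.
#'
#' @param matrix symmetric similarity matrix from [pairwise_matrix()].
#' @param atc named list from [parse_atc()].
#' @param level ATC level of the grouping (default 1).
#' @param n_perm number of permutations (default 20000).
#' @param seed integer RNG seed; results are reproducible given the seed.
#' @return data.frame with one row per tested class: `atc_class`, `n_drugs`,
#'   `observed_mean`, `null_mean`, `null_sd`, `p_value`, `n_perm`, `seed`.
#' @export
within_class_permutation_test <- function(matrix, atc, level = 1L,
                                          n_perm = 20000L, seed = 1L) {
  ids <- sort(rownames(matrix))
  mat <- matrix[ids, ids, drop = FALSE]
  labels <- atc_class_labels(atc, ids, level = level)
  testable <- !(labels %in% c("multiple", "NoCategory"))
  sizes <- table(labels[testable])
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    warning("skipping ATC class(es) with < 2 drugs: ",
            paste(small, collapse = ", "), call. = FALSE)
  classes <- names(sizes)[sizes >= 2L]
  empty <- data.frame(atc_class = character(), n_drugs = integer(),
                      observed_mean = double(), null_mean = double(),
                      null_sd = double(), p_value = double(),
                      n_perm = integer(), seed = integer(),
                      stringsAsFactors = FALSE)
  if (!length(classes)) return(empty)

  n <- length(ids)
  offdiag_mean <- function(idx) {
    k <- length(idx)
    (sum(mat[idx, idx]) - sum(diag(mat)[idx])) / (k * (k - 1L))
  }
  pos <- lapply(classes, function(cl) which(labels == cl))
  observed <- vapply(pos, offdiag_mean, double(1))

  nulls <- matrix(NA_real_, n_perm, length(classes))
  with_preserved_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      for (ci in seq_along(classes))
        nulls[b, ci] <- offdiag_mean(perm[pos[[ci]]])
    }
  })
  p <- vapply(seq_along(classes), function(ci)
    (1 + sum(nulls[, ci] >= observed[ci])) / (1 + n_perm), double(1))
  data.frame(atc_class = classes,
             n_drugs = as.integer(sizes[classes]),
             observed_mean = observed,
             null_mean = colMeans(nulls),
             null_sd = apply(nulls, 2, stats::sd),
             p_value = p,
             n_perm = as.integer(n_perm),
             seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
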