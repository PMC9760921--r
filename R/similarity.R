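#' Tanimoto similarity of two gene sets
#'
#' The Tanimoto (Jaccard) coefficient T(a, b) = |a ∩ b| / (|a| + |b| − |a ∩ b|),
#' i.e. the intersection over the union. The result carries the set sizes,
#' the coefficient, and its interpretation band (see [classify_band()]).
#' Two empty sets are defined as identical (T = 1): there is no evidence of
#' any difference between them.
#'
#' @param a,b character vectors (gene id sets; duplicates ignored).
#' @return a `similarity_result` with fields `p_a`, `p_b`, `p_ab`, `t`,
#'   `band`.
#' @examples
#' tanimoto(c("G1", "G2", "G3", "G4"), c("G1", "G2", "G5"))  # t = 0.4
#' @export
tanimoto <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  p_a <- length(a); p_b <- length(b)
  p_ab <- length(intersect(a, b))
  denom <- p_a + p_b - p_ab
  t <- if (denom == 0) 1.0 else p_ab / denom
  structure(list(p_a = p_a, p_b = p_b, p_ab = p_ab, t = t,
                 band = classify_band(t)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "Tanimoto similarity: |a| = %d, |b| = %d, |a ∩ b| = %d, T = %.3f (%s)\n",
    x$p_a, x$p_b, x$p_ab, x$t, x$band))
  invisible(x)
}

#' Interpretation band of a Tanimoto coefficient
#'
#' Convention used throughout the package: T in \[0.70, 1.0\] — the two sets
#' are effectively identical; T in \[0.55, 0.70) — similarity is much
#' weaker; T below 0.55 — the sets differ considerably. The 0.55 boundary
#' itself falls in the "weaker" band.
#'
#' @param t numeric vector of coefficients in \[0, 1\].
#' @return character vector: `"identical"`, `"weaker"` or `"different"`.
#' @examples
#' classify_band(c(0.75, 0.63, 0.40))
#' @export
classify_band <- function(t) {
  if (any(t < 0 | t > 1, na.rm = TRUE))
    stop("validation error: Tanimoto coefficient must lie in [0, 1]")
  ifelse(t >= 0.70, "identical", ifelse(t >= 0.55, "weaker", "different"))
}

#' Exclusive-region decomposition of two or three labeled sets
#'
#' Classifies every element of the union by its exact membership pattern,
#' yielding the counts of the 2^k − 1 exclusive Venn regions (k = 2 or 3).
#' Regions are keyed by their label subset joined with `&`
#' (e.g. `"d1&d3"`). The region counts are disjoint and sum to the union
#' size.
#'
#' @param sets named list of 2 or 3 character vectors with distinct names.
#' @return a `venn_decomposition`: list with `labels` and `region_counts`
#'   (named integer vector), plus a `region_members` attribute.
#' @examples
#' venn(list(A = c(1, 2), B = c(2, 3), C = c(3, 4)))
#' @export
venn <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3)
    stop("unsupported: venn() takes 2 or 3 sets, got ", k)
  labels <- names(sets)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == ""))
    stop("sets must carry distinct non-empty labels")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)

  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(labels, m, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(subsets)), subsets)
  members <- stats::setNames(vector("list", length(subsets)), subsets)
  if (length(universe) > 0) {
    key <- apply(membership, 1, function(row)
      paste(labels[row], collapse = "&"))
    tab <- table(key)
    counts[names(tab)] <- as.integer(tab)
    members <- lapply(stats::setNames(subsets, subsets),
                      function(s) sort(universe[key == s]))
  }
  structure(list(labels = labels, region_counts = counts),
            region_members = members,
            class = "venn_decomposition")
}

#' @export
print.venn_decomposition <- function(x, ...) {
  cat("Venn decomposition of", length(x$labels), "sets (union =",
      sum(x$region_counts), "genes)\n")
  print(x$region_counts)
  invisible(x)
}

#' Inter-donor variability of detection
#'
#' For each donor, the donor-specific genes are those detected in that donor
#' and in no other. The variability statistic is the mean over donors of
#' (donor-specific count) / (total genes detected by the technology, i.e.
#' the union across donors). A value near zero means the donors' detection
#' sets are nearly interchangeable.
#'
#' @param sets_by_donor named list (>= 2 donors) of character vectors.
#' @return a `variability_result`: `per_donor_specific` (named integer
#'   vector), `denominator` (union size), `mean_variability` (fraction).
#' @examples
#' donor_variability(list(A = c(1, 2, 3), B = c(1, 2, 4), C = c(1, 2)))
#' @export
donor_variability <- function(sets_by_donor) {
  if (length(sets_by_donor) < 2)
    stop("at least two donors required")
  sets_by_donor <- lapply(sets_by_donor,
                          function(s) unique(as.character(s)))
  union_all <- unique(unlist(sets_by_donor, use.names = FALSE))
  if (length(union_all) == 0)
    stop("undefined variability: all donor sets are empty")
  specific <- vapply(seq_along(sets_by_donor), function(i) {
    others <- unique(unlist(sets_by_donor[-i], use.names = FALSE))
    length(setdiff(sets_by_donor[[i]], others))
  }, integer(1))
  names(specific) <- names(sets_by_donor)
  structure(
    list(per_donor_specific = specific,
         denominator = length(union_all),
         mean_variability = mean(specific / length(union_all))),
    class = "variability_result"
  )
}

#' @export
print.variability_result <- function(x, ...) {
  cat(sprintf(
    "Inter-donor variability: %.2f%% (specific counts: %s; union = %d)\n",
    100 * x$mean_variability,
    paste(sprintf("%s=%d", names(x$per_donor_specific),
                  x$per_donor_specific), collapse = ", "),
    x$denominator))
  invisible(x)
}
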