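#' Pair platform abundances with qPCR copy numbers for calibration
#'
#' Restricts to genes detected by BOTH platforms — abundance > 0, copies per
#' cell > 0, and (when a Ct is recorded) Ct at or below the detection limit
#' — then log10-transforms both axes. The log–log scale is the one on which
#' a single linear relation between relative abundance and absolute copy
#' number is meaningful across the multi-decade dynamic range of a
#' transcriptome.
#'
#' @param quant a `quant_table` of platform `"illumina"` or `"ont"`.
#' @param qpcr a `quant_table` of platform `"qpcr"` (copies per cell, with
#'   Ct when available).
#' @param ct_limit Ct detection limit (default 40).
#' @return a `calibration_pairs` data.frame with columns `gene_id`,
#'   `log10_abundance`, `log10_copies`; the platform is carried as an
#'   attribute.
#' @export
pair_for_calibration <- function(quant, qpcr, ct_limit = 40) {
  stopifnot(inherits(quant, "quant_table"), inherits(qpcr, "quant_table"))
  if (qpcr$platform != "qpcr")
    stop("second table must be a qPCR table")
  m <- merge(quant$data[, c("gene_id", "abundance")],
             qpcr$data[, c("gene_id", "abundance", "ct")],
             by = "gene_id", suffixes = c("", "_copies"))
  keep <- m$abundance > 0 & m$abundance_copies > 0 &
    (is.na(m$ct) | m$ct <= ct_limit)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3)
    stop("insufficient data: ", nrow(m),
         " gene pair(s) detected by both platforms; need at least 3")
  out <- data.frame(gene_id = m$gene_id,
                    log10_abundance = log10(m$abundance),
                    log10_copies = log10(m$abundance_copies),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "platform") <- quant$platform
  attr(out, "unit") <- quant$unit
  class(out) <- c("calibration_pairs", "data.frame")
  out
}

#' Fit a log–log calibration model converting abundance to copies per cell
#'
#' Ordinary least squares of log10(copies per cell) on log10(abundance).
#' The fit reports slope, intercept, the coefficient of determination R²,
#' and the number of gene pairs n. Conversion of abundances into absolute
#' copy numbers through the model is only considered acceptable when
#' R² > 0.5; below that, the relation is too loose for the regression
#' equation to be used quantitatively, and [convert_abundance()] refuses.
#'
#' @param pairs a `calibration_pairs` object from [pair_for_calibration()],
#'   or any data.frame with columns `log10_abundance`, `log10_copies`.
#' @return a `calibration_fit`: slope, intercept, `r_squared`, `n`,
#'   `platform`, `conversion_acceptable`, and the underlying `lm` fit.
#' @examples
#' pairs <- data.frame(log10_abundance = 0:4 / 2,
#'                     log10_copies = 1 + 2 * (0:4 / 2))
#' fit <- fit_calibration(pairs)
#' coef(fit)                       # intercept 1, slope 2
#' convert_abundance(fit, 10)      # 10^(2*1 + 1) = 1000
#' @export
fit_calibration <- function(pairs) {
  stopifnot(all(c("log10_abundance", "log10_copies") %in% names(pairs)))
  x <- pairs$log10_abundance; y <- pairs$log10_copies
  if (length(x) < 3) stop("insufficient data: need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in calibration pairs")
  if (stats::var(x) == 0)
    stop("degenerate fit: zero variance in log10 abundance")
  if (stats::var(y) == 0)
    stop("degenerate fit: zero variance in log10 copies (R² undefined)")
  fit <- stats::lm(log10_copies ~ log10_abundance, data = pairs)
  # a perfect fit is a legitimate input here (exact-line fixtures);
  # summary.lm's reliability warning does not apply to R² itself
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(platform = attr(pairs, "platform") %||% "unknown",
         unit = attr(pairs, "unit") %||% "abundance",
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n = length(x),
         conversion_acceptable = r2 > 0.5,
         fit = fit),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Calibration (%s): log10(copies/cell) = %.*f * log10(%s) + %.*f\n",
    x$platform, digits, x$slope, x$unit, digits, x$intercept))
  cat(sprintf("  R² = %.*f on n = %d gene pairs; conversion %s\n",
              digits, x$r_squared, x$n,
              if (x$conversion_acceptable) "acceptable (R² > 0.5)"
              else "refused (R² ≤ 0.5)"))
  invisible(x)
}

#' @export
summary.calibration_fit <- function(object, ...) {
  print(object)
  summary(object$fit, ...)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.calibration_fit <- function(object, ...) {
  stats::residuals(object$fit)
}

#' Predict copies per cell from abundance
#'
#' @param object a `calibration_fit`.
#' @param newdata numeric vector of abundances (platform units, > 0), or a
#'   data.frame with a `log10_abundance` column. Omitted: fitted values.
#' @param ... unused.
#' @return numeric vector of copies-per-cell estimates (linear scale).
#' @export
predict.calibration_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(10^stats::fitted(object$fit))
  lx <- if (is.data.frame(newdata)) newdata$log10_abundance
        else {
          if (any(newdata <= 0)) stop("domain error: abundance must be > 0")
          log10(newdata)
        }
  10^(object$slope * lx + object$intercept)
}

#' @export
plot.calibration_fit <- function(x, ...) {
  d <- x$fit$model
  plot(d$log10_abundance, d$log10_copies,
       xlab = paste0("log10 ", x$unit), ylab = "log10 copies per cell",
       main = sprintf("%s calibration (R² = %.2f, n = %d)",
                      x$platform, x$r_squared, x$n), ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' @export
simulate.calibration_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Convert an abundance into copies per cell, enforcing the R² rule
#'
#' Applies the calibration equation 10^(slope · log10(abundance) +
#' intercept) only when the model's R² exceeds 0.5. Otherwise conversion is
#' refused with a classed error (`genecov_conversion_refused`): a loose
#' calibration must not silently produce absolute copy numbers.
#'
#' @param model a `calibration_fit`.
#' @param abundance numeric vector of positive abundances.
#' @return numeric vector of copies-per-cell estimates.
#' @export
convert_abundance <- function(model, abundance) {
  stopifnot(inherits(model, "calibration_fit"))
  if (any(abundance <= 0))
    stop("domain error: abundance must be > 0")
  if (!model$conversion_acceptable)
    stop(structure(
      class = c("genecov_conversion_refused", "error", "condition"),
      list(message = sprintf(
             "conversion refused: R² = %.3f is not greater than 0.5",
             model$r_squared),
           call = sys.call(-1))))
  10^(model$slope * log10(abundance) + model$intercept)
}

#' Serialize / restore a calibration model as JSON
#'
#' Stores the numeric summary (platform, unit, slope, intercept, R², n,
#' acceptability); the underlying `lm` object is not persisted, so a
#' restored model supports prediction and conversion but not residual
#' inspection.
#'
#' @param model a `calibration_fit`.
#' @param path output JSON path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   a `calibration_fit` (without the `lm` component).
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(
    model[c("platform", "unit", "slope", "intercept", "r_squared", "n",
            "conversion_acceptable")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(c(m, list(fit = NULL)), class = "calibration_fit")
}
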