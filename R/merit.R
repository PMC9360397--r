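# Analytical figures of merit: precision (CV%), limits of detection and
# quantification, linearity range and mean recovery, assembled into a
# report shaped like the study's merit-comparison table.

#' Coefficient of variation in percent
#'
#' `CV = SD / mean * 100` over replicate determinations (sample SD,
#' n - 1 denominator). Scale-invariant for positive rescaling.
#'
#' @param replicate_values Numeric vector, n >= 2, non-zero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(replicate_values) {
  if (length(replicate_values) < 2) stop("need at least 2 replicates")
  m <- mean(replicate_values)
  if (m == 0) stop("CV is undefined for zero-mean replicates")
  stats::sd(replicate_values) / m * 100
}

#' Limits of detection and quantification from blank determinations
#'
#' `LOD = 3 * SD(blanks)` and `LOQ = 10 * SD(blanks)` over the predicted
#' concentrations of serum blanks (the convention is ten blanks; other
#' counts are accepted with a warning). Negative blank predictions are
#' legitimate inputs — truncating them would shrink the SD and understate
#' the limits.
#'
#' @param blank_predictions Predicted blank concentrations (g/L), n >= 2.
#' @return List with `lod` and `loq` (g/L); `loq / lod` is exactly 10/3.
#' @export
lod_loq <- function(blank_predictions) {
  n <- length(blank_predictions)
  if (n < 2) stop("need at least 2 blank determinations")
  if (n != 10)
    warning("LOD/LOQ are conventionally computed from 10 blanks; got ", n)
  s <- stats::sd(blank_predictions)
  list(lod = 3 * s, loq = 10 * s)
}

#' Mean recovery in percent
#'
#' Mean of `100 * predicted / reference` over validation pairs. Pairs with
#' reference at or below `min_reference` are excluded: recovery is
#' undefined at zero concentration, and the ratio is meaningless below the
#' quantifiable range (callers assessing a method pass the LOQ here, the
#' usual analytical convention).
#'
#' @param predicted,reference Equal-length vectors (g/L).
#' @param min_reference Exclusion threshold (g/L); default 0 excludes only
#'   blanks.
#' @return Mean recovery in percent.
#' @export
mean_recovery <- function(predicted, reference, min_reference = 0) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  keep <- reference > min_reference
  if (!any(keep)) stop("no reference values above ", min_reference)
  mean(100 * predicted[keep] / reference[keep])
}

#' Assemble a figures-of-merit report
#'
#' One method's row of the merit-comparison table: CV% at each replicate
#' level, LOD, LOQ, linearity range (LOD up to `linearity_high`) and mean
#' recovery. Any missing ingredient leaves its fields `NA` with a message,
#' so a partial report is still emitted.
#'
#' @param method Method label (e.g. `"uv"`, `"red"`, `"pls"`, `"ann"`).
#' @param replicate_predictions Named list, one vector of replicate
#'   predictions (g/L) per concentration level; names are the levels
#'   (conventionally `"0.5"`, `"2.5"`, `"10"` g/L).
#' @param blank_predictions Predicted concentrations of the serum blanks.
#' @param validation_predicted,validation_reference Validation pairs (g/L).
#' @param linearity_high Upper end of the verified linear range (g/L).
#' @return An object of class `merit_report`.
#' @export
merit_report <- function(method,
                         replicate_predictions = NULL,
                         blank_predictions = NULL,
                         validation_predicted = NULL,
                         validation_reference = NULL,
                         linearity_high = 10) {
  cv_by_level <- NULL
  if (is.null(replicate_predictions)) {
    message("merit_report(", method, "): no replicate sets; CV% omitted")
  } else {
    cv_by_level <- vapply(replicate_predictions, cv_percent, numeric(1))
  }
  lod <- loq <- NA_real_
  if (is.null(blank_predictions)) {
    message("merit_report(", method, "): no blanks; LOD/LOQ omitted")
  } else {
    ll <- lod_loq(blank_predictions)
    lod <- ll$lod; loq <- ll$loq
  }
  recovery <- NA_real_
  if (is.null(validation_predicted) || is.null(validation_reference)) {
    message("merit_report(", method, "): no validation pairs; recovery omitted")
  } else {
    # assess recovery at quantifiable levels only: below the LOQ the
    # predicted/reference ratio is noise
    cut <- if (is.finite(loq)) loq else 0
    recovery <- mean_recovery(validation_predicted, validation_reference,
                              min_reference = cut)
  }
  structure(list(method = method, cv_by_level = cv_by_level,
                 lod = lod, loq = loq,
                 linearity_low = lod, linearity_high = linearity_high,
                 mean_recovery = recovery),
            class = "merit_report")
}

#' @export
print.merit_report <- function(x, ...) {
  cat("Figures of merit -", x$method, "\n")
  if (!is.null(x$cv_by_level))
    for (lv in names(x$cv_by_level))
      cat(sprintf("  CV%% at %s g/L: %.2f\n", lv, x$cv_by_level[lv]))
  cat(sprintf("  LOD %.3f g/L, LOQ %.3f g/L\n", x$lod, x$loq))
  cat(sprintf("  linearity %.2f-%.0f g/L, mean recovery %.1f%%\n",
              x$linearity_low, x$linearity_high, x$mean_recovery))
  invisible(x)
}

#' Merit-comparison table for several methods
#'
#' Stacks merit reports into the table layout of the study: one row per
#' figure (CV at each level, LOD, LOQ, linearity, recovery) and one column
#' per method.
#'
#' @param reports List of [merit_report()] objects.
#' @return `data.frame` with a `figure` column and one column per method.
#' @export
merit_table <- function(reports) {
  stopifnot(length(reports) >= 1)
  levels <- names(reports[[1]]$cv_by_level)
  figures <- c(sprintf("CV%% at %s g/L", levels),
               "LOD (g/L)", "LOQ (g/L)", "Linearity (g/L)",
               "Mean recovery (%)")
  out <- data.frame(figure = figures, stringsAsFactors = FALSE)
  for (rep in reports) {
    col <- c(sprintf("%.2f", rep$cv_by_level[levels]),
             sprintf("%.3f", rep$lod), sprintf("%.3f", rep$loq),
             sprintf("%.2f-%.0f", rep$linearity_low, rep$linearity_high),
             sprintf("%.1f", rep$mean_recovery))
    out[[rep$method]] <- col
  }
  out
}

#' Serialize / deserialize a merit report as one CSV row
#'
#' @param report A [merit_report()].
#' @param path CSV file path.
#' @return `write_merit_report` returns `path` invisibly;
#'   `read_merit_report` the restored report.
#' @export
write_merit_report <- function(report, path) {
  cvs <- report$cv_by_level
  df <- data.frame(method = report$method, lod = report$lod,
                   loq = report$loq, linearity_low = report$linearity_low,
                   linearity_high = report$linearity_high,
                   mean_recovery = report$mean_recovery)
  if (!is.null(cvs))
    for (lv in names(cvs)) df[[paste0("cv_", lv)]] <- cvs[[lv]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_merit_report
#' @export
read_merit_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cv_cols <- grep("^cv_", names(df), value = TRUE)
  cvs <- NULL
  if (length(cv_cols)) {
    cvs <- as.numeric(df[1, cv_cols])
    names(cvs) <- sub("^cv_", "", cv_cols)
  }
  structure(list(method = df$method, cv_by_level = cvs,
                 lod = df$lod, loq = df$loq,
                 linearity_low = df$linearity_low,
                 linearity_high = df$linearity_high,
                 mean_recovery = df$mean_recovery),
            class = "merit_report")
}
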