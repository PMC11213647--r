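#' PairedErrors: per-case ground-truth vs sCT values for one metric
#'
#' @slot method sCT method name.
#' @slot metric metric name.
#' @slot truth,sct aligned per-case values.
#' @slot differences sct - truth.
#' @export
setClass("PairedErrors",
  representation(method = "character", metric = "character",
                 truth = "numeric", sct = "numeric",
                 differences = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@truth) != length(object@sct) ||
        length(object@truth) < 2L)
      msg <- c(msg, "need equal-length truth/sct with n >= 2")
    if (any(!is.finite(object@differences)))
      msg <- c(msg, "differences must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname PairedErrors-class
#' @param method,metric,truth,sct see slots.
#' @export
PairedErrors <- function(method, metric, truth, sct) {
  new("PairedErrors", method = method, metric = metric,
      truth = as.numeric(truth), sct = as.numeric(sct),
      differences = as.numeric(sct) - as.numeric(truth))
}

setMethod("show", "PairedErrors", function(object) {
  cat(sprintf("PairedErrors [%s / %s]: n = %d, mean diff %.4g\n",
              object@method, object@metric, length(object@truth),
              mean(object@differences)))
})

#' Summary error statistics for one method and metric
#'
#' Mean and sample SD (n - 1) of the per-case differences; in absolute mode
#' (the convention for absolute-percent risk errors) the mean of |diff| is
#' reported and the SD is taken over |diff| as well.
#'
#' @param errors a \linkS4class{PairedErrors} (or numeric differences).
#' @param absolute summarize |differences| instead of signed differences.
#' @return list(mean, sd, n).
#' @export
errorSummary <- function(errors, absolute = TRUE) {
  d <- if (is(errors, "PairedErrors")) errors@differences else
    as.numeric(errors)
  if (length(d) < 2L) stop("need n >= 2")
  v <- if (absolute) abs(d) else d
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Bland-Altman 95 percent limits of agreement
#'
#' mean difference plus/minus 1.96 times its SD.
#'
#' @param mean,sd summary statistics of the paired differences (sd >= 0).
#' @return c(lower, upper).
#' @export
limitsOfAgreement <- function(mean, sd) {
  stopifnot(sd >= 0)
  c(lower = mean - 1.96 * sd, upper = mean + 1.96 * sd)
}

#' Two-sided paired t-test on a difference vector
#'
#' t = mean / (sd / sqrt(n)) with n - 1 degrees of freedom. Degenerate
#' zero-variance inputs follow the declared contract: p = 1 when the mean
#' is also zero, p = 0 (with a warning) otherwise.
#'
#' @param differences numeric vector, n >= 2.
#' @return two-sided p-value.
#' @export
pairedT <- function(differences) {
  n <- length(differences)
  if (n < 2L) stop("need n >= 2")
  s <- stats::sd(differences)
  m <- mean(differences)
  if (s == 0) {
    if (m == 0) return(1)
    warning("zero variance with nonzero mean; p reported as 0")
    return(0)
  }
  stats::t.test(differences)$p.value
}

#' Shapiro-Wilk normality test
#'
#' Standard W statistic and p-value (Royston's approximation), restricted to
#' the 3 <= n <= 50 range used for per-cohort residual checks. Identical
#' values are rejected as degenerate.
#'
#' @param values numeric vector.
#' @return p-value.
#' @export
shapiroWilk <- function(values) {
  n <- length(values)
  if (n < 3L || n > 50L) stop("shapiroWilk requires 3 <= n <= 50")
  if (stats::sd(values) == 0) stop("degenerate sample: all values identical")
  stats::shapiro.test(values)$p.value
}

#' Assemble the per-method / per-metric comparison report
#'
#' Pure function of its inputs: writes one CSV per metric (per-case truth,
#' sCT value and difference for every method), a JSON summary with the six
#' summary fields per method and metric (mean absolute error, SD, limits of
#' agreement, paired-t p, Shapiro-Wilk p), and one box-plot figure of
#' errors per metric. Missing methods produce explicit gaps. The number of
#' significance tests performed is recorded in the summary (no
#' multiple-testing correction is applied).
#'
#' @param pairedList list of \linkS4class{PairedErrors}.
#' @param outDir output directory (created if needed).
#' @param figures write box-plot PNGs (default TRUE).
#' @return invisibly, the summary list.
#' @export
buildReport <- function(pairedList, outDir, figures = TRUE) {
  if (!length(pairedList)) stop("need >= 1 method/metric result")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  metrics <- unique(vapply(pairedList, function(p) p@metric, character(1)))
  methods <- unique(vapply(pairedList, function(p) p@method, character(1)))
  summary <- list()
  nTests <- 0L
  for (met in metrics) {
    sel <- Filter(function(p) p@metric == met, pairedList)
    perCase <- NULL
    for (p in sel) {
      df <- data.frame(case = seq_along(p@truth), method = p@method,
                       truth = p@truth, sct = p@sct, diff = p@differences)
      perCase <- rbind(perCase, df)
    }
    write.csv(perCase, file.path(outDir, paste0("metric_", met, ".csv")),
              row.names = FALSE)
    msum <- list()
    for (meth in methods) {
      p <- Filter(function(q) q@method == meth, sel)
      if (!length(p)) { msum[[meth]] <- "missing"; next }
      p <- p[[1]]
      es <- errorSummary(p, absolute = TRUE)
      loa <- limitsOfAgreement(mean(p@differences),
                               stats::sd(p@differences))
      pval <- pairedT(p@differences)
      normp <- tryCatch(shapiroWilk(p@differences), error = function(e) NA)
      nTests <- nTests + 1L
      msum[[meth]] <- list(mean_abs_error = es$mean, sd_abs_error = es$sd,
                           loa_lower = unname(loa[1]),
                           loa_upper = unname(loa[2]),
                           p_value = pval, normality_p = normp)
    }
    summary[[met]] <- msum
    if (figures) {
      grDevices::png(file.path(outDir, paste0("errors_", met, ".png")),
                     width = 700, height = 450)
      graphics::boxplot(diff ~ method, data = perCase,
                        ylab = paste("error in", met), xlab = "sCT method")
      graphics::abline(h = 0, lty = 2)
      grDevices::dev.off()
    }
  }
  summary$n_significance_tests <- nTests
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
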