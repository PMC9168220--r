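#' @export
print.sca <- function(x, ...) {
  cat("Structural covariance network contrast analysis\n")
  cat(sprintf("  subcases: %d (%d same-property, %d cross-property)\n",
              nrow(x$subcases), sum(x$subcases$type == "same"),
              sum(x$subcases$type == "cross")))
  cat(sprintf("  density grid: %.2f..%.2f (%d points)\n",
              min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("  FDR scope: %s; tiers: q < %g / q < %g\n",
              x$fdr_scope, x$alpha1, x$alpha2))
  for (nm in names(x$contrasts)) {
    cf <- x$contrasts[[nm]]
    nperm <- nrow(cf$null[[1L]])
    nsig1 <- sum(unlist(cf$q) < x$alpha1)
    nsig2 <- sum(unlist(cf$q) < x$alpha2)
    cat(sprintf("  %s: %d permutations; %d tests; %d at q < %g (%d at q < %g)\n",
                nm, nperm, length(unlist(cf$p)), nsig1, x$alpha1,
                nsig2, x$alpha2))
    if (cf$n_regenerated > 0L)
      cat(sprintf("    (%d density-infeasible shuffles redrawn)\n",
                  cf$n_regenerated))
  }
  invisible(x)
}

#' Summarize a fitted analysis as a significance table
#'
#' @param object An `sca` fit.
#' @param significant_only Return only rows with `q < alpha1`.
#' @param ... Unused.
#' @return data.frame of class `sca_report` (see [significance_report()]),
#'   sorted by q.
#' @export
summary.sca <- function(object, significant_only = FALSE, ...) {
  rep <- significance_report(object)
  out <- if (significant_only) rep$significant else rep$full
  class(out) <- c("sca_report", "data.frame")
  out
}

#' @export
print.sca_report <- function(x, n = 20L, ...) {
  cat(sprintf("Significance report (%d rows; showing up to %d)\n",
              nrow(x), n))
  print.data.frame(utils::head(x, n), digits = 4L, row.names = FALSE)
  invisible(x)
}

#' Observed AUC differences of a fitted analysis
#'
#' @param object An `sca` fit.
#' @param contrast Contrast name; defaults to the first one.
#' @param ... Unused.
#' @return Named list of per-region delta-AUC vectors, one per subcase.
#' @export
coef.sca <- function(object, contrast = NULL, ...) {
  contrast <- contrast %||% names(object$contrasts)[1L]
  object$contrasts[[contrast]]$delta
}

#' Null-distribution plot for one subcase and region
#'
#' Histogram of the permutation null of the AUC difference with the
#' observed value as a dashed vertical line — the standard visual check on
#' a permutation result.
#'
#' @param x An `sca` fit.
#' @param subcase Subcase label (e.g. `"MC.degree"`); default: first.
#' @param region Region name or index; default: smallest p in the subcase.
#' @param contrast Contrast name; default: first.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.sca <- function(x, subcase = NULL, region = NULL, contrast = NULL, ...) {
  contrast <- contrast %||% names(x$contrasts)[1L]
  cf <- x$contrasts[[contrast]]
  subcase <- subcase %||% x$subcases$subcase[1L]
  null <- cf$null[[subcase]]
  delta <- cf$delta[[subcase]]
  if (is.null(region)) region <- which.min(cf$p[[subcase]])
  if (is.character(region)) region <- match(region, names(delta))
  rname <- names(delta)[region] %||% as.character(region)
  graphics::hist(null[, region], breaks = 40L,
                 main = sprintf("%s / %s / %s", contrast, subcase, rname),
                 xlab = expression(Delta[AUC]), col = "grey85",
                 border = "grey40", ...)
  graphics::abline(v = delta[region], lty = 2L, lwd = 2L)
  invisible(x)
}
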