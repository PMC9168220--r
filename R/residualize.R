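#' Regress confounds out of a morphometric table
#'
#' Removes the linear effects of age, gender and total gray-matter volume
#' from every region by ordinary least squares, within a single group. The
#' design is `[intercept, age, gender, total_gmv]`; residuals therefore have
#' zero mean per region and are orthogonal to every covariate column. All
#' covariance computations in the pipeline operate on these residuals.
#'
#' @param values Numeric subjects x regions matrix for one group and one
#'   property; rows must align with `covariates`.
#' @param covariates data.frame (or matrix) with columns `age`, `gender`,
#'   `total_gmv`, one row per subject of `values`.
#' @return Residual matrix of the same shape and dimnames as `values`.
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' cv <- data.frame(age = rnorm(10, 70, 8), gender = rep(0:1, 5),
#'                  total_gmv = rnorm(10, 6e5, 6e4))
#' r <- residualize(x, cv)
#' max(abs(colMeans(r)))            # ~0: intercept removed
#' max(abs(crossprod(r, cv$age)))   # ~0: orthogonal to age
#' @export
residualize <- function(values, covariates) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (anyNA(values)) stop("values contain missing entries")
  need <- c("age", "gender", "total_gmv")
  if (!all(need %in% colnames(covariates)))
    stop("covariates must have columns: ", paste(need, collapse = ", "))
  if (nrow(covariates) != nrow(values))
    stop("covariate rows (", nrow(covariates),
         ") do not align with subject rows (", nrow(values), ")")
  X <- cbind(intercept = 1,
             age = as.numeric(covariates[["age"]]),
             gender = as.numeric(covariates[["gender"]]),
             total_gmv = as.numeric(covariates[["total_gmv"]]))
  if (nrow(X) < ncol(X) + 1L)
    stop("need more subjects (", nrow(X), ") than covariates + 1 (",
         ncol(X) + 1L, ")")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("degenerate confound design: column(s) ",
         paste(dropped, collapse = ", "),
         " are collinear with the rest (e.g. a constant column)")
  }
  res <- qr.resid(qx, values)
  dimnames(res) <- dimnames(values)
  res
}

#' Residualize every property table of a cohort, separately per group
#'
#' Applies [residualize()] to each group's tables using that group's own
#' covariates, so one group's subjects never influence another group's
#' residuals.
#'
#' @param cohort An `sca_cohort` (from [simulate_cohort()] or assembled from
#'   files); must carry `data` and `subjects`.
#' @return The cohort with `data` replaced by residual tables and a
#'   `residualized` flag set.
#' @export
residualize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "sca_cohort"))
  if (isTRUE(cohort$residualized)) return(cohort)
  for (g in names(cohort$data)) {
    covs <- cohort$subjects[cohort$subjects$group == g,
                            c("age", "gender", "total_gmv"), drop = FALSE]
    cohort$data[[g]] <- lapply(cohort$data[[g]], residualize, covariates = covs)
  }
  cohort$residualized <- TRUE
  cohort
}
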