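#' Read a subjects x regions morphometry table
#'
#' Expects tab-delimited text with a header: first column the subject id,
#' remaining columns named after atlas regions (any column order; the
#' result is aligned to the requested region order). This is the layout of
#' Freesurfer-style stats-to-table exports.
#'
#' @param path File path.
#' @param regions Character vector of required region names, in the order
#'   the returned matrix should have (e.g. `atlas$name[atlas$cortical]`).
#' @return Numeric matrix, subjects x regions, with subject-id rownames.
#' @export
read_morphometry_table <- function(path, regions) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table needs a subject column plus region columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  have <- colnames(df)[-1L]
  missing <- setdiff(regions, have)
  if (length(missing))
    stop("table ", path, " is missing region column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(have, regions)
  if (length(extra))
    warning("ignoring non-atlas column(s): ", paste(extra, collapse = ", "))
  vals <- df[, regions, drop = FALSE]
  for (cn in regions) {
    v <- vals[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        stop("non-numeric cell in column '", cn, "', row ", bad[1L],
             " (subject ", ids[bad[1L]], "): '", v[bad[1L]], "'")
      vals[[cn]] <- conv
    }
  }
  M <- as.matrix(vals)
  if (anyNA(M)) stop("missing values in ", path)
  rownames(M) <- ids
  M
}

#' Write a subjects x regions morphometry table
#'
#' Inverse of [read_morphometry_table()]; round-trips exactly at full
#' double precision.
#'
#' @param values Numeric matrix with subject rownames and region colnames.
#' @param path Output file path.
#' @export
write_morphometry_table <- function(values, path) {
  df <- data.frame(subject_id = rownames(values) %||%
                     sprintf("S%03d", seq_len(nrow(values))),
                   values, check.names = FALSE)
  utils::write.table(format(df, digits = 17L, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to a directory of tabular files
#'
#' One table per (group, property), plus `subjects.tsv` and `atlas.tsv` —
#' the same formats [read_cohort()] consumes, so the synthetic generator
#' doubles as a fixture factory.
#'
#' @param cohort An `sca_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sca_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(cohort$data))
    for (p in names(cohort$data[[g]]))
      write_morphometry_table(cohort$data[[g]][[p]],
                              file.path(dir, paste0(g, "_", p, ".tsv")))
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cohort$atlas), file.path(dir, "atlas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory holding `<group>_<property>.tsv` tables,
#'   `subjects.tsv` and `atlas.tsv`.
#' @return An `sca_cohort` (raw, not residualized).
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.delim(file.path(dir, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  subjects$pair_id[is.na(subjects$pair_id)] <- ""
  atlas <- utils::read.delim(file.path(dir, "atlas.tsv"),
                             stringsAsFactors = FALSE)
  class(atlas) <- c("region_atlas", "data.frame")
  files <- list.files(dir, pattern = "^[A-Za-z_]+_[A-Z]+\\.tsv$")
  data <- list()
  for (f in files) {
    stem <- sub("\\.tsv$", "", f)
    p <- sub(".*_", "", stem)
    g <- sub(paste0("_", p, "$"), "", stem)
    regions <- if (p == "VOL") atlas$name[!atlas$cortical]
               else atlas$name[atlas$cortical]
    data[[g]][[p]] <- read_morphometry_table(file.path(dir, f), regions)
  }
  # order property tables consistently and groups canonically
  data <- data[order(names(data))]
  structure(list(data = data, subjects = subjects, atlas = atlas,
                 config = NULL),
            class = "sca_cohort")
}

#' Pooled-variance two-sample t-test from summary moments
#'
#' Recomputes a two-sample comparison from printed group means, standard
#' deviations and sizes (as in demographic/clinical summary tables), using
#' the pooled-variance t statistic with `df = n1 + n2 - 2` and a two-sided
#' p-value.
#'
#' @param mean1,sd1,n1 First group's moments and size.
#' @param mean2,sd2,n2 Second group's moments and size.
#' @return List with `t`, `df` and `p`.
#' @examples
#' # pre- vs post-intervention activities-of-daily-living score
#' two_sample_t_from_summary(29.59, 11.39, 34, 6.03, 11.26, 34)
#' @export
two_sample_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2L || n2 < 2L) stop("sample sizes must be at least 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate/read -> residualize -> covariance graphs -> metrics ->
#' permutation inference -> report, writes all artifacts to the output
#' directory, and returns the fit. Given the same configuration and seed
#' the outputs are byte-identical.
#'
#' @param config A named list, or path to a YAML file holding one, with
#'   elements: `input_dir` (cohort directory) or `simulate` (arguments for
#'   [cohort_config()]); optional `grid` (list: `rho_min`, `rho_max`,
#'   `step`), `contrasts`, `n_permutations`, `shuffle_scheme`, `fdr_scope`,
#'   `alpha1`, `alpha2`, `check_connected`, `seed`; and `output_dir`.
#' @return The `sca` fit, invisibly. Artifacts written: `report.tsv`,
#'   `significant.tsv`, `auc_delta_<contrast>.tsv` and `manifest.json`.
#' @export
run_sca_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  seed <- as.integer(config$seed %||% 1L)
  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else if (!is.null(config$simulate)) {
    simulate_cohort(do.call(cohort_config,
                            c(config$simulate, list(seed = seed))))
  } else stop("config needs input_dir or simulate")
  grid <- if (is.null(config$grid)) density_grid()
          else do.call(density_grid, config$grid)
  contrasts <- config$contrasts %||% c("HC_minus_ETpre", "ETpost_minus_ETpre")
  contrasts <- intersect(contrasts,
                         c(if (all(c("HC", "ET_pre") %in% names(cohort$data)))
                             "HC_minus_ETpre",
                           if (all(c("ET_post", "ET_pre") %in% names(cohort$data)))
                             "ETpost_minus_ETpre"))
  if (!length(contrasts)) stop("no requested contrast is computable from the cohort")
  fit <- sca(cohort, contrasts = contrasts, grid = grid,
             n_permutations = as.integer(config$n_permutations %||% 8000L),
             shuffle_scheme = config$shuffle_scheme %||% "unrestricted",
             fdr_scope = config$fdr_scope %||% "pooled_across_subcases",
             alpha1 = config$alpha1 %||% 0.01,
             alpha2 = config$alpha2 %||% 0.001,
             seed = seed,
             check_connected = config$check_connected %||% TRUE)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  rep <- significance_report(fit)
  utils::write.table(rep$full, file.path(out, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rep$significant, file.path(out, "significant.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(fit$contrasts)) {
    d <- fit$contrasts[[nm]]$delta
    long <- do.call(rbind, lapply(names(d), function(sc)
      data.frame(subcase = sc, region = names(d[[sc]]),
                 delta_auc = unname(d[[sc]]))))
    utils::write.table(long, file.path(out, paste0("auc_delta_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    config = config, config_md5 = unname(tools::md5sum(tmp)), seed = seed,
    grid = list(rho_min = min(grid), rho_max = max(grid),
                n_points = length(grid)),
    package_version = as.character(utils::packageVersion("scna")),
    r_version = R.version.string)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}

#' Write a weighted adjacency matrix as tabular text
#'
#' Dense regions x regions matrix with region names as header and first
#' column.
#'
#' @param adjacency Square matrix (e.g. from [threshold_to_density()]).
#' @param path Output file path.
#' @export
write_adjacency <- function(adjacency, path) {
  nm <- rownames(adjacency) %||% sprintf("R%03d", seq_len(nrow(adjacency)))
  df <- data.frame(region = nm, adjacency, check.names = FALSE)
  colnames(df) <- c("region", colnames(adjacency) %||% nm)
  utils::write.table(format(df, digits = 17L, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph as a weighted edge list
#'
#' One `(source, target, weight)` row per nonzero edge; undirected graphs
#' emit each unordered pair once (upper triangle), directed graphs emit
#' ordered pairs. The format is importable by standard graph tooling.
#'
#' @param adjacency Square nonnegative matrix.
#' @param path Output file path.
#' @param directed Treat the matrix as directed.
#' @export
write_edge_list <- function(adjacency, path, directed = FALSE) {
  nm <- rownames(adjacency) %||% sprintf("R%03d", seq_len(nrow(adjacency)))
  keep <- if (directed) adjacency != 0 & row(adjacency) != col(adjacency)
          else adjacency != 0 & row(adjacency) < col(adjacency)
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(source = nm[idx[, 1L]], target = nm[idx[, 2L]],
                   weight = adjacency[idx])
  df <- df[order(df$source, df$target), ]
  utils::write.table(format(df, digits = 17L, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reshape metric curves to a long-format table
#'
#' @param curves Named list of regions x densities matrices
#'   (from [metric_curves()]).
#' @param grid The [density_grid()] the curves were computed on.
#' @param group,case Labels attached to every row.
#' @return data.frame: `region`, `group`, `case`, `metric`, `density`,
#'   `value`.
#' @export
metric_curves_long <- function(curves, grid, group = "group", case = "case") {
  out <- do.call(rbind, lapply(names(curves), function(m) {
    M <- curves[[m]]
    nm <- rownames(M) %||% sprintf("R%03d", seq_len(nrow(M)))
    data.frame(region = rep(nm, ncol(M)), group = group, case = case,
               metric = m,
               density = rep(as.numeric(grid), each = nrow(M)),
               value = as.vector(M))
  }))
  rownames(out) <- NULL
  out
}
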