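#' Fitted-parameter table for the 15 reference canopies
#'
#' Loads the bundled table of LAI and the six fitted switching-rate
#' parameters for 15 contrasting reference canopies (wheat and Bambara
#' groundnut assemblies at several planting densities).
#'
#' @param path optional path to an alternative CSV with the same columns
#'   (`canopy, lai, a_on, b1_on, b2_on, a_off, b1_off, b2_off`).
#' @return data frame.
#' @export
canopy_param_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_canopy_params.csv",
                        package = "canolux", mustWork = TRUE)
  tab <- read.csv(path, comment.char = "#")
  need <- c("canopy", "lai", "a_on", "b1_on", "b2_on",
            "a_off", "b1_off", "b2_off")
  if (!all(need %in% names(tab))) stop("parameter table missing columns")
  if (anyNA(tab[need])) stop("parameter table has missing cells")
  tab
}

#' Reference rate parameters for one canopy label
#' @param label canopy label (e.g. `"G"`).
#' @param table a parameter table; defaults to [canopy_param_table()].
#' @return a [rate_params()].
#' @export
reference_rate_params <- function(label, table = canopy_param_table()) {
  row <- table[table$canopy == label, ]
  if (nrow(row) != 1L) stop("unknown canopy label: ", label)
  rate_params(row$a_on, row$b1_on, row$b2_on,
              row$a_off, row$b1_off, row$b2_off)
}

#' PCA of fitted switching-rate parameters across canopies
#'
#' Principal component analysis based on the correlation matrix (columns
#' standardized) of the six rate parameters; LAI is excluded (it is the
#' external correlate). Components are signed so that the loading of largest
#' magnitude is positive.
#'
#' @param table a parameter table as from [canopy_param_table()] (>= 3 rows).
#' @return list of class `canopy_pca`: `loadings` (6 x 6), `var_explained`,
#'   `scores` (rows = canopies), `labels`.
#' @export
pca_params <- function(table) {
  cols <- c("a_on", "b1_on", "b2_on", "a_off", "b1_off", "b2_off")
  if (!all(cols %in% names(table))) stop("table missing parameter columns")
  m <- as.matrix(table[, cols])
  if (nrow(m) < 3L) stop("need at least 3 canopies for PCA")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant parameter column: zero variance under standardization")
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, k]))
    if (p$rotation[i, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  structure(list(loadings = p$rotation,
                 var_explained = p$sdev^2 / sum(p$sdev^2),
                 scores = p$x,
                 labels = table$canopy),
            class = "canopy_pca")
}

#' @export
print.canopy_pca <- function(x, ...) {
  cat("canopy_pca over", nrow(x$scores), "canopies; variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Correlation between a principal component and LAI
#'
#' Pearson correlation between the chosen component's scores and the LAI
#' column, reported as an absolute value (the sign of a PC is conventional).
#'
#' @param pca a `canopy_pca` from [pca_params()].
#' @param table the parameter table the PCA was computed from.
#' @param component component index (default 1).
#' @return |Pearson correlation|.
#' @export
pc_lai_correlation <- function(pca, table, component = 1L) {
  stopifnot(inherits(pca, "canopy_pca"))
  if (component < 1L || component > ncol(pca$scores))
    stop("invalid component index")
  abs(cor(pca$scores[, component], table$lai))
}

#' Compare sunlit/shaded duration distributions
#'
#' Builds histograms of the two sets of durations on a common binning and
#' reports the two-sample Kolmogorov-Smirnov statistic per state. Typical
#' use: durations extracted from ray-traced (or shading-oracle) data versus
#' durations simulated from the fitted stochastic model.
#'
#' @param durations_data,durations_model lists as returned by
#'   [duration_distributions()].
#' @param binwidth_min histogram bin width, minutes.
#' @return list with elements `sunlit` and `shaded`, each containing
#'   `ks_stat`, `p_value`, `breaks`, `counts_data`, `counts_model`.
#' @export
compare_durations <- function(durations_data, durations_model,
                              binwidth_min = 10) {
  one <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L)
      stop("empty duration set")
    top <- max(a, b) + binwidth_min
    breaks <- seq(0, top + binwidth_min, by = binwidth_min)
    ks <- suppressWarnings(ks.test(a, b))
    list(ks_stat = unname(ks$statistic), p_value = ks$p.value,
         breaks = breaks,
         counts_data = hist(a, breaks = breaks, plot = FALSE)$counts,
         counts_model = hist(b, breaks = breaks, plot = FALSE)$counts)
  }
  list(sunlit = one(durations_data$sunlit, durations_model$sunlit),
       shaded = one(durations_data$shaded, durations_model$shaded))
}

#' @importFrom graphics hist
NULL
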