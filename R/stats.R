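#' Mann-Whitney rank-sum comparison
#'
#' Two-sample rank-sum test used to compare diet breadth detected by direct
#' observation against pollen-load analysis. The reported statistic W counts
#' the (x, y) pairs with x > y, ties as 1/2 — so W below its null mean
#' n_x * n_y / 2 indicates the first sample tends to be smaller. The p-value
#' uses the normal approximation with the midrank tie correction and a
#' continuity correction (count data are heavily tied, which makes the exact
#' distribution ill-defined); set `exact = TRUE` to request the exact
#' distribution when there are no ties.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact,correct passed to [stats::wilcox.test()].
#' @return List with `statistic` (W), `p_value`, `n_x`, `n_y`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = FALSE, correct = TRUE) {
  if (length(x) == 0 || length(y) == 0) {
    stop("rank-sum test requires two non-empty samples")
  }
  ht <- stats::wilcox.test(x, y, exact = exact, correct = correct)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_x = length(x), n_y = length(y), method = ht$method)
}

#' Gaussian linear model of occurrence on diet breadth
#'
#' Ordinary least squares of the number of farms a bee species occupies on
#' its rarefied diet breadth, optionally with bee family and/or farm
#' management type as fixed factors (treatment coding, reference level =
#' alphabetically first). Errors on degenerate designs (collinear columns).
#'
#' @param data data.frame with columns `n_farms`, `rarefied_breadth`, and
#'   (as needed) `bee_family`, `farm_type`.
#' @param include_bee_family,include_farm_type add the factor to the model.
#' @return List with `coefficients` (data.frame: term, estimate, std_error,
#'   t, p), `adj_r_squared`, `df_residual`, `formula`, and the underlying
#'   `model`.
#' @export
gaussian_linear_fit <- function(data, include_bee_family = FALSE,
                                include_farm_type = FALSE) {
  if (nrow(data) < 3) stop("need at least 3 rows to fit the model")
  terms <- "rarefied_breadth"
  if (include_bee_family) {
    data$bee_family <- factor(data$bee_family)
    terms <- c(terms, "bee_family")
  }
  if (include_farm_type) {
    data$farm_type <- factor(data$farm_type)
    terms <- c(terms, "farm_type")
  }
  fml <- stats::reformulate(terms, response = "n_farms")
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("degenerate (collinear) design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  s <- summary(fit)
  co <- as.data.frame(s$coefficients)
  names(co) <- c("estimate", "std_error", "t", "p")
  co <- cbind(term = rownames(co), co, stringsAsFactors = FALSE)
  rownames(co) <- NULL
  list(coefficients = co, adj_r_squared = s$adj.r.squared,
       df_residual = fit$df.residual, formula = deparse(fml), model = fit)
}

#' Spearman rank correlation of diet breadth and occurrence
#'
#' Rank correlation (midranks for ties) between rarefied diet breadth and
#' number of farms occupied, for groups whose occurrence counts cannot be
#' brought to normality. Constant input has no defined rank correlation and
#' is signalled as an error.
#'
#' @param data data.frame with columns `rarefied_breadth` and `n_farms`.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rank <- function(data) {
  if (nrow(data) < 3) stop("need at least 3 rows")
  x <- data$rarefied_breadth
  y <- data$n_farms
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rank correlation undefined for constant input")
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = nrow(data))
}

#' Column means and standard errors of a paired breadth table
#'
#' Per-column mean and standard error (sd / sqrt(n)) over the numeric
#' columns of a diet-breadth table (e.g. plant species and families detected
#' by observation vs pollen loads). The SE of a single row is undefined and
#' reported as NA.
#'
#' @param table data.frame; non-numeric columns are ignored, NAs dropped
#'   per column.
#' @return data.frame with columns `column`, `mean`, `se`, `n`.
#' @export
summarise_breadth <- function(table) {
  if (nrow(table) == 0) stop("empty table")
  num <- vapply(table, is.numeric, logical(1))
  rows <- lapply(names(table)[num], function(col) {
    v <- table[[col]]
    v <- v[!is.na(v)]
    data.frame(column = col, mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
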