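# Treated-versus-control volcano selection and one-way ANOVA with Tukey's
# post-hoc test.

.matrix_areas <- function(features) {
  as.matrix(features[, setdiff(names(features), c("mz", "rt_s")),
                     drop = FALSE])
}

#' Volcano comparison of two sample groups
#'
#' Per feature: absent values are imputed as `impute_floor_frac` times the
#' smallest positive area observed anywhere in the matrix (adducts are
#' typically absent from controls, so a floor is needed for a defined fold
#' change); the fold change is `log2(mean_b / mean_a)` of imputed areas and
#' the p-value comes from a two-sided Welch t-test on log2 areas.
#'
#' @param features A `feature_matrix` from [assemble_features()] (or any
#'   data frame with `mz`, `rt_s` and sample area columns).
#' @param group_a,group_b Group labels; fold changes are b over a
#'   (a = control, b = treated in the usual design).
#' @param groups Named character vector mapping sample columns to group
#'   labels; defaults to the matrix `groups` attribute.
#' @param fc_thresh Fold-change selection threshold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param impute_floor_frac Fraction of the smallest positive area used as
#'   imputation floor (default 0.2).
#' @param adjust If `TRUE`, select on Benjamini-Hochberg adjusted p-values;
#'   default `FALSE` (selection on raw p).
#' @return Data frame: `mz`, `rt_s`, `log2fc`, `p`, `p_adj`, `selected`.
#' @export
volcano <- function(features, group_a, group_b,
                    groups = attr(features, "groups"),
                    fc_thresh = 2, alpha = 0.05,
                    impute_floor_frac = 0.2, adjust = FALSE) {
  if (!nrow(features)) stop("empty feature matrix")
  areas <- .matrix_areas(features)
  if (is.null(groups)) stop("no group labels available")
  ga <- colnames(areas)[groups[colnames(areas)] == group_a]
  gb <- colnames(areas)[groups[colnames(areas)] == group_b]
  if (length(ga) < 2L || length(gb) < 2L)
    stop("each group needs at least 2 samples")
  pos <- areas[areas > 0 & !is.na(areas)]
  if (!length(pos)) stop("no positive areas in matrix")
  floor_val <- impute_floor_frac * min(pos)
  areas[is.na(areas)] <- floor_val
  la <- log2(areas)
  p <- vapply(seq_len(nrow(areas)), function(i) {
    xa <- la[i, ga]; xb <- la[i, gb]
    if (stats::sd(c(xa, xb)) == 0) return(1)
    tryCatch(stats::t.test(xb, xa)$p.value,
             error = function(e) if (isTRUE(all.equal(mean(xa), mean(xb))))
               1 else 0)
  }, numeric(1))
  log2fc <- log2(rowMeans(areas[, gb, drop = FALSE]) /
                 rowMeans(areas[, ga, drop = FALSE]))
  p_adj <- stats::p.adjust(p, method = "BH")
  p_sel <- if (adjust) p_adj else p
  out <- data.frame(mz = features$mz, rt_s = features$rt_s,
                    log2fc = log2fc, p = p, p_adj = p_adj,
                    selected = abs(log2fc) >= log2(fc_thresh) & p_sel <= alpha)
  rownames(out) <- NULL
  out
}

#' Write volcano results to CSV
#'
#' @param res Data frame from [volcano()].
#' @param path Output CSV path; retention time is printed in minutes (2 d.p.).
#' @export
write_volcano <- function(res, path) {
  out <- data.frame(mz = res$mz, rt_min = round(res$rt_s / 60, 2),
                    log2fc = res$log2fc, p = res$p, p_adj = res$p_adj,
                    selected = res$selected)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' One-way ANOVA with Tukey's post-hoc test
#'
#' Standard one-way ANOVA decomposition followed by Tukey's honest
#' significant difference on the pooled within-group variance (studentized
#' range distribution; Tukey-Kramer for unequal group sizes).
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @param alpha Significance level used for the `significant` flag and the
#'   confidence level of the Tukey intervals (default 0.05).
#' @return A list of class `tukey_result`: `f_statistic`, `p_value`,
#'   `pairwise` (data frame `group1`, `group2`, `diff`, `p`, `significant`),
#'   `alpha`. With zero total variance the F test is undefined; by contract
#'   all p-values are 1 and a warning is issued.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 values")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  cmb <- utils::combn(names(groups), 2L)
  pairs <- data.frame(group1 = cmb[2, ], group2 = cmb[1, ])
  if (stats::var(value) == 0) {
    warning("zero total variance; all p-values set to 1")
    pw <- cbind(pairs, diff = 0, p = 1, significant = FALSE)
    return(structure(list(f_statistic = NaN, p_value = 1, pairwise = pw,
                          alpha = alpha), class = "tukey_result"))
  }
  fit <- stats::aov(value ~ g)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  key <- paste(pairs$group1, pairs$group2, sep = "-")
  tk <- tk[key, , drop = FALSE]
  pw <- cbind(pairs, diff = tk[, "diff"], p = tk[, "p adj"])
  pw$significant <- pw$p <= alpha
  rownames(pw) <- NULL
  structure(list(f_statistic = sm$`F value`[1], p_value = sm$`Pr(>F)`[1],
                 pairwise = pw, alpha = alpha), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g\n",
              x$f_statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}
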