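# Correlation, partial-correlation, CV and subject-summary statistics over
# Monte Carlo amplitude tables.

new_correlation_matrix <- function(r, n, note = NULL) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  structure(list(labels = rownames(r), r = r, n = n, note = note),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<correlation_matrix> %d labels%s%s\n", length(x$labels),
              if (is.na(x$n)) "" else sprintf(", n = %d", x$n),
              if (is.null(x$note)) "" else paste0(" (", x$note, ")")))
  print(round(x$r, digits))
  invisible(x)
}

#' Pearson correlation matrix of a Monte Carlo result
#'
#' Standard product-moment correlations between the fitted per-metabolite
#' columns across noise realizations. Constant columns yield `NA` entries
#' (flagged, excluded from summaries).
#'
#' @param result An `mc_result` (see [run_realizations()]) or a numeric
#'   matrix with metabolite columns.
#' @param which `"concentration"` (after ATP referencing; what the study
#'   correlates) or `"amplitude"` (raw fitted amplitudes; what the analytic
#'   oracle predicts).
#' @return A `correlation_matrix` with fields `labels`, `r`, `n`.
#' @export
pearson_matrix <- function(result, which = c("concentration", "amplitude")) {
  which <- match.arg(which)
  m <- if (inherits(result, "mc_result")) {
    if (which == "concentration") result$concentrations else result$amplitudes
  } else as.matrix(result)
  if (nrow(m) < 3) stop("need at least 3 realizations")
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  new_correlation_matrix(r, n = nrow(m))
}

#' Partial correlation of A and B given C
#'
#' `r_AB|C = (r_AB - r_AC r_BC) / (sqrt(1 - r_AC^2) sqrt(1 - r_BC^2))`:
#' the correlation between A and B with the linear influence of the
#' intervening variable C removed. If the partial correlation is much
#' smaller than `r_AB`, the raw correlation is considered spurious.
#'
#' @param r_ab,r_ac,r_bc Pearson coefficients, each in `[-1, 1]`;
#'   `|r_ac| < 1` and `|r_bc| < 1`.
#' @return The partial correlation coefficient.
#' @export
#' @examples
#' partial_correlation(0.5, 0, 0)        # 0.5: no confounder
#' partial_correlation(0.30, 0.60, 0.50) # 0: fully explained by C
partial_correlation <- function(r_ab, r_ac, r_bc) {
  vals <- c(r_ab, r_ac, r_bc)
  if (any(!is.finite(vals)) || any(abs(vals) > 1))
    stop("correlations must be finite and within [-1, 1]")
  if (abs(r_ac) >= 1 || abs(r_bc) >= 1)
    stop("partial correlation undefined when |r_AC| = 1 or |r_BC| = 1")
  (r_ab - r_ac * r_bc) / (sqrt(1 - r_ac^2) * sqrt(1 - r_bc^2))
}

#' Coefficient-of-variation table of a Monte Carlo result
#'
#' `CV_m = 100 * sd(column m) / mean(column m)` (sample SD, n-1), in
#' percent. Columns with non-positive mean are flagged `NA`.
#'
#' @param result An `mc_result` or numeric matrix.
#' @param which `"concentration"` or `"amplitude"`.
#' @return Data frame with `metabolite`, `cv_percent`, plus condition
#'   metadata columns when available.
#' @export
cv_table <- function(result, which = c("concentration", "amplitude")) {
  which <- match.arg(which)
  m <- if (inherits(result, "mc_result")) {
    if (which == "concentration") result$concentrations else result$amplitudes
  } else as.matrix(result)
  if (nrow(m) < 3) stop("need at least 3 realizations")
  mu <- colMeans(m)
  cv <- ifelse(mu > 0, 100 * apply(m, 2, stats::sd) / mu, NA_real_)
  out <- data.frame(metabolite = colnames(m), cv_percent = as.numeric(cv),
                    row.names = NULL)
  if (inherits(result, "mc_result")) {
    out$field <- result$condition$field
    out$lb_factor <- result$condition$lb_factor
    out$baseline <- result$condition$baseline
  }
  out
}

#' Entrywise difference of two correlation matrices
#'
#' Computes `a - b` (convention: with-baseline minus without-baseline when
#' comparing baseline conditions).
#'
#' @param a,b `correlation_matrix` objects with identical labels.
#' @return Numeric matrix of differences.
#' @export
difference_matrix <- function(a, b) {
  if (!identical(a$labels, b$labels))
    stop("correlation matrices have different labels")
  a$r - b$r
}

#' Summarize per-subject correlation matrices across paired conditions
#'
#' For each metabolite pair: mean and SD of `r` across subjects in each
#' condition, plus the paired effect size (Cohen's d of the within-subject
#' condition differences, `mean(diff)/sd(diff)`) and an optional paired
#' two-sided t-test p-value. With zero difference SD the effect size is
#' flagged undefined (`NA` with `d_undefined = TRUE`).
#'
#' @param with_list,without_list Lists (one `correlation_matrix` per
#'   subject) for the two paired conditions, aligned by subject.
#' @param t_test If `TRUE`, add paired t-test p-values.
#' @return Data frame with one row per unordered metabolite pair.
#' @export
summarize_subjects <- function(with_list, without_list, t_test = TRUE) {
  stopifnot(length(with_list) == length(without_list),
            length(with_list) >= 2)
  labels <- with_list[[1]]$labels
  for (cm in c(with_list, without_list))
    if (!identical(cm$labels, labels)) stop("subject matrices must share labels")
  pairs <- which(upper.tri(with_list[[1]]$r), arr.ind = TRUE)
  n <- length(with_list)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    rw <- vapply(with_list, function(cm) cm$r[i, j], 0)
    ro <- vapply(without_list, function(cm) cm$r[i, j], 0)
    d <- rw - ro
    sd_d <- stats::sd(d)
    und <- !is.finite(sd_d) || sd_d == 0
    p <- NA_real_
    if (t_test && !und) p <- stats::t.test(rw, ro, paired = TRUE)$p.value
    data.frame(metabolite_a = labels[i], metabolite_b = labels[j],
               mean_with = mean(rw), sd_with = stats::sd(rw),
               mean_without = mean(ro), sd_without = stats::sd(ro),
               mean_diff = mean(d),
               effect_size_d = if (und) NA_real_ else mean(d) / sd_d,
               d_undefined = und, p_value = p, n_subjects = n)
  })
  do.call(rbind, rows)
}

#' Minimal correlation-matrix heatmap
#'
#' @param cm A `correlation_matrix`.
#' @param main Plot title.
#' @return Invisibly, `cm`.
#' @export
plot_correlation_matrix <- function(cm, main = NULL) {
  k <- length(cm$labels)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(seq_len(k), seq_len(k), t(cm$r[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "",
                  ylab = "", main = main)
  graphics::axis(1, seq_len(k), cm$labels, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(cm$labels), las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(cm)
}
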