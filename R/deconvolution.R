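## Group comparisons of ssGSEA enrichment scores: the forest-plot
## fold-change statistic FC_e = exp(mean ES_A - mean ES_B) with a t-based
## confidence interval and the matching paired/unpaired t-test p-value.

#' Enrichment-score fold changes between groups
#'
#' For each signature row of an enrichment matrix, computes the natural
#' anti-log fold change `FC_e = exp(mean ES_A - mean ES_B)`, the
#' exponentiated t-based confidence interval of the mean difference (the
#' raw-difference CI is reported alongside), and the p-value of the
#' matching paired or unpaired t-test. Rows with degenerate variance are
#' flagged.
#'
#' @param es numeric matrix, signatures x samples (e.g. from
#'   [ssgseaMatrix()]).
#' @param annotation validated annotation `data.frame`.
#' @param design see [resolveComparison()]; paired uses post vs pre,
#'   unpaired CR vs NR.
#' @param varianceMode `"pooled"` (default) or `"welch"` for unpaired
#'   designs.
#' @param ciLevel confidence level (default 0.95).
#' @return `data.frame`: `signature`, `fold_change`, `ci_low`, `ci_high`,
#'   `mean_diff`, `raw_ci_low`, `raw_ci_high`, `p_value`, `significant`
#'   (p < 0.05 two-tailed), `design`, `degenerate`.
#' @export
scoreFoldChange <- function(es, annotation, design = "paired_post_vs_pre",
                            varianceMode = c("pooled", "welch"),
                            ciLevel = 0.95) {
  varianceMode <- match.arg(varianceMode)
  cmp <- resolveComparison(annotation, design)
  alpha <- 1 - ciLevel
  rows <- lapply(rownames(es), function(nm) {
    x <- es[nm, ]
    if (cmp$design == "paired_post_vs_pre") {
      d <- x[cmp$pairs$post] - x[cmp$pairs$pre]
      n <- length(d)
      mu <- mean(d)
      se <- stats::sd(d) / sqrt(n)
      df <- n - 1
    } else {
      a <- x[cmp$groupA]; b <- x[cmp$groupB]
      na <- length(a); nb <- length(b)
      mu <- mean(a) - mean(b)
      if (varianceMode == "pooled") {
        sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
          (na + nb - 2)
        se <- sqrt(sp2 * (1 / na + 1 / nb))
        df <- na + nb - 2
      } else {
        va <- stats::var(a) / na; vb <- stats::var(b) / nb
        se <- sqrt(va + vb)
        df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
      }
    }
    degenerate <- !is.finite(se) || se == 0
    if (degenerate) {
      tstat <- NA_real_; p <- 1
      lo <- mu; hi <- mu
    } else {
      tstat <- mu / se
      p <- 2 * stats::pt(-abs(tstat), df = df)
      tc <- stats::qt(1 - alpha / 2, df = df)
      lo <- mu - tc * se
      hi <- mu + tc * se
    }
    data.frame(signature = nm, fold_change = exp(mu), ci_low = exp(lo),
               ci_high = exp(hi), mean_diff = mu, raw_ci_low = lo,
               raw_ci_high = hi, p_value = p,
               significant = !degenerate & p < 0.05, design = cmp$design,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
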