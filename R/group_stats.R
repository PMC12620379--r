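# Channel-discrimination statistics: Lilliefors-corrected KS normality
# screening, one-way ANOVA per Higuchi attribute across the four groups,
# Tukey HSD post hoc, and mapping of significant attributes to channels.

#' Kolmogorov-Smirnov normality screen (Lilliefors correction)
#'
#' One-sample KS test of each group's values against a normal distribution
#' with estimated mean and SD. Because the parameters are estimated from the
#' sample, the Lilliefors-corrected test is used (flagged in the output);
#' below five observations the uncorrected KS test is substituted. Constant
#' samples are degenerate and reported as p = 0 with a warning.
#'
#' @param values numeric vector.
#' @param groups optional grouping, same length; `NULL` treats `values` as
#'   one sample.
#' @return data.frame: `group`, `n`, `p`, `method`.
#' @export
ks_normality <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(values))
  split_vals <- split(values, groups)
  rows <- lapply(names(split_vals), function(g) {
    v <- split_vals[[g]]
    if (length(v) < 3L) stop_input(sprintf("group %s has n < 3", g))
    if (stats::sd(v) == 0) {
      warning(sprintf("group %s is constant; reporting p = 0", g))
      return(data.frame(group = g, n = length(v), p = 0,
                        method = "degenerate", stringsAsFactors = FALSE))
    }
    if (length(v) >= 5L) {
      p <- nortest::lillie.test(v)$p.value
      meth <- "lilliefors"
    } else {
      p <- stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value
      meth <- "ks-estimated"
    }
    data.frame(group = g, n = length(v), p = p, method = meth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-way ANOVA across groups for every attribute
#'
#' Standard fixed-effects one-way ANOVA of each feature column against the
#' group factor. Significance is reported uncorrected at `alpha` (matching
#' the per-attribute screening convention) with a Bonferroni-adjusted column
#' alongside. Attributes with any group of fewer than two observations are
#' skipped with a warning.
#'
#' @param features n x p numeric table (e.g. the higu_ feature table).
#' @param groups group labels, length n (all groups present).
#' @param alpha significance level (default 0.05).
#' @return data.frame, one row per attribute: `attribute`, `F`, `p`,
#'   `p_bonferroni`, `significant`, `significant_bonferroni`, and per-group
#'   means `mean_<group>`.
#' @export
anova_per_attribute <- function(features, groups, alpha = 0.05) {
  features <- as.data.frame(features)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop_input("need at least two groups")
  if (any(table(g) < 2L)) {
    warning("a group has fewer than 2 observations; attributes skipped")
    return(NULL)
  }
  p_attr <- ncol(features)
  rows <- lapply(seq_len(p_attr), function(j) {
    v <- features[[j]]
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1]]
    Fv <- s[["F value"]][1]
    pv <- s[["Pr(>F)"]][1]
    means <- tapply(v, g, mean)
    out <- data.frame(attribute = colnames(features)[j], F = Fv, p = pv,
                      p_bonferroni = min(1, pv * p_attr),
                      significant = pv < alpha,
                      significant_bonferroni = min(1, pv * p_attr) < alpha,
                      stringsAsFactors = FALSE)
    for (lv in levels(g)) out[[paste0("mean_", lv)]] <- means[[lv]]
    out
  })
  do.call(rbind, rows)
}

#' Tukey HSD post hoc for one attribute
#'
#' All pairwise group-mean comparisons with studentized-range adjusted
#' p-values (single-step), following a one-way ANOVA fit.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`, `significant`
#'   (6 rows for 4 groups).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop_input("need at least two groups")
  if (any(table(g) < 2L)) stop_input("every group needs at least 2 observations")
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Channel attribution of significant attributes
#'
#' Maps the significant attributes of an ANOVA table to their channels and
#' electrode names via [feature_to_channel()], collapsing duplicates.
#'
#' @param anova_results output of [anova_per_attribute()] on higu_ columns.
#' @param montage electrode names in channel order.
#' @param use_bonferroni attribute significance column to use.
#' @return list: `attributes` (significant attribute names), `channels`
#'   (data.frame channel, electrode, attributes).
#' @export
attribute_channel_report <- function(anova_results,
                                     montage = montage_1020()$names,
                                     use_bonferroni = FALSE) {
  col <- if (use_bonferroni) "significant_bonferroni" else "significant"
  sig <- anova_results$attribute[anova_results[[col]]]
  if (length(sig) == 0L)
    return(list(attributes = character(0),
                channels = data.frame(channel = integer(0),
                                      electrode = character(0),
                                      attributes = character(0))))
  j <- as.integer(sub("^higu_", "", sig))
  map <- feature_to_channel(j, montage)
  ch <- sort(unique(map$channel))
  channels <- data.frame(
    channel = ch,
    electrode = montage[ch],
    attributes = vapply(ch, function(c0)
      paste(map$feature[map$channel == c0], collapse = ";"), ""),
    stringsAsFactors = FALSE)
  list(attributes = sig, channels = channels)
}
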