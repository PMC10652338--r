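# The study-style statistical toolbox: normality-gated two-group tests,
# cluster-aware (nested) t-test, Box-Cox transformation, one-way ANOVA with
# Tukey letters, categorical tests, and 4-parameter logistic calibration.

.test_result <- function(method, statistic, df, p_value, alpha = 0.05,
                         extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(method = method, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value), alpha = alpha),
              extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (%ssignificant at alpha %.2f)\n",
              x$method, x$statistic,
              if (!is.null(x$df) && !all(is.na(x$df)))
                paste0(", df = ", paste(signif(x$df, 4), collapse = ", ")) else "",
              x$p_value, if (x$p_value < x$alpha) "" else "not ", x$alpha))
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk is run on each group (alpha 0.05); if both pass, a two-sided
#' Student's t-test is used, otherwise a Mann-Whitney U (Wilcoxon rank-sum)
#' test. Kolmogorov-Smirnov normality p-values are reported alongside for
#' information but do not drive the decision.
#'
#' @param x,y numeric samples for the two groups.
#' @param alpha significance level (default 0.05).
#' @param var_equal passed to [stats::t.test()] (default FALSE, Welch).
#' @return a `test_result` with extras `normality` (per-group Shapiro-Wilk and
#'   KS p-values) and `gate` (`"t"` or `"mann-whitney"`).
#' @export
choose_two_group_test <- function(x, y, alpha = 0.05, var_equal = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("need at least 3 observations per group", call. = FALSE)
  }
  sw <- function(v) if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
  ks <- function(v) if (stats::sd(v) == 0) 0 else
    suppressWarnings(stats::ks.test(scale(v), "pnorm")$p.value)
  swp <- c(x = sw(x), y = sw(y))
  normal <- all(swp >= alpha)
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    .test_result("Student's t-test (two-sided)", tt$statistic, tt$parameter,
                 tt$p.value, alpha,
                 extra = list(gate = "t",
                              normality = list(shapiro_p = swp,
                                               ks_p = c(x = ks(x), y = ks(y)))))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    .test_result("Mann-Whitney U", wt$statistic, NA_real_, wt$p.value, alpha,
                 extra = list(gate = "mann-whitney",
                              normality = list(shapiro_p = swp,
                                               ks_p = c(x = ks(x), y = ks(y)))))
  }
}

#' Construct a grouped (clustered) sample
#'
#' @param values numeric measurements (e.g. one per COC).
#' @param cluster_id cluster of each value (e.g. mouse or patient).
#' @param group group label of each value (two levels for [nested_t_test()]).
#' @return object of class `grouped_sample`.
#' @export
grouped_sample <- function(values, cluster_id, group) {
  if (length(values) != length(cluster_id) || length(values) != length(group)) {
    stop("values, cluster_id and group must have equal length", call. = FALSE)
  }
  structure(list(values = as.numeric(values),
                 cluster_id = as.character(cluster_id),
                 group = as.character(group)),
            class = "grouped_sample")
}

#' Nested (cluster-aware) t-test
#'
#' Observations from the same animal/patient are not independent; the nested
#' t-test compares group means at the cluster level: each cluster is reduced
#' to its mean and a two-sided Student's t-test (equal variances,
#' `df = n_clusters - 2`) is run on the cluster means. For balanced designs
#' this matches the nested-ANOVA formulation with clusters as subgroups.
#'
#' @param s a [grouped_sample()] with exactly two groups and >= 2 clusters per
#'   group.
#' @return a `test_result` with extra `cluster_means`.
#' @export
nested_t_test <- function(s) {
  stopifnot(inherits(s, "grouped_sample"))
  groups <- unique(s$group)
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  cm <- tapply(s$values, list(s$cluster_id, s$group), mean)
  means <- lapply(groups, function(g) {
    v <- cm[, g]; v[!is.na(v)]
  })
  if (any(lengths(means) < 2L)) {
    stop("need >= 2 clusters per group", call. = FALSE)
  }
  if (stats::var(unlist(means)) == 0) {
    return(.test_result("nested t-test (cluster means)", 0,
                        sum(lengths(means)) - 2L, 1,
                        extra = list(cluster_means = means)))
  }
  tt <- stats::t.test(means[[1L]], means[[2L]], var.equal = TRUE)
  .test_result("nested t-test (cluster means)", tt$statistic, tt$parameter,
               tt$p.value, extra = list(cluster_means = means))
}

#' Box-Cox power transformation
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0`; strictly increasing in `y`.
#' The default lambda -0.4242 is the value used for HA polydispersity
#' comparisons in human follicular fluid.
#'
#' @param y positive numeric values.
#' @param lambda transformation exponent (nonzero; default -0.4242).
#' @return transformed values.
#' @export
boxcox_transform <- function(y, lambda = -0.4242) {
  if (lambda == 0) stop("lambda must be nonzero (use log for lambda = 0)",
                        call. = FALSE)
  if (any(y <= 0)) stop("Box-Cox requires positive values", call. = FALSE)
  (y^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @param z transformed values.
#' @return `boxcox_inverse(z)` recovers the original scale.
#' @export
boxcox_inverse <- function(z, lambda = -0.4242) {
  if (lambda == 0) stop("lambda must be nonzero", call. = FALSE)
  (lambda * z + 1)^(1 / lambda)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Omnibus F-test across >= 3 groups followed by Tukey honest significant
#' difference pairwise comparisons; groups sharing no letter are significantly
#' different (letters via insert-and-absorb).
#'
#' @param values numeric measurements.
#' @param group group label per value (>= 3 levels).
#' @param alpha significance level (default 0.05).
#' @return a `test_result` with extras `tukey` (pairwise table) and `letters`
#'   (named character vector, one letter set per group).
#' @export
anova_tukey <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 3L) {
    stop("anova_tukey needs >= 3 groups (use the two-group path otherwise)",
         call. = FALSE)
  }
  d <- data.frame(y = as.numeric(values), g = group)
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1L]]
  if (stats::var(d$y) == 0) {
    letters <- stats::setNames(rep("a", nlevels(group)), levels(group))
    return(.test_result("one-way ANOVA", 0, c(an$Df[1L], an$Df[2L]), 1, alpha,
                        extra = list(tukey = NULL, letters = letters)))
  }
  tk <- stats::TukeyHSD(fit)$g
  pmat <- matrix(FALSE, nlevels(group), nlevels(group),
                 dimnames = list(levels(group), levels(group)))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    sig <- tk[i, "p adj"] < alpha
    pmat[a, b] <- pmat[b, a] <- sig
  }
  letters <- compact_letters(pmat)
  .test_result("one-way ANOVA", an$`F value`[1L], c(an$Df[1L], an$Df[2L]),
               an$`Pr(>F)`[1L], alpha,
               extra = list(tukey = as.data.frame(tk), letters = letters))
}

#' Compact letter display from a significance matrix
#'
#' Insert-and-absorb algorithm: start with one letter covering all groups;
#' for each significantly different pair split every letter containing both;
#' absorb letters that are subsets of others. Groups sharing a letter are not
#' significantly different.
#'
#' @param sig_matrix square logical matrix, `TRUE` where the pair differs
#'   significantly; dimnames are group names.
#' @return named character vector of letter strings per group.
#' @export
compact_letters <- function(sig_matrix) {
  g <- rownames(sig_matrix)
  sets <- list(g)
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (j <= i || !sig_matrix[i, j]) next
    for (k in seq_along(sets)) {
      s <- sets[[k]]
      if (all(c(g[i], g[j]) %in% s)) {
        sets[[k]] <- setdiff(s, g[i])
        sets[[length(sets) + 1L]] <- setdiff(s, g[j])
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
          !(all(sets[[b]] %in% sets[[a]]) && a < b)) {
        keep[a] <- FALSE
      }
    }
    sets <- sets[keep]
  }
  sets <- sets[lengths(sets) > 0L]
  out <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(sets)) {
    for (m in sets[[k]]) out[m] <- paste0(out[m], letters[k])
  }
  out
}

#' Categorical association test
#'
#' Fisher's exact test when any expected count is 5 or less (the chi-square
#' approximation needs all expected counts to exceed 5), otherwise the
#' chi-square test; the rule applied is recorded in the result.
#'
#' @param tab contingency table (matrix of counts, e.g. 2 x k).
#' @param alpha significance level (default 0.05).
#' @return a `test_result` with extra `rule`.
#' @export
categorical_test <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) {
    ft <- stats::fisher.test(tab)
    .test_result("Fisher's exact test", NA_real_, NA_real_, ft$p.value, alpha,
                 extra = list(rule = "expected count <= 5"))
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    .test_result("chi-square test", ct$statistic, ct$parameter, ct$p.value,
                 alpha, extra = list(rule = "all expected counts > 5"))
  }
}

#' Fit a four-parameter logistic (4PL) calibration curve
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x/c)^b)`: `a` is the response
#' at zero concentration, `d` the response at infinite concentration, `c` the
#' inflection concentration (EC50) and `b` the slope. Used to read ELISA
#' standard curves.
#'
#' @param conc standard concentrations (> 0).
#' @param resp measured responses.
#' @return object of class `logistic_4pl` with fields `a`, `b`, `c`, `d` and
#'   the `nls` fit.
#' @export
fit_4pl <- function(conc, resp) {
  stopifnot(length(conc) == length(resp), all(conc > 0), length(conc) >= 5L)
  o <- order(conc)
  conc <- conc[o]; resp <- resp[o]
  a0 <- resp[1L]; d0 <- resp[length(resp)]
  c0 <- exp(stats::approx(resp, log(conc), xout = (a0 + d0) / 2, ties = mean)$y)
  if (!is.finite(c0)) c0 <- exp(mean(log(range(conc))))
  b0 <- if (d0 > a0) 2 else -2
  # logit-log refinement of the slope start
  fr <- (resp - a0) / (d0 - a0)
  okf <- fr > 0.02 & fr < 0.98
  if (sum(okf) >= 3L) {
    lf <- stats::lm(log(fr[okf] / (1 - fr[okf])) ~ log(conc[okf]))
    sl <- unname(stats::coef(lf)[2L])
    if (is.finite(sl) && abs(sl) > 0.1) b0 <- if (d0 > a0) abs(sl) else -abs(sl)
  }
  # warnOnly + suppressWarnings: on noiseless standards the relative-offset
  # criterion cannot improve past machine precision and warns spuriously
  fit <- suppressWarnings(
    stats::nls(resp ~ d + (a - d) / (1 + (conc / c)^b),
               start = list(a = a0, b = b0, c = c0, d = d0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)))
  cf <- as.list(stats::coef(fit))
  structure(list(a = cf$a, b = cf$b, c = cf$c, d = cf$d, fit = fit),
            class = "logistic_4pl")
}

#' @export
print.logistic_4pl <- function(x, ...) {
  cat(sprintf("4PL: a = %.4g, b = %.4g, c = %.4g, d = %.4g\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Predict and invert a 4PL curve
#'
#' `predict_4pl` evaluates the curve; `invert_4pl` maps sample readings back
#' to concentrations. Readings at or beyond the asymptotes are flagged
#' out-of-range (`NA` concentration).
#'
#' @param fit a `logistic_4pl`.
#' @param conc concentrations to evaluate.
#' @return `predict_4pl`: responses; `invert_4pl`: data.frame
#'   `response`, `conc`, `flag` (`"ok"`/`"out-of-range"`).
#' @export
predict_4pl <- function(fit, conc) {
  fit$d + (fit$a - fit$d) / (1 + (conc / fit$c)^fit$b)
}

#' @rdname predict_4pl
#' @param resp sample readings to invert.
#' @export
invert_4pl <- function(fit, resp) {
  lo <- min(fit$a, fit$d); hi <- max(fit$a, fit$d)
  ok <- resp > lo & resp < hi
  conc <- rep(NA_real_, length(resp))
  conc[ok] <- fit$c * ((fit$a - fit$d) / (resp[ok] - fit$d) - 1)^(1 / fit$b)
  data.frame(response = resp, conc = conc,
             flag = ifelse(ok, "ok", "out-of-range"))
}
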