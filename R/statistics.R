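# Measurement-table statistics: descriptives, K-S normality, paired
# Wilcoxon signed-rank, one-way ANOVA with pooled-MSE Bonferroni post-hoc.

#' Load the packaged root-measurement table
#'
#' Twenty roots of seventeen teeth: per-root bucco-lingual (BL),
#' mesio-distal (MD) and root-length (RL) dimensions of the reference
#' model (`*_1`), the extracted test model (`*_2`), and their errors
#' (reference minus test), transcribed from the published measurement
#' table.
#'
#' @return data.frame with columns root_id, bl_1, bl_2, bl_error, md_1,
#'   md_2, md_error, rl_1, rl_2, rl_error (mm), 20 rows.
#' @export
loadTable1 <- function() {
  path <- system.file("extdata", "root_measurements.csv", package = "pdlroot",
                      mustWork = TRUE)
  read.csv(path)
}

#' Read a measurement table from CSV
#'
#' Expected columns: root_id, bl_1, bl_2, md_1, md_2, rl_1, rl_2. Error
#' columns are recomputed as reference minus test, never trusted from the
#' file.
#'
#' @param path CSV file path.
#' @return data.frame in the [loadTable1()] layout.
#' @export
readMeasurementTable <- function(path) {
  t <- read.csv(path)
  need <- c("bl_1", "bl_2", "md_1", "md_2", "rl_1", "rl_2")
  if (!all(need %in% names(t)))
    stop("measurement table must contain columns: ", paste(need, collapse = ", "))
  t$bl_error <- t$bl_1 - t$bl_2
  t$md_error <- t$md_1 - t$md_2
  t$rl_error <- t$rl_1 - t$rl_2
  t
}

#' Mean and sample SD of the dimensional errors
#'
#' @param table a measurement table (see [loadTable1()]), >= 2 rows.
#' @return data.frame with rows bl/md/rl and columns mean, sd (mm; SD with
#'   the n-1 denominator).
#' @export
descriptiveErrors <- function(table) {
  if (nrow(table) < 2L) stop("need at least 2 rows")
  cols <- c(bl = "bl_error", md = "md_error", rl = "rl_error")
  data.frame(dimension = names(cols),
             mean = vapply(cols, function(cn) mean(table[[cn]]), numeric(1)),
             sd = vapply(cols, function(cn) sd(table[[cn]]), numeric(1)),
             row.names = names(cols))
}

#' Kolmogorov-Smirnov normality test
#'
#' One-sample K-S against a normal with sample-estimated mean and SD;
#' `lilliefors = TRUE` applies the Lilliefors correction for the estimated
#' parameters instead.
#'
#' @param x numeric sample, n >= 5.
#' @param lilliefors use the Lilliefors-corrected variant.
#' @return p-value.
#' @export
ksNormality <- function(x, lilliefors = FALSE) {
  if (length(x) < 5L) stop("need at least 5 observations")
  if (sd(x) == 0) return(0)
  if (lilliefors) return(nortest::lillie.test(x)$p.value)
  suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of the paired differences a - b. Zero differences are
#' dropped (Wilcoxon convention); absolute differences are ranked with
#' average ranks for ties. For n <= 15 non-zero pairs the exact two-sided
#' p-value is computed from the full sign-flip distribution of the
#' positive-rank sum (a dynamic program over doubled ranks, exact also
#' under ties); larger samples use the normal approximation with the tie
#' correction.
#'
#' @param a,b paired numeric vectors of equal length >= 6.
#' @return list with `statistic` (positive-rank sum W), `p.value`, `n`
#'   (pairs after zero-drop) and `method`.
#' @export
wilcoxonPaired <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 6L) stop("need at least 6 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 15L) {
    r2 <- as.integer(round(2 * r))      # doubled ranks are integers
    f <- numeric(sum(r2) + 1L)          # f[s+1] = #assignments with W2 = s
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1L):length(f)] <- g[(ri + 1L):length(f)] + f[1:(length(f) - ri)]
      f <- g
    }
    w2 <- as.integer(round(2 * W))
    lo <- sum(f[1:(w2 + 1L)])
    hi <- sum(f[(w2 + 1L):length(f)])
    p <- min(1, 2 * min(lo, hi) / 2^n)
    method <- "exact sign-flip distribution"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p.value = p, n = n, method = method)
}

#' One-way ANOVA with Levene test and pooled-MSE Bonferroni post-hoc
#'
#' Standard one-way ANOVA across the groups; Levene's homogeneity test
#' (centred at the mean); pairwise two-sided t-tests using the pooled
#' ANOVA mean-square error with N - k degrees of freedom, p-values
#' multiplied by the number of comparisons and capped at 1 (the Bonferroni
#' post-hoc convention of the mainstream commercial statistics packages).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `levene_p`, and `pairwise` (data.frame:
#'   group1, group2, t, p_unadjusted, p_adjusted).
#' @export
anovaBonferroni <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  fit <- aov(x ~ g)
  tab <- anova(fit)
  Fv <- tab$`F value`[1]
  pv <- tab$`Pr(>F)`[1]
  mse <- tab$`Mean Sq`[2]
  dfe <- tab$Df[2]
  lev <- car::leveneTest(x, g, center = mean)
  levene_p <- lev$`Pr(>F)`[1]
  cmb <- utils::combn(names(groups), 2)
  k <- ncol(cmb)
  pw <- do.call(rbind, lapply(seq_len(k), function(i) {
    g1 <- cmb[1, i]; g2 <- cmb[2, i]
    n1 <- length(groups[[g1]]); n2 <- length(groups[[g2]])
    tstat <- (mean(groups[[g1]]) - mean(groups[[g2]])) /
      sqrt(mse * (1 / n1 + 1 / n2))
    pun <- 2 * pt(-abs(tstat), dfe)
    data.frame(group1 = g1, group2 = g2, t = tstat, p_unadjusted = pun,
               p_adjusted = min(1, k * pun))
  }))
  list(F = Fv, p = pv, levene_p = levene_p, pairwise = pw)
}

#' Full statistical report for a measurement table
#'
#' Runs the complete analysis: descriptive error statistics, K-S normality
#' for the six measurement columns, paired Wilcoxon signed-rank tests for
#' the three reference/test pairs, and one-way ANOVA with Levene test and
#' pooled-MSE Bonferroni post-hoc across the three error groups.
#'
#' @param table a measurement table (see [loadTable1()]).
#' @param alpha significance level for the flags (default 0.05).
#' @return object of class `pdlStatReport`: list with `descriptive`, `ks`,
#'   `wilcoxon`, `anova`, `alpha`, `n_rows`.
#' @export
buildReport <- function(table, alpha = 0.05) {
  if (is.null(table) || nrow(table) == 0L) stop("empty measurement table")
  desc <- descriptiveErrors(table)
  kcols <- c("bl_1", "md_1", "rl_1", "bl_2", "md_2", "rl_2")
  ks <- vapply(kcols, function(cn) ksNormality(table[[cn]]), numeric(1))
  pairs <- list(bl = c("bl_1", "bl_2"), md = c("md_1", "md_2"),
                rl = c("rl_1", "rl_2"))
  wil <- lapply(pairs, function(p) wilcoxonPaired(table[[p[1]]], table[[p[2]]]))
  an <- anovaBonferroni(list(bl = table$bl_error, md = table$md_error,
                             rl = table$rl_error))
  structure(list(descriptive = desc, ks = ks, wilcoxon = wil, anova = an,
                 alpha = alpha, n_rows = nrow(table)),
            class = "pdlStatReport")
}

#' @export
print.pdlStatReport <- function(x, ...) {
  cat(sprintf("Root measurement statistics (%d roots)\n", x$n_rows))
  cat("\nDimensional errors, reference - test (mm):\n")
  d <- x$descriptive
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s: %6.2f +/- %.2f\n", toupper(d$dimension[i]), d$mean[i], d$sd[i]))
  cat("\nK-S normality p-values:\n")
  cat(sprintf("  %s: %s\n", names(x$ks), signif(x$ks, 3)), sep = "")
  cat("\nWilcoxon signed-rank (reference vs test):\n")
  for (nm in names(x$wilcoxon)) {
    w <- x$wilcoxon[[nm]]
    cat(sprintf("  %s: W = %.1f, p = %.3g%s\n", toupper(nm), w$statistic,
                w$p.value, if (w$p.value < x$alpha) " *" else ""))
  }
  cat(sprintf("\nOne-way ANOVA across errors: F = %.2f, p = %.3g (Levene p = %.3g)\n",
              x$anova$F, x$anova$p, x$anova$levene_p))
  cat("Bonferroni post-hoc (pooled MSE):\n")
  pw <- x$anova$pairwise
  for (i in seq_len(nrow(pw)))
    cat(sprintf("  %s vs %s: adjusted p = %.3g%s\n", toupper(pw$group1[i]),
                toupper(pw$group2[i]), pw$p_adjusted[i],
                if (pw$p_adjusted[i] < x$alpha) " *" else ""))
  invisible(x)
}

#' Serialize a statistics report to JSON
#'
#' @param report a `pdlStatReport`.
#' @param path optional output path; if NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
reportToJSON <- function(report, path = NULL) {
  payload <- list(
    n_rows = report$n_rows,
    descriptive = report$descriptive,
    ks_p = as.list(report$ks),
    wilcoxon_p = lapply(report$wilcoxon, `[[`, "p.value"),
    anova = list(F = report$anova$F, p = report$anova$p,
                 levene_p = report$anova$levene_p,
                 bonferroni = report$anova$pairwise))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
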