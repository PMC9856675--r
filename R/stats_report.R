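#' Factorial ANOVA on saliency activations
#'
#' Fits `activation ~ electrode * band * category` (all interactions) on an
#' activation table, optionally with a random intercept per sample or per
#' subject (mixed-effects model via `lmer`, Satterthwaite denominator
#' degrees of freedom, type III sums of squares with sum-to-zero
#' contrasts). Reports F, numerator/denominator df and p for the three main
#' effects, three two-way interactions and the three-way interaction.
#'
#' @param table An `activation_table` from [extract_activations()] (columns
#'   `sample`, `subject`, `category`, `electrode`, `band`, `activation`).
#' @param random_intercept `"sample"` (default), `"subject"`, or `"none"`
#'   for a fixed-effects-only fit.
#' @return `data.frame` of class `anova_report`: `effect`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
factorial_anova <- function(table, random_intercept = c("sample", "subject", "none")) {
  random_intercept <- match.arg(random_intercept)
  table <- prepare_activation_table(table)
  cells <- table(table$electrode, table$band, table$category)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: electrode %s, band %s, category %s",
                 dimnames(cells)[[1]][empty[1]], dimnames(cells)[[2]][empty[2]],
                 dimnames(cells)[[3]][empty[3]]))
  }
  ctr <- list(electrode = stats::contr.sum, band = stats::contr.sum,
              category = stats::contr.sum)
  if (random_intercept == "none") {
    m <- stats::lm(activation ~ electrode * band * category, data = table,
                   contrasts = ctr)
    if (any(is.na(stats::coef(m)))) stop("rank-deficient fixed-effects design")
    a <- car::Anova(m, type = 3)
    keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
    out <- data.frame(effect = rownames(a)[keep], F = a$`F value`[keep],
                      df1 = a$Df[keep], df2 = m$df.residual,
                      p = a$`Pr(>F)`[keep])
  } else {
    g <- if (random_intercept == "sample") table$sample else table$subject
    table$grp <- factor(g)
    m <- lmerTest::lmer(activation ~ electrode * band * category + (1 | grp),
                        data = table, contrasts = ctr,
                        control = lme4::lmerControl(calc.derivs = FALSE))
    a <- stats::anova(m, type = 3)
    out <- data.frame(effect = rownames(a), F = a$`F value`,
                      df1 = a$NumDF, df2 = a$DenDF, p = a$`Pr(>F)`)
  }
  rownames(out) <- NULL
  class(out) <- c("anova_report", "data.frame")
  out
}

prepare_activation_table <- function(table) {
  stopifnot(all(c("category", "electrode", "band", "activation") %in% names(table)))
  table <- as.data.frame(table)
  table$electrode <- factor(table$electrode)
  table$band <- factor(table$band)
  table$category <- factor(as.character(table$category),
                           levels = intersect(rt_categories, unique(as.character(table$category))))
  table
}

#' Render ANOVA rows as report strings
#' @param report An `anova_report`.
#' @return Character vector like `"electrode: F(63, 13637) = 7.49, p = 1e-12"`.
#' @export
format_anova <- function(report) {
  sprintf("%s: F(%d, %s) = %.2f, p = %.3g", report$effect, report$df1,
          format(round(report$df2), trim = TRUE), report$F, report$p)
}

#' Tukey HSD posthoc contrasts between RT categories
#'
#' Within the queried cell (an electrode, a band, or their combination; or
#' the whole table), fits `activation ~ category` and tests all pairwise
#' category contrasts with studentized-range (Tukey) adjustment over the
#' within-cell contrast family.
#'
#' @param table An `activation_table`.
#' @param electrode Optional electrode to slice on.
#' @param band Optional band to slice on.
#' @return `data.frame` of class `posthoc_report`: `contrast`, `mean_1`,
#'   `mean_2`, `estimate`, `se`, `z_ratio`, `p_adj`.
#' @export
tukey_contrasts <- function(table, electrode = NULL, band = NULL) {
  table <- prepare_activation_table(table)
  if (!is.null(electrode)) table <- table[table$electrode %in% electrode, ]
  if (!is.null(band)) table <- table[table$band %in% band, ]
  table <- droplevels(table)
  if (nlevels(table$category) < 2) stop("need at least 2 categories in the cell")
  if (any(table(table$category) < 2)) stop("singleton category group in the cell")
  m <- stats::lm(activation ~ category, data = table)
  em <- emmeans::emmeans(m, ~category)
  pr <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  means <- as.data.frame(em)
  mlook <- stats::setNames(means$emmean, means$category)
  parts <- strsplit(as.character(pr$contrast), " - ")
  out <- data.frame(
    contrast = as.character(pr$contrast),
    mean_1 = mlook[vapply(parts, `[`, character(1), 1)],
    mean_2 = mlook[vapply(parts, `[`, character(1), 2)],
    estimate = pr$estimate, se = pr$SE,
    z_ratio = pr$t.ratio, p_adj = pr$p.value,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("posthoc_report", "data.frame")
  out
}

#' Tiered ranking of electrode activations
#'
#' Per (band, category), electrode activations are averaged over samples and
#' the 64 means are clustered with a 3-component univariate Gaussian
#' mixture; electrodes are assigned to `low` / `relevant` / `high` tiers by
#' ascending component mean.
#'
#' @param table An `activation_table`.
#' @param seed Integer seed for the mixture EM restarts.
#' @return `data.frame` of class `ranking_report`: `band`, `category`,
#'   `electrode`, `mean_activation`, `tier`.
#' @export
rank_activations <- function(table, seed = 1L) {
  table <- prepare_activation_table(table)
  out <- list()
  for (b in levels(table$band)) {
    for (cat in levels(table$category)) {
      sub <- table[table$band == b & table$category == cat, ]
      if (!nrow(sub)) next
      mu <- tapply(sub$activation, droplevels(sub$electrode), mean)
      if (length(unique(round(mu, 12))) < 3) {
        stop(sprintf("band %s category %s: fewer than 3 distinct electrode means", b, cat))
      }
      fit <- with_local_seed(seed, gmm1d_fit(as.numeric(mu), 3, "component", restarts = 10))
      resp <- gmm1d_responsibilities(fit$means, fit$variances, fit$weights,
                                     as.numeric(mu))
      comp <- max.col(resp, ties.method = "first")
      tiers <- c("low", "relevant", "high")[rank(fit$means)[comp]]
      out[[length(out) + 1]] <- data.frame(
        band = b, category = cat, electrode = names(mu),
        mean_activation = as.numeric(mu), tier = tiers,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ranking_report", "data.frame")
  res
}

#' Write a stats report (ANOVA/posthoc/ranking) to CSV
#' @param report A report `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
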