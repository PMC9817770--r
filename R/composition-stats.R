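#' Shapiro-Wilk normality screen
#'
#' Runs the Shapiro-Wilk test on one trait's values and emits the data for
#' a visual normal-quantile inspection alongside the formal test.
#'
#' @param x Numeric values (3 <= n <= 5000, not constant).
#' @param alpha Significance level for the pass flag (default 0.05).
#' @return List with `statistic`, `p_value`, `pass` (`p >= alpha`), and
#'   `qq` (data frame with `theoretical` and `sample` quantiles).
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L)
    stop("normality check needs at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("normality check is undefined for constant input", call. = FALSE)
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       pass = sw$p.value >= alpha,
       qq = data.frame(theoretical = stats::qnorm(stats::ppoints(length(x))),
                       sample = sort(x)))
}

# Insert-and-absorb compact letter display from a symmetric p-value matrix.
# Two groups share a letter iff their pairwise p >= alpha. Letters are
# ordered so the column containing the highest group mean gets "a"; group
# order inside the matrix is alphabetical for reproducibility.
.compact_letters <- function(pmat, means, alpha = 0.05) {
  groups <- sort(rownames(pmat))
  pmat <- pmat[groups, groups, drop = FALSE]
  cols <- list(groups)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  for (pr in pairs) {
    if (pmat[pr[1L], pr[2L]] >= alpha) next
    hit <- vapply(cols, function(cl) all(pr %in% cl), logical(1L))
    if (!any(hit)) next
    new_cols <- cols[!hit]
    for (cl in cols[hit]) {
      new_cols <- c(new_cols, list(setdiff(cl, pr[1L])),
                    list(setdiff(cl, pr[2L])))
    }
    # absorb: drop empty and duplicated/subset columns
    new_cols <- Filter(length, new_cols)
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
      if (i != j && keep[j] &&
          all(new_cols[[i]] %in% new_cols[[j]]) &&
          (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j))
        keep[i] <- FALSE
    }
    cols <- new_cols[keep]
  }
  ord <- order(-vapply(cols, function(cl) max(means[cl]), numeric(1L)),
               vapply(cols, function(cl) paste(cl, collapse = ""),
                      character(1L)))
  cols <- cols[ord]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    lab <- letters[i]
    for (g in cols[[i]])
      letters_out[g] <- paste0(letters_out[g], lab)
  }
  vapply(letters_out,
         function(s) paste(sort(strsplit(s, "")[[1L]]), collapse = ""),
         character(1L))
}

#' One-way ANOVA by breed with Tukey compact letter display
#'
#' Standard one-way analysis of variance of one trait on the breed factor,
#' followed by Tukey's honestly-significant-difference test on all breed
#' pairs (the Tukey--Kramer form handles unbalanced groups), and a compact
#' letter display derived from the pairwise matrix by the insert-and-absorb
#' algorithm: two breeds share a letter exactly when their Tukey p-value is
#' at least `alpha`. Group means are arithmetic means, which coincide with
#' least-squares means in a one-way layout.
#'
#' @param comp Composition table (long format, one row per pooled sample).
#' @param trait Trait column name.
#' @param group Grouping column (default `"breed"`).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `trait_anova`: `trait`, `group_stats` (data
#'   frame with group, n, mean, sd, letters), `f_statistic`, `p_value`,
#'   `tukey_p` (symmetric matrix), `letters`, `alpha`.
#' @export
anova_tukey <- function(comp, trait, group = "breed", alpha = 0.05) {
  d <- data.frame(y = as.numeric(comp[[trait]]),
                  g = as.character(comp[[group]]),
                  stringsAsFactors = FALSE)
  d <- d[stats::complete.cases(d), ]
  counts <- table(d$g)
  if (length(counts) < 2L)
    stop("ANOVA needs at least two groups", call. = FALSE)
  if (any(counts < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)
  d$g <- factor(d$g)
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  lv <- levels(d$g)
  pmat <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
  # reconstruct TukeyHSD row order ourselves: group labels may themselves
  # contain "-" (breed codes do), so the rownames cannot be split safely
  pairs <- utils::combn(lv, 2L)
  expected <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
  if (!identical(rownames(tk), expected))
    stop("unexpected TukeyHSD pair ordering", call. = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  means <- tapply(d$y, d$g, mean)
  lets <- .compact_letters(pmat, means, alpha)
  gs <- data.frame(group = lv, n = as.integer(table(d$g)[lv]),
                   mean = as.numeric(means[lv]),
                   sd = as.numeric(tapply(d$y, d$g, stats::sd)[lv]),
                   letters = unname(lets[lv]), stringsAsFactors = FALSE)
  structure(list(trait = trait, group_stats = gs,
                 f_statistic = an$`F value`[1L], p_value = an$`Pr(>F)`[1L],
                 tukey_p = pmat, letters = lets, alpha = alpha),
            class = "trait_anova")
}

#' @export
print.trait_anova <- function(x, ...) {
  cat(sprintf("<trait_anova> %s: F = %.2f, p = %.3g\n",
              x$trait, x$f_statistic, x$p_value))
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `""` otherwise.
#'
#' @param p Numeric p-value(s).
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else ""
  }, character(1L))
}

#' White- versus tinted-eggshell group contrast
#'
#' One-way ANOVA of one trait with the two-level shell-color factor, which
#' for two groups is equivalent to the pooled-variance two-sample
#' comparison (F equals the squared t statistic). Star annotations at the
#' 0.05/0.01/0.001 thresholds.
#'
#' @param comp Composition table with a `shell_group` column.
#' @param trait Trait column name.
#' @return An object of class `group_contrast`: `trait`, `group_stats`
#'   (mean, sd, n per shell group), `f_statistic`, `p_value`, `stars`.
#' @export
shell_group_contrast <- function(comp, trait) {
  d <- data.frame(y = as.numeric(comp[[trait]]),
                  g = as.character(comp$shell_group),
                  stringsAsFactors = FALSE)
  d <- d[stats::complete.cases(d), ]
  counts <- table(d$g)
  if (length(counts) != 2L)
    stop("shell contrast needs exactly two non-empty groups", call. = FALSE)
  if (any(counts < 2L))
    stop("each shell group needs at least 2 samples", call. = FALSE)
  d$g <- factor(d$g)
  an <- summary(stats::aov(y ~ g, data = d))[[1L]]
  gs <- data.frame(group = levels(d$g),
                   n = as.integer(counts[levels(d$g)]),
                   mean = as.numeric(tapply(d$y, d$g, mean)),
                   sd = as.numeric(tapply(d$y, d$g, stats::sd)),
                   stringsAsFactors = FALSE)
  p <- an$`Pr(>F)`[1L]
  structure(list(trait = trait, group_stats = gs,
                 f_statistic = an$`F value`[1L], p_value = p,
                 stars = significance_stars(p)),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast> %s: F = %.2f, p = %.3g %s\n",
              x$trait, x$f_statistic, x$p_value, x$stars))
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Breed-by-trait summary table with letters
#'
#' Renders the classic composition report: one row per trait, one column
#' per breed, cells formatted `"mean +/- sd ^letters^"` from [anova_tukey()].
#'
#' @param comp Composition table.
#' @param traits Character vector of trait columns (default: all trait
#'   columns present).
#' @param digits Rounding for mean and sd (default 2).
#' @return Data frame, rownames = traits, columns = breeds.
#' @export
composition_summary_table <- function(comp, traits = NULL, digits = 2L) {
  if (is.null(traits))
    traits <- grep("_(wb|dm)$", names(comp), value = TRUE)
  breeds <- unique(comp$breed)
  rows <- lapply(traits, function(tr) {
    res <- anova_tukey(comp, tr)
    gs <- res$group_stats
    cells <- sprintf("%.*f ± %.*f ^%s^", digits, gs$mean, digits, gs$sd,
                     gs$letters)
    stats::setNames(cells, gs$group)[breeds]
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- traits
  names(out) <- breeds
  out
}
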